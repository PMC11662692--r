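#' Export an interval table as BED
#'
#' @param intervals interval `data.frame` (0-based half-open).
#' @param path output path.
#' @param names optional name column (4th BED field).
#' @export
write_bed <- function(intervals, path, names = NULL) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   stringsAsFactors = FALSE)
  if (!is.null(names)) {
    df$name <- names
    df$score <- 0
    df$strand <- if (!is.null(intervals$strand)) intervals$strand else "*"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export an interval table in the SAF dialect
#'
#' SAF: GeneID, Chr, Start, End, Strand with 1-based inclusive
#' coordinates (the feature-counting convention).
#'
#' @param intervals interval `data.frame` (0-based half-open).
#' @param path output path.
#' @param ids feature identifiers (recycled).
#' @export
write_saf <- function(intervals, path, ids) {
  df <- data.frame(GeneID = rep_len(ids, nrow(intervals)),
                   Chr = intervals$chrom,
                   Start = intervals$start + 1L,
                   End = intervals$end,
                   Strand = if (!is.null(intervals$strand))
                     intervals$strand else "*",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an annotation database as GFF3
#'
#' Emits gene / mRNA (or transcript for noncoding biotypes) / exon / CDS
#' rows with 1-based inclusive coordinates.
#'
#' @param db an [annotation_db()].
#' @param path output path.
#' @export
write_gff3 <- function(db, path) {
  lines <- "##gff-version 3"
  g <- db$genes[order(db$genes$chrom, db$genes$span_start), , drop = FALSE]
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, paste(g$chrom[i], "drsage", "gene",
                            g$span_start[i] + 1L, g$span_end[i], ".",
                            g$strand[i], ".",
                            paste0("ID=", gid, ";biotype=", g$biotype[i]),
                            sep = "\t"))
    txs <- db$transcripts[db$transcripts$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[j]
      e <- db$exons[db$exons$transcript_id == tid, , drop = FALSE]
      cc <- db$cds[db$cds$transcript_id == tid, , drop = FALSE]
      ttype <- if (nrow(cc)) "mRNA" else "transcript"
      lines <- c(lines, paste(txs$chrom[j], "drsage", ttype,
                              min(e$start) + 1L, max(e$end), ".",
                              txs$strand[j], ".",
                              paste0("ID=", tid, ";Parent=", gid,
                                     ";biotype=", txs$biotype[j]),
                              sep = "\t"))
      for (k in seq_len(nrow(e)))
        lines <- c(lines, paste(e$chrom[k], "drsage", "exon",
                                e$start[k] + 1L, e$end[k], ".",
                                e$strand[k], ".",
                                paste0("ID=", tid, ".e", k, ";Parent=", tid),
                                sep = "\t"))
      for (k in seq_len(nrow(cc)))
        lines <- c(lines, paste(cc$chrom[k], "drsage", "CDS",
                                cc$start[k] + 1L, cc$end[k], ".",
                                cc$strand[k], "0",
                                paste0("ID=", tid, ".c", k, ";Parent=", tid),
                                sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a STAR-style SJ.out.tab junction table
#'
#' @param junctions `data.frame` in the internal convention (`chrom`,
#'   `start`, `end` 0-based half-open, `strand`, `unique_reads`, and
#'   optionally `motif`, `annotated_flag`, `multi_reads`,
#'   `max_overhang`).
#' @param path output path.
#' @export
write_sj_table <- function(junctions, path) {
  code <- c("*" = 0L, "+" = 1L, "-" = 2L)
  df <- data.frame(junctions$chrom,
                   junctions$start + 1L,
                   junctions$end,
                   code[junctions$strand],
                   if (!is.null(junctions$motif)) junctions$motif else 0L,
                   if (!is.null(junctions$annotated_flag))
                     junctions$annotated_flag else 0L,
                   junctions$unique_reads,
                   if (!is.null(junctions$multi_reads))
                     junctions$multi_reads else 0L,
                   if (!is.null(junctions$max_overhang))
                     junctions$max_overhang else 30L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# plain deterministic TSV writer for report tables
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
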