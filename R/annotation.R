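#' Build an annotation database from component tables
#'
#' The annotation database is the reference object every pipeline stage
#' compares against. It holds gene and transcript models plus the genome
#' and chromosome sizes; derived interval sets (stringent introns,
#' stringent intergenic, the junction database, TSS and 3'UTR-end sets)
#' are computed from it by the `derive_*` / `build_*` / `collect_*`
#' functions.
#'
#' @param transcripts `data.frame` with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `biotype`.
#' @param exons `data.frame` with columns `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param cds like `exons`, optional (rows only for coding transcripts).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param genome optional [Biostrings::DNAStringSet] covering all
#'   chromosomes.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(transcripts, exons, cds = NULL, chrom_sizes,
                          genome = NULL) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "biotype") %in% names(transcripts)))
  validate_intervals(exons)
  if (!is.null(cds) && nrow(cds)) validate_intervals(cds)
  missing_tx <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_tx))
    stop("transcript(s) with no exons: ", paste(missing_tx, collapse = ", "))
  bad_chrom <- setdiff(exons$chrom, names(chrom_sizes))
  if (length(bad_chrom))
    stop("exons on chromosome(s) absent from the genome: ",
         paste(bad_chrom, collapse = ", "))
  sz <- chrom_sizes[exons$chrom]
  over <- which(exons$end > sz)
  if (length(over))
    stop("exon outside chromosome bounds for transcript ",
         exons$transcript_id[over[1]], " (", exons$chrom[over[1]], ":",
         exons$start[over[1]], "-", exons$end[over[1]], ")")
  # order exons in genome order within transcript
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", tid)
  }
  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    for (tid in unique(cds$transcript_id)) {
      ce <- cds[cds$transcript_id == tid, , drop = FALSE]
      ee <- exons[exons$transcript_id == tid, , drop = FALSE]
      d <- interval_setdiff(ce, ee)
      if (nrow(d)) stop("CDS outside exon union in transcript ", tid)
    }
  } else {
    cds <- exons[0, , drop = FALSE]
  }
  tx2gene <- transcripts$gene_id[match(unique(transcripts$gene_id),
                                       transcripts$gene_id)]
  genes <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id),
    function(tt) {
      e <- exons[exons$transcript_id %in% tt$transcript_id, , drop = FALSE]
      data.frame(gene_id = tt$gene_id[1], chrom = tt$chrom[1],
                 strand = tt$strand[1], biotype = tt$biotype[1],
                 span_start = min(e$start), span_end = max(e$end),
                 stringsAsFactors = FALSE)
    }))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, chrom_sizes = chrom_sizes, genome = genome),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Parse a GFF3 annotation and genome FASTA
#'
#' Ingests gene / mRNA (or transcript) / exon / CDS features. GFF3
#' 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention; chromosome sizes are taken from the FASTA.
#' Feature types other than the four above are skipped (a message
#' reports how many).
#'
#' @param gff_path path to a GFF3 file.
#' @param fasta_path path to the genome FASTA.
#' @return An [annotation_db()].
#' @export
parse_gff <- function(gff_path, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_sizes <- stats::setNames(Biostrings::width(genome), names(genome))

  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  keep_types <- c("gene", "mRNA", "transcript", "exon", "CDS")
  skipped <- sum(!type %in% keep_types)
  if (skipped > 0)
    message("parse_gff: skipped ", skipped, " feature(s) of unhandled type")

  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, id = ids, parent = parents,
                   stringsAsFactors = FALSE)
  biotype <- rep(NA_character_, nrow(df))
  for (col in c("biotype", "gene_biotype", "so_term_name"))
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      biotype[is.na(biotype)] <- v[is.na(biotype)]
    }
  df$biotype <- biotype

  gene_rows <- df[df$type == "gene", , drop = FALSE]
  tx_rows <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (anyNA(tx_rows$id)) stop("transcript feature without an ID attribute")
  gene_biotype <- stats::setNames(gene_rows$biotype, gene_rows$id)

  transcripts <- data.frame(
    transcript_id = tx_rows$id,
    gene_id = ifelse(is.na(tx_rows$parent), tx_rows$id, tx_rows$parent),
    chrom = tx_rows$chrom, strand = tx_rows$strand,
    biotype = ifelse(!is.na(tx_rows$biotype), tx_rows$biotype,
      ifelse(!is.na(gene_biotype[tx_rows$parent]),
             gene_biotype[tx_rows$parent], "protein_coding")),
    stringsAsFactors = FALSE)

  exon_rows <- df[df$type == "exon" & df$parent %in% transcripts$transcript_id,
                  , drop = FALSE]
  cds_rows <- df[df$type == "CDS" & df$parent %in% transcripts$transcript_id,
                 , drop = FALSE]
  exons <- data.frame(transcript_id = exon_rows$parent,
                      chrom = exon_rows$chrom, start = exon_rows$start,
                      end = exon_rows$end, strand = exon_rows$strand,
                      stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = cds_rows$parent, chrom = cds_rows$chrom,
                    start = cds_rows$start, end = cds_rows$end,
                    strand = cds_rows$strand, stringsAsFactors = FALSE)
  annotation_db(transcripts, exons, cds, chrom_sizes, genome)
}

# inter-exon gaps (introns) of every transcript, one row per gap
transcript_introns <- function(db) {
  ex <- db$exons
  out <- lapply(split(ex, ex$transcript_id), function(e) {
    if (nrow(e) < 2) return(NULL)
    e <- e[order(e$start), , drop = FALSE]
    data.frame(transcript_id = e$transcript_id[1], chrom = e$chrom[1],
               start = e$end[-nrow(e)], end = e$start[-1],
               strand = e$strand[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res
}

#' Stringent intron set
#'
#' Regions lying between annotated exons within transcripts, minus any
#' region overlapping an annotated exon of any gene (all biotypes, both
#' strands). Returned unstranded as maximal disjoint intervals.
#'
#' @param db an [annotation_db()].
#' @return Interval `data.frame` (`chrom`, `start`, `end`, `strand = "*"`).
#' @export
derive_stringent_introns <- function(db) {
  gaps <- transcript_introns(db)
  if (nrow(gaps) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  interval_setdiff(gaps, db$exons)
}

#' Stringent intergenic set
#'
#' Complement of the union of transcript spans on each chromosome, minus
#' any annotated exon. With `include_termini = FALSE` (default) the
#' regions before the first and after the last transcript span on each
#' chromosome are dropped, so only regions lying *between* annotated
#' transcripts remain.
#'
#' @inheritParams derive_stringent_introns
#' @param include_termini keep chromosome-terminal regions?
#' @return Interval `data.frame`.
#' @export
derive_stringent_intergenic <- function(db, include_termini = FALSE) {
  spans <- do.call(rbind, lapply(split(db$exons, db$exons$transcript_id),
    function(e) data.frame(chrom = e$chrom[1], start = min(e$start),
                           end = max(e$end), stringsAsFactors = FALSE)))
  pieces <- lapply(names(db$chrom_sizes), function(ch) {
    sz <- db$chrom_sizes[[ch]]
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    whole <- data.frame(chrom = ch, start = 0L, end = sz,
                        stringsAsFactors = FALSE)
    if (nrow(sp) == 0) {
      if (include_termini) return(whole) else return(NULL)
    }
    comp <- interval_setdiff(whole, sp)
    if (!include_termini)
      comp <- comp[comp$start >= min(sp$start) & comp$end <= max(sp$end),
                   , drop = FALSE]
    comp
  })
  comp <- do.call(rbind, pieces)
  if (is.null(comp) || nrow(comp) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  res <- interval_setdiff(comp, db$exons)
  rownames(res) <- NULL
  res
}

#' Annotated splice-junction database
#'
#' One entry per distinct inter-exon gap (intron) across all
#' transcripts; introns shared by several transcripts collapse to one
#' row.
#'
#' @inheritParams derive_stringent_introns
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open intron coordinates).
#' @export
build_junction_db <- function(db) {
  gaps <- transcript_introns(db)
  if (nrow(gaps) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  key <- paste(gaps$chrom, gaps$start, gaps$end, gaps$strand)
  res <- gaps[!duplicated(key), c("chrom", "start", "end", "strand"),
              drop = FALSE]
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Median gene span length
#'
#' Gene span = max transcript end minus min transcript start over the
#' gene's transcripts. With an even number of genes the median is the
#' mean of the two middle values, rounded half away from zero (the
#' reference value for C. elegans is the integer 1956 nt).
#'
#' @inheritParams derive_stringent_introns
#' @return Integer median span.
#' @export
median_gene_length <- function(db) {
  if (nrow(db$genes) == 0) stop("annotation contains no genes")
  lens <- sort(db$genes$span_end - db$genes$span_start)
  n <- length(lens)
  if (n %% 2 == 1) as.integer(lens[(n + 1) / 2])
  else as.integer(.round_half_away((lens[n / 2] + lens[n / 2 + 1]) / 2))
}

#' Transcription start site set
#'
#' Strand-aware 5' ends of all transcripts: the minimal exon start for
#' `+` strand, the maximal exon end for `-` strand.
#'
#' @inheritParams derive_stringent_introns
#' @return `data.frame` with `chrom`, `pos`, `strand`, `gene_id`,
#'   `transcript_id`.
#' @export
collect_tss <- function(db) {
  out <- lapply(split(db$exons, db$exons$transcript_id), function(e) {
    pos <- if (e$strand[1] == "-") max(e$end) else min(e$start)
    data.frame(chrom = e$chrom[1], pos = pos, strand = e$strand[1],
               transcript_id = e$transcript_id[1], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$gene_id <- db$transcripts$gene_id[match(res$transcript_id,
                                              db$transcripts$transcript_id)]
  rownames(res) <- NULL
  res
}

#' Annotated 3'UTR end coordinates per gene
#'
#' For each coding transcript (one with annotated CDS) the transcript's
#' 3' end: the maximal exon end on `+` strand, the minimal exon start on
#' `-` strand.
#'
#' @inheritParams derive_stringent_introns
#' @return Named list, gene_id -> sorted unique integer end coordinates.
#' @export
collect_utr3_ends <- function(db) {
  coding <- unique(db$cds$transcript_id)
  out <- list()
  for (tid in coding) {
    e <- db$exons[db$exons$transcript_id == tid, , drop = FALSE]
    gid <- db$transcripts$gene_id[match(tid, db$transcripts$transcript_id)]
    end3 <- if (e$strand[1] == "-") min(e$start) else max(e$end)
    out[[gid]] <- c(out[[gid]], end3)
  }
  lapply(out, function(v) sort(unique(as.integer(v))))
}

# spliced sequence of a set of exon intervals (genome order), 5'->3'
spliced_sequence <- function(genome, chrom, starts, ends, strand) {
  parts <- vapply(seq_along(starts), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], starts[i] + 1L, ends[i]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
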