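#' Read tables
#'
#' A read table holds one aligned long read per row: `read_id`, `chrom`,
#' `strand`, list-columns `block_starts` / `block_ends` (aligned segment
#' coordinates, 0-based half-open, sorted, non-overlapping), flags
#' `is_secondary` / `is_supplementary`, and the poly(A) caller's QC
#' verdict `polya_qc` (`PASS` or other) with `polya_length` in nt
#' (present iff PASS).
#'
#' @param path TSV with columns `read_id`, `chrom`, `strand`,
#'   `block_starts`, `block_ends` (comma-separated integers),
#'   `is_secondary`, `is_supplementary` (0/1), `polya_qc`,
#'   `polya_length` (`NA` unless PASS).
#' @return Read table `data.frame`.
#' @export
read_read_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(polya_length = "numeric"))
  df$block_starts <- lapply(strsplit(as.character(df$block_starts), ","),
                            as.integer)
  df$block_ends <- lapply(strsplit(as.character(df$block_ends), ","),
                          as.integer)
  df$is_secondary <- as.logical(df$is_secondary)
  df$is_supplementary <- as.logical(df$is_supplementary)
  df
}

#' @rdname read_read_table
#' @param reads a read table.
#' @export
write_read_table <- function(reads, path) {
  out <- reads
  out$block_starts <- vapply(reads$block_starts, paste, character(1),
                             collapse = ",")
  out$block_ends <- vapply(reads$block_ends, paste, character(1),
                           collapse = ",")
  out$is_secondary <- as.integer(out$is_secondary)
  out$is_supplementary <- as.integer(out$is_supplementary)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# strand-aware 5' end of each read: min start on +, max end on -
read_five_prime <- function(reads) {
  mapply(function(st, en, strand) {
    if (strand == "-") max(en) else min(st)
  }, reads$block_starts, reads$block_ends, reads$strand)
}

# aligned bases per read
read_aligned_bases <- function(reads) {
  mapply(function(st, en) sum(en - st), reads$block_starts, reads$block_ends)
}

#' Filter reads to full-length status
#'
#' Sequential filter mirroring a full-length DRS read definition:
#' (1) drop secondary/supplementary alignments, (2) drop reads on
#' chromosomes absent from the annotation, (3) drop reads whose
#' strand-aware 5'-most aligned position is farther than `tss_window`
#' nt from every annotated TSS on the same chromosome and strand,
#' (4) drop reads without a PASS poly(A) QC tag.
#'
#' @param reads read table.
#' @param db an [annotation_db()].
#' @param tss_window maximal distance (nt) from an annotated TSS.
#' @return List with `reads` (kept rows) and `counts`, a named integer
#'   vector of per-stage removals that sums back to the input size
#'   (`input = secondary_supplementary + unknown_chrom + tss_fail +
#'   polya_fail + kept`).
#' @export
filter_full_length <- function(reads, db, tss_window = 10) {
  n_input <- nrow(reads)
  sec <- reads$is_secondary | reads$is_supplementary
  n_sec <- sum(sec)
  reads <- reads[!sec, , drop = FALSE]

  known <- reads$chrom %in% names(db$chrom_sizes)
  n_unknown <- sum(!known)
  reads <- reads[known, , drop = FALSE]

  tss <- collect_tss(db)
  ok_tss <- logical(nrow(reads))
  if (nrow(reads)) {
    p5 <- read_five_prime(reads)
    key <- paste(reads$chrom, reads$strand)
    for (k in unique(key)) {
      idx <- which(key == k)
      tt <- tss$pos[paste(tss$chrom, tss$strand) == k]
      if (!length(tt)) next
      ok_tss[idx] <- vapply(p5[idx],
                            function(p) min(abs(tt - p)) <= tss_window,
                            logical(1))
    }
  }
  n_tss <- sum(!ok_tss)
  reads <- reads[ok_tss, , drop = FALSE]

  pass <- reads$polya_qc == "PASS"
  n_polya <- sum(!pass)
  reads <- reads[pass, , drop = FALSE]

  counts <- c(input = n_input, secondary_supplementary = n_sec,
              unknown_chrom = n_unknown, tss_fail = n_tss,
              polya_fail = n_polya, kept = nrow(reads))
  list(reads = reads, counts = counts)
}

#' Assign reads to features by fractional overlap
#'
#' A read is assigned to a feature when at least `frac_overlap` of its
#' aligned bases fall inside the feature; among qualifying features the
#' one with the largest base overlap wins, and an exact tie leaves the
#' read unassigned-ambiguous (reads are never double-counted).
#'
#' @param reads read table.
#' @param features interval `data.frame` with a `feature_id` column.
#' @param frac_overlap required fraction of aligned bases (0..1).
#' @param strand_mode `"ignore"`, `"same"`, or `"opposite"` (the
#'   reversely-stranded protocol of `-s 2` style counting).
#' @return List with `assignments` (read_id, feature_id or NA, status),
#'   `feature_counts` (named integer), `percent_assigned`.
#' @export
assign_reads_to_features <- function(reads, features, frac_overlap = 0.5,
                                     strand_mode = c("ignore", "same",
                                                     "opposite")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot("feature_id" %in% names(features))
  n <- nrow(reads)
  aligned <- if (n) read_aligned_bases(reads) else integer(0)
  best_id <- rep(NA_character_, n)
  status <- rep("unassigned", n)

  if (n && nrow(features)) {
    # flatten blocks
    nb <- lengths(reads$block_starts)
    bl <- data.frame(read = rep(seq_len(n), nb),
                     chrom = rep(reads$chrom, nb),
                     start = unlist(reads$block_starts),
                     end = unlist(reads$block_ends),
                     stringsAsFactors = FALSE)
    ov_list <- list()
    for (ch in unique(bl$chrom)) {
      bi <- which(bl$chrom == ch)
      fi <- which(features$chrom == ch)
      if (!length(fi)) next
      hits <- IRanges::findOverlaps(.to_ir(bl[bi, , drop = FALSE]),
                                    .to_ir(features[fi, , drop = FALSE]))
      if (!length(hits)) next
      q <- bi[S4Vectors::queryHits(hits)]
      s <- fi[S4Vectors::subjectHits(hits)]
      w <- pmin(bl$end[q], features$end[s]) -
           pmax(bl$start[q], features$start[s])
      ov_list[[ch]] <- data.frame(read = bl$read[q], feat = s, w = w)
    }
    ov <- do.call(rbind, ov_list)
    if (!is.null(ov) && nrow(ov)) {
      if (strand_mode != "ignore") {
        fs <- features$strand[ov$feat]
        rs <- reads$strand[ov$read]
        keep <- if (strand_mode == "same") fs == "*" | fs == rs
                else fs == "*" | fs != rs
        ov <- ov[keep, , drop = FALSE]
      }
      if (nrow(ov)) {
        # intervals sharing a feature_id act as one (meta-)feature
        ov$fid <- features$feature_id[ov$feat]
        tot <- stats::aggregate(w ~ read + fid, data = ov, FUN = sum)
        for (rows in split(tot, tot$read)) {
          r <- rows$read[1]
          need <- frac_overlap * aligned[r]
          rows <- rows[rows$w >= need & rows$w > 0, , drop = FALSE]
          if (!nrow(rows)) next
          mx <- max(rows$w)
          top <- rows$fid[rows$w == mx]
          if (length(top) > 1) {
            status[r] <- "ambiguous"
          } else {
            best_id[r] <- top
            status[r] <- "assigned"
          }
        }
      }
    }
  }
  feature_counts <- table(factor(best_id,
                                 levels = unique(features$feature_id)))
  assignments <- data.frame(read_id = reads$read_id, feature_id = best_id,
                            status = status, stringsAsFactors = FALSE)
  list(assignments = assignments,
       feature_counts = stats::setNames(as.integer(feature_counts),
                                        names(feature_counts)),
       percent_assigned = if (n) 100 * sum(status == "assigned") / n
                          else NA_real_)
}

#' Metagene read-density profile
#'
#' Per protein-coding gene, block coverage over the gene span is
#' averaged into `n_bins` equal-width bins ordered 5' to 3'
#' (strand-aware), each gene is normalised to the mean of its own bin
#' values (so each covered gene contributes bins summing to `n_bins`),
#' and the profile is the mean over genes. Genes with zero coverage are
#' excluded from the average.
#'
#' @param reads read table.
#' @param db an [annotation_db()].
#' @param n_bins number of bins (default 100).
#' @return Numeric vector of length `n_bins`.
#' @export
metagene_profile <- function(reads, db, n_bins = 100) {
  genes <- db$genes[db$genes$biotype == "protein_coding" &
                    (db$genes$span_end - db$genes$span_start) >= n_bins, ,
                    drop = FALSE]
  if (!nrow(genes)) stop("no protein-coding gene long enough for ", n_bins,
                         " bins")
  profs <- list()
  nb <- lengths(reads$block_starts)
  bl <- data.frame(chrom = rep(reads$chrom, nb),
                   strand = rep(reads$strand, nb),
                   start = unlist(reads$block_starts),
                   end = unlist(reads$block_ends),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    b <- bl[bl$chrom == g$chrom & bl$strand == g$strand &
            bl$end > g$span_start & bl$start < g$span_end, , drop = FALSE]
    if (!nrow(b)) next
    L <- g$span_end - g$span_start
    cov <- integer(L)
    s <- pmax(b$start, g$span_start) - g$span_start
    e <- pmin(b$end, g$span_end) - g$span_start
    for (j in seq_len(nrow(b))) {
      idx <- (s[j] + 1L):e[j]
      cov[idx] <- cov[idx] + 1L
    }
    if (all(cov == 0)) next
    edges <- floor(seq(0, L, length.out = n_bins + 1))
    cs <- c(0, cumsum(cov))
    binmean <- (cs[edges[-1] + 1] - cs[edges[-(n_bins + 1)] + 1]) /
               (edges[-1] - edges[-(n_bins + 1)])
    if (g$strand == "-") binmean <- rev(binmean)
    profs[[length(profs) + 1]] <- binmean / mean(binmean)
  }
  if (!length(profs)) stop("no gene with nonzero coverage")
  colMeans(do.call(rbind, profs))
}
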