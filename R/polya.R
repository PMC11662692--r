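#' Poly(A) tail record tables
#'
#' One row per read: `read_id`, `isoform_id`, `sample_id`, `age_group`
#' (`young`/`old`), `tail_length` (nt, real-valued), `qc_tag` (`PASS` or
#' other). The default sample -> age-group mapping pools the three
#' earliest adult days as young and the three latest as old.
#'
#' @param path tab-separated file with the columns above.
#' @return `data.frame`.
#' @export
read_tail_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_tail_table
#' @param records tail record table.
#' @export
write_tail_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default sample day to age-group mapping
#'
#' Days 1, 2 and 3 are pooled as `young`; days 7, 10 and 15 as `old`.
#'
#' @param day integer vector of adult days.
#' @return Character vector `young`/`old` (`NA` for unmapped days).
#' @export
age_group_of_day <- function(day) {
  ifelse(day %in% c(1, 2, 3), "young",
         ifelse(day %in% c(7, 10, 15), "old", NA_character_))
}

#' Keep only PASS-tagged tail records
#'
#' @param records tail record table.
#' @return List with `records` (kept) and `removed` (count).
#' @export
filter_pass <- function(records) {
  keep <- records$qc_tag == "PASS"
  list(records = records[keep, , drop = FALSE], removed = sum(!keep))
}

#' Pooled tail-length distribution of an age group
#'
#' @param records PASS-filtered tail record table.
#' @param group `"young"` or `"old"`.
#' @return List with `lengths` (sorted) and `median` (midpoint rule).
#' @export
group_tail_distribution <- function(records, group) {
  v <- sort(records$tail_length[records$age_group == group])
  list(lengths = v, median = stats::median(v))
}

#' Two-sample Kolmogorov-Smirnov comparison of tail lengths
#'
#' Classical two-sided two-sample KS `D` with the asymptotic p-value.
#'
#' @param lengths_a,lengths_b numeric vectors.
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(lengths_a, lengths_b) {
  kt <- suppressWarnings(stats::ks.test(lengths_a, lengths_b,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Abundance-quartile bins for isoform expression
#'
#' Quartile cut points (type-7 linear-interpolation quantiles) on the
#' expression values; `low` = 1st quartile, `medium` = 2nd and 3rd,
#' `high` = 4th. Values exactly at a cut point go to the lower bin. When
#' the two cut points coincide (degenerate spread) everything at the cut
#' is `medium` and a warning is issued.
#'
#' @param isoform_expression named numeric vector (names = isoform ids).
#' @return Named character vector of bins.
#' @export
abundance_bins <- function(isoform_expression) {
  q <- stats::quantile(isoform_expression, c(0.25, 0.75), names = FALSE,
                       type = 7)
  if (q[1] == q[2]) {
    warning("degenerate expression spread: quartile cut points coincide")
    bins <- ifelse(isoform_expression < q[1], "low",
                   ifelse(isoform_expression > q[1], "high", "medium"))
  } else {
    bins <- ifelse(isoform_expression <= q[1], "low",
                   ifelse(isoform_expression <= q[2], "medium", "high"))
  }
  stats::setNames(bins, names(isoform_expression))
}

#' Per-isoform tail medians by age group
#'
#' @param records PASS-filtered tail record table.
#' @return `data.frame` with `isoform_id`, `n_young`, `n_old`,
#'   `median_young`, `median_old`.
#' @export
isoform_tail_medians <- function(records) {
  out <- lapply(split(records, records$isoform_id), function(d) {
    y <- d$tail_length[d$age_group == "young"]
    o <- d$tail_length[d$age_group == "old"]
    data.frame(isoform_id = d$isoform_id[1],
               n_young = length(y), n_old = length(o),
               median_young = if (length(y)) stats::median(y) else NA_real_,
               median_old = if (length(o)) stats::median(o) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify per-isoform changes in median tail length
#'
#' Only isoforms with at least `min_reads` PASS reads in both age groups
#' are eligible. The absolute old-minus-young median difference is
#' binned as `<10`, `10-20` (closed interval, boundaries 10 and 20
#' included) or `>20` nt.
#'
#' @param medians output of [isoform_tail_medians()].
#' @param min_reads minimum reads per group (default 5).
#' @return `data.frame` with `isoform_id`, `delta` (signed, nt),
#'   `class`.
#' @export
delta_median_classes <- function(medians, min_reads = 5) {
  el <- medians[medians$n_young >= min_reads & medians$n_old >= min_reads,
                , drop = FALSE]
  delta <- el$median_old - el$median_young
  ad <- abs(delta)
  cls <- ifelse(ad < 10, "<10", ifelse(ad <= 20, "10-20", ">20"))
  data.frame(isoform_id = el$isoform_id, delta = delta, class = cls,
             stringsAsFactors = FALSE)
}
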