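#' Read a STAR-style collapsed splice-junction table
#'
#' SJ.out.tab dialect: 9 tab-separated columns (chrom, intron first base
#' 1-based, intron last base 1-based, strand code 0/1/2, motif code,
#' annotated flag, unique reads, multi reads, max overhang). Intron
#' coordinates are converted to the internal 0-based half-open
#' convention; strand codes become `"*"`, `"+"`, `"-"`.
#'
#' @param path path to an SJ.out.tab-style file (no header).
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`,
#'   `motif`, `annotated_flag`, `unique_reads`, `multi_reads`,
#'   `max_overhang`.
#' @export
read_sj_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "first", "last", "strand_code", "motif",
                 "annotated_flag", "unique_reads", "multi_reads",
                 "max_overhang")
  data.frame(chrom = df$chrom,
             start = df$first - 1L,
             end = df$last,
             strand = c("*", "+", "-")[df$strand_code + 1L],
             motif = df$motif, annotated_flag = df$annotated_flag,
             unique_reads = df$unique_reads, multi_reads = df$multi_reads,
             max_overhang = df$max_overhang, stringsAsFactors = FALSE)
}

#' Classify splice junctions against the annotated junction database
#'
#' A junction is `annotated` iff its (chrom, start, end) exactly matches
#' a database intron. Strand is ignored by default because collapsed
#' junction tables carry undefined strands (code 0); set
#' `check_strand = TRUE` to also require a strand match.
#'
#' @param junctions `data.frame` from [read_sj_table()] (or with the
#'   same coordinate columns).
#' @param junction_db output of [build_junction_db()].
#' @param check_strand require strand equality as well?
#' @return `junctions` with an added `annotated` logical column.
#' @export
classify_junctions <- function(junctions, junction_db,
                               check_strand = FALSE) {
  if (check_strand) {
    key_j <- paste(junctions$chrom, junctions$start, junctions$end,
                   junctions$strand)
    key_db <- paste(junction_db$chrom, junction_db$start, junction_db$end,
                    junction_db$strand)
  } else {
    key_j <- paste(junctions$chrom, junctions$start, junctions$end)
    key_db <- paste(junction_db$chrom, junction_db$start, junction_db$end)
  }
  junctions$annotated <- key_j %in% key_db
  junctions
}

#' Unannotated splice-junction read percentage
#'
#' 100 x (unique reads over unannotated junctions) / (unique reads over
#' all junctions).
#'
#' @param classified output of [classify_junctions()].
#' @return Percentage in `[0, 100]`.
#' @export
fidelity_percentage <- function(classified) {
  total <- sum(classified$unique_reads)
  if (total <= 0) stop("no junction-spanning unique reads")
  100 * sum(classified$unique_reads[!classified$annotated]) / total
}

#' Attribute an unannotated junction's mismatch to its ends
#'
#' The donor is the strand-aware 5' coordinate of the intron (start on
#' `+`, end on `-`), the acceptor the 3' coordinate. The label names the
#' end that deviates from the annotation: a junction sharing a donor
#' with some annotated intron but no acceptor deviates at its 3' end
#' (`three_prime_only`), and vice versa; `both` means neither end is
#' annotated. A junction whose donor and acceptor each match annotated
#' coordinates, but whose pairing is new (e.g. exon skipping), is
#' labelled `novel_combination`.
#'
#' @param junctions unannotated junction rows (`chrom`, `start`, `end`,
#'   `strand`).
#' @param junction_db output of [build_junction_db()].
#' @param check_strand compare donor/acceptor sets strand-aware?
#' @return Character vector of labels, one per junction.
#' @export
attribute_mismatch_end <- function(junctions, junction_db,
                                   check_strand = FALSE) {
  donor_of <- function(df) ifelse(df$strand == "-", df$end, df$start)
  acceptor_of <- function(df) ifelse(df$strand == "-", df$start, df$end)
  db_donor <- donor_of(junction_db)
  db_acceptor <- acceptor_of(junction_db)
  out <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    sel <- junction_db$chrom == j$chrom
    if (check_strand && j$strand %in% c("+", "-"))
      sel <- sel & junction_db$strand == j$strand
    jd <- if (j$strand == "-" ) j$end else j$start
    ja <- if (j$strand == "-" ) j$start else j$end
    donor_hit <- any(sel & db_donor == jd)
    acceptor_hit <- any(sel & db_acceptor == ja)
    out[i] <- if (donor_hit && acceptor_hit) "novel_combination"
      else if (donor_hit) "three_prime_only"
      else if (acceptor_hit) "five_prime_only"
      else "both"
  }
  out
}

#' Compare two groups of percentages after probit transformation
#'
#' Each percentage is divided by 100 and transformed by the inverse
#' standard-normal CDF, then a two-sample two-sided t-test is applied
#' (pooled variance by default; Welch via `var_equal = FALSE`). Values
#' of exactly 0% or 100% are clamped to `1/(2n)` (respectively
#' `1 - 1/(2n)`) with `n` the group's read total when supplied, else to
#' `1e-6`, with a warning.
#'
#' @param values_young,values_old percentages in `[0, 100]`.
#' @param var_equal pooled-variance (Student) t-test (default) or Welch.
#' @param n_young,n_old optional group read totals used for clamping.
#' @return List with `t`, `p`, `df`, and group means on the probit
#'   scale.
#' @export
compare_groups_probit <- function(values_young, values_old,
                                  var_equal = TRUE,
                                  n_young = NULL, n_old = NULL) {
  stopifnot(length(values_young) >= 2, length(values_old) >= 2)
  clamp <- function(v, n) {
    p <- v / 100
    eps <- if (!is.null(n)) 1 / (2 * n) else 1e-6
    bad <- p <= 0 | p >= 1
    if (any(bad)) {
      warning("clamping ", sum(bad), " boundary proportion(s) to [",
              signif(eps, 3), ", ", signif(1 - eps, 3), "]")
      p <- pmin(pmax(p, eps), 1 - eps)
    }
    p
  }
  x <- stats::qnorm(clamp(values_young, n_young))
  y <- stats::qnorm(clamp(values_old, n_old))
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, p = 1, df = length(x) + length(y) - 2,
                mean_young = mean(x), mean_old = mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_young = mean(x), mean_old = mean(y))
}
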