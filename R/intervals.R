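#' Genomic interval tables
#'
#' All coordinates inside the package are 0-based, half-open
#' (`start` inclusive, `end` exclusive), the BED convention. File readers
#' and writers convert 1-based formats (GFF3, SAF, SJ.out.tab) at the
#' boundary. An interval table is a plain `data.frame` with columns
#' `chrom`, `start`, `end` and optionally `strand` (one of `"+"`, `"-"`,
#' `"*"`).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand characters, recycled; `"*"` means unstranded.
#' @return A validated interval `data.frame`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval with empty chromosome name")
  if (any(df$start < 0)) stop("interval with negative start")
  if (any(df$end <= df$start)) stop("interval with end <= start")
  invisible(df)
}

# IRanges bridge: 0-based half-open -> 1-based closed and back.
.to_ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

.from_ir <- function(ir, chrom) {
  data.frame(chrom = rep_len(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             strand = rep_len("*", length(ir)),
             stringsAsFactors = FALSE)
}

# Union (reduce) of an interval table, per chromosome, unstranded.
interval_union <- function(df) {
  if (nrow(df) == 0)
    return(genomic_intervals(character(), integer(), integer()))
  out <- lapply(split(df, df$chrom), function(d) {
    .from_ir(IRanges::reduce(.to_ir(d)), d$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Set difference a \ b, per chromosome, unstranded, as maximal
# disjoint intervals.
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a[0, c("chrom", "start", "end", "strand")])
  out <- lapply(split(a, a$chrom), function(d) {
    bb <- b[b$chrom == d$chrom[1], , drop = FALSE]
    if (nrow(bb) == 0) ir <- IRanges::reduce(.to_ir(d))
    else ir <- IRanges::setdiff(.to_ir(d), .to_ir(bb))
    .from_ir(ir, d$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[res$end > res$start, , drop = FALSE]
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Total number of bases covered by the union of a table.
interval_covered_bases <- function(df) {
  u <- interval_union(df)
  sum(as.numeric(u$end - u$start))
}

# For each query row, TRUE if it overlaps (>= 1 nt) any subject row.
interval_overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  hit <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ss <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(ss) == 0) next
    ov <- IRanges::countOverlaps(.to_ir(query[qi, , drop = FALSE]),
                                 .to_ir(ss))
    hit[qi] <- ov > 0
  }
  hit
}
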