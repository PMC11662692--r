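#' Isoform call sets
#'
#' An isoform call set couples isoform structures (one row per isoform:
#' `isoform_id`, `gene_id` — `NA` when unassigned —, `chrom`, `strand`,
#' list-columns `block_starts` / `block_ends`) with a per-sample read
#' count matrix (rownames = isoform ids).
#'
#' @param isoforms isoform structure `data.frame` as above.
#' @param counts numeric matrix, isoforms x samples; rownames must match
#'   `isoforms$isoform_id`.
#' @return An object of class `isoform_callset`.
#' @export
isoform_callset <- function(isoforms, counts) {
  stopifnot(identical(rownames(counts), isoforms$isoform_id))
  structure(list(isoforms = isoforms, counts = counts),
            class = "isoform_callset")
}

#' @export
print.isoform_callset <- function(x, ...) {
  cat("isoform_callset:", nrow(x$isoforms), "isoforms x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Read isoform structures from BED12
#'
#' @param path BED12 file (blockStarts/blockSizes describe the exons).
#' @return Isoform structure `data.frame` (no counts).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  bl <- rtracklayer::blocks(gr)
  n <- length(gr)
  starts <- vector("list", n)
  ends <- vector("list", n)
  for (i in seq_len(n)) {
    b <- bl[[i]]
    starts[[i]] <- GenomicRanges::start(b) - 1L
    ends[[i]] <- GenomicRanges::end(b)
  }
  df <- data.frame(isoform_id = as.character(gr$name),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$block_starts <- starts
  df$block_ends <- ends
  df$gene_id <- NA_character_
  df
}

#' Write isoform structures as BED12
#'
#' @param isoforms isoform structure `data.frame`.
#' @param path output path.
#' @export
write_bed12 <- function(isoforms, path) {
  lines <- vapply(seq_len(nrow(isoforms)), function(i) {
    st <- isoforms$block_starts[[i]]
    en <- isoforms$block_ends[[i]]
    paste(isoforms$chrom[i], st[1], en[length(en)],
          isoforms$isoform_id[i], 0, isoforms$strand[i],
          st[1], en[length(en)], "0,0,0", length(st),
          paste0(paste(en - st, collapse = ","), ","),
          paste0(paste(st - st[1], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# intron chain of one isoform row: data.frame of gaps
isoform_introns <- function(st, en) {
  k <- length(st)
  if (k < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = en[-k], end = st[-1])
}

#' Assign isoforms to annotated genes by exonic overlap
#'
#' Each isoform gets the gene whose annotated exons share the most
#' exonic bases with it; ties or zero overlap leave it unassigned.
#'
#' @param isoforms isoform structure `data.frame`.
#' @param db an [annotation_db()].
#' @param same_strand restrict to genes on the isoform's strand.
#' @return `isoforms` with the `gene_id` column filled in.
#' @export
assign_isoform_genes <- function(isoforms, db, same_strand = TRUE) {
  ex <- db$exons
  ex$gene_id <- db$transcripts$gene_id[match(ex$transcript_id,
                                             db$transcripts$transcript_id)]
  for (i in seq_len(nrow(isoforms))) {
    sel <- ex$chrom == isoforms$chrom[i]
    if (same_strand) sel <- sel & ex$strand == isoforms$strand[i]
    cand <- ex[sel, , drop = FALSE]
    if (!nrow(cand)) { isoforms$gene_id[i] <- NA_character_; next }
    iso <- data.frame(chrom = isoforms$chrom[i],
                      start = isoforms$block_starts[[i]],
                      end = isoforms$block_ends[[i]])
    ov <- vapply(split(cand, cand$gene_id), function(g) {
      gu <- interval_union(g[, c("chrom", "start", "end")])
      tot <- 0L
      for (j in seq_len(nrow(gu)))
        tot <- tot + sum(pmax(0L, pmin(iso$end, gu$end[j]) -
                                  pmax(iso$start, gu$start[j])))
      tot
    }, numeric(1))
    best <- max(ov)
    top <- names(ov)[ov == best]
    isoforms$gene_id[i] <- if (best > 0 && length(top) == 1) top
                           else NA_character_
  }
  isoforms
}

#' Filter an isoform call set by support and within-gene share
#'
#' Keeps isoforms with at least `min_total_reads` reads summed over all
#' samples AND carrying at least `min_gene_fraction` of the summed reads
#' of all isoforms assigned to the same gene (computed on the call set
#' as given). Unassigned isoforms pass the fraction rule vacuously.
#' Both boundaries are inclusive. The filter is idempotent.
#'
#' @param callset an [isoform_callset()].
#' @param min_total_reads minimum reads across all samples (default 20).
#' @param min_gene_fraction minimum share of the gene's reads (default
#'   0.10).
#' @return Filtered [isoform_callset()].
#' @export
filter_isoforms <- function(callset, min_total_reads = 20,
                            min_gene_fraction = 0.10) {
  totals <- rowSums(callset$counts)
  gid <- callset$isoforms$gene_id
  gene_tot <- tapply(totals, gid, sum)
  frac_ok <- rep(TRUE, length(totals))
  has_gene <- !is.na(gid)
  frac_ok[has_gene] <-
    totals[has_gene] >= min_gene_fraction * gene_tot[gid[has_gene]]
  keep <- totals >= min_total_reads & frac_ok
  isoform_callset(callset$isoforms[keep, , drop = FALSE],
                  callset$counts[keep, , drop = FALSE])
}

# ordered intron-chain key per annotated transcript, same chrom+strand space
annotated_chain_keys <- function(db) {
  keys <- character(0)
  for (tid in unique(db$exons$transcript_id)) {
    e <- db$exons[db$exons$transcript_id == tid, , drop = FALSE]
    g <- isoform_introns(e$start, e$end)
    if (!nrow(g)) next
    keys <- c(keys, paste(e$chrom[1], e$strand[1],
                          paste(g$start, g$end, sep = "-", collapse = ";")))
  }
  unique(keys)
}

#' Classify isoforms as splice-known or splice-novel
#'
#' An isoform is `known` iff some annotated transcript on the same
#' chromosome and strand has an identical ordered intron chain (exact
#' junction coordinates; terminal exon ends are free, matching
#' collapse-style isoform identity). A mono-exonic isoform is known iff
#' it is contained within a mono-exonic annotated transcript extended by
#' `end_tolerance` nt at both ends.
#'
#' @param isoforms isoform structure `data.frame`.
#' @param db an [annotation_db()].
#' @param end_tolerance slack (nt) for mono-exonic containment.
#' @return Character vector, `"known"` or `"novel"`, one per isoform.
#' @export
classify_splice_novelty <- function(isoforms, db, end_tolerance = 10) {
  chain_keys <- annotated_chain_keys(db)
  # mono-exonic annotated transcripts
  mono <- do.call(rbind, lapply(split(db$exons, db$exons$transcript_id),
    function(e) if (nrow(e) == 1) e else NULL))
  out <- character(nrow(isoforms))
  for (i in seq_len(nrow(isoforms))) {
    st <- isoforms$block_starts[[i]]
    en <- isoforms$block_ends[[i]]
    if (length(st) >= 2) {
      g <- isoform_introns(st, en)
      key <- paste(isoforms$chrom[i], isoforms$strand[i],
                   paste(g$start, g$end, sep = "-", collapse = ";"))
      out[i] <- if (key %in% chain_keys) "known" else "novel"
    } else {
      hit <- FALSE
      if (!is.null(mono)) {
        m <- mono[mono$chrom == isoforms$chrom[i] &
                  mono$strand == isoforms$strand[i], , drop = FALSE]
        hit <- any(m$start - end_tolerance <= st[1] &
                   m$end + end_tolerance >= en[1])
      }
      out[i] <- if (hit) "known" else "novel"
    }
  }
  out
}

# genomic position of transcript coordinate p (0-based) in an isoform
tx_to_genome <- function(st, en, strand, p) {
  lens <- en - st
  if (strand == "-") { st <- rev(st); en <- rev(en); lens <- rev(lens) }
  cum <- c(0, cumsum(lens))
  k <- findInterval(p, cum, rightmost.closed = FALSE)
  off <- p - cum[k]
  if (strand == "-") en[k] - 1L - off else st[k] + off
}

# transcript coordinate of genomic position g, or NA if not exonic
genome_to_tx <- function(st, en, strand, g) {
  lens <- en - st
  cum <- c(0, cumsum(lens))
  k <- which(g >= st & g < en)
  if (!length(k)) return(NA_integer_)
  if (strand == "-") {
    n <- length(st)
    kk <- n - k + 1
    cumr <- c(0, cumsum(rev(lens)))
    as.integer(cumr[kk] + (en[k] - 1L - g))
  } else {
    as.integer(cum[k] + (g - st[k]))
  }
}

#' Predict coding productivity of isoforms
#'
#' Builds each isoform's spliced sequence 5' to 3', picks a start codon
#' — the annotated start codon of the assigned gene when it maps into
#' the isoform (the 5'-most mappable one if several transcripts
#' disagree), else the first AUG — and scans in frame. The isoform is
#' `productive` when an in-frame stop codon completes before the
#' transcript end; otherwise `unproductive` (no start codon, or
#' run-through). No NMD rule is applied: a premature stop still counts
#' as productive.
#'
#' @param isoforms isoform structure `data.frame` with `gene_id` filled.
#' @param db an [annotation_db()].
#' @param genome [Biostrings::DNAStringSet]; defaults to `db$genome`.
#' @return `data.frame` with `isoform_id`, `productive`, `reason`,
#'   `start_tx`, `stop_tx_start`, `stop_tx_end` (0-based transcript
#'   coordinates; `stop_tx_end` is the base after the stop codon).
#' @export
predict_productivity <- function(isoforms, db, genome = db$genome) {
  if (is.null(genome)) stop("a genome is required")
  res <- data.frame(isoform_id = isoforms$isoform_id,
                    productive = FALSE, reason = "",
                    start_tx = NA_integer_, stop_tx_start = NA_integer_,
                    stop_tx_end = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(isoforms))) {
    st <- isoforms$block_starts[[i]]
    en <- isoforms$block_ends[[i]]
    strand <- isoforms$strand[i]
    seq <- spliced_sequence(genome, isoforms$chrom[i], st, en, strand)
    txlen <- nchar(seq)
    start_tx <- NA_integer_
    gid <- isoforms$gene_id[i]
    if (!is.na(gid)) {
      tids <- db$transcripts$transcript_id[db$transcripts$gene_id == gid]
      cand <- integer(0)
      for (tid in tids) {
        cc <- db$cds[db$cds$transcript_id == tid, , drop = FALSE]
        if (!nrow(cc)) next
        gpos <- if (strand == "-") max(cc$end) - 1L else min(cc$start)
        tp <- genome_to_tx(st, en, strand, gpos)
        if (!is.na(tp)) cand <- c(cand, tp)
      }
      if (length(cand)) {
        cand <- cand[cand + 3 <= txlen &
                     substr(seq, cand + 1, cand + 3) == "ATG"]
        if (length(cand)) start_tx <- min(cand)
      }
    }
    if (is.na(start_tx)) {
      m <- regexpr("ATG", seq, fixed = TRUE)
      if (m > 0) start_tx <- as.integer(m - 1L)
    }
    if (is.na(start_tx)) {
      res$reason[i] <- "no_start_codon"
      next
    }
    res$start_tx[i] <- start_tx
    pos <- start_tx
    found <- FALSE
    while (pos + 3 <= txlen) {
      cod <- substr(seq, pos + 1, pos + 3)
      if (.CODON_TABLE[[cod]] == "*") { found <- TRUE; break }
      pos <- pos + 3
    }
    if (found) {
      res$productive[i] <- TRUE
      res$stop_tx_start[i] <- pos
      res$stop_tx_end[i] <- pos + 3L
    } else {
      res$reason[i] <- "no_stop_codon"
    }
  }
  res
}

#' Extract the 3'UTR of a productive isoform
#'
#' The spliced region from the base after the stop codon to the isoform
#' 3' end, returned as genomic interval(s) plus the terminal genomic
#' 3'-end coordinate (maximal exon end on `+`, minimal exon start on
#' `-`).
#'
#' @param isoform one isoform row (`data.frame` of one row).
#' @param stop_tx_end transcript coordinate of the base after the stop
#'   codon (from [predict_productivity()]).
#' @return List with `intervals` (interval `data.frame`), `utr3_end`
#'   (genomic coordinate), `length` (nt).
#' @export
extract_utr3 <- function(isoform, stop_tx_end) {
  st <- isoform$block_starts[[1]]
  en <- isoform$block_ends[[1]]
  strand <- isoform$strand[1]
  txlen <- sum(en - st)
  utr3_end <- if (strand == "-") st[1] else en[length(en)]
  if (stop_tx_end >= txlen)
    return(list(intervals = genomic_intervals(character(), integer(),
                                              integer()),
                utr3_end = utr3_end, length = 0L))
  # genomic footprint of transcript interval [stop_tx_end, txlen)
  lens <- en - st
  ord_st <- st; ord_en <- en; ord_lens <- lens
  if (strand == "-") {
    ord_st <- rev(st); ord_en <- rev(en); ord_lens <- rev(lens)
  }
  cum <- c(0, cumsum(ord_lens))
  ivs <- list()
  for (k in seq_along(ord_st)) {
    a <- max(stop_tx_end, cum[k]); b <- cum[k + 1]
    if (a >= b) next
    if (strand == "-") {
      gs <- ord_en[k] - (b - cum[k]); ge <- ord_en[k] - (a - cum[k])
    } else {
      gs <- ord_st[k] + (a - cum[k]); ge <- ord_st[k] + (b - cum[k])
    }
    ivs[[length(ivs) + 1]] <- data.frame(chrom = isoform$chrom[1],
                                         start = gs, end = ge,
                                         strand = strand,
                                         stringsAsFactors = FALSE)
  }
  ints <- do.call(rbind, ivs)
  ints <- ints[order(ints$start), , drop = FALSE]
  rownames(ints) <- NULL
  list(intervals = ints, utr3_end = utr3_end,
       length = as.integer(txlen - stop_tx_end))
}

#' Classify a 3'UTR end as known or novel
#'
#' Known iff the end lies within `window` nt (inclusive) of an annotated
#' 3'UTR end — of the same gene by default, of any gene with
#' `gene_scope = FALSE`.
#'
#' @param utr3_end genomic 3'-end coordinate of the isoform.
#' @param gene_id the isoform's assigned gene.
#' @param utr3_index output of [collect_utr3_ends()].
#' @param window tolerance in nt (default 10, boundary inclusive).
#' @param gene_scope compare only against the same gene's ends?
#' @return `"known"` or `"novel"`.
#' @export
classify_utr3_novelty <- function(utr3_end, gene_id, utr3_index,
                                  window = 10, gene_scope = TRUE) {
  ends <- if (gene_scope) {
    if (is.na(gene_id) || is.null(utr3_index[[gene_id]])) integer(0)
    else utr3_index[[gene_id]]
  } else unlist(utr3_index, use.names = FALSE)
  if (!length(ends)) return("novel")
  if (min(abs(ends - utr3_end)) <= window) "known" else "novel"
}

#' Screen isoforms for fusion candidates
#'
#' A candidate has (a) at least one intron strictly longer than
#' `min_intron` nt (default: the annotation's median gene span) and
#' (b) exons overlapping (>= 1 nt) annotated exons of two or more
#' distinct genes.
#'
#' @param isoforms isoform structure `data.frame` (normally the
#'   splice-novel subset).
#' @param db an [annotation_db()].
#' @param min_intron intron length threshold (strict `>`).
#' @return Logical vector, one per isoform, plus attribute
#'   `"fusion_genes"`: list of the overlapped gene ids.
#' @export
screen_fusion_isoforms <- function(isoforms, db,
                                   min_intron = median_gene_length(db)) {
  ex <- db$exons
  ex$gene_id <- db$transcripts$gene_id[match(ex$transcript_id,
                                             db$transcripts$transcript_id)]
  out <- logical(nrow(isoforms))
  glist <- vector("list", nrow(isoforms))
  for (i in seq_len(nrow(isoforms))) {
    st <- isoforms$block_starts[[i]]
    en <- isoforms$block_ends[[i]]
    g <- isoform_introns(st, en)
    if (!nrow(g) || max(g$end - g$start) <= min_intron) next
    cand <- ex[ex$chrom == isoforms$chrom[i], , drop = FALSE]
    hit <- unique(cand$gene_id[
      vapply(seq_len(nrow(cand)), function(j)
        any(pmin(en, cand$end[j]) - pmax(st, cand$start[j]) > 0),
        logical(1))])
    glist[[i]] <- sort(hit)
    out[i] <- length(hit) >= 2
  }
  attr(out, "fusion_genes") <- glist
  out
}

#' Four-way isoform classification report
#'
#' Applies splice-novelty, productivity/3'UTR novelty and the fusion
#' screen to a call set, producing one exclusive label per isoform with
#' priority fusion > novel > novel_utr3 > known: a splice-novel isoform
#' passing the fusion screen is a `fusion` candidate, a splice-known
#' productive isoform whose 3' end is farther than `utr3_window` nt from
#' every annotated end of its gene is `novel_utr3`.
#'
#' @param callset an [isoform_callset()] with genes assigned.
#' @param db an [annotation_db()].
#' @param utr3_window 3'UTR novelty window (nt).
#' @param end_tolerance mono-exon containment slack (nt).
#' @param min_intron fusion intron threshold (default median gene span).
#' @return `data.frame` with one row per isoform: `isoform_id`,
#'   `gene_id`, `total_reads`, `splice`, `productive`, `utr3_end`,
#'   `utr3_dist`, `category`, `fusion_genes`.
#' @export
classify_isoforms <- function(callset, db, utr3_window = 10,
                              end_tolerance = 10,
                              min_intron = median_gene_length(db)) {
  iso <- callset$isoforms
  splice <- classify_splice_novelty(iso, db, end_tolerance)
  prod <- predict_productivity(iso, db)
  utr3_index <- collect_utr3_ends(db)
  fus <- screen_fusion_isoforms(iso, db, min_intron)
  fusion_genes <- attr(fus, "fusion_genes")

  n <- nrow(iso)
  utr3_end <- rep(NA_integer_, n)
  utr3_dist <- rep(NA_real_, n)
  category <- character(n)
  for (i in seq_len(n)) {
    if (splice[i] == "novel") {
      category[i] <- if (fus[i]) "fusion" else "novel"
      next
    }
    if (prod$productive[i]) {
      u <- extract_utr3(iso[i, , drop = FALSE], prod$stop_tx_end[i])
      utr3_end[i] <- u$utr3_end
      gid <- iso$gene_id[i]
      ends <- if (!is.na(gid) && !is.null(utr3_index[[gid]]))
        utr3_index[[gid]] else integer(0)
      utr3_dist[i] <- if (length(ends)) min(abs(ends - u$utr3_end))
                      else NA_real_
      lab <- classify_utr3_novelty(u$utr3_end, gid, utr3_index,
                                   window = utr3_window)
      category[i] <- if (lab == "novel") "novel_utr3" else "known"
    } else {
      category[i] <- "known"
    }
  }
  data.frame(isoform_id = iso$isoform_id, gene_id = iso$gene_id,
             total_reads = rowSums(callset$counts),
             splice = splice, productive = prod$productive,
             utr3_end = utr3_end, utr3_dist = utr3_dist,
             category = category,
             fusion_genes = vapply(fusion_genes, function(g)
               paste(g, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}
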