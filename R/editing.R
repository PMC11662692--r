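#' Read per-replicate A-to-G edit calls (SAILOR-style BED)
#'
#' Dialect: 6 BED columns — chrom, start (0-based), end, a
#' `coverage,edited_fraction` payload, confidence score in `[0,1]`,
#' strand.
#'
#' @param path BED file.
#' @param replicate_id,age_group labels attached to every row.
#' @return Edit-call `data.frame` (`chrom`, `pos`, `strand`, `modality`,
#'   `edited_fraction`, `coverage`, `confidence`, `replicate_id`,
#'   `age_group`).
#' @export
read_sailor_bed <- function(path, replicate_id, age_group) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  payload <- strsplit(as.character(df$V4), ",", fixed = TRUE)
  data.frame(chrom = df$V1, pos = df$V2, strand = df$V6,
             modality = "AtoI",
             edited_fraction = as.numeric(vapply(payload, `[`, "", 2)),
             coverage = as.integer(vapply(payload, `[`, "", 1)),
             confidence = as.numeric(df$V5),
             replicate_id = replicate_id, age_group = age_group,
             stringsAsFactors = FALSE)
}

#' Read per-replicate pseudouridine calls (probability TSV)
#'
#' Columns: `chrom`, `pos` (0-based), `strand`, `probability`,
#' `replicate_id`; `age_group` is supplied or taken from a column.
#'
#' @param path TSV file with header.
#' @param age_group group label (ignored if the file has a column).
#' @return Edit-call `data.frame` in the same layout as
#'   [read_sailor_bed()] (`edited_fraction` is `NA` — the pseudouridine
#'   caller emits a probability only).
#' @export
read_psi_table <- function(path, age_group = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$age_group)) df$age_group <- age_group
  data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
             modality = "Psi", edited_fraction = NA_real_,
             coverage = if (!is.null(df$coverage)) df$coverage else
               NA_integer_,
             confidence = df$probability,
             replicate_id = df$replicate_id, age_group = df$age_group,
             stringsAsFactors = FALSE)
}

#' Replicate-consensus modification sites
#'
#' A site passes in an age group iff it is called in at least
#' `n_required` replicates of that group, each call meeting the
#' thresholds: for A-to-I both `edited_fraction >= fraction_min` and
#' `confidence >= confidence_min`; for pseudouridine only
#' `confidence >= confidence_min` (the caller emits a probability, no
#' fraction). Thresholds are inclusive. The group mean edited fraction
#' is computed over the passing replicates.
#'
#' @param calls single-modality edit-call `data.frame`.
#' @param fraction_min minimal edited fraction (A-to-I; default 0.05).
#' @param confidence_min minimal confidence; default 0.99 for A-to-I,
#'   0.90 for pseudouridine.
#' @param n_required replicates required (default 3).
#' @return `data.frame` with one row per (site, age_group):
#'   `chrom`, `pos`, `strand`, `modality`, `age_group`, `n_pass`,
#'   `pass`, `mean_fraction`.
#' @export
consensus_sites <- function(calls, fraction_min = 0.05,
                            confidence_min = NULL, n_required = 3) {
  if (!nrow(calls)) stop("empty call table")
  site_key <- paste(calls$chrom, calls$pos, calls$strand)
  mix <- tapply(calls$modality, site_key,
                function(m) length(unique(m)) > 1)
  if (any(mix))
    stop("modality mixing at site ", names(mix)[which(mix)[1]])
  modality <- calls$modality[1]
  if (length(unique(calls$modality)) > 1)
    stop("call table mixes modalities; split before consensus")
  if (is.null(confidence_min))
    confidence_min <- if (modality == "AtoI") 0.99 else 0.90

  ok <- calls$confidence >= confidence_min
  if (modality == "AtoI")
    ok <- ok & calls$edited_fraction >= fraction_min

  # one call per site x replicate x group
  dup <- duplicated(paste(site_key, calls$replicate_id, calls$age_group))
  calls <- calls[!dup, , drop = FALSE]
  ok <- ok[!dup]
  site_key <- site_key[!dup]

  grp_key <- paste(site_key, calls$age_group, sep = "\r")
  n_pass <- tapply(ok, grp_key, sum)
  mean_frac <- tapply(ifelse(ok, calls$edited_fraction, NA_real_), grp_key,
                      function(v) if (all(is.na(v))) NA_real_
                                  else mean(v, na.rm = TRUE))
  first <- !duplicated(grp_key)
  res <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                    strand = calls$strand[first], modality = modality,
                    age_group = calls$age_group[first],
                    stringsAsFactors = FALSE)
  k <- grp_key[first]
  res$n_pass <- as.integer(n_pass[k])
  res$pass <- res$n_pass >= n_required
  res$mean_fraction <- as.numeric(mean_frac[k])
  res <- res[order(res$chrom, res$pos, res$strand, res$age_group), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# region of pos within one transcript's model: CDS / 3UTR / 5UTR /
# noncoding_exon / intron
.tx_region <- function(db, tid, pos) {
  e <- db$exons[db$exons$transcript_id == tid, , drop = FALSE]
  cc <- db$cds[db$cds$transcript_id == tid, , drop = FALSE]
  exonic <- any(pos >= e$start & pos < e$end)
  if (nrow(cc)) {
    if (any(pos >= cc$start & pos < cc$end)) return("CDS")
    if (exonic) {
      after_cds <- if (e$strand[1] == "-") pos < min(cc$start)
                   else pos >= max(cc$end)
      return(if (after_cds) "3UTR" else "5UTR")
    }
    return("intron")
  }
  if (exonic) "noncoding_exon" else "intron"
}

#' Assign consensus sites to gene features
#'
#' Among transcripts on the site's strand whose span contains the
#' position, the label is chosen by fixed priority
#' CDS > 3'UTR > 5'UTR > noncoding exon > intron, carrying the winning
#' transcript's gene and biotype. Positions contained only by
#' opposite-strand genes are labelled `antisense_intragenic` (excluded
#' from feature counts downstream); positions in no gene are
#' `intergenic`.
#'
#' @param sites `data.frame` with `chrom`, `pos`, `strand`.
#' @param db an [annotation_db()].
#' @return `sites` with added `feature`, `gene_id`, `biotype` columns.
#' @export
assign_site_feature <- function(sites, db) {
  prio <- c(CDS = 1, `3UTR` = 2, `5UTR` = 3, noncoding_exon = 4,
            intron = 5)
  tx <- db$transcripts
  spans <- do.call(rbind, lapply(split(db$exons, db$exons$transcript_id),
    function(e) data.frame(transcript_id = e$transcript_id[1],
                           chrom = e$chrom[1], start = min(e$start),
                           end = max(e$end), strand = e$strand[1],
                           stringsAsFactors = FALSE)))
  feature <- character(nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  biotype <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    inside <- spans$chrom == sites$chrom[i] &
              spans$start <= sites$pos[i] & spans$end > sites$pos[i]
    same <- inside & spans$strand == sites$strand[i]
    if (!any(inside)) { feature[i] <- "intergenic"; next }
    if (!any(same)) { feature[i] <- "antisense_intragenic"; next }
    tids <- spans$transcript_id[same]
    regs <- vapply(tids, function(t) .tx_region(db, t, sites$pos[i]),
                   character(1))
    best <- which.min(prio[regs])
    feature[i] <- regs[best]
    gene_id[i] <- tx$gene_id[match(tids[best], tx$transcript_id)]
    biotype[i] <- tx$biotype[match(tids[best], tx$transcript_id)]
  }
  sites$feature <- feature
  sites$gene_id <- gene_id
  sites$biotype <- biotype
  sites
}

#' Recoding consequence of an A-to-I site in coding sequence
#'
#' Locates the codon containing the site in the representative CDS (the
#' longest CDS among same-strand transcripts containing the position)
#' and evaluates the A-to-G substitution with [codon_consequence()]. The
#' transcript-strand base at the site must be `A` (genome `T` for minus
#' strand genes); anything else signals an inconsistent site call.
#'
#' @param site one-row `data.frame` with `chrom`, `pos`, `strand`.
#' @param db an [annotation_db()].
#' @param genome [Biostrings::DNAStringSet]; defaults to `db$genome`.
#' @return List: `transcript_id`, `gene_id`, `codon_index`,
#'   `codon_offset`, plus the [codon_consequence()] fields.
#' @export
recoding_consequence <- function(site, db, genome = db$genome) {
  if (is.null(genome)) stop("a genome is required")
  cand <- character(0); cds_len <- numeric(0)
  for (tid in unique(db$cds$transcript_id)) {
    cc <- db$cds[db$cds$transcript_id == tid, , drop = FALSE]
    if (cc$chrom[1] != site$chrom || cc$strand[1] != site$strand) next
    if (!any(site$pos >= cc$start & site$pos < cc$end)) next
    cand <- c(cand, tid)
    cds_len <- c(cds_len, sum(cc$end - cc$start))
  }
  if (!length(cand)) stop("site is not inside any same-strand CDS")
  tid <- cand[which.max(cds_len)]
  cc <- db$cds[db$cds$transcript_id == tid, , drop = FALSE]
  cc <- cc[order(cc$start), , drop = FALSE]
  cds_pos <- genome_to_tx(cc$start, cc$end, cc$strand[1], site$pos)
  seq <- spliced_sequence(genome, cc$chrom[1], cc$start, cc$end,
                          cc$strand[1])
  base <- substr(seq, cds_pos + 1, cds_pos + 1)
  if (base != "A")
    stop("inconsistent site call: transcript-strand base at ",
         site$chrom, ":", site$pos, " is ", base, ", not A")
  idx <- cds_pos %/% 3
  off <- cds_pos %% 3
  codon <- substr(seq, idx * 3 + 1, idx * 3 + 3)
  cons <- codon_consequence(codon, off, "G")
  c(list(transcript_id = tid,
         gene_id = db$transcripts$gene_id[match(tid,
                     db$transcripts$transcript_id)],
         codon_index = idx, codon_offset = off), cons)
}

#' Classify per-site editing change between age groups
#'
#' Restricted to sites passing consensus in both groups. The change is
#' measured in percentage points of the edited-read fraction
#' (`100 * (mean_old - mean_young)`); `relative = TRUE` switches to
#' percent change relative to the young fraction. `increase` when the
#' change exceeds `threshold`, `decrease` below `-threshold`, else
#' `stable` (strict inequalities).
#'
#' @param consensus output of [consensus_sites()] covering both groups.
#' @param threshold percentage-point (or percent, if relative) cutoff,
#'   default 10.
#' @param relative use relative percent change instead of points.
#' @return `data.frame` with `chrom`, `pos`, `strand`, `mean_young`,
#'   `mean_old`, `delta`, `class`.
#' @export
delta_editing <- function(consensus, threshold = 10, relative = FALSE) {
  key <- paste(consensus$chrom, consensus$pos, consensus$strand)
  y <- consensus[consensus$age_group == "young" & consensus$pass, ,
                 drop = FALSE]
  o <- consensus[consensus$age_group == "old" & consensus$pass, ,
                 drop = FALSE]
  ky <- paste(y$chrom, y$pos, y$strand)
  ko <- paste(o$chrom, o$pos, o$strand)
  shared <- intersect(ky, ko)
  y <- y[match(shared, ky), , drop = FALSE]
  o <- o[match(shared, ko), , drop = FALSE]
  delta <- if (relative)
    100 * (o$mean_fraction - y$mean_fraction) / y$mean_fraction
  else 100 * (o$mean_fraction - y$mean_fraction)
  cls <- ifelse(delta > threshold, "increase",
                ifelse(delta < -threshold, "decrease", "stable"))
  data.frame(chrom = y$chrom, pos = y$pos, strand = y$strand,
             mean_young = y$mean_fraction, mean_old = o$mean_fraction,
             delta = delta, class = cls, stringsAsFactors = FALSE)
}

#' Repeat-overlap enrichment of modification sites
#'
#' Compares the fraction of sites overlapping the repeat track with the
#' fraction of the genome covered by repeats (union of repeat
#' intervals), by a one-sample two-sided proportion test against the
#' genomic base fraction: normal approximation by default, exact
#' binomial via `method = "binomial"`.
#'
#' @param sites `data.frame` with `chrom`, `pos`.
#' @param repeat_track interval `data.frame` (BED-style).
#' @param chrom_sizes named integer vector.
#' @param method `"normal"` or `"binomial"`.
#' @return List: `site_fraction`, `genome_fraction`, `statistic`
#'   (z, `NA` for binomial), `p`, `n_sites`.
#' @export
repeat_enrichment <- function(sites, repeat_track, chrom_sizes,
                              method = c("normal", "binomial")) {
  method <- match.arg(method)
  n <- nrow(sites)
  if (n == 0) stop("no sites supplied")
  site_iv <- data.frame(chrom = sites$chrom, start = sites$pos,
                        end = sites$pos + 1L, stringsAsFactors = FALSE)
  x <- sum(interval_overlaps_any(site_iv, repeat_track))
  p0 <- interval_covered_bases(repeat_track) / sum(as.numeric(chrom_sizes))
  phat <- x / n
  if (method == "normal") {
    z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
    p <- 2 * stats::pnorm(-abs(z))
    list(site_fraction = phat, genome_fraction = p0, statistic = z,
         p = p, n_sites = n)
  } else {
    bt <- stats::binom.test(x, n, p0)
    list(site_fraction = phat, genome_fraction = p0, statistic = NA_real_,
         p = bt$p.value, n_sites = n)
  }
}

#' Consensus edits per gene
#'
#' @param annotated_sites output of [assign_site_feature()] restricted
#'   to passing consensus sites; intergenic and antisense sites are
#'   excluded.
#' @return Named integer vector, gene_id -> site count.
#' @export
edits_per_gene <- function(annotated_sites) {
  keep <- !is.na(annotated_sites$gene_id) &
          !annotated_sites$feature %in% c("intergenic",
                                          "antisense_intragenic")
  tab <- table(annotated_sites$gene_id[keep])
  stats::setNames(as.integer(tab), names(tab))
}

#' Overlap of edited gene sets between age groups
#'
#' @param genes_young,genes_old character vectors of gene ids.
#' @return Named integer vector `young_only`, `shared`, `old_only`.
#' @export
group_overlap <- function(genes_young, genes_old) {
  y <- unique(genes_young); o <- unique(genes_old)
  c(young_only = length(setdiff(y, o)),
    shared = length(intersect(y, o)),
    old_only = length(setdiff(o, y)))
}

#' Mean tissue z-scores of a gene set
#'
#' Each gene's expression row is standardised across tissues
#' (`(x - row mean) / row sd`); the output is the per-tissue mean of
#' these z-scores over the gene set. Genes with zero row sd are excluded
#' with a warning.
#'
#' @param expression numeric matrix, genes x tissues (rownames = genes).
#' @param gene_set character vector of gene ids.
#' @return Named numeric vector, one mean z per tissue.
#' @export
gene_set_tissue_zscore <- function(expression, gene_set) {
  rows <- intersect(gene_set, rownames(expression))
  if (!length(rows)) stop("no gene of the set is in the matrix")
  m <- expression[rows, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " gene(s) with zero variance")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(m)) stop("all genes in the set have zero variance")
  }
  z <- sweep(sweep(m, 1, rowMeans(m)), 1, sds, `/`)
  colMeans(z)
}
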