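#' Run the full synthetic-study pipeline
#'
#' Generates every input from the seeded configuration, re-ingests the
#' generated files through the package's own parsers, runs all analysis
#' stages and writes one report table per stage under `outdir/reports`.
#' Identical configurations (same seed) produce byte-identical inputs
#' and reports.
#'
#' Stages: annotation parsing and derived interval sets (stringent
#' introns / intergenic as BED and SAF, junction database, median gene
#' span); full-length read filtering with per-stage counts; fractional
#' overlap read-to-feature assignment; metagene profiles before and
#' after filtering; per-sample junction fidelity with a probit-scale
#' group comparison; isoform filtering and four-way classification;
#' poly(A) analytics (group medians, KS comparison, abundance bins,
#' delta-median classes); modification-site consensus, feature and
#' consequence annotation, editing deltas, per-gene counts,
#' pseudouridine gene-set overlap and repeat enrichment.
#'
#' @param config a [sim_config()].
#' @param outdir output directory; inputs go to `outdir/inputs`,
#'   reports to `outdir/reports`.
#' @return Invisible list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  inp <- file.path(outdir, "inputs")
  rep_dir <- file.path(outdir, "reports")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- generate + ingest ----------------------------------------------
  ann <- generate_annotation(config, inp)
  db <- parse_gff(ann$gff, ann$fasta)

  introns <- derive_stringent_introns(db)
  intergenic <- derive_stringent_intergenic(db)
  write_bed(introns, file.path(rep_dir, "stringent_introns.bed"))
  write_bed(intergenic, file.path(rep_dir, "stringent_intergenic.bed"))
  write_saf(introns, file.path(rep_dir, "stringent_introns.saf"),
            sprintf("intron_%04d", seq_len(nrow(introns))))
  write_saf(intergenic, file.path(rep_dir, "stringent_intergenic.saf"),
            sprintf("intergenic_%04d", seq_len(nrow(intergenic))))
  med_len <- median_gene_length(db)
  jdb <- build_junction_db(db)

  gen_reads <- generate_reads(config, ann, inp)
  reads <- read_read_table(gen_reads$read_tsv)

  # ---- full-length filter ---------------------------------------------
  fl <- filter_full_length(reads, db, tss_window = 10)
  write_tsv(data.frame(stage = names(fl$counts),
                       reads = as.integer(fl$counts)),
            file.path(rep_dir, "full_length_filter.tsv"))

  # ---- feature assignment ---------------------------------------------
  # three meta-features in the SAF spirit: all exonic bases, stringent
  # introns, stringent intergenic
  exonic <- interval_union(db$exons)
  feats <- rbind(
    data.frame(chrom = exonic$chrom, start = exonic$start,
               end = exonic$end, strand = "*", feature_id = "exonic",
               stringsAsFactors = FALSE),
    data.frame(chrom = introns$chrom, start = introns$start,
               end = introns$end, strand = "*", feature_id = "intron",
               stringsAsFactors = FALSE),
    data.frame(chrom = intergenic$chrom, start = intergenic$start,
               end = intergenic$end, strand = "*",
               feature_id = "intergenic", stringsAsFactors = FALSE))
  asg <- assign_reads_to_features(reads, feats, frac_overlap = 0.5)
  acat <- ifelse(asg$assignments$status == "assigned",
                 asg$assignments$feature_id, "unassigned")
  cat_counts <- table(factor(acat, levels = c("exonic", "intron",
                                              "intergenic", "unassigned")))
  write_tsv(data.frame(category = names(cat_counts),
                       reads = as.integer(cat_counts),
                       percent = 100 * as.integer(cat_counts) /
                         nrow(reads)),
            file.path(rep_dir, "feature_assignment.tsv"))

  # ---- metagene --------------------------------------------------------
  prof_pre <- metagene_profile(reads, db, n_bins = 100)
  prof_post <- metagene_profile(fl$reads, db, n_bins = 100)
  write_tsv(data.frame(bin = 1:100, pre_filter = prof_pre,
                       post_filter = prof_post),
            file.path(rep_dir, "metagene.tsv"))

  # ---- junction fidelity ----------------------------------------------
  fid <- vapply(gen_reads$sj_paths, function(p) {
    fidelity_percentage(classify_junctions(read_sj_table(p), jdb))
  }, numeric(1))
  grp <- config$samples$age_group[match(names(fid),
                                        config$samples$sample_id)]
  cmp <- compare_groups_probit(fid[grp == "young"], fid[grp == "old"])
  write_tsv(data.frame(sample = names(fid), age_group = grp,
                       unannotated_pct = unname(fid)),
            file.path(rep_dir, "junction_fidelity.tsv"))
  write_tsv(data.frame(t = cmp$t, p = cmp$p, df = cmp$df),
            file.path(rep_dir, "junction_fidelity_test.tsv"))

  # ---- isoforms --------------------------------------------------------
  gen_iso <- generate_isoform_callset(config, ann, inp)
  iso_df <- read_bed12(gen_iso$bed)
  cts <- utils::read.delim(gen_iso$counts_tsv, check.names = FALSE)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$isoform_id
  counts <- counts[iso_df$isoform_id, , drop = FALSE]
  iso_df <- assign_isoform_genes(iso_df, db)
  callset <- isoform_callset(iso_df, counts)
  kept <- filter_isoforms(callset)
  iso_report <- classify_isoforms(kept, db)
  write_tsv(iso_report, file.path(rep_dir, "isoform_classification.tsv"))

  # ---- poly(A) ---------------------------------------------------------
  gen_tails <- generate_tails(config, gen_iso$truth, inp)
  tails <- filter_pass(read_tail_table(gen_tails$tsv))$records
  dy <- group_tail_distribution(tails, "young")
  do <- group_tail_distribution(tails, "old")
  ks <- ks_compare(dy$lengths, do$lengths)
  write_tsv(data.frame(group = c("young", "old"),
                       n = c(length(dy$lengths), length(do$lengths)),
                       median_nt = c(dy$median, do$median)),
            file.path(rep_dir, "polya_group_medians.tsv"))
  write_tsv(data.frame(D = ks$D, p = ks$p),
            file.path(rep_dir, "polya_ks.tsv"))

  expr <- rowSums(callset$counts) / sum(callset$counts) * 1e6
  bins <- abundance_bins(expr)
  tails$bin <- bins[tails$isoform_id]
  bin_med <- vapply(c("low", "medium", "high"), function(b)
    stats::median(tails$tail_length[tails$bin == b & !is.na(tails$bin)]),
    numeric(1))
  write_tsv(data.frame(bin = names(bin_med), median_tail_nt = bin_med),
            file.path(rep_dir, "polya_abundance_bins.tsv"))

  med_tab <- isoform_tail_medians(tails)
  dmc <- delta_median_classes(med_tab)
  write_tsv(dmc, file.path(rep_dir, "polya_delta_classes.tsv"))

  # ---- editing ---------------------------------------------------------
  gen_ed <- generate_edit_calls(config, ann, inp)
  atoi_calls <- do.call(rbind, lapply(names(gen_ed$atoi_paths), function(k) {
    g <- sub("_rep[0-9]+$", "", k)
    r <- sub("^.*_(rep[0-9]+)$", "\\1", k)
    read_sailor_bed(gen_ed$atoi_paths[[k]], r, g)
  }))
  psi_calls <- do.call(rbind, lapply(gen_ed$psi_paths, read_psi_table))

  cons_a <- consensus_sites(atoi_calls)
  cons_p <- consensus_sites(psi_calls)
  pass_a <- unique(cons_a[cons_a$pass, c("chrom", "pos", "strand")])
  ann_a <- assign_site_feature(pass_a, db)
  cons_rec <- lapply(which(ann_a$feature == "CDS"), function(i)
    recoding_consequence(ann_a[i, ], db))
  ann_a$consequence <- NA_character_
  ann_a$consequence[ann_a$feature == "CDS"] <-
    vapply(cons_rec, `[[`, "", "consequence")
  write_tsv(ann_a, file.path(rep_dir, "atoi_consensus_annotated.tsv"))

  deltas <- delta_editing(cons_a)
  write_tsv(deltas, file.path(rep_dir, "atoi_delta_editing.tsv"))

  epg <- edits_per_gene(ann_a)
  write_tsv(data.frame(gene_id = names(epg), n_sites = epg),
            file.path(rep_dir, "atoi_edits_per_gene.tsv"))

  pass_p <- unique(cons_p[cons_p$pass, c("chrom", "pos", "strand",
                                         "age_group")])
  ann_p <- assign_site_feature(pass_p[, c("chrom", "pos", "strand")], db)
  ann_p$age_group <- pass_p$age_group
  genic <- !is.na(ann_p$gene_id)
  ov <- group_overlap(ann_p$gene_id[genic & ann_p$age_group == "young"],
                      ann_p$gene_id[genic & ann_p$age_group == "old"])
  write_tsv(data.frame(set = names(ov), genes = as.integer(ov)),
            file.path(rep_dir, "psi_gene_overlap.tsv"))

  rep_track <- utils::read.delim(gen_ed$repeat_bed, header = FALSE,
                                 col.names = c("chrom", "start", "end"))
  enr <- repeat_enrichment(ann_a, rep_track, db$chrom_sizes)
  write_tsv(data.frame(site_fraction = enr$site_fraction,
                       genome_fraction = enr$genome_fraction,
                       z = enr$statistic, p = enr$p, n = enr$n_sites),
            file.path(rep_dir, "atoi_repeat_enrichment.tsv"))

  invisible(list(db = db, median_gene_length = med_len,
                 filter_counts = fl$counts,
                 assignment = cat_counts, fidelity = fid,
                 fidelity_test = cmp, iso_report = iso_report,
                 polya = list(median_young = dy$median,
                              median_old = do$median, ks = ks,
                              bin_medians = bin_med, delta = dmc),
                 editing = list(consensus_atoi = cons_a,
                                consensus_psi = cons_p,
                                annotated = ann_a, deltas = deltas,
                                edits_per_gene = epg, psi_overlap = ov,
                                enrichment = enr),
                 truth = list(annotation = ann$truth,
                              reads = gen_reads$truth,
                              isoforms = gen_iso$truth,
                              tails = gen_tails$truth,
                              sites = gen_ed$truth)))
}
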