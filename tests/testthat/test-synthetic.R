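# a slimmed configuration keeps the generator tests fast; structure
# plants (boundary cases, gene layout) are identical to the default
small_cfg <- function(seed = 7) sim_config(seed, n_reads = 1500L)

test_that("identical seeds give byte-identical generated files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg, d1)
  a2 <- generate_annotation(cfg, d2)
  r1 <- generate_reads(cfg, a1, d1)
  r2 <- generate_reads(cfg, a2, d2)
  i1 <- generate_isoform_callset(cfg, a1, d1)
  i2 <- generate_isoform_callset(cfg, a2, d2)
  t1 <- generate_tails(cfg, i1$truth, d1)
  t2 <- generate_tails(cfg, i2$truth, d2)
  e1 <- generate_edit_calls(cfg, a1, d1)
  e2 <- generate_edit_calls(cfg, a2, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the data
  a3 <- generate_annotation(sim_config(8, n_reads = 1500L),
                            withr::local_tempdir())
  expect_false(identical(as.character(a1$db$genome[[1]]),
                         as.character(a3$db$genome[[1]])))
})

test_that("the planted median gene span is 1956 nt", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  expect_equal(median_gene_length(ann$db), 1956L)
  s <- sort(ann$truth$genes$span)
  expect_equal(s[30], 1956L)
  expect_equal(s[31], 1956L)
})

test_that("emitted GFF3/FASTA reparse to the in-memory database", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  db <- parse_gff(ann$gff, ann$fasta)
  expect_equal(db$chrom_sizes, ann$db$chrom_sizes)
  expect_setequal(db$transcripts$transcript_id,
                  ann$db$transcripts$transcript_id)
  ord <- function(e) e[order(e$transcript_id, e$start),
                       c("transcript_id", "start", "end", "strand")]
  expect_equal(ord(db$exons), ord(ann$db$exons),
               ignore_attr = TRUE)
  expect_equal(ord(db$cds), ord(ann$db$cds), ignore_attr = TRUE)
  expect_identical(as.character(db$genome[["chrS1"]]),
                   as.character(ann$db$genome[["chrS1"]]))
})

test_that("planted CDSs start with ATG and have no internal stop", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  db <- ann$db
  for (tid in unique(db$cds$transcript_id)) {
    cc <- db$cds[db$cds$transcript_id == tid, ]
    seq <- drsage:::spliced_sequence(db$genome, cc$chrom[1], cc$start,
                                     cc$end, cc$strand[1])
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
    expect_equal(substr(aa, 1, 1), "M", info = tid)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*", info = tid)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)), info = tid)
  }
})

test_that("full-length filtering recovers the planted read cohort", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  gr <- generate_reads(cfg, ann, withr::local_tempdir())
  fl <- filter_full_length(gr$reads, ann$db, tss_window = 10)
  expect_setequal(fl$reads$read_id,
                  gr$truth$reads$read_id[gr$truth$reads$expected_kept])
  expect_equal(unname(fl$counts["input"]),
               sum(fl$counts[c("secondary_supplementary",
                               "unknown_chrom", "tss_fail",
                               "polya_fail", "kept")]))
  # with no truncation every primary PASS read survives
  cfg0 <- sim_config(7, n_reads = 400L, truncation_fraction = 0)
  ann0 <- generate_annotation(cfg0, withr::local_tempdir())
  gr0 <- generate_reads(cfg0, ann0, withr::local_tempdir())
  fl0 <- filter_full_length(gr0$reads, ann0$db, tss_window = 10)
  pr <- gr0$reads[!gr0$reads$is_secondary & !gr0$reads$is_supplementary &
                  gr0$reads$polya_qc == "PASS" &
                  gr0$reads$chrom != "chrUn", ]
  expect_setequal(fl0$reads$read_id, pr$read_id)
})

test_that("truncated cohorts flatten after full-length filtering", {
  cfg <- sim_config(7, n_reads = 4000L)
  ann <- generate_annotation(cfg, withr::local_tempdir())
  gr <- generate_reads(cfg, ann, withr::local_tempdir())
  pre <- metagene_profile(gr$reads, ann$db, n_bins = 20)
  post <- metagene_profile(
    filter_full_length(gr$reads, ann$db, 10)$reads, ann$db, n_bins = 20)
  # truncations bias coverage 3'-ward: rising pre-filter trend,
  # measured as the difference between 3'-half and 5'-half means
  bias_pre <- mean(pre[11:20]) - mean(pre[1:10])
  bias_post <- mean(post[11:20]) - mean(post[1:10])
  expect_gt(bias_pre, 0.2)
  expect_lt(abs(bias_post), abs(bias_pre) / 2)
})

test_that("generated junction tables carry the exact planted fractions", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  gr <- generate_reads(cfg, ann, withr::local_tempdir())
  jdb <- build_junction_db(ann$db)
  sj <- read_sj_table(gr$sj_paths[["day1"]])
  cl <- classify_junctions(sj, jdb)
  expect_equal(sum(cl$unique_reads),
               cfg$junction_reads_per_sample)
  expect_equal(fidelity_percentage(cl),
               unname(gr$truth$fidelity["day1"]))
  # classification agrees with the truth flags row by row
  tr <- gr$truth$junctions
  key_t <- paste(tr$chrom, tr$start, tr$end)
  expect_identical(cl$annotated,
                   tr$annotated[match(paste(cl$chrom, cl$start, cl$end),
                                      key_t)])
})

test_that("every planted boundary case is present in the default plants", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, withr::local_tempdir())
  gi <- generate_isoform_callset(cfg, ann, withr::local_tempdir())
  expect_true(any(gi$truth$total_reads == 19))
  expect_true(any(gi$truth$total_reads == 20))
  # 10 nt (known) and 11 nt (novel) 3'UTR offsets
  expect_true("iso_utr_g053_b10" %in% gi$truth$isoform_id)
  expect_true("iso_utr_g021" %in% gi$truth$isoform_id)
  # 1956 nt (novel) and >1956 nt (fusion) bridging introns
  b <- gi$callset$isoforms[gi$callset$isoforms$isoform_id ==
                             "iso_boundary_g037_g038", ]
  expect_equal(b$block_starts[[1]][2] - b$block_ends[[1]][1], 1956L)
  ed <- generate_edit_calls(cfg, ann, withr::local_tempdir())
  expect_true(any(ed$truth$site_id == "a09"))  # 0.05/0.99 boundary pass
  expect_true(any(ed$truth$site_id == "a10"))  # 0.049/0.989 fail
})
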