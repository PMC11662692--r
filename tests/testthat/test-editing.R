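mk_calls <- function(pos, rep_id, group, frac, conf, modality = "AtoI",
                     strand = "+") {
  data.frame(chrom = "c", pos = pos, strand = strand,
             modality = modality, edited_fraction = frac,
             coverage = 50L, confidence = conf, replicate_id = rep_id,
             age_group = group, stringsAsFactors = FALSE)
}

test_that("A-to-I consensus needs both thresholds in all replicates", {
  calls <- rbind(
    mk_calls(100, c("r1", "r2", "r3"), "young",
             c(0.06, 0.05, 0.07), c(0.995, 0.999, 0.992)),
    mk_calls(200, c("r1", "r2", "r3"), "young",
             c(0.04, 0.30, 0.30), c(0.999, 0.999, 0.999)),
    mk_calls(300, c("r1", "r2", "r3"), "young",
             c(0.30, 0.30, 0.30), c(0.989, 0.999, 0.999)),
    mk_calls(400, c("r1", "r2"), "young",
             c(0.30, 0.30), c(0.999, 0.999)))
  res <- consensus_sites(calls)
  pass <- res$pos[res$pass]
  expect_equal(pass, 100)
  expect_equal(res$mean_fraction[res$pos == 100], mean(c(0.06, 0.05, 0.07)))
  # boundary: exactly 0.05 / 0.99 passes (inclusive)
  b <- consensus_sites(mk_calls(1, c("r1", "r2", "r3"), "young",
                                rep(0.05, 3), rep(0.99, 3)))
  expect_true(b$pass)
})

test_that("pseudouridine consensus ignores the edited fraction", {
  calls <- mk_calls(10, c("r1", "r2", "r3"), "old", NA_real_,
                    c(0.95, 0.90, 0.91), modality = "Psi")
  res <- consensus_sites(calls)
  expect_true(res$pass)
  fail <- consensus_sites(mk_calls(10, c("r1", "r2", "r3"), "old",
                                   NA_real_, c(0.95, 0.89, 0.91),
                                   modality = "Psi"))
  expect_false(fail$pass)
})

test_that("consensus equals a brute-force filter on random call tables", {
  set.seed(5)
  n_sites <- 400
  rows <- list()
  for (s in seq_len(n_sites)) {
    for (g in c("young", "old")) {
      reps <- sample(c("r1", "r2", "r3"),
                     sample(1:3, 1, prob = c(0.1, 0.2, 0.7)))
      rows[[length(rows) + 1]] <- mk_calls(
        s, reps, g, round(runif(length(reps), 0.0, 0.12), 3),
        round(runif(length(reps), 0.97, 1.0), 3))
    }
  }
  calls <- do.call(rbind, rows)
  res <- consensus_sites(calls, fraction_min = 0.05,
                         confidence_min = 0.99)
  # brute force
  key <- paste(calls$pos, calls$age_group)
  for (k in unique(key)) {
    d <- calls[key == k, ]
    ok <- d$edited_fraction >= 0.05 & d$confidence >= 0.99
    expected <- sum(ok) >= 3
    got <- res$pass[res$pos == d$pos[1] & res$age_group == d$age_group[1]]
    expect_identical(got, expected, info = k)
  }
  # monotonicity: tightening thresholds never adds sites
  tighter <- consensus_sites(calls, fraction_min = 0.06,
                             confidence_min = 0.995)
  k_res <- paste(res$pos, res$age_group)[res$pass]
  k_tight <- paste(tighter$pos, tighter$age_group)[tighter$pass]
  expect_true(all(k_tight %in% k_res))
})

test_that("modality mixing at one site is an error", {
  calls <- rbind(mk_calls(5, "r1", "young", 0.1, 0.99),
                 mk_calls(5, "r1", "young", NA, 0.95, modality = "Psi"))
  expect_error(consensus_sites(calls), "modality")
})

test_that("site features follow the fixed priority and strand rules", {
  db <- toy_db()
  # gA (+): exons [10,40)+[60,90), CDS [20,40)+[60,80)
  sites <- data.frame(
    chrom = "chrT",
    pos = c(25L, 85L, 12L, 45L, 105L, 45L),
    strand = c("+", "+", "+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  res <- assign_site_feature(sites, db)
  expect_equal(res$feature, c("CDS", "3UTR", "5UTR", "intron",
                              "intergenic", "antisense_intragenic"))
  expect_equal(res$gene_id[1], "gA")
  expect_true(is.na(res$gene_id[5]))
  # minus-strand gene: 3'UTR is at the low-coordinate side
  res2 <- assign_site_feature(
    data.frame(chrom = "chrT", pos = 125L, strand = "-"), db)
  expect_equal(res2$feature, "3UTR")
  expect_equal(res2$gene_id, "gB")
})

test_that("CDS beats intron when transcripts disagree", {
  tx <- data.frame(transcript_id = c("t1", "t2"),
                   gene_id = c("g1", "g2"), chrom = "c", strand = "+",
                   biotype = "x")
  ex <- rbind(
    data.frame(transcript_id = "t1", chrom = "c", start = c(0L, 50L),
               end = c(20L, 70L), strand = "+"),
    data.frame(transcript_id = "t2", chrom = "c", start = c(0L, 30L),
               end = c(10L, 40L), strand = "+"))
  cds <- data.frame(transcript_id = "t2", chrom = "c", start = 30L,
                    end = 40L, strand = "+")
  db <- annotation_db(tx, ex, cds, c(c = 100L))
  # pos 35: intron of t1, CDS of t2 -> CDS wins
  res <- assign_site_feature(
    data.frame(chrom = "c", pos = 35L, strand = "+"), db)
  expect_equal(res$feature, "CDS")
  expect_equal(res$gene_id, "g2")
})

test_that("recoding consequence works through minus-strand CDS", {
  # gene on -: CDS genomic [10,22), transcript seq = revcomp
  # transcript CDS: ATG AGA TAA  -> genomic plus strand: TTATCTCAT
  txseq <- c("ATG", "AGA", "TAA", "CAT")  # 12 nt incl. dummy
  cds_tx <- paste(txseq[1:3], collapse = "")
  gseq_cds <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds_tx)))
  chars <- rep("G", 60)
  chars[11:19] <- strsplit(gseq_cds, "")[[1]]
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "cm"
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "cm",
                   strand = "-", biotype = "protein_coding")
  ex <- data.frame(transcript_id = "t1", chrom = "cm", start = 5L,
                   end = 25L, strand = "-")
  cds <- data.frame(transcript_id = "t1", chrom = "cm", start = 10L,
                    end = 19L, strand = "-")
  db <- annotation_db(tx, ex, cds, c(cm = 60L), genome)
  # transcript codon 2 is AGA; its first A is CDS position 3 ->
  # genomic position: cds interval [10,19), minus strand, cds_pos 3 ->
  # genomic 19 - 1 - 3 = 15; plus-strand base there is T
  expect_equal(as.character(Biostrings::subseq(genome[["cm"]], 16, 16)),
               "T")
  res <- recoding_consequence(
    data.frame(chrom = "cm", pos = 15L, strand = "-"), db)
  expect_equal(res$consequence, "missense")
  expect_equal(c(res$aa_before, res$aa_after), c("R", "G"))
  expect_true(res$property_change)
  # a non-A transcript base is an inconsistency error
  expect_error(recoding_consequence(
    data.frame(chrom = "cm", pos = 16L, strand = "-"), db), "not A")
})

test_that("editing deltas classify on percentage points of fraction", {
  cons <- data.frame(
    chrom = "c", pos = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
    strand = "+", modality = "AtoI",
    age_group = rep(c("young", "old"), 5),
    n_pass = 3L,
    pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
             TRUE, TRUE),
    mean_fraction = c(0.20, 0.35, 0.20, 0.25, 0.35, 0.22, 0.10, 0.50,
                      0.20, 0.301),
    stringsAsFactors = FALSE)
  d <- delta_editing(cons, threshold = 10)
  # site 4 fails in old -> excluded
  expect_equal(d$pos, c(1, 2, 3, 5))
  expect_equal(d$class, c("increase", "stable", "decrease", "increase"))
  expect_equal(d$delta[1], 15)
  # a +10.0 point change is stable (strict >)
  cons$mean_fraction[10] <- 0.30
  d2 <- delta_editing(cons)
  expect_equal(d2$class[d2$pos == 5], "stable")
  # relative mode
  dr <- delta_editing(cons, relative = TRUE)
  expect_equal(dr$delta[dr$pos == 1], 75)
})

test_that("repeat enrichment compares site and genome fractions", {
  reps <- data.frame(chrom = "c", start = c(0L, 500L),
                     end = c(300L, 800L))
  sizes <- c(c = 1000L)
  inside <- data.frame(chrom = "c", pos = c(10L, 100L, 290L, 600L))
  res <- repeat_enrichment(inside, reps, sizes)
  expect_equal(res$site_fraction, 1)
  expect_equal(res$genome_fraction, 0.6)
  expect_true(res$p < 0.2)
  # all sites in repeats vs a 30% genome: overwhelming
  reps30 <- data.frame(chrom = "c", start = 0L, end = 300L)
  many <- data.frame(chrom = "c", pos = rep(seq(10L, 290L, by = 5L), 3))
  expect_true(repeat_enrichment(many, reps30, sizes)$p < 1e-6)
  # binomial flag agrees in direction
  expect_true(repeat_enrichment(many, reps30, sizes,
                                method = "binomial")$p < 1e-6)
  expect_error(repeat_enrichment(inside[0, , drop = FALSE], reps, sizes),
               "no sites")
})

test_that("edits per gene and group overlap are simple set summaries", {
  ann <- data.frame(gene_id = c("a", "a", "a", "b", NA, "c"),
                    feature = c("CDS", "3UTR", "intron", "CDS",
                                "intergenic", "antisense_intragenic"))
  epg <- edits_per_gene(ann)
  expect_equal(epg, c(a = 3L, b = 1L))
  expect_equal(group_overlap(c("a", "b"), c("b", "c")),
               c(young_only = 1L, shared = 1L, old_only = 1L))
  expect_equal(group_overlap(c("a", "b"), c("a", "b")),
               c(young_only = 0L, shared = 2L, old_only = 0L))
  set.seed(8)
  y <- sample(letters, 12); o <- sample(letters, 15)
  ov <- group_overlap(y, o)
  expect_equal(unname(ov["shared"]), length(intersect(y, o)))
  expect_equal(sum(ov), length(union(y, o)))
})

test_that("tissue z-scores standardise rows before averaging", {
  set.seed(13)
  m <- matrix(rnorm(50, 10, 3), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("t", 1:10)))
  z <- gene_set_tissue_zscore(m, paste0("g", 1:5))
  direct <- colMeans(t(apply(m, 1, function(x) (x - mean(x)) / sd(x))))
  expect_equal(z, direct, tolerance = 1e-12)
  # per-row standardisation: mean 0, sd 1
  zr <- t(apply(m, 1, function(x) (x - mean(x)) / sd(x)))
  expect_true(all(abs(rowMeans(zr)) < 1e-9))
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-9))
  # constant rows are excluded with a warning
  m2 <- rbind(m, g6 = rep(4, 10))
  expect_warning(z2 <- gene_set_tissue_zscore(m2, paste0("g", 1:6)),
                 "zero variance")
  expect_equal(z2, direct, tolerance = 1e-12)
  # a gene expressed in one tissue peaks there
  m3 <- matrix(c(10, rep(0, 9)), nrow = 1,
               dimnames = list("solo", paste0("t", 1:10)))
  z3 <- gene_set_tissue_zscore(m3, "solo")
  expect_equal(names(which.max(z3)), "t1")
})
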