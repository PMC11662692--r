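# helper: minimal callset from totals and gene ids
mk_callset <- function(totals, genes, chain_starts = NULL) {
  n <- length(totals)
  iso <- data.frame(isoform_id = paste0("i", seq_len(n)), chrom = "c",
                    strand = "+", stringsAsFactors = FALSE)
  iso$block_starts <- replicate(n, c(0L, 100L), simplify = FALSE)
  iso$block_ends <- replicate(n, c(50L, 150L), simplify = FALSE)
  iso$gene_id <- genes
  counts <- cbind(s1 = floor(totals / 2), s2 = ceiling(totals / 2))
  rownames(counts) <- iso$isoform_id
  isoform_callset(iso, counts)
}

test_that("isoform filter applies the 20-read and 10%-of-gene rules", {
  cs <- mk_callset(c(19, 20, 180, 20, 200, 21),
                   c("gA", "gB", "gC", "gC", "gD", "gD"))
  kept <- filter_isoforms(cs)
  # 19 reads dropped; 20 kept; 180/20 both kept (20/200 = 10%,
  # inclusive); 21/221 = 9.5% dropped by the fraction rule
  expect_setequal(kept$isoforms$isoform_id, c("i2", "i3", "i4", "i5"))
  # unassigned isoforms pass the fraction rule vacuously
  cs2 <- mk_callset(c(25, 1000), c(NA, NA))
  expect_setequal(filter_isoforms(cs2)$isoforms$isoform_id,
                  c("i1", "i2"))
})

test_that("isoform filter is idempotent and matches a brute-force oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 25
    totals <- sample(1:300, n, replace = TRUE)
    genes <- sample(c(paste0("g", 1:6), NA), n, replace = TRUE)
    cs <- mk_callset(totals, genes)
    kept <- filter_isoforms(cs)
    # oracle
    tot <- rowSums(cs$counts)
    keep <- logical(n)
    for (i in seq_len(n)) {
      ok_reads <- tot[i] >= 20
      ok_frac <- if (is.na(genes[i])) TRUE
        else tot[i] >= 0.10 * sum(tot[!is.na(genes) & genes == genes[i]])
      keep[i] <- ok_reads && ok_frac
    }
    expect_setequal(kept$isoforms$isoform_id,
                    cs$isoforms$isoform_id[keep])
    twice <- filter_isoforms(kept)
    expect_identical(twice$isoforms$isoform_id,
                     kept$isoforms$isoform_id)
  }
})

test_that("splice novelty is decided by the intron chain alone", {
  db <- toy_db()
  mk_iso <- function(st, en, strand = "+") {
    iso <- data.frame(isoform_id = "x", chrom = "chrT", strand = strand,
                      stringsAsFactors = FALSE)
    iso$block_starts <- list(as.integer(st))
    iso$block_ends <- list(as.integer(en))
    iso$gene_id <- NA_character_
    iso
  }
  # same chain as gA.t1 ([40,60) intron), different terminal ends
  expect_equal(classify_splice_novelty(mk_iso(c(5, 60), c(40, 95)), db),
               "known")
  # shifted acceptor -> novel
  expect_equal(classify_splice_novelty(mk_iso(c(5, 65), c(40, 95)), db),
               "novel")
  # right chain on the wrong strand -> novel
  expect_equal(classify_splice_novelty(mk_iso(c(5, 60), c(40, 95), "-"),
                                       db), "novel")
})

test_that("mono-exonic isoforms use tolerant containment", {
  tx <- data.frame(transcript_id = "m.t1", gene_id = "m", chrom = "c",
                   strand = "+", biotype = "x")
  ex <- data.frame(transcript_id = "m.t1", chrom = "c", start = 100L,
                   end = 200L, strand = "+")
  db <- annotation_db(tx, ex, NULL, c(c = 1000L))
  iso <- data.frame(isoform_id = "x", chrom = "c", strand = "+",
                    stringsAsFactors = FALSE)
  iso$block_starts <- list(95L); iso$block_ends <- list(205L)
  iso$gene_id <- NA_character_
  expect_equal(classify_splice_novelty(iso, db, end_tolerance = 10),
               "known")
  expect_equal(classify_splice_novelty(iso, db, end_tolerance = 2),
               "novel")
})

# a 300 nt chromosome whose gene gP (+) has exons [10,40)+[60,100),
# CDS [20,40)+[60,70): ATG at genomic 20, TAA at 67; background all C
prod_db <- function() {
  chars <- rep("C", 300)
  chars[21:23] <- c("A", "T", "G")
  chars[68:70] <- c("T", "A", "A")
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrP"
  tx <- data.frame(transcript_id = c("gP.t1", "gQ.t1"),
                   gene_id = c("gP", "gQ"), chrom = "chrP",
                   strand = "+", biotype = "protein_coding",
                   stringsAsFactors = FALSE)
  ex <- rbind(
    data.frame(transcript_id = "gP.t1", chrom = "chrP",
               start = c(10L, 60L), end = c(40L, 100L), strand = "+"),
    data.frame(transcript_id = "gQ.t1", chrom = "chrP", start = 150L,
               end = 180L, strand = "+"))
  cds <- data.frame(transcript_id = "gP.t1", chrom = "chrP",
                    start = c(20L, 60L), end = c(40L, 70L), strand = "+")
  annotation_db(tx, ex, cds, c(chrP = 300L), genome)
}

test_that("productivity finds the annotated start and in-frame stop", {
  db <- prod_db()
  iso <- data.frame(isoform_id = "full", chrom = "chrP", strand = "+",
                    stringsAsFactors = FALSE)
  iso$block_starts <- list(c(10L, 60L))
  iso$block_ends <- list(c(40L, 100L))
  iso$gene_id <- "gP"
  res <- predict_productivity(iso, db)
  expect_true(res$productive)
  expect_equal(res$start_tx, 10L)
  expect_equal(res$stop_tx_start, 37L)   # tx coord of TAA
  expect_equal(res$stop_tx_end, 40L)
})

test_that("an isoform with no start codon is unproductive", {
  db <- prod_db()
  iso <- data.frame(isoform_id = "noatg", chrom = "chrP", strand = "+",
                    stringsAsFactors = FALSE)
  iso$block_starts <- list(150L); iso$block_ends <- list(180L)
  iso$gene_id <- "gQ"
  res <- predict_productivity(iso, db)
  expect_false(res$productive)
  expect_equal(res$reason, "no_start_codon")
})

test_that("run-through isoforms without a stop are unproductive", {
  db <- prod_db()
  # truncate before the stop codon: exons [10,40) + [60,66)
  iso <- data.frame(isoform_id = "runthrough", chrom = "chrP",
                    strand = "+", stringsAsFactors = FALSE)
  iso$block_starts <- list(c(10L, 60L)); iso$block_ends <- list(c(40L, 66L))
  iso$gene_id <- "gP"
  res <- predict_productivity(iso, db)
  expect_false(res$productive)
  expect_equal(res$reason, "no_stop_codon")
})

test_that("3'UTR extraction returns spliced intervals and the 3' end", {
  iso <- data.frame(isoform_id = "full", chrom = "chrP", strand = "+",
                    stringsAsFactors = FALSE)
  iso$block_starts <- list(c(10L, 60L))
  iso$block_ends <- list(c(40L, 100L))
  u <- extract_utr3(iso, 40L)   # stop ends at tx 40 -> UTR [40,70) tx
  expect_equal(u$length, 30L)
  expect_equal(nrow(u$intervals), 1)
  expect_equal(u$intervals$start, 70L)
  expect_equal(u$intervals$end, 100L)
  expect_equal(u$utr3_end, 100L)
  # stop in the penultimate exon -> two intervals
  u2 <- extract_utr3(iso, 25L)
  expect_equal(nrow(u2$intervals), 2)
  expect_equal(u2$intervals$start, c(35L, 60L))
  expect_equal(u2$intervals$end, c(40L, 100L))
  expect_equal(u2$length, 45L)
})

test_that("3'UTR novelty uses an inclusive 10 nt window on the same gene", {
  idx <- list(gA = c(90L), gB = c(500L))
  expect_equal(classify_utr3_novelty(90L, "gA", idx), "known")
  expect_equal(classify_utr3_novelty(100L, "gA", idx), "known")   # 10 nt
  expect_equal(classify_utr3_novelty(101L, "gA", idx), "novel")   # 11 nt
  expect_equal(classify_utr3_novelty(80L, "gA", idx), "known")    # |.| rule
  # gene scoping: 500 belongs to gB only
  expect_equal(classify_utr3_novelty(500L, "gA", idx), "novel")
  expect_equal(classify_utr3_novelty(500L, "gA", idx,
                                     gene_scope = FALSE), "known")
})

test_that("fusion screen needs a long intron AND exons of two genes", {
  tx <- data.frame(transcript_id = c("gX.t1", "gY.t1"),
                   gene_id = c("gX", "gY"), chrom = "c", strand = "+",
                   biotype = "x")
  ex <- rbind(
    data.frame(transcript_id = "gX.t1", chrom = "c",
               start = c(0L, 150L), end = c(100L, 250L), strand = "+"),
    data.frame(transcript_id = "gY.t1", chrom = "c",
               start = c(2300L, 2450L), end = c(2400L, 2550L),
               strand = "+"))
  db <- annotation_db(tx, ex, NULL, c(c = 6000L))
  mk <- function(st, en) {
    iso <- data.frame(isoform_id = "f", chrom = "c", strand = "+",
                      stringsAsFactors = FALSE)
    iso$block_starts <- list(as.integer(st))
    iso$block_ends <- list(as.integer(en))
    iso$gene_id <- NA_character_
    iso
  }
  # 2050 nt intron bridging both genes -> candidate
  expect_true(screen_fusion_isoforms(mk(c(200, 2300), c(250, 2350)), db,
                                     min_intron = 1956))
  # intron exactly 1956 nt -> not a candidate (strict >)
  expect_false(screen_fusion_isoforms(mk(c(200, 2206), c(250, 2300)), db,
                                      min_intron = 1956))
  # long intron but exons within one gene's neighbourhood only
  expect_false(screen_fusion_isoforms(mk(c(0, 2020), c(50, 2070)), db,
                                      min_intron = 1956))
  # the gene list is reported
  res <- screen_fusion_isoforms(mk(c(200, 2300), c(250, 2350)), db,
                                min_intron = 1956)
  expect_equal(attr(res, "fusion_genes")[[1]], c("gX", "gY"))
})

test_that("gene assignment takes the gene with most exonic overlap", {
  db <- toy_db()
  iso <- data.frame(isoform_id = "x", chrom = "chrT", strand = "+",
                    stringsAsFactors = FALSE)
  iso$block_starts <- list(c(10L, 60L))
  iso$block_ends <- list(c(40L, 90L))
  iso$gene_id <- NA_character_
  expect_equal(assign_isoform_genes(iso, db)$gene_id, "gA")
  # opposite strand only -> unassigned under same_strand
  iso$strand <- "-"
  expect_true(is.na(assign_isoform_genes(iso, db)$gene_id))
  expect_equal(assign_isoform_genes(iso, db,
                                    same_strand = FALSE)$gene_id, "gA")
})
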