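test_that("parse_gff converts coordinates and groups transcripts", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fa")
  writeLines(c(">chrI", strrep("ACGT", 50)), fasta)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsrc\tgene\t11\t100\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chrI\tsrc\tmRNA\t11\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chrI\tsrc\texon\t11\t20\t.\t+\t.\tID=t1.e1;Parent=t1",
    "chrI\tsrc\texon\t41\t100\t.\t+\t.\tID=t1.e2;Parent=t1",
    "chrI\tsrc\tmRNA\t11\t90\t.\t+\t.\tID=t2;Parent=g1",
    "chrI\tsrc\texon\t11\t90\t.\t+\t.\tID=t2.e1;Parent=t2"), gff)
  db <- parse_gff(gff, fasta)
  expect_equal(nrow(db$genes), 1)
  expect_equal(nrow(db$transcripts), 2)
  e1 <- db$exons[db$exons$transcript_id == "t1", ]
  expect_equal(e1$start, c(10L, 40L))   # 1-based 11 -> 0-based 10
  expect_equal(e1$end, c(20L, 100L))
  expect_equal(db$chrom_sizes[["chrI"]], 200L)
})

test_that("parse_gff rejects exons outside chromosome bounds", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "g.fa")
  writeLines(c(">chrI", strrep("A", 60)), fasta)
  gff <- file.path(dir, "a.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chrI\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "chrI\tsrc\texon\t1\t100\t.\t+\t.\tID=t1.e1;Parent=t1"), gff)
  expect_error(parse_gff(gff, fasta), "outside chromosome bounds")
})

test_that("annotation_db rejects transcripts with no exons", {
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   chrom = "c", strand = "+", biotype = "x")
  ex <- data.frame(transcript_id = "t1", chrom = "c", start = 0L,
                   end = 10L, strand = "+")
  expect_error(annotation_db(tx, ex, NULL, c(c = 100L)), "no exons")
})

test_that("stringent introns follow the any-exon subtraction rule", {
  tx <- data.frame(transcript_id = c("t1", "t2"),
                   gene_id = c("g1", "g2"), chrom = "c",
                   strand = c("+", "+"), biotype = "x")
  ex <- rbind(
    data.frame(transcript_id = "t1", chrom = "c",
               start = c(0L, 20L), end = c(10L, 30L), strand = "+"),
    data.frame(transcript_id = "t2", chrom = "c",
               start = 12L, end = 18L, strand = "+"))
  db1 <- annotation_db(tx[1, ], ex[1:2, ], NULL, c(c = 100L))
  expect_equal(derive_stringent_introns(db1)[, c("start", "end")],
               data.frame(start = 10L, end = 20L))
  db2 <- annotation_db(tx, ex, NULL, c(c = 100L))
  expect_equal(derive_stringent_introns(db2)[, c("start", "end")],
               data.frame(start = c(10L, 18L), end = c(12L, 20L)))
})

test_that("stringent intergenic handles chromosome termini", {
  tx <- data.frame(transcript_id = c("t1", "t2"),
                   gene_id = c("g1", "g2"), chrom = "c",
                   strand = "+", biotype = "x")
  ex <- rbind(
    data.frame(transcript_id = "t1", chrom = "c", start = 0L, end = 30L,
               strand = "+"),
    data.frame(transcript_id = "t2", chrom = "c", start = 50L, end = 80L,
               strand = "+"))
  db <- annotation_db(tx, ex, NULL, c(c = 100L))
  expect_equal(derive_stringent_intergenic(db)[, c("start", "end")],
               data.frame(start = 30L, end = 50L))
  with_term <- derive_stringent_intergenic(db, include_termini = TRUE)
  expect_equal(with_term[, c("start", "end")],
               data.frame(start = c(30L, 80L), end = c(50L, 100L)))
})

test_that("interval derivations match the per-base oracle on random toys", {
  for (seed in 1:25) {
    db <- random_toy_db(seed)
    len <- db$chrom_sizes[["chrR"]]
    m <- perbase_masks(db, "chrR", len)
    intr <- derive_stringent_introns(db)
    expect_identical(intervals_to_mask(intr, len), m$gap & !m$exon,
                     info = paste("introns seed", seed))
    ig <- derive_stringent_intergenic(db, include_termini = TRUE)
    expect_identical(intervals_to_mask(ig, len), !m$span & !m$exon,
                     info = paste("intergenic seed", seed))
    # the three sets tile the chromosome
    expect_true(all(m$exon | (m$gap & !m$exon) | (!m$span & !m$exon)))
  }
})

test_that("junction database collapses shared introns", {
  tx <- data.frame(transcript_id = c("t1", "t2"),
                   gene_id = c("g1", "g1"), chrom = "c", strand = "+",
                   biotype = "x")
  ex <- rbind(
    data.frame(transcript_id = "t1", chrom = "c",
               start = c(0L, 20L, 40L), end = c(10L, 30L, 50L),
               strand = "+"),
    data.frame(transcript_id = "t2", chrom = "c",
               start = c(0L, 20L), end = c(10L, 30L), strand = "+"))
  db <- annotation_db(tx, ex, NULL, c(c = 100L))
  jdb <- build_junction_db(db)
  expect_equal(nrow(jdb), 2)  # [10,20) shared, [30,40) unique
  expect_setequal(paste(jdb$start, jdb$end), c("10 20", "30 40"))
})

test_that("junction database equals brute-force enumeration on random toys", {
  for (seed in 26:40) {
    db <- random_toy_db(seed)
    jdb <- build_junction_db(db)
    brute <- character(0)
    for (tid in unique(db$exons$transcript_id)) {
      e <- db$exons[db$exons$transcript_id == tid, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1)
        brute <- c(brute, paste(e$chrom[1], e$end[-nrow(e)], e$start[-1],
                                e$strand[1]))
    }
    expect_setequal(paste(jdb$chrom, jdb$start, jdb$end, jdb$strand),
                    unique(brute))
  }
})

test_that("median gene length uses half-away-from-zero rounding", {
  mk <- function(spans) {
    tx <- data.frame(transcript_id = paste0("t", seq_along(spans)),
                     gene_id = paste0("g", seq_along(spans)),
                     chrom = "c", strand = "+", biotype = "x")
    ex <- data.frame(transcript_id = tx$transcript_id, chrom = "c",
                     start = seq(0L, by = 5000L,
                                 length.out = length(spans)),
                     end = seq(0L, by = 5000L,
                               length.out = length(spans)) + spans,
                     strand = "+")
    annotation_db(tx, ex, NULL, c(c = 5100000L))
  }
  expect_equal(median_gene_length(mk(c(100L, 200L, 300L))), 200L)
  expect_equal(median_gene_length(mk(c(100L, 200L))), 150L)
  expect_equal(median_gene_length(mk(c(100L, 201L))), 151L)  # 150.5 up

  set.seed(99)
  spans <- sample(100:5000, 1000, replace = TRUE)
  db <- mk(as.integer(spans))
  s <- sort(spans)
  oracle <- (s[500] + s[501]) / 2
  oracle <- as.integer(sign(oracle) * floor(abs(oracle) + 0.5))
  expect_equal(median_gene_length(db), oracle)
  # invariance under reordering
  perm <- sample(1000)
  expect_equal(median_gene_length(mk(as.integer(spans[perm]))), oracle)
})

test_that("3'UTR ends are strand-aware and restricted to coding tx", {
  db <- toy_db()
  ends <- collect_utr3_ends(db)
  expect_equal(ends$gA, 90L)   # + strand: max exon end
  expect_equal(ends$gB, 120L)  # - strand: min exon start
  # drop CDS -> no ends
  db2 <- annotation_db(db$transcripts, db$exons, NULL, db$chrom_sizes)
  expect_length(collect_utr3_ends(db2), 0)
})

test_that("TSS set is strand-aware", {
  tss <- collect_tss(toy_db())
  expect_equal(tss$pos[tss$transcript_id == "gA.t1"], 10L)
  expect_equal(tss$pos[tss$transcript_id == "gB.t1"], 190L)
})
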