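# Toy annotation builders and per-base oracles shared across tests.

# small fixed two-gene annotation on one 200 nt chromosome:
#   gA (+): tx gA.t1 exons [10,40) [60,90), CDS [20,40)+[60,80)
#   gB (-): tx gB.t1 exons [120,150) [160,190), CDS [130,150)+[160,180)
toy_db <- function(genome = NULL) {
  tx <- data.frame(
    transcript_id = c("gA.t1", "gB.t1"),
    gene_id = c("gA", "gB"),
    chrom = "chrT", strand = c("+", "-"),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  ex <- data.frame(
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1"),
    chrom = "chrT",
    start = c(10L, 60L, 120L, 160L),
    end = c(40L, 90L, 150L, 190L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1"),
    chrom = "chrT",
    start = c(20L, 60L, 130L, 160L),
    end = c(40L, 80L, 150L, 180L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  annotation_db(tx, ex, cds, c(chrT = 200L), genome)
}

# random toy annotation: possibly overlapping genes, 1-2 transcripts
# each, on one chromosome
random_toy_db <- function(seed, chrom_len = 600L) {
  set.seed(seed)
  n_genes <- sample(2:5, 1)
  tx <- list(); ex <- list()
  for (g in seq_len(n_genes)) {
    gid <- paste0("g", g)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(1:2, 1)
    for (t in seq_len(n_tx)) {
      tid <- paste0(gid, ".t", t)
      k <- sample(1:4, 1)
      # 2k distinct sorted breakpoints -> k exons with gaps >= 1
      b <- sort(sample(0:(chrom_len - 1), 2 * k))
      st <- b[seq(1, 2 * k, by = 2)]
      en <- b[seq(2, 2 * k, by = 2)]
      ok <- en > st
      st <- st[ok]; en <- en[ok]
      if (!length(st)) { st <- 0L; en <- 10L }
      tx[[length(tx) + 1]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = "chrR",
        strand = strand, biotype = "protein_coding",
        stringsAsFactors = FALSE)
      ex[[length(ex) + 1]] <- data.frame(
        transcript_id = tid, chrom = "chrR", start = st, end = en,
        strand = strand, stringsAsFactors = FALSE)
    }
  }
  annotation_db(do.call(rbind, tx), do.call(rbind, ex), NULL,
                c(chrR = chrom_len))
}

# per-base occupancy oracle over one chromosome of a db
# returns logical vectors: exon, gap (inter-exon within some transcript),
# span (within some transcript span)
perbase_masks <- function(db, chrom, len) {
  exon <- logical(len); gap <- logical(len); span <- logical(len)
  for (tid in unique(db$exons$transcript_id)) {
    e <- db$exons[db$exons$transcript_id == tid &
                  db$exons$chrom == chrom, , drop = FALSE]
    if (!nrow(e)) next
    e <- e[order(e$start), , drop = FALSE]
    for (r in seq_len(nrow(e)))
      exon[(e$start[r] + 1):e$end[r]] <- TRUE
    span[(min(e$start) + 1):max(e$end)] <- TRUE
    if (nrow(e) > 1)
      for (r in seq_len(nrow(e) - 1))
        if (e$start[r + 1] > e$end[r])
          gap[(e$end[r] + 1):e$start[r + 1]] <- TRUE
  }
  list(exon = exon, gap = gap, span = span)
}

# expand an interval table into a per-base logical mask
intervals_to_mask <- function(iv, len) {
  m <- logical(len)
  for (r in seq_len(nrow(iv)))
    if (iv$end[r] > iv$start[r]) m[(iv$start[r] + 1):iv$end[r]] <- TRUE
  m
}

# tiny read-table constructor
make_read <- function(read_id, chrom, strand, starts, ends,
                      secondary = FALSE, supplementary = FALSE,
                      qc = "PASS", tail = if (qc == "PASS") 50 else NA) {
  df <- data.frame(read_id = read_id, chrom = chrom, strand = strand,
                   stringsAsFactors = FALSE)
  df$block_starts <- list(as.integer(starts))
  df$block_ends <- list(as.integer(ends))
  df$is_secondary <- secondary
  df$is_supplementary <- supplementary
  df$polya_qc <- qc
  df$polya_length <- tail
  df
}

bind_reads <- function(...) do.call(rbind, list(...))
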