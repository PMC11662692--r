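#' Simulation configuration
#'
#' Seeded configuration for the synthetic-data generator. The defaults
#' describe a desk-scale worm-like study: 2 chromosomes x 200 kb, 60
#' genes laid out non-overlapping with a planted median gene span of
#' exactly 1956 nt, 20,000 long reads with a 50% truncation rate,
#' 3 young (days 1-3) and 3 old (days 7, 10, 15) samples, per-sample
#' junction tables planting exact unannotated-read fractions, an isoform
#' call set planting the four classification categories including every
#' threshold boundary (19 vs 20 reads, 10 vs 11 nt 3'UTR offset, 1956 vs
#' 1957 nt fusion intron), an abundance-anticorrelated poly(A) tail
#' model with paired old-minus-young median shifts, and modification
#' sites straddling the 0.05 / 0.99 (A-to-I) and 0.90 (pseudouridine)
#' consensus thresholds.
#'
#' @param seed integer seed (mandatory); every generator substream is
#'   derived from it deterministically.
#' @param n_genes_per_chrom genes per chromosome.
#' @param chrom_length chromosome length (nt).
#' @param n_reads total simulated reads.
#' @param truncation_fraction fraction of 5'-truncated reads.
#' @param tss_jitter maximal absolute 5'-end jitter (nt) of full-length
#'   reads.
#' @param junction_reads_per_sample total junction-spanning unique reads
#'   per sample.
#' @param unann_frac named list of per-sample unannotated-read
#'   fractions for the `young` and `old` groups.
#' @param repeat_density target fraction of the genome covered by the
#'   repeat track.
#' @param old_tail_shift baseline old-minus-young tail shift (nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes_per_chrom = 30,
                       chrom_length = 200000L,
                       n_reads = 20000L,
                       truncation_fraction = 0.5,
                       tss_jitter = 5L,
                       junction_reads_per_sample = 10000L,
                       unann_frac = list(young = c(0.044, 0.050, 0.056),
                                         old = c(0.074, 0.080, 0.086)),
                       repeat_density = 0.30,
                       old_tail_shift = 3) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(seed = as.integer(seed),
                 n_genes_per_chrom = n_genes_per_chrom,
                 chrom_length = as.integer(chrom_length),
                 n_reads = as.integer(n_reads),
                 truncation_fraction = truncation_fraction,
                 tss_jitter = as.integer(tss_jitter),
                 junction_reads_per_sample =
                   as.integer(junction_reads_per_sample),
                 unann_frac = unann_frac,
                 repeat_density = repeat_density,
                 old_tail_shift = old_tail_shift,
                 samples = data.frame(
                   sample_id = c("day1", "day2", "day3",
                                 "day7", "day10", "day15"),
                   day = c(1L, 2L, 3L, 7L, 10L, 15L),
                   age_group = c("young", "young", "young",
                                 "old", "old", "old"),
                   stringsAsFactors = FALSE)),
            class = "sim_config")
}

# deterministic substream seeds below 2^31
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + k * 9973) %% 2147483647
}

.SENSE_CODONS <- setdiff(names(.CODON_TABLE),
                         c("TAA", "TAG", "TGA"))

.comp <- function(x) chartr("ACGT", "TGCA", x)

# genomic footprint (genome-order data.frame start/end) of the
# transcript-orientation interval [a, b) over exons st/en (genome order)
.tx_footprint <- function(st, en, strand, a, b) {
  lens <- en - st
  ost <- st; oen <- en; olens <- lens
  if (strand == "-") { ost <- rev(st); oen <- rev(en); olens <- rev(lens) }
  cum <- c(0, cumsum(olens))
  out <- list()
  for (k in seq_along(ost)) {
    lo <- max(a, cum[k]); hi <- min(b, cum[k + 1])
    if (lo >= hi) next
    if (strand == "-") {
      gs <- oen[k] - (hi - cum[k]); ge <- oen[k] - (lo - cum[k])
    } else {
      gs <- ost[k] + (lo - cum[k]); ge <- ost[k] + (hi - cum[k])
    }
    out[[length(out) + 1]] <- data.frame(start = gs, end = ge)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

# split total into n non-negative integers summing to total,
# roughly proportional to w
.int_split <- function(total, w) {
  x <- floor(total * w / sum(w))
  r <- total - sum(x)
  if (r > 0) x[seq_len(r)] <- x[seq_len(r)] + 1L
  as.integer(x)
}

#' Generate the synthetic genome and annotation
#'
#' Lays out non-overlapping genes with multi-exon transcripts (a subset
#' of genes carries a second transcript sharing all introns but with an
#' extended 3' terminal exon, so some introns and TSSs are shared and
#' every such gene has two annotated 3'UTR ends), plants gene spans
#' whose median is exactly 1956 nt, writes CDSs built from sense codons
#' only (guaranteed start codon and no internal stop), places specific
#' codons at known positions for the recoding-consequence plants, and
#' emits FASTA + GFF3 plus a truth fragment.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return List: `db` (the in-memory [annotation_db()]), `fasta`, `gff`
#'   (paths), `truth` (gene/transcript tables, planted median, planted
#'   codon sites, per-gene region bookkeeping used by the downstream
#'   generators).
#' @export
generate_annotation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.sub_seed(config$seed, 1))
  n_per <- config$n_genes_per_chrom
  n_genes <- 2L * n_per
  chroms <- c("chrS1", "chrS2")
  chrom_sizes <- stats::setNames(rep(config$chrom_length, 2), chroms)

  # planted spans: median exactly 1956 (n even; the two middle values
  # are 1956 anchors, everything else strictly below or above)
  n_low <- n_genes / 2 - 1
  n_high <- n_genes / 2 - 1
  lows <- sample(seq(1200L, 1900L, by = 1L), n_low, replace = TRUE)
  highs <- sample(seq(2100L, 3600L, by = 1L), n_high, replace = TRUE)
  highs[1] <- max(highs[1], 2600L)

  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  gene_chrom <- rep(chroms, each = n_per)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE,
                   prob = c(0.65, 0.35))
  # forced structure for the fusion / boundary constructs (chrS2,
  # genes g031..g042 on + strand, single transcript, coding)
  special <- which(gene_ids %in% sprintf("g%03d", 31:42))
  strand[special] <- "+"
  # g038 hosts the exact-1956 boundary fusion exon and needs a wide
  # first exon, so it always receives the guaranteed-large span
  g038 <- which(gene_ids == "g038")
  spans <- integer(n_genes)
  spans[g038] <- highs[1]
  rest <- sample(c(lows, 1956L, 1956L, highs[-1]))
  spans[-g038] <- rest

  two_tx <- gene_ids %in% sprintf("g%03d", 1:20)
  nc_rna <- gene_ids %in% sprintf("g%03d", 55:60)
  min3_exon <- gene_ids %in% sprintf("g%03d", 43:50)

  # layout: sequential with controlled gaps
  gap_fusion <- stats::setNames(rep(2500L, 5),
                                c("g032", "g034", "g036", "g040", "g042"))
  gap_boundary <- c(g038 = 1000L)
  span_start <- integer(n_genes)
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    pos <- 3000L
    for (i in idx) {
      gid <- gene_ids[i]
      gap <- if (gid %in% names(gap_fusion)) gap_fusion[[gid]]
             else if (gid %in% names(gap_boundary)) gap_boundary[[gid]]
             else sample(800:3000, 1)
      if (i != idx[1]) pos <- pos + gap
      span_start[i] <- pos
      pos <- pos + spans[i]
    }
    if (pos > config$chrom_length - 2000L)
      stop("chromosome too short for the configured gene layout")
  }
  span_end <- span_start + spans

  # per-gene exon structure
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  gene_info <- vector("list", n_genes)
  names(gene_info) <- gene_ids
  planted_codons <- list()
  codon_plan <- list(
    g001 = list(codon = "AGA", idx = 5L, off = 0L),
    g002 = list(codon = "ATA", idx = 5L, off = 2L),
    g003 = list(codon = "CCA", idx = 5L, off = 2L),
    g004 = list(codon = "stop", idx = NA, off = 2L),  # TGA -> TGG
    g005 = list(codon = "stop", idx = NA, off = 1L),  # TAA -> TGA
    g006 = list(codon = "AAA", idx = 6L, off = 0L),
    g007 = list(codon = "ACA", idx = 5L, off = 2L),
    g008 = list(codon = "AGA", idx = 7L, off = 2L),
    g009 = list(codon = "GAT", idx = 5L, off = 1L),
    g010 = list(codon = "AAC", idx = 6L, off = 0L))

  genome_chars <- lapply(chrom_sizes, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  for (i in seq_len(n_genes)) {
    gid <- gene_ids[i]
    S <- spans[i]
    k <- if (gid == "g038") 2L
         else if (min3_exon[i]) sample(3:5, 1)
         else sample(2:4, 1)
    # minimum part sizes: terminal exons 300, internal exons 90,
    # introns 80
    exon_min <- c(300L, rep(90L, max(0, k - 2)), if (k > 1) 300L)
    if (gid == "g038") exon_min <- c(1300L, 300L)
    intron_min <- rep(80L, k - 1)
    mins <- integer(2 * k - 1)
    mins[seq(1, 2 * k - 1, by = 2)] <- exon_min
    if (k > 1) mins[seq(2, 2 * k - 2, by = 2)] <- intron_min
    slack <- S - sum(mins)
    if (slack < 0) stop("span too small for ", gid)
    w <- stats::runif(2 * k - 1)
    extra <- .int_split(slack, w)
    parts <- mins + extra
    bounds <- span_start[i] + c(0L, cumsum(parts))
    ex_idx <- seq(1, 2 * k - 1, by = 2)
    e_start <- bounds[ex_idx]
    e_end <- bounds[ex_idx + 1]

    str_i <- strand[i]
    # tx1: for two-transcript genes, trim 120 nt off the 3' terminal
    # exon; tx2 keeps the full span
    t1_start <- e_start; t1_end <- e_end
    if (two_tx[i]) {
      if (str_i == "+") t1_end[k] <- t1_end[k] - 120L
      else t1_start[1] <- t1_start[1] + 120L
    }
    tid1 <- paste0(gid, ".t1")
    biot <- if (nc_rna[i]) "ncRNA" else "protein_coding"
    tx_rows[[length(tx_rows) + 1]] <- data.frame(
      transcript_id = tid1, gene_id = gid, chrom = gene_chrom[i],
      strand = str_i, biotype = biot, stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1]] <- data.frame(
      transcript_id = tid1, chrom = gene_chrom[i], start = t1_start,
      end = t1_end, strand = str_i, stringsAsFactors = FALSE)
    if (two_tx[i]) {
      tid2 <- paste0(gid, ".t2")
      tx_rows[[length(tx_rows) + 1]] <- data.frame(
        transcript_id = tid2, gene_id = gid, chrom = gene_chrom[i],
        strand = str_i, biotype = biot, stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        transcript_id = tid2, chrom = gene_chrom[i], start = e_start,
        end = e_end, strand = str_i, stringsAsFactors = FALSE)
    }

    info <- list(gene_id = gid, chrom = gene_chrom[i], strand = str_i,
                 span_start = span_start[i], span_end = span_end[i],
                 exon_start = t1_start, exon_end = t1_end,
                 exon2_start = if (two_tx[i]) e_start else NULL,
                 exon2_end = if (two_tx[i]) e_end else NULL,
                 biotype = biot, two_tx = two_tx[i])

    if (!nc_rna[i]) {
      txlen <- sum(t1_end - t1_start)
      u5 <- 20L
      u3 <- sample(80:120, 1)
      cds_len <- txlen - u5 - u3
      u3 <- u3 + cds_len %% 3L
      cds_len <- txlen - u5 - u3
      stopifnot(cds_len %% 3 == 0, cds_len >= 60)
      n_cod <- cds_len / 3L
      stop_codon <- if (gid == "g004") "TGA" else "TAA"
      codons <- c("ATG",
                  sample(.SENSE_CODONS, n_cod - 2L, replace = TRUE),
                  stop_codon)
      cp <- codon_plan[[gid]]
      if (!is.null(cp) && !identical(cp$codon, "stop"))
        codons[cp$idx + 1L] <- cp$codon
      cds_seq <- paste(codons, collapse = "")
      # write into the genome across the CDS genomic footprint
      fp <- .tx_footprint(t1_start, t1_end, str_i, u5, u5 + cds_len)
      gseq <- if (str_i == "-")
        rev(.comp(strsplit(cds_seq, "")[[1]]))
      else strsplit(cds_seq, "")[[1]]
      off <- 0L
      for (r in seq_len(nrow(fp))) {
        w_ <- fp$end[r] - fp$start[r]
        genome_chars[[gene_chrom[i]]][(fp$start[r] + 1L):fp$end[r]] <-
          gseq[(off + 1L):(off + w_)]
        off <- off + w_
      }
      cds_rows[[length(cds_rows) + 1]] <- data.frame(
        transcript_id = tid1, chrom = gene_chrom[i], start = fp$start,
        end = fp$end, strand = str_i, stringsAsFactors = FALSE)
      if (two_tx[i])
        cds_rows[[length(cds_rows) + 1]] <- data.frame(
          transcript_id = paste0(gid, ".t2"), chrom = gene_chrom[i],
          start = fp$start, end = fp$end, strand = str_i,
          stringsAsFactors = FALSE)
      # guarantee an A and a U position on the transcript strand inside
      # the short 5'UTR (site plants need both)
      u5fp <- .tx_footprint(t1_start, t1_end, str_i, 3L, 5L)
      genome_chars[[gene_chrom[i]]][(u5fp$start[1] + 1L):u5fp$end[1]] <-
        if (str_i == "-") rev(.comp(c("A", "T"))) else c("A", "T")
      info$u5 <- u5; info$u3 <- u3; info$cds_len <- cds_len
      info$cds_start_tx <- u5; info$cds_seq <- cds_seq
      info$cds_fp <- fp
      if (!is.null(cp)) {
        cds_pos <- if (identical(cp$codon, "stop"))
          (n_cod - 1L) * 3L + cp$off
        else cp$idx * 3L + cp$off
        # genomic position of that CDS coordinate
        gfp <- .tx_footprint(t1_start, t1_end, str_i,
                             u5 + cds_pos, u5 + cds_pos + 1L)
        codon_txt <- codons[cds_pos %/% 3L + 1L]
        cons <- codon_consequence(codon_txt, cds_pos %% 3L, "G")
        planted_codons[[gid]] <- data.frame(
          gene_id = gid, chrom = gene_chrom[i], pos = gfp$start[1],
          strand = str_i, codon = codon_txt,
          codon_offset = cds_pos %% 3L,
          consequence = cons$consequence,
          property_change = cons$property_change,
          stringsAsFactors = FALSE)
      }
    }
    gene_info[[gid]] <- info
  }

  transcripts <- do.call(rbind, tx_rows)
  exons <- do.call(rbind, exon_rows)
  cds <- do.call(rbind, cds_rows)
  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, character(1), collapse = ""))
  names(genome) <- chroms
  db <- annotation_db(transcripts, exons, cds, chrom_sizes, genome)

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 80)
  gff <- file.path(dir, "annotation.gff3")
  write_gff3(db, gff)

  truth_genes <- data.frame(gene_id = gene_ids, chrom = gene_chrom,
                            strand = strand, span_start = span_start,
                            span_end = span_end, span = spans,
                            biotype = ifelse(nc_rna, "ncRNA",
                                             "protein_coding"),
                            two_tx = two_tx, stringsAsFactors = FALSE)
  truth <- list(genes = truth_genes,
                median_gene_length = 1956L,
                planted_codons = do.call(rbind, planted_codons),
                gene_info = gene_info)
  write_tsv(truth_genes, file.path(dir, "truth_genes.tsv"))
  list(db = db, fasta = fasta, gff = gff, truth = truth)
}

# per-transcript structure cache used by the read generator
.tx_cache <- function(db) {
  lapply(split(db$exons, db$exons$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    list(chrom = e$chrom[1], strand = e$strand[1], st = e$start,
         en = e$end, txlen = sum(e$end - e$start))
  })
}

#' Generate simulated long reads and per-sample junction tables
#'
#' Full-length reads start within `tss_jitter` nt of their transcript's
#' TSS and mostly carry PASS poly(A) tags; truncated reads (the
#' configured fraction) start at least 50 nt downstream, emulating the
#' 3'-biased coverage of degraded or partially sequenced molecules. A
#' small fraction of reads is flagged secondary or supplementary, and a
#' few reads sit on an unknown chromosome. Junction tables are
#' constructed per sample so that unannotated-junction reads are exactly
#' the configured fraction of the sample's junction-spanning reads, with
#' donor-shifted, acceptor-shifted and doubly-shifted junctions planted
#' for mismatch-end attribution.
#'
#' @param config a [sim_config()].
#' @param ann output of [generate_annotation()].
#' @param dir output directory.
#' @return List: `reads` (read table), `read_tsv`, `sj_paths` (named by
#'   sample), `truth` (per-read expected filter outcome; per-junction
#'   annotated flag and mismatch label; per-sample exact fidelity
#'   percentage).
#' @export
generate_reads <- function(config, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.sub_seed(config$seed, 2))
  db <- ann$db
  txc <- .tx_cache(db)
  tids <- names(txc)
  w <- stats::rexp(length(tids)) + 0.1
  n <- config$n_reads
  pick <- sample(tids, n, replace = TRUE, prob = w)
  full <- stats::runif(n) >= config$truncation_fraction
  is_sec <- stats::runif(n) < 0.03
  is_sup <- !is_sec & stats::runif(n) < 0.02

  starts <- vector("list", n); ends <- vector("list", n)
  chrom <- character(n); strand <- character(n)
  qc <- character(n); tail_len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    t <- txc[[pick[i]]]
    chrom[i] <- t$chrom; strand[i] <- t$strand
    if (full[i]) {
      j <- sample(-config$tss_jitter:config$tss_jitter, 1)
      st <- t$st; en <- t$en
      if (t$strand == "+") st[1] <- max(0L, st[1] + j)
      else en[length(en)] <- en[length(en)] - j
      starts[[i]] <- st; ends[[i]] <- en
      pass <- stats::runif(1) < 0.95
      qc[i] <- if (pass) "PASS" else "FAIL"
      if (pass) tail_len[i] <- round(stats::rlnorm(1, log(50), 0.3), 2)
    } else {
      d <- sample(50:(t$txlen - 100L), 1)
      fp <- .tx_footprint(t$st, t$en, t$strand, d, t$txlen)
      starts[[i]] <- fp$start; ends[[i]] <- fp$end
      pass <- stats::runif(1) < 0.5
      qc[i] <- if (pass) "PASS" else "FAIL"
      if (pass) tail_len[i] <- round(stats::rlnorm(1, log(50), 0.3), 2)
    }
  }
  reads <- data.frame(read_id = sprintf("r%06d", seq_len(n)),
                      chrom = chrom, strand = strand,
                      stringsAsFactors = FALSE)
  reads$block_starts <- starts
  reads$block_ends <- ends
  reads$is_secondary <- is_sec
  reads$is_supplementary <- is_sup
  reads$polya_qc <- qc
  reads$polya_length <- tail_len
  # a few reads on an unknown chromosome
  extra <- data.frame(read_id = sprintf("u%02d", 1:5), chrom = "chrUn",
                      strand = "+", stringsAsFactors = FALSE)
  extra$block_starts <- replicate(5, c(100L), simplify = FALSE)
  extra$block_ends <- replicate(5, c(600L), simplify = FALSE)
  extra$is_secondary <- FALSE
  extra$is_supplementary <- FALSE
  extra$polya_qc <- "PASS"
  extra$polya_length <- 50
  reads <- rbind(reads, extra)

  expected_kept <- c(!is_sec & !is_sup & full & qc == "PASS",
                     rep(FALSE, 5))
  read_truth <- data.frame(read_id = reads$read_id,
                           transcript_id = c(pick, rep(NA, 5)),
                           full_length = c(full, rep(FALSE, 5)),
                           expected_kept = expected_kept,
                           stringsAsFactors = FALSE)

  read_tsv <- file.path(dir, "reads.tsv")
  write_read_table(reads, read_tsv)
  write_tsv(read_truth, file.path(dir, "truth_reads.tsv"))

  # ---- junction tables -------------------------------------------------
  set.seed(.sub_seed(config$seed, 3))
  jdb <- build_junction_db(db)
  n_ann <- min(40L, nrow(jdb))
  ann_j <- jdb[sample(nrow(jdb), n_ann), , drop = FALSE]

  all_starts <- split(jdb$start, jdb$chrom)
  all_ends <- split(jdb$end, jdb$chrom)
  coord_taken <- function(chrom, x) {
    x %in% all_starts[[chrom]] || x %in% all_ends[[chrom]]
  }
  base_j <- jdb[sample(nrow(jdb), 6), , drop = FALSE]
  kinds <- c("donor", "donor", "acceptor", "acceptor", "both", "both")
  unann <- base_j
  labels <- character(6)
  for (q in seq_len(6)) {
    b <- base_j[q, ]
    repeat {
      k <- sample(c(3:9), 1) * sample(c(-1L, 1L), 1)
      s <- b$start; e <- b$end
      donor_is_start <- b$strand != "-"
      if (kinds[q] %in% c("donor", "both")) {
        if (donor_is_start) s <- b$start + k else e <- b$end + k
      }
      if (kinds[q] %in% c("acceptor", "both")) {
        k2 <- sample(c(3:9), 1) * sample(c(-1L, 1L), 1)
        if (donor_is_start) e <- b$end + k2 else s <- b$start + k2
      }
      moved_s <- s != b$start; moved_e <- e != b$end
      ok <- e - s > 20 &&
        (!moved_s || !coord_taken(b$chrom, s)) &&
        (!moved_e || !coord_taken(b$chrom, e))
      if (ok) { unann$start[q] <- s; unann$end[q] <- e; break }
    }
    labels[q] <- switch(kinds[q], donor = "five_prime_only",
                        acceptor = "three_prime_only", both = "both")
  }

  sj_paths <- character(0)
  fid_truth <- list()
  N <- config$junction_reads_per_sample
  for (si in seq_len(nrow(config$samples))) {
    s <- config$samples[si, ]
    grp_fracs <- config$unann_frac[[s$age_group]]
    ri <- sum(config$samples$age_group[seq_len(si)] == s$age_group)
    k_s <- as.integer(round(grp_fracs[ri] * N))
    cnt_un <- .int_split(k_s, stats::runif(6, 0.5, 1.5))
    cnt_an <- .int_split(N - k_s, stats::runif(n_ann, 0.5, 1.5))
    tab <- rbind(
      data.frame(chrom = ann_j$chrom, start = ann_j$start,
                 end = ann_j$end, strand = ann_j$strand,
                 unique_reads = cnt_an, stringsAsFactors = FALSE),
      data.frame(chrom = unann$chrom, start = unann$start,
                 end = unann$end, strand = unann$strand,
                 unique_reads = cnt_un, stringsAsFactors = FALSE))
    tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
    p <- file.path(dir, paste0("SJ_", s$sample_id, ".tab"))
    write_sj_table(tab, p)
    sj_paths[s$sample_id] <- p
    fid_truth[[s$sample_id]] <- 100 * k_s / N
  }
  junction_truth <- rbind(
    data.frame(chrom = ann_j$chrom, start = ann_j$start, end = ann_j$end,
               strand = ann_j$strand, annotated = TRUE,
               mismatch = NA_character_, stringsAsFactors = FALSE),
    data.frame(chrom = unann$chrom, start = unann$start, end = unann$end,
               strand = unann$strand, annotated = FALSE,
               mismatch = labels, stringsAsFactors = FALSE))
  write_tsv(junction_truth, file.path(dir, "truth_junctions.tsv"))

  list(reads = reads, read_tsv = read_tsv, sj_paths = sj_paths,
       truth = list(reads = read_truth, junctions = junction_truth,
                    fidelity = unlist(fid_truth)))
}

# copy a transcript's exon structure as isoform blocks
.copy_chain <- function(info, use_tx2 = FALSE) {
  if (use_tx2 && !is.null(info$exon2_start))
    list(st = info$exon2_start, en = info$exon2_end)
  else list(st = info$exon_start, en = info$exon_end)
}

#' Generate the synthetic isoform call set
#'
#' Plants the four classification categories with every threshold
#' boundary: known isoforms copy annotated intron chains with small
#' terminal-end jitter; novel isoforms skip an internal exon; novel-3'UTR
#' isoforms keep a known chain but move the 3' end by more than 10 nt
#' (plus one boundary isoform moved exactly 10 nt, which stays known);
#' fusion isoforms bridge two genes with a 2500 nt intron (plus one
#' boundary isoform whose bridging intron is exactly 1956 nt, which is
#' merely novel); and read counts straddle the 20-read and 10%-of-gene
#' filters (19-read isoform dropped; a 10%-share isoform kept; a
#' 9.5%-share isoform dropped).
#'
#' @param config a [sim_config()].
#' @param ann output of [generate_annotation()].
#' @param dir output directory.
#' @return List: `callset` (an [isoform_callset()]), `bed`, `counts_tsv`
#'   (paths), `truth` (per-isoform category, expected filter survival,
#'   per-group read totals).
#' @export
generate_isoform_callset <- function(config, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.sub_seed(config$seed, 4))
  gi <- ann$truth$gene_info

  iso <- list()
  add_iso <- function(id, gene, st, en, strand, chrom, total, category,
                      survives) {
    iso[[length(iso) + 1]] <<- list(id = id, gene = gene, st = st,
                                    en = en, strand = strand,
                                    chrom = chrom, total = total,
                                    category = category,
                                    survives = survives)
  }

  # known isoforms: copy tx1 chains, jitter terminal ends by <= 5 nt
  for (g in sprintf("g%03d", 1:15)) {
    f <- gi[[g]]
    st <- f$exon_start; en <- f$exon_end
    k <- length(st)
    st[1] <- st[1] + sample(-5:5, 1)
    en[k] <- en[k] + sample(-5:5, 1)
    add_iso(paste0("iso_known_", g), g, st, en, f$strand, f$chrom,
            2L * sample(150:800, 1), "known", TRUE)
  }
  # exactly 20 reads: kept (boundary)
  f <- gi[["g026"]]
  add_iso("iso_known_g026_b20", "g026", f$exon_start, f$exon_end,
          f$strand, f$chrom, 20L, "known", TRUE)
  # 19 reads: dropped (boundary)
  f <- gi[["g046"]]
  add_iso("iso_known_g046_b19", "g046", f$exon_start, f$exon_end,
          f$strand, f$chrom, 19L, "known", FALSE)

  # novel isoforms: skip the second exon of a >=3 exon gene
  for (g in c("g043", "g044", "g045", "g049", "g050")) {
    f <- gi[[g]]
    st <- f$exon_start[-2]; en <- f$exon_end[-2]
    add_iso(paste0("iso_novel_", g), g, st, en, f$strand, f$chrom,
            2L * sample(60:400, 1), "novel", TRUE)
  }
  # 10%-of-gene boundary pair on g047: 180 + 20 reads (20/200 = 10%)
  f <- gi[["g047"]]
  add_iso("iso_known_g047_major", "g047", f$exon_start, f$exon_end,
          f$strand, f$chrom, 180L, "known", TRUE)
  add_iso("iso_novel_g047_minor", "g047", f$exon_start[-2],
          f$exon_end[-2], f$strand, f$chrom, 20L, "novel", TRUE)
  # 9.5%-of-gene pair on g048: 200 + 21 reads (21/221 < 10%)
  f <- gi[["g048"]]
  add_iso("iso_known_g048_major", "g048", f$exon_start, f$exon_end,
          f$strand, f$chrom, 200L, "known", TRUE)
  add_iso("iso_novel_g048_minor", "g048", f$exon_start[-2],
          f$exon_end[-2], f$strand, f$chrom, 21L, "novel", FALSE)

  # novel 3'UTR isoforms: known chain, 3' end moved by > 10 nt
  utr_plan <- c(g021 = 11L, g022 = -11L, g023 = 25L, g024 = 40L,
                g051 = 50L, g052 = 30L)
  for (g in names(utr_plan)) {
    f <- gi[[g]]
    st <- f$exon_start; en <- f$exon_end
    k <- length(st)
    off <- utr_plan[[g]]
    if (f$strand == "+") en[k] <- en[k] + off else st[1] <- st[1] - off
    add_iso(paste0("iso_utr_", g), g, st, en, f$strand, f$chrom,
            2L * sample(50:300, 1), "novel_utr3", TRUE)
  }
  # boundary: moved exactly 10 nt -> still known
  f <- gi[["g053"]]
  st <- f$exon_start; en <- f$exon_end
  k <- length(st)
  if (f$strand == "+") en[k] <- en[k] + 10L else st[1] <- st[1] - 10L
  add_iso("iso_utr_g053_b10", "g053", st, en, f$strand, f$chrom, 40L,
          "known", TRUE)

  # fusion isoforms: bridge adjacent genes with a 2500 nt intron
  pairs <- list(c("g031", "g032"), c("g033", "g034"), c("g035", "g036"),
                c("g039", "g040"), c("g041", "g042"))
  for (p in pairs) {
    a <- gi[[p[1]]]; b <- gi[[p[2]]]
    a_end <- a$exon_end[length(a$exon_end)]
    b_start <- b$exon_start[1]
    stopifnot(b_start - a_end > 1956)
    st <- c(a_end - 100L, b_start)
    en <- c(a_end, b_start + 150L)
    add_iso(paste0("iso_fusion_", p[1], "_", p[2]), NA_character_,
            st, en, "+", a$chrom, 2L * sample(20:60, 1), "fusion", TRUE)
  }
  # boundary: bridging intron exactly 1956 nt -> novel, not fusion
  a <- gi[["g037"]]; b <- gi[["g038"]]
  a_end <- a$exon_end[length(a$exon_end)]
  st <- c(a_end - 100L, a_end + 1956L)
  en <- c(a_end, a_end + 1956L + 200L)
  stopifnot(st[2] >= b$exon_start[1],
            en[2] <= b$exon_end[1])
  add_iso("iso_boundary_g037_g038", NA_character_, st, en, "+", a$chrom,
          40L, "novel", TRUE)

  # assemble tables
  n <- length(iso)
  isoforms <- data.frame(
    isoform_id = vapply(iso, `[[`, "", "id"),
    chrom = vapply(iso, `[[`, "", "chrom"),
    strand = vapply(iso, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  isoforms$block_starts <- lapply(iso, function(x) as.integer(x$st))
  isoforms$block_ends <- lapply(iso, function(x) as.integer(x$en))
  isoforms$gene_id <- NA_character_

  totals <- vapply(iso, function(x) as.integer(x$total), integer(1))
  n_young <- totals %/% 2L
  n_old <- totals - n_young
  counts <- matrix(0L, n, 6,
                   dimnames = list(isoforms$isoform_id,
                                   config$samples$sample_id))
  for (i in seq_len(n)) {
    counts[i, 1:3] <- .int_split(n_young[i], stats::runif(3, 0.8, 1.2))
    counts[i, 4:6] <- .int_split(n_old[i], stats::runif(3, 0.8, 1.2))
  }
  callset <- isoform_callset(isoforms, counts)

  bed <- file.path(dir, "isoforms.bed")
  write_bed12(isoforms, bed)
  counts_tsv <- file.path(dir, "isoform_counts.tsv")
  write_tsv(data.frame(isoform_id = isoforms$isoform_id, counts,
                       check.names = FALSE), counts_tsv)
  truth <- data.frame(isoform_id = isoforms$isoform_id,
                      planted_gene = vapply(iso, `[[`, "", "gene"),
                      category = vapply(iso, `[[`, "", "category"),
                      survives = vapply(iso, function(x) x$survives,
                                        logical(1)),
                      total_reads = totals, n_young = n_young,
                      n_old = n_old, stringsAsFactors = FALSE)
  write_tsv(truth, file.path(dir, "truth_isoforms.tsv"))
  list(callset = callset, bed = bed, counts_tsv = counts_tsv,
       truth = truth)
}

#' Generate poly(A) tail records with planted structure
#'
#' Per-isoform tail medians decrease with abundance rank (log-normal
#' lengths around a location running from 40 nt for the most abundant
#' isoform to 95 nt for the least); old-group reads are the young
#' median plus an exact per-isoform shift plus a zero-median symmetric
#' scatter, so the old-minus-young median difference equals the planted
#' shift exactly. Most isoforms shift by the configured baseline
#' (default 3 nt, class `<10`); designated isoforms shift by 15, 25,
#' -15, 30, 12 nt and the boundary values 10 and 20 nt. A few percent of
#' extra records carry a non-PASS QC tag.
#'
#' @param config a [sim_config()].
#' @param iso_truth `truth` table from [generate_isoform_callset()].
#' @param dir output directory.
#' @return List: `records` (tail table), `tsv`, `truth` (per-isoform
#'   planted shift, eligibility at the 5-read rule, expected class).
#' @export
generate_tails <- function(config, iso_truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.sub_seed(config$seed, 5))
  tt <- iso_truth
  n <- nrow(tt)
  r <- rank(-tt$total_reads, ties.method = "first")
  m <- 40 + 55 * (r - 1) / (n - 1)

  delta_plan <- c(iso_known_g001 = 15, iso_known_g002 = 25,
                  iso_known_g003 = -15, iso_known_g004 = 10,
                  iso_known_g005 = 20, iso_known_g006 = 30,
                  iso_utr_g021 = 12)
  delta <- rep(config$old_tail_shift, n)
  names(delta) <- tt$isoform_id
  delta[names(delta_plan)] <- delta_plan

  young_samples <- config$samples$sample_id[
    config$samples$age_group == "young"]
  old_samples <- config$samples$sample_id[
    config$samples$age_group == "old"]
  rows <- list()
  for (i in seq_len(n)) {
    ny <- tt$n_young[i]; no <- tt$n_old[i]
    y <- round(stats::rlnorm(ny, log(m[i]), 0.18), 2)
    my <- stats::median(y)
    if (ny == no) {
      # same young multiset shifted: median difference exactly delta,
      # distribution shape preserved
      o <- pmax(1, sample(y) + delta[i])
    } else {
      nh <- no %/% 2L
      h <- round(pmin(abs(stats::rnorm(nh, 0, 3)), 15), 2)
      sym <- c(h, -h, if (no %% 2L == 1L) 0)
      o <- pmax(1, my + delta[i] + sample(sym))
    }
    ys <- rep(young_samples, .int_split(ny, stats::runif(3, 0.8, 1.2)))
    os <- rep(old_samples, .int_split(no, stats::runif(3, 0.8, 1.2)))
    rows[[i]] <- data.frame(
      read_id = sprintf("t_%s_%04d", tt$isoform_id[i], seq_len(ny + no)),
      isoform_id = tt$isoform_id[i],
      sample_id = c(ys, os),
      age_group = c(rep("young", ny), rep("old", no)),
      tail_length = c(y, o), qc_tag = "PASS",
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  # non-PASS extras (~2%)
  n_fail <- ceiling(nrow(records) * 0.02)
  fails <- data.frame(
    read_id = sprintf("t_fail_%04d", seq_len(n_fail)),
    isoform_id = sample(tt$isoform_id, n_fail, replace = TRUE),
    sample_id = sample(config$samples$sample_id, n_fail, replace = TRUE),
    age_group = NA_character_, tail_length =
      round(stats::rlnorm(n_fail, log(45), 0.4), 2),
    qc_tag = "ADAPTER", stringsAsFactors = FALSE)
  fails$age_group <- config$samples$age_group[
    match(fails$sample_id, config$samples$sample_id)]
  records <- rbind(records, fails)
  rownames(records) <- NULL

  eligible <- tt$n_young >= 5 & tt$n_old >= 5
  ad <- abs(delta)
  truth <- data.frame(isoform_id = tt$isoform_id, planted_delta = delta,
                      eligible = eligible,
                      class = ifelse(ad < 10, "<10",
                                     ifelse(ad <= 20, "10-20", ">20")),
                      stringsAsFactors = FALSE)
  tsv <- file.path(dir, "polya_tails.tsv")
  write_tail_table(records, tsv)
  write_tsv(truth, file.path(dir, "truth_tails.tsv"))
  list(records = records, tsv = tsv, truth = truth)
}

# sample one 0-based position within `intervals` (data.frame start/end,
# genome coordinates) whose transcript-strand base equals `tx_base`
.find_base <- function(genome, chrom, intervals, strand, tx_base) {
  want <- if (strand == "-") .comp(tx_base) else tx_base
  cand <- integer(0)
  for (r in seq_len(nrow(intervals))) {
    s <- intervals$start[r]; e <- intervals$end[r]
    chars <- strsplit(as.character(
      Biostrings::subseq(genome[[chrom]], s + 1L, e)), "")[[1]]
    cand <- c(cand, s + which(chars == want) - 1L)
  }
  if (!length(cand)) stop("no ", want, " base available in target region")
  if (length(cand) == 1) cand else sample(cand, 1)
}

.frac3 <- function(m) c(m - 0.01, m, m + 0.01)
.CONF3 <- c(0.995, 0.996, 0.997)

#' Generate per-replicate modification calls and the repeat track
#'
#' Plants A-to-I sites (with per-replicate edited fractions and SAILOR
#' style confidences) and pseudouridine sites (per-replicate
#' probabilities) across CDS, 3'UTR, 5'UTR, intron, noncoding-exon and
#' intergenic locations, straddling every consensus boundary: fraction
#' triples at exactly 0.05 and at 0.049, confidences at 0.99 and 0.989,
#' probabilities at 0.90 and 0.89, sites missing from one replicate, and
#' sites passing in only one age group. CDS A-to-I sites sit at the
#' planted codon positions, so each recoding-consequence class
#' (synonymous, missense with and without property change, stop_lost,
#' stop_retained) is represented. A repeat track at the configured
#' genome density is emitted and each site's actual repeat overlap is
#' recorded as truth.
#'
#' @param config a [sim_config()].
#' @param ann output of [generate_annotation()].
#' @param dir output directory.
#' @return List: `atoi_paths`, `psi_paths` (named `group_rep`),
#'   `repeat_bed`, `truth` (per-site table), `repeats` (interval
#'   `data.frame`).
#' @export
generate_edit_calls <- function(config, ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.sub_seed(config$seed, 6))
  db <- ann$db
  gi <- ann$truth$gene_info
  genome <- db$genome
  pc <- ann$truth$planted_codons

  # ---- repeat track ----------------------------------------------------
  reps <- list()
  for (ch in names(db$chrom_sizes)) {
    L <- db$chrom_sizes[[ch]]
    n_iv <- round(config$repeat_density * L / 550)
    len <- sample(300:800, n_iv, replace = TRUE)
    st <- sample(0:(L - 900L), n_iv, replace = TRUE)
    reps[[ch]] <- data.frame(chrom = ch, start = st, end = st + len,
                             stringsAsFactors = FALSE)
  }
  repeats <- interval_union(do.call(rbind, reps))
  repeat_bed <- file.path(dir, "repeats.bed")
  write_bed(repeats, repeat_bed)

  # region helpers based on tx1 structure
  region_of <- function(g, what) {
    f <- gi[[g]]
    st <- f$exon_start; en <- f$exon_end
    txlen <- sum(en - st)
    switch(what,
      utr3 = .tx_footprint(st, en, f$strand, txlen - f$u3 + 5L, txlen - 5L),
      utr5 = .tx_footprint(st, en, f$strand, 0L, f$u5),
      cds = f$cds_fp,
      intron = data.frame(start = en[-length(en)] + 3L,
                          end = st[-1] - 3L),
      exon = data.frame(start = st, end = en))
  }
  pos_in <- function(g, what, tx_base) {
    f <- gi[[g]]
    .find_base(genome, f$chrom, region_of(g, what), f$strand, tx_base)
  }
  intergenic_pos <- function(g_a, g_b, base) {
    a <- gi[[g_a]]; b <- gi[[g_b]]
    stopifnot(a$chrom == b$chrom, b$span_start - a$span_end > 120)
    iv <- data.frame(start = a$span_end + 50L, end = b$span_start - 50L)
    .find_base(genome, a$chrom, iv, "+", base)
  }

  site <- function(id, gene, feature, pos, chrom, strand,
                   y_frac = NULL, o_frac = NULL,
                   y_conf = .CONF3, o_conf = .CONF3,
                   y_reps = 1:3, o_reps = 1:3,
                   y_pass, o_pass, consequence = NA_character_,
                   property_change = NA) {
    list(id = id, gene = gene, feature = feature, pos = pos,
         chrom = chrom, strand = strand, y_frac = y_frac,
         o_frac = o_frac, y_conf = y_conf, o_conf = o_conf,
         y_reps = y_reps, o_reps = o_reps, y_pass = y_pass,
         o_pass = o_pass, consequence = consequence,
         property_change = property_change)
  }
  gsite <- function(id, gene, feature, tx_base, ...) {
    f <- gi[[gene]]
    p <- if (feature == "CDS" && tx_base == "A")
      pc$pos[pc$gene_id == gene]
    else pos_in(gene, switch(feature, CDS = "cds", `3UTR` = "utr3",
                             `5UTR` = "utr5", intron = "intron",
                             noncoding_exon = "exon"), tx_base)
    site(id, gene, feature, p, f$chrom, f$strand, ...)
  }

  atoi <- list(
    gsite("a01", "g001", "CDS", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.35), y_pass = TRUE, o_pass = TRUE),
    gsite("a02", "g002", "CDS", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.32), y_pass = TRUE, o_pass = TRUE),
    gsite("a03", "g003", "CDS", "A", y_frac = .frac3(0.35),
          o_frac = .frac3(0.22), y_pass = TRUE, o_pass = TRUE),
    gsite("a04", "g004", "CDS", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.25), y_pass = TRUE, o_pass = TRUE),
    gsite("a05", "g005", "CDS", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.30), y_pass = TRUE, o_pass = TRUE),
    gsite("a06", "g006", "CDS", "A", y_frac = .frac3(0.10),
          o_frac = .frac3(0.35), y_pass = TRUE, o_pass = TRUE),
    gsite("a07", "g007", "CDS", "A", y_frac = .frac3(0.20),
          o_frac = c(0.04, 0.20, 0.20), y_pass = TRUE, o_pass = FALSE),
    gsite("a08", "g008", "CDS", "A", y_frac = c(0.20, 0.21),
          y_reps = 1:2, o_frac = .frac3(0.25), y_pass = FALSE,
          o_pass = TRUE),
    gsite("a09", "g009", "CDS", "A", y_frac = c(0.05, 0.05, 0.05),
          o_frac = c(0.05, 0.05, 0.05), y_conf = rep(0.99, 3),
          o_conf = rep(0.99, 3), y_pass = TRUE, o_pass = TRUE),
    gsite("a10", "g010", "CDS", "A", y_frac = c(0.049, 0.05, 0.05),
          o_frac = .frac3(0.25), o_conf = c(0.989, 0.995, 0.995),
          y_pass = FALSE, o_pass = FALSE),
    gsite("a11", "g011", "3UTR", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.36), y_pass = TRUE, o_pass = TRUE),
    gsite("a12", "g012", "3UTR", "A", y_frac = .frac3(0.25),
          o_frac = .frac3(0.28), y_pass = TRUE, o_pass = TRUE),
    gsite("a13", "g013", "3UTR", "A", y_frac = .frac3(0.40),
          o_frac = .frac3(0.22), y_pass = TRUE, o_pass = TRUE),
    gsite("a14", "g014", "3UTR", "A", y_frac = .frac3(0.15),
          o_frac = .frac3(0.45), y_pass = TRUE, o_pass = TRUE),
    gsite("a15", "g015", "5UTR", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.24), y_pass = TRUE, o_pass = TRUE),
    gsite("a16", "g016", "5UTR", "A", y_frac = .frac3(0.12),
          o_frac = .frac3(0.30), y_pass = TRUE, o_pass = TRUE),
    gsite("a17", "g017", "intron", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.33), y_pass = TRUE, o_pass = TRUE),
    gsite("a18", "g018", "intron", "A", y_frac = .frac3(0.30),
          o_frac = .frac3(0.33), y_pass = TRUE, o_pass = TRUE),
    gsite("a19", "g019", "intron", "A", y_frac = NULL, y_reps = integer(0),
          o_frac = .frac3(0.25), y_pass = FALSE, o_pass = TRUE),
    gsite("a20", "g055", "noncoding_exon", "A", y_frac = .frac3(0.20),
          o_frac = .frac3(0.32), y_pass = TRUE, o_pass = TRUE),
    gsite("a21", "g056", "noncoding_exon", "A", y_frac = .frac3(0.22),
          o_frac = .frac3(0.25), y_pass = TRUE, o_pass = TRUE),
    site("a22", NA, "intergenic", intergenic_pos("g025", "g026", "A"),
         gi[["g025"]]$chrom, "+", y_frac = .frac3(0.20),
         o_frac = .frac3(0.35), y_pass = TRUE, o_pass = TRUE),
    site("a23", NA, "intergenic", intergenic_pos("g026", "g027", "A"),
         gi[["g026"]]$chrom, "+", y_frac = .frac3(0.25),
         o_frac = .frac3(0.27), y_pass = TRUE, o_pass = TRUE),
    site("a24", NA, "intergenic", intergenic_pos("g027", "g028", "A"),
         gi[["g027"]]$chrom, "+", y_frac = .frac3(0.20),
         o_frac = c(0.03, 0.04, 0.20), y_pass = TRUE, o_pass = FALSE),
    gsite("a25", "g023", "3UTR", "A", y_frac = .frac3(0.18),
          o_frac = .frac3(0.40), y_pass = TRUE, o_pass = TRUE),
    gsite("a26", "g024", "intron", "A", y_frac = c(0.20, 0.21),
          y_reps = 1:2, o_frac = c(0.22, 0.23), o_reps = 2:3,
          y_pass = FALSE, o_pass = FALSE))

  # annotate consequences of CDS sites from the codon plant
  for (i in seq_along(atoi)) {
    s <- atoi[[i]]
    if (!is.na(s$gene) && s$feature == "CDS") {
      row <- pc[pc$gene_id == s$gene, ]
      atoi[[i]]$consequence <- row$consequence
      atoi[[i]]$property_change <- row$property_change
    }
  }

  psi <- list(
    gsite("p01", "g001", "CDS", "T", y_conf = c(0.95, 0.93, 0.97),
          o_conf = c(0.96, 0.94, 0.92), y_pass = TRUE, o_pass = TRUE),
    gsite("p02", "g002", "CDS", "T", y_conf = c(0.95, 0.96, 0.97),
          o_conf = c(0.89, 0.95, 0.96), y_pass = TRUE, o_pass = FALSE),
    gsite("p03", "g003", "3UTR", "T", y_conf = c(0.95, 0.96),
          y_reps = 1:2, o_conf = c(0.95, 0.96, 0.97), y_pass = FALSE,
          o_pass = TRUE),
    gsite("p04", "g011", "CDS", "T", y_conf = rep(0.90, 3),
          o_conf = rep(0.90, 3), y_pass = TRUE, o_pass = TRUE),
    gsite("p05", "g012", "3UTR", "T", y_conf = c(0.93, 0.95, 0.97),
          o_conf = c(0.92, 0.94, 0.96), y_pass = TRUE, o_pass = TRUE),
    gsite("p06", "g013", "intron", "T", y_conf = c(0.91, 0.93, 0.95),
          o_conf = c(0.92, 0.94, 0.96), y_pass = TRUE, o_pass = TRUE),
    gsite("p07", "g055", "noncoding_exon", "T",
          y_conf = c(0.93, 0.95, 0.97), o_conf = c(0.92, 0.94, 0.96),
          y_pass = TRUE, o_pass = TRUE),
    site("p08", NA, "intergenic", intergenic_pos("g028", "g029", "T"),
         gi[["g028"]]$chrom, "+", y_conf = c(0.93, 0.95, 0.97),
         o_conf = c(0.92, 0.94, 0.96), y_pass = TRUE, o_pass = TRUE),
    gsite("p09", "g014", "CDS", "T", y_conf = c(0.93, 0.95, 0.97),
          o_conf = c(0.89, 0.89, 0.96), y_pass = TRUE, o_pass = FALSE),
    gsite("p10", "g015", "CDS", "T", y_conf = c(0.89, 0.95, 0.96),
          o_conf = c(0.93, 0.95, 0.97), y_pass = FALSE, o_pass = TRUE),
    gsite("p11", "g016", "3UTR", "T", y_conf = c(0.89, 0.89, 0.89),
          o_conf = c(0.89, 0.88, 0.87), y_pass = FALSE, o_pass = FALSE),
    gsite("p12", "g017", "5UTR", "T", y_conf = c(0.93, 0.95, 0.97),
          o_conf = c(0.92, 0.94, 0.96), y_pass = TRUE, o_pass = TRUE))

  # ---- write per-replicate files --------------------------------------
  groups <- c("young", "old")
  atoi_paths <- character(0); psi_paths <- character(0)
  for (g in groups) {
    for (r in 1:3) {
      rows <- list()
      for (s in atoi) {
        reps_g <- if (g == "young") s$y_reps else s$o_reps
        if (!r %in% reps_g) next
        j <- match(r, reps_g)
        fr <- if (g == "young") s$y_frac[j] else s$o_frac[j]
        cf <- if (g == "young") s$y_conf[j] else s$o_conf[j]
        rows[[length(rows) + 1]] <- data.frame(
          V1 = s$chrom, V2 = s$pos, V3 = s$pos + 1L,
          V4 = paste0(50L, ",", format(fr, trim = TRUE)), V5 = cf,
          V6 = s$strand, stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      tab <- tab[order(tab$V1, tab$V2), , drop = FALSE]
      p <- file.path(dir, paste0("atoi_", g, "_rep", r, ".bed"))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      atoi_paths[paste0(g, "_rep", r)] <- p

      rows <- list()
      for (s in psi) {
        reps_g <- if (g == "young") s$y_reps else s$o_reps
        if (!r %in% reps_g) next
        j <- match(r, reps_g)
        cf <- if (g == "young") s$y_conf[j] else s$o_conf[j]
        rows[[length(rows) + 1]] <- data.frame(
          chrom = s$chrom, pos = s$pos, strand = s$strand,
          probability = cf, replicate_id = paste0("rep", r),
          age_group = g, stringsAsFactors = FALSE)
      }
      tab <- do.call(rbind, rows)
      tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
      p <- file.path(dir, paste0("psi_", g, "_rep", r, ".tsv"))
      write_tsv(tab, p)
      psi_paths[paste0(g, "_rep", r)] <- p
    }
  }

  # ---- truth table ----------------------------------------------------
  truth_one <- function(s, modality) {
    y_mean <- if (s$y_pass && !is.null(s$y_frac)) mean(s$y_frac)
              else NA_real_
    o_mean <- if (s$o_pass && !is.null(s$o_frac)) mean(s$o_frac)
              else NA_real_
    delta <- if (modality == "AtoI" && s$y_pass && s$o_pass)
      100 * (o_mean - y_mean) else NA_real_
    dclass <- if (!is.na(delta))
      ifelse(delta > 10, "increase",
             ifelse(delta < -10, "decrease", "stable"))
    else NA_character_
    in_rep <- interval_overlaps_any(
      data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 1L),
      repeats)
    data.frame(site_id = s$id, modality = modality, chrom = s$chrom,
               pos = s$pos, strand = s$strand,
               gene_id = if (is.na(s$gene)) NA_character_ else s$gene,
               feature = s$feature, consequence = s$consequence,
               property_change = s$property_change,
               y_pass = s$y_pass, o_pass = s$o_pass, y_mean = y_mean,
               o_mean = o_mean, delta = delta, delta_class = dclass,
               repeat_overlap = in_rep, stringsAsFactors = FALSE)
  }
  truth <- rbind(do.call(rbind, lapply(atoi, truth_one, "AtoI")),
                 do.call(rbind, lapply(psi, truth_one, "Psi")))
  write_tsv(truth, file.path(dir, "truth_sites.tsv"))
  list(atoi_paths = atoi_paths, psi_paths = psi_paths,
       repeat_bed = repeat_bed, truth = truth, repeats = repeats)
}
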