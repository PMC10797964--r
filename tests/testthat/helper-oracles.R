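# Independent oracles and small fixtures shared across the suite.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorised implementations.

CODON <- Biostrings::GENETIC_CODE  # the standard code, as a lookup table

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(s) {
  n <- nchar(s) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(s, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("N", cod)) "X" else unname(CODON[cod])
  }
  paste(out, collapse = "")
}

# six-frame fragments by definition: per frame, translate codon by codon,
# split at stops and untranslatable codons
oracle_six_frames <- function(read) {
  out <- list()
  for (dir in c("fwd", "rev")) {
    s <- if (dir == "fwd") read else oracle_revcomp(read)
    for (f in 1:3) {
      aa <- oracle_translate(substr(s, f, nchar(s)))
      frags <- strsplit(aa, "[*X]+")[[1]]
      out[[paste0(if (dir == "fwd") "+" else "-", f)]] <-
        frags[nzchar(frags)]
    }
  }
  out
}

# all 8-11-mers of a read by double loop
oracle_kmers <- function(read, k_min = 8, k_max = 11) {
  res <- character(0)
  for (frags in oracle_six_frames(read)) {
    for (fr in frags) {
      for (k in k_min:k_max) {
        if (nchar(fr) < k) next
        for (i in seq_len(nchar(fr) - k + 1)) {
          res <- c(res, substr(fr, i, i + k - 1))
        }
      }
    }
  }
  res
}

# all-positions ungapped scoring scan (match - mismatch), both strands
oracle_best_alignment <- function(segment, genome) {
  best <- NULL
  L <- nchar(segment)
  qs <- list(`+` = strsplit(segment, "")[[1]],
             `-` = strsplit(oracle_revcomp(segment), "")[[1]])
  for (chrom in names(genome)) {
    sv <- strsplit(genome[[chrom]], "")[[1]]
    for (strand in c("+", "-")) {
      q <- qs[[strand]]
      for (i in seq_len(length(sv) - L + 1)) {
        mm <- sum(q != sv[i:(i + L - 1)])
        sc <- (L - mm) - mm
        if (is.null(best) || sc > best$score)
          best <- list(chrom = chrom, start = i - 1L, strand = strand,
                       score = sc, n_best = 1L)
        else if (sc == best$score) best$n_best <- best$n_best + 1L
      }
    }
  }
  best
}

random_read <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# one shared full-scale simulation per test run (the default stated
# world: 3 x 50 kb, 30 transcripts, 50-peptide editing plan)
.shared <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- sim_config(seed = 1L)
    sim <- simulate_genome(cfg)
    reads <- simulate_reads(cfg, sim)
    .shared$sim <- c(sim, list(config = cfg, reads = reads))
  }
  .shared$sim
}
shared_dbs <- function() {
  if (is.null(.shared$dbs))
    .shared$dbs <- build_dbs_from_reads(shared_sim()$reads$samples)
  .shared$dbs
}

# small hand-built transcript fixtures
toy_models <- function() {
  data.table::data.table(
    gene_name = c("gA", "gB", "gC"),
    tx_id = c("txA", "txB", "txC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(0L, 200L, 0L),
    tx_end = c(100L, 300L, 120L),
    cds_start = c(20L, 220L, 0L),
    cds_end = c(80L, 280L, 0L),
    exon_starts = c("0,", "200,", "0,"),
    exon_ends = c("100,", "300,", "120,"))
}
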