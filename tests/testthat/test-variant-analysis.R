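mini_vset <- function(df, ...) variant_set(data.table::as.data.table(df), ...)

test_that("filter_somatic applies germline subtraction and depth rules", {
  germ <- mini_vset(data.frame(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "T", total_depth = 50L,
                               alt_depth = 25L))
  calls <- mini_vset(data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("T", "G", "A", "C"),
    total_depth = c(50L, 10L, 9L, 40L),
    alt_depth = c(25L, 9L, 9L, 8L)))
  kept <- filter_somatic(calls, germ)
  # germline subtracted; depth 10/alt 9 boundary kept; 9x dropped; alt 8 dropped
  expect_equal(kept$pos, 200L)

  # monotone: raising thresholds never increases the kept set
  for (md in c(10, 20, 40)) for (ma in c(9, 15)) {
    k2 <- filter_somatic(calls, germ, min_depth = md, min_alt_reads = ma)
    expect_true(all(paste(k2$chrom, k2$pos) %in% paste(kept$chrom, kept$pos)) ||
                  nrow(k2) <= nrow(kept))
  }
})

test_that("tmb_by_region computes variants per Mb with one label each", {
  gs <- c(chr1 = 400L, chr2 = 200L)
  tr <- tracks_from_transcripts(toy_models(), gs)
  vs <- mini_vset(data.frame(
    chrom = c("chr1", "chr1", "chr1"), pos = c(30L, 5L, 350L),
    ref = "A", alt = "T", total_depth = 50L, alt_depth = 25L))
  tb <- tmb_by_region(vs, tr)
  expect_equal(sum(tb$n_SNV + tb$n_indel), 3)  # each variant counted once
  coding_size <- tb$region_size_bp[tb$label == "coding"]
  expect_equal(tb$tmb_per_mb[tb$label == "coding"], 1 / (coding_size / 1e6))
  # zero-variant table: TMB 0 everywhere, NA for zero-size regions
  tb0 <- tmb_by_region(mini_vset(data.frame()), tr)
  expect_true(all(tb0$tmb_per_mb == 0, na.rm = TRUE))
  expect_true(is.na(tb0$tmb_per_mb[tb0$region_size_bp == 0][1]))
})

test_that("editing_logratio matches its closed form and sentinels", {
  expect_equal(editing_logratio(2.5, 2.5), 0)
  expect_equal(editing_logratio(1.0, 2.0), log(2))
  expect_equal(editing_logratio(2.5, 0), -Inf)
  expect_true(is.na(editing_logratio(0, 2.5)))
})

test_that("gained_lost recovers planted set differences per Mb", {
  gs <- c(chr1 = 400L, chr2 = 200L)
  tr <- tracks_from_transcripts(toy_models(), gs)
  pre <- mini_vset(data.frame(chrom = "chr1", pos = c(30L, 40L, 350L),
                              ref = "A", alt = "T",
                              total_depth = 50L, alt_depth = 25L))
  # identical sets: nothing gained or lost
  gl0 <- gained_lost(pre, pre, tr)
  expect_true(all(gl0$gained_per_mb == 0, na.rm = TRUE) &&
                all(gl0$lost_per_mb == 0, na.rm = TRUE))
  # drop one coding variant, add one extragenic
  post <- mini_vset(data.frame(chrom = "chr1", pos = c(30L, 350L, 360L),
                               ref = "A", alt = "T",
                               total_depth = 50L, alt_depth = 25L))
  gl <- gained_lost(pre, post, tr)
  coding_mb <- region_sizes(tr)[["coding"]] / 1e6
  expect_equal(gl$lost_per_mb[gl$label == "coding"], 1 / coding_mb)
  expect_equal(sum(gl$gained_per_mb > 0, na.rm = TRUE), 1)

  # host delta: loss only in the BALB/c arm gives a negative delta_lost
  d <- host_editing_delta(pre, pre, post, tr)
  expect_lt(d$delta_lost[d$label == "coding"], 0)
})

test_that("coding_effect agrees with a whole-protein translation oracle", {
  set.seed(21)
  # 10 random single-exon transcripts on alternating strands
  n_tx <- 10
  genome <- list()
  models <- list()
  vars <- list()
  for (i in seq_len(n_tx)) {
    chrom <- paste0("c", i)
    seq <- random_read(300)
    genome[[chrom]] <- seq
    strand <- if (i %% 2 == 0) "-" else "+"
    models[[i]] <- data.table::data.table(
      gene_name = paste0("g", i), tx_id = paste0("t", i), chrom = chrom,
      strand = strand, tx_start = 0L, tx_end = 300L, cds_start = 30L,
      cds_end = 30L + 90L, exon_starts = "0,", exon_ends = "300,")
    pos <- sample(30:119, 3)
    for (p in pos) {
      ref <- substr(seq, p + 1, p + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      vars[[length(vars) + 1]] <- data.table::data.table(
        chrom = chrom, pos = p, ref = ref, alt = alt,
        total_depth = 60L, alt_depth = 30L)
    }
  }
  models <- data.table::rbindlist(models)
  vset <- variant_set(data.table::rbindlist(vars))
  got <- coding_effect(vset, models, unlist(genome))

  # oracle: mutate the genome, retranslate the whole CDS, compare proteins
  for (j in seq_len(nrow(got))) {
    v <- got[j, ]
    m <- models[models$chrom == v$chrom, ]
    cds <- substr(genome[[v$chrom]], m$cds_start + 1, m$cds_end)
    mut_genome <- genome[[v$chrom]]
    substr(mut_genome, v$pos + 1, v$pos + 1) <- v$alt
    cds_mut <- substr(mut_genome, m$cds_start + 1, m$cds_end)
    if (m$strand == "-") {
      cds <- oracle_revcomp(cds); cds_mut <- oracle_revcomp(cds_mut)
    }
    oracle <- if (oracle_translate(cds) == oracle_translate(cds_mut))
      "silent" else "nonsilent"
    expect_equal(v$effect, oracle, info = paste(v$chrom, v$pos))
  }
})

test_that("coding_effect handles indels, noncoding and bad ref alleles", {
  genome <- c(chr1 = "ATGAAACCCGGGTTTTAAACGTACGT")
  m <- data.table::data.table(
    gene_name = "g", tx_id = "t", chrom = "chr1", strand = "+",
    tx_start = 0L, tx_end = 26L, cds_start = 0L, cds_end = 18L,
    exon_starts = "0,", exon_ends = "26,")
  del <- variant_set(data.table::data.table(
    chrom = "chr1", pos = 4L, ref = "AA", alt = "A",
    total_depth = 60L, alt_depth = 30L))
  expect_equal(coding_effect(del, m, genome)$effect, "nonsilent")
  out <- variant_set(data.table::data.table(
    chrom = "chr1", pos = 19L, ref = "C", alt = "T",
    total_depth = 60L, alt_depth = 30L))
  expect_equal(coding_effect(out, m, genome)$effect, "noncoding")
  bad <- variant_set(data.table::data.table(
    chrom = "chr1", pos = 0L, ref = "C", alt = "T",
    total_depth = 60L, alt_depth = 30L))
  expect_error(coding_effect(bad, m, genome), "disagrees")
})

test_that("scan_microsatellites finds maximal primitive tandem repeats", {
  g <- c(chr1 = paste0("GC", strrep("A", 10), "GCGT",
                       strrep("AC", 5), "GTTT"))
  loci <- scan_microsatellites(g, min_repeats = 5)
  polyA <- loci[loci$unit == "A", ]
  expect_equal(polyA$repeat_count, 10L)
  expect_equal(polyA$end - polyA$start, 10L)
  ac <- loci[loci$unit_length == 2, ]
  expect_equal(ac$unit, "AC")
  expect_equal(ac$repeat_count, 5L)
  # no non-primitive duplicates (e.g. "AA" within the poly-A run)
  expect_false(any(nchar(loci$unit) == 2 & loci$unit %in% c("AA")))
  # locus length invariant
  expect_true(all(loci$repeat_count * loci$unit_length ==
                    loci$end - loci$start))
})

test_that("flag_ms_indels marks only indels overlapping a locus", {
  g <- c(chr1 = paste0(strrep("A", 12), "CGATCGTTAGCCATGGATCCTTGAACTGTTAGCAGATTACGGAT"))
  loci <- scan_microsatellites(g, min_repeats = 5)
  expect_equal(loci$unit, "A")  # the tail is repeat-free
  vs <- variant_set(data.table::data.table(
    chrom = "chr1", pos = c(5L, 30L, 40L),
    ref = c("AA", substr(g, 31, 32), substr(g, 41, 41)),
    alt = c("A", substr(g, 31, 31), "C"),
    total_depth = 60L, alt_depth = 30L))
  fl <- flag_ms_indels(vs, loci)
  expect_equal(fl$microsatellite, c(TRUE, FALSE, FALSE))
  expect_gt(msi_fraction(vs, loci), 0)
})

test_that("MMRd exceeds MMRp TMB in every region on simulated data", {
  # direction check at a 10x planted rate factor
  ok <- 0L
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, chrom_lengths = c(chr1 = 40000L,
                                                     chr2 = 40000L),
                      n_transcripts = 16L, n_silent_tx = 2L)
    sim <- simulate_genome(cfg)
    v <- simulate_variants(cfg, sim)
    filt <- lapply(v$samples[c("mmrp_pre", "mmrd_pre")], filter_somatic,
                   germline = v$germline)
    tp <- tmb_by_region(filt$mmrp_pre, sim$tracks)
    td <- tmb_by_region(filt$mmrd_pre, sim$tracks)
    if (all(td$tmb_per_mb > tp$tmb_per_mb)) ok <- ok + 1L
  }
  expect_gte(ok, 2L)
})
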