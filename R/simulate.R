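#' Synthetic immunoediting experiments with planted truth
#'
#' Generates every input of the pipeline at desk scale: a toy
#' multi-chromosome genome with coding/UTR/intron/ncRNA/extragenic
#' structure and microsatellite runs; germline and per-sample somatic
#' variant sets with elevated MMRd rates; RNA-seq-like reads from
#' canonical and non-canonical transcription; an immune-editing plan
#' whose target peptides lose all supporting reads in immunocompetent
#' MMRd hosts; and an observed-peptide list drawn from the planted
#' truth. All generators are deterministic under the config seed.
#'
#' The sample design mirrors the two-arm experiment: one MMRp arm
#' (pre-injection cells, one NOD-SCID tumour, one BALB/c tumour) and one
#' MMRd arm (pre-injection, one NOD-SCID, three BALB/c replicates).
#'
#' @name synthetic_data
NULL

#' Simulation configuration with desk-scale defaults
#'
#' Defaults encode the stated experimental world: a 3 x 50 kb genome,
#' ~30 transcripts, an MMRd/MMRp mutation-rate factor of 10 (the
#' characteristic hypermutation fold of MMR loss), a 50-peptide editing
#' plan whose support (12 reads) clears the >= 10-count database floor,
#' and noise rates of zero (the noiseless world in which planted truth
#' is exactly recoverable). Per-Mb rates are inflated relative to real
#' tumours so that every region label receives a workable number of
#' events on a 150 kb genome; see the methods vignette.
#'
#' @param seed integer seed driving every generator.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_transcripts total transcript count.
#' @param frac_ncrna fraction of transcripts that are non-coding
#'   (cdsStart = cdsEnd).
#' @param n_silent_tx coding transcripts with no background expression
#'   (hosts for in-frame planted peptides).
#' @param n_ms_loci microsatellite runs planted in intergenic space.
#' @param somatic_rate_mmrp,rate_factor somatic variants per Mb in the
#'   MMRp arm, and the MMRd multiplier (default 10).
#' @param germline_rate germline variants per Mb.
#' @param gain_rate_frac gained-variant rate after in vivo growth, as a
#'   fraction of the arm's somatic rate.
#' @param editing_fraction fraction of immunogenic-label variants
#'   removed in immunocompetent MMRd tumours.
#' @param editing_labels labels whose variants are immune targets.
#' @param indel_frac_mmrp,indel_frac_mmrd indel share of somatic calls.
#' @param ms_indel_rate_mmrd,ms_indel_rate_mmrp per-locus probability of
#'   a somatic microsatellite deletion.
#' @param read_length,tile_step background read length and tiling step.
#' @param n_edit_peptides editing-plan size (MMRd arm).
#' @param n_mmrp_edit_peptides editing-plan size for the MMRp arm.
#' @param n_support supporting reads per planted peptide (>= the
#'   10-count floor).
#' @param n_noncanonical_windows windows of non-canonical transcription
#'   (intronic/extragenic/UTR) expressed in every sample.
#' @param n_antisense_windows antisense transcription windows.
#' @param error_rate per-base sequencing error rate (default 0).
#' @param variant_read_af allele frequency at which SNVs are spiked into
#'   overlapping contiguous reads (default 0).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 50000L, chr2 = 50000L,
                                         chr3 = 50000L),
                       n_transcripts = 30L,
                       frac_ncrna = 0.15,
                       n_silent_tx = 4L,
                       n_ms_loci = 30L,
                       somatic_rate_mmrp = 200,
                       rate_factor = 10,
                       germline_rate = 400,
                       gain_rate_frac = 0.05,
                       editing_fraction = 0.5,
                       editing_labels = c("coding", "utr5"),
                       indel_frac_mmrp = 0.15,
                       indel_frac_mmrd = 0.3,
                       ms_indel_rate_mmrd = 0.3,
                       ms_indel_rate_mmrp = 0.02,
                       read_length = 90L,
                       tile_step = 15L,
                       n_edit_peptides = 50L,
                       n_mmrp_edit_peptides = 10L,
                       n_support = 12L,
                       n_noncanonical_windows = 9L,
                       n_antisense_windows = 3L,
                       error_rate = 0,
                       variant_read_af = 0) {
  cfg <- as.list(environment())
  stopifnot(rate_factor >= 1, editing_fraction >= 0, editing_fraction <= 1,
            n_support >= 10)
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Simulate the toy genome, transcript models and region tracks
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `genome_sizes`,
#'   `models` (transcript table with an `expressed` column), `tracks`
#'   and `ms_planted` (the deliberately planted microsatellite runs).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed + 101L)
  sizes <- config$chrom_lengths
  genome <- vapply(sizes, rand_dna, character(1))
  names(genome) <- names(sizes)

  n_nc <- round(config$n_transcripts * config$frac_ncrna)
  n_coding <- config$n_transcripts - n_nc
  kinds <- sample(c(rep("coding", n_coding), rep("ncRNA", n_nc)))
  rows <- list()
  ti <- 0L
  chroms <- rep(names(sizes), length.out = config$n_transcripts * 3)
  cursors <- stats::setNames(rep(600L, length(sizes)), names(sizes))
  for (kind in kinds) {
    placed <- FALSE
    for (chrom in sample(names(sizes))) {
      span_budget <- sizes[[chrom]] - cursors[[chrom]] - 600L
      if (span_budget < 2600L) next
      ti <- ti + 1L
      strand <- sample(c("+", "-"), 1L)
      m <- make_transcript(chrom, cursors[[chrom]], strand,
                           coding = kind == "coding", id = ti)
      rows[[length(rows) + 1L]] <- m
      cursors[[chrom]] <- m$tx_end + sample(400:1200, 1L)
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  models <- data.table::rbindlist(rows)
  coding_idx <- which(models$cds_end > models$cds_start)
  silent <- utils::head(sample(coding_idx), config$n_silent_tx)
  models[, expressed := TRUE]
  models$expressed[silent] <- FALSE
  validate_transcripts(models)

  # microsatellite runs in intergenic gaps
  ms <- list()
  occ <- models[, .(chrom, start = tx_start, end = tx_end)]
  tries <- 0L
  while (length(ms) < config$n_ms_loci && tries < config$n_ms_loci * 20L) {
    tries <- tries + 1L
    chrom_i <- sample(names(sizes), 1L)
    u <- sample(1:2, 1L, prob = c(0.7, 0.3))
    reps <- sample(8:15, 1L)
    len <- u * reps
    pos <- sample(200:(sizes[[chrom_i]] - len - 200L), 1L)
    if (any(occ$chrom == chrom_i & occ$start < pos + len & occ$end > pos))
      next
    unit <- rand_dna(u)
    if (min_period(unit) != u) next
    run <- paste(rep(unit, reps), collapse = "")
    substr(genome[[chrom_i]], pos + 1L, pos + len) <- run
    ms[[length(ms) + 1L]] <- data.table::data.table(
      chrom = chrom_i, start = pos, end = pos + len, unit = unit,
      unit_length = u, repeat_count = reps)
    occ <- rbind(occ, data.table::data.table(chrom = chrom_i, start = pos,
                                             end = pos + len))
  }
  ms_planted <- if (length(ms)) data.table::rbindlist(ms) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer())
  tracks <- tracks_from_transcripts(models, sizes)
  list(genome = genome, genome_sizes = sizes, models = models,
       tracks = tracks, ms_planted = ms_planted)
}

make_transcript <- function(chrom, offset, strand, coding, id) {
  n_ex <- sample(1:3, 1L)
  ex_len <- sample(500:700, n_ex, replace = TRUE)
  in_len <- if (n_ex > 1) sample(150:400, n_ex - 1L, replace = TRUE) else
    integer(0)
  starts <- integer(n_ex); ends <- integer(n_ex)
  cur <- offset
  for (i in seq_len(n_ex)) {
    starts[i] <- cur; ends[i] <- cur + ex_len[i]
    cur <- ends[i] + if (i < n_ex) in_len[i] else 0L
  }
  tx_start <- starts[1]; tx_end <- ends[n_ex]
  if (!coding) {
    cds_start <- cds_end <- tx_start
  } else {
    utr_left <- sample(150:220, 1L)   # genomic-left UTR within first exon
    utr_right <- sample(150:220, 1L)
    cds_start <- tx_start + utr_left
    cds_end <- tx_end - utr_right
    # trim so the exonic CDS length is a codon multiple
    exonic_cds <- sum(pmax(pmin(ends, cds_end) - pmax(starts, cds_start), 0L))
    cds_end <- cds_end - (exonic_cds %% 3L)
  }
  data.table::data.table(
    gene_name = sprintf("gene%03d", id), tx_id = sprintf("tx%03d", id),
    chrom = chrom, strand = strand, tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end, exon_count = n_ex,
    exon_starts = paste0(paste(starts, collapse = ","), ","),
    exon_ends = paste0(paste(ends, collapse = ","), ","))
}

SIM_SAMPLES <- data.table::data.table(
  sample_id = c("mmrp_pre", "mmrp_nod", "mmrp_balbc1",
                "mmrd_pre", "mmrd_nod", "mmrd_balbc1", "mmrd_balbc2",
                "mmrd_balbc3"),
  genotype = c(rep("MMRp", 3), rep("MMRd", 5)),
  host = c("pre", "NOD-SCID", "BALB/c", "pre", "NOD-SCID",
           "BALB/c", "BALB/c", "BALB/c"),
  replicate = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L))

#' Simulate germline and per-sample somatic variant sets
#'
#' Somatic variants are Poisson-planted per region label at the arm's
#' rate (MMRd = `rate_factor` x MMRp). Post-injection samples inherit
#' the pre-injection somatic set, gain a small number of new variants,
#' and — only in immunocompetent MMRd tumours — lose a fraction
#' `editing_fraction` of variants in the immunogenic labels
#' (`editing_labels`). MMRd samples additionally acquire microsatellite
#' deletions. Depths are drawn so that most calls clear the 10x / 9-read
#' filter, with a 10% admixture of low-support decoy calls that the
#' filter must remove. Raw per-sample call sets include the germline
#' variants (subtracted later by [filter_somatic()]).
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return list with `germline` (a `variant_set`), `samples` (named list
#'   of raw `variant_set`s) and `truth` (expected post-filter somatic
#'   keys and the edited-variant keys per sample).
#' @export
simulate_variants <- function(config, sim) {
  set.seed(config$seed + 202L)
  tracks <- sim$tracks
  genome <- sim$genome
  sizes <- region_sizes(tracks)

  draw_in_label <- function(n, label) {
    t <- tracks[[label]]
    if (!nrow(t) || n == 0)
      return(data.table::data.table(chrom = character(), pos = integer()))
    w <- t$end - t$start
    row <- sample(nrow(t), n, replace = TRUE, prob = w)
    data.table::data.table(chrom = t$chrom[row],
                           pos = t$start[row] +
                             floor(stats::runif(n) * w[row]))
  }
  alleles <- function(dt, indel_frac) {
    n <- nrow(dt)
    if (!n) return(dt[, `:=`(ref = character(0), alt = character(0))])
    base <- substring(genome[dt$chrom], dt$pos + 1L, dt$pos + 1L)
    nxt <- substring(genome[dt$chrom], dt$pos + 1L, dt$pos + 2L)
    kind <- stats::runif(n) < indel_frac & nchar(nxt) == 2L
    other <- vapply(base, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    ins <- stats::runif(n) < 0.5
    dt[, ref := ifelse(kind & !ins, nxt, base)]
    dt[, alt := ifelse(kind, ifelse(ins, paste0(base, other), base), other)]
    dt
  }
  with_depths <- function(dt, decoy_frac = 0.1) {
    n <- nrow(dt)
    if (!n) return(dt[, `:=`(total_depth = integer(0),
                             alt_depth = integer(0))])
    # locals must not collide with the ref/alt columns under NSE
    dp_tot <- 10L + stats::rpois(n, 60)
    dp_alt <- pmax(9L, stats::rbinom(n, dp_tot, 0.45))
    dp_alt <- pmin(dp_alt, dp_tot)
    decoy <- stats::runif(n) < decoy_frac
    dp_tot[decoy] <- sample(3:9, sum(decoy), replace = TRUE)
    dp_alt[decoy] <- pmin(dp_tot[decoy],
                          sample(1:8, sum(decoy), replace = TRUE))
    dt[, `:=`(total_depth = dp_tot, alt_depth = dp_alt)]
    dt
  }
  draw_set <- function(rate_per_mb, indel_frac) {
    parts <- lapply(names(tracks), function(lab) {
      n <- stats::rpois(1L, rate_per_mb * sizes[[lab]] / 1e6)
      alleles(draw_in_label(n, lab), indel_frac)
    })
    unique(data.table::rbindlist(parts), by = c("chrom", "pos"))
  }

  germ <- with_depths(draw_set(config$germline_rate, 0.1), decoy_frac = 0)
  germ_vs <- variant_set(germ, "germline", host = NA_character_)

  out_samples <- list()
  truth <- list(expected = list(), edited = list())
  for (geno in c("MMRp", "MMRd")) {
    rate <- config$somatic_rate_mmrp *
      (if (geno == "MMRd") config$rate_factor else 1)
    indel_frac <- if (geno == "MMRd") config$indel_frac_mmrd else
      config$indel_frac_mmrp
    pre <- draw_set(rate, indel_frac)
    if (geno == "MMRd" && nrow(sim$ms_planted)) {
      hit <- stats::runif(nrow(sim$ms_planted)) < config$ms_indel_rate_mmrd
      msv <- sim$ms_planted[hit]
      if (nrow(msv)) {
        msdt <- data.table::data.table(chrom = msv$chrom, pos = msv$start)
        msdt[, ref := substring(genome[chrom], pos + 1L, pos + 2L)]
        msdt[, alt := substring(ref, 1L, 1L)]
        pre <- unique(rbind(pre, msdt, fill = TRUE), by = c("chrom", "pos"))
      }
    }
    pre <- with_depths(pre)
    pre_labels <- assign_region(
      data.table::data.table(chrom = pre$chrom, start = pre$pos,
                             end = pre$pos + nchar(pre$ref)), sim$tracks)
    immunogenic <- pre_labels %in% config$editing_labels
    arm_samples <- SIM_SAMPLES[SIM_SAMPLES$genotype == geno, ]
    for (si in seq_len(nrow(arm_samples))) {
      s <- arm_samples[si, ]
      som <- data.table::copy(pre)
      edited_keys <- character(0)
      if (s$host != "pre") {
        if (s$host == "BALB/c" && geno == "MMRd") {
          drop <- immunogenic &
            stats::runif(nrow(som)) < config$editing_fraction
          edited_keys <- paste(som$chrom[drop], som$pos[drop],
                               som$ref[drop], som$alt[drop])
          som <- som[!drop]
        }
        gain <- with_depths(draw_set(rate * config$gain_rate_frac,
                                     indel_frac), decoy_frac = 0)
        som <- unique(rbind(som, gain), by = c("chrom", "pos"))
      }
      raw <- unique(rbind(som, data.table::as.data.table(germ_vs)[
        , names(som), with = FALSE]), by = c("chrom", "pos"))
      out_samples[[s$sample_id]] <- variant_set(
        raw, s$sample_id, geno, s$host, s$replicate)
      ok <- som$total_depth >= 10L & som$alt_depth >= 9L
      truth$expected[[s$sample_id]] <-
        paste(som$chrom[ok], som$pos[ok], som$ref[ok], som$alt[ok])
      truth$edited[[s$sample_id]] <- edited_keys
    }
  }
  list(germline = germ_vs, samples = out_samples, truth = truth)
}

# exonic genomic positions of a transcript in transcript order (0-based)
tx_genome_positions <- function(m) {
  ex_s <- exon_list(m$exon_starts); ex_e <- exon_list(m$exon_ends)
  gpos <- unlist(lapply(seq_along(ex_s), function(i)
    seq.int(ex_s[i], ex_e[i] - 1L)))
  if (m$strand == "-") gpos <- rev(gpos)
  gpos
}

positions_to_blocks <- function(gpos, chrom) {
  gpos <- sort(gpos)
  brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
  data.table::data.table(
    chrom = chrom,
    start = gpos[brk[-length(brk)] + 1L],
    end = gpos[brk[-1L]] + 1L)
}

# fast scalar translation (codon-table lookup; avoids per-call setup of
# Biostrings' fuzzy-codon machinery inside the rejection sampler)
translate_quick <- function(seq, reverse = FALSE) {
  if (reverse) seq <- revcomp_chr(seq)
  n <- (nchar(seq) %/% 3L) * 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

genome_substr <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp_chr(s)
  s
}

#' Simulate RNA-seq reads with planted immune editing
#'
#' Background reads are deterministic tilings of expressed transcripts
#' (spliced), of configured non-canonical transcription windows
#' (UTR-initiated, intronic, extragenic) and antisense windows; the same
#' background is emitted for every sample, so in the noiseless world
#' background peptides have identical counts everywhere. Planted editing
#' targets are 8-mer peptides carried by minimal 24-nt support reads
#' constructed so that only reading frame +1 yields a k-mer: `n_support`
#' copies appear in the arm's pre-injection and NOD-SCID samples and
#' none in the designated immunocompetent (BALB/c) samples. Window
#' labels span coding in-frame (in unexpressed transcripts), coding
#' out-of-frame, UTRs, intron, extragenic and antisense placements, and
#' each planted peptide is unique in the genome and absent from the
#' background k-mer set.
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome()].
#' @return list with `samples` (named list of read tables), `blocks`
#'   (named list of genomic footprint tables for coverage), `plan`
#'   (MMRd editing-plan truth table) and `mmrp_plan`.
#' @export
simulate_reads <- function(config, sim) {
  set.seed(config$seed + 303L)
  genome <- sim$genome
  models <- sim$models
  rl <- config$read_length

  bg_reads <- list(); bg_blocks <- list()
  add_bg <- function(id, seq, blocks, origin) {
    bg_reads[[length(bg_reads) + 1L]] <<- data.table::data.table(
      read_id = id, seq = seq, chrom = blocks$chrom[1],
      start = min(blocks$start), end = max(blocks$end),
      strand = "+", origin = origin,
      contiguous = nrow(blocks) == 1L)
    blocks$read_id <- id
    bg_blocks[[length(bg_blocks) + 1L]] <<- blocks
  }

  # canonical transcription: tile spliced mRNA of expressed transcripts
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    if (!m$expressed) next
    gpos <- tx_genome_positions(m)
    mrna <- paste(substring(genome[[m$chrom]], sort(gpos) + 1L,
                            sort(gpos) + 1L), collapse = "")
    if (m$strand == "-") mrna <- revcomp_chr(mrna)
    L <- nchar(mrna)
    if (L < rl) next
    for (p in seq(1L, L - rl + 1L, by = config$tile_step)) {
      tx_slice <- gpos[p:(p + rl - 1L)]
      add_bg(sprintf("bg_%s_%04d", m$tx_id, p),
             substr(mrna, p, p + rl - 1L),
             positions_to_blocks(tx_slice, m$chrom),
             paste0("mrna:", m$tx_id))
    }
  }

  # non-canonical transcription windows (genomically contiguous)
  nc_labels <- rep(c("intron", "extragenic", "utr5"),
                   length.out = config$n_noncanonical_windows)
  for (wi in seq_len(config$n_noncanonical_windows)) {
    w <- sample_window(sim, nc_labels[wi], 220L)
    if (is.null(w)) next
    seq <- genome_substr(genome, w$chrom, w$start, w$end)
    for (p in seq(1L, nchar(seq) - rl + 1L, by = 30L)) {
      add_bg(sprintf("bg_nc%02d_%03d", wi, p), substr(seq, p, p + rl - 1L),
             data.table::data.table(chrom = w$chrom,
                                    start = w$start + p - 1L,
                                    end = w$start + p - 1L + rl),
             paste0("noncanonical:", nc_labels[wi]))
    }
  }
  # antisense windows over coding exons
  for (wi in seq_len(config$n_antisense_windows)) {
    w <- sample_window(sim, "coding", 220L)
    if (is.null(w)) next
    seq <- revcomp_chr(genome_substr(genome, w$chrom, w$start, w$end))
    for (p in seq(1L, nchar(seq) - rl + 1L, by = 30L)) {
      add_bg(sprintf("bg_as%02d_%03d", wi, p), substr(seq, p, p + rl - 1L),
             data.table::data.table(chrom = w$chrom,
                                    start = w$end - (p - 1L) - rl,
                                    end = w$end - (p - 1L)),
             "antisense:coding")
    }
  }
  background <- data.table::rbindlist(bg_reads)
  background_blocks <- data.table::rbindlist(bg_blocks)
  # keyed table: O(log n) membership tests inside the rejection sampler
  bg_peptides <- data.table::data.table(
    peptide = count_peptides(background)$peptide, key = "peptide")
  subjects <- lapply(genome, Biostrings::DNAString)

  # planted editing targets
  plan_labels <- function(n) rep(c("utr5", "utr3", "intron", "extragenic",
                                   "coding_oof", "coding_if", "antisense"),
                                 length.out = n)
  taken <- character(0)
  plant <- function(n, arm) {
    labs <- plan_labels(n)
    rows <- list()
    for (i in seq_len(n)) {
      w <- plant_window(config, sim, labs[i], bg_peptides, taken, subjects)
      if (is.null(w))
        stop("could not place planted window of type ", labs[i])
      taken <<- c(taken, w$peptide)
      w$plan_id <- sprintf("%s_ed%03d", arm, i)
      rows[[length(rows) + 1L]] <- w
    }
    data.table::rbindlist(rows)
  }
  plan <- plant(config$n_edit_peptides, "mmrd")
  mmrp_plan <- plant(config$n_mmrp_edit_peptides, "mmrp")

  support_reads <- function(planned, n_support) {
    data.table::rbindlist(lapply(seq_len(nrow(planned)), function(i) {
      p <- planned[i, ]
      data.table::data.table(
        read_id = sprintf("%s_r%02d", p$plan_id, seq_len(n_support)),
        seq = p$read_seq, chrom = p$chrom, start = p$start, end = p$end,
        strand = p$strand, origin = paste0("planted:", p$label),
        contiguous = TRUE)
    }))
  }
  plan_sup <- support_reads(plan, config$n_support)
  mmrp_sup <- support_reads(mmrp_plan, config$n_support)

  samples <- list(); blocks <- list()
  for (si in seq_len(nrow(SIM_SAMPLES))) {
    s <- SIM_SAMPLES[si, ]
    rd <- data.table::copy(background)
    bl <- data.table::copy(background_blocks)
    sup <- NULL
    if (s$genotype == "MMRd" && s$host != "BALB/c") sup <- plan_sup
    if (s$genotype == "MMRp" && s$host != "BALB/c") sup <- mmrp_sup
    if (!is.null(sup)) {
      rd <- rbind(rd, sup)
      bl <- rbind(bl, sup[, .(chrom, start, end, read_id)],
                  use.names = TRUE)
    }
    rd[, sample_id := s$sample_id]
    if (config$error_rate > 0)
      rd[, seq := mutate_seq(seq, config$error_rate)]
    samples[[s$sample_id]] <- rd
    blocks[[s$sample_id]] <- bl
  }
  list(samples = samples, blocks = blocks, plan = plan,
       mmrp_plan = mmrp_plan)
}

mutate_seq <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    for (h in hit)
      substr(s, h, h) <- sample(c("A", "C", "G", "T"), 1L)
    s
  }, character(1), USE.NAMES = FALSE)
}

# random window of a given length fully inside one interval of a track,
# not overlapping any higher-priority track
sample_window <- function(sim, label, len, tries = 50L) {
  t <- sim$tracks[[label]]
  t <- t[t$end - t$start >= len]
  if (!nrow(t)) return(NULL)
  higher <- REGION_PRIORITY[seq_len(match(label, REGION_PRIORITY) - 1L)]
  hgr <- NULL
  hi_dt <- data.table::rbindlist(
    lapply(intersect(higher, names(sim$tracks)),
           function(l) sim$tracks[[l]][, c("chrom", "start", "end")]))
  if (!is.null(hi_dt) && nrow(hi_dt)) hgr <- as_granges0(hi_dt)
  for (k in seq_len(tries)) {
    row <- sample(nrow(t), 1L)
    s <- t$start[row] + sample.int(t$end[row] - t$start[row] - len + 1L, 1L) - 1L
    w <- data.table::data.table(chrom = t$chrom[row], start = s,
                                end = s + len)
    if (!is.null(hgr) &&
        length(GenomicRanges::findOverlaps(as_granges0(w), hgr)) > 0) next
    return(w)
  }
  NULL
}

# Construct one planted 8-mer window of the requested type. The 24-nt
# support read must: translate stop-free in frame +1; contain a stop in
# frame -1 (so no reverse-frame k-mer leaks out); be unique in the
# genome (both strands); and its peptide must be absent from the
# background and from previously planted peptides.
plant_window <- function(config, sim, type, bg_peptides, taken,
                         subjects = NULL, tries = 400L) {
  genome <- sim$genome
  if (is.null(subjects)) subjects <- lapply(genome, Biostrings::DNAString)
  in_bg <- function(p) nrow(bg_peptides[data.table::.(p), nomatch = NULL]) > 0
  len <- 24L
  for (k in seq_len(tries)) {
    if (type %in% c("coding_if", "coding_oof")) {
      # unexpressed transcripts only: expressed mRNA is tiled by
      # background reads whose six-frame k-mers would already contain
      # any in-exon peptide, in every phase
      pool <- sim$models[sim$models$cds_end > sim$models$cds_start &
                           !sim$models$expressed, ]
      if (!nrow(pool)) stop("config needs n_silent_tx >= 1")
      m <- pool[sample(nrow(pool), 1L), ]
      ex_s <- exon_list(m$exon_starts); ex_e <- exon_list(m$exon_ends)
      ei <- sample(length(ex_s), 1L)
      lo <- max(ex_s[ei], m$cds_start); hi <- min(ex_e[ei], m$cds_end)
      if (hi - lo < len + 6L) next
      s <- lo + sample.int(hi - lo - len + 1L, 1L) - 1L
      strand <- m$strand
      first_base <- if (strand == "+") s else s + len - 1L
      cpos <- cds_coordinate(m, first_base)
      if (is.na(cpos)) next
      want_phase0 <- type == "coding_if"
      if (want_phase0 != (cpos %% 3L == 0L)) next
      w <- data.table::data.table(chrom = m$chrom, start = s, end = s + len)
      label <- "coding"
      frame_truth <- if (want_phase0) "in-frame" else "out-of-frame"
    } else if (type == "antisense") {
      pool <- sim$models[sim$models$cds_end > sim$models$cds_start &
                           !sim$models$expressed, ]
      if (!nrow(pool)) stop("config needs n_silent_tx >= 1")
      m <- pool[sample(nrow(pool), 1L), ]
      ex_s <- exon_list(m$exon_starts); ex_e <- exon_list(m$exon_ends)
      ei <- sample(length(ex_s), 1L)
      lo <- max(ex_s[ei], m$cds_start); hi <- min(ex_e[ei], m$cds_end)
      if (hi - lo < len + 6L) next
      s <- lo + sample.int(hi - lo - len + 1L, 1L) - 1L
      strand <- if (m$strand == "+") "-" else "+"
      w <- data.table::data.table(chrom = m$chrom, start = s, end = s + len)
      label <- "coding"
      frame_truth <- "out-of-frame"
    } else {
      w <- sample_window(sim, type, len, tries = 5L)
      if (is.null(w)) next
      strand <- sample(c("+", "-"), 1L)
      label <- type
      frame_truth <- "out-of-frame"
    }
    # by construction the window sits wholly inside its own label
    # (containment in the track interval, no higher-priority overlap)
    read_seq <- genome_substr(genome, w$chrom, w$start, w$end, strand)
    aa <- translate_quick(read_seq)
    if (grepl("[*X]", aa)) next
    rev_aa <- translate_quick(read_seq, reverse = TRUE)
    if (!grepl("\\*", rev_aa)) next
    if (aa %in% taken || in_bg(aa)) next
    if (genome_hits(genome, read_seq, subjects) != 1L) next
    # for coding in-frame truth, the peptide must equal the genome-frame
    # translation (guaranteed by phase); for frame_status we also need no
    # other same-strand transcript to put it in frame (genes don't overlap)
    return(data.table::data.table(
      chrom = w$chrom, start = w$start, end = w$end, strand = strand,
      label = label, frame = frame_truth,
      canonical = if (label == "coding" && frame_truth == "in-frame")
        "Canonical" else "Non-canonical",
      peptide = aa, read_seq = read_seq))
  }
  NULL
}

genome_hits <- function(genome, seq, subjects = NULL) {
  if (is.null(subjects)) subjects <- lapply(genome, Biostrings::DNAString)
  rc <- revcomp_chr(seq)
  tot <- 0L
  for (chrom in names(genome)) {
    tot <- tot + length(Biostrings::matchPattern(seq, subjects[[chrom]]))
    if (rc != seq)
      tot <- tot + length(Biostrings::matchPattern(rc, subjects[[chrom]]))
  }
  tot
}

#' Simulate an observed (eluted) peptide list from the planted truth
#'
#' A sample of the MMRd editing plan plus decoys — peptides private to
#' the MMRp plan and random 8-11-mers — with synthetic log-normal MS
#' intensities and replicate counts.
#'
#' @param config a [sim_config()].
#' @param reads output of [simulate_reads()].
#' @param n_true,n_decoy_mmrp,n_decoy_random composition of the list.
#' @return data.table `peptide`, `ms_intensity`, `ms_replicates`,
#'   `source` (truth bookkeeping).
#' @export
simulate_observed_peptides <- function(config, reads, n_true = 30L,
                                       n_decoy_mmrp = 5L,
                                       n_decoy_random = 5L) {
  set.seed(config$seed + 404L)
  true_pep <- sample(reads$plan$peptide, min(n_true, nrow(reads$plan)))
  mmrp_pep <- sample(reads$mmrp_plan$peptide,
                     min(n_decoy_mmrp, nrow(reads$mmrp_plan)))
  rand_pep <- vapply(seq_len(n_decoy_random), function(i)
    paste(sample(AA_ALPHABET20, sample(8:11, 1L), replace = TRUE),
          collapse = ""), character(1))
  dt <- data.table::data.table(
    peptide = c(true_pep, mmrp_pep, rand_pep),
    source = c(rep("planted_mmrd", length(true_pep)),
               rep("decoy_mmrp", length(mmrp_pep)),
               rep("decoy_random", length(rand_pep))))
  dt[, ms_intensity := round(stats::rlnorm(.N, meanlog = 14, sdlog = 1))]
  dt[, ms_replicates := sample(1:4, .N, replace = TRUE,
                               prob = c(0.5, 0.25, 0.15, 0.1))]
  dt[]
}

#' Run every generator under one config
#'
#' @param config a [sim_config()].
#' @return list with `config`, `genome`, `genome_sizes`, `models`,
#'   `tracks`, `ms_planted`, `variants`, `reads`, `observed`.
#' @export
simulate_immunoediting <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  variants <- simulate_variants(config, sim)
  reads <- simulate_reads(config, sim)
  observed <- simulate_observed_peptides(config, reads)
  c(sim, list(config = config, variants = variants, reads = reads,
              observed = observed))
}
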