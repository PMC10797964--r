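#' Somatic variant filtering, per-region TMB and immune-editing ratios
#'
#' @name variant_analysis
NULL

empty_variants <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         vclass = character(), total_depth = integer(),
                         alt_depth = integer())
}

#' Construct a sample variant set
#'
#' @param variants data.frame with `chrom`, `pos` (0-based), `ref`, `alt`
#'   and read depths `total_depth`, `alt_depth`. The variant class
#'   (SNV/INS/DEL) is derived from allele lengths.
#' @param sample_id sample label.
#' @param genotype `"MMRp"` or `"MMRd"` (or NA).
#' @param host `"pre"`, `"NOD-SCID"` or `"BALB/c"` (or NA).
#' @param replicate replicate index.
#' @return a `variant_set` (data.table with metadata attributes).
#' @export
variant_set <- function(variants, sample_id = NA_character_,
                        genotype = NA_character_, host = NA_character_,
                        replicate = NA_integer_) {
  v <- data.table::as.data.table(variants)
  if (nrow(v) == 0) v <- empty_variants()
  if (any(v$alt_depth > v$total_depth, na.rm = TRUE))
    stop("alt_depth exceeds total_depth")
  v[, vclass := data.table::fcase(
    nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    nchar(alt) > nchar(ref), "INS",
    nchar(ref) > nchar(alt), "DEL",
    default = "SNV")]
  v <- unique(v, by = c("chrom", "pos", "ref", "alt"))
  data.table::setkeyv(v, c("chrom", "pos"))
  data.table::setattr(v, "sample_id", sample_id)
  data.table::setattr(v, "genotype", genotype)
  data.table::setattr(v, "host", host)
  data.table::setattr(v, "replicate", replicate)
  data.table::setattr(v, "class", c("variant_set", class(v)))
  v[]
}

vs_meta <- function(vset) {
  list(sample_id = attr(vset, "sample_id"), genotype = attr(vset, "genotype"),
       host = attr(vset, "host"), replicate = attr(vset, "replicate"))
}

#' Filter somatic calls against germline and depth thresholds
#'
#' Removes any call whose `(chrom, pos, ref, alt)` key is present in the
#' germline set, then keeps calls with `total_depth >= min_depth` and
#' `alt_depth >= min_alt_reads` (defaults: minimum depth 10x, at least
#' nine mutated reads).
#'
#' @param calls,germline `variant_set` objects on the same genome.
#' @param min_depth minimum total depth (default 10).
#' @param min_alt_reads minimum variant-supporting reads (default 9).
#' @return filtered `variant_set` with the metadata of `calls`.
#' @export
filter_somatic <- function(calls, germline, min_depth = 10L,
                           min_alt_reads = 9L) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  keep <- !(key(calls) %in% key(germline)) &
    calls$total_depth >= min_depth & calls$alt_depth >= min_alt_reads
  m <- vs_meta(calls)
  variant_set(data.table::as.data.table(calls)[keep],
              m$sample_id, m$genotype, m$host, m$replicate)
}

variant_footprint <- function(vset) {
  data.table::data.table(chrom = vset$chrom, start = vset$pos,
                         end = vset$pos + pmax(nchar(vset$ref), 1L))
}

#' Per-region mutation summary and normalised TMB
#'
#' Each variant is assigned exactly one region label by applying the
#' priority rule to its reference footprint `[pos, pos + len(ref))`.
#' TMB is `(n_SNV + n_indel) / (region size / 1e6)` variants per Mb.
#'
#' @param vset a `variant_set` (optionally carrying `effect` and
#'   `microsatellite` columns from [coding_effect()] /
#'   [flag_ms_indels()], which are then summarised too).
#' @param tracks a `region_tracks` object.
#' @return data.table with one row per label: counts, region size and
#'   `tmb_per_mb`.
#' @export
tmb_by_region <- function(vset, tracks) {
  sizes <- region_sizes(tracks)
  labs <- names(tracks)
  v <- data.table::as.data.table(vset)
  if (nrow(v)) {
    v <- data.table::copy(v)
    v[, label := assign_region(variant_footprint(vset), tracks)]
  } else v[, label := character(0)]
  out <- data.table::data.table(label = labs,
                                region_size_bp = as.numeric(sizes[labs]))
  cnt <- v[, .(n_SNV = sum(vclass == "SNV"),
               n_indel = sum(vclass != "SNV"),
               n_silent = sum(.SD$effect == "silent"),
               n_nonsilent = sum(.SD$effect == "nonsilent"),
               n_microsatellite_indels = sum(.SD$microsatellite %in% TRUE)),
           by = label,
           .SDcols = intersect(c("effect", "microsatellite", "vclass"),
                               names(v))]
  if (!"effect" %in% names(v))
    cnt[, `:=`(n_silent = NA_integer_, n_nonsilent = NA_integer_)]
  if (!"microsatellite" %in% names(v))
    cnt[, n_microsatellite_indels := NA_integer_]
  out <- merge(out, cnt, by = "label", all.x = TRUE)
  for (cc in c("n_SNV", "n_indel"))
    out[is.na(get(cc)), (cc) := 0L]
  out[, tmb_per_mb := ifelse(region_size_bp > 0,
                             (n_SNV + n_indel) / (region_size_bp / 1e6),
                             NA_real_)]
  out[match(labs, label)]
}

#' Immune-editing log-ratio of post- vs pre-injection TMB
#'
#' The natural logarithm of the ratio between post- and pre-injection
#' normalised TMB for one region. A zero pre-injection TMB yields `NA`
#' (undefined); a zero post-injection TMB yields `-Inf`, a flagged
#' sentinel for complete loss.
#'
#' @param tmb_pre,tmb_post TMB values (variants per Mb) for the same
#'   region label.
#' @return `ln(tmb_post / tmb_pre)` (vectorised).
#' @export
editing_logratio <- function(tmb_pre, tmb_post) {
  out <- ifelse(tmb_pre <= 0, NA_real_, log(tmb_post / tmb_pre))
  out
}

#' Gained and lost alterations per region after in vivo growth
#'
#' `gained` are variants present post- but not pre-injection; `lost` the
#' converse. Rates are normalised per Mb of region size.
#'
#' @param pre_set,post_set filtered `variant_set` objects.
#' @param tracks a `region_tracks` object.
#' @return data.table per label: `gained_per_mb`, `lost_per_mb`.
#' @export
gained_lost <- function(pre_set, post_set, tracks) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  pre <- data.table::as.data.table(pre_set)
  post <- data.table::as.data.table(post_set)
  gained <- post[!(key(post) %in% key(pre))]
  lost <- pre[!(key(pre) %in% key(post))]
  sizes <- region_sizes(tracks)
  labs <- names(tracks)
  count_by <- function(v) {
    if (!nrow(v)) return(stats::setNames(rep(0, length(labs)), labs))
    tab <- table(assign_region(
      variant_footprint(variant_set(v)), tracks))
    out <- stats::setNames(rep(0, length(labs)), labs)
    out[names(tab)] <- as.numeric(tab)
    out
  }
  mb <- ifelse(sizes[labs] > 0, sizes[labs] / 1e6, NA_real_)
  data.table::data.table(
    label = labs,
    gained_per_mb = count_by(gained)[labs] / mb,
    lost_per_mb = count_by(lost)[labs] / mb)
}

#' Host delta of gained/lost rates (immunocompromised minus competent)
#'
#' Compares how many alterations per Mb were gained/lost during growth in
#' an immunocompromised (NOD-SCID) versus an immunocompetent (BALB/c)
#' host. A negative `delta_lost` for a label means more variants of that
#' label were lost in the immunocompetent host — the immune-editing
#' signature.
#'
#' @param pre_set pre-injection filtered `variant_set`.
#' @param post_nod,post_balbc post-injection sets from the two hosts.
#' @param tracks a `region_tracks` object.
#' @return data.table per label with per-host rates and
#'   `delta_gained` / `delta_lost` (NOD-SCID minus BALB/c).
#' @export
host_editing_delta <- function(pre_set, post_nod, post_balbc, tracks) {
  a <- gained_lost(pre_set, post_nod, tracks)
  b <- gained_lost(pre_set, post_balbc, tracks)
  data.table::data.table(
    label = a$label,
    gained_nod = a$gained_per_mb, gained_balbc = b$gained_per_mb,
    lost_nod = a$lost_per_mb, lost_balbc = b$lost_per_mb,
    delta_gained = a$gained_per_mb - b$gained_per_mb,
    delta_lost = a$lost_per_mb - b$lost_per_mb)
}

#' Silent / non-silent / noncoding classification of variants
#'
#' An SNV inside the CDS of a coding transcript is `silent` iff the
#' altered codon encodes the same amino acid on the transcript strand;
#' coding indels are `nonsilent` (frameshift or in-frame disruption);
#' variants outside every CDS are `noncoding`. With several overlapping
#' transcripts, a variant is non-silent if non-silent in any of them.
#'
#' @param vset a `variant_set`.
#' @param models a `transcript_models` table.
#' @param genome named character vector of chromosome sequences.
#' @return the variant set with an added `effect` column.
#' @export
coding_effect <- function(vset, models, genome) {
  v <- data.table::copy(data.table::as.data.table(vset))
  if (!nrow(v)) { v[, effect := character(0)]; return(v[]) }
  coding <- models[models$cds_end > models$cds_start, , drop = FALSE]
  cds_cache <- lapply(seq_len(nrow(coding)), function(i)
    cds_structure(coding[i, ], genome))
  eff <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    chrom <- v$chrom[j]; pos <- v$pos[j]
    ref <- v$ref[j]; alt <- v$alt[j]
    gref <- substr(genome[[chrom]], pos + 1L, pos + nchar(ref))
    if (!identical(toupper(gref), toupper(ref)))
      stop("ref allele disagrees with genome at ", chrom, ":", pos)
    res <- "noncoding"
    for (cs in cds_cache) {
      if (cs$chrom != chrom) next
      idx <- match(pos, cs$gpos)   # CDS coordinate of this genomic base
      if (is.na(idx)) next
      if (nchar(ref) != 1L || nchar(alt) != 1L) { res <- "nonsilent"; break }
      cpos <- if (cs$strand == "+") idx - 1L else length(cs$gpos) - idx
      codon_i <- cpos %/% 3L
      codon <- substr(cs$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      base <- if (cs$strand == "+") alt else chartr("ACGT", "TGCA", alt)
      mut <- codon
      substr(mut, cpos %% 3L + 1L, cpos %% 3L + 1L) <- base
      same <- Biostrings::GENETIC_CODE[[codon]] ==
        Biostrings::GENETIC_CODE[[mut]]
      if (!same) { res <- "nonsilent"; break }
      res <- "silent"
    }
    eff[j] <- res
  }
  v[, effect := eff]
  v[]
}

# CDS layout of one coding transcript: ordered genomic positions (0-based)
# of CDS bases in genome order, plus the strand-oriented CDS sequence.
cds_structure <- function(m, genome) {
  ex_s <- exon_list(m$exon_starts); ex_e <- exon_list(m$exon_ends)
  gpos <- unlist(lapply(seq_along(ex_s), function(i) {
    lo <- max(ex_s[i], m$cds_start); hi <- min(ex_e[i], m$cds_end)
    if (hi > lo) seq.int(lo, hi - 1L) else integer(0)
  }))
  seq_fwd <- paste(substring(genome[[m$chrom]], gpos + 1L, gpos + 1L),
                   collapse = "")
  seq <- if (m$strand == "+") seq_fwd else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  list(chrom = m$chrom, strand = m$strand, gpos = gpos, seq = seq)
}

#' Scan a genome for microsatellite loci
#'
#' Finds maximal perfect tandem repeats with unit length 1-`unit_max`
#' and at least `min_repeats` copies. A locus spans exactly
#' `repeat_count * unit_length` bases; tracts whose repeat unit is itself
#' periodic (e.g. "AA" within a poly-A run) are reported once at the
#' primitive unit. This is a simplified stand-in for a full MSI caller:
#' instability is summarised downstream as the fraction of scanned loci
#' carrying a somatic indel.
#'
#' @param genome named character vector of chromosome sequences.
#' @param unit_max maximum repeat-unit length (default 5).
#' @param min_repeats minimum copies of the unit (default 5).
#' @return data.table of loci: chrom/start/end (0-based half-open),
#'   `unit`, `unit_length`, `repeat_count`.
#' @export
scan_microsatellites <- function(genome, unit_max = 5L, min_repeats = 5L) {
  out <- list()
  for (chrom in names(genome)) {
    s <- strsplit(genome[[chrom]], "")[[1]]
    nlen <- length(s)
    for (u in seq_len(unit_max)) {
      if (nlen <= u) next
      eq <- s[seq_len(nlen - u)] == s[(u + 1L):nlen]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & (r$lengths + u) >= u * min_repeats)
      for (h in hit) {
        i <- starts[h]                     # 1-based start of tract
        tract_len <- r$lengths[h] + u
        reps <- tract_len %/% u
        if (reps < min_repeats) next
        unit <- paste(s[i:(i + u - 1L)], collapse = "")
        if (min_period(unit) != u) next    # non-primitive unit
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = chrom, start = i - 1L, end = i - 1L + reps * u,
          unit = unit, unit_length = u, repeat_count = reps)
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), unit = character(),
                                  unit_length = integer(),
                                  repeat_count = integer()))
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("chrom", "start"))
  res[]
}

min_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
        unit == paste(rep(substr(unit, 1, p), n / p), collapse = ""))
      return(p)
  }
  n
}

#' Flag indel calls overlapping microsatellite loci
#'
#' @param vset a `variant_set`.
#' @param loci microsatellite loci from [scan_microsatellites()].
#' @return the variant set with a logical `microsatellite` column (TRUE
#'   only for indels whose reference footprint overlaps a locus).
#' @export
flag_ms_indels <- function(vset, loci) {
  v <- data.table::copy(data.table::as.data.table(vset))
  if (!nrow(v)) { v[, microsatellite := logical(0)]; return(v[]) }
  v[, microsatellite := FALSE]
  idx <- which(v$vclass != "SNV")
  if (length(idx) && nrow(loci)) {
    fp <- variant_footprint(v[idx])
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(as_granges0(fp), as_granges0(loci),
                                  ignore.strand = TRUE))
    v$microsatellite[idx[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  v[]
}

#' Fraction of microsatellite loci carrying a somatic indel
#'
#' Proxy for an MSI score: the share of scanned microsatellite loci whose
#' interval overlaps at least one filtered somatic indel.
#'
#' @param vset filtered `variant_set`.
#' @param loci loci from [scan_microsatellites()].
#' @return a single numeric fraction in `[0, 1]`.
#' @export
msi_fraction <- function(vset, loci) {
  if (!nrow(loci)) return(NA_real_)
  v <- data.table::as.data.table(vset)
  ind <- v[vclass != "SNV"]
  if (!nrow(ind)) return(0)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(loci),
                                as_granges0(variant_footprint(ind)),
                                ignore.strand = TRUE))
  length(unique(S4Vectors::queryHits(ov))) / nrow(loci)
}
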