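#' Expression normalisation, peptide TPM and candidate selection
#'
#' @name quantification_selection
NULL

#' Coverage profile (bedgraph runs) from read genomic footprints
#'
#' @param reads read table with `chrom`, `start`, `end` origin columns.
#' @param genome_sizes named vector chrom -> length.
#' @return data.table chrom/start/end/depth of non-overlapping sorted
#'   runs covering each chromosome (depth 0 runs included, as with
#'   `genomecov -bga`).
#' @export
coverage_profile <- function(reads, genome_sizes) {
  gr <- as_granges0(reads[, c("chrom", "start", "end")], genome_sizes)
  cov <- GenomicRanges::coverage(gr)
  out <- list()
  for (chrom in names(genome_sizes)) {
    r <- cov[[chrom]]
    if (is.null(r)) {
      out[[chrom]] <- data.table::data.table(
        chrom = chrom, start = 0L, end = genome_sizes[[chrom]], depth = 0L)
      next
    }
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    out[[chrom]] <- data.table::data.table(
      chrom = chrom, start = as.integer(starts), end = as.integer(ends),
      depth = as.integer(S4Vectors::runValue(r)))
  }
  data.table::rbindlist(out)
}

#' Bases covered at a minimum depth, per region label
#'
#' @param profile bedgraph-style run table (chrom/start/end/depth).
#' @param tracks a `region_tracks` object.
#' @param min_depth minimum depth (default 10).
#' @return named numeric vector label -> covered bp.
#' @export
covered_bases <- function(profile, tracks, min_depth = 10L) {
  runs <- profile[profile$depth >= min_depth, ]
  labs <- names(tracks)
  out <- stats::setNames(numeric(length(labs)), labs)
  if (!nrow(runs)) return(out)
  rgr <- as_granges0(runs)
  for (lab in labs) {
    t <- tracks[[lab]]
    if (!nrow(t)) next
    out[lab] <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(rgr, as_granges0(t), ignore.strand = TRUE))))
  }
  out
}

#' MAP counts per Mb of covered sequence
#'
#' @param map_counts named vector label -> number of annotated MAPs.
#' @param covered_bp named vector label -> bases covered at >= 10x
#'   (from [covered_bases()]).
#' @return named vector label -> MAPs per Mb of covered sequence; `NA`
#'   (flagged missing) where `covered_bp` is 0 but the count is not.
#' @export
maps_per_mb <- function(map_counts, covered_bp) {
  labs <- names(map_counts)
  out <- map_counts / (covered_bp[labs] / 1e6)
  out[covered_bp[labs] == 0 & map_counts > 0] <- NA_real_
  out[covered_bp[labs] == 0 & map_counts == 0] <- 0
  out
}

#' Region-level peptide TPM
#'
#' The published region normalisation: for each region,
#' `P = (MAP-supporting reads mapped to the region * 1e3) / region
#' length in bp`, and `TPM = P / sum(P) * 1e6`, so TPM sums to one
#' million across regions.
#'
#' @param supporting_reads named vector label -> MAP-supporting read
#'   count.
#' @param region_lengths named vector label -> region length in bp
#'   (must be > 0).
#' @return named vector label -> TPM; all-`NA` when every P is zero.
#' @export
peptide_tpm <- function(supporting_reads, region_lengths) {
  labs <- names(supporting_reads)
  stopifnot(all(region_lengths[labs] > 0))
  P <- supporting_reads * 1e3 / region_lengths[labs]
  if (sum(P) == 0) return(stats::setNames(rep(NA_real_, length(labs)), labs))
  P / sum(P) * 1e6
}

#' RNA-level fold change of a MAP after in vivo growth
#'
#' Natural log fold change from pre-injection of RNA read counts + 1:
#' `ln((post + 1) / (pre + 1))`.
#'
#' @param pre_count,post_count supporting-read counts (vectorised).
#' @return numeric vector.
#' @export
map_rna_foldchange <- function(pre_count, post_count) {
  log((post_count + 1) / (pre_count + 1))
}

#' Select and pool candidate immunogenic MAPs
#'
#' Applies the candidate filters:
#' (a) present in the pre-injection RNA-seq (`pre_count > 0`);
#' (b) not found in the immunocompetent tumours — strict: zero
#' supporting reads in **all** replicates; `filter_b = "two_of_three"`
#' relaxes to lost in at least two replicates;
#' (c) generated by an atypical translational event (non-canonical).
#' Survivors are ranked by a documented composite (d): the sum of
#' z-scores of log1p pre-injection expression, of log1p MS intensity
#' where present, and of allele frequency for mutated MAPs (equal
#' weights; absent components contribute 0). The top `top_n` are kept
#' and assigned to `n_pools` pools round-robin by rank.
#'
#' @param records annotated MAP data.table with columns `peptide`,
#'   `canonical`, `pre_count`, per-replicate immunocompetent counts
#'   named `balbc*`, and optionally `ms_intensity`, `allele_frequency`,
#'   `mutation`.
#' @param n_pools number of peptide pools (default 3).
#' @param top_n candidates to retain (default 20).
#' @param filter_b `"all"` (strict, default) or `"two_of_three"`.
#' @return data.table of candidates with filter flags, `rank` and
#'   `pool`.
#' @export
select_candidates <- function(records, n_pools = 3L, top_n = 20L,
                              filter_b = c("all", "two_of_three")) {
  filter_b <- match.arg(filter_b)
  r <- data.table::copy(data.table::as.data.table(records))
  balbc_cols <- grep("^balbc", names(r), value = TRUE)
  if (!length(balbc_cols)) stop("records need balbc* count columns")
  zero_n <- Reduce(`+`, lapply(balbc_cols, function(cc)
    as.integer(r[[cc]] == 0)))
  r[, flag_a := pre_count > 0]
  r[, flag_b := if (filter_b == "all") zero_n == length(balbc_cols) else
    zero_n >= 2L]
  r[, flag_c := canonical == "Non-canonical"]
  surv <- r[flag_a & flag_b & flag_c]
  if (!nrow(surv)) return(surv[, pool := integer(0)][])
  zsafe <- function(x) {
    x <- as.numeric(x)
    present <- !is.na(x)
    z <- rep(0, length(x))
    if (sum(present) > 1 && stats::sd(x[present]) > 0)
      z[present] <- (x[present] - mean(x[present])) / stats::sd(x[present])
    z
  }
  comp <- zsafe(log1p(surv$pre_count))
  if ("ms_intensity" %in% names(surv))
    comp <- comp + zsafe(log1p(surv$ms_intensity))
  if (all(c("allele_frequency", "mutation") %in% names(surv))) {
    af <- ifelse(surv$mutation %in% c("SNV", "indel"),
                 surv$allele_frequency, NA_real_)
    comp <- comp + zsafe(af)
  }
  surv[, rank_score := comp]
  data.table::setorderv(surv, c("rank_score", "peptide"),
                        order = c(-1L, 1L))
  if (nrow(surv) < top_n)
    warning("fewer survivors (", nrow(surv), ") than top_n (", top_n, ")")
  surv <- utils::head(surv, top_n)
  surv[, rank := seq_len(.N)]
  surv[, pool := ((rank - 1L) %% n_pools) + 1L]
  surv[]
}

#' Read an annotated candidate-MAP table
#'
#' Parses a TSV of annotated candidate peptides with the columns
#' peptide, coordinates, region, n_reads, alteration, canonical,
#' percent_af, ms_replicates, ms_intensity, gene_fpkm, pool — the column
#' layout of a published candidate list bundled at
#' `system.file("extdata", "published_map_candidates.tsv",
#' package = "immunedit")`.
#'
#' @param path TSV path.
#' @return data.table of candidates.
#' @export
read_candidate_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  req <- c("peptide", "region", "pool")
  if (!all(req %in% names(dt)))
    stop("candidate table missing columns: ",
         paste(setdiff(req, names(dt)), collapse = ", "))
  dt[]
}
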