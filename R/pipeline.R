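#' Pipeline orchestration and command-line entry point
#'
#' One driver chains the stages of the workflow: `simulate` writes all
#' synthetic inputs; `regions` builds the region tracks; `tmb` filters
#' variants and reports per-region TMB and editing ratios; `build-db`
#' counts six-frame k-mers and assembles both peptide databases;
#' `match` cross-checks an observed peptide list; `annotate` back-maps
#' matched peptides; `quantify` computes coverage-normalised rates and
#' TPM; `select` ranks and pools candidates; `all` runs everything.
#' Every stage reads the previous stage's serialized outputs, so stages
#' are independently invokable.
#'
#' @name pipeline_cli
NULL

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Any key of [sim_config()] may be set, plus the analysis thresholds
#' `min_depth`, `min_alt_reads`, `min_count`, `min_diff`, `min_ratio`,
#' `merge_distance`, `coverage_min_depth`, `top_n`, `n_pools`.
#'
#' @param path config file; `NULL` gives all defaults.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(min_depth = 10L, min_alt_reads = 9L, min_count = 10,
                   min_diff = 10, min_ratio = 10, merge_distance = 5L,
                   coverage_min_depth = 10L, top_n = 20L, n_pools = 3L)
  user <- list()
  if (!is.null(path)) {
    if (grepl("\\.ya?ml$", path)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the yaml package; use JSON instead")
      user <- yaml::read_yaml(path)
    } else {
      user <- jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  utils::modifyList(defaults, as.list(user))
}

#' Run pipeline stages
#'
#' @param stage one of `simulate`, `regions`, `tmb`, `build-db`,
#'   `match`, `annotate`, `quantify`, `select`, `all`.
#' @param outdir output directory (created if absent).
#' @param config configuration list from [read_pipeline_config()] (or a
#'   path to a config file).
#' @param seed overrides the config seed when not `NULL`.
#' @return invisibly, the path of the run manifest.
#' @export
run_pipeline <- function(stage = "all", outdir = "immunedit_run",
                         config = NULL, seed = NULL) {
  stages <- c("simulate", "regions", "tmb", "build-db", "match",
              "annotate", "quantify", "select")
  if (!stage %in% c(stages, "all"))
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(c(stages, "all"), collapse = ", "))
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(read_pipeline_config(NULL),
                              as.list(if (is.null(config)) list() else
                                        config))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  todo <- if (stage == "all") stages else stage
  for (st in todo) {
    message("[immunedit] stage: ", st)
    switch(st,
           "simulate" = stage_simulate(outdir, config),
           "regions" = stage_regions(outdir, config),
           "tmb" = stage_tmb(outdir, config),
           "build-db" = stage_build_db(outdir, config),
           "match" = stage_match(outdir, config),
           "annotate" = stage_annotate(outdir, config),
           "quantify" = stage_quantify(outdir, config),
           "select" = stage_select(outdir, config))
  }
  write_manifest(outdir, config)
}

need_file <- function(path, hint) {
  if (!file.exists(path))
    stop("missing input ", path, " — run the ", hint, " stage first",
         call. = FALSE)
  path
}

sim_cfg_from <- function(config) {
  keys <- names(formals(sim_config))
  do.call(sim_config, config[intersect(names(config), keys)])
}

stage_simulate <- function(outdir, config) {
  sim <- simulate_immunoediting(sim_cfg_from(config))
  d <- file.path(outdir, "sim")
  dir.create(d, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(d, "genome.fa"))
  write_genome_sizes(sim$genome_sizes, file.path(d, "genome.sizes"))
  write_refflat(sim$models, file.path(d, "transcripts.refflat"))
  write_vcf_min(sim$variants$germline, file.path(d, "germline.vcf"))
  for (nm in names(sim$variants$samples))
    write_vcf_min(sim$variants$samples[[nm]],
                  file.path(d, paste0(nm, ".vcf")))
  for (nm in names(sim$reads$samples)) {
    write_reads_fasta(sim$reads$samples[[nm]],
                      file.path(d, paste0(nm, ".reads.fa")))
    data.table::fwrite(sim$reads$samples[[nm]],
                       file.path(d, paste0(nm, ".reads.tsv")), sep = "\t")
    data.table::fwrite(sim$reads$blocks[[nm]],
                       file.path(d, paste0(nm, ".blocks.tsv")), sep = "\t")
  }
  data.table::fwrite(sim$observed, file.path(d, "observed_peptides.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$reads$plan, file.path(d, "truth_plan.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$reads$mmrp_plan,
                     file.path(d, "truth_plan_mmrp.tsv"), sep = "\t")
  invisible(d)
}

load_tracks <- function(outdir) {
  sizes <- read_genome_sizes(need_file(
    file.path(outdir, "sim", "genome.sizes"), "simulate"))
  models <- read_refflat(file.path(outdir, "sim", "transcripts.refflat"))
  tracks_from_transcripts(models, sizes)
}

stage_regions <- function(outdir, config) {
  tracks <- load_tracks(outdir)
  d <- file.path(outdir, "regions")
  dir.create(d, showWarnings = FALSE)
  for (lab in names(tracks))
    write_bed(tracks[[lab]], file.path(d, paste0(lab, ".bed")))
  sizes <- region_sizes(tracks)
  data.table::fwrite(data.table::data.table(label = names(sizes),
                                            bp = as.integer(sizes)),
                     file.path(d, "region_sizes.tsv"), sep = "\t")
  invisible(d)
}

read_sample_vcfs <- function(outdir) {
  d <- file.path(outdir, "sim")
  out <- list()
  for (i in seq_len(nrow(SIM_SAMPLES))) {
    s <- SIM_SAMPLES[i, ]
    out[[s$sample_id]] <- read_vcf_min(
      need_file(file.path(d, paste0(s$sample_id, ".vcf")), "simulate"),
      s$sample_id, s$genotype, s$host, s$replicate)
  }
  out
}

stage_tmb <- function(outdir, config) {
  tracks <- load_tracks(outdir)
  germ <- read_vcf_min(file.path(outdir, "sim", "germline.vcf"))
  samples <- read_sample_vcfs(outdir)
  d <- file.path(outdir, "tmb")
  dir.create(d, showWarnings = FALSE)
  filt <- lapply(samples, filter_somatic, germline = germ,
                 min_depth = config$min_depth,
                 min_alt_reads = config$min_alt_reads)
  tmb <- data.table::rbindlist(lapply(names(filt), function(nm)
    cbind(sample_id = nm, tmb_by_region(filt[[nm]], tracks))))
  data.table::fwrite(tmb, file.path(d, "tmb_by_region.tsv"), sep = "\t")
  ratios <- list()
  for (geno in c("mmrp", "mmrd")) {
    pre <- tmb[sample_id == paste0(geno, "_pre")]
    posts <- grep(paste0("^", geno, "_(nod|balbc)"), unique(tmb$sample_id),
                  value = TRUE)
    for (ps in posts) {
      post <- tmb[sample_id == ps]
      ratios[[length(ratios) + 1L]] <- data.table::data.table(
        genotype = toupper(geno), sample_id = ps, label = pre$label,
        logratio = editing_logratio(pre$tmb_per_mb, post$tmb_per_mb))
    }
  }
  data.table::fwrite(data.table::rbindlist(ratios),
                     file.path(d, "editing_logratio.tsv"), sep = "\t")
  invisible(d)
}

read_sample_reads <- function(outdir) {
  d <- file.path(outdir, "sim")
  out <- list()
  for (nm in SIM_SAMPLES$sample_id)
    out[[nm]] <- data.table::fread(
      need_file(file.path(d, paste0(nm, ".reads.tsv")), "simulate"))
  out
}

#' Assemble both peptide databases from per-sample read tables
#'
#' Convenience wrapper used by the `build-db` stage and the acceptance
#' checks: counts peptides per sample and applies [build_mmrp_db()] and
#' [build_mmrd_db()].
#'
#' @param reads_by_sample named list of read tables (the naming of
#'   [simulate_reads()]: `mmrp_pre`, `mmrp_nod`, `mmrp_balbc1`,
#'   `mmrd_pre`, `mmrd_nod`, `mmrd_balbc1..3`).
#' @param min_count,min_diff,min_ratio selection thresholds.
#' @return list with `mmrp`, `mmrd` (`peptide_db`s) and `counts` (named
#'   list of per-sample count tables).
#' @export
build_dbs_from_reads <- function(reads_by_sample, min_count = 10,
                                 min_diff = 10, min_ratio = 10) {
  counts <- lapply(reads_by_sample, count_peptides)
  mmrp <- build_mmrp_db(
    list(pre = counts$mmrp_pre, nod = counts$mmrp_nod,
         balbc = counts$mmrp_balbc1), min_count = min_count)
  mmrp_tumor <- unique(c(counts$mmrp_nod$peptide,
                         counts$mmrp_balbc1$peptide))
  mmrd <- build_mmrd_db(
    list(pre = counts$mmrd_pre, nod = counts$mmrd_nod,
         balbc1 = counts$mmrd_balbc1, balbc2 = counts$mmrd_balbc2,
         balbc3 = counts$mmrd_balbc3),
    mmrp_cell_counts = counts$mmrp_pre,
    mmrp_tumor_peptides = mmrp_tumor,
    min_count = min_count, min_diff = min_diff, min_ratio = min_ratio)
  list(mmrp = mmrp, mmrd = mmrd, counts = counts)
}

stage_build_db <- function(outdir, config) {
  reads <- read_sample_reads(outdir)
  dbs <- build_dbs_from_reads(reads, min_count = config$min_count,
                              min_diff = config$min_diff,
                              min_ratio = config$min_ratio)
  d <- file.path(outdir, "db")
  dir.create(d, showWarnings = FALSE)
  write_peptide_db(dbs$mmrp, file.path(d, "mmrp_db.tsv"),
                   file.path(d, "mmrp_db.fa"))
  write_peptide_db(dbs$mmrd, file.path(d, "mmrd_db.tsv"),
                   file.path(d, "mmrd_db.fa"))
  invisible(d)
}

stage_match <- function(outdir, config) {
  obs <- data.table::fread(need_file(
    file.path(outdir, "sim", "observed_peptides.tsv"), "simulate"))
  mmrd <- data.table::fread(need_file(
    file.path(outdir, "db", "mmrd_db.tsv"), "build-db"))
  mmrp <- data.table::fread(file.path(outdir, "db", "mmrp_db.tsv"))
  m <- match_observed(obs$peptide,
                      peptide_db(mmrd, "MMRd"), peptide_db(mmrp, "MMRp"))
  d <- file.path(outdir, "match")
  dir.create(d, showWarnings = FALSE)
  for (nm in c("exclusive", "cross_checked", "unmatched"))
    writeLines(m[[nm]], file.path(d, paste0(nm, ".txt")))
  invisible(d)
}

stage_annotate <- function(outdir, config) {
  tracks <- load_tracks(outdir)
  models <- read_refflat(file.path(outdir, "sim", "transcripts.refflat"))
  genome <- read_genome_fasta(file.path(outdir, "sim", "genome.fa"))
  matched <- readLines(need_file(
    file.path(outdir, "match", "exclusive.txt"), "match"))
  reads <- data.table::fread(
    file.path(outdir, "sim", "mmrd_pre.reads.tsv"))
  germ <- read_vcf_min(file.path(outdir, "sim", "germline.vcf"))
  vset <- filter_somatic(
    read_vcf_min(file.path(outdir, "sim", "mmrd_pre.vcf")), germ,
    config$min_depth, config$min_alt_reads)
  loci <- scan_microsatellites(genome)
  vset <- flag_ms_indels(vset, loci)
  ann <- annotate_peptides(matched, reads, genome, tracks, models,
                           vset = vset,
                           merge_distance = config$merge_distance)
  ann <- uniqueness_filter(ann)
  d <- file.path(outdir, "annotate")
  dir.create(d, showWarnings = FALSE)
  data.table::fwrite(ann, file.path(d, "map_records.tsv"), sep = "\t")
  invisible(d)
}

stage_quantify <- function(outdir, config) {
  tracks <- load_tracks(outdir)
  sizes <- read_genome_sizes(file.path(outdir, "sim", "genome.sizes"))
  ann <- data.table::fread(need_file(
    file.path(outdir, "annotate", "map_records.tsv"), "annotate"))
  d <- file.path(outdir, "quantify")
  dir.create(d, showWarnings = FALSE)
  # per-sample supporting-read counts of each annotated peptide
  reads <- read_sample_reads(outdir)
  counts <- lapply(reads, count_peptides, count_mode = "reads")
  per_sample <- matrix(0L, nrow = nrow(ann), ncol = length(counts),
                       dimnames = list(NULL, paste0("n_", names(counts))))
  for (nm in names(counts)) {
    idx <- match(ann$peptide, counts[[nm]]$peptide)
    per_sample[, paste0("n_", nm)] <-
      ifelse(is.na(idx), 0L, counts[[nm]]$count[idx])
  }
  ann <- cbind(ann, data.table::as.data.table(per_sample))
  for (h in c("mmrd_balbc1", "mmrd_balbc2", "mmrd_balbc3"))
    ann[[paste0("lfc_", h)]] <- map_rna_foldchange(
      ann$n_mmrd_pre, ann[[paste0("n_", h)]])
  data.table::fwrite(ann, file.path(d, "map_quantified.tsv"), sep = "\t")
  # region-level coverage normalisation and TPM from the pre sample
  blocks <- data.table::fread(
    file.path(outdir, "sim", "mmrd_pre.blocks.tsv"))
  prof <- coverage_profile(blocks, sizes)
  write_bedgraph(prof, file.path(d, "mmrd_pre.bedgraph"))
  cov10 <- covered_bases(prof, tracks, config$coverage_min_depth)
  map_counts <- stats::setNames(rep(0, length(names(tracks))),
                                names(tracks))
  tb <- table(ann$region)
  map_counts[names(tb)] <- as.numeric(tb)
  sup <- tapply(ann$n_mmrd_pre, ann$region, sum)
  sup_reads <- stats::setNames(rep(0, length(names(tracks))),
                               names(tracks))
  sup_reads[names(sup)] <- as.numeric(sup)
  reg <- data.table::data.table(
    label = names(tracks),
    region_length_bp = as.numeric(region_sizes(tracks)),
    covered_bp_ge10 = as.numeric(cov10[names(tracks)]),
    n_maps = as.numeric(map_counts),
    maps_per_mb_covered = as.numeric(
      maps_per_mb(map_counts, cov10)[names(tracks)]),
    supporting_reads = sup_reads,
    tpm = as.numeric(peptide_tpm(sup_reads,
                                 region_sizes(tracks))[names(tracks)]))
  data.table::fwrite(reg, file.path(d, "region_expression.tsv"),
                     sep = "\t")
  invisible(d)
}

stage_select <- function(outdir, config) {
  ann <- data.table::fread(need_file(
    file.path(outdir, "quantify", "map_quantified.tsv"), "quantify"))
  obs <- data.table::fread(
    file.path(outdir, "sim", "observed_peptides.tsv"))
  ann[, ms_intensity := obs$ms_intensity[match(peptide, obs$peptide)]]
  data.table::setnames(
    ann, c("n_mmrd_pre", "n_mmrd_balbc1", "n_mmrd_balbc2",
           "n_mmrd_balbc3"),
    c("pre_count", "balbc1", "balbc2", "balbc3"))
  cand <- select_candidates(ann, n_pools = config$n_pools,
                            top_n = config$top_n)
  d <- file.path(outdir, "select")
  dir.create(d, showWarnings = FALSE)
  data.table::fwrite(cand, file.path(d, "candidates.tsv"), sep = "\t")
  invisible(d)
}

write_manifest <- function(outdir, config) {
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  manifest <- list(
    tool = "immunedit",
    version = as.character(utils::packageVersion("immunedit")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_hash = config_hash(config),
    files = as.list(stats::setNames(unname(sums),
                                    sub(paste0("^", outdir, "/?"), "",
                                        files))))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' `Rscript -e 'immunedit::immunedit_cli()' <stage> --outdir DIR
#' [--config FILE] [--seed N] [--log-level LEVEL]`, with stage one of
#' simulate/regions/tmb/build-db/match/annotate/quantify/select/all.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
immunedit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1L] else default
  }
  stage <- if (length(args) && !startsWith(args[1], "--")) args[1] else "all"
  level <- get_opt("--log-level", "info")
  run <- function() run_pipeline(
    stage = stage,
    outdir = get_opt("--outdir", "immunedit_run"),
    config = get_opt("--config"),
    seed = get_opt("--seed"))
  status <- tryCatch({
    if (level == "quiet") suppressMessages(run()) else run()
    0L
  }, error = function(e) {
    message("immunedit error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
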