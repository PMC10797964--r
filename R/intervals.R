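#' Genomic intervals and labelled region tracks
#'
#' User-facing interval tables are BED-convention data.frames with columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `strand`.
#' Internally everything is converted to 1-based `GRanges`. The helpers
#' here are deliberately thin wrappers so every module shares a single
#' coordinate convention.
#'
#' @name intervals
NULL

REGION_LABELS <- c("coding", "utr5", "utr3", "ncRNA", "intron", "extragenic")

# Priority used when a query overlaps several labels. The published rule
# orders coding > 5'UTR > 3'UTR > intronic > extragenic; ncRNA (exonic,
# hence more specific than intron) is slotted between utr3 and intron.
REGION_PRIORITY <- c("coding", "utr5", "utr3", "ncRNA", "intron", "extragenic")

#' Convert a BED-convention interval table to GRanges
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand`.
#' @param genome_sizes optional named vector of chromosome lengths used to
#'   set `seqlengths` and validate bounds.
#' @return a `GRanges` (1-based, closed).
#' @export
as_granges0 <- function(df, genome_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(df$start < 0) || any(df$end <= df$start))
      stop("invalid interval: require 0 <= start < end")
    if (any(is.na(df$chrom)) || any(!nzchar(as.character(df$chrom))))
      stop("invalid interval: empty chrom")
  }
  strand <- if ("strand" %in% names(df)) as.character(df$strand) else
    rep("*", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
  if (!is.null(genome_sizes)) {
    missing <- setdiff(unique(as.character(df$chrom)), names(genome_sizes))
    if (length(missing))
      stop("chromosome(s) absent from genome sizes: ",
           paste(missing, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(genome_sizes)
    GenomeInfoDb::seqlengths(gr) <- unname(genome_sizes)
    if (nrow(df) > 0 &&
        any(df$end > genome_sizes[as.character(df$chrom)]))
      stop("interval end beyond chromosome length")
  }
  gr
}

#' Convert GRanges back to a BED-convention data.table
#' @param gr a `GRanges`.
#' @return data.table with `chrom`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @export
as_bed_dt <- function(gr) {
  dt <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  extra <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(extra)) dt <- cbind(dt, data.table::as.data.table(extra))
  dt[]
}

#' Merge intervals within a gap distance
#'
#' Reproduces `bedtools merge -d <distance>` semantics: same-chromosome
#' intervals whose gap is `<= distance` are unioned (so bookended
#' intervals merge at `distance = 0`), strand is ignored, and each output
#' interval carries the number of inputs merged into it (`n_merged`).
#'
#' @param intervals BED-convention data.frame or `GRanges`.
#' @param distance non-negative integer gap.
#' @return data.table of merged intervals, sorted, with `n_merged`.
#' @export
merge_intervals <- function(intervals, distance = 0L) {
  if (length(distance) != 1 || is.na(distance) || distance < 0)
    stop("distance must be a single non-negative integer")
  gr <- if (inherits(intervals, "GRanges")) intervals else
    as_granges0(intervals)
  if (length(gr) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  n_merged = integer()))
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = distance + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  S4Vectors::mcols(red)$n_merged <- lengths(S4Vectors::mcols(red)$revmap)
  S4Vectors::mcols(red)$revmap <- NULL
  as_bed_dt(red)
}

#' Complement of a set of region tracks over a genome
#'
#' Returns the extragenic track: every base of every chromosome not
#' covered by any of the supplied tracks.
#'
#' @param genome_sizes named vector chrom -> length.
#' @param tracks a `region_tracks` object or list of interval tables.
#' @return data.table of complement intervals.
#' @export
complement_intervals <- function(genome_sizes, tracks) {
  grl <- lapply(tracks, function(t)
    if (inherits(t, "GRanges")) t else as_granges0(t, genome_sizes))
  genome_gr <- GenomicRanges::GRanges(
    names(genome_sizes),
    IRanges::IRanges(1L, unname(genome_sizes)))
  if (length(grl)) {
    all_gr <- GenomicRanges::reduce(do.call(c, unname(lapply(grl, function(g) {
      GenomicRanges::strand(g) <- "*"
      S4Vectors::mcols(g) <- NULL
      g
    }))), ignore.strand = TRUE)
    for (gi in seq_along(grl)) {
      bad <- GenomicRanges::end(grl[[gi]]) >
        genome_sizes[as.character(GenomeInfoDb::seqnames(grl[[gi]]))]
      if (any(bad)) stop("interval end beyond chromosome length")
    }
    comp <- GenomicRanges::setdiff(genome_gr, all_gr, ignore.strand = TRUE)
  } else {
    comp <- genome_gr
  }
  as_bed_dt(GenomicRanges::sort(comp))
}

#' Total size in bp of each region track
#' @param tracks a `region_tracks` object.
#' @return named numeric vector label -> bp.
#' @export
region_sizes <- function(tracks) {
  vapply(tracks, function(t) {
    gr <- if (inherits(t, "GRanges")) t else as_granges0(t)
    sum(as.numeric(GenomicRanges::width(gr)))
  }, numeric(1))
}

#' Build labelled region tracks from transcript models
#'
#' Derives the region partition used throughout the pipeline from a
#' refFlat-style transcript table:
#' * `coding` — exonic sequence within `[cdsStart, cdsEnd)` of coding
#'   transcripts;
#' * `utr5` / `utr3` — exonic sequence upstream/downstream of the CDS,
#'   respecting strand;
#' * `ncRNA` — exons of transcripts with `cdsEnd - cdsStart = 0`;
#' * `intron` — transcript span minus exons;
#' * `extragenic` — genome complement of the union of the above.
#'
#' Each track is merged (bookended intervals unioned) and unstranded, as
#' after a BED merge; strand is only consulted to orient the UTRs.
#'
#' @param models a `transcript_models` data.frame (see [read_refflat()]).
#' @param genome_sizes named vector chrom -> length.
#' @param include_ncrna_track keep the ncRNA track in the partition
#'   (default TRUE); if FALSE ncRNA exons fall through to intron or
#'   extragenic.
#' @return a `region_tracks` object: named list of merged interval
#'   data.tables with attribute `genome_sizes`.
#' @export
tracks_from_transcripts <- function(models, genome_sizes,
                                    include_ncrna_track = TRUE) {
  validate_transcripts(models)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  parts <- list(coding = list(), utr5 = list(), utr3 = list(),
                ncRNA = list(), intron = list())
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    ex_s <- exon_list(m$exon_starts)
    ex_e <- exon_list(m$exon_ends)
    exons <- data.table::data.table(chrom = m$chrom, start = ex_s, end = ex_e)
    # introns: span minus exons
    if (length(ex_s) > 1) {
      parts$intron[[length(parts$intron) + 1L]] <- data.table::data.table(
        chrom = m$chrom, start = ex_e[-length(ex_e)], end = ex_s[-1])
    }
    if (m$cds_end == m$cds_start) {
      parts$ncRNA[[length(parts$ncRNA) + 1L]] <- exons
      next
    }
    cds <- clip_intervals(exons, m$cds_start, m$cds_end)
    left <- clip_intervals(exons, m$tx_start, m$cds_start)
    right <- clip_intervals(exons, m$cds_end, m$tx_end)
    parts$coding[[length(parts$coding) + 1L]] <- cds
    if (m$strand == "+") {
      parts$utr5[[length(parts$utr5) + 1L]] <- left
      parts$utr3[[length(parts$utr3) + 1L]] <- right
    } else {
      parts$utr5[[length(parts$utr5) + 1L]] <- right
      parts$utr3[[length(parts$utr3) + 1L]] <- left
    }
  }
  tracks <- lapply(parts, function(p) {
    if (!length(p)) return(empty)
    merge_intervals(data.table::rbindlist(p)[end > start],
                    distance = 0L)[, c("chrom", "start", "end")]
  })
  if (!include_ncrna_track) tracks$ncRNA <- NULL
  tracks$extragenic <- complement_intervals(
    genome_sizes, tracks)[, c("chrom", "start", "end")]
  structure(tracks, genome_sizes = genome_sizes, class = "region_tracks")
}

clip_intervals <- function(dt, lo, hi) {
  out <- dt[pmin(end, hi) > pmax(start, lo)]
  if (nrow(out)) out[, `:=`(start = pmax(start, lo), end = pmin(end, hi))]
  out
}

exon_list <- function(x) {
  if (is.list(x)) x <- x[[1]]
  if (is.character(x))
    x <- as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  as.integer(x)
}

validate_transcripts <- function(models) {
  req <- c("gene_name", "tx_id", "chrom", "strand", "tx_start", "tx_end",
           "cds_start", "cds_end", "exon_starts", "exon_ends")
  if (!all(req %in% names(models)))
    stop("transcript table missing columns: ",
         paste(setdiff(req, names(models)), collapse = ", "))
  with(models, {
    if (any(!(tx_start <= cds_start & cds_start <= cds_end &
                cds_end <= tx_end)))
      stop("CDS outside transcript span")
  })
  for (i in seq_len(nrow(models))) {
    s <- exon_list(models$exon_starts[i]); e <- exon_list(models$exon_ends[i])
    if (length(s) != length(e) || any(e <= s) || is.unsorted(s, strictly = TRUE))
      stop("malformed exon lists for transcript ", models$tx_id[i])
    if (s[1] < models$tx_start[i] || e[length(e)] > models$tx_end[i])
      stop("exons outside transcript span for ", models$tx_id[i])
  }
  invisible(models)
}

#' Assign a region label to query intervals by priority
#'
#' When a query overlaps several region labels the highest-priority label
#' wins, in the order coding > utr5 > utr3 > ncRNA > intron > extragenic.
#'
#' @param query BED-convention data.frame of intervals.
#' @param tracks a `region_tracks` object.
#' @return character vector of labels, one per query row.
#' @export
assign_region <- function(query, tracks) {
  genome_sizes <- attr(tracks, "genome_sizes")
  if (!is.null(genome_sizes)) {
    missing <- setdiff(unique(as.character(query$chrom)), names(genome_sizes))
    if (length(missing))
      stop("query chromosome(s) not in genome: ",
           paste(missing, collapse = ", "))
  }
  qgr <- as_granges0(query)
  out <- rep(NA_character_, length(qgr))
  for (lab in intersect(REGION_PRIORITY, names(tracks))) {
    t <- tracks[[lab]]
    if (!nrow(t)) next
    hit <- S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(qgr, as_granges0(t),
                                  ignore.strand = TRUE)))
    out[setdiff(hit, which(!is.na(out)))] <- lab
  }
  out[is.na(out)] <- "extragenic"
  out
}

#' @export
print.region_tracks <- function(x, ...) {
  sizes <- region_sizes(x)
  cat("region_tracks:", paste(names(x), collapse = ", "), "\n")
  cat("sizes (bp):", paste(sprintf("%s=%d", names(sizes), as.integer(sizes)),
                           collapse = " "), "\n")
  invisible(x)
}
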