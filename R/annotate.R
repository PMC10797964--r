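#' Genomic back-annotation of observed peptides
#'
#' Observed peptides are traced to the reads that generated them, the
#' encoding nucleotide segment is located inside the read, placed on the
#' genome with a seed-and-extend matcher scored as
#' `match + rep_match - mismatch - q_gap_count - t_gap_count`
#' (rep_match is always 0 here: no repeat masking), best-score placements
#' are merged within 5 bp, non-unique peptides are dropped, and the
#' survivors are annotated with region label, frame status and mutation
#' status.
#'
#' @name map_annotation
NULL

#' Locate the nucleotide segment encoding a peptide inside a read
#'
#' @param peptide amino-acid sequence derived from this read and frame.
#' @param read nucleotide sequence of the read.
#' @param frame one of `+1, +2, +3, -1, -2, -3` (integer or the string
#'   form). Negative frames are on the reverse complement; the returned
#'   range is reported on the read's forward coordinates.
#' @return list with `start`, `end` (0-based half-open nt range on the
#'   forward read) and `strand` (`"+"` or `"-"` relative to the read).
#' @export
locate_peptide_in_read <- function(peptide, read, frame) {
  f <- parse_frame(frame)
  aa <- translate_frame(read, abs(f), reverse = f < 0)
  off <- as.integer(regexpr(peptide, aa, fixed = TRUE)) - 1L
  if (off < 0)
    stop("peptide not found in frame ", frame, " of read (provenance error)")
  L <- nchar(peptide)
  s <- (abs(f) - 1L) + 3L * off
  if (f > 0) {
    list(start = s, end = s + 3L * L, strand = "+")
  } else {
    n <- nchar(read)
    list(start = n - (s + 3L * L), end = n - s, strand = "-")
  }
}

parse_frame <- function(frame) {
  if (is.character(frame)) frame <- as.integer(sub("^\\+", "", frame))
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  frame
}

#' Place a nucleotide segment on the genome and keep the best score
#'
#' Seed-and-extend exact/near-exact search: seeds are `max_mismatch + 1`
#' non-overlapping slices of the query (pigeonhole: any placement with at
#' most `max_mismatch` mismatches matches one seed exactly); each seed
#' hit is extended to the full query and scored as
#' `matches - mismatches` (gap counts are zero for ungapped placements).
#' Optionally a spliced placement of two exactly-matching blocks split at
#' a codon boundary is allowed (score = query length, no gap penalty) —
#' these are only searched when no contiguous perfect hit exists. The
#' best-scoring placement is returned, ties broken deterministically by
#' chromosome name then coordinate, with the number of equal-score
#' placements recorded in `n_best`.
#'
#' @param segment query nucleotide sequence.
#' @param genome named character vector of chromosome sequences.
#' @param max_mismatch maximum mismatches for a contiguous placement
#'   (default 2).
#' @param min_score minimum acceptable score (default
#'   `0.9 * nchar(segment)`); below it, `NULL` is returned (unaligned).
#' @param allow_split allow one two-block spliced placement (default
#'   TRUE).
#' @param max_splice maximum separation of split blocks (default 10 kb).
#' @return data.table of the best placement's block(s): chrom, start,
#'   end (0-based half-open), strand, match, mismatch, q_gap_count,
#'   t_gap_count, score, n_best; or `NULL` when unaligned.
#' @export
align_and_select <- function(segment, genome, max_mismatch = 2L,
                             min_score = NULL, allow_split = TRUE,
                             max_splice = 10000L) {
  L <- nchar(segment)
  if (is.null(min_score)) min_score <- ceiling(0.9 * L)
  cand <- candidate_placements(segment, genome, max_mismatch)
  have_perfect <- nrow(cand) > 0 && max(cand$score) == L
  splits <- NULL
  if (allow_split && !have_perfect)
    splits <- split_placements(segment, genome, max_splice)
  all <- data.table::rbindlist(list(cand, splits), fill = TRUE)
  if (!nrow(all)) return(NULL)
  best <- max(all$score)
  if (best < min_score) return(NULL)
  top <- all[score == best]
  data.table::setorderv(top, c("chrom", "start"))
  aln_ids <- unique(top$aln_id)
  pick <- top[top$aln_id == aln_ids[1]]
  pick[, n_best := length(aln_ids)]
  pick[]
}

# Contiguous placements with <= max_mismatch mismatches, via pigeonhole
# seeding on exact matchPattern hits.
candidate_placements <- function(segment, genome, max_mismatch) {
  L <- nchar(segment)
  n_seed <- max_mismatch + 1L
  bounds <- unique(round(seq(0L, L, length.out = n_seed + 1L)))
  rows <- list()
  seen <- character(0)
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    clen <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") segment else revcomp_chr(segment)
      for (si in seq_len(length(bounds) - 1L)) {
        s0 <- bounds[si] + 1L; s1 <- bounds[si + 1L]
        if (s1 < s0 + 3L) next
        seed <- substr(q, s0, s1)
        hits <- Biostrings::matchPattern(seed, subject)
        for (h in seq_along(hits)) {
          gstart <- Biostrings::start(hits)[h] - (s0 - 1L)  # 1-based
          if (gstart < 1L || gstart + L - 1L > clen) next
          tag <- paste(chrom, strand, gstart)
          if (tag %in% seen) next
          seen <- c(seen, tag)
          ref <- substr(genome[[chrom]], gstart, gstart + L - 1L)
          mm <- count_mismatches(q, ref)
          if (mm > max_mismatch) next
          rows[[length(rows) + 1L]] <- data.table::data.table(
            aln_id = tag, chrom = chrom, start = gstart - 1L,
            end = gstart - 1L + L, strand = strand,
            match = L - mm, mismatch = mm,
            q_gap_count = 0L, t_gap_count = 0L, score = L - 2L * mm + mm - mm)
        }
      }
    }
  }
  if (!length(rows))
    return(data.table::data.table(aln_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), match = integer(),
                                  mismatch = integer(),
                                  q_gap_count = integer(),
                                  t_gap_count = integer(), score = integer()))
  out <- data.table::rbindlist(rows)
  out[, score := match - mismatch - q_gap_count - t_gap_count]
  out
}

count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Two-block spliced placements: both blocks exact, split at a codon
# boundary, same chromosome and strand, ordered, gap <= max_splice.
split_placements <- function(segment, genome, max_splice) {
  L <- nchar(segment)
  rows <- list()
  for (p in seq(3L, L - 3L, by = 3L)) {
    a <- substr(segment, 1L, p); b <- substr(segment, p + 1L, L)
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      for (strand in c("+", "-")) {
        qa <- if (strand == "+") a else revcomp_chr(b)
        qb <- if (strand == "+") b else revcomp_chr(a)
        ha <- Biostrings::start(Biostrings::matchPattern(qa, subject))
        hb <- Biostrings::start(Biostrings::matchPattern(qb, subject))
        if (!length(ha) || !length(hb)) next
        for (sa in ha) for (sb in hb) {
          gap <- sb - (sa + nchar(qa))
          if (gap <= 0 || gap > max_splice) next
          id <- paste(chrom, strand, sa, sb, "split")
          rows[[length(rows) + 1L]] <- data.table::data.table(
            aln_id = id, chrom = chrom,
            start = c(sa - 1L, sb - 1L),
            end = c(sa - 1L + nchar(qa), sb - 1L + nchar(qb)),
            strand = strand, match = c(nchar(qa), nchar(qb)),
            mismatch = 0L, q_gap_count = 0L, t_gap_count = 0L,
            score = L)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  data.table::rbindlist(rows)
}

#' Merge per-read placements of one peptide into loci
#'
#' Placements within `distance` bp (default 5, the published merge
#' parameter) are unioned; each merged locus carries the distinct read
#' ids and their count. Blocks belonging to one spliced alignment are
#' linked so that a two-block placement still counts as a single locus.
#'
#' @param alignments data.table of placements with columns `chrom`,
#'   `start`, `end`, `strand`, `read_id`, `aln_id`.
#' @param distance merge gap (default 5).
#' @return list with `loci` (merged data.table: chrom/start/end,
#'   `read_ids`, `n_reads`, `locus_group`) and `n_loci` (number of locus
#'   groups after split-linking).
#' @export
merge_loci <- function(alignments, distance = 5L) {
  stopifnot(nrow(alignments) > 0)
  gr <- as_granges0(alignments)
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                               min.gapwidth = distance + 1L,
                               ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  loci <- as_bed_dt(red)
  loci$revmap <- NULL
  loci$read_ids <- vapply(revmap, function(ix)
    paste(sort(unique(alignments$read_id[ix])), collapse = ","),
    character(1))
  loci$n_reads <- vapply(revmap, function(ix)
    length(unique(alignments$read_id[ix])), integer(1))
  # link merged intervals sharing a spliced alignment into locus groups
  grp <- seq_len(nrow(loci))
  for (aln in unique(alignments$aln_id)) {
    members <- which(vapply(revmap, function(ix)
      any(alignments$aln_id[ix] == aln), logical(1)))
    if (length(members) > 1) grp[members] <- min(grp[members])
  }
  loci$locus_group <- match(grp, unique(grp))
  list(loci = data.table::as.data.table(loci),
       n_loci = length(unique(grp)))
}

#' Keep only uniquely mapped peptides
#'
#' @param records list of per-peptide annotation records (each carrying
#'   `n_loci`), or a data.table with an `n_loci` column.
#' @return the records whose merged best placements form one locus.
#' @export
uniqueness_filter <- function(records) {
  if (is.data.frame(records)) return(records[records$n_loci == 1L, ])
  records[vapply(records, function(r) r$n_loci == 1L, logical(1))]
}

#' Mutation status of a peptide locus
#'
#' `indel` if any filtered indel footprint overlaps the merged loci
#' (taking precedence), else `SNV` if an SNV overlaps, else `WT`. The
#' microsatellite flag of the overlapping indel is propagated.
#'
#' @param loci merged locus data.table (chrom/start/end).
#' @param vset filtered `variant_set`, ideally after [flag_ms_indels()].
#' @return list with `status` ("WT"/"SNV"/"indel"), `microsatellite`
#'   flag and `variants` (overlapping subset).
#' @export
annotate_mutation <- function(loci, vset) {
  v <- data.table::as.data.table(vset)
  if (!nrow(v) || !nrow(loci))
    return(list(status = "WT", microsatellite = FALSE,
                variants = empty_variants()))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(variant_footprint(v)),
                                as_granges0(loci),
                                ignore.strand = TRUE))
  hit <- v[unique(S4Vectors::queryHits(ov))]
  if (!nrow(hit))
    return(list(status = "WT", microsatellite = FALSE, variants = hit))
  has_indel <- any(hit$vclass != "SNV")
  ms <- if ("microsatellite" %in% names(hit))
    any(hit$microsatellite[hit$vclass != "SNV"] %in% TRUE) else FALSE
  list(status = if (has_indel) "indel" else "SNV",
       microsatellite = has_indel && ms, variants = hit)
}

#' In-frame / out-of-frame status of a peptide locus
#'
#' A peptide is in-frame iff its first codon base lies within the CDS of
#' a canonical transcript on the same strand and its codon phase matches
#' the transcript reading frame, computed in transcript coordinates
#' (introns removed). UTR, intronic, extragenic, antisense and
#' phase-shifted placements are all out-of-frame.
#'
#' @param loci merged locus data.table (blocks of one peptide).
#' @param strand peptide strand (`"+"` or `"-"` on the genome).
#' @param models `transcript_models` table.
#' @param genome named character vector (only chromosome names used).
#' @return `"in-frame"` or `"out-of-frame"`.
#' @export
frame_status <- function(loci, strand, models, genome = NULL) {
  # genomic position (0-based) of the peptide's first codon base
  first_base <- if (strand == "+") min(loci$start) else max(loci$end) - 1L
  q_chrom <- loci$chrom[1]
  q_strand <- strand
  keep <- models$cds_end > models$cds_start & models$chrom == q_chrom &
    models$strand == q_strand
  coding <- as.data.frame(models)[keep, , drop = FALSE]
  for (i in seq_len(nrow(coding))) {
    m <- coding[i, ]
    cpos <- cds_coordinate(m, first_base)
    if (is.na(cpos)) next
    if (cpos %% 3L == 0L) return("in-frame")
  }
  "out-of-frame"
}

# CDS coordinate (0-based, transcript direction) of genomic base g, or NA
cds_coordinate <- function(m, g) {
  ex_s <- exon_list(m$exon_starts); ex_e <- exon_list(m$exon_ends)
  gpos <- unlist(lapply(seq_along(ex_s), function(i) {
    lo <- max(ex_s[i], m$cds_start); hi <- min(ex_e[i], m$cds_end)
    if (hi > lo) seq.int(lo, hi - 1L) else integer(0)
  }))
  idx <- match(g, gpos)
  if (is.na(idx)) return(NA_integer_)
  if (m$strand == "+") idx - 1L else length(gpos) - idx
}

#' Annotate matched peptides with genomic origin, region, frame and
#' mutation status
#'
#' The full back-annotation driver. For each peptide, supporting reads
#' are found (from provenance columns on the read table when
#' `use_provenance = TRUE`, otherwise by searching the six-frame
#' translations), the encoding segment is located and placed on the
#' genome, per-read best placements are merged (`-d 5`), non-uniquely
#' mapped peptides are dropped, and region label (priority rule), frame
#' status and mutation status are assigned. `canonical` is `"Canonical"`
#' iff region is coding **and** the peptide is in-frame.
#'
#' @param peptides character vector of peptide sequences.
#' @param reads read table with `read_id`, `seq` (and, for the fast
#'   provenance path, `chrom`, `start`, `end`, `strand` of the read's
#'   origin).
#' @param genome named character vector of chromosome sequences.
#' @param tracks a `region_tracks` object.
#' @param models `transcript_models` table.
#' @param vset optional filtered `variant_set` for mutation status.
#' @param use_provenance use read-origin metadata instead of the
#'   seed-and-extend matcher (default FALSE).
#' @param merge_distance locus merge gap (default 5).
#' @param ... further arguments to [align_and_select()].
#' @return data.table of `map_record`s: peptide, loci, region, frame,
#'   canonical, mutation, microsatellite, n_reads, n_loci.
#' @export
annotate_peptides <- function(peptides, reads, genome, tracks, models,
                              vset = NULL, use_provenance = FALSE,
                              merge_distance = 5L, ...) {
  support <- find_supporting_reads(peptides, reads)
  out <- list()
  for (pep in unique(peptides)) {
    sup <- support[support$peptide == pep, ]
    if (!nrow(sup)) next
    placements <- list()
    for (i in seq_len(nrow(sup))) {
      rd <- reads[match(sup$read_id[i], reads$read_id), ]
      loc <- locate_peptide_in_read(pep, rd$seq, sup$frame[i])
      if (use_provenance) {
        pl <- provenance_placement(rd, loc)
      } else {
        segment <- substr(rd$seq, loc$start + 1L, loc$end)
        pl <- align_and_select(segment, genome, ...)
        if (is.null(pl)) next
        # orient: placement strand is relative to the segment as written
        # in the read; flip if the peptide was on the read's - strand
        if (loc$strand == "-")
          pl$strand <- ifelse(pl$strand == "+", "-", "+")
      }
      pl$read_id <- rd$read_id
      if (!"aln_id" %in% names(pl))
        pl$aln_id <- paste(rd$read_id, pl$chrom[1], pl$start[1])
      placements[[length(placements) + 1L]] <- pl
    }
    if (!length(placements)) next
    aln <- data.table::rbindlist(placements, fill = TRUE)
    ml <- merge_loci(aln, distance = merge_distance)
    pep_strand <- names(sort(table(aln$strand), decreasing = TRUE))[1]
    region <- region_of_loci(ml$loci, tracks)
    frame <- frame_status(ml$loci, pep_strand, models)
    mut <- if (is.null(vset))
      list(status = "WT", microsatellite = FALSE) else
        annotate_mutation(ml$loci, vset)
    out[[length(out) + 1L]] <- data.table::data.table(
      peptide = pep,
      loci = paste(sprintf("%s:%d-%d", ml$loci$chrom, ml$loci$start,
                           ml$loci$end), collapse = " "),
      chrom = ml$loci$chrom[1],
      start = min(ml$loci$start), end = max(ml$loci$end),
      strand = pep_strand, region = region, frame = frame,
      canonical = if (region == "coding" && frame == "in-frame")
        "Canonical" else "Non-canonical",
      mutation = mut$status, microsatellite = mut$microsatellite,
      n_reads = length(unique(aln$read_id)), n_loci = ml$n_loci)
  }
  if (!length(out))
    return(data.table::data.table(peptide = character(), loci = character(),
                                  chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  region = character(), frame = character(),
                                  canonical = character(),
                                  mutation = character(),
                                  microsatellite = logical(),
                                  n_reads = integer(), n_loci = integer()))
  data.table::rbindlist(out)
}

region_of_loci <- function(loci, tracks) {
  labs <- assign_region(loci, tracks)
  intersect(REGION_PRIORITY, labs)[1]
}

provenance_placement <- function(rd, loc) {
  # read origin is a contiguous genomic window [start, end) on `strand`;
  # map the nt sub-interval of the read onto it
  if (rd$strand == "+") {
    s <- rd$start + loc$start
    e <- rd$start + loc$end
    pl_strand <- loc$strand
  } else {
    s <- rd$end - loc$end
    e <- rd$end - loc$start
    pl_strand <- ifelse(loc$strand == "+", "-", "+")
  }
  data.table::data.table(chrom = rd$chrom, start = s, end = e,
                         strand = pl_strand, match = loc$end - loc$start,
                         mismatch = 0L, q_gap_count = 0L, t_gap_count = 0L,
                         score = loc$end - loc$start)
}

#' Find the reads and frames supporting each peptide
#'
#' Searches the six-frame translations of every read for exact
#' occurrences of the given peptides.
#'
#' @param peptides character vector of peptides.
#' @param reads read table with `read_id`, `seq`.
#' @return data.table `peptide`, `read_id`, `frame` (+1..+3/-1..-3 as
#'   integers, negative = reverse strand of the read).
#' @export
find_supporting_reads <- function(peptides, reads) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  aa_by_frame <- lapply(frames, function(f)
    translate_frame(reads$seq, abs(f), reverse = f < 0))
  out <- list()
  for (pep in unique(peptides)) {
    for (fi in seq_along(frames)) {
      hit <- grepl(pep, aa_by_frame[[fi]], fixed = TRUE)
      if (any(hit))
        out[[length(out) + 1L]] <- data.table::data.table(
          peptide = pep, read_id = reads$read_id[hit],
          frame = frames[fi])
    }
  }
  if (!length(out))
    return(data.table::data.table(peptide = character(),
                                  read_id = character(), frame = integer()))
  data.table::rbindlist(out)
}
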