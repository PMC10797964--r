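#' Six-frame k-mer peptide databases
#'
#' RNA-seq reads are translated in all six reading frames; maximal
#' stop-free (and N-free) stretches are cut into 8-11-mer peptides and
#' counted per sample. Genotype-specific databases are then assembled
#' with the differential selection formulas: a peptide enters the MMRd
#' database when it is well supported before injection and in the
#' immunocompromised host, lost or strongly counter-selected in at least
#' one immunocompetent tumour, and absent from the MMRp arm.
#'
#' @name peptide_db
NULL

FRAME_NAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Translate a character vector of reads in one frame (1, 2 or 3) of the
# given strand, returning the raw amino-acid strings (stops as '*',
# untranslatable codons as 'X').
translate_frame <- function(seqs, frame, reverse = FALSE) {
  dna <- Biostrings::DNAStringSet(seqs)
  if (reverse) dna <- Biostrings::reverseComplement(dna)
  w <- Biostrings::width(dna)
  keep_len <- pmax(((w - frame + 1L) %/% 3L) * 3L, 0L)
  res <- character(length(seqs))
  ok <- keep_len >= 3L
  if (any(ok)) {
    sub <- Biostrings::subseq(dna[ok], start = frame,
                              width = keep_len[ok])
    res[ok] <- as.character(
      suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                             no.init.codon = TRUE)))
  }
  res
}

#' Six-frame translation of a read into stop-free fragments
#'
#' Translates the read in frames +1..+3 and, on the reverse complement,
#' -1..-3 with the standard genetic code. Fragments are the maximal
#' stretches free of stop codons; codons containing N are untranslatable
#' and also split fragments.
#'
#' @param seq a single nucleotide sequence (A/C/G/T/N).
#' @return named list of six character vectors of peptide fragments.
#' @export
six_frame_translate <- function(seq) {
  stopifnot(length(seq) == 1L)
  out <- vector("list", 6L)
  names(out) <- FRAME_NAMES
  for (f in 1:3) {
    out[[f]] <- split_fragments(translate_frame(seq, f, FALSE))
    out[[f + 3L]] <- split_fragments(translate_frame(seq, f, TRUE))
  }
  out
}

split_fragments <- function(aa) {
  if (!length(aa) || !nzchar(aa)) return(character(0))
  frags <- unlist(strsplit(aa, "[*X]+"))
  frags[nzchar(frags)]
}

#' Cut peptide fragments into 8-11-mers
#'
#' Returns every substring of length `k` for each `k` in
#' `[k_min, k_max]` from every fragment, as a multiset (duplicates kept:
#' the count of a peptide is its number of generating
#' (fragment, offset, k) occurrences).
#'
#' @param fragments character vector of amino-acid fragments.
#' @param k_min,k_max k-mer length bounds (defaults 8 and 11).
#' @return character vector of peptides (multiset).
#' @export
kmerize <- function(fragments, k_min = 8L, k_max = 11L) {
  stopifnot(k_min <= k_max, k_min >= 1L)
  fragments <- fragments[nchar(fragments) >= k_min]
  if (!length(fragments)) return(character(0))
  out <- vector("list", k_max - k_min + 1L)
  for (ki in seq_along(out)) {
    k <- k_min + ki - 1L
    nk <- nchar(fragments) - k + 1L
    use <- nk > 0L
    if (!any(use)) next
    starts <- sequence(nk[use])
    out[[ki]] <- substring(rep(fragments[use], nk[use]), starts,
                           starts + k - 1L)
  }
  unlist(out, use.names = FALSE)
}

#' Count 8-11-mer peptides across a sample's reads
#'
#' Vectorised six-frame translation + k-merisation of a whole read table.
#' By default the counting unit is occurrences (read x frame x offset x
#' k); `count_mode = "reads"` collapses to the number of distinct reads
#' supporting each peptide.
#'
#' @param reads data.table with a `seq` column (and `read_id` when
#'   `count_mode = "reads"`).
#' @param k_min,k_max k-mer length bounds.
#' @param count_mode `"occurrences"` (default) or `"reads"`.
#' @return data.table `peptide`, `count`, keyed by peptide.
#' @export
count_peptides <- function(reads, k_min = 8L, k_max = 11L,
                           count_mode = c("occurrences", "reads")) {
  count_mode <- match.arg(count_mode)
  if (!nrow(reads))
    return(data.table::data.table(peptide = character(), count = integer(),
                                  key = "peptide"))
  pieces <- list()
  for (f in 1:3) for (rev in c(FALSE, TRUE)) {
    aa <- translate_frame(reads$seq, f, rev)
    frag_by_read <- strsplit(aa, "[*X]+")
    nfrag <- lengths(frag_by_read)
    frags <- unlist(frag_by_read, use.names = FALSE)
    keep <- nchar(frags) >= k_min
    if (!any(keep)) next
    if (count_mode == "reads") {
      ridx <- rep(seq_len(nrow(reads)), nfrag)[keep]
      frags <- frags[keep]
      for (k in k_min:k_max) {
        nk <- pmax(nchar(frags) - k + 1L, 0L)
        use <- nk > 0L
        if (!any(use)) next
        starts <- sequence(nk[use])
        pieces[[length(pieces) + 1L]] <- data.table::data.table(
          peptide = substring(rep(frags[use], nk[use]), starts,
                              starts + k - 1L),
          read = rep(ridx[use], nk[use]))
      }
    } else {
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        peptide = kmerize(frags[keep], k_min, k_max))
    }
  }
  if (!length(pieces))
    return(data.table::data.table(peptide = character(), count = integer(),
                                  key = "peptide"))
  all <- data.table::rbindlist(pieces)
  out <- if (count_mode == "reads")
    unique(all)[, .(count = .N), by = peptide] else
      all[, .(count = .N), by = peptide]
  data.table::setkeyv(out, "peptide")
  out[]
}

total_kmers <- function(len, k_min, k_max) {
  ks <- k_min:k_max
  vapply(len, function(L) sum(pmax(L - ks + 1L, 0L)), integer(1))
}

#' Lost-or-counter-selected test for one immunocompetent replicate
#'
#' The printed selection rule: a peptide is lost or strongly
#' counter-selected in a BALB/c tumour when
#' `counts_balbc == 0` **or**
#' (`counts_pre - counts_balbc >= min_diff` **and**
#'  `counts_pre / counts_balbc >= min_ratio`).
#'
#' @param counts_pre pre-selected (pre-injection) counts.
#' @param counts_balbc counts in the immunocompetent tumour.
#' @param min_diff,min_ratio thresholds (defaults 10 and 10).
#' @return logical vector.
#' @export
lost_or_counterselected <- function(counts_pre, counts_balbc,
                                    min_diff = 10, min_ratio = 10) {
  counts_balbc == 0 |
    (counts_pre - counts_balbc >= min_diff &
       counts_pre / counts_balbc >= min_ratio)
}

#' Strong-expansion test of MMRd vs MMRp counts
#'
#' `counts_mmrd - counts_mmrp >= min_diff` and
#' `counts_mmrd / counts_mmrp >= min_ratio`. The `zero_division`
#' argument controls the ratio when `counts_mmrp == 0`: `"inf"`
#' (default) treats it as +Inf so the test can pass on absent MMRp
#' counts; `"false"` treats the ratio condition as unmet (used inside
#' [build_mmrd_db()], where absence from MMRp is handled by the
#' presence-exclusion clause — see the methods vignette).
#'
#' @param counts_mmrd,counts_mmrp k-mer counts in the two genotypes.
#' @param min_diff,min_ratio thresholds (defaults 10 and 10).
#' @param zero_division `"inf"` or `"false"`.
#' @return logical vector.
#' @export
expanded_in_mmrd <- function(counts_mmrd, counts_mmrp,
                             min_diff = 10, min_ratio = 10,
                             zero_division = c("inf", "false")) {
  zero_division <- match.arg(zero_division)
  ratio <- ifelse(counts_mmrp == 0,
                  if (zero_division == "inf") Inf else NA_real_,
                  counts_mmrd / counts_mmrp)
  ratio_ok <- !is.na(ratio) & ratio >= min_ratio
  counts_mmrd - counts_mmrp >= min_diff & ratio_ok
}

assemble_counts <- function(count_tables) {
  # named list of data.tables (peptide, count) -> wide table of counts
  stopifnot(length(count_tables) >= 1, !is.null(names(count_tables)))
  peps <- unique(unlist(lapply(count_tables, `[[`, "peptide")))
  wide <- data.table::data.table(peptide = peps, key = "peptide")
  for (nm in names(count_tables)) {
    tb <- count_tables[[nm]]
    wide[, (nm) := 0L]
    if (nrow(tb)) wide[tb$peptide, (nm) := tb$count]
  }
  wide[]
}

#' Build the MMR-proficient peptide database
#'
#' Selects k-mers with at least `min_count` occurrences both at the time
#' of injection and after excision from the immunocompromised host, that
#' disappeared (count 0, strict) in the immunocompetent tumour. Set
#' `disappeared = "counterselected"` to reuse the MMRd
#' loss/counter-selection formula instead of strict zero.
#'
#' @param counts wide count table with columns `peptide`, `pre`, `nod`,
#'   `balbc`, or a named list of per-sample count tables with those
#'   names.
#' @param min_count retention floor (default 10).
#' @param disappeared `"zero"` (default) or `"counterselected"`.
#' @param min_diff,min_ratio thresholds for the counter-selection option.
#' @return a `peptide_db` object.
#' @export
build_mmrp_db <- function(counts, min_count = 10,
                          disappeared = c("zero", "counterselected"),
                          min_diff = 10, min_ratio = 10) {
  disappeared <- match.arg(disappeared)
  if (is.list(counts) && !is.data.frame(counts))
    counts <- assemble_counts(counts)
  need <- c("peptide", "pre", "nod", "balbc")
  if (!all(need %in% names(counts)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  gone <- if (disappeared == "zero") counts$balbc == 0 else
    lost_or_counterselected(counts$pre, counts$balbc, min_diff, min_ratio)
  sel <- counts$pre >= min_count & counts$nod >= min_count & gone
  peptide_db(counts[sel], genotype = "MMRp",
             params = list(min_count = min_count, disappeared = disappeared))
}

#' Build the MMR-deficient peptide database
#'
#' Assembly of the MMRd-specific database:
#' 1. keep k-mers with `pre >= min_count` and `nod >= min_count`
#'    occurrences in the MMRd arm;
#' 2. require [lost_or_counterselected()] in at least `n_lost_required`
#'    of the immunocompetent (BALB/c) replicates;
#' 3. exclude peptides found in MMRp tumours (either host);
#' 4. exclude peptides present in MMRp cells
#'    (count > `mmrp_presence_threshold`);
#' 5. exclude peptides strongly expanded in MMRd relative to MMRp cells
#'    ([expanded_in_mmrd()] with `zero_division = "false"`, so MMRd
#'    exclusive peptides — MMRp count 0 — are not discarded by the ratio
#'    test).
#'
#' @param counts_mmrd wide table (or named list of count tables) with
#'   columns `peptide`, `pre`, `nod` and one `balbc*` column per
#'   immunocompetent replicate.
#' @param mmrp_cell_counts count table (peptide/count) of MMRp
#'   pre-injection cells.
#' @param mmrp_tumor_peptides character vector of peptides seen in MMRp
#'   tumours (BALB/c and NOD-SCID pooled).
#' @param min_count retention floor (default 10).
#' @param n_lost_required replicates in which loss is required (default
#'   1, "at least one").
#' @param min_diff,min_ratio formula thresholds (defaults 10/10).
#' @param mmrp_presence_threshold count above which a peptide counts as
#'   present in MMRp cells (default 0, i.e. any occurrence).
#' @param expansion_zero_division passed to [expanded_in_mmrd()]
#'   (default `"false"`; see that help page).
#' @return a `peptide_db` object.
#' @export
build_mmrd_db <- function(counts_mmrd, mmrp_cell_counts = NULL,
                          mmrp_tumor_peptides = character(),
                          min_count = 10, n_lost_required = 1L,
                          min_diff = 10, min_ratio = 10,
                          mmrp_presence_threshold = 0,
                          expansion_zero_division = c("false", "inf")) {
  expansion_zero_division <- match.arg(expansion_zero_division)
  if (is.list(counts_mmrd) && !is.data.frame(counts_mmrd))
    counts_mmrd <- assemble_counts(counts_mmrd)
  balbc_cols <- grep("^balbc", names(counts_mmrd), value = TRUE)
  if (length(balbc_cols) < 1L)
    stop("need at least one balbc* replicate column")
  if (!all(c("peptide", "pre", "nod") %in% names(counts_mmrd)))
    stop("count table must have peptide, pre and nod columns")
  dt <- data.table::as.data.table(counts_mmrd)
  sel <- dt$pre >= min_count & dt$nod >= min_count
  lost_n <- Reduce(`+`, lapply(balbc_cols, function(cc)
    as.integer(lost_or_counterselected(dt$pre, dt[[cc]],
                                       min_diff, min_ratio))))
  sel <- sel & lost_n >= n_lost_required
  cross_log <- dt$peptide[sel & dt$peptide %in% mmrp_tumor_peptides]
  sel <- sel & !(dt$peptide %in% mmrp_tumor_peptides)
  mmrp_n <- rep(0L, nrow(dt))
  if (!is.null(mmrp_cell_counts) && nrow(mmrp_cell_counts)) {
    m <- match(dt$peptide, mmrp_cell_counts$peptide)
    mmrp_n[!is.na(m)] <- mmrp_cell_counts$count[m[!is.na(m)]]
  }
  sel <- sel & mmrp_n <= mmrp_presence_threshold
  sel <- sel & !expanded_in_mmrd(dt$pre, mmrp_n, min_diff, min_ratio,
                                 zero_division = expansion_zero_division)
  out <- dt[sel]
  # hard invariant: the MMRd database never intersects the MMRp cell set
  if (!is.null(mmrp_cell_counts)) {
    present <- mmrp_cell_counts$peptide[
      mmrp_cell_counts$count > mmrp_presence_threshold]
    stopifnot(!any(out$peptide %in% present))
  }
  peptide_db(out, genotype = "MMRd",
             params = list(min_count = min_count,
                           n_lost_required = n_lost_required,
                           min_diff = min_diff, min_ratio = min_ratio,
                           mmrp_presence_threshold = mmrp_presence_threshold,
                           excluded_in_cross_check = length(cross_log)))
}

#' Construct a peptide database object
#' @param entries data.table with a `peptide` column plus per-sample
#'   counts.
#' @param genotype database label.
#' @param params build metadata.
#' @return a `peptide_db`.
#' @export
peptide_db <- function(entries, genotype, params = list()) {
  structure(list(genotype = genotype,
                 entries = data.table::as.data.table(entries),
                 params = params),
            class = "peptide_db")
}

#' @export
print.peptide_db <- function(x, ...) {
  cat(sprintf("peptide_db [%s]: %d peptides\n", x$genotype,
              nrow(x$entries)))
  invisible(x)
}

#' @export
length.peptide_db <- function(x) nrow(x$entries)

#' Match observed (eluted) peptides against the custom databases
#'
#' Exact-string lookup of an observed peptide list against the genotype's
#' own database; peptides also present in the other genotype's database
#' are logged and removed from the exclusive set (the cross-check rule).
#' Peptides with residues outside the 20-letter alphabet are skipped
#' with a warning.
#'
#' @param observed character vector of observed peptide sequences.
#' @param db_self `peptide_db` of the sample's genotype.
#' @param db_other `peptide_db` of the other genotype.
#' @return list with `exclusive`, `cross_checked`, `unmatched`,
#'   `invalid` character vectors.
#' @export
match_observed <- function(observed, db_self, db_other = NULL) {
  ok <- grepl(paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$"),
              observed)
  if (any(!ok))
    warning(sum(!ok), " observed peptide(s) with invalid residues skipped")
  obs <- unique(observed[ok])
  in_self <- obs %in% db_self$entries$peptide
  in_other <- if (is.null(db_other)) rep(FALSE, length(obs)) else
    obs %in% db_other$entries$peptide
  list(exclusive = obs[in_self & !in_other],
       cross_checked = obs[in_self & in_other],
       unmatched = obs[!in_self],
       invalid = unique(observed[!ok]))
}

#' Write a peptide database as TSV and FASTA
#' @param db a `peptide_db`.
#' @param tsv_path,fasta_path output paths (either may be NULL).
#' @export
write_peptide_db <- function(db, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path))
    data.table::fwrite(db$entries, tsv_path, sep = "\t")
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(db$entries$peptide)
    names(aa) <- sprintf("%s_pep%06d", db$genotype,
                         seq_len(nrow(db$entries)))
    Biostrings::writeXStringSet(aa, fasta_path)
  }
  invisible(db)
}
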