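test_that("six_frame_translate matches hand-worked examples", {
  expect_equal(six_frame_translate("ATGAAA")[["+1"]], "MK")
  # revcomp of ATGAAAGGG is CCCTTTCAT -> PFH in frame -1
  expect_equal(six_frame_translate("ATGAAAGGG")[["-1"]], "PFH")
  # stop codons split fragments
  expect_equal(six_frame_translate("ATGTAAATG")[["+1"]], c("M", "M"))
  # codons containing N are dropped and split fragments
  expect_equal(six_frame_translate("ATGANAATG")[["+1"]], c("M", "M"))
})

test_that("six-frame translation of the revcomp swaps +/- frames", {
  set.seed(5)
  for (i in 1:20) {
    r <- random_read(sample(30:80, 1))
    a <- six_frame_translate(r)
    b <- six_frame_translate(oracle_revcomp(r))
    # frame sets swap as multisets of fragments
    expect_equal(sort(unname(unlist(a[1:3]))), sort(unname(unlist(b[4:6]))))
    expect_equal(sort(unname(unlist(a[4:6]))), sort(unname(unlist(b[1:3]))))
  }
})

test_that("kmerize counts substrings for every k in 8..11", {
  expect_length(kmerize(strrep("A", 11)), 10)  # 4+3+2+1
  expect_length(kmerize(strrep("A", 7)), 0)
  expect_length(kmerize(strrep("A", 8)), 1)
  expect_error(kmerize("AAAA", k_min = 9, k_max = 8))
})

test_that("count_peptides equals the naive enumeration oracle on 100 reads", {
  set.seed(101)
  reads <- data.table::data.table(
    read_id = sprintf("r%03d", 1:100),
    seq = vapply(1:100, function(i) random_read(sample(24:90, 1)),
                 character(1)))
  got <- count_peptides(reads)
  oracle <- table(unlist(lapply(reads$seq, oracle_kmers)))
  expect_equal(nrow(got), length(oracle))
  expect_equal(got$count[match(names(oracle), got$peptide)],
               as.integer(oracle))
})

test_that("count_mode = reads collapses to distinct supporting reads", {
  reads <- data.table::data.table(
    read_id = c("a", "b"),
    seq = rep("GCTGCTGCTGCTGCTGCTGCTGCTGCT", 2))  # AAAAAAAAA repeats of Ala
  occ <- count_peptides(reads)
  byread <- count_peptides(reads, count_mode = "reads")
  expect_true(all(byread$count <= occ$count))
  expect_true(all(byread$count <= 2))
  # the 8-mer "AAAAAAAA" is supported by both reads
  expect_equal(byread[byread$peptide == "AAAAAAAA", ]$count, 2L)
})

test_that("lost_or_counterselected reproduces the printed truth table", {
  # (pre, balbc) -> expected
  cases <- rbind(
    c(10, 0, TRUE),    # lost outright
    c(0, 0, TRUE),     # zero counts still "lost" by the first disjunct
    c(50, 4, TRUE),    # diff 46 >= 10 and ratio 12.5 >= 10
    c(50, 10, FALSE),  # diff 40 but ratio 5 < 10
    c(19, 1, TRUE),    # diff 18 and ratio 19
    c(11, 1, TRUE),    # diff 10 boundary, ratio 11
    c(10, 1, FALSE),   # diff 9 < 10
    c(100, 10, TRUE))  # diff 90, ratio 10 boundary
  got <- lost_or_counterselected(cases[, 1], cases[, 2])
  expect_equal(got, as.logical(cases[, 3]))
})

test_that("expanded_in_mmrd reproduces the printed formula with both zero conventions", {
  expect_true(expanded_in_mmrd(30, 2))     # diff 28, ratio 15
  expect_false(expanded_in_mmrd(30, 20))   # ratio 1.5
  expect_true(expanded_in_mmrd(10, 0))     # diff 10, ratio Inf (default)
  expect_false(expanded_in_mmrd(10, 0, zero_division = "false"))
  expect_true(expanded_in_mmrd(20, 2))     # boundary diff 18, ratio 10
  expect_false(expanded_in_mmrd(11, 2))    # diff 9
})

test_that("build_mmrp_db selects on the retention floor and disappearance", {
  counts <- data.table::data.table(
    peptide = c("P1", "P2", "P3", "P4"),
    pre = c(10, 9, 50, 50), nod = c(10, 50, 50, 50),
    balbc = c(0, 0, 1, 0))
  db <- build_mmrp_db(counts)
  expect_setequal(db$entries$peptide, c("P1", "P4"))
  # counter-selection variant admits strong depletion
  db2 <- build_mmrp_db(counts, disappeared = "counterselected")
  expect_true("P3" %in% db2$entries$peptide)
})

test_that("build_mmrd_db implements the full assembly with exclusions", {
  counts <- data.table::data.table(
    peptide = c("keep", "lowpre", "notlost", "inMMRpTumor", "inMMRpCells"),
    pre = c(20, 5, 20, 20, 20), nod = c(20, 20, 20, 20, 20),
    balbc1 = c(0, 0, 15, 0, 0), balbc2 = c(15, 15, 15, 15, 15),
    balbc3 = c(15, 15, 15, 15, 15))
  mmrp_cells <- data.table::data.table(peptide = "inMMRpCells", count = 3L)
  db <- build_mmrd_db(counts, mmrp_cell_counts = mmrp_cells,
                      mmrp_tumor_peptides = "inMMRpTumor")
  expect_equal(db$entries$peptide, "keep")
  expect_error(build_mmrd_db(counts[, c("peptide", "pre", "nod")]),
               "balbc")
})

test_that("raising the count floor never grows either database", {
  dbs <- shared_dbs()
  counts <- dbs$counts
  n10 <- length(dbs$mmrd)
  mmrp_tumor <- unique(c(counts$mmrp_nod$peptide,
                         counts$mmrp_balbc1$peptide))
  for (floor in c(11, 12, 20)) {
    d <- build_mmrd_db(
      list(pre = counts$mmrd_pre, nod = counts$mmrd_nod,
           balbc1 = counts$mmrd_balbc1, balbc2 = counts$mmrd_balbc2,
           balbc3 = counts$mmrd_balbc3),
      mmrp_cell_counts = counts$mmrp_pre,
      mmrp_tumor_peptides = mmrp_tumor, min_count = floor)
    expect_lte(length(d), n10)
    p <- build_mmrp_db(list(pre = counts$mmrp_pre, nod = counts$mmrp_nod,
                            balbc = counts$mmrp_balbc1),
                       min_count = floor)
    expect_lte(length(p), length(dbs$mmrp))
  }
})

test_that("the MMRd database never intersects the MMRp cell peptides", {
  dbs <- shared_dbs()
  mmrp_cells <- dbs$counts$mmrp_pre$peptide
  expect_length(intersect(dbs$mmrd$entries$peptide, mmrp_cells), 0)
})

test_that("match_observed separates exclusive, cross-checked and unmatched", {
  db_self <- peptide_db(data.table::data.table(peptide = c("AAAAAAAA",
                                                           "CCCCCCCC")),
                        "MMRd")
  db_other <- peptide_db(data.table::data.table(peptide = "CCCCCCCC"),
                         "MMRp")
  expect_warning(
    m <- match_observed(c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD", "AAAAAAB1"),
                        db_self, db_other),
    "invalid")
  expect_equal(m$exclusive, "AAAAAAAA")
  expect_equal(m$cross_checked, "CCCCCCCC")
  expect_equal(m$unmatched, "DDDDDDDD")
  expect_equal(m$invalid, "AAAAAAB1")
})

test_that("peptide databases serialize to TSV and FASTA", {
  db <- peptide_db(data.table::data.table(peptide = c("ACDEFGHI",
                                                      "KLMNPQRS"),
                                          pre = c(12L, 15L)), "MMRd")
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  write_peptide_db(db, tsv, fa)
  expect_equal(data.table::fread(tsv)$peptide, db$entries$peptide)
  expect_equal(as.character(Biostrings::readAAStringSet(fa)),
               stats::setNames(db$entries$peptide,
                               names(Biostrings::readAAStringSet(fa))))
})
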