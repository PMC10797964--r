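test_that("merge_intervals follows bedtools -d semantics with counts", {
  dt <- data.table::data.table(chrom = c("chr1", "chr1"),
                               start = c(10L, 23L), end = c(20L, 30L))
  m5 <- merge_intervals(dt, distance = 5)
  expect_equal(m5$start, 10L)
  expect_equal(m5$end, 30L)
  expect_equal(m5$n_merged, 2L)

  m0 <- merge_intervals(dt, distance = 0)
  expect_equal(nrow(m0), 2L)

  # bookended intervals merge at distance 0
  book <- data.table::data.table(chrom = "chr1", start = c(10L, 20L),
                                 end = c(20L, 30L))
  expect_equal(nrow(merge_intervals(book, 0)), 1L)

  expect_equal(nrow(merge_intervals(dt[0], 5)), 0L)
  expect_error(merge_intervals(dt, -1), "non-negative")
})

test_that("merge_intervals is idempotent", {
  set.seed(42)
  for (d in c(0L, 3L, 10L)) {
    dt <- data.table::data.table(
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = sample(0:500, 40))
    dt$end <- dt$start + sample(1:30, 40, replace = TRUE)
    once <- merge_intervals(dt, d)
    twice <- merge_intervals(once, d)
    expect_equal(twice[, c("chrom", "start", "end")],
                 once[, c("chrom", "start", "end")])
  }
})

test_that("complement tiles the genome and inverts itself", {
  gs <- c(chr1 = 100L)
  tracks <- list(a = data.table::data.table(
    chrom = "chr1", start = c(0L, 60L), end = c(40L, 100L)))
  comp <- complement_intervals(gs, tracks)
  expect_equal(comp$start, 40L)
  expect_equal(comp$end, 60L)

  expect_equal(nrow(complement_intervals(
    gs, list(a = data.table::data.table(chrom = "chr1", start = 0L,
                                        end = 100L)))), 0L)
  full <- complement_intervals(gs, list())
  expect_equal(full$end - full$start, 100L)

  # complement of the complement returns the merged input
  back <- complement_intervals(gs, list(comp))
  expect_equal(back[, c("start", "end")],
               merge_intervals(tracks$a, 0)[, c("start", "end")])

  expect_error(suppressWarnings(complement_intervals(
    gs, list(a = data.table::data.table(chrom = "chr1", start = 0L,
                                        end = 150L)))))
})

test_that("tracks_from_transcripts derives UTRs, CDS, introns, ncRNA", {
  gs <- c(chr1 = 400L, chr2 = 200L)
  tr <- tracks_from_transcripts(toy_models(), gs)
  # + strand: utr5 left of CDS
  expect_true(any(tr$utr5$start == 0 & tr$utr5$end == 20))
  expect_true(any(tr$coding$start == 20 & tr$coding$end == 80))
  expect_true(any(tr$utr3$start == 80 & tr$utr3$end == 100))
  # - strand transcript: sides flip
  expect_true(any(tr$utr5$start == 280 & tr$utr5$end == 300))
  expect_true(any(tr$utr3$start == 200 & tr$utr3$end == 220))
  # cdsStart == cdsEnd => ncRNA exons
  expect_equal(tr$ncRNA, data.table::data.table(
    chrom = "chr2", start = 0L, end = 120L))
  # partition covers the genome exactly
  expect_equal(sum(region_sizes(tr)), sum(gs))

  bad <- toy_models()
  bad$cds_end[1] <- 150L
  expect_error(tracks_from_transcripts(bad, gs), "CDS outside")
})

test_that("introns come from the transcript span minus exons", {
  gs <- c(chr1 = 1000L)
  m <- data.table::data.table(
    gene_name = "g", tx_id = "t", chrom = "chr1", strand = "+",
    tx_start = 0L, tx_end = 300L, cds_start = 10L, cds_end = 280L,
    exon_starts = "0,100,", exon_ends = "50,300,")
  tr <- tracks_from_transcripts(m, gs)
  expect_equal(tr$intron, data.table::data.table(
    chrom = "chr1", start = 50L, end = 100L))
})

test_that("assign_region applies the priority order", {
  gs <- c(chr1 = 400L, chr2 = 200L)
  tr <- tracks_from_transcripts(toy_models(), gs)
  q <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(75L, 310L, 75L), end = c(85L, 320L, 82L))
  # overlaps coding and utr3 -> coding wins
  expect_equal(assign_region(q[1], tr), "coding")
  # no annotation -> extragenic
  expect_equal(assign_region(q[2], tr), "extragenic")
  expect_error(assign_region(
    data.table::data.table(chrom = "chrZ", start = 1L, end = 2L), tr),
    "not in genome")
})

test_that("assign_region matches a per-base priority oracle on a random fixture", {
  set.seed(11)
  gs <- c(chrR = 10000L)
  mk <- function(n) {
    s <- sort(sample(0:9900, n))
    data.table::data.table(chrom = "chrR", start = s,
                           end = s + sample(20:120, n, replace = TRUE))
  }
  tracks <- structure(list(coding = mk(8), utr5 = mk(6), utr3 = mk(6),
                           ncRNA = mk(4), intron = mk(8)),
                      genome_sizes = gs, class = "region_tracks")
  tracks$extragenic <- complement_intervals(gs, tracks)
  # per-base oracle: label each base independently by priority
  base_label <- rep("extragenic", 10000)
  for (lab in rev(c("coding", "utr5", "utr3", "ncRNA", "intron"))) {
    for (i in seq_len(nrow(tracks[[lab]]))) {
      sel <- (tracks[[lab]]$start[i] + 1):min(tracks[[lab]]$end[i], 10000)
      base_label[sel] <- lab
    }
  }
  priority <- c("coding", "utr5", "utr3", "ncRNA", "intron", "extragenic")
  q <- mk(60)
  got <- assign_region(q, tracks)
  for (j in seq_len(nrow(q))) {
    labs <- unique(base_label[(q$start[j] + 1):min(q$end[j], 10000)])
    expect_equal(got[j], priority[min(match(labs, priority))])
  }
})

test_that("region partition sums to genome size for a simulated genome", {
  sim <- shared_sim()
  expect_equal(sum(region_sizes(sim$tracks)), sum(sim$genome_sizes))
})

test_that("BED and refFlat round-trip through files", {
  tmp <- tempfile(fileext = ".bed")
  dt <- data.table::data.table(chrom = c("chr1", "chr2"),
                               start = c(5L, 10L), end = c(50L, 90L))
  write_bed(dt, tmp)
  expect_equal(read_bed(tmp)[, 1:3], dt)

  tmp2 <- tempfile(fileext = ".refflat")
  write_refflat(toy_models(), tmp2)
  back <- read_refflat(tmp2)
  expect_equal(back$tx_id, toy_models()$tx_id)
  expect_equal(back$cds_start, toy_models()$cds_start)
  expect_equal(exon_starts <- back$exon_starts[1], "0,")
})
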