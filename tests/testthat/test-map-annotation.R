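test_that("locate_peptide_in_read returns the encoding nt range", {
  read <- "ATGAAACCCGGGTTT"     # frame +1: MKPGF
  loc <- locate_peptide_in_read("MKP", read, 1)
  expect_equal(loc$start, 0L)
  expect_equal(loc$end, 9L)
  expect_equal(loc$strand, "+")
  # amino-acid offset 2 in frame +2 -> nt start 1 + 3*2 = 7
  read2 <- paste0("G", read)
  loc2 <- locate_peptide_in_read("PG", read2, 2)
  expect_equal(loc2$start, 1 + 3 * 2)
  # reverse frame ranges are on forward coordinates
  rc <- oracle_revcomp(read)
  loc3 <- locate_peptide_in_read("MKP", rc, -1)
  expect_equal(loc3$strand, "-")
  expect_equal(substr(rc, loc3$start + 1, loc3$end), oracle_revcomp("ATGAAACCC"))
  expect_error(locate_peptide_in_read("MKP", read, 2), "provenance")
})

test_that("align_and_select matches brute-force all-position scoring", {
  set.seed(33)
  genome <- c(c1 = random_read(4000), c2 = random_read(3000))
  for (i in 1:8) {
    chrom <- sample(names(genome), 1)
    s <- sample(100:2000, 1)
    segment <- substr(genome[[chrom]], s, s + 26)
    if (i %% 2 == 0) segment <- oracle_revcomp(segment)
    if (i > 6)  # plant one mismatch
      substr(segment, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                         substr(segment, 10, 10))[1]
    got <- align_and_select(segment, genome, min_score = 0,
                            allow_split = FALSE)
    oracle <- oracle_best_alignment(segment, genome)
    expect_equal(got$score[1], oracle$score)
    expect_equal(got$chrom[1], oracle$chrom)
    expect_equal(got$start[1], oracle$start)
  }
})

test_that("align_and_select scores with the published formula and breaks ties", {
  genome <- c(c1 = paste0("AAAA", strrep("T", 20), "CCCCGGGGCCCC",
                          strrep("T", 20), "CCCCGGGGCCCC", "AA"))
  # segment occurs twice -> tie broken to the lower coordinate, flagged
  got <- align_and_select("CCCCGGGGCCCC", genome, min_score = 0,
                          allow_split = FALSE)
  expect_equal(got$start[1], 24L)
  expect_gt(got$n_best[1], 1L)
  expect_equal(got$score[1], 12L)          # perfect: score = length
  # below min_score -> unaligned
  expect_null(align_and_select(strrep("A", 24), c(c1 = strrep("C", 100))))
})

test_that("spliced two-block placements are found and scored without gap penalty", {
  left <- "ATGGCTAAGGCTTCC"; right <- "GGATTCGATGAC"
  genome <- c(c1 = paste0(random_read(50), left, strrep("T", 200), right,
                          random_read(50)))
  seg <- paste0(left, right)
  got <- align_and_select(seg, genome, max_mismatch = 0)
  expect_equal(nrow(got), 2L)
  expect_equal(got$score, c(nchar(seg), nchar(seg)))
  expect_equal(got$end[1] - got$start[1], nchar(left))
})

test_that("merge_loci merges within 5 bp and links split blocks", {
  aln <- data.table::data.table(
    chrom = c("c1", "c1", "c2"), start = c(100L, 106L, 500L),
    end = c(130L, 136L, 530L), strand = "+",
    read_id = c("r1", "r2", "r3"), aln_id = c("a1", "a2", "a3"))
  ml <- merge_loci(aln, distance = 5)
  expect_equal(ml$n_loci, 2L)        # c1 pair merges (gap 6-5... gap = 106-130?)
  got_c1 <- ml$loci[ml$loci$chrom == "c1", ]
  expect_equal(got_c1$n_reads, 2L)
  expect_equal(got_c1$read_ids, "r1,r2")
  # a split alignment's two far-apart blocks still count as one locus
  spl <- data.table::data.table(
    chrom = "c1", start = c(100L, 1000L), end = c(115L, 1012L),
    strand = "+", read_id = "r1", aln_id = c("s", "s"))
  expect_equal(merge_loci(spl)$n_loci, 1L)
})

test_that("uniqueness_filter drops multi-locus peptides", {
  recs <- data.table::data.table(peptide = c("A", "B"), n_loci = c(1L, 2L))
  expect_equal(uniqueness_filter(recs)$peptide, "A")
})

test_that("annotate_mutation applies indel precedence and the MS flag", {
  loci <- data.table::data.table(chrom = "c1", start = 100L, end = 130L)
  vs <- variant_set(data.table::data.table(
    chrom = "c1", pos = c(105L, 110L), ref = c("A", "AT"),
    alt = c("G", "A"), total_depth = 60L, alt_depth = 30L))
  vs$microsatellite <- c(FALSE, TRUE)
  m <- annotate_mutation(loci, vs)
  expect_equal(m$status, "indel")     # indel beats SNV
  expect_true(m$microsatellite)
  snv_only <- annotate_mutation(loci, variant_set(data.table::data.table(
    chrom = "c1", pos = 105L, ref = "A", alt = "G",
    total_depth = 60L, alt_depth = 30L)))
  expect_equal(snv_only$status, "SNV")
  wt <- annotate_mutation(loci, variant_set(data.table::data.table(
    chrom = "c1", pos = 500L, ref = "A", alt = "G",
    total_depth = 60L, alt_depth = 30L)))
  expect_equal(wt$status, "WT")
})

test_that("frame_status follows CDS phase in transcript coordinates", {
  models <- toy_models()   # txA: + strand, CDS 20-80 on chr1
  # phase 0 start -> in-frame
  in_frame <- data.table::data.table(chrom = "chr1", start = 26L, end = 50L)
  expect_equal(frame_status(in_frame, "+", models), "in-frame")
  # shifted by 1 nt -> out-of-frame
  shifted <- data.table::data.table(chrom = "chr1", start = 27L, end = 51L)
  expect_equal(frame_status(shifted, "+", models), "out-of-frame")
  # antisense to the transcript -> out-of-frame
  expect_equal(frame_status(in_frame, "-", models), "out-of-frame")
  # minus-strand transcript txB: CDS 220-280; the peptide's first codon
  # base is its rightmost position; phase 0 at genomic 279 - 3k
  minus_if <- data.table::data.table(chrom = "chr1", start = 253L, end = 277L)
  expect_equal(frame_status(minus_if, "-", models), "in-frame")
  expect_equal(frame_status(
    data.table::data.table(chrom = "chr1", start = 252L, end = 276L),
    "-", models), "out-of-frame")
  expect_equal(frame_status(
    data.table::data.table(chrom = "chr1", start = 250L, end = 274L),
    "-", models), "in-frame")
  # intronic / outside CDS -> out-of-frame
  expect_equal(frame_status(
    data.table::data.table(chrom = "chr1", start = 3L, end = 15L),
    "+", models), "out-of-frame")
})

test_that("spliced CDS phase uses transcript, not genomic, coordinates", {
  # two exons; intron of 50 nt between; CDS spans both
  m <- data.table::data.table(
    gene_name = "g", tx_id = "t", chrom = "chr1", strand = "+",
    tx_start = 0L, tx_end = 250L, cds_start = 10L, cds_end = 240L,
    exon_starts = "0,150,", exon_ends = "100,250,")
  # first exon CDS part: 10..99 (90 nt, phase 0 at 10); second exon
  # begins at CDS coordinate 90 -> genomic 150 is phase 0
  expect_equal(frame_status(data.table::data.table(
    chrom = "chr1", start = 150L, end = 174L), "+", m), "in-frame")
  expect_equal(frame_status(data.table::data.table(
    chrom = "chr1", start = 151L, end = 175L), "+", m), "out-of-frame")
})

test_that("back-annotation recovers planted truth on the shared simulation", {
  sim <- shared_sim()
  plan <- sim$reads$plan
  # full seed-and-extend path on a representative subset of the plan
  idx <- unlist(lapply(split(seq_len(nrow(plan)), plan$label),
                       utils::head, 2))
  sub <- plan[idx, ]
  ann <- annotate_peptides(sub$peptide, sim$reads$samples$mmrd_pre,
                           sim$genome, sim$tracks, sim$models)
  m <- merge(ann, plan, by = "peptide", suffixes = c("", ".truth"))
  expect_equal(nrow(m), nrow(sub))
  expect_equal(m$region, m$label)
  expect_equal(m$frame, m$frame.truth)
  expect_equal(m$canonical, m$canonical.truth)
  expect_true(all(m$n_loci == 1L))
  # provenance fast path on the whole plan
  ann2 <- annotate_peptides(plan$peptide, sim$reads$samples$mmrd_pre,
                            sim$genome, sim$tracks, sim$models,
                            use_provenance = TRUE)
  m2 <- merge(ann2, plan, by = "peptide", suffixes = c("", ".truth"))
  expect_equal(nrow(m2), nrow(plan))
  expect_equal(m2$region, m2$label)
  expect_equal(m2$frame, m2$frame.truth)
})
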