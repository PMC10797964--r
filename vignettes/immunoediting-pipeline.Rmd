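---
title: "Detecting immune editing of canonical and non-canonical MHC-I peptides"
author: "immunedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting immune editing of canonical and non-canonical MHC-I peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(immunedit)
```

# The model

`immunedit` analyses a two-arm, two-host experiment. Isogenic
mismatch-repair-proficient (MMRp) and -deficient (MMRd) tumour cells
are sequenced before injection and after growth in an
immunocompromised host (no T-cell selection) and in immunocompetent
hosts (T-cell selection active). Immune editing is then read out at
two levels:

* **DNA.** Variants carried by immunogenic subclones are depleted in
  immunocompetent hosts. After filtering (total depth ≥ 10×, ≥ 9
  variant-supporting reads, germline subtracted), each variant gets
  exactly one region label by interval priority, and the per-region
  statistic is the normalised burden TMB = variants/Mb. Editing is the
  natural-log ratio `ln(TMB_post / TMB_pre)` per region; a negative
  value in a label means variants of that label were selectively lost.
  Gained/lost rates (set differences, per Mb of region size) and their
  host delta (immunocompromised − immunocompetent) give the same
  signal without conflating gains.

* **RNA/peptide.** Each RNA-seq read is six-frame translated;
  stop-free fragments are cut into all 8–11-mers ("the peptide space
  the transcriptome could present") and counted per sample. A peptide
  targeted by the immune system should be well supported in the
  pre-injection cells and in the immunocompromised tumour, but lost or
  strongly counter-selected in immunocompetent tumours. The retention
  floor and the loss/counter-selection and expansion formulas, with
  their published constants, are:

  * retention: `counts_pre ≥ 10` and `counts_NOD ≥ 10`;
  * loss/counter-selection (per immunocompetent replicate, ≥ 1 required):
    `counts_BALBc = 0` **or** (`counts_pre − counts_BALBc ≥ 10` **and**
    `counts_pre / counts_BALBc ≥ 10`);
  * arm exclusivity: absent from MMRp tumours (either host) and from
    MMRp cells; not strongly expanded versus MMRp
    (`diff ≥ 10` and `ratio ≥ 10`).

Observed MS-eluted peptides are matched exactly against these
databases, cross-checked against the other genotype's database, traced
back through their supporting reads to genomic loci, and annotated.
**Canonical** means coding region *and* in-frame (CDS phase match in
transcript coordinates, same strand); UTR, intronic, extragenic,
antisense and phase-shifted peptides are non-canonical.

# Numerical and design choices

Where the published procedure is silent or ambiguous, this package
makes the following choices (each is a documented argument):

* **Zero division in the expansion exclusion.** Read literally with
  `ratio(x, 0) = ∞`, the expansion test would exclude *every* peptide
  absent from MMRp cells that passes the 10-count floor, leaving the
  MMRd database empty by construction — contradicting both the intent
  (MMRd-exclusive peptides are the point of the database) and the
  published database size. `build_mmrd_db()` therefore treats the
  ratio condition as unmet when the MMRp count is zero
  (`expansion_zero_division = "false"`); absence from MMRp is handled
  by the presence-exclusion clause. The standalone
  `expanded_in_mmrd()` defaults to the `∞` convention so the printed
  formula's limit behaviour remains available.
* **"Disappeared" in the MMRp arm** is strict (`counts_BALBc = 0`),
  since the explicit counter-selection formula is given only for the
  MMRd arm; `disappeared = "counterselected"` reuses it symmetrically.
* **MMRp "presence"** is any nonzero count
  (`mmrp_presence_threshold = 0`). With a higher threshold the
  expansion test becomes the active guard for low MMRp counts.
* **Counting unit** is occurrences (read × frame × offset × k);
  `count_mode = "reads"` collapses to distinct supporting reads, which
  is what the expression/fold-change stage uses. The 10-count floor is
  applied to the pooled per-sample count, not per k length.
* **Stop codons split fragments** (peptides never span a stop), and
  codons containing N are untranslatable and also split. Initiator
  special-casing is disabled: a leading CTG/TTG translates as L, not
  M, matching a plain codon-table oracle.
* **ncRNA priority.** The published priority list (coding > 5'UTR >
  3'UTR > intronic > extragenic) omits ncRNA; exonic ncRNA is more
  specific than intron, so it slots between 3'UTR and intron. The
  track can be excluded (`include_ncrna_track = FALSE`), in which case
  ncRNA exons fall through to intron/extragenic.
* **Interval conventions.** 0-based half-open BED coordinates in all
  user-facing tables; merges follow `bedtools merge -d`: gap ≤ d is
  merged, so bookended intervals merge at d = 0. Region tracks are
  unstranded after construction; strand matters only for UTR sides
  and frame status.
* **Variant region assignment** uses the reference footprint
  `[pos, pos + len(ref))` and the same priority rule; an indel
  spanning two labels gets the higher-priority label. Per-Mb
  normalisation of gained/lost uses region size (as in the TMB
  definition), not covered size.
* **Alignment.** The external aligner is replaced by a seed-and-extend
  matcher: pigeonhole seeds guarantee all placements within
  `max_mismatch` (default 2) are found; scoring is the published
  formula with `rep_match = 0` (no repeat masking). One two-block
  spliced placement (both blocks exact, split at a codon boundary, gap
  ≤ 10 kb) is allowed and does not incur a gap penalty, mirroring
  spliced reads; splits are only searched when no contiguous perfect
  hit exists. Minimum acceptable score defaults to 0.9 × segment
  length; ties break to the lowest chromosome name, then coordinate,
  and tied peptides are flagged and removed by the uniqueness filter
  (a spliced placement's two blocks count as one locus).
* **Candidate ranking** (filter "d") has no published formula; the
  composite here is the sum of z-scores of log1p pre-injection
  expression, log1p MS intensity (where present) and allele frequency
  (mutated MAPs only), equal weights. Pools are assigned round-robin
  by rank — explicitly a stand-in, as the published pools (sizes
  5/7/8) follow no stated rule.
* **Degenerate inputs.** `ln` of a zero post-TMB returns `-Inf` as a
  flagged sentinel (complete loss), a zero pre-TMB returns `NA`;
  zero-size regions give `NA` rates; all-zero P gives undefined TPM.

# The synthetic world

`sim_config()` defaults state the simulated experiment once:

| parameter | default | why |
|---|---|---|
| genome | 3 × 50 kb | desk-scale; minutes on one CPU |
| transcripts | 30 (15% ncRNA, 4 unexpressed) | all six region labels populated |
| exons / UTRs | 1–3 exons of 500–700 nt; UTRs 150–220 nt | realistic mammalian-like geometry at toy scale; UTR tracks large enough to carry per-label signal |
| MMRp somatic rate | 200 /Mb | inflated ~100× over real tumours so a 150 kb genome yields tens of events per label |
| MMRd/MMRp factor | 10 | the characteristic hypermutation fold of MMR loss |
| editing fraction | 0.5 in coding + 5'UTR | strong, detectable editing confined to immunogenic labels |
| gained-variant rate | 5% of the somatic rate | growth without selection adds few variants |
| reads | 90 nt, tiling step 15 | deterministic ~6× background depth |
| editing plan | 50 peptides × 12 support reads | clears the 10-count floor with margin |
| noise | 0 | the noiseless world in which truth is exactly recoverable |

Planted editing targets are 8-mers carried by minimal 24-nt support
reads constructed so that **only reading frame +1 yields any k-mer**:
frames ±2/±3 have seven codons, and frame −1 is required to contain a
stop. This makes the planted set *exactly* the k-mer output of its
support reads, so the master round-trip (database = plan, precision =
recall = 1) is well defined without a k-mer-closure convention.
Windows are placed by rejection sampling: inside a single interval of
the intended label, not overlapping a higher-priority track, stop-free
in frame +1, absent from the background k-mer set, unique in the
genome (both strands), and — for coding in-frame/out-of-frame and
antisense plants — inside *unexpressed* transcripts, because expressed
mRNA is tiled by background reads whose six-frame k-mers would already
contain any in-exon peptide in every phase. Background reads are
identical across samples, so in the noiseless world background
peptides have equal counts everywhere and can never satisfy the loss
formula; this is what makes the round trip exact rather than merely
probable.

What the generator does **not** emulate: sequencing quality profiles
(a flat error rate only), PCR duplicates, spliced-alignment artefacts,
MS spectra and search-engine FDR, copy-number effects, subclonal
structure beyond the binary edited/retained plan, and realistic per-Mb
rates. A green test therefore establishes the *logic* of the pipeline
— formulas, interval algebra, frame arithmetic, selection semantics —
not its robustness to real sequencing noise.

# Known limitations

* The microsatellite module is a simplified maximal-perfect-repeat
  scanner; the published MSI score is replaced by the fraction of
  scanned loci carrying a somatic indel.
* The matcher handles ≤ `max_mismatch` mismatches and one exact split;
  it is not a general gapped aligner, and `rep_match` is always 0.
* FPKM-style gene expression is pass-through metadata; the package
  quantifies only MAP-supporting reads.
* Allele-frequency semantics for wild-type MAPs are undefined here
  (reported only for mutated MAPs), as the published table's "%AF =
  100 for WT" column has no stated definition.

# Reproducibility

Every generator and the pipeline driver are deterministic under
`seed`; `run_pipeline()` writes a manifest with per-file MD5 checksums
and a config hash, and identical config + seed reproduce identical
checksums. All thresholds surface as config keys with the published
constants as defaults (depth ≥ 10, alt ≥ 9, count floor 10, diff ≥ 10,
ratio ≥ 10, merge distance 5, coverage depth 10, k = 8–11).
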