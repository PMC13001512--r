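---
title: "Methods: integrating G4, chromatin accessibility and expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating G4, chromatin accessibility and expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadchrom)
```

# Scope and model of the data

`quadchrom` analyzes two-condition studies (disease vs. control, drug vs.
vehicle) measured in three modalities over a shared genome: G-quadruplex
(G4) ChIP-seq peaks, ATAC-seq open-chromatin peaks, and RNA-seq gene
counts. G4 structures form in single-stranded, G-rich DNA; endogenous G4
peaks concentrate in promoters and co-occur with open chromatin, so the
scientific questions the package addresses are inherently integrative:

* are G4 peaks enriched in particular genomic features (promoters, first
  exon–intron junctions), beyond what random placement explains?
* do differential G4 formation, differential accessibility and
  differential expression move together across conditions?
* on which DNA strand does a G4 form, and does the template /
  non-template distinction matter for expression?
* do accessibility and G4 changes act additively or cooperatively on
  expression?

Peaks and hits are held as `GRanges` (1-based, closed intervals, the
Bioconductor convention); BED, GTF and chrom.sizes conversion happens at
the I/O boundary, exactly as `rtracklayer` performs it. All overlap
computations ignore strand, because BG4-type ChIP peaks are unstranded;
strand enters only through G4-seq hits and gene orientation.

# Copy-number-aware normalization

Comparing count matrices between genomes with different copy numbers
confounds copy-number ratio (CNR) with true signal change. The package
takes a segment table (chromosome, start, end, log2 ratio; the CNVkit
`.cns` dialect) as input, converts log2 ratios back to linear CNR, and:

1. assigns every peak to a segment — the overlapping segment; the one
   with the largest overlap when several overlap; the closest by edge
   distance when none does (ties break to the lower start). Peaks on
   chromosomes without segments fall back to CNR = 1 with a warning
   rather than being dropped.
2. rescales counts per feature: if CNR ≥ 1, case counts are divided by
   the CNR; if CNR < 1, control counts are multiplied by it. Either way
   the condition carrying the copy-number excess is shrunk toward the
   other, and CNR = 1 is the identity.

Scaled values are rounded half-up to keep the integer contract of
count-based tests; at typical counts (tens to hundreds) the rounding
perturbation is negligible relative to sampling noise. Whether a peak
spanning two segments should follow the larger overlap, and whether
scaled counts should be re-integerized, are not dictated by the upstream
tools this mirrors; both choices are recorded here and tested.

# The simplified differential stage

The differential module is an explicit, small stand-in for
DESeq2/edgeR-class machinery — enough statistical engine to test the
copy-number logic and the integrative stages against planted truth,
without claiming numeric parity with those packages.

* **Normalization.** Median-of-ratios size factors
  (`factor_j = median_i count_ij / geomean_i`, over features positive in
  all samples). The raw-ratio median is used (DESeq2 medians in log
  space; the two differ only in the interpolated middle of an even
  count). For contrasts with a trended MA plot, a per-sample loess fit of
  M on A supplies feature-by-sample offsets instead; with no trend the
  offsets reduce to log size factors.
* **Dispersion.** Per-feature method of moments,
  `alpha = (s² − m)/m²` pooled within conditions, floored at 1e-8, then
  moderated toward a mean–dispersion trend with weight
  `df/(df + 20)` on the per-feature value. The trend is a ratio of sums
  (`Σ(s² − m)/Σm²`) over mean-ordered bins of ≥ 50 features: averaging
  per-feature ratios is biased downward at 2–6 replicates and that bias
  alone pushes the Wald test's size from 0.05 to ≈ 0.10; the pooled-ratio
  trend removes it (type-I error 0.05–0.06 in the suite's simulations).
* **Test.** Per feature, the NB log-link model
  `mu = exp(offset + b0 + b1·case)` with fixed dispersion, fitted by
  IRLS vectorized across features (the two-group design gives the
  weighted-least-squares update in closed form), Wald statistic
  `b1/se(b1)` against a standard normal, `log2fc = b1/ln 2`. All-zero and
  non-converged features are flagged `NA` and excluded from the BH
  denominator. There is no fold-change shrinkage, Cook's filtering or
  independent filtering.
* **Calls.** Benjamini–Hochberg over tested features; status `up` /
  `down` when `p_adj < 0.05` (configurable) with the matching sign, else
  `nd`.

# Interval enrichment

Enrichment of a query interval set in a subject set is quantified as
observed overlap against a randomized null: z-score, one-sided normal p,
add-one empirical p `(1 + #{null ≥ obs})/(1 + n_perm)` (never exactly 0),
and fold = observed/expected. Two null generators sit behind one
interface, matching the two randomizations the analyses need:

* **Genome shuffle** — each interval is relocated uniformly among
  positions of the same length on its chromosome (optionally any
  chromosome, sampled proportionally to legal positions), rejecting
  placements that touch excluded regions (assembly gaps, blacklists);
  rejection sampling is capped at 10⁴ rounds before erroring.
* **Universe resampling** — a same-size subset is drawn without
  replacement from a fixed universe, for questions like "are the TSSs of
  differential genes special among TSSs of expressed genes".

Overlap counting defaults to *subject elements hit* (the natural reading
of "overlaps with TSSs"); a pair-counting mode is available and is what
the planted-enrichment recovery uses, since its expectation is linear in
the planting fraction. The permutation loop runs on plain sorted vectors
(`findInterval` arithmetic) rather than allocating a `GRanges` per
permutation; the fast path is cross-checked against the interval engine
in the tests. The published peak-pairing rule "overlap larger than
150 bp" is implemented literally as `min_overlap = 151`.

# Strand inference and template classification

Unstranded G4 ChIP peaks inherit strand from strand-resolved G4-seq hits:
a peak intersecting only Watson-strand hits is called `watson`, only
Crick-strand hits `crick`, both `ambiguous`, none `unassigned`. The
"transcribing" strand of a gene is interpreted as the template strand
(the strand the polymerase reads): for a "+" gene that is the Crick
strand, so a `crick` G4 on a "+" gene is `transcribing` and a `watson`
G4 is `non-transcribing`, mirrored for "−" genes. Only peaks with a
definite call and a promoter-linked gene are classified.

# Tri-modal integration

* **Linking.** A peak links to a gene when its nearest edge is < 3 kb
  from the TSS (distance 0 if it covers the TSS); the nearest TSS wins,
  exact ties go to the lexicographically smaller gene id. Center-to-TSS
  distance is available behind a flag.
* **Expression.** TPM (`rate_i·10⁶/Σrates`, summing to 10⁶ exactly) and
  RPKM with the in-feature total as library size. Activity calls use the
  zFPKM construction: the mode of the log2 expression density
  (Silverman's bandwidth, 4096-point grid) with the peak refined as the
  vertex of a locally fitted parabola — the raw argmax of a kernel
  density is a noisy location estimator and the refinement roughly
  triples its precision without bias for a locally symmetric peak — and
  a half-Gaussian standard deviation `mean(x > mu − mu)·sqrt(pi/2)`;
  genes with `z ≤ −3` are inactive.
* **Quadrants.** Two differential contrasts joined by feature id form
  signed quadrants (++ / −− / +− / −+). Each quadrant is tested
  hypergeometrically with sign-stratified margins (for ++: K = up in A,
  n = up in B, population N = features tested in both); the population
  restricted to doubly-differential features is available behind a flag.
  Same-sign quadrants are typically tested for enrichment
  (`p_upper`), opposite-sign for depletion (`p_lower`).
* **Proximity decay.** ATAC peaks are indexed per G4 site by signed rank
  (0 = overlapping, ±k = k-th non-overlapping peak at
  increasing/decreasing coordinate — the coordinate-based sign is a
  recorded convention; the biological readout, decay with |offset|, is
  symmetric) and by edge-distance bins; per offset, the Pearson r
  between the two log2 fold-change vectors. Full intervals (not
  summits) define the distances.
* **Stratification and interaction.** Genes bucketed by
  (ATAC status × G4 status) are summarized by median RNA log2FC with
  rank-sum tests against the doubly-`nd` reference, and the cooperative
  hypothesis is tested by the type-III ANOVA
  `rna_log2fc ~ atac_status * g4_status` under sum-to-zero contrasts
  (via `car::Anova`, the same route the field uses). With empty design
  cells the interaction row is flagged and its F computed on the
  estimable subspace (full model minus aliased columns vs. additive
  model); main effects then come from the additive model.

# The synthetic study generator

`generate_study()` builds a complete two-condition study with planted
ground truth, so every stage above is testable without external data.
What it emulates, and its default conditions:

* a 2 × 5 Mb genome with ~2% excluded regions (gap/blacklist analogue);
* 200 non-overlapping spliced genes (≥ 2 exons each, so a first
  exon–intron junction exists; CDS set mid-first-exon to mid-last-exon so
  both UTRs exist), half per strand;
* 500 G4 peaks, 80% planted uniformly inside promoter windows
  (TSS ± 3 kb) — the promoter share reported for endogenous G4 peaks —
  each with a true strand; 1500 ATAC peaks, with 75% of G4 peaks covered
  by one (G4-overlapping ATAC peaks default to 988 bp and background
  peaks to 347 bp, the published median widths of the two classes);
  strand-resolved G4-seq hits covering 80% of G4 peaks on the true
  strand plus uniform background hits;
* copy-number segments tiling each chromosome (defaults: 5% at
  log2 = +1, 5% at −1, remainder neutral);
* negative-binomial counts per modality,
  `mu = baseline · sizefactor · 2^(lfc·case) · CNR^case` with variance
  `mu + alpha·mu²` (alpha = 0.05), lognormal baselines, library factors
  in [0.7, 1.3], 3 replicates per condition. CNR multiplies the case
  condition of the ATAC and G4 matrices — the modalities that are
  copy-number normalized downstream — and not RNA.

Differential effects are planted per promoter-linked trio (gene, its
promoter G4, the ATAC peak covering that G4): the gene draws one
differential indicator and one latent effect *b*, and every modality's
log2FC in the trio is `sqrt(rho)·b + sqrt(1−rho)·e`, giving pairwise
cross-modality correlation `rho` (default 0.6, in the range of the
promoter-level correlations reported for such data). Unlinked features
draw independent effects at per-modality differential fractions
(defaults 0.30/0.15/0.30 for ATAC/G4/RNA, scaled-down echoes of the
reported differential shares). Because zero–zero pairs lie on the
regression line, the planted correlation is recoverable from the truth
tables including non-differential features.

One top-level seed drives everything; each generator consumes an
independent child stream derived from `(seed, generator name)`, so adding
a generator does not perturb the others, and identical configs give
byte-identical bundles. Bundles serialize to plain text only
(chrom.sizes, BED6, BED12, TSV, YAML) and round-trip.

The planted promoter enrichment fold is computed analytically as
`(p + (1−p)q0)/q0`, where `q0` is the probability that a uniformly
placed peak overlaps a promoter window (promoter coverage widened by the
peak width over the allowed genome, edge effects ignored);
`promoter_fraction_for_fold()` inverts this to plant a target fold. The
approximation ignores promoter–excluded-region intersections, which
biases the planted fold by well under the tolerances used.

What the generator does **not** emulate: read-level data (no FASTQ,
fragment lengths or Tn5 insertion bias), sequence content (no G-runs),
peak-calling artefacts, or multi-factor designs. Passing tests therefore
demonstrate that the statistical machinery recovers planted interval and
count structure — not that any upstream peak caller or aligner behaves.

# Numerical and design choices

* Coordinates are 1-based closed in memory (`GRanges`); BED I/O converts.
  All published threshold semantics are preserved: "overlap > 150 bp" ⇒
  ≥ 151; "less than 3 kb from the TSS" ⇒ strict inequality, so an edge
  exactly 3000 bp away does not link; the TSS of a "−" gene is its last
  covered base.
* Feature annotation precedence (promoter/TSS > 5′UTR > junction > first
  exon > first intron > other exon > other intron > 3′UTR > intergenic)
  makes the category assignment total and deterministic; exon categories
  cover the CDS-clipped exon portions so terminal-exon UTRs retain their
  own labels. The junction label requires covering both bases flanking
  the first exon–intron boundary.
* `closest` ties break to the lower start coordinate; book-ended
  intervals have distance 0 (the Bioconductor convention), the only
  departure from "distance 0 iff overlapping", on a measure-zero case.
* The empirical p uses the add-one rule, making it conservative and
  strictly positive; the z-based normal p is reported alongside, as the
  headline permutation analyses quote z-tests.
* Problem sizes in the test suite (genomes of 1–10 Mb, 200–5000 features,
  100–1000 permutations, 100–200 simulation runs) are chosen so planted
  parameters are recoverable at the stated tolerances on a single CPU in
  minutes; they are scaled-down study analogues, not reproductions of
  dataset-scale counts.

# Known limitations

* The Wald/normal reference is slightly anticonservative below ~4
  replicates per group; the suite's calibration checks run at 4–6.
* Median-of-ratios assumes most features are non-differential; with
  ≥ 30–50% one-directional effects the size factors absorb part of the
  signal (the loess offset variant shares this limit).
* Strand inference is only as good as the hit catalogue: peaks without
  hits are unassigned, and dense background hits produce ambiguity.
* The hypergeometric quadrant test conditions on the observed margins;
  it does not model the dependence of the two contrasts beyond sign.
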