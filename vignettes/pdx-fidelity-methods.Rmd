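---
title: "Methods: quantifying genomic and transcriptomic fidelity of patient-derived xenografts"
author: "pdxfid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genomic and transcriptomic fidelity of patient-derived xenografts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Patient-derived xenografts (PDXs) are human tumor fragments grown in
immunodeficient mice. Before a PDX can stand in for the patient's tumor in
drug studies, one must show that it preserves the tumor's somatic mutations,
copy-number landscape, subclonal architecture and expression program. pdxfid
implements the computational chain used for exactly that comparison on
paired patient/PDX whole-exome and RNA-seq data: read-level host
deconvolution, somatic variant filtering, concordance metrics, exome CNV
analysis, subclone/purity modeling, splice-isoform quantification and
fold-change differential expression — plus a synthetic cohort generator
whose ground truth makes every stage testable without access to patient
data.

The package operates downstream of alignment and variant calling: its
inputs are read sets, variant tables with per-sample read counts and
annotations, per-interval coverage, splice-junction tables and gene count
matrices.

# Graft/host read classification

PDX sequencing mixes graft (human) and host (mouse) reads. Each read is
classified against two k-mer indexes, one per reference, by counting its
canonical (strand-collapsed) k-mers that occur only in the graft index
(g), only in the host index (h), in both (b) or in neither (z):

* g > 0, h = 0 → **graft**; h > 0, g = 0 → **host**;
* g = h = 0, b > 0 → **both**; all zero → **neither**;
* g > 0 and h > 0 → **ambiguous**.

Mate pairs are classified jointly on the union of both mates' k-mers; a
pair with specific evidence for both genomes is ambiguous. Only reads
classified **host** are removed downstream — both/neither/ambiguous reads
are retained to maximize the graft-derived signal reaching the analysis.

`k` defaults to 25, the scale used by published xenograft deconvolution
tools; smaller k inflates the shared ("both") class, larger k loses
tolerance to sequencing errors. Canonical k-mers are used because
sequencing strand is arbitrary. Reads shorter than k carry no evidence and
fall into "neither" with a logged count.

# Somatic variant filter chains

Three filter chains serve three purposes, and all fail closed on missing
annotations (an unannotated variant is excluded and counted):

* **Reporting**: zero germline alt reads, exonic, HIGH or MODERATE
  predicted impact, absent from the 1000 Genomes and Exome Sequencing
  Project databases.
* **Concordance eligibility** (per variant identity key, over the union of
  samples in which it was called): HIGH/MODERATE impact, absent from the
  1000 Genomes European and African panels, zero germline reads, and a
  uniquely mapping flanking window (below).
* **Purity eligibility**: depth ≥ 50 in every modeled sample, no overlap
  with a called CNV segment (|Log2R| ≥ 0.5), not a dbSNP site, autosomal
  (chrX and chrM excluded), at most one germline alt read, and a uniquely
  mapping flanking window.

The flanking-window check extracts the 101 bp sequence centered on the
variant (an odd window admits a center; the analogous "100 bp" convention
is ambiguous about centering) and scans the whole reference on both strands
by ungapped sliding comparison; the site is unique iff exactly one locus
reaches 90% identity. At 101 bp and 90%, a competing locus qualifies with
up to 10 mismatches. Gapped alignment is deliberately omitted at this
scale; the ungapped scan is the package's reproducible stand-in for an
external aligner-based mappability check, and the identity fraction is
matches / window length.

Caller provenance is carried as a set-valued column and combined by union;
variant identity is exact `(chrom, pos, ref, alt)` matching with no fuzzy
locus matching.

# Concordance metrics

With P the somatic mutation set called in a patient tissue and X the set
called in a derived xenograft,

* recall = |P ∩ X| / |P| — the fraction of patient mutations rediscovered
  in the PDX;
* precision = |P ∩ X| / |X| — the fraction of PDX calls present in the
  patient.

Empty sets yield flagged missing values rather than zero. Each PDX is
compared only against its originating visit's patient sample (its lineage
parent); aggregates are the mean and median over PDXs. The VAF concordance
matrix holds per-sample variant allele fractions for a selected variant
panel (default: the 60 eligible variants with the highest patient-sample
depth — the display-panel size is conventional and the selection rule is
the package's own, since depth-ranking favors the most reliably measured
sites), with per-variant across-sample standard deviation as the
concordance score.

# Exome coverage-pattern CNV

Coverage is summarized as RPKM per 120 bp capture interval. A pool of
germline reference exomes provides, per interval, the median RPKM and its
sample variance (n−1). Intervals with reference median below 1 RPKM, or
zero coverage in half the references, are masked — log ratios against a
near-empty reference are noise.

**GC correction.** Intervals are grouped by GC bin (width 0.02) × capture
pool copy count; within each group the peak of the coverage kernel density
(Silverman bandwidth) is aligned to the global peak by a multiplicative
factor. Groups under 20 intervals merge into the nearest GC bin. Every
sample — references included — is corrected with its own factors before
model learning and ratio computation.

**Log2 ratio.** `log2((tumor + ε) / (median + ε))` with ε = 0.1 RPKM. The
reference variance is moved to the log2 scale by the delta method, scaled
by the reference/tumor mean-coverage ratio (the "predicted variance,
adjusted for tumor coverage"), and then moderated by shrinking each
interval's estimate toward the genome-wide median (prior weight 20 against
the pool's n−1 degrees of freedom). With small reference pools the raw
per-interval variances are wildly unstable; unmoderated inverse-variance
weights let a handful of near-zero estimates dominate segment means and
destroy the standardized signal, which we observed directly on 4-reference
pools.

**Segmentation.** Circular binary segmentation on the
variance-standardized sequence, per chromosome: the maximal circular-arc
t statistic is tested against a permutation null (1,000 permutations,
α = 0.01, with early termination once significance is impossible — this is
what keeps copy-neutral chromosomes cheap); accepted arcs split the
sequence recursively; segments narrower than 3 intervals merge into the
neighbor with the nearer mean. The O(n²) arc scan and the permutation loop
are implemented in C++; permutations draw from R's RNG so a set seed fixes
the segmentation exactly. Segment means are inverse-variance-weighted
means of the unstandardized log2 ratios.

**Normalization and calls.** Per sample, the median per-interval segmented
value is subtracted (median-zero convention). Across samples, an optional
re-centering shifts each sample so an anchor chromosome assumed
copy-neutral (default chr2) sits at log2 ratio 0 — a reproducible stand-in
for manual cross-sample review. A segment is amplified when its mean
exceeds +0.5 and deleted below −0.5, strict inequalities; a gene is called
when any overlapping segment is called.

Coordinates are 0-based half-open internally and in BED output; variant
tables and VCF are 1-based, declared in file headers.

# Subclone and purity model

Purity-eligible variants across S sequential samples are modeled as a
K-component binomial mixture: variant i with alt count a_is at depth d_is
in sample s, cluster k with weight π_k and per-sample success probability
θ_ks,

L = Π_i Σ_k π_k Π_s Binomial(a_is | d_is, θ_ks).

Cluster membership is shared across samples — the joint-timepoint feature:
a variant belongs to the same cell population in every biopsy and PDX, only
the population's prevalence changes. Fitting is by EM (10 restarts from
k-quantile initial centers with jitter; convergence at relative
log-likelihood change < 1e−8 or 500 iterations; a cluster with π_k < 1/n
triggers a restart), and the EM monotonicity invariant is checked in the
tests on every fitted trace. K is chosen by BIC with p = K−1 + K·S. EM with
BIC was chosen over MCMC with DIC deliberately: at these problem sizes it
is deterministic under a fixed seed, orders of magnitude faster, and
optimizes the same likelihood.

Under a heterozygous-diploid model a clonal variant has expected VAF =
purity/2, so per-sample purity is reported as min(1, 2·max_k θ_ks). The
factor of 2 is the package's reading of "purity from the most frequent
subclone's frequency": without it, a pure tumor's clonal cluster at VAF 0.5
would report purity 0.5. Copy-number interference is avoided by
construction — eligibility already excluded loci in called CNVs. Clone
trajectories are reported as θ_ks across declared sample order with
normal-approximation binomial bands, and a scatter of alt reads versus
depth colored by cluster is available via `plot()`.

# Splice-isoform quantification

Isoforms sharing upstream exons are quantified by their discriminating
splice junctions only. For the androgen receptor (hg19): AR-V7 by reads
joining exon 3 (chrX:66905852–66905968) to the cryptic exon in intron 3
(chrX:66914515–66915580); full-length AR by reads joining exon 4
(chrX:66931244–66931531) to exon 5 (chrX:66937320–66937464). A spliced
read counts when its donor end falls anywhere inside the donor exon and its
acceptor start anywhere inside the acceptor exon (spanning reads, not
exact-boundary reads; no minimum overhang by default, configurable).
Counts are normalized to SRPM — splice reads per million total splice
reads — and isoform fold changes are `(SRPM_a + f)/(SRPM_b + f)` with
f = 0.1 SRPM stabilizing zeros.

# Expression

RPKM_gs = 1e9 · c_gs / (L_g · N_s) with exon-union gene lengths.
Between-sample correlation is Pearson on log10 RPKM over genes expressed
(> 0) in both samples — dropping zeros rather than flooring them keeps the
correlation estimate free of an arbitrary pseudo-count, while fold-change
ratios (which need zeros handled) use a 0.1 RPKM floor. Differential
expression between visits is a pure fold-change rule: up if
(v2+f)/(v1+f) > 2, down if < 0.5, strict inequalities, no variance model —
matching the definition this analysis reproduces. Ranked lists are exported
for downstream enrichment tools; enrichment itself is out of scope.

# The synthetic cohort

The generator's defaults describe the study design the package targets:
one germline blood sample; two patient biopsies of one metastatic prostate
tumor (visits 1 and 2, before and during treatment); ten PDXs — six from
visit 1 and four from visit 2 across two mouse generations. Its key
settings, chosen once as realistic study conditions:

* **Three subclones** at stable cellular prevalences 1.0 / 0.53 / 0.21
  carrying 50/30/20% of the somatic variants; with purity 0.75 these give
  per-sample expected VAFs of about 0.375 / 0.20 / 0.08.
* **Purity** 0.75 (visit 1), 0.76 (visit 2), 0.98 in PDXs (engraftment
  removes human stroma and host reads are filtered).
* **Host contamination** 8% of PDX reads; graft/host references diverge by
  5% per base with conserved stretches (so "both" reads exist).
* **PDX-private false calls** at rate 0.5 per true variant, modeling
  residual mouse reads and clonal drift as a rate rather than simulating
  aligner behavior — the tests target the metrics, not the aligner. With
  no dropout this makes expected precision ≈ 1/(1+r) while recall stays
  near 1.
* **Copy events**: a 20-interval focal amplification to 39 tumor copies
  (log2 ratio ≈ +3.9 at purity 0.75, the regime of a high-level AR-locus
  amplification) and a 300-interval single-copy loss (≈ −0.678 in tissue,
  ≈ −0.97 in a near-pure PDX — the TP53-locus regime).
* **Coverage**: 2,000 intervals of 120 bp over three chromosomes
  (chromosome 2 left copy-neutral as the re-centering anchor), mean 100
  reads per diploid interval, gamma-Poisson overdispersion 0.02, smooth
  per-sample GC bias of ±20% scale. Overdispersion is gamma-Poisson
  because exome capture variance is super-Poisson and the reference-model
  learning needs realistic variance to be worth testing.
* **Variant annotations**: 15/60/15/10% HIGH/MODERATE/LOW/MODIFIER impact,
  5% 1000 Genomes, 4% ESP, 10% dbSNP, 90% exonic, germline alt-read counts
  0/1/2 at 90/7/3%, 4% chrX and 1% chrM loci, and 3% of variants planted
  inside a duplicated genome segment so the uniqueness filter has true
  positives.
* **Expression**: 5,000 genes, log10-normal profiles; the two visits are
  near-replicates (latent correlation 0.998) apart from a planted 4% of
  genes changed 4-fold (60% up), because sequential biopsies of one tumor
  differ mainly by treatment effect; patient↔PDX correlation is
  calibrated to 0.93. Without the near-replicate structure, threshold-only
  DE between visits would be dominated by sampling noise — an instructive
  property of fold-change DE, but not the biology the cohort emulates.
* **Junctions**: AR-V7 at 50 vs 8 SRPM across visits (ratio 6.25) and
  AR-FL at 120 vs 25.5 (ratio 4.71), at one million total splice reads.

A noise-free variant (`identity_cohort_config()`) switches every
stochastic component off; on it the pipeline must report recall =
precision = correlation = 1 and zero DE calls, which the tests assert.

What the generator does **not** emulate: read-level error profiles and
mapping artifacts, indel realignment, capture-efficiency structure beyond
smooth GC bias, allele-specific copy number, and fusion transcripts.
Passing tests therefore validate the statistical machinery and its
contracts, not robustness to aligner-specific artifacts in real data.

# Problem sizes and determinism

Test and acceptance runs use the cohort defaults above (2,000 coverage
intervals, 200 variants plus private calls, 2,000 reads per PDX, 5,000
genes), sizes at which every stage completes in seconds to a few minutes
on one core while keeping all asymptotic behavior visible. All randomness
flows from explicit integer seeds: the generator derives per-stage
sub-seeds from the cohort seed, and segmentation permutations and EM
restarts are seeded by the pipeline, so a manifest plus a seed reproduces
every output byte for byte (run logs record package version, seed and
parameters; timestamps are deliberately absent from outputs).

# Known limitations

* The uniqueness check is ungapped; a paralog matching only via an indel
  would be missed. At 90% identity over 101 bp this is a minor channel.
* The subclone model ignores variant multiplicity and local copy number
  (mitigated, not eliminated, by CNV-overlap exclusion) and assumes
  heterozygous diploid origin for the purity factor of 2.
* Fold-change-only DE has no error control; it is faithful to the
  definition it implements, and the near-replicate assumption above is
  what makes it usable.
* CBS here tests arcs against a permutation null without DNAcopy's
  pruning/undo heuristics; on very long chromosomes with many events the
  recursion can oversegment slightly before minimum-width merging.
* The k-mer classifier holds both indexes in memory as character vectors;
  it is designed for the package's validation scale, not for indexing full
  mammalian genomes.
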