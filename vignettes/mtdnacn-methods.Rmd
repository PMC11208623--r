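---
title: "Measuring relative mtDNA copy number: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring relative mtDNA copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcn)
```

## The quantity and the two estimators

Each cell carries one diploid nuclear genome and a variable number of
mitochondrial genomes. Relative mtDNA copy number (mtDNAcn) is that number
expressed against the diploid nuclear genome, and `mtcn` estimates it two
ways.

**qPCR (ΔCt).** For a well with amplification efficiency *E*, template
copies scale as *E*^−Ct^. Comparing a mitochondrial target to a nuclear
reference in the same DNA,

$$N = E^{\Delta Ct}, \qquad \Delta Ct = Ct_{\text{nuclear}} - Ct_{\text{mito}},$$

and the estimators fix *E* = 2 (ideal doubling per cycle). The assay uses
two such comparisons — ΔCt₁ = Ct(*BECN1*) − Ct(*ND1*) and
ΔCt₂ = Ct(*NEB*) − Ct(*ND6*) — and averages the two copy numbers:
mtDNAcn = (2^ΔCt₁^ + 2^ΔCt₂^)/2. Averaging replicate Cts happens in Ct
space (the standard ΔΔCt practice) before conversion; an alternative —
converting each replicate and averaging copies — would differ only at
second order in the replicate noise, and Ct-space averaging keeps the
estimator a deterministic function of the per-gene mean Ct.

The *commercial-style* variant normalizes both mitochondrial genes against
the *geometric mean* of the two nuclear signals. Because copy signals are
2^−Ct^, the geometric mean of signals is the arithmetic mean of Cts, so the
nuclear reference Ct is (Ct(*BECN1*) + Ct(*NEB*))/2 and
*N*~g~ = 2^(refCt − Ct~g~)^ per mitochondrial gene. This is the only
reading of "geometric mean" consistent with ΔCt arithmetic; interpreting it
as a geometric mean *of Cts* would not reduce to the paired method when the
two nuclear Cts coincide, whereas this reading does — exactly, a property
the test suite asserts on random Ct sets.

**Low-pass WGS (coverage ratio).** With mean sequencing depth *d*~mito~
over the mitochondrial contig and *d*~auto~ over the autosomes,

$$\text{mtDNAcn} = \frac{d_\text{mito}}{d_\text{auto}} \times 2,$$

the 2 converting per-haploid-genome depth to the diploid cell. Equal
depths therefore give exactly 2. Depth is computed as aligned bases over
contig length; the autosomal mean is **length-weighted across autosomes
only** (Σ aligned bases / Σ lengths), excluding sex chromosomes — whose
depth depends on the donor's sex — and unplaced/decoy contigs. "Aligned
bases" counts CIGAR `M`/`=`/`X` only: deletions and reference skips advance
the reference without sequenced bases, clips and insertions consume no
reference. The mitochondrial contig length is taken from the alignment
header, not hard-coded.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sd_max` (replicate SD flag) | 0.5 | cycles | common qPCR QC convention; triplicates above it are flagged `HIGH_CT_SD`, not dropped |
| `max_allowed_ct` (NTC) | 35 | cycles | NTC amplification at ≤ 35 of 40 cycles indicates contamination; later crossings are primer-dimer territory |
| `max_drift_pct` (reference sample) | 20 | % of across-plate mean | flags plates whose control (e.g. NA12878) drifts; report-only, never used to renormalize samples |
| `min_mapq` | 1 | — | MAPQ 0 reads include NUMT cross-mapping; 1 removes them without discarding confident alignments |
| duplicate/secondary/supplementary/unmapped drops | all on | — | duplicates inflate depth at 0.5–1X; all switchable off to reproduce unfiltered coverage |
| `k` (haplogroup) | 12 | bp | 4¹² ≈ 16.8M ≫ 16,569, so chance k-mer collisions are rare while a few private variants leave most k-mers intact |
| `min_score` (haplogroup) | 0.01 | fraction | classification floor; see below |

Undetermined Ct wells are excluded from replicate means rather than imputed
at the cycle limit: imputation at 40 would bias ΔCt downward for weak
wells, while exclusion only widens the replicate SD, which QC already
flags.

## The synthetic-data generator

The simulator exists so every estimator and the concordance analysis can
run end-to-end offline; its defaults are the study conditions it emulates.

- **Cohort truth.** Per-sample true mtDNAcn is lognormal with moments
  matched to the group mean and SD — infants 229.2 ± 66.4, mothers
  136.7 ± 41.8 relative copies. Lognormal rather than truncated normal
  because positivity then needs no truncation and the moment match
  (σ² = log(1 + s²/m²), μ = log m − σ²/2) is exact for any mean/SD.
- **Ct plates.** Nuclear Cts are a 25-cycle baseline (defined at 2 ng
  template) plus homoscedastic Gaussian replicate noise (default SD 0.15
  cycles, a plausible triplicate pipetting/instrument scale; the source
  study referenced its inter/intra-day CVs to supplementary material, so
  this magnitude is an assumption, and configurable). Mitochondrial Cts
  sit log(mtDNAcn)/log(E) cycles earlier. With zero noise and E = 2 the
  paired estimator inverts the simulation exactly — the basis of the
  noiseless identity checks. The amplification-efficiency knob exists only
  here, for robustness testing; estimators always assume 2.
- **Alignments.** A toy genome (two 200 kb autosomes + 16,569 bp chrM,
  100 bp reads, 1X autosomal target) keeps files small while preserving
  the quantity under test: per contig the read count is Poisson with mean
  length × depth / read length, mitochondrial depth is
  autosomal depth × mtDNAcn/2, starts are uniform, and every read is a
  perfect primary 100M alignment at MAPQ 60. `expected_depth_profile()`
  is the sampling-free limit. Reads are error-free and uniquely mapped by
  design — the estimator, not an aligner, is under test.

What passing tests on these data do **not** show: robustness to real
sequencing artifacts (GC bias, duplicates beyond the flag model, NUMT
cross-mapping — no mitochondrial-region blacklisting is applied, matching
common practice but a known accuracy caveat), to qPCR inhibitors or
efficiency below 2, or to real haplogroup phylogenetic structure.

## Numerical and degenerate-input choices

- `relative_copy_number()` is exactly `2^ΔCt` in double precision; no
  rounding is applied anywhere in the estimators, only in on-disk tables
  (6 significant digits, for byte-stable reruns; rows sorted by sample).
- Zero autosomal depth is an error (the ratio is undefined); zero
  mitochondrial depth returns 0 with a `LOW_MITO_COVERAGE` flag rather
  than erroring, since an absent-signal sample is a reportable outcome.
- Pearson r requires n ≥ 3 and nonzero variance in both vectors and errors
  otherwise — a deliberate refusal to return `NaN` from degenerate input.
  Concordance is computed on the raw mtDNAcn scale (matching how such
  comparisons are usually plotted); a log-scale option exists, off by
  default.
- All-undetermined (sample, gene) pairs produce no summary but are
  recorded as QC failures; a sample missing one of the four genes is a
  hard error naming the sample and gene.
- Haplogroup score ties break lexicographically and carry a `TIED` flag,
  keeping ranked output deterministic.

## Haplogroup calling: a labelled simplification

`build_kmer_panel()`/`call_haplogroup()` implement the *idea* of k-mer
haplogroup classification — score each candidate by the fraction of its
k-mers present in the query — not any published tool's library, weighting
or PhyloTree versioning. The scoring is asymmetric (fraction of the
*panel* haplogroup's k-mers found in the query) so extra query content,
e.g. reads beyond a consensus, costs nothing. K-mer extraction wraps the
circular genome's origin by appending the first k − 1 bases, making the
set rotation-invariant (asserted against a brute-force rotation oracle).

A random query is not expected to share *zero* k-mers with a 16.6 kb panel
entry: the expected chance overlap is about |panel set| × |query set| /
4^k — a few k-mers at k = 12 — so an exact-empty-intersection rule would
almost never fire. Calls below a `min_score` floor (default 0.01, orders
of magnitude above chance overlap yet far below the ≥ 0.98 scores of
heavily mutated true matches, since m substitutions destroy at most
m × k matching k-mers) are reported `"unclassified"`. The packaged panel
sequences are synthetic (random backbone, planted variants; seed 101) and
are labelled as such; building a panel from real consensus FASTA plus the
editable prefix→region TSV is the intended user path.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make sampling
variability negligible relative to the asserted tolerances while keeping
the default run fast: 10,000 samples per group for simulator moment
matching (2% tolerance), 36- and 40-sample cohorts for noisy concordance,
200 seeds per estimator for recovery error at true mtDNAcn 200, 20 seeded
fixtures for streaming-vs-pileup equality, and a 10 kb-scale toy genome
for the per-base oracle. The oracle comparisons are exact (`identical`),
not tolerance-based.

## Known limitations

- qPCR efficiency is fixed at 2; systematically lower efficiency biases
  2^ΔCt multiplicatively and is not corrected.
- No NUMT blacklisting, GC-bias correction, heteroplasmy estimation or
  mtDNA variant calling; reads arrive aligned (no alignment step).
- The reference control is monitored, not used for between-run
  normalization.
- The haplogroup module is a teaching-grade stand-in; region assignments
  are only as good as the user-supplied prefix map.
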