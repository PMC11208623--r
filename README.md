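# mtcn

Relative mitochondrial DNA copy number (mtDNAcn) — the ratio of
mitochondrial to nuclear genome copies per cell — is an accessible marker of
mitochondrial change under physiological stress, and can be measured from
small, non-invasive specimens such as buccal swabs. `mtcn` is an R toolkit
for labs measuring mtDNAcn by two complementary routes and validating that
they agree:

- **Dual-gene ΔCt qPCR.** Triplicate Ct values for two mitochondrial genes
  (*ND1*, *ND6*) and two single-copy nuclear genes (*BECN1*, *NEB*) give
  paired differences ΔCt₁ = Ct(*BECN1*) − Ct(*ND1*) and
  ΔCt₂ = Ct(*NEB*) − Ct(*ND6*); each converts to a relative copy number
  *N* = 2^ΔCt and the final mtDNAcn is (*N*₁ + *N*₂)/2. A commercial-style
  variant normalizes both mitochondrial genes against the geometric mean of
  the nuclear signals (the arithmetic mean of the nuclear Cts).
- **Low-pass WGS coverage ratio.** From aligned shallow whole-genome
  sequencing (~0.5–1X autosomal depth),
  mtDNAcn = (mean mitochondrial depth / mean autosomal depth) × 2,
  the factor 2 accounting for the diploid nuclear genome. At 1X autosomes
  the mitochondrial contig typically sits at 100–1000X.

Around the two estimators the package provides replicate/NTC/reference-drift
QC, inter/intra-day variability tables, Pearson concordance analysis between
methods, a deliberately simplified k-mer haplogroup-region caller, and a
synthetic-data generator (ground-truth cohorts, matched Ct plates, toy SAM
alignments) so the entire pipeline runs end-to-end with no external data.

## Worked example

Simulate a small cohort, assay it by both routes, and check concordance:

```r
library(mtcn)

truth <- simulate_cohort(n_infants = 5, n_mothers = 5, seed = 42)
plate <- simulate_ct_plate(truth, ct_sd = 0.15, seed = 43)
qpcr  <- qpcr_mtdnacn(plate, method = "paired")
qpcr
#> # A tibble: 10 × 8
#>   sample_id method delta_ct_1 delta_ct_2   n_1   n_2 mtdnacn qc_flags
#>   <chr>     <chr>       <dbl>      <dbl> <dbl> <dbl>   <dbl> <chr>
#> 1 I001      paired       8.43       8.33  345.  321.    333. ""
#> 2 I002      paired       7.45       7.47  175.  178.    176. ""
#> 3 I003      paired       8.09       8.03  273.  262.    267. ""
#> # i 7 more rows
```

Sample I001's mitochondrial targets cross threshold ~8.4 cycles before the
nuclear references, i.e. ≈ 2^8.4 ≈ 333 mitochondrial genomes per diploid
nuclear genome; empty `qc_flags` means clean triplicates.

```r
lp <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
  reads <- simulate_lpwgs_reads(truth$true_mtdnacn[i], seed = 43 + i)
  mtdnacn_from_coverage(mean_depth(reads), sample_id = truth$sample_id[i])
}))
conc <- method_concordance(rbind(qpcr[c("sample_id", "method", "mtdnacn")],
                                 lp[c("sample_id", "method", "mtdnacn")]))
tidy(conc)
#> # A tibble: 1 × 4
#>   method_a method_b     n pearson_r
#>   <chr>    <chr>    <int>     <dbl>
#> 1 lpwgs    paired      10     0.980

group_summary(truth, true_mtdnacn, group)
#> # A tibble: 2 × 4
#>   group      n  mean    sd
#>   <chr>  <int> <dbl> <dbl>
#> 1 infant     5  253.  49.2
#> 2 mother     5  165.  53.3
```

The two independent assays agree with Pearson r ≈ 0.98 at realistic
technical noise (0.15-cycle replicate SD, Poisson read sampling at 1X).
`autoplot(conc)` draws the per-pair scatter; `tidy()`/`glance()` methods
cover concordance, coverage and reference-QC objects.

A command-line pipeline over the same functions ships at
`inst/scripts/mtcn` (subcommands `simulate`, `qpcr`, `lpwgs`,
`concordance`, `haplogroup`); see `?mtcn_run`.

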