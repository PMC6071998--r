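# girscan

Population-structure and selection-signature analysis for two recently
diverged livestock populations genotyped on a SNP array. The package is
aimed at animal-genetics workflows of the kind applied to a dual-purpose
zebu breed split into a closed beef-selected herd and a multi-source
dairy-selected population: quality control, PCA/DAPC-style structure
inference, per-locus diversity and F<sub>ST</sub> outlier detection, iHS
and XP-EHH haplotype scans, and candidate-gene annotation — plus a forward
Wright–Fisher simulator of two diverging populations for end-to-end
validation. Every user-facing function takes and returns tibbles (or small
matrix-backed containers with `tidy()`/`glance()`/`autoplot()` methods), so
analyses compose with the pipe.

## The statistics

* **Diversity** (per SNP, populations weighted equally): H<sub>o</sub>,
  H<sub>s</sub> = mean 2p<sub>k</sub>(1−p<sub>k</sub>),
  H<sub>t</sub> = 2p̄(1−p̄), F<sub>ST</sub> = (H<sub>t</sub> −
  H<sub>s</sub>)/H<sub>t</sub> (Nei), F<sub>IS</sub> = 1 −
  H<sub>o</sub>/H<sub>s</sub>; Nei–Chesser small-sample corrections behind
  a flag; negative F<sub>ST</sub> clamped to 0; outliers by the
  control-chart rule mean + 3 SD per autosome.
* **iHS**: UniHS = ln(iHH<sub>A</sub>/iHH<sub>D</sub>), the log-ratio of
  trapezoid-integrated EHH decay for ancestral vs derived cores,
  standardised within derived-allele-frequency bins; significance via
  p<sub>iHS</sub> = −log10(2Φ(−|iHS|)) against a fixed or empirical-null
  cutoff.
* **XP-EHH**: LRiES = ln(iES<sub>ref</sub>/iES<sub>obs</sub>) from
  allele-agnostic site-EHH integrals, standardised by median and SD;
  significant at two-sided p < 0.01; sign-to-population mapping is
  configurable (see the vignette — the conventional formula and the
  published reading disagree).
* **Structure**: PCA on binomially scaled dosages, K-means over PC scores
  scored by BIC(K) = n·ln(WSS/n) + K·ln(n), linear discriminant axes
  between clusters (clamped to K−1).

## Worked example

Simulate the default two-population design (three 3-Mb autosomes, 300 SNPs
each; open dairy population N<sub>e</sub> = 300 vs closed beef herd
N<sub>e</sub> = 120; split 50 generations ago) with one locus under
selection in dairy (s = 0.1 from starting frequency 0.1), then run the
stages:

```r
library(girscan)

cfg <- sim_config(selected_loci = tibble::tibble(chrom = 1, index = 150,
                                                 s_pop1 = 0.1, s_pop2 = 0),
                  seed = 42)
sim <- simulate_divergence(cfg)
#> <girscan_sim> 900 SNPs on 3 chromosomes; populations: dairy (n=60),
#>   beef (n=40); t_split = 50

qc <- run_qc(sim$genotypes_combined)
qc$report
#>   rule              removed surviving axis
#> 1 sample_call_rate        0       100 sample
#> 2 monomorphic           549       351 snp
#> 3 snp_call_rate           0       351 snp
#> 4 maf                     3       348 snp
#> 5 hwe_het_deviation      11       337 snp
```

(Heavy monomorphic attrition is expected: the fixed marker panel drifts
without mutation through the burn-in, and QC removes what fixed.)

```r
pca <- run_pca(qc$genotypes, n_pc = 10)
pca
#> <girscan_pca> 100 samples, 10 retained PCs
#>   leading eigenvalues: 38.47, 14.02, 12.60
#>   percent variance: 10.93,  3.98,  3.58

cl <- select_k_bic(pca$scores, k_grid = 1:5, seed = 1)
table(cl$assignments_by_k[[2]],
      sim$labels$population[match(names(cl$assignments), sim$labels$sample_id)])
#>     beef dairy
#>   1   40     0
#>   2    0    60
```

PC1 carries 10.9% of the variance and separates the populations; K-means at
K = 2 recovers the two populations exactly (inspect the BIC curve with
`autoplot(cl)` rather than trusting its argmin — see the vignette).

```r
div <- per_locus_stats(qc$genotypes, sim$labels) |> clamp_negative_fst()
diversity_overall(div)[, c("mean_fst", "mean_fis", "mean_ho_dairy", "mean_ho_beef")]
#>   mean_fst mean_fis mean_ho_dairy mean_ho_beef
#> 1   0.0560  -0.0207         0.325        0.300

fo <- fst_outliers(div)
sum(fo$snps$outlier)
#> [1] 3
```

The closed beef herd shows lower heterozygosity than the open dairy
population, mean F<sub>ST</sub> is a few percent, and three SNPs exceed
their autosome's mean + 3 SD threshold. The swept locus itself was removed
by the pooled Hardy–Weinberg filter (the Wahlund effect at strongly
diverged loci — see the vignette); on the unfiltered matrix it is a clear
outlier:

```r
div_all <- per_locus_stats(sim$genotypes_combined, sim$labels) |> clamp_negative_fst()
fo_all <- fst_outliers(div_all)
sel <- sim$truth[sim$truth$selected, ]
fo_all$snps[fo_all$snps$snp_id == sel$snp_id, c("fst", "threshold", "outlier")]
#>     fst threshold outlier
#> 1 0.346     0.210    TRUE
```

Haplotype scans (0.1-wide frequency bins at this marker count; the fixed
cutoff corresponding to two-sided p < 0.008 is p<sub>iHS</sub> ≥ 2.10):

```r
sc <- ihs_scan(sim$panels$dairy, scan_config(freq_bin_width = 0.1))
cut <- empirical_null_cutoff(sc, mode = "fixed", p_fixed = 0.008)
round(cut$cutoff_pihs, 2)
#> [1] 2.1
sc <- mark_significant(sc, cut$cutoff_pihs)
sum(sc$significant)
#> [1] 3

xp <- xpehh_scan(sim$panels$dairy, sim$panels$beef)
sum(xp$significant, na.rm = TRUE)
#> [1] 11
xp[xp$snp_id == sel$snp_id, c("xpehh", "pxpehh")]
#>   xpehh pxpehh
#> 1  2.34   1.71
```

The swept locus (derived frequency 0.86 in dairy vs 0.28 in beef) scores
XP-EHH = +2.34 — positive, because the sweep inflates the *reference*
population's iES; use `scan_config(sign_convention = "positive_is_reference")`
when interpreting directions on simulated data (vignette, "EHH, iHS and
XP-EHH"). Candidate windows and gene overlap then follow with
`make_windows()`, `overlap_intervals()` and `consensus_genes()`, or run
everything at once with `run_pipeline(sim, out_dir, seed = 1)`, which writes
per-stage TSVs, a BED of candidate windows, and a JSON manifest.

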