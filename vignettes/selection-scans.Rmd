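---
title: "Population structure and selection-signature scans with girscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure and selection-signature scans with girscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girscan)
```

girscan analyses SNP-array genotypes from two recently diverged livestock
populations — the motivating system is a dual-purpose zebu breed split into a
closed beef-selected herd and a multi-farm dairy-selected population — and
asks two questions: how strongly structured are the populations, and which
genomic regions carry signatures of the divergent artificial selection? This
vignette explains the statistics the package implements, the choices behind
their implementation, and what the bundled simulator can and cannot tell you
about behaviour on real data.

## Quality control

`filter_samples()` and `filter_snps()` apply the conventional chip-QC rules:
samples with call rate < 0.90 are dropped, then SNPs that are monomorphic,
have call rate < 0.90, minor allele frequency < 0.01, or an absolute
deviation of the observed heterozygote frequency from its Hardy–Weinberg
expectation $|H_{obs} - 2p(1-p)| > 0.15$. All thresholds are strict
inequalities and every threshold is a `qc_config()` field. The
Hardy–Weinberg rule deserves a note: the conventional phrasing of this
filter ("expected versus observed frequencies differ by more than 0.15") is
ambiguous, since allele frequencies cannot deviate from their own
expectation; the implemented reading — heterozygote frequency against
$2p(1-p)$ — is the standard chip-QC statistic this phrasing paraphrases.

SNP filters run on the pooled sample, in the fixed order monomorphic → call
rate → MAF → heterozygosity deviation, so attrition reports are
reproducible. One consequence worth knowing: at *strongly* diverged loci the
pooled sample shows a heterozygote deficit (the Wahlund effect), so the
Hardy–Weinberg filter preferentially removes exactly the most differentiated
SNPs. With the mild genome-wide differentiation typical of within-breed
comparisons (mean $F_{ST} \approx 0.03$) this is a non-issue, but in
simulations with a strong sweep the swept locus itself can be a casualty;
run the diversity scan before QC if the goal is to study such loci.

## Structure: PCA, K-means/BIC, discriminant axes

`run_pca()` centres each SNP's dosage by twice its allele frequency and, by
default, scales by the binomial standard deviation $\sqrt{2p(1-p)}$, so
rare and common alleles contribute comparable variance. Missing calls are
mean-imputed per SNP before centring (they then sit exactly at the column
mean and contribute nothing to the covariance). The percent variance of a
component is its eigenvalue times 100 divided by the sum of all the
eigenvalues, and the full vector sums to 100.

`select_k_bic()` runs K-means (k-means++ seeding, `n_starts` restarts under
a mandatory seed) on the retained PC scores for each candidate K and scores
each fit with
$$\mathrm{BIC}(K) = n\,\ln(\mathrm{WSS}_K/n) + K \ln n,$$
choosing the smallest K within $10^{-9}$ of the minimum. This is the
documented default so that results are stable across machines; any
monotone-equivalent variant would rank clusterings the same way. A caveat a
user should know: this BIC drifts towards $K > 1$ on *homogeneous* data
whenever samples comfortably outnumber the retained dimensions, because a
2-means split of a Gaussian cloud always removes about $2/\pi$ of the
leading sample-eigenvalue axis, and $n\ln(1 - 0.64\,\lambda_{max}/d)$
eventually beats the $\ln n$ penalty. Inspect the BIC curve (`tidy()`,
`autoplot()`) rather than trusting the argmin blindly — the curve flattens
visibly once real structure is exhausted, which is also how the original
DAPC literature recommends reading it.

`discriminant_functions()` fits linear discriminant axes between the
inferred clusters on the PC scores. At most $K-1$ axes exist; a larger
request (for instance 10 axes with 2 clusters) is clamped with a message
rather than an error, since published analyses routinely request more.

## Diversity and the Fst control chart

`per_locus_stats()` computes, per SNP over populations $k$ with allele
frequencies $p_k$:

* $H_o$: mean observed heterozygote frequency,
* $H_s$: mean of $2p_k(1-p_k)$,
* $H_t$: $2\bar p(1-\bar p)$ with $\bar p$ the *unweighted* mean of the
  population frequencies,
* $F_{ST} = (H_t - H_s)/H_t$ and $F_{IS} = 1 - H_o/H_s$.

Populations are weighted equally regardless of sample size, the
hierarchical-statistics convention, because the two samples (273 vs 173 in
the motivating design) differ in size for reasons unrelated to the biology.
With `corrected = TRUE` the Nei–Chesser small-sample estimators are used:
$\tilde H_s = \frac{\tilde n}{\tilde n - 1}(H_s - H_o/2\tilde n)$ with
$\tilde n$ the harmonic mean sample size, and
$\tilde H_t = H_t + \tilde H_s/(\tilde n k) - H_o/(2 \tilde n k)$. The
corrected estimator is the source of legitimately negative per-locus
$F_{ST}$ values; `clamp_negative_fst()` sets them to zero (they have no
biological interpretation) and reports the count.

Two points about estimator scale matter when validating against theory.
First, with only $k = 2$ demes, Nei's $G_{ST}$ does not estimate the drift
parameter $F = 1 - (1 - 1/2N_e)^t$ but $F/(2-F)$ (about half of it): from
$H_t - H_s = (p_1-p_2)^2/2$ one gets $E[H_t - H_s] = p_0q_0F$ while
$E[H_t] = p_0q_0(2 - F)$. The package's tests therefore recover the drift
parameter as $2G/(1+G)$ from the pooled ratio-of-sums $G$, and that mapping
is what a user should apply when comparing two-population $F_{ST}$ values
with drift expectations (`expected_fst()`).

`fst_outliers()` implements the control-chart rule: a SNP is an outlier
when its clamped $F_{ST}$ exceeds the mean plus three standard deviations of
the values in scope. The default scope is per chromosome; genome-wide is
available because the two conventions genuinely differ when differentiation
varies between chromosomes. Chromosomes with fewer than two defined values
get no threshold and a warning.

## EHH, iHS and XP-EHH

Extended haplotype homozygosity at marker $m$ around a focal SNP is
$$\mathrm{EHH}(m) = \frac{\sum_h \binom{n_h}{2}}{\binom{n}{2}},$$
where $n_h$ counts carrier haplotypes identical at every marker from the
focal SNP to $m$. For the ancestral/derived cores the carriers all share the
focal allele, so EHH starts at exactly 1; for the allele-agnostic *site*
core (the XP-EHH building block) the focal alleles themselves split the
haplotype classes, so EHH starts at the focal SNP's haplotype homozygosity.
These two conventions cannot be reconciled with a single "EHH(focal) = 1"
rule, and the package follows the definition (identity over the closed
interval) for the site core, which is the convention under which iES sums
behave like Sabeti-style integrals.

Each flank is followed outward until EHH drops below `ehh_floor` (default
0.05; the final trapezoid down to that marker is included), an inter-marker
gap exceeds `max_gap_bp` (default 20 kb; the flank simply ends, no gap
rescaling), or the chromosome ends (the curve is kept and flagged
border-truncated). `integrate_ehh()` is a trapezoid over physical distance
in bp, so iHH is in bp·EHH units; physical rather than genetic distance is
used because the motivating analysis supplied the physical map. The inner
walk is compiled code (a partition-refinement sweep, linear per marker in
the number of haplotypes); a pure-R pair-enumeration oracle in the test
suite checks it exactly on small panels.

`ihs_scan()` computes, per focal SNP passing the MAF filter (default 0.01),
$\mathrm{UniHS} = \ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, then standardises
within derived-allele-frequency bins (subtract bin mean, divide by bin SD).
Natural log is used; the base is immaterial after standardisation. The
default bin width is 0.01, matching an analysis of ~23,000 post-QC SNPs
where each 1% bin still holds hundreds of SNPs. **Bin width must scale with
marker count**: bins need at least 2 SNPs to standardise at all (sparser
bins are flagged and left unstandardised), and bins with only a few dozen
SNPs truncate the score tails (the largest attainable $|z|$ within a bin of
$n$ SNPs is $(n-1)/\sqrt n$). Desk-scale analyses in this package's tests
use 0.1-width bins for that reason, and the nominal 5% tail mass beyond
$|z| = 1.96$ is only recovered with well-filled bins.

The significance transform is
$$p_{iHS} = -\log_{10}\!\big(1 - 2\,|\Phi(\mathrm{iHS}) - 0.5|\big)
          = -\log_{10}\!\big(2\,\Phi(-|\mathrm{iHS}|)\big),$$
a two-sided Gaussian p-value on the $-\log_{10}$ scale. The second form is
the implemented one: the first loses all precision past $|x| \approx 6$ to
cancellation, and reproducing a score of $-7.02 \to 11.65$ requires the
complementary-tail evaluation (`pihs_transform()` uses `pnorm(log.p)`).

`xpehh_scan()` integrates the site-EHH (iES) in each population, forms
$\mathrm{LRiES} = \ln(\mathrm{iES}_{ref}/\mathrm{iES}_{obs})$, and
standardises by the *median* and SD over all scored SNPs (the median guards
the centre against the selected tail). SNPs beyond the two-sided 1% Gaussian
threshold are significant; no further multiple-testing correction is
applied, matching the motivating analysis. Ancestral alleles are not needed.

The sign convention is deliberately configuration-driven. With the
reference population in the numerator, a sweep *in the reference* inflates
$\mathrm{iES}_{ref}$ and gives a **positive** score — yet the motivating
study states, and its tables reflect, that negative scores mark selection in
the reference population. The formula and the prose cannot both be right,
so `scan_config(sign_convention=)` decides how the `direction` column is
assigned: the default `negative_is_reference` reproduces the published
reading, while `positive_is_reference` matches the formula's arithmetic and
is what the bundled simulator's ground truth confirms (a simulated sweep in
the reference population produces positive scores). Users of the simulator
should prefer the latter; users reproducing the published convention should
keep the default. The two-sided significance flag is unaffected either way.

## The iHS significance cutoff

`empirical_null_cutoff()` has two modes. `fixed` converts a chosen two-sided
p-value to the $p_{iHS}$ scale ($p = 0.008 \to 2.10$, $p = 0.006 \to 2.20$).
`empirical_null` estimates the null proportion $\eta_0$ from the upper tail
of the p-value distribution (mean density on $[\tau, 1]$, $\tau = 0.75$,
clipped to 1) and returns the largest p-value whose estimated tail false
discovery proportion $\eta_0\,p\,n / \#\{p_i \le p\}$ stays below
`fdr_level` (default 0.05); when nothing qualifies it falls back to the
Šidák-style per-comparison point $1 - (1-\alpha)^{1/n}$, so a pure-null scan
always yields a cutoff more stringent than any conventional per-SNP
threshold. This is a documented approximation to the local-false-nondiscovery
machinery of the tool the motivating analysis cited, whose exact algorithm
is not described there; the fixed mode reproduces that study's printed
thresholds exactly.

## Candidate windows and gene overlap

`make_windows()` builds $\pm 250$ kb windows (500 kb total) around
significant SNPs, clips them at position 1 (and at the chromosome end when
lengths are supplied), and merges overlapping windows *within* a method ×
population group, keeping the peak SNP with the largest absolute score —
merging across methods would destroy the per-method tallies that the
consensus step needs. `overlap_intervals()` reports any 1-bp-or-more
overlap, 1-based inclusive on both ends; BED input is converted from
0-based half-open at the reader boundary, so a BED record
`16 25895747 25936856` becomes the 1-based interval 25,895,748–25,936,856.
`consensus_genes()` unions hits across methods and can filter to genes
supported by two or more approaches.

## The simulator: what it emulates and what it does not

`simulate_divergence()` is a forward Wright–Fisher simulator chosen over a
coalescent because divergent selection and unequal population sizes are then
direct: an ancestral population at linkage equilibrium with
ascertainment-like initial derived-allele frequencies (uniform on
[0.05, 0.95]) is evolved for a burn-in (default $2 N_e^{anc}$ generations —
the pairwise coalescent depth, so neutral haplotypes acquire a realistic
*age structure*; a short burn-in leaves every haplotype young and
artificially inflates background EHH), then split into two populations that
drift for `t_split` generations with additive selection (fitnesses
$1, 1+s, 1+2s$) at designated loci, random mating, and recombination as an
at-most-one-crossover-per-chromosome Markov walk (exact Poisson crossover
counts behind `multiple_crossovers = TRUE`; at the simulated map lengths of
$\sim 0.3$ expected crossovers per chromosome the approximation is
accurate). Selected standing variants are planted at their configured
frequency *at the split*, on random haplotype backgrounds, so that burn-in
drift can neither lose nor inflate them — selection in this system begins
with the breed split, not before.

The default study conditions mirror the motivating populations at desk
scale: three 3-Mb autosomes with 300 jittered-grid markers each (~10 kb
spacing), a per-bp recombination rate of $10^{-7}$ (a scaled-down map: with
markers 10× denser in bp than a real LD chip, scaling $r$ up 10× keeps the
genetic length per marker interval realistic), an open "dairy" population of
$N_e = 300$ against a closed "beef" herd of $N_e = 120$ (lower
heterozygosity, more relatedness), a split ~50 generations ago, and samples
of 60 and 40 diploids. Everything is seeded and byte-reproducible.

What the simulator does **not** emulate: mutation (the marker panel is
fixed, like an array, so burn-in drift fixes a substantial fraction of
SNPs — they are simply monomorphic in the output, as real chips also carry
monomorphic markers, and QC removes them); the deep, heterogeneous
coalescent structure of a real cattle breed ($N_e$ in the hundreds here
versus effective histories of thousands); chip ascertainment against an
external discovery panel; genotyping error and missingness (panels are
complete — the scans require complete phased input by contract); and the
sex chromosomes. Consequently, passing tests demonstrate the *statistics
are computed correctly* and behave sensibly under drift and selection at
small scale; they do not certify power on real data.

On power: at desk-scale $N_e$ (a few hundred), the background iHH integral
is dominated by recently coalesced haplotype pairs, and the minor-allele
core at a swept SNP — a handful of carriers in a small population — has
iHH comparable to the sweep's own derived core. The attainable
$|\mathrm{iHS}|$ z-score of even an established single-origin sweep
saturates around 2–3, which is also where the top-1% boundary of a
forced-standard distribution sits, so single-locus rank-based sweep
recovery is intrinsically unreliable in this regime (the package's tests
assert the aggregate derived-iHH excess over replicates instead). iHS is a
large-$N_e$ statistic; the motivating study's real data, with breed
histories orders of magnitude deeper, is the regime it was designed for.
$F_{ST}$ outlier recovery of simulated sweeps, by contrast, works well at
desk scale.

## Numerical and design choices, in brief

* Coordinates are 1-based inclusive bp throughout; BED converts at the
  boundary. Marker maps must be strictly increasing within chromosome;
  containers sort on construction.
* Ancestral-allele recoding matches on the reported strand only; A/T and
  C/G SNPs, SNPs whose ancestral allele matches neither observed allele,
  and SNPs with unknown ancestral state become missing, with a per-SNP
  report. Scans then require those markers to be dropped
  (`subset_markers()`) — the package performs no imputation by design.
* K-means uses Euclidean distance, k-means++ seeding, 10 restarts, and a
  mandatory seed; empty-cluster fits are retried and count as degenerate
  restarts. Ties in BIC resolve to the smallest K within $10^{-9}$.
* Per-bin iHS standardisation requires ≥ 2 SNPs and positive SD; XP-EHH
  standardisation requires ≥ 10 scored SNPs. Undefined EHH curves (< 2
  core carriers) are flagged, not errors; zero iHH skips the SNP with a
  recorded reason.
* Test problem sizes are chosen for single-CPU desk scale: panels of a few
  hundred SNPs and tens of samples for unit properties, 30 neutral
  replicates for drift recovery, 50 replicates at $N_e = 200$, $t = 50$,
  $s = 0.1$ for the sweep-recovery experiment, and the default
  900-SNP/100-sample configuration for the end-to-end determinism check.
* `run_pipeline()` writes every stage's TSV as soon as the stage completes
  plus a JSON manifest of stage status, counts and thresholds; reruns with
  the same inputs and seed are byte-identical, and a failing stage leaves
  partial outputs plus the manifest naming it.
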