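# Marker and sample quality control: monomorphic, call-rate, MAF and
# heterozygosity-deviation filters, applied in a fixed order so attrition
# counts are reproducible. All thresholds are strict inequalities.

#' Quality-control configuration
#'
#' Thresholds for [filter_snps()] and [filter_samples()]. A SNP is removed
#' when it is monomorphic, has a call rate strictly below
#' `snp_call_rate_min`, a minor allele frequency strictly below `maf_min`, or
#' an absolute difference between observed heterozygote frequency and the
#' Hardy-Weinberg expectation 2p(1-p) strictly above `hwe_het_dev_max`.
#' Samples are removed when their call rate is strictly below
#' `sample_call_rate_min`.
#'
#' @param snp_call_rate_min,sample_call_rate_min Minimum call rates.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_het_dev_max Maximum |observed het - 2p(1-p)|.
#' @param drop_monomorphic Drop monomorphic SNPs first?
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(snp_call_rate_min = 0.90, sample_call_rate_min = 0.90,
                      maf_min = 0.01, hwe_het_dev_max = 0.15,
                      drop_monomorphic = TRUE) {
  fr <- c(snp_call_rate_min, sample_call_rate_min, maf_min, hwe_het_dev_max)
  if (any(fr < 0) || any(fr > 1)) abort("all QC fractions must be in [0, 1]")
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 maf_min = maf_min, hwe_het_dev_max = hwe_het_dev_max,
                 drop_monomorphic = isTRUE(drop_monomorphic)),
            class = "qc_config")
}

#' Per-SNP allele frequencies
#'
#' Frequency of the counted allele, overall and (optionally) per population.
#' The overall frequency is the called-allele-weighted mean; a SNP with no
#' calls in a stratum gets `NA` there, never 0.
#'
#' @param g A [geno_matrix()].
#' @param labels Optional tibble with `sample_id`, `population`.
#' @return A tibble with `snp_id`, `chrom`, `pos_bp`, `n_called`, `p`, `maf`
#'   and, when labels are given, one `p_<population>` and `n_<population>`
#'   column pair per population.
#' @export
allele_frequencies <- function(g, labels = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  called <- unname(colSums(!is.na(g$calls)))
  p <- unname(ifelse(called > 0, colMeans(g$calls, na.rm = TRUE) / 2,
                     NA_real_))
  out <- tibble(snp_id = g$map$snp_id, chrom = g$map$chrom,
                pos_bp = g$map$pos_bp, n_called = as.integer(called),
                p = p, maf = pmin(p, 1 - p))
  if (!is.null(labels)) {
    lab <- check_labels(labels, g$samples)
    for (pop in sort(unique(lab))) {
      rows <- lab == pop
      nk <- unname(colSums(!is.na(g$calls[rows, , drop = FALSE])))
      pk <- unname(ifelse(nk > 0,
                          colMeans(g$calls[rows, , drop = FALSE],
                                   na.rm = TRUE) / 2,
                          NA_real_))
      out[[paste0("p_", pop)]] <- pk
      out[[paste0("n_", pop)]] <- as.integer(nk)
    }
  }
  out
}

snp_stats <- function(g) {
  calls <- unname(g$calls)
  called <- colSums(!is.na(calls))
  call_rate <- called / nrow(calls)
  p <- ifelse(called > 0, colMeans(calls, na.rm = TRUE) / 2, NA_real_)
  het <- ifelse(called > 0, colMeans(calls == 1L, na.rm = TRUE), NA_real_)
  list(call_rate = call_rate, p = p, maf = pmin(p, 1 - p), het_obs = het)
}

#' Filter SNPs on quality-control rules
#'
#' Applies, in order: monomorphic, call rate, MAF, heterozygosity deviation
#' from Hardy-Weinberg expectation. Each rule sees only the SNPs surviving
#' the previous one, so the attrition report reconciles exactly.
#'
#' @param g A [geno_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (tibble: rule, removed, surviving).
#' @export
filter_snps <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "qc_config"))
  keep <- rep(TRUE, ncol(g$calls))
  report <- list()
  note <- function(rule, removed) {
    report[[length(report) + 1L]] <<-
      tibble(rule = rule, removed = removed, surviving = sum(keep))
  }
  st <- snp_stats(g)
  if (cfg$drop_monomorphic) {
    mono <- !is.na(st$p) & (st$p == 0 | st$p == 1)
    keep <- keep & !mono
    note("monomorphic", sum(mono))
  }
  cr <- keep & (st$call_rate < cfg$snp_call_rate_min)
  keep <- keep & !cr
  note("snp_call_rate", sum(cr))
  mf <- keep & (is.na(st$maf) | st$maf < cfg$maf_min)
  keep <- keep & !mf
  note("maf", sum(mf))
  hw <- keep & !is.na(st$het_obs) &
    (abs(st$het_obs - 2 * st$p * (1 - st$p)) > cfg$hwe_het_dev_max)
  keep <- keep & !hw
  note("hwe_het_deviation", sum(hw))
  if (!any(keep)) {
    abort("no SNPs survive quality control; review the thresholds")
  }
  list(genotypes = geno_matrix(g$calls[, keep, drop = FALSE], g$map[keep, ],
                               g$samples),
       report = bind_rows(report))
}

#' Filter samples on call rate
#'
#' @param g A [geno_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `genotypes` and `report` as in [filter_snps()].
#' @export
filter_samples <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "geno_matrix"), inherits(cfg, "qc_config"))
  call_rate <- rowMeans(!is.na(g$calls))
  keep <- call_rate >= cfg$sample_call_rate_min
  if (!any(keep)) abort("no samples survive quality control")
  list(genotypes = geno_matrix(g$calls[keep, , drop = FALSE], g$map,
                               g$samples[keep]),
       report = tibble(rule = "sample_call_rate", removed = sum(!keep),
                       surviving = sum(keep)))
}

#' Run the full QC pass
#'
#' Samples are filtered first, then SNPs, matching a single pooled QC pass
#' before any per-population analysis.
#'
#' @param g A [geno_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `genotypes` and the combined `report`.
#' @export
run_qc <- function(g, cfg = qc_config()) {
  s <- filter_samples(g, cfg)
  m <- filter_snps(s$genotypes, cfg)
  list(genotypes = m$genotypes,
       report = bind_rows(mutate(s$report, axis = "sample"),
                          mutate(m$report, axis = "snp")))
}
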