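# Per-locus diversity across populations, after Nei: observed heterozygosity
# Ho, within-population gene diversity Hs, total gene diversity Ht, Fis and
# Fst = (Ht - Hs) / Ht. Populations are weighted equally (unweighted means of
# per-population quantities), the hierarchical-statistics convention, since
# sample sizes can differ between populations.

#' Per-locus diversity statistics
#'
#' For each SNP, per population k with allele frequency p_k: `Ho` is the mean
#' observed heterozygote frequency, `Hs` the mean of `2 p_k (1 - p_k)`, `Ht`
#' is `2 p̄ (1 - p̄)` with p̄ the unweighted mean of the population
#' frequencies, `Fst_raw = (Ht - Hs) / Ht` and `Fis = 1 - Ho / Hs`. With
#' `corrected = TRUE` the Nei-Chesser small-sample estimators are used
#' instead (the source of legitimately negative Fst values):
#' `Hs* = ñ/(ñ-1) (Hs - Ho/(2ñ))` with ñ the harmonic mean per-population
#' sample size, and `Ht* = Ht + Hs*/(ñ k) - Ho/(2 ñ k)`.
#'
#' A SNP where a population has fewer than 2 genotyped samples is flagged
#' undefined; a SNP with `Ht = 0` has undefined Fst (excluded from means).
#'
#' @param g A [geno_matrix()].
#' @param labels Tibble with `sample_id`, `population` (2 or more
#'   populations).
#' @param corrected Apply the small-sample corrections?
#' @return A tibble with per-SNP `ho`, `hs`, `ht`, `fis`, `fst_raw`,
#'   per-population `p_<pop>`, `ho_<pop>`, `n_<pop>` columns, and a
#'   `defined` flag.
#' @export
per_locus_stats <- function(g, labels, corrected = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  lab <- check_labels(labels, g$samples)
  pops <- sort(unique(lab))
  npop <- length(pops)
  if (npop < 2L) abort("diversity statistics need at least 2 populations")

  nmat <- pmat <- homat <- matrix(NA_real_, ncol(g$calls), npop,
                                  dimnames = list(NULL, pops))
  for (i in seq_along(pops)) {
    sub <- g$calls[lab == pops[i], , drop = FALSE]
    nk <- colSums(!is.na(sub))
    nmat[, i] <- nk
    pmat[, i] <- ifelse(nk > 0, colMeans(sub, na.rm = TRUE) / 2, NA_real_)
    homat[, i] <- ifelse(nk > 0, colMeans(sub == 1L, na.rm = TRUE), NA_real_)
  }
  defined <- rowSums(nmat >= 2) == npop

  ho <- rowMeans(homat)
  hs_plug <- rowMeans(2 * pmat * (1 - pmat))
  pbar <- rowMeans(pmat)
  ht_plug <- 2 * pbar * (1 - pbar)
  if (corrected) {
    ntilde <- npop / rowSums(1 / nmat)
    hs <- ntilde / (ntilde - 1) * (hs_plug - ho / (2 * ntilde))
    ht <- ht_plug + hs / (ntilde * npop) - ho / (2 * ntilde * npop)
  } else {
    hs <- hs_plug
    ht <- ht_plug
  }
  fst_raw <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  fis <- ifelse(hs > 0, 1 - ho / hs, NA_real_)

  out <- tibble(snp_id = g$map$snp_id, chrom = g$map$chrom,
                pos_bp = g$map$pos_bp, defined = defined,
                ho = ho, hs = hs, ht = ht, fis = fis, fst_raw = fst_raw)
  out[!defined, c("ho", "hs", "ht", "fis", "fst_raw")] <- NA_real_
  for (i in seq_along(pops)) {
    out[[paste0("p_", pops[i])]] <- pmat[, i]
    out[[paste0("ho_", pops[i])]] <- homat[, i]
    out[[paste0("n_", pops[i])]] <- as.integer(nmat[, i])
  }
  attr(out, "populations") <- pops
  attr(out, "corrected") <- corrected
  out
}

#' Set negative Fst values to zero
#'
#' Negative per-locus Fst estimates have no biological interpretation and are
#' clamped to zero; the number of clamped SNPs is attached as attribute
#' `n_clamped` and reported by [diversity_overall()].
#'
#' @param table Output of [per_locus_stats()].
#' @return The table with an added `fst` column (`max(fst_raw, 0)`).
#' @export
clamp_negative_fst <- function(table) {
  stopifnot("fst_raw" %in% names(table))
  table$fst <- pmax(table$fst_raw, 0)
  attr(table, "n_clamped") <- sum(table$fst_raw < 0, na.rm = TRUE)
  table
}

#' Flag Fst outliers by the control-chart rule
#'
#' A SNP is an outlier when its (clamped) Fst exceeds the mean plus `k_sd`
#' standard deviations of the Fst values in scope -- per chromosome by
#' default, optionally genome-wide. Chromosomes with fewer than 2 defined
#' Fst values get no threshold (warning) and no outliers.
#'
#' @param table Output of [clamp_negative_fst()].
#' @param k_sd Number of standard deviations above the mean.
#' @param scope `"per_chromosome"` or `"genome_wide"`.
#' @return A list with `snps` (the table plus `threshold` and `outlier`
#'   columns) and `thresholds` (per scope unit: n, mean, sd, threshold).
#' @export
fst_outliers <- function(table, k_sd = 3,
                         scope = c("per_chromosome", "genome_wide")) {
  scope <- match.arg(scope)
  if (!"fst" %in% names(table)) {
    abort("run clamp_negative_fst() before fst_outliers()")
  }
  tab <- as_tibble(table)
  tab$.unit <- if (scope == "per_chromosome") tab$chrom else 0L
  thr <- tab %>%
    filter(!is.na(.data$fst)) %>%
    group_by(.data$.unit) %>%
    summarise(n = dplyr::n(), mean_fst = mean(.data$fst),
              sd_fst = stats::sd(.data$fst), .groups = "drop") %>%
    mutate(threshold = ifelse(.data$n >= 2,
                              .data$mean_fst + k_sd * .data$sd_fst, NA_real_))
  if (any(thr$n < 2)) {
    warn(paste0("scope unit(s) with < 2 defined Fst values have no threshold: ",
                paste(thr$.unit[thr$n < 2], collapse = ", ")))
  }
  tab <- left_join(tab, thr[, c(".unit", "threshold")], by = ".unit")
  tab$outlier <- !is.na(tab$fst) & !is.na(tab$threshold) &
    tab$fst > tab$threshold
  tab$.unit <- NULL
  names(thr)[names(thr) == ".unit"] <-
    if (scope == "per_chromosome") "chrom" else "scope"
  list(snps = tab, thresholds = thr)
}

#' Genome-wide diversity summary
#'
#' Mean Fst over defined loci, clamped-SNP count, and per-population mean Ho
#' and overall Fis (`1 - sum(Ho_k) / sum(Hs_k)`, the ratio-of-sums
#' convention).
#'
#' @param table Output of [clamp_negative_fst()] (or [per_locus_stats()]).
#' @return A one-row tibble of global summaries plus one `fis_<pop>` /
#'   `mean_ho_<pop>` pair per population.
#' @export
diversity_overall <- function(table) {
  pops <- attr(table, "populations")
  out <- tibble(
    n_snps = nrow(table),
    n_defined = sum(table$defined),
    mean_fst = if ("fst" %in% names(table)) {
      mean(table$fst, na.rm = TRUE)
    } else {
      mean(pmax(table$fst_raw, 0), na.rm = TRUE)
    },
    mean_fst_raw = mean(table$fst_raw, na.rm = TRUE),
    n_clamped = attr(table, "n_clamped") %||%
      sum(table$fst_raw < 0, na.rm = TRUE),
    mean_fis = 1 - sum(table$ho, na.rm = TRUE) / sum(table$hs, na.rm = TRUE))
  for (pop in pops) {
    hok <- table[[paste0("ho_", pop)]]
    pk <- table[[paste0("p_", pop)]]
    hsk <- 2 * pk * (1 - pk)
    out[[paste0("mean_ho_", pop)]] <- mean(hok, na.rm = TRUE)
    out[[paste0("fis_", pop)]] <- 1 - sum(hok, na.rm = TRUE) / sum(hsk, na.rm = TRUE)
  }
  out
}

#' Mean observed heterozygosity per chromosome and population
#'
#' @param g A [geno_matrix()].
#' @param labels Tibble with `sample_id`, `population`.
#' @return A tibble with one row per chromosome, one `ho_<pop>` column per
#'   population and a `diff` column (first population minus second, in sorted
#'   population order) when exactly two populations are present.
#' @export
per_chromosome_heterozygosity <- function(g, labels) {
  stopifnot(inherits(g, "geno_matrix"))
  lab <- check_labels(labels, g$samples)
  pops <- sort(unique(lab))
  out <- tibble(chrom = sort(unique(g$map$chrom)))
  for (pop in pops) {
    sub <- g$calls[lab == pop, , drop = FALSE]
    ho <- colMeans(sub == 1L, na.rm = TRUE)
    agg <- tapply(ho, g$map$chrom, mean, na.rm = TRUE)
    out[[paste0("ho_", pop)]] <- as.numeric(agg[as.character(out$chrom)])
  }
  if (length(pops) == 2L) {
    out$diff <- out[[paste0("ho_", pops[1])]] - out[[paste0("ho_", pops[2])]]
  }
  out
}
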