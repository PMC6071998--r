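# Haplotype-based selection scans. EHH decays outward from a focal SNP; its
# integral over physical distance (iHH per core allele, iES for the
# allele-agnostic site core) feeds the iHS and XP-EHH statistics. Scores are
# standardised (iHS within derived-allele-frequency bins; XP-EHH by median
# and SD genome-wide) and mapped to -log10 two-sided Gaussian p-values.

#' Selection-scan configuration
#'
#' @param ehh_floor Stop integrating a flank once EHH drops below this value
#'   (the final trapezoid down to that marker is included).
#' @param max_gap_bp An inter-marker gap larger than this ends the flank.
#' @param maf Minimum minor (derived) allele frequency for a focal SNP to be
#'   scored in the iHS scan.
#' @param freq_bin_width Width of the derived-allele-frequency bins used to
#'   standardise iHS.
#' @param xpehh_alpha Two-sided p-value threshold for XP-EHH significance.
#' @param sign_convention Which sign marks selection in the reference
#'   population: `"negative_is_reference"` (default) or
#'   `"positive_is_reference"`.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(ehh_floor = 0.05, max_gap_bp = 20000, maf = 0.01,
                        freq_bin_width = 0.01, xpehh_alpha = 0.01,
                        sign_convention = c("negative_is_reference",
                                            "positive_is_reference")) {
  sign_convention <- match.arg(sign_convention)
  if (ehh_floor <= 0 || ehh_floor >= 1) abort("ehh_floor must be in (0, 1)")
  if (freq_bin_width <= 0 || freq_bin_width > 0.5) {
    abort("freq_bin_width must be in (0, 0.5]")
  }
  structure(list(ehh_floor = ehh_floor, max_gap_bp = max_gap_bp, maf = maf,
                 freq_bin_width = freq_bin_width, xpehh_alpha = xpehh_alpha,
                 sign_convention = sign_convention),
            class = "scan_config")
}

check_complete <- function(panel, what) {
  if (anyNA(panel$haps)) {
    abort(paste0(what, " requires a complete phased panel (no missing ",
                 "alleles); markers set missing by recoding must be dropped ",
                 "first, e.g. with subset_markers()"))
  }
}

resolve_focal <- function(panel, focal) {
  if (is.character(focal)) {
    i <- match(focal, panel$map$snp_id)
    if (is.na(i)) abort(paste0("unknown focal SNP: ", focal))
    i
  } else {
    i <- as.integer(focal)
    if (i < 1L || i > nrow(panel$map)) abort("focal index out of range")
    i
  }
}

#' EHH decay curve around a focal SNP
#'
#' EHH at a marker m is the probability that two randomly chosen carrier
#' haplotypes are identical over the interval from the focal SNP to m:
#' `sum_h C(n_h, 2) / C(n, 2)` over the haplotype classes h spanning the
#' interval. For the `ancestral`/`derived` cores, carriers are the haplotypes
#' bearing that allele at the focal SNP and EHH starts at 1 there; for the
#' `site` core all haplotypes are used and EHH starts at the focal SNP's
#' haplotype homozygosity (the iES building block). Each flank is followed
#' until EHH falls below `ehh_floor`, an inter-marker gap exceeds
#' `max_gap_bp`, or the chromosome ends (flagged border-truncated).
#'
#' @param panel A complete [hap_panel()]; ancestral/derived coding is
#'   required for allele cores.
#' @param focal Focal SNP id or column index.
#' @param core `"ancestral"`, `"derived"` or `"site"`.
#' @param cfg A [scan_config()].
#' @return An `ehh_curve`: tibble with `snp_id`, `pos_bp`, `distance_bp`,
#'   `side`, `ehh`, with attributes `focal` (id), `core`,
#'   `n_haplotypes_retained`, `stop_left`/`stop_right`
#'   (`floor`/`gap`/`chrom_end`), `undefined` and `border_truncated`.
#' @export
ehh_decay <- function(panel, focal, core = c("ancestral", "derived", "site"),
                      cfg = scan_config()) {
  stopifnot(inherits(panel, "hap_panel"))
  core <- match.arg(core)
  if (core != "site" && panel$coding != "ancestral") {
    abort("allele cores require a panel recoded to ancestral/derived")
  }
  i <- resolve_focal(panel, focal)
  chrom <- panel$map$chrom[i]
  on_chrom <- which(panel$map$chrom == chrom)
  H <- panel$haps[, on_chrom, drop = FALSE]
  if (anyNA(H)) check_complete(list(haps = H), "ehh_decay")
  pos <- panel$map$pos_bp[on_chrom]
  j <- match(i, on_chrom)

  carriers <- switch(core,
                     ancestral = which(H[, j] == 0L),
                     derived = which(H[, j] == 1L),
                     site = seq_len(nrow(H)))
  meta <- list(focal = panel$map$snp_id[i], focal_pos = panel$map$pos_bp[i],
               chrom = chrom, core = core,
               n_haplotypes_retained = length(carriers))
  if (length(carriers) < 2L) {
    out <- tibble(snp_id = character(), pos_bp = numeric(),
                  distance_bp = numeric(), side = character(),
                  ehh = numeric())
    attributes(out) <- c(attributes(out), meta,
                         list(undefined = TRUE, border_truncated = FALSE))
    class(out) <- c("ehh_curve", class(out))
    return(out)
  }
  w <- cpp_ehh_walk(H, carriers - 1L, pos, j - 1L, cfg$ehh_floor,
                    cfg$max_gap_bp, core == "site")
  stop_lab <- c("floor", "gap", "chrom_end")
  li <- rev(w$left_idx) + 1L
  ri <- w$right_idx + 1L
  out <- tibble(
    snp_id = panel$map$snp_id[on_chrom][c(li, j, ri)],
    pos_bp = pos[c(li, j, ri)],
    distance_bp = abs(pos[c(li, j, ri)] - pos[j]),
    side = c(rep("left", length(li)), "focal", rep("right", length(ri))),
    ehh = c(rev(w$left_ehh), w$ehh0, w$right_ehh))
  attributes(out) <- c(attributes(out), meta, list(
    undefined = FALSE,
    stop_left = stop_lab[w$left_stop + 1L],
    stop_right = stop_lab[w$right_stop + 1L],
    border_truncated = w$left_stop == 2L || w$right_stop == 2L))
  class(out) <- c("ehh_curve", class(out))
  out
}

#' Integrate an EHH decay curve
#'
#' Trapezoidal integral of EHH over physical distance, both flanks summed.
#' Truncation follows the curve itself: a flank that stopped at the EHH floor
#' contributes its final trapezoid down to the first marker below the floor;
#' a flank cut by a gap or the chromosome end is integrated to its last
#' marker.
#'
#' @param curve An `ehh_curve` from [ehh_decay()].
#' @return iHH in bp x EHH units (`NA` for an undefined curve).
#' @export
integrate_ehh <- function(curve) {
  stopifnot(inherits(curve, "ehh_curve"))
  if (isTRUE(attr(curve, "undefined"))) return(NA_real_)
  total <- 0
  for (s in c("left", "right")) {
    seg <- curve[curve$side %in% c("focal", s), ]
    seg <- seg[order(seg$distance_bp), ]
    if (nrow(seg) > 1L) {
      total <- total + sum(0.5 * (seg$ehh[-1] + seg$ehh[-nrow(seg)]) *
                             diff(seg$distance_bp))
    }
  }
  total
}

#' -log10 two-sided Gaussian p-value of a standardised score
#'
#' Computes `-log10(1 - 2|Phi(x) - 0.5|)` via the equivalent, numerically
#' stable complementary tail `-log10(2 Phi(-|x|))`, so extreme scores (|x| >
#' 6) do not lose precision to cancellation. Symmetric in the sign of the
#' score; 0 maps to 0.
#'
#' @param score Finite standardised score(s).
#' @return `-log10` two-sided p-value(s), non-negative.
#' @export
pihs_transform <- function(score) {
  if (any(!is.finite(score))) abort("scores must be finite")
  -(pnorm(-abs(score), log.p = TRUE) + log(2)) / log(10)
}

#' @rdname pihs_transform
#' @export
pxpehh_transform <- pihs_transform

# iHH over all markers of a panel, chromosome by chromosome.
panel_ihh <- function(panel, cfg) {
  m <- nrow(panel$map)
  out <- matrix(NA_real_, m, 5,
                dimnames = list(NULL, c("ihh_a", "ihh_d", "n_anc", "n_der",
                                        "border")))
  for (chrom in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == chrom)
    out[idx, ] <- cpp_scan_ihh(panel$haps[, idx, drop = FALSE],
                               panel$map$pos_bp[idx],
                               cfg$ehh_floor, cfg$max_gap_bp)
  }
  out
}

panel_ies <- function(panel, cfg) {
  m <- nrow(panel$map)
  out <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("ies", "border")))
  for (chrom in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == chrom)
    out[idx, ] <- cpp_scan_ies(panel$haps[, idx, drop = FALSE],
                               panel$map$pos_bp[idx],
                               cfg$ehh_floor, cfg$max_gap_bp)
  }
  out
}

#' Within-population iHS scan
#'
#' For every focal SNP passing the MAF filter, integrates the EHH decay for
#' the ancestral and derived cores, forms `UniHS = ln(iHH_A / iHH_D)`, and
#' standardises it within derived-allele-frequency bins of width
#' `freq_bin_width` (subtracting the bin mean and dividing by the bin SD).
#' `piHS` is the -log10 two-sided Gaussian p-value of the standardised score.
#' SNPs in bins with fewer than 2 scored SNPs are left unstandardised and
#' flagged `sparse_bin`; SNPs with a zero or undefined iHH on either core are
#' skipped with a reason.
#'
#' @param panel A complete [hap_panel()] in ancestral/derived coding.
#' @param cfg A [scan_config()].
#' @return A tibble with one row per SNP: `snp_id`, `chrom`, `pos_bp`,
#'   `freq_derived`, `ihh_a`, `ihh_d`, `unihs`, `ihs`, `pihs`,
#'   `border_truncated`, `skip_reason` (`NA` = scored).
#' @export
ihs_scan <- function(panel, cfg = scan_config()) {
  stopifnot(inherits(panel, "hap_panel"))
  if (panel$coding != "ancestral") {
    abort("ihs_scan requires a panel recoded to ancestral/derived")
  }
  check_complete(panel, "ihs_scan")
  ih <- panel_ihh(panel, cfg)
  nhap <- nrow(panel$haps)
  freq <- ih[, "n_der"] / nhap
  out <- tibble(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                pos_bp = panel$map$pos_bp, freq_derived = freq,
                ihh_a = ih[, "ihh_a"], ihh_d = ih[, "ihh_d"],
                border_truncated = ih[, "border"] == 1,
                skip_reason = NA_character_)
  out$skip_reason[freq < cfg$maf | freq > 1 - cfg$maf] <- "maf"
  zero_or_na <- is.na(out$skip_reason) &
    (is.na(out$ihh_a) | is.na(out$ihh_d) | out$ihh_a == 0 | out$ihh_d == 0)
  out$skip_reason[zero_or_na] <- "zero_ihh"
  scored <- is.na(out$skip_reason)
  out$unihs <- ifelse(scored, log(out$ihh_a / out$ihh_d), NA_real_)

  # frequency-bin standardisation
  bin <- ceiling(pmax(freq, 1e-12) / cfg$freq_bin_width)
  out$ihs <- NA_real_
  for (b in unique(bin[scored])) {
    in_bin <- scored & bin == b
    if (sum(in_bin) >= 2L && stats::sd(out$unihs[in_bin]) > 0) {
      out$ihs[in_bin] <- (out$unihs[in_bin] - mean(out$unihs[in_bin])) /
        stats::sd(out$unihs[in_bin])
    } else {
      out$skip_reason[in_bin] <- "sparse_bin"
    }
  }
  out$pihs <- NA_real_
  out$pihs[!is.na(out$ihs)] <- pihs_transform(out$ihs[!is.na(out$ihs)])
  out
}

#' Cross-population XP-EHH scan
#'
#' Integrates the allele-agnostic site EHH (iES) in each population, forms
#' `LRiES = ln(iES_ref / iES_obs)` per SNP, and standardises by the median
#' and SD of LRiES over all scored SNPs. `pXP-EHH` is the -log10 two-sided
#' Gaussian p-value; a SNP is significant when it exceeds
#' `-log10(xpehh_alpha)`. The `direction` column assigns the population under
#' selection from the sign of the score according to
#' `cfg$sign_convention` (ancestral-allele information is not needed).
#'
#' @param panel_ref,panel_obs Complete [hap_panel()]s for the reference and
#'   observed populations, on the same marker map.
#' @param cfg A [scan_config()].
#' @return A tibble per SNP: `ies_ref`, `ies_obs`, `lries`, `xpehh`,
#'   `pxpehh`, `significant`, `direction`, `skip_reason`.
#' @export
xpehh_scan <- function(panel_ref, panel_obs, cfg = scan_config()) {
  stopifnot(inherits(panel_ref, "hap_panel"), inherits(panel_obs, "hap_panel"))
  if (!identical(panel_ref$map$snp_id, panel_obs$map$snp_id) ||
      !identical(panel_ref$map$pos_bp, panel_obs$map$pos_bp)) {
    abort("the two panels must share the same marker map")
  }
  check_complete(panel_ref, "xpehh_scan")
  check_complete(panel_obs, "xpehh_scan")
  ref <- panel_ies(panel_ref, cfg)
  obs <- panel_ies(panel_obs, cfg)
  out <- tibble(snp_id = panel_ref$map$snp_id, chrom = panel_ref$map$chrom,
                pos_bp = panel_ref$map$pos_bp,
                ies_ref = ref[, "ies"], ies_obs = obs[, "ies"],
                border_truncated = ref[, "border"] == 1 | obs[, "border"] == 1,
                skip_reason = NA_character_)
  bad <- is.na(out$ies_ref) | is.na(out$ies_obs) |
    out$ies_ref == 0 | out$ies_obs == 0
  out$skip_reason[bad] <- "zero_ies"
  scored <- !bad
  if (sum(scored) < 10L) {
    abort("fewer than 10 scored SNPs; XP-EHH standardisation is unstable")
  }
  out$lries <- ifelse(scored, log(out$ies_ref / out$ies_obs), NA_real_)
  med <- stats::median(out$lries[scored])
  sdv <- stats::sd(out$lries[scored])
  out$xpehh <- (out$lries - med) / sdv
  out$pxpehh <- NA_real_
  out$pxpehh[!is.na(out$xpehh)] <-
    pxpehh_transform(out$xpehh[!is.na(out$xpehh)])
  out$significant <- !is.na(out$pxpehh) &
    out$pxpehh > -log10(cfg$xpehh_alpha)
  neg_is_ref <- cfg$sign_convention == "negative_is_reference"
  out$direction <- dplyr::case_when(
    is.na(out$xpehh) | out$xpehh == 0 ~ NA_character_,
    (out$xpehh < 0) == neg_is_ref ~ "reference",
    TRUE ~ "observed")
  out
}

#' Significance cutoff for piHS values
#'
#' `fixed` mode converts a user-supplied two-sided p-value threshold to the
#' piHS scale (`-log10 p`). `empirical_null` mode estimates the null
#' proportion eta0 from the upper tail of the p-value distribution
#' (truncated-density estimate on `[tau, 1]`, clipped to 1) and returns the
#' largest p-value whose estimated tail false discovery proportion
#' `eta0 * p * n / #{p_i <= p}` stays below `fdr_level`; when no p-value
#' qualifies the Sidak-style per-comparison point `1 - (1 - fdr_level)^(1/n)`
#' is returned, so a pure-null scan yields a cutoff more stringent than any
#' conventional per-SNP threshold.
#'
#' @param pihs Numeric vector of piHS values, or a tibble with a `pihs`
#'   column (only scored SNPs are used).
#' @param mode `"empirical_null"` or `"fixed"`.
#' @param p_fixed Two-sided p threshold for `fixed` mode (e.g. 0.008).
#' @param tau Truncation point of the eta0 estimator.
#' @param fdr_level Tail FDR level for `empirical_null` mode.
#' @return A list: `cutoff_pihs`, `cutoff_p`, `eta0` (`NA` in fixed mode),
#'   `mode`, `n`.
#' @export
empirical_null_cutoff <- function(pihs, mode = c("empirical_null", "fixed"),
                                  p_fixed = NULL, tau = 0.75,
                                  fdr_level = 0.05) {
  mode <- match.arg(mode)
  if (is.data.frame(pihs)) pihs <- pihs$pihs
  pihs <- pihs[!is.na(pihs)]
  if (mode == "fixed") {
    if (is.null(p_fixed)) abort("fixed mode needs `p_fixed`")
    return(list(cutoff_pihs = -log10(p_fixed), cutoff_p = p_fixed,
                eta0 = NA_real_, mode = mode, n = length(pihs)))
  }
  n <- length(pihs)
  if (n < 100L) abort("empirical_null mode needs at least 100 scored SNPs")
  p <- 10^(-pihs)
  if (diff(range(p)) < 1e-12) {
    abort("degenerate p-value distribution (all values equal)")
  }
  eta0 <- min(1, mean(p > tau) / (1 - tau))
  ps <- sort(p)
  fdp <- eta0 * ps * n / seq_len(n)
  ok <- which(fdp <= fdr_level)
  cutoff_p <- if (length(ok)) ps[max(ok)] else 1 - (1 - fdr_level)^(1 / n)
  list(cutoff_pihs = -log10(cutoff_p), cutoff_p = cutoff_p, eta0 = eta0,
       mode = mode, n = n)
}

#' Flag significant scan rows against a piHS cutoff
#'
#' @param scan An [ihs_scan()] result.
#' @param cutoff_pihs Significance threshold on the piHS scale.
#' @return The tibble with a `significant` column.
#' @export
mark_significant <- function(scan, cutoff_pihs) {
  scan$significant <- !is.na(scan$pihs) & scan$pihs >= cutoff_pihs
  scan
}
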