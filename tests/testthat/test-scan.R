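# The EHH walker is checked against a pair-enumeration oracle on tiny panels,
# then the composite statistics are checked for their structural properties.

no_trunc <- function() scan_config(ehh_floor = 1e-9, max_gap_bp = 1e15,
                                   freq_bin_width = 0.1)

test_that("EHH starts at 1 for allele cores and stays 1 on identical flanks", {
  haps <- rbind(c(1L, 1L, 0L, 1L, 1L),
                c(1L, 1L, 0L, 1L, 1L),
                c(0L, 0L, 1L, 0L, 0L),
                c(1L, 1L, 1L, 0L, 1L))
  panel <- toy_panel(haps)
  cur <- ehh_decay(panel, 3, core = "derived", cfg = no_trunc())
  expect_equal(attr(cur, "n_haplotypes_retained"), 2L)
  expect_equal(cur$ehh[cur$side == "focal"], 1)
  # carriers of the derived core (rows 3, 4) differ on both flanks
  expect_true(all(cur$ehh <= 1 + 1e-12))

  ident <- toy_panel(rbind(c(1L, 1L, 1L), c(1L, 1L, 1L),
                           c(1L, 1L, 1L), c(1L, 1L, 1L)))
  cur2 <- ehh_decay(ident, 2, core = "derived", cfg = no_trunc())
  expect_true(all(cur2$ehh == 1))
})

test_that("4 carriers splitting 2/2 at the first flank SNP give EHH = 1/3", {
  haps <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
                c(0L, 0L), c(0L, 0L))
  panel <- toy_panel(haps)
  cur <- ehh_decay(panel, 1, core = "derived", cfg = no_trunc())
  expect_equal(cur$ehh[cur$side == "right"], (1 + 1) / 6)
})

test_that("EHH curves match the pair-enumeration oracle on random panels", {
  for (seed in 1:12) {
    n_hap <- sample(c(4L, 6L, 8L), 1)
    n_snp <- sample(4:10, 1)
    h <- random_panel(n_hap, n_snp, seed = 100 + seed)
    panel <- toy_panel(h)
    focal <- sample(n_snp, 1)
    for (core in c("ancestral", "derived", "site")) {
      carriers <- switch(core,
                         ancestral = which(h[, focal] == 0L),
                         derived = which(h[, focal] == 1L),
                         site = seq_len(n_hap))
      cur <- ehh_decay(panel, focal, core = core, cfg = no_trunc())
      if (length(carriers) < 2) {
        expect_true(attr(cur, "undefined"))
        next
      }
      for (r in seq_len(nrow(cur))) {
        m <- match(cur$snp_id[r], panel$map$snp_id)
        expect_equal(cur$ehh[r],
                     brute_ehh(h, focal, m, carriers,
                               condition_focal = core == "site"),
                     tolerance = 1e-12,
                     label = paste("seed", seed, core, "marker", m))
      }
      # monotone decay away from the focal SNP on each flank
      left <- cur$ehh[cur$side == "left"]
      right <- cur$ehh[cur$side == "right"]
      expect_true(all(diff(left) >= -1e-12))        # stored outward-in
      expect_true(all(diff(right) <= 1e-12))
    }
  }
})

test_that("trapezoidal integration matches closed forms and scales with distance", {
  # EHH == 1 over [-L, +L] then cut by the chromosome end: iHH = 2L
  ident <- toy_panel(matrix(1L, 4, 5), spacing = 500)
  cur <- ehh_decay(ident, 3, core = "derived", cfg = no_trunc())
  expect_equal(integrate_ehh(cur), 2 * 1000)

  # hand-built one-flank trapezoid (0,1) -> (1000, 0.5): area 750
  curve <- tibble::tibble(snp_id = c("a", "b"), pos_bp = c(0, 1000),
                          distance_bp = c(0, 1000),
                          side = c("focal", "right"), ehh = c(1, 0.5))
  attr(curve, "undefined") <- FALSE
  class(curve) <- c("ehh_curve", class(curve))
  expect_equal(integrate_ehh(curve), 750)

  h <- random_panel(6, 8, seed = 41)
  p1 <- toy_panel(h, spacing = 1000)
  p2 <- toy_panel(h, spacing = 2000)
  i1 <- integrate_ehh(ehh_decay(p1, 4, core = "site", cfg = no_trunc()))
  i2 <- integrate_ehh(ehh_decay(p2, 4, core = "site", cfg = no_trunc()))
  expect_equal(i2, 2 * i1)
})

test_that("flank truncation rules stop at floor, gap, and chromosome end", {
  h <- random_panel(8, 10, seed = 43)
  panel <- toy_panel(h, spacing = 1000)
  cur <- ehh_decay(panel, 5, core = "site",
                   cfg = scan_config(ehh_floor = 0.3, max_gap_bp = 1e9))
  right <- cur$ehh[cur$side == "right"]
  if (attr(cur, "stop_right") == "floor") {
    expect_lt(right[length(right)], 0.3)
    expect_true(all(right[-length(right)] >= 0.3))
  }
  # a huge gap between markers 7 and 8 cuts the right flank
  map <- toy_map(10, spacing = 1000)
  map$pos_bp[8:10] <- map$pos_bp[8:10] + 1e6
  pg <- hap_panel(h, map, samples = paste0("i", 1:4), coding = "ancestral")
  curg <- ehh_decay(pg, 5, core = "site",
                    cfg = scan_config(ehh_floor = 1e-9, max_gap_bp = 20000))
  expect_equal(attr(curg, "stop_right"), "gap")
  expect_equal(max(match(curg$snp_id, map$snp_id)), 7L)
  # chromosome end is flagged border-truncated
  cure <- ehh_decay(pg, 2, core = "site",
                    cfg = scan_config(ehh_floor = 1e-9, max_gap_bp = 1e9))
  expect_equal(attr(cure, "stop_left"), "chrom_end")
  expect_true(attr(cure, "border_truncated"))
})

test_that("score transforms match the Gaussian tail and are symmetric and stable", {
  expect_equal(pihs_transform(0), 0)
  x <- c(0.5, 1.3, 2.2, 4.4, 7.02, 10)
  expect_equal(pihs_transform(x), pihs_transform(-x))
  expect_equal(pihs_transform(x[1:3]), -log10(2 * pnorm(-x[1:3])))
  expect_true(all(is.finite(pihs_transform(c(20, 38)))))
  expect_identical(pxpehh_transform, pihs_transform)
  expect_error(pihs_transform(Inf), "finite")
})

test_that("iHS standardisation yields mean 0 / SD 1 bins and honours skip rules", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 150, chrom_length_bp = 1.5e6,
                    ne_ancestral = 100, ne_pop1 = 100, ne_pop2 = 100,
                    burn_in = 200, t_split = 30, n_sample_pop1 = 30,
                    n_sample_pop2 = 30, seed = 51)
  sim <- simulate_divergence(cfg)
  sc <- ihs_scan(sim$panels$dairy, scan_config(freq_bin_width = 0.1))
  scored <- sc[!is.na(sc$ihs), ]
  expect_gt(nrow(scored), 50)
  bins <- ceiling(scored$freq_derived / 0.1)
  for (b in unique(bins)) {
    v <- scored$ihs[bins == b]
    if (length(v) >= 2) {
      expect_equal(mean(v), 0, tolerance = 1e-9)
      expect_equal(sd(v), 1, tolerance = 1e-9)
    }
  }
  # piHS agrees with the transform wherever scored
  expect_equal(scored$pihs, pihs_transform(scored$ihs))
  # maf rule: monomorphic/rare SNPs are skipped with a reason
  rare <- sc$freq_derived < 0.01 | sc$freq_derived > 0.99
  expect_true(all(sc$skip_reason[rare] == "maf"))
  expect_true(all(is.na(sc$ihs[!is.na(sc$skip_reason)])))
})

test_that("scans demand complete ancestral-coded panels", {
  h <- random_panel(6, 12, seed = 61)
  raw <- toy_panel(h, coding = "raw")
  expect_error(ihs_scan(raw), "ancestral")
  hm <- h
  hm[1, 1] <- NA
  panel <- toy_panel(hm)
  expect_error(ihs_scan(panel), "complete")
})

test_that("XP-EHH is antisymmetric under population swap and median-centred", {
  cfg <- sim_config(n_chrom = 1, snps_per_chrom = 120, chrom_length_bp = 1.2e6,
                    ne_ancestral = 100, ne_pop1 = 100, ne_pop2 = 60,
                    burn_in = 150, t_split = 30, n_sample_pop1 = 25,
                    n_sample_pop2 = 25, seed = 71)
  sim <- simulate_divergence(cfg)
  a <- xpehh_scan(sim$panels$dairy, sim$panels$beef)
  b <- xpehh_scan(sim$panels$beef, sim$panels$dairy)
  expect_equal(b$xpehh, -a$xpehh, tolerance = 1e-9)
  expect_equal(median(a$xpehh, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(a$pxpehh, b$pxpehh, tolerance = 1e-9)
  # direction flips with the convention, not with the data
  sig <- which(a$significant & a$xpehh < 0)
  if (length(sig)) expect_true(all(a$direction[sig] == "reference"))
  cfg2 <- scan_config(sign_convention = "positive_is_reference")
  a2 <- xpehh_scan(sim$panels$dairy, sim$panels$beef, cfg2)
  if (length(sig)) expect_true(all(a2$direction[sig] == "observed"))
})

test_that("XP-EHH input contracts are enforced", {
  h <- random_panel(8, 12, seed = 81)
  p1 <- toy_panel(h)
  p2 <- toy_panel(random_panel(8, 12, seed = 82))
  short <- subset_markers(p1, paste0("s", 1:5))
  expect_error(xpehh_scan(short, subset_markers(p2, paste0("s", 1:4))),
               "same marker map")
})

test_that("significance cutoffs behave in fixed and empirical-null modes", {
  fx <- empirical_null_cutoff(numeric(0), mode = "fixed", p_fixed = 0.008)
  expect_equal(round(fx$cutoff_pihs, 2), 2.10)
  expect_equal(empirical_null_cutoff(numeric(0), mode = "fixed",
                                     p_fixed = 1)$cutoff_pihs, 0)

  set.seed(91)
  p_null <- runif(10000)
  en <- empirical_null_cutoff(-log10(p_null), mode = "empirical_null")
  expect_gte(en$eta0, 0.9)
  expect_lte(en$eta0, 1.0)
  expect_lt(en$cutoff_p, 0.01)  # pure null: more stringent than 1%

  # signal-bearing mixture admits a usable cutoff
  p_mix <- c(10^-runif(300, 3, 8), runif(9700))
  em <- empirical_null_cutoff(-log10(p_mix), mode = "empirical_null")
  expect_lt(em$eta0, 1)
  expect_gt(sum(p_mix <= em$cutoff_p), 0)

  expect_error(empirical_null_cutoff(rep(1, 200)), "degenerate")
  expect_error(empirical_null_cutoff(-log10(runif(50))), "at least 100")
  sc <- mark_significant(tibble::tibble(pihs = c(2.2, 1.9, NA)), 2.10)
  expect_equal(sc$significant, c(TRUE, FALSE, FALSE))
})

test_that("established incomplete sweeps inflate the derived-core iHH on average", {
  # at desk-scale Ne the per-replicate iHS rank of a sweep is noisy, but the
  # derived-core iHH excess over same-frequency-bin SNPs is positive in
  # expectation; assert the aggregate over replicates
  ratios <- c()
  for (s in 101:108) {
    sim <- simulate_divergence(sim_config(
      n_chrom = 2, snps_per_chrom = 250, chrom_length_bp = 3e6,
      ne_ancestral = 150, ne_pop1 = 150, ne_pop2 = 150, burn_in = 300,
      t_split = 25, n_sample_pop1 = 50, n_sample_pop2 = 50,
      selected_loci = tibble::tibble(chrom = 1, index = 125,
                                     s_pop1 = 0.25, s_pop2 = 0),
      selected_start_freq = 0.05, seed = s))
    tr <- sim$truth[sim$truth$selected, ]
    sc <- ihs_scan(sim$panels$dairy, scan_config(freq_bin_width = 0.1))
    L <- sc[sc$snp_id == tr$snp_id, ]
    if (is.na(L$ihh_d)) next  # sweep lost or fixed: locus not scored
    b <- ceiling(sc$freq_derived / 0.1)
    others <- sc$ihh_d[b == ceiling(L$freq_derived / 0.1) &
                         !is.na(sc$ihh_d) & sc$snp_id != tr$snp_id]
    ratios <- c(ratios, L$ihh_d / median(others))
  }
  expect_gte(length(ratios), 4)
  expect_gt(mean(ratios), 1)
})

test_that("neutral iHS has a ~5% tail beyond 1.96 when bins are well filled", {
  # standardisation within small bins truncates the tails (bin max |z| is
  # bounded by (n-1)/sqrt(n)); with wide bins the UniHS distribution is
  # close enough to Gaussian for the nominal tail mass to appear
  fr <- c()
  for (s in 771:776) {
    sim <- simulate_divergence(sim_config(
      n_chrom = 2, snps_per_chrom = 200, chrom_length_bp = 2e6,
      ne_ancestral = 120, ne_pop1 = 120, ne_pop2 = 120, burn_in = 240,
      t_split = 30, n_sample_pop1 = 40, n_sample_pop2 = 40, seed = s))
    sc <- ihs_scan(sim$panels$dairy, scan_config(freq_bin_width = 0.5))
    v <- sc$ihs[!is.na(sc$ihs)]
    fr <- c(fr, mean(abs(v) > 1.96))
  }
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.05), 3 * se + 1e-12)
})
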