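# Genotype fixtures are built so the population allele frequencies and
# heterozygote shares are exact.

test_that("undifferentiated populations in HWE give Fst = 0 and Fis = 0", {
  # each pop: dosages {0,1,1,2}: p = 0.5, Ho = 0.5 = 2pq
  pop <- c(0L, 1L, 1L, 2L)
  g <- toy_geno(matrix(c(pop, pop), ncol = 1))
  d <- per_locus_stats(g, two_pop_labels(4, 4))
  expect_equal(d$fst_raw, 0)
  expect_equal(d$fis, 0)
  expect_equal(d$ho, 0.5)
})

test_that("oppositely fixed populations give Hs = 0, Ht = 0.5, Fst = 1", {
  g <- toy_geno(matrix(c(rep(2L, 3), rep(0L, 3)), ncol = 1))
  d <- per_locus_stats(g, two_pop_labels(3, 3))
  expect_equal(d$hs, 0)
  expect_equal(d$ht, 0.5)
  expect_equal(d$fst_raw, 1)
})

test_that("the printed Nei formulas give Hs 0.32, Ht 0.5, Fst 0.36 at p = 0.2/0.8", {
  # pop1 dosages {1,1,0,0,0}: p1 = 0.2; pop2 {1,1,2,2,2}: p2 = 0.8
  g <- toy_geno(matrix(c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L), ncol = 1))
  d <- per_locus_stats(g, two_pop_labels(5, 5))
  expect_equal(d$hs, 0.32)
  expect_equal(d$ht, 0.5)
  expect_equal(d$fst_raw, 0.36)
})

test_that("per-locus statistics match the brute-force oracle to 1e-12", {
  set.seed(21)
  for (rep in 1:4) {
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    n_snp <- sample(3:10, 1)
    calls <- matrix(rbinom((n1 + n2) * n_snp, 2, 0.5), n1 + n2, n_snp)
    calls[sample(length(calls), 2)] <- NA
    g <- toy_geno(calls)
    labels <- two_pop_labels(n1, n2)
    for (corrected in c(FALSE, TRUE)) {
      d <- per_locus_stats(g, labels, corrected = corrected)
      for (j in seq_len(n_snp)) {
        o <- brute_diversity(list(calls[1:n1, j], calls[n1 + 1:n2, j]),
                             corrected = corrected)
        expect_equal(d$ho[j], o$ho, tolerance = 1e-12)
        expect_equal(d$hs[j], o$hs, tolerance = 1e-12)
        expect_equal(d$ht[j], o$ht, tolerance = 1e-12)
        if (!is.na(o$fst)) expect_equal(d$fst_raw[j], o$fst, tolerance = 1e-12)
        if (!is.na(o$fis)) expect_equal(d$fis[j], o$fis, tolerance = 1e-12)
      }
    }
  }
})

test_that("the corrected estimator can go negative and clamping zeroes it", {
  # two tiny heterozygote-free samples at p = 0.5: the Nei-Chesser correction
  # inflates Hs above Ht, a legitimately negative Fst estimate
  pop <- c(0L, 2L)
  g <- toy_geno(matrix(c(pop, pop), ncol = 1))
  d <- per_locus_stats(g, two_pop_labels(2, 2), corrected = TRUE)
  expect_lt(d$fst_raw, 0)
  cl <- clamp_negative_fst(d)
  expect_equal(cl$fst, 0)
  expect_equal(attr(cl, "n_clamped"), 1L)

  d2 <- tibble::tibble(fst_raw = c(-0.004, 0.36))
  cl2 <- clamp_negative_fst(d2)
  expect_equal(cl2$fst, c(0, 0.36))
  expect_equal(attr(cl2, "n_clamped"), 1L)
})

test_that("the 3-SD control chart flags exactly the extreme SNP", {
  base <- tibble::tibble(
    snp_id = paste0("s", 1:101), chrom = 1L, pos_bp = 1:101 * 1000,
    defined = TRUE, fst_raw = c(rep(0.03, 100), 0.5))
  set.seed(2)
  base$fst_raw[1:100] <- base$fst_raw[1:100] + runif(100, -0.01, 0.01)
  tab <- clamp_negative_fst(base)
  fo <- fst_outliers(tab)
  expect_equal(tab$snp_id[fo$snps$outlier], "s101")
  expect_equal(nrow(fo$thresholds), 1L)

  flat <- clamp_negative_fst(tibble::tibble(
    snp_id = paste0("f", 1:20), chrom = 1L, pos_bp = 1:20, defined = TRUE,
    fst_raw = rep(0.1, 20)))
  fo_flat <- fst_outliers(flat)
  expect_false(any(fo_flat$snps$outlier))  # SD = 0, nothing above mean + 0

  single <- clamp_negative_fst(tibble::tibble(
    snp_id = "x", chrom = 2L, pos_bp = 1, defined = TRUE, fst_raw = 0.2))
  expect_warning(fst_outliers(single), "no threshold")
})

test_that("per-chromosome heterozygosity means are exact", {
  homo <- matrix(rep(c(0L, 2L), each = 4), 4, 2)  # no hets anywhere
  het1 <- matrix(c(1L, 1L, 0L, 2L), 4, 1)         # Ho = 0.5
  calls <- cbind(homo, het1)
  g <- geno_matrix(calls, toy_map(3, chrom = c(1L, 1L, 2L)),
                   samples = paste0("ind", 1:4))
  labels <- two_pop_labels(2, 2)
  hc <- per_chromosome_heterozygosity(g, labels)
  expect_equal(hc$chrom, c(1L, 2L))
  expect_equal(hc$ho_beef[1], 0)    # chromosome of homozygous SNPs
  expect_equal(hc$ho_dairy[2], 1)   # single-SNP chromosome = that SNP's Ho
  expect_equal(hc$ho_beef[2], 0)
  expect_equal(hc$diff[2], -1)      # beef minus dairy (sorted pop order)
})

test_that("a closed (small-Ne) population shows lower heterozygosity", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 100, chrom_length_bp = 1e6,
                    ne_ancestral = 150, ne_pop1 = 150, ne_pop2 = 50,
                    burn_in = 50, t_split = 60, n_sample_pop1 = 25,
                    n_sample_pop2 = 25, seed = 31)
  sim <- simulate_divergence(cfg)
  hc <- per_chromosome_heterozygosity(sim$genotypes_combined, sim$labels)
  expect_lt(mean(hc$ho_beef), mean(hc$ho_dairy))
})
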