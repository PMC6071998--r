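make_blobs <- function(n_per, k, sep = 10, d = 20, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d), n_per, d), 2,
          c(sep * i, rep(0, d - 1)), "+")
  }))
  rownames(X) <- paste0("ind", seq_len(nrow(X)))
  X
}

test_that("percent variance shares sum to 100 and follow the eigenvalue ratio", {
  ev <- c(5, 3, 1.5, 0.5)
  pv <- percent_variance(ev)
  expect_equal(sum(pv), 100)
  expect_equal(pv[1] / pv[2], ev[1] / ev[2])
})

test_that("PCA separates two diverged populations on PC1", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 120, chrom_length_bp = 1.2e6,
                    ne_ancestral = 100, ne_pop1 = 100, ne_pop2 = 100,
                    burn_in = 40, t_split = 40, n_sample_pop1 = 25,
                    n_sample_pop2 = 25, seed = 5)
  sim <- simulate_divergence(cfg)
  pca <- run_pca(sim$genotypes_combined, n_pc = 4)
  expect_equal(sum(pca$percent_variance), 100, tolerance = 1e-9)
  expect_true(all(pca$eigenvalues >= -1e-9))
  expect_true(all(diff(pca$eigenvalues) <= 1e-9))
  lab <- sim$labels$population[match(rownames(pca$scores),
                                     sim$labels$sample_id)]
  pc1 <- pca$scores[, 1]
  # the two label groups sit on opposite sides of zero on PC1
  expect_true(all(sign(pc1[lab == "dairy"]) ==
                    sign(pc1[lab == "dairy"][1])))
  expect_true(all(sign(pc1[lab == "beef"]) ==
                    -sign(pc1[lab == "dairy"][1])))
  # between-population variance concentrates on PC1
  bv <- vapply(seq_len(4), function(j) {
    m <- tapply(pca$scores[, j], lab, mean)
    diff(m)^2
  }, numeric(1))
  expect_equal(which.max(bv), 1L)
})

test_that("duplicating every sample leaves percent variance unchanged", {
  set.seed(3)
  calls <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30)
  g1 <- toy_geno(calls)
  g2 <- geno_matrix(rbind(calls, calls), g1$map,
                    samples = paste0("ind", 1:40))
  p1 <- run_pca(g1, n_pc = 3)
  p2 <- run_pca(g2, n_pc = 3)
  keep <- p1$percent_variance > 1e-8
  expect_equal(p2$percent_variance[keep][1:5], p1$percent_variance[keep][1:5],
               tolerance = 1e-6)
})

test_that("PCA rejects impossible requests", {
  g <- toy_geno(matrix(rbinom(12, 2, 0.5), 4, 3))
  expect_error(run_pca(g, n_pc = 5), "n_pc")
  expect_error(run_pca(toy_geno(matrix(1L, 4, 3)), n_pc = 2), "constant")
})

test_that("BIC selects the generating number of clusters", {
  X2 <- make_blobs(30, 2, sep = 20, seed = 11)
  cl2 <- select_k_bic(X2, k_grid = 1:5, seed = 42)
  expect_equal(cl2$best_k, 2L)
  expect_true(all(table(cl2$assignments, rep(1:2, each = 30)) %in% c(0, 30)))

  # homogeneous data: no K > 1 earns a noticeable BIC improvement
  # (when samples comfortably outnumber dimensions the k-means BIC can
  # drift to K > 1 on pure noise; see the methods vignette)
  X1 <- make_blobs(25, 1, d = 50, seed = 12)
  cl1 <- select_k_bic(X1, k_grid = 1:4, seed = 42)
  expect_equal(cl1$best_k, 1L)
})

test_that("clustering is deterministic under a fixed seed and restarts only improve", {
  X <- make_blobs(15, 3, sep = 6, seed = 9)
  a <- select_k_bic(X, k_grid = 1:5, seed = 7)
  b <- select_k_bic(X, k_grid = 1:5, seed = 7)
  expect_identical(a$bic, b$bic)
  expect_identical(a$assignments, b$assignments)
  more <- select_k_bic(X, k_grid = 1:5, seed = 7, n_starts = 20)
  expect_true(min(more$bic) <= min(a$bic) + 1e-9)
})

test_that("discriminant axes are clamped to K-1 and separate clusters", {
  X <- make_blobs(20, 2, seed = 13)
  grp <- rep(1:2, each = 20)
  expect_message(df <- discriminant_functions(X, grp, n_df = 10), "clamped")
  expect_equal(attr(df, "n_df"), 1L)
  expect_true("LD1" %in% names(df))
  r1 <- range(df$LD1[grp == 1])
  r2 <- range(df$LD1[grp == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # disjoint ranges
  expect_error(discriminant_functions(X, rep(1, 40)), "at least 2")
})

test_that("permuting cluster labels preserves the discriminant subspace up to sign", {
  X <- make_blobs(15, 3, sep = 6, seed = 17)
  grp <- rep(1:3, each = 15)
  perm <- c(3L, 1L, 2L)[grp]
  d1 <- discriminant_functions(X, grp)
  d2 <- discriminant_functions(X, perm)
  for (ax in c("LD1", "LD2")) {
    cors <- abs(cor(d1[[ax]], cbind(d2$LD1, d2$LD2)))
    expect_gt(max(cors), 0.999)
  }
})
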