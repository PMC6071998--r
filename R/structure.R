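# Population structure: PCA of the dosage matrix, K-means over PC scores with
# BIC model choice, and linear discriminant axes between the inferred
# clusters (the DAPC composition).

#' Principal component analysis of genotypes
#'
#' Missing calls are mean-imputed per SNP; dosages are centred per SNP by
#' twice the allele frequency and, when `scale = TRUE`, divided by the
#' binomial standard deviation `sqrt(2p(1-p))` so rare and common alleles
#' contribute comparable variance. Eigenvalues are those of the sample
#' covariance matrix; the percent variance of a component is its eigenvalue
#' times 100 divided by the sum of all the eigenvalues.
#'
#' @param g A [geno_matrix()].
#' @param n_pc Number of components to retain (scores/loadings).
#' @param scale Scale each SNP by its binomial standard deviation?
#' @return An object of class `girscan_pca` with elements `eigenvalues` and
#'   `percent_variance` (all components), `scores` (samples x `n_pc`),
#'   `loadings` (SNPs x `n_pc`) and `n_pc`.
#' @export
run_pca <- function(g, n_pc = 10, scale = TRUE) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$calls
  n <- nrow(X)
  if (n < 2L) abort("PCA needs at least 2 samples")
  if (n_pc > min(n - 1L, ncol(X))) {
    abort("n_pc exceeds min(samples - 1, SNPs)")
  }
  p <- colMeans(X, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  mu <- 2 * p
  X <- sweep(X, 2L, mu)
  X[is.na(X)] <- 0  # mean imputation: imputed cells sit at the column mean
  if (scale) {
    sdv <- sqrt(2 * p * (1 - p))
    ok <- sdv > 0
    X[, ok] <- sweep(X[, ok, drop = FALSE], 2L, sdv[ok], "/")
  }
  if (all(abs(X) < 1e-12)) abort("constant genotype matrix; PCA is undefined")
  sv <- svd(X, nu = n_pc, nv = n_pc)
  eig <- sv$d^2 / (n - 1L)
  pct <- eig * 100 / sum(eig)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pc)], n_pc, n_pc)
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(n_pc)))
  loadings <- sv$v
  dimnames(loadings) <- list(g$map$snp_id, paste0("PC", seq_len(n_pc)))
  structure(list(eigenvalues = eig, percent_variance = pct, scores = scores,
                 loadings = loadings, n_pc = n_pc, scale = scale,
                 samples = g$samples),
            class = "girscan_pca")
}

#' Percent variance explained
#'
#' Share of total variance per component: eigenvalue times 100 divided by the
#' sum of all the eigenvalues.
#'
#' @param eigenvalues Non-negative eigenvalues.
#' @param total Sum of all eigenvalues (defaults to `sum(eigenvalues)`;
#'   supply it when only the leading eigenvalues are at hand).
#' @return Numeric vector of percentages.
#' @export
percent_variance <- function(eigenvalues, total = sum(eigenvalues)) {
  if (total <= 0) abort("total variance must be positive")
  eigenvalues * 100 / total
}

#' @export
print.girscan_pca <- function(x, ...) {
  cat("<girscan_pca> ", length(x$samples), " samples, ", x$n_pc,
      " retained PCs\n  leading eigenvalues: ",
      paste(format(head(x$eigenvalues, 3), digits = 4), collapse = ", "),
      "\n  percent variance: ",
      paste(format(head(x$percent_variance, 3), digits = 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.girscan_pca <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         percent_variance = x$percent_variance,
         cumulative_percent = cumsum(x$percent_variance))
}

#' @export
glance.girscan_pca <- function(x, ...) {
  tibble(n_samples = length(x$samples), n_pc = x$n_pc,
         total_variance = sum(x$eigenvalues),
         pc1_percent = x$percent_variance[1])
}

#' PCA scores as a tibble
#'
#' @param x A `girscan_pca` object.
#' @param labels Optional tibble (`sample_id`, `population`) joined on.
#' @return A tibble: `sample_id`, `PC1..PCk` and optionally `population`.
#' @export
pca_scores <- function(x, labels = NULL) {
  out <- dplyr::bind_cols(tibble(sample_id = rownames(x$scores)),
                          as_tibble(x$scores))
  if (!is.null(labels)) out <- left_join(out, as_tibble(labels), by = "sample_id")
  out
}

# k-means++ seeding: spread the initial centers with probability proportional
# to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (i in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[i, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[i, ])^2))
    }
  }
  centers
}

#' Choose the number of clusters by BIC over K-means fits
#'
#' For each K in `k_grid`, runs K-means (k-means++ seeding, `n_starts`
#' restarts, fixed seed stream) on the PC scores and evaluates
#' `BIC(K) = n log(WSS_K / n) + K log(n)` with `WSS_K` the total
#' within-cluster sum of squares. The selected K is the smallest one whose
#' BIC is within `1e-9` of the minimum, so a larger K must improve the BIC
#' noticeably to be preferred.
#'
#' @param scores Numeric matrix of PC scores (or a `girscan_pca` object).
#' @param k_grid Candidate cluster counts.
#' @param seed Integer seed (mandatory, for reproducible restarts).
#' @param n_starts Restarts per K.
#' @return An object of class `girscan_clusters` with `k_grid`, `bic`,
#'   `best_k`, `assignments` (named integer vector) and `wss`.
#' @export
select_k_bic <- function(scores, k_grid = 1:6, seed, n_starts = 10) {
  if (inherits(scores, "girscan_pca")) scores <- scores$scores
  X <- as.matrix(scores)
  n <- nrow(X)
  if (missing(seed)) abort("`seed` is mandatory")
  if (any(k_grid < 1L) || any(k_grid > n - 1L)) {
    abort("k_grid must lie within [1, n_samples - 1]")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  bic <- wss <- numeric(length(k_grid))
  assign_by_k <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    best <- NULL
    for (s in seq_len(n_starts)) {
      fit <- tryCatch({
        cent <- kmeanspp_centers(X, k)
        stats::kmeans(X, centers = cent, iter.max = 100L)
      }, error = function(e) NULL)
      if (is.null(fit)) next  # degenerate start (empty cluster): restart
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) abort(paste0("all K-means restarts degenerate at K = ", k))
    wss[i] <- best$tot.withinss
    bic[i] <- n * log(max(wss[i], .Machine$double.eps) / n) + k * log(n)
    assign_by_k[[i]] <- setNames(best$cluster, rownames(X))
  }
  best_i <- which(bic <= min(bic) + 1e-9)[1]
  structure(list(k_grid = as.integer(k_grid), bic = bic, wss = wss,
                 best_k = as.integer(k_grid[best_i]),
                 assignments = assign_by_k[[best_i]],
                 assignments_by_k = assign_by_k, seed = seed,
                 n_starts = n_starts),
            class = "girscan_clusters")
}

#' @export
print.girscan_clusters <- function(x, ...) {
  cat("<girscan_clusters> best K = ", x$best_k, " over grid {",
      paste(x$k_grid, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
tidy.girscan_clusters <- function(x, ...) {
  tibble(k = x$k_grid, bic = x$bic, wss = x$wss, best = x$k_grid == x$best_k)
}

#' @export
glance.girscan_clusters <- function(x, ...) {
  tibble(best_k = x$best_k, min_bic = min(x$bic),
         n_samples = length(x$assignments))
}

#' Linear discriminant functions between clusters
#'
#' Fits linear discriminant axes that maximise the between- over
#' within-cluster variance ratio on the retained PC scores. At most K - 1
#' axes exist for K clusters; a larger request is clamped with a message.
#'
#' @param scores PC score matrix (or `girscan_pca`).
#' @param assignments Cluster assignment vector (one per sample).
#' @param n_df Number of discriminant functions requested.
#' @return A tibble of per-sample discriminant scores (`sample_id`, `cluster`,
#'   `LD1`, ...), with the fitted [MASS::lda()] object in attribute `model`
#'   and the clamped axis count in attribute `n_df`.
#' @export
discriminant_functions <- function(scores, assignments, n_df = NULL) {
  if (inherits(scores, "girscan_pca")) scores <- scores$scores
  X <- as.matrix(scores)
  grp <- factor(assignments)
  k <- nlevels(grp)
  if (k < 2L) abort("discriminant axes need at least 2 clusters")
  max_df <- min(k - 1L, ncol(X))
  n_df <- n_df %||% max_df
  if (n_df > max_df) {
    inform(paste0("n_df clamped from ", n_df, " to ", max_df,
                  " (at most K - 1 axes exist)"))
    n_df <- max_df
  }
  fit <- MASS::lda(X, grouping = grp)
  ld <- predict(fit, X)$x[, seq_len(n_df), drop = FALSE]
  out <- dplyr::bind_cols(
    tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
           cluster = as.integer(grp)),
    as_tibble(ld))
  attr(out, "model") <- fit
  attr(out, "n_df") <- n_df
  out
}

#' PCA + K-means/BIC + discriminant axes in one call
#'
#' Convenience composition of [run_pca()], [select_k_bic()] and
#' [discriminant_functions()].
#'
#' @param g A [geno_matrix()].
#' @param n_pc Retained PCs.
#' @param k_grid Candidate cluster counts.
#' @param seed Integer seed.
#' @param n_df Discriminant functions (clamped to K - 1).
#' @param scale Passed to [run_pca()].
#' @return A list with `pca`, `clusters` and (when `best_k > 1`)
#'   `discriminants`.
#' @export
run_dapc <- function(g, n_pc = 10, k_grid = 1:6, seed, n_df = NULL,
                     scale = TRUE) {
  pca <- run_pca(g, n_pc = n_pc, scale = scale)
  cl <- select_k_bic(pca$scores, k_grid = k_grid, seed = seed)
  disc <- if (cl$best_k > 1L) {
    discriminant_functions(pca$scores, cl$assignments, n_df = n_df)
  }
  list(pca = pca, clusters = cl, discriminants = disc)
}
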