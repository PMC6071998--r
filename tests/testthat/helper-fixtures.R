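# Fixture builders and independent brute-force oracles. Oracles are written
# long-hand (explicit loops over pairs / alleles) so they share no code path
# with the implementation they check.

toy_map <- function(n, chrom = 1L, spacing = 1000, anc = NULL) {
  tibble::tibble(
    snp_id = paste0("s", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos_bp = rep(spacing * seq_len(n), length.out = n) +
      1e6 * (rep_len(chrom, n) - min(chrom)),
    allele_a = rep("A", n), allele_b = rep("G", n),
    ancestral_allele = if (is.null(anc)) rep("A", n) else anc)
}

toy_geno <- function(calls, chrom = 1L, spacing = 1000) {
  calls <- as.matrix(calls)
  geno_matrix(calls, toy_map(ncol(calls), chrom = chrom, spacing = spacing),
              samples = paste0("ind", seq_len(nrow(calls))))
}

toy_panel <- function(haps, chrom = 1L, spacing = 1000,
                      coding = "ancestral") {
  haps <- as.matrix(haps)
  hap_panel(haps, toy_map(ncol(haps), chrom = chrom, spacing = spacing),
            samples = paste0("ind", seq_len(nrow(haps) / 2)),
            coding = coding)
}

two_pop_labels <- function(n1, n2, pops = c("dairy", "beef")) {
  tibble::tibble(
    sample_id = paste0("ind", seq_len(n1 + n2)),
    population = rep(pops, c(n1, n2)))
}

# EHH by explicit pair enumeration: probability that two distinct carrier
# haplotypes are identical at every marker from `focal` to `m` inclusive
# (`condition_focal = FALSE` skips the focal marker itself, as for
# allele-conditioned cores where carriers share it by construction).
brute_ehh <- function(haps, focal, m, carriers, condition_focal = TRUE) {
  span <- seq(min(focal, m), max(focal, m))
  if (!condition_focal) span <- setdiff(span, focal)
  n <- length(carriers)
  if (n < 2) return(NA_real_)
  same <- 0L
  tot <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1L
      if (length(span) == 0L ||
          all(haps[carriers[i], span] == haps[carriers[j], span])) {
        same <- same + 1L
      }
    }
  }
  same / tot
}

# Nei / Nei-Chesser statistics recomputed long-hand from genotype counts.
brute_diversity <- function(calls_by_pop, corrected = FALSE) {
  npop <- length(calls_by_pop)
  n <- het <- p <- numeric(npop)
  for (k in seq_len(npop)) {
    g <- calls_by_pop[[k]]
    g <- g[!is.na(g)]
    n[k] <- length(g)
    het[k] <- sum(g == 1) / length(g)
    p[k] <- sum(g) / (2 * length(g))
  }
  ho <- mean(het)
  # expected heterozygosity via explicit allele sums (alleles: counted, other)
  hs_k <- vapply(p, function(pk) 1 - (pk^2 + (1 - pk)^2), numeric(1))
  hs <- mean(hs_k)
  pbar <- mean(p)
  ht <- 1 - (pbar^2 + (1 - pbar)^2)
  if (corrected) {
    ntilde <- npop / sum(1 / n)
    hs <- (ntilde / (ntilde - 1)) * (hs - ho / (2 * ntilde))
    ht <- ht + hs / (ntilde * npop) - ho / (2 * ntilde * npop)
  }
  list(ho = ho, hs = hs, ht = ht,
       fis = if (hs > 0) 1 - ho / hs else NA_real_,
       fst = if (ht > 0) (ht - hs) / ht else NA_real_)
}

# small deterministic random panel (complete, 0/1)
random_panel <- function(n_hap, n_snp, seed) {
  set.seed(seed)
  repeat {
    h <- matrix(rbinom(n_hap * n_snp, 1, runif(n_snp, 0.2, 0.8)[
      rep(seq_len(n_snp), each = n_hap)]), n_hap, n_snp)
    if (all(colSums(h) > 0) && all(colSums(h) < n_hap)) return(h)
  }
}

write_lines_file <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
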