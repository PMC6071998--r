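# Forward Wright-Fisher simulator of two populations splitting from a common
# ancestor: neutral drift genome-wide, additive divergent selection at
# designated loci, random mating with recombination along the marker map.
# The marker panel is fixed (no new mutations after initialisation), like a
# genotyping array, and initial derived-allele frequencies mimic chip
# ascertainment.

#' Simulation configuration
#'
#' Defaults describe two same-breed populations that split some tens of
#' generations ago: a larger multi-source population (pop1, "dairy") and a
#' smaller closed herd (pop2, "beef") with lower heterozygosity.
#'
#' @param n_chrom Number of autosomes.
#' @param snps_per_chrom Markers per autosome.
#' @param chrom_length_bp Autosome length in bp (markers sit on a jittered
#'   regular grid, mimicking array spacing).
#' @param ne_ancestral,ne_pop1,ne_pop2 Diploid effective sizes.
#' @param t_split Generations since the split.
#' @param burn_in Ancestral generations before the split (default
#'   `2 * ne_ancestral`, the pairwise coalescent depth, so neutral haplotypes
#'   acquire a realistic age structure on top of the linkage-equilibrium
#'   initialisation).
#' @param selected_loci Tibble with `chrom`, `index` (marker index within the
#'   chromosome), `s_pop1`, `s_pop2`: additive selection coefficients on the
#'   derived allele (fitnesses 1, 1+s, 1+2s).
#' @param n_sample_pop1,n_sample_pop2 Diploids sampled at the end.
#' @param recomb_rate Per-bp per-generation crossover probability (1e-8 =
#'   1 cM/Mb).
#' @param init_freq_range Range of the uniform initial derived-allele
#'   frequency draw (chip ascertainment: intermediate frequencies).
#' @param selected_start_freq Initial derived-allele frequency at selected
#'   loci.
#' @param pop_names Names of the two populations.
#' @param multiple_crossovers Use Poisson crossover counts instead of the
#'   at-most-one-crossover approximation.
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 3, snps_per_chrom = 300,
                       chrom_length_bp = 3e6,
                       ne_ancestral = 300, ne_pop1 = 300, ne_pop2 = 120,
                       t_split = 50, burn_in = NULL, selected_loci = NULL,
                       n_sample_pop1 = 60, n_sample_pop2 = 40,
                       recomb_rate = 1e-7,
                       init_freq_range = c(0.05, 0.95),
                       selected_start_freq = 0.1,
                       pop_names = c("dairy", "beef"),
                       multiple_crossovers = FALSE, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  burn_in <- burn_in %||% (2L * ne_ancestral)
  sizes <- c(n_chrom, snps_per_chrom, chrom_length_bp, ne_ancestral,
             ne_pop1, ne_pop2, n_sample_pop1, n_sample_pop2)
  if (any(sizes <= 0)) abort("sizes and counts must be positive")
  if (t_split < 0) abort("t_split must be >= 0")
  if (n_sample_pop1 > ne_pop1 || n_sample_pop2 > ne_pop2) {
    abort("sample size cannot exceed population size")
  }
  if (!is.null(selected_loci)) {
    selected_loci <- as_tibble(selected_loci)
    stopifnot(all(c("chrom", "index", "s_pop1", "s_pop2") %in%
                    names(selected_loci)))
    if (any(abs(c(selected_loci$s_pop1, selected_loci$s_pop2)) >= 1)) {
      abort("|s| must be < 1")
    }
  }
  structure(list(n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
                 chrom_length_bp = chrom_length_bp,
                 ne_ancestral = ne_ancestral, ne_pop1 = ne_pop1,
                 ne_pop2 = ne_pop2, t_split = t_split, burn_in = burn_in,
                 selected_loci = selected_loci,
                 n_sample_pop1 = n_sample_pop1, n_sample_pop2 = n_sample_pop2,
                 recomb_rate = recomb_rate, init_freq_range = init_freq_range,
                 selected_start_freq = selected_start_freq,
                 pop_names = pop_names,
                 multiple_crossovers = isTRUE(multiple_crossovers),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected Fst under pure drift
#'
#' The classic divergence expectation for a population of diploid effective
#' size Ne drifting t generations from its ancestor:
#' `1 - (1 - 1/(2 Ne))^t`.
#'
#' @param ne Diploid effective size.
#' @param t Generations.
#' @return Expected differentiation on the drift scale.
#' @export
expected_fst <- function(ne, t) {
  stopifnot(all(ne > 0), all(t >= 0))
  1 - (1 - 1 / (2 * ne))^t
}

# One Wright-Fisher generation: fitness-weighted parent sampling, one gamete
# per parent draw, at most one crossover per chromosome (or Poisson counts).
wf_generation <- function(H, ne_next, map_split, s_vec, recomb_rate,
                          chrom_length, multiple_crossovers) {
  n_par <- nrow(H) %/% 2L
  w <- rep(1, n_par)
  sel <- which(s_vec != 0)
  if (length(sel)) {
    dose <- H[seq(1L, 2L * n_par, 2L), sel, drop = FALSE] +
      H[seq(2L, 2L * n_par, 2L), sel, drop = FALSE]
    for (k in seq_along(sel)) {
      w <- w * (1 + s_vec[sel[k]] * dose[, k])
    }
    w <- pmax(w, 0)
    if (all(w == 0)) w <- rep(1, n_par)
  }
  n_gam <- 2L * ne_next
  parent <- sample.int(n_par, n_gam, replace = TRUE, prob = w)
  out <- matrix(0L, n_gam, ncol(H))
  for (ci in seq_along(map_split)) {
    cols <- map_split[[ci]]
    pos <- attr(map_split, "pos")[[ci]]
    m <- length(cols)
    start_hap <- sample.int(2L, n_gam, replace = TRUE)
    a <- 2L * (parent - 1L) + start_hap
    b <- 2L * (parent - 1L) + (3L - start_hap)
    if (!multiple_crossovers) {
      px <- min(1, recomb_rate * chrom_length)
      xo <- runif(n_gam) < px
      cutcol <- rep(m, n_gam)  # no crossover: whole chromosome from hap a
      if (any(xo)) {
        bp <- runif(sum(xo), 0, chrom_length)
        cutcol[xo] <- findInterval(bp, pos)
      }
      cmp <- outer(cutcol, seq_len(m), ">=")
      src <- ifelse(cmp, a, b)
    } else {
      k <- rpois(n_gam, recomb_rate * chrom_length)
      src <- matrix(a, n_gam, m)
      for (g in which(k > 0)) {
        bps <- sort(runif(k[g], 0, chrom_length))
        phase <- (findInterval(pos, bps) %% 2L) == 1L
        src[g, phase] <- b[g]
      }
    }
    out[, cols] <- H[cbind(as.vector(src), rep(cols, each = n_gam))]
  }
  out
}

#' Simulate two diverging populations
#'
#' An ancestral population is initialised at linkage equilibrium with
#' ascertainment-like allele frequencies, evolved `burn_in` generations to
#' accumulate LD, then split into two populations of the configured sizes
#' that evolve `t_split` generations independently under drift,
#' recombination and any configured divergent selection. Finally
#' `n_sample_*` diploids are drawn from each population without replacement.
#' The same seed reproduces the same outputs exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `girscan_sim`: `panels` (named list of two
#'   [hap_panel()]s in ancestral coding), `genotypes` (named list of two
#'   [geno_matrix()]s counting the derived allele), `genotypes_combined`,
#'   `labels` (sample_id/population tibble), `map`, `truth` (per-SNP tibble:
#'   ancestral allele, initial and final frequencies, selection flags,
#'   drift-expected Fst), `config`.
#' @export
simulate_divergence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  n_snp <- cfg$n_chrom * cfg$snps_per_chrom
  spacing <- cfg$chrom_length_bp / (cfg$snps_per_chrom + 1)
  pos_one <- function() {
    sort(round(spacing * seq_len(cfg$snps_per_chrom) +
                 runif(cfg$snps_per_chrom, -0.3 * spacing, 0.3 * spacing)))
  }
  map <- purrr::map_dfr(seq_len(cfg$n_chrom), function(ch) {
    tibble(chrom = ch, pos_bp = pos_one())
  })
  # jitter cannot reorder (amplitude < half spacing) but guard anyway
  map <- arrange(map, .data$chrom, .data$pos_bp)
  nucs <- c("A", "C", "G", "T")
  anc_nuc <- sample(nucs, n_snp, replace = TRUE)
  der_nuc <- vapply(anc_nuc, function(a) sample(setdiff(nucs, a), 1L), "")
  map <- mutate(map,
                snp_id = paste0("snp", .data$chrom, "_",
                                formatC(dplyr::row_number(), width = 4, flag = "0")),
                allele_a = anc_nuc, allele_b = der_nuc,
                ancestral_allele = anc_nuc)
  map <- map[, c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b",
                 "ancestral_allele")]

  s1 <- s2 <- rep(0, n_snp)
  freq0 <- runif(n_snp, cfg$init_freq_range[1], cfg$init_freq_range[2])
  sel_idx <- integer()
  if (!is.null(cfg$selected_loci)) {
    sel_idx <- (cfg$selected_loci$chrom - 1L) * cfg$snps_per_chrom +
      cfg$selected_loci$index
    stopifnot(all(sel_idx >= 1), all(sel_idx <= n_snp))
    s1[sel_idx] <- cfg$selected_loci$s_pop1
    s2[sel_idx] <- cfg$selected_loci$s_pop2
    freq0[sel_idx] <- cfg$selected_start_freq
  }

  chrom_cols <- split(seq_len(n_snp), map$chrom)
  attr(chrom_cols, "pos") <- split(map$pos_bp, map$chrom)

  # ancestral population at linkage equilibrium, then burn-in drift
  H <- matrix(rbinom(2L * cfg$ne_ancestral * n_snp, 1L,
                     rep(freq0, each = 2L * cfg$ne_ancestral)),
              2L * cfg$ne_ancestral, n_snp)
  for (g in seq_len(cfg$burn_in)) {
    H <- wf_generation(H, cfg$ne_ancestral, chrom_cols, rep(0, n_snp),
                       cfg$recomb_rate, cfg$chrom_length_bp,
                       cfg$multiple_crossovers)
  }
  # selection starts at the split: plant the standing selected variant at its
  # configured frequency on random haplotype backgrounds at that moment, so
  # burn-in drift can neither lose nor inflate it beforehand
  for (j in sel_idx) {
    target <- max(1L, round(2L * cfg$ne_ancestral * cfg$selected_start_freq))
    carriers <- which(H[, j] == 1L)
    if (length(carriers) > target) {
      H[sample(carriers, length(carriers) - target), j] <- 0L
    } else if (length(carriers) < target) {
      non <- which(H[, j] == 0L)
      H[sample(non, target - length(carriers)), j] <- 1L
    }
  }
  freq_split <- colMeans(H)

  # the founding draw of each daughter population is its first generation of
  # drift, so t_split generations in total separate each from the ancestor
  pops <- list(H, H)
  ne <- c(cfg$ne_pop1, cfg$ne_pop2)
  svecs <- list(s1, s2)
  for (k in 1:2) {
    Hk <- pops[[k]]
    for (g in seq_len(cfg$t_split)) {
      Hk <- wf_generation(Hk, ne[k], chrom_cols, svecs[[k]],
                          cfg$recomb_rate, cfg$chrom_length_bp,
                          cfg$multiple_crossovers)
    }
    pops[[k]] <- Hk
  }

  freq_final <- lapply(pops, colMeans)
  n_samp <- c(cfg$n_sample_pop1, cfg$n_sample_pop2)
  panels <- genos <- list()
  labels <- list()
  for (k in 1:2) {
    ids <- sample.int(nrow(pops[[k]]) %/% 2L, n_samp[k])
    rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    haps <- pops[[k]][rows, , drop = FALSE]
    sample_ids <- paste0(cfg$pop_names[k], "_", formatC(seq_len(n_samp[k]),
                                                        width = 3, flag = "0"))
    panels[[cfg$pop_names[k]]] <- hap_panel(haps, map, sample_ids,
                                            coding = "ancestral")
    calls <- haps[seq(1L, nrow(haps), 2L), , drop = FALSE] +
      haps[seq(2L, nrow(haps), 2L), , drop = FALSE]
    rownames(calls) <- sample_ids
    genos[[cfg$pop_names[k]]] <- geno_matrix(calls, map, sample_ids)
    labels[[k]] <- tibble(sample_id = sample_ids,
                          population = cfg$pop_names[k])
  }
  labels <- bind_rows(labels)
  combined <- geno_matrix(rbind(genos[[1]]$calls, genos[[2]]$calls), map,
                          c(genos[[1]]$samples, genos[[2]]$samples))

  truth <- tibble(snp_id = map$snp_id, chrom = map$chrom, pos_bp = map$pos_bp,
                  ancestral_allele = map$ancestral_allele,
                  freq_init = freq0, freq_at_split = freq_split,
                  freq_final_pop1 = freq_final[[1]],
                  freq_final_pop2 = freq_final[[2]],
                  selected = seq_len(n_snp) %in% sel_idx,
                  s_pop1 = s1, s_pop2 = s2,
                  lost_both = freq_final[[1]] == 0 & freq_final[[2]] == 0,
                  expected_fst_drift = mean(expected_fst(c(cfg$ne_pop1,
                                                           cfg$ne_pop2),
                                                         cfg$t_split)))
  structure(list(panels = panels, genotypes = genos,
                 genotypes_combined = combined, labels = labels, map = map,
                 truth = truth, config = cfg),
            class = "girscan_sim")
}

#' @export
print.girscan_sim <- function(x, ...) {
  cat("<girscan_sim> ", nrow(x$map), " SNPs on ", x$config$n_chrom,
      " chromosomes; populations: ",
      paste(paste0(x$config$pop_names, " (n=",
                   c(x$config$n_sample_pop1, x$config$n_sample_pop2), ")"),
            collapse = ", "),
      "; t_split = ", x$config$t_split, "\n", sep = "")
  invisible(x)
}
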