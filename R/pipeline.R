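# End-to-end pipeline: QC -> structure -> diversity/Fst -> iHS per
# population -> XP-EHH -> candidate windows -> gene overlap/consensus.
# Every stage writes its TSV as soon as it completes; a JSON manifest records
# completed stages, attrition counts, thresholds and the seed, so a failed
# run leaves its partial outputs plus the manifest behind.

#' Run the full analysis pipeline
#'
#' Takes a simulated dataset (a `girscan_sim` from [simulate_divergence()])
#' or an equivalent list with elements `genotypes_combined` ([geno_matrix()]),
#' `panels` (named list of two complete [hap_panel()]s in ancestral coding,
#' first = reference population for XP-EHH) and `labels`, runs every stage,
#' and writes deterministic TSV outputs plus a `manifest.json` into
#' `out_dir`. Rerunning with the same inputs and seed reproduces every output
#' byte for byte.
#'
#' @param data A `girscan_sim` or equivalent list (see Details).
#' @param out_dir Output directory (created if absent).
#' @param qc A [qc_config()].
#' @param scan A [scan_config()].
#' @param n_pc Retained PCs for the structure stage.
#' @param k_grid Candidate cluster counts.
#' @param seed Integer seed for the stochastic stages.
#' @param half_width Candidate-window half width (bp).
#' @param ihs_cutoff `"empirical_null"` or `"fixed"`.
#' @param ihs_p_fixed Fixed two-sided p threshold when `ihs_cutoff = "fixed"`.
#' @param intervals Optional interval tibble ([read_intervals()]) for the
#'   annotation stage.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(data, out_dir, qc = qc_config(), scan = scan_config(),
                         n_pc = 10, k_grid = 1:5, seed, half_width = 250000,
                         ihs_cutoff = c("empirical_null", "fixed"),
                         ihs_p_fixed = 0.01, intervals = NULL) {
  if (missing(seed)) abort("`seed` is mandatory")
  ihs_cutoff <- match.arg(ihs_cutoff)
  for (el in c("genotypes_combined", "panels", "labels")) {
    if (is.null(data[[el]])) abort(paste0("`data` is missing element ", el))
  }
  if (length(data$panels) != 2L) abort("exactly two population panels required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(seed = seed, package_version = as.character(
    utils::packageVersion("girscan")), stages = list())
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), out$meta %||% list())
    flush_manifest()
    out$value
  }

  res$qc <- stage("qc", function() {
    q <- run_qc(data$genotypes_combined, qc)
    write_table(q$report, file.path(out_dir, "qc_report.tsv"))
    freqs <- allele_frequencies(q$genotypes, data$labels)
    write_table(freqs, file.path(out_dir, "allele_frequencies.tsv"))
    list(value = c(q, list(freqs = freqs)),
         meta = list(snps_in = ncol(data$genotypes_combined$calls),
                     snps_out = ncol(q$genotypes$calls),
                     samples_out = length(q$genotypes$samples)))
  })
  g <- res$qc$genotypes

  res$structure <- stage("structure", function() {
    dapc <- run_dapc(g, n_pc = min(n_pc, length(g$samples) - 1L),
                     k_grid = k_grid, seed = seed)
    write_table(tidy(dapc$pca), file.path(out_dir, "pca_eigenvalues.tsv"))
    write_table(pca_scores(dapc$pca, data$labels),
                file.path(out_dir, "pca_scores.tsv"))
    write_table(tidy(dapc$clusters), file.path(out_dir, "bic.tsv"))
    assignments <- tibble(sample_id = names(dapc$clusters$assignments),
                          cluster = unname(dapc$clusters$assignments))
    write_table(assignments, file.path(out_dir, "assignments.tsv"))
    if (!is.null(dapc$discriminants)) {
      write_table(as_tibble(dapc$discriminants),
                  file.path(out_dir, "discriminant_scores.tsv"))
    }
    list(value = dapc, meta = list(best_k = dapc$clusters$best_k))
  })

  res$diversity <- stage("diversity", function() {
    div <- per_locus_stats(g, data$labels) %>% clamp_negative_fst()
    fo <- fst_outliers(div)
    write_table(fo$snps, file.path(out_dir, "diversity.tsv"))
    write_table(fo$thresholds, file.path(out_dir, "fst_thresholds.tsv"))
    write_table(per_chromosome_heterozygosity(g, data$labels),
                file.path(out_dir, "chromosome_heterozygosity.tsv"))
    overall <- diversity_overall(div)
    write_table(overall, file.path(out_dir, "diversity_overall.tsv"))
    list(value = fo, meta = list(n_outliers = sum(fo$snps$outlier),
                                 n_clamped = attr(div, "n_clamped"),
                                 mean_fst = overall$mean_fst))
  })

  pops <- names(data$panels)
  res$ihs <- stage("ihs", function() {
    value <- list()
    meta <- list()
    for (pop in pops) {
      panel <- data$panels[[pop]]
      keep <- intersect(g$map$snp_id, panel$map$snp_id)
      sc <- ihs_scan(subset_markers(panel, keep), scan)
      cut <- if (ihs_cutoff == "fixed") {
        empirical_null_cutoff(sc, mode = "fixed", p_fixed = ihs_p_fixed)
      } else {
        empirical_null_cutoff(sc, mode = "empirical_null")
      }
      sc <- mark_significant(sc, cut$cutoff_pihs)
      write_table(sc, file.path(out_dir, paste0("ihs_", pop, ".tsv")))
      value[[pop]] <- list(scan = sc, cutoff = cut)
      meta[[pop]] <- list(cutoff_pihs = cut$cutoff_pihs,
                          n_significant = sum(sc$significant))
    }
    list(value = value, meta = meta)
  })

  res$xpehh <- stage("xpehh", function() {
    keep <- intersect(g$map$snp_id, data$panels[[1]]$map$snp_id)
    sc <- xpehh_scan(subset_markers(data$panels[[1]], keep),
                     subset_markers(data$panels[[2]], keep), scan)
    write_table(sc, file.path(out_dir, "xpehh.tsv"))
    list(value = sc, meta = list(n_significant = sum(sc$significant),
                                 reference = pops[1], observed = pops[2]))
  })

  res$windows <- stage("windows", function() {
    sig <- list()
    fo <- res$diversity$snps
    if (any(fo$outlier)) {
      sig$fst <- fo %>% filter(.data$outlier) %>%
        mutate(method = "fst", population = "both", score = .data$fst) %>%
        select("chrom", "pos_bp", "snp_id", "score", "method", "population")
    }
    for (pop in pops) {
      sc <- res$ihs[[pop]]$scan
      if (any(sc$significant)) {
        sig[[paste0("ihs_", pop)]] <- sc %>% filter(.data$significant) %>%
          mutate(method = "ihs", population = pop, score = .data$ihs) %>%
          select("chrom", "pos_bp", "snp_id", "score", "method", "population")
      }
    }
    xp <- res$xpehh
    if (any(xp$significant)) {
      sig$xpehh <- xp %>% filter(.data$significant) %>%
        mutate(method = "xpehh",
               population = ifelse(.data$direction == "reference",
                                   pops[1], pops[2]),
               score = .data$xpehh) %>%
        select("chrom", "pos_bp", "snp_id", "score", "method", "population")
    }
    win <- make_windows(bind_rows(sig), half_width = half_width)
    write_table(win, file.path(out_dir, "windows.tsv"))
    # BED export: back to 0-based half-open
    bed <- win %>%
      mutate(start0 = format(.data$start_bp - 1, scientific = FALSE,
                             trim = TRUE),
             end0 = format(.data$end_bp, scientific = FALSE, trim = TRUE),
             label = paste(.data$method, .data$population,
                           .data$peak_snp_id, sep = "|"))
    writeLines(paste(bed$chrom, bed$start0, bed$end0, bed$label, sep = "\t"),
               file.path(out_dir, "windows.bed"))
    list(value = win, meta = list(n_windows = nrow(win)))
  })

  if (!is.null(intervals)) {
    res$annotate <- stage("annotate", function() {
      hits <- overlap_intervals(res$windows, intervals)
      write_table(hits, file.path(out_dir, "gene_hits.tsv"))
      consensus <- consensus_genes(hits)
      write_table(consensus, file.path(out_dir, "consensus_genes.tsv"))
      list(value = list(hits = hits, consensus = consensus),
           meta = list(n_genes = nrow(hits),
                       n_multi_method = sum(consensus$n_methods >= 2)))
    })
  }

  if (inherits(data, "girscan_sim")) {
    res$truth_check <- stage("truth_check", function() {
      cmp <- left_join(data$truth,
                       res$diversity$snps[, c("snp_id", "fst", "outlier")],
                       by = "snp_id")
      write_table(cmp, file.path(out_dir, "truth_comparison.tsv"))
      list(value = cmp,
           meta = list(selected_flagged =
                         sum(cmp$outlier & cmp$selected, na.rm = TRUE)))
    })
  }

  manifest$status <- "complete"
  flush_manifest()
  res$manifest <- manifest
  invisible(res)
}
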