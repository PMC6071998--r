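# Candidate windows around significant SNPs and their overlap with gene/QTL
# intervals. Coordinates are 1-based inclusive; overlap is any-overlap
# (>= 1 bp). Interval arithmetic is delegated to IRanges.

#' Build candidate windows around significant SNPs
#'
#' Each significant SNP spawns a window `[pos - half_width, pos + half_width]`
#' (500 kb total at the default), clipped at 1 and, when chromosome lengths
#' are supplied, at the chromosome end. Overlapping windows on the same
#' chromosome from the same method and population are merged, keeping the
#' peak SNP with the largest absolute score.
#'
#' @param sig_snps Tibble with `chrom`, `pos_bp`, `snp_id`, `score`, and
#'   optional `method` and `population` columns (merge groups).
#' @param half_width Half window width in bp.
#' @param merge Merge overlapping windows?
#' @param chrom_lengths Optional named vector of chromosome lengths (names =
#'   chromosome ids).
#' @return A tibble of windows: `chrom`, `start_bp`, `end_bp`, `method`,
#'   `population`, `peak_snp_id`, `peak_pos_bp`, `peak_score`, `merged_from`.
#' @export
make_windows <- function(sig_snps, half_width = 250000, merge = TRUE,
                         chrom_lengths = NULL) {
  cols <- c("chrom", "start_bp", "end_bp", "method", "population",
            "peak_snp_id", "peak_pos_bp", "peak_score", "merged_from")
  empty <- tibble(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  method = character(), population = character(),
                  peak_snp_id = character(), peak_pos_bp = numeric(),
                  peak_score = numeric(), merged_from = integer())
  if (is.null(sig_snps) || nrow(sig_snps) == 0L) return(empty)
  s <- as_tibble(sig_snps)
  if (!"method" %in% names(s)) s$method <- NA_character_
  if (!"population" %in% names(s)) s$population <- NA_character_
  if (!"score" %in% names(s)) s$score <- NA_real_
  s$start_bp <- pmax(1, s$pos_bp - half_width)
  s$end_bp <- s$pos_bp + half_width
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[as.character(s$chrom)]
    s$end_bp <- pmin(s$end_bp, ifelse(is.na(len), s$end_bp, len))
  }
  if (!merge) {
    return(select(mutate(s, peak_snp_id = .data$snp_id,
                         peak_pos_bp = .data$pos_bp, peak_score = .data$score,
                         merged_from = 1L),
                  all_of(cols)))
  }
  groups <- split(s, interaction(s$chrom, s$method, s$population, drop = TRUE))
  merged <- lapply(groups, function(gr) {
    ir <- IRanges::IRanges(start = gr$start_bp, end = gr$end_bp)
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red)
    member <- S4Vectors::subjectHits(hit)
    purrr::map_dfr(seq_along(red), function(w) {
      rows <- gr[member == w, ]
      peak <- rows[which.max(abs(rows$score)), ]
      tibble(chrom = rows$chrom[1],
             start_bp = as.numeric(IRanges::start(red)[w]),
             end_bp = as.numeric(IRanges::end(red)[w]),
             method = rows$method[1], population = rows$population[1],
             peak_snp_id = peak$snp_id, peak_pos_bp = peak$pos_bp,
             peak_score = peak$score, merged_from = nrow(rows))
    })
  })
  arrange(bind_rows(merged), .data$chrom, .data$start_bp)
}

#' Overlap candidate windows with gene/QTL intervals
#'
#' Reports every interval that overlaps a window by at least 1 bp (1-based
#' inclusive on both sides). Intervals on chromosomes absent from the window
#' set are skipped with a warning.
#'
#' @param windows Output of [make_windows()].
#' @param intervals An interval tibble from [read_intervals()].
#' @return A tibble of hits: `name`, `category`, `chrom`, `start_bp`,
#'   `end_bp`, `n_windows`, `methods`, `populations` (comma-collapsed sets).
#' @export
overlap_intervals <- function(windows, intervals) {
  empty <- tibble(name = character(), category = character(),
                  chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  n_windows = integer(), methods = character(),
                  populations = character())
  if (nrow(windows) == 0L || nrow(intervals) == 0L) return(empty)
  iv <- as_tibble(intervals)
  off <- !iv$chrom %in% unique(windows$chrom)
  if (any(off)) {
    warn(paste0(sum(off), " interval(s) on chromosomes without windows skipped"))
    iv <- iv[!off, ]
  }
  if (nrow(iv) == 0L) return(empty)
  hits <- purrr::map_dfr(unique(iv$chrom), function(ch) {
    ivc <- iv[iv$chrom == ch, ]
    wc <- windows[windows$chrom == ch, ]
    if (nrow(wc) == 0L) return(NULL)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ivc$start_bp, ivc$end_bp),
      IRanges::IRanges(wc$start_bp, wc$end_bp))
    if (!length(ov)) return(NULL)
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    tibble(name = ivc$name[q], category = ivc$category[q], chrom = ch,
           start_bp = ivc$start_bp[q], end_bp = ivc$end_bp[q],
           method = wc$method[s], population = wc$population[s])
  })
  if (nrow(hits) == 0L) return(empty)
  hits %>%
    group_by(.data$name, .data$category, .data$chrom, .data$start_bp,
             .data$end_bp) %>%
    summarise(n_windows = dplyr::n(),
              methods = paste(sort(unique(stats::na.omit(.data$method))),
                              collapse = ","),
              populations = paste(sort(unique(stats::na.omit(.data$population))),
                                  collapse = ","),
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start_bp)
}

#' Cross-method consensus genes
#'
#' Unions per-method gene hits and reports, per gene, the set of supporting
#' methods (and populations), filterable to genes supported by at least
#' `min_methods` approaches.
#'
#' @param hits A [overlap_intervals()] result carrying a `methods` column, or
#'   a named list of such results (names are used when a result's `methods`
#'   field is empty).
#' @param min_methods Keep genes supported by at least this many methods.
#' @return A tibble: `name`, `category`, `chrom`, `start_bp`, `end_bp`,
#'   `methods`, `n_methods`, `populations`.
#' @export
consensus_genes <- function(hits, min_methods = 1) {
  if (is.data.frame(hits)) hits <- list(hits)
  tagged <- purrr::imap_dfr(hits, function(h, nm) {
    if (nrow(h) == 0L) return(NULL)
    if (!is.null(nm) && nzchar(nm)) {
      blank <- is.na(h$methods) | h$methods == ""
      h$methods[blank] <- nm
    }
    h
  })
  if (is.null(tagged) || nrow(tagged) == 0L) {
    return(tibble(name = character(), category = character(),
                  chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  methods = character(), n_methods = integer(),
                  populations = character()))
  }
  tagged %>%
    tidyr::separate_rows("methods", sep = ",") %>%
    group_by(.data$name, .data$category, .data$chrom, .data$start_bp,
             .data$end_bp) %>%
    summarise(
      n_methods = dplyr::n_distinct(.data$methods),
      methods = paste(sort(unique(.data$methods)), collapse = ","),
      populations = paste(sort(unique(unlist(strsplit(
        stats::na.omit(.data$populations), ",")))), collapse = ","),
      .groups = "drop") %>%
    filter(.data$n_methods >= min_methods) %>%
    arrange(dplyr::desc(.data$n_methods), .data$chrom, .data$start_bp)
}
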