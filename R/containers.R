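# Matrix-backed containers. Genotypes and haplotypes stay as integer matrices
# for speed; everything a user normally touches is exposed as a tibble.

#' Construct a genotype matrix
#'
#' Bundles a samples-by-SNPs dosage matrix with its marker map. Calls count
#' copies of the marker's counted allele (`allele_b` in the map), so each cell
#' is 0, 1, 2 or `NA` for a missing call.
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns; values in
#'   `{0, 1, 2, NA}`.
#' @param map Marker map tibble with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`, `ancestral_allele` (may be `NA`). One row per
#'   column of `calls`, same order.
#' @param samples Character vector of sample ids, one per row of `calls`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- validate_marker_map(map)
  if (is.null(samples)) abort("sample ids are required")
  samples <- as.character(samples)
  if (nrow(calls) != length(samples)) {
    abort("`calls` must have one row per sample")
  }
  if (ncol(calls) != nrow(map)) {
    abort("`calls` must have one column per marker map row")
  }
  calls <- calls[, attr(map, "perm"), drop = FALSE]
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, map$snp_id)
  structure(list(calls = calls, map = map, samples = samples),
            class = "geno_matrix")
}

#' Construct a phased haplotype panel
#'
#' Holds a haplotypes-by-SNPs allele matrix (two rows per sample) together
#' with the marker map. In `raw` coding the 0/1 codes index `allele_a` /
#' `allele_b` of the map; after [recode_ancestral()] the coding is
#' `ancestral` and 0 = ancestral, 1 = derived.
#'
#' @param haps Integer matrix of 0/1 allele codes (`NA` = missing),
#'   2 * n_samples rows.
#' @param map Marker map tibble (see [geno_matrix()]).
#' @param samples Character vector of sample ids (length `nrow(haps) / 2`);
#'   haplotype rows are ordered sample-by-sample, two consecutive rows each.
#' @param coding `"raw"` or `"ancestral"`.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haps, map, samples, coding = c("raw", "ancestral")) {
  coding <- match.arg(coding)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  map <- validate_marker_map(map)
  samples <- as.character(samples)
  if (nrow(haps) != 2L * length(samples)) {
    abort("a haplotype panel needs exactly two rows per sample")
  }
  if (ncol(haps) != nrow(map)) {
    abort("`haps` must have one column per marker map row")
  }
  haps <- haps[, attr(map, "perm"), drop = FALSE]
  bad <- haps[!is.na(haps)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 1L)) {
    abort("haplotype allele codes must be 0, 1 or NA")
  }
  soh <- rep(samples, each = 2L)
  rownames(haps) <- paste0(soh, "_", rep(1:2, length(samples)))
  colnames(haps) <- map$snp_id
  structure(list(haps = haps, map = map, samples = samples,
                 sample_of_haplotype = soh, coding = coding),
            class = "hap_panel")
}

validate_marker_map <- function(map) {
  map <- as_tibble(map)
  needed <- c("snp_id", "chrom", "pos_bp")
  miss <- setdiff(needed, names(map))
  if (length(miss)) {
    abort(paste0("marker map is missing column(s): ", paste(miss, collapse = ", ")))
  }
  for (col in c("allele_a", "allele_b", "ancestral_allele")) {
    if (!col %in% names(map)) map[[col]] <- NA_character_
  }
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  if (anyNA(map$chrom) || any(map$chrom < 1L)) {
    abort("chromosomes must be positive integers")
  }
  if (any(map$pos_bp < 1)) abort("positions must be >= 1 (1-based bp)")
  if (anyDuplicated(map$snp_id)) {
    abort(paste0("duplicated snp_id: ",
                 paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", ")))
  }
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, ]
  dup_pos <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup_pos)) {
    abort("positions must be strictly increasing within a chromosome")
  }
  attr(map, "perm") <- ord
  map
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ", nrow(x$map),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s); ",
      format(100 * mean(is.na(x$calls)), digits = 3), "% missing\n", sep = "")
  invisible(x)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", nrow(x$haps), " haplotypes (", length(x$samples),
      " samples) x ", nrow(x$map), " SNPs; coding: ", x$coding, "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' @export
dim.hap_panel <- function(x) dim(x$haps)

#' Tidy a genotype matrix into long format
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, SNP) call.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble(sample_id = rep(x$samples, times = ncol(x$calls)),
         snp_id = rep(x$map$snp_id, each = nrow(x$calls)),
         dosage = as.integer(x$calls))
}

#' Restrict a container to a set of markers
#'
#' @param x A [geno_matrix()] or [hap_panel()].
#' @param snp_ids Character vector of marker ids to keep (map order preserved).
#' @return An object of the same class as `x`.
#' @export
subset_markers <- function(x, snp_ids) {
  keep <- x$map$snp_id %in% snp_ids
  if (!any(keep)) abort("no markers left after subsetting")
  if (inherits(x, "geno_matrix")) {
    geno_matrix(x$calls[, keep, drop = FALSE], x$map[keep, ], x$samples)
  } else if (inherits(x, "hap_panel")) {
    hap_panel(x$haps[, keep, drop = FALSE], x$map[keep, ], x$samples,
              coding = x$coding)
  } else {
    abort("`x` must be a geno_matrix or hap_panel")
  }
}

#' Restrict a genotype matrix to a set of samples
#'
#' @param x A [geno_matrix()].
#' @param sample_ids Sample ids to keep.
#' @return A [geno_matrix()].
#' @export
subset_samples <- function(x, sample_ids) {
  keep <- x$samples %in% sample_ids
  if (!any(keep)) abort("no samples left after subsetting")
  geno_matrix(x$calls[keep, , drop = FALSE], x$map, x$samples[keep])
}
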