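# Readers and writers for the formats the pipeline consumes: PED/MAP and VCF
# genotypes, phased VCF / haplotype-table panels, BED intervals, label TSVs.
# Coordinates are 1-based inclusive internally; BED is converted at the
# boundary. Chromosome names may carry a "chr" prefix, which is stripped.

norm_chrom <- function(x) {
  suppressWarnings(as.integer(sub("^[Cc]hr", "", as.character(x))))
}

STRAND_AMBIGUOUS <- list(c("A", "T"), c("C", "G"))

is_strand_ambiguous <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Read diploid genotypes
#'
#' Reads a PED/MAP pair or a VCF into a [geno_matrix()], keeping only markers
#' on the listed autosomes and sorting them by (chromosome, position).
#' Unphased genotypes are accepted; `./.` (VCF) or allele code `0` (PED)
#' become missing calls. For a VCF the counted allele is ALT and an `AA=` INFO
#' tag, when present, populates the ancestral allele. For PED the two alleles
#' observed at a marker are ordered alphabetically and the second is counted.
#'
#' @param path Path to the `.ped` file (or prefix of the pair) or to the VCF.
#' @param format `"ped_map"` or `"vcf"`.
#' @param autosomes Integer vector of admissible chromosomes (cattle: 1-29).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("ped_map", "vcf"),
                           autosomes = 1:29) {
  format <- match.arg(format)
  g <- switch(format,
              ped_map = read_ped_map(path),
              vcf = read_vcf_genotypes(path))
  keep <- g$map$chrom %in% as.integer(autosomes)
  if (!any(keep)) abort("no SNPs left after restricting to the autosome set")
  geno_matrix(g$calls[, keep, drop = FALSE], g$map[keep, ], g$samples)
}

read_ped_map <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_file <- paste0(prefix, ".ped")
  map_file <- paste0(prefix, ".map")
  for (f in c(ped_file, map_file)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  map_lines <- readLines(map_file)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "\\s+")
  nf <- lengths(map_fields)
  if (length(nf) && !all(nf %in% c(3L, 4L))) {
    abort(paste0("malformed MAP line ", which(!nf %in% c(3L, 4L))[1],
                 " in ", map_file))
  }
  chrom <- norm_chrom(vapply(map_fields, `[`, "", 1L))
  snp_id <- vapply(map_fields, `[`, "", 2L)
  pos <- suppressWarnings(as.numeric(vapply(map_fields, function(f) f[length(f)], "")))
  if (anyNA(pos)) {
    abort(paste0("malformed MAP line ", which(is.na(pos))[1], " in ", map_file))
  }
  n_snp <- length(snp_id)

  ped_lines <- readLines(ped_file)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "\\s+")
  expected <- 6L + 2L * n_snp
  bad <- which(lengths(ped_fields) != expected)
  if (length(bad)) {
    abort(paste0("malformed PED line ", bad[1], " in ", ped_file,
                 ": expected ", expected, " fields, found ",
                 lengths(ped_fields)[bad[1]]))
  }
  samples <- vapply(ped_fields, `[`, "", 2L)
  al <- matrix(unlist(lapply(ped_fields, `[`, -(1:6))),
               nrow = length(samples), byrow = TRUE)
  al[al == "0"] <- NA_character_
  a1 <- al[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]

  allele_a <- allele_b <- rep(NA_character_, n_snp)
  calls <- matrix(NA_integer_, length(samples), n_snp)
  for (j in seq_len(n_snp)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2L) {
      abort(paste0("marker ", snp_id[j], " has more than two alleles"))
    }
    if (length(obs) >= 1L) allele_a[j] <- obs[1L]
    if (length(obs) == 2L) allele_b[j] <- obs[2L]
    ok <- !is.na(a1[, j]) & !is.na(a2[, j])
    if (!is.na(allele_b[j])) {
      calls[ok, j] <- (a1[ok, j] == allele_b[j]) + (a2[ok, j] == allele_b[j])
    } else {
      calls[ok, j] <- 0L
    }
  }
  map <- tibble(snp_id = snp_id, chrom = chrom, pos_bp = pos,
                allele_a = allele_a, allele_b = allele_b,
                ancestral_allele = NA_character_)
  list(calls = calls, map = fix_chrom_na(map), samples = samples)
}

# Non-numeric chromosomes (X, MT, ...) are never autosomes; park them on a
# sentinel above any real autosome so map validation passes and the autosome
# filter drops them.
fix_chrom_na <- function(map) {
  if (anyNA(map$chrom)) {
    map$chrom[is.na(map$chrom)] <- max(c(map$chrom, 0L), na.rm = TRUE) + 1000L
  }
  map
}

read_vcf_body <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ids <- fix$ID
  noid0 <- is.na(ids) | ids == "."
  ids[noid0] <- paste0(fix$CHROM[noid0], "_", fix$POS[noid0])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated snp_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(paste0(sum(multi), " multi-allelic record(s) dropped"))
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  aa <- rep(NA_character_, nrow(fix))
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("(?<=^AA=|;AA=)[A-Za-z.]+", fix$INFO,
                                      perl = TRUE))
    has <- grepl("(^|;)AA=", fix$INFO)
    aa[has] <- m
    aa[aa == "."] <- NA_character_
  }
  snp_id <- fix$ID
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  map <- tibble(snp_id = snp_id,
                chrom = norm_chrom(fix$CHROM),
                pos_bp = as.numeric(fix$POS),
                allele_a = fix$REF, allele_b = fix$ALT,
                ancestral_allele = toupper(aa))
  list(map = fix_chrom_na(map), gt = gt)
}

read_vcf_genotypes <- function(path) {
  body <- read_vcf_body(path)
  gt <- body$gt
  samples <- colnames(gt)
  alleles <- function(x) strsplit(x, "[/|]")
  n_snp <- nrow(gt)
  calls <- matrix(NA_integer_, length(samples), n_snp)
  for (j in seq_len(n_snp)) {
    parts <- alleles(gt[j, ])
    dose <- vapply(parts, function(p) {
      if (length(p) != 2L || anyNA(p) || any(p == ".")) return(NA_integer_)
      sum(p == "1")
    }, integer(1))
    calls[, j] <- dose
  }
  list(calls = calls, map = body$map, samples = samples)
}

#' Read phased haplotypes
#'
#' Reads a phased VCF or a plain haplotype table into a [hap_panel()] in raw
#' allele coding (0 = `allele_a`/REF, 1 = `allele_b`/ALT). Every genotype in a
#' phased VCF must use the `|` separator; an unphased record is an error. The
#' haplotype-table dialect is a TSV whose first six columns are the marker map
#' (`snp_id`, `chrom`, `pos_bp`, `allele_a`, `allele_b`, `ancestral_allele`)
#' followed by two 0/1 columns per sample named `<sample>_1`, `<sample>_2`.
#'
#' @param path Input file path.
#' @param format `"vcf_phased"` or `"hap_table"`.
#' @return A [hap_panel()] with two rows per sample, ordered
#'   sample-by-sample (haplotype A then B).
#' @export
read_haplotypes <- function(path, format = c("vcf_phased", "hap_table")) {
  format <- match.arg(format)
  if (format == "vcf_phased") {
    body <- read_vcf_body(path)
    gt <- body$gt
    samples <- colnames(gt)
    unphased <- which(!grepl("|", gt, fixed = TRUE) & !is.na(gt))
    if (length(unphased)) {
      j <- (unphased[1] - 1) %% nrow(gt) + 1
      abort(paste0("unphased genotype at record ", body$map$snp_id[j]))
    }
    n_snp <- nrow(gt)
    haps <- matrix(NA_integer_, 2L * length(samples), n_snp)
    for (j in seq_len(n_snp)) {
      parts <- strsplit(gt[j, ], "|", fixed = TRUE)
      a <- vapply(parts, function(p) {
        if (length(p) != 2L || any(p == ".")) return(c(NA_integer_, NA_integer_))
        as.integer(p)
      }, integer(2))
      haps[, j] <- as.integer(a)
    }
    hap_panel(haps, body$map, samples, coding = "raw")
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    meta_cols <- c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b",
                   "ancestral_allele")
    miss <- setdiff(meta_cols, names(tab))
    if (length(miss)) {
      abort(paste0("haplotype table is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    hcols <- setdiff(names(tab), meta_cols)
    if (!length(hcols) || length(hcols) %% 2L != 0L) {
      abort("haplotype table needs two columns per sample")
    }
    samples <- unique(sub("_[12]$", "", hcols))
    expect <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
    if (!identical(sort(hcols), sort(expect))) {
      abort("haplotype columns must come in <sample>_1/<sample>_2 pairs")
    }
    haps <- t(as.matrix(tab[, expect]))
    hap_panel(haps, tab[, meta_cols], samples, coding = "raw")
  }
}

#' Write phased haplotypes
#'
#' Writes a [hap_panel()] as a phased VCF (raw coding required) or as the
#' haplotype-table TSV dialect of [read_haplotypes()]. Reading the written
#' file back yields an identical panel.
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @param format `"vcf_phased"` or `"hap_table"`.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path, format = c("vcf_phased", "hap_table")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "hap_panel"))
  map <- panel$map
  if (format == "vcf_phased") {
    if (panel$coding != "raw") {
      abort("phased VCF output requires raw allele coding")
    }
    i1 <- seq(1L, nrow(panel$haps), by = 2L)
    gt <- matrix(paste0(t(panel$haps)[, i1], "|", t(panel$haps)[, i1 + 1L]),
                 nrow = nrow(map))
    gt[grepl("NA", gt)] <- ".|."
    info <- ifelse(is.na(map$ancestral_allele), ".",
                   paste0("AA=", map$ancestral_allele))
    header <- c("##fileformat=VCFv4.2",
                "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", panel$samples), collapse = "\t"))
    body <- cbind(map$chrom,
                  format(map$pos_bp, scientific = FALSE, trim = TRUE),
                  map$snp_id, map$allele_a, map$allele_b, ".", "PASS",
                  info, "GT", gt)
    writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), path)
  } else {
    tab <- as_tibble(map[, c("snp_id", "chrom", "pos_bp", "allele_a",
                             "allele_b", "ancestral_allele")])
    hm <- t(panel$haps)
    colnames(hm) <- as.vector(rbind(paste0(panel$samples, "_1"),
                                    paste0(panel$samples, "_2")))
    write_table(dplyr::bind_cols(tab, as_tibble(hm)), path)
  }
  invisible(path)
}

#' Recode a haplotype panel to ancestral/derived alleles
#'
#' Maps raw allele codes to 0 = ancestral, 1 = derived using the ancestral
#' alleles in the marker map. A marker whose ancestral state is unknown, whose
#' ancestral allele matches neither observed allele, or whose allele pair is
#' strand-ambiguous (A/T or C/G) has all its alleles set missing; those
#' markers are listed in the returned report. Matching is on the reported
#' strand only.
#'
#' @param panel A [hap_panel()] in raw coding.
#' @param map Optional replacement marker map carrying `ancestral_allele`
#'   (defaults to the panel's own map).
#' @return A list with `panel` (recoded, coding `"ancestral"`) and `report`,
#'   a tibble of markers set missing with the reason
#'   (`unknown_ancestral`, `strand_ambiguous`, `incompatible_ancestral`).
#' @export
recode_ancestral <- function(panel, map = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  if (panel$coding == "ancestral") {
    abort("panel is already in ancestral/derived coding")
  }
  m <- map %||% panel$map
  m <- validate_marker_map(m)
  if (!identical(m$snp_id, panel$map$snp_id)) {
    idx <- match(panel$map$snp_id, m$snp_id)
    if (anyNA(idx)) abort("`map` does not cover all panel markers")
    m <- m[idx, ]
  }
  anc <- toupper(m$ancestral_allele)
  a <- toupper(m$allele_a)
  b <- toupper(m$allele_b)

  reason <- rep(NA_character_, nrow(m))
  reason[is.na(anc)] <- "unknown_ancestral"
  amb <- !is.na(anc) & !is.na(a) & !is.na(b) & is_strand_ambiguous(a, b)
  reason[amb] <- "strand_ambiguous"
  incomp <- is.na(reason) & !(
    (!is.na(a) & anc == a) | (!is.na(b) & anc == b))
  reason[incomp] <- "incompatible_ancestral"

  haps <- panel$haps
  flip <- is.na(reason) & !is.na(b) & anc == b
  if (any(flip)) {
    haps[, flip] <- 1L - haps[, flip]
  }
  drop <- !is.na(reason)
  if (any(drop)) haps[, drop] <- NA_integer_

  newmap <- panel$map
  newmap$ancestral_allele <- anc
  out <- hap_panel(haps, newmap, panel$samples, coding = "ancestral")
  report <- tibble(snp_id = m$snp_id[drop], reason = reason[drop])
  list(panel = out, report = report)
}

#' Read gene/QTL intervals from a BED file
#'
#' BED records are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention (`start_bp = start + 1`, `end_bp = end`).
#' Records on chromosomes that are not positive integers (after stripping a
#' `chr` prefix) are skipped with a warning; the count of skipped records is
#' attached as attribute `n_skipped`.
#'
#' @param path BED file path. Columns: chrom, start, end, name, and an
#'   optional category (defaults to `"gene"`).
#' @return A tibble with columns `chrom`, `start_bp`, `end_bp`, `name`,
#'   `category`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  empty <- tibble(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  name = character(), category = character())
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("malformed BED line ", which(nf < 3L)[1]))
  }
  chrom <- norm_chrom(vapply(fields, `[`, "", 1L))
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    abort(paste0("malformed BED line ",
                 which(is.na(start0) | is.na(end0))[1]))
  }
  if (any(start0 >= end0)) {
    abort(paste0("interval with start >= end at BED line ",
                 which(start0 >= end0)[1]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  category <- ifelse(nf >= 5L,
                     vapply(fields, function(f) f[min(5L, length(f))], ""),
                     "gene")
  bad_chrom <- is.na(chrom) | chrom < 1L
  if (any(bad_chrom)) {
    warn(paste0(sum(bad_chrom), " BED record(s) on unrecognised chromosomes skipped"))
  }
  out <- tibble(chrom = chrom, start_bp = start0 + 1, end_bp = end0,
                name = name, category = category)[!bad_chrom, ]
  attr(out, "n_skipped") <- sum(bad_chrom)
  out
}

#' Read population labels
#'
#' @param path TSV with header columns `sample_id` and `population`.
#' @return A tibble with those two columns.
#' @export
read_labels <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("sample_id", "population"), names(tab))
  if (length(miss)) {
    abort(paste0("labels file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab$population <- as.character(tab$population)
  if (anyDuplicated(tab$sample_id)) abort("duplicated sample_id in labels")
  tab[, c("sample_id", "population")]
}

# Every genotyped sample must carry exactly one label; populations need at
# least two samples for diversity statistics.
check_labels <- function(labels, samples) {
  labels <- as_tibble(labels)
  missing_lab <- setdiff(samples, labels$sample_id)
  if (length(missing_lab)) {
    abort(paste0(length(missing_lab), " sample(s) have no population label"))
  }
  lab <- labels$population[match(samples, labels$sample_id)]
  if (any(table(lab) < 2L)) {
    abort("every population needs at least 2 samples")
  }
  setNames(lab, samples)
}

#' Write a result table as TSV
#'
#' Deterministic TSV output (header row, columns in the order given,
#' `NA` literal for missing values).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(path)
}
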