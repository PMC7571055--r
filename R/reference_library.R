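# Embedded reference library: the 23 HMW-GS allele variant records (22
# distinct subunit names; 1Bx7 is split into group 1 / group 2 / OE variant
# records), the locus haplotypes they occur in, and the measured mass tables
# for the 24 standard and 38 Korean cultivars.

GLU1_LOCI <- c("Glu-A1", "Glu-B1", "Glu-D1")
GLU1_MASS_RANGE <- c(60000, 110000)

# Corrected-mass boundary separating 1Bx7 group 1 (~82,400 Da) from the
# group 2 / OE class (~83,000 Da): midpoint of the two class centroids.
BX7_GROUP_BOUNDARY <- 82700

.fixture_path <- function() {
  p <- system.file("extdata", "glu1", package = "glutencaller")
  if (!nzchar(p)) stop("packaged reference fixtures not found", call. = FALSE)
  p
}

.read_fixture <- function(file, required) {
  if (!file.exists(file))
    stop(sprintf("fixture file not found: %s", file), call. = FALSE)
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("schema error in %s: missing column(s) %s",
                 basename(file), paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  df
}

.check_numeric <- function(df, cols, file) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1L]
      stop(sprintf("schema error in %s: row %d, column '%s' is not numeric",
                   basename(file), bad, col), call. = FALSE)
    }
  }
  invisible(df)
}

# Split a haplotype label into its x/y member display names using the
# haplotype table, e.g. "7+8" -> c(x = "7", y = "8"), "N" -> c(NA, NA).
.haplotype_members <- function(haplotypes, locus, label) {
  row <- haplotypes[haplotypes$locus == locus & haplotypes$label == label, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown %s haplotype label '%s'", locus, label),
         call. = FALSE)
  c(x = row$x, y = row$y)
}

# Resolve a (locus, type, display) triple to a variant id; 1Bx7's display
# "7" is shared by the group 1 and group 2 records, split on corrected mass.
.resolve_variant <- function(alleles, locus, type, display, mass = NULL) {
  hit <- alleles[alleles$locus == locus & alleles$type == type &
                   alleles$display == display, ]
  if (nrow(hit) == 0L)
    stop(sprintf("no allele with display '%s' (%s, %s-type)",
                 display, locus, type), call. = FALSE)
  if (nrow(hit) == 1L) return(hit$variant)
  if (is.null(mass))
    stop(sprintf("display '%s' is ambiguous without a mass", display),
         call. = FALSE)
  corrected <- strip_vp(mass, hit$cys[1L])
  if (corrected < BX7_GROUP_BOUNDARY) hit$variant[grepl("g1$", hit$variant)]
  else hit$variant[grepl("g2$", hit$variant)]
}

.slot_columns <- c(a1x = "a1x_mass", b1x = "b1x_mass", b1y = "b1y_mass",
                   d1x = "d1x_mass", d1y = "d1y_mass")
.slot_locus <- c(a1x = "Glu-A1", b1x = "Glu-B1", b1y = "Glu-B1",
                 d1x = "Glu-D1", d1y = "Glu-D1")
.slot_type <- c(a1x = "x", b1x = "x", b1y = "y", d1x = "x", d1y = "y")

# One observation per printed mass cell, resolved to its variant record.
.reference_observations <- function(alleles, haplotypes, table, source) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    members <- c(
      a1x = unname(.haplotype_members(haplotypes, "Glu-A1", r$glu_a1)["x"]),
      b1x = unname(.haplotype_members(haplotypes, "Glu-B1", r$glu_b1)["x"]),
      b1y = unname(.haplotype_members(haplotypes, "Glu-B1", r$glu_b1)["y"]),
      d1x = unname(.haplotype_members(haplotypes, "Glu-D1", r$glu_d1)["x"]),
      d1y = unname(.haplotype_members(haplotypes, "Glu-D1", r$glu_d1)["y"]))
    out <- list()
    for (slot in names(.slot_columns)) {
      mass <- r[[.slot_columns[[slot]]]]
      if (is.na(members[[slot]])) {
        if (!is.na(mass))
          stop(sprintf("schema error: %s has a %s mass but no %s subunit",
                       r$cultivar, slot, slot), call. = FALSE)
        next
      }
      if (is.na(mass))
        stop(sprintf("schema error: %s lacks the %s mass for subunit %s",
                     r$cultivar, slot, members[[slot]]), call. = FALSE)
      variant <- .resolve_variant(alleles, .slot_locus[[slot]],
                                  .slot_type[[slot]], members[[slot]], mass)
      cys <- alleles$cys[alleles$variant == variant]
      out[[slot]] <- data.frame(
        cultivar = r$cultivar, slot = slot, variant = variant,
        mass = mass, corrected = strip_vp(mass, cys), source = source,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.validate_glu1_library <- function(lib) {
  al <- lib$alleles
  y <- al$type == "y"
  if (!all(al$cys[y] == 7L))
    stop("invariant violated: y-type alleles must have 7 cysteines")
  x_exceptions <- c(`1Dx5` = 5L, `1Bx20` = 2L)
  expected_x <- ifelse(al$name %in% names(x_exceptions),
                       x_exceptions[al$name], 4L)
  if (!all(al$cys[!y] == expected_x[!y]))
    stop("invariant violated: x-type cysteine counts")
  obs <- lib$observations
  if (any(obs$mass < GLU1_MASS_RANGE[1L] | obs$mass > GLU1_MASS_RANGE[2L]))
    stop("invariant violated: reference mass outside the acquisition range")
  hap_members <- c(lib$haplotypes$x, lib$haplotypes$y)
  hap_members <- hap_members[!is.na(hap_members)]
  for (i in seq_len(nrow(lib$haplotypes))) {
    h <- lib$haplotypes[i, ]
    for (type in c("x", "y")) {
      d <- h[[type]]
      if (!is.na(d) &&
          !any(al$locus == h$locus & al$type == type & al$display == d))
        stop(sprintf("haplotype %s references unknown %s-type allele '%s'",
                     h$label, type, d))
    }
  }
  a1y <- lib$haplotypes$locus == "Glu-A1" & !is.na(lib$haplotypes$y)
  if (any(a1y))
    stop("invariant violated: Glu-A1 haplotypes carry no y member")
  b1 <- lib$haplotypes[lib$haplotypes$locus == "Glu-B1", ]
  if (any(is.na(b1$x)))
    stop("invariant violated: Glu-B1 haplotypes always have an x member")
  d1 <- lib$haplotypes[lib$haplotypes$locus == "Glu-D1", ]
  if (any(is.na(d1$x)) || any(is.na(d1$y)))
    stop("invariant violated: Glu-D1 haplotypes have both members")
  invisible(lib)
}

#' Load the embedded HMW-GS reference library
#'
#' Reads the packaged allele, haplotype and cultivar mass tables and derives
#' per-allele reference mass observations (both as measured on alkylated
#' protein and after 4-vinylpyridine correction).
#'
#' @param path Directory holding the five fixture TSVs; defaults to the
#'   tables shipped with the package.
#' @return An object of class `glu1_library` with elements `alleles`,
#'   `haplotypes`, `standards_table`, `korean_table`, `predicted_table` and
#'   `observations`.
#' @examples
#' lib <- load_glu1_library()
#' subset(lib$alleles, name == "1Dx5")$cys  # 5
#' @export
load_glu1_library <- function(path = .fixture_path()) {
  alleles <- .read_fixture(
    file.path(path, "alleles.tsv"),
    c("variant", "name", "display", "locus", "type", "cys",
      "predicted_mass", "sim_mass", "accession", "notes"))
  .check_numeric(alleles, c("cys", "predicted_mass", "sim_mass"),
                 file.path(path, "alleles.tsv"))
  alleles$display <- as.character(alleles$display)
  haplotypes <- .read_fixture(file.path(path, "haplotypes.tsv"),
                              c("locus", "label", "x", "y"))
  for (col in c("label", "x", "y"))
    haplotypes[[col]] <- as.character(haplotypes[[col]])
  mass_cols <- unname(.slot_columns)
  rsd_cols <- sub("_mass$", "_rsd", mass_cols)
  tab_cols <- c("cultivar", "glu_a1", "glu_b1", "glu_d1",
                mass_cols, rsd_cols)
  standards <- .read_fixture(file.path(path, "standards_table2.tsv"),
                             tab_cols)
  korean <- .read_fixture(file.path(path, "korean_table4.tsv"), tab_cols)
  .check_numeric(standards, c(mass_cols, rsd_cols),
                 file.path(path, "standards_table2.tsv"))
  .check_numeric(korean, c(mass_cols, rsd_cols),
                 file.path(path, "korean_table4.tsv"))
  for (col in c("glu_a1", "glu_b1", "glu_d1")) {
    standards[[col]] <- as.character(standards[[col]])
    korean[[col]] <- as.character(korean[[col]])
  }
  predicted <- .read_fixture(
    file.path(path, "predicted_table3.tsv"),
    c("variant", "cultivar", "corrected_mass", "difference", "error_pct"))
  .check_numeric(predicted, c("corrected_mass", "difference", "error_pct"),
                 file.path(path, "predicted_table3.tsv"))

  observations <- rbind(
    .reference_observations(alleles, haplotypes, standards, "standard"),
    .reference_observations(alleles, haplotypes, korean, "korean"))

  # per-variant summaries over the standard cultivars (the calling windows)
  std <- observations[observations$source == "standard", ]
  agg <- function(v, f) vapply(alleles$variant, function(a) {
    x <- v[std$variant == a]
    if (length(x)) f(x) else NA_real_
  }, numeric(1))
  alleles$n_obs <- vapply(alleles$variant,
                          function(a) sum(std$variant == a), numeric(1))
  alleles$ref_mean <- round(agg(std$mass, mean))
  alleles$ref_min <- agg(std$mass, min)
  alleles$ref_max <- agg(std$mass, max)
  alleles$corr_mean <- round(agg(std$corrected, mean))
  alleles$corr_min <- agg(std$corrected, min)
  alleles$corr_max <- agg(std$corrected, max)

  lib <- structure(
    list(alleles = alleles, haplotypes = haplotypes,
         standards_table = standards, korean_table = korean,
         predicted_table = predicted, observations = observations),
    class = "glu1_library")
  .validate_glu1_library(lib)
  lib
}

#' Write a reference library back to fixture files
#'
#' Serialises the five component tables as TSV so that
#' [load_glu1_library()] on the output directory reproduces the library.
#'
#' @param lib A `glu1_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_glu1_library <- function(lib, dir) {
  stopifnot(inherits(lib, "glu1_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(alleles = "alleles.tsv", haplotypes = "haplotypes.tsv",
             standards_table = "standards_table2.tsv",
             korean_table = "korean_table4.tsv",
             predicted_table = "predicted_table3.tsv")
  base_cols <- list(
    alleles = c("variant", "name", "display", "locus", "type", "cys",
                "predicted_mass", "sim_mass", "accession", "notes"),
    haplotypes = c("locus", "label", "x", "y"),
    standards_table = names(lib$standards_table),
    korean_table = names(lib$korean_table),
    predicted_table = names(lib$predicted_table))
  for (el in names(files))
    utils::write.table(lib[[el]][, base_cols[[el]]],
                       file.path(dir, files[[el]]), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}

# Resolve an allele argument (variant id, subunit name, or display label
# unique within the library) to one or more variant ids.
.match_allele <- function(lib, allele) {
  al <- lib$alleles
  if (allele %in% al$variant) return(allele)
  if (allele %in% al$name) return(al$variant[al$name == allele])
  stop(sprintf("unknown allele '%s'", allele), call. = FALSE)
}

#' Reference mass statistics for one subunit allele
#'
#' Mean (rounded to integer Da), minimum, maximum and count of the
#' standard-cultivar reference masses for an allele. `allele` may be a
#' subunit name (`"1Bx7"` pools the group 1 and group 2 variant records) or
#' a variant id (`"1Bx7g1"`).
#'
#' @param lib A `glu1_library`.
#' @param allele Subunit name or variant id.
#' @param corrected If `TRUE`, statistics of the 4-vp-corrected masses;
#'   default is the as-measured (alkylated) masses.
#' @return Named numeric vector `c(mean, min, max, n)`.
#' @examples
#' lib <- load_glu1_library()
#' allele_mass_stats(lib, "1Ax2*")["mean"]  # 86594
#' @export
allele_mass_stats <- function(lib, allele, corrected = FALSE) {
  stopifnot(inherits(lib, "glu1_library"))
  variants <- .match_allele(lib, allele)
  obs <- lib$observations
  x <- obs[obs$source == "standard" & obs$variant %in% variants,
           if (corrected) "corrected" else "mass"]
  if (!length(x))
    stop(sprintf("allele '%s' has no reference masses", allele),
         call. = FALSE)
  c(mean = round(mean(x)), min = min(x), max = max(x), n = length(x))
}

#' Mass-matching window for one subunit allele
#'
#' The window spans the standard-cultivar reference masses padded by `tol`
#' on each side, the matching rule used by the genotype caller.
#'
#' @inheritParams allele_mass_stats
#' @param tol Non-negative padding in Da.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
allele_window <- function(lib, allele, tol = 300, corrected = FALSE) {
  if (length(tol) != 1L || is.na(tol) || tol < 0)
    stop("`tol` must be a single non-negative number", call. = FALSE)
  s <- allele_mass_stats(lib, allele, corrected = corrected)
  c(lo = unname(s["min"]) - tol, hi = unname(s["max"]) + tol)
}

#' @export
print.glu1_library <- function(x, ...) {
  cat(sprintf(paste0(
    "HMW-GS reference library: %d allele variant records (%d subunits),\n",
    "  %d locus haplotypes, %d standard and %d cohort cultivars\n"),
    nrow(x$alleles), length(unique(x$alleles$name)), nrow(x$haplotypes),
    nrow(x$standards_table), nrow(x$korean_table)))
  invisible(x)
}
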