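# Replicate aggregation, predicted-vs-measured comparison tables and
# cohort-level summaries.

#' Aggregate replicate acquisitions of one sample
#'
#' Checks that all replicate genotype calls agree on the composition, then
#' reports the per-subunit mean mass (integer Da, half-up) and replicate
#' RSD. Discordant replicate sets are returned as a discordance report, not
#' aggregated.
#'
#' @param calls List of `genotype_call`s for replicates of one sample
#'   (at least 2).
#' @return A `replicate_set`: either `discordant = FALSE` with a
#'   `subunits` table (`variant`, `name`, `display`, `mean_mass`,
#'   `rsd_pct`, `n`), or `discordant = TRUE` with the per-replicate
#'   compositions.
#' @export
aggregate_replicates <- function(calls) {
  if (length(calls) < 2L)
    stop("need at least 2 replicate calls", call. = FALSE)
  stopifnot(all(vapply(calls, inherits, logical(1), "genotype_call")))
  sample_id <- calls[[1L]]$sample_id
  reps <- vapply(calls, `[[`, character(1), "replicate_id")
  comps <- vapply(calls, `[[`, character(1), "composition")
  if (any(vapply(calls, `[[`, logical(1), "uncallable")) ||
      length(unique(comps)) > 1L) {
    return(structure(list(
      sample_id = sample_id, n_replicates = length(calls),
      discordant = TRUE,
      report = data.frame(replicate_id = reps, composition = comps,
                          stringsAsFactors = FALSE)),
      class = "replicate_set"))
  }
  tmpl <- calls[[1L]]$calls
  subunits <- do.call(rbind, lapply(seq_len(nrow(tmpl)), function(i) {
    masses <- vapply(calls, function(cl)
      cl$calls$peak_mass[cl$calls$slot == tmpl$slot[i]], numeric(1))
    data.frame(slot = tmpl$slot[i], variant = tmpl$variant[i],
               name = tmpl$name[i], display = tmpl$display[i],
               mean_mass = floor(mean(masses) + 0.5),
               rsd_pct = rsd_percent(masses), n = length(masses),
               stringsAsFactors = FALSE)
  }))
  structure(list(sample_id = sample_id, n_replicates = length(calls),
                 discordant = FALSE, composition = comps[[1L]],
                 subunits = subunits),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  if (x$discordant) {
    cat(sprintf("Sample '%s': DISCORDANT across %d replicates\n",
                x$sample_id, x$n_replicates))
    print.data.frame(x$report)
  } else {
    cat(sprintf("Sample '%s' (%d replicates): %s\n", x$sample_id,
                x$n_replicates, x$composition))
    print.data.frame(x$subunits)
  }
  invisible(x)
}

#' Predicted-vs-measured comparison table
#'
#' One row per called subunit: gene-predicted mature-protein mass,
#' 4-vp-corrected measured mass, their difference and percent error via
#' [diff_and_error()]. Alleles without a gene sequence (no predicted mass)
#' get blank difference/error cells.
#'
#' @param lib A `glu1_library`.
#' @param calls A `genotype_call` or list of them.
#' @return `data.frame` with `allele`, `group`, `cultivar`,
#'   `predicted_mass`, `corrected_mass`, `difference`, `error_pct`.
#' @export
comparison_table <- function(lib, calls) {
  stopifnot(inherits(lib, "glu1_library"))
  if (inherits(calls, "genotype_call")) calls <- list(calls)
  al <- lib$alleles
  rows <- lapply(calls, function(cl) {
    if (cl$uncallable) return(NULL)
    cc <- cl$calls[!is.na(cl$calls$corrected_mass), , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    j <- match(cc$variant, al$variant)
    predicted <- al$predicted_mass[j]
    de <- data.frame(difference = rep(NA_integer_, nrow(cc)),
                     error_pct = rep(NA_real_, nrow(cc)))
    has_pred <- !is.na(predicted)
    if (any(has_pred))
      de[has_pred, ] <- diff_and_error(cc$corrected_mass[has_pred],
                                       predicted[has_pred])
    data.frame(allele = cc$name, group = al$notes[j],
               cultivar = cl$sample_id, predicted_mass = predicted,
               corrected_mass = cc$corrected_mass,
               difference = de$difference, error_pct = de$error_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(allele = character(), group = character(),
                      cultivar = character(), predicted_mass = numeric(),
                      corrected_mass = numeric(), difference = integer(),
                      error_pct = numeric())
  out
}

#' Cohort-level summary statistics
#'
#' Per-allele call counts, 1Bx7 carrier and group counts, and the list of
#' library alleles never called in the cohort.
#'
#' @param lib A `glu1_library`.
#' @param calls List of `genotype_call`s.
#' @return List with `n_samples`, `n_uncallable`, `allele_counts` (named
#'   integer vector over subunit names), `bx7_carriers`,
#'   `bx7_carrier_pct`, `bx7_group1`, `bx7_group2` (the heavier mass
#'   class, including calls not yet resolved against the overexpression
#'   allele), `bx7_oe`, and `absent_alleles`.
#' @export
cohort_summary_stats <- function(lib, calls) {
  stopifnot(inherits(lib, "glu1_library"), length(calls) >= 1L)
  if (inherits(calls, "genotype_call")) calls <- list(calls)
  ok <- !vapply(calls, `[[`, logical(1), "uncallable")
  called <- lapply(calls[ok], function(cl)
    cl$calls$name[!is.na(cl$calls$peak_mass)])
  all_names <- unique(lib$alleles$name)
  counts <- stats::setNames(integer(length(all_names)), all_names)
  for (nm in unlist(called)) counts[[nm]] <- counts[[nm]] + 1L
  b1x_name <- vapply(calls[ok], function(cl) {
    b <- cl$calls[cl$calls$slot == "b1x" & !is.na(cl$calls$peak_mass), ]
    if (nrow(b)) b$name else NA_character_
  }, character(1))
  groups <- vapply(calls[ok], `[[`, character(1), "bx7_group")
  carriers <- sum(b1x_name == "1Bx7", na.rm = TRUE)
  list(
    n_samples = length(calls), n_uncallable = sum(!ok),
    allele_counts = counts,
    bx7_carriers = carriers,
    bx7_carrier_pct = round(100 * carriers / length(calls), 1),
    bx7_group1 = sum(groups == "group1", na.rm = TRUE),
    bx7_group2 = sum(groups %in% c("group2", "group2_or_OE"), na.rm = TRUE),
    bx7_oe = sum(groups == "OE", na.rm = TRUE),
    absent_alleles = sort(all_names[counts == 0L]))
}

#' Write a cohort report to disk
#'
#' Writes `calls.tsv` (one row per sample: composition, 1Bx7 group,
#' flags), `subunit_calls.tsv` (one row per called subunit) and
#' `summary.json`.
#'
#' @param cohort A `glu1_cohort` from [call_cohort()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(cohort, dir, formats = c("tsv", "json")) {
  stopifnot(inherits(cohort, "glu1_cohort"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  calls <- cohort$calls
  if ("tsv" %in% formats) {
    per_sample <- do.call(rbind, lapply(calls, function(cl) data.frame(
      sample_id = cl$sample_id,
      composition = cl$composition,
      bx7_group = cl$bx7_group,
      uncallable = cl$uncallable,
      flags = paste(cl$flags, collapse = "; "),
      stringsAsFactors = FALSE)))
    utils::write.table(per_sample, file.path(dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    per_subunit <- do.call(rbind, lapply(calls, function(cl) {
      if (cl$uncallable) return(NULL)
      cbind(sample_id = cl$sample_id, cl$calls)
    }))
    if (!is.null(per_subunit))
      utils::write.table(per_subunit, file.path(dir, "subunit_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         na = "NA")
  }
  if ("json" %in% formats) {
    s <- cohort$summary
    s$allele_counts <- as.list(s$allele_counts)
    jsonlite::write_json(s, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
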