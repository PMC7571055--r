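# Mass-window genotype calling under locus-haplotype constraints, with
# linked-pair disambiguation, 1Bx7 group resolution and orthogonal
# evidence (PCR gene-duplication assay, RP-HPLC subunit confirmation).

#' Orthogonal evidence flags for one sample
#'
#' @param bx7_duplication_pcr `TRUE` if the PCR assay for the 1Bx7 gene
#'   duplication was positive, `FALSE` if negative, `NA` (default) if not
#'   performed. The duplication is what separates the overexpression allele
#'   from the ordinary group 2 protein; the two are not separable by mass.
#' @param rphplc_calls Character vector of subunit labels confirmed by
#'   RP-HPLC retention behaviour (e.g. `"8*"`, `"2*"`); used to resolve the
#'   near-identical-mass pairs 1By8/1By8* and 1Ax2*/1Bx6.
#' @return An `evidence_flags` object.
#' @export
evidence_flags <- function(bx7_duplication_pcr = NA,
                           rphplc_calls = character()) {
  if (!is.logical(bx7_duplication_pcr) || length(bx7_duplication_pcr) != 1L)
    stop("`bx7_duplication_pcr` must be TRUE, FALSE or NA", call. = FALSE)
  structure(list(bx7_duplication_pcr = bx7_duplication_pcr,
                 rphplc_calls = as.character(rphplc_calls)),
            class = "evidence_flags")
}

# Normalise RP-HPLC labels to display form ("1By8*" and "8*" both work).
.rphplc_displays <- function(lib, labels) {
  al <- lib$alleles
  out <- vapply(labels, function(l) {
    if (l %in% al$display) l
    else if (l %in% al$name) al$display[match(l, al$name)]
    else stop(sprintf("unknown RP-HPLC subunit label '%s'", l),
              call. = FALSE)
  }, character(1))
  unique(unname(out))
}

#' Candidate alleles for one corrected mass
#'
#' All allele variants whose matching window (corrected-mass reference
#' range padded by `tol`) contains `corrected_mass`, ordered by distance to
#' the reference mean.
#'
#' @param lib A `glu1_library`.
#' @param corrected_mass 4-vp-corrected mass in Da.
#' @param tol Matching tolerance in Da (default 300, the separation below
#'   which subunits are not distinguishable by mass alone).
#' @return `data.frame` with `variant`, `name`, `display`, `delta`
#'   (corrected mass minus reference mean), possibly empty.
#' @export
candidate_alleles <- function(lib, corrected_mass, tol = 300) {
  stopifnot(inherits(lib, "glu1_library"))
  if (length(tol) != 1L || tol <= 0)
    stop("`tol` must be a single positive number", call. = FALSE)
  al <- lib$alleles
  hit <- !is.na(al$corr_min) &
    corrected_mass >= al$corr_min - tol &
    corrected_mass <= al$corr_max + tol
  out <- data.frame(variant = al$variant[hit], name = al$name[hit],
                    display = al$display[hit],
                    delta = corrected_mass - al$corr_mean[hit],
                    stringsAsFactors = FALSE)
  out[order(abs(out$delta)), , drop = FALSE]
}

#' Classify a 1Bx7-class corrected mass into its variant group
#'
#' Corrected masses below the group boundary (82,700 Da) are the group 1
#' protein; the heavier class is group 2 or the overexpression allele,
#' separable only by the gene-duplication PCR result.
#'
#' @inheritParams candidate_alleles
#' @param evidence An [evidence_flags()] object.
#' @param boundary Corrected-mass boundary between the two classes, Da.
#' @return One of `"group1"`, `"group2"`, `"OE"`, `"group2_or_OE"`.
#' @examples
#' lib <- load_glu1_library()
#' classify_bx7(lib, 82410)  # "group1"
#' @export
classify_bx7 <- function(lib, corrected_mass, evidence = evidence_flags(),
                         tol = 300, boundary = BX7_GROUP_BOUNDARY) {
  stopifnot(inherits(lib, "glu1_library"))
  al <- lib$alleles
  v7 <- al[al$name %in% c("1Bx7", "1Bx7OE"), ]
  lo <- min(v7$corr_min) - tol
  hi <- max(v7$corr_max) + tol
  if (length(corrected_mass) != 1L || is.na(corrected_mass) ||
      corrected_mass < lo || corrected_mass > hi)
    stop(sprintf("corrected mass %s is outside the 1Bx7 window [%d, %d]",
                 format(corrected_mass), round(lo), round(hi)),
         call. = FALSE)
  if (corrected_mass < boundary) return("group1")
  dup <- evidence$bx7_duplication_pcr
  if (isTRUE(dup)) "OE" else if (isFALSE(dup)) "group2" else "group2_or_OE"
}

# ---- combination enumeration ------------------------------------------------

# Variants backing one display label at (locus, type), after evidence
# gating of the 1Bx7 group 2 / OE records.
.display_variants <- function(lib, locus, type, display, dup) {
  al <- lib$alleles
  v <- al$variant[al$locus == locus & al$type == type &
                    al$display == display]
  if (isTRUE(dup)) v <- setdiff(v, "1Bx7g2")
  if (isFALSE(dup)) v <- setdiff(v, "1Bx7OE")
  v
}

# All haplotype-resolved combinations for one locus: each option carries
# the haplotype label and the variant chosen for each member slot.
.locus_options <- function(lib, locus, dup) {
  haps <- lib$haplotypes[lib$haplotypes$locus == locus, ]
  opts <- list()
  for (i in seq_len(nrow(haps))) {
    h <- haps[i, ]
    xs <- if (is.na(h$x)) list(NULL) else
      as.list(.display_variants(lib, locus, "x", h$x, dup))
    ys <- if (is.na(h$y)) list(NULL) else
      as.list(.display_variants(lib, locus, "y", h$y, dup))
    if (!length(xs) || !length(ys)) next  # haplotype excluded by evidence
    for (xv in xs) for (yv in ys)
      opts[[length(opts) + 1L]] <- list(label = h$label, x = xv, y = yv)
  }
  opts
}

.SLOT_ORDER <- c("a1x", "b1x", "b1y", "d1x", "d1y")

.combo_slots <- function(a1, b1, d1) {
  slots <- c(a1x = if (!is.null(a1$x)) a1$x,
             b1x = if (!is.null(b1$x)) b1$x,
             b1y = if (!is.null(b1$y)) b1$y,
             d1x = if (!is.null(d1$x)) d1$x,
             d1y = if (!is.null(d1$y)) d1$y)
  slots[intersect(.SLOT_ORDER, names(slots))]
}

# Composition string from chosen variants, e.g. "N, 7+8, 2+12".
.combo_composition <- function(lib, a1, b1, d1) {
  disp <- function(v) lib$alleles$display[match(v, lib$alleles$variant)]
  part <- function(opt, silent = "N") {
    if (is.null(opt$x) && is.null(opt$y)) return(silent)
    paste(c(disp(opt$x), disp(opt$y)), collapse = "+")
  }
  paste(part(a1), part(b1), part(d1), sep = ", ")
}

# Greedy nearest-mean matching of one combination against the peaks.
.score_combo <- function(slots, corr_by_cys, in_range, al_idx, al,
                         tol, penalty_missing, penalty_unassigned) {
  n_peaks <- length(in_range)
  used <- rep(FALSE, n_peaks)
  assigned <- stats::setNames(rep(NA_integer_, length(slots)), names(slots))
  deltas <- stats::setNames(rep(NA_real_, length(slots)), names(slots))
  score <- 0
  n_missing <- 0L
  for (si in seq_along(slots)) {
    v <- slots[[si]]
    j <- al_idx[[v]]
    corr <- corr_by_cys[[as.character(al$cys[j])]]
    ok <- !used & in_range &
      corr >= al$corr_min[j] - tol & corr <= al$corr_max[j] + tol
    if (!any(ok)) {
      n_missing <- n_missing + 1L
      score <- score + penalty_missing
      next
    }
    d <- abs(corr - al$corr_mean[j])
    d[!ok] <- Inf
    pick <- which.min(d)  # ties resolve to the lower mass
    assigned[si] <- pick
    deltas[si] <- corr[pick] - al$corr_mean[j]
    used[pick] <- TRUE
    score <- score + d[pick]
  }
  n_unassigned <- sum(in_range & !used)
  list(assigned = assigned, deltas = deltas, n_missing = n_missing,
       n_unassigned = n_unassigned,
       score = score + penalty_unassigned * n_unassigned)
}

.flag_pair <- function(d1, d2) {
  if (setequal(c(d1, d2), c("7", "7OE"))) "7 group2 vs 7OE"
  else paste(sort(c(d1, d2)), collapse = "/")
}

#' Call the HMW-GS genotype of one sample
#'
#' Every combination of one haplotype per locus is scored by greedily
#' matching each haplotype member to the nearest unassigned peak whose
#' corrected mass falls in the member's reference window; the score is the
#' summed distance to the reference means plus penalties for unmatched
#' members and unassigned peaks, and the minimum-score combination is
#' returned. Combinations that explain the same peaks with alleles less
#' than `ambiguity_margin` apart in reference mass are reported as
#' ambiguous alternatives unless the supplied evidence resolves them.
#'
#' @inheritParams candidate_alleles
#' @param peaks A calibrated [peaklist()] with 1-8 peaks in the
#'   acquisition range.
#' @param evidence An [evidence_flags()] object.
#' @param alkylated Whether the sample was alkylated with 4-vinylpyridine
#'   (default `TRUE`); correction is applied per candidate allele's
#'   cysteine count during matching.
#' @param penalty_missing Score penalty per required-but-unmatched
#'   haplotype member.
#' @param penalty_unassigned Score penalty per peak left unassigned.
#' @param ambiguity_margin Reference-mean separation (Da) below which two
#'   alleles explaining the same peak are reported as an ambiguous pair.
#' @return A `genotype_call`: composition string, per-locus haplotypes,
#'   per-subunit call table, 1Bx7 group, advisory flags, ambiguous
#'   alternative compositions, unassigned peaks and the search score.
#' @examples
#' lib <- load_glu1_library()
#' pk <- peaklist(c(83488, 75886, 87493, 69410),
#'                sample_id = "Chinese Spring", calibrated = TRUE)
#' call_genotype(lib, pk)$composition  # "N, 7+8, 2+12"
#' @export
call_genotype <- function(lib, peaks, tol = 300,
                          evidence = evidence_flags(), alkylated = TRUE,
                          penalty_missing = 10000,
                          penalty_unassigned = 1000,
                          ambiguity_margin = 300) {
  stopifnot(inherits(lib, "glu1_library"), inherits(peaks, "peaklist"))
  if (!inherits(evidence, "evidence_flags"))
    stop("`evidence` must be an evidence_flags() object", call. = FALSE)
  if (!attr(peaks, "calibrated"))
    stop("peak list must be calibrated before genotype calling",
         call. = FALSE)
  al <- lib$alleles
  al_idx <- stats::setNames(seq_len(nrow(al)), al$variant)
  dup <- evidence$bx7_duplication_pcr
  rphplc <- .rphplc_displays(lib, evidence$rphplc_calls)

  in_range <- peaks$mass >= GLU1_MASS_RANGE[1L] &
    peaks$mass <= GLU1_MASS_RANGE[2L]
  sample_id <- attr(peaks, "sample_id")
  base_result <- function(reason) {
    structure(list(sample_id = sample_id,
                   replicate_id = attr(peaks, "replicate_id"),
                   uncallable = TRUE, composition = NA_character_,
                   haplotypes = NULL, calls = NULL, bx7_group = NA_character_,
                   flags = reason, ambiguous_alternatives = character(),
                   unassigned = data.frame(mass = peaks$mass,
                                           intensity = peaks$intensity),
                   score = NA_real_, evidence_used = character()),
              class = "genotype_call")
  }
  if (sum(in_range) == 0L)
    return(base_result("no peaks inside the acquisition range"))
  if (sum(in_range) > 8L)
    warning(sprintf("%s: %d peaks in range; expected 1-8",
                    sample_id, sum(in_range)))

  # corrected mass per peak for each cysteine-count hypothesis
  corr_by_cys <- lapply(stats::setNames(nm = sort(unique(al$cys))),
                        function(cys) {
    cys <- as.numeric(cys)
    if (alkylated) floor(peaks$mass - vp_shift(cys)) else floor(peaks$mass)
  })

  a1_opts <- .locus_options(lib, "Glu-A1", dup)
  b1_opts <- .locus_options(lib, "Glu-B1", dup)
  d1_opts <- .locus_options(lib, "Glu-D1", dup)

  combos <- list()
  for (a1 in a1_opts) for (b1 in b1_opts) for (d1 in d1_opts) {
    slots <- .combo_slots(a1, b1, d1)
    sc <- .score_combo(slots, corr_by_cys, in_range, al_idx, al, tol,
                       penalty_missing, penalty_unassigned)
    combos[[length(combos) + 1L]] <- c(
      list(a1 = a1, b1 = b1, d1 = d1, slots = slots,
           composition = .combo_composition(lib, a1, b1, d1)), sc)
  }
  scores <- vapply(combos, `[[`, numeric(1), "score")
  unas <- vapply(combos, `[[`, numeric(1), "n_unassigned")
  comps <- vapply(combos, `[[`, character(1), "composition")
  ord <- order(scores, unas, comps, method = "radix")
  combos <- combos[ord]
  best <- combos[[1L]]
  if (all(is.na(best$assigned)))
    return(base_result("no haplotype combination matched any peak"))

  # indistinguishable alternatives: same slots, same peaks, allele swaps
  # closer than the ambiguity margin in reference mean
  sig <- function(cb) paste(names(cb$slots), cb$assigned, cb$n_missing,
                            collapse = ";")
  alts <- Filter(function(cb) {
    if (identical(cb$slots, best$slots)) return(FALSE)
    if (!identical(sig(cb), sig(best))) return(FALSE)
    diff_slots <- names(best$slots)[best$slots != cb$slots]
    all(vapply(diff_slots, function(s) {
      m1 <- al$corr_mean[al_idx[[best$slots[[s]]]]]
      m2 <- al$corr_mean[al_idx[[cb$slots[[s]]]]]
      abs(m1 - m2) < ambiguity_margin
    }, logical(1)))
  }, combos[-1L])

  # within an indistinguishable set the sub-window mass deltas carry no
  # information, so the call defaults to the canonical composition
  # (fewest label characters, then byte order: "8" before "8*", "7"
  # before "7OE") and the set is reported as ambiguous
  finalists <- c(list(best), alts)
  # score of the equivalence class: its minimum (the members differ only
  # by sub-resolution allele swaps)
  class_score <- min(vapply(finalists, `[[`, numeric(1), "score"))
  comps_f <- vapply(finalists, `[[`, character(1), "composition")
  finalists <- finalists[order(nchar(comps_f), comps_f, method = "radix")]
  best <- finalists[[1L]]
  alts <- finalists[-1L]

  # RP-HPLC evidence selects among the best combination and its
  # indistinguishable alternatives
  evidence_used <- character()
  if (length(rphplc) && length(finalists) > 1L) {
    consistency <- vapply(finalists, function(cb)
      sum(al$display[al_idx[unlist(cb$slots)]] %in% rphplc), numeric(1))
    keep <- which(consistency == max(consistency))
    if (!1L %in% keep || length(keep) < length(finalists))
      evidence_used <- c(evidence_used,
                         paste0("rphplc:", paste(rphplc, collapse = ",")))
    finalists <- finalists[keep]
    best <- finalists[[1L]]
    alts <- finalists[-1L]
  }

  # residual ambiguity flags (pairs not covered by RP-HPLC evidence)
  slot_ambiguity <- stats::setNames(rep("none", length(best$slots)),
                                    names(best$slots))
  flags <- character()
  kept_alts <- list()
  for (cb in alts) {
    diff_slots <- names(best$slots)[best$slots != cb$slots]
    pair_disp <- lapply(diff_slots, function(s)
      c(al$display[al_idx[[best$slots[[s]]]]],
        al$display[al_idx[[cb$slots[[s]]]]]))
    covered <- vapply(pair_disp, function(p) any(p %in% rphplc), logical(1))
    if (all(covered)) next
    kept_alts[[length(kept_alts) + 1L]] <- cb$composition
    for (k in seq_along(diff_slots)) {
      if (covered[k]) next
      s <- diff_slots[k]
      fl <- .flag_pair(pair_disp[[k]][1L], pair_disp[[k]][2L])
      slot_ambiguity[s] <- fl
      flags <- c(flags, if (identical(fl, "7 group2 vs 7OE"))
        "PCR recommended to resolve 1Bx7 group 2 vs 1Bx7OE"
        else sprintf("RP-HPLC recommended for %s",
                     sub("/", " vs ", fl, fixed = TRUE)))
    }
  }

  # near-identical-mass cross-locus pair 1Ax2*/1Bx6: advisory when the
  # matched peak also sits in the other allele's window
  for (s in names(best$slots)) {
    d <- al$display[al_idx[[best$slots[[s]]]]]
    if (!d %in% c("2*", "6") || is.na(best$assigned[[s]])) next
    other <- if (d == "2*") "1Bx6" else "1Ax2*"
    oj <- al_idx[[other]]
    corr <- corr_by_cys[[as.character(al$cys[oj])]][best$assigned[[s]]]
    if (corr >= al$corr_min[oj] - tol && corr <= al$corr_max[oj] + tol) {
      if (any(c(d, al$display[oj]) %in% rphplc)) next
      slot_ambiguity[s] <- "2*/6"
      flags <- c(flags, "RP-HPLC recommended for 2* vs 6")
    }
  }

  if (!is.na(dup))
    evidence_used <- c(evidence_used,
                       sprintf("bx7_duplication_pcr=%s", dup))

  # per-subunit call table
  slots <- best$slots
  calls <- do.call(rbind, lapply(names(slots), function(s) {
    j <- al_idx[[slots[[s]]]]
    pk <- best$assigned[[s]]
    matched <- !is.na(pk)
    data.frame(
      slot = s, locus = al$locus[j], type = al$type[j],
      variant = al$variant[j], name = al$name[j], display = al$display[j],
      peak_mass = if (matched) peaks$mass[pk] else NA_real_,
      corrected_mass = if (matched)
        corr_by_cys[[as.character(al$cys[j])]][pk] else NA_real_,
      delta = unname(best$deltas[[s]]),
      ambiguity = unname(slot_ambiguity[[s]]),
      stringsAsFactors = FALSE)
  }))
  if (any(is.na(calls$peak_mass)))
    flags <- c(flags, sprintf("unmatched haplotype member(s): %s",
                              paste(calls$name[is.na(calls$peak_mass)],
                                    collapse = ", ")))

  # 1Bx7 group annotation
  bx7_group <- NA_character_
  b1x <- calls[calls$slot == "b1x", ]
  if (nrow(b1x) == 1L && b1x$name %in% c("1Bx7", "1Bx7OE") &&
      !is.na(b1x$corrected_mass)) {
    bx7_group <- classify_bx7(lib, b1x$corrected_mass, evidence, tol = tol)
    if (identical(bx7_group, "group2_or_OE") &&
        !any(grepl("PCR recommended", flags)))
      flags <- c(flags, "PCR recommended to resolve 1Bx7 group 2 vs 1Bx7OE")
  }

  used_idx <- best$assigned[!is.na(best$assigned)]
  un_idx <- setdiff(which(in_range), used_idx)
  unassigned <- data.frame(mass = peaks$mass[un_idx],
                           intensity = peaks$intensity[un_idx])
  if (nrow(unassigned))
    flags <- c(flags, sprintf("%d peak(s) matched no allele window",
                              nrow(unassigned)))
  out_of_range <- which(!in_range)
  if (length(out_of_range))
    flags <- c(flags, sprintf("%d peak(s) outside the acquisition range",
                              length(out_of_range)))

  structure(list(
    sample_id = sample_id, replicate_id = attr(peaks, "replicate_id"),
    uncallable = FALSE, composition = best$composition,
    haplotypes = c(`Glu-A1` = best$a1$label, `Glu-B1` = best$b1$label,
                   `Glu-D1` = best$d1$label),
    calls = calls, bx7_group = bx7_group, flags = unique(flags),
    ambiguous_alternatives = unique(unlist(kept_alts)),
    unassigned = unassigned, score = class_score,
    evidence_used = evidence_used), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$uncallable) {
    cat(sprintf("Sample '%s': uncallable (%s)\n", x$sample_id,
                paste(x$flags, collapse = "; ")))
    return(invisible(x))
  }
  cat(sprintf("Sample '%s': %s", x$sample_id, x$composition))
  if (!is.na(x$bx7_group)) cat(sprintf("  [1Bx7 %s]", x$bx7_group))
  cat("\n")
  if (length(x$flags))
    cat(paste0("  - ", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Call genotypes for a cohort of samples
#'
#' @inheritParams call_genotype
#' @param samples List of calibrated [peaklist()]s.
#' @param evidence A single [evidence_flags()] applied to every sample, or
#'   a list of one per sample.
#' @param ... Further arguments passed to [call_genotype()].
#' @return A `glu1_cohort`: list of `genotype_call`s plus the
#'   [cohort_summary_stats()] summary.
#' @export
call_cohort <- function(lib, samples, evidence = evidence_flags(), ...) {
  stopifnot(inherits(lib, "glu1_library"), length(samples) >= 1L)
  if (inherits(evidence, "evidence_flags"))
    evidence <- rep(list(evidence), length(samples))
  if (length(evidence) != length(samples))
    stop("`evidence` must be one evidence_flags() or one per sample",
         call. = FALSE)
  calls <- lapply(seq_along(samples), function(i)
    call_genotype(lib, samples[[i]], evidence = evidence[[i]], ...))
  names(calls) <- vapply(calls, `[[`, character(1), "sample_id")
  structure(list(calls = calls,
                 summary = cohort_summary_stats(lib, calls)),
            class = "glu1_cohort")
}

#' @export
print.glu1_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("HMW-GS cohort: %d samples (%d uncallable)\n",
              s$n_samples, s$n_uncallable))
  cat(sprintf("  1Bx7 carriers: %d (%.1f%%); group 1: %d, group 2: %d\n",
              s$bx7_carriers, s$bx7_carrier_pct, s$bx7_group1,
              s$bx7_group2))
  if (length(s$absent_alleles))
    cat("  absent alleles:", paste(s$absent_alleles, collapse = ", "), "\n")
  invisible(x)
}
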