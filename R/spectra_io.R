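# Peak-list and profile-spectrum containers, text I/O, peak detection and
# external one-point mass calibration.

#' Construct a peak list
#'
#' A peak list holds calibrated or uncalibrated `(mass, intensity, snr)`
#' triples for one acquisition, sorted by mass; duplicate masses are
#' collapsed keeping the highest intensity.
#'
#' @param mass Peak masses in Da.
#' @param intensity Peak intensities (default 1).
#' @param snr Signal-to-noise ratios (optional).
#' @param sample_id,replicate_id Identifiers carried through calling and
#'   reporting.
#' @param calibrated Whether masses are already on the calibrated scale.
#' @return A `peaklist` (a `data.frame` with metadata attributes).
#' @examples
#' peaklist(c(83488, 69410), sample_id = "demo", calibrated = TRUE)
#' @export
peaklist <- function(mass, intensity = rep(1, length(mass)),
                     snr = rep(NA_real_, length(mass)),
                     sample_id = "sample", replicate_id = "1",
                     calibrated = FALSE) {
  if (anyNA(mass) || any(mass <= 0))
    stop("peak masses must be positive and non-missing", call. = FALSE)
  if (length(intensity) != length(mass) || length(snr) != length(mass))
    stop("`intensity` and `snr` must match `mass` in length", call. = FALSE)
  df <- data.frame(mass = as.numeric(mass),
                   intensity = as.numeric(intensity),
                   snr = as.numeric(snr))
  df <- df[order(df$mass, -df$intensity), , drop = FALSE]
  df <- df[!duplicated(df$mass), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, replicate_id = replicate_id,
            calibrated = isTRUE(calibrated),
            class = c("peaklist", "data.frame"))
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list '%s' (replicate %s, %s): %d peaks\n",
              attr(x, "sample_id"), attr(x, "replicate_id"),
              if (attr(x, "calibrated")) "calibrated" else "uncalibrated",
              nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

.split_table_line <- function(line) {
  strsplit(trimws(line), "[\t,;[:space:]]+")[[1L]]
}

#' Read a peak list from delimited text
#'
#' Accepts two-column (`mass`, `intensity`) or three-column
#' (`mass`, `intensity`, `snr`) TSV/CSV, with or without a header row.
#'
#' @param path File to read.
#' @param dialect `"auto"` (default), `"tsv"` or `"csv"`; auto-detection
#'   splits on tabs, commas or whitespace.
#' @param sample_id,replicate_id Identifiers; default `sample_id` is the
#'   file name without extension.
#' @return A [peaklist()] with `calibrated = FALSE`.
#' @export
read_peaklist <- function(path, dialect = c("auto", "tsv", "csv"),
                          sample_id = NULL, replicate_id = "1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    stop(sprintf("empty peak-list file: %s", path), call. = FALSE)
  sep <- switch(dialect, tsv = "\t", csv = ",", auto = "[\t,;[:space:]]+")
  fields <- lapply(lines, function(l) strsplit(trimws(l), sep)[[1L]])
  # tolerate one header row of non-numeric labels
  first_num <- suppressWarnings(as.numeric(fields[[1L]]))
  if (anyNA(first_num)) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (!length(fields))
      stop(sprintf("no data rows in peak-list file: %s", path),
           call. = FALSE)
  }
  ncol <- lengths(fields)
  if (any(ncol < 2L | ncol > 3L))
    stop(sprintf("parse error in %s at line %d: expected 2 or 3 columns",
                 path, lineno[which(ncol < 2L | ncol > 3L)[1L]]),
         call. = FALSE)
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  # literal NA is tolerated in the optional snr column only
  bad <- which(vapply(seq_along(vals), function(i) {
    v <- vals[[i]]
    any(is.na(v) & fields[[i]] != "NA") || anyNA(v[1:2])
  }, logical(1)))
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, lineno[bad[1L]]), call. = FALSE)
  mass <- vapply(vals, `[`, numeric(1), 1L)
  intensity <- vapply(vals, `[`, numeric(1), 2L)
  snr <- vapply(vals, function(v) if (length(v) >= 3L) v[3L] else NA_real_,
                numeric(1))
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]+$", "", basename(path))
  peaklist(mass, intensity, snr, sample_id = sample_id,
           replicate_id = replicate_id, calibrated = FALSE)
}

#' Write a peak list as canonical TSV
#'
#' @param x A [peaklist()].
#' @param path Output file; columns `mass_da`, `intensity`, `snr`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  out <- data.frame(mass_da = x$mass, intensity = x$intensity, snr = x$snr)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a profile spectrum
#'
#' Dense `(m/z, intensity)` sampling of one acquisition over the
#' instrument's mass range (default 60,000-110,000 Da).
#'
#' @param mass Strictly increasing m/z grid in Da.
#' @param intensity Non-negative intensities.
#' @param acquisition_range Length-2 acquisition window in Da.
#' @return A `profile_spectrum` (a `data.frame` with an
#'   `acquisition_range` attribute).
#' @export
profile_spectrum <- function(mass, intensity,
                             acquisition_range = GLU1_MASS_RANGE) {
  if (length(mass) != length(intensity))
    stop("`mass` and `intensity` lengths differ", call. = FALSE)
  if (any(diff(mass) <= 0))
    stop("profile m/z values must be strictly increasing", call. = FALSE)
  if (any(intensity < 0) || any(mass < 0))
    stop("profile values must be non-negative", call. = FALSE)
  structure(data.frame(mass = mass, intensity = intensity),
            acquisition_range = acquisition_range,
            class = c("profile_spectrum", "data.frame"))
}

#' Detect peaks in a profile spectrum
#'
#' The trace is smoothed with a moving average, the noise level estimated
#' as the median absolute deviation (scaled to SD) of the
#' baseline-subtracted trace, and local maxima with signal-to-noise at
#' least `min_snr` retained. Peak mass is the intensity-weighted centroid
#' over the half-height region; peaks closer than `min_spacing_da` are
#' merged keeping the higher one.
#'
#' @param spectrum A [profile_spectrum()] with at least 50 points.
#' @param min_snr Minimum signal-to-noise ratio.
#' @param min_spacing_da Minimum distance between reported peaks, Da.
#' @param smooth_window_da Moving-average window width, Da.
#' @param sample_id,replicate_id Identifiers for the returned peak list.
#' @return A [peaklist()] (uncalibrated).
#' @export
detect_peaks <- function(spectrum, min_snr = 3, min_spacing_da = 300,
                         smooth_window_da = 25, sample_id = "sample",
                         replicate_id = "1") {
  stopifnot(inherits(spectrum, "profile_spectrum"))
  if (nrow(spectrum) < 50L)
    stop("profile spectrum must have at least 50 points", call. = FALSE)
  if (min_snr <= 0 || min_spacing_da <= 0 || smooth_window_da <= 0)
    stop("detection parameters must be positive", call. = FALSE)
  x <- spectrum$mass
  y <- spectrum$intensity
  step <- stats::median(diff(x))
  k <- max(1L, round(smooth_window_da / step))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  baseline <- stats::median(sm)
  noise <- stats::mad(sm - baseline)
  if (!is.finite(noise) || noise <= 0)
    noise <- max(.Machine$double.eps, 1e-12 * max(abs(sm)))
  n <- length(sm)
  mid <- 2L:(n - 1L)
  apex <- mid[sm[mid] > sm[mid - 1L] & sm[mid] >= sm[mid + 1L]]
  snr <- (sm[apex] - baseline) / noise
  apex <- apex[snr >= min_snr]
  snr <- snr[snr >= min_snr]
  if (!length(apex)) {
    return(peaklist(numeric(0), numeric(0), numeric(0),
                    sample_id = sample_id, replicate_id = replicate_id))
  }
  centroid <- vapply(apex, function(i) {
    half <- baseline + (sm[i] - baseline) / 2
    lo <- i
    while (lo > 1L && sm[lo - 1L] >= half && sm[lo - 1L] <= sm[lo]) {
      lo <- lo - 1L
    }
    hi <- i
    while (hi < n && sm[hi + 1L] >= half && sm[hi + 1L] <= sm[hi]) {
      hi <- hi + 1L
    }
    w <- sm[lo:hi] - baseline
    sum(x[lo:hi] * w) / sum(w)
  }, numeric(1))
  height <- sm[apex]
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(centroid[i] - centroid[kept]) >= min_spacing_da))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  peaklist(centroid[kept], height[kept], snr[kept],
           sample_id = sample_id, replicate_id = replicate_id)
}

#' Apply external one-point mass calibration
#'
#' Rescales every peak mass by `true_standard / observed_standard`, the
#' single-point multiplicative calibration implied by one external protein
#' standard (bovine serum albumin, 66,463 Da, by default). A two-point
#' linear model is fitted when two observed/true pairs are supplied.
#'
#' @param peaks A [peaklist()].
#' @param observed_standard Observed mass(es) of the standard(s), Da.
#' @param true_standard True mass(es); default BSA 66,463 Da.
#' @param standard_name Label recorded in the calibration model.
#' @return A list with `peaks` (calibrated [peaklist()]) and `model`
#'   (kind, parameters, reference).
#' @examples
#' pl <- peaklist(83000)
#' calibrate_peaklist(pl, observed_standard = 66529.463)$peaks$mass
#' @export
calibrate_peaklist <- function(peaks, observed_standard,
                               true_standard = 66463,
                               standard_name = "BSA") {
  stopifnot(inherits(peaks, "peaklist"))
  if (length(observed_standard) != length(true_standard))
    stop("observed and true standard masses must pair up", call. = FALSE)
  if (length(observed_standard) == 1L) {
    scale <- true_standard / observed_standard
    if (scale < 0.95 || scale > 1.05)
      stop(sprintf(
        "calibration error: scale %.4f outside [0.95, 1.05]", scale),
        call. = FALSE)
    new_mass <- peaks$mass * scale
    model <- list(kind = "one-point multiplicative",
                  parameters = c(scale = scale),
                  reference = data.frame(standard = standard_name,
                                         true_mass = true_standard,
                                         observed_mass = observed_standard))
  } else if (length(observed_standard) == 2L) {
    fit <- stats::lm(true_standard ~ observed_standard,
                     data.frame(true_standard, observed_standard))
    slope <- unname(stats::coef(fit)[2L])
    offset <- unname(stats::coef(fit)[1L])
    if (slope < 0.95 || slope > 1.05)
      stop(sprintf("calibration error: slope %.4f outside [0.95, 1.05]",
                   slope), call. = FALSE)
    new_mass <- offset + slope * peaks$mass
    model <- list(kind = "two-point linear",
                  parameters = c(scale = slope, offset = offset),
                  reference = data.frame(standard = standard_name,
                                         true_mass = true_standard,
                                         observed_mass = observed_standard))
  } else {
    stop("supply one or two standard masses", call. = FALSE)
  }
  out <- peaklist(new_mass, peaks$intensity, peaks$snr,
                  sample_id = attr(peaks, "sample_id"),
                  replicate_id = attr(peaks, "replicate_id"),
                  calibrated = TRUE)
  list(peaks = out, model = model)
}
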