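# Scalar mass arithmetic: average protein mass, 4-vinylpyridine adduct
# handling, predicted-vs-measured comparison, replicate reproducibility.

# Average (not monoisotopic) residue masses, Da. HMW-GS are 67-101 kDa
# intact proteins, so average masses are the right scale throughout.
.AA_AVERAGE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

# 4-vinylpyridine adds this mass per alkylated cysteine residue.
VP_MASS <- 105.14

#' Average molecular mass of a protein sequence
#'
#' Sums standard average residue masses and adds one water mass
#' (`18.0153` Da), the convention used by sequence-based mass calculators
#' for intact proteins.
#'
#' @param sequence Single amino-acid string using the 20 standard one-letter
#'   codes (case-insensitive).
#' @return Average molecular mass in Da.
#' @examples
#' average_mass("G")  # glycine: 57.0519 + 18.0153
#' @export
average_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string", call. = FALSE)
  if (!nzchar(sequence))
    stop("`sequence` must not be empty", call. = FALSE)
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% names(.AA_AVERAGE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d",
                 res[bad[1L]], bad[1L]), call. = FALSE)
  sum(.AA_AVERAGE_MASS[res]) + .WATER_MASS
}

#' Mass shift from 4-vinylpyridine alkylation
#'
#' Each alkylated cysteine adds one 4-vinylpyridine adduct of
#' `105.14` Da to the intact protein.
#'
#' @param n_cys Number of cysteine residues (non-negative integer,
#'   vectorised).
#' @param per_site_mass Adduct mass per cysteine in Da.
#' @return Total adduct mass in Da.
#' @examples
#' vp_shift(4)  # x-type subunits: 420.56
#' vp_shift(7)  # y-type subunits: 735.98
#' @export
vp_shift <- function(n_cys, per_site_mass = VP_MASS) {
  if (length(n_cys) == 0L || anyNA(n_cys) || any(n_cys < 0) ||
      any(n_cys != trunc(n_cys)))
    stop("`n_cys` must be a non-negative integer", call. = FALSE)
  per_site_mass * n_cys
}

#' Remove the 4-vinylpyridine adduct mass from a measured mass
#'
#' Subtracts `105.14` Da per cysteine from an alkylated measured mass and
#' truncates to integer Da. Truncation (floor), not rounding, is the
#' convention the embedded reference tables follow.
#'
#' @param measured Measured (alkylated) mass in Da, vectorised.
#' @param n_cys Cysteine count of the subunit hypothesis.
#' @inheritParams vp_shift
#' @return Corrected mass as integer Da.
#' @examples
#' strip_vp(83488, 4)  # 83067
#' strip_vp(84014, 2)  # 83803
#' @export
strip_vp <- function(measured, n_cys, per_site_mass = VP_MASS) {
  shift <- vp_shift(n_cys, per_site_mass)
  out <- measured - shift
  if (anyNA(measured) || any(out <= 0))
    stop("measured mass must exceed the total adduct mass", call. = FALSE)
  as.integer(floor(out))
}

#' Difference and relative error between corrected and predicted mass
#'
#' @param measured_corrected Adduct-corrected measured mass, Da.
#' @param predicted Sequence-predicted mature-protein mass, Da.
#' @return `data.frame` with integer `difference` (measured minus predicted)
#'   and `error_pct` (percent of predicted, rounded half-away-from-zero to
#'   2 decimals). Vectorised over both arguments.
#' @examples
#' diff_and_error(83067, 82527)  # 540 Da, 0.65 %
#' @export
diff_and_error <- function(measured_corrected, predicted) {
  if (any(measured_corrected <= 0, na.rm = TRUE) ||
      any(predicted <= 0, na.rm = TRUE))
    stop("masses must be positive", call. = FALSE)
  d <- measured_corrected - predicted
  e <- 100 * d / predicted
  e <- sign(e) * floor(abs(e) * 100 + 0.5) / 100
  data.frame(difference = as.integer(round(d)), error_pct = e)
}

#' Relative standard deviation of replicate mass measurements
#'
#' Sample standard deviation (n - 1 denominator) over the mean, as percent,
#' the reproducibility metric reported for replicate acquisitions.
#'
#' @param values Numeric vector of at least two positive masses.
#' @param digits Decimals to round to (default 3).
#' @return RSD in percent.
#' @examples
#' rsd_percent(c(100000, 100100))  # 0.071
#' @export
rsd_percent <- function(values, digits = 3) {
  if (length(values) < 2L)
    stop("need at least 2 values to compute an RSD", call. = FALSE)
  if (anyNA(values) || any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  round(100 * stats::sd(values) / mean(values), digits)
}
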