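# Synthetic peak lists and profile spectra with the statistical structure
# the caller assumes: one peak per expressed subunit, multiplicative
# Gaussian mass error (constant relative SD, matching how replicate
# reproducibility is reported), log-normal intensities, Gaussian peak
# shapes over a constant baseline.

# run expr with a temporary RNG state seeded by `seed` (NULL = use the
# current stream)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Parse one composition into variant ids. The Glu-B1 "7" label must be
# group-qualified ("7g1"/"7g2") because the two groups are distinct
# proteins with different masses.
.parse_composition <- function(lib, composition) {
  if (length(composition) == 1L)
    composition <- strsplit(composition, ",")[[1L]]
  composition <- trimws(composition)
  if (length(composition) != 3L)
    stop("composition must have one haplotype per locus (Glu-A1, Glu-B1, Glu-D1)",
         call. = FALSE)
  al <- lib$alleles
  out <- list()
  for (i in 1:3) {
    locus <- GLU1_LOCI[i]
    label <- composition[i]
    plain <- gsub("7g[12]", "7", label)
    h <- lib$haplotypes[lib$haplotypes$locus == locus &
                          lib$haplotypes$label == plain, ]
    if (nrow(h) != 1L)
      stop(sprintf("unknown %s haplotype label '%s'", locus, label),
           call. = FALSE)
    members <- c(x = h$x, y = h$y)
    variants <- character()
    for (type in c("x", "y")) {
      d <- members[[type]]
      if (is.na(d)) next
      v <- al$variant[al$locus == locus & al$type == type &
                        al$display == d]
      if (length(v) > 1L) {  # 1Bx7: need the group qualifier
        qual <- regmatches(label, regexpr("7g[12]", label))
        if (!length(qual))
          stop(sprintf(
            "ambiguous 1Bx7 group in '%s': write '7g1' or '7g2'", label),
            call. = FALSE)
        v <- v[endsWith(v, sub("7", "", qual))]
      }
      variants <- c(variants, v)
    }
    out[[locus]] <- list(label = plain, variants = variants)
  }
  out
}

#' Specification for one simulated sample
#'
#' @param composition Character of length 3 (or one comma-separated
#'   string): the Glu-A1, Glu-B1 and Glu-D1 haplotype labels, with the
#'   1Bx7 group qualified as `"7g1"` or `"7g2"` (e.g.
#'   `c("2*", "7g1+8", "5+10")`).
#' @param alkylated Simulate 4-vinylpyridine-alkylated protein (adds
#'   105.14 Da per cysteine to every true mass). Default `TRUE`, the
#'   recommended extraction protocol.
#' @param relative_mass_sd Relative SD of the multiplicative mass error
#'   (default 5e-4, i.e. 0.05%, inside the observed replicate RSD range of
#'   0.011-0.096%). Must be in [0, 0.005].
#' @param peak_width_sigma Gaussian peak SD in Da for profile simulation.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param baseline_level,noise_sd Profile baseline and additive noise.
#' @param n_replicates Number of replicate acquisitions.
#' @param seed Optional integer seed for reproducibility.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(composition, alkylated = TRUE,
                            relative_mass_sd = 5e-4,
                            peak_width_sigma = 150,
                            intensity_meanlog = log(5000),
                            intensity_sdlog = 0.3,
                            baseline_level = 1, noise_sd = 0.05,
                            n_replicates = 1L, seed = NULL) {
  if (relative_mass_sd < 0 || relative_mass_sd > 0.005)
    stop("`relative_mass_sd` must lie in [0, 0.005]", call. = FALSE)
  if (peak_width_sigma <= 0 || n_replicates < 1L)
    stop("invalid simulation parameters", call. = FALSE)
  structure(list(composition = composition, alkylated = alkylated,
                 relative_mass_sd = relative_mass_sd,
                 peak_width_sigma = peak_width_sigma,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "simulation_spec")
}

# true (noise-free) masses for a parsed composition
.true_masses <- function(lib, parsed, alkylated) {
  al <- lib$alleles
  variants <- unlist(lapply(parsed, `[[`, "variants"), use.names = FALSE)
  j <- match(variants, al$variant)
  mass <- al$sim_mass[j] + if (alkylated) vp_shift(al$cys[j]) else 0
  stats::setNames(mass, variants)
}

#' Simulate a peak list for one genotype
#'
#' One peak per expressed subunit at
#' `true mass * (1 + Normal(0, relative_mass_sd))`, where the true mass is
#' the allele's simulation mass (gene-predicted mature-protein mass, or
#' the measured mean where no usable gene sequence exists) plus the
#' alkylation shift. Deterministic under a fixed `seed`.
#'
#' @param lib A `glu1_library`.
#' @param spec A [simulation_spec()].
#' @param sample_id,replicate_id Identifiers for the peak list.
#' @return List with `peaks` (a calibrated [peaklist()]) and `truth`
#'   (composition string, variants, true masses, seed).
#' @examples
#' lib <- load_glu1_library()
#' sp <- simulation_spec(c("2*", "7g1+8", "5+10"), relative_mass_sd = 0)
#' simulate_peaklist(lib, sp)$peaks$mass
#' @export
simulate_peaklist <- function(lib, spec, sample_id = "sim",
                              replicate_id = "1") {
  stopifnot(inherits(lib, "glu1_library"),
            inherits(spec, "simulation_spec"))
  parsed <- .parse_composition(lib, spec$composition)
  true_mass <- .true_masses(lib, parsed, spec$alkylated)
  .with_seed(spec$seed, {
    n <- length(true_mass)
    observed <- true_mass * (1 + stats::rnorm(n, 0, spec$relative_mass_sd))
    intensity <- stats::rlnorm(n, spec$intensity_meanlog,
                               spec$intensity_sdlog)
    peaks <- peaklist(observed, intensity, sample_id = sample_id,
                      replicate_id = replicate_id, calibrated = TRUE)
    truth <- list(
      composition = paste(vapply(parsed, `[[`, character(1), "label"),
                          collapse = ", "),
      variants = names(true_mass), true_masses = true_mass,
      alkylated = spec$alkylated, seed = spec$seed)
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate a profile spectrum for one genotype
#'
#' Sum of Gaussian peaks (area proportional to the drawn intensity,
#' SD = `peak_width_sigma`) over a constant baseline with additive
#' Gaussian noise, sampled on a uniform m/z grid across the acquisition
#' range.
#'
#' @inheritParams simulate_peaklist
#' @param grid_step m/z grid spacing in Da.
#' @return List with `spectrum` (a [profile_spectrum()]) and `truth`.
#' @export
simulate_profile <- function(lib, spec, grid_step = 5,
                             sample_id = "sim") {
  stopifnot(inherits(lib, "glu1_library"),
            inherits(spec, "simulation_spec"))
  sim <- simulate_peaklist(lib, spec, sample_id = sample_id)
  grid <- seq(GLU1_MASS_RANGE[1L], GLU1_MASS_RANGE[2L], by = grid_step)
  y <- rep(spec$baseline_level, length(grid))
  for (i in seq_len(nrow(sim$peaks))) {
    y <- y + sim$peaks$intensity[i] *
      stats::dnorm(grid, sim$peaks$mass[i], spec$peak_width_sigma) *
      grid_step
  }
  if (spec$noise_sd > 0) {
    y <- y + .with_seed(
      if (is.null(spec$seed)) NULL else spec$seed + 1L,
      stats::rnorm(length(grid), 0, spec$noise_sd))
    y <- pmax(y, 0)
  }
  list(spectrum = profile_spectrum(grid, y), truth = sim$truth)
}

#' Simulate a cohort of samples with replicates
#'
#' Draws genotypes from a composition table (by default the empirical
#' composition frequencies of the embedded cohort table, group-resolved),
#' assigns each sample a seed derived from the master seed, and simulates
#' `n_replicates` peak lists per sample.
#'
#' @param lib A `glu1_library`.
#' @param n_samples Number of samples to draw.
#' @param compositions Optional `data.frame` with a `composition` column
#'   (group-qualified labels, see [simulation_spec()]) and optional
#'   `weight` column.
#' @param seed Master seed (integer).
#' @param ... Further arguments to [simulation_spec()] (noise levels,
#'   `n_replicates`, ...).
#' @return List with `manifest` (`sample_id`, `composition`, `seed`),
#'   `samples` (per sample: list of replicate [peaklist()]s) and `truth`.
#' @export
simulate_cohort <- function(lib, n_samples, compositions = NULL,
                            seed = 1L, ...) {
  stopifnot(inherits(lib, "glu1_library"), n_samples >= 1L)
  if (is.null(compositions)) compositions <- cohort_compositions(lib)
  if (is.null(compositions$weight)) compositions$weight <- 1
  spec_args <- list(...)
  .with_seed(seed, {
    idx <- sample.int(nrow(compositions), n_samples, replace = TRUE,
                      prob = compositions$weight)
    sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
    manifest <- data.frame(
      sample_id = sprintf("sim%03d", seq_len(n_samples)),
      composition = compositions$composition[idx],
      seed = sample_seeds, stringsAsFactors = FALSE)
    samples <- vector("list", n_samples)
    truth <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      n_rep <- if (is.null(spec_args$n_replicates)) 1L else
        spec_args$n_replicates
      reps <- vector("list", n_rep)
      for (r in seq_len(n_rep)) {
        spec <- do.call(simulation_spec, c(
          list(composition = manifest$composition[i],
               seed = manifest$seed[i] %% (2^31 - 2) + r),
          spec_args[setdiff(names(spec_args),
                            c("seed", "n_replicates"))]))
        sim <- simulate_peaklist(lib, spec,
                                 sample_id = manifest$sample_id[i],
                                 replicate_id = as.character(r))
        reps[[r]] <- sim$peaks
        if (r == 1L) truth[[i]] <- sim$truth
      }
      samples[[i]] <- reps
    }
    names(samples) <- manifest$sample_id
    names(truth) <- manifest$sample_id
    list(manifest = manifest, samples = samples, truth = truth)
  })
}

#' Empirical composition table of the embedded cohort
#'
#' Distinct group-qualified compositions of the embedded Korean cohort
#' table with their frequencies, usable directly as the `compositions`
#' argument of [simulate_cohort()].
#'
#' @param lib A `glu1_library`.
#' @return `data.frame` with `composition` and `weight`.
#' @export
cohort_compositions <- function(lib) {
  stopifnot(inherits(lib, "glu1_library"))
  tab <- lib$korean_table
  obs <- lib$observations[lib$observations$source == "korean", ]
  comp <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    b1 <- r$glu_b1
    b1x <- obs$variant[obs$cultivar == r$cultivar & obs$slot == "b1x"]
    if (length(b1x) == 1L && grepl("^1Bx7g", b1x))
      b1 <- sub("^7", sub("1Bx", "", b1x), b1)
    paste(r$glu_a1, b1, r$glu_d1, sep = ", ")
  }, character(1))
  agg <- table(comp)
  data.frame(composition = names(agg), weight = as.integer(agg),
             stringsAsFactors = FALSE)
}
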