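# Shared test fixtures: the embedded reference library, peak lists built
# from its cultivar tables, and independent oracles.

.test_env <- new.env(parent = emptyenv())

glu1_test_lib <- function() {
  if (is.null(.test_env$lib)) .test_env$lib <- load_glu1_library()
  .test_env$lib
}

.mass_slots <- c("a1x_mass", "b1x_mass", "b1y_mass", "d1x_mass", "d1y_mass")

# one calibrated peak list per cultivar row, from the printed mean masses
table_peaklists <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    m <- unlist(tab[i, .mass_slots])
    peaklist(m[!is.na(m)], sample_id = tab$cultivar[i], calibrated = TRUE)
  })
}

table_compositions <- function(tab) {
  paste(tab$glu_a1, tab$glu_b1, tab$glu_d1, sep = ", ")
}

# evidence as the study had it: duplication PCR result for every
# 1Bx7/1Bx7OE carrier, RP-HPLC confirmation for the near-identical-mass
# subunits that appear in the printed composition
table_evidence <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    labs <- unlist(strsplit(c(r$glu_a1, r$glu_b1, r$glu_d1), "+",
                            fixed = TRUE))
    dup <- if (grepl("7OE", r$glu_b1)) TRUE
      else if (grepl("(^|[^1])7($|\\+)", r$glu_b1)) FALSE
      else NA
    evidence_flags(dup, intersect(labs, c("2*", "6", "8", "8*")))
  })
}

# group-qualified composition strings (7 -> 7g1/7g2 by corrected mass),
# usable as simulator ground truth
group_qualified_compositions <- function(lib, tab, source) {
  obs <- lib$observations[lib$observations$source == source, ]
  vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    b1 <- r$glu_b1
    b1x <- obs$variant[obs$cultivar == r$cultivar & obs$slot == "b1x"]
    if (length(b1x) == 1L && grepl("^1Bx7g", b1x))
      b1 <- sub("^7", sub("1Bx", "", b1x), b1)
    paste(r$glu_a1, b1, r$glu_d1, sep = ", ")
  }, character(1))
}

# independent residue-by-residue average-mass oracle (simple loop, its own
# constants transcribed from the standard average residue-mass table)
oracle_average_mass <- function(seq) {
  tab <- list(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  total <- 18.0153
  for (ch in strsplit(seq, "")[[1]]) total <- total + tab[[ch]]
  total
}

# independent exhaustive enumeration of haplotype combinations with the
# published matching rule, written as plain nested loops; returns the
# minimum score over all combinations
oracle_min_score <- function(lib, peaks, tol = 300, dup = NA,
                             penalty_missing = 10000,
                             penalty_unassigned = 1000) {
  al <- lib$alleles
  variants_for <- function(locus, type, display) {
    v <- al$variant[al$locus == locus & al$type == type &
                      al$display == display]
    if (isTRUE(dup)) v <- setdiff(v, "1Bx7g2")
    if (isFALSE(dup)) v <- setdiff(v, "1Bx7OE")
    v
  }
  locus_opts <- function(locus) {
    hs <- lib$haplotypes[lib$haplotypes$locus == locus, ]
    res <- list()
    for (i in seq_len(nrow(hs))) {
      xs <- if (is.na(hs$x[i])) list(NULL) else
        as.list(variants_for(locus, "x", hs$x[i]))
      ys <- if (is.na(hs$y[i])) list(NULL) else
        as.list(variants_for(locus, "y", hs$y[i]))
      if (!length(xs) || !length(ys)) next
      # wrap in a list: a zero-member haplotype (silent Glu-A1) is c(NULL,
      # NULL) = NULL, and assigning bare NULL would drop the element
      for (x in xs) for (y in ys)
        res[[length(res) + 1]] <- list(members = c(x, y))
    }
    res
  }
  score_of <- function(members) {
    used <- rep(FALSE, nrow(peaks))
    s <- 0
    for (v in members) {
      j <- which(al$variant == v)
      corr <- floor(peaks$mass - 105.14 * al$cys[j])
      ok <- which(!used & corr >= al$corr_min[j] - tol &
                    corr <= al$corr_max[j] + tol)
      if (!length(ok)) { s <- s + penalty_missing; next }
      d <- abs(corr[ok] - al$corr_mean[j])
      pick <- ok[which.min(d)]
      used[pick] <- TRUE
      s <- s + min(d)
    }
    s + penalty_unassigned * sum(!used)
  }
  best <- Inf
  for (a in locus_opts("Glu-A1"))
    for (b in locus_opts("Glu-B1"))
      for (d in locus_opts("Glu-D1"))
        best <- min(best, score_of(c(a$members, b$members, d$members)))
  best
}

# session-scoped scratch directory (cleaned up with the R session)
make_tempdir <- function() {
  d <- tempfile("glu1-test-")
  dir.create(d)
  d
}
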