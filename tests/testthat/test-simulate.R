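test_that("zero-noise peaks sit exactly at predicted mass plus adduct", {
  lib <- glu1_test_lib()
  spec <- simulation_spec(c("2*", "7g1+8", "5+10"), relative_mass_sd = 0)
  sim <- simulate_peaklist(lib, spec)
  # predicted mature masses 86335 / 82527 / 75159 / 88126 / 67475 shifted
  # by 105.14 Da per cysteine (4/4/7/5/7)
  expect_equal(sort(unname(sim$truth$true_masses)),
               c(67475 + 735.98, 75159 + 735.98, 82527 + 420.56,
                 86335 + 420.56, 88126 + 525.70))
  expect_equal(sim$peaks$mass, sort(unname(sim$truth$true_masses)))
  bare <- simulate_peaklist(
    lib, simulation_spec(c("2*", "7g1+8", "5+10"), alkylated = FALSE,
                         relative_mass_sd = 0))
  expect_equal(bare$peaks$mass, sort(c(86335, 82527, 75159, 88126, 67475)))
})

test_that("simulation is deterministic under a fixed seed", {
  lib <- glu1_test_lib()
  spec <- simulation_spec(c("N", "7g2+8", "2.2+12"), seed = 123)
  s1 <- simulate_peaklist(lib, spec)
  s2 <- simulate_peaklist(lib, spec)
  expect_identical(s1$peaks, s2$peaks)
  c1 <- simulate_cohort(lib, 5, seed = 77)
  c2 <- simulate_cohort(lib, 5, seed = 77)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$samples, c2$samples)
})

test_that("composition parsing validates labels and 1Bx7 groups", {
  lib <- glu1_test_lib()
  expect_error(
    simulate_peaklist(lib, simulation_spec("not-a-composition")), "locus")
  expect_error(
    simulate_peaklist(lib, simulation_spec(c("N", "7+8", "2+12"))),
    "7g1.*7g2")
  expect_error(
    simulate_peaklist(lib, simulation_spec(c("N", "9+9", "2+12"))),
    "unknown Glu-B1")
  expect_error(simulation_spec(c("N", "7g1", "2+12"),
                               relative_mass_sd = 0.1), "0.005")
})

test_that("profile simulation peaks at the true mass", {
  lib <- glu1_test_lib()
  spec <- simulation_spec(c("N", "7g1", "2+12"), relative_mass_sd = 0,
                          noise_sd = 0, seed = 2)
  sim <- simulate_profile(lib, spec)
  truth <- sort(unname(sim$truth$true_masses))
  apex <- sim$spectrum$mass[which.max(sim$spectrum$intensity)]
  expect_true(min(abs(truth - apex)) <= 5)  # within one grid step
  found <- detect_peaks(sim$spectrum)
  expect_equal(found$mass, truth, tolerance = 1 / 70000)
})

test_that("cohort simulation writes a manifest with derived seeds", {
  lib <- glu1_test_lib()
  co <- simulate_cohort(lib, 1, seed = 5)
  expect_equal(nrow(co$manifest), 1)
  expect_equal(names(co$samples), co$manifest$sample_id)
  co3 <- simulate_cohort(lib, 38, seed = 8, n_replicates = 2)
  expect_equal(length(co3$samples[[1]]), 2)
  # drawn from the cohort composition frequencies: most samples carry 1Bx7
  frac7 <- mean(grepl("7g", co3$manifest$composition))
  expect_gt(frac7, 0.4)
})

test_that("empirical replicate RSD recovers the injected relative SD", {
  lib <- glu1_test_lib()
  spec <- simulation_spec(c("2*", "7g2+8", "5+10"), relative_mass_sd = 5e-4,
                          seed = 31)
  masses <- vapply(1:200, function(r) {
    s <- spec; s$seed <- 31 + r
    simulate_peaklist(lib, s)$peaks$mass[1]
  }, numeric(1))
  rsd <- rsd_percent(masses)
  expect_gt(rsd, 0.5 * 0.05)
  expect_lt(rsd, 2 * 0.05)
})

test_that("genotypes are recovered end-to-end from simulated peak lists", {
  lib <- glu1_test_lib()
  # all distinct fixture compositions, zero noise: exact recovery
  comps <- unique(c(
    group_qualified_compositions(lib, lib$standards_table, "standard"),
    cohort_compositions(lib)$composition))
  for (cc in comps) {
    sim <- simulate_peaklist(lib, simulation_spec(cc,
                                                  relative_mass_sd = 0))
    cl <- call_genotype(lib, sim$peaks)
    recovered <- cl$composition == sim$truth$composition ||
      sim$truth$composition %in% cl$ambiguous_alternatives
    expect_true(recovered, label = sprintf("zero-noise recovery of %s", cc))
  }
  # 200 seeded samples at 0.05% relative SD: at least 95% recovered
  co <- simulate_cohort(lib, 200, seed = 42, relative_mass_sd = 5e-4)
  hit <- vapply(seq_len(200), function(i) {
    cl <- call_genotype(lib, co$samples[[i]][[1]])
    truth <- co$truth[[i]]$composition
    !cl$uncallable && (cl$composition == truth ||
                         truth %in% cl$ambiguous_alternatives)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
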