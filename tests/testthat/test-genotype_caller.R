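test_that("candidate_alleles returns window hits ordered by delta", {
  lib <- glu1_test_lib()
  # 1Ax2* and 1Bx6 means differ by only 249 Da: both are candidates
  hits <- candidate_alleles(lib, 86420, tol = 300)
  expect_setequal(hits$name, c("1Ax2*", "1Bx6"))
  expect_equal(hits$name[1], "1Bx6")  # closer mean first
  expect_identical(candidate_alleles(lib, 67630)$name, "1Dy10")
  expect_equal(nrow(candidate_alleles(lib, 50000)), 0)
  expect_error(candidate_alleles(lib, 86420, tol = 0), "positive")
})

test_that("classify_bx7 splits the mass classes and applies PCR evidence", {
  lib <- glu1_test_lib()
  expect_identical(classify_bx7(lib, 82410), "group1")
  expect_identical(classify_bx7(lib, 83067), "group2_or_OE")
  expect_identical(classify_bx7(lib, 83067, evidence_flags(FALSE)),
                   "group2")
  expect_identical(classify_bx7(lib, 83113, evidence_flags(TRUE)), "OE")
  expect_error(classify_bx7(lib, 90000), "outside")
})

test_that("call_genotype reproduces representative standard cultivars", {
  lib <- glu1_test_lib()
  cs <- call_genotype(lib, peaklist(c(83488, 75886, 87493, 69410),
                                    sample_id = "Chinese Spring",
                                    calibrated = TRUE))
  expect_identical(cs$composition, "N, 7+8, 2+12")
  expect_identical(cs$bx7_group, "group2_or_OE")
  # the Glu-B1 x slot is obligatory: the lone x-type peak goes to 1Bx6,
  # not 1Ax2*, even though both windows contain it
  br <- call_genotype(lib, peaklist(c(86840, 75993, 87431, 69404),
                                    sample_id = "Brimstone",
                                    calibrated = TRUE))
  expect_identical(br$composition, "N, 6+8*, 2+12")
  ch <- call_genotype(lib, peaklist(c(86556, 82824, 74295, 88450, 68400),
                                    sample_id = "Cheyenne",
                                    calibrated = TRUE))
  expect_identical(ch$composition, "2*, 7+9, 5+10")
  expect_identical(ch$bx7_group, "group1")
})

test_that("corrected masses in calls obey the per-allele adduct rule", {
  lib <- glu1_test_lib()
  cl <- call_genotype(lib, peaklist(c(86556, 82824, 74295, 88450, 68400),
                                    sample_id = "Cheyenne",
                                    calibrated = TRUE))
  al <- lib$alleles
  for (i in seq_len(nrow(cl$calls))) {
    cys <- al$cys[al$variant == cl$calls$variant[i]]
    expect_identical(cl$calls$corrected_mass[i],
                     floor(cl$calls$peak_mass[i] - vp_shift(cys)))
  }
})

test_that("degenerate inputs give uncallable results, not errors", {
  lib <- glu1_test_lib()
  out_of_range <- peaklist(c(20000, 30000), calibrated = TRUE)
  r <- call_genotype(lib, out_of_range)
  expect_true(r$uncallable)
  expect_match(r$flags, "acquisition range")
  nothing <- peaklist(65000, calibrated = TRUE)  # matches no window
  r2 <- call_genotype(lib, nothing)
  expect_true(r2$uncallable)
  expect_error(call_genotype(lib, peaklist(83488)), "calibrated")
})

test_that("RP-HPLC evidence flips the 8/8* call and silences the flag", {
  lib <- glu1_test_lib()
  pk <- peaklist(c(86606, 82859, 75874, 88475, 68416),
                 sample_id = "Baekchal", calibrated = TRUE)
  no_ev <- call_genotype(lib, pk)
  expect_identical(no_ev$composition, "2*, 7+8, 5+10")
  expect_true("2*, 7+8*, 5+10" %in% no_ev$ambiguous_alternatives)
  expect_true(any(no_ev$calls$ambiguity == "8/8*"))
  with_ev <- call_genotype(lib, pk,
                           evidence = evidence_flags(rphplc_calls = "8*"))
  expect_identical(with_ev$composition, "2*, 7+8*, 5+10")
  expect_false(any(with_ev$calls$ambiguity == "8/8*"))
})

test_that("duplication PCR evidence separates 1Bx7 group 2 from OE", {
  lib <- glu1_test_lib()
  pk <- peaklist(c(86591, 83402, 75878, 88477, 68353),
                 sample_id = "Glenlea", calibrated = TRUE)
  pos <- call_genotype(lib, pk, evidence = evidence_flags(TRUE))
  expect_identical(pos$composition, "2*, 7OE+8*, 5+10")
  expect_identical(pos$bx7_group, "OE")
  neg <- call_genotype(lib, pk, evidence = evidence_flags(FALSE))
  expect_identical(neg$composition, "2*, 7+8, 5+10")
  expect_identical(neg$bx7_group, "group2")
  unknown <- call_genotype(lib, pk)
  expect_true("2*, 7OE+8*, 5+10" %in% unknown$ambiguous_alternatives)
})

test_that("all 62 cultivar tables are called exactly given the study's
           orthogonal evidence", {
  lib <- glu1_test_lib()
  for (tab in list(lib$standards_table, lib$korean_table)) {
    calls <- mapply(function(pk, ev) call_genotype(lib, pk, evidence = ev),
                    table_peaklists(tab), table_evidence(tab),
                    SIMPLIFY = FALSE)
    got <- vapply(calls, `[[`, character(1), "composition")
    expect_identical(got, table_compositions(tab))
  }
})

test_that("the returned combination is optimal against independent full
           enumeration", {
  lib <- glu1_test_lib()
  for (tab in list(lib$standards_table, lib$korean_table)) {
    pks <- table_peaklists(tab)
    for (pk in pks) {
      cl <- call_genotype(lib, pk)
      expect_equal(cl$score, oracle_min_score(lib, pk),
                   label = sprintf("score optimality for %s",
                                   attr(pk, "sample_id")))
    }
  }
})

test_that("cohorts propagate per-sample failures without aborting", {
  lib <- glu1_test_lib()
  samples <- list(
    peaklist(c(83488, 75886, 87493, 69410), sample_id = "good",
             calibrated = TRUE),
    peaklist(65000, sample_id = "dud", calibrated = TRUE))
  co <- call_cohort(lib, samples)
  expect_equal(co$summary$n_samples, 2)
  expect_equal(co$summary$n_uncallable, 1)
  expect_false(co$calls[["good"]]$uncallable)
})
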