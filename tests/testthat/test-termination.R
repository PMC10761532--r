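test_that("normalizing the reference abundances gives the known profile", {
  p <- termination_profile(c(2.8, 2.96, 2.36, 1.68, 0.54, 0.19))
  expect_equal(round(100 * as.numeric(p), 1),
               c(26.6, 28.1, 22.4, 16.0, 5.1, 1.8))
  expect_equal(sum(p), 1)
})

test_that("degenerate profiles behave", {
  expect_equal(as.numeric(termination_profile(7)), 1)
  expect_equal(as.numeric(termination_profile(c(3, 3))), c(0.5, 0.5))
  expect_error(termination_profile(c(0, 0)), "undefined")
  expect_error(termination_profile(c(-1, 2)), "non-negative")
})

test_that("profiles are scale invariant and count inputs carry SEs", {
  set.seed(12)
  for (i in 1:10) {
    a <- runif(sample(2:8, 1), 0, 5)
    if (sum(a) == 0) next
    expect_equal(as.numeric(termination_profile(a)),
                 as.numeric(termination_profile(a * runif(1, 0.1, 100))))
  }
  counts <- c(280, 296, 236, 168, 54, 19)
  p <- termination_profile(counts)
  se <- attr(p, "se")
  expect_equal(as.numeric(se),
               sqrt(as.numeric(p) * (1 - as.numeric(p)) / sum(counts)))
  expect_null(attr(termination_profile(c(2.8, 2.96)), "se"))
})

test_that("abundance_ratio cancels normalization", {
  pr <- reference_abundances("ttr1320_cdms_profile")
  expect_equal(abundance_ratio(pr, 2, 1), 1.74, tolerance = 0.01)
  expect_equal(abundance_ratio(termination_profile(pr), 2, 1),
               abundance_ratio(pr, 2, 1))
  expect_equal(abundance_ratio(c(50, 25, 25), 1, 2), 2)
  expect_equal(abundance_ratio(c(1, 2), 2, 2), 1)
  expect_error(abundance_ratio(c(1, 0), 1, 2), "denominator")
  expect_error(abundance_ratio(c(1, 2), 3, 1), "out of range")
})

test_that("profile comparison computes total variation distance", {
  p <- termination_profile(c(1, 2, 3))
  expect_equal(compare_profiles(p, p)$tv, 0)
  expect_equal(compare_profiles(c(1, 0), c(0, 1))$tv, 1)
  # CD-MS vs gel profiles of the 848 construct; 0.214 frozen from direct
  # hand evaluation of 0.5 * sum(|p - q|)
  cdms <- termination_profile(c(26.6, 28.1, 22.4, 16.0, 5.1, 1.8))
  gel <- termination_profile(reference_abundances("ttr848_gel_profile"),
                             source = "gel")
  expect_equal(compare_profiles(cdms, gel)$tv, 0.214, tolerance = 0.002)
  expect_error(compare_profiles(c(1, 1), c(1, 1, 1)), "different numbers")
})

test_that("noise-free pipeline profile equals the packaged conditional", {
  mt <- mass_table_1320()
  mx <- mixture_1320()
  quant <- simulate_and_quantify(mx, mt, n_ions = 4000, seed = 13,
                                 charge_sigma = 0, mz_cv = 0)
  p <- profile_from_quant(quant)
  drawn <- table(factor(attr(quant, "assignment"),
                        levels = species_label(2:5)))
  expect_equal(as.numeric(p), as.numeric(drawn) / sum(drawn))
})

test_that("fold change recovers known empty-fraction ratios", {
  expect_equal(fold_change(0.5, 0.5), 1)
  expect_equal(fold_change(0.6, 0.2), 3)
  expect_error(fold_change(0.1, 0), "denominator")
  # round trip through the CD-MS pipeline with empty fractions 0.3 and 0.6
  mt <- mass_table_1320()
  e1 <- simulate_and_quantify(mixture_1320(0.3), mt, 10000, seed = 14,
                              mode = "standard")
  e2 <- simulate_and_quantify(mixture_1320(0.6), mt, 10000, seed = 15,
                              mode = "standard")
  f1 <- e1$rel_abundance[e1$label == "empty"]
  f2 <- e2$rel_abundance[e2$label == "empty"]
  expect_equal(fold_change(f2, f1), 2, tolerance = 0.06)
})

test_that("gel profiles come from intensity or molar fractions", {
  sp <- enumerate_species(ttr1320())
  fr <- reference_abundances("ttr1320_gel_profile")
  fr <- fr / sum(fr)
  lane <- simulate_lane(fr, sp, gel_config(noise_sigma = 0), seed = 1)
  bq <- quantify_bands(lane, sp)
  p <- profile_from_bands(bq)
  expect_equal(as.numeric(p), bq$intensity_fraction)
  expect_error(profile_from_bands(bq, molar = TRUE), "molar_correct")
  bq2 <- molar_correct(bq, stats::setNames(sp$nt_length, sp$label))
  pm <- profile_from_bands(bq2, molar = TRUE)
  expect_equal(as.numeric(pm), bq2$molar_fraction)
})
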