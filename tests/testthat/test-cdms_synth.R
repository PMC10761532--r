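test_that("mixture_spec validates and completes the partial remainder", {
  mx <- suspension_mixture_848()
  expect_equal(nrow(mx), 8)
  expect_equal(mx$label[8], "partial")
  expect_equal(sum(mx$fraction), 1)
  expect_equal(mx$fraction[8], 1 - 0.9033)
  expect_error(mixture_spec(c("a", "b"), c(0.8, 0.4)), "> 1")
  expect_error(mixture_spec("a", -0.1), "non-negative")
  expect_error(mixture_spec(c("a", "partial"), c(0.5, 0.2)), "partial")
  expect_error(mixture_spec(character(0), numeric(0)), "at least one")
})

test_that("sim_config presets map to the two trapping modes", {
  expect_equal(sim_config(seed = 1, mode = "standard")$charge_sigma, 1.0)
  expect_equal(sim_config(seed = 1, mode = "high-resolution")$charge_sigma,
               0.5)
  expect_error(sim_config(), "seed")
  expect_error(sim_config(n_ions = 0, seed = 1), "n_ions")
})

test_that("noise-free simulation is a point mass at the predicted mass", {
  mt <- mass_table_848()
  mx <- mixture_spec("empty", 1)
  ions <- simulate_ions(mx, mt, sim_config(n_ions = 200, charge_sigma = 0,
                                           mz_cv = 0, seed = 3))
  # true-charge spread cancels exactly: m/z compensates the drawn charge
  expect_equal(ions$derived_mass, rep(mt$predicted_mass_da[1], 200))
  expect_equal(ions$derived_mass, ions$measured_mz * ions$measured_charge)
})

test_that("simulation is deterministic for a fixed seed", {
  mt <- mass_table_848()
  mx <- suspension_mixture_848()
  a <- simulate_ions(mx, mt, sim_config(n_ions = 500, seed = 11))
  b <- simulate_ions(mx, mt, sim_config(n_ions = 500, seed = 11))
  expect_identical(a, b)
  c <- simulate_ions(mx, mt, sim_config(n_ions = 500, seed = 12))
  expect_false(identical(a$derived_mass, c$derived_mass))
})

test_that("species draws are multinomial at the mixture fractions", {
  mt <- mass_table_848()
  mx <- suspension_mixture_848()
  ions <- simulate_ions(mx, mt, sim_config(n_ions = 10000, seed = 21,
                                           mode = "standard"))
  counts <- table(factor(ions$true_species, levels = mx$label))
  expected <- 10000 * mx$fraction
  sds <- sqrt(10000 * mx$fraction * (1 - mx$fraction))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3 * sds))
})

test_that("unknown mixture species raises a configuration error", {
  mt <- mass_table_848()
  expect_error(
    simulate_ions(mixture_spec(c("empty", "9GOI-10ITR"), c(0.5, 0.5)), mt,
                  sim_config(n_ions = 10, seed = 1)),
    "not present in mass table")
})

test_that("ion CSV round trip preserves events", {
  mt <- mass_table_848()
  ions <- simulate_ions(suspension_mixture_848(), mt,
                        sim_config(n_ions = 2000, seed = 31))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ions(ions, f, truth = TRUE)
  back <- read_ions(f)
  expect_equal(back$derived_mass, ions$derived_mass, tolerance = 1e-11)
  expect_equal(back$true_species, ions$true_species)
  # production schema omits the truth column
  write_ions(ions, f)
  expect_false("true_species" %in% names(read_ions(f)))
})

test_that("ion CSV schema and row errors are explicit", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("ion_id,measured_mz,derived_mass\n1,100,200", f)
  expect_error(read_ions(f), "measured_charge")
  writeLines(c("ion_id,measured_mz,measured_charge,derived_mass",
               "1,24000,155,3720000",
               "2,24000,oops,3720000"), f)
  expect_error(read_ions(f), "row 2")
  # empty event list round-trips as a header-only file
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ions(events_from_masses(numeric(0)), f2)
  expect_equal(length(readLines(f2)), 1L)
  expect_equal(nrow(read_ions(f2)), 0L)
})

test_that("mean derived mass converges to the table prediction", {
  mt <- mass_table_1320()
  mx <- mixture_spec(c("empty", species_label(2:5)), rep(0.2, 5))
  ions <- simulate_ions(mx, mt, sim_config(n_ions = 50000, seed = 41,
                                           mode = "standard"))
  for (i in seq_len(nrow(mt))) {
    m <- ions$derived_mass[ions$true_species == mt$label[i]]
    expect_lt(abs(mean(m) / mt$predicted_mass_da[i] - 1), 0.001)
  }
})

test_that("simulated mass resolution matches the closed-form prediction", {
  mt <- mass_table_848()
  sim <- sim_config(n_ions = 20000, seed = 51, mode = "standard")
  ions <- simulate_ions(mixture_spec("empty", 1), mt, sim)
  res <- estimate_resolution(ions)
  rel_sd <- sqrt((sim$charge_sigma / sim$charge_mean)^2 + sim$mz_cv^2)
  predicted <- 1 / (2.3548 * rel_sd)
  expect_lt(abs(res / predicted - 1), 0.3)
  # and the preset lands at the instrument's nominal order of magnitude
  # (~100; FWHM vs sigma conventions differ by 2.35x, so factor-2 band)
  expect_gt(predicted, 50)
  expect_lt(predicted, 200)
})
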