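test_that("spectrum binning conserves counts and localizes point masses", {
  one <- build_spectrum(events_from_masses(3729510), bin_width = 1e4)
  expect_equal(sum(one$counts), 1)
  nz <- which(one$counts > 0)
  expect_length(nz, 1)
  expect_true(one$edges[nz] <= 3729510 && 3729510 < one$edges[nz + 1])

  two <- events_from_masses(rep(c(3729510, 4001935), c(30, 20)))
  sp <- build_spectrum(two, bin_width = 1e4)
  expect_equal(sum(sp$counts > 0), 2)
  expect_equal(sum(sp$counts), 50)
  half <- build_spectrum(two, bin_width = 5e3)
  expect_equal(sum(half$counts), 50)
  expect_error(build_spectrum(events_from_masses(numeric(0))), "zero ions")
})

test_that("zero-noise assignment recovers the multinomial draw exactly", {
  mt <- mass_table_848()
  ions <- simulate_ions(suspension_mixture_848(), mt,
                        sim_config(n_ions = 5000, charge_sigma = 0,
                                   mz_cv = 0, seed = 61))
  quant <- assign_ions(ions, mt)
  truth <- table(factor(ions$true_species,
                        levels = c(mt$label, "partial")))
  expect_equal(quant$ion_count,
               as.integer(truth))  # partial truth maps to unassigned row
  assigned <- attr(quant, "assignment")
  model <- ions$true_species != "partial"
  expect_identical(assigned[model], ions$true_species[model])
  expect_true(all(is.na(assigned[!model])))
})

test_that("assignment conserves counts and reports unassigned explicitly", {
  mt <- mass_table_848()
  quant <- simulate_and_quantify(suspension_mixture_848(), mt,
                                 n_ions = 4000, seed = 71,
                                 mode = "standard")
  expect_equal(sum(quant$ion_count), 4000)
  expect_equal(sum(quant$rel_abundance), 1)
  expect_equal(attr(quant, "total_ions"), 4000)
  # far-out-of-range masses are counted, never dropped
  stray <- events_from_masses(c(1e6, 7e6, 4001935))
  q2 <- assign_ions(stray, mt)
  expect_equal(sum(q2$ion_count), 3)
  expect_equal(q2$ion_count[q2$label == "unassigned"], 2L)
  expect_error(assign_ions(stray, data.frame()), "mass table")
})

test_that("a boundary mass goes to the lower-mass species", {
  sp <- enumerate_species(ttr848(), include_empty = TRUE)
  mt <- build_mass_table(sp, round_capsid(), window_half_width = 0.2)
  boundary <- mt$window_high_da[3]  # shared clipped edge of rows 3 and 4
  expect_equal(boundary, mt$window_low_da[4])
  q <- assign_ions(events_from_masses(boundary), mt)
  expect_equal(q$ion_count[3], 1L)
  expect_equal(q$ion_count[4], 0L)
})

test_that("clipped-window assignment equals nearest-predicted-mass", {
  mt <- build_mass_table(enumerate_species(ttr848(), include_empty = TRUE),
                         aav8_capsid_preset(), window_half_width = 0.2)
  set.seed(81)
  masses <- runif(1000, min(mt$window_low_da), max(mt$window_high_da))
  q <- assign_ions(events_from_masses(masses), mt)
  got <- attr(q, "assignment")
  nearest <- mt$label[
    vapply(masses, function(m) which.min(abs(mt$predicted_mass_da - m)),
           integer(1))]
  inside <- !is.na(got)
  expect_identical(got[inside], nearest[inside])
})

test_that("abundance estimates converge to the mixture truth", {
  mt <- mass_table_1320()
  mx <- mixture_1320()
  quant <- simulate_and_quantify(mx, mt, n_ions = 50000, seed = 91,
                                 mode = "standard")
  est <- quant$rel_abundance[match(mx$label, quant$label)]
  expect_lt(max(abs(est - mx$fraction)), 0.005)
})

test_that("charge summary flags only genuinely elevated charges", {
  mt <- mass_table_848()
  ions <- simulate_ions(suspension_mixture_848(), mt,
                        sim_config(n_ions = 8000, seed = 101,
                                   mode = "standard"))
  quant <- assign_ions(ions, mt)
  cs <- charge_summary(ions, quant)
  expect_false(any(cs$flagged))  # shared-charge model: nothing elevated

  # positive control: splice in monomer ions carrying +20 e
  hot_mass <- mt$predicted_mass_da[mt$label == "1GOI-2ITR"]
  set.seed(5)
  hot_z <- rnorm(300, 175, 3)
  hot <- data.frame(ion_id = seq_len(300) + nrow(ions),
                    true_species = "1GOI-2ITR",
                    measured_mz = hot_mass / hot_z,
                    measured_charge = hot_z,
                    derived_mass = hot_mass)
  spiked <- rbind(as.data.frame(ions), hot)
  q2 <- assign_ions(spiked, mt)
  cs2 <- charge_summary(spiked, q2)
  expect_true(cs2$flagged[cs2$label == "1GOI-2ITR"])
  expect_false(any(cs2$flagged[cs2$label != "1GOI-2ITR"]))
})

test_that("single-species charge mean equals the mean over assigned ions", {
  mt <- mass_table_848()
  ions <- simulate_ions(mixture_spec("empty", 1), mt,
                        sim_config(n_ions = 3000, seed = 111,
                                   mode = "standard"))
  quant <- assign_ions(ions, mt)
  cs <- charge_summary(ions, quant)
  assigned <- !is.na(attr(quant, "assignment"))
  expect_equal(cs$mean_charge[cs$label == "empty"],
               mean(ions$measured_charge[assigned]))
  expect_equal(cs$n_ions[cs$label != "empty"], rep(0L, 6))
  expect_true(all(is.na(cs$mean_charge[cs$label != "empty"])))
})
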