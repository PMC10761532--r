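# shared fixtures: the two ladder constructs, a round-number capsid, and a
# compact simulate->quantify wrapper

ttr848 <- function() construct_def("TTR-848", 848, capacity = 4700)
ttr1320 <- function() construct_def("TTR-1320", 1320, capacity = 5200)

round_capsid <- function() capsid_model(80000, 66000, 60000)

mass_table_848 <- function(capsid = aav8_capsid_preset(), ...) {
  build_mass_table(enumerate_species(ttr848(), include_empty = TRUE),
                   capsid, mass_model_params(), ...)
}

mass_table_1320 <- function(capsid = aav8_capsid_preset(), ...) {
  build_mass_table(enumerate_species(ttr1320(), include_empty = TRUE),
                   capsid, mass_model_params(), ...)
}

# the seven-component suspension mixture for the 848 construct (empty +
# six species; deficit auto-assigned to "partial")
suspension_mixture_848 <- function() {
  ra <- reference_abundances("ttr848_suspension_cdms")
  mixture_spec(ra$label, ra$fraction)
}

# 1320-construct mixture: 70% empty, 30% split per the CD-MS profile
mixture_1320 <- function(empty_fraction = 0.7) {
  pr <- reference_abundances("ttr1320_cdms_profile")
  mixture_spec(c("empty", species_label(2:5)),
               c(empty_fraction, (1 - empty_fraction) * pr / sum(pr)))
}

simulate_and_quantify <- function(mixture, mass_table, n_ions, seed, ...) {
  events <- simulate_ions(mixture, mass_table,
                          sim_config(n_ions = n_ions, seed = seed, ...))
  assign_ions(events, mass_table)
}

# bare ion-event table with given derived masses (assignment only needs these)
events_from_masses <- function(masses, charge = 155) {
  data.frame(ion_id = seq_along(masses),
             measured_mz = masses / charge,
             measured_charge = rep(charge, length(masses)),
             derived_mass = masses)
}
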