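#' Specify a particle-species mixture
#'
#' Ground-truth composition for the ion simulator: one abundance fraction per
#' particle species (labels must match the mass table, e.g. `"empty"`,
#' `"1GOI-2ITR"`). If the supplied fractions sum to less than 1, the deficit
#' is assigned to the reserved `"partial"` component — capsids holding DNA of
#' intermediate, model-unassignable mass — so published subpopulation tables
#' that omit the partial remainder can be used verbatim as mixtures.
#'
#' @param labels Character vector of species labels.
#' @param fractions Numeric abundance fractions, all `>= 0`, summing to at
#'   most 1 (within 1e-9).
#' @return A `data.frame` of class `mixture_spec` with columns `label`,
#'   `fraction`; fractions sum to exactly 1.
#' @export
#' @examples
#' # seven-component empty + hexamer ladder; remainder becomes "partial"
#' mixture_spec(c("empty", "1GOI-2ITR"), c(0.798, 0.028))
mixture_spec <- function(labels, fractions) {
  stopifnot(is.character(labels), is.numeric(fractions),
            length(labels) == length(fractions))
  if (length(labels) == 0) stop("mixture must have at least one component",
                                call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicate species label in mixture",
                                  call. = FALSE)
  if (any(is.na(fractions)) || any(fractions < 0)) {
    stop("mixture fractions must be non-negative", call. = FALSE)
  }
  s <- sum(fractions)
  if (s > 1 + 1e-9) {
    stop("mixture fractions sum to ", format(s), " (> 1)", call. = FALSE)
  }
  if (s < 1 - 1e-9) {
    if ("partial" %in% labels) {
      stop("fractions sum to ", format(s), " < 1 but a 'partial' component ",
           "is already present; fractions must sum to 1", call. = FALSE)
    }
    labels <- c(labels, "partial")
    fractions <- c(fractions, 1 - s)
  } else {
    # absorb rounding so downstream multinomial weights are exact
    fractions <- fractions / s
  }
  structure(data.frame(label = labels, fraction = fractions,
                       stringsAsFactors = FALSE),
            class = c("mixture_spec", "data.frame"))
}

#' CD-MS acquisition settings for the simulator
#'
#' Emulates single-ion charge-detection acquisition: each trapped ion yields a
#' measured m/z and a measured charge. Two instrument presets are exposed via
#' `mode`: `"standard"` (charge uncertainty 1 e, the short-trapping setting)
#' and `"high-resolution"` (0.5 e, long trapping). Mean ion charge is a free
#' parameter — it is never reported for these particles and cancels out of
#' abundance estimates; 155 e is typical for ~4 MDa electrosprayed ions.
#'
#' @param n_ions Number of single-ion events (default 10,000, a typical
#'   dataset size).
#' @param charge_mean Mean true ion charge in elementary charges (default
#'   155).
#' @param charge_sigma Charge measurement uncertainty in e. Overridden by
#'   `mode` if that is given.
#' @param mz_cv Fractional (coefficient-of-variation) m/z measurement error
#'   (default 0.002; the charge term dominates total mass error at defaults).
#' @param charge_spread Standard deviation of the true charge distribution in
#'   e (default 3). Cancels exactly in derived mass because m/z compensates.
#' @param seed Integer RNG seed; mandatory for reproducibility.
#' @param mode Optional preset name: `"standard"` or `"high-resolution"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_ions = 10000, charge_mean = 155, charge_sigma = 1.0,
                       mz_cv = 0.002, charge_spread = 3, seed, mode = NULL) {
  if (missing(seed)) stop("seed is mandatory for a reproducible simulation",
                          call. = FALSE)
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("standard", "high-resolution"))
    charge_sigma <- c("standard" = 1.0, "high-resolution" = 0.5)[[mode]]
  }
  structure(
    list(n_ions = check_count(n_ions, "n_ions", min = 1),
         charge_mean = check_number(charge_mean, "charge_mean", min = 0,
                                    strict = TRUE),
         charge_sigma = check_number(charge_sigma, "charge_sigma", min = 0),
         mz_cv = check_number(mz_cv, "mz_cv", min = 0),
         charge_spread = check_number(charge_spread, "charge_spread", min = 0),
         seed = check_count(seed, "seed")),
    class = "sim_config"
  )
}

# inter-window gaps of a mass table: where "partial" true masses live
window_gaps <- function(mass_table) {
  tab <- mass_table[order(mass_table$predicted_mass_da), , drop = FALSE]
  lo <- tab$window_high_da[-nrow(tab)]
  hi <- tab$window_low_da[-1]
  keep <- hi > lo
  cbind(lo = lo[keep], hi = hi[keep])
}

#' Simulate CD-MS single-ion events
#'
#' Draws `n_ions` ions multinomially from the mixture; every model-species
#' ion carries the species' predicted mass as true mass, a true charge
#' `Normal(charge_mean, charge_spread)` shared across species (charges are
#' empirically similar across genome lengths when packaging is complete), a
#' measured charge with additive `Normal(0, charge_sigma)` error and a
#' measured m/z with multiplicative `Normal(0, mz_cv)` error; the derived
#' mass is `measured_mz * measured_charge`. Ions of the phenomenological
#' `"partial"` component — defined by the unassigned (gray) mass regions —
#' get their measured mass drawn uniformly from the gaps between adjacent
#' assignment windows, with m/z back-computed from the measured charge.
#'
#' @param mixture A [mixture_spec()]. All labels (other than `"partial"`)
#'   must appear in `mass_table`.
#' @param mass_table A [build_mass_table()] result.
#' @param sim A [sim_config()].
#' @return A `data.frame` of class `ion_events` with columns `ion_id`,
#'   `true_species`, `measured_mz`, `measured_charge`, `derived_mass`.
#' @export
#' @examples
#' ct <- construct_def("TTR-848", 848, capacity = 4700)
#' mt <- build_mass_table(enumerate_species(ct, include_empty = TRUE),
#'                        aav8_capsid_preset())
#' mx <- mixture_spec(c("empty", "1GOI-2ITR"), c(0.8, 0.2))
#' ions <- simulate_ions(mx, mt, sim_config(n_ions = 1000, seed = 1))
simulate_ions <- function(mixture, mass_table, sim) {
  stopifnot(inherits(mixture, "mixture_spec"),
            inherits(mass_table, "mass_table"),
            inherits(sim, "sim_config"))
  model_labels <- mass_table$label
  unknown <- setdiff(mixture$label, c(model_labels, "partial"))
  if (length(unknown) > 0) {
    stop("mixture species not present in mass table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(sim$seed)
  n <- sim$n_ions
  draw <- sample(mixture$label, n, replace = TRUE, prob = mixture$fraction)

  true_mass <- numeric(n)
  is_model <- draw != "partial"
  if (any(is_model)) {
    true_mass[is_model] <-
      mass_table$predicted_mass_da[match(draw[is_model], model_labels)]
  }

  z_true <- stats::rnorm(n, sim$charge_mean, sim$charge_spread)
  z_true <- pmax(z_true, 1)
  z_meas <- z_true + stats::rnorm(n, 0, sim$charge_sigma)
  mz <- (true_mass / z_true) * (1 + stats::rnorm(n, 0, sim$mz_cv))

  if (any(!is_model)) {
    # "partial" is a phenomenological component defined by the unassigned
    # (gray) mass regions between species windows, so its MEASURED masses are
    # drawn there directly; m/z is back-computed from the measured charge to
    # keep every event record self-consistent.
    gaps <- window_gaps(mass_table)
    if (nrow(gaps) == 0) {
      stop("cannot simulate 'partial' ions: species windows leave no gaps",
           call. = FALSE)
    }
    widths <- gaps[, "hi"] - gaps[, "lo"]
    k <- sum(!is_model)
    g <- sample.int(nrow(gaps), k, replace = TRUE, prob = widths)
    m_meas <- stats::runif(k, gaps[g, "lo"], gaps[g, "hi"])
    mz[!is_model] <- m_meas / z_meas[!is_model]
  }
  events <- data.frame(
    ion_id = seq_len(n),
    true_species = draw,
    measured_mz = mz,
    measured_charge = z_meas,
    derived_mass = mz * z_meas,
    stringsAsFactors = FALSE
  )
  class(events) <- c("ion_events", "data.frame")
  events
}

ion_columns <- c("ion_id", "measured_mz", "measured_charge", "derived_mass")

#' Write ion events to CSV
#'
#' Production schema is `ion_id,measured_mz,measured_charge,derived_mass`;
#' the simulation-truth column is written only on request so real-format
#' files stay free of test-only columns. Floats are written to 12 significant
#' digits.
#'
#' @param events An [simulate_ions()] table (or compatible `data.frame`).
#' @param path Output file path.
#' @param truth Also write the `true_species` column? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_ions <- function(events, path, truth = FALSE) {
  cols <- ion_columns
  if (truth && "true_species" %in% names(events)) {
    cols <- c(cols, "true_species")
  }
  out <- as.data.frame(events)[, cols, drop = FALSE]
  for (nm in c("measured_mz", "measured_charge", "derived_mass")) {
    out[[nm]] <- sprintf("%.12g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ion events from CSV
#'
#' @param path File written by [write_ions()] (truth column optional).
#' @return An `ion_events` data.frame.
#' @export
read_ions <- function(path) {
  if (!file.exists(path)) stop("ion file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, comment.char = "#")
  missing_cols <- setdiff(ion_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("ion file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- data.frame(ion_id = suppressWarnings(as.integer(raw$ion_id)),
                       stringsAsFactors = FALSE)
  if ("true_species" %in% names(raw)) events$true_species <- raw$true_species
  for (nm in c("measured_mz", "measured_charge", "derived_mass")) {
    events[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  }
  bad <- which(is.na(events$ion_id) | is.na(events$measured_mz) |
                 is.na(events$measured_charge) | is.na(events$derived_mass))
  if (length(bad) > 0) {
    stop("malformed ion record at data row ", bad[1], " of ", path,
         call. = FALSE)
  }
  class(events) <- c("ion_events", "data.frame")
  events
}

#' Estimate the empirical mass resolution of an ion dataset
#'
#' Mass resolution in the conventional sense `M / FWHM`, estimated per
#' species from the derived-mass spread of ions of known origin (simulated
#' data) and summarized as the median across species with at least
#' `min_ions` ions.
#'
#' @param events Ion events carrying a `true_species` column.
#' @param min_ions Minimum ions per species to contribute (default 50).
#' @return Median `M / (2.3548 * sd(M))` across qualifying species.
#' @export
estimate_resolution <- function(events, min_ions = 50) {
  if (!"true_species" %in% names(events)) {
    stop("resolution estimation needs the simulation-truth column",
         call. = FALSE)
  }
  keep <- events$true_species != "partial"
  sp <- split(events$derived_mass[keep], events$true_species[keep])
  sp <- sp[vapply(sp, length, integer(1)) >= min_ions]
  if (length(sp) == 0) stop("no species with enough ions", call. = FALSE)
  res <- vapply(sp, function(m) mean(m) / (2.3548 * stats::sd(m)), numeric(1))
  stats::median(res)
}
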