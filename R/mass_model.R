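#' Capsid stoichiometry model
#'
#' The AAV capsid is a T=1 icosahedron of 60 viral-protein subunits, a mix of
#' VP1, VP2 and VP3 (canonically 5:5:50). The empty-particle mass is the
#' stoichiometry-weighted sum of the subunit masses. Subunit masses are
#' required arguments: they are serotype- and construct-specific and silently
#' defaulting them would hide a ~MDa-scale assumption.
#'
#' @param vp1_mass,vp2_mass,vp3_mass Subunit masses in Da.
#' @param vp1_count,vp2_count,vp3_count Subunit copy numbers; must total 60.
#' @return An object of class `capsid_model`.
#' @seealso [aav8_capsid_preset()] for an approximate AAV8 parameterization.
#' @export
capsid_model <- function(vp1_mass, vp2_mass, vp3_mass,
                         vp1_count = 5, vp2_count = 5, vp3_count = 50) {
  vp1_mass <- check_number(vp1_mass, "vp1_mass", min = 0, strict = TRUE)
  vp2_mass <- check_number(vp2_mass, "vp2_mass", min = 0, strict = TRUE)
  vp3_mass <- check_number(vp3_mass, "vp3_mass", min = 0, strict = TRUE)
  vp1_count <- check_count(vp1_count, "vp1_count", min = 0)
  vp2_count <- check_count(vp2_count, "vp2_count", min = 0)
  vp3_count <- check_count(vp3_count, "vp3_count", min = 0)
  if (vp1_count + vp2_count + vp3_count != 60) {
    stop("capsid subunit counts must sum to 60 (T=1 icosahedral capsid)",
         call. = FALSE)
  }
  structure(
    list(vp1_mass = vp1_mass, vp2_mass = vp2_mass, vp3_mass = vp3_mass,
         vp1_count = vp1_count, vp2_count = vp2_count, vp3_count = vp3_count),
    class = "capsid_model"
  )
}

#' Approximate AAV8 capsid preset
#'
#' Sequence-based approximate AAV8 VP subunit masses at the canonical 5:5:50
#' stoichiometry, giving an empty-capsid mass of ~3.73 MDa. Approximate:
#' real preparations vary with VP processing and modification; supply measured
#' subunit masses via [capsid_model()] when available.
#'
#' @return A [capsid_model()].
#' @export
aav8_capsid_preset <- function() {
  capsid_model(vp1_mass = 81624, vp2_mass = 66648, vp3_mass = 59763)
}

#' @export
print.capsid_model <- function(x, ...) {
  cat(sprintf("capsid model: %d:%d:%d VP1:VP2:VP3, empty mass %.0f Da\n",
              x$vp1_count, x$vp2_count, x$vp3_count, capsid_mass(x)))
  invisible(x)
}

#' Empty-capsid mass
#'
#' @param capsid A [capsid_model()].
#' @return Mass in Da.
#' @export
capsid_mass <- function(capsid) {
  stopifnot(inherits(capsid, "capsid_model"))
  capsid$vp1_count * capsid$vp1_mass +
    capsid$vp2_count * capsid$vp2_mass +
    capsid$vp3_count * capsid$vp3_mass
}

#' Genome mass-model parameters
#'
#' @param avg_nt_mass Average ssDNA residue mass in Da per nucleotide
#'   (default 308.9, mean free-acid residue; sequence-dependent in reality).
#' @param counterion_factor Dimensionless multiplier `>= 1` applied to the
#'   genome mass to account for bound salt counterions. Measured packaged-DNA
#'   masses run ~4% above the bare-sequence prediction, hence the default
#'   1.04. Applied to the DNA only, never to the capsid.
#' @return An object of class `mass_model_params`.
#' @export
mass_model_params <- function(avg_nt_mass = 308.9, counterion_factor = 1.04) {
  avg_nt_mass <- check_number(avg_nt_mass, "avg_nt_mass", min = 0,
                              strict = TRUE)
  counterion_factor <- check_number(counterion_factor, "counterion_factor",
                                    min = 1)
  structure(list(avg_nt_mass = avg_nt_mass,
                 counterion_factor = counterion_factor),
            class = "mass_model_params")
}

#' Counterion-corrected ssDNA genome mass
#'
#' @param nt_length Genome length in nucleotides, `>= 0`.
#' @param params A [mass_model_params()].
#' @return Mass in Da: `nt_length * avg_nt_mass * counterion_factor`.
#' @export
genome_mass <- function(nt_length, params = mass_model_params()) {
  stopifnot(inherits(params, "mass_model_params"))
  if (!is.numeric(nt_length) || any(is.na(nt_length)) || any(nt_length < 0)) {
    stop("nt_length must be non-negative", call. = FALSE)
  }
  nt_length * params$avg_nt_mass * params$counterion_factor
}

#' Build the per-species mass table with assignment windows
#'
#' Predicts the total particle mass of every species (empty capsid included)
#' and attaches the mass window used for single-ion assignment: predicted mass
#' `+/- window_half_width` (a fraction of the predicted mass), with
#' overlapping adjacent windows clipped at the arithmetic midpoint of the two
#' predicted masses so windows never overlap.
#'
#' @param species A [enumerate_species()] table. If it lacks the empty
#'   species, the empty row is prepended.
#' @param capsid A [capsid_model()].
#' @param params A [mass_model_params()].
#' @param window_half_width Half-width of the assignment window as a fraction
#'   of predicted mass; default 0.025 separates adjacent species of a
#'   ~700-nt ladder at instrument-typical mass precision.
#' @return A `data.frame` of class `mass_table` with columns `label`,
#'   `nt_length`, `predicted_mass_da`, `window_low_da`, `window_high_da`.
#' @export
#' @examples
#' sp <- enumerate_species(construct_def("TTR-848", 848, capacity = 4700),
#'                         include_empty = TRUE)
#' build_mass_table(sp, aav8_capsid_preset(), mass_model_params())
build_mass_table <- function(species, capsid, params = mass_model_params(),
                             window_half_width = 0.025) {
  stopifnot(is.data.frame(species), inherits(capsid, "capsid_model"),
            inherits(params, "mass_model_params"))
  window_half_width <- check_number(window_half_width, "window_half_width",
                                    min = 0, strict = TRUE)
  if (!any(species$is_empty)) {
    empty <- data.frame(label = "empty", n_itr = 0L, n_goi = 0L,
                        nt_length = 0, is_empty = TRUE,
                        stringsAsFactors = FALSE)
    species <- rbind(empty, as.data.frame(species)[, names(empty)])
  }
  species <- species[order(species$nt_length), , drop = FALSE]
  cm <- capsid_mass(capsid)
  pred <- cm + genome_mass(species$nt_length, params)
  low <- pred * (1 - window_half_width)
  high <- pred * (1 + window_half_width)
  # midpoint clipping where adjacent +/- windows would overlap
  if (length(pred) > 1) {
    mid <- (pred[-length(pred)] + pred[-1]) / 2
    high[-length(pred)] <- pmin(high[-length(pred)], mid)
    low[-1] <- pmax(low[-1], mid)
  }
  tab <- data.frame(
    label = species$label,
    n_itr = species$n_itr,
    nt_length = species$nt_length,
    predicted_mass_da = pred,
    window_low_da = low,
    window_high_da = high,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "capsid_mass") <- cm
  attr(tab, "params") <- params
  attr(tab, "window_half_width") <- window_half_width
  class(tab) <- c("mass_table", "data.frame")
  tab
}

#' Write a mass table to CSV
#'
#' @param mass_table A [build_mass_table()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mass_table <- function(mass_table, path) {
  utils::write.csv(
    mass_table[, c("label", "nt_length", "predicted_mass_da",
                   "window_low_da", "window_high_da")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
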