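#' Alkaline-gel lane settings
#'
#' Parameters of the simulated densitometry lane. Migration follows the
#' standard semi-log model `position = intercept - slope * log10(nt_length)`,
#' so longer species sit at smaller position values. Position units are
#' arbitrary (the lane carries no ruler); defaults are documented constants,
#' not a calibration.
#'
#' @param mobility_intercept,mobility_slope Migration-model coefficients
#'   (defaults 100 and 55 position units).
#' @param band_sigma Gaussian band width (s.d.) in position units (default
#'   1.5; resolves adjacent bands of a ~700-nt ladder).
#' @param noise_sigma Additive per-sample noise s.d., in intensity units of a
#'   lane whose total band area is 1 (default 0.002, about 2% of a dominant
#'   band's peak height).
#' @param dx Position sampling step (default 0.05).
#' @param pad Margin beyond the outermost band centers (default 8 units).
#' @return An object of class `gel_config`.
#' @export
gel_config <- function(mobility_intercept = 100, mobility_slope = 55,
                       band_sigma = 1.5, noise_sigma = 0.002,
                       dx = 0.05, pad = 8) {
  structure(
    list(mobility_intercept = check_number(mobility_intercept,
                                           "mobility_intercept"),
         mobility_slope = check_number(mobility_slope, "mobility_slope",
                                       min = 0, strict = TRUE),
         band_sigma = check_number(band_sigma, "band_sigma", min = 0,
                                   strict = TRUE),
         noise_sigma = check_number(noise_sigma, "noise_sigma", min = 0),
         dx = check_number(dx, "dx", min = 0, strict = TRUE),
         pad = check_number(pad, "pad", min = 0, strict = TRUE)),
    class = "gel_config"
  )
}

#' Expected migration position of a fragment
#'
#' @param nt_length Fragment length(s) in nucleotides, `> 0`.
#' @param config A [gel_config()].
#' @return Position(s) in lane units; strictly decreasing in length.
#' @export
migration_position <- function(nt_length, config = gel_config()) {
  stopifnot(inherits(config, "gel_config"))
  if (any(nt_length <= 0)) stop("nt_length must be positive", call. = FALSE)
  config$mobility_intercept - config$mobility_slope * log10(nt_length)
}

#' Simulate a densitometry lane
#'
#' Builds an intensity profile as a sum of Gaussian bands centered at the
#' species' migration positions, band areas proportional to the supplied
#' mass-intensity fractions (stain binds per nucleotide, so intensity tracks
#' DNA mass, not molarity), plus additive Gaussian noise, clipped at zero.
#'
#' @param band_fractions Intensity fractions, one per species, summing to 1.
#'   May be named by species label; otherwise taken in `species` row order.
#' @param species A [enumerate_species()] table (packaged species only).
#' @param config A [gel_config()].
#' @param seed Integer RNG seed for the noise draw.
#' @return A `data.frame` of class `gel_lane` with columns `position`
#'   (strictly increasing), `intensity` (non-negative); the config and the
#'   species positions are attached as attributes.
#' @export
simulate_lane <- function(band_fractions, species, config = gel_config(),
                          seed = 1) {
  stopifnot(inherits(config, "gel_config"), is.data.frame(species))
  seed <- check_count(seed, "seed")
  sp <- species[!species$is_empty, , drop = FALSE]
  if (length(band_fractions) != nrow(sp)) {
    stop("need one band fraction per packaged species (",
         nrow(sp), "), got ", length(band_fractions), call. = FALSE)
  }
  if (!is.null(names(band_fractions))) {
    if (!setequal(names(band_fractions), sp$label)) {
      stop("band fraction names do not match the species labels",
           call. = FALSE)
    }
    band_fractions <- band_fractions[sp$label]
  }
  if (any(band_fractions < 0) || abs(sum(band_fractions) - 1) > 1e-9) {
    stop("band fractions must be non-negative and sum to 1", call. = FALSE)
  }
  centers <- migration_position(sp$nt_length, config)
  x <- seq(min(centers) - config$pad, max(centers) + config$pad,
           by = config$dx)
  signal <- rep(0, length(x))
  for (i in seq_along(centers)) {
    signal <- signal +
      band_fractions[i] * stats::dnorm(x, centers[i], config$band_sigma)
  }
  set.seed(seed)
  intensity <- pmax(signal + stats::rnorm(length(x), 0, config$noise_sigma), 0)
  lane <- data.frame(position = x, intensity = intensity)
  attr(lane, "config") <- config
  attr(lane, "band_centers") <- stats::setNames(centers, sp$label)
  class(lane) <- c("gel_lane", "data.frame")
  lane
}

#' Quantify band intensities from a lane profile
#'
#' Baseline-subtracted integration of the intensity in a window around each
#' species' expected migration position. The baseline is the median of the
#' off-window signal (robust, parameter-free); overlapping windows are
#' clipped at the midpoint between expected positions, with a warning.
#' Errors if no band rises convincingly above the noise floor.
#'
#' @param lane A [simulate_lane()] profile (or any `data.frame` with
#'   `position`, `intensity`).
#' @param species A [enumerate_species()] table (packaged species only).
#' @param config A [gel_config()]; defaults to the lane's own config when it
#'   carries one.
#' @param window_half_width Integration half-window in position units
#'   (default `2 * band_sigma`).
#' @return A `data.frame` of class `band_quant`: `label`, `position`,
#'   `integral`, `intensity_fraction` (fractions sum to 1).
#' @export
quantify_bands <- function(lane, species, config = NULL,
                           window_half_width = NULL) {
  if (is.null(config)) config <- attr(lane, "config")
  if (is.null(config)) config <- gel_config()
  stopifnot(inherits(config, "gel_config"), is.data.frame(species))
  if (is.null(window_half_width)) window_half_width <- 2 * config$band_sigma
  window_half_width <- check_number(window_half_width, "window_half_width",
                                    min = 0, strict = TRUE)
  sp <- species[!species$is_empty, , drop = FALSE]
  if (nrow(sp) == 0) stop("no species to quantify", call. = FALSE)
  centers <- migration_position(sp$nt_length, config)
  ord <- order(centers)
  lo <- centers - window_half_width
  hi <- centers + window_half_width
  # clip overlapping windows at midpoints between adjacent expected positions
  cs <- centers[ord]
  if (length(cs) > 1) {
    mid <- (cs[-length(cs)] + cs[-1]) / 2
    overlap <- hi[ord][-length(cs)] > lo[ord][-1]
    if (any(overlap)) {
      warning("overlapping band windows clipped at position midpoints")
      hi[ord[-length(cs)]] <- pmin(hi[ord[-length(cs)]], mid)
      lo[ord[-1]] <- pmax(lo[ord[-1]], mid)
    }
  }
  x <- lane$position
  y <- lane$intensity
  dx <- stats::median(diff(x))
  in_any <- rep(FALSE, length(x))
  for (i in seq_along(centers)) in_any <- in_any | (x >= lo[i] & x <= hi[i])
  off <- y[!in_any]
  baseline <- if (length(off) > 0) stats::median(off) else 0
  # mean positive-part off-window signal: robust noise floor under the
  # non-negativity clipping (MAD collapses to zero there)
  noise_floor <- if (length(off) > 0) mean(pmax(off - baseline, 0)) else 0

  integral <- band_mean <- numeric(length(centers))
  for (i in seq_along(centers)) {
    w <- x >= lo[i] & x <= hi[i]
    integral[i] <- sum(pmax(y[w] - baseline, 0)) * dx
    band_mean[i] <- if (any(w)) integral[i] / ((hi[i] - lo[i])) else 0
  }
  if (sum(integral) <= 0 || all(band_mean <= 5 * noise_floor)) {
    stop("no bands detected above the noise floor", call. = FALSE)
  }
  out <- data.frame(label = sp$label, position = centers,
                    integral = integral,
                    intensity_fraction = integral / sum(integral),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("band_quant", "data.frame")
  out
}

#' Convert mass-intensity band fractions to molar fractions
#'
#' Stain intensity scales with DNA mass, so equal molar amounts of species
#' with different lengths give unequal band intensities. Dividing each band
#' integral by its fragment length and renormalizing yields molar fractions:
#' `molar_i = (intensity_i / length_i) / sum_j (intensity_j / length_j)`.
#' Off by default throughout the pipeline because standard gel percentages
#' are raw-intensity shares.
#'
#' @param band_quant A [quantify_bands()] result (or any `data.frame` with
#'   `label` and `integral` or `intensity_fraction`).
#' @param lengths Fragment lengths in nucleotides, one per band, `> 0`; may
#'   be named by label.
#' @return `band_quant` with a `molar_fraction` column appended.
#' @export
#' @examples
#' bq <- data.frame(label = c("a", "b"), integral = c(10, 20))
#' molar_correct(bq, c(a = 1000, b = 2000))  # equal molar amounts
molar_correct <- function(band_quant, lengths) {
  stopifnot(is.data.frame(band_quant))
  if (length(lengths) != nrow(band_quant)) {
    stop("need one length per band", call. = FALSE)
  }
  if (!is.null(names(lengths))) lengths <- lengths[band_quant$label]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("fragment lengths must be positive", call. = FALSE)
  }
  w <- if ("integral" %in% names(band_quant)) band_quant$integral
       else band_quant$intensity_fraction
  molar <- (w / lengths) / sum(w / lengths)
  band_quant$molar_fraction <- molar
  band_quant
}

#' Write a lane or band quantification to CSV
#'
#' @param x A `gel_lane` or `band_quant` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gel <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
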