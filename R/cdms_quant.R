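#' Bin ion masses into a display spectrum
#'
#' Histogram of derived single-ion masses, spanning the observed mass range
#' padded by one bin on each side. Binning is for display and reporting only;
#' species assignment ([assign_ions()]) always uses the raw per-ion masses.
#'
#' @param events Ion events with a `derived_mass` column; at least one row.
#' @param bin_width Bin width in Da (default 10 kDa).
#' @return An object of class `mass_spectrum`: list with `edges` (length
#'   `n_bins + 1`, strictly increasing), `counts`, `bin_width`. Bins are
#'   left-closed, right-open.
#' @export
build_spectrum <- function(events, bin_width = 1e4) {
  bin_width <- check_number(bin_width, "bin_width", min = 0, strict = TRUE)
  m <- events$derived_mass
  if (is.null(m) || length(m) == 0) {
    stop("cannot build a spectrum from zero ions", call. = FALSE)
  }
  lo <- floor(min(m) / bin_width) * bin_width - bin_width
  hi <- max(m) + bin_width
  edges <- seq(lo, hi + bin_width, by = bin_width)
  idx <- findInterval(m, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, counts = counts, bin_width = bin_width),
            class = "mass_spectrum")
}

#' Write a spectrum to CSV
#'
#' @param spectrum A [build_spectrum()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  n <- length(spectrum$counts)
  utils::write.csv(
    data.frame(bin_low = spectrum$edges[seq_len(n)],
               bin_high = spectrum$edges[seq_len(n) + 1L],
               count = spectrum$counts),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign ions to species mass windows and quantify subpopulations
#'
#' Each ion is assigned to the species whose assignment window contains its
#' derived mass; windows are non-overlapping (midpoint-clipped), and an ion
#' falling exactly on a shared boundary goes to the lower-mass species.
#' Ions below half the empty-capsid mass, above the top window's high edge
#' plus 10%, or in a gap between windows are counted as
#' unassigned ("partials") — never silently dropped. Relative abundance is
#' ion count over total ions, so abundances including the unassigned row sum
#' to 1.
#'
#' @param events Ion events (from [simulate_ions()] or [read_ions()]).
#' @param mass_table A [build_mass_table()] result.
#' @return A `data.frame` of class `subpop_quant` with one row per species in
#'   ascending mass order plus a final `"unassigned"` row; columns `label`,
#'   `ion_count`, `rel_abundance`. The per-ion assignment vector is attached
#'   as attribute `"assignment"` (`NA` for unassigned) and the total as
#'   `"total_ions"`.
#' @export
assign_ions <- function(events, mass_table) {
  if (!inherits(mass_table, "mass_table") || nrow(mass_table) == 0) {
    stop("a non-empty mass table is required for assignment", call. = FALSE)
  }
  m <- events$derived_mass
  n <- length(m)
  if (n == 0) stop("no ions to assign", call. = FALSE)
  tab <- mass_table[order(mass_table$predicted_mass_da), , drop = FALSE]
  cm <- attr(mass_table, "capsid_mass")
  if (is.null(cm)) cm <- min(tab$predicted_mass_da)
  floor_mass <- 0.5 * cm
  ceiling_mass <- tab$window_high_da[nrow(tab)] * 1.1

  assigned <- rep(NA_character_, n)
  in_range <- m >= floor_mass & m <= ceiling_mass
  for (i in seq_len(nrow(tab))) {  # ascending order => boundary ties go low
    hit <- is.na(assigned) & in_range &
      m >= tab$window_low_da[i] & m <= tab$window_high_da[i]
    assigned[hit] <- tab$label[i]
  }
  counts <- vapply(tab$label, function(l) sum(assigned == l, na.rm = TRUE),
                   integer(1))
  unassigned <- n - sum(counts)
  quant <- data.frame(
    label = c(tab$label, "unassigned"),
    ion_count = as.integer(c(counts, unassigned)),
    rel_abundance = c(counts, unassigned) / n,
    stringsAsFactors = FALSE
  )
  rownames(quant) <- NULL
  attr(quant, "assignment") <- assigned
  attr(quant, "total_ions") <- n
  class(quant) <- c("subpop_quant", "data.frame")
  quant
}

#' @export
print.subpop_quant <- function(x, ...) {
  cat("CD-MS subpopulation quantification (", attr(x, "total_ions"),
      " ions)\n", sep = "")
  out <- as.data.frame(x)
  out$rel_abundance <- format_mixed_pct(out$rel_abundance)
  print(out, row.names = FALSE)
  invisible(x)
}

# the reporting convention used for abundances: one decimal, except
# sub-percent entries which get two
format_mixed_pct <- function(frac) {
  pct <- 100 * frac
  ifelse(pct < 1, sprintf("%.2f%%", pct), sprintf("%.1f%%", pct))
}

#' Per-species charge statistics and elevated-charge screen
#'
#' Incompletely packaged DNA trailing outside the capsid raises the ion
#' charge; a filled species whose mean measured charge significantly exceeds
#' the empty-capsid mean is therefore flagged. "Significantly" means the
#' mean difference exceeds `threshold` combined standard errors
#' (one-sided; default 3).
#'
#' @param events The ion events that were assigned.
#' @param quant The matching [assign_ions()] result (its `"assignment"`
#'   attribute is used).
#' @param threshold Flagging threshold in combined standard errors.
#' @return A `data.frame` of class `charge_summary`: `label`, `n_ions`,
#'   `mean_charge`, `sd_charge`, `flagged`. Species with zero ions get `NA`
#'   means and are never flagged.
#' @export
charge_summary <- function(events, quant, threshold = 3) {
  stopifnot(inherits(quant, "subpop_quant"))
  threshold <- check_number(threshold, "threshold", min = 0)
  assigned <- attr(quant, "assignment")
  if (is.null(assigned) || length(assigned) != nrow(events)) {
    stop("quant does not carry an assignment for these events", call. = FALSE)
  }
  labels <- setdiff(quant$label, "unassigned")
  stat <- lapply(labels, function(l) {
    z <- events$measured_charge[!is.na(assigned) & assigned == l]
    if (length(z) == 0) {
      c(n = 0, mean = NA_real_, sd = NA_real_)
    } else {
      c(n = length(z), mean = mean(z),
        sd = if (length(z) > 1) stats::sd(z) else NA_real_)
    }
  })
  n <- vapply(stat, `[[`, numeric(1), "n")
  mu <- vapply(stat, `[[`, numeric(1), "mean")
  sdv <- vapply(stat, `[[`, numeric(1), "sd")
  se <- sdv / sqrt(pmax(n, 1))

  flagged <- rep(FALSE, length(labels))
  i_empty <- which(labels == "empty")
  if (length(i_empty) == 1 && n[i_empty] > 1) {
    for (i in seq_along(labels)) {
      if (i == i_empty || n[i] < 2) next
      se_diff <- sqrt(se[i]^2 + se[i_empty]^2)
      flagged[i] <- (mu[i] - mu[i_empty]) > threshold * se_diff
    }
  } else if (length(labels) > 1) {
    warning("no empty-capsid reference ions; elevated-charge screen skipped")
  }
  out <- data.frame(label = labels, n_ions = as.integer(n), mean_charge = mu,
                    sd_charge = sdv, flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("charge_summary", "data.frame")
  out
}

#' Write a subpopulation quantification to CSV
#'
#' @param quant An [assign_ions()] result.
#' @param path Output file path.
#' @param charges Optional matching [charge_summary()] to merge in.
#' @return `path`, invisibly.
#' @export
write_quant <- function(quant, path, charges = NULL) {
  out <- as.data.frame(quant)
  if (!is.null(charges)) {
    out <- merge(out, as.data.frame(charges)[, c("label", "mean_charge",
                                                 "sd_charge", "flagged")],
                 by = "label", all.x = TRUE, sort = FALSE)
    out <- out[match(quant$label, out$label), , drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
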