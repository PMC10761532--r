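#' Per-ITR termination probabilities from packaged-species abundances
#'
#' Packaging starts at the origin ITR and may stop at any downstream ITR; the
#' species with `N` ITRs is the one that terminated at sequential ITR
#' `k = N - 1`. Normalizing the packaged-species abundances (empty capsids
#' and unassigned/partial ions excluded by the caller) over their own total
#' gives the probability that packaging terminated at each sequential ITR.
#' Scale-invariant: counts, fractions or percentages all give the same
#' profile.
#'
#' @param abundances Numeric vector of packaged-species abundances in
#'   ascending species order (first entry = 1GOI-2ITR); all `>= 0`, positive
#'   total.
#' @param source Label for provenance: `"cdms"` or `"gel"`.
#' @param construct Optional construct name carried on the result.
#' @return An object of class `termination_profile`: named numeric vector of
#'   probabilities (`ITR1`, `ITR2`, ...) summing to 1. If `abundances` are
#'   whole-number counts, multinomial standard errors are attached as
#'   attribute `"se"`.
#' @export
#' @examples
#' termination_profile(c(2.8, 2.96, 2.36, 1.68, 0.54, 0.19))
termination_profile <- function(abundances, source = c("cdms", "gel"),
                                construct = NULL) {
  source <- match.arg(source)
  if (!is.numeric(abundances) || length(abundances) == 0 ||
      any(is.na(abundances)) || any(abundances < 0)) {
    stop("abundances must be non-negative numbers", call. = FALSE)
  }
  total <- sum(abundances)
  if (total <= 0) {
    stop("undefined termination profile: all abundances are zero",
         call. = FALSE)
  }
  p <- abundances / total
  names(p) <- paste0("ITR", seq_along(p))
  se <- NULL
  if (all(abs(abundances - round(abundances)) < 1e-9) && total > 1) {
    se <- sqrt(p * (1 - p) / total)  # multinomial standard errors from counts
  }
  structure(p, source = source, construct = construct, se = se,
            class = "termination_profile")
}

#' @export
print.termination_profile <- function(x, ...) {
  cat(sprintf("termination profile (%s%s), K = %d ITRs\n",
              attr(x, "source"),
              if (is.null(attr(x, "construct"))) ""
              else paste0(", ", attr(x, "construct")),
              length(x)))
  line <- paste(sprintf("%s %s", names(x), format_mixed_pct(unclass(x))),
                collapse = "  ")
  cat(" ", line, "\n")
  invisible(x)
}

#' Termination profile from a CD-MS subpopulation quantification
#'
#' Drops the empty and unassigned rows of an [assign_ions()] result and
#' normalizes the packaged-species ion counts into a termination profile.
#'
#' @param quant An [assign_ions()] result.
#' @param construct Optional construct name carried on the result.
#' @return A [termination_profile()].
#' @export
profile_from_quant <- function(quant, construct = NULL) {
  stopifnot(inherits(quant, "subpop_quant"))
  keep <- !(quant$label %in% c("empty", "unassigned"))
  termination_profile(quant$ion_count[keep], source = "cdms",
                      construct = construct)
}

#' Termination profile from gel band quantification
#'
#' @param band_quant A [quantify_bands()] result.
#' @param molar Use molar-corrected fractions (requires a `molar_fraction`
#'   column)? Default `FALSE`: raw intensity shares, the standard gel
#'   normalization.
#' @param construct Optional construct name carried on the result.
#' @return A [termination_profile()].
#' @export
profile_from_bands <- function(band_quant, molar = FALSE, construct = NULL) {
  stopifnot(is.data.frame(band_quant))
  a <- if (molar) {
    if (is.null(band_quant$molar_fraction)) {
      stop("no molar_fraction column; run molar_correct() first",
           call. = FALSE)
    }
    band_quant$molar_fraction
  } else {
    band_quant$intensity_fraction
  }
  termination_profile(a, source = "gel", construct = construct)
}

#' Ratio between two termination-profile entries
#'
#' Normalization cancels, so the ratio of profile entries equals the ratio of
#' the underlying raw abundances.
#'
#' @param profile A [termination_profile()] or raw abundance vector.
#' @param k1,k2 Sequential ITR indices (numerator, denominator).
#' @return `p[k1] / p[k2]`.
#' @export
#' @examples
#' abundance_ratio(c(30.6, 53.3, 15.7, 0.45), 2, 1)  # ~1.74
abundance_ratio <- function(profile, k1, k2) {
  k1 <- check_count(k1, "k1", min = 1)
  k2 <- check_count(k2, "k2", min = 1)
  p <- as.numeric(profile)
  if (k1 > length(p) || k2 > length(p)) {
    stop("ITR index out of range", call. = FALSE)
  }
  if (p[k2] <= 0) stop("undefined ratio: denominator entry is zero",
                       call. = FALSE)
  p[k1] / p[k2]
}

#' Compare two termination profiles
#'
#' @param p,q [termination_profile()]s (or probability vectors) over the same
#'   construct, same number of ITRs.
#' @return An object of class `profile_comparison`: list with `per_itr`
#'   (absolute differences) and `tv` (total variation distance,
#'   `0.5 * sum(|p - q|)`, in `[0, 1]`).
#' @export
compare_profiles <- function(p, q) {
  pv <- as.numeric(p) / sum(as.numeric(p))
  qv <- as.numeric(q) / sum(as.numeric(q))
  if (length(pv) != length(qv)) {
    stop("profiles have different numbers of ITRs (", length(pv), " vs ",
         length(qv), ")", call. = FALSE)
  }
  d <- abs(pv - qv)
  names(d) <- paste0("ITR", seq_along(d))
  structure(list(per_itr = d, tv = sum(d) / 2), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("profile comparison: total variation distance %.3f\n", x$tv))
  print(round(x$per_itr, 4))
  invisible(x)
}

#' Fold change between two fractions
#'
#' Convenience for cross-system comparisons (e.g. suspension vs adherent
#' empty-particle fractions).
#'
#' @param a,b Fractions; `b > 0`.
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  a <- check_number(a, "a")
  b <- check_number(b, "b")
  if (b <= 0) stop("undefined fold change: denominator is zero or negative",
                   call. = FALSE)
  a / b
}

#' Write a termination profile (and optional comparison) to CSV
#'
#' @param profile A [termination_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(itr = seq_along(profile),
                    probability = as.numeric(profile),
                    stringsAsFactors = FALSE)
  se <- attr(profile, "se")
  if (!is.null(se)) out$se <- as.numeric(se)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
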