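#' Bundled demonstration constructs
#'
#' The four FVIII-derived truncation constructs used throughout the examples
#' and tests: unit genomes of 848, 1,320, 2,981 and 4,707 nt (ITR to ITR).
#' The 848 construct carries capacity 4,700 nt and the others 5,200 nt; these
#' are the cutoffs under which the observed ladders contain six and four
#' species respectively (the effective cutoff is preparation-dependent, so it
#' is per-construct configuration, not physics).
#'
#' @param name One of `"ttr848"`, `"ttr1320"`, `"ttr2981"`, `"ttr4707"`.
#' @return A [construct_def()].
#' @export
#' @examples
#' enumerate_species(construct_preset("ttr848"))
construct_preset <- function(name = c("ttr848", "ttr1320", "ttr2981",
                                      "ttr4707")) {
  name <- match.arg(name)
  switch(name,
    ttr848 = construct_def("TTR-848", 848, capacity = 4700),
    ttr1320 = construct_def("TTR-1320", 1320, capacity = 5200),
    ttr2981 = construct_def("TTR-2981", 2981, capacity = 5200),
    ttr4707 = construct_def("TTR-4707", 4707, capacity = 5200)
  )
}

#' Reference subpopulation abundances and termination profiles
#'
#' Published-style reference values for the demonstration constructs, used as
#' simulation ground truth and in regression tests. Available sets:
#'
#' * `"ttr848_suspension_cdms"`: the seven CD-MS subpopulation abundances
#'   (fractions of all ions) for the 848 construct from suspension-cell
#'   production — empty capsid then the six multimer species. They sum to
#'   0.9033; the remainder is the unassigned "partial" population, which
#'   [mixture_spec()] restores automatically.
#' * `"ttr848_gel_profile"`: the six gel band intensity fractions (percent of
#'   total band intensity) for the same construct.
#' * `"ttr1320_cdms_profile"`: the four-entry CD-MS termination profile (%)
#'   for the 1,320 construct.
#' * `"ttr1320_gel_profile"`: the four-entry gel termination profile (%).
#'
#' @param name Reference set name.
#' @return For `"ttr848_suspension_cdms"`, a `data.frame` with `label` and
#'   `fraction`; for profiles, a numeric vector of percentages in sequential
#'   ITR order.
#' @export
reference_abundances <- function(name = c("ttr848_suspension_cdms",
                                          "ttr848_gel_profile",
                                          "ttr1320_cdms_profile",
                                          "ttr1320_gel_profile")) {
  name <- match.arg(name)
  switch(name,
    ttr848_suspension_cdms = data.frame(
      label = c("empty", species_label(2:7)),
      fraction = c(0.798, 0.028, 0.0296, 0.0236, 0.0168, 0.0054, 0.0019),
      stringsAsFactors = FALSE),
    ttr848_gel_profile = c(5.2, 35.4, 24.1, 25.6, 6.2, 3.6),
    ttr1320_cdms_profile = c(30.6, 53.3, 15.7, 0.45),
    ttr1320_gel_profile = c(14.3, 45.2, 25.5, 14.9)
  )
}
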