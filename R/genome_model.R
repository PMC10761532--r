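#' Define an rAAV construct
#'
#' A construct is the unit vector genome: one gene-of-interest (GOI) cassette
#' flanked by two inverted terminal repeats (ITRs). Multimer genome species
#' arise when packaging of a replication intermediate runs through one or more
#' downstream ITRs before terminating, so every species is fully determined by
#' the unit length, the per-junction ITR contribution `I`, and the capsid
#' capacity.
#'
#' @param name Text label for the construct (e.g. `"TTR-848"`).
#' @param unit_length Length in nucleotides of the complete 1GOI-2ITR genome,
#'   ITR to ITR inclusive.
#' @param itr_junction_length Nucleotides contributed by each ITR position in a
#'   multimer (`I`). The default 130 nt is the effective junction length fixed
#'   by observed multimer ladders (848 -> 1,566 and 1,320 -> 2,510 both imply
#'   `I = 130`), slightly below the 145 nt of a complete ITR.
#' @param capacity Maximum packageable length in nucleotides (default 5,200,
#'   the commonly cited rAAV limit).
#'
#' @return An object of class `construct_def`.
#' @seealso [species_length()], [enumerate_species()], [construct_preset()]
#' @export
#' @examples
#' construct_def("TTR-848", unit_length = 848, capacity = 4700)
construct_def <- function(name, unit_length, itr_junction_length = 130,
                          capacity = 5200) {
  stopifnot(is.character(name), length(name) == 1L)
  unit_length <- check_count(unit_length, "unit_length", min = 1)
  itr_junction_length <- check_count(itr_junction_length,
                                     "itr_junction_length", min = 1)
  capacity <- check_count(capacity, "capacity", min = 1)
  if (unit_length <= 2 * itr_junction_length) {
    stop("invalid construct: unit_length must exceed 2 * itr_junction_length ",
         "(internal segment G = unit_length - 2I must be positive)",
         call. = FALSE)
  }
  if (capacity < unit_length) {
    stop("invalid construct: capacity must be at least unit_length",
         call. = FALSE)
  }
  structure(
    list(name = name,
         unit_length = unit_length,
         itr_junction_length = itr_junction_length,
         capacity = capacity),
    class = "construct_def"
  )
}

#' @export
print.construct_def <- function(x, ...) {
  g <- x$unit_length - 2L * x$itr_junction_length
  cat(sprintf("rAAV construct '%s': unit %d nt (I = %d, G = %d), capacity %d nt\n",
              x$name, x$unit_length, x$itr_junction_length, g, x$capacity))
  invisible(x)
}

#' Predicted length of a multimer genome species
#'
#' Length of the packaged ssDNA species with `n_itr` ITR junctions under the
#' replication-intermediate model: `L = N * I + (N - 1) * G`, where `N` is the
#' ITR count, `I` the per-junction ITR length, and `G = unit_length - 2 * I`
#' the internal gene segment. A species with `N` ITRs carries `N - 1` GOI
#' copies; `N = 1` is the degenerate single-ITR case of length `I`.
#'
#' @param n_itr Integer ITR count, `>= 1`.
#' @param construct A [construct_def()].
#' @return Integer nucleotide length.
#' @export
#' @examples
#' ttr848 <- construct_def("TTR-848", 848, capacity = 4700)
#' species_length(2, ttr848)  # 848, the unit genome
#' species_length(7, ttr848)  # 4438, the 6GOI-7ITR hexamer
species_length <- function(n_itr, construct) {
  stopifnot(inherits(construct, "construct_def"))
  n_itr <- check_count(n_itr, "n_itr", min = 1)
  i <- construct$itr_junction_length
  g <- construct$unit_length - 2L * i
  n_itr * i + (n_itr - 1L) * g
}

#' Canonical label of a multimer species
#'
#' @param n_itr Integer ITR count(s); 0 gives `"empty"`.
#' @return Character vector like `"2GOI-3ITR"`.
#' @export
species_label <- function(n_itr) {
  ifelse(n_itr == 0L, "empty", sprintf("%dGOI-%dITR", n_itr - 1L, n_itr))
}

#' Enumerate the packageable multimer species of a construct
#'
#' Lists every genome species with `n_itr >= 2` whose predicted length fits
#' the capsid capacity, in ascending length order. With
#' `include_empty = TRUE`, the empty-capsid pseudo-species (0 nt) is prepended
#' as the first row, giving the full particle model used for mass-table
#' construction.
#'
#' @param construct A [construct_def()].
#' @param include_empty Prepend the empty (genome-free) species? Default
#'   `FALSE`.
#' @return A `data.frame` of class `species_table` with columns `label`,
#'   `n_itr`, `n_goi`, `nt_length`, `is_empty`.
#' @export
#' @examples
#' enumerate_species(construct_def("TTR-1320", 1320, capacity = 5200))
enumerate_species <- function(construct, include_empty = FALSE) {
  stopifnot(inherits(construct, "construct_def"))
  n_max <- 50L  # termination guard for degenerate tiny constructs
  n <- 2:n_max
  len <- vapply(n, species_length, numeric(1), construct = construct)
  keep <- len <= construct$capacity
  n <- n[keep]
  len <- len[keep]
  tab <- data.frame(
    label = species_label(n),
    n_itr = as.integer(n),
    n_goi = as.integer(n - 1L),
    nt_length = as.numeric(len),
    is_empty = rep(FALSE, length(n)),
    stringsAsFactors = FALSE
  )
  if (include_empty) {
    empty <- data.frame(label = "empty", n_itr = 0L, n_goi = 0L,
                        nt_length = 0, is_empty = TRUE,
                        stringsAsFactors = FALSE)
    tab <- rbind(empty, tab)
  }
  rownames(tab) <- NULL
  attr(tab, "construct") <- construct
  class(tab) <- c("species_table", "data.frame")
  tab
}

#' Collapse a multimer species into unit-scale restriction fragments
#'
#' Models the restriction-digest check that multimer bands are concatemers of
#' unit genomes: a single cut at the midpoint of each internal ITR junction
#' collapses the species with `N` ITRs into `N - 1 = n_goi` fragments, each of
#' unit-scale length (interior fragments `G + I`; the two terminal fragments
#' additionally carry the uncut half-ITRs). Fragment lengths always sum to the
#' species length.
#'
#' @param species A single species: either one row of a
#'   [enumerate_species()] table, a species label such as `"3GOI-4ITR"`, or an
#'   integer ITR count.
#' @param construct The [construct_def()] the species belongs to.
#' @return Integer vector of `n_goi` fragment lengths (nt).
#' @export
#' @examples
#' ttr848 <- construct_def("TTR-848", 848, capacity = 4700)
#' digest_to_units("3GOI-4ITR", ttr848)
digest_to_units <- function(species, construct) {
  stopifnot(inherits(construct, "construct_def"))
  n_itr <- resolve_n_itr(species)
  if (n_itr == 0L) {
    stop("cannot digest the empty species: it has no genome", call. = FALSE)
  }
  if (n_itr < 2L) {
    stop("species must have at least 2 ITRs", call. = FALSE)
  }
  i <- construct$itr_junction_length
  g <- construct$unit_length - 2L * i
  total <- species_length(n_itr, construct)
  if (n_itr == 2L) return(total)
  # cut positions: midpoint of each internal ITR (internal ITR k starts at
  # k * (I + G) nucleotides from the 5' end)
  k <- seq_len(n_itr - 2L)
  cuts <- round(k * (i + g) + i / 2)
  diff(c(0, cuts, total))
}

resolve_n_itr <- function(species) {
  if (is.data.frame(species)) {
    if (nrow(species) != 1L) {
      stop("species must be a single row", call. = FALSE)
    }
    return(as.integer(species$n_itr))
  }
  if (is.character(species)) {
    if (identical(species, "empty")) return(0L)
    m <- regmatches(species, regexec("^([0-9]+)GOI-([0-9]+)ITR$", species))[[1]]
    if (length(m) != 3L) {
      stop("unrecognized species label: ", species, call. = FALSE)
    }
    return(as.integer(m[3]))
  }
  as.integer(check_count(species, "species (n_itr)", min = 0))
}

#' Fit a construct from its first two observed multimer lengths
#'
#' Solves the species-length model for `I` and `G` given the monomer
#' (`2I + G`) and dimer (`3I + 2G`) lengths of an observed ladder:
#' `I = 2 * l_monomer - l_dimer`.
#'
#' @param l_monomer Length (nt) of the 1GOI-2ITR species.
#' @param l_dimer Length (nt) of the 2GOI-3ITR species.
#' @param name,capacity Passed to [construct_def()].
#' @return A [construct_def()].
#' @export
#' @examples
#' fit_construct(848, 1566, capacity = 4700)   # recovers I = 130
fit_construct <- function(l_monomer, l_dimer, name = "fitted",
                          capacity = 5200) {
  l_monomer <- check_count(l_monomer, "l_monomer", min = 1)
  l_dimer <- check_count(l_dimer, "l_dimer", min = 1)
  i <- 2 * l_monomer - l_dimer
  if (i <= 0) {
    stop("inconsistent ladder: implied ITR length is not positive",
         call. = FALSE)
  }
  construct_def(name, unit_length = l_monomer, itr_junction_length = i,
                capacity = capacity)
}

#' Write a species table to CSV
#'
#' @param species A [enumerate_species()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_species <- function(species, path) {
  utils::write.csv(species[, c("label", "n_itr", "n_goi", "nt_length")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
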