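#' Read and validate a run configuration
#'
#' The configuration is a single JSON mapping holding every stage parameter:
#' construct, capsid, mass-model, CD-MS simulation/quantification and gel
#' settings, plus the output directory. Validated against the expected schema
#' at load; round-trips unchanged through [write_run_config()].
#'
#' @param path Path to a JSON config file.
#' @return An object of class `run_config` (a named list).
#' @seealso [demo_config_path()] for a complete example.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
  attr(cfg, "fingerprint") <- config_fingerprint(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_config <- function(config) {
  config <- unclass(config)
  attr(config, "fingerprint") <- NULL
  config
}

config_fingerprint <- function(config) {
  fnv1a32(jsonlite::toJSON(unclass_config(config), auto_unbox = TRUE,
                           digits = NA))
}

validate_run_config <- function(cfg) {
  need <- function(block, fields) {
    if (is.null(cfg[[block]])) {
      stop("config is missing the '", block, "' block", call. = FALSE)
    }
    miss <- setdiff(fields, names(cfg[[block]]))
    if (length(miss) > 0) {
      stop("config block '", block, "' is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need("construct", c("name", "unit_length"))
  need("capsid", c("vp1_mass", "vp2_mass", "vp3_mass"))
  if (!is.null(cfg$cdms)) {
    need("cdms", "seed")
    if (is.null(cfg$cdms$ions_file)) need("cdms", "mixture")
  }
  if (!is.null(cfg$gel)) {
    if (is.null(cfg$gel$lane_file)) need("gel", c("band_fractions", "seed"))
  }
  if (is.null(cfg$cdms) && is.null(cfg$gel)) {
    stop("config must define at least one of 'cdms' or 'gel'", call. = FALSE)
  }
  invisible(cfg)
}

config_construct <- function(cfg) {
  c_ <- cfg$construct
  construct_def(c_$name, c_$unit_length,
                itr_junction_length = c_$itr_junction_length %||% 130,
                capacity = c_$capacity %||% 5200)
}

config_capsid <- function(cfg) {
  k <- cfg$capsid
  capsid_model(k$vp1_mass, k$vp2_mass, k$vp3_mass,
               vp1_count = k$vp1_count %||% 5,
               vp2_count = k$vp2_count %||% 5,
               vp3_count = k$vp3_count %||% 50)
}

config_mass_params <- function(cfg) {
  p <- cfg$mass_params
  mass_model_params(avg_nt_mass = p$avg_nt_mass %||% 308.9,
                    counterion_factor = p$counterion_factor %||% 1.04)
}

config_sim <- function(cfg, seed_override = NULL) {
  s <- cfg$cdms
  sim_config(n_ions = s$n_ions %||% 10000,
             charge_mean = s$charge_mean %||% 155,
             charge_sigma = s$charge_sigma %||% 1.0,
             mz_cv = s$mz_cv %||% 0.002,
             charge_spread = s$charge_spread %||% 3,
             seed = seed_override %||% s$seed,
             mode = s$mode)
}

config_gel <- function(cfg) {
  g <- cfg$gel %||% list()
  gel_config(mobility_intercept = g$mobility_intercept %||% 100,
             mobility_slope = g$mobility_slope %||% 55,
             band_sigma = g$band_sigma %||% 1.5,
             noise_sigma = g$noise_sigma %||% 0.002,
             dx = g$dx %||% 0.05,
             pad = g$pad %||% 8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stage CSV with a provenance comment line; read back with comment.char = "#"
write_stage_csv <- function(df, path, fingerprint, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# aavterm config=%s seed=%s", fingerprint,
                     ifelse(is.na(seed), "-", format(seed))), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, per the configuration: species enumeration, mass-table
#' construction, CD-MS arm (simulate or load ions, build spectrum, assign,
#' charge screen, termination profile), gel arm (simulate or load lane, band
#' quantification, optional molar correction, termination profile), and —
#' when both arms yield profiles of equal length — their comparison. All
#' stage tables are written as CSV under `out_dir`, each headed by a comment
#' recording the config fingerprint and stage seed, plus a plain-text
#' summary. Identical config + seeds give identical outputs.
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory; default the config's `output_dir`.
#' @param verbose Emit per-stage log messages? Default `TRUE`.
#' @return An object of class `run_report` (named list of all stage results),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  fp <- attr(config, "fingerprint") %||% config_fingerprint(config)
  out_dir <- out_dir %||% config$output_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- "construct"
  report <- list(fingerprint = fp)
  tryCatch({
    construct <- config_construct(config)
    if (construct$itr_junction_length != 145) {
      log_stage(verbose, stage,
                "ITR junction length %d nt differs from the 145 nt of a complete ITR (effective junction length)",
                construct$itr_junction_length)
    }
    stage <- "predict-species"
    species <- enumerate_species(construct, include_empty = TRUE)
    packaged <- species[!species$is_empty, , drop = FALSE]
    log_stage(verbose, stage, "%d packageable species for %s (capacity %d nt)",
              nrow(packaged), construct$name, construct$capacity)
    write_stage_csv(species[, c("label", "n_itr", "n_goi", "nt_length")],
                    file.path(out_dir, "species.csv"), fp)
    report$construct <- construct
    report$species <- species

    stage <- "mass-table"
    capsid <- config_capsid(config)
    params <- config_mass_params(config)
    whw <- config$mass_params$window_half_width %||% 0.025
    mass_table <- build_mass_table(species, capsid, params,
                                   window_half_width = whw)
    write_stage_csv(as.data.frame(mass_table),
                    file.path(out_dir, "mass_table.csv"), fp)
    report$mass_table <- mass_table

    if (!is.null(config$cdms)) {
      report$cdms <- run_cdms_arm(config, construct, mass_table, out_dir, fp,
                                  verbose)
    }
    if (!is.null(config$gel)) {
      report$gel <- run_gel_arm(config, construct, packaged, out_dir, fp,
                                verbose)
    }
    stage <- "compare"
    if (!is.null(report$cdms$profile) && !is.null(report$gel$profile) &&
        length(report$cdms$profile) == length(report$gel$profile)) {
      report$comparison <- compare_profiles(report$cdms$profile,
                                            report$gel$profile)
      log_stage(verbose, stage, "CD-MS vs gel TV distance %.3f",
                report$comparison$tv)
    }
    stage <- "report"
    write_text_report(report, file.path(out_dir, "report.txt"))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(report) <- "run_report"
  invisible(report)
}

run_cdms_arm <- function(config, construct, mass_table, out_dir, fp,
                         verbose) {
  s <- config$cdms
  if (!is.null(s$ions_file)) {
    log_stage(verbose, "simulate-ions", "loading ions from %s", s$ions_file)
    events <- read_ions(s$ions_file)
    seed <- NA
  } else {
    mx <- mixture_spec(s$mixture$labels, s$mixture$fractions)
    sim <- config_sim(config)
    seed <- sim$seed
    events <- simulate_ions(mx, mass_table, sim)
    log_stage(verbose, "simulate-ions",
              "%d ions, charge sigma %.2f e, mz cv %.4f, seed %d",
              sim$n_ions, sim$charge_sigma, sim$mz_cv, sim$seed)
    write_ions(events, file.path(out_dir, "ions.csv"),
               truth = isTRUE(s$truth))
  }
  spectrum <- build_spectrum(events, bin_width = s$bin_width %||% 1e4)
  write_spectrum(spectrum, file.path(out_dir, "spectrum.csv"))
  quant <- assign_ions(events, mass_table)
  charges <- charge_summary(events, quant,
                            threshold = s$charge_threshold %||% 3)
  log_stage(verbose, "quantify-ions",
            "empty %.1f%%, unassigned %.1f%% of %d ions",
            100 * quant$rel_abundance[quant$label == "empty"],
            100 * quant$rel_abundance[quant$label == "unassigned"],
            attr(quant, "total_ions"))
  if (any(charges$flagged)) {
    log_stage(verbose, "quantify-ions",
              "elevated-charge flag raised for: %s",
              paste(charges$label[charges$flagged], collapse = ", "))
  }
  write_stage_csv(merge_quant_charges(quant, charges),
                  file.path(out_dir, "cdms_quant.csv"), fp, seed)
  profile <- profile_from_quant(quant, construct = construct$name)
  write_stage_csv(profile_df(profile),
                  file.path(out_dir, "cdms_profile.csv"), fp, seed)
  if ("true_species" %in% names(events)) {
    assigned <- ifelse(is.na(attr(quant, "assignment")), "unassigned",
                       attr(quant, "assignment"))
    truth <- ifelse(events$true_species == "partial", "unassigned",
                    events$true_species)
    conf <- table(truth = truth, assigned = assigned)
    log_stage(verbose, "quantify-ions",
              "truth-tagged input: %.2f%% of ions correctly assigned",
              100 * mean(truth == assigned))
  } else {
    conf <- NULL
  }
  list(events = events, spectrum = spectrum, quant = quant,
       charges = charges, profile = profile, confusion = conf)
}

merge_quant_charges <- function(quant, charges) {
  out <- merge(as.data.frame(quant),
               as.data.frame(charges)[, c("label", "mean_charge", "sd_charge",
                                          "flagged")],
               by = "label", all.x = TRUE, sort = FALSE)
  out[match(quant$label, out$label), , drop = FALSE]
}

profile_df <- function(profile) {
  out <- data.frame(itr = seq_along(profile),
                    probability = as.numeric(profile))
  if (!is.null(attr(profile, "se"))) out$se <- as.numeric(attr(profile, "se"))
  out
}

run_gel_arm <- function(config, construct, packaged, out_dir, fp, verbose) {
  g <- config$gel
  gcfg <- config_gel(config)
  if (!is.null(g$lane_file)) {
    lane <- utils::read.csv(g$lane_file, comment.char = "#")
    if (!all(c("position", "intensity") %in% names(lane))) {
      stop("lane file must have columns position, intensity", call. = FALSE)
    }
    seed <- NA
  } else {
    fr <- unlist(g$band_fractions)
    fr <- fr / sum(fr)  # accept percentages or fractions
    seed <- g$seed
    lane <- simulate_lane(fr, packaged, gcfg, seed = seed)
    log_stage(verbose, "simulate-lane",
              "%d bands, band sigma %.2f, noise sigma %.4f, seed %d",
              nrow(packaged), gcfg$band_sigma, gcfg$noise_sigma, seed)
    write_stage_csv(as.data.frame(lane), file.path(out_dir, "lane.csv"),
                    fp, seed)
  }
  bands <- quantify_bands(lane, packaged, gcfg,
                          window_half_width = g$window_half_width %||% NULL)
  if (isTRUE(g$molar)) {
    bands <- molar_correct(bands, stats::setNames(packaged$nt_length,
                                                  packaged$label))
  }
  log_stage(verbose, "quantify-lane", "band fractions: %s",
            paste(sprintf("%.1f%%", 100 * bands$intensity_fraction),
                  collapse = ", "))
  write_stage_csv(bands, file.path(out_dir, "band_quant.csv"), fp, seed)
  profile <- profile_from_bands(bands, molar = isTRUE(g$molar),
                                construct = construct$name)
  write_stage_csv(profile_df(profile),
                  file.path(out_dir, "gel_profile.csv"), fp, seed)
  list(lane = lane, bands = bands, profile = profile)
}

write_text_report <- function(report, path) {
  lines <- c(
    sprintf("aavterm run report (config %s)", report$fingerprint),
    sprintf("construct: %s, %d packageable species",
            report$construct$name, sum(!report$species$is_empty)),
    ""
  )
  fmt_profile <- function(p) {
    paste(sprintf("%s %s", names(p), format_mixed_pct(as.numeric(p))),
          collapse = "  ")
  }
  if (!is.null(report$cdms)) {
    q <- report$cdms$quant
    lines <- c(lines, "CD-MS subpopulations (share of all ions):",
               sprintf("  %-12s %s", q$label,
                       format_mixed_pct(q$rel_abundance)),
               sprintf("CD-MS termination profile: %s",
                       fmt_profile(report$cdms$profile)), "")
  }
  if (!is.null(report$gel)) {
    lines <- c(lines,
               sprintf("gel termination profile:   %s",
                       fmt_profile(report$gel$profile)), "")
  }
  if (!is.null(report$comparison)) {
    lines <- c(lines, sprintf("CD-MS vs gel total variation distance: %.3f",
                              report$comparison$tv))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("aavterm run report — construct", x$construct$name, "\n")
  if (!is.null(x$cdms)) print(x$cdms$profile)
  if (!is.null(x$gel)) print(x$gel$profile)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Path to the bundled demo configuration
#'
#' A complete end-to-end configuration for the 848-nt construct with both
#' CD-MS and gel arms.
#'
#' @return File path of the installed demo config.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.json", package = "aavterm",
              mustWork = TRUE)
}
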