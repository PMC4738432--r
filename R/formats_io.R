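#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm lm.fit median optimize pchisq pt qt quantile
#'   rWishart rlnorm rnorm runif sd setNames var complete.cases residuals
#'   anova acf
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- delimited tables -------------------------------------------------------

# Columns every study table must carry; measurement columns vary by table kind.
.mandatory_cols <- c("species_id", "individual_id", "state")

.read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a study trait table
#'
#' Reads a delimited table (CSV or TSV, autodetected from the file extension)
#' holding one row per individual plant and state. The table must carry
#' `species_id`, `individual_id` and `state` columns; measurement columns
#' (masses, lengths, areas, times) are validated to be non-negative. Unknown
#' columns are preserved and row order is retained.
#'
#' @param path Path to a delimited text file with a single header row.
#' @param require_state If `FALSE`, tables without a `state` column are
#'   accepted (e.g. per-individual structural measurements taken once).
#' @return A `data.frame` of class `study_table`.
#' @export
read_trait_table <- function(path, require_state = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_delim_auto(path)
  as_study_table(df, require_state = require_state)
}

#' Validate a data frame as a study table
#'
#' @param df A data frame with `species_id`, `individual_id` and (optionally)
#'   `state` columns.
#' @inheritParams read_trait_table
#' @return The validated data frame with class `study_table` prepended.
#' @export
as_study_table <- function(df, require_state = TRUE) {
  need <- if (require_state) .mandatory_cols else setdiff(.mandatory_cols, "state")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$species_id <- trimws(as.character(df$species_id))
  df$individual_id <- trimws(as.character(df$individual_id))
  if ("state" %in% names(df)) {
    df$state <- trimws(as.character(df$state))
    bad <- which(!df$state %in% c("fresh", "dry"))
    if (length(bad)) {
      stop("validation error: state must be 'fresh' or 'dry' (row ",
           bad[1L], ")")
    }
  }
  # non-negativity for any measurement-like numeric column
  meas <- names(df)[vapply(df, is.numeric, logical(1))]
  meas <- grep("mass|height|width|area|thickness|time|length|load|cover|heat",
               meas, value = TRUE, ignore.case = TRUE)
  for (cl in meas) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    if (length(bad)) {
      stop("validation error: negative value in column '", cl,
           "' (row ", bad[1L], ")")
    }
  }
  for (pair in list(c("fresh_mass_g", "dry_mass_g"),
                    c("fresh_mass", "dry_mass"))) {
    if (all(pair %in% names(df))) {
      fr <- df[[pair[1L]]]; dr <- df[[pair[2L]]]
      bad <- which(!is.na(fr) & !is.na(dr) & dr > fr * 1.01)
      if (length(bad)) {
        stop("validation error: ", pair[2L], " exceeds ", pair[1L],
             " (row ", bad[1L], ")")
      }
    }
  }
  key_cols <- intersect(c("species_id", "individual_id", "state"), names(df))
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if ("state" %in% names(df) && anyDuplicated(key)) {
    stop("validation error: duplicate individual_id within species x state (row ",
         which(duplicated(key))[1L], ")")
  }
  class(df) <- unique(c("study_table", class(df)))
  df
}

#' Write a study table to CSV
#'
#' @param df A `study_table` (or plain data frame).
#' @param path Output path; written as comma-separated UTF-8 with one header
#'   row and `.` decimal separator.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- mass-loss series -------------------------------------------------------

#' Construct a mass-loss series
#'
#' A timestamped record of sample mass from one plant-scale burn. Time must be
#' strictly increasing at a nominal 0.2-s logging interval and the final mass
#' may not exceed the initial mass.
#'
#' @param individual_id,species_id,state Identifiers for the burned clump.
#' @param time Seconds since logging started, strictly increasing.
#' @param mass Sample mass in grams, non-negative.
#' @param interval Nominal logging interval in seconds.
#' @param interval_tol Relative tolerance on the logging interval.
#' @param min_points Minimum number of observations required.
#' @return A list of class `mass_loss_series`.
#' @export
mass_loss_series <- function(individual_id, state, time, mass,
                             species_id = NA_character_,
                             interval = 0.2, interval_tol = 0.25,
                             min_points = 30L) {
  if (length(time) != length(mass)) stop("time and mass lengths differ")
  if (length(time) < min_points) {
    stop("validation error: fewer than ", min_points, " points")
  }
  if (any(diff(time) <= 0)) stop("validation error: time not strictly increasing")
  if (any(mass < 0)) stop("validation error: negative mass")
  dt <- diff(time)
  if (any(abs(dt - interval) > interval_tol * interval)) {
    warning("sampling interval departs from nominal ", interval, " s")
  }
  if (mass[length(mass)] > mass[1L] + 1e-9 * max(mass[1L], 1)) {
    stop("validation error: final mass exceeds initial mass")
  }
  structure(
    list(individual_id = as.character(individual_id),
         species_id = as.character(species_id),
         state = match.arg(state, c("fresh", "dry")),
         time = as.numeric(time), mass = as.numeric(mass)),
    class = "mass_loss_series")
}

#' @export
print.mass_loss_series <- function(x, ...) {
  cat(sprintf("<mass_loss_series> %s [%s], %d points, %.1f-%.1f s, %.3f -> %.3f g\n",
              x$individual_id, x$state, length(x$time),
              min(x$time), max(x$time), x$mass[1L], x$mass[length(x$mass)]))
  invisible(x)
}

#' Read plant-scale mass-loss series from a delimited file
#'
#' Expects columns `species_id`, `individual_id`, `state`, `time_s`, `mass_g`;
#' one series per individual x state.
#'
#' @inheritParams read_trait_table
#' @param ... Passed to [mass_loss_series()] (tolerances).
#' @return A list of `mass_loss_series` objects.
#' @export
read_mass_loss <- function(path, ...) {
  df <- .read_delim_auto(path)
  need <- c("species_id", "individual_id", "state", "time_s", "mass_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  sp <- split(df, paste(df$species_id, df$individual_id, df$state, sep = "\r"))
  out <- lapply(sp, function(d) {
    d <- d[order(d$time_s), ]
    mass_loss_series(d$individual_id[1L], d$state[1L], d$time_s, d$mass_g,
                     species_id = d$species_id[1L], ...)
  })
  names(out) <- vapply(out, function(s)
    paste(s$species_id, s$individual_id, s$state, sep = "."), character(1))
  out
}

#' Write mass-loss series to a long-format CSV
#'
#' @param series A list of `mass_loss_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mass_loss <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(species_id = s$species_id, individual_id = s$individual_id,
               state = s$state, time_s = s$time, mass_g = s$mass)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- leaf burn events -------------------------------------------------------

#' Read leaf-scale burn event times
#'
#' One row per epiradiator test: the sample mass and the times of sample
#' application, first flaming and flame extinction. Event ordering
#' `t_application <= t_first_flame <= t_flame_out` is enforced.
#'
#' @inheritParams read_trait_table
#' @return A `data.frame` of class `leaf_burn_events`.
#' @export
read_leaf_events <- function(path) {
  df <- .read_delim_auto(path)
  as_leaf_events(df)
}

#' Validate a data frame of leaf burn events
#' @param df Data frame with columns `species_id`, `individual_id`, `state`,
#'   `sample_mass_g`, `t_application_s`, `t_first_flame_s`, `t_flame_out_s`.
#' @return The validated data frame with class `leaf_burn_events`.
#' @export
as_leaf_events <- function(df) {
  need <- c("species_id", "individual_id", "state", "sample_mass_g",
            "t_application_s", "t_first_flame_s", "t_flame_out_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(df$sample_mass_g <= 0)
  if (length(bad)) stop("validation error: non-positive sample mass (row ",
                        bad[1L], ")")
  bad <- which(df$t_application_s > df$t_first_flame_s |
                 df$t_first_flame_s > df$t_flame_out_s)
  if (length(bad)) stop("validation error: event times out of order (row ",
                        bad[1L], ")")
  class(df) <- unique(c("leaf_burn_events", class(df)))
  df
}

# ---- vertical profiles ------------------------------------------------------

#' Read vertical biomass profiles
#'
#' One row per height interval of one clump: the interval top height (cm,
#' measured from ground level) and the dry (and optionally fresh) mass in the
#' interval. Intervals must be of equal length within a profile; the standard
#' interval lengths are 2.5, 5, 10 or 15 cm depending on plant height.
#'
#' @inheritParams read_trait_table
#' @param allowed_intervals Permitted interval lengths in cm.
#' @return A list of `vertical_profile` objects keyed by
#'   `species_id.individual_id`.
#' @export
read_profiles <- function(path, allowed_intervals = c(2.5, 5, 10, 15)) {
  df <- .read_delim_auto(path)
  need <- c("species_id", "individual_id", "interval_top_cm", "dry_mass_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  sp <- split(df, paste(df$species_id, df$individual_id, sep = "\r"))
  out <- lapply(sp, function(d) {
    d <- d[order(d$interval_top_cm), ]
    vertical_profile(d$individual_id[1L], d$interval_top_cm, d$dry_mass_g,
                     fresh_mass = if ("fresh_mass_g" %in% names(d)) d$fresh_mass_g,
                     species_id = d$species_id[1L],
                     allowed_intervals = allowed_intervals)
  })
  names(out) <- vapply(out, function(p)
    paste(p$species_id, p$individual_id, sep = "."), character(1))
  out
}

#' Construct a vertical biomass profile
#'
#' @param individual_id,species_id Identifiers.
#' @param interval_top_cm Interval top heights in cm, strictly increasing from
#'   ground level, equally spaced.
#' @param dry_mass Dry mass (g) in each interval.
#' @param fresh_mass Optional fresh mass (g) per interval.
#' @param allowed_intervals Permitted interval lengths (cm).
#' @return A list of class `vertical_profile`.
#' @export
vertical_profile <- function(individual_id, interval_top_cm, dry_mass,
                             fresh_mass = NULL, species_id = NA_character_,
                             allowed_intervals = c(2.5, 5, 10, 15)) {
  h <- as.numeric(interval_top_cm)
  if (any(diff(h) <= 0)) stop("validation error: heights not increasing")
  if (any(dry_mass < 0)) stop("validation error: negative interval mass")
  len <- unique(round(diff(c(0, h)), 6))
  if (length(len) > 1L) stop("validation error: unequal interval lengths")
  if (!is.null(allowed_intervals) && !isTRUE(all.equal(min(abs(len - allowed_intervals)), 0))) {
    warning("interval length ", len, " cm is not one of the standard lengths")
  }
  if (length(h) < 5L) {
    warning("profile has fewer than 5 intervals; density slope will be noisy")
  }
  structure(
    list(individual_id = as.character(individual_id),
         species_id = as.character(species_id),
         interval_top_cm = h,
         dry_mass = as.numeric(dry_mass),
         fresh_mass = if (!is.null(fresh_mass)) as.numeric(fresh_mass)),
    class = "vertical_profile")
}

#' @export
print.vertical_profile <- function(x, ...) {
  cat(sprintf("<vertical_profile> %s, %d intervals to %.1f cm, %.2f g dry\n",
              x$individual_id, length(x$interval_top_cm),
              max(x$interval_top_cm), sum(x$dry_mass)))
  invisible(x)
}

# ---- trees ------------------------------------------------------------------

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the contracts the
#' comparative analyses need: a single rooted tree, labelled tips, and
#' non-negative branch lengths.
#'
#' @param path Path to a single-tree Newick file with branch lengths.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("parse error: not a valid Newick file: ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found several")
  if (is.null(tr$edge.length)) stop("parse error: tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("validation error: negative branch length")
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label))) {
    stop("parse error: unlabeled tip in tree")
  }
  tr$tip.label <- trimws(tr$tip.label)
  tr
}

#' Write a phylogeny to Newick
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 14)
  invisible(path)
}

#' Cross-check tree tips against the species in a trait table
#'
#' @param tree An [ape::phylo] object.
#' @param species Character vector of species identifiers (any duplication is
#'   collapsed).
#' @return `TRUE` invisibly if the sets match exactly, otherwise an error
#'   naming the offending species.
#' @export
validate_inputs <- function(tree, species) {
  sp <- unique(trimws(as.character(species)))
  tips <- trimws(tree$tip.label)
  only_tree <- setdiff(tips, sp)
  only_data <- setdiff(sp, tips)
  if (length(only_tree) || length(only_data)) {
    stop("tip/trait mismatch: ",
         if (length(only_tree)) paste0("in tree only: ",
                                       paste(only_tree, collapse = ", "), "; "),
         if (length(only_data)) paste0("in data only: ",
                                       paste(only_data, collapse = ", ")))
  }
  invisible(TRUE)
}

# ---- run configuration ------------------------------------------------------

#' Default pipeline configuration
#'
#' Returns the full configuration list the pipeline runs from, optionally
#' overridden from a YAML (or JSON) file and/or a named list. Values are the
#' study defaults: Rothermel environment constants (moisture of extinction
#' 0.25, total mineral content 0.0555, effective mineral content 0.010,
#' particle density 512.6 kg/m3, no wind, flat ground), Boltzmann-fit
#' acceptance R2 of 0.95, and desk-scale MCMC settings.
#'
#' @param path Optional YAML/JSON config file; keys override defaults.
#' @param overrides Optional named list applied after the file.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    out_dir = "grassflam-run",
    boltzmann = list(r2_min = 0.95, n_starts = 5L, window_s = 3),
    density = list(mode = "log-linear"),
    rothermel = list(
      wind_ms = 0, slope_frac = 0,
      moisture_of_extinction = 0.25,
      total_mineral = 0.0555, effective_mineral = 0.010,
      particle_density_kg_m3 = 512.6),
    mcmc = list(n_iter = 50000L, burnin = 1000L, thin = 50L,
                prior_V = 2, prior_nu = 0.002),
    generator = list(n_species = 25L, n_individuals = 7L)
  )
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    file_cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
                else yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    stop("config error: seed must be an integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  cfg
}
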