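# Structural and chemical explanatory traits measured on each clump:
# biomass quantity, vertical biomass-density slope, moisture content,
# leaf SA/V ratio, leaf effective heat of combustion, plus height/cover
# and the derived fuel load.

#' Biomass moisture content
#'
#' Water mass per unit dry mass: `(fresh - dry) / dry`, in g/g. A small
#' tolerance (default 1%) absorbs weighing noise when a nominally fresh mass
#' comes in just under the dry mass.
#'
#' @param fresh_mass Fresh mass in grams.
#' @param dry_mass Oven-dry mass in grams; must be positive.
#' @param tol Relative tolerance by which `fresh_mass` may fall below
#'   `dry_mass` before an error is raised.
#' @return Moisture content in g water per g dry mass (negative values within
#'   tolerance are clamped to zero).
#' @export
moisture_content <- function(fresh_mass, dry_mass, tol = 0.01) {
  if (any(dry_mass <= 0)) stop("domain error: dry_mass must be positive")
  if (any(fresh_mass < dry_mass * (1 - tol))) {
    stop("validation error: fresh_mass below dry_mass beyond tolerance")
  }
  pmax((fresh_mass - dry_mass) / dry_mass, 0)
}

#' Leaf surface-area-to-volume ratio
#'
#' Computed under a flat-slab model of the grass lamina: both leaf faces
#' contribute surface (`SA = 2 * area`), volume is `area * thickness`, and the
#' thin edge is neglected, so `SA/V = 2 / thickness` (per mm). Leaf area thus
#' cancels; it is accepted as an argument because the measurement protocol
#' records it and other SA/V conventions use it.
#'
#' @param mean_leaf_area Mean leaf area in mm^2 (must be positive).
#' @param mean_thickness Mean leaf thickness in mm, averaged over leaves.
#' @return SA/V ratio in mm^-1.
#' @export
leaf_sav <- function(mean_leaf_area, mean_thickness) {
  if (any(mean_leaf_area <= 0)) stop("domain error: leaf area must be positive")
  if (any(mean_thickness <= 0)) stop("domain error: thickness must be positive")
  2 / mean_thickness
}

#' Vertical biomass-density slope
#'
#' Fits an ordinary least-squares line to the logged cumulative dry biomass of
#' a clump against vertical height. Cumulative mass is accumulated from ground
#' level and evaluated at interval top heights. Two response/predictor
#' conventions are available: `"log-linear"` regresses `log10(cumulative
#' mass)` on height (cm), and `"log-log"` regresses `log10(cumulative mass)`
#' on `log10(height)` so the slope is a dimensionless power-law exponent.
#' High slopes indicate biomass packed low and densely in the canopy.
#'
#' @param profile A [vertical_profile()].
#' @param mode `"log-linear"` (default) or `"log-log"`.
#' @return A list of class `density_fit` with `slope`, `intercept`,
#'   `r_squared`, `n_points`, `mode`.
#' @export
density_slope <- function(profile, mode = c("log-linear", "log-log")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "vertical_profile"))
  h <- profile$interval_top_cm
  cum <- cumsum(profile$dry_mass)
  usable <- cum > 0
  if (mode == "log-log") usable <- usable & h > 0
  if (any(!usable)) {
    warning("dropping ", sum(!usable), " point(s) with zero cumulative mass")
  }
  h <- h[usable]; cum <- cum[usable]
  if (length(h) < 3L) stop("fewer than 3 usable points in profile")
  x <- if (mode == "log-log") log10(h) else h
  y <- log10(cum)
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else NA_real_
  structure(
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = r2,
         n_points = length(h),
         mode = mode,
         individual_id = profile$individual_id),
    class = "density_fit")
}

#' Effective heat of combustion from calorimeter replicates
#'
#' Each replicate's total heat release (kJ) is divided by its sample mass (g);
#' replicates are averaged per individual.
#'
#' @param replicate_heat_kj Heat release per replicate, kJ.
#' @param sample_mass_g Sample mass per replicate, g (positive).
#' @param individual Optional factor of individual identifiers; when given,
#'   a named vector of per-individual means is returned.
#' @return EHoC in kJ/g: a scalar mean, or per-individual means.
#' @export
ehoc_mean <- function(replicate_heat_kj, sample_mass_g, individual = NULL) {
  if (any(sample_mass_g <= 0)) stop("domain error: sample mass must be positive")
  per_rep <- replicate_heat_kj / sample_mass_g
  if (is.null(individual)) return(mean(per_rep))
  tapply(per_rep, as.character(individual), mean)
}

#' Compute individual-level traits from raw study tables
#'
#' Combines the clump table (fresh/dry masses, height, width), the vertical
#' profiles, the leaf measurements (area, thickness) and the calorimeter
#' replicates into one row of explanatory traits per individual. Cover area is
#' taken as the area of a circle with the measured maximum horizontal spread
#' as diameter; fuel load is total dry biomass divided by cover area.
#'
#' @param clumps `study_table` with columns `species_id`, `individual_id`,
#'   `fresh_mass_g`, `dry_mass_g`, `height_cm`, `width_cm`.
#' @param profiles List of [vertical_profile()] keyed
#'   `species_id.individual_id`.
#' @param leaves `study_table` with `mean_leaf_area_mm2`, `mean_thickness_mm`.
#' @param ehoc Data frame of calorimeter replicates with `species_id`,
#'   `individual_id`, `heat_kj`, `mass_g` (a subset of individuals; missing
#'   individuals inherit their species mean).
#' @param density_mode Passed to [density_slope()].
#' @return A data frame of class `individual_traits`, one row per individual.
#' @export
individual_traits <- function(clumps, profiles, leaves, ehoc,
                              density_mode = "log-linear") {
  key <- paste(clumps$species_id, clumps$individual_id, sep = ".")
  slopes <- vapply(key, function(k) {
    p <- profiles[[k]]
    if (is.null(p)) return(NA_real_)
    density_slope(p, mode = density_mode)$slope
  }, numeric(1))

  lkey <- paste(leaves$species_id, leaves$individual_id, sep = ".")
  sav <- leaf_sav(leaves$mean_leaf_area_mm2, leaves$mean_thickness_mm)
  sav <- sav[match(key, lkey)]

  ehoc_ind <- ehoc_mean(ehoc$heat_kj, ehoc$mass_g,
                        individual = paste(ehoc$species_id, ehoc$individual_id,
                                           sep = "."))
  ehoc_val <- ehoc_ind[key]
  # calorimetry covers a subset of individuals; others take the species mean
  sp_of <- sub("\\..*$", "", names(ehoc_ind))
  sp_mean <- tapply(ehoc_ind, sp_of, mean)
  ehoc_val[is.na(ehoc_val)] <- sp_mean[clumps$species_id[is.na(ehoc_val)]]

  cover <- pi * (clumps$width_cm / 2)^2
  out <- data.frame(
    species_id = clumps$species_id,
    individual_id = clumps$individual_id,
    biomass_quantity_g = clumps$dry_mass_g,
    biomass_density_slope = unname(slopes),
    moisture_content = moisture_content(clumps$fresh_mass_g, clumps$dry_mass_g),
    leaf_sav_mm = unname(sav),
    leaf_ehoc_kj_g = unname(ehoc_val),
    height_cm = clumps$height_cm,
    cover_area_cm2 = cover,
    fuel_load_g_cm2 = clumps$dry_mass_g / cover,
    stringsAsFactors = FALSE)
  class(out) <- c("individual_traits", class(out))
  out
}

#' Aggregate individual traits to species means and CVs
#'
#' Arithmetic means and coefficients of variation (sd/mean, reported as
#' percent) per species for every numeric trait column.
#'
#' @param traits An `individual_traits` data frame (or any data frame with
#'   `species_id` and numeric trait columns).
#' @return A data frame of class `species_traits`: one row per species with
#'   `<trait>` mean columns and `<trait>_cv_pct` columns, plus `n_individuals`.
#' @export
aggregate_species <- function(traits) {
  num <- names(traits)[vapply(traits, is.numeric, logical(1))]
  sp <- split(traits, traits$species_id)
  rows <- lapply(sp, function(d) {
    m <- vapply(d[num], mean, numeric(1), na.rm = TRUE)
    cv <- vapply(d[num], function(v) {
      mu <- mean(v, na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) return(NA_real_)
      100 * sd(v, na.rm = TRUE) / mu
    }, numeric(1))
    cbind(data.frame(species_id = d$species_id[1L],
                     n_individuals = nrow(d), stringsAsFactors = FALSE),
          as.data.frame(as.list(m)),
          setNames(as.data.frame(as.list(cv)), paste0(num, "_cv_pct")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_traits", class(out))
  out
}
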