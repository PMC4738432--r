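# Single-class Rothermel (1972) surface fire-spread model, implemented from
# the published equation set. Fuel models are built from measured plant
# traits; environment constants (moisture of extinction, mineral contents,
# particle density) come from configuration. Computation runs internally in
# the source model's imperial units (ft, lb, BTU, min) with SI conversion at
# the boundary; spread rate is reported in m/min.

# SI -> imperial conversion factors, derived from the exact definitions
# 1 ft = 0.3048 m, 1 lb = 0.45359237 kg, 1 BTU/lb = 2.326 kJ/kg
.ros_const <- list(
  sav_per_m_to_per_ft = 0.3048,            # 1/m -> 1/ft
  kj_kg_to_btu_lb = 1 / 2.326,             # kJ/kg -> BTU/lb
  kg_m2_to_lb_ft2 = 0.3048^2 / 0.45359237, # kg/m2 -> lb/ft2
  m_to_ft = 1 / 0.3048,                    # m -> ft
  kg_m3_to_lb_ft3 = 0.3048^3 / 0.45359237, # kg/m3 -> lb/ft3
  ms_to_ft_min = 60 / 0.3048,              # m/s -> ft/min
  ft_min_to_m_min = 0.3048                 # ft/min -> m/min
)

#' Build a Rothermel fuel model from plant traits
#'
#' Converts one individual's measured traits to the SI fuel-model inputs of
#' the spread model: leaf SA/V (per mm -> m^2/m^3), leaf effective heat of
#' combustion (kJ/g -> kJ/kg), fuel load (g/cm^2 -> kg/m^2), plant height as
#' fuel-bed depth (cm -> m), and biomass moisture content (g/g fraction).
#' Environment constants not measured on plants (moisture of extinction,
#' mineral contents, particle density) are supplied by the configuration.
#'
#' @param traits One row of an `individual_traits` data frame (or a list with
#'   fields `leaf_sav_mm`, `leaf_ehoc_kj_g`, `fuel_load_g_cm2`, `height_cm`,
#'   `moisture_content`).
#' @param env The `rothermel` section of [run_config()] (moisture of
#'   extinction, mineral contents, particle density).
#' @return A list of class `fuel_model` with SI fields `sav_m2_m3`,
#'   `heat_kj_kg`, `load_kg_m2`, `depth_m`, `moisture`, `mx`,
#'   `total_mineral`, `effective_mineral`, `particle_density_kg_m3`.
#' @export
build_fuel_model <- function(traits, env = run_config()$rothermel) {
  need <- c("leaf_sav_mm", "leaf_ehoc_kj_g", "fuel_load_g_cm2", "height_cm",
            "moisture_content")
  for (f in need) {
    v <- traits[[f]]
    if (is.null(v) || !is.finite(v)) stop("missing trait: ", f)
  }
  fm <- list(
    sav_m2_m3 = traits$leaf_sav_mm * 1000,       # 1/mm -> 1/m == m2/m3
    heat_kj_kg = traits$leaf_ehoc_kj_g * 1000,   # kJ/g -> kJ/kg
    load_kg_m2 = traits$fuel_load_g_cm2 * 10,    # g/cm2 -> kg/m2
    depth_m = traits$height_cm / 100,            # cm -> m
    moisture = traits$moisture_content,
    mx = env$moisture_of_extinction,
    total_mineral = env$total_mineral,
    effective_mineral = env$effective_mineral,
    particle_density_kg_m3 = env$particle_density_kg_m3)
  stopifnot(fm$mx > 0, fm$total_mineral > 0, fm$total_mineral < 1,
            fm$effective_mineral > 0, fm$effective_mineral < 1,
            fm$particle_density_kg_m3 > 0, fm$moisture >= 0)
  class(fm) <- "fuel_model"
  fm
}

#' Moisture damping coefficient
#'
#' The cubic polynomial in the moisture ratio `r = moisture / Mx`:
#' `1 - 2.59 r + 5.11 r^2 - 3.52 r^3`, clamped to zero for `r >= 1` (the
#' moisture of extinction) and to the unit interval elsewhere. At `r = 1` the
#' polynomial itself evaluates to zero, so damping is continuous at
#' extinction.
#'
#' @param moisture Fuel moisture content, fraction (g/g).
#' @param mx Moisture of extinction, fraction.
#' @return Damping coefficient in `[0, 1]`.
#' @export
moisture_damping <- function(moisture, mx) {
  r <- moisture / mx
  eta <- ifelse(r >= 1, 0, 1 - 2.59 * r + 5.11 * r^2 - 3.52 * r^3)
  pmin(pmax(eta, 0), 1)
}

#' Rothermel spread rate with all intermediate quantities
#'
#' Runs the full equation chain of the single-fuel-class surface spread
#' model: packing ratio and its optimum, maximum and actual reaction
#' velocity, mineral and moisture damping, reaction intensity, propagating
#' flux ratio, effective heating number, heat of preignition, wind and slope
#' factors, and finally the forward rate of spread
#' `R = I_R * xi * (1 + phi_w + phi_s) / (rho_b * eps * Q_ig)`.
#'
#' @param fm A [build_fuel_model()] result.
#' @param wind_ms Midflame wind speed, m/s.
#' @param slope_frac Terrain slope as a fraction (rise/run).
#' @return A list of class `rothermel_result` holding `spread_rate_m_min` and
#'   all intermediates (imperial-unit internals documented per field).
#' @export
spread_rate <- function(fm, wind_ms = 0, slope_frac = 0) {
  stopifnot(inherits(fm, "fuel_model"))
  k <- .ros_const
  if (fm$load_kg_m2 <= 0 || fm$depth_m <= 0) {
    warning("zero fuel load or depth: no spread")
    return(.ros_zero(fm))
  }
  sigma <- fm$sav_m2_m3 * k$sav_per_m_to_per_ft        # 1/ft
  h <- fm$heat_kj_kg * k$kj_kg_to_btu_lb               # BTU/lb
  w0 <- fm$load_kg_m2 * k$kg_m2_to_lb_ft2              # lb/ft2
  delta <- fm$depth_m * k$m_to_ft                      # ft
  rho_p <- fm$particle_density_kg_m3 * k$kg_m3_to_lb_ft3  # lb/ft3
  mf <- fm$moisture
  u <- wind_ms * k$ms_to_ft_min                        # ft/min

  rho_b <- w0 / delta
  beta <- rho_b / rho_p
  beta_op <- 3.348 * sigma^(-0.8189)
  gamma_max <- sigma^1.5 / (495 + 0.0594 * sigma^1.5)
  a_exp <- 133 * sigma^(-0.7913)
  gamma <- gamma_max * (beta / beta_op)^a_exp *
    exp(a_exp * (1 - beta / beta_op))
  w_n <- w0 * (1 - fm$total_mineral)
  eta_m <- moisture_damping(mf, fm$mx)
  eta_s <- min(0.174 * fm$effective_mineral^(-0.19), 1)
  i_r <- gamma * w_n * h * eta_m * eta_s               # BTU/ft2/min
  xi <- exp((0.792 + 0.681 * sqrt(sigma)) * (beta + 0.1)) /
    (192 + 0.2595 * sigma)
  eps <- exp(-138 / sigma)
  q_ig <- 250 + 1116 * mf                              # BTU/lb
  cc <- 7.47 * exp(-0.133 * sigma^0.55)
  bb <- 0.02526 * sigma^0.54
  ee <- 0.715 * exp(-3.59e-4 * sigma)
  phi_w <- if (u > 0) cc * u^bb * (beta / beta_op)^(-ee) else 0
  phi_s <- if (slope_frac > 0) 5.275 * beta^(-0.3) * slope_frac^2 else 0
  r_ft_min <- i_r * xi * (1 + phi_w + phi_s) / (rho_b * eps * q_ig)

  out <- list(
    spread_rate_m_min = r_ft_min * k$ft_min_to_m_min,
    reaction_intensity = i_r,
    optimum_reaction_velocity = gamma,
    moisture_damping = eta_m,
    mineral_damping = eta_s,
    propagating_flux_ratio = xi,
    packing_ratio = beta,
    optimum_packing_ratio = beta_op,
    bulk_density = rho_b,
    effective_heating_number = eps,
    heat_of_preignition = q_ig,
    wind_factor = phi_w,
    slope_factor = phi_s,
    fuel_model = fm, wind_ms = wind_ms, slope_frac = slope_frac)
  class(out) <- "rothermel_result"
  out
}

.ros_zero <- function(fm) {
  out <- list(spread_rate_m_min = 0, reaction_intensity = 0,
              optimum_reaction_velocity = 0, moisture_damping = 0,
              mineral_damping = min(0.174 * fm$effective_mineral^(-0.19), 1),
              propagating_flux_ratio = 0, packing_ratio = 0,
              optimum_packing_ratio = NA_real_, bulk_density = 0,
              effective_heating_number = 0,
              heat_of_preignition = 250 + 1116 * fm$moisture,
              wind_factor = 0, slope_factor = 0,
              fuel_model = fm, wind_ms = 0, slope_frac = 0)
  class(out) <- "rothermel_result"
  out
}

#' @export
print.rothermel_result <- function(x, ...) {
  cat(sprintf(
    "<rothermel_result> R = %.4f m/min (I_R %.1f, eta_M %.3f, xi %.4f, beta %.4g)\n",
    x$spread_rate_m_min, x$reaction_intensity, x$moisture_damping,
    x$propagating_flux_ratio, x$packing_ratio))
  invisible(x)
}

#' One-at-a-time sensitivity of the spread model to a trait
#'
#' Re-evaluates [spread_rate()] over a grid of values for one fuel-model
#' field, holding everything else fixed.
#'
#' @param fm Baseline [build_fuel_model()] result.
#' @param trait One of `"sav"`, `"heat_content"`, `"fuel_load"`,
#'   `"fuel_depth"`, `"moisture"`.
#' @param grid Numeric vector of trait values (in the fuel model's SI units).
#' @param wind_ms,slope_frac Passed to [spread_rate()].
#' @return A data frame, one row per grid value, with the spread rate and all
#'   intermediate quantities.
#' @export
sensitivity <- function(fm, trait, grid, wind_ms = 0, slope_frac = 0) {
  field <- switch(match.arg(trait, c("sav", "heat_content", "fuel_load",
                                     "fuel_depth", "moisture")),
                  sav = "sav_m2_m3", heat_content = "heat_kj_kg",
                  fuel_load = "load_kg_m2", fuel_depth = "depth_m",
                  moisture = "moisture")
  if (!length(grid)) stop("empty grid")
  rows <- lapply(grid, function(v) {
    fm2 <- fm
    fm2[[field]] <- v
    r <- spread_rate(fm2, wind_ms, slope_frac)
    data.frame(trait = trait, value = v,
               spread_rate_m_min = r$spread_rate_m_min,
               reaction_intensity = r$reaction_intensity,
               moisture_damping = r$moisture_damping,
               mineral_damping = r$mineral_damping,
               propagating_flux_ratio = r$propagating_flux_ratio,
               packing_ratio = r$packing_ratio,
               optimum_packing_ratio = r$optimum_packing_ratio,
               bulk_density = r$bulk_density,
               effective_heating_number = r$effective_heating_number,
               heat_of_preignition = r$heat_of_preignition,
               wind_factor = r$wind_factor, slope_factor = r$slope_factor)
  })
  do.call(rbind, rows)
}
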