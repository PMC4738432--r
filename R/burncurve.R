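# Flammability-component extraction from burn records.
#
# Leaf scale (epiradiator tests): time to ignition (ignitability), flaming
# time (sustainability) and average combustion rate (combustibility), plus
# the fresh-minus-dry moisture effect. Plant scale (clump burns on a balance):
# Boltzmann sigmoid fits to the mass-loss record give the width parameter
# (sustainability) and the maximum combustion rate from a windowed regression
# at the inflection point (combustibility); the mass-standardised intercept of
# log(rate) ~ log(mass burned) is the species' intrinsic combustibility.

# ---- leaf scale -------------------------------------------------------------

#' Leaf-scale flammability metrics from burn event times
#'
#' Time to ignition is the delay between sample application and first flaming;
#' flaming time runs from ignition to flame extinction; the average combustion
#' rate is the sample mass divided by flaming time. Records with zero flaming
#' time are marked excluded ("no sustained flaming") rather than dropped.
#'
#' @param events A `leaf_burn_events` data frame (see [read_leaf_events()]).
#' @return A data frame of class `leaf_flammability` with columns `tti_s`,
#'   `ft_s`, `combustion_rate_g_s`, `excluded`, `exclude_reason`.
#' @export
leaf_metrics <- function(events) {
  stopifnot(inherits(events, "leaf_burn_events") ||
              all(c("t_application_s", "t_first_flame_s", "t_flame_out_s",
                    "sample_mass_g") %in% names(events)))
  tti <- events$t_first_flame_s - events$t_application_s
  ft <- events$t_flame_out_s - events$t_first_flame_s
  excluded <- ft <= 0
  rate <- ifelse(excluded, NA_real_, events$sample_mass_g / ft)
  out <- data.frame(
    species_id = events$species_id,
    individual_id = events$individual_id,
    state = events$state,
    tti_s = tti,
    ft_s = ifelse(excluded, NA_real_, ft),
    combustion_rate_g_s = rate,
    excluded = excluded,
    exclude_reason = ifelse(excluded, "no sustained flaming", ""),
    stringsAsFactors = FALSE)
  class(out) <- c("leaf_flammability", class(out))
  out
}

#' Fresh-minus-dry moisture effect on leaf flammability
#'
#' For each individual with both a fresh and a dry record, the difference
#' (fresh - dry) in each leaf flammability metric; species means of the
#' differences follow. Unpaired individuals are excluded with a warning.
#'
#' @param leaf A `leaf_flammability` data frame covering both states.
#' @return A list with `individual` (per-individual differences, plus the
#'   fresh/dry TTI ratio) and `species` (species means of the differences and
#'   the mean percent increase in ignition delay).
#' @export
moisture_effect <- function(leaf) {
  keep <- !leaf$excluded
  fresh <- leaf[keep & leaf$state == "fresh", ]
  dry <- leaf[keep & leaf$state == "dry", ]
  key_f <- paste(fresh$species_id, fresh$individual_id)
  key_d <- paste(dry$species_id, dry$individual_id)
  common <- intersect(key_f, key_d)
  n_unpaired <- length(setdiff(union(key_f, key_d), common))
  if (n_unpaired > 0) {
    warning(n_unpaired, " unpaired individual(s) excluded from moisture effect")
  }
  f <- fresh[match(common, key_f), ]
  d <- dry[match(common, key_d), ]
  ind <- data.frame(
    species_id = f$species_id,
    individual_id = f$individual_id,
    d_tti_s = f$tti_s - d$tti_s,
    d_ft_s = f$ft_s - d$ft_s,
    d_rate_g_s = f$combustion_rate_g_s - d$combustion_rate_g_s,
    tti_ratio = f$tti_s / d$tti_s,
    stringsAsFactors = FALSE)
  spl <- split(ind, ind$species_id)
  species <- do.call(rbind, lapply(spl, function(x) data.frame(
    species_id = x$species_id[1L],
    n_pairs = nrow(x),
    d_tti_s = mean(x$d_tti_s),
    d_ft_s = mean(x$d_ft_s),
    d_rate_g_s = mean(x$d_rate_g_s),
    tti_increase_pct = 100 * (mean(x$tti_ratio) - 1),
    stringsAsFactors = FALSE)))
  rownames(species) <- NULL
  list(individual = ind, species = species)
}

# ---- plant scale: Boltzmann fitting ----------------------------------------

#' Evaluate the Boltzmann sigmoid
#'
#' `m(t) = A2 + (A1 - A2) / (1 + exp((t - t0)/dx))`: mass decays from the
#' upper asymptote `A1` to the lower asymptote `A2` around the inflection time
#' `t0`; `dx` is the width parameter, the time scale over which most mass is
#' lost.
#'
#' @param t Time(s), seconds.
#' @param A1,A2 Upper and lower mass asymptotes (g).
#' @param t0 Inflection time (s).
#' @param dx Width parameter (s), positive.
#' @return Predicted mass (g).
#' @export
boltzmann <- function(t, A1, A2, t0, dx) {
  A2 + (A1 - A2) / (1 + exp((t - t0) / dx))
}

.boltzmann_starts <- function(time, mass, n_starts = 5L) {
  n <- length(time)
  head_med <- median(mass[seq_len(max(3L, n %/% 10))])
  tail_med <- median(mass[seq(n - max(3L, n %/% 10) + 1L, n)])
  # steepest observed decline locates the inflection
  k <- max(5L, n %/% 20)
  sl <- (mass[seq_len(n - k)] - mass[seq(k + 1L, n)]) /
    (time[seq(k + 1L, n)] - time[seq_len(n - k)])
  t0 <- time[which.max(sl) + k %/% 2]
  # 10-90% transit time: a Boltzmann crosses those levels 2*ln(9)*dx apart
  rng <- head_med - tail_med
  lo <- tail_med + 0.1 * rng
  hi <- tail_med + 0.9 * rng
  t_hi <- time[which(mass <= hi)[1L]]
  t_lo <- time[which(mass <= lo)[1L]]
  dx0 <- (t_lo - t_hi) / (2 * log(9))
  if (!is.finite(dx0) || dx0 <= 0) dx0 <- diff(range(time)) / 10
  mult <- exp(seq(-1, 1, length.out = n_starts))
  lapply(dx0 * mult, function(dx)
    list(A1 = head_med, A2 = tail_med, t0 = t0, dx = dx))
}

#' Fit a Boltzmann sigmoid to a mass-loss series
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialisation: the inflection starts at the steepest observed mass drop,
#' the width at the 10-90% transit time, the asymptotes at head and tail
#' medians; several width multipliers guard against local minima. A fit whose
#' R-squared falls below `r2_min` is flagged excluded with reason
#' "noise around the curve".
#'
#' @param series A [mass_loss_series()].
#' @param r2_min Lack-of-fit exclusion threshold on R-squared.
#' @param n_starts Number of width-parameter starting values.
#' @return A list of class `boltzmann_fit` with elements `A1`, `A2`, `t0`,
#'   `dx`, `rss`, `r_squared`, `converged`, `excluded`, `exclude_reason`.
#' @export
fit_boltzmann <- function(series, r2_min = 0.95, n_starts = 5L) {
  stopifnot(inherits(series, "mass_loss_series"))
  time <- series$time; mass <- series$mass
  if (diff(range(mass)) <= 0) stop("mass range is zero; nothing to fit")
  starts <- .boltzmann_starts(time, mass, n_starts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        mass ~ A2 + (A1 - A2) / (1 + exp((time - t0) / dx)),
        start = s,
        lower = c(A1 = -Inf, A2 = -Inf, t0 = min(time) - diff(range(time)),
                  dx = 1e-6),
        upper = c(A1 = Inf, A2 = Inf, t0 = max(time) + diff(range(time)),
                  dx = 10 * diff(range(time))),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  tss <- sum((mass - mean(mass))^2)
  if (is.null(best)) {
    out <- list(A1 = NA_real_, A2 = NA_real_, t0 = NA_real_, dx = NA_real_,
                rss = NA_real_, r_squared = NA_real_, converged = FALSE,
                excluded = TRUE, exclude_reason = "noise around the curve",
                individual_id = series$individual_id, state = series$state)
    class(out) <- "boltzmann_fit"
    return(out)
  }
  p <- as.list(coef(best$fit))
  r2 <- 1 - best$rss / tss
  excluded <- r2 < r2_min
  out <- list(A1 = p$A1, A2 = p$A2, t0 = p$t0, dx = p$dx,
              rss = best$rss, r_squared = r2,
              converged = isTRUE(best$fit$convInfo$isConv),
              excluded = excluded,
              exclude_reason = if (excluded) "noise around the curve" else "",
              individual_id = series$individual_id, state = series$state)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> A1=%.4g A2=%.4g t0=%.4g dx=%.4g R2=%.4f%s\n",
    x$A1, x$A2, x$t0, x$dx, x$r_squared,
    if (x$excluded) paste0(" [excluded: ", x$exclude_reason, "]") else ""))
  invisible(x)
}

#' Maximum combustion rate from a windowed regression at the inflection
#'
#' Selects the observations within `window_s` seconds either side of the
#' fitted inflection time and fits an ordinary least-squares line of mass on
#' time; the absolute slope is the maximum combustion rate in g/s.
#'
#' @param series A [mass_loss_series()].
#' @param fit The [fit_boltzmann()] result for that series.
#' @param window_s Half-width of the window in seconds.
#' @param min_points Minimum observations required inside the window.
#' @return Maximum combustion rate (g/s), as `abs(slope)`.
#' @export
max_combustion_rate <- function(series, fit, window_s = 3, min_points = 5L) {
  stopifnot(inherits(series, "mass_loss_series"))
  t0 <- if (inherits(fit, "boltzmann_fit")) fit$t0 else fit
  if (!is.finite(t0)) stop("inflection time is not finite")
  if (t0 < min(series$time) || t0 > max(series$time)) {
    stop("inflection outside series")
  }
  sel <- series$time >= t0 - window_s & series$time <= t0 + window_s
  if (sum(sel) < min_points) {
    stop("fewer than ", min_points, " points in the inflection window")
  }
  co <- coef(lm(series$mass[sel] ~ series$time[sel]))
  abs(unname(co[2L]))
}

#' Plant-scale flammability for a set of mass-loss series
#'
#' Fits each series with [fit_boltzmann()], takes the width parameter as the
#' plant-scale flaming time, and computes the maximum combustion rate in the
#' inflection window. Mass burned is `A1 - A2`.
#'
#' @param series_list A list of [mass_loss_series()].
#' @param r2_min,n_starts Passed to [fit_boltzmann()].
#' @param window_s Passed to [max_combustion_rate()].
#' @return A data frame of class `plant_flammability`, one row per series.
#' @export
plant_metrics <- function(series_list, r2_min = 0.95, n_starts = 5L,
                          window_s = 3) {
  rows <- lapply(series_list, function(s) {
    f <- fit_boltzmann(s, r2_min = r2_min, n_starts = n_starts)
    rate <- NA_real_
    reason <- f$exclude_reason
    excluded <- f$excluded
    if (!excluded) {
      rate <- tryCatch(max_combustion_rate(s, f, window_s = window_s),
                       error = function(e) NA_real_)
      if (!is.finite(rate) || rate <= 0) {
        excluded <- TRUE
        reason <- "no measurable combustion in window"
        rate <- NA_real_
      }
    }
    data.frame(species_id = s$species_id, individual_id = s$individual_id,
               state = s$state,
               flaming_time_s = if (excluded) NA_real_ else f$dx,
               max_combustion_rate_g_s = rate,
               mass_burned_g = if (excluded) NA_real_ else f$A1 - f$A2,
               r_squared = f$r_squared,
               excluded = excluded, exclude_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("plant_flammability", class(out))
  out
}

# ---- intrinsic combustibility ----------------------------------------------

#' Species intrinsic combustibility from the rate-mass allometry
#'
#' Within one species, regresses `log10(max combustion rate)` on `log10(mass
#' burned)` separately for fresh, dry and the combined data (balanced to
#' fresh/dry pairs; unpaired burns are dropped). A nested-model F-test
#' compares state-specific slopes against a common slope; when slopes do not
#' differ (the usual case) the states are pooled and a second F-test compares
#' state-specific intercepts. The species' intrinsic combustibility is the
#' combined-model intercept, unless the fresh and dry intercepts differ
#' significantly, in which case the fresh-data intercept is used.
#'
#' @param plant A `plant_flammability` data frame for one species (both
#'   states; excluded rows are ignored).
#' @param alpha Significance level for the slope/intercept equality tests.
#' @return A list of class `intrinsic_combustibility`: `species_id`, `slope`,
#'   `y_intercept` (log10 g/s at log10 mass = 0), `source` ("combined" or
#'   "fresh-only"), `p_slope_equal`, `p_intercept_equal`, per-state fits.
#' @export
intrinsic_combustibility <- function(plant, alpha = 0.05) {
  d <- plant[!plant$excluded &
               is.finite(plant$max_combustion_rate_g_s) &
               is.finite(plant$mass_burned_g) & plant$mass_burned_g > 0, ]
  # balance to fresh/dry pairs
  key_f <- d$individual_id[d$state == "fresh"]
  key_d <- d$individual_id[d$state == "dry"]
  paired <- intersect(key_f, key_d)
  d <- d[d$individual_id %in% paired, ]
  if (sum(d$state == "fresh") < 3L || sum(d$state == "dry") < 3L) {
    stop("need at least 3 fresh and 3 dry records per species")
  }
  lx <- log10(d$mass_burned_g)
  ly <- log10(d$max_combustion_rate_g_s)
  if (diff(range(lx)) < 1e-12) stop("intercept unidentifiable: no mass range")
  st <- factor(d$state, levels = c("fresh", "dry"))

  m_comb <- lm(ly ~ lx)
  m_int <- lm(ly ~ lx + st)            # common slope, state intercepts
  m_full <- lm(ly ~ lx * st)           # state slopes and intercepts
  p_slope <- anova(m_int, m_full)[2L, "Pr(>F)"]
  p_intercept <- anova(m_comb, m_int)[2L, "Pr(>F)"]

  m_fresh <- lm(ly[st == "fresh"] ~ lx[st == "fresh"])
  m_dry <- lm(ly[st == "dry"] ~ lx[st == "dry"])

  use_fresh <- is.finite(p_intercept) && p_intercept < alpha
  src <- if (use_fresh) "fresh-only" else "combined"
  pick <- if (use_fresh) m_fresh else m_comb
  out <- list(
    species_id = d$species_id[1L],
    slope = unname(coef(pick)[2L]),
    y_intercept = unname(coef(pick)[1L]),
    source = src,
    p_slope_equal = p_slope,
    p_intercept_equal = p_intercept,
    fits = list(fresh = m_fresh, dry = m_dry, combined = m_comb),
    n = nrow(d))
  class(out) <- "intrinsic_combustibility"
  out
}

#' @export
print.intrinsic_combustibility <- function(x, ...) {
  cat(sprintf(
    "<intrinsic_combustibility> %s: intercept %.4f (source %s), slope %.4f\n",
    x$species_id, x$y_intercept, x$source, x$slope))
  invisible(x)
}

#' Whole-plant combustion rate by allometric extrapolation
#'
#' Extrapolates the common across-species rate-mass relationship to a species'
#' mean total biomass while keeping that species' intrinsic combustibility:
#' `log10(rate) = y_intercept + b_common * log10(total biomass)`.
#'
#' @param intrinsic An `intrinsic_combustibility` result (or its numeric
#'   `y_intercept`).
#' @param b_common The common across-species slope (e.g. the posterior mean
#'   from [bivariate_mixed_model()]).
#' @param species_mean_total_biomass_g Species mean total dry biomass, g.
#' @return Predicted whole-plant maximum combustion rate, g/s.
#' @export
whole_plant_rate <- function(intrinsic, b_common, species_mean_total_biomass_g) {
  y0 <- if (inherits(intrinsic, "intrinsic_combustibility"))
    intrinsic$y_intercept else as.numeric(intrinsic)
  if (!is.finite(b_common)) stop("b_common must be finite")
  if (any(species_mean_total_biomass_g <= 0)) {
    stop("domain error: biomass must be positive")
  }
  10^(y0 + b_common * log10(species_mean_total_biomass_g))
}
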