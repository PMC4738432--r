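test_that("leaf metrics compute TTI, FT and rate with zero-FT exclusion", {
  ev <- as_leaf_events(data.frame(
    species_id = "spA", individual_id = c("i1", "i2", "i3"), state = "dry",
    sample_mass_g = 0.2, t_application_s = 0,
    t_first_flame_s = c(4, 1, 1), t_flame_out_s = c(10, 1, 9)))
  lm_ <- leaf_metrics(ev)
  expect_equal(lm_$tti_s, c(4, 1, 1))
  expect_true(lm_$excluded[2])
  expect_equal(lm_$exclude_reason[2], "no sustained flaming")
  expect_equal(lm_$combustion_rate_g_s[3], 0.2 / 8)
  expect_equal(lm_$ft_s[1], 6)
})

test_that("moisture effect pairs fresh/dry per individual and drops unpaired", {
  ev <- as_leaf_events(data.frame(
    species_id = "spA",
    individual_id = c("i1", "i1", "i2", "i2", "i3"),
    state = c("fresh", "dry", "fresh", "dry", "fresh"),
    sample_mass_g = 0.2, t_application_s = 0,
    t_first_flame_s = c(2, 1, 1.5, 1.5, 9),
    t_flame_out_s = c(8, 8, 8, 8, 12)))
  lf <- leaf_metrics(ev)
  expect_warning(me <- moisture_effect(lf), "unpaired")
  expect_equal(nrow(me$individual), 2L)
  expect_equal(me$individual$d_tti_s, c(1, 0))
  expect_equal(me$species$d_tti_s, 0.5)
  # a 42% fresh/dry ratio shows up as ~42% mean increase
  ev2 <- as_leaf_events(data.frame(
    species_id = "spB", individual_id = rep(paste0("i", 1:5), 2),
    state = rep(c("dry", "fresh"), each = 5),
    sample_mass_g = 0.2, t_application_s = 0,
    t_first_flame_s = c(1, 1.2, 0.9, 1.1, 1, 1.42 * c(1, 1.2, 0.9, 1.1, 1)),
    t_flame_out_s = 20))
  me2 <- moisture_effect(leaf_metrics(ev2))
  expect_equal(me2$species$tti_increase_pct, 42, tolerance = 1e-9)
})

test_that("noiseless Boltzmann curves are recovered to solver precision", {
  s <- make_series(A1 = 2, A2 = 0.2, t0 = 30, dx = 5)
  f <- fit_boltzmann(s)
  expect_true(f$converged)
  expect_false(f$excluded)
  expect_equal(f$A1, 2, tolerance = 1e-6)
  expect_equal(f$A2, 0.2, tolerance = 1e-6)
  expect_equal(f$t0, 30, tolerance = 1e-6)
  expect_equal(f$dx, 5, tolerance = 1e-6)
  # flaming time at plant scale is the width parameter itself
  pm <- plant_metrics(list(s))
  expect_equal(pm$flaming_time_s, f$dx, tolerance = 1e-6)
  # fixed point: refitting the fitted curve returns the same parameters
  s2 <- mass_loss_series("i1", "dry", s$time,
                         boltzmann(s$time, f$A1, f$A2, f$t0, f$dx),
                         species_id = "spX")
  f2 <- fit_boltzmann(s2)
  expect_equal(c(f2$A1, f2$A2, f2$t0, f2$dx), c(f$A1, f$A2, f$t0, f$dx),
               tolerance = 1e-6)
})

test_that("noisy Boltzmann fits match the grid-refined oracle optimum", {
  set.seed(31)
  for (rep in 1:4) {
    s <- make_series(A1 = 2, A2 = 0.2, t0 = 30, dx = 5, noise_sd = 0.01)
    f <- fit_boltzmann(s)
    o <- oracle_boltzmann(s$time, s$mass)
    # both optimizers should land on the same RSS basin
    expect_lte(f$rss, o$rss * (1 + 1e-6))
    expect_equal(f$dx, o$dx, tolerance = 1e-3)
    expect_equal(f$t0, o$t0, tolerance = 1e-3)
  }
})

test_that("heavily corrupted series are excluded for lack of fit", {
  set.seed(5)
  tt <- seq(0, 60, 0.2)
  mm <- 2 - 0.03 * tt + rnorm(length(tt), 0, 0.4)   # not sigmoidal
  mm <- pmax(mm, 0); mm[length(mm)] <- min(mm[length(mm)], mm[1])
  s <- mass_loss_series("i1", "dry", tt, mm, species_id = "spX")
  f <- fit_boltzmann(s)
  expect_true(f$excluded)
  expect_equal(f$exclude_reason, "noise around the curve")
})

test_that("windowed combustion rate matches the analytic-curve oracle", {
  s <- make_series(A1 = 2, A2 = 0.2, t0 = 30, dx = 5)
  f <- fit_boltzmann(s)
  r <- max_combustion_rate(s, f, window_s = 3)
  o <- oracle_window_rate(s$time, s$mass, f$t0, window = 3)
  expect_equal(r, unname(o), tolerance = 1e-9)
  # near, but below, the tangent rate (A1-A2)/(4 dx)
  expect_lt(abs(r - 1.8 / 20) / (1.8 / 20), 0.05)
  # invariant to adding a constant mass offset
  s2 <- mass_loss_series("i1", "dry", s$time, s$mass + 5, species_id = "spX")
  expect_equal(max_combustion_rate(s2, f), r, tolerance = 1e-12)
  # quasi-linear limit: slope tends to the linear decline rate
  slin <- make_series(A1 = 10, A2 = 0, t0 = 150, dx = 120, tmax = 300)
  flin <- list(t0 = 150); class(flin) <- "boltzmann_fit"
  rlin <- max_combustion_rate(slin, flin)
  expect_equal(rlin, 10 / (4 * 120), tolerance = 1e-3)
  # inflection outside the record errors
  expect_error(max_combustion_rate(s, list(t0 = 99) |>
                                     structure(class = "boltzmann_fit")),
               "outside")
})

test_that("intrinsic combustibility reproduces exact allometries and the fresh-only rule", {
  mk <- function(int_f, int_d, slope = 0.6, n = 6, sd = 0) {
    m <- rep(10^seq(0, 1, length.out = n), 2)
    st <- rep(c("fresh", "dry"), each = n)
    ints <- ifelse(st == "fresh", int_f, int_d)
    r <- 10^(ints + slope * log10(m) + rnorm(2 * n, 0, sd))
    out <- data.frame(species_id = "spA",
                      individual_id = rep(paste0("i", 1:n), 2),
                      state = st, flaming_time_s = 5,
                      max_combustion_rate_g_s = r, mass_burned_g = m,
                      r_squared = 1, excluded = FALSE, exclude_reason = "")
    class(out) <- c("plant_flammability", class(out))
    out
  }
  # identical states: combined intercept recovered exactly
  ic <- intrinsic_combustibility(mk(-1, -1))
  expect_equal(ic$y_intercept, -1, tolerance = 1e-10)
  expect_equal(ic$slope, 0.6, tolerance = 1e-10)
  expect_equal(ic$source, "combined")
  # clearly separated intercepts force the fresh-only rule
  set.seed(8)
  ic2 <- intrinsic_combustibility(mk(-1, -0.7, sd = 0.01))
  expect_equal(ic2$source, "fresh-only")
  expect_equal(ic2$y_intercept, -1, tolerance = 0.05)
  # coefficients and F-test decisions match an independent lm/anova oracle
  set.seed(9)
  d <- mk(-1, -0.95, sd = 0.05)
  ic3 <- intrinsic_combustibility(d)
  lx <- log10(d$mass_burned_g); ly <- log10(d$max_combustion_rate_g_s)
  o_comb <- oracle_ols(lx, ly)
  expect_equal(ic3$p_slope_equal,
               anova(lm(ly ~ lx + d$state), lm(ly ~ lx * d$state))[2, "Pr(>F)"],
               tolerance = 1e-10)
  if (ic3$source == "combined") {
    expect_equal(ic3$y_intercept, unname(o_comb["intercept"]),
                 tolerance = 1e-10)
  }
  # degenerate mass range
  dd <- mk(-1, -1); dd$mass_burned_g <- 3
  expect_error(intrinsic_combustibility(dd), "unidentifiable")
})

test_that("whole-plant extrapolation is log-linear in biomass", {
  expect_equal(whole_plant_rate(-1, 0.797, 1), 0.1)
  expect_equal(whole_plant_rate(-1, 0.797, 10), 10^(-1 + 0.797),
               tolerance = 1e-12)
  expect_equal(whole_plant_rate(-1, 0.797, 10), 0.627, tolerance = 1e-3)
  # doubling biomass multiplies the rate by 2^b
  r1 <- whole_plant_rate(-0.5, 0.7, 8)
  r2 <- whole_plant_rate(-0.5, 0.7, 16)
  expect_equal(r2 / r1, 2^0.7, tolerance = 1e-12)
  expect_error(whole_plant_rate(-1, 0.797, -2), "biomass")
  expect_error(whole_plant_rate(-1, NA, 2), "finite")
})
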