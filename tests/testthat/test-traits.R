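test_that("moisture content follows (fresh - dry)/dry with domain checks", {
  expect_equal(moisture_content(1.5, 1.0), 0.5)
  expect_equal(moisture_content(1.0, 1.0), 0.0)
  expect_equal(moisture_content(2.0, 0.8), 1.5)
  expect_error(moisture_content(1, 0), "dry_mass")
  expect_error(moisture_content(0.5, 1), "tolerance")
  # within-tolerance undershoot clamps to zero
  expect_equal(moisture_content(0.995, 1.0), 0)
})

test_that("leaf SA/V is 2/thickness under the flat-slab model", {
  expect_equal(leaf_sav(500, 0.2), 10)
  expect_equal(leaf_sav(123, 0.5), 4)       # area cancels
  expect_equal(leaf_sav(500, 0.5), 4)
  expect_error(leaf_sav(500, 0), "thickness")
  expect_error(leaf_sav(0, 0.2), "area")
})

test_that("density slope recovers exact log-linear and power-law profiles", {
  # log10 C(h) = -1 + 0.05 h at h in {5,...,30}
  h <- seq(5, 30, 5)
  cum <- 10^(-1 + 0.05 * h)
  p <- vertical_profile("i1", h, diff(c(0, cum)))
  f <- density_slope(p)
  expect_equal(f$slope, 0.05, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # uniform vertical density: C(h) proportional to h -> log-log slope 1
  cum2 <- 0.3 * h
  p2 <- vertical_profile("i2", h, diff(c(0, cum2)))
  f2 <- density_slope(p2, mode = "log-log")
  expect_equal(f2$slope, 1.0, tolerance = 1e-12)
})

test_that("density slope equals the normal-equations oracle on noisy data", {
  set.seed(4)
  for (rep in 1:5) {
    h <- seq(10, 60, 10)
    cum <- 10^(-0.5 + 0.04 * h + rnorm(6, 0, 0.05))
    cum <- cummax(cum)  # keep interval masses nonnegative
    p <- vertical_profile("i1", h, diff(c(0, cum)), allowed_intervals = NULL)
    f <- density_slope(p)
    o <- oracle_ols(h, log10(cum))
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
})

test_that("density slope is invariant to scaling all masses", {
  h <- seq(5, 40, 5)
  m <- diff(c(0, 10^(-1 + 0.03 * h))) * exp(rnorm(8, 0, 0.1))
  p1 <- vertical_profile("i1", h, m)
  p2 <- vertical_profile("i1", h, m * 7.3)
  f1 <- density_slope(p1); f2 <- density_slope(p2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log10(7.3), tolerance = 1e-12)
})

test_that("zero-mass points are dropped with warning; too few points error", {
  h <- seq(5, 30, 5)
  m <- c(0, 0, 1, 2, 3, 4)      # cumulative mass 0 at first two heights
  p <- suppressWarnings(vertical_profile("i1", h, m))
  expect_warning(f <- density_slope(p), "dropping")
  expect_equal(f$n_points, 4L)
  p2 <- suppressWarnings(vertical_profile("i2", c(5, 10, 15), c(0, 0, 1)))
  expect_error(suppressWarnings(density_slope(p2)), "fewer than 3")
})

test_that("EHoC averages heat release per unit mass across replicates", {
  expect_equal(ehoc_mean(100, 5), 20)
  expect_equal(ehoc_mean(c(20, 22), c(1, 1)), 21)
  ind <- ehoc_mean(c(21, 19, 20), c(1, 1, 1), individual = c("a", "b", "c"))
  expect_equal(mean(ind), 20)
  expect_error(ehoc_mean(10, 0), "mass")
})

test_that("species aggregation matches a group-by oracle and is permutation-invariant", {
  set.seed(9)
  df <- data.frame(species_id = rep(c("spA", "spB", "spC"), each = 4),
                   individual_id = rep(paste0("i", 1:4), 3),
                   trait1 = rnorm(12, 10), trait2 = runif(12))
  agg <- aggregate_species(df)
  # oracle group-by
  for (sp in unique(df$species_id)) {
    sub <- df[df$species_id == sp, ]
    expect_equal(agg$trait1[agg$species_id == sp], mean(sub$trait1),
                 tolerance = 1e-12)
    expect_equal(agg$trait1_cv_pct[agg$species_id == sp],
                 100 * sd(sub$trait1) / mean(sub$trait1), tolerance = 1e-12)
  }
  # permutation invariance
  agg2 <- aggregate_species(df[sample(nrow(df)), ])
  expect_equal(agg2[order(agg2$species_id), ], agg[order(agg$species_id), ],
               ignore_attr = TRUE)
  # identical individuals -> CV 0; two individuals (10, 20) -> mean 15
  df3 <- data.frame(species_id = c("s", "s", "t", "t"),
                    trait = c(5, 5, 10, 20))
  a3 <- aggregate_species(df3)
  expect_equal(a3$trait_cv_pct[a3$species_id == "s"], 0)
  expect_equal(a3$trait[a3$species_id == "t"], 15)
})

test_that("individual_traits assembles the five traits with derived fuel load", {
  b <- small_study(seed = 3, n_species = 4, n_individuals = 3)
  ti <- individual_traits(b$clumps, b$profiles, b$leaves, b$ehoc)
  expect_equal(nrow(ti), 12L)
  expect_true(all(ti$fuel_load_g_cm2 > 0))
  expect_equal(ti$fuel_load_g_cm2, ti$biomass_quantity_g / ti$cover_area_cm2)
  # moisture matches the clump masses
  expect_equal(ti$moisture_content,
               (b$clumps$fresh_mass_g - b$clumps$dry_mass_g) /
                 b$clumps$dry_mass_g)
  # density slope recovers each individual's generating slope exactly
  truth <- vapply(paste(ti$species_id, ti$individual_id, sep = "."),
                  function(k) b$truth$individuals[[k]]$biomass_density_slope,
                  numeric(1))
  expect_equal(ti$biomass_density_slope, unname(truth), tolerance = 1e-9)
})
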