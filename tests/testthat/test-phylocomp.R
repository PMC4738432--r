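test_that("phylo covariance encodes shared path lengths scaled by lambda", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", nwk)
  tr <- read_newick(nwk)
  v1 <- phylo_covariance(tr, 1)
  expect_equal(v1["A", "B"], 1)
  expect_equal(v1["A", "C"], 0)
  expect_equal(diag(v1), c(A = 2, B = 2, C = 2))
  # lambda scales off-diagonals only
  v5 <- phylo_covariance(tr, 0.5)
  expect_equal(v5["A", "B"], 0.5)
  expect_equal(diag(v5), diag(v1))
  v0 <- phylo_covariance(tr, 0)
  expect_true(all(v0[upper.tri(v0)] == 0))
  expect_error(phylo_covariance(tr, 1.2), "lambda")
  # two-tip tree with zero shared stem
  writeLines("(A:1,B:1):0;", nwk)
  tr2 <- read_newick(nwk)
  expect_equal(phylo_covariance(tr2, 1)["A", "B"], 0)
})

test_that("Brownian covariance equals the pairwise-MRCA oracle", {
  set.seed(2)
  for (n in c(10, 40)) {
    tr <- gen_tree(n)
    v <- phylo_covariance(tr, 1)
    o <- oracle_vcv(tr)
    expect_equal(v[tr$tip.label, tr$tip.label],
                 o[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("PGLS with lambda 0 equals OLS and matrix-inverse GLS matches whitening", {
  set.seed(3)
  tr <- gen_tree(30)
  x <- rnorm(30)
  y <- setNames(1 + 0.4 * x + rnorm(30, 0, 0.3), tr$tip.label)
  f0 <- pgls_fit(y, matrix(x, ncol = 1), tr, lambda = 0)
  o <- oracle_ols(x, unname(y))
  expect_equal(f0$coefficients$estimate, unname(o), tolerance = 1e-8)
  # dual-algorithm: Cholesky whitening vs direct inverse at lambda = 0.7
  f7 <- pgls_fit(y, matrix(x, ncol = 1), tr, lambda = 0.7)
  V <- phylo_covariance(tr, 0.7)
  og <- oracle_gls(unname(y), cbind(1, x), V)
  expect_equal(f7$coefficients$estimate, unname(og), tolerance = 1e-9)
  # log-likelihood invariant to consistent reordering of species
  perm <- sample(30)
  fperm <- pgls_fit(y[perm], matrix(x[perm], ncol = 1,
                                    dimnames = list(NULL, "x1")), tr,
                    lambda = 0.7)
  expect_equal(fperm$logLik, f7$logLik, tolerance = 1e-9)
  expect_error(pgls_fit(y, cbind(x, x), tr, lambda = 0.5), "rank")
})

test_that("PGLS recovers a known slope within its standard errors", {
  set.seed(41)
  hits <- 0L; n_rep <- 60L
  for (i in seq_len(n_rep)) {
    tr <- gen_tree(100)
    x <- rnorm(100)
    y <- setNames(1 + 0.5 * x +
                    MASS::mvrnorm(1, rep(0, 100),
                                  0.5 * phylo_covariance(tr, 1)),
                  tr$tip.label)
    f <- pgls_fit(y, matrix(x, ncol = 1), tr, lambda = 1)
    est <- f$coefficients["x1", ]
    hits <- hits + (abs(est$estimate - 0.5) <= 3 * est$se)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("lambda estimation finds boundaries and interior maxima", {
  set.seed(6)
  tr <- gen_tree(80)
  # Brownian trait: lambda near 1
  yb <- setNames(MASS::mvrnorm(1, rep(0, 80), phylo_covariance(tr, 1)),
                 tr$tip.label)
  eb <- estimate_lambda(yb, tr)
  expect_gte(eb$lambda_ml, 0.8)
  expect_gte(eb$p_vs_1, 0.05)
  # tree-independent trait: lambda near 0
  y0 <- setNames(rnorm(80), tr$tip.label)
  e0 <- estimate_lambda(y0, tr)
  expect_lte(e0$lambda_ml, 0.2)
  # profile likelihood never exceeds the reported maximum on a grid
  grid_ll <- vapply(seq(0, 1, 0.1), function(l)
    pgls_fit(yb, matrix(1, 80, 0), tr, lambda = l)$logLik, numeric(1))
  expect_true(all(grid_ll <= eb$logLik_ml + 1e-6))
  # logLik at the optimum dominates both boundaries
  expect_gte(eb$logLik_ml, max(eb$logLik_0, eb$logLik_1) - 1e-8)
  # star tree: flat likelihood warning
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  ys <- setNames(rnorm(8), star$tip.label)
  expect_warning(estimate_lambda(ys, star), "star tree")
})

test_that("lambda estimate agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tr <- gen_tree(60)
  y <- setNames(MASS::mvrnorm(1, rep(0, 60), phylo_covariance(tr, 0.6)),
                tr$tip.label)
  mine <- estimate_lambda(y, tr)
  ref <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(mine$lambda_ml, ref$lambda, tolerance = 1e-3)
  expect_equal(mine$logLik_ml, ref$logL, tolerance = 1e-4)
})

test_that("HPD intervals are shortest and contain the mean for unimodal draws", {
  set.seed(10)
  x <- rnorm(4000)
  h <- hpd_interval(x)
  expect_lt(h[1], mean(x)); expect_gt(h[2], mean(x))
  expect_equal(mean(x >= h[1] & x <= h[2]), 0.95, tolerance = 0.01)
  # for a skewed distribution the HPD is shorter than the quantile interval
  xs <- rexp(4000)
  hs <- hpd_interval(xs)
  qs <- quantile(xs, c(0.025, 0.975))
  expect_lt(diff(hs), diff(qs))
})

test_that("bivariate mixed model separates within- and across-species slopes", {
  set.seed(12)
  tr <- gen_tree(25, seed = 120)
  Ssp <- sigma_from_slope(0.5, 0.8, 0.1)
  Sre <- sigma_from_slope(0.3, 0.6, 0.05)
  d <- sim_bivariate(tr, 14, Ssp, Sre)
  f <- do.call(bivariate_mixed_model,
               c(list(x = d$x, y = d$y, species = d$species, tree = tr),
                 fast_mcmc))
  s <- f$summary
  w <- s[s$parameter == "b_within", ]
  a <- s[s$parameter == "b_across", ]
  expect_lt(abs(w$mean - 0.6), 0.1)
  expect_true(a$hpd_lower <= 0.8 && 0.8 <= a$hpd_upper)
  # HPDs contain the posterior means
  expect_true(all(s$hpd_lower <= s$mean & s$mean <= s$hpd_upper))
  # two chains with different seeds agree within Monte-Carlo error
  set.seed(77)
  f2 <- do.call(bivariate_mixed_model,
                c(list(x = d$x, y = d$y, species = d$species, tree = tr),
                  fast_mcmc))
  s2 <- f2$summary
  for (p in c("b_within", "b_across")) {
    m1 <- s[s$parameter == p, ]; m2 <- s2[s2$parameter == p, ]
    mcse <- sqrt(var(f$draws[, p]) / m1$ess + var(f2$draws[, p]) / m2$ess)
    expect_lt(abs(m1$mean - m2$mean), 4 * mcse)
  }
})

test_that("diagonal generating covariances give slopes straddling zero", {
  set.seed(19)
  tr <- gen_tree(20, seed = 21)
  d <- sim_bivariate(tr, 8, diag(c(0.5, 0.5)), diag(c(0.3, 0.3)))
  f <- do.call(bivariate_mixed_model,
               c(list(x = d$x, y = d$y, species = d$species, tree = tr),
                 fast_mcmc))
  s <- f$summary
  for (p in c("b_within", "b_across")) {
    row <- s[s$parameter == p, ]
    expect_true(row$hpd_lower <= 0 && 0 <= row$hpd_upper, label = p)
  }
})
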