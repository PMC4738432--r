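# simulation helpers shared across test files

# noiseless Boltzmann mass-loss series
make_series <- function(A1 = 2, A2 = 0.2, t0 = 30, dx = 5, tmax = 60,
                        by = 0.2, noise_sd = 0, state = "dry", id = "i1") {
  tt <- seq(0, tmax, by = by)
  mm <- grassflam::boltzmann(tt, A1, A2, t0, dx)
  if (noise_sd > 0) mm <- mm + rnorm(length(tt), 0, noise_sd)
  if (mm[length(mm)] > mm[1L]) mm[length(mm)] <- mm[1L]
  grassflam::mass_loss_series(id, state, tt, pmax(mm, 0), species_id = "spX")
}

# bivariate mixed-model data with known within/across-species slopes:
# Sigma_sp implies across slope sp_xy/sp_xx, Sigma_res the within slope
sim_bivariate <- function(tree, n_per, Sigma_sp, Sigma_res) {
  S <- length(tree$tip.label)
  C <- grassflam::phylo_covariance(tree, 1)
  U <- t(chol(Sigma_sp)) %*% matrix(rnorm(2 * S), 2, S) %*% chol(C)
  sp <- rep(tree$tip.label, each = n_per)
  E <- MASS::mvrnorm(S * n_per, c(0, 0), Sigma_res)
  d <- t(U)[rep(seq_len(S), each = n_per), ] + E
  list(x = d[, 1L] + 1, y = d[, 2L] - 1, species = sp)
}

sigma_from_slope <- function(var_x, slope, extra_var_y) {
  matrix(c(var_x, slope * var_x, slope * var_x,
           slope^2 * var_x + extra_var_y), 2, 2)
}

# small complete synthetic study for pipeline-level tests
small_study <- function(seed = 42, n_species = 25, n_individuals = 7) {
  grassflam::gen_study(grassflam::generator_spec(
    n_species = n_species, n_individuals = n_individuals, seed = seed))
}

fast_mcmc <- list(n_iter = 3000L, burnin = 500L, thin = 5L,
                  prior_V = 2, prior_nu = 0.002)
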