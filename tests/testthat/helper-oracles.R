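# Independent oracles, coded separately from the package internals.

# ordinary least squares by the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = b[1L], slope = b[2L])
}

# Brownian phylogenetic covariance from pairwise MRCA root-path lengths
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  m <- ape::mrca(tree)
  v <- matrix(depth[m], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(v) <- depth[seq_len(n)]
  v
}

# GLS coefficients by the direct matrix-inverse formula
oracle_gls <- function(y, X, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}

# second, independent transcription of the surface fire-spread chain,
# written straight down in SI-converted imperial units as one expression path
oracle_ros <- function(sav_m2_m3, heat_kj_kg, load_kg_m2, depth_m, moisture,
                       mx, st = 0.0555, se = 0.010, rho_p_si = 512.6,
                       wind_ms = 0, slope_frac = 0) {
  s <- sav_m2_m3 * 0.3048
  h <- heat_kj_kg / 2.326            # kJ/kg -> BTU/lb (1 BTU/lb = 2.326 kJ/kg)
  w0 <- load_kg_m2 / 4.882427636383  # kg/m2 -> lb/ft2
  d <- depth_m / 0.3048
  rp <- rho_p_si / 16.01846337396    # kg/m3 -> lb/ft3
  u <- wind_ms / 0.00508             # m/s -> ft/min (1 ft/min = 0.00508 m/s)

  rb <- w0 / d
  b <- rb / rp
  bop <- 3.348 / s^0.8189
  gmax <- 1 / (495 / s^1.5 + 0.0594)
  aa <- 133 / s^0.7913
  g <- gmax * exp(aa * (log(b / bop) + 1 - b / bop))
  rm <- moisture / mx
  etam <- if (rm >= 1) 0 else 1 - 2.59 * rm + 5.11 * rm^2 - 3.52 * rm^3
  etas <- min(0.174 / se^0.19, 1)
  ir <- g * (w0 * (1 - st)) * h * etam * etas
  xi <- exp((0.792 + 0.681 * s^0.5) * (b + 0.1)) / (192 + 0.2595 * s)
  phw <- if (u > 0) {
    7.47 * exp(-0.133 * s^0.55) * u^(0.02526 * s^0.54) *
      (b / bop)^(-0.715 * exp(-3.59e-4 * s))
  } else 0
  phs <- if (slope_frac > 0) 5.275 * slope_frac^2 / b^0.3 else 0
  eps <- exp(-138 / s)
  qig <- 250 + 1116 * moisture
  ir * xi * (1 + phw + phs) / (rb * eps * qig) * 0.3048   # ft/min -> m/min
}

# grid-refined least-squares Boltzmann oracle: the model is linear in the
# asymptotes given (t0, dx), so profile those two on a grid and polish
oracle_boltzmann <- function(time, mass) {
  rss_of <- function(t0, dx) {
    s <- 1 / (1 + exp((time - t0) / dx))
    X <- cbind(s, 1 - s)            # columns: A1, A2
    b <- tryCatch(qr.solve(X, mass), error = function(e) return(NULL))
    if (is.null(b)) return(Inf)
    sum((mass - X %*% b)^2)
  }
  t0g <- seq(min(time), max(time), length.out = 60)
  dxg <- exp(seq(log(diff(range(time)) / 200), log(diff(range(time)) / 2),
                 length.out = 40))
  grid <- expand.grid(t0 = t0g, dx = dxg)
  rss <- mapply(rss_of, grid$t0, grid$dx)
  st <- grid[which.min(rss), ]
  op <- optim(c(st$t0, st$dx), function(p) rss_of(p[1L], p[2L]),
              method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 5000))
  s <- 1 / (1 + exp((time - op$par[1L]) / op$par[2L]))
  b <- qr.solve(cbind(s, 1 - s), mass)
  list(A1 = b[1L], A2 = b[2L], t0 = op$par[1L], dx = op$par[2L],
       rss = op$value)
}

# windowed-regression combustion-rate oracle on an analytic curve
oracle_window_rate <- function(time, mass, t0, window = 3) {
  sel <- time >= t0 - window & time <= t0 + window
  abs(oracle_ols(time[sel], mass[sel])["slope"])
}

# random valid fuel model for the dual-transcription check
random_fuel_model <- function() {
  fm <- list(sav_m2_m3 = runif(1, 2000, 20000),
             heat_kj_kg = runif(1, 14000, 24000),
             load_kg_m2 = runif(1, 0.05, 3),
             depth_m = runif(1, 0.1, 1.5),
             moisture = runif(1, 0, 0.6),
             mx = 0.25, total_mineral = 0.0555, effective_mineral = 0.010,
             particle_density_kg_m3 = 512.6)
  class(fm) <- "fuel_model"
  fm
}
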