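# Synthetic-study generator. Emulates the full experimental design with
# known ground truth: 25 species x 7 individuals on a Yule phylogeny,
# species trait values evolved under a lambda-scaled Brownian model, fresh
# and dry clump pairs, log-linear vertical biomass profiles, leaf burn
# events with a configurable fresh/dry ignition-delay ratio, and Boltzmann
# mass-loss series logged at 0.2-s intervals with Gaussian noise.

#' Generator specification with study-design defaults
#'
#' Returns the full set of knobs for the synthetic study. Defaults mirror the
#' study design: 25 species, 7 individuals each, fresh/dry pairs, 0.2-s mass
#' logging, vertical profile intervals from {2.5, 5, 10, 15} cm, a fresh/dry
#' ignition-delay ratio of 1.42 (fresh leaves take 42% longer to ignite),
#' fresh flaming 7% longer, and strong phylogenetic signal (lambda = 1) in
#' leaf SA/V only. One species is given a high moisture content so that the
#' spread model predicts no fire for it, as happens for a wet invasive grass.
#'
#' @param n_species,n_individuals Study dimensions.
#' @param seed Master seed; each generation stage draws from an offset of it.
#' @param traits Per-trait generation settings: `lambda`, `range` (species
#'   means are Brownian values rescaled into this range), and `log10` (range
#'   given on the log10 scale).
#' @param cv_within Within-species coefficient of variation for individual
#'   draws around species means.
#' @param tti_ratio_fresh_dry Multiplier on dry ignition delay for fresh
#'   samples.
#' @param ft_ratio_fresh_dry Multiplier on dry flaming time for fresh
#'   samples.
#' @param high_moisture_species Index of the species whose moisture content
#'   is forced to `high_moisture_value` (set `NULL` to disable).
#' @param high_moisture_value Moisture content (g/g) of that species.
#' @param noise_sd_mass Gaussian noise sd (g) on the logged mass-loss series.
#' @param sampling_interval_s Mass-logging interval.
#' @param burn_fraction_range Fraction of a clump burned in a plant-scale
#'   test (uniform draw).
#' @param ash_fraction Residual (lower-asymptote) mass fraction.
#' @param dx_base_s Base width parameter of the mass-loss sigmoid before the
#'   trait couplings (moisture increases it, SA/V and a mild mass allometry
#'   modulate it).
#' @param profile_intervals_cm Permitted vertical profile interval lengths.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_species = 25L, n_individuals = 7L, seed = 1L,
                           traits = list(
                             biomass_quantity_g = list(lambda = 0, range = c(1, 2.2), log10 = TRUE),
                             biomass_density_slope = list(lambda = 0, range = c(0.02, 0.08)),
                             moisture_content = list(lambda = 0, range = c(0.05, 0.22)),
                             leaf_sav_mm = list(lambda = 1, range = c(4, 20)),
                             leaf_ehoc_kj_g = list(lambda = 0, range = c(16, 22)),
                             height_cm = list(lambda = 0, range = c(25, 90)),
                             width_cm = list(lambda = 0, range = c(15, 60)),
                             tti_dry_s = list(lambda = 0, range = c(0.8, 2.8)),
                             ft_dry_s = list(lambda = 0, range = c(4, 8))),
                           cv_within = 0.15,
                           tti_ratio_fresh_dry = 1.42,
                           ft_ratio_fresh_dry = 1.07,
                           high_moisture_species = 1L,
                           high_moisture_value = 0.45,
                           noise_sd_mass = 0.01,
                           sampling_interval_s = 0.2,
                           burn_fraction_range = c(0.3, 0.9),
                           ash_fraction = 0.08,
                           dx_base_s = 6,
                           profile_intervals_cm = c(2.5, 5, 10, 15)) {
  spec <- as.list(environment())
  class(spec) <- c("generator_spec", "list")
  spec
}

#' Simulate an ultrametric Yule tree rescaled to unit depth
#'
#' @param n Number of tips (>= 2); tips are labelled `sp01`, `sp02`, ...
#' @param seed Optional seed set before simulation.
#' @return An [ape::phylo] object with all tips at depth 1.
#' @export
gen_tree <- function(n, seed = NULL) {
  if (n < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

# simulate one trait on the tree under a lambda-transformed Brownian model,
# then rescale affinely into the requested range (an affine map preserves
# the correlation structure, hence lambda)
.sim_trait <- function(tree, lambda, range, log10scale = FALSE, sigma2 = 1) {
  n <- length(tree$tip.label)
  if (sigma2 <= 0) {
    v <- rep(mean(range), n)
  } else {
    V <- phylo_covariance(tree, lambda) * sigma2
    z <- MASS::mvrnorm(1, rep(0, n), V)
    if (diff(range(z)) < 1e-12) {
      v <- rep(mean(range), n)
    } else {
      v <- (z - min(z)) / diff(range(z)) * diff(range) + range[1L]
    }
  }
  if (log10scale) v <- 10^v
  names(v) <- tree$tip.label
  v
}

#' Simulate species mean traits on a phylogeny
#'
#' Each trait evolves under Brownian motion with its own Pagel's lambda
#' transform and is affinely rescaled into its configured range (which
#' preserves lambda). The generating lambda values are stored as ground
#' truth. The designated high-moisture species override is applied last.
#'
#' @param tree An [ape::phylo] from [gen_tree()].
#' @param spec A [generator_spec()].
#' @return A list with `species` (data frame of species mean traits) and
#'   `truth` (per-trait generating lambda and range).
#' @export
gen_species_traits <- function(tree, spec = generator_spec()) {
  n <- length(tree$tip.label)
  cols <- lapply(names(spec$traits), function(tn) {
    tspec <- spec$traits[[tn]]
    .sim_trait(tree, tspec$lambda, tspec$range,
               log10scale = isTRUE(tspec$log10),
               sigma2 = if (is.null(tspec$sigma2)) 1 else tspec$sigma2)
  })
  names(cols) <- names(spec$traits)
  df <- data.frame(species_id = tree$tip.label, cols,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(spec$high_moisture_species)) {
    df$moisture_content[spec$high_moisture_species] <- spec$high_moisture_value
  }
  truth <- lapply(spec$traits, function(t)
    list(lambda = t$lambda, range = t$range))
  list(species = df, truth = truth)
}

# multiplicative within-species noise with unit mean
.ind_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.profile_interval <- function(height, allowed) {
  ok <- allowed[floor(height / allowed) >= 5]
  if (!length(ok)) return(min(allowed))
  max(ok)
}

#' Generate the full individual-level study data
#'
#' Draws individuals around the species means, builds the fresh/dry clump
#' table, exactly log-linear vertical biomass profiles (the generating
#' density slope is recovered exactly by [density_slope()] at zero noise),
#' leaf burn events with the configured fresh/dry ignition-delay ratio, the
#' calorimeter replicate table (3 individuals per species in duplicate), and
#' Boltzmann mass-loss series for every individual in both states.
#'
#' @param species_traits Result of [gen_species_traits()].
#' @param spec A [generator_spec()].
#' @return A list with `clumps`, `leaves`, `ehoc`, `leaf_events` (data
#'   frames), `profiles`, `mass_loss` (lists), and `truth` (generating
#'   parameters per individual, including every Boltzmann parameter set).
#' @export
gen_individual_data <- function(species_traits, spec = generator_spec()) {
  sp <- species_traits$species
  nind <- spec$n_individuals
  cv <- spec$cv_within

  clump_rows <- list(); leaf_rows <- list(); ehoc_rows <- list()
  event_rows <- list(); profiles <- list(); series <- list()
  truth_ind <- list()

  for (si in seq_len(nrow(sp))) {
    spid <- sp$species_id[si]
    for (ii in seq_len(nind)) {
      iid <- sprintf("ind%02d", ii)
      key <- paste(spid, iid, sep = ".")
      biomass <- sp$biomass_quantity_g[si] * .ind_noise(1, cv)
      slope <- sp$biomass_density_slope[si] * .ind_noise(1, cv / 2)
      moist <- sp$moisture_content[si] * .ind_noise(1, cv / 2)
      sav <- sp$leaf_sav_mm[si] * .ind_noise(1, cv / 2)
      ehoc <- sp$leaf_ehoc_kj_g[si] * .ind_noise(1, cv / 3)
      height <- sp$height_cm[si] * .ind_noise(1, cv / 2)
      width <- sp$width_cm[si] * .ind_noise(1, cv / 2)

      clump_rows[[key]] <- data.frame(
        species_id = spid, individual_id = iid,
        fresh_mass_g = biomass * (1 + moist), dry_mass_g = biomass,
        height_cm = height, width_cm = width, stringsAsFactors = FALSE)

      thickness <- 2 / sav
      leaf_rows[[key]] <- data.frame(
        species_id = spid, individual_id = iid,
        mean_leaf_area_mm2 = runif(1, 200, 900),
        mean_thickness_mm = thickness, stringsAsFactors = FALSE)

      # exactly log-linear vertical profile: log10 C(h) = a + slope * h
      ilen <- .profile_interval(height, spec$profile_intervals_cm)
      k <- max(3L, floor(height / ilen))
      tops <- ilen * seq_len(k)
      a <- log10(biomass) - slope * tops[k]
      cum <- 10^(a + slope * tops)
      dmass <- diff(c(0, cum))
      profiles[[key]] <- vertical_profile(
        iid, tops, dmass, fresh_mass = dmass * (1 + moist), species_id = spid,
        allowed_intervals = spec$profile_intervals_cm)

      # leaf burn events, both states, paired within individual
      tti_dry <- sp$tti_dry_s[si] * .ind_noise(1, cv)
      tti_fresh <- tti_dry * spec$tti_ratio_fresh_dry * .ind_noise(1, 0.02)
      ft_dry <- sp$ft_dry_s[si] * .ind_noise(1, cv)
      ft_fresh <- ft_dry * spec$ft_ratio_fresh_dry * .ind_noise(1, 0.02)
      event_rows[[key]] <- data.frame(
        species_id = spid, individual_id = iid,
        state = c("dry", "fresh"), sample_mass_g = 0.2,
        t_application_s = 0,
        t_first_flame_s = c(tti_dry, tti_fresh),
        t_flame_out_s = c(tti_dry + ft_dry, tti_fresh + ft_fresh),
        stringsAsFactors = FALSE)

      # plant-scale mass-loss series, both states
      for (state in c("fresh", "dry")) {
        frac <- runif(1, spec$burn_fraction_range[1L],
                      spec$burn_fraction_range[2L])
        a1 <- frac * biomass * if (state == "fresh") (1 + moist) else 1
        a2 <- spec$ash_fraction * a1
        m_state <- if (state == "fresh") moist else 0
        dx <- spec$dx_base_s * (1 + m_state) / sqrt(sav / 10) *
          (a1 / 10)^0.25
        dx <- min(max(dx, 2), 15)
        t0 <- runif(1, 20, 40)
        tmax <- t0 + max(8 * dx, 20)
        tt <- seq(0, tmax, by = spec$sampling_interval_s)
        mm <- boltzmann(tt, a1, a2, t0, dx) +
          rnorm(length(tt), 0, spec$noise_sd_mass)
        mm <- pmax(mm, 0)
        # keep the record consistent with a monotone balance trace at the ends
        if (mm[length(mm)] > mm[1L]) mm[length(mm)] <- mm[1L]
        skey <- paste(spid, iid, state, sep = ".")
        series[[skey]] <- mass_loss_series(
          iid, state, tt, mm, species_id = spid,
          interval = spec$sampling_interval_s)
        truth_ind[[skey]] <- list(A1 = a1, A2 = a2, t0 = t0, dx = dx,
                                  burn_fraction = frac)
      }

      truth_ind[[key]] <- list(
        biomass_quantity_g = biomass, biomass_density_slope = slope,
        moisture_content = moist, leaf_sav_mm = sav,
        leaf_ehoc_kj_g = ehoc, height_cm = height, width_cm = width,
        tti_dry_s = tti_dry, tti_fresh_s = tti_fresh)
    }

    # calorimetry: 3 individuals per species, duplicate replicates
    cal_ind <- sprintf("ind%02d", seq_len(min(3L, nind)))
    for (iid in cal_ind) {
      eh <- truth_ind[[paste(spid, iid, sep = ".")]]$leaf_ehoc_kj_g
      mass <- runif(2, 0.0046, 0.0054)
      ehoc_rows[[paste(spid, iid, sep = ".")]] <- data.frame(
        species_id = spid, individual_id = iid, replicate = 1:2,
        heat_kj = eh * mass * .ind_noise(2, 0.02),
        mass_g = mass, stringsAsFactors = FALSE)
    }
  }

  clumps <- as_study_table(do.call(rbind, clump_rows), require_state = FALSE)
  leaves <- do.call(rbind, leaf_rows)
  ehoc <- do.call(rbind, ehoc_rows)
  events <- as_leaf_events(do.call(rbind, event_rows))
  rownames(clumps) <- rownames(leaves) <- rownames(ehoc) <-
    rownames(events) <- NULL
  list(clumps = clumps, leaves = leaves, ehoc = ehoc,
       leaf_events = events, profiles = profiles, mass_loss = series,
       truth = truth_ind)
}

#' Generate a complete synthetic study bundle
#'
#' Tree, species traits and individual-level data, all from one master seed
#' (each stage draws from a fixed offset of it so stages can be regenerated
#' independently).
#'
#' @param spec A [generator_spec()].
#' @return A list of class `study_bundle`: `tree`, `species`, plus all
#'   elements of [gen_individual_data()], and `truth` combining species- and
#'   individual-level generating values.
#' @export
gen_study <- function(spec = generator_spec()) {
  tree <- gen_tree(spec$n_species, seed = spec$seed)
  set.seed(spec$seed + 1000L)
  st <- gen_species_traits(tree, spec)
  set.seed(spec$seed + 2000L)
  ind <- gen_individual_data(st, spec)
  out <- c(list(tree = tree, species = st$species), ind)
  out$truth <- list(species = st$truth, individuals = ind$truth,
                    spec = spec[c("n_species", "n_individuals", "seed",
                                  "cv_within", "tti_ratio_fresh_dry",
                                  "ft_ratio_fresh_dry", "noise_sd_mass")])
  class(out) <- c("study_bundle", "list")
  out
}

#' Write a study bundle to a directory of plain-text files
#'
#' Emits `clumps.csv`, `leaves.csv`, `ehoc.csv`, `leaf_events.csv`,
#' `profiles.csv`, `mass_loss.csv`, `tree.nwk` and `truth.json`.
#'
#' @param bundle A [gen_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trait_table(bundle$clumps, file.path(dir, "clumps.csv"))
  write_trait_table(bundle$leaves, file.path(dir, "leaves.csv"))
  write_trait_table(bundle$ehoc, file.path(dir, "ehoc.csv"))
  write_trait_table(bundle$leaf_events, file.path(dir, "leaf_events.csv"))
  prof <- do.call(rbind, lapply(bundle$profiles, function(p) {
    data.frame(species_id = p$species_id, individual_id = p$individual_id,
               interval_top_cm = p$interval_top_cm, dry_mass_g = p$dry_mass,
               fresh_mass_g = if (is.null(p$fresh_mass)) NA else p$fresh_mass)
  }))
  write_trait_table(prof, file.path(dir, "profiles.csv"))
  write_mass_loss(bundle$mass_loss, file.path(dir, "mass_loss.csv"))
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a study bundle back from a directory
#' @param dir Directory written by [write_study()].
#' @return A `study_bundle` list (without `truth` unless present on disk).
#' @export
read_study <- function(dir) {
  out <- list(
    tree = read_newick(file.path(dir, "tree.nwk")),
    clumps = read_trait_table(file.path(dir, "clumps.csv"),
                              require_state = FALSE),
    leaves = read_trait_table(file.path(dir, "leaves.csv"),
                              require_state = FALSE),
    ehoc = read_trait_table(file.path(dir, "ehoc.csv"),
                            require_state = FALSE),
    leaf_events = as_leaf_events(
      .read_delim_auto(file.path(dir, "leaf_events.csv"))),
    profiles = read_profiles(file.path(dir, "profiles.csv")),
    mass_loss = read_mass_loss(file.path(dir, "mass_loss.csv")))
  out$species <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) out$truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  class(out) <- c("study_bundle", "list")
  out
}
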