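# End-to-end orchestration: traits -> burn curves -> spread model ->
# phylogenetic comparative statistics, with tidy CSV outputs and a
# sign-concordance report against the a-priori trait/flammability
# prediction matrix.

#' A-priori predicted signs of trait effects on flammability
#'
#' The hypothesis matrix of the study design: each cell is the predicted
#' direction ('+', '-', '0') of a plant trait's effect on a flammability
#' component. `NA` marks untestable combinations.
#'
#' @return A data frame with one row per (flammability trait, plant trait)
#'   pair and a `predicted` sign column.
#' @export
flam_predictions <- function() {
  f <- c("tti", "spread_rate", "flaming_time", "combustion_rate")
  traits <- c("biomass_quantity", "biomass_density", "moisture_content",
              "leaf_sav", "leaf_ehoc")
  pred <- rbind(
    tti             = c(NA,  NA,  "-", "+", "0"),
    spread_rate     = c("+", "+", "-", "+", "+"),
    flaming_time    = c("+", "-", "+", "-", "-"),
    combustion_rate = c("+", "+", "-", "+", "+"))
  out <- expand.grid(flam_trait = f, plant_trait = traits,
                     stringsAsFactors = FALSE)
  out$predicted <- mapply(function(ft, pt)
    pred[ft, match(pt, traits)], out$flam_trait, out$plant_trait)
  out[!is.na(out$predicted), ]
}

.sign_chr <- function(x, zero_tol = 0) {
  ifelse(abs(x) <= zero_tol, "0", ifelse(x > 0, "+", "-"))
}

#' Run the full analysis pipeline on a study bundle
#'
#' Stages: (1) individual and species explanatory traits; (2) leaf
#' flammability metrics and fresh/dry moisture effects; (3) plant-scale
#' Boltzmann fits, maximum combustion rates and species intrinsic
#' combustibility; (4) Rothermel spread-rate predictions per individual
#' (fresh state by default); (5) phylogenetic comparative statistics: the
#' bivariate mixed model for within/across-species slopes, whole-plant rate
#' extrapolation, PGLS trait-contribution tables at leaf and plant scale,
#' and Pagel's lambda per trait; (6) the sign-concordance report against
#' [flam_predictions()]. Outputs are written as CSVs when `out_dir` is set.
#'
#' @param bundle A `study_bundle` (from [gen_study()] or [read_study()]).
#' @param config A [run_config()] list.
#' @param out_dir Output directory for CSVs, or `NULL` to skip writing.
#' @return A list of class `pipeline_result` holding every stage's tables.
#' @export
run_pipeline <- function(bundle, config = run_config(), out_dir = NULL) {
  set.seed(config$seed)
  stage <- "traits"
  res <- tryCatch({
    ind_traits <- individual_traits(bundle$clumps, bundle$profiles,
                                    bundle$leaves, bundle$ehoc,
                                    density_mode = config$density$mode)
    sp_traits <- aggregate_species(ind_traits)

    stage <- "burncurve"
    leaf <- leaf_metrics(bundle$leaf_events)
    meffect <- moisture_effect(leaf)
    plant <- plant_metrics(bundle$mass_loss,
                           r2_min = config$boltzmann$r2_min,
                           n_starts = config$boltzmann$n_starts,
                           window_s = config$boltzmann$window_s)
    intr <- lapply(split(plant, plant$species_id), function(d)
      tryCatch(intrinsic_combustibility(d), error = function(e) NULL))
    intr <- intr[!vapply(intr, is.null, logical(1))]
    intr_df <- do.call(rbind, lapply(intr, function(x) data.frame(
      species_id = x$species_id, y_intercept = x$y_intercept,
      slope = x$slope, source = x$source,
      p_slope_equal = x$p_slope_equal,
      p_intercept_equal = x$p_intercept_equal,
      stringsAsFactors = FALSE)))
    rownames(intr_df) <- NULL

    stage <- "rothermel"
    spread <- do.call(rbind, lapply(seq_len(nrow(ind_traits)), function(i) {
      r <- spread_rate(build_fuel_model(ind_traits[i, ], config$rothermel),
                       wind_ms = config$rothermel$wind_ms,
                       slope_frac = config$rothermel$slope_frac)
      data.frame(species_id = ind_traits$species_id[i],
                 individual_id = ind_traits$individual_id[i],
                 spread_rate_m_min = r$spread_rate_m_min,
                 moisture_damping = r$moisture_damping,
                 reaction_intensity = r$reaction_intensity,
                 stringsAsFactors = FALSE)
    }))

    stage <- "phylocomp"
    ok <- !plant$excluded & is.finite(plant$mass_burned_g) &
      plant$mass_burned_g > 0 & is.finite(plant$max_combustion_rate_g_s)
    biv <- bivariate_mixed_model(
      x = log10(plant$mass_burned_g[ok]),
      y = log10(plant$max_combustion_rate_g_s[ok]),
      species = plant$species_id[ok], tree = bundle$tree,
      n_iter = config$mcmc$n_iter, burnin = config$mcmc$burnin,
      thin = config$mcmc$thin, prior_V = config$mcmc$prior_V,
      prior_nu = config$mcmc$prior_nu)
    b_across <- biv$summary$mean[biv$summary$parameter == "b_across"]

    wp <- merge(intr_df[, c("species_id", "y_intercept")],
                sp_traits[, c("species_id", "biomass_quantity_g")])
    wp$whole_plant_rate_g_s <- whole_plant_rate(
      wp$y_intercept, b_across, wp$biomass_quantity_g)

    # species-mean response tables for the PGLS trait-contribution fits
    leaf_sp <- aggregate_species(leaf[!leaf$excluded & leaf$state == "fresh",
                                      c("species_id", "tti_s", "ft_s",
                                        "combustion_rate_g_s")])
    plant_sp <- aggregate_species(plant[!plant$excluded,
                                        c("species_id", "flaming_time_s",
                                          "max_combustion_rate_g_s")])
    spread_sp <- aggregate_species(spread[, c("species_id",
                                              "spread_rate_m_min")])
    pgls_tabs <- .pgls_tables(sp_traits, leaf_sp, plant_sp, spread_sp,
                              meffect$species, bundle$tree)
    lam_tab <- .lambda_table(sp_traits, leaf_sp, plant_sp, bundle$tree)
    concord <- .sign_concordance(pgls_tabs)

    stage <- "summary"
    species_summary <- Reduce(function(a, b) merge(a, b, all = TRUE), list(
      sp_traits,
      setNames(leaf_sp[, c("species_id", "tti_s", "ft_s",
                           "combustion_rate_g_s")],
               c("species_id", "leaf_tti_s", "leaf_ft_s", "leaf_rate_g_s")),
      setNames(plant_sp[, c("species_id", "flaming_time_s",
                            "max_combustion_rate_g_s")],
               c("species_id", "plant_flaming_time_s", "plant_rate_g_s")),
      setNames(spread_sp[, c("species_id", "spread_rate_m_min")],
               c("species_id", "spread_rate_m_min")),
      wp[, c("species_id", "whole_plant_rate_g_s")]))

    exclusions <- data.frame(
      stage = c("leaf", "plant"),
      n_in = c(nrow(leaf), nrow(plant)),
      n_excluded = c(sum(leaf$excluded), sum(plant$excluded)))

    list(individual_traits = ind_traits, species_traits = sp_traits,
         leaf = leaf, moisture_effect = meffect, plant = plant,
         intrinsic = intr_df, spread = spread, bivariate = biv,
         whole_plant = wp, pgls = pgls_tabs, lambda_signal = lam_tab,
         sign_concordance = concord, species_summary = species_summary,
         exclusions = exclusions, config = config)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
  class(res) <- c("pipeline_result", "list")
  if (!is.null(out_dir)) .write_pipeline(res, out_dir)
  res
}

# PGLS trait-contribution tables, leaf and plant scale
.pgls_tables <- function(sp_traits, leaf_sp, plant_sp, spread_sp, meffect_sp,
                         tree) {
  rows <- list()
  fit_one <- function(resp_name, flam_trait, y_df, y_col, X_cols) {
    d <- merge(y_df[, c("species_id", y_col)],
               sp_traits[, c("species_id", names(X_cols))])
    d <- d[complete.cases(d), ]
    if (nrow(d) < length(X_cols) + 3) return(NULL)
    y <- setNames(log10(pmax(d[[y_col]], 1e-12)), d$species_id)
    X <- as.matrix(d[names(X_cols)])
    for (j in seq_along(X_cols)) if (X_cols[[j]]) {
      X[, j] <- log10(pmax(X[, j], 1e-12))
    }
    tr <- ape::keep.tip(tree, d$species_id)
    f <- tryCatch(pgls_fit(y, X, tr, lambda = "ml"),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cf <- f$coefficients[-1L, , drop = FALSE]
    data.frame(response = resp_name, flam_trait = flam_trait,
               plant_trait = .trait_alias(rownames(cf)),
               estimate = cf$estimate, lower = cf$lower, upper = cf$upper,
               p = cf$p, lambda = f$lambda, r_squared = f$r_squared,
               stringsAsFactors = FALSE)
  }
  leaf_X <- c(moisture_content = FALSE, leaf_sav_mm = FALSE,
              leaf_ehoc_kj_g = TRUE)
  plant_X <- c(biomass_quantity_g = TRUE, biomass_density_slope = TRUE,
               moisture_content = TRUE, leaf_sav_mm = FALSE,
               leaf_ehoc_kj_g = TRUE)
  rows$leaf_tti <- fit_one("leaf_tti", "tti", leaf_sp, "tti_s", leaf_X)
  rows$leaf_ft <- fit_one("leaf_ft", "flaming_time", leaf_sp, "ft_s", leaf_X)
  rows$leaf_rate <- fit_one("leaf_rate", "combustion_rate", leaf_sp,
                            "combustion_rate_g_s", leaf_X)
  rows$plant_ft <- fit_one("plant_ft", "flaming_time", plant_sp,
                           "flaming_time_s", plant_X)
  rows$plant_rate <- fit_one("plant_rate", "combustion_rate", plant_sp,
                             "max_combustion_rate_g_s", plant_X)
  rows$spread <- fit_one("spread_rate", "spread_rate", spread_sp,
                         "spread_rate_m_min", plant_X)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

.trait_alias <- function(cols) {
  map <- c(biomass_quantity_g = "biomass_quantity",
           biomass_density_slope = "biomass_density",
           moisture_content = "moisture_content",
           leaf_sav_mm = "leaf_sav", leaf_ehoc_kj_g = "leaf_ehoc")
  unname(ifelse(cols %in% names(map), map[cols], cols))
}

.lambda_table <- function(sp_traits, leaf_sp, plant_sp, tree) {
  vars <- list(
    biomass_quantity = log10(setNames(sp_traits$biomass_quantity_g,
                                      sp_traits$species_id)),
    biomass_density = setNames(sp_traits$biomass_density_slope,
                               sp_traits$species_id),
    moisture_content = setNames(sp_traits$moisture_content,
                                sp_traits$species_id),
    leaf_sav = setNames(sp_traits$leaf_sav_mm, sp_traits$species_id),
    leaf_ehoc = setNames(sp_traits$leaf_ehoc_kj_g, sp_traits$species_id),
    leaf_tti = log10(setNames(leaf_sp$tti_s, leaf_sp$species_id)),
    leaf_ft = log10(setNames(leaf_sp$ft_s, leaf_sp$species_id)),
    leaf_rate = log10(setNames(leaf_sp$combustion_rate_g_s,
                               leaf_sp$species_id)),
    plant_ft = log10(setNames(plant_sp$flaming_time_s, plant_sp$species_id)),
    plant_rate = log10(setNames(plant_sp$max_combustion_rate_g_s,
                                plant_sp$species_id)))
  rows <- lapply(names(vars), function(vn) {
    y <- vars[[vn]]
    y <- y[is.finite(y)]
    if (length(y) < 4) return(NULL)
    tr <- ape::keep.tip(tree, names(y))
    s <- tryCatch(estimate_lambda(y, tr), error = function(e) NULL)
    if (is.null(s)) return(NULL)
    data.frame(trait = vn, lambda = s$lambda_ml, p_vs_0 = s$p_vs_0,
               p_vs_1 = s$p_vs_1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

.sign_concordance <- function(pgls_tabs) {
  pred <- flam_predictions()
  obs <- pgls_tabs
  obs$observed <- ifelse(obs$p < 0.05, .sign_chr(obs$estimate), "0")
  m <- merge(pred, obs[, c("flam_trait", "plant_trait", "response",
                           "estimate", "p", "observed")],
             by = c("flam_trait", "plant_trait"))
  m$consistent <- m$predicted == m$observed |
    (m$predicted %in% c("+", "-") & m$observed == "0")  # weak evidence, not contradiction
  m$contradicted <- m$predicted %in% c("+", "-") & m$observed != "0" &
    m$observed != m$predicted
  m
}

.write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_trait_table(df, file.path(out_dir, name))
  w(res$individual_traits, "individual_traits.csv")
  w(res$species_traits, "species_traits.csv")
  w(res$leaf, "leaf_flammability.csv")
  w(res$moisture_effect$species, "moisture_effect_species.csv")
  w(res$plant, "plant_flammability.csv")
  w(res$intrinsic, "intrinsic_combustibility.csv")
  w(res$spread, "spread_rates.csv")
  w(res$bivariate$summary, "bivariate_posterior_summary.csv")
  w(res$whole_plant, "whole_plant_rates.csv")
  w(res$pgls, "pgls_coefficients.csv")
  w(res$lambda_signal, "lambda_signal.csv")
  w(res$sign_concordance, "sign_concordance.csv")
  w(res$species_summary, "species_summary.csv")
  w(res$exclusions, "exclusions.csv")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species, %d individuals\n",
              nrow(x$species_traits), nrow(x$individual_traits)))
  cat("exclusions:\n"); print(x$exclusions, row.names = FALSE)
  invisible(x)
}

# ---- command line -----------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic study bundle), `traits`,
#' `burncurve`, `rothermel`, `phylo` (run one stage on a bundle directory)
#' and `pipeline` (full run). All take `--config <yaml>`; `simulate` and
#' `pipeline` honour `--seed` and `--out`. Returns an exit code rather than
#' calling `quit()` so it is testable; the installed
#' `inst/scripts/grassflam` wrapper forwards `commandArgs()` and exits.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code: 0 on success, 1 on usage error.
#' @export
cli_main <- function(argv = character()) {
  usage <- paste0(
    "usage: grassflam <simulate|traits|burncurve|rothermel|phylo|pipeline>",
    " [--config cfg.yml] [--seed N] [--in dir] [--out dir]\n")
  if (!length(argv)) { cat(usage); return(1L) }
  cmd <- argv[1L]
  opts <- list(config = NULL, seed = NULL, `in` = NULL, out = NULL)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) { cat(usage); return(1L) }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  cfg <- run_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out <- if (!is.null(opts$out)) opts$out else cfg$out_dir

  load_bundle <- function() {
    indir <- if (!is.null(opts$`in`)) opts$`in` else out
    read_study(indir)
  }
  ok <- switch(
    cmd,
    simulate = {
      spec <- generator_spec(
        n_species = cfg$generator$n_species,
        n_individuals = cfg$generator$n_individuals, seed = cfg$seed)
      write_study(gen_study(spec), out)
      message("wrote synthetic study to ", out, " (seed ", cfg$seed, ")")
      TRUE
    },
    pipeline = {
      b <- load_bundle()
      run_pipeline(b, cfg, out_dir = file.path(out, "results"))
      message("pipeline outputs in ", file.path(out, "results"))
      TRUE
    },
    traits = {
      b <- load_bundle()
      ti <- individual_traits(b$clumps, b$profiles, b$leaves, b$ehoc,
                              density_mode = cfg$density$mode)
      write_trait_table(ti, file.path(out, "individual_traits.csv"))
      write_trait_table(aggregate_species(ti),
                        file.path(out, "species_traits.csv"))
      TRUE
    },
    burncurve = {
      b <- load_bundle()
      leaf <- leaf_metrics(b$leaf_events)
      write_trait_table(leaf, file.path(out, "leaf_flammability.csv"))
      write_trait_table(plant_metrics(b$mass_loss,
                                      r2_min = cfg$boltzmann$r2_min),
                        file.path(out, "plant_flammability.csv"))
      TRUE
    },
    rothermel = {
      b <- load_bundle()
      ti <- individual_traits(b$clumps, b$profiles, b$leaves, b$ehoc)
      ros <- do.call(rbind, lapply(seq_len(nrow(ti)), function(i) {
        r <- spread_rate(build_fuel_model(ti[i, ], cfg$rothermel),
                         cfg$rothermel$wind_ms, cfg$rothermel$slope_frac)
        data.frame(species_id = ti$species_id[i],
                   individual_id = ti$individual_id[i],
                   spread_rate_m_min = r$spread_rate_m_min)
      }))
      write_trait_table(ros, file.path(out, "spread_rates.csv"))
      TRUE
    },
    phylo = {
      b <- load_bundle()
      ti <- individual_traits(b$clumps, b$profiles, b$leaves, b$ehoc)
      sp <- aggregate_species(ti)
      y <- setNames(sp$leaf_sav_mm, sp$species_id)
      s <- estimate_lambda(y, ape::keep.tip(b$tree, names(y)))
      write_trait_table(
        data.frame(trait = "leaf_sav", lambda = s$lambda_ml,
                   p_vs_0 = s$p_vs_0, p_vs_1 = s$p_vs_1),
        file.path(out, "lambda_signal.csv"))
      TRUE
    },
    { cat(usage); return(1L) }
  )
  if (isTRUE(ok)) 0L else 1L
}
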