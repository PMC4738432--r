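test_that("trait tables round-trip losslessly and validate their schema", {
  df <- data.frame(species_id = c("spA", "spA", "spB"),
                   individual_id = c("i1", "i2", "i1"),
                   state = c("fresh", "fresh", "dry"),
                   fresh_mass_g = c(10.5, 8.25, 3),
                   dry_mass_g = c(7, 5.5, 3),
                   note = c("a", "b", "c"))
  st <- as_study_table(df)
  expect_s3_class(st, "study_table")
  expect_equal(nrow(st), 3L)
  expect_true("note" %in% names(st))  # unknown columns preserved

  path <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(st, path)
  back <- read_trait_table(path)
  expect_equal(as.data.frame(back), as.data.frame(st))

  # missing mandatory column named in the error
  expect_error(as_study_table(df[, -1]), "species_id")
  # negative mass addressed by row
  df2 <- df; df2$dry_mass_g[2] <- -1
  expect_error(as_study_table(df2), "row 2")
  # dry exceeding fresh addressed by row
  df3 <- df; df3$dry_mass_g[2] <- 9
  expect_error(as_study_table(df3), "row 2")
  # bad state
  df4 <- df; df4$state[3] <- "moist"
  expect_error(as_study_table(df4), "fresh")
  # duplicated individual within species x state
  df5 <- df; df5$individual_id[2] <- "i1"
  expect_error(as_study_table(df5), "duplicate")
})

test_that("mass-loss series enforce their invariants", {
  tt <- seq(0, 10, 0.2)
  mm <- seq(2, 1, length.out = length(tt))
  s <- mass_loss_series("i1", "dry", tt, mm)
  expect_s3_class(s, "mass_loss_series")
  expect_error(mass_loss_series("i1", "dry", tt[1:10], mm[1:10]),
               "fewer than")
  expect_error(mass_loss_series("i1", "dry", rev(tt), mm), "increasing")
  expect_error(mass_loss_series("i1", "dry", tt, rev(mm)), "final mass")
  expect_warning(mass_loss_series("i1", "dry", tt * 3, mm), "interval")
})

test_that("leaf event tables enforce time ordering and positive mass", {
  ev <- data.frame(species_id = "spA", individual_id = "i1", state = "dry",
                   sample_mass_g = 0.2, t_application_s = 0,
                   t_first_flame_s = 2, t_flame_out_s = 8)
  expect_s3_class(as_leaf_events(ev), "leaf_burn_events")
  bad <- ev; bad$t_flame_out_s <- 1
  expect_error(as_leaf_events(bad), "out of order")
  bad2 <- ev; bad2$sample_mass_g <- 0
  expect_error(as_leaf_events(bad2), "sample mass")
})

test_that("newick I/O preserves topology and branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_newick(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(depths, rep(2, 3))

  # round-trip to 1e-12
  tr2 <- gen_tree(70, seed = 123)
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr2, p2)
  back <- read_newick(p2)
  expect_equal(length(back$tip.label), 70L)
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  d1 <- ape::node.depth.edgelength(tr2)[seq_len(70)]
  d2 <- ape::node.depth.edgelength(back)[match(tr2$tip.label, back$tip.label)]
  expect_equal(d2, d1, tolerance = 1e-12)

  expect_error(validate_inputs(tr, c("A", "B", "D")), "mismatch")
  expect_true(validate_inputs(tr, c("A", "B", "C")))
})

test_that("run_config applies file and list overrides and checks the seed", {
  cfg <- run_config()
  expect_equal(cfg$rothermel$moisture_of_extinction, 0.25)
  yml <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("seed: 7", "rothermel:", "  wind_ms: 2.5"), yml)
  cfg2 <- run_config(yml, overrides = list(out_dir = "zzz"))
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$rothermel$wind_ms, 2.5)
  expect_equal(cfg2$rothermel$moisture_of_extinction, 0.25)
  expect_equal(cfg2$out_dir, "zzz")
  expect_error(run_config(overrides = list(seed = 1.5)), "seed")
})

test_that("cli rejects unknown subcommands and simulate is seed-deterministic", {
  expect_equal(cli_main(c("bogus")), 1L)
  expect_equal(cli_main(character()), 1L)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("generator:", "  n_species: 6", "  n_individuals: 3"), cfg)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", cfg, "--seed", "5", "--out", d1))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--config", cfg, "--seed", "5", "--out", d2))), 0L)
  for (f in c("clumps.csv", "leaf_events.csv", "mass_loss.csv", "tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
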