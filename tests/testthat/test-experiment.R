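test_that("the full-scale grid enumerates 60 treatments", {
  grid <- treatment_grid(experiment_config())
  expect_equal(nrow(grid), 60)
  expect_equal(length(unique(grid$method)), 5)
  # DH budget constant across the cross/progeny pairings
  expect_true(all(grid$n_crosses * grid$progeny_per_cross == 15000))
  expect_equal(anyDuplicated(grid[, -1]), 0L)
})

test_that("configuration files load, validate, and reject bad input", {
  prof <- system.file("extdata", "desk-small.yaml", package = "crossel")
  cfg <- load_config(prof)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$program$founders$n_founders, 100)
  expect_equal(cfg$program$capacity$pyt, 60)
  expect_equal(nrow(treatment_grid(cfg)), 2)

  full <- load_config(system.file("extdata", "full-scale.yaml",
                                  package = "crossel"))
  expect_equal(nrow(treatment_grid(full)), 60)
  expect_equal(full$n_replicates, 50)
  expect_equal(full$program$mcmc$iterations, 40000)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("program:", "  h2: {nursery: 1.5}", "  nonsense: 1",
               "wrong_top: 2"), bad)
  err <- tryCatch(load_config(bad), error = identity)
  expect_match(conditionMessage(err), "heritabilities")
  expect_match(conditionMessage(err), "nonsense")
  expect_match(conditionMessage(err), "wrong_top")

  expect_error(program_config(bogus = 1), "unknown config elements")
})

test_that("seed derivation is pure, bounded, and collision-averse", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  seeds <- outer(0:20, 0:10, function(t, r) derive_seed(42, t, r))
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_equal(anyDuplicated(as.vector(seeds)), 0L)
  expect_false(derive_seed(1, 1, 1) == derive_seed(2, 1, 1))
})

test_that("a small grid runs, aggregates, and reproduces", {
  cfg <- experiment_config(
    program = tiny_program_config(),
    n_parents = 8, crosses_progeny = list(c(10, 12)),
    methods = c("PMV", "RandPheno"),
    n_replicates = 2, master_seed = 5, years = 1)
  res <- run_grid(cfg)
  expect_s3_class(res, "results_table")
  expect_null(res$errors)
  # 2 treatments x 2 replicates x (years+1) x 4 traits
  expect_equal(nrow(res$raw), 2 * 2 * 2 * 4)

  # summary means recompute from raw rows
  one <- res$raw[res$raw$method == "PMV" & res$raw$year == 1 &
                   res$raw$trait == "YLD", ]
  sm <- res$summary[res$summary$method == "PMV" & res$summary$year == 1 &
                      res$summary$trait == "YLD", ]
  expect_equal(sm$mean_mean, mean(one$mean))
  expect_equal(sm$variance_sd, sd(one$variance))

  # same master seed: identical results
  res2 <- run_grid(cfg)
  expect_identical(res$raw, res2$raw)

  # within a replicate the two methods share their year-0 baseline
  y0 <- res$raw[res$raw$year == 0 & res$raw$replicate == 1, ]
  expect_equal(unique(table(y0$trait)), 2L)
  expect_equal(y0$mean[y0$method == "PMV"], y0$mean[y0$method == "RandPheno"])
})

test_that("reports round-trip tables and emit plot files", {
  cfg <- experiment_config(
    program = tiny_program_config(),
    n_parents = 8, crosses_progeny = list(c(10, 12)),
    methods = c("PMV", "RandPheno"),
    n_replicates = 1, master_seed = 9, years = 1)
  res <- run_grid(cfg)
  out <- withr::local_tempdir()
  files <- report(res, out)
  expect_true(file.exists(file.path(out, "raw.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  pngs <- list.files(out, pattern = "\\.png$")
  expect_equal(length(pngs), 4 * 3)   # traits x metric families

  back <- read.csv(file.path(out, "raw.csv"))
  expect_equal(back$mean, res$raw$mean)
  expect_equal(back$variance, res$raw$variance)

  mf <- file.path(out, "manifest.json")
  write_manifest(cfg, mf)
  man <- jsonlite::read_json(mf)
  expect_equal(man$master_seed, 9L)
  expect_equal(man$n_treatments, 2L)

  expect_error(report(structure(list(raw = NULL), class = "results_table"),
                      out), "empty")
})
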