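test_that("sampled QTN effects realise the requested correlations", {
  g <- build_genome(1, 1, 600)
  set.seed(11)
  part <- partition_sites(g, qtn_per_chrom = 500, snp_per_chrom = 50)
  sp <- two_increase_specs()

  a0 <- sample_effects(part, sp, diag(2))
  expect_lt(abs(cor(a0$effects[, 1], a0$effects[, 2])), 0.1)

  a9 <- sample_effects(part, sp, matrix(c(1, 0.9, 0.9, 1), 2))
  expect_gt(cor(a9$effects[, 1], a9$effects[, 2]), 0.7)

  a1 <- sample_effects(part, sp[1], matrix(1))
  expect_equal(dim(a1$effects), c(500L, 1L))

  expect_error(sample_effects(part, sp, matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("calibration hits founder targets exactly and is idempotent", {
  g <- tiny_genome()
  set.seed(12)
  f <- tiny_founders(30, g)
  part <- partition_sites(g, 10, 15)
  arch <- sample_effects(part, default_trait_specs(), default_correlations())
  cal <- calibrate(arch, f)
  gv <- genetic_values(f, cal)
  targets_m <- c(5.78, 433, 81, 67)
  targets_v <- c(3.59, 50.10, 12.24, 15.80)
  expect_equal(unname(colMeans(gv)), targets_m, tolerance = 1e-10)
  expect_equal(unname(apply(gv, 2, var)), targets_v, tolerance = 1e-10)

  cal2 <- calibrate(cal, f)
  expect_equal(cal2$effects, cal$effects, tolerance = 1e-12)
  expect_equal(cal2$intercepts, cal$intercepts, tolerance = 1e-12)

  # scale invariance: pre-scaling effects changes nothing after calibration
  arch_scaled <- arch
  arch_scaled$effects <- arch$effects * 2
  expect_equal(genetic_values(f, calibrate(arch_scaled, f)), gv,
               tolerance = 1e-10)
})

test_that("genetic values equal the brute-force dosage-by-effect sum", {
  g <- build_genome(1, 1, 10)
  set.seed(13)
  f <- generate_founders(g, 6, 6, 5)
  part <- list(qtn = c(2L, 4L, 5L, 7L, 9L), snp = c(1L, 3L, 8L))
  class(part) <- "site_partition"
  arch <- sample_effects(part, two_increase_specs(), diag(2))
  arch$intercepts[] <- c(1.5, -2)

  gv <- genetic_values(f, arch)
  d <- dosage(f)
  for (i in 1:6) for (t in 1:2) {
    acc <- arch$intercepts[t]
    for (q in seq_along(part$qtn))
      acc <- acc + d[i, part$qtn[q]] * arch$effects[q, t]
    expect_equal(unname(gv[i, t]), unname(acc))
  }

  # all-reference individual scores the intercept
  f0 <- f
  f0$haplo[1:2, ] <- 0L
  expect_equal(unname(genetic_values(f0, arch)[1, ]),
               unname(arch$intercepts))
})

test_that("phenotypes realise the configured heritability", {
  g <- tiny_genome(2, 1, 40)
  set.seed(14)
  f <- generate_founders(g, 2000, 12, 8)
  part <- partition_sites(g, 8, 20)
  arch <- calibrate(sample_effects(part, default_trait_specs(),
                                   default_correlations()), f)
  gv <- genetic_values(f, arch)

  # h2 = 1, no location effects: phenotype equals the genetic value
  pt1 <- simulate_phenotypes(f, arch, trial_design("x", 1, 1, 1, plot_h2 = 1))
  expect_equal(unname(entry_means(pt1)), unname(gv), tolerance = 1e-12)

  # h2 = 0.5: regression slope ~ 1 and R2 ~ 0.5
  pt <- simulate_phenotypes(f, arch, trial_design("x", 1, 1, 1, plot_h2 = 0.5))
  fit <- lm(entry_means(pt)[, 1] ~ gv[, 1])
  expect_lt(abs(unname(coef(fit)[2]) - 1), 0.1)
  expect_lt(abs(summary(fit)$r.squared - 0.5), 0.05)

  # nursery-style h2 = 0.1
  ptn <- simulate_phenotypes(f, arch, trial_design("n", 1, 1, 1, plot_h2 = 0.1))
  expect_lt(abs(cor(entry_means(ptn)[, 1], gv[, 1])^2 - 0.1), 0.05)

  # realised h2 averaged over seeds stays within 0.05 of configured
  r2s <- vapply(1:10, function(s) {
    set.seed(300 + s)
    p <- simulate_phenotypes(f, arch, trial_design("x", 1, 1, 1, plot_h2 = 0.3))
    cor(entry_means(p)[, 2], gv[, 2])^2
  }, 0)
  expect_lt(abs(mean(r2s) - 0.3), 0.05)

  expect_error(trial_design("x", 1, 1, 1, plot_h2 = 1.5), "plot_h2")
  expect_error(trial_design("x", 0, 1, 1, 0.5), "dimensions")
})

test_that("phenotype tables carry the full trial structure", {
  g <- tiny_genome(1, 1, 20)
  set.seed(15)
  f <- generate_founders(g, 10, 8, 5)
  part <- partition_sites(g, 4, 8)
  arch <- calibrate(sample_effects(part, default_trait_specs(),
                                   default_correlations()), f)
  pt <- simulate_phenotypes(f, arch, trial_design("PYT", 2, 2, 1,
                                                  plot_h2 = 0.5,
                                                  gxe_variance_ratio = 0.2))
  expect_equal(nrow(pt), 10 * 4 * 2 * 2 * 1)   # id x trait x loc x rep x year
  expect_equal(dim(entry_means(pt)), c(10L, 4L))
  # one row per id x trait x location x rep x year
  expect_false(any(duplicated(pt[, c("id", "trait", "location", "rep",
                                     "year")])))
})
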