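test_that("Rogers' distance counts differing loci for inbreds", {
  expect_equal(rogers_distance(c(0, 2, 2, 0), c(0, 2, 2, 0)), 0)
  expect_equal(rogers_distance(c(0, 0, 0), c(2, 2, 2)), 1)
  expect_equal(rogers_distance(c(0, 2, 0, 2), c(2, 0, 0, 2)), 0.5)
  expect_equal(rogers_distance(c(1, 1), c(0, 2)), 0.5)  # het midpoint
  expect_error(rogers_distance(numeric(0), numeric(0)), "at least one")
})

test_that("cross mean and LD-phase parameter follow their definitions", {
  expect_equal(mean_gebv_cross(10, 14), 12)
  expect_equal(mean_gebv_cross(3, 3), 3)
  expect_equal(mean_gebv_cross(2, 7), mean_gebv_cross(7, 2))

  expect_equal(ld_parameter(1, 0, 1, 0), 0.25)   # coupling
  expect_equal(ld_parameter(1, 0, 0, 1), -0.25)  # repulsion
  expect_equal(ld_parameter(1, 1, 1, 0), 0)      # shared allele at j
  expect_equal(ld_parameter(0, 1, 1, 1), 0)      # shared allele at k
  # symmetric under parent swap
  expect_equal(ld_parameter(0, 1, 0, 1), ld_parameter(1, 0, 1, 0))
  expect_error(ld_parameter(0.5, 0, 1, 0), "inbred")
})

test_that("progeny covariance matches its limiting cases", {
  g <- build_genome(2, 1, 5)   # 0.25 M spacing
  A <- rep(1L, 10); B <- rep(0L, 10)
  pop <- manual_inbred_pair(g, A, B)

  sig <- progeny_covariance(pop, 1, 2)
  expect_equal(unname(diag(sig)), rep(1, 10))
  # coupling phase: off-diagonal is exp(-2d) within a chromosome
  expect_equal(sig[1, 2], exp(-2 * 0.25))
  expect_equal(sig[1, 2], 1 - 2 * recombination_fraction(0.25))
  # across chromosomes: zero
  expect_true(all(sig[1:5, 6:10] == 0))

  # identical parents: zero matrix
  sig0 <- progeny_covariance(pop, 1, 1)
  expect_true(all(sig0 == 0))

  # one segregating locus
  B2 <- A; B2[3] <- 0L
  pop2 <- manual_inbred_pair(g, A, B2)
  sig1 <- progeny_covariance(pop2, 1, 2)
  expect_equal(sum(sig1 != 0), 1)
  expect_equal(sig1[3, 3], 1)

  # repulsion phase gives negative covariance
  A3 <- c(1L, 0L, rep(0L, 8)); B3 <- c(0L, 1L, rep(0L, 8))
  pop3 <- manual_inbred_pair(g, A3, B3)
  sig3 <- progeny_covariance(pop3, 1, 2)
  expect_equal(sig3[1, 2], -exp(-2 * 0.25))

  # PSD on random crosses
  set.seed(51)
  f <- tiny_founders(8, tiny_genome(2, 1, 30))
  parents <- tiny_inbred_parents(6, tiny_genome(2, 1, 30))
  for (k in 1:5) {
    pr <- sample(6, 2)
    s <- progeny_covariance(parents, pr[1], pr[2])
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }

  expect_error(progeny_covariance(pop, 1, 2, markers = 99), "out of range")
})

test_that("PMV reduces correctly for point-mass posteriors", {
  g <- build_genome(1, 1, 4)
  A <- c(1L, 1L, 0L, 0L); B <- c(1L, 0L, 0L, 0L)
  pop <- manual_inbred_pair(g, A, B)
  sig <- progeny_covariance(pop, 1, 2)
  b <- c(0.5, 2, -1, 3)
  expect_equal(pmv(b, sig), 4)        # single segregating locus: b_2^2
  # identical parents: zero for any posterior
  sig0 <- progeny_covariance(pop, 2, 2)
  expect_equal(pmv(matrix(rnorm(40), 10, 4), sig0), 0)
  expect_error(pmv(matrix(0, 0, 4), sig), "draws")
})

test_that("PMV equals the Monte-Carlo progeny GEBV variance", {
  set.seed(52)
  g <- build_genome(2, 1, 50)
  parents <- tiny_inbred_parents(6, g)
  markers <- seq_len(g$n_sites)
  b <- rnorm(length(markers), 0, 0.2)
  for (k in 1:2) {
    pr <- sample(n_ind(parents), 2)
    pred <- pmv(b, progeny_covariance(parents, pr[1], pr[2], markers))
    dh <- make_dh(make_cross(parents, pr[1], pr[2], 1), 1, 20000)
    emp <- var(gebv(dosage(dh, markers), b))
    expect_lt(abs(pred - emp) / emp, 0.02)
  }
})

test_that("batched PMV agrees with the quadratic-form definition", {
  set.seed(53)
  g <- tiny_genome(2, 1, 30)
  parents <- tiny_inbred_parents(5, g)
  markers <- sort(sample(g$n_sites, 20))
  B <- matrix(rnorm(15 * 20, 0, 0.3), 15, 20)
  h <- crossel:::inbred_haplotypes(parents, 1:5, markers)
  pairs <- t(combn(5, 2))
  delta <- t(h[pairs[, 1], ] - h[pairs[, 2], ])
  batch <- crossel:::pmv_batch(B, delta, g, markers)
  naive <- apply(pairs, 1, function(pr)
    pmv(B, progeny_covariance(parents, pr[1], pr[2], markers)))
  expect_equal(batch, naive, tolerance = 1e-10)
})

test_that("selection intensity matches the normal-theory values", {
  expect_equal(selection_intensity(1), 0, tolerance = 1e-12)
  expect_equal(selection_intensity(0.5), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_equal(selection_intensity(0.5), 0.797885, tolerance = 1e-6)
  expect_equal(selection_intensity(0.1), 1.754983, tolerance = 1e-6)
  expect_error(selection_intensity(0), "proportion")
  expect_error(selection_intensity(1.2), "proportion")
})

test_that("usefulness criterion combines mean and progeny SD", {
  expect_equal(uc(5, 0, 4), 5)
  expect_equal(uc(10, 2, 2.25), 13)
  set.seed(54)
  m <- rnorm(20); v <- rexp(20)
  expect_true(all(uc(m, 1.5, v) >= m))
  expect_error(uc(1, 1, -0.5), "non-negative")
})

test_that("OHV doubles the best haplotype segment scores", {
  g <- build_genome(1, 1, 6)
  A <- c(1L, 1L, 1L, 0L, 0L, 0L); B <- c(0L, 0L, 0L, 1L, 1L, 1L)
  pop <- manual_inbred_pair(g, A, B)
  b <- c(1, 1, 1, 2, 2, 2)
  markers <- 1:6
  # one segment: haplotype scores 3 (A) and 6 (B) -> 12
  expect_equal(ohv(pop, 1, 2, b, markers, segments = list(1:6)), 12)
  # two segments: best is B then... A scores (3,0), B scores (0,6) -> 2*(3+6)
  expect_equal(ohv(pop, 1, 2, b, markers, segments = list(1:3, 4:6)), 18)
  # identical parents: OHV equals the parent GEBV
  expect_equal(ohv(pop, 1, 1, b, markers, segments = list(1:3, 4:6)),
               gebv(matrix(2 * A, 1), b))
  expect_error(ohv(pop, 1, 2, b, markers, segments = list(integer(0))),
               "empty")

  # dominance over parental GEBVs on random toys
  set.seed(55)
  gg <- tiny_genome(2, 1, 30)
  parents <- tiny_inbred_parents(8, gg)
  mk <- seq_len(gg$n_sites)
  bb <- rnorm(length(mk), 0, 0.5)
  pg <- gebv(dosage(parents, mk), bb)
  segs <- make_segments(gg, mk)
  for (k in 1:10) {
    pr <- sample(8, 2)
    o <- ohv(parents, pr[1], pr[2], bb, mk, segs)
    expect_gte(o + 1e-10, max(pg[pr]))
    # symmetry
    expect_equal(o, ohv(parents, pr[2], pr[1], bb, mk, segs))
  }
})

test_that("metric scaling behaves as theory predicts", {
  set.seed(56)
  g <- tiny_genome(2, 1, 30)
  parents <- tiny_inbred_parents(6, g)
  mk <- seq_len(g$n_sites)
  b <- rnorm(length(mk), 0, 0.3)
  k <- 2.7
  pr <- c(1, 4)
  sig <- progeny_covariance(parents, pr[1], pr[2], mk)
  expect_equal(pmv(k * b, sig), k^2 * pmv(b, sig))
  segs <- make_segments(g, mk)
  expect_equal(ohv(parents, pr[1], pr[2], k * b, mk, segs),
               k * ohv(parents, pr[1], pr[2], b, mk, segs))
  pg <- gebv(dosage(parents, mk), b)
  expect_equal(mean_gebv_cross(k * pg[1], k * pg[2]),
               k * mean_gebv_cross(pg[1], pg[2]))
})

test_that("select_crosses ranks pairs and respects the prefilter", {
  set.seed(57)
  g <- tiny_genome(2, 1, 40)
  parents <- tiny_inbred_parents(6, g)
  mk <- seq_len(g$n_sites)
  L <- 30
  post <- structure(list(beta = matrix(rnorm(L * length(mk), 0, 0.2), L),
                         beta_hat = NULL, L = L), class = "brr_fit")
  post$beta_hat <- colMeans(post$beta)

  plan <- select_crosses(parents, post, mk, method = "PMV", n_crosses = 4,
                         progeny_per_cross = 10)
  expect_equal(nrow(plan), choose(6, 2))
  expect_equal(sum(plan$selected), 4)
  expect_equal(sum(plan$n_progeny), 40)
  # selected pairs carry the largest scores
  expect_gte(min(plan$score[plan$selected]),
             max(plan$score[!plan$selected]))

  # UC consistency with its parts
  plan_uc <- select_crosses(parents, post, mk, method = "UC", n_crosses = 2,
                            progeny_per_cross = 5, intensity_p = 0.1)
  expect_equal(plan_uc$uc,
               uc(plan_uc$mean_gebv, selection_intensity(0.1), plan_uc$pmv))

  # RandPheno is reproducible under a fixed seed and needs no posterior
  set.seed(99)
  p1 <- select_crosses(parents, NULL, mk, method = "RandPheno",
                       n_crosses = 3, progeny_per_cross = 7)
  set.seed(99)
  p2 <- select_crosses(parents, NULL, mk, method = "RandPheno",
                       n_crosses = 3, progeny_per_cross = 7)
  expect_identical(p1$parent_a[p1$selected], p2$parent_a[p2$selected])
  expect_true(all(is.na(p1$mean_gebv)))

  # the literal "< 0.1" prefilter usually empties the candidate set for
  # unrelated parents, triggering the documented fallback
  expect_warning(
    select_crosses(parents, post, mk, method = "MeanGEBV", n_crosses = 3,
                   progeny_per_cross = 5),
    "prefilter")
  # with direction "gt" distant pairs stay eligible: no warning
  expect_silent(
    select_crosses(parents, post, mk, method = "MeanGEBV", n_crosses = 3,
                   progeny_per_cross = 5, distance_direction = "gt"))

  expect_error(select_crosses(parents, NULL, mk, method = "UC",
                              n_crosses = 2, progeny_per_cross = 5),
               "posterior")
  expect_error(select_crosses(parents, post, mk, method = "PMV",
                              n_crosses = 30, progeny_per_cross = 5),
               "fewer candidate pairs")
})
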