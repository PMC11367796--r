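#' Define a trait
#'
#' @param name Trait name (e.g. `"YLD"`).
#' @param target_mean Founder-population genetic mean the trait is calibrated
#'   to, in trait units.
#' @param target_variance Founder-population genetic variance (> 0).
#' @param direction Improvement direction: `"increase"`, `"decrease"`, or
#'   `"optimum"` (requires `optimum`).
#' @param optimum Target value when `direction = "optimum"`.
#' @return A `trait_spec` list.
#' @examples
#' trait_spec("YLD", 5.78, 3.59, "increase")
#' trait_spec("PH", 67, 15.8, "optimum", optimum = 50)
#' @export
trait_spec <- function(name, target_mean, target_variance,
                       direction = c("increase", "decrease", "optimum"),
                       optimum = NULL) {
  direction <- match.arg(direction)
  if (target_variance <= 0) stop("target_variance must be positive")
  if (direction == "optimum" && is.null(optimum))
    stop("direction 'optimum' requires an optimum value")
  structure(list(name = name, target_mean = target_mean,
                 target_variance = target_variance, direction = direction,
                 optimum = optimum),
            class = "trait_spec")
}

#' Default four-trait pulse-crop configuration
#'
#' Grain yield (YLD) and thousand-kernel weight (TKW) are improved upward;
#' plant height (PH) and days to physiological maturity (DPM) are driven
#' toward optimum targets (defaults 50 cm and 79 d, below the founder means).
#'
#' @param ph_optimum,dpm_optimum Optimum targets for PH and DPM.
#' @return List of four `trait_spec`s.
#' @export
default_trait_specs <- function(ph_optimum = 50, dpm_optimum = 79) {
  list(
    YLD = trait_spec("YLD", 5.78, 3.59, "increase"),
    TKW = trait_spec("TKW", 433.00, 50.10, "increase"),
    DPM = trait_spec("DPM", 81.00, 12.24, "optimum", optimum = dpm_optimum),
    PH  = trait_spec("PH", 67.00, 15.80, "optimum", optimum = ph_optimum)
  )
}

#' Sample correlated additive QTN effects
#'
#' Each QTN receives one allele-substitution effect per trait, drawn from a
#' zero-mean multivariate Gaussian with the given genetic correlation matrix.
#' Effects are attached to QTN sites only; the raw scale is arbitrary until
#' [calibrate()] rescales per trait.
#'
#' @param partition A `site_partition`.
#' @param trait_specs List of `trait_spec`s (one per trait).
#' @param correlations Symmetric positive-definite correlation matrix
#'   (`n_traits` x `n_traits`); identity by default.
#' @return A `trait_architecture`: list with `qtn`, `effects`
#'   (`n_qtn` x `n_traits`), per-trait `intercepts`, `specs`, `correlations`,
#'   and a `calibrated` flag.
#' @export
sample_effects <- function(partition, trait_specs, correlations = NULL) {
  n_traits <- length(trait_specs)
  if (is.null(correlations)) correlations <- diag(n_traits)
  correlations <- as.matrix(correlations)
  if (!isSymmetric(unname(correlations), tol = 1e-8) ||
      any(abs(diag(correlations) - 1) > 1e-8))
    stop("correlations must be a symmetric matrix with unit diagonal")
  ch <- tryCatch(chol(correlations),
                 error = function(e) stop("correlation matrix must be positive definite"))
  n_qtn <- length(partition$qtn)
  z <- matrix(rnorm(n_qtn * n_traits), n_qtn, n_traits)
  effects <- z %*% ch
  colnames(effects) <- vapply(trait_specs, `[[`, "", "name")
  structure(list(qtn = partition$qtn, effects = effects,
                 intercepts = setNames(numeric(n_traits), colnames(effects)),
                 specs = trait_specs, correlations = correlations,
                 calibrated = FALSE),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("trait architecture:", length(x$qtn), "QTN,",
      ncol(x$effects), "traits",
      if (x$calibrated) "(calibrated)" else "(uncalibrated)", "\n")
  invisible(x)
}

#' Calibrate QTN effects to founder targets
#'
#' Applies an affine rescaling per trait (effect scaling plus intercept) so
#' that the founder population's genetic mean and variance equal each trait's
#' `target_mean` and `target_variance` exactly (sample variance, denominator
#' n - 1). Calibration is idempotent.
#'
#' @param arch A `trait_architecture`.
#' @param founders Founder `population`.
#' @return The calibrated `trait_architecture`.
#' @export
calibrate <- function(arch, founders) {
  d <- dosage(founders, arch$qtn)
  g <- d %*% arch$effects
  effects <- arch$effects
  intercepts <- arch$intercepts
  for (t in seq_along(arch$specs)) {
    v <- var(g[, t])
    if (v <= 0) stop("degenerate architecture: zero founder genetic variance for trait ",
                     arch$specs[[t]]$name)
    s <- sqrt(arch$specs[[t]]$target_variance / v)
    effects[, t] <- effects[, t] * s
    intercepts[t] <- arch$specs[[t]]$target_mean - mean(g[, t]) * s
  }
  arch$effects <- effects
  arch$intercepts <- intercepts
  arch$calibrated <- TRUE
  arch
}

#' True genetic values of a population
#'
#' Per trait: intercept + sum over QTN of allele dosage times additive effect.
#'
#' @param pop A `population` sharing the architecture's genome.
#' @param arch A `trait_architecture`.
#' @return Numeric matrix (individuals x traits) with id row names.
#' @export
genetic_values <- function(pop, arch) {
  if (max(arch$qtn) > pop$genome$n_sites)
    stop("population genome does not match trait architecture")
  d <- dosage(pop, arch$qtn)
  g <- d %*% arch$effects
  g <- sweep(g, 2L, arch$intercepts, "+")
  rownames(g) <- pop$ids
  g
}

#' Describe a field-trial stage
#'
#' @param stage Stage label (e.g. `"nursery"`, `"PYT"`, `"AYT"`).
#' @param n_locations,n_reps,n_years Trial dimensions (>= 1).
#' @param plot_h2 Per-trait plot-level narrow-sense heritability in (0, 1];
#'   recycled over traits.
#' @param gxe_variance_ratio Location-effect variance as a fraction of the
#'   current genetic variance (non-heritable G-by-E-like noise).
#' @return A `trial_design` list.
#' @export
trial_design <- function(stage, n_locations = 1, n_reps = 1, n_years = 1,
                         plot_h2 = 0.5, gxe_variance_ratio = 0) {
  if (any(plot_h2 <= 0) || any(plot_h2 > 1))
    stop("plot_h2 must be in (0, 1]")
  if (n_locations < 1 || n_reps < 1 || n_years < 1)
    stop("trial dimensions must be >= 1")
  if (gxe_variance_ratio < 0) stop("gxe_variance_ratio must be >= 0")
  structure(list(stage = stage, n_locations = as.integer(n_locations),
                 n_reps = as.integer(n_reps), n_years = as.integer(n_years),
                 plot_h2 = plot_h2, gxe_variance_ratio = gxe_variance_ratio),
            class = "trial_design")
}

#' Simulate plot-level phenotypes and entry means
#'
#' Per trait, phenotype = genetic value + location effect + plot residual.
#' The plot residual variance is \eqn{\sigma_e^2 = \sigma_g^2 (1 - h^2)/h^2}
#' with \eqn{\sigma_g^2} the current cohort genetic variance and \eqn{h^2}
#' the configured plot-level heritability; location effects are i.i.d.
#' Gaussian per location x year x trait with variance
#' `gxe_variance_ratio` x \eqn{\sigma_g^2} (non-heritable, shared by all
#' entries at a location). Entry means average over locations, reps and
#' years.
#'
#' @param pop A `population`.
#' @param arch A calibrated `trait_architecture`.
#' @param design A `trial_design`.
#' @return A `phenotype_table`: data frame with columns `id`, `trait`,
#'   `location`, `rep`, `year`, `value`, carrying the entry-mean matrix as
#'   attribute `"entry_means"` (retrieved with [entry_means()]).
#' @export
simulate_phenotypes <- function(pop, arch, design) {
  g <- genetic_values(pop, arch)
  n <- nrow(g)
  traits <- unname(colnames(g))
  h2 <- rep_len(design$plot_h2, length(traits))
  nl <- design$n_locations; nr <- design$n_reps; ny <- design$n_years
  rows <- vector("list", length(traits))
  em <- matrix(0, n, length(traits), dimnames = list(pop$ids, traits))
  for (t in seq_along(traits)) {
    sg2 <- var(g[, t])
    se2 <- sg2 * (1 - h2[t]) / h2[t]
    sloc2 <- design$gxe_variance_ratio * sg2
    # location effects indexed by location x year
    loc_eff <- matrix(rnorm(nl * ny, 0, sqrt(sloc2)), nl, ny)
    vals <- array(0, dim = c(n, nl, nr, ny))
    for (y in seq_len(ny)) for (l in seq_len(nl)) for (r in seq_len(nr)) {
      vals[, l, r, y] <- g[, t] + loc_eff[l, y] + rnorm(n, 0, sqrt(se2))
    }
    em[, t] <- rowMeans(vals)
    rows[[t]] <- data.frame(
      id = rep(pop$ids, times = nl * nr * ny),
      trait = traits[t],
      location = rep(rep(seq_len(nl), each = n), times = nr * ny),
      rep = rep(rep(seq_len(nr), each = n * nl), times = ny),
      year = rep(seq_len(ny), each = n * nl * nr),
      value = as.vector(vals))
  }
  out <- do.call(rbind, rows)
  attr(out, "entry_means") <- em
  attr(out, "stage") <- design$stage
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Entry-mean phenotypes of a phenotype table
#' @param pt A `phenotype_table` from [simulate_phenotypes()].
#' @return Numeric matrix (individuals x traits).
#' @export
entry_means <- function(pt) attr(pt, "entry_means")
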