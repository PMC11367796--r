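#' Default genetic correlation matrix for the four default traits
#'
#' Modest correlations (|r| <= 0.3), positive definite, used when no matrix
#' is supplied via configuration.
#' @return 4 x 4 correlation matrix (YLD, TKW, DPM, PH).
#' @export
default_correlations <- function() {
  m <- diag(4)
  dimnames(m) <- list(c("YLD", "TKW", "DPM", "PH"),
                      c("YLD", "TKW", "DPM", "PH"))
  m["YLD", "TKW"] <- m["TKW", "YLD"] <- 0.3
  m["YLD", "DPM"] <- m["DPM", "YLD"] <- 0.2
  m["YLD", "PH"]  <- m["PH", "YLD"]  <- 0.1
  m["TKW", "DPM"] <- m["DPM", "TKW"] <- 0.1
  m["TKW", "PH"]  <- m["PH", "TKW"]  <- 0.2
  m["DPM", "PH"]  <- m["PH", "DPM"]  <- 0.2
  m
}

#' Program configuration
#'
#' Assembles the full set of tunables for the recurrent-selection pipeline:
#' genome and founder parameters, trait specifications, stage heritabilities
#' and trial layouts, stage capacities, MCMC schedule, cross-selection
#' options, and burn-in settings. Any element can be overridden by name;
#' unnamed defaults follow the full-scale program (7 chromosomes x 600 sites,
#' 200 founders, 4,000-entry nursery cap, 400-entry PYT, 40-entry AYT).
#'
#' @param ... Named overrides of top-level elements (replaced wholesale).
#' @return A `program_config` list.
#' @export
program_config <- function(...) {
  cfg <- list(
    genome = list(n_chrom = 7, chrom_length = 1.0, sites_per_chrom = 600),
    founders = list(n_founders = 200, n_ancestral_haplotypes = 20,
                    n_drift_generations = 50),
    partition = list(qtn_per_chrom = NULL, snp_per_chrom = 500),
    traits = default_trait_specs(),
    correlations = default_correlations(),
    h2 = list(nursery = 0.1,
              pyt = c(YLD = 0.3, TKW = 0.6, DPM = 0.7, PH = 0.5),
              ayt = c(YLD = 0.3, TKW = 0.6, DPM = 0.7, PH = 0.5)),
    gxe_variance_ratio = 0.2,
    capacity = list(nursery_cap = 4000, pyt = 400, ayt = 40),
    mcmc = list(iterations = 2000, burn_in = 500, thin = 5,
                prior_df = 5, R2 = 0.5),
    selection = list(intensity_p = NULL, segments_per_chrom = 3,
                     distance_threshold = 0.1, distance_direction = "lt"),
    burn_in = list(years = 10, n_parents = 40, n_crosses = 100,
                   progeny_per_cross = 150),
    years_post_burnin = 30,
    run_ayt = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config elements: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "program_config")
}

#' Define a simulation treatment
#'
#' One cell of the resource-allocation grid: a cross-selection method plus
#' the numbers of parents, crosses, and progeny per cross. At full scale the
#' grid pairs 50/100/150/200 crosses with 300/150/100/75 progeny so the DH
#' budget is a constant 15,000.
#'
#' @param method `"UC"`, `"PMV"`, `"OHV"`, `"MeanGEBV"` or `"RandPheno"`.
#' @param n_parents Parents recycled into the crossing block.
#' @param n_crosses Crosses per cycle.
#' @param progeny_per_cross DH progeny per cross.
#' @return A `treatment` list.
#' @export
treatment <- function(method, n_parents, n_crosses, progeny_per_cross) {
  method <- match.arg(method, c("UC", "PMV", "OHV", "MeanGEBV", "RandPheno"))
  stopifnot(n_parents >= 2, n_crosses >= 1, progeny_per_cross >= 1)
  structure(list(method = method, n_parents = as.integer(n_parents),
                 n_crosses = as.integer(n_crosses),
                 progeny_per_cross = as.integer(progeny_per_cross)),
            class = "treatment")
}

nursery_design <- function(cfg) trial_design("nursery", 1, 1, 1,
                                             plot_h2 = cfg$h2$nursery,
                                             gxe_variance_ratio = 0)
pyt_design <- function(cfg) trial_design("PYT", 2, 2, 1, plot_h2 = cfg$h2$pyt,
                                         gxe_variance_ratio = cfg$gxe_variance_ratio)
ayt_design <- function(cfg) trial_design("AYT", 6, 3, 2, plot_h2 = cfg$h2$ayt,
                                         gxe_variance_ratio = cfg$gxe_variance_ratio)

# generate the DH cohort for the selected crosses of a plan
make_dh_cohort <- function(parents, plan, prefix) {
  sel <- plan[plan$selected, , drop = FALSE]
  g <- parents$genome
  het <- any(heterozygosity(parents) > 0)
  n_tot <- sum(sel$n_progeny)
  haplo <- matrix(0L, nrow = 2L * n_tot, ncol = g$n_sites)
  ids <- character(n_tot)
  row <- 0L
  for (k in seq_len(nrow(sel))) {
    a <- sel$parent_a[k]; b <- sel$parent_b[k]; n <- sel$n_progeny[k]
    if (het) {
      # per-progeny F1s: with non-inbred parents each F1 is distinct
      f1 <- make_cross(parents, a, b, n)
      gam <- matrix(0L, n, g$n_sites)
      for (i in seq_len(n)) gam[i, ] <- make_gamete(f1, i)
    } else {
      # inbred parents: all F1s are identical, one suffices
      f1 <- make_cross(parents, a, b, 1L)
      gam <- gamete_matrix(f1$haplo, g, n)
    }
    rows <- row + seq_len(2L * n)
    haplo[rows, ] <- gam[rep(seq_len(n), each = 2L), , drop = FALSE]
    ids[(row %/% 2L) + seq_len(n)] <- sprintf("%s_c%d_%d", prefix, k,
                                              seq_len(n))
    row <- row + 2L * n
  }
  new_population(g, haplo, ids, "DH")
}

#' Per-trait genetic metrics of a cohort
#'
#' Genetic mean and variance of true genetic values plus gains relative to a
#' baseline: `gain_raw = mean - baseline_mean` (trait units) and
#' `gain_std = gain_raw / baseline_sd` (baseline genetic-SD units).
#'
#' @param pop Cohort `population` (non-empty).
#' @param arch `trait_architecture`.
#' @param baseline_means,baseline_sds Named per-trait baselines.
#' @return Data frame with one row per trait: `trait`, `mean`, `variance`,
#'   `gain_raw`, `gain_std`.
#' @export
compute_metrics <- function(pop, arch, baseline_means, baseline_sds) {
  if (n_ind(pop) < 1L) stop("empty cohort")
  g <- genetic_values(pop, arch)
  traits <- colnames(g)
  data.frame(
    trait = traits,
    mean = colMeans(g),
    variance = if (nrow(g) == 1L) 0 else apply(g, 2L, var),
    gain_raw = colMeans(g) - baseline_means[traits],
    gain_std = (colMeans(g) - baseline_means[traits]) / baseline_sds[traits],
    row.names = NULL)
}

#' Run the burn-in phase
#'
#' Ten (configurable) cycles of the full pipeline under phenotypic RSI parent
#' selection with random mating among the selected parents (the RandPheno
#' baseline), starting from calibrated founders. The returned state is shared
#' across all treatments of a replicate, so methods diverge only after
#' burn-in. The genetic mean and SD of the final burn-in DH cohort become the
#' year-0 baseline for gain accounting.
#'
#' @param founders Founder `population`.
#' @param arch Calibrated `trait_architecture`.
#' @param partition `site_partition` (supplies the SNP chip).
#' @param config A `program_config`.
#' @param seed Optional integer seed.
#' @return A `program_state`.
#' @export
run_burn_in <- function(founders, arch, partition, config = program_config(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!isTRUE(arch$calibrated)) stop("trait architecture must be calibrated")
  state <- structure(list(
    config = config, genome = founders$genome, partition = partition,
    markers = partition$snp, arch = arch,
    pyt_pop = founders, pyt_em = entry_means(
      simulate_phenotypes(founders, arch, pyt_design(config))),
    dh_pop = NULL, posterior = NULL, year = 0L,
    baseline = NULL), class = "program_state")
  bt <- treatment("RandPheno", config$burn_in$n_parents,
                  config$burn_in$n_crosses, config$burn_in$progeny_per_cross)
  for (y in seq_len(config$burn_in$years)) {
    state <- run_year_cycle(state, bt)
  }
  g <- genetic_values(state$dh_pop, arch)
  state$baseline <- list(means = colMeans(g), sds = apply(g, 2L, sd))
  state
}

#' @export
print.program_state <- function(x, ...) {
  cat("program state: year", x$year, "|", n_ind(x$pyt_pop), "PYT entries")
  if (!is.null(x$dh_pop)) cat(" |", n_ind(x$dh_pop), "DH in last cohort")
  cat("\n")
  invisible(x)
}

#' Advance the program by one year
#'
#' One full cycle: (1) select `n_parents` from the PYT cohort by RSI of
#' entry-mean phenotypes; (2) fit BRR to the (negated) PYT RSI on marker
#' dosages (skipped for RandPheno); (3) score and select crosses by the
#' treatment's method; (4) produce the DH cohort (`n_crosses` x
#' `progeny_per_cross`); (5) nursery: visual phenotypes at the nursery
#' heritability, optional capacity pre-screen, advance the PYT capacity by
#' RSI; (6) PYT trial phenotypes (2 reps x 2 locations); (7) AYT: the best
#' entries by PYT RSI, evaluated terminally; (8) metrics on the DH cohort's
#' true genetic values.
#'
#' @param state A `program_state`.
#' @param treatment A `treatment`.
#' @return The advanced `program_state` (with `$last_metrics`).
#' @export
run_year_cycle <- function(state, treatment) {
  cfg <- state$config
  arch <- state$arch
  specs <- arch$specs
  markers <- state$markers

  # 1. parents by RSI of PYT entry means
  idx_rank <- rsi(state$pyt_em, specs)
  n_avail <- n_ind(state$pyt_pop)
  if (n_avail < treatment$n_parents)
    stop("parent selection: PYT cohort (", n_avail, ") smaller than n_parents")
  parents <- subset_population(state$pyt_pop,
                               select_by_rsi(idx_rank, treatment$n_parents),
                               generation = "parent")

  # 2. genomic prediction on the derived phenotype (negated RSI: merit)
  posterior <- NULL
  if (treatment$method != "RandPheno") {
    y <- -rsi(state$pyt_em, specs)
    X <- dosage(state$pyt_pop, markers)
    posterior <- fit_brr(y, X, iterations = cfg$mcmc$iterations,
                         burn_in = cfg$mcmc$burn_in, thin = cfg$mcmc$thin,
                         prior_df = cfg$mcmc$prior_df, R2 = cfg$mcmc$R2)
  }

  # 3. crossing plan
  n_dh_budget <- treatment$n_crosses * treatment$progeny_per_cross
  ip <- cfg$selection$intensity_p
  if (is.null(ip)) ip <- cfg$capacity$pyt / n_dh_budget
  plan <- select_crosses(parents, posterior, markers,
                         method = treatment$method,
                         n_crosses = treatment$n_crosses,
                         progeny_per_cross = treatment$progeny_per_cross,
                         intensity_p = ip,
                         segments_per_chrom = cfg$selection$segments_per_chrom,
                         distance_threshold = cfg$selection$distance_threshold,
                         distance_direction = cfg$selection$distance_direction)

  # 4. DH cohort
  dh <- make_dh_cohort(parents, plan, prefix = sprintf("y%d", state$year + 1L))
  if (n_ind(dh) != n_dh_budget)
    stop("DH stage: cohort size ", n_ind(dh), " != budget ", n_dh_budget)

  # 5. nursery: visual phenotypes, optional cap pre-screen, advance to PYT
  nur <- simulate_phenotypes(dh, arch, nursery_design(cfg))
  nur_rsi <- rsi(entry_means(nur), specs)
  keep <- seq_len(n_ind(dh))
  cap <- cfg$capacity$nursery_cap
  if (!is.null(cap) && n_ind(dh) > cap) keep <- select_by_rsi(nur_rsi, cap)
  if (length(keep) < cfg$capacity$pyt)
    stop("nursery stage: fewer entries (", length(keep),
         ") than PYT capacity")
  adv <- keep[select_by_rsi(nur_rsi[keep], cfg$capacity$pyt,
                            ids = dh$ids[keep])]
  pyt_pop <- subset_population(dh, adv, generation = "PYT")

  # 6. PYT evaluation
  pyt_em <- entry_means(simulate_phenotypes(pyt_pop, arch, pyt_design(cfg)))

  # 7. AYT (terminal)
  ayt_metrics <- NULL
  if (isTRUE(cfg$run_ayt)) {
    ayt_idx <- select_by_rsi(rsi(pyt_em, specs), cfg$capacity$ayt)
    ayt_pop <- subset_population(pyt_pop, ayt_idx, generation = "AYT")
    invisible(simulate_phenotypes(ayt_pop, arch, ayt_design(cfg)))
    if (!is.null(state$baseline))
      ayt_metrics <- compute_metrics(ayt_pop, arch, state$baseline$means,
                                     state$baseline$sds)
  }

  state$pyt_pop <- pyt_pop
  state$pyt_em <- pyt_em
  state$dh_pop <- dh
  state$posterior <- posterior
  state$year <- state$year + 1L
  if (!is.null(state$baseline))
    state$last_metrics <- compute_metrics(dh, arch, state$baseline$means,
                                          state$baseline$sds)
  state$last_ayt_metrics <- ayt_metrics
  state
}

#' Run a treatment for a number of post-burn-in years
#'
#' Starting from a shared burn-in state, runs the yearly cycle under the
#' given treatment and logs per-year, per-trait genetic metrics of the DH
#' cohort. Year 0 is the post-burn-in baseline (the burn-in's final DH
#' cohort), so its gains are zero by construction and identical across
#' treatments sharing the burn-in state.
#'
#' @param state A `program_state` from [run_burn_in()].
#' @param treatment A `treatment`.
#' @param years Post-burn-in years to simulate (default from config).
#' @param seed Optional integer seed (stream for this treatment run).
#' @return A `program_result`: list with `log` (data frame: `year`, `trait`,
#'   `mean`, `variance`, `gain_raw`, `gain_std` plus treatment columns) and
#'   `state` (final).
#' @export
run_program <- function(state, treatment, years = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- state$config
  if (is.null(years)) years <- cfg$years_post_burnin
  if (is.null(state$baseline)) stop("state must come from run_burn_in()")
  base <- state$baseline
  logs <- vector("list", years + 1L)
  m0 <- compute_metrics(state$dh_pop, state$arch, base$means, base$sds)
  logs[[1L]] <- cbind(year = 0L, m0)
  for (y in seq_len(years)) {
    state <- run_year_cycle(state, treatment)
    logs[[y + 1L]] <- cbind(year = y, state$last_metrics)
  }
  log <- do.call(rbind, logs)
  log$method <- treatment$method
  log$n_parents <- treatment$n_parents
  log$n_crosses <- treatment$n_crosses
  log$progeny_per_cross <- treatment$progeny_per_cross
  structure(list(log = log, state = state, treatment = treatment),
            class = "program_result")
}

#' @export
print.program_result <- function(x, ...) {
  yrs <- max(x$log$year)
  cat("program result:", x$treatment$method, "|", yrs, "post-burn-in years\n")
  fin <- x$log[x$log$year == yrs, c("trait", "mean", "variance", "gain_std")]
  print(fin, row.names = FALSE)
  invisible(x)
}

#' @export
plot.program_result <- function(x, metric = c("mean", "variance", "gain_raw",
                                              "gain_std"), ...) {
  metric <- match.arg(metric)
  traits <- unique(x$log$trait)
  op <- par(mfrow = c(2, ceiling(length(traits) / 2)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (tr in traits) {
    d <- x$log[x$log$trait == tr, ]
    plot(d$year, d[[metric]], type = "l", xlab = "year post burn-in",
         ylab = metric, main = tr, ...)
  }
  invisible(x)
}

#' Set up a program from scratch
#'
#' Convenience wrapper: builds the genome, founders, site partition and
#' calibrated trait architecture from a configuration.
#'
#' @param config A `program_config`.
#' @param seed Optional integer seed.
#' @return List with `genome`, `founders`, `partition`, `arch`.
#' @export
init_program <- function(config = program_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- build_genome(config$genome$n_chrom, config$genome$chrom_length,
                    config$genome$sites_per_chrom)
  founders <- generate_founders(g, config$founders$n_founders,
                                config$founders$n_ancestral_haplotypes,
                                config$founders$n_drift_generations)
  part <- partition_sites(g, config$partition$qtn_per_chrom,
                          config$partition$snp_per_chrom)
  arch <- calibrate(sample_effects(part, config$traits, config$correlations),
                    founders)
  list(genome = g, founders = founders, partition = part, arch = arch)
}
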