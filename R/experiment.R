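#' Experiment configuration
#'
#' Bundles a [program_config()] with the treatment grid (numbers of parents,
#' cross/progeny pairings, methods), replication and seeding. At the full
#' scale the grid is 3 parent counts x 4 cross/progeny pairings x 5 methods
#' = 60 treatments, each replicated 50 times.
#'
#' @param program A `program_config`.
#' @param n_parents Parent counts of the grid.
#' @param crosses_progeny List of `c(n_crosses, progeny_per_cross)` pairings.
#' @param methods Cross-selection methods of the grid.
#' @param n_replicates Replicates per treatment.
#' @param master_seed Master seed; all run streams derive from it.
#' @param years Post-burn-in years.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(program = program_config(),
                              n_parents = c(30, 40, 50),
                              crosses_progeny = list(c(50, 300), c(100, 150),
                                                     c(150, 100), c(200, 75)),
                              methods = c("UC", "PMV", "OHV", "MeanGEBV",
                                          "RandPheno"),
                              n_replicates = 50, master_seed = 1,
                              years = program$years_post_burnin) {
  structure(list(program = program, n_parents = n_parents,
                 crosses_progeny = crosses_progeny, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 years = as.integer(years)),
            class = "experiment_config")
}

#' Enumerate the treatment grid
#' @param config An `experiment_config`.
#' @return Data frame with columns `treatment_id`, `method`, `n_parents`,
#'   `n_crosses`, `progeny_per_cross`.
#' @export
treatment_grid <- function(config) {
  rows <- list()
  for (m in config$methods)
    for (np in config$n_parents)
      for (cp in config$crosses_progeny)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, n_parents = np, n_crosses = cp[1L],
          progeny_per_cross = cp[2L])
  g <- do.call(rbind, rows)
  cbind(treatment_id = seq_len(nrow(g)), g)
}

#' Derive a run seed from the master seed
#'
#' Pure function of (master seed, treatment index, replicate index); no
#' global state. Treatment index 0 is reserved for the replicate's shared
#' burn-in stream.
#'
#' @param master_seed,treatment_id,replicate Integers.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, treatment_id, replicate) {
  s <- as.numeric(master_seed) %% 2147483647
  s <- (s * 69069 + as.numeric(treatment_id) * 40503 +
          as.numeric(replicate) * 7919) %% 2147483646
  as.integer(s + 1)
}

#' Load an experiment configuration from YAML
#'
#' Reads a nested-key YAML file, fills unspecified values from the package
#' defaults, and validates. All schema violations found are reported
#' together. Two packaged profiles are available via
#' `system.file("extdata", "full-scale.yaml", package = "crossel")` and
#' `"desk-small.yaml"`.
#'
#' @param path Path to a YAML configuration file.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  problems <- character(0)
  known_top <- c("program", "grid", "n_replicates", "master_seed", "years")
  bad <- setdiff(names(raw), known_top)
  if (length(bad))
    problems <- c(problems, paste("unknown top-level keys:",
                                  paste(bad, collapse = ", ")))

  prog <- program_config()
  p <- raw$program
  if (!is.null(p)) {
    known_prog <- names(unclass(prog))
    bad <- setdiff(names(p), known_prog)
    if (length(bad))
      problems <- c(problems, paste("unknown program keys:",
                                    paste(bad, collapse = ", ")))
    for (k in intersect(names(p), known_prog)) {
      v <- p[[k]]
      if (k == "traits") {
        v <- lapply(v, function(tr)
          trait_spec(tr$name, tr$target_mean, tr$target_variance,
                     tr$direction, tr$optimum))
        names(v) <- vapply(v, `[[`, "", "name")
      } else if (k == "correlations") {
        v <- do.call(rbind, lapply(v, as.numeric))
      } else if (is.list(prog[[k]]) && is.list(v)) {
        merged <- prog[[k]]
        bad2 <- setdiff(names(v), names(merged))
        if (length(bad2))
          problems <- c(problems, paste0("unknown keys in program$", k, ": ",
                                         paste(bad2, collapse = ", ")))
        merged[intersect(names(v), names(merged))] <-
          v[intersect(names(v), names(merged))]
        v <- merged
      }
      prog[[k]] <- v
    }
  }
  if (is.null(p$correlations) && !is.null(p$traits))
    warning("no correlation matrix supplied; using identity over the ",
            "configured traits")
  if (!is.null(p$traits) && is.null(p$correlations))
    prog$correlations <- diag(length(prog$traits))

  nt <- length(prog$traits)
  if (!is.matrix(prog$correlations) ||
      any(dim(prog$correlations) != c(nt, nt)))
    problems <- c(problems, "correlation matrix dimensions must match traits")
  h2all <- c(prog$h2$nursery, prog$h2$pyt, prog$h2$ayt)
  if (any(h2all <= 0 | h2all > 1))
    problems <- c(problems, "all heritabilities must lie in (0, 1]")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))

  grid <- raw$grid
  experiment_config(
    program = prog,
    n_parents = if (!is.null(grid$n_parents)) unlist(grid$n_parents)
                else c(30, 40, 50),
    crosses_progeny = if (!is.null(grid$crosses_progeny))
      lapply(grid$crosses_progeny, unlist)
      else list(c(50, 300), c(100, 150), c(150, 100), c(200, 75)),
    methods = if (!is.null(grid$methods)) unlist(grid$methods)
              else c("UC", "PMV", "OHV", "MeanGEBV", "RandPheno"),
    n_replicates = if (!is.null(raw$n_replicates)) raw$n_replicates else 50,
    master_seed = if (!is.null(raw$master_seed)) raw$master_seed else 1,
    years = if (!is.null(raw$years)) raw$years
            else prog$years_post_burnin)
}

#' Run the full treatment grid
#'
#' Executes every treatment for every replicate. Within a replicate the
#' burn-in is computed once (its stream depends only on the master seed and
#' the replicate index) and shared across treatments, so all methods start
#' from the same base population; each treatment then continues under its
#' own derived seed, making results independent of execution order. A
#' treatment that errors is recorded and does not affect the others.
#'
#' @param config An `experiment_config`.
#' @return A `results_table`: list with `raw` (concatenated metric logs with
#'   `replicate` column), `summary` (mean and sd over replicates per
#'   treatment x year x trait), and `errors`.
#' @export
run_grid <- function(config) {
  grid <- treatment_grid(config)
  raw <- list(); errors <- list()
  for (r in seq_len(config$n_replicates)) {
    setup_seed <- derive_seed(config$master_seed, 0L, r)
    setup <- init_program(config$program, seed = setup_seed)
    state0 <- run_burn_in(setup$founders, setup$arch, setup$partition,
                          config$program)
    for (ti in seq_len(nrow(grid))) {
      tr <- treatment(grid$method[ti], grid$n_parents[ti],
                      grid$n_crosses[ti], grid$progeny_per_cross[ti])
      res <- tryCatch(
        run_program(state0, tr, years = config$years,
                    seed = derive_seed(config$master_seed, ti, r)),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          treatment_id = ti, replicate = r, message = conditionMessage(res))
      } else {
        raw[[length(raw) + 1L]] <- cbind(res$log, replicate = r,
                                         treatment_id = grid$treatment_id[ti])
      }
    }
  }
  raw <- do.call(rbind, raw)
  structure(list(raw = raw, summary = summarize_results(raw),
                 errors = if (length(errors)) do.call(rbind, errors) else NULL,
                 grid = grid),
            class = "results_table")
}

#' Summarise raw metric logs over replicates
#' @param raw Raw log data frame (from `run_grid()$raw`).
#' @return Data frame of means and sds per treatment x year x trait.
#' @export
summarize_results <- function(raw) {
  key <- c("method", "n_parents", "n_crosses", "progeny_per_cross", "year",
           "trait")
  agg <- function(col, fn, nm) {
    out <- aggregate(raw[[col]], raw[key], fn)
    names(out)[ncol(out)] <- nm
    out
  }
  out <- agg("mean", mean, "mean_mean")
  for (spec in list(c("mean", "sd", "mean_sd"),
                    c("variance", "mean", "variance_mean"),
                    c("variance", "sd", "variance_sd"),
                    c("gain_raw", "mean", "gain_raw_mean"),
                    c("gain_std", "mean", "gain_std_mean"))) {
    out <- merge(out, agg(spec[1L], get(spec[2L]), spec[3L]), by = key)
  }
  out[order(out$method, out$n_parents, out$n_crosses, out$year, out$trait), ]
}

#' @export
print.results_table <- function(x, ...) {
  cat("results:", length(unique(x$raw$treatment_id)), "treatments x",
      length(unique(x$raw$replicate)), "replicates,",
      max(x$raw$year), "years\n")
  if (!is.null(x$errors)) cat("  (", nrow(x$errors), "failed runs )\n")
  invisible(x)
}

#' Write result tables and trajectory plots
#'
#' Writes `raw.csv` and `summary.csv` plus one PNG per trait x metric family
#' (genetic mean, standardised gain, genetic variance): trajectories over
#' years, one line per method, one panel per parents-by-crosses combination.
#'
#' @param results A `results_table`.
#' @param output_dir Directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
report <- function(results, output_dir) {
  if (is.null(results$raw) || nrow(results$raw) == 0L)
    stop("empty results")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(file.path(output_dir, "raw.csv"),
             file.path(output_dir, "summary.csv"))
  utils::write.csv(results$raw, files[1L], row.names = FALSE)
  utils::write.csv(results$summary, files[2L], row.names = FALSE)
  sm <- results$summary
  combos <- unique(sm[, c("n_parents", "n_crosses", "progeny_per_cross")])
  methods <- unique(sm$method)
  cols <- setNames(seq_along(methods), methods)
  for (tr in unique(sm$trait)) {
    for (metric in c("mean_mean", "gain_std_mean", "variance_mean")) {
      f <- file.path(output_dir, sprintf("%s_%s.png", tr,
                                         sub("_mean$", "", metric)))
      grDevices::png(f, width = 320 * min(nrow(combos), 4),
                     height = 320 * ceiling(nrow(combos) / 4))
      par(mfrow = c(ceiling(nrow(combos) / 4), min(nrow(combos), 4)),
          mar = c(4, 4, 2, 1))
      for (ci in seq_len(nrow(combos))) {
        d <- sm[sm$trait == tr &
                  sm$n_parents == combos$n_parents[ci] &
                  sm$n_crosses == combos$n_crosses[ci], ]
        plot(NULL, xlim = range(d$year), ylim = range(d[[metric]]),
             xlab = "year", ylab = sub("_mean$", "", metric),
             main = sprintf("%s | %dP x %dC", tr, combos$n_parents[ci],
                            combos$n_crosses[ci]))
        for (m in methods) {
          dm <- d[d$method == m, ]
          lines(dm$year, dm[[metric]], col = cols[m])
        }
        legend("topleft", legend = methods, col = cols, lty = 1, cex = 0.7,
               bty = "n")
      }
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Write a JSON run manifest
#' @param config An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("crossel")),
    master_seed = config$master_seed,
    n_replicates = config$n_replicates,
    years = config$years,
    n_treatments = nrow(treatment_grid(config)),
    timestamp = format(Sys.time(), tz = "UTC")
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
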