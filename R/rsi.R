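#' Rank individuals on one trait
#'
#' Rank 1 is best. For `direction = "increase"` the largest value ranks 1,
#' for `"decrease"` the smallest, and for `"optimum"` the value closest to
#' the target. Ties receive average ranks, which makes the ranking invariant
#' to the order individuals are listed in.
#'
#' @param values Numeric vector of trait measurements (finite).
#' @param spec A `trait_spec` giving the improvement direction.
#' @return Numeric vector of ranks (1 = best).
#' @examples
#' rank_trait(c(3, 9, 5), trait_spec("y", 0, 1, "increase"))
#' @export
rank_trait <- function(values, spec) {
  if (length(values) < 1L) stop("need at least one individual")
  if (any(!is.finite(values))) stop("trait values must be finite")
  key <- switch(spec$direction,
    increase = -values,
    decrease = values,
    optimum = abs(values - spec$optimum))
  rank(key, ties.method = "average")
}

#' Rank summation index (RSI)
#'
#' The multi-trait rank summation index: each individual is ranked within
#' each trait (respecting that trait's improvement direction) and the ranks
#' are summed. Lower sums indicate better overall performance. The RSI is the
#' derived phenotype used for parent selection and as the response of the
#' whole-genome regression.
#'
#' @param trait_matrix Numeric matrix (individuals x traits).
#' @param specs List of `trait_spec`s, one per column.
#' @return Numeric vector of index values (one per individual; lower is
#'   better), with `trait_matrix` row names preserved.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(10, 8, 9))
#' sp <- list(trait_spec("a", 0, 1, "increase"), trait_spec("b", 0, 1, "increase"))
#' rsi(m, sp)  # 4 5 3
#' @export
rsi <- function(trait_matrix, specs) {
  trait_matrix <- as.matrix(trait_matrix)
  if (ncol(trait_matrix) != length(specs))
    stop("one trait_spec is required per column of trait_matrix")
  ranks <- vapply(seq_along(specs),
                  function(j) rank_trait(trait_matrix[, j], specs[[j]]),
                  numeric(nrow(trait_matrix)))
  out <- rowSums(as.matrix(ranks))
  names(out) <- rownames(trait_matrix)
  out
}

# indices of the n best (lowest-RSI) individuals; ties broken by id order
# (radix sort: C-locale, independent of the session collation)
select_by_rsi <- function(index_values, n, ids = names(index_values)) {
  ord <- order(index_values, ids, method = "radix")
  ord[seq_len(n)]
}
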