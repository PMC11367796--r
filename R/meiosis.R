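#' Haldane recombination fraction
#'
#' Maps a genetic distance in Morgans to a recombination fraction under the
#' Haldane map function (no crossover interference):
#' \eqn{c = 0.5 (1 - e^{-2d})}.
#'
#' @param d Map distance in Morgans (>= 0); vectorised.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recombination_fraction(c(0, 0.1, 0.5, 10))
#' @export
recombination_fraction <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

gamete_matrix <- function(individual_haplo, genome, n) {
  cpp_gametes(individual_haplo, as.integer(n), genome$pos,
              genome$sites_per_chrom, genome$chrom_len)
}

#' Sample a gamete from an individual
#'
#' Crossovers per chromosome are Poisson with mean equal to the chromosome
#' map length, positions uniform on the map, starting haplotype chosen with
#' probability 1/2; chromosomes assort independently.
#'
#' @param pop A `population`.
#' @param individual Index (or id) of the individual within `pop`.
#' @return Integer vector of alleles over all sites.
#' @export
make_gamete <- function(pop, individual = 1L) {
  if (is.character(individual)) individual <- match(individual, pop$ids)
  rows <- c(2L * individual - 1L, 2L * individual)
  drop(gamete_matrix(pop$haplo[rows, , drop = FALSE], pop$genome, 1L))
}

#' Cross two parents
#'
#' Each progeny receives one gamete from each parent.
#'
#' @param pop A `population` containing both parents.
#' @param parent_a,parent_b Indices or ids of the parents within `pop`.
#' @param n_progeny Number of progeny (>= 1).
#' @param ids Optional progeny ids.
#' @param generation Generation tag (default `"F1"`).
#' @return A `population` of `n_progeny` individuals.
#' @export
make_cross <- function(pop, parent_a, parent_b, n_progeny,
                       ids = NULL, generation = "F1") {
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  if (is.character(parent_a)) parent_a <- match(parent_a, pop$ids)
  if (is.character(parent_b)) parent_b <- match(parent_b, pop$ids)
  g <- pop$genome
  ga <- gamete_matrix(pop$haplo[c(2L * parent_a - 1L, 2L * parent_a), ,
                                drop = FALSE], g, n_progeny)
  gb <- gamete_matrix(pop$haplo[c(2L * parent_b - 1L, 2L * parent_b), ,
                                drop = FALSE], g, n_progeny)
  haplo <- matrix(0L, nrow = 2L * n_progeny, ncol = g$n_sites)
  haplo[seq(1L, 2L * n_progeny, by = 2L), ] <- ga
  haplo[seq(2L, 2L * n_progeny, by = 2L), ] <- gb
  if (is.null(ids)) ids <- sprintf("%s_x_%s_%d", pop$ids[parent_a],
                                   pop$ids[parent_b], seq_len(n_progeny))
  new_population(g, haplo, ids, generation)
}

#' Derive doubled-haploid lines from an F1 individual
#'
#' Each DH line is a single gamete of the F1, doubled: the two haplotypes are
#' identical, so every DH is fully homozygous.
#'
#' @param pop A `population` containing the F1.
#' @param individual Index or id of the F1 within `pop`.
#' @param n_dh Number of DH lines.
#' @param ids Optional DH ids.
#' @param generation Generation tag (default `"DH"`).
#' @return A fully homozygous `population` of `n_dh` individuals.
#' @export
make_dh <- function(pop, individual = 1L, n_dh = 1L, ids = NULL,
                    generation = "DH") {
  if (n_dh < 1) stop("n_dh must be >= 1")
  if (is.character(individual)) individual <- match(individual, pop$ids)
  g <- pop$genome
  gam <- gamete_matrix(pop$haplo[c(2L * individual - 1L, 2L * individual), ,
                                 drop = FALSE], g, n_dh)
  haplo <- gam[rep(seq_len(n_dh), each = 2L), , drop = FALSE]
  if (is.null(ids)) ids <- sprintf("%s_DH%d", pop$ids[individual],
                                   seq_len(n_dh))
  new_population(g, haplo, ids, generation)
}

#' Proportion of heterozygous sites per individual
#' @param pop A `population`.
#' @return Numeric vector, one value per individual.
#' @export
heterozygosity <- function(pop) {
  n <- n_ind(pop)
  h1 <- pop$haplo[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- pop$haplo[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rowMeans(h1 != h2)
}
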