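#' Build a genome with evenly spaced sites
#'
#' Constructs the shared genome object used by all simulation components: a
#' set of chromosomes, each with a genetic map length in Morgans and a fixed
#' number of sites placed at equal map spacing (endpoints included).
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_lengths Map length in Morgans per chromosome; a scalar is
#'   recycled across chromosomes.
#' @param sites_per_chrom Number of sites per chromosome (>= 2); a scalar is
#'   recycled.
#' @return An object of class `genome`: a list with `n_chrom`, `chrom_len`,
#'   `sites_per_chrom`, per-site vectors `chrom` (chromosome index) and `pos`
#'   (within-chromosome position in Morgans), `site_ids`, and `n_sites`.
#' @examples
#' g <- build_genome(n_chrom = 2, chrom_lengths = 1, sites_per_chrom = 5)
#' g$n_sites
#' @export
build_genome <- function(n_chrom, chrom_lengths = 1, sites_per_chrom = 600) {
  if (length(n_chrom) != 1L || n_chrom < 1) stop("n_chrom must be >= 1")
  n_chrom <- as.integer(n_chrom)
  chrom_lengths <- rep_len(as.numeric(chrom_lengths), n_chrom)
  sites_per_chrom <- rep_len(as.integer(sites_per_chrom), n_chrom)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (any(sites_per_chrom < 2)) stop("sites_per_chrom must be >= 2")
  pos <- unlist(lapply(seq_len(n_chrom), function(c) {
    seq(0, chrom_lengths[c], length.out = sites_per_chrom[c])
  }))
  chrom <- rep(seq_len(n_chrom), sites_per_chrom)
  site_ids <- unlist(lapply(seq_len(n_chrom), function(c) {
    sprintf("c%d_s%d", c, seq_len(sites_per_chrom[c]))
  }))
  structure(list(
    n_chrom = n_chrom,
    chrom_len = chrom_lengths,
    sites_per_chrom = sites_per_chrom,
    chrom = chrom,
    pos = pos,
    site_ids = site_ids,
    n_sites = sum(sites_per_chrom)
  ), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", x$n_chrom, "chromosomes,", x$n_sites, "sites,",
      sum(x$chrom_len), "Morgans total map length\n")
  invisible(x)
}

new_population <- function(genome, haplo, ids, generation = "unknown") {
  stopifnot(ncol(haplo) == genome$n_sites, nrow(haplo) == 2L * length(ids))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  structure(list(genome = genome, haplo = haplo, ids = as.character(ids),
                 generation = generation),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("population:", n_ind(x), "individuals (", x$generation, "),",
      x$genome$n_sites, "sites\n")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `population` object.
#' @return Integer count.
#' @export
n_ind <- function(pop) nrow(pop$haplo) %/% 2L

#' Allele dosage matrix of a population
#'
#' @param pop A `population` object.
#' @param sites Optional integer vector of site indices to restrict to.
#' @return Integer matrix (individuals x sites) of allele dosages 0/1/2,
#'   with individual ids as row names.
#' @export
dosage <- function(pop, sites = NULL) {
  h <- pop$haplo
  if (!is.null(sites)) h <- h[, sites, drop = FALSE]
  n <- nrow(h) %/% 2L
  d <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(d) <- pop$ids
  d
}

#' Extract a subset of individuals from a population
#' @param pop A `population` object.
#' @param idx Integer indices or character ids of individuals to keep.
#' @param generation Optional new generation tag.
#' @return A `population` with the selected individuals.
#' @export
subset_population <- function(pop, idx, generation = pop$generation) {
  if (is.character(idx)) idx <- match(idx, pop$ids)
  if (anyNA(idx)) stop("unknown individual in subset")
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  new_population(pop$genome, pop$haplo[rows, , drop = FALSE],
                 pop$ids[idx], generation)
}

#' Merge populations over a shared genome
#' @param ... `population` objects with identical genomes.
#' @param generation Generation tag for the merged population.
#' @return A `population`.
#' @export
merge_populations <- function(..., generation = "merged") {
  pops <- list(...)
  g <- pops[[1L]]$genome
  new_population(g, do.call(rbind, lapply(pops, `[[`, "haplo")),
                 unlist(lapply(pops, `[[`, "ids")), generation)
}

#' Generate a founder population with LD structure
#'
#' Founders are built as recombinant mosaics of a small panel of ancestral
#' haplotypes: each site of each ancestral haplotype carries an allele drawn
#' Bernoulli(0.5), founders start as random pairs of ancestral haplotypes and
#' then undergo `n_drift_generations` of random mating through the meiosis
#' engine. This produces segregating, linkage-structured founders (LD decays
#' with map distance) without an external coalescent simulator. Any site fixed
#' after drift has its ancestral allele column redrawn (bounded retries) so
#' every returned site is polymorphic.
#'
#' @param genome A `genome`.
#' @param n_founders Number of founder individuals (>= 2).
#' @param n_ancestral_haplotypes Size of the ancestral haplotype panel
#'   (default 20).
#' @param n_drift_generations Random-mating generations applied to build LD
#'   (default 50).
#' @param max_retries Redraw attempts per fixed site before failing.
#' @return A `population` of `n_founders` individuals, every site segregating.
#' @examples
#' g <- build_genome(2, 1, 50)
#' set.seed(1)
#' f <- generate_founders(g, 20)
#' range(colMeans(dosage(f)) / 2)   # all allele frequencies in (0, 1)
#' @export
generate_founders <- function(genome, n_founders,
                              n_ancestral_haplotypes = 20,
                              n_drift_generations = 50,
                              max_retries = 50) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  K <- as.integer(n_ancestral_haplotypes)
  if (K < 2) stop("need at least 2 ancestral haplotypes")
  S <- genome$n_sites
  n2 <- 2L * n_founders

  # drift on ancestor *indices*; alleles are assigned afterwards so that a
  # site that fixes can be repaired by redrawing its ancestral allele column
  anc_idx <- matrix(sample.int(K, n2, replace = TRUE), nrow = n2, ncol = S)
  if (n_drift_generations > 0) {
    for (gen in seq_len(n_drift_generations)) {
      nxt <- matrix(0L, nrow = n2, ncol = S)
      for (i in seq_len(n_founders)) {
        par <- sample.int(n_founders, 2L)   # two distinct parents
        nxt[2L * i - 1L, ] <- cpp_gametes(
          anc_idx[c(2L * par[1L] - 1L, 2L * par[1L]), , drop = FALSE], 1L,
          genome$pos, genome$sites_per_chrom, genome$chrom_len)
        nxt[2L * i, ] <- cpp_gametes(
          anc_idx[c(2L * par[2L] - 1L, 2L * par[2L]), , drop = FALSE], 1L,
          genome$pos, genome$sites_per_chrom, genome$chrom_len)
      }
      anc_idx <- nxt
    }
  }

  # sites whose lineages all coalesced to one ancestor can never segregate;
  # graft the ancestor-index column of the nearest multi-ancestor site on the
  # same chromosome (locally near-identical mosaic, so LD is preserved)
  n_anc <- apply(anc_idx, 2L, function(col) length(unique(col)))
  if (any(n_anc == 1L)) {
    for (c in seq_len(genome$n_chrom)) {
      on_c <- which(genome$chrom == c)
      mono <- on_c[n_anc[on_c] == 1L]
      poly <- on_c[n_anc[on_c] > 1L]
      if (length(mono) == 0L) next
      if (length(poly) == 0L)
        stop("degenerate genome: could not keep all sites segregating")
      for (s in mono) {
        donor <- poly[which.min(abs(genome$pos[poly] - genome$pos[s]))]
        anc_idx[, s] <- anc_idx[, donor]
      }
    }
  }

  # assign Bernoulli(0.5) alleles to ancestors; redraw columns that fix
  anc_allele <- matrix(rbinom(K * S, 1L, 0.5), nrow = K, ncol = S)
  haplo <- matrix(0L, nrow = n2, ncol = S)
  for (s in seq_len(S)) haplo[, s] <- anc_allele[anc_idx[, s], s]
  fixed <- which(colSums(haplo) %in% c(0L, n2))
  tries <- 0L
  while (length(fixed) > 0L) {
    tries <- tries + 1L
    if (tries > max_retries)
      stop("degenerate genome: could not keep all sites segregating")
    for (s in fixed) {
      anc_allele[, s] <- rbinom(K, 1L, 0.5)
      haplo[, s] <- anc_allele[anc_idx[, s], s]
    }
    fixed <- fixed[colSums(haplo[, fixed, drop = FALSE]) %in% c(0L, n2)]
  }

  new_population(genome, haplo, sprintf("F%03d", seq_len(n_founders)),
                 generation = "founder")
}

#' Partition genome sites into QTN and SNP-chip sets
#'
#' Randomly draws disjoint QTN and marker (SNP chip) site sets per chromosome.
#' At the full configuration (7 chromosomes) the default QTN allocation
#' alternates 71/72 per chromosome (four chromosomes get 71 and three get 72)
#' so the total is exactly 500, with 500 chip SNPs per chromosome (3,500
#' total). The genomic prediction model only ever sees the SNP set, never the
#' QTN.
#'
#' @param genome A `genome`.
#' @param qtn_per_chrom Integer vector (recycled) of QTN counts per chromosome,
#'   or `NULL` for the default 71/72 alternation at 7 chromosomes.
#' @param snp_per_chrom Integer (recycled) count of chip SNPs per chromosome.
#' @return An object of class `site_partition`: list with sorted integer site
#'   index vectors `qtn` and `snp` (disjoint).
#' @export
partition_sites <- function(genome, qtn_per_chrom = NULL, snp_per_chrom = 500) {
  if (is.null(qtn_per_chrom)) {
    # four chromosomes at 71, three at 72: 4*71 + 3*72 = 500 at n_chrom = 7
    qtn_per_chrom <- rep(c(71L, 72L), length.out = genome$n_chrom)
    if (genome$n_chrom == 7L) qtn_per_chrom <- c(71L, 71L, 71L, 71L, 72L, 72L, 72L)
  }
  qtn_per_chrom <- rep_len(as.integer(qtn_per_chrom), genome$n_chrom)
  snp_per_chrom <- rep_len(as.integer(snp_per_chrom), genome$n_chrom)
  if (any(qtn_per_chrom < 0) || any(snp_per_chrom < 0))
    stop("site counts must be non-negative")
  if (any(qtn_per_chrom + snp_per_chrom > genome$sites_per_chrom))
    stop("requested QTN + SNP exceed available sites on some chromosome")
  qtn <- integer(0); snp <- integer(0)
  off <- 0L
  for (c in seq_len(genome$n_chrom)) {
    m <- genome$sites_per_chrom[c]
    pick <- sample.int(m, qtn_per_chrom[c] + snp_per_chrom[c])
    qtn <- c(qtn, off + pick[seq_len(qtn_per_chrom[c])])
    snp <- c(snp, off + pick[qtn_per_chrom[c] + seq_len(snp_per_chrom[c])])
    off <- off + m
  }
  structure(list(qtn = sort(qtn), snp = sort(snp)), class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat("site partition:", length(x$qtn), "QTN,", length(x$snp), "chip SNPs\n")
  invisible(x)
}

#' Export / import a genetic map as tab-delimited text
#'
#' Columns: `chrom` (1-based), `site_id`, `position_morgan`.
#'
#' @param genome A `genome`.
#' @param path File path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   `genome`.
#' @export
write_map <- function(genome, path) {
  df <- data.frame(chrom = genome$chrom, site_id = genome$site_ids,
                   position_morgan = genome$pos)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "site_id", "position_morgan") %in% names(df)))
    stop("map file must have columns chrom, site_id, position_morgan")
  df <- df[order(df$chrom, df$position_morgan), ]
  chroms <- sort(unique(df$chrom))
  sites_per_chrom <- as.integer(table(factor(df$chrom, levels = chroms)))
  pos <- df$position_morgan
  for (i in seq_along(chroms)) {
    p <- pos[df$chrom == chroms[i]]
    if (any(diff(p) <= 0)) stop("map positions must be strictly increasing")
  }
  g <- structure(list(
    n_chrom = length(chroms),
    chrom_len = as.numeric(tapply(df$position_morgan, df$chrom, max)),
    sites_per_chrom = sites_per_chrom,
    chrom = match(df$chrom, chroms),
    pos = pos,
    site_ids = df$site_id,
    n_sites = nrow(df)
  ), class = "genome")
  g
}

#' Export haplotypes or dosages as delimited text
#'
#' @param pop A `population`.
#' @param path File path.
#' @param what `"dosage"` (individuals x sites, 0/1/2) or `"haplotype"`
#'   (two rows per individual, 0/1).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path, what = c("dosage", "haplotype")) {
  what <- match.arg(what)
  m <- if (what == "dosage") dosage(pop) else {
    h <- pop$haplo
    rownames(h) <- paste0(rep(pop$ids, each = 2L), c("_h1", "_h2"))
    h
  }
  colnames(m) <- pop$genome$site_ids
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
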