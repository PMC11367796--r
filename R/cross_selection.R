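#' Rogers' distance between two genotypes
#'
#' For biallelic loci with within-individual allele frequency p = dosage/2,
#' \eqn{RD = \frac{1}{m}\sum_j |p_{Aj} - p_{Bj}|}. For fully inbred lines
#' this is the proportion of loci at which the two lines differ.
#'
#' @param dosage_a,dosage_b Dosage vectors (0/1/2) over the same marker set.
#' @return Distance in `[0, 1]`.
#' @export
rogers_distance <- function(dosage_a, dosage_b) {
  if (length(dosage_a) == 0L) stop("need at least one marker")
  if (length(dosage_a) != length(dosage_b)) stop("marker sets must match")
  mean(abs(dosage_a - dosage_b)) / 2
}

#' Expected progeny mean of a cross
#'
#' The mid-parent GEBV: \eqn{\mu_{P_A \times P_B} = (GEBV_A + GEBV_B)/2}.
#'
#' @param gebv_a,gebv_b Parental GEBVs.
#' @return Numeric; vectorised and symmetric in its arguments.
#' @export
mean_gebv_cross <- function(gebv_a, gebv_b) (gebv_a + gebv_b) / 2

#' LD parameter of a parent pair at two loci
#'
#' The linkage-phase parameter \eqn{D_{jk}} feeding the progeny covariance:
#' 0 if the two (inbred) parents share the same allele at either locus,
#' +0.25 when the differing alleles are in coupling phase and -0.25 in
#' repulsion.
#'
#' @param a_j,b_j Parent A's and B's allele (0/1) at locus j.
#' @param a_k,b_k Alleles at locus k.
#' @return One of 0, 0.25, -0.25.
#' @export
ld_parameter <- function(a_j, b_j, a_k, b_k) {
  al <- c(a_j, b_j, a_k, b_k)
  if (!all(al %in% c(0, 1))) stop("alleles must be 0/1 (inbred parents)")
  if (a_j == b_j || a_k == b_k) return(0)
  if ((a_j - b_j) * (a_k - b_k) > 0) 0.25 else -0.25
}

# one representative haplotype per individual, erroring on heterozygosity
inbred_haplotypes <- function(pop, individuals, sites) {
  rows1 <- 2L * individuals - 1L
  rows2 <- 2L * individuals
  h1 <- pop$haplo[rows1, sites, drop = FALSE]
  h2 <- pop$haplo[rows2, sites, drop = FALSE]
  if (any(h1 != h2))
    stop("cross metrics require parents inbred (homozygous) at all markers")
  h1
}

#' Progeny allele covariance matrix of a cross
#'
#' For DH progeny of the F1 of two inbred parents, the covariance between
#' allele dosages at marker loci j and k is
#' \eqn{\Sigma_{jk} = 4 D_{jk} (1 - 2 c_{jk})}, with \eqn{D_{jk}} the
#' parental linkage-phase parameter ([ld_parameter()]) and \eqn{c_{jk}} the
#' Haldane recombination fraction for the map distance between the loci
#' (0.5 across chromosomes, so cross-chromosome entries vanish). Diagonal
#' entries are 1 at loci segregating between the parents and 0 elsewhere.
#'
#' @param pop A `population` holding both parents.
#' @param parent_a,parent_b Indices or ids of the (inbred) parents.
#' @param markers Site indices to build the matrix over (default: all sites).
#' @return Symmetric positive semidefinite matrix (markers x markers).
#' @export
progeny_covariance <- function(pop, parent_a, parent_b, markers = NULL) {
  g <- pop$genome
  if (is.null(markers)) markers <- seq_len(g$n_sites)
  if (any(markers < 1L | markers > g$n_sites))
    stop("markers out of range for this genome")
  if (is.character(parent_a)) parent_a <- match(parent_a, pop$ids)
  if (is.character(parent_b)) parent_b <- match(parent_b, pop$ids)
  h <- inbred_haplotypes(pop, c(parent_a, parent_b), markers)
  delta <- h[1L, ] - h[2L, ]                 # in {-1, 0, 1}
  r <- phase_decay_matrix(g, markers)
  sig <- tcrossprod(delta) * r
  dimnames(sig) <- list(g$site_ids[markers], g$site_ids[markers])
  sig
}

# block-diagonal matrix of (1 - 2 c_jk) = exp(-2 d_jk) over marker positions
phase_decay_matrix <- function(genome, markers) {
  p <- length(markers)
  r <- matrix(0, p, p)
  chrom <- genome$chrom[markers]
  pos <- genome$pos[markers]
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    d <- abs(outer(pos[i], pos[i], "-"))
    r[i, i] <- exp(-2 * d)
  }
  r
}

#' Posterior mean-variance of a cross (PMV)
#'
#' The predicted within-cross progeny variance of the index:
#' \eqn{PMV = \frac{1}{L} \sum_{l=1}^{L} \beta^{(l)\prime} \Sigma \beta^{(l)}},
#' averaging the quadratic form over the retained posterior marker-effect
#' draws. With a point-mass posterior (one draw) this reduces to
#' \eqn{\hat\beta' \Sigma \hat\beta}.
#'
#' @param posterior A `brr_fit`, or a numeric matrix of posterior draws
#'   (L x markers), or a single effect vector (point mass).
#' @param sigma Progeny covariance matrix from [progeny_covariance()].
#' @return Non-negative scalar.
#' @export
pmv <- function(posterior, sigma) {
  B <- posterior_draws(posterior)
  if (nrow(B) == 0L) stop("posterior has no retained draws")
  if (ncol(B) != ncol(sigma))
    stop("posterior draws and covariance matrix disagree on marker count")
  # (1/L) sum_l b' Sigma b = sum(Sigma * crossprod(B)/L)
  sum(sigma * crossprod(B)) / nrow(B)
}

posterior_draws <- function(posterior) {
  if (inherits(posterior, "brr_fit")) return(posterior$beta)
  if (is.matrix(posterior)) return(posterior)
  matrix(posterior, nrow = 1L)
}

#' Standardised selection intensity
#'
#' Mean of the selected upper tail of a standard normal:
#' \eqn{i = \phi(\Phi^{-1}(1 - p)) / p} for selected proportion p.
#'
#' @param p Selected proportion in (0, 1]; vectorised.
#' @return Intensity (>= 0); 0 at p = 1.
#' @examples
#' selection_intensity(c(1, 0.5, 0.1))
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p > 1)) stop("selected proportion must be in (0, 1]")
  dnorm(qnorm(1 - p)) / p
}

#' Usefulness criterion of a cross
#'
#' \eqn{UC = \mu + i \sigma_g}: the expected mean of the selected fraction of
#' the cross's progeny, with \eqn{\mu} the mid-parent GEBV, i the selection
#' intensity and \eqn{\sigma_g = \sqrt{PMV}} the predicted progeny standard
#' deviation of the index.
#'
#' @param mean_value Mid-parent GEBV ([mean_gebv_cross()]).
#' @param i Selection intensity ([selection_intensity()]).
#' @param pmv_value Predicted progeny variance (>= 0).
#' @return Numeric; `UC >= mean_value` whenever `i >= 0`.
#' @export
uc <- function(mean_value, i, pmv_value) {
  if (any(pmv_value < 0)) stop("pmv_value must be non-negative")
  mean_value + i * sqrt(pmv_value)
}

#' Partition markers into map segments
#'
#' Splits each chromosome's map into `segments_per_chrom` equal-length
#' intervals and assigns markers by position; empty intervals are dropped.
#' Used by the optimal haploid value.
#'
#' @param genome A `genome`.
#' @param markers Marker site indices.
#' @param segments_per_chrom Number of segments per chromosome (default 3).
#' @return List of integer vectors indexing into `markers`.
#' @export
make_segments <- function(genome, markers, segments_per_chrom = 3) {
  segs <- list()
  chrom <- genome$chrom[markers]
  pos <- genome$pos[markers]
  for (c in seq_len(genome$n_chrom)) {
    i <- which(chrom == c)
    if (length(i) == 0L) next
    br <- seq(0, genome$chrom_len[c], length.out = segments_per_chrom + 1L)
    bin <- findInterval(pos[i], br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (s in seq_len(segments_per_chrom)) {
      idx <- i[bin == s]
      if (length(idx) > 0L) segs[[length(segs) + 1L]] <- idx
    }
  }
  segs
}

#' Optimal haploid value of a parent pair
#'
#' \eqn{OHV = 2 \sum_{segments} \max(H^s \beta^s)}: per map segment, the best
#' haplotype score among the parents' haplotypes, doubled — the index value
#' of the ideal DH recoverable from the cross. For an inbred pair each parent
#' contributes one distinct haplotype per segment.
#'
#' @param pop A `population` holding both parents.
#' @param parent_a,parent_b Indices or ids of the (inbred) parents.
#' @param beta_hat Estimated marker effects (length = number of markers).
#' @param markers Marker site indices.
#' @param segments Segment list from [make_segments()] (indices into
#'   `markers`).
#' @return Scalar OHV; always at least the larger parental GEBV.
#' @export
ohv <- function(pop, parent_a, parent_b, beta_hat, markers,
                segments = make_segments(pop$genome, markers)) {
  if (any(lengths(segments) == 0L)) stop("empty segment")
  if (is.character(parent_a)) parent_a <- match(parent_a, pop$ids)
  if (is.character(parent_b)) parent_b <- match(parent_b, pop$ids)
  h <- inbred_haplotypes(pop, c(parent_a, parent_b), markers)
  contrib <- h * rep(beta_hat, each = 2L)
  seg_scores <- vapply(segments,
                       function(s) rowSums(contrib[, s, drop = FALSE]),
                       numeric(2L))
  2 * sum(apply(as.matrix(seg_scores), 2L, max))
}

# Batch PMV over many parent pairs sharing one posterior.
# delta: markers x n_pairs matrix of parental allele differences.
# Uses sum(Q * outer(delta, delta)) with Q = phase_decay * posterior second
# moment, block-diagonal by chromosome.
pmv_batch <- function(B, delta, genome, markers) {
  L <- nrow(B)
  chrom <- genome$chrom[markers]
  pos <- genome$pos[markers]
  out <- numeric(ncol(delta))
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    M <- crossprod(B[, i, drop = FALSE]) / L
    Q <- M * exp(-2 * abs(outer(pos[i], pos[i], "-")))
    dc <- delta[i, , drop = FALSE]
    out <- out + colSums(dc * (Q %*% dc))
  }
  out
}

#' Score candidate parent pairs and select a crossing plan
#'
#' Enumerates all unordered pairs of the supplied (inbred) parents, scores
#' every pair with Rogers' distance, mid-parent GEBV, PMV, UC and OHV, and
#' selects the top `n_crosses` pairs by the requested method. The GEBV scale
#' is treated as a merit (higher is better); the breeding-program driver fits
#' the regression on the negated rank summation index so this orientation
#' holds. For `method = "MeanGEBV"` pairs are prefiltered by Rogers' distance
#' before ranking (threshold and direction configurable; if the filter
#' leaves fewer than `n_crosses` pairs it is dropped with a warning).
#' `method = "RandPheno"` draws pairs uniformly without replacement.
#'
#' @param pop A `population` holding the candidate parents (all of them).
#' @param posterior A `brr_fit` (may be `NULL` for `method = "RandPheno"`,
#'   in which case metric columns are `NA`).
#' @param markers Marker site indices (the SNP chip).
#' @param method One of `"UC"`, `"PMV"`, `"OHV"`, `"MeanGEBV"`,
#'   `"RandPheno"`.
#' @param n_crosses Number of crosses to select.
#' @param progeny_per_cross Progeny budget per cross.
#' @param intensity_p Selected proportion for the UC intensity (default
#'   400/15,000).
#' @param segments_per_chrom OHV segments per chromosome.
#' @param distance_threshold,distance_direction MeanGEBV prefilter: keep
#'   pairs with Rogers' distance `"lt"` (default, the literal published rule)
#'   or `"gt"` the threshold. `"gt"` is arguably the intended direction
#'   (crossing *distant* parents limits coancestry); both are supported.
#' @return A `cross_plan`: data frame with one row per candidate pair,
#'   columns `parent_a`, `parent_b`, `rogers_distance`, `mean_gebv`, `pmv`,
#'   `uc`, `ohv`, `score`, `selected`, `n_progeny`; attributes `method` and
#'   `n_crosses`. Selected rows are ordered first.
#' @export
select_crosses <- function(pop, posterior, markers,
                           method = c("UC", "PMV", "OHV", "MeanGEBV",
                                      "RandPheno"),
                           n_crosses, progeny_per_cross,
                           intensity_p = 400 / 15000,
                           segments_per_chrom = 3,
                           distance_threshold = 0.1,
                           distance_direction = c("lt", "gt")) {
  method <- match.arg(method)
  distance_direction <- match.arg(distance_direction)
  n_par <- n_ind(pop)
  if (n_par < 2L) stop("need at least two parents")
  pairs <- which(upper.tri(matrix(0, n_par, n_par)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  n_pairs <- nrow(pairs)
  if (n_pairs < n_crosses) stop("fewer candidate pairs than n_crosses")

  dos <- dosage(pop, markers)
  rd <- as.matrix(dist(dos, method = "manhattan")) / (2 * length(markers))
  rd_pair <- rd[pairs]

  if (!is.null(posterior)) {
    h <- inbred_haplotypes(pop, seq_len(n_par), markers)   # parents x markers
    bh <- posterior$beta_hat
    pg <- gebv(dos, bh)
    mg <- mean_gebv_cross(pg[pairs[, 1L]], pg[pairs[, 2L]])
    delta <- t(h[pairs[, 1L], , drop = FALSE] - h[pairs[, 2L], , drop = FALSE])
    pmv_v <- pmv_batch(posterior$beta, delta, pop$genome, markers)
    pmv_v[pmv_v < 0] <- 0          # guard tiny negative rounding
    uc_v <- uc(mg, selection_intensity(intensity_p), pmv_v)
    segs <- make_segments(pop$genome, markers, segments_per_chrom)
    seg_scores <- vapply(segs,
                         function(s) rowSums((h * rep(bh, each = n_par))[, s, drop = FALSE]),
                         numeric(n_par))
    seg_scores <- as.matrix(seg_scores)
    ohv_v <- 2 * rowSums(pmax(seg_scores[pairs[, 1L], , drop = FALSE],
                              seg_scores[pairs[, 2L], , drop = FALSE]))
  } else {
    if (method != "RandPheno")
      stop("method ", method, " requires a fitted posterior")
    mg <- pmv_v <- uc_v <- ohv_v <- rep(NA_real_, n_pairs)
  }

  plan <- data.frame(
    parent_a = pop$ids[pairs[, 1L]],
    parent_b = pop$ids[pairs[, 2L]],
    rogers_distance = rd_pair,
    mean_gebv = mg, pmv = pmv_v, uc = uc_v, ohv = ohv_v,
    stringsAsFactors = FALSE)

  eligible <- rep(TRUE, n_pairs)
  if (method == "MeanGEBV") {
    eligible <- if (distance_direction == "lt") rd_pair < distance_threshold
                else rd_pair > distance_threshold
    if (sum(eligible) < n_crosses) {
      warning("Rogers-distance prefilter left fewer pairs than n_crosses; ",
              "falling back to unfiltered ranking")
      eligible <- rep(TRUE, n_pairs)
    }
  }

  if (method == "RandPheno") {
    sel_idx <- sample(which(eligible), n_crosses)
    plan$score <- NA_real_
  } else {
    plan$score <- switch(method, UC = uc_v, PMV = pmv_v, OHV = ohv_v,
                         MeanGEBV = mg)
    # radix: C-locale tie-breaking, independent of session collation
    ord <- order(!eligible, -plan$score, plan$parent_a, plan$parent_b,
                 method = "radix")
    sel_idx <- ord[seq_len(n_crosses)]
  }
  plan$selected <- FALSE
  plan$selected[sel_idx] <- TRUE
  plan$n_progeny <- ifelse(plan$selected, progeny_per_cross, 0L)
  plan <- plan[order(-plan$selected, plan$parent_a, plan$parent_b,
                     method = "radix"), ]
  rownames(plan) <- NULL
  attr(plan, "method") <- method
  attr(plan, "n_crosses") <- n_crosses
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

#' @export
print.cross_plan <- function(x, ...) {
  cat("cross plan (", attr(x, "method"), "):", attr(x, "n_crosses"),
      "crosses selected from", nrow(x), "candidate pairs,",
      sum(x$n_progeny), "total progeny\n")
  print.data.frame(utils::head(x[x$selected, ], 10L))
  invisible(x)
}

#' Write a cross report as CSV
#' @param plan A `cross_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cross_report <- function(plan, path) {
  df <- as.data.frame(plan)
  df$method <- attr(plan, "method")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
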