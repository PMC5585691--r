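#' Alpha diversity indices
#'
#' Shannon entropy (natural log), observed richness, and Pielou's evenness.
#' Diversity is conventionally computed on common-scaled, singleton-removed
#' tables without further filtering, which removes the dependence of observed
#' diversity on sequencing depth.
#'
#' @param abundances Non-negative numeric vector (counts or relative
#'   abundances; the indices are invariant to rescaling).
#' @return `shannon()`: entropy in nats, in `[0, log(S)]`. `richness()`:
#'   number of taxa with positive abundance. `pielou()`: `H / log(richness)`
#'   in `(0, 1]`, defined as 1 for a single-taxon sample.
#' @export
shannon <- function(abundances) {
  .check_abund(abundances)
  p <- abundances[abundances > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
richness <- function(abundances) {
  .check_abund(abundances)
  sum(abundances > 0)
}

#' @rdname shannon
#' @export
pielou <- function(abundances) {
  s <- richness(abundances)
  if (s == 1) return(1)
  shannon(abundances) / log(s)
}

.check_abund <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  if (all(x == 0)) stop("all-zero abundance vector")
  invisible(x)
}

#' Per-sample diversity table
#'
#' @param x A [count_table()].
#' @return data.frame with one row per sample: `sample_id`, `shannon`,
#'   `richness`, `pielou`.
#' @export
diversity_table <- function(x) {
  v <- x$values
  data.frame(
    sample_id = sample_ids(x),
    shannon = apply(v, 2, shannon),
    richness = apply(v, 2, richness),
    pielou = apply(v, 2, pielou),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis distance matrix
#'
#' `d(a, b) = sum |x_a - x_b| / sum (x_a + x_b)` between sample columns.
#'
#' @param x A [count_table()] with at least two samples.
#' @return A `dist` object labelled with sample ids; entries in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  if (ncol(x$values) < 2) stop("need at least two samples")
  zero <- colSums(x$values) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for a pair of all-zero samples: ",
         paste(sample_ids(x)[zero], collapse = ", "))
  vegan::vegdist(t(x$values), method = "bray")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between-group versus within-group
#' distances. `R = (mean_between_rank - mean_within_rank) / (M / 2)` with
#' `M = n(n-1)/2`. The permutation p-value uses the +1 correction,
#' `p = (1 + #{R* >= R_obs}) / (1 + n_perm)`, so it can never be exactly
#' zero. With `exact = TRUE` (two groups only) all distinct label
#' assignments are enumerated and `p = #{R* >= R_obs} / #assignments`.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param groups Group labels, one per sample; every group must have at least
#'   two members.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Optional integer seed for the permutations.
#' @param exact Enumerate all assignments instead of sampling (two groups).
#' @return List with `statistic` (R), `p_value`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 10000, seed = NULL,
                        exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match number of samples")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2))
    stop("group of size 1: ", names(sizes)[sizes < 2][1])
  lower <- lower.tri(dm)
  r <- rank(dm[lower])
  M <- n * (n - 1) / 2
  same <- outer(groups, groups, "==")[lower]
  stat_for <- function(within) {
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  r_obs <- stat_for(same)
  if (exact) {
    if (length(sizes) != 2)
      stop("exact enumeration supported for two groups only")
    g1 <- names(sizes)[1]
    combos <- utils::combn(n, sizes[[1]])
    r_perm <- apply(combos, 2, function(idx) {
      lab <- rep(names(sizes)[2], n)
      lab[idx] <- g1
      stat_for(outer(lab, lab, "==")[lower])
    })
    p <- mean(r_perm >= r_obs - 1e-12)
    return(list(statistic = r_obs, p_value = p, n_perm = length(r_perm)))
  }
  if (!is.null(seed)) set.seed(seed)
  r_perm <- replicate(n_perm, {
    lab <- sample(groups)
    stat_for(outer(lab, lab, "==")[lower])
  })
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  list(statistic = r_obs, p_value = p, n_perm = n_perm)
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via iterative majorization, started from the
#' classical metric-scaling (PCoA) configuration, with optional random
#' restarts; the lowest-stress solution is returned. Coordinates are defined
#' only up to rotation, reflection and translation.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of dimensions (default 2; must be `< n - 1`).
#' @param n_restarts Additional random starting configurations (default 0).
#' @param seed Optional seed for the random restarts.
#' @param maxit Maximum iterations per start.
#' @return List with `points` (n x k matrix), `stress` (Kruskal stress-1 as a
#'   fraction), and `converged`.
#' @export
nmds <- function(d, k = 2, n_restarts = 0, seed = NULL, maxit = 100) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  if (!is.null(seed)) set.seed(seed)
  # jitter zero distances: isoMDS requires positive dissimilarities
  dv <- as.vector(d)
  if (any(dv == 0)) {
    eps <- min(dv[dv > 0], na.rm = TRUE) * 1e-4
    d[as.vector(d) == 0] <- eps
  }
  # PCoA start; rank deficiency is expected for k near n and padded below
  start <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(start) < k)
    start <- cbind(start, matrix(0, nrow = n, ncol = k - ncol(start)))
  fits <- list(MASS::isoMDS(d, y = start, k = k, maxit = maxit, trace = FALSE))
  if (n_restarts > 0) {
    for (i in seq_len(n_restarts)) {
      y0 <- matrix(stats::rnorm(n * k), n, k)
      fits[[i + 1]] <- tryCatch(
        MASS::isoMDS(d, y = y0, k = k, maxit = maxit, trace = FALSE),
        error = function(e) NULL)
    }
    fits <- Filter(Negate(is.null), fits)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  rownames(best$points) <- attr(d, "Labels")
  list(points = best$points, stress = best$stress / 100,
       converged = TRUE)
}

#' Correlation between two distance matrices
#'
#' Pearson correlation over the strictly-lower-triangle entries; used to
#' check the robustness of sample structuring to collapsing OTU tables to
#' the genus level.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples in
#'   the same order.
#' @return Pearson correlation coefficient.
#' @export
matrix_correlation <- function(d1, d2) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices have different sizes")
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices are over different sample sets")
  stats::cor(m1[lower.tri(m1)], m2[lower.tri(m2)])
}
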