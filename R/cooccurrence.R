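#' Construct a correlation matrix object
#'
#' @param values Symmetric numeric matrix in `[-1, 1]` with unit diagonal.
#' @param method `"spearman"` or `"sparcc"`.
#' @param flavor `"temporal"` (contemporaneous, fecal time series) or
#'   `"spatial"` (biopsy site-mean profiles).
#' @return Object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(values, method, flavor) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("matrix must be symmetric")
  values <- (values + t(values)) / 2
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  structure(list(values = values, method = method, flavor = flavor,
                 taxa_ids = rownames(values)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix (", x$method, ", ", x$flavor, "): ",
      nrow(x$values), " taxa\n", sep = "")
  invisible(x)
}

#' Spearman co-occurrence matrix
#'
#' Pairwise Spearman rank correlations between per-taxon relative abundance
#' profiles across samples, with average ranks for ties. Constant taxa get
#' zero correlations and are flagged degenerate.
#'
#' @param x A [count_table()] (converted to relative abundances) with at
#'   least 3 samples.
#' @param flavor Stored on the result: `"temporal"` or `"spatial"`.
#' @return A `correlation_matrix`; degenerate taxa are listed in the
#'   `degenerate` element.
#' @export
spearman_matrix <- function(x, flavor = "temporal") {
  if (ncol(x$values) < 3) stop("need at least 3 samples")
  rel <- relative_abundance(x)
  const <- apply(rel, 1, function(z) stats::var(z) == 0)
  r <- suppressWarnings(stats::cor(t(rel), method = "spearman"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  cm <- correlation_matrix(r, "spearman", flavor)
  cm$degenerate <- rownames(rel)[const]
  cm
}

# Dirichlet-resampled fractions: one draw per sample column, prior +1
.dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow = nrow(counts))
  sweep(g, 2, colSums(g), "/")
}

# One SparCC correlation estimate from a matrix of log fractions:
# basis variances solved from the log-ratio variation matrix under the
# sparsity assumption, with iterative exclusion of strongly correlated pairs.
.sparcc_once <- function(logf, n_outer, exclusion_threshold) {
  d <- nrow(logf)
  V <- stats::cov(t(logf))
  vars <- diag(V)
  TT <- outer(vars, vars, "+") - 2 * V    # variation matrix t_ij
  M <- matrix(1, d, d) + diag(d - 2, d)
  tvec <- rowSums(TT)
  excluded <- matrix(FALSE, d, d)
  rho <- NULL
  for (round in seq_len(n_outer + 1)) {
    omega <- tryCatch(solve(M, tvec), error = function(e) NULL)
    if (is.null(omega)) {
      warning("basis-variance system singular after exclusions; ",
              "returning last stable estimate")
      break
    }
    omega[omega <= 0] <- .Machine$double.eps
    denom <- 2 * sqrt(outer(omega, omega))
    rho_new <- (outer(omega, rep(1, d)) + outer(rep(1, d), omega) - TT) / denom
    rho_new[rho_new > 1] <- 1
    rho_new[rho_new < -1] <- -1
    diag(rho_new) <- 1
    rho <- rho_new
    if (round > n_outer) break
    cand <- abs(rho)
    cand[excluded | row(cand) >= col(cand)] <- 0
    # a taxon excluded from too many pairs would make its row unidentifiable
    deg <- diag(M)
    cand[deg <= 2, ] <- 0
    cand[, deg <= 2] <- 0
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[mx[1], mx[2]] <= exclusion_threshold) break
    i <- mx[1]; j <- mx[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    tvec[i] <- tvec[i] - TT[i, j]
    tvec[j] <- tvec[j] - TT[i, j]
  }
  rho
}

#' SparCC co-occurrence matrix
#'
#' Sparse compositional correlation: estimates correlations between the
#' (unobserved) basis abundances underlying compositional count data. Each
#' inner iteration resamples fractions from a per-sample Dirichlet posterior
#' (counts + 1), computes the log-ratio variation matrix
#' `t_ij = var(log(x_i / x_j))`, solves the linear system for basis
#' variances under the assumption that the underlying correlation network
#' is sparse, and iteratively excludes the most strongly correlated pair
#' above `exclusion_threshold` (up to `n_outer` rounds) before re-solving.
#' The final estimate is the elementwise median over inner iterations,
#' clipped to `[-1, 1]`.
#'
#' @param x A [count_table()] of counts (>= 4 taxa; the basis-variance
#'   system is not solvable below that).
#' @param n_outer Maximum exclusion rounds (default 10).
#' @param exclusion_threshold Correlation magnitude above which a pair is
#'   excluded from the basis-variance estimation (default 0.1).
#' @param n_inner Number of Dirichlet resamplings (default 20).
#' @param seed Optional integer seed (fixed seed gives identical output).
#' @param flavor Stored on the result: `"temporal"` or `"spatial"`.
#' @return A `correlation_matrix`.
#' @export
sparcc_matrix <- function(x, n_outer = 10, exclusion_threshold = 0.1,
                          n_inner = 20, seed = NULL, flavor = "temporal") {
  if (nrow(x$values) < 4) stop("SparCC needs at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  ests <- vector("list", n_inner)
  for (k in seq_len(n_inner)) {
    f <- .dirichlet_fractions(x$values)
    ests[[k]] <- .sparcc_once(log(f), n_outer, exclusion_threshold)
  }
  ests <- Filter(Negate(is.null), ests)
  if (!length(ests)) stop("SparCC failed on every resampling")
  arr <- simplify2array(ests)
  med <- apply(arr, c(1, 2), stats::median)
  dimnames(med) <- list(taxa_ids(x), taxa_ids(x))
  correlation_matrix(med, "sparcc", flavor)
}

#' Site-mean spatial profile table
#'
#' Mean relative abundance per OTU per GI site (over the replicate
#' biopsies), columns ordered from the terminal ileum to the rectum. This
#' 7-column table is the input for spatial co-occurrence.
#'
#' @param x A biopsy [count_table()].
#' @param metadata Biopsy sample metadata.
#' @return A [count_table()] of mean relative abundances with one column per
#'   site present, ordered TI to R.
#' @export
spatial_profile_table <- function(x, metadata) {
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (any(md$sample_type != "biopsy")) stop("all samples must be biopsies")
  rel <- relative_abundance(x)
  sites <- intersect(gi_sites, unique(md$site))
  reps <- table(md$site)
  if (length(unique(reps)) > 1)
    warning("unequal replicate counts per site; averaging over available")
  prof <- vapply(sites, function(s)
    rowMeans(rel[, md$site == s, drop = FALSE]), numeric(nrow(rel)))
  count_table(prof, taxa_ids = taxa_ids(x), sample_ids = sites)
}
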