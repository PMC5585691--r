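#' Log relative abundance series
#'
#' Transforms a fecal count time series to log relative abundances,
#' `x = log((count + pc) / (library + S * pc))` with pseudocount `pc`
#' (default 0.5, the standard continuity correction) and `S` the number of
#' taxa, guaranteeing finite values at zero counts. Samples are ordered by
#' collection day.
#'
#' @param x A [count_table()] of fecal samples (typically
#'   consistency-filtered, 0.05% of reads in >= 90% of samples).
#' @param metadata Sample metadata with a `day` column, or `NULL` if the
#'   columns of `x` are already day-ordered with days 1..T.
#' @param pseudocount Pseudocount in (scaled) reads (default 0.5).
#' @return List of class `log_abundance_series`: `values` (taxa x days
#'   matrix of log relative abundances), `days` (integer vector),
#'   `pseudocount`.
#' @export
to_log_relative <- function(x, metadata = NULL, pseudocount = 0.5) {
  if (is.null(metadata)) {
    days <- seq_len(ncol(x$values))
  } else {
    md <- metadata[match(sample_ids(x), metadata$sample_id), ]
    if (any(is.na(md$day))) stop("fecal samples must have a day")
    days <- md$day
  }
  if (anyDuplicated(days)) stop("duplicate collection days")
  ord <- order(days)
  v <- x$values[, ord, drop = FALSE]
  days <- as.integer(days[ord])
  s <- nrow(v)
  libs <- colSums(v)
  logrel <- log(sweep(v + pseudocount, 2, libs + s * pseudocount, "/"))
  structure(list(values = logrel, days = days, pseudocount = pseudocount),
            class = "log_abundance_series")
}

# indices t of usable one-day transitions (day[t+1] == day[t] + 1)
.transition_index <- function(days) {
  which(diff(days) == 1L)
}

#' Fit one pairwise interaction model
#'
#' Discrete-time model of the effect of taxon j on taxon i:
#' `x_{i,t+1} - x_{i,t} = alpha + beta * x_{j,t}`, fitted by OLS over all
#' one-day transitions (transitions spanning a sampling gap are dropped).
#' beta is interpreted as the biotic interaction: positive = cooperative or
#' commensal effect of j on i, negative = competitive or amensal.
#'
#' @param series A `log_abundance_series` (see [to_log_relative()]).
#' @param i,j Taxon indices or ids: response i, predictor j.
#' @return List with `alpha`, `beta`, `p_value` (two-sided t-test on beta),
#'   `n_transitions`, `degenerate` (TRUE when the predictor has zero
#'   variance; then beta 0, p 1).
#' @export
fit_pair <- function(series, i, j) {
  v <- series$values
  if (is.character(i)) i <- match(i, rownames(v))
  if (is.character(j)) j <- match(j, rownames(v))
  tt <- .transition_index(series$days)
  if (length(tt) < 10) stop("fewer than 10 usable one-day transitions")
  dy <- v[i, tt + 1] - v[i, tt]
  xj <- v[j, tt]
  if (stats::var(xj) == 0)
    return(list(alpha = mean(dy), beta = 0, p_value = 1,
                n_transitions = length(tt), degenerate = TRUE))
  fit <- stats::lm(dy ~ xj)
  co <- suppressWarnings(summary(fit)$coefficients)
  beta <- unname(co["xj", "Estimate"])
  p <- unname(co["xj", "Pr(>|t|)"])
  if (is.na(p)) p <- if (abs(beta) < 1e-12) 1 else 0  # exact fit
  list(alpha = unname(co["(Intercept)", "Estimate"]),
       beta = beta, p_value = p,
       n_transitions = length(tt), degenerate = FALSE)
}

# Vectorized OLS of every response row of D on every predictor row of P.
# Returns list of n x n matrices (rows = response i, cols = predictor j).
.fit_all_pairs <- function(D, P) {
  m <- ncol(D)
  Dc <- D - rowMeans(D)
  Pc <- P - rowMeans(P)
  sxx <- rowSums(Pc^2)                      # per predictor j
  syy <- rowSums(Dc^2)                      # per response i
  cross <- tcrossprod(Dc, Pc)               # [i, j] = sum_t Dc_i Pc_j
  degen <- sxx == 0
  sxx_safe <- ifelse(degen, 1, sxx)
  beta <- sweep(cross, 2, sxx_safe, "/")
  beta[, degen] <- 0
  alpha <- outer(unname(rowMeans(D)), rep(1, nrow(P))) -
    sweep(beta, 2, rowMeans(P), "*")
  sse <- pmax(outer(syy, rep(1, nrow(P))) -
                sweep(beta^2, 2, sxx_safe, "*"), 0)
  sigma2 <- sse / (m - 2)
  se <- sqrt(sweep(sigma2, 2, sxx_safe, "/"))
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = m - 2)
  p[, degen] <- 1
  p[se == 0] <- ifelse(beta[se == 0] == 0, 1, 0)
  nm <- list(rownames(D), rownames(P))
  dimnames(alpha) <- dimnames(beta) <- dimnames(p) <- nm
  list(alpha = alpha, beta = beta, p = p)
}

#' Build the full pairwise interaction matrix
#'
#' Fits all `n^2` ordered-pair models (response i, predictor j) over the
#' one-day transitions and applies Benjamini-Hochberg adjustment over the
#' `n^2 - n` off-diagonal p-values. The matrix is generally nonsymmetric:
#' the effect of j on i is estimated separately from the effect of i on j.
#' Diagonal (within-OTU) models are computed to mirror the full system but
#' flagged excluded — the predictor is part of the response — and never
#' enter the BH adjustment or any downstream summary.
#'
#' @param series A `log_abundance_series`.
#' @return Object of class `interaction_matrix`: list with `alpha`, `beta`,
#'   `p_raw`, `p_bh` (n x n matrices; `p_bh` diagonal is NA), `taxa_ids`,
#'   `n_transitions`.
#' @export
build_interaction_matrix <- function(series) {
  v <- series$values
  n <- nrow(v)
  if (n < 2) stop("need at least two taxa")
  tt <- .transition_index(series$days)
  if (length(tt) < 10) stop("fewer than 10 usable one-day transitions")
  D <- v[, tt + 1, drop = FALSE] - v[, tt, drop = FALSE]
  P <- v[, tt, drop = FALSE]
  fit <- .fit_all_pairs(D, P)
  off <- !diag(n)
  p_bh <- matrix(NA_real_, n, n, dimnames = dimnames(fit$p))
  p_bh[off] <- stats::p.adjust(fit$p[off], method = "BH")
  structure(list(alpha = fit$alpha, beta = fit$beta, p_raw = fit$p,
                 p_bh = p_bh, taxa_ids = rownames(v),
                 n_transitions = length(tt)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  n <- length(x$taxa_ids)
  cat("interaction_matrix:", n, "taxa,", n^2 - n, "off-diagonal models,",
      x$n_transitions, "transitions\n")
  invisible(x)
}

#' Ecological category of one taxon pair
#'
#' From the two directed coefficients and their significance flags:
#' both significant positive = cooperation (+/+); both significant negative
#' = competition (-/-); one significant positive, other nonsignificant =
#' commensalism (+/0); one significant negative, other nonsignificant =
#' amensalism (-/0); both significant with opposite signs = parasitism
#' (+/-); neither significant = none.
#'
#' @param beta_ij,beta_ji Directed coefficients.
#' @param sig_ij,sig_ji Logical significance flags (BH-adjusted p < alpha).
#' @return Category string.
#' @export
classify_pair <- function(beta_ij, sig_ij, beta_ji, sig_ji) {
  if (sig_ij && sig_ji) {
    if (beta_ij > 0 && beta_ji > 0) return("cooperation")
    if (beta_ij < 0 && beta_ji < 0) return("competition")
    return("parasitism")
  }
  if (xor(sig_ij, sig_ji)) {
    b <- if (sig_ij) beta_ij else beta_ji
    return(if (b > 0) "commensalism" else "amensalism")
  }
  "none"
}

#' Classify all unordered pairs of an interaction matrix
#'
#' @param im An `interaction_matrix`.
#' @param alpha BH-adjusted significance threshold (default 0.01, i.e.
#'   significance at a 99% confidence level).
#' @return data.frame with one row per unordered pair: `taxon_a`, `taxon_b`,
#'   `beta_ab` (effect of b on a), `beta_ba`, `sig_ab`, `sig_ba`,
#'   `category`.
#' @export
classify_interactions <- function(im, alpha = 0.01) {
  n <- length(im$taxa_ids)
  pairs <- utils::combn(n, 2)
  out <- data.frame(
    taxon_a = im$taxa_ids[pairs[1, ]],
    taxon_b = im$taxa_ids[pairs[2, ]],
    beta_ab = im$beta[cbind(pairs[1, ], pairs[2, ])],
    beta_ba = im$beta[cbind(pairs[2, ], pairs[1, ])],
    sig_ab = im$p_bh[cbind(pairs[1, ], pairs[2, ])] < alpha,
    sig_ba = im$p_bh[cbind(pairs[2, ], pairs[1, ])] < alpha,
    stringsAsFactors = FALSE
  )
  out$category <- mapply(classify_pair, out$beta_ab, out$sig_ab,
                         out$beta_ba, out$sig_ba)
  out
}

#' Permutation robustness test of the interaction models
#'
#' Refits the full set of pairwise models `n_perm` times after independently
#' permuting the time order of each predictor series, destroying any
#' temporal association while preserving each series' marginal distribution.
#' On data with no real temporal signal the raw p-values should be
#' distributed around 0.5 and, after BH adjustment at `alpha`, permuted
#' replicates should typically yield no significant models at all.
#'
#' @param series A `log_abundance_series`.
#' @param n_perm Number of permutation replicates (default 100).
#' @param seed Optional integer seed.
#' @param alpha BH significance threshold for counting significant permuted
#'   models (default 0.01).
#' @return List: `mean_p_raw` and `mean_p_bh` (n x n matrices of p-values
#'   averaged over replicates, diagonal NA), `n_sig_per_rep` (significant
#'   off-diagonal models per replicate after BH), `pooled_mean_p_raw`
#'   (grand mean of all off-diagonal raw p-values), `n_pooled` (number of
#'   pooled p-values), `n_perm`.
#' @export
permutation_null <- function(series, n_perm = 100, seed = NULL,
                             alpha = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  v <- series$values
  n <- nrow(v)
  tt <- .transition_index(series$days)
  D <- v[, tt + 1, drop = FALSE] - v[, tt, drop = FALSE]
  P <- v[, tt, drop = FALSE]
  off <- !diag(n)
  sum_raw <- matrix(0, n, n)
  sum_bh <- matrix(0, n, n)
  n_sig <- integer(n_perm)
  pooled_sum <- 0
  for (r in seq_len(n_perm)) {
    Pp <- t(apply(P, 1, sample))
    fit <- .fit_all_pairs(D, Pp)
    bh <- matrix(NA_real_, n, n)
    bh[off] <- stats::p.adjust(fit$p[off], method = "BH")
    sum_raw <- sum_raw + fit$p
    sum_bh[off] <- sum_bh[off] + bh[off]
    n_sig[r] <- sum(bh[off] < alpha)
    pooled_sum <- pooled_sum + sum(fit$p[off])
  }
  mean_raw <- sum_raw / n_perm
  mean_bh <- sum_bh / n_perm
  diag(mean_raw) <- NA
  diag(mean_bh) <- NA
  dimnames(mean_raw) <- dimnames(mean_bh) <- list(rownames(v), rownames(v))
  n_pooled <- n_perm * sum(off)
  list(mean_p_raw = mean_raw, mean_p_bh = mean_bh, n_sig_per_rep = n_sig,
       pooled_mean_p_raw = pooled_sum / n_pooled, n_pooled = n_pooled,
       n_perm = n_perm)
}

#' Within- versus between-rank interaction strength
#'
#' Compares significant interaction coefficients between taxon pairs that
#' share a label at the given taxonomic rank against pairs that do not,
#' asking whether competition is more intense among close relatives. Pairs
#' unassigned at the rank are excluded.
#'
#' @param im An `interaction_matrix`.
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy()]).
#' @param rank Rank to partition by (default `"phylum"`).
#' @param alpha BH significance threshold for including a coefficient
#'   (default 0.01).
#' @return List: `mean_within`, `mean_between`, `p_value` (one-sided
#'   Wilcoxon rank-sum, alternative: within-rank coefficients are more
#'   negative), `n_within`, `n_between`.
#' @export
taxonomic_contrast <- function(im, taxonomy, rank = "phylum", alpha = 0.01) {
  rank <- match.arg(rank, .tax_ranks)
  lab <- taxonomy[[rank]][match(im$taxa_ids, taxonomy$otu_id)]
  lab[lab == ""] <- NA
  n <- length(im$taxa_ids)
  sig <- !is.na(im$p_bh) & im$p_bh < alpha
  same <- outer(lab, lab, "==")          # NA when either label is NA
  use <- sig & !is.na(same)
  within <- im$beta[use & same]
  between <- im$beta[use & !same]
  if (!length(within) || !length(between))
    stop("empty partition: ", length(within), " within-rank, ",
         length(between), " between-rank significant coefficients")
  wt <- stats::wilcox.test(within, between, alternative = "less",
                           exact = FALSE)
  list(mean_within = mean(within), mean_between = mean(between),
       p_value = wt$p.value, n_within = length(within),
       n_between = length(between))
}
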