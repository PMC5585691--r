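# Independent oracles used to freeze expected values. These deliberately use
# naive formulations (normal equations, exhaustive enumeration) distinct from
# the implementation paths they check.

# OLS slope/intercept/p via explicit normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - 2
  s2 <- sum(res^2) / df
  covb <- s2 * solve(t(X) %*% X)
  tstat <- b[2] / sqrt(covb[2, 2])
  list(alpha = b[1], beta = b[2], p_value = 2 * pt(-abs(tstat), df))
}

# Benjamini-Hochberg step-up written out longhand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# ANOSIM R from the definition, looping over pairs
anosim_r_oracle <- function(dmat, groups) {
  n <- nrow(dmat)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(dmat[lower.tri(dmat)])
  rw <- c(); rb <- c()
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (groups[i] == groups[j]) rw <- c(rw, rk[i, j]) else rb <- c(rb, rk[i, j])
  }
  (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
}

# Exhaustive two-group ANOSIM permutation p (all label assignments)
anosim_exact_oracle <- function(dmat, groups) {
  n <- nrow(dmat)
  lv <- unique(groups)
  stopifnot(length(lv) == 2)
  obs <- anosim_r_oracle(dmat, groups)
  combos <- combn(n, sum(groups == lv[1]))
  rs <- apply(combos, 2, function(idx) {
    g <- rep(lv[2], n); g[idx] <- lv[1]
    anosim_r_oracle(dmat, g)
  })
  list(statistic = obs, p_value = mean(rs >= obs - 1e-12))
}

# Exact two-sided rank-sum p by enumerating all splits (no ties assumed)
wilcox_exact_oracle <- function(x, y) {
  all <- c(x, y)
  rk <- rank(all)
  w_obs <- sum(rk[seq_along(x)])
  combos <- combn(length(all), length(x))
  ws <- apply(combos, 2, function(idx) sum(rk[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# biopsy metadata for 7 sites x n replicates, matching a column layout
biopsy_metadata <- function(sample_ids, n_rep = 3) {
  data.frame(sample_id = sample_ids, sample_type = "biopsy", day = NA,
             site = rep(gi_sites, each = n_rep),
             replicate = rep(seq_len(n_rep), times = 7),
             distance_cm = NA, stringsAsFactors = FALSE)
}

# counts with every library equalized to `lib` via a filler row
equalized_biopsy_counts <- function(n_otus, lib = 600, lambda = 15,
                                    n_rep = 3) {
  counts <- matrix(rpois(n_otus * 7 * n_rep, lambda), n_otus)
  counts <- rbind(counts, lib - colSums(counts))
  stopifnot(all(counts >= 0))
  dimnames(counts) <- list(paste0("OTU", seq_len(n_otus + 1)),
                           paste0("s", seq_len(7 * n_rep)))
  count_table(counts)
}
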