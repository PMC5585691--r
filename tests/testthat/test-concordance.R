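# build a small interaction_matrix by hand
mock_im <- function(beta, p_bh) {
  n <- nrow(beta)
  ids <- paste0("OTU", seq_len(n))
  dimnames(beta) <- dimnames(p_bh) <- list(ids, ids)
  diag(p_bh) <- NA
  structure(list(beta = beta, p_bh = p_bh, taxa_ids = ids),
            class = "interaction_matrix")
}

mock_cm <- function(vals, flavor = "spatial", method = "spearman") {
  ids <- paste0("OTU", seq_len(nrow(vals)))
  dimnames(vals) <- list(ids, ids)
  correlation_matrix(vals, method, flavor)
}

test_that("coefficient-correlation association detects monotone coupling", {
  set.seed(81)
  n <- 8
  beta <- matrix(rnorm(n * n), n, n)
  corr <- -(beta + t(beta)) / 2           # strictly decreasing in beta_sym
  corr <- corr / max(abs(corr))
  diag(corr) <- 1
  im <- mock_im(beta, matrix(0.5, n, n))
  cm <- mock_cm(corr)
  res <- coefficient_vs_correlation(im, cm, "spearman",
                                    pairing = "unordered")
  expect_equal(res$estimate, -1)
  expect_equal(res$n, choose(n, 2))
  # ordered pairing statistic matches direct computation on flattened vectors
  res2 <- coefficient_vs_correlation(im, cm, "pearson")
  off <- !diag(n)
  expect_equal(res2$estimate, cor(beta[off], corr[off]), tolerance = 1e-12)
  expect_equal(res2$n, n * n - n)
})

test_that("coefficient-correlation p-values are calibrated under independence", {
  set.seed(82)
  ps <- replicate(30, {
    n <- 7
    beta <- matrix(rnorm(n * n), n, n)
    r <- matrix(rnorm(n * n), n, n); r <- (r + t(r)) / 4; diag(r) <- 1
    coefficient_vs_correlation(mock_im(beta, matrix(0.5, n, n)),
                               mock_cm(r), "pearson")$p_value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("mismatched taxon sets are rejected", {
  im <- mock_im(matrix(0, 4, 4), matrix(0.5, 4, 4))
  cm <- mock_cm(diag(5))
  expect_error(coefficient_vs_correlation(im, cm), "different taxa")
})

test_that("partitioning splits distributions as constructed", {
  set.seed(83)
  n <- 20
  p_bh <- matrix(1, n, n)
  sig_pairs <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10))
  p_bh[sig_pairs] <- 0.001              # one direction significant: "either"
  beta <- matrix(0, n, n)
  corr <- matrix(0, n, n)
  corr[lower.tri(corr)] <- rnorm(choose(n, 2), 0, 0.03)
  corr <- corr + t(corr)
  for (k in seq_len(nrow(sig_pairs)))
    corr[sig_pairs[k, 1], sig_pairs[k, 2]] <-
      corr[sig_pairs[k, 2], sig_pairs[k, 1]] <- 0.2 + rnorm(1, 0, 0.02)
  diag(corr) <- 1
  res <- partition_by_significance(mock_cm(corr), mock_im(beta, p_bh))
  expect_equal(res$n_sig, 5)
  expect_equal(res$mean_sig, mean(res$values_sig))       # means are means
  expect_equal(res$mean_nonsig, mean(res$values_nonsig))
  expect_gt(res$mean_sig, res$mean_nonsig)
  expect_lt(res$p_value, 0.01)
  # "both" rule: no pair has both directions significant here
  expect_error(partition_by_significance(mock_cm(corr),
                                         mock_im(beta, p_bh), rule = "both"),
               "empty partition")
})

test_that("partitioning is null when significance is uninformative", {
  set.seed(84)
  ps <- replicate(30, {
    n <- 14
    p_bh <- matrix(1, n, n)
    p_bh[cbind(1:4, 5:8)] <- 0.001
    r <- matrix(0, n, n)
    r[lower.tri(r)] <- rnorm(choose(n, 2), 0, 0.2)
    r <- r + t(r); diag(r) <- 1
    partition_by_significance(mock_cm(r),
                              mock_im(matrix(0, n, n), p_bh))$p_value
  })
  expect_gt(mean(ps), 0.3)
})

test_that("the concordance report aggregates the individual comparisons", {
  set.seed(85)
  cs <- simulate_coupled_study(n_taxa = 14, n_days = 120, seed = 6)
  ser <- to_log_relative(cs$fecal$counts, cs$fecal$metadata)
  im <- build_interaction_matrix(ser)
  t_sp <- spearman_matrix(cs$fecal$counts, "temporal")
  prof <- spatial_profile_table(cs$biopsy$counts, cs$biopsy$metadata)
  s_sp <- spearman_matrix(prof, "spatial")
  rep <- concordance_report(im, temporal_spearman = t_sp,
                            spatial_spearman = s_sp)
  # absent SparCC inputs are marked absent
  expect_null(rep$partitioned$temporal_sparcc)
  expect_null(rep$temporal_vs_spatial$sparcc)
  # present sections equal the individual operations' outputs
  direct <- partition_by_significance(s_sp, im)
  expect_equal(rep$partitioned$spatial_spearman$mean_sig, direct$mean_sig)
  expect_equal(rep$partitioned$spatial_spearman$p_value, direct$p_value)
  direct2 <- coefficient_vs_correlation(im, t_sp, "spearman")
  expect_equal(rep$beta_vs_temporal$temporal_spearman$spearman_rho$estimate,
               direct2$estimate)
  lt <- lower.tri(t_sp$values)
  expect_equal(rep$temporal_vs_spatial$spearman$estimate,
               cor(t_sp$values[lt], s_sp$values[lt]))
})

test_that("concordance statistics are invariant to taxon relabeling", {
  set.seed(86)
  n <- 10
  beta <- matrix(rnorm(n * n), n, n)
  p_bh <- matrix(runif(n * n, 0, 0.2), n, n)
  r <- matrix(0, n, n); r[lower.tri(r)] <- rnorm(choose(n, 2), 0, 0.3)
  r <- r + t(r); diag(r) <- 1
  perm <- sample(n)
  a <- partition_by_significance(mock_cm(r), mock_im(beta, p_bh),
                                 alpha = 0.05)
  b <- partition_by_significance(mock_cm(r[perm, perm]),
                                 mock_im(beta[perm, perm],
                                         p_bh[perm, perm]), alpha = 0.05)
  expect_equal(sort(b$values_sig), sort(a$values_sig))
  expect_equal(b$p_value, a$p_value)
})
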