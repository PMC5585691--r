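# small helper: wrap a matrix of log abundances as a series
as_series <- function(m, days = seq_len(ncol(m)), pc = 0.5) {
  rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  structure(list(values = m, days = as.integer(days), pseudocount = pc),
            class = "log_abundance_series")
}

test_that("log-relative transform maps counts as specified", {
  ct <- count_table(matrix(c(10, 990), 2, 1), sample_ids = "d1")
  md <- data.frame(sample_id = "d1", sample_type = "fecal", day = 1,
                   site = NA, replicate = NA, distance_cm = NA)
  ser <- to_log_relative(ct, md, pseudocount = 1e-9)
  expect_equal(ser$values[1, 1], log(0.01), tolerance = 1e-6)

  # zero counts stay finite under the default pseudocount
  ct2 <- count_table(matrix(c(0, 100, 400), 3, 1))
  ser2 <- to_log_relative(ct2, pseudocount = 0.5)
  expect_true(all(is.finite(ser2$values)))
  # ordering of counts within a sample is preserved
  expect_true(all(diff(ser2$values[, 1]) > 0))

  md_dup <- data.frame(sample_id = c("a", "b"), sample_type = "fecal",
                       day = c(3, 3), site = NA, replicate = NA,
                       distance_cm = NA)
  ct3 <- count_table(matrix(1:4, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(to_log_relative(ct3, md_dup), "duplicate")
})

test_that("pairwise fit recovers a noise-free linear law exactly", {
  set.seed(61)
  T_ <- 40
  xj <- rnorm(T_)
  xi <- numeric(T_)
  for (t in 1:(T_ - 1)) xi[t + 1] <- xi[t] + 0.5 - 0.2 * xj[t]
  ser <- as_series(rbind(xi, xj))
  fit <- fit_pair(ser, 1, 2)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-9)
  expect_equal(fit$beta, -0.2, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-10)

  const <- as_series(rbind(rnorm(T_), rep(1, T_)))
  dfit <- fit_pair(const, 1, 2)
  expect_true(dfit$degenerate)
  expect_equal(dfit$beta, 0)
  expect_equal(dfit$p_value, 1)
})

test_that("pairwise fits match the normal-equations oracle", {
  set.seed(62)
  m <- matrix(rnorm(3 * 30), 3, 30)
  ser <- as_series(m)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    fit <- fit_pair(ser, i, j)
    dy <- m[i, -1] - m[i, -30]
    orc <- ols_oracle(m[j, -30], dy)
    expect_lt(abs(fit$beta - orc$beta), 1e-8)
    expect_lt(abs(fit$p_value - orc$p_value), 1e-8)
  }
})

test_that("the vectorized matrix build agrees with per-pair fits", {
  set.seed(63)
  ser <- as_series(matrix(rnorm(5 * 25), 5, 25))
  im <- build_interaction_matrix(ser)
  for (i in c(1, 3)) for (j in c(2, 5)) {
    fit <- fit_pair(ser, i, j)
    expect_equal(im$beta[i, j], fit$beta, tolerance = 1e-10)
    expect_equal(im$alpha[i, j], fit$alpha, tolerance = 1e-10)
    expect_equal(im$p_raw[i, j], fit$p_value, tolerance = 1e-10)
  }
  expect_equal(sum(!is.na(im$p_bh)), 5^2 - 5)
})

test_that("transitions across sampling gaps are dropped", {
  set.seed(64)
  m <- matrix(rnorm(2 * 30), 2, 30)
  days <- c(1:20, 22:31)          # gap between day 20 and 22
  ser <- as_series(m, days = days)
  fit <- fit_pair(ser, 1, 2)
  expect_equal(fit$n_transitions, 28)
})

test_that("BH adjustment inside the matrix matches a longhand step-up", {
  set.seed(65)
  ser <- as_series(matrix(rnorm(6 * 40), 6, 40))
  im <- build_interaction_matrix(ser)
  off <- !diag(6)
  expect_equal(im$p_bh[off], bh_oracle(im$p_raw[off]), tolerance = 1e-12)
  # hand case for the longhand implementation itself
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("pair categories follow the sign/significance scheme", {
  expect_equal(classify_pair(-0.3, TRUE, -0.1, TRUE), "competition")
  expect_equal(classify_pair(0.2, TRUE, 0.1, TRUE), "cooperation")
  expect_equal(classify_pair(0.2, TRUE, 0.0, FALSE), "commensalism")
  expect_equal(classify_pair(-0.2, TRUE, 0.3, FALSE), "amensalism")
  expect_equal(classify_pair(0.2, TRUE, -0.2, TRUE), "parasitism")
  expect_equal(classify_pair(0.2, FALSE, -0.2, FALSE), "none")
})

test_that("matrix-level classification is consistent with classify_pair", {
  set.seed(66)
  cs <- simulate_coupled_study(n_taxa = 12, n_days = 120, seed = 5)
  ser <- to_log_relative(cs$fecal$counts, cs$fecal$metadata)
  im <- build_interaction_matrix(ser)
  cls <- classify_interactions(im, alpha = 0.01)
  expect_equal(nrow(cls), choose(12, 2))
  k <- which(cls$category == "competition")[1]
  if (!is.na(k)) {
    expect_true(cls$sig_ab[k] && cls$sig_ba[k])
    expect_true(cls$beta_ab[k] < 0 && cls$beta_ba[k] < 0)
  }
})

test_that("predictor permutation gives uniform p and no significant models", {
  sim <- simulate_time_series(n_taxa = 10, n_days = 80, seed = 67)
  ser <- to_log_relative(sim$counts, sim$metadata)
  res <- permutation_null(ser, n_perm = 10, seed = 68)
  expect_lt(abs(res$pooled_mean_p_raw - 0.5), 0.05)
  expect_gte(mean(res$n_sig_per_rep == 0), 0.9)
  # fixed seed reproduces identical output
  res2 <- permutation_null(ser, n_perm = 10, seed = 68)
  expect_identical(res, res2)
})

test_that("the interaction matrix is equivariant to taxon relabeling", {
  set.seed(69)
  m <- matrix(rnorm(4 * 30), 4, 30)
  perm <- c(3, 1, 4, 2)
  im1 <- build_interaction_matrix(as_series(m))
  im2 <- build_interaction_matrix(as_series(m[perm, ]))
  expect_equal(unname(im2$beta), unname(im1$beta[perm, perm]),
               tolerance = 1e-12)
  expect_equal(unname(im2$p_raw), unname(im1$p_raw[perm, perm]),
               tolerance = 1e-12)
})

test_that("within-phylum competition contrast matches construction", {
  # 6 taxa: phylum A = 1:3, phylum B = 4:6; significant betas set by hand
  n <- 6
  beta <- matrix(0, n, n)
  p_bh <- matrix(1, n, n)
  within <- rbind(c(1, 2), c(2, 1), c(1, 3), c(4, 5))
  between <- rbind(c(1, 4), c(4, 1), c(2, 5), c(3, 6), c(6, 3))
  beta[within] <- -0.2
  beta[between] <- 0.1
  p_bh[rbind(within, between)] <- 0.001
  diag(p_bh) <- NA
  im <- structure(list(beta = beta, p_bh = p_bh,
                       taxa_ids = paste0("OTU", 1:n)),
                  class = "interaction_matrix")
  tax <- data.frame(otu_id = paste0("OTU", 1:n), kingdom = "Bacteria",
                    phylum = rep(c("A", "B"), each = 3), class = "c",
                    order = "o", family = "f", genus = "g")
  res <- taxonomic_contrast(im, tax, "phylum", alpha = 0.01)
  expect_equal(res$mean_within, -0.2)
  expect_equal(res$mean_between, 0.1)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n_within, 4)
  expect_equal(res$n_between, 5)
  # all pairs share the same genus label -> between partition is empty
  expect_error(taxonomic_contrast(im, tax, "genus", alpha = 0.01),
               "empty partition")
})

test_that("the rank-sum test agrees with exhaustive enumeration", {
  set.seed(70)
  for (i in 1:3) {
    x <- rnorm(4); y <- rnorm(5) + 0.5
    expect_equal(wilcox.test(x, y, exact = TRUE)$p.value,
                 wilcox_exact_oracle(x, y), tolerance = 1e-12)
  }
})
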