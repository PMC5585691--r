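sites21 <- rep(gi_sites, each = 3)

test_that("monotonic trend fits match the normal-equations oracle", {
  set.seed(51)
  pos <- site_positions(sites21, "ordinal")
  for (i in 1:5) {
    y <- 0.01 * pos + rnorm(21, sd = 0.02)
    fit <- fit_monotonic_trend(y, pos)
    orc <- ols_oracle(pos, y)
    expect_equal(fit$slope, orc$beta, tolerance = 1e-10)
    expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
  }
})

test_that("perfect and degenerate profiles are handled", {
  pos <- site_positions(sites21, "ordinal")
  exact <- fit_monotonic_trend(0.02 * pos, pos)
  expect_gt(exact$slope, 0)
  expect_lt(exact$p_value, 1e-10)
  flat <- fit_monotonic_trend(rep(0.3, 21), pos)
  expect_true(flat$degenerate)
  expect_equal(flat$p_value, 1)
  expect_equal(classify_gradient(flat), "none")
})

test_that("gradient direction is invariant to the positional convention", {
  set.seed(52)
  rising <- 0.005 * site_positions(sites21, "ordinal") + rnorm(21, sd = 0.003)
  for (conv in c("ordinal", "distance_cm")) {
    tr <- fit_monotonic_trend(rising, site_positions(sites21, conv))
    expect_equal(classify_gradient(tr, alpha = 0.05), "MGA")
  }
  for (conv in c("ordinal", "distance_cm")) {
    tr <- fit_monotonic_trend(rev(rising), site_positions(sites21, conv))
    expect_equal(classify_gradient(tr, alpha = 0.05), "MGD")
  }
  # distance convention: rising toward rectum has negative slope vs raw cm,
  # but site_positions() negates, so the fitted slope is positive
  tr <- fit_monotonic_trend(rising, site_positions(sites21, "distance_cm"))
  expect_gt(tr$slope, 0)
})

test_that("breakpoint model recovers hinge shapes and their p-values", {
  set.seed(53)
  pos <- site_positions(sites21, "ordinal")
  bp <- match("AC", gi_sites)
  v <- abs(pos - bp) * 0.01 + 0.02 + rnorm(21, sd = 0.002)  # V at AC
  fit <- fit_breakpoint_model(v, sites21, "AC")
  expect_lt(fit$p_break, 1e-4)
  expect_lt(fit$slope_left, 0)
  expect_gt(fit$slope_right, 0)
  expect_equal(classify_breakpoint(fit), "GAB")

  lin <- fit_breakpoint_model(0.01 * pos, sites21, "TC")  # strictly linear
  expect_equal(lin$slope_left, lin$slope_right, tolerance = 1e-10)
  expect_equal(lin$p_break, 1)

  flat <- fit_breakpoint_model(rep(0.1, 21), sites21, "AC")
  expect_true(flat$degenerate)
})

test_that("hinge coefficient equals the difference of segment slopes", {
  # noise-free continuous piecewise-linear data
  pos <- site_positions(sites21, "ordinal")
  bp <- match("TC", gi_sites)
  y <- ifelse(pos <= bp, 0.05 - 0.01 * pos, 0.05 - 0.01 * bp +
                0.025 * (pos - bp))
  fit <- fit_breakpoint_model(y, sites21, "TC")
  left <- ols_oracle(pos[pos <= bp], y[pos <= bp])$beta
  right <- ols_oracle(pos[pos >= bp], y[pos >= bp])$beta
  expect_equal(fit$slope_right - fit$slope_left, right - left,
               tolerance = 1e-10)
  expect_equal(fit$slope_left, left, tolerance = 1e-10)
})

test_that("breakpoint classification needs both significance and sign change", {
  mk <- function(sl, sr, p) list(slope_left = sl, slope_right = sr,
                                 p_break = p, degenerate = FALSE)
  expect_equal(classify_breakpoint(mk(-1, 1, 0.01)), "GAB")
  expect_equal(classify_breakpoint(mk(1, -1, 0.01)), "GDB")
  expect_equal(classify_breakpoint(mk(1, 2, 0.01)), "none")   # no sign change
  expect_equal(classify_breakpoint(mk(-1, 1, 0.2)), "none")   # not significant
})

test_that("NB exact test converges to the conditional binomial at low dispersion", {
  set.seed(54)
  ct <- equalized_biopsy_counts(10, lib = 600, lambda = 15)
  md <- biopsy_metadata(sample_ids(ct))
  res <- nb_exact_test(ct, md, "TI", dispersion = 1e-10)
  v <- counts_matrix(ct)
  s1 <- rowSums(v[, md$site == "TI"])
  S <- rowSums(v)
  p0 <- 3 / 21
  oracle <- vapply(seq_len(nrow(v)), function(i)
    min(1, 2 * min(pbinom(s1[i], S[i], p0),
                   1 - pbinom(s1[i] - 1, S[i], p0))), numeric(1))
  expect_lt(max(abs(res$p_value - oracle)), 1e-3)
})

test_that("NB exact test is null on identical group means", {
  set.seed(55)
  m <- matrix(rpois(6 * 21, 500), 6, 21)
  ct <- count_table(m)
  md <- biopsy_metadata(sample_ids(ct))
  res <- nb_exact_test(ct, md, "AC")
  expect_gt(min(res$p_value), 0.01)
  expect_gt(mean(res$p_value), 0.3)
})

test_that("an 8-fold TI enrichment is recovered by the exact test", {
  set.seed(56)
  hits <- replicate(100, {
    mu <- matrix(100, 8, 21)
    mu[1, sites21 == "TI"] <- 800           # 8-fold enrichment at TI
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.2), 8, 21)
    ct <- count_table(m, sample_ids = paste0("s", 1:21))
    res <- nb_exact_test(ct, biopsy_metadata(sample_ids(ct)), "TI")
    res$p_value[1] < 0.01 && res$fdr[1] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("specialist classification applies both thresholds jointly", {
  tst <- data.frame(otu_id = c("a", "b", "c", "d"),
                    log_fc = c(2, 1, -2, 1),
                    p_value = c(0.001, 0.005, 0.002, 0.5),
                    fdr = c(0.01, 0.2, 0.01, 0.9),
                    direction = c(1, 1, -1, 1))
  expect_equal(classify_specialist(tst), c("HS", "none", "HA", "none"))
})

test_that("every spatial classifier attains full recall as noise vanishes", {
  labels <- spatial_labels(c(flat = 4, MGA = 2, MGD = 2, GAB = 2, GDB = 2,
                             HS = 2, HA = 2))
  sp <- simulate_spatial(labels, fold = 8, dispersion = 0,
                         lib_meanlog = 12, lib_sdlog = 0.01, seed = 57)
  cls <- classify_spatial(sp$counts, sp$metadata,
                          specialist_sites = c("TI", "AC", "R"))
  truth <- labels[labels$category != "flat", ]
  for (k in seq_len(nrow(truth))) {
    got <- cls$category[cls$otu_id == truth$otu_id[k]]
    expect_true(truth$category[k] %in% got,
                label = paste(truth$otu_id[k], truth$category[k], "->",
                              paste(got, collapse = "/")))
  }
})

test_that("an OTU can hold categories from different tests simultaneously", {
  # steep descending gradient is also enriched proximally: MGD and HS at TI;
  # a broad flat background keeps the common-dispersion estimate realistic
  labels <- data.frame(otu_id = paste0("OTU", 1:31),
                       category = c("MGD", rep("flat", 30)),
                       site = NA, stringsAsFactors = FALSE)
  sp <- simulate_spatial(labels, fold = 30, dispersion = 0,
                         lib_meanlog = 12, lib_sdlog = 0.01, seed = 58)
  cls <- classify_spatial(sp$counts, sp$metadata, specialist_sites = "TI")
  cats <- cls$category[cls$otu_id == "OTU1"]
  expect_true("MGD" %in% cats)
  expect_true("HS" %in% cats)
})
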