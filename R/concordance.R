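#' Time-series coefficients versus co-occurrence correlations
#'
#' Association between the directed interaction coefficients and the
#' symmetric co-occurrence coefficients over the same taxa: every ordered
#' off-diagonal pair (i, j) contributes (beta_ij, corr_ij), so each
#' unordered pair appears once per direction (`pairing = "ordered"`,
#' default). `pairing = "unordered"` instead pairs each correlation with
#' the mean of the two directed coefficients.
#'
#' @param im An `interaction_matrix`.
#' @param cm A `correlation_matrix` over the same taxa.
#' @param method `"spearman"` (rho) or `"pearson"` (r).
#' @param pairing `"ordered"` or `"unordered"`.
#' @return List: `estimate`, `p_value`, `n` (number of paired values).
#' @export
coefficient_vs_correlation <- function(im, cm,
                                       method = c("spearman", "pearson"),
                                       pairing = c("ordered", "unordered")) {
  method <- match.arg(method)
  pairing <- match.arg(pairing)
  .check_same_taxa(im$taxa_ids, cm$taxa_ids)
  n <- length(im$taxa_ids)
  if (pairing == "ordered") {
    off <- !diag(n)
    b <- im$beta[off]
    r <- cm$values[off]
  } else {
    pairs <- utils::combn(n, 2)
    i1 <- cbind(pairs[1, ], pairs[2, ])
    i2 <- cbind(pairs[2, ], pairs[1, ])
    b <- (im$beta[i1] + im$beta[i2]) / 2
    r <- cm$values[i1]
  }
  ct <- suppressWarnings(stats::cor.test(b, r, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(b))
}

.check_same_taxa <- function(a, b) {
  if (length(a) != length(b) || !all(a == b))
    stop("interaction and correlation matrices cover different taxa")
}

#' Partition co-occurrence coefficients by time-series significance
#'
#' Splits the unordered-pair co-occurrence coefficients into those whose
#' pair has a significant time-series interaction model and those without,
#' and tests for a location difference. Agreement between the temporal and
#' spatial views shows up as a positive skew of the significant-pair
#' distribution: taxa that interact (mostly competitively) over time tend to
#' co-occur along the GI tract.
#'
#' @param cm A `correlation_matrix`.
#' @param im An `interaction_matrix` over the same taxa.
#' @param alpha BH significance threshold on the directed models (default
#'   0.01).
#' @param rule A pair counts as significant if `"either"` directed model is
#'   significant (default) or only if `"both"` are.
#' @return List: `values_sig`, `values_nonsig` (coefficient vectors),
#'   `mean_sig`, `mean_nonsig`, `p_value` (two-sample Wilcoxon rank-sum),
#'   `p_vs_zero` (one-sample Wilcoxon of the significant partition against
#'   zero), `n_sig`, `n_nonsig`.
#' @export
partition_by_significance <- function(cm, im, alpha = 0.01,
                                      rule = c("either", "both")) {
  rule <- match.arg(rule)
  .check_same_taxa(im$taxa_ids, cm$taxa_ids)
  n <- length(im$taxa_ids)
  pairs <- utils::combn(n, 2)
  i1 <- cbind(pairs[1, ], pairs[2, ])
  i2 <- cbind(pairs[2, ], pairs[1, ])
  s1 <- im$p_bh[i1] < alpha
  s2 <- im$p_bh[i2] < alpha
  sig <- if (rule == "either") s1 | s2 else s1 & s2
  r <- cm$values[i1]
  if (!any(sig) || all(sig))
    stop("empty partition: ", sum(sig), " significant of ", length(sig),
         " pairs")
  vs <- r[sig]; vn <- r[!sig]
  wt <- stats::wilcox.test(vs, vn, exact = FALSE)
  wz <- stats::wilcox.test(vs, mu = 0, exact = FALSE)
  list(values_sig = vs, values_nonsig = vn,
       mean_sig = mean(vs), mean_nonsig = mean(vn),
       p_value = wt$p.value, p_vs_zero = wz$p.value,
       n_sig = length(vs), n_nonsig = length(vn))
}

#' Full concordance report
#'
#' Runs the partitioned-distribution test for each supplied co-occurrence
#' matrix (temporal/spatial x Spearman/SparCC), the coefficient-versus-
#' correlation comparisons against the temporal matrices, and the
#' scatter relationships between temporal and spatial co-occurrence and
#' between interaction coefficients and spatial co-occurrence. Sections
#' whose inputs are missing are marked absent (`NULL`).
#'
#' @param im An `interaction_matrix`.
#' @param temporal_spearman,temporal_sparcc,spatial_spearman,spatial_sparcc
#'   `correlation_matrix` objects (any may be `NULL`).
#' @param alpha BH significance threshold (default 0.01).
#' @return A nested list (JSON-serializable): `partitioned` (one entry per
#'   matrix: means, Wilcoxon p), `beta_vs_temporal` (Spearman rho and
#'   Pearson r of coefficients against each temporal matrix),
#'   `temporal_vs_spatial` and `beta_vs_spatial` (Pearson r), and `alpha`.
#' @export
concordance_report <- function(im, temporal_spearman = NULL,
                               temporal_sparcc = NULL,
                               spatial_spearman = NULL,
                               spatial_sparcc = NULL, alpha = 0.01) {
  mats <- list(temporal_spearman = temporal_spearman,
               temporal_sparcc = temporal_sparcc,
               spatial_spearman = spatial_spearman,
               spatial_sparcc = spatial_sparcc)
  partitioned <- lapply(mats, function(m) {
    if (is.null(m)) return(NULL)
    p <- partition_by_significance(m, im, alpha = alpha)
    p[c("mean_sig", "mean_nonsig", "p_value", "p_vs_zero",
        "n_sig", "n_nonsig")]
  })
  beta_vs_temporal <- lapply(mats[1:2], function(m) {
    if (is.null(m)) return(NULL)
    list(spearman_rho = coefficient_vs_correlation(im, m, "spearman"),
         pearson_r = coefficient_vs_correlation(im, m, "pearson"))
  })
  pearson_tri <- function(a, b) {
    lt <- lower.tri(a$values)
    ct <- stats::cor.test(a$values[lt], b$values[lt])
    list(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = sum(lt))
  }
  temporal_vs_spatial <- list(
    spearman = if (!is.null(temporal_spearman) && !is.null(spatial_spearman))
      pearson_tri(temporal_spearman, spatial_spearman),
    sparcc = if (!is.null(temporal_sparcc) && !is.null(spatial_sparcc))
      pearson_tri(temporal_sparcc, spatial_sparcc))
  beta_vs_spatial <- lapply(mats[3:4], function(m) {
    if (is.null(m)) return(NULL)
    coefficient_vs_correlation(im, m, "pearson")
  })
  list(partitioned = partitioned,
       beta_vs_temporal = beta_vs_temporal,
       temporal_vs_spatial = temporal_vs_spatial,
       beta_vs_spatial = beta_vs_spatial,
       alpha = alpha)
}
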