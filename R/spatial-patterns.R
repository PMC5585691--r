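#' Positions of GI sites under the two positional conventions
#'
#' The GI tract can be treated either as a continuum (position = distance
#' from the anus in cm) or as a series of physiologically distinct segments
#' (position = ordinal 1..7 from terminal ileum to rectum). So that a
#' positive slope always means "abundance increasing toward the rectum"
#' under both conventions, the distance convention returns the negated
#' cm-from-anus values.
#'
#' @param sites Character vector of site codes.
#' @param convention `"ordinal"` or `"distance_cm"`.
#' @return Numeric positions, oriented so larger = closer to the rectum.
#' @export
site_positions <- function(sites, convention = c("ordinal", "distance_cm")) {
  convention <- match.arg(convention)
  bad <- setdiff(sites, gi_sites)
  if (length(bad)) stop("unknown GI site: ", bad[1])
  if (convention == "ordinal") {
    match(sites, gi_sites)
  } else {
    -unname(gi_site_distance_cm[sites])
  }
}

#' Per-OTU site profiles from a biopsy table
#'
#' @param x A [count_table()] of biopsy samples.
#' @param metadata Sample metadata (see [read_sample_metadata()]) covering
#'   the samples of `x`.
#' @return List with `rel` (taxa x samples relative abundances), `site`,
#'   `replicate` (per sample), ordered TI to R then by replicate.
#' @export
site_profiles <- function(x, metadata) {
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (any(is.na(md$sample_id))) stop("metadata missing for some samples")
  if (any(md$sample_type != "biopsy")) stop("all samples must be biopsies")
  ord <- order(match(md$site, gi_sites), md$replicate)
  rel <- relative_abundance(x)[, ord, drop = FALSE]
  list(rel = rel, site = md$site[ord], replicate = md$replicate[ord])
}

#' Linear trend of abundance along the GI tract
#'
#' Ordinary least squares of relative abundance on position, using all
#' site-replicate observations (replicates are not averaged, preserving
#' within-site variance for inference).
#'
#' @param abundance Numeric vector of relative abundances.
#' @param positions Numeric positions (see [site_positions()]).
#' @return List with `slope`, `p_value` (two-sided, t distribution),
#'   `degenerate` (TRUE when the profile has zero variance; then slope 0,
#'   p 1).
#' @export
fit_monotonic_trend <- function(abundance, positions) {
  if (length(abundance) != length(positions))
    stop("abundance and positions differ in length")
  if (stats::var(abundance) == 0)
    return(list(slope = 0, p_value = 1, degenerate = TRUE))
  fit <- stats::lm(abundance ~ positions)
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(co["positions", "Estimate"])
  p <- unname(co["positions", "Pr(>|t|)"])
  if (is.na(p)) p <- if (abs(slope) < 1e-12) 1 else 0  # exact fit
  list(slope = slope, p_value = p, degenerate = FALSE)
}

#' Classify a monotonic gradient
#'
#' MGA (monotonous gradient ascending): significant increase toward the
#' rectum; MGD: significant decrease. Positions from [site_positions()] are
#' already oriented rectum-ward under both conventions, so the slope sign is
#' convention-invariant.
#'
#' @param trend Result of [fit_monotonic_trend()].
#' @param alpha Significance level (default 0.05).
#' @return `"MGA"`, `"MGD"`, or `"none"`.
#' @export
classify_gradient <- function(trend, alpha = 0.05) {
  if (isTRUE(trend$degenerate) || trend$p_value >= alpha) return("none")
  if (trend$slope > 0) "MGA" else "MGD"
}

#' Broken-stick (segmented) model with a fixed breakpoint site
#'
#' Continuous two-segment linear model with a hinge at the breakpoint site's
#' ordinal position: `abundance ~ pos + max(0, pos - bp)`. The hinge
#' coefficient is the change in slope; its two-sided t-test p-value tests
#' whether the slope changes at the breakpoint. Candidate breakpoints are
#' the interior colonic sites AC, TC and DC.
#'
#' @param abundance Relative abundances over site-replicate observations.
#' @param sites Site code per observation.
#' @param breakpoint_site `"AC"`, `"TC"` or `"DC"`.
#' @return List with `slope_left`, `slope_right`, `p_break`, `degenerate`.
#' @export
fit_breakpoint_model <- function(abundance, sites,
                                 breakpoint_site = c("AC", "TC", "DC")) {
  breakpoint_site <- match.arg(breakpoint_site)
  pos <- site_positions(sites, "ordinal")
  bp <- match(breakpoint_site, gi_sites)
  if (stats::var(abundance) == 0)
    return(list(slope_left = 0, slope_right = 0, p_break = 1,
                degenerate = TRUE))
  hinge <- pmax(0, pos - bp)
  fit <- stats::lm(abundance ~ pos + hinge)
  co <- suppressWarnings(summary(fit)$coefficients)
  b1 <- unname(co["pos", "Estimate"])
  b2 <- if ("hinge" %in% rownames(co)) unname(co["hinge", "Estimate"]) else 0
  p2 <- if ("hinge" %in% rownames(co)) unname(co["hinge", "Pr(>|t|)"]) else 1
  # numerically exact fits: the t-test is meaningless at zero residual
  scale <- stats::sd(abundance)
  sigma <- suppressWarnings(summary(fit)$sigma)
  if (is.na(p2) || sigma < 1e-8 * scale)
    p2 <- if (abs(b2) < 1e-8 * scale) 1 else 0
  list(slope_left = b1, slope_right = b1 + b2, p_break = p2,
       degenerate = FALSE)
}

#' Classify a broken-stick profile
#'
#' Requires a significant hinge term and a sign change between segments.
#' Convention (documented, since "ascending with breakpoint" is ambiguous):
#' GAB = descending then ascending toward the rectum (a V shape, the shape of
#' the dominant biopsy OTU with an AC breakpoint); GDB = ascending then
#' descending (an inverted V). Segment slopes are returned by
#' [fit_breakpoint_model()] so the call can always be audited.
#'
#' @param fit Result of [fit_breakpoint_model()].
#' @param alpha Significance level for the hinge term (default 0.05).
#' @return `"GAB"`, `"GDB"`, or `"none"`.
#' @export
classify_breakpoint <- function(fit, alpha = 0.05) {
  if (isTRUE(fit$degenerate) || fit$p_break >= alpha) return("none")
  if (fit$slope_left < 0 && fit$slope_right > 0) return("GAB")
  if (fit$slope_left > 0 && fit$slope_right < 0) return("GDB")
  "none"
}

#' Negative-binomial exact test: one site versus all others
#'
#' Tests each OTU for a difference in mean between the (typically 3) samples
#' of one GI site and all other biopsy samples, on RAW counts — library-size
#' differences are handled inside the test by quantile-equalizing libraries,
#' a common negative-binomial dispersion is estimated across OTUs by
#' conditional maximum likelihood, and the exact conditional p-value sums
#' the probabilities of outcomes as or more extreme in both directions
#' given the pooled total. Implemented with edgeR. P-values are BH-adjusted
#' across OTUs.
#'
#' @param x A [count_table()] of RAW biopsy counts, prefiltered to the
#'   abundant OTUs (0.1% in >= 3 samples on the common-scaled table).
#' @param metadata Biopsy sample metadata.
#' @param site Site code to contrast against all other sites.
#' @param dispersion `"common"` (conditional-ML common dispersion, default)
#'   or a numeric value.
#' @return data.frame: `otu_id`, `log_fc` (positive = enriched at `site`),
#'   `p_value`, `fdr`, `direction` (+1 enriched / -1 depleted / 0).
#' @export
nb_exact_test <- function(x, metadata, site, dispersion = "common") {
  md <- metadata[match(sample_ids(x), metadata$sample_id), ]
  if (!site %in% md$site) stop("no samples from site ", site)
  grp <- factor(ifelse(md$site == site, "site", "other"),
                levels = c("other", "site"))
  if (sum(grp == "other") < 1) stop("no reference samples")
  y <- edgeR::DGEList(counts = x$values, group = grp)
  if (identical(dispersion, "common")) {
    y <- edgeR::estimateCommonDisp(y)
    et <- edgeR::exactTest(y, pair = c("other", "site"))
  } else {
    et <- edgeR::exactTest(y, pair = c("other", "site"),
                           dispersion = dispersion)
  }
  tab <- et$table
  p <- tab$PValue
  data.frame(
    otu_id = taxa_ids(x),
    log_fc = tab$logFC,
    p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    direction = sign(tab$logFC),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify habitat specialists and avoiders
#'
#' HS: significantly elevated relative abundance at a site (enriched,
#' p < `p_thresh` and FDR < `fdr_thresh`); HA: significantly lowered.
#'
#' @param test Result of [nb_exact_test()] (one row per OTU).
#' @param p_thresh Raw p-value threshold (default 0.01).
#' @param fdr_thresh BH FDR threshold (default 0.05).
#' @return Character vector per OTU: `"HS"`, `"HA"`, or `"none"`.
#' @export
classify_specialist <- function(test, p_thresh = 0.01, fdr_thresh = 0.05) {
  out <- rep("none", nrow(test))
  hit <- test$p_value < p_thresh & test$fdr < fdr_thresh
  out[hit & test$direction > 0] <- "HS"
  out[hit & test$direction < 0] <- "HA"
  out
}

#' Full spatial classification of a biopsy table
#'
#' Runs, for every OTU: the monotonic-trend fit under both positional
#' conventions (MGA/MGD at `alpha_trend`), the broken-stick fit at each
#' candidate breakpoint (GAB/GDB at `alpha_break`), and the one-site-vs-rest
#' negative-binomial exact tests (HS/HA at `p_hs`/`fdr_hs`). An OTU can hold
#' categories from different tests simultaneously.
#'
#' @param raw A RAW-count biopsy [count_table()] (used for the exact tests).
#' @param metadata Biopsy metadata.
#' @param scaled Optional common-scaled table for the regressions; defaults
#'   to `common_scale(raw)`.
#' @param alpha_trend,alpha_break,p_hs,fdr_hs Thresholds (defaults 0.05,
#'   0.05, 0.01, 0.05).
#' @param breakpoints Candidate breakpoint sites (default AC, TC, DC).
#' @param specialist_sites Sites to test for specialists (default all 7).
#' @return A long data.frame with columns `otu_id`, `category`, `test`
#'   (gradient/breakpoint/specialist), `convention`, `site`, `slope`,
#'   `slope_left`, `slope_right`, `p_value`, `fdr`; one row per OTU per
#'   assigned category, plus `"none"` rows for unclassified OTUs are omitted.
#' @export
classify_spatial <- function(raw, metadata, scaled = NULL,
                             alpha_trend = 0.05, alpha_break = 0.05,
                             p_hs = 0.01, fdr_hs = 0.05,
                             breakpoints = c("AC", "TC", "DC"),
                             specialist_sites = gi_sites) {
  if (is.null(scaled)) scaled <- common_scale(raw)
  prof <- site_profiles(scaled, metadata)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (i in seq_along(taxa_ids(scaled))) {
    otu <- taxa_ids(scaled)[i]
    ab <- prof$rel[i, ]
    for (conv in c("ordinal", "distance_cm")) {
      tr <- fit_monotonic_trend(ab, site_positions(prof$site, conv))
      cat_g <- classify_gradient(tr, alpha_trend)
      if (cat_g != "none")
        add(otu_id = otu, category = cat_g, test = "gradient",
            convention = conv, site = NA_character_, slope = tr$slope,
            slope_left = NA_real_, slope_right = NA_real_,
            p_value = tr$p_value, fdr = NA_real_)
    }
    for (bp in breakpoints) {
      fb <- fit_breakpoint_model(ab, prof$site, bp)
      cat_b <- classify_breakpoint(fb, alpha_break)
      if (cat_b != "none")
        add(otu_id = otu, category = cat_b, test = "breakpoint",
            convention = "ordinal", site = bp, slope = NA_real_,
            slope_left = fb$slope_left, slope_right = fb$slope_right,
            p_value = fb$p_break, fdr = NA_real_)
    }
  }

  for (s in intersect(specialist_sites, unique(metadata$site))) {
    et <- nb_exact_test(raw, metadata, s)
    cls <- classify_specialist(et, p_hs, fdr_hs)
    for (i in which(cls != "none"))
      add(otu_id = et$otu_id[i], category = cls[i], test = "specialist",
          convention = NA_character_, site = s, slope = NA_real_,
          slope_left = NA_real_, slope_right = NA_real_,
          p_value = et$p_value[i], fdr = et$fdr[i])
  }
  if (!length(rows))
    return(data.frame(otu_id = character(), category = character(),
                      test = character(), convention = character(),
                      site = character(), slope = numeric(),
                      slope_left = numeric(), slope_right = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
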