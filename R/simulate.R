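#' Simulate a fecal count time series from the interaction model
#'
#' Runs the pairwise interaction model forward as a generative process on
#' log abundances: `x_{t+1} = x_t + alpha + B x_t + eps_t` with Gaussian
#' process noise, closes each day to a composition (softmax), and draws
#' multinomial read counts at a lognormally distributed library size. The
#' default library distribution matches daily fecal sequencing depths of
#' roughly 139,000 +/- 71,000 reads; the default horizon is 139 daily
#' samples. Intercepts are chosen so the deterministic system is at
#' equilibrium at the baseline composition, making `beta` the only source
#' of cross-taxon dynamics.
#'
#' @param n_taxa Number of taxa (default 20).
#' @param n_days Number of consecutive daily samples (default 139).
#' @param beta Interaction matrix `B` (n x n). Diagonal entries are
#'   self-regulation terms and must keep the linearized map `I + B` stable
#'   (spectral radius < 1). Default: no cross-interactions, self-regulation
#'   `self_reg` on the diagonal.
#' @param self_reg Default diagonal of `beta` (default -0.9: strong daily
#'   mean reversion, matching the rapid day-to-day compositional
#'   fluctuation of dense fecal series).
#' @param baseline Baseline log abundances (default drawn N(0, 1)).
#' @param noise_sd SD of daily Gaussian process noise on log abundances
#'   (default 0.15, i.e. ~15% day-to-day fluctuation).
#' @param lib_meanlog,lib_sdlog Lognormal library-size parameters (defaults
#'   11.73 and 0.48).
#' @param seed Optional integer seed; fixed seed gives bit-identical tables.
#' @return List: `counts` (a [count_table()], taxa x days), `metadata`
#'   (fecal, day 1..n_days), `beta_true`, `alpha_true`, `log_abundance`
#'   (the latent log-abundance trajectories).
#' @export
simulate_time_series <- function(n_taxa = 20, n_days = 139, beta = NULL,
                                 self_reg = -0.9, baseline = NULL,
                                 noise_sd = 0.15, lib_meanlog = 11.73,
                                 lib_sdlog = 0.48, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- diag(self_reg, n_taxa)
  beta <- as.matrix(beta)
  if (nrow(beta) != n_taxa || ncol(beta) != n_taxa)
    stop("beta must be ", n_taxa, " x ", n_taxa)
  sr <- max(Mod(eigen(diag(n_taxa) + beta, only.values = TRUE)$values))
  if (sr >= 1 + 1e-8)
    stop("unstable interaction matrix (spectral radius of I + B = ",
         signif(sr, 4), " >= 1); use stronger self-regulation")
  if (is.null(baseline)) baseline <- stats::rnorm(n_taxa)
  alpha <- as.vector(-beta %*% baseline)
  x <- matrix(0, n_taxa, n_days)
  x[, 1] <- baseline
  for (t in seq_len(n_days - 1)) {
    x[, t + 1] <- x[, t] + alpha + as.vector(beta %*% x[, t]) +
      stats::rnorm(n_taxa, 0, noise_sd)
    if (any(abs(x[, t + 1]) > 50))
      stop("divergent trajectory at day ", t + 1,
           "; use stronger self-regulation")
  }
  probs <- apply(x, 2, function(z) {
    e <- exp(z - max(z)); e / sum(e)
  })
  libs <- pmax(1, round(stats::rlnorm(n_days, lib_meanlog, lib_sdlog)))
  counts <- vapply(seq_len(n_days), function(t)
    stats::rmultinom(1, libs[t], probs[, t])[, 1], numeric(n_taxa))
  taxa <- paste0("OTU", seq_len(n_taxa))
  samples <- sprintf("day_%03d", seq_len(n_days))
  dimnames(counts) <- list(taxa, samples)
  md <- data.frame(sample_id = samples, sample_type = "fecal",
                   day = seq_len(n_days), site = NA, replicate = NA,
                   distance_cm = NA, stringsAsFactors = FALSE)
  rownames(x) <- taxa
  list(counts = count_table(counts), metadata = md, beta_true = beta,
       alpha_true = alpha, log_abundance = x)
}

#' Sparse signed interaction matrix for simulations
#'
#' Places `n_pairs` reciprocal interactions (both directions set) between
#' randomly chosen disjoint taxon pairs, with magnitude `strength` and sign
#' drawn according to `prop_negative`, on top of uniform negative
#' self-regulation.
#'
#' @param n_taxa Number of taxa.
#' @param n_pairs Number of interacting pairs (default `n_taxa / 4`).
#' @param strength Magnitude of interaction coefficients (default 0.7).
#'   Under strong self-regulation the pairwise estimator recovers an
#'   attenuated coefficient, so detectable interactions must be of the
#'   same order as the self-regulation term.
#' @param prop_negative Probability an interaction is competitive (both
#'   coefficients negative; default 0.8, competition being the dominant
#'   observed mode).
#' @param self_reg Diagonal self-regulation (default -0.9).
#' @param seed Optional seed.
#' @return List: `beta` (n x n matrix), `pairs` (data.frame of taxon index
#'   pairs and their signs).
#' @export
random_interaction_matrix <- function(n_taxa, n_pairs = floor(n_taxa / 4),
                                      strength = 0.7, prop_negative = 0.8,
                                      self_reg = -0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (2 * n_pairs > n_taxa) stop("too many pairs for disjoint assignment")
  beta <- diag(self_reg, n_taxa)
  idx <- sample(n_taxa, 2 * n_pairs)
  a <- idx[seq_len(n_pairs)]
  b <- idx[n_pairs + seq_len(n_pairs)]
  sgn <- ifelse(stats::runif(n_pairs) < prop_negative, -1, 1)
  for (k in seq_len(n_pairs)) {
    beta[a[k], b[k]] <- sgn[k] * strength
    beta[b[k], a[k]] <- sgn[k] * strength
  }
  list(beta = beta,
       pairs = data.frame(a = a, b = b, sign = sgn))
}

.spatial_categories <- c("flat", "MGA", "MGD", "GAB", "GDB", "HS", "HA")

# archetype mean profile over the 7 ordinal sites (TI..R), max/min = fold
.archetype_profile <- function(category, fold, site = NA) {
  b <- if (!is.na(site)) match(site, gi_sites) else NA
  switch(category,
    flat = rep(1, 7),
    MGA = seq(1, fold, length.out = 7),
    MGD = seq(fold, 1, length.out = 7),
    GAB = c(seq(fold, 1, length.out = b),
            seq(1, fold, length.out = 8 - b)[-1]),
    GDB = c(seq(1, fold, length.out = b),
            seq(fold, 1, length.out = 8 - b)[-1]),
    HS = { p <- rep(1, 7); p[b] <- fold; p },
    HA = { p <- rep(1, 7); p[b] <- 1 / fold; p },
    stop("unknown spatial category: ", category))
}

#' Default spatial category assignment
#'
#' @param n_per_category Named integer vector of OTU counts per category
#'   (names from `flat`, `MGA`, `MGD`, `GAB`, `GDB`, `HS`, `HA`).
#' @param sites Sites cycled over for the categories that need one
#'   (breakpoint sites for GAB/GDB, target sites for HS/HA).
#' @return data.frame with `otu_id`, `category`, `site`.
#' @export
spatial_labels <- function(n_per_category = c(flat = 8, MGA = 3, MGD = 3,
                                              GAB = 2, GDB = 2, HS = 3,
                                              HA = 3),
                           sites = c("AC", "TC", "DC")) {
  bad <- setdiff(names(n_per_category), .spatial_categories)
  if (length(bad)) stop("unknown category: ", bad[1])
  cats <- rep(names(n_per_category), n_per_category)
  site <- rep(NA_character_, length(cats))
  need <- cats %in% c("GAB", "GDB")
  site[need] <- rep_len(sites, sum(need))
  spec <- cats %in% c("HS", "HA")
  site[spec] <- rep_len(c("TI", "AC", "R"), sum(spec))
  data.frame(otu_id = paste0("OTU", seq_along(cats)), category = cats,
             site = site, stringsAsFactors = FALSE)
}

#' Simulate a biopsy table with known spatial structure
#'
#' Builds each OTU's 7-site mean relative-abundance profile from its
#' category archetype (linear ramps for monotonic gradients, hinge shapes
#' for breakpoint gradients, single-site spikes/dips for specialists and
#' avoiders, constant for flat), scales profiles by lognormal baseline
#' abundances, closes each site to a composition, and draws
#' negative-binomial counts per replicate at the stated dispersion and a
#' lognormal library size (default matching biopsy depths of roughly
#' 60,000 +/- 40,000 reads).
#'
#' @param labels data.frame with `otu_id`, `category`, `site` (see
#'   [spatial_labels()]).
#' @param fold Effect size: max/min ratio of the mean profile (default 4;
#'   must exceed 1 for any non-flat label).
#' @param dispersion Negative-binomial dispersion (default 0.2; 0 gives
#'   Poisson counts).
#' @param n_replicates Replicate biopsies per site (default 3).
#' @param lib_meanlog,lib_sdlog Lognormal library-size parameters (defaults
#'   10.82 and 0.61).
#' @param baseline Per-OTU lognormal baseline weights (default drawn with
#'   sdlog 1).
#' @param seed Optional seed.
#' @return List: `counts` (a [count_table()], taxa x 21 samples),
#'   `metadata`, `labels` (the truth), `mean_profiles` (taxa x 7 expected
#'   relative abundances).
#' @export
simulate_spatial <- function(labels = spatial_labels(), fold = 4,
                             dispersion = 0.2, n_replicates = 3,
                             lib_meanlog = 10.82, lib_sdlog = 0.61,
                             baseline = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fold <= 1 && any(labels$category != "flat"))
    stop("effect size (fold) must exceed 1 for non-flat categories")
  n <- nrow(labels)
  if (is.null(baseline)) baseline <- stats::rlnorm(n, 0, 1)
  W <- t(mapply(.archetype_profile, labels$category,
                MoreArgs = list(fold = fold),
                site = labels$site))
  W <- W * baseline
  fracs <- sweep(W, 2, colSums(W), "/")    # expected composition per site
  samples <- as.vector(outer(seq_len(n_replicates), gi_sites,
                             function(r, s) paste0(s, "_", r)))
  site_of <- rep(gi_sites, each = n_replicates)
  rep_of <- rep(seq_len(n_replicates), times = 7)
  libs <- pmax(1, round(stats::rlnorm(length(samples), lib_meanlog,
                                      lib_sdlog)))
  counts <- vapply(seq_along(samples), function(k) {
    mu <- fracs[, match(site_of[k], gi_sites)] * libs[k]
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }, numeric(n))
  dimnames(counts) <- list(labels$otu_id, samples)
  md <- data.frame(sample_id = samples, sample_type = "biopsy", day = NA,
                   site = site_of, replicate = rep_of,
                   distance_cm = unname(gi_site_distance_cm[site_of]),
                   stringsAsFactors = FALSE)
  rownames(fracs) <- labels$otu_id
  colnames(fracs) <- gi_sites
  list(counts = count_table(counts), metadata = md, labels = labels,
       mean_profiles = fracs)
}

#' Generate a hierarchical taxonomy
#'
#' Deterministic nested labels (`Phylum1`, `Phylum1_Genus2`, ...) with a
#' configurable number of OTUs per genus; every OTU is fully ranked.
#'
#' @param n_phyla,genera_per_phylum,otus_per_genus Tree shape (defaults
#'   4, 4, 5 giving 80 OTUs).
#' @return data.frame with `otu_id` and the six rank columns.
#' @export
generate_taxonomy <- function(n_phyla = 4, genera_per_phylum = 4,
                              otus_per_genus = 5) {
  rows <- expand.grid(otu = seq_len(otus_per_genus),
                      genus = seq_len(genera_per_phylum),
                      phylum = seq_len(n_phyla))
  p <- paste0("Phylum", rows$phylum)
  g <- paste0(p, "_Genus", rows$genus)
  data.frame(
    otu_id = paste0("OTU", seq_len(nrow(rows))),
    kingdom = "Bacteria",
    phylum = p,
    class = paste0(p, "_Class1"),
    order = paste0(p, "_Order1"),
    family = g,
    genus = g,
    stringsAsFactors = FALSE
  )
}

#' Simulate a coupled spatial + temporal study
#'
#' Generates a fecal time series and a biopsy table over the same taxa,
#' with competitive interaction pairs optionally placed into overlapping
#' spatial niches. Each taxon's spatial profile is a Gaussian bump around a
#' niche center site; with probability `niche_coupling` the two members of
#' a competitive pair share a center, producing the resource-competition
#' signature in which temporally interacting pairs co-occur spatially
#' (positive spatial correlation among significant interaction pairs).
#' With `niche_coupling = 0` centers are independent and the partitioned
#' concordance test is null.
#'
#' @param n_taxa,n_days As in [simulate_time_series()].
#' @param n_pairs Number of competitive pairs (default `n_taxa / 4`).
#' @param strength Interaction magnitude (default 0.7).
#' @param niche_coupling Probability a competitive pair shares a niche
#'   center, in `[0, 1]` (default 1).
#' @param niche_width SD of the Gaussian spatial bump in ordinal site units
#'   (default 1.2).
#' @param dispersion Biopsy negative-binomial dispersion (default 0.2).
#' @param noise_sd,seed Passed to the generators.
#' @return List: `fecal` (output of [simulate_time_series()]), `biopsy`
#'   (`counts`, `metadata`), `beta_true`, `pairs`, `niche_centers`.
#' @export
simulate_coupled_study <- function(n_taxa = 20, n_days = 139,
                                   n_pairs = floor(n_taxa / 4),
                                   strength = 0.7, niche_coupling = 1,
                                   niche_width = 1.2, dispersion = 0.2,
                                   noise_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rim <- random_interaction_matrix(n_taxa, n_pairs, strength,
                                   prop_negative = 1)
  fecal <- simulate_time_series(n_taxa, n_days, beta = rim$beta,
                                noise_sd = noise_sd)
  centers <- sample(1:7, n_taxa, replace = TRUE)
  share <- stats::runif(n_pairs) < niche_coupling
  centers[rim$pairs$b[share]] <- centers[rim$pairs$a[share]]
  pos <- 1:7
  W <- t(vapply(centers, function(c0)
    exp(-(pos - c0)^2 / (2 * niche_width^2)), numeric(7)))
  W <- W * stats::rlnorm(n_taxa, 0, 0.5)
  fracs <- sweep(W, 2, colSums(W), "/")
  samples <- as.vector(outer(1:3, gi_sites, function(r, s)
    paste0(s, "_", r)))
  site_of <- rep(gi_sites, each = 3)
  libs <- pmax(1, round(stats::rlnorm(length(samples), 10.82, 0.61)))
  counts <- vapply(seq_along(samples), function(k) {
    mu <- fracs[, match(site_of[k], gi_sites)] * libs[k]
    stats::rnbinom(n_taxa, mu = mu, size = 1 / dispersion)
  }, numeric(n_taxa))
  taxa <- paste0("OTU", seq_len(n_taxa))
  dimnames(counts) <- list(taxa, samples)
  md <- data.frame(sample_id = samples, sample_type = "biopsy", day = NA,
                   site = site_of, replicate = rep(1:3, times = 7),
                   distance_cm = unname(gi_site_distance_cm[site_of]),
                   stringsAsFactors = FALSE)
  list(fecal = fecal,
       biopsy = list(counts = count_table(counts), metadata = md),
       beta_true = rim$beta, pairs = rim$pairs, niche_centers = centers)
}
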