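#' Common scaling of library sizes
#'
#' Multiplies each sample's counts by the ratio of the smallest library size
#' to that sample's library size, so that every scaled column sums to the
#' smallest original library. This replaces rarefying: it is the expected
#' table under infinitely repeated subsampling to the smallest depth.
#'
#' @param x A [count_table()].
#' @return A [count_table()] of common-scaled (possibly fractional) counts.
#' @export
common_scale <- function(x) {
  libs <- library_sizes(x)
  if (length(libs) < 1) stop("no samples")
  if (any(libs == 0))
    stop("zero library size in sample: ", sample_ids(x)[which(libs == 0)[1]])
  count_table(sweep(x$values, 2, min(libs) / libs, "*"))
}

#' Remove singleton OTUs
#'
#' Drops OTUs whose total count over all samples is at most one read. Applied
#' to raw (unscaled) tables.
#'
#' @param x A [count_table()].
#' @return A [count_table()] without singleton OTUs.
#' @export
remove_singletons <- function(x) {
  subset_table(x, taxa = rowSums(x$values) > 1)
}

# Per-sample qualifying-count thresholds: ceiling of fraction x library size,
# matching "0.1% relative abundance (11 reads)" of a 10,662-read library.
.abund_threshold <- function(x, min_rel_abund) {
  ceiling(min_rel_abund * library_sizes(x) - 1e-9)
}

#' Prevalence filter
#'
#' Retains OTUs observed at or above a relative-abundance threshold in at
#' least `min_samples` samples. The per-sample qualifying count is the
#' ceiling of `min_rel_abund` times the library size, so on a common-scaled
#' table the threshold is a fixed read count (0.1% of 10,662 reads -> 11).
#'
#' @param x A [count_table()] (common-scaled when reproducing the published
#'   thresholds).
#' @param min_rel_abund Minimum relative abundance (default 0.001, i.e. 0.1%).
#' @param min_samples Minimum number of qualifying samples (default 3, the
#'   number of biopsy replicates per site).
#' @return A filtered [count_table()]; surviving values are unchanged.
#' @export
filter_prevalence <- function(x, min_rel_abund = 0.001, min_samples = 3) {
  if (min_samples > ncol(x$values))
    stop("min_samples (", min_samples, ") exceeds number of samples (",
         ncol(x$values), ")")
  thr <- .abund_threshold(x, min_rel_abund)
  n_qual <- rowSums(sweep(x$values, 2, thr, ">="))
  subset_table(x, taxa = n_qual >= min_samples)
}

#' Consistency filter
#'
#' As [filter_prevalence()], but the sample criterion is a fraction of all
#' samples: an OTU must qualify in at least
#' `ceiling(min_sample_fraction * n_samples)` samples (default 0.05% of reads
#' in at least 90% of samples, the criterion used to select taxa consistent
#' enough for time-series modeling).
#'
#' @param x A [count_table()].
#' @param min_rel_abund Minimum relative abundance (default 0.0005).
#' @param min_sample_fraction Minimum fraction of samples (default 0.9).
#' @return A filtered [count_table()].
#' @export
filter_consistency <- function(x, min_rel_abund = 0.0005,
                               min_sample_fraction = 0.9) {
  min_samples <- ceiling(min_sample_fraction * ncol(x$values) - 1e-9)
  thr <- .abund_threshold(x, min_rel_abund)
  n_qual <- rowSums(sweep(x$values, 2, thr, ">="))
  subset_table(x, taxa = n_qual >= min_samples)
}
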