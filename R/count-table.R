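#' OTU count table
#'
#' A `count_table` holds a taxa-by-samples abundance matrix together with its
#' taxon and sample identifiers. Raw tables contain integer read counts;
#' common-scaled tables (see [common_scale()]) may hold fractional values.
#' Per-sample library sizes are always the column sums.
#'
#' @param values Numeric matrix, taxa as rows and samples as columns. All
#'   entries must be non-negative and finite.
#' @param taxa_ids Character vector of OTU identifiers (defaults to rownames).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   colnames).
#'
#' @return An object of class `count_table`.
#' @export
#' @examples
#' ct <- count_table(matrix(1:6, nrow = 3,
#'                          dimnames = list(paste0("OTU", 1:3), c("s1", "s2"))))
#' library_sizes(ct)
count_table <- function(values, taxa_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(taxa_ids)) taxa_ids <- paste0("OTU", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  taxa_ids <- as.character(taxa_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxa_ids) != nrow(values))
    stop("taxa_ids length (", length(taxa_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(taxa_ids))
    stop("duplicated taxon id: ", taxa_ids[duplicated(taxa_ids)][1])
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1])
  if (any(!is.finite(values)))
    stop("non-finite values in count table")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative value at taxon '", taxa_ids[bad[1]], "', sample '",
         sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(taxa_ids, sample_ids)
  structure(list(values = values), class = "count_table")
}

#' @export
dim.count_table <- function(x) dim(x$values)

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$values), "taxa x", ncol(x$values), "samples\n")
  cat("library sizes:", paste(signif(utils::head(library_sizes(x), 5), 6),
                              collapse = ", "),
      if (ncol(x$values) > 5) "..." else "", "\n")
  invisible(x)
}

#' Accessors for count tables
#'
#' @param x A [count_table()].
#' @return `taxa_ids()` and `sample_ids()` return character vectors;
#'   `library_sizes()` returns the named vector of per-sample column sums;
#'   `counts_matrix()` returns the underlying numeric matrix.
#' @export
taxa_ids <- function(x) rownames(x$values)

#' @rdname taxa_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname taxa_ids
#' @export
library_sizes <- function(x) colSums(x$values)

#' @rdname taxa_ids
#' @export
counts_matrix <- function(x) x$values

#' Relative abundances
#'
#' Divides each column by its library size.
#'
#' @param x A [count_table()].
#' @return Numeric matrix of per-sample relative abundances (columns sum to 1).
#' @export
relative_abundance <- function(x) {
  libs <- library_sizes(x)
  if (any(libs == 0))
    stop("sample with zero library size: ",
         sample_ids(x)[which(libs == 0)[1]])
  sweep(x$values, 2, libs, "/")
}

#' Subset a count table
#'
#' @param x A [count_table()].
#' @param taxa,samples Index vectors (logical, integer or character).
#' @return A [count_table()].
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(taxa)) v <- v[taxa, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  count_table(v)
}

#' Read an OTU count table
#'
#' The canonical format is tab-separated text with taxa as rows: the first
#' column (`otu_id`) holds OTU identifiers and the header row holds sample
#' identifiers. BIOM 2.x/1.0 files are supported through the biomformat
#' package when it is installed.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return A [count_table()]; taxa and sample order is preserved from the file.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(count_table(m))
  }
  if (file.size(path) == 0) stop("parse error: empty file: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("parse error: expected an otu_id column plus at least one sample in ",
         path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("parse error: non-numeric counts in ", path)
  rownames(m) <- ids
  count_table(m)
}

#' Write an OTU count table as TSV
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(otu_id = taxa_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' GI tract biopsy sites
#'
#' Site codes ordered proximal to distal (terminal ileum to rectum), and their
#' approximate distances from the anus in centimeters.
#'
#' @format `gi_sites` is a character vector of the seven site codes;
#'   `gi_site_distance_cm` is the named numeric vector of distances.
#' @export
gi_sites <- c("TI", "IV", "AC", "TC", "DC", "SC", "R")

#' @rdname gi_sites
#' @export
gi_site_distance_cm <- c(TI = 155, IV = 150, AC = 142, TC = 109,
                         DC = 64, SC = 20, R = 10)

#' Read or validate sample metadata
#'
#' Metadata is a table with one row per sample and columns `sample_id`,
#' `sample_type` (`"fecal"` or `"biopsy"`), `day` (integer collection day,
#' fecal samples), `site` (GI site code, biopsy samples), `replicate`
#' (biopsy samples) and `distance_cm` (distance from the anus; filled in from
#' [gi_site_distance_cm] when missing for a known site).
#'
#' @param path Path to a TSV file.
#' @param df A data.frame to validate instead of reading from `path`.
#' @return A validated data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path = NULL, df = NULL) {
  if (is.null(df)) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  }
  required <- c("sample_id", "sample_type")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  if (!all(df$sample_type %in% c("fecal", "biopsy")))
    stop("sample_type must be 'fecal' or 'biopsy'")
  for (col in c("day", "site", "replicate", "distance_cm"))
    if (is.null(df[[col]])) df[[col]] <- NA
  bio <- df$sample_type == "biopsy"
  if (any(bio)) {
    if (any(is.na(df$site[bio])))
      stop("biopsy samples must have a site")
    if (!all(df$site[bio] %in% gi_sites))
      stop("unknown GI site: ",
           setdiff(df$site[bio], gi_sites)[1],
           " (expected one of ", paste(gi_sites, collapse = ", "), ")")
    if (any(is.na(df$replicate[bio])))
      stop("biopsy samples must have a replicate id")
    fill <- bio & is.na(df$distance_cm)
    df$distance_cm[fill] <- gi_site_distance_cm[df$site[fill]]
  }
  fec <- df$sample_type == "fecal"
  if (any(fec) && any(is.na(df$day[fec])))
    stop("fecal samples must have a collection day")
  df
}

#' @rdname read_sample_metadata
#' @param metadata A metadata data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' @param path TSV with columns `otu_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`; empty or NA cells denote unassigned ranks.
#' @return A data.frame with those seven columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(c("otu_id", .tax_ranks), names(df))
  if (length(missing))
    stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Collapse a count table to a taxonomic rank
#'
#' Member OTU counts are summed within each distinct label at the requested
#' rank. OTUs unassigned at that rank (or absent from the taxonomy, with a
#' warning) are pooled into a reserved `"unclassified_<rank>"` bucket so that
#' per-sample totals are conserved exactly.
#'
#' @param x A [count_table()].
#' @param taxonomy A taxonomy data.frame (see [read_taxonomy()]).
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A [count_table()] whose taxa are rank labels.
#' @export
collapse_to_rank <- function(x, taxonomy, rank = "genus") {
  rank <- match.arg(rank, .tax_ranks)
  labels <- taxonomy[[rank]][match(taxa_ids(x), taxonomy$otu_id)]
  absent <- is.na(match(taxa_ids(x), taxonomy$otu_id))
  if (any(absent))
    warning(sum(absent), " OTU(s) missing from taxonomy; pooled as unclassified_",
            rank)
  unassigned <- absent | is.na(labels) | labels == ""
  labels[unassigned] <- paste0("unclassified_", rank)
  v <- rowsum(x$values, group = labels, reorder = FALSE)
  count_table(v)
}
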