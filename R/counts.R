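# Core count-table representation and the shared normalisation /
# transformation / filtering primitives.

#' Convert a count data frame to a numeric matrix
#'
#' Accepts the package's standard wide count table (a data frame whose first
#' column, `sample_id`, holds unique sample identifiers and whose remaining
#' columns are numeric per-taxon counts) or a numeric matrix with sample ids
#' as row names, and returns the matrix form used internally.
#'
#' @param counts Wide count data frame or numeric matrix (samples x taxa).
#' @param require_integer Require all entries to be whole numbers.
#' @return Numeric matrix with sample ids as rownames, taxon ids as colnames.
#' @export
count_matrix <- function(counts, require_integer = FALSE) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  } else if (is.data.frame(counts)) {
    id_col <- if ("sample_id" %in% names(counts)) "sample_id" else names(counts)[1]
    ids <- as.character(counts[[id_col]])
    m <- as.matrix(counts[setdiff(names(counts), id_col)])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    abort("`counts` must be a data frame or a numeric matrix.")
  }
  if (anyDuplicated(rownames(m))) abort("sample ids must be unique.")
  if (anyDuplicated(colnames(m))) abort("taxon ids must be unique.")
  if (anyNA(m)) abort("count table contains missing values.")
  if (any(m < 0)) abort("count table contains negative entries.")
  if (require_integer && any(abs(m - round(m)) > 1e-8)) {
    abort("count table must contain integer counts for this operation.")
  }
  m
}

# as count_matrix() but for real-valued tables (CLR scores may be negative)
value_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  } else {
    id_col <- if ("sample_id" %in% names(x)) "sample_id" else names(x)[1]
    ids <- as.character(x[[id_col]])
    m <- as.matrix(x[setdiff(names(x), id_col)])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  }
  if (anyNA(m)) abort("table contains missing values.")
  m
}

#' Convert a count matrix back to the standard wide tibble
#'
#' @param m Numeric matrix, samples in rows.
#' @return Tibble with a `sample_id` column followed by taxon columns.
#' @export
count_tbl <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Read / write count tables as TSV
#'
#' The on-disk format is a tab-separated table with a header row of taxon
#' ids, one row per sample, and the sample id in the first column
#' (`sample_id`).
#'
#' @param path File path.
#' @return `read_counts()` returns the wide count tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  tibble::as_tibble(x)
}

#' @rdname read_counts
#' @param counts Wide count table.
#' @export
write_counts <- function(counts, path) {
  m <- count_matrix(counts)
  readr::write_tsv(count_tbl(m), path, progress = FALSE)
  invisible(path)
}

#' Read / write count tables as BIOM v1 (JSON)
#'
#' Thin wrappers around the biomformat package. BIOM stores observations
#' (taxa) as rows; these wrappers transpose to the package's samples-in-rows
#' convention.
#'
#' @param path File path.
#' @return `read_counts_biom()` returns the wide count tibble.
#' @export
read_counts_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the biomformat package is required for BIOM i/o.")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  count_tbl(m)
}

#' @rdname read_counts_biom
#' @param counts Wide count table.
#' @export
write_counts_biom <- function(counts, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the biomformat package is required for BIOM i/o.")
  }
  m <- count_matrix(counts)
  b <- biomformat::make_biom(t(m))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a metadata TSV and coerces the standard cohort columns
#' (`diagnosis`, `time_point`, `sex`) to factors with the levels used
#' throughout the package.
#'
#' @param path File path.
#' @return Metadata tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("diagnosis" %in% names(x)) {
    x$diagnosis <- factor(x$diagnosis, levels = c("Control", "CD", "UC", "uIBD"))
  }
  if ("time_point" %in% names(x)) {
    x$time_point <- factor(x$time_point, levels = c("BL", "F1", "F2", "F3"))
  }
  if ("sex" %in% names(x)) x$sex <- factor(x$sex)
  tibble::as_tibble(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over reference taxa,
#' of the ratio of a sample's count to the taxon's geometric mean across
#' samples; the reference set is the taxa with strictly positive counts in
#' every sample. Factors are rescaled to geometric mean 1.
#'
#' @param counts Wide count table or matrix.
#' @param pseudo_reference If no taxon is positive in every sample, fall
#'   back to a pseudo-reference built from taxa positive in at least half of
#'   the samples (geometric mean over their positive entries). Off by
#'   default: the error message points at this flag.
#' @return Tibble with columns `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- count_matrix(counts)
  if (any(rowSums(m) == 0)) abort("every sample must have at least one nonzero taxon.")
  all_pos <- colSums(m > 0) == nrow(m)
  if (!any(all_pos) && !pseudo_reference) {
    abort(paste(
      "no taxon has strictly positive counts in every sample;",
      "rerun with `pseudo_reference = TRUE` to use a pseudo-reference."
    ))
  }
  if (any(all_pos)) {
    ref <- m[, all_pos, drop = FALSE]
    geo <- exp(colMeans(log(ref)))
    ratios <- sweep(ref, 2, geo, `/`)
  } else {
    keep <- colSums(m > 0) >= nrow(m) / 2
    if (!any(keep)) abort("too many zeros: no usable reference taxa.")
    ref <- m[, keep, drop = FALSE]
    geo <- exp(apply(ref, 2, function(x) mean(log(x[x > 0]))))
    ratios <- sweep(ref, 2, geo, `/`)
    ratios[ref == 0] <- NA
  }
  sf <- apply(ratios, 1, median, na.rm = TRUE)
  sf <- sf / exp(mean(log(sf)))
  tibble::tibble(sample_id = rownames(m), size_factor = unname(sf))
}

#' Normalise a count table
#'
#' @param counts Wide count table or matrix.
#' @param method One of `"median_of_ratios"` (counts divided by
#'   median-of-ratios size factors), `"relative_abundance"` (rows sum to 1)
#'   or `"clr"` (centred log-ratio, see [clr_transform()]).
#' @param pseudocount Pseudocount for the CLR method.
#' @param ... Passed to [size_factors()].
#' @return Wide tibble of transformed values with attributes `method` and,
#'   for median-of-ratios, `size_factors`.
#' @export
normalize_counts <- function(counts,
                             method = c("median_of_ratios", "relative_abundance", "clr"),
                             pseudocount = 0.5, ...) {
  method <- match.arg(method)
  m <- count_matrix(counts)
  if (method == "median_of_ratios") {
    sf <- size_factors(m, ...)
    out <- sweep(m, 1, sf$size_factor, `/`)
    res <- count_tbl(out)
    attr(res, "size_factors") <- sf
  } else if (method == "relative_abundance") {
    tot <- rowSums(m)
    if (any(tot == 0)) warn("all-zero samples produce NaN relative abundances.")
    res <- count_tbl(sweep(m, 1, tot, `/`))
  } else {
    return(clr_transform(counts, pseudocount = pseudocount))
  }
  attr(res, "method") <- method
  res
}

#' Centred log-ratio transform
#'
#' Per sample, `clr_i = log(x_i + pc) - mean_k log(x_k + pc)`; each
#' transformed row sums to zero. With `pseudocount = 0` the transform is
#' invariant to per-sample rescaling of the counts, but requires strictly
#' positive entries.
#'
#' @param counts Wide count table or matrix.
#' @param pseudocount Non-negative value added to all counts before taking
#'   logs. Default 0.5 (half the smallest nonzero integer count).
#' @return Wide tibble of CLR values with attribute `method = "clr"`.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  m <- count_matrix(counts)
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  if (pseudocount == 0 && any(m == 0)) {
    abort("zero counts require a positive `pseudocount`.")
  }
  lx <- log(m + pseudocount)
  out <- lx - rowMeans(lx)
  res <- count_tbl(out)
  attr(res, "method") <- "clr"
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Prevalence filter on normalised counts
#'
#' Retains taxa whose median-of-ratios-normalised count reaches
#' `min_normalized_count` in at least `ceiling(min_sample_fraction * n)`
#' samples. The defaults (5 counts in 1% of samples) are the standard
#' pre-filter applied before differential abundance testing. The boundary is
#' inclusive on both thresholds.
#'
#' @param counts Wide count table or matrix.
#' @param min_normalized_count Minimum normalised count (default 5).
#' @param min_sample_fraction Minimum fraction of samples (default 0.01).
#' @param size_factors Optional precomputed size-factor tibble (as returned
#'   by [size_factors()]); computed from `counts` when `NULL`.
#' @return Filtered wide count tibble (same rows, subset of taxon columns).
#' @export
prevalence_filter <- function(counts, min_normalized_count = 5,
                              min_sample_fraction = 0.01,
                              size_factors = NULL) {
  if (min_normalized_count < 0 || min_sample_fraction < 0) {
    abort("filter thresholds must be non-negative.")
  }
  m <- count_matrix(counts)
  sf <- size_factors %||% microfam::size_factors(m, pseudo_reference = TRUE)
  sfv <- sf$size_factor[match(rownames(m), sf$sample_id)]
  norm <- sweep(m, 1, sfv, `/`)
  need <- ceiling(min_sample_fraction * nrow(m))
  keep <- colSums(norm >= min_normalized_count) >= need
  count_tbl(m[, keep, drop = FALSE])
}
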