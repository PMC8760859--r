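#' Median-of-ratios size factors
#'
#' Estimates one positive scaling factor per sample by the median-of-ratios
#' method: each sample's counts are divided by the per-feature geometric
#' mean across samples, the per-sample median of those ratios is taken over
#' the features that are positive in every sample, and the factors are then
#' rescaled to have geometric mean 1.
#'
#' @param counts A data frame with `feature_id` and one numeric column per
#'   sample (extra metadata columns `feature_type` and `length` are
#'   ignored), or a numeric matrix with feature row names.
#' @return Named numeric vector of size factors, geometric mean 1.
#' @examples
#' m <- tibble::tibble(feature_id = c("a", "b", "c"), s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors(m)
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("need at least two samples")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort(paste(
      "no feature has positive counts in every sample;",
      "median-of-ratios is undefined (a pseudo-reference fallback is not",
      "applied silently)"
    ))
  }
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  sf <- apply(m[all_pos, , drop = FALSE] / ref, 2, median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Normalize counts by size factors
#'
#' Divides each sample's raw counts by its median-of-ratios size factor.
#' This is the expression scale used for differential expression and
#' co-expression.
#'
#' @inheritParams size_factors
#' @param factors Optional precomputed size factors; computed from `counts`
#'   when missing.
#' @return A tibble in the same layout as `counts` (metadata columns kept)
#'   with normalized values, carrying attribute `unit = "normalized_count"`.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  m <- as_count_matrix(counts)
  factors <- factors %||% size_factors(counts)
  if (!setequal(names(factors), colnames(m))) {
    abort("`factors` names must match the sample columns")
  }
  norm <- sweep(m, 2, factors[colnames(m)], `/`)
  out <- rebuild_expression(counts, norm)
  attr(out, "unit") <- "normalized_count"
  out
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count * 1e9 / (length * per-sample total count)`, computed from
#' raw counts and feature lengths in bp. Provided for reporting parity with
#' assembler-derived abundance estimates; differential expression and
#' co-expression use normalized counts instead.
#'
#' @param counts A data frame with `feature_id`, a `length` column (bp), and
#'   one numeric column per sample.
#' @return A tibble in the same layout with FPKM values, attribute
#'   `unit = "FPKM"`.
#' @examples
#' x <- tibble::tibble(feature_id = "g", length = 1000L, s1 = 100)
#' fpkm(x)$s1 # 1e9 * 100 / (1000 * 100)
#' @export
fpkm <- function(counts) {
  assert_columns(counts, c("feature_id", "length"), "counts")
  if (any(counts$length < 1)) abort("feature `length` must be >= 1 bp")
  m <- as_count_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) abort("every sample must have total mapped counts > 0")
  vals <- sweep(m / counts$length * 1e9, 2, totals, `/`)
  out <- rebuild_expression(counts, vals)
  attr(out, "unit") <- "FPKM"
  out
}

# Internal: extract the numeric sample matrix from a counts tibble/matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) abort("count matrix needs feature row names")
    storage.mode(counts) <- "double"
    m <- counts
  } else {
    assert_columns(counts, "feature_id", "counts")
    meta <- intersect(names(counts), c("feature_id", "feature_type", "length"))
    m <- as.matrix(counts[setdiff(names(counts), meta)])
    rownames(m) <- counts$feature_id
  }
  if (anyDuplicated(rownames(m))) abort("duplicate feature ids")
  if (!is.numeric(m) || any(m < 0) || any(!is.finite(m))) {
    abort("counts must be finite and non-negative")
  }
  m
}

rebuild_expression <- function(counts, values) {
  if (is.matrix(counts)) {
    counts <- tibble::as_tibble(counts, rownames = "feature_id")
  }
  meta <- intersect(names(counts), c("feature_id", "feature_type", "length"))
  dplyr::bind_cols(counts[meta], tibble::as_tibble(values))
}
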