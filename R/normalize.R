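#' Median-of-ratios size factors
#'
#' The per-sample size factor is the median, across reference genes, of
#' the ratio of the gene's count in that sample to the gene's geometric
#' mean across all samples.  Reference genes are those with strictly
#' positive counts in every sample; genes with any zero count do not
#' enter the median.
#'
#' @param counts An [expression_set()] of raw counts, or a numeric
#'   genes-by-samples matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "expression_set")) counts$values else counts
  stopifnot(is.matrix(m), is.numeric(m))
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    snet_stop(paste0("no gene has all-positive counts; cannot form the ",
                     "geometric-mean reference (consider adding a ",
                     "pseudocount upstream)"),
              "saltnet_normalization_error")
  lm <- log(m[ref, , drop = FALSE])
  geo <- exp(rowMeans(lm))
  ratios <- m[ref, , drop = FALSE] / geo
  factors <- apply(ratios, 2L, stats::median)
  names(factors) <- colnames(m)
  factors
}

#' Size-factor normalization and log2 transform
#'
#' Prepares the correlation input: `log2(count / s_j + pseudocount)` with
#' per-sample size factor `s_j`.  Within each sample the transform is
#' strictly increasing, so gene ranks are preserved.
#'
#' @param counts An [expression_set()] of raw counts.
#' @param factors Named size-factor vector from
#'   [estimate_size_factors()]; computed if `NULL`.
#' @param pseudocount Positive offset before the log (default 1).
#' @return An [expression_set()] of normalized log2 abundances with the
#'   original sample metadata.
#' @export
normalize_counts <- function(counts, factors = NULL, pseudocount = 1) {
  stopifnot(inherits(counts, "expression_set"), pseudocount > 0)
  if (is.null(factors)) factors <- estimate_size_factors(counts)
  miss <- setdiff(colnames(counts$values), names(factors))
  if (length(miss))
    snet_stop("no size factor for sample(s): %s",
              "saltnet_normalization_error", paste(miss, collapse = ", "))
  if (any(factors <= 0))
    snet_stop("size factors must be positive",
              "saltnet_normalization_error")
  s <- factors[colnames(counts$values)]
  norm <- log2(sweep(counts$values, 2L, s, "/") + pseudocount)
  expression_set(norm, counts$samples)
}
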