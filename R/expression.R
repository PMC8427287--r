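#' Expression set: genes-by-samples matrix with sample metadata
#'
#' Container pairing a non-negative numeric matrix (genes in rows, samples
#' in columns) with a sample sheet assigning each sample a condition state
#' (`"normal"` or `"stress"`), a free-text stage label and a replicate
#' number.
#'
#' @param values Numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids).
#' @param samples Data frame with columns `sample_id`, `state`, `stage`,
#'   `replicate`; every column of `values` must appear exactly once.
#'
#' @return An object of class `expression_set`: a list with elements
#'   `values` (the matrix) and `samples` (the sample sheet, ordered to
#'   match the matrix columns).
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    snet_stop("`values` must be a numeric matrix", "saltnet_format_error")
  gene_ids <- rownames(values)
  if (is.null(gene_ids) && nrow(values) == 0L) gene_ids <- character(0)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    snet_stop("`values` must carry gene rownames and sample colnames",
              "saltnet_format_error")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    snet_stop("duplicate gene id(s): %s", "saltnet_format_error",
              paste(unique(dup), collapse = ", "))
  if (anyDuplicated(sample_ids))
    snet_stop("duplicate sample id(s) in matrix", "saltnet_format_error")
  req <- c("sample_id", "state", "stage", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    snet_stop("sample sheet lacks column(s): %s", "saltnet_format_error",
              paste(miss, collapse = ", "))
  absent <- setdiff(sample_ids, samples$sample_id)
  if (length(absent))
    snet_stop("sample(s) in matrix absent from sample sheet: %s",
              "saltnet_format_error", paste(absent, collapse = ", "))
  samples <- samples[match(sample_ids, samples$sample_id), req, drop = FALSE]
  rownames(samples) <- NULL
  bad_state <- setdiff(unique(samples$state), c("normal", "stress"))
  if (length(bad_state))
    snet_stop("unknown state label(s): %s (expected normal/stress)",
              "saltnet_format_error", paste(bad_state, collapse = ", "))
  if (any(!is.finite(values)))
    snet_stop("expression values must all be finite", "saltnet_format_error")
  structure(list(values = values, samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  st <- table(x$samples$state)
  cat(sprintf("expression_set: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Sample ids carrying a given state
#' @param x An `expression_set`.
#' @param state `"normal"` or `"stress"`.
#' @return Character vector of sample ids.
#' @export
state_samples <- function(x, state) {
  stopifnot(inherits(x, "expression_set"))
  x$samples$sample_id[x$samples$state == state]
}

#' Combine the two single-state matrices into one expression set
#'
#' The per-state generator returns one matrix per condition; downstream
#' functions take a single set holding both.  Gene panels must be
#' identical and in identical order; sample ids must not collide.
#'
#' @param normal,stress `expression_set` objects, one state each.
#' @return A combined `expression_set`.
#' @export
combine_states <- function(normal, stress) {
  stopifnot(inherits(normal, "expression_set"),
            inherits(stress, "expression_set"))
  if (!identical(rownames(normal$values), rownames(stress$values)))
    snet_stop("gene panels differ between the two states",
              "saltnet_contract_error")
  if (length(intersect(colnames(normal$values), colnames(stress$values))))
    snet_stop("sample ids collide between the two states",
              "saltnet_contract_error")
  expression_set(cbind(normal$values, stress$values),
                 rbind(normal$samples, stress$samples))
}

#' Restrict an expression set to a gene list
#'
#' Typical use: restrict the panel to differentially expressed genes
#' identified by an upstream count-based test before building networks.
#'
#' @param x An `expression_set`.
#' @param genes Character vector of gene ids to keep; ids absent from the
#'   panel are dropped with a warning.
#' @return The restricted `expression_set`.
#' @export
restrict_genes <- function(x, genes) {
  stopifnot(inherits(x, "expression_set"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    snet_warn("%d gene id(s) not in the panel were ignored", length(missing))
  keep <- intersect(rownames(x$values), genes)
  expression_set(x$values[keep, , drop = FALSE], x$samples)
}
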