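#' Pearson correlation matrix over one condition's samples
#'
#' Correlates every gene pair using only the samples assigned the
#' requested state.  Genes with zero variance in those samples cannot be
#' correlated; by convention their correlations (including the diagonal)
#' are set to 0 and a warning reports how many genes were affected.
#'
#' @param expr An [expression_set()] (normalized log abundances).
#' @param state `"normal"` or `"stress"`.
#' @return List of class `correlation_matrix`: `gene_ids`, `r` (symmetric
#'   matrix, unit diagonal for non-degenerate genes), `n_samples`,
#'   `state`.
#' @export
correlation_matrix <- function(expr, state) {
  stopifnot(inherits(expr, "expression_set"))
  ids <- state_samples(expr, state)
  if (length(ids) < 3L)
    snet_stop("state '%s' has %d sample(s); >= 3 required to correlate",
              "saltnet_insufficient_data_error", state, length(ids))
  m <- expr$values[, ids, drop = FALSE]
  if (nrow(m) == 0L)
    return(structure(list(gene_ids = character(),
                          r = matrix(numeric(), 0L, 0L),
                          n_samples = length(ids), state = state),
                     class = "correlation_matrix"))
  sds <- apply(m, 1L, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(t(m)))
  if (any(flat)) {
    snet_warn("%d zero-variance gene(s) in state '%s'; correlations set to 0",
              sum(flat), state)
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r)[!flat] <- 1
  structure(list(gene_ids = rownames(expr$values), r = r,
                 n_samples = length(ids), state = state),
            class = "correlation_matrix")
}

#' Build one state's co-expression network from correlations
#'
#' Edges join gene pairs whose correlation passes the threshold:
#' `r >= threshold` in `"signed"` mode (the default selection rule) or
#' `|r| >= threshold` in `"absolute"` mode.  The comparison is inclusive.
#' Edge weights are absolute correlations; by default only
#' supra-threshold edges keep their weight, so the binary and weighted
#' graphs share one topology (`dense_weights = TRUE` keeps every `|r|`
#' instead).
#'
#' @param corr A [correlation_matrix()].
#' @param edge_threshold Correlation cutoff in (0, 1]; default 0.9.
#' @param edge_mode `"signed"` or `"absolute"`.
#' @param dense_weights Keep sub-threshold `|r|` as weights too.
#' @return Object of class `state_network`: `state`, `gene_ids`,
#'   `adjacency` (0/1 matrix, zero diagonal), `weights` (|r| in [0,1],
#'   zero diagonal), `edge_threshold`, `edge_mode`.
#' @export
build_state_network <- function(corr, edge_threshold = 0.9,
                                edge_mode = c("signed", "absolute"),
                                dense_weights = FALSE) {
  stopifnot(inherits(corr, "correlation_matrix"))
  edge_mode <- match.arg(edge_mode)
  if (!(edge_threshold > 0 && edge_threshold <= 1))
    snet_stop("edge_threshold must lie in (0, 1]", "saltnet_config_error")
  r <- corr$r
  a <- if (edge_mode == "signed") r >= edge_threshold else
    abs(r) >= edge_threshold
  diag(a) <- FALSE
  w <- if (dense_weights) abs(r) else abs(r) * a
  diag(w) <- 0
  state_network(adjacency = a * 1, weights = w, state = corr$state,
                edge_threshold = edge_threshold, edge_mode = edge_mode)
}

#' Construct a state network from explicit adjacency and weights
#'
#' Low-level constructor used by [build_state_network()] and by tests
#' that pose a graph directly (e.g. a hand-drawn topology).
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal; dimnames
#'   give the gene ids.
#' @param weights Symmetric matrix in `[0, 1]` with zero diagonal; every
#'   binary edge must carry positive weight.  Defaults to `adjacency`
#'   (unit weights).
#' @param state Condition label.
#' @param edge_threshold,edge_mode Provenance of the edge rule (purely
#'   descriptive here).
#' @return A `state_network`.
#' @export
state_network <- function(adjacency, weights = NULL, state = "stress",
                          edge_threshold = NA_real_,
                          edge_mode = "signed") {
  a <- as.matrix(adjacency) * 1
  if (nrow(a) != ncol(a) || !isTRUE(all.equal(a, t(a))))
    snet_stop("adjacency must be square and symmetric",
              "saltnet_contract_error")
  if (any(diag(a) != 0))
    snet_stop("adjacency diagonal must be zero", "saltnet_contract_error")
  if (!all(a %in% c(0, 1)))
    snet_stop("adjacency entries must be 0/1", "saltnet_contract_error")
  if (is.null(weights)) weights <- a
  w <- as.matrix(weights)
  if (!identical(dim(w), dim(a)))
    snet_stop("weights and adjacency dimensions differ",
              "saltnet_contract_error")
  if (any(w < 0) || any(w > 1))
    snet_stop("weights must lie in [0, 1]", "saltnet_domain_error")
  if (any(diag(w) != 0))
    snet_stop("weight diagonal must be zero", "saltnet_contract_error")
  if (any(a == 1 & w <= 0))
    snet_stop("every binary edge must carry positive weight",
              "saltnet_contract_error")
  ids <- rownames(a) %||% sprintf("n%03d", seq_len(nrow(a)))
  dimnames(a) <- dimnames(w) <- list(ids, ids)
  structure(list(state = state, gene_ids = ids, adjacency = a,
                 weights = w, edge_threshold = edge_threshold,
                 edge_mode = edge_mode),
            class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat(sprintf("state_network [%s]: %d genes, %d edges (threshold %s, %s)\n",
              x$state, length(x$gene_ids), sum(x$adjacency) / 2,
              format(x$edge_threshold), x$edge_mode))
  invisible(x)
}

#' Build the normal-state and stress-state networks from one matrix
#'
#' Splits the samples by state, correlates each state separately, and
#' thresholds each correlation matrix into a network over the shared
#' gene panel.
#'
#' @inheritParams build_state_network
#' @param expr An [expression_set()] holding both states' samples.
#' @return Named list with `normal` and `stress` `state_network`s.
#' @export
build_two_state_networks <- function(expr, edge_threshold = 0.9,
                                     edge_mode = c("signed", "absolute"),
                                     dense_weights = FALSE) {
  edge_mode <- match.arg(edge_mode)
  nets <- lapply(c(normal = "normal", stress = "stress"), function(st)
    build_state_network(correlation_matrix(expr, st),
                        edge_threshold = edge_threshold,
                        edge_mode = edge_mode,
                        dense_weights = dense_weights))
  nets
}

#' Serialize a network as an edge-list TSV
#' @param net A `state_network`.
#' @param path Output path; columns gene_a, gene_b, weight (one row per
#'   undirected edge, gene_a < gene_b lexicographically).
#' @return Invisibly, the edge data frame.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "state_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1,
               arr.ind = TRUE)
  df <- data.frame(gene_a = net$gene_ids[idx[, 1L]],
                   gene_b = net$gene_ids[idx[, 2L]],
                   weight = net$weights[idx])
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
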