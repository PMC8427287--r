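#' Node degree
#'
#' Number of edges incident to each gene in the binary network.
#'
#' @param net A `state_network`.
#' @param genes Gene ids to report (default: all, in panel order).
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(net, genes = NULL) {
  stopifnot(inherits(net, "state_network"))
  k <- as.integer(rowSums(net$adjacency))
  names(k) <- net$gene_ids
  pick_genes(k, net, genes)
}

#' Watts-Strogatz clustering coefficient
#'
#' For gene *i* with neighbors N(i) and degree k_i, the coefficient is
#' the ordered-pair sum of closed triples over its neighbors,
#' `C(i) = sum_{j, q != j} a_ij a_iq a_jq / (k_i (k_i - 1))`, i.e. the
#' fraction of realized links among the neighbors of *i*.  `C(i)` lies in
#' `[0, 1]`; nodes with fewer than two neighbors have an undefined
#' denominator and return 0 by convention.
#'
#' @inheritParams node_degree
#' @return Named numeric vector of coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, genes = NULL) {
  stopifnot(inherits(net, "state_network"))
  a <- net$adjacency
  k <- rowSums(a)
  # ordered closed triples at i = (A^3)_ii = sum_j A_ij (A^2)_ij (A symmetric)
  closed <- rowSums(a * (a %*% a))
  cc <- ifelse(k >= 2, closed / (k * (k - 1)), 0)
  names(cc) <- net$gene_ids
  pick_genes(cc, net, genes)
}

#' Weighted degree
#'
#' Sum of the weights of all edges incident to each gene.
#'
#' @inheritParams node_degree
#' @return Named numeric vector.
#' @export
weighted_degree <- function(net, genes = NULL) {
  stopifnot(inherits(net, "state_network"))
  wd <- rowSums(net$weights)
  names(wd) <- net$gene_ids
  pick_genes(wd, net, genes)
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' Generalizes the clustering coefficient to weighted graphs by scoring
#' each closed triple with the geometric mean of its three edge weights:
#' `C_w(i) = sum_{j, q != j} |w_ij w_iq w_jq|^{1/3} / (k_i (k_i - 1))`,
#' where k_i counts the neighbors connected to *i* by nonzero weight.
#' With all weights at most 1 the value lies in `[0, 1]`, and with all
#' weights exactly 1 it reduces to the binary coefficient.  Nodes with
#' fewer than two weighted neighbors return 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector of coefficients in `[0, 1]`.
#' @export
weighted_clustering_coefficient <- function(net, genes = NULL) {
  stopifnot(inherits(net, "state_network"))
  if (any(abs(net$weights) > 1))
    snet_stop("edge weights exceed 1; the [0,1] range guarantee breaks",
              "saltnet_domain_error")
  cw <- abs(net$weights)^(1 / 3)
  k <- rowSums(net$weights != 0)
  # ordered weighted closed triples at i = (W'^3)_ii, W' = cube-root weights
  closed <- rowSums(cw * (cw %*% cw))
  wcc <- ifelse(k >= 2, closed / (k * (k - 1)), 0)
  names(wcc) <- net$gene_ids
  pick_genes(wcc, net, genes)
}

pick_genes <- function(v, net, genes) {
  if (is.null(genes)) return(v)
  unknown <- setdiff(genes, net$gene_ids)
  if (length(unknown))
    snet_stop("gene(s) not in network: %s", "saltnet_lookup_error",
              paste(unknown, collapse = ", "))
  v[genes]
}

#' Per-gene, per-state metrics table
#'
#' Assembles all four centrality surfaces (degree, clustering
#' coefficient, weighted degree, weighted clustering coefficient) for
#' both condition networks into one long-format table, one row per gene
#' per state, genes in panel order within state.
#'
#' @param normal,stress `state_network`s over an identical gene panel.
#' @return Data frame of class `node_metrics` with columns `gene_id`,
#'   `state`, `degree`, `cc`, `wdegree`, `wcc`.
#' @export
node_metrics <- function(normal, stress) {
  stopifnot(inherits(normal, "state_network"),
            inherits(stress, "state_network"))
  if (!identical(normal$gene_ids, stress$gene_ids))
    snet_stop("the two networks must share one gene panel",
              "saltnet_contract_error")
  one <- function(net) data.frame(
    gene_id = net$gene_ids,
    state = rep(net$state, length(net$gene_ids)),
    degree = unname(node_degree(net)),
    cc = unname(clustering_coefficient(net)),
    wdegree = unname(weighted_degree(net)),
    wcc = unname(weighted_clustering_coefficient(net)))
  out <- rbind(one(normal), one(stress))
  rownames(out) <- NULL
  structure(out, class = c("node_metrics", "data.frame"))
}

#' Write a metrics table as TSV
#' @param metrics A `node_metrics` data frame.
#' @param path Output path.
#' @return Invisibly, `metrics`.
#' @export
write_node_metrics <- function(metrics, path) {
  utils::write.table(as.data.frame(metrics), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(metrics)
}
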