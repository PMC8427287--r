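#' Differential centrality selection for one surface
#'
#' Selects genes whose network centrality is high under stress and low
#' under normal conditions, on one of the three surfaces: `gcn_degree`
#' (binary degree), `cc` (clustering coefficient) or `wgcn` (weighted
#' degree by default, weighted clustering coefficient via `wgcn_rank`).
#'
#' Three explicit rules are offered, since "high under stress, low under
#' normal" needs a numeric definition to be reproducible:
#' * `percentile` (default): keep genes with stress metric at or above
#'   the `stress_min_percentile` of the stress-state distribution AND
#'   normal metric at or below the `normal_max_percentile` of the
#'   normal-state distribution (empirical quantiles, type 7).
#' * `threshold`: absolute cutoffs `stress_min_value` /
#'   `normal_max_value`.
#' * `top_k`: the `k` largest values of (stress - normal), ties broken
#'   lexicographically by gene id.
#'
#' @param metrics A [node_metrics()] table holding both states.
#' @param method `"gcn_degree"`, `"cc"` or `"wgcn"`.
#' @param mode `"percentile"`, `"threshold"` or `"top_k"`.
#' @param stress_min_percentile,normal_max_percentile Percentiles in
#'   (0, 100) for `percentile` mode (defaults 90 and 50).
#' @param stress_min_value,normal_max_value Cutoffs for `threshold`
#'   mode.
#' @param k Set size for `top_k` mode.
#' @param wgcn_rank Surface used by the `wgcn` method: `"wdegree"`
#'   (default) or `"wcc"`.
#' @return Sorted character vector of selected gene ids.
#' @export
select_differential <- function(metrics,
                                method = c("gcn_degree", "cc", "wgcn"),
                                mode = c("percentile", "threshold", "top_k"),
                                stress_min_percentile = 90,
                                normal_max_percentile = 50,
                                stress_min_value = NULL,
                                normal_max_value = NULL,
                                k = NULL,
                                wgcn_rank = c("wdegree", "wcc")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  wgcn_rank <- match.arg(wgcn_rank)
  surface <- switch(method, gcn_degree = "degree", cc = "cc",
                    wgcn = wgcn_rank)
  if (nrow(metrics) == 0L) return(character())
  for (st in c("normal", "stress"))
    if (!any(metrics$state == st))
      snet_stop("metrics table has no '%s' rows", "saltnet_contract_error",
                st)
  nm <- metrics[metrics$state == "normal", , drop = FALSE]
  st <- metrics[metrics$state == "stress", , drop = FALSE]
  if (!setequal(nm$gene_id, st$gene_id))
    snet_stop("normal and stress rows cover different gene panels",
              "saltnet_contract_error")
  st <- st[match(nm$gene_id, st$gene_id), , drop = FALSE]
  genes <- nm$gene_id
  x_n <- nm[[surface]]
  x_s <- st[[surface]]
  sel <- switch(mode,
    percentile = {
      stopifnot(stress_min_percentile > 0, stress_min_percentile < 100,
                normal_max_percentile > 0, normal_max_percentile < 100)
      cut_s <- stats::quantile(x_s, stress_min_percentile / 100,
                               names = FALSE)
      cut_n <- stats::quantile(x_n, normal_max_percentile / 100,
                               names = FALSE)
      genes[x_s >= cut_s & x_n <= cut_n]
    },
    threshold = {
      if (is.null(stress_min_value) || is.null(normal_max_value))
        snet_stop("threshold mode needs stress_min_value and normal_max_value",
                  "saltnet_config_error")
      genes[x_s >= stress_min_value & x_n <= normal_max_value]
    },
    top_k = {
      if (is.null(k) || !is_count(k))
        snet_stop("top_k mode needs a positive integer k",
                  "saltnet_config_error")
      if (k > length(genes))
        snet_stop("k = %d exceeds the %d-gene panel",
                  "saltnet_config_error", k, length(genes))
      ord <- order(-(x_s - x_n), genes)
      genes[ord[seq_len(k)]]
    })
  sort(sel)
}

#' The three method-specific candidate gene sets
#'
#' Bundle of the GCN (degree), CC (clustering coefficient) and WGCN
#' (weighted network) candidate sets over one shared gene panel.
#'
#' @param gcn,cc,wgcn Character vectors of gene ids.
#' @return Object of class `candidate_sets` (a list of three sorted,
#'   de-duplicated character vectors).
#' @export
candidate_sets <- function(gcn = character(), cc = character(),
                           wgcn = character()) {
  structure(list(gcn = sort(unique(as.character(gcn))),
                 cc = sort(unique(as.character(cc))),
                 wgcn = sort(unique(as.character(wgcn)))),
            class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat(sprintf("candidate_sets: GCN %d, CC %d, WGCN %d (union %d)\n",
              length(x$gcn), length(x$cc), length(x$wgcn),
              length(unique(c(x$gcn, x$cc, x$wgcn)))))
  invisible(x)
}

#' Apply the differential selection to all three surfaces
#'
#' @param metrics A [node_metrics()] table.
#' @param gcn_params,cc_params,wgcn_params Named lists of arguments
#'   forwarded to [select_differential()] for each method (e.g.
#'   `list(mode = "top_k", k = 20)`); empty lists use the defaults.
#' @return A [candidate_sets()] object.
#' @export
select_all_methods <- function(metrics, gcn_params = list(),
                               cc_params = list(),
                               wgcn_params = list()) {
  run <- function(method, params)
    do.call(select_differential,
            c(list(metrics = metrics, method = method), params))
  candidate_sets(gcn = run("gcn_degree", gcn_params),
                 cc = run("cc", cc_params),
                 wgcn = run("wgcn", wgcn_params))
}
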