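#' Fit the two-state differential co-expression analysis
#'
#' End-to-end analysis: median-of-ratios normalization, per-condition
#' co-expression networks at the correlation threshold, the four node
#' centrality surfaces, differential (stress-high / normal-low)
#' candidate selection on each surface, the Venn partition of the three
#' sets, and — when variant and positional evidence are supplied — the
#' SNP filter and the QTL-interval filter yielding the final prioritized
#' genes.
#'
#' @param counts An [expression_set()] of raw counts holding samples of
#'   both states (set `normalize = FALSE` if the matrix is already
#'   normalized/log-transformed).
#' @param gene_list Optional character vector restricting the panel
#'   (e.g. differentially expressed genes from an upstream count test).
#' @param normalize Apply [normalize_counts()] before correlating.
#' @param pseudocount Offset for the log2 transform.
#' @param edge_threshold Correlation cutoff for edges (default 0.9).
#' @param edge_mode `"signed"` (edge iff r >= threshold) or
#'   `"absolute"` (edge iff |r| >= threshold).
#' @param dense_weights Keep sub-threshold `|r|` as weights (see
#'   [build_state_network()]).
#' @param gcn_params,cc_params,wgcn_params Selection parameters per
#'   method, forwarded to [select_differential()].
#' @param snps Optional `snp_table` for the SNP-evidence filter.
#' @param snp_region_classes Optional restriction of SNP evidence to
#'   chosen region classes.
#' @param annotation,interval Optional `gene_annotation` and
#'   [genomic_interval()] for the positional filter.
#' @param interval_mode `"overlap"` or `"within"`.
#' @return Object of class `saltnet`: a list with `expr` (normalized),
#'   `size_factors`, `networks` (normal/stress), `metrics`,
#'   `candidates`, `venn`, `snp_filtered` (or NULL), `final_genes`
#'   (after every supplied filter), and `params`.
#' @examples
#' sim <- simulate_two_state_expression(sim_config(n_genes = 120,
#'   n_modules = 3, module_size = 10, n_planted = 10, seed = 7))
#' fit <- saltnet(combine_states(sim$normal, sim$stress))
#' summary(fit)
#' @export
saltnet <- function(counts,
                    gene_list = NULL,
                    normalize = TRUE,
                    pseudocount = 1,
                    edge_threshold = 0.9,
                    edge_mode = c("signed", "absolute"),
                    dense_weights = FALSE,
                    gcn_params = list(),
                    cc_params = list(),
                    wgcn_params = list(),
                    snps = NULL,
                    snp_region_classes = NULL,
                    annotation = NULL,
                    interval = NULL,
                    interval_mode = c("overlap", "within")) {
  stopifnot(inherits(counts, "expression_set"))
  edge_mode <- match.arg(edge_mode)
  interval_mode <- match.arg(interval_mode)
  if (!is.null(gene_list)) counts <- restrict_genes(counts, gene_list)
  size_factors <- NULL
  expr <- counts
  if (normalize) {
    size_factors <- estimate_size_factors(counts)
    expr <- normalize_counts(counts, size_factors,
                             pseudocount = pseudocount)
  }
  nets <- build_two_state_networks(expr, edge_threshold = edge_threshold,
                                   edge_mode = edge_mode,
                                   dense_weights = dense_weights)
  metrics <- node_metrics(nets$normal, nets$stress)
  candidates <- select_all_methods(metrics, gcn_params = gcn_params,
                                   cc_params = cc_params,
                                   wgcn_params = wgcn_params)
  venn <- venn_partition(candidates)
  snp_filtered <- NULL
  final_genes <- sort(unique(c(candidates$gcn, candidates$cc,
                               candidates$wgcn)))
  if (!is.null(snps)) {
    snp_filtered <- filter_by_snp(candidates, snps,
                                  region_classes = snp_region_classes)
    final_genes <- snp_filtered$combined
  }
  if (!is.null(annotation) && !is.null(interval))
    final_genes <- filter_by_interval(final_genes, annotation, interval,
                                      mode = interval_mode)
  structure(list(
    expr = expr,
    size_factors = size_factors,
    networks = nets,
    metrics = metrics,
    candidates = candidates,
    venn = venn,
    snp_filtered = snp_filtered,
    final_genes = final_genes,
    params = list(normalize = normalize, pseudocount = pseudocount,
                  edge_threshold = edge_threshold, edge_mode = edge_mode,
                  dense_weights = dense_weights,
                  gcn_params = gcn_params, cc_params = cc_params,
                  wgcn_params = wgcn_params,
                  snp_region_classes = snp_region_classes,
                  interval_mode = interval_mode,
                  snp_filter = !is.null(snps),
                  interval_filter = !is.null(annotation) &&
                    !is.null(interval))),
    class = "saltnet")
}

#' @export
print.saltnet <- function(x, ...) {
  cat("saltnet two-state co-expression fit\n")
  cat(sprintf("  genes: %d, edge rule: %s r >= %s\n",
              nrow(x$expr$values), x$params$edge_mode,
              format(x$params$edge_threshold)))
  cat(sprintf("  edges: normal %d, stress %d\n",
              sum(x$networks$normal$adjacency) / 2,
              sum(x$networks$stress$adjacency) / 2))
  print(x$candidates)
  if (x$params$snp_filter)
    cat(sprintf("  SNP-supported candidates: %d\n",
                length(x$snp_filtered$combined)))
  cat(sprintf("  final prioritized genes: %d\n", length(x$final_genes)))
  invisible(x)
}

#' @export
summary.saltnet <- function(object, ...) {
  x <- object
  counts <- c(
    genes = nrow(x$expr$values),
    edges_normal = sum(x$networks$normal$adjacency) / 2,
    edges_stress = sum(x$networks$stress$adjacency) / 2,
    gcn = length(x$candidates$gcn),
    cc = length(x$candidates$cc),
    wgcn = length(x$candidates$wgcn),
    union = x$venn$union_size,
    snp_supported = if (x$params$snp_filter)
      length(x$snp_filtered$combined) else NA_integer_,
    final = length(x$final_genes))
  out <- list(counts = counts,
              venn = vapply(x$venn$regions, length, integer(1L)),
              final_genes = x$final_genes,
              params = x$params)
  class(out) <- "summary.saltnet"
  out
}

#' @export
print.summary.saltnet <- function(x, ...) {
  cat("Stage counts:\n")
  print(x$counts)
  cat("Venn regions:\n")
  print(x$venn)
  cat("Final genes:", if (length(x$final_genes))
    paste(x$final_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Plot method: per-gene degree under stress versus normal
#'
#' Scatter of each gene's stress-state degree against its normal-state
#' degree; the final prioritized genes are highlighted.  Genes above the
#' diagonal gained connectivity under stress.
#'
#' @param x A `saltnet` fit.
#' @param surface Metric to plot: `"degree"`, `"cc"`, `"wdegree"` or
#'   `"wcc"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.saltnet <- function(x, surface = c("degree", "wdegree", "cc", "wcc"),
                         ...) {
  surface <- match.arg(surface)
  nm <- x$metrics[x$metrics$state == "normal", , drop = FALSE]
  st <- x$metrics[x$metrics$state == "stress", , drop = FALSE]
  st <- st[match(nm$gene_id, st$gene_id), , drop = FALSE]
  hi <- nm$gene_id %in% x$final_genes
  graphics::plot(nm[[surface]], st[[surface]],
                 xlab = paste("normal", surface),
                 ylab = paste("stress", surface),
                 col = ifelse(hi, "firebrick", grDevices::grey(0.55)),
                 pch = ifelse(hi, 19, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

#' JSON run summary of a fit
#'
#' Serializes every stage count and every parameter of a fit as a
#' deterministic (alphabetically keyed) JSON document.
#'
#' @param fit A `saltnet` fit.
#' @param path Output JSON path.
#' @return Invisibly, the summary list.
#' @export
write_run_summary <- function(fit, path) {
  stopifnot(inherits(fit, "saltnet"))
  s <- summary(fit)
  doc <- list(
    counts = as.list(s$counts),
    venn_regions = as.list(s$venn),
    final_genes = fit$final_genes,
    snp_region_breakdown = if (fit$params$snp_filter)
      as.list(fit$snp_filtered$region_breakdown) else NULL,
    params = fit$params[c("normalize", "pseudocount", "edge_threshold",
                          "edge_mode", "dense_weights", "interval_mode",
                          "snp_filter", "interval_filter")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(doc)
}

#' Run the full pipeline from a configuration file
#'
#' Reads every input named in a YAML configuration, runs [saltnet()],
#' and writes the intermediate tables (normalized matrix, edge lists,
#' metrics), the candidate table and the JSON run summary into the
#' output directory.  Reruns of one configuration are byte-identical.
#'
#' Recognized keys: `counts`, `samples` (paths, required); `gene_list`
#' (path to a one-column text file); `snps`, `annotation` (paths);
#' `interval` (string `chrom:start-end`); `out_dir` (default `"."`);
#' plus the scalar parameters of [saltnet()] (`edge_threshold`,
#' `edge_mode`, `pseudocount`, ...) and nested `gcn_params`/`cc_params`/
#' `wgcn_params` lists.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The `saltnet` fit, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("counts", "samples"))
    if (is.null(cfg[[key]]))
      snet_stop("config lacks required key '%s'", "saltnet_config_error",
                key)
  counts <- read_expression_matrix(cfg$counts, cfg$samples)
  gene_list <- if (!is.null(cfg$gene_list)) readLines(cfg$gene_list)
  snps <- if (!is.null(cfg$snps)) read_snp_table(cfg$snps)
  annotation <- if (!is.null(cfg$annotation))
    read_gene_annotation(cfg$annotation)
  interval <- if (!is.null(cfg$interval)) parse_interval(cfg$interval)
  fit <- saltnet(counts,
                 gene_list = gene_list,
                 normalize = cfg$normalize %||% TRUE,
                 pseudocount = cfg$pseudocount %||% 1,
                 edge_threshold = cfg$edge_threshold %||% 0.9,
                 edge_mode = cfg$edge_mode %||% "signed",
                 dense_weights = cfg$dense_weights %||% FALSE,
                 gcn_params = cfg$gcn_params %||% list(),
                 cc_params = cfg$cc_params %||% list(),
                 wgcn_params = cfg$wgcn_params %||% list(),
                 snps = snps,
                 snp_region_classes = cfg$snp_region_classes,
                 annotation = annotation,
                 interval = interval,
                 interval_mode = cfg$interval_mode %||% "overlap")
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_expression_matrix(fit$expr, p("normalized.tsv"), p("samples.tsv"))
  write_network(fit$networks$normal, p("network_normal.tsv"))
  write_network(fit$networks$stress, p("network_stress.tsv"))
  write_node_metrics(fit$metrics, p("metrics.tsv"))
  write_candidates(fit$candidates, fit$metrics, p("candidates.tsv"))
  writeLines(fit$final_genes, p("final_genes.txt"))
  write_run_summary(fit, p("run_summary.json"))
  invisible(fit)
}
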