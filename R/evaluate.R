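#' Recovery of planted hub genes across simulation replicates
#'
#' Runs the whole analysis on freshly simulated data for each seed and
#' scores the union of the three candidate sets against the planted
#' ground truth.  This is the package's self-check that the differential
#' selection recovers condition-specific hubs it should recover.
#'
#' @param config A [sim_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds Integer vector of simulation seeds.
#' @param ... Further arguments passed to [saltnet()] (selection
#'   parameters, edge rule, ...).
#' @return Data frame with one row per seed: `seed`, `n_selected`,
#'   `recall`, `precision`.
#' @export
planted_recovery <- function(config = sim_config(), seeds = 1:10, ...) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    sim <- simulate_two_state_expression(cfg)
    fit <- saltnet(combine_states(sim$normal, sim$stress), ...)
    sel <- unique(c(fit$candidates$gcn, fit$candidates$cc,
                    fit$candidates$wgcn))
    planted <- sim$truth$planted_gene_ids
    tp <- length(intersect(sel, planted))
    data.frame(seed = s, n_selected = length(sel),
               recall = tp / length(planted),
               precision = if (length(sel)) tp / length(sel) else NA_real_)
  })
  do.call(rbind, rows)
}
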