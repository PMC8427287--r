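#' Configuration for the two-condition synthetic expression generator
#'
#' The generator emulates the data structure the two-state network
#' comparison assumes: genes organized in co-expression modules, a subset
#' of "planted" genes whose module correlation is active only under
#' stress, and negative-binomial count noise around a log-normal signal.
#'
#' Correlation is induced through a per-module latent factor: a member
#' gene's log-expression is `sqrt(rho) * factor + sqrt(1 - rho) * noise`,
#' so `rho` is the pairwise correlation of the latent log signal.
#' Planted genes use `rho_on` under stress and `rho_off` under normal;
#' non-planted module genes use `rho_on` in both states; genes outside
#' modules are independent noise.
#'
#' @param n_genes Total genes.
#' @param n_samples_per_state Samples per condition (>= 4).
#' @param n_modules,module_size Module layout; module genes are the first
#'   `n_modules * module_size` gene ids.
#' @param n_planted Number of planted differential-hub genes (the first
#'   `n_planted` gene ids); must not exceed `n_modules * module_size`.
#' @param rho_on Module correlation when active, in (0, 1).
#' @param rho_off Background correlation for planted genes under normal,
#'   in `[0, rho_on)`.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param mean_log_expression Mean of natural-log expression.
#' @param sd_log_expression Standard deviation of the latent natural-log
#'   signal across samples.
#' @param snp_fraction_planted,snp_fraction_background Probability that a
#'   planted (resp. background) gene carries at least one SNP record in
#'   the simulated variant table.
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration including the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600L,
                       n_samples_per_state = 30L,
                       n_modules = 10L,
                       module_size = 20L,
                       n_planted = 30L,
                       rho_on = 0.95,
                       rho_off = 0,
                       nb_dispersion = 0.005,
                       mean_log_expression = 7,
                       sd_log_expression = 1.5,
                       snp_fraction_planted = 0.5,
                       snp_fraction_background = 0.05,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_state = as.integer(n_samples_per_state),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              n_planted = as.integer(n_planted),
              rho_on = rho_on, rho_off = rho_off,
              nb_dispersion = nb_dispersion,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              snp_fraction_planted = snp_fraction_planted,
              snp_fraction_background = snp_fraction_background,
              seed = as.integer(seed))
  if (cfg$n_samples_per_state < 4L)
    snet_stop("n_samples_per_state must be >= 4", "saltnet_config_error")
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    snet_stop("module layout exceeds n_genes", "saltnet_config_error")
  if (cfg$n_planted > cfg$n_modules * cfg$module_size)
    snet_stop("n_planted exceeds the module gene count",
              "saltnet_config_error")
  if (!(cfg$rho_on > 0 && cfg$rho_on < 1))
    snet_stop("rho_on must lie in (0, 1)", "saltnet_config_error")
  if (cfg$rho_off < 0 || cfg$rho_off >= cfg$rho_on)
    snet_stop("rho_off must lie in [0, rho_on)", "saltnet_config_error")
  if (cfg$nb_dispersion <= 0)
    snet_stop("nb_dispersion must be positive", "saltnet_config_error")
  for (f in c("snp_fraction_planted", "snp_fraction_background"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      snet_stop("%s must lie in [0, 1]", "saltnet_config_error", f)
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# latent log-signal matrix for one state, genes x samples.
# Correlations are planted in the empirical sense: the module factor is
# standardized to unit sample variance and each gene's noise vector is
# residualized against it, so the realized within-module Pearson
# correlation concentrates at rho (jitter O((1-rho)/sqrt(n))) instead of
# carrying the full Fisher sampling noise of an iid draw.  This is what
# makes edge formation at a correlation threshold predictable from rho.
sim_log_signal <- function(cfg, planted_rho) {
  n <- cfg$n_samples_per_state
  std <- function(v) {
    v <- v - mean(v)
    v / stats::sd(v)
  }
  sig <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  planted <- seq_len(cfg$n_planted)
  for (m in seq_len(cfg$n_modules)) {
    f <- std(stats::rnorm(n))
    idx <- ((m - 1L) * cfg$module_size + 1L):(m * cfg$module_size)
    rho <- ifelse(idx %in% planted, planted_rho, cfg$rho_on)
    e <- sig[idx, , drop = FALSE]
    e <- e - (e %*% f) %*% t(f) / sum(f * f)   # sample-orthogonal to f
    e <- t(apply(e, 1L, std))
    sig[idx, ] <- sqrt(rho) * matrix(f, length(idx), n, byrow = TRUE) +
      sqrt(1 - rho) * e
  }
  sig
}

sim_counts <- function(cfg, sig, sample_ids) {
  mu <- exp(cfg$mean_log_expression + cfg$sd_log_expression * sig)
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion),
                nrow = nrow(mu),
                dimnames = list(sim_gene_ids(cfg$n_genes), sample_ids))
  storage.mode(cnt) <- "double"
  cnt
}

#' Generate two-condition expression with planted stress-specific hubs
#'
#' Draws one count matrix per condition from the latent-factor model of
#' [sim_config()].  Planted genes are module members whose correlation is
#' `rho_on` under stress but `rho_off` under normal, so their network
#' degree rises under stress; all other module genes are equally
#' correlated in both states and background genes are independent.
#'
#' @param config A [sim_config()].
#' @return List with elements `normal` and `stress` (single-state
#'   [expression_set()]s over an identical gene panel) and `truth`, a
#'   list holding `planted_gene_ids` and `module_assignment` (named
#'   integer vector, `NA` for genes outside modules).
#' @export
simulate_two_state_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples_per_state
    mk_sheet <- function(ids, state)
      data.frame(sample_id = ids, state = state, stage = "pooled",
                 replicate = seq_along(ids))
    nid <- sprintf("N%02d", seq_len(n))
    sid <- sprintf("S%02d", seq_len(n))
    normal <- expression_set(
      sim_counts(config, sim_log_signal(config, config$rho_off), nid),
      mk_sheet(nid, "normal"))
    stress <- expression_set(
      sim_counts(config, sim_log_signal(config, config$rho_on), sid),
      mk_sheet(sid, "stress"))
    genes <- sim_gene_ids(config$n_genes)
    module <- rep(NA_integer_, config$n_genes)
    nm <- config$n_modules * config$module_size
    module[seq_len(nm)] <- rep(seq_len(config$n_modules),
                               each = config$module_size)
    names(module) <- genes
    list(normal = normal, stress = stress,
         truth = list(planted_gene_ids = genes[seq_len(config$n_planted)],
                      module_assignment = module))
  })
}

#' Generate a SNP evidence table over a simulated gene panel
#'
#' Each planted gene receives at least one SNP record with probability
#' `snp_fraction_planted`; every other gene with probability
#' `snp_fraction_background`.  A gene carrying SNPs gets `1 + Poisson(1)`
#' records with random positions, distinct alleles, and a region class
#' drawn uniformly from promoter/5'UTR/exon/intron/3'UTR.
#'
#' @param truth Ground-truth list from [simulate_two_state_expression()].
#' @param all_genes Character vector: the full gene panel.
#' @param config The [sim_config()] (fractions and seed are read from it).
#' @return A `snp_table` data frame (see [read_snp_table()]).
#' @export
simulate_snp_table <- function(truth, all_genes, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    planted <- all_genes %in% truth$planted_gene_ids
    p <- ifelse(planted, config$snp_fraction_planted,
                config$snp_fraction_background)
    has_snp <- stats::runif(length(all_genes)) < p
    rows <- list()
    bases <- c("A", "C", "G", "T")
    for (g in all_genes[has_snp]) {
      k <- 1L + stats::rpois(1L, 1)
      ref <- sample(bases, k, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      rows[[g]] <- data.frame(
        gene_id = g,
        position = sample.int(5000L, k),
        ref = ref, alt = unname(alt),
        region_class = sample(known_region_classes, k, replace = TRUE))
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene_id = character(), position = integer(),
                 ref = character(), alt = character(),
                 region_class = character())
    rownames(out) <- NULL
    structure(out, n_rejected = 0L,
              class = c("snp_table", "data.frame"))
  })
}

#' Generate a gene annotation around a QTL-like interval
#'
#' Places `round(in_interval_fraction_planted * n_planted)` planted genes
#' inside the query interval and every other gene outside it, on the same
#' chromosome, as non-overlapping fixed-width loci.
#'
#' @param all_genes Character vector: the full gene panel.
#' @param interval A [genomic_interval()] the planted genes should fall
#'   in.
#' @param truth Ground-truth list from [simulate_two_state_expression()].
#' @param in_interval_fraction_planted Fraction of planted genes placed
#'   inside the interval.
#' @param seed Integer seed.
#' @param gene_width Width of each simulated locus (default 500 bp).
#' @return A `gene_annotation` data frame (see [read_gene_annotation()]).
#' @export
simulate_annotation <- function(all_genes, interval, truth,
                                in_interval_fraction_planted = 1,
                                seed = 1L, gene_width = 500L) {
  stopifnot(inherits(interval, "genomic_interval"))
  with_seed(seed, {
    planted <- intersect(all_genes, truth$planted_gene_ids)
    n_in <- round(in_interval_fraction_planted * length(planted))
    inside <- planted[seq_len(n_in)]
    outside <- setdiff(all_genes, inside)
    slot <- gene_width + 10L
    if (n_in * slot > interval$end - interval$start)
      snet_stop("interval too small for %d genes of width %d",
                "saltnet_config_error", n_in, gene_width)
    rows <- list()
    if (n_in > 0L) {
      starts <- interval$start + (seq_len(n_in) - 1L) * slot
      rows$inside <- data.frame(gene_id = inside,
                                chromosome = interval$chromosome,
                                start = starts, end = starts + gene_width)
    }
    if (length(outside)) {
      starts <- interval$end + 10L + (seq_along(outside) - 1L) * slot
      rows$outside <- data.frame(gene_id = outside,
                                 chromosome = interval$chromosome,
                                 start = starts, end = starts + gene_width)
    }
    df <- do.call(rbind, rows)
    df <- df[match(all_genes, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    structure(df, class = c("gene_annotation", "data.frame"))
  })
}
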