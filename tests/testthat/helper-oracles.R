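# Independent oracles and fixture builders shared across the test files.
# Every oracle is a direct, slow transcription of a definition, kept free
# of any package internals so it can contradict them.

# fraction of realized links among the neighbors of each node, computed
# by explicit ordered-triple enumeration
cc_brute <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, ])
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (q in seq_len(n)) if (q != j)
      s <- s + a[i, j] * a[i, q] * a[j, q]
    out[i] <- s / (k * (k - 1))
  }
  out
}

# geometric-mean weighted clustering coefficient by triple enumeration
wcc_brute <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] != 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (q in seq_len(n)) if (q != j)
      s <- s + abs(w[i, j] * w[i, q] * w[j, q])^(1 / 3)
    out[i] <- s / (k * (k - 1))
  }
  out
}

# median-of-ratios size factors, written out gene by gene
size_factors_brute <- function(m) {
  keep <- apply(m, 1, function(x) all(x > 0))
  ref <- m[keep, , drop = FALSE]
  geo <- apply(ref, 1, function(x) prod(x)^(1 / length(x)))
  vapply(seq_len(ncol(m)), function(j) median(ref[, j] / geo), numeric(1))
}

# symmetric Erdos-Renyi adjacency, optionally with U(0,1) weights
random_graph <- function(n, p = 0.3, weighted = FALSE) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(runif(length(up)) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  if (!weighted) return(a)
  w <- matrix(0, n, n)
  w[up] <- runif(length(up))
  w <- (w + t(w)) * a
  dimnames(w) <- dimnames(a)
  list(a = a, w = w)
}

# the hand-drawn example topology: three hub genes over disjoint
# neighborhoods -- H1 with 4 unlinked neighbors, H2 with 6 neighbors of
# which exactly one pair is linked, H3 with 4 unlinked neighbors
hub_example_network <- function() {
  nodes <- c("H1", paste0("a", 1:4), "H2", paste0("b", 1:6),
             "H3", paste0("c", 1:4))
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  link <- function(x, y) {
    a[x, y] <<- 1
    a[y, x] <<- 1
  }
  for (v in paste0("a", 1:4)) link("H1", v)
  for (v in paste0("b", 1:6)) link("H2", v)
  for (v in paste0("c", 1:4)) link("H3", v)
  link("b1", "b2")
  state_network(a, state = "stress")
}

# small two-state expression fixture with one stress-only module
small_sim <- function(seed = 1, n_genes = 120, n_modules = 3,
                      module_size = 10, n_planted = 10,
                      n_samples = 20, ...) {
  cfg <- sim_config(n_genes = n_genes, n_samples_per_state = n_samples,
                    n_modules = n_modules, module_size = module_size,
                    n_planted = n_planted, seed = seed, ...)
  sim <- simulate_two_state_expression(cfg)
  sim$combined <- combine_states(sim$normal, sim$stress)
  sim$config <- cfg
  sim
}
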