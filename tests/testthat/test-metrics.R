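test_that("the hand-drawn hub example reproduces its degrees and CCs", {
  net <- hub_example_network()
  expect_equal(unname(node_degree(net, c("H1", "H2", "H3"))), c(4L, 6L, 4L))
  cc <- clustering_coefficient(net, c("H1", "H2", "H3"))
  expect_equal(unname(cc), c(0, 1 / 15, 0))
})

test_that("degree covers the degenerate and complete extremes", {
  a <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  a[1:5, 1:5] <- 1; diag(a) <- 0        # K5 plus isolated node f
  net <- state_network(a)
  expect_equal(unname(node_degree(net)), c(rep(4L, 5), 0L))
  expect_equal(unname(clustering_coefficient(net)), c(rep(1, 5), 0))
  expect_error(node_degree(net, "zz"), class = "saltnet_lookup_error")
})

test_that("a triangle clusters fully; low-degree nodes return 0", {
  a <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  a[1, 2] <- a[2, 1] <- a[1, 3] <- a[3, 1] <- a[2, 3] <- a[3, 2] <- 1
  a[1, 4] <- a[4, 1] <- 1   # pendant node d, degree 1
  net <- state_network(a)
  cc <- clustering_coefficient(net)
  expect_equal(unname(cc[c("b", "c", "d")]), c(1, 1, 0))
})

test_that("binary coefficient matches brute-force triple enumeration", {
  set.seed(13)
  for (i in 1:100) {
    a <- random_graph(sample(4:15, 1), runif(1, 0.1, 0.6))
    net <- state_network(a)
    expect_equal(unname(clustering_coefficient(net)), cc_brute(a))
    expect_equal(unname(node_degree(net)), as.integer(rowSums(a)))
  }
})

test_that("binary coefficient matches the graph-library local transitivity", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (i in 1:20) {
    a <- random_graph(12, 0.4)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    ref <- igraph::transitivity(g, type = "local", isolates = "zero")
    # isolates="zero" covers k<2; same convention as ours
    expect_equal(unname(clustering_coefficient(state_network(a))),
                 unname(ref))
  }
})

test_that("weighted degree is the row sum of the weight matrix", {
  a <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  a["x", "y"] <- a["y", "x"] <- 1
  a["x", "z"] <- a["z", "x"] <- 1
  w <- a; w["x", "y"] <- w["y", "x"] <- 0.9
  w["x", "z"] <- w["z", "x"] <- 0.95
  net <- state_network(a, w)
  expect_equal(unname(weighted_degree(net, "x")), 1.85)

  set.seed(15)
  g <- random_graph(12, 0.4, weighted = TRUE)
  net <- state_network(g$a, g$w)
  expect_equal(unname(weighted_degree(net)), unname(rowSums(g$w)),
               tolerance = 1e-12)
})

test_that("unit weights collapse the weighted coefficient onto the binary", {
  set.seed(16)
  for (i in 1:25) {
    a <- random_graph(sample(5:15, 1), runif(1, 0.2, 0.6))
    net <- state_network(a, a)
    expect_equal(weighted_clustering_coefficient(net),
                 clustering_coefficient(net), tolerance = 1e-12)
  }
})

test_that("a uniform triangle recovers its weight as the coefficient", {
  a <- matrix(0, 3, 3, dimnames = list(c("i", "j", "q"), c("i", "j", "q")))
  a[upper.tri(a)] <- 1; a <- a + t(a)
  net <- state_network(a, a * 0.8)
  # numerator 2 * (0.8^3)^(1/3), denominator 2 * 1
  expect_equal(unname(weighted_clustering_coefficient(net, "i")), 0.8)
})

test_that("weighted coefficient matches brute-force triple enumeration", {
  set.seed(17)
  for (i in 1:100) {
    g <- random_graph(sample(4:12, 1), runif(1, 0.2, 0.7), weighted = TRUE)
    net <- state_network(g$a, g$w)
    expect_equal(unname(weighted_clustering_coefficient(net)),
                 wcc_brute(g$w), tolerance = 1e-12)
  }
})

test_that("weights above one are refused", {
  a <- matrix(0, 2, 2); a[1, 2] <- a[2, 1] <- 1
  expect_error(state_network(a, a * 1.5), class = "saltnet_domain_error")
  net <- state_network(a)
  net$weights <- net$weights * 2   # corrupt an existing object
  expect_error(weighted_clustering_coefficient(net),
               class = "saltnet_domain_error")
})

test_that("degree sum, metric ranges, and neighbor-edge monotonicity hold", {
  set.seed(18)
  for (i in 1:20) {
    g <- random_graph(12, runif(1, 0.2, 0.7), weighted = TRUE)
    net <- state_network(g$a, g$w)
    expect_equal(sum(node_degree(net)), sum(g$a))   # = 2 |E|
    cc <- clustering_coefficient(net)
    wcc <- weighted_clustering_coefficient(net)
    expect_true(all(cc >= 0 & cc <= 1))
    expect_true(all(wcc >= 0 & wcc <= 1))
    # closing a neighbor pair of some node cannot decrease that node's CC
    k <- rowSums(g$a)
    i0 <- which(k >= 2)[1]
    if (!is.na(i0)) {
      nb <- which(g$a[i0, ] == 1)
      open <- which(g$a[nb, nb] == 0 & upper.tri(g$a[nb, nb]), arr.ind = TRUE)
      if (nrow(open)) {
        a2 <- g$a
        a2[nb[open[1, 1]], nb[open[1, 2]]] <- 1
        a2[nb[open[1, 2]], nb[open[1, 1]]] <- 1
        cc2 <- clustering_coefficient(state_network(a2))
        expect_gte(cc2[i0], cc[i0])
      }
    }
  }
})

test_that("ordered-pair and unordered-pair conventions agree", {
  # numerator counts each neighbor pair twice, denominator k(k-1); halving
  # both leaves the value unchanged -- checked against the halved form
  set.seed(19)
  a <- random_graph(10, 0.5)
  net <- state_network(a)
  cc <- clustering_coefficient(net)
  halved <- vapply(seq_len(10), function(i) {
    nb <- which(a[i, ] == 1); k <- length(nb)
    if (k < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  expect_equal(unname(cc), halved, tolerance = 1e-12)
})

test_that("the metrics table assembles all four surfaces per state", {
  sim <- small_sim(seed = 20, n_genes = 40, n_modules = 2, module_size = 8,
                   n_planted = 4, n_samples = 10)
  nets <- build_two_state_networks(normalize_counts(sim$combined))
  tab <- node_metrics(nets$normal, nets$stress)
  expect_equal(nrow(tab), 80L)
  expect_setequal(unique(tab$state), c("normal", "stress"))
  # recount oracle for the degree column
  for (st in c("normal", "stress")) {
    sub <- tab[tab$state == st, ]
    expect_equal(sub$degree,
                 unname(as.integer(rowSums(nets[[st]]$adjacency))))
  }
  # mismatched panels are refused
  bad <- nets$stress
  bad$gene_ids <- rev(bad$gene_ids)
  expect_error(node_metrics(nets$normal, bad),
               class = "saltnet_contract_error")
})
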