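test_that("modularity matches the Newman-Girvan formula and igraph", {
  # two disconnected equal cliques, split into the cliques: Q = 1/2
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  expect_equal(modularity_score(A, rep(1:2, each = 4)), 0.5)
  # all-in-one partition has Q = 0 on any graph
  for (net in fixture_networks()) {
    W <- network_adjacency(net)
    n <- nrow(W)
    expect_equal(modularity_score(W, rep(1, n)), 0, tolerance = 1e-14)
    # singleton partition: -sum (k_i / 2m)^2
    k <- rowSums(W)
    expect_equal(modularity_score(W, seq_len(n)), -sum((k / sum(k))^2),
                 tolerance = 1e-12)
    # cross-check a nontrivial partition against igraph's implementation
    set.seed(1)
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_score(W, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  expect_error(modularity_score(A, rep(1, 3)), "length")
})

test_that("seeded Louvain attains the exhaustive optimum on small graphs", {
  fixtures <- list(
    two_cliques = network_adjacency(generate_network("two_cliques",
                                                     clique_size = 4)),
    weak_bridge = network_adjacency(generate_network("two_cliques",
                                                     clique_size = 4,
                                                     bridge_weight = 0.1)),
    path = network_adjacency(generate_network("path", 7)),
    complete = network_adjacency(generate_network("complete", 6)),
    weighted_random = {
      set.seed(42)
      A <- matrix(0, 7, 7)
      idx <- which(upper.tri(A))
      on <- sample(idx, 12)
      A[on] <- stats::runif(12, 0.1, 2)
      A <- A + t(A)
      A
    }
  )
  for (nm in names(fixtures)) {
    W <- fixtures[[nm]]
    part <- louvain_partition(W, seed = 1, n_restarts = 10)
    expect_equal(part$modularity, brute_force_best_q(W), tolerance = 1e-12)
    expect_equal(modularity_score(W, part$assignment), part$modularity)
  }
  # the weak-bridge optimum is the two planted cliques
  part <- louvain_partition(fixtures$weak_bridge, seed = 3)
  expect_equal(part$n_modules, 2)
  expect_equal(unname(part$assignment), rep(1:2, each = 4))
})

test_that("Louvain is deterministic given seed and never below trivial partitions", {
  for (net in fixture_networks()[c("ws", "weighted_ws", "rgg")]) {
    W <- network_adjacency(net)
    a <- louvain_partition(W, seed = 5, n_restarts = 4)
    b <- louvain_partition(W, seed = 5, n_restarts = 4)
    expect_identical(a$assignment, b$assignment)
    n <- nrow(W)
    q_singleton <- modularity_score(W, seq_len(n))
    q_one <- modularity_score(W, rep(1, n))
    expect_gte(a$modularity, max(q_singleton, q_one))
    # ids contiguous from 1
    expect_setequal(unique(unname(a$assignment)), seq_len(a$n_modules))
  }
  expect_equal(louvain_partition(
    network_adjacency(generate_network("complete", 6)))$n_modules, 1)
  expect_error(louvain_partition(matrix(0, 3, 3)), "edgeless")
})

test_that("functional partitions coarsen from many modules to one across scales", {
  ws <- generate_network("watts_strogatz", 100, mean_degree = 4,
                         p_rewire = 0.05, seed = 2)
  dec <- spectral_decomposition(ws)
  small <- functional_partition(dec, 1e-10 * dec$diffusion_time, seed = 1)
  large <- functional_partition(dec, 10 * dec$diffusion_time, seed = 1)
  expect_gt(small$n_modules, 5) # structure-like: many local neighbourhoods
  expect_lte(large$n_modules, 3) # near equilibrium: few large modules
  expect_gte(small$n_modules, large$n_modules)
  # phi0 is a pure scale: partitions identical
  p1 <- functional_partition(dec, 0.3, phi0 = 1, seed = 9)
  p2 <- functional_partition(dec, 0.3, phi0 = 173.2, seed = 9)
  expect_identical(p1$assignment, p2$assignment)
})

test_that("module-count curves are monotone end-to-end across seeds", {
  ws <- generate_network("watts_strogatz", 60, mean_degree = 4,
                         p_rewire = 0.05, seed = 8)
  dec <- spectral_decomposition(ws)
  grid <- rescaled_tau_grid(dec, n_points = 2) # just the two end points
  ends <- sapply(1:10, function(s) {
    module_count_curve(dec, grid, seed = s, n_restarts = 5)$n_modules
  })
  expect_true(all(ends[1, ] >= ends[2, ]))
  expect_gte(stats::median(ends[1, ]), stats::median(ends[2, ]))
  # empty grid gives an empty table
  empty <- module_count_curve(dec, tibble::tibble(ratio = double(),
                                                  tau = double()))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("ratio", "tau", "n_modules", "modularity"))
})

test_that("planted blocks are recovered from the functional state at intermediate scales", {
  ari <- sapply(1:20, function(s) {
    sbm <- generate_network("stochastic_block", 200, block_sizes = rep(50, 4),
                            p_within = 0.5, p_between = 1e-3, seed = s)
    dec <- spectral_decomposition(sbm)
    part <- functional_partition(dec, 0.1 * dec$diffusion_time, seed = s,
                                 n_restarts = 5)
    igraph::compare(part$assignment, planted_blocks(sbm),
                    method = "adjusted.rand")
  })
  expect_gte(mean(ari), 0.95)
})

test_that("a 4-module plateau appears over an intermediate ratio window", {
  sbm <- generate_network("stochastic_block", 200, block_sizes = rep(50, 4),
                          p_within = 0.5, p_between = 1e-3, seed = 17)
  dec <- spectral_decomposition(sbm)
  grid <- rescaled_tau_grid(dec, 1e-3, 0.3, 7)
  mc <- module_count_curve(dec, grid, seed = 1, n_restarts = 5)
  expect_gte(sum(mc$n_modules == 4), 3) # plateau at the planted count
})

test_that("the modules-entropy relation is fit by OLS on log counts", {
  s <- seq(0.2, 3, length.out = 12)
  ident <- modules_entropy_relation(
    tibble::tibble(entropy = s, n_modules = exp(s))
  )
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1, tolerance = 1e-12)
  flat <- modules_entropy_relation(
    tibble::tibble(entropy = s, n_modules = 1)
  )
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(
    modules_entropy_relation(tibble::tibble(entropy = 1:2, n_modules = 1:2)),
    "3 points"
  )
  g <- glance(ident)
  expect_named(g, c("slope", "intercept", "r_squared", "n"))
  expect_equal(g$n, 12L)
})

test_that("partition tidiers and TSV export expose the node-module map", {
  tc <- generate_network("two_cliques", clique_size = 4, bridge_weight = 0.1)
  part <- louvain_partition(network_adjacency(tc), seed = 1)
  td <- tidy(part)
  expect_named(td, c("node", "module"))
  expect_equal(nrow(td), 8)
  gl <- glance(part)
  expect_equal(gl$n_modules, 2L)
  f <- withr::local_tempfile()
  write_partition(part, f)
  back <- utils::read.table(f, sep = "\t")
  expect_equal(back$V2, unname(part$assignment))
})
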