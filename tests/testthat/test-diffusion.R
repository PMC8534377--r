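test_that("Laplacian spectra match the characteristic-polynomial oracle", {
  two <- weighted_network(data.frame(from = "a", to = "b", weight = 1))
  expect_equal(spectral_decomposition(two)$eigenvalues, c(0, 2),
               tolerance = 1e-12)
  p3 <- generate_network("path", 3)
  dec3 <- spectral_decomposition(p3)
  expect_equal(dec3$eigenvalues, c(0, 1, 3), tolerance = 1e-10)
  expect_equal(dec3$eigenvalues,
               charpoly_eigenvalues(dec3$laplacian), tolerance = 1e-8)
  # small weighted fixture against the independent oracle
  net <- generate_network("watts_strogatz", 8, mean_degree = 4,
                          p_rewire = 0.2, seed = 5,
                          weight_fn = function(m) stats::runif(m, 0.5, 2))
  dec <- spectral_decomposition(net)
  expect_equal(dec$eigenvalues, charpoly_eigenvalues(dec$laplacian),
               tolerance = 1e-7)
  # orthonormal eigenbasis
  V <- dec$eigenvectors
  expect_equal(t(V) %*% V, diag(nrow(V)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("component counting follows the zero eigenvalues", {
  disjoint <- weighted_network(data.frame(
    from = c("a", "c"), to = c("b", "d"), weight = 1
  ))
  dec <- spectral_decomposition(disjoint)
  expect_equal(dec$n_components, 2)
  expect_lt(abs(dec$eigenvalues[2]), 1e-12)
  expect_true(is.na(dec$diffusion_time))
  for (net in fixture_networks()) {
    expect_equal(spectral_decomposition(net)$n_components,
                 network_components(net))
  }
})

test_that("the propagator is the heat kernel: identity at 0, closed form, equilibrium", {
  two <- weighted_network(data.frame(from = "a", to = "b", weight = 1))
  dec <- spectral_decomposition(two)
  expect_equal(propagator(dec, 0), diag(2), tolerance = 1e-14,
               ignore_attr = TRUE)
  for (tau in c(0.1, 0.7, 3)) {
    expect_equal(propagator(dec, tau)[1, 2], (1 - exp(-2 * tau)) / 2,
                 tolerance = 1e-12)
  }
  ws <- fixture_networks()$ws
  n <- network_size(ws)
  U <- propagator(ws, 1e4)
  expect_equal(U, matrix(1 / n, n, n), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(propagator(dec, -1), "nonnegative")
})

test_that("the propagator is doubly stochastic and obeys the semigroup law", {
  for (net in fixture_networks()) {
    dec <- spectral_decomposition(net)
    grid_taus <- c(1e-6, 0.1, 1, 10)
    for (tau in grid_taus) {
      U <- propagator(dec, tau)
      expect_lt(max(abs(rowSums(U) - 1)), 1e-8)
      expect_lt(max(abs(colSums(U) - 1)), 1e-8)
      expect_true(all(U >= 0))
    }
    U1 <- propagator(dec, 0.3)
    U2 <- propagator(dec, 0.9)
    expect_equal(U1 %*% U2, propagator(dec, 1.2), tolerance = 1e-8)
  }
})

test_that("the propagator matches direct ODE integration of the diffusion equation", {
  nets <- list(
    generate_network("path", 6),
    generate_network("barabasi_albert", 12, m = 1, seed = 4),
    generate_network("watts_strogatz", 20, mean_degree = 4, p_rewire = 0.1,
                     seed = 2, weight_fn = function(m) stats::runif(m, 0.5, 2))
  )
  for (net in nets) {
    dec <- spectral_decomposition(net)
    for (tau in c(0.2, 1.5)) {
      expect_equal(propagator(dec, tau), ode_propagator(dec$laplacian, tau),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("functional states linearise to the structure at small tau", {
  ws <- generate_network("watts_strogatz", 50, mean_degree = 4,
                         p_rewire = 0.05, seed = 21)
  W <- network_adjacency(ws)
  tau <- 1e-6
  phi0 <- 2.5
  st <- functional_state(ws, tau, phi0 = phi0)
  on_edges <- W > 0
  rel <- abs(st$matrix[on_edges] - phi0 * tau * W[on_edges]) /
    (phi0 * tau * W[on_edges])
  expect_lt(max(rel), 1e-3) # relative error O(tau)
})

test_that("functional states have zero diagonal, bounded entries, symmetry", {
  for (net in fixture_networks()) {
    st <- functional_state(net, 0.8, phi0 = 1.7)
    expect_equal(unname(diag(st$matrix)), rep(0, network_size(net)))
    expect_true(all(st$matrix >= 0 & st$matrix <= 1.7 + 1e-12))
    expect_equal(st$matrix, t(st$matrix))
    expect_equal(st$mean_strength, sum(st$matrix) / network_size(net))
  }
})

test_that("non-uniform initial distributions scale the propagator rows", {
  ws <- fixture_networks()$ws
  n <- network_size(ws)
  dec <- spectral_decomposition(ws)
  pi <- (1:n) / sum(1:n)
  st <- functional_state(dec, 0.5, pi = pi)
  U <- propagator(dec, 0.5)
  M <- pi * U
  diag(M) <- 0
  expect_equal(unname(st$matrix), unname(M))
  expect_false(isTRUE(all.equal(st$matrix, t(st$matrix))))
  expect_error(functional_state(dec, 0.5, pi = rep(1, n)), "sum to 1")
  expect_error(functional_state(dec, 0.5, pi = c(2, -1, rep(0, n - 2))), "nonnegative")
})

test_that("mean functional strength rises monotonically to phi0 (N-1)/N", {
  for (net in fixture_networks()[c("ws", "ba", "weighted_ws")]) {
    dec <- spectral_decomposition(net)
    n <- network_size(net)
    grid <- rescaled_tau_grid(dec, n_points = 25)
    kc <- mean_strength_curve(dec, grid, phi0 = 1)
    expect_true(all(diff(kc$mean_strength) >= -1e-12))
    expect_true(all(kc$mean_strength <= (n - 1) / n + 1e-10))
    expect_lt(kc$mean_strength[1], 1e-6)
    # large-tau limit: fully entangled state
    expect_equal(functional_state(dec, 1e4)$mean_strength, (n - 1) / n,
                 tolerance = 1e-8)
  }
})

test_that("rescaled grids are log-spaced multiples of the diffusion time", {
  two <- weighted_network(data.frame(from = "a", to = "b", weight = 1))
  dec <- spectral_decomposition(two)
  expect_equal(dec$diffusion_time, 0.5) # lambda_2 = 2
  g <- rescaled_tau_grid(dec, 0.01, 1, 3)
  expect_equal(g$ratio, c(0.01, 0.1, 1))
  expect_equal(g$tau, c(0.005, 0.05, 0.5))
  expect_equal(rescaled_tau_grid(dec)$ratio[c(1, 100)], c(1e-10, 10))
  expect_error(rescaled_tau_grid(dec, 1, 1), "ratio_min < ratio_max")
  disjoint <- weighted_network(data.frame(
    from = c("a", "c"), to = c("b", "d"), weight = 1
  ))
  expect_error(rescaled_tau_grid(disjoint), "lambda_2 = 0")
})

test_that("at tau_d the second propagator eigenvalue is exactly 1/e", {
  for (net in fixture_networks()[c("path", "ws", "weighted_ws")]) {
    dec <- spectral_decomposition(net)
    ev <- sort(eigen(propagator(dec, dec$diffusion_time),
                     symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(ev[2], exp(-1), tolerance = 1e-10)
  }
})

test_that("functional state export respects the weight threshold", {
  ws <- fixture_networks()$ws
  st <- functional_state(ws, 0.5)
  all_edges <- functional_state_edges(st)
  n <- network_size(ws)
  expect_equal(nrow(all_edges), n * (n - 1) / 2) # dense state
  thr <- stats::median(all_edges$weight)
  kept <- functional_state_edges(st, min_weight = thr)
  expect_true(all(kept$weight >= thr))
  expect_lt(nrow(kept), nrow(all_edges))
})
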