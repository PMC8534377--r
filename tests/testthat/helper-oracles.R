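# Independent oracles, deliberately avoiding the code paths they check.

# Eigenvalues of a small symmetric matrix via the characteristic polynomial
# (root finding on det(A - x I) expanded numerically with polyroot).
charpoly_eigenvalues <- function(A) {
  n <- nrow(A)
  # coefficients of det(A - x I) via Faddeev-LeVerrier
  coefs <- numeric(n + 1)
  coefs[n + 1] <- 1 # x^n coefficient of (-1)^n det(A - xI), handled below
  M <- diag(n)
  c_prev <- 1
  cs <- numeric(n)
  for (k in 1:n) {
    M <- A %*% M
    cs[k] <- -sum(diag(M)) / k
    M <- M + diag(cs[k], n)
  }
  # p(x) = x^n + cs[1] x^{n-1} + ... + cs[n]
  roots <- polyroot(rev(c(1, cs)))
  sort(Re(roots))
}

# Propagator column by direct numerical integration of the diffusion
# equation d phi / d tau = -L phi from a canonical unit vector.
ode_propagator <- function(L, tau, rtol = 1e-10, atol = 1e-12) {
  n <- nrow(L)
  sapply(seq_len(n), function(i) {
    y0 <- numeric(n)
    y0[i] <- 1
    out <- deSolve::ode(
      y = y0, times = c(0, tau),
      func = function(t, y, parms) list(-as.vector(L %*% y)),
      rtol = rtol, atol = atol
    )
    as.numeric(out[2, -1])
  })
}

# Dense-matrix Von Neumann entropy: build U(tau) elementwise by scaling and
# squaring of (I - tau L / 2^k), normalize to rho, diagonalize rho itself.
dense_entropy <- function(L, tau) {
  n <- nrow(L)
  k <- max(0, ceiling(log2(max(tau * max(abs(L)), 1e-16))) + 20)
  U <- diag(n) - (tau / 2^k) * L + ((tau / 2^k)^2 / 2) * (L %*% L)
  for (i in seq_len(k)) U <- U %*% U
  rho <- U / sum(diag(U))
  p <- eigen((rho + t(rho)) / 2, symmetric = TRUE, only.values = TRUE)$values
  p <- pmax(p, 0)
  p <- p / sum(p)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (id in seq_len(maxid + 1)) {
      recurse(c(prefix, id), max(maxid, id))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Brute-force maximum-modularity partition by exhaustive enumeration.
brute_force_best_q <- function(W) {
  n <- nrow(W)
  k <- rowSums(W)
  two_m <- sum(k)
  B <- W - outer(k, k) / two_m
  best <- -Inf
  for (a in all_partitions(n)) {
    q <- sum(B * outer(a, a, "==")) / two_m
    if (q > best) best <- q
  }
  best
}

# Small fixture set reused across property tests.
fixture_networks <- function() {
  list(
    path = generate_network("path", 8),
    complete = generate_network("complete", 6),
    two_cliques = generate_network("two_cliques", clique_size = 4),
    ba = generate_network("barabasi_albert", 30, m = 1, seed = 7),
    ws = generate_network("watts_strogatz", 40, mean_degree = 4,
                          p_rewire = 0.05, seed = 3),
    rgg = generate_network("random_geometric", 40, radius = 0.3, seed = 5),
    weighted_ws = generate_network(
      "watts_strogatz", 30, mean_degree = 4, p_rewire = 0.1, seed = 9,
      weight_fn = function(m) 10^stats::runif(m, -1.5, 1.5)
    )
  )
}
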