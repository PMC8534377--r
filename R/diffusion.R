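#' Spectral decomposition of the network Laplacian
#'
#' Computes the full symmetric eigendecomposition of the combinatorial
#' Laplacian \eqn{L = K - W} (strength diagonal minus weight matrix), which
#' drives the diffusion equation \eqn{\partial_\tau \phi = -L \phi}. All
#' propagators, functional states and spectral entropies at every scale
#' \eqn{\tau} reuse this single decomposition, so it is computed once per
#' network.
#'
#' The number of connected components is the count of eigenvalues below
#' `zero_tol * max(lambda)`; the diffusion time \eqn{\tau_d = 1/\lambda_2}
#' (the scale at which the slowest non-trivial mode has decayed to
#' \eqn{1/e}) is defined only for connected networks and is `NA` otherwise.
#'
#' @param net a `weighted_network`
#' @param zero_tol relative threshold under which an eigenvalue counts as
#'   zero (default `1e-10`)
#' @return an object of class `spectral_decomposition` with fields
#'   `laplacian`, `eigenvalues` (ascending, \eqn{\lambda_1 = 0}),
#'   `eigenvectors` (orthonormal columns), `n_components`, `diffusion_time`,
#'   `labels`.
#' @examples
#' net <- generate_network("path", 3)
#' spectral_decomposition(net)$eigenvalues  # 0, 1, 3
#' @export
spectral_decomposition <- function(net, zero_tol = 1e-10) {
  validate_weighted_network(net)
  W <- net$weights
  L <- diag(net$strengths) - W
  es <- eigen(L, symmetric = TRUE)
  lam <- rev(es$values) # ascending
  V <- es$vectors[, rev(seq_along(lam)), drop = FALSE]
  lam[lam < 0 & abs(lam) < zero_tol * max(abs(lam), 1)] <- 0
  lam_max <- max(lam)
  n_comp <- if (lam_max <= 0) length(lam) else sum(lam < zero_tol * lam_max)
  n_comp <- max(n_comp, 1L)
  structure(
    list(
      laplacian = L,
      eigenvalues = lam,
      eigenvectors = V,
      n_components = as.integer(n_comp),
      diffusion_time = if (n_comp == 1L) 1 / lam[2] else NA_real_,
      labels = net$labels
    ),
    class = "spectral_decomposition"
  )
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf(
    "<spectral_decomposition> N = %d, components = %d, lambda_2 = %.6g, tau_d = %.6g\n",
    length(x$labels), x$n_components, x$eigenvalues[2], x$diffusion_time
  ))
  invisible(x)
}

as_decomposition <- function(x) {
  if (inherits(x, "spectral_decomposition")) x
  else spectral_decomposition(as_weighted_network(x))
}

#' Diffusion propagator (heat kernel)
#'
#' The propagator \eqn{U(\tau) = e^{-\tau L}} solving the network diffusion
#' equation, built as \eqn{V e^{-\tau \Lambda} V^T} from the stored
#' eigendecomposition. For undirected networks \eqn{U} is symmetric and
#' doubly stochastic (rows and columns sum to 1, because L has zero row
#' sums), and provably nonnegative; entries that come out negative by
#' floating-point noise (magnitude below `clip_tol`) are clipped to zero,
#' while larger negatives abort, signalling an internal inconsistency.
#'
#' @param dec a `spectral_decomposition` (or a network, decomposed on the
#'   fly)
#' @param tau propagation scale, `tau >= 0`
#' @param clip_tol magnitude below which negative entries are treated as
#'   roundoff (default `1e-12`)
#' @return N x N propagator matrix with node-label dimnames
#' @examples
#' net <- weighted_network(data.frame(from = "a", to = "b", weight = 1))
#' propagator(net, 0.3)[1, 2]  # (1 - exp(-0.6)) / 2
#' @export
propagator <- function(dec, tau, clip_tol = 1e-12) {
  dec <- as_decomposition(dec)
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0) {
    rlang::abort("`tau` must be a single nonnegative number")
  }
  V <- dec$eigenvectors
  U <- V %*% (exp(-tau * dec$eigenvalues) * t(V))
  U <- (U + t(U)) / 2
  neg <- min(U)
  if (neg < -clip_tol) {
    rlang::abort(sprintf(
      "propagator entry %.3e below -clip_tol: eigendecomposition inconsistent",
      neg
    ))
  }
  U[U < 0] <- 0
  dimnames(U) <- list(dec$labels, dec$labels)
  U
}

#' Emergent functional state at scale tau
#'
#' The emergent functional state \eqn{\tilde W(\tau)} is the network whose
#' link \eqn{i}--\eqn{j} carries the flow exchanged between the two nodes
#' within propagation time \eqn{\tau}: the off-diagonal propagator rescaled
#' by the initial field amount \eqn{\phi_0},
#' \deqn{\tilde W_{ij}(\tau) = \phi_0 \, U_{ij}(\tau) (1 - \delta_{ij}).}
#' At small \eqn{\tau} it linearises to \eqn{\phi_0 \tau W} (the structure);
#' at large \eqn{\tau} on a connected network every entry tends to
#' \eqn{\phi_0 / N} (fully entangled state).
#'
#' A non-uniform initial distribution is folded into the propagator as
#' \eqn{U(\tau) = \Pi e^{-\tau L}} with \eqn{\Pi_{ii} = \phi_i / \phi_0};
#' `pi` gives its diagonal (nonnegative, summing to 1). With `pi = NULL`
#' the uniform \eqn{\Pi = I} is used and the state is symmetric.
#'
#' @inheritParams propagator
#' @param phi0 initial field amount per node (default 1); a pure scale on
#'   the state.
#' @param pi optional length-N nonnegative vector summing to 1, the diagonal
#'   of \eqn{\Pi}
#' @return an object of class `functional_state`: fields `tau`, `phi0`,
#'   `matrix` (zero diagonal), `functional_strengths` (\eqn{k_i}),
#'   `mean_strength` (\eqn{\bar k = \frac{1}{N}\sum_{ij}\tilde W_{ij}}),
#'   `symmetric`.
#' @export
functional_state <- function(dec, tau, phi0 = 1, pi = NULL, clip_tol = 1e-12) {
  dec <- as_decomposition(dec)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    rlang::abort("`tau` must be a single positive number")
  }
  if (!is.numeric(phi0) || phi0 <= 0) rlang::abort("`phi0` must be positive")
  U <- propagator(dec, tau, clip_tol = clip_tol)
  n <- length(dec$labels)
  symmetric <- is.null(pi)
  if (!is.null(pi)) {
    if (length(pi) != n || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
      rlang::abort("`pi` must be length-N, nonnegative and sum to 1")
    }
    U <- pi * U # row scaling by the initial distribution
  }
  M <- phi0 * U
  diag(M) <- 0
  k <- rowSums(M) # functional strengths k_i = sum_j W~_ij
  structure(
    list(
      tau = tau, phi0 = phi0, matrix = M,
      functional_strengths = stats::setNames(k, dec$labels),
      mean_strength = sum(M) / n,
      symmetric = symmetric
    ),
    class = "functional_state"
  )
}

#' @export
print.functional_state <- function(x, ...) {
  cat(sprintf(
    "<functional_state> N = %d, tau = %.6g, phi0 = %g, mean strength = %.6g\n",
    nrow(x$matrix), x$tau, x$phi0, x$mean_strength
  ))
  invisible(x)
}

#' Log-spaced grid of rescaled propagation scales
#'
#' Diffusion times differ across networks; comparability is obtained by
#' working in the rescaled parameter \eqn{\tau / \tau_d}. This builds
#' `n_points` log-spaced ratios in `[ratio_min, ratio_max]` (defaults
#' \eqn{10^{-10}} to \eqn{10}, the range spanning no-flow to full
#' entanglement) and pairs each with the absolute \eqn{\tau = r \tau_d} of
#' this network.
#'
#' @inheritParams propagator
#' @param ratio_min,ratio_max positive bounds, `ratio_min < ratio_max`
#' @param n_points number of grid points (>= 2)
#' @return a tibble with columns `ratio`, `tau`
#' @export
rescaled_tau_grid <- function(dec, ratio_min = 1e-10, ratio_max = 10,
                              n_points = 100) {
  dec <- as_decomposition(dec)
  if (dec$n_components > 1L) {
    rlang::abort("diffusion time undefined (lambda_2 = 0): network disconnected")
  }
  if (!(ratio_min > 0 && ratio_max > ratio_min)) {
    rlang::abort("need 0 < ratio_min < ratio_max")
  }
  if (n_points < 2) rlang::abort("`n_points` must be at least 2")
  r <- exp(seq(log(ratio_min), log(ratio_max), length.out = n_points))
  tibble::tibble(ratio = r, tau = r * dec$diffusion_time)
}

#' Mean functional strength across scales
#'
#' Evaluates \eqn{\bar k(\tau) = \frac{1}{N} \sum_{ij} \tilde W_{ij}(\tau)}
#' over a scale grid. On a connected network it rises monotonically from 0
#' to \eqn{\phi_0 (N-1)/N} as the functional state fills in.
#'
#' @inheritParams functional_state
#' @param grid tibble with columns `ratio`, `tau` (see
#'   [rescaled_tau_grid()])
#' @return tibble with columns `ratio`, `tau`, `mean_strength`
#' @export
mean_strength_curve <- function(dec, grid = NULL, phi0 = 1) {
  dec <- as_decomposition(dec)
  if (is.null(grid)) grid <- rescaled_tau_grid(dec)
  ks <- purrr::map_dbl(grid$tau, function(tau) {
    functional_state(dec, tau, phi0 = phi0)$mean_strength
  })
  dplyr::mutate(tibble::as_tibble(grid), mean_strength = ks)
}

#' Export a functional state as a network table or file
#'
#' @param state a `functional_state`
#' @param min_weight drop links with flow below this value (default 0:
#'   keep the fully dense state)
#' @return [functional_state_edges()]: edge tibble; `as_weighted_network`
#'   method: the state as a `weighted_network` (asymmetric states are
#'   symmetrised as \eqn{(\tilde W + \tilde W^T)/2}).
#' @export
functional_state_edges <- function(state, min_weight = 0) {
  net <- as_weighted_network(state)
  ed <- edge_tibble(net)
  dplyr::filter(ed, .data$weight >= min_weight, .data$weight > 0)
}

#' @export
as_weighted_network.functional_state <- function(x, ...) {
  M <- (x$matrix + t(x$matrix)) / 2
  as_weighted_network(M)
}
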