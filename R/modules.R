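#' Weighted Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[ A_{ij} -
#'   \frac{k_i k_j}{2m} \right] \delta(c_i, c_j)}
#' with \eqn{m} the total edge weight. Works on any symmetric nonnegative
#' matrix with zero diagonal, in particular on dense emergent functional
#' states; invariant under uniform rescaling of the weights.
#'
#' @param weights symmetric nonnegative N x N matrix, zero diagonal (a
#'   `weighted_network` or `functional_state` is also accepted)
#' @param assignment length-N module ids (any label type; grouping is what
#'   matters)
#' @return modularity Q in `[-1, 1]`
#' @export
modularity_score <- function(weights, assignment) {
  W <- module_weights(weights)
  n <- nrow(W)
  if (length(assignment) != n) {
    rlang::abort(sprintf("`assignment` has length %d, need %d",
                         length(assignment), n))
  }
  k <- rowSums(W)
  two_m <- sum(k)
  if (two_m <= 0) rlang::abort("modularity undefined for an edgeless graph")
  same <- outer(assignment, assignment, "==")
  sum((W - outer(k, k) / two_m) * same) / two_m
}

module_weights <- function(x) {
  if (inherits(x, "functional_state")) x <- as_weighted_network(x)
  if (inherits(x, "weighted_network")) x <- x$weights
  if (!is.matrix(x) || nrow(x) != ncol(x)) rlang::abort("need a square matrix")
  if (any(x < 0)) rlang::abort("weights must be nonnegative")
  x
}

#' Louvain community detection with seeded restarts
#'
#' Greedy two-phase modularity maximisation (local moving + aggregation)
#' applied to a weighted graph, restarted `n_restarts` times from the
#' seeded random generator with the highest-modularity partition kept.
#' Deterministic given `seed`. The optimisation is delegated to igraph's
#' Louvain implementation; modularity of the winning partition is
#' re-evaluated with [modularity_score()] on the input matrix.
#'
#' @inheritParams modularity_score
#' @param seed integer seed controlling the randomized sweep order
#' @param n_restarts number of independent restarts (default 10)
#' @return an object of class `partition`: `assignment` (1-based contiguous
#'   integer ids, first-appearance order), `n_modules`, `modularity`,
#'   `labels`, `seed`, `n_restarts`, `tau` (`NA` unless produced from a
#'   functional state)
#' @export
louvain_partition <- function(weights, seed = 1L, n_restarts = 10L) {
  W <- module_weights(weights)
  if (sum(W) <= 0) rlang::abort("cannot partition an edgeless graph")
  if (n_restarts < 1) rlang::abort("`n_restarts` must be >= 1")
  labels <- rownames(W)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(W)))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  best <- NULL
  best_q <- -Inf
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      memb <- igraph::membership(igraph::cluster_louvain(g, weights = ew))
      q <- modularity_score(W, as.integer(memb))
      if (q > best_q + 1e-15) {
        best_q <- q
        best <- as.integer(memb)
      }
    }
  })
  new_partition(best, best_q, labels, seed = as.integer(seed),
                n_restarts = as.integer(n_restarts))
}

new_partition <- function(assignment, q, labels, seed, n_restarts,
                          tau = NA_real_) {
  ids <- match(assignment, unique(assignment)) # contiguous, first-appearance
  structure(
    list(
      assignment = stats::setNames(ids, labels),
      n_modules = length(unique(ids)),
      modularity = q,
      labels = labels,
      seed = seed,
      n_restarts = n_restarts,
      tau = tau
    ),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d modules, Q = %.4f%s\n",
              length(x$assignment), x$n_modules, x$modularity,
              if (is.na(x$tau)) "" else sprintf(" (tau = %.4g)", x$tau)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a partition into a node-module table
#'
#' @param x a `partition`
#' @param ... unused
#' @return tibble with columns `node`, `module`
#' @export
tidy.partition <- function(x, ...) {
  tibble::tibble(node = x$labels, module = unname(x$assignment))
}

#' @rdname tidy.partition
#' @return `glance()`: one-row tibble with `n_modules`, `modularity`,
#'   `tau`, `seed`, `n_restarts`
#' @export
glance.partition <- function(x, ...) {
  tibble::tibble(n_modules = x$n_modules, modularity = x$modularity,
                 tau = x$tau, seed = x$seed, n_restarts = x$n_restarts)
}

#' Write a partition as a two-column TSV
#'
#' @param x a `partition`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_partition <- function(x, path) {
  utils::write.table(tidy(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Functional modules at a propagation scale
#'
#' Builds the emergent functional state \eqn{\tilde W(\tau)} and runs
#' seeded Louvain on its (fully dense, unthresholded) matrix. Functional
#' modules are groups of nodes that exchange more flow among themselves
#' than with the rest at scale \eqn{\tau}: many small neighbourhood-like
#' modules at small \eqn{\tau}, few large ones beyond the diffusion time.
#' A non-uniform initial distribution `pi` yields an asymmetric state; it
#' is symmetrised as \eqn{(\tilde W + \tilde W^T)/2} before modularity
#' optimisation.
#'
#' @inheritParams functional_state
#' @inheritParams louvain_partition
#' @return a `partition` tagged with `tau`
#' @export
functional_partition <- function(dec, tau, phi0 = 1, seed = 1L,
                                 n_restarts = 10L, pi = NULL) {
  dec <- as_decomposition(dec)
  st <- functional_state(dec, tau, phi0 = phi0, pi = pi)
  M <- (st$matrix + t(st$matrix)) / 2
  part <- louvain_partition(M, seed = seed, n_restarts = n_restarts)
  part$tau <- tau
  part
}

#' Number of functional modules across scales
#'
#' Runs [functional_partition()] at every grid point with the same seed
#' policy, tracing how the mesoscale organisation of the functional state
#' coarsens with the propagation scale.
#'
#' @inheritParams functional_partition
#' @inheritParams mean_strength_curve
#' @return tibble with columns `ratio`, `tau`, `n_modules`, `modularity`
#' @export
module_count_curve <- function(dec, grid = NULL, seed = 1L, n_restarts = 10L,
                               phi0 = 1) {
  dec <- as_decomposition(dec)
  if (is.null(grid)) grid <- rescaled_tau_grid(dec)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    return(tibble::tibble(ratio = double(), tau = double(),
                          n_modules = integer(), modularity = double()))
  }
  rows <- purrr::map(grid$tau, function(tau) {
    p <- functional_partition(dec, tau, phi0 = phi0, seed = seed,
                              n_restarts = n_restarts)
    tibble::tibble(n_modules = p$n_modules, modularity = p$modularity)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(rows))
}

#' Fit the modules-entropy scaling relation
#'
#' Across scales (and optionally across networks), the number of functional
#' modules scales logarithmically with the Von Neumann entropy of the
#' structural network: \eqn{\log n_{modules} \approx a\, S(\tau) + b}.
#' This fits that relation by ordinary least squares on the pooled points.
#'
#' @param data data frame with columns `n_modules` and `entropy` (e.g. a
#'   join of [module_count_curve()] and [entropy_curve()] outputs, possibly
#'   row-bound across networks)
#' @return an object of class `modules_entropy_fit` wrapping the `lm`;
#'   fields `slope`, `intercept`, `r_squared`, `n`. `tidy()` and `glance()`
#'   methods are provided.
#' @examples
#' df <- tibble::tibble(entropy = seq(0.1, 2, length.out = 10),
#'                      n_modules = exp(seq(0.1, 2, length.out = 10)))
#' glance(modules_entropy_relation(df))  # slope 1, r^2 1
#' @export
modules_entropy_relation <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("n_modules", "entropy") %in% names(data))) {
    rlang::abort("`data` needs columns `n_modules` and `entropy`")
  }
  data <- data[is.finite(data$n_modules) & is.finite(data$entropy) &
                 data$n_modules > 0, , drop = FALSE]
  if (nrow(data) < 3) rlang::abort("need at least 3 points to fit")
  fit <- stats::lm(log(n_modules) ~ entropy, data = data)
  # summary.lm warns on an exactly collinear (constructed) input; harmless
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- if (stats::sd(log(data$n_modules)) == 0) 1 else NA_real_
  structure(
    list(
      fit = fit,
      slope = unname(stats::coef(fit)[["entropy"]]),
      intercept = unname(stats::coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      n = nrow(data)
    ),
    class = "modules_entropy_fit"
  )
}

#' @export
print.modules_entropy_fit <- function(x, ...) {
  cat(sprintf(
    "<modules_entropy_fit> log(n_modules) ~ %.4f * S %+.4f  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' @export
tidy.modules_entropy_fit <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = unname(co[, "Std. Error"])
  )
}

#' @export
glance.modules_entropy_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}
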