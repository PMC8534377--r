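#' Construct a weighted undirected network from an edge table
#'
#' The core data structure of the package: a node-labelled, undirected,
#' weighted network holding the symmetric weight matrix \eqn{W} and the node
#' strengths \eqn{K_i = \sum_j W_{ij}}. Edges are given as a data frame with
#' one row per undirected link; duplicate rows for the same unordered pair
#' are summed.
#'
#' Node order is canonical first-appearance order: nodes appear in the order
#' they are first seen scanning the edge table row-wise (`from` before `to`),
#' followed by any extra labels in `nodes`. All matrices returned by the
#' package are indexed in this order.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Labels are coerced to character. Self-loops are rejected.
#' @param nodes optional character vector of node labels; must contain every
#'   label used in `edges`, and may add isolated nodes.
#' @return An object of class `weighted_network` with fields `labels`,
#'   `weights` (symmetric N x N matrix with zero diagonal) and `strengths`.
#' @examples
#' net <- weighted_network(tibble::tibble(
#'   from = c("A", "B", "A"), to = c("B", "C", "C"),
#'   weight = c(1, 2, 0.5)
#' ))
#' network_strengths(net)
#' @export
weighted_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    rlang::abort("`edges` must have columns `from` and `to`.")
  }
  if (is.null(edges$weight)) edges$weight <- 1
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w))) rlang::abort("edge weights must be finite numbers")
  if (any(w < 0)) rlang::abort("negative edge weight")
  if (any(from == to)) {
    bad <- which(from == to)[1]
    rlang::abort(sprintf("self-loop on node '%s' (edge row %d)", from[bad], bad))
  }
  labels <- unique(c(rbind(from, to)))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    missing <- setdiff(labels, nodes)
    if (length(missing) > 0) {
      rlang::abort(sprintf("edge labels not in `nodes`: %s",
                           paste(missing, collapse = ", ")))
    }
    labels <- nodes
  }
  n <- length(labels)
  if (n < 2) rlang::abort("a network needs at least 2 nodes")
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  i <- match(from, labels)
  j <- match(to, labels)
  for (e in seq_along(i)) {
    W[i[e], j[e]] <- W[i[e], j[e]] + w[e]
    W[j[e], i[e]] <- W[j[e], i[e]] + w[e]
  }
  new_weighted_network(labels, W)
}

new_weighted_network <- function(labels, W) {
  structure(
    list(labels = labels, weights = W, strengths = rowSums(W)),
    class = "weighted_network"
  )
}

#' Validate the invariants of a weighted network
#'
#' Checks symmetry, zero diagonal, nonnegativity, strength consistency and
#' minimum size. Called internally by constructors; exported because null
#' models and tests assert it per realization.
#'
#' @param net a `weighted_network`
#' @param tol numerical tolerance for symmetry/strength checks
#' @return `net`, invisibly; aborts on violation.
#' @export
validate_weighted_network <- function(net, tol = 1e-10) {
  stopifnot(inherits(net, "weighted_network"))
  W <- net$weights
  n <- length(net$labels)
  if (n < 2) rlang::abort("invalid network: fewer than 2 nodes")
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n) {
    rlang::abort("invalid network: weight matrix dimension mismatch")
  }
  if (any(W < 0)) rlang::abort("invalid network: negative weights")
  if (any(diag(W) != 0)) rlang::abort("invalid network: nonzero diagonal (self-loops)")
  scale <- max(abs(W), 1)
  if (max(abs(W - t(W))) > tol * scale) {
    rlang::abort("invalid network: weight matrix not symmetric")
  }
  if (max(abs(net$strengths - rowSums(W))) > tol * max(net$strengths, 1)) {
    rlang::abort("invalid network: strengths inconsistent with weights")
  }
  invisible(net)
}

#' Coerce to a weighted network
#'
#' @param x a symmetric adjacency matrix (dimnames used as labels), an
#'   igraph graph (edge attribute `weight` used if present), or a data frame
#'   of edges (passed to [weighted_network()]).
#' @param ... passed to methods.
#' @return a `weighted_network`
#' @export
as_weighted_network <- function(x, ...) UseMethod("as_weighted_network")

#' @export
as_weighted_network.weighted_network <- function(x, ...) x

#' @rdname as_weighted_network
#' @param tol symmetry tolerance for matrix input
#' @export
as_weighted_network.matrix <- function(x, tol = 1e-8, ...) {
  if (nrow(x) != ncol(x)) rlang::abort("adjacency matrix must be square")
  scale <- max(abs(x), 1)
  if (max(abs(x - t(x))) > tol * scale) {
    rlang::abort("adjacency matrix asymmetric beyond tolerance")
  }
  if (any(x < 0)) rlang::abort("negative weight in adjacency matrix")
  if (any(diag(x) != 0)) rlang::abort("self-loop: nonzero diagonal in adjacency matrix")
  x <- (x + t(x)) / 2
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  dimnames(x) <- list(labels, labels)
  new_weighted_network(labels, x)
}

#' @export
as_weighted_network.igraph <- function(x, ...) {
  if (igraph::is_directed(x)) rlang::abort("directed graphs are not supported")
  W <- as.matrix(igraph::as_adjacency_matrix(
    x, attr = if ("weight" %in% igraph::edge_attr_names(x)) "weight" else NULL,
    sparse = TRUE
  ))
  labels <- igraph::vertex_attr(x, "name")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  diag(W) <- 0
  new_weighted_network(labels, W)
}

#' @export
as_weighted_network.data.frame <- function(x, ...) weighted_network(x, ...)

#' @export
print.weighted_network <- function(x, ...) {
  m <- sum(x$weights > 0) / 2
  cat(sprintf(
    "<weighted_network> %d nodes, %d edges, total weight %.6g\n",
    length(x$labels), m, sum(x$weights) / 2
  ))
  invisible(x)
}

# -- accessors ---------------------------------------------------------------

#' Accessors for weighted networks
#'
#' @param net a `weighted_network`
#' @return `network_adjacency()`: the symmetric weight matrix;
#'   `network_strengths()`: named strengths \eqn{K_i}; `network_labels()`:
#'   node labels; `network_size()`: node count; `edge_tibble()`: one row per
#'   undirected edge (`from`, `to`, `weight`), in canonical order.
#' @export
network_adjacency <- function(net) net$weights

#' @rdname network_adjacency
#' @export
network_strengths <- function(net) stats::setNames(net$strengths, net$labels)

#' @rdname network_adjacency
#' @export
network_labels <- function(net) net$labels

#' @rdname network_adjacency
#' @export
network_size <- function(net) length(net$labels)

#' @rdname network_adjacency
#' @export
edge_tibble <- function(net) {
  W <- net$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    from = net$labels[idx[, 1]],
    to = net$labels[idx[, 2]],
    weight = W[idx]
  )
}

#' Convert a weighted network to an igraph graph
#'
#' @param net a `weighted_network`
#' @return an undirected igraph graph with `weight` edge attribute
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Number of connected components (structural)
#'
#' @param net a `weighted_network`
#' @return integer component count
#' @export
network_components <- function(net) {
  igraph::count_components(as_igraph(net))
}

#' @rdname network_components
#' @export
is_connected_network <- function(net) network_components(net) == 1L

# -- file I/O ----------------------------------------------------------------

#' Read a weighted network from disk
#'
#' Two plain-text dialects are supported. `edgelist`: tab-separated, three
#' columns (node label, node label, positive weight), no header, `#` starts a
#' comment line. `adjacency`: dense CSV with a header row of node labels and
#' a symmetric nonnegative matrix body. Duplicate undirected edges in an edge
#' list are summed; self-loops are rejected in both dialects.
#'
#' @param path file path
#' @param format `"edgelist"` or `"adjacency"`
#' @return a `weighted_network`; node order is first-appearance (edgelist)
#'   or header order (adjacency).
#' @export
read_network <- function(path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "edgelist") {
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- which(keep)
    if (length(rows) == 0) rlang::abort(sprintf("no edges in %s", path))
    parts <- strsplit(lines[rows], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad) > 0) {
      rlang::abort(sprintf("malformed edge list row at line %d of %s",
                           rows[bad[1]], path))
    }
    m <- do.call(rbind, parts)
    w <- suppressWarnings(as.numeric(m[, 3]))
    if (any(is.na(w))) {
      rlang::abort(sprintf("non-numeric weight at line %d of %s",
                           rows[which(is.na(w))[1]], path))
    }
    if (any(w <= 0)) {
      rlang::abort(sprintf("non-positive weight at line %d of %s",
                           rows[which(w <= 0)[1]], path))
    }
    weighted_network(data.frame(from = m[, 1], to = m[, 2], weight = w))
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    A <- as.matrix(tab)
    rownames(A) <- colnames(A)
    storage.mode(A) <- "double"
    as_weighted_network(A)
  }
}

#' Write a weighted network to disk
#'
#' Inverse of [read_network()]: `read_network(write_network(net, p), fmt)`
#' reproduces `net` exactly (weights are printed with 17 significant digits,
#' enough to round-trip doubles bit-exactly).
#'
#' @param net a `weighted_network`
#' @param path file path
#' @param format `"edgelist"` or `"adjacency"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  validate_weighted_network(net)
  if (format == "edgelist") {
    ed <- edge_tibble(net)
    lines <- sprintf("%s\t%s\t%s", ed$from, ed$to,
                     formatC(ed$weight, format = "g", digits = 17))
    writeLines(lines, path)
  } else {
    W <- net$weights
    body <- apply(W, 1, function(r) {
      paste(formatC(r, format = "g", digits = 17), collapse = ",")
    })
    writeLines(c(paste(net$labels, collapse = ","), body), path)
  }
  invisible(path)
}
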