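#' Configuration for a multiscale sweep
#'
#' Bundles the knobs shared by [sweep_network()] and [corpus_summary()].
#' Defaults follow the analysis conventions of the package: rescaled scales
#' \eqn{\tau/\tau_d} log-spaced over \eqn{[10^{-10}, 10]}, unit initial
#' field \eqn{\phi_0}, 10 Louvain restarts, 20 RWCM realizations, and a
#' 500-node cap on corpus members (dense spectral machinery is cubic in N).
#'
#' @param ratio_bounds length-2 positive bounds on \eqn{\tau/\tau_d}
#' @param n_points grid resolution (>= 2)
#' @param phi0 initial field amount
#' @param seed master seed for Louvain restarts and nulls
#' @param n_restarts Louvain restarts per scale
#' @param n_null RWCM ensemble size
#' @param max_nodes refuse networks larger than this in sweeps/corpora
#' @return a `sweep_config` list
#' @export
sweep_config <- function(ratio_bounds = c(1e-10, 10), n_points = 100L,
                         phi0 = 1, seed = 1L, n_restarts = 10L,
                         n_null = 20L, max_nodes = 500L) {
  if (length(ratio_bounds) != 2 || !(ratio_bounds[1] > 0) ||
      !(ratio_bounds[2] > ratio_bounds[1])) {
    rlang::abort("`ratio_bounds` must be ordered positive bounds")
  }
  if (n_points < 2) rlang::abort("`n_points` must be >= 2")
  structure(
    list(ratio_bounds = as.numeric(ratio_bounds),
         n_points = as.integer(n_points), phi0 = phi0,
         seed = as.integer(seed), n_restarts = as.integer(n_restarts),
         n_null = as.integer(n_null), max_nodes = as.integer(max_nodes)),
    class = "sweep_config"
  )
}

#' Full multiscale sweep of one network
#'
#' Computes, on one shared spectral decomposition: the mean functional
#' strength curve, the Von Neumann entropy curve, the functional module
#' count curve, and the node-level partitions at every scale of the
#' rescaled grid. Deterministic given the configuration seed.
#'
#' @param net a connected `weighted_network` with `N <= config$max_nodes`
#' @param config a [sweep_config()]
#' @return an object of class `funcstate_sweep`: tibbles `strength`,
#'   `entropy`, `modules`, `partitions` (long: `ratio`, `tau`, `node`,
#'   `module`) and a `manifest` list (config echo, network facts).
#' @export
sweep_network <- function(net, config = sweep_config()) {
  net <- as_weighted_network(net)
  n <- network_size(net)
  if (n > config$max_nodes) {
    rlang::abort(sprintf(
      "network has %d nodes, over the %d-node cap; raise `max_nodes` in sweep_config() to proceed",
      n, config$max_nodes
    ))
  }
  dec <- spectral_decomposition(net)
  if (dec$n_components > 1L) {
    rlang::abort("cannot sweep a disconnected network: lambda_2 = 0, diffusion time undefined")
  }
  grid <- rescaled_tau_grid(dec, config$ratio_bounds[1], config$ratio_bounds[2],
                            config$n_points)
  strength <- mean_strength_curve(dec, grid, phi0 = config$phi0)
  entropy <- entropy_curve(dec, grid)
  parts <- purrr::map(grid$tau, function(tau) {
    functional_partition(dec, tau, phi0 = config$phi0, seed = config$seed,
                         n_restarts = config$n_restarts)
  })
  modules <- dplyr::bind_cols(
    grid,
    dplyr::bind_rows(purrr::map(parts, function(p) {
      tibble::tibble(n_modules = p$n_modules, modularity = p$modularity)
    }))
  )
  partitions <- dplyr::bind_rows(purrr::map2(seq_len(nrow(grid)), parts,
    function(i, p) {
      dplyr::mutate(tidy(p), ratio = grid$ratio[i], tau = grid$tau[i],
                    .before = 1)
    }))
  structure(
    list(
      strength = strength, entropy = entropy, modules = modules,
      partitions = partitions,
      manifest = list(
        n_nodes = n, n_edges = nrow(edge_tibble(net)),
        total_weight = sum(net$weights) / 2,
        diffusion_time = dec$diffusion_time,
        config = unclass(config)
      )
    ),
    class = "funcstate_sweep"
  )
}

#' @export
print.funcstate_sweep <- function(x, ...) {
  cat(sprintf(
    "<funcstate_sweep> N = %d, %d scales in tau/tau_d [%g, %g], tau_d = %.6g\n",
    x$manifest$n_nodes, nrow(x$entropy),
    x$manifest$config$ratio_bounds[1], x$manifest$config$ratio_bounds[2],
    x$manifest$diffusion_time
  ))
  invisible(x)
}

#' Write a sweep to a directory of CSVs plus a JSON manifest
#'
#' Emits `strength.csv`, `entropy.csv`, `modules.csv`, `partitions.csv` and
#' `manifest.json` (configuration, network facts and md5 checksums of the
#' tables). Identical sweeps write byte-identical tables, so a run is
#' reproducible from its manifest alone.
#'
#' @param x a `funcstate_sweep`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_sweep <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("strength", "entropy", "modules", "partitions")
  for (nm in tabs) {
    utils::write.csv(format_sweep_table(x[[nm]]), file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  sums <- tools::md5sum(file.path(dir, paste0(tabs, ".csv")))
  manifest <- c(x$manifest, list(checksums = as.list(stats::setNames(unname(sums), tabs))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

format_sweep_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 17))
  df
}

#' Summarise a corpus of networks on a shared rescaled grid
#'
#' Applies the size cap and connectivity requirement to each input, sweeps
#' the survivors, and averages entropy (raw and normalised) and module
#' counts at matched \eqn{\tau/\tau_d} ratios — each network is evaluated
#' at its own absolute \eqn{\tau = r\,\tau_d}, no interpolation. Also
#' returns the pooled modules-entropy relation fit.
#'
#' @param networks list of `weighted_network`s and/or file paths (edge-list
#'   files; named elements name the networks)
#' @param config a [sweep_config()]
#' @return an object of class `corpus_summary`: tibbles `summary`
#'   (per-ratio mean/sd columns with `n` networks), `per_network` (long:
#'   `network`, `ratio`, `entropy`, `entropy_norm`, `n_modules`),
#'   `rejected` (tibble of `network`, `reason`), and `fit`
#'   (a `modules_entropy_fit`).
#' @export
corpus_summary <- function(networks, config = sweep_config()) {
  if (length(networks) == 0) rlang::abort("empty corpus")
  nms <- names(networks)
  if (is.null(nms)) nms <- rep("", length(networks))
  loaded <- purrr::map(seq_along(networks), function(i) {
    x <- networks[[i]]
    nm <- if (nzchar(nms[[i]])) nms[[i]] else if (is.character(x)) basename(x)
          else paste0("network_", i)
    net <- if (is.character(x)) read_network(x) else as_weighted_network(x)
    list(name = nm, net = net)
  })
  rejected <- list()
  kept <- list()
  for (item in loaded) {
    n <- network_size(item$net)
    if (n > config$max_nodes) {
      rejected[[length(rejected) + 1]] <-
        tibble::tibble(network = item$name,
                       reason = sprintf("%d nodes > max_nodes = %d", n,
                                        config$max_nodes))
    } else if (!is_connected_network(item$net)) {
      rejected[[length(rejected) + 1]] <-
        tibble::tibble(network = item$name, reason = "disconnected")
    } else {
      kept[[length(kept) + 1]] <- item
    }
  }
  if (length(kept) == 0) {
    msg <- paste(purrr::map_chr(rejected, function(r) {
      paste0(r$network, ": ", r$reason)
    }), collapse = "; ")
    rlang::abort(paste0("no network survived the corpus filter — ", msg))
  }
  per_network <- dplyr::bind_rows(purrr::map(kept, function(item) {
    sw <- sweep_network(item$net, config)
    dplyr::mutate(
      dplyr::inner_join(sw$entropy,
                        dplyr::select(sw$modules, "ratio", "n_modules",
                                      "modularity"),
                        by = "ratio"),
      network = item$name, .before = 1
    )
  }))
  summary <- dplyr::summarise(
    dplyr::group_by(per_network, .data$ratio),
    entropy_mean = mean(.data$entropy),
    entropy_sd = stats::sd(.data$entropy),
    entropy_norm_mean = mean(.data$entropy_norm),
    entropy_norm_sd = stats::sd(.data$entropy_norm),
    n_modules_mean = mean(.data$n_modules),
    n_modules_sd = stats::sd(.data$n_modules),
    n = dplyr::n(),
    .groups = "drop"
  )
  fit <- modules_entropy_relation(per_network)
  structure(
    list(summary = summary, per_network = per_network,
         rejected = dplyr::bind_rows(rejected), fit = fit,
         n_kept = length(kept), n_rejected = length(rejected)),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("<corpus_summary> %d networks kept, %d rejected, %d ratios\n",
              x$n_kept, x$n_rejected, nrow(x$summary)))
  print(x$fit)
  invisible(x)
}
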