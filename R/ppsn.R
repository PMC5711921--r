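#' Build the participant-participant similarity network
#'
#' Connects two participants whenever their Euclidean distance in
#' normalized model-input space falls strictly below a threshold
#' (default 0.198). Nodes carry the participant id and bone status;
#' edges carry the distance as weight.
#'
#' @param cohort Cohort tibble.
#' @param features Model input columns used as space coordinates.
#' @param threshold Positive edge threshold on the distance.
#' @param normalization Optional pre-fitted `minmax_params`; fitted on
#'   `cohort` when `NULL`.
#' @return An undirected `igraph` graph with node attributes `name`
#'   (id) and `status`, edge attribute `weight` (distance), and graph
#'   attribute `threshold`.
#' @export
build_ppsn <- function(cohort, features, threshold = 0.198,
                       normalization = NULL) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  validate_cohort(cohort)
  if (is.null(normalization)) normalization <- fit_minmax(cohort, features)
  Xn <- as.matrix(normalize_features(normalization, cohort, features))
  d <- sqrt(sqdist(Xn, Xn))
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- cohort$id
  igraph::V(g)$status <- as.character(cohort$status)
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- d[cbind(ends[, 1], ends[, 2])]
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Density-peak clustering (Rodriguez-Laio)
#'
#' For each point, the local density `rho` counts neighbours within the
#' cutoff `d_c`, and `delta` is the distance to the nearest point of
#' higher density (for the densest point, the maximum distance).
#' Cluster centres are the points with the largest `gamma = rho * delta`
#' -- by default as many as fall before the largest gap in the sorted
#' `gamma` sequence -- and every remaining point joins the cluster of
#' its nearest higher-density point, swept in order of decreasing
#' density. Density ties are broken by position (lower index counts as
#' denser), so duplicated points join their representative's cluster.
#'
#' @param dist_mat Full symmetric distance matrix.
#' @param d_c Positive density cutoff; defaults to the PPSN edge
#'   threshold 0.198.
#' @param n_centers Number of cluster centres; `NULL` for the automatic
#'   largest-gap rule.
#' @return A `density_peak` tibble with per-point `rho`, `delta`,
#'   `gamma`, `is_center`, and `cluster`.
#' @export
density_peak <- function(dist_mat, d_c = 0.198, n_centers = NULL) {
  if (d_c <= 0) stop("d_c must be positive", call. = FALSE)
  dist_mat <- as.matrix(dist_mat)
  n <- nrow(dist_mat)
  rho <- rowSums(dist_mat < d_c) - 1L
  # order of decreasing density; ties -> lower index is "denser"
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n)
  nearest_denser <- integer(n)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (pos == 1L) {
      delta[i] <- if (n > 1L) max(dist_mat[i, ]) else 0
      nearest_denser[i] <- NA_integer_
    } else {
      prev <- ord[seq_len(pos - 1L)]
      j <- prev[which.min(dist_mat[i, prev])]
      delta[i] <- dist_mat[i, j]
      nearest_denser[i] <- j
    }
  }
  gamma <- rho * delta
  if (is.null(n_centers)) {
    gs <- sort(gamma, decreasing = TRUE)
    n_centers <- if (n == 1L || all(gs == 0)) 1L else {
      gaps <- gs[-n] - gs[-1]
      which.max(gaps)
    }
  }
  n_centers <- max(1L, min(n_centers, n))
  centers <- order(-gamma, seq_len(n))[seq_len(n_centers)]
  cluster <- rep(NA_integer_, n)
  cluster[centers] <- seq_len(n_centers)
  for (i in ord) {
    if (is.na(cluster[i])) cluster[i] <- cluster[nearest_denser[i]]
  }
  res <- tibble::tibble(point = seq_len(n), rho = as.numeric(rho),
                        delta = delta, gamma = gamma,
                        is_center = seq_len(n) %in% centers,
                        cluster = cluster)
  class(res) <- c("density_peak", class(res))
  res
}

#' Export a similarity graph to GraphML or SIF
#'
#' @param graph An `igraph` graph (e.g. from [build_ppsn()]).
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"` (simple interaction format,
#'   relation `sim`; isolated nodes written as bare names).
#' @return The path, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el) > 0) paste(el[, 1], "sim", el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(graph)$name, unique(c(el)))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Re-import a graph written by [export_graph()]
#'
#' @inheritParams export_graph
#' @return An undirected `igraph` graph.
#' @export
import_graph <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path)
    parts <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
    edges <- purrr::keep(parts, ~ length(.x) >= 3)
    singles <- purrr::keep(parts, ~ length(.x) == 1)
    el <- do.call(rbind, purrr::map(edges, ~ .x[c(1, 3)]))
    g <- igraph::make_empty_graph(directed = FALSE)
    verts <- unique(c(as.vector(el), unlist(singles)))
    g <- igraph::add_vertices(g, length(verts), name = verts)
    if (!is.null(el)) {
      g <- igraph::add_edges(g, t(matrix(match(el, verts), ncol = 2)))
    }
    g
  }
}
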