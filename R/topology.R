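# Global and focal-node topology diagnostics: the scale-free / small-world
# parameters used to contrast condition networks with the random baseline.

#' Log-log power-law fit of the degree distribution
#'
#' Least-squares line on (log10 degree, log10 frequency) over the
#' nonzero-frequency bins of the total-degree histogram of the undirected
#' projection ("node connectivity"). The quality criterion is the log-log
#' correlation R-squared, not a maximum-likelihood exponent.
#'
#' @param x A `signaling_network`, or a numeric vector of node degrees.
#' @param mode Degree mode for network input: `"total"` (undirected
#'   projection, default), `"in"` or `"out"`.
#' @return List with `exponent` (positive for a decaying distribution) and
#'   `r_squared`. Errors if fewer than 3 distinct positive degrees exist.
#' @export
degree_power_law_fit <- function(x, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  deg <- if (is.numeric(x)) {
    x
  } else {
    g <- as_igraph(x)
    if (mode == "total") {
      igraph::degree(igraph::as_undirected(g, mode = "collapse"))
    } else {
      igraph::degree(g, mode = mode)
    }
  }
  deg <- deg[deg > 0]
  tab <- table(deg)
  if (length(tab) < 3) {
    stop("power-law fit undefined: need >= 3 distinct positive degree values")
  }
  d <- log10(as.numeric(names(tab)))
  f <- log10(as.numeric(tab))
  fit <- stats::lm(f ~ d)
  # summary.lm warns on an exactly collinear (perfect) fit; that case is
  # legitimate here (e.g. data constructed on the line)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(exponent = -unname(stats::coef(fit)[2]), r_squared = r2)
}

#' Global topology report
#'
#' Mean clustering coefficient (average local transitivity of the undirected
#' projection, nodes of degree < 2 contributing 0), characteristic path
#' length (mean directed shortest-path hop count over reachable ordered
#' pairs), the full path-length distribution, degree histograms and - when
#' defined - the power-law fit.
#'
#' @param net A `signaling_network`.
#' @return List of class `topology_report`.
#' @export
global_topology <- function(net) {
  g <- as_igraph(net)
  if (igraph::gorder(g) == 0) stop("empty network")
  gu <- igraph::as_undirected(g, mode = "collapse")
  lc <- igraph::transitivity(gu, type = "local")
  lc[is.nan(lc)] <- 0
  d <- igraph::distances(g, mode = "out")
  finite <- d[is.finite(d) & d > 0]
  dist_tab <- if (length(finite)) table(finite) else table(numeric())
  pl <- tryCatch(degree_power_law_fit(net), error = function(e) NULL)
  structure(list(
    n_nodes = igraph::gorder(g),
    n_edges = igraph::gsize(g),
    clustering = mean(lc),
    char_path_length = if (length(finite)) mean(finite) else NA_real_,
    path_length_dist = data.frame(length = as.numeric(names(dist_tab)),
                                  count = as.vector(dist_tab)),
    degree_hist = data.frame(
      node = igraph::V(g)$name %||% as.character(seq_len(igraph::gorder(g))),
      degree_in = igraph::degree(g, mode = "in"),
      degree_out = igraph::degree(g, mode = "out"),
      degree_total = igraph::degree(g, mode = "all"),
      row.names = NULL),
    power_law = pl
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0("<topology_report> %d nodes, %d edges | clustering %.3f",
                     " | char path length %.3f\n"),
              x$n_nodes, x$n_edges, x$clustering, x$char_path_length))
  if (!is.null(x$power_law)) {
    cat(sprintf("  degree power law: exponent %.2f, R^2 %.3f\n",
                x$power_law$exponent, x$power_law$r_squared))
  }
  invisible(x)
}

#' Focal-node topology metrics
#'
#' Degrees, neighborhood connectivity (mean undirected degree of the node's
#' undirected neighbors), harmonic closeness (mean of 1/distance to every
#' other node, unreachable contributing 0, out-direction), normalized
#' directed betweenness, and mean shortest-path lengths from, to, and
#' through the node (paths with the node as intermediate on some shortest
#' route; the from/to and through variants are all reported because
#' "average path length through a node" is used with both meanings).
#'
#' @param net A `signaling_network`.
#' @param focal Accession of the node of interest.
#' @return Named list of metrics.
#' @export
focal_node_metrics <- function(net, focal) {
  g <- as_igraph(net)
  if (!(focal %in% igraph::V(g)$name)) {
    stop("focal node ", focal, " not in network")
  }
  n <- igraph::gorder(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  nb <- igraph::neighbors(gu, focal)
  neigh_conn <- if (length(nb)) mean(igraph::degree(gu, nb)) else NA_real_
  D <- igraph::distances(g, mode = "out")
  v <- which(igraph::V(g)$name == focal)
  dout <- D[v, -v]
  din <- D[-v, v]
  closeness <- if (n > 1) sum(1 / dout[dout > 0]) / (n - 1) else NA_real_
  betw <- if (n > 2) {
    igraph::betweenness(g, v = focal, directed = TRUE,
                        normalized = TRUE)
  } else {
    0
  }
  # shortest paths s->t (s,t != v) on which v lies: d(s,v) + d(v,t) = d(s,t)
  through <- {
    sv <- D[-v, v, drop = TRUE]
    vt <- D[v, -v, drop = TRUE]
    st <- D[-v, -v, drop = FALSE]
    cand <- outer(sv, vt, `+`)
    use <- is.finite(st) & st > 0 & is.finite(cand) & cand == st
    if (any(use)) mean(st[use]) else NA_real_
  }
  list(
    degree_in = unname(igraph::degree(g, focal, mode = "in")),
    degree_out = unname(igraph::degree(g, focal, mode = "out")),
    degree_total = unname(igraph::degree(g, focal, mode = "all")),
    neighborhood_connectivity = neigh_conn,
    closeness = unname(closeness),
    betweenness = unname(betw),
    mean_spl_from = if (any(is.finite(dout) & dout > 0)) {
      mean(dout[is.finite(dout) & dout > 0])
    } else NA_real_,
    mean_spl_to = if (any(is.finite(din) & din > 0)) {
      mean(din[is.finite(din) & din > 0])
    } else NA_real_,
    mean_spl_through = through
  )
}
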