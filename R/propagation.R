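# Signal propagation: random-walk-weighted shortest, k-shortest and
# near-shortest loopless paths from the focal kinase to its experimentally
# identified targets, and the union subnetwork they span.

#' Edge weighting schemes for path extraction
#'
#' Under the `random_walk` scheme each edge u->v weighs
#' `w(u->v) = log2(outdeg(u))`, so a path's total weight equals -log2 of the
#' probability that an unbiased random walk starting at its first node
#' follows exactly that edge sequence; the minimum-weight path is therefore
#' the maximum-probability walk. The `unit` scheme (w = 1) recovers plain
#' hop-shortest paths.
#'
#' @param net A `signaling_network`.
#' @param scheme `"random_walk"` (default) or `"unit"`.
#' @return Object of class `edge_weighting`: list with `scheme` and `weights`
#'   (one non-negative finite weight per edge, in igraph edge order).
#' @export
weight_edges <- function(net, scheme = c("random_walk", "unit")) {
  scheme <- match.arg(scheme)
  g <- as_igraph(net)
  w <- if (scheme == "unit") {
    rep(1, igraph::gsize(g))
  } else {
    outdeg <- igraph::degree(g, mode = "out")
    tails <- igraph::tail_of(g, igraph::E(g))  # edge sources
    log2(outdeg[tails])
  }
  stopifnot(all(is.finite(w)), all(w >= 0))
  structure(list(scheme = scheme, weights = unname(w)),
            class = "edge_weighting")
}

path_weight <- function(g, nodes, w) {
  if (length(nodes) < 2) return(0)
  eids <- igraph::get_edge_ids(
    g, as.vector(rbind(nodes[-length(nodes)], nodes[-1])))
  sum(w[eids])
}

# deterministic ordering key: weight, then lexicographic node sequence
path_key <- function(nodes) paste(nodes, collapse = "\r")

sssp <- function(g, w, from, to) {
  res <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, weights = w,
                           mode = "out", output = "vpath"))
  v <- res$vpath[[1]]
  if (length(v) == 0) return(NULL)
  nodes <- igraph::V(g)$name[v]
  list(nodes = nodes, weight = path_weight(g, nodes, w))
}

#' k-shortest and near-shortest loopless paths (Yen's algorithm)
#'
#' Enumerates simple paths from `source` to `target` in order of
#' non-decreasing total weight, keeping every path that is among the `k`
#' best OR whose weight is within `epsilon` of the minimum (the
#' near-shortest extension). Ties are broken deterministically by
#' lexicographic node sequence.
#'
#' @param net A `signaling_network`.
#' @param weights An [weight_edges()] object (or `NULL` for unit weights).
#' @param source,target Accessions present in the network.
#' @param k Number of ranked paths to keep (>= 1).
#' @param epsilon Near-shortest tolerance (>= 0); with the random-walk
#'   scheme, 1.0 admits paths down to half the best walk probability.
#' @return List of paths, each `list(nodes = <character>, weight = <num>)`,
#'   sorted by (weight, node sequence); empty if the target is unreachable.
#' @export
k_shortest_paths <- function(net, weights, source, target, k = 5,
                             epsilon = 1.0) {
  stopifnot(k >= 1, epsilon >= 0)
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  if (!(source %in% nm)) stop("source ", source, " not in network")
  if (!(target %in% nm)) stop("target ", target, " not in network")
  w <- if (is.null(weights)) rep(1, igraph::gsize(g)) else weights$weights
  stopifnot(length(w) == igraph::gsize(g))
  g <- igraph::set_edge_attr(g, ".w", value = w)

  first <- sssp(g, w, source, target)
  if (is.null(first)) return(list())
  A <- list(first)
  akeys <- path_key(first$nodes)
  B <- list()
  bkeys <- character()
  wmin <- first$weight
  repeat {
    last <- A[[length(A)]]$nodes
    # spur paths deviating from the most recently accepted path
    for (i in seq_len(length(last) - 1)) {
      root <- last[seq_len(i)]
      g2 <- g
      # remove edges used by already-accepted paths sharing this root
      drop_pairs <- NULL
      for (p in A) {
        pn <- p$nodes
        if (length(pn) > i && identical(pn[seq_len(i)], root)) {
          drop_pairs <- rbind(drop_pairs, c(pn[i], pn[i + 1]))
        }
      }
      eids <- unique(igraph::get_edge_ids(g2, as.vector(t(drop_pairs))))
      eids <- eids[eids > 0]
      if (length(eids)) g2 <- igraph::delete_edges(g2, eids)
      if (i > 1) g2 <- igraph::delete_vertices(g2, root[seq_len(i - 1)])
      spur <- sssp(g2, igraph::E(g2)$.w, root[i], target)
      if (!is.null(spur)) {
        nodes <- c(root[seq_len(i - 1)], spur$nodes)
        key <- path_key(nodes)
        if (!(key %in% akeys) && !(key %in% bkeys)) {
          B[[length(B) + 1]] <- list(nodes = nodes,
                                     weight = path_weight(g, nodes, w))
          bkeys <- c(bkeys, key)
        }
      }
    }
    if (length(B) == 0) break
    bw <- vapply(B, `[[`, numeric(1), "weight")
    bk <- vapply(B, function(p) path_key(p$nodes), character(1))
    j <- order(bw, bk)[1]
    nxt <- B[[j]]
    B <- B[-j]
    bkeys <- bkeys[bkeys != bk[j]]
    # stop once everything still pending is beyond both retention rules
    wk <- if (length(A) >= k) A[[k]]$weight else Inf
    if (nxt$weight > max(wmin + epsilon, wk)) break
    A[[length(A) + 1]] <- nxt
    akeys <- c(akeys, path_key(nxt$nodes))
    if (length(A) > 5000) break  # safety valve on pathological graphs
  }
  aw <- vapply(A, `[[`, numeric(1), "weight")
  ak <- vapply(A, function(p) path_key(p$nodes), character(1))
  ord <- order(aw, ak)
  A <- A[ord]
  aw <- aw[ord]
  keep <- seq_along(A) <= k | aw <= wmin + epsilon
  A[keep]
}

#' Propagation subnetwork from the focal kinase to its targets
#'
#' Runs [k_shortest_paths()] from `source` to every target of every
#' condition and unions the resulting paths into one subnetwork whose nodes
#' and edges are labeled with the set of conditions whose paths use them.
#' In `all_pathways` mode one shared prior-knowledge network (built from the
#' whole database, irrespective of enrichment) is used for all conditions,
#' which removes the reachability bias of per-condition networks; in
#' `enriched_only` mode `net` is a named list giving each condition its own
#' built network. A target that is a direct neighbor of the source always
#' contributes its one-edge path, whatever its weight rank.
#'
#' @param net A `signaling_network` (`all_pathways`) or a named list of them
#'   (`enriched_only`, names matching dataset names).
#' @param weights [weight_edges()] output for `net` (or `NULL` to compute
#'   with `scheme`); ignored (recomputed per network) in `enriched_only`
#'   mode.
#' @param source Focal kinase accession.
#' @param datasets List of `target_dataset` objects (one per condition).
#' @param k,epsilon Path retention parameters, see [k_shortest_paths()].
#' @param mode `"all_pathways"` or `"enriched_only"`.
#' @param scheme Weighting scheme used when `weights` is `NULL`.
#' @return Object of class `path_ensemble`: per-condition per-target path
#'   lists, unreachable targets, and the union `signaling_network` with
#'   semicolon-joined condition labels on nodes and edges.
#' @export
propagation_subnetwork <- function(net, weights = NULL, source, datasets,
                                   k = 5, epsilon = 1.0,
                                   mode = c("all_pathways", "enriched_only"),
                                   scheme = "random_walk") {
  mode <- match.arg(mode)
  conds <- vapply(datasets, `[[`, character(1), "name")
  nets <- if (mode == "all_pathways") {
    stats::setNames(rep(list(net), length(conds)), conds)
  } else {
    stopifnot(all(conds %in% names(net)))
    net[conds]
  }
  wts <- lapply(nets, function(nn) {
    if (mode == "all_pathways" && !is.null(weights)) weights
    else weight_edges(nn, scheme = scheme)
  })
  ensembles <- list()
  unreachable <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    g <- as_igraph(nets[[ci]])
    if (!(source %in% igraph::V(g)$name)) {
      stop("source ", source, " absent from network for ", cond)
    }
    targets <- setdiff(intersect(target_accessions(datasets[[ci]]),
                                 igraph::V(g)$name), source)
    per_target <- list()
    unreach <- character()
    for (tg in targets) {
      paths <- k_shortest_paths(nets[[ci]], wts[[ci]], source, tg,
                                k = k, epsilon = epsilon)
      # direct-phosphorylation shortcut: keep the 1-edge path if it exists
      if (igraph::are_adjacent(g, source, tg)) {
        key1 <- path_key(c(source, tg))
        if (!key1 %in% vapply(paths, function(p) path_key(p$nodes),
                              character(1))) {
          w1 <- path_weight(g, c(source, tg), wts[[ci]]$weights)
          paths <- c(paths, list(list(nodes = c(source, tg), weight = w1)))
          ord <- order(vapply(paths, `[[`, numeric(1), "weight"),
                       vapply(paths, function(p) path_key(p$nodes),
                              character(1)))
          paths <- paths[ord]
        }
      }
      if (length(paths) == 0) unreach <- c(unreach, tg)
      per_target[[tg]] <- paths
    }
    ensembles[[cond]] <- per_target
    unreachable[[cond]] <- unreach
  }
  sub <- paths_union_network(ensembles, source)
  structure(list(source = source, ensembles = ensembles,
                 unreachable = unreachable, subnetwork = sub,
                 params = list(k = k, epsilon = epsilon, mode = mode,
                               scheme = if (is.null(weights)) scheme
                                        else weights$scheme)),
            class = "path_ensemble")
}

# union subnetwork of all reported paths; origins = conditions using each
# node/edge (an edge is present iff some reported path uses it)
paths_union_network <- function(ensembles, source) {
  nodes <- list()
  edges <- list()
  for (cond in names(ensembles)) {
    for (paths in ensembles[[cond]]) {
      for (p in paths) {
        for (v in p$nodes) nodes[[v]] <- union(nodes[[v]], cond)
        if (length(p$nodes) > 1) {
          for (j in seq_len(length(p$nodes) - 1)) {
            key <- paste(p$nodes[j], p$nodes[j + 1], sep = "\r")
            edges[[key]] <- union(edges[[key]], cond)
          }
        }
      }
    }
  }
  if (length(nodes) == 0) {
    return(signaling_network(igraph::make_empty_graph(directed = TRUE),
                             condition = "propagation"))
  }
  nf <- data.frame(name = names(nodes),
                   origins = vapply(nodes, join_field, character(1)),
                   stringsAsFactors = FALSE)
  nf <- nf[order(nf$name), , drop = FALSE]
  ek <- do.call(rbind, strsplit(names(edges), "\r", fixed = TRUE))
  ef <- data.frame(from = ek[, 1], to = ek[, 2],
                   origins = vapply(edges, join_field, character(1)),
                   stringsAsFactors = FALSE)
  ef <- ef[order(ef$from, ef$to), , drop = FALSE]
  signaling_network(
    igraph::graph_from_data_frame(ef, directed = TRUE, vertices = nf),
    condition = "propagation")
}

#' @export
print.path_ensemble <- function(x, ...) {
  nr <- vapply(x$ensembles, function(e) sum(lengths(e) > 0), integer(1))
  nu <- lengths(x$unreachable)
  cat(sprintf("<path_ensemble> source %s | %s\n", x$source,
              paste(sprintf("%s: %d reachable, %d unreachable",
                            names(x$ensembles), nr, nu), collapse = " | ")))
  invisible(x)
}

#' Restrict a target dataset to a GO process group
#'
#' Keeps the targets directly annotated with any term of the named group
#' (e.g. cell adhesion and motility), so propagation can focus on a process.
#'
#' @param ds A `target_dataset`.
#' @param go A [go_annotation()] with configured groups.
#' @param group Group label.
#' @return The filtered `target_dataset` (warned if empty).
#' @export
restrict_targets_by_go <- function(ds, go, group) {
  if (!(group %in% names(go$groups))) {
    stop("unknown GO group '", group, "'; configured groups: ",
         paste(names(go$groups), collapse = ", "))
  }
  terms <- intersect(go$groups[[group]], names(go$terms))
  annotated <- unique(unlist(go$terms[terms]))
  keep <- ds$targets$accession %in% annotated
  if (!any(keep)) warning("no target of '", ds$name,
                          "' is annotated with group '", group, "'")
  target_dataset(ds$name, ds$targets[keep, , drop = FALSE],
                 direction_filtered = ds$direction_filtered)
}
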