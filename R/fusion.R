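# Network alignment: merging condition networks, presence labels
# (common / exclusive / shared-by-subset), per-node rewiring scores and
# proximal (first-neighbor) subnetworks.

# ---- attribute-preserving node/edge frames ---------------------------------

node_frame <- function(net) {
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  data.frame(
    name = nm,
    origins = igraph::vertex_attr(g, "origins") %||%
      rep(net$condition %||% NA_character_, length(nm)),
    targets = igraph::vertex_attr(g, "targets") %||% rep("", length(nm)),
    sites = igraph::vertex_attr(g, "sites") %||% rep("", length(nm)),
    stringsAsFactors = FALSE)
}

edge_frame <- function(net) {
  g <- as_igraph(net)
  el <- igraph::as_edgelist(g)
  ne <- nrow(el)
  data.frame(
    from = el[, 1], to = el[, 2],
    sign = igraph::edge_attr(g, "sign") %||% rep("unknown", ne),
    provenance = igraph::edge_attr(g, "provenance") %||% rep("", ne),
    dbs = igraph::edge_attr(g, "dbs") %||% rep("", ne),
    origins = igraph::edge_attr(g, "origins") %||%
      rep(net$condition %||% NA_character_, ne),
    stringsAsFactors = FALSE)
}

merge_semicolon <- function(x) join_field(unlist(lapply(x, split_field)))

# union of node/edge frames keyed by accession and ordered (from,to) pair
union_frames <- function(nets) {
  nf <- do.call(rbind, lapply(nets, node_frame))
  ef <- do.call(rbind, lapply(nets, edge_frame))
  nodes <- do.call(rbind, lapply(split(nf, nf$name), function(s) {
    data.frame(name = s$name[1], origins = merge_semicolon(s$origins),
               targets = merge_semicolon(s$targets),
               sites = merge_semicolon(s$sites), stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  edges <- if (nrow(ef)) {
    do.call(rbind, lapply(split(ef, paste(ef$from, ef$to, sep = "\r")),
                          function(s) {
      signs <- setdiff(unique(s$sign), "unknown")
      data.frame(from = s$from[1], to = s$to[1],
                 sign = if (length(signs) == 1) signs else "unknown",
                 provenance = merge_semicolon(s$provenance),
                 dbs = merge_semicolon(s$dbs),
                 origins = merge_semicolon(s$origins),
                 stringsAsFactors = FALSE)
    }))
  } else {
    ef
  }
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

frames_to_graph <- function(fr) {
  igraph::graph_from_data_frame(fr$edges, directed = TRUE,
                                vertices = fr$nodes)
}

#' Merge condition networks into one, keeping origin labels
#'
#' Node and edge union; every node and edge carries the set of condition
#' labels it came from (attribute `origins`, semicolon-joined). Target
#' annotations of the inputs are preserved. Merging a network with itself is
#' the identity.
#'
#' @param nets List of `signaling_network` objects (each with a condition
#'   label, or with `origins` attributes from a previous merge).
#' @param label Condition label of the merged network.
#' @return A [signaling_network()].
#' @export
merge_condition_networks <- function(nets, label) {
  stopifnot(length(nets) >= 1)
  fr <- union_frames(nets)
  signaling_network(frames_to_graph(fr), condition = label,
                    params = list(merged_from = vapply(nets, `[[`,
                                                       character(1), "condition")))
}

# ---- alignment -------------------------------------------------------------

#' Align two signaling networks into a fusion network
#'
#' Nodes correspond by accession and edges by their ordered (source, target)
#' pair, deliberately ignoring sign and database provenance so that edges are
#' not discriminated by their database of origin. The fusion network is the
#' union graph; every node and edge carries a presence set (`origins`) and a
#' label: `common` (present on every side's origin), `<side>-exclusive`, or
#' `shared` (present in a subset spanning both sides). Per-node rewiring
#' scores between the two sides are attached as node attribute `rewiring`.
#'
#' @param a,b `signaling_network` objects (typically built per condition, or
#'   merged with [merge_condition_networks()]).
#' @return A `fusion_network` object: the union igraph plus the origin label
#'   sets of each side.
#' @export
align_networks <- function(a, b) {
  side_a <- origin_labels(a)
  side_b <- origin_labels(b)
  fr <- union_frames(list(a, b))
  g <- frames_to_graph(fr)
  fn <- structure(list(graph = g, side_a = side_a, side_b = side_b,
                       label_a = a$condition, label_b = b$condition),
                  class = "fusion_network")
  all_origins <- c(side_a, side_b)
  g <- igraph::set_vertex_attr(g, "label", value = presence_label(
    igraph::vertex_attr(g, "origins"), side_a, side_b, all_origins,
    a$condition, b$condition))
  if (igraph::gsize(g) > 0) {
    g <- igraph::set_edge_attr(g, "label", value = presence_label(
      igraph::edge_attr(g, "origins"), side_a, side_b, all_origins,
      a$condition, b$condition))
  }
  rw <- rewiring_scores(fn, side_a, side_b)
  score <- rw$score[match(igraph::V(g)$name, rw$accession)]
  g <- igraph::set_vertex_attr(g, "rewiring", value = score)
  fn$graph <- g
  fn
}

origin_labels <- function(net) {
  g <- as_igraph(net)
  o <- igraph::vertex_attr(g, "origins")
  if (is.null(o)) net$condition else sort(unique(unlist(lapply(o, split_field))))
}

# label is a pure function of the presence set
presence_label <- function(origins, side_a, side_b, all_origins,
                           name_a, name_b) {
  vapply(origins, function(o) {
    pres <- split_field(o)
    if (setequal(pres, all_origins)) return("common")
    if (all(pres %in% side_a)) return(paste0(name_a, "-exclusive"))
    if (all(pres %in% side_b)) return(paste0(name_b, "-exclusive"))
    "shared"
  }, character(1))
}

#' @export
print.fusion_network <- function(x, ...) {
  cat(sprintf("<fusion_network> %s vs %s: %d nodes, %d edges\n",
              x$label_a, x$label_b, igraph::gorder(x$graph),
              igraph::gsize(x$graph)))
  invisible(x)
}

#' Per-node rewiring between two sides of a fusion network
#'
#' For node v let E_a(v) and E_b(v) be its incident directed edges present on
#' each side. The rewiring score is the Jaccard distance
#' `1 - |E_a n E_b| / |E_a u E_b|`: 0 for identical incidence, 1 for fully
#' disjoint incidence. Nodes with no incident edge on either side are
#' excluded (attribute `"excluded"`). An optional degree-corrected variant
#' (`score * sqrt(min(|E_a|, |E_b|))`) de-emphasizes low-degree nodes.
#'
#' @param fn A `fusion_network`.
#' @param side_a,side_b Character vectors of origin labels partitioning the
#'   fusion origins into the two compared sides (defaults: the aligned
#'   networks' own origin sets).
#' @param degree_corrected Add and sort by the degree-corrected score.
#' @return Data frame `accession`, `score`, `n_a`, `n_b`, `n_shared`,
#'   `n_union` (plus `score_corrected` when requested), sorted by descending
#'   score, ties broken by accession.
#' @export
rewiring_scores <- function(fn, side_a = fn$side_a, side_b = fn$side_b,
                            degree_corrected = FALSE) {
  g <- fn$graph
  el <- igraph::as_edgelist(g)
  origins <- lapply(igraph::edge_attr(g, "origins") %||%
                      rep("", igraph::gsize(g)), split_field)
  on_a <- vapply(origins, function(o) any(o %in% side_a), logical(1))
  on_b <- vapply(origins, function(o) any(o %in% side_b), logical(1))
  nodes <- igraph::V(g)$name
  rows <- lapply(nodes, function(v) {
    inc <- which(el[, 1] == v | el[, 2] == v)
    ea <- inc[on_a[inc]]
    eb <- inc[on_b[inc]]
    nu <- length(union(ea, eb))
    if (nu == 0) return(NULL)
    ns <- length(intersect(ea, eb))
    data.frame(accession = v, score = 1 - ns / nu,
               n_a = length(ea), n_b = length(eb),
               n_shared = ns, n_union = nu, stringsAsFactors = FALSE)
  })
  excluded <- nodes[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows) %||%
    data.frame(accession = character(), score = numeric(), n_a = integer(),
               n_b = integer(), n_shared = integer(), n_union = integer(),
               stringsAsFactors = FALSE)
  if (degree_corrected && nrow(out)) {
    out$score_corrected <- out$score * sqrt(pmin(out$n_a, out$n_b))
    out <- out[order(-out$score_corrected, out$accession), , drop = FALSE]
  } else if (nrow(out)) {
    out <- out[order(-out$score, out$accession), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Proximal (first-neighbor) subnetwork
#'
#' Induced subgraph on the seed nodes, their in- and out-neighbors, and all
#' interactions among them; annotations and presence labels are preserved.
#'
#' @param x A `signaling_network` or `fusion_network`.
#' @param seeds Accessions of the proteins of interest (all must be present).
#' @return Object of the same class as `x`.
#' @export
proximal_subnetwork <- function(x, seeds) {
  g <- as_igraph(x)
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing)) {
    stop("seed(s) not in network: ", paste(missing, collapse = ", "))
  }
  nb <- unique(unlist(lapply(seeds, function(s) {
    igraph::V(g)$name[igraph::neighbors(g, s, mode = "all")]
  })))
  sub <- igraph::induced_subgraph(g, union(seeds, nb))
  out <- x
  out$graph <- sub
  out
}
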