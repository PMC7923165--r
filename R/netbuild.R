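# Prior-knowledge signaling network construction from selected pathways,
# plus the random-protein baseline built through the identical procedure.

#' Construct a signaling network object
#'
#' Thin wrapper around a directed [igraph] graph with node annotations
#' (target membership, phosphosites, modifier and focal flags) and edge
#' provenance (sign, contributing pathways, source databases, condition
#' origins).
#'
#' @param graph A directed igraph object with named vertices.
#' @param condition Condition label.
#' @param random Whether this is a random-baseline network.
#' @param params Build-parameter list kept as metadata.
#' @export
signaling_network <- function(graph, condition = NA_character_,
                              random = FALSE, params = list()) {
  stopifnot(igraph::is_directed(graph) || igraph::gorder(graph) == 0)
  structure(list(graph = graph, condition = condition, random = random,
                 params = params),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("<signaling_network> %s: %d nodes, %d edges%s\n",
              x$condition, igraph::gorder(x$graph), igraph::gsize(x$graph),
              if (x$random) " (random baseline)" else ""))
  invisible(x)
}

#' Underlying igraph of a network object
#' @param x A `signaling_network` or `fusion_network`.
#' @export
as_igraph <- function(x) x$graph

#' Build a prior-knowledge signaling network from selected pathways
#'
#' Nodes are the union of the members of the selected pathways; edges are the
#' database interactions with both endpoints in that node set (including
#' edges spanning two different selected pathways, which is what creates the
#' hyperconnected cross-pathway core). Cleanup then removes self-loops,
#' merges duplicate directed edges (provenance and source-db union; an
#' activate-versus-inhibit conflict becomes sign `unknown`), and drops
#' isolated nodes.
#'
#' @param db A `pathway_db`.
#' @param selected Character vector of selected pathway ids (subset of
#'   `db$pathways$id`).
#' @param datasets List of `target_dataset` objects used to annotate nodes.
#' @param focal Optional focal kinase accession; an error is raised if it is
#'   absent after cleanup (such a network cannot seed propagation).
#' @param modifiers Optional named logical vector from [annotate_modifiers()].
#' @param condition Condition label stored in the metadata.
#' @return A [signaling_network()].
#' @export
build_network <- function(db, selected, datasets = list(), focal = NULL,
                          modifiers = NULL, condition = NA_character_) {
  unknown <- setdiff(selected, db$pathways$id)
  if (length(unknown)) stop("unknown pathway id(s): ",
                            paste(unknown, collapse = ", "))
  nodes <- sort(unique(unlist(
    db$pathways$members[db$pathways$id %in% selected])))
  ii <- db$interactions$from %in% nodes & db$interactions$to %in% nodes &
    db$interactions$from != db$interactions$to
  inter <- db$interactions[ii, , drop = FALSE]
  edges <- dedup_edges(inter, restrict_provenance = selected)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  iso <- igraph::degree(g, mode = "all") == 0
  g <- igraph::delete_vertices(g, which(iso))
  g <- annotate_nodes(g, datasets, focal = focal, modifiers = modifiers)
  if (!is.null(focal) && !(focal %in% igraph::V(g)$name)) {
    stop("focal node ", focal, " absent from the built network")
  }
  signaling_network(g, condition = condition,
                    params = list(selected = selected, focal = focal))
}

# collapse duplicate (from,to) rows; union provenance/sources, resolve signs
dedup_edges <- function(inter, restrict_provenance = NULL) {
  if (nrow(inter) == 0) {
    return(data.frame(from = character(), to = character(), sign = character(),
                      provenance = character(), dbs = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(inter$from, inter$to, sep = "\r")
  idx <- split(seq_len(nrow(inter)), key)
  idx <- idx[order(vapply(idx, min, integer(1)))]
  rows <- lapply(idx, function(ix) {
    signs <- setdiff(unique(inter$sign[ix]), "unknown")
    sign <- if (length(signs) == 1) signs else "unknown"
    prov <- unique(unlist(inter$provenance[ix]))
    if (!is.null(restrict_provenance)) prov <- intersect(prov, restrict_provenance)
    data.frame(from = inter$from[ix[1]], to = inter$to[ix[1]], sign = sign,
               provenance = join_field(prov),
               dbs = join_field(inter$source[ix]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$from, out$to), , drop = FALSE]
}

annotate_nodes <- function(g, datasets, focal = NULL, modifiers = NULL) {
  nm <- igraph::V(g)$name
  tlabels <- rep("", length(nm))
  slabels <- rep("", length(nm))
  for (ds in datasets) {
    j <- match(nm, ds$targets$accession)
    hit <- !is.na(j)
    tlabels[hit] <- ifelse(nzchar(tlabels[hit]),
                           paste(tlabels[hit], ds$name, sep = ";"), ds$name)
    sites <- vapply(j[hit], function(r)
      format_sites(ds$targets$sites[[r]], ds$targets$direct[[r]]), character(1))
    add <- nzchar(sites)
    slabels[hit][add] <- ifelse(nzchar(slabels[hit][add]),
                                paste(slabels[hit][add],
                                      paste0(ds$name, ":", sites[add]),
                                      sep = ";"),
                                paste0(ds$name, ":", sites[add]))
  }
  g <- igraph::set_vertex_attr(g, "targets", value = tlabels)
  g <- igraph::set_vertex_attr(g, "sites", value = slabels)
  g <- igraph::set_vertex_attr(g, "is_focal",
                               value = !is.null(focal) & nm == (focal %||% ""))
  if (!is.null(modifiers)) {
    g <- igraph::set_vertex_attr(g, "is_modifier",
                                 value = unname(modifiers[nm]) %in% TRUE)
  }
  g
}

#' Build a random-protein baseline network
#'
#' Samples `size` accessions uniformly from the database universe (seeded),
#' treats them as pseudo-targets and runs the identical
#' enrichment -> selection -> build procedure. Comparing its topology with a
#' real network's separates what the reconstruction method imposes from what
#' the data contribute.
#'
#' @param db A `pathway_db`.
#' @param size Number of random pseudo-targets; a sensible default is the
#'   mean target-list size across the real conditions.
#' @param seed Integer seed (the run is fully deterministic given it).
#' @param alpha Significance threshold forwarded to [select_pathways()].
#' @param pool Accession pool to sample from. Defaults to the database
#'   universe; pass the full proteome when one is available, since sampling
#'   "random proteins" from a space much larger than the curated pathway
#'   universe is what makes the baseline genuinely random.
#' @return A [signaling_network()] with `random = TRUE`; empty (with a
#'   warning) if the random proteins select no pathway.
#' @export
build_random_network <- function(db, size, seed, alpha = 0.05,
                                 pool = db$universe) {
  stopifnot(size <= length(pool))
  acc <- with_seed(seed, sample(pool, size))
  rows <- lapply(acc, function(a) phospho_target(a))
  ds <- target_dataset("random", do.call(rbind, rows) %||% NULL,
                       direction_filtered = TRUE)
  net <- suppressMessages({
    res <- suppressWarnings(fisher_enrichment(ds, db))
    sel <- select_pathways(res, ds, db, alpha = alpha)
    if (nrow(sel) == 0) {
      warning("random proteins selected no pathway; returning empty network")
      signaling_network(igraph::make_empty_graph(directed = TRUE))
    } else {
      build_network(db, sel$pathway, datasets = list(ds),
                    condition = "random")
    }
  })
  net$random <- TRUE
  net$params <- c(net$params, list(seed = seed, size = size, alpha = alpha))
  net
}

#' Write a network to GraphML (annotations kept) or SIF (topology only)
#' @param net A `signaling_network` or `fusion_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    sign <- igraph::edge_attr(g, "sign") %||% rep("unknown", nrow(el))
    writeLines(sprintf("%s\t%s\t%s", el[, 1], sign, el[, 2]), path)
  }
  invisible(path)
}
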