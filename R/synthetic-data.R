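# Synthetic ground-truth data: scale-free interactomes, overlapping pathway
# databases, target lists with planted enrichment, and condition pairs with
# planted edge rewiring. Every generator is fully deterministic under
# (spec, seed); per-purpose sub-seeds are derived by hashing so the streams
# stay independent.
#
# Design notes (expanded in the methods vignette):
# * The interactome is preferential attachment plus degree-weighted triadic
#   closure: pure preferential attachment is scale-free but has vanishing
#   clustering, while real interactomes (and the small-world contrast the
#   pipeline is meant to detect) need triangle-rich cores.
# * Pathways are breadth-limited random snowballs, so each is a locally
#   connected module rather than an immediate absorption of the hub core.
# * Enriched pathways are seeded at high-degree nodes: target-enriched
#   signaling pathways cluster around receptor-proximal hubs in real data.
# * Target-list background draws and the random-baseline pool cover the
#   whole interactome, not just pathway members, emulating random sampling
#   from a proteome much larger than the curated pathway universe.

#' Specification for the synthetic-data generators
#'
#' Defaults describe a desk-scale but realistically proportioned study: a
#' 2000-protein scale-free interactome, 40 overlapping pathways of 20-60
#' members, 3 pathways carrying planted target enrichment, 150-protein
#' target lists per condition drawn from the planted pathways with
#' probability `p_in`, and rewired condition pairs where half of the
#' incident edges of 10 planted nodes are redirected.
#'
#' @param n_proteins Interactome size.
#' @param attach_m Preferential-attachment out-links per new node.
#' @param n_pathways Number of generated pathways.
#' @param pathway_size Length-2 integer range of pathway sizes.
#' @param n_enriched Number of ground-truth enriched pathways.
#' @param p_in Probability a target is drawn from an enriched pathway's
#'   members; `p_out = 1 - p_in` is the background draw probability
#'   (uniform over the universe).
#' @param n_targets Targets per condition (after direction filtering).
#' @param n_conditions Number of conditions.
#' @param rewire_frac Fraction rho of a planted node's incident edges that
#'   are redirected in the rewired copy.
#' @param n_rewired Number of planted rewired nodes.
#' @param sign_probs Probabilities for edge signs activate/inhibit/unknown.
#' @param decoy_frac Fraction of additional down-regulated decoy targets
#'   (exercises the direction filter).
#' @param tri_frac Triangle-closing edges added per interactome node
#'   (degree-weighted triadic closure; gives the core realistic clustering).
#' @param snowball_breadth Maximum neighbors absorbed per expanded node in
#'   pathway snowball sampling (keeps pathways modular).
#' @param seed Master seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 2000, attach_m = 3, n_pathways = 40,
                           pathway_size = c(20, 60), n_enriched = 3,
                           p_in = 0.7, n_targets = 150, n_conditions = 3,
                           rewire_frac = 0.5, n_rewired = 10,
                           sign_probs = c(activate = 0.40, inhibit = 0.25,
                                          unknown = 0.35),
                           decoy_frac = 0.2, tri_frac = 0.5,
                           snowball_breadth = 3, seed = 1) {
  p_out <- 1 - p_in
  stopifnot(n_proteins >= attach_m + 1, n_pathways >= 1,
            tri_frac >= 0, snowball_breadth >= 1,
            length(pathway_size) == 2, pathway_size[1] >= 2,
            pathway_size[2] >= pathway_size[1],
            pathway_size[2] <= n_proteins,
            n_enriched >= 1, n_enriched <= n_pathways,
            p_in > 0, p_in <= 1, p_out >= 0, p_out < p_in,
            n_targets >= 1, n_conditions >= 1,
            rewire_frac >= 0, rewire_frac <= 1, n_rewired >= 0,
            abs(sum(sign_probs) - 1) < 1e-9, decoy_frac >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a scale-free directed interactome
#'
#' Directed preferential-attachment graph (each new node links to `attach_m`
#' existing nodes chosen proportionally to degree), re-oriented so signal
#' flows outward from the well-connected core, then augmented with
#' degree-weighted triangle-closing edges (`tri_frac` per node). The result
#' has the qualitative structure real condition networks show: a
#' power-law-like connectivity distribution and a clustered, hyperconnected
#' core.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed (defaults to the spec's master seed).
#' @return A [signaling_network()] with accession-style node names.
#' @export
gen_interactome <- function(spec, seed = spec$seed) {
  with_seed(sub_seed(seed, "interactome"), {
    g <- igraph::sample_pa(spec$n_proteins, power = 1, m = spec$attach_m,
                           directed = TRUE)
    # orient edges hub -> newer node: signal flows outward from the
    # well-connected core, as it does from a receptor-proximal kinase
    g <- igraph::reverse_edges(g)
    g <- close_triads(g, round(spec$tri_frac * spec$n_proteins))
    g <- igraph::set_vertex_attr(
      g, "name", value = sprintf("SP%05d", seq_len(spec$n_proteins)))
    g <- igraph::set_edge_attr(
      g, "sign",
      value = sample(names(spec$sign_probs), igraph::gsize(g),
                     replace = TRUE, prob = spec$sign_probs))
    signaling_network(g, condition = "interactome",
                      params = list(spec_seed = seed))
  })
}

# add n_tri edges closing open two-paths, centers drawn degree-weighted;
# pure preferential attachment has vanishing clustering, real interactomes
# (and the small-world diagnostics) do not
close_triads <- function(g, n_tri) {
  if (n_tri <= 0) return(g)
  n <- igraph::gorder(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  seen <- new.env(hash = TRUE, size = nrow(el) * 2L)
  for (i in seq_len(nrow(el))) {
    assign(paste(el[i, 1], el[i, 2]), TRUE, envir = seen)
  }
  deg <- lengths(adj)
  added <- 0L
  tries <- 0L
  new_edges <- integer(0)
  while (added < n_tri && tries < n_tri * 50L) {
    tries <- tries + 1L
    v <- sample.int(n, 1, prob = deg)
    nb <- adj[[v]]
    if (length(nb) < 2) next
    ab <- nb[sample.int(length(nb), 2)]
    if (ab[1] == ab[2]) next
    if (exists(paste(ab[1], ab[2]), envir = seen) ||
        exists(paste(ab[2], ab[1]), envir = seen)) next
    assign(paste(ab[1], ab[2]), TRUE, envir = seen)
    new_edges <- c(new_edges, ab)
    added <- added + 1L
  }
  igraph::add_edges(g, new_edges)
}

#' Generate a pathway database over an interactome
#'
#' Pathways are breadth-limited snowball samples: starting from a seed node,
#' at most `snowball_breadth` randomly chosen unvisited neighbors (undirected)
#' are absorbed per expanded node, up to a size drawn from the configured
#' range - so every pathway's members induce a weakly connected, locally
#' modular subgraph instead of instantly swallowing the hub core. The
#' `n_enriched` ground-truth enriched pathways are seeded at high-degree
#' core nodes, the way target-enriched signaling pathways concentrate around
#' receptor-proximal hubs. Interactions are the graph edges whose endpoints
#' share at least one pathway, with that pathway set as provenance.
#'
#' @param net Interactome from [gen_interactome()].
#' @param spec A [synthetic_spec()].
#' @param seed Seed.
#' @return List `db` (a [pathway_db()]) and `truth` (list with `enriched`).
#' @export
gen_pathway_db <- function(net, spec, seed = spec$seed) {
  g <- as_igraph(net)
  gu <- igraph::as_undirected(g, mode = "collapse")
  nm <- igraph::V(g)$name
  with_seed(sub_seed(seed, "pathways"), {
    sizes <- sample(seq(spec$pathway_size[1], spec$pathway_size[2]),
                    spec$n_pathways, replace = TRUE)
    deg <- igraph::degree(gu)
    core <- nm[order(-deg)][seq_len(max(20, round(0.025 * length(nm))))]
    enr_idx <- seq_len(spec$n_enriched)
    members <- lapply(seq_len(spec$n_pathways), function(j) {
      start <- if (j %in% enr_idx) sample(core, 1) else sample(nm, 1)
      snowball(gu, nm, start, sizes[j], spec$snowball_breadth)
    })
    ids <- sprintf("sim:PW%02d", seq_len(spec$n_pathways))
    pathways <- data.frame(id = ids, name = ids, source = "sim",
                           stringsAsFactors = FALSE)
    pathways$members <- members
    el <- igraph::as_edgelist(g)
    keep <- logical(nrow(el))
    prov <- vector("list", nrow(el))
    memb_idx <- lapply(members, function(m) nm %in% m)
    inm <- match(el[, 1], nm)
    out <- match(el[, 2], nm)
    for (j in seq_along(members)) {
      hit <- memb_idx[[j]][inm] & memb_idx[[j]][out]
      keep <- keep | hit
      for (e in which(hit)) prov[[e]] <- c(prov[[e]], ids[j])
    }
    interactions <- data.frame(from = el[keep, 1], to = el[keep, 2],
                               sign = igraph::E(g)$sign[keep],
                               source = "sim", stringsAsFactors = FALSE)
    interactions$provenance <- prov[keep]
    db <- pathway_db(pathways, interactions)
    truth <- list(enriched = ids[enr_idx])
    list(db = db, truth = truth)
  })
}

# breadth-limited snowball: absorb at most `breadth` random unvisited
# neighbors per expanded node until `size` nodes are collected
snowball <- function(gu, nm, start, size, breadth) {
  visited <- start
  queue <- start
  while (length(queue) && length(visited) < size) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- setdiff(nm[igraph::neighbors(gu, v)], visited)
    if (length(nb)) {
      take <- nb[sample.int(length(nb),
                            min(breadth, length(nb), size - length(visited)))]
      visited <- c(visited, take)
      queue <- c(queue, take)
    }
  }
  sort(visited)
}

#' Generate target lists with planted pathway enrichment
#'
#' Each target is drawn from the union of enriched-pathway members with
#' probability `p_in`, otherwise uniformly from the background pool;
#' duplicate draws are rejected. The pool defaults to the database universe
#' but the canonical study configuration passes the whole interactome
#' protein set: real screens identify plenty of proteins outside any curated
#' pathway. Phosphosites are random residue positions and all planted
#' targets are up-regulated; a `decoy_frac` fraction of additional
#' down-regulated decoys is appended so [normalize_targets()] has work to
#' do. Per-condition sub-seeds are derived from the master seed, so two
#' conditions from the same seed get different lists.
#'
#' @param db,truth Output of [gen_pathway_db()].
#' @param spec A [synthetic_spec()].
#' @param n_conditions Number of condition datasets.
#' @param seed Seed.
#' @param pool Background accession pool (default: the database universe).
#' @return List `datasets` (list of raw `target_dataset`s) and `truth`
#'   (input truth extended with per-condition `target_origin` vectors:
#'   generating pathway id, or `NA` for background draws).
#' @export
gen_target_lists <- function(db, truth, spec,
                             n_conditions = spec$n_conditions,
                             seed = spec$seed, pool = db$universe) {
  if (spec$n_targets > length(pool)) {
    stop("n_targets exceeds the accession pool size")
  }
  enriched_members <- db$pathways$members[match(truth$enriched,
                                                db$pathways$id)]
  datasets <- list()
  truth$target_origin <- list()
  for (ci in seq_len(n_conditions)) {
    name <- sprintf("cond%d", ci)
    with_seed(sub_seed(seed, "targets", ci), {
      acc <- character(0)
      origin <- character(0)
      while (length(acc) < spec$n_targets) {
        if (stats::runif(1) < spec$p_in) {
          pw <- sample(seq_along(enriched_members), 1)
          cand <- sample(enriched_members[[pw]], 1)
          org <- truth$enriched[pw]
        } else {
          cand <- sample(pool, 1)
          org <- NA_character_
        }
        if (!(cand %in% acc)) {
          acc <- c(acc, cand)
          origin <- c(origin, org)
        }
      }
      rows <- lapply(acc, function(a) {
        ns <- sample(1:2, 1)
        phospho_target(a, sites = sample(30:1300, ns),
                       direction = "up")
      })
      n_decoy <- floor(spec$decoy_frac * spec$n_targets)
      if (n_decoy > 0) {
        decoys <- sample(setdiff(pool, acc), n_decoy)
        rows <- c(rows, lapply(decoys, function(a) {
          phospho_target(a, sites = sample(30:1300, 1), direction = "down")
        }))
      }
      datasets[[name]] <- target_dataset(name, do.call(rbind, rows))
      truth$target_origin[[name]] <- stats::setNames(origin, acc)
    })
  }
  list(datasets = datasets, truth = truth)
}

#' Generate a condition pair with planted node rewiring
#'
#' Returns the input network and a copy in which, for each planted node, a
#' fraction `rewire_frac` of its incident edges is deleted and replaced by
#' edges to uniformly chosen new endpoints (no self-loops, no duplicate
#' edges); the rest of the structure is untouched. Planted nodes for which
#' `rewire_frac * degree < 1` are skipped with a warning.
#'
#' @param net A `signaling_network`.
#' @param spec A [synthetic_spec()].
#' @param seed Seed.
#' @param labels Condition labels given to the two copies.
#' @return List `net_a`, `net_b`, `truth` (list with `rewired`, the planted
#'   node accessions actually rewired).
#' @export
gen_rewired_pair <- function(net, spec, seed = spec$seed,
                             labels = c("a", "b")) {
  g <- as_igraph(net)
  nm <- igraph::V(g)$name
  stopifnot(spec$n_rewired <= length(nm))
  with_seed(sub_seed(seed, "rewire"), {
    planted <- sample(nm, spec$n_rewired)
    el <- igraph::as_edgelist(g)
    sign <- igraph::edge_attr(g, "sign") %||% rep("unknown", nrow(el))
    ekeys <- function() paste(el[, 1], el[, 2], sep = "\r")
    rewired <- character(0)
    for (v in planted) {
      inc <- which(el[, 1] == v | el[, 2] == v)
      n_rw <- floor(spec$rewire_frac * length(inc))
      if (spec$rewire_frac * length(inc) < 1) {
        warning("planted node ", v, " skipped: rho * degree < 1")
        next
      }
      chosen <- if (length(inc) == 1) inc else sample(inc, n_rw)
      keys <- ekeys()
      for (e in chosen) {
        for (try in 1:100) {
          cand <- sample(nm, 1)
          if (cand == v) next
          newkey <- if (el[e, 1] == v) paste(v, cand, sep = "\r") else
            paste(cand, v, sep = "\r")
          if (!(newkey %in% keys)) {
            if (el[e, 1] == v) el[e, 2] <- cand else el[e, 1] <- cand
            keys <- ekeys()
            break
          }
        }
      }
      rewired <- c(rewired, v)
    }
    ef <- data.frame(from = el[, 1], to = el[, 2], sign = sign,
                     stringsAsFactors = FALSE)
    gb <- igraph::graph_from_data_frame(ef, directed = TRUE,
                                        vertices = data.frame(name = nm))
    net_a <- net
    net_a$condition <- labels[1]
    net_b <- signaling_network(gb, condition = labels[2],
                               params = net$params)
    list(net_a = net_a, net_b = net_b,
         truth = list(rewired = sort(rewired)))
  })
}

#' Write a synthetic study to disk
#'
#' Emits the standard exchange formats every pipeline stage reads: one
#' target TSV per condition, GMT + SIF for the pathway database, and a JSON
#' ground-truth record.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_synthetic_study <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- gen_interactome(spec)
  pw <- gen_pathway_db(net, spec)
  tl <- gen_target_lists(pw$db, pw$truth, spec,
                         pool = igraph::V(as_igraph(net))$name)
  write_pathway_db(pw$db, file.path(out_dir, "pathways.gmt"),
                   file.path(out_dir, "interactions.sif"))
  for (ds in tl$datasets) {
    write_target_table(ds, file.path(out_dir, paste0(ds$name, "_targets.tsv")))
  }
  jsonlite::write_json(
    list(enriched = tl$truth$enriched,
         target_origin = lapply(tl$truth$target_origin, as.list)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, null = "null")
  invisible(list(interactome = net, db = pw$db, truth = tl$truth,
                 datasets = tl$datasets))
}
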