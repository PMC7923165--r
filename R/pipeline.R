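# End-to-end orchestration: normalize -> enrich/select -> build (+ random
# baseline) -> topology -> fuse/rewire -> propagate, with a reproducible run
# manifest. Stages are the exported module functions; the orchestrator only
# sequences them.

#' Build and validate a run configuration
#'
#' @param targets Named list: condition label -> target TSV path or
#'   `target_dataset`.
#' @param gmt,sif Pathway database export paths.
#' @param db_source Source label for the database.
#' @param focal Focal kinase accession (required).
#' @param out_dir Output directory.
#' @param alpha Selection significance threshold.
#' @param log_base Enrichment-score log base.
#' @param clustering List with `distance` and `linkage`.
#' @param sides List with `a` and `b`: condition labels forming the two
#'   fusion sides (default: all but the last condition vs the last).
#' @param propagation List with `k`, `epsilon`, `scheme`, `mode`.
#' @param random_size Random-baseline pseudo-target count (default: mean
#'   target-list size, computed after normalization).
#' @param seed Integer seed for the random baseline.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(targets, gmt, sif, db_source = "db", focal, out_dir,
                       alpha = 0.05, log_base = 10,
                       clustering = list(distance = "euclidean",
                                         linkage = "complete"),
                       sides = NULL,
                       propagation = list(k = 5, epsilon = 1.0,
                                          scheme = "random_walk",
                                          mode = "all_pathways"),
                       random_size = NULL, seed = 1) {
  if (missing(focal) || is.null(focal) || !nzchar(focal)) {
    stop("run_config: a focal kinase accession is required")
  }
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("run_config: 'targets' must be a named list (condition labels)")
  }
  for (p in Filter(is.character, targets)) {
    if (!file.exists(p)) stop("run_config: missing target table ", p)
  }
  for (p in c(gmt, sif)) {
    if (!file.exists(p)) stop("run_config: missing database file ", p)
  }
  if (is.null(sides)) {
    nm <- names(targets)
    sides <- list(a = nm[-length(nm)], b = nm[length(nm)])
  }
  stopifnot(all(unlist(sides) %in% names(targets)),
            length(sides$a) >= 1, length(sides$b) >= 1)
  structure(list(targets = targets, gmt = gmt, sif = sif,
                 db_source = db_source, focal = focal, out_dir = out_dir,
                 alpha = alpha, log_base = log_base, clustering = clustering,
                 sides = sides, propagation = propagation,
                 random_size = random_size, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; relative input
#' paths are resolved against the YAML file's directory.
#' @param path YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    ifelse(is.character(p) & !file.exists(p) & !startsWith(p, "/"),
           file.path(base, p), p)
  }
  for (f in c("gmt", "sif")) if (!is.null(y[[f]])) y[[f]] <- fix(y[[f]])
  if (!is.null(y$targets)) y$targets <- lapply(y$targets, fix)
  do.call(run_config, y)
}

#' Run the full comparative analysis
#'
#' Executes every stage on the configured inputs, writes all stage outputs
#' under `cfg$out_dir`, and records them (with MD5 checksums) in a JSON run
#' manifest. Given identical inputs and seeds the run is deterministic;
#' manifests differ only in their timestamp.
#'
#' @param cfg A [run_config()].
#' @return The manifest, invisibly; side effect: files in `cfg$out_dir`.
#' @export
run_compare <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  db <- stage("load", read_pathway_db(cfg$gmt, cfg$sif, cfg$db_source))
  datasets <- stage("load", lapply(names(cfg$targets), function(nm) {
    x <- cfg$targets[[nm]]
    if (inherits(x, "target_dataset")) x else read_target_table(x, nm)
  }))
  names(datasets) <- names(cfg$targets)

  datasets <- stage("normalize", lapply(datasets, function(ds) {
    if (ds$direction_filtered) ds else suppressMessages(normalize_targets(ds))
  }))

  enrich <- stage("enrich", lapply(datasets, function(ds) {
    suppressMessages(fisher_enrichment(ds, db, log_base = cfg$log_base))
  }))
  selections <- stage("select", lapply(names(datasets), function(nm) {
    select_pathways(enrich[[nm]], datasets[[nm]], db, alpha = cfg$alpha)
  }))
  names(selections) <- names(datasets)

  nets <- stage("build", lapply(names(datasets), function(nm) {
    build_network(db, selections[[nm]]$pathway, datasets = datasets[nm],
                  focal = cfg$focal, condition = nm)
  }))
  names(nets) <- names(datasets)
  rnd_size <- cfg$random_size %||%
    round(mean(vapply(datasets, function(d) nrow(d$targets), numeric(1))))
  random_net <- stage("build", suppressWarnings(
    build_random_network(db, rnd_size, seed = cfg$seed, alpha = cfg$alpha)))

  topo <- stage("topology", lapply(nets, function(nn) {
    rep <- global_topology(nn)
    rep$focal <- focal_node_metrics(nn, cfg$focal)
    rep
  }))
  topo$random <- stage("topology", if (igraph::gorder(random_net$graph) > 0) {
    global_topology(random_net)
  } else {
    NULL
  })

  fused <- stage("fuse", {
    side_a <- merge_condition_networks(nets[cfg$sides$a],
                                       paste(cfg$sides$a, collapse = "+"))
    side_b <- merge_condition_networks(nets[cfg$sides$b],
                                       paste(cfg$sides$b, collapse = "+"))
    align_networks(side_a, side_b)
  })
  rewiring <- stage("rewire", rewiring_scores(fused))

  full_net <- stage("propagate",
                    build_network(db, db$pathways$id, datasets = datasets,
                                  focal = cfg$focal, condition = "all_pathways"))
  paths <- stage("propagate", propagation_subnetwork(
    full_net, weights = NULL, source = cfg$focal, datasets = datasets,
    k = cfg$propagation$k, epsilon = cfg$propagation$epsilon,
    mode = "all_pathways", scheme = cfg$propagation$scheme))

  out <- function(f) file.path(cfg$out_dir, f)
  for (nm in names(enrich)) {
    utils::write.table(enrich[[nm]], out(paste0("enrich_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(selections[[nm]], out(paste0("selection_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(nets[[nm]], out(paste0("net_", nm, ".graphml")))
  }
  if (igraph::gorder(random_net$graph) > 0) {
    write_network(random_net, out("net_random.graphml"))
  }
  diff <- differential_enrichment(enrich)
  utils::write.table(diff, out("diff_enrich.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mat <- es_matrix(enrich)
  if (nrow(mat) >= 2 && ncol(mat) >= 2) {
    cl <- cluster_enrichment(mat, cfg$clustering$distance,
                             cfg$clustering$linkage)
    jsonlite::write_json(list(row_order = cl$row_order,
                              col_order = cl$col_order),
                         out("cluster.json"))
  }
  write_network(fused, out("fusion.graphml"))
  utils::write.table(rewiring, out("rewiring.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(topology_json(topo), out("topology.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(paths_json(paths), out("paths.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_network(paths$subnetwork, out("propagation.graphml"))

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- list(
    config = cfg[setdiff(names(cfg), "targets")],
    conditions = names(datasets),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(out(f))))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

topology_json <- function(topo) {
  lapply(topo, function(t) {
    if (is.null(t)) return(NULL)
    list(n_nodes = t$n_nodes, n_edges = t$n_edges,
         clustering = t$clustering, char_path_length = t$char_path_length,
         power_law = t$power_law, focal = t$focal %||% NULL)
  })
}

paths_json <- function(pe) {
  list(source = pe$source, params = pe$params,
       unreachable = pe$unreachable,
       paths = lapply(pe$ensembles, function(per_target) {
         lapply(per_target, function(paths) {
           lapply(paths, function(p) {
             list(nodes = p$nodes, weight = p$weight)
           })
         })
       }))
}
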