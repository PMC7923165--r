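# In-code fixtures: tiny target tables, pathway databases and toy graphs.

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tmp_target_tsv <- function(rows) {
  write_tmp(c("accession\tsymbol\tsites\tevidence\tdirection", rows))
}

# quick dataset from accession / direction vectors
quick_ds <- function(name, acc, direction = "up", sites = NULL,
                     filtered = TRUE) {
  direction <- rep_len(direction, length(acc))
  rows <- lapply(seq_along(acc), function(i) {
    phospho_target(acc[i], sites = sites[[i]] %||% integer(),
                   direction = direction[i])
  })
  target_dataset(name, do.call(rbind, rows), direction_filtered = filtered)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# pathway_db built directly from lists (single source by default)
quick_db <- function(members, edges = NULL, source = "kegg") {
  ids <- paste0(source, ":", names(members))
  pathways <- data.frame(id = ids, name = ids, source = source,
                         stringsAsFactors = FALSE)
  pathways$members <- unname(members)
  if (is.null(edges)) {
    interactions <- data.frame(from = character(), to = character(),
                               sign = character(), source = character(),
                               stringsAsFactors = FALSE)
    interactions$provenance <- list()
  } else {
    interactions <- data.frame(from = edges$from, to = edges$to,
                               sign = edges$sign %||%
                                 rep("unknown", length(edges$from)),
                               source = source, stringsAsFactors = FALSE)
    interactions$provenance <- lapply(seq_along(edges$from), function(i) {
      ids[vapply(pathways$members, function(m) {
        edges$from[i] %in% m && edges$to[i] %in% m
      }, logical(1))]
    })
  }
  pathway_db(pathways, interactions)
}

# toy signaling network from from/to vectors
toy_network <- function(from, to, condition = "toy", nodes = NULL,
                        sign = NULL) {
  nodes <- sort(unique(c(from, to, nodes)))
  ef <- data.frame(from = from, to = to,
                   sign = sign %||% rep("unknown", length(from)),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ef, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  signaling_network(g, condition = condition)
}

# seeded random simple digraph (no self loops, no duplicate edges)
random_digraph <- function(n, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample.int(nrow(pairs), min(n_edges, nrow(pairs))), ]
  toy_network(pick$from, pick$to, nodes = nodes)
}

syk_fixture_path <- function(f) {
  p <- system.file("extdata", "syk", f, package = "phosnet")
  if (!nzchar(p)) stop("fixture not found: ", f)
  p
}
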