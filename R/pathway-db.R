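# Pathway databases: pathway membership (GMT) plus directed signed
# interactions (SIF), with a per-source protein universe.

#' Default SIF relation-to-sign map
#'
#' Maps interaction relation tokens to the edge signs used throughout the
#' package. Unknown tokens map to `"unknown"` with a warning at read time.
#' @return Named character vector token -> sign.
#' @export
default_sign_map <- function() {
  c(activate = "activate", activates = "activate",
    phosphorylates = "activate",
    inhibit = "inhibit", inhibits = "inhibit",
    dephosphorylates = "inhibit",
    unknown = "unknown", interacts = "unknown")
}

#' Construct a pathway database
#'
#' @param pathways Data frame with columns `id`, `name`, `source` and a
#'   list-column `members` (character accession vectors).
#' @param interactions Data frame with columns `from`, `to`, `sign`, `source`
#'   and a list-column `provenance` (ids of pathways containing both
#'   endpoints; may be empty).
#' @return A `pathway_db` object; `universe` is the union of all pathway
#'   members and interaction endpoints.
#' @export
pathway_db <- function(pathways, interactions) {
  stopifnot(all(c("id", "name", "source", "members") %in% names(pathways)),
            all(c("from", "to", "sign", "source", "provenance") %in%
                  names(interactions)))
  if (anyDuplicated(pathways$id)) stop("pathway ids must be unique")
  universe <- sort(unique(c(unlist(pathways$members),
                            interactions$from, interactions$to)))
  bad <- setdiff(unlist(pathways$members), universe)
  stopifnot(length(bad) == 0)
  rownames(pathways) <- NULL
  rownames(interactions) <- NULL
  structure(list(pathways = pathways, interactions = interactions,
                 universe = universe),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways (%s), %d interactions, universe %d\n",
              nrow(x$pathways), paste(unique(x$pathways$source), collapse = ","),
              nrow(x$interactions), length(x$universe)))
  invisible(x)
}

#' Read a pathway database from GMT + SIF exports
#'
#' GMT lines are `pathway-id <TAB> name <TAB> member...`; SIF lines are
#' `source <TAB> relation <TAB> target`. Pathway ids are prefixed with the
#' source label (`kegg:...`) so several databases can be combined without
#' collisions. Each interaction's provenance is the set of pathways whose
#' member set contains both endpoints (possibly empty).
#'
#' @param gmt,sif File paths.
#' @param source Source database label (e.g. `"kegg"`, `"pc"`).
#' @param sign_map Relation token -> sign map; see [default_sign_map()].
#' @return A [pathway_db()].
#' @export
read_pathway_db <- function(gmt, sif, source, sign_map = default_sign_map()) {
  glines <- readLines(gmt)
  glines <- glines[nzchar(trimws(glines))]
  prows <- lapply(seq_along(glines), function(i) {
    f <- strsplit(glines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("%s line %d: GMT record needs >= 3 tab-separated fields",
                   gmt, i))
    }
    id <- f[1]
    if (!startsWith(id, paste0(source, ":"))) id <- paste0(source, ":", id)
    out <- data.frame(id = id, name = f[2], source = source,
                      stringsAsFactors = FALSE)
    out$members <- list(unique(f[-(1:2)]))
    out
  })
  pathways <- do.call(rbind, prows)

  slines <- readLines(sif)
  slines <- slines[nzchar(trimws(slines))]
  if (length(slines)) {
    sf <- do.call(rbind, strsplit(slines, "\t", fixed = TRUE))
    if (ncol(sf) < 3) stop(sif, ": SIF records need 3 tab-separated fields")
    rel <- sf[, 2]
    sign <- unname(sign_map[rel])
    if (anyNA(sign)) {
      warning("unknown relation token(s) mapped to sign 'unknown': ",
              paste(unique(rel[is.na(sign)]), collapse = ", "))
      sign[is.na(sign)] <- "unknown"
    }
    interactions <- data.frame(from = sf[, 1], to = sf[, 3], sign = sign,
                               source = source, stringsAsFactors = FALSE)
  } else {
    interactions <- data.frame(from = character(), to = character(),
                               sign = character(), source = character(),
                               stringsAsFactors = FALSE)
  }
  interactions$provenance <- interaction_provenance(interactions, pathways)
  pathway_db(pathways, interactions)
}

# pathways whose member set contains both endpoints of each interaction
interaction_provenance <- function(interactions, pathways) {
  lapply(seq_len(nrow(interactions)), function(i) {
    hit <- vapply(pathways$members, function(m) {
      interactions$from[i] %in% m && interactions$to[i] %in% m
    }, logical(1))
    pathways$id[hit]
  })
}

#' Combine pathway databases from several sources
#'
#' Pathway ids are already source-prefixed, so concatenation is collision-free;
#' the universe becomes the union. Enrichment and selection still operate
#' within each source independently (see [fisher_enrichment()]).
#' @param ... `pathway_db` objects.
#' @export
combine_pathway_dbs <- function(...) {
  dbs <- list(...)
  pathway_db(do.call(rbind, lapply(dbs, `[[`, "pathways")),
             do.call(rbind, lapply(dbs, `[[`, "interactions")))
}

#' Per-source protein universe
#' @param db A `pathway_db`.
#' @param source Source label.
#' @keywords internal
#' @export
db_universe <- function(db, source) {
  p <- db$pathways[db$pathways$source == source, , drop = FALSE]
  i <- db$interactions[db$interactions$source == source, , drop = FALSE]
  sort(unique(c(unlist(p$members), i$from, i$to)))
}

#' Write a pathway database back to GMT + SIF
#'
#' Inverse of [read_pathway_db()] for a single-source database (provenance is
#' recomputed from membership on re-read, so the round-trip is lossless).
#' @param db A `pathway_db`.
#' @param gmt,sif Output paths.
#' @export
write_pathway_db <- function(db, gmt, sif) {
  glines <- vapply(seq_len(nrow(db$pathways)), function(i) {
    paste(c(db$pathways$id[i], db$pathways$name[i],
            db$pathways$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(glines, gmt)
  slines <- sprintf("%s\t%s\t%s", db$interactions$from,
                    db$interactions$sign, db$interactions$to)
  writeLines(slines, sif)
  invisible(db)
}
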