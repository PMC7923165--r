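# Gene Ontology annotations: term -> accession sets read from GAF 2.x,
# plus named term groups used for modifier tagging and path restriction.

#' Construct a GO annotation object
#'
#' @param terms Named list: GO term id (`GO:NNNNNNN`) -> character vector of
#'   annotated accessions.
#' @param groups Named list: group label -> character vector of term ids
#'   (see [default_go_groups()]).
#' @export
go_annotation <- function(terms = list(), groups = list()) {
  if (length(terms) && !all(grepl("^GO:[0-9]{7}$", names(terms)))) {
    stop("term ids must look like GO:NNNNNNN")
  }
  bad <- unlist(groups)[!grepl("^GO:[0-9]{7}$", unlist(groups))]
  if (length(bad)) stop("malformed term id(s) in groups: ",
                        paste(bad, collapse = ", "))
  structure(list(terms = terms, groups = groups), class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("<go_annotation> %d terms, %d groups\n",
              length(x$terms), length(x$groups)))
  invisible(x)
}

#' Process/function term groups used for subnetwork extraction
#'
#' Groups of GO terms representing broad processes a signaling path can be
#' restricted to: cell adhesion and motility, cell growth and death, immunity
#' and inflammation, and cell differentiation.
#' @return Named list of GO term-id vectors.
#' @export
default_go_groups <- function() {
  list(
    cell_adhesion_motility = c("GO:0048870", "GO:0007155", "GO:0034330",
                               "GO:0022610", "GO:0060352", "GO:0030030"),
    cell_growth_death = c("GO:0008283", "GO:0007049", "GO:0008219",
                          "GO:0019835", "GO:0000920", "GO:0007569",
                          "GO:0051301", "GO:0060242"),
    immunity_inflammation = c("GO:0002376", "GO:0001906"),
    cell_differentiation = c("GO:0030154", "GO:0036166")
  )
}

#' Read GO annotations from a GAF 2.x file
#'
#' Uses column 2 (object id / accession), column 4 (qualifier; `NOT`
#' annotations are dropped) and column 5 (GO id). Comment lines start `!`.
#'
#' @param path GAF file path.
#' @param groups Term groups to attach (default [default_go_groups()]).
#' @return A [go_annotation()].
#' @export
read_gaf <- function(path, groups = default_go_groups()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) return(go_annotation(list(), groups))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(f) >= 5
  if (!all(ok)) stop(path, ": GAF records need >= 5 tab-separated fields")
  acc <- vapply(f, `[`, character(1), 2)
  qual <- vapply(f, `[`, character(1), 4)
  term <- vapply(f, `[`, character(1), 5)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  terms <- lapply(split(acc[keep], term[keep]), function(a) sort(unique(a)))
  go_annotation(terms, groups)
}

#' Flag phospho-tyrosine modifiers
#'
#' A protein is a phospho-tyrosine modifier if it carries the tyrosine kinase
#' (GO:0004713) or tyrosine phosphatase (GO:0004725) term, or appears in a
#' curated extension list (supplied as input; the curation itself is not
#' recomputed here).
#'
#' @param db A `pathway_db` whose universe is annotated.
#' @param go A [go_annotation()].
#' @param extension Character vector of additional modifier accessions.
#' @param terms GO term ids defining modifiers.
#' @return Named logical vector over `db$universe`.
#' @export
annotate_modifiers <- function(db, go, extension = character(),
                               terms = c("GO:0004713", "GO:0004725")) {
  annotated <- unique(unlist(go$terms[intersect(terms, names(go$terms))]))
  flags <- db$universe %in% annotated | db$universe %in% extension
  stats::setNames(flags, db$universe)
}
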