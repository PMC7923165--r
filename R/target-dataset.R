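# Target datasets: per-condition lists of (phospho)proteins identified as
# differentially phosphorylated or enriched after perturbing the focal kinase.

#' Construct a single phospho-target record
#'
#' @param accession UniProt-style accession (the identity key everywhere in
#'   this package; gene symbols are display-only).
#' @param symbol Optional gene symbol.
#' @param sites Integer vector of 1-based phosphosite residue positions (may
#'   be empty, e.g. for proteins identified only through interaction with
#'   phosphorylated partners).
#' @param direct Logical vector parallel to `sites`: `TRUE` for sites that can
#'   be directly phosphorylated by the focal kinase (rendered as `*` in
#'   per-pathway target tables).
#' @param evidence Either `"phosphosite"` (site-level evidence) or
#'   `"presence"` (protein co-purified with phosphorylated proteins, no site).
#' @param direction `"up"` or `"down"`: sign of the phosphorylation change in
#'   the kinase-positive condition.
#' @param manual `TRUE` for a-posteriori curated additions.
#' @return A one-row data frame suitable for [target_dataset()].
#' @export
phospho_target <- function(accession, symbol = NA_character_,
                           sites = integer(), direct = NULL,
                           evidence = c("phosphosite", "presence"),
                           direction = "up", manual = FALSE) {
  evidence <- match.arg(evidence)
  sites <- as.integer(sites)
  if (length(sites) && any(is.na(sites) | sites <= 0)) {
    stop("phosphosite positions must be positive integers")
  }
  if (is.null(direct)) direct <- rep(FALSE, length(sites))
  if (length(direct) != length(sites)) {
    stop("'direct' must be parallel to 'sites'")
  }
  df <- data.frame(accession = as.character(accession),
                   symbol = as.character(symbol),
                   evidence = evidence, direction = direction,
                   manual = manual, stringsAsFactors = FALSE)
  df$sites <- list(sites)
  df$direct <- list(as.logical(direct))
  df
}

#' Construct a target dataset for one condition
#'
#' @param name Condition / cell-line label.
#' @param targets Data frame with columns `accession`, `symbol`, `evidence`,
#'   `direction`, `manual` and list-columns `sites`, `direct` (one row per
#'   accession; rows sharing an accession are merged by site-set union).
#' @param direction_filtered Whether [normalize_targets()] has been applied.
#' @return A `target_dataset` object.
#' @export
target_dataset <- function(name, targets = NULL, direction_filtered = FALSE) {
  if (is.null(targets) || nrow(targets) == 0) {
    targets <- empty_targets_df()
  }
  stopifnot(all(c("accession", "symbol", "evidence", "direction",
                  "manual", "sites", "direct") %in% names(targets)))
  if (any(!nzchar(targets$accession) | is.na(targets$accession))) {
    stop("every target needs a non-empty accession")
  }
  targets <- merge_duplicate_accessions(targets)
  rownames(targets) <- NULL
  structure(list(name = name, targets = targets,
                 direction_filtered = isTRUE(direction_filtered)),
            class = "target_dataset")
}

empty_targets_df <- function() {
  df <- data.frame(accession = character(), symbol = character(),
                   evidence = character(), direction = character(),
                   manual = logical(), stringsAsFactors = FALSE)
  df$sites <- list()
  df$direct <- list()
  df
}

# union rows that share an accession: sites merged, per-site direct flags OR'd
merge_duplicate_accessions <- function(df) {
  if (!anyDuplicated(df$accession)) return(df)
  pieces <- split(seq_len(nrow(df)), df$accession)
  out <- lapply(pieces, function(ix) {
    sub <- df[ix, , drop = FALSE]
    sites <- unlist(sub$sites)
    direct <- unlist(sub$direct)
    agg <- if (length(sites)) {
      tapply(direct, sites, any)
    } else {
      NULL
    }
    row <- sub[1, , drop = FALSE]
    row$symbol <- sub$symbol[which(!is.na(sub$symbol))[1]] %||% NA_character_
    row$evidence <- if (any(sub$evidence == "phosphosite")) "phosphosite" else "presence"
    if (length(unique(sub$direction)) > 1) {
      warning("conflicting direction for ", row$accession, "; keeping first")
    }
    row$manual <- any(sub$manual)
    row$sites <- list(as.integer(names(agg) %||% character()))
    row$direct <- list(as.logical(agg %||% logical()))
    row
  })
  out <- do.call(rbind, out)
  out[order(match(out$accession, df$accession)), , drop = FALSE]
}

#' @export
print.target_dataset <- function(x, ...) {
  cat(sprintf("<target_dataset> %s: %d targets (%s)\n", x$name,
              nrow(x$targets),
              if (x$direction_filtered) "direction-filtered" else "raw"))
  invisible(x)
}

#' Accessions of a target dataset
#' @param ds A `target_dataset`.
#' @export
target_accessions <- function(ds) ds$targets$accession

#' Read a target table (TSV)
#'
#' Expected header columns: `accession`, `symbol`, `sites` (semicolon-separated
#' residue positions, a trailing `*` marking direct phosphorylation by the
#' focal kinase, may be blank), `evidence` (`phosphosite`/`presence`),
#' `direction` (`up`/`down`). An optional `manual` column survives round-trips.
#' Duplicate accessions are merged by site-set union.
#'
#' @param path TSV file path.
#' @param name Condition label for the resulting dataset.
#' @param strip_isoforms Drop `-N` isoform suffixes from accessions (default
#'   `TRUE`; pathway databases index canonical accessions).
#' @return A [target_dataset()].
#' @export
read_target_table <- function(path, name, strip_isoforms = TRUE) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"accession" %in% names(raw)) {
    stop("target table ", path, " lacks the required 'accession' column")
  }
  if (strip_isoforms && nrow(raw)) {
    stripped <- sub("-[0-9]+$", "", raw$accession)
    if (any(stripped != raw$accession)) {
      message(sum(stripped != raw$accession),
              " isoform suffix(es) stripped from accessions")
      raw$accession <- stripped
    }
  }
  n <- nrow(raw)
  if (n == 0) return(target_dataset(name))
  sym <- if ("symbol" %in% names(raw)) raw$symbol else rep(NA_character_, n)
  sitestr <- if ("sites" %in% names(raw)) raw$sites else rep("", n)
  dir <- if ("direction" %in% names(raw)) raw$direction else rep("up", n)
  man <- if ("manual" %in% names(raw)) {
    tolower(raw$manual) %in% c("true", "1", "yes")
  } else {
    rep(FALSE, n)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    parsed <- parse_sites(sitestr[i], row = i)
    ev <- if ("evidence" %in% names(raw) && nzchar(raw$evidence[i])) {
      raw$evidence[i]
    } else if (length(parsed$sites)) "phosphosite" else "presence"
    rows[[i]] <- phospho_target(raw$accession[i], sym[i],
                                sites = parsed$sites, direct = parsed$direct,
                                evidence = ev, direction = dir[i],
                                manual = man[i])
  }
  target_dataset(name, do.call(rbind, rows))
}

# "759*;550" -> sites c(759,550), direct c(TRUE,FALSE)
parse_sites <- function(s, row = NA) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(list(sites = integer(), direct = logical()))
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  ok <- grepl("^[0-9]+\\*?$", toks)
  if (!all(ok)) {
    stop(sprintf("row %s: non-integer phosphosite token(s): %s",
                 row, paste(toks[!ok], collapse = ", ")))
  }
  list(sites = as.integer(sub("\\*$", "", toks)),
       direct = grepl("\\*$", toks))
}

format_sites <- function(sites, direct, sep = ";", star = "*") {
  if (!length(sites)) return("")
  paste0(sites, ifelse(direct, star, ""), collapse = sep)
}

#' Write a target table (TSV)
#'
#' Inverse of [read_target_table()]; the round-trip is lossless.
#' @param ds A `target_dataset`.
#' @param path Output TSV path.
#' @export
write_target_table <- function(ds, path) {
  df <- data.frame(accession = ds$targets$accession,
                   symbol = ds$targets$symbol,
                   sites = mapply(format_sites, ds$targets$sites,
                                  ds$targets$direct),
                   evidence = ds$targets$evidence,
                   direction = ds$targets$direction,
                   manual = ds$targets$manual,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep only targets whose phosphorylation increased
#'
#' Datasets from different studies mix up- and down-regulated sites; to
#' compare conditions on an equal footing only proteins whose phosphorylation
#' rises in the kinase-positive condition are retained.
#'
#' @param ds A `target_dataset`.
#' @return The filtered dataset with `direction_filtered = TRUE`. Applying the
#'   function twice is a warned no-op.
#' @export
normalize_targets <- function(ds) {
  if (ds$direction_filtered) {
    warning("dataset '", ds$name, "' is already direction-filtered; no-op")
    return(ds)
  }
  keep <- ds$targets$direction == "up"
  message(sprintf("normalize_targets[%s]: kept %d, dropped %d",
                  ds$name, sum(keep), sum(!keep)))
  if (!any(keep) && nrow(ds$targets) > 0) {
    warning("dataset '", ds$name, "' has no up-regulated targets")
  }
  target_dataset(ds$name, ds$targets[keep, , drop = FALSE],
                 direction_filtered = TRUE)
}

#' Add curated a-posteriori targets
#'
#' Known direct substrates missing from a screen (e.g. ezrin in the breast
#' cancer datasets) can be appended from configuration; they are flagged as
#' manual and merged by accession with anything already present.
#'
#' @param ds A `target_dataset`.
#' @param additions Data frame of [phospho_target()] rows (rbind-ed).
#' @export
add_manual_targets <- function(ds, additions) {
  if (is.null(additions) || nrow(additions) == 0) return(ds)
  additions$manual <- TRUE
  additions$direction <- "up"
  target_dataset(ds$name, rbind(ds$targets, additions),
                 direction_filtered = ds$direction_filtered)
}

#' Accessions shared by two target datasets
#'
#' @param a,b `target_dataset` objects.
#' @return Character vector of accessions present in both.
#' @export
shared_targets <- function(a, b) {
  sort(intersect(target_accessions(a), target_accessions(b)))
}
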