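# Pathway over-representation scoring and selection.
#
# The enrichment score of a pathway is ES = -log10(p) where p is the
# one-sided Fisher exact (hypergeometric upper-tail) probability of drawing
# at least k targets in a pathway of size n, given K targets among the N
# proteins of the source database's universe:
#
#   p = P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)

#' Pathway over-representation by one-sided Fisher exact test
#'
#' Targets outside the database universe are dropped (and counted). The
#' universe, and therefore N and K, is per source database: the background is
#' everything the source database knows about, not the detected proteome.
#'
#' @param ds A `target_dataset`.
#' @param db A `pathway_db` (possibly multi-source).
#' @param log_base Base of the enrichment-score logarithm (default 10).
#' @param p_adjust `"none"` (default; the selection rule uses raw p-values)
#'   or `"BH"` for Benjamini-Hochberg, reported in column `p_adj`.
#' @param two_sided Use the two-sided Fisher test instead of the
#'   over-representation tail (default `FALSE`).
#' @return Data frame with one row per pathway, columns `pathway`, `source`,
#'   `name`, `N`, `K`, `n`, `k`, `p`, `p_adj`, `es`, sorted by ascending `p`
#'   (ties: descending `k`, then pathway id).
#' @export
fisher_enrichment <- function(ds, db, log_base = 10,
                              p_adjust = c("none", "BH"), two_sided = FALSE) {
  p_adjust <- match.arg(p_adjust)
  acc <- target_accessions(ds)
  dropped <- setdiff(acc, db$universe)
  if (length(dropped)) {
    message(sprintf("fisher_enrichment[%s]: %d target(s) outside universe dropped",
                    ds$name, length(dropped)))
  }
  if (length(acc) == 0 || length(intersect(acc, db$universe)) == 0) {
    warning("empty target set for '", ds$name, "': all p-values are 1")
  }
  sources <- unique(db$pathways$source)
  res <- lapply(sources, function(src) {
    uni <- db_universe(db, src)
    N <- length(uni)
    targ <- intersect(acc, uni)
    K <- length(targ)
    sel <- db$pathways$source == src
    n <- lengths(db$pathways$members[sel])
    if (any(n > N)) stop("pathway larger than its source universe")
    k <- vapply(db$pathways$members[sel],
                function(m) length(intersect(m, targ)), integer(1))
    p <- if (two_sided) {
      vapply(seq_along(n), function(i) {
        stats::fisher.test(matrix(c(k[i], K - k[i], n[i] - k[i],
                                    N - K - n[i] + k[i]), 2))$p.value
      }, numeric(1))
    } else {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    p <- pmin(p, 1)
    data.frame(pathway = db$pathways$id[sel], source = src,
               name = db$pathways$name[sel],
               N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- if (p_adjust == "BH") {
    stats::ave(res$p, res$source, FUN = function(x) stats::p.adjust(x, "BH"))
  } else {
    res$p
  }
  res$es <- -log(res$p, base = log_base)
  res$es[res$p >= 1] <- 0  # k = 0 (or degenerate) => no enrichment
  res <- res[order(res$p, -res$k, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select pathways: significance plus target coverage
#'
#' Within each source database: (1) keep every pathway with `p < alpha`;
#' (2) for targets not contained in any selected pathway, add covering
#' pathways greedily in ascending-p order (ties: larger overlap k, then
#' pathway id) until no further target can be covered. Targets contained in
#' no pathway at all are reported via the `"uncovered"` attribute.
#'
#' @param results Output of [fisher_enrichment()].
#' @param ds The `target_dataset` the results were computed from.
#' @param db The `pathway_db`.
#' @param alpha Significance threshold on the (raw) p-value, default 0.05.
#' @param use_adjusted Threshold `p_adj` instead of `p`.
#' @return Data frame `pathway`, `source`, `reason` (`significant` or
#'   `coverage`); attribute `uncovered` lists accessions no pathway contains.
#' @export
select_pathways <- function(results, ds, db, alpha = 0.05,
                            use_adjusted = FALSE) {
  acc <- target_accessions(ds)
  pcol <- if (use_adjusted) "p_adj" else "p"
  out <- lapply(unique(results$source), function(src) {
    r <- results[results$source == src, , drop = FALSE]
    r <- r[order(r[[pcol]], -r$k, r$pathway), , drop = FALSE]
    members <- db$pathways$members[match(r$pathway, db$pathways$id)]
    targ <- intersect(acc, db_universe(db, src))
    sig <- r[[pcol]] < alpha
    covered <- unique(unlist(members[sig]))
    uncovered <- setdiff(targ, covered)
    reason <- ifelse(sig, "significant", NA_character_)
    for (i in which(!sig)) {
      if (!length(uncovered)) break
      gain <- intersect(members[[i]], uncovered)
      if (length(gain)) {
        reason[i] <- "coverage"
        uncovered <- setdiff(uncovered, gain)
      }
    }
    keep <- !is.na(reason)
    list(sel = data.frame(pathway = r$pathway[keep],
                          source = rep(src, sum(keep)),
                          reason = reason[keep], stringsAsFactors = FALSE),
         uncovered = uncovered)
  })
  sel <- do.call(rbind, lapply(out, `[[`, "sel"))
  rownames(sel) <- NULL
  attr(sel, "uncovered") <- sort(unique(unlist(lapply(out, `[[`, "uncovered"))))
  sel
}

#' Differential enrichment across conditions
#'
#' Pathways are scored in every condition (a pathway missing from one
#' condition's results gets ES = 0), sorted by descending mean ES, and each
#' condition's deviation from that mean is attached; per-pathway deviations
#' sum to zero by construction.
#'
#' @param per_condition Named list (condition -> [fisher_enrichment()]
#'   output); at least two conditions.
#' @return Data frame `pathway`, `mean_es`, then `es_<cond>` and `dev_<cond>`
#'   columns, sorted by descending `mean_es`.
#' @export
differential_enrichment <- function(per_condition) {
  if (length(per_condition) < 2) {
    stop("differential enrichment needs at least two conditions")
  }
  mat <- es_matrix(per_condition)
  mean_es <- rowMeans(mat)
  dev <- mat - mean_es
  out <- data.frame(pathway = rownames(mat), mean_es = mean_es,
                    stringsAsFactors = FALSE)
  for (cn in colnames(mat)) out[[paste0("es_", cn)]] <- mat[, cn]
  for (cn in colnames(mat)) out[[paste0("dev_", cn)]] <- dev[, cn]
  out <- out[order(-out$mean_es, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment-score matrix (pathways x conditions), zero-filled
#' @param per_condition Named list of [fisher_enrichment()] outputs.
#' @export
es_matrix <- function(per_condition) {
  ids <- sort(unique(unlist(lapply(per_condition, `[[`, "pathway"))))
  mat <- sapply(per_condition, function(r) {
    stats::setNames(r$es, r$pathway)[ids]
  })
  mat[is.na(mat)] <- 0
  rownames(mat) <- ids
  mat
}

#' Bidirectional hierarchical clustering of enrichment scores
#'
#' Agglomerative clustering of the pathway x condition ES matrix along both
#' axes. With a constant matrix all distances are zero and `stats::hclust`
#' merges in input order, which is the documented deterministic tie-break.
#'
#' @param mat Numeric matrix (pathways x conditions), at least 2x2.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `rows`, `cols` (hclust trees) and `row_order`,
#'   `col_order` (leaf label orders).
#' @export
cluster_enrichment <- function(mat, distance = "euclidean",
                               linkage = "complete") {
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need a matrix of at least 2x2")
  hr <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  hc <- stats::hclust(stats::dist(t(mat), method = distance), method = linkage)
  list(rows = hr, cols = hc,
       row_order = rownames(mat)[hr$order],
       col_order = colnames(mat)[hc$order])
}

#' Per-pathway target table
#'
#' One row per pathway member that is a target in at least one dataset, with
#' per-dataset evidence: `"X"` for presence-level evidence, otherwise the
#' phosphosites (direct sites starred), e.g. `"759 * ; 550"`.
#'
#' @param pathway_id Pathway id present in `db`.
#' @param datasets List of `target_dataset` objects.
#' @param db The `pathway_db`.
#' @return Data frame with columns `symbol`, `accession` and one column per
#'   dataset name.
#' @export
pathway_target_table <- function(pathway_id, datasets, db) {
  i <- match(pathway_id, db$pathways$id)
  if (is.na(i)) stop("unknown pathway id: ", pathway_id)
  members <- db$pathways$members[[i]]
  cells <- lapply(datasets, function(ds) {
    j <- match(members, ds$targets$accession)
    vapply(seq_along(members), function(m) {
      if (is.na(j[m])) return("")
      if (ds$targets$evidence[j[m]] == "presence") return("X")
      format_sites(ds$targets$sites[[j[m]]], ds$targets$direct[[j[m]]],
                   sep = " ; ", star = " *")
    }, character(1))
  })
  names(cells) <- vapply(datasets, `[[`, character(1), "name")
  hit <- Reduce(`|`, lapply(cells, nzchar))
  sym <- rep(NA_character_, length(members))
  for (ds in datasets) {
    j <- match(members, ds$targets$accession)
    sym[is.na(sym) & !is.na(j)] <- ds$targets$symbol[j[is.na(sym) & !is.na(j)]]
  }
  out <- data.frame(symbol = sym, accession = members,
                    stringsAsFactors = FALSE)
  for (nm in names(cells)) out[[nm]] <- cells[[nm]]
  out <- out[hit, , drop = FALSE]
  out <- out[order(out$symbol, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
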