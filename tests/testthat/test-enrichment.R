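# Over-representation scoring, selection rule, differential enrichment,
# clustering, and per-pathway target tables.

test_that("Fisher tail probability matches the printed worked example", {
  # N=20 proteins, K=4 targets, pathway of n=5 with k=3 targets:
  # p = (C(4,3) C(16,2) + C(4,4) C(16,1)) / C(20,5) = 496/15504
  db <- quick_db(list(pw1 = sprintf("P%02d", 1:5)))
  # pad the universe to 20 with a second pathway
  db <- quick_db(list(pw1 = sprintf("P%02d", 1:5),
                      pw2 = sprintf("P%02d", 1:20)))
  ds <- quick_ds("x", c("P01", "P02", "P03", "P10"))
  res <- fisher_enrichment(ds, db)
  expect_equal(res$p[res$pathway == "kegg:pw1"], 496 / 15504,
               tolerance = 1e-12)
  expect_equal(res$p[res$pathway == "kegg:pw1"],
               oracle_hyper_tail(20, 4, 5, 3), tolerance = 1e-12)
  # pathway spanning the whole universe is never enriched
  expect_equal(res$p[res$pathway == "kegg:pw2"], 1)
  expect_equal(res$es[res$pathway == "kegg:pw2"], 0)
})

test_that("enrichment p-values equal the hypergeometric-tail oracle", {
  set.seed(42)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    uni <- sprintf("P%03d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    db <- quick_db(list(pw = sample(uni, n), all = uni))
    ds <- quick_ds("t", sample(uni, K))
    res <- suppressMessages(fisher_enrichment(ds, db))
    row <- res[res$pathway == "kegg:pw", ]
    expect_equal(row$p, oracle_hyper_tail(N, K, n, row$k), tolerance = 1e-10)
  }
})

test_that("scores fall with p and extra in-pathway targets never raise p", {
  uni <- sprintf("P%03d", 1:40)
  db <- quick_db(list(pw = uni[1:10], all = uni))
  p_prev <- 1
  for (k in 1:8) {
    ds <- quick_ds("t", c(uni[seq_len(k)], uni[30:34]))
    res <- suppressMessages(fisher_enrichment(ds, db))
    p_now <- res$p[res$pathway == "kegg:pw"]
    expect_lte(p_now, p_prev)
    p_prev <- p_now
  }
  # es monotone non-increasing in p across a result table
  ds <- quick_ds("t", uni[c(1:6, 30:33)])
  res <- suppressMessages(fisher_enrichment(ds, db))
  expect_true(all(diff(res$es[order(res$p)]) <= 1e-12))
})

test_that("empty targets and out-of-universe targets are handled", {
  db <- quick_db(list(pw = c("A", "B")))
  empty <- target_dataset("none")
  expect_warning(res <- fisher_enrichment(empty, db), "empty target")
  expect_true(all(res$p == 1))

  ds <- quick_ds("t", c("A", "ZZ"))
  expect_message(res2 <- fisher_enrichment(ds, db), "outside universe")
  expect_equal(res2$K[1], 1)
})

test_that("selection keeps significant pathways and greedily covers the rest", {
  # P1 significant covering {a,b}; P2 weak but contains c; P3 contains none
  uni <- c("a", "b", "c", sprintf("u%02d", 1:37))
  db <- quick_db(list(P1 = c("a", "b", "u01"),
                      P2 = c("c", paste0("u", sprintf("%02d", 2:21))),
                      P3 = paste0("u", sprintf("%02d", 22:31))))
  ds <- quick_ds("t", c("a", "b", "c"))
  res <- suppressMessages(fisher_enrichment(ds, db))
  sel <- select_pathways(res, ds, db, alpha = 0.05)
  expect_setequal(sel$pathway, c("kegg:P1", "kegg:P2"))
  expect_equal(sel$reason[sel$pathway == "kegg:P1"], "significant")
  expect_equal(sel$reason[sel$pathway == "kegg:P2"], "coverage")
  expect_length(attr(sel, "uncovered"), 0)

  # all targets already inside the significant pathway -> no coverage step
  ds2 <- quick_ds("t", c("a", "b"))
  res2 <- suppressMessages(fisher_enrichment(ds2, db))
  sel2 <- select_pathways(res2, ds2, db)
  expect_true(all(sel2$reason == "significant"))

  # no pathway contains any target -> empty selection, all uncovered
  ds3 <- quick_ds("t", c("x1", "x2"))
  res3 <- suppressMessages(suppressWarnings(fisher_enrichment(ds3, db)))
  sel3 <- select_pathways(res3, ds3, db)
  expect_equal(nrow(sel3), 0)
})

test_that("selection output always covers every coverable target", {
  set.seed(7)
  for (i in 1:20) {
    uni <- sprintf("P%03d", 1:50)
    members <- lapply(1:8, function(j) sample(uni, sample(4:12, 1)))
    names(members) <- paste0("pw", 1:8)
    db <- quick_db(members)
    ds <- quick_ds("t", sample(uni, 12))
    res <- suppressMessages(suppressWarnings(fisher_enrichment(ds, db)))
    sel <- select_pathways(res, ds, db)
    sig <- res$pathway[res$p < 0.05]
    expect_true(all(sig %in% sel$pathway))  # superset of significant set
    selected_members <- unlist(
      db$pathways$members[db$pathways$id %in% sel$pathway])
    coverable <- intersect(target_accessions(ds),
                           unlist(db$pathways$members))
    covered <- intersect(target_accessions(ds), selected_members)
    expect_setequal(covered, coverable)
    expect_setequal(attr(sel, "uncovered"),
                    setdiff(intersect(target_accessions(ds), db$universe),
                            coverable))
  }
})

test_that("differential enrichment sorts by mean score, deviations sum to 0", {
  mk <- function(es) data.frame(pathway = c("p1", "p2", "p3"),
                                source = "kegg", es = es,
                                stringsAsFactors = FALSE)
  per <- list(c1 = mk(c(2, 4, 0)), c2 = mk(c(4, 4, 3)), c3 = mk(c(6, 4, 0)))
  out <- differential_enrichment(per)
  # p1 and p2 tie on mean 4; deterministic tie-break by pathway id
  expect_equal(out$pathway, c("p1", "p2", "p3"))
  p1 <- out[out$pathway == "p1", ]
  expect_equal(p1$mean_es, 4)
  expect_equal(unlist(p1[paste0("dev_", names(per))], use.names = FALSE),
               c(-2, 0, 2))
  devs <- as.matrix(out[paste0("dev_", names(per))])
  expect_true(all(abs(rowSums(devs)) < 1e-9))

  # a pathway missing from one condition scores 0 there
  per2 <- list(a = mk(c(0, 1, 2))[2:3, ], b = mk(c(3, 3, 3)))
  out2 <- differential_enrichment(per2)
  p1b <- out2[out2$pathway == "p1", ]
  expect_equal(p1b$mean_es, 1.5)
  expect_equal(c(p1b$dev_a, p1b$dev_b), c(-1.5, 1.5))

  expect_error(differential_enrichment(per[1]), "two conditions")
})

test_that("bidirectional clustering merges identical columns first", {
  mat <- cbind(c1 = c(0, 1, 5), c2 = c(0, 1, 5), c3 = c(9, 2, 1))
  rownames(mat) <- c("p1", "p2", "p3")
  cl <- cluster_enrichment(mat)
  first_merge <- cl$cols$merge[1, ]
  expect_setequal(colnames(mat)[-first_merge], c("c1", "c2"))
  expect_equal(cl$cols$height[1], 0)
  # rows {0},{1},{5} in two identical columns, complete linkage:
  # closest pair {0},{1} merges first at Euclidean height sqrt(2)
  cl2 <- cluster_enrichment(mat[, 1:2])
  expect_setequal(rownames(mat)[-cl2$rows$merge[1, ]], c("p1", "p2"))
  expect_equal(cl2$rows$height[1], sqrt(2))

  m2 <- matrix(c(0, 1, 2, 3), 2, dimnames = list(c("a", "b"), c("x", "y")))
  cl2 <- cluster_enrichment(m2)
  expect_equal(nrow(cl2$rows$merge), 1)
  expect_equal(nrow(cl2$cols$merge), 1)
  expect_error(cluster_enrichment(mat[1, , drop = FALSE]), "2x2")
})

test_that("per-pathway target tables render the printed worked examples", {
  db <- read_pathway_db(syk_fixture_path("pathways.gmt"),
                        syk_fixture_path("interactions.sif"), "kegg")
  datasets <- list(
    read_target_table(syk_fixture_path("mcf7_targets.tsv"), "MCF7"),
    read_target_table(syk_fixture_path("mda231_targets.tsv"), "MDA231"),
    read_target_table(syk_fixture_path("dg75_targets.tsv"), "DG75"))
  bcr <- pathway_target_table("kegg:hsa04662", datasets, db)
  btk <- bcr[bcr$symbol == "BTK", ]
  expect_equal(btk$DG75, "551 *")
  expect_equal(btk$accession, "Q06187")
  expect_equal(btk$MCF7, "")

  actin <- pathway_target_table("kegg:hsa04810", datasets, db)
  ezr <- actin[actin$symbol == "EZR", ]
  expect_equal(ezr$MCF7, "X")
  expect_equal(ezr$MDA231, "424")
  # a pathway member that is no dataset's target (RDX) is absent
  expect_false("P35241" %in% actin$accession)

  expect_error(pathway_target_table("kegg:nope", datasets, db), "unknown")
  # pathway with no targets at all gives an empty table
  db2 <- quick_db(list(empty = c("Z1", "Z2")))
  expect_equal(nrow(pathway_target_table("kegg:empty", datasets, db2)), 0)
})
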