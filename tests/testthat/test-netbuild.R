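# Prior-knowledge network assembly and the random baseline.

test_that("cleanup removes self-loops and isolated nodes", {
  db <- quick_db(list(pw = c("A", "B", "C")),
                 edges = list(from = c("A", "A"), to = c("B", "A")))
  net <- build_network(db, "kegg:pw")
  g <- as_igraph(net)
  expect_setequal(igraph::V(g)$name, c("A", "B"))  # C isolated, A->A dropped
  expect_equal(igraph::gsize(g), 1)
  expect_equal(igraph::ecount(igraph::simplify(g)), igraph::ecount(g))
})

test_that("pathway union keeps distinct provenance and cross-pathway edges", {
  db <- quick_db(list(p1 = c("A", "B"), p2 = c("B", "C"), p3 = c("A", "C")),
                 edges = list(from = c("A", "B", "A"), to = c("B", "C", "C")))
  net <- build_network(db, c("kegg:p1", "kegg:p2"))
  g <- as_igraph(net)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::gsize(g), 3)
  ef <- igraph::as_data_frame(g, what = "edges")
  expect_equal(ef$provenance[ef$from == "A" & ef$to == "B"], "kegg:p1")
  expect_equal(ef$provenance[ef$from == "B" & ef$to == "C"], "kegg:p2")
  # A->C spans the two selected pathways: included, provenance outside
  # the selection is dropped (kegg:p3 not selected)
  expect_equal(ef$provenance[ef$from == "A" & ef$to == "C"], "")
})

test_that("the same edge from two source databases deduplicates", {
  a <- quick_db(list(pw = c("A", "B")),
                edges = list(from = "A", to = "B", sign = "activate"),
                source = "kegg")
  b <- quick_db(list(pw = c("A", "B")),
                edges = list(from = "A", to = "B", sign = "activate"),
                source = "pc")
  db <- combine_pathway_dbs(a, b)
  net <- build_network(db, c("kegg:pw", "pc:pw"))
  g <- as_igraph(net)
  expect_equal(igraph::gsize(g), 1)
  expect_equal(igraph::E(g)$dbs, "kegg;pc")
  expect_equal(igraph::E(g)$sign, "activate")
})

test_that("conflicting signs on a deduplicated edge become unknown", {
  a <- quick_db(list(pw = c("A", "B")),
                edges = list(from = "A", to = "B", sign = "activate"))
  b <- quick_db(list(pw = c("A", "B")),
                edges = list(from = "A", to = "B", sign = "inhibit"),
                source = "pc")
  net <- build_network(combine_pathway_dbs(a, b), c("kegg:pw", "pc:pw"))
  expect_equal(igraph::E(as_igraph(net))$sign, "unknown")
})

test_that("build is deterministic and annotates targets and the focal node", {
  db <- quick_db(list(pw = c("A", "B", "C")),
                 edges = list(from = c("A", "B"), to = c("B", "C")))
  ds <- quick_ds("m", c("B"), sites = list(42L))
  n1 <- build_network(db, "kegg:pw", datasets = list(ds), focal = "A")
  n2 <- build_network(db, "kegg:pw", datasets = list(ds), focal = "A")
  expect_identical(igraph::as_data_frame(as_igraph(n1), "both"),
                   igraph::as_data_frame(as_igraph(n2), "both"))
  g <- as_igraph(n1)
  expect_equal(igraph::V(g)$targets[igraph::V(g)$name == "B"], "m")
  expect_equal(igraph::V(g)$sites[igraph::V(g)$name == "B"], "m:42")
  expect_true(igraph::V(g)$is_focal[igraph::V(g)$name == "A"])
  expect_error(build_network(db, "kegg:pw", focal = "ZZ"), "focal")
  expect_error(build_network(db, "kegg:nope"), "unknown pathway")
})

test_that("random baseline is seed-deterministic and handles boundaries", {
  set.seed(99)
  uni <- sprintf("P%03d", 1:60)
  members <- lapply(1:6, function(j) sample(uni, 12))
  names(members) <- paste0("pw", 1:6)
  edges <- list(from = sample(uni, 80, TRUE), to = sample(uni, 80, TRUE))
  keep <- edges$from != edges$to
  db <- quick_db(members, edges = list(from = edges$from[keep],
                                       to = edges$to[keep]))
  r1 <- suppressWarnings(build_random_network(db, 15, seed = 5))
  r2 <- suppressWarnings(build_random_network(db, 15, seed = 5))
  expect_identical(igraph::as_data_frame(as_igraph(r1), "both"),
                   igraph::as_data_frame(as_igraph(r2), "both"))
  expect_true(r1$random)

  r0 <- suppressWarnings(build_random_network(db, 0, seed = 1))
  expect_equal(igraph::gorder(as_igraph(r0)), 0)
})

test_that("random baseline differs in size from a planted network", {
  # planted targets concentrate in few pathways and select a compact
  # network; scattered random pseudo-targets trigger the coverage rule
  # across many pathways and select a larger one
  spec <- synthetic_spec(n_proteins = 800, n_pathways = 20, n_targets = 60,
                         seed = 11)
  net <- gen_interactome(spec)
  pool <- igraph::V(as_igraph(net))$name
  pw <- gen_pathway_db(net, spec)
  sizes <- t(sapply(1:5, function(i) {
    tl <- gen_target_lists(pw$db, pw$truth, spec, n_conditions = 1,
                           seed = spec$seed + i, pool = pool)
    ds <- suppressMessages(suppressWarnings(
      normalize_targets(tl$datasets[[1]])))
    res <- suppressMessages(suppressWarnings(fisher_enrichment(ds, pw$db)))
    sel <- select_pathways(res, ds, pw$db)
    bn <- build_network(pw$db, sel$pathway, datasets = list(ds))
    rn <- suppressWarnings(build_random_network(pw$db, 60, seed = 100 + i))
    c(planted = igraph::gorder(as_igraph(bn)),
      random = igraph::gorder(as_igraph(rn)))
  }))
  expect_gt(mean(sizes[, "random"]), mean(sizes[, "planted"]))
})

test_that("built networks satisfy the cleanup invariants", {
  set.seed(3)
  for (i in 1:10) {
    uni <- sprintf("P%02d", 1:30)
    members <- lapply(1:4, function(j) sample(uni, 8))
    names(members) <- paste0("pw", 1:4)
    e <- list(from = sample(uni, 60, TRUE), to = sample(uni, 60, TRUE))
    db <- quick_db(members, edges = e)
    sel <- paste0("kegg:pw", 1:3)
    net <- build_network(db, sel)
    g <- as_igraph(net)
    expect_equal(sum(igraph::which_loop(g)), 0)
    expect_equal(sum(igraph::degree(g) == 0), 0)
    expect_equal(igraph::ecount(igraph::simplify(g, remove.loops = FALSE)),
                 igraph::ecount(g))
    prov <- unlist(lapply(igraph::E(g)$provenance,
                          function(x) strsplit(x, ";")[[1]]))
    expect_true(all(prov %in% sel))
  }
})

test_that("networks survive a GraphML round-trip with annotations", {
  db <- quick_db(list(pw = c("A", "B", "C")),
                 edges = list(from = c("A", "B"), to = c("B", "C"),
                              sign = c("activate", "inhibit")))
  net <- build_network(db, "kegg:pw", datasets = list(quick_ds("m", "B")))
  f <- tempfile(fileext = ".graphml")
  write_network(net, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_setequal(igraph::E(g2)$sign, c("activate", "inhibit"))
  expect_equal(igraph::V(g2)$targets[igraph::V(g2)$name == "B"], "m")

  fs <- tempfile(fileext = ".sif")
  write_network(net, fs, format = "sif")
  expect_equal(length(readLines(fs)), 2)
})
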