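# Random-walk edge weighting, Yen k-shortest / near-shortest paths, the
# propagation union subnetwork, and GO-restricted target sets.

test_that("random-walk weights are log2 of the source out-degree", {
  net <- toy_network(c("A", rep("B", 8)),
                     c("B", paste0("T", 1:8)))
  w <- weight_edges(net)
  g <- as_igraph(net)
  ef <- igraph::as_edgelist(g)
  expect_equal(unname(w$weights[ef[, 1] == "A"]), 0)        # outdeg 1
  expect_true(all(w$weights[ef[, 1] == "B"] == 3))          # outdeg 8
  # forced walk: chain path weight 0 means walk probability 1
  chain <- toy_network(c("A", "B"), c("B", "C"))
  p <- k_shortest_paths(chain, weight_edges(chain), "A", "C", k = 1)
  expect_equal(p[[1]]$nodes, c("A", "B", "C"))
  expect_equal(p[[1]]$weight, 0)
  expect_true(all(weight_edges(chain, "unit")$weights == 1))
})

test_that("a longer forced path outranks a short hub detour", {
  # S->H->T with outdeg(S)=2, outdeg(H)=10 versus S->a->b->T forced:
  # weights 1 + log2(10) vs 1 + 0 + 0
  from <- c("S", "S", "H", paste0("H", 1:9), "a", "b")
  to <- c("H", "a", "T", paste0("X", 1:9), "b", "T")
  from <- c("S", "S", "H", rep("H", 9), "a", "b")
  to <- c("H", "a", "T", paste0("X", 1:9), "b", "T")
  net <- toy_network(from, to)
  w <- weight_edges(net)
  paths <- k_shortest_paths(net, w, "S", "T", k = 2, epsilon = 0)
  expect_equal(paths[[1]]$nodes, c("S", "a", "b", "T"))
  expect_equal(paths[[1]]$weight, 1)
  expect_equal(paths[[2]]$nodes, c("S", "H", "T"))
  expect_equal(paths[[2]]$weight, 1 + log2(10))
})

test_that("unreachable targets give an empty path list", {
  net <- toy_network("A", "B", nodes = c("A", "B", "Z"))
  expect_length(k_shortest_paths(net, NULL, "A", "Z", k = 3), 0)
  expect_error(k_shortest_paths(net, NULL, "A", "QQ"), "not in network")
})

test_that("path search equals exhaustive enumeration on random digraphs", {
  for (seed in 1:40) {
    n <- sample(4:10, 1)
    net <- random_digraph(n, sample(n:(3 * n), 1), seed)
    g <- as_igraph(net)
    nodes <- igraph::V(g)$name
    el <- igraph::as_edgelist(g)
    scheme <- if (seed %% 2) "random_walk" else "unit"
    w <- weight_edges(net, scheme)
    wmap <- as.list(stats::setNames(w$weights,
                                    paste(el[, 1], el[, 2], sep = "\r")))
    st <- sample(nodes, 2)
    k <- sample(1:5, 1)
    eps <- sample(c(0, 0.5, 1, 2), 1)
    got <- k_shortest_paths(net, w, st[1], st[2], k = k, epsilon = eps)
    want <- oracle_keep_paths(
      oracle_simple_paths(nodes, el[, 1], el[, 2], wmap, st[1], st[2]),
      k, eps)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$nodes, want[[i]]$nodes)
      expect_equal(got[[i]]$weight, want[[i]]$weight, tolerance = 1e-9)
    }
    # weights are non-decreasing; the first is the true minimum
    if (length(got)) {
      wts <- vapply(got, `[[`, numeric(1), "weight")
      expect_true(all(diff(wts) >= -1e-12))
      d <- igraph::distances(g, v = st[1], to = st[2], mode = "out",
                             weights = w$weights)[1, 1]
      expect_equal(wts[1], unname(d), tolerance = 1e-9)
    }
  }
})

test_that("unit weighting reproduces hop-shortest paths", {
  for (seed in 101:110) {
    net <- random_digraph(8, 16, seed)
    g <- as_igraph(net)
    nodes <- igraph::V(g)$name
    st <- sample(nodes, 2)
    got <- k_shortest_paths(net, weight_edges(net, "unit"),
                            st[1], st[2], k = 1, epsilon = 0)
    d <- igraph::distances(g, v = st[1], to = st[2], mode = "out")[1, 1]
    if (is.finite(d)) {
      expect_equal(got[[1]]$weight, unname(d))
      expect_equal(length(got[[1]]$nodes) - 1, unname(d))
    } else {
      expect_length(got, 0)
    }
  }
})

test_that("the union subnetwork carries per-condition labels, no orphans", {
  #        A -> B -> T1 ;  A -> C -> T2 ; T2 only targeted by cond2
  net <- toy_network(c("A", "B", "A", "C"), c("B", "T1", "C", "T2"))
  ds1 <- quick_ds("c1", "T1")
  ds2 <- quick_ds("c2", c("T1", "T2"))
  pe <- propagation_subnetwork(net, source = "A", datasets = list(ds1, ds2),
                               k = 2, epsilon = 1)
  g <- as_igraph(pe$subnetwork)
  ef <- igraph::as_data_frame(g, "edges")
  expect_equal(ef$origins[ef$to == "T1"], "c1;c2")
  expect_equal(ef$origins[ef$to == "T2"], "c2")
  # every edge is used by some reported path
  used <- unique(unlist(lapply(names(pe$ensembles), function(cn) {
    unlist(lapply(pe$ensembles[[cn]], function(paths) {
      lapply(paths, function(p) {
        if (length(p$nodes) > 1) {
          paste(p$nodes[-length(p$nodes)], p$nodes[-1])
        }
      })
    }))
  })))
  expect_setequal(paste(ef$from, ef$to), used)
  # symmetric conditions label everything as shared
  pe2 <- propagation_subnetwork(net, source = "A",
                                datasets = list(quick_ds("x", c("T1", "T2")),
                                                quick_ds("y", c("T1", "T2"))))
  ef2 <- igraph::as_data_frame(as_igraph(pe2$subnetwork), "edges")
  expect_true(all(ef2$origins == "x;y"))
})

test_that("direct neighbors always contribute their one-edge path", {
  # A->T direct, plus a cheap two-hop route A->B->T that outranks it
  net <- toy_network(c("A", "A", "A", "B"), c("T", "B", "X", "T"))
  w <- weight_edges(net)
  pe <- propagation_subnetwork(net, w, source = "A",
                               datasets = list(quick_ds("c", "T")),
                               k = 1, epsilon = 0)
  keys <- vapply(pe$ensembles$c$T, function(p) paste(p$nodes, collapse = ">"),
                 character(1))
  expect_true("A>T" %in% keys)
  expect_true(length(keys) >= 1)
})

test_that("unreachable targets are reported per condition", {
  net <- toy_network("A", "B", nodes = c("A", "B", "Z"))
  pe <- propagation_subnetwork(net, source = "A",
                               datasets = list(quick_ds("c", c("B", "Z"))))
  expect_equal(pe$unreachable$c, "Z")
  expect_error(propagation_subnetwork(net, source = "QQ",
                                      datasets = list(quick_ds("c", "B"))),
               "source")
})

test_that("GO groups restrict targets to annotated processes", {
  go <- go_annotation(list("GO:0007155" = c("P1", "P2"),
                           "GO:0008283" = "P3"),
                      groups = list(adhesion = "GO:0007155",
                                    growth = "GO:0008283"))
  ds <- quick_ds("c", c("P1", "P2", "P3", "P4"))
  adh <- restrict_targets_by_go(ds, go, "adhesion")
  expect_setequal(target_accessions(adh), c("P1", "P2"))
  expect_error(restrict_targets_by_go(ds, go, "nope"), "configured groups")
  empty_go <- go_annotation(list("GO:0007155" = "QQ"),
                            groups = list(adhesion = "GO:0007155"))
  expect_warning(out <- restrict_targets_by_go(ds, empty_go, "adhesion"),
                 "no target")
  expect_equal(nrow(out$targets), 0)
})
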