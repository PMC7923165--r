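# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own code paths: hypergeometric tails by direct enumeration,
# distances by hand-rolled BFS, betweenness by shortest-path counting,
# simple paths by exhaustive DFS.

oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# adjacency list (by node index) from an edge matrix of node names
oracle_adj <- function(nodes, from, to) {
  adj <- lapply(seq_along(nodes), function(i) integer())
  for (e in seq_along(from)) {
    i <- match(from[e], nodes)
    adj[[i]] <- c(adj[[i]], match(to[e], nodes))
  }
  adj
}

# all-pairs directed hop distances by BFS
oracle_distances <- function(nodes, from, to) {
  n <- length(nodes)
  adj <- oracle_adj(nodes, from, to)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (D[s, w] > d) {
            D[s, w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# number of distinct shortest s->t paths, by DP over BFS distance layers
oracle_sigma <- function(nodes, from, to, D = oracle_distances(nodes, from, to)) {
  n <- length(nodes)
  pred <- lapply(seq_len(n), function(i) integer())   # pred[[t]] = sources of t
  for (e in seq_along(from)) {
    t_i <- match(to[e], nodes)
    pred[[t_i]] <- c(pred[[t_i]], match(from[e], nodes))
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t_i in ord) {
      if (t_i == s || !is.finite(D[s, t_i])) next
      for (p in pred[[t_i]]) {
        if (is.finite(D[s, p]) && D[s, p] + 1 == D[s, t_i]) {
          sigma[s, t_i] <- sigma[s, t_i] + sigma[s, p]
        }
      }
    }
  }
  sigma
}

# directed betweenness of every node, normalized by (n-1)(n-2)
oracle_betweenness <- function(nodes, from, to) {
  n <- length(nodes)
  D <- oracle_distances(nodes, from, to)
  sigma <- oracle_sigma(nodes, from, to, D)
  B <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t_i in seq_len(n)) {
        if (s == t_i || s == v || t_i == v) next
        if (!is.finite(D[s, t_i]) || sigma[s, t_i] == 0) next
        if (is.finite(D[s, v]) && is.finite(D[v, t_i]) &&
            D[s, v] + D[v, t_i] == D[s, t_i]) {
          B[v] <- B[v] + sigma[s, v] * sigma[v, t_i] / sigma[s, t_i]
        }
      }
    }
  }
  if (n > 2) B / ((n - 1) * (n - 2)) else B
}

# harmonic closeness: mean over u != v of 1/d(v,u), unreachable -> 0
oracle_closeness <- function(nodes, from, to, v_name) {
  D <- oracle_distances(nodes, from, to)
  v <- match(v_name, nodes)
  d <- D[v, -v]
  if (!length(d)) return(NA_real_)
  sum(ifelse(is.finite(d) & d > 0, 1 / d, 0)) / (length(nodes) - 1)
}

# mean local clustering coefficient of the undirected simple projection
oracle_clustering <- function(nodes, from, to) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n)
  for (e in seq_along(from)) {
    i <- match(from[e], nodes)
    j <- match(to[e], nodes)
    if (i != j) A[i, j] <- A[j, i] <- TRUE
  }
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(cc)
}

# characteristic path length: mean finite positive directed distance
oracle_char_path_length <- function(nodes, from, to) {
  D <- oracle_distances(nodes, from, to)
  vals <- D[is.finite(D) & D > 0]
  if (length(vals)) mean(vals) else NA_real_
}

# all simple source->target paths with their weights (edge weights given as
# a named vector "from\rto" -> w), by exhaustive DFS
oracle_simple_paths <- function(nodes, from, to, w, source, target) {
  adj <- list()
  for (v in nodes) adj[[v]] <- to[from == v]
  out <- list()
  dfs <- function(path, weight) {
    v <- path[length(path)]
    if (v == target) {
      out[[length(out) + 1]] <<- list(nodes = path, weight = weight)
      return()
    }
    for (nxt in adj[[v]]) {
      if (!(nxt %in% path)) {
        dfs(c(path, nxt), weight + w[[paste(v, nxt, sep = "\r")]])
      }
    }
  }
  dfs(source, 0)
  if (!length(out)) return(out)
  ord <- order(vapply(out, `[[`, numeric(1), "weight"),
               vapply(out, function(p) paste(p$nodes, collapse = "\r"),
                      character(1)))
  out[ord]
}

# the retention rule: keep ranked paths while (rank <= k or weight <= wmin+eps)
oracle_keep_paths <- function(sorted_paths, k, epsilon) {
  if (!length(sorted_paths)) return(sorted_paths)
  wts <- vapply(sorted_paths, `[[`, numeric(1), "weight")
  keep <- seq_along(sorted_paths) <= k | wts <= wts[1] + epsilon
  sorted_paths[keep]
}
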