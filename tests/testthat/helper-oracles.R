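# Brute-force oracles, deliberately independent of the package's
# igraph/BFS implementations: edge-list scans and Floyd-Warshall matrix
# recurrences on dense adjacency matrices.

random_tfn <- function(n_nodes, p_edge = 0.1, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  if (!nrow(edges)) {
    edges <- data.frame(regulator = nodes[1], target = nodes[min(2, n_nodes)])
  }
  edges$effect <- sample(c(-1L, 0L, 1L), nrow(edges), replace = TRUE,
                         prob = c(0.45, 0.1, 0.45))
  tfn_graph(edges, nodes = nodes)
}

oracle_profile <- function(graph, universe) {
  universe <- sort(unique(tolower(universe)))
  do.call(rbind, lapply(universe, function(g) {
    rows <- graph$edges[graph$edges$target == g, , drop = FALSE]
    data.frame(gene = g, k_tf = nrow(rows), sum_r = sum(rows$effect),
               b = abs(sum(rows$effect)), stringsAsFactors = FALSE)
  }))
}

# all-pairs shortest distances and path counts by Floyd-Warshall
oracle_apsp <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  C <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges[graph$edges$regulator != graph$edges$target, ,
                   drop = FALSE]
  for (i in seq_len(nrow(e))) {
    D[e$regulator[i], e$target[i]] <- 1
    C[e$regulator[i], e$target[i]] <- 1
  }
  for (k in seq_len(n)) {
    newD <- outer(D[, k], D[k, ], `+`)
    CC <- outer(C[, k], C[k, ])
    better <- newD < D
    equal <- is.finite(newD) & newD == D
    C[better] <- CC[better]
    C[equal] <- C[equal] + CC[equal]
    D[better] <- newD[better]
  }
  diag(D) <- Inf # self-pairs excluded throughout
  diag(C) <- 0
  list(D = D, C = C)
}

oracle_pairs <- function(graph, max_L) {
  D <- oracle_apsp(graph)$D
  hit <- which(is.finite(D) & D <= max_L, arr.ind = TRUE)
  out <- data.frame(input_gene = rownames(D)[hit[, 1]],
                    output_gene = colnames(D)[hit[, 2]],
                    L = as.integer(D[hit]), stringsAsFactors = FALSE)
  out[order(out$L, out$input_gene, out$output_gene), , drop = FALSE]
}

oracle_metrics <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  e <- graph$edges
  indeg <- vapply(nodes, function(g) sum(e$target == g), integer(1))
  outdeg <- vapply(nodes, function(g) sum(e$regulator == g), integer(1))

  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(e))) A[e$regulator[i], e$target[i]] <- 1L
  U <- (A + t(A)) > 0
  diag(U) <- FALSE

  cc <- vapply(seq_len(n), function(v) {
    nb <- which(U[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    sum(U[nb, nb]) / (k * (k - 1))
  }, numeric(1))

  ap <- oracle_apsp(graph)
  D <- ap$D; C <- ap$C
  ecc <- vapply(seq_len(n), function(v) {
    f <- D[v, is.finite(D[v, ])]
    if (length(f)) max(f) else 0
  }, numeric(1))
  aspl <- vapply(seq_len(n), function(v) {
    f <- D[v, is.finite(D[v, ])]
    if (length(f)) mean(f) else 0
  }, numeric(1))

  btw <- numeric(n); stress <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], `+`) == D & is.finite(D)
    through[v, ] <- FALSE; through[, v] <- FALSE; diag(through) <- FALSE
    cnt <- outer(C[, v], C[v, ])
    stress[v] <- sum(cnt[through])
    frac <- cnt / C
    btw[v] <- sum(frac[through])
  }

  conn <- rowSums(U)
  nbc <- vapply(seq_len(n), function(v) {
    nb <- which(U[v, ])
    if (!length(nb)) return(0)
    mean(conn[nb])
  }, numeric(1))

  data.frame(gene = nodes, in_degree = indeg, out_degree = outdeg,
             edge_count = indeg + outdeg, clustering_coefficient = cc,
             eccentricity = ecc, average_shortest_path_length = aspl,
             betweenness = btw, stress_centrality = stress,
             neighbourhood_connectivity = nbc, stringsAsFactors = FALSE,
             row.names = NULL)
}

# exact E|sum of k iid +/-1 signs| by binomial enumeration
expected_abs_bias <- function(k) {
  if (k == 0) return(0)
  a <- 0:k
  sum(choose(k, a) * abs(2 * a - k)) / 2^k
}
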