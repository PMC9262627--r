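#' Signed, directed, gene-level transcription-factor network
#'
#' A `tfn_graph` holds the gene-level network after operon/TU expansion:
#' `nodes` (normalized gene names) and `edges`, one merged row per
#' (regulator, target) pair with the signed regulatory effect
#' r in \{-1, 0, +1\}. Edge direction is regulator -> target, so a gene's
#' in-degree equals its number of distinct input TFs (K_TF). Self-loops
#' (autoregulation) are permitted and kept.
#'
#' @param edges data.frame with columns `regulator`, `target`, `effect`.
#' @param nodes optional extra node names to carry (e.g. regulated genes
#'   known to exist but without interactions); defaults to the edge
#'   endpoints.
#' @param n_skipped count of records dropped during expansion.
#' @return object of class `tfn_graph`.
#' @export
tfn_graph <- function(edges, nodes = NULL, n_skipped = 0L) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "target", "effect") %in% names(edges)))
  edges$effect <- as.integer(edges$effect)
  stopifnot(all(edges$effect %in% c(-1L, 0L, 1L)))
  if (anyDuplicated(edges[c("regulator", "target")])) {
    stop("edges must be merged: one row per (regulator, target) pair")
  }
  nodes <- sort(unique(c(edges$regulator, edges$target, nodes)))
  structure(list(nodes = nodes,
                 edges = edges[order(edges$regulator, edges$target), ,
                               drop = FALSE],
                 n_skipped = as.integer(n_skipped)),
            class = "tfn_graph")
}

#' @export
print.tfn_graph <- function(x, ...) {
  cat("Signed TFN graph:", length(x$nodes), "genes,",
      nrow(x$edges), "merged edges (",
      sum(x$edges$regulator == x$edges$target), "self-loops )\n")
  invisible(x)
}

# collapse several signed assertions about one (regulator, target) pair:
# a single consistent non-zero sign is kept; conflicting signs, or only
# unknown/dual assertions, give r = 0
.merge_effects <- function(effects) {
  s <- unique(effects[effects != 0L])
  if (length(s) == 1L) s else 0L
}

#' Expand interaction records to the gene-level signed graph
#'
#' TF->operon and TF->TU records are expanded so the TF regulates every
#' member gene of the unit with the record's effect (all members share the
#' unit's promoter, hence its regulation). Multiple records asserting the
#' same (regulator, target gene) pair -- e.g. a direct TF-gene record plus
#' the gene's operon record -- merge into one edge: one input TF counts
#' once toward K_TF, and conflicting signs collapse to r = 0.
#'
#' @param records interaction records (see [parse_interactions()]).
#' @param annotations unit annotation (see [read_unit_annotation()]);
#'   required when any record targets an operon/TU.
#' @param synonyms optional named character vector mapping alternate
#'   regulator names to gene names (applied after normalization).
#' @param known_genes optional character vector; when given, regulators
#'   whose (synonym-resolved) name is not in it are skipped with a warning
#'   and counted in `n_skipped`.
#' @return a [tfn_graph()].
#' @export
expand_to_gene_graph <- function(records, annotations = NULL,
                                 synonyms = NULL, known_genes = NULL) {
  stopifnot(is.data.frame(records))
  reg <- normalize_gene_name(records$regulator)
  tgt <- normalize_gene_name(records$target)
  kind <- records$target_kind
  eff <- as.integer(records$effect)

  if (!is.null(synonyms)) {
    names(synonyms) <- normalize_gene_name(names(synonyms))
    synonyms <- normalize_gene_name(synonyms)
    hit <- match(reg, names(synonyms))
    reg[!is.na(hit)] <- synonyms[hit[!is.na(hit)]]
  }
  n_skipped <- 0L
  if (!is.null(known_genes)) {
    known <- normalize_gene_name(known_genes)
    bad <- !(reg %in% known)
    if (any(bad)) {
      n_skipped <- sum(bad)
      warning(n_skipped, " record(s) skipped: unresolvable regulator name(s) ",
              paste(unique(records$regulator[bad]), collapse = ", "))
      reg <- reg[!bad]; tgt <- tgt[!bad]; kind <- kind[!bad]; eff <- eff[!bad]
    }
  }

  is_unit <- kind %in% c("operon", "tu")
  if (any(is_unit)) {
    if (is.null(annotations)) {
      stop("operon/TU-level records require a unit annotation")
    }
    ann_unit <- normalize_gene_name(annotations$unit_id)
    ann_gene <- normalize_gene_name(annotations$gene)
    members <- split(ann_gene, ann_unit)
    missing_units <- setdiff(unique(tgt[is_unit]), names(members))
    if (length(missing_units)) {
      stop("no annotation for unit(s): ",
           paste(missing_units, collapse = ", "))
    }
    fan <- lengths(members)[tgt[is_unit]]
    exp_reg <- c(reg[!is_unit], rep(reg[is_unit], fan))
    exp_tgt <- c(tgt[!is_unit], unlist(members[tgt[is_unit]], use.names = FALSE))
    exp_eff <- c(eff[!is_unit], rep(eff[is_unit], fan))
  } else {
    exp_reg <- reg; exp_tgt <- tgt; exp_eff <- eff
  }

  if (!length(exp_reg)) {
    return(tfn_graph(data.frame(regulator = character(), target = character(),
                                effect = integer()), n_skipped = n_skipped))
  }
  key <- paste(exp_reg, exp_tgt, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  edges <- data.frame(regulator = exp_reg[!dup], target = exp_tgt[!dup],
                      effect = exp_eff[!dup], stringsAsFactors = FALSE)
  if (any(dup)) {
    merged <- vapply(split(exp_eff[dup], key[dup]), .merge_effects,
                     integer(1))
    parts <- strsplit(names(merged), "\r", fixed = TRUE)
    edges <- rbind(edges,
                   data.frame(regulator = vapply(parts, `[`, "", 1L),
                              target = vapply(parts, `[`, "", 2L),
                              effect = unname(merged),
                              stringsAsFactors = FALSE))
  }
  tfn_graph(edges, n_skipped = n_skipped)
}

#' Per-gene regulatory profile: K_TF, sum of r, and bias b
#'
#' For every gene in `gene_universe`, counts the distinct input TFs
#' (K_TF = in-degree of the merged graph), the signed sum of their
#' regulatory effects (sum_r) and the regulatory bias b = |sum_r|. Genes in
#' the universe but absent from the graph have K_TF = 0, sum_r = 0, b = 0.
#'
#' @param graph a [tfn_graph()].
#' @param gene_universe character vector of genes under study (normalized
#'   internally); must be non-empty.
#' @return data.frame `gene`, `k_tf`, `sum_r`, `b`.
#' @export
regulatory_profile <- function(graph, gene_universe) {
  stopifnot(inherits(graph, "tfn_graph"))
  universe <- unique(normalize_gene_name(gene_universe))
  if (!length(universe)) stop("gene universe is empty")
  tgt <- factor(graph$edges$target, levels = universe)
  keep <- !is.na(tgt)
  k <- tabulate(tgt[keep], nbins = length(universe))
  s <- numeric(length(universe))
  if (any(keep)) {
    agg <- rowsum(as.numeric(graph$edges$effect[keep]),
                  as.integer(tgt[keep]))
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  out <- data.frame(gene = universe,
                    k_tf = as.integer(k),
                    sum_r = as.integer(s),
                    stringsAsFactors = FALSE)
  out$b <- abs(out$sum_r)
  rownames(out) <- NULL
  out
}

.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[c("regulator", "target", "effect")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes))
}

#' Minimum directed path lengths between gene pairs
#'
#' Breadth-first traversal from every regulator node of the unsigned
#' directed graph; each ordered (input, output) pair is reported at exactly
#' its minimum path length L (in edges), up to `max_L`. Self-pairs are
#' excluded, so autoregulation never produces a trivially perfect
#' input-output match.
#'
#' @param graph a [tfn_graph()].
#' @param max_L largest path length reported (default 8).
#' @return data.frame `input_gene`, `output_gene`, `L`.
#' @export
min_path_lengths <- function(graph, max_L = 8L) {
  stopifnot(inherits(graph, "tfn_graph"), max_L >= 1)
  empty <- data.frame(input_gene = character(), output_gene = character(),
                      L = integer(), stringsAsFactors = FALSE)
  if (!nrow(graph$edges)) return(empty)
  g <- .as_igraph(graph)
  sources <- unique(graph$edges$regulator)
  d <- igraph::distances(g, v = sources, mode = "out")
  hit <- which(is.finite(d) & d >= 1 & d <= max_L, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(input_gene = rownames(d)[hit[, 1]],
                    output_gene = colnames(d)[hit[, 2]],
                    L = as.integer(d[hit]),
                    stringsAsFactors = FALSE)
  out <- out[out$input_gene != out$output_gene, , drop = FALSE]
  out <- out[order(out$L, out$input_gene, out$output_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node-level and global topology metrics
#'
#' Standard node metrics on the directed merged graph: in-/out-degree,
#' edge-count (incident edges), local clustering coefficient (on the
#' underlying simple undirected graph; degree < 2 gives 0), eccentricity
#' and average shortest path length over the out-reachable set, betweenness,
#' stress centrality (number of shortest paths through the node) and
#' neighbourhood connectivity (mean number of neighbours of the node's
#' neighbours, undirected). The global summary counts nodes, edges, weakly
#' connected components, isolated nodes and self-loops.
#'
#' Stress centrality is cubic in node count; disable it on genome-scale
#' graphs via `include_stress = FALSE`.
#'
#' @param graph a [tfn_graph()].
#' @param include_stress compute stress centrality (default TRUE).
#' @return list with `nodes` (data.frame of per-node metrics) and `summary`.
#' @export
topology_metrics <- function(graph, include_stress = TRUE) {
  stopifnot(inherits(graph, "tfn_graph"))
  g <- .as_igraph(graph)
  n <- length(graph$nodes)
  indeg <- igraph::degree(g, mode = "in", loops = TRUE)
  outdeg <- igraph::degree(g, mode = "out", loops = TRUE)

  gu <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0

  d <- igraph::distances(g, mode = "out")
  diag(d) <- NA_real_
  ecc <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) max(f) else 0
  })
  aspl <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else 0
  })

  btw <- igraph::betweenness(g, directed = TRUE)

  nb <- igraph::adjacent_vertices(gu, igraph::V(gu))
  conn <- lengths(nb) # distinct undirected neighbours, self excluded
  nbc <- vapply(seq_len(n), function(i) {
    if (!conn[i]) return(0)
    mean(conn[as.integer(nb[[i]])])
  }, numeric(1))

  stress <- if (include_stress) .stress_centrality(g) else rep(NA_real_, n)

  nodes <- data.frame(gene = graph$nodes,
                      in_degree = as.integer(indeg),
                      out_degree = as.integer(outdeg),
                      edge_count = as.integer(indeg + outdeg),
                      clustering_coefficient = as.numeric(cc),
                      eccentricity = as.numeric(ecc),
                      average_shortest_path_length = as.numeric(aspl),
                      betweenness = as.numeric(btw),
                      stress_centrality = as.numeric(stress),
                      neighbourhood_connectivity = nbc,
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  summary <- list(n_nodes = n,
                  n_edges = nrow(graph$edges),
                  n_components = igraph::count_components(g, mode = "weak"),
                  n_isolated = sum(indeg + outdeg == 0),
                  n_self_loops = sum(graph$edges$regulator ==
                                       graph$edges$target))
  list(nodes = nodes, summary = summary)
}

# stress centrality via all-pairs shortest-path counts: per-source BFS
# builds sigma(s, .) level by level, then stress(v) = sum over (s, t) pairs
# with d(s,v) + d(v,t) = d(s,t) of sigma(s,v) * sigma(v,t); self-loops and
# endpoints excluded, as in the usual definition
.stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  gs <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  adj <- igraph::as_adj_list(gs, mode = "out")
  adj <- lapply(adj, as.integer)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n) # S[s, t] = number of shortest s->t paths
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) sig[v] <- sig[v] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sig
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    dv_in <- D[, v]; dv_out <- D[v, ]
    ok <- outer(dv_in, dv_out, `+`) == D & is.finite(D)
    ok[v, ] <- FALSE; ok[, v] <- FALSE; diag(ok) <- FALSE
    contrib <- outer(S[, v], S[v, ])
    stress[v] <- sum(contrib[ok])
  }
  stress
}

#' Export a TFN graph to disk
#'
#' Edge-list TSV (`regulator  target  r`) or GraphML with an integer `r`
#' edge attribute; both round-trip through [import_graph()] exactly.
#'
#' @param graph a [tfn_graph()].
#' @param path output file path.
#' @param format "tsv" or "graphml".
#' @export
export_graph <- function(graph, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(graph, "tfn_graph"))
  format <- match.arg(format)
  if (format == "tsv") {
    out <- graph$edges
    names(out) <- c("regulator", "target", "r")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- .as_igraph(graph)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a TFN graph written by [export_graph()]
#'
#' @param path file path.
#' @param format "tsv" or "graphml".
#' @return a [tfn_graph()].
#' @export
import_graph <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character",
                                            "integer"))
    edges <- data.frame(regulator = tab$regulator, target = tab$target,
                        effect = as.integer(tab$r), stringsAsFactors = FALSE)
    tfn_graph(edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(regulator = el$from, target = el$to,
                        effect = as.integer(el$effect),
                        stringsAsFactors = FALSE)
    tfn_graph(edges, nodes = igraph::V(g)$name)
  }
}
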