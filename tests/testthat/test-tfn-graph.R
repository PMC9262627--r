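test_that("interaction tables parse with the dialect map, preserving rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("regulator\ttarget\ttarget_kind\teffect",
               "crp\taraB\tgene\t+",
               "fis\trrnB-operon\toperon\t+-",
               "arcA\tsodA\tgene\t-"), f)
  rec <- parse_interactions(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$effect, c(1L, 0L, -1L))
  expect_equal(rec$regulator, c("crp", "fis", "arcA"))

  writeLines(c("regulator\ttarget\ttarget_kind\teffect",
               "crp\taraB\tgene\t%%"), f)
  expect_error(parse_interactions(f), "unknown effect token '%%' at row 1")
  writeLines(c("regulator\ttarget\ttarget_kind\teffect",
               "crp\taraB\tplasmid\t+"), f)
  expect_error(parse_interactions(f), "unknown target_kind")
})

test_that("operon/TU records expand to every member gene with the record sign", {
  ann <- unit_annotation("op1", "operon", c("x1", "x2"), 1:2)
  rec <- interaction_records("a", "op1", "operon", 1L)
  g <- expand_to_gene_graph(rec, ann)
  expect_setequal(paste(g$edges$regulator, g$edges$target, g$edges$effect),
                  c("a x1 1", "a x2 1"))

  # two TFs x one 3-gene operon each -> 6 edges
  ann2 <- unit_annotation(rep(c("opA", "opB"), each = 3), "operon",
                          sprintf("g%d", 1:6), rep(1:3, 2))
  rec2 <- interaction_records(c("tf1", "tf2"), c("opA", "opB"),
                              "operon", c(1L, -1L))
  g2 <- expand_to_gene_graph(rec2, ann2)
  expect_equal(nrow(g2$edges), 6)

  # operon target without annotation is a hard error
  expect_error(expand_to_gene_graph(rec, annotations = NULL), "annotation")
  expect_error(expand_to_gene_graph(
    interaction_records("a", "nope", "operon", 1L), ann),
    "no annotation for unit")
})

test_that("duplicate (regulator, target) assertions merge; conflicts give r = 0", {
  ann <- unit_annotation("tu1", "tu", c("g", "h"), 1:2)
  rec <- interaction_records(c("a", "a"), c("g", "tu1"), c("gene", "tu"),
                             c(1L, -1L))
  g <- expand_to_gene_graph(rec, ann)
  eg <- g$edges[g$edges$target == "g", ]
  expect_equal(nrow(eg), 1)
  expect_equal(eg$effect, 0L)
  # the non-conflicting member keeps the unit-level sign
  expect_equal(g$edges$effect[g$edges$target == "h"], -1L)

  # consistent repetition keeps the sign and still counts once
  rec2 <- interaction_records(c("a", "a"), c("g", "tu1"), c("gene", "tu"),
                              c(-1L, -1L))
  g2 <- expand_to_gene_graph(rec2, ann)
  expect_equal(g2$edges$effect[g2$edges$target == "g"], -1L)
  expect_equal(sum(g2$edges$target == "g"), 1)
})

test_that("expansion is idempotent on already gene-level records", {
  set.seed(42)
  g <- random_tfn(20, 0.1, seed = 42)
  rec <- data.frame(regulator = g$edges$regulator, target = g$edges$target,
                    target_kind = "gene", effect = g$edges$effect)
  g2 <- expand_to_gene_graph(rec)
  expect_equal(g2$edges, g$edges, ignore_attr = TRUE)
})

test_that("unresolvable regulators are skipped with a warning and counted", {
  rec <- interaction_records(c("known", "ghost"), c("x", "y"),
                             "gene", c(1L, 1L))
  expect_warning(
    g <- expand_to_gene_graph(rec, known_genes = c("known", "x", "y")),
    "ghost")
  expect_equal(g$n_skipped, 1L)
  expect_equal(nrow(g$edges), 1)
})

test_that("regulatory profiles follow the arithmetic of signed inputs", {
  edges <- data.frame(regulator = c("t1", "t2", "t3", "t1", "t2"),
                      target = c("a", "a", "a", "b", "b"),
                      effect = c(1L, 1L, -1L, 1L, -1L))
  g <- tfn_graph(edges)
  prof <- regulatory_profile(g, c("a", "b", "c"))
  expect_equal(prof$k_tf[prof$gene == "a"], 3L)
  expect_equal(prof$b[prof$gene == "a"], 1L)
  expect_equal(prof$k_tf[prof$gene == "b"], 2L)
  expect_equal(prof$b[prof$gene == "b"], 0L) # cancellation
  # genes absent from the graph get all-zero profiles
  expect_equal(unlist(prof[prof$gene == "c", c("k_tf", "sum_r", "b")]),
               c(k_tf = 0L, sum_r = 0L, b = 0L))
  expect_error(regulatory_profile(g, character(0)), "empty")
})

test_that("profiles and K_TF conservation hold against the edge-list oracle", {
  for (s in 1:25) {
    g <- random_tfn(sample(5:50, 1), runif(1, 0.03, 0.2), seed = s)
    prof <- regulatory_profile(g, g$nodes)
    prof <- prof[order(prof$gene), ]
    orc <- oracle_profile(g, g$nodes)
    expect_equal(prof, orc, ignore_attr = TRUE)
    expect_true(all(prof$b <= prof$k_tf))
    expect_equal(sum(prof$k_tf), nrow(g$edges)) # conservation
  }
})

test_that("minimum path lengths match the chain/minimality examples", {
  g <- tfn_graph(data.frame(regulator = c("a", "b"), target = c("b", "c"),
                            effect = c(1L, -1L)))
  pp <- min_path_lengths(g, max_L = 8)
  expect_equal(pp, data.frame(input_gene = c("a", "b", "a"),
                              output_gene = c("b", "c", "c"),
                              L = c(1L, 1L, 2L))[order(c(1, 1, 2)), ],
               ignore_attr = TRUE)
  # shortcut wins: (a, c) at L = 1 only
  g2 <- tfn_graph(data.frame(regulator = c("a", "a", "b"),
                             target = c("b", "c", "c"),
                             effect = 1L))
  pp2 <- min_path_lengths(g2, max_L = 8)
  expect_equal(pp2$L[pp2$input_gene == "a" & pp2$output_gene == "c"], 1L)
  expect_equal(sum(pp2$input_gene == "a" & pp2$output_gene == "c"), 1)
  # self-pairs excluded even with self-loops and cycles
  g3 <- tfn_graph(data.frame(regulator = c("a", "a", "b"),
                             target = c("a", "b", "a"), effect = 1L))
  pp3 <- min_path_lengths(g3, max_L = 8)
  expect_false(any(pp3$input_gene == pp3$output_gene))
  expect_equal(min_path_lengths(tfn_graph(
    data.frame(regulator = character(), target = character(),
               effect = integer())), 3),
    data.frame(input_gene = character(), output_gene = character(),
               L = integer()), ignore_attr = TRUE)
})

test_that("path lengths agree with the Floyd-Warshall oracle", {
  for (s in 1:25) {
    g <- random_tfn(sample(5:30, 1), runif(1, 0.05, 0.25), seed = 100 + s)
    maxL <- sample(1:8, 1)
    got <- min_path_lengths(g, maxL)
    orc <- oracle_pairs(g, maxL)
    expect_equal(got, orc, ignore_attr = TRUE)
  }
})

test_that("topology metrics match hand examples and global counts", {
  star <- tfn_graph(data.frame(regulator = "tf",
                               target = sprintf("g%d", 1:5), effect = 1L))
  tm <- topology_metrics(star)
  expect_equal(tm$nodes$out_degree[tm$nodes$gene == "tf"], 5L)
  expect_true(all(tm$nodes$in_degree[tm$nodes$gene != "tf"] == 1L))
  expect_equal(tm$summary$n_self_loops, 0L)
  expect_equal(tm$summary$n_components, 1L)

  tri <- tfn_graph(data.frame(regulator = c("a", "b", "c"),
                              target = c("b", "c", "a"), effect = 1L))
  tmt <- topology_metrics(tri)
  expect_equal(length(unique(tmt$nodes$betweenness)), 1) # symmetry
  expect_equal(length(unique(tmt$nodes$stress_centrality)), 1)
})

test_that("topology metrics agree with the matrix oracle on random graphs", {
  for (s in 1:15) {
    g <- random_tfn(sample(5:20, 1), runif(1, 0.08, 0.3), seed = 200 + s)
    got <- topology_metrics(g)$nodes
    orc <- oracle_metrics(g)
    expect_equal(got, orc, tolerance = 1e-10)
  }
})

test_that("graph export/import round-trips both formats exactly", {
  g <- random_tfn(12, 0.2, seed = 7)
  for (fmt in c("tsv", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_graph(g, f, fmt)
    g2 <- import_graph(f, fmt)
    e1 <- g$edges[order(g$edges$regulator, g$edges$target), ]
    e2 <- g2$edges[order(g2$edges$regulator, g2$edges$target), ]
    expect_equal(e1, e2, ignore_attr = TRUE)
  }
  # empty graph still writes a valid file
  ge <- tfn_graph(data.frame(regulator = character(), target = character(),
                             effect = integer()))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_graph(ge, f, "tsv")
  expect_equal(nrow(import_graph(f, "tsv")$edges), 0)
})

test_that("removing one activating input decreases sum_r by exactly one", {
  g <- random_tfn(30, 0.15, seed = 33)
  prof <- regulatory_profile(g, g$nodes)
  pos <- which(prof$sum_r > 0)
  expect_gt(length(pos), 0)
  gene <- prof$gene[pos[1]]
  act <- which(g$edges$target == gene & g$edges$effect == 1L)[1]
  g2 <- tfn_graph(g$edges[-act, ], nodes = g$nodes)
  prof2 <- regulatory_profile(g2, g$nodes)
  expect_equal(prof2$sum_r[prof2$gene == gene],
               prof$sum_r[prof$gene == gene] - 1L)
})
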