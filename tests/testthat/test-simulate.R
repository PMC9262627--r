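test_that("network generation respects the feasibility limits and sign logic", {
  expect_error(network_spec(n_genes = 100, n_tfs = 5, mean_in_degree = 10),
               "infeasible")
  # all-activator limit: b == K_TF for every gene after expansion
  net <- generate_network(network_spec(n_genes = 500, n_tfs = 50,
                                       frac_activating = 1, seed = 2))
  g <- expand_to_gene_graph(net$records, net$annotations)
  prof <- regulatory_profile(g, net$genes)
  expect_true(all(prof$b == prof$k_tf))
  expect_true(all(net$records$regulator %in% net$tfs))
  # every operon/tu target is annotated, so expansion never errors
  kinds <- net$records$target_kind
  expect_true(all(kinds %in% c("gene", "tf", "operon", "tu")))
})

test_that("generation is byte-identical across runs at a fixed seed", {
  spec <- network_spec(n_genes = 300, n_tfs = 30, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_network(generate_network(spec), d1)
  write_network(generate_network(spec), d2)
  for (f in c("interactions.tsv", "annotations.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and the emitted dialect is consumed unchanged by the parsers
  rec <- parse_interactions(file.path(d1, "interactions.tsv"))
  ann <- read_unit_annotation(file.path(d1, "annotations.tsv"))
  net <- generate_network(spec)
  expect_equal(rec$effect, net$records$effect)
  expect_equal(nrow(ann), nrow(net$annotations))
  g1 <- expand_to_gene_graph(rec, ann)
  g2 <- expand_to_gene_graph(net$records, net$annotations)
  expect_equal(g1$edges, g2$edges, ignore_attr = TRUE)
})

test_that("the staged response model follows its update rule exactly", {
  # no shift, no noise: everything is zero
  g0 <- tfn_graph(data.frame(regulator = "a", target = "b", effect = -1L))
  p0 <- sim_params(rnap_fold = 1, sigma_short = 0, sigma_mid = 0,
                   sigma_prior = 0, sensitivity_sd = 0, w = 2,
                   center_lfc = FALSE, seed = 1)
  tr0 <- simulate_shift(g0, p0)
  expect_true(all(tr0$lfc_short == 0 & tr0$lfc_mid == 0 & tr0$lfc_prior == 0))

  # single repressing edge, rho = 0.5, s = 1, w = 0.5: the repressor's drop
  # de-represses its target at mid-term
  p1 <- sim_params(rnap_fold = 0.5, sigma_short = 0, sigma_mid = 0,
                   sigma_prior = 0, sensitivity_sd = 0, w = 0.5,
                   center_lfc = FALSE, seed = 1)
  tr1 <- simulate_shift(g0, p1)
  expect_equal(tr1$lfc_short[tr1$gene == "b"], -1)
  expect_equal(tr1$lfc_mid[tr1$gene == "b"], -0.5)
  expect_equal(tr1$lfc_mid[tr1$gene == "a"], -1) # no inputs: unchanged

  # bias mechanism forced by the formula: balanced inputs cancel
  g2 <- tfn_graph(data.frame(regulator = c("t1", "t2", "t1", "t2"),
                             target = c("u", "u", "v", "v"),
                             effect = c(1L, 1L, 1L, -1L)))
  tr2 <- simulate_shift(g2, p1)
  expect_gt(abs(tr2$lfc_mid[tr2$gene == "u"]),
            abs(tr2$lfc_mid[tr2$gene == "v"]))
  expect_equal(tr2$lfc_mid[tr2$gene == "v"], -1) # exact cancellation
})

test_that("emitted DE tables are calibrated and honour the conventions", {
  net <- generate_network(network_spec(n_genes = 4000, n_tfs = 300,
                                       seed = 3))
  g <- expand_to_gene_graph(net$records, net$annotations)
  # null truth: raw p-values are uniform (t-test is exact here)
  pnull <- sim_params(rnap_fold = 1, sigma_short = 0, sigma_mid = 0,
                      sigma_prior = 0, w = 0, seed = 4)
  trn <- simulate_shift(g, pnull, genes = net$genes)
  den <- emit_de_table(trn, pnull, "mid")
  expect_gt(mean(den$pvalue < 0.05), 0.03)
  expect_lt(mean(den$pvalue < 0.05), 0.07)
  # zero-sum convention holds exactly with centering on
  expect_lt(abs(sum(den$lfc)), 1e-9)
  expect_true(zero_sum_check(den)$pass)
  # BH adjustment is monotone in the raw p-value
  ord <- order(den$pvalue)
  expect_true(all(diff(den$fdr[ord]) >= -1e-12))
  # vanishing replicate noise sends true responders' FDR to zero
  psharp <- sim_params(sigma_rep = 1e-6, seed = 5)
  trs <- simulate_shift(g, psharp, genes = net$genes)
  des <- emit_de_table(trs, psharp, "mid")
  movers <- abs(trs$lfc_mid - mean(trs$lfc_mid)) > 0.2
  expect_lt(max(des$fdr[movers]), 1e-6)
})

test_that("without propagation the mid- and short-term tables are alike", {
  net <- generate_network(network_spec(n_genes = 2000, n_tfs = 150,
                                       seed = 1))
  g <- expand_to_gene_graph(net$records, net$annotations)
  rejections <- vapply(1:10, function(s) {
    params <- sim_params(w = 0, seed = s)
    tr <- simulate_shift(g, params, genes = net$genes)
    de_s <- emit_de_table(tr, params, "short")
    de_m <- emit_de_table(tr, params, "mid")
    suppressWarnings(stats::ks.test(de_s$lfc, de_m$lfc))$p.value < 0.1
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("RNAP time series emit the exact logistic when noiseless", {
  ts <- emit_rnap_timeseries(a = 1, c = 0.5, t0 = 100, k = 0.05, sem = 0)
  expect_equal(ts$y, 1 + (0.5 - 1) / (1 + exp(-0.05 * (ts$t - 100))))
  # equal asymptotes give a constant series
  tsc <- emit_rnap_timeseries(a = 0.7, c = 0.7, t0 = 100, k = 0.05, sem = 0)
  expect_true(all(tsc$y == 0.7))
  # noisy series carry their per-point SEM for downstream fitting
  tsn <- emit_rnap_timeseries(1, 0.5, 100, 0.05, sem = 0.02, seed = 6)
  expect_true(all(tsn$y_sem == 0.02))
  expect_false(all(tsn$y == ts$y))
})

test_that("scenario driver writes all artifacts consistently", {
  d <- withr::local_tempdir()
  out <- simulate_scenario(list(network = list(n_genes = 300, n_tfs = 30,
                                               seed = 8),
                                params = list(seed = 9)),
                           dir = d)
  expect_true(all(file.exists(file.path(
    d, c("interactions.tsv", "annotations.tsv",
         "de_prior.csv", "de_short.csv", "de_mid.csv")))))
  back <- load_de_table(file.path(d, "de_mid.csv"))
  expect_equal(back$lfc, out$tables$mid$lfc, tolerance = 1e-12)
})

test_that("mean bias grows with in-degree under independent random signs", {
  net <- generate_network(network_spec(n_genes = 10000, n_tfs = 600,
                                       mean_in_degree = 1.6,
                                       frac_activating = 0.5, seed = 10))
  g <- expand_to_gene_graph(net$records, net$annotations)
  prof <- regulatory_profile(g, net$genes)
  # E|sum of k signs| is flat between k and k+1 for odd k, so compare
  # pooled classes where the closed form is strictly ordered
  grp <- cut(prof$k_tf, c(0.5, 2.5, 4.5, Inf),
             labels = c("1-2", "3-4", "5+"))
  mb <- tapply(prof$b[!is.na(grp)], grp[!is.na(grp)], mean)
  expect_true(all(diff(mb) > 0))
})
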