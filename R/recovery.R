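#' End-to-end synthetic shift study
#'
#' Runs the whole pipeline on one synthetic realization of the study
#' conditions: generate a signed network with operon structure, simulate
#' the staged RNAP-shift response, emit DE-style tables for the three
#' timepoints, and measure the quantities the analysis is about --
#' with/without-input response contrast, ensemble response curves over
#' mean |b|, the constant-|b| control over mean K_TF, and input-output
#' pair regressions at path lengths 1..3 for the short- and mid-term
#' tables.
#'
#' @param seed seed controlling network, simulation and sampling.
#' @param n_genes,n_tfs network size (defaults 4000 genes, 300 TFs).
#' @param rnap_fold RNAP concentration ratio (default 0.5).
#' @param w propagation weight (default 0.4).
#' @param b_grid ensemble grid of imposed mean |b|.
#' @param k_grid grid of imposed mean K_TF for the constant-|b| control.
#' @param fixed_b the |b| value held fixed in the control (default 1).
#' @param cohort_size genes per cohort (default 10).
#' @param max_cohorts_per_point,max_draws ensemble sampling effort.
#' @param m Monte-Carlo expansion factor for the curve fits.
#' @return list: `profiles`, `responses` (mid/short/prior), curve fits
#'   `fit_b_mid`, `fit_b_short`, `fit_kconst_mid`, pair fits `fit_L`
#'   (list over L = 1..3, mid) and `fit_L1_short`, plus
#'   `with_without` (t-test and mean |LFC| of K_TF >= 1 vs K_TF = 0).
#' @export
run_shift_study <- function(seed, n_genes = 4000, n_tfs = 300,
                            rnap_fold = 0.5, w = 0.4,
                            b_grid = seq(0.25, 2, 0.25),
                            k_grid = seq(1, 3, 0.25), fixed_b = 1,
                            cohort_size = 10,
                            max_cohorts_per_point = 2000, max_draws = 3e5,
                            m = 1000) {
  net <- generate_network(network_spec(n_genes = n_genes, n_tfs = n_tfs,
                                       seed = seed))
  graph <- expand_to_gene_graph(net$records, net$annotations)
  params <- sim_params(rnap_fold = rnap_fold, w = w, seed = seed + 1L)
  truth <- simulate_shift(graph, params, genes = net$genes)
  responses <- list(mid = emit_de_table(truth, params, "mid"),
                    short = emit_de_table(truth, params, "short"),
                    prior = emit_de_table(truth, params, "prior"))
  profiles <- regulatory_profile(graph, net$genes)

  # with vs without input TFs (mid-term)
  amid <- abs(responses$mid$lfc)
  k <- profiles$k_tf[match(responses$mid$gene, profiles$gene)]
  tt <- two_sample_t(amid[k >= 1], amid[k == 0])
  with_without <- list(mu_with = mean(amid[k >= 1]),
                       mu_without = mean(amid[k == 0]),
                       p_value = tt$p_value)

  # ensemble response curves over imposed mean |b|
  cs_b <- sample_cohorts(profiles, "b", grid = b_grid, size = cohort_size,
                         max_cohorts_per_point = max_cohorts_per_point,
                         max_draws = max_draws, seed = seed + 2L)
  curve_mid <- response_curve(cs_b, responses$mid)
  curve_short <- response_curve(cs_b, responses$short)
  fit_b_mid <- mc_ols(curve_mid$x, curve_mid$y, curve_mid$y_sem,
                      m = m, seed = seed + 3L)
  fit_b_short <- mc_ols(curve_short$x, curve_short$y, curve_short$y_sem,
                        m = m, seed = seed + 4L)

  # constant-|b| control: varying mean K_TF must carry no trend
  fit_kconst_mid <- NULL
  curve_kconst <- NULL
  cs_k <- suppressWarnings(
    conditional_cohorts(profiles, fixed = "b", fixed_value = fixed_b,
                        varying_grid = k_grid, size = cohort_size,
                        max_cohorts_per_point = max_cohorts_per_point,
                        max_draws = max_draws, seed = seed + 5L))
  if (length(cs_k$points) >= 3) {
    curve_kconst <- response_curve(cs_k, responses$mid)
    fit_kconst_mid <- mc_ols(curve_kconst$x, curve_kconst$y,
                             curve_kconst$y_sem, m = m, seed = seed + 6L)
  }

  # input-output pair regressions at path lengths 1..3
  pp <- min_path_lengths(graph, max_L = 3)
  fit_L <- lapply(1:3, function(L) {
    pr <- pair_responses(pp, responses$mid, L)
    if (nrow(pr) < 3) return(NULL)
    mc_ols(pr$input_abs_lfc, pr$output_abs_lfc, rep(0, nrow(pr)), m = 1)
  })
  pr1s <- pair_responses(pp, responses$short, 1)
  fit_L1_short <- if (nrow(pr1s) >= 3) {
    mc_ols(pr1s$input_abs_lfc, pr1s$output_abs_lfc, rep(0, nrow(pr1s)),
           m = 1)
  }

  list(profiles = profiles, responses = responses,
       curve_b_mid = curve_mid, curve_b_short = curve_short,
       curve_kconst = curve_kconst,
       fit_b_mid = fit_b_mid, fit_b_short = fit_b_short,
       fit_kconst_mid = fit_kconst_mid,
       fit_L = fit_L, fit_L1_short = fit_L1_short,
       with_without = with_without)
}
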