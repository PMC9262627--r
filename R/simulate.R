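#' Specification of a random signed TFN with operon structure
#'
#' Defaults emulate the scale and shape of the *E. coli* TFN: ~4000 genes
#' regulated by ~300 TF-coding genes, heavy-tailed TF out-degrees (a few
#' global regulators with very many targets), activators and repressors in
#' comparable numbers, and operons/TUs of 1-5 genes whose members share all
#' unit-level inputs.
#'
#' @param n_genes total genes (default 4000).
#' @param n_tfs TF-coding genes (default 300).
#' @param mean_in_degree target mean number of input TFs per gene
#'   (default 1.2, matching a network of ~4700 interactions over ~4500
#'   genes); must not exceed `n_tfs`.
#' @param out_exponent Pareto tail exponent of TF out-degree (default 2.5;
#'   smaller = heavier tail). The default puts the largest regulator at
#'   roughly 5-15% of all interactions, the share the master regulators of
#'   enteric bacteria actually hold.
#' @param frac_activating probability that an interaction activates
#'   (default 0.5).
#' @param operon_size_probs probabilities of unit sizes 1..5 (default
#'   c(0.55, 0.20, 0.12, 0.08, 0.05)); size-1 entries stay standalone
#'   genes.
#' @param seed RNG seed.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(n_genes = 4000, n_tfs = 300, mean_in_degree = 1.2,
                         out_exponent = 2.5, frac_activating = 0.5,
                         operon_size_probs = c(0.55, 0.20, 0.12, 0.08, 0.05),
                         seed = 1L) {
  stopifnot(n_tfs <= n_genes, frac_activating >= 0, frac_activating <= 1,
            length(operon_size_probs) >= 1, all(operon_size_probs >= 0))
  if (mean_in_degree > n_tfs) {
    stop("infeasible spec: mean in-degree exceeds the number of TFs")
  }
  structure(list(n_genes = n_genes, n_tfs = n_tfs,
                 mean_in_degree = mean_in_degree,
                 out_exponent = out_exponent,
                 frac_activating = frac_activating,
                 operon_size_probs = operon_size_probs /
                   sum(operon_size_probs),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a random signed network in the interaction-table dialect
#'
#' Genes are partitioned into transcription units by drawing unit sizes
#' from the operon-size distribution; multi-gene units become operons or
#' TUs (half each), singletons stay plain gene targets. TF out-degrees are
#' drawn from a truncated Pareto law and scaled so the expanded gene-level
#' mean in-degree approximates the requested value; each TF regulates
#' distinct,
#' uniformly chosen units, activating with probability `frac_activating`
#' (else repressing). The emitted records/annotations are exactly what
#' [expand_to_gene_graph()] consumes, and [write_network()] serializes them
#' in the [parse_interactions()] dialect.
#'
#' @param spec a [network_spec()].
#' @return list: `records` (interaction records, integer effects),
#'   `annotations` (unit annotation), `genes` (all gene names), `tfs`
#'   (TF-coding gene names).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  genes <- sprintf("g%05d", seq_len(spec$n_genes))
  tfs <- sort(sample(genes, spec$n_tfs))

  # partition genes into units
  sizes <- integer(0)
  total <- 0
  while (total < spec$n_genes) {
    s <- sample.int(length(spec$operon_size_probs), 1,
                    prob = spec$operon_size_probs)
    sizes <- c(sizes, min(s, spec$n_genes - total))
    total <- total + min(s, spec$n_genes - total)
  }
  unit_of <- rep(seq_along(sizes), sizes)
  multi <- which(sizes >= 2)
  unit_kind <- rep(NA_character_, length(sizes))
  if (length(multi)) {
    unit_kind[multi] <- sample(c("operon", "tu"), length(multi),
                               replace = TRUE)
  }
  unit_id <- ifelse(is.na(unit_kind), NA_character_,
                    sprintf("%s%04d", substr(unit_kind, 1, 2),
                            seq_along(sizes)))
  ann_rows <- which(!is.na(unit_id[unit_of]))
  annotations <- data.frame(
    unit_id = unit_id[unit_of[ann_rows]],
    unit_kind = unit_kind[unit_of[ann_rows]],
    gene = genes[ann_rows],
    position = stats::ave(seq_along(ann_rows), unit_of[ann_rows],
                          FUN = seq_along),
    stringsAsFactors = FALSE)

  # target pool: one entry per unit (or standalone gene), with its fan-out
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  standalone <- which(sizes == 1)
  pool_target <- c(genes[starts[standalone]], unit_id[multi])
  pool_kind <- c(rep("gene", length(standalone)), unit_kind[multi])
  pool_fan <- c(rep(1L, length(standalone)), sizes[multi])
  # mark standalone TF-coding targets as "tf" records for dialect fidelity
  pool_kind[pool_kind == "gene" & pool_target %in% tfs] <- "tf"

  n_records <- max(spec$n_tfs,
                   round(spec$n_genes * spec$mean_in_degree /
                           mean(pool_fan)))
  # heavy-tailed out-degrees: truncated Pareto, scaled to n_records
  u <- stats::runif(spec$n_tfs)
  w <- u^(-1 / (spec$out_exponent - 1))
  d <- pmax(1L, round(w / sum(w) * n_records))
  d <- pmin(d, length(pool_target))

  tgt_idx <- unlist(lapply(d, function(dj) sample.int(length(pool_target),
                                                      dj)))
  records <- data.frame(
    regulator = rep(tfs, d),
    target = pool_target[tgt_idx],
    target_kind = pool_kind[tgt_idx],
    effect = ifelse(stats::runif(length(tgt_idx)) < spec$frac_activating,
                    1L, -1L),
    stringsAsFactors = FALSE)
  list(records = records, annotations = annotations,
       genes = genes, tfs = tfs)
}

#' Serialize a generated network to the interaction-table dialect
#'
#' Writes `interactions.tsv` (effects as "+" / "-" / "?") and
#' `annotations.tsv` into `dir`; [parse_interactions()] and
#' [read_unit_annotation()] read them back unchanged.
#'
#' @param network output of [generate_network()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two file paths.
#' @export
write_network <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- network$records
  rec$effect <- c("-", "?", "+")[rec$effect + 2L]
  f1 <- file.path(dir, "interactions.tsv")
  f2 <- file.path(dir, "annotations.tsv")
  utils::write.table(rec, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$annotations, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f1, f2))
}

#' Parameters of the staged RNAP-shift response simulation
#'
#' @param rnap_fold RNAP concentration ratio shifted/control (rho > 0;
#'   default 0.5, the mid dilution).
#' @param sensitivity_sd lognormal spread of the per-gene RNAP sensitivity
#'   s_i (mean 1; default 0.3). Diversity in s_i stands in for unmodelled
#'   single-gene features (promoter affinities etc.).
#' @param w propagation weight of direct input-TF changes at mid-term
#'   (default 0.4; 0 switches the network influence off).
#' @param sigma_short,sigma_mid,sigma_prior biological noise SD of the
#'   short-term, additional mid-term and pre-shift log2 fold changes
#'   (defaults 0.2, 0.05, 0.05). The mid-term increment is small: it covers
#'   ~55 min on top of the short-term state, and with the propagation
#'   switched off the mid-term table must remain statistically
#'   indistinguishable from the short-term one.
#' @param n_rep replicates per condition for emitted DE tables
#'   (default 3).
#' @param sigma_rep replicate measurement noise SD (default 0.3).
#' @param center_lfc enforce the zero-sum LFC convention on emitted tables
#'   (default TRUE).
#' @param seed RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(rnap_fold = 0.5, sensitivity_sd = 0.3, w = 0.4,
                       sigma_short = 0.2, sigma_mid = 0.05,
                       sigma_prior = 0.05, n_rep = 3, sigma_rep = 0.3,
                       center_lfc = TRUE, seed = 1L) {
  stopifnot(rnap_fold > 0, sensitivity_sd >= 0, w >= 0,
            sigma_short >= 0, sigma_mid >= 0, sigma_prior >= 0,
            n_rep >= 2, sigma_rep >= 0)
  structure(list(rnap_fold = rnap_fold, sensitivity_sd = sensitivity_sd,
                 w = w, sigma_short = sigma_short, sigma_mid = sigma_mid,
                 sigma_prior = sigma_prior, n_rep = as.integer(n_rep),
                 sigma_rep = sigma_rep, center_lfc = center_lfc,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate staged short- and mid-term responses to an RNAP shift
#'
#' Implements the minimal mechanistic propagation model. Short-term, every
#' gene follows the RNAP shift through its own sensitivity:
#' `lfc_short_i = s_i * log2(rho) + eps_i`. Mid-term, changed input-TF
#' abundances additionally push their output genes according to the signed
#' regulatory logic:
#' `lfc_mid_i = lfc_short_i + w * sum_j r_ji * lfc_short_j + eps'_i`
#' over the merged input edges j -> i (r = 0 inputs contribute nothing).
#' Pre-shift LFCs are pure noise. Optional centering subtracts the
#' gene-mean from each timepoint's LFC vector (the zero-sum convention).
#' Genes whose input TFs all share the direction of the RNAP shift (large
#' bias |b|) therefore receive coherent mid-term pushes, while balanced
#' inputs cancel -- the bias mechanism under study.
#'
#' @param graph gene-level [tfn_graph()].
#' @param params a [sim_params()].
#' @param genes gene universe (default: the graph's nodes).
#' @return data.frame `gene`, `lfc_prior`, `lfc_short`, `lfc_mid`, with
#'   attribute `timepoints = c(prior = 60, short = 125, mid = 180)` (min).
#' @export
simulate_shift <- function(graph, params, genes = NULL) {
  stopifnot(inherits(graph, "tfn_graph"), inherits(params, "sim_params"))
  if (is.null(genes)) genes <- graph$nodes
  genes <- unique(normalize_gene_name(genes))
  n <- length(genes)
  set.seed(params$seed)
  # lognormal with mean 1 and coefficient of variation sensitivity_sd
  if (params$sensitivity_sd > 0) {
    sdl <- sqrt(log(1 + params$sensitivity_sd^2))
    s <- stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else {
    s <- rep(1, n)
  }
  shift <- log2(params$rnap_fold)
  lfc_short <- s * shift + stats::rnorm(n, 0, params$sigma_short)
  if (params$rnap_fold == 1 && params$sigma_short == 0) lfc_short <- rep(0, n)

  push <- numeric(n)
  e <- graph$edges
  ri <- match(e$regulator, genes)
  ti <- match(e$target, genes)
  ok <- !is.na(ri) & !is.na(ti) & e$effect != 0L
  if (any(ok)) {
    contrib <- e$effect[ok] * lfc_short[ri[ok]]
    agg <- tapply(contrib, ti[ok], sum)
    push[as.integer(names(agg))] <- as.numeric(agg)
  }
  lfc_mid <- lfc_short + params$w * push + stats::rnorm(n, 0, params$sigma_mid)
  lfc_prior <- stats::rnorm(n, 0, params$sigma_prior)
  if (params$center_lfc) {
    lfc_prior <- lfc_prior - mean(lfc_prior)
    lfc_short <- lfc_short - mean(lfc_short)
    lfc_mid <- lfc_mid - mean(lfc_mid)
  }
  out <- data.frame(gene = genes, lfc_prior = lfc_prior,
                    lfc_short = lfc_short, lfc_mid = lfc_mid,
                    stringsAsFactors = FALSE)
  attr(out, "timepoints") <- c(prior = 60, short = 125, mid = 180)
  out
}

#' Emit a DE-style result table from simulated true responses
#'
#' Per gene, `n_rep` replicate LFC observations are drawn as
#' true LFC + Normal(0, sigma_rep); the reported LFC is the replicate
#' mean, the SE the replicate SEM, the p-value a two-sided t-test of
#' LFC/SE at n_rep - 1 degrees of freedom, and the FDR the
#' Benjamini-Hochberg adjustment across genes. With centering on, each
#' replicate column is centered across genes first, so the emitted LFC
#' vector sums to zero exactly.
#'
#' @param true_responses output of [simulate_shift()].
#' @param params a [sim_params()].
#' @param stage which truth column to observe: "prior", "short" or "mid".
#' @param condition condition label for the table.
#' @param seed RNG seed (default: derived from `params$seed` and stage so
#'   the three stages get independent replicate noise).
#' @return a [gene_responses()] table (is_deg unset).
#' @export
emit_de_table <- function(true_responses, params,
                          stage = c("mid", "short", "prior"),
                          condition = "synthetic", seed = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(params, "sim_params"))
  truth <- true_responses[[paste0("lfc_", stage)]]
  n <- length(truth)
  if (is.null(seed)) {
    seed <- params$seed + match(stage, c("prior", "short", "mid")) * 1000L
  }
  set.seed(seed)
  reps <- truth + matrix(stats::rnorm(n * params$n_rep, 0, params$sigma_rep),
                         n, params$n_rep)
  if (params$center_lfc) {
    reps <- sweep(reps, 2, colMeans(reps))
  }
  lfc <- rowMeans(reps)
  se <- apply(reps, 1, stats::sd) / sqrt(params$n_rep)
  se[se == 0] <- .Machine$double.eps
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = params$n_rep - 1)
  fdr <- stats::p.adjust(p, method = "BH")
  tp <- attr(true_responses, "timepoints")[stage]
  gene_responses(gene = true_responses$gene, lfc = lfc, lfc_se = se,
                 pvalue = p, fdr = fdr, condition = condition,
                 timepoint = unname(tp))
}

#' Write a DE table in the DESeq2-style CSV dialect
#'
#' @param responses a [gene_responses()] table.
#' @param path output CSV path.
#' @export
write_de_table <- function(responses, path) {
  out <- data.frame(gene = responses$gene,
                    log2FoldChange = responses$lfc,
                    lfcSE = responses$lfc_se,
                    pvalue = responses$pvalue,
                    padj = responses$fdr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Emit a noisy logistic RNAP time series
#'
#' Logistic curve a + (c - a)/(1 + exp(-k (t - t0))) evaluated at the
#' given timepoints plus Normal(0, sem) noise, with the per-point SEM
#' attached -- shaped like flow-cytometry mean RNAP trajectories and
#' directly consumable by [sigmoid_mc_fit()].
#'
#' @param a,c lower/upper asymptotes.
#' @param t0 midpoint time.
#' @param k rate.
#' @param sem per-point SEM (scalar or vector).
#' @param timepoints ascending measurement times (default 0..210 by 15
#'   min).
#' @param seed RNG seed.
#' @return data.frame `t`, `y`, `y_sem`.
#' @export
emit_rnap_timeseries <- function(a, c, t0, k, sem = 0,
                                 timepoints = seq(0, 210, by = 15),
                                 seed = NULL) {
  stopifnot(!is.unsorted(timepoints), all(sem >= 0))
  if (!is.null(seed)) set.seed(seed)
  sem <- rep_len(sem, length(timepoints))
  mu <- .logistic4(timepoints, a, c, t0, k)
  data.frame(t = timepoints, y = mu + stats::rnorm(length(mu), 0, sem),
             y_sem = sem)
}

#' Run a full synthetic scenario and write its artifacts
#'
#' Generates the network, simulates the shift, and writes the interaction
#' and annotation TSVs plus one DE-style CSV per timepoint into `dir`.
#' `scenario` is a list (or YAML file path, read with \pkg{yaml}) with
#' optional elements `network` and `params` holding arguments for
#' [network_spec()] and [sim_params()].
#'
#' @param scenario list or YAML path.
#' @param dir output directory.
#' @return invisible list with the generated `network`, `truth` and the
#'   three response tables.
#' @export
simulate_scenario <- function(scenario = list(), dir) {
  if (is.character(scenario)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML scenarios requires the yaml package")
    }
    scenario <- yaml::read_yaml(scenario)
  }
  spec <- do.call(network_spec, scenario$network %||% list())
  params <- do.call(sim_params, scenario$params %||% list())
  net <- generate_network(spec)
  write_network(net, dir)
  graph <- expand_to_gene_graph(net$records, net$annotations)
  truth <- simulate_shift(graph, params, genes = net$genes)
  tables <- lapply(c(prior = "prior", short = "short", mid = "mid"),
                   function(st) {
                     tab <- emit_de_table(truth, params, stage = st)
                     write_de_table(tab, file.path(dir,
                                                   paste0("de_", st, ".csv")))
                     tab
                   })
  invisible(list(network = net, truth = truth, tables = tables))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
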