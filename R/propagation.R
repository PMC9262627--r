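#' Pair input and output gene responses at a given path length
#'
#' Joins the minimum-path-length pair list with a response table: each
#' ordered (input gene, output gene) pair at path length `L` contributes
#' one (input |LFC|, output |LFC|) observation. Pairs where either gene
#' lacks a response are dropped and counted; self-pairs are already
#' excluded upstream. Optionally restricts output genes to one or more
#' K_TF classes (e.g. K_TF = 1 isolates single-input genes).
#'
#' @param path_pairs output of [min_path_lengths()].
#' @param responses response table of one condition/timepoint.
#' @param L path length to select.
#' @param profiles regulatory profiles; required with `ktf_filter`.
#' @param ktf_filter integer vector of output-gene K_TF classes to keep.
#' @return data.frame `L`, `input_gene`, `output_gene`, `input_abs_lfc`,
#'   `output_abs_lfc`, with attribute `n_dropped`.
#' @export
pair_responses <- function(path_pairs, responses, L, profiles = NULL,
                           ktf_filter = NULL) {
  pp <- path_pairs[path_pairs$L == L, , drop = FALSE]
  if (!is.null(ktf_filter)) {
    if (is.null(profiles)) stop("ktf_filter requires profiles")
    keep_genes <- profiles$gene[profiles$k_tf %in% ktf_filter]
    pp <- pp[pp$output_gene %in% keep_genes, , drop = FALSE]
  }
  lut <- abs(responses$lfc)
  names(lut) <- responses$gene
  in_a <- unname(lut[pp$input_gene])
  out_a <- unname(lut[pp$output_gene])
  ok <- !is.na(in_a) & !is.na(out_a)
  out <- data.frame(L = L,
                    input_gene = pp$input_gene[ok],
                    output_gene = pp$output_gene[ok],
                    input_abs_lfc = in_a[ok],
                    output_abs_lfc = out_a[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Maximal-correlation bound for paired responses
#'
#' Sorts the input and output |LFC| values independently in ascending order
#' and re-pairs them rank to rank before fitting by ordinary least squares.
#' By the rearrangement inequality this pairing maximizes the sample
#' correlation over all re-pairings, giving the upper bound against which
#' the observed pairing's fit is judged.
#'
#' @param paired output of [pair_responses()] (>= 3 pairs).
#' @return an `mc_fit` of the rank-matched pairs (exact OLS; no
#'   uncertainty expansion).
#' @export
max_correlation_bound <- function(paired) {
  if (nrow(paired) < 3) stop("need at least 3 pairs")
  x <- sort(paired$input_abs_lfc)
  y <- sort(paired$output_abs_lfc)
  mc_ols(x, y, y_sem = rep(0, length(y)), m = 1)
}

#' Within-operon position effect on input-TF coupling
#'
#' Case study on operons with exactly three genes: every operon-level input
#' TF (a regulator hitting all three members) is paired with each member,
#' and the (input |LFC|, output |LFC|) relationship is fitted separately
#' for positions 1, 2 and 3 (promoter-proximal to distal). Pairwise ANCOVA
#' then tests whether the three position lines share slope and intercept;
#' under equal propagation to all members the lines are indistinguishable.
#'
#' @param annotations unit annotation table.
#' @param graph gene-level [tfn_graph()].
#' @param responses response table.
#' @param unit_kind "operon" (default) or "tu".
#' @return list: `fits` (per-position `mc_fit` or NULL when < 3 pairs),
#'   `pairs` (per-position pair tables), `ancova` (data.frame of pairwise
#'   slope/intercept p-values, NULL when skipped), `n_units`.
#' @export
position_effect_test <- function(annotations, graph, responses,
                                 unit_kind = "operon") {
  ann <- annotations[annotations$unit_kind == unit_kind, , drop = FALSE]
  ann$unit_id <- normalize_gene_name(ann$unit_id)
  ann$gene <- normalize_gene_name(ann$gene)
  sizes <- table(ann$unit_id)
  units3 <- names(sizes)[sizes == 3]
  if (!length(units3)) stop("no 3-gene ", unit_kind, "s in annotation")

  edges <- graph$edges
  lut <- abs(responses$lfc)
  names(lut) <- responses$gene

  pair_rows <- list()
  n_units_used <- 0L
  for (u in units3) {
    members <- ann[ann$unit_id == u, , drop = FALSE]
    members <- members[order(members$position), , drop = FALSE]
    # operon-level input TFs: regulators hitting every member gene
    regs <- Reduce(intersect,
                   lapply(members$gene,
                          function(g) edges$regulator[edges$target == g]))
    regs <- setdiff(regs, members$gene) # autoregulation is not an input here
    if (!length(regs)) next
    n_units_used <- n_units_used + 1L
    for (p in 1:3) {
      g <- members$gene[p]
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        position = p, input_gene = regs, output_gene = g,
        input_abs_lfc = unname(lut[regs]),
        output_abs_lfc = unname(lut[g]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pair_rows)) stop("no 3-gene ", unit_kind,
                               " has operon-level input TFs")
  pairs <- do.call(rbind, pair_rows)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  by_pos <- split(pairs, pairs$position)

  fits <- lapply(1:3, function(p) {
    d <- by_pos[[as.character(p)]]
    if (is.null(d) || nrow(d) < 3 || stats::var(d$input_abs_lfc) == 0) {
      return(NULL)
    }
    mc_ols(d$input_abs_lfc, d$output_abs_lfc,
           y_sem = rep(0, nrow(d)), m = 1)
  })
  names(fits) <- paste0("position_", 1:3)

  ancova <- NULL
  if (n_units_used < 2) {
    warning("single usable ", unit_kind,
            ": position fits computed, ANCOVA skipped")
  } else {
    combos <- utils::combn(3, 2)
    ancova <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
      a <- by_pos[[as.character(combos[1, i])]]
      b <- by_pos[[as.character(combos[2, i])]]
      if (is.null(a) || is.null(b) || nrow(a) < 3 || nrow(b) < 3) {
        return(NULL)
      }
      cmp <- ancova_compare(a$input_abs_lfc, a$output_abs_lfc,
                            b$input_abs_lfc, b$output_abs_lfc)
      data.frame(position_a = combos[1, i], position_b = combos[2, i],
                 p_slope = cmp$p_slope, p_intercept = cmp$p_intercept)
    }))
  }
  list(fits = fits, pairs = by_pos, ancova = ancova, n_units = n_units_used)
}
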