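#' Filter a raw count matrix before differential-expression analysis
#'
#' A gene is removed iff it has fewer than `min_count` counts in strictly
#' more than `max_low_samples` samples, or its mean count is below
#' `min_mean`. Gene order is preserved. `max_low_samples = 3` matches a
#' single-batch design; merged multi-batch designs use 6.
#'
#' @param counts numeric matrix genes x samples, non-negative, with gene
#'   rownames and unique sample colnames.
#' @param min_count low-count threshold (default 5).
#' @param max_low_samples maximum tolerated number of low-count samples
#'   (default 3).
#' @param min_mean minimum mean count (default 10).
#' @return the filtered matrix.
#' @export
filter_counts <- function(counts, min_count = 5, max_low_samples = 3,
                          min_mean = 10) {
  stopifnot(is.matrix(counts), nrow(counts) > 0, ncol(counts) > 0)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(colnames(counts))) stop("sample labels must be unique")
  n_low <- rowSums(counts < min_count)
  keep <- !(n_low > max_low_samples) & !(rowMeans(counts) < min_mean)
  counts[keep, , drop = FALSE]
}

#' Load a differential-expression result table
#'
#' Reads a delimited table of per-gene DE results (as produced by a
#' DESeq2-style engine) into the internal response format. Column names are
#' configurable; missing adjusted p-values are preserved as NA.
#'
#' @param path file path (TSV or CSV; `sep` guessed from the extension
#'   unless given).
#' @param condition condition label attached to every row (e.g. "LB_0.5x").
#' @param timepoint timepoint in minutes.
#' @param columns named character vector mapping internal fields
#'   `gene`, `lfc`, `lfc_se`, `pvalue`, `fdr` to file column names.
#' @param sep field separator; default guesses "," for .csv else tab.
#' @return data.frame of gene responses: `gene`, `lfc`, `lfc_se`, `pvalue`,
#'   `fdr`, `condition`, `timepoint`, `is_deg` (NA until classified).
#' @export
load_de_table <- function(path, condition = NA_character_,
                          timepoint = NA_real_,
                          columns = c(gene = "gene", lfc = "log2FoldChange",
                                      lfc_se = "lfcSE", pvalue = "pvalue",
                                      fdr = "padj"),
                          sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "lfc", "lfc_se", "pvalue", "fdr")
  if (!all(need %in% names(columns))) {
    stop("`columns` must name: ", paste(need, collapse = ", "))
  }
  missing_cols <- setdiff(unname(columns[need]), names(tab))
  if (length(missing_cols)) {
    stop("DE table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  gene <- normalize_gene_name(tab[[columns["gene"]]])
  if (anyDuplicated(gene)) {
    stop("duplicate gene id: ", gene[which(duplicated(gene))[1]])
  }
  num <- function(field) {
    v <- tab[[columns[field]]]
    bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stop("non-numeric ", field, " at row ", bad[1], ": '", v[bad[1]], "'")
    }
    suppressWarnings(as.numeric(v))
  }
  lfc <- num("lfc")
  if (anyNA(lfc)) stop("non-numeric lfc at row ", which(is.na(lfc))[1])
  gene_responses(gene = gene, lfc = lfc, lfc_se = num("lfc_se"),
                 pvalue = num("pvalue"), fdr = num("fdr"),
                 condition = condition, timepoint = timepoint)
}

#' Assemble a gene-response table from vectors
#'
#' @param gene,lfc,lfc_se,pvalue,fdr parallel vectors (fdr may contain NA).
#' @param condition,timepoint labels recycled across rows.
#' @return response data.frame as in [load_de_table()].
#' @export
gene_responses <- function(gene, lfc, lfc_se = NA_real_, pvalue = NA_real_,
                           fdr = NA_real_, condition = NA_character_,
                           timepoint = NA_real_) {
  out <- data.frame(gene = normalize_gene_name(gene),
                    lfc = as.numeric(lfc),
                    lfc_se = as.numeric(lfc_se),
                    pvalue = as.numeric(pvalue),
                    fdr = as.numeric(fdr),
                    condition = as.character(condition),
                    timepoint = as.numeric(timepoint),
                    is_deg = NA,
                    stringsAsFactors = FALSE)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE)) {
    stop("fdr values must lie in [0, 1]")
  }
  out
}

#' Two-stage differentially-expressed-gene classification
#'
#' Stage one keeps genes with FDR below `fdr_threshold`; stage two
#' additionally requires |LFC| strictly above the condition's mean |LFC| of
#' the non-significant genes (FDR > `fdr_threshold`). This removes genes
#' that are statistically significant but have negligible fold changes.
#' Genes with missing FDR take part in neither the threshold mean nor DEG
#' eligibility.
#'
#' @param responses response table of one condition/timepoint.
#' @param fdr_threshold FDR cut (default 0.05).
#' @return list with `threshold` (the |LFC| cut used) and `responses`
#'   (input with `is_deg` filled in).
#' @export
deg_classify <- function(responses, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(responses),
            all(c("gene", "lfc", "fdr") %in% names(responses)))
  ns <- !is.na(responses$fdr) & responses$fdr > fdr_threshold
  if (!any(ns)) {
    stop("no genes with FDR > ", fdr_threshold,
         ": |LFC| threshold undefined")
  }
  threshold <- mean(abs(responses$lfc[ns]))
  responses$is_deg <- !is.na(responses$fdr) &
    responses$fdr < fdr_threshold &
    abs(responses$lfc) > threshold
  list(threshold = threshold, responses = responses)
}

#' Summarize the response of a gene cohort
#'
#' Computes mean and standard deviation of |LFC| over the cohort, the SEM,
#' and the DEG count/fraction. Duplicated genes (with-replacement cohorts)
#' contribute with multiplicity. A singleton cohort has SEM 0 by convention.
#'
#' @param responses response table covering the cohort genes.
#' @param gene_set character vector of cohort members (duplicates allowed).
#' @param cohort_id optional identifier carried into the output.
#' @return one-row data.frame: `cohort`, `n`, `mu_abs_lfc`, `sigma_abs_lfc`,
#'   `sem`, `n_deg`, `frac_deg`.
#' @export
summarize_cohort <- function(responses, gene_set, cohort_id = NA_character_) {
  gene_set <- normalize_gene_name(gene_set)
  if (!length(gene_set)) stop("empty cohort")
  idx <- match(gene_set, responses$gene)
  if (anyNA(idx)) {
    stop("cohort gene(s) missing from responses: ",
         paste(unique(gene_set[is.na(idx)]), collapse = ", "))
  }
  a <- abs(responses$lfc[idx])
  n <- length(a)
  sd_a <- if (n > 1) stats::sd(a) else 0
  deg <- responses$is_deg[idx]
  n_deg <- sum(deg, na.rm = TRUE)
  data.frame(cohort = cohort_id, n = n, mu_abs_lfc = mean(a),
             sigma_abs_lfc = sd_a, sem = sd_a / sqrt(n),
             n_deg = n_deg, frac_deg = n_deg / n,
             stringsAsFactors = FALSE)
}

#' Check the zero-sum log-fold-change convention
#'
#' Median-of-ratios normalization plus zero-centered LFC shrinkage make the
#' genome-wide signed LFC sum vanish; this verifies the convention on a
#' full condition table.
#'
#' @param responses full response table of one condition.
#' @param tolerance maximum |mean LFC| accepted (default 1e-6).
#' @return list with `pass` (logical) and `mean_lfc`.
#' @export
zero_sum_check <- function(responses, tolerance = 1e-6) {
  m <- mean(responses$lfc)
  list(pass = abs(m) <= tolerance, mean_lfc = m)
}
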