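#' Sample gene cohorts with an imposed mean attribute (ensemble approach)
#'
#' Draws fixed-size gene cohorts with replacement from the regulated genes
#' (K_TF >= 1) and keeps each cohort when its achieved mean of the chosen
#' attribute (|b| or K_TF) lies within half a grid step of a grid point,
#' assigning it to the nearest point. Averaging responses over many such
#' cohorts suppresses local-topology effects, isolating the global
#' relationship between the attribute and the response.
#'
#' Cohorts are drawn in one common stream and routed to their nearest grid
#' point, so every point shares the iteration budget; sampling stops when
#' all points reach `max_cohorts_per_point` or the budget is spent. Fully
#' reproducible from `seed`.
#'
#' @param profiles regulatory profile table (see [regulatory_profile()]).
#' @param attribute "b" or "k_tf".
#' @param grid uniformly spaced target means (default 0 to 5 by 0.25).
#' @param size cohort size (default 10).
#' @param max_cohorts_per_point per-point cap (default 25000).
#' @param max_draws total draw budget (default 1e6).
#' @param seed RNG seed.
#' @return object of class `cohort_set`: attribute, grid, size and
#'   `points`, a list (one per non-empty grid point) of
#'   `list(target, members, achieved)` where `members` is an
#'   n_cohorts x size character matrix of gene names. Grid points with no
#'   accepted cohort are omitted with a warning.
#' @export
sample_cohorts <- function(profiles, attribute = c("b", "k_tf"),
                           grid = seq(0, 5, by = 0.25), size = 10,
                           max_cohorts_per_point = 25000, max_draws = 1e6,
                           seed = NULL) {
  attribute <- match.arg(attribute)
  stopifnot(length(grid) >= 1, size >= 1)
  if (length(grid) > 1) {
    steps <- diff(grid)
    stopifnot(all(abs(steps - steps[1]) < 1e-9))
    step <- steps[1]
  } else {
    step <- Inf # single target: any achieved mean is "nearest"
  }
  pool <- profiles[profiles$k_tf >= 1, , drop = FALSE]
  if (!nrow(pool)) stop("no regulated genes (K_TF >= 1) in profiles")
  vals <- pool[[attribute]]
  genes <- pool$gene
  if (!is.null(seed)) set.seed(seed)

  accepted <- lapply(seq_along(grid), function(i) list())
  counts <- integer(length(grid))
  drawn <- 0
  batch <- 20000L
  while (drawn < max_draws && any(counts < max_cohorts_per_point)) {
    nb <- min(batch, max_draws - drawn)
    drawn <- drawn + nb
    idx <- matrix(sample.int(length(vals), nb * size, replace = TRUE),
                  nrow = nb)
    mu <- rowMeans(matrix(vals[idx], nrow = nb))
    if (is.finite(step)) {
      pt <- round((mu - grid[1]) / step) + 1
      ok <- pt >= 1 & pt <= length(grid) &
        abs(mu - grid[pmin(pmax(pt, 1), length(grid))]) <= step / 2 + 1e-12
    } else {
      pt <- rep(1L, nb)
      ok <- abs(mu - grid[1]) <= 1e-12
    }
    for (p in unique(pt[ok])) {
      room <- max_cohorts_per_point - counts[p]
      if (room <= 0) next
      rows <- which(ok & pt == p)
      rows <- rows[seq_len(min(room, length(rows)))]
      accepted[[p]] <- c(accepted[[p]],
                         list(list(idx = idx[rows, , drop = FALSE],
                                   mu = mu[rows])))
      counts[p] <- counts[p] + length(rows)
    }
  }
  points <- list()
  for (p in seq_along(grid)) {
    if (!counts[p]) next
    idx <- do.call(rbind, lapply(accepted[[p]], `[[`, "idx"))
    members <- matrix(genes[idx], nrow = nrow(idx))
    points[[length(points) + 1]] <- list(
      target = grid[p], members = members,
      achieved = unlist(lapply(accepted[[p]], `[[`, "mu")))
  }
  empty <- grid[counts == 0]
  if (length(empty)) {
    warning("no cohorts accepted at grid point(s): ",
            paste(empty, collapse = ", "))
  }
  structure(list(attribute = attribute, grid = grid, size = size,
                 points = points),
            class = "cohort_set")
}

#' Cohorts varying one attribute at a fixed value of the other
#'
#' Like [sample_cohorts()], but cohorts are additionally required to hold
#' the mean of a second attribute fixed (within half a grid step of
#' `fixed_value`) while the varying attribute's mean spans the grid. This
#' disentangles the effect of mean |b| from mean K_TF, which are strongly
#' correlated over real networks.
#'
#' @param profiles regulatory profile table.
#' @param fixed attribute held constant: "b" or "k_tf".
#' @param fixed_value imposed mean of the fixed attribute.
#' @param varying_grid uniformly spaced targets for the other attribute.
#' @inheritParams sample_cohorts
#' @return a `cohort_set` over the varying attribute; infeasible grid
#'   points are omitted with a warning. Each point records
#'   `achieved_fixed`, the fixed-attribute means of its cohorts.
#' @export
conditional_cohorts <- function(profiles, fixed = c("b", "k_tf"),
                                fixed_value, varying_grid = seq(0, 5, 0.25),
                                size = 10, max_cohorts_per_point = 25000,
                                max_draws = 1e6, seed = NULL) {
  fixed <- match.arg(fixed)
  varying <- if (fixed == "b") "k_tf" else "b"
  stopifnot(length(varying_grid) >= 1)
  if (length(varying_grid) > 1) {
    steps <- diff(varying_grid)
    stopifnot(all(abs(steps - steps[1]) < 1e-9))
    step <- steps[1]
  } else step <- 0.25
  pool <- profiles[profiles$k_tf >= 1, , drop = FALSE]
  if (!nrow(pool)) stop("no regulated genes (K_TF >= 1) in profiles")
  fv <- pool[[fixed]]
  vv <- pool[[varying]]
  genes <- pool$gene
  if (!is.null(seed)) set.seed(seed)

  accepted <- lapply(seq_along(varying_grid), function(i) list())
  counts <- integer(length(varying_grid))
  drawn <- 0
  batch <- 20000L
  while (drawn < max_draws && any(counts < max_cohorts_per_point)) {
    nb <- min(batch, max_draws - drawn)
    drawn <- drawn + nb
    idx <- matrix(sample.int(length(genes), nb * size, replace = TRUE),
                  nrow = nb)
    mu_f <- rowMeans(matrix(fv[idx], nrow = nb))
    mu_v <- rowMeans(matrix(vv[idx], nrow = nb))
    pt <- round((mu_v - varying_grid[1]) / step) + 1
    ok <- abs(mu_f - fixed_value) <= step / 2 + 1e-12 &
      pt >= 1 & pt <= length(varying_grid) &
      abs(mu_v - varying_grid[pmin(pmax(pt, 1), length(varying_grid))]) <=
        step / 2 + 1e-12
    for (p in unique(pt[ok])) {
      room <- max_cohorts_per_point - counts[p]
      if (room <= 0) next
      rows <- which(ok & pt == p)
      rows <- rows[seq_len(min(room, length(rows)))]
      accepted[[p]] <- c(accepted[[p]],
                         list(list(idx = idx[rows, , drop = FALSE],
                                   mu = mu_v[rows], muf = mu_f[rows])))
      counts[p] <- counts[p] + length(rows)
    }
  }
  points <- list()
  for (p in seq_along(varying_grid)) {
    if (!counts[p]) next
    idx <- do.call(rbind, lapply(accepted[[p]], `[[`, "idx"))
    points[[length(points) + 1]] <- list(
      target = varying_grid[p],
      members = matrix(genes[idx], nrow = nrow(idx)),
      achieved = unlist(lapply(accepted[[p]], `[[`, "mu")),
      achieved_fixed = unlist(lapply(accepted[[p]], `[[`, "muf")))
  }
  empty <- varying_grid[counts == 0]
  if (length(empty)) {
    warning("infeasible grid point(s) omitted: ",
            paste(empty, collapse = ", "))
  }
  structure(list(attribute = varying, grid = varying_grid, size = size,
                 fixed = fixed, fixed_value = fixed_value, points = points),
            class = "cohort_set")
}

#' Bootstrap equal-size control for the K_TF response trend
#'
#' The raw K_TF classes shrink as K_TF grows, so their mean responses have
#' unequal precision. This control subsamples every class down to a common
#' cohort size (default: the size of the smallest class used) without
#' replacement, `n_cohorts` times, and reports the bootstrap mean and SEM
#' of the class mean |LFC|. Classes smaller than the cohort size fall back
#' to sampling with replacement and are flagged.
#'
#' @param profiles regulatory profile table.
#' @param responses response table covering the profiled genes.
#' @param ktf_classes K_TF values to analyse (default: all observed).
#' @param n_cohorts bootstrap cohorts per class (default 10000).
#' @param cohort_size common subsample size (default: smallest class size).
#' @param seed RNG seed.
#' @return data.frame: `k_tf`, `n_genes`, `cohort_size`, `mu_abs_lfc`,
#'   `sem`, `with_replacement`.
#' @export
bootstrap_equal_size <- function(profiles, responses, ktf_classes = NULL,
                                 n_cohorts = 10000, cohort_size = NULL,
                                 seed = NULL) {
  merged <- merge(profiles, responses[c("gene", "lfc")], by = "gene")
  if (is.null(ktf_classes)) ktf_classes <- sort(unique(merged$k_tf))
  class_sizes <- vapply(ktf_classes,
                        function(k) sum(merged$k_tf == k), integer(1))
  if (any(class_sizes == 0)) stop("empty K_TF class requested")
  if (is.null(cohort_size)) cohort_size <- min(class_sizes)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(ktf_classes), function(i) {
    k <- ktf_classes[i]
    a <- abs(merged$lfc[merged$k_tf == k])
    n <- length(a)
    replace <- n < cohort_size
    mus <- vapply(seq_len(n_cohorts), function(j) {
      mean(a[sample.int(n, cohort_size, replace = replace)])
    }, numeric(1))
    data.frame(k_tf = k, n_genes = n, cohort_size = cohort_size,
               mu_abs_lfc = mean(mus),
               sem = if (n_cohorts > 1) stats::sd(mus) / sqrt(n_cohorts) else 0,
               with_replacement = replace)
  })
  do.call(rbind, out)
}

#' Response curve over a cohort set
#'
#' For every grid point, averages the cohort-level mean |LFC| over all its
#' cohorts; the point's y_sem is the SEM of those cohort means. Cohorts
#' containing genes without a response are dropped and counted.
#'
#' @param cohorts a `cohort_set` (see [sample_cohorts()]).
#' @param responses response table.
#' @return data.frame: `x` (imposed mean attribute), `y` (mean over cohorts
#'   of cohort mu|LFC|), `y_sem`, `n_cohorts`, `n_dropped`.
#' @export
response_curve <- function(cohorts, responses) {
  stopifnot(inherits(cohorts, "cohort_set"))
  lut <- abs(responses$lfc)
  names(lut) <- responses$gene
  rows <- lapply(cohorts$points, function(p) {
    m <- matrix(lut[p$members], nrow = nrow(p$members))
    complete <- !apply(is.na(m), 1, any)
    n_drop <- sum(!complete)
    if (!any(complete)) return(NULL)
    mus <- rowMeans(m[complete, , drop = FALSE])
    data.frame(x = p$target, y = mean(mus),
               y_sem = if (length(mus) > 1) {
                 stats::sd(mus) / sqrt(length(mus))
               } else 0,
               n_cohorts = length(mus), n_dropped = n_drop)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no cohort has complete responses")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dump a cohort set to TSV for auditability
#'
#' One row per cohort member: `grid_point  cohort_id  gene`.
#'
#' @param cohorts a `cohort_set`.
#' @param path output TSV path.
#' @export
write_cohorts <- function(cohorts, path) {
  stopifnot(inherits(cohorts, "cohort_set"))
  rows <- lapply(cohorts$points, function(p) {
    n <- nrow(p$members)
    data.frame(grid_point = p$target,
               cohort_id = rep(seq_len(n), times = ncol(p$members)),
               gene = as.vector(p$members), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$grid_point, tab$cohort_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mean achieved attribute pairing for a cohort set
#'
#' For each grid point of an attribute-|b| (or attribute-K_TF) cohort set,
#' returns the imposed mean together with the mean of the other attribute
#' over the same cohorts, exposing how mean |b| and mean K_TF co-vary.
#'
#' @param cohorts a `cohort_set`.
#' @param profiles regulatory profile table.
#' @return data.frame `x` (imposed mean), `other_mean`, `other_sem`,
#'   `n_cohorts`.
#' @export
attribute_pairing <- function(cohorts, profiles) {
  stopifnot(inherits(cohorts, "cohort_set"))
  other <- if (cohorts$attribute == "b") "k_tf" else "b"
  lut <- profiles[[other]]
  names(lut) <- profiles$gene
  rows <- lapply(cohorts$points, function(p) {
    m <- matrix(lut[p$members], nrow = nrow(p$members))
    mus <- rowMeans(m)
    data.frame(x = p$target, other_mean = mean(mus),
               other_sem = if (length(mus) > 1) {
                 stats::sd(mus) / sqrt(length(mus))
               } else 0,
               n_cohorts = length(mus))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
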