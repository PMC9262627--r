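make_profiles <- function(k_tf, b, prefix = "g") {
  data.frame(gene = sprintf("%s%04d", prefix, seq_along(k_tf)),
             k_tf = as.integer(k_tf), sum_r = as.integer(b),
             b = as.integer(b), stringsAsFactors = FALSE)
}

test_that("degenerate attribute pools land every cohort on one grid point", {
  prof <- make_profiles(k_tf = rep(3, 50), b = rep(2, 50))
  cs <- suppressWarnings(
    sample_cohorts(prof, "b", grid = 1:3, size = 10,
                   max_cohorts_per_point = 100, max_draws = 5000,
                   seed = 1))
  expect_warning(
    sample_cohorts(prof, "b", grid = 1:3, size = 10,
                   max_cohorts_per_point = 10, max_draws = 2000, seed = 1),
    "no cohorts accepted")
  targets <- vapply(cs$points, `[[`, numeric(1), "target")
  expect_equal(targets, 2)
  expect_equal(nrow(cs$points[[1]]$members), 100)
  expect_true(all(cs$points[[1]]$achieved == 2))
})

test_that("accepted cohorts sit within half a grid step of their point", {
  set.seed(2)
  prof <- make_profiles(k_tf = sample(1:5, 400, TRUE),
                        b = sample(0:4, 400, TRUE))
  cs <- sample_cohorts(prof, "b", grid = 1:3, size = 10,
                       max_cohorts_per_point = 200, max_draws = 1e4,
                       seed = 3)
  blut <- prof$b
  names(blut) <- prof$gene
  for (p in cs$points) {
    # exhaustive post-hoc recheck from the member lists themselves
    mus <- rowMeans(matrix(blut[p$members], nrow = nrow(p$members)))
    expect_equal(mus, p$achieved, ignore_attr = TRUE)
    expect_true(all(abs(mus - p$target) <= 0.5 + 1e-12))
  }
})

test_that("cohort sampling is bit-for-bit reproducible from the seed", {
  set.seed(4)
  prof <- make_profiles(k_tf = sample(1:5, 200, TRUE),
                        b = sample(0:4, 200, TRUE))
  a <- sample_cohorts(prof, "k_tf", grid = seq(2, 4, 0.5), size = 10,
                      max_cohorts_per_point = 50, max_draws = 5000, seed = 11)
  b <- sample_cohorts(prof, "k_tf", grid = seq(2, 4, 0.5), size = 10,
                      max_cohorts_per_point = 50, max_draws = 5000, seed = 11)
  expect_identical(a, b)
})

test_that("conditional cohorts hold the fixed attribute while spanning the grid", {
  # all genes have b = 1 but K_TF in {1, 3, 5}
  prof <- make_profiles(k_tf = rep(c(1, 3, 5), each = 60),
                        b = rep(1, 180))
  cc <- conditional_cohorts(prof, fixed = "b", fixed_value = 1,
                            varying_grid = seq(1, 5, 0.5), size = 10,
                            max_cohorts_per_point = 50, max_draws = 5e4,
                            seed = 5)
  expect_gt(length(cc$points), 3)
  for (p in cc$points) {
    expect_true(all(abs(p$achieved_fixed - 1) <= 0.25 + 1e-12))
    expect_true(all(abs(p$achieved - p$target) <= 0.25 + 1e-12))
  }
  # fixed K_TF = 2 with b in {0, 2}: mean |b| spans 0..2
  prof2 <- make_profiles(k_tf = rep(2, 120), b = rep(c(0, 2), 60))
  cc2 <- conditional_cohorts(prof2, fixed = "k_tf", fixed_value = 2,
                             varying_grid = seq(0, 2, 0.5), size = 10,
                             max_cohorts_per_point = 30, max_draws = 5e4,
                             seed = 6)
  got <- vapply(cc2$points, `[[`, numeric(1), "target")
  expect_true(all(c(0.5, 1, 1.5) %in% got))
  # infeasible stratum is omitted with a warning
  expect_warning(
    conditional_cohorts(prof2, fixed = "k_tf", fixed_value = 2,
                        varying_grid = seq(4, 5, 0.5), size = 10,
                        max_cohorts_per_point = 10, max_draws = 2000,
                        seed = 7),
    "infeasible")
})

test_that("bootstrap equal-size control recovers class means", {
  set.seed(8)
  prof <- make_profiles(k_tf = rep(c(0, 1, 2), times = c(60, 50, 12)),
                        b = rep(0, 122))
  resp <- gene_responses(gene = prof$gene,
                         lfc = rnorm(122, 0.3 + 0.1 * prof$k_tf, 0.2))
  bs <- bootstrap_equal_size(prof, resp, n_cohorts = 500, seed = 9)
  expect_equal(bs$cohort_size, rep(12, 3)) # smallest class size
  # class of exactly cohort_size genes: every subsample is the whole class
  k2 <- bs[bs$k_tf == 2, ]
  full_mu <- mean(abs(resp$lfc[match(prof$gene[prof$k_tf == 2],
                                     resp$gene)]))
  expect_equal(k2$mu_abs_lfc, full_mu)
  expect_equal(k2$sem, 0)
  expect_false(any(bs$with_replacement))
  # larger classes: bootstrap mean close to the full-class mean
  for (k in 0:1) {
    full <- mean(abs(resp$lfc[match(prof$gene[prof$k_tf == k],
                                    resp$gene)]))
    row <- bs[bs$k_tf == k, ]
    expect_lt(abs(row$mu_abs_lfc - full), 3 * max(row$sem, 0.02))
  }
  # undersized class flips to with-replacement and is flagged
  bs2 <- bootstrap_equal_size(prof, resp, ktf_classes = 2,
                              n_cohorts = 10, cohort_size = 20, seed = 10)
  expect_true(bs2$with_replacement)
  # a single cohort has SEM 0 by convention
  bs3 <- bootstrap_equal_size(prof, resp, ktf_classes = 0, n_cohorts = 1,
                              cohort_size = 5, seed = 11)
  expect_equal(bs3$sem, 0)
})

test_that("response curves average cohort means with the right SEM", {
  resp <- gene_responses(gene = c("a", "b"), lfc = c(0.4, -0.2))
  one <- structure(list(attribute = "b", grid = 1, size = 10,
                        points = list(list(
                          target = 1,
                          members = matrix("a", 1, 10),
                          achieved = 1))),
                   class = "cohort_set")
  rc <- response_curve(one, resp)
  expect_equal(rc$y, 0.4)
  expect_equal(rc$y_sem, 0)

  two <- structure(list(attribute = "b", grid = 1, size = 2,
                        points = list(list(
                          target = 1,
                          members = rbind(c("a", "a"), c("b", "b")),
                          achieved = c(1, 1)))),
                   class = "cohort_set")
  rc2 <- response_curve(two, resp)
  expect_equal(rc2$y, 0.3)
  expect_equal(rc2$y_sem, sd(c(0.4, 0.2)) / sqrt(2))
  # permuting the response table does not change the curve
  rc3 <- response_curve(two, resp[2:1, ])
  expect_equal(rc2, rc3)
  # cohorts with unresolvable members are dropped and counted
  three <- structure(list(attribute = "b", grid = 1, size = 2,
                          points = list(list(
                            target = 1,
                            members = rbind(c("a", "a"), c("zz", "b")),
                            achieved = c(1, 1)))),
                     class = "cohort_set")
  rc4 <- response_curve(three, resp)
  expect_equal(rc4$n_cohorts, 1)
  expect_equal(rc4$n_dropped, 1)
})

test_that("cohort dumps are auditable TSVs", {
  prof <- make_profiles(k_tf = rep(2, 40), b = rep(2, 40))
  cs <- sample_cohorts(prof, "b", grid = 2, size = 5,
                       max_cohorts_per_point = 8, max_draws = 1000, seed = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohorts(cs, f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("grid_point", "cohort_id", "gene"))
  expect_equal(nrow(tab), 8 * 5)
  expect_true(all(tab$gene %in% prof$gene))
})
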