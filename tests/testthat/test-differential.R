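make_pair <- function(control_vals, treated_vals, genes = NULL) {
  n <- length(control_vals)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(n))
  rn <- sprintf("p%02d", seq_len(n))
  cm <- matrix(control_vals, n, 2)
  tm <- matrix(treated_vals, n, 2)
  rownames(cm) <- rownames(tm) <- rn
  list(control = tc_matrix(cm, c(1, 1), genes, c(1, 2)),
       treated = tc_matrix(tm, c(1, 1), genes, c(1, 2)))
}

test_that("fold-change calls use inclusive thresholds", {
  pair <- make_pair(c(100, 100, 100, 100), c(200, 51, 50, 199))
  calls <- call_responsive(pair$control, pair$treated, fold_threshold = 2)
  expect_identical(calls$probe_calls$direction,
                   c("increased", "unchanged", "decreased", "unchanged"))
  expect_equal(calls$probe_calls$fold_change, c(2, 0.51, 0.5, 1.99))
})

test_that("gene collapse picks the largest-magnitude probe", {
  pair <- make_pair(c(100, 100, 100), c(300, 25, 110),
                    genes = c("gA", "gA", "gB"))
  calls <- call_responsive(pair$control, pair$treated)
  gA <- calls$gene_calls[calls$gene_calls$gene_symbol == "gA", ]
  # |log 0.25| > |log 3|: the decreased probe wins
  expect_identical(gA$direction, "decreased")
  expect_equal(gA$fold_change, 0.25)
  expect_equal(calls$n_direction_conflicts, 1)
})

test_that("swapping conditions inverts every direction", {
  set.seed(20)
  ctrl <- runif(30, 50, 500)
  trt <- ctrl * exp(rnorm(30, 0, 1))
  pair <- make_pair(ctrl, trt)
  fwd <- call_responsive(pair$control, pair$treated)
  rev <- call_responsive(pair$treated, pair$control)
  flip <- c(increased = "decreased", unchanged = "unchanged",
            decreased = "increased")
  expect_identical(unname(flip[fwd$probe_calls$direction]),
                   rev$probe_calls$direction)
  expect_equal(fwd$probe_calls$fold_change,
               1 / rev$probe_calls$fold_change, tolerance = 1e-12)
})

test_that("summary reports gene-level split percentages", {
  pair <- make_pair(rep(100, 6), c(300, 300, 25, 30, 110, 90))
  s <- responsive_summary(call_responsive(pair$control, pair$treated))
  expect_equal(s$n_increased, 2)
  expect_equal(s$n_decreased, 2)
  expect_equal(s$pct_increased, 50)
  # 2:1 planted split mirrors a two-thirds/one-third report
  pair2 <- make_pair(rep(100, 9), c(rep(300, 6), rep(25, 3)))
  s2 <- responsive_summary(call_responsive(pair2$control, pair2$treated))
  expect_equal(s2$pct_increased, 200 / 3, tolerance = 1e-10)
  expect_equal(s2$pct_decreased, 100 / 3, tolerance = 1e-10)
  # empty responsive set is flagged
  s3 <- responsive_summary(call_responsive(pair$control, pair$control))
  expect_true(s3$empty)
  expect_true(is.na(s3$pct_increased))
})

test_that("calls equal planted truth on a noiseless experiment", {
  sim <- generate_timecourse(genes_per_cluster = 10, n_background = 30,
                             noise_cv = 0, seed = 21)
  tx <- generate_treatment_experiment(sim$truth, seed = 22)
  calls <- call_responsive(tx$control, tx$treated)
  expect_identical(calls$probe_calls$direction, tx$truth$direction)
})

test_that("summary counts are invariant to probe order", {
  sim <- generate_timecourse(genes_per_cluster = 5, n_background = 10,
                             noise_cv = 0.1, seed = 23)
  tx <- generate_treatment_experiment(sim$truth, seed = 24)
  s1 <- responsive_summary(call_responsive(tx$control, tx$treated))
  perm <- sample(nrow(tx$control))
  s2 <- responsive_summary(call_responsive(tc_subset(tx$control, perm),
                                           tc_subset(tx$treated, perm)))
  expect_identical(s1, s2)
})

test_that("differential calling validates inputs", {
  pair <- make_pair(c(100, 100), c(50, 200))
  expect_error(call_responsive(pair$control,
                               tc_matrix(matrix(1, 3, 2), c(1, 1),
                                         replicate = c(1, 2))),
               "differ")
  zm <- matrix(0, 2, 2)
  rownames(zm) <- rownames(pair$treated)
  expect_error(call_responsive(tc_matrix(zm, c(1, 1), replicate = c(1, 2)),
                               pair$treated),
               "non-positive")
})
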