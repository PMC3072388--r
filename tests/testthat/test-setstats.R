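test_that("EASE score matches hand-enumerated cases", {
  # tail from an overlap of 3 reduced by one, in a 6-gene universe
  expect_equal(ease_score(3, 3, 3, 6), 0.5)
  expect_equal(ease_score(1, 10, 10, 100), 1)
  expect_equal(ease_score(0, 10, 10, 100), 1)
  expect_error(ease_score(5, 3, 4, 100), "exceeds")
  expect_error(ease_score(2, 3, 4, 3), "universe")
})

test_that("EASE equals the enumeration oracle and dominates plain Fisher", {
  for (N in c(8, 15, 22, 30)) {
    for (cs in seq(1, N, by = 3)) {
      for (ss in seq(1, N, by = 4)) {
        amax <- min(cs, ss)
        for (a in max(0, cs + ss - N):amax) {
          got <- ease_score(a, cs, ss, N)
          expect_equal(got, oracle_ease(a, cs, ss, N), tolerance = 1e-10,
                       label = sprintf("a=%d cs=%d ss=%d N=%d", a, cs, ss,
                                       N))
          fisher <- stats::phyper(a - 1, ss, N - ss, cs,
                                  lower.tail = FALSE)
          expect_gte(got + 1e-12, fisher)
        }
      }
    }
  }
})

test_that("enrichment flags a planted gene set and respects the null", {
  sim <- generate_timecourse(genes_per_cluster = 10, n_background = 40,
                             noise_cv = 0, seed = 15)
  labels <- sim$truth$archetype
  genes <- sim$truth$gene_symbol
  cluster1 <- genes[!is.na(labels) & labels == 1]
  bg <- unique(genes)
  set.seed(16)
  coll <- gene_set_collection(
    c(list(planted = cluster1),
      lapply(stats::setNames(1:20, paste0("rand", 1:20)),
             function(i) sample(bg, 10))),
    background = bg)
  enr <- enrich_clusters(labels, genes, coll, alpha = 1e-3)
  row1 <- enr[enr$cluster == 1 & enr$set == "planted", ]
  expect_true(row1$enriched)
  expect_equal(row1$overlap, 10)
  expect_equal(min(enr$p_ease[enr$cluster == 1]), row1$p_ease)
  # the planted set is disjoint from every other cluster
  other <- enr[enr$set == "planted" & enr$cluster != 1, ]
  expect_true(all(other$p_ease == 1))
  expect_true(all(enr$p_ease >= 0 & enr$p_ease <= 1))
  # under the null, enrichment calls are at most alpha-rare
  rand_rows <- enr[enr$set != "planted", ]
  expect_lte(mean(rand_rows$enriched), 1e-3 + 0.01)
})

test_that("enrichment p is monotone decreasing in overlap at fixed margins", {
  p <- vapply(0:10, ease_score, numeric(1), cluster_size = 10,
              set_size = 15, universe = 60)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("Yates chi-square matches the hand example and the null case", {
  expect_equal(round(yates_chi_square(30, 10, 10, 50)$statistic, 2), 31.64)
  expect_equal(yates_chi_square(5, 5, 5, 5)$statistic, 0)
  expect_warning(z <- yates_chi_square(0, 0, 5, 5), "zero margin")
  expect_equal(z$statistic, 0)
  expect_error(yates_chi_square(-1, 1, 1, 1), "non-negative")
})

test_that("Yates statistic matches chisq.test on small tables", {
  mismatches <- 0
  checked <- 0
  for (N in c(5, 9, 14)) {
    tabs <- expand.grid(a = 0:N, b = 0:N)
    tabs <- tabs[tabs$a + tabs$b <= N, ]
    for (r in seq_len(nrow(tabs))) {
      a <- tabs$a[r]; b <- tabs$b[r]
      rest <- N - a - b
      for (cc in 0:rest) {
        d <- rest - cc
        if ((a + b) * (cc + d) * (a + cc) * (b + d) == 0) next
        ours <- yates_chi_square(a, b, cc, d)
        ref <- suppressWarnings(
          stats::chisq.test(matrix(c(a, cc, b, d), 2, 2), correct = TRUE))
        checked <- checked + 1
        if (abs(ours$statistic - unname(ref$statistic)) > 1e-8 ||
            abs(ours$p_value - ref$p.value) > 1e-8) {
          mismatches <- mismatches + 1
        }
      }
    }
  }
  expect_gt(checked, 300)
  expect_equal(mismatches, 0)
})

test_that("Yates correction never exceeds the uncorrected statistic", {
  set.seed(17)
  for (i in 1:200) {
    cells <- rmultinom(1, size = sample(10:200, 1), prob = runif(4))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    if ((a + b) * (cc + d) * (a + cc) * (b + d) == 0) next
    yates <- yates_chi_square(a, b, cc, d)$statistic
    n <- a + b + cc + d
    pearson <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_lte(yates, pearson + 1e-12)
  }
})

test_that("overlap analysis builds the published-style table margins", {
  # counts as printed for the inhibitor experiment: 526 shared genes out of
  # responsive (2592) and early-transcriptome (1991) sets
  res <- overlap_analysis(universe = 14000, overlap = 526, size1 = 2592,
                          size2 = 1991)
  expect_equal(res$table["in", "in"], 526)
  expect_equal(res$table["in", "out"], 2592 - 526)   # responsive only
  expect_equal(res$table["out", "in"], 1991 - 526)   # transcriptome only
  expect_equal(sum(res$table), 14000)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 1e-4)
})

test_that("overlap analysis handles identical and disjoint sets", {
  s <- paste0("g", 1:40)
  same <- overlap_analysis(s, s, universe = 100)
  direct <- yates_chi_square(40, 0, 0, 60)
  expect_equal(same$statistic, direct$statistic)
  # disjoint sets covering the whole universe: d = 0, margins all positive,
  # statistic follows the Yates formula directly
  disj <- overlap_analysis(paste0("a", 1:5), paste0("b", 1:5),
                           universe = 10)
  expect_equal(disj$statistic, yates_chi_square(0, 5, 5, 0)$statistic)
  # an empty comparison set zeroes a margin and downgrades to a warning
  expect_warning(
    emp <- overlap_analysis(paste0("a", 1:5), character(0), universe = 10),
    "zero margin")
  expect_equal(emp$statistic, 0)
  expect_error(overlap_analysis(s, s, universe = 30), "universe")
})

test_that("per-cluster response counts match planted truth at zero noise", {
  sim <- generate_timecourse(genes_per_cluster = 8, n_background = 10,
                             noise_cv = 0, seed = 18)
  tx <- generate_treatment_experiment(sim$truth, up_effect = 3,
                                      down_effect = 3,
                                      p_up_in_cluster1 = 1,
                                      p_down_elsewhere = 0.5, seed = 19)
  calls <- call_responsive(tx$control, tx$treated)
  counts <- per_cluster_response_counts(sim$truth$archetype,
                                        sim$truth$gene_symbol, calls)
  truth_dir <- tx$truth
  for (cl in 1:12) {
    planted_up <- sum(truth_dir$direction == "increased" &
                        !is.na(truth_dir$archetype) &
                        truth_dir$archetype == cl)
    planted_down <- sum(truth_dir$direction == "decreased" &
                          !is.na(truth_dir$archetype) &
                          truth_dir$archetype == cl)
    expect_equal(counts$n_increased[counts$cluster == cl], planted_up)
    expect_equal(counts$n_decreased[counts$cluster == cl], planted_down)
  }
  # empty responsive set gives all-zero counts
  none <- call_responsive(tx$control, tx$control)
  zero <- per_cluster_response_counts(sim$truth$archetype,
                                      sim$truth$gene_symbol, none)
  expect_true(all(zero$n_increased == 0) && all(zero$n_decreased == 0))
})

test_that("GMT files round-trip into collections", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tsource\tg2\tg4"), tmp)
  coll <- read_gmt(tmp)
  expect_named(coll$sets, c("setA", "setB"))
  expect_setequal(coll$background, paste0("g", 1:4))
  writeLines("broken", tmp)
  expect_error(read_gmt(tmp), "malformed")
  expect_error(gene_set_collection(list(a = "g1", a = "g2"), "g1"),
               "unique")
})
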