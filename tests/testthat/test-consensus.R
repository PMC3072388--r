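test_that("agreement matrix counts co-membership fractions", {
  ens <- cbind(c(1, 1, 2), c(1, 2, 2))
  am <- build_agreement_matrix(ens)
  expect_equal(am[1, 2], 0.5)
  expect_equal(am[2, 3], 0.5)
  expect_equal(am[1, 3], 0)
  expect_equal(unname(diag(am)), rep(1, 3))
  expect_equal(unclass(am), t(unclass(am)), ignore_attr = TRUE)
  expect_identical(attr(am, "n_partitions"), 2L)
})

test_that("agreement entries are counts over partitions and permute with rows", {
  set.seed(3)
  ens <- replicate(5, sample.int(3, 12, replace = TRUE))
  am <- build_agreement_matrix(ens)
  expect_true(all(abs(am * 5 - round(am * 5)) < 1e-9))
  perm <- sample(12)
  amp <- build_agreement_matrix(ens[perm, ])
  expect_equal(unclass(amp), unclass(am)[perm, perm], ignore_attr = TRUE)
})

test_that("identical partitions give a 0/1 agreement matrix and exact recovery", {
  lab <- rep(1:3, each = 4)
  am <- build_agreement_matrix(cbind(lab, lab, lab))
  expect_true(all(am %in% c(0, 1)))
  for (delta in c(0.1, 0.5, 0.7, 1)) {
    expect_equal(adjusted_rand_index(consensus_agglomerate(am, delta), lab),
                 1)
  }
})

test_that("block agreement matrices agglomerate into their blocks", {
  am <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(consensus_agglomerate(am, 0.7)), c(1, 1, 2, 2))
})

test_that("delta = 1 with sub-unit agreement yields all singletons", {
  am <- block_am(c(3, 3), delta = 0.7, margin = 0.1, seed = 2)
  am[am == 1] <- 0.9
  diag(am) <- 1
  expect_equal(unname(consensus_agglomerate(am, 1)), 1:6)
})

test_that("agglomeration matches the exhaustive partition-search oracle", {
  # separated random block structures of several shapes
  cases <- list(c(2, 3), c(3, 3), c(2, 2, 2), c(4, 3), c(1, 3, 2))
  for (i in seq_along(cases)) {
    am <- block_am(cases[[i]], delta = 0.7, margin = 0.08, seed = i)
    got <- canon_labels(unname(consensus_agglomerate(am, 0.7)))
    expect_identical(got, oracle_consensus(am, 0.7),
                     label = paste("blocks", paste(cases[[i]],
                                                   collapse = "-")))
  }
  # chain: a-b and b-c strong, a-c weak; only one pair may merge
  chain <- rbind(c(1, 0.8, 0.5), c(0.8, 1, 0.8), c(0.5, 0.8, 1))
  expect_identical(canon_labels(unname(consensus_agglomerate(chain, 0.7))),
                   oracle_consensus(chain, 0.7))
  expect_equal(unname(consensus_agglomerate(chain, 0.7)), c(1, 1, 2))
})

test_that("every output cluster satisfies the delta constraint post hoc", {
  set.seed(5)
  for (rep in 1:5) {
    ens <- replicate(8, sample.int(3, 10, replace = TRUE))
    am <- build_agreement_matrix(ens)
    for (delta in c(0.5, 0.7, 0.9)) {
      lab <- consensus_agglomerate(am, delta)
      for (cl in unique(lab)) {
        idx <- which(lab == cl)
        if (length(idx) > 1) {
          sub <- unclass(am)[idx, idx]
          expect_gte(min(sub[upper.tri(sub)]), delta)
        }
      }
    }
  }
})

test_that("raising delta only refines the partition on fixture matrices", {
  am <- block_am(c(3, 3, 2), delta = 0.6, margin = 0.05, seed = 4)
  lab_lo <- consensus_agglomerate(am, 0.55)
  lab_hi <- consensus_agglomerate(am, 0.85)
  # probes separated at low delta stay separated at high delta
  n <- nrow(am)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (lab_lo[i] != lab_lo[j]) expect_true(lab_hi[i] != lab_hi[j])
    }
  }
})

test_that("k-star scan finds planted group counts on separated data", {
  sim <- generate_timecourse(make_default_archetypes()[c(1, 6, 11)],
                             genes_per_cluster = 12, n_background = 0,
                             noise_cv = 0.05, seed = 5)
  x <- average_replicates(sim$matrix)
  ks <- suppressWarnings(select_k_star(x, 2:6, seed = 1))
  expect_equal(ks$k_star, 3)
  expect_equal(which.max(ks$scores$stability), 2)
  expect_error(select_k_star(x, integer(0)), "empty")
})

test_that("tied stabilities resolve to the smallest k", {
  x <- toy_matrix(n_dyn = 9, n_flat = 0, seed = 7)
  ks <- suppressWarnings(select_k_star(x, 2:4, seed = 1))
  smax <- max(ks$scores$stability)
  expect_equal(ks$k_star, min(ks$scores$k[ks$scores$stability == smax]))
})

test_that("trivial-cluster screen keeps coherent clusters, drops singletons", {
  set.seed(8)
  n <- 30
  ens <- replicate(10, sample.int(5, n, replace = TRUE))
  am <- unclass(build_agreement_matrix(ens))
  # implant a perfectly coherent block
  am[1:6, 1:6] <- 1
  labels <- c(rep(1L, 6), 2L, rep(3L, 23))
  res <- remove_trivial_clusters(labels, am, p_value = 0.05,
                                 n_permutations = 500, seed = 3)
  expect_true(all(!is.na(res$labels[1:6])))
  expect_true(is.na(res$labels[7]))            # singleton always trivial
  expect_true(2 %in% res$trivial_removed$cluster)
  expect_error(remove_trivial_clusters(labels, am, n_permutations = 50),
               "100")
})

test_that("screen results are reproducible under a fixed seed", {
  set.seed(9)
  ens <- replicate(6, sample.int(4, 20, replace = TRUE))
  am <- build_agreement_matrix(ens)
  lab <- consensus_agglomerate(am, 0.5)
  r1 <- remove_trivial_clusters(lab, am, n_permutations = 200, seed = 7)
  r2 <- remove_trivial_clusters(lab, am, n_permutations = 200, seed = 7)
  expect_identical(r1, r2)
})
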