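# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, brute-force restatement of the quantity it checks
# and never calls the implementation under test.

# --- partitions ------------------------------------------------------------

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_max + 1L)) {
      recurse(c(labels, l), max(next_max, l))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Canonical first-occurrence renumbering of a label vector.
canon_labels <- function(labels) {
  match(labels, unique(labels))
}

# Exhaustive consensus oracle: among all partitions whose within-cluster
# pairwise agreements all reach delta, pick the fewest clusters, then the
# largest minimum within-cluster agreement, then the lexicographically
# smallest canonical labeling.
oracle_consensus <- function(am, delta) {
  n <- nrow(am)
  parts <- all_partitions(n)
  feasible <- Filter(function(p) {
    for (cl in unique(p)) {
      idx <- which(p == cl)
      if (length(idx) > 1) {
        sub <- am[idx, idx]
        if (min(sub[upper.tri(sub)]) < delta) return(FALSE)
      }
    }
    TRUE
  }, parts)
  k <- vapply(feasible, max, 0L)
  cand <- feasible[k == min(k)]
  if (length(cand) > 1) {
    minw <- vapply(cand, function(p) {
      w <- 1
      for (cl in unique(p)) {
        idx <- which(p == cl)
        if (length(idx) > 1) {
          sub <- am[idx, idx]
          w <- min(w, sub[upper.tri(sub)])
        }
      }
      w
    }, numeric(1))
    cand <- cand[minw == max(minw)]
  }
  if (length(cand) > 1) {
    key <- vapply(cand, function(p) paste(canon_labels(p), collapse = ""),
                  "")
    cand <- cand[order(key)]
  }
  canon_labels(cand[[1]])
}

# Block agreement matrix: within-block entries >= delta + margin, cross
# entries <= delta - margin, unit diagonal; counts rounded to n_partitions
# grid so the matrix is a legal agreement matrix.
block_am <- function(sizes, delta = 0.7, margin = 0.1, n_partitions = 10,
                     seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  with_seed_local(seed, {
    hi <- matrix(stats::runif(n * n, delta + margin, 1), n, n)
    lo <- matrix(stats::runif(n * n, 0, delta - margin), n, n)
    am <- ifelse(outer(lab, lab, `==`), hi, lo)
    am[lower.tri(am)] <- t(am)[lower.tri(am)]
    am <- round(am * n_partitions) / n_partitions
    am <- pmin(pmax(am, 0), 1)
    diag(am) <- 1
    am
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# --- hypergeometric / chi-square ------------------------------------------

# EASE score by direct enumeration of the hypergeometric mass function.
oracle_ease <- function(overlap, cluster_size, set_size, universe) {
  if (overlap <= 1) return(1)
  j <- seq(overlap - 1, min(cluster_size, set_size))
  sum(choose(set_size, j) * choose(universe - set_size, cluster_size - j)) /
    choose(universe, cluster_size)
}

# --- small data builders ---------------------------------------------------

# Tiny averaged matrix with planted dynamic and flat probes.
toy_matrix <- function(n_dyn = 4, n_flat = 4, seed = 1) {
  arks <- make_default_archetypes()[c(1, 4, 7, 10)]
  with_seed_local(seed, {
    rows <- lapply(seq_len(n_dyn), function(i) {
      arks[[(i - 1) %% 4 + 1]]$profile * stats::runif(1, 100, 1000)
    })
    flats <- lapply(seq_len(n_flat), function(i) {
      rep(stats::runif(1, 100, 1000), 7)
    })
    vals <- do.call(rbind, c(rows, flats))
    rownames(vals) <- sprintf("p%02d", seq_len(nrow(vals)))
    tc_matrix(vals, archetype_days(),
              gene_symbols = sprintf("g%02d", seq_len(nrow(vals))))
  })
}
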