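#' Build the agreement matrix of a partition ensemble
#'
#' Entry (i, j) is the fraction of base partitions that place probes i and j
#' in the same cluster. The matrix is symmetric with unit diagonal and every
#' entry times the number of partitions is an integer count. Pooling many
#' methods and metrics this way dilutes the biases of any single clustering
#' algorithm or distance.
#'
#' @param ensemble a `partition_ensemble` from [run_base_clusterers()], or a
#'   plain integer matrix with one label column per partition
#' @return an n x n `agreement_matrix` (numeric matrix with attribute
#'   `n_partitions`)
#' @export
build_agreement_matrix <- function(ensemble) {
  lab <- if (inherits(ensemble, "partition_ensemble")) ensemble$labels
         else as.matrix(ensemble)
  if (ncol(lab) < 1) stop("empty ensemble")
  n <- nrow(lab)
  acc <- matrix(0, n, n)
  for (j in seq_len(ncol(lab))) {
    lv <- lab[, j]
    if (length(lv) != n) stop("partitions differ in length")
    z <- outer(lv, sort(unique(lv)), `==`) * 1
    acc <- acc + tcrossprod(z)
  }
  am <- acc / ncol(lab)
  dimnames(am) <- list(rownames(lab), rownames(lab))
  structure(am, n_partitions = ncol(lab),
            class = c("agreement_matrix", "matrix", "array"))
}

#' Select the suggestive cluster number K*
#'
#' For every candidate k the full base ensemble is run, its agreement matrix
#' built, and the agreement stability scored as the mean over off-diagonal
#' entries of `|2 AM - 1|`: 1 when every pair is either always or never
#' co-clustered (a bimodal, stable consensus) and 0 when every pair is
#' co-clustered half the time. K* is the candidate with the largest score,
#' ties resolved towards the smallest k. The score is a replaceable
#' stability heuristic; the per-k scores are returned so the scan can be
#' inspected.
#'
#' @param x averaged [tc_matrix()] of dynamic probes
#' @param k_range integer vector of candidate cluster numbers (within
#'   \[2, n - 1\])
#' @param seed integer seed forwarded to the stochastic base methods
#' @param config see [pipeline_config()]
#' @return list with `k_star` and `scores` (data frame of k, stability,
#'   ensemble size)
#' @export
select_k_star <- function(x, k_range = 2:12, seed = 1,
                          config = pipeline_config()) {
  vals <- if (inherits(x, "tc_matrix")) tc_values(x) else as.matrix(x)
  if (length(k_range) == 0) stop("empty 'k_range'")
  if (min(k_range) < 2 || max(k_range) > nrow(vals) - 1)
    stop("'k_range' must lie within [2, n - 1]")
  prep <- prepare_base_inputs(vals)
  off <- upper.tri(matrix(0, nrow(vals), nrow(vals)))
  stab <- numeric(length(k_range))
  msize <- integer(length(k_range))
  for (i in seq_along(k_range)) {
    ens <- run_base_clusterers(vals, k_range[i], seed = seed,
                               config = config, prep = prep)
    am <- build_agreement_matrix(ens)
    stab[i] <- mean(abs(2 * am[off] - 1))
    msize[i] <- ncol(ens$labels)
  }
  list(k_star = k_range[which.max(stab)],
       scores = data.frame(k = k_range, stability = stab,
                           n_partitions = msize))
}

#' Consensus agglomeration under an agreement level
#'
#' Agglomerative consensus clustering over the agreement matrix: every probe
#' starts as its own cluster; at each step the two clusters whose weakest
#' cross-pair agreement is largest are merged, as long as that weakest
#' agreement is at least `delta`. This is complete-linkage agglomeration in
#' agreement space, so the stopping rule guarantees the defining property of
#' the output: within every final cluster, all pairwise agreements are at
#' least `delta`. Tied merge candidates are resolved towards the smallest
#' probe index pair, making the procedure deterministic.
#'
#' @param am an `agreement_matrix` (or symmetric numeric matrix in \[0,1\])
#' @param delta minimum pairwise agreement within a cluster, in (0, 1]
#' @return integer label vector (clusters numbered by smallest member index)
#' @examples
#' am <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
#' consensus_agglomerate(am, delta = 0.7)  # 1 1 2 2
#' @export
consensus_agglomerate <- function(am, delta = 0.7) {
  if (delta <= 0 || delta > 1) stop("'delta' must lie in (0, 1]")
  S <- unclass(as.matrix(am))
  n <- nrow(S)
  if (n != ncol(S)) stop("agreement matrix must be square")
  diag(S) <- -Inf
  parent <- seq_len(n)                 # cluster slot of each probe
  # Merging always absorbs the higher slot into the lower, so a slot index
  # equals the smallest probe index of its cluster; the first column-major
  # hit of which.max is then exactly the smallest tied (i, j) pair.
  repeat {
    pos <- which.max(S)
    best <- S[pos]
    if (best < delta) break
    i <- (pos - 1L) %/% n + 1L         # column (smaller slot)
    j <- (pos - 1L) %% n + 1L          # row (larger slot)
    newrow <- pmin(S[i, ], S[j, ])
    S[i, ] <- newrow
    S[, i] <- newrow
    S[i, i] <- -Inf
    S[j, ] <- -Inf
    S[, j] <- -Inf
    parent[parent == j] <- i
  }
  labels <- match(parent, sort(unique(parent)))
  names(labels) <- rownames(am)
  labels
}

#' Remove trivial consensus clusters
#'
#' Screens every consensus cluster for significance against a permutation
#' null: the observed mean intra-cluster agreement is compared with the mean
#' agreement of `n_permutations` random probe sets of the same size drawn
#' from the same agreement matrix. Clusters whose permutation p-value is not
#' below `p_value`, and all singletons, are marked unassigned (`NA`) and
#' reported; only the surviving significant patterns are analyzed further.
#'
#' @param labels integer labels from [consensus_agglomerate()]
#' @param am the `agreement_matrix` the labels were derived from
#' @param p_value significance threshold (default 0.05)
#' @param n_permutations number of random draws per cluster (>= 100)
#' @param seed integer seed for the draws
#' @return list with `labels` (surviving clusters renumbered 1..K by
#'   smallest member index, `NA` for unassigned probes) and
#'   `trivial_removed` (data frame of cluster id, size, p-value; singletons
#'   carry p-value `NA`)
#' @export
remove_trivial_clusters <- function(labels, am, p_value = 0.05,
                                    n_permutations = 1000, seed = 1) {
  if (n_permutations < 100)
    stop("'n_permutations' must be at least 100 to resolve p = 0.05")
  A <- unclass(as.matrix(am))
  n <- length(labels)
  if (nrow(A) != n) stop("labels and agreement matrix disagree in size")
  ids <- sort(unique(labels))
  out <- rep(NA_integer_, n)
  removed <- data.frame(cluster = integer(), size = integer(),
                        p_value = numeric())
  kept_min_idx <- integer()
  kept_ids <- integer()
  with_seed(seed, {
    for (cl in ids) {
      idx <- which(labels == cl)
      s <- length(idx)
      if (s < 2) {
        removed <- rbind(removed, data.frame(cluster = cl, size = s,
                                             p_value = NA_real_))
        next
      }
      obs <- (sum(A[idx, idx]) - s) / (s * (s - 1))
      null <- vapply(seq_len(n_permutations), function(b) {
        r <- sample.int(n, s)
        (sum(A[r, r]) - s) / (s * (s - 1))
      }, numeric(1))
      p <- (1 + sum(null >= obs)) / (1 + n_permutations)
      if (p < p_value) {
        kept_ids <- c(kept_ids, cl)
        kept_min_idx <- c(kept_min_idx, min(idx))
      } else {
        removed <- rbind(removed, data.frame(cluster = cl, size = s,
                                             p_value = p))
      }
    }
  })
  if (length(kept_ids)) {
    renum <- order(kept_min_idx)
    for (r in seq_along(renum)) {
      out[labels == kept_ids[renum[r]]] <- r
    }
  }
  names(out) <- names(labels)
  list(labels = out, trivial_removed = removed)
}
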