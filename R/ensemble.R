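#' Pairwise distances between probe profiles
#'
#' Distances feeding the non-Euclidean base clusterers. The Pearson distance
#' is `1 - r` where `r` is the Pearson correlation of two row profiles, so
#' it is invariant to scaling a profile and ranges over \[0, 2\].
#'
#' @param x a [tc_matrix()] or numeric matrix (probes in rows)
#' @param metric `"euclidean"`, `"manhattan"` or `"pearson"`
#' @return a [stats::dist] object
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
#' as.matrix(pairwise_distance(m, "pearson"))["a", "b"]  # 2: r = -1
#' @export
pairwise_distance <- function(x, metric = c("euclidean", "manhattan",
                                            "pearson")) {
  metric <- match.arg(metric)
  vals <- if (inherits(x, "tc_matrix")) tc_values(x) else as.matrix(x)
  if (nrow(vals) < 2) stop("at least two rows are required")
  if (metric == "pearson") {
    if (any(apply(vals, 1, stats::sd) == 0))
      stop("constant row: Pearson correlation undefined")
    d <- stats::as.dist(1 - stats::cor(t(vals)))
    attr(d, "method") <- "pearson"
    d
  } else {
    stats::dist(vals, method = metric)
  }
}

# Harden a fuzzy membership matrix (rows = items) by maximal membership,
# ties broken towards the lowest cluster index.
harden_membership <- function(memb) {
  max.col(memb, ties.method = "first")
}

# Deterministic 1 x k batch self-organizing map on raw profiles.
# Codebooks are initialised linearly along the first principal component
# (sign fixed so the heaviest-loading coordinate is positive), then updated
# for a fixed epoch budget with a Gaussian neighbourhood that shrinks
# towards single-unit updates. Unit assignment is the returned partition.
som_line <- function(x, k, epochs = 20) {
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  sc <- xc %*% v
  pos <- seq(min(sc), max(sc), length.out = k)
  W <- outer(pos, v) + rep(ctr, each = k)          # k x p codebooks
  xsq <- rowSums(x^2)
  bmu <- integer(n)
  for (e in seq_len(epochs)) {
    d2 <- outer(xsq, rowSums(W^2), `+`) - 2 * x %*% t(W)
    bmu <- max.col(-d2, ties.method = "first")
    sigma <- max(k / 2 * (1 - (e - 1) / epochs), 0.5)
    h <- exp(-(outer(bmu, seq_len(k), `-`))^2 / (2 * sigma^2))
    wsum <- colSums(h)
    wsum[wsum == 0] <- 1
    W <- crossprod(h, x) / wsum
  }
  d2 <- outer(xsq, rowSums(W^2), `+`) - 2 * x %*% t(W)
  max.col(-d2, ties.method = "first")
}

# Precompute the k-independent ingredients of the base ensemble: the three
# distance matrices and both hierarchical trees per non-Euclidean metric.
prepare_base_inputs <- function(x) {
  vals <- if (inherits(x, "tc_matrix")) tc_values(x) else as.matrix(x)
  d <- list(pearson = pairwise_distance(vals, "pearson"),
            manhattan = pairwise_distance(vals, "manhattan"))
  list(values = vals, dist = d,
       hclust = lapply(d, stats::hclust, method = "average"),
       diana = lapply(d, cluster::diana))
}

#' Run the base clustering battery
#'
#' Produces the partition ensemble feeding the agreement matrix: the four
#' distance-based methods — average-linkage hierarchical (`hclust`),
#' divisive (`diana`), fuzzy medoid (`fanny`) and medoid partitioning
#' (`pam`) — each under Pearson and Manhattan distance, plus `kmeans`, fuzzy
#' c-means (`cmeans`), a 1-by-k self-organizing map and Gaussian model-based
#' clustering (`mclust`) on the raw Euclidean profiles, i.e. twelve
#' partitions when all methods succeed. Fuzzy partitions are hardened by
#' maximal membership (ties to the lowest cluster index). A method that
#' errors, fails to converge or degenerates to uniform memberships is
#' dropped with a warning and recorded, so the ensemble size may fall below
#' twelve.
#'
#' @param x averaged [tc_matrix()] (or numeric matrix) of dynamic probes
#' @param k number of clusters requested from every base method
#' @param seed integer seed controlling the stochastic methods (k-means
#'   restarts, c-means initialisation)
#' @param config ensemble settings, see [pipeline_config()]; only the
#'   `fanny_memb_exp`, `cmeans_m`, `kmeans_nstart` and `som_epochs` entries
#'   are used
#' @param prep optional precomputed `prepare_base_inputs(x)` (reused across
#'   `k` during the K* scan)
#' @return object of class `partition_ensemble`: list with `labels` (n x m
#'   integer matrix, one column per successful partition), `provenance`
#'   (data frame of method, metric, k per column) and `dropped` (character
#'   vector of failed method/metric pairs)
#' @export
run_base_clusterers <- function(x, k, seed = 1, config = pipeline_config(),
                                prep = NULL) {
  vals <- if (inherits(x, "tc_matrix")) tc_values(x) else as.matrix(x)
  n <- nrow(vals)
  if (k < 2 || k > n) stop("'k' must lie in [2, n]")
  if (is.null(prep)) prep <- prepare_base_inputs(vals)

  runs <- list()
  add <- function(method, metric, fn) {
    runs[[length(runs) + 1]] <<- list(method = method, metric = metric,
                                      fn = fn)
  }
  for (metric in c("pearson", "manhattan")) {
    local({
      m <- metric
      add("hclust", m, function() stats::cutree(prep$hclust[[m]], k))
      add("diana", m, function() stats::cutree(stats::as.hclust(prep$diana[[m]]), k))
      add("fanny", m, function() {
        f <- cluster::fanny(prep$dist[[m]], k, memb.exp = config$fanny_memb_exp,
                            maxit = 500)
        if (f$coeff[["normalized"]] < 0.01)
          stop("fanny memberships degenerate to uniform")
        harden_membership(f$membership)
      })
      add("pam", m, function() cluster::pam(prep$dist[[m]], k,
                                            cluster.only = TRUE))
    })
  }
  add("kmeans", "euclidean", function() {
    # sample starting centers from the distinct rows so exact duplicates
    # (noise-free data) cannot abort the run
    uniq <- unique(vals)
    if (nrow(uniq) < k) stop("fewer distinct profiles than clusters")
    with_seed(child_seed(seed, 1L), {
      best <- NULL
      for (s in seq_len(config$kmeans_nstart)) {
        ctr <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
        fit <- suppressWarnings(stats::kmeans(vals, centers = ctr,
                                              iter.max = 100))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss)
          best <- fit
      }
      best$cluster
    })
  })
  add("cmeans", "euclidean", function() {
    f <- with_seed(child_seed(seed, 2L),
                   e1071::cmeans(vals, centers = k, m = config$cmeans_m,
                                 iter.max = 200))
    if (max(f$membership) < 1 / k + 0.01)
      stop("cmeans memberships degenerate to uniform")
    harden_membership(f$membership)
  })
  add("som", "euclidean", function() som_line(vals, k, config$som_epochs))
  add("mclust", "euclidean", function() {
    fit <- mclust::Mclust(vals, G = k, verbose = FALSE)
    if (is.null(fit)) stop("mclust failed to fit any model")
    fit$classification
  })

  labels <- list()
  prov <- list()
  dropped <- character()
  for (r in runs) {
    res <- tryCatch(suppressWarnings(r$fn()), error = function(e) e)
    tag <- paste0(r$method, "/", r$metric)
    if (inherits(res, "error")) {
      warning(sprintf("base method %s dropped: %s", tag,
                      conditionMessage(res)), call. = FALSE)
      dropped <- c(dropped, tag)
    } else {
      labels[[length(labels) + 1]] <- as.integer(res)
      prov[[length(prov) + 1]] <- data.frame(method = r$method,
                                             metric = r$metric, k = k,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(labels) == 0) stop("every base clustering method failed")
  lab <- do.call(cbind, labels)
  rownames(lab) <- rownames(vals)
  structure(list(labels = lab, provenance = do.call(rbind, prov),
                 dropped = dropped),
            class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("partition_ensemble: %d partitions over %d probes (k = %s)\n",
              ncol(x$labels), nrow(x$labels),
              paste(unique(x$provenance$k), collapse = ",")))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
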