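#' Scale chips to a common mean intensity
#'
#' Rescales every chip (column) by a single factor so that its mean signal
#' equals `target_mean`, the global scaling conventionally applied to MAS5
#' summaries (here 150 by default). Within-chip structure is preserved
#' exactly; no per-gene normalization is performed.
#'
#' @param x a [tc_matrix()] (replicate-level or averaged)
#' @param target_mean positive target for every column mean
#' @return a `tc_matrix` whose column means all equal `target_mean`
#' @export
scale_chips <- function(x, target_mean = 150) {
  stopifnot(inherits(x, "tc_matrix"))
  if (target_mean <= 0) stop("'target_mean' must be positive")
  mu <- colMeans(tc_values(x))
  if (any(mu <= 0)) stop("chip with non-positive mean intensity")
  vals <- sweep(tc_values(x), 2, target_mean / mu, `*`)
  tc_matrix(vals, tc_timepoints(x), tc_genes(x), tc_replicates(x))
}

#' Average replicate chips per time point
#'
#' Collapses a replicate-level matrix to one column per time point by
#' arithmetic mean of the replicate chips. No further normalization is
#' applied; clustering downstream consumes these averaged raw values.
#'
#' @param x replicate-level [tc_matrix()] (with a replicate map)
#' @return averaged `tc_matrix` with one column per time point
#' @export
average_replicates <- function(x) {
  stopifnot(inherits(x, "tc_matrix"))
  if (is.null(tc_replicates(x)))
    stop("matrix has no replicate map; already averaged?")
  tp <- tc_timepoints(x)
  days <- sort(unique(tp))
  vals <- vapply(days, function(d) {
    cols <- which(tp == d)
    if (length(cols) == 0) stop("time point without replicates")
    rowMeans(tc_values(x)[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x),
                 dimnames = list(rownames(x), NULL))
  tc_matrix(vals, days, tc_genes(x), NULL)
}

#' Kinetic two-fold filter
#'
#' Keeps the probes whose replicate-averaged profile changes at least
#' `fold_threshold`-fold over the whole course (maximum over time points
#' divided by minimum, threshold inclusive). This defines the analyzed
#' dynamic transcriptome; static background probes are discarded. The filter
#' is idempotent and invariant to rescaling a probe by a positive constant.
#'
#' @param x averaged [tc_matrix()] with strictly positive values
#' @param fold_threshold minimum max/min ratio to keep a probe
#' @return list with `matrix` (filtered `tc_matrix`, original order
#'   preserved) and `keep` (named logical mask over input probes)
#' @examples
#' m <- tc_matrix(rbind(a = c(100, 210, 100), b = c(100, 110, 100)),
#'                timepoints = c(0, 1, 2))
#' kinetic_filter(m)$keep
#' @export
kinetic_filter <- function(x, fold_threshold = 2) {
  stopifnot(inherits(x, "tc_matrix"))
  if (!is.null(tc_replicates(x)))
    stop("kinetic filter expects a replicate-averaged matrix")
  if (fold_threshold < 1) stop("'fold_threshold' must be >= 1")
  vals <- tc_values(x)
  if (any(vals <= 0))
    stop("zero or negative intensity: fold ratio undefined")
  ratio <- apply(vals, 1, max) / apply(vals, 1, min)
  keep <- ratio >= fold_threshold
  names(keep) <- rownames(x)
  list(matrix = tc_subset(x, which(keep)), keep = keep)
}
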