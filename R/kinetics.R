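#' Wave classification rules
#'
#' Tunable thresholds behind [classify_wave()]. The pivot day separates
#' "early" from "late" changes (day 3 of the course, following the
#' description of rapid regulation prior to day 3 versus progressive change
#' after it); the remaining thresholds quantify the otherwise qualitative
#' shape descriptions.
#'
#' @param pivot_day day (within the sampled interval) before which a change
#'   counts as early
#' @param direction_fold minimum end/start (or start/end) ratio to call a
#'   net direction
#' @param transient_return_tol fraction of the starting level within which
#'   the final value counts as "returned to baseline"
#' @param early_fraction fraction of the total change that must occur by
#'   `pivot_day` to call the change early, in (0, 1)
#' @return list of class `wave_rules`
#' @export
wave_rules <- function(pivot_day = 3, direction_fold = 1.5,
                       transient_return_tol = 0.25, early_fraction = 0.5) {
  if (pivot_day <= 0 || direction_fold <= 1 || transient_return_tol <= 0)
    stop("rule thresholds must be positive (direction_fold > 1)")
  if (early_fraction <= 0 || early_fraction >= 1)
    stop("'early_fraction' must lie in (0, 1)")
  structure(list(pivot_day = pivot_day, direction_fold = direction_fold,
                 transient_return_tol = transient_return_tol,
                 early_fraction = early_fraction),
            class = "wave_rules")
}

#' Classify a mean profile into a kinetic wave
#'
#' Deterministic shape classification of a positive time-course profile:
#' \enumerate{
#'   \item `transient_up_late_down` if the maximum sits at an interior time
#'     point, is at least `direction_fold` times the starting level, and the
#'     profile ends within `transient_return_tol` of where it started;
#'   \item otherwise the net direction is read from the end/start ratio
#'     against `direction_fold`;
#'   \item net-down profiles are `early_down` (the four-wave scheme has no
#'     late-down class; the fraction of the decline realised by the pivot
#'     day is reported alongside the label by the per-cluster report);
#'   \item net-up profiles are `early_up` when at least `early_fraction` of
#'     the total rise is realised by `pivot_day` (values between sampled
#'     days are interpolated linearly), else `late_up`.
#' }
#' Profiles with no qualifying shape (flat within `direction_fold`) return
#' `"none"`; such profiles can only reach the classifier when user data
#' bypassed the kinetic filter. The label is invariant to rescaling the
#' profile by a positive constant.
#'
#' @param profile numeric vector of positive mean intensities
#' @param timepoints sampling days, one per profile value
#' @param rules a [wave_rules()] object
#' @return a single wave label (see [wave_levels()]) or `"none"`
#' @examples
#' classify_wave(c(100, 50, 25, 12, 12, 12, 12))          # early_down
#' classify_wave(c(100, 200, 300, 300, 150, 100, 100))    # transient
#' @export
classify_wave <- function(profile, timepoints = archetype_days(),
                          rules = wave_rules()) {
  profile <- as.numeric(profile)
  if (length(profile) < 3) stop("at least three time points are required")
  if (length(profile) != length(timepoints))
    stop("profile and timepoints differ in length")
  if (any(profile <= 0)) stop("profile must be strictly positive")
  if (rules$pivot_day < min(timepoints) || rules$pivot_day > max(timepoints))
    stop("'pivot_day' outside the sampled interval")
  start <- profile[1]
  end <- profile[length(profile)]
  imax <- which.max(profile)
  at_pivot <- stats::approx(timepoints, profile, xout = rules$pivot_day)$y

  if (imax > 1 && imax < length(profile) &&
      profile[imax] / start >= rules$direction_fold &&
      end <= start * (1 + rules$transient_return_tol)) {
    return("transient_up_late_down")
  }
  if (end / start >= rules$direction_fold) {
    frac <- (at_pivot - start) / (end - start)
    return(if (frac >= rules$early_fraction) "early_up" else "late_up")
  }
  if (start / end >= rules$direction_fold) {
    return("early_down")
  }
  "none"
}

#' Per-cluster mean expression profiles
#'
#' Arithmetic mean intensity of a cluster's member probes at each time
#' point. Unassigned probes (`NA` labels) are excluded.
#'
#' @param x averaged [tc_matrix()]
#' @param labels integer cluster labels over the rows of `x` (`NA` =
#'   unassigned)
#' @return numeric matrix, one row per cluster (rownames = cluster id),
#'   columns named by day
#' @export
cluster_mean_profiles <- function(x, labels) {
  vals <- if (inherits(x, "tc_matrix")) tc_values(x) else as.matrix(x)
  if (length(labels) != nrow(vals))
    stop("labels must cover every row of the matrix")
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) == 0) stop("no assigned cluster")
  prof <- t(vapply(ids, function(cl) {
    idx <- which(!is.na(labels) & labels == cl)
    if (length(idx) == 0) stop("empty cluster")
    colMeans(vals[idx, , drop = FALSE])
  }, numeric(ncol(vals))))
  rownames(prof) <- ids
  colnames(prof) <- colnames(vals)
  prof
}

#' Annotate clusters with kinetic waves
#'
#' Computes mean profiles per cluster and classifies each with
#' [classify_wave()]. The report carries probe and unique-gene counts and
#' the fraction of the net change realised by the pivot day, so slow
#' decliners inside the single down wave remain visible.
#'
#' @inheritParams cluster_mean_profiles
#' @param gene_symbols optional per-probe gene symbols (defaults to the
#'   matrix annotation)
#' @param rules a [wave_rules()] object
#' @return list with `waves` (named character vector per cluster),
#'   `profiles` (matrix from [cluster_mean_profiles()]) and `report` (data
#'   frame: cluster, wave, n_probes, n_genes, early_change_fraction, then
#'   mean profile values)
#' @export
annotate_waves <- function(x, labels, gene_symbols = NULL,
                           rules = wave_rules()) {
  if (is.null(gene_symbols) && inherits(x, "tc_matrix"))
    gene_symbols <- tc_genes(x)
  prof <- cluster_mean_profiles(x, labels)
  tp <- if (inherits(x, "tc_matrix")) tc_timepoints(x)
        else seq_len(ncol(prof)) - 1
  waves <- apply(prof, 1, classify_wave, timepoints = tp, rules = rules)
  frac_by_pivot <- apply(prof, 1, function(p) {
    at_pivot <- stats::approx(tp, p, xout = rules$pivot_day)$y
    tot <- p[length(p)] - p[1]
    if (tot == 0) NA_real_ else (at_pivot - p[1]) / tot
  })
  ids <- as.integer(rownames(prof))
  n_probes <- vapply(ids, function(cl) sum(labels == cl, na.rm = TRUE), 0L)
  n_genes <- vapply(ids, function(cl) {
    g <- gene_symbols[!is.na(labels) & labels == cl]
    length(unique(g[!is.na(g) & g != ""]))
  }, 0L)
  report <- data.frame(cluster = ids, wave = unname(waves),
                       n_probes = n_probes, n_genes = n_genes,
                       early_change_fraction = unname(frac_by_pivot),
                       prof, check.names = FALSE)
  list(waves = waves, profiles = prof, report = report)
}
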