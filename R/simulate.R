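#' Simulate a replicate-level differentiation time course
#'
#' Generates probe-level intensities that emulate the structure of a
#' scaled-MAS5 microarray time course of differentiating progenitor
#' cultures: 7 sampled days, several biological replicates per day, a
#' minority of dynamic probes following planted kinetic archetypes and a
#' static background majority.
#'
#' Each planted cluster carries one characteristic expression level —
#' levels are equally spaced on the log scale across `baseline_range`,
#' down-regulated waves taking the highest levels and late-rising waves the
#' lowest (seeded shuffle within a wave) — so clusters are separated both by
#' kinetic shape and by expression level, as in real intensity data where
#' co-expressed groups with the same timing can still differ in magnitude,
#' and total chip intensity stays roughly constant over the course. By default all probes of a cluster sit exactly at the cluster
#' level and realized within-cluster spread comes from the measurement
#' noise alone, making noiseless generation an exact fixed point of the
#' clustering pipeline; `level_jitter` can widen the interval to add
#' persistent per-probe level variation on top. Background probes draw
#' independent per-probe levels log-uniformly over the full range and stay
#' flat in expectation. Noise is multiplicative log-normal with
#' coefficient of variation `noise_cv`, independent across chips and time
#' points, with unit mean so that averaging replicates is unbiased.
#'
#' @param archetypes list of [kinetic_archetype()] objects to plant
#' @param genes_per_cluster number of probes planted per archetype
#' @param n_background number of static background probes
#' @param baseline_range length-2 positive interval for expression levels
#'   (default spans typical scaled intensities around a chip mean of 150)
#' @param level_jitter length-2 positive interval of per-probe multiplicative
#'   jitter around the cluster level
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param n_replicates number of replicate chips per time point
#' @param probes_per_gene number of consecutive probes sharing one gene
#'   symbol (1 = one probe per gene; larger values exercise probe-vs-gene
#'   counting)
#' @param seed integer seed; identical seeds give identical output
#'
#' @return list of class `kinwave_sim` with elements
#'   \describe{
#'     \item{matrix}{replicate-level [tc_matrix()]}
#'     \item{truth}{data frame with `probe_id`, `gene_symbol`, `archetype`
#'       (`NA` for background), `wave` (`"background"` for background probes)
#'       and `baseline`; carries the generator settings as attributes}
#'   }
#' @examples
#' sim <- generate_timecourse(genes_per_cluster = 5, n_background = 20,
#'                            noise_cv = 0, seed = 1)
#' dim(sim$matrix)
#' @export
generate_timecourse <- function(archetypes = make_default_archetypes(),
                                genes_per_cluster = 50,
                                n_background = 500,
                                baseline_range = c(50, 5000),
                                level_jitter = c(1, 1),
                                noise_cv = 0.2,
                                n_replicates = 4,
                                probes_per_gene = 1,
                                seed = 1) {
  if (length(archetypes) < 1) stop("at least one archetype is required")
  if (genes_per_cluster < 1) stop("'genes_per_cluster' must be >= 1")
  if (n_background < 0) stop("'n_background' must be >= 0")
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (any(baseline_range <= 0) || diff(baseline_range) < 0)
    stop("'baseline_range' must be a positive, non-decreasing interval")
  days <- archetype_days()
  n_ark <- length(archetypes)
  n_planted <- n_ark * genes_per_cluster
  n <- n_planted + n_background

  with_seed(seed, {
    # Cluster levels: log-equally spaced across baseline_range. Waves are
    # interleaved along the level ladder so that clusters adjacent in
    # expression level always belong to different waves (level separates
    # same-wave clusters, kinetic shape separates same-level clusters), and
    # the wave-to-rung pattern is weighted so that the signal lost by the
    # high-level down-regulated clusters roughly balances the signal gained
    # by the rising ones — total chip intensity stays near-constant over
    # the course, as on real arrays, and scaling chips to a common mean
    # stays benign. Which archetype of a wave takes which of its wave's
    # rungs is shuffled under the seed.
    levels_spaced <- sort(exp(seq(log(baseline_range[1]),
                                  log(baseline_range[2]),
                                  length.out = max(n_ark, 2)))[seq_len(n_ark)],
                          decreasing = TRUE)
    cluster_level <- assign_levels(archetypes, levels_spaced)
    jit <- exp(stats::runif(n_planted, log(level_jitter[1]),
                            log(level_jitter[2])))
    ark_of <- rep(seq_len(n_ark), each = genes_per_cluster)
    baseline <- c(cluster_level[ark_of] * jit,
                  exp(stats::runif(n_background, log(baseline_range[1]),
                                   log(baseline_range[2]))))
    prof <- archetype_profiles(archetypes)
    expected <- rbind(prof[ark_of, , drop = FALSE],
                      matrix(1, n_background, length(days))) * baseline

    tp <- rep(days, each = n_replicates)
    rp <- rep(seq_len(n_replicates), times = length(days))
    vals <- expected[, rep(seq_along(days), each = n_replicates),
                     drop = FALSE]
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      vals <- vals * matrix(exp(stats::rnorm(n * length(tp), 0, sdlog) -
                                  sdlog^2 / 2), n, length(tp))
    }
    probe_id <- sprintf("probe_%05d_at", seq_len(n))
    gene_planted <- sprintf("G%05d", (seq_len(n_planted) - 1) %/%
                              probes_per_gene + 1L)
    gene_bg <- sprintf("BG%05d", seq_len(n_background))
    gene <- c(gene_planted, gene_bg)
    rownames(vals) <- probe_id

    truth <- data.frame(
      probe_id = probe_id,
      gene_symbol = gene,
      archetype = c(ark_of, rep(NA_integer_, n_background)),
      wave = c(vapply(archetypes, function(a) a$wave, "")[ark_of],
               rep("background", n_background)),
      baseline = baseline,
      stringsAsFactors = FALSE)
    attr(truth, "noise_cv") <- noise_cv
    attr(truth, "n_replicates") <- n_replicates
    attr(truth, "seed") <- seed
    attr(truth, "archetypes") <- archetypes

    structure(list(matrix = tc_matrix(vals, tp, gene, rp), truth = truth),
              class = "kinwave_sim")
  })
}

# Map descending expression levels onto archetypes. For the canonical
# three-per-wave design the rung pattern (by wave rank 1 = early down,
# 2 = transient, 3 = early up, 4 = late up) is the drift-balanced
# interleave below; otherwise waves are round-robined along the ladder.
# Within a wave, rungs are shuffled among its archetypes (caller provides
# RNG state).
assign_levels <- function(archetypes, levels_desc) {
  n <- length(archetypes)
  wave_rank <- match(vapply(archetypes, function(a) a$wave, ""),
                     wave_levels())
  counts <- tabulate(wave_rank, nbins = 4)
  pattern <- if (all(counts == c(3, 3, 3, 3))) {
    c(1, 1, 2, 3, 1, 4, 2, 3, 2, 4, 3, 4)
  } else {
    present <- which(counts > 0)
    left <- counts
    out <- integer(n)
    i <- 1
    while (i <= n) {
      for (w in present) {
        if (left[w] > 0) {
          out[i] <- w
          left[w] <- left[w] - 1
          i <- i + 1
        }
      }
    }
    out
  }
  level <- numeric(n)
  for (w in unique(pattern)) {
    members <- which(wave_rank == w)
    if (length(members) > 1) members <- members[sample.int(length(members))]
    level[members] <- levels_desc[which(pattern == w)]
  }
  level
}

#' Simulate a paired control/treated experiment at day 1
#'
#' Builds one-day control and treated chip sets over the probes of an
#' existing simulation, emulating a histone-deacetylase-inhibitor experiment
#' in which treatment de-represses the earliest down-regulated genes:
#' a Bernoulli(`p_up_in_cluster1`) subset of cluster-1 probes is increased
#' `up_effect`-fold in the treated condition, a Bernoulli(`p_down_elsewhere`)
#' subset of probes from the remaining clusters is decreased
#' `down_effect`-fold, and background probes are untouched. Control
#' expectation is the probe's day-1 level from its archetype; noise model,
#' replicate count and noise level are inherited from the originating
#' simulation truth. Defaults plant roughly a 2:1 increased:decreased split
#' among responsive genes.
#'
#' @param truth `truth` data frame from [generate_timecourse()]
#' @param up_effect fold increase planted on responsive cluster-1 probes
#'   (>= 1)
#' @param down_effect fold decrease planted on responsive probes of the
#'   other clusters (>= 1)
#' @param p_up_in_cluster1 probability that a cluster-1 probe responds
#' @param p_down_elsewhere probability that a probe of clusters 2+ responds
#' @param seed integer seed
#' @return list of class `kinwave_treatment` with `control` and `treated`
#'   (single-day replicate-level [tc_matrix()] objects) and `truth` (data
#'   frame of planted per-probe directions: `"increased"`, `"decreased"` or
#'   `"unchanged"`)
#' @export
generate_treatment_experiment <- function(truth,
                                          up_effect = 4,
                                          down_effect = 3,
                                          p_up_in_cluster1 = 0.8,
                                          p_down_elsewhere = 0.04,
                                          seed = 1) {
  if (up_effect < 1 || down_effect < 1) stop("effects must be >= 1")
  if (p_up_in_cluster1 < 0 || p_up_in_cluster1 > 1 ||
      p_down_elsewhere < 0 || p_down_elsewhere > 1)
    stop("probabilities must lie in [0, 1]")
  noise_cv <- attr(truth, "noise_cv")
  n_rep <- attr(truth, "n_replicates")
  archetypes <- attr(truth, "archetypes")
  if (is.null(noise_cv) || is.null(n_rep) || is.null(archetypes))
    stop("'truth' must come from generate_timecourse()")
  n <- nrow(truth)
  day1 <- vapply(archetypes, function(a) a$profile[match(1, a$days)],
                 numeric(1))
  level1 <- ifelse(is.na(truth$archetype), truth$baseline,
                   truth$baseline * day1[truth$archetype])

  with_seed(seed, {
    in_c1 <- !is.na(truth$archetype) & truth$archetype == 1L
    in_rest <- !is.na(truth$archetype) & truth$archetype != 1L
    up <- in_c1 & stats::runif(n) < p_up_in_cluster1
    down <- in_rest & stats::runif(n) < p_down_elsewhere
    effect <- rep(1, n)
    effect[up] <- up_effect
    effect[down] <- 1 / down_effect

    noisy <- function(expected) {
      m <- matrix(rep(expected, n_rep), n, n_rep)
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        m <- m * matrix(exp(stats::rnorm(n * n_rep, 0, sdlog) - sdlog^2 / 2),
                        n, n_rep)
      }
      rownames(m) <- truth$probe_id
      tc_matrix(m, rep(1, n_rep), truth$gene_symbol, seq_len(n_rep))
    }
    control <- noisy(level1)
    treated <- noisy(level1 * effect)

    direction <- rep("unchanged", n)
    direction[up] <- "increased"
    direction[down] <- "decreased"
    structure(list(control = control, treated = treated,
                   truth = data.frame(probe_id = truth$probe_id,
                                      gene_symbol = truth$gene_symbol,
                                      archetype = truth$archetype,
                                      direction = direction,
                                      stringsAsFactors = FALSE)),
              class = "kinwave_treatment")
  })
}

#' Write simulation output as TSV
#'
#' Writes the replicate-level matrix, the replicate-averaged matrix and the
#' simulation truth into a directory.
#'
#' @param sim result of [generate_timecourse()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tc_matrix(sim$matrix, file.path(dir, "timecourse_replicates.tsv"))
  write_tc_matrix(average_replicates(sim$matrix),
                  file.path(dir, "timecourse_averaged.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
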