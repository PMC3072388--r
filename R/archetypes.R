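#' Kinetic archetype profiles
#'
#' A kinetic archetype is an idealised expression trajectory over the seven
#' sampled days of the differentiation course (days 0, 1, 2, 3, 5, 7, 9),
#' expressed as multiples of the day-0 level. Archetypes are the planted
#' truth of the synthetic-data generator: each belongs to one of the four
#' kinetic waves used to summarise co-expression clusters — `early_down`
#' (rapid loss before day 3), `transient_up_late_down` (interior peak
#' returning to baseline), `early_up` (most of the rise before day 3) and
#' `late_up` (progressive rise after day 3).
#'
#' @param id integer archetype/cluster identifier
#' @param wave one of `"early_down"`, `"transient_up_late_down"`,
#'   `"early_up"`, `"late_up"`
#' @param profile numeric vector of 7 positive values at days 0,1,2,3,5,7,9,
#'   as multiples of the day-0 level; must span at least a two-fold range so
#'   that every archetype passes the kinetic filter
#' @return an object of class `kinetic_archetype`
#' @seealso [make_default_archetypes()], [classify_wave()]
#' @export
kinetic_archetype <- function(id, wave, profile) {
  wave <- match.arg(wave, wave_levels())
  profile <- as.numeric(profile)
  if (length(profile) != length(archetype_days()))
    stop("profile must have one value per sampled day")
  if (any(profile <= 0)) stop("profile values must be positive")
  if (max(profile) / min(profile) < 2)
    stop("archetype must span at least a two-fold range")
  structure(list(id = as.integer(id), wave = wave, profile = profile,
                 days = archetype_days()),
            class = "kinetic_archetype")
}

#' @rdname kinetic_archetype
#' @export
archetype_days <- function() c(0, 1, 2, 3, 5, 7, 9)

#' @rdname kinetic_archetype
#' @export
wave_levels <- function() {
  c("early_down", "transient_up_late_down", "early_up", "late_up")
}

#' @export
print.kinetic_archetype <- function(x, ...) {
  cat(sprintf("kinetic_archetype %d (%s): %s\n", x$id, x$wave,
              paste(format(x$profile), collapse = " ")))
  invisible(x)
}

#' Default planted archetypes
#'
#' Twelve archetypes, three per kinetic wave, mirroring the structure of the
#' twelve significant co-expression patterns of a differentiating
#' oligodendrocyte progenitor culture: archetypes 1-3 are down-regulated
#' early (1 loses most of its signal within the first day, 2 and 3
#' progressively later), 4-6 peak transiently and return to baseline (with
#' staggered peak times), 7-9 rise mostly before day 3 with staggered onset,
#' and 10-12 rise progressively late. Every profile changes at least
#' 2.8-fold so planted probes clear the two-fold kinetic filter with margin
#' even under measurement noise.
#'
#' @return list of 12 [kinetic_archetype()] objects; deterministic.
#' @examples
#' arks <- make_default_archetypes()
#' sapply(arks, function(a) a$wave)
#' @export
make_default_archetypes <- function() {
  p <- list(
    c(1.00, 0.35, 0.25, 0.20, 0.18, 0.16, 0.15),  # down within day 1
    c(1.00, 0.70, 0.40, 0.28, 0.24, 0.22, 0.20),  # down by day 2
    c(1.00, 1.00, 0.88, 0.55, 0.32, 0.27, 0.25),  # shoulder, down by day 3
    c(1.00, 3.20, 2.20, 1.50, 1.20, 1.05, 1.00),  # sharp day-1 peak
    c(1.00, 1.60, 3.00, 2.60, 1.60, 1.20, 1.05),  # day-2 peak
    c(1.00, 1.10, 1.60, 2.60, 2.90, 1.60, 1.10),  # broad day-3/5 peak
    c(1.00, 3.00, 3.80, 4.00, 4.10, 4.10, 4.10),  # immediate rise, plateau
    c(1.00, 1.10, 1.60, 3.20, 3.50, 3.50, 3.50),  # jump at day 3
    c(1.00, 2.40, 2.90, 3.10, 3.00, 2.90, 2.80),  # fast rise, mild sag
    c(1.00, 1.05, 1.15, 1.30, 2.80, 3.00, 3.10),  # step up after day 3
    c(1.00, 1.02, 1.05, 1.10, 1.30, 2.00, 4.50),  # late acceleration
    c(1.00, 1.15, 1.35, 1.70, 2.50, 3.40, 3.70)   # steady late climb
  )
  waves <- rep(wave_levels(), each = 3)
  mapply(kinetic_archetype, id = seq_along(p), wave = waves, profile = p,
         SIMPLIFY = FALSE)
}

#' Archetype profiles as a matrix
#'
#' @param archetypes list of [kinetic_archetype()] objects
#' @return numeric matrix, one row per archetype, columns named by day
#' @export
archetype_profiles <- function(archetypes = make_default_archetypes()) {
  m <- t(vapply(archetypes, function(a) a$profile,
                numeric(length(archetype_days()))))
  rownames(m) <- vapply(archetypes, function(a) as.character(a$id), "")
  colnames(m) <- paste0("D", archetype_days())
  m
}
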