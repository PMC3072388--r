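# internal helpers shared across modules

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed; keeps values well
# inside 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()], used throughout to
#' compare recovered cluster labels with planted truth. Chance-corrected: 1
#' for identical partitions (up to relabeling), around 0 for independent ones.
#'
#' @param a,b label vectors of equal length; `NA`s allowed in either (pairs
#'   with an `NA` are dropped only if `na.rm = TRUE`, otherwise `NA` is
#'   treated as its own label).
#' @param na.rm drop positions that are `NA` in either vector
#' @return a single numeric value
#' @export
adjusted_rand_index <- function(a, b, na.rm = FALSE) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (na.rm) {
    keep <- !(is.na(a) | is.na(b))
    a <- a[keep]; b <- b[keep]
  } else {
    a <- ifelse(is.na(a), -1L, a)
    b <- ifelse(is.na(b), -1L, b)
  }
  mclust::adjustedRandIndex(a, b)
}
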