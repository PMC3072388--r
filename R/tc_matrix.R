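#' Time-course expression matrix
#'
#' Container for a probes-by-chips matrix of non-negative intensities sampled
#' along a differentiation time course. Columns correspond either to
#' individual chips (replicate-level data, one chip per time point and
#' replicate) or to time points (replicate-averaged data). Rows are probe
#' sets; an optional probe-to-gene map travels with the matrix so that
#' downstream counting can be reported both per probe set and per annotated
#' gene.
#'
#' @param values numeric matrix of non-negative intensities with one row per
#'   probe. Row names are used as probe identifiers; if absent, identifiers
#'   `probe_0001` ... are assigned.
#' @param timepoints numeric vector, one entry per column, giving the day at
#'   which each chip was sampled. Must be non-decreasing, and strictly
#'   increasing when `replicate` is `NULL` (averaged layout).
#' @param gene_symbols character vector of gene symbols, one per row. May
#'   contain empty strings for unannotated probes. Defaults to empty symbols.
#' @param replicate optional integer vector, one entry per column, giving the
#'   replicate index of each chip. `NULL` marks a replicate-averaged matrix.
#'
#' @return An object of class `tc_matrix`: the values matrix with attributes
#'   `timepoints`, `gene_symbols` and `replicate`.
#' @examples
#' m <- tc_matrix(matrix(c(100, 50, 200, 400), 2, 2), timepoints = c(0, 1))
#' tc_timepoints(m)
#' @export
tc_matrix <- function(values, timepoints, gene_symbols = NULL, replicate = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("intensity matrix contains missing values")
  if (any(values < 0)) stop("intensity matrix contains negative values")
  if (length(timepoints) != ncol(values))
    stop("'timepoints' must have one entry per column")
  if (is.unsorted(timepoints)) stop("'timepoints' must be non-decreasing")
  if (is.null(replicate) && anyDuplicated(timepoints))
    stop("averaged layout requires strictly increasing time points")
  if (!is.null(replicate) && length(replicate) != ncol(values))
    stop("'replicate' must have one entry per column")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe_%04d", seq_len(nrow(values)))
  if (is.null(gene_symbols)) gene_symbols <- rep("", nrow(values))
  if (length(gene_symbols) != nrow(values))
    stop("'gene_symbols' must have one entry per row")
  colnames(values) <- if (is.null(replicate)) {
    paste0("D", timepoints)
  } else {
    paste0("D", timepoints, "_r", replicate)
  }
  structure(values,
            timepoints = as.numeric(timepoints),
            gene_symbols = as.character(gene_symbols),
            replicate = if (is.null(replicate)) NULL else as.integer(replicate),
            class = c("tc_matrix", "matrix", "array"))
}

#' @rdname tc_matrix
#' @param x a `tc_matrix`
#' @export
tc_timepoints <- function(x) attr(x, "timepoints")

#' @rdname tc_matrix
#' @export
tc_genes <- function(x) attr(x, "gene_symbols")

#' @rdname tc_matrix
#' @export
tc_replicates <- function(x) attr(x, "replicate")

#' @rdname tc_matrix
#' @export
tc_values <- function(x) {
  y <- unclass(x)
  attr(y, "timepoints") <- NULL
  attr(y, "gene_symbols") <- NULL
  attr(y, "replicate") <- NULL
  y
}

#' Subset a time-course matrix by probe
#'
#' Row subsetting keeps the probe-to-gene map and chip annotation aligned;
#' column subsetting is intentionally not supported (chips belong together).
#'
#' @param x a `tc_matrix`
#' @param i row (probe) index
#' @param ... ignored
#' @return a `tc_matrix` restricted to the selected probes
#' @export
tc_subset <- function(x, i, ...) {
  tc_matrix(tc_values(x)[i, , drop = FALSE], tc_timepoints(x),
            tc_genes(x)[i], tc_replicates(x))
}

#' @export
print.tc_matrix <- function(x, ...) {
  rep <- tc_replicates(x)
  cat(sprintf("tc_matrix: %d probes x %d chips (%s layout)\n",
              nrow(x), ncol(x),
              if (is.null(rep)) "averaged" else "replicate-level"))
  cat("  days:", paste(unique(tc_timepoints(x)), collapse = ", "), "\n")
  n <- min(4L, nrow(x))
  print(utils::head(tc_values(x), n))
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Write a time-course matrix as TSV
#'
#' The layout mirrors the package's reader: columns `probe_id`,
#' `gene_symbol`, then one column per chip labelled `D<day>` (averaged) or
#' `D<day>_r<replicate>` (replicate-level).
#'
#' @param x a `tc_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tc_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), gene_symbol = tc_genes(x),
                   tc_values(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-course matrix from TSV
#'
#' Accepts both layouts written by [write_tc_matrix()]: value columns named
#' `D<day>` (averaged) or `D<day>_r<replicate>` (replicate-level). A
#' `gene_symbol` column is optional.
#'
#' @param path input file path
#' @return a `tc_matrix`
#' @export
read_tc_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"probe_id" %in% names(df)) stop("missing 'probe_id' column")
  val_cols <- grep("^D[0-9.]+(_r[0-9]+)?$", names(df), value = TRUE)
  if (length(val_cols) == 0) stop("no D<day> value columns found")
  has_rep <- grepl("_r", val_cols[1])
  if (!all(grepl("_r", val_cols) == has_rep))
    stop("mixed averaged and replicate-level columns")
  days <- as.numeric(sub("^D([0-9.]+).*$", "\\1", val_cols))
  reps <- if (has_rep) as.integer(sub("^.*_r([0-9]+)$", "\\1", val_cols)) else NULL
  o <- order(days, if (has_rep) reps else seq_along(days))
  vals <- as.matrix(df[, val_cols, drop = FALSE])[, o, drop = FALSE]
  rownames(vals) <- df$probe_id
  gene <- if ("gene_symbol" %in% names(df)) as.character(df$gene_symbol)
          else rep("", nrow(df))
  gene[is.na(gene)] <- ""
  tc_matrix(vals, days[o], gene, if (has_rep) reps[o] else NULL)
}
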