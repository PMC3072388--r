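#' Gene-set collection
#'
#' Named sets of gene symbols plus the background universe against which
#' enrichment is computed (conventionally the whole genome represented on
#' the platform). Symbols in a set that are missing from the background are
#' kept but flagged, so a mismatched annotation is visible rather than
#' silently shrinking the universe.
#'
#' @param sets named list of character vectors of gene symbols
#' @param background character vector of gene symbols forming the universe
#' @return object of class `gene_set_collection`
#' @export
gene_set_collection <- function(sets, background) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must carry unique names")
  if (length(background) == 0) stop("empty background universe")
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  out_of_bg <- lapply(sets, function(s) setdiff(s, background))
  structure(list(sets = sets, background = background,
                 out_of_background = out_of_bg),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path GMT file path
#' @param background universe of gene symbols; defaults to the union of all
#'   set members
#' @return a [gene_set_collection()]
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  if (is.null(background)) background <- unique(unlist(sets))
  gene_set_collection(sets, background)
}

#' EASE score: conservative one-sided enrichment p-value
#'
#' The EASE score is a jackknifed variant of the one-sided Fisher exact
#' test: one overlapping gene is removed before computing the upper-tail
#' hypergeometric probability, penalising categories supported by a single
#' gene. An overlap of 0 or 1 therefore scores 1. The score is always at
#' least as large as the plain Fisher p-value on the same table.
#'
#' @param overlap number of genes in both the study set and the category
#' @param cluster_size size of the study set (e.g. a co-expression cluster)
#' @param set_size size of the category within the universe
#' @param universe size of the background universe
#' @return one-sided p-value in \[0, 1\]
#' @examples
#' ease_score(3, 3, 3, 6)  # 0.5
#' @export
ease_score <- function(overlap, cluster_size, set_size, universe) {
  if (overlap < 0 || cluster_size < 0 || set_size < 0 || universe <= 0)
    stop("counts must be non-negative and universe positive")
  if (overlap > min(cluster_size, set_size))
    stop("overlap exceeds a set size")
  if (cluster_size > universe || set_size > universe)
    stop("set larger than universe")
  if (overlap <= 1) return(1)
  # P(X >= overlap - 1), X ~ Hypergeometric(universe, set_size, cluster_size)
  stats::phyper(overlap - 2, set_size, universe - set_size, cluster_size,
                lower.tail = FALSE)
}

#' EASE enrichment of clusters against a gene-set collection
#'
#' Scores every (cluster, set) pair with [ease_score()]. Genes, not probes,
#' are the counting unit: duplicate probes of one gene are collapsed and
#' blank symbols dropped; cluster and set memberships are intersected with
#' the background universe. A Benjamini-Hochberg column is appended for
#' information only — the enrichment call itself uses the fixed `alpha`.
#'
#' @param labels integer cluster labels per probe (`NA` = unassigned)
#' @param gene_symbols gene symbol per probe
#' @param collection a [gene_set_collection()]
#' @param alpha enrichment threshold on the EASE score (default `1e-3`)
#' @return data frame: cluster, set, overlap, cluster_size, set_size,
#'   p_ease, enriched, p_bh
#' @export
enrich_clusters <- function(labels, gene_symbols, collection, alpha = 1e-3) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(labels) != length(gene_symbols))
    stop("labels and gene symbols differ in length")
  bg <- collection$background
  universe <- length(bg)
  ids <- sort(unique(labels[!is.na(labels)]))
  rows <- list()
  for (cl in ids) {
    g <- unique(gene_symbols[!is.na(labels) & labels == cl])
    g <- intersect(g[!is.na(g) & g != ""], bg)
    for (sn in names(collection$sets)) {
      s <- intersect(collection$sets[[sn]], bg)
      ov <- length(intersect(g, s))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, set = sn, overlap = ov, cluster_size = length(g),
        set_size = length(s),
        p_ease = ease_score(ov, length(g), length(s), universe),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$enriched <- tab$p_ease < alpha
  tab$p_bh <- stats::p.adjust(tab$p_ease, method = "BH")
  tab
}

#' Yates-corrected chi-square test of a 2x2 table
#'
#' Continuity-corrected chi-square statistic
#' `N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with a p-value
#' from the chi-square distribution on 1 degree of freedom. A table with a
#' zero margin is degenerate; it returns statistic 0 (p = 1) with a warning
#' rather than an error, because such tables are reachable from real inputs
#' (e.g. disjoint gene sets covering the whole universe). The corrected
#' statistic never exceeds the uncorrected Pearson statistic.
#'
#' @param a,b,c,d non-negative integer cell counts: `a` in both sets, `b`
#'   first set only, `c` second set only, `d` neither. Alternatively pass a
#'   2x2 matrix as `a`.
#' @return list with `statistic` and `p_value`
#' @examples
#' yates_chi_square(30, 10, 10, 50)$statistic  # 31.64
#' @export
yates_chi_square <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("zero margin: chi-square statistic set to 0", call. = FALSE)
    return(list(statistic = 0, p_value = 1))
  }
  num <- max(abs(a * d - b * c) - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Overlap test between two gene sets
#'
#' Builds the 2x2 contingency table of two gene sets over a stated universe
#' and applies [yates_chi_square()], the test used to ask whether
#' treatment-responsive genes are independent of the normally regulated
#' transcriptome. Sets may be given as character vectors (overlap computed)
#' or as counts via `overlap`, `size1`, `size2` for published tallies.
#'
#' @param set1,set2 character vectors of gene symbols, or `NULL` when counts
#'   are supplied directly
#' @param universe size of the gene universe (must be stated explicitly;
#'   it is rarely printed alongside published statistics but the test is
#'   sensitive to it)
#' @param overlap,size1,size2 optional counts overriding `set1`/`set2`
#' @return list with `table` (2x2 matrix), `statistic` and `p_value`
#' @export
overlap_analysis <- function(set1 = NULL, set2 = NULL, universe,
                             overlap = NULL, size1 = NULL, size2 = NULL) {
  if (is.null(overlap)) {
    set1 <- unique(as.character(set1))
    set2 <- unique(as.character(set2))
    overlap <- length(intersect(set1, set2))
    size1 <- length(set1)
    size2 <- length(set2)
  }
  if (overlap > min(size1, size2)) stop("overlap exceeds a set size")
  b <- size1 - overlap
  c <- size2 - overlap
  d <- universe - overlap - b - c
  if (d < 0) stop("universe smaller than the union of the sets")
  tab <- matrix(c(overlap, c, b, d), 2, 2,
                dimnames = list(set1 = c("in", "out"),
                                set2 = c("in", "out")))
  test <- yates_chi_square(overlap, b, c, d)
  list(table = tab, statistic = test$statistic, p_value = test$p_value)
}

#' Per-cluster counts of treatment-responsive genes
#'
#' Tallies, for every cluster, how many member genes were called increased
#' and decreased by a paired treatment comparison. Genes are the counting
#' unit (duplicate probes collapse to their gene's call).
#'
#' @param labels integer cluster labels per probe (`NA` = unassigned)
#' @param gene_symbols gene symbol per probe
#' @param calls gene-level direction calls: a `differential_calls` object
#'   from [call_responsive()] or a data frame with `gene_symbol` and
#'   `direction`
#' @return data frame: cluster, n_genes, n_increased, n_decreased
#' @export
per_cluster_response_counts <- function(labels, gene_symbols, calls) {
  if (inherits(calls, "differential_calls")) calls <- calls$gene_calls
  dir_of <- calls$direction[match(unique(calls$gene_symbol),
                                  calls$gene_symbol)]
  names(dir_of) <- unique(calls$gene_symbol)
  ids <- sort(unique(labels[!is.na(labels)]))
  do.call(rbind, lapply(ids, function(cl) {
    g <- unique(gene_symbols[!is.na(labels) & labels == cl])
    g <- g[!is.na(g) & g != ""]
    d <- dir_of[intersect(g, names(dir_of))]
    data.frame(cluster = cl, n_genes = length(g),
               n_increased = sum(d == "increased"),
               n_decreased = sum(d == "decreased"))
  }))
}
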