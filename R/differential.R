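#' Call treatment-responsive probes and genes
#'
#' Fold-change calling for a paired control/treated design (one time point,
#' replicated chips per condition). Replicates are averaged within condition
#' first; the probe fold change is mean(treated)/mean(control); probes at or
#' beyond `fold_threshold` (or its reciprocal) are called increased or
#' decreased, boundaries inclusive. Because platforms carry several probes
#' per gene, the gene-level call is taken from the member probe with the
#' largest absolute log fold change — a deterministic collapse that lets
#' counts be reported both per probe set and per gene. Genes whose
#' responsive probes disagree in direction are resolved by the same rule and
#' counted in `n_direction_conflicts`.
#'
#' @param control,treated [tc_matrix()] objects (or numeric matrices) with
#'   matched rows; multiple columns are treated as replicates
#' @param fold_threshold minimum fold change called responsive (>= 1)
#' @return object of class `differential_calls`: list with `probe_calls`
#'   (probe_id, gene_symbol, fold_change, direction), `gene_calls`
#'   (gene_symbol, fold_change, direction), `n_direction_conflicts` and
#'   `fold_threshold`
#' @export
call_responsive <- function(control, treated, fold_threshold = 2) {
  cvals <- if (inherits(control, "tc_matrix")) tc_values(control)
           else as.matrix(control)
  tvals <- if (inherits(treated, "tc_matrix")) tc_values(treated)
           else as.matrix(treated)
  if (nrow(cvals) != nrow(tvals)) stop("probe sets differ between conditions")
  if (!is.null(rownames(cvals)) && !is.null(rownames(tvals)) &&
      !identical(rownames(cvals), rownames(tvals)))
    stop("probe order differs between conditions")
  if (fold_threshold < 1) stop("'fold_threshold' must be >= 1")
  genes <- if (inherits(control, "tc_matrix")) tc_genes(control)
           else rep("", nrow(cvals))
  cmean <- rowMeans(cvals)
  tmean <- rowMeans(tvals)
  if (any(cmean <= 0)) stop("non-positive control mean: fold undefined")
  if (any(tmean <= 0)) stop("non-positive treated mean: fold undefined")
  fc <- tmean / cmean
  direction <- ifelse(fc >= fold_threshold, "increased",
                      ifelse(fc <= 1 / fold_threshold, "decreased",
                             "unchanged"))
  probe_calls <- data.frame(
    probe_id = if (is.null(rownames(cvals)))
      sprintf("probe_%05d", seq_along(fc)) else rownames(cvals),
    gene_symbol = genes, fold_change = fc, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL)

  known <- probe_calls[!is.na(probe_calls$gene_symbol) &
                         probe_calls$gene_symbol != "", ]
  ord <- order(-abs(log(known$fold_change)))
  top <- known[ord, ][!duplicated(known$gene_symbol[ord]), ]
  gene_calls <- data.frame(gene_symbol = top$gene_symbol,
                           fold_change = top$fold_change,
                           direction = top$direction,
                           stringsAsFactors = FALSE, row.names = NULL)
  gene_calls <- gene_calls[order(gene_calls$gene_symbol), ]
  conflicts <- sum(vapply(split(known$direction, known$gene_symbol),
                          function(d) {
                            all(c("increased", "decreased") %in% d)
                          }, logical(1)))
  structure(list(probe_calls = probe_calls, gene_calls = gene_calls,
                 n_direction_conflicts = conflicts,
                 fold_threshold = fold_threshold),
            class = "differential_calls")
}

#' Summary of a responsive gene set
#'
#' Gene- and probe-level counts of the responsive set with the percentage
#' split between increased and decreased genes.
#'
#' @param calls a `differential_calls` object from [call_responsive()]
#' @return list: n_probes (responsive probe sets), n_genes (responsive
#'   genes), n_increased, n_decreased (gene level), pct_increased,
#'   pct_decreased (percent of responsive genes; `NA` with an
#'   `empty` flag when nothing responded)
#' @export
responsive_summary <- function(calls) {
  stopifnot(inherits(calls, "differential_calls"))
  gc <- calls$gene_calls
  pc <- calls$probe_calls
  n_inc <- sum(gc$direction == "increased")
  n_dec <- sum(gc$direction == "decreased")
  n_resp <- n_inc + n_dec
  list(n_probes = sum(pc$direction != "unchanged"),
       n_genes = n_resp,
       n_increased = n_inc,
       n_decreased = n_dec,
       pct_increased = if (n_resp) 100 * n_inc / n_resp else NA_real_,
       pct_decreased = if (n_resp) 100 * n_dec / n_resp else NA_real_,
       empty = n_resp == 0)
}
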