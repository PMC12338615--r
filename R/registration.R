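#' Spatial registration of two annotation systems
#'
#' Correlates one-vs-rest enrichment t-statistics between a reference and a
#' query DE table over the union of the reference groups' top markers: the
#' instrument for annotating data-driven domains against histology, mapping
#' cell types to spatial domains, and comparing regions. The marker set is
#' the union over reference groups of each group's `top_n` genes by t,
#' computed on the common-gene intersection; `corr[r, q]` is the Pearson
#' correlation of the two t-vectors over that set.
#'
#' @param stats_ref,stats_query DE tables (gene, group, t) from
#'   [enrichment_model()].
#' @param top_n markers per reference group.
#' @return a `registration` object: `corr` (reference groups x query
#'   groups), `genes_used`, `top_n`, `direction`. Correlations undefined
#'   because of a zero-variance t-vector are `NA`, never 0.
#' @export
register <- function(stats_ref, stats_query, top_n = 100) {
  t_ref <- t_matrix(stats_ref)
  t_query <- t_matrix(stats_query)
  common <- intersect(rownames(t_ref), rownames(t_query))
  if (length(common) < top_n) {
    stop(sprintf("only %d genes are shared; top_n = %d requires at least that many",
                 length(common), top_n))
  }
  t_ref <- t_ref[common, , drop = FALSE]
  t_query <- t_query[common, , drop = FALSE]
  markers <- unique(unlist(lapply(seq_len(ncol(t_ref)), function(j) {
    common[order(-t_ref[, j])[seq_len(top_n)]]
  })))
  A <- t_ref[markers, , drop = FALSE]
  B <- t_query[markers, , drop = FALSE]
  corr <- suppressWarnings(stats::cor(A, B))
  corr[is.nan(corr)] <- NA_real_
  structure(
    list(corr = corr, genes_used = markers, top_n = top_n,
         direction = "reference -> query"),
    class = "registration"
  )
}

t_matrix <- function(stats) {
  groups <- sort(unique(stats$group))
  genes <- sort(unique(stats$gene))
  m <- matrix(NA_real_, length(genes), length(groups),
              dimnames = list(genes, groups))
  m[cbind(match(stats$gene, genes), match(stats$group, groups))] <- stats$t
  m[stats::complete.cases(m), , drop = FALSE]
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("registration (%s): %d x %d groups over %d marker genes\n",
              x$direction, nrow(x$corr), ncol(x$corr), length(x$genes_used)))
  print(round(x$corr, 2))
  invisible(x)
}

#' Mark high-confidence registration entries
#'
#' @param reg a [register()] result.
#' @param cutoff correlation cutoff; entries with `corr >= cutoff`
#'   (inclusive) are confident. `NA` correlations stay `NA`.
#' @return logical matrix shaped like `reg$corr`.
#' @export
mark_confidence <- function(reg, cutoff = 0.25) {
  reg$corr >= cutoff
}
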