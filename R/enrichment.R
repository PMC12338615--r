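#' Build up/down signature gene sets from an external DEG table
#'
#' Restricts the external results to the genes shared with the local
#' universe, then splits: up = adjusted p strictly below `alpha` with
#' positive logFC, down = adjusted p strictly below `alpha` with negative
#' logFC, background = every other overlapping gene.
#'
#' @param external_table data.frame with columns `gene`, `logFC`, `adj_p`.
#' @param local_genes the local gene universe (e.g. genes in the enrichment
#'   model results).
#' @param alpha adjusted-p threshold (strict `<`).
#' @return list: `up`, `down`, `background`, `universe`.
#' @export
build_signature_sets <- function(external_table, local_genes, alpha = 0.1) {
  tab <- external_table[external_table$gene %in% local_genes, , drop = FALSE]
  if (!nrow(tab)) stop("no overlap between the external table and the local genes")
  up <- tab$gene[tab$adj_p < alpha & tab$logFC > 0]
  down <- tab$gene[tab$adj_p < alpha & tab$logFC < 0]
  list(up = up, down = down,
       background = setdiff(tab$gene, c(up, down)),
       universe = tab$gene)
}

#' Build per-domain (or per-cell-type) gene sets from local DE statistics
#'
#' For each group: the set is genes with `fdr < alpha` and `logFC > lfc`
#' (strict on both, enrichment direction only); the background is the
#' remaining genes of that group's results.
#'
#' @param local_stats an [enrichment_model()] table.
#' @param alpha FDR threshold (strict `<`).
#' @param lfc logFC threshold (strict `>`).
#' @return named list per group: `set`, `background`, `universe`; groups
#'   with empty sets carry a `note`.
#' @export
build_domain_sets <- function(local_stats, alpha = 0.05, lfc = 1) {
  lapply(split(local_stats, local_stats$group), function(s) {
    set <- s$gene[s$fdr < alpha & s$logFC > lfc]
    out <- list(set = set, background = setdiff(s$gene, set),
                universe = s$gene)
    if (!length(set)) out$note <- "empty set; test will be skipped"
    out
  })
}

#' Two-sided Fisher's exact test of two gene sets in a universe
#'
#' Builds the 2x2 table (in/out of `set_a` by in/out of `set_b` over the
#' universe) and tests independence with the two-sided exact test (summing
#' hypergeometric probabilities at or below the observed table's). A
#' degenerate margin (an empty set or a full set) is skipped with a note.
#'
#' @param set_a,set_b character gene sets (subsets of `universe`).
#' @param universe the declared gene universe.
#' @return list: `table`, `odds_ratio` (sample OR), `p`, `skipped`, `note`.
#' @export
fisher_test <- function(set_a, set_b, universe) {
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  cc <- length(setdiff(set_b, set_a))
  dd <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, dd), 2, 2,
                dimnames = list(c("in_a", "out_a"), c("in_b", "out_b")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_,
                skipped = TRUE, note = "degenerate margin"))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or_sample <- (a * dd) / (b * cc)
  list(table = tab, odds_ratio = or_sample, conditional_or = unname(ft$estimate),
       p = ft$p.value, skipped = FALSE, note = NULL)
}

#' Run a family of Fisher tests of domain sets against signature sets
#'
#' Tests every (domain set, signature direction) combination on the shared
#' universe and applies Benjamini-Hochberg across the family.
#'
#' @param domain_sets output of [build_domain_sets()].
#' @param signature_sets output of [build_signature_sets()].
#' @return data.frame (domain, signature, overlap, set_size, sig_size,
#'   odds_ratio, p, fdr, skipped).
#' @export
run_enrichment <- function(domain_sets, signature_sets) {
  rows <- list()
  for (dn in names(domain_sets)) {
    dom <- domain_sets[[dn]]
    universe <- intersect(dom$universe, signature_sets$universe)
    for (dir in c("up", "down")) {
      sig <- intersect(signature_sets[[dir]], universe)
      set <- intersect(dom$set, universe)
      ft <- fisher_test(set, sig, universe)
      rows[[paste(dn, dir)]] <- data.frame(
        domain = dn, signature = dir,
        overlap = length(intersect(set, sig)),
        set_size = length(set), sig_size = length(sig),
        odds_ratio = ft$odds_ratio, p = ft$p,
        skipped = ft$skipped, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !out$skipped
  out$fdr[ok] <- stats::p.adjust(out$p[ok], "BH")
  rownames(out) <- NULL
  out
}

#' Map genes through an ortholog table
#'
#' Keeps one-to-one rows; one-to-many mappings are resolved by the table's
#' `priority` column when present (highest wins), otherwise all conflicting
#' rows are dropped and reported. Duplicate target symbols from different
#' sources are treated the same way.
#'
#' @param genes character vector of source genes.
#' @param mapping_table data.frame with columns `from`, `to` and optionally
#'   `priority`.
#' @return list: `mapped` (data.frame from/to), `dropped` (counts by
#'   reason).
#' @export
ortholog_map <- function(genes, mapping_table) {
  tab <- mapping_table[mapping_table$from %in% genes, , drop = FALSE]
  unmatched <- sum(!genes %in% tab$from)
  if (nrow(tab) && "priority" %in% names(tab)) {
    tab <- tab[order(tab$from, -tab$priority), , drop = FALSE]
    tab <- tab[!duplicated(tab$from), , drop = FALSE]
    tab <- tab[order(tab$to, -tab$priority), , drop = FALSE]
    tab <- tab[!duplicated(tab$to), , drop = FALSE]
    ambiguous <- 0L
  } else if (nrow(tab)) {
    dup_from <- tab$from %in% tab$from[duplicated(tab$from)]
    dup_to <- tab$to %in% tab$to[duplicated(tab$to)]
    ambiguous <- length(unique(tab$from[dup_from | dup_to]))
    tab <- tab[!(dup_from | dup_to), , drop = FALSE]
  } else {
    ambiguous <- 0L
  }
  list(mapped = data.frame(from = tab$from, to = tab$to, row.names = NULL),
       dropped = c(unmatched = unmatched, ambiguous = ambiguous))
}

#' Build per-group genome annotations from expression specificity
#'
#' From a pseudobulk: drops columns with fewer than `min_obs` member
#' observations, applies the CPM expression prefilter, removes duplicated
#' symbols and non-protein-coding genes, computes per-group mean normalized
#' CPM (or a specificity ratio, group CPM over total CPM), takes the top
#' `top_frac` of genes per group, and expands each gene's span by `window`
#' bases on both sides (clipped at zero) as 0-based half-open BED intervals.
#'
#' @param pb a [pseudobulk()] object.
#' @param gene_coords data.frame keyed by gene: `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive), optional `symbol`, `biotype`.
#' @param top_frac fraction of genes per group set.
#' @param window flank added on both sides, in bases.
#' @param min_obs minimum observations behind a retained column.
#' @param score `"mean_cpm"` (per-group mean CPM) or `"specificity"`
#'   (group share of the gene's total CPM).
#' @return list per group: data.frame (chrom, start, end, gene) in BED
#'   coordinates; genes lacking coordinates are dropped and counted in
#'   attribute `dropped_no_coords`.
#' @export
specificity_annotation <- function(pb, gene_coords, top_frac = 0.10,
                                   window = 1e5, min_obs = 50,
                                   score = c("mean_cpm", "specificity")) {
  score <- match.arg(score)
  keep <- pb$meta$n_obs >= min_obs
  if (!any(keep)) stop("no pseudobulk columns have enough observations")
  counts <- pb$counts[, keep, drop = FALSE]
  meta <- pb$meta[keep, , drop = FALSE]
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  genes <- rownames(counts)

  gc <- gene_coords[!duplicated(gene_coords$gene), , drop = FALSE]
  if ("symbol" %in% names(gc)) {
    gc <- gc[!duplicated(gc$symbol), , drop = FALSE]
  }
  if ("biotype" %in% names(gc)) {
    gc <- gc[gc$biotype == "protein_coding", , drop = FALSE]
  }
  usable <- intersect(genes, gc$gene)
  dropped <- length(genes) - length(usable)
  cpm <- cpm[usable, , drop = FALSE]
  gc <- gc[match(usable, gc$gene), , drop = FALSE]

  groups <- sort(unique(meta$group))
  group_cpm <- vapply(groups, function(g) {
    rowMeans(cpm[, meta$group == g, drop = FALSE])
  }, numeric(nrow(cpm)))
  sc <- if (score == "mean_cpm") {
    group_cpm
  } else {
    group_cpm / pmax(rowSums(group_cpm), .Machine$double.eps)
  }
  n_take <- max(1L, floor(top_frac * nrow(sc)))
  out <- lapply(groups, function(g) {
    top <- usable[order(-sc[, g])[seq_len(n_take)]]
    i <- match(top, gc$gene)
    data.frame(
      chrom = gc$chrom[i],
      start = pmax(0, gc$start[i] - 1 - window),   # BED is 0-based
      end = gc$end[i] + window,
      gene = top, row.names = NULL
    )
  })
  names(out) <- groups
  attr(out, "dropped_no_coords") <- dropped
  out
}

#' Write a BED annotation list to files
#'
#' @param beds list of BED data.frames from [specificity_annotation()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_bed <- function(beds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(beds), function(g) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", g), ".bed"))
    utils::write.table(beds[[g]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
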