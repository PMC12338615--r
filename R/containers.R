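#' Construct a count assay
#'
#' The shared container for SRT and snRNA-seq data: a sparse non-negative
#' integer matrix with genes as rows and observations (spots or nuclei) as
#' columns, plus per-gene and per-observation metadata tables. Genes-as-rows
#' is the canonical orientation throughout the package; readers transpose as
#' needed.
#'
#' @param counts matrix or sparse Matrix of non-negative counts,
#'   genes x observations.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param obs_ids character vector of unique observation identifiers
#'   (columns).
#' @param gene_meta optional data.frame keyed by `gene_id` (e.g. symbol,
#'   chromosome, start, end, biotype, `mito` flag).
#' @param obs_meta optional data.frame keyed by `obs_id` (e.g. donor, sample,
#'   group labels, numeric QC fields).
#' @return an object of class `count_assay`.
#' @export
count_assay <- function(counts, gene_ids = rownames(counts),
                        obs_ids = colnames(counts),
                        gene_meta = NULL, obs_meta = NULL) {
  if (!methods::is(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  # pattern/logical sparse matrices (e.g. an all-zero MTX read back) become
  # numeric
  counts <- methods::as(methods::as(methods::as(
    counts, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if (is.null(gene_ids) || is.null(obs_ids)) {
    stop("gene_ids and obs_ids must be supplied (or present as dimnames)")
  }
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(obs_ids)) {
    stop(sprintf(
      "counts is %d x %d but %d gene ids and %d obs ids were given",
      nrow(counts), ncol(counts), length(gene_ids), length(obs_ids)
    ))
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicated gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  dup <- unique(obs_ids[duplicated(obs_ids)])
  if (length(dup)) {
    stop("duplicated observation ids: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (length(counts@x)) {
    if (any(!is.finite(counts@x))) stop("counts contain non-finite values")
    if (any(counts@x < 0)) stop("counts contain negative values")
  }
  dimnames(counts) <- list(gene_ids, obs_ids)
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = gene_ids, row.names = gene_ids)
  } else {
    gene_meta <- as.data.frame(gene_meta)
    if (nrow(gene_meta) != length(gene_ids)) {
      stop("gene_meta rows must match gene_ids")
    }
    gene_meta$gene_id <- gene_ids
    rownames(gene_meta) <- gene_ids
  }
  if (is.null(obs_meta)) {
    obs_meta <- data.frame(obs_id = obs_ids, row.names = obs_ids)
  } else {
    obs_meta <- as.data.frame(obs_meta)
    if (nrow(obs_meta) != length(obs_ids)) {
      stop("obs_meta rows must match obs_ids")
    }
    obs_meta$obs_id <- obs_ids
    rownames(obs_meta) <- obs_ids
  }
  structure(
    list(counts = counts, gene_ids = gene_ids, obs_ids = obs_ids,
         gene_meta = gene_meta, obs_meta = obs_meta),
    class = "count_assay"
  )
}

#' @export
print.count_assay <- function(x, ...) {
  cat(sprintf("count_assay: %d genes x %d observations (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
dim.count_assay <- function(x) dim(x$counts)

#' Subset a count assay by genes and/or observations
#'
#' @param assay a `count_assay`.
#' @param genes gene ids or integer/logical index, or NULL to keep all.
#' @param obs observation ids or integer/logical index, or NULL to keep all.
#' @return subsetted `count_assay`.
#' @export
subset_assay <- function(assay, genes = NULL, obs = NULL) {
  gi <- if (is.null(genes)) seq_along(assay$gene_ids) else genes
  oi <- if (is.null(obs)) seq_along(assay$obs_ids) else obs
  if (is.character(gi)) gi <- match(gi, assay$gene_ids)
  if (is.character(oi)) oi <- match(oi, assay$obs_ids)
  if (anyNA(gi) || anyNA(oi)) stop("unknown gene or observation ids")
  count_assay(assay$counts[gi, oi, drop = FALSE],
              gene_ids = assay$gene_ids[gi], obs_ids = assay$obs_ids[oi],
              gene_meta = assay$gene_meta[gi, , drop = FALSE],
              obs_meta = assay$obs_meta[oi, , drop = FALSE])
}

#' Construct a spatial sample (one capture area)
#'
#' @param assay a `count_assay` of spots.
#' @param xy two-column numeric matrix of planar spot coordinates (array
#'   pixel units), one row per observation.
#' @param in_tissue logical per spot.
#' @param sample_id sample identifier.
#' @param donor donor identifier.
#' @param domain optional per-spot categorical domain (layer) label.
#' @return an object of class `spatial_sample`.
#' @export
spatial_sample <- function(assay, xy, in_tissue, sample_id, donor,
                           domain = NULL) {
  stopifnot(inherits(assay, "count_assay"))
  xy <- as.matrix(xy)
  if (nrow(xy) != ncol(assay$counts)) {
    stop("xy row count must equal the number of observations")
  }
  colnames(xy) <- c("x", "y")
  rownames(xy) <- assay$obs_ids
  in_tissue <- as.logical(in_tissue)
  if (length(in_tissue) == 1L) in_tissue <- rep(in_tissue, nrow(xy))
  stopifnot(length(in_tissue) == nrow(xy))
  if (!is.null(domain)) {
    domain <- as.character(domain)
    stopifnot(length(domain) == nrow(xy))
  }
  structure(
    list(assay = assay, xy = xy, in_tissue = in_tissue,
         domain = domain, sample_id = sample_id, donor = donor),
    class = "spatial_sample"
  )
}

#' @export
print.spatial_sample <- function(x, ...) {
  cat(sprintf("spatial_sample '%s' (donor %s): %d genes x %d spots, %d in tissue\n",
              x$sample_id, x$donor, nrow(x$assay$counts),
              ncol(x$assay$counts), sum(x$in_tissue)))
  invisible(x)
}

#' Subset a spatial sample by spots (and optionally genes)
#'
#' @param sample a `spatial_sample`.
#' @param obs spot index (ids, integer or logical).
#' @param genes optional gene index.
#' @return subsetted `spatial_sample`.
#' @export
subset_sample <- function(sample, obs = NULL, genes = NULL) {
  oi <- if (is.null(obs)) seq_along(sample$assay$obs_ids) else obs
  if (is.character(oi)) oi <- match(oi, sample$assay$obs_ids)
  if (is.logical(oi)) oi <- which(oi)
  spatial_sample(
    subset_assay(sample$assay, genes = genes, obs = oi),
    xy = sample$xy[oi, , drop = FALSE],
    in_tissue = sample$in_tissue[oi],
    sample_id = sample$sample_id, donor = sample$donor,
    domain = if (is.null(sample$domain)) NULL else sample$domain[oi]
  )
}

#' Log-normalize a count assay
#'
#' Computes `log2(count / column_total * scale + 1)` per observation, with
#' `scale` = 1e4 (counts per 10k, `cp10k`) or 1e6 (`cpm`). Columns whose
#' total is zero map to all-zero columns.
#'
#' @param assay a `count_assay`.
#' @param mode `"cp10k"` or `"cpm"`.
#' @return list with `values` (sparse genes x observations matrix) and
#'   `normalization` (the mode), class `lognorm_matrix`.
#' @export
log_normalize <- function(assay, mode = c("cp10k", "cpm")) {
  mode <- match.arg(mode)
  scale <- if (mode == "cpm") 1e6 else 1e4
  m <- assay$counts
  if (ncol(m) == 0L) stop("assay has no observations")
  tot <- Matrix::colSums(m)
  if (length(m@x)) {
    colidx <- rep(seq_len(ncol(m)), diff(m@p))
    m@x <- log2(m@x / tot[colidx] * scale + 1)
  }
  structure(list(values = m, normalization = mode), class = "lognorm_matrix")
}
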