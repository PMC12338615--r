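#' Read a 10x-style Matrix Market count matrix
#'
#' Reads the `matrix.mtx` / `features.tsv` / `barcodes.tsv` triplet written
#' by SpaceRanger/CellRanger (gzipped or plain). Features are returned as
#' rows (genes), barcodes as columns.
#'
#' @param matrix_path path to the `.mtx` or `.mtx.gz` file.
#' @param features_path path to the features table (tab-separated, no header:
#'   id, symbol[, type]).
#' @param barcodes_path path to the barcode table (one barcode per line).
#' @return a `count_assay`.
#' @export
read_10x_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- read_mm(matrix_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (nrow(feats) != nrow(m) || length(bcs) != ncol(m)) {
    stop(sprintf(
      "matrix is %d x %d but %d features and %d barcodes were provided",
      nrow(m), ncol(m), nrow(feats), length(bcs)
    ))
  }
  ids <- as.character(feats[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated feature id(s) in features file: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  gene_meta <- data.frame(gene_id = ids, row.names = ids)
  if (ncol(feats) >= 2) gene_meta$symbol <- as.character(feats[[2]])
  if (ncol(feats) >= 3) gene_meta$type <- as.character(feats[[3]])
  count_assay(m, gene_ids = ids, obs_ids = bcs, gene_meta = gene_meta)
}

read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    m <- Matrix::readMM(con)
  } else {
    m <- Matrix::readMM(path)
  }
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Write a count assay as 10x-style Matrix Market files
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` (uncompressed) so
#' that [read_10x_mtx()] round-trips the counts, ids and symbols exactly.
#'
#' @param assay a `count_assay`.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
write_10x_mtx <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "matrix.mtx")
  fp <- file.path(dir, "features.tsv")
  bp <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(assay$counts, mp)
  symbol <- if ("symbol" %in% names(assay$gene_meta)) {
    assay$gene_meta$symbol
  } else {
    assay$gene_ids
  }
  utils::write.table(
    data.frame(assay$gene_ids, symbol, "Gene Expression"),
    fp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  writeLines(assay$obs_ids, bp)
  invisible(c(matrix = mp, features = fp, barcodes = bp))
}

#' Read a Visium tissue-positions table and attach spot geometry
#'
#' Accepts both the headered (`tissue_positions.csv`) and headerless
#' (`tissue_positions_list.csv`) dialects: barcode, in_tissue flag, array
#' row, array col, pixel row, pixel col. Spots are aligned to the assay by
#' barcode id, never by order; position rows whose barcode is absent from
#' the assay are dropped with a warning stating the count, as are assay
#' barcodes that have no position row.
#'
#' @param positions_path path to the positions CSV.
#' @param assay a `count_assay` of spot barcodes.
#' @param sample_id,donor identifiers for the resulting sample.
#' @return a `spatial_sample` over the overlapping barcodes.
#' @export
read_spot_positions <- function(positions_path, assay, sample_id = "sample",
                                donor = "donor") {
  first <- readLines(positions_path, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(positions_path, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(pos) < 6) stop("positions table must have 6 columns")
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  keep <- pos$barcode %in% assay$obs_ids
  if (!any(keep)) stop("no position barcodes overlap the assay")
  if (any(!keep)) {
    warning(sprintf("%d position barcode(s) absent from the assay; dropped",
                    sum(!keep)))
  }
  pos <- pos[keep, , drop = FALSE]
  missing_pos <- setdiff(assay$obs_ids, pos$barcode)
  if (length(missing_pos)) {
    warning(sprintf("%d assay barcode(s) have no position; dropped",
                    length(missing_pos)))
    assay <- subset_assay(assay, obs = setdiff(assay$obs_ids, missing_pos))
  }
  pos <- pos[match(assay$obs_ids, pos$barcode), , drop = FALSE]
  spatial_sample(
    assay,
    xy = cbind(x = as.numeric(pos$pxl_col), y = as.numeric(pos$pxl_row)),
    in_tissue = pos$in_tissue == 1,
    sample_id = sample_id, donor = donor
  )
}

#' Write a data.frame as tab-separated values
#'
#' Thin wrapper used by the analysis drivers so all result tables share one
#' dialect (tab separator, no quoting, no row names).
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
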