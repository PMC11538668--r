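#' Spot-level spatial expression dataset
#'
#' A `spot_dataset` bundles a gene x spot integer count matrix with spot
#' positions on the Visium array, gene identifiers and an optional per-spot
#' nutritional-condition label. It is the common currency of the package:
#' the reader, the simulator and all downstream steps produce or consume it.
#'
#' @param counts gene x spot matrix of non-negative integer counts (dense or
#'   `Matrix` sparse; stored as `dgCMatrix`).
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_symbols character vector of gene symbols, same length as
#'   `gene_ids` (defaults to `gene_ids`).
#' @param barcodes character vector of unique spot barcodes (columns).
#' @param positions data.frame with one row per spot and columns
#'   `array_row`, `array_col` (integer), `pixel_x`, `pixel_y` (numeric),
#'   `in_tissue` (0/1).
#' @param condition character vector of per-spot condition labels
#'   (e.g. `"ctrl"`, `"fasted"`, `"refed"`), or a single label recycled, or
#'   `NA` when unknown.
#'
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, gene_ids, gene_symbols = gene_ids,
                         barcodes, positions, condition = NA_character_) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (length(condition) == 1L) condition <- rep(condition, length(barcodes))
  ds <- structure(list(
    counts = counts,
    gene_ids = as.character(gene_ids),
    gene_symbols = as.character(gene_symbols),
    barcodes = as.character(barcodes),
    positions = local({
      p <- as.data.frame(positions)
      rownames(p) <- NULL
      p
    }),
    condition = as.character(condition)
  ), class = "spot_dataset")
  validate_spot_dataset(ds)
  ds
}

#' Validate a spot_dataset
#'
#' Checks the structural invariants: matching dimensions, unique gene ids and
#' barcodes, non-negative integral counts, and complete position columns.
#'
#' @param ds a `spot_dataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_spot_dataset <- function(ds) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (nrow(ds$counts) != length(ds$gene_ids))
    stop("counts has ", nrow(ds$counts), " rows but ", length(ds$gene_ids),
         " gene ids", call. = FALSE)
  if (ncol(ds$counts) != length(ds$barcodes))
    stop("counts has ", ncol(ds$counts), " columns but ", length(ds$barcodes),
         " barcodes", call. = FALSE)
  if (length(ds$gene_symbols) != length(ds$gene_ids))
    stop("gene_symbols length differs from gene_ids", call. = FALSE)
  if (anyDuplicated(ds$gene_ids))
    stop("duplicated gene ids: ", ds$gene_ids[anyDuplicated(ds$gene_ids)],
         call. = FALSE)
  if (anyDuplicated(ds$barcodes))
    stop("duplicated barcodes: ", ds$barcodes[anyDuplicated(ds$barcodes)],
         call. = FALSE)
  x <- ds$counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers", call. = FALSE)
  need <- c("array_row", "array_col", "pixel_x", "pixel_y", "in_tissue")
  miss <- setdiff(need, names(ds$positions))
  if (length(miss))
    stop("positions is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ds$positions) != length(ds$barcodes))
    stop("positions row count differs from barcode count", call. = FALSE)
  if (length(ds$condition) != length(ds$barcodes))
    stop("condition length differs from barcode count", call. = FALSE)
  invisible(ds)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cond <- unique(x$condition)
  cat("spot_dataset: ", nrow(x$counts), " genes x ", ncol(x$counts), " spots\n",
      "conditions: ", paste(cond, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Subset a spot_dataset by spot index
#'
#' @param ds a `spot_dataset`.
#' @param spots integer or logical index over spots.
#' @return a `spot_dataset` restricted to the selected spots.
#' @export
subset_spots <- function(ds, spots) {
  spot_dataset(ds$counts[, spots, drop = FALSE], ds$gene_ids, ds$gene_symbols,
               ds$barcodes[spots], ds$positions[spots, , drop = FALSE],
               ds$condition[spots])
}
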