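#' Read a Space Ranger-style spatial expression bundle
#'
#' Reads `matrix.mtx[.gz]`, `features.tsv[.gz]`, `barcodes.tsv[.gz]` and a
#' tissue-positions CSV (`tissue_positions.csv` with header, or the older
#' `tissue_positions_list.csv` without) from `dir_path` and returns the spots
#' flagged `in_tissue == 1`. Gene order follows the features file.
#'
#' @param dir_path directory containing the bundle.
#' @param condition condition label to attach to every spot (default `NA`).
#' @return a [spot_dataset].
#' @export
read_visium <- function(dir_path, condition = NA_character_) {
  find_one <- function(base, exts) {
    for (e in exts) {
      p <- file.path(dir_path, paste0(base, e))
      if (file.exists(p)) return(p)
    }
    stop("missing file in bundle: ", base, exts[1L], " (looked in ", dir_path,
         ")", call. = FALSE)
  }
  mtx_path <- find_one("matrix.mtx", c("", ".gz"))
  feat_path <- find_one("features.tsv", c("", ".gz"))
  bc_path <- find_one("barcodes.tsv", c("", ".gz"))
  pos_path <- NULL
  for (nm in c("tissue_positions.csv", "tissue_positions_list.csv")) {
    p <- file.path(dir_path, nm)
    if (file.exists(p)) { pos_path <- p; break }
  }
  if (is.null(pos_path))
    stop("missing file in bundle: tissue_positions.csv (looked in ", dir_path,
         ")", call. = FALSE)

  counts <- Matrix::readMM(mtx_path)
  read_tsv_lines <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) return(data.frame(V1 = character()))
    as.data.frame(do.call(rbind, strsplit(lines, "\t", fixed = TRUE)))
  }
  features <- read_tsv_lines(feat_path)
  barcodes <- read_tsv_lines(bc_path)[[1L]]
  if (nrow(counts) != nrow(features))
    stop("matrix has ", nrow(counts), " rows but features.tsv lists ",
         nrow(features), " genes", call. = FALSE)
  if (ncol(counts) != length(barcodes))
    stop("matrix has ", ncol(counts), " columns but barcodes.tsv lists ",
         length(barcodes), " barcodes", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicated barcode in barcodes.tsv: ",
         barcodes[anyDuplicated(barcodes)], call. = FALSE)

  first <- readLines(pos_path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  pos <- utils::read.csv(pos_path, header = has_header,
                         colClasses = c("character", "integer", "integer",
                                        "integer", "numeric", "numeric"))
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row_in_fullres", "pxl_col_in_fullres")
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx))
    stop("positions file lacks barcode(s): ",
         paste(utils::head(barcodes[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  pos <- pos[idx, , drop = FALSE]

  positions <- data.frame(array_row = pos$array_row,
                          array_col = pos$array_col,
                          pixel_x = pos$pxl_col_in_fullres,
                          pixel_y = pos$pxl_row_in_fullres,
                          in_tissue = pos$in_tissue)
  ds <- spot_dataset(counts, features[[1L]],
                     if (ncol(features) >= 2L) features[[2L]] else features[[1L]],
                     barcodes, positions, condition)
  subset_spots(ds, ds$positions$in_tissue == 1L)
}

#' Write a spot_dataset as a Space Ranger-style bundle
#'
#' Writes plain (uncompressed) `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#' and `tissue_positions.csv`. Pixel coordinates are serialized with 17
#' significant digits so that `read_visium(write_visium(ds))` reproduces all
#' fields bit-exactly.
#'
#' @param ds a [spot_dataset].
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_visium <- function(ds, dir_path) {
  validate_spot_dataset(ds)
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE,
                                           showWarnings = FALSE)
  if (!ok || !dir.exists(dir_path))
    stop("cannot create output directory: ", dir_path, call. = FALSE)
  Matrix::writeMM(ds$counts, file.path(dir_path, "matrix.mtx"))
  feat <- data.frame(id = ds$gene_ids, symbol = ds$gene_symbols,
                     type = rep("Gene Expression", length(ds$gene_ids)))
  utils::write.table(feat, file.path(dir_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(ds$barcodes, file.path(dir_path, "barcodes.tsv"))
  pos <- ds$positions
  lines <- c("barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
             sprintf("%s,%d,%d,%d,%.17g,%.17g", ds$barcodes, pos$in_tissue,
                     pos$array_row, pos$array_col, pos$pixel_y, pos$pixel_x))
  writeLines(lines, file.path(dir_path, "tissue_positions.csv"))
  invisible(dir_path)
}

#' Merge per-condition samples into one dataset
#'
#' Column-concatenates samples that share an identical gene list and ordering.
#' Barcodes are suffixed with the sample's condition label so they stay unique
#' in the merged dataset. No expression integration is performed: samples are
#' merged as-is and downstream steps operate per condition or on jointly
#' normalized values.
#'
#' @param samples list of [spot_dataset] objects.
#' @param conditions character vector of condition labels, one per sample.
#' @return a merged [spot_dataset].
#' @export
merge_conditions <- function(samples, conditions) {
  stopifnot(length(samples) >= 1L, length(samples) == length(conditions))
  ref <- samples[[1L]]$gene_ids
  for (i in seq_along(samples)) {
    g <- samples[[i]]$gene_ids
    if (length(g) != length(ref) || any(g != ref)) {
      j <- if (length(g) != length(ref)) 1L else which(g != ref)[1L]
      stop("gene lists differ between samples (first mismatch at position ",
           j, ": '", ref[min(j, length(ref))], "' vs '", g[min(j, length(g))],
           "')", call. = FALSE)
    }
  }
  counts <- do.call(cbind, lapply(samples, function(s) s$counts))
  barcodes <- unlist(mapply(function(s, cond) paste0(s$barcodes, "_", cond),
                            samples, conditions, SIMPLIFY = FALSE))
  positions <- do.call(rbind, lapply(samples, function(s) s$positions))
  rownames(positions) <- NULL
  condition <- unlist(mapply(function(s, cond) rep(cond, length(s$barcodes)),
                             samples, conditions, SIMPLIFY = FALSE))
  spot_dataset(counts, ref, samples[[1L]]$gene_symbols, barcodes, positions,
               condition)
}
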