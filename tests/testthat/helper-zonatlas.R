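# shared fixtures; everything is generated in code at test time

# hand-written 5 gene x 4 spot Space Ranger-style bundle; returns the dir and
# the dense matrix implied by the MTX triplets
toy_bundle <- function(dir = tempfile("bundle"), in_tissue = rep(1L, 4L),
                       barcodes = paste0("BC", 1:4)) {
  dir.create(dir)
  triplets <- data.frame(i = c(1L, 2L, 2L, 3L, 4L, 5L, 5L),
                         j = c(1L, 1L, 2L, 3L, 4L, 2L, 4L),
                         x = c(3L, 1L, 7L, 2L, 5L, 4L, 6L))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "5 4 7",
               sprintf("%d %d %d", triplets$i, triplets$j, triplets$x)),
             file.path(dir, "matrix.mtx"))
  writeLines(sprintf("ENSG%02d\tGene%d\tGene Expression", 1:5, 1:5),
             file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(c("barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
               sprintf("%s,%d,%d,%d,%.1f,%.1f", barcodes, in_tissue,
                       0:3, c(0L, 2L, 4L, 6L), (1:4) * 10.5, (1:4) * 20.5)),
             file.path(dir, "tissue_positions.csv"))
  dense <- matrix(0L, 5L, 4L)
  dense[cbind(triplets$i, triplets$j)] <- triplets$x
  list(dir = dir, dense = dense, barcodes = barcodes)
}

# minimal in-memory dataset builder
toy_dataset <- function(counts, gene_ids = sprintf("g%d", seq_len(nrow(counts))),
                        condition = "ctrl") {
  n <- ncol(counts)
  zonatlas::spot_dataset(
    counts, gene_ids, gene_ids, sprintf("S%03d", seq_len(n)),
    data.frame(array_row = seq_len(n), array_col = seq_len(n) * 2L,
               pixel_x = as.numeric(seq_len(n)),
               pixel_y = as.numeric(seq_len(n)), in_tissue = 1L),
    condition)
}

# the default simulated study and full pipeline run, computed once per
# session and shared across tests (the acceptance checks all measure it)
.zonatlas_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.zonatlas_cache$study)) {
    seed <- (1L + sum(utf8ToInt("simulate")) * 10007L) %% 2147483647L
    .zonatlas_cache$study <- zonatlas::simulate_study(seed = seed)
  }
  .zonatlas_cache$study
}

cached_run <- function() {
  if (is.null(.zonatlas_cache$run)) {
    out <- file.path(tempdir(), "zonatlas-default-run")
    .zonatlas_cache$run <- zonatlas::run_pipeline(
      list(output_dir = out, seed = 1L))
  }
  .zonatlas_cache$run
}

# independent brute-force ssGSEA oracle: direct O(n * m) double loop over
# ranked positions, written without reference to the package implementation
brute_ssgsea <- function(norm, gene_set, alpha = 0.25) {
  vapply(seq_len(ncol(norm)), function(j) {
    x <- norm[, j]
    n <- length(x)
    rk <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    in_set <- rownames(norm)[ord] %in% gene_set
    m <- sum(in_set)
    w_tot <- sum(rk[ord][in_set]^alpha)
    score <- 0; p_in <- 0; p_out <- 0
    for (pos in seq_len(n)) {
      if (in_set[pos]) p_in <- p_in + rk[ord][pos]^alpha / w_tot
      else p_out <- p_out + 1 / (n - m)
      score <- score + (p_in - p_out)
    }
    score
  }, numeric(1L))
}

label_accuracy <- function(run) {
  truth <- run$truth$genes
  m <- merge(run$labels[, c("gene", "condition", "label")],
             truth[, c("gene_id", "condition", "true_label")],
             by.x = c("gene", "condition"), by.y = c("gene_id", "condition"))
  tapply(m$label == m$true_label, m$true_label, mean)
}
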