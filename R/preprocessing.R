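#' Per-spot QC metrics
#'
#' Computes detected genes, total UMIs, and the mitochondrial and hemoglobin
#' UMI fractions per spot. Fractions for zero-total spots are defined as 0
#' and such spots are flagged for removal.
#'
#' @param ds a [spot_dataset].
#' @param mito_prefix gene-id prefix identifying mitochondrial transcripts
#'   (default `"mt-"`, mouse nomenclature).
#' @param hemoglobin_genes character vector of hemoglobin gene ids (default:
#'   mouse adult alpha/beta globins).
#' @return data.frame with columns `barcode`, `n_genes_detected`,
#'   `total_umi`, `mito_fraction`, `hemoglobin_fraction`, `flag_removal`.
#' @export
compute_qc <- function(ds, mito_prefix = "mt-",
                       hemoglobin_genes = c("Hba-a1", "Hba-a2", "Hbb-bs",
                                            "Hbb-bt")) {
  validate_spot_dataset(ds)
  is_mito <- startsWith(ds$gene_ids, mito_prefix)
  is_hb <- ds$gene_ids %in% hemoglobin_genes
  if (!any(is_mito))
    warning("no gene id matches mito prefix '", mito_prefix, "'", call. = FALSE)
  if (!any(is_hb))
    warning("no gene id matches the hemoglobin gene list", call. = FALSE)
  total <- Matrix::colSums(ds$counts)
  n_det <- Matrix::colSums(ds$counts > 0)
  mito <- Matrix::colSums(ds$counts[is_mito, , drop = FALSE])
  hb <- Matrix::colSums(ds$counts[is_hb, , drop = FALSE])
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  data.frame(barcode = ds$barcodes,
             n_genes_detected = as.integer(n_det),
             total_umi = as.integer(round(total)),
             mito_fraction = safe_div(mito, total),
             hemoglobin_fraction = safe_div(hb, total),
             flag_removal = total == 0)
}

#' Log library-size normalization
#'
#' `x -> log(1 + count * scale / spot_total)`; spots with zero total map to
#' all zeros. This is the package's specified stand-in for variance
#' stabilization: fully determined, monotone within a spot, and sufficient
#' for recovery of simulated zonation structure.
#'
#' @param ds a [spot_dataset].
#' @param scale size factor target (default 1e4).
#' @return dense numeric gene x spot matrix with dimnames.
#' @export
normalize_log <- function(ds, scale = 1e4) {
  total <- Matrix::colSums(ds$counts)
  sf <- ifelse(total > 0, scale / total, 0)
  m <- as.matrix(ds$counts %*% Matrix::Diagonal(x = sf))
  m <- log1p(m)
  dimnames(m) <- list(ds$gene_ids, ds$barcodes)
  m
}

top_variable_genes <- function(norm, n_hvg) {
  v <- apply(norm, 1L, stats::var)
  ord <- order(v, decreasing = TRUE)
  ord[seq_len(min(n_hvg, sum(v > 0)))]
}

#' PCA, k-NN graph and Leiden clustering
#'
#' Standardizes the top variable genes of the normalized matrix, runs PCA,
#' builds a k-nearest-neighbor graph in PC space (Euclidean) and partitions
#' it by Leiden modularity optimization at the given resolution.
#'
#' @param norm normalized gene x spot matrix (from [normalize_log()]).
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbors for the graph (default 15).
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed (community detection is seeded).
#' @param n_hvg number of highly variable genes used for PCA (default 2000).
#' @return list of class `embedding_result`: `pc_scores` (spot x n_pcs),
#'   `neighbor_graph` (sparse symmetric adjacency, no self-loops),
#'   `cluster_labels` (0-based contiguous integers), `major_flag`
#'   (per-cluster logical, all `TRUE` until [flag_erythroid_clusters()]),
#'   `k_neighbors`, `barcodes`.
#' @export
reduce_and_cluster <- function(norm, n_pcs = 30L, k_neighbors = 15L,
                               resolution = 0.8, seed = 1L, n_hvg = 2000L) {
  n_spots <- ncol(norm)
  if (k_neighbors < 2L) stop("k_neighbors must be >= 2", call. = FALSE)
  if (n_spots < k_neighbors + 1L)
    stop("need more spots than k_neighbors + 1 (have ", n_spots, ")",
         call. = FALSE)
  hvg <- top_variable_genes(norm, n_hvg)
  x <- t(norm[hvg, , drop = FALSE])             # spots x genes
  x <- scale(x)
  x[!is.finite(x)] <- 0
  n_pcs <- min(n_pcs, ncol(x) - 1L, nrow(x) - 1L)
  sv <- svd(x, nu = n_pcs, nv = 0L)
  pc <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(pc) <- colnames(norm)

  adj <- snn_adjacency(pc, k_neighbors)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L,
                               weights = igraph::E(g)$weight)
  labels <- as.integer(igraph::membership(cl))
  # relabel by decreasing cluster size, 0-based
  ord <- order(tabulate(labels), decreasing = TRUE)
  labels <- match(labels, ord) - 1L
  structure(list(pc_scores = pc, neighbor_graph = adj,
                 cluster_labels = labels,
                 major_flag = rep(TRUE, max(labels) + 1L),
                 k_neighbors = k_neighbors,
                 barcodes = colnames(norm)),
            class = "embedding_result")
}

# symmetric kNN adjacency (union of directed kNN), no self-loops
knn_adjacency <- function(pc, k) {
  n <- nrow(pc)
  d <- as.matrix(stats::dist(pc))
  idx <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(idx))
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  adj <- ((adj + Matrix::t(adj)) > 0) * 1
  Matrix::drop0(adj)
}

# shared-nearest-neighbor graph: edges weighted by the Jaccard overlap of
# the two spots' k-neighborhoods (pruned below 1/15), as in the standard
# Seurat-style neighborhood graph; sharper community boundaries than the
# raw kNN union
snn_adjacency <- function(pc, k, prune = 1 / 15) {
  n <- nrow(pc)
  d <- as.matrix(stats::dist(pc))
  idx <- t(apply(d, 1L, function(row) order(row)[seq_len(k + 1L)]))
  nb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                             j = as.vector(t(idx)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(nb)              # |N_i intersect N_j|
  jac <- shared / (2 * (k + 1L) - shared)
  jac[jac < prune] <- 0
  Matrix::diag(jac) <- 0
  Matrix::drop0(jac)
}

#' Flag erythroid-contaminated clusters
#'
#' Clusters whose median per-spot hemoglobin fraction exceeds `hb_threshold`
#' are marked minor (`major_flag = FALSE`); axis inference operates on major
#' clusters only. This mirrors the observation that globin-rich inner spot
#' clusters reflect red-blood-cell contamination rather than hepatocytes.
#'
#' @param emb an `embedding_result`.
#' @param qc QC table from [compute_qc()] on the same spots, same order.
#' @param hb_threshold hemoglobin-fraction cutoff (default 0.1).
#' @return `emb` with `major_flag` updated.
#' @export
flag_erythroid_clusters <- function(emb, qc, hb_threshold = 0.1) {
  stopifnot(length(emb$cluster_labels) == nrow(qc))
  med <- tapply(qc$hemoglobin_fraction, emb$cluster_labels, stats::median)
  emb$major_flag <- as.vector(med[as.character(seq_along(emb$major_flag) - 1L)] <=
                                hb_threshold)
  emb$major_flag[is.na(emb$major_flag)] <- TRUE
  emb
}

#' Per-spot major-cluster membership
#'
#' @param emb an `embedding_result`.
#' @return logical vector: spot belongs to a major (hepatocyte) cluster.
#' @export
major_spots <- function(emb) {
  emb$major_flag[emb$cluster_labels + 1L]
}
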