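#' Diffusion map of the major-cluster spots
#'
#' Builds a Gaussian kernel on Euclidean distances in PC space (per-spot
#' adaptive bandwidth = distance to the k-th neighbor when
#' `kernel_width = "auto"`), row-normalizes it into a transition matrix, and
#' returns the top non-trivial right eigenvectors scaled by their
#' eigenvalues. Minor (erythroid) clusters are excluded.
#'
#' @param emb an `embedding_result` from [reduce_and_cluster()].
#' @param n_dc number of diffusion components (default 1: the portal-central
#'   axis is a single gradient, and the first non-trivial component is the
#'   standard one-dimensional zonation coordinate; higher components mostly
#'   encode between-sample variation and curvature that distort root
#'   distances).
#' @param kernel_width `"auto"` for the adaptive bandwidth, or a fixed
#'   numeric width.
#' @return list of class `diffusion_map`: `components` (spot x n_dc, rownames
#'   = barcodes), `eigenvalues`, `spots` (indices into `emb` of the spots
#'   used).
#' @export
diffusion_map <- function(emb, n_dc = 1L, kernel_width = "auto") {
  keep <- which(major_spots(emb))
  pc <- emb$pc_scores[keep, , drop = FALSE]
  n <- nrow(pc)
  if (n < n_dc + 2L)
    stop("need at least n_dc + 2 spots (have ", n, ")", call. = FALSE)

  # connectivity is checked on unique coordinates: duplicated spots are
  # zero-distance copies of their twin and cannot disconnect the kernel
  pu <- unique(pc)
  if (nrow(pu) > emb$k_neighbors + 1L) {
    g <- igraph::graph_from_adjacency_matrix(
      knn_adjacency(pu, emb$k_neighbors), mode = "undirected")
    if (igraph::components(g)$no > 1L)
      stop("neighbor graph is disconnected on major spots; ",
           "increase k_neighbors", call. = FALSE)
  }

  d <- as.matrix(stats::dist(pc))
  if (identical(kernel_width, "auto")) {
    k <- emb$k_neighbors
    # k-th smallest non-negligible distance: duplicated spots (zero
    # distances up to numerical noise) must not collapse the bandwidth
    tol <- 1e-8 * max(d)
    sig <- apply(d, 1L, function(row) {
      pos <- sort(row[row > tol])
      if (!length(pos)) 1 else pos[min(k, length(pos))]
    })
    denom <- outer(sig, sig)                    # local scaling kernel
  } else {
    denom <- kernel_width^2
  }
  W <- exp(-d^2 / denom)
  comp <- transition_eigen(W, n_dc)
  rownames(comp$components) <- emb$barcodes[keep]
  structure(list(components = comp$components, eigenvalues = comp$values,
                 spots = keep), class = "diffusion_map")
}

# Eigendecompose the row-normalized transition matrix P = D^-1 W through its
# symmetric conjugate; returns right eigenvectors of P (columns, unit norm on
# the D^1/2 scale) scaled by eigenvalues, trivial first eigenvector dropped.
transition_eigen <- function(W, n_dc) {
  rs <- rowSums(W)
  s <- 1 / sqrt(rs)
  S <- W * outer(s, s)
  eg <- eigen(S, symmetric = TRUE)
  ord <- order(eg$values, decreasing = TRUE)
  vals <- eg$values[ord][2:(n_dc + 1L)]
  vecs <- eg$vectors[, ord, drop = FALSE][, 2:(n_dc + 1L), drop = FALSE]
  phi <- vecs * s                               # right eigenvectors of P
  phi <- sweep(phi, 2L, sqrt(colSums(phi^2)), "/")
  list(components = sweep(phi, 2L, vals, "*"), values = vals)
}

#' Diffusion pseudotime from a root cluster
#'
#' The root spot is the medoid of the root cluster in diffusion-component
#' space; pseudotime is each spot's Euclidean distance to the root in that
#' space, min-max rescaled to `[0, 1]`.
#'
#' @param dm a `diffusion_map`.
#' @param emb the `embedding_result` the map was computed from.
#' @param root_cluster cluster id (0-based) used as the root.
#' @return list of class `pseudotime_axis`: `t` (named by barcode),
#'   `root_spot`, `orientation_applied`, `diffusion_components`, `spots`.
#' @export
pseudotime <- function(dm, emb, root_cluster) {
  labels <- emb$cluster_labels[dm$spots]
  in_root <- which(labels == root_cluster)
  if (!length(in_root))
    stop("root cluster ", root_cluster, " is empty on major spots",
         call. = FALSE)
  dc <- dm$components
  sub <- dc[in_root, , drop = FALSE]
  ctr <- colMeans(sub)
  medoid <- in_root[which.min(colSums((t(sub) - ctr)^2))]
  t_raw <- sqrt(colSums((t(dc) - dc[medoid, ])^2))
  rng <- range(t_raw)
  t <- if (rng[2] > rng[1]) (t_raw - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(t_raw))
  names(t) <- rownames(dc)
  structure(list(t = t, root_spot = rownames(dc)[medoid],
                 orientation_applied = FALSE, diffusion_components = dc,
                 spots = dm$spots), class = "pseudotime_axis")
}

#' Pick the default root cluster by portal-marker expression
#'
#' @param emb an `embedding_result`.
#' @param norm normalized matrix (genes x spots, all spots of `emb`).
#' @param portal_markers portal landmark gene ids.
#' @return cluster id (0-based) with the highest mean marker expression among
#'   major clusters.
#' @export
pick_root_cluster <- function(emb, norm,
                              portal_markers = c("Alb", "Cyp2f2")) {
  mk <- intersect(portal_markers, rownames(norm))
  if (!length(mk)) stop("no portal marker found in the gene list", call. = FALSE)
  expr <- colMeans(norm[mk, , drop = FALSE])
  means <- tapply(expr, emb$cluster_labels, mean)
  ids <- as.integer(names(means))
  major <- emb$major_flag[ids + 1L]
  ids[major][which.max(means[major])]
}

#' Orient the axis so that t = 0 is periportal
#'
#' If mean portal-marker expression correlates positively with `t`, the axis
#' is flipped (`t <- 1 - t`). Orientation is idempotent.
#'
#' @param axis a `pseudotime_axis`.
#' @param norm normalized matrix (genes x spots; must cover the axis spots).
#' @param portal_markers,central_markers landmark gene ids for the two poles;
#'   at least one portal marker must be present (central markers are used
#'   only as a fallback when no portal marker is found).
#' @return the axis with `t` possibly flipped and `orientation_applied = TRUE`.
#' @export
orient_axis <- function(axis, norm,
                        portal_markers = c("Alb", "Cyp2f2"),
                        central_markers = c("Glul", "Lgr5")) {
  pm <- intersect(portal_markers, rownames(norm))
  cm <- intersect(central_markers, rownames(norm))
  if (!length(pm) && !length(cm))
    stop("no portal or central marker found; orientation cannot be established",
         call. = FALSE)
  bc <- names(axis$t)
  flip <- if (length(pm)) {
    expr <- colMeans(norm[pm, bc, drop = FALSE])
    stats::cor(expr, axis$t) > 0
  } else {
    expr <- colMeans(norm[cm, bc, drop = FALSE])
    stats::cor(expr, axis$t) < 0
  }
  if (isTRUE(flip)) axis$t <- 1 - axis$t
  axis$orientation_applied <- TRUE
  axis
}

#' Binned expression profiles along the axis
#'
#' Cuts `[0, 1]` into `n_bins` equal-width bins on `t` and computes, per gene
#' and bin, the mean and standard error (sd/sqrt(n)) of normalized expression
#' over the spots of the requested condition. Empty bins are recorded as
#' missing, not zero.
#'
#' @param norm normalized gene x spot matrix.
#' @param axis an oriented `pseudotime_axis`.
#' @param n_bins number of bins (default 20).
#' @param condition condition label, or `NULL` for all axis spots.
#' @param spot_conditions per-spot condition labels named by barcode
#'   (required when `condition` is given).
#' @param genes optional subset of gene ids.
#' @return data.frame: `gene`, `condition`, `bin`, `bin_lo`, `bin_hi`,
#'   `mean`, `se`, `n`.
#' @export
bin_profiles <- function(norm, axis, n_bins = 20L, condition = NULL,
                         spot_conditions = NULL, genes = rownames(norm)) {
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  bc <- names(axis$t)
  t <- axis$t
  if (!is.null(condition)) {
    if (is.null(spot_conditions))
      stop("spot_conditions required when filtering by condition", call. = FALSE)
    keep <- bc[spot_conditions[bc] == condition]
    t <- t[keep]
    bc <- keep
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1L), n_bins)
  m <- norm[genes, bc, drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    cols <- which(bin == b)
    n <- length(cols)
    if (n == 0L) {
      data.frame(gene = genes, bin = b, mean = NA_real_, se = NA_real_, n = 0L)
    } else {
      sub <- m[, cols, drop = FALSE]
      mu <- rowMeans(sub)
      se <- if (n > 1L) sqrt(apply(sub, 1L, stats::var) / n) else
        rep(NA_real_, length(genes))
      data.frame(gene = genes, bin = b, mean = mu, se = se, n = n)
    }
  }))
  out$bin_lo <- edges[out$bin]
  out$bin_hi <- edges[out$bin + 1L]
  out$condition <- if (is.null(condition)) NA_character_ else condition
  rownames(out) <- NULL
  out[, c("gene", "condition", "bin", "bin_lo", "bin_hi", "mean", "se", "n")]
}
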