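#' Wilcoxon rank-sum differential expression
#'
#' Two-sided Mann-Whitney test per gene between two disjoint spot groups:
#' exact enumeration when both groups have at most 10 spots and the values
#' are tie-free, otherwise the tie-corrected normal approximation (with
#' continuity correction). Average log2 fold change is computed on de-logged
#' normalized values with a pseudocount of 1:
#' `log2((mean_a + 1) / (mean_b + 1))`. FDR is Benjamini-Hochberg across the
#' tested genes.
#'
#' @param norm normalized gene x spot matrix (log1p scale).
#' @param group_a,group_b disjoint spot selections (barcodes or indices),
#'   each of size >= 3.
#' @param lfc_threshold,fdr_threshold thresholds defining `passes`
#'   (defaults 0.25 and 0.05).
#' @return data.frame: `gene`, `avg_log2fc`, `p_value`, `fdr`, `direction`,
#'   `passes`.
#' @export
wilcoxon_de <- function(norm, group_a, group_b, lfc_threshold = 0.25,
                        fdr_threshold = 0.05) {
  idx <- function(sel) if (is.character(sel)) match(sel, colnames(norm)) else sel
  ia <- idx(group_a); ib <- idx(group_b)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown spot in group selection", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("groups overlap", call. = FALSE)
  if (length(ia) < 3L || length(ib) < 3L)
    stop("both groups need at least 3 spots", call. = FALSE)
  a <- norm[, ia, drop = FALSE]
  b <- norm[, ib, drop = FALSE]
  small <- length(ia) <= 10L && length(ib) <= 10L
  p <- vapply(seq_len(nrow(norm)), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (all(x == x[1L]) && all(y == y[1L]) && x[1L] == y[1L]) return(1)
    exact <- small && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                        correct = TRUE)$p.value)
  }, numeric(1L))
  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  fdr <- bh_fdr(p)
  data.frame(gene = rownames(norm),
             avg_log2fc = lfc,
             p_value = p,
             fdr = fdr,
             direction = ifelse(lfc >= 0, "up", "down"),
             passes = abs(lfc) > lfc_threshold & fdr < fdr_threshold,
             row.names = NULL)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up adjustment with monotonicity enforcement; input order preserved.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  sets
}

#' Default pathway gene-set registry
#'
#' The five MSigDB set names used for axis-resolved pathway scoring (RAS,
#' mTORC1, PGC1a, WNT, PPARa signaling) ship with EMPTY member lists:
#' memberships are MSigDB-licensed content and must be supplied by the user
#' as a GMT file ([read_gmt()]).
#'
#' @return named list of (empty) character vectors.
#' @export
default_gene_sets <- function() {
  nm <- c("HALLMARK_KRAS_SIGNALING_UP", "HALLMARK_MTORC1_SIGNALING",
          "BIOCARTA_PGC1A_PATHWAY",
          "MEBARKI_HCC_PROGENITOR_WNT_UP_CTNNB1_DEPENDENT",
          "KEGG_PPAR_SIGNALING_PATHWAY")
  stats::setNames(rep(list(character()), length(nm)), nm)
}

#' Per-spot ssGSEA enrichment scores
#'
#' For each spot, genes are ranked by expression (descending; ties get the
#' average rank). Walking down that ranking, the running sum accumulates the
#' difference between the weighted in-set ECDF (weights = rank value to the
#' power `alpha`, normalized over the set) and the unweighted out-of-set
#' ECDF; the score is the sum of the running-sum values over all positions
#' (integrated deviation). Sets sharing fewer than `min_overlap` genes with
#' the matrix get `NA` scores.
#'
#' @param norm normalized gene x spot matrix.
#' @param gene_sets named list of gene-id vectors (see [read_gmt()]).
#' @param alpha rank-weighting exponent (default 0.25).
#' @param min_overlap minimum set/matrix overlap (default 5).
#' @param normalize_across_spots if `TRUE`, min-max normalize each set's
#'   scores across spots (default `FALSE`).
#' @return numeric matrix, gene sets x spots.
#' @export
ssgsea_scores <- function(norm, gene_sets, alpha = 0.25, min_overlap = 5L,
                          normalize_across_spots = FALSE) {
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  genes <- rownames(norm)
  n <- length(genes)
  scores <- matrix(NA_real_, length(gene_sets), ncol(norm),
                   dimnames = list(names(gene_sets), colnames(norm)))
  memb <- lapply(gene_sets, function(s) genes %in% s)
  for (si in seq_along(gene_sets)) {
    in_set <- memb[[si]]
    m <- sum(in_set)
    if (m < min_overlap) {
      message("gene set '", names(gene_sets)[si], "' overlaps only ", m,
              " gene(s); score skipped")
      next
    }
    for (j in seq_len(ncol(norm))) {
      x <- norm[, j]
      rk <- rank(x, ties.method = "average")    # highest expression = rank n
      ord <- order(x, decreasing = TRUE)
      inset_ord <- in_set[ord]
      w <- ifelse(inset_ord, rk[ord]^alpha, 0)
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset_ord) / (n - m)
      scores[si, j] <- sum(p_in - p_out)
    }
  }
  if (normalize_across_spots) {
    for (si in seq_len(nrow(scores))) {
      v <- scores[si, ]
      rng <- range(v, na.rm = TRUE)
      if (is.finite(rng[1]) && rng[2] > rng[1])
        scores[si, ] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  scores
}

#' Pathway scores binned along the axis
#'
#' Same binning contract as [bin_profiles()], applied to a ssGSEA score
#' matrix: per set and bin, mean and standard error over the spots of the
#' requested condition.
#'
#' @param scores set x spot matrix from [ssgsea_scores()].
#' @param axis an oriented `pseudotime_axis`.
#' @param n_bins number of bins (default 20).
#' @param condition,spot_conditions as in [bin_profiles()].
#' @return data.frame: `gene` (set name), `condition`, `bin`, `bin_lo`,
#'   `bin_hi`, `mean`, `se`, `n`.
#' @export
pathway_axis_profile <- function(scores, axis, n_bins = 20L,
                                 condition = NULL, spot_conditions = NULL) {
  if (!isTRUE(axis$orientation_applied))
    stop("axis must be oriented", call. = FALSE)
  bin_profiles(scores, axis, n_bins = n_bins, condition = condition,
               spot_conditions = spot_conditions, genes = rownames(scores))
}
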