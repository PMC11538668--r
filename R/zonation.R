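ZONATION_LEVELS <- c("periportal", "pericentral", "midzonal", "bipolar",
                     "non_zonated")

#' Filter genes by detection along pseudotime
#'
#' Keeps gene `g` iff the number of spots where its count strictly exceeds
#' `min_count` is at least `min_spots` ("over 10 counts in at least 200
#' spots").
#'
#' @param ds a [spot_dataset] (or a counts matrix).
#' @param min_count strict count threshold (default 10).
#' @param min_spots minimum number of qualifying spots (default 200).
#' @param spots optional spot subset (index or barcode) to count within.
#' @return character vector of surviving gene ids.
#' @export
filter_genes <- function(ds, min_count = 10L, min_spots = 200L, spots = NULL) {
  if (min_count < 0L || min_spots < 0L)
    stop("thresholds must be non-negative", call. = FALSE)
  counts <- if (inherits(ds, "spot_dataset")) ds$counts else ds
  ids <- if (inherits(ds, "spot_dataset")) ds$gene_ids else rownames(counts)
  if (inherits(ds, "spot_dataset")) colnames(counts) <- ds$barcodes
  if (!is.null(spots)) counts <- counts[, spots, drop = FALSE]
  n_qual <- Matrix::rowSums(counts > min_count)
  ids[n_qual >= min_spots]
}

model_curve <- function(family, params, t) {
  p <- params
  switch(family,
         poly2 = p$a + p$b * t + p$c * t^2,
         gauss = p$h * exp(-(t - p$mu)^2 / (2 * p$sigma^2)),
         inv_gauss = p$C - p$h * exp(-(t - p$mu)^2 / (2 * p$sigma^2)))
}

new_fit <- function(family, params, rss, n, t_range, converged,
                    grid_n = 512L) {
  grid <- seq(t_range[1], t_range[2], length.out = grid_n)
  y <- if (converged) model_curve(family, params, grid) else rep(NA_real_, grid_n)
  structure(list(family = family, params = params, rss = rss, n_points = n,
                 fitted_min = if (converged) min(y) else NA_real_,
                 fitted_max = if (converged) max(y) else NA_real_,
                 grid = grid, grid_values = y,
                 converged = converged),
            class = "zonation_fit")
}

#' Fit the three zonation model families to one expression profile
#'
#' Least-squares fits of a quadratic polynomial, a Gaussian peak and an
#' inverted Gaussian (constant minus Gaussian) to expression along
#' pseudotime. Starting values follow the published scheme: all polynomial
#' coefficients at unity (the polynomial optimum is computed exactly, being
#' linear in its parameters), Gaussian peak height 1, mean at the average
#' pseudotime and sd 1, and the inverted Gaussian's constant at the maximum
#' observed expression (its remaining starts: height = max - min, mean =
#' average pseudotime, sd 1). The Gaussian families use Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) with mild bounds (`h, C >= 0`,
#' `mu` in `[-0.5, 1.5]`, `sigma` in `[0.02, 10]`) to exclude degenerate
#' optima. Failures are recorded as `converged = FALSE`, never raised.
#' Fitted extrema are evaluated on a 512-point grid over the observed
#' pseudotime range.
#'
#' @param expr numeric expression values (e.g. bin means).
#' @param t pseudotime of each value, same length, not all identical.
#' @param weights optional non-negative case weights (e.g. spots per bin:
#'   the variance of a bin mean scales as 1/n, so weighting by n makes the
#'   fit equivalent to fitting every spot at its bin center). Default:
#'   unweighted.
#' @return named list of three `zonation_fit` objects
#'   (`poly2`, `gauss`, `inv_gauss`).
#' @export
fit_models <- function(expr, t, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(expr))
  ok <- is.finite(expr) & is.finite(t) & is.finite(weights)
  expr <- expr[ok]; t <- t[ok]; weights <- weights[ok]
  if (length(expr) < 8L)
    stop("need at least 8 points to fit (have ", length(expr), ")",
         call. = FALSE)
  if (max(t) == min(t)) stop("t values are all identical", call. = FALSE)
  t_range <- range(t)
  n <- length(expr)
  df <- data.frame(y = expr, t = t)

  lf <- stats::lm(y ~ t + I(t^2), data = df, weights = weights)
  cf <- stats::coef(lf)
  poly_fit <- new_fit("poly2",
                      list(a = unname(cf[1]), b = unname(cf[2]),
                           c = unname(cf[3])),
                      sum(weights * stats::resid(lf)^2), n, t_range, TRUE)

  # Raw Levenberg-Marquardt (nls.lm): at the sigma = 1 starting value the
  # constant and peak-height directions are nearly collinear, which the
  # nls-model wrapper rejects as a singular gradient even though LM handles
  # it. The published starting values come first; a second, data-driven
  # start (peak/trough located at the observed extremum, width a quarter of
  # the pseudotime range) guards against the flat-likelihood degeneracy at
  # sigma = 1 for narrow features -- the lower-RSS solution wins.
  sw <- sqrt(weights)
  try_nls <- function(curve_fn, starts, lower, upper, family, par_names) {
    res_fn <- function(par) sw * (expr - curve_fn(as.list(par), t))
    best <- NULL
    for (start in starts) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = start, lower = lower, upper = upper, fn = res_fn,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                               ptol = 1e-14))),
        error = function(e) NULL)
      ok <- !is.null(fit) && fit$info %in% 1:4 &&
        all(is.finite(unlist(fit$par)))
      if (!ok) next
      rss <- sum(res_fn(fit$par)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(par = as.list(unlist(fit$par)), rss = rss)
    }
    if (is.null(best))
      return(new_fit(family, stats::setNames(as.list(rep(NA_real_,
             length(par_names))), par_names), NA_real_, n, t_range, FALSE))
    new_fit(family, best$par[par_names], best$rss, n, t_range, TRUE)
  }

  # a feature narrower than the spacing of the fitted t values cannot be
  # identified from them; bound sigma below accordingly
  sig_lo <- max(0.02, min(diff(sort(unique(t)))))
  w4 <- diff(t_range) / 4
  gauss_fit <- try_nls(
    function(p, t) p$h * exp(-(t - p$mu)^2 / (2 * p$sigma^2)),
    starts = list(list(h = 1, mu = mean(t), sigma = 1),
                  list(h = max(expr), mu = t[which.max(expr)], sigma = w4)),
    lower = c(h = 0, mu = -0.5, sigma = sig_lo),
    upper = c(h = Inf, mu = 1.5, sigma = 10),
    "gauss", c("h", "mu", "sigma"))

  invg_fit <- try_nls(
    function(p, t) p$C - p$h * exp(-(t - p$mu)^2 / (2 * p$sigma^2)),
    starts = list(list(C = max(expr), h = max(expr) - min(expr),
                       mu = mean(t), sigma = 1),
                  list(C = max(expr), h = max(expr) - min(expr),
                       mu = t[which.min(expr)], sigma = w4)),
    lower = c(C = 0, h = 0, mu = -0.5, sigma = sig_lo),
    upper = c(C = Inf, h = Inf, mu = 1.5, sigma = 10),
    "inv_gauss", c("C", "h", "mu", "sigma"))

  list(poly2 = poly_fit, gauss = gauss_fit, inv_gauss = invg_fit)
}

#' Normalized range of a fitted model
#'
#' `(max - min) / max` of the fitted model values over the observed
#' pseudotime range (512-point grid). Defined as 0 when the fitted maximum
#' does not exceed `epsilon`, which forces a non-zonated call.
#'
#' @param fit a converged `zonation_fit`.
#' @param epsilon positivity guard for the maximum (default 1e-8).
#' @return the normalized range (>= 0 for non-negative profiles).
#' @export
normalized_range <- function(fit, epsilon = 1e-8) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (!(fit$fitted_max > epsilon)) return(0)
  rng <- fit$fitted_max - fit$fitted_min
  # a range at relative machine precision is a constant profile
  if (rng <= epsilon * abs(fit$fitted_max)) return(0)
  rng / fit$fitted_max
}

#' Select the best model by AIC
#'
#' Among converged fits, minimizes `n log(rss/n) + 2k` with k = 3, 3, 4
#' parameters; ties break in the order poly2, gauss, inv_gauss.
#'
#' @param fits the list returned by [fit_models()].
#' @return the winning `zonation_fit`, or `NULL` when no fit converged.
#' @export
select_model <- function(fits) {
  fits <- fits[c("poly2", "gauss", "inv_gauss")]
  k <- c(poly2 = 3, gauss = 3, inv_gauss = 4)
  aic <- vapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!isTRUE(f$converged)) return(Inf)
    f$n_points * log(max(f$rss, 0) / f$n_points) + 2 * k[[nm]]
  }, numeric(1L))
  if (all(!is.finite(aic)) && all(aic > 0)) return(NULL)
  fits[[which.min(aic)]]
}

#' Classify one gene's zonation pattern
#'
#' With pseudotime oriented 0 = periportal, 1 = pericentral: a normalized
#' range below `threshold` gives `non_zonated`. A selected inverted Gaussian
#' whose trough is interior and whose endpoints both sit at least
#' `threshold * fitted_max` above the trough gives `bipolar`. Otherwise the
#' grid-argmax location decides: `<= pole_lo` periportal, `>= pole_hi`
#' pericentral, interior peak midzonal.
#'
#' @param best the selected `zonation_fit` (or `NULL`).
#' @param threshold non-zonated cutoff on the normalized range (default 0.1).
#' @param pole_lo,pole_hi pole boundaries on t (defaults 0.25 / 0.75).
#' @return a label string.
#' @export
classify_gene <- function(best, threshold = 0.1, pole_lo = 0.25,
                          pole_hi = 0.75) {
  if (is.null(best)) return("non_zonated")
  if (normalized_range(best) < threshold) return("non_zonated")
  y <- best$grid_values
  grid <- best$grid
  if (best$family == "inv_gauss") {
    i_min <- which.min(y)
    interior <- i_min > 1L && i_min < length(y)
    elevated <- all(y[c(1L, length(y))] >= min(y) + threshold * best$fitted_max)
    if (interior && elevated) return("bipolar")
  }
  m <- grid[which.max(y)]
  if (m <= pole_lo) "periportal"
  else if (m >= pole_hi) "pericentral"
  else "midzonal"
}

#' Classify all genes per condition
#'
#' For each condition, expression is summarized as 20-bin mean profiles of
#' the normalized values along the oriented axis, the three models are
#' fitted, the best is selected by AIC, and the five-way label is assigned.
#' Genes failing the detection filter in a condition get no label there.
#'
#' @param ds the merged [spot_dataset].
#' @param axis an oriented `pseudotime_axis` over the major spots of `ds`.
#' @param norm normalized matrix from [normalize_log()] (computed if `NULL`).
#' @param gene_list gene ids to classify, or `NULL` to apply [filter_genes()]
#'   per condition over the axis spots.
#' @param conditions conditions to process (default: all present).
#' @param n_bins bins along the axis (default 20).
#' @param threshold,pole_lo,pole_hi passed to [classify_gene()].
#' @param min_count,min_spots passed to [filter_genes()] when `gene_list` is
#'   `NULL`.
#' @param min_bin_spots bins resting on fewer spots than this are treated as
#'   missing, like empty bins (default 5): their means carry no usable
#'   standard error and would otherwise dominate the fit tails.
#' @return data.frame: `gene`, `condition`, `label`, `family`,
#'   `normalized_range`, `rss`, and parameter columns (`a, b, c, h, mu,
#'   sigma, C`; `NA` where not applicable).
#' @export
classify_all <- function(ds, axis, norm = NULL, gene_list = NULL,
                         conditions = NULL, n_bins = 20L, threshold = 0.1,
                         pole_lo = 0.25, pole_hi = 0.75, min_count = 10L,
                         min_spots = 200L, min_bin_spots = 5L) {
  if (!isTRUE(axis$orientation_applied))
    stop("axis must be oriented before classification", call. = FALSE)
  if (is.null(norm)) norm <- normalize_log(ds)
  spot_cond <- stats::setNames(ds$condition, ds$barcodes)
  if (is.null(conditions))
    conditions <- unique(spot_cond[names(axis$t)])
  par_cols <- c("a", "b", "c", "h", "mu", "sigma", "C")
  n_failed <- 0L; failed_genes <- character()
  out <- list()
  for (cond in conditions) {
    axis_bc <- names(axis$t)[spot_cond[names(axis$t)] == cond]
    genes <- if (is.null(gene_list))
      filter_genes(ds, min_count, min_spots, spots = axis_bc) else
      intersect(gene_list, ds$gene_ids)
    if (!length(genes)) next
    prof <- bin_profiles(norm, axis, n_bins = n_bins, condition = cond,
                         spot_conditions = spot_cond, genes = genes)
    for (g in genes) {
      pg <- prof[prof$gene == g & !is.na(prof$mean) &
                   prof$n >= min_bin_spots, , drop = FALSE]
      if (nrow(pg) < 8L) { n_failed <- n_failed + 1L
        failed_genes <- c(failed_genes, g); next }
      tt <- (pg$bin_lo + pg$bin_hi) / 2
      fits <- fit_models(pg$mean, tt, weights = pg$n)
      best <- select_model(fits)
      label <- classify_gene(best, threshold, pole_lo, pole_hi)
      row <- stats::setNames(as.list(rep(NA_real_, length(par_cols))), par_cols)
      if (!is.null(best)) row[names(best$params)] <- best$params
      out[[length(out) + 1L]] <- cbind(
        data.frame(gene = g, condition = cond,
                   label = label,
                   family = if (is.null(best)) NA_character_ else best$family,
                   normalized_range = if (is.null(best)) 0 else
                     normalized_range(best),
                   rss = if (is.null(best)) NA_real_ else best$rss,
                   stringsAsFactors = FALSE),
        as.data.frame(row))
    }
  }
  if (n_failed > 0L)
    warning(n_failed, " gene/condition profile(s) had too few bins to fit ",
            "(first: ", paste(utils::head(failed_genes, 10L), collapse = ", "),
            ")", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate zonation-label transitions between two conditions
#'
#' Builds the 5 x 5 gene-count matrix of label flows from condition A (rows)
#' to condition B (columns) over the genes classified in both, retaining the
#' per-cell gene lists (attribute `"genes"`) for export (e.g. Sankey
#' diagrams).
#'
#' @param labels_a,labels_b data.frames with columns `gene` and `label` (as
#'   returned by [classify_all()], one condition each), or named label
#'   vectors.
#' @return integer matrix with `dimnames` the five labels and attribute
#'   `genes` (a list-matrix of gene id vectors).
#' @export
transition_table <- function(labels_a, labels_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(as.character(x$label), x$gene)
    else x
  }
  a <- as_vec(labels_a); b <- as_vec(labels_b)
  shared <- intersect(names(a), names(b))
  if (!length(shared))
    stop("label tables share no genes", call. = FALSE)
  fa <- factor(a[shared], levels = ZONATION_LEVELS)
  fb <- factor(b[shared], levels = ZONATION_LEVELS)
  tab <- table(fa, fb, dnn = NULL)
  m <- matrix(as.integer(tab), 5L, 5L,
              dimnames = list(ZONATION_LEVELS, ZONATION_LEVELS))
  genes <- matrix(vector("list", 25L), 5L, 5L,
                  dimnames = dimnames(m))
  for (i in ZONATION_LEVELS) for (j in ZONATION_LEVELS)
    genes[[i, j]] <- shared[fa == i & fb == j]
  attr(m, "genes") <- genes
  m
}

#' Export a transition table as Sankey-ready JSON
#'
#' @param tab a matrix from [transition_table()].
#' @param path output file.
#' @param from,to names of the two conditions (for node labels).
#' @return `path`, invisibly.
#' @export
write_transition_json <- function(tab, path, from = "A", to = "B") {
  links <- do.call(rbind, lapply(ZONATION_LEVELS, function(i)
    do.call(rbind, lapply(ZONATION_LEVELS, function(j)
      data.frame(source = paste0(from, ":", i), target = paste0(to, ":", j),
                 value = tab[i, j])))))
  links <- links[links$value > 0, , drop = FALSE]
  jsonlite::write_json(list(nodes = data.frame(
    name = c(paste0(from, ":", ZONATION_LEVELS),
             paste0(to, ":", ZONATION_LEVELS))), links = links),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
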