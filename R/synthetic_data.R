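#' Gene specification for the lobule simulator
#'
#' Describes one gene's true radial expression profile. The profile is a
#' function of the radial coordinate `r` (0 at the central vein, 1 at the
#' portal boundary) drawn from the same families the zonation classifier
#' fits: a quadratic polynomial, a Gaussian peak, an inverted Gaussian
#' trough, or a flat level.
#'
#' @param gene_id gene identifier.
#' @param family one of `"poly2"`, `"gauss"`, `"inv_gauss"`, `"flat"`.
#' @param params named list of family parameters: poly2 `a, b, c`;
#'   gauss `h, mu, sigma`; inv_gauss `C, h, mu, sigma`; flat `level`.
#' @param baseline_fraction relative abundance weight (> 0).
#' @param condition_effects named list (by condition) of overrides; each entry
#'   may carry `family`, `params` and/or a multiplicative amplitude `scale`.
#' @param is_mito,is_hemoglobin logical flags used for QC artifacts.
#' @return an object of class `gene_spec`.
#' @export
gene_spec <- function(gene_id, family, params, baseline_fraction = 1,
                      condition_effects = list(), is_mito = FALSE,
                      is_hemoglobin = FALSE) {
  family <- match.arg(family, c("poly2", "gauss", "inv_gauss", "flat"))
  check_params <- function(family, params) {
    need <- switch(family,
                   poly2 = c("a", "b", "c"),
                   gauss = c("h", "mu", "sigma"),
                   inv_gauss = c("C", "h", "mu", "sigma"),
                   flat = "level")
    miss <- setdiff(need, names(params))
    if (length(miss))
      stop("gene ", gene_id, ": family '", family, "' needs parameter(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (family %in% c("gauss", "inv_gauss")) {
      if (params$h <= 0 || params$sigma <= 0)
        stop("gene ", gene_id, ": h and sigma must be positive", call. = FALSE)
      if (family == "inv_gauss" && params$C < params$h)
        stop("gene ", gene_id, ": inv_gauss requires C >= h", call. = FALSE)
    }
  }
  check_params(family, params)
  for (cond in names(condition_effects)) {
    eff <- condition_effects[[cond]]
    if (!is.null(eff$family)) check_params(eff$family, eff$params)
  }
  structure(list(gene_id = gene_id, family = family, params = params,
                 baseline_fraction = baseline_fraction,
                 condition_effects = condition_effects,
                 is_mito = is_mito, is_hemoglobin = is_hemoglobin),
            class = "gene_spec")
}

resolve_spec <- function(spec, condition) {
  family <- spec$family
  params <- spec$params
  scale <- 1
  eff <- spec$condition_effects[[condition]]
  if (!is.null(eff)) {
    if (!is.null(eff$family)) family <- eff$family
    if (!is.null(eff$params)) params <- eff$params
    if (!is.null(eff$scale)) scale <- eff$scale
  }
  list(family = family, params = params, scale = scale)
}

#' True mean expression profile of a simulated gene
#'
#' Evaluates the (condition-resolved) profile at radial coordinate `r`;
#' negative values are clipped to zero.
#'
#' @param spec a [gene_spec].
#' @param r radial coordinate(s) in `[0, 1]` (0 = central vein).
#' @param condition condition label; matching `condition_effects` are applied
#'   before evaluation.
#' @return non-negative mean expression, same length as `r`.
#' @export
profile_mean <- function(spec, r, condition = "ctrl") {
  rs <- resolve_spec(spec, condition)
  p <- rs$params
  y <- switch(rs$family,
              poly2 = p$a + p$b * r + p$c * r^2,
              gauss = p$h * exp(-(r - p$mu)^2 / (2 * p$sigma^2)),
              inv_gauss = p$C - p$h * exp(-(r - p$mu)^2 / (2 * p$sigma^2)),
              flat = rep(p$level, length(r)))
  pmax(rs$scale * y, 0)
}

#' Hexagonal lobule geometry on a triangular spot grid
#'
#' Places `n_lobules` hexagonal lobules (central veins at the centers, portal
#' nodes at the corners) side by side and covers them with a triangular spot
#' lattice at Visium-like spacing. Each spot's radial coordinate is its
#' distance to the nearest central vein divided by the lobule inradius,
#' clipped to `[0, 1]`; a lobule then spans roughly 10-13 concentric spot
#' layers, matching the ~9-12 cell layers of a ~0.5 mm mouse lobule.
#'
#' @param n_lobules number of lobules (>= 1).
#' @param spots_per_lobule approximate number of spots per lobule (>= 10).
#' @param seed integer seed (used only for a small jitter of the pixel
#'   coordinates; the lattice and `r` are deterministic).
#' @param lobule_radius lobule inradius in mm (default 0.25, i.e. 0.5 mm
#'   diameter).
#' @return data.frame with columns `barcode`, `lobule_id`, `r`, `array_row`,
#'   `array_col`, `pixel_x`, `pixel_y`.
#' @export
make_lobule_geometry <- function(n_lobules, spots_per_lobule, seed = 1L,
                                 lobule_radius = 0.25) {
  if (n_lobules < 1L) stop("n_lobules must be >= 1", call. = FALSE)
  if (spots_per_lobule < 10L) stop("spots_per_lobule must be >= 10", call. = FALSE)
  R <- lobule_radius
  s <- 2 * R / sqrt(spots_per_lobule)           # lattice spacing
  # central veins on lattice row 0, 2R apart (snapped to lattice columns)
  step <- round(2 * R / s)
  cx <- (seq_len(n_lobules) - 1L) * step * s
  cy <- rep(0, n_lobules)
  # triangular lattice covering all lobules plus the hexagon circumradius
  Rc <- 2 * R / sqrt(3) * 1.0001                # Voronoi-cell circumradius
  pad <- Rc + s
  xr <- c(min(cx) - pad, max(cx) + pad)
  yr <- c(-pad, pad)
  jj <- seq(floor(yr[1] / (s * sqrt(3) / 2)), ceiling(yr[2] / (s * sqrt(3) / 2)))
  grid <- do.call(rbind, lapply(jj, function(j) {
    y <- j * s * sqrt(3) / 2
    off <- (abs(j) %% 2L) * s / 2
    ii <- seq(floor((xr[1] - off) / s), ceiling((xr[2] - off) / s))
    data.frame(i = ii, j = j, x = ii * s + off, y = y)
  }))
  d2 <- outer(grid$x, cx, "-")^2 + outer(grid$y, cy, "-")^2
  lob <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(grid)), lob)])
  keep <- dmin <= Rc
  grid <- grid[keep, , drop = FALSE]
  lob <- lob[keep]
  r <- pmin(dmin[keep] / R, 1)
  set.seed(seed)
  n <- nrow(grid)
  px_scale <- 1000                              # mm -> arbitrary pixel units
  data.frame(
    barcode = sprintf("SP%05d-1", seq_len(n)),
    lobule_id = lob,
    r = r,
    array_row = grid$j - min(grid$j),
    array_col = 2L * (grid$i - min(grid$i)) + (abs(grid$j) %% 2L),
    pixel_x = grid$x * px_scale + stats::runif(n, -0.5, 0.5),
    pixel_y = grid$y * px_scale + stats::runif(n, -0.5, 0.5)
  )
}

#' Zonation label implied by a gene's true profile
#'
#' Applies the classifier's labeling rule to the noiseless profile expressed
#' on the analysis axis `t = 1 - r` (0 = periportal): normalized range of the
#' true curve below the threshold gives `non_zonated`; an inverted-Gaussian
#' trough with elevated poles gives `bipolar`; otherwise the argmax location
#' decides periportal (<= 0.25), pericentral (>= 0.75) or midzonal.
#'
#' @param spec a [gene_spec].
#' @param condition condition label.
#' @param threshold normalized-range cutoff (default 0.1).
#' @return a label string.
#' @export
true_label <- function(spec, condition = "ctrl", threshold = 0.1) {
  tg <- seq(0, 1, length.out = 512L)
  y <- profile_mean(spec, 1 - tg, condition)    # profile over t
  ymax <- max(y); ymin <- min(y)
  nr <- if (ymax > 1e-8) (ymax - ymin) / ymax else 0
  if (nr < threshold) return("non_zonated")
  fam <- resolve_spec(spec, condition)$family
  if (fam == "inv_gauss") {
    i_min <- which.min(y)
    interior <- i_min > 1L && i_min < length(y)
    if (interior && all(y[c(1L, length(y))] >= ymin + threshold * ymax))
      return("bipolar")
  }
  m <- tg[which.max(y)]
  if (m <= 0.25) "periportal" else if (m >= 0.75) "pericentral" else "midzonal"
}

#' Default balanced gene panel
#'
#' Draws a panel balanced across five truth families: periportal-monotone and
#' pericentral-monotone quadratics, midzonal Gaussian peaks, bipolar inverted
#' Gaussians, and flat (non-zonated) genes. The panel is compositionally
#' balanced by construction: each pericentral gene is the exact mirror
#' (`r -> 1 - r`) of a periportal draw and each bipolar gene is the
#' complement of a midzonal draw (same peak height, location and width under
#' a constant), so the summed expected expression is near-uniform along the
#' radius and per-spot proportion normalization does not induce spurious
#' zonation in flat genes. A fraction of the zonated genes carries a
#' condition effect that switches the family to flat in the refed state
#' (emulating lipogenic genes such as Fasn/Thrsp whose portal zonation
#' collapses after refeeding), and a fraction gets a 1.5x amplitude scaling
#' in the fasted state; paired genes share these effects so the balance is
#' kept in every condition. The flat family hosts the QC artifact genes:
#' mitochondrial (`mt-*`) and hemoglobin (`Hba/Hbb`) genes. The first genes
#' of the monotone families reuse landmark names (Alb, Cyp2f2, Pck1 portal;
#' Glul, Lgr5, Cyp2e1 central) so that default axis orientation markers are
#' present.
#'
#' @param n_per_family genes per family (>= 1).
#' @param seed integer seed.
#' @param switch_fraction fraction of each zonated family switched to flat in
#'   the refed condition (default 0.1).
#' @param scale_fraction fraction of genes amplitude-scaled 1.5x when fasted.
#' @return list of [gene_spec] objects (length `5 * n_per_family`).
#' @export
default_gene_panel <- function(n_per_family = 120L, seed = 1L,
                               switch_fraction = 0.1, scale_fraction = 0.1) {
  if (n_per_family < 1L) stop("n_per_family must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- n_per_family
  specs <- list()

  pp_names <- c("Alb", "Cyp2f2", "Pck1", "Fasn", "Thrsp", "Aldh1b1")
  pc_names <- c("Glul", "Lgr5", "Cyp2e1", "Axin2", "Gck")
  name_or <- function(i, pool, prefix)
    if (i <= length(pool)) pool[i] else sprintf("%s%03d", prefix, i)

  draw_mono <- function() {
    a <- stats::runif(1, 0.2, 0.6)
    b <- stats::runif(1, 1.5, 3)
    c <- stats::runif(1, -b / 3, b / 2)
    list(a = a, b = b, c = c)
  }
  flat_override <- function(spec_params, family) {
    # level matching the mean of the original profile keeps abundance stable
    rr <- seq(0, 1, length.out = 101L)
    p <- spec_params
    y <- switch(family,
                poly2 = p$a + p$b * rr + p$c * rr^2,
                gauss = p$h * exp(-(rr - p$mu)^2 / (2 * p$sigma^2)),
                inv_gauss = p$C - p$h * exp(-(rr - p$mu)^2 / (2 * p$sigma^2)))
    list(family = "flat", params = list(level = mean(pmax(y, 0))))
  }

  n_switch <- max(1L, round(switch_fraction * n))
  n_scale <- max(1L, round(scale_fraction * n))

  make_spec <- function(i, mk, names_pool, prefix, bf) {
    eff <- list()
    if (i <= n_switch)
      eff$refed <- flat_override(mk$params, mk$family)
    if (i > n_switch && i <= n_switch + n_scale)
      eff$fasted <- list(scale = 1.5)
    gene_spec(gene_id = name_or(i, names_pool, prefix),
              family = mk$family, params = mk$params,
              baseline_fraction = bf, condition_effects = eff)
  }

  # paired draws: pc mirrors pp, bp complements mz; pairs share the
  # abundance weight and condition effects so the sum stays flat in r
  pp_draws <- replicate(n, draw_mono(), simplify = FALSE)
  mz_draws <- replicate(n, list(h = stats::runif(1, 1.5, 3),
                                mu = stats::runif(1, 0.35, 0.65),
                                sigma = stats::runif(1, 0.08, 0.15)),
                        simplify = FALSE)
  bf_mono <- stats::runif(n, 0.7, 1.5)
  bf_peak <- stats::runif(n, 0.7, 1.5)

  for (i in seq_len(n))                         # periportal: increasing in r
    specs[[length(specs) + 1L]] <- make_spec(
      i, list(family = "poly2", params = pp_draws[[i]]), pp_names, "Ppg",
      bf_mono[i])
  for (i in seq_len(n)) {                       # pericentral: mirror r -> 1-r
    p <- pp_draws[[i]]
    specs[[length(specs) + 1L]] <- make_spec(
      i, list(family = "poly2",
              params = list(a = p$a + p$b + p$c, b = -p$b - 2 * p$c,
                            c = p$c)), pc_names, "Pcg", bf_mono[i])
  }
  for (i in seq_len(n))                         # midzonal Gaussian peak
    specs[[length(specs) + 1L]] <- make_spec(
      i, list(family = "gauss", params = mz_draws[[i]]), character(), "Mzg",
      bf_peak[i])
  for (i in seq_len(n)) {                       # bipolar complement
    p <- mz_draws[[i]]
    C <- p$h * stats::runif(1, 1.15, 1.6)
    specs[[length(specs) + 1L]] <- make_spec(
      i, list(family = "inv_gauss",
              params = list(C = C, h = p$h, mu = p$mu, sigma = p$sigma)),
      character(), "Bpg", bf_peak[i])
  }

  mito_names <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
                  "mt-Atp6", "mt-Cytb", "mt-Nd4")
  hb_names <- c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt")
  for (i in seq_len(n)) {
    is_mito <- i <= min(length(mito_names), n)
    left <- i - length(mito_names)
    is_hb <- !is_mito && left >= 1L && left <= length(hb_names) && n >= i
    id <- if (is_mito) mito_names[i] else if (is_hb) hb_names[left] else
      sprintf("Flg%03d", i)
    level <- if (is_hb) stats::runif(1, 1.5, 2.5) else stats::runif(1, 0.8, 2)
    specs[[length(specs) + 1L]] <- gene_spec(
      gene_id = id, family = "flat", params = list(level = level),
      baseline_fraction = if (is_hb) 1.5 else stats::runif(1, 0.7, 1.5),
      is_mito = is_mito, is_hemoglobin = is_hb)
  }
  specs
}

#' Simulate spot counts over a lobule geometry
#'
#' Per spot, gene proportions are the true profiles times the baseline
#' abundance weights, renormalized to sum to one. Mitochondrial genes are
#' boosted by a per-condition factor before renormalization (emulating the
#' elevated mitochondrial fraction of fasted liver); a fixed fraction of
#' spots is "erythroid-contaminated", with hemoglobin-gene proportions
#' inflated `hb_inflation`-fold. Library sizes are log-normal around
#' `lib_size_mean` and counts are negative-binomial with a single global
#' dispersion.
#'
#' @param geometry data.frame from [make_lobule_geometry()].
#' @param gene_specs list of [gene_spec].
#' @param condition condition label for all spots.
#' @param lib_size_mean mean library size (UMIs per spot; default 24000, the
#'   depth scale of mouse-liver Visium data).
#' @param dispersion negative-binomial size parameter (> 0; larger = closer
#'   to Poisson).
#' @param mito_boost named per-condition multiplier for mitochondrial genes.
#' @param erythroid_fraction fraction of spots flagged erythroid; the count
#'   is `round(fraction * n_spots)`, placement is random.
#' @param hb_inflation hemoglobin proportion inflation in erythroid spots.
#' @param lib_size_sdlog log-sd of the library size distribution.
#' @param noise `"nb"` for negative-binomial sampling, `"none"` for rounded
#'   expected counts at a fixed library size (noiseless-mean variant).
#' @param seed integer seed; identical seed gives identical output.
#' @return list with elements `dataset` (a [spot_dataset]) and `truth` (list
#'   of data.frames `genes` and `spots`; spots carry `r`, `t_true = 1 - r`,
#'   `lobule_id`, `erythroid_flag`).
#' @export
simulate_counts <- function(geometry, gene_specs, condition = "ctrl",
                            lib_size_mean = 24000, dispersion = 10,
                            mito_boost = c(ctrl = 1, fasted = 1.5, refed = 1),
                            erythroid_fraction = 0.05, hb_inflation = 20,
                            lib_size_sdlog = 0.3,
                            noise = c("nb", "none"), seed = 1L) {
  noise <- match.arg(noise)
  if (!length(gene_specs)) stop("gene_specs must be non-empty", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  n_spots <- nrow(geometry)
  n_genes <- length(gene_specs)
  gene_ids <- vapply(gene_specs, `[[`, character(1L), "gene_id")

  prof <- matrix(0, n_genes, n_spots)
  for (g in seq_len(n_genes))
    prof[g, ] <- profile_mean(gene_specs[[g]], geometry$r, condition) *
      gene_specs[[g]]$baseline_fraction
  is_mito <- vapply(gene_specs, `[[`, logical(1L), "is_mito")
  is_hb <- vapply(gene_specs, `[[`, logical(1L), "is_hemoglobin")
  boost <- if (condition %in% names(mito_boost)) mito_boost[[condition]] else 1
  prof[is_mito, ] <- prof[is_mito, , drop = FALSE] * boost

  set.seed(seed)
  n_ery <- round(erythroid_fraction * n_spots)
  ery_idx <- if (n_ery > 0L) sample.int(n_spots, n_ery) else integer()
  prof[is_hb, ery_idx] <- prof[is_hb, ery_idx, drop = FALSE] * hb_inflation

  tot <- colSums(prof)
  if (any(tot <= 0))
    stop("all-zero expected proportions for spot(s): ",
         paste(utils::head(geometry$barcode[tot <= 0], 3L), collapse = ", "),
         call. = FALSE)
  p <- sweep(prof, 2L, tot, "/")

  if (noise == "nb") {
    lib <- stats::rlnorm(n_spots, meanlog = log(lib_size_mean) -
                           lib_size_sdlog^2 / 2, sdlog = lib_size_sdlog)
    mu <- sweep(p, 2L, lib, "*")
    counts <- matrix(stats::rnbinom(n_genes * n_spots, mu = mu,
                                    size = dispersion), n_genes, n_spots)
  } else {
    counts <- round(p * lib_size_mean)
  }

  positions <- data.frame(array_row = geometry$array_row,
                          array_col = geometry$array_col,
                          pixel_x = geometry$pixel_x,
                          pixel_y = geometry$pixel_y,
                          in_tissue = 1L)
  ds <- spot_dataset(counts, gene_ids, gene_ids, geometry$barcode, positions,
                     condition)

  par_cols <- c("a", "b", "c", "h", "mu", "sigma", "C", "level")
  genes <- do.call(rbind, lapply(gene_specs, function(sp) {
    rs <- resolve_spec(sp, condition)
    row <- as.list(rep(NA_real_, length(par_cols)))
    names(row) <- par_cols
    row[names(rs$params)] <- lapply(rs$params, function(v) v * 1)
    cbind(data.frame(gene_id = sp$gene_id, condition = condition,
                     family = rs$family,
                     true_label = true_label(sp, condition),
                     stringsAsFactors = FALSE),
          as.data.frame(row))
  }))
  spots <- data.frame(barcode = geometry$barcode, condition = condition,
                      r = geometry$r, t_true = 1 - geometry$r,
                      lobule_id = geometry$lobule_id,
                      erythroid_flag = seq_len(n_spots) %in% ery_idx)
  list(dataset = ds, truth = list(genes = genes, spots = spots))
}

#' Simulate the default three-condition study
#'
#' Convenience wrapper: one geometry shared across conditions, the default
#' gene panel, and one simulated sample per condition (ctrl, fasted, refed),
#' merged into a single dataset. The fasted sample gets the mitochondrial
#' boost; refed carries the programmed pattern switches.
#'
#' @param n_lobules,spots_per_lobule geometry parameters (defaults 2 x 500).
#' @param n_per_family panel size per family (default 120).
#' @param conditions conditions to simulate.
#' @param seed integer seed; per-condition seeds are derived from it.
#' @param ... passed to [simulate_counts()].
#' @return list with `dataset` (merged), `truth` (genes table across
#'   conditions, spots table with suffixed barcodes), `panel`, `geometry`.
#' @export
simulate_study <- function(n_lobules = 2L, spots_per_lobule = 500L,
                           n_per_family = 120L,
                           conditions = c("ctrl", "fasted", "refed"),
                           seed = 1L, ...) {
  geom <- make_lobule_geometry(n_lobules, spots_per_lobule, seed = seed)
  panel <- default_gene_panel(n_per_family, seed = seed)
  sims <- lapply(seq_along(conditions), function(i)
    simulate_counts(geom, panel, condition = conditions[i],
                    seed = seed + i, ...))
  merged <- merge_conditions(lapply(sims, `[[`, "dataset"), conditions)
  genes <- do.call(rbind, lapply(sims, function(s) s$truth$genes))
  spots <- do.call(rbind, lapply(seq_along(sims), function(i) {
    sp <- sims[[i]]$truth$spots
    sp$barcode <- paste0(sp$barcode, "_", conditions[i])
    sp
  }))
  rownames(genes) <- rownames(spots) <- NULL
  list(dataset = merged, truth = list(genes = genes, spots = spots),
       panel = panel, geometry = geom)
}

#' Write simulator truth tables as TSV
#'
#' @param truth the `truth` element returned by [simulate_counts()] or
#'   [simulate_study()].
#' @param dir_path output directory.
#' @return `dir_path`, invisibly.
#' @export
write_truth <- function(truth, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  utils::write.table(truth$genes, file.path(dir_path, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$spots, file.path(dir_path, "truth_spots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir_path)
}
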