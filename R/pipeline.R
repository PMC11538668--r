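#' Default run configuration
#'
#' Returns the full parameter set of the pipeline with its documented
#' defaults. Any subset can be overridden via a YAML file or a named list;
#' unknown keys are rejected. The global `seed` is fanned out to per-stage
#' seeds by a fixed derivation (seed + a stage-name character hash, modulo
#' 2^31 - 1) so stages never share a stream.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    input_dirs = NULL,                 # named list condition -> bundle dir
    simulate = list(n_lobules = 2L, spots_per_lobule = 500L,
                    n_per_family = 120L,
                    conditions = c("ctrl", "fasted", "refed"),
                    lib_size_mean = 24000, dispersion = 10,
                    mito_boost = c(ctrl = 1, fasted = 1.5, refed = 1),
                    erythroid_fraction = 0.05, noise = "nb"),
    qc = list(mito_prefix = "mt-",
              hemoglobin_genes = c("Hba-a1", "Hba-a2", "Hbb-bs", "Hbb-bt"),
              hb_threshold = 0.1),
    normalize = list(scale = 1e4),
    cluster = list(n_pcs = 30L, k_neighbors = 15L, resolution = 0.8,
                   n_hvg = 2000L),
    axis = list(n_dc = 1L, n_bins = 20L,
                portal_markers = c("Alb", "Cyp2f2"),
                central_markers = c("Glul", "Lgr5"),
                root_cluster = NULL),
    zonation = list(threshold = 0.1, min_count = 10L, min_spots = 200L,
                    n_bins = 20L, pole_lo = 0.25, pole_hi = 0.75),
    de = list(lfc_threshold = 0.25, fdr_threshold = 0.05,
              comparisons = list(c("fasted", "ctrl"), c("refed", "fasted"))),
    ssgsea = list(alpha = 0.25, min_overlap = 5L, gmt = NULL,
                  normalize_across_spots = FALSE)
  )
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage)) * 10007L) %% 2147483647L
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown config field: ", key, call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]]) && nm != "comparisons" &&
        nm != "input_dirs") {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config path to a YAML file, or a named list of overrides, or
#'   `NULL` for pure defaults.
#' @return the resolved configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$output_dir))
    stop("config field missing: output_dir", call. = FALSE)
  cfg
}

#' Run the full zonation pipeline
#'
#' Orchestrates simulate (or read) -> merge -> QC -> normalize -> cluster ->
#' erythroid flagging -> diffusion pseudotime -> orientation -> zonation
#' classification -> transition tables -> differential expression ->
#' optional ssGSEA, writing every artifact as TSV/MTX under
#' `config$output_dir` together with a JSON run report echoing the resolved
#' configuration. Identical config and seed give identical artifacts.
#'
#' @param config as for [load_config()].
#' @return (invisibly) a list with the in-memory results: `dataset`, `truth`
#'   (when simulated), `qc`, `emb`, `axis`, `labels`, `transitions`, `de`,
#'   `scores`, `config`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  out <- cfg$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  report <- list(config = cfg, stages = list())
  tsv <- function(df, name) utils::write.table(
    df, file.path(out, name), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- input: read bundles or simulate ------------------------------------
  truth <- NULL
  if (!is.null(cfg$input_dirs)) {
    samples <- lapply(names(cfg$input_dirs), function(cond)
      read_visium(cfg$input_dirs[[cond]], condition = cond))
    ds <- merge_conditions(samples, names(cfg$input_dirs))
  } else {
    sim <- cfg$simulate
    study <- simulate_study(
      n_lobules = sim$n_lobules, spots_per_lobule = sim$spots_per_lobule,
      n_per_family = sim$n_per_family, conditions = sim$conditions,
      seed = stage_seed(cfg$seed, "simulate"),
      lib_size_mean = sim$lib_size_mean, dispersion = sim$dispersion,
      mito_boost = unlist(sim$mito_boost),
      erythroid_fraction = sim$erythroid_fraction, noise = sim$noise)
    ds <- study$dataset
    truth <- study$truth
    for (cond in sim$conditions) {
      sel <- ds$condition == cond
      sub <- subset_spots(ds, sel)
      sub$barcodes <- sub(paste0("_", cond, "$"), "", sub$barcodes)
      write_visium(sub, file.path(out, paste0("bundle_", cond)))
    }
    write_truth(truth, out)
  }
  report$stages$input <- list(n_genes = nrow(ds$counts),
                              n_spots = ncol(ds$counts))

  # --- QC / normalize / cluster -------------------------------------------
  qc <- compute_qc(ds, cfg$qc$mito_prefix, cfg$qc$hemoglobin_genes)
  tsv(qc, "qc.tsv")
  ds <- subset_spots(ds, !qc$flag_removal)
  qc <- qc[!qc$flag_removal, , drop = FALSE]
  norm <- normalize_log(ds, cfg$normalize$scale)
  emb <- reduce_and_cluster(norm, n_pcs = cfg$cluster$n_pcs,
                            k_neighbors = cfg$cluster$k_neighbors,
                            resolution = cfg$cluster$resolution,
                            seed = stage_seed(cfg$seed, "cluster"),
                            n_hvg = cfg$cluster$n_hvg)
  emb <- flag_erythroid_clusters(emb, qc, cfg$qc$hb_threshold)
  tsv(data.frame(barcode = ds$barcodes, cluster = emb$cluster_labels,
                 major_flag = major_spots(emb)), "clusters.tsv")
  report$stages$cluster <- list(n_clusters = length(emb$major_flag),
                                n_major = sum(emb$major_flag))

  # --- axis ----------------------------------------------------------------
  dm <- diffusion_map(emb, n_dc = cfg$axis$n_dc)
  root <- cfg$axis$root_cluster
  if (is.null(root))
    root <- pick_root_cluster(emb, norm, cfg$axis$portal_markers)
  axis <- pseudotime(dm, emb, root)
  axis <- orient_axis(axis, norm, cfg$axis$portal_markers,
                      cfg$axis$central_markers)
  spot_cond <- stats::setNames(ds$condition, ds$barcodes)
  tsv(data.frame(barcode = names(axis$t), t = unname(axis$t),
                 condition = unname(spot_cond[names(axis$t)])), "axis.tsv")
  report$stages$axis <- list(root_cluster = root, root_spot = axis$root_spot)

  # --- zonation ------------------------------------------------------------
  zn <- cfg$zonation
  labels <- classify_all(ds, axis, norm = norm, n_bins = zn$n_bins,
                         threshold = zn$threshold, pole_lo = zn$pole_lo,
                         pole_hi = zn$pole_hi, min_count = zn$min_count,
                         min_spots = zn$min_spots)
  tsv(labels, "zonation_labels.tsv")
  conds <- unique(labels$condition)
  transitions <- list()
  for (i in seq_len(max(length(conds) - 1L, 0L))) {
    a <- conds[i]; b <- conds[i + 1L]
    tt <- transition_table(labels[labels$condition == a, ],
                           labels[labels$condition == b, ])
    key <- paste0(a, "_to_", b)
    transitions[[key]] <- tt
    tsv(as.data.frame(as.table(tt), responseName = "n_genes"),
        paste0("transitions_", key, ".tsv"))
    write_transition_json(tt, file.path(out, paste0("transitions_", key,
                                                    ".json")), a, b)
  }

  # --- differential expression --------------------------------------------
  de <- list()
  maj <- major_spots(emb)
  for (cmp in cfg$de$comparisons) {
    ga <- ds$barcodes[maj & ds$condition == cmp[1L]]
    gb <- ds$barcodes[maj & ds$condition == cmp[2L]]
    if (length(ga) >= 3L && length(gb) >= 3L) {
      key <- paste0(cmp[1L], "_vs_", cmp[2L])
      de[[key]] <- wilcoxon_de(norm, ga, gb, cfg$de$lfc_threshold,
                               cfg$de$fdr_threshold)
      tsv(de[[key]], paste0("de_", key, ".tsv"))
    }
  }

  # --- ssGSEA --------------------------------------------------------------
  scores <- NULL
  sets <- if (!is.null(cfg$ssgsea$gmt)) read_gmt(cfg$ssgsea$gmt) else
    default_gene_sets()
  usable <- vapply(sets, function(s)
    sum(s %in% ds$gene_ids) >= cfg$ssgsea$min_overlap, logical(1L))
  if (any(usable)) {
    scores <- ssgsea_scores(norm, sets[usable], alpha = cfg$ssgsea$alpha,
                            min_overlap = cfg$ssgsea$min_overlap,
                            normalize_across_spots =
                              cfg$ssgsea$normalize_across_spots)
    utils::write.table(cbind(gene_set = rownames(scores),
                             as.data.frame(scores, check.names = FALSE)),
                       file.path(out, "ssgsea_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prof <- do.call(rbind, lapply(unique(ds$condition), function(cond)
      pathway_axis_profile(scores, axis, n_bins = cfg$axis$n_bins,
                           condition = cond, spot_conditions = spot_cond)))
    tsv(prof, "ssgsea_axis_profiles.tsv")
  }

  report$stages$zonation <- list(
    n_classified = nrow(labels),
    label_counts = as.list(table(labels$label)))
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(dataset = ds, truth = truth, qc = qc, emb = emb,
                 axis = axis, labels = labels, transitions = transitions,
                 de = de, scores = scores, config = cfg))
}
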