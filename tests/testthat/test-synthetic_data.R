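test_that("lobule geometry spans the full radial range in concentric layers", {
  geom <- make_lobule_geometry(2, 500, seed = 7)
  expect_true(any(geom$r == 0))                 # spot at a central vein
  expect_true(any(geom$r == 1))                 # clipped boundary spots
  expect_true(all(geom$r >= 0 & geom$r <= 1))
  bins <- cut(geom$r, seq(0, 1, length.out = 13), include.lowest = TRUE)
  expect_gte(length(unique(bins)), 9L)
  expect_identical(sort(unique(geom$lobule_id)), c(1L, 2L))
  expect_error(make_lobule_geometry(0, 100), "n_lobules")
  expect_error(make_lobule_geometry(1, 5), "spots_per_lobule")
})

test_that("profile_mean evaluates each family and applies condition effects", {
  g <- gene_spec("g", "gauss", list(h = 1, mu = 0.5, sigma = 0.15))
  expect_equal(profile_mean(g, 0.5), 1.0)
  ig <- gene_spec("i", "inv_gauss", list(C = 2, h = 1, mu = 0.5, sigma = 0.15))
  expect_equal(profile_mean(ig, 0.5), 1.0)
  p <- gene_spec("p", "poly2", list(a = 1, b = -1, c = 0))
  expect_equal(profile_mean(p, 0.25), 0.75)
  expect_equal(profile_mean(p, 2), 0)           # clipped at zero

  sw <- gene_spec("s", "poly2", list(a = 0, b = 2, c = 0),
                  condition_effects = list(
                    refed = list(family = "flat", params = list(level = 3)),
                    fasted = list(scale = 1.5)))
  expect_equal(profile_mean(sw, 0.5, "ctrl"), 1)
  expect_equal(profile_mean(sw, 0.5, "fasted"), 1.5)
  expect_equal(profile_mean(sw, 0.9, "refed"), 3)
})

test_that("gene_spec rejects invalid parameters", {
  expect_error(gene_spec("g", "gauss", list(h = 1, mu = 0.5)), "sigma")
  expect_error(gene_spec("g", "gauss", list(h = -1, mu = 0.5, sigma = 1)),
               "positive")
  expect_error(gene_spec("g", "inv_gauss",
                         list(C = 0.5, h = 1, mu = 0.5, sigma = 1)),
               "C >= h")
})

test_that("default panel is balanced, deterministic and carries switches", {
  panel <- default_gene_panel(120, seed = 1)
  expect_length(panel, 600L)
  fam <- table(vapply(panel, `[[`, character(1), "family"))
  expect_equal(as.vector(fam[c("poly2", "gauss", "inv_gauss", "flat")]),
               c(240L, 120L, 120L, 120L))
  labs <- table(vapply(panel, function(s) true_label(s, "ctrl"), character(1)))
  expect_equal(sort(as.vector(labs)), rep(120L, 5L))

  panel2 <- default_gene_panel(120, seed = 1)
  expect_identical(panel, panel2)

  switched <- vapply(panel, function(s)
    !is.null(s$condition_effects$refed$family), logical(1))
  expect_true(any(switched))
  sw1 <- panel[switched][[1]]
  expect_false(true_label(sw1, "ctrl") == true_label(sw1, "refed"))
  expect_identical(true_label(sw1, "refed"), "non_zonated")

  expect_true(any(vapply(panel, `[[`, logical(1), "is_mito")))
  expect_true(any(vapply(panel, `[[`, logical(1), "is_hemoglobin")))
})

test_that("panel composition is balanced along the radius", {
  panel <- default_gene_panel(120, seed = 2)
  rr <- seq(0, 1, 0.05)
  for (cond in c("ctrl", "fasted", "refed")) {
    Z <- vapply(rr, function(r)
      sum(vapply(panel, function(s)
        profile_mean(s, r, cond) * s$baseline_fraction, numeric(1))),
      numeric(1))
    expect_lt((max(Z) - min(Z)) / max(Z), 0.05)
  }
})

test_that("simulate_counts is seed-deterministic with exact erythroid count", {
  geom <- make_lobule_geometry(2, 500, seed = 3)
  panel <- default_gene_panel(20, seed = 3)
  s1 <- simulate_counts(geom, panel, "ctrl", erythroid_fraction = 0.1,
                        seed = 9)
  s2 <- simulate_counts(geom, panel, "ctrl", erythroid_fraction = 0.1,
                        seed = 9)
  expect_identical(as.matrix(s1$dataset$counts), as.matrix(s2$dataset$counts))
  expect_identical(s1$truth, s2$truth)
  expect_identical(sum(s1$truth$spots$erythroid_flag),
                   as.integer(round(0.1 * nrow(geom))))
  s3 <- simulate_counts(geom, panel, "ctrl", seed = 10)
  expect_false(identical(as.matrix(s1$dataset$counts),
                         as.matrix(s3$dataset$counts)))
})

test_that("counts recover the library depth for a single flat gene", {
  geom <- make_lobule_geometry(1, 500, seed = 4)
  one <- list(gene_spec("only", "flat", list(level = 1)))
  sim <- simulate_counts(geom, one, "ctrl", lib_size_mean = 10000,
                         dispersion = 1e6, erythroid_fraction = 0,
                         seed = 5)
  totals <- Matrix::colSums(sim$dataset$counts)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 10000), 3 * se)
})

test_that("noiseless mode yields the expected proportions exactly", {
  geom <- make_lobule_geometry(1, 100, seed = 6)
  panel <- default_gene_panel(5, seed = 6)
  sim <- simulate_counts(geom, panel, "ctrl", noise = "none",
                         erythroid_fraction = 0, seed = 7)
  # expected proportions sum to 1 before sampling -> totals ~ lib_size_mean
  expect_true(all(abs(Matrix::colSums(sim$dataset$counts) - 24000) <
                    nrow(sim$dataset$counts) / 2))
})

test_that("monotone poly2 genes give monotone binned profiles", {
  geom <- make_lobule_geometry(2, 500, seed = 8)
  panel <- default_gene_panel(30, seed = 8)
  sim <- simulate_counts(geom, panel, "ctrl", erythroid_fraction = 0,
                         seed = 9)
  tg <- sim$truth$genes
  pp <- tg$gene_id[tg$true_label == "periportal"][1:5]
  counts <- as.matrix(sim$dataset$counts)
  rownames(counts) <- sim$dataset$gene_ids
  bins <- cut(sim$truth$spots$r, seq(0, 1, length.out = 11),
              include.lowest = TRUE)
  for (g in pp) {
    bm <- tapply(counts[g, ] / Matrix::colSums(sim$dataset$counts), bins, mean)
    rho <- cor(seq_along(bm), as.vector(bm), method = "spearman",
               use = "complete.obs")
    expect_gte(abs(rho), 0.9)
    expect_gt(rho, 0)                           # increasing toward the portal
  }
})

test_that("mitochondrial boost raises the fasted mito fraction", {
  geom <- make_lobule_geometry(1, 300, seed = 10)
  panel <- default_gene_panel(20, seed = 10)
  ctrl <- simulate_counts(geom, panel, "ctrl", seed = 11)
  fast <- simulate_counts(geom, panel, "fasted", seed = 11)
  qc_c <- compute_qc(ctrl$dataset)
  qc_f <- compute_qc(fast$dataset)
  expect_gt(mean(qc_f$mito_fraction), mean(qc_c$mito_fraction))
})

test_that("truth tables are written as TSV", {
  geom <- make_lobule_geometry(1, 100, seed = 12)
  panel <- default_gene_panel(3, seed = 12)
  sim <- simulate_counts(geom, panel, "ctrl", seed = 13)
  out <- tempfile("truth")
  write_truth(sim$truth, out)
  genes <- read.delim(file.path(out, "truth_genes.tsv"))
  spots <- read.delim(file.path(out, "truth_spots.tsv"))
  expect_identical(nrow(genes), 15L)
  expect_identical(nrow(spots), nrow(geom))
  expect_true(all(abs(spots$t_true - (1 - spots$r)) < 1e-12))
})
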