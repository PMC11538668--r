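test_that("filter_genes applies strict count and inclusive spot thresholds", {
  # gene A: count 11 in exactly 200 spots -> kept (boundary)
  # gene B: count 10 in 1000 spots -> dropped ("over 10" is strict)
  n <- 1000L
  counts <- rbind(A = c(rep(11L, 200L), rep(0L, n - 200L)),
                  B = rep(10L, n))
  kept <- filter_genes(counts, min_count = 10, min_spots = 200)
  expect_identical(kept, "A")
})

test_that("filter_genes matches a brute-force scan on a 6-gene fixture", {
  set.seed(31)
  n <- 400L
  counts <- rbind(
    g1 = rep(11L, n),                           # always qualifies
    g2 = rep(10L, n),                           # never (strict >)
    g3 = c(rep(20L, 199L), rep(0L, n - 199L)),  # one spot short
    g4 = c(rep(20L, 200L), rep(0L, n - 200L)),  # exactly at the bound
    g5 = rpois(n, 10),
    g6 = rpois(n, 25))
  brute <- rownames(counts)[vapply(seq_len(nrow(counts)), function(g) {
    q <- 0L
    for (j in seq_len(n)) if (counts[g, j] > 10L) q <- q + 1L
    q >= 200L
  }, logical(1))]
  expect_identical(filter_genes(counts), brute)
  expect_true("g4" %in% brute && !"g3" %in% brute)
})

test_that("noiseless fits recover each model family exactly", {
  t <- seq(0, 1, length.out = 100)
  y <- 0.5 + 1 * t
  f <- fit_models(y, t)$poly2
  expect_equal(unlist(f$params), c(a = 0.5, b = 1, c = 0), tolerance = 1e-8)
  expect_lt(f$rss, 1e-12)

  yg <- 2 * exp(-(t - 0.4)^2 / (2 * 0.2^2))
  fg <- fit_models(yg, t)$gauss
  expect_equal(unlist(fg$params), c(h = 2, mu = 0.4, sigma = 0.2),
               tolerance = 1e-6)
  expect_lt(fg$rss, 1e-12)

  fc <- fit_models(rep(3, 20), seq(0, 1, length.out = 20))$poly2
  expect_equal(unlist(fc$params), c(a = 3, b = 0, c = 0), tolerance = 1e-8)
  expect_equal(normalized_range(fc), 0)

  expect_error(fit_models(1:5, seq(0, 1, length.out = 5)), "8 points")
  expect_error(fit_models(1:8, rep(0.5, 8)), "identical")
})

test_that("normalized_range matches closed forms", {
  mk <- function(family, params)
    zonatlas:::new_fit(family, params, 0, 100, c(0, 1), TRUE)
  f <- mk("poly2", list(a = 0.5, b = 0.5, c = 0))
  expect_equal(normalized_range(f), 0.5)        # max 1.0, min 0.5
  g <- mk("gauss", list(h = 1, mu = 0.5, sigma = 0.15))
  expect_equal(normalized_range(g), 1 - exp(-0.5^2 / (2 * 0.15^2)),
               tolerance = 1e-6)
  flat <- mk("poly2", list(a = 0, b = 0, c = 0))
  expect_equal(normalized_range(flat), 0)       # zero maximum guard
})

test_that("normalized_range is scale-invariant", {
  t <- seq(0, 1, length.out = 50)
  y <- 1 + 2 * t + 0.5 * t^2
  for (c_scale in c(0.01, 1, 250)) {
    f <- fit_models(c_scale * y, t)$poly2
    expect_equal(normalized_range(f), normalized_range(fit_models(y, t)$poly2),
                 tolerance = 1e-8)
  }
})

test_that("select_model prefers low AIC and breaks ties toward poly2", {
  t <- seq(0, 1, length.out = 50)
  fits <- fit_models(2 * exp(-(t - 0.5)^2 / (2 * 0.1^2)), t)
  expect_identical(select_model(fits)$family, "gauss")

  # exact tie: two identical fits under different names
  f1 <- zonatlas:::new_fit("poly2", list(a = 1, b = 1, c = 0), 1, 20, c(0, 1),
                           TRUE)
  f2 <- zonatlas:::new_fit("gauss", list(h = 1, mu = 0.5, sigma = 1),
                           1 * exp(0), 20, c(0, 1), TRUE)
  f3 <- zonatlas:::new_fit("inv_gauss",
                           list(C = 1, h = 0.5, mu = 0.5, sigma = 1), 5, 20,
                           c(0, 1), TRUE)
  f2$rss <- f1$rss                              # identical rss, same k
  expect_identical(select_model(list(poly2 = f1, gauss = f2,
                                     inv_gauss = f3))$family, "poly2")

  # only one converged candidate
  f1$converged <- FALSE; f3$converged <- FALSE
  expect_identical(select_model(list(poly2 = f1, gauss = f2,
                                     inv_gauss = f3))$family, "gauss")
  f2$converged <- FALSE
  expect_null(select_model(list(poly2 = f1, gauss = f2, inv_gauss = f3)))
})

test_that("classify_gene follows the normalized-range and argmax rules", {
  t <- seq(0, 1, length.out = 50)
  # weak zonation below the cutoff
  weak <- fit_models(1 + 0.05 * t, t)
  expect_lt(normalized_range(select_model(weak)), 0.1)
  expect_identical(classify_gene(select_model(weak)), "non_zonated")
  # increasing profile on oriented t -> pericentral
  inc <- select_model(fit_models(0.5 + 2 * t, t))
  expect_identical(classify_gene(inc), "pericentral")
  # decreasing -> periportal
  dec <- select_model(fit_models(2.5 - 2 * t, t))
  expect_identical(classify_gene(dec), "periportal")
  # interior Gaussian peak -> midzonal
  mid <- select_model(fit_models(2 * exp(-(t - 0.5)^2 / (2 * 0.15^2)), t))
  expect_identical(classify_gene(mid), "midzonal")
  # interior trough with elevated poles -> bipolar
  bp <- select_model(fit_models(2 - 1.5 * exp(-(t - 0.5)^2 / (2 * 0.12^2)), t))
  expect_identical(classify_gene(bp), "bipolar")
  # unclassifiable gene (no converged fit) -> non_zonated
  expect_identical(classify_gene(NULL), "non_zonated")
})

test_that("classification is label-equivariant under axis flip", {
  t <- seq(0, 1, length.out = 60)
  profiles <- list(
    periportal = 2.5 - 2 * t,
    pericentral = 0.5 + 2 * t,
    midzonal = 2 * exp(-(t - 0.45)^2 / (2 * 0.12^2)),
    bipolar = 2 - 1.5 * exp(-(t - 0.55)^2 / (2 * 0.12^2)),
    non_zonated = rep(1.5, length(t)))
  swap <- c(periportal = "pericentral", pericentral = "periportal",
            midzonal = "midzonal", bipolar = "bipolar",
            non_zonated = "non_zonated")
  for (nm in names(profiles)) {
    y <- profiles[[nm]]
    lab <- classify_gene(select_model(fit_models(y, t)))
    lab_flipped <- classify_gene(select_model(fit_models(y, 1 - t)))
    expect_identical(lab, nm)
    expect_identical(lab_flipped, unname(swap[nm]))
  }
})

test_that("transition tables cross-tabulate and conserve marginals", {
  a <- c(g1 = "periportal", g2 = "periportal", g3 = "midzonal")
  b <- c(g1 = "periportal", g2 = "non_zonated", g3 = "midzonal")
  tt <- transition_table(a, b)
  expect_identical(tt["periportal", "periportal"], 1L)
  expect_identical(tt["periportal", "non_zonated"], 1L)
  expect_identical(tt["midzonal", "midzonal"], 1L)
  expect_identical(sum(tt), 3L)
  expect_identical(attr(tt, "genes")[["periportal", "non_zonated"]], "g2")

  # identical vectors -> diagonal
  td <- transition_table(a, a)
  expect_identical(sum(td) - sum(diag(td)), 0L)

  # marginals equal per-condition label counts on shared genes
  set.seed(41)
  levs <- c("periportal", "pericentral", "midzonal", "bipolar", "non_zonated")
  la <- setNames(sample(levs, 200, TRUE), sprintf("g%03d", 1:200))
  lb <- setNames(sample(levs, 180, TRUE), sprintf("g%03d", 21:200))
  tm <- transition_table(la, lb)
  shared <- intersect(names(la), names(lb))
  expect_identical(sum(tm), length(shared))
  expect_equal(rowSums(tm),
               table(factor(la[shared], levels = levs))[levs],
               ignore_attr = TRUE)
  expect_equal(colSums(tm),
               table(factor(lb[shared], levels = levs))[levs],
               ignore_attr = TRUE)

  expect_error(transition_table(c(x = "midzonal"), c(y = "midzonal")),
               "share no genes")
})

test_that("classify_all is deterministic and respects per-condition filters", {
  geom <- make_lobule_geometry(1, 260, seed = 50)
  panel <- default_gene_panel(10, seed = 50)
  ds <- merge_conditions(
    list(simulate_counts(geom, panel, "ctrl", seed = 51,
                         erythroid_fraction = 0)$dataset,
         simulate_counts(geom, panel, "fasted", seed = 52,
                         erythroid_fraction = 0)$dataset),
    c("ctrl", "fasted"))
  norm <- normalize_log(ds)
  truth <- simulate_counts(geom, panel, "ctrl", seed = 51)$truth$spots
  tt <- c(setNames(truth$t_true, paste0(truth$barcode, "_ctrl")),
          setNames(truth$t_true, paste0(truth$barcode, "_fasted")))
  ax <- structure(list(t = tt, orientation_applied = TRUE),
                  class = "pseudotime_axis")
  l1 <- classify_all(ds, ax, norm = norm, min_spots = 150)
  l2 <- classify_all(ds, ax, norm = norm, min_spots = 150)
  expect_identical(l1, l2)
  expect_setequal(unique(l1$condition), c("ctrl", "fasted"))
  # unoriented axis is rejected
  ax_raw <- ax; ax_raw$orientation_applied <- FALSE
  expect_error(classify_all(ds, ax_raw, norm = norm), "oriented")
})
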