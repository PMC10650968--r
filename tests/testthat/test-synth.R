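test_that("generate_layout: determinism, zero case, fit error, fibrosis count", {
  a <- generate_layout(256, 256, 0.5, cell_length_um = 60,
                       fibrosis_fraction = 0.1, seed = 41)
  b <- generate_layout(256, 256, 0.5, cell_length_um = 60,
                       fibrosis_fraction = 0.1, seed = 41)
  expect_identical(a$label, b$label)
  expect_identical(a$fibrotic, b$fibrotic)
  z <- generate_layout(256, 256, 0.5, cell_length_um = 60,
                       fibrosis_fraction = 0, seed = 41)
  expect_false(any(z$fibrotic))
  expect_error(generate_layout(128, 128, 0.5, cell_length_um = 100,
                               seed = 1), "cell does not fit")
  # realized fibrotic-patch fraction within 1 pp of request (direct count)
  lay <- generate_layout(1024, 1024, 0.5, fibrosis_fraction = 0.19, seed = 42)
  frac <- sum(lay$fibrotic) / length(lay$fibrotic)
  expect_true(frac >= 0.18 && frac <= 0.20)
  expect_equal(lay$realized_patch_fraction, frac)
  # cells have positive area and do not overlap fibrotic patches
  expect_true(all(lay$cells$area_px > 0))
  expect_false(any(lay$fibrotic & lay$label > 0))
})

test_that("render_sample: exact budgets, zero-lateral case, determinism", {
  lay <- generate_layout(512, 512, 0.5, fibrosis_fraction = 0.05, seed = 43)
  gt <- ground_truth(cx43_fraction_pct = 2.73, lateral_fraction_pct = 0,
                     seed = 44)
  smp <- render_sample(lay, gt)
  # noise-free masks are the generation masks; budget is exact
  n_cell <- sum(lay$label > 0)
  expect_equal(sum(smp$masks$cx43), round(0.0273 * n_cell))
  expect_equal(smp$realized$cx43_fraction_pct,
               100 * sum(smp$masks$cx43) / sum(smp$masks$serca2))
  # lateral fraction 0: no CX43 pixel in any cell's middle-half band
  for (i in seq_len(nrow(lay$cells))) {
    cl <- lay$cells[i, ]
    idx <- which(smp$masks$cx43 & lay$label == cl$id)
    if (!length(idx)) next
    y <- ((idx - 1L) %% 512L) + 1L
    x <- ((idx - 1L) %/% 512L) + 1L
    th <- cl$angle_deg * pi / 180
    u <- (x - cl$cx_px) * cos(th) + (y - cl$cy_px) * sin(th)
    expect_true(all(abs(u) > cl$half_len_px / 2))
  }
  # same gt seed -> identical channels
  smp2 <- render_sample(lay, gt)
  expect_identical(smp$channels$cx43, smp2$channels$cx43)
  # infeasible budget errors
  expect_error(render_sample(lay, ground_truth(cx43_fraction_pct = 90,
                                               seed = 44)),
               "CX43 budget infeasible")
})

test_that("parameter recovery: CX43 fraction Spearman >= 0.95 over 20 samples", {
  set.seed(45)
  truth <- seq(0.5, 5.3, length.out = 20)
  lay <- generate_layout(384, 384, 0.5, cell_length_um = 80,
                         fibrosis_fraction = 0.03, seed = 46)
  meas <- vapply(seq_along(truth), function(i) {
    gt <- ground_truth(cx43_fraction_pct = truth[i], seed = 400 + i)
    quantify_sample(render_sample(lay, gt))$pct_cx43_cm
  }, numeric(1))
  expect_gte(spearman(truth, meas)$rho, 0.95)
  # absolute recovery at the population median
  gt <- ground_truth(cx43_fraction_pct = 2.73, seed = 47)
  q <- quantify_sample(render_sample(lay, gt))
  expect_lt(abs(q$pct_cx43_cm - 2.73), 0.15)
})

test_that("lateralization recovery is monotone over {0,10,20,30,40}", {
  lay <- generate_layout(512, 512, 0.5, fibrosis_fraction = 0, seed = 11)
  vals <- vapply(c(0, 10, 20, 30, 40), function(lf) {
    gt <- ground_truth(lateral_fraction_pct = lf, seed = 21)
    quantify_sample(render_sample(lay, gt))$pct_lateral
  }, numeric(1))
  expect_false(is.unsorted(vals))
  expect_lt(abs(vals[1]), 1e-9)
})

test_that("heterogeneity knob strictly increases measured CX43_H on average", {
  lay <- generate_layout(512, 512, 0.5, fibrosis_fraction = 0, seed = 11)
  hs <- c(0.15, 0.5, 0.85)
  het <- vapply(hs, function(h) {
    mean(vapply(1:10, function(s) {
      gt <- ground_truth(cx43_clustering = h, seed = 100 + s)
      quantify_sample(render_sample(lay, gt))$heterogeneity_um
    }, numeric(1)))
  }, numeric(1))
  expect_lt(het[1], het[2])
  expect_lt(het[2], het[3])
})

test_that("fibrosis recovery within 1.5 pp on noise-free renders", {
  for (pf in c(0.02, 0.1, 0.16)) {
    lay <- generate_layout(384, 384, 0.5, fibrosis_fraction = pf,
                           seed = round(100 * pf))
    gt <- ground_truth(seed = 48)
    smp <- render_sample(lay, gt)
    q <- quantify_sample(smp)
    expect_lte(abs(q$pct_fibrosis - smp$realized$fibrosis_pct), 1.5)
  }
})

test_that("ground_truth validates its ranges", {
  expect_error(ground_truth(cx43_fraction_pct = -1), "0")
  expect_error(ground_truth(cx43_clustering = 1.5), "clustering")
  gt <- ground_truth(seed = 1)
  expect_s3_class(gt, "ground_truth")
})

test_that("generate_cohort: determinism, table shape, bounded draws", {
  co1 <- generate_cohort(n = 3, seed = 51, width_px = 256, height_px = 256)
  co2 <- generate_cohort(n = 3, seed = 51, width_px = 256, height_px = 256)
  expect_identical(co1$table, co2$table)
  expect_equal(nrow(co1$table), 3)
  expect_length(co1$samples, 3)
  expect_true(all(co1$table$age >= 50 & co1$table$age <= 84))
  expect_true(all(co1$table$cx43_fraction_pct >= 0.44 &
                    co1$table$cx43_fraction_pct <= 5.34))
  # unbounded custom distribution rejected
  bad <- list(lipofuscin_pct = list(range = c(0, Inf),
                                    sample = function(n, age) rexp(n)))
  expect_error(generate_cohort(n = 2, parameter_distributions = bad,
                               seed = 1), "finite range")
  # single sample cohort
  co3 <- generate_cohort(n = 1, seed = 52, width_px = 256, height_px = 256)
  expect_equal(nrow(co3$table), 1)
})

test_that("cohort writing round-trips through TIFF and CSV", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(n = 2, seed = 53, width_px = 256, height_px = 256,
                        out_dir = dir)
  expect_null(co$samples)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_length(tifs, 10)  # 2 samples x 5 channels
  paths <- file.path(dir, paste0("sample_001_",
                                 c("serca2", "wga", "cx43", "lipofuscin",
                                   "autofluorescence"), ".tif"))
  names(paths) <- c("serca2", "wga", "cx43", "lipofuscin",
                    "autofluorescence")
  smp <- read_histology_sample(paths, pixel_size_um = 0.5)
  expect_s3_class(smp, "histology_sample")
  expect_equal(dim(smp$channels$cx43), c(256, 256))
  q <- quantify_sample(smp, masks = "otsu")
  expect_true(is.finite(q$pct_cx43_cm))
})

test_that("quantify_sample returns the canonical metric columns", {
  lay <- generate_layout(384, 384, 0.5, fibrosis_fraction = 0.05, seed = 54)
  gt <- ground_truth(seed = 55)
  smp <- render_sample(lay, gt, noise_sd = 200)
  q <- quantify_sample(smp, masks = "otsu")
  expect_named(q, c("pct_cx43_cm", "pct_cx43_t", "expr_cm", "expr_t",
                    "heterogeneity_um", "pct_lateral", "pct_fibrosis",
                    "pct_lipofuscin"))
  prov <- attr(q, "provenance")
  expect_equal(prov$mask_source, "otsu")
  expect_true(all(c("cx43", "serca2") %in% names(prov$thresholds)))
  expect_lte(q$pct_cx43_t, q$pct_cx43_cm)
  # metrics CSV + provenance sidecar
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics(q, f, provenance = prov)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".json")))
  back <- read.csv(f)
  expect_equal(back$pct_fibrosis, q$pct_fibrosis)
})
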