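test_that("build_mesh geometry: grid size, islands, protected strip", {
  m <- build_mesh(3, dx_cm = 0.025, seed = 1)
  expect_equal(dim(m$celltype), c(121, 121))
  # independent geometric oracle for the mid-island mask
  xs <- (0:120) * 0.025
  mid <- matrix(FALSE, 121, 121)
  for (k in 1:3) {
    cx <- c(0.25, 0.60, 0.75)[k] * 3
    cy <- c(0.70, 0.30, 0.75)[k] * 3
    d2 <- outer((xs - cy)^2, (xs - cx)^2, `+`)  # rows = y, cols = x
    mid <- mid | (d2 <= 0.45^2)
  }
  expect_identical(m$celltype == 1L, mid)
  # protected stimulus strip: left 0.5 cm = 20 columns
  expect_true(all(m$protected[, 1:20]))
  expect_false(any(m$protected[, 21:121]))
  expect_equal(m$DL[60, 60], 0.0013)
  expect_equal(m$ratio, 0.19)
  # no-island and custom-island variants
  m0 <- build_mesh(3, islands = NULL)
  expect_true(all(m0$celltype == 0L))
  bad <- data.frame(x_frac = c(0.4, 0.5), y_frac = c(0.5, 0.5),
                    r_cm = c(0.3, 0.3))
  expect_error(build_mesh(3, islands = bad), "overlapping islands")
  expect_error(build_mesh(3, dx_cm = 0.07), "divide")
})

test_that("5-cm mesh is the rescaled 3-cm layout", {
  m3 <- build_mesh(3)
  m5 <- build_mesh(5)
  expect_equal(dim(m5$celltype), c(201, 201))
  expect_equal(m5$islands$r_cm, rep(0.75, 3))
  expect_equal(m5$islands$x_frac, m3$islands$x_frac)
  # mid area fraction is scale-invariant up to rasterization
  f3 <- mean(m3$celltype == 1L)
  f5 <- mean(m5$celltype == 1L)
  expect_lt(abs(f3 - f5), 0.005)
  # rasterization error is bounded by the perimeter band: 3*2*pi*r*dx/A
  expect_lt(abs(f3 - 3 * pi * 0.15^2), 0.01)
})

test_that("conductivity scenarios hit the closed forms exactly", {
  m <- build_mesh(3)
  S0 <- 0.0013 * 1.19
  # DIF 40, conserved sum
  d40 <- set_conductivity_scenario(m, dif_reduction_pct = 40)
  expect_equal(d40$DL[1, 1], 0.00078)
  expect_true(all(abs(d40$DL * (1 + d40$ratio) - S0 * 0.6) < 1e-15))
  # LAT 0.35, conserved sum: D_L + D_T invariant vs control
  l35 <- set_conductivity_scenario(m, lat_ratio = 0.35)
  expect_equal(l35$DL[1, 1] * (1 + 0.35), S0, tolerance = 1e-12)
  expect_lt(l35$DL[1, 1], 0.0013)          # sum shifts toward transverse
  expect_gt(l35$DL[1, 1] * 0.35, 0.0013 * 0.19)
  # without conservation D_L scales directly
  d10 <- set_conductivity_scenario(m, dif_reduction_pct = 10,
                                   conserve_sum = FALSE)
  expect_equal(d10$DL[1, 1], 0.0013 * 0.9)
  expect_equal(d10$ratio, 0.19)
  expect_error(set_conductivity_scenario(m, dif_reduction_pct = 95), "90")
  expect_error(set_conductivity_scenario(m, lat_ratio = 0), "lat_ratio")
})

test_that("assign_fibrosis converts the exact count outside the strip", {
  m <- build_mesh(3, seed = 5)
  f <- assign_fibrosis(m, 19)
  n_elig <- sum(!m$protected)            # all nodes eligible except strip
  expect_equal(sum(f$celltype == 2L), round(0.19 * n_elig))
  expect_false(any(f$celltype[, 1:20] == 2L))
  # determinism and zero case
  f2 <- assign_fibrosis(m, 19)
  expect_identical(f$celltype, f2$celltype)
  expect_false(identical(f$celltype,
                         assign_fibrosis(m, 19, seed = 6)$celltype))
  expect_identical(assign_fibrosis(m, 0)$celltype, m$celltype)
  # non-fibroblast identity of untouched nodes is preserved
  conv <- f$celltype == 2L & m$celltype != 2L
  expect_identical(f$celltype[!conv], m$celltype[!conv])
  expect_error(assign_fibrosis(m, 101), "100")
})

test_that("assign_heterogeneity: two-level image maps to two D_L levels", {
  m <- build_mesh(3, islands = NULL, seed = 7)
  # image: 30% zeros, 70% twos -> bins 1 and 20 of [0,2], centers 0.05, 1.95;
  # the median (2) bin maps to the control D_L before global rescale
  img <- matrix(rep(c(0, 2), times = c(300, 700)), 25, 40)
  h <- assign_heterogeneity(m, img, seed = 7)
  u <- sort(unique(as.vector(h$DL)))
  expect_length(u, 2)
  expect_equal(u[1] / u[2], 0.05 / 1.95, tolerance = 1e-12)
  # node apportionment follows the image bin occupancies (largest remainder)
  N <- length(m$DL)
  expect_equal(sum(h$DL == u[1]), floor(0.3 * N))
  expect_equal(sum(h$DL == u[2]), N - floor(0.3 * N))
  # summed D_L conserved exactly
  expect_equal(sum(h$DL), sum(m$DL), tolerance = 1e-10)
})

test_that("assign_heterogeneity: conservation, permutation, degeneracy", {
  m <- build_mesh(3, seed = 8)
  set.seed(12)
  img <- matrix(rgamma(5000, 2, 1 / 50), 50, 100)
  h1 <- assign_heterogeneity(m, img, seed = 8)
  expect_equal(sum(h1$DL), sum(m$DL), tolerance = 1e-10)
  expect_gt(stats::sd(h1$DL), 0)
  # different seeds permute the same multiset of values
  h2 <- assign_heterogeneity(m, img, seed = 9)
  expect_equal(sort(as.vector(h1$DL)), sort(as.vector(h2$DL)),
               tolerance = 1e-12)
  expect_false(identical(h1$DL, h2$DL))
  # same seed is reproducible
  expect_identical(h1$DL, assign_heterogeneity(m, img, seed = 8)$DL)
  expect_error(assign_heterogeneity(m, matrix(3, 5, 5)),
               "degenerate histogram")
})

test_that("meshes round-trip through write_mesh/read_mesh", {
  m <- assign_fibrosis(set_conductivity_scenario(build_mesh(3, seed = 9),
                                                 dif_reduction_pct = 10),
                       7)
  p <- withr::local_tempfile(fileext = ".rds")
  write_mesh(m, p)
  back <- read_mesh(p)
  expect_identical(back$celltype, m$celltype)
  expect_identical(back$DL, m$DL)
  expect_identical(back$scenario, m$scenario)
  # non-mesh content is rejected
  saveRDS(list(a = 1), p, version = 3)
  expect_error(read_mesh(p), "mesh")
})

test_that("build_cable is a single protected-edge row", {
  cb <- build_cable(3, 0.025)
  expect_equal(dim(cb$celltype), c(1, 121))
  expect_true(all(cb$protected[1, 1:20]))
  expect_equal(cb$DL[1, 1], 0.0013)
  # tidy/autoplot interfaces on meshes
  td <- generics::tidy(build_mesh(3, seed = 1))
  expect_true(all(c("row", "col", "celltype", "DL") %in% names(td)))
  expect_equal(nrow(td), 121^2)
  expect_s3_class(ggplot2::autoplot(build_mesh(3, seed = 1)), "ggplot")
})
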