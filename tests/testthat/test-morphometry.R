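# Brute-force O(n^2) nearest-neighbour oracle, independent of the package's
# spatial-grid C++ implementation.
oracle_nn_sd <- function(mask, pixel_size_um, pop = FALSE) {
  w <- which(mask, arr.ind = TRUE)
  n <- nrow(w)
  d <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt((w[, 1] - w[i, 1])^2 + (w[, 2] - w[i, 2])^2)
    d[i] <- min(dd[-i])
  }
  if (pop) sqrt(mean((d - mean(d))^2)) * pixel_size_um
  else sd(d) * pixel_size_um
}

mk <- function(nr, nc, ones = integer()) {
  m <- matrix(FALSE, nr, nc); m[ones] <- TRUE; m
}

test_that("preprocess_channel saturates per mode", {
  img <- matrix(c(0, 1000, 4000, 2000), 2, 2)
  out <- preprocess_channel(img, "fixed_window", window = c(0, 3500))
  expect_equal(out[3], 3500)
  expect_equal(out[c(1, 2, 4)], img[c(1, 2, 4)])
  expect_error(preprocess_channel(img, "fixed_window", window = c(10, 10)),
               "lo")
  # 0.2% clip on a 1000-pixel ramp 0..999: pixels <=1 and >=998 saturate
  ramp <- matrix(0:999, 25, 40)
  cl <- preprocess_channel(ramp, "percentile_clip", clip_fraction = 0.002)
  lo <- quantile(0:999, 0.002, names = FALSE)
  hi <- quantile(0:999, 0.998, names = FALSE)
  expect_equal(min(cl), lo)
  expect_equal(max(cl), hi)
  expect_equal(sum(cl == lo), sum(0:999 <= lo))   # 0 and 1 saturated
  expect_equal(sum(cl == hi), sum(0:999 >= hi))   # 998 and 999 saturated
  expect_equal(cl[ramp > lo & ramp < hi], ramp[ramp > lo & ramp < hi])
  # constant image unchanged
  cst <- matrix(5, 3, 3)
  expect_equal(preprocess_channel(cst, "percentile_clip"), cst)
  expect_equal(preprocess_channel(img, "none"), img)
})

test_that("binarize is strict > with recorded threshold; otsu separates", {
  img <- matrix(c(50, 150), 2, 2)
  m <- binarize(img, "fixed", threshold = 100)
  expect_equal(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(m, "threshold"), 100)
  expect_false(any(binarize(img, "fixed", threshold = 150)))  # strict >
  expect_error(binarize(matrix(7, 3, 3), "otsu"), "degenerate histogram")
  set.seed(8)
  truth <- matrix(runif(10000) < 0.4, 100, 100)
  img2 <- matrix(rnorm(10000, ifelse(truth, 800, 200), 20), 100, 100)
  m2 <- binarize(img2, "otsu")
  expect_gte(mean(m2 == truth), 0.999)
})

test_that("refine_cx43_mask: identity, isolated-pixel removal, hole filling", {
  m <- mk(9, 9, c(41, 5))
  expect_equal(refine_cx43_mask(m, 0, 0), m)
  single <- mk(9, 9, 41)
  expect_false(any(refine_cx43_mask(single, 1, 0)))
  # 3x3 square with a centre hole: closing fills it; verify against a
  # brute-force dilation-then-erosion with the same 4-neighbour disk
  sq <- matrix(FALSE, 9, 9); sq[4:6, 4:6] <- TRUE; sq[5, 5] <- FALSE
  closed <- refine_cx43_mask(sq, 0, 1)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  dil <- function(m) {
    acc <- m
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      acc <- acc | shift(m, d[1], d[2])
    acc
  }
  ero <- function(m) {
    acc <- m
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      acc <- acc & shift(m, d[1], d[2])
    acc
  }
  expect_equal(closed, ero(dil(sq)))
  expect_true(closed[5, 5])
})

test_that("cx43_amount matches pixel-count oracles", {
  serca <- mk(10, 10, 1:48)
  cx <- mk(10, 10, 1:12)
  expect_equal(cx43_amount(cx, serca, denom = "cm"), 12 * 100 / 48)
  expect_equal(cx43_amount(mk(10, 10), serca, denom = "cm"), 0)
  # |SERCA2|=80, |WGA|=40, overlap=20, |CX43|=10 -> 10*100/100
  serca2 <- mk(12, 12, 1:80)
  wga <- mk(12, 12, 61:100)
  cx2 <- mk(12, 12, 1:10)
  expect_equal(cx43_amount(cx2, serca2, wga, denom = "tissue"), 10)
  expect_error(cx43_amount(cx2, mk(12, 12), denom = "cm"),
               "no tissue detected")
  # tissue denom <= cm denom when WGA adds pixels; equal when WGA subset
  expect_lte(cx43_amount(cx2, serca2, wga, denom = "tissue"),
             cx43_amount(cx2, serca2, denom = "cm"))
  wga_sub <- mk(12, 12, 1:20)
  expect_equal(cx43_amount(cx2, serca2, wga_sub, denom = "tissue"),
               cx43_amount(cx2, serca2, denom = "cm"))
})

test_that("cx43_expression matches the arithmetic oracle and is linear", {
  img <- matrix(0, 6, 6)
  img[1:3] <- c(100, 200, 300)
  cx <- mk(6, 6, 1:3)
  serca <- mk(6, 6, 1:6)
  expect_equal(cx43_expression(img, cx, serca, denom = "cm"), 100)
  expect_equal(cx43_expression(2 * img, cx, serca, denom = "cm"), 200)
  expect_equal(cx43_expression(img, mk(6, 6), serca, denom = "cm"), 0)
})

test_that("cx43_heterogeneity equals the O(n^2) brute-force oracle", {
  # two positive pixels anywhere -> SD 0
  expect_equal(cx43_heterogeneity(mk(8, 8, c(3, 60)), 1), 0)
  # collinear pixels x = 0,1,3 -> NN {1,1,2}, sample SD = 0.5774
  col3 <- mk(1, 5, c(1, 2, 4))
  expect_equal(cx43_heterogeneity(col3, 1), sd(c(1, 1, 2)), tolerance = 1e-9)
  expect_equal(round(cx43_heterogeneity(col3, 1), 4), 0.5774)
  # dense grid -> all distances 1 -> SD 0
  expect_equal(cx43_heterogeneity(matrix(TRUE, 5, 7), 1), 0)
  expect_error(cx43_heterogeneity(mk(5, 5, 3), 1), "heterogeneity undefined")
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(3000) < 0.05, 60, 50)
    if (sum(m) < 2) next
    expect_equal(cx43_heterogeneity(m, 0.5), oracle_nn_sd(m, 0.5),
                 tolerance = 1e-9)
  }
  # population SD option
  m <- mk(10, 10, c(1, 2, 35, 77))
  expect_equal(cx43_heterogeneity(m, 2, sd_type = "population"),
               oracle_nn_sd(m, 2, pop = TRUE), tolerance = 1e-9)
})

test_that("fibrosis and lipofuscin match counting oracles", {
  serca <- mk(10, 10, 1:60)
  wga_in <- mk(10, 10, 11:30)
  expect_equal(fibrosis_percent(wga_in, serca), 0)  # WGA subset of SERCA2
  serca_b <- mk(10, 10, 1:81)
  wga <- mk(10, 10, 75:100)  # 19 px outside SERCA2, union = 100
  expect_equal(fibrosis_percent(wga, serca_b), 19)
  expect_equal(fibrosis_percent(wga, mk(10, 10)), 100)
  expect_error(fibrosis_percent(mk(2, 2), mk(2, 2)), "no tissue")
  # union partition conservation for disjoint masks
  s2 <- mk(10, 10, 1:40); w2 <- mk(10, 10, 41:100)
  expect_equal(fibrosis_percent(w2, s2) + 100 * sum(s2) / sum(s2 | w2), 100)

  auto <- mk(25, 20, 1:500)
  lipo <- mk(25, 20, 1:5)
  expect_equal(lipofuscin_percent(lipo, auto), 1)
  expect_equal(lipofuscin_percent(mk(25, 20), auto), 0)
  expect_equal(lipofuscin_percent(auto, auto), 100)
  expect_error(lipofuscin_percent(lipo, mk(25, 20)), "no tissue")
})

test_that("ratio metrics are invariant under translation and 90-degree rotation", {
  set.seed(10)
  serca <- matrix(runif(900) < 0.5, 30, 30)
  wga <- matrix(runif(900) < 0.3, 30, 30)
  cx <- serca & matrix(runif(900) < 0.2, 30, 30)
  if (sum(cx) < 2) cx[1:2] <- TRUE
  pad <- function(m) rbind(matrix(FALSE, 5, ncol(m) + 5),
                           cbind(matrix(FALSE, nrow(m), 5), m))
  rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  for (f in list(pad, rot)) {
    expect_equal(cx43_amount(f(cx), f(serca), f(wga), denom = "tissue"),
                 cx43_amount(cx, serca, wga, denom = "tissue"))
    expect_equal(fibrosis_percent(f(wga), f(serca)),
                 fibrosis_percent(wga, serca))
    expect_equal(cx43_heterogeneity(f(cx), 0.7),
                 cx43_heterogeneity(cx, 0.7), tolerance = 1e-12)
  }
})
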