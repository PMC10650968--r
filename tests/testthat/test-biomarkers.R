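# closed-form trapezoidal AP: rest, instantaneous upstroke, linear descent
trap_ap <- function(n_rest = 10, v_rest = -85, v_peak = 30,
                    v_end = -90, n_desc = 301) {
  c(rep(v_rest, n_rest), seq(v_peak, v_end, length.out = n_desc))
}

test_that("apd90 matches the closed form on a trapezoidal AP", {
  vm <- trap_ap()
  # activation at the steepest-rise sample (t = 9 ms); level = 30 - 0.9*115;
  # descent slope 120/300 mV/ms from t = 10 ms
  level <- 30 - 0.9 * (30 - (-85))
  t_cross <- 10 + (30 - level) / (120 / 300)
  expect_equal(apd90(vm, dt_ms = 1), t_cross - 9, tolerance = 1e-9)
  # shift invariance: more diastole before the upstroke
  expect_equal(apd90(c(rep(-85, 40), vm), dt_ms = 1), apd90(vm, dt_ms = 1))
  # dt rescaling scales the result
  expect_equal(apd90(vm, dt_ms = 0.5), apd90(vm, dt_ms = 1) / 2)
})

test_that("apd90 rejects non-AP traces", {
  expect_error(apd90(rep(-85, 100), dt_ms = 1), "no AP detected")
  expect_error(apd90(c(rep(-85, 10), seq(-85, 30, length.out = 100)), 1),
               "no AP detected")   # never repolarizes
  expect_error(apd90(1, 1), "numeric trace")
  expect_error(apd90(trap_ap(), 0), "positive")
})

test_that("cv_field recovers planar waves exactly", {
  dx <- 0.025
  # axis-aligned plane at 60 cm/s
  tm <- outer(rep(1, 21), (0:20) * dx / 0.06)
  f <- cv_field(tm, dx)
  expect_equal(f$cv_median, 60, tolerance = 1e-9)
  inner <- f$speed[3:19, 3:19]
  expect_true(all(abs(inner - 60) < 1e-6))
  expect_true(all(abs(f$vx[3:19, 3:19] - 60) < 1e-6))
  expect_true(all(abs(f$vy[3:19, 3:19]) < 1e-6))
  # tilted plane: T = (x cos a + y sin a) / v, any window, still exact
  a <- 30 * pi / 180; v <- 0.045   # cm/ms
  xs <- (0:20) * dx
  tm2 <- outer(xs * sin(a), xs * cos(a), `+`) / v
  f2 <- cv_field(tm2, dx, fit_window_nodes = 3)
  expect_equal(f2$cv_median, 1000 * v, tolerance = 1e-9)
  expect_equal(f2$vx[10, 10], 1000 * v * cos(a), tolerance = 1e-6)
  expect_equal(f2$vy[10, 10], 1000 * v * sin(a), tolerance = 1e-6)
})

test_that("cv_field: cable mode, NA handling, exclusions, errors", {
  dx <- 0.025
  tm <- matrix((0:60) * dx / 0.0597, 1)
  expect_equal(cv_field(tm, dx)$cv_median, 59.7, tolerance = 1e-9)
  # simultaneous activation (stimulus strip) is singular, not infinite
  tm2 <- outer(rep(1, 21), c(rep(0, 5), (1:16) * dx / 0.06))
  f <- cv_field(tm2, dx)
  expect_gt(f$n_singular, 0)
  expect_true(all(is.finite(f$speed[!is.na(f$speed)])))
  # excluding the strip moves the median onto the clean front
  excl <- matrix(FALSE, 21, 21); excl[, 1:8] <- TRUE
  expect_equal(cv_field(tm2, dx, exclude = excl)$cv_median, 60,
               tolerance = 1e-6)
  # NA holes: fit proceeds when enough points remain
  tm3 <- outer(rep(1, 21), (0:20) * dx / 0.06)
  tm3[10, 10] <- NA
  f3 <- cv_field(tm3, dx)
  expect_equal(f3$speed[12, 12], 60, tolerance = 1e-6)
  expect_error(cv_field(tm3, dx, fit_window_nodes = 4), "odd")
  expect_error(cv_field(matrix(0, 3, 3), dx), "smaller than the fit window")
  expect_error(cv_field(tm3, -1), "positive")
})

test_that("repolarization gradient and HRG area match ramp closed forms", {
  dx <- 0.025
  xs <- (0:20) * dx
  g_cm <- 120                      # ms/cm along x
  Tm <- outer(rep(0, 21), xs * g_cm, `+`)
  G <- repol_gradient_map(Tm, dx)
  expect_true(all(is.na(G[, 1]) & is.na(G[, 21])))
  expect_true(all(abs(G[2:20, 2:20] - g_cm / 10) < 1e-9))
  expect_equal(hrg_area(G, threshold = 9), 100)    # 12 ms/mm everywhere
  expect_equal(hrg_area(G, threshold = 12 + 1e-6), 0)  # strict >
  # diagonal ramp: magnitude combines the two components
  Tm2 <- outer(xs * 30, xs * 40, `+`)
  G2 <- repol_gradient_map(Tm2, dx)
  expect_equal(G2[10, 10], 5, tolerance = 1e-9)    # sqrt(3^2+4^2) ms/mm
  # piecewise ramp: 2 ms/mm on the left half, 20 ms/mm on the right half
  tv <- c(0, cumsum(c(rep(20 * dx, 10), rep(200 * dx, 10))))
  Tm3 <- outer(rep(0, 21), tv, `+`)
  G3 <- repol_gradient_map(Tm3, dx)
  h1 <- hrg_area(G3, 9)
  expect_gt(h1, 0); expect_lt(h1, 100)
  expect_gte(h1, hrg_area(G3, 15))                 # monotone in threshold
  expect_error(hrg_area(matrix(NA_real_, 3, 3)), "no valid")
  expect_error(repol_gradient_map(matrix(0, 2, 2), dx), "too small")
})

test_that("apd_map and tissue_mean_apd difference the solver maps", {
  res <- structure(list(act = matrix(c(10, 12, NA, 14), 2, 2),
                        repol = matrix(c(250, 260, NA, NA), 2, 2)),
                   class = "monodomain_result")
  m <- apd_map(res)
  expect_equal(m[1, 1], 240)
  expect_equal(m[2, 1], 248)
  expect_true(is.na(m[2, 2]))
  expect_equal(tissue_mean_apd(res), 244)
  res$repol <- matrix(NA_real_, 2, 2)
  expect_error(tissue_mean_apd(res), "no action potentials")
})

test_that("vulnerability_window counts the sustained block", {
  s2 <- seq(230, 330, by = 5)
  oc <- tibble::tibble(
    s2_ms = s2,
    outcome = ifelse(s2 >= 255 & s2 <= 300, "sustained_reentry",
                     ifelse(s2 < 255, "no_capture", "propagated_no_reentry")))
  vw <- vulnerability_window(oc)
  expect_equal(vw$vw_ms, 300 - 255 + 5)
  # no sustained timing -> 0
  oc0 <- oc; oc0$outcome <- "propagated_no_reentry"
  expect_equal(vulnerability_window(oc0)$vw_ms, 0)
  # the largest of two blocks wins
  oc2 <- oc
  oc2$outcome[oc2$s2_ms %in% c(235, 270)] <- c("sustained_reentry",
                                               "no_capture")
  expect_equal(vulnerability_window(oc2)$vw_ms, 300 - 275 + 5)
  # ratio against a baseline table and against a number
  expect_equal(vulnerability_window(oc, baseline = oc)$vw_ratio, 1)
  expect_equal(vulnerability_window(oc, baseline = 100)$vw_ratio, 0.5)
  expect_true(is.na(vulnerability_window(oc, baseline = 0)$vw_ratio))
  expect_error(vulnerability_window(oc[c(2, 1), ]), "sorted")
  expect_error(vulnerability_window(oc[1, ]), "one row")
  expect_error(vulnerability_window(tibble::tibble(x = 1)), "outcome")
})

test_that("detect_sustained_reentry classifies scripted activity", {
  mk_res <- function(bins, t_end = 2000, last_stim = 400) {
    list(upcross_bins = bins, upcross_bin_ms = 50, duration_ms = 2000,
         last_stim_end_ms = last_stim, t_end = t_end)
  }
  active <- rep(3, 40)
  expect_true(detect_sustained_reentry(mk_res(active)))
  # a silent chunk inside the final window breaks sustainment
  gap <- active; gap[37] <- 0; gap[38] <- 0
  expect_false(detect_sustained_reentry(mk_res(gap)))
  # early quiet-stop is never sustained
  expect_false(detect_sustained_reentry(mk_res(active, t_end = 1500)))
  # a stimulus inside the final window is a protocol error
  expect_error(detect_sustained_reentry(mk_res(active, last_stim = 1800)),
               "final window")
  expect_error(detect_sustained_reentry(list(duration_ms = 1)), "bins")
})
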