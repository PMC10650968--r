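# median front speed on a cable/mesh activation map, stimulus strip excluded
front_cv <- function(res, mesh) {
  cv_field(res$act, mesh$dx_cm, exclude = mesh$protected)$cv_median
}

run_cable <- function(dx, dt, dif_pct = 0, conserve = FALSE, amp = 100,
                      duration = 80, quiet_stop_ms = 0) {
  cb <- build_cable(1.5, dx)
  if (dif_pct > 0)
    cb <- set_conductivity_scenario(cb, dif_reduction_pct = dif_pct,
                                    conserve_sum = conserve)
  pr <- stimulus_protocol(cb, t_s1_ms = 10, n_s1 = 1, s1_amp = amp)
  list(mesh = cb,
       res = run_monodomain(cb, pr, dt_ms = dt, duration_ms = duration,
                            meas_start_ms = 0, quiet_stop_ms = quiet_stop_ms))
}

test_that("zero-amplitude stimulus leaves the tissue at rest", {
  cb <- build_cable(1.5, 0.025)
  pr <- stimulus_protocol(cb, t_s1_ms = 5, n_s1 = 1, s1_amp = 0)
  res <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 40,
                        meas_start_ms = 0)
  expect_true(all(is.na(res$act)))
  expect_equal(sum(res$upcross_count), 0)
  expect_true(all(res$v_final < -80))
})

test_that("whole-domain stimulus activates all nodes near-simultaneously", {
  cb <- build_cable(1.5, 0.025)
  pr <- stimulus_protocol(cb, t_s1_ms = 5, n_s1 = 1, s1_amp = 100,
                          s1_region = list(rows = c(1L, 1L),
                                           cols = c(1L, 61L)))
  res <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 40,
                        meas_start_ms = 0)
  expect_true(all(!is.na(res$act)))
  expect_lt(diff(range(res$act)), 1)
})

test_that("identical runs are bitwise identical", {
  a <- run_cable(0.025, 0.02, duration = 60)$res
  b <- run_cable(0.025, 0.02, duration = 60)$res
  expect_identical(a$act, b$act)
  expect_identical(a$repol, b$repol)
  expect_identical(a$v_final, b$v_final)
})

test_that("the CFL guard rejects unstable steps", {
  cb <- build_cable(1.5, 0.025)
  pr <- stimulus_protocol(cb, s1_amp = 100)
  expect_error(run_monodomain(cb, pr, dt_ms = 0.5), "stability limit")
})

test_that("diastolic threshold: propagation above, none just below", {
  cb <- build_cable(1.5, 0.025)
  thr <- find_diastolic_threshold(cb, td_ms = 2, dt_ms = 0.02)
  expect_gt(thr, 0)
  probe <- function(amp) {
    pr <- stimulus_protocol(cb, t_s1_ms = 2, s1_dur_ms = 2, n_s1 = 1,
                            s1_amp = amp)
    res <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 80,
                          meas_start_ms = 0)
    res$upcross_count[1, 55] > 0
  }
  expect_true(probe(thr))
  expect_false(probe(0.8 * thr))
})

test_that("cable CV scales as sqrt of the diffusion coefficient", {
  cv0 <- front_cv(run_cable(0.00625, 0.005)$res, build_cable(1.5, 0.00625))
  r40 <- run_cable(0.00625, 0.005, dif_pct = 40, conserve = FALSE,
                   duration = 100)
  cv40 <- front_cv(r40$res, r40$mesh)
  expect_lt(abs(cv40 / cv0 - sqrt(0.6)), 0.05 * sqrt(0.6))
})

test_that("cable CV converges under grid refinement", {
  cv_fine <- front_cv(run_cable(0.00625, 0.005)$res,
                      build_cable(1.5, 0.00625))
  cv_mid <- front_cv(run_cable(0.0125, 0.005)$res, build_cable(1.5, 0.0125))
  expect_lt(abs(cv_mid - cv_fine) / cv_fine, 0.05)
  # physiological magnitude on the converged grid
  expect_gt(cv_fine, 40)
  expect_lt(cv_fine, 80)
})

test_that("a transverse planar wave reduces to a ratio-scaled cable", {
  # with a planar top-edge stimulus the x-diffusion terms vanish node-wise,
  # so every column must evolve exactly like a 1D cable whose diffusion
  # coefficient is ratio * D_L -- this pins how the anisotropy ratio enters
  # the stencil
  m <- build_mesh(1, dx_cm = 0.025, islands = NULL)   # ratio 0.19
  d <- dim(m$celltype)
  depth <- as.integer(round(m$size_cm / 6 / m$dx_cm))
  prT <- stimulus_protocol(m, t_s1_ms = 5, n_s1 = 1, s1_amp = 100,
                           s1_region = list(rows = c(1L, depth),
                                            cols = c(1L, d[2])))
  resT <- run_monodomain(m, prT, dt_ms = 0.02, duration_ms = 90,
                         meas_start_ms = 0)
  cb <- build_cable(1, 0.025, baseline_DL = 0.19 * 0.0013)
  prC <- stimulus_protocol(cb, t_s1_ms = 5, n_s1 = 1, s1_amp = 100)
  resC <- run_monodomain(cb, prC, dt_ms = 0.02, duration_ms = 90,
                         meas_start_ms = 0)
  for (cc in c(1L, 21L, 41L))
    expect_equal(resT$act[, cc], as.vector(resC$act), tolerance = 1e-9)
  expect_equal(resT$repol[, 21], as.vector(resC$repol), tolerance = 1e-9)
})

test_that("an isotropic mesh is symmetric under transposition", {
  m <- build_mesh(1, dx_cm = 0.025, islands = NULL, baseline_ratio = 1)
  d <- dim(m$celltype)
  depth <- as.integer(round(m$size_cm / 6 / m$dx_cm))
  prL <- stimulus_protocol(m, t_s1_ms = 5, n_s1 = 1, s1_amp = 100)
  prT <- stimulus_protocol(m, t_s1_ms = 5, n_s1 = 1, s1_amp = 100,
                           s1_region = list(rows = c(1L, depth),
                                            cols = c(1L, d[2])))
  actL <- run_monodomain(m, prL, dt_ms = 0.02, duration_ms = 60,
                         meas_start_ms = 0)$act
  actT <- run_monodomain(m, prT, dt_ms = 0.02, duration_ms = 60,
                         meas_start_ms = 0)$act
  expect_equal(actT, t(actL), tolerance = 1e-6)
})

test_that("quiet-stop exits early without changing the measured maps", {
  full <- run_cable(0.025, 0.02, duration = 500)$res
  qs <- run_cable(0.025, 0.02, duration = 500, quiet_stop_ms = 50)$res
  expect_lt(qs$t_end, 500)
  expect_gt(qs$t_end, 250)          # not before repolarization completes
  expect_identical(qs$act, full$act)
  expect_identical(qs$repol, full$repol)
})

test_that("state chaining reproduces the uninterrupted run", {
  cb <- build_cable(1.5, 0.025)
  pr <- stimulus_protocol(cb, t_s1_ms = 5, n_s1 = 1, s1_amp = 100)
  a <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 30,
                      meas_start_ms = 0, return_state = TRUE)
  expect_false(is.null(a$state))
  # continue from the snapshot with no further stimulus
  pr0 <- stimulus_protocol(cb, t_s1_ms = 0, s1_dur_ms = 0.5,
                           s1_period_ms = 1, n_s1 = 1, s1_amp = 0)
  b <- run_monodomain(cb, pr0, dt_ms = 0.02, duration_ms = 30,
                      meas_start_ms = 0, init = a$state)
  full <- run_monodomain(cb, pr, dt_ms = 0.02, duration_ms = 60,
                         meas_start_ms = 0)
  expect_equal(b$v_final, full$v_final, tolerance = 1e-10)
})

test_that("stimulus_protocol validates regions and periods", {
  cb <- build_cable(1.5, 0.025)
  expect_error(stimulus_protocol(cb, s1_region = list(rows = c(1, 2),
                                                      cols = c(1, 10))),
               "outside the grid")
  expect_error(stimulus_protocol(cb, s1_period_ms = 1, s1_dur_ms = 2),
               "exceed")
  p <- stimulus_protocol(build_mesh(3), s2_t_ms = 400)
  expect_equal(p$s2$region$rows, c(1L, 30L))  # default corner patch
  expect_equal(p$s2$region$cols, c(1L, 30L))
})

test_that("s1s2 scan machinery classifies a scripted membrane correctly", {
  mock <- function(s2_ms) {
    bins <- integer(40)                      # 40 x 50 ms bins over 2000 ms
    s2e <- s2_ms + 2
    sustained <- s2_ms >= 255 && s2_ms <= 300
    if (sustained) {
      bins[] <- 2L
      t_end <- 2000
    } else if (s2_ms > 300) {                # captures, dies out
      act <- which((seq_along(bins) - 1) * 50 < s2e + 200 &
                     seq_along(bins) * 50 > s2e)
      bins[act] <- 1L
      t_end <- s2e + 400
    } else {                                 # refractory: no capture
      t_end <- s2e + 300
    }
    list(upcross_bins = bins, upcross_bin_ms = 50, duration_ms = 2000,
         last_stim_end_ms = s2e, t_end = t_end, s2_end_ms = s2e,
         capture_bins_ms = c(s2e, s2e + 150))
  }
  sc <- s1s2_scan(NULL, NULL, seq(230, 330, by = 5), runner = mock)
  expect_s3_class(sc, "s1s2_scan")
  expect_equal(sc$outcome[sc$s2_ms < 255], rep("no_capture", 5))
  expect_equal(sc$outcome[sc$s2_ms >= 255 & sc$s2_ms <= 300],
               rep("sustained_reentry", 10))
  expect_equal(sc$outcome[sc$s2_ms > 300], rep("propagated_no_reentry", 6))
  expect_equal(vulnerability_window(sc)$vw_ms, 50)
  # edge refinement narrows the window to the true 1-ms-resolution span
  vw <- vw_scan(NULL, NULL, 230, 330, step_ms = 5, refine_ms = 1,
                runner = mock)
  expect_equal(vw$scan_step_ms, 1)
  expect_equal(vw$vw_ms, 300 - 255 + 1)
  expect_error(s1s2_scan(NULL, NULL, c(250, 250), runner = mock),
               "strictly increasing")
})
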