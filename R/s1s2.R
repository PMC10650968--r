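#' Scan premature-stimulus timings (S1-S2 protocol)
#'
#' Delivers the conditioning S1 train once, snapshots the tissue state just
#' after the last S1 pulse, and then, for every requested S2 timing, restarts
#' from that snapshot with a single premature cross-field pulse and simulates
#' a `sustain_horizon_ms` horizon. Each run is classified as `no_capture`
#' (no new upstrokes after the S2 pulse), `propagated_no_reentry`, or
#' `sustained_reentry` (per [detect_sustained_reentry()]).
#'
#' @param mesh A `tissue_mesh`.
#' @param protocol A `stimulus_protocol`; its S2 region/duration/amplitude
#'   are used (defaults are created when it has no S2).
#' @param s2_times Sorted vector of absolute S2 onset times, ms (each must
#'   fall after the last S1 pulse).
#' @param sustain_horizon_ms Simulated horizon after each S2.
#' @param dt_ms Integration step, ms.
#' @param na_variant Myocyte sodium-current formulation.
#' @param quiet_stop_ms Early-exit window for electrically quiet tissue
#'   (0 disables; the default keeps failed inductions cheap without touching
#'   the classification).
#' @param runner Optional function `function(s2_ms) -> result` substituting
#'   the simulator (used to validate the scan/classification machinery
#'   against scripted membrane behavior); the result needs the fields used
#'   by [detect_sustained_reentry()] plus `s2_end_ms` and `capture_bins_ms`.
#' @return An `s1s2_scan` tibble: `s2_ms`, `outcome`, `n_upcross`,
#'   `t_end_ms`.
#' @export
s1s2_scan <- function(mesh, protocol, s2_times, sustain_horizon_ms = 2000,
                      dt_ms = 0.02, na_variant = "calibrated",
                      quiet_stop_ms = 300, runner = NULL) {
  abort_if(length(s2_times) < 1, "need at least one S2 time")
  abort_if(is.unsorted(s2_times, strictly = TRUE),
           "s2_times must be strictly increasing")

  if (is.null(runner)) {
    abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
    abort_if(!inherits(protocol, "stimulus_protocol"),
             "protocol must be a stimulus_protocol")
    s1 <- protocol$s1
    t_snap <- s1$t_ms + (s1$n - 1) * s1$period_ms + s1$dur_ms + 1
    abort_if(any(s2_times <= t_snap + dt_ms),
             "every S2 must fall after the last S1 pulse")
    base <- run_monodomain(mesh, protocol, dt_ms = dt_ms,
                           duration_ms = t_snap, meas_start_ms = 0,
                           return_state = TRUE, na_variant = na_variant)
    snap <- base$state
    s1_amp <- base$s1_amp
    d <- dim(mesh$celltype)
    s2_region <- if (!is.null(protocol$s2)) protocol$s2$region else
      list(rows = c(1L, max(1L, as.integer(round(0.25 * d[1])))),
           cols = c(1L, max(1L, as.integer(round(0.25 * d[2])))))
    s2_dur <- if (!is.null(protocol$s2)) protocol$s2$dur_ms else 2
    s2_amp <- (if (!is.null(protocol$s2)) protocol$s2$amp else NULL) %||%
      s1_amp
    runner <- function(s2_ms) {
      rel <- s2_ms - t_snap
      pr <- stimulus_protocol(mesh, t_s1_ms = 0, s1_dur_ms = 0.5,
                              s1_period_ms = 1, n_s1 = 1, s1_amp = 0,
                              s2_t_ms = rel, s2_dur_ms = s2_dur,
                              s2_amp = s2_amp, s2_region = s2_region)
      res <- run_monodomain(mesh, pr, dt_ms = dt_ms,
                            duration_ms = rel + sustain_horizon_ms,
                            meas_start_ms = 0, init = snap,
                            na_variant = na_variant,
                            quiet_stop_ms = quiet_stop_ms)
      res$s2_end_ms <- rel + s2_dur
      res$capture_bins_ms <- c(rel + s2_dur, rel + s2_dur + 150)
      res
    }
  }

  rows <- lapply(s2_times, function(ts2) {
    res <- runner(ts2)
    bins <- res$upcross_bins
    bw <- res$upcross_bin_ms
    cw <- res$capture_bins_ms
    idx <- which((seq_along(bins) - 1) * bw < cw[2] &
                   seq_along(bins) * bw > cw[1])
    captured <- sum(bins[idx]) > 0
    outcome <- if (detect_sustained_reentry(res)) "sustained_reentry"
      else if (captured) "propagated_no_reentry" else "no_capture"
    tibble::tibble(s2_ms = ts2, outcome = outcome,
                   n_upcross = sum(bins),
                   t_end_ms = res$t_end %||% res$duration_ms)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("s1s2_scan", class(out))
  attr(out, "sustain_horizon_ms") <- sustain_horizon_ms
  out
}

#' Vulnerability-window scan with edge refinement
#'
#' Convenience wrapper around [s1s2_scan()] and [vulnerability_window()]:
#' scans a coarse S2 grid and then refines the edges of the largest sustained
#' block on a finer grid, returning the refined window length.
#'
#' @inheritParams s1s2_scan
#' @param s2_from,s2_to Coarse scan range (absolute S2 times, ms).
#' @param step_ms Coarse scan step.
#' @param refine_ms Refinement step at the block edges (`NULL` to skip).
#' @param ... Passed on to [s1s2_scan()].
#' @return List with `vw_ms`, the combined `outcomes` table, and
#'   `scan_step_ms` (the effective resolution).
#' @export
vw_scan <- function(mesh, protocol, s2_from, s2_to, step_ms = 5,
                    refine_ms = 1, ...) {
  grid <- seq(s2_from, s2_to, by = step_ms)
  out <- s1s2_scan(mesh, protocol, grid, ...)
  step_eff <- step_ms
  if (!is.null(refine_ms) && refine_ms < step_ms &&
      any(out$outcome == "sustained_reentry")) {
    sus <- which(out$outcome == "sustained_reentry")
    edges <- c(out$s2_ms[min(sus)] - step_ms, out$s2_ms[max(sus)])
    extra <- unlist(lapply(edges, function(e)
      seq(e + refine_ms, e + step_ms - refine_ms, by = refine_ms)))
    extra <- sort(setdiff(round(extra, 9), out$s2_ms))
    extra <- extra[extra >= s2_from - step_ms & extra <= s2_to]
    if (length(extra)) {
      out2 <- s1s2_scan(mesh, protocol, extra, ...)
      out <- dplyr::bind_rows(out, out2)
      out <- out[order(out$s2_ms), ]
      class(out) <- c("s1s2_scan", class(tibble::tibble()))
      step_eff <- refine_ms
    }
  }
  vw <- vulnerability_window(out, scan_step_ms = step_eff)
  list(vw_ms = vw$vw_ms, outcomes = out, scan_step_ms = step_eff)
}
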