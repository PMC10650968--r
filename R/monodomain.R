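#' Define an S1 (and optional S2) stimulation protocol
#'
#' The conditioning S1 train is delivered to a left-edge strip (by default the
#' full edge, 0.5-cm deep on the 3-cm reference mesh) with onset 50 ms, pulse
#' duration 2 ms, period 1000 ms and an amplitude of twice the diastolic
#' threshold. The premature S2 pulse, when given, is delivered to a top-left
#' corner patch.
#'
#' @param mesh The `tissue_mesh` the protocol is for (regions are derived
#'   from its dimensions).
#' @param t_s1_ms Onset of the first S1 pulse, ms.
#' @param s1_dur_ms S1 pulse duration, ms.
#' @param s1_period_ms S1 period, ms.
#' @param n_s1 Number of S1 beats.
#' @param s1_amp S1 amplitude in uA/uF, or `NULL` for twice the diastolic
#'   threshold (found by bisection on a control cable and cached).
#' @param s1_region,s2_region Node-index rectangles `list(rows = c(r0, r1),
#'   cols = c(c0, c1))` (1-based, inclusive); defaults are the full-left-edge
#'   strip and the top-left corner patch.
#' @param s2_t_ms Absolute S2 onset time in ms, or `NULL` for no S2.
#' @param s2_dur_ms S2 pulse duration, ms.
#' @param s2_amp S2 amplitude in uA/uF (`NULL`: same as resolved S1).
#' @param s2_frac Fractional side length of the default corner S2 patch.
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(mesh, t_s1_ms = 50, s1_dur_ms = 2,
                              s1_period_ms = 1000, n_s1 = 1, s1_amp = NULL,
                              s1_region = NULL, s2_t_ms = NULL,
                              s2_dur_ms = 2, s2_amp = NULL, s2_region = NULL,
                              s2_frac = 0.25) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  d <- dim(mesh$celltype)
  if (is.null(s1_region)) {
    depth <- max(1L, as.integer(round(mesh$size_cm / 6 / mesh$dx_cm)))
    s1_region <- list(rows = c(1L, d[1]), cols = c(1L, min(depth, d[2])))
  }
  check_region <- function(rg, nm) {
    abort_if(!is.list(rg) || !all(c("rows", "cols") %in% names(rg)),
             paste(nm, "must be list(rows=, cols=)"))
    abort_if(rg$rows[1] < 1 || rg$rows[2] > d[1] || rg$cols[1] < 1 ||
               rg$cols[2] > d[2] || rg$rows[1] > rg$rows[2] ||
               rg$cols[1] > rg$cols[2],
             paste(nm, "outside the grid"))
  }
  check_region(s1_region, "s1_region")
  abort_if(s1_dur_ms <= 0, "s1_dur_ms must be positive")
  abort_if(s1_period_ms <= s1_dur_ms, "s1_period_ms must exceed s1_dur_ms")
  s2 <- NULL
  if (!is.null(s2_t_ms)) {
    if (is.null(s2_region)) {
      s2_region <- list(rows = c(1L, max(1L, as.integer(round(s2_frac * d[1])))),
                        cols = c(1L, max(1L, as.integer(round(s2_frac * d[2])))))
    }
    check_region(s2_region, "s2_region")
    s2 <- list(region = s2_region, t_ms = s2_t_ms, dur_ms = s2_dur_ms,
               amp = s2_amp)
  }
  structure(list(s1 = list(region = s1_region, t_ms = t_s1_ms,
                           dur_ms = s1_dur_ms, period_ms = s1_period_ms,
                           n = as.integer(n_s1), amp = s1_amp),
                 s2 = s2),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  s1 <- x$s1
  cat("<stimulus_protocol> S1: ", s1$n, " pulse(s) from t = ", s1$t_ms,
      " ms, dur ", s1$dur_ms, " ms, period ", s1$period_ms, " ms, amp ",
      if (is.null(s1$amp)) "2x diastolic threshold" else
        paste0(s1$amp, " uA/uF"), "\n", sep = "")
  if (!is.null(x$s2))
    cat("  S2 at t = ", x$s2$t_ms, " ms on rows ",
        paste(x$s2$region$rows, collapse = ".."), ", cols ",
        paste(x$s2$region$cols, collapse = ".."), "\n", sep = "")
  invisible(x)
}

#' Diastolic threshold of a mesh or cable
#'
#' Bisects (to 1% relative precision) the minimal amplitude of a single
#' `td_ms`-long pulse, delivered to the mesh's default stimulus strip from
#' the paced-steady resting state, that produces a propagated activation
#' (a -40 mV upstroke) at least 1 cm from the stimulus edge (or at 80% of
#' the available distance on smaller meshes).
#'
#' @param mesh A `tissue_mesh` (a cable from [build_cable()] works too).
#' @param td_ms Pulse duration, ms.
#' @param dt_ms Integration step, ms.
#' @param max_amp Upper bracket for the search, uA/uF.
#' @param na_variant Myocyte sodium-current formulation (see
#'   [run_single_cell()]).
#' @return Threshold amplitude in uA/uF.
#' @export
find_diastolic_threshold <- function(mesh, td_ms = 2, dt_ms = 0.02,
                                     max_amp = 200,
                                     na_variant = "calibrated") {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  d <- dim(mesh$celltype)
  depth <- max(1L, as.integer(round(mesh$size_cm / 6 / mesh$dx_cm)))
  stim_cols <- min(depth, d[2])
  target_off <- min(as.integer(round(1 / mesh$dx_cm)),
                    as.integer(floor(0.8 * (d[2] - stim_cols))))
  target_col <- stim_cols + max(1L, target_off)
  abort_if(target_col > d[2], "mesh too small for a propagation check")
  target_row <- as.integer(ceiling(d[1] / 2))
  dur <- 20 + target_off * mesh$dx_cm / 0.01  # generous travel budget (ms)

  propagates <- function(amp) {
    pr <- stimulus_protocol(mesh, t_s1_ms = 2, s1_dur_ms = td_ms,
                            n_s1 = 1, s1_amp = amp,
                            s1_region = list(rows = c(1L, d[1]),
                                             cols = c(1L, stim_cols)))
    res <- run_monodomain(mesh, pr, dt_ms = dt_ms, duration_ms = dur,
                          meas_start_ms = 0, na_variant = na_variant)
    res$upcross_count[target_row, target_col] > 0
  }
  lo <- 0
  hi <- 10
  while (!propagates(hi)) {
    lo <- hi
    hi <- hi * 2
    abort_if(hi > max_amp, "unexcitable")
  }
  while ((hi - lo) / hi > 0.01) {
    mid <- (hi + lo) / 2
    if (propagates(mid)) hi <- mid else lo <- mid
  }
  hi
}

# resolve a protocol amplitude given in multiples of the diastolic threshold;
# the control-cable threshold is cached per (na_variant, dt, pulse duration)
default_s1_amp <- function(dt_ms, dur_ms, na_variant) {
  key <- paste("thr", na_variant, dt_ms, dur_ms, sep = "|")
  if (is.null(the$steady[[key]])) {
    cab <- build_cable(1.5, 0.025)
    the$steady[[key]] <- find_diastolic_threshold(cab, td_ms = dur_ms,
                                                  dt_ms = dt_ms,
                                                  na_variant = na_variant)
  }
  2 * the$steady[[key]]
}

#' Run a 2D (or cable) monodomain simulation
#'
#' Explicit finite-difference solution of the monodomain equation on a
#' `tissue_mesh`: anisotropic 5-point diffusion stencil with per-edge
#' coefficients (harmonic mean of the node values, divided by 3 on any edge
#' touching a fibroblast node), no-flux boundaries, forward-Euler diffusion
#' and Rush-Larsen gating updates. Myocyte nodes start from the cached
#' 1000-beat paced single-cell steady state, fibroblast nodes from their
#' resting state.
#'
#' @param mesh A `tissue_mesh`.
#' @param protocol A `stimulus_protocol`.
#' @param dt_ms Time step, ms (must satisfy the diffusive stability limit).
#' @param duration_ms Total simulated time; defaults to the end of the last
#'   S1 cycle (or 300 ms past S2 when an S2 is present).
#' @param meas_start_ms Start of the measurement window for the activation /
#'   repolarization maps; defaults to the onset of the last S1 beat.
#' @param output_interval_ms If > 0, record full Vm snapshots every this many
#'   ms (from `meas_start_ms`).
#' @param init Either `"steady"` (default), or a full state matrix as
#'   returned in `$state` when `return_state = TRUE` (used to chain runs).
#' @param return_state Return the final per-node state matrix.
#' @param na_variant Myocyte sodium-current formulation (see
#'   [run_single_cell()]); the conduction-calibrated variant is the tissue
#'   default.
#' @param upcross_bin_ms Width of the global upstroke-count time bins used by
#'   reentry detection.
#' @param quiet_stop_ms If > 0, stop early once no node's potential changes
#'   faster than 0.05 mV/ms for this long after the last scheduled stimulus.
#' @return A `monodomain_result`: matrices `act`, `repol`, `dvdtmax`,
#'   `vpeak`, `vrest`, `v_final` (activation/repolarization in absolute ms,
#'   `NA` where undetected), `upcross_count`, vector `upcross_bins`, optional
#'   traces, and provenance fields.
#' @export
run_monodomain <- function(mesh, protocol, dt_ms = 0.02, duration_ms = NULL,
                           meas_start_ms = NULL, output_interval_ms = 0,
                           init = "steady", return_state = FALSE,
                           na_variant = c("calibrated", "ord"),
                           upcross_bin_ms = 50, quiet_stop_ms = 0) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  abort_if(!inherits(protocol, "stimulus_protocol"),
           "protocol must be a stimulus_protocol")
  na_variant <- match.arg(na_variant)
  # diffusive stability limit (forward Euler, 5-point stencil)
  dmax <- max(mesh$DL) * (1 + mesh$ratio)
  cfl <- mesh$dx_cm^2 / (2 * dmax)
  abort_if(dt_ms > cfl,
           sprintf("dt %g ms violates the stability limit %.4g ms", dt_ms, cfl))

  s1 <- protocol$s1
  s1_amp <- s1$amp %||% default_s1_amp(dt_ms, s1$dur_ms, na_variant)
  last_s1 <- s1$t_ms + (s1$n - 1) * s1$period_ms
  last_stim_end <- last_s1 + s1$dur_ms
  if (is.null(duration_ms)) {
    duration_ms <- last_s1 + s1$period_ms
    if (!is.null(protocol$s2)) duration_ms <- max(duration_ms,
                                                  protocol$s2$t_ms + 300)
  }
  if (is.null(meas_start_ms)) meas_start_ms <- max(0, last_s1 - 1)
  stims <- list(c(s1$region$rows[1], s1$region$rows[2],
                  s1$region$cols[1], s1$region$cols[2],
                  s1$t_ms, s1$dur_ms, s1$period_ms, s1$n, s1_amp))
  if (!is.null(protocol$s2)) {
    s2 <- protocol$s2
    s2_amp <- s2$amp %||% s1_amp
    stims <- c(stims, list(c(s2$region$rows[1], s2$region$rows[2],
                             s2$region$cols[1], s2$region$cols[2],
                             s2$t_ms, s2$dur_ms, -1, 1, s2_amp)))
    last_stim_end <- max(last_stim_end, s2$t_ms + s2$dur_ms)
  }

  if (is.matrix(init)) {
    init_full <- init
    init_epi <- ord_initial_state_cpp()
    init_mid <- init_epi
    init_fib <- fib_initial_state_cpp()
  } else {
    abort_if(!identical(init, "steady"),
             'init must be "steady" or a state matrix')
    init_full <- NULL
    init_epi <- cell_steady_state("epi", na_variant = na_variant)
    init_mid <- if (any(mesh$celltype == 1L))
      cell_steady_state("mid", na_variant = na_variant) else init_epi
    init_fib <- cell_steady_state("fibroblast")
  }

  res <- monodomain_cpp(mesh$celltype, mesh$DL, mesh$ratio, mesh$dx_cm,
                        dt_ms, duration_ms, stims,
                        init_epi, init_mid, init_fib, init_full,
                        meas_start_ms, output_interval_ms, upcross_bin_ms,
                        -40, return_state, na_variant == "calibrated",
                        quiet_stop_ms, last_stim_end + 1)
  structure(c(res,
              list(celltype = mesh$celltype, dx_cm = mesh$dx_cm,
                   ratio = mesh$ratio, dt_ms = dt_ms,
                   duration_ms = duration_ms, meas_start_ms = meas_start_ms,
                   upcross_bin_ms = upcross_bin_ms,
                   last_stim_end_ms = last_stim_end,
                   s1_amp = s1_amp, na_variant = na_variant,
                   protocol = protocol)),
            class = "monodomain_result")
}

#' @export
print.monodomain_result <- function(x, ...) {
  d <- dim(x$act)
  cat("<monodomain_result> ", d[1], "x", d[2], " nodes, ",
      format(x$t_end %||% x$duration_ms), "/", x$duration_ms,
      " ms simulated (dt ", x$dt_ms, " ms)\n", sep = "")
  cat("  activated nodes: ", sum(!is.na(x$act)), "/", length(x$act),
      " in the measurement window (from ", x$meas_start_ms, " ms)\n",
      sep = "")
  invisible(x)
}
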