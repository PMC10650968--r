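#' Simulate a single paced cardiac cell
#'
#' Runs the single-cell membrane model for one node: the human ventricular
#' action potential model in its epicardial or midmyocardial variant, or the
#' active-fibroblast membrane model. Myocytes are paced with brief current
#' pulses at a fixed cycle length; the fibroblast runs freely (it is not
#' excitable) unless a pulse is requested.
#'
#' @param variant `"epi"`, `"mid"` or `"fibroblast"`.
#' @param pacing_cl_ms Pacing cycle length in ms (ignored for the fibroblast,
#'   which runs for `n_beats * pacing_cl_ms` ms unpaced by default).
#' @param n_beats Number of beats to simulate.
#' @param dt_ms Integration time step in ms.
#' @param stim_amp Stimulus amplitude in uA/uF (depolarizing, positive).
#' @param stim_dur_ms Stimulus pulse duration in ms.
#' @param record_beats How many trailing beats to record in the trace.
#' @param out_dt_ms Trace output interval in ms.
#' @param init Optional initial state vector (as returned in `$state`);
#'   defaults to the model's published initial conditions.
#' @param na_variant Sodium-current formulation for myocytes: `"calibrated"`
#'   (conduction-calibrated fast sodium current, the tissue default) or
#'   `"ord"` (the original formulation). See the methods vignette.
#'
#' @return A list of class `cell_sim` with elements `trace` (a tibble with
#'   columns `time`, `vm` and, for myocytes, `cai`), `state` (the final state
#'   vector), and the call parameters.
#' @export
#' @examples
#' \donttest{
#' ap <- run_single_cell("epi", n_beats = 2, record_beats = 1)
#' apd90(ap$trace$vm, dt_ms = 0.1)
#' }
run_single_cell <- function(variant = c("epi", "mid", "fibroblast"),
                            pacing_cl_ms = 1000, n_beats = 1, dt_ms = 0.02,
                            stim_amp = 80, stim_dur_ms = 0.5,
                            record_beats = n_beats, out_dt_ms = 0.1,
                            init = NULL, na_variant = c("calibrated", "ord")) {
  variant <- match.arg(variant)
  na_variant <- match.arg(na_variant)
  abort_if(pacing_cl_ms <= 0 || n_beats < 1 || dt_ms <= 0,
           "pacing_cl_ms, n_beats and dt_ms must be positive")
  if (variant == "fibroblast") {
    st <- init %||% fib_initial_state_cpp()
    dur <- pacing_cl_ms * n_beats
    res <- fib_run_cpp(st, dur, dt_ms, stim_amp = 0, stim_dur = 0,
                       stim_t0 = 0, out_dt = out_dt_ms)
    trace <- tibble::tibble(time = res$time, vm = res$v)
  } else {
    st <- init %||% ord_initial_state_cpp()
    res <- ord_pace_cpp(st, celltype = if (variant == "mid") 1L else 0L,
                        cl = pacing_cl_ms, nbeats = as.integer(n_beats),
                        dt = dt_ms, stim_amp = stim_amp,
                        stim_dur = stim_dur_ms,
                        record_beats = as.integer(record_beats),
                        out_dt = out_dt_ms,
                        ina_tp06 = (na_variant == "calibrated"))
    trace <- tibble::tibble(time = res$time, vm = res$v, cai = res$cai)
  }
  structure(list(trace = trace, state = res$state, variant = variant,
                 pacing_cl_ms = pacing_cl_ms, n_beats = n_beats,
                 dt_ms = dt_ms, out_dt_ms = out_dt_ms,
                 na_variant = na_variant),
            class = "cell_sim")
}

#' @export
print.cell_sim <- function(x, ...) {
  cat("<cell_sim> ", x$variant, " variant, ", x$n_beats, " beat(s) at CL ",
      x$pacing_cl_ms, " ms, dt ", x$dt_ms, " ms\n", sep = "")
  cat("  trace: ", nrow(x$trace), " samples at ", x$out_dt_ms, " ms\n",
      sep = "")
  invisible(x)
}

#' Paced steady state of a cell variant
#'
#' Returns the state vector after long pacing (default 1000 beats) for
#' myocyte variants, or after a 20 s free run for the fibroblast. Results are
#' cached per (variant, cycle length, beat count, dt, sodium variant) for the
#' session, since tissue simulations start every node from this state.
#'
#' @inheritParams run_single_cell
#' @param n_beats Number of conditioning beats.
#' @return Numeric state vector.
#' @export
cell_steady_state <- function(variant, pacing_cl_ms = 1000, n_beats = 1000,
                              dt_ms = 0.02, na_variant = "calibrated") {
  if (variant == "fibroblast") {
    key <- "fib"
    if (is.null(the$steady[[key]])) {
      res <- fib_run_cpp(fib_initial_state_cpp(), 20000, dt_ms, 0, 0, 0, 1e9)
      the$steady[[key]] <- res$state
    }
    return(the$steady[[key]])
  }
  key <- paste(variant, pacing_cl_ms, n_beats, dt_ms, na_variant, sep = "|")
  if (is.null(the$steady[[key]])) {
    sim <- run_single_cell(variant, pacing_cl_ms = pacing_cl_ms,
                           n_beats = n_beats, dt_ms = dt_ms,
                           record_beats = 0, na_variant = na_variant)
    the$steady[[key]] <- sim$state
  }
  the$steady[[key]]
}

#' Action potential duration at 90% repolarization
#'
#' Computes APD90 from a single-AP membrane-potential trace: activation is the
#' time of the maximum upstroke derivative, the repolarization level is
#' `peak - 0.9 * (peak - preceding diastolic Vm)`, and the crossing time is
#' found by linear interpolation between samples.
#'
#' @param vm Numeric vector of membrane potential samples (mV) containing one
#'   full action potential.
#' @param dt_ms Sampling interval of `vm` in ms (uniform).
#' @param slope_floor Minimum upstroke derivative (mV/ms) for a deflection to
#'   count as an action potential; traces below it raise an error. The default
#'   accepts the slow electrotonic depolarizations of coupled fibroblast nodes.
#' @return APD90 in ms.
#' @export
#' @examples
#' vm <- c(rep(-85, 10), rep(30, 10), seq(30, -90, length.out = 300))
#' apd90(vm, dt_ms = 1)
apd90 <- function(vm, dt_ms, slope_floor = 5) {
  abort_if(!is.numeric(vm) || length(vm) < 3, "vm must be a numeric trace")
  abort_if(dt_ms <= 0, "dt_ms must be positive")
  dv <- diff(vm) / dt_ms
  iup <- which.max(dv)
  abort_if(dv[iup] < slope_floor, "no AP detected")
  t_act <- (iup - 1) * dt_ms  # sample at the start of the steepest rise
  seg <- vm[iup:length(vm)]
  vdia <- min(vm[seq_len(iup)])
  vpeak <- max(seg)
  level <- vpeak - 0.9 * (vpeak - vdia)
  ipk <- which.max(seg)
  post <- seg[ipk:length(seg)]
  below <- which(post < level)
  abort_if(length(below) == 0, "no AP detected")
  ib <- below[1]
  abort_if(ib == 1, "no AP detected")
  # linear interpolation of the downward crossing
  v0 <- post[ib - 1]; v1 <- post[ib]
  frac <- (v0 - level) / (v0 - v1)
  t_cross <- (iup - 1 + ipk - 1 + ib - 2 + frac) * dt_ms
  t_cross - t_act
}
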