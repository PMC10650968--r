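#' Local conduction-velocity field from an activation map
#'
#' Fits a local quadratic polynomial surface to the activation times in a
#' sliding window around every node and converts the fitted gradient into a
#' velocity vector, `v = grad(T) / |grad(T)|^2` (the standard
#' activation-gradient construction: speed is `1/|grad T|` along the normal).
#' The summary value is the median speed over interior activated nodes.
#'
#' @param activation_map Numeric matrix of activation times in ms (`NA` =
#'   not activated). A 1-row matrix (cable) is fitted along the cable only.
#' @param dx_cm Node spacing, cm.
#' @param fit_window_nodes Odd window side length (default 5).
#' @param exclude_margin Number of node layers at the domain border excluded
#'   from the median.
#' @param exclude Optional logical matrix of nodes to exclude from the median
#'   (e.g. the stimulated strip, whose simultaneous activation carries no
#'   front information).
#' @return A `cv_field` object: `vx`, `vy`, `speed` matrices (cm/s),
#'   `cv_median` (cm/s), `n_used`, `n_singular`.
#' @export
#' @examples
#' tm <- outer(rep(1, 20), (0:19) * 0.025 / 0.06)  # planar wave at 60 cm/s
#' cv_field(tm, 0.025)$cv_median
cv_field <- function(activation_map, dx_cm, fit_window_nodes = 5,
                     exclude_margin = 2, exclude = NULL) {
  T <- activation_map
  abort_if(!is.matrix(T) || !is.numeric(T), "activation_map must be numeric")
  abort_if(dx_cm <= 0, "dx_cm must be positive")
  w <- as.integer(fit_window_nodes)
  abort_if(w < 3 || w %% 2 == 0, "fit_window_nodes must be odd and >= 3")
  ny <- nrow(T); nx <- ncol(T)
  cable <- ny == 1
  h <- (w - 1L) %/% 2L
  abort_if(nx < w || (!cable && ny < w),
           "activation map smaller than the fit window")

  # design matrix over window offsets (physical units)
  if (cable) {
    offs <- expand.grid(di = 0L, dj = -h:h)
  } else {
    offs <- expand.grid(di = -h:h, dj = -h:h)
  }
  X <- with(offs, {
    x <- dj * dx_cm; y <- di * dx_cm
    if (cable) cbind(1, x, x^2) else cbind(1, x, y, x^2, x * y, y^2)
  })
  P <- solve(crossprod(X), t(X))   # coefficient extractor
  ix <- 2L                          # d/dx row
  iy <- if (cable) NA_integer_ else 3L

  gx <- matrix(NA_real_, ny, nx)
  gy <- matrix(NA_real_, ny, nx)
  rows <- if (cable) 1L else (h + 1L):(ny - h)
  cols <- (h + 1L):(nx - h)
  n_singular <- 0L
  for (r in rows) for (cc in cols) {
    win <- if (cable) T[1, (cc - h):(cc + h)] else
      as.vector(T[(r - h):(r + h), (cc - h):(cc + h)])
    ok <- !is.na(win)
    if (all(ok)) {
      gx[r, cc] <- sum(P[ix, ] * win)
      if (!cable) gy[r, cc] <- sum(P[iy, ] * win)
    } else if (sum(ok) >= ncol(X) + 1L) {
      fit <- tryCatch(qr.coef(qr(X[ok, , drop = FALSE]), win[ok]),
                      error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit[seq_len(if (cable) 2 else 3)])) {
        gx[r, cc] <- fit[ix]
        if (!cable) gy[r, cc] <- fit[iy]
      }
    }
  }
  if (cable) gy[] <- 0
  g2 <- gx^2 + gy^2                      # (ms/cm)^2
  sing <- !is.na(g2) & g2 < 1e-12
  n_singular <- sum(sing)
  g2[sing] <- NA
  vx <- 1000 * gx / g2                   # cm/s
  vy <- 1000 * gy / g2
  speed <- 1000 / sqrt(g2)

  use <- !is.na(speed) & !is.na(T)
  if (exclude_margin > 0) {
    m <- exclude_margin
    keep <- matrix(FALSE, ny, nx)
    if (cable) {
      keep[1, (m + 1):(nx - m)] <- TRUE
    } else if (ny > 2 * m && nx > 2 * m) {
      keep[(m + 1):(ny - m), (m + 1):(nx - m)] <- TRUE
    }
    use <- use & keep
  }
  if (!is.null(exclude)) use <- use & !exclude
  structure(list(vx = vx, vy = vy, speed = speed,
                 cv_median = if (any(use)) median(speed[use]) else NA_real_,
                 n_used = sum(use), n_singular = n_singular,
                 dx_cm = dx_cm, fit_window_nodes = w),
            class = "cv_field")
}

#' @export
print.cv_field <- function(x, ...) {
  cat("<cv_field> median speed ", format(x$cv_median, digits = 5),
      " cm/s over ", x$n_used, " nodes (", x$n_singular,
      " singular)\n", sep = "")
  invisible(x)
}

#' Per-node action-potential duration map
#'
#' APD90 per node from the solver's activation (maximum upstroke derivative)
#' and 90%-repolarization time maps; `NA` where no action potential (or no
#' suprathreshold electrotonic response) was detected. Fibroblast nodes whose
#' potential crosses the detection level are included.
#'
#' @param result A `monodomain_result`.
#' @return Matrix of APD90 values in ms.
#' @export
apd_map <- function(result) {
  abort_if(!inherits(result, "monodomain_result"),
           "result must be a monodomain_result")
  result$repol - result$act
}

#' Tissue-mean APD90
#'
#' Mean of [apd_map()] over all nodes with a detected action potential.
#'
#' @inheritParams apd_map
#' @return Mean APD90 in ms.
#' @export
tissue_mean_apd <- function(result) {
  m <- apd_map(result)
  abort_if(all(is.na(m)), "no action potentials detected")
  mean(m, na.rm = TRUE)
}

#' Repolarization-gradient map
#'
#' Magnitude of the spatial gradient of the repolarization-time map,
#' estimated by central differences over the one-node-radius neighborhood,
#' in ms/mm. Border nodes and nodes with an undefined neighbor are `NA`.
#'
#' @param repol_map Matrix of repolarization times, ms.
#' @param dx_cm Node spacing, cm.
#' @return Matrix of gradient magnitudes, ms/mm.
#' @export
repol_gradient_map <- function(repol_map, dx_cm) {
  abort_if(dx_cm <= 0, "dx_cm must be positive")
  T <- repol_map
  ny <- nrow(T); nx <- ncol(T)
  abort_if(ny < 3 || nx < 3, "repolarization map too small")
  gx <- matrix(NA_real_, ny, nx)
  gy <- matrix(NA_real_, ny, nx)
  gx[, 2:(nx - 1)] <- (T[, 3:nx] - T[, 1:(nx - 2)]) / (2 * dx_cm)
  gy[2:(ny - 1), ] <- (T[3:ny, ] - T[1:(ny - 2), ]) / (2 * dx_cm)
  sqrt(gx^2 + gy^2) / 10  # ms/cm -> ms/mm
}

#' High-repolarization-gradient (HRG) area
#'
#' Percentage of valid nodes whose repolarization gradient exceeds the
#' threshold (9 ms/mm by default), a dispersion-of-repolarization surrogate
#' for arrhythmic risk.
#'
#' @param grad_map Matrix from [repol_gradient_map()].
#' @param threshold Gradient threshold, ms/mm.
#' @return Percentage in \[0, 100\].
#' @export
hrg_area <- function(grad_map, threshold = 9) {
  valid <- !is.na(grad_map)
  abort_if(!any(valid), "no valid gradient nodes")
  100 * sum(grad_map[valid] > threshold) / sum(valid)
}

#' Detect sustained reentrant activity
#'
#' A simulation counts as sustained reentry when self-driven activation (new
#' -40 mV upstroke crossings anywhere in the tissue) continues throughout the
#' final `final_window_ms` of the run with no external stimulus scheduled in
#' that window: every ~100-ms chunk of the window must contain at least one
#' upstroke. Runs stopped early by the quiet-tissue exit are never sustained.
#'
#' @param result A `monodomain_result` (or a list with fields `upcross_bins`,
#'   `upcross_bin_ms`, `duration_ms`, `last_stim_end_ms`, optionally `t_end`).
#' @param final_window_ms Length of the terminal window that must stay
#'   active.
#' @return Logical flag.
#' @export
detect_sustained_reentry <- function(result, final_window_ms = 500) {
  bins <- result$upcross_bins
  bw <- result$upcross_bin_ms
  dur <- result$duration_ms
  abort_if(is.null(bins) || is.null(bw) || bw <= 0,
           "result carries no upstroke-count bins")
  abort_if((result$last_stim_end_ms %||% 0) > dur - final_window_ms,
           "a stimulus is scheduled inside the final window")
  t_end <- result$t_end %||% dur
  if (t_end < dur - 1e-9) return(FALSE)  # tissue went quiet before the end
  from <- dur - final_window_ms
  chunk <- max(bw, 100)
  starts <- seq(from, dur - 1e-9, by = chunk)
  for (s in starts) {
    e <- min(s + chunk, dur)
    idx <- which((seq_along(bins) - 1) * bw < e & seq_along(bins) * bw > s)
    if (sum(bins[idx]) < 1) return(FALSE)
  }
  TRUE
}

#' Vulnerability window from an S1-S2 outcome table
#'
#' The vulnerability window is the span of premature-stimulus timings that
#' induce sustained reentry: `(last - first) + scan_step` over the largest
#' contiguous sustained block of the scan grid, and 0 when no S2 timing is
#' sustained. When a baseline table (or length) is supplied, the VW ratio
#' (scenario / baseline) is also returned.
#'
#' @param outcomes Tibble from [s1s2_scan()] (columns `s2_ms`, `outcome`),
#'   sorted by `s2_ms`.
#' @param scan_step_ms Scan step; inferred from the grid when `NULL`.
#' @param baseline Optional baseline outcome table or baseline VW length
#'   in ms.
#' @return List with `vw_ms` and (when a baseline is given) `vw_ratio`.
#' @export
vulnerability_window <- function(outcomes, scan_step_ms = NULL,
                                 baseline = NULL) {
  abort_if(!all(c("s2_ms", "outcome") %in% names(outcomes)),
           "outcomes needs columns s2_ms and outcome")
  s2 <- outcomes$s2_ms
  abort_if(is.unsorted(s2, strictly = TRUE), "outcome table must be sorted")
  if (is.null(scan_step_ms)) {
    abort_if(length(s2) < 2, "cannot infer the scan step from one row")
    scan_step_ms <- min(diff(s2))
  }
  sus <- outcomes$outcome == "sustained_reentry"
  vw <- 0
  if (any(sus)) {
    runs <- rle(sus)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- 0
    for (i in which(runs$values)) {
      len <- s2[ends[i]] - s2[starts[i]] + scan_step_ms
      if (len > best) best <- len
    }
    vw <- best
  }
  out <- list(vw_ms = vw)
  if (!is.null(baseline)) {
    base_vw <- if (is.numeric(baseline)) baseline else
      vulnerability_window(baseline, scan_step_ms)$vw_ms
    out$vw_ratio <- if (base_vw > 0) vw / base_vw else NA_real_
  }
  out
}
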