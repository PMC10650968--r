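#' Segment cardiomyocytes from SERCA2 and WGA masks
#'
#' Cardiomyocytes are the connected components (8-connectivity) of
#' `SERCA2 & !WGA` above a minimum area. For each component the principal
#' axis is taken from the pixel covariance matrix, an oriented bounding box
#' is built around it, and the box is divided into 4 equal-length rectangles
#' (Q1..Q4) along the long axis. A component is `accepted` as longitudinally
#' oriented when its aspect ratio is at least `aspect_min` and its axis lies
#' within `angle_tol_deg` of the tissue's dominant (area-weighted) axis.
#'
#' @param serca2_mask,wga_mask Binary masks of one sample.
#' @param pixel_size_um Pixel size in micrometers.
#' @param min_area_um2 Minimum component area in square micrometers.
#' @param aspect_min Minimum length/width ratio for acceptance.
#' @param angle_tol_deg Maximum deviation from the dominant tissue axis.
#' @param exclude_border Drop components touching the image border; truncated
#'   cells cannot be quartered faithfully and would bias lateralization.
#' @return A `cm_segments` tibble with one row per component: `id`,
#'   `area_px`, `centroid_x`, `centroid_y` (pixel coordinates),
#'   `angle_deg` (principal axis vs image x-axis, in (-90, 90]),
#'   `length_um`, `width_um`, `aspect`, `accepted`, and list-columns
#'   `px_idx` (linear pixel indices) and `px_quarter` (1-4 per pixel, along
#'   the long axis). The dominant angle is attached as attribute
#'   `dominant_angle_deg`.
#' @export
segment_cardiomyocytes <- function(serca2_mask, wga_mask,
                                   pixel_size_um = 0.5, min_area_um2 = 100,
                                   aspect_min = 2.5, angle_tol_deg = 30,
                                   exclude_border = TRUE) {
  se <- as_binary_mask(serca2_mask, "serca2_mask")
  wg <- as_binary_mask(wga_mask, "wga_mask")
  check_same_shape(se, wg)
  abort_if(pixel_size_um <= 0, "pixel_size_um must be positive")
  cellpx <- se & !wg
  lab <- EBImage::bwlabel(matrix(as.numeric(cellpx), nrow(se), ncol(se)))
  lab <- matrix(as.integer(lab), nrow(se), ncol(se))
  nlab <- max(lab)
  min_px <- min_area_um2 / pixel_size_um^2
  empty <- tibble::tibble(id = integer(), area_px = integer(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          angle_deg = numeric(), length_um = numeric(),
                          width_um = numeric(), aspect = numeric(),
                          accepted = logical(), px_idx = list(),
                          px_quarter = list())
  if (nlab == 0) {
    class(empty) <- c("cm_segments", class(empty))
    return(empty)
  }
  idx_by_lab <- split(which(lab > 0), lab[lab > 0])
  rows <- list()
  ny <- nrow(se)
  for (nm in names(idx_by_lab)) {
    idx <- idx_by_lab[[nm]]
    if (length(idx) < min_px) next
    # pixel coordinates: x along columns, y along rows
    y <- ((idx - 1L) %% ny) + 1L
    x <- ((idx - 1L) %/% ny) + 1L
    if (exclude_border &&
        (min(y) == 1L || max(y) == ny ||
         min(x) == 1L || max(x) == ncol(se))) next
    cxm <- mean(x); cym <- mean(y)
    sxx <- mean((x - cxm)^2); syy <- mean((y - cym)^2)
    sxy <- mean((x - cxm) * (y - cym))
    theta <- 0.5 * atan2(2 * sxy, sxx - syy)   # radians, principal axis
    u <- (x - cxm) * cos(theta) + (y - cym) * sin(theta)
    v <- -(x - cxm) * sin(theta) + (y - cym) * cos(theta)
    len_px <- diff(range(u)) + 1
    wid_px <- diff(range(v)) + 1
    if (wid_px > len_px) {  # ensure the long axis defines the quarters
      theta <- theta + pi / 2
      tmp <- u; u <- v; v <- -tmp
      tmp <- len_px; len_px <- wid_px; wid_px <- tmp
    }
    span <- diff(range(u))
    quarter <- if (span == 0) rep(1L, length(u)) else
      pmin(4L, as.integer(floor((u - min(u)) / (span / 4))) + 1L)
    ang <- theta * 180 / pi
    ang <- ((ang + 90) %% 180) - 90
    if (ang == -90) ang <- 90
    rows[[nm]] <- tibble::tibble(
      id = as.integer(nm), area_px = length(idx),
      centroid_x = cxm, centroid_y = cym, angle_deg = ang,
      length_um = len_px * pixel_size_um, width_um = wid_px * pixel_size_um,
      aspect = len_px / wid_px, accepted = NA,
      px_idx = list(idx), px_quarter = list(quarter))
  }
  if (length(rows) == 0) {
    class(empty) <- c("cm_segments", class(empty))
    return(empty)
  }
  out <- dplyr::bind_rows(rows)
  # dominant axis: area-weighted circular mean on the 180-degree circle
  th2 <- out$angle_deg * pi / 90
  dom <- 0.5 * atan2(sum(out$area_px * sin(th2)), sum(out$area_px * cos(th2)))
  dom_deg <- dom * 180 / pi
  dev <- abs(out$angle_deg - dom_deg) %% 180
  dev <- pmin(dev, 180 - dev)
  out$accepted <- out$aspect >= aspect_min & dev <= angle_tol_deg
  attr(out, "dominant_angle_deg") <- dom_deg
  class(out) <- c("cm_segments", class(out))
  out
}

#' CX43 lateralization
#'
#' For every accepted (longitudinally oriented) cardiomyocyte holding at
#' least `min_cx43_px` CX43-positive pixels, the per-cell lateralization is
#' the CX43 signal in the two middle quarters (the lateral sides) as a
#' percentage of the cell's total CX43 signal. The sample value
#' `%CX43_LAT` is the unweighted mean over those cells.
#'
#' @param segments A `cm_segments` table from [segment_cardiomyocytes()].
#' @param cx43_mask Binary CX43 mask (same image geometry).
#' @param min_cx43_px Minimum CX43 pixels for a cell to contribute.
#' @return List with `pct_lateral` (sample mean) and `per_cell` (tibble
#'   `id`, `n_cx43`, `pct_lateral`).
#' @export
lateralization <- function(segments, cx43_mask, min_cx43_px = 10) {
  abort_if(!inherits(segments, "cm_segments"),
           "segments must come from segment_cardiomyocytes()")
  cx <- as_binary_mask(cx43_mask, "cx43_mask")
  acc <- segments[which(segments$accepted), ]
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    idx <- acc$px_idx[[i]]
    q <- acc$px_quarter[[i]]
    pos <- cx[idx]
    n <- sum(pos)
    if (n < min_cx43_px) next
    lat <- 100 * sum(pos & q %in% c(2L, 3L)) / n
    rows[[length(rows) + 1]] <- tibble::tibble(id = acc$id[i], n_cx43 = n,
                                               pct_lateral = lat)
  }
  abort_if(length(rows) == 0, "lateralization not computable")
  per_cell <- dplyr::bind_rows(rows)
  list(pct_lateral = mean(per_cell$pct_lateral), per_cell = per_cell)
}
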