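#' Preprocess an intensity channel
#'
#' Saturates channel intensities before binarization: `percentile_clip`
#' saturates the given fraction of lowest and highest values at the
#' corresponding quantiles (0.2% per tail by default, the lipofuscin
#' preprocessing); `fixed_window` saturates outside a fixed intensity window
#' (0-3500 by default); `none` returns the image unchanged. The image keeps
#' its bit depth; no rescaling is applied.
#'
#' @param image Numeric intensity matrix.
#' @param mode `"percentile_clip"`, `"fixed_window"` or `"none"`.
#' @param clip_fraction Per-tail fraction for `percentile_clip`.
#' @param window `c(lo, hi)` for `fixed_window`.
#' @return The saturated image.
#' @export
#' @examples
#' preprocess_channel(matrix(c(100, 4000), 1), "fixed_window")[1, 2]  # 3500
preprocess_channel <- function(image,
                               mode = c("percentile_clip", "fixed_window",
                                        "none"),
                               clip_fraction = 0.002, window = c(0, 3500)) {
  mode <- match.arg(mode)
  abort_if(!is.numeric(image) || !is.matrix(image),
           "image must be a numeric matrix")
  if (mode == "none") return(image)
  if (mode == "percentile_clip") {
    abort_if(clip_fraction < 0 || clip_fraction >= 0.5,
             "clip_fraction must be in [0, 0.5)")
    q <- quantile(image, c(clip_fraction, 1 - clip_fraction), names = FALSE,
                  type = 7)
    lo <- q[1]; hi <- q[2]
  } else {
    lo <- window[1]; hi <- window[2]
    abort_if(lo >= hi, "window lower bound must be below upper bound")
  }
  image[image < lo] <- lo
  image[image > hi] <- hi
  image
}

#' Binarize an intensity channel
#'
#' Thresholds a channel into a binary mask with a strict `>` comparison:
#' `mask = image > threshold`. The Otsu method picks the threshold maximizing
#' between-class variance of the integer intensity histogram; the chosen
#' threshold is attached as the `"threshold"` attribute for provenance.
#'
#' @param image Numeric intensity matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"` (must lie in the image
#'   range).
#' @return Logical mask with attribute `threshold`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  abort_if(!is.numeric(image) || !is.matrix(image),
           "image must be a numeric matrix")
  if (method == "fixed") {
    abort_if(is.null(threshold), "fixed binarization needs a threshold")
    abort_if(threshold < min(image) || threshold > max(image),
             "threshold outside the image range")
    thr <- threshold
  } else {
    thr <- otsu_threshold(image)
  }
  structure(image > thr, threshold = thr)
}

# Otsu's method on the integer-valued histogram; returns the bin value t
# maximizing between-class variance for the split (<= t) / (> t).
otsu_threshold <- function(image) {
  v <- round(as.vector(image))
  rng <- range(v)
  abort_if(rng[1] == rng[2], "degenerate histogram")
  lev <- as.numeric(rng[1]:rng[2])
  counts <- as.numeric(tabulate(v - rng[1] + 1L, nbins = length(lev)))
  w <- cumsum(counts)
  m <- cumsum(counts * lev)
  n <- w[length(w)]
  mt <- m[length(m)]
  w0 <- w[-length(w)]
  m0 <- m[-length(m)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(w0))
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 /
    (as.double(w0[valid]) * w1[valid])
  lev[which.max(bcv)]
}

#' Morphological refinement of a CX43 mask
#'
#' Opening (erosion then dilation) followed by closing (dilation then
#' erosion) with disk structuring elements, removing isolated noise pixels
#' and filling small holes. A radius of 0 skips the corresponding operation.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param opening_radius_px,closing_radius_px Disk radii in pixels.
#' @return Refined logical mask.
#' @export
refine_cx43_mask <- function(mask, opening_radius_px = 1,
                             closing_radius_px = 1) {
  m <- as_binary_mask(mask)
  abort_if(opening_radius_px < 0 || closing_radius_px < 0,
           "radii must be non-negative")
  if (opening_radius_px == 0 && closing_radius_px == 0) return(m)
  img <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (opening_radius_px > 0) {
    k <- EBImage::makeBrush(2 * opening_radius_px + 1, shape = "disc")
    img <- EBImage::opening(img, k)
  }
  if (closing_radius_px > 0) {
    k <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    img <- EBImage::closing(img, k)
  }
  matrix(as.vector(img) > 0.5, nrow(m), ncol(m))
}

# shared denominator: |SERCA2| or |SERCA2 union WGA| (union, not sum)
tissue_denominator <- function(serca2_mask, wga_mask, denom) {
  if (denom == "cm") sum(serca2_mask) else sum(serca2_mask | wga_mask)
}

#' CX43 amount (area fraction)
#'
#' `%CX43_CM`: CX43-positive pixels x 100 / SERCA2-positive pixels
#' (cardiomyocyte denominator). `%CX43_T`: CX43-positive pixels x 100 /
#' pixels positive to SERCA2 or WGA, counting pixels positive in both masks
#' once (tissue denominator).
#'
#' @param cx43_mask,serca2_mask,wga_mask Binary masks of one sample
#'   (`wga_mask` is only needed for `denom = "tissue"`).
#' @param denom `"cm"` or `"tissue"`.
#' @return Percentage.
#' @export
cx43_amount <- function(cx43_mask, serca2_mask, wga_mask = NULL,
                        denom = c("cm", "tissue")) {
  denom <- match.arg(denom)
  cx <- as_binary_mask(cx43_mask, "cx43_mask")
  se <- as_binary_mask(serca2_mask, "serca2_mask")
  if (denom == "tissue") {
    wg <- as_binary_mask(wga_mask, "wga_mask")
    check_same_shape(cx, se, wg)
  } else {
    wg <- NULL
    check_same_shape(cx, se)
  }
  d <- tissue_denominator(se, wg, denom)
  abort_if(d == 0, "no tissue detected")
  sum(cx) * 100 / d
}

#' CX43 expression level
#'
#' `CX43_E-CM` / `CX43_E-T`: sum of CX43-channel intensities over
#' CX43-positive pixels divided by the denominator pixel count (SERCA2 or
#' SERCA2-union-WGA), in normalized fluorescence units.
#'
#' @param cx43_image Preprocessed CX43 intensity channel.
#' @inheritParams cx43_amount
#' @return Mean expression in n.f.u.
#' @export
cx43_expression <- function(cx43_image, cx43_mask, serca2_mask,
                            wga_mask = NULL, denom = c("cm", "tissue")) {
  denom <- match.arg(denom)
  abort_if(!is.numeric(cx43_image) || !is.matrix(cx43_image),
           "cx43_image must be a numeric matrix")
  cx <- as_binary_mask(cx43_mask, "cx43_mask")
  se <- as_binary_mask(serca2_mask, "serca2_mask")
  if (denom == "tissue") {
    wg <- as_binary_mask(wga_mask, "wga_mask")
    check_same_shape(cx43_image, cx, se, wg)
  } else {
    wg <- NULL
    check_same_shape(cx43_image, cx, se)
  }
  d <- tissue_denominator(se, wg, denom)
  abort_if(d == 0, "no tissue detected")
  sum(cx43_image[cx]) / d
}

#' CX43 spatial heterogeneity
#'
#' For every CX43-positive pixel, the shortest Euclidean distance to any
#' other positive pixel is computed; `CX43_H` is the sample standard
#' deviation (n - 1 denominator) of these nearest-neighbour distances,
#' converted to micrometers.
#'
#' @param cx43_mask Binary mask with at least 2 positive pixels.
#' @param pixel_size_um Pixel size in micrometers (isotropic).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Heterogeneity in micrometers.
#' @export
#' @examples
#' m <- matrix(FALSE, 1, 5); m[1, c(1, 2, 4)] <- TRUE
#' cx43_heterogeneity(m, 1)  # sd of {1, 1, 2} = 0.5774
cx43_heterogeneity <- function(cx43_mask, pixel_size_um,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- as_binary_mask(cx43_mask, "cx43_mask")
  abort_if(pixel_size_um <= 0, "pixel_size_um must be positive")
  abort_if(sum(m) < 2, "heterogeneity undefined")
  d <- nn_distances_cpp(m)
  s <- sd(d)
  if (sd_type == "population") s <- s * sqrt((length(d) - 1) / length(d))
  s * pixel_size_um
}

#' Fibrosis area percentage
#'
#' `%Fibrosis`: pixels positive only to WGA x 100 / pixels positive to
#' SERCA2 or WGA (union, counting doubly positive pixels once).
#'
#' @param wga_mask,serca2_mask Binary masks.
#' @return Percentage.
#' @export
fibrosis_percent <- function(wga_mask, serca2_mask) {
  wg <- as_binary_mask(wga_mask, "wga_mask")
  se <- as_binary_mask(serca2_mask, "serca2_mask")
  check_same_shape(wg, se)
  u <- sum(wg | se)
  abort_if(u == 0, "no tissue detected")
  100 * sum(wg & !se) / u
}

#' Lipofuscin content percentage
#'
#' `%Lipofuscin`: lipofuscin-positive pixels divided by tissue
#' autofluorescence-positive pixels. The printed formula is a plain ratio
#' although named a percentage; this implementation reports the ratio x 100.
#'
#' @param lipofuscin_mask,autofluorescence_mask Binary masks.
#' @return Percentage (ratio x 100).
#' @export
lipofuscin_percent <- function(lipofuscin_mask, autofluorescence_mask) {
  li <- as_binary_mask(lipofuscin_mask, "lipofuscin_mask")
  au <- as_binary_mask(autofluorescence_mask, "autofluorescence_mask")
  check_same_shape(li, au)
  abort_if(sum(au) == 0, "no tissue")
  100 * sum(li) / sum(au)
}
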