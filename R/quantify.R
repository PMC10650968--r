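#' Quantify one histology sample
#'
#' Runs the full morphometry pipeline on a sample and returns one metrics row
#' with the canonical column names: `pct_cx43_cm`, `pct_cx43_t`, `expr_cm`,
#' `expr_t`, `heterogeneity_um`, `pct_lateral`, `pct_fibrosis`,
#' `pct_lipofuscin`. Masks are taken from the sample when present (synthetic
#' ground-truth masks) or derived from the channels by Otsu binarization; the
#' CX43 mask is optionally refined morphologically. Lateralization uses
#' cardiomyocyte segmentation and is `NA` when no accepted cell carries
#' enough CX43 signal (mirroring excluded donors).
#'
#' @param sample A `histology_sample`.
#' @param masks `"stored"` (use `sample$masks`, falling back to Otsu when
#'   absent) or `"otsu"` (always re-derive).
#' @param preprocess_lipofuscin Apply the percentile-clip preprocessing to
#'   the lipofuscin channel before thresholding (only relevant when masks are
#'   re-derived).
#' @param opening_radius_px,closing_radius_px CX43 mask refinement radii
#'   (only applied when masks are re-derived).
#' @param min_cx43_px Minimum per-cell CX43 pixels for lateralization.
#' @param segment_args Extra arguments to [segment_cardiomyocytes()].
#' @return One-row tibble of metrics; the provenance (thresholds, radii,
#'   mask source) is attached as the `"provenance"` attribute.
#' @export
quantify_sample <- function(sample, masks = c("stored", "otsu"),
                            preprocess_lipofuscin = TRUE,
                            opening_radius_px = 1, closing_radius_px = 1,
                            min_cx43_px = 10, segment_args = list()) {
  abort_if(!inherits(sample, "histology_sample"),
           "sample must be a histology_sample")
  masks <- match.arg(masks)
  prov <- list(mask_source = masks, thresholds = list(),
               opening_radius_px = opening_radius_px,
               closing_radius_px = closing_radius_px,
               min_cx43_px = min_cx43_px)
  ch <- sample$channels
  if (masks == "stored" && !is.null(sample$masks)) {
    mk <- sample$masks
  } else {
    prov$mask_source <- "otsu"
    mk <- list()
    for (nm in names(ch)) {
      img <- ch[[nm]]
      if (nm == "lipofuscin" && preprocess_lipofuscin)
        img <- preprocess_channel(img, "percentile_clip")
      m <- binarize(img, "otsu")
      prov$thresholds[[nm]] <- attr(m, "threshold")
      mk[[nm]] <- m
    }
    mk$cx43 <- refine_cx43_mask(mk$cx43, opening_radius_px,
                                closing_radius_px)
  }

  segs <- do.call(segment_cardiomyocytes,
                  c(list(mk$serca2, mk$wga,
                         pixel_size_um = sample$pixel_size_um),
                    segment_args))
  lat <- tryCatch(lateralization(segs, mk$cx43, min_cx43_px = min_cx43_px),
                  error = function(e) NULL)
  het <- tryCatch(cx43_heterogeneity(mk$cx43, sample$pixel_size_um),
                  error = function(e) NA_real_)

  out <- tibble::tibble(
    pct_cx43_cm = cx43_amount(mk$cx43, mk$serca2, denom = "cm"),
    pct_cx43_t = cx43_amount(mk$cx43, mk$serca2, mk$wga, denom = "tissue"),
    expr_cm = cx43_expression(ch$cx43, mk$cx43, mk$serca2, denom = "cm"),
    expr_t = cx43_expression(ch$cx43, mk$cx43, mk$serca2, mk$wga,
                             denom = "tissue"),
    heterogeneity_um = het,
    pct_lateral = if (is.null(lat)) NA_real_ else lat$pct_lateral,
    pct_fibrosis = fibrosis_percent(mk$wga, mk$serca2),
    pct_lipofuscin = lipofuscin_percent(mk$lipofuscin, mk$autofluorescence))
  attr(out, "provenance") <- prov
  out
}

#' Write a metrics table with a provenance sidecar
#'
#' Writes the per-sample metrics as CSV and, when provenance attributes are
#' supplied, a JSON sidecar (`<path>.json`) recording thresholds, refinement
#' radii and seeds.
#'
#' @param metrics Tibble of metric rows (e.g. bound [quantify_sample()]
#'   results).
#' @param path Output CSV path.
#' @param provenance Optional list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, provenance = NULL) {
  utils::write.csv(metrics, path, row.names = FALSE)
  if (!is.null(provenance)) {
    jsonlite::write_json(provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Quantify a whole cohort
#'
#' Applies [quantify_sample()] to every sample of a [generate_cohort()]
#' result (or any list of samples) and binds the rows to the cohort table.
#'
#' @param cohort List with `table` and `samples` as returned by
#'   [generate_cohort()].
#' @param ... Passed to [quantify_sample()].
#' @return The cohort table with the measured metric columns appended.
#' @export
quantify_cohort <- function(cohort, ...) {
  abort_if(is.null(cohort$samples), "cohort carries no in-memory samples")
  rows <- lapply(cohort$samples, quantify_sample, ...)
  dplyr::bind_cols(cohort$table, dplyr::bind_rows(rows))
}
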