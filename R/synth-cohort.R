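# default cohort parameter distributions, parameterized to the published
# population medians/ranges (CX43 fraction median 2.73%, range 0.44-5.34%;
# lateral fraction median 18.78%, range 6.42-35.78%; fibrosis up to 19%
# including the interstitial baseline) with mild age couplings so that the
# cohort statistics have signal to find
default_cohort_distributions <- function() {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  list(
    age = list(range = c(50, 84),
               sample = function(n, age = NULL) runif(n, 50, 84)),
    cx43_fraction_pct = list(range = c(0.44, 5.34),
      sample = function(n, age)
        clamp(2.73 * exp(-0.015 * (age - 67)) * exp(rnorm(n, 0, 0.45)),
              0.44, 5.34)),
    lateral_fraction_pct = list(range = c(6.42, 35.78),
      sample = function(n, age)
        clamp(18.78 * exp(0.012 * (age - 67)) * exp(rnorm(n, 0, 0.30)),
              6.42, 35.78)),
    cx43_clustering = list(range = c(0.15, 0.85),
      sample = function(n, age)
        clamp(0.5 + 0.01 * (age - 67) + rnorm(n, 0, 0.15), 0.15, 0.85)),
    patch_fraction = list(range = c(0, 0.16),
      sample = function(n, age)
        clamp(0.05 * exp(0.02 * (age - 67)) * exp(rnorm(n, 0, 0.6)),
              0, 0.16)),
    lipofuscin_pct = list(range = c(0.3, 8),
      sample = function(n, age)
        clamp(2 * exp(0.03 * (age - 67)) * exp(rnorm(n, 0, 0.4)), 0.3, 8))
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-donor ground-truth parameters from bounded distributions
#' (defaults target the published population medians and ranges), generates
#' one layout + render per donor, and returns the samples together with a
#' ground-truth table. The cohort is exactly regenerable from its seed.
#'
#' @param n Number of donors.
#' @param parameter_distributions Optional named list overriding the default
#'   distributions; each entry must be `list(range = c(lo, hi), sample =
#'   function(n, age) ...)` with a finite range (unbounded distributions are
#'   rejected).
#' @param seed Cohort seed.
#' @param width_px,height_px,pixel_size_um Image geometry per sample.
#' @param noise_sd,psf_sigma_um Rendering noise/blur (see [render_sample()]).
#' @param out_dir If given, per-sample channel TIFFs and the ground-truth
#'   table (`ground_truth.csv`) are written there and the in-memory samples
#'   are dropped (the table then carries the file paths).
#' @return List with `table` (tibble: `id`, `age`, the drawn parameters, and
#'   the realized true fractions) and `samples` (list of
#'   `histology_sample`, `NULL` when `out_dir` is used).
#' @export
generate_cohort <- function(n = 44, parameter_distributions = NULL, seed = 1,
                            width_px = 512, height_px = 512,
                            pixel_size_um = 0.5, noise_sd = 0,
                            psf_sigma_um = 0, out_dir = NULL) {
  abort_if(n < 1, "n must be at least 1")
  dists <- default_cohort_distributions()
  if (!is.null(parameter_distributions)) {
    for (nm in names(parameter_distributions))
      dists[[nm]] <- parameter_distributions[[nm]]
  }
  for (nm in names(dists)) {
    rg <- dists[[nm]]$range
    abort_if(is.null(rg) || length(rg) != 2 || any(!is.finite(rg)),
             paste0("distribution '", nm, "' must declare a finite range"))
  }
  draws <- with_seed(seed, {
    age <- sort(dists$age$sample(n))
    out <- tibble::tibble(id = seq_len(n), age = age)
    for (nm in setdiff(names(dists), "age")) {
      x <- dists[[nm]]$sample(n, age)
      rg <- dists[[nm]]$range
      abort_if(any(x < rg[1] - 1e-9 | x > rg[2] + 1e-9),
               paste0("distribution '", nm,
                      "' produced values outside its declared range"))
      out[[nm]] <- x
    }
    out
  })

  samples <- vector("list", n)
  realized <- vector("list", n)
  paths <- character(n)
  for (i in seq_len(n)) {
    si <- child_seed(seed, i)
    layout <- generate_layout(width_px, height_px, pixel_size_um,
                              fibrosis_fraction = draws$patch_fraction[i],
                              seed = si)
    gt <- ground_truth(cx43_fraction_pct = draws$cx43_fraction_pct[i],
                       lateral_fraction_pct = draws$lateral_fraction_pct[i],
                       cx43_clustering = draws$cx43_clustering[i],
                       lipofuscin_pct = draws$lipofuscin_pct[i],
                       seed = si + 1L)
    smp <- render_sample(layout, gt, noise_sd = noise_sd,
                         psf_sigma_um = psf_sigma_um)
    realized[[i]] <- tibble::as_tibble(
      setNames(smp$realized, paste0("true_", names(smp$realized))))
    if (is.null(out_dir)) {
      samples[[i]] <- smp
    } else {
      p <- write_histology_sample(smp, out_dir,
                                  prefix = sprintf("sample_%03d", i))
      paths[i] <- dirname(p[1])
      samples[i] <- list(NULL)
    }
  }
  table <- dplyr::bind_cols(draws, dplyr::bind_rows(realized))
  table$seed <- child_seed(seed, seq_len(n)) + 1L
  if (!is.null(out_dir)) {
    table$dir <- out_dir
    utils::write.csv(table, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    samples <- NULL
  }
  list(table = table, samples = samples)
}
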