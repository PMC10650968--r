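#' Build a 2D ventricular tissue mesh
#'
#' Constructs a regular square grid of nodes with an epicardial background and
#' (optionally) three circular midmyocardial islands, the geometry used for
#' the tissue-level simulations. The 5-cm mesh is the 3-cm layout rescaled, so
#' island positions and radii scale with `size_cm`.
#'
#' @param size_cm Physical side length in cm (3 and 5 reproduce the reference
#'   geometries; any positive multiple of `dx_cm` is accepted).
#' @param dx_cm Node spacing in cm. The default 0.025 makes the 3-cm mesh
#'   121x121 nodes, so the default stimulus strip spans the full left edge
#'   with a 0.5-cm depth (20 columns).
#' @param islands `"default"` for three mid islands (radius 0.15 x `size_cm`,
#'   fixed fractional centers), `NULL` for an all-epicardial mesh, or a data
#'   frame with columns `x_frac`, `y_frac` (fractional center coordinates in
#'   (0,1)) and `r_cm` (radius).
#' @param baseline_DL Control longitudinal diffusion coefficient, cm^2/ms.
#' @param baseline_ratio Control transverse-to-longitudinal ratio.
#' @param stim_depth_cm Depth of the protected left-edge stimulus strip;
#'   nodes inside it are never converted to fibroblasts. Use 0 for no
#'   protected region.
#' @param seed Integer seed recorded on the mesh (used by the stochastic
#'   scenario operations when they are not given their own seed).
#'
#' @return A `tissue_mesh` object: list with `celltype` (integer matrix,
#'   0 = epi, 1 = mid, 2 = fibroblast), `DL` (per-node longitudinal diffusion,
#'   cm^2/ms), `ratio`, `dx_cm`, `size_cm`, `protected` (logical matrix),
#'   `islands`, `seed` and a `scenario` provenance list.
#' @export
#' @examples
#' m <- build_mesh(3)
#' dim(m$celltype)
build_mesh <- function(size_cm = 3, dx_cm = 0.025, islands = "default",
                       baseline_DL = 0.0013, baseline_ratio = 0.19,
                       stim_depth_cm = size_cm / 6, seed = NULL) {
  abort_if(size_cm <= 0 || dx_cm <= 0, "size_cm and dx_cm must be positive")
  nseg <- size_cm / dx_cm
  abort_if(abs(nseg - round(nseg)) > 1e-9, "dx_cm must divide size_cm")
  n <- as.integer(round(nseg)) + 1L
  if (identical(islands, "default")) {
    islands <- tibble::tibble(
      x_frac = c(0.25, 0.60, 0.75),
      y_frac = c(0.70, 0.30, 0.75),
      r_cm = 0.15 * size_cm)
  }
  celltype <- matrix(0L, n, n)
  if (!is.null(islands) && nrow(islands) > 0) {
    isl <- tibble::as_tibble(islands)
    abort_if(!all(c("x_frac", "y_frac", "r_cm") %in% names(isl)),
             "islands needs columns x_frac, y_frac, r_cm")
    cx <- isl$x_frac * size_cm
    cy <- isl$y_frac * size_cm
    if (nrow(isl) > 1) {
      for (i in seq_len(nrow(isl) - 1))
        for (j in (i + 1):nrow(isl)) {
          d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
          abort_if(d < isl$r_cm[i] + isl$r_cm[j], "overlapping islands")
        }
    }
    xs <- (seq_len(n) - 1) * dx_cm
    for (i in seq_len(nrow(isl))) {
      if (isl$r_cm[i] <= 0) next
      dx2 <- outer(rep(1, n), (xs - cx[i])^2)   # columns = x
      dy2 <- outer((xs - cy[i])^2, rep(1, n))   # rows = y
      celltype[dx2 + dy2 <= isl$r_cm[i]^2] <- 1L
    }
    islands <- isl
  } else {
    islands <- NULL
  }
  protected <- matrix(FALSE, n, n)
  if (stim_depth_cm > 0) {
    depth <- max(1L, as.integer(round(stim_depth_cm / dx_cm)))
    protected[, seq_len(min(depth, n))] <- TRUE
  }
  structure(list(celltype = celltype,
                 DL = matrix(baseline_DL, n, n),
                 ratio = baseline_ratio,
                 dx_cm = dx_cm, size_cm = size_cm,
                 baseline_DL = baseline_DL, baseline_ratio = baseline_ratio,
                 protected = protected, islands = islands, seed = seed,
                 scenario = list()),
            class = "tissue_mesh")
}

#' Build a 1D cable mesh
#'
#' A single row of epicardial nodes, used for conduction-velocity calibration
#' and convergence studies where the transverse direction is irrelevant.
#'
#' @param length_cm Cable length in cm.
#' @param dx_cm Node spacing in cm.
#' @inheritParams build_mesh
#' @return A `tissue_mesh` with one row of nodes.
#' @export
build_cable <- function(length_cm = 3, dx_cm = 0.025, baseline_DL = 0.0013,
                        baseline_ratio = 0.19,
                        stim_depth_cm = length_cm / 6, seed = NULL) {
  abort_if(length_cm <= 0 || dx_cm <= 0, "dimensions must be positive")
  nseg <- length_cm / dx_cm
  abort_if(abs(nseg - round(nseg)) > 1e-9, "dx_cm must divide length_cm")
  n <- as.integer(round(nseg)) + 1L
  protected <- matrix(FALSE, 1, n)
  if (stim_depth_cm > 0)
    protected[, seq_len(min(max(1L, as.integer(round(stim_depth_cm / dx_cm))),
                            n))] <- TRUE
  structure(list(celltype = matrix(0L, 1, n),
                 DL = matrix(baseline_DL, 1, n),
                 ratio = baseline_ratio, dx_cm = dx_cm, size_cm = length_cm,
                 baseline_DL = baseline_DL, baseline_ratio = baseline_ratio,
                 protected = protected, islands = NULL, seed = seed,
                 scenario = list()),
            class = "tissue_mesh")
}

#' @export
print.tissue_mesh <- function(x, ...) {
  d <- dim(x$celltype)
  cat("<tissue_mesh> ", d[1], "x", d[2], " nodes, dx ", x$dx_cm, " cm (",
      x$size_cm, " cm)\n", sep = "")
  n <- length(x$celltype)
  cat("  node types: epi ", sum(x$celltype == 0L), ", mid ",
      sum(x$celltype == 1L), ", fibroblast ", sum(x$celltype == 2L), "\n",
      sep = "")
  cat("  D_L: ", format(min(x$DL), digits = 4), "..",
      format(max(x$DL), digits = 4), " cm^2/ms, ratio ", x$ratio, "\n",
      sep = "")
  if (length(x$scenario))
    cat("  scenario:", paste(names(x$scenario), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a conductivity scenario to a mesh
#'
#' Encodes the two deterministic experimental axes: reduced CX43 amount as a
#' proportional reduction of the longitudinal conductivity (DIF), and CX43
#' lateralization as an increased transverse-to-longitudinal ratio with the
#' conductivity sum conserved (LAT). With `conserve_sum` the baseline sum
#' `S = D_L0 (1 + r0)` is first scaled by the DIF factor and then split as
#' `D_L = S / (1 + r)`, `D_T = S r / (1 + r)`. Without it, `D_L` is scaled
#' directly and the ratio is set as given (the sum is not conserved).
#'
#' Note: this resets `DL` uniformly, so apply it before
#' [assign_heterogeneity()].
#'
#' @param mesh A `tissue_mesh`.
#' @param dif_reduction_pct Percent reduction of longitudinal conductivity,
#'   in \[0, 90\] (0, 10, 20, 30, 40 are the study values).
#' @param lat_ratio Transverse-to-longitudinal ratio in (0, 1\]
#'   (0.19 control; 0.23-0.35 are the study values).
#' @param conserve_sum Keep `D_L + D_T` at the (DIF-scaled) baseline sum.
#' @return The modified `tissue_mesh`.
#' @export
#' @examples
#' m <- set_conductivity_scenario(build_mesh(3), dif_reduction_pct = 40)
#' m$DL[1, 1]  # 0.00078
set_conductivity_scenario <- function(mesh, dif_reduction_pct = 0,
                                      lat_ratio = mesh$baseline_ratio,
                                      conserve_sum = TRUE) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  abort_if(dif_reduction_pct < 0 || dif_reduction_pct > 90,
           "dif_reduction_pct must be in [0, 90]")
  abort_if(lat_ratio <= 0 || lat_ratio > 1, "lat_ratio must be in (0, 1]")
  fac <- 1 - dif_reduction_pct / 100
  if (conserve_sum) {
    S <- mesh$baseline_DL * (1 + mesh$baseline_ratio) * fac
    DL <- S / (1 + lat_ratio)
  } else {
    DL <- mesh$baseline_DL * fac
  }
  mesh$DL[] <- DL
  mesh$ratio <- lat_ratio
  mesh$scenario$conductivity <- list(dif_reduction_pct = dif_reduction_pct,
                                     lat_ratio = lat_ratio,
                                     conserve_sum = conserve_sum)
  mesh
}

#' Convert a random subset of nodes to fibroblasts
#'
#' Realizes a fibrosis scenario by giving `round(f N / 100)` of the eligible
#' nodes (non-fibroblast nodes outside the protected stimulus strip, N =
#' number of eligible nodes) the membrane properties of fibroblasts, chosen
#' uniformly at random without replacement. Edges touching fibroblast nodes
#' carry one third of the myocyte-myocyte coupling in the solver.
#'
#' @param mesh A `tissue_mesh`.
#' @param fib_fraction_pct Percent of eligible nodes to convert, in
#'   \[0, 100\] (7, 11, 15, 19 are the study values).
#' @param seed Integer seed for the random choice (defaults to the mesh seed).
#' @return The modified `tissue_mesh`.
#' @export
assign_fibrosis <- function(mesh, fib_fraction_pct, seed = mesh$seed) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  abort_if(fib_fraction_pct < 0 || fib_fraction_pct > 100,
           "fib_fraction_pct must be in [0, 100]")
  eligible <- which(mesh$celltype != 2L & !mesh$protected)
  n_conv <- as.integer(round(fib_fraction_pct * length(eligible) / 100))
  abort_if(n_conv > 0 && length(eligible) == 0,
           "stimulus region cannot be preserved")
  if (n_conv > 0) {
    chosen <- with_seed(seed, sample(eligible, n_conv))
    mesh$celltype[chosen] <- 2L
  }
  mesh$scenario$fibrosis <- list(fib_fraction_pct = fib_fraction_pct,
                                 n_converted = n_conv, seed = seed)
  mesh
}

#' Map a CX43 intensity image onto heterogeneous conductivities
#'
#' Builds a 20-bin histogram of the intensity image, assigns each bin a
#' candidate longitudinal diffusion coefficient proportional to its bin-center
#' intensity relative to the bin holding the median intensity (which maps to
#' the mesh's current control value), apportions the node population across
#' bins in proportion to the bin occupancies (largest-remainder rounding),
#' permutes the values uniformly over the nodes, and finally rescales all
#' values by one global factor so that the summed longitudinal diffusion
#' equals the homogeneous mesh's sum exactly.
#'
#' @param mesh A `tissue_mesh`.
#' @param cx43_intensity_image Numeric matrix of CX43 channel intensities.
#' @param n_bins Number of histogram bins (20 reproduces the reference
#'   procedure).
#' @param seed Integer seed for the random assignment.
#' @return The modified `tissue_mesh`.
#' @export
assign_heterogeneity <- function(mesh, cx43_intensity_image, n_bins = 20,
                                 seed = mesh$seed) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  img <- cx43_intensity_image
  abort_if(!is.numeric(img), "intensity image must be numeric")
  rng <- range(img)
  abort_if(rng[1] == rng[2], "degenerate histogram")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin_of <- pmin(pmax(findInterval(img, breaks, rightmost.closed = TRUE),
                      1L), n_bins)
  counts <- tabulate(bin_of, nbins = n_bins)
  med_bin <- pmin(pmax(findInterval(median(img), breaks,
                                    rightmost.closed = TRUE), 1L), n_bins)
  dl_bin <- mesh$baseline_DL * centers / centers[med_bin]
  abort_if(any(dl_bin[counts > 0] <= 0),
           "bin-center map produced non-positive diffusion")

  # apportion the N nodes across bins by largest remainder
  N <- length(mesh$DL)
  quota <- counts / sum(counts) * N
  n_k <- floor(quota)
  rem <- N - sum(n_k)
  if (rem > 0) {
    ord <- order(quota - n_k, decreasing = TRUE)
    n_k[ord[seq_len(rem)]] <- n_k[ord[seq_len(rem)]] + 1
  }
  vals <- rep(dl_bin, times = n_k)
  target <- sum(mesh$DL)
  vals <- vals * (target / sum(vals))
  mesh$DL[] <- with_seed(seed, sample(vals))
  mesh$scenario$heterogeneity <- list(n_bins = n_bins, seed = seed,
                                      med_bin = med_bin,
                                      dl_values = sort(unique(vals)))
  mesh
}

#' Serialize / restore a tissue mesh
#'
#' Round-trip container for meshes: all scenario operations commute with
#' `write_mesh()` followed by `read_mesh()`.
#'
#' @param mesh A `tissue_mesh`.
#' @param path File path (conventionally `.rds`).
#' @return `write_mesh()` returns `path` invisibly; `read_mesh()` returns the
#'   `tissue_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  abort_if(!inherits(mesh, "tissue_mesh"), "mesh must be a tissue_mesh")
  saveRDS(mesh, path, version = 3)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  mesh <- readRDS(path)
  abort_if(!inherits(mesh, "tissue_mesh"), "file does not contain a mesh")
  mesh
}
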