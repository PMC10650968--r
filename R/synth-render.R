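#' Ground truth for a synthetic sample
#'
#' Bundles the true, generator-side values of every quantity the
#' histomorphometry pipeline later measures: the CX43 area fraction relative
#' to cardiomyocyte area, the lateral CX43 fraction, the dimensionless
#' spatial-clustering control (0 = dispersed puncta, 1 = maximally clustered
#' plaques; larger values yield larger measured CX43_H), and the lipofuscin
#' fraction. The seed makes any sample exactly regenerable.
#'
#' @param cx43_fraction_pct True CX43 area as % of cardiomyocyte area.
#' @param lateral_fraction_pct True lateral (middle-two-quarters) share of
#'   the CX43 signal, %.
#' @param cx43_clustering Clustering control in \[0, 1\].
#' @param lipofuscin_pct True lipofuscin area as % of the autofluorescent
#'   (whole-tissue) area.
#' @param cx43_intensity Mean CX43 punctum intensity, n.f.u. (16-bit scale).
#' @param seed Integer seed for the stochastic placement.
#' @return A `ground_truth` object (named list).
#' @export
ground_truth <- function(cx43_fraction_pct = 2.73,
                         lateral_fraction_pct = 18.78,
                         cx43_clustering = 0.5, lipofuscin_pct = 2,
                         cx43_intensity = 11700, seed = 1) {
  for (v in c(cx43_fraction_pct, lateral_fraction_pct, lipofuscin_pct))
    abort_if(v < 0 || v > 100, "fractions must be in [0, 100]")
  abort_if(cx43_clustering < 0 || cx43_clustering > 1,
           "cx43_clustering must be in [0, 1]")
  structure(list(cx43_fraction_pct = cx43_fraction_pct,
                 lateral_fraction_pct = lateral_fraction_pct,
                 cx43_clustering = cx43_clustering,
                 lipofuscin_pct = lipofuscin_pct,
                 cx43_intensity = cx43_intensity, seed = seed),
            class = "ground_truth")
}

# largest-remainder apportionment of `total` across weights `w`
apportion <- function(total, w) {
  if (total == 0 || length(w) == 0) return(rep(0L, length(w)))
  q <- w / sum(w) * total
  n <- floor(q)
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(q - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  as.integer(n)
}

# choose exactly `b` pixels from a zone (linear indices `idx`) with a
# Neyman-Scott-style punctum process; h in [0,1] controls clustering
place_in_zone <- function(idx, b, h, b_iso = NULL) {
  nz <- length(idx)
  if (b <= 0) return(integer())
  abort_if(b > nz, "CX43 budget infeasible")
  if (is.null(b_iso)) b_iso <- as.integer(round(0.12 * b))
  b_iso <- min(b_iso, b)
  # Neyman-Scott knob: clustering h concentrates the plaque sites (fewer
  # sites, tighter spread), leaving growing empty space. A fixed share of the
  # pixel budget is spent on genuinely isolated single-pixel puncta whose
  # nearest plaque therefore sits increasingly far away as h grows — that
  # empty-space distance is what drives the nearest-neighbour SD (CX43_H) up.
  k_sites <- max(1L, as.integer(round((1 - h) * 10)) + 1L)
  sigma <- 2 + 30 * (1 - h)                             # site spread (px)
  chosen <- logical(nz)
  n_chosen <- 0L
  sites <- sample.int(nz, min(k_sites, nz))
  # pixel coordinates of the zone (caller passes idx with attribute ny)
  ny <- attr(idx, "ny")
  zy <- ((idx - 1L) %% ny); zx <- ((idx - 1L) %/% ny)
  guard <- 0L
  while (n_chosen < b - b_iso && guard < 20L * b + 100L) {
    guard <- guard + 1L
    s <- sites[sample.int(length(sites), 1L)]
    cxp <- zx[s] + rnorm(1, 0, sigma)
    cyp <- zy[s] + rnorm(1, 0, sigma)
    r <- runif(1, 1, 2)                      # punctum disk, 1-2 um diameter
    d2 <- (zx - cxp)^2 + (zy - cyp)^2
    hit <- which(d2 <= r^2 & !chosen)
    if (length(hit)) {
      take <- head(hit, b - b_iso - n_chosen)
      chosen[take] <- TRUE
      n_chosen <- n_chosen + length(take)
    }
  }
  # isolated singles: prefer pixels whose 8-neighbourhood holds nothing
  # already chosen (otherwise their NN distance would collapse to 1)
  offs <- as.vector(outer(c(-1L, 0L, 1L), c(-ny, 0L, ny), `+`))
  blocked <- unique(as.vector(outer(idx[chosen], offs, `+`)))
  while (n_chosen < b) {
    free <- which(!chosen)
    if (length(free) == 0) break
    iso <- free[!(idx[free] %in% blocked)]
    if (length(iso) == 0) iso <- free
    take <- if (length(iso) == 1L) iso else iso[sample.int(length(iso), 1L)]
    chosen[take] <- TRUE
    n_chosen <- n_chosen + 1L
    blocked <- c(blocked, idx[take] + offs)
  }
  idx[chosen]
}

#' Render a multi-channel histology sample
#'
#' Converts a layout plus ground truth into the five registered 16-bit
#' channels (SERCA2 inside cells; WGA over interstitium, ribbons and fibrotic
#' patches; punctate CX43 split between polar and lateral membrane zones and
#' clustered per the heterogeneity control; granular lipofuscin inside cells;
#' autofluorescence over all tissue) together with the exact generation masks.
#' Pixel budgets for CX43 and lipofuscin are hit exactly, so the morphometric
#' ground truth is recovered by construction on noise-free renders.
#'
#' @param layout A `tissue_layout`.
#' @param gt A `ground_truth`.
#' @param noise_sd Gaussian read-noise SD (n.f.u.); a Poisson-like
#'   `sqrt(1 + I/5000)` scaling is applied on top. 0 disables noise.
#' @param psf_sigma_um Gaussian blur SD in um. 0 disables blurring.
#' @return A `histology_sample`: `channels` and `masks` (named lists over
#'   serca2, wga, cx43, lipofuscin, autofluorescence), `pixel_size_um`,
#'   `ground_truth`, and realized truth values in `$realized`.
#' @export
render_sample <- function(layout, gt, noise_sd = 0, psf_sigma_um = 0) {
  abort_if(!inherits(layout, "tissue_layout"), "layout must be a tissue_layout")
  abort_if(!inherits(gt, "ground_truth"), "gt must be a ground_truth")
  ny <- layout$dims[["ny"]]; nx <- layout$dims[["nx"]]
  label <- layout$label
  cell_mask <- label > 0L
  n_cell <- sum(cell_mask)
  abort_if(n_cell == 0, "layout has no cells")
  wga_mask <- !cell_mask
  auto_mask <- matrix(TRUE, ny, nx)

  with_seed(gt$seed, {
    h <- gt$cx43_clustering
    lat <- gt$lateral_fraction_pct / 100
    B <- round(gt$cx43_fraction_pct / 100 * n_cell)

    cells <- layout$cells
    ncell <- nrow(cells)
    idx_by_cell <- split(which(cell_mask), label[cell_mask])

    # per-cell zones from the ideal rectangle geometry (3-px margin keeps
    # measured quarters and true zones consistent)
    margin <- 3
    zones <- vector("list", ncell)
    for (i in seq_len(ncell)) {
      cid <- as.character(cells$id[i])
      idx <- idx_by_cell[[cid]]
      if (is.null(idx)) idx <- integer()
      y <- ((idx - 1L) %% ny) + 1L
      x <- ((idx - 1L) %/% ny) + 1L
      th <- cells$angle_deg[i] * pi / 180
      u <- (x - cells$cx_px[i]) * cos(th) + (y - cells$cy_px[i]) * sin(th)
      v <- -(x - cells$cx_px[i]) * sin(th) + (y - cells$cy_px[i]) * cos(th)
      hl <- cells$half_len_px[i]; hw <- cells$half_wid_px[i]
      pol <- idx[abs(u) > hl / 2 + margin]
      latz <- idx[abs(u) < hl / 2 - margin & abs(v) > hw - 4]
      attr(pol, "ny") <- ny; attr(latz, "ny") <- ny
      zones[[i]] <- list(polar = pol, lateral = latz)
    }
    cap <- vapply(zones, function(z) length(z$polar) + length(z$lateral),
                  numeric(1))
    abort_if(B > sum(cap), "CX43 budget infeasible")

    # Split the budget into clustered plaques and isolated singles. Plaque
    # budgets use area x gamma weights (small gamma shape concentrates the
    # signal on few cells: tissue-scale clustering); the singles budget is
    # spread by zone area over ALL cells, so at high clustering many singles
    # land in plaque-free cells, far from any other punctum.
    B_iso <- as.integer(round(0.12 * B))
    alpha <- 10^(1.5 - 2.5 * h)
    w <- cells$area_px * rgamma(ncell, shape = alpha, rate = 1)
    if (all(w == 0)) w <- cells$area_px
    b <- apportion(B - B_iso, w) + apportion(B_iso, cap)
    # cap at zone capacity, redistributing any overflow
    repeat {
      b <- pmin(b, cap)
      deficit <- B - sum(b)
      if (deficit == 0L) break
      room <- cap - b
      add <- apportion(deficit, room)
      b <- b + pmin(add, room)
    }
    b_iso_cell <- pmin(apportion(B_iso, cap), b)

    cx43_mask <- matrix(FALSE, ny, nx)
    for (i in seq_len(ncell)) {
      if (b[i] == 0) next
      b_lat <- round(b[i] * lat)
      b_pol <- b[i] - b_lat
      np <- length(zones[[i]]$polar); nl <- length(zones[[i]]$lateral)
      if (b_lat > nl) { b_pol <- b_pol + (b_lat - nl); b_lat <- nl }
      if (b_pol > np) { b_lat <- min(nl, b_lat + (b_pol - np)); b_pol <- np }
      iso_lat <- as.integer(round(b_iso_cell[i] * b_lat / b[i]))
      iso_pol <- b_iso_cell[i] - iso_lat
      cx43_mask[place_in_zone(zones[[i]]$polar, b_pol, h, iso_pol)] <- TRUE
      cx43_mask[place_in_zone(zones[[i]]$lateral, b_lat, h, iso_lat)] <- TRUE
    }

    # lipofuscin granules inside cells, exact budget
    lipo_mask <- matrix(FALSE, ny, nx)
    Bl <- round(gt$lipofuscin_pct / 100 * sum(auto_mask))
    abort_if(Bl > n_cell, "lipofuscin budget infeasible")
    if (Bl > 0) {
      cell_idx <- which(cell_mask)
      n_lipo <- 0L
      while (n_lipo < Bl) {
        ctr <- cell_idx[sample.int(n_cell, 1L)]
        cyp <- ((ctr - 1L) %% ny) + 1L
        cxp <- ((ctr - 1L) %/% ny) + 1L
        r <- runif(1, 2, 4)
        px <- ellipse_pixels(cxp, cyp, r, r, 0, ny, nx)
        px <- px[cell_mask[px] & !lipo_mask[px]]
        if (length(px) > Bl - n_lipo) px <- sample(px, Bl - n_lipo)
        lipo_mask[px] <- TRUE
        n_lipo <- n_lipo + length(px)
      }
    }

    # intensity channels (16-bit n.f.u.)
    cellfac <- runif(max(cells$id, 1L), 0.85, 1.15)
    serca2 <- matrix(0, ny, nx)
    serca2[cell_mask] <- 20000 * cellfac[label[cell_mask]]
    wga <- matrix(0, ny, nx)
    wga[wga_mask] <- 15000 * runif(sum(wga_mask), 0.9, 1.1)
    cx43 <- matrix(0, ny, nx)
    ncx <- sum(cx43_mask)
    if (ncx > 0)
      cx43[cx43_mask] <- gt$cx43_intensity * exp(rnorm(ncx, 0, 0.25))
    lipo <- matrix(0, ny, nx)
    if (sum(lipo_mask) > 0)
      lipo[lipo_mask] <- 18000 * runif(sum(lipo_mask), 0.9, 1.1)
    auto <- matrix(7000 * runif(ny * nx, 0.9, 1.1), ny, nx)

    channels <- list(serca2 = serca2, wga = wga, cx43 = cx43,
                     lipofuscin = lipo, autofluorescence = auto)
    if (psf_sigma_um > 0) {
      sp <- psf_sigma_um / layout$pixel_size_um
      channels <- lapply(channels, function(m)
        matrix(as.vector(EBImage::gblur(m, sigma = sp)), ny, nx))
    }
    if (noise_sd > 0) {
      channels <- lapply(channels, function(m)
        m + rnorm(length(m), 0, noise_sd * sqrt(1 + m / 5000)))
    }
    channels <- lapply(channels, function(m) {
      m[m < 0] <- 0; m[m > 65535] <- 65535
      round(m)
    })

    masks <- list(serca2 = cell_mask, wga = wga_mask, cx43 = cx43_mask,
                  lipofuscin = lipo_mask, autofluorescence = auto_mask)
    realized <- list(
      cx43_fraction_pct = 100 * sum(cx43_mask) / n_cell,
      fibrosis_pct = 100 * sum(wga_mask & !cell_mask) /
        sum(wga_mask | cell_mask),
      lipofuscin_pct = 100 * sum(lipo_mask) / sum(auto_mask))
    structure(list(channels = channels, masks = masks,
                   pixel_size_um = layout$pixel_size_um,
                   ground_truth = gt, realized = realized,
                   provenance = list(noise_sd = noise_sd,
                                     psf_sigma_um = psf_sigma_um,
                                     layout_seed = layout$seed)),
              class = "histology_sample")
  })
}

#' @export
print.histology_sample <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<histology_sample> ", d[1], "x", d[2], " px at ", x$pixel_size_um,
      " um/px, channels: ", paste(names(x$channels), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a histology sample as per-channel TIFFs
#'
#' Each channel is written as a 16-bit single-page grayscale TIFF named
#' `<prefix>_<channel>.tif`.
#'
#' @param sample A `histology_sample`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return `write_histology_sample()` returns the file paths invisibly.
#' @export
write_histology_sample <- function(sample, dir, prefix = "sample") {
  abort_if(!inherits(sample, "histology_sample"),
           "sample must be a histology_sample")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (ch in names(sample$channels)) {
    p <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    tiff::writeTIFF(sample$channels[[ch]] / 65535, p, bits.per.sample = 16)
    paths[ch] <- p
  }
  invisible(paths)
}

#' @rdname write_histology_sample
#' @param paths Named character vector of channel TIFF paths (names as in
#'   `channels`).
#' @param pixel_size_um Pixel size of the stored images.
#' @return `read_histology_sample()` returns a `histology_sample` without
#'   masks (derive them with [binarize()]).
#' @export
read_histology_sample <- function(paths, pixel_size_um) {
  channels <- lapply(paths, function(p) {
    m <- tiff::readTIFF(p)
    abort_if(!is.matrix(m), "expected single-page grayscale TIFF")
    round(m * 65535)
  })
  structure(list(channels = channels, masks = NULL,
                 pixel_size_um = pixel_size_um,
                 ground_truth = NULL, realized = NULL,
                 provenance = list(paths = paths)),
            class = "histology_sample")
}
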