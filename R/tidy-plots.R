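#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mesh_node_tibble <- function(mesh) {
  ny <- nrow(mesh$celltype); nx <- ncol(mesh$celltype)
  tibble::tibble(
    row = rep(seq_len(ny), times = nx),
    col = rep(seq_len(nx), each = ny),
    x_cm = (rep(seq_len(nx), each = ny) - 1) * mesh$dx_cm,
    y_cm = (rep(seq_len(ny), times = nx) - 1) * mesh$dx_cm,
    celltype = factor(as.vector(mesh$celltype), levels = 0:2,
                      labels = c("epi", "mid", "fibroblast")),
    DL = as.vector(mesh$DL))
}

#' @rdname tidy
#' @param x Object to tidy.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tissue_mesh <- function(x, ...) mesh_node_tibble(x)

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.monodomain_result <- function(x, ...) {
  ny <- nrow(x$act); nx <- ncol(x$act)
  tibble::tibble(
    row = rep(seq_len(ny), times = nx),
    col = rep(seq_len(nx), each = ny),
    celltype = as.vector(x$celltype),
    act_ms = as.vector(x$act),
    repol_ms = as.vector(x$repol),
    apd_ms = as.vector(x$repol - x$act),
    dvdt_max = as.vector(x$dvdtmax),
    v_peak = as.vector(x$vpeak))
}

#' Tidy and summary methods
#'
#' `tidy()` returns node-level tibbles for meshes, simulation results and
#' conduction-velocity fields, and coefficient-style rows for statistical
#' tests. `glance()` returns one-row summaries.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.cv_field <- function(x, ...) {
  ny <- nrow(x$speed); nx <- ncol(x$speed)
  tibble::tibble(
    row = rep(seq_len(ny), times = nx),
    col = rep(seq_len(nx), each = ny),
    vx_cm_s = as.vector(x$vx),
    vy_cm_s = as.vector(x$vy),
    speed_cm_s = as.vector(x$speed))
}

#' @rdname tidy
#' @exportS3Method generics::tidy
tidy.cohort_test <- function(x, ...) {
  if (x$test == "spearman") {
    tibble::tibble(estimate = x$rho, statistic = x$rho, p.value = x$p,
                   method = paste("spearman,", x$method))
  } else {
    tibble::tibble(estimate = x$U, statistic = x$U, p.value = x$p,
                   method = paste("mann_whitney,", x$method),
                   alternative = x$alternative)
  }
}

#' @rdname tidy
#' @exportS3Method generics::glance
glance.cohort_test <- function(x, ...) {
  tibble::tibble(p.value = x$p, n = sum(x$n), method = x$method,
                 test = x$test)
}

#' @rdname tidy
#' @exportS3Method generics::glance
glance.monodomain_result <- function(x, ...) {
  apd <- x$repol - x$act
  tibble::tibble(
    n_activated = sum(is.finite(x$act)),
    n_nodes = length(x$act),
    mean_apd_ms = mean(apd[is.finite(apd) & x$celltype != 2]),
    duration_ms = x$duration_ms,
    t_end_ms = x$t_end,
    n_upcross = sum(x$upcross_count))
}

#' @rdname tidy
#' @exportS3Method generics::glance
glance.cv_field <- function(x, ...) {
  tibble::tibble(cv_median_cm_s = x$cv_median,
                 n_used = x$n_used,
                 n_singular = x$n_singular)
}

#' Plot methods
#'
#' `autoplot()` draws a labelled ggplot: node types and longitudinal
#' diffusion for a mesh, the activation map for a simulation result, the
#' local speed field for a CV fit, and the channel images of a histology
#' sample.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @name autoplot
NULL

#' @rdname autoplot
#' @param fill `"celltype"` or `"DL"`.
#' @exportS3Method ggplot2::autoplot
autoplot.tissue_mesh <- function(object, fill = c("celltype", "DL"), ...) {
  fill <- match.arg(fill)
  df <- mesh_node_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_cm, y = .data$y_cm,
                                   fill = .data[[fill]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = fill) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @param what `"activation"`, `"repolarization"` or `"apd"`.
#' @exportS3Method ggplot2::autoplot
autoplot.monodomain_result <- function(object,
                                       what = c("activation",
                                                "repolarization", "apd"),
                                       ...) {
  what <- match.arg(what)
  df <- tidy.monodomain_result(object)
  df$x_cm <- (df$col - 1) * object$dx_cm
  df$y_cm <- (df$row - 1) * object$dx_cm
  val <- switch(what, activation = "act_ms", repolarization = "repol_ms",
                apd = "apd_ms")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_cm, y = .data$y_cm,
                                   fill = .data[[val]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = paste(what, "(ms)")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.cv_field <- function(object, ...) {
  df <- tidy.cv_field(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$speed_cm_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "speed (cm/s)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot
#' @param channel Channel name (default `"cx43"`).
#' @exportS3Method ggplot2::autoplot
autoplot.histology_sample <- function(object, channel = "cx43", ...) {
  abort_if(!channel %in% names(object$channels),
           paste("no channel", channel))
  m <- object$channels[[channel]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    intensity = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = channel) +
    ggplot2::theme_minimal()
}
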