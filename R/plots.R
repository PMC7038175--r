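## Base-graphics displays: a mid-slice quiver of a flow field over its
## volume, and per-phase error curves.

#' Plot a flow field slice as a quiver over the image
#'
#' @param flow A `flow_field`.
#' @param volume Optional volume of the same shape shown underneath.
#' @param slice Axis-3 slice index for 3D fields (default middle slice).
#' @param step Arrow subsampling step in voxels.
#' @param scale Arrow length multiplier.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_flow <- function(flow, volume = NULL, slice = NULL, step = 4, scale = 2,
                      ...) {
  if (flow$ndim == 3) {
    slice <- slice %||% ceiling(flow$shape[3] / 2)
    u <- flow$u[, , slice]; v <- flow$v[, , slice]
    bg <- if (!is.null(volume)) volume[, , slice]
  } else {
    u <- flow$u; v <- flow$v
    bg <- volume
  }
  d <- dim(u)
  if (is.null(bg)) bg <- matrix(0, d[1], d[2])
  graphics::image(seq_len(d[1]), seq_len(d[2]), bg,
                  col = grDevices::gray.colors(64), xlab = "x", ylab = "y",
                  asp = 1, ...)
  xs <- seq(1, d[1], by = step)
  ys <- seq(1, d[2], by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  du <- u[cbind(gx, gy)] * scale
  dv <- v[cbind(gx, gy)] * scale
  keep <- sqrt(du^2 + dv^2) > 1e-6
  if (any(keep)) {
    graphics::arrows(gx[keep], gy[keep], gx[keep] + du[keep],
                     gy[keep] + dv[keep], length = 0.04, col = "red")
  }
  invisible(NULL)
}

#' Plot per-phase interpolation-error curves
#'
#' @param ... Named data.frames from [evaluate_sequence()]; one line each.
#' @param metric `"ie"` or `"ne"`.
#' @return Invisibly, `NULL`.
#' @export
plot_error_curves <- function(..., metric = c("ie", "ne")) {
  metric <- match.arg(metric)
  tables <- list(...)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste("series", seq_along(tables))
  }
  ymax <- max(vapply(tables, function(t) max(t[[metric]]), 0))
  first <- tables[[1]]
  graphics::plot(first$transition, first[[metric]], type = "o", pch = 16,
                 ylim = c(0, ymax * 1.05), xlab = "transition",
                 ylab = toupper(metric), col = 1)
  if (length(tables) > 1) {
    for (i in 2:length(tables)) {
      graphics::lines(tables[[i]]$transition, tables[[i]][[metric]],
                      type = "o", pch = 16, col = i)
    }
  }
  graphics::legend("topright", legend = names(tables), col = seq_along(tables),
                   lty = 1, pch = 16, bty = "n")
  invisible(NULL)
}
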