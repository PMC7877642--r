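#' Render a spatiotemporal (ST) map
#'
#' Writes a PNG raster of the diameter matrix with time on the x axis, oral
#' to anal position top to bottom on the y axis, intensity mapped to diameter
#' (dark = constricted) and a printed colour scale. Output is deterministic
#' for a fixed input.
#'
#' @inheritParams frame_times
#' @param out path of the PNG file to write.
#' @param width,height device size in pixels.
#' @return `out` invisibly.
#' @export
render_st_map <- function(dm, out, width = 1000, height = 400) {
  validate_diameter_matrix(dm)
  dir <- dirname(out)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(dm)
  invisible(out)
}

#' Plot a diameter matrix as an ST map
#'
#' @param x a [diameter_matrix()].
#' @param events optional detected-event table (from [detect_contractions()]);
#'   constriction paths are overlaid.
#' @param ... ignored.
#' @export
plot.diameter_matrix <- function(x, events = NULL, ...) {
  v <- x$values
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  pal <- grDevices::hcl.colors(128, "Grays", rev = FALSE)
  t_h <- frame_times(x) / 3600
  pos <- positions_mm(x)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(1:2, ncol = 2), widths = c(5, 1))
  graphics::par(mar = c(4, 4, 2.5, 0.5))
  graphics::image(t_h, pos, t(v), ylim = rev(range(pos)), zlim = rng,
                  col = pal, useRaster = TRUE,
                  xlab = "time (h)", ylab = "position (mm, oral at top)",
                  main = sprintf("%s (%s)", x$preparation_id, x$treatment))
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      p <- events$path[[k]]
      graphics::lines(p$t_s / 3600, p$pos_mm, col = "red", lwd = 1.5)
    }
  }
  graphics::par(mar = c(4, 1, 2.5, 3))
  scale_vals <- seq(rng[1], rng[2], length.out = 128)
  graphics::image(1, scale_vals, matrix(scale_vals, nrow = 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("diameter (mm)", side = 4, line = 2, cex = 0.8)
  invisible(x)
}
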