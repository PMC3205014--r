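#' Bull's eye rendering with significance overlays
#'
#' `bullseye_rgb()` turns a database mean map or a comparison result
#' into a deterministic RGB array; `render_bullseye()` writes it to
#' disk.  Mean maps use a thermal count palette; comparison results
#' show the |t| field in grey with significantly lower pixels in green
#' and significantly higher pixels in yellow, matching the usual
#' overlay semantics of normal-database figures.  Pixels outside the
#' disc are background (transparent in PNG output, white in PPM).
#'
#' @param x a `normal_database`, `mps_comparison`, or plain grid
#'   matrix.
#' @param zlim value range mapped onto the palette (default: the data
#'   range, or `c(0, 120)` for normalized databases).
#' @return `bullseye_rgb()`: an `grid x grid x 3` array in \[0, 1\]
#'   plus an `"alpha"` attribute (logical mask of drawn pixels).
#' @export
bullseye_rgb <- function(x, zlim = NULL) {
  thermal <- grDevices::colorRamp(
    c("#000000", "#800000", "#FF0000", "#FFA500", "#FFFF00", "#FFFFFF"))
  if (inherits(x, "normal_database")) {
    vals <- x$mean_map
    if (is.null(zlim)) zlim <- c(0, 120)
    overlay_lo <- overlay_hi <- NULL
  } else if (inherits(x, "mps_comparison")) {
    vals <- abs(x$t_map)
    if (is.null(zlim)) zlim <- c(0, max(abs(x$t_map), 1, na.rm = TRUE))
    thermal <- grDevices::colorRamp(c("#FFFFFF", "#404040"))
    overlay_lo <- x$sig_lower
    overlay_hi <- x$sig_higher
  } else {
    vals <- x
    if (is.null(zlim)) zlim <- range(vals, na.rm = TRUE)
    overlay_lo <- overlay_hi <- NULL
  }
  n <- nrow(vals)
  inside <- !is.na(vals)
  z <- pmin(pmax((vals - zlim[1]) / max(zlim[2] - zlim[1], 1e-12), 0), 1)
  rgb <- array(1, dim = c(n, n, 3))
  if (any(inside)) {
    cols <- thermal(z[inside]) / 255
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[inside] <- cols[, k]
      rgb[, , k] <- plane
    }
  }
  paint <- function(mask, col) {
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[mask] <- col[k]
      rgb[, , k] <<- plane
    }
  }
  if (!is.null(overlay_lo) && any(overlay_lo))
    paint(overlay_lo, c(0, 0.75, 0))
  if (!is.null(overlay_hi) && any(overlay_hi))
    paint(overlay_hi, c(1, 1, 0))
  attr(rgb, "alpha") <- inside
  rgb
}

#' @rdname bullseye_rgb
#' @param path output file; `.ppm` writes a plain-text PPM (bit
#'   deterministic), `.png` an upscaled PNG via the `png()` device.
#' @param scale integer pixel upscaling factor for PNG output.
#' @return `render_bullseye()`: `path`, invisibly.
#' @export
render_bullseye <- function(x, path, zlim = NULL, scale = 8L) {
  rgb <- bullseye_rgb(x, zlim = zlim)
  ext <- tolower(tools::file_ext(path))
  n <- dim(rgb)[1]
  if (ext == "ppm") {
    px <- round(255 * rgb)
    body <- vapply(seq_len(n), function(i)
      paste(as.vector(t(cbind(px[i, , 1], px[i, , 2], px[i, , 3]))),
            collapse = " "), character(1))
    writeLines(c("P3", paste(n, n), "255", body), path)
  } else if (ext == "png") {
    alpha <- attr(rgb, "alpha")
    hex <- matrix(grDevices::rgb(rgb[, , 1], rgb[, , 2], rgb[, , 3],
                                 alpha = as.numeric(alpha)), n, n)
    grDevices::png(path, width = n * scale, height = n * scale,
                   bg = "transparent")
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(hex), 0, 0, 1, 1,
                          interpolate = FALSE)
  } else {
    stop("unsupported output format '.", ext, "' (use .png or .ppm)",
         call. = FALSE)
  }
  invisible(path)
}
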