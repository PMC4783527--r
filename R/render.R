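#' @title Rendering: one scene graph, six file formats
#' @description
#' The multi-format adaptor: [render()] serializes a scene to any of the
#' three vector formats (SVG, EPS, PDF — deterministic, hand-written) or
#' rasterizes it to PNG, JPEG or BMP through the cairo graphics devices at a
#' requested resolution.  Raster pixel dimensions are exactly
#' \code{round(canvas_pt * dpi / 72)}.
#' @name synviz-render
NULL

VECTOR_FORMATS <- c("svg", "eps", "pdf")
RASTER_FORMATS <- c("png", "jpeg", "bmp")

## ---- raster backend --------------------------------------------------------

draw_primitive_base <- function(p) {
  st <- p$style
  if (p$kind == "segment") {
    graphics::segments(p$geometry$x1, p$geometry$y1, p$geometry$x2,
                       p$geometry$y2,
                       col = style_field(p, "stroke", "#000000"),
                       lwd = style_field(p, "stroke_width", 1) * 96 / 72)
    return(invisible())
  }
  if (p$kind == "text") {
    g <- p$geometry
    adj <- switch(g$anchor, start = c(0, 0.5), end = c(1, 0.5), c(0.5, 0.5))
    graphics::text(g$x, g$y, g$text, srt = -g$rotation, adj = adj,
                   col = style_field(p, "fill", "#000000"),
                   cex = st$font_size / graphics::par("ps"))
    return(invisible())
  }
  pts <- primitive_outline(p)
  fill <- grDevices::adjustcolor(style_field(p, "fill", "#000000"),
                                 alpha.f = style_field(p, "opacity", 1))
  stroke <- style_field(p, "stroke", NA)
  graphics::polygon(pts[, 1L], pts[, 2L], col = fill,
                    border = if (is.na(stroke)) NA else stroke,
                    lwd = style_field(p, "stroke_width", 1) * 96 / 72)
  invisible()
}

write_raster <- function(scene, path, format, dpi, quality = 92) {
  px_w <- round(scene$width * dpi / 72)
  px_h <- round(scene$height * dpi / 72)
  switch(format,
    png = grDevices::png(path, width = px_w, height = px_h, res = dpi,
                         type = "cairo", bg = scene$background),
    jpeg = grDevices::jpeg(path, width = px_w, height = px_h, res = dpi,
                           type = "cairo", quality = quality,
                           bg = scene$background),
    bmp = grDevices::bmp(path, width = px_w, height = px_h, res = dpi,
                         type = "cairo", bg = scene$background))
  ok <- FALSE
  on.exit({
    grDevices::dev.off()
    if (!ok && file.exists(path)) unlink(path)
  })
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  # canvas convention: origin top-left, y downward, units = points
  graphics::plot.window(xlim = c(0, scene$width),
                        ylim = c(scene$height, 0))
  graphics::rect(0, scene$height, scene$width, 0, col = scene$background,
                 border = NA)
  for (p in scene$primitives) draw_primitive_base(p)
  ok <- TRUE
  invisible(path)
}

## ---- public API ------------------------------------------------------------

#' Render a scene to a file
#'
#' @param scene a \code{scene} from [layout_to_scene()].
#' @param out_format one of \code{svg}, \code{eps}, \code{pdf} (vector) or
#'   \code{png}, \code{jpeg}, \code{bmp} (raster).
#' @param path output file path.
#' @param raster_dpi resolution for the raster formats; pixel dimensions are
#'   \code{round(canvas * dpi / 72)}.
#' @param jpeg_quality JPEG quality (1-100).
#' @return The path, invisibly.
#' @export
render <- function(scene, out_format, path, raster_dpi = 300,
                   jpeg_quality = 92) {
  if (!out_format %in% c(VECTOR_FORMATS, RASTER_FORMATS))
    svz_render_error(sprintf(
      "unknown output format '%s' (supported: %s)", out_format,
      paste(c(VECTOR_FORMATS, RASTER_FORMATS), collapse = ", ")))
  dir <- dirname(path)
  if (!dir.exists(dir))
    svz_render_error(sprintf("output directory does not exist: %s", dir))
  res <- tryCatch(
    switch(out_format,
           svg = write_svg(scene, path),
           eps = write_eps(scene, path),
           pdf = write_pdf(scene, path),
           write_raster(scene, path, out_format, raster_dpi, jpeg_quality)),
    error = function(e) {
      if (inherits(e, "svz_error")) stop(e)
      svz_render_error(sprintf("failed to write %s output to %s: %s",
                               out_format, path, conditionMessage(e)))
    })
  if (!file.exists(path) || file.size(path) == 0L)
    svz_render_error(sprintf("render produced no %s output at %s",
                             out_format, path))
  invisible(res)
}

#' Render a scene to all six formats
#'
#' @param scene a \code{scene}.
#' @param basename output path stem; files are written as
#'   \code{<basename>.<format>}.
#' @param raster_dpi resolution of the raster outputs.
#' @param jpeg_quality JPEG quality.
#' @return Named character vector of the six file paths.
#' @export
render_all_formats <- function(scene, basename, raster_dpi = 300,
                               jpeg_quality = 92) {
  fmts <- c(VECTOR_FORMATS, RASTER_FORMATS)
  paths <- stats::setNames(paste0(basename, ".", fmts), fmts)
  for (f in fmts)
    tryCatch(render(scene, f, paths[[f]], raster_dpi, jpeg_quality),
             error = function(e) svz_render_error(
               sprintf("format %s: %s", f, conditionMessage(e))))
  paths
}

#' Identify a graphics file by its magic signature
#'
#' @param path file to sniff.
#' @return One of \code{"svg"}, \code{"eps"}, \code{"pdf"}, \code{"png"},
#'   \code{"jpeg"}, \code{"bmp"}, or \code{NA} if unrecognized.
#' @export
file_signature <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) return(NA_character_)
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", 64L)
  starts_with <- function(sig) length(bytes) >= length(sig) &&
    identical(bytes[seq_along(sig)], sig)
  ascii <- rawToChar(bytes[bytes != as.raw(0)])
  if (starts_with(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))))
    return("png")
  if (starts_with(as.raw(c(0xFF, 0xD8)))) return("jpeg")
  if (starts_with(charToRaw("BM"))) return("bmp")
  if (starts_with(charToRaw("%PDF"))) return("pdf")
  if (starts_with(charToRaw("%!PS"))) return("eps")
  if (grepl("^\\s*(<\\?xml|<svg)", ascii)) return("svg")
  NA_character_
}
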