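#' @title Vector writers: SVG, EPS, PDF
#' @description
#' Deterministic serializers from the scene graph to the three vector
#' formats.  No timestamps, generator strings or randomized element ids are
#' ever written, so identical scenes produce byte-identical files.  All
#' writers share the same curve flattening as the raster path, a single
#' sans-serif face (Helvetica, referenced, not embedded), and fixed 3-decimal
#' coordinate formatting.
#' @name synviz-vector
NULL

fnum <- function(x) {
  s <- sprintf("%.3f", x)
  sub("^-(0\\.?0*)$", "\\1", s)  # normalize -0.000 to 0.000
}

hex_rgb <- function(col) {
  v <- grDevices::col2rgb(col)[, 1L] / 255
  unname(v)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

style_field <- function(p, name, default) {
  v <- p$style[[name]]
  if (is.null(v)) default else v
}

# Approximate advance width of Helvetica text, used for PDF anchoring.
approx_text_width <- function(text, size) 0.522 * size * nchar(text)

## ---- SVG -------------------------------------------------------------------

path_d <- function(pts) {
  paste0("M", fnum(pts[1L, 1L]), ",", fnum(pts[1L, 2L]),
         paste0("L", fnum(pts[-1L, 1L]), ",", fnum(pts[-1L, 2L]),
                collapse = ""), "Z")
}

svg_primitive <- function(p) {
  fill <- style_field(p, "fill", "#000000")
  op <- style_field(p, "opacity", 1)
  stroke <- style_field(p, "stroke", NA)
  sw <- style_field(p, "stroke_width", 1)
  if (p$kind == "segment") {
    g <- p$geometry
    return(sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      fnum(g$x1), fnum(g$y1), fnum(g$x2), fnum(g$y2), stroke, fnum(sw)))
  }
  if (p$kind == "text") {
    g <- p$geometry
    anchor <- c(start = "start", middle = "middle", end = "end")[[g$anchor]]
    rot <- if (g$rotation != 0)
      sprintf(' transform="rotate(%s,%s,%s)"', fnum(g$rotation),
              fnum(g$x), fnum(g$y)) else ""
    return(sprintf(
      '<text x="%s" y="%s" font-family="Helvetica" font-size="%s" text-anchor="%s" fill="%s"%s>%s</text>',
      fnum(g$x), fnum(g$y), fnum(p$style$font_size), anchor, fill, rot,
      xml_escape(g$text)))
  }
  pts <- primitive_outline(p)
  stroke_attr <- if (is.na(stroke)) ' stroke="none"' else
    sprintf(' stroke="%s" stroke-width="%s"', stroke, fnum(sw))
  op_attr <- if (op < 1) sprintf(' fill-opacity="%s"', fnum(op)) else ""
  sprintf('<path d="%s" fill="%s"%s%s/>', path_d(pts), fill, op_attr,
          stroke_attr)
}

write_svg <- function(scene, path) {
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8" standalone="no"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%spt" height="%spt" viewBox="0 0 %s %s">',
            fnum(scene$width), fnum(scene$height), fnum(scene$width),
            fnum(scene$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fnum(scene$width), fnum(scene$height), scene$background),
    vapply(scene$primitives, svg_primitive, ""),
    '</svg>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---- EPS -------------------------------------------------------------------

# PostScript has no alpha channel: translucent fills are pre-blended with
# the scene background, which is exact for the dominant case of shapes over
# the background and a close approximation where ribbons overlap.
blend_with_bg <- function(col, opacity, bg) {
  c0 <- hex_rgb(col); b <- hex_rgb(bg)
  b + opacity * (c0 - b)
}

ps_color <- function(rgb01) {
  paste(fnum(rgb01[[1L]]), fnum(rgb01[[2L]]), fnum(rgb01[[3L]]),
        "setrgbcolor")
}

ps_escape <- function(s) gsub("([()\\\\])", "\\\\\\1", s)

eps_primitive <- function(p, H, bg) {
  flipy <- function(y) H - y
  if (p$kind == "segment") {
    g <- p$geometry
    return(c(ps_color(hex_rgb(style_field(p, "stroke", "#000000"))),
             paste(fnum(style_field(p, "stroke_width", 1)), "setlinewidth"),
             paste(fnum(g$x1), fnum(flipy(g$y1)), "moveto"),
             paste(fnum(g$x2), fnum(flipy(g$y2)), "lineto"), "stroke"))
  }
  if (p$kind == "text") {
    g <- p$geometry
    shift <- switch(g$anchor,
                    middle = "dup stringwidth pop 2 div neg 0 rmoveto",
                    end = "dup stringwidth pop neg 0 rmoveto",
                    "")
    c("gsave",
      ps_color(hex_rgb(style_field(p, "fill", "#000000"))),
      sprintf("/Helvetica findfont %s scalefont setfont",
              fnum(p$style$font_size)),
      paste(fnum(g$x), fnum(flipy(g$y)), "translate"),
      if (g$rotation != 0) paste(fnum(-g$rotation), "rotate"),
      "0 0 moveto",
      sprintf("(%s) %s show", ps_escape(g$text), shift),
      "grestore")
  } else {
    pts <- primitive_outline(p)
    fill <- blend_with_bg(style_field(p, "fill", "#000000"),
                          style_field(p, "opacity", 1), bg)
    body <- c("newpath",
              paste(fnum(pts[1L, 1L]), fnum(flipy(pts[1L, 2L])), "moveto"),
              paste(fnum(pts[-1L, 1L]), fnum(flipy(pts[-1L, 2L])), "lineto"),
              "closepath")
    stroke <- style_field(p, "stroke", NA)
    out <- c(ps_color(fill), body,
             if (!is.na(stroke)) "gsave fill grestore" else "fill")
    if (!is.na(stroke))
      out <- c(out, ps_color(hex_rgb(stroke)),
               paste(fnum(style_field(p, "stroke_width", 1)), "setlinewidth"),
               "stroke")
    out
  }
}

write_eps <- function(scene, path) {
  W <- scene$width; H <- scene$height
  lines <- c(
    "%!PS-Adobe-3.0 EPSF-3.0",
    sprintf("%%%%BoundingBox: 0 0 %d %d", ceiling(W), ceiling(H)),
    sprintf("%%%%HiResBoundingBox: 0 0 %s %s", fnum(W), fnum(H)),
    "%%Pages: 1",
    "%%EndComments",
    "%%Page: 1 1",
    ps_color(hex_rgb(scene$background)),
    "newpath",
    paste("0 0 moveto", fnum(W), "0 lineto", fnum(W), fnum(H), "lineto 0",
          fnum(H), "lineto closepath fill"),
    unlist(lapply(scene$primitives, eps_primitive, H = H,
                  bg = scene$background)),
    "showpage",
    "%%EOF")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## ---- PDF -------------------------------------------------------------------

pdf_escape <- function(s) gsub("([()\\\\])", "\\\\\\1", s)

pdf_primitive_ops <- function(p, H, gs_name) {
  flipy <- function(y) H - y
  rgb_op <- function(col, op = "rg")
    paste(paste(fnum(hex_rgb(col)), collapse = " "), op)
  if (p$kind == "segment") {
    g <- p$geometry
    return(c("q", gs_name(1),
             rgb_op(style_field(p, "stroke", "#000000"), "RG"),
             paste(fnum(style_field(p, "stroke_width", 1)), "w"),
             paste(fnum(g$x1), fnum(flipy(g$y1)), "m"),
             paste(fnum(g$x2), fnum(flipy(g$y2)), "l"), "S", "Q"))
  }
  if (p$kind == "text") {
    g <- p$geometry
    size <- p$style$font_size
    w <- approx_text_width(g$text, size)
    dx <- switch(g$anchor, middle = -w / 2, end = -w, 0)
    r <- -g$rotation * pi / 180          # canvas-clockwise -> pdf angle
    cr <- cos(r); sr <- sin(r)
    x <- g$x + dx * cr; y <- flipy(g$y) + dx * sr
    return(c("q", gs_name(1), "BT",
             rgb_op(style_field(p, "fill", "#000000")),
             sprintf("/F1 %s Tf", fnum(size)),
             paste(fnum(cr), fnum(sr), fnum(-sr), fnum(cr), fnum(x), fnum(y),
                   "Tm"),
             sprintf("(%s) Tj", pdf_escape(g$text)),
             "ET", "Q"))
  }
  pts <- primitive_outline(p)
  op <- style_field(p, "opacity", 1)
  stroke <- style_field(p, "stroke", NA)
  body <- c(paste(fnum(pts[1L, 1L]), fnum(flipy(pts[1L, 2L])), "m"),
            paste(fnum(pts[-1L, 1L]), fnum(flipy(pts[-1L, 2L])), "l"), "h")
  c("q", gs_name(op), rgb_op(style_field(p, "fill", "#000000")),
    if (!is.na(stroke)) c(rgb_op(stroke, "RG"),
                          paste(fnum(style_field(p, "stroke_width", 1)), "w")),
    body, if (is.na(stroke)) "f" else "B", "Q")
}

write_pdf <- function(scene, path) {
  W <- scene$width; H <- scene$height
  opacities <- sort(unique(c(1, vapply(scene$primitives, function(p)
    style_field(p, "opacity", 1), 0))))
  gs_name <- function(op) sprintf("/GS%d gs", match(op, opacities))

  content <- c(
    "q", gs_name(1),
    paste(paste(fnum(hex_rgb(scene$background)), collapse = " "), "rg"),
    paste("0 0", fnum(W), fnum(H), "re f"), "Q",
    unlist(lapply(scene$primitives, pdf_primitive_ops, H = H,
                  gs_name = gs_name)))
  stream <- paste(content, collapse = "\n")

  n_gs <- length(opacities)
  gs_obj_ids <- seq_len(n_gs) + 5L
  gs_dict <- paste(sprintf("/GS%d %d 0 R", seq_len(n_gs), gs_obj_ids),
                   collapse = " ")
  objs <- c(
    "<< /Type /Catalog /Pages 2 0 R >>",
    "<< /Type /Pages /Kids [3 0 R] /Count 1 >>",
    sprintf(paste0("<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %s %s] ",
                   "/Contents 4 0 R /Resources << /Font << /F1 5 0 R >> ",
                   "/ExtGState << %s >> >> >>"),
            fnum(W), fnum(H), gs_dict),
    sprintf("<< /Length %d >>\nstream\n%s\nendstream", nchar(stream, "bytes"),
            stream),
    "<< /Type /Font /Subtype /Type1 /BaseFont /Helvetica >>",
    sprintf("<< /Type /ExtGState /ca %s /CA %s >>", fnum(opacities),
            fnum(opacities)))

  header <- "%PDF-1.4"
  body_parts <- sprintf("%d 0 obj\n%s\nendobj", seq_along(objs), objs)
  offsets <- integer(length(objs))
  pos <- nchar(header, "bytes") + 1L
  for (i in seq_along(body_parts)) {
    offsets[[i]] <- pos
    pos <- pos + nchar(body_parts[[i]], "bytes") + 1L
  }
  xref_pos <- pos
  xref <- c(sprintf("xref\n0 %d", length(objs) + 1L),
            "0000000000 65535 f ",
            sprintf("%010d 00000 n ", offsets))
  trailer <- c(sprintf("trailer\n<< /Size %d /Root 1 0 R >>",
                       length(objs) + 1L),
               "startxref", as.character(xref_pos), "%%EOF")
  writeLines(c(header, body_parts, xref, trailer), path, useBytes = TRUE)
  invisible(path)
}
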