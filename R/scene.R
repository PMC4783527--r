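#' @title Backend-neutral scene graph
#' @description
#' Layouts are converted to a \code{scene}: an ordered draw list of
#' primitives (\code{arc_band}, \code{cubic_ribbon}, \code{polygon},
#' \code{segment}, \code{circle_marker}, \code{text}) in painter's order.
#' Writers for the six output formats consume scenes and never see layout
#' objects, so no plot code knows about file formats.
#' @name synviz-scene
NULL

primitive <- function(kind, geometry, style = list()) {
  stopifnot(kind %in% c("arc_band", "cubic_ribbon", "polygon", "segment",
                        "circle_marker", "text"))
  structure(list(kind = kind, geometry = geometry, style = style),
            class = "scene_primitive")
}

new_scene <- function(width, height, background = "#FFFFFF",
                      primitives = list()) {
  structure(list(width = width, height = height, background = background,
                 primitives = primitives), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  kinds <- vapply(x$primitives, `[[`, "", "kind")
  cat(sprintf("scene %g x %g pt, %d primitives\n", x$width, x$height,
              length(kinds)))
  if (length(kinds)) print(table(kinds))
  invisible(x)
}

## ---- layout -> scene -------------------------------------------------------

#' Convert a layout to a drawable scene
#'
#' Ideogram spans are drawn first, then ribbons/bands/points, then labels,
#' so overlap order is deterministic.  For the circular layout the scene is
#' exactly one \code{arc_band} per chromosome, one \code{cubic_ribbon} per
#' block and one \code{text} per chromosome label.
#'
#' @param layout a \code{layout_result}.
#' @param config a [plot_config()].
#' @return A \code{scene}.
#' @export
layout_to_scene <- function(layout, config) {
  prims <- switch(layout$plot_type,
                  circle = scene_circle(layout, config),
                  bar = scene_bar(layout, config),
                  dot = scene_dot(layout, config),
                  dual = scene_dual(layout, config),
                  svz_layout_error("unknown layout type"))
  new_scene(layout$canvas[["width"]], layout$canvas[["height"]],
            config$background, prims)
}

label_prims <- function(labels, config, color = "#000000") {
  if (is.null(labels) || !nrow(labels)) return(list())
  lapply(seq_len(nrow(labels)), function(i) {
    primitive("text",
              list(x = labels$x[[i]], y = labels$y[[i]],
                   text = labels$text[[i]], rotation = labels$rotation[[i]],
                   anchor = labels$anchor[[i]]),
              list(fill = color, font_size = config$label_font_size))
  })
}

scene_circle <- function(layout, config) {
  sp <- layout$spans
  arcs <- lapply(seq_len(nrow(sp)), function(i) {
    primitive("arc_band",
              list(cx = layout$center[["x"]], cy = layout$center[["y"]],
                   r_inner = layout$r_inner, r_outer = layout$r_outer,
                   theta_start = sp$theta_start[[i]],
                   theta_end = sp$theta_end[[i]]),
              list(fill = sp$color[[i]], opacity = 1))
  })
  ribbons <- lapply(layout$marks, function(rb) {
    primitive("cubic_ribbon",
              list(cx = layout$center[["x"]], cy = layout$center[["y"]],
                   radius = rb$radius, theta = rb$theta,
                   endpoints = rb$endpoints,
                   control_points = rb$control_points),
              list(fill = rb$fill, opacity = rb$opacity))
  })
  c(arcs, ribbons, label_prims(layout$labels, config))
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

scene_bar <- function(layout, config) {
  sp <- layout$spans
  bars <- lapply(seq_len(nrow(sp)), function(i) {
    h2 <- sp$height[[i]] / 2
    primitive("polygon",
              list(points = rect_poly(sp$x_start[[i]], sp$y[[i]] - h2,
                                      sp$x_end[[i]], sp$y[[i]] + h2)),
              list(fill = "#E8E8E8", stroke = "#555555", stroke_width = 0.6,
                   opacity = 1))
  })
  iv <- layout$intervals
  paint <- if (is.null(iv) || !nrow(iv)) list() else
    lapply(seq_len(nrow(iv)), function(i) {
      h2 <- iv$height[[i]] / 2
      primitive("polygon",
                list(points = rect_poly(iv$x_start[[i]], iv$y[[i]] - h2,
                                        iv$x_end[[i]], iv$y[[i]] + h2)),
                list(fill = iv$color[[i]], opacity = config$ribbon_opacity))
    })
  c(bars, paint, label_prims(layout$labels, config))
}

scene_dot <- function(layout, config) {
  segs <- layout$segments
  grid <- lapply(seq_len(nrow(segs)), function(i) {
    primitive("segment",
              list(x1 = segs$x1[[i]], y1 = segs$y1[[i]],
                   x2 = segs$x2[[i]], y2 = segs$y2[[i]]),
              list(stroke = "#BBBBBB", stroke_width = 0.6))
  })
  pts <- layout$points
  markers <- lapply(seq_len(nrow(pts)), function(i) {
    primitive("circle_marker",
              list(cx = pts$x[[i]], cy = pts$y[[i]], r = 1.6),
              list(fill = pts$color[[i]], opacity = 0.85))
  })
  c(grid, markers, label_prims(layout$labels, config))
}

scene_dual <- function(layout, config) {
  sp <- layout$spans
  bars <- lapply(seq_len(nrow(sp)), function(i) {
    primitive("polygon",
              list(points = rect_poly(sp$x[[i]], sp$y_start[[i]],
                                      sp$x[[i]] + sp$width[[i]],
                                      sp$y_end[[i]])),
              list(fill = sp$color[[i]], stroke = "#333333",
                   stroke_width = 0.6, opacity = 1))
  })
  bands <- lapply(layout$bands, function(bd) {
    primitive("polygon", list(points = bd$corners),
              list(fill = bd$fill, opacity = bd$opacity))
  })
  c(bars, bands, label_prims(layout$labels, config))
}

## ---- shared geometry flattening -------------------------------------------

# Every backend flattens curves identically so vector and raster output
# draw the same shapes.  64 segments per full curve keeps chord error far
# below half a pixel at 300 dpi.
FLATTEN_N <- 64L

arc_points <- function(cx, cy, r, theta_from, theta_to, n = FLATTEN_N) {
  th <- seq(theta_from, theta_to, length.out = max(2L, n))
  polar_xy(cx, cy, r, th)
}

bezier_points <- function(p0, c1, c2, p1, n = FLATTEN_N) {
  t <- seq(0, 1, length.out = max(2L, n))
  b <- function(a0, a1, a2, a3)
    (1 - t)^3 * a0 + 3 * (1 - t)^2 * t * a1 + 3 * (1 - t) * t^2 * a2 + t^3 * a3
  cbind(x = b(p0[[1L]], c1[[1L]], c2[[1L]], p1[[1L]]),
        y = b(p0[[2L]], c1[[2L]], c2[[2L]], p1[[2L]]))
}

# Closed outline of any filled primitive as an n x 2 matrix of canvas
# points; NULL for segments and text.
primitive_outline <- function(p) {
  g <- p$geometry
  switch(p$kind,
    arc_band = {
      outer <- arc_points(g$cx, g$cy, g$r_outer, g$theta_start, g$theta_end)
      inner <- arc_points(g$cx, g$cy, g$r_inner, g$theta_end, g$theta_start)
      rbind(outer, inner)
    },
    cubic_ribbon = {
      ep <- g$endpoints; cp <- g$control_points
      edge_a <- arc_points(g$cx, g$cy, g$radius, g$theta[["a1"]], g$theta[["a2"]])
      curve_ab <- bezier_points(ep["a2", ], cp["ctrl_a", ], cp["ctrl_b", ],
                                ep["b1", ])
      edge_b <- arc_points(g$cx, g$cy, g$radius, g$theta[["b1"]], g$theta[["b2"]])
      curve_ba <- bezier_points(ep["b2", ], cp["ctrl_b", ], cp["ctrl_a", ],
                                ep["a1", ])
      rbind(edge_a, curve_ab, edge_b, curve_ba)
    },
    polygon = g$points,
    circle_marker = arc_points(g$cx, g$cy, g$r, 0, 2 * pi, 48L),
    NULL)
}

# All coordinates a scene will draw (outline vertices, segment ends, text
# anchors) -- used by the canvas-bounds property tests.
scene_coordinates <- function(scene) {
  pts <- lapply(scene$primitives, function(p) {
    o <- primitive_outline(p)
    if (!is.null(o)) return(o)
    g <- p$geometry
    if (p$kind == "segment") cbind(x = c(g$x1, g$x2), y = c(g$y1, g$y2))
    else cbind(x = g$x, y = g$y)
  })
  do.call(rbind, pts)
}
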