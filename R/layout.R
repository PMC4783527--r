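#' @title Layout engine: genomic coordinates to canvas geometry
#' @description
#' Pure functions mapping the validated dataset to canvas coordinates for
#' the four plot geometries: circular ideogram, bar plot, dot plot and dual
#' synteny plot.  One fixed canvas convention is used everywhere: origin at
#' the top-left, y increasing downward, units in points; on the circle,
#' angle 0 sits at 12 o'clock and increases clockwise (ideogram convention).
#' @name synviz-layout
NULL

# Polar to canvas: angle 0 at 12 o'clock, clockwise, y down.
polar_xy <- function(cx, cy, r, theta) {
  cbind(x = cx + r * sin(theta), y = cy - r * cos(theta))
}

ordered_chromosomes <- function(dataset) chromosome_table(dataset$genomes)

palette_color <- function(palette, index1) {
  palette[((index1 - 1L) %% length(palette)) + 1L]
}

#' Drop blocks with too few anchors
#'
#' @param blocks list of \code{synteny_block}.
#' @param config a [plot_config()]; its \code{min_block_anchors} is the
#'   threshold.
#' @return Filtered list, original order preserved.
#' @export
filter_blocks <- function(blocks, config) {
  Filter(function(b) nrow(b$anchors) >= config$min_block_anchors, blocks)
}

## ---- circular ideogram -----------------------------------------------------

#' Circular ideogram layout
#'
#' Chromosomes of all genomes are laid end to end around one ring (genomes
#' ordered by species tag, chromosomes natural-sorted within each), with a
#' fixed angular gap between consecutive chromosomes.  Each chromosome's arc
#' is proportional to its length:
#' \deqn{span_i = (2\pi - C g) \; length_i / \sum_j length_j}
#' where \eqn{C} is the chromosome count and \eqn{g} the gap angle.  Each
#' surviving block becomes one ribbon chord between the arcs of its two
#' chromosomes; labels (species abbreviation plus chromosome id) sit at arc
#' midpoints, rotated tangentially.
#'
#' @param dataset a \code{synteny_dataset}.
#' @param config a [plot_config()].
#' @return A \code{layout_result} with arc \code{spans}, ribbon \code{marks}
#'   and \code{labels}.
#' @export
circular_layout <- function(dataset, config) {
  ct <- ordered_chromosomes(dataset)
  C <- nrow(ct)
  if (C < 1L) svz_layout_error("no chromosomes to lay out")
  g <- config$gap_angle
  if (C * g >= 2 * pi)
    svz_layout_error(sprintf(
      "gap angle too large: %d chromosomes x %.4f rad >= 2*pi", C, g))
  cv <- resolve_canvas(config, "circle")
  total <- sum(ct$length_bp)
  spans_theta <- (2 * pi - C * g) * ct$length_bp / total

  theta_start <- cumsum(c(0, utils::head(spans_theta, -1L) + g))
  r_outer <- min(cv) / 2 - config$margin
  if (r_outer <= 0) svz_layout_error("margin leaves no drawing area")
  band <- 0.05 * r_outer
  spans <- data.frame(chrom_id = ct$chrom_id, species_tag = ct$species_tag,
                      length_bp = ct$length_bp,
                      theta_start = theta_start,
                      theta_end = theta_start + spans_theta,
                      radius = r_outer,
                      color = palette_color(config$palette, seq_len(C)),
                      stringsAsFactors = FALSE)

  layout <- structure(list(
    plot_type = "circle", canvas = cv, spans = spans,
    center = c(x = cv[["width"]] / 2, y = cv[["height"]] / 2),
    r_outer = r_outer, r_inner = r_outer - band,
    gene_index = dataset$gene_index, marks = list(),
    labels = NULL), class = "layout_result")

  layout$marks <- lapply(dataset$blocks, ribbon_for_block,
                         layout = layout, config = config)

  mid <- (spans$theta_start + spans$theta_end) / 2
  lp <- polar_xy(layout$center[["x"]], layout$center[["y"]],
                 r_outer + 0.45 * config$margin, mid)
  layout$labels <- data.frame(text = spans$chrom_id, x = lp[, "x"], y = lp[, "y"],
                              rotation = mid * 180 / pi, anchor = "middle",
                              stringsAsFactors = FALSE)
  layout
}

#' Map a genomic position to a circle angle
#'
#' Linear interpolation within the chromosome's arc span: position 1 maps to
#' the arc start, position \code{length_bp} to the arc end.
#'
#' @param chrom_id chromosome id as in the layout's spans.
#' @param pos_bp position in base pairs, within \code{[1, length_bp]}.
#' @param layout a circular \code{layout_result}.
#' @return Angle in radians.
#' @export
genomic_to_angle <- function(chrom_id, pos_bp, layout) {
  i <- match(chrom_id, layout$spans$chrom_id)
  if (is.na(i))
    svz_layout_error(sprintf("chromosome '%s' not in layout", chrom_id))
  sp <- layout$spans[i, ]
  if (any(pos_bp < 1 | pos_bp > sp$length_bp))
    svz_layout_error(sprintf("position out of range for %s (1..%g)",
                             chrom_id, sp$length_bp))
  if (sp$length_bp <= 1)
    return(rep((sp$theta_start + sp$theta_end) / 2, length(pos_bp)))
  sp$theta_start + (pos_bp - 1) / (sp$length_bp - 1) *
    (sp$theta_end - sp$theta_start)
}

#' Ribbon geometry for one block
#'
#' The block's extent on each chromosome (min anchor start to max anchor
#' end) gives two arc segments at the inner ideogram radius; the ribbon is
#' bounded by those two arc edges and two cubic curves whose interior
#' control points are the chord endpoints pulled toward the circle center by
#' \code{config$ribbon_pull} (0 places them at the center).
#'
#' @param block a \code{synteny_block}.
#' @param layout a circular \code{layout_result}.
#' @param config a [plot_config()].
#' @return A \code{ribbon_geometry} list: four endpoint coordinates, two
#'   control points, fill color (palette color of \code{chrom_a}) and
#'   opacity.
#' @export
ribbon_for_block <- function(block, layout, config) {
  ea <- block_extent(block, "a", layout$gene_index)
  eb <- block_extent(block, "b", layout$gene_index)
  th <- c(a1 = genomic_to_angle(ea$chrom_id, ea$start, layout),
          a2 = genomic_to_angle(ea$chrom_id, ea$end, layout),
          b1 = genomic_to_angle(eb$chrom_id, eb$start, layout),
          b2 = genomic_to_angle(eb$chrom_id, eb$end, layout))
  ctr <- layout$center
  pts <- polar_xy(ctr[["x"]], ctr[["y"]], layout$r_inner, th)
  rownames(pts) <- names(th)
  pull <- function(p) c(ctr[["x"]], ctr[["y"]]) +
    config$ribbon_pull * (p - c(ctr[["x"]], ctr[["y"]]))
  ia <- match(ea$chrom_id, layout$spans$chrom_id)
  structure(list(block_id = block$block_id,
                 chrom_a = ea$chrom_id, chrom_b = eb$chrom_id,
                 theta = th, radius = layout$r_inner, endpoints = pts,
                 control_points = rbind(ctrl_a = pull(pts["a2", ]),
                                        ctrl_b = pull(pts["b1", ])),
                 fill = layout$spans$color[[ia]],
                 opacity = config$ribbon_opacity),
            class = "ribbon_geometry")
}

## ---- dot plot --------------------------------------------------------------

# Cumulative axis map for one genome: chromosome i occupies
# [offset_i, offset_i + len_i * scale] with a fixed pixel gap between
# consecutive chromosomes.
axis_map <- function(ct, origin, span_pt, gap_pt) {
  n <- nrow(ct)
  scale <- (span_pt - (n - 1L) * gap_pt) / sum(ct$length_bp)
  if (scale <= 0) svz_layout_error("axis gap leaves no room for chromosomes")
  offsets <- origin + cumsum(c(0, utils::head(ct$length_bp, -1L))) * scale +
    (seq_len(n) - 1L) * gap_pt
  data.frame(chrom_id = ct$chrom_id, length_bp = ct$length_bp,
             offset = offsets, scale = scale,
             stringsAsFactors = FALSE)
}

axis_pos <- function(amap, chrom_id, pos_bp) {
  i <- match(chrom_id, amap$chrom_id)
  amap$offset[i] + (pos_bp - 1) * amap$scale[i]
}

# The two genomes put on the axes: dual_pair if configured, else the first
# two genomes, else the single genome on both axes.
select_axis_genomes <- function(dataset, config) {
  tags <- vapply(dataset$genomes, `[[`, "", "species_tag")
  pick <- function(tag) {
    i <- match(tag, tags)
    if (is.na(i)) svz_layout_error(sprintf("unknown species tag '%s'", tag))
    dataset$genomes[[i]]
  }
  if (!is.null(config$dual_pair))
    list(a = pick(config$dual_pair[[1L]]), b = pick(config$dual_pair[[2L]]))
  else if (length(tags) >= 2L)
    list(a = dataset$genomes[[1L]], b = dataset$genomes[[2L]])
  else
    list(a = dataset$genomes[[1L]], b = dataset$genomes[[1L]])
}

#' Macrosynteny dot plot layout
#'
#' The x axis concatenates the chromosomes of one genome in cumulative
#' base-pair coordinates (fixed inter-chromosome gap in points), the y axis
#' the other genome's (a single-genome dataset uses all its chromosomes on
#' both axes).  Every anchor pair becomes one point at the two gene
#' midpoints; points are colored by the block orientation (plus vs minus).
#' Chromosome boundary gridlines and axis labels are included.
#'
#' @inheritParams circular_layout
#' @return A \code{layout_result} with axis maps, \code{points}, gridline
#'   \code{segments} and \code{labels}.
#' @export
dotplot_layout <- function(dataset, config) {
  if (!length(dataset$blocks)) svz_layout_error("no blocks to plot")
  cv <- resolve_canvas(config, "dot")
  gsel <- select_axis_genomes(dataset, config)
  ct_a <- chromosome_table(structure(list(gsel$a), class = "genome_set"))
  ct_b <- chromosome_table(structure(list(gsel$b), class = "genome_set"))

  m <- config$margin
  x0 <- m; x1 <- cv[["width"]] - m
  y0 <- m; y1 <- cv[["height"]] - m
  xmap <- axis_map(ct_a, x0, x1 - x0, config$axis_gap)
  ymap <- axis_map(ct_b, y0, y1 - y0, config$axis_gap)

  gi <- dataset$gene_index
  midpoint <- function(ids) {
    r <- gi[match(ids, gi$gene_id), , drop = FALSE]
    (r$start + r$end) / 2
  }
  pts <- do.call(rbind, lapply(dataset$blocks, function(blk) {
    on_x_a <- blk$chrom_a %in% xmap$chrom_id && blk$chrom_b %in% ymap$chrom_id
    on_x_b <- blk$chrom_b %in% xmap$chrom_id && blk$chrom_a %in% ymap$chrom_id
    if (!on_x_a && !on_x_b) return(NULL)
    if (on_x_a) {
      cx <- blk$chrom_a; cy <- blk$chrom_b
      mx <- midpoint(blk$anchors$gene_a); my <- midpoint(blk$anchors$gene_b)
    } else {
      cx <- blk$chrom_b; cy <- blk$chrom_a
      mx <- midpoint(blk$anchors$gene_b); my <- midpoint(blk$anchors$gene_a)
    }
    data.frame(x = axis_pos(xmap, cx, mx), y = axis_pos(ymap, cy, my),
               block_id = blk$block_id, orientation = blk$orientation,
               color = if (blk$orientation == "plus") config$palette[[1L]]
                       else config$palette[[2L]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pts))
    svz_layout_error("no anchor pairs fall on the selected axis genomes")

  # gridlines at chromosome boundaries (between consecutive chromosomes)
  xb <- utils::tail(xmap$offset, -1L) - config$axis_gap / 2
  yb <- utils::tail(ymap$offset, -1L) - config$axis_gap / 2
  segs <- rbind(
    if (length(xb)) data.frame(x1 = xb, y1 = y0, x2 = xb, y2 = y1),
    if (length(yb)) data.frame(x1 = x0, y1 = yb, x2 = x1, y2 = yb),
    data.frame(x1 = c(x0, x0), y1 = c(y0, y1), x2 = c(x1, x0), y2 = c(y1, y0)))

  labels <- rbind(
    data.frame(text = xmap$chrom_id,
               x = xmap$offset + xmap$length_bp * xmap$scale / 2,
               y = y1 + 0.4 * m, rotation = 0, anchor = "middle",
               stringsAsFactors = FALSE),
    data.frame(text = ymap$chrom_id, x = x0 - 0.4 * m,
               y = ymap$offset + ymap$length_bp * ymap$scale / 2,
               rotation = 90, anchor = "middle", stringsAsFactors = FALSE))

  structure(list(plot_type = "dot", canvas = cv, xmap = xmap, ymap = ymap,
                 frame = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
                 points = pts, segments = segs, labels = labels,
                 gene_index = dataset$gene_index),
            class = "layout_result")
}

## ---- bar plot --------------------------------------------------------------

#' Bar plot layout
#'
#' Every chromosome is one horizontal bar on its own track, stacked
#' vertically, left-aligned, lengths sharing a single global scale.  Each
#' block paints a colored interval at its genomic extent on BOTH partner
#' bars; the two intervals of a block share one per-block color cycled from
#' the palette so matches can be read across bars.
#'
#' @inheritParams circular_layout
#' @return A \code{layout_result} with linear \code{spans}, painted
#'   \code{intervals} and \code{labels}.
#' @export
bar_layout <- function(dataset, config) {
  ct <- ordered_chromosomes(dataset)
  C <- nrow(ct)
  if (C < 1L) svz_layout_error("no chromosomes to lay out")
  cv <- resolve_canvas(config, "bar")
  m <- config$margin
  label_space <- 60
  x0 <- m + label_space
  scale <- (cv[["width"]] - m - x0) / max(ct$length_bp)
  if (scale <= 0) svz_layout_error("canvas too small for bar layout")
  row_h <- (cv[["height"]] - 2 * m) / C
  bar_h <- min(16, 0.6 * row_h)
  y_base <- m + (seq_len(C) - 0.5) * row_h

  spans <- data.frame(chrom_id = ct$chrom_id, species_tag = ct$species_tag,
                      length_bp = ct$length_bp, track = seq_len(C),
                      x_start = x0, x_end = x0 + ct$length_bp * scale,
                      y = y_base, height = bar_h, scale = scale,
                      stringsAsFactors = FALSE)

  gi <- dataset$gene_index
  intervals <- do.call(rbind, lapply(seq_along(dataset$blocks), function(k) {
    blk <- dataset$blocks[[k]]
    col <- palette_color(config$palette, k)
    do.call(rbind, lapply(c("a", "b"), function(side) {
      ext <- block_extent(blk, side, gi)
      i <- match(ext$chrom_id, spans$chrom_id)
      data.frame(block_id = blk$block_id, chrom_id = ext$chrom_id,
                 x_start = x0 + (ext$start - 1) * scale,
                 x_end = x0 + ext$end * scale,
                 y = spans$y[i], height = bar_h, color = col,
                 stringsAsFactors = FALSE)
    }))
  }))

  labels <- data.frame(text = ct$chrom_id, x = x0 - 8, y = y_base,
                       rotation = 0, anchor = "end", stringsAsFactors = FALSE)
  structure(list(plot_type = "bar", canvas = cv, spans = spans,
                 intervals = intervals, labels = labels,
                 gene_index = dataset$gene_index),
            class = "layout_result")
}

## ---- dual synteny plot -----------------------------------------------------

#' Dual synteny plot layout
#'
#' Two parallel vertical columns of chromosome bars — one species on the
#' left, one on the right — with each block drawn as a quadrilateral band
#' from its extent on the left chromosome to its extent on the right one.
#' Blocks not joining the pair are excluded.  Both columns share one global
#' base-pair scale.
#'
#' @inheritParams circular_layout
#' @param pair \code{c(species_a, species_b)}; defaults to
#'   \code{config$dual_pair} or the dataset's first two genomes.
#' @return A \code{layout_result} with vertical \code{spans} (side "left" /
#'   "right"), quadrilateral \code{bands} and \code{labels}.
#' @export
dual_synteny_layout <- function(dataset, config, pair = NULL) {
  if (is.null(pair)) pair <- config$dual_pair
  tags <- vapply(dataset$genomes, `[[`, "", "species_tag")
  if (is.null(pair)) {
    if (length(tags) < 2L)
      svz_layout_error("dual synteny plot needs two species (or an explicit pair)")
    pair <- tags[1:2]
  }
  if (!all(pair %in% tags))
    svz_layout_error(sprintf("unknown species tag '%s'",
                             setdiff(pair, tags)[[1L]]))
  cv <- resolve_canvas(config, "dual")
  m <- config$margin
  ga <- dataset$genomes[[match(pair[[1L]], tags)]]
  gb <- dataset$genomes[[match(pair[[2L]], tags)]]
  ct_a <- chromosome_table(structure(list(ga), class = "genome_set"))
  ct_b <- chromosome_table(structure(list(gb), class = "genome_set"))

  blocks <- Filter(function(b) {
    (b$chrom_a %in% ct_a$chrom_id && b$chrom_b %in% ct_b$chrom_id) ||
    (b$chrom_a %in% ct_b$chrom_id && b$chrom_b %in% ct_a$chrom_id)
  }, dataset$blocks)
  if (!length(blocks))
    svz_layout_error(sprintf("no synteny between %s and %s",
                             pair[[1L]], pair[[2L]]))

  bar_w <- 18
  gap <- 8
  col_h <- cv[["height"]] - 2 * m
  scale <- min(
    (col_h - (nrow(ct_a) - 1L) * gap) / sum(ct_a$length_bp),
    (col_h - (nrow(ct_b) - 1L) * gap) / sum(ct_b$length_bp))
  if (scale <= 0) svz_layout_error("canvas too small for dual layout")
  column <- function(ct, x, side) {
    y_start <- m + cumsum(c(0, utils::head(ct$length_bp, -1L))) * scale +
      (seq_len(nrow(ct)) - 1L) * gap
    data.frame(chrom_id = ct$chrom_id, species_tag = ct$species_tag,
               length_bp = ct$length_bp, track = seq_len(nrow(ct)),
               x = x, width = bar_w, y_start = y_start,
               y_end = y_start + ct$length_bp * scale,
               side = side, scale = scale,
               color = palette_color(config$palette, seq_len(nrow(ct))),
               stringsAsFactors = FALSE)
  }
  xL <- m + 50                      # room for left labels
  xR <- cv[["width"]] - m - 50 - bar_w
  spans <- rbind(column(ct_a, xL, "left"), column(ct_b, xR, "right"))

  ypos <- function(chrom_id, pos_bp) {
    i <- match(chrom_id, spans$chrom_id)
    spans$y_start[i] + (pos_bp - 1) * scale
  }
  gi <- dataset$gene_index
  bands <- lapply(blocks, function(blk) {
    a_left <- blk$chrom_a %in% ct_a$chrom_id
    eL <- block_extent(blk, if (a_left) "a" else "b", gi)
    eR <- block_extent(blk, if (a_left) "b" else "a", gi)
    iL <- match(eL$chrom_id, spans$chrom_id)
    corners <- rbind(
      c(xL + bar_w, ypos(eL$chrom_id, eL$start)),
      c(xL + bar_w, ypos(eL$chrom_id, eL$end)),
      c(xR,         ypos(eR$chrom_id, eR$end)),
      c(xR,         ypos(eR$chrom_id, eR$start)))
    colnames(corners) <- c("x", "y")
    list(block_id = blk$block_id, chrom_left = eL$chrom_id,
         chrom_right = eR$chrom_id, corners = corners,
         fill = spans$color[[iL]], opacity = config$ribbon_opacity)
  })

  labels <- data.frame(
    text = spans$chrom_id,
    x = ifelse(spans$side == "left", xL - 8, xR + bar_w + 8),
    y = (spans$y_start + spans$y_end) / 2,
    rotation = 0,
    anchor = ifelse(spans$side == "left", "end", "start"),
    stringsAsFactors = FALSE)

  structure(list(plot_type = "dual", canvas = cv, spans = spans,
                 bands = bands, labels = labels, pair = pair,
                 gene_index = dataset$gene_index),
            class = "layout_result")
}

#' Compute the layout for any plot type
#'
#' @param dataset a \code{synteny_dataset}.
#' @param config a [plot_config()]; \code{config$plot_type} selects the
#'   geometry.
#' @param plot_type optional override of \code{config$plot_type}.
#' @return A \code{layout_result}.
#' @export
layout_dataset <- function(dataset, config, plot_type = config$plot_type) {
  switch(plot_type,
         circle = circular_layout(dataset, config),
         bar = bar_layout(dataset, config),
         dot = dotplot_layout(dataset, config),
         dual = dual_synteny_layout(dataset, config),
         svz_config_error(sprintf("unknown plot type '%s'", plot_type)))
}
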