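circle_layout_of <- function(dataset, ...) {
  circular_layout(dataset, plot_config(plot_type = "circle", ...))
}

test_that("arc spans follow the proportional formula and close the circle", {
  # lengths 100/200/300 with gap 0.1 rad, checked against a direct
  # independent evaluation of the span formula
  genes <- gene_table(c("A1", "B1", "C1"), c("aa01", "aa02", "aa03"),
                      c(1L, 1L, 1L), c(100L, 200L, 300L))
  genomes <- build_genome_models(genes)
  ds <- join_and_validate(genomes, list())
  lay <- circle_layout_of(ds, gap_angle = 0.1)
  expected <- (2 * pi - 3 * 0.1) * c(1, 2, 3) / 6
  expect_equal(lay$spans$theta_end - lay$spans$theta_start, expected,
               tolerance = 1e-12)
  expect_equal(sum(lay$spans$theta_end - lay$spans$theta_start) + 3 * 0.1,
               2 * pi, tolerance = 1e-9)
  # arcs pairwise disjoint and within [0, 2*pi)
  expect_true(all(diff(as.vector(rbind(lay$spans$theta_start,
                                       lay$spans$theta_end))) >= 0))
  expect_true(all(lay$spans$theta_start >= 0 & lay$spans$theta_end < 2 * pi))
})

test_that("degenerate circle cases: single arc and equal-length symmetry", {
  one <- join_and_validate(
    build_genome_models(gene_table("G", "xx01", 1L, 500L)), list())
  lay <- circle_layout_of(one, gap_angle = 0)
  expect_equal(lay$spans$theta_end - lay$spans$theta_start, 2 * pi)

  two <- join_and_validate(
    build_genome_models(gene_table(c("G", "H"), c("xx01", "xx02"),
                                   c(1L, 1L), c(500L, 500L))), list())
  g <- 0.12
  lay2 <- circle_layout_of(two, gap_angle = g)
  expect_equal(lay2$spans$theta_end - lay2$spans$theta_start,
               rep(pi - g, 2L), tolerance = 1e-12)

  expect_error(circle_layout_of(two, gap_angle = 3.2), "gap angle too large",
               class = "svz_layout_error")
})

test_that("genomic_to_angle agrees with an independent interpolation oracle", {
  fx <- small_fixture()
  ds <- dataset_from_fixture(fx)
  lay <- circle_layout_of(ds)
  set.seed(11)
  for (q in seq_len(1000L)) {
    i <- sample(nrow(lay$spans), 1L)
    sp <- lay$spans[i, ]
    pos <- sample.int(sp$length_bp, 1L)
    oracle <- stats::approx(x = c(1, sp$length_bp),
                            y = c(sp$theta_start, sp$theta_end),
                            xout = pos)$y
    expect_equal(genomic_to_angle(sp$chrom_id, pos, lay), oracle,
                 tolerance = 1e-12)
  }
  # boundaries map to the arc ends exactly
  sp <- lay$spans[1L, ]
  expect_identical(genomic_to_angle(sp$chrom_id, 1, lay), sp$theta_start)
  expect_identical(genomic_to_angle(sp$chrom_id, sp$length_bp, lay),
                   sp$theta_end)
  expect_error(genomic_to_angle(sp$chrom_id, sp$length_bp + 1, lay),
               "out of range", class = "svz_layout_error")
})

test_that("angle maps are strictly increasing within a chromosome", {
  ds <- dataset_from_fixture(small_fixture())
  lay <- circle_layout_of(ds)
  for (i in seq_len(nrow(lay$spans))) {
    sp <- lay$spans[i, ]
    pos <- round(seq(1, sp$length_bp, length.out = 25L))
    expect_true(all(diff(genomic_to_angle(sp$chrom_id, pos, lay)) > 0))
  }
})

test_that("ribbon endpoints sit on the circle at their genomic angles", {
  cfg <- plot_config()
  for (seed in c(5L, 6L)) {
    ds <- dataset_from_fixture(small_fixture(seed = seed, n_blocks = 10L))
    lay <- circular_layout(ds, cfg)
    for (rb in lay$marks) {
      # oracle: recompute endpoint coordinates from the angles directly
      expected <- cbind(
        x = lay$center[["x"]] + lay$r_inner * sin(rb$theta),
        y = lay$center[["y"]] - lay$r_inner * cos(rb$theta))
      expect_equal(unname(rb$endpoints), unname(expected), tolerance = 1e-9)
      # default pull factor 0: control points at the circle center
      expect_equal(unname(rb$control_points[1L, ]),
                   unname(c(lay$center[["x"]], lay$center[["y"]])))
    }
  }
})

test_that("self-synteny ribbons on one chromosome are valid", {
  genes <- gene_table(c("A", "B", "C", "D"), rep("zz01", 4L),
                      c(100L, 300L, 700L, 900L), c(200L, 400L, 800L, 950L))
  lines <- c("## Alignment 0: score=100 e_value=0 N=2 zz1&zz1 plus",
             " 0-  0:\tA\tC\t0", " 0-  1:\tB\tD\t0")
  ds <- join_and_validate(build_genome_models(genes),
                          parse_collinearity(write_lines_tmp(lines)))
  lay <- circle_layout_of(ds)
  expect_length(lay$marks, 1L)
  rb <- lay$marks[[1L]]
  expect_identical(rb$chrom_a, rb$chrom_b)
  expect_true(all(is.finite(rb$endpoints)))
})

test_that("dot plot offsets match explicit cumulative sums", {
  # chromosomes 1000 and 2000 bp with a 10 pt gap on an 800 pt wide canvas
  genes <- gene_table(c("A", "A2", "B", "X", "Y"),
                      c("aa01", "aa01", "aa02", "bb01", "bb01"),
                      c(1L, 500L, 1L, 1L, 1000L),
                      c(100L, 1000L, 2000L, 200L, 1500L))
  lines <- c("## Alignment 0: score=1 e_value=0 N=2 aa1&bb1 plus",
             " 0- 0:\tA\tX\t0", " 0- 1:\tA2\tY\t0")
  ds <- join_and_validate(build_genome_models(genes),
                          parse_collinearity(write_lines_tmp(lines)), "drop")
  cfg <- plot_config(plot_type = "dot", canvas_width = 800,
                     canvas_height = 800, margin = 40, axis_gap = 10)
  lay <- dotplot_layout(ds, cfg)
  # oracle: explicit cumulative-sum computation
  span <- 800 - 2 * 40
  scale <- (span - 1 * 10) / 3000
  expect_equal(lay$xmap$offset, c(40, 40 + 1000 * scale + 10),
               tolerance = 1e-12)
  expect_equal(lay$xmap$scale, rep(scale, 2L))
  # an anchor at the very first base of each first chromosome maps to the
  # frame origin corner
  expect_equal(synviz:::axis_pos(lay$xmap, "aa01", 1), 40)
  expect_equal(synviz:::axis_pos(lay$ymap, "bb01", 1), 40)
})

test_that("swapping dot-plot axis genomes transposes every point", {
  fx <- small_fixture(seed = 9L)
  ds <- dataset_from_fixture(fx)
  sq <- plot_config(plot_type = "dot", canvas_width = 900,
                    canvas_height = 900)
  ab <- dotplot_layout(ds, sq); ab$config <- NULL
  ba_cfg <- sq; ba_cfg$dual_pair <- c("bb", "aa")
  ba <- dotplot_layout(ds, ba_cfg)
  ord_ab <- order(ab$points$block_id, ab$points$x, ab$points$y)
  ord_ba <- order(ba$points$block_id, ba$points$y, ba$points$x)
  expect_equal(ab$points$x[ord_ab], ba$points$y[ord_ba])
  expect_equal(ab$points$y[ord_ab], ba$points$x[ord_ba])
})

test_that("dot plot colors points by block orientation", {
  ds <- dataset_from_fixture(small_fixture(seed = 12L, n_blocks = 10L))
  cfg <- plot_config(plot_type = "dot")
  lay <- dotplot_layout(ds, cfg)
  expect_setequal(unique(lay$points$orientation),
                  unique(vapply(ds$blocks, `[[`, "", "orientation")))
  expect_identical(unique(lay$points$color[lay$points$orientation == "plus"]),
                   cfg$palette[[1L]])
  plus_minus <- lay$points$orientation == "minus"
  if (any(plus_minus))
    expect_identical(unique(lay$points$color[plus_minus]), cfg$palette[[2L]])
  expect_error(dotplot_layout(ds, plot_config(plot_type = "dot",
                                              dual_pair = c("aa", "zz"))),
               "unknown species tag", class = "svz_layout_error")
})

test_that("bar lengths are proportional and intervals match scale * extent", {
  ds <- dataset_from_fixture(small_fixture(seed = 4L))
  cfg <- plot_config(plot_type = "bar")
  lay <- bar_layout(ds, cfg)
  sp <- lay$spans
  # pixel length ratio equals genomic length ratio
  expect_equal((sp$x_end - sp$x_start) / sp$length_bp,
               rep(sp$scale[[1L]], nrow(sp)))
  # oracle: painted extents recomputed as scale * genomic extent
  for (i in seq_len(nrow(lay$intervals))) {
    iv <- lay$intervals[i, ]
    blk <- ds$blocks[[match(iv$block_id,
                            vapply(ds$blocks, `[[`, 0L, "block_id"))]]
    side <- if (blk$chrom_a == iv$chrom_id) "a" else "b"
    ext <- synviz:::block_extent(blk, side, ds$gene_index)
    expect_equal(iv$x_end - iv$x_start,
                 (ext$end - ext$start + 1) * sp$scale[[1L]],
                 tolerance = 1e-9)
  }
  # both partner intervals of a block share one color
  cols <- tapply(lay$intervals$color, lay$intervals$block_id,
                 function(x) length(unique(x)))
  expect_true(all(cols == 1L))
})

test_that("a block spanning a whole chromosome paints the full bar", {
  genes <- gene_table(c("A", "B", "X", "Y"), c("aa01", "aa01", "bb01", "bb01"),
                      c(1L, 800L, 1L, 500L), c(300L, 1000L, 200L, 900L))
  lines <- c("## Alignment 0: score=1 e_value=0 N=2 aa1&bb1 plus",
             " 0- 0:\tA\tX\t0", " 0- 1:\tB\tY\t0")
  ds <- join_and_validate(build_genome_models(genes),
                          parse_collinearity(write_lines_tmp(lines)))
  lay <- bar_layout(ds, plot_config(plot_type = "bar"))
  iv <- lay$intervals[lay$intervals$chrom_id == "aa01", ]
  sp <- lay$spans[lay$spans$chrom_id == "aa01", ]
  expect_equal(iv$x_end, sp$x_end, tolerance = 1e-9)
})

test_that("dual synteny bands land exactly on the two bar edges", {
  ds <- dataset_from_fixture(small_fixture(seed = 8L))
  cfg <- plot_config(plot_type = "dual")
  lay <- dual_synteny_layout(ds, cfg, pair = c("aa", "bb"))
  left <- lay$spans[lay$spans$side == "left", ]
  right <- lay$spans[lay$spans$side == "right", ]
  xL_edge <- unique(left$x + left$width)
  xR_edge <- unique(right$x)
  for (bd in lay$bands) {
    expect_equal(unname(bd$corners[1:2, "x"]), rep(xL_edge, 2L))
    expect_equal(unname(bd$corners[3:4, "x"]), rep(xR_edge, 2L))
    # oracle: y corners recomputed from the span scale
    iL <- match(bd$chrom_left, lay$spans$chrom_id)
    expect_true(all(bd$corners[1:2, "y"] >= lay$spans$y_start[iL] - 1e-9 &
                    bd$corners[1:2, "y"] <= lay$spans$y_end[iL] + 1e-9))
  }
  # a pair with no joining blocks is an error naming the pair
  expect_error(dual_synteny_layout(ds, cfg, pair = c("aa", "aa")),
               "no synteny between aa and aa", class = "svz_layout_error")
})

test_that("block filtering drops exactly the sub-threshold blocks", {
  mk <- function(n) {
    an <- data.frame(gene_a = paste0("a", seq_len(n)),
                     gene_b = paste0("b", seq_len(n)), e_value = 0,
                     index_in_block = seq_len(n) - 1L)
    synviz:::new_synteny_block(0L, 1, 0, n, "x1", "y1", "plus", an)
  }
  blocks <- lapply(c(1L, 2L, 5L), mk)
  kept <- filter_blocks(blocks, plot_config(min_block_anchors = 2))
  expect_equal(vapply(kept, function(b) nrow(b$anchors), 0L), c(2L, 5L))
  expect_identical(filter_blocks(list(), plot_config()), list())
  # oracle: survivor count from the generator's anchor-count histogram
  fx <- small_fixture(seed = 3L, n_blocks = 15L)
  ds <- dataset_from_fixture(fx)
  kept6 <- filter_blocks(ds$blocks, plot_config(min_block_anchors = 6))
  hist <- fx$anchor_histogram
  expect_length(kept6, sum(hist[as.integer(names(hist)) >= 6L]))
})

test_that("every canvas coordinate of every layout stays inside the canvas", {
  ds <- dataset_from_fixture(small_fixture(seed = 10L))
  for (pt in c("circle", "bar", "dot", "dual")) {
    cfg <- plot_config(plot_type = pt)
    scene <- layout_to_scene(layout_dataset(ds, cfg), cfg)
    xy <- synviz:::scene_coordinates(scene)
    expect_true(all(xy[, 1L] >= 0 & xy[, 1L] <= scene$width),
                label = paste(pt, "x in canvas"))
    expect_true(all(xy[, 2L] >= 0 & xy[, 2L] <= scene$height),
                label = paste(pt, "y in canvas"))
  }
})

test_that("layouts are deterministic and scale linearly with the canvas", {
  ds <- dataset_from_fixture(small_fixture(seed = 2L))
  cfg <- plot_config(plot_type = "bar")
  expect_identical(bar_layout(ds, cfg), bar_layout(ds, cfg))
  # doubling the canvas doubles linear-layout coordinates
  cfg2 <- plot_config(plot_type = "bar", canvas_width = 2000,
                      canvas_height = 1400, margin = 80)
  a <- bar_layout(ds, cfg)
  b <- bar_layout(ds, cfg2)
  expect_equal(b$spans$x_start, 2 * a$spans$x_start - 60,  # label gutter fixed
               tolerance = 1e-9)
  expect_equal(b$spans$y, 2 * a$spans$y, tolerance = 1e-9)
  # circle layout preserves angles exactly under radius change
  c1 <- circular_layout(ds, plot_config())
  c2 <- circular_layout(ds, plot_config(canvas_width = 2000,
                                        canvas_height = 2000))
  expect_identical(c1$spans$theta_start, c2$spans$theta_start)
  expect_identical(c1$spans$theta_end, c2$spans$theta_end)
})
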