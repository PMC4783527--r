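# Rendering tests work on one small reusable scene.
render_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- dataset_from_fixture(small_fixture(seed = 21L, n_blocks = 5L))
      cfg <- plot_config(canvas_width = 200, canvas_height = 200,
                         margin = 20, label_font_size = 6)
      cache <<- layout_to_scene(circular_layout(ds, cfg), cfg)
    }
    cache
  }
})

read_u16be <- function(b, i) 256L * as.integer(b[i]) + as.integer(b[i + 1L])
read_u32le <- function(b, i) sum(as.integer(b[i + 0:3]) * 256^(0:3))

jpeg_dims <- function(path) {
  b <- readBin(path, "raw", file.size(path))
  i <- 3L
  while (i < length(b)) {
    stopifnot(b[i] == as.raw(0xFF))
    marker <- as.integer(b[i + 1L])
    len <- read_u16be(b, i + 2L)
    if (marker %in% c(0xC0L, 0xC1L, 0xC2L))
      return(c(width = read_u16be(b, i + 7L), height = read_u16be(b, i + 5L)))
    i <- i + 2L + len
  }
  stop("no SOF marker")
}

bmp_dims <- function(path) {
  b <- readBin(path, "raw", 30L)
  c(width = read_u32le(b, 19L), height = read_u32le(b, 23L))
}

test_that("each format writes a non-empty file with its magic signature", {
  scene <- render_scene()
  for (fmt in c("svg", "eps", "pdf", "png", "jpeg", "bmp")) {
    path <- tempfile(fileext = paste0(".", fmt))
    render(scene, fmt, path, raster_dpi = 72)
    expect_gt(file.size(path), 0)
    expect_identical(file_signature(path), fmt)
  }
})

test_that("unknown formats and unwritable paths fail with named errors", {
  scene <- render_scene()
  expect_error(render(scene, "tiff", tempfile()), "unknown output format",
               class = "svz_render_error")
  expect_error(render(scene, "svg", "/no/such/dir/x.svg"),
               "directory", class = "svz_render_error")
})

test_that("vector outputs are byte-identical across repeated runs", {
  scene <- render_scene()
  for (fmt in c("svg", "eps", "pdf")) {
    p1 <- tempfile(fileext = paste0(".", fmt))
    p2 <- tempfile(fileext = paste0(".", fmt))
    render(scene, fmt, p1)
    render(scene, fmt, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)),
                     label = paste(fmt, "bytes"))
  }
})

test_that("vector files contain one drawable element per scene primitive", {
  scene <- render_scene()
  kinds <- vapply(scene$primitives, `[[`, "", "kind")
  n_shapes <- sum(kinds != "text" & kinds != "segment")
  n_text <- sum(kinds == "text")
  n_seg <- sum(kinds == "segment")

  svg <- readLines(render(scene, "svg", tempfile(fileext = ".svg")))
  expect_identical(sum(grepl("^<path ", svg)), n_shapes + 0L)
  expect_identical(sum(grepl("^<text ", svg)), n_text)
  expect_identical(sum(grepl("^<line ", svg)), n_seg)

  eps <- readLines(render(scene, "eps", tempfile(fileext = ".eps")))
  expect_identical(sum(eps == "closepath"), n_shapes + 0L)
  expect_identical(sum(grepl(" show$", eps)), n_text)
  expect_identical(eps[[2L]], "%%BoundingBox: 0 0 200 200")

  pdf <- readLines(render(scene, "pdf", tempfile(fileext = ".pdf")))
  expect_identical(sum(pdf == "h"), n_shapes)
  expect_identical(sum(pdf == "ET"), n_text)
})

test_that("the hand-written PDF cross-references are internally consistent", {
  scene <- render_scene()
  path <- render(scene, "pdf", tempfile(fileext = ".pdf"))
  bytes <- readBin(path, "raw", file.size(path))
  txt <- rawToChar(bytes)
  # every xref offset must point at the matching "N 0 obj" byte
  xref <- regmatches(txt, regexpr("xref\n[^t]*", txt))
  offsets <- as.integer(regmatches(xref,
    gregexpr("\\d{10}(?= 00000 n)", xref, perl = TRUE))[[1L]])
  for (i in seq_along(offsets)) {
    at <- rawToChar(bytes[(offsets[[i]] + 1L):(offsets[[i]] + 12L)])
    expect_match(at, sprintf("^%d 0 obj", i))
  }
  # declared stream length matches the actual stream byte count
  len <- as.integer(sub(".*/Length (\\d+).*", "\\1", txt))
  stream <- regmatches(txt, regexpr("stream\n.*?\nendstream", txt))
  expect_identical(nchar(stream, "bytes") - nchar("stream\n\nendstream"), len)
})

test_that("raster pixel dimensions are round(canvas * dpi / 72)", {
  scene <- render_scene()  # 200 x 200 pt
  png72 <- render(scene, "png", tempfile(fileext = ".png"), raster_dpi = 72)
  expect_identical(dim(png::readPNG(png72))[1:2], c(200L, 200L))
  png150 <- render(scene, "png", tempfile(fileext = ".png"), raster_dpi = 150)
  expect_equal(dim(png::readPNG(png150))[1:2],
               rep(round(200 * 150 / 72), 2L))
  expect_equal(unname(jpeg_dims(render(scene, "jpeg",
                                       tempfile(fileext = ".jpg"),
                                       raster_dpi = 72))), c(200, 200))
  expect_equal(unname(bmp_dims(render(scene, "bmp",
                                      tempfile(fileext = ".bmp"),
                                      raster_dpi = 72))), c(200, 200))
})

test_that("doubling dpi doubles raster pixels while SVG bytes are unchanged", {
  scene <- render_scene()
  s1 <- render(scene, "svg", tempfile(fileext = ".svg"))
  p72 <- render(scene, "png", tempfile(fileext = ".png"), raster_dpi = 72)
  p144 <- render(scene, "png", tempfile(fileext = ".png"), raster_dpi = 144)
  s2 <- render(scene, "svg", tempfile(fileext = ".svg"))
  d72 <- dim(png::readPNG(p72)); d144 <- dim(png::readPNG(p144))
  expect_identical(d144[1:2], 2L * d72[1:2])
  expect_identical(readBin(s1, "raw", file.size(s1)),
                   readBin(s2, "raw", file.size(s2)))
})

test_that("render_all_formats writes six files with six correct signatures", {
  scene <- render_scene()
  stem <- tempfile("all")
  files <- render_all_formats(scene, stem, raster_dpi = 72)
  expect_length(files, 6L)
  expect_setequal(names(files), c("svg", "eps", "pdf", "png", "jpeg", "bmp"))
  for (fmt in names(files))
    expect_identical(file_signature(files[[fmt]]), fmt)
  # an empty scene still yields six valid minimal files
  empty <- synviz:::new_scene(100, 80)
  files0 <- render_all_formats(empty, tempfile("empty"), raster_dpi = 72)
  for (fmt in names(files0))
    expect_identical(file_signature(files0[[fmt]]), fmt)
})

test_that("externally rasterized SVG agrees with the direct PNG", {
  # independent oracle for the hand-written SVG: rsvg renders it, and the
  # result must match the cairo-rendered PNG up to anti-aliasing noise
  rsvg <- Sys.which("rsvg-convert")
  expect_true(nzchar(rsvg))
  scene <- render_scene()
  direct <- render(scene, "png", tempfile(fileext = ".png"), raster_dpi = 72)
  svg <- render(scene, "svg", tempfile(fileext = ".svg"))
  via_svg <- tempfile(fileext = ".png")
  system2(rsvg, c("-w", "200", "-h", "200", svg, "-o", via_svg),
          stderr = FALSE)
  a <- png::readPNG(direct); b <- png::readPNG(via_svg)
  if (dim(b)[3L] == 4L) {  # composite alpha over white
    al <- b[, , 4L]
    b <- array(b[, , 1:3] * as.vector(al) + (1 - as.vector(al)), dim(a))
  }
  expect_lt(mean(abs(a - b)), 0.02)
})
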