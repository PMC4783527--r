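#' @title Readers for the three input files
#' @description
#' The toolkit takes three inputs: a synteny/collinearity file in the
#' MCScanX output dialect, a gene annotation file (MCScanX simplified
#' 4-column positions or GFF3, auto-detected), and a flat key=value control
#' file of plot parameters.
#' @name synviz-io
NULL

## ---- collinearity ----------------------------------------------------------

# MCScanX block header, e.g.
#   ## Alignment 0: score=9171.0 e_value=0 N=155 os1&sb1 plus
RE_HEADER <- paste0("^##\\s*Alignment\\s+(\\d+):\\s*",
                    "score\\s*=\\s*([0-9.eE+-]+)\\s+",
                    "e_value\\s*=\\s*(\\S+)\\s+",
                    "N\\s*=\\s*(\\d+)\\s+",
                    "(\\S+)&(\\S+)\\s+(plus|minus)\\s*$")
# Anchor line, e.g. "  0-  0:\tOs01g0100100\tSb01g000200\t  0"
RE_ANCHOR <- "^\\s*(\\d+)-\\s*(\\d+):\\s*(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*$"

parse_evalue <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) return(NA_real_)
  max(v, 0)  # underflowed scientific notation clamps to 0
}

#' Parse an MCScanX collinearity file
#'
#' Reads "## Alignment" block headers and the anchor gene-pair lines that
#' follow each one.  All other lines starting with \code{#} (the parameter
#' and statistics banners MCScanX writes) are ignored.  Tabs, spaces and
#' alignment padding are tolerated anywhere.
#'
#' @param path path to a \code{.collinearity} text file.
#' @return List of \code{synteny_block}, in file order.  Each block carries
#'   \code{block_id}, \code{score}, \code{e_value}, \code{n_declared},
#'   \code{chrom_a}, \code{chrom_b}, \code{orientation} and an
#'   \code{anchors} data frame (\code{gene_a}, \code{gene_b}, \code{e_value},
#'   \code{index_in_block}).
#' @export
parse_collinearity <- function(path) {
  if (!file.exists(path))
    svz_usage_error(sprintf("collinearity file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  blocks <- list()
  cur <- NULL
  cur_anchors <- list()
  flush_block <- function() {
    if (is.null(cur)) return()
    an <- if (length(cur_anchors)) do.call(rbind, cur_anchors) else
      data.frame(gene_a = character(), gene_b = character(),
                 e_value = numeric(), stringsAsFactors = FALSE)
    if (nrow(an) != cur$n_declared)
      svz_format_error(sprintf("block %d: declared %d anchors, found %d",
                               cur$block_id, cur$n_declared, nrow(an)))
    an$index_in_block <- seq_len(nrow(an)) - 1L
    blocks[[length(blocks) + 1L]] <<- new_synteny_block(
      cur$block_id, cur$score, cur$e_value, cur$n_declared,
      cur$chrom_a, cur$chrom_b, cur$orientation, an)
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*$", ln)) next
    hm <- regmatches(ln, regexec(RE_HEADER, ln))[[1L]]
    if (length(hm)) {
      flush_block()
      cur_anchors <- list()
      ev <- parse_evalue(hm[[4L]])
      if (is.na(ev))
        svz_format_error(sprintf("line %d: unparsable e_value '%s'", i, hm[[4L]]))
      cur <- list(block_id = as.integer(hm[[2L]]),
                  score = as.numeric(hm[[3L]]), e_value = ev,
                  n_declared = as.integer(hm[[5L]]),
                  chrom_a = hm[[6L]], chrom_b = hm[[7L]],
                  orientation = hm[[8L]])
      next
    }
    if (grepl("^\\s*#", ln)) {
      if (grepl("^\\s*##\\s*Alignment", ln))
        svz_format_error(sprintf("line %d: unparsable block header: %s", i, ln))
      next  # commentary / parameter banner
    }
    am <- regmatches(ln, regexec(RE_ANCHOR, ln))[[1L]]
    if (!length(am))
      svz_format_error(sprintf("line %d: unrecognized line in collinearity file: %s",
                               i, trimws(ln)))
    if (is.null(cur))
      svz_format_error(sprintf("line %d: anchor pair before any block header", i))
    ev <- parse_evalue(am[[6L]])
    if (is.na(ev))
      svz_format_error(sprintf("line %d: unparsable e_value '%s'", i, am[[6L]]))
    cur_anchors[[length(cur_anchors) + 1L]] <-
      data.frame(gene_a = am[[4L]], gene_b = am[[5L]], e_value = ev,
                 stringsAsFactors = FALSE)
  }
  flush_block()
  blocks
}

## ---- gene annotation -------------------------------------------------------

#' Detect the gene annotation dialect
#'
#' @param first_data_lines character vector of non-comment lines sampled from
#'   the file head.
#' @return \code{"simplified"} (MCScanX 4-column gene positions) or
#'   \code{"gff3"}.
#' @export
detect_annotation_dialect <- function(first_data_lines) {
  lines <- first_data_lines[!grepl("^\\s*(#|$)", first_data_lines)]
  if (!length(lines))
    svz_format_error("annotation file has no data lines")
  shape <- vapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) == 4L &&
        !anyNA(suppressWarnings(as.integer(f[3:4])))) "simplified"
    else if (length(f) >= 8L) "gff3"
    else "unknown"
  }, "", USE.NAMES = FALSE)
  u <- unique(shape)
  if (length(u) != 1L || u == "unknown")
    svz_format_error("unrecognized annotation format: neither 4-column gene positions nor GFF3")
  u
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))[[1L]]
  if (length(m) < 2L) NA_character_ else m[[2L]]
}

#' Parse a gene annotation file
#'
#' Auto-detects the dialect.  The simplified dialect is the tab-separated
#' 4-column file MCScanX distributes (\code{chrom_id  gene_id  start  end});
#' strand is recorded as \code{"unknown"}.  For GFF3, only rows whose type
#' column is \code{gene} are kept; the gene id is the \code{ID} attribute.
#'
#' @param path path to the annotation file.
#' @return Gene data frame (see [gene_table()]).
#' @export
parse_gene_positions <- function(path) {
  if (!file.exists(path))
    svz_usage_error(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  dialect <- detect_annotation_dialect(utils::head(lines[keep], 50L))
  lineno <- which(keep)
  lines <- lines[keep]

  if (dialect == "simplified") {
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) != 4L)
    if (length(bad))
      svz_format_error(sprintf("line %d: expected 4 tab-separated fields",
                               lineno[[bad[[1L]]]]))
    m <- do.call(rbind, f)
    start <- suppressWarnings(as.integer(m[, 3L]))
    end <- suppressWarnings(as.integer(m[, 4L]))
    bad <- which(is.na(start) | is.na(end) | start > end | start < 1L)
    if (length(bad))
      svz_format_error(sprintf("line %d: bad gene coordinates (%s..%s)",
                               lineno[[bad[[1L]]]], m[bad[[1L]], 3L], m[bad[[1L]], 4L]))
    genes <- data.frame(gene_id = trimws(m[, 2L]), chrom_id = trimws(m[, 1L]),
                        start = start, end = end, strand = "unknown",
                        stringsAsFactors = FALSE)
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    is_gene <- vapply(f, function(x) length(x) >= 9L && x[[3L]] == "gene", NA)
    rows <- f[is_gene]
    lineno <- lineno[is_gene]
    if (!length(rows))
      svz_format_error("GFF3 file contains no rows of type 'gene'")
    ids <- vapply(seq_along(rows), function(i) {
      id <- gff3_attr(rows[[i]][[9L]], "ID")
      if (is.na(id))
        svz_format_error(sprintf("line %d: GFF3 gene row lacks an ID attribute",
                                 lineno[[i]]))
      id
    }, "")
    start <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 4L)))
    end <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 5L)))
    bad <- which(is.na(start) | is.na(end) | start > end | start < 1L)
    if (length(bad))
      svz_format_error(sprintf("line %d: bad gene coordinates", lineno[[bad[[1L]]]]))
    strand <- vapply(rows, `[[`, "", 7L)
    strand[!strand %in% c("+", "-")] <- "unknown"
    genes <- data.frame(gene_id = ids,
                        chrom_id = vapply(rows, `[[`, "", 1L),
                        start = start, end = end, strand = strand,
                        stringsAsFactors = FALSE)
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    svz_format_error(sprintf("duplicate gene_id '%s' in annotation", dup[[1L]]))
  genes
}

## ---- control file / plot configuration -------------------------------------

#' Default qualitative palette
#'
#' Twenty distinguishable hues cycled by chromosome (or block) index.
#' @return Character vector of 20 \code{#RRGGBB} colors.
#' @export
default_palette <- function() c(
  "#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
  "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
  "#AEC7E8", "#FFBB78", "#98DF8A", "#FF9896", "#C5B0D5",
  "#C49C94", "#F7B6D2", "#C7C7C7", "#DBDB8D", "#9EDAE5")

PLOT_TYPES <- c("circle", "bar", "dot", "dual")
OUT_FORMATS <- c("svg", "eps", "pdf", "png", "jpeg", "bmp")

check_hex <- function(cols, key) {
  ok <- grepl("^#[0-9A-Fa-f]{6}$", cols)
  if (!all(ok))
    svz_config_error(sprintf("%s: '%s' is not a #RRGGBB color", key, cols[!ok][[1L]]))
  toupper(cols)
}

#' Construct a plot configuration
#'
#' All parameters of the four plot geometries and six output formats, with
#' documented defaults.  \code{canvas_height} defaults to 1000 pt for the
#' square geometries (circle, dot) and 700 pt for the track geometries
#' (bar, dual) when left \code{NA}.
#'
#' @param plot_type one of circle, bar, dot, dual.
#' @param out_format one of svg, eps, pdf, png, jpeg, bmp.
#' @param canvas_width,canvas_height canvas size in points.
#' @param margin outer margin in points.
#' @param gap_angle inter-chromosome gap of the circular layout, radians.
#' @param palette ordered vector of \code{#RRGGBB} colors, cycled by index.
#' @param ribbon_opacity fill opacity of ribbons/bands in \code{[0, 1]}.
#' @param ribbon_pull curvature of ribbon edges: interior control points are
#'   the chord endpoints pulled toward the circle center by this factor
#'   (0 = control points at the center, the classic chord-diagram pinch).
#' @param dual_pair optional \code{c(species_a, species_b)} for the dual plot.
#' @param label_font_size label size in points.
#' @param min_block_anchors blocks with fewer anchors are filtered out
#'   (>= 2).
#' @param raster_dpi resolution of PNG/JPEG/BMP output.
#' @param axis_gap inter-chromosome gap of the dot-plot axes, points.
#' @param chrom_length_overrides named list chrom_id -> bp.
#' @param validation_policy \code{"strict"} or \code{"drop"}.
#' @param background canvas background color.
#' @param jpeg_quality JPEG quality, 1-100.
#' @return A \code{plot_config} object (list).
#' @export
plot_config <- function(plot_type = "circle", out_format = "svg",
                        canvas_width = 1000, canvas_height = NA,
                        margin = 40, gap_angle = 2 * pi / 180,
                        palette = default_palette(),
                        ribbon_opacity = 0.45, ribbon_pull = 0,
                        dual_pair = NULL, label_font_size = 12,
                        min_block_anchors = 2, raster_dpi = 300,
                        axis_gap = 10, chrom_length_overrides = list(),
                        validation_policy = "strict",
                        background = "#FFFFFF", jpeg_quality = 92) {
  if (!plot_type %in% PLOT_TYPES)
    svz_config_error(sprintf("plot_type must be one of %s (got '%s')",
                             paste(PLOT_TYPES, collapse = ", "), plot_type))
  if (!out_format %in% OUT_FORMATS)
    svz_config_error(sprintf("out_format must be one of %s (got '%s')",
                             paste(OUT_FORMATS, collapse = ", "), out_format))
  num_pos <- function(x, key, min = NULL, max = NULL, allow_na = FALSE) {
    if (allow_na && is.na(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) svz_config_error(sprintf("%s must be numeric", key))
    if (!is.null(min) && v < min || !is.null(max) && v > max)
      svz_config_error(sprintf("%s must be in [%s,%s]", key,
                               if (is.null(min)) "-Inf" else min,
                               if (is.null(max)) "Inf" else max))
    v
  }
  cfg <- list(
    plot_type = plot_type, out_format = out_format,
    canvas_width = num_pos(canvas_width, "canvas_width", min = 1),
    canvas_height = num_pos(canvas_height, "canvas_height", min = 1,
                            allow_na = TRUE),
    margin = num_pos(margin, "margin", min = 0),
    gap_angle = num_pos(gap_angle, "gap_angle", min = 0),
    palette = check_hex(palette, "palette"),
    ribbon_opacity = num_pos(ribbon_opacity, "ribbon_opacity", 0, 1),
    ribbon_pull = num_pos(ribbon_pull, "ribbon_pull", 0, 1),
    dual_pair = dual_pair,
    label_font_size = num_pos(label_font_size, "label_font_size", min = 1),
    min_block_anchors = as.integer(num_pos(min_block_anchors,
                                           "min_block_anchors", min = 2)),
    raster_dpi = as.integer(num_pos(raster_dpi, "raster_dpi", min = 1)),
    axis_gap = num_pos(axis_gap, "axis_gap", min = 0),
    chrom_length_overrides = chrom_length_overrides,
    validation_policy = match.arg(validation_policy, c("strict", "drop")),
    background = check_hex(background, "background"),
    jpeg_quality = as.integer(num_pos(jpeg_quality, "jpeg_quality", 1, 100)))
  structure(cfg, class = "plot_config")
}

#' Canvas size resolved for a concrete plot type
#'
#' Square geometries (circle, dot) default to 1000 x 1000 pt, track
#' geometries (bar, dual) to 1000 x 700 pt; an explicit
#' \code{canvas_height} always wins.
#'
#' @param config a [plot_config()].
#' @param plot_type plot type to resolve for.
#' @return Named numeric \code{c(width, height)} in points.
#' @export
resolve_canvas <- function(config, plot_type = config$plot_type) {
  h <- config$canvas_height
  if (is.na(h)) h <- if (plot_type %in% c("circle", "dot")) 1000 else 700
  c(width = config$canvas_width, height = h)
}

#' @export
print.plot_config <- function(x, ...) {
  cv <- resolve_canvas(x)
  cat(sprintf("plot_config: %s -> %s, canvas %g x %g pt, margin %g pt\n",
              x$plot_type, x$out_format, cv[["width"]], cv[["height"]],
              x$margin))
  invisible(x)
}

#' Parse a control file into a plot configuration
#'
#' The control file is flat \code{key=value} text, one pair per line,
#' \code{#} comments allowed.  Unknown keys warn and are ignored; missing
#' keys take the defaults of [plot_config()].  List-valued keys:
#' \code{palette} is comma-separated colors, \code{dual_pair} is
#' \code{tagA,tagB}, and \code{chrom_lengths} is comma-separated
#' \code{chrom:bp} pairs.
#'
#' @param x path to a control file, or a named list of values.
#' @param overrides named list applied on top (CLI precedence).
#' @return A \code{plot_config}.
#' @export
parse_config <- function(x = list(), overrides = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x))
      svz_usage_error(sprintf("control file not found: %s", x))
    lines <- readLines(x, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- regmatches(lines, regexec("^\\s*([A-Za-z_.]+)\\s*=\\s*(.*?)\\s*$", lines))
    bad <- which(lengths(kv) < 3L)
    if (length(bad))
      svz_format_error(sprintf("control file: unparsable line '%s'",
                               lines[[bad[[1L]]]]))
    x <- stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
  }
  vals <- utils::modifyList(as.list(x), as.list(overrides))

  split_csv <- function(s) trimws(strsplit(paste(s, collapse = ","), ",")[[1L]])
  if (!is.null(vals$palette)) vals$palette <- split_csv(vals$palette)
  if (!is.null(vals$dual_pair)) {
    vals$dual_pair <- split_csv(vals$dual_pair)
    if (length(vals$dual_pair) != 2L)
      svz_config_error("dual_pair must name exactly two species tags (tagA,tagB)")
  }
  if (!is.null(vals$chrom_lengths)) {
    pairs <- split_csv(vals$chrom_lengths)
    m <- regmatches(pairs, regexec("^(\\S+):(\\d+)$", pairs))
    if (any(lengths(m) < 3L))
      svz_config_error("chrom_lengths must be comma-separated chrom:bp pairs")
    vals$chrom_length_overrides <-
      stats::setNames(lapply(m, function(p) as.numeric(p[[3L]])),
                      vapply(m, `[[`, "", 2L))
    vals$chrom_lengths <- NULL
  }

  known <- names(formals(plot_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown control-file key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    vals <- vals[setdiff(names(vals), unknown)]
  }
  do.call(plot_config, vals)
}
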