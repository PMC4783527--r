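#' @title Plot manager: one call from input files to figures
#' @description
#' The driver that integrates all plot types and output formats behind one
#' entry point: parse the three inputs, validate, filter, lay out, build the
#' scene, render.  [run_matrix()] renders the Cartesian product of requested
#' plot types and formats with deterministic file names.
#' @name synviz-run
NULL

#' Describe one plotting run
#'
#' @param collinearity_path path to the MCScanX-dialect collinearity file.
#' @param annotation_path path to the gene annotation file (simplified
#'   4-column or GFF3).
#' @param config_path optional control file (flat key=value).
#' @param overrides named list of config values applied on top of the
#'   control file (CLI precedence: file < overrides).
#' @param out_path output path: used verbatim by [run_synteny_plot()] when
#'   it ends in the requested format's extension, otherwise treated as a
#'   stem for \code{<stem>.<plot>.<format>} names.
#' @return A \code{run_request}.
#' @export
run_request <- function(collinearity_path, annotation_path,
                        config_path = NULL, overrides = list(),
                        out_path = "synteny") {
  if (missing(collinearity_path) || is.null(collinearity_path))
    svz_usage_error("--collinearity: a collinearity file is required")
  if (missing(annotation_path) || is.null(annotation_path))
    svz_usage_error("--gff: a gene annotation file is required")
  structure(list(collinearity_path = collinearity_path,
                 annotation_path = annotation_path,
                 config_path = config_path, overrides = overrides,
                 out_path = out_path),
            class = "run_request")
}

# Shared front half of every run: inputs -> filtered, validated dataset.
load_dataset <- function(request, config) {
  genes <- parse_gene_positions(request$annotation_path)
  genomes <- build_genome_models(genes, config$chrom_length_overrides)
  blocks <- parse_collinearity(request$collinearity_path)
  n_parsed <- length(blocks)
  dataset <- join_and_validate(genomes, blocks, config$validation_policy)
  n_valid <- length(dataset$blocks)
  dataset$blocks <- filter_blocks(dataset$blocks, config)
  dataset$report$blocks_filtered <- n_valid - length(dataset$blocks)
  dataset$report$blocks_parsed <- n_parsed
  dataset
}

run_log <- function(dataset, files, verbose) {
  ct <- chromosome_table(dataset$genomes)
  lines <- c(
    sprintf("genomes: %d (%s)", length(dataset$genomes),
            paste(vapply(dataset$genomes, `[[`, "", "species_tag"),
                  collapse = ", ")),
    sprintf("chromosomes: %d", nrow(ct)),
    sprintf("genes: %d", nrow(dataset$gene_index)),
    sprintf("blocks: %d parsed, %d kept, %d dropped by validation, %d filtered",
            dataset$report$blocks_parsed, length(dataset$blocks),
            dataset$report$blocks_dropped, dataset$report$blocks_filtered),
    sprintf("anchors dropped: %d", dataset$report$anchors_dropped),
    sprintf("wrote: %s", files))
  if (verbose) message(paste(lines, collapse = "\n"))
  lines
}

#' Run one plotting pipeline
#'
#' parse -> validate -> filter -> layout -> scene -> render, for the plot
#' type and format(s) in the resolved configuration.
#'
#' @param request a [run_request()].
#' @param formats character vector of output formats (defaults to the
#'   configured \code{out_format}).
#' @param verbose emit the summary log as messages.
#' @return Invisibly, a list with \code{files}, \code{dataset},
#'   \code{config} and the summary \code{log} lines.
#' @export
run_synteny_plot <- function(request, formats = NULL, verbose = FALSE) {
  config <- parse_config(
    if (is.null(request$config_path)) list() else request$config_path,
    request$overrides)
  if (is.null(formats)) formats <- config$out_format
  dataset <- load_dataset(request, config)
  layout <- layout_dataset(dataset, config)
  scene <- layout_to_scene(layout, config)

  files <- character(0)
  for (f in formats) {
    path <- if (length(formats) == 1L &&
                grepl(paste0("\\.", f, "$"), request$out_path))
      request$out_path
    else paste0(sub("\\.[A-Za-z]+$", "", request$out_path), ".",
                config$plot_type, ".", f)
    render(scene, f, path, config$raster_dpi, config$jpeg_quality)
    files <- c(files, path)
  }
  log <- run_log(dataset, files, verbose)
  invisible(list(files = files, dataset = dataset, config = config,
                 log = log))
}

#' Render the full plot-by-format matrix
#'
#' One call for the Cartesian product of plot types and formats;
#' \code{"all"} x \code{"all"} yields the 4 x 6 = 24 files
#' \code{<stem>.<plot>.<format>}.
#'
#' @param request a [run_request()]; its \code{out_path} is the stem.
#' @param plots \code{"all"} or a subset of
#'   \code{c("circle","bar","dot","dual")}.
#' @param formats \code{"all"} or a subset of
#'   \code{c("svg","eps","pdf","png","jpeg","bmp")}.
#' @param verbose emit the summary log.
#' @return Invisibly, list with \code{files} (named by
#'   \code{<plot>.<format>}), \code{dataset}, \code{config}, \code{log}.
#' @export
run_matrix <- function(request, plots = "all", formats = "all",
                       verbose = FALSE) {
  if (identical(plots, "all")) plots <- PLOT_TYPES
  if (identical(formats, "all")) formats <- OUT_FORMATS
  bad <- setdiff(plots, PLOT_TYPES)
  if (length(bad))
    svz_usage_error(sprintf("unknown plot type '%s'", bad[[1L]]))
  bad <- setdiff(formats, OUT_FORMATS)
  if (length(bad))
    svz_render_error(sprintf(
      "unknown output format '%s' (supported: %s)", bad[[1L]],
      paste(OUT_FORMATS, collapse = ", ")))

  config <- parse_config(
    if (is.null(request$config_path)) list() else request$config_path,
    request$overrides)
  dataset <- load_dataset(request, config)
  stem <- sub("\\.[A-Za-z]+$", "", request$out_path)

  files <- character(0)
  for (p in plots) {
    cfg_p <- config
    cfg_p$plot_type <- p
    scene <- tryCatch(
      layout_to_scene(layout_dataset(dataset, cfg_p), cfg_p),
      error = function(e) svz_stop(
        sprintf("plot %s: %s", p, conditionMessage(e)),
        class(e)[[1L]]))
    for (f in formats) {
      path <- paste0(stem, ".", p, ".", f)
      tryCatch(render(scene, f, path, config$raster_dpi, config$jpeg_quality),
               error = function(e) svz_render_error(
                 sprintf("combination %s x %s: %s", p, f,
                         conditionMessage(e))))
      files[[paste0(p, ".", f)]] <- path
    }
  }
  log <- run_log(dataset, files, verbose)
  invisible(list(files = files, dataset = dataset, config = config,
                 log = log))
}
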