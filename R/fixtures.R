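#' @title Seeded synthetic fixture generator
#' @description
#' Emits format-valid collinearity + annotation file pairs with known ground
#' truth, so every pipeline stage is testable without real genome data.
#' Genes are laid end to start with exponential intergenic gaps; blocks pair
#' runs of consecutive genes on two chromosome segments (order reversed on
#' side b for minus-orientation blocks).  The same seed always yields
#' byte-identical files.  Fixtures are shape-controllable stand-ins, not
#' simulations of real evolutionary block structure.
#' @name synviz-fixtures
NULL

# Run code under a private RNG stream: the global .Random.seed is saved and
# restored, so generation is seed-addressable without touching user state.
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture generation parameters
#'
#' @param seed integer seed; same seed, same bytes.
#' @param species list of species descriptors, each a list with \code{tag},
#'   \code{n_chromosomes}, \code{genes_per_chromosome},
#'   \code{mean_gene_length_bp}, \code{mean_intergenic_bp}.
#' @param n_blocks number of collinear blocks to emit.
#' @param anchors_per_block integer range \code{c(min, max)} of anchors per
#'   block.
#' @param p_minus probability a block has minus orientation.
#' @param p_cross_species probability a block joins two different species.
#' @return A \code{fixture_params} list.
#' @export
fixture_params <- function(seed = 1L,
                           species = list(
                             list(tag = "aa", n_chromosomes = 3L,
                                  genes_per_chromosome = 40L,
                                  mean_gene_length_bp = 2000,
                                  mean_intergenic_bp = 3000),
                             list(tag = "bb", n_chromosomes = 2L,
                                  genes_per_chromosome = 40L,
                                  mean_gene_length_bp = 2000,
                                  mean_intergenic_bp = 3000)),
                           n_blocks = 12L,
                           anchors_per_block = c(3L, 8L),
                           p_minus = 0.3, p_cross_species = 1.0) {
  stopifnot(length(species) >= 1L, n_blocks >= 1L,
            all(anchors_per_block >= 1L),
            p_minus >= 0, p_minus <= 1,
            p_cross_species >= 0, p_cross_species <= 1)
  structure(list(seed = as.integer(seed), species = species,
                 n_blocks = as.integer(n_blocks),
                 anchors_per_block = as.integer(range(anchors_per_block)),
                 p_minus = p_minus, p_cross_species = p_cross_species),
            class = "fixture_params")
}

generate_genes <- function(sp) {
  do.call(rbind, lapply(seq_len(sp$n_chromosomes), function(ci) {
    n <- sp$genes_per_chromosome
    gaps <- 1L + round(stats::rexp(n, 1 / sp$mean_intergenic_bp))
    lens <- 1L + round(stats::rexp(n, 1 / sp$mean_gene_length_bp))
    start <- cumsum(gaps) + cumsum(c(0L, utils::head(lens, -1L)))
    data.frame(
      gene_id = sprintf("%s%02dg%04d", toupper(sp$tag), ci, seq_len(n) * 10L),
      chrom_id = sprintf("%s%02d", sp$tag, ci),
      start = as.integer(start), end = as.integer(start + lens - 1L),
      strand = "unknown", stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic fixture
#'
#' Writes a collinearity file and a simplified 4-column annotation file in
#' the exact dialects the package reads, and returns the ground truth they
#' encode.
#'
#' @param params a [fixture_params()].
#' @param dir directory to write into (created if needed).
#' @return A \code{fixture_truth} list: \code{genomes} (a
#'   \code{genome_set}), \code{blocks}, \code{genes}, the per-block
#'   \code{anchor_histogram}, and the two file paths
#'   (\code{collinearity_path}, \code{annotation_path}).
#' @export
generate_fixture <- function(params, dir = tempfile("fixture")) {
  stopifnot(inherits(params, "fixture_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_private_seed(params$seed, {
    genes <- do.call(rbind, lapply(params$species, generate_genes))
    genomes <- build_genome_models(genes)
    ct <- chromosome_table(genomes)
    tags <- vapply(params$species, `[[`, "", "tag")

    # sample one integer from [lo, hi] without R's sample(n, 1) pitfall
    sample_range <- function(lo, hi)
      if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

    blocks <- lapply(seq_len(params$n_blocks) - 1L, function(bid) {
      k <- sample_range(params$anchors_per_block[[1L]],
                        params$anchors_per_block[[2L]])
      max_genes <- max(vapply(params$species, `[[`, 0L,
                              "genes_per_chromosome"))
      if (k > max_genes)
        svz_usage_error(sprintf(
          "fixture params demand %d anchors but chromosomes carry at most %d genes",
          k, max_genes))
      cross <- length(tags) > 1L &&
        stats::runif(1L) < params$p_cross_species
      if (cross) {
        pair <- sample(tags, 2L)
        ca <- sample(ct$chrom_id[ct$species_tag == pair[[1L]]], 1L)
        cb <- sample(ct$chrom_id[ct$species_tag == pair[[2L]]], 1L)
      } else {
        tag <- sample(tags, 1L)
        ca <- sample(ct$chrom_id[ct$species_tag == tag], 1L)
        cb <- sample(ct$chrom_id[ct$species_tag == tag], 1L)
      }
      pick_run <- function(cid) {
        g <- genes[genes$chrom_id == cid, , drop = FALSE]
        g <- g[order(g$start), , drop = FALSE]
        i0 <- sample_range(1L, nrow(g) - k + 1L)
        g$gene_id[i0:(i0 + k - 1L)]
      }
      ga <- pick_run(ca)
      gb <- pick_run(cb)
      minus <- stats::runif(1L) < params$p_minus
      if (minus) gb <- rev(gb)
      an <- data.frame(gene_a = ga, gene_b = gb,
                       e_value = 0, index_in_block = seq_len(k) - 1L,
                       stringsAsFactors = FALSE)
      new_synteny_block(bid, score = 50 * k, e_value = 0, n_declared = k,
                        chrom_a = ca, chrom_b = cb,
                        orientation = if (minus) "minus" else "plus",
                        anchors = an)
    })

    coll_path <- file.path(dir, "fixture.collinearity")
    gff_path <- file.path(dir, "fixture.gff")
    write_collinearity_file(blocks, coll_path)
    write_annotation_file(genes, gff_path)
    structure(list(genomes = genomes, blocks = blocks, genes = genes,
                   anchor_histogram = table(vapply(blocks, function(b)
                     nrow(b$anchors), 0L)),
                   collinearity_path = coll_path,
                   annotation_path = gff_path),
              class = "fixture_truth")
  })
}

# Emit the MCScanX collinearity dialect (zero padding dropped in header
# chromosome tags, as MCScanX does).
write_collinearity_file <- function(blocks, path) {
  lines <- c("############### Parameters ###############",
             "# MATCH_SCORE: 50",
             "# MATCH_SIZE: 5",
             "# GAP_PENALTY: -1",
             "############### Statistics ###############",
             sprintf("# Number of collinear blocks: %d", length(blocks)))
  for (b in blocks) {
    lines <- c(lines, sprintf(
      "## Alignment %d: score=%.1f e_value=%s N=%d %s&%s %s",
      b$block_id, b$score, format(b$e_value, scientific = TRUE, digits = 3),
      b$n_declared, normalize_chrom_id(b$chrom_a),
      normalize_chrom_id(b$chrom_b), b$orientation))
    lines <- c(lines, sprintf("%3d-%3d:\t%s\t%s\t%7s", b$block_id,
                              b$anchors$index_in_block, b$anchors$gene_a,
                              b$anchors$gene_b,
                              format(b$anchors$e_value, digits = 3)))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Simplified 4-column gene positions, tab-separated.
write_annotation_file <- function(genes, path) {
  g <- genes[order(genes$chrom_id, genes$start), , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%d\t%d", g$chrom_id, g$gene_id, g$start, g$end),
             path, useBytes = TRUE)
  invisible(path)
}

#' Rice/Sorghum-shaped demo fixture
#'
#' A convenience preset shaped like a rice vs sorghum comparison: two
#' species tagged \code{os} (12 chromosomes) and \code{sb} (10 chromosomes),
#' cross-species blocks only.  This is a desk-scale synthetic stand-in for
#' that kind of dataset, not real genome data.
#'
#' @param dir directory to write the two files into.
#' @param seed seed for the generator (fixed default so the preset is
#'   reproducible).
#' @return A \code{fixture_truth}; the genome set has exactly 22
#'   chromosomes.
#' @export
rice_sorghum_like <- function(dir = tempfile("rice_sorghum"), seed = 42L) {
  params <- fixture_params(
    seed = seed,
    species = list(
      list(tag = "os", n_chromosomes = 12L, genes_per_chromosome = 30L,
           mean_gene_length_bp = 2500, mean_intergenic_bp = 12000),
      list(tag = "sb", n_chromosomes = 10L, genes_per_chromosome = 30L,
           mean_gene_length_bp = 2500, mean_intergenic_bp = 15000)),
    n_blocks = 40L, anchors_per_block = c(3L, 10L),
    p_minus = 0.3, p_cross_species = 1.0)
  generate_fixture(params, dir)
}
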