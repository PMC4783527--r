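# Shared in-code fixtures: everything is built at test time, no data files.

# A minimal two-species gene table: two chromosomes of "os", one of "sb".
tiny_genes <- function() {
  gene_table(
    gene_id = c("OsA", "OsB", "OsC", "OsD", "SbA", "SbB"),
    chrom_id = c("os01", "os01", "os02", "os02", "sb01", "sb01"),
    start = c(2983L, 6000L, 100L, 900L, 50L, 700L),
    end   = c(5000L, 10815L, 500L, 1500L, 400L, 1200L))
}

# Collinearity text for the tiny gene set: one plus block os01~sb01 and one
# minus block os02~sb01 (header tags with zero padding dropped, as MCScanX
# writes them).
tiny_collinearity_lines <- function() c(
  "############### Parameters ###############",
  "# MATCH_SCORE: 50",
  "############### Statistics ###############",
  "## Alignment 0: score=9171.0 e_value=0 N=2 os1&sb1 plus",
  "  0-  0:\tOsA\tSbA\t  0",
  "  0-  1:\tOsB\tSbB\t1e-50",
  "## Alignment 1: score=300.0 e_value=2e-10 N=2 os2&sb1 minus",
  "  1-  0:\tOsC\tSbB\t  0",
  "  1-  1:\tOsD\tSbA\t  0")

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_dataset <- function(policy = "strict") {
  genomes <- build_genome_models(tiny_genes())
  blocks <- parse_collinearity(write_lines_tmp(tiny_collinearity_lines()))
  join_and_validate(genomes, blocks, policy)
}

# Small but non-trivial generated fixture used across layout/render tests.
small_fixture <- function(seed = 7L, n_blocks = 8L) {
  generate_fixture(fixture_params(seed = seed, n_blocks = n_blocks))
}

dataset_from_fixture <- function(fx, config = plot_config()) {
  genomes <- build_genome_models(parse_gene_positions(fx$annotation_path))
  blocks <- parse_collinearity(fx$collinearity_path)
  join_and_validate(genomes, blocks, config$validation_policy)
}

expect_blocks_equal <- function(parsed, truth) {
  expect_length(parsed, length(truth))
  for (i in seq_along(truth)) {
    p <- parsed[[i]]; t <- truth[[i]]
    expect_identical(p$block_id, t$block_id)
    expect_equal(p$score, t$score)
    expect_equal(p$e_value, t$e_value)
    expect_identical(p$n_declared, t$n_declared)
    expect_identical(normalize_chrom_id(p$chrom_a),
                     normalize_chrom_id(t$chrom_a))
    expect_identical(normalize_chrom_id(p$chrom_b),
                     normalize_chrom_id(t$chrom_b))
    expect_identical(p$orientation, t$orientation)
    expect_identical(p$anchors$gene_a, t$anchors$gene_a)
    expect_identical(p$anchors$gene_b, t$anchors$gene_b)
    expect_identical(p$anchors$index_in_block, t$anchors$index_in_block)
  }
}
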