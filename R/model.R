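#' @title Domain model: genomes, chromosomes, genes, blocks
#' @description
#' The in-memory model every later stage draws over.  Genes are rows of a
#' plain data frame (columns \code{gene_id}, \code{chrom_id}, \code{start},
#' \code{end}, \code{strand}); chromosomes, genomes and synteny blocks are
#' lightweight S3 lists.  Coordinates are 1-based inclusive base pairs
#' throughout (GFF convention); conversion to canvas units happens only in
#' the layout stage.
#' @name synviz-model
NULL

## ---- identifier helpers ----------------------------------------------------

# Leading alphabetic run of a chromosome id, e.g. "os01" -> "os".
species_prefix <- function(chrom_id) {
  m <- regmatches(chrom_id, regexpr("^[A-Za-z]+", chrom_id))
  out <- character(length(chrom_id))
  has <- grepl("^[A-Za-z]", chrom_id)
  out[has] <- m
  out[!has] <- NA_character_
  out
}

#' Canonical chromosome id
#'
#' Collinearity headers drop zero padding ("os1") while annotations usually
#' keep it ("os01"); both normalize to species prefix plus unpadded number.
#'
#' @param chrom_id character vector of chromosome ids.
#' @return Normalized ids.
#' @export
normalize_chrom_id <- function(chrom_id) {
  pre <- species_prefix(chrom_id)
  suf <- substring(chrom_id, nchar(pre) + 1L)
  num <- suppressWarnings(as.integer(suf))
  ifelse(is.na(pre), chrom_id,
         ifelse(!is.na(num), paste0(pre, num), chrom_id))
}

# Natural sort order: species prefix lexicographic, then numeric suffix
# ("os2" before "os10"), non-numeric suffixes after, lexicographically.
natural_order <- function(ids) {
  pre <- species_prefix(ids)
  pre[is.na(pre)] <- ""
  suf <- substring(ids, nchar(pre) + 1L)
  num <- suppressWarnings(as.integer(suf))
  order(pre, !is.finite(num), num, ids)
}

## ---- constructors ----------------------------------------------------------

#' Assemble a validated gene table
#'
#' @param gene_id,chrom_id character vectors.
#' @param start,end 1-based inclusive coordinates, \code{start <= end}.
#' @param strand \code{"+"}, \code{"-"} or \code{"unknown"}.
#' @return A data frame with one row per gene.
#' @export
gene_table <- function(gene_id, chrom_id, start, end,
                       strand = rep("unknown", length(gene_id))) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L | start > end))
    svz_format_error("gene coordinates must satisfy 1 <= start <= end")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    svz_format_error(sprintf("duplicate gene_id '%s'", dup[[1L]]))
  stopifnot(all(strand %in% c("+", "-", "unknown")))
  data.frame(gene_id = as.character(gene_id),
             chrom_id = as.character(chrom_id),
             start = start, end = end,
             strand = as.character(strand),
             stringsAsFactors = FALSE)
}

new_synteny_block <- function(block_id, score, e_value, n_declared,
                              chrom_a, chrom_b, orientation, anchors) {
  stopifnot(orientation %in% c("plus", "minus"))
  structure(list(block_id = as.integer(block_id), score = as.numeric(score),
                 e_value = as.numeric(e_value),
                 n_declared = as.integer(n_declared),
                 chrom_a = chrom_a, chrom_b = chrom_b,
                 orientation = orientation, anchors = anchors),
            class = "synteny_block")
}

#' Build genome models from a gene table
#'
#' Groups genes into chromosomes and chromosomes into genomes.  The species
#' tag of a chromosome is the leading alphabetic run of its id ("os01" ->
#' "os"), matching the labeling convention of comparative-genomics figures.
#' Chromosome extents are not part of the input triad, so each chromosome's
#' length is inferred as the maximum gene end it carries unless an explicit
#' override is supplied.
#'
#' @param genes data frame as returned by [gene_table()] or
#'   [parse_gene_positions()].
#' @param length_overrides optional named list/vector, chromosome id ->
#'   length in bp; overrides the inferred extent.
#' @return A \code{genome_set}: list of \code{genome_model} objects, each
#'   holding natural-sorted \code{chromosome_model}s.  Genomes are ordered by
#'   species tag.
#' @export
build_genome_models <- function(genes, length_overrides = NULL) {
  if (is.null(genes) || nrow(genes) == 0L)
    svz_format_error("no genes: annotation is empty")
  pre <- species_prefix(genes$chrom_id)
  if (anyNA(pre)) {
    bad <- which(is.na(pre))[[1L]]
    svz_format_error(sprintf(
      "malformed chromosome id '%s' (gene '%s'): no alphabetic species prefix",
      genes$chrom_id[[bad]], genes$gene_id[[bad]]))
  }
  overrides <- if (is.null(length_overrides)) numeric() else
    unlist(length_overrides)

  chrom_ids <- unique(genes$chrom_id)
  chrom_ids <- chrom_ids[natural_order(chrom_ids)]
  chroms <- lapply(chrom_ids, function(cid) {
    g <- genes[genes$chrom_id == cid, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    rownames(g) <- NULL
    len <- if (cid %in% names(overrides)) as.numeric(overrides[[cid]])
           else max(g$end)
    if (len < max(g$end))
      svz_format_error(sprintf(
        "length override for %s (%g bp) is shorter than its last gene (%d bp)",
        cid, len, max(g$end)))
    structure(list(chrom_id = cid, species_tag = species_prefix(cid),
                   length_bp = len, genes = g),
              class = "chromosome_model")
  })
  tags <- vapply(chroms, `[[`, "", "species_tag")
  structure(lapply(sort(unique(tags)), function(tag) {
    structure(list(species_tag = tag, display_name = tag,
                   chromosomes = chroms[tags == tag]),
              class = "genome_model")
  }), class = "genome_set")
}

#' Flat chromosome table of a genome set
#'
#' One row per chromosome in display order (genomes by species tag,
#' chromosomes natural-sorted within each genome).
#'
#' @param genomes a \code{genome_set}.
#' @return Data frame with \code{chrom_id}, \code{species_tag},
#'   \code{length_bp}.
#' @export
chromosome_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    data.frame(chrom_id = vapply(g$chromosomes, `[[`, "", "chrom_id"),
               species_tag = g$species_tag,
               length_bp = vapply(g$chromosomes, `[[`, 0, "length_bp"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Gene index: gene_id -> (species_tag, chrom_id, start, end, strand).
build_gene_index <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    do.call(rbind, lapply(g$chromosomes, function(ch) {
      cbind(ch$genes, species_tag = g$species_tag)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Join annotation with collinearity blocks and validate anchors
#'
#' Every anchor gene in every block must be resolvable in the annotation.
#' Under \code{policy = "strict"} (the default) an unresolvable gene is an
#' error naming the gene and its block.  Under \code{policy = "drop"}
#' offending anchors are removed, blocks left with fewer than two anchors are
#' removed, and the counts are reported.  Block header chromosome tags (which
#' in the MCScanX dialect drop zero padding, e.g. "os1") are reconciled with
#' the annotation's ids; a header that disagrees with where its anchor genes
#' actually lie is an error in strict mode and is back-filled from the genes
#' in drop mode.
#'
#' @param genomes a \code{genome_set} from [build_genome_models()].
#' @param blocks list of \code{synteny_block} from [parse_collinearity()].
#' @param policy \code{"strict"} or \code{"drop"}.
#' @return A \code{synteny_dataset}: list with \code{genomes}, \code{blocks},
#'   \code{gene_index} and a \code{report} of
#'   \code{anchors_dropped}/\code{blocks_dropped}.
#' @export
join_and_validate <- function(genomes, blocks, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  idx <- build_gene_index(genomes)
  norm2real <- stats::setNames(idx$chrom_id, normalize_chrom_id(idx$chrom_id))
  lookup <- stats::setNames(seq_len(nrow(idx)), idx$gene_id)

  anchors_dropped <- 0L
  blocks_dropped <- 0L
  kept <- list()
  for (blk in blocks) {
    an <- blk$anchors
    hit_a <- lookup[an$gene_a]
    hit_b <- lookup[an$gene_b]
    bad <- is.na(hit_a) | is.na(hit_b)
    if (any(bad)) {
      if (policy == "strict") {
        missing_gene <- c(an$gene_a[is.na(hit_a)], an$gene_b[is.na(hit_b)])[[1L]]
        svz_validation_error(sprintf(
          "anchor gene '%s' in block %d is absent from the annotation",
          missing_gene, blk$block_id))
      }
      anchors_dropped <- anchors_dropped + sum(bad)
      an <- an[!bad, , drop = FALSE]
      hit_a <- hit_a[!bad]; hit_b <- hit_b[!bad]
    }
    if (nrow(an) < 2L) {
      blocks_dropped <- blocks_dropped + 1L
      next
    }
    # reconcile header chromosome tags with where the anchors actually sit
    real_a <- unique(idx$chrom_id[hit_a])
    real_b <- unique(idx$chrom_id[hit_b])
    if (length(real_a) != 1L || length(real_b) != 1L)
      svz_validation_error(sprintf(
        "block %d: anchor genes span multiple chromosomes on one side",
        blk$block_id))
    for (side in c("a", "b")) {
      real <- if (side == "a") real_a else real_b
      hdr <- blk[[paste0("chrom_", side)]]
      if (normalize_chrom_id(hdr) != normalize_chrom_id(real)) {
        if (policy == "strict")
          svz_validation_error(sprintf(
            "block %d: header names chromosome '%s' but its anchors lie on '%s'",
            blk$block_id, hdr, real))
      }
      blk[[paste0("chrom_", side)]] <- real
    }
    an$index_in_block <- seq_len(nrow(an)) - 1L
    rownames(an) <- NULL
    blk$anchors <- an
    kept[[length(kept) + 1L]] <- blk
  }

  structure(list(genomes = genomes, blocks = kept, gene_index = idx,
                 report = list(anchors_dropped = anchors_dropped,
                               blocks_dropped = blocks_dropped)),
            class = "synteny_dataset")
}

#' @export
print.synteny_dataset <- function(x, ...) {
  ct <- chromosome_table(x$genomes)
  cat(sprintf("synteny_dataset: %d genome(s) [%s], %d chromosomes, %d genes, %d blocks\n",
              length(x$genomes),
              paste(vapply(x$genomes, `[[`, "", "species_tag"), collapse = ", "),
              nrow(ct), nrow(x$gene_index), length(x$blocks)))
  if (x$report$anchors_dropped || x$report$blocks_dropped)
    cat(sprintf("  validation dropped %d anchor(s), %d block(s)\n",
                x$report$anchors_dropped, x$report$blocks_dropped))
  invisible(x)
}

#' @export
print.genome_set <- function(x, ...) {
  for (g in x)
    cat(sprintf("genome %s: %d chromosome(s), %d genes\n", g$species_tag,
                length(g$chromosomes),
                sum(vapply(g$chromosomes, function(ch) nrow(ch$genes), 0L))))
  invisible(x)
}

# Genomic extent of a block on one side: [min start, max end] over that
# side's anchor genes.  side is "a" or "b".
block_extent <- function(block, side, gene_index) {
  ids <- block$anchors[[paste0("gene_", side)]]
  rows <- gene_index[match(ids, gene_index$gene_id), , drop = FALSE]
  list(chrom_id = block[[paste0("chrom_", side)]],
       start = min(rows$start), end = max(rows$end))
}
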