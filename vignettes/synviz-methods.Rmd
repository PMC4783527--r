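---
title: "synviz: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synviz: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synviz)
```

## The problem and the data model

Collinearity detectors (MCScanX and relatives) emit two text artifacts: a
*collinearity file* — alignment blocks, each a header
(`## Alignment i: score=… e_value=… N=… chrA&chrB plus|minus`) followed by
`N` anchor gene pairs — and a *gene annotation* giving each gene's
chromosome and coordinates. `synviz` joins the two into a validated model
and draws it. The model is deliberately minimal: genes are rows of a data
frame (1-based inclusive base-pair coordinates, the GFF convention,
everywhere; canvas units appear only in the layout stage), chromosomes and
genomes are S3 lists, and a `synteny_dataset` guarantees that every anchor
gene of every block resolves in its gene index.

Three reconciliation rules matter in practice:

* **Species grouping.** A chromosome's species is the leading alphabetic
  run of its id (`os01` → `os`), the labeling convention of
  comparative-genomics figures. Ids without such a prefix are rejected with
  the offending gene named.
* **Zero-padding.** Collinearity headers write `os1` where annotations
  write `os01`; both normalize to (prefix, integer) before comparison. The
  annotation's spelling is authoritative and is back-filled into blocks.
* **Chromosome extents.** The input pair carries no karyotype, so a
  chromosome's length is inferred as the maximum gene end it carries;
  explicit `chrom_lengths` overrides exist for users who know the real
  extents (an override shorter than its genes is an error).

Validation policy is `strict` by default — an anchor gene absent from the
annotation aborts with the gene and block named — because a silent drop
can turn a mis-matched annotation release into a quietly wrong figure.
`drop` is available for dirty data: it removes offending anchors, removes
blocks left with fewer than two anchors (a "block" of one pair is no longer
evidence of collinearity), and reports both counts. Both policies are
provided because upstream behavior is unspecified; failing loudly is the
safer default.

## Layout geometry

One canvas convention is used by every layout and every backend: origin at
the top-left, y downward, units in points; on the circle, angle 0 at
12 o'clock increasing clockwise (the ideogram convention). A single
convention means a coordinate bug cannot hide in a renderer-specific flip.

**Circle.** All chromosomes — both genomes — share one ring, ordered by
species tag then natural sort (`os2` before `os10`). With `C` chromosomes,
gap angle `g` (default 2° in radians) and lengths `L_i`, arc `i` spans
`(2π − C·g)·L_i/ΣL`; the suite checks `Σ spans + C·g = 2π` to 1e-9.
Genomic positions map into an arc by linear interpolation with position 1
at the arc start and `L` at the arc end (midpoint for a length-1
degenerate). A block's extent on a chromosome is `[min start, max end]`
over that side's anchors — the natural envelope, chosen because detectors
publish no extent definition. Ribbons connect the two extents at the inner
ideogram radius: two arc edges plus two cubic curves whose interior control
points are the chord endpoints pulled toward the center by `ribbon_pull`
(default 0, i.e. control points *at* the center — the classic
chord-diagram pinch; larger values relax the waist).

**Dot.** Axes are cumulative base-pair coordinates per genome with a fixed
`axis_gap` (10 pt) between chromosomes; a single-genome dataset uses all
its chromosomes on both axes. Each anchor is one point at its two gene
midpoints — base pairs, not gene ranks, so dense and sparse regions keep
their proportions. Points are colored by the block's orientation token
(plus/minus, the first two palette entries), which makes inversions visible
as anti-diagonal runs in the second color.

**Bar.** One track per chromosome, left-aligned, one global scale (pixel
length ratios equal base-pair ratios). Each block paints its extent on
*both* partner bars in one per-block color cycled from the palette, so a
match can be read across bars by color.

**Dual synteny.** Two vertical columns of chromosome bars (left species,
right species) sharing one global scale; each block joining the pair is a
quadrilateral band between its two extents, colored by its left
chromosome. Blocks not joining the pair are excluded; a pair with no
joining blocks is an error rather than an empty figure.

All layouts are pure functions of (dataset, config): identical inputs give
bit-identical layouts, coordinates always fall inside the canvas, and
within a chromosome every genomic-to-canvas map is strictly increasing.

## Scene graph and the six writers

Layouts are converted to a *scene*: an ordered painter's-order draw list of
six primitive kinds (`arc_band`, `cubic_ribbon`, `polygon`, `segment`,
`circle_marker`, `text`). Plot code never sees file formats; writers never
see layouts.

The three vector writers (SVG 1.1, EPS with a correct `%%BoundingBox`,
PDF 1.4 with uncompressed streams and a hand-built xref table) are written
in-package so their output is fully deterministic — no creation dates,
producer strings or randomized ids, fixed 3-decimal coordinate formatting,
a single referenced Helvetica face. Byte-identical output across runs is a
contract the test suite asserts, and is why the package does not route
vector output through R's graphics devices, which timestamp their files.
Curves are flattened once, identically for all backends (64 segments per
curve — chord error far below half a pixel at 300 dpi); each scene
primitive becomes exactly one drawable element, which the tests count.

PostScript has no alpha channel, so the EPS writer pre-blends translucent
fills with the scene background (`c' = bg + α(c − bg)`) — exact for shapes
over the background, a close approximation where ribbons overlap. SVG and
PDF carry real alpha. JPEG quality defaults to 92; BMP is whatever the
cairo BMP device writes (24-bit uncompressed).

The raster writers replay the same scene on the cairo `png()`, `jpeg()`
and `bmp()` devices at `round(canvas_pt · dpi / 72)` pixels (default
300 dpi). Doubling the dpi exactly doubles the pixel dimensions while the
vector bytes do not change — scalability lives in the vector file, not in
re-layout. The suite also cross-checks the hand-written SVG against an
independent rasterizer (`rsvg-convert`) pixel-wise against the directly
produced PNG, with a mean per-channel tolerance of 0.02 (of 1.0) to absorb
anti-aliasing differences between the two rasterizers.

## Configuration

The control file is flat `key=value` text (hand-editable, and symmetric
with CLI overrides, which take precedence). Defaults: canvas 1000×1000 pt
for the square geometries (circle, dot) and 1000×700 pt for the track
geometries (bar, dual); margin 40 pt; `gap_angle` 2° in radians;
`ribbon_opacity` 0.45 (overlapping chords stay readable); a 20-color
qualitative palette cycled by chromosome or block index;
`min_block_anchors` 2 (the definitional floor — a single pair is not a
block); `raster_dpi` 300. Unknown keys warn rather than error so a config
written for a newer version degrades gracefully; out-of-range values error
naming the key. Colors must be `#RRGGBB`. E-values parse from plain or
scientific notation, with underflow clamped to 0.

## The synthetic fixture generator

Every test input is generated in code from a seeded generator, so ground
truth is known exactly. Genes are laid end to start with exponential
intergenic gaps and exponential lengths (a serviceable caricature of gene
spacing); blocks pick two chromosome segments and pair consecutive genes
in collinear order, reversing side b for minus blocks; files are emitted in
the exact dialects the parsers read, including MCScanX's zero-padding drop
in headers and its `#` banner lines. The generator runs on a private RNG
stream (the caller's `.Random.seed` is saved and restored) and the same
seed yields byte-identical files — the parser round-trip property
(`parse(generate(p)) == truth`, checked over 50 seeds) is therefore exact,
not approximate.

The `rice_sorghum_like()` preset (12 + 10 chromosomes, 30 genes each,
40 cross-species blocks of 3–10 anchors, 30% minus) is shaped like a
rice/sorghum comparison at desk scale; the chromosome counts are common
biological knowledge used as a fixture shape only. What fixtures do *not*
emulate: realistic block density, nested inversions, whole-genome
duplication ratios, or real intergenic length distributions — so passing
tests demonstrate format, geometry and pipeline correctness, not
biological realism of the rendering on any particular genome pair.

Problem sizes throughout the suite (2–22 chromosomes, tens of blocks,
hundreds of genes, 72-dpi rasters) were chosen as the smallest instances
that still exercise every code path — multi-genome ordering, both
orientations, both dialects, all 24 plot-format combinations.

## Command-line driver

`inst/cli/synviz.R` is a thin `optparse` shell over `run_request()` +
`run_synteny_plot()`/`run_matrix()`: `--collinearity`, `--gff`,
`--config`, `--plot` and `--format` (single value, comma-list, or `all`),
`--out`, `--dual-pair`, `--min-anchors`, `--policy`, `--verbose`. There is
deliberately no `--seed`: the plotting pipeline contains no randomness.
Every failure maps to a classed condition and a stable exit code (1 usage,
2 format, 3 validation, 4 render) with a one-line message, never a stack
trace.

## Known limitations

* One ring, one track: no multi-ring circular tracks, no gene-level
  micro-synteny zoom, no interactivity.
* Block extent is the anchor envelope; a block with distant outlier
  anchors paints a wider interval than its core run.
* EPS opacity is emulated by background blending (see above).
* Text metrics in the PDF writer use a fixed average-width approximation
  for anchoring (the face itself is rendered by the viewer); SVG and EPS
  anchor text exactly.
* The dot plot draws every anchor as a constant-size marker; it does not
  scale markers by e-value or block score.
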