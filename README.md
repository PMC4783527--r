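# synviz — vector and raster figures for genome synteny and collinearity

Synteny (co-localization of genes across chromosomes) and collinearity
(synteny with conserved gene order) are central observations in comparative
genomics: they expose whole-genome duplications, segmental duplications,
inversions and translocations. Detection tools such as MCScanX report their
results as text — a *collinearity file* of alignment blocks and anchor gene
pairs — and leave visualization to the user. `synviz` closes that gap: it
turns a collinearity file plus a gene annotation into publication-quality
figures in four geometries and six file formats, from R or from a shell.

## What it computes

From three inputs —

1. a **collinearity file** in the MCScanX output dialect
   (`## Alignment i: score=… e_value=… N=… chrA&chrB plus|minus` headers
   followed by anchor gene-pair lines),
2. a **gene annotation** (MCScanX simplified 4-column positions or GFF3
   `gene` rows; auto-detected),
3. an optional flat `key=value` **control file** of plot parameters —

the package builds a validated model (genomes → chromosomes → genes, blocks
→ anchor pairs) and maps it to canvas geometry:

* **Circle plot** — all chromosomes on one ring. With chromosome count *C*,
  gap angle *g* and lengths *Lᵢ*, each arc spans
  *spanᵢ = (2π − C·g) · Lᵢ / ΣLⱼ*; every block becomes a ribbon chord whose
  ends sit at the linearly interpolated angles of its genomic extent and
  whose curved edges are cubic curves pinched toward the circle center.
* **Bar plot** — one horizontal bar per chromosome on a shared base-pair
  scale; each block paints its extent on both partner bars in one per-block
  color.
* **Dot plot** — macrosynteny scatter: the two genomes on the two axes in
  cumulative base-pair coordinates, one point per anchor pair at the gene
  midpoints, colored by block orientation (plus/minus).
* **Dual synteny plot** — two parallel columns of chromosome bars with
  quadrilateral bands joining each block's extents.

Layouts are serialized through a backend-neutral scene graph to **SVG, EPS
and PDF** (hand-written, byte-deterministic: no timestamps or random ids)
and rasterized to **PNG, JPEG and BMP** at any resolution
(pixel dimensions = `round(canvas_pt · dpi / 72)`).

## Worked example

The package ships a seeded generator of format-valid synthetic fixtures,
including a rice/sorghum-shaped preset (12 + 10 chromosomes, cross-species
blocks only — a synthetic stand-in, not real genome data):

```r
library(synviz)
fx  <- rice_sorghum_like(dir = "demo")
req <- run_request(fx$collinearity_path, fx$annotation_path,
                   overrides = list(raster_dpi = 150),
                   out_path = "demo/figure")
res <- run_synteny_plot(req, formats = c("svg", "png"), verbose = TRUE)
```

prints

```
genomes: 2 (os, sb)
chromosomes: 22
genes: 660
blocks: 40 parsed, 40 kept, 0 dropped by validation, 0 filtered
anchors dropped: 0
wrote: demo/figure.circle.svg
wrote: demo/figure.circle.png
```

i.e. the two genomes parsed into 22 chromosomes carrying 660 genes, all 40
collinear blocks survived validation (every anchor gene resolved in the
annotation) and the circular ideogram was written as a deterministic SVG
and a 150-dpi PNG. `run_matrix(req, "all", "all")` renders all 4 plot
types × 6 formats = 24 files named `<stem>.<plot>.<format>`.

The same pipeline is available from a shell:

```sh
Rscript inst/cli/synviz.R --collinearity demo/fixture.collinearity \
    --gff demo/fixture.gff --plot all --format all --out demo/figure
```

Exit codes: 0 success, 1 usage, 2 input format error, 3 validation error,
4 render error.

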