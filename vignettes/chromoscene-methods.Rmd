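---
title: "Working with 3D genome structure tables: model, selection and visual encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with 3D genome structure tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscene)
```

## The data model

A 3D genome structure is a polymer-like model that assigns an XYZ
coordinate to each genomic bin — typically the output of a Hi-C-based
reconstruction (e.g. single-cell Hi-C structures of mammalian nuclei) or
a de novo polymer simulation. `chromoscene` represents such a structure
as a `BinTable`: one row per bin with a chromosome label, a 0-based
half-open genomic interval `[start, end)` in base pairs, the coordinate
triple, and any number of numeric or categorical annotation columns.

Three modelling decisions shape everything downstream:

* **Coordinates are 0-based, half-open** (the BED convention). Bin width
  is then simply `end - start`, abutting bins compose without off-by-one
  adjustments, and a position equal to a bin's `end` belongs to the next
  bin. GTF input (1-based inclusive) is converted on read.
* **Row order is chain order.** Structure files encode polymer
  connectivity by row sequence, so no operation reorders rows unless that
  is its purpose; subsetting preserves relative order. Out-of-order bin
  starts within a chromosome are reported as a *warning* (broken chain
  order), not an error, as are duplicated `(chrom, start)` pairs — the
  latter occur legitimately in diploid models where both homologs are
  present, and homolog identity belongs in an annotation column.
* **Missing coordinates are a hard error**, not maskable: every spatial
  operation (planes, spheres, meshes) assumes finite points. Model units
  are dimensionless; no unit metadata is stored.

`validateStructure()` checks all of this and *reports* rather than
throws, so a malformed foreign file yields a complete diagnosis in one
pass. Constructors and readers refuse to produce a `BinTable` whose
report carries errors — an invalid table cannot escape the I/O layer.

The resolution of a structure is not stored but recovered:
`inferResolution()` takes the modal bin width, breaking ties toward the
smallest tied width (the conservative choice: a finer resolution never
merges bins that a coarser guess would).

```{r}
bt <- makeTestGenome(c(chr1 = 1e6, chr2 = 5e5), resolution = 1e5, seed = 0)
bt
inferResolution(bt)
```

## File dialects

Structure files in circulation disagree on almost everything, so each
reader targets one dialect explicitly:

* **`.3dg`** (`read3dg`/`write3dg`): the whitespace-separated
  `chrom  start  x  y  z` layout of the single-cell Hi-C structure
  literature. The position field is interpreted as the *bin start*, the
  dominant convention in that literature, and bin ends are synthesized
  from the per-chromosome modal spacing of consecutive starts
  (tie → smallest; single-bin chromosomes fall back to the genome-wide
  mode, or an explicit `resolution` argument).
* **Delimited tables** (`readTableStructure` + `columnMapping`): the
  general escape hatch for foreign CSV/TSV layouts. Unmapped columns ride
  along as annotations; a carried column that would shadow a reserved
  name is an error rather than a silent rename.
* **Reinterpreted PDB** (`readPdbDialect`/`writePdbDialect`): chromatin
  tools have long abused the atomistic PDB format for bead models, each
  with its own conventions. Genomic coordinates span up to nine digits
  and cannot fit the 4-column residue-number field, so our writer refuses
  to overload `resSeq`: it stores the within-chromosome bin index there
  and the true intervals in a trailing `REMARK 350 BINPOS` table, making
  the file lossless without breaking fixed-width parsing. The reader
  accepts fixed columns (tolerating 5-digit residue numbers that overflow
  into the insertion-code column) with a whitespace fallback, ignores
  foreign REMARK blocks (too dialect-specific to trust), and therefore
  requires an explicit resolution. `strict = TRUE` turns the two lossy
  conditions (more than 36 chromosomes, more than 9999 bins per
  chromosome) into errors instead of wrap-with-warning.
* **Arrow IPC/Feather** (`readColumnar`/`writeColumnar`): the canonical
  binary form — lossless and bit-exact for every column including
  annotations, and readable by any Arrow-aware tool.

Text output prints coordinates at 6 significant digits; round-trip tests
compare at `1e-5`, which that precision guarantees for the coordinate
magnitudes structures use. All readers accept CRLF and missing trailing
newlines. Chromosome names pass through verbatim — no `chr` aliasing —
except single-character PDB chain identifiers, which are prefixed with
`chr` so integer-like chain labels cannot collide with real names.

## Selection

Selections — the genomic and spatial filtering layer — return logical
masks aligned with bin rows rather than materialized subsets. Masks
compose with `combineMasks()` (and plain boolean algebra), can drive
visual highlighting as well as subsetting, and `applyMask()`
materializes at the end.

* `selectByRanges()` marks bins overlapping query intervals
  (`any_overlap`), or contained in one (`contained`, read as *bin ⊆
  query*: "the bins fully inside this region", the natural reading when
  structures are coarser than query ranges). Chromosome matching is
  exact string equality; an absent chromosome simply matches nothing.
  The engine is GenomicRanges, after converting half-open intervals to
  its 1-based closed convention; the test suite holds it to an
  independent O(n·m) brute-force oracle.
* `cutByPlane()` computes signed distances `s = n̂·p + d`. The boundary
  `s = 0` is assigned to the positive side so the two half-space masks
  always partition the structure deterministically — no bin is lost to
  floating-point fate.
* `selectSphere()` is boundary-inclusive; `selectSphereAroundLocus()`
  composes a genomic lookup (the unique bin covering a position) with the
  spatial query, erroring on zero or multiple covering bins (the diploid
  case must be disambiguated by an annotation filter first).

Brute force is the deliberate implementation scale: structures top out
around 10^6 bins, where vectorized distance arithmetic is instant and a
KD-tree would buy nothing.

The boundary conventions above (plane boundary positive, sphere boundary
inclusive, half-open intervals on both sides of a range query) are this
package's own documented choices, made for determinism; they are not
claims about what any other tool does.

## Annotation aggregation

`binFeatures()` turns interval annotations (genes from a GTF, anything
from BED) into per-bin numeric columns. Four modes, because "gene
density" is genuinely ambiguous:

* `count` — features with any overlap. A boundary-spanning gene counts
  in every bin it touches; this matches the visual intent of density
  encodings (dense regions pop) and is the default.
* `count_midpoint` — features whose midpoint `floor((start+end)/2)`
  falls in the bin. Each feature counts at most once genome-wide, so
  totals are exactly conservation-checkable — the property the test
  suite verifies against a brute-force census.
* `coverage_fraction` — covered fraction of the bin, with overlapping
  features unioned *first* so stacked transcripts cannot push it past 1.
* `mean_value` — length-weighted mean of feature values over the covered
  part of the bin; uncovered bins get `NA` (0 would be a claim, `NA` is
  an absence).

Features on chromosomes absent from the structure are ignored with a
logged count: annotations are usually genome-wide while structures are
often single-chromosome, and erroring there would make every GTF
unusable.

The BED and GTF readers are intentionally small line-oriented parsers
for the 3–6 column and 9-column subsets this package consumes: the error
contract (line-numbered diagnostics for non-integer coordinates or short
rows) and BED's column-5 value capture sit below the granularity of the
general-purpose importers. GFF2 (`gene_id "G1";`) and GFF3
(`gene_id=G1`/`ID=G1`) attribute syntaxes are auto-detected.

## The view-config grammar

A `ViewConfig` declares how bins become graphics, in the
grammar-of-graphics spirit: a *mark* per bin (`sphere` or `box`), a
*color* channel and a *scale* channel that are each either constant or
data-driven, a base size, and optional chain links. Resolution
(`resolveViewConfig()`) turns this into an `AttributeTable` — concrete
RGBA, size and mark per bin — and is deterministic given (table,
config).

Channel semantics:

* Continuous mappings normalize the column to `[0, 1]` —
  `(v - min)/(max - min)`, clipped; degenerate domains map to 0.5 with a
  warning — then pass through a colormap (color) or a linear ramp into a
  multiplier range, default `[0.25, 1.5]` (scale). The default colormap
  is viridis (perceptually uniform, embedded as the standard 256-anchor
  table); `bluered` is the two-anchor diverging alternative. Colormap
  lookup is piecewise-linear in RGB with round-half-up.
* Categorical mappings assign entries of a fixed 12-color qualitative
  palette in **order of first appearance** (not lexicographic), so the
  chromosome order of the file controls color order — predictable for
  sorted genomes, and mapping `chrom` categorically gives exactly one
  color per chromosome. Past 12 categories the palette cycles with a
  warning.
* Domains default to the per-structure data range and are **recomputed
  after filtering**; pin `domain` explicitly when colors must be
  comparable across structures or subsets (the ensemble-comparison
  case). Both behaviors are tested.
* `base_size = "auto"` resolves to half the median distance between
  consecutive same-chromosome bins — marks about touching, not fusing —
  with a fallback of 1 when no consecutive pair exists. Final size is
  `base_size × multiplier` and must stay positive.

Config documents are JSON with exactly the keys `mark`, `color`,
`scale`, `base_size`, `links`; unknown keys are errors (fail-fast, like
other grammar validators), while *field existence* is checked only at
resolve time so a config remains structure-independent. Explicit colors
accept `#RRGGBBAA`, but no channel maps data to opacity: occlusion is
handled by scaling marks down, not by transparency.

This schema — key names, defaults, boundary conventions — is this
package's own design; it is documented here precisely because it is not
inherited from anywhere.

## Meshes and rendering

`buildMeshes()` realizes a scene (ordered structure/config pairs) as one
triangle mesh: per bin an icosphere at subdivision 2 (162 vertices, 320
faces — a fixed quality/size compromise) or a cube (8/12), scaled and
translated, every vertex carrying the bin's RGBA; links are thin
open 8-sided prisms between consecutive same-chromosome bins. Vertex and
face counts are therefore exact linear functions of bin counts, which
the tests assert, and sub-mesh face ranges are disjoint by construction.

PLY output (ascii or binary little-endian) uses per-vertex `uchar` RGBA
— the most portable colored-PLY dialect; ascii output is byte-identical
across runs. OBJ export exists for geometry-only consumers and warns
that colors are dropped. `renderStatic()` is a deliberately minimal
orthographic painter's-algorithm rasterizer (far-to-near, flat discs and
quads, white background) for smoke tests and documentation images — a
z-buffered product renderer is explicitly not the goal of a headless
toolkit.

## Synthetic fixtures

Every test input is generated, seeded, in code:

* `randomWalkChain()` — a freely jointed chain, steps uniform on the
  unit sphere. It obeys the ideal-chain law ⟨R²⟩ = N·b², which the suite
  checks as a Monte-Carlo limit (200 chains of 10^4 beads, 10%
  tolerance — the sampling error at that ensemble size is ~5%, so the
  band is two sigma).
* `confinedChain()` — the same walk with rejection inside a confinement
  sphere and a minimum bead separation, with single-step backtracking
  and a total-failure budget. This gives compact, non-self-intersecting
  territory-like blobs.
* `makeTestGenome()` — one confined chain per chromosome on a lattice of
  territory centers. Internal defaults, chosen once as territory-like
  and not tuned: bond length 1 model unit, confinement radius
  `max(2, 0.6·√n)` (the random-walk extent scale), bead separation 0.3,
  territory spacing 2.5× the largest radius.
* `makeTestAnnotation()` — synthetic "genes" with lengths uniform in
  [1 kb, 10 kb] and starts from a mixture of uniform (weight
  `1 - clustering`) and Beta(2, 8)-skewed positions (weight
  `clustering`, piling features near chromosome starts; Beta(2, 8) has
  mean 0.2). The clustering dial gives the gene-density demo a known
  ground-truth gradient.

All generators run on R's Mersenne-Twister with inversion sampling,
through a wrapper that restores the caller's RNG state, so they are pure
functions of (parameters, seed) and bit-reproducible across sessions.

What the fixtures deliberately do **not** emulate: Hi-C constraint
structure, loop extrusion, compartments, realistic contact statistics.
Passing tests demonstrate the correctness of the table/selection/
encoding machinery on polymer-shaped data, not biological fidelity of
any structure.

## Problem sizes and numerical choices

The shipped test and acceptance workloads use structures of 10²–10⁴
bins, 100 seeded structures for the selection-oracle sweep, 1000
structure/plane pairs for the partition property, 50 genome/annotation
pairs for aggregation conservation, and 200 chains of 10⁴ beads for the
physics limit — sizes at which the brute-force oracles stay exact and
the whole suite runs comfortably on one CPU.

Numerical conventions, collected: text floats at 6 significant digits
(tolerance 1e-5); plane boundary to the positive side; sphere boundary
inclusive; colormap interpolation round-half-up (so the bluered midpoint
is exactly (128, 0, 128, 255)); modal-width ties toward the smaller
width; categorical assignment by first appearance; `NA` annotation
values normalize to the neutral 0.5.

## Limitations

An ensemble of conformations is a plain list of `BinTable`s — there is
no ensemble container, per-bin uncertainty, or trajectory format. No
mmCIF or g3d input. No k-nearest-neighbor or density queries. The raster
renderer has no lighting or z-buffer. Strand is carried through interval
tables but never used in aggregation.
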