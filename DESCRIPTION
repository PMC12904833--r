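Package: chromoscene
Title: Headless Tools for 3D Genome Structure Tables, Selection and Visual Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Loads, validates, filters, annotates and visually encodes 3D genome
    structures represented as tables that link genomic bins to XYZ coordinates,
    such as models reconstructed from single-cell Hi-C or produced by polymer
    simulation. Provides readers and writers for the structure-table dialects in
    circulation (.3dg, delimited tables with column mapping, a reinterpreted-PDB
    chromatin dialect, Arrow IPC/Feather), genomic-range and spatial selection
    (interval queries, cutting planes, spherical neighborhoods), aggregation of
    BED/GTF features into structure bins, a declarative view-config grammar that
    resolves data columns to per-bin color, scale and mark attributes, triangle-mesh
    export (PLY/OBJ) with per-vertex colors, a minimal static raster renderer, and
    seeded synthetic polymer generators for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    arrow,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
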