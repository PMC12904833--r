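#' @rdname ValidationReport-class
#' @param x a `ValidationReport`.
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))

#' @rdname BinTable-class
#' @param x a `BinTable`.
#' @export
setGeneric("chroms", function(x) standardGeneric("chroms"))

#' @rdname BinTable-class
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @rdname BinTable-class
#' @export
setGeneric("binEnds", function(x) standardGeneric("binEnds"))

#' @rdname BinTable-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname BinTable-class
#' @export
setGeneric("binAnnotations", function(x) standardGeneric("binAnnotations"))

#' @rdname BinTable-class
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' Infer the genomic resolution of a structure
#'
#' Returns the most frequent bin width (`end - start`) in base pairs;
#' ties resolve to the smallest tied width. Invariant under row permutation.
#'
#' @param x a [BinTable] (or object coercible to its validated form).
#' @return integer-valued numeric scalar, base pairs.
#' @examples
#' bt <- binTableFromCoordinates(diag(3), chrom = "chr1", resolution = 1e5)
#' inferResolution(bt)
#' @export
setGeneric("inferResolution", function(x) standardGeneric("inferResolution"))

#' @rdname Scene-class
#' @param x a `Scene`.
#' @param structure a [BinTable].
#' @param config a [ViewConfig].
#' @export
setGeneric("addStructure",
  function(x, structure, config) standardGeneric("addStructure"))
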