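#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

RESERVED_COLUMNS <- c("chrom", "start", "end", "x", "y", "z")

#' Structure validation report
#'
#' Collects the problems found by [validateStructure()] or
#' [validateViewConfig()] without throwing. `errors` and `warnings` are
#' data.frames with columns `rule` (short rule identifier), `row` (offending
#' row index, or `NA` for table-level problems) and `message`.
#'
#' @slot errors data.frame of hard errors.
#' @slot warnings data.frame of non-fatal findings.
#' @aliases ValidationReport
#' @seealso [isValid()], [validateStructure()]
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(errors = "data.frame", warnings = "data.frame"),
  prototype(
    errors = data.frame(rule = character(), row = integer(),
                        message = character(), stringsAsFactors = FALSE),
    warnings = data.frame(rule = character(), row = integer(),
                          message = character(), stringsAsFactors = FALSE)
  )
)

setValidity("ValidationReport", function(object) {
  need <- c("rule", "row", "message")
  if (!all(need %in% names(object@errors)) ||
      !all(need %in% names(object@warnings)))
    return("errors/warnings must have columns rule, row, message")
  TRUE
})

#' Binned 3D genome structure
#'
#' The central container: one row per genomic bin, linking a half-open
#' 0-based interval (`chrom`, `start`, `end`) to a model-space coordinate
#' (`x`, `y`, `z`), plus any number of numeric or categorical annotation
#' columns. Row order is significant: it encodes polymer chain order, and
#' every operation that does not explicitly reorder preserves it.
#' Coordinates are dimensionless model units, consistent within a structure.
#'
#' Construct with [binTable()], [binTableFromCoordinates()] or one of the
#' readers ([read3dg()], [readTableStructure()], [readPdbDialect()],
#' [readColumnar()]); all constructors reject tables whose
#' [validateStructure()] report carries errors.
#'
#' @slot data a `DataFrame` with the reserved columns `chrom`, `start`,
#'   `end`, `x`, `y`, `z` first, followed by annotation columns.
#' @aliases BinTable
#' @seealso [chroms()], [binStarts()], [binEnds()], [coords()],
#'   [binAnnotations()], [nbins()]
#' @exportClass BinTable
setClass("BinTable", representation(data = "DataFrame"))

setValidity("BinTable", function(object) {
  rep <- validateStructure(object@data)
  if (!isValid(rep))
    return(paste(rep@errors$message, collapse = "; "))
  TRUE
})

#' Genomic interval table
#'
#' Plain intervals (`chrom`, `start`, `end`; 0-based half-open) with
#' optional `name`, `value` and `strand` columns, used both as selection
#' queries ([selectByRanges()]) and as annotation sources ([binFeatures()]).
#'
#' @slot data a `DataFrame` with at least `chrom`, `start`, `end`.
#' @aliases IntervalTable
#' @seealso [intervalTable()], [readBed()], [readGtfFeatures()]
#' @exportClass IntervalTable
setClass("IntervalTable", representation(data = "DataFrame"))

setValidity("IntervalTable", function(object) {
  d <- object@data
  if (!all(c("chrom", "start", "end") %in% names(d)))
    return("IntervalTable needs chrom, start, end columns")
  if (nrow(d) && any(d$start >= d$end))
    return("intervals must satisfy start < end")
  if (nrow(d) && any(d$start < 0))
    return("interval starts must be non-negative")
  TRUE
})

#' Cutting plane
#'
#' A plane in model space given by a normal vector (any nonzero length;
#' normalized internally) and a signed offset `d`, defining the signed
#' distance \eqn{s = \hat{n} \cdot p + d} used by [cutByPlane()].
#'
#' @slot normal numeric(3), nonzero.
#' @slot offset numeric(1).
#' @aliases Plane
#' @seealso [plane()], [cutByPlane()]
#' @exportClass Plane
setClass("Plane", representation(normal = "numeric", offset = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@normal) != 3L || !all(is.finite(object@normal)))
    return("normal must be a finite numeric triple")
  if (sqrt(sum(object@normal^2)) == 0)
    return("normal must have nonzero length")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    return("offset must be a single finite number")
  TRUE
})

#' Declarative view configuration
#'
#' Maps data columns of a [BinTable] to visual channels. `mark` is the
#' geometric primitive per bin ("sphere" or "box"); `color` and `scale` are
#' channel specifications (see [channelConstant()] / [channelMapping()]);
#' `baseSize` is the mark size in model units, or `"auto"` to derive it from
#' the chain geometry; `links` asks for connecting segments between
#' consecutive bins of a chromosome. Resolve against a structure with
#' [resolveViewConfig()].
#'
#' @slot mark character(1), "sphere" or "box".
#' @slot color list, a channel spec.
#' @slot scale list, a channel spec resolving to positive multipliers.
#' @slot baseSize numeric(1) or the string "auto".
#' @slot links logical(1).
#' @aliases ViewConfig
#' @seealso [viewConfig()], [validateViewConfig()], [resolveViewConfig()]
#' @exportClass ViewConfig
setClass("ViewConfig",
  representation(mark = "character", color = "list", scale = "list",
                 baseSize = "ANY", links = "logical"))

setValidity("ViewConfig", function(object) {
  if (!object@mark %in% VALID_MARKS)
    return(sprintf("mark must be one of: %s", paste(VALID_MARKS, collapse = ", ")))
  if (!(identical(object@baseSize, "auto") ||
        (is.numeric(object@baseSize) && length(object@baseSize) == 1L &&
         is.finite(object@baseSize) && object@baseSize > 0)))
    return("baseSize must be a positive number or \"auto\"")
  if (length(object@links) != 1L || is.na(object@links))
    return("links must be TRUE or FALSE")
  TRUE
})

#' Resolved per-bin visual attributes
#'
#' The concrete output of [resolveViewConfig()]: an RGBA color, a size in
#' model units and a mark name per bin, aligned with the source [BinTable]
#' by row order.
#'
#' @slot rgba integer matrix, N x 4, components in \[0, 255\].
#' @slot size numeric vector of positive mark sizes (model units).
#' @slot mark character vector of mark names.
#' @aliases AttributeTable
#' @exportClass AttributeTable
setClass("AttributeTable",
  representation(rgba = "matrix", size = "numeric", mark = "character"))

setValidity("AttributeTable", function(object) {
  n <- length(object@size)
  if (nrow(object@rgba) != n || length(object@mark) != n)
    return("rgba, size and mark must have one entry per bin")
  if (ncol(object@rgba) != 4L)
    return("rgba must have 4 columns")
  if (n && (any(object@rgba < 0) || any(object@rgba > 255)))
    return("rgba components must lie in [0, 255]")
  if (n && any(!is.finite(object@size) | object@size <= 0))
    return("all sizes must be positive and finite")
  TRUE
})

#' Scene: structures paired with view configs
#'
#' An ordered list of (structure, view config) pairs; entries are
#' independent. Materialize with [buildMeshes()] or rasterize with
#' [renderStatic()].
#'
#' @slot entries list of `list(structure = BinTable, config = ViewConfig)`.
#' @aliases Scene
#' @seealso [scene()], [addStructure()]
#' @exportClass Scene
setClass("Scene", representation(entries = "list"))

setValidity("Scene", function(object) {
  for (i in seq_along(object@entries)) {
    e <- object@entries[[i]]
    if (!is.list(e) || !is(e$structure, "BinTable") || !is(e$config, "ViewConfig"))
      return(sprintf("entry %d must pair a BinTable with a ViewConfig", i))
  }
  TRUE
})

#' Triangle mesh with per-vertex colors
#'
#' @slot vertices numeric matrix, N x 3.
#' @slot faces integer matrix, M x 3, 1-based vertex indices.
#' @slot vertexColors integer matrix, N x 4 RGBA in \[0, 255\].
#' @aliases Mesh
#' @seealso [buildMeshes()], [writePly()], [writeObj()]
#' @exportClass Mesh
setClass("Mesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexColors = "matrix"))

setValidity("Mesh", function(object) {
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
  if (ncol(object@faces) != 3L) return("faces must be M x 3")
  if (nrow(object@vertexColors) != nv || ncol(object@vertexColors) != 4L)
    return("vertexColors must be N x 4")
  if (nrow(object@faces)) {
    f <- object@faces
    if (any(f < 1L) || any(f > nv))
      return("face indices out of range")
    if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
      return("degenerate face (repeated vertex index)")
  }
  TRUE
})
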