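#' @importFrom S4Vectors DataFrame
#' @importFrom stats median
NULL

report <- function(errors, warnings) {
  empty <- data.frame(rule = character(), row = integer(),
                      message = character(), stringsAsFactors = FALSE)
  if (!length(errors)) errors <- empty else errors <- do.call(rbind, errors)
  if (!length(warnings)) warnings <- empty else warnings <- do.call(rbind, warnings)
  new("ValidationReport", errors = errors, warnings = warnings)
}

finding <- function(rule, row, message) {
  data.frame(rule = rule, row = if (is.null(row)) NA_integer_ else as.integer(row),
             message = message, stringsAsFactors = FALSE)
}

#' @describeIn ValidationReport-class `TRUE` iff the report has no errors.
#' @export
setMethod("isValid", "ValidationReport", function(x) nrow(x@errors) == 0L)

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d error(s), %d warning(s))\n",
              if (isValid(object)) "valid" else "INVALID",
              nrow(object@errors), nrow(object@warnings)))
  fmt <- function(df, label) {
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %s [%s]%s: %s\n", label, df$rule[i],
                  if (is.na(df$row[i])) "" else sprintf(" row %d", df$row[i]),
                  df$message[i]))
  }
  fmt(object@errors, "error")
  fmt(object@warnings, "warning")
})

#' Validate a candidate structure table
#'
#' Checks any table-like object (data.frame, `DataFrame` or [BinTable])
#' against the structure-table contract and reports every problem found;
#' nothing is thrown. Hard errors: missing required column, `start >= end`,
#' negative `start`, non-finite coordinate. Warnings: bin starts not
#' strictly increasing within a chromosome (broken chain order),
#' non-uniform bin widths within a chromosome, duplicate `(chrom, start)`
#' pairs (legitimate in diploid models, hence not an error).
#'
#' @param x table-like object expected to carry columns
#'   `chrom`, `start`, `end`, `x`, `y`, `z`.
#' @return a [ValidationReport].
#' @examples
#' df <- data.frame(chrom = "chr1", start = 0, end = 1e5, x = 0, y = 0, z = 0)
#' isValid(validateStructure(df))
#' @export
validateStructure <- function(x) {
  if (is(x, "BinTable")) x <- x@data
  x <- as.data.frame(x)
  errs <- list(); warns <- list()

  missing_cols <- setdiff(RESERVED_COLUMNS, names(x))
  if (length(missing_cols)) {
    errs[[length(errs) + 1L]] <- finding("missing_column", NULL,
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
    return(report(errs, warns))
  }

  n <- nrow(x)
  start <- suppressWarnings(as.numeric(x$start))
  end <- suppressWarnings(as.numeric(x$end))

  for (i in which(is.na(start) | is.na(end)))
    errs[[length(errs) + 1L]] <- finding("non_numeric_interval", i,
      sprintf("row %d: start/end not numeric", i))
  ok <- !is.na(start) & !is.na(end)
  for (i in which(ok & start < 0))
    errs[[length(errs) + 1L]] <- finding("negative_start", i,
      sprintf("row %d: negative start (%s)", i, format(start[i])))
  for (i in which(ok & start >= end))
    errs[[length(errs) + 1L]] <- finding("empty_interval", i,
      sprintf("row %d: start (%s) >= end (%s)", i, format(start[i]), format(end[i])))

  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    for (i in which(!is.finite(v)))
      errs[[length(errs) + 1L]] <- finding("nonfinite_coordinate", i,
        sprintf("row %d: non-finite %s coordinate", i, col))
  }

  ann <- setdiff(names(x), RESERVED_COLUMNS)
  # reserved names cannot be shadowed by construction here (unique names),
  # but duplicated column names can smuggle one in
  dup <- names(x)[duplicated(names(x))]
  if (length(dup))
    errs[[length(errs) + 1L]] <- finding("duplicate_column", NULL,
      sprintf("duplicated column name(s): %s", paste(unique(dup), collapse = ", ")))

  if (n && !length(errs)) {
    chrom <- as.character(x$chrom)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      s <- start[idx]
      if (length(s) > 1L && any(diff(s) <= 0))
        warns[[length(warns) + 1L]] <- finding("chain_order", idx[which(diff(s) <= 0)[1L] + 1L],
          sprintf("%s: bin starts not strictly increasing (chain order broken)", cc))
      w <- end[idx] - s
      if (length(unique(w)) > 1L)
        warns[[length(warns) + 1L]] <- finding("nonuniform_width", NULL,
          sprintf("%s: non-uniform bin widths (%s)", cc,
                  paste(sort(unique(w)), collapse = ", ")))
    }
    key <- paste(chrom, start)
    if (anyDuplicated(key))
      warns[[length(warns) + 1L]] <- finding("duplicate_bin", which(duplicated(key))[1L],
        "duplicate (chrom, start) pairs present (diploid homologs?)")
  }

  report(errs, warns)
}

#' Construct a BinTable from a table-like object
#'
#' Validates and wraps a data.frame (or `DataFrame`) carrying the reserved
#' columns plus optional annotation columns. Fails with the collected
#' validation errors if the table is malformed; row order is kept as given.
#'
#' @param data table with columns `chrom`, `start`, `end`, `x`, `y`, `z`
#'   and optional annotation columns.
#' @return a [BinTable].
#' @export
binTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rep <- validateStructure(data)
  if (!isValid(rep))
    stop("invalid structure table: ", paste(rep@errors$message, collapse = "; "),
         call. = FALSE)
  ann <- setdiff(names(data), RESERVED_COLUMNS)
  d <- DataFrame(
    chrom = as.character(data$chrom),
    start = as.numeric(data$start),
    end = as.numeric(data$end),
    x = as.numeric(data$x), y = as.numeric(data$y), z = as.numeric(data$z)
  )
  for (a in ann) {
    v <- data[[a]]
    if (is.factor(v)) v <- as.character(v)
    d[[a]] <- v
  }
  rownames(d) <- NULL
  new("BinTable", data = d)
}

#' Build a structure from a bare coordinate matrix
#'
#' The bare-matrix ingestion path: row `i` of the matrix becomes the bin
#' `[startOffset + (i-1) * resolution, startOffset + i * resolution)` on a
#' single chromosome, with coordinates copied in order.
#'
#' @param coordsMatrix numeric N x 3 matrix of finite XYZ coordinates.
#' @param chrom chromosome label shared by every bin.
#' @param resolution bin width in base pairs (>= 1).
#' @param startOffset genomic start of the first bin, base pairs (>= 0).
#' @return a [BinTable] with N bins.
#' @examples
#' binTableFromCoordinates(matrix(rnorm(30), ncol = 3), "chr1", 1e5)
#' @export
binTableFromCoordinates <- function(coordsMatrix, chrom, resolution,
                                    startOffset = 0) {
  coordsMatrix <- as.matrix(coordsMatrix)
  if (ncol(coordsMatrix) != 3L)
    stop("coordinate matrix must have exactly 3 columns, got ",
         ncol(coordsMatrix), call. = FALSE)
  if (nrow(coordsMatrix) < 1L) stop("need at least one coordinate row", call. = FALSE)
  if (!is.numeric(coordsMatrix))
    stop("coordinate matrix must be numeric", call. = FALSE)
  bad <- which(!apply(is.finite(coordsMatrix), 1L, all))
  if (length(bad))
    stop("non-finite coordinate in row ", bad[1L], call. = FALSE)
  stopifnot(resolution >= 1, startOffset >= 0)
  n <- nrow(coordsMatrix)
  start <- startOffset + (seq_len(n) - 1) * resolution
  binTable(data.frame(
    chrom = chrom, start = start, end = start + resolution,
    x = coordsMatrix[, 1L], y = coordsMatrix[, 2L], z = coordsMatrix[, 3L]
  ))
}

#' @describeIn BinTable-class chromosome label per bin.
#' @export
setMethod("chroms", "BinTable", function(x) x@data$chrom)

#' @describeIn BinTable-class 0-based bin starts (bp).
#' @export
setMethod("binStarts", "BinTable", function(x) x@data$start)

#' @describeIn BinTable-class exclusive bin ends (bp).
#' @export
setMethod("binEnds", "BinTable", function(x) x@data$end)

#' @describeIn BinTable-class N x 3 coordinate matrix (model units).
#' @export
setMethod("coords", "BinTable", function(x)
  cbind(x = x@data$x, y = x@data$y, z = x@data$z))

#' @describeIn BinTable-class `DataFrame` of annotation columns (may be empty).
#' @export
setMethod("binAnnotations", "BinTable", function(x)
  x@data[, setdiff(names(x@data), RESERVED_COLUMNS), drop = FALSE])

#' @describeIn BinTable-class number of bins.
#' @export
setMethod("nbins", "BinTable", function(x) nrow(x@data))

#' @export
setMethod("length", "BinTable", function(x) nrow(x@data))

#' @describeIn BinTable-class subset rows, preserving order and all columns.
#' @param i row subscript (logical mask or indices).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "BinTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, data = x@data[i, , drop = FALSE])
})

#' Convert a BinTable or IntervalTable to GRanges
#'
#' Converts the 0-based half-open intervals to the 1-based closed
#' convention of [GenomicRanges::GRanges]; XYZ coordinates and annotations
#' become metadata columns. Row order is preserved.
#'
#' @param x a [BinTable] or [IntervalTable].
#' @return a `GRanges`.
#' @export
asGRanges <- function(x) {
  d <- if (is(x, "BinTable") || is(x, "IntervalTable")) x@data else
    stop("need a BinTable or IntervalTable")
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1, end = d$end))
  extra <- setdiff(names(d), c("chrom", "start", "end"))
  if (length(extra))
    S4Vectors::mcols(gr) <- d[, extra, drop = FALSE]
  gr
}

binWidths <- function(x) binEnds(x) - binStarts(x)

#' @describeIn inferResolution mode of bin widths, smallest on ties.
#' @export
setMethod("inferResolution", "BinTable", function(x) {
  if (nbins(x) == 0L) stop("structure has no bins", call. = FALSE)
  modeSmallest(binWidths(x))
})

# mode with ties broken toward the smallest value
modeSmallest <- function(v) {
  tab <- table(v)
  min(as.numeric(names(tab)[tab == max(tab)]))
}

setMethod("show", "BinTable", function(object) {
  n <- nbins(object)
  cs <- unique(chroms(object))
  ann <- setdiff(names(object@data), RESERVED_COLUMNS)
  cat(sprintf("BinTable: %d bin(s), %d chromosome(s)%s\n", n, length(cs),
              if (n) sprintf(", resolution %s bp", format(inferResolution(object))) else ""))
  cat("  chromosomes:", paste(utils::head(cs, 8L), collapse = ", "),
      if (length(cs) > 8L) "..." else "", "\n")
  if (length(ann))
    cat("  annotations:", paste(ann, collapse = ", "), "\n")
  if (n) {
    bb <- apply(coords(object), 2L, range)
    cat(sprintf("  bounding box: x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
})

#' Construct an IntervalTable
#'
#' @param chrom chromosome labels (recycled).
#' @param start,end 0-based half-open interval bounds in base pairs.
#' @param name optional feature names.
#' @param value optional numeric values (e.g. a signal or score).
#' @param strand optional strand characters (carried through, unused).
#' @return an [IntervalTable].
#' @examples
#' intervalTable("chr1", c(0, 5e5), c(1e5, 6e5))
#' @export
intervalTable <- function(chrom, start, end, name = NULL, value = NULL,
                          strand = NULL) {
  d <- DataFrame(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end))
  if (!is.null(name)) d$name <- as.character(name)
  if (!is.null(value)) d$value <- as.numeric(value)
  if (!is.null(strand)) d$strand <- as.character(strand)
  new("IntervalTable", data = d)
}

#' @rdname IntervalTable-class
#' @param x an `IntervalTable`.
#' @export
nintervals <- function(x) nrow(x@data)

#' @rdname IntervalTable-class
#' @export
intervalData <- function(x) as.data.frame(x@data)

setMethod("show", "IntervalTable", function(object) {
  cat(sprintf("IntervalTable: %d interval(s) on %d chromosome(s)\n",
              nrow(object@data), length(unique(object@data$chrom))))
})
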