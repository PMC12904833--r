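#' Column mapping for delimited structure tables
#'
#' Describes how the columns of a foreign CSV/TSV map onto the structure
#' model. Exactly one of `endCol` / `resolution` must be given: when
#' `endCol` is absent, bin ends are synthesized as `start + resolution`.
#'
#' @param chromCol,startCol,xCol,yCol,zCol source column names.
#' @param endCol source column holding bin ends, or `NULL`.
#' @param resolution bin width in bp used to synthesize ends, or `NULL`.
#' @return a `ColumnMapping` list.
#' @seealso [readTableStructure()]
#' @export
columnMapping <- function(chromCol, startCol, xCol, yCol, zCol,
                          endCol = NULL, resolution = NULL) {
  if (is.null(endCol) == is.null(resolution))
    stop("exactly one of endCol / resolution must be given", call. = FALSE)
  structure(list(chromCol = chromCol, startCol = startCol, endCol = endCol,
                 xCol = xCol, yCol = yCol, zCol = zCol,
                 resolution = resolution),
            class = "ColumnMapping")
}

#' Read a delimited table as a structure
#'
#' Reads a CSV or TSV and builds a [BinTable] according to a
#' [columnMapping()]. Columns not named in the mapping are carried over as
#' annotation columns under their original names; a carried column whose
#' name collides with a reserved column name (`chrom`, `start`, `end`,
#' `x`, `y`, `z`) while not being the mapped source is an error.
#'
#' @param path file path.
#' @param mapping a [columnMapping()].
#' @param dialect `"csv"` or `"tsv"`.
#' @return a [BinTable].
#' @seealso [writeTableStructure()]
#' @export
readTableStructure <- function(path, mapping, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mapping, "ColumnMapping"))
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  mapped <- c(chrom = mapping$chromCol, start = mapping$startCol,
              end = mapping$endCol,
              x = mapping$xCol, y = mapping$yCol, z = mapping$zCol)
  absent <- mapped[!mapped %in% names(df)]
  if (length(absent))
    stop("mapped column(s) not in file: ", paste(absent, collapse = ", "),
         call. = FALSE)
  carried <- setdiff(names(df), mapped)
  clash <- intersect(carried, RESERVED_COLUMNS)
  if (length(clash))
    stop("reserved-name collision: unmapped input column(s) ",
         paste(clash, collapse = ", "),
         " would shadow structure columns; rename or map them", call. = FALSE)
  out <- data.frame(chrom = df[[mapping$chromCol]],
                    start = df[[mapping$startCol]],
                    stringsAsFactors = FALSE)
  out$end <- if (is.null(mapping$endCol)) out$start + mapping$resolution
             else df[[mapping$endCol]]
  out$x <- df[[mapping$xCol]]; out$y <- df[[mapping$yCol]]
  out$z <- df[[mapping$zCol]]
  for (a in carried) out[[a]] <- df[[a]]
  binTable(out)
}

#' Write a structure as a delimited table
#'
#' Emits `chrom`, `start`, `end`, `x`, `y`, `z` followed by all annotation
#' columns, with a header, in row order. Such a file reads back with the
#' identity mapping.
#'
#' @param x a [BinTable].
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
writeTableStructure <- function(x, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "BinTable"))
  df <- as.data.frame(x@data)
  for (col in c("x", "y", "z")) df[[col]] <- formatCoord(df[[col]])
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identity column mapping for files written by [writeTableStructure()]
#' @param resolution ignored unless the file lacks an `end` column.
#' @return a [columnMapping()].
#' @export
identityMapping <- function(resolution = NULL) {
  columnMapping("chrom", "start", "x", "y", "z",
                endCol = if (is.null(resolution)) "end" else NULL,
                resolution = resolution)
}

#' Read a column mapping from a JSON document
#'
#' Accepts keys `chrom_col`, `start_col`, `end_col`, `x_col`, `y_col`,
#' `z_col`, `resolution` (camelCase also accepted).
#'
#' @param path JSON file path.
#' @return a [columnMapping()].
#' @export
readColumnMapping <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(doc[[k]])) return(doc[[k]])
    NULL
  }
  columnMapping(
    chromCol = pick("chrom_col", "chromCol"),
    startCol = pick("start_col", "startCol"),
    endCol = pick("end_col", "endCol"),
    xCol = pick("x_col", "xCol"), yCol = pick("y_col", "yCol"),
    zCol = pick("z_col", "zCol"),
    resolution = pick("resolution"))
}
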