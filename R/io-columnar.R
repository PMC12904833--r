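# Canonical binary form: Arrow IPC / Feather. Lossless for every column
# the model defines, including annotation columns and their types, and
# bit-exact for floating-point coordinates.

#' Write a structure as an Arrow IPC (Feather) file
#'
#' All columns — reserved and annotation, numeric and categorical — round
#' trip losslessly through [readColumnar()], preserving row order and
#' column types; floats are bit-exact.
#'
#' @param x a [BinTable].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeColumnar <- function(x, path) {
  stopifnot(is(x, "BinTable"))
  arrow::write_feather(as.data.frame(x@data), path)
  invisible(path)
}

#' Read a structure from an Arrow IPC (Feather) file
#'
#' @param path file path.
#' @return a [BinTable].
#' @export
readColumnar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(arrow::read_feather(path))
  missing_cols <- setdiff(RESERVED_COLUMNS, names(df))
  if (length(missing_cols))
    stop("columnar file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  binTable(df)
}
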