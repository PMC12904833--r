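#' Read a .3dg structure file
#'
#' The .3dg dialect of the single-cell Hi-C structure literature: one bin
#' per line, whitespace-separated fields `chromosome`, `bin start` (bp),
#' `x`, `y`, `z`. Lines beginning with `#` are skipped. The format carries
#' no bin ends, so `end` is synthesized as `start + resolution`, where the
#' resolution is, per chromosome, the most frequent difference between
#' consecutive starts (ties -> smallest); chromosomes with a single bin
#' fall back to the most frequent difference genome-wide. The "position"
#' field is interpreted as the bin start, not a midpoint.
#'
#' @param path file path.
#' @param resolution optional explicit bin width in bp; overrides
#'   inference. Required when no chromosome has two bins.
#' @return a [BinTable].
#' @seealso [write3dg()]
#' @export
read3dg <- function(path, resolution = NULL) {
  lines <- readStructureLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 5L))
    stop(sprintf("malformed line %d in %s: expected 5 fields, got %d",
                 keep[which(nf != 5L)[1L]], path, nf[which(nf != 5L)[1L]]),
         call. = FALSE)
  m <- do.call(rbind, fields)
  num <- apply(m[, 2:5, drop = FALSE], 2L, function(col) suppressWarnings(as.numeric(col)))
  num <- matrix(num, ncol = 4L)
  bad <- which(apply(num, 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: non-numeric field", keep[bad[1L]], path),
         call. = FALSE)
  chrom <- m[, 1L]; start <- num[, 1L]

  if (is.null(resolution)) {
    diffs <- unlist(lapply(split(start, factor(chrom, levels = unique(chrom))),
                           function(s) if (length(s) > 1L) abs(diff(s)) else numeric()))
    diffs <- diffs[diffs > 0]
    if (!length(diffs))
      stop("cannot synthesize bin ends: every chromosome has fewer than 2 bins ",
           "and no resolution was given", call. = FALSE)
    globalRes <- modeSmallest(diffs)
    res <- vapply(split(start, factor(chrom, levels = unique(chrom))), function(s) {
      d <- abs(diff(s)); d <- d[d > 0]
      if (length(d)) modeSmallest(d) else globalRes
    }, numeric(1))
    end <- start + res[match(chrom, unique(chrom))]
  } else {
    end <- start + resolution
  }

  binTable(data.frame(chrom = chrom, start = start, end = end,
                      x = num[, 2L], y = num[, 3L], z = num[, 4L]))
}

#' Write a .3dg structure file
#'
#' One tab-separated line per bin: `chrom`, `start`, `x`, `y`, `z`, in row
#' order. Coordinates are printed at 6 significant digits; annotation
#' columns are not emitted (the format cannot carry them) and bin ends are
#' dropped (recovered on read by resolution inference).
#'
#' @param x a [BinTable].
#' @param path output path.
#' @return invisibly, `path`.
#' @seealso [read3dg()]
#' @export
write3dg <- function(x, path) {
  stopifnot(is(x, "BinTable"))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s",
                   chroms(x), formatBp(binStarts(x)),
                   formatCoord(x@data$x), formatCoord(x@data$y),
                   formatCoord(x@data$z))
  writeLines(lines, path)
  invisible(path)
}

# text floats at 6 significant digits (round-trip tolerance 1e-5);
# formatC pads vectors to a common width, so strip that again
formatCoord <- function(v) trimws(formatC(v, digits = 6L, format = "g"))

# genomic coordinates are integral; print without scientific notation
formatBp <- function(v) format(v, scientific = FALSE, trim = TRUE)

# read lines tolerating CRLF and missing trailing newline
readStructureLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sub("\r$", "", readLines(path, warn = FALSE))
}
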