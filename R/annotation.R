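#' Read a BED file of intervals
#'
#' Accepts 3 or more columns; `track`/`browser`/`#` lines are tolerated
#' and skipped. BED is already 0-based half-open and is passed through
#' unchanged; column 4 becomes `name` and column 5 becomes a numeric
#' `value`, column 6 a `strand` (carried through, unused) when present.
#'
#' @param path file path.
#' @return an [IntervalTable].
#' @export
readBed <- function(path) {
  lines <- readStructureLines(path)
  keep <- which(!grepl("^\\s*($|#|track\\b|browser\\b)", lines))
  if (!length(keep)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d in %s: fewer than 3 BED columns",
                 keep[which(nf < 3L)[1L]], path), call. = FALSE)
  getcol <- function(j) vapply(fields, function(f) if (length(f) >= j) f[j] else NA_character_,
                               character(1))
  start <- suppressWarnings(as.numeric(getcol(2L)))
  end <- suppressWarnings(as.numeric(getcol(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("line %d in %s: non-integer coordinate", keep[bad[1L]], path),
         call. = FALSE)
  hasName <- all(nf >= 4L); hasValue <- all(nf >= 5L); hasStrand <- all(nf >= 6L)
  intervalTable(getcol(1L), start, end,
                name = if (hasName) getcol(4L) else NULL,
                value = if (hasValue) suppressWarnings(as.numeric(getcol(5L))) else NULL,
                strand = if (hasStrand) getcol(6L) else NULL)
}

#' Read features of one type from a GTF/GFF file
#'
#' Keeps the 9-column rows whose third field equals `featureType`
#' (e.g. `"gene"`), converting coordinates from the 1-based inclusive GTF
#' convention to 0-based half-open (`start - 1`, `end`). The attribute
#' field is parsed for `gene_id` under GFF2/GTF syntax
#' (`key "value";`) or, auto-detected, `gene_id=`/`ID=` under GFF3
#' syntax; the result becomes `name` when present.
#'
#' @param path file path.
#' @param featureType feature type to keep (3rd GTF field).
#' @return an [IntervalTable].
#' @export
readGtfFeatures <- function(path, featureType = "gene") {
  lines <- readStructureLines(path)
  keep <- which(!grepl("^\\s*($|#)", lines))
  if (!length(keep)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t")
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("line %d in %s: fewer than 9 GTF fields (%d)",
                 keep[which(nf < 9L)[1L]], path, nf[which(nf < 9L)[1L]]),
         call. = FALSE)
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  sel <- m[, 3L] == featureType
  if (!any(sel))
    return(intervalTable(character(), numeric(), numeric(),
                         name = character(), strand = character()))
  m <- m[sel, , drop = FALSE]
  rows <- keep[sel]
  start1 <- suppressWarnings(as.numeric(m[, 4L]))
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop(sprintf("line %d in %s: non-numeric coordinate", rows[bad[1L]], path),
         call. = FALSE)
  name <- vapply(m[, 9L], parseFeatureId, character(1), USE.NAMES = FALSE)
  intervalTable(m[, 1L], start1 - 1, end1, name = name, strand = m[, 7L])
}

# gene_id from GFF2/GTF (`gene_id "G1";`) or GFF3 (`gene_id=G1` / `ID=G1`)
parseFeatureId <- function(attr) {
  m <- regmatches(attr, regexec('gene_id\\s+"([^"]*)"', attr))[[1L]]
  if (length(m) == 2L) return(m[2L])
  for (key in c("gene_id", "ID")) {
    m <- regmatches(attr, regexec(paste0('(^|;)\\s*', key, '=([^;]*)'), attr))[[1L]]
    if (length(m) == 3L) return(m[3L])
  }
  NA_character_
}

#' Aggregate genomic features into structure bins
#'
#' Adds one numeric annotation column summarizing, per bin, the features
#' that fall on it — the gene-density computation behind color/scale
#' encodings of annotation data. Modes:
#' \describe{
#'   \item{`count`}{number of features with a nonempty half-open
#'     intersection with the bin (a feature spanning a bin boundary counts
#'     in every bin it touches).}
#'   \item{`count_midpoint`}{number of features whose midpoint
#'     `floor((start + end) / 2)` lies in the bin — each feature counts at
#'     most once genome-wide, so totals are conservation-checkable.}
#'   \item{`coverage_fraction`}{fraction of the bin covered by the union
#'     of the features (overlaps merged first), in \[0, 1\].}
#'   \item{`mean_value`}{length-weighted mean of the features' `value`
#'     over the covered part of the bin; uncovered bins get `NA`.}
#' }
#' Uncovered bins get 0 for the count/coverage modes. Features on
#' chromosomes absent from the structure are ignored (a count is
#' reported via `message()`), since annotations are usually genome-wide.
#' Existing columns, row count and row order are never changed.
#'
#' @param x a [BinTable].
#' @param features an [IntervalTable].
#' @param mode aggregation mode (see above); default `"count"`.
#' @param column name of the new annotation column; must not be reserved
#'   or already present.
#' @return a [BinTable] with one extra numeric column.
#' @export
binFeatures <- function(x, features,
                        mode = c("count", "count_midpoint",
                                 "coverage_fraction", "mean_value"),
                        column = mode) {
  mode <- match.arg(mode)
  column <- column[1L]
  stopifnot(is(x, "BinTable"), is(features, "IntervalTable"))
  if (column %in% RESERVED_COLUMNS)
    stop("column name '", column, "' is reserved", call. = FALSE)
  if (column %in% names(x@data))
    stop("column '", column, "' already exists", call. = FALSE)

  fd <- features@data
  known <- fd$chrom %in% unique(chroms(x))
  if (any(!known))
    message(sum(!known), " feature(s) on chromosomes absent from the structure ignored")
  fd <- fd[known, , drop = FALSE]
  bins <- asGRanges(x)

  if (mode == "mean_value" && is.null(fd$value))
    stop("mode 'mean_value' requires features with a value column", call. = FALSE)

  result <- if (nrow(fd) == 0L) {
    if (mode == "mean_value") rep(NA_real_, nbins(x)) else rep(0, nbins(x))
  } else {
    feats <- GRanges(fd$chrom, IRanges(fd$start + 1, fd$end))
    switch(mode,
      count = as.numeric(countOverlaps(bins, feats)),
      count_midpoint = {
        mid <- floor((fd$start + fd$end) / 2)
        pts <- GRanges(fd$chrom, IRanges(mid + 1, width = 1))
        as.numeric(countOverlaps(bins, pts))
      },
      coverage_fraction = {
        merged <- reduce(feats)
        fo <- findOverlaps(bins, merged)
        w <- GenomicRanges::width(pintersect(bins[S4Vectors::queryHits(fo)],
                                             merged[S4Vectors::subjectHits(fo)]))
        covered <- rep(0, nbins(x))
        agg <- tapply(w, S4Vectors::queryHits(fo), sum)
        covered[as.integer(names(agg))] <- agg
        covered / binWidths(x)
      },
      mean_value = {
        fo <- findOverlaps(bins, feats)
        w <- GenomicRanges::width(pintersect(bins[S4Vectors::queryHits(fo)],
                                             feats[S4Vectors::subjectHits(fo)]))
        v <- fd$value[S4Vectors::subjectHits(fo)]
        num <- tapply(w * v, S4Vectors::queryHits(fo), sum)
        den <- tapply(w, S4Vectors::queryHits(fo), sum)
        out <- rep(NA_real_, nbins(x))
        out[as.integer(names(num))] <- num / den
        out
      })
  }
  y <- x
  y@data[[column]] <- result
  validObject(y)
  y
}
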