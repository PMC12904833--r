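#' @importFrom GenomicRanges GRanges countOverlaps findOverlaps reduce pintersect
#' @importFrom IRanges IRanges
NULL

# Selections return logical masks aligned with the bin rows, not subsets:
# masks compose cheaply (combineMasks) and can drive both subsetting
# (applyMask) and visual highlighting. apply_mask materializes.

checkMask <- function(x, mask, arg = "mask") {
  if (!is.logical(mask) || anyNA(mask))
    stop(arg, " must be a logical vector without NAs", call. = FALSE)
  if (length(mask) != nbins(x))
    stop(sprintf("%s length (%d) does not match bin count (%d)",
                 arg, length(mask), nbins(x)), call. = FALSE)
  invisible(mask)
}

#' Select bins by genomic ranges
#'
#' Marks every bin that overlaps at least one query interval on the same
#' chromosome (exact string match; no `chr` aliasing). Intervals are
#' 0-based half-open on both sides, so a query ending at a bin's start
#' does not touch it. `mode = "any_overlap"` requires a nonempty
#' intersection; `mode = "contained"` requires the bin to lie entirely
#' inside a single query interval (bin ⊆ query — the natural reading when
#' structures are coarser than queries). A query chromosome absent from
#' the structure matches nothing.
#'
#' @param x a [BinTable].
#' @param query an [IntervalTable] (e.g. from [readBed()]).
#' @param mode `"any_overlap"` or `"contained"`.
#' @return logical selection mask, one entry per bin.
#' @examples
#' bt <- binTableFromCoordinates(matrix(0, 3, 3), "chr1", 1e5)
#' selectByRanges(bt, intervalTable("chr1", 150e3, 160e3))
#' @export
selectByRanges <- function(x, query, mode = c("any_overlap", "contained")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "BinTable"), is(query, "IntervalTable"))
  if (nbins(x) == 0L) return(logical())
  if (nrow(query@data) == 0L) return(rep(FALSE, nbins(x)))
  bins <- asGRanges(x)
  q <- asGRanges(query)
  # a query chromosome absent from the structure matches nothing, silently
  lev <- union(GenomeInfoDb::seqlevels(bins), GenomeInfoDb::seqlevels(q))
  GenomeInfoDb::seqlevels(bins) <- lev
  GenomeInfoDb::seqlevels(q) <- lev
  GenomicRanges::countOverlaps(
    bins, q, type = if (mode == "contained") "within" else "any",
    ignore.strand = TRUE) > 0L
}

#' Construct a cutting plane
#'
#' @param normal numeric triple; need not be unit length.
#' @param offset signed offset `d` in the plane equation
#'   \eqn{\hat{n} \cdot p + d = 0}.
#' @return a [Plane].
#' @export
plane <- function(normal, offset = 0) {
  new("Plane", normal = as.numeric(normal), offset = as.numeric(offset))
}

#' Cross-section a structure with a cutting plane
#'
#' Computes the signed distance \eqn{s_i = \hat{n} \cdot p_i + d} of every
#' bin and keeps one side. Bins exactly on the plane (`s = 0`) belong to
#' the positive side, so the two masks always partition the structure.
#'
#' @param x a [BinTable].
#' @param cutPlane a [plane()].
#' @param keep `"positive"` (s >= 0) or `"negative"` (s < 0).
#' @return logical selection mask.
#' @export
cutByPlane <- function(x, cutPlane, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  stopifnot(is(x, "BinTable"), is(cutPlane, "Plane"))
  n <- cutPlane@normal / sqrt(sum(cutPlane@normal^2))
  s <- as.numeric(coords(x) %*% n) + cutPlane@offset
  if (keep == "positive") s >= 0 else s < 0
}

#' Select a spherical neighborhood
#'
#' Marks bins within Euclidean distance `radius` of `center` (boundary
#' inclusive).
#'
#' @param x a [BinTable].
#' @param center numeric triple, model units.
#' @param radius positive radius, model units.
#' @return logical selection mask.
#' @export
selectSphere <- function(x, center, radius) {
  stopifnot(is(x, "BinTable"))
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite numeric triple", call. = FALSE)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number", call. = FALSE)
  p <- coords(x)
  d2 <- (p[, 1L] - center[1L])^2 + (p[, 2L] - center[2L])^2 +
        (p[, 3L] - center[3L])^2
  d2 <= radius^2
}

#' Select a spherical neighborhood around a genomic locus
#'
#' Finds the unique bin covering `(chrom, pos)` (half-open: a position
#' equal to a bin's `end` belongs to the next bin) and selects the sphere
#' of the given radius centered on that bin's coordinates. The anchoring
#' bin itself is always selected (distance 0). Zero covering bins, or
#' several (diploid duplicates), are errors; disambiguate duplicates by
#' filtering on an annotation column first.
#'
#' @param x a [BinTable].
#' @param chrom chromosome label (exact match).
#' @param pos 0-based genomic position in bp.
#' @param radius positive radius, model units.
#' @return logical selection mask.
#' @export
selectSphereAroundLocus <- function(x, chrom, pos, radius) {
  stopifnot(is(x, "BinTable"))
  hit <- which(chroms(x) == chrom & binStarts(x) <= pos & pos < binEnds(x))
  if (length(hit) == 0L)
    stop(sprintf("locus %s:%s is not covered by any bin", chrom, formatBp(pos)),
         call. = FALSE)
  if (length(hit) > 1L)
    stop(sprintf(
      "locus %s:%s is covered by %d bins (rows %s); disambiguate homologs by filtering on an annotation column first",
      chrom, formatBp(pos), length(hit), paste(hit, collapse = ", ")),
      call. = FALSE)
  selectSphere(x, coords(x)[hit, ], radius)
}

#' Materialize a selection
#'
#' Returns the row subset of the structure where the mask is true, with
#' original row order and every column preserved.
#'
#' @param x a [BinTable].
#' @param mask logical mask of length `nbins(x)`.
#' @return a [BinTable] (possibly empty, same schema).
#' @export
applyMask <- function(x, mask) {
  stopifnot(is(x, "BinTable"))
  checkMask(x, mask)
  x[mask]
}

#' Combine selection masks
#'
#' Elementwise boolean algebra over equal-length masks; `"not_a"` is unary
#' and ignores `b`.
#'
#' @param a,b logical masks of equal length.
#' @param op `"and"`, `"or"` or `"not_a"`.
#' @return logical mask.
#' @export
combineMasks <- function(a, b = NULL, op = c("and", "or", "not_a")) {
  op <- match.arg(op)
  if (!is.logical(a) || anyNA(a)) stop("a must be a logical mask", call. = FALSE)
  if (op == "not_a") return(!a)
  if (!is.logical(b) || anyNA(b)) stop("b must be a logical mask", call. = FALSE)
  if (length(a) != length(b))
    stop(sprintf("mask length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  switch(op, and = a & b, or = a | b)
}
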