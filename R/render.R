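# Minimal static raster: orthographic projection + painter's algorithm.
# A smoke-test and documentation device, not a product renderer: marks are
# flat-shaded discs (spheres) and axis-aligned quads (boxes), drawn
# far-to-near so the nearest mark wins each pixel. Deterministic.

#' Render a scene to a PNG
#'
#' Projects every mark orthographically along `viewDirection`, sorts by
#' depth and paints flat discs/quads back to front onto a white
#' background. Output is deterministic for fixed inputs.
#'
#' @param x a [Scene] (or a [BinTable], with `config`).
#' @param viewDirection nonzero numeric triple; the camera looks along it.
#' @param imageSize image side in pixels (square).
#' @param output PNG path.
#' @param config used when `x` is a [BinTable].
#' @return invisibly, `output`.
#' @export
renderStatic <- function(x, viewDirection = c(1, 1, 1), imageSize = 400L,
                         output, config = viewConfig()) {
  if (is(x, "BinTable")) x <- scene(x, config)
  stopifnot(is(x, "Scene"))
  viewDirection <- as.numeric(viewDirection)
  if (length(viewDirection) != 3L || sqrt(sum(viewDirection^2)) == 0)
    stop("view direction must be a nonzero triple", call. = FALSE)
  w <- viewDirection / sqrt(sum(viewDirection^2))
  u <- if (abs(w[3L]) < 0.9) {
    cu <- c(-w[2L], w[1L], 0); cu / sqrt(sum(cu^2))
  } else c(1, 0, 0)
  v <- c(w[2L] * u[3L] - w[3L] * u[2L],
         w[3L] * u[1L] - w[1L] * u[3L],
         w[1L] * u[2L] - w[2L] * u[1L])

  centers <- NULL; colors <- NULL; sizes <- NULL; marks <- NULL
  for (e in x@entries) {
    attrs <- resolveViewConfig(e$structure, e$config)
    centers <- rbind(centers, coords(e$structure))
    colors <- rbind(colors, attrColors(attrs))
    sizes <- c(sizes, attrSizes(attrs))
    marks <- c(marks, attrMarks(attrs))
  }

  img <- array(1, dim = c(imageSize, imageSize, 3L))  # white background
  if (!is.null(centers) && nrow(centers)) {
    px <- centers %*% u
    py <- centers %*% v
    depth <- centers %*% w
    lo <- c(min(px - sizes), min(py - sizes))
    hi <- c(max(px + sizes), max(py + sizes))
    span <- max(hi - lo, 1e-12)
    margin <- 0.05
    toPix <- function(val, axis)  # [lo, hi] -> pixel coords with margin
      (val - lo[axis]) / span * imageSize * (1 - 2 * margin) +
        imageSize * margin
    cx <- toPix(px, 1L)
    cy <- imageSize + 1 - toPix(py, 2L)  # row 1 = top
    r <- pmax(sizes / span * imageSize * (1 - 2 * margin), 1)
    for (i in order(depth, decreasing = TRUE)) {  # far first
      rows <- max(1L, floor(cy[i] - r[i])):min(imageSize, ceiling(cy[i] + r[i]))
      cols <- max(1L, floor(cx[i] - r[i])):min(imageSize, ceiling(cx[i] + r[i]))
      if (!length(rows) || !length(cols) || rows[1L] > imageSize || cols[1L] > imageSize)
        next
      rgb01 <- colors[i, 1:3] / 255
      if (marks[i] == "sphere") {
        dy2 <- (rows - cy[i])^2
        dx2 <- (cols - cx[i])^2
        hitR <- outer(dy2, dx2, "+") <= r[i]^2
        for (ch in 1:3) {
          block <- img[rows, cols, ch]
          block[hitR] <- rgb01[ch]
          img[rows, cols, ch] <- block
        }
      } else {
        for (ch in 1:3) img[rows, cols, ch] <- rgb01[ch]
      }
    }
  }
  png::writePNG(img, output)
  invisible(output)
}
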