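#' @importFrom grDevices col2rgb
NULL

VALID_MARKS <- c("sphere", "box")
VALID_COLORMAPS <- c("viridis", "bluered")
VALID_CONFIG_KEYS <- c("mark", "color", "scale", "base_size", "links")
VALID_CHANNEL_KEYS <- c("constant", "field", "scale_type", "domain", "range")
DEFAULT_SCALE_RANGE <- c(0.25, 1.5)

#' Constant channel specification
#'
#' A channel that broadcasts one value to every bin: a color string
#' (`"#RRGGBB"`, `"#RRGGBBAA"` or an R color name) for the color channel,
#' a positive number for the scale channel.
#'
#' @param value the constant.
#' @return a channel spec list.
#' @seealso [channelMapping()], [viewConfig()]
#' @export
channelConstant <- function(value) list(constant = value)

#' Data-driven channel specification
#'
#' Maps an annotation (or reserved) column to a visual channel.
#' Continuous mappings normalize the column into \[0, 1\] over `domain`
#' (default: the column's min/max, recomputed per structure; fix it
#' explicitly for cross-structure comparability) and pass it through a
#' colormap (color channel) or a linear ramp into `range` (scale
#' channel). Categorical mappings assign palette entries to categories in
#' order of first appearance, or in the order of an explicit `domain`.
#'
#' @param field column name in the target structure.
#' @param scaleType `"continuous"` or `"categorical"`.
#' @param domain optional `c(min, max)` (continuous) or category vector
#'   (categorical).
#' @param range optional: a colormap name or explicit color vector for
#'   the color channel; a numeric `c(lo, hi)` multiplier pair for the
#'   scale channel.
#' @return a channel spec list.
#' @export
channelMapping <- function(field, scaleType = c("continuous", "categorical"),
                           domain = NULL, range = NULL) {
  scaleType <- match.arg(scaleType)
  spec <- list(field = field, scale_type = scaleType)
  if (!is.null(domain)) spec$domain <- domain
  if (!is.null(range)) spec$range <- range
  spec
}

checkChannel <- function(spec, channel, errs) {
  where <- function(msg) finding(paste0("channel_", channel), NULL,
                                 sprintf("%s channel: %s", channel, msg))
  if (!is.list(spec))
    return(c(errs, list(where("must be an object"))))
  unknown <- setdiff(names(spec), VALID_CHANNEL_KEYS)
  if (length(unknown))
    errs[[length(errs) + 1L]] <- where(
      sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  hasConst <- "constant" %in% names(spec)
  hasField <- "field" %in% names(spec)
  if (hasConst == hasField) {
    errs[[length(errs) + 1L]] <- where(
      "exactly one of 'constant' / 'field' is required")
    return(errs)
  }
  if (hasConst && length(spec$constant) != 1L)
    errs[[length(errs) + 1L]] <- where("'constant' must be a single value")
  if (hasField) {
    st <- spec$scale_type
    if (!is.null(st) && !st %in% c("continuous", "categorical"))
      errs[[length(errs) + 1L]] <- where(
        "scale_type must be 'continuous' or 'categorical'")
    if (channel == "color" && !is.null(spec$range) &&
        is.character(spec$range) && length(spec$range) == 1L &&
        !spec$range %in% VALID_COLORMAPS)
      errs[[length(errs) + 1L]] <- where(
        sprintf("unknown colormap '%s' (built-ins: %s)", spec$range,
                paste(VALID_COLORMAPS, collapse = ", ")))
    if (channel == "scale" && !is.null(spec$range) &&
        (!is.numeric(spec$range) || length(spec$range) != 2L))
      errs[[length(errs) + 1L]] <- where(
        "scale range must be a numeric [lo, hi] pair")
  }
  errs
}

#' Validate a view-config document
#'
#' Checks a JSON-like document (named list, e.g. from
#' `jsonlite::read_json`) against the grammar: unknown keys are errors
#' (fail-fast), channels must be well-formed, mark and colormap names
#' must be known. Field existence is deferred to
#' [resolveViewConfig()] so a config stays structure-independent.
#' Nothing is thrown; problems are reported.
#'
#' @param doc named list / parsed JSON.
#' @return a [ValidationReport].
#' @examples
#' isValid(validateViewConfig(list()))           # all defaults
#' isValid(validateViewConfig(list(mark = "tetrahedron")))
#' @export
validateViewConfig <- function(doc) {
  errs <- list()
  if (!is.list(doc))
    return(report(list(finding("config_type", NULL, "config must be an object")),
                  list()))
  unknown <- setdiff(names(doc), VALID_CONFIG_KEYS)
  if (length(unknown))
    errs[[length(errs) + 1L]] <- finding("unknown_key", NULL,
      sprintf("unknown key(s): %s (allowed: %s)",
              paste(unknown, collapse = ", "),
              paste(VALID_CONFIG_KEYS, collapse = ", ")))
  if (!is.null(doc$mark) && !doc$mark %in% VALID_MARKS)
    errs[[length(errs) + 1L]] <- finding("unknown_mark", NULL,
      sprintf("unknown mark '%s' (allowed: %s)", doc$mark,
              paste(VALID_MARKS, collapse = ", ")))
  for (channel in c("color", "scale"))
    if (!is.null(doc[[channel]]))
      errs <- checkChannel(doc[[channel]], channel, errs)
  if (!is.null(doc$base_size) &&
      !(identical(doc$base_size, "auto") ||
        (is.numeric(doc$base_size) && doc$base_size > 0)))
    errs[[length(errs) + 1L]] <- finding("base_size", NULL,
      "base_size must be a positive number or \"auto\"")
  if (!is.null(doc$links) && !is.logical(doc$links))
    errs[[length(errs) + 1L]] <- finding("links", NULL,
      "links must be true or false")
  report(errs, list())
}

#' Construct a view configuration
#'
#' Defaults: sphere marks, constant mid-grey color, constant scale
#' multiplier 1, `baseSize = "auto"` (half the median distance between
#' consecutive same-chromosome bins, a size that keeps neighboring marks
#' from fusing), no links.
#'
#' @param mark `"sphere"` or `"box"`.
#' @param color channel spec ([channelConstant()] / [channelMapping()]).
#' @param scale channel spec resolving to positive multipliers.
#' @param baseSize positive number (model units) or `"auto"`.
#' @param links draw connecting segments between consecutive bins of a
#'   chromosome.
#' @return a [ViewConfig].
#' @export
viewConfig <- function(mark = "sphere", color = channelConstant("#808080"),
                       scale = channelConstant(1.0), baseSize = "auto",
                       links = FALSE) {
  doc <- list(mark = mark, color = color, scale = scale,
              base_size = baseSize, links = links)
  rep <- validateViewConfig(doc)
  if (!isValid(rep))
    stop("invalid view config: ", paste(rep@errors$message, collapse = "; "),
         call. = FALSE)
  new("ViewConfig", mark = mark, color = color, scale = scale,
      baseSize = baseSize, links = links)
}

#' Read a view configuration from JSON
#'
#' @param path JSON file path (keys `mark`, `color`, `scale`,
#'   `base_size`, `links`).
#' @return a [ViewConfig].
#' @export
readViewConfig <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- validateViewConfig(doc)
  if (!isValid(rep))
    stop("invalid view config in ", path, ": ",
         paste(rep@errors$message, collapse = "; "), call. = FALSE)
  viewConfig(mark = doc$mark %||% "sphere",
             color = doc$color %||% channelConstant("#808080"),
             scale = doc$scale %||% channelConstant(1.0),
             baseSize = doc$base_size %||% "auto",
             links = isTRUE(doc$links))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize numeric values into \[0, 1\]
#'
#' `t = (v - min) / (max - min)`, clipped to \[0, 1\]; the domain
#' defaults to the finite data range. A degenerate (zero-spread) domain
#' maps everything to 0.5. `NA` input normalizes to 0.5 (neutral).
#'
#' @param values numeric vector.
#' @param domain optional `c(min, max)`.
#' @return numeric vector in \[0, 1\].
#' @examples
#' normalizeValues(c(0, 5, 10))          # 0.0 0.5 1.0
#' normalizeValues(5, domain = c(0, 20)) # 0.25
#' @export
normalizeValues <- function(values, domain = NULL) {
  values <- as.numeric(values)
  if (is.null(domain)) {
    fin <- values[is.finite(values)]
    domain <- if (length(fin)) range(fin) else c(0, 1)
  }
  lo <- domain[1L]; hi <- domain[2L]
  out <- if (hi > lo) pmin(1, pmax(0, (values - lo) / (hi - lo)))
         else rep(0.5, length(values))
  out[!is.finite(values)] <- 0.5
  out
}

colormapAnchors <- function(name) {
  switch(name,
    viridis = VIRIDIS_ANCHORS,
    bluered = BLUERED_ANCHORS,
    stop(sprintf("unknown colormap '%s' (built-ins: %s)", name,
                 paste(VALID_COLORMAPS, collapse = ", ")), call. = FALSE))
}

# piecewise-linear interpolation through RGBA anchors, round-half-up
interpolateAnchors <- function(anchors, t) {
  rgba <- t(col2rgb(anchors, alpha = TRUE))  # k x 4
  k <- nrow(rgba)
  t <- pmin(1, pmax(0, t))
  pos <- t * (k - 1)
  i <- pmin(floor(pos), k - 2)
  frac <- pos - i
  out <- (1 - frac) * rgba[i + 1L, , drop = FALSE] +
         frac * rgba[i + 2L, , drop = FALSE]
  mode(out) <- "numeric"
  matrix(as.integer(floor(out + 0.5)), ncol = 4L,
         dimnames = list(NULL, c("red", "green", "blue", "alpha")))
}

#' Look up a continuous colormap
#'
#' Piecewise-linear interpolation (in RGB, round-half-up) through the
#' colormap's anchor colors. Built-ins: `"viridis"` (the standard
#' 256-anchor perceptually uniform table) and `"bluered"` (pure blue to
#' pure red).
#'
#' @param name colormap name.
#' @param t numeric vector in \[0, 1\] (clipped).
#' @return integer matrix, `length(t)` x 4 RGBA in \[0, 255\].
#' @examples
#' continuousColormap("bluered", c(0, 0.5, 1))
#' @export
continuousColormap <- function(name, t) {
  interpolateAnchors(colormapAnchors(name), t)
}

#' Assign qualitative colors to categories
#'
#' Assigns, in the order given, entries of a fixed built-in 12-color
#' qualitative palette; more than 12 categories cycle through the palette
#' again, with a warning. Deterministic across runs.
#'
#' @param categories ordered vector of distinct category labels.
#' @return named list mapping each category to an RGBA integer vector.
#' @export
categoricalPalette <- function(categories) {
  categories <- as.character(categories)
  stopifnot(length(categories) >= 1L, !anyDuplicated(categories))
  if (length(categories) > length(PALETTE12))
    warning(sprintf("%d categories exceed the 12-color palette; colors repeat",
                    length(categories)), call. = FALSE)
  idx <- ((seq_along(categories) - 1L) %% length(PALETTE12)) + 1L
  cols <- t(col2rgb(PALETTE12[idx], alpha = TRUE))
  out <- lapply(seq_along(categories), function(i) as.integer(cols[i, ]))
  names(out) <- categories
  out
}

parseColor <- function(value, where) {
  rgba <- tryCatch(col2rgb(value, alpha = TRUE),
                   error = function(e) stop(sprintf(
                     "%s: cannot parse color '%s'", where, value), call. = FALSE))
  as.integer(rgba[, 1L])
}

resolveColorChannel <- function(x, spec) {
  n <- nbins(x)
  if (!is.null(spec$constant)) {
    rgba <- parseColor(spec$constant, "color channel")
    return(matrix(rep(rgba, each = n), nrow = n,
                  dimnames = list(NULL, c("red", "green", "blue", "alpha"))))
  }
  v <- fieldValues(x, spec$field)
  if (identical(spec$scale_type %||% "continuous", "continuous")) {
    if (!is.numeric(v))
      stop(sprintf("continuous color mapping over non-numeric column '%s'",
                   spec$field), call. = FALSE)
    t <- normalizeWithWarning(v, spec$domain, spec$field)
    rng <- spec$range %||% "viridis"
    if (is.character(rng) && length(rng) == 1L && !grepl("^#", rng))
      continuousColormap(rng, t)
    else
      interpolateAnchors(unlist(rng), t)
  } else {
    cats <- as.character(spec$domain %||% unique(as.character(v)))
    extra <- setdiff(unique(as.character(v)), cats)
    pal <- categoricalPalette(c(cats, extra))
    do.call(rbind, pal[as.character(v)])
  }
}

normalizeWithWarning <- function(v, domain, field) {
  fin <- v[is.finite(v)]
  dom <- if (is.null(domain)) {
    if (length(fin)) range(fin) else c(0, 1)
  } else as.numeric(domain)
  if (dom[2L] <= dom[1L])
    warning(sprintf("zero-spread domain for field '%s'; all values map to 0.5",
                    field), call. = FALSE)
  normalizeValues(v, dom)
}

resolveScaleChannel <- function(x, spec) {
  n <- nbins(x)
  if (!is.null(spec$constant)) {
    mult <- as.numeric(spec$constant)
    if (!is.finite(mult) || mult <= 0)
      stop("scale channel: constant multiplier must be positive", call. = FALSE)
    return(rep(mult, n))
  }
  v <- fieldValues(x, spec$field)
  rng <- as.numeric(spec$range %||% DEFAULT_SCALE_RANGE)
  if (identical(spec$scale_type %||% "continuous", "continuous")) {
    if (!is.numeric(v))
      stop(sprintf("continuous scale mapping over non-numeric column '%s'",
                   spec$field), call. = FALSE)
    t <- normalizeWithWarning(v, spec$domain, spec$field)
  } else {
    cats <- as.character(spec$domain %||% unique(as.character(v)))
    cats <- union(cats, unique(as.character(v)))
    k <- length(cats)
    lev <- match(as.character(v), cats)
    t <- if (k == 1L) rep(0.5, n) else (lev - 1) / (k - 1)
  }
  mult <- rng[1L] + t * (rng[2L] - rng[1L])
  if (any(mult <= 0))
    stop("scale channel resolves to non-positive multipliers; adjust range",
         call. = FALSE)
  mult
}

fieldValues <- function(x, field) {
  if (!field %in% names(x@data))
    stop(sprintf("field '%s' not found; available columns: %s", field,
                 paste(names(x@data), collapse = ", ")), call. = FALSE)
  x@data[[field]]
}

autoBaseSize <- function(x) {
  p <- coords(x)
  same <- chroms(x)[-1L] == chroms(x)[-nbins(x)]
  if (nbins(x) < 2L || !any(same)) return(1.0)
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nbins(x), , drop = FALSE])^2))
  0.5 * median(d[same])
}

#' Resolve a view config against a structure
#'
#' Turns the declarative config into concrete per-bin attributes:
#' constant channels broadcast; continuous channels normalize the mapped
#' column and pass it through a colormap (color) or a linear ramp into
#' the multiplier range, default \[0.25, 1.5\] (scale); categorical
#' channels assign palette colors (or evenly spaced multipliers) to
#' categories in order of first appearance. `baseSize = "auto"` resolves
#' to half the median distance between consecutive same-chromosome bins.
#' Final mark size is `baseSize * multiplier`. Data-driven domains are
#' recomputed per structure unless fixed in the channel spec.
#'
#' @param x a [BinTable].
#' @param config a [ViewConfig].
#' @return an [AttributeTable], row-aligned with `x`.
#' @examples
#' bt <- binTableFromCoordinates(matrix(rnorm(9), 3, 3), "chr1", 1e5)
#' cfg <- viewConfig(color = channelMapping("chrom", "categorical"))
#' resolveViewConfig(bt, cfg)
#' @export
resolveViewConfig <- function(x, config) {
  stopifnot(is(x, "BinTable"), is(config, "ViewConfig"))
  n <- nbins(x)
  rgba <- resolveColorChannel(x, config@color)
  mult <- resolveScaleChannel(x, config@scale)
  base <- if (identical(config@baseSize, "auto")) autoBaseSize(x)
          else as.numeric(config@baseSize)
  new("AttributeTable", rgba = rgba, size = base * mult,
      mark = rep(config@mark, n))
}

#' @rdname AttributeTable-class
#' @param x an `AttributeTable`.
#' @export
attrColors <- function(x) x@rgba

#' @rdname AttributeTable-class
#' @export
attrSizes <- function(x) x@size

#' @rdname AttributeTable-class
#' @export
attrMarks <- function(x) x@mark

setMethod("show", "AttributeTable", function(object) {
  cat(sprintf("AttributeTable: %d bin(s), %d distinct color(s), sizes [%.4g, %.4g]\n",
              length(object@size),
              nrow(unique(object@rgba)),
              if (length(object@size)) min(object@size) else NA,
              if (length(object@size)) max(object@size) else NA))
})
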