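#' Construct a scene
#'
#' @param structures list of [BinTable]s (or a single one).
#' @param configs list of [ViewConfig]s, recycled if one is given.
#' @return a [Scene].
#' @export
scene <- function(structures = list(), configs = list()) {
  if (is(structures, "BinTable")) structures <- list(structures)
  if (is(configs, "ViewConfig")) configs <- list(configs)
  if (length(configs) == 1L && length(structures) > 1L)
    configs <- rep(configs, length(structures))
  if (length(structures) != length(configs))
    stop("need one view config per structure", call. = FALSE)
  entries <- Map(function(s, c) list(structure = s, config = c),
                 structures, configs)
  new("Scene", entries = unname(entries))
}

#' @describeIn Scene-class append one structure/config pair.
#' @export
setMethod("addStructure", "Scene", function(x, structure, config) {
  initialize(x, entries = c(x@entries,
                            list(list(structure = structure, config = config))))
})

#' @rdname Scene-class
#' @export
sceneEntries <- function(x) x@entries

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d structure(s)\n", length(object@entries)))
  for (i in seq_along(object@entries))
    cat(sprintf("  [%d] %d bins, mark=%s\n", i,
                nbins(object@entries[[i]]$structure),
                object@entries[[i]]$config@mark))
})

setMethod("length", "Scene", function(x) length(x@entries))

# ---- unit geometry ---------------------------------------------------------

# icosahedron subdivided `subdiv` times and projected to the unit sphere;
# subdiv = 2 gives 162 vertices / 320 faces
icosphere <- function(subdiv = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    verts <- v
    midpoint <- function(a, b) {
      k <- edgeKey(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      verts <<- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
      mids[[k]] <- nrow(verts)
      nrow(verts)
    }
    newf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- newf
  }
  v <- v / sqrt(rowSums(v^2))
  list(vertices = v, faces = f)
}

unitCube <- function() {
  v <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))) / 2
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = -1/2
    c(5, 6, 8), c(5, 8, 7),   # z = +1/2
    c(1, 2, 6), c(1, 6, 5),   # y = -1/2
    c(3, 7, 8), c(3, 8, 4),   # y = +1/2
    c(1, 5, 7), c(1, 7, 3),   # x = -1/2
    c(2, 4, 8), c(2, 8, 6))   # x = +1/2
  list(vertices = v, faces = f)
}

# open 8-sided prism from p to q; ring vertices colored by nearest endpoint
linkPrism <- function(p, q, radius) {
  axis <- q - p
  len <- sqrt(sum(axis^2))
  if (len == 0) return(NULL)
  w <- axis / len
  u <- if (abs(w[3L]) < 0.9) c(-w[2L], w[1L], 0) else c(0, -w[3L], w[2L])
  u <- u / sqrt(sum(u^2))
  vv <- c(w[2L] * u[3L] - w[3L] * u[2L],
          w[3L] * u[1L] - w[1L] * u[3L],
          w[1L] * u[2L] - w[2L] * u[1L])
  ang <- (0:7) * pi / 4
  ring <- outer(cos(ang), u) + outer(sin(ang), vv)
  verts <- rbind(sweep(radius * ring, 2L, p, "+"),
                 sweep(radius * ring, 2L, q, "+"))
  i <- 1:8; j <- c(2:8, 1)
  faces <- rbind(cbind(i, j, j + 8L), cbind(i, j + 8L, i + 8L))
  list(vertices = verts, faces = faces)
}

.geomCache <- new.env(parent = emptyenv())

markGeometry <- function(mark) {
  if (is.null(.geomCache$geoms))
    .geomCache$geoms <- list(sphere = icosphere(2L), box = unitCube())
  .geomCache$geoms[[mark]]
}

emptyMesh <- function() {
  new("Mesh",
      vertices = matrix(numeric(), 0L, 3L),
      faces = matrix(integer(), 0L, 3L),
      vertexColors = matrix(integer(), 0L, 4L))
}

concatMeshParts <- function(vertList, faceList, colorList) {
  if (!length(vertList)) return(emptyMesh())
  nv <- vapply(vertList, nrow, integer(1))
  offset <- cumsum(c(0L, nv[-length(nv)]))
  faces <- do.call(rbind, Map(function(f, o) f + o, faceList, offset))
  new("Mesh",
      vertices = do.call(rbind, vertList),
      faces = matrix(as.integer(faces), ncol = 3L),
      vertexColors = do.call(rbind, colorList))
}

#' Merge meshes, reindexing faces
#' @param ... [Mesh] objects.
#' @return a single [Mesh].
#' @export
concatMeshes <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1L]]) && !is(ms[[1L]], "Mesh"))
    ms <- ms[[1L]]
  concatMeshParts(lapply(ms, function(m) m@vertices),
                  lapply(ms, function(m) m@faces),
                  lapply(ms, function(m) m@vertexColors))
}

#' Materialize a scene as a triangle mesh
#'
#' Resolves every structure/config pair and emits, per bin, a unit mark
#' — icosphere (2 subdivisions: 162 vertices, 320 faces) or axis-aligned
#' cube (8 vertices, 12 faces) — scaled by the resolved size, centered on
#' the bin's coordinates, with every vertex carrying the bin's RGBA.
#' `links = TRUE` adds thin 8-sided open prisms (16 vertices, 16 faces
#' each) between consecutive same-chromosome bins. Sub-meshes are
#' concatenated with reindexed faces, structures in scene order.
#'
#' @param x a [Scene] (or a single [BinTable] with a config).
#' @param config used when `x` is a [BinTable].
#' @return a [Mesh].
#' @export
buildMeshes <- function(x, config = viewConfig()) {
  if (is(x, "BinTable")) x <- scene(x, config)
  stopifnot(is(x, "Scene"))
  parts <- lapply(seq_along(x@entries), function(k) {
    e <- x@entries[[k]]
    attrs <- tryCatch(resolveViewConfig(e$structure, e$config),
                      error = function(err) stop(sprintf(
                        "scene entry %d: %s", k, conditionMessage(err)),
                        call. = FALSE))
    structureMesh(e$structure, e$config, attrs)
  })
  concatMeshes(parts)
}

structureMesh <- function(bt, config, attrs) {
  n <- nbins(bt)
  if (n == 0L) return(emptyMesh())
  geom <- markGeometry(config@mark)
  vPer <- nrow(geom$vertices)
  centers <- coords(bt)
  sizes <- attrSizes(attrs)
  # vertices: unit geometry scaled per bin, translated to bin center
  verts <- geom$vertices[rep(seq_len(vPer), n), , drop = FALSE] *
    sizes[rep(seq_len(n), each = vPer)] +
    centers[rep(seq_len(n), each = vPer), , drop = FALSE]
  offs <- (rep(seq_len(n), each = nrow(geom$faces)) - 1L) * vPer
  faces <- geom$faces[rep(seq_len(nrow(geom$faces)), n), , drop = FALSE] + offs
  colors <- attrColors(attrs)[rep(seq_len(n), each = vPer), , drop = FALSE]
  mesh <- new("Mesh", vertices = verts,
              faces = matrix(as.integer(faces), ncol = 3L),
              vertexColors = matrix(as.integer(colors), ncol = 4L))
  if (config@links && n > 1L) {
    same <- which(chroms(bt)[-1L] == chroms(bt)[-n])
    lv <- list(); lf <- list(); lc <- list()
    for (i in same) {
      pr <- linkPrism(centers[i, ], centers[i + 1L, ],
                      0.2 * min(sizes[i], sizes[i + 1L]))
      if (is.null(pr)) next
      lv[[length(lv) + 1L]] <- pr$vertices
      lf[[length(lf) + 1L]] <- pr$faces
      lc[[length(lc) + 1L]] <- rbind(
        matrix(rep(attrColors(attrs)[i, ], each = 8L), 8L, 4L),
        matrix(rep(attrColors(attrs)[i + 1L, ], each = 8L), 8L, 4L))
    }
    if (length(lv))
      mesh <- concatMeshes(list(mesh, concatMeshParts(lv, lf, lc)))
  }
  mesh
}

#' @rdname Mesh-class
#' @param x a `Mesh`.
#' @export
meshVertices <- function(x) x@vertices

#' @rdname Mesh-class
#' @export
meshFaces <- function(x) x@faces

#' @rdname Mesh-class
#' @export
meshColors <- function(x) x@vertexColors

setMethod("show", "Mesh", function(object) {
  cat(sprintf("Mesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

#' Write a mesh as PLY
#'
#' Per-vertex `uchar` RGBA (the most portable colored-PLY dialect);
#' `binary = FALSE` writes ascii (byte-identical across runs for fixed
#' input), `binary = TRUE` writes `binary_little_endian` 1.0.
#'
#' @param mesh a [Mesh].
#' @param path output path.
#' @param binary write binary little-endian instead of ascii.
#' @return invisibly, `path`.
#' @export
writePly <- function(mesh, path, binary = FALSE) {
  stopifnot(is(mesh, "Mesh"))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    "comment chromoscene mesh",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "property uchar alpha",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  if (!binary) {
    vlines <- sprintf("%s %s %s %d %d %d %d",
                      formatCoord(mesh@vertices[, 1L]),
                      formatCoord(mesh@vertices[, 2L]),
                      formatCoord(mesh@vertices[, 3L]),
                      mesh@vertexColors[, 1L], mesh@vertexColors[, 2L],
                      mesh@vertexColors[, 3L], mesh@vertexColors[, 4L])
    flines <- sprintf("3 %d %d %d", mesh@faces[, 1L] - 1L,
                      mesh@faces[, 2L] - 1L, mesh@faces[, 3L] - 1L)
    writeLines(c(header, if (nv) vlines, if (nf) flines), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh@vertices[i, ]), con, size = 4L,
               endian = "little")
      writeBin(as.raw(mesh@vertexColors[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh@faces[i, ] - 1L), con, size = 4L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Write a mesh as OBJ
#'
#' Positions and faces only: the OBJ core format cannot carry per-vertex
#' colors, so they are dropped (with a warning and a comment line in the
#' file); use [writePly()] when colors matter.
#'
#' @param mesh a [Mesh].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeObj <- function(mesh, path) {
  stopifnot(is(mesh, "Mesh"))
  warning("OBJ drops per-vertex colors; use writePly() to keep them",
          call. = FALSE)
  lines <- c("# chromoscene mesh",
             "# note: per-vertex colors are not representable in OBJ and were dropped",
             sprintf("v %s %s %s",
                     formatCoord(mesh@vertices[, 1L]),
                     formatCoord(mesh@vertices[, 2L]),
                     formatCoord(mesh@vertices[, 3L])),
             sprintf("f %d %d %d", mesh@faces[, 1L], mesh@faces[, 2L],
                     mesh@faces[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
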