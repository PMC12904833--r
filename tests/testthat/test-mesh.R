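oneBin <- function(col = "#ff0000", mark = "box") {
  bt <- binTableFromCoordinates(matrix(0, 1, 3), "chr1", 1e5)
  scene(bt, viewConfig(mark = mark, color = channelConstant(col), baseSize = 1))
}

test_that("per-mark vertex and face counts are exact", {
  box <- buildMeshes(oneBin(mark = "box"))
  expect_identical(dim(meshVertices(box)), c(8L, 3L))
  expect_identical(dim(meshFaces(box)), c(12L, 3L))
  expect_identical(nrow(unique(meshColors(box))), 1L)

  bt2 <- binTableFromCoordinates(matrix(rnorm(6), 2, 3), "chr1", 1e5)
  sph <- buildMeshes(scene(bt2, viewConfig(baseSize = 1)))
  expect_identical(nrow(meshVertices(sph)), 2L * 162L)
  expect_identical(nrow(meshFaces(sph)), 2L * 320L)
  # face index ranges of the two bins are disjoint
  expect_true(all(meshFaces(sph)[1:320, ] <= 162L))
  expect_true(all(meshFaces(sph)[321:640, ] > 162L))
})

test_that("scene meshes equal the concatenation of per-structure meshes", {
  s1 <- oneBin("#ff0000", "box")
  bt2 <- binTableFromCoordinates(matrix(1, 1, 3), "chr2", 1e5)
  cfg2 <- viewConfig(mark = "sphere", baseSize = 1)
  s2 <- scene(bt2, cfg2)
  combined <- buildMeshes(addStructure(s1, bt2, cfg2))
  manual <- concatMeshes(buildMeshes(s1), buildMeshes(s2))
  expect_identical(meshVertices(combined), meshVertices(manual))
  expect_identical(meshFaces(combined), meshFaces(manual))
  expect_identical(meshColors(combined), meshColors(manual))
})

test_that("links add 8-sided prisms between consecutive same-chromosome bins", {
  bt <- binTable(data.frame(chrom = c("chr1", "chr1", "chr2"),
                            start = c(0, 1e5, 0), end = c(1e5, 2e5, 1e5),
                            x = c(0, 1, 5), y = 0, z = 0))
  msh <- buildMeshes(scene(bt, viewConfig(mark = "box", baseSize = 0.5,
                                          links = TRUE)))
  # 3 boxes + 1 link (chr1-chr2 junction gets none)
  expect_identical(nrow(meshVertices(msh)), 3L * 8L + 16L)
  expect_identical(nrow(meshFaces(msh)), 3L * 12L + 16L)
})

test_that("meshes translate rigidly with the structure", {
  set.seed(5)
  m <- matrix(rnorm(15), 5, 3)
  bt <- binTableFromCoordinates(m, "chr1", 1e5)
  shifted <- binTableFromCoordinates(sweep(m, 2, c(1, -2, 3), "+"), "chr1", 1e5)
  cfg <- viewConfig(baseSize = 1)
  v1 <- meshVertices(buildMeshes(scene(bt, cfg)))
  v2 <- meshVertices(buildMeshes(scene(shifted, cfg)))
  expect_equal(sweep(v1, 2, c(1, -2, 3), "+"), v2)
})

test_that("mesh building surfaces resolution errors with the scene entry", {
  bt <- binTableFromCoordinates(matrix(0, 1, 3), "chr1", 1e5)
  bad <- viewConfig(color = channelMapping("absent"))
  expect_error(buildMeshes(scene(bt, bad)), "scene entry 1")
})

test_that("ascii PLY declares counts and round-trips via an independent parser", {
  msh <- buildMeshes(oneBin())
  f <- withr::local_tempfile(fileext = ".ply")
  writePly(msh, f)
  header <- readLines(f, n = 12)
  expect_true("element vertex 8" %in% header)
  expect_true("element face 12" %in% header)
  ply <- readAsciiPly(f)
  expect_identical(ply$nVertices, 8L)
  expect_identical(ply$nFaces, 12L)
  expect_equal(ply$vertices, unname(meshVertices(msh)), tolerance = 1e-5)
  expect_identical(ply$colors[1, ], c(255, 0, 0, 255))
  expect_true(all(ply$faces >= 0 & ply$faces <= 7))

  # byte-identical across runs
  f2 <- withr::local_tempfile(fileext = ".ply")
  writePly(buildMeshes(oneBin()), f2)
  expect_identical(readLines(f), readLines(f2))

  # empty scene -> valid empty PLY
  writePly(buildMeshes(scene()), f)
  expect_true("element vertex 0" %in% readLines(f))
})

test_that("trimesh (independent mesh library) reads our ascii and binary PLY", {
  msh <- buildMeshes(oneBin("#00ff00"))
  fa <- withr::local_tempfile(fileext = ".ply")
  fb <- withr::local_tempfile(fileext = ".ply")
  writePly(msh, fa, binary = FALSE)
  writePly(msh, fb, binary = TRUE)
  for (f in c(fa, fb)) {
    info <- trimeshInfo(f)
    expect_identical(info$nv, 8L)
    expect_identical(info$nf, 12L)
    expect_identical(info$first_color, c(0L, 255L, 0L, 255L))
  }
})

test_that("OBJ export writes positions and faces, warning about colors", {
  msh <- buildMeshes(oneBin())
  f <- withr::local_tempfile(fileext = ".obj")
  expect_warning(writeObj(msh, f), "colors")
  lines <- readLines(f)
  expect_identical(sum(startsWith(lines, "v ")), 8L)
  expect_identical(sum(startsWith(lines, "f ")), 12L)
})

test_that("static rendering paints marks with painter's-algorithm occlusion", {
  f <- withr::local_tempfile(fileext = ".png")
  renderStatic(oneBin("#ff0000", mark = "sphere"), viewDirection = c(0, 0, 1),
               imageSize = 101L, output = f)
  img <- png::readPNG(f)
  center <- img[51, 51, ]
  expect_equal(unname(center[1:3]), c(1, 0, 0))  # red at center

  # two bins along the view axis: nearer wins the center pixel
  bt <- binTable(data.frame(chrom = "chr1", start = c(0, 1e5),
                            end = c(1e5, 2e5), x = 0, y = 0, z = c(0, 5)))
  cfg <- viewConfig(color = channelMapping("z", range = "bluered"),
                    baseSize = 1)
  renderStatic(scene(bt, cfg), viewDirection = c(0, 0, -1),
               imageSize = 101L, output = f)
  img <- png::readPNG(f)
  # camera looks along -z: the z=5 bin (red, v max) is nearer
  expect_equal(unname(img[51, 51, 1:3]), c(1, 0, 0))

  renderStatic(scene(), output = f)
  img <- png::readPNG(f)
  expect_true(all(img == 1))  # background only
})
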