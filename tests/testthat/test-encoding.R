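chromColorConfig <- function()
  viewConfig(color = channelMapping("chrom", "categorical"), baseSize = 1)

test_that("config validation is fail-fast on unknown keys, marks and colormaps", {
  expect_true(isValid(validateViewConfig(list())))           # all defaults
  rep <- validateViewConfig(list(mark = "tetrahedron"))
  expect_false(isValid(rep))
  expect_match(rep@errors$message, "sphere, box")
  rep <- validateViewConfig(list(color = list(constant = "#fff", field = "v")))
  expect_false(isValid(rep))
  expect_match(rep@errors$message, "exactly one")
  expect_false(isValid(validateViewConfig(list(glow = TRUE))))
  expect_false(isValid(validateViewConfig(
    list(color = list(field = "v", range = "jet")))))
  expect_match(validateViewConfig(
    list(color = list(field = "v", range = "jet")))@errors$message,
    "viridis, bluered")
})

test_that("categorical chromosome coloring gives one color per chromosome", {
  bt <- makeTestGenome(c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                       resolution = 1e5, seed = 2)
  at <- resolveViewConfig(bt, chromColorConfig())
  cols <- attrColors(at)
  expect_identical(nrow(unique(cols)), 3L)
  for (cc in unique(chroms(bt)))
    expect_identical(nrow(unique(cols[chroms(bt) == cc, , drop = FALSE])), 1L)
})

test_that("categorical colors follow first-appearance order and cycle past 12", {
  pal <- categoricalPalette(c("b", "a", "c"))
  expect_identical(names(pal), c("b", "a", "c"))
  pal2 <- categoricalPalette(c("a", "b", "c"))
  expect_identical(pal[["b"]], pal2[["a"]])  # order drives assignment
  expect_warning(pal13 <- categoricalPalette(paste0("k", 1:13)), "12")
  expect_identical(pal13[[13]], pal13[[1]])
  expect_identical(categoricalPalette(c("x", "y")),
                   categoricalPalette(c("x", "y")))  # deterministic
})

test_that("normalizeValues clips, defaults the domain and handles degeneracy", {
  expect_equal(normalizeValues(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalizeValues(5, domain = c(0, 20)), 0.25)
  expect_equal(normalizeValues(30, domain = c(0, 20)), 1)
  expect_equal(normalizeValues(c(7, 7, 7)), c(0.5, 0.5, 0.5))
})

test_that("continuous colormaps hit their anchor endpoints and midpoints", {
  expect_identical(continuousColormap("bluered", 0)[1, ],
                   c(red = 0L, green = 0L, blue = 255L, alpha = 255L))
  expect_identical(continuousColormap("bluered", 1)[1, ],
                   c(red = 255L, green = 0L, blue = 0L, alpha = 255L))
  expect_identical(continuousColormap("bluered", 0.5)[1, ],
                   c(red = 128L, green = 0L, blue = 128L, alpha = 255L))
  v0 <- continuousColormap("viridis", 0)[1, 1:3]
  expect_identical(unname(v0), c(0x44L, 0x01L, 0x54L))  # first anchor #440154
  expect_error(continuousColormap("jet", 0.5), "viridis, bluered")
})

test_that("continuous channels map domain endpoints to the colormap ends", {
  bt <- binTable(cbind(as.data.frame(randomStructure(81, n = 50)@data),
                       v = seq(3, 17, length.out = 50)))
  cfg <- viewConfig(color = channelMapping("v", "continuous",
                                           range = "bluered"))
  cols <- attrColors(resolveViewConfig(bt, cfg))
  expect_identical(cols[1, ], continuousColormap("bluered", 0)[1, ])
  expect_identical(cols[50, ], continuousColormap("bluered", 1)[1, ])
  # monotone data -> monotone interpolation parameter (red increases)
  expect_true(all(diff(cols[, "red"]) >= 0))
})

test_that("constant channels broadcast and sizes multiply base size", {
  bt <- randomStructure(82, n = 10)
  cfg <- viewConfig(color = channelConstant("#ff0000"),
                    scale = channelConstant(2), baseSize = 1)
  at <- resolveViewConfig(bt, cfg)
  expect_true(all(attrColors(at)[, "red"] == 255L))
  expect_true(all(attrColors(at)[, "green"] == 0L))
  expect_identical(attrSizes(at), rep(2, 10))
  expect_identical(attrMarks(at), rep("sphere", 10))
  # 8-digit hex alpha
  at2 <- resolveViewConfig(bt, viewConfig(color = channelConstant("#00FF0080"),
                                          baseSize = 1))
  expect_identical(unique(attrColors(at2)[, "alpha"]), 128L)
})

test_that("scale channel ramps into its range; bad fields and types error", {
  bt <- binTable(cbind(as.data.frame(randomStructure(83, n = 5)@data),
                       v = c(0, 1, 2, 3, 4), lab = letters[1:5]))
  cfg <- viewConfig(scale = channelMapping("v", "continuous"), baseSize = 1)
  s <- attrSizes(resolveViewConfig(bt, cfg))
  expect_equal(range(s), c(0.25, 1.5))   # default multiplier range
  cfg <- viewConfig(scale = channelMapping("v", "continuous",
                                           range = c(1, 3)), baseSize = 2)
  expect_equal(range(attrSizes(resolveViewConfig(bt, cfg))), c(2, 6))

  expect_error(resolveViewConfig(bt, viewConfig(
    color = channelMapping("nope"))), "available columns")
  expect_error(resolveViewConfig(bt, viewConfig(
    color = channelMapping("lab", "continuous"))), "non-numeric")
  expect_warning(resolveViewConfig(
    binTable(cbind(as.data.frame(randomStructure(84, n = 3)@data), v = 7)),
    viewConfig(color = channelMapping("v"))), "zero-spread")
})

test_that("auto base size is half the median consecutive same-chromosome distance", {
  m <- matrix(c(0, 0, 0, 2, 0, 0, 4, 0, 0), ncol = 3, byrow = TRUE)
  bt <- binTableFromCoordinates(m, "chr1", 1e5)
  at <- resolveViewConfig(bt, viewConfig())
  expect_equal(unique(attrSizes(at)), 0.5 * 2)
})

test_that("resolution output length always equals bin count and is deterministic", {
  for (seed in 91:93) {
    bt <- randomStructure(seed, n = 50 + seed)
    at <- resolveViewConfig(bt, chromColorConfig())
    expect_identical(nrow(attrColors(at)), nbins(bt))
    expect_identical(length(attrSizes(at)), nbins(bt))
    at2 <- resolveViewConfig(bt, chromColorConfig())
    expect_identical(attrColors(at), attrColors(at2))
  }
})

test_that("color resolution ignores unrelated annotation columns", {
  bt <- randomStructure(94, n = 40)
  at <- resolveViewConfig(bt, chromColorConfig())
  bt2 <- binFeatures(bt, makeTestAnnotation(c(chr1 = 1e7), 10, seed = 9),
                     "count", "unrelated")
  expect_identical(attrColors(resolveViewConfig(bt2, chromColorConfig())),
                   attrColors(at))
})

test_that("masked resolution equals subset only for constant channels", {
  bt <- binTable(cbind(as.data.frame(randomStructure(95, n = 30)@data),
                       v = seq_len(30) * 1.0))
  mask <- rep(c(TRUE, FALSE), 15)
  constCfg <- viewConfig(color = channelConstant("#123456"), baseSize = 1)
  expect_identical(
    attrColors(resolveViewConfig(applyMask(bt, mask), constCfg)),
    attrColors(resolveViewConfig(bt, constCfg))[mask, , drop = FALSE])
  # data-driven default domain is recomputed on the subset: not equal
  dataCfg <- viewConfig(color = channelMapping("v", range = "bluered"),
                        baseSize = 1)
  expect_false(identical(
    attrColors(resolveViewConfig(applyMask(bt, mask), dataCfg)),
    attrColors(resolveViewConfig(bt, dataCfg))[mask, , drop = FALSE]))
  # ... unless the domain is pinned explicitly
  pinned <- viewConfig(color = channelMapping("v", domain = c(1, 30),
                                              range = "bluered"), baseSize = 1)
  expect_identical(
    attrColors(resolveViewConfig(applyMask(bt, mask), pinned)),
    attrColors(resolveViewConfig(bt, pinned))[mask, , drop = FALSE])
})

test_that("view configs round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    mark = "box",
    color = list(field = "gene_density", scale_type = "continuous",
                 range = "viridis"),
    scale = list(constant = 2),
    base_size = 0.8, links = TRUE), f, auto_unbox = TRUE)
  cfg <- readViewConfig(f)
  expect_identical(cfg@mark, "box")
  expect_identical(cfg@color$field, "gene_density")
  expect_identical(cfg@baseSize, 0.8)
  expect_true(cfg@links)
  jsonlite::write_json(list(mark = "cone"), f, auto_unbox = TRUE)
  expect_error(readViewConfig(f), "cone")
})
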