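threeBins <- function() binTableFromCoordinates(
  matrix(c(0, 0, -1, 0, 0, 0, 0, 0, 2), ncol = 3, byrow = TRUE), "chr1", 1e5)

test_that("range selection honors half-open boundaries", {
  bt <- threeBins()
  expect_identical(selectByRanges(bt, intervalTable("chr1", 150e3, 160e3)),
                   c(FALSE, TRUE, FALSE))
  # [0,100k) must not touch a query starting at 100k
  expect_identical(selectByRanges(bt, intervalTable("chr1", 100e3, 200e3)),
                   c(FALSE, TRUE, FALSE))
  # absent chromosome matches nothing
  expect_identical(selectByRanges(bt, intervalTable("chrX", 0, 1e9)),
                   rep(FALSE, 3))
})

test_that("contained mode requires bin inside query", {
  bt <- threeBins()
  expect_identical(
    selectByRanges(bt, intervalTable("chr1", 50e3, 250e3), mode = "contained"),
    c(FALSE, TRUE, FALSE))
  expect_identical(
    selectByRanges(bt, intervalTable("chr1", 0, 300e3), mode = "contained"),
    rep(TRUE, 3))
})

test_that("range selection matches the brute-force oracle on random instances", {
  for (seed in 1:10) {
    bt <- randomStructure(seed, n = 1000)
    q <- randomQuery(seed + 100, m = 50)
    expect_identical(selectByRanges(bt, q), bfRangeMask(bt, q, "any_overlap"))
    expect_identical(selectByRanges(bt, q, "contained"),
                     bfRangeMask(bt, q, "contained"))
  }
})

test_that("range selection is invariant under query permutation and splitting", {
  bt <- randomStructure(21, n = 500)
  q <- randomQuery(22, m = 30)
  qd <- intervalData(q)
  base <- selectByRanges(bt, q)
  set.seed(23)
  o <- sample(nrow(qd))
  permuted <- intervalTable(qd$chrom[o], qd$start[o], qd$end[o])
  expect_identical(selectByRanges(bt, permuted), base)
  # split every interval into two abutting halves
  mid <- floor((qd$start + qd$end) / 2)
  ok <- mid > qd$start & mid < qd$end
  split <- intervalTable(c(qd$chrom[ok], qd$chrom[ok], qd$chrom[!ok]),
                         c(qd$start[ok], mid[ok], qd$start[!ok]),
                         c(mid[ok], qd$end[ok], qd$end[!ok]))
  expect_identical(selectByRanges(bt, split), base)
})

test_that("plane cuts assign the boundary to the positive side and partition", {
  bt <- threeBins()  # z = -1, 0, 2
  expect_identical(cutByPlane(bt, plane(c(0, 0, 1), 0)), c(FALSE, TRUE, TRUE))
  # normalization invariance
  expect_identical(cutByPlane(bt, plane(c(0, 0, 2), 0)), c(FALSE, TRUE, TRUE))
  expect_error(plane(c(0, 0, 0), 0), "nonzero")

  for (seed in 1:20) {
    bt <- randomStructure(seed, n = 200)
    set.seed(seed + 500)
    pl <- plane(rnorm(3), rnorm(1))
    pos <- cutByPlane(bt, pl, "positive")
    neg <- cutByPlane(bt, pl, "negative")
    expect_true(all(pos | neg))
    expect_false(any(pos & neg))
    expect_identical(pos, bfPlaneMask(bt, pl@normal, pl@offset))
  }
})

test_that("sphere selection is boundary-inclusive and matches brute force", {
  bt <- binTableFromCoordinates(
    matrix(c(0.5, 0, 0, 1, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE),
    "chr1", 1e5)
  expect_identical(selectSphere(bt, c(0, 0, 0), 1), c(TRUE, TRUE, FALSE))
  expect_identical(selectSphere(bt, c(0, 0, 0), 100), rep(TRUE, 3))
  expect_error(selectSphere(bt, c(0, 0, 0), 0), "positive")

  for (seed in 1:10) {
    bt <- randomStructure(seed, n = 1000)
    set.seed(seed + 900)
    center <- rnorm(3); r <- runif(1, 0.5, 2)
    expect_identical(selectSphere(bt, center, r), bfSphereMask(bt, center, r))
  }
})

test_that("sphere selection is invariant under joint rigid rotation", {
  bt <- randomStructure(31, n = 300)
  set.seed(32)
  center <- rnorm(3); r <- 1.2
  theta <- runif(1, 0, 2 * pi)
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rotated <- binTable(cbind(
    data.frame(chrom = chroms(bt), start = binStarts(bt), end = binEnds(bt)),
    stats::setNames(as.data.frame(coords(bt) %*% t(R)), c("x", "y", "z"))))
  expect_identical(selectSphere(rotated, as.numeric(R %*% center), r),
                   selectSphere(bt, center, r))
})

test_that("locus-anchored spheres compose find-bin with select-sphere", {
  bt <- randomStructure(41, n = 500)
  # a locus at a bin's start always selects that bin
  i <- 137
  m <- selectSphereAroundLocus(bt, chroms(bt)[i], binStarts(bt)[i], 0.5)
  expect_true(m[i])
  expect_identical(m, selectSphere(bt, coords(bt)[i, ], 0.5))
  # pos == end belongs to the NEXT bin
  j <- which(chroms(bt) == chroms(bt)[i] & binStarts(bt) == binEnds(bt)[i])
  m2 <- selectSphereAroundLocus(bt, chroms(bt)[i], binEnds(bt)[i], 0.5)
  expect_identical(m2, selectSphere(bt, coords(bt)[j, ], 0.5))
  # uncovered and duplicated loci error
  expect_error(selectSphereAroundLocus(bt, "chrZ", 0, 1), "not covered")
  dup <- binTable(rbind(as.data.frame(bt@data), as.data.frame(bt@data[i, ])))
  expect_error(selectSphereAroundLocus(dup, chroms(bt)[i], binStarts(bt)[i], 1),
               "annotation")
})

test_that("applyMask materializes row subsets and composes", {
  bt <- randomStructure(51, n = 200)
  expect_identical(as.data.frame(applyMask(bt, rep(TRUE, 200))@data),
                   as.data.frame(bt@data))
  empty <- applyMask(bt, rep(FALSE, 200))
  expect_identical(nbins(empty), 0L)
  expect_identical(names(empty@data), names(bt@data))
  expect_error(applyMask(bt, TRUE), "length")

  set.seed(52)
  m <- runif(200) < 0.5
  sub <- applyMask(bt, m)
  m2 <- runif(nbins(sub)) < 0.5
  # restricted second mask == single combined mask on the original
  expanded <- logical(200); expanded[which(m)[m2]] <- TRUE
  expect_identical(as.data.frame(applyMask(sub, m2)@data),
                   as.data.frame(applyMask(bt, m & expanded)@data))
  # row-subset invariant: output rows appear in input order
  expect_identical(binStarts(sub), binStarts(bt)[m])
})

test_that("mask algebra obeys boolean laws", {
  set.seed(61)
  a <- runif(100) < 0.5; b <- runif(100) < 0.3
  expect_identical(combineMasks(a, combineMasks(a, op = "not_a"), "and"),
                   rep(FALSE, 100))
  expect_identical(combineMasks(a, combineMasks(a, op = "not_a"), "or"),
                   rep(TRUE, 100))
  # De Morgan
  expect_identical(combineMasks(combineMasks(a, b, "and"), op = "not_a"),
                   combineMasks(combineMasks(a, op = "not_a"),
                                combineMasks(b, op = "not_a"), "or"))
  expect_error(combineMasks(a, b[1:10], "and"), "mismatch")
})
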