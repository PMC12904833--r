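# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's GenomicRanges-backed code paths: plain double loops
# and arithmetic only, so they can arbitrate.

# random structure with several chromosomes, random coords, random widths
randomStructure <- function(seed, n = 500, nchrom = 3, resolution = 1e5) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", seq_len(nchrom)), n, replace = TRUE))
  idx <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  start <- (idx - 1) * resolution
  data.frame(chrom = chrom, start = start, end = start + resolution,
             x = rnorm(n), y = rnorm(n), z = rnorm(n),
             stringsAsFactors = FALSE) |> binTable()
}

randomQuery <- function(seed, m = 50, nchrom = 4, span = 5e7) {
  set.seed(seed)
  start <- floor(runif(m, 0, span))
  intervalTable(paste0("chr", sample(nchrom, m, replace = TRUE)),
                start, start + floor(runif(m, 1, 5e5)) + 1)
}

# O(n*m) half-open interval overlap, exact string chrom match
bfRangeMask <- function(bt, q, mode = "any_overlap") {
  qd <- intervalData(q)
  chrom <- chroms(bt); bs <- binStarts(bt); be <- binEnds(bt)
  n <- length(chrom)
  mask <- logical(n)
  for (i in seq_len(n)) {   # per bin, test every query interval directly
    same <- chrom[i] == qd$chrom
    hit <- if (mode == "any_overlap")
      same & bs[i] < qd$end & qd$start < be[i]
    else
      same & bs[i] >= qd$start & be[i] <= qd$end
    mask[i] <- any(hit)
  }
  mask
}

bfPlaneMask <- function(bt, normal, offset, keep = "positive") {
  nhat <- normal / sqrt(sum(normal^2))
  p <- coords(bt)
  s <- vapply(seq_len(nrow(p)),
              function(i) sum(p[i, ] * nhat) + offset, numeric(1))
  if (keep == "positive") s >= 0 else s < 0
}

bfSphereMask <- function(bt, center, radius) {
  p <- coords(bt)
  vapply(seq_len(nrow(p)),
         function(i) sqrt(sum((p[i, ] - center)^2)) <= radius, logical(1))
}

# count of features whose midpoint falls inside any bin (half-open)
bfMidpointCensus <- function(bt, feats) {
  fd <- intervalData(feats)
  chrom <- chroms(bt); bs <- binStarts(bt); be <- binEnds(bt)
  total <- 0L
  for (j in seq_len(nrow(fd))) {
    mid <- floor((fd$start[j] + fd$end[j]) / 2)
    hit <- any(chrom == fd$chrom[j] & bs <= mid & mid < be)
    total <- total + as.integer(hit)
  }
  total
}

# minimal independent ascii-PLY reader (not the package's writer inverted)
readAsciiPly <- function(path) {
  lines <- readLines(path)
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[endh + seq_len(nv)]
  fl <- lines[endh + nv + seq_len(nf)]
  vm <- if (nv) do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
        else matrix(numeric(), 0, 7)
  fm <- if (nf) do.call(rbind, lapply(strsplit(fl, " "), as.integer))
        else matrix(integer(), 0, 4)
  list(nVertices = nv, nFaces = nf,
       vertices = vm[, 1:3, drop = FALSE],
       colors = vm[, 4:7, drop = FALSE],
       faces = fm[, 2:4, drop = FALSE])
}

# read a PLY (ascii or binary) through Python trimesh, the independent
# mesh library; returns counts and colors
trimeshInfo <- function(path) {
  script <- sprintf("
import json, sys, trimesh
m = trimesh.load('%s', process=False)
cols = m.visual.vertex_colors
print(json.dumps({'nv': int(len(m.vertices)), 'nf': int(len(m.faces)),
                  'first_color': [int(c) for c in cols[0]] if len(cols) else None}))
", path)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  jsonlite::fromJSON(out[length(out)])
}

writeLinesCRLF <- function(lines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(lines, collapse = "\r\n"), "\r\n")), con)
}
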