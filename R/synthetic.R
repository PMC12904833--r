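# Seeded synthetic fixtures: every module is testable without downloads.
# Generators are pure functions of their parameters and seed (Mersenne-
# Twister + Inversion through withSeed, which never disturbs the caller's
# RNG state). Not a physical chromatin simulator — fixture engine only.

#' @importFrom stats rnorm runif rbeta
NULL

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

unitSphereDirections <- function(n) {
  m <- matrix(rnorm(3L * n), ncol = 3L)
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm < 1e-12
  if (any(zero)) { m[zero, ] <- rep(c(1, 0, 0), each = sum(zero)); nrm[zero] <- 1 }
  m / nrm
}

#' Ideal-chain random walk
#'
#' A freely jointed chain: \eqn{p_0} at the origin,
#' \eqn{p_{i+1} = p_i + b\,u_i} with \eqn{u_i} uniform on the unit
#' sphere. Obeys the ideal-chain law \eqn{\langle R^2 \rangle = N b^2}
#' for the mean squared end-to-end distance. Deterministic per seed.
#'
#' @param n number of beads (>= 1).
#' @param step bond length `b` (> 0), model units.
#' @param seed integer seed.
#' @return n x 3 numeric coordinate matrix.
#' @examples
#' dim(randomWalkChain(10, 1, seed = 0))
#' @export
randomWalkChain <- function(n, step = 1, seed = 0) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(step), step > 0)
  n <- as.integer(n)
  if (n == 1L) return(matrix(0, 1L, 3L))
  withSeed(seed, {
    steps <- step * unitSphereDirections(n - 1L)
    rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
  })
}

#' Confined self-avoiding chain
#'
#' A random walk with rejection: proposals outside the confinement
#' sphere (centered at the origin) or within `minSeparation` of any
#' prior bead are redrawn; when a bead exhausts its local proposals the
#' walk backtracks one step. After `maxAttempts` total failures the
#' generator errors, reporting the attempts used. Emulates a compact
#' chromosome-territory-like conformation.
#'
#' @param n beads.
#' @param step bond length (> 0).
#' @param confinementRadius sphere radius (> step).
#' @param minSeparation minimal pairwise bead distance (< step).
#' @param seed integer seed.
#' @param maxAttempts total rejected proposals tolerated.
#' @return n x 3 coordinate matrix; all points within
#'   `confinementRadius`, consecutive distances exactly `step`, pairwise
#'   distances >= `minSeparation`.
#' @export
confinedChain <- function(n, step = 1, confinementRadius = 10,
                          minSeparation = 0.3, seed = 0,
                          maxAttempts = 10000L) {
  stopifnot(n >= 1, step > 0)
  if (confinementRadius <= step)
    stop("confinementRadius must exceed step", call. = FALSE)
  if (minSeparation >= step)
    stop("minSeparation must be smaller than step", call. = FALSE)
  n <- as.integer(n)
  withSeed(seed, {
    pts <- matrix(NA_real_, n, 3L)
    pts[1L, ] <- 0
    i <- 2L
    failures <- 0L
    triesPerBead <- 50L
    while (i <= n) {
      placed <- FALSE
      for (t in seq_len(triesPerBead)) {
        cand <- pts[i - 1L, ] + step * unitSphereDirections(1L)[1L, ]
        prior <- pts[seq_len(i - 1L), , drop = FALSE]
        ok <- sqrt(sum(cand^2)) <= confinementRadius &&
          min(sqrt(rowSums((prior - rep(cand, each = i - 1L))^2))) >= minSeparation
        if (ok) { pts[i, ] <- cand; i <- i + 1L; placed <- TRUE; break }
        failures <- failures + 1L
        if (failures >= maxAttempts)
          stop(sprintf("confinedChain: infeasible parameters (%d rejected proposals at bead %d/%d)",
                       failures, i, n), call. = FALSE)
      }
      if (!placed) {
        if (i <= 2L)
          stop(sprintf("confinedChain: cannot place second bead (%d rejected proposals)",
                       failures), call. = FALSE)
        i <- i - 1L  # backtrack one step and retry
        pts[i, ] <- NA_real_
      }
    }
    pts
  })
}

normalizeChromSizes <- function(chromSizes) {
  if (is.list(chromSizes) && !is.data.frame(chromSizes) &&
      is.null(names(chromSizes)))
    chromSizes <- stats::setNames(
      vapply(chromSizes, function(p) as.numeric(p[[2L]]), numeric(1)),
      vapply(chromSizes, function(p) as.character(p[[1L]]), character(1)))
  sizes <- unlist(chromSizes)
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromSizes must be named (chromosome -> size in bp)", call. = FALSE)
  sizes
}

territoryConfinementRadius <- function(n, step) pmax(2 * step, 0.6 * step * sqrt(n))

#' Generate a synthetic multi-chromosome genome structure
#'
#' One confined chain per chromosome (`n = ceiling(size / resolution)`
#' beads), each territory centered on a distinct lattice offset with
#' neighboring offsets `territorySpacing` apart — a cartoon of
#' chromosome territories. Genomic coordinates tile `[0, size)` at the
#' given resolution, the last bin truncated to the chromosome size.
#' Internal chain parameters: bond length 1 model unit, confinement
#' radius `max(2, 0.6 * sqrt(n))`, minimal bead separation 0.3.
#'
#' @param chromSizes named numeric vector (or list of `(name, bp)`
#'   pairs): chromosome sizes in bp.
#' @param resolution bin width in bp.
#' @param territorySpacing distance between neighboring territory
#'   centers, model units; default 2.5 x the largest confinement radius.
#' @param seed integer seed.
#' @return a [BinTable] that passes [validateStructure()] cleanly.
#' @examples
#' makeTestGenome(c(chr1 = 1e6, chr2 = 5e5), resolution = 1e5, seed = 0)
#' @export
makeTestGenome <- function(chromSizes, resolution, territorySpacing = NULL,
                           seed = 0) {
  sizes <- normalizeChromSizes(chromSizes)
  stopifnot(resolution >= 1, all(sizes >= resolution))
  nPer <- ceiling(sizes / resolution)
  step <- 1
  radii <- territoryConfinementRadius(nPer, step)
  if (is.null(territorySpacing)) territorySpacing <- 2.5 * max(radii)
  k <- length(sizes)
  grid <- ceiling(k^(1 / 3))
  tabs <- lapply(seq_len(k), function(j) {
    chain <- confinedChain(nPer[j], step = step,
                           confinementRadius = radii[j],
                           minSeparation = 0.3 * step,
                           # one sub-seed per chromosome, stable per seed
                           seed = (seed * 1009L + j) %% .Machine$integer.max)
    off <- territorySpacing *
      c((j - 1L) %% grid, ((j - 1L) %/% grid) %% grid, (j - 1L) %/% grid^2)
    start <- (seq_len(nPer[j]) - 1) * resolution
    data.frame(chrom = names(sizes)[j], start = start,
               end = pmin(start + resolution, sizes[j]),
               x = chain[, 1L] + off[1L], y = chain[, 2L] + off[2L],
               z = chain[, 3L] + off[3L])
  })
  binTable(do.call(rbind, tabs))
}

#' Generate synthetic gene-like annotations
#'
#' Draws `nFeatures` intervals over the genome (chromosome chosen with
#' probability proportional to size). Start positions come from a
#' mixture: uniform with weight `1 - clustering`, and a Beta(2, 8)-skewed
#' position with weight `clustering`, so at `clustering = 1` features
#' pile up near the chromosome start (Beta(2, 8) mean 0.2). Lengths are
#' uniform in \[1 kb, 10 kb\], clipped to the chromosome. Every feature
#' gets a `name` and a value ~ U(0, 1), so all aggregation modes of
#' [binFeatures()] are exercisable.
#'
#' @param chromSizes as in [makeTestGenome()].
#' @param nFeatures number of features (>= 1).
#' @param clustering mixture weight in \[0, 1\].
#' @param seed integer seed.
#' @return an [IntervalTable] with `0 <= start < end <= size` everywhere.
#' @export
makeTestAnnotation <- function(chromSizes, nFeatures, clustering = 0,
                               seed = 0) {
  sizes <- normalizeChromSizes(chromSizes)
  stopifnot(nFeatures >= 1, clustering >= 0, clustering <= 1)
  nFeatures <- as.integer(nFeatures)
  withSeed(seed, {
    chromIdx <- sample.int(length(sizes), nFeatures, replace = TRUE,
                           prob = sizes / sum(sizes))
    len <- round(runif(nFeatures, 1e3, 1e4))
    size <- sizes[chromIdx]
    len <- pmin(len, size - 1)
    frac <- ifelse(runif(nFeatures) < clustering,
                   rbeta(nFeatures, 2, 8), runif(nFeatures))
    start <- floor(frac * (size - len))
    intervalTable(names(sizes)[chromIdx], start, pmin(start + len, size),
                  name = sprintf("feat%d", seq_len(nFeatures)),
                  value = runif(nFeatures))
  })
}
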