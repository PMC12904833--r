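#' Gene-density encoding demo pipeline
#'
#' End-to-end recipe: generate a seeded two-chromosome territory
#' structure and a strongly clustered synthetic gene annotation
#' (`clustering = 1`, so genes pile up near chromosome starts), aggregate
#' the genes into structure bins (`count` mode — any-overlap gene
#' density), and encode that density to both the color (viridis) and the
#' scale of the marks, so gene-rich regions pop visually. Writes the
#' resulting colored mesh as ascii PLY and a static PNG snapshot.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving both generators.
#' @param chromSizes named sizes in bp.
#' @param resolution bin width in bp.
#' @param nFeatures synthetic gene count.
#' @return invisible list: the annotated `table`, resolved `attrs`, the
#'   `config`, and paths `ply`/`png`.
#' @export
demoGeneDensity <- function(outDir = tempdir(), seed = 0,
                            chromSizes = c(chr1 = 2e6, chr2 = 1e6),
                            resolution = 1e5, nFeatures = 300) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bt <- makeTestGenome(chromSizes, resolution = resolution, seed = seed)
  genes <- makeTestAnnotation(chromSizes, nFeatures = nFeatures,
                              clustering = 1, seed = seed + 1)
  bt <- binFeatures(bt, genes, mode = "count", column = "gene_density")
  cfg <- viewConfig(
    mark = "sphere",
    color = channelMapping("gene_density", "continuous", range = "viridis"),
    scale = channelMapping("gene_density", "continuous"),
    links = TRUE)
  attrs <- resolveViewConfig(bt, cfg)
  plyPath <- file.path(outDir, "gene_density.ply")
  pngPath <- file.path(outDir, "gene_density.png")
  writePly(buildMeshes(scene(bt, cfg)), plyPath)
  renderStatic(scene(bt, cfg), viewDirection = c(1, 1, 1), imageSize = 400L,
               output = pngPath)
  invisible(list(table = bt, attrs = attrs, config = cfg,
                 ply = plyPath, png = pngPath))
}
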