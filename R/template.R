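#' Toy white-matter FA template and tract atlas
#'
#' Builds a deterministic phantom of the white-matter skeleton: a set of
#' box-shaped "tracts" with elevated baseline FA (0.40-0.56) on a low-FA
#' background (0.08), together with a matching 17-label tract atlas — one
#' midline corpus-callosum-like region plus 8 left/right tract pairs. The
#' geometry is expressed in grid fractions so any grid of edge length >= 16
#' hosts the same layout. Region placement keeps all tracts disjoint.
#'
#' Baseline FA inside tracts is well above the 0.2 analysis-mask threshold
#' and background is well below it, so with modest subject noise the
#' cohort-mean mask recovers the tract set.
#'
#' @param gridShape Integer length-3 grid dimensions (each >= 16).
#' @param voxelSize Voxel edge lengths in mm (default 2 mm isotropic).
#' @return A list with elements `fa` (3D baseline FA array), `atlas`
#'   (a [TractAtlas-class]) and `voxelSize`.
#' @examples
#' tmpl <- faTemplate(c(24, 24, 24))
#' sum(tmpl$fa > 0.2)
#' tmpl$atlas
#' @export
faTemplate <- function(gridShape = c(32L, 32L, 32L), voxelSize = c(2, 2, 2)) {
    gridShape <- as.integer(gridShape)
    if (length(gridShape) != 3L || any(gridShape < 16L))
        stop("gridShape must be 3 integers, each >= 16")
    band <- function(lo, hi, n) seq.int(max(1L, round(lo * n) + 1L),
                                        min(n, round(hi * n)))
    fa <- array(0.08, gridShape)
    labels <- array(0L, gridShape)
    fill <- function(xs, ys, zs, label, value) {
        labels[xs, ys, zs] <<- label
        fa[xs, ys, zs] <<- value
    }
    nx <- gridShape[1L]; ny <- gridShape[2L]; nz <- gridShape[3L]

    ## midline corpus-callosum-like slab, label 1
    fill(band(0.38, 0.62, nx), band(0.30, 0.70, ny), band(0.38, 0.56, nz),
         1L, 0.56)

    pairNames <- c("corticospinal_tract",
                   "superior_longitudinal_fasciculus",
                   "inferior_longitudinal_fasciculus",
                   "inferior_fronto_occipital_fasciculus",
                   "uncinate_fasciculus",
                   "cingulum_cingulate",
                   "cingulum_hippocampal",
                   "anterior_thalamic_radiation")
    yBands <- list(c(0.15, 0.40), c(0.60, 0.85))
    zBands <- list(c(0.10, 0.28), c(0.34, 0.52), c(0.58, 0.76),
                   c(0.80, 0.95))
    xL <- band(0.12, 0.31, nx)
    xR <- rev(nx + 1L - xL)           # mirror through the midsagittal plane
    k <- 0L
    for (yb in yBands) for (zb in zBands) {
        k <- k + 1L
        ys <- band(yb[1L], yb[2L], ny)
        zs <- band(zb[1L], zb[2L], nz)
        value <- 0.40 + 0.02 * (k - 1L)
        fill(xL, ys, zs, 2L * k, value)
        fill(xR, ys, zs, 2L * k + 1L, value)
    }

    ids <- c(1L, as.vector(rbind(2L * seq_len(8L), 2L * seq_len(8L) + 1L)))
    nms <- c("corpus_callosum",
             as.vector(rbind(paste0(pairNames, "_left"),
                             paste0(pairNames, "_right"))))
    lat <- c("midline", rep(c("left", "right"), 8L))
    names(nms) <- ids
    names(lat) <- ids
    atlas <- new("TractAtlas", labels = labels, tractNames = nms,
                 laterality = lat, voxelSize = as.numeric(voxelSize))
    list(fa = fa, atlas = atlas, voxelSize = as.numeric(voxelSize))
}

#' @rdname faTemplate
#' @export
toyTractAtlas <- function(gridShape = c(32L, 32L, 32L),
                          voxelSize = c(2, 2, 2)) {
    faTemplate(gridShape, voxelSize)$atlas
}
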