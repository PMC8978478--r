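## Cluster detection: maximal connected components of suprathreshold z
## voxels, separately for the two polarities. A "pothole" is a contiguous
## cluster with every voxel z < -threshold; a "molehill" the mirror cluster
## with every voxel z > +threshold.

.neighborOffsets <- function(connectivity) {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    off <- off[rowSums(off != 0L) > 0L, , drop = FALSE]
    d <- rowSums(abs(off))
    keep <- switch(as.character(connectivity),
        "6"  = d == 1L,
        "18" = d <= 2L,
        "26" = rep(TRUE, nrow(off)),
        stop("connectivity must be one of 6, 18, 26"))
    off[keep, , drop = FALSE]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first flood fill over a zero-padded copy of the grid, so
#' neighbor lookups are plain linear-index offsets with no boundary tests.
#' Components are numbered in order of their first voxel in column-major
#' scan order, which makes the labeling independent of any caller-side
#' voxel ordering.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26
#'   (faces+edges+corners).
#' @return Integer array of the same shape: 0 for background, 1..k for the
#'   k components.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE; m[4, 4, 4] <- TRUE
#' max(labelComponents(m, 6))
#' @export
labelComponents <- function(mask, connectivity = 26) {
    stopifnot(is.logical(mask), length(dim(mask)) == 3L)
    dm <- dim(mask)
    pd <- dm + 2L
    pm <- array(FALSE, pd)
    pm[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
    off <- .neighborOffsets(connectivity)
    delta <- off[, 1L] + off[, 2L] * pd[1L] +
        off[, 3L] * pd[1L] * pd[2L]
    lab <- array(0L, pd)
    seeds <- which(pm)
    cur <- 0L
    for (i in seeds) {
        if (lab[i] != 0L) next
        cur <- cur + 1L
        lab[i] <- cur
        frontier <- i
        while (length(frontier)) {
            nb <- unique(as.vector(outer(frontier, delta, `+`)))
            nb <- nb[pm[nb] & lab[nb] == 0L]
            lab[nb] <- cur
            frontier <- nb
        }
    }
    lab[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
}

.clusterRows <- function(z, exceed, polarity, voxelSize, connectivity,
                         subject) {
    lab <- labelComponents(exceed, connectivity)
    k <- max(lab)
    if (k == 0L)
        return(NULL)
    voxvol <- prod(voxelSize)
    idx <- which(lab > 0L)
    coords <- arrayInd(idx, dim(lab))
    comp <- lab[idx]
    ord <- order(comp)
    coords <- coords[ord, , drop = FALSE]
    idx <- idx[ord]
    comp <- comp[ord]
    split.at <- split(seq_along(comp), comp)
    rows <- lapply(split.at, function(ii) {
        vox <- coords[ii, , drop = FALSE]
        zz <- z[idx[ii]]
        data.frame(subject = subject, polarity = polarity,
                   nVoxels = nrow(vox), volumeMM3 = nrow(vox) * voxvol,
                   peakAbsZ = max(abs(zz)),
                   centroidX = mean(vox[, 1L]), centroidY = mean(vox[, 2L]),
                   centroidZ = mean(vox[, 3L]),
                   voxels = I(list(unname(vox))),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

.emptyClusterTable <- function() {
    data.frame(subject = character(), polarity = character(),
               nVoxels = integer(), volumeMM3 = numeric(),
               peakAbsZ = numeric(), centroidX = numeric(),
               centroidY = numeric(), centroidZ = numeric(),
               voxels = I(list()), stringsAsFactors = FALSE)
}

.orderClusters <- function(tab) {
    if (nrow(tab) == 0L)
        return(tab)
    ## descending volume; ties broken by the lexicographically smallest
    ## voxel coordinate so output files are deterministic
    minvox <- t(vapply(tab$voxels, function(v) {
        v[order(v[, 1L], v[, 2L], v[, 3L])[1L], ]
    }, numeric(3L)))
    ord <- order(-tab$volumeMM3, minvox[, 1L], minvox[, 2L], minvox[, 3L])
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    tab
}

#' Detect potholes and molehills in a z-map
#'
#' Finds maximal connected components of the two suprathreshold sets
#' \{z < -t\} (potholes) and \{z > +t\} (molehills), using strict
#' inequalities by default. Every suprathreshold voxel belongs to exactly
#' one cluster. `NA` voxels (off-mask) never exceed the threshold.
#'
#' @param z A [ZMapSet-class] (all subjects) or a 3D numeric array
#'   (a single z-map; give `voxelSize` then).
#' @param zThreshold Positive z cutoff (default 2).
#' @param connectivity Voxel adjacency: 6, 18 or 26 (default 26).
#' @param inclusive Use `>=`/`<=` instead of strict inequalities.
#' @param voxelSize Required when `z` is a bare array.
#' @param subject Subject id recorded when `z` is a bare array.
#' @param ... Passed through to methods.
#' @return A data.frame with one row per cluster: `subject`, `polarity`
#'   (`"pothole"`/`"molehill"`), `nVoxels`, `volumeMM3`, `peakAbsZ`,
#'   centroid coordinates and a `voxels` list-column of coordinate
#'   matrices. Rows are ordered by descending volume with coordinate
#'   tie-break, within subject.
#' @examples
#' z <- array(0, c(6, 6, 6)); z[2:3, 2:3, 2] <- -3
#' detectClusters(z, voxelSize = c(2, 2, 2))
#' @export
setGeneric("detectClusters",
    function(z, zThreshold = 2, connectivity = 26, inclusive = FALSE, ...)
        standardGeneric("detectClusters"))

#' @rdname detectClusters
#' @export
setMethod("detectClusters", "array",
    function(z, zThreshold = 2, connectivity = 26, inclusive = FALSE,
             voxelSize = NULL, subject = "subject") {
        stopifnot(length(dim(z)) == 3L, zThreshold > 0)
        if (is.null(voxelSize))
            stop("voxelSize (mm) is required for a bare z array")
        lo <- if (inclusive) z <= -zThreshold else z < -zThreshold
        hi <- if (inclusive) z >= zThreshold else z > zThreshold
        lo[is.na(lo)] <- FALSE
        hi[is.na(hi)] <- FALSE
        tab <- rbind(
            .clusterRows(z, lo, "pothole", voxelSize, connectivity, subject),
            .clusterRows(z, hi, "molehill", voxelSize, connectivity, subject))
        if (is.null(tab))
            tab <- .emptyClusterTable()
        .orderClusters(tab)
    })

#' @rdname detectClusters
#' @export
setMethod("detectClusters", "ZMapSet",
    function(z, zThreshold = 2, connectivity = 26, inclusive = FALSE) {
        tabs <- lapply(seq_len(nSubjects(z)), function(i) {
            detectClusters(z@data[, , , i, drop = TRUE],
                           zThreshold = zThreshold,
                           connectivity = connectivity,
                           inclusive = inclusive,
                           voxelSize = z@voxelSize,
                           subject = z@subjects[i])
        })
        out <- do.call(rbind, tabs)
        rownames(out) <- NULL
        out
    })

#' Filter clusters by minimum volume
#'
#' Retains clusters whose volume strictly exceeds the cutoff (matching the
#' "> 25 mm3" convention of the cluster-size profiles); order is preserved.
#'
#' @param clusters Cluster table from [detectClusters()].
#' @param minVolumeMM3 Volume cutoff in mm^3 (>= 0).
#' @param inclusive Use `>=` instead of strict `>`.
#' @return The filtered cluster table.
#' @export
filterByMinVolume <- function(clusters, minVolumeMM3, inclusive = FALSE) {
    stopifnot(minVolumeMM3 >= 0)
    keep <- if (inclusive) clusters$volumeMM3 >= minVolumeMM3
            else clusters$volumeMM3 > minVolumeMM3
    out <- clusters[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Pothole/molehill count profile across volume thresholds
#'
#' Counts, per polarity, the clusters whose volume strictly exceeds each of
#' an increasing ladder of volume thresholds (default 25, 50, 100 and 200
#' mm^3). Counts are non-increasing along the ladder.
#'
#' @param z A [ZMapSet-class] or 3D z array (see [detectClusters()]).
#' @param thresholds Strictly increasing volume thresholds in mm^3.
#' @param zThreshold,connectivity,inclusive,... As in [detectClusters()].
#' @return A data.frame with columns `subject`, `polarity`, `thresholdMM3`
#'   and `count` (one row per subject x polarity x threshold).
#' @export
countProfile <- function(z, thresholds = c(25, 50, 100, 200),
                         zThreshold = 2, connectivity = 26,
                         inclusive = FALSE, ...) {
    if (any(diff(thresholds) <= 0) || length(thresholds) < 1L)
        stop("thresholds must be strictly increasing")
    clusters <- detectClusters(z, zThreshold = zThreshold,
                               connectivity = connectivity,
                               inclusive = inclusive, ...)
    clusterCountProfile(clusters,
                        subjects = if (is(z, "ZMapSet")) subjectIds(z)
                                   else unique(clusters$subject),
                        thresholds = thresholds, inclusive = inclusive)
}

#' @rdname countProfile
#' @param clusters A cluster table from [detectClusters()].
#' @param subjects Subject ids to report (zero counts included).
#' @export
clusterCountProfile <- function(clusters,
                                subjects = unique(clusters$subject),
                                thresholds = c(25, 50, 100, 200),
                                inclusive = FALSE) {
    if (length(subjects) == 0L)
        subjects <- "subject"
    grid <- expand.grid(subject = subjects,
                        polarity = c("pothole", "molehill"),
                        thresholdMM3 = thresholds,
                        stringsAsFactors = FALSE)
    cmp <- if (inclusive) `>=` else `>`
    grid$count <- mapply(function(s, pol, thr) {
        sum(clusters$subject == s & clusters$polarity == pol &
            cmp(clusters$volumeMM3, thr))
    }, grid$subject, grid$polarity, grid$thresholdMM3)
    grid <- grid[order(match(grid$subject, subjects), grid$polarity,
                       grid$thresholdMM3), , drop = FALSE]
    rownames(grid) <- NULL
    grid
}
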