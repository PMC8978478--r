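#' @import methods
NULL

.checkVoxelSize <- function(vs) {
    if (length(vs) != 3L || !is.numeric(vs) || any(!is.finite(vs)) ||
        any(vs <= 0))
        return("voxelSize must be 3 positive finite numbers (mm)")
    NULL
}

#' Cohort of aligned fractional-anisotropy volumes
#'
#' An `FACohort` holds a cohort of 3D fractional-anisotropy (FA) scalar
#' volumes that share one geometry: identical grid shape and voxel
#' dimensions. FA is unitless and lies in \[0, 1\]. Volumes are stored as a
#' 4D array whose fourth dimension indexes subjects.
#'
#' @slot data 4D numeric array (x, y, z, subject) of FA values in \[0, 1\].
#' @slot voxelSize Numeric length-3, voxel edge lengths in mm.
#' @slot subjects Character vector of subject identifiers, one per volume.
#'
#' @seealso [faCohort()], [computeReference()], [cohortZMaps()]
#' @export
setClass("FACohort",
    representation(data = "array", voxelSize = "numeric",
                   subjects = "character"))

setValidity("FACohort", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L)
        return("data must be a 4D array (x, y, z, subject)")
    if (length(object@subjects) != d[4L])
        return(sprintf("found %d subject ids for %d volumes",
                       length(object@subjects), d[4L]))
    if (anyDuplicated(object@subjects))
        return("subject ids must be unique")
    msg <- .checkVoxelSize(object@voxelSize)
    if (!is.null(msg)) return(msg)
    rng <- range(object@data)
    if (anyNA(object@data) || rng[1L] < 0 || rng[2L] > 1)
        return("FA values must be finite and within [0, 1]")
    TRUE
})

#' Construct an FACohort
#'
#' @param data 4D numeric array (x, y, z, subject) of FA values.
#' @param voxelSize Voxel edge lengths in mm (length 3).
#' @param subjects Optional subject ids; defaults to `S001`, `S002`, ...
#' @return An [FACohort-class] object.
#' @examples
#' coh <- faCohort(array(0.5, c(4, 4, 4, 3)), voxelSize = c(2, 2, 2))
#' nSubjects(coh)
#' @export
faCohort <- function(data, voxelSize = c(2, 2, 2), subjects = NULL) {
    if (is.null(subjects))
        subjects <- sprintf("S%03d", seq_len(dim(data)[4L]))
    new("FACohort", data = data, voxelSize = as.numeric(voxelSize),
        subjects = as.character(subjects))
}

#' Voxel-wise cohort reference images
#'
#' Mean and sample-SD FA images computed across a reference cohort, one
#' value per voxel. These define the normative distribution that
#' per-subject z-maps are expressed against.
#'
#' @slot mean 3D array of voxel-wise mean FA.
#' @slot sd 3D array of voxel-wise sample SD (n - 1 denominator by default).
#' @slot nReference Number of subjects contributing to the reference.
#' @slot voxelSize Voxel edge lengths in mm.
#'
#' @seealso [computeReference()], [wmMask()], [zTransform()]
#' @export
setClass("FAReference",
    representation(mean = "array", sd = "array", nReference = "integer",
                   voxelSize = "numeric"))

setValidity("FAReference", function(object) {
    if (!identical(dim(object@mean), dim(object@sd)))
        return("mean and sd grids must share one shape")
    if (length(dim(object@mean)) != 3L)
        return("reference images must be 3D")
    if (any(object@sd < 0))
        return("sd must be non-negative everywhere")
    if (object@nReference < 2L)
        return("a reference needs at least 2 subjects")
    msg <- .checkVoxelSize(object@voxelSize)
    if (!is.null(msg)) return(msg)
    TRUE
})

#' Per-subject z-maps over a white-matter mask
#'
#' z-values (FA minus cohort mean, divided by cohort SD) for each subject,
#' defined only on the analysis mask; voxels outside the mask carry `NA`.
#'
#' @slot data 4D array (x, y, z, subject) of z-values, `NA` off mask.
#' @slot mask Logical 3D array: the white-matter analysis mask.
#' @slot voxelSize Voxel edge lengths in mm.
#' @slot subjects Subject identifiers.
#'
#' @seealso [cohortZMaps()], [detectClusters()], [countProfile()]
#' @export
setClass("ZMapSet",
    representation(data = "array", mask = "array", voxelSize = "numeric",
                   subjects = "character"))

setValidity("ZMapSet", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L)
        return("data must be a 4D array (x, y, z, subject)")
    if (!identical(dim(object@mask), d[1:3]))
        return("mask shape must match the z-map grid")
    if (!is.logical(object@mask))
        return("mask must be logical")
    if (length(object@subjects) != d[4L])
        return("one subject id per z-map required")
    msg <- .checkVoxelSize(object@voxelSize)
    if (!is.null(msg)) return(msg)
    on <- object@data[rep(object@mask, d[4L])]
    if (anyNA(on) || any(!is.finite(on)))
        return("z-values must be finite on the mask")
    off <- object@data[rep(!object@mask, d[4L])]
    if (length(off) && !all(is.na(off)))
        return("z-values must be NA off the mask")
    TRUE
})

#' Labeled white-matter tract atlas
#'
#' Integer tract labels on the cohort grid (0 = background), with a
#' label-to-name table and a laterality flag per tract used to decide which
#' association models receive a handedness covariate.
#'
#' @slot labels 3D integer array of tract labels, 0 for background.
#' @slot tractNames Character vector of tract names, names() are label ids.
#' @slot laterality Character vector over the same labels, each one of
#'   `"left"`, `"right"` or `"midline"`.
#' @slot voxelSize Voxel edge lengths in mm.
#'
#' @seealso [toyTractAtlas()], [assignCluster()], [tractCounts()]
#' @export
setClass("TractAtlas",
    representation(labels = "array", tractNames = "character",
                   laterality = "character", voxelSize = "numeric"))

setValidity("TractAtlas", function(object) {
    if (length(dim(object@labels)) != 3L)
        return("label grid must be 3D")
    used <- setdiff(unique(as.integer(object@labels)), 0L)
    if (!all(as.character(used) %in% names(object@tractNames)))
        return("every nonzero label must appear in tractNames")
    if (!identical(sort(names(object@tractNames)),
                   sort(names(object@laterality))))
        return("tractNames and laterality must cover the same labels")
    if (!all(object@laterality %in% c("left", "right", "midline")))
        return("laterality must be left, right or midline")
    msg <- .checkVoxelSize(object@voxelSize)
    if (!is.null(msg)) return(msg)
    TRUE
})

#' Per-subject polygenic scores
#'
#' Raw additive scores (sum over selected variants of dosage times effect
#' size) and, when standardization is on, the scaled version with mean 0 and
#' SD 1 over the analyzed subjects.
#'
#' @slot raw Named numeric vector of raw scores (names are subject ids).
#' @slot standardized Named numeric vector of standardized scores, or
#'   length-0 when standardization is off.
#' @slot nVariantsUsed Number of variants entering the score.
#' @slot pThreshold The inclusion threshold P_T applied to GWAS p-values.
#'
#' @seealso [computePRS()], [selectVariants()]
#' @export
setClass("PolygenicScores",
    representation(raw = "numeric", standardized = "numeric",
                   nVariantsUsed = "integer", pThreshold = "numeric"))

setValidity("PolygenicScores", function(object) {
    if (is.null(names(object@raw)))
        return("raw scores must be named by subject id")
    if (length(object@standardized) &&
        !identical(names(object@standardized), names(object@raw)))
        return("standardized scores must align with raw scores")
    if (length(object@standardized)) {
        if (abs(mean(object@standardized)) > 1e-10 ||
            abs(stats::sd(object@standardized) - 1) > 1e-10)
            return("standardized scores must have mean 0 and SD 1")
    }
    TRUE
})

## ---- generics ----

#' @rdname FACohort-class
#' @param x An object with a cohort geometry.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname FACohort-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FACohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname FACohort-class
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
#' @rdname FACohort-class
setMethod("voxelSize", "FACohort", function(x) x@voxelSize)
#' @export
#' @rdname FAReference-class
#' @param x An `FAReference`.
setMethod("voxelSize", "FAReference", function(x) x@voxelSize)
#' @export
#' @rdname ZMapSet-class
#' @param x A `ZMapSet`.
setMethod("voxelSize", "ZMapSet", function(x) x@voxelSize)
#' @export
#' @rdname TractAtlas-class
#' @param x A `TractAtlas`.
setMethod("voxelSize", "TractAtlas", function(x) x@voxelSize)

#' @export
#' @rdname FACohort-class
setMethod("subjectIds", "FACohort", function(x) x@subjects)
#' @export
#' @rdname ZMapSet-class
setMethod("subjectIds", "ZMapSet", function(x) x@subjects)

#' @export
#' @rdname FACohort-class
setMethod("nSubjects", "FACohort", function(x) dim(x@data)[4L])
#' @export
#' @rdname ZMapSet-class
setMethod("nSubjects", "ZMapSet", function(x) dim(x@data)[4L])

#' @export
#' @rdname FACohort-class
setMethod("gridShape", "FACohort", function(x) dim(x@data)[1:3])
#' @export
#' @rdname FAReference-class
setMethod("gridShape", "FAReference", function(x) dim(x@mean))
#' @export
#' @rdname ZMapSet-class
setMethod("gridShape", "ZMapSet", function(x) dim(x@data)[1:3])
#' @export
#' @rdname TractAtlas-class
setMethod("gridShape", "TractAtlas", function(x) dim(x@labels))

#' Extract the FA data array from a cohort
#' @param x An [FACohort-class].
#' @return The 4D FA array.
#' @export
faData <- function(x) {
    stopifnot(is(x, "FACohort"))
    x@data
}

#' Extract the z-value array or mask from a ZMapSet
#' @param x A [ZMapSet-class].
#' @return `zData`: the 4D z array; `maskArray`: the logical 3D mask.
#' @export
zData <- function(x) {
    stopifnot(is(x, "ZMapSet"))
    x@data
}

#' @rdname zData
#' @export
maskArray <- function(x) {
    stopifnot(is(x, "ZMapSet"))
    x@mask
}

#' Reference image accessors
#' @param x An [FAReference-class].
#' @return `refMean`/`refSD`: 3D arrays; `nReference`: integer.
#' @export
refMean <- function(x) {
    stopifnot(is(x, "FAReference"))
    x@mean
}

#' @rdname refMean
#' @export
refSD <- function(x) {
    stopifnot(is(x, "FAReference"))
    x@sd
}

#' @rdname refMean
#' @export
nReference <- function(x) {
    stopifnot(is(x, "FAReference"))
    x@nReference
}

#' Atlas accessors
#' @param x A [TractAtlas-class].
#' @return `atlasLabels`: the 3D integer label array; `tractNames` /
#'   `tractLaterality`: character vectors named by label id.
#' @export
atlasLabels <- function(x) {
    stopifnot(is(x, "TractAtlas"))
    x@labels
}

#' @rdname atlasLabels
#' @export
tractNames <- function(x) {
    stopifnot(is(x, "TractAtlas"))
    x@tractNames
}

#' @rdname atlasLabels
#' @export
tractLaterality <- function(x) {
    stopifnot(is(x, "TractAtlas"))
    x@laterality
}

#' Polygenic score accessors
#' @param x A [PolygenicScores-class].
#' @return `rawScores`/`scaledScores`: named numeric vectors (the latter is
#'   `NULL` when standardization was off); `nVariantsUsed`: integer.
#' @export
rawScores <- function(x) {
    stopifnot(is(x, "PolygenicScores"))
    x@raw
}

#' @rdname rawScores
#' @export
scaledScores <- function(x) {
    stopifnot(is(x, "PolygenicScores"))
    if (length(x@standardized)) x@standardized else NULL
}

#' @rdname rawScores
#' @export
nVariantsUsed <- function(x) {
    stopifnot(is(x, "PolygenicScores"))
    x@nVariantsUsed
}

## ---- show methods ----

setMethod("show", "FACohort", function(object) {
    d <- dim(object@data)
    cat(sprintf("FACohort: %d subjects on a %s grid, %s mm voxels\n",
                d[4L], paste(d[1:3], collapse = "x"),
                paste(object@voxelSize, collapse = "x")))
    cat(sprintf("  FA range: [%.3f, %.3f]\n",
                min(object@data), max(object@data)))
})

setMethod("show", "FAReference", function(object) {
    cat(sprintf("FAReference from %d subjects on a %s grid\n",
                object@nReference,
                paste(dim(object@mean), collapse = "x")))
    cat(sprintf("  mean FA range: [%.3f, %.3f]; voxels with mean > 0.2: %d\n",
                min(object@mean), max(object@mean),
                sum(object@mean > 0.2)))
})

setMethod("show", "ZMapSet", function(object) {
    cat(sprintf("ZMapSet: %d subjects, %d masked voxels of %s\n",
                dim(object@data)[4L], sum(object@mask),
                paste(dim(object@mask), collapse = "x")))
})

setMethod("show", "TractAtlas", function(object) {
    cat(sprintf("TractAtlas: %d tracts on a %s grid (%d labeled voxels)\n",
                length(object@tractNames),
                paste(dim(object@labels), collapse = "x"),
                sum(object@labels != 0L)))
    lat <- table(object@laterality)
    cat("  laterality:", paste(names(lat), lat, sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "PolygenicScores", function(object) {
    cat(sprintf("PolygenicScores: %d subjects, %d variants, P_T < %g\n",
                length(object@raw), object@nVariantsUsed,
                object@pThreshold))
    if (length(object@standardized))
        cat("  standardized (mean 0, SD 1)\n")
})
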