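## NIfTI and TSV I/O. Voxel dimensions always travel in the NIfTI header
## (pixdim); they are never assumed constant.

.writeNiftiArray <- function(arr, voxelSize, path) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- rep_len(voxelSize, length(dim(arr)))
    RNifti::writeNifti(im, path)
    invisible(path)
}

#' Write / read an FA cohort as a 4D NIfTI
#'
#' The cohort is stored as one 4D volume (x, y, z, subject) with voxel
#' dimensions in the header; subject ids are stored alongside in a
#' one-column TSV (`<path>.subjects.tsv`).
#'
#' @param cohort An [FACohort-class].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `writeFACohort`: the path, invisibly. `readFACohort`: an
#'   [FACohort-class].
#' @export
writeFACohort <- function(cohort, path) {
    stopifnot(is(cohort, "FACohort"))
    .writeNiftiArray(cohort@data, cohort@voxelSize, path)
    utils::write.table(data.frame(subject = cohort@subjects),
                       paste0(path, ".subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFACohort
#' @export
readFACohort <- function(path) {
    im <- RNifti::readNifti(path)
    vs <- RNifti::pixdim(im)[1:3]
    subjFile <- paste0(path, ".subjects.tsv")
    subjects <- if (file.exists(subjFile))
        utils::read.delim(subjFile)$subject
    else NULL
    faCohort(array(as.numeric(im), dim(im)), vs, subjects)
}

#' Write reference, mask or z-map volumes as NIfTI
#'
#' @param reference An [FAReference-class].
#' @param meanPath,sdPath Output paths for the two reference images.
#' @return Paths, invisibly.
#' @export
writeReference <- function(reference, meanPath, sdPath) {
    stopifnot(is(reference, "FAReference"))
    .writeNiftiArray(reference@mean, reference@voxelSize, meanPath)
    .writeNiftiArray(reference@sd, reference@voxelSize, sdPath)
    invisible(c(meanPath, sdPath))
}

#' @rdname writeReference
#' @param zmaps A [ZMapSet-class].
#' @param zPath,maskPath Output paths (z-maps as 4D, mask as 0/1 volume).
#' @export
writeZMaps <- function(zmaps, zPath, maskPath) {
    stopifnot(is(zmaps, "ZMapSet"))
    z <- zmaps@data
    z[is.na(z)] <- 0            # NIfTI has no NA; mask delimits validity
    .writeNiftiArray(z, zmaps@voxelSize, zPath)
    .writeNiftiArray(array(as.numeric(zmaps@mask), dim(zmaps@mask)),
                     zmaps@voxelSize, maskPath)
    utils::write.table(data.frame(subject = zmaps@subjects),
                       paste0(zPath, ".subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(zPath, maskPath))
}

#' @rdname writeReference
#' @export
readZMaps <- function(zPath, maskPath) {
    zim <- RNifti::readNifti(zPath)
    mim <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(mim) > 0.5, dim(mim))
    z <- array(as.numeric(zim), dim(zim))
    z[array(rep(!mask, dim(z)[4L]), dim(z))] <- NA_real_
    subjFile <- paste0(zPath, ".subjects.tsv")
    subjects <- if (file.exists(subjFile))
        utils::read.delim(subjFile)$subject
    else sprintf("S%03d", seq_len(dim(z)[4L]))
    new("ZMapSet", data = z, mask = mask,
        voxelSize = RNifti::pixdim(zim)[1:3],
        subjects = as.character(subjects))
}

#' Write / read a tract atlas (integer NIfTI + label table)
#'
#' @param atlas A [TractAtlas-class].
#' @param niftiPath Label-volume path.
#' @param tsvPath Label table path (columns `label`, `tract`,
#'   `laterality`).
#' @return Paths / a [TractAtlas-class].
#' @export
writeTractAtlas <- function(atlas, niftiPath, tsvPath) {
    stopifnot(is(atlas, "TractAtlas"))
    .writeNiftiArray(array(as.numeric(atlas@labels), dim(atlas@labels)),
                     atlas@voxelSize, niftiPath)
    ids <- as.integer(names(atlas@tractNames))
    utils::write.table(
        data.frame(label = ids, tract = unname(atlas@tractNames),
                   laterality = unname(atlas@laterality[
                       as.character(ids)])),
        tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(niftiPath, tsvPath))
}

#' @rdname writeTractAtlas
#' @export
readTractAtlas <- function(niftiPath, tsvPath) {
    im <- RNifti::readNifti(niftiPath)
    labels <- array(as.integer(round(as.numeric(im))), dim(im))
    tab <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
    nms <- tab$tract
    lat <- tab$laterality
    names(nms) <- tab$label
    names(lat) <- tab$label
    new("TractAtlas", labels = labels, tractNames = nms, laterality = lat,
        voxelSize = RNifti::pixdim(im)[1:3])
}

#' Plain TSV writers for pipeline tables
#'
#' Cluster tables drop the voxel-coordinate list-column; all other tables
#' are written as-is, tab-separated without quoting, so reruns with the
#' same seed are byte-identical.
#'
#' @param x The table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTableTSV <- function(x, path) {
    x <- as.data.frame(x)
    x$voxels <- NULL
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
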