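#' Construct a GMVolume
#'
#' @param data 3D numeric array of non-negative intensities.
#' @param affine 4x4 voxel-to-world transform (defaults to identity spacing).
#' @param subjectId Subject identifier.
#' @return A [GMVolume-class] object.
#' @examples
#' vol <- GMVolume(array(1, c(4, 4, 4)), diag(c(1.5, 1.5, 1.5, 1)))
#' voxelSize(vol)
#' @export
GMVolume <- function(data, affine = diag(4), subjectId = "subject") {
  storage.mode(data) <- "double"
  new("GMVolume", data = data, affine = affine, subjectId = subjectId)
}

#' Read a gray-matter volume from NIfTI
#'
#' Reads a 3D NIfTI-1/2 image (e.g. a modulated warped GM segment) and returns
#' it as a [GMVolume-class]. Negative intensities — which can arise from
#' interpolation ringing in resampled segmentations — are clipped to zero; the
#' number of clipped voxels is reported with a warning and attached as the
#' \code{"clipped"} attribute of the returned object's data.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param subjectId Subject identifier; defaults to the file stem.
#' @return A [GMVolume-class].
#' @section Errors: \code{chaosgm_missing_file} if the file does not exist,
#'   \code{chaosgm_non_3d} if the image is not 3-dimensional,
#'   \code{chaosgm_bad_affine} if the stored affine is singular.
#' @export
readGMVolume <- function(path, subjectId = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("chaosgm_missing_file", "error", "condition")))
  }
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop(errorCondition(sprintf("non-3D image (%d dimensions): %s",
                                length(dim(img)), path),
                        class = c("chaosgm_non_3d", "error", "condition")))
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  if (abs(det(affine)) < .Machine$double.eps^0.5) {
    stop(errorCondition(sprintf("non-invertible affine in %s", path),
                        class = c("chaosgm_bad_affine", "error", "condition")))
  }
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  nneg <- sum(arr < 0)
  if (nneg > 0) {
    warning(sprintf("clipped %d negative voxel(s) to 0 in %s", nneg, path))
    arr[arr < 0] <- 0
  }
  vol <- GMVolume(arr, affine, subjectId)
  attr(vol@data, "clipped") <- nneg
  vol
}

#' Write a volume to NIfTI
#'
#' Writes the data array and affine (as sform, code 2) so that a subsequent
#' [readGMVolume()] round-trips both exactly at double precision.
#'
#' @param vol A [GMVolume-class] or [LambdaMap-class].
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L) {
    stop(errorCondition(sprintf("cannot write to %s", dir),
                        class = c("chaosgm_unwritable", "error", "condition")))
  }
  arr <- volData(vol)
  attributes(arr) <- list(dim = dim(arr))
  img <- RNifti::asNifti(arr, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(volAffine(vol), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a covariate table
#'
#' Reads a delimited text table (CSV or TSV, sniffed from the header line)
#' with one row per subject. Required columns: \code{subject_id} and
#' \code{group}. Binary categorical covariates (\code{sex}, \code{alcohol},
#' or any non-numeric two-level column) are recoded as 0/1 indicators by the
#' alphabetical order of their levels (first level = 0), which makes the
#' encoding deterministic.
#'
#' @param path Path to the delimited file.
#' @return A data.frame with character \code{subject_id}, factor \code{group},
#'   and numeric covariate columns.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("chaosgm_missing_file", "error", "condition")))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in c("subject_id", "group")) {
    if (!col %in% names(tab)) {
      stop(errorCondition(sprintf("missing required column '%s'", col),
                          class = c("chaosgm_missing_column", "error", "condition")))
    }
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) {
    stop(errorCondition("duplicated subject_id",
                        class = c("chaosgm_duplicate_subject", "error", "condition")))
  }
  tab$group <- factor(tab$group)
  for (nm in setdiff(names(tab), c("subject_id", "group"))) {
    if (!is.numeric(tab[[nm]])) {
      lev <- sort(unique(as.character(tab[[nm]])))
      if (length(lev) > 2L) {
        stop(errorCondition(sprintf("covariate '%s' has >2 non-numeric levels", nm),
                            class = c("chaosgm_bad_covariate", "error", "condition")))
      }
      tab[[nm]] <- as.numeric(match(as.character(tab[[nm]]), lev) - 1L)
    }
  }
  tab
}
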