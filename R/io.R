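#' Write and read a phantom as NIfTI plus a JSON sidecar
#'
#' The image, ROI and ground-truth mask are written as three NIfTI
#' volumes; geometry (pixel spacing, slice thickness, gap), the landmark
#' table, the generation seed and the exact truth volume go into a JSON
#' sidecar, which is authoritative for geometry on re-import.
#'
#' @param phantom a [VATPhantom-class].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
writePhantomNIfTI <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- phantom@image
  pd <- c(st@pixelSpacing, st@pixelSpacing,
          st@sliceThickness + st@intersliceGap)
  RNifti::writeNifti(RNifti::asNifti(st@slices, pixdim = pd),
                     file.path(dir, "image.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom@roi * 1L, pixdim = pd),
                     file.path(dir, "roi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom@truthMask * 1L, pixdim = pd),
                     file.path(dir, "truth_mask.nii.gz"))
  meta <- list(
    pixelSpacingMm = st@pixelSpacing,
    sliceThicknessMm = st@sliceThickness,
    intersliceGapMm = st@intersliceGap,
    landmarks = as.list(phantom@landmarks),
    truthVolumeMl = phantom@truthVolumeMl,
    separabilityWarning = phantom@separabilityWarning,
    seed = phantom@spec$seed)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writePhantomNIfTI
#' @export
readPhantomNIfTI <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  img <- array(as.numeric(RNifti::readNifti(file.path(dir, "image.nii.gz"))),
               dim = dim(RNifti::readNifti(file.path(dir, "image.nii.gz"))))
  roi <- array(RNifti::readNifti(file.path(dir, "roi.nii.gz")) != 0,
               dim = dim(img))
  truth <- array(RNifti::readNifti(file.path(dir, "truth_mask.nii.gz")) != 0,
                 dim = dim(img))
  stack <- imageStack(img, meta$pixelSpacingMm, meta$sliceThicknessMm,
                      meta$intersliceGapMm)
  new("VATPhantom",
      image = stack, roi = roi, truthMask = truth,
      truthVolumeMl = meta$truthVolumeMl,
      landmarks = structure(as.integer(unlist(meta$landmarks)),
                            names = names(meta$landmarks)),
      separabilityWarning = isTRUE(meta$separabilityWarning),
      spec = list(seed = meta$seed))
}

#' Write and read a cohort table as CSV
#'
#' One row per subject, columns as in [generateCohort()]; the effective
#' slice thickness travels in a \code{# stCm:} comment header so the file
#' round-trips losslessly.
#'
#' @param cohort a cohort data frame.
#' @param path CSV file path.
#' @return \code{path} (write) / the cohort data frame with its
#'   \code{stCm} attribute (read).
#' @export
writeCohortCsv <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  st <- attr(cohort, "stCm")
  if (!is.null(st)) writeLines(sprintf("# stCm: %.17g", st), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  first <- readLines(path, n = 1L)
  st <- NULL
  if (startsWith(first, "# stCm:"))
    st <- as.numeric(sub("# stCm:", "", first))
  cohort <- utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (!is.null(st)) attr(cohort, "stCm") <- st
  cohort
}

#' Write a landmark table as JSON
#'
#' @param landmarks named integer vector of landmark slice indices.
#' @param path JSON file path.
#' @return \code{path}, invisibly / the landmark table as a named integer
#'   vector.
#' @export
writeLandmarksJson <- function(landmarks, path) {
  jsonlite::write_json(as.list(validateLandmarks(landmarks)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeLandmarksJson
#' @export
readLandmarksJson <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  validateLandmarks(structure(as.integer(unlist(lst)), names = names(lst)))
}

#' Write a sweep table as CSV
#'
#' @param rows sweep table from [landmarkSweep()].
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeSweepCsv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
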