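#' Write a volume as NIfTI-1
#'
#' @param vol 3D or 4D numeric array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, affine = diag(4)) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @return List with `data` (array) and `affine` (4x4 matrix).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Write a FreeSurfer-style ASCII colour lookup table
#'
#' Columns: id, name, R, G, B, A. Colours are generated deterministically
#' from the label id.
#'
#' @param lut Lookup-table data.frame (id, name, hemisphere, lobe).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_lut <- function(lut, path) {
  rgb <- t(vapply(lut$id, function(id) {
    c((37 * id) %% 256, (101 * id) %% 256, (173 * id) %% 256)
  }, numeric(3)))
  lines <- sprintf("%d %s_%s %d %d %d 0", lut$id,
                   ifelse(lut$hemisphere == "none", "ctx",
                          substr(lut$hemisphere, 1, 1)),
                   lut$name, rgb[, 1], rgb[, 2], rgb[, 3])
  writeLines(c("# id name R G B A", lines), path)
  invisible(path)
}

#' Write a phantom to disk
#'
#' Anatomy and label map as NIfTI-1, the lookup table as an ASCII colour
#' table, and (when given) the DSC series as 4D NIfTI with a JSON sidecar
#' carrying TR and TE.
#'
#' @param phantom A `label_phantom`.
#' @param dir Output directory.
#' @param dsc Optional `dsc_series`.
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir, dsc = NULL) {
  stopifnot(inherits(phantom, "label_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    write_volume(phantom$anatomy, file.path(dir, "anat.nii.gz"), phantom$affine),
    write_volume(phantom$labels$labels, file.path(dir, "labels.nii.gz"),
                 phantom$affine),
    write_lut(phantom$labels$lut, file.path(dir, "labels_lut.txt")))
  if (!is.null(dsc)) {
    files <- c(files,
               write_volume(dsc$signal, file.path(dir, "dsc.nii.gz"),
                            phantom$affine))
    sidecar <- file.path(dir, "dsc.json")
    writeLines(sprintf('{"tr": %.17g, "te": %.17g}', dsc$tr, dsc$te), sidecar)
    files <- c(files, sidecar)
  }
  invisible(files)
}

#' Write simulated ratings to CSV
#'
#' @param ratings Rating data.frame (subject_id, rater, level, region,
#'   category).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}
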