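#' Read a 3-D volume from a NIfTI-1 file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as one of `"scalar"` or `"label"`; label volumes must hold
#'   non-negative integers.
#' @param namespace namespace tag for label volumes.
#' @return A [scalar_volume()] or [label_volume()].
#' @export
read_volume <- function(path, as = c("scalar", "label"),
                        namespace = "final") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions in '%s'",
                 length(d), path))
  grid <- grid_from_nifti(img)
  arr <- array(as.vector(img), dim = d)
  if (as == "label") {
    if (any(!is.finite(arr)) || any(arr < 0) || any(arr != round(arr)))
      stop("file does not contain non-negative integer labels")
    label_volume(arr, grid, namespace = namespace)
  } else {
    scalar_volume(arr, grid)
  }
}

grid_from_nifti <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  d <- dim(img)[1:3]
  sp <- RNifti::pixdim(img)[1:3]
  volume_grid(d, sp, aff)
}

#' Write a volume to a NIfTI-1 file
#'
#' Scalar volumes are stored as 64-bit floats (lossless for R doubles);
#' label volumes as 32-bit integers.
#'
#' @param volume a [scalar_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "scalar_volume")) {
    arr <- volume$values
    dt <- "double"
  } else if (inherits(volume, "label_volume")) {
    arr <- volume$labels
    dt <- "int"
  } else stop("'volume' must be a scalar_volume or label_volume")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$grid$spacing
  aff <- structure(volume$grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a diffusion series with FSL-style bval/bvec files
#'
#' `bval` holds whitespace-separated b-values on one line; `bvec` holds three
#' rows (x, y, z) of gradient components, or the 3-column transpose (detected
#' from the shape). Gradient rows of zeros are accepted on baseline volumes.
#'
#' @param image_path 4-D NIfTI-1 file.
#' @param bval_path,bvec_path FSL-dialect gradient text files.
#' @param b0_threshold baseline b-value cutoff (s/mm^2).
#' @return A [dwi_series()].
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, b0_threshold = 50) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D diffusion series in '%s'", image_path))
  grid <- grid_from_nifti(img)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) bv <- t(bv)
  if (ncol(bv) != 3L && nrow(bv) == 3L) bv <- t(bv)
  if (ncol(bv) != 3L)
    stop("bvec file must have 3 rows or 3 columns")
  dimnames(bv) <- NULL
  dwi_series(array(as.vector(img), dim = d), grid, bvals, bv,
             b0_threshold = b0_threshold)
}

#' Write a diffusion series with FSL-style bval/bvec files
#'
#' @param dwi a [dwi_series()].
#' @param image_path output NIfTI-1 path.
#' @param bval_path,bvec_path output gradient text paths; default to
#'   `image_path` with `.bval`/`.bvec` extensions.
#' @return `image_path`, invisibly.
#' @export
write_dwi <- function(dwi, image_path,
                      bval_path = sub("\\.nii(\\.gz)?$", ".bval", image_path),
                      bvec_path = sub("\\.nii(\\.gz)?$", ".bvec", image_path)) {
  stopifnot(inherits(dwi, "dwi_series"))
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- dwi$grid$spacing
  aff <- structure(dwi$grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, image_path, datatype = "double")
  writeLines(paste(format(dwi$bvals, trim = TRUE), collapse = " "), bval_path)
  bv <- t(dwi$bvecs)   # three rows: x, y, z
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(image_path)
}
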