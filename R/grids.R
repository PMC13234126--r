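#' Volume grid geometry
#'
#' A `volume_grid` describes the sampling lattice of a 3-D volume: its shape
#' (voxels per axis), voxel spacing in mm, the 4x4 affine mapping 0-based
#' voxel indices to world coordinates (mm, at voxel centers, NIfTI
#' convention), and a three-letter orientation code giving the anatomical
#' direction of increasing index along each axis (e.g. `"LIA"`).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm.
#'   Defaults to 1 mm isotropic.
#' @param affine 4x4 voxel-to-world matrix. If `NULL`, a diagonal affine is
#'   built from `spacing` with the volume centered at the world origin.
#' @param orientation optional three-letter code; derived from the affine
#'   when omitted.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL,
                        orientation = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    # center the lattice on the world origin
    affine[1:3, 4] <- -spacing * (shape - 1L) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("'affine' must be invertible")
  derived <- orientation_code(affine)
  if (is.null(orientation)) {
    orientation <- derived
  } else if (!identical(toupper(orientation), derived)) {
    warning(sprintf("stated orientation '%s' disagrees with affine axes ('%s')",
                    orientation, derived))
  }
  structure(list(shape = shape, spacing = spacing, affine = affine,
                 orientation = toupper(orientation)),
            class = "volume_grid")
}

#' Derive the orientation code of an affine
#'
#' Each voxel axis is assigned the anatomical letter of the world axis it is
#' most aligned with, following NIfTI world conventions (+x = Right,
#' +y = Anterior, +z = Superior). The letter names the direction of
#' *increasing* voxel index.
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return A three-letter string such as `"RAS"` or `"LIA"`.
#' @export
orientation_code <- function(affine) {
  m <- affine[1:3, 1:3]
  pos <- c("R", "A", "S")
  neg <- c("L", "P", "I")
  letters3 <- character(3)
  for (j in 1:3) {
    ax <- which.max(abs(m[, j]))
    letters3[j] <- if (m[ax, j] >= 0) pos[ax] else neg[ax]
  }
  paste(letters3, collapse = "")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, spacing %s mm, orientation %s\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf("%s @ %s mm (%s)", paste(x$shape, collapse = "x"),
          paste(format(x$spacing, digits = 4), collapse = "x"), x$orientation)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Scalar volume
#'
#' A real-valued 3-D lattice tied to a [volume_grid()]. All values must be
#' finite.
#'
#' @param values numeric 3-D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param name optional map name (e.g. `"F"` for fractional anisotropy).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, name = NULL) {
  if (!inherits(grid, "volume_grid")) stop("'grid' must be a volume_grid")
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop("lattice shape does not match grid shape")
  if (any(!is.finite(values)))
    stop("scalar volume contains non-finite values")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, name = name),
            class = "scalar_volume")
}

#' Label volume
#'
#' A non-negative integer 3-D lattice tied to a [volume_grid()]. Zero is
#' reserved for background. The `namespace` tag records which label space the
#' integers live in: the 7-group coarse space, a per-group fine space, the
#' final 101-label space, or an external lookup-table space.
#'
#' @param labels integer 3-D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param namespace one of `"coarse"`, `"fine"`, `"final"`, `"lut"`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid,
                         namespace = c("final", "coarse", "fine", "lut")) {
  namespace <- match.arg(namespace)
  if (!inherits(grid, "volume_grid")) stop("'grid' must be a volume_grid")
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L || !all(dim(labels) == grid$shape))
    stop("lattice shape does not match grid shape")
  if (any(!is.finite(labels))) stop("label volume contains non-finite values")
  if (any(labels < 0)) stop("labels must be non-negative (0 = background)")
  if (any(labels != round(labels))) stop("labels must be integer-valued")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid, namespace = namespace),
            class = "label_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume%s: %s, range [%g, %g]\n",
              if (is.null(x$name)) "" else sprintf(" '%s'", x$name),
              format(x$grid), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("label_volume [%s]: %s, %d non-background label%s\n",
              x$namespace, format(x$grid), length(ids),
              if (length(ids) == 1L) "" else "s"))
  invisible(x)
}

#' Diffusion-weighted image series
#'
#' A 4-D diffusion signal with one b-value and one gradient direction per
#' volume. At least one baseline (b close to zero) and six diffusion-weighted
#' volumes are required so the six unique tensor components (plus the
#' baseline signal) are identifiable. Gradient vectors must be unit-norm
#' wherever b exceeds the baseline threshold.
#'
#' @param signal non-negative 4-D array `(x, y, z, volume)`.
#' @param grid a [volume_grid()] for the spatial axes.
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3-column matrix of gradient directions, one row per volume.
#' @param b0_threshold b-values at or below this count as baseline
#'   (default 50 s/mm^2).
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, grid, bvals, bvecs, b0_threshold = 50) {
  if (!inherits(grid, "volume_grid")) stop("'grid' must be a volume_grid")
  signal <- as.array(signal)
  d <- dim(signal)
  if (length(d) != 4L) stop("'signal' must be a 4-D array (x, y, z, volume)")
  if (!all(d[1:3] == grid$shape)) stop("spatial shape does not match grid")
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("'bvecs' must have 3 columns")
  if (length(bvals) != d[4] || nrow(bvecs) != d[4])
    stop(sprintf("volume count mismatch: %d volumes, %d b-values, %d b-vectors",
                 d[4], length(bvals), nrow(bvecs)))
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signal must be finite and non-negative")
  weighted <- bvals > b0_threshold
  if (!any(!weighted))
    stop("no baseline (b ~ 0) volume present")
  if (sum(weighted) < 6L)
    stop("insufficient directions: >= 6 diffusion-weighted volumes required")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[weighted] - 1) > 1e-3))
    stop("b-vectors must be unit-norm where b > 0 (tolerance 1e-3)")
  structure(list(signal = signal, grid = grid, bvals = bvals, bvecs = bvecs,
                 b0_threshold = b0_threshold),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  nb0 <- sum(x$bvals <= x$b0_threshold)
  cat(sprintf("dwi_series: %s, %d volumes (%d baseline, %d weighted), b up to %g s/mm^2\n",
              format(x$grid), length(x$bvals), nb0, length(x$bvals) - nb0,
              max(x$bvals)))
  invisible(x)
}
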