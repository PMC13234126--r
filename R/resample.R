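#' Resample a volume onto a target grid
#'
#' Maps every target voxel center through the two affines into source voxel
#' coordinates and interpolates. Label volumes always use nearest-neighbor
#' sampling; scalar volumes may use nearest or trilinear interpolation.
#' Target voxels falling outside the source extent are filled with
#' background (0).
#'
#' @param volume a [scalar_volume()] or [label_volume()].
#' @param target a [volume_grid()].
#' @param mode `"nearest"` or `"trilinear"`. Trilinear is rejected for label
#'   volumes.
#' @return A volume of the same class on `target`.
#' @export
resample <- function(volume, target, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  if (!inherits(target, "volume_grid")) stop("'target' must be a volume_grid")
  is_label <- inherits(volume, "label_volume")
  if (is_label && mode == "trilinear")
    stop("trilinear interpolation is not defined for label volumes")
  if (!is_label && !inherits(volume, "scalar_volume"))
    stop("'volume' must be a scalar_volume or label_volume")
  src <- if (is_label) volume$labels else volume$values
  if (grids_equal(volume$grid, target)) {
    out <- src
  } else {
    M <- solve(volume$grid$affine) %*% target$affine
    out <- map_lattice(src, volume$grid$shape, target$shape, M, mode)
  }
  if (is_label) {
    label_volume(out, target, namespace = volume$namespace)
  } else {
    scalar_volume(out, target, name = volume$name)
  }
}

# Pull-back interpolation: 'M' maps 0-based target voxel indices to 0-based
# source voxel indices. Works one target slice at a time to bound memory.
map_lattice <- function(src, sshape, tshape, M, mode) {
  nx <- tshape[1]; ny <- tshape[2]; nz <- tshape[3]
  sx <- sshape[1]; sy <- sshape[2]; sz <- sshape[3]
  out <- array(0, dim = tshape)
  i <- rep(seq_len(nx) - 1, times = ny)
  j <- rep(seq_len(ny) - 1, each = nx)
  base_x <- M[1, 1] * i + M[1, 2] * j + M[1, 4]
  base_y <- M[2, 1] * i + M[2, 2] * j + M[2, 4]
  base_z <- M[3, 1] * i + M[3, 2] * j + M[3, 4]
  for (k in seq_len(nz) - 1) {
    xs <- base_x + M[1, 3] * k
    ys <- base_y + M[2, 3] * k
    zs <- base_z + M[3, 3] * k
    if (mode == "nearest") {
      xi <- round(xs); yi <- round(ys); zi <- round(zs)
      ok <- xi >= 0 & xi < sx & yi >= 0 & yi < sy & zi >= 0 & zi < sz
      vals <- numeric(length(xs))
      if (any(ok)) {
        lin <- xi[ok] + sx * (yi[ok] + sy * zi[ok]) + 1
        vals[ok] <- src[lin]
      }
    } else {
      x0 <- floor(xs); y0 <- floor(ys); z0 <- floor(zs)
      fx <- xs - x0; fy <- ys - y0; fz <- zs - z0
      vals <- numeric(length(xs))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
        w <- (if (dx) fx else 1 - fx) *
             (if (dy) fy else 1 - fy) *
             (if (dz) fz else 1 - fz)
        ok <- xi >= 0 & xi < sx & yi >= 0 & yi < sy & zi >= 0 & zi < sz & w > 0
        if (any(ok)) {
          lin <- xi[ok] + sx * (yi[ok] + sy * zi[ok]) + 1
          vals[ok] <- vals[ok] + w[ok] * src[lin]
        }
      }
    }
    out[, , k + 1] <- vals
  }
  out
}

#' Conform a volume to an isotropic reference grid
#'
#' Resamples onto a cubic, isotropic, fixed-orientation grid centered on the
#' input volume's world center. The defaults (1 mm spacing, 256 voxels per
#' edge, LIA orientation) follow the FreeSurfer-style conformed space used
#' for whole-brain processing; smaller cubes are supported for phantoms and
#' testing. An input already on the requested grid is returned unchanged.
#'
#' @param volume a [scalar_volume()] or [label_volume()].
#' @param size cube edge in voxels (default 256).
#' @param spacing isotropic voxel size in mm (default 1).
#' @param orientation three-letter code for the conformed axes (default
#'   `"LIA"`).
#' @param mode interpolation mode; labels always use nearest. Default:
#'   trilinear for scalar volumes, nearest for labels.
#' @return A volume of the same class on the conformed grid.
#' @export
conform <- function(volume, size = 256, spacing = 1, orientation = "LIA",
                    mode = NULL) {
  target <- conformed_grid(volume$grid, size = size, spacing = spacing,
                           orientation = orientation)
  if (grids_equal(volume$grid, target)) return(volume)
  if (is.null(mode))
    mode <- if (inherits(volume, "label_volume")) "nearest" else "trilinear"
  resample(volume, target, mode = mode)
}

#' Build a conformed grid centered on a reference grid's world center
#'
#' @param reference a [volume_grid()] whose world center the conformed cube
#'   is centered on.
#' @inheritParams conform
#' @return A [volume_grid()].
#' @export
conformed_grid <- function(reference, size = 256, spacing = 1,
                           orientation = "LIA") {
  size <- as.integer(size)
  stopifnot(size >= 1L, spacing > 0)
  dirs <- orientation_axes(orientation)
  M <- dirs * spacing
  cw <- (reference$affine %*% c((reference$shape - 1) / 2, 1))[1:3]
  affine <- diag(4)
  affine[1:3, 1:3] <- M
  affine[1:3, 4] <- cw - M %*% rep((size - 1) / 2, 3)
  volume_grid(rep(size, 3), rep(spacing, 3), affine)
}

orientation_axes <- function(code) {
  code <- toupper(code)
  if (nchar(code) != 3L) stop("orientation code must have 3 letters")
  dir1 <- list(R = c(1, 0, 0), L = c(-1, 0, 0),
               A = c(0, 1, 0), P = c(0, -1, 0),
               S = c(0, 0, 1), I = c(0, 0, -1))
  cols <- lapply(strsplit(code, "")[[1]], function(ch) {
    if (is.null(dir1[[ch]])) stop(sprintf("unknown orientation letter '%s'", ch))
    dir1[[ch]]
  })
  M <- do.call(cbind, cols)
  if (abs(det(M)) < 0.5)
    stop(sprintf("orientation '%s' does not span three distinct axes", code))
  M
}
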