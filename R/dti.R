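#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, solves `ln S_i = ln S0 - b_i g_i' D g_i` for the six unique
#' tensor components and the baseline signal `S0` by ordinary least squares
#' over all volumes (baselines included as rows with b = 0 weighting).
#' Voxels with any non-positive signal, or outside the optional mask, are
#' flagged invalid and get zero components.
#'
#' @param dwi a [dwi_series()].
#' @param mask optional [label_volume()]; voxels with label 0 are skipped.
#' @return A `tensor_volume`: per-voxel components
#'   `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)` in mm^2/s, the `s0` estimate, and a
#'   `valid_mask`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_series"))
  if (length(dwi$bvals) < 7L)
    stop("tensor fit requires >= 7 volumes (baseline + 6 directions)")
  b <- dwi$bvals
  g <- dwi$bvecs
  # design for ln S = ln S0 - b g'Dg, components (xx, xy, xz, yy, yz, zz)
  X <- cbind(1,
             -b * g[, 1]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -b * g[, 2]^2,
             -2 * b * g[, 2] * g[, 3],
             -b * g[, 3]^2)
  nvol <- length(b)
  nvox <- prod(dwi$grid$shape)
  sig <- matrix(dwi$signal, nrow = nvox, ncol = nvol)
  valid <- rowSums(sig <= 0) == 0L
  if (!is.null(mask)) {
    if (!all(mask$grid$shape == dwi$grid$shape))
      stop("mask grid does not match DWI grid")
    valid <- valid & (as.vector(mask$labels) > 0L)
  }
  comp <- matrix(0, nrow = nvox, ncol = 6)
  s0 <- numeric(nvox)
  if (any(valid)) {
    qrX <- qr(X)
    if (qrX$rank < 7L)
      stop("insufficient directions: gradient scheme does not determine all 6 tensor components")
    beta <- qr.coef(qrX, t(log(sig[valid, , drop = FALSE])))
    s0[valid] <- exp(beta[1, ])
    comp[valid, ] <- t(beta[2:7, , drop = FALSE])
  }
  structure(list(grid = dwi$grid,
                 components = comp,
                 s0 = array(s0, dim = dwi$grid$shape),
                 valid_mask = array(valid, dim = dwi$grid$shape)),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("tensor_volume: %s, %d/%d voxels fitted\n", format(x$grid),
              sum(x$valid_mask), length(x$valid_mask)))
  invisible(x)
}

#' Eigenvalues of a symmetric tensor field
#'
#' Computes the three eigenvalues of the per-voxel symmetric 3x3 tensor,
#' sorted descending, with the closed-form trigonometric method for
#' symmetric matrices (fully vectorized). Invalid voxels yield zeros.
#'
#' @param tensor a `tensor_volume` from [fit_tensor()].
#' @return A list of three [scalar_volume()]s named `E1`, `E2`, `E3` with
#'   `E1 >= E2 >= E3` voxel-wise.
#' @export
eigensystem <- function(tensor) {
  stopifnot(inherits(tensor, "tensor_volume"))
  ev <- symmetric3_eigenvalues(tensor$components)
  ev[!as.vector(tensor$valid_mask), ] <- 0
  sh <- tensor$grid$shape
  list(E1 = scalar_volume(array(ev[, 1], sh), tensor$grid, name = "E1"),
       E2 = scalar_volume(array(ev[, 2], sh), tensor$grid, name = "E2"),
       E3 = scalar_volume(array(ev[, 3], sh), tensor$grid, name = "E3"))
}

# Rows of 'comp' are (xx, xy, xz, yy, yz, zz). Returns an n x 3 matrix of
# eigenvalues sorted descending. Analytic method: shift by the mean
# eigenvalue, scale, then solve the depressed characteristic equation
# trigonometrically; exact for multiples of the identity.
symmetric3_eigenvalues <- function(comp) {
  xx <- comp[, 1]; xy <- comp[, 2]; xz <- comp[, 3]
  yy <- comp[, 4]; yz <- comp[, 5]; zz <- comp[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  ax <- xx - q; ay <- yy - q; az <- zz - q
  # det((A - qI)/p) / 2, guarded where p == 0 (isotropic voxels)
  safe_p <- ifelse(p > 0, p, 1)
  detB <- (ax * (ay * az - yz^2) -
           xy * (xy * az - yz * xz) +
           xz * (xy * yz - ay * xz)) / safe_p^3
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  # eigenvalues of B = (A - qI)/p solve beta^3 - 3 beta - 2 r = 0; the trig
  # solution loses ~sqrt(eps) accuracy near double roots (|r| ~ 1), so the
  # isolated (simple) root is Newton-polished and the near-degenerate pair
  # recovered exactly from the deflated quadratic
  biso <- ifelse(r >= 0, 2 * cos(phi), 2 * cos(phi + 2 * pi / 3))
  for (it in 1:3) {
    f <- biso^3 - 3 * biso - 2 * r
    fp <- 3 * biso^2 - 3
    biso <- biso - ifelse(abs(fp) > 1e-12, f / fp, 0)
  }
  disc <- sqrt(pmax(12 - 3 * biso^2, 0))
  bp1 <- (-biso + disc) / 2
  bp2 <- (-biso - disc) / 2
  e1 <- q + p * ifelse(r >= 0, biso, bp1)
  e2 <- q + p * ifelse(r >= 0, bp1, bp2)
  e3 <- q + p * ifelse(r >= 0, bp2, biso)
  iso <- p2 <= 0
  if (any(iso)) { e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso] }
  cbind(e1, e2, e3, deparse.level = 0)
}

#' Fractional anisotropy, trace and Westin shape measures
#'
#' From sorted eigenvalue maps, computes:
#' \deqn{FA = \sqrt{\frac{(E_1-E_2)^2 + (E_2-E_3)^2 + (E_1-E_3)^2}
#'                       {2 (E_1^2+E_2^2+E_3^2)}}}
#' \deqn{CL = \frac{E_1-E_2}{E_1+E_2+E_3},\quad
#'       CP = \frac{2 (E_2-E_3)}{E_1+E_2+E_3},\quad
#'       CS = \frac{3 E_3}{E_1+E_2+E_3}}
#' and the trace `T = E1 + E2 + E3`. CL + CP + CS = 1 identically wherever
#' the trace is positive. Voxels with non-positive trace or an all-zero
#' eigenvalue triple fall back to zeros in every output (T included), which
#' avoids division blow-ups at background and degenerate fits.
#'
#' @param E1,E2,E3 [scalar_volume()]s with `E1 >= E2 >= E3` voxel-wise
#'   (small numerical violations up to 1e-8 are tolerated).
#' @return A named list of [scalar_volume()]s: `F`, `T`, `CL`, `CP`, `CS`.
#' @export
westin_and_fa <- function(E1, E2, E3) {
  e1 <- E1$values; e2 <- E2$values; e3 <- E3$values
  if (any(e1 - e2 < -1e-8) || any(e2 - e3 < -1e-8))
    stop("eigenvalue maps must be sorted descending (E1 >= E2 >= E3)")
  tr <- e1 + e2 + e3
  ss <- e1^2 + e2^2 + e3^2
  ok <- tr > 0 & ss > 0
  fa <- cl <- cp <- cs <- tt <- array(0, dim = dim(e1))
  fa[ok] <- sqrt(((e1 - e2)^2 + (e2 - e3)^2 + (e1 - e3)^2)[ok] / (2 * ss[ok]))
  fa <- pmin(fa, 1)   # can exceed 1 only when a fitted eigenvalue is negative
  cl[ok] <- (e1 - e2)[ok] / tr[ok]
  cp[ok] <- 2 * (e2 - e3)[ok] / tr[ok]
  cs[ok] <- 3 * e3[ok] / tr[ok]
  tt[ok] <- tr[ok]
  g <- E1$grid
  list(F  = scalar_volume(fa, g, name = "F"),
       T  = scalar_volume(tt, g, name = "T"),
       CL = scalar_volume(cl, g, name = "CL"),
       CP = scalar_volume(cp, g, name = "CP"),
       CS = scalar_volume(cs, g, name = "CS"))
}

#' All eight diffusion scalar maps, in a chosen channel order
#'
#' Computes the eigenvalue maps and the derived measures once and returns
#' the requested subset in the requested order. The order is part of the
#' trained-model contract: the default `(T, F, CS, E1)` — trace, fractional
#' anisotropy, sphericity, maximum eigenvalue — is the input configuration
#' used by both segmentation stages.
#'
#' @param tensor a `tensor_volume`.
#' @param selection character vector drawn without repetition from
#'   `F, T, CL, CP, CS, E1, E2, E3`.
#' @return A `scalar_map_set`: list with `grid` and `maps` (named list of
#'   [scalar_volume()]s in selection order).
#' @export
assemble_maps <- function(tensor, selection = c("T", "F", "CS", "E1")) {
  all_names <- c("F", "T", "CL", "CP", "CS", "E1", "E2", "E3")
  if (length(selection) == 0L) stop("'selection' must not be empty")
  bad <- setdiff(selection, all_names)
  if (length(bad))
    stop(sprintf("unknown map name(s): %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(selection))
    stop("duplicate map names in 'selection'")
  ev <- eigensystem(tensor)
  shape <- westin_and_fa(ev$E1, ev$E2, ev$E3)
  pool <- c(shape, ev)
  structure(list(grid = tensor$grid, maps = pool[selection]),
            class = "scalar_map_set")
}

#' @export
print.scalar_map_set <- function(x, ...) {
  cat(sprintf("scalar_map_set: %s, channels (%s)\n", format(x$grid),
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}
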