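#' Specification of a synthetic diffusion phantom
#'
#' The phantom emulates, at desk scale, the structure the parcellation
#' pipeline is built for: a brain-like ball on an isotropic grid, split by
#' the midsagittal plane into two hemispheres, each with an outer cortical
#' ribbon divided into 34 angular parcels, a one-label white-matter core, and
#' a ring of 13 deep/periventricular parcels; a midline column carries 5
#' central labels. Every coarse group is assigned a diffusion-tensor
#' archetype, and the diffusion signal is forward-simulated as
#' `S = S0 * exp(-b g' D g)` with optional noise.
#'
#' Default archetypes (eigenvalues in mm^2/s) are literature-typical:
#' white-matter-like `(1.7, 0.3, 0.3) x 1e-3` with the principal axis
#' oriented radially; gray-matter-like `(0.9, 0.7, 0.7) x 1e-3`
#' (near-isotropic, fixed axes); fluid-like `(3.0, 3.0, 3.0) x 1e-3` for the
#' midline compartment; `S0 = 100` everywhere inside the phantom. They give
#' well-separated trace/FA/sphericity/E1 contrasts between compartments.
#'
#' @param grid_size cube edge in voxels (>= 24; default 48).
#' @param hierarchy a `label_hierarchy` (default [default_hierarchy()]).
#' @param spacing isotropic voxel size in mm.
#' @param bval diffusion weighting in s/mm^2 (default 1000).
#' @param n_directions number of diffusion-weighted directions (>= 6;
#'   default 64, acquired on a deterministic spherical spiral; one baseline
#'   volume is always added).
#' @param noise_sigma standard deviation of additive noise on the signal
#'   (default 0, so derived maps equal their analytic values exactly).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param skew white-matter-core inflation factor (>= 1); larger values
#'   grow the core relative to the other parcels to sharpen the final-label
#'   class imbalance.
#' @param seed integer seed controlling the noise realization.
#' @param archetypes optional named list overriding the per-kind tensor
#'   archetypes; entries `wm`, `gm`, `fluid`, each
#'   `list(ev = <3 descending eigenvalues>, s0 = <baseline>)`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_size = 48, hierarchy = default_hierarchy(),
                         spacing = 1, bval = 1000, n_directions = 64,
                         noise_sigma = 0, noise_model = c("gaussian", "rician"),
                         skew = 1, seed = 1, archetypes = NULL) {
  noise_model <- match.arg(noise_model)
  if (grid_size < 24) stop("grid_size must be >= 24")
  if (n_directions < 6) stop("n_directions must be >= 6")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (skew < 1) stop("skew must be >= 1")
  defaults <- list(
    wm    = list(ev = c(1.7, 0.3, 0.3) * 1e-3, s0 = 100),
    gm    = list(ev = c(0.9, 0.7, 0.7) * 1e-3, s0 = 100),
    fluid = list(ev = c(3.0, 3.0, 3.0) * 1e-3, s0 = 100))
  if (!is.null(archetypes)) defaults[names(archetypes)] <- archetypes
  for (a in defaults) {
    if (any(a$ev <= 0) || is.unsorted(rev(a$ev)))
      stop("archetype eigenvalues must be positive and sorted descending")
  }
  structure(list(grid_size = as.integer(grid_size), hierarchy = hierarchy,
                 spacing = spacing, bval = bval,
                 n_directions = as.integer(n_directions),
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 skew = skew, seed = as.integer(seed),
                 archetypes = defaults),
            class = "phantom_spec")
}

# coarse group -> tissue archetype kind
group_kind <- function(coarse_id) {
  switch(coarse_id, "wm", "wm", "gm", "gm", "gm", "gm", "fluid")
}

#' Generate the phantom's final-label volume
#'
#' Deterministic geometry (no randomness): a ball of radius ~0.42 x grid
#' edge centered on the lattice. The midsagittal slab hosts the 5 midline
#' labels as axial bands; each hemisphere gets a cortical shell split into
#' 34 angular sectors, a deep torus split into 13 sectors, and the
#' remaining interior as the single white-matter label. Every final id of
#' the hierarchy is present with at least 8 voxels, or an error is raised.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()] in the final namespace, on a centered
#'   isotropic grid.
#' @export
generate_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$hierarchy
  sizes <- vapply(h$groups, function(g) length(g$final_ids), integer(1))
  if (length(h$groups) != 7L)
    stop("the phantom geometry requires a 7-group hierarchy")
  g <- spec$grid_size
  grid <- volume_grid(rep(g, 3), rep(spec$spacing, 3))
  ctr <- (g + 1) / 2
  ax <- seq_len(g) - ctr
  dx <- array(rep(ax, times = g * g), c(g, g, g))
  dy <- array(rep(rep(ax, each = g), times = g), c(g, g, g))
  dz <- array(rep(ax, each = g * g), c(g, g, g))
  r <- sqrt(dx^2 + dy^2 + dz^2)
  R <- 0.42 * g
  # skew > 1 inflates the white-matter core at the expense of the shell
  shell_frac <- min(0.92, 0.78 * spec$skew^(1 / 3))
  Rin <- shell_frac * R
  w <- max(1.5, 0.03 * g)          # midsagittal slab half-width
  inside <- r <= R
  lab <- array(0L, dim = c(g, g, g))

  grp <- function(i) h$groups[[i]]$final_ids

  # midline column: 5 axial (z) bands inside the slab
  mid <- inside & abs(dx) <= w
  zb <- findInterval(dz[mid], seq(-R, R, length.out = 6),
                     rightmost.closed = TRUE)
  zb <- pmin(pmax(zb, 1L), 5L)
  lab[mid] <- grp(7)[zb]

  phi <- atan2(dz, dy)             # angle in the sagittal (y,z) plane
  for (side in 1:2) {
    hemi <- inside & (if (side == 1) dx < -w else dx > w)
    # cortical ribbon: angular sectors of the outer shell
    cort_ids <- grp(if (side == 1) 5 else 6)
    shell <- hemi & r > Rin
    sec <- pmin(floor((phi[shell] + pi) / (2 * pi) * 34) + 1L, 34L)
    lab[shell] <- cort_ids[sec]
    # deep ring: torus at |x| = 0.45 Rin, radius 0.5 Rin in (y,z), tube 1.5
    deep_ids <- grp(if (side == 1) 3 else 4)
    xb <- 0.45 * Rin * (if (side == 1) -1 else 1)
    rho <- sqrt(dy^2 + dz^2)
    torus <- hemi & r <= Rin &
      sqrt((dx - xb)^2 + (rho - 0.5 * Rin)^2) <= 1.5
    dsec <- pmin(floor((phi[torus] + pi) / (2 * pi) * 13) + 1L, 13L)
    lab[torus] <- deep_ids[dsec]
    # white-matter core: remaining interior
    core <- hemi & r <= Rin & lab == 0L
    lab[core] <- grp(if (side == 1) 1 else 2)[1]
  }

  counts <- tabulate(lab[lab > 0L], nbins = max_final_id(h))
  expected <- unlist(lapply(h$groups, `[[`, "final_ids"))
  short <- expected[counts[expected] < 8L]
  if (length(short))
    stop(sprintf("grid too small: label(s) %s have fewer than 8 voxels",
                 paste(short, collapse = ", ")))
  label_volume(lab, grid, namespace = "final")
}

#' Deterministic near-uniform directions on the sphere
#'
#' Generalized-spiral (Fibonacci lattice) construction: reproducible without
#' a stored gradient table.
#'
#' @param n number of directions.
#' @return An `n x 3` matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(rho * cos(th), rho * sin(th), z, deparse.level = 0)
}

#' Forward-simulate the diffusion signal of a phantom
#'
#' Builds a per-voxel tensor from the coarse group's archetype — principal
#' axis oriented radially for white-matter-like groups, fixed (axis-aligned)
#' otherwise — and evaluates `S_i = S0 exp(-b g_i' D g_i)` for one baseline
#' and `n_directions` weighted volumes. Gaussian (or Rician) noise of
#' standard deviation `noise_sigma` is added and the signal clipped at 0.
#' The noise realization is a pure function of `spec$seed`.
#'
#' @param labels the [label_volume()] from [generate_labels()] (or any
#'   final-namespace volume over the same hierarchy).
#' @param spec the [phantom_spec()].
#' @return A [dwi_series()].
#' @export
simulate_dwi <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  h <- spec$hierarchy
  fc <- final_to_coarse_map(h)
  lab <- labels$labels
  present <- setdiff(unique(as.vector(lab)), 0L)
  if (any(present > length(fc)) || any(fc[present] == 0L))
    stop("label volume contains ids not mapped by the hierarchy")
  g <- dim(lab)[1]
  ctr <- (dim(lab) + 1) / 2
  ax <- function(k) seq_len(dim(lab)[k]) - ctr[k]
  dxv <- array(rep(ax(1), times = prod(dim(lab)[2:3])), dim(lab))
  dyv <- array(rep(rep(ax(2), each = dim(lab)[1]), times = dim(lab)[3]), dim(lab))
  dzv <- array(rep(ax(3), each = prod(dim(lab)[1:2])), dim(lab))

  dirs <- sphere_directions(spec$n_directions)
  bvals <- c(0, rep(spec$bval, spec$n_directions))
  bvecs <- rbind(c(0, 0, 0), dirs)

  nz <- which(lab > 0L)
  cid <- fc[lab[nz]]
  kind <- vapply(cid, group_kind, character(1))
  ev <- vapply(spec$archetypes, `[[`, numeric(3), "ev")   # 3 x kinds
  s0k <- vapply(spec$archetypes, `[[`, numeric(1), "s0")
  l1 <- ev[1, kind]; l2 <- ev[2, kind]; l3 <- ev[3, kind]
  s0 <- s0k[kind]

  # radial unit axis for white-matter-like voxels
  vx <- dxv[nz]; vy <- dyv[nz]; vz <- dzv[nz]
  nrm <- sqrt(vx^2 + vy^2 + vz^2); nrm[nrm == 0] <- 1
  vx <- vx / nrm; vy <- vy / nrm; vz <- vz / nrm
  radial <- kind == "wm"

  nvol <- length(bvals)
  sig <- array(0, dim = c(dim(lab), nvol))
  nvox <- prod(dim(lab))
  for (v in seq_len(nvol)) {
    if (bvals[v] == 0) {
      s <- s0
    } else {
      gv <- bvecs[v, ]
      # g'Dg: for a radially-oriented axially symmetric tensor (l2 == l3),
      # l2 + (l1 - l2) (g.v)^2; for fixed-frame tensors, diag(l1,l2,l3).
      q <- numeric(length(nz))
      if (any(radial)) {
        dot <- gv[1] * vx[radial] + gv[2] * vy[radial] + gv[3] * vz[radial]
        q[radial] <- l2[radial] + (l1[radial] - l2[radial]) * dot^2
      }
      if (any(!radial)) {
        q[!radial] <- l1[!radial] * gv[1]^2 + l2[!radial] * gv[2]^2 +
          l3[!radial] * gv[3]^2
      }
      s <- s0 * exp(-bvals[v] * q)
    }
    plane <- numeric(nvox)
    plane[nz] <- s
    sig[, , , v] <- plane
  }

  if (spec$noise_sigma > 0) {
    with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        sig <- sig + array(rnorm(length(sig), sd = spec$noise_sigma), dim(sig))
      } else {
        n1 <- array(rnorm(length(sig), sd = spec$noise_sigma), dim(sig))
        n2 <- array(rnorm(length(sig), sd = spec$noise_sigma), dim(sig))
        sig <- sqrt((sig + n1)^2 + n2^2)
      }
    })
    sig[sig < 0] <- 0
  }
  dwi_series(sig, labels$grid, bvals, bvecs)
}

#' Generate a complete phantom: labels, coarse labels, and DWI
#'
#' @param spec a [phantom_spec()].
#' @return A list with `labels` (final), `coarse`, and `dwi`.
#' @export
generate_phantom <- function(spec) {
  labels <- generate_labels(spec)
  list(labels = labels,
       coarse = to_coarse(labels, spec$hierarchy),
       dwi = simulate_dwi(labels, spec))
}

# evaluate 'expr' under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
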