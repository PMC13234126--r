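#' Dice similarity coefficient for one label
#'
#' `2 |P intersect R| / (|P| + |R|)`. When the label is absent from both
#' volumes the overlap is defined as 1; absent from exactly one, 0.
#'
#' @param pred,ref [label_volume()]s on a common grid.
#' @param label the label id to score.
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(pred, ref, label) {
  stopifnot(inherits(pred, "label_volume"), inherits(ref, "label_volume"))
  if (!all(pred$grid$shape == ref$grid$shape))
    stop("'pred' and 'ref' must share a grid")
  p <- pred$labels == label
  r <- ref$labels == label
  np <- sum(p); nr <- sum(r)
  if (np + nr == 0L) return(1)
  2 * sum(p & r) / (np + nr)
}

# boundary voxels of a mask: mask voxels with a background 6-neighbor
# (volume edges count as background)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pm <- pad1(mask)
  ix <- 2:(d[1] + 1L); iy <- 2:(d[2] + 1L); iz <- 2:(d[3] + 1L)
  interior <- pm[ix - 1L, iy, iz] & pm[ix + 1L, iy, iz] &
              pm[ix, iy - 1L, iz] & pm[ix, iy + 1L, iz] &
              pm[ix, iy, iz - 1L] & pm[ix, iy, iz + 1L]
  mask & !interior
}

# chunked nearest-neighbor distances (mm) from points A to point set B;
# A, B are n x 3 matrices already in mm
min_dists <- function(A, B, chunk = 512L) {
  nA <- nrow(A)
  out <- numeric(nA)
  bb <- t(B)
  b2 <- colSums(bb^2)
  for (s in seq.int(1L, nA, by = chunk)) {
    e <- min(s + chunk - 1L, nA)
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b2, "+") - 2 * Ac %*% bb
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance for one label (mm)
#'
#' Directed Euclidean surface distances between the two masks' boundary
#' voxels (6-connectivity erosion definition of the boundary, coordinates
#' scaled by the voxel spacing) are computed in both directions, pooled,
#' and summarized by the 95th percentile (linear interpolation between
#' order statistics). Undefined when either mask is empty.
#'
#' @param pred,ref [label_volume()]s on a common grid.
#' @param label the label id.
#' @param spacing voxel spacing in mm; defaults to the grid's.
#' @return The HD95 in mm, or `NA` if either mask is empty.
#' @export
hd95 <- function(pred, ref, label, spacing = NULL) {
  stopifnot(inherits(pred, "label_volume"), inherits(ref, "label_volume"))
  if (!all(pred$grid$shape == ref$grid$shape))
    stop("'pred' and 'ref' must share a grid")
  if (is.null(spacing)) spacing <- pred$grid$spacing
  pm <- pred$labels == label
  rm_ <- ref$labels == label
  if (!any(pm) || !any(rm_)) return(NA_real_)
  coords <- function(mask) {
    b <- boundary_voxels(mask)
    ai <- arrayInd(which(b), dim(mask))
    sweep(ai, 2, spacing, "*")
  }
  P <- coords(pm); R <- coords(rm_)
  pooled <- c(min_dists(P, R), min_dists(R, P))
  as.numeric(stats::quantile(pooled, 0.95, type = 7))
}

#' Relative standard deviation of a map within a region
#'
#' `RSD = std / mean` (the coefficient of variation) of the scalar map's
#' values over the region's voxels, using the population standard
#' deviation so single-voxel regions are well defined (RSD 0). Lower RSD
#' means greater within-region homogeneity. Undefined (missing) when the
#' region is empty or its mean is within 1e-12 of zero; a negative mean
#' yields a negative RSD, reported as-is with a warning.
#'
#' @param map a [scalar_volume()].
#' @param parcellation a [label_volume()] on the same grid.
#' @param label the region's label id.
#' @return The RSD, or `NA` when undefined.
#' @export
rsd <- function(map, parcellation, label) {
  stopifnot(inherits(map, "scalar_volume"),
            inherits(parcellation, "label_volume"))
  if (!all(map$grid$shape == parcellation$grid$shape))
    stop("'map' and 'parcellation' must share a grid")
  v <- map$values[parcellation$labels == label]
  if (length(v) == 0L) return(NA_real_)
  m <- mean(v)
  if (abs(m) < 1e-12) {
    warning("region mean is (near) zero; RSD undefined")
    return(NA_real_)
  }
  s <- sqrt(mean((v - m)^2))     # population standard deviation
  out <- s / m
  if (out < 0) warning("negative region mean: RSD is negative")
  out
}

#' Softmax-derived confidence, uncertainty and margin maps
#'
#' From a voxel-wise probability-simplex score volume: confidence is the
#' maximum class score, uncertainty is `1 - confidence`, and margin is the
#' gap between the top and second scores. Uncertainty concentrates along
#' anatomical boundaries where class scores compete.
#'
#' @param scores numeric array `(n_classes, x, y, z)`, voxel-wise simplex.
#' @param grid a [volume_grid()] for the outputs.
#' @return A list of three [scalar_volume()]s: `confidence`,
#'   `uncertainty`, `margin`.
#' @export
confidence_maps <- function(scores, grid) {
  d <- dim(scores)
  stopifnot(length(d) == 4L)
  C <- d[1]
  top <- array(-Inf, dim = d[2:4])
  second <- array(-Inf, dim = d[2:4])
  for (c in seq_len(C)) {
    sc <- array(scores[c, , , ], dim = d[2:4])
    newtop <- sc > top
    second[newtop] <- top[newtop]
    top[newtop] <- sc[newtop]
    mid <- !newtop & sc > second
    second[mid] <- sc[mid]
  }
  if (C == 1L) second[] <- 0
  list(confidence = scalar_volume(top, grid, name = "confidence"),
       uncertainty = scalar_volume(1 - top, grid, name = "uncertainty"),
       margin = scalar_volume(top - second, grid, name = "margin"))
}

#' Per-label segmentation metrics
#'
#' Computes DSC and HD95 for every label present in either volume, plus the
#' RSD of each supplied scalar map within the predicted region. MD (mean
#' diffusivity), when requested for RSD reporting, should be supplied as a
#' map equal to trace/3.
#'
#' @param pred,ref [label_volume()]s on a common grid.
#' @param maps optional named list of [scalar_volume()]s for RSD columns.
#' @param labels label ids to score; defaults to all ids present in either
#'   volume.
#' @return A data frame with one row per label: `label`, `dsc`, `hd95_mm`,
#'   and one `rsd_<name>` column per map. Missing values are `NA`.
#' @export
compute_metrics <- function(pred, ref, maps = NULL, labels = NULL) {
  if (is.null(labels))
    labels <- setdiff(sort(unique(c(as.vector(pred$labels),
                                    as.vector(ref$labels)))), 0L)
  rows <- lapply(labels, function(id) {
    row <- data.frame(label = id,
                      dsc = dsc(pred, ref, id),
                      hd95_mm = hd95(pred, ref, id))
    for (nm in names(maps))
      row[[paste0("rsd_", nm)]] <- suppressWarnings(rsd(maps[[nm]], pred, id))
    row
  })
  if (!length(rows)) {
    out <- data.frame(label = integer(0), dsc = numeric(0),
                      hd95_mm = numeric(0))
    for (nm in names(maps)) out[[paste0("rsd_", nm)]] <- numeric(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Write per-label and macro metric tables
#'
#' Writes a TSV with one row per label in a fixed column order, followed by
#' a `macro` row holding the column means over the per-label rows (labels
#' absent from both volumes never appear; missing values are excluded from
#' each macro mean and written as `NA`).
#'
#' @param records a data frame from [compute_metrics()].
#' @param path output TSV path.
#' @return The macro-average row, invisibly.
#' @export
report_metrics <- function(records, path) {
  num_cols <- setdiff(names(records), "label")
  macro <- as.data.frame(lapply(records[num_cols], function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)))
  tab <- records
  tab$label <- as.character(tab$label)
  if (nrow(records)) {
    macro_row <- cbind(data.frame(label = "macro"), macro)
    tab <- rbind(tab, macro_row)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(macro)
}

#' Macro-average DSC over a reference label set
#'
#' Mean DSC over the given labels (defaults to all labels present in either
#' volume).
#'
#' @inheritParams compute_metrics
#' @return A number in `[0, 1]`.
#' @export
macro_dsc <- function(pred, ref, labels = NULL) {
  if (is.null(labels))
    labels <- setdiff(sort(unique(c(as.vector(pred$labels),
                                    as.vector(ref$labels)))), 0L)
  mean(vapply(labels, function(id) dsc(pred, ref, id), numeric(1)))
}
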