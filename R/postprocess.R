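#' Restrict fine segmentations to their coarse compartments
#'
#' Any fine-stage voxel falling outside its group's coarse mask is removed
#' (set to background): the coarse segmentation acts as a hard spatial
#' constraint on each group's refinement.
#'
#' @param fine named list of per-group [label_volume()]s (from
#'   [run_fine()]).
#' @param coarse the coarse [label_volume()].
#' @param h a `label_hierarchy`.
#' @return The restricted list of per-group [label_volume()]s.
#' @export
restrict_to_coarse <- function(fine, coarse, h) {
  stopifnot(inherits(coarse, "label_volume"))
  by_name <- setNames(h$groups,
                      vapply(h$groups, `[[`, character(1), "name"))
  lapply(setNames(nm = names(fine)), function(nm) {
    g <- by_name[[nm]]
    if (is.null(g)) stop(sprintf("unknown group '%s'", nm))
    v <- fine[[nm]]
    lab <- v$labels
    lab[coarse$labels != g$coarse_id] <- 0L
    label_volume(lab, v$grid, namespace = v$namespace)
  })
}

# 26-neighborhood offsets (excluding the center)
offsets26 <- local({
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
})

# pad a 3-D array with a zero border of width 1
pad1 <- function(a) {
  d <- dim(a)
  out <- array(if (is.integer(a)) 0L else 0, d + 2L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  out
}

# neighbor labels of the voxels 'idx' (linear indices into 'lab'):
# returns a length(idx) x 26 matrix
neighbor_labels <- function(lab, idx) {
  d <- dim(lab)
  pl <- pad1(lab)
  pd <- d + 2L
  ai <- arrayInd(idx, d)     # 1-based; +1 for the pad offset
  out <- matrix(0L, length(idx), 26L)
  for (t in seq_len(26L)) {
    xi <- ai[, 1] + 1L + offsets26[t, 1]
    yi <- ai[, 2] + 1L + offsets26[t, 2]
    zi <- ai[, 3] + 1L + offsets26[t, 3]
    out[, t] <- pl[cbind(xi, yi, zi)]
  }
  out
}

#' Gap-filling dilation of fine segmentations
#'
#' Iteratively grows the fine labels into unlabeled voxels to improve
#' boundary continuity and close small gaps: in each pass, every background
#' voxel lying inside its group's coarse mask that has at least one labeled
#' 26-neighbor adopts the majority label among its labeled 26-neighbors
#' (ties break toward the lowest label id). Already-labeled voxels are never
#' overwritten and growth never crosses the coarse mask. Passes repeat until
#' no voxel changes or `max_iters` is reached.
#'
#' @inheritParams restrict_to_coarse
#' @param max_iters maximum number of passes (default 3).
#' @return The dilated list of per-group [label_volume()]s.
#' @export
dilate_fill <- function(fine, coarse, h, max_iters = 3) {
  by_name <- setNames(h$groups,
                      vapply(h$groups, `[[`, character(1), "name"))
  lapply(setNames(nm = names(fine)), function(nm) {
    g <- by_name[[nm]]
    if (is.null(g)) stop(sprintf("unknown group '%s'", nm))
    lab <- fine[[nm]]$labels
    inmask <- coarse$labels == g$coarse_id
    for (pass in seq_len(max_iters)) {
      cand <- which(lab == 0L & inmask)
      if (!length(cand)) break
      nb <- neighbor_labels(lab, cand)
      has_nb <- rowSums(nb > 0L) > 0L
      if (!any(has_nb)) break
      cand <- cand[has_nb]
      nb <- nb[has_nb, , drop = FALSE]
      newlab <- apply(nb, 1, function(v) {
        v <- v[v > 0L]
        tb <- tabulate(v)
        which.max(tb)      # ties resolve to the lowest id
      })
      lab[cand] <- as.integer(newlab)
    }
    label_volume(lab, fine[[nm]]$grid, namespace = fine[[nm]]$namespace)
  })
}

#' Connected components of a binary mask under 26-connectivity
#'
#' Component ids are the minimum linear voxel index (x-fastest scan order)
#' of each component, found by iterative minimum-label propagation; this
#' makes the scan-order tie-break of [keep_largest_component()] a direct
#' comparison of component ids.
#'
#' @param mask logical 3-D array.
#' @return Integer array: 0 outside the mask, the component id (minimum
#'   member linear index) inside.
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, dim = d)
  comp[mask] <- which(mask)
  if (!any(mask)) return(comp)
  pd <- d + 2L
  inner_x <- 2:(d[1] + 1L); inner_y <- 2:(d[2] + 1L); inner_z <- 2:(d[3] + 1L)
  big <- .Machine$integer.max
  repeat {
    pc <- array(big, dim = pd)
    pc[inner_x, inner_y, inner_z] <- ifelse(mask, comp, big)
    new <- comp
    for (t in seq_len(26L)) {
      sh <- pc[inner_x + offsets26[t, 1],
               inner_y + offsets26[t, 2],
               inner_z + offsets26[t, 3]]
      new <- pmin(new, ifelse(mask, sh, new))
    }
    new[!mask] <- 0L
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

#' Keep only the largest connected component of each label
#'
#' For every non-background label independently, ranks its 26-connected
#' components by voxel count and sets all but the largest to background. A
#' tie on size keeps the component whose minimum linear voxel index
#' (x-fastest scan order) is smallest. No minimum voxel-count threshold is
#' applied.
#'
#' @param labels a [label_volume()].
#' @return A [label_volume()] in the same namespace.
#' @export
keep_largest_component <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    # work inside the label's bounding box; scan-order ranks are preserved
    # because cropping is monotone in the linear index within the box
    w <- which(lab == id)
    ai <- arrayInd(w, d)
    lo <- apply(ai, 2, min); hi <- apply(ai, 2, max)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dim(sub) <- hi - lo + 1L
    mask <- sub == id
    comp <- connected_components(mask)
    ids <- comp[mask]
    tb <- table(ids)
    if (length(tb) <= 1L) next
    sizes <- as.vector(tb)
    cid <- as.integer(names(tb))
    best <- cid[sizes == max(sizes)]
    keep <- min(best)                    # scan-order tie-break
    drop_lin_sub <- which(mask & comp != keep)
    ai2 <- arrayInd(drop_lin_sub, dim(mask))
    lab[cbind(ai2[, 1] + lo[1] - 1L, ai2[, 2] + lo[2] - 1L,
              ai2[, 3] + lo[3] - 1L)] <- 0L
  }
  label_volume(lab, labels$grid, namespace = labels$namespace)
}

#' Merge coarse and fine outputs into the final parcellation
#'
#' Terminal groups (the two cerebral white matter compartments) contribute
#' their single final id wherever the coarse map assigns their coarse id;
#' non-terminal voxels take the fine-stage label. A voxel claimed by both
#' keeps the fine label. Voxels inside a non-terminal coarse mask left
#' unlabeled after cleaning stay background.
#'
#' @param coarse the coarse [label_volume()].
#' @param fine named list of post-processed per-group [label_volume()]s.
#' @param h a `label_hierarchy`.
#' @return A [label_volume()] with namespace `"final"`.
#' @export
merge_final <- function(coarse, fine, h) {
  out <- array(0L, dim = coarse$grid$shape)
  for (g in terminal_groups(h))
    out[coarse$labels == g$coarse_id] <- g$final_ids[1]
  for (v in fine) {
    nz <- v$labels > 0L
    out[nz] <- v$labels[nz]
  }
  label_volume(out, coarse$grid, namespace = "final")
}

#' Return a parcellation to a native grid
#'
#' Nearest-neighbor resampling of the final labels back onto the original
#' (native) acquisition grid.
#'
#' @param labels a [label_volume()].
#' @param native_grid the target [volume_grid()].
#' @return A [label_volume()] on `native_grid`.
#' @export
to_native <- function(labels, native_grid) {
  resample(labels, native_grid, mode = "nearest")
}

#' Remap labels through a lookup table
#'
#' Applies the hierarchy's lookup table (e.g. internal ids to FreeSurfer
#' ids), a bijective relabeling; every id present in the volume must have an
#' entry.
#'
#' @param labels a [label_volume()].
#' @param lut named integer vector mapping final ids (names) to external
#'   ids, typically `h$lut`.
#' @return A [label_volume()] with namespace `"lut"`.
#' @export
apply_lookup <- function(labels, lut) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(lut)) stop("no lookup table defined")
  present <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
  missing_ids <- setdiff(as.character(present), names(lut))
  if (length(missing_ids))
    stop(sprintf("no lookup-table entry for id(s): %s",
                 paste(missing_ids, collapse = ", ")))
  if (anyDuplicated(as.integer(lut[as.character(present)])))
    stop("lookup table is not one-to-one on the labels present")
  lab <- labels$labels
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- as.integer(lut[as.character(lab[nz])])
  label_volume(out, labels$grid, namespace = "lut")
}

#' Full post-processing chain
#'
#' Applies the pipeline's fixed cleanup order: restrict the fine outputs to
#' their coarse compartments, run the gap-filling dilation, keep each
#' label's largest 26-connected component (per group, before merging),
#' merge with the terminal coarse labels into the final 101-label volume,
#' and optionally resample to a native grid and remap through the lookup
#' table.
#'
#' @param coarse the coarse [label_volume()].
#' @param fine named list of per-group fine [label_volume()]s.
#' @param h a `label_hierarchy`.
#' @param native_grid optional [volume_grid()] to return the result on.
#' @param apply_lut remap through `h$lut` if defined (default `FALSE`).
#' @param max_iters dilation passes (default 3).
#' @return A [label_volume()] (namespace `"final"`, or `"lut"` when
#'   remapped).
#' @export
postprocess_parcellation <- function(coarse, fine, h, native_grid = NULL,
                                     apply_lut = FALSE, max_iters = 3) {
  fine <- restrict_to_coarse(fine, coarse, h)
  fine <- dilate_fill(fine, coarse, h, max_iters = max_iters)
  fine <- lapply(fine, keep_largest_component)
  out <- merge_final(coarse, fine, h)
  if (!is.null(native_grid)) out <- to_native(out, native_grid)
  if (apply_lut) out <- apply_lookup(out, h$lut)
  out
}
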