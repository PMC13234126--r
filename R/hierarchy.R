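#' The default seven-group label hierarchy
#'
#' The parcellation refines seven coarse anatomical compartments into 101
#' final labels: left and right cerebral white matter (1 label each, final
#' at the coarse stage), left and right deep/periventricular non-cortical
#' structures (13 labels each), left and right cortical parcels (34 each,
#' the Desikan-Killiany cortical regions per hemisphere), and midline/
#' central structures (5 labels): 1+1+13+13+34+34+5 = 101. The default
#' final-label namespace is the synthetic range 1..101 assigned in group
#' order; a user-supplied configuration (see [load_hierarchy()]) can carry
#' FreeSurfer ids and a lookup table instead.
#'
#' @return A `label_hierarchy` object: ordered list of groups, each with
#'   `coarse_id` (1..7), `name`, `final_ids`, and a `terminal` flag marking
#'   groups whose single label needs no fine-stage refinement.
#' @export
default_hierarchy <- function() {
  sizes <- c(1L, 1L, 13L, 13L, 34L, 34L, 5L)
  names7 <- c("lh_cerebral_wm", "rh_cerebral_wm",
              "lh_deep", "rh_deep",
              "lh_cortical", "rh_cortical",
              "midline")
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  groups <- lapply(seq_along(sizes), function(i) {
    list(coarse_id = i,
         name = names7[i],
         final_ids = seq.int(starts[i], ends[i]),
         terminal = sizes[i] == 1L)
  })
  new_label_hierarchy(groups, lut = NULL)
}

new_label_hierarchy <- function(groups, lut = NULL, strict_default = FALSE) {
  ids_all <- unlist(lapply(groups, `[[`, "final_ids"))
  if (anyDuplicated(ids_all)) {
    dup <- unique(ids_all[duplicated(ids_all)])
    stop(sprintf("final id(s) assigned to more than one group: %s",
                 paste(dup, collapse = ", ")))
  }
  if (any(ids_all < 1L)) stop("final ids must be positive (0 = background)")
  cids <- vapply(groups, `[[`, integer(1), "coarse_id")
  if (anyDuplicated(cids)) stop("coarse ids must be unique")
  sizes <- vapply(groups, function(g) length(g$final_ids), integer(1))
  default_sizes <- c(1L, 1L, 13L, 13L, 34L, 34L, 5L)
  is_default_shape <- length(sizes) == 7L && all(sort(sizes) == sort(default_sizes))
  if (strict_default && !is_default_shape)
    stop(sprintf("strict_default: expected 7 groups of sizes (%s), got %d group(s) of sizes (%s)",
                 paste(default_sizes, collapse = ","), length(sizes),
                 paste(sizes, collapse = ",")))
  if (!is_default_shape)
    warning(sprintf("non-default hierarchy: %d group(s) spanning %d final label(s)",
                    length(sizes), sum(sizes)))
  for (g in groups)
    if (g$terminal && length(g$final_ids) != 1L)
      stop(sprintf("terminal group '%s' must contain exactly one final id", g$name))
  if (!is.null(lut)) {
    lut_ids <- as.integer(names(lut))
    if (any(is.na(lut_ids))) stop("lut names must be final ids")
  }
  structure(list(groups = groups[order(cids)], lut = lut),
            class = "label_hierarchy")
}

#' Load a label hierarchy from a YAML or JSON configuration
#'
#' The configuration has a `groups` list, each entry with keys `coarse_id`,
#' `name`, `final_ids`, `terminal`, and an optional top-level `lut` mapping
#' final ids to external lookup-table ids (e.g. FreeSurfer ids). With
#' `strict_default = TRUE`, the group sizes must match the default
#' (1,1,13,13,34,34,5) partition; otherwise deviations only warn.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param strict_default enforce the default group sizes.
#' @return A `label_hierarchy`.
#' @export
load_hierarchy <- function(path, strict_default = FALSE) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$groups)) stop("configuration has no 'groups' entry")
  groups <- lapply(cfg$groups, function(g) {
    if (is.null(g$coarse_id) || is.null(g$final_ids))
      stop("each group needs 'coarse_id' and 'final_ids'")
    list(coarse_id = as.integer(g$coarse_id),
         name = if (is.null(g$name)) sprintf("group%d", g$coarse_id) else g$name,
         final_ids = as.integer(unlist(g$final_ids)),
         terminal = isTRUE(g$terminal))
  })
  lut <- NULL
  if (!is.null(cfg$lut)) {
    lut <- vapply(cfg$lut, function(v) as.integer(v), integer(1))
    if (is.null(names(lut)) || any(!nzchar(names(lut))))
      stop("'lut' must map final ids (names) to lookup-table ids")
  }
  new_label_hierarchy(groups, lut = lut, strict_default = strict_default)
}

#' Write a hierarchy configuration to YAML
#'
#' @param h a `label_hierarchy`.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  cfg <- list(groups = lapply(h$groups, function(g)
    list(coarse_id = g$coarse_id, name = g$name,
         final_ids = as.integer(g$final_ids), terminal = g$terminal)))
  if (!is.null(h$lut)) cfg$lut <- as.list(h$lut)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.label_hierarchy <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$final_ids), integer(1))
  cat(sprintf("label_hierarchy: %d groups, %d final labels\n",
              length(x$groups), sum(sizes)))
  for (g in x$groups)
    cat(sprintf("  [%d] %-16s %3d label%s%s\n", g$coarse_id, g$name,
                length(g$final_ids),
                if (length(g$final_ids) == 1L) " " else "s",
                if (g$terminal) " (terminal)" else ""))
  invisible(x)
}

n_final_labels <- function(h) sum(vapply(h$groups, function(g)
  length(g$final_ids), integer(1)))

max_final_id <- function(h) max(unlist(lapply(h$groups, `[[`, "final_ids")))

nonterminal_groups <- function(h) Filter(function(g) !g$terminal, h$groups)

terminal_groups <- function(h) Filter(function(g) g$terminal, h$groups)

# final id -> coarse id lookup vector (index = final id)
final_to_coarse_map <- function(h) {
  m <- integer(max_final_id(h))
  for (g in h$groups) m[g$final_ids] <- g$coarse_id
  m
}

#' Collapse a final-label volume to the coarse namespace
#'
#' Each voxel takes the coarse id of the group owning its final label;
#' background is preserved. Labels absent from the hierarchy are an error.
#'
#' @param final a [label_volume()] in the final namespace.
#' @param h a `label_hierarchy`.
#' @return A [label_volume()] with namespace `"coarse"`.
#' @export
to_coarse <- function(final, h) {
  stopifnot(inherits(final, "label_volume"))
  lab <- final$labels
  m <- final_to_coarse_map(h)
  present <- setdiff(unique(as.vector(lab)), 0L)
  unknown <- present[present > length(m) | m[pmin(present, length(m))] == 0L]
  if (length(unknown))
    stop(sprintf("label(s) not in hierarchy: %s",
                 paste(sort(unknown), collapse = ", ")))
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- m[lab[nz]]
  label_volume(out, final$grid, namespace = "coarse")
}

#' Per-label voxel counts over one or more label volumes
#'
#' @param volumes a [label_volume()] or list of them.
#' @return A `label_stats` object: named integer vector of counts for every
#'   non-background label observed.
#' @export
label_stats <- function(volumes) {
  if (inherits(volumes, "label_volume")) volumes <- list(volumes)
  counts <- integer(0)
  for (v in volumes) {
    stopifnot(inherits(v, "label_volume"))
    tb <- tabulate(v$labels[v$labels > 0L])
    n <- max(length(counts), length(tb))
    counts <- c(counts, integer(n - length(counts)))
    tb <- c(tb, integer(n - length(tb)))
    counts <- counts + tb
  }
  counts <- counts[seq_along(counts)]
  names(counts) <- seq_along(counts)
  structure(counts[counts > 0L], class = "label_stats")
}

#' Write label statistics as a TSV table
#'
#' @param stats a `label_stats` object.
#' @param path output path; columns `label` and `count`.
#' @return `path`, invisibly.
#' @export
write_label_stats <- function(stats, path) {
  utils::write.table(data.frame(label = as.integer(names(stats)),
                                count = as.integer(stats)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum-to-median voxel-count ratio
#'
#' The imbalance statistic over non-background labels: the largest label's
#' voxel count divided by the median count (mean of the central pair for an
#' even number of labels). Collapsing final labels into balanced coarse
#' groups drives this ratio down, which is the motivation for the two-stage
#' design.
#'
#' @param stats a `label_stats` object (or bare named count vector).
#' @return A number `>= 1`.
#' @export
imbalance_ratio <- function(stats) {
  counts <- as.numeric(stats)
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    stop("no non-background labels with positive counts")
  max(counts) / median(counts)
}

#' Inverse-label-frequency class weights
#'
#' Weight of class `c` is proportional to `1 / count_c`, normalized so the
#' mean weight over the `n_classes` classes is 1. Classes absent from the
#' counts (zero voxels) receive the maximum weight observed among present
#' classes before normalization.
#'
#' @param stats a `label_stats` (names are class labels) or a plain count
#'   vector for classes `1..n_classes`.
#' @param n_classes number of foreground classes.
#' @return A numeric weight vector of length `n_classes` (mean 1).
#' @export
inverse_frequency_weights <- function(stats, n_classes) {
  counts <- numeric(n_classes)
  s <- as.numeric(stats)
  if (!is.null(names(stats))) {
    idx <- as.integer(names(stats))
    keep <- idx >= 1L & idx <= n_classes
    counts[idx[keep]] <- s[keep]
  } else {
    counts[seq_len(min(length(s), n_classes))] <-
      s[seq_len(min(length(s), n_classes))]
  }
  if (all(counts == 0)) stop("no class has a positive count")
  w <- ifelse(counts > 0, 1 / counts, NA_real_)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w / mean(w)
}

#' Normalized coarse-mask channel
#'
#' Converts a coarse label volume into the scalar channel appended to the
#' diffusion maps for the fine stage: `coarse_id / 7` (background maps to
#' 0), a single channel normalized to the range 0..1 so that label values
#' do not dominate the input scale.
#'
#' @param coarse a [label_volume()] with namespace `"coarse"` and ids 0..7.
#' @return A [scalar_volume()] with values in `[0, 1]`.
#' @export
group_channel <- function(coarse) {
  stopifnot(inherits(coarse, "label_volume"))
  if (coarse$namespace != "coarse")
    stop("'coarse' must be a coarse-namespace label volume")
  if (any(coarse$labels > 7L))
    stop("coarse ids must lie in 0..7")
  scalar_volume(coarse$labels / 7, coarse$grid, name = "coarse_mask")
}
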