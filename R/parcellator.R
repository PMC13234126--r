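#' Fit a hierarchical coarse-to-fine parcellator
#'
#' Trains the complete two-stage segmentation pipeline on one or more
#' training cases: first a coarse model predicting the seven anatomical
#' compartments from the four diffusion scalar maps (trace, FA, sphericity,
#' maximum eigenvalue by default), then one dedicated model per non-terminal
#' group on five-channel inputs (the four maps plus the coarse mask scaled
#' to 0..1). The stages are trained sequentially, not jointly. By default
#' the fine models are trained in "teacher" mode, with the reference coarse
#' mask (derived from the training labels) as the fifth channel; set
#' `fine_mask = "predicted"` to train them on the coarse model's own
#' prediction instead.
#'
#' @param maps a `scalar_map_set` (see [assemble_maps()]), or a
#'   [dwi_series()] from which the default maps are derived.
#' @param labels a final-namespace [label_volume()] of training labels.
#' @param hierarchy a `label_hierarchy` (default [default_hierarchy()]).
#' @param coarse_config,fine_config [train_config()]s for the two stages.
#'   Defaults train with a patch spanning the whole volume, which the
#'   reference backbone's patch-relative positional encoding expects.
#' @param backbone a `function(n_in_channels, n_classes, channels, seed)`
#'   returning a trainable model; defaults to [mlp_backbone()].
#' @param fine_mask `"reference"` (teacher forcing, default) or
#'   `"predicted"`.
#' @param infer_config [inference_config()] used when `fine_mask =
#'   "predicted"` and by [predict.dk_parcellator()] as the default.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return An object of class `dk_parcellator` with the trained models,
#'   loss traces, hierarchy and channel contract.
#' @export
dk_parcellator <- function(maps, labels, hierarchy = default_hierarchy(),
                           coarse_config = NULL, fine_config = NULL,
                           backbone = NULL,
                           fine_mask = c("reference", "predicted"),
                           infer_config = NULL, seed = 1) {
  fine_mask <- match.arg(fine_mask)
  if (inherits(maps, "dwi_series"))
    maps <- assemble_maps(fit_tensor(maps))
  stopifnot(inherits(maps, "scalar_map_set"),
            inherits(labels, "label_volume"))
  vol_dim <- maps$grid$shape
  if (is.null(coarse_config))
    coarse_config <- train_config(patch_size = vol_dim, iterations = 600,
                                  seed = seed)
  if (is.null(fine_config))
    fine_config <- train_config(patch_size = vol_dim, iterations = 600,
                                seed = seed + 1L)
  if (is.null(infer_config))
    infer_config <- inference_config(patch_size = vol_dim)
  if (is.null(backbone))
    backbone <- function(n_in_channels, n_classes, channels, seed)
      mlp_backbone(n_in_channels, n_classes, channels = channels, seed = seed)

  channel_names <- names(maps$maps)
  chans <- normalize_channels(maps)
  coarse_ref <- to_coarse(labels, hierarchy)

  # stage 1: coarse compartments (background + 7)
  cmodel <- backbone(length(chans), 8L, channels = channel_names,
                     seed = seed + 100L)
  cfit <- train_stage(cmodel, chans, coarse_ref$labels, coarse_config)

  # fifth channel for the fine stage
  mask_src <- if (fine_mask == "reference") coarse_ref
              else run_coarse(maps, cfit$model, infer_config)
  mask_chan <- group_channel(mask_src)$values

  fine_models <- list()
  fine_traces <- list()
  for (g in nonterminal_groups(hierarchy)) {
    ids <- sort(g$final_ids)
    tgt <- array(0L, dim = vol_dim)
    for (i in seq_along(ids)) tgt[labels$labels == ids[i]] <- i
    fchans <- c(chans, list(coarse_mask = mask_chan))
    fmodel <- backbone(length(fchans), length(ids) + 1L,
                       channels = c(channel_names, "coarse_mask"),
                       seed = seed + 100L + g$coarse_id)
    cfg <- fine_config
    cfg$seed <- fine_config$seed + g$coarse_id
    ffit <- train_stage(fmodel, fchans, tgt, cfg)
    fine_models[[g$name]] <- ffit$model
    fine_traces[[g$name]] <- ffit$trace
  }

  structure(list(coarse_model = cfit$model,
                 fine_models = fine_models,
                 hierarchy = hierarchy,
                 channels = channel_names,
                 coarse_trace = cfit$trace,
                 fine_traces = fine_traces,
                 fine_mask = fine_mask,
                 infer_config = infer_config,
                 seed = seed),
            class = "dk_parcellator")
}

#' @export
print.dk_parcellator <- function(x, ...) {
  cat("Hierarchical coarse-to-fine parcellator\n")
  cat(sprintf("  channels: (%s)\n", paste(x$channels, collapse = ", ")))
  cat(sprintf("  coarse stage: 7 compartments (+background), final loss %.4f\n",
              tail(x$coarse_trace, 1)))
  cat(sprintf("  fine stage: %d group models (%s)\n",
              length(x$fine_models),
              paste(names(x$fine_models), collapse = ", ")))
  cat(sprintf("  final label space: %d labels\n",
              n_final_labels(x$hierarchy)))
  invisible(x)
}

#' @export
summary.dk_parcellator <- function(object, ...) {
  cat("Hierarchical coarse-to-fine parcellator\n\n")
  tr <- object$coarse_trace
  cat(sprintf("coarse stage: %d iterations, loss %.4f -> %.4f\n",
              length(tr), tr[1], tail(tr, 1)))
  for (nm in names(object$fine_traces)) {
    tr <- object$fine_traces[[nm]]
    cat(sprintf("fine stage '%s': %d iterations, loss %.4f -> %.4f\n",
                nm, length(tr), tr[1], tail(tr, 1)))
  }
  cat(sprintf("\nfine-stage mask channel: %s; channel contract (%s)\n",
              object$fine_mask, paste(object$channels, collapse = ", ")))
  invisible(object)
}

#' Predict a parcellation with a fitted parcellator
#'
#' Runs the two trained stages with sliding-window inference and the full
#' post-processing chain (coarse-mask restriction, gap-filling dilation,
#' largest-component retention, merge), optionally returning the result on
#' a native grid and/or through the hierarchy's lookup table.
#'
#' @param object a fitted `dk_parcellator`.
#' @param maps a `scalar_map_set` (or [dwi_series()]) for the new case.
#' @param native_grid optional [volume_grid()] to resample the result onto.
#' @param apply_lut remap through the hierarchy's lookup table.
#' @param infer_config optional [inference_config()] override.
#' @param ... unused.
#' @return A final-namespace [label_volume()].
#' @export
predict.dk_parcellator <- function(object, maps, native_grid = NULL,
                                   apply_lut = FALSE, infer_config = NULL,
                                   ...) {
  if (inherits(maps, "dwi_series"))
    maps <- assemble_maps(fit_tensor(maps), selection = object$channels)
  cfg <- if (is.null(infer_config)) object$infer_config else infer_config
  coarse <- run_coarse(maps, object$coarse_model, cfg)
  fine <- run_fine(maps, coarse, object$hierarchy, object$fine_models, cfg)
  postprocess_parcellation(coarse, fine, object$hierarchy,
                           native_grid = native_grid, apply_lut = apply_lut)
}
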