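#' Composite Dice + cross-entropy loss
#'
#' The training objective of both stages: soft Dice loss and cross-entropy
#' with equal (1:1) weighting. The Dice term is
#' `1 - mean_c 2 sum(p_c y_c) / (sum(p_c) + sum(y_c) + eps)` with
#' `eps = 1e-5`, averaged over foreground classes present in the target or
#' the prediction (background and classes absent from both are excluded).
#' The cross-entropy term is the mean over voxels of `-log p_y`, optionally
#' scaled per voxel by a class weight (see [inverse_frequency_weights()]).
#'
#' @param scores numeric array `(n_classes, x, y, z)` of voxel-normalized
#'   class scores.
#' @param target integer array `(x, y, z)` of class indices in
#'   `0..n_classes-1`.
#' @param class_weights optional numeric vector of length `n_classes`.
#' @return A single non-negative loss value.
#' @export
dice_ce_loss <- function(scores, target, class_weights = NULL) {
  d <- dim(scores)
  if (length(d) != 4L) stop("'scores' must be (n_classes, x, y, z)")
  if (!all(d[2:4] == dim(target)))
    stop("spatial shape of 'scores' and 'target' disagree")
  C <- d[1]
  y <- as.integer(target)
  if (any(y < 0L) || any(y >= C))
    stop("target labels must lie in 0..n_classes-1")
  P <- t(matrix(scores, nrow = C))
  n <- nrow(P)
  if (!is.null(class_weights) && length(class_weights) != C)
    stop("'class_weights' must have one entry per class")
  w <- if (is.null(class_weights)) rep(1, C) else class_weights
  py <- pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)
  ce <- mean(w[y + 1L] * -log(py))
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  sp <- colSums(P); sy <- colSums(Y); inter <- colSums(P * Y)
  eps <- 1e-5
  fgc <- which(seq_len(C) > 1 & (sp + sy) > 0)
  dl <- if (length(fgc)) 1 - mean(2 * inter[fgc] / (sp[fgc] + sy[fgc] + eps))
        else 0
  ce + dl
}

#' Training configuration
#'
#' Desk-scale defaults; the published configuration for GPU-scale training
#' of this kind of pipeline (patch 128^3, batch 2, polynomial learning-rate
#' decay of power 0.9) is kept as the shape of the schedule, scaled down.
#'
#' @param patch_size integer scalar or length-3 vector, patch edge in
#'   voxels.
#' @param batch_size patches per optimization step.
#' @param iterations number of optimization steps.
#' @param loss `"dice_ce"` (default) or `"dice_wce"` (class-weighted
#'   cross-entropy term).
#' @param class_weights optional explicit per-class weights for
#'   `"dice_wce"`; computed from inverse label frequency on the training
#'   target when omitted.
#' @param lr initial learning rate (polynomial decay, power
#'   `poly_power`).
#' @param poly_power exponent of the polynomial decay schedule.
#' @param sample_voxels voxels per step used by the reference backbone.
#' @param oversample_fg probability that a sampled patch is centered on a
#'   foreground voxel (default 0.5).
#' @param seed seed for patch sampling and voxel subsampling.
#' @return A `train_config` object.
#' @export
train_config <- function(patch_size = 32, batch_size = 1, iterations = 300,
                         loss = c("dice_ce", "dice_wce"),
                         class_weights = NULL, lr = 0.1, poly_power = 0.9,
                         sample_voxels = 8192, oversample_fg = 0.5,
                         seed = 1) {
  loss <- match.arg(loss)
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  stopifnot(all(patch_size >= 1), batch_size >= 1, iterations >= 0,
            lr > 0, oversample_fg >= 0, oversample_fg <= 1)
  structure(list(patch_size = patch_size, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations), loss = loss,
                 class_weights = class_weights, lr = lr,
                 poly_power = poly_power,
                 sample_voxels = as.integer(sample_voxels),
                 oversample_fg = oversample_fg, seed = as.integer(seed)),
            class = "train_config")
}

#' Sliding-window inference configuration
#'
#' @param patch_size integer scalar or length-3 vector.
#' @param overlap_fraction fractional overlap between adjacent windows along
#'   each axis, in `[0, 1)` (default 0.5).
#' @param gaussian_sigma_scale the Gaussian window weight has standard
#'   deviation `gaussian_sigma_scale * patch edge` (default 1/8).
#' @return An `inference_config` object.
#' @export
inference_config <- function(patch_size = 32, overlap_fraction = 0.5,
                             gaussian_sigma_scale = 1 / 8) {
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must lie in [0, 1)")
  step <- pmax(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  structure(list(patch_size = patch_size,
                 overlap_fraction = overlap_fraction,
                 gaussian_sigma_scale = gaussian_sigma_scale,
                 step = step),
            class = "inference_config")
}

# deterministic private-RNG helper: returns a function(n) yielding uniforms
# from a stream independent of (and not disturbing) the caller's RNG
private_rng <- function(seed) {
  env <- new.env()
  with_seed(seed, env$state <- get(".Random.seed", envir = globalenv()))
  function(n) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    u
  }
}

# crop-with-zero-padding: returns the patch of 'arr' with the given 1-based
# origin, padding with zeros where the patch extends outside the volume
extract_patch <- function(arr, origin, patch) {
  d <- dim(arr)
  out <- array(if (is.integer(arr)) 0L else 0, dim = patch)
  lo <- pmax(origin, 1L)
  hi <- pmin(origin + patch - 1L, d)
  if (any(lo > hi)) return(out)
  plo <- lo - origin + 1L
  phi <- hi - origin + 1L
  out[plo[1]:phi[1], plo[2]:phi[2], plo[3]:phi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  out
}

#' Random patch sampler
#'
#' Returns a closure producing `(channel patch, label patch)` pairs. Each
#' draw is centered on a random foreground voxel with probability
#' `oversample_fg` (when foreground exists), otherwise placed uniformly;
#' patches extending past the volume are zero-padded. The stream is
#' deterministic given `seed` and does not disturb the caller's RNG.
#'
#' @param channels list of co-registered 3-D numeric arrays.
#' @param target integer 3-D array of class indices (0 = background).
#' @param patch_size length-3 integer vector.
#' @param oversample_fg foreground-centering probability.
#' @param seed RNG seed for the private stream.
#' @return A `function()` returning `list(x = (C,px,py,pz) array,
#'   y = (px,py,pz) array, origin = <1-based origin>)`.
#' @export
patch_sampler <- function(channels, target, patch_size, oversample_fg = 0.5,
                          seed = 1) {
  d <- dim(target)
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  fg <- which(target > 0L)
  rng <- private_rng(seed)
  max_origin <- pmax(d - patch_size + 1L, 1L)
  function() {
    u <- rng(5)
    if (length(fg) > 0L && u[1] < oversample_fg) {
      center <- arrayInd(fg[ceiling(u[2] * length(fg))], d)[1, ]
      origin <- center - patch_size %/% 2L
      origin <- pmin(pmax(origin, 1L), max_origin)
    } else {
      origin <- 1L + floor(u[3:5] * max_origin)
      origin <- pmin(origin, max_origin)
    }
    x <- vapply(channels, extract_patch, array(0, dim = patch_size),
                origin = origin, patch = patch_size)
    # vapply stacks along the last axis; put channels first
    x <- aperm(x, c(4, 1, 2, 3))
    list(x = x, y = extract_patch(target, origin, patch_size),
         origin = origin)
  }
}

#' Train one segmentation stage
#'
#' Runs `iterations` optimization steps of the model on patches drawn from
#' the channel stack, recording the composite loss per step. The learning
#' rate follows polynomial decay `lr * (1 - t/iterations)^power`. With
#' `loss = "dice_wce"` and no explicit weights, per-class weights are
#' computed from inverse label frequency over the training target
#' (background included).
#'
#' @param model a trainable segmentation model (see [train_step()]).
#' @param channels list of co-registered 3-D numeric arrays (already
#'   normalized as desired).
#' @param target integer 3-D array of class indices in `0..n_classes-1`.
#' @param config a [train_config()].
#' @return `list(model = trained model, trace = numeric vector of per-step
#'   mean losses)`.
#' @export
train_stage <- function(model, channels, target, config = train_config()) {
  if (length(channels) != model$n_in_channels)
    stop(sprintf("expected %d channels, got %d", model$n_in_channels,
                 length(channels)))
  if (config$iterations == 0L)
    return(list(model = model, trace = numeric(0)))
  cw <- config$class_weights
  if (config$loss == "dice_wce" && is.null(cw)) {
    counts <- tabulate(as.integer(target) + 1L, nbins = model$n_classes)
    w <- ifelse(counts > 0, 1 / counts, NA_real_)
    w[is.na(w)] <- max(w, na.rm = TRUE)
    cw <- w / mean(w)
  }
  sampler <- patch_sampler(channels, target, config$patch_size,
                           oversample_fg = config$oversample_fg,
                           seed = config$seed)
  rng <- private_rng(config$seed + 1L)
  trace <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    lr_t <- config$lr * (1 - (it - 1) / config$iterations)^config$poly_power
    losses <- numeric(config$batch_size)
    for (b in seq_len(config$batch_size)) {
      p <- sampler()
      st <- train_step(model, p$x, p$y, lr = lr_t, loss = config$loss,
                       class_weights = cw,
                       sample_voxels = config$sample_voxels, rng = rng)
      model <- st$model
      losses[b] <- st$loss
    }
    trace[it] <- mean(losses)
  }
  list(model = model, trace = trace)
}

#' Sliding-window prediction over a full volume
#'
#' Tiles the (zero-padded) volume with windows at the configured overlap,
#' accumulates per-window scores under a separable Gaussian weight centered
#' in each window, and renormalizes the accumulated scores to a voxel-wise
#' probability simplex.
#'
#' @param model a segmentation model implementing [predict_scores()].
#' @param channels list of co-registered 3-D numeric arrays.
#' @param config an [inference_config()].
#' @return Numeric array `(n_classes, x, y, z)` summing to 1 per voxel.
#' @export
sliding_window_predict <- function(model, channels,
                                   config = inference_config()) {
  d <- dim(channels[[1]])
  p <- config$patch_size
  pd <- pmax(d, p)
  # window origins along each axis, last window flush with the padded end
  origins_axis <- function(n, pe, st) {
    o <- seq.int(1L, max(n - pe + 1L, 1L), by = st)
    if (o[length(o)] != n - pe + 1L && n > pe) o <- c(o, n - pe + 1L)
    o
  }
  ox <- origins_axis(pd[1], p[1], config$step[1])
  oy <- origins_axis(pd[2], p[2], config$step[2])
  oz <- origins_axis(pd[3], p[3], config$step[3])
  wax <- function(pe) {
    t <- seq_len(pe) - (pe + 1) / 2
    sg <- max(config$gaussian_sigma_scale * pe, 1e-3)
    exp(-t^2 / (2 * sg^2))
  }
  w3 <- outer(outer(wax(p[1]), wax(p[2])), wax(p[3]))
  w3 <- pmax(w3, max(w3) * 1e-6)
  C <- model$n_classes
  acc <- array(0, dim = c(C, pd))
  wsum <- array(0, dim = pd)
  wrep <- aperm(array(w3, dim = c(p, C)), c(4, 1, 2, 3))
  for (i in ox) for (j in oy) for (k in oz) {
    x <- vapply(channels, extract_patch, array(0, dim = p),
                origin = c(i, j, k), patch = p)
    x <- aperm(x, c(4, 1, 2, 3))
    sc <- predict_scores(model, x)
    xi <- i:(i + p[1] - 1L); yj <- j:(j + p[2] - 1L); zk <- k:(k + p[3] - 1L)
    acc[, xi, yj, zk] <- acc[, xi, yj, zk] + sc * wrep
    wsum[xi, yj, zk] <- wsum[xi, yj, zk] + w3
  }
  acc <- acc / rep(wsum, each = C)
  acc <- acc[, seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  tot <- apply(acc, 2:4, sum)
  acc / rep(tot, each = C)
}

#' Voxel-wise argmax of a score volume
#'
#' Ties break toward the lower class index. Class index 1 (the first score
#' channel) maps to label 0 (background).
#'
#' @param scores numeric array `(n_classes, x, y, z)`.
#' @return Integer array `(x, y, z)` with values `0..n_classes-1`.
#' @export
argmax_scores <- function(scores) {
  d <- dim(scores)
  C <- d[1]
  best <- array(scores[1, , , ], dim = d[2:4])
  idx <- array(0L, dim = d[2:4])
  for (c in seq_len(C - 1L)) {
    sc <- array(scores[c + 1L, , , ], dim = d[2:4])
    better <- sc > best
    best[better] <- sc[better]
    idx[better] <- c
  }
  idx
}

#' Per-channel z-score normalization over foreground
#'
#' Channel intensities are standardized using the mean and standard
#' deviation over foreground voxels (voxels where any channel is non-zero);
#' the transform is then applied to the whole lattice. Channels that are
#' constant over the foreground are zeroed.
#'
#' @param maps a `scalar_map_set` or list of 3-D numeric arrays.
#' @return A list of normalized 3-D arrays, named as the input channels.
#' @export
normalize_channels <- function(maps) {
  chans <- if (inherits(maps, "scalar_map_set"))
    lapply(maps$maps, `[[`, "values") else maps
  fg <- Reduce(`|`, lapply(chans, function(a) a != 0))
  lapply(chans, function(a) {
    if (!any(fg)) return(a * 0)
    m <- mean(a[fg]); s <- stats::sd(a[fg])
    if (!is.finite(s) || s == 0) return(a * 0)
    (a - m) / s
  })
}

check_channel_contract <- function(model, channel_names) {
  if (!is.null(model$channels) &&
      !identical(model$channels, channel_names))
    warning(sprintf(
      "channel order (%s) differs from the model's training contract (%s); predictions are undefined",
      paste(channel_names, collapse = ","),
      paste(model$channels, collapse = ",")))
  invisible(TRUE)
}

#' Coarse-stage inference
#'
#' Normalizes the four-map channel stack, runs sliding-window prediction
#' with the coarse model (8 classes: background + 7 compartments), and takes
#' the voxel-wise argmax.
#'
#' @param maps a `scalar_map_set` with the model's four channels.
#' @param model the trained coarse model.
#' @param config an [inference_config()].
#' @return A [label_volume()] with namespace `"coarse"`.
#' @export
run_coarse <- function(maps, model, config = inference_config()) {
  stopifnot(inherits(maps, "scalar_map_set"))
  check_channel_contract(model, names(maps$maps))
  chans <- normalize_channels(maps)
  scores <- sliding_window_predict(model, chans, config)
  label_volume(argmax_scores(scores), maps$grid, namespace = "coarse")
}

#' Fine-stage inference for all non-terminal groups
#'
#' Each of the five group models receives a five-channel input: the four
#' normalized diffusion maps plus the coarse segmentation mask scaled to
#' `[0, 1]` (see [group_channel()]). Each model's argmax output is mapped
#' back to the group's final label ids. Terminal groups (single-label
#' white matter) are bypassed: their labels come straight from the coarse
#' stage at merge time.
#'
#' @param maps a `scalar_map_set` with the four diffusion channels.
#' @param coarse the coarse [label_volume()].
#' @param h a `label_hierarchy`.
#' @param models named list of trained models, one per non-terminal group
#'   (names are group names).
#' @param config an [inference_config()].
#' @return Named list of [label_volume()]s (namespace `"fine"`), one per
#'   non-terminal group, each containing only that group's final ids.
#' @export
run_fine <- function(maps, coarse, h, models, config = inference_config()) {
  stopifnot(inherits(maps, "scalar_map_set"),
            inherits(coarse, "label_volume"))
  nt <- nonterminal_groups(h)
  nt_names <- vapply(nt, `[[`, character(1), "name")
  extra <- setdiff(names(models), nt_names)
  if (length(extra))
    stop(sprintf("model(s) supplied for terminal or unknown group(s): %s",
                 paste(extra, collapse = ", ")))
  missing_m <- setdiff(nt_names, names(models))
  if (length(missing_m))
    stop(sprintf("missing model(s) for non-terminal group(s): %s",
                 paste(missing_m, collapse = ", ")))
  base <- normalize_channels(maps)
  mask_chan <- group_channel(coarse)$values
  out <- list()
  for (g in nt) {
    model <- models[[g$name]]
    chans <- c(base, list(coarse_mask = mask_chan))
    if (model$n_in_channels != length(chans))
      stop(sprintf("expected %d channels, got %d for group '%s'",
                   model$n_in_channels, length(chans), g$name))
    check_channel_contract(model, names(chans))
    scores <- sliding_window_predict(model, chans, config)
    cls <- argmax_scores(scores)
    ids <- sort(g$final_ids)
    lab <- array(0L, dim = dim(cls))
    nz <- cls > 0L
    lab[nz] <- ids[cls[nz]]
    out[[g$name]] <- label_volume(lab, maps$grid, namespace = "fine")
  }
  out
}
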