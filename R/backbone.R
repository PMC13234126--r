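#' Tiny reference segmentation backbone
#'
#' The training and inference engine is backbone-agnostic: any object
#' implementing [predict_scores()] (and [train_step()] if it is to be
#' trained) can be plugged in. This reference backbone is a voxel-wise
#' multilayer perceptron applied convolutionally (a stack of 1x1x1
#' convolutions): each voxel's class scores are computed from its channel
#' intensities plus a Fourier positional encoding of the voxel's location
#' within the patch (normalized coordinates and sines/cosines at a few
#' spatial frequencies). The positional encoding gives the otherwise
#' receptive-field-1 network the spatial context needed to separate
#' compartments with identical tissue contrast (left vs right, sectors of a
#' ribbon), while keeping the parameter count tiny (well under 100k) and
#' training CPU-friendly. Because the encoding is patch-relative, the
#' backbone is intended to be trained and applied with a patch spanning the
#' full volume; with `use_coords = FALSE` it degenerates to a pure
#' receptive-field-1 intensity classifier usable at any patch size.
#'
#' @param n_in_channels number of input channels (4 for the coarse stage,
#'   5 for the fine stage).
#' @param n_classes number of output classes including background.
#' @param hidden width of the hidden layer.
#' @param freqs spatial frequencies (cycles per patch) of the positional
#'   encoding.
#' @param use_coords include the positional encoding (default `TRUE`).
#' @param channels optional character vector recording the channel-order
#'   contract the model is trained under.
#' @param seed seed for the parameter initialization.
#' @return An object of class `mlp_backbone`.
#' @export
mlp_backbone <- function(n_in_channels, n_classes, hidden = 96,
                         freqs = c(1, 2, 3, 4, 6, 8, 12, 16),
                         use_coords = TRUE, channels = NULL, seed = 1) {
  n_feat <- n_in_channels + if (use_coords) 3 + 6 * length(freqs) else 0
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(hidden * n_feat, sd = sqrt(1 / n_feat)), hidden, n_feat),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(n_classes * hidden, sd = sqrt(1 / hidden)),
                n_classes, hidden),
    b2 = numeric(n_classes)))
  velocity <- lapply(params, function(p) p * 0)
  structure(list(n_in_channels = as.integer(n_in_channels),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), freqs = freqs,
                 use_coords = use_coords, channels = channels,
                 params = params, velocity = velocity),
            class = "mlp_backbone")
}

#' @export
print.mlp_backbone <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("mlp_backbone: %d channels -> %d hidden -> %d classes (%d parameters%s)\n",
              x$n_in_channels, x$hidden, x$n_classes, np,
              if (x$use_coords) ", positional encoding" else ""))
  invisible(x)
}

# feature matrix for the voxels 'idx' (linear indices) of a patch with
# spatial dims 'pdim'; 'xmat' is the nvox x C channel matrix
backbone_features <- function(model, xmat, pdim, idx) {
  X <- xmat[idx, , drop = FALSE]
  if (!model$use_coords) return(X)
  i0 <- (idx - 1L) %% pdim[1]
  j0 <- ((idx - 1L) %/% pdim[1]) %% pdim[2]
  k0 <- (idx - 1L) %/% (pdim[1] * pdim[2])
  u <- cbind(if (pdim[1] > 1) i0 / (pdim[1] - 1) - 0.5 else i0 * 0,
             if (pdim[2] > 1) j0 / (pdim[2] - 1) - 0.5 else j0 * 0,
             if (pdim[3] > 1) k0 / (pdim[3] - 1) - 0.5 else k0 * 0)
  enc <- list(X, u)
  for (f in model$freqs) {
    enc[[length(enc) + 1L]] <- sin(2 * pi * f * u)
    enc[[length(enc) + 1L]] <- cos(2 * pi * f * u)
  }
  do.call(cbind, enc)
}

backbone_forward <- function(model, X) {
  A <- tcrossprod(X, model$params$W1)
  A <- sweep(A, 2, model$params$b1, "+")
  H <- tanh(A)
  Z <- tcrossprod(H, model$params$W2)
  Z <- sweep(Z, 2, model$params$b2, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  list(H = H, P = P)
}

#' Per-class scores of a model on a channel patch
#'
#' Generic prediction surface of the segmentation-model contract: given a
#' channel patch of shape `(n_in_channels, px, py, pz)`, returns non-negative
#' per-class scores of shape `(n_classes, px, py, pz)` summing to 1 at every
#' voxel.
#'
#' @param model a segmentation model (e.g. [mlp_backbone()]).
#' @param patch numeric array `(channels, x, y, z)`.
#' @return Numeric array `(n_classes, x, y, z)`.
#' @export
predict_scores <- function(model, patch) UseMethod("predict_scores")

#' @export
predict_scores.mlp_backbone <- function(model, patch) {
  d <- dim(patch)
  if (length(d) != 4L || d[1] != model$n_in_channels)
    stop(sprintf("expected %d channels, got %s", model$n_in_channels,
                 if (length(d) == 4L) d[1] else "a non-4-D patch"))
  pdim <- d[2:4]
  nvox <- prod(pdim)
  xmat <- t(matrix(patch, nrow = d[1]))
  X <- backbone_features(model, xmat, pdim, seq_len(nvox))
  P <- backbone_forward(model, X)$P
  array(t(P), dim = c(model$n_classes, pdim))
}

#' One optimization step of a trainable model
#'
#' Generic training surface of the segmentation-model contract. The
#' reference backbone subsamples voxels from the patch (half drawn from
#' foreground when available), evaluates the composite Dice +
#' cross-entropy objective on them, and takes one SGD-with-momentum step.
#'
#' @param model a trainable segmentation model.
#' @param patch channel patch `(channels, x, y, z)`.
#' @param target integer array `(x, y, z)` of class indices in
#'   `0..n_classes-1`.
#' @param lr learning rate for this step.
#' @param loss `"dice_ce"` or `"dice_wce"`.
#' @param class_weights optional per-class weight vector (length
#'   `n_classes`) for the weighted cross-entropy term.
#' @param sample_voxels number of voxels per step (reference backbone).
#' @param rng a `function(n)` returning `n` uniform deviates, used for all
#'   randomness so training is reproducible.
#' @return `list(model = updated model, loss = objective value)`.
#' @export
train_step <- function(model, patch, target, lr, loss = "dice_ce",
                       class_weights = NULL, sample_voxels = 8192,
                       rng = stats::runif) UseMethod("train_step")

#' @export
train_step.mlp_backbone <- function(model, patch, target, lr,
                                    loss = "dice_ce", class_weights = NULL,
                                    sample_voxels = 8192,
                                    rng = stats::runif) {
  d <- dim(patch)
  if (d[1] != model$n_in_channels)
    stop(sprintf("expected %d channels, got %d", model$n_in_channels, d[1]))
  pdim <- d[2:4]
  nvox <- prod(pdim)
  y <- as.integer(target)
  # half uniform, half foreground (when present)
  n_s <- min(sample_voxels, nvox)
  idx <- ceiling(rng(n_s) * nvox)
  fg <- which(y > 0L)
  if (length(fg) > 0L) {
    nf <- n_s %/% 2L
    idx[seq_len(nf)] <- fg[ceiling(rng(nf) * length(fg))]
  }
  xmat <- t(matrix(patch, nrow = d[1]))
  X <- backbone_features(model, xmat, pdim, idx)
  ys <- y[idx]
  fwd <- backbone_forward(model, X)
  P <- fwd$P; H <- fwd$H
  n <- nrow(P); C <- model$n_classes
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), ys + 1L)] <- 1

  w <- if (loss == "dice_wce" && !is.null(class_weights))
    class_weights else rep(1, C)
  wv <- w[ys + 1L]
  eps <- 1e-5
  py <- pmax(P[cbind(seq_len(n), ys + 1L)], 1e-12)
  ce <- mean(wv * -log(py))
  # soft Dice over foreground classes present in target or prediction
  sp <- colSums(P); sy <- colSums(Y)
  inter <- colSums(P * Y)
  fgc <- which(seq_len(C) > 1 & (sp + sy) > 0)
  if (length(fgc)) {
    A <- sp[fgc] + sy[fgc] + eps
    dice <- 2 * inter[fgc] / A
    dloss <- 1 - mean(dice)
  } else dloss <- 0
  total <- ce + dloss

  # gradient wrt logits: CE part
  Gz <- (P - Y) * (wv / n)
  # Dice part via dL/dP chained through softmax
  if (length(fgc)) {
    Gp <- matrix(0, n, C)
    m <- length(fgc)
    A <- sp[fgc] + sy[fgc] + eps
    N2 <- 2 * inter[fgc]
    # d(1 - mean dice)/dP[v,c] = -(2 Y[v,c] A_c - N_c) / (m A_c^2)
    Gp[, fgc] <- sweep(sweep(2 * Y[, fgc, drop = FALSE], 2, A, "*"),
                       2, N2, "-")
    Gp[, fgc] <- -sweep(Gp[, fgc, drop = FALSE], 2, m * A^2, "/")
    Gz <- Gz + P * (Gp - rowSums(Gp * P))
  }

  gW2 <- crossprod(Gz, H)
  gb2 <- colSums(Gz)
  dH <- Gz %*% model$params$W2
  dA <- dH * (1 - H^2)
  gW1 <- crossprod(dA, X)
  gb1 <- colSums(dA)

  mu <- 0.9
  g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  for (nm in names(g)) {
    model$velocity[[nm]] <- mu * model$velocity[[nm]] - lr * g[[nm]]
    model$params[[nm]] <- model$params[[nm]] + model$velocity[[nm]]
  }
  list(model = model, loss = total)
}
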