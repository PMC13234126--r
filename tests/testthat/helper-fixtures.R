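# Shared fixtures and independent oracles used across the suite.

# independent breadth-first flood fill (26- or 6-connectivity); the package
# uses iterative minimum-label propagation, so this is a genuinely separate
# route to the same partition
bfs_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  comp <- array(0L, d)
  nextid <- 0L
  for (s in which(mask)) {
    if (comp[s] > 0L) next
    nextid <- nextid + 1L
    queue <- s
    comp[s] <- nextid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ai <- arrayInd(v, d)
      for (t in seq_len(nrow(offs))) {
        p <- ai + offs[t, ]
        if (all(p >= 1) && all(p <= d) && mask[p[1], p[2], p[3]] &&
            comp[p[1], p[2], p[3]] == 0L) {
          comp[p[1], p[2], p[3]] <- nextid
          queue <- c(queue, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
        }
      }
    }
  }
  comp
}

# do two component labelings describe the same partition of the mask?
same_partition <- function(a, b, mask) {
  pa <- a[mask]; pb <- b[mask]
  length(unique(paste(pa, pb))) == length(unique(pa)) &&
    length(unique(pa)) == length(unique(pb))
}

# forward diffusion signal from an explicit 3x3 tensor (independent of the
# package's axially-symmetric shortcut)
forward_signal <- function(D, s0, bvals, bvecs) {
  vapply(seq_along(bvals), function(i) {
    g <- bvecs[i, ]
    s0 * exp(-bvals[i] * as.numeric(t(g) %*% D %*% g))
  }, numeric(1))
}

# a uniform-gradient scheme with a baseline: n directions plus b = 0
scheme <- function(n, bval = 1000) {
  dirs <- dkparc::sphere_directions(n)
  list(bvals = c(0, rep(bval, n)), bvecs = rbind(c(0, 0, 0), dirs))
}

# a DWI series whose every voxel carries the same tensor
uniform_dwi <- function(D, s0 = 100, n_dir = 12, shape = c(3, 3, 3)) {
  sch <- scheme(n_dir)
  sig <- forward_signal(D, s0, sch$bvals, sch$bvecs)
  arr <- array(rep(sig, each = prod(shape)), c(shape, length(sig)))
  dwi_series(arr, volume_grid(shape), sch$bvals, sch$bvecs)
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# a voxel-wise (receptive-field-1) score model whose prediction depends only
# on the first channel's intensity: class scores softmax(c * x). Registered
# as a predict_scores method so the engine can drive it.
rf1_model <- function(n_classes, n_in_channels = 1) {
  structure(list(n_in_channels = n_in_channels, n_classes = n_classes),
            class = "rf1_model")
}
predict_scores.rf1_model <- function(model, patch) {
  d <- dim(patch)
  x <- array(patch[1, , , ], dim = d[2:4])
  z <- vapply(seq_len(model$n_classes), function(c) c * x,
              array(0, dim = d[2:4]))
  z <- aperm(z, c(4, 1, 2, 3))
  z <- exp(z - rep(apply(z, 2:4, max), each = model$n_classes))
  z / rep(apply(z, 2:4, sum), each = model$n_classes)
}
.S3method("predict_scores", "rf1_model", predict_scores.rf1_model)

# a model that always outputs the same score vector
const_model <- function(scores) {
  structure(list(n_in_channels = 1L, n_classes = length(scores),
                 scores = scores), class = "const_model")
}
predict_scores.const_model <- function(model, patch) {
  d <- dim(patch)[2:4]
  array(rep(model$scores, times = prod(d)), dim = c(model$n_classes, d))
}
.S3method("predict_scores", "const_model", predict_scores.const_model)
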