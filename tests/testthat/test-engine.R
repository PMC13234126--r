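test_that("dice_ce_loss hits its closed-form values", {
  d <- c(3, 3, 3)
  target <- array(sample(0:2, 27, TRUE), d)
  onehot <- array(0, c(3, d))
  for (v in 1:27) onehot[target[v] + 1L, arrayInd(v, d)[1],
                         arrayInd(v, d)[2], arrayInd(v, d)[3]] <- 1
  expect_lt(dice_ce_loss(onehot, target), 1e-4)   # perfect prediction
  # uniform scores, all-background target: CE term is exactly log K, and
  # each foreground class is predicted but absent, so the Dice term is 1
  K <- 4
  uni <- array(1 / K, c(K, d))
  tgt0 <- array(0L, d)
  expect_equal(dice_ce_loss(uni, tgt0), log(K) + 1, tolerance = 1e-12)
  # symmetry under permutations of the foreground classes (background fixed,
  # since it is excluded from the Dice mean)
  perm <- c(0L, 2L, 1L)
  target_p <- array(perm[target + 1L], d)
  scores <- array(runif(3 * 27), c(3, d))
  scores <- scores / rep(apply(scores, 2:4, sum), each = 3)
  scores_p <- array(scores[match(0:2, perm), , , , drop = FALSE], c(3, d))
  expect_equal(dice_ce_loss(scores, target),
               dice_ce_loss(scores_p, target_p), tolerance = 1e-12)
  expect_error(dice_ce_loss(scores, array(0L, c(2, 2, 2))), "disagree")
  expect_error(dice_ce_loss(scores, array(5L, d)), "0..n_classes")
})

test_that("weighted cross-entropy scales per-voxel contributions", {
  d <- c(2, 2, 2)
  target <- array(c(rep(0L, 4), rep(1L, 4)), d)
  scores <- array(0, c(2, d))
  scores[1, , , ] <- 0.5; scores[2, , , ] <- 0.5
  base <- dice_ce_loss(scores, target)
  up <- dice_ce_loss(scores, target, class_weights = c(1, 3))
  # half the voxels carry weight 3 instead of 1 in the CE term (log 2 each)
  expect_equal(up - base, 0.5 * 2 * log(2), tolerance = 1e-10)
})

test_that("patch sampling is deterministic, oversamples foreground, and pads edges", {
  d <- c(10, 10, 10)
  target <- array(0L, d)
  target[1:5, 1:4, 1:5] <- 1L      # 10% foreground
  chans <- list(array(runif(1000), d))
  s1 <- patch_sampler(chans, target, patch_size = 4, seed = 99)
  s2 <- patch_sampler(chans, target, patch_size = 4, seed = 99)
  draws1 <- replicate(20, s1()$origin)
  draws2 <- replicate(20, s2()$origin)
  expect_identical(draws1, draws2)
  # foreground-containing fraction over many draws
  s3 <- patch_sampler(chans, target, patch_size = 4, seed = 7)
  hits <- vapply(1:1000, function(i) any(s3()$y > 0L), logical(1))
  expect_gte(mean(hits), 0.5)
  # all-background volumes still produce patches
  s4 <- patch_sampler(chans, array(0L, d), patch_size = 4, seed = 1)
  p <- s4()
  expect_identical(dim(p$x), c(1L, 4L, 4L, 4L))
  expect_true(all(p$y == 0L))
  # patch larger than the volume: single zero-padded patch
  s5 <- patch_sampler(chans, target, patch_size = 16, seed = 1)
  p5 <- s5()
  expect_identical(dim(p5$y), rep(16L, 3))
  expect_identical(p5$y[1:10, 1:10, 1:10], target)
  expect_true(all(p5$y[11:16, , ] == 0L))
})

test_that("train_stage validates channels and is inert at zero iterations", {
  m <- mlp_backbone(5, 3, hidden = 8, seed = 1)
  chans4 <- replicate(4, array(0, c(4, 4, 4)), simplify = FALSE)
  expect_error(train_stage(m, chans4, array(0L, c(4, 4, 4))),
               "expected 5 channels")
  m4 <- mlp_backbone(4, 3, hidden = 8, seed = 1)
  out <- train_stage(m4, chans4, array(0L, c(4, 4, 4)),
                     train_config(patch_size = 4, iterations = 0))
  expect_identical(out$model$params, m4$params)
  expect_length(out$trace, 0)
})

test_that("training on a separable toy volume drives the loss down deterministically", {
  set.seed(4)
  d <- c(8, 8, 8)
  x <- array(rnorm(prod(d)), d)
  target <- array(as.integer(x > 0), d)
  m <- mlp_backbone(1, 2, hidden = 8, use_coords = FALSE, seed = 2)
  cfg <- train_config(patch_size = 8, iterations = 60, lr = 0.3, seed = 3,
                      sample_voxels = 512)
  f1 <- train_stage(m, list(x), target, cfg)
  f2 <- train_stage(m, list(x), target, cfg)
  expect_identical(f1$model$params, f2$model$params)   # seeded determinism
  expect_lt(mean(tail(f1$trace, 10)), mean(head(f1$trace, 10)))
  # the weighted variant runs and also learns
  fw <- train_stage(m, list(x), target,
                    train_config(patch_size = 8, iterations = 60, lr = 0.3,
                                 seed = 3, sample_voxels = 512,
                                 loss = "dice_wce"))
  expect_lt(mean(tail(fw$trace, 10)), mean(head(fw$trace, 10)))
})

test_that("sliding-window scores stay on the simplex and constants pass through", {
  cm <- const_model(c(0.5, 0.3, 0.2))
  chans <- list(array(runif(6 * 7 * 9), c(6, 7, 9)))
  sc <- sliding_window_predict(cm, chans,
                               inference_config(patch_size = 4,
                                                overlap_fraction = 0.5))
  expect_identical(dim(sc), c(3L, 6L, 7L, 9L))
  expect_lt(max(abs(apply(sc, 2:4, sum) - 1)), 1e-5)
  expect_lt(max(abs(sc[1, , , ] - 0.5)), 1e-10)   # weighting cancels
  # volume smaller than the patch: one padded window, cropped back
  sc2 <- sliding_window_predict(cm, list(array(0, c(3, 3, 3))),
                                inference_config(patch_size = 8))
  expect_identical(dim(sc2), c(3L, 3L, 3L, 3L))
})

test_that("windowed prediction equals full-volume prediction for a voxel-wise model", {
  set.seed(12)
  m <- rf1_model(n_classes = 4)
  chans <- list(array(rnorm(9 * 8 * 7), c(9, 8, 7)))
  full <- predict_scores(m, array(chans[[1]], c(1, 9, 8, 7)))
  win <- sliding_window_predict(m, chans,
                                inference_config(patch_size = 4,
                                                 overlap_fraction = 0.5))
  expect_identical(argmax_scores(win), argmax_scores(full))
  # and with an untrained reference backbone restricted to intensities
  mb <- mlp_backbone(1, 3, hidden = 6, use_coords = FALSE, seed = 5)
  fullb <- predict_scores(mb, array(chans[[1]], c(1, 9, 8, 7)))
  winb <- sliding_window_predict(mb, chans,
                                 inference_config(patch_size = 5,
                                                  overlap_fraction = 0.5))
  expect_identical(argmax_scores(winb), argmax_scores(fullb))
})

test_that("argmax breaks ties toward the lower class id", {
  sc <- array(0, c(3, 1, 1, 1))
  sc[, 1, 1, 1] <- c(0.4, 0.4, 0.2)
  expect_identical(argmax_scores(sc)[1, 1, 1], 0L)
  sc[, 1, 1, 1] <- c(0.2, 0.4, 0.4)
  expect_identical(argmax_scores(sc)[1, 1, 1], 1L)
})

test_that("run_fine enforces the five-model contract and label restriction", {
  spec <- phantom_spec(grid_size = 24, n_directions = 8)
  ph <- generate_phantom(spec)
  maps <- assemble_maps(fit_tensor(ph$dwi))
  h <- spec$hierarchy
  mk <- function(n_cls) mlp_backbone(5, n_cls, hidden = 4, seed = 1)
  nt <- Filter(function(g) !g$terminal, h$groups)
  models <- setNames(lapply(nt, function(g) mk(length(g$final_ids) + 1L)),
                     vapply(nt, `[[`, character(1), "name"))
  expect_error(run_fine(maps, ph$coarse, h, models[-1]), "missing model")
  bad <- c(models, list(lh_cerebral_wm = mk(2)))
  expect_error(run_fine(maps, ph$coarse, h, bad), "terminal or unknown")
  out <- run_fine(maps, ph$coarse, h, models,
                  inference_config(patch_size = 24))
  expect_length(out, 5)
  for (g in nt) {
    ids <- sort(unique(as.vector(out[[g$name]]$labels)))
    expect_true(all(ids %in% c(0L, g$final_ids)))
  }
  # all-background coarse mask: the mask channel is zero but outputs remain
  # restricted to the group's namespace
  empty <- label_volume(array(0L, dim(ph$coarse$labels)), ph$coarse$grid,
                        namespace = "coarse")
  out0 <- run_fine(maps, empty, h, models, inference_config(patch_size = 24))
  expect_length(out0, 5)
  # channel count mismatch is refused
  models4 <- models
  models4[[1]] <- mlp_backbone(4, length(nt[[1]]$final_ids) + 1L,
                               hidden = 4, seed = 1)
  expect_error(run_fine(maps, ph$coarse, h, models4), "expected 4 channels")
})

test_that("a model warns when fed channels that break its training contract", {
  m <- mlp_backbone(4, 8, hidden = 4, channels = c("T", "F", "CS", "E1"),
                    seed = 1)
  spec <- phantom_spec(grid_size = 24, n_directions = 8)
  ph <- generate_phantom(spec)
  maps_perm <- assemble_maps(fit_tensor(ph$dwi), c("F", "T", "CS", "E1"))
  expect_warning(run_coarse(maps_perm, m, inference_config(patch_size = 24)),
                 "contract")
})
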