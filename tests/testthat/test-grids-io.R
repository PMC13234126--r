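test_that("NIfTI round trips preserve lattices and affines", {
  td <- withr::local_tempdir()
  g <- volume_grid(c(5, 6, 7), spacing = c(1.5, 2, 1),
                   affine = rbind(c(0, -2, 0, 4), c(1.5, 0, 0, -3),
                                  c(0, 0, 1, 9), c(0, 0, 0, 1)))
  set.seed(3)
  sv <- scalar_volume(array(rnorm(210), c(5, 6, 7)), g)
  f <- file.path(td, "s.nii.gz")
  write_volume(sv, f)
  sv2 <- read_volume(f)
  expect_identical(sv2$values, sv$values)      # 64-bit storage is lossless
  expect_lt(max(abs(sv2$grid$affine - g$affine)), 1e-6)

  lv <- label_volume(array(sample(0:4, 210, TRUE), c(5, 6, 7)), g,
                     namespace = "coarse")
  f2 <- file.path(td, "l.nii")
  write_volume(lv, f2)
  lv2 <- read_volume(f2, as = "label", namespace = "coarse")
  expect_identical(lv2$labels, lv$labels)
  expect_identical(lv2$namespace, "coarse")
  expect_true(all(lv2$labels >= 0L))
})

test_that("volumes with non-finite or negative content are rejected", {
  g <- volume_grid(c(2, 2, 2))
  bad <- array(1, c(2, 2, 2)); bad[1] <- NaN
  expect_error(scalar_volume(bad, g), "non-finite")
  expect_error(label_volume(array(-1L, c(2, 2, 2)), g), "non-negative")
  td <- withr::local_tempdir()
  f <- file.path(td, "nan.nii.gz")
  img <- RNifti::asNifti(array(c(NaN, rep(1, 7)), c(2, 2, 2)))
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "non-finite")
})

test_that("read_dwi parses FSL bval/bvec dialects and validates counts", {
  td <- withr::local_tempdir()
  sch <- scheme(64)
  sig <- array(runif(4 * 4 * 4 * 65, 1, 2), c(4, 4, 4, 65))
  dwi <- dwi_series(sig, volume_grid(c(4, 4, 4)), sch$bvals, sch$bvecs)
  f <- file.path(td, "d.nii.gz")
  write_dwi(dwi, f)
  d2 <- read_dwi(f, file.path(td, "d.bval"), file.path(td, "d.bvec"))
  expect_equal(length(d2$bvals), 65)           # 1 baseline + 64 directions
  expect_equal(sum(d2$bvals <= 50), 1)
  expect_lt(max(abs(d2$bvecs - sch$bvecs)), 1e-6)

  # 3-column layout is auto-detected
  bv3col <- file.path(td, "cols.bvec")
  write.table(sch$bvecs, bv3col, row.names = FALSE, col.names = FALSE)
  d3 <- read_dwi(f, file.path(td, "d.bval"), bv3col)
  expect_lt(max(abs(d3$bvecs - sch$bvecs)), 1e-6)

  # count mismatch between files
  writeLines(paste(sch$bvals[-1], collapse = " "), file.path(td, "short.bval"))
  expect_error(read_dwi(f, file.path(td, "short.bval"),
                        file.path(td, "d.bvec")), "mismatch")
})

test_that("a series without enough directions or baseline is rejected", {
  g <- volume_grid(c(2, 2, 2))
  sig5 <- array(1, c(2, 2, 2, 6))
  sch5 <- scheme(5)
  expect_error(dwi_series(sig5, g, sch5$bvals, sch5$bvecs), "insufficient")
  sch6 <- scheme(6)
  expect_error(dwi_series(array(1, c(2, 2, 2, 6)), g, sch6$bvals[-1],
                          sch6$bvecs[-1, ]), "baseline")
  # zero b-vectors on baseline volumes are fine
  expect_s3_class(dwi_series(array(1, c(2, 2, 2, 7)), g, sch6$bvals,
                             sch6$bvecs), "dwi_series")
})

test_that("resample is the identity on the same grid and matches the affine oracle", {
  set.seed(11)
  rand_affine <- function() {
    M <- qr.Q(qr(matrix(rnorm(9), 3))) %*% diag(runif(3, 0.8, 2))
    A <- diag(4); A[1:3, 1:3] <- M; A[1:3, 4] <- rnorm(3, sd = 3); A
  }
  for (rep in 1:4) {
    gs <- volume_grid(c(7, 6, 5), affine = rand_affine())
    gt <- volume_grid(c(6, 7, 6), affine = rand_affine())
    lab <- array(0L, c(7, 6, 5))
    lab[sample(210, 25)] <- sample.int(5, 25, TRUE)
    lv <- label_volume(lab, gs)
    out <- resample(lv, gt, "nearest")
    expect_identical(resample(lv, gs, "nearest")$labels, lab)
    # oracle: direct per-voxel affine arithmetic
    Minv <- solve(gs$affine)
    oracle <- array(0L, gt$shape)
    for (k in 0:(gt$shape[3] - 1)) for (j in 0:(gt$shape[2] - 1))
      for (i in 0:(gt$shape[1] - 1)) {
        s <- round((Minv %*% gt$affine %*% c(i, j, k, 1))[1:3])
        if (all(s >= 0) && all(s < gs$shape))
          oracle[i + 1, j + 1, k + 1] <- lab[s[1] + 1, s[2] + 1, s[3] + 1]
      }
    expect_identical(out$labels, oracle)
  }
})

test_that("nearest resampling commutes with bijective relabeling and inverts 2x upsampling", {
  g1 <- volume_grid(c(6, 6, 6))
  lab <- array(sample(0:3, 216, TRUE), c(6, 6, 6))
  lv <- label_volume(lab, g1)
  g2 <- volume_grid(c(12, 12, 12), spacing = c(0.5, 0.5, 0.5),
                    affine = {
                      A <- diag(4); diag(A)[1:3] <- 0.5
                      A[1:3, 4] <- g1$affine[1:3, 4] - 0.25; A
                    })
  up <- resample(lv, g2, "nearest")
  down <- resample(up, g1, "nearest")
  expect_identical(down$labels, lab)
  # relabeling commutes
  perm <- c(0L, 7L, 5L, 9L)
  relab <- function(v) label_volume(array(perm[v$labels + 1L], dim(v$labels)),
                                    v$grid, namespace = v$namespace)
  expect_identical(resample(relab(lv), g2, "nearest")$labels,
                   relab(up)$labels)
  expect_error(resample(lv, g2, "trilinear"), "not defined for label")
})

test_that("conform produces the requested cube and inverts cleanly on labels", {
  native <- volume_grid(c(32, 32, 32), spacing = c(2, 2, 2))
  ph <- generate_labels(phantom_spec(grid_size = 32))
  lv <- label_volume(ph$labels, native)
  conf <- conform(lv, size = 64, spacing = 1)
  expect_identical(conf$grid$shape, rep(64L, 3))
  expect_equal(conf$grid$spacing, rep(1, 3))
  expect_identical(conf$grid$orientation, "LIA")
  expect_identical(conform(conf, size = 64, spacing = 1), conf)  # idempotent
  back <- resample(conf, native, "nearest")
  inside <- lv$labels > 0L
  expect_gte(mean(back$labels[inside] == lv$labels[inside]), 0.99)
  # grid metadata round-trips exactly
  expect_identical(back$grid$shape, native$shape)
  expect_lt(max(abs(back$grid$affine - native$affine)), 1e-12)
})

test_that("grid validation catches degenerate geometry", {
  expect_error(volume_grid(c(2, 2), spacing = c(1, 1, 1)), "3 positive")
  expect_error(volume_grid(c(2, 2, 2), spacing = c(1, -1, 1)), "positive")
  A <- diag(4); A[1, 1] <- 0
  expect_error(volume_grid(c(2, 2, 2), affine = A), "invertible")
  expect_identical(orientation_code(diag(4)), "RAS")
  A2 <- diag(4); A2[1, 1] <- -1; A2[2, 2] <- 0; A2[3, 2] <- -1
  A2[2, 3] <- 1; A2[3, 3] <- 0
  expect_identical(orientation_code(A2), "LIA")
})
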