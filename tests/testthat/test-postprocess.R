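# hand-built 5^3 scene used by several tests: coarse compartment 3 occupies
# a 10-voxel bar; the fine segmentation puts 7 voxels inside it and 3 outside
make_restrict_fixture <- function() {
  g <- volume_grid(c(5, 5, 5))
  coarse <- array(0L, c(5, 5, 5))
  coarse[1:5, 2, 2] <- 3L
  coarse[1:5, 3, 2] <- 3L
  fine <- array(0L, c(5, 5, 5))
  fine[1:4, 2, 2] <- 10L          # 4 inside
  fine[1:3, 3, 2] <- 11L          # 3 inside
  fine[1:3, 4, 2] <- 11L          # 3 outside the compartment
  list(grid = g,
       coarse = label_volume(coarse, g, namespace = "coarse"),
       fine = list(lh_deep = label_volume(fine, g, namespace = "fine")))
}

test_that("restrict_to_coarse removes exactly the voxels outside the compartment", {
  fx <- make_restrict_fixture()
  h <- default_hierarchy()
  out <- restrict_to_coarse(fx$fine, fx$coarse, h)
  expect_identical(sum(out$lh_deep$labels > 0L), 7L)
  expect_identical(out$lh_deep$labels[1:4, 2, 2], rep(10L, 4))
  expect_identical(out$lh_deep$labels[1:3, 3, 2], rep(11L, 3))
  expect_true(all(out$lh_deep$labels[, 4, ] == 0L))
  # monotone: counts never increase
  expect_lte(sum(out$lh_deep$labels == 10L), sum(fx$fine$lh_deep$labels == 10L))
  # a fine volume already inside its mask is unchanged
  again <- restrict_to_coarse(out, fx$coarse, h)
  expect_identical(again$lh_deep$labels, out$lh_deep$labels)
})

test_that("dilate_fill follows the majority / lowest-id rule, oracle-checked", {
  g <- volume_grid(c(3, 3, 3))
  h <- default_hierarchy()
  coarse <- label_volume(array(3L, c(3, 3, 3)), g, namespace = "coarse")
  # gap voxel at the center; 2 neighbors vote 9, 1 votes 4 -> majority 9
  lab <- array(0L, c(3, 3, 3))
  lab[1, 2, 2] <- 4L; lab[3, 2, 2] <- 9L; lab[3, 3, 3] <- 9L
  out <- dilate_fill(list(lh_deep = label_volume(lab, g, "fine")), coarse, h,
                     max_iters = 1)
  # oracle: exhaustive 26-neighbor count at the center voxel
  votes <- table(lab[-14][lab[-14] > 0])
  expect_identical(out$lh_deep$labels[2, 2, 2],
                   as.integer(names(votes)[which.max(votes)]))
  expect_identical(out$lh_deep$labels[2, 2, 2], 9L)
  # equal votes tie toward the lower id
  lab2 <- array(0L, c(3, 3, 3))
  lab2[1, 2, 2] <- 9L; lab2[3, 2, 2] <- 4L
  out2 <- dilate_fill(list(lh_deep = label_volume(lab2, g, "fine")), coarse,
                      h, max_iters = 1)
  expect_identical(out2$lh_deep$labels[2, 2, 2], 4L)
  # never overwrites labels, never crosses the coarse mask
  coarse_part <- array(0L, c(3, 3, 3)); coarse_part[1:2, , ] <- 3L
  outp <- dilate_fill(list(lh_deep = label_volume(lab2, g, "fine")),
                      label_volume(coarse_part, g, "coarse"), h,
                      max_iters = 5)
  expect_identical(outp$lh_deep$labels[1, 2, 2], 9L)
  expect_true(all(outp$lh_deep$labels[3, , ] == lab2[3, , ]))
  # volumes with no background inside the mask are untouched
  full <- array(7L, c(3, 3, 3))
  outf <- dilate_fill(list(lh_deep = label_volume(full, g, "fine")), coarse,
                      h, max_iters = 3)
  expect_identical(outf$lh_deep$labels, full)
})

test_that("connected components match an independent flood fill", {
  set.seed(17)
  for (rep in 1:6) {
    mask <- array(runif(8 * 7 * 6) < 0.35, c(8, 7, 6))
    comp <- connected_components(mask)
    oracle <- bfs_components(mask)
    expect_true(same_partition(comp, oracle, mask))
    # component ids are the minimum member linear index
    for (cid in setdiff(unique(as.vector(comp)), 0L))
      expect_identical(min(which(comp == cid)), as.integer(cid))
  }
  # diagonal-touching voxels form one component under 26-connectivity
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_identical(length(setdiff(unique(as.vector(
    connected_components(m))), 0L)), 1L)
})

test_that("keep_largest_component retains the biggest piece of each label", {
  g <- volume_grid(c(9, 5, 5))
  lab <- array(0L, c(9, 5, 5))
  lab[1:5, 2, 2] <- 4L                   # size 5
  lab[8:9, 4, 4] <- 4L                   # size 2, disconnected
  lab[1:3, 4, 2] <- 6L                   # other label, single component
  lv <- label_volume(lab, g)
  out <- keep_largest_component(lv)
  expect_identical(sum(out$labels == 4L), 5L)
  expect_true(all(out$labels[8:9, 4, 4] == 0L))
  expect_identical(sum(out$labels == 6L), 3L)      # untouched
  # oracle check: the surviving voxels are the flood fill's largest blob
  oracle <- bfs_components(lab == 4L)
  sizes <- table(oracle[oracle > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  expect_identical(out$labels == 4L, oracle == big)
  # monotone cleanup
  expect_lte(sum(out$labels > 0L), sum(lab > 0L))
  # size tie: the component first reached in x-fastest scan order wins
  tie <- array(0L, c(7, 3, 3))
  tie[1:2, 2, 2] <- 5L; tie[6:7, 2, 2] <- 5L
  out_tie <- keep_largest_component(label_volume(tie, g = volume_grid(c(7, 3, 3))))
  expect_identical(which(out_tie$labels == 5L),
                   which(tie == 5L)[1:2])
})

test_that("merge_final combines terminal and refined groups correctly", {
  h <- default_hierarchy()
  g <- volume_grid(c(6, 3, 3))
  coarse <- array(0L, c(6, 3, 3))
  coarse[1:2, 1, 1] <- 1L      # left WM (terminal, final id 1)
  coarse[3:4, 1, 1] <- 2L      # right WM (terminal, final id 2)
  coarse[5:6, 1, 1] <- 3L      # left deep
  cz <- label_volume(coarse, g, namespace = "coarse")
  fine <- array(0L, c(6, 3, 3))
  fine[5, 1, 1] <- 7L
  fine[2, 1, 1] <- 9L          # claims a terminal voxel: fine wins
  fv <- list(lh_deep = label_volume(fine, g, namespace = "fine"))
  out <- merge_final(cz, fv, h)
  expect_identical(out$namespace, "final")
  expect_identical(out$labels[1, 1, 1], 1L)
  expect_identical(out$labels[2, 1, 1], 9L)
  expect_identical(out$labels[3, 1, 1], 2L)
  expect_identical(out$labels[5, 1, 1], 7L)
  expect_identical(out$labels[6, 1, 1], 0L)   # unlabeled fine voxel stays 0
  # terminal-only input yields only the two white-matter ids
  out2 <- merge_final(cz, list(), h)
  expect_identical(setdiff(sort(unique(as.vector(out2$labels))), 0L)[1:2],
                   c(1L, 2L))
})

test_that("lookup-table remapping is a bijection preserving counts", {
  g <- volume_grid(c(3, 3, 3))
  lab <- label_volume(array(c(rep(1L, 10), rep(2L, 8), rep(0L, 9)),
                            c(3, 3, 3)), g)
  lut <- c(`1` = 2L, `2` = 41L)
  out <- apply_lookup(lab, lut)
  expect_identical(out$namespace, "lut")
  expect_identical(sum(out$labels == 2L), 10L)
  expect_identical(sum(out$labels == 41L), 8L)
  expect_error(apply_lookup(lab, c(`1` = 2L)), "no lookup-table entry")
  expect_error(apply_lookup(lab, NULL), "no lookup table")
  expect_error(apply_lookup(lab, c(`1` = 5L, `2` = 5L)), "one-to-one")
})

test_that("the full chain yields hierarchical containment and single components", {
  # build a noisy fine segmentation on the phantom and clean it up
  spec <- phantom_spec(grid_size = 32)
  ph <- generate_phantom(spec)
  h <- spec$hierarchy
  set.seed(31)
  fine <- list()
  for (g in Filter(function(x) !x$terminal, h$groups)) {
    lab <- ph$labels$labels
    lab[!(lab %in% g$final_ids)] <- 0L
    # corrupt: sprinkle stray voxels of this group's first id outside the mask
    stray <- sample(which(lab == 0L), 40)
    lab[stray] <- g$final_ids[1]
    fine[[g$name]] <- label_volume(lab, ph$labels$grid, namespace = "fine")
  }
  out <- postprocess_parcellation(ph$coarse, fine, h)
  ids <- setdiff(sort(unique(as.vector(out$labels))), 0L)
  expect_true(all(ids %in% 1:101))
  # containment: every voxel's final label belongs to the coarse group there
  fc <- integer(101)
  for (g in h$groups) fc[g$final_ids] <- g$coarse_id
  nz <- which(out$labels > 0L)
  expect_true(all(fc[out$labels[nz]] == ph$coarse$labels[nz]))
  # single 26-connected component per label
  for (id in ids) {
    comp <- bfs_components(out$labels == id)
    expect_identical(max(comp), 1L)
  }
})

test_that("to_native resampling survives a half-resolution round trip", {
  spec <- phantom_spec(grid_size = 32)
  lab <- generate_labels(spec)
  half <- conformed_grid(lab$grid, size = 16, spacing = 2)
  down <- to_native(lab, half)
  back <- to_native(down, lab$grid)
  # interior voxels: non-background with all 6 face neighbors sharing the
  # label, i.e. at least one voxel away from any parcel boundary
  d <- dim(lab$labels)
  same6 <- array(TRUE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    idx_dst[[ax]] <- pmin(pmax(seq_len(n) + s, 1L), n)
    shifted <- do.call(`[`, c(list(lab$labels), idx_dst))
    dim(shifted) <- d
    same6 <- same6 & (shifted == lab$labels)
  }
  interior <- lab$labels > 0L & same6
  expect_gt(sum(interior), 1000)
  expect_gte(mean(back$labels[interior] == lab$labels[interior]), 0.95)
})
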