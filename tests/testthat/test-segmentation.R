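gray_stack <- function(value, d = c(6, 6, 3)) array(value, d)

test_that("threshold labeling is polarity-correct and first-match-wins", {
  dark <- list(label_spec("stain", 100, "dark"))
  lv <- threshold_label(gray_stack(255), dark)
  expect_true(all(lv$labels == 0L))
  lv <- threshold_label(gray_stack(0), dark)
  expect_true(all(lv$labels == 1L))
  # overlapping specs: list order decides ownership
  specs <- list(label_spec("a", 120, "dark"), label_spec("b", 200, "dark"))
  lv <- threshold_label(gray_stack(110), specs)
  expect_true(all(lv$labels == 1L))
  lv2 <- threshold_label(gray_stack(150), specs)
  expect_true(all(lv2$labels == 2L))
  expect_error(threshold_label(gray_stack(0),
                               list(label_spec("x", 10), label_spec("x", 20))),
               "duplicate")
})

test_that("raising a dark threshold never unselects a voxel", {
  set.seed(21)
  g <- array(sample(0:255, 8 * 8 * 4, TRUE), c(8, 8, 4))
  sel_prev <- NULL
  for (thr in c(60, 120, 200)) {
    sel <- threshold_label(g, list(label_spec("s", thr, "dark")))$labels == 1L
    if (!is.null(sel_prev)) expect_true(all(sel[sel_prev]))
    sel_prev <- sel
  }
})

test_that("phantom stain segmentation reaches Dice >= 0.90 against truth", {
  ph <- small_phantom()
  vs <- virtual_sections(ph, 5, stain_model(noise_sigma = 4, speck_rate = 0))
  gray <- simplify2array(lapply(vs$stack$sections, to_grayscale))
  lv <- threshold_label(gray, list(label_spec("stain", 130, "dark")))
  truth <- simplify2array(lapply(vs$masks, function(m) m == 2L | m == 4L))
  expect_gte(dice(lv$labels == 1L, truth), 0.90)
})

test_that("manual masks add and erase exactly and can repair a labeling", {
  g <- gray_stack(255, c(5, 5, 2))
  lv <- threshold_label(g, list(label_spec("s", 100, "dark")))
  empty <- matrix(FALSE, 5, 5)
  expect_identical(apply_manual_masks(lv, list(empty), 1L, 1L)$labels,
                   lv$labels)
  m <- matrix(FALSE, 5, 5); m[2:3, 2:4] <- TRUE
  added <- apply_manual_masks(lv, list(m), 1L, sections = 2L)
  expect_equal(sum(added$labels == 1L), 6L)
  undone <- apply_manual_masks(added, list(m), 1L, sections = 2L,
                               mode = "erase")
  expect_identical(undone$labels, lv$labels)
  expect_error(apply_manual_masks(lv, list(matrix(FALSE, 4, 4)), 1L, 1L),
               "dimensions")
  # repairing a false negative strictly increases Dice
  truth <- array(FALSE, c(5, 5, 2)); truth[2:3, 2:4, 2] <- TRUE
  d0 <- dice(lv$labels == 1L, truth)
  d1 <- dice(added$labels == 1L, truth)
  expect_gt(d1, d0)
})

test_that("3D components match the flood-fill oracle across seeds", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  cc <- components_3d(one)
  expect_equal(cc$n_components, 1L)
  expect_equal(cc$sizes$voxels, 1L)
  # diagonal contact: joined at 26, split at 6
  diag2 <- array(FALSE, c(3, 3, 3)); diag2[1, 1, 1] <- TRUE; diag2[2, 2, 2] <- TRUE
  expect_equal(components_3d(diag2, connectivity = 26)$n_components, 1L)
  expect_equal(components_3d(diag2, connectivity = 6)$n_components, 2L)
  for (seed in 1:20) {
    set.seed(seed)
    m <- array(runif(10 * 9 * 5) < 0.3, c(10, 9, 5))
    conn <- sample(c(6L, 18L, 26L), 1)
    cc <- components_3d(m, connectivity = conn)
    oracle <- flood_fill_components(m, conn)
    expect_equal(cc$n_components, oracle$n)
    expect_equal(cc$sizes$voxels, sort(oracle$sizes, decreasing = TRUE))
    expect_equal(sum(cc$sizes$voxels), sum(m))  # partition property
    # identical partition: same co-membership on a sample of voxel pairs
    fg <- which(m)
    if (length(fg) >= 2) {
      pick <- fg[seq(1, length(fg), length.out = min(25, length(fg)))]
      for (i in seq_along(pick)[-1]) {
        expect_equal(cc$map[pick[1]] == cc$map[pick[i]],
                     oracle$map[pick[1]] == oracle$map[pick[i]])
      }
    }
  }
})

test_that("component sizes convert to physical volume", {
  labels <- array(0L, c(4, 4, 4)); labels[1:2, 1, 1] <- 1L
  lv <- label_volume(labels, list("1" = label_spec("s", 100)),
                     spacing = c(1, 1, 10),
                     physical_spacing_um = c(2.5, 2.5, 5))
  cc <- components_3d(lv, 1L)
  expect_equal(cc$sizes$um3, 2 * 2.5 * 2.5 * 5)
  expect_error(components_3d(lv, 7L), "unknown")
})

test_that("connectivity verdicts match a BFS oracle and ignore labeling order", {
  labels <- array(0L, c(8, 8, 4))
  labels[2:4, 2:4, 1:2] <- 1L           # stain A touching the reference
  labels[6:7, 6:7, 3:4] <- 1L           # stain B detached
  labels[2:4, 2:4, 3] <- 2L             # reference adjacent to A only
  lv <- label_volume(labels, list("1" = label_spec("stain", 100),
                                  "2" = label_spec("duct", 100,
                                                   color = c(0, 0, 255))),
                     spacing = c(1, 1, 1))
  q <- connectivity_query(lv, 1L, 2L)
  expect_equal(q$n_connected, 1L)
  expect_equal(q$n_isolated, 1L)
  big <- q$verdicts$verdict[which.max(q$verdicts$voxels)]
  expect_equal(big, "connected")
  # overlap counts as connected too
  seeds <- which(labels == 1L, arr.ind = TRUE)[1, , drop = FALSE]
  q2 <- connectivity_query(lv, 1L, seeds)
  expect_equal(q2$n_connected, 1L)
  expect_error(connectivity_query(lv, 1L, matrix(numeric(0), 0, 3)), "empty")
  # random fixtures against the independent BFS oracle
  for (seed in 1:8) {
    set.seed(100 + seed)
    m <- array(runif(9 * 9 * 4) < 0.25, c(9, 9, 4))
    ref <- array(FALSE, c(9, 9, 4)); ref[5, 5, 2] <- TRUE
    m[ref] <- FALSE
    lab <- array(0L, dim(m)); lab[m] <- 1L; lab[ref] <- 2L
    lvr <- label_volume(lab, list("1" = label_spec("s", 1),
                                  "2" = label_spec("r", 1)), c(1, 1, 1))
    qq <- connectivity_query(lvr, 1L, 2L)
    oo <- bfs_connectivity_verdicts(m, ref)
    expect_equal(qq$n_connected, sum(oo$connected))
    expect_equal(qq$n_isolated, sum(!oo$connected))
  }
})

test_that("size filtering keeps exactly the surviving census", {
  labels <- array(0L, c(10, 10, 3))
  labels[1:3, 1:3, 1:2] <- 1L           # 18 voxels
  labels[8, 8, 1:2] <- 1L               # 2 voxels
  labels[5, 5, 3] <- 1L                 # 1 voxel
  lv <- label_volume(labels, list("1" = label_spec("s", 100)), c(1, 1, 1))
  expect_identical(filter_small(lv, 1L, 1L)$labels, lv$labels)
  f <- filter_small(lv, 1L, 10L)
  oracle <- flood_fill_components(f$labels == 1L)
  expect_equal(oracle$n, 1L)
  expect_equal(sum(f$labels == 1L), 18L)
  # min 3 removes both the 2-voxel and the 1-voxel component
  f2 <- filter_small(lv, 1L, 3L)
  expect_equal(sum(f2$labels == 1L), 18L)
  # min 2 keeps the 2-voxel pair
  f3 <- filter_small(lv, 1L, 2L)
  expect_equal(sum(f3$labels == 1L), 20L)
})

test_that("border-touching bright components are dropped, interior kept", {
  labels <- array(0L, c(8, 8, 2))
  labels[1, , ] <- 1L; labels[, 1, ] <- 1L   # frame touching the border
  labels[4:5, 4:5, ] <- 1L                    # interior lumen
  lv <- label_volume(labels, list("1" = label_spec("lumen", 250, "bright")),
                     c(1, 1, 1))
  out <- drop_border_components(lv, 1L)
  expect_equal(sum(out$labels == 1L), 8L)
  expect_true(all(out$labels[4:5, 4:5, ] == 1L))
})

test_that("labeling runs are bit-for-bit deterministic", {
  set.seed(77)
  g <- array(sample(0:255, 12 * 12 * 4, TRUE), c(12, 12, 4))
  specs <- list(label_spec("a", 90, "dark"), label_spec("b", 230, "bright"))
  l1 <- threshold_label(g, specs)
  l2 <- threshold_label(g, specs)
  expect_identical(l1$labels, l2$labels)
  expect_identical(components_3d(l1, 1L)$map, components_3d(l2, 1L)$map)
})
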