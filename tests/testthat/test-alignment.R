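test_that("landmark fits recover exact rigid motions", {
  p <- cbind(c(10, 80, 80, 10), c(10, 10, 60, 60))
  fit <- estimate_rigid_from_landmarks(p, p)
  expect_equal(fit$transform$theta, 0)
  expect_equal(c(fit$transform$tx, fit$transform$ty), c(0, 0))
  expect_equal(fit$rms, 0)
  # pure translation
  fit <- estimate_rigid_from_landmarks(p + cbind(rep(5, 4), rep(-3, 4)), p)
  expect_equal(fit$transform$theta, 0)
  expect_equal(c(fit$transform$tx, fit$transform$ty), c(5, -3))
  expect_equal(fit$rms, 0, tolerance = 1e-12)
  # estimate-after-apply recovers any transform exactly (noise-free)
  ctr <- c(45, 35)
  for (seed in 1:5) {
    set.seed(seed)
    truth <- rigid2d(runif(1, -0.5, 0.5), runif(1, -20, 20),
                     runif(1, -20, 20), ctr)
    q <- rigid_apply(truth, p)
    fit <- estimate_rigid_from_landmarks(q, p, ctr)
    expect_equal(fit$transform$theta, truth$theta, tolerance = 1e-9)
    expect_equal(fit$transform$tx, truth$tx, tolerance = 1e-8)
    expect_equal(fit$transform$ty, truth$ty, tolerance = 1e-8)
  }
})

test_that("noisy landmark fit agrees with an exhaustive grid search", {
  ctr <- c(50, 50)
  p <- cbind(c(20, 80, 80, 20), c(20, 20, 70, 70))
  truth <- rigid2d(10 * pi / 180, 6, -4, ctr)
  set.seed(17)
  q <- rigid_apply(truth, p) + matrix(rnorm(8, 0, 0.5), 4, 2)
  fit <- estimate_rigid_from_landmarks(q, p, ctr)
  expect_lt(abs(fit$transform$theta - truth$theta) * 180 / pi, 0.5)
  oracle <- grid_search_rigid(q, p, ctr)
  # closed form must beat-or-match the grid oracle at its own resolution
  expect_lt(abs(fit$transform$theta - oracle$theta), 0.06 * pi / 180)
  res <- rigid_apply(fit$transform, p) - q
  expect_lte(sum(res^2), oracle$ss + 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  expect_error(estimate_rigid_from_landmarks(cbind(1, 2), cbind(1, 2)),
               "degenerate")
  coin <- cbind(c(5, 5, 5), c(7, 7, 7))
  expect_error(estimate_rigid_from_landmarks(coin, coin), "coincident")
})

test_that("chaining pairwise transforms matches the matrix oracle", {
  id <- rigid2d()
  abs_tr <- compose_to_reference(list(id, id, id))
  for (tr in abs_tr) {
    expect_equal(tr$theta, 0)
    expect_equal(c(tr$tx, tr$ty), c(0, 0))
  }
  # five unit translations accumulate
  shift <- rigid2d(tx = 1, ty = 0)
  abs_tr <- compose_to_reference(rep(list(shift), 5))
  expect_equal(abs_tr[[6]]$tx, 5)
  expect_equal(abs_tr[[6]]$ty, 0)
  # random chains vs step-by-step homogeneous matrix products
  set.seed(31)
  ctr <- c(10, 20)
  pairwise <- lapply(1:6, function(i) {
    rigid2d(runif(1, -0.3, 0.3), runif(1, -5, 5), runif(1, -5, 5), ctr)
  })
  abs_tr <- compose_to_reference(pairwise)
  M <- diag(3)
  for (i in seq_along(pairwise)) {
    M <- M %*% rigid_matrix(pairwise[[i]])
    expect_equal(rigid_matrix(abs_tr[[i + 1]]), M, tolerance = 1e-12)
  }
})

test_that("resampling inverts correctly and fills borders white", {
  img <- array(0L, c(20, 30, 3))
  img[5:10, 7:12, ] <- 200L
  s <- section_image(img)
  expect_identical(resample_section(s, rigid2d(), "nearest")$pixels, img)
  expect_identical(resample_section(s, rigid2d(), "bilinear")$pixels, img)
  # integer translation with nearest = exact shifted copy + white fill
  sh <- resample_section(s, rigid2d(tx = 3, ty = 2), "nearest")
  expect_true(all(sh$pixels[7:12, 10:15, ] == 200L))
  expect_true(all(sh$pixels[1:2, , ] == 255L))
  expect_true(all(sh$pixels[, 1:3, ] == 255L))
  # 90-degree rotation about the center of a square = index permutation
  n <- 15
  sq <- array(sample(0:255, n * n * 3, replace = TRUE), c(n, n, 3))
  ssq <- section_image(sq)
  rot <- resample_section(ssq, rigid2d(theta = pi / 2,
                                       center = c((n - 1) / 2, (n - 1) / 2)),
                          "nearest")
  # hand-derived index remap: output[r, c] = input[n + 1 - c, r]
  perm <- sq
  for (ch in 1:3) perm[, , ch] <- t(sq[n:1, , ch])
  expect_identical(rot$pixels, perm)
  # round trip through T and T^-1 restores the interior
  tr <- rigid2d(theta = 0.2, tx = 2, ty = -1, center = c(14.5, 9.5))
  fwd <- resample_section(s, tr, "nearest")
  back <- resample_section(fwd, rigid_invert(tr), "nearest")
  interior <- back$pixels[8:13, 9:22, ]
  expect_true(mean(interior == img[8:13, 9:22, ]) > 0.95)
  expect_error(resample_section(s, rigid2d(), "cubic"), "interpolation")
})

test_that("phase-correlation alignment recovers translations and rotations", {
  set.seed(7)
  base <- matrix(as.integer(sample(0:255, 64 * 64, TRUE)), 64, 64)
  s <- section_image(array(rep(base, 3), c(64, 64, 3)))
  id <- auto_align_pair(s, s)
  expect_lt(abs(id$tx) + abs(id$ty), 1)
  moved <- resample_section(s, rigid2d(tx = 7, ty = -4), "nearest")
  rec <- auto_align_pair(moved, s)
  expect_equal(c(rec$tx, rec$ty), c(7, -4), tolerance = 1)
  expect_error(auto_align_pair(section_image(array(100L, c(8, 8, 3))),
                               section_image(array(100L, c(8, 8, 3)))),
               "featureless")
})

test_that("injected phantom misalignment is recovered by the landmark path", {
  ph <- small_phantom()
  vs <- virtual_sections(ph, 5)
  pert <- perturb_alignment(vs$stack, sigma_t_px = 5, sigma_theta_deg = 2,
                            seed = 4)
  d <- dim(pert$stack$sections[[1]]$pixels)
  ctr <- c((d[2] - 1) / 2, (d[1] - 1) / 2)
  pts <- as.matrix(expand.grid(x = c(12, 30, 48), y = c(12, 30, 48)))
  jit <- function(m) m + matrix(rnorm(length(m), 0, 0.25), nrow(m), ncol(m))
  set.seed(99)
  errs <- vapply(seq_along(pert$truth)[-1], function(i) {
    tt <- pert$truth[[i]]
    moving <- jit(rigid_apply(rigid_invert(tt), pts))
    fit <- estimate_rigid_from_landmarks(pts, moving, ctr)$transform
    c(sqrt((fit$tx - tt$tx)^2 + (fit$ty - tt$ty)^2),
      abs(fit$theta - tt$theta) * 180 / pi)
  }, numeric(2))
  expect_lt(mean(errs[1, ]), 1)
  expect_lt(mean(errs[2, ]), 0.5)
})
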