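make_stack_from_arrays <- function(planes) {
  section_stack(lapply(seq_along(planes), function(i) {
    section_image(planes[[i]], section_index = i - 1L)
  }))
}

test_that("channel recombination derives alpha as max of inverted channels", {
  # originally pure-white sections invert to black: fully transparent
  white_inv <- invert_channels(section_image(array(255L, c(4, 5, 3))))
  vol <- build_rgba_volume(make_stack_from_arrays(
    list(white_inv$pixels, white_inv$pixels)))
  expect_true(all(vol$voxels[, , , 4] == 0L))
  expect_equal(anisotropy_ratio(vol), 10)
  # single voxel (200, 40, 10) -> A = 200
  px <- array(0L, c(1, 1, 3)); px[1, 1, ] <- c(200L, 40L, 10L)
  v1 <- build_rgba_volume(make_stack_from_arrays(list(px)))
  expect_equal(v1$voxels[1, 1, 1, 4], 200L)
  # mixed dimensions refuse to combine
  expect_error(build_rgba_volume(make_stack_from_arrays(
    list(array(0L, c(4, 4, 3)), array(0L, c(5, 4, 3))))), "dimensions")
})

test_that("excluded sections keep their depth under both gap policies", {
  secs <- lapply(c(0L, 1L, 3L), function(i) {
    section_image(array((i + 1L) * 50L, c(3, 3, 3)), section_index = i)
  })
  stack <- section_stack(secs)
  v_skip <- build_rgba_volume(stack)
  expect_equal(dim(v_skip$voxels)[3], 4L)          # index 2 still holds depth
  expect_true(all(v_skip$voxels[, , 3, 4] == 0L))  # gap slot transparent
  v_near <- build_rgba_volume(stack, gap_policy = "nearest")
  expect_identical(v_near$voxels[, , 3, ], v_near$voxels[, , 2, ])
  expect_identical(v_near$voxels[, , 4, ], v_skip$voxels[, , 4, ])
})

test_that("re-inversion restores colors and passes alpha through", {
  vox <- array(0L, c(2, 2, 2, 4))
  vox[1, 1, 1, ] <- c(0L, 0L, 0L, 200L)
  v <- rgba_volume(vox)
  out <- reinvert_volume(v)
  expect_equal(as.vector(out$voxels[1, 1, 1, ]), c(255L, 255L, 255L, 200L))
  set.seed(2)
  vox2 <- array(sample(0:255, 3 * 4 * 2 * 4, TRUE), c(3, 4, 2, 4))
  v2 <- rgba_volume(vox2)
  expect_identical(reinvert_volume(reinvert_volume(v2))$voxels, v2$voxels)
  expect_identical(tabulate(reinvert_volume(v2)$voxels[, , , 4] + 1L, 256),
                   tabulate(v2$voxels[, , , 4] + 1L, 256))
})

test_that("alpha scaling clips and preserves colors", {
  set.seed(3)
  vox <- array(sample(0:255, 2 * 2 * 2 * 4, TRUE), c(2, 2, 2, 4))
  vox[1, 1, 1, 4] <- 200L
  v <- rgba_volume(vox)
  expect_true(all(scale_alpha(v, 0)$voxels[, , , 4] == 0L))
  expect_identical(scale_alpha(v, 1)$voxels, v$voxels)
  doubled <- scale_alpha(v, 2)
  expect_equal(doubled$voxels[1, 1, 1, 4], 255L)
  expect_identical(doubled$voxels[, , , 1:3], v$voxels[, , , 1:3])
  expect_error(scale_alpha(v, -1), "factor")
})

test_that("compositing follows the front-to-back closed form", {
  # fully transparent volume on white background renders uniform white
  empty <- rgba_volume(array(0L, c(3, 3, 2, 4)))
  expect_true(all(render_projection(empty, "+z") == 255L))
  # a single opaque voxel occludes everything behind it
  vox <- array(0L, c(1, 1, 2, 4))
  vox[1, 1, 1, ] <- c(250L, 0L, 0L, 255L)
  vox[1, 1, 2, ] <- c(10L, 220L, 30L, 255L)
  img <- render_projection(rgba_volume(vox), "+z", background = c(0, 0, 0))
  expect_equal(as.vector(img[1, 1, ]), c(250L, 0L, 0L))
  # two-sample closed form: 200*0.5 + 100*1.0*0.5 = 150
  vox2 <- array(0L, c(1, 1, 2, 4))
  vox2[1, 1, 1, ] <- c(200L, 200L, 200L, 128L)  # alpha 128/255 ~ 0.502
  vox2[1, 1, 2, ] <- c(100L, 100L, 100L, 255L)
  img2 <- render_projection(rgba_volume(vox2), "+z", background = c(0, 0, 0))
  a1 <- 128 / 255
  expect_equal(as.vector(img2[1, 1, ]),
               rep(round(200 * a1 + 100 * (1 - a1)), 3))
})

test_that("rendering is stable under transparency padding and z symmetry", {
  set.seed(8)
  vox <- array(sample(0:255, 4 * 5 * 3 * 4, TRUE), c(4, 5, 3, 4))
  v <- rgba_volume(vox)
  base <- render_projection(v, "+z")
  padded <- array(0L, c(4, 5, 5, 4))
  padded[, , 2:4, ] <- vox
  expect_identical(render_projection(rgba_volume(padded), "+z"), base)
  # symmetric volume: +z and -z agree
  sym <- array(0L, c(4, 5, 4, 4))
  sym[, , 1, ] <- vox[, , 1, ]; sym[, , 4, ] <- vox[, , 1, ]
  sym[, , 2, ] <- vox[, , 2, ]; sym[, , 3, ] <- vox[, , 2, ]
  vs <- rgba_volume(sym)
  expect_identical(render_projection(vs, "+z"), render_projection(vs, "-z"))
  # energy bound: on black background no output channel exceeds the ray max
  dark <- render_projection(v, "+z", background = c(0, 0, 0))
  for (ch in 1:3) {
    upper <- apply(vox[, , , ch], c(1, 2), max)
    expect_true(all(dark[, , ch] <= upper + 1L))
  }
  expect_error(render_projection(v, "+w"), "view")
  expect_error(render_projection(v, "+z", mode = "sum"), "mode")
})

test_that("side views stretch the section axis by the anisotropy", {
  vox <- array(0L, c(6, 7, 3, 4))
  vox[2, 3, 2, ] <- c(200L, 0L, 0L, 255L)
  v <- rgba_volume(vox, spacing = c(1, 1, 10))
  side <- render_projection(v, "+x", background = c(255, 255, 255))
  expect_equal(dim(side)[1:2], c(6L, 30L))
  mip <- render_projection(v, "+y", mode = "mip", background = c(0, 0, 0))
  expect_equal(dim(mip)[1:2], c(7L, 30L))
  # the red voxel shows up in the stretched z band of slice 2
  expect_true(any(side[2, 11:20, 1] == 200L))
})

test_that("oblique orthographic rendering samples the whole volume", {
  vox <- array(0L, c(8, 8, 4, 4))
  vox[4, 4, 2, ] <- c(220L, 30L, 30L, 255L)
  v <- rgba_volume(vox, spacing = c(1, 1, 2))
  img <- render_projection(v, c(35, 25), "composite")
  expect_true(length(dim(img)) == 3 && all(dim(img)[1:2] > 2))
  expect_true(any(img[, , 1] > img[, , 2]))  # the red voxel is visible
})
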