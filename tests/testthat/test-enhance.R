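test_that("brightness/contrast follows the mid-gray formula with clipping", {
  s <- random_section(1)
  expect_identical(adjust_brightness_contrast(s, enhance_params())$pixels,
                   s$pixels)
  # hand evaluation: slope 2 about 128 maps 100 -> 72, 250 clips to 255
  v <- section_image(array(c(100L, 250L, 0L), c(1, 1, 3)))
  out <- adjust_brightness_contrast(v, enhance_params(contrast_slope = 2))
  expect_equal(as.vector(out$pixels), c(72L, 255L, 0L))
  sat <- adjust_brightness_contrast(s, enhance_params(brightness_offset = 255))
  expect_true(all(sat$pixels == 255L))
})

test_that("background whitening touches only background-colored pixels", {
  white <- section_image(array(255L, c(6, 6, 3)))
  expect_identical(whiten_background(white)$pixels, white$pixels)
  # tolerance 0: only the exact triple becomes white
  px <- array(0L, c(5, 5, 3))
  px[, , 1] <- 250L; px[, , 2] <- 248L; px[, , 3] <- 246L
  px[3, 3, ] <- c(250L, 248L, 245L)  # one channel off by one
  s <- section_image(px)
  out <- whiten_background(s, enhance_params(background_tolerance = 0),
                           background = c(250, 248, 246))
  expect_true(all(out$pixels[1, 1, ] == 255L))
  expect_identical(out$pixels[3, 3, ], px[3, 3, ])
})

test_that("phantom background whitens fully without touching stain", {
  ph <- small_phantom()
  vs <- virtual_sections(ph, 5, stain_model(noise_sigma = 2, speck_rate = 0))
  k <- 3
  s <- vs$stack$sections[[k]]
  mask <- vs$masks[[k]]
  out <- whiten_background(s, enhance_params(background_tolerance = 12),
                           background = c(248, 247, 245))
  bg <- mask == 0
  stain <- mask %in% c(2L, 4L)
  whitened <- out$pixels[, , 1] == 255L & out$pixels[, , 2] == 255L &
              out$pixels[, , 3] == 255L
  expect_gt(mean(whitened[bg]), 0.99)
  for (ch in 1:3) {
    expect_identical(out$pixels[, , ch][stain], s$pixels[, , ch][stain])
  }
})

test_that("color-range cleanup removes specks and preserves stain blobs", {
  p <- enhance_params(color_range_target = c(60, 50, 45),
                      color_range_tolerance = 30, refine_radius = 0,
                      min_noise_size = 10)
  bgpx <- array(240L, c(20, 20, 3))
  s <- section_image(bgpx)
  expect_identical(remove_color_range_noise(s, p)$pixels, bgpx)
  # isolated 3-px dark speck is whitened
  px <- bgpx
  px[5, 5:7, 1] <- 60L; px[5, 5:7, 2] <- 50L; px[5, 5:7, 3] <- 45L
  out <- remove_color_range_noise(section_image(px), p)
  expect_true(all(out$pixels[5, 5:7, ] == 255L))
  expect_identical(out$pixels[10, , ], px[10, , ])
  # a genuine large blob in the same color range survives bit-exactly
  px2 <- bgpx
  px2[3:18, 3:18, 1] <- 60L
  px2[3:18, 3:18, 2] <- 50L
  px2[3:18, 3:18, 3] <- 45L
  out2 <- remove_color_range_noise(section_image(px2), p)
  expect_identical(out2$pixels, px2)
})

test_that("channel inversion is the protocol involution", {
  z <- section_image(array(0L, c(2, 2, 3)))
  expect_true(all(invert_channels(z)$pixels == 255L))
  w <- section_image(array(255L, c(1, 1, 3)))
  expect_true(all(invert_channels(w)$pixels == 0L))
  for (seed in 1:3) {
    s <- random_section(seed)
    expect_identical(invert_channels(invert_channels(s))$pixels, s$pixels)
  }
})

test_that("halving resize is 2x2 block averaging with doubled pixel size", {
  big <- section_image(array(100L, c(1040, 1392, 3)), pixel_size_um = 0.642)
  out <- resize_section(big)
  expect_equal(dim(out$pixels)[1:2], c(520L, 696L))
  expect_equal(out$pixel_size_um, 1.284)
  tiny <- resize_section(section_image(array(37L, c(2, 2, 3))))
  expect_equal(dim(tiny$pixels)[1:2], c(1L, 1L))
  expect_equal(as.vector(tiny$pixels), rep(37L, 3))
  # 4x4 gradient: each output pixel is its 2x2 block mean
  g <- matrix(seq(0, 150, by = 10), 4, 4)
  s <- section_image(array(rep(g, 3), c(4, 4, 3)))
  out <- resize_section(s)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    oracle[i, j] <- mean(g[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(out$pixels[, , 1], matrix(as.integer(round(oracle)), 2, 2))
  # mean intensity preserved within half a gray level
  r <- random_section(9, h = 18, w = 22)
  halved <- resize_section(r)
  expect_lt(abs(mean(halved$pixels) - mean(r$pixels)), 0.5)
  expect_error(resize_section(r, width = 0, height = 5), "width")
})

test_that("grayscale conversion uses Rec. 601 luma", {
  expect_equal(to_grayscale(section_image(array(255L, c(1, 1, 3))))[1, 1], 255)
  expect_equal(to_grayscale(section_image(array(0L, c(1, 1, 3))))[1, 1], 0)
  red <- section_image(array(c(255L, 0L, 0L), c(1, 1, 3)))
  expect_equal(to_grayscale(red)[1, 1], 76)
})

test_that("lumen enhancement brightens lumina, darkens tissue, idempotent", {
  white <- section_image(array(255L, c(4, 4, 3)))
  expect_identical(enhance_lumina(white)$pixels, white$pixels)
  ph <- small_phantom()
  vs <- virtual_sections(ph, 5, stain_model(noise_sigma = 2, speck_rate = 0))
  k <- 4
  s <- vs$stack$sections[[k]]
  mask <- vs$masks[[k]]
  out <- enhance_lumina(s, enhance_params())
  lumen <- mask == 1L
  tissue <- mask == 5L
  expect_true(any(lumen))
  expect_true(all(out$pixels[, , 1][lumen] >= 250))
  expect_lt(median(out$pixels[, , 1][tissue]),
            median(s$pixels[, , 1][tissue]))
  # exact idempotence
  twice <- enhance_lumina(out, enhance_params())
  expect_identical(twice$pixels, out$pixels)
  # a pixel already at pure white is never darkened
  wp <- s$pixels[, , 1] == 255L & s$pixels[, , 2] == 255L &
        s$pixels[, , 3] == 255L
  if (any(wp)) {
    for (ch in 1:3) expect_true(all(out$pixels[, , ch][wp] == 255L))
  }
  white_in <- enhance_lumina(section_image(array(255L, c(3, 3, 3))))
  expect_true(all(white_in$pixels == 255L))
})

test_that("operators preserve dimensions and stay in range", {
  s <- random_section(13)
  ops <- list(
    function(x) adjust_brightness_contrast(x, enhance_params(contrast_slope = 3)),
    function(x) whiten_background(x),
    function(x) remove_color_range_noise(x),
    invert_channels,
    function(x) enhance_lumina(x)
  )
  for (f in ops) {
    out <- f(s)
    expect_equal(dim(out$pixels), dim(s$pixels))
    expect_true(min(out$pixels) >= 0L && max(out$pixels) <= 255L)
  }
})
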