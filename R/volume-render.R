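#' RGBA voxel volume
#'
#' Anisotropic voxel grid of color plus opacity. `voxels` is an
#' `H x W x Z x 4` integer array (R, G, B, A planes, each in `[0, 255]`);
#' `spacing` holds the relative voxel edge lengths `(sx, sy, sz)` — the
#' protocol convention is `(1, 1, 10)`, chosen to give the thin stack visual
#' depth; `physical_spacing_um`, when supplied, records the true edge lengths
#' `(pixel_size, pixel_size, thickness x interval)` in micrometres.
#'
#' @param voxels `H x W x Z x 4` integer array in `[0, 255]`.
#' @param spacing relative `(sx, sy, sz)`, all > 0.
#' @param physical_spacing_um optional physical `(x, y, z)` edge lengths (um).
#' @return object of class `rgba_volume`.
#' @export
rgba_volume <- function(voxels, spacing = c(1, 1, 10),
                        physical_spacing_um = NULL) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L, dim(voxels)[4] == 4L)
  storage.mode(voxels) <- "integer"
  if (min(voxels) < 0L || max(voxels) > 255L) {
    stop("voxel channels must be in [0, 255]")
  }
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 physical_spacing_um = physical_spacing_um),
            class = "rgba_volume")
}

#' @export
print.rgba_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("rgba_volume: %d x %d x %d voxels, spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' z/x anisotropy ratio of a volume
#' @param volume an [rgba_volume] (or [label_volume]).
#' @return `spacing_z / spacing_x`.
#' @export
anisotropy_ratio <- function(volume) volume$spacing[3] / volume$spacing[1]

#' Combine a color-inverted stack into an RGBA volume
#'
#' Recombines the R, G and B channels of the inverted section series into one
#' volume and derives the new alpha (transparency) channel automatically:
#' `A = max(R_inv, G_inv, B_inv)`, so a pixel that was pure white in the
#' original image (black after inversion) becomes fully transparent and a
#' saturated stain becomes nearly opaque. The max-of-channels rule is a
#' documented convention (see `alpha_rule`): the interactive tool it replaces
#' does not publish its formula.
#'
#' @param stack a `section_stack` of the color-inverted series (all sections
#'   sharing dimensions).
#' @param spacing relative voxel spacing, default the protocol `(1, 1, 10)`.
#' @param alpha_rule `"max"` (default), `"luminance"` or `"mean"` of the
#'   inverted channels.
#' @param physical when `TRUE`, records physical spacing
#'   `(pixel_size, pixel_size, thickness x sampling_interval)` in um.
#' @param gap_policy how to fill z-slots of sections excluded from the
#'   manifest but inside the index range: `"skip"` (default) leaves them
#'   fully transparent so the excluded depth stays visible as a gap;
#'   `"nearest"` copies the nearest included section.
#' @return an [rgba_volume] with one z-slot per cut index spanned by the
#'   manifest (`Z = ` number of sections when the series is complete).
#' @export
build_rgba_volume <- function(stack, spacing = c(1, 1, 10),
                              alpha_rule = c("max", "luminance", "mean"),
                              physical = FALSE,
                              gap_policy = c("skip", "nearest")) {
  alpha_rule <- match.arg(alpha_rule)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(stack, "section_stack"))
  dims <- vapply(stack$sections, function(s) dim(s$pixels)[1:2], integer(2))
  if (any(dims != dims[, 1])) stop("sections have mixed dimensions")
  h <- dims[1, 1]; w <- dims[2, 1]
  idx <- vapply(stack$sections, function(s) s$section_index, integer(1))
  slots <- idx - min(idx) + 1L          # true cut positions keep their depth
  nz <- max(slots)
  vox <- array(0L, c(h, w, nz, 4L))
  filled <- integer(0)
  for (k in seq_along(stack$sections)) {
    z <- slots[k]
    px <- stack$sections[[k]]$pixels
    vox[, , z, 1:3] <- px
    vox[, , z, 4] <- switch(alpha_rule,
      max = pmax(px[, , 1], px[, , 2], px[, , 3]),
      luminance = to_u8(0.299 * px[, , 1] + 0.587 * px[, , 2] +
                        0.114 * px[, , 3]),
      mean = to_u8((px[, , 1] + px[, , 2] + px[, , 3]) / 3))
    filled <- c(filled, z)
  }
  if (gap_policy == "nearest" && length(filled) < nz) {
    for (z in setdiff(seq_len(nz), filled)) {
      src <- filled[which.min(abs(filled - z))]
      vox[, , z, ] <- vox[, , src, ]
    }
  }
  phys <- NULL
  if (physical) {
    m <- stack$manifest
    phys <- c(m$pixel_size_um, m$pixel_size_um,
              m$thickness_um * m$sampling_interval)
  }
  rgba_volume(vox, spacing, phys)
}

#' Re-invert the color channels of a volume
#'
#' Applies `v * -1 + 255` to each color channel, restoring the original
#' colors after the inverted-channel recombination; the alpha channel passes
#' through unchanged.
#' @param volume an [rgba_volume].
#' @return re-inverted [rgba_volume].
#' @export
reinvert_volume <- function(volume) {
  vox <- volume$voxels
  vox[, , , 1:3] <- 255L - vox[, , , 1:3]
  rgba_volume(vox, volume$spacing, volume$physical_spacing_um)
}

#' Scale the alpha channel
#'
#' Tunes the transparency of the rendered volume:
#' `A' = clip(round(factor * A), 0, 255)`; colors are untouched.
#' @param volume an [rgba_volume].
#' @param factor non-negative multiplier.
#' @return adjusted [rgba_volume].
#' @export
scale_alpha <- function(volume, factor) {
  if (!is.finite(factor) || factor < 0) stop("alpha factor must be >= 0")
  vox <- volume$voxels
  vox[, , , 4] <- to_u8(factor * vox[, , , 4])
  rgba_volume(vox, volume$spacing, volume$physical_spacing_um)
}

stretch_axis <- function(img, factor, along = 1L) {
  if (factor == 1) return(img)
  n <- dim(img)[along]
  idx <- pmin(n, pmax(1L, ceiling((1:round(n * factor)) / factor)))
  if (along == 1L) img[idx, , , drop = FALSE] else img[, idx, , drop = FALSE]
}

composite_slices <- function(get_slice, n_slices, h, w, background,
                             early_exit = 0.999) {
  Cacc <- array(0, c(h, w, 3L))
  Aacc <- matrix(0, h, w)
  for (k in seq_len(n_slices)) {
    sl <- get_slice(k)                 # h x w x 4 in [0,255]
    a <- sl[, , 4] / 255
    wgt <- (1 - Aacc) * a
    for (ch in 1:3) Cacc[, , ch] <- Cacc[, , ch] + wgt * sl[, , ch]
    Aacc <- Aacc + wgt
    if (min(Aacc) >= early_exit) break
  }
  for (ch in 1:3) Cacc[, , ch] <- Cacc[, , ch] + (1 - Aacc) * background[ch]
  to_u8(Cacc)
}

mip_slices <- function(get_slice, n_slices, h, w, background) {
  M <- array(0, c(h, w, 3L))
  Amax <- matrix(0, h, w)
  for (k in seq_len(n_slices)) {
    sl <- get_slice(k)
    a <- sl[, , 4] / 255
    Amax <- pmax(Amax, a)
    for (ch in 1:3) M[, , ch] <- pmax(M[, , ch], a * sl[, , ch])
  }
  # rays that met no opacity at all show the background
  empty <- Amax == 0
  for (ch in 1:3) {
    plane <- M[, , ch]
    plane[empty] <- background[ch]
    M[, , ch] <- plane
  }
  to_u8(M)
}

#' Orthographic projection of an RGBA volume
#'
#' Renders the volume to a 2D RGB image. `"composite"` performs front-to-back
#' alpha compositing per ray (`C += (1 - A_acc) * a_i * C_i`, early exit at
#' accumulated opacity 0.999, residual weight filled with the background
#' color); `"mip"` takes the per-ray channelwise maximum of alpha-weighted
#' color. Axis views composite the voxel slices directly and stretch the
#' off-plane axis by the spacing anisotropy; an `(azimuth, elevation)` view
#' resamples the volume along ray steps of `min(spacing) / 2`.
#'
#' @param volume an [rgba_volume].
#' @param view `"+z"`, `"-z"`, `"+x"`, `"-x"`, `"+y"`, `"-y"`, or a numeric
#'   `c(azimuth_deg, elevation_deg)`.
#' @param mode `"composite"` or `"mip"`.
#' @param background background `(R, G, B)` in `[0, 255]`.
#' @return `H x W x 3` integer RGB array.
#' @export
render_projection <- function(volume, view = "+z",
                              mode = c("composite", "mip"),
                              background = c(255, 255, 255)) {
  if (is.character(mode)) {
    if (!all(mode %in% c("composite", "mip"))) stop("unknown render mode")
  }
  mode <- match.arg(mode)
  vox <- volume$voxels
  d <- dim(vox)
  h <- d[1]; w <- d[2]; nz <- d[3]
  sp <- volume$spacing

  if (is.numeric(view)) {
    return(render_oblique(volume, view[1], view[2], mode, background))
  }
  if (!view %in% c("+z", "-z", "+x", "-x", "+y", "-y")) {
    stop("unknown view: ", view)
  }
  axis <- substr(view, 2, 2)
  fwd <- substr(view, 1, 1) == "+"

  if (axis == "z") {
    ord <- if (fwd) seq_len(nz) else rev(seq_len(nz))
    get <- function(k) {
      sl <- vox[, , ord[k], , drop = FALSE]
      dim(sl) <- c(h, w, 4L)
      sl
    }
    img <- if (mode == "composite") {
      composite_slices(get, nz, h, w, background)
    } else mip_slices(get, nz, h, w, background)
    return(img)
  }
  if (axis == "x") {
    ord <- if (fwd) seq_len(w) else rev(seq_len(w))
    # slice image: rows = y, cols = z
    get <- function(k) {
      sl <- vox[, ord[k], , , drop = FALSE]
      dim(sl) <- c(h, nz, 4L)
      sl
    }
    img <- if (mode == "composite") {
      composite_slices(get, w, h, nz, background)
    } else mip_slices(get, w, h, nz, background)
    return(stretch_axis(img, sp[3] / sp[2], along = 2L))
  }
  # axis == "y": rows = x (columns of the section), cols = z
  ord <- if (fwd) seq_len(h) else rev(seq_len(h))
  get <- function(k) {
    sl <- vox[ord[k], , , , drop = FALSE]
    dim(sl) <- c(w, nz, 4L)
    sl
  }
  img <- if (mode == "composite") {
    composite_slices(get, h, w, nz, background)
  } else mip_slices(get, h, w, nz, background)
  stretch_axis(img, sp[3] / sp[1], along = 2L)
}

# generic orthographic ray caster, nearest-voxel sampling
render_oblique <- function(volume, azimuth_deg, elevation_deg,
                           mode = "composite", background = c(255, 255, 255)) {
  vox <- volume$voxels
  d <- dim(vox)
  sp <- volume$spacing
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  dir <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))  # ray direction
  up <- if (abs(dir[3]) < 0.99) c(0, 0, 1) else c(0, 1, 0)
  u <- c(dir[2] * up[3] - dir[3] * up[2],
         dir[3] * up[1] - dir[1] * up[3],
         dir[1] * up[2] - dir[2] * up[1])
  u <- u / sqrt(sum(u^2))
  v <- c(u[2] * dir[3] - u[3] * dir[2],
         u[3] * dir[1] - u[1] * dir[3],
         u[1] * dir[2] - u[2] * dir[1])
  # physical-corner projections set the film extent
  ext <- c((d[2] - 1) * sp[1], (d[1] - 1) * sp[2], (d[3] - 1) * sp[3])
  corners <- as.matrix(expand.grid(x = c(0, ext[1]), y = c(0, ext[2]),
                                   z = c(0, ext[3])))
  pu <- corners %*% u
  pv <- corners %*% v
  pd <- corners %*% dir
  pitch <- min(sp)
  us <- seq(min(pu), max(pu), by = pitch)
  vs <- seq(min(pv), max(pv), by = pitch)
  step <- min(sp) / 2
  ts <- seq(min(pd), max(pd), by = step)
  npix <- length(us) * length(vs)
  U <- rep(us, times = length(vs))
  V <- rep(vs, each = length(us))
  h_out <- length(vs); w_out <- length(us)

  Cacc <- array(0, c(npix, 3L))
  Aacc <- numeric(npix)
  Atouch <- numeric(npix)
  for (t in ts) {
    px <- U * u[1] + V * v[1] + t * dir[1]
    py <- U * u[2] + V * v[2] + t * dir[2]
    pz <- U * u[3] + V * v[3] + t * dir[3]
    ci <- round(px / sp[1]) + 1
    ri <- round(py / sp[2]) + 1
    zi <- round(pz / sp[3]) + 1
    ok <- ci >= 1 & ci <= d[2] & ri >= 1 & ri <= d[1] & zi >= 1 & zi <= d[3]
    if (!any(ok)) next
    lin <- (ri[ok] - 1) + (ci[ok] - 1) * d[1] + (zi[ok] - 1) * d[1] * d[2]
    plane_sz <- d[1] * d[2] * d[3]
    a <- vox[lin + 3 * plane_sz + 1] / 255
    if (mode == "composite") {
      wgt <- (1 - Aacc[ok]) * a
      for (ch in 1:3) {
        Cacc[ok, ch] <- Cacc[ok, ch] + wgt * vox[lin + (ch - 1) * plane_sz + 1]
      }
      Aacc[ok] <- Aacc[ok] + wgt
      if (min(Aacc) >= 0.999) break
    } else {
      for (ch in 1:3) {
        Cacc[ok, ch] <- pmax(Cacc[ok, ch],
                             a * vox[lin + (ch - 1) * plane_sz + 1])
      }
      Atouch[ok] <- pmax(Atouch[ok], a)
    }
  }
  if (mode == "composite") {
    for (ch in 1:3) Cacc[, ch] <- Cacc[, ch] + (1 - Aacc) * background[ch]
  } else {
    empty <- Atouch == 0
    for (ch in 1:3) Cacc[empty, ch] <- background[ch]
  }
  out <- array(0L, c(h_out, w_out, 3L))
  for (ch in 1:3) {
    out[, , ch] <- to_u8(matrix(Cacc[, ch], nrow = w_out,
                                ncol = h_out)[, h_out:1, drop = FALSE] |> t())
  }
  out
}

#' Render a turntable sequence
#'
#' Emits `n` frames rotating the azimuth through 360 degrees at fixed
#' elevation, written as numbered PNGs.
#' @param volume an [rgba_volume].
#' @param n number of frames.
#' @param directory output directory.
#' @param elevation_deg camera elevation.
#' @param mode `"composite"` or `"mip"`.
#' @param background background color.
#' @return invisibly, the vector of file paths.
#' @export
render_turntable <- function(volume, n, directory, elevation_deg = 20,
                             mode = "composite",
                             background = c(255, 255, 255)) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n)
  for (i in seq_len(n)) {
    az <- 360 * (i - 1) / n
    img <- render_projection(volume, c(az, elevation_deg), mode, background)
    paths[i] <- file.path(directory, sprintf("frame_%04d.png", i - 1L))
    png::writePNG(img / 255, paths[i])
  }
  invisible(paths)
}
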