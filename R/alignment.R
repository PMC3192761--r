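#' Rigid 2D transform (rotation + translation)
#'
#' The transform maps a point `p = (x, y)` (pixel coordinates, x along
#' columns, y along rows, 0-based) of the *moving* section into the frame of
#' the *reference* section:
#' \deqn{T(p) = R(\theta)\,(p - c) + c + t}
#' where `c` is the rotation center (by convention the image center, so theta
#' and t are decoupled the way manual slice alignment behaves). The linear
#' part is a pure rotation (determinant +1): no scale or shear, so the
#' physical pixel size is preserved.
#'
#' @param theta rotation angle in radians, counterclockwise.
#' @param tx,ty translation in pixels.
#' @param center rotation center `c(cx, cy)` in 0-based pixel coordinates.
#' @return object of class `rigid2d`.
#' @export
rigid2d <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty),
            length(center) == 2L, all(is.finite(center)))
  structure(list(theta = as.numeric(theta), tx = as.numeric(tx),
                 ty = as.numeric(ty), center = as.numeric(center)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: theta = %.4f deg, t = (%.3f, %.3f), center = (%g, %g)\n",
              x$theta * 180 / pi, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

#' Homogeneous 3x3 matrix of a rigid transform
#' @param transform a [rigid2d].
#' @return 3x3 numeric matrix acting on column vectors `(x, y, 1)`.
#' @export
rigid_matrix <- function(transform) {
  th <- transform$theta
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  c0 <- transform$center
  b <- c0 + c(transform$tx, transform$ty) - R %*% c0
  rbind(cbind(R, b), c(0, 0, 1))
}

matrix_to_rigid <- function(M, center = c(0, 0)) {
  theta <- atan2(M[2, 1], M[1, 1])
  R <- M[1:2, 1:2]
  t <- M[1:2, 3] - center + as.vector(R %*% center)
  rigid2d(theta, t[1], t[2], center)
}

#' Compose two rigid transforms
#'
#' `rigid_compose(a, b)` returns the transform applying `b` first, then `a`
#' (i.e. `a %*% b` on homogeneous matrices). Both must share a rotation
#' center; the result keeps it.
#' @param a,b [rigid2d] transforms with the same center.
#' @return a [rigid2d].
#' @export
rigid_compose <- function(a, b) {
  stopifnot(isTRUE(all.equal(a$center, b$center)))
  matrix_to_rigid(rigid_matrix(a) %*% rigid_matrix(b), a$center)
}

#' Invert a rigid transform
#' @param transform a [rigid2d].
#' @return the inverse [rigid2d] (same center).
#' @export
rigid_invert <- function(transform) {
  matrix_to_rigid(solve(rigid_matrix(transform)), transform$center)
}

#' Apply a rigid transform to points
#' @param transform a [rigid2d].
#' @param points n x 2 matrix of `(x, y)` pixel coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
rigid_apply <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  M <- rigid_matrix(transform)
  out <- cbind(points, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}

#' Least-squares rigid transform from landmark pairs
#'
#' Solves the 2D orthogonal Procrustes problem for the rigid transform that
#' carries the moving-section landmarks onto the fixed-section landmarks:
#' centroids are removed, the rotation comes from the cross-covariance of the
#' centered sets (reflections excluded by construction of the 2D closed form),
#' and the translation re-attaches the centroids under the chosen rotation
#' center convention.
#'
#' @param fixed n x 2 matrix of `(x, y)` landmarks on the fixed section.
#' @param moving n x 2 matrix of corresponding landmarks on the moving section.
#' @param center rotation center for the returned transform (image center in
#'   the usual workflow).
#' @return list with `transform` ([rigid2d]) and `rms` (root-mean-square
#'   residual in pixels).
#' @examples
#' p <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' estimate_rigid_from_landmarks(p + 2, p)$transform$tx  # 2
#' @export
estimate_rigid_from_landmarks <- function(fixed, moving, center = c(0, 0)) {
  fixed <- matrix(as.numeric(fixed), ncol = 2L)
  moving <- matrix(as.numeric(moving), ncol = 2L)
  if (nrow(fixed) != nrow(moving)) stop("landmark sets differ in length")
  if (nrow(fixed) < 2L) stop("degenerate landmarks: need >= 2 pairs")
  if (!all(is.finite(fixed)) || !all(is.finite(moving))) {
    stop("landmark coordinates must be finite")
  }
  cf <- colMeans(fixed)
  cm <- colMeans(moving)
  Fm <- sweep(fixed, 2L, cf)
  Mm <- sweep(moving, 2L, cm)
  if (all(abs(Mm) < 1e-12) || all(abs(Fm) < 1e-12)) {
    if (all(abs(Mm) < 1e-12) && all(abs(Fm) < 1e-12)) {
      # all points coincident on both sides: translation only
      if (nrow(fixed) < 2L) stop("degenerate landmarks")
      stop("degenerate landmarks: all points coincident")
    }
    stop("degenerate landmarks: all points coincident")
  }
  # 2D closed form: theta = atan2(sum(xm*yf - ym*xf), sum(xm*xf + ym*yf))
  s <- sum(Mm[, 1] * Fm[, 2] - Mm[, 2] * Fm[, 1])
  cth <- sum(Mm[, 1] * Fm[, 1] + Mm[, 2] * Fm[, 2])
  theta <- atan2(s, cth)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  # T(p) = R (p - c) + c + t must send cm to cf
  t <- cf - (as.vector(R %*% (cm - center)) + center)
  tr <- rigid2d(theta, t[1], t[2], center)
  res <- rigid_apply(tr, moving) - fixed
  list(transform = tr, rms = sqrt(mean(rowSums(res^2))))
}

#' Chain pairwise transforms into absolute (to-reference) transforms
#'
#' Given `pairwise[[i]]` mapping section `i + 1` into the frame of section
#' `i`, returns absolute transforms into the frame of the first (reference)
#' section: `absolute[[1]] = identity`,
#' `absolute[[i + 1]] = absolute[[i]] o pairwise[[i]]`.
#'
#' @param pairwise list of [rigid2d], length `n - 1` for an `n`-section stack.
#' @return list of `n` absolute [rigid2d] transforms.
#' @export
compose_to_reference <- function(pairwise) {
  center <- if (length(pairwise)) pairwise[[1]]$center else c(0, 0)
  absolute <- vector("list", length(pairwise) + 1L)
  absolute[[1]] <- rigid2d(center = center)
  for (i in seq_along(pairwise)) {
    absolute[[i + 1L]] <- rigid_compose(absolute[[i]], pairwise[[i]])
  }
  absolute
}

#' Resample a section under a rigid transform
#'
#' Inverse-mapping resampling: output pixel `p` takes the input value at
#' `T^{-1}(p)`, with `"nearest"` or `"bilinear"` interpolation. Samples
#' falling outside the input canvas are filled with pure white, the
#' background convention of the downstream editing stage. The output canvas
#' equals the input canvas.
#'
#' @param section a [section_image] (or an `H x W` grayscale matrix).
#' @param transform a [rigid2d] mapping the section into the reference frame.
#' @param interpolation `"bilinear"` (display images) or `"nearest"`
#'   (label masks; never mixes values).
#' @return resampled [section_image] (or matrix, matching the input).
#' @export
resample_section <- function(section, transform,
                             interpolation = c("bilinear", "nearest")) {
  if (!is.character(interpolation) ||
      !all(interpolation %in% c("bilinear", "nearest"))) {
    stop("unknown interpolation; use 'bilinear' or 'nearest'")
  }
  interpolation <- match.arg(interpolation)
  is_gray <- is.matrix(section)
  px <- if (is_gray) section else section$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  Minv <- solve(rigid_matrix(transform))
  # output pixel grid, 0-based (x = col - 1, y = row - 1)
  xs <- rep(0:(w - 1L), each = h)
  ys <- rep(0:(h - 1L), times = w)
  sx <- Minv[1, 1] * xs + Minv[1, 2] * ys + Minv[1, 3]
  sy <- Minv[2, 1] * xs + Minv[2, 2] * ys + Minv[2, 3]

  sample_plane <- function(plane) {
    out <- matrix(255, h, w)
    if (interpolation == "nearest") {
      ri <- round(sy) + 1; ci <- round(sx) + 1
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      out[cbind(rep(1:h, w)[ok], rep(1:w, each = h)[ok])] <-
        plane[cbind(ri[ok], ci[ok])]
    } else {
      ok <- sx >= 0 & sx <= (w - 1) & sy >= 0 & sy <= (h - 1)
      # clamp the cell so samples exactly on the far edge stay in range
      x0 <- pmin(floor(sx), max(w - 2, 0)); y0 <- pmin(floor(sy), max(h - 2, 0))
      fx <- sx - x0; fy <- sy - y0
      r0 <- y0 + 1; c0 <- x0 + 1
      v <- (1 - fx[ok]) * (1 - fy[ok]) * plane[cbind(r0[ok], c0[ok])] +
           fx[ok] * (1 - fy[ok]) * plane[cbind(r0[ok], c0[ok] + 1)] +
           (1 - fx[ok]) * fy[ok] * plane[cbind(r0[ok] + 1, c0[ok])] +
           fx[ok] * fy[ok] * plane[cbind(r0[ok] + 1, c0[ok] + 1)]
      out[cbind(rep(1:h, w)[ok], rep(1:w, each = h)[ok])] <- v
    }
    out
  }

  if (is_gray) {
    return(to_u8(sample_plane(px)))
  }
  out <- array(0L, dim(px))
  for (ch in 1:3) out[, , ch] <- to_u8(sample_plane(px[, , ch]))
  with_pixels(section, out)
}

image_center <- function(img) {
  d <- if (is.matrix(img)) dim(img) else dim(img$pixels)
  c((d[2] - 1) / 2, (d[1] - 1) / 2)
}

#' Automatic rigid alignment of a section pair
#'
#' Convenience replacement for manual landmarking: the translation comes from
#' phase correlation of the grayscale images; optionally a coarse angular
#' search (maximizing the phase-correlation peak) estimates an in-plane
#' rotation first. This is a heuristic — the landmark path
#' ([estimate_rigid_from_landmarks]) remains the reference behavior.
#'
#' @param fixed,moving [section_image]s (or grayscale matrices) of equal size.
#' @param rotation_range half-width of the angular search in degrees; `0`
#'   restricts to pure translation.
#' @param rotation_step angular search step in degrees.
#' @return a [rigid2d] mapping `moving` into the frame of `fixed` (center =
#'   image center).
#' @export
auto_align_pair <- function(fixed, moving, rotation_range = 0,
                            rotation_step = 0.5) {
  gf <- if (is.matrix(fixed)) fixed else to_grayscale(fixed)
  gm <- if (is.matrix(moving)) moving else to_grayscale(moving)
  if (!all(dim(gf) == dim(gm))) stop("images must share dimensions")
  if (stats::sd(gf) == 0 || stats::sd(gm) == 0) {
    stop("alignment failure: featureless (constant) image")
  }
  center <- image_center(gf)

  peak_for <- function(theta_deg) {
    g2 <- if (theta_deg == 0) gm else {
      resample_section(gm, rigid2d(theta = theta_deg * pi / 180,
                                   center = center), "bilinear")
    }
    Fa <- stats::fft(gf)
    Fb <- stats::fft(g2)
    R <- Fa * Conj(Fb)
    mag <- Mod(R)
    mag[mag < 1e-12] <- 1e-12
    corr <- Re(stats::fft(R / mag, inverse = TRUE))
    i <- which.max(corr)
    h <- nrow(gf); w <- ncol(gf)
    ri <- (i - 1L) %% h; ci <- (i - 1L) %/% h
    dy <- if (ri > h / 2) ri - h else ri
    dx <- if (ci > w / 2) ci - w else ci
    list(value = max(corr), dx = dx, dy = dy, theta_deg = theta_deg)
  }

  angles <- if (rotation_range > 0) {
    seq(-rotation_range, rotation_range, by = rotation_step)
  } else 0
  best <- NULL
  for (a in angles) {
    p <- peak_for(a)
    if (is.null(best) || p$value > best$value) best <- p
  }
  # phase correlation finds the shift d with moving(p) ~ fixed(p - d);
  # mapping moving into fixed's frame is the translation +d after rotation
  rigid_compose(rigid2d(tx = best$dx, ty = best$dy, center = center),
                rigid2d(theta = best$theta_deg * pi / 180, center = center))
}

#' Read landmark pairs from a plain-text file
#'
#' One row per pair: `i_fixed x y i_moving x y` (whitespace- or
#' comma-separated; `#` comments allowed).
#' @param path landmark file.
#' @return list with `fixed` and `moving` n x 2 matrices and the two section
#'   indices.
#' @export
read_landmarks <- function(path) {
  tb <- utils::read.table(path, comment.char = "#", sep = "",
                          col.names = c("i_fixed", "xf", "yf",
                                        "i_moving", "xm", "ym"))
  list(fixed = as.matrix(tb[, c("xf", "yf")]),
       moving = as.matrix(tb[, c("xm", "ym")]),
       i_fixed = tb$i_fixed[1], i_moving = tb$i_moving[1])
}

#' Write transforms to a YAML sidecar
#' @param transforms list of [rigid2d], one per section.
#' @param path output path.
#' @param indices optional section indices (defaults to 0-based order).
#' @return invisibly, `path`.
#' @export
write_transforms <- function(transforms, path, indices = NULL) {
  if (is.null(indices)) indices <- seq_along(transforms) - 1L
  recs <- Map(function(tr, i) {
    list(index = as.integer(i), theta_deg = tr$theta * 180 / pi,
         tx = tr$tx, ty = tr$ty,
         center = as.numeric(tr$center))
  }, transforms, indices)
  yaml::write_yaml(list(transforms = recs), path)
  invisible(path)
}

#' Read transforms written by [write_transforms]
#' @param path YAML transforms file.
#' @return list of [rigid2d].
#' @export
read_transforms <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw$transforms, function(r) {
    rigid2d(r$theta_deg * pi / 180, r$tx, r$ty, unlist(r$center))
  })
}
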