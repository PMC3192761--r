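#' Branching tube-tree phantom specification
#'
#' Geometry of the synthetic validation object: a branching tube (portal
#' vein-like lumen with a stained wall, optionally sheathed by an annular
#' "ductal plate" sleeve) growing through the block in z, plus optional
#' deliberately detached stained spheres — the ground-truth counterpart of
#' stained aggregations without connection to the duct system. All randomness
#' flows from the single seed.
#'
#' Defaults emulate the study conditions the protocol was designed for: a
#' block of 240 x 240 x 250 um (fifty 5-um sections) sampled on an isotropic
#' 2.5-um grid, a trunk of 22 um radius with two binary branching levels, and
#' DAB-plausible stain geometry (7.5-um stained wall).
#'
#' @param trunk_radius_um trunk outer radius (um).
#' @param wall_um stained wall thickness (um).
#' @param branch_factor children per node.
#' @param depth branching levels below the trunk (0 = single straight tube).
#' @param branch_angle_deg `c(min, max)` polar deviation of a child from its
#'   parent direction (degrees).
#' @param segment_length_um `c(min, max)` trunk segment length (um); child
#'   lengths and radii shrink by 0.7 and 0.8 per level.
#' @param sleeve_um annular sleeve thickness directly sheathing the wall
#'   (um); 0 disables the sleeve.
#' @param detached_bodies number of isolated stained spheres.
#' @param detached_radius_um radius of each detached sphere (um).
#' @param extent_um block size `c(x, y, z)` in um.
#' @param grid_res_um isotropic grid resolution (um); the z extent must be a
#'   multiple of it.
#' @param seed random seed fixing all phantom randomness.
#' @return object of class `tube_tree_spec`.
#' @export
tube_tree_spec <- function(trunk_radius_um = 22, wall_um = 7.5,
                           branch_factor = 2L, depth = 2L,
                           branch_angle_deg = c(15, 35),
                           segment_length_um = c(70, 90),
                           sleeve_um = 0, detached_bodies = 0L,
                           detached_radius_um = 12,
                           extent_um = c(240, 240, 250),
                           grid_res_um = 2.5, seed = 1L) {
  stopifnot(trunk_radius_um > 0, wall_um > 0, wall_um < trunk_radius_um,
            branch_factor >= 1L, depth >= 0L,
            length(branch_angle_deg) == 2L, length(segment_length_um) == 2L,
            sleeve_um >= 0, detached_bodies >= 0L, detached_radius_um > 0,
            length(extent_um) == 3L, all(extent_um > 0), grid_res_um > 0)
  structure(list(trunk_radius_um = trunk_radius_um, wall_um = wall_um,
                 branch_factor = as.integer(branch_factor),
                 depth = as.integer(depth),
                 branch_angle_deg = branch_angle_deg,
                 segment_length_um = segment_length_um,
                 sleeve_um = sleeve_um,
                 detached_bodies = as.integer(detached_bodies),
                 detached_radius_um = detached_radius_um,
                 extent_um = as.numeric(extent_um),
                 grid_res_um = grid_res_um, seed = as.integer(seed)),
            class = "tube_tree_spec")
}

#' Histochemical appearance model for phantom rendering
#'
#' Colors approximate a DAB (brown) stain over a pale hematoxylin-like
#' counterstain on a near-white slide background; they are a plausibility
#' choice recorded in config, not measured values. Noise is per-channel
#' Gaussian plus Poisson-placed dark specks.
#'
#' @param stain stain (DAB-like) color.
#' @param counterstain pale counterstain color of unstained tissue.
#' @param background slide background color.
#' @param lumen vessel-lumen color (near-white).
#' @param sleeve sleeve (ductal-plate) stain color.
#' @param speck dark speck color.
#' @param noise_sigma per-channel Gaussian sigma (gray levels).
#' @param speck_rate expected dark specks per square millimetre.
#' @return object of class `stain_model`.
#' @export
stain_model <- function(stain = c(120, 70, 40),
                        counterstain = c(190, 175, 210),
                        background = c(248, 247, 245),
                        lumen = c(240, 238, 236),
                        sleeve = c(150, 105, 70),
                        speck = c(60, 50, 45),
                        noise_sigma = 4, speck_rate = 50) {
  stopifnot(noise_sigma >= 0, speck_rate >= 0)
  cols <- list(stain = stain, counterstain = counterstain,
               background = background, lumen = lumen, sleeve = sleeve,
               speck = speck)
  for (v in cols) stopifnot(length(v) == 3L, all(v >= 0), all(v <= 255))
  structure(c(cols, list(noise_sigma = noise_sigma, speck_rate = speck_rate)),
            class = "stain_model")
}

# phantom ground-truth label ids
PH_BG <- 0L; PH_LUMEN <- 1L; PH_WALL <- 2L; PH_SLEEVE <- 3L
PH_DETACHED <- 4L; PH_TISSUE <- 5L

# distance from grid points to a 3D segment, vectorized over points
dist_to_segment <- function(X, Y, Z, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) {
    return(sqrt((X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2))
  }
  t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
  t[t < 0] <- 0
  t[t > 1] <- 1
  sqrt((X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
       (Z - (p0[3] + t * v[3]))^2)
}

#' Generate a branching tube-tree phantom
#'
#' Rasterizes a recursive tube tree into an isotropic micrometre grid with
#' ground-truth labels (0 background, 1 lumen, 2 stained wall, 3 sleeve,
#' 4 detached body, 5 unstained tissue) and returns the topology record:
#' the segment table (parent/child/level/endpoints/radius) and the detached
#' bodies. Identical specs give bit-identical output. Anisotropy enters only
#' later, at the virtual-sectioning stage, mirroring how thin sections and a
#' coarse z-step arise in reality.
#'
#' @param spec a [tube_tree_spec].
#' @return object of class `tube_tree_phantom`: list with `labels`
#'   (`H x W x Zg` integer array), `grid_res_um`, `extent_um`, `segments`
#'   (data.frame), `detached` (data.frame), `spec`.
#' @export
generate_tube_tree <- function(spec = tube_tree_spec()) {
  stopifnot(inherits(spec, "tube_tree_spec"))
  set.seed(spec$seed)
  res <- spec$grid_res_um
  nx <- round(spec$extent_um[1] / res)
  ny <- round(spec$extent_um[2] / res)
  nz <- round(spec$extent_um[3] / res)
  # grid point physical coordinates (voxel centers)
  xs <- (seq_len(nx) - 0.5) * res
  ys <- (seq_len(ny) - 0.5) * res
  zs <- (seq_len(nz) - 0.5) * res
  X <- array(rep(xs, each = ny), c(ny, nx, nz))
  Y <- array(rep(ys, times = nx * nz), c(ny, nx, nz))
  Z <- array(rep(zs, each = ny * nx), c(ny, nx, nz))

  # grow the tree: trunk starts at the block center of the first section,
  # pointing in +z with slight jitter; children deviate by the branch angle
  segs <- list()
  grow <- function(p0, dir, level, parent) {
    len <- stats::runif(1, spec$segment_length_um[1],
                        spec$segment_length_um[2]) * 0.7^level
    radius <- spec$trunk_radius_um * 0.8^level
    p1 <- p0 + dir * len
    id <- length(segs) + 1L
    segs[[id]] <<- c(id = id, parent = parent, level = level,
                     x0 = p0[1], y0 = p0[2], z0 = p0[3],
                     x1 = p1[1], y1 = p1[2], z1 = p1[3], radius = radius)
    if (level < spec$depth) {
      for (k in seq_len(spec$branch_factor)) {
        ang <- stats::runif(1, spec$branch_angle_deg[1],
                            spec$branch_angle_deg[2]) * pi / 180
        azi <- stats::runif(1, 0, 2 * pi)
        # perturb the parent direction by polar angle `ang`
        a <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        u <- c(dir[2] * a[3] - dir[3] * a[2],
               dir[3] * a[1] - dir[1] * a[3],
               dir[1] * a[2] - dir[2] * a[1])
        u <- u / sqrt(sum(u^2))
        w <- c(dir[2] * u[3] - dir[3] * u[2],
               dir[3] * u[1] - dir[1] * u[3],
               dir[1] * u[2] - dir[2] * u[1])
        nd <- cos(ang) * dir + sin(ang) * (cos(azi) * u + sin(azi) * w)
        nd <- nd / sqrt(sum(nd^2))
        grow(p1, nd, level + 1L, id)
      }
    }
  }
  start <- c(spec$extent_um[1] / 2, spec$extent_um[2] / 2, 2)
  jitter <- stats::runif(2, -0.05, 0.05)
  dir0 <- c(jitter, 1)
  dir0 <- dir0 / sqrt(sum(dir0^2))
  grow(start, dir0, 0L, NA_integer_)
  segments <- as.data.frame(do.call(rbind, segs))

  # bounds check: every capsule (+ sleeve) must stay inside the block
  reach <- segments$radius + spec$sleeve_um
  if (any(segments$x1 < reach) || any(segments$x1 > spec$extent_um[1] - reach) ||
      any(segments$y1 < reach) || any(segments$y1 > spec$extent_um[2] - reach) ||
      any(segments$z1 > spec$extent_um[3])) {
    stop("phantom exceeds grid bounds; enlarge extent_um or reduce ",
         "depth/segment lengths")
  }

  # signed distance beyond the local tube radius, minimized over segments
  excess <- array(Inf, c(ny, nx, nz))
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    dseg <- dist_to_segment(X, Y, Z, c(s$x0, s$y0, s$z0),
                            c(s$x1, s$y1, s$z1))
    excess <- pmin(excess, dseg - s$radius)
  }
  labels <- array(PH_TISSUE, c(ny, nx, nz))
  labels[excess <= 0 & excess > -spec$wall_um] <- PH_WALL
  labels[excess <= -spec$wall_um] <- PH_LUMEN
  if (spec$sleeve_um > 0) {
    labels[excess > 0 & excess <= spec$sleeve_um] <- PH_SLEEVE
  }
  # tissue disc: outside it lies slide background
  rx <- 0.46 * spec$extent_um[1]
  ry <- 0.46 * spec$extent_um[2]
  in_disc <- ((X - spec$extent_um[1] / 2) / rx)^2 +
             ((Y - spec$extent_um[2] / 2) / ry)^2 <= 1
  labels[!in_disc] <- PH_BG

  # detached stained spheres, placed clear of the tree and the block faces
  detached <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), radius = numeric(0))
  if (spec$detached_bodies > 0L) {
    clearance <- 12
    placed <- 0L
    tries <- 0L
    while (placed < spec$detached_bodies && tries < 2000L) {
      tries <- tries + 1L
      r <- spec$detached_radius_um
      cand <- c(stats::runif(1, r + 6, spec$extent_um[1] - r - 6),
                stats::runif(1, r + 6, spec$extent_um[2] - r - 6),
                stats::runif(1, r + 6, spec$extent_um[3] - r - 6))
      # inside the tissue disc?
      if (((cand[1] - spec$extent_um[1] / 2) / (rx - r))^2 +
          ((cand[2] - spec$extent_um[2] / 2) / (ry - r))^2 > 1) next
      # clear of the tube tree (and previously placed bodies)?
      dtree <- min(vapply(seq_len(nrow(segments)), function(i) {
        s <- segments[i, ]
        dist_to_segment(cand[1], cand[2], cand[3],
                        c(s$x0, s$y0, s$z0), c(s$x1, s$y1, s$z1)) - s$radius
      }, numeric(1)))
      if (dtree < r + spec$sleeve_um + clearance) next
      if (nrow(detached) > 0L) {
        dprev <- min(sqrt((detached$x - cand[1])^2 +
                          (detached$y - cand[2])^2 +
                          (detached$z - cand[3])^2))
        if (dprev < 2 * r + clearance) next
      }
      placed <- placed + 1L
      detached <- rbind(detached,
                        data.frame(id = placed, x = cand[1], y = cand[2],
                                   z = cand[3], radius = r))
      sphere <- sqrt((X - cand[1])^2 + (Y - cand[2])^2 +
                     (Z - cand[3])^2) <= r
      labels[sphere] <- PH_DETACHED
    }
    if (placed < spec$detached_bodies) {
      stop("could not place all detached bodies; enlarge extent_um")
    }
  }
  structure(list(labels = labels, grid_res_um = res,
                 extent_um = spec$extent_um, segments = segments,
                 detached = detached, spec = spec),
            class = "tube_tree_phantom")
}

#' @export
print.tube_tree_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "tube_tree_phantom: %d x %d x %d grid @ %g um, %d segments, %d detached\n",
    d[1], d[2], d[3], x$grid_res_um, nrow(x$segments), nrow(x$detached)))
  invisible(x)
}

#' Virtually section a phantom into a stained RGB stack
#'
#' Cuts the isotropic phantom grid into sections of the given thickness
#' (which must be a multiple of the grid resolution), renders each section
#' with the stain model (stain/sleeve/lumen/counterstain/background colors,
#' Gaussian channel noise, Poisson-placed dark specks) and returns the stack
#' together with noise-free per-section ground-truth label masks. Within a
#' section slab the most stain-like structure wins the pixel, emulating the
#' full-thickness opacity of chromogen deposits.
#'
#' @param phantom a `tube_tree_phantom`.
#' @param thickness_um section thickness (um).
#' @param stain a [stain_model].
#' @param seed seed for rendering noise (defaults to the phantom seed + 1).
#' @return list with `stack` (a `section_stack`), `masks` (list of `H x W`
#'   integer ground-truth masks) and `planes_per_section`.
#' @export
virtual_sections <- function(phantom, thickness_um = 5,
                             stain = stain_model(), seed = NULL) {
  stopifnot(inherits(phantom, "tube_tree_phantom"))
  res <- phantom$grid_res_um
  pps <- thickness_um / res
  if (abs(pps - round(pps)) > 1e-9) {
    stop("thickness_um must be a multiple of the grid resolution (",
         res, " um)")
  }
  pps <- as.integer(round(pps))
  d <- dim(phantom$labels)
  if (d[3] %% pps != 0L) {
    stop("grid z-extent is not divisible into whole sections")
  }
  n_sections <- d[3] %/% pps
  if (is.null(seed)) seed <- phantom$spec$seed + 1L
  set.seed(seed)
  # priority when collapsing a slab to one mask pixel
  priority <- c(0, 2, 4, 3, 5, 1)  # indexed by label id + 1
  colors <- rbind(stain$background, stain$lumen, stain$stain, stain$sleeve,
                  stain$stain, stain$counterstain)  # by label id + 1
  area_mm2 <- prod(d[1:2]) * (res / 1000)^2
  sections <- vector("list", n_sections)
  masks <- vector("list", n_sections)
  for (si in seq_len(n_sections)) {
    slab <- phantom$labels[, , ((si - 1L) * pps + 1L):(si * pps),
                           drop = FALSE]
    pr <- array(priority[slab + 1L], dim(slab))
    best <- apply(pr, c(1, 2), which.max)
    mask <- matrix(0L, d[1], d[2])
    for (k in seq_len(pps)) {
      sel <- best == k
      mask[sel] <- slab[, , k][sel]
    }
    masks[[si]] <- mask
    px <- array(0, c(d[1], d[2], 3L))
    for (ch in 1:3) {
      px[, , ch] <- matrix(colors[mask + 1L, ch], d[1], d[2])
    }
    if (stain$speck_rate > 0) {
      n_specks <- stats::rpois(1, stain$speck_rate * area_mm2)
      if (n_specks > 0) {
        sr <- sample.int(d[1], n_specks, replace = TRUE)
        sc <- sample.int(d[2], n_specks, replace = TRUE)
        for (q in seq_len(n_specks)) {
          rr <- max(1, sr[q] - 1):min(d[1], sr[q] + 1)
          cc <- max(1, sc[q] - 1):min(d[2], sc[q] + 1)
          for (ch in 1:3) px[rr, cc, ch] <- stain$speck[ch]
        }
      }
    }
    if (stain$noise_sigma > 0) {
      px <- px + stats::rnorm(length(px), 0, stain$noise_sigma)
    }
    sections[[si]] <- section_image(to_u8(px), pixel_size_um = res,
                                    section_index = si - 1L,
                                    thickness_um = thickness_um)
  }
  man <- stack_manifest(data.frame(index = seq_len(n_sections) - 1L,
                                   file = NA_character_),
                        thickness_um = thickness_um, pixel_size_um = res)
  list(stack = section_stack(sections, man), masks = masks,
       planes_per_section = pps)
}

#' Inject per-section rigid misalignment
#'
#' Displaces every section (except the first, the reference) by a rigid
#' transform drawn from centered Gaussians and returns, per section, the
#' exact transform that realigns it — the ground truth the alignment stage
#' must recover. Seed-reproducible.
#'
#' @param stack a `section_stack`.
#' @param sigma_t_px translation sigma (pixels).
#' @param sigma_theta_deg rotation sigma (degrees).
#' @param seed random seed.
#' @param interpolation passed to [resample_section].
#' @return list with `stack` (misaligned) and `truth` (list of [rigid2d]
#'   mapping each misaligned section back into the reference frame).
#' @export
perturb_alignment <- function(stack, sigma_t_px = 5, sigma_theta_deg = 2,
                              seed = 1L, interpolation = "bilinear") {
  stopifnot(inherits(stack, "section_stack"),
            sigma_t_px >= 0, sigma_theta_deg >= 0)
  set.seed(seed)
  center <- image_center(stack$sections[[1]])
  n <- length(stack$sections)
  out <- stack$sections
  truth <- vector("list", n)
  truth[[1]] <- rigid2d(center = center)
  for (i in seq_len(n)[-1]) {
    applied <- rigid2d(theta = stats::rnorm(1, 0, sigma_theta_deg) * pi / 180,
                       tx = stats::rnorm(1, 0, sigma_t_px),
                       ty = stats::rnorm(1, 0, sigma_t_px),
                       center = center)
    if (sigma_t_px == 0 && sigma_theta_deg == 0) {
      truth[[i]] <- rigid2d(center = center)
      next
    }
    out[[i]] <- resample_section(stack$sections[[i]], applied, interpolation)
    truth[[i]] <- rigid_invert(applied)
  }
  list(stack = section_stack(out, stack$manifest), truth = truth)
}
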