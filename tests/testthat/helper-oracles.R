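# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no igraph, no vectorized index arithmetic):
# plain queue-based flood fill and exhaustive search.

# connected components of a 3D logical mask by breadth-first flood fill
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- switch(as.character(connectivity),
    "6" = offs[rowSums(abs(offs)) == 1, ],
    "18" = offs[rowSums(abs(offs)) <= 2, ],
    "26" = offs)
  comp <- array(0L, d)
  n <- 0L
  sizes <- integer(0)
  for (s in seq_len(d[3])) for (cc in seq_len(d[2])) for (r in seq_len(d[1])) {
    if (!mask[r, cc, s] || comp[r, cc, s] > 0L) next
    n <- n + 1L
    queue <- matrix(c(r, cc, s), ncol = 3)
    comp[r, cc, s] <- n
    size <- 0L
    while (nrow(queue) > 0L) {
      v <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- v[1] + offs$dr[k]; c2 <- v[2] + offs$dc[k]; s2 <- v[3] + offs$ds[k]
        if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2] ||
            s2 < 1 || s2 > d[3]) next
        if (mask[r2, c2, s2] && comp[r2, c2, s2] == 0L) {
          comp[r2, c2, s2] <- n
          queue <- rbind(queue, c(r2, c2, s2))
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(map = comp, sizes = sizes, n = n)
}

# BFS verdicts: is each flood-fill component of `mask` adjacent to (or
# overlapping) the reference mask under the connectivity rule?
bfs_connectivity_verdicts <- function(mask, ref_mask, connectivity = 26L) {
  d <- dim(mask)
  oc <- flood_fill_components(mask, connectivity)
  offs <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offs <- switch(as.character(connectivity),
    "6" = offs[rowSums(abs(offs)) == 1, ],
    "18" = offs[rowSums(abs(offs)) <= 2, ],
    "26" = offs[rowSums(abs(offs)) > 0, ])
  offs <- rbind(c(dr = 0, dc = 0, ds = 0), offs)
  connected <- rep(FALSE, oc$n)
  idx <- which(ref_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    for (k in seq_len(nrow(offs))) {
      r2 <- idx[i, 1] + offs$dr[k]
      c2 <- idx[i, 2] + offs$dc[k]
      s2 <- idx[i, 3] + offs$ds[k]
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2] ||
          s2 < 1 || s2 > d[3]) next
      id <- oc$map[r2, c2, s2]
      if (id > 0L) connected[id] <- TRUE
    }
  }
  list(components = oc, connected = connected)
}

# exhaustive rigid fit: grid search over theta, translation derived from the
# centroids for each candidate angle (independent of the closed form)
grid_search_rigid <- function(fixed, moving, center,
                              theta_grid = seq(-20, 20, by = 0.05) * pi / 180) {
  best <- NULL
  cf <- colMeans(fixed)
  cm <- colMeans(moving)
  for (th in theta_grid) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t <- cf - (as.vector(R %*% (cm - center)) + center)
    pred <- t(R %*% t(sweep(moving, 2, center))) +
      matrix(center + t, nrow(moving), 2, byrow = TRUE)
    ss <- sum((pred - fixed)^2)
    if (is.null(best) || ss < best$ss) best <- list(theta = th, t = t, ss = ss)
  }
  best
}

# small random RGB section for property tests
random_section <- function(seed, h = 16, w = 20) {
  set.seed(seed)
  section_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

# quick small phantom shared by several tests (cached per session)
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- tube_tree_spec(depth = 1L, segment_length_um = c(50, 60),
                             extent_um = c(150, 150, 120), seed = 42L)
      cache <<- generate_tube_tree(spec)
    }
    cache
  }
})

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
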