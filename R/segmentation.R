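#' Label specification
#'
#' One named, colored structure to be segmented from the grayscale stack by
#' thresholding: `"dark"` polarity selects voxels with value `<= threshold`
#' (immunostains after grayscale conversion), `"bright"` selects
#' `>= threshold` (whitened vessel lumina).
#'
#' @param name unique label name (e.g. `"CK19"`, `"portal_vein_lumen"`).
#' @param threshold grayscale cut in `[0, 255]`.
#' @param polarity `"dark"` or `"bright"`.
#' @param color display color `(R, G, B)`.
#' @return object of class `label_spec`.
#' @export
label_spec <- function(name, threshold, polarity = c("dark", "bright"),
                       color = c(200, 60, 40)) {
  polarity <- match.arg(polarity)
  stopifnot(is.character(name), nchar(name) > 0,
            threshold >= 0, threshold <= 255, length(color) == 3L)
  structure(list(name = name, threshold = as.numeric(threshold),
                 polarity = polarity, color = as.numeric(color)),
            class = "label_spec")
}

#' Labeled voxel volume
#'
#' Integer-labeled grid (`0` = unlabeled) with its label table and spacing.
#' @param labels `H x W x Z` integer array of label ids.
#' @param table named list: label id (as character) -> [label_spec].
#' @param spacing relative voxel spacing.
#' @param physical_spacing_um optional physical edge lengths in um.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, table, spacing = c(1, 1, 10),
                         physical_spacing_um = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0L]
  if (!all(as.character(ids) %in% names(table))) {
    stop("every nonzero label id must be present in the label table")
  }
  structure(list(labels = labels, table = table,
                 spacing = as.numeric(spacing),
                 physical_spacing_um = physical_spacing_um),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels, %d labels\n",
              d[1], d[2], d[3], length(x$table)))
  for (id in names(x$table)) {
    cat(sprintf("  %s: %s (%d voxels)\n", id, x$table[[id]]$name,
                sum(x$labels == as.integer(id))))
  }
  invisible(x)
}

#' Threshold-label a grayscale stack
#'
#' Assigns each voxel to the first spec (in list order) whose
#' polarity/threshold matches; unmatched voxels stay `0`. First-match-wins
#' mirrors an exclusive per-voxel segmentation editor.
#'
#' @param gray_stack `H x W x Z` numeric array (or list of grayscale
#'   matrices) in `[0, 255]`.
#' @param specs list of [label_spec] with unique names; list position is the
#'   label id.
#' @param spacing relative voxel spacing for the resulting volume.
#' @param physical_spacing_um optional physical spacing (um).
#' @return a [label_volume].
#' @export
threshold_label <- function(gray_stack, specs, spacing = c(1, 1, 10),
                            physical_spacing_um = NULL) {
  if (is.list(gray_stack)) {
    gray_stack <- simplify2array(gray_stack)
  }
  if (length(dim(gray_stack)) == 2L) {
    gray_stack <- array(gray_stack, c(dim(gray_stack), 1L))
  }
  stopifnot(length(dim(gray_stack)) == 3L, length(specs) >= 1L)
  if (inherits(specs, "label_spec")) specs <- list(specs)
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate label names in specs")
  labels <- array(0L, dim(gray_stack))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    sel <- if (s$polarity == "dark") gray_stack <= s$threshold
           else gray_stack >= s$threshold
    labels[sel & labels == 0L] <- i
  }
  tab <- stats::setNames(specs, as.character(seq_along(specs)))
  label_volume(labels, tab, spacing, physical_spacing_um)
}

#' Apply manual per-section masks to a label volume
#'
#' The manual labeling path: `"add"` sets the masked voxels of the given
#' sections to `id`, `"erase"` zeroes them; voxels outside the masks are
#' untouched.
#'
#' @param volume a [label_volume].
#' @param masks list of `H x W` logical/0-1 matrices, one per entry of
#'   `sections`.
#' @param id target label id (must exist in the table for `"add"`).
#' @param sections 1-based z indices the masks apply to (defaults to
#'   `seq_along(masks)`).
#' @param mode `"add"` or `"erase"`.
#' @return modified [label_volume].
#' @export
apply_manual_masks <- function(volume, masks, id,
                               sections = seq_along(masks),
                               mode = c("add", "erase")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "label_volume"),
            length(masks) == length(sections))
  if (mode == "add" && !as.character(id) %in% names(volume$table)) {
    stop("unknown label id: ", id)
  }
  labels <- volume$labels
  d <- dim(labels)
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    if (!all(dim(m)[1:2] == d[1:2])) {
      stop("mask dimensions do not match sections")
    }
    m <- m > 0
    plane <- labels[, , sections[k]]
    plane[m] <- if (mode == "add") as.integer(id) else 0L
    labels[, , sections[k]] <- plane
  }
  label_volume(labels, volume$table, volume$spacing,
               volume$physical_spacing_um)
}

neighbor_offsets <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(off)) == 1L,
    "18" = rowSums(abs(off)) <= 2L,
    "26" = rep(TRUE, nrow(off)),
    stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

# half-neighborhood (lexicographically positive offsets) for edge building
half_offsets <- function(connectivity) {
  off <- neighbor_offsets(connectivity)
  pos <- off[, 3] > 0L | (off[, 3] == 0L & off[, 2] > 0L) |
         (off[, 3] == 0L & off[, 2] == 0L & off[, 1] > 0L)
  off[pos, , drop = FALSE]
}

#' 3D connected components of one label
#'
#' Maximal connected voxel sets of `id` under 6-, 18- or 26-adjacency.
#' Components are relabeled `1..k` in decreasing size order, so the output is
#' deterministic for identical input. Sizes are reported in voxels and, when
#' physical spacing is available, in cubic micrometres.
#'
#' @param volume a [label_volume] (or a logical/0-1 3D array).
#' @param id label id to analyze (ignored for plain mask input).
#' @param connectivity 6, 18 or 26 (default 26: with strongly anisotropic z,
#'   face-only adjacency artifactually disconnects structures crossing
#'   sections obliquely).
#' @return list with `map` (`H x W x Z` integer array of component ids),
#'   `sizes` (data.frame `component`, `voxels`, `um3`, sorted by size
#'   descending) and `n_components`.
#' @export
components_3d <- function(volume, id = 1L, connectivity = 26L) {
  if (inherits(volume, "label_volume")) {
    if (!as.character(id) %in% names(volume$table)) {
      stop("unknown label id: ", id)
    }
    mask <- volume$labels == as.integer(id)
    sp <- if (!is.null(volume$physical_spacing_um)) {
      volume$physical_spacing_um
    } else volume$spacing
  } else {
    mask <- volume > 0
    sp <- c(1, 1, 1)
  }
  d <- dim(mask)
  vox_um3 <- prod(sp)
  fg <- which(mask)
  map <- array(0L, d)
  if (!length(fg)) {
    return(list(map = map,
                sizes = data.frame(component = integer(0), voxels = integer(0),
                                   um3 = numeric(0)),
                n_components = 0L))
  }
  # voxel coordinates of the foreground
  r <- ((fg - 1L) %% d[1]) + 1L
  cc <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  s <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  pos_of <- integer(prod(d))
  pos_of[fg] <- seq_along(fg)
  off <- half_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- r + off[k, 1]; c2 <- cc + off[k, 2]; s2 <- s + off[k, 3]
    ok <- r2 >= 1L & r2 <= d[1] & c2 >= 1L & c2 <= d[2] &
          s2 >= 1L & s2 <= d[3]
    lin2 <- r2[ok] + (c2[ok] - 1L) * d[1] + (s2[ok] - 1L) * d[1] * d[2]
    hit <- pos_of[lin2] > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, pos_of[lin2[hit]])
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)
  sizes <- tabulate(comp$membership, comp$no)
  ord <- order(sizes, decreasing = TRUE)
  rank_of <- integer(comp$no)
  rank_of[ord] <- seq_len(comp$no)
  map[fg] <- rank_of[comp$membership]
  list(map = map,
       sizes = data.frame(component = seq_len(comp$no),
                          voxels = sizes[ord],
                          um3 = sizes[ord] * vox_um3),
       n_components = comp$no)
}

#' Connectivity of stained components to a reference structure
#'
#' Formalizes "connected to the ducts" versus "aggregation without
#' connection": a component of the stain label is *connected* iff it
#' contains, or is adjacent to (under the same connectivity rule), at least
#' one reference voxel; otherwise it is *isolated*.
#'
#' @param volume a [label_volume].
#' @param stain_id label id of the stain to test.
#' @param reference either a label id present in the volume, or an `n x 3`
#'   matrix of voxel coordinates `(row, col, slice)` seeding the reference
#'   region.
#' @param connectivity 6, 18 or 26.
#' @return list with `verdicts` (data.frame `component`, `voxels`,
#'   `verdict`), `n_connected`, `n_isolated` and `components` (the
#'   [components_3d] result for the stain).
#' @export
connectivity_query <- function(volume, stain_id, reference,
                               connectivity = 26L) {
  stopifnot(inherits(volume, "label_volume"))
  d <- dim(volume$labels)
  if (is.matrix(reference)) {
    stopifnot(ncol(reference) == 3L)
    if (nrow(reference) == 0L) stop("empty reference region")
    ref_lin <- reference[, 1] + (reference[, 2] - 1L) * d[1] +
               (reference[, 3] - 1L) * d[1] * d[2]
  } else {
    if (!as.character(reference) %in% names(volume$table)) {
      stop("unknown reference label id: ", reference)
    }
    ref_lin <- which(volume$labels == as.integer(reference))
    if (!length(ref_lin)) stop("empty reference region")
  }
  comps <- components_3d(volume, stain_id, connectivity)
  if (comps$n_components == 0L) {
    return(list(verdicts = data.frame(component = integer(0),
                                      voxels = integer(0),
                                      verdict = character(0)),
                n_connected = 0L, n_isolated = 0L, components = comps))
  }
  # dilate the reference by the neighborhood, then test membership
  r <- ((ref_lin - 1L) %% d[1]) + 1L
  cc <- (((ref_lin - 1L) %/% d[1]) %% d[2]) + 1L
  s <- ((ref_lin - 1L) %/% (d[1] * d[2])) + 1L
  off <- rbind(c(0L, 0L, 0L), neighbor_offsets(connectivity))
  touch <- logical(prod(d))
  for (k in seq_len(nrow(off))) {
    r2 <- r + off[k, 1]; c2 <- cc + off[k, 2]; s2 <- s + off[k, 3]
    ok <- r2 >= 1L & r2 <= d[1] & c2 >= 1L & c2 <= d[2] &
          s2 >= 1L & s2 <= d[3]
    touch[r2[ok] + (c2[ok] - 1L) * d[1] + (s2[ok] - 1L) * d[1] * d[2]] <- TRUE
  }
  stain_lin <- which(comps$map > 0L)
  comp_id <- comps$map[stain_lin]
  hit <- touch[stain_lin]
  connected_ids <- sort(unique(comp_id[hit]))
  verdict <- ifelse(comps$sizes$component %in% connected_ids,
                    "connected", "isolated")
  verdicts <- data.frame(component = comps$sizes$component,
                         voxels = comps$sizes$voxels,
                         verdict = verdict)
  list(verdicts = verdicts,
       n_connected = sum(verdict == "connected"),
       n_isolated = sum(verdict == "isolated"),
       components = comps)
}

#' Remove small components of a label
#'
#' Despeckling before surfacing: components of `id` smaller than
#' `min_voxels` are set to 0; everything else is untouched.
#' @param volume a [label_volume].
#' @param id label id.
#' @param min_voxels minimum surviving component size (>= 1).
#' @param connectivity 6, 18 or 26.
#' @return filtered [label_volume].
#' @export
filter_small <- function(volume, id, min_voxels, connectivity = 26L) {
  stopifnot(min_voxels >= 1)
  comps <- components_3d(volume, id, connectivity)
  if (comps$n_components == 0L) return(volume)
  small <- comps$sizes$component[comps$sizes$voxels < min_voxels]
  if (!length(small)) return(volume)
  labels <- volume$labels
  labels[comps$map %in% small] <- 0L
  label_volume(labels, volume$table, volume$spacing,
               volume$physical_spacing_um)
}

#' Drop components touching the in-plane image border
#'
#' Used to separate interior vessel lumina from the whitened slide
#' background, which is bright in the same way but always reaches the section
#' edge.
#' @param volume a [label_volume].
#' @param id label id.
#' @param connectivity 6, 18 or 26.
#' @return filtered [label_volume].
#' @export
drop_border_components <- function(volume, id, connectivity = 26L) {
  comps <- components_3d(volume, id, connectivity)
  if (comps$n_components == 0L) return(volume)
  d <- dim(volume$labels)
  border <- array(FALSE, d)
  border[1, , ] <- TRUE; border[d[1], , ] <- TRUE
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  touching <- unique(comps$map[border & comps$map > 0L])
  if (!length(touching)) return(volume)
  labels <- volume$labels
  labels[comps$map %in% touching] <- 0L
  label_volume(labels, volume$table, volume$spacing,
               volume$physical_spacing_um)
}

#' Persist a label volume as indexed PNGs plus a sidecar
#'
#' Writes one 8-bit grayscale PNG per section whose pixel values are the
#' label ids, and a YAML sidecar with the label table and spacing.
#' @param volume a [label_volume].
#' @param directory output directory.
#' @return invisibly, the sidecar path.
#' @export
write_label_volume <- function(volume, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$labels)
  for (z in seq_len(d[3])) {
    png::writePNG(volume$labels[, , z] / 255,
                  file.path(directory, sprintf("labels_%04d.png", z - 1L)))
  }
  tab <- lapply(names(volume$table), function(id) {
    s <- volume$table[[id]]
    list(id = as.integer(id), name = s$name, color = as.numeric(s$color),
         threshold = s$threshold, polarity = s$polarity)
  })
  path <- file.path(directory, "labels.yaml")
  yaml::write_yaml(list(spacing = volume$spacing,
                        physical_spacing_um = volume$physical_spacing_um,
                        n_sections = d[3], labels = tab), path)
  invisible(path)
}
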