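#' Pipeline configuration
#'
#' Config for an end-to-end run of the two-branch reconstruction workflow:
#' align, copy into three derived stacks (one for volumetric rendering, one
#' for vessel lumina, one for immunostains), edit each branch with its own
#' parameters, then render the volume and segment/surface the labels, ending
#' in a machine-readable report. Each branch's parameters affect only that
#' branch's outputs.
#'
#' @param manifest path to a stack manifest file, or an in-memory
#'   `section_stack`.
#' @param output_dir run directory (created).
#' @param alignment exactly one of `"none"`, `"landmarks"`, `"auto"`.
#' @param landmark_files character vector of landmark files (one per
#'   consecutive pair, in order), required for `alignment = "landmarks"`.
#' @param transforms optional list of precomputed absolute [rigid2d] (one per
#'   section; overrides `alignment`).
#' @param volume_params,lumen_params,stain_params [enhance_params] per
#'   branch.
#' @param stain_threshold grayscale cut for the stain label (dark polarity).
#' @param lumen_threshold grayscale cut for the lumen label (bright
#'   polarity).
#' @param stain_name name recorded for the stain label (e.g. the marker).
#' @param spacing relative voxel spacing for volumes.
#' @param views list of projection views for the volume branch.
#' @param render_mode `"composite"` or `"mip"`.
#' @param alpha_factor transparency tuning factor.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels despeckle threshold for stain components.
#' @param reference `"lumen"` (the interior lumen label) or an `n x 3` seed
#'   voxel matrix for the connectivity query.
#' @param resize_half halve section dimensions before volume building.
#' @param turntable number of turntable frames (0 disables).
#' @param seed recorded seed (the pipeline itself is deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, output_dir,
                            alignment = c("none", "landmarks", "auto"),
                            landmark_files = NULL, transforms = NULL,
                            volume_params = enhance_params(),
                            lumen_params = enhance_params(),
                            stain_params = enhance_params(),
                            stain_threshold = 130, lumen_threshold = 250,
                            stain_name = "stain",
                            spacing = c(1, 1, 10),
                            views = list("+z"),
                            render_mode = "composite", alpha_factor = 1,
                            connectivity = 26L, min_voxels = 30L,
                            reference = "lumen", resize_half = FALSE,
                            turntable = 0L, seed = 1L) {
  if (is.character(alignment) && length(alignment) == 1L &&
      !alignment %in% c("none", "landmarks", "auto")) {
    stop("alignment must be one of 'none', 'landmarks', 'auto'")
  }
  alignment <- match.arg(alignment)
  if (is.character(manifest) && !file.exists(manifest)) {
    stop("manifest path does not exist: ", manifest)
  }
  if (alignment == "landmarks" && is.null(landmark_files) &&
      is.null(transforms)) {
    stop("alignment 'landmarks' needs landmark_files")
  }
  if (!is.null(landmark_files) && !all(file.exists(landmark_files))) {
    stop("missing landmark file(s)")
  }
  structure(list(manifest = manifest, output_dir = output_dir,
                 alignment = alignment, landmark_files = landmark_files,
                 transforms = transforms, volume_params = volume_params,
                 lumen_params = lumen_params, stain_params = stain_params,
                 stain_threshold = stain_threshold,
                 lumen_threshold = lumen_threshold, stain_name = stain_name,
                 spacing = as.numeric(spacing), views = views,
                 render_mode = render_mode, alpha_factor = alpha_factor,
                 connectivity = as.integer(connectivity),
                 min_voxels = as.integer(min_voxels), reference = reference,
                 resize_half = isTRUE(resize_half),
                 turntable = as.integer(turntable), seed = as.integer(seed)),
            class = "pipeline_config")
}

params_as_list <- function(p) unclass(p)

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the two-branch reconstruction pipeline
#'
#' Executes the workflow in protocol order — align, branch into three derived
#' stacks, edit, volumetric rendering on one branch, segmentation-based
#' surface rendering on the other two, connectivity analysis of the stain
#' against the vessel reference — and writes the run directory: aligned and
#' edited stacks, projection PNGs, the persisted label volume, exported
#' meshes, a log and `report.json`. Identical config and seed give an
#' identical report.
#'
#' @param config a [pipeline_config].
#' @return invisibly, the report (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
  }
  logf("pipeline start, seed %d", config$seed)

  stack <- stage("read", {
    if (is.character(config$manifest)) read_stack(config$manifest)
    else config$manifest
  })
  n <- length(stack$sections)
  logf("read %d sections", n)

  # --- alignment -----------------------------------------------------------
  aligned <- stage("align", {
    if (!is.null(config$transforms)) {
      abs_tr <- config$transforms
    } else if (config$alignment == "none") {
      abs_tr <- NULL
    } else if (config$alignment == "landmarks") {
      if (length(config$landmark_files) != n - 1L) {
        stop("need one landmark file per consecutive section pair")
      }
      center <- image_center(stack$sections[[1]])
      pairwise <- lapply(config$landmark_files, function(fp) {
        lm <- read_landmarks(fp)
        estimate_rigid_from_landmarks(lm$fixed, lm$moving, center)$transform
      })
      abs_tr <- compose_to_reference(pairwise)
    } else {  # auto
      pairwise <- vector("list", n - 1L)
      for (i in seq_len(n - 1L)) {
        pairwise[[i]] <- auto_align_pair(stack$sections[[i]],
                                         stack$sections[[i + 1L]])
      }
      abs_tr <- compose_to_reference(pairwise)
    }
    if (is.null(abs_tr)) stack else {
      write_transforms(abs_tr, file.path(out, "transforms.yaml"),
                       vapply(stack$sections, function(s) s$section_index,
                              integer(1)))
      secs <- stack$sections
      for (i in seq_len(n)) {
        secs[[i]] <- resample_section(secs[[i]], abs_tr[[i]], "bilinear")
      }
      section_stack(secs, stack$manifest)
    }
  })
  logf("alignment mode: %s", config$alignment)

  # --- three derived stacks, each edited with its own parameters -----------
  volume_stack <- stage("enhance-volume", {
    secs <- lapply(aligned$sections, function(s) {
      s <- adjust_brightness_contrast(s, config$volume_params)
      s <- whiten_background(s, config$volume_params)
      if (config$resize_half) s <- resize_section(s)
      invert_channels(s)
    })
    section_stack(secs, aligned$manifest)
  })
  lumen_gray <- stage("enhance-lumen", {
    simplify2array(lapply(aligned$sections, function(s) {
      to_grayscale(enhance_lumina(s, config$lumen_params))
    }))
  })
  stain_gray <- stage("enhance-stain", {
    simplify2array(lapply(aligned$sections, function(s) {
      s <- whiten_background(s, config$stain_params)
      s <- remove_color_range_noise(s, config$stain_params)
      to_grayscale(s)
    }))
  })

  # --- volumetric rendering branch ----------------------------------------
  projections <- stage("volume", {
    vol <- build_rgba_volume(volume_stack, config$spacing)
    vol <- reinvert_volume(vol)
    if (config$alpha_factor != 1) vol <- scale_alpha(vol, config$alpha_factor)
    proj_dir <- file.path(out, "projections")
    dir.create(proj_dir, showWarnings = FALSE)
    paths <- character(0)
    for (v in config$views) {
      img <- render_projection(vol, v, config$render_mode)
      nm <- if (is.character(v)) gsub("[+]", "p", gsub("-", "m", v))
            else sprintf("az%03.0f_el%02.0f", v[1], v[2])
      p <- file.path(proj_dir, sprintf("projection_%s.png", nm))
      png::writePNG(img / 255, p)
      paths <- c(paths, p)
    }
    if (config$turntable > 0L) {
      paths <- c(paths, render_turntable(vol, config$turntable,
                                         file.path(proj_dir, "turntable")))
    }
    paths
  })
  logf("wrote %d projection(s)", length(projections))

  # --- segmentation branch -------------------------------------------------
  phys <- c(aligned$manifest$pixel_size_um, aligned$manifest$pixel_size_um,
            aligned$manifest$thickness_um * aligned$manifest$sampling_interval)
  labels <- stage("segment", {
    lum <- threshold_label(lumen_gray,
      list(label_spec("lumen", config$lumen_threshold, "bright",
                      c(180, 40, 40))),
      config$spacing, phys)
    lum <- drop_border_components(lum, 1L, config$connectivity)
    stn <- threshold_label(stain_gray,
      list(label_spec(config$stain_name, config$stain_threshold, "dark",
                      c(120, 70, 40))),
      config$spacing, phys)
    if (config$min_voxels > 1L) {
      stn <- filter_small(stn, 1L, config$min_voxels, config$connectivity)
    }
    combined <- lum$labels
    combined[stn$labels == 1L] <- 2L
    label_volume(combined,
                 list("1" = lum$table[["1"]], "2" = stn$table[["1"]]),
                 config$spacing, phys)
  })
  write_label_volume(labels, file.path(out, "labels"))

  query <- stage("connectivity", {
    ref <- if (is.matrix(config$reference)) config$reference else 1L
    connectivity_query(labels, 2L, ref, config$connectivity)
  })
  logf("stain components: %d connected, %d isolated",
       query$n_connected, query$n_isolated)

  meshes <- stage("surface", {
    mesh_dir <- file.path(out, "meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    res <- list()
    for (id in names(labels$table)) {
      if (!any(labels$labels == as.integer(id))) next
      m <- marching_surface(labels, as.integer(id))
      export_mesh(m, file.path(mesh_dir,
                               paste0(labels$table[[id]]$name, ".ply")))
      mm <- mesh_measures(m)
      res[[labels$table[[id]]$name]] <- mm
    }
    res
  })

  # --- aligned + edited stacks on disk ------------------------------------
  write_stack(aligned, file.path(out, "aligned"), "png")
  write_stack(volume_stack, file.path(out, "volume_branch"), "png")

  lab_counts <- lapply(names(labels$table), function(id) {
    list(id = as.integer(id), name = labels$table[[id]]$name,
         voxels = sum(labels$labels == as.integer(id)))
  })
  report <- list(
    seed = config$seed,
    n_sections = n,
    alignment = config$alignment,
    spacing = config$spacing,
    connectivity = config$connectivity,
    parameters = list(volume = params_as_list(config$volume_params),
                      lumen = params_as_list(config$lumen_params),
                      stain = params_as_list(config$stain_params),
                      stain_threshold = config$stain_threshold,
                      lumen_threshold = config$lumen_threshold,
                      min_voxels = config$min_voxels,
                      alpha_factor = config$alpha_factor),
    labels = lab_counts,
    stain_components = list(
      n_components = query$components$n_components,
      n_connected = query$n_connected,
      n_isolated = query$n_isolated,
      verdicts = query$verdicts,
      sizes_voxels = utils::head(query$components$sizes$voxels, 10L)),
    meshes = meshes
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline done")
  invisible(report)
}
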