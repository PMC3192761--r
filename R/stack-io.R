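#' Construct a stack manifest
#'
#' The manifest is the sidecar that records the physical bookkeeping of a cut
#' series: which file holds which section, the cutting thickness, the in-plane
#' pixel size, and (for interleaved staining series) the sampling interval
#' meaning every k-th section carries a given marker. Section indices are
#' 0-based cut positions; a section excluded from imaging keeps its index so
#' the z-geometry of the block is preserved.
#'
#' @param sections data.frame with columns `index` (0-based integer cut
#'   position), `file` (image path, may be `NA` for in-memory stacks) and
#'   optionally `marker` (character, `NA` when unstained/unspecified).
#' @param thickness_um section thickness in micrometres.
#' @param pixel_size_um in-plane pixel size in micrometres.
#' @param sampling_interval integer k: every k-th section carries one marker.
#' @return object of class `stack_manifest`.
#' @export
stack_manifest <- function(sections, thickness_um = 5, pixel_size_um = 1,
                           sampling_interval = 1L) {
  if (!is.data.frame(sections) || nrow(sections) == 0L) {
    stop("manifest must list at least one section")
  }
  if (!all(c("index", "file") %in% names(sections))) {
    stop("manifest sections need columns 'index' and 'file'")
  }
  if (is.null(sections$marker)) sections$marker <- NA_character_
  sections$index <- as.integer(sections$index)
  sections <- sections[order(sections$index), , drop = FALSE]
  rownames(sections) <- NULL
  if (anyDuplicated(sections$index)) {
    stop("section indices must be strictly increasing (no duplicates)")
  }
  if (any(sections$index < 0L)) stop("section indices must be >= 0")
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("thickness_um must be > 0")
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  sampling_interval <- as.integer(sampling_interval)
  if (sampling_interval < 1L) stop("sampling_interval must be >= 1")
  structure(
    list(sections = sections,
         thickness_um = as.numeric(thickness_um),
         pixel_size_um = as.numeric(pixel_size_um),
         sampling_interval = sampling_interval),
    class = "stack_manifest"
  )
}

#' @export
print.stack_manifest <- function(x, ...) {
  cat(sprintf("stack_manifest: %d sections, %g um thick, %.3g um/px, interval %d\n",
              nrow(x$sections), x$thickness_um, x$pixel_size_um,
              x$sampling_interval))
  invisible(x)
}

#' Physical z-extent of a manifest
#'
#' Depth in micrometres spanned by the cut series:
#' `(max_index - min_index + 1) * thickness_um`. Sections excluded from the
#' manifest but inside the index range still occupy depth in the block, so a
#' gap never shortens the extent.
#'
#' @param manifest a [stack_manifest] (or a `section_stack`).
#' @return depth in micrometres.
#' @examples
#' m <- stack_manifest(data.frame(index = 0:49, file = NA), thickness_um = 5)
#' z_extent(m)  # 250
#' @export
z_extent <- function(manifest) {
  if (inherits(manifest, "section_stack")) manifest <- manifest$manifest
  stopifnot(inherits(manifest, "stack_manifest"))
  idx <- manifest$sections$index
  (max(idx) - min(idx) + 1) * manifest$thickness_um
}

#' Section indices carrying one marker
#'
#' For an interleaved staining design where every `interval`-th section is
#' stained for a given protein, returns the 0-based indices
#' `{i : i == offset (mod interval), 0 <= i < n_sections}`.
#'
#' @param n_sections number of consecutive sections in the series.
#' @param interval staining interval (k in "every k-th section").
#' @param offset phase of this marker within the interval, `0 <= offset < interval`.
#' @return integer vector of section indices.
#' @examples
#' length(marker_schedule(50, 10))  # 5 inclusions per marker
#' @export
marker_schedule <- function(n_sections, interval = 10L, offset = 0L) {
  n_sections <- as.integer(n_sections)
  interval <- as.integer(interval)
  offset <- as.integer(offset)
  if (n_sections < 1L) stop("n_sections must be >= 1")
  if (interval < 1L) stop("interval must be >= 1")
  if (offset < 0L || offset >= interval) {
    stop("offset must satisfy 0 <= offset < interval")
  }
  if (offset >= n_sections) return(integer(0))
  seq.int(offset, n_sections - 1L, by = interval)
}

png_bit_depth <- function(path) {
  # IHDR bit-depth byte: offset 25 (0-based 24) of the file
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("not a PNG file: ", path)
  as.integer(hdr[25L])
}

read_section_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("image file not found: ", path)
  px <- switch(ext,
    tif = , tiff = {
      img <- tiff::readTIFF(path, info = TRUE)
      bits <- attr(img, "bits.per.sample")
      if (!is.null(bits) && any(bits != 8L)) {
        stop("unsupported format: ", path, " is not 8 bits per sample")
      }
      img
    },
    png = {
      if (png_bit_depth(path) != 8L) {
        stop("unsupported format: ", path, " is not 8 bits per sample")
      }
      png::readPNG(path)
    },
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha plane
  out <- to_u8(px * 255)
  array(out, dim(out))  # shed reader metadata attributes
}

write_section_file <- function(pixels, path, format, jpeg_quality = 0.95) {
  img <- pixels / 255
  switch(format,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L,
                           compression = "none"),
    png = png::writePNG(img, path),
    jpeg = jpeg::writeJPEG(img, path, quality = jpeg_quality),
    stop("unknown format: ", format)
  )
  invisible(path)
}

#' Read a section stack from a manifest file
#'
#' The manifest is a YAML (or JSON) sidecar with global physical metadata and
#' one record per section:
#' \preformatted{
#' pixel_size_um: 0.642
#' thickness_um: 5
#' sampling_interval: 10
#' sections:
#'   - {index: 0, file: s000.tif, marker: CK19}
#' }
#' Relative file paths are resolved against the manifest's directory. All
#' images must share dimensions (or `target_size: [W, H]` must be declared in
#' the manifest, in which case every section is resized on load). RGB input is
#' reported as 24 bits per pixel on the returned stack.
#'
#' @param manifest_path path to the manifest file.
#' @return a `section_stack`: list with `manifest` ([stack_manifest]),
#'   `sections` (list of [section_image] in index order) and attribute-like
#'   field `bits_per_pixel` (24 for RGB input).
#' @export
read_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest file not found: ", manifest_path)
  }
  raw <- yaml::read_yaml(manifest_path)
  if (is.null(raw$sections) || length(raw$sections) == 0L) {
    stop("manifest lists no sections")
  }
  sec <- data.frame(
    index = vapply(raw$sections, function(s) as.integer(s$index), integer(1)),
    file = vapply(raw$sections, function(s) as.character(s$file), character(1)),
    marker = vapply(raw$sections, function(s)
      if (is.null(s$marker)) NA_character_ else as.character(s$marker),
      character(1)),
    stringsAsFactors = FALSE
  )
  man <- stack_manifest(sec,
    thickness_um = if (is.null(raw$thickness_um)) 5 else raw$thickness_um,
    pixel_size_um = if (is.null(raw$pixel_size_um)) 1 else raw$pixel_size_um,
    sampling_interval = if (is.null(raw$sampling_interval)) 1L
                        else raw$sampling_interval)
  base_dir <- dirname(manifest_path)
  target <- raw$target_size  # optional c(W, H) resize directive
  sections <- vector("list", nrow(man$sections))
  for (i in seq_len(nrow(man$sections))) {
    f <- man$sections$file[i]
    if (!file.exists(f)) f <- file.path(base_dir, man$sections$file[i])
    if (!file.exists(f)) {
      stop("missing image file for section index ", man$sections$index[i],
           ": ", man$sections$file[i])
    }
    px <- read_section_file(f)
    s <- section_image(px, man$pixel_size_um, man$sections$index[i],
                       man$thickness_um)
    if (!is.null(target)) {
      s <- resize_section(s, width = target[[1]], height = target[[2]])
    }
    sections[[i]] <- s
  }
  dims <- vapply(sections, function(s) dim(s$pixels)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent section dimensions and no target_size directive")
  }
  section_stack(sections, man)
}

#' Assemble an in-memory section stack
#'
#' @param sections list of [section_image], any order (sorted by index).
#' @param manifest optional [stack_manifest]; built from the sections when
#'   omitted.
#' @return a `section_stack`.
#' @export
section_stack <- function(sections, manifest = NULL) {
  stopifnot(length(sections) >= 1L)
  sections <- lapply(sections, as_section)
  ord <- order(vapply(sections, function(s) s$section_index, integer(1)))
  sections <- sections[ord]
  if (is.null(manifest)) {
    manifest <- stack_manifest(
      data.frame(index = vapply(sections, function(s) s$section_index,
                                integer(1)),
                 file = NA_character_),
      thickness_um = sections[[1]]$thickness_um,
      pixel_size_um = sections[[1]]$pixel_size_um)
  }
  structure(list(manifest = manifest, sections = sections,
                 bits_per_pixel = 24L),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]]$pixels)
  cat(sprintf("section_stack: %d sections of %d x %d px, %d-bit, z-extent %g um\n",
              length(x$sections), d[1], d[2], x$bits_per_pixel, z_extent(x)))
  invisible(x)
}

#' @export
length.section_stack <- function(x) length(x$sections)

#' Write a section stack to disk
#'
#' Writes one image file per section plus a rewritten manifest sidecar
#' (`manifest.yaml`) so the output directory is itself a readable stack.
#' TIFF output is uncompressed 24-bit; TIFF and PNG round-trip pixel values
#' exactly, JPEG is lossy (quality 0.95 by default).
#'
#' @param stack a `section_stack`.
#' @param directory output directory (created if missing).
#' @param format one of `"tiff"`, `"png"`, `"jpeg"`.
#' @param jpeg_quality quality in (0, 1] used for JPEG only.
#' @return invisibly, the manifest path.
#' @export
write_stack <- function(stack, directory, format = c("tiff", "png", "jpeg"),
                        jpeg_quality = 0.95) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "section_stack"), length(stack$sections) >= 1L)
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L) {
    stop("cannot write to directory: ", directory)
  }
  ext <- c(tiff = "tif", png = "png", jpeg = "jpg")[[format]]
  man <- stack$manifest
  files <- character(length(stack$sections))
  for (i in seq_along(stack$sections)) {
    s <- stack$sections[[i]]
    files[i] <- sprintf("section_%04d.%s", s$section_index, ext)
    write_section_file(s$pixels, file.path(directory, files[i]), format,
                       jpeg_quality)
  }
  man$sections$file <- files
  write_manifest(man, file.path(directory, "manifest.yaml"))
}

#' Write a manifest sidecar
#' @param manifest a [stack_manifest].
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  secs <- lapply(seq_len(nrow(manifest$sections)), function(i) {
    r <- manifest$sections[i, ]
    rec <- list(index = r$index, file = r$file)
    if (!is.na(r$marker)) rec$marker <- r$marker
    rec
  })
  yaml::write_yaml(list(pixel_size_um = manifest$pixel_size_um,
                        thickness_um = manifest$thickness_um,
                        sampling_interval = manifest$sampling_interval,
                        sections = secs), path)
  invisible(path)
}
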