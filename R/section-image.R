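#' Construct a section image
#'
#' A `section_image` holds one digitized histological section as an 8-bit RGB
#' pixel grid together with its physical metadata: the in-plane pixel size and
#' the cutting thickness (both in micrometres), and the 0-based position of the
#' section in the cut series.
#'
#' @param pixels integer array of dimension `H x W x 3` (rows, columns, RGB),
#'   values in `[0, 255]`. A plain `H x W` matrix is promoted to gray RGB.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param section_index 0-based integer position in the cut series.
#' @param thickness_um physical section thickness in micrometres.
#' @return an object of class `section_image`.
#' @examples
#' img <- section_image(array(255L, dim = c(4, 4, 3)), pixel_size_um = 0.64)
#' dim(img$pixels)
#' @export
section_image <- function(pixels, pixel_size_um = 1, section_index = 0L,
                          thickness_um = 5) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("section image must have H >= 1 and W >= 1")
  }
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop("channel values must be integers in [0, 255]")
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0")
  }
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("thickness_um must be > 0")
  }
  structure(
    list(pixels = pixels,
         pixel_size_um = as.numeric(pixel_size_um),
         section_index = as.integer(section_index),
         thickness_um = as.numeric(thickness_um)),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image %d x %d px (24-bit RGB), %.3g um/px, index %d, %g um thick\n",
              d[1], d[2], x$pixel_size_um, x$section_index, x$thickness_um))
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$pixels)

# replace the pixel grid, keeping metadata
with_pixels <- function(section, pixels) {
  section_image(pixels, section$pixel_size_um, section$section_index,
                section$thickness_um)
}

as_section <- function(x) {
  if (inherits(x, "section_image")) x else section_image(x)
}

clip255 <- function(v) {
  v[v < 0] <- 0
  v[v > 255] <- 255
  v
}

# round-half-away-from-zero is irrelevant here: values are >= 0, use round()
to_u8 <- function(v) {
  v <- round(v)
  storage.mode(v) <- "integer"
  clip255(v)
}
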