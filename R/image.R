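#' RGB raster images
#'
#' An `rgb_image` is a `height x width x 3` numeric array of 8-bit channel
#' values (integers in 0--255, channel order R, G, B) with a `name` attribute
#' holding the source file stem. It is the universal input of the pipeline.
#' Pixel positions are 1-based `(row, col)` with the origin at the top-left;
#' "x-pixel" is the width and "y-pixel" the height.
#'
#' @param pixels numeric array of dimension `c(height, width, 3)`, values in
#'   0--255.
#' @param name character scalar, the image name (file stem).
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 6, 3)), "flat")
#' img_dims(img)
#' @export
rgb_image <- function(pixels, name = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("'pixels' must be a height x width x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must be at least 1 x 1", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must be in [0, 255]", call. = FALSE)
  pixels <- round(pixels)
  structure(pixels, name = as.character(name)[1], class = "rgb_image")
}

#' @rdname rgb_image
#' @param img an `rgb_image`.
#' @return `img_dims()` returns `c(height, width)`; `img_name()` the name.
#' @export
img_dims <- function(img) dim(img)[1:2]

#' @rdname rgb_image
#' @export
img_name <- function(img) attr(img, "name")

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image '%s': %d x %d (h x w), 3 channels>\n",
              img_name(x), d[1], d[2]))
  invisible(x)
}

stopifnot_same_dims <- function(a, b, what_a = "first image",
                                what_b = "second image") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(da, db))
    stop(sprintf("dimension mismatch: %s is %d x %d, %s is %d x %d",
                 what_a, da[1], da[2], what_b, db[1], db[2]), call. = FALSE)
  invisible(TRUE)
}

#' Read and write RGB images
#'
#' Reads 8-bit PNG or JPEG files into an [rgb_image()] (grayscale and
#' RGBA inputs are expanded/truncated to 3 channels) and writes an
#' `rgb_image` as PNG. Channel order is RGB throughout.
#'
#' @param path file path; the extension selects the reader
#'   (`.png`, `.jpg`, `.jpeg`).
#' @return `read_rgb_image()` returns an [rgb_image()] named after the file
#'   stem; `write_rgb_image()` returns `path` invisibly.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' (use png/jpg/jpeg): %s",
                 ext, path), call. = FALSE)
  )
  if (length(dim(raw)) == 2L)                      # grayscale
    raw <- array(raw, dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(round(raw * 255), name = tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_rgb_image
#' @param img an `rgb_image`.
#' @export
write_rgb_image <- function(img, path) {
  arr <- unclass(img) / 255
  attributes(arr) <- list(dim = dim(img))
  png::writePNG(arr, path)
  invisible(path)
}

# Logical H x W matrix helper used by the mask-producing operations.
as_mask <- function(m) {
  storage.mode(m) <- "logical"
  m
}
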