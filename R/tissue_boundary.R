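#' Classify background pixels
#'
#' A pixel is background when, on every channel,
#' `|value - bk_mean| <= alpha * kappa_bk * max(bk_sd, 1)`.
#' `alpha` therefore widens or narrows the background acceptance band:
#' larger values classify more pixels as background and tighten the detected
#' tissue boundary. The SD floor of 1 channel unit keeps a zero-SD channel
#' from degenerating to exact matching.
#'
#' @param image an [rgb_image()].
#' @param bundle a [calibration_bundle()].
#' @return Logical `height x width` matrix (TRUE = background).
#' @export
classify_background <- function(image, bundle) {
  band_mask(image, bundle$bk, bundle$alpha * bundle$kappa_bk)
}

# per-channel acceptance band test shared by both classifiers
band_mask <- function(image, stats, width_sd) {
  hw <- width_sd * pmax(stats$sd, SD_FLOOR)
  px <- unclass(image)
  out <- abs(px[, , 1] - stats$mean[1]) <= hw[1] &
    abs(px[, , 2] - stats$mean[2]) <= hw[2] &
    abs(px[, , 3] - stats$mean[3]) <= hw[3]
  dim(out) <- dim(px)[1:2]        # 1 x n slices drop dims otherwise
  out
}

#' Convex hull of a binary mask
#'
#' Convex hull of the set pixels' centres; the hull area is the shoelace
#' area of the vertex polygon. Note the vertex-polygon convention: a filled
#' axis-aligned rectangle of `10 x 20` pixel centres has hull area
#' `9 x 19 = 171`, not 200. Degenerate masks (a single pixel, collinear
#' pixels) have area 0.
#'
#' @param mask logical matrix with at least one set pixel.
#' @return A list with `polygon` (ordered `k x 2` matrix of `(row, col)`
#'   vertices) and `hull_area` (pixels^2).
#' @export
convex_hull <- function(mask) {
  pts <- which(as_mask(mask), arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("empty mask has no hull", call. = FALSE)
  if (nrow(pts) <= 2L) {
    poly <- pts
  } else {
    # chull works in (x, y); use x = col, y = row
    idx <- grDevices::chull(pts[, 2], pts[, 1])
    poly <- pts[idx, , drop = FALSE]
  }
  dimnames(poly) <- list(NULL, c("row", "col"))
  list(polygon = poly, hull_area = shoelace_area(poly))
}

shoelace_area <- function(poly) {
  k <- nrow(poly)
  if (k < 3L) return(0)
  r <- poly[, 1]; cc <- poly[, 2]
  nxt <- c(2:k, 1L)
  abs(sum(cc * r[nxt] - cc[nxt] * r)) / 2
}

#' Segment the tissue section
#'
#' The tissue candidate set is the complement of the background mask
#' ([classify_background()]); the largest 8-connected candidate component is
#' retained (one section per image), its fully-enclosed holes are filled,
#' and the convex hull and areas are computed. `hull_area` is the analyzed
#' surface; `tissue_ratio = hull_area / image_area` is the ratio of tissue
#' size to image size reported in the records. If more than half of the
#' retained tissue pixels fall outside the inside-tissue colour band
#' (`inside mean +/- 4 SD`) a warning flags a likely calibration problem.
#'
#' @inheritParams classify_background
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix), `hull` (polygon vertices), `hull_area`, `mask_area`,
#'   `image_area`, `tissue_ratio`.
#' @export
tissue_mask <- function(image, bundle) {
  cand <- !classify_background(image, bundle)
  if (!any(cand))
    stop("no tissue detected (alpha too large?)", call. = FALSE)
  mask <- fill_holes(largest_component(cand, connectivity = 8))
  hull <- convex_hull(mask)
  d <- img_dims(image)
  image_area <- prod(d)
  inside_ok <- band_mask(image, bundle$inside, 4)
  frac_out <- 1 - sum(inside_ok & mask) / sum(mask)
  if (frac_out > 0.5)
    warning(sprintf(paste0("%.0f%% of retained tissue pixels fall outside the ",
                           "inside-tissue colour band; check the calibration"),
                    100 * frac_out), call. = FALSE)
  structure(list(mask = mask, hull = hull$polygon,
                 hull_area = hull$hull_area, mask_area = sum(mask),
                 image_area = image_area,
                 tissue_ratio = hull$hull_area / image_area),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf(paste0("<tissue_mask: %d tissue px, hull area %.1f px^2 ",
                     "(%.1f%% of image), %d hull vertices>\n"),
              x$mask_area, x$hull_area, 100 * x$tissue_ratio, nrow(x$hull)))
  invisible(x)
}

# morphological boundary: set pixels with a 4-neighbour outside the mask
# (or on the image border)
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !core
}

#' Diagnostic region overlays ("bound" and "hull" images)
#'
#' `bound` is the input with the tissue mask's morphological boundary traced
#' in a contrasting colour; `hull` is the input with the convex hull polygon
#' outlined. The input image is not modified.
#'
#' @inheritParams classify_background
#' @param tissue a [tissue_mask()].
#' @param bound_color,hull_color RGB triples for the traced pixels.
#' @return A list with `bound` and `hull`, both [rgb_image()]s of the same
#'   dimensions as the input.
#' @export
render_region_overlays <- function(image, tissue,
                                   bound_color = c(0, 200, 0),
                                   hull_color = c(255, 0, 0)) {
  stopifnot_same_dims(image, tissue$mask, "image", "tissue mask")
  bound <- paint_pixels(image, which(mask_boundary(tissue$mask), arr.ind = TRUE),
                        bound_color)
  attr(bound, "name") <- paste0(img_name(image), "_bound")
  hull <- paint_polygon(image, tissue$hull, hull_color)
  attr(hull, "name") <- paste0(img_name(image), "_hull")
  list(bound = bound, hull = hull)
}

paint_pixels <- function(image, coords, color) {
  out <- unclass(image)
  if (length(coords) > 0L) {
    if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
    for (ch in 1:3) out[, , ch][coords] <- color[ch]
  }
  structure(out, name = img_name(image), class = "rgb_image")
}

# rasterize polygon edges with Bresenham segments
paint_polygon <- function(image, poly, color) {
  k <- nrow(poly)
  coords <- do.call(rbind, lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    line_pixels(poly[i, 1], poly[i, 2], poly[j, 1], poly[j, 2])
  }))
  paint_pixels(image, unique(coords), color)
}

line_pixels <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(round(seq(r0, r1, length.out = n)), round(seq(c0, c1, length.out = n)))
}
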