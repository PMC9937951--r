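#' Classify chromogen-positive pixels
#'
#' A pixel is positive when it lies inside the tissue mask AND every channel
#' satisfies `|value - pt_mean| <= kappa_pt * max(pt_sd, 1)`. The positive
#' band is NOT scaled by alpha: alpha tunes only the tissue boundary, so the
#' two tunables stay orthogonal.
#'
#' @inheritParams classify_background
#' @param tissue a [tissue_mask()] for the same image.
#' @return Logical matrix (TRUE = positive pixel).
#' @export
classify_positive <- function(image, bundle, tissue) {
  stopifnot_same_dims(image, tissue$mask, "image", "tissue mask")
  tissue$mask & band_mask(image, bundle$pt, bundle$kappa_pt)
}

# Moore-neighbour contour trace of a single connected component given as a
# logical grid; returns the closed outer contour as (row, col) pixel centres.
# The walk is a deterministic map on (pixel, backtrack-direction) states, so
# it must eventually repeat a state; the periodic part of the orbit is the
# closed outer-boundary cycle and is what gets returned. (Plain Jacob's
# stopping criterion can spin forever on thin 8-connected diagonals, whose
# orbit never returns to the exact start state.)
trace_contour <- function(grid) {
  pts <- which(grid, arr.ind = TRUE)
  if (nrow(pts) == 1L) return(pts)
  # clockwise Moore neighbourhood (row axis points down): N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  nr <- nrow(grid); nc <- ncol(grid)
  ord <- order(pts[, 1], pts[, 2])
  p <- as.integer(pts[ord[1], ])         # top-left-most pixel
  bdir <- 7L                             # entered from the west (background)
  seen <- matrix(0L, nr * nc, 8L)        # step at which each state occurred
  path <- matrix(0L, 4L * nrow(pts) + 8L, 2L)
  step <- 0L
  cycle_start <- 1L
  repeat {
    code <- (p[2] - 1L) * nr + p[1]
    if (seen[code, bdir] > 0L) { cycle_start <- seen[code, bdir]; break }
    step <- step + 1L
    if (step > nrow(path)) path <- rbind(path, path * 0L)
    seen[code, bdir] <- step
    path[step, ] <- p
    found <- FALSE
    for (s in 1:8) {
      k <- ((bdir - 1L + s) %% 8L) + 1L
      r2 <- p[1] + dr[k]; c2 <- p[2] + dc[k]
      inside <- r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc
      if (inside && grid[r2, c2]) {
        kb <- ((bdir - 1L + s - 1L) %% 8L) + 1L
        br <- p[1] + dr[kb]; bc <- p[2] + dc[kb]   # last background scanned
        p <- c(r2, c2)
        bdir <- which(dr == br - p[1] & dc == bc - p[2])
        found <- TRUE
        break
      }
    }
    if (!found) break                    # isolated pixel (padded grids only)
  }
  path[cycle_start:step, , drop = FALSE]
}

contour_perimeter <- function(contour) {
  k <- nrow(contour)
  if (k < 2L) return(0)
  nxt <- c(2:k, 1L)
  sum(sqrt((contour[nxt, 1] - contour[, 1])^2 +
             (contour[nxt, 2] - contour[, 2])^2))
}

#' Roundness score of a blob
#'
#' The isoperimetric quotient `q = 4 * pi * area / perimeter^2` of the
#' blob's outer contour, clipped to `[0, 1]`: 1 for a disk, small for
#' elongated shapes. The perimeter is the Moore contour length (unit steps
#' for 4-neighbours, `sqrt(2)` for diagonal steps) and the area is the
#' region enclosed by that contour (the hole-filled component), so interior
#' holes affect neither term. Blobs of 2 pixels or fewer score 1.0: the
#' contour length is ill-defined at that scale.
#'
#' @param pixels integer `n x 2` matrix of the blob's `(row, col)` pixels
#'   (one 8-connected component).
#' @return A roundness score in `[0, 1]`.
#' @export
shape_score <- function(pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  if (nrow(pixels) <= 2L) return(1.0)
  # local grid with 1-pixel pad
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  grid <- matrix(FALSE, max(pixels[, 1]) - r0 + 3L, max(pixels[, 2]) - c0 + 3L)
  grid[cbind(pixels[, 1] - r0 + 2L, pixels[, 2] - c0 + 2L)] <- TRUE
  filled <- fill_holes(grid)
  per <- contour_perimeter(trace_contour(filled))
  if (per <= 0) return(1.0)
  min(1, 4 * pi * sum(filled) / per^2)
}

#' Group positive pixels into blobs
#'
#' Labels the 8-connected components of a positive-pixel mask and measures
#' each: area (pixel count), outer-contour perimeter, centroid, bounding
#' box, fill ratio (area / bounding-box area, the "ratio of painted area to
#' the cell"), and roundness score ([shape_score()]).
#'
#' @param mask logical matrix of positive pixels.
#' @return A tibble with one row per blob: `id`, `area`, `perimeter`,
#'   `centroid_row`, `centroid_col`, `bbox_row0`, `bbox_col0`, `bbox_row1`,
#'   `bbox_col1` (half-open), `fill_ratio`, `shape_score` and a `pixels`
#'   list-column of coordinate matrices. Empty mask: zero rows.
#' @export
label_blobs <- function(mask) {
  lab <- label_components(as_mask(mask), connectivity = 8)
  n <- max(lab)
  if (n == 0L) return(empty_blob_table())
  coords <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[coords]
  ord <- order(labs)
  coords <- coords[ord, , drop = FALSE]
  labs <- labs[ord]
  split_idx <- split(seq_len(nrow(coords)), labs)
  rows <- lapply(seq_len(n), function(i) {
    px <- coords[split_idx[[i]], , drop = FALSE]
    dimnames(px) <- list(NULL, c("row", "col"))
    area <- nrow(px)
    bb <- c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1L, max(px[, 2]) + 1L)
    bbox_area <- (bb[3] - bb[1]) * (bb[4] - bb[2])
    grid_per <- if (area <= 2L) 0 else {
      r0 <- bb[1]; c0 <- bb[2]
      g <- matrix(FALSE, bb[3] - r0 + 2L, bb[4] - c0 + 2L)
      g[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- TRUE
      contour_perimeter(trace_contour(fill_holes(g)))
    }
    tibble::tibble(
      id = i, area = area, perimeter = grid_per,
      centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
      bbox_row0 = bb[1], bbox_col0 = bb[2], bbox_row1 = bb[3], bbox_col1 = bb[4],
      fill_ratio = area / bbox_area,
      shape_score = shape_score(px),
      pixels = list(px)
    )
  })
  do.call(rbind, rows)
}

empty_blob_table <- function() {
  tibble::tibble(id = integer(), area = integer(), perimeter = numeric(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 bbox_row0 = integer(), bbox_col0 = integer(),
                 bbox_row1 = integer(), bbox_col1 = integer(),
                 fill_ratio = numeric(), shape_score = numeric(),
                 pixels = list())
}

#' Filter blobs by roundness and size, and count
#'
#' Keeps blobs with `shape_score >= shape` and `area >= min_area`. With
#' `shape = 0` and `min_area = 1` every blob is counted (including dye
#' speckle); the default `min_area = 4` suppresses single-pixel
#' contamination.
#'
#' @param blobs a blob table from [label_blobs()].
#' @param shape roundness cutoff in `[0, 1]`.
#' @param min_area minimum blob area in pixels (>= 1).
#' @return An object of class `detection_result`: list with `kept` and
#'   `rejected` blob tables, `count` (number kept) and `mean_fill_ratio`
#'   (0 when nothing is kept).
#' @export
filter_and_count <- function(blobs, shape = 0.5, min_area = 4) {
  if (shape < 0 || shape > 1) stop("shape must be in [0, 1]", call. = FALSE)
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  keep <- blobs$shape_score >= shape & blobs$area >= min_area
  kept <- blobs[keep, , drop = FALSE]
  structure(list(kept = kept, rejected = blobs[!keep, , drop = FALSE],
                 count = nrow(kept),
                 mean_fill_ratio = if (nrow(kept)) mean(kept$fill_ratio) else 0),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result: %d kept, %d rejected, mean fill ratio %.3f>\n",
              x$count, nrow(x$rejected), x$mean_fill_ratio))
  invisible(x)
}

#' Positive-cell density per unit area
#'
#' `count / pixel_area * 1e6`: cells per million pixels^2, the unit-area
#' normalisation applied to each record of `data.txt`.
#'
#' @param count non-negative integer cell count.
#' @param pixel_area image area in pixels^2 (> 0).
#' @return Density in cells per 10^6 pixels^2.
#' @examples
#' density_per_area(2, 500000)  # 4
#' @export
density_per_area <- function(count, pixel_area) {
  if (any(pixel_area <= 0)) stop("pixel_area must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count / pixel_area * 1e6
}
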