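# 3x5 bitmap glyphs for the counter annotations drawn on the "blue" overlay.
# Only what the annotations need: digits, minus, dot, space.
DIGIT_FONT <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "001", "001", "001"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111"),
  "-" = c("000", "000", "111", "000", "000"),
  "." = c("000", "000", "000", "000", "010"),
  " " = c("000", "000", "000", "000", "000")
)

glyph_pixels <- function(ch) {
  rows <- DIGIT_FONT[[ch]]
  if (is.null(rows)) rows <- DIGIT_FONT[[" "]]
  bits <- do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]])))
  which(bits == 1L, arr.ind = TRUE)
}

# draw text at (row, col) top-left anchor; scale enlarges the 3x5 glyphs
draw_text <- function(image, text, row, col, color = c(0, 0, 0), scale = 3L) {
  chars <- strsplit(as.character(text), "")[[1]]
  d <- img_dims(image)
  coords <- list()
  x <- col
  for (ch in chars) {
    g <- glyph_pixels(ch)
    if (nrow(g) > 0L) {
      base <- cbind(row + (g[, 1] - 1L) * scale, x + (g[, 2] - 1L) * scale)
      block <- expand.grid(0:(scale - 1L), 0:(scale - 1L))
      px <- do.call(rbind, lapply(seq_len(nrow(base)), function(i)
        cbind(base[i, 1] + block[, 1], base[i, 2] + block[, 2])))
      coords[[length(coords) + 1L]] <- px
    }
    x <- x + 4L * scale                  # 3 columns + 1 spacing
  }
  if (!length(coords)) return(image)
  px <- do.call(rbind, coords)
  px <- px[px[, 1] >= 1 & px[, 1] <= d[1] & px[, 2] >= 1 & px[, 2] <= d[2], ,
           drop = FALSE]
  paint_pixels(image, px, color)
}

text_width <- function(text, scale = 3L) nchar(as.character(text)) * 4L * scale

#' Annotated "blue" overlay
#'
#' Copy of the input with every kept blob's outer contour traced, the cell
#' count printed top-left and the analyzed surface area (pixels^2) printed
#' top-right.
#'
#' @inheritParams classify_background
#' @param result a [filter_and_count()] detection result.
#' @param area analyzed surface area in pixels^2 (printed top-right;
#'   typically the tissue hull area).
#' @param outline_color RGB triple for blob contours.
#' @return An [rgb_image()] of the same dimensions as the input.
#' @export
annotate_blue_overlay <- function(image, result, area,
                                  outline_color = c(255, 0, 0)) {
  out <- image
  if (result$count > 0) {
    for (px in result$kept$pixels) {
      if (nrow(px) <= 2L) { ctr <- px } else {
        r0 <- min(px[, 1]); c0 <- min(px[, 2])
        g <- matrix(FALSE, max(px[, 1]) - r0 + 3L, max(px[, 2]) - c0 + 3L)
        g[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- TRUE
        ctr <- trace_contour(fill_holes(g))
        ctr <- cbind(ctr[, 1] + r0 - 2L, ctr[, 2] + c0 - 2L)
      }
      out <- paint_pixels(out, ctr, outline_color)
    }
  }
  d <- img_dims(image)
  area_txt <- format(round(area), scientific = FALSE, trim = TRUE)
  out <- draw_text(out, result$count, row = 6L, col = 6L, color = c(0, 0, 0))
  out <- draw_text(out, area_txt, row = 6L,
                   col = max(6L, d[2] - text_width(area_txt) - 2L),
                   color = c(0, 0, 0))
  attr(out, "name") <- paste0(img_name(image), "_blue")
  out
}
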