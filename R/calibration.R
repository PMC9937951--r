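#' Per-class colour statistics
#'
#' Mean and population standard deviation (divisor `n`) of the R, G and B
#' channels over a set of pixels, plus the number of contributing pixels.
#' These triples are the whole colour model: a pixel belongs to a class when
#' every channel lies inside `mean +/- half-width`, where the half-width is a
#' multiple of the (floored) SD.
#'
#' @param mean,sd numeric length-3 vectors (R, G, B); means in 0--255,
#'   SDs non-negative.
#' @param n integer, number of pixels the statistics were computed from.
#' @return An object of class `color_stats`.
#' @export
color_stats <- function(mean, sd, n = 1L) {
  mean <- as.numeric(mean); sd <- as.numeric(sd); n <- as.integer(n)
  if (length(mean) != 3L || length(sd) != 3L)
    stop("mean and sd must each have 3 channels", call. = FALSE)
  if (anyNA(mean) || min(mean) < 0 || max(mean) > 255)
    stop("mean channel values must be in [0, 255]", call. = FALSE)
  if (anyNA(sd) || min(sd) < 0)
    stop("sd channel values must be non-negative", call. = FALSE)
  if (is.na(n) || n < 1L)
    stop("n must be a positive integer", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "color_stats")
}

#' @export
print.color_stats <- function(x, ...) {
  cat(sprintf("<color_stats: mean (%.1f, %.1f, %.1f)  sd (%.2f, %.2f, %.2f)  n = %d>\n",
              x$mean[1], x$mean[2], x$mean[3], x$sd[1], x$sd[2], x$sd[3], x$n))
  invisible(x)
}

#' Recover annotated pixels from a scribbled copy of a reference image
#'
#' Calibration images are annotated by drawing black scribbles (background /
#' inside-tissue classes) or white dots (positive-cell class) on a copy of a
#' reference image. A pixel counts as annotated when it differs from the
#' original by more than `diff_threshold` on at least one channel AND the
#' annotated colour matches the requested polarity (dark: mean channel
#' intensity `<= dark_cutoff`; light: `>= light_cutoff`). The thresholds
#' tolerate lossy (JPEG) re-encoding of the annotated copy.
#'
#' The returned positions index into the ORIGINAL image: class statistics are
#' always computed from the tissue colours underneath the scribble, never from
#' the scribble colour itself.
#'
#' @param original,annotated [rgb_image()]s of identical dimensions.
#' @param polarity `"dark"` for black scribbles, `"light"` for white dots.
#' @param diff_threshold per-channel absolute difference above which a pixel
#'   counts as changed (default 30).
#' @param dark_cutoff,light_cutoff mean-intensity cutoffs defining the two
#'   polarities (defaults 60 and 195).
#' @return An integer `n x 2` matrix of 1-based `(row, col)` positions.
#' @export
extract_scribble_pixels <- function(original, annotated,
                                    polarity = c("dark", "light"),
                                    diff_threshold = 30,
                                    dark_cutoff = 60, light_cutoff = 195) {
  polarity <- match.arg(polarity)
  stopifnot_same_dims(original, annotated, "original", "annotated")
  d <- abs(unclass(annotated) - unclass(original))
  changed <- pmax(d[, , 1], d[, , 2], d[, , 3]) > diff_threshold
  intens <- (annotated[, , 1] + annotated[, , 2] + annotated[, , 3]) / 3
  hit <- changed & (if (polarity == "dark") intens <= dark_cutoff
                    else intens >= light_cutoff)
  coords <- which(hit, arr.ind = TRUE)
  if (nrow(coords) == 0L)
    stop("no annotated pixels found: re-annotate the reference image ",
         "(calibration cannot proceed on zero pixels)", call. = FALSE)
  dimnames(coords) <- list(NULL, c("row", "col"))
  coords
}

#' Colour statistics over a pixel set
#'
#' Per-channel arithmetic mean and population standard deviation (divisor
#' `n`, so a single pixel has SD 0) over the given positions of an image.
#'
#' @param image an [rgb_image()].
#' @param pixels integer `n x 2` matrix of `(row, col)` positions.
#' @return A [color_stats()].
#' @export
compute_color_stats <- function(image, pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  n <- nrow(pixels)
  if (n == 0L) stop("empty pixel set", call. = FALSE)
  d <- img_dims(image)
  if (min(pixels) < 1L || max(pixels[, 1]) > d[1] || max(pixels[, 2]) > d[2])
    stop("pixel positions out of image bounds", call. = FALSE)
  vals <- vapply(1:3, function(ch) {
    unclass(image)[, , ch][pixels]
  }, numeric(n))
  vals <- matrix(vals, nrow = n)
  m <- colMeans(vals)
  s <- sqrt(colMeans(sweep(vals, 2, m)^2))
  color_stats(mean = m, sd = s, n = n)
}

#' Calibration bundle
#'
#' Bundles the three per-class colour statistics with the two scalar tuning
#' parameters. `alpha` scales the background acceptance band and so tunes the
#' detected tissue boundary (larger alpha: more pixels accepted as background,
#' tighter boundary); `shape` is the 0--1 roundness cutoff applied to blobs
#' (0 keeps everything, values near 1 keep only near-circular blobs).
#' `kappa_bk` and `kappa_pt` are the acceptance half-widths in SD units for
#' the background and positive classes.
#'
#' @param bk,inside,pt [color_stats()] for the background, inside-tissue and
#'   positive-cell classes.
#' @param alpha positive real; boundary sensitivity (default 1).
#' @param shape roundness cutoff in `[0, 1]` (default 0.5).
#' @param kappa_bk,kappa_pt positive SD multipliers (default 2).
#' @return An object of class `calibration_bundle`.
#' @export
calibration_bundle <- function(bk, inside, pt, alpha = 1, shape = 0.5,
                               kappa_bk = 2, kappa_pt = 2) {
  for (s in list(bk, inside, pt))
    if (!inherits(s, "color_stats"))
      stop("bk, inside and pt must be color_stats objects", call. = FALSE)
  alpha <- as.numeric(alpha); shape <- as.numeric(shape)
  if (is.na(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (is.na(shape) || shape < 0 || shape > 1)
    stop("shape must be in [0, 1]", call. = FALSE)
  if (kappa_bk <= 0 || kappa_pt <= 0)
    stop("kappa multipliers must be > 0", call. = FALSE)
  structure(list(bk = bk, inside = inside, pt = pt, alpha = alpha,
                 shape = shape, kappa_bk = kappa_bk, kappa_pt = kappa_pt),
            class = "calibration_bundle")
}

#' @export
print.calibration_bundle <- function(x, ...) {
  cat(sprintf("<calibration_bundle: alpha = %g, shape = %g, kappa = (%g, %g)>\n",
              x$alpha, x$shape, x$kappa_bk, x$kappa_pt))
  for (cls in c("bk", "inside", "pt")) { cat(" ", cls, ": "); print(x[[cls]]) }
  invisible(x)
}

# SD floor (channel units): a zero-SD channel still accepts a +/- 1 band,
# so single-pixel calibration never degenerates to exact matching.
SD_FLOOR <- 1.0

#' Read and write calibration parameter files
#'
#' Plain-text dialect of the `cfg` folder. Stats files (`cfg_bk.txt`,
#' `cfg_in.txt`, `cfg_pt.txt`) hold two whitespace-separated lines --
#' `mean_r mean_g mean_b` then `sd_r sd_g sd_b` -- with an optional third
#' line `n <count>`; `#` starts a comment. Scalar files (`cfg_alpha.txt`,
#' `cfg_shape.txt`) hold a single decimal number. Round trips are lossless
#' to at least 9 significant digits.
#'
#' @param stats a [color_stats()].
#' @param path file path.
#' @return `read_stats_file()` a [color_stats()]; `read_scalar_file()` a
#'   numeric scalar; the writers return `path` invisibly.
#' @export
write_stats_file <- function(stats, path) {
  if (!inherits(stats, "color_stats")) stop("not a color_stats", call. = FALSE)
  fmt3 <- function(v) paste(sprintf("%.9g", v), collapse = " ")
  writeLines(c(fmt3(stats$mean), fmt3(stats$sd), sprintf("n %d", stats$n)),
             path)
  invisible(path)
}

# strip comments/blank lines, keeping original line numbers for errors
cfg_lines <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  keep <- grepl("\\S", stripped)
  list(text = trimws(stripped[keep]), lineno = which(keep), path = path)
}

parse_nums <- function(text, lineno, path, expect) {
  parts <- strsplit(text, "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != expect || anyNA(vals))
    stop(sprintf("%s: line %d: expected %d numeric value(s), got '%s'",
                 path, lineno, expect, text), call. = FALSE)
  vals
}

#' @rdname write_stats_file
#' @export
read_stats_file <- function(path) {
  ln <- cfg_lines(path)
  if (length(ln$text) < 2L)
    stop(sprintf("%s: line %d: expected two lines of channel values (mean, sd)",
                 path, length(ln$text) + 1L), call. = FALSE)
  m <- parse_nums(ln$text[1], ln$lineno[1], path, 3L)
  s <- parse_nums(ln$text[2], ln$lineno[2], path, 3L)
  n <- 1L
  if (length(ln$text) >= 3L) {
    nl <- ln$text[3]
    if (!grepl("^n\\s", nl))
      stop(sprintf("%s: line %d: expected 'n <count>', got '%s'",
                   path, ln$lineno[3], nl), call. = FALSE)
    n <- as.integer(parse_nums(sub("^n\\s+", "", nl), ln$lineno[3], path, 1L))
  }
  color_stats(mean = m, sd = s, n = n)
}

#' @rdname write_stats_file
#' @param value numeric scalar.
#' @export
write_scalar_file <- function(value, path) {
  writeLines(sprintf("%.9g", as.numeric(value)), path)
  invisible(path)
}

#' @rdname write_stats_file
#' @export
read_scalar_file <- function(path) {
  ln <- cfg_lines(path)
  if (length(ln$text) != 1L)
    stop(sprintf("%s: expected a single decimal number", path), call. = FALSE)
  parse_nums(ln$text[1], ln$lineno[1], path, 1L)
}

# The six reference stems and their roles/polarities.
REFERENCE_PAIRS <- list(
  bk     = list(original = "file1", annotated = "file1_bk",     polarity = "dark"),
  inside = list(original = "file2", annotated = "file2_inside", polarity = "dark"),
  pt     = list(original = "t1",    annotated = "t1_pt",        polarity = "light")
)

REFERENCE_STEMS <- unlist(lapply(REFERENCE_PAIRS, function(p)
  c(p$original, p$annotated)), use.names = FALSE)

find_reference_image <- function(dir, stem) {
  for (ext in c("png", "jpg", "jpeg", "PNG", "JPG", "JPEG")) {
    p <- file.path(dir, paste0(stem, ".", ext))
    if (file.exists(p)) return(p)
  }
  stop(sprintf("missing reference image '%s' (looked for %s.{png,jpg,jpeg} in %s)",
               stem, stem, dir), call. = FALSE)
}

#' Calibrate colour classes from an annotated reference set
#'
#' Reads the three reference pairs (`file1`/`file1_bk` for background,
#' `file2`/`file2_inside` for inside-tissue, `t1`/`t1_pt` for positive cells;
#' any of `.png/.jpg/.jpeg`), recovers the scribbled pixels (black scribbles
#' for the two dark classes, white dots for the positive class), computes the
#' per-class colour statistics from the original image underneath the
#' annotations, and writes `cfg_bk.txt`, `cfg_in.txt` and `cfg_pt.txt`.
#' `alpha` and `shape` are loaded from `cfg_alpha.txt` / `cfg_shape.txt` when
#' present, else default to 1 and 0.5.
#'
#' @param cfg_dir directory holding the six reference images (and optionally
#'   the scalar parameter files).
#' @param write_cfg write the three stats files into `cfg_dir` (default TRUE).
#' @return A [calibration_bundle()].
#' @export
auto_calibrate <- function(cfg_dir, write_cfg = TRUE) {
  if (!dir.exists(cfg_dir))
    stop(sprintf("cfg directory not found: %s", cfg_dir), call. = FALSE)
  stats <- lapply(REFERENCE_PAIRS, function(p) {
    orig <- read_rgb_image(find_reference_image(cfg_dir, p$original))
    anno <- read_rgb_image(find_reference_image(cfg_dir, p$annotated))
    compute_color_stats(orig, extract_scribble_pixels(orig, anno, p$polarity))
  })
  alpha_path <- file.path(cfg_dir, "cfg_alpha.txt")
  shape_path <- file.path(cfg_dir, "cfg_shape.txt")
  alpha <- if (file.exists(alpha_path)) read_scalar_file(alpha_path) else 1.0
  shape <- if (file.exists(shape_path)) read_scalar_file(shape_path) else 0.5
  bundle <- calibration_bundle(bk = stats$bk, inside = stats$inside,
                               pt = stats$pt, alpha = alpha, shape = shape)
  if (write_cfg) {
    write_stats_file(bundle$bk, file.path(cfg_dir, "cfg_bk.txt"))
    write_stats_file(bundle$inside, file.path(cfg_dir, "cfg_in.txt"))
    write_stats_file(bundle$pt, file.path(cfg_dir, "cfg_pt.txt"))
  }
  bundle
}
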