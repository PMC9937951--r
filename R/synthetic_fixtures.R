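#' Specification of a synthetic stained section
#'
#' Describes a counterstained tissue ellipse on a near-white background with
#' blue chromogen-positive disks, brown distractor blobs (mimicking an IHC
#' chromogen) and elongated low-roundness blue smears (mimicking dye
#' contamination), plus per-channel Gaussian noise. The default palette
#' mirrors the colour classes of SA-beta-Gal / DAB / Fast-red histology:
#' background (235, 232, 228), tissue pink (222, 150, 160), positive blue
#' (60, 90, 170), distractor brown (120, 80, 40).
#'
#' The class colour separation must satisfy
#' `min pairwise distance >= 8 * noise_sd` so that the calibration bands
#' remain learnable from noisy scribbles.
#'
#' @param width,height canvas size in pixels.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param background_color,tissue_color,positive_color,distractor_color RGB
#'   triples in 0--255.
#' @param tissue_shape list with `center` `(row, col)`, `semi_axes`
#'   `(a_row, a_col)` and `rotation` (radians); `NULL` entries get defaults
#'   (centred ellipse, semi-axes 0.40 height x 0.35 width, rotation pi/7).
#' @param n_positive number of positive disks.
#' @param positive_radius_range `(min, max)` disk radius in pixels.
#' @param n_distractor_brown number of brown distractor blobs.
#' @param n_irregular_blue number of elongated blue smears.
#' @param noise_sd per-channel Gaussian noise SD (channel units).
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(width = 512, height = 512, seed = 1,
                         background_color = c(235, 232, 228),
                         tissue_color = c(222, 150, 160),
                         tissue_shape = list(),
                         n_positive = 30,
                         positive_color = c(60, 90, 170),
                         positive_radius_range = c(3, 7),
                         n_distractor_brown = 10,
                         distractor_color = c(120, 80, 40),
                         n_irregular_blue = 5,
                         noise_sd = 6) {
  shape <- list(
    center = tissue_shape$center %||% c(height / 2, width / 2),
    semi_axes = tissue_shape$semi_axes %||% c(0.40 * height, 0.35 * width),
    rotation = tissue_shape$rotation %||% (pi / 7)
  )
  spec <- list(width = as.integer(width), height = as.integer(height),
               seed = as.integer(seed),
               background_color = background_color,
               tissue_color = tissue_color, tissue_shape = shape,
               n_positive = as.integer(n_positive),
               positive_color = positive_color,
               positive_radius_range = positive_radius_range,
               n_distractor_brown = as.integer(n_distractor_brown),
               distractor_color = distractor_color,
               n_irregular_blue = as.integer(n_irregular_blue),
               noise_sd = noise_sd)
  validate_section_spec(spec)
  structure(spec, class = "section_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_section_spec <- function(s) {
  for (col in list(s$background_color, s$tissue_color, s$positive_color,
                   s$distractor_color))
    if (length(col) != 3L || min(col) < 0 || max(col) > 255)
      stop("colors must be RGB triples in [0, 255]", call. = FALSE)
  if (s$n_positive < 0 || s$n_distractor_brown < 0 || s$n_irregular_blue < 0)
    stop("object counts must be >= 0", call. = FALSE)
  if (s$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (s$positive_radius_range[1] < 1 ||
      s$positive_radius_range[2] < s$positive_radius_range[1])
    stop("invalid positive_radius_range", call. = FALSE)
  # rotated-ellipse bounding half-extents must fit the canvas
  sh <- s$tissue_shape
  ext_r <- sqrt((sh$semi_axes[1] * cos(sh$rotation))^2 +
                  (sh$semi_axes[2] * sin(sh$rotation))^2)
  ext_c <- sqrt((sh$semi_axes[1] * sin(sh$rotation))^2 +
                  (sh$semi_axes[2] * cos(sh$rotation))^2)
  if (sh$center[1] - ext_r < 1 || sh$center[1] + ext_r > s$height ||
      sh$center[2] - ext_c < 1 || sh$center[2] + ext_c > s$width)
    stop("tissue ellipse does not fit the canvas", call. = FALSE)
  means <- rbind(s$background_color, s$tissue_color, s$positive_color)
  dists <- as.numeric(stats::dist(means))
  if (min(dists) < 8 * s$noise_sd)
    stop("class colour separation must be >= 8 * noise_sd", call. = FALSE)
  invisible(s)
}

# signed ellipse coordinate: <= 1 means inside the ellipse shrunk by 'margin'
inside_ellipse <- function(r, c, shape, margin = 0) {
  dr <- r - shape$center[1]; dc <- c - shape$center[2]
  th <- shape$rotation
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  a1 <- max(shape$semi_axes[1] - margin, 1)
  a2 <- max(shape$semi_axes[2] - margin, 1)
  (u / a1)^2 + (v / a2)^2 <= 1
}

paint_disk <- function(canvas, class_map, center, radius, color, class_id) {
  h <- nrow(class_map); w <- ncol(class_map)
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(h, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(w, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  sel <- which(d2 <= radius^2, arr.ind = TRUE)
  px <- cbind(rr[sel[, 1]], cc[sel[, 2]])
  for (ch in 1:3) canvas[, , ch][px] <- color[ch]
  class_map[px] <- class_id
  list(canvas = canvas, class_map = class_map)
}

#' Render a synthetic stained section with ground truth
#'
#' Renders, in order: the background, the tissue ellipse, `n_positive`
#' non-overlapping blue disks fully inside the tissue, `n_irregular_blue`
#' elongated blue smears (random near-straight polylines stroked 2 pixels
#' wide, isoperimetric quotient well below 0.3), `n_distractor_brown` brown
#' blobs, and finally clipped Gaussian channel noise. Fully reproducible
#' from `spec$seed`. Object placement is retried at most 1000 times per
#' object before giving up with an error.
#'
#' @param spec a [section_spec()].
#' @param name image name (file stem) for the rendered [rgb_image()].
#' @return A list with `image` (an [rgb_image()]) and `truth`, a
#'   `ground_truth` object: `positive_centers` (`n x 2`), `positive_radii`,
#'   `distractor_centers`, `tissue_pixel_count`, `class_map` (0 background,
#'   1 tissue, 2 positive, 3 distractor, 4 smear) and `spec`.
#' @export
generate_section <- function(spec, name = "section") {
  stopifnot(inherits(spec, "section_spec"))
  withr::with_seed(spec$seed, generate_section_impl(spec, name))
}

generate_section_impl <- function(spec, name) {
  h <- spec$height; w <- spec$width
  canvas <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) canvas[, , ch] <- spec$background_color[ch]
  rr <- .row(c(h, w)); cc <- .col(c(h, w))
  ellipse <- inside_ellipse(rr, cc, spec$tissue_shape)
  class_map <- matrix(0L, h, w)
  class_map[ellipse] <- 1L
  for (ch in 1:3) {
    plane <- canvas[, , ch]; plane[ellipse] <- spec$tissue_color[ch]
    canvas[, , ch] <- plane
  }

  # positive disks: non-overlapping, fully inside the tissue
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  bbox <- ellipse_bbox(spec$tissue_shape)
  for (i in seq_len(spec$n_positive)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      r <- stats::runif(1, spec$positive_radius_range[1],
                        spec$positive_radius_range[2])
      cand <- c(stats::runif(1, bbox[1], bbox[2]),
                stats::runif(1, bbox[3], bbox[4]))
      if (!inside_ellipse(cand[1], cand[2], spec$tissue_shape, margin = r + 3))
        next
      if (nrow(centers) > 0 &&
          any(sqrt(rowSums(sweep(centers, 2, cand)^2)) < radii + r + 3))
        next
      centers <- rbind(centers, cand); radii <- c(radii, r)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", spec$n_positive, " non-overlapping positive ",
           "disks; use fewer or smaller disks", call. = FALSE)
  }
  for (i in seq_len(nrow(centers))) {
    res <- paint_disk(canvas, class_map, centers[i, ], radii[i],
                      spec$positive_color, 2L)
    canvas <- res$canvas; class_map <- res$class_map
  }

  # elongated blue smears (dye contamination): near-straight 2 px strokes
  smear_pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(spec$n_irregular_blue)) {
    path <- NULL
    for (try in seq_len(1000L)) {
      path <- smear_path(spec, centers, radii, bbox)
      if (!is.null(path)) break
    }
    if (is.null(path))
      stop("could not place irregular blue smears inside the tissue",
           call. = FALSE)
    px <- unique(rbind(cbind(floor(path[, 1]), floor(path[, 2])),
                       cbind(floor(path[, 1]) + 1L, floor(path[, 2])),
                       cbind(floor(path[, 1]), floor(path[, 2]) + 1L),
                       cbind(floor(path[, 1]) + 1L, floor(path[, 2]) + 1L)))
    px <- px[px[, 1] >= 1 & px[, 1] <= h & px[, 2] >= 1 & px[, 2] <= w, ,
             drop = FALSE]
    for (ch in 1:3) canvas[, , ch][px] <- spec$positive_color[ch]
    class_map[px] <- 4L
    smear_pts <- rbind(smear_pts, path)
  }

  # brown distractor blobs
  dcenters <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(spec$n_distractor_brown)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      dr <- stats::runif(1, 2, 5)
      cand <- c(stats::runif(1, bbox[1], bbox[2]),
                stats::runif(1, bbox[3], bbox[4]))
      if (!inside_ellipse(cand[1], cand[2], spec$tissue_shape, margin = dr + 3))
        next
      if (nrow(centers) > 0 &&
          any(sqrt(rowSums(sweep(centers, 2, cand)^2)) < radii + dr + 3))
        next
      if (nrow(smear_pts) > 0 &&
          min(sqrt(rowSums(sweep(smear_pts, 2, cand)^2))) < dr + 6)
        next
      res <- paint_disk(canvas, class_map, cand, dr, spec$distractor_color, 3L)
      canvas <- res$canvas; class_map <- res$class_map
      dcenters <- rbind(dcenters, cand)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place brown distractor blobs", call. = FALSE)
  }

  if (spec$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(length(canvas), 0, spec$noise_sd)
    canvas <- pmin(pmax(round(canvas), 0), 255)
  }

  truth <- structure(list(
    positive_centers = unname(centers), positive_radii = radii,
    distractor_centers = unname(dcenters),
    tissue_pixel_count = sum(ellipse),
    class_map = class_map, spec = spec
  ), class = "ground_truth")
  list(image = rgb_image(canvas, name = name), truth = truth)
}

ellipse_bbox <- function(shape) {
  ext_r <- sqrt((shape$semi_axes[1] * cos(shape$rotation))^2 +
                  (shape$semi_axes[2] * sin(shape$rotation))^2)
  ext_c <- sqrt((shape$semi_axes[1] * sin(shape$rotation))^2 +
                  (shape$semi_axes[2] * cos(shape$rotation))^2)
  c(shape$center[1] - ext_r, shape$center[1] + ext_r,
    shape$center[2] - ext_c, shape$center[2] + ext_c)
}

# one candidate smear polyline, or NULL if it collides with a positive disk
# or leaves the tissue
smear_path <- function(spec, centers, radii, bbox) {
  start <- c(stats::runif(1, bbox[1], bbox[2]),
             stats::runif(1, bbox[3], bbox[4]))
  if (!inside_ellipse(start[1], start[2], spec$tissue_shape, margin = 8))
    return(NULL)
  len <- sample(30:45, 1)
  ang <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, nrow = len, ncol = 2)
  pts[1, ] <- start
  for (k in 2:len) {
    ang <- ang + stats::rnorm(1, 0, 0.15)
    pts[k, ] <- pts[k - 1, ] + c(sin(ang), cos(ang))
  }
  if (!all(inside_ellipse(pts[, 1], pts[, 2], spec$tissue_shape, margin = 6)))
    return(NULL)
  if (nrow(centers) > 0) {
    d <- outer(pts[, 1], centers[, 1], `-`)^2 +
      outer(pts[, 2], centers[, 2], `-`)^2
    if (any(sqrt(d) < matrix(radii + 5, nrow(pts), length(radii), byrow = TRUE)))
      return(NULL)
  }
  pts
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth: %d positive disks, %d distractors, ",
                     "%d tissue px, seed %d>\n"),
              nrow(x$positive_centers), nrow(x$distractor_centers),
              x$tissue_pixel_count, x$spec$seed))
  invisible(x)
}

# deterministic search for annotation strokes of one class: horizontal
# thick segments fully inside that class, scanned over a coarse grid
find_strokes <- function(class_map, class_id, n_strokes = 4L,
                         len = 30L, thick = 3L) {
  h <- nrow(class_map); w <- ncol(class_map)
  out <- list()
  for (ar in seq(4L, h - thick - 1L, by = 13L)) {
    for (ac in seq(4L, w - len - 1L, by = 19L)) {
      block <- class_map[ar:(ar + thick - 1L), ac:(ac + len - 1L)]
      if (all(block == class_id)) {
        out[[length(out) + 1L]] <-
          as.matrix(expand.grid(row = ar:(ar + thick - 1L),
                                col = ac:(ac + len - 1L)))
        if (length(out) >= n_strokes)
          return(do.call(rbind, out))
      }
    }
  }
  if (!length(out))
    stop("could not find annotation stroke positions for class ", class_id,
         call. = FALSE)
  do.call(rbind, out)
}

#' Write a scribble-annotated reference set
#'
#' Emits the six calibration files expected by [auto_calibrate()] into
#' `out_dir`: `file1`/`file2`/`t1` (copies of the image) and their annotated
#' counterparts -- `file1_bk` with black scribbles on the background,
#' `file2_inside` with black scribbles on plain tissue (avoiding positives,
#' smears and distractors), and `t1_pt` with white radius-2 dots at the
#' positive-disk centres. Scribbles are generated programmatically from the
#' ground-truth class map, so the set is deterministic for a given section.
#'
#' @param image the rendered [rgb_image()].
#' @param truth its `ground_truth`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the six file paths.
#' @export
generate_reference_set <- function(image, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  black <- c(0, 0, 0); white <- c(255, 255, 255)
  bk_px <- find_strokes(truth$class_map, 0L)
  in_px <- find_strokes(truth$class_map, 1L)
  f1 <- image; attr(f1, "name") <- "file1"
  f2 <- image; attr(f2, "name") <- "file2"
  t1 <- image; attr(t1, "name") <- "t1"
  f1bk <- paint_pixels(image, bk_px, black)
  f2in <- paint_pixels(image, in_px, black)
  t1pt <- image
  for (i in seq_len(nrow(truth$positive_centers))) {
    res <- paint_disk(unclass(t1pt), matrix(0L, nrow(truth$class_map),
                                            ncol(truth$class_map)),
                      truth$positive_centers[i, ], 2, white, 0L)
    t1pt <- structure(res$canvas, name = img_name(image), class = "rgb_image")
  }
  paths <- file.path(out_dir, c("file1.png", "file1_bk.png", "file2.png",
                                "file2_inside.png", "t1.png", "t1_pt.png"))
  write_rgb_image(f1, paths[1]); write_rgb_image(f1bk, paths[2])
  write_rgb_image(f2, paths[3]); write_rgb_image(f2in, paths[4])
  write_rgb_image(t1, paths[5]); write_rgb_image(t1pt, paths[6])
  invisible(paths)
}

#' Score a detection against ground truth
#'
#' Greedy one-to-one matching (nearest pair first) of kept-blob centroids to
#' true positive-disk centres within `match_radius`. The false-negative rate
#' is the fraction of unmatched truths (0 when there are no truths); the
#' false-positive rate is the fraction of unmatched blobs (denominator
#' `max(n_blobs, 1)`).
#'
#' @param result a [filter_and_count()] detection result.
#' @param truth a `ground_truth` from [generate_section()].
#' @param match_radius maximum centroid-to-centre distance in pixels.
#' @return A list with `fp_rate`, `fn_rate`, `n_matched`, `n_blobs`,
#'   `n_truth`.
#' @export
score_detection <- function(result, truth, match_radius) {
  if (match_radius <= 0) stop("match_radius must be > 0", call. = FALSE)
  blobs <- cbind(result$kept$centroid_row, result$kept$centroid_col)
  truths <- truth$positive_centers
  nb <- nrow(blobs); nt <- nrow(truths)
  matched <- 0L
  if (nb > 0 && nt > 0) {
    d <- sqrt(outer(blobs[, 1], truths[, 1], `-`)^2 +
                outer(blobs[, 2], truths[, 2], `-`)^2)
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_b <- logical(nb); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        b <- cand[i, 1]; t <- cand[i, 2]
        if (!used_b[b] && !used_t[t]) {
          used_b[b] <- TRUE; used_t[t] <- TRUE
          matched <- matched + 1L
        }
      }
    }
  }
  list(fp_rate = (nb - matched) / max(nb, 1L),
       fn_rate = if (nt > 0) (nt - matched) / nt else 0,
       n_matched = matched, n_blobs = nb, n_truth = nt)
}

#' Benchmark presets
#'
#' `"standard"` is the noisy validation condition: 512 x 512 sections, 30
#' positive disks of radius 3--7, 10 brown distractors, 5 irregular blue
#' smears, channel noise SD 6. `"clean"` removes distractors, smears and
#' noise (and is scored with `shape = 0`), the condition under which counts
#' must match ground truth exactly.
#'
#' @param preset `"standard"` or `"clean"`.
#' @param seed RNG seed for the section.
#' @param width,height canvas size.
#' @return A [section_spec()].
#' @export
benchmark_spec <- function(preset = c("standard", "clean"), seed = 1,
                           width = 512, height = 512) {
  preset <- match.arg(preset)
  if (preset == "standard")
    section_spec(width = width, height = height, seed = seed)
  else
    section_spec(width = width, height = height, seed = seed,
                 n_distractor_brown = 0, n_irregular_blue = 0, noise_sd = 0)
}

#' Run a seeded detection benchmark
#'
#' Generates `n_images` synthetic sections (per-image seeds `seed + i`),
#' writes the scribble reference set of the FIRST section, auto-calibrates
#' from it, runs the full detection pipeline on every section with the
#' calibrated bundle, and scores each against its ground truth with match
#' radius equal to the maximum positive-disk radius.
#'
#' @inheritParams benchmark_spec
#' @param n_images number of sections.
#' @param seed base seed.
#' @param shape roundness cutoff; `NULL` uses the calibrated default
#'   (0.5 for `"standard"`) or 0 for `"clean"`.
#' @param min_area minimum blob area.
#' @param cfg_dir directory for the generated reference set (default: a
#'   fresh temporary directory).
#' @return A tibble with one row per section: `image`, `n_truth`, `n_kept`,
#'   `fp_rate`, `fn_rate`.
#' @export
run_benchmark <- function(preset = c("standard", "clean"), n_images = 20,
                          seed = 1, shape = NULL, min_area = 4,
                          cfg_dir = tempfile("cq_cfg_")) {
  preset <- match.arg(preset)
  if (is.null(shape)) shape <- if (preset == "clean") 0 else NULL
  sections <- lapply(seq_len(n_images), function(i)
    generate_section(benchmark_spec(preset, seed = seed + i),
                     name = sprintf("section_%03d", i)))
  generate_reference_set(sections[[1]]$image, sections[[1]]$truth, cfg_dir)
  bundle <- auto_calibrate(cfg_dir)
  if (!is.null(shape)) bundle$shape <- shape
  match_radius <- max(vapply(sections, function(s)
    s$truth$spec$positive_radius_range[2], numeric(1)))
  rows <- lapply(sections, function(s) {
    tis <- tissue_mask(s$image, bundle)
    blobs <- label_blobs(heal_mask(classify_positive(s$image, bundle, tis)))
    res <- filter_and_count(blobs, shape = bundle$shape, min_area = min_area)
    sc <- score_detection(res, s$truth, match_radius)
    tibble::tibble(image = img_name(s$image), n_truth = sc$n_truth,
                   n_kept = sc$n_blobs, fp_rate = sc$fp_rate,
                   fn_rate = sc$fn_rate)
  })
  do.call(rbind, rows)
}

#' Write a folder of synthetic sections with ground-truth manifests
#'
#' Backend of the `simulate` CLI subcommand. Writes
#' `section_001.png ... section_N.png`, one JSON manifest per section
#' (positive centres/radii, distractor centres, tissue pixel count, spec), a
#' combined `centers.csv`, and the reference set of section 1 under
#' `cfg_ref/`.
#'
#' @inheritParams run_benchmark
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a tibble of image paths and truth counts.
#' @export
simulate_sections <- function(out_dir, n_images = 5, seed = 1,
                              preset = c("standard", "clean")) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  center_rows <- list()
  info <- list()
  for (i in seq_len(n_images)) {
    nm <- sprintf("section_%03d", i)
    sec <- generate_section(benchmark_spec(preset, seed = seed + i), name = nm)
    img_path <- file.path(out_dir, paste0(nm, ".png"))
    write_rgb_image(sec$image, img_path)
    manifest <- sec$truth[c("positive_centers", "positive_radii",
                            "distractor_centers", "tissue_pixel_count")]
    manifest$spec <- unclass(sec$truth$spec)
    jsonlite::write_json(manifest, file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    center_rows[[i]] <- tibble::tibble(
      image = nm,
      row = sec$truth$positive_centers[, 1],
      col = sec$truth$positive_centers[, 2],
      radius = sec$truth$positive_radii)
    if (i == 1L)
      generate_reference_set(sec$image, sec$truth, file.path(out_dir, "cfg_ref"))
    info[[i]] <- tibble::tibble(image = nm, path = img_path,
                                n_positive = nrow(sec$truth$positive_centers))
  }
  utils::write.csv(do.call(rbind, center_rows),
                   file.path(out_dir, "centers.csv"), row.names = FALSE)
  invisible(do.call(rbind, info))
}
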