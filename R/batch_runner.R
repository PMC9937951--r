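#' Configuration of a batch quantification run
#'
#' Bundles the paths and parameters for [process_folder()]. When `bundle` is
#' `NULL` it is calibrated from `cfg_dir` via [auto_calibrate()];
#' `alpha`/`shape` override the bundle's values when given (CLI flags map
#' onto these).
#'
#' @param input_dir directory of images to quantify (`.png/.jpg/.jpeg`;
#'   the six reference stems are excluded by name).
#' @param out_dir run output directory: overlays go to `out_dir/process/`,
#'   `data.txt` to the run root.
#' @param cfg_dir calibration directory (required when `bundle` is NULL).
#' @param bundle an optional pre-built [calibration_bundle()].
#' @param alpha,shape optional overrides of the bundle parameters.
#' @param min_area minimum blob area in pixels (default 4).
#' @param overwrite allow replacing an existing `data.txt` (default FALSE;
#'   the record file is otherwise append-only across runs).
#' @param verbose emit one message per processed image.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir, out_dir, cfg_dir = NULL, bundle = NULL,
                       alpha = NULL, shape = NULL, min_area = 4,
                       overwrite = FALSE, verbose = TRUE) {
  if (!dir.exists(input_dir))
    stop(sprintf("input directory not found: %s", input_dir), call. = FALSE)
  if (is.null(bundle)) {
    if (is.null(cfg_dir))
      stop("either a calibration bundle or cfg_dir is required", call. = FALSE)
    bundle <- auto_calibrate(cfg_dir)
  }
  if (!is.null(alpha)) bundle <- utils::modifyList(bundle, list(alpha = as.numeric(alpha)))
  if (!is.null(shape)) bundle$shape <- as.numeric(shape)
  if (bundle$alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (bundle$shape < 0 || bundle$shape > 1)
    stop("shape must be in [0, 1]", call. = FALSE)
  structure(list(input_dir = input_dir, out_dir = out_dir, cfg_dir = cfg_dir,
                 bundle = bundle, min_area = min_area, overwrite = overwrite,
                 verbose = verbose),
            class = "run_config")
}

#' Quantify one image
#'
#' Runs the full pipeline on one image -- tissue segmentation, positive
#' classification, blob labelling, shape filtering and counting -- writes
#' the three diagnostic overlays (`<name>_blue.png`, `<name>_bound.png`,
#' `<name>_hull.png`) into `out_dir/process/`, and returns the
#' quantification record. `pixel_area` is the IMAGE area
#' (`x_pixel * y_pixel`); the blue overlay prints the hull (analyzed
#' surface) area top-right, and `pixel_area * tissue_ratio` recovers it from
#' the record. An unreadable file yields a warning and `NULL`; an image with
#' no detectable tissue yields a record with zero count and zero tissue
#' ratio.
#'
#' @param path image path.
#' @param config a [run_config()].
#' @return A one-row tibble (`image_name`, `counted_points`, `pixel_area`,
#'   `x_pixel`, `y_pixel`, `tissue_ratio`, `painted_ratio`) or `NULL`.
#' @export
process_image <- function(path, config) {
  img <- tryCatch(read_rgb_image(path), error = function(e) {
    warning(sprintf("skipping unreadable image %s: %s", path,
                    conditionMessage(e)), call. = FALSE)
    NULL
  })
  if (is.null(img)) return(NULL)
  d <- img_dims(img)
  nm <- img_name(img)
  tis <- tryCatch(tissue_mask(img, config$bundle), error = function(e) NULL)
  if (is.null(tis)) {
    if (config$verbose)
      message(sprintf("%s: no tissue detected; recording zero count", nm))
    return(tibble::tibble(image_name = nm, counted_points = 0L,
                          pixel_area = prod(d), x_pixel = d[2], y_pixel = d[1],
                          tissue_ratio = 0, painted_ratio = 0))
  }
  pos <- heal_mask(classify_positive(img, config$bundle, tis))
  res <- filter_and_count(label_blobs(pos),
                          shape = config$bundle$shape,
                          min_area = config$min_area)
  proc_dir <- file.path(config$out_dir, "process")
  dir.create(proc_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- render_region_overlays(img, tis)
  write_rgb_image(annotate_blue_overlay(img, res, tis$hull_area),
                  file.path(proc_dir, paste0(nm, "_blue.png")))
  write_rgb_image(ov$bound, file.path(proc_dir, paste0(nm, "_bound.png")))
  write_rgb_image(ov$hull, file.path(proc_dir, paste0(nm, "_hull.png")))
  if (config$verbose)
    message(sprintf("%s: %d cells, hull area %.0f px^2 (%.1f%% of image)",
                    nm, res$count, tis$hull_area, 100 * tis$tissue_ratio))
  tibble::tibble(image_name = nm, counted_points = res$count,
                 pixel_area = prod(d), x_pixel = d[2], y_pixel = d[1],
                 tissue_ratio = tis$tissue_ratio,
                 painted_ratio = res$mean_fill_ratio)
}

is_reference_stem <- function(stem) stem %in% REFERENCE_STEMS

#' Quantify a folder of images
#'
#' Processes every `.png/.jpg/.jpeg` in `input_dir` (reference images
#' excluded by stem) in lexicographic filename order, appends one line per
#' record to `out_dir/data.txt`, mirrors the records to
#' `out_dir/records.csv`, and returns them as a tibble. An existing
#' `data.txt` stops the run unless `overwrite = TRUE` (accidental
#' accumulation guard).
#'
#' @param config a [run_config()].
#' @return A tibble of quantification records in processing order.
#' @export
process_folder <- function(config) {
  files <- list.files(config$input_dir, pattern = "\\.(png|jpe?g)$",
                      ignore.case = TRUE)
  files <- files[!is_reference_stem(tools::file_path_sans_ext(files))]
  files <- sort(files)
  if (!length(files))
    stop(sprintf("no images to quantify in %s", config$input_dir),
         call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_path <- file.path(config$out_dir, "data.txt")
  if (file.exists(data_path)) {
    if (!config$overwrite)
      stop(sprintf("data.txt exists in %s (use overwrite to replace it)",
                   config$out_dir), call. = FALSE)
    file.remove(data_path)
  }
  records <- list()
  for (f in files) {
    rec <- process_image(file.path(config$input_dir, f), config)
    if (is.null(rec)) next
    cat(format_record(rec), "\n", sep = "", file = data_path, append = TRUE)
    records[[length(records) + 1L]] <- rec
  }
  if (!length(records))
    stop("no images could be processed", call. = FALSE)
  out <- do.call(rbind, records)
  utils::write.csv(out, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE)
  out
}

#' Serialize and parse quantification records
#'
#' One `data.txt` line per image, fields joined by `": "` in the order
#' image name, counted points, pixel area, x-pixel, y-pixel, tissue ratio
#' (tissue size / image size), painted ratio (painted area / cell); the two
#' ratios carry 6 decimal places. `parse_record()` is the exact inverse.
#'
#' @param record a one-row record tibble (see [process_image()]).
#' @return `format_record()` a character line; `parse_record()` a one-row
#'   tibble.
#' @examples
#' format_record(tibble::tibble(image_name = "img1", counted_points = 7L,
#'   pixel_area = 20000, x_pixel = 200, y_pixel = 100,
#'   tissue_ratio = 0.5, painted_ratio = 0.75))
#' @export
format_record <- function(record) {
  sprintf("%s: %d: %d: %d: %d: %.6f: %.6f",
          record$image_name, as.integer(record$counted_points),
          as.integer(record$pixel_area), as.integer(record$x_pixel),
          as.integer(record$y_pixel), record$tissue_ratio,
          record$painted_ratio)
}

#' @rdname format_record
#' @param line a `data.txt` line.
#' @export
parse_record <- function(line) {
  parts <- strsplit(line, ": ", fixed = TRUE)[[1]]
  if (length(parts) != 7L)
    stop(sprintf("malformed record (expected 7 ': '-separated fields): %s",
                 line), call. = FALSE)
  nums <- suppressWarnings(as.numeric(parts[2:7]))
  if (anyNA(nums))
    stop(sprintf("malformed record (non-numeric field): %s", line),
         call. = FALSE)
  rec <- tibble::tibble(image_name = parts[1],
                        counted_points = as.integer(nums[1]),
                        pixel_area = as.integer(nums[2]),
                        x_pixel = as.integer(nums[3]),
                        y_pixel = as.integer(nums[4]),
                        tissue_ratio = nums[5], painted_ratio = nums[6])
  if (rec$pixel_area != rec$x_pixel * rec$y_pixel)
    stop(sprintf("inconsistent record: pixel_area %d != %d x %d",
                 rec$pixel_area, rec$x_pixel, rec$y_pixel), call. = FALSE)
  rec
}

#' Per-image positive-cell densities
#'
#' Applies the unit-area normalisation `counted_points / pixel_area * 1e6`
#' to each record. `density_tissue` additionally normalises by the analyzed
#' tissue fraction (`counted_points / (pixel_area * tissue_ratio) * 1e6`),
#' an extension useful when section sizes differ between images; it is 0
#' for images with zero count and no detected tissue.
#'
#' @param records a record tibble from [process_folder()].
#' @return The records with `density` and `density_tissue` columns added.
#' @export
summarize_records <- function(records) {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  dens <- density_per_area(records$counted_points, records$pixel_area)
  tissue_px <- records$pixel_area * records$tissue_ratio
  dens_t <- ifelse(tissue_px > 0, records$counted_points / tissue_px * 1e6,
                   ifelse(records$counted_points == 0, 0, NA_real_))
  records$density <- dens
  records$density_tissue <- dens_t
  records
}
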