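make_run_dirs <- function(n_images = 3, seed = 71, width = 140, height = 120,
                          n_positive = 6) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  input <- file.path(root, "input"); dir.create(input)
  cfg <- file.path(root, "cfg"); dir.create(cfg)
  out <- file.path(root, "out")
  truths <- list()
  for (i in seq_len(n_images)) {
    sp <- section_spec(width = width, height = height, seed = seed + i,
                       n_positive = n_positive, n_distractor_brown = 0,
                       n_irregular_blue = 0, noise_sd = 0)
    sec <- generate_section(sp, sprintf("img%02d", i))
    write_rgb_image(sec$image, file.path(input, sprintf("img%02d.png", i)))
    truths[[i]] <- sec$truth
    if (i == 1L) generate_reference_set(sec$image, sec$truth, cfg)
  }
  list(input = input, cfg = cfg, out = out, truths = truths)
}

test_that("single-image processing returns the record and the overlays", {
  d <- make_run_dirs(n_images = 1)
  cfg <- run_config(d$input, d$out, cfg_dir = d$cfg, shape = 0,
                    verbose = FALSE)
  rec <- process_image(file.path(d$input, "img01.png"), cfg)
  expect_equal(rec$counted_points, nrow(d$truths[[1]]$positive_centers))
  expect_equal(rec$x_pixel, 140)
  expect_equal(rec$y_pixel, 120)
  expect_equal(rec$pixel_area, 140 * 120)   # pixel area is the image area
  expect_true(rec$tissue_ratio > 0 && rec$tissue_ratio < 1)
  expect_true(rec$painted_ratio > 0 && rec$painted_ratio <= 1)
  expect_true(all(file.exists(file.path(d$out, "process",
    paste0("img01", c("_blue", "_bound", "_hull"), ".png")))))

  # unreadable image: warning, no record
  bad <- file.path(d$input, "broken.png")
  writeLines("not a png", bad)
  expect_warning(res <- process_image(bad, cfg), "skipping unreadable")
  expect_null(res)
  file.remove(bad)
})

test_that("folder runs process images in lexicographic order", {
  d <- make_run_dirs(n_images = 3)
  cfg <- run_config(d$input, d$out, cfg_dir = d$cfg, shape = 0,
                    verbose = FALSE)
  recs <- process_folder(cfg)
  expect_equal(recs$image_name, c("img01", "img02", "img03"))
  lines <- readLines(file.path(d$out, "data.txt"))
  expect_length(lines, 3L)
  expect_equal(vapply(lines, function(l) parse_record(l)$image_name,
                      character(1), USE.NAMES = FALSE),
               recs$image_name)

  # aggregate equals per-image calls
  per_image <- lapply(file.path(d$input, paste0("img0", 1:3, ".png")),
                      process_image, config = cfg)
  expect_equal(sum(recs$counted_points),
               sum(vapply(per_image, function(r) r$counted_points, numeric(1))))

  # counts equal ground truth on clean sections
  expect_equal(recs$counted_points,
               vapply(d$truths, function(t) nrow(t$positive_centers),
                      numeric(1)))

  # existing data.txt blocks a re-run unless overwrite is requested
  expect_error(process_folder(cfg), "data.txt exists")
  cfg2 <- run_config(d$input, d$out, cfg_dir = d$cfg, shape = 0,
                     overwrite = TRUE, verbose = FALSE)
  first <- readLines(file.path(d$out, "data.txt"))
  process_folder(cfg2)
  expect_identical(readLines(file.path(d$out, "data.txt")), first)

  # reference stems are never quantified
  expect_false(any(grepl("file1|file2|t1", recs$image_name)))

  # empty input folder
  empty <- withr::local_tempdir()
  expect_error(run_config(empty, d$out, bundle = cfg$bundle) |> process_folder(),
               "no images")
})

test_that("record lines round-trip through the ': ' dialect", {
  rec <- tibble::tibble(image_name = "img1", counted_points = 7L,
                        pixel_area = 20000L, x_pixel = 200L, y_pixel = 100L,
                        tissue_ratio = 0.5, painted_ratio = 0.75)
  line <- format_record(rec)
  expect_identical(line, "img1: 7: 20000: 200: 100: 0.500000: 0.750000")
  expect_equal(parse_record(line), rec)

  # property: round trip is the identity for random valid records
  withr::with_seed(81, {
    for (i in 1:10) {
      x <- sample(50:400, 1); y <- sample(50:400, 1)
      r <- tibble::tibble(image_name = paste0("s", i),
                          counted_points = sample(0:50, 1),
                          pixel_area = x * y, x_pixel = x, y_pixel = y,
                          tissue_ratio = round(runif(1), 6),
                          painted_ratio = round(runif(1), 6))
      expect_equal(parse_record(format_record(r)), r)
    }
  })

  expect_error(parse_record("a: 1: 2: 3: 4: 5"), "7")
  expect_error(parse_record("a: x: 20000: 200: 100: 0.1: 0.2"), "non-numeric")
  expect_error(parse_record("a: 1: 999: 200: 100: 0.1: 0.2"), "inconsistent")
})

test_that("summaries apply the density formula per record", {
  recs <- tibble::tibble(
    image_name = c("a", "b", "c"),
    counted_points = c(5L, 0L, 2L),
    pixel_area = c(1e6, 2e5, 5e5),
    x_pixel = c(1000L, 500L, 1000L), y_pixel = c(1000L, 400L, 500L),
    tissue_ratio = c(0.5, 0.25, 0), painted_ratio = c(0.7, 0, 0))
  s <- summarize_records(recs)
  expect_equal(s$density, c(5, 0, 4))
  expect_equal(s$density,
               vapply(seq_len(3), function(i)
                 density_per_area(recs$counted_points[i], recs$pixel_area[i]),
                 numeric(1)))
  expect_equal(s$density_tissue[1], 5 / 0.5)
  expect_true(is.na(s$density_tissue[3]))   # count without detected tissue
})

test_that("re-runs are byte-identical", {
  d <- make_run_dirs(n_images = 2, seed = 91)
  out2 <- paste0(d$out, "_b")
  cfg1 <- run_config(d$input, d$out, cfg_dir = d$cfg, verbose = FALSE)
  cfg2 <- run_config(d$input, out2, cfg_dir = d$cfg, verbose = FALSE)
  process_folder(cfg1)
  process_folder(cfg2)
  f1 <- readLines(file.path(d$out, "data.txt"))
  f2 <- readLines(file.path(out2, "data.txt"))
  expect_identical(f1, f2)
  for (f in list.files(file.path(d$out, "process"))) {
    expect_identical(readBin(file.path(d$out, "process", f), "raw", 1e6),
                     readBin(file.path(out2, "process", f), "raw", 1e6))
  }
})
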