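test_that("section rendering is seeded, bounded and colour-exact", {
  sp0 <- section_spec(width = 100, height = 100, seed = 13, n_positive = 0,
                      n_distractor_brown = 0, n_irregular_blue = 0,
                      noise_sd = 0)
  sec <- generate_section(sp0, "flat")
  cols <- unique(matrix(unclass(sec$image), ncol = 3))
  expect_equal(nrow(cols), 2L)   # background + tissue only

  # same seed twice: byte-identical
  sp <- section_spec(width = 100, height = 100, seed = 14, n_positive = 5,
                     n_distractor_brown = 2, n_irregular_blue = 1)
  a <- generate_section(sp, "a"); b <- generate_section(sp, "b")
  expect_identical(unclass(a$image)[TRUE], unclass(b$image)[TRUE])
  expect_identical(a$truth$positive_centers, b$truth$positive_centers)

  # rendered disk pixel counts near pi r^2
  sp1 <- section_spec(width = 150, height = 150, seed = 15, n_positive = 8,
                      n_distractor_brown = 0, n_irregular_blue = 0,
                      noise_sd = 0)
  sec1 <- generate_section(sp1, "disks")
  for (i in seq_len(8)) {
    ctr <- sec1$truth$positive_centers[i, ]
    r <- sec1$truth$positive_radii[i]
    n_px <- sum(sec1$truth$class_map == 2L &
                  (row(sec1$truth$class_map) - ctr[1])^2 +
                  (col(sec1$truth$class_map) - ctr[2])^2 <= (r + 0.5)^2)
    expect_lt(abs(n_px - pi * r^2) / (pi * r^2), 0.1)
  }

  # impossible placements fail with advice, not an endless loop
  tiny <- section_spec(width = 60, height = 60, seed = 16, n_positive = 40,
                       tissue_shape = list(semi_axes = c(18, 18)),
                       n_distractor_brown = 0, n_irregular_blue = 0)
  expect_error(generate_section(tiny), "fewer or smaller")

  # colour separation guard
  expect_error(section_spec(noise_sd = 30), "separation")
})

test_that("the reference set reproduces the annotation protocol", {
  tdir <- withr::local_tempdir()
  sp <- section_spec(width = 150, height = 150, seed = 17, n_positive = 6,
                     n_distractor_brown = 2, n_irregular_blue = 1,
                     noise_sd = 0)
  sec <- generate_section(sp, "ref")
  generate_reference_set(sec$image, sec$truth, tdir)

  expect_identical(sort(list.files(tdir)),
                   sort(c("file1.png", "file1_bk.png", "file2.png",
                          "file2_inside.png", "t1.png", "t1_pt.png")))

  # background scribbles lie strictly outside the tissue ellipse
  orig <- read_rgb_image(file.path(tdir, "file1.png"))
  anno <- read_rgb_image(file.path(tdir, "file1_bk.png"))
  sc <- extract_scribble_pixels(orig, anno, "dark")
  expect_true(all(sec$truth$class_map[sc] == 0L))

  # noise-free calibration recovers the exact palette
  bundle <- auto_calibrate(tdir)
  expect_true(all(abs(bundle$bk$mean - sp$background_color) <= 2))
  expect_true(all(abs(bundle$inside$mean - sp$tissue_color) <= 2))
  expect_true(all(abs(bundle$pt$mean - sp$positive_color) <= 2))
})

test_that("detection scoring matches optimal matching on unambiguous cases", {
  truth <- structure(list(positive_centers = rbind(c(10, 10), c(30, 30),
                                                   c(50, 10))),
                     class = "ground_truth")
  mk_result <- function(centroids) {
    k <- nrow(centroids)
    structure(list(kept = tibble::tibble(centroid_row = centroids[, 1],
                                         centroid_col = centroids[, 2])),
              class = "detection_result")
  }

  perfect <- mk_result(rbind(c(10, 10), c(30, 30), c(50, 10)))
  sc <- score_detection(perfect, truth, match_radius = 5)
  expect_equal(c(sc$fp_rate, sc$fn_rate), c(0, 0))

  nothing <- mk_result(matrix(numeric(0), ncol = 2))
  sc0 <- score_detection(nothing, truth, match_radius = 5)
  expect_equal(sc0$fn_rate, 1)
  expect_equal(sc0$fp_rate, 0)   # denominator max(n_blobs, 1)

  none_truth <- structure(list(positive_centers = matrix(numeric(0), ncol = 2)),
                          class = "ground_truth")
  expect_equal(score_detection(perfect, none_truth, 5)$fn_rate, 0)

  # shuffled blob order gives the same rates as exhaustive optimal matching
  withr::with_seed(19, {
    blobs <- rbind(c(11, 9), c(29, 31), c(80, 80), c(51, 11))
    for (i in 1:5) {
      sh <- blobs[sample(nrow(blobs)), , drop = FALSE]
      scs <- score_detection(mk_result(sh), truth, 5)
      opt <- oracle_optimal_matching(sh, truth$positive_centers, 5)
      expect_equal(scs$n_matched, opt)
      expect_equal(scs$fp_rate, (nrow(sh) - opt) / nrow(sh))
      expect_equal(scs$fn_rate, (3 - opt) / 3)
    }
  })
})

test_that("raising the shape cutoff drops smears but keeps disks", {
  secs <- lapply(1:2, function(i)
    generate_section(benchmark_spec("standard", seed = 142 + i), paste0("s", i)))
  tdir <- withr::local_tempdir()
  generate_reference_set(secs[[1]]$image, secs[[1]]$truth, tdir)
  b <- auto_calibrate(tdir)
  tot <- c(d0 = 0, d6 = 0, s0 = 0, s6 = 0)
  for (s in secs) {
    tis <- tissue_mask(s$image, b)
    blobs <- label_blobs(heal_mask(classify_positive(s$image, b, tis)))
    for (sh in c(0, 0.6)) {
      res <- filter_and_count(blobs, shape = sh, min_area = 4)
      sc <- score_detection(res, s$truth, 7)
      smear <- sum(vapply(res$kept$pixels, function(px)
        mean(s$truth$class_map[px] == 4L) >= 0.5, logical(1)))
      key <- if (sh == 0) c("d0", "s0") else c("d6", "s6")
      tot[key] <- tot[key] + c(sc$n_matched, smear)
    }
  }
  expect_gt(tot[["s0"]], 0)                          # smears are detected at 0
  expect_lte(tot[["s6"]], 0.1 * tot[["s0"]])         # ...and removed at 0.6
  expect_gte(tot[["d6"]], 0.9 * tot[["d0"]])         # disks survive the cutoff
})

test_that("simulate writes images, manifests, centres and the reference set", {
  tdir <- withr::local_tempdir()
  info <- simulate_sections(tdir, n_images = 2, seed = 3, preset = "clean")
  expect_true(all(file.exists(file.path(tdir, c("section_001.png",
                                                "section_002.png",
                                                "section_001.json",
                                                "centers.csv")))))
  expect_true(dir.exists(file.path(tdir, "cfg_ref")))
  man <- jsonlite::read_json(file.path(tdir, "section_001.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man$positive_centers), 30)
  cent <- utils::read.csv(file.path(tdir, "centers.csv"))
  expect_equal(nrow(cent), 60)
  # manifest matches the regenerated ground truth
  sec <- generate_section(benchmark_spec("clean", seed = 4), "section_001")
  expect_equal(man$positive_centers, unname(sec$truth$positive_centers))
})
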