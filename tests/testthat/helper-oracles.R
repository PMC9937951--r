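# Independent oracles: deliberately naive implementations (explicit loops,
# textbook formulas) that the vectorised / compiled code paths are checked
# against.

# two-pass per-channel mean and population SD
oracle_color_stats <- function(image, pixels) {
  n <- nrow(pixels)
  vals <- matrix(0, n, 3)
  for (i in seq_len(n))
    for (ch in 1:3)
      vals[i, ch] <- unclass(image)[pixels[i, 1], pixels[i, 2], ch]
  m <- numeric(3); s <- numeric(3)
  for (ch in 1:3) {
    m[ch] <- sum(vals[, ch]) / n
    s[ch] <- sqrt(sum((vals[, ch] - m[ch])^2) / n)
  }
  list(mean = m, sd = s)
}

# pixel-by-pixel acceptance-band classifier
oracle_band_mask <- function(image, mu, half_width) {
  d <- dim(image)[1:2]
  out <- matrix(FALSE, d[1], d[2])
  for (r in seq_len(d[1]))
    for (cc in seq_len(d[2])) {
      ok <- TRUE
      for (ch in 1:3)
        if (abs(unclass(image)[r, cc, ch] - mu[ch]) > half_width[ch]) ok <- FALSE
      out[r, cc] <- ok
    }
  out
}

# BFS flood-fill component labelling
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, cc)); lab[r, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# convex-polygon containment by cross-product signs (eps tolerant)
oracle_point_in_convex_poly <- function(pt, poly, eps = 1e-9) {
  k <- nrow(poly)
  if (k == 1L) return(all(abs(pt - poly[1, ]) < eps))
  sgn <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (pt[1] - poly[i, 1])
    if (abs(cr) < eps) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

# exhaustive optimal one-to-one matching (maximise matches within radius);
# feasible only for small cases
oracle_optimal_matching <- function(blobs, truths, radius) {
  nb <- nrow(blobs); nt <- nrow(truths)
  if (nb == 0 || nt == 0) return(0L)
  d <- sqrt(outer(blobs[, 1], truths[, 1], `-`)^2 +
              outer(blobs[, 2], truths[, 2], `-`)^2)
  best <- 0L
  recurse <- function(bi, used_t, matched) {
    if (bi > nb) { best <<- max(best, matched); return(invisible()) }
    recurse(bi + 1L, used_t, matched)           # leave blob bi unmatched
    for (ti in seq_len(nt))
      if (!used_t[ti] && d[bi, ti] <= radius) {
        used_t[ti] <- TRUE
        recurse(bi + 1L, used_t, matched + 1L)
        used_t[ti] <- FALSE
      }
  }
  recurse(1L, logical(nt), 0L)
  best
}

# small solid-colour image with optional forced pixels
flat_image <- function(h, w, color, name = "flat") {
  arr <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) arr[, , ch] <- color[ch]
  rgb_image(arr, name)
}

set_pixel <- function(img, r, c, color) {
  arr <- unclass(img)
  arr[r, c, ] <- color
  rgb_image(arr, attr(img, "name"))
}

# hand-built bundle for classifier tests
test_bundle <- function(bk_mean = c(235, 232, 228), bk_sd = c(5, 5, 5),
                        in_mean = c(222, 150, 160), in_sd = c(5, 5, 5),
                        pt_mean = c(60, 90, 170), pt_sd = c(5, 5, 5),
                        alpha = 1, shape = 0.5) {
  calibration_bundle(bk = color_stats(bk_mean, bk_sd, 10),
                     inside = color_stats(in_mean, in_sd, 10),
                     pt = color_stats(pt_mean, pt_sd, 10),
                     alpha = alpha, shape = shape)
}

# random RGB image drawn from a set of class colours plus uniform noise
random_class_image <- function(h, w, colors, seed) {
  withr::with_seed(seed, {
    arr <- array(0, dim = c(h, w, 3))
    pick <- sample(seq_len(nrow(colors)), h * w, replace = TRUE)
    for (ch in 1:3)
      arr[, , ch] <- pmin(pmax(colors[pick, ch] +
                                 sample(-15:15, h * w, TRUE), 0), 255)
    rgb_image(arr, "random")
  })
}

# rasterised disk / line pixel sets for shape tests
disk_pixels <- function(center, radius) {
  rr <- floor(center[1] - radius):ceiling(center[1] + radius)
  cc <- floor(center[2] - radius):ceiling(center[2] + radius)
  g <- expand.grid(row = rr, col = cc)
  as.matrix(g[(g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2, ])
}

line_pixels_h <- function(row, col0, len) cbind(row = rep(row, len),
                                                col = col0 + seq_len(len) - 1L)
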