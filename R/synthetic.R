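# Synthetic image/mask fixtures with the statistical structure of the two
# target domains: class-imbalanced brain-slice-like grayscale images (one
# smooth elliptical foreground, sometimes tiny) and blood-smear-like RGB
# images (1-10 small dark disks, sometimes touching, over faint distractor
# disks that are excluded from the mask).

#' Fixture generation settings
#'
#' @param kind `"brain_like"` or `"smear_like"`.
#' @param n_images Number of samples.
#' @param height,width Image dimensions in pixels.
#' @param foreground_fraction_range Range of the ellipse area as a fraction of
#'   the frame (brain-like only).
#' @param small_target_probability Probability that a brain-like sample draws
#'   its area from the low (< 1 percent) end of the range, emulating the
#'   category-imbalanced slices of a brain volume.
#' @param n_cells_range Integer range of target cell counts per smear-like
#'   image (default 1-10).
#' @param adhesion_probability Probability that a smear-like image contains a
#'   touching ("adhesion") pair of target cells.
#' @param noise_sigma Standard deviation of the additive Gaussian intensity
#'   noise, on the 0-1 scale (default 0.05); values are clipped back to [0,1].
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("brain_like", "smear_like"), n_images = 4,
                         height = 64, width = 64,
                         foreground_fraction_range = c(0.002, 0.2),
                         small_target_probability = 0.3,
                         n_cells_range = c(1, 10),
                         adhesion_probability = 0.3,
                         noise_sigma = 0.05, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_images >= 1, height >= 8, width >= 8,
            length(foreground_fraction_range) == 2,
            foreground_fraction_range[1] > 0, foreground_fraction_range[2] < 1,
            foreground_fraction_range[1] <= foreground_fraction_range[2],
            small_target_probability >= 0, small_target_probability <= 1,
            length(n_cells_range) == 2, n_cells_range[1] >= 1,
            n_cells_range[1] <= n_cells_range[2],
            adhesion_probability >= 0, adhesion_probability <= 1,
            noise_sigma >= 0)
  structure(list(kind = kind, n_images = as.integer(n_images),
                 height = as.integer(height), width = as.integer(width),
                 foreground_fraction_range = foreground_fraction_range,
                 small_target_probability = small_target_probability,
                 n_cells_range = as.integer(n_cells_range),
                 adhesion_probability = adhesion_probability,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Construct a segmentation sample
#' @param image Intensity array `[H, W, C]` with values in `[0, 1]`.
#' @param mask Binary matrix `[H, W]`.
#' @param id Identifier string.
#' @return An object of class `segmentation_sample`.
#' @export
segmentation_sample <- function(image, mask, id) {
  image <- .as_batch(image, "image")[, , , 1, drop = TRUE]
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]),
            all(mask == 0 | mask == 1))
  structure(list(image = image, mask = mask, id = id),
            class = "segmentation_sample")
}

#' @export
print.segmentation_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("segmentation sample '%s': %dx%d, %d channel(s), foreground %.4f\n",
              x$id, d[1], d[2], d[3], mean(x$mask)))
  invisible(x)
}

# Smooth low-frequency random field in [0, 1], bilinearly upscaled from a
# coarse grid; gives mild background texture.
.smooth_field <- function(H, W, cells = 6) {
  g <- matrix(stats::runif(cells * cells), cells, cells)
  ih <- seq(1, cells, length.out = H)
  iw <- seq(1, cells, length.out = W)
  h0 <- pmin(floor(ih), cells - 1); fh <- ih - h0
  w0 <- pmin(floor(iw), cells - 1); fw <- iw - w0
  a <- g[cbind(rep(h0, W), rep(w0, each = H))]
  b <- g[cbind(rep(h0 + 1, W), rep(w0, each = H))]
  cc <- g[cbind(rep(h0, W), rep(w0 + 1, each = H))]
  d <- g[cbind(rep(h0 + 1, W), rep(w0 + 1, each = H))]
  v <- a * (1 - fh) * rep(1 - fw, each = H) + b * fh * rep(1 - fw, each = H) +
    cc * (1 - fh) * rep(fw, each = H) + d * fh * rep(fw, each = H)
  matrix(v, H, W)
}

# Pixel-center rasterisation of an ellipse: pixel (r, c) is foreground iff its
# center lies inside the ellipse.
.ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  r <- matrix(seq_len(H), H, W)
  cl <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- r - cy
  dx <- cl - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  (u^2 + v^2 <= 1) * 1
}

.disk_mask <- function(H, W, cy, cx, radius) {
  r <- matrix(seq_len(H), H, W)
  cl <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((r - cy)^2 + (cl - cx)^2 <= radius^2) * 1
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate brain-slice-like samples
#'
#' Each sample is a grayscale image with one smooth elliptical foreground
#' region (randomised axes, orientation and intensity gradient) over a darker
#' textured background plus additive Gaussian noise. With probability
#' `small_target_probability` the ellipse area is drawn from the low end of
#' `foreground_fraction_range` (capped at 1 percent of the frame), emulating
#' the slices where the target occupies a very small proportion of the image.
#'
#' @param spec A [fixture_spec()] with `kind = "brain_like"`.
#' @return A list of [segmentation_sample()] objects.
#' @export
generate_brain_like <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "brain_like")
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  rng <- spec$foreground_fraction_range
  low_hi <- max(rng[1], min(rng[2], 0.01))
  lapply(seq_len(spec$n_images), function(i) {
    small <- stats::runif(1) < spec$small_target_probability
    frac <- if (small) stats::runif(1, rng[1], low_hi) else stats::runif(1, rng[1], rng[2])
    area <- frac * H * W
    rho <- stats::runif(1, 0.5, 2)
    a <- sqrt(area * rho / pi)
    b <- sqrt(area / (rho * pi))
    # shrink until the ellipse fits the frame with a 1-pixel margin
    while (2 * max(a, b) > min(H, W) - 2) {
      a <- a * 0.9; b <- b * 0.9
      message("ellipse larger than frame; shrinking axes")
    }
    theta <- stats::runif(1, 0, pi)
    mr <- max(a, b) + 1
    cy <- stats::runif(1, 1 + mr, H - mr)
    cx <- stats::runif(1, 1 + mr, W - mr)
    mask <- .ellipse_mask(H, W, cy, cx, a, b, theta)
    bg <- 0.12 + 0.12 * .smooth_field(H, W)
    gdir <- stats::runif(1, 0, 2 * pi)
    gfield <- (matrix(seq_len(H), H, W) * sin(gdir) +
                 matrix(seq_len(W), H, W, byrow = TRUE) * cos(gdir))
    gfield <- (gfield - min(gfield)) / max(1e-9, diff(range(gfield)))
    fg <- 0.55 + 0.25 * gfield
    img <- bg * (1 - mask) + fg * mask
    img <- .clip01(img + stats::rnorm(H * W, sd = spec$noise_sigma))
    dim(img) <- c(H, W, 1L)
    segmentation_sample(img, mask, sprintf("brain_%03d", i))
  })
}

#' Generate blood-smear-like samples
#'
#' RGB images with a pale textured background, many faint distractor disks
#' (emulating red cells, never part of the mask) and `k ~ Uniform(n_cells_range)`
#' dark target disks that define the mask. With probability
#' `adhesion_probability` (and `k >= 2`) two target disks are placed with
#' overlapping boundaries so they form a single touching component, the
#' "adhesion cell" stress case. Target and distractor intensities overlap, so
#' the task is not solvable by a global threshold. The distractor-only layer is
#' attached to each sample as `attr(sample, "distractor_mask")`.
#'
#' @param spec A [fixture_spec()] with `kind = "smear_like"`.
#' @return A list of [segmentation_sample()] objects.
#' @export
generate_smear_like <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$kind == "smear_like")
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  rmin <- 0.05 * min(H, W)
  rmax <- 0.09 * min(H, W)
  lapply(seq_len(spec$n_images), function(i) {
    k <- sample(seq(spec$n_cells_range[1], spec$n_cells_range[2]), 1)
    adhesion <- k >= 2 && stats::runif(1) < spec$adhesion_probability
    centers <- list()
    mask <- matrix(0, H, W)
    place <- function(radius, near = NULL) {
      for (try in 1:50) {
        if (is.null(near)) {
          cy <- stats::runif(1, 1 + radius, H - radius)
          cx <- stats::runif(1, 1 + radius, W - radius)
        } else {
          d <- (near$r + radius) * stats::runif(1, 0.7, 0.95)
          ang <- stats::runif(1, 0, 2 * pi)
          cy <- min(max(near$cy + d * sin(ang), 1 + radius), H - radius)
          cx <- min(max(near$cx + d * cos(ang), 1 + radius), W - radius)
        }
        ok <- TRUE
        for (c0 in centers) {
          lim <- if (!is.null(near) && identical(c0, near)) 0 else (c0$r + radius + 1)
          if ((c0$cy - cy)^2 + (c0$cx - cx)^2 < lim^2) { ok <- FALSE; break }
        }
        if (ok || !is.null(near)) return(list(cy = cy, cx = cx, r = radius))
      }
      NULL
    }
    placed <- 0
    while (placed < k) {
      r <- stats::runif(1, rmin, rmax)
      c0 <- place(r)
      if (is.null(c0)) {
        message("cell placement failed; generating fewer cells")
        break
      }
      centers[[length(centers) + 1]] <- c0
      placed <- placed + 1
      if (adhesion && placed == 1) {
        r2 <- stats::runif(1, rmin, rmax)
        c2 <- place(r2, near = c0)
        centers[[length(centers) + 1]] <- c2
        placed <- placed + 1
        if (placed >= k) break
      }
    }
    for (c0 in centers) mask <- pmax(mask, .disk_mask(H, W, c0$cy, c0$cx, c0$r))
    # distractors: faint disks, clipped so they never enter the mask layer
    distractor <- matrix(0, H, W)
    n_distr <- sample(12:25, 1)
    for (j in seq_len(n_distr)) {
      r <- stats::runif(1, 0.6 * rmin, rmax)
      cy <- stats::runif(1, 1, H)
      cx <- stats::runif(1, 1, W)
      distractor <- pmax(distractor, .disk_mask(H, W, cy, cx, r))
    }
    distractor <- distractor * (1 - mask)
    base_r <- 0.93 - 0.06 * .smooth_field(H, W)
    base_g <- 0.88 - 0.06 * .smooth_field(H, W)
    base_b <- 0.92 - 0.04 * .smooth_field(H, W)
    # overlapping intensity ranges: targets ~U(0.30,0.50), distractors ~U(0.45,0.70)
    tgt_int <- stats::runif(1, 0.30, 0.50)
    dis_int <- stats::runif(1, 0.45, 0.70)
    img <- array(0, c(H, W, 3))
    img[, , 1] <- base_r * (1 - pmax(mask, distractor)) +
      (tgt_int * 0.8) * mask + (dis_int + 0.15) * distractor
    img[, , 2] <- base_g * (1 - pmax(mask, distractor)) +
      (tgt_int * 0.6) * mask + (dis_int * 0.75) * distractor
    img[, , 3] <- base_b * (1 - pmax(mask, distractor)) +
      tgt_int * mask + (dis_int * 0.9) * distractor
    img <- .clip01(img + stats::rnorm(length(img), sd = spec$noise_sigma))
    dim(img) <- c(H, W, 3L)
    s <- segmentation_sample(img, mask, sprintf("smear_%03d", i))
    attr(s, "distractor_mask") <- distractor
    s
  })
}

#' Generate samples according to a fixture spec
#' @param spec A [fixture_spec()].
#' @return A list of [segmentation_sample()] objects.
#' @export
generate_fixtures <- function(spec) {
  switch(spec$kind,
         brain_like = generate_brain_like(spec),
         smear_like = generate_smear_like(spec))
}

#' Write a fixture set to disk
#'
#' `"png_pairs"` writes `image_NNN.png` / `mask_NNN.png` pairs (8-bit; masks
#' as 0/255); `"nifti_stack"` stacks the grayscale slices into `image.nii` and
#' `mask.nii` volumes, exercising the same reader path as real sliced-volume
#' data. A `manifest.csv` records path, kind, seed and foreground fraction per
#' file. Images are quantised to 8 bits before writing so that a write/read
#' round trip is bit-exact.
#'
#' @param samples List of [segmentation_sample()] objects.
#' @param directory Output directory (created if missing).
#' @param format `"png_pairs"` or `"nifti_stack"`.
#' @param kind Kind label recorded in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return The manifest data frame, invisibly.
#' @export
write_fixture_set <- function(samples, directory,
                              format = c("png_pairs", "nifti_stack"),
                              kind = "unknown", seed = NA_integer_) {
  format <- match.arg(format)
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  rows <- list()
  if (format == "png_pairs") {
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      img <- round(s$image * 255) / 255     # 8-bit quantisation
      if (dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
      ip <- file.path(directory, sprintf("image_%03d.png", i))
      mp <- file.path(directory, sprintf("mask_%03d.png", i))
      png::writePNG(img, ip)
      png::writePNG(s$mask, mp)
      rows[[length(rows) + 1]] <- data.frame(
        path = c(ip, mp), kind = kind, seed = seed,
        foreground_fraction = mean(s$mask), stringsAsFactors = FALSE)
    }
  } else {
    d <- dim(samples[[1]]$image)
    if (d[3] != 1)
      stop("nifti_stack supports grayscale samples only", call. = FALSE)
    n <- length(samples)
    vol <- array(0, c(d[1], d[2], n))
    msk <- array(0, c(d[1], d[2], n))
    for (i in seq_len(n)) {
      vol[, , i] <- samples[[i]]$image[, , 1]
      msk[, , i] <- samples[[i]]$mask
    }
    ip <- file.path(directory, "image.nii")
    mp <- file.path(directory, "mask.nii")
    RNifti::writeNifti(vol, ip, datatype = "double")
    RNifti::writeNifti(msk, mp, datatype = "double")
    rows[[1]] <- data.frame(path = c(ip, mp), kind = kind, seed = seed,
                            foreground_fraction = mean(msk),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
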