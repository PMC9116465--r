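# Synthetic circular-field-of-view phantoms with graded distortions and
# pseudo mean-opinion scores. The generator emulates the shape of a
# confocal-endoscopy quality dataset - cell-like texture inside a circular
# effective region, degraded by blur, noise, and contrast loss, with
# monotone subjective labels - so the whole pipeline is trainable and
# testable without any instrument data. No claim of biological realism is
# made; see the methods vignette for what it does and does not emulate.

# Separable Gaussian blur with reflective padding. sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  m <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-m, m), sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(x) {     # filter columns of x
    n <- nrow(x)
    top <- x[pmin(m, n):1, , drop = FALSE]
    bot <- x[n:pmax(1L, n - m + 1L), , drop = FALSE]
    padded <- rbind(top, x, bot)
    f <- stats::filter(padded, k, sides = 2L)
    matrix(f[(nrow(top) + 1L):(nrow(top) + n), ], n, ncol(x))
  }
  t(blur_1d(t(blur_1d(img))))
}

# Linear motion blur: average of the image shifted along a digital line of
# `len` pixels at `angle` radians, replicate padding at the borders.
motion_blur <- function(img, len, angle) {
  if (len <= 1L) return(img)
  h <- nrow(img); w <- ncol(img)
  half <- (len - 1) / 2
  ts <- seq(-half, half, by = 1)
  acc <- matrix(0, h, w)
  for (t in ts) {
    dr <- round(-t * sin(angle)); dc <- round(t * cos(angle))
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    acc <- acc + img[ri, ci, drop = FALSE]
  }
  acc / length(ts)
}

fov_mask <- function(h, w, center, radius) {
  outer((seq_len(h) - center[1L])^2, (seq_len(w) - center[2L])^2, `+`) <=
    radius^2
}

#' Generate a circular-field-of-view textured phantom
#'
#' Renders a cell-like texture - soft-edged elliptical blobs over a dim
#' background, plus a fine smoothed-noise grain so that every spatial
#' frequency band carries structure - inside a centered circular field of
#' view, zero outside, quantized to the 8-bit range. Deterministic given
#' the seed.
#'
#' @param size Raster side in pixels (>= 64, default 256).
#' @param blob_density Expected blobs per pixel of disk area
#'   (default 2e-3). Zero gives a uniform-background disk.
#' @param blob_radius Length-2 range of blob Gaussian radii in pixels.
#' @param contrast Length-2 range of blob peak amplitudes (gray levels).
#' @param background Background gray level inside the disk.
#' @param grain_sd SD of the fine texture grain (gray levels).
#' @param fov_radius_fraction Circle radius as a fraction of `size / 2`.
#' @param seed Integer seed.
#' @return An [fov_image()].
#' @export
generate_phantom <- function(size = 256L, blob_density = 2e-3,
                             blob_radius = c(3, 10), contrast = c(40, 140),
                             background = 60, grain_sd = 10,
                             fov_radius_fraction = 0.95, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("phantom size must be at least 64", call. = FALSE)
  if (fov_radius_fraction <= 0 || fov_radius_fraction > 1)
    stop("fov_radius_fraction must be in (0, 1]", call. = FALSE)
  center <- c((size + 1) / 2, (size + 1) / 2)
  radius <- fov_radius_fraction * size / 2
  with_seed(seed, {
    img <- matrix(background, size, size)
    n_blobs <- round(blob_density * pi * radius^2)
    for (b in seq_len(n_blobs)) {
      # blob center uniform in the disk
      a <- stats::runif(1, 0, 2 * pi); rr <- radius * sqrt(stats::runif(1))
      cr <- center[1L] + rr * sin(a); cc <- center[2L] + rr * cos(a)
      s1 <- stats::runif(1, blob_radius[1L], blob_radius[2L])
      s2 <- s1 * stats::runif(1, 0.5, 1)          # elliptical
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, contrast[1L], contrast[2L]) *
        sample(c(1, -0.4), 1L, prob = c(0.8, 0.2)) # mostly bright cells
      m <- ceiling(3 * s1)
      ri <- max(1L, floor(cr - m)):min(size, ceiling(cr + m))
      ci <- max(1L, floor(cc - m)):min(size, ceiling(cc + m))
      dy <- ri - cr; dx <- ci - cc
      u <- outer(dy, dx, function(y, x)  cos(th) * y + sin(th) * x)
      v <- outer(dy, dx, function(y, x) -sin(th) * y + cos(th) * x)
      img[ri, ci] <- img[ri, ci] + amp * exp(-(u^2 / s1^2 + v^2 / s2^2) / 2)
    }
    if (grain_sd > 0)
      img <- img + gaussian_blur(matrix(stats::rnorm(size^2, 0, grain_sd),
                                        size, size), 0.8)
    img <- pmin(pmax(round(img), 0), 255)
    img[!fov_mask(size, size, center, radius)] <- 0
    fov_image(img, center, radius)
  })
}

#' Apply a graded distortion to a phantom
#'
#' Degrades the image inside its circular field of view with one of the
#' distortion families common in confocal endoscopy; pixels outside the
#' circle stay untouched. Severity 0 is the exact identity; each family's
#' physical parameter grows monotonically with severity:
#' \describe{
#'   \item{defocus_blur}{Gaussian blur, `sigma = 3 * severity` px.}
#'   \item{motion_blur}{linear blur, length `1 + round(14 * severity)` px
#'     at a seeded random angle.}
#'   \item{gaussian_noise}{additive white noise, `sd = 30 * severity` gray
#'     levels.}
#'   \item{contrast_compression}{intensities pulled toward the in-FOV mean
#'     by factor `1 - 0.8 * severity`.}
#'   \item{mixed}{blur, then noise, then contrast loss, with component
#'     severities drawn in `severity * [0.5, 1]` from the seed.}
#' }
#'
#' @param image An [fov_image()].
#' @param kind Distortion family (see above).
#' @param severity Real in \[0, 1\].
#' @param seed Integer seed for the stochastic components (noise values,
#'   motion angle, mixed-component severities).
#' @return A degraded [fov_image()] with the same geometry.
#' @export
apply_distortion <- function(image, kind = c("defocus_blur", "motion_blur",
                                             "gaussian_noise",
                                             "contrast_compression", "mixed"),
                             severity, seed = 1L) {
  kind <- match.arg(kind)
  image <- as_fov_image(image)
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 1)
    stop("severity must be a single number in [0, 1]", call. = FALSE)
  if (severity == 0) return(image)
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  mask <- fov_mask(h, w, image$center, image$radius)
  out <- with_seed(seed, switch(kind,
    defocus_blur = gaussian_blur(px, 3 * severity),
    motion_blur = motion_blur(px, 1L + round(14 * severity),
                              stats::runif(1, 0, pi)),
    gaussian_noise = px + matrix(stats::rnorm(h * w, 0, 30 * severity), h, w),
    contrast_compression = {
      mu <- mean(px[mask])
      mu + (px - mu) * (1 - 0.8 * severity)
    },
    mixed = {
      sv <- severity * stats::runif(3, 0.5, 1)
      y <- gaussian_blur(px, 3 * sv[1L])
      y <- y + matrix(stats::rnorm(h * w, 0, 30 * sv[2L]), h, w)
      mu <- mean(y[mask])
      mu + (y - mu) * (1 - 0.8 * sv[3L])
    }))
  out <- pmin(pmax(out, 0), 255)
  out[!mask] <- px[!mask]
  fov_image(out, image$center, image$radius)
}

#' Generate a synthetic quality dataset
#'
#' Full factorial design: `n_phantoms` textured phantoms (different seeds),
#' each degraded at every severity with a distortion family assigned round-
#' robin (one family per phantom, so each phantom contributes one coherent
#' severity ladder). Pseudo-MOS emulates an 8-rater subjective study: the
#' true quality is `5 - 4 * severity`, each simulated rater adds Gaussian
#' noise, and the recorded MOS is the rater mean (SD 0.25), clipped to
#' \[1, 5\]. Ladders whose simulated rater SD exceeds `max_rater_std` can
#' optionally be discarded, mirroring screening of unreliable subjective
#' scores.
#'
#' @param n_phantoms Number of base phantoms (>= 1).
#' @param severities Numeric vector of severities in \[0, 1\]
#'   (default `seq(0, 1, 0.25)`).
#' @param kinds Distortion families cycled across phantoms.
#' @param seed Integer master seed; every phantom, rater, and distortion
#'   seed derives from it.
#' @param out_dir If non-NULL, PNG images and a `manifest.csv` are written
#'   there (created if needed); otherwise the dataset stays in memory.
#' @param size Phantom raster side (default 256).
#' @param rater_sd Per-rater noise SD (default `0.25 * sqrt(8)`, so the
#'   8-rater mean has SD 0.25).
#' @param max_rater_std If finite, rows whose simulated rater SD exceeds it
#'   are dropped (default `Inf`: keep everything).
#' @return List of class `"ceiqa_dataset"`: `manifest` (data frame with
#'   `id`, `image_path` (NA when in memory), `phantom`, `kind`, `severity`,
#'   `mos_true`, `mos`, `rater_std`) and `images` (list of [fov_image()]s,
#'   aligned with the manifest).
#' @export
generate_dataset <- function(n_phantoms, severities = seq(0, 1, by = 0.25),
                             kinds = c("defocus_blur", "motion_blur",
                                       "gaussian_noise",
                                       "contrast_compression", "mixed"),
                             seed = 1L, out_dir = NULL, size = 256L,
                             rater_sd = 0.25 * sqrt(8),
                             max_rater_std = Inf) {
  stopifnot(n_phantoms >= 1L, length(severities) >= 1L,
            all(severities >= 0 & severities <= 1))
  rows <- list(); images <- list(); idx <- 0L
  for (ph in seq_len(n_phantoms)) {
    kind <- kinds[(ph - 1L) %% length(kinds) + 1L]
    base <- generate_phantom(size = size, seed = seed * 1000L + ph)
    for (sv in severities) {
      idx <- idx + 1L
      dseed <- (seed * 100003L + ph * 101L + round(100 * sv)) %%
        .Machine$integer.max
      img <- apply_distortion(base, kind, sv, seed = dseed)
      raters <- with_seed(dseed + 7L,
                          pmin(pmax(5 - 4 * sv + stats::rnorm(8, 0, rater_sd),
                                    1), 5))
      rows[[idx]] <- data.frame(
        id = sprintf("ph%03d_%s_s%03d", ph, kind, round(100 * sv)),
        image_path = NA_character_, phantom = ph, kind = kind,
        severity = sv, mos_true = 5 - 4 * sv,
        mos = mean(raters), rater_std = stats::sd(raters),
        stringsAsFactors = FALSE)
      images[[idx]] <- img
    }
  }
  manifest <- do.call(rbind, rows)
  keep <- manifest$rater_std <= max_rater_std
  manifest <- manifest[keep, , drop = FALSE]
  images <- images[keep]
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    for (i in seq_along(images)) {
      p <- file.path(out_dir, paste0(manifest$id[i], ".png"))
      png::writePNG(images[[i]]$pixels / 255, p)
      manifest$image_path[i] <- p
    }
    utils::write.csv(manifest[, setdiff(names(manifest), "image")],
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, images = images, seed = seed,
                 out_dir = out_dir), class = "ceiqa_dataset")
}

#' @export
print.ceiqa_dataset <- function(x, ...) {
  cat(sprintf("Synthetic quality dataset: %d images, %d phantoms, seed %d\n",
              nrow(x$manifest), length(unique(x$manifest$phantom)), x$seed))
  cat("  kinds:", paste(unique(x$manifest$kind), collapse = ", "), "\n")
  cat("  severities:", paste(sort(unique(x$manifest$severity)),
                             collapse = ", "), "\n")
  if (!is.null(x$out_dir)) cat("  written to:", x$out_dir, "\n")
  invisible(x)
}

#' Manifest of a synthetic dataset with in-memory images attached
#'
#' Returns the dataset's manifest with an `image` list column holding the
#' in-memory [fov_image()]s, ready for [extract_batch()] without touching
#' the filesystem.
#'
#' @param dataset A [generate_dataset()] result.
#' @return Data frame with metadata columns plus an `image` list column.
#' @export
dataset_manifest <- function(dataset) {
  m <- dataset$manifest
  m$image <- dataset$images
  m
}
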