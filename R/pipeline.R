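# From raw circular-field-of-view raster to the 444-dimensional descriptor:
# inscribed-square crop, three-scale pyramid, per-scale DE-LBP and WB-LTP
# blocks, plus batch extraction over a manifest and feature-table I/O.

#' Circular field-of-view image
#'
#' Wraps an intensity matrix together with the geometry of its circular
#' effective region (fiber-bundle endoscopes image a disk surrounded by
#' black pixels). When center/radius are omitted, the largest centered
#' circle is assumed.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\].
#' @param center Length-2 numeric `(row, col)` of the circle center;
#'   default the raster center.
#' @param radius Circle radius in pixels; default `min(dim)/2`.
#' @return An object of class `"fov_image"`.
#' @export
fov_image <- function(pixels, center = NULL, radius = NULL) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  if (is.null(radius)) radius <- min(h, w) / 2
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (center[1L] - radius < 0.5 - 1e-9 || center[1L] + radius > h + 0.5 + 1e-9 ||
      center[2L] - radius < 0.5 - 1e-9 || center[2L] + radius > w + 0.5 + 1e-9)
    stop("circle does not fit inside the raster", call. = FALSE)
  structure(list(pixels = pixels, center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "fov_image")
}

#' @export
print.fov_image <- function(x, ...) {
  cat(sprintf("fov_image: %d x %d raster, circle center (%.1f, %.1f), radius %.1f\n",
              nrow(x$pixels), ncol(x$pixels), x$center[1L], x$center[2L], x$radius))
  invisible(x)
}

as_fov_image <- function(x) {
  if (inherits(x, "fov_image")) x else fov_image(as_gray_matrix(x))
}

# Multi-channel arrays (H x W x C) are averaged to one channel.
as_gray_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    return(matrix(rowMeans(matrix(x, d[1L] * d[2L], d[3L])), d[1L], d[2L]))
  }
  stop("cannot interpret input as a grayscale image", call. = FALSE)
}

#' Crop the axis-aligned square inscribed in the valid circle
#'
#' The black annulus outside the circular field of view would contaminate
#' texture statistics, so only the largest axis-aligned square inside the
#' circle is analyzed: side `floor(radius * sqrt(2))`, centered on the
#' circle center. Every returned pixel lies inside the circle.
#'
#' @param image An [fov_image()] (or a plain matrix, in which case the
#'   largest centered circle is assumed).
#' @param min_side Smallest usable crop side (default 3, one full 3x3
#'   neighborhood); smaller circles raise an error.
#' @return Numeric matrix (the cropped square).
#' @examples
#' img <- fov_image(matrix(0, 512, 512))
#' dim(crop_inscribed_square(img)) # 362 x 362
#' @export
crop_inscribed_square <- function(image, min_side = 3L) {
  image <- as_fov_image(image)
  side <- floor(image$radius * sqrt(2))
  if (side < min_side)
    stop(sprintf("circle radius %.1f gives a %d-pixel crop, below the minimum %d",
                 image$radius, side, min_side), call. = FALSE)
  r0 <- round(image$center[1L] - side / 2 + 0.5)
  c0 <- round(image$center[2L] - side / 2 + 0.5)
  image$pixels[r0:(r0 + side - 1L), c0:(c0 + side - 1L), drop = FALSE]
}

#' Halve an image by 2x2 mean pooling
#'
#' Each output pixel is the mean of a disjoint 2x2 block, so dimensions
#' floor-halve and a trailing odd row/column is dropped. Mean pooling
#' low-passes before decimation, avoiding aliasing without parameters.
#'
#' @param img Numeric matrix with both dimensions >= 2.
#' @return Numeric matrix of dimension `floor(dim/2)`.
#' @export
downsample <- function(img) {
  h <- nrow(img) %/% 2L; w <- ncol(img) %/% 2L
  if (h < 1L || w < 1L)
    stop("image too small to downsample", call. = FALSE)
  i <- seq_len(h) * 2L; j <- seq_len(w) * 2L
  (img[i - 1L, j - 1L, drop = FALSE] + img[i - 1L, j, drop = FALSE] +
     img[i, j - 1L, drop = FALSE] + img[i, j, drop = FALSE]) / 4
}

#' Extract the multi-scale perceptual feature vector of one image
#'
#' The full descriptor pipeline: inscribed-square crop, +1 intensity offset
#' (applied once, globally, so every relative-contrast ratio and DE center
#' is bounded away from zero), adaptive Weber threshold `t` computed from
#' the original-scale DE map, then for each scale `s` (downsampling `s`
#' times): DE map, pattern-code map, their joint histogram (`M x N`,
#' flattened code-major), WB-LTP channels at threshold `t / 2^s`, the three
#' channel histograms, and the three channel entropies.
#'
#' @param image An [fov_image()] or plain matrix/array in \[0, 255\].
#' @param config A [ceiqa_config()].
#' @return Named numeric vector of length `feature_length(config)` with
#'   attributes `fingerprint` and `threshold` (the scale-0 Weber threshold).
#' @export
ceiqa_features <- function(image, config = ceiqa_config()) {
  crop <- crop_inscribed_square(image,
                                min_side = 2L * ceiling(config$R) + 1L)
  img <- crop + 1            # one global offset; see weber_threshold()
  de0 <- de_map(img, config$P, config$R)
  thr <- weber_threshold(de0, config$n_scales)
  out <- numeric(0)
  for (s in seq_len(config$n_scales) - 1L) {
    if (s > 0L) img <- downsample(img)
    de <- if (s == 0L) de0 else de_map(img, config$P, config$R)
    lbp <- lbp_map(img, config$P, config$R)
    H <- joint_de_lbp_histogram(lbp, de, config$M, config$N)
    ch <- wb_ltp(img, thr$t_s[s + 1L], config$P, config$R)
    top <- 2^config$P - 1
    out <- c(out, attr(H, "flat"),
             channel_histogram(ch$up, config$n_bins, c(0, top)),
             channel_histogram(ch$low, config$n_bins, c(0, top)),
             channel_histogram(ch$magnitude, config$n_bins,
                               c(0, top * sqrt(2))),
             pattern_entropy(ch$up), pattern_entropy(ch$low),
             pattern_entropy(ch$magnitude))
  }
  if (any(!is.finite(out)))
    stop("internal error: non-finite feature values", call. = FALSE)
  names(out) <- feature_names(config)
  structure(out, fingerprint = config_fingerprint(config), threshold = thr$t)
}

#' Read a grayscale raster image
#'
#' PNG, TIFF, and JPEG are supported (8-bit; multi-channel images are
#' averaged to one channel). Intensities are returned on the \[0, 255\]
#' scale regardless of the on-disk encoding.
#'
#' @param path Image file path.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG images", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
  as_gray_matrix(px) * 255
}

#' Batch feature extraction over a dataset manifest
#'
#' Processes every row of a manifest (CSV with columns `image_path` and
#' optionally `mos` and `split`), extracting one feature vector per image.
#' Unreadable images are recorded as failures and skipped; the run
#' continues, and only an entirely failed batch is an error.
#'
#' @param manifest Data frame or path to a manifest CSV. A column of
#'   in-memory images (`image`, a list of matrices or [fov_image()]s) may
#'   stand in for `image_path`.
#' @param config A [ceiqa_config()].
#' @return Data frame: `image_path` (or `id`), optional `mos`, and one
#'   column per feature; attributes `fingerprint`, `config`, and `failures`
#'   (data frame of failed paths and error messages).
#' @export
extract_batch <- function(manifest, config = ceiqa_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(is.data.frame(manifest))
  has_mem <- !is.null(manifest[["image"]])
  if (!has_mem && is.null(manifest$image_path))
    stop("manifest needs an 'image_path' (or in-memory 'image') column",
         call. = FALSE)
  n <- nrow(manifest)
  feats <- vector("list", n)
  fail <- character(n)
  for (i in seq_len(n)) {
    feats[[i]] <- tryCatch({
      img <- if (has_mem) manifest[["image"]][[i]]
             else read_gray_image(manifest$image_path[i])
      ceiqa_features(img, config)
    }, error = function(e) {
      fail[i] <<- conditionMessage(e)
      NULL
    })
  }
  ok <- !vapply(feats, is.null, logical(1L))
  if (!any(ok)) stop("all manifest rows failed feature extraction",
                     call. = FALSE)
  X <- do.call(rbind, feats[ok])
  id <- if (has_mem) {
    if (!is.null(manifest$id)) manifest$id[ok] else which(ok)
  } else manifest$image_path[ok]
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  if (!is.null(manifest$mos)) out$mos <- manifest$mos[ok]
  out <- cbind(out, as.data.frame(X))
  failures <- data.frame(
    id = if (has_mem) which(!ok) else manifest$image_path[!ok],
    error = fail[!ok], stringsAsFactors = FALSE)
  structure(out, fingerprint = config_fingerprint(config),
            config = config, failures = failures)
}

#' Read a dataset manifest CSV
#'
#' @param path CSV with header; comment lines start with `#`.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a feature table
#'
#' CSV with a provenance header (`# ceiqa <version>; fingerprint; seed`)
#' followed by one row per image: identifier, optional `mos`, and every
#' feature column named after the layout ([feature_names()]).
#'
#' @param features Feature table from [extract_batch()].
#' @param path Output CSV path.
#' @param seed Optional seed to record in the provenance header.
#' @return `path`, invisibly (`write_feature_table`); the feature table
#'   with its `fingerprint` attribute restored (`read_feature_table`).
#' @export
write_feature_table <- function(features, path, seed = NA) {
  fp <- attr(features, "fingerprint")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ceiqa %s; fingerprint=%s; seed=%s",
                     as.character(utils::packageVersion("ceiqa")),
                     if (is.null(fp)) "unknown" else fp,
                     as.character(seed)), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such feature table: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  fp <- if (grepl("fingerprint=", header))
    sub(";.*$", "", sub("^.*fingerprint=", "", header)) else NULL
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  structure(out, fingerprint = fp)
}

#' Numeric feature matrix of a feature table
#'
#' Drops the metadata columns (`id`, `mos`, `split`) and returns the
#' feature columns as a numeric matrix, one image per row.
#'
#' @param features Feature table from [extract_batch()] or
#'   [read_feature_table()].
#' @return Numeric matrix.
#' @export
feature_matrix <- function(features) {
  meta <- intersect(c("id", "mos", "split"), names(features))
  as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
}
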