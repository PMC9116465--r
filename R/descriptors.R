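# Per-pixel perceptual descriptors: differential excitation, rotation-
# invariant uniform LBP, their joint histogram, and the Weber-thresholded
# local ternary pattern. All maps are computed only where the full circular
# neighborhood exists (no padding), so outputs shrink by ceiling(R) on each
# side relative to the input raster.

# Interior view of `img` shifted so that element (i,j) is the neighbor of
# interior pixel (i,j) at continuous offset (dr, dc). Bilinear interpolation
# for non-integer offsets; offsets within 1e-6 of a grid point snap to it.
neighbor_matrix <- function(img, dr, dc, Rc) {
  h <- nrow(img); w <- ncol(img)
  rows <- (1L + Rc):(h - Rc); cols <- (1L + Rc):(w - Rc)
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  if (fr < 1e-6) fr <- 0 else if (fr > 1 - 1e-6) { fr <- 0; r0 <- r0 + 1L }
  if (fc < 1e-6) fc <- 0 else if (fc > 1 - 1e-6) { fc <- 0; c0 <- c0 + 1L }
  g <- function(ro, co) img[rows + ro, cols + co, drop = FALSE]
  if (fr == 0 && fc == 0) return(g(r0, c0))
  (1 - fr) * (1 - fc) * g(r0, c0)     + (1 - fr) * fc * g(r0, c0 + 1L) +
    fr     * (1 - fc) * g(r0 + 1L, c0) + fr       * fc * g(r0 + 1L, c0 + 1L)
}

# Circular sampling offsets (row, col) for P points at radius R, in circular
# order. For the canonical R = 1, P = 8 the 8 grid neighbors are used exactly.
neighbor_offsets <- function(P, R) {
  a <- 2 * pi * (seq_len(P) - 1L) / P
  if (P == 8L && R == 1) {           # the 8 grid neighbors, no interpolation
    dr <- round(-sqrt(2) * sin(a)); dc <- round(sqrt(2) * cos(a))
  } else {
    dr <- -R * sin(a); dc <- R * cos(a)
    dr[abs(dr) < 1e-9] <- 0; dc[abs(dc) < 1e-9] <- 0
  }
  list(dr = dr, dc = dc, Rc = as.integer(ceiling(R - 1e-9)))
}

check_gray <- function(img, P, R) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  Rc <- as.integer(ceiling(R - 1e-9))
  if (nrow(img) < 2L * Rc + 1L || ncol(img) < 2L * Rc + 1L)
    stop(sprintf("image (%d x %d) smaller than the %d x %d neighborhood",
                 nrow(img), ncol(img), 2L * Rc + 1L, 2L * Rc + 1L),
         call. = FALSE)
  if (any(!is.finite(img)))
    stop("image contains non-finite intensities", call. = FALSE)
  invisible(Rc)
}

#' Differential-excitation map
#'
#' Per-pixel perceptual contrast after Weber's law: for center intensity
#' `x_c` with `P` circular neighbors `x_i`,
#' `DE = arctan( sum_i (x_i - x_c) / x_c )`.
#' The arctangent compresses the relative-change ratio into
#' \[-pi/2, pi/2\] and guards against numerical blow-up for small centers.
#' Distorted (blurred) images concentrate DE mass near zero; structured
#' images spread it out, which is what makes the DE distribution a quality
#' feature.
#'
#' The map is computed on the intensities as given. Centers equal to zero are
#' rejected: callers are expected to apply a +1 offset to 8-bit images first
#' (the feature pipeline does this once, globally).
#'
#' @param img Numeric matrix of intensities (all finite, centers non-zero).
#' @param P Number of circular neighbors (default 8).
#' @param R Neighborhood radius in pixels (default 1).
#' @return Numeric matrix of DE values in \[-pi/2, pi/2\], shrunk by
#'   `ceiling(R)` on each side.
#' @examples
#' m <- matrix(100, 5, 5); m[3, 3] <- 100; m[c(2, 4), 2:4] <- 110
#' de_map(m)
#' @export
de_map <- function(img, P = 8L, R = 1) {
  Rc <- check_gray(img, P, R)
  off <- neighbor_offsets(P, R)
  ctr <- img[(1L + off$Rc):(nrow(img) - off$Rc),
             (1L + off$Rc):(ncol(img) - off$Rc), drop = FALSE]
  if (any(ctr == 0))
    stop(paste("zero-valued center pixel: apply the +1 intensity offset",
               "before computing differential excitation"), call. = FALSE)
  acc <- matrix(0, nrow(ctr), ncol(ctr))
  for (i in seq_len(P))
    acc <- acc + neighbor_matrix(img, off$dr[i], off$dc[i], off$Rc) - ctr
  atan(acc / ctr)
}

# Shared LBP/LTP plumbing: list of P neighbor matrices plus the center.
neighbor_stack <- function(img, P, R) {
  Rc <- check_gray(img, P, R)
  off <- neighbor_offsets(P, R)
  ctr <- img[(1L + off$Rc):(nrow(img) - off$Rc),
             (1L + off$Rc):(ncol(img) - off$Rc), drop = FALSE]
  nb <- lapply(seq_len(P), function(i)
    neighbor_matrix(img, off$dr[i], off$dc[i], off$Rc))
  list(center = ctr, neighbors = nb)
}

#' Rotation-invariant uniform local binary pattern map
#'
#' Each pixel's `P` circular neighbors are thresholded at the center
#' (`g_i - g_c >= 0` gives bit 1). A pattern is *uniform* when its circular
#' bit string has at most two 0/1 transitions; uniform patterns are coded by
#' their number of set bits (0..P) and all remaining patterns share the
#' single code `P + 1`. Codes are invariant to image rotation and to adding
#' a constant to all intensities.
#'
#' @inheritParams de_map
#' @return Integer matrix of codes in `{0, ..., P+1}`, shrunk by
#'   `ceiling(R)` per side.
#' @examples
#' lbp_map(matrix(1:25, 5, 5))
#' @export
lbp_map <- function(img, P = 8L, R = 1) {
  st <- neighbor_stack(img, P, R)
  bits <- lapply(st$neighbors, function(nb) (nb - st$center) >= 0)
  s <- Reduce(`+`, bits)
  u <- abs(bits[[P]] - bits[[1L]])
  for (i in 2:P) u <- u + abs(bits[[i]] - bits[[i - 1L]])
  codes <- ifelse(u <= 2, s, P + 1L)
  storage.mode(codes) <- "integer"
  codes
}

#' Joint histogram of pattern codes and differential excitation
#'
#' Two-dimensional relative-frequency histogram `H(m, n)`: the fraction of
#' pixels whose pattern code is `m` and whose absolute DE value falls in the
#' `n`-th of `N` equal-width bins over \[0, pi/2\]. Capturing the two maps
#' jointly preserves which contrast levels each micro-structure occurs at.
#'
#' @param lbp Integer matrix of pattern codes (from [lbp_map()]).
#' @param de Numeric matrix of DE values (from [de_map()]), same shape.
#' @param M Number of code bins (codes `0..M-1`; default 10).
#' @param N Number of absolute-DE bins (default 10).
#' @return `M x N` matrix of relative frequencies summing to 1, with an
#'   attribute `"flat"` holding the row-major (code-major) flattened vector.
#' @export
joint_de_lbp_histogram <- function(lbp, de, M = 10L, N = 10L) {
  if (!identical(dim(lbp), dim(de)))
    stop("pattern map and DE map have different shapes", call. = FALSE)
  if (any(lbp < 0L) || any(lbp >= M))
    stop("pattern codes outside 0..M-1", call. = FALSE)
  a <- abs(de)
  n_bin <- pmin(floor(a / (pi / 2) * N), N - 1L) + 1L
  H <- matrix(0, M, N)
  counts <- table(factor(as.vector(lbp), levels = 0:(M - 1L)),
                  factor(as.vector(n_bin), levels = 1:N))
  H[] <- as.numeric(counts) / length(lbp)
  structure(H, flat = as.vector(t(H)))
}

#' Adaptive Weber threshold
#'
#' The relative-contrast threshold used by the Weber-thresholded ternary
#' pattern: `t = tan(mean(|DE|)) / 256`, i.e. the image's average variation
#' intensity mapped back from the arctangent scale to a delta-I/I ratio.
#' Neighborhood contrasts above `t` count as perceptually high variation.
#' Per-scale thresholds halve with each downsampling step: `t_s = t / 2^s`.
#'
#' @param de Numeric matrix of DE values.
#' @param n_scales Number of pyramid scales for which to report `t_s`.
#' @return List with `t` (scalar) and `t_s` (numeric vector, one per scale).
#' @examples
#' weber_threshold(matrix(pi / 4, 3, 3))$t  # tan(pi/4)/256 = 1/256
#' @export
weber_threshold <- function(de, n_scales = 3L) {
  if (length(de) == 0L) stop("empty DE map", call. = FALSE)
  t0 <- tan(mean(abs(de))) / 256
  list(t = t0, t_s = t0 / 2^(seq_len(n_scales) - 1L))
}

#' Weber-thresholded local ternary pattern channels
#'
#' A ternary code per neighbor based on *relative* contrast, the Weber form:
#' +1 when `(g_i - g_c)/g_c > t`, -1 when `(g_i - g_c)/g_c < -t`, else 0
#' (ties at exactly `t` count as 0). The ternary map is split into two
#' binary channels - `up` weights the +1 codes by powers of two, `low` the
#' -1 codes - plus a magnitude channel `sqrt(up^2 + low^2)`.
#'
#' Callers must apply the +1 intensity offset beforehand (the pipeline
#' does); a zero center would make the ratio test unstable.
#'
#' @inheritParams de_map
#' @param t Non-negative relative-contrast threshold, typically from
#'   [weber_threshold()].
#' @return List of matrices `up`, `low` (integers in `[0, 2^P - 1]`) and
#'   `magnitude`, each shrunk by `ceiling(R)` per side.
#' @export
wb_ltp <- function(img, t, P = 8L, R = 1) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("threshold t must be a single non-negative number", call. = FALSE)
  st <- neighbor_stack(img, P, R)
  if (any(st$center == 0))
    stop(paste("zero-valued center pixel: apply the +1 intensity offset",
               "before the relative-contrast test"), call. = FALSE)
  up <- matrix(0, nrow(st$center), ncol(st$center)); low <- up
  for (i in seq_len(P)) {
    ratio <- (st$neighbors[[i]] - st$center) / st$center
    up  <- up  + 2^(i - 1L) * (ratio > t)
    low <- low + 2^(i - 1L) * (ratio < -t)
  }
  list(up = up, low = low, magnitude = sqrt(up^2 + low^2))
}

#' Equal-width relative-frequency histogram of a channel
#'
#' Bins channel values into `n_bins` equal-width bins over a fixed range
#' (defaulting to the observed `[0, max]`-free convention of the caller:
#' the full theoretical channel range must be passed explicitly for
#' comparability across images). Values at the upper edge fall in the last
#' bin; entries sum to 1.
#'
#' @param channel Numeric matrix or vector.
#' @param n_bins Number of bins (>= 2; default 15).
#' @param range Length-2 numeric range the bins span (default `c(0, 255)`).
#' @return Numeric vector of `n_bins` relative frequencies.
#' @export
channel_histogram <- function(channel, n_bins = 15L, range = c(0, 255)) {
  if (length(channel) == 0L) stop("empty channel", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  x <- pmin(pmax(as.vector(channel), range[1L]), range[2L])
  idx <- pmin(floor((x - range[1L]) / diff(range) * n_bins), n_bins - 1L) + 1L
  tabulate(idx, nbins = n_bins) / length(x)
}

#' Shannon entropy of an integer-valued channel
#'
#' `E = -sum_i p_i log2 p_i` over the discrete levels of the channel, with
#' `0 log 0 = 0`. Values are rounded to the nearest integer first (the up
#' and low ternary channels are already integral; the magnitude channel is
#' discretized this way). For 8-bit channels `E` lies in \[0, 8\] and is 0
#' exactly when the channel is constant.
#'
#' @param channel Numeric matrix or vector of (near-)integer values.
#' @return Scalar entropy in bits.
#' @examples
#' pattern_entropy(matrix(c(0, 0, 7, 7), 2, 2)) # 1 bit
#' @export
pattern_entropy <- function(channel) {
  if (length(channel) == 0L) stop("empty channel", call. = FALSE)
  v <- round(as.vector(channel))
  p <- tabulate(match(v, unique(v))) / length(v)
  -sum(p * log2(p))
}
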