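# Independent brute-force oracles: literal per-pixel / per-element
# transcriptions of the descriptor and statistic definitions, kept free of
# any package internals so they can arbitrate.

# Circular neighbor offsets (row, col) used by both oracles, in the same
# circular order as the implementation's convention for R = 1, P = 8:
# E, NE, N, NW, W, SW, S, SE (grid neighbors).
oracle_offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                       c(0, -1), c(1, -1), c(1, 0), c(1, 1))

# Differential excitation of one pixel: arctan(sum(x_i - x_c) / x_c).
oracle_de_pixel <- function(img, r, c) {
  xc <- img[r, c]
  s <- 0
  for (o in oracle_offsets) s <- s + img[r + o[1], c + o[2]] - xc
  atan(s / xc)
}

# Rotation-invariant uniform LBP code of one pixel, Eqs-as-written:
# bits S(g_i - g_c), transition count u, sum-of-bits if u <= 2 else P+1.
oracle_lbp_pixel <- function(img, r, c) {
  gc <- img[r, c]
  bits <- vapply(oracle_offsets,
                 function(o) as.integer(img[r + o[1], c + o[2]] - gc >= 0),
                 integer(1))
  u <- abs(bits[8] - bits[1]) +
    sum(abs(bits[2:8] - bits[1:7]))
  if (u <= 2) sum(bits) else 9L
}

# Joint DE-LBP histogram by literal double-loop counting.
oracle_joint_hist <- function(img, M = 10, N = 10) {
  h <- nrow(img); w <- ncol(img)
  H <- matrix(0, M, N)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    m <- oracle_lbp_pixel(img, r, c)
    de <- abs(oracle_de_pixel(img, r, c))
    n <- min(floor(de / (pi / 2) * N), N - 1) + 1
    H[m + 1, n] <- H[m + 1, n] + 1
  }
  H / sum(H)
}

# Spearman correlation via explicit midranks and the Pearson formula.
oracle_srocc <- function(a, b) {
  # midrank = average position of equal values in the sorted order
  midrank <- function(x)
    vapply(x, function(v) mean(which(sort(x) == v)), numeric(1))
  ra <- midrank(a); rb <- midrank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Corrected resampled paired t decision, transcribed term by term.
oracle_corrected_t <- function(a, b, n_train, n_test, alpha = 0.05) {
  d <- a - b
  K <- length(d)
  t_stat <- mean(d) / sqrt(var(d) * (1 / K + n_test / n_train))
  p <- 2 * (1 - pt(abs(t_stat), K - 1))
  if (p >= alpha) 0L else if (t_stat > 0) 1L else -1L
}

# Random 8-bit test image with no zero pixels (DE-safe).
rand_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(1:255, h * w, replace = TRUE), h, w)
}
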