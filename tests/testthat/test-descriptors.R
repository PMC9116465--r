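# Per-pixel descriptors: differential excitation, LBP^riu2, joint
# histogram, Weber threshold, WB-LTP channels, histograms, entropy.

test_that("differential excitation matches hand-evaluated cases", {
  # constant image: every neighborhood difference is 0
  expect_true(all(de_map(matrix(100, 6, 6)) == 0))
  # center 100, all 8 neighbors 110: arctan(8 * 10 / 100)
  m <- matrix(110, 3, 3); m[2, 2] <- 100
  expect_equal(de_map(m)[1, 1], atan(80 / 100))
  # scalar oracle agreement on a random image
  img <- rand_image(9, 9, seed = 11)
  de <- de_map(img)
  for (r in 2:8) for (c in 2:8)
    expect_equal(de[r - 1, c - 1], oracle_de_pixel(img, r, c))
})

test_that("differential excitation is bounded and scale-invariant", {
  for (s in 1:5) {
    img <- rand_image(16, 16, seed = s)
    de <- de_map(img)
    expect_true(all(de >= -pi / 2 & de <= pi / 2))
    expect_equal(de_map(img * 2), de)           # multiplicative invariance
    expect_equal(de_map(img * 0.37), de, tolerance = 1e-12)
  }
})

test_that("differential excitation rejects zero centers", {
  m <- matrix(100, 5, 5); m[3, 3] <- 0
  expect_error(de_map(m), "offset")
})

test_that("LBP^riu2 codes match the literal per-pixel oracle", {
  # constant image: all bits 1, u = 0, code = sum of bits = 8
  expect_true(all(lbp_map(matrix(7, 5, 5)) == 8L))
  # one neighbor below center, seven above: uniform with 7 set bits
  m <- matrix(110, 3, 3); m[2, 2] <- 100; m[1, 1] <- 90
  expect_identical(lbp_map(m)[1, 1], 7L)
  for (s in 1:5) {
    img <- rand_image(8, 8, seed = 100 + s)
    codes <- lbp_map(img)
    expect_true(all(codes %in% 0:9))
    for (r in 2:7) for (c in 2:7)
      expect_identical(codes[r - 1, c - 1], oracle_lbp_pixel(img, r, c))
  }
})

test_that("LBP is invariant to intensity shifts and 90-degree rotation", {
  for (s in 1:5) {
    img <- rand_image(14, 14, seed = 200 + s)
    codes <- lbp_map(img)
    expect_identical(lbp_map(img + 31L), codes)
    rot <- t(img)[ncol(img):1, ]
    expect_identical(tabulate(lbp_map(rot) + 1L, 10L),
                     tabulate(codes + 1L, 10L))
  }
})

test_that("LBP rejects images smaller than the neighborhood", {
  expect_error(lbp_map(matrix(1, 2, 5)), "smaller")
})

test_that("joint DE-LBP histogram counts like the double-loop oracle", {
  # constant image: all mass at code 8, lowest-|DE| bin
  H <- joint_de_lbp_histogram(lbp_map(matrix(50, 5, 5)),
                              de_map(matrix(50, 5, 5)))
  expect_equal(H[9, 1], 1)
  expect_equal(sum(H), 1)
  # all 512 interior-pixel configurations of a two-letter 5x5 image,
  # embedded in a fixed random border, plus random binary images
  set.seed(5)
  border <- matrix(sample(c(100, 200), 25, replace = TRUE), 5, 5)
  for (code in 0:511) {
    img <- border
    img[2:4, 2:4] <- ifelse(bitwAnd(code, 2^(0:8)) > 0, 200, 100)
    H <- joint_de_lbp_histogram(lbp_map(img), de_map(img))
    expect_equal(unclass(H), oracle_joint_hist(img),
                 ignore_attr = TRUE)
  }
  for (s in 1:20) {
    set.seed(600 + s)
    img <- matrix(sample(c(100, 200), 25, replace = TRUE), 5, 5)
    H <- joint_de_lbp_histogram(lbp_map(img), de_map(img))
    expect_equal(unclass(H), oracle_joint_hist(img), ignore_attr = TRUE)
    expect_equal(sum(H), 1)
  }
  # random-integer image against the oracle
  img <- rand_image(8, 8, seed = 77)
  expect_equal(unclass(joint_de_lbp_histogram(lbp_map(img), de_map(img))),
               oracle_joint_hist(img), ignore_attr = TRUE)
})

test_that("joint histogram flattening is code-major and shapes must align", {
  img <- rand_image(8, 8, seed = 3)
  H <- joint_de_lbp_histogram(lbp_map(img), de_map(img))
  expect_equal(attr(H, "flat"), as.vector(t(unclass(H))))
  expect_error(joint_de_lbp_histogram(lbp_map(img), de_map(img)[1:3, 1:3]),
               "shapes")
})

test_that("the Weber threshold follows tan(mean |DE|)/256 and halves per scale", {
  expect_equal(weber_threshold(matrix(0, 4, 4))$t, 0)
  expect_equal(weber_threshold(matrix(pi / 4, 4, 4))$t, 1 / 256)
  # mean over absolute values: mixed-sign map with |DE| = pi/4 everywhere
  m <- matrix(c(pi / 4, -pi / 4), 4, 4)
  expect_equal(weber_threshold(m)$t, 1 / 256)
  expect_equal(weber_threshold(matrix(0.1, 2, 2), n_scales = 3)$t_s,
               tan(0.1) / 256 / c(1, 2, 4))
})

test_that("WB-LTP channels degenerate correctly at extreme thresholds", {
  img <- rand_image(10, 10, seed = 9)
  # huge threshold: no relative contrast exceeds it
  ch <- wb_ltp(img, t = 1e6)
  expect_true(all(ch$up == 0) && all(ch$low == 0) && all(ch$magnitude == 0))
  expect_equal(pattern_entropy(ch$up), 0)
  # t = 0 on an image with no tied neighbors: up bits are the strict
  # positive-difference pattern, and up/low partition the non-tied pairs
  set.seed(10)
  img2 <- matrix(sample(1:255, 64), 8, 8)
  ch0 <- wb_ltp(img2, t = 0)
  up_oracle <- low_oracle <- matrix(0, 6, 6)
  for (r in 2:7) for (c in 2:7) for (i in 1:8) {
    o <- oracle_offsets[[i]]
    d <- img2[r + o[1], c + o[2]] - img2[r, c]
    if (d > 0) up_oracle[r - 1, c - 1] <- up_oracle[r - 1, c - 1] + 2^(i - 1)
    if (d < 0) low_oracle[r - 1, c - 1] <- low_oracle[r - 1, c - 1] + 2^(i - 1)
  }
  expect_equal(ch0$up, up_oracle)
  expect_equal(ch0$low, low_oracle)
  expect_true(all(ch0$up + ch0$low == 255))     # full partition, no ties
})

test_that("WB-LTP magnitude dominates both channels pointwise", {
  for (s in 1:5) {
    img <- rand_image(12, 12, seed = 300 + s)
    ch <- wb_ltp(img, t = 0.02)
    expect_equal(ch$magnitude, sqrt(ch$up^2 + ch$low^2))
    expect_true(all(ch$magnitude >= ch$up))
    expect_true(all(ch$magnitude >= ch$low))
  }
})

test_that("WB-LTP validates its threshold and ties count as zero codes", {
  img <- rand_image(6, 6, seed = 2)
  expect_error(wb_ltp(img, t = -0.1), "non-negative")
  # exact tie |delta|/g_c == t goes to the zero code
  m <- matrix(100, 3, 3); m[1, ] <- 110   # ratio exactly 0.1 for 3 neighbors
  ch <- wb_ltp(m, t = 0.1)
  expect_equal(ch$up[1, 1], 0)
})

test_that("channel histograms are normalized equal-width counts", {
  expect_equal(channel_histogram(matrix(0, 4, 4), 15)[1], 1)
  expect_equal(sum(channel_histogram(matrix(0, 4, 4), 15)), 1)
  # 16-value toy channel vs direct counting
  v <- c(0, 5, 16, 17, 33, 34, 50, 100, 128, 200, 254, 255, 255, 17, 90, 64)
  h <- channel_histogram(v, n_bins = 16, range = c(0, 256))
  direct <- tabulate(floor(v / 16) + 1, 16) / 16
  expect_equal(h, direct)
  expect_error(channel_histogram(numeric(0)), "empty")
  expect_error(channel_histogram(1:5, n_bins = 1), "at least 2")
})

test_that("pattern entropy hits its closed-form anchors and bounds", {
  expect_equal(pattern_entropy(matrix(42, 5, 5)), 0)
  expect_equal(pattern_entropy(c(0, 0, 7, 7)), 1)
  expect_equal(pattern_entropy(0:255), 8)
  for (s in 1:10) {
    set.seed(400 + s)
    ch <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    e <- pattern_entropy(ch)
    expect_true(e >= 0 && e <= 8)
    expect_true(e > 0)            # 100 draws from 256 levels: never constant
  }
})
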