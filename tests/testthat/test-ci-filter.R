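test_that("filter_params defaults match the 95% normal band", {
  p <- filter_params()
  expect_equal(p$tile, c(8L, 8L))
  expect_equal(p$confidence, 0.95)
  expect_equal(p$z, 1.96)
  expect_equal(p$replacement, "mean")
  expect_equal(p$band_n, "nominal")

  # explicit confidence derives z from the two-sided normal quantile
  expect_equal(filter_params(confidence = 0.95)$z, qnorm(0.975))
  expect_equal(filter_params(confidence = 0.99)$z, qnorm(0.995))
  # Student-t option widens the band for the same confidence
  pt <- filter_params(tile = c(2, 2), confidence = 0.95, use_t = TRUE)
  expect_equal(pt$z, qt(0.975, df = 3))
  expect_gt(pt$z, qnorm(0.975))

  expect_error(filter_params(confidence = 1.2), "confidence")
  expect_error(filter_params(z = -1), "positive")
})

test_that("ci_band is the symmetric normal-theory band for the tile mean", {
  p <- filter_params(tile = c(2, 2))
  b <- ci_band(list(mean = 0.6, n_actual = 4), sqrt(0.03), p)
  expect_equal(unname(b), 0.6 + c(-1, 1) * 1.96 * sqrt(0.03) / 2,
               tolerance = 1e-12)
  expect_equal(unname(b), c(0.430259, 0.769741), tolerance = 1e-6)

  # degenerate band at sigma = 0
  expect_equal(unname(ci_band(list(mean = 0.37, n_actual = 9), 0, p)),
               c(0.37, 0.37))

  # nominal n = 52 gives the half-width 1.96/sqrt(52) * sigma
  p52 <- filter_params(tile = c(4, 13))
  b <- ci_band(list(mean = 0.5, n_actual = 52), 1, p52)
  expect_equal(unname(b[2] - b[1]) / 2, 1.96 / sqrt(52), tolerance = 1e-12)
  expect_equal(round(1.96 / sqrt(52), 4), 0.2718)

  # band_n = "actual" uses the ragged tile's true count
  pa <- filter_params(tile = c(4, 13), band_n = "actual")
  ba <- ci_band(list(mean = 0.5, n_actual = 20), 1, pa)
  expect_equal(unname(ba[2] - ba[1]) / 2, 1.96 / sqrt(20), tolerance = 1e-12)
})

test_that("apply_ci_filter reproduces the hand-evaluated band rule", {
  # constant image is a fixed point: the degenerate band rejects every
  # pixel but the replacement mean equals the constant
  cst <- matrix(0.42, 6, 6)
  expect_identical(apply_ci_filter(cst, filter_params(tile = c(3, 3))), cst)

  img <- matrix(c(0.5, 0.5, 0.5, 0.9), 2, 2)
  out <- apply_ci_filter(img, filter_params(tile = c(2, 2)))
  expect_equal(out, matrix(c(0.5, 0.5, 0.5, 0.6), 2, 2), tolerance = 1e-12)

  # the same case under the min/max replacement alternatives
  expect_equal(apply_ci_filter(img, filter_params(tile = c(2, 2),
                                                  replacement = "min"))[2, 2], 0.5)
  expect_equal(apply_ci_filter(img, filter_params(tile = c(2, 2),
                                                  replacement = "max"))[2, 2], 0.9)
})

test_that("apply_ci_filter equals the per-pixel brute-force oracle exactly", {
  set.seed(31)
  for (i in 1:100) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    img <- random_image(nr, nc)
    ia <- sample(1:9, 1); ja <- sample(1:9, 1)
    z <- runif(1, 0.3, 3)
    repl <- sample(c("mean", "min", "max"), 1)
    bn <- sample(c("nominal", "actual"), 1)
    p <- filter_params(tile = c(ia, ja), z = z, replacement = repl,
                       band_n = bn)
    expect_identical(apply_ci_filter(img, p),
                     oracle_ci_filter(img, ia, ja, z, repl, bn))
  }
})

test_that("filter output pixels stay inside their own tile's range", {
  set.seed(32)
  for (i in 1:20) {
    img <- random_image(sample(8:24, 1), sample(8:24, 1))
    p <- filter_params(tile = c(sample(2:6, 1), sample(2:6, 1)),
                       z = runif(1, 0.3, 3),
                       replacement = sample(c("mean", "min", "max"), 1))
    out <- apply_ci_filter(img, p)
    g <- make_tile_grid(nrow(img), ncol(img), p$tile)
    for (k in seq_len(nrow(g))) {
      rows <- g$row[k]:(g$row[k] + g$height[k] - 1)
      cols <- g$col[k]:(g$col[k] + g$width[k] - 1)
      tin <- img[rows, cols]; tout <- out[rows, cols]
      expect_true(all(tout >= min(tin) - 1e-15 & tout <= max(tin) + 1e-15))
      # provenance: each output pixel is its input value or the tile's
      # replacement statistic, nothing else
      rv <- switch(p$replacement, mean = mean(tin), min = min(tin),
                   max = max(tin))
      expect_true(all(tout == tin | abs(tout - rv) < 1e-15))
    }
  }
})

test_that("filtering is deterministic and single-pass", {
  set.seed(33)
  img <- random_image(20, 17)
  p <- filter_params(tile = c(5, 4))
  expect_identical(apply_ci_filter(img, p), apply_ci_filter(img, p))

  # statistics come from the original image: filtering the filtered
  # image with replacement-fed-back statistics would differ, so check
  # the reported sigma is the input's, not the output's
  d <- apply_ci_filter(img, p, details = TRUE)
  expect_equal(d$sigma, global_std(img))
  expect_equal(d$np, nrow(make_tile_grid(20, 17, c(5, 4))))
  expect_equal(d$retention, mean(d$kept))
})

test_that("retention on an i.i.d. Gaussian flat field matches normal theory", {
  # kept fraction ~ 2*Phi(z/sqrt(n)) - 1 for n = 52, z = 1.96
  set.seed(34)
  img <- clip01(matrix(rnorm(260 * 260, 0.5, 0.08), 260, 260))
  d <- apply_ci_filter(img, filter_params(tile = c(4, 13)), details = TRUE)
  expect_lt(abs(d$retention - (2 * pnorm(1.96 / sqrt(52)) - 1)), 0.01)
})
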