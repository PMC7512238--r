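test_that("gray_histogram follows the stated bin convention", {
  h <- gray_histogram(matrix(0, 3, 3))
  expect_equal(h$counts[1], 9)
  expect_equal(sum(h$counts), 9)

  img <- matrix(c(rep(0.25, 50), rep(0.75, 50)), 10, 10)
  h <- gray_histogram(img)
  expect_equal(h$counts[64 + 1], 50)   # floor(0.25 * 256) = 64
  expect_equal(h$counts[192 + 1], 50)  # floor(0.75 * 256) = 192
  expect_equal(sum(h$counts), 100)

  # intensity 1.0 lands in the closed last bin
  h <- gray_histogram(matrix(1, 2, 2), nbins = 16)
  expect_equal(h$counts[16], 4)
  expect_error(gray_histogram(matrix(0.5, 2, 2), nbins = 1), "nbins")
})

test_that("between_class_variance matches hand computation and the oracle", {
  # two equal spikes at intensities 0.2 and 0.8 (nbins = 10, bins 2 and
  # 8), split between them: w0*w1*(mu0 - mu1)^2 = 0.25 * 0.36
  counts <- integer(10); counts[c(3, 9)] <- 50
  h <- structure(list(counts = counts, nbins = 10L),
                 class = "gray_histogram")
  expect_equal(between_class_variance(h, 4), 0.09, tolerance = 1e-12)

  # one populated class: zero separability everywhere
  counts1 <- integer(10); counts1[4] <- 7
  h1 <- structure(list(counts = counts1, nbins = 10L),
                  class = "gray_histogram")
  for (t in c(0, 4, 8)) expect_equal(between_class_variance(h1, t), 0)

  expect_error(between_class_variance(h, c(4, 4)), "strictly increasing")
  expect_error(
    between_class_variance(structure(list(counts = integer(10), nbins = 10L),
                                     class = "gray_histogram"), 4),
    "empty")

  set.seed(41)
  for (i in 1:25) {
    h <- random_hist(sample(8:32, 1))
    m <- sample(1:3, 1)
    ts <- sort(sample(0:(h$nbins - 2), m))
    expect_equal(between_class_variance(h, ts),
                 oracle_bcv(h$counts, ts), tolerance = 1e-12)
  }
})

test_that("between- and within-class variance decompose the total variance", {
  set.seed(42)
  for (i in 1:25) {
    h <- random_hist(sample(8:32, 1))
    m <- sample(1:3, 1)
    ts <- sort(sample(0:(h$nbins - 2), m))
    p <- h$counts / sum(h$counts)
    vals <- (seq_along(h$counts) - 1) / h$nbins
    total <- sum(p * (vals - sum(p * vals))^2)
    expect_lt(abs(between_class_variance(h, ts) +
                  oracle_wcv(h$counts, ts) - total), 1e-10)
    expect_lte(between_class_variance(h, ts), total + 1e-12)
  }
})

test_that("otsu_thresholds attains the enumerated optimum with the
           lexicographic tie-break", {
  # two equal spikes, m = 1: every threshold between the spikes ties;
  # the smallest (the left spike's bin) is returned
  img <- matrix(c(rep(0.25, 50), rep(0.75, 50)), 10, 10)
  expect_equal(otsu_thresholds(gray_histogram(img), m = 1), 64L)

  # single spike: all candidates tie at zero, so threshold 0
  expect_equal(otsu_thresholds(gray_histogram(matrix(0.5, 5, 5), 16), m = 1),
               0L)

  # four equal spikes, m = 3: the separating thresholds
  counts <- integer(8); counts[c(2, 4, 6, 8)] <- 10
  h4 <- structure(list(counts = counts, nbins = 8L),
                  class = "gray_histogram")
  expect_equal(otsu_thresholds(h4, m = 3), c(1L, 3L, 5L))
  ref <- oracle_enum_otsu(counts, 3)
  expect_equal(otsu_thresholds(h4, m = 3), as.integer(ref$thresholds))

  expect_error(otsu_thresholds(h4, m = 0), "m")
  expect_error(otsu_thresholds(h4, m = 8), "m")
})

test_that("otsu_thresholds is optimal on random histograms", {
  set.seed(43)
  for (i in 1:40) {
    h <- random_hist(sample(8:32, 1))
    m <- sample(1:3, 1)
    got <- otsu_thresholds(h, m = m)
    ref <- oracle_enum_otsu(h$counts, m)
    expect_equal(between_class_variance(h, got), ref$value,
                 tolerance = 1e-12)
    expect_equal(got, as.integer(ref$thresholds))
  }
})

test_that("otsu_thresholds is invariant to scaling all counts", {
  set.seed(44)
  for (i in 1:10) {
    h <- random_hist(24)
    h2 <- h; h2$counts <- h$counts * 7L
    m <- sample(1:3, 1)
    expect_identical(otsu_thresholds(h, m), otsu_thresholds(h2, m))
  }
})

test_that("m = 1 maximizes the two-class criterion w0*w1*(mu0 - mu1)^2", {
  set.seed(45)
  for (i in 1:10) {
    h <- random_hist(20)
    t1 <- otsu_thresholds(h, 1)
    p <- h$counts / sum(h$counts)
    vals <- (seq_along(h$counts) - 1) / h$nbins
    idx <- seq_along(p) - 1
    crit <- vapply(0:(h$nbins - 2), function(t) {
      w0 <- sum(p[idx <= t]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) return(0)
      mu0 <- sum((p * vals)[idx <= t]) / w0
      mu1 <- sum((p * vals)[idx > t]) / w1
      w0 * w1 * (mu0 - mu1)^2
    }, 0)
    expect_equal(crit[t1 + 1], max(crit), tolerance = 1e-12)
  }
})

test_that("apply_thresholds labels by the strict-greater bin rule", {
  # m thresholds give m + 1 intensity-ordered classes
  img <- matrix(seq(0, 1, length.out = 16), 4, 4)
  lab <- apply_thresholds(img, c(3L, 7L, 11L), nbins = 16)
  expect_equal(sort(unique(as.vector(lab))), 0:3)

  # a pixel in the threshold bin stays in the lower class; the next bin
  # starts the upper class
  nb <- 16
  img2 <- matrix(c(5 / nb, 6 / nb), 1, 2)
  lab2 <- apply_thresholds(img2, 5L, nbins = nb)
  expect_equal(as.vector(lab2), c(0L, 1L))

  # thresholds from a clean 4-level phantom reproduce its truth exactly
  ph <- make_phantom(96, 96, n_classes = 4, seed = 5)
  ts <- otsu_thresholds(gray_histogram(ph$image), m = 3)
  expect_identical(apply_thresholds(ph$image, ts), ph$labels)
})
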