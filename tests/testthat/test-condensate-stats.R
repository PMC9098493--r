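# Shape and partition statistics: analytic values, algebraic identities,
# scale invariance.

make_cset <- function(P, N = 2, background = N, areas = rep(10, length(P)),
                      nucleus_area = 1000, context = "in_vivo") {
  regions <- data.frame(label = seq_along(P), area = areas,
                        perimeter = rep(12, length(P)), mean_intensity = P,
                        centroid_row = seq_along(P), centroid_col = seq_along(P))
  condensate_set(regions, nucleus_area = nucleus_area,
                 nucleus_mean_intensity = N,
                 background_mean_intensity = background, context = context)
}

empty_cset <- function(background = 100, N = 100)
  condensate_set(data.frame(label = integer(), area = numeric(),
                            perimeter = numeric(), mean_intensity = numeric(),
                            centroid_row = numeric(),
                            centroid_col = numeric()),
                 nucleus_area = 1000, nucleus_mean_intensity = N,
                 background_mean_intensity = background)

test_that("circularity matches analytic shapes and decreases with elongation", {
  for (r in c(1, 5, 20, 137))
    expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(1, 4), pi / 4)
  # fixed area, growing perimeter (a x b rectangles of area 36)
  sides <- list(c(6, 6), c(9, 4), c(12, 3), c(18, 2))
  circs <- vapply(sides, function(s)
    circularity(s[1] * s[2], 2 * (s[1] + s[2])), numeric(1))
  expect_true(all(diff(circs) < 0))
  expect_error(circularity(10, 0), class = "domain_error")

  # rasterized disk with the package's own perimeter estimator
  d <- disk_mask_oracle(c(51, 51), c(26, 26), 20)
  expect_equal(circularity(sum(d), perimeter_crofton(d)), 1, tolerance = 0.1)
})

test_that("Crofton perimeter reproduces independent reference values", {
  # values computed with scikit-image perimeter_crofton (directions = 4)
  ref <- c("10" = 65.198, "20" = 127.714, "50" = 315.262)
  for (r in c(10, 20, 50)) {
    n <- 2 * r + 9
    d <- disk_mask_oracle(c(n, n), c(n %/% 2 + 1, n %/% 2 + 1), r)
    expect_equal(perimeter_crofton(d), unname(ref[as.character(r)]),
                 tolerance = 1e-4)
  }
})

test_that("partition ratios: defaults, direct values, identities, invariance", {
  expect_identical(partition_ratio(empty_cset()), 1)
  expect_identical(partition_ratio_timepoint(empty_cset()), 1)
  expect_equal(partition_ratio(make_cset(500, background = 100)), 5)
  # sum P / (n N): P = [6, 4], n = 2, N = 2 -> 2.5
  expect_equal(partition_ratio_timepoint(make_cset(c(6, 4), N = 2)), 2.5)
  expect_equal(partition_ratio_timepoint(make_cset(rep(7, 4), N = 7)), 1)

  set.seed(21)
  for (i in 1:10) {
    P <- stats::runif(5, 1, 100); N <- stats::runif(1, 1, 50)
    cs <- make_cset(P, N = N)
    # algebraic identity: sum P/(nN) == mean(P/N)
    expect_equal(partition_ratio_timepoint(cs), mean(P / N))
    # common intensity rescaling cancels
    cs2 <- make_cset(P * 13, N = N * 13)
    expect_equal(partition_ratio_timepoint(cs2), partition_ratio_timepoint(cs))
    expect_equal(partition_ratio(cs2), partition_ratio(cs))
  }
  bad <- make_cset(5, N = 2)
  bad$nucleus_mean_intensity <- 0
  expect_error(partition_ratio_timepoint(bad), class = "domain_error")
})

test_that("measured partition ratio matches the truth-mask pixel scan", {
  sc <- test_scene(n = 3, fold = 5, noise_sd = 0)
  img <- generate_condensate_image(sc)$image
  cs <- detect_condensates(img, segment_nucleus(img), context = "in_vitro")
  # in vitro: background is the full-frame mean
  truth <- {
    res <- generate_condensate_image(sc)
    mean(res$image[res$masks$condensate > 0L]) / mean(res$image)
  }
  expect_equal(partition_ratio(cs), truth, tolerance = 0.05)

  csv <- detect_condensates(img, segment_nucleus(img), context = "in_vivo")
  expect_equal(partition_ratio(csv), truth_partition_ratio(sc),
               tolerance = 0.05)
})

test_that("size_fraction: direct values, uniform tail, monotone in threshold", {
  expect_equal(size_fraction(c(0.5, 0.8, 1.2, 0.7)), 0.5)
  expect_equal(size_fraction(c(0.1, 0.75, 0.3)), 0)   # strictly-greater rule
  set.seed(8)
  a <- stats::runif(1000, 0, 1.5)
  expect_equal(size_fraction(a, 0.75), 0.5, tolerance = 0.05)
  thr <- seq(0, 1.5, by = 0.1)
  fr <- vapply(thr, function(t) size_fraction(a, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(size_fraction(numeric()), class = "domain_error")
})

test_that("count_per_area handles pixel and physical units", {
  cs <- make_cset(c(5, 5, 5, 5, 5), nucleus_area = 50)
  expect_equal(count_per_area(cs), 0.1)
  cs$pixel_size <- 0.5                      # um per px -> area in um^2
  expect_equal(count_per_area(cs), 5 / (50 * 0.25))
  expect_equal(count_per_area(empty_cset()), 0)
})

test_that("normalized size series starts at 1 and tracks truth growth", {
  g1 <- list(make_cset(c(5, 5), areas = c(10, 20), nucleus_area = 1000))
  g2 <- list(make_cset(c(5, 5), areas = c(20, 40), nucleus_area = 1000))
  out <- normalized_size_series(c(0, 10), list(g1, g2))
  expect_equal(out$normalized_size, c(1, 2))

  # synthetic truth: areas growing 1x, 2x, 4x (radius sqrt scaling)
  radii <- 4 * sqrt(c(1, 2, 4))
  csets <- lapply(radii, function(r) {
    sc <- test_scene(n = 2, radius = r, noise_sd = 0)
    img <- generate_condensate_image(sc)$image
    list(detect_condensates(img, segment_nucleus(img)))
  })
  out2 <- normalized_size_series(c(0, 5, 10), csets)
  expect_equal(out2$normalized_size, c(1, 2, 4), tolerance = 0.1)

  expect_error(normalized_size_series(1, list(list(empty_cset()))),
               class = "domain_error")
})
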