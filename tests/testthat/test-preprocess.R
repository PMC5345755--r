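test_that("median denoising removes impulses and keeps exact residuals", {
  const <- channel_image(matrix(0.4, 20, 20), "BIOMARKER")
  dn <- denoise(const, 1)
  expect_identical(dn$denoised$pixels, const$pixels)
  expect_true(all(dn$residual == 0))

  px <- matrix(0, 21, 21)
  px[11, 11] <- 0.9
  dn <- denoise(channel_image(px, "BIOMARKER"), 1)
  expect_true(all(dn$denoised$pixels == 0))
  expect_equal(dn$residual[11, 11], 0.9)
  expect_equal(sum(dn$residual != 0), 1L)

  expect_error(denoise(const, 0), ">= 1")
  expect_error(denoise(const, 11), "exceeds")
})

test_that("median filter matches the brute-force sliding-window oracle", {
  set.seed(21)
  for (radius in 1:2) {
    px <- matrix(runif(19 * 17), 19, 17)
    dn <- denoise(channel_image(px, "DAPI"), radius)
    expect_identical(dn$denoised$pixels, oracle_median_filter(px, radius))
  }
})

test_that("denoised + residual reconstructs every input exactly", {
  set.seed(8)
  imgs <- list(
    channel_image(matrix(runif(32 * 32), 32), "BIOMARKER"),
    small_scene(seed = 2)$field$dapi,
    small_scene(seed = 2)$field$biomarker
  )
  for (img in imgs) {
    for (radius in 1:2) {
      dn <- denoise(img, radius)
      expect_identical(reconstruct(dn), img$pixels)
      # the plain residual alone reconstructs to within one ulp; the
      # lsb term carries only sub-ulp rounding remainders
      expect_lt(max(abs(dn$denoised$pixels + dn$residual - img$pixels)),
                2^-50)
      expect_lt(max(abs(dn$residual_lsb)), 2^-50)
    }
  }
})

test_that("region histograms conserve mass and match a direct tally", {
  img <- channel_image(matrix(7 / 255, 20, 20), "BIOMARKER", 8L)
  h <- region_histogram(img, c(3, 3, 10, 10), 256)
  expect_equal(sum(h$counts), 100L)
  expect_equal(h$counts[8], 100L)   # gray level 7 in 0-based bin 7

  px <- matrix(rep(c(0, 1), each = 200), 20, 20)
  h2 <- region_histogram(channel_image(px, "DAPI"), c(1, 1, 20, 20), 2)
  expect_equal(h2$counts, c(200L, 200L))

  set.seed(3)
  px <- matrix(runif(30 * 30), 30, 30)
  img <- channel_image(px, "BIOMARKER")
  rect <- c(5, 7, 12, 9)
  h3 <- region_histogram(img, rect, 16)
  sub <- px[5:16, 7:15]
  direct <- tabulate(pmin(floor(as.vector(sub) * 16) + 1, 16), 16)
  expect_equal(h3$counts, direct)
  expect_equal(sum(h3$counts), length(sub))
  expect_error(region_histogram(img, c(25, 25, 10, 10), 16), "bounds")
})

test_that("background profiles summarize control images", {
  zero <- channel_image(matrix(0, 20, 20), "CONTROL")
  p <- estimate_background(zero)
  expect_equal(c(p$mean_level, p$sd_level, p$percentile_99), c(0, 0, 0))

  const <- channel_image(matrix(0.35, 20, 20), "CONTROL")
  p <- estimate_background(const)
  expect_equal(p$mean_level, 0.35)
  expect_equal(p$sd_level, 0)
  expect_equal(p$percentile_99, 0.35)

  # a control scene with planted artifact blobs and no true signal:
  # the bright tail (99th percentile) sits far above the mean, the
  # configuration that motivates gating instead of thresholding
  scn <- generate_scene(scene_spec(n_nuclei = 0L, n_artifacts = 14L,
                                   seed = 4))
  ctrl <- channel_image(scn$field$biomarker$pixels, "CONTROL")
  p <- estimate_background(ctrl)
  expect_gt(p$percentile_99, p$mean_level + 0.5)
})

test_that("percentile normalization is an identity on full-range input", {
  px <- matrix(seq(0, 1, length.out = 400), 20, 20)
  img <- channel_image(px, "BIOMARKER")
  expect_equal(normalize_channel(img, 0, 100)$pixels, px,
               tolerance = 1e-12)
})

test_that("normalization cancels multiplicative illumination exactly", {
  set.seed(12)
  px <- matrix(runif(28 * 28), 28, 28)
  img <- channel_image(px, "BIOMARKER")
  for (cf in c(0.5, 0.7, 0.93)) {
    scaled <- channel_image(px * cf, "BIOMARKER")
    expect_equal(normalize_channel(scaled)$pixels,
                 normalize_channel(img)$pixels, tolerance = 1e-12)
  }
})

test_that("normalized output hits the requested percentiles", {
  set.seed(13)
  px <- matrix(runif(50 * 50), 50, 50)
  out <- normalize_channel(channel_image(px, "DAPI"), 5, 95)$pixels
  # clipping makes the output quantiles interpolate across the clip
  # boundary; they sit at the endpoints to within interpolation error
  expect_equal(quantile(out, 0.05, names = FALSE), 0, tolerance = 1e-3)
  expect_equal(quantile(out, 0.95, names = FALSE), 1, tolerance = 1e-3)
  expect_equal(mean(out == 0), 0.05, tolerance = 0.01)
  expect_equal(mean(out == 1), 0.05, tolerance = 0.01)
  expect_error(normalize_channel(channel_image(matrix(0.5, 16, 16),
                                               "DAPI")),
               "zero dynamic range.*DAPI")
  expect_error(normalize_channel(channel_image(px, "DAPI"), 60, 40),
               "low_pct")
})
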