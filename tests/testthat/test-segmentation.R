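test_that("clustering a k-valued image returns those values as centroids", {
  vals <- c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95)
  px <- matrix(rep(vals, each = 100), 20, 30)
  cl <- cluster_intensities(channel_image(px, "BIOMARKER"), k = 6)
  expect_equal(cl$centroids, vals)
  expect_true(all(px[cl$label_map == 6] == 0.95))
  for (j in 1:6) expect_true(all(px[cl$label_map == j] == vals[j]))
})

test_that("two-value clustering puts the threshold at the midpoint", {
  px <- matrix(rep(c(0.1, 0.9), 200), 20, 20)
  cl <- cluster_intensities(channel_image(px, "DAPI"), k = 2)
  expect_equal(cl$positive_threshold, 0.5)
  expect_error(cluster_intensities(channel_image(px, "DAPI"), k = 3),
               "distinct")
})

test_that("clustering is deterministic and centroids are ordered", {
  set.seed(31)
  x <- c(runif(150, 0, 0.3), runif(50, 0.7, 1))
  cl1 <- cluster_intensities(x, 4)
  cl2 <- cluster_intensities(x, 4)
  expect_identical(cl1$centroids, cl2$centroids)
  expect_identical(cl1$labels, cl2$labels)
  expect_true(all(diff(cl1$centroids) > 0))
  # every point sits with its nearest centroid (ties to lower index)
  d <- abs(outer(x, cl1$centroids, "-"))
  nearest <- apply(d, 1, which.min)
  expect_equal(cl1$labels, as.integer(nearest))
})

test_that("clustering attains the DP global optimum on random instances", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    k <- sample(2:6, 1)
    x <- if (i %% 2 == 0) {
      runif(n)
    } else {
      pmin(pmax(c(rnorm(ceiling(n / 2), 0.2, 0.05),
                  rnorm(floor(n / 2), 0.8, 0.04)), 0), 1)
    }
    if (length(unique(x)) < k) next
    cl <- cluster_intensities(x, k)
    expect_equal(realized_wcss(x, cl), oracle_kmeans1d_wcss(x, k),
                 tolerance = 1e-9)
  }
})

test_that("DAPI masks capture planted nuclei and reject background", {
  # background-only scene: no nucleus pixels should survive labelling
  bg <- generate_scene(scene_spec(n_nuclei = 0L, n_artifacts = 0L,
                                  seed = 9))
  dd <- denoise(bg$field$dapi, 1)$denoised
  cl <- cluster_intensities(dd, k = 2)
  mask <- dapi_mask(dd, cl, 2)
  expect_equal(length(label_nuclei(mask, 50)), 0L)

  scn <- generate_scene(scene_spec(seed = 10))
  dn <- denoise(normalize_channel(scn$field$dapi), 1)$denoised
  cl <- cluster_intensities(dn, k = 2)
  mask <- dapi_mask(dn, cl, 2)
  planted <- scn$truth$label_map > 0
  expect_gt(sum(mask & planted) / sum(planted), 0.9)   # coverage
  expect_lt(sum(mask & !planted) / sum(!planted), 0.02) # false positives

  # scaling DAPI by 0.7 before normalization leaves the mask unchanged
  dim_dapi <- scn$field$dapi
  dim_dapi$pixels <- dim_dapi$pixels * 0.7
  dn2 <- denoise(normalize_channel(dim_dapi), 1)$denoised
  cl2 <- cluster_intensities(dn2, k = 2)
  expect_equal(dapi_mask(dn2, cl2, 2), mask)

  expect_error(dapi_mask(dn, cl, 1), "2..k")
  expect_error(dapi_mask(dn, cl, 5), "2..k")
})

test_that("nucleus labelling honors connectivity and min_area", {
  mask <- matrix(FALSE, 40, 40)
  mask[3:12, 3:12] <- TRUE
  mask[20:29, 25:34] <- TRUE
  regions <- label_nuclei(mask, min_area = 50)
  expect_length(regions, 2L)
  expect_equal(vapply(regions, `[[`, numeric(1), "area"), c(100, 100))
  expect_equal(regions[[1]]$centroid, c(row = 6.5, col = 6.5))

  small <- matrix(FALSE, 20, 20)
  small[3:10, 3:7] <- TRUE   # area 40
  expect_length(label_nuclei(small, min_area = 50), 0L)
  expect_length(label_nuclei(small, min_area = 40), 1L)

  # diagonal touch merges under 8-connectivity
  diagm <- matrix(FALSE, 16, 16)
  diagm[2:4, 2:4] <- TRUE
  diagm[5:7, 5:7] <- TRUE
  expect_length(label_nuclei(diagm, min_area = 1), 1L)
})

test_that("component labelling matches a flood-fill oracle on random blobs", {
  set.seed(33)
  for (i in 1:10) {
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    regions <- label_nuclei(mask, min_area = 1)
    expect_length(regions, oracle_component_count(mask))
    expect_equal(sum(vapply(regions, `[[`, numeric(1), "area")),
                 sum(mask))
  }
})

test_that("merging takes the pixelwise maximum and dominates biomarker", {
  set.seed(34)
  d <- channel_image(matrix(runif(24 * 24), 24), "DAPI")
  b <- channel_image(matrix(runif(24 * 24), 24), "BIOMARKER")
  m <- merge_dapi_biomarker(d, b)
  expect_equal(m$channel_label, "MERGED")
  expect_identical(m$pixels, pmax(d$pixels, b$pixels))
  expect_true(all(m$pixels >= b$pixels))

  zero_b <- channel_image(matrix(0, 24, 24), "BIOMARKER")
  expect_identical(merge_dapi_biomarker(d, zero_b)$pixels, d$pixels)
  wrong <- channel_image(matrix(0, 20, 20), "BIOMARKER")
  expect_error(merge_dapi_biomarker(d, wrong), "dimensions")
})
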