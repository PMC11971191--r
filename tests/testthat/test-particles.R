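test_that("segmentation counts connected components above threshold", {
  blank <- image_from_pixels(32, 32, integer(0), bg = 100L)
  expect_equal(nrow(segment_particles(blank, threshold = 500)), 0)

  # two disks touching diagonally merge under 8-connectivity ...
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1000L
  m[4:5, 4:5] <- 1000L
  img <- image_grid(m, 1)
  expect_equal(nrow(segment_particles(img, threshold = 500)), 1)
  # ... but stay separate under 4-connectivity
  expect_equal(nrow(segment_particles(img, threshold = 500,
                                      connectivity = 4L)), 2)
})

test_that("segmentation recovers generator ground truth exactly", {
  spec <- histology_image_spec(width_px = 320, height_px = 320,
                               n_diffuse = 25, n_perikaryal = 3,
                               pixel_size_um = 0.25)
  sim <- simulate_histology_image(spec, seed = 21)
  parts <- segment_particles(sim$image, threshold = 10000)
  expect_equal(nrow(parts), nrow(sim$ground_truth))
  # areas match ground truth to within one pixel-area
  pa <- 0.25^2
  got <- sort(parts$area_um2)
  want <- sort(sim$ground_truth$area_um2)
  expect_true(all(abs(got - want) <= pa + 1e-12))
  counts <- classify_particles(parts)
  expect_equal(counts$diffuse_count, 25)
  expect_equal(counts$perikaryal_count, 3)
  expect_equal(counts$other_count, 0)
})

test_that("class counts are invariant to image resolution", {
  for (px in c(0.5, 0.25)) {
    spec <- histology_image_spec(width_px = round(96 / px),
                                 height_px = round(96 / px),
                                 n_diffuse = 12, n_perikaryal = 2,
                                 pixel_size_um = px)
    sim <- simulate_histology_image(spec, seed = 31)
    counts <- classify_particles(segment_particles(sim$image, 10000))
    expect_equal(counts$diffuse_count, 12)
    expect_equal(counts$perikaryal_count, 2)
  }
})

test_that("Otsu thresholding separates clean foreground and rejects flat images", {
  sim <- simulate_histology_image(
    histology_image_spec(width_px = 160, height_px = 160, n_diffuse = 10,
                         n_perikaryal = 2),
    seed = 7
  )
  counts <- classify_particles(segment_particles(sim$image, "otsu"))
  expect_equal(counts$diffuse_count, 10)
  expect_equal(counts$perikaryal_count, 2)
  flat <- image_from_pixels(16, 16, integer(0), bg = 42L)
  expect_error(segment_particles(flat, "otsu"), "threshold")
})

test_that("particle classification maps areas to closed windows", {
  parts <- data.frame(area_um2 = c(2.0, 50.0, 0.5))
  counts <- classify_particles(parts)
  expect_equal(unlist(counts, use.names = FALSE), c(1L, 1L, 1L))
  # boundary values are inclusive
  edge <- classify_particles(data.frame(area_um2 = c(1.5, 3.5, 12.5, 100)))
  expect_equal(edge$diffuse_count, 2)
  expect_equal(edge$perikaryal_count, 2)
  empty <- classify_particles(data.frame(area_um2 = numeric(0)))
  expect_equal(unlist(empty, use.names = FALSE), c(0L, 0L, 0L))
  expect_error(size_windows(c(1, 20), c(12.5, 100)), "overlap")
})

test_that("sample means average per-image counts", {
  counts <- data.frame(diffuse_count = c(30, 40, 50),
                       perikaryal_count = c(1, 2, 3),
                       other_count = c(0, 0, 0))
  m <- sample_mean_counts(counts)
  expect_equal(m$diffuse_mean, 40)
  expect_equal(m$perikaryal_mean, 2)
  expect_equal(m$n_images, 3)
  one <- sample_mean_counts(counts[2, ])
  expect_equal(one$diffuse_mean, 40)
  expect_error(sample_mean_counts(list()), "at least one")
})

test_that("GFAP burden is the stained-area percentage with guarded domain", {
  expect_equal(gfap_burden(25, 100), 25)
  expect_equal(gfap_burden(0, 100), 0)
  expect_equal(gfap_burden(100, 100), 100)
  expect_error(gfap_burden(1, 0), "> 0")
  expect_error(gfap_burden(101, 100), "exceed")
  set.seed(8)
  roi <- runif(200, 1, 1e6)
  stain <- roi * runif(200)
  b <- gfap_burden(stain, roi)
  expect_equal(b, 100 * stain / roi)
  expect_true(all(b >= 0 & b <= 100))
})
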