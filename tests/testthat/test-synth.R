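# Synthetic shape population, nucleus rendering and cohort generation.

test_that("group shape parameters carry the published group means", {
  af <- sample_shape_params("AF")
  lf <- sample_shape_params("LF")
  expect_equal(unname(af$ha_means["HA2"]), 0.905)
  expect_equal(unname(lf$ha_means["HA2"]), 0.872)
  expect_equal(unname(af$ha_means["HA0"]), 2.851)
  # SEM -> per-sperm SD conversion at the study's 100 sperm per ram
  expect_equal(unname(af$ha_sds["HA2"]), 0.006 * sqrt(100))
  expect_true(all(af$ha_sds >= 0))
  expect_error(sample_shape_params("XX"), "unknown group")
})

test_that("zero spread yields identical sampled amplitudes", {
  p <- sample_shape_params("AF")
  p$ha_sds[] <- 0
  p$phase_jitter <- 0
  hs1 <- draw_nucleus(p, rotation = 0)
  hs2 <- draw_nucleus(p, rotation = 1.3)
  expect_equal(hs1$amplitudes, hs2$amplitudes, tolerance = 1e-12)
})

test_that("centroid anchoring preserves the drawn amplitudes and zeroes the centroid", {
  p <- sample_shape_params("AF")
  set.seed(3)
  hs <- draw_nucleus(p, rotation = 0.4)
  # dense polygon as independent centroid oracle (its own discretization
  # error is ~(2 pi / n)^2)
  poly <- harmonic_polygon(hs, n = 65536, closed = FALSE)
  a_ctr <- abs(spermshape:::polygon_centroid(poly$x, poly$y))
  expect_lt(max(a_ctr), 2e-9)
  # HA0 and HA2..HA5 equal the draw (only HA1 is constrained)
  p0 <- sample_shape_params("AF")
  p0$ha_sds[] <- 0
  p0$phase_jitter <- 0
  hs0 <- draw_nucleus(p0, rotation = 0)
  expect_equal(unname(hs0$amplitudes[c(1, 3:6)]),
               unname(p0$ha_means[c(1, 3:6)]), tolerance = 1e-10)
})

test_that("rendering a pure circle gives the analytic disk area and is deterministic", {
  hs <- harmonic_set(2.85, numeric(5), numeric(5))
  rn <- render_nucleus(hs, pixel_size_um = 0.1, rng_seed = 42)
  area <- sum(rn$mask) * 0.1^2
  expect_lt(abs(area - pi * 2.85^2) / (pi * 2.85^2), 0.02)
  rn2 <- render_nucleus(hs, pixel_size_um = 0.1, rng_seed = 42)
  expect_identical(rn$image, rn2$image)
  rn3 <- render_nucleus(hs, pixel_size_um = 0.1, rng_seed = 43)
  expect_false(identical(rn$image, rn3$image))
})

test_that("mask area is invariant to pose rotation within 1%", {
  hs <- fixture_nucleus(7)
  areas <- vapply(seq(0, 2 * pi, length.out = 9)[-9], function(a) {
    sum(render_nucleus(hs, pose = list(rotation = a), pixel_size_um = 0.11,
                       rng_seed = 1)$mask)
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
})

test_that("rendering rejects coarse grids and out-of-bounds poses", {
  hs <- harmonic_set(1, numeric(5), numeric(5))
  expect_error(render_nucleus(hs, pixel_size_um = 0.2), "20 px")
  hs2 <- harmonic_set(2.85, numeric(5), numeric(5))
  expect_error(render_nucleus(hs2, pose = list(center_px = c(5, 5)),
                              pixel_size_um = 0.1), "bounds")
})

test_that("generate_field honours counts, disjointness and overlap flags", {
  p <- sample_shape_params("AF")
  f0 <- generate_field(0, p, field_px = 64, rng_seed = 1)
  expect_equal(nrow(f0$truth), 0)
  expect_true(all(f0$labels == 0))

  f <- generate_field(12, p, overlap_fraction = 0, pixel_size_um = 0.11,
                      rng_seed = 2)
  expect_equal(nrow(f$truth), 12)
  expect_false(any(f$truth$overlap_flag))
  # non-overlap by construction: every nucleus keeps its full mask area
  tab <- table(factor(f$labels[f$labels > 0], levels = 1:12))
  expect_true(all(tab > 1500 * (0.11 / 0.11)^2 * 0.5))

  fo <- generate_field(30, p, overlap_fraction = 0.2, pixel_size_um = 0.11,
                       rng_seed = 3)
  expect_gte(sum(fo$truth$overlap_flag), 6 - 1)
  f2 <- generate_field(12, p, overlap_fraction = 0, pixel_size_um = 0.11,
                       rng_seed = 2)
  expect_identical(f$fluorescence, f2$fluorescence)
})

test_that("cohorts have the requested design and are seed-deterministic", {
  coh <- generate_cohort(5, 2, 8, rng_seed = 9)
  expect_equal(nrow(coh$truth), 56)
  expect_equal(nrow(coh$fertility), 7)
  expect_equal(sum(coh$fertility$group == "AF"), 5)
  expect_equal(length(coh$traces), 56)
  expect_true(all(coh$fertility$conception_rate >= 0 &
                    coh$fertility$conception_rate <= 100))
  coh2 <- generate_cohort(5, 2, 8, rng_seed = 9)
  expect_equal(coh$truth, coh2$truth)
  expect_equal(coh$fertility, coh2$fertility)
})

test_that("harmonic analysis of true cohort outlines recovers the sampled amplitudes", {
  # unrasterized ground truth, dense vertices: recovery to < 1e-6 um
  coh <- generate_cohort(2, 1, 3, n_vertices = 8192, rng_seed = 4)
  ht <- fha_table(coh$traces, M = 128, K = 5)
  for (k in 0:5) {
    expect_lt(max(abs(ht[[paste0("HA", k)]] -
                        coh$truth[[paste0("HA", k)]])), 1e-6)
  }
})

test_that("mean rendered nucleus area matches the published scale within 15%", {
  p <- sample_shape_params("AF")
  set.seed(21)
  areas <- replicate(12, {
    hs <- draw_nucleus(p)
    sum(render_nucleus(hs, pixel_size_um = 0.11)$mask) * 0.11^2
  })
  expect_lt(abs(mean(areas) - 28.257) / 28.257, 0.15)
})
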