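# Laplacian-of-Gaussian segmentation, object QC and perimeter tracing.

test_that("LoG thresholding handles blank and offset images", {
  blank <- matrix(0, 64, 64)
  expect_false(any(log_threshold(blank, 0.11)))
  # constants are killed by the Laplacian: a uniform offset changes nothing
  hs <- fixture_nucleus(2)
  rn <- render_nucleus(hs, pixel_size_um = 0.11, rng_seed = 5)
  m1 <- log_threshold(rn$image, 0.11)
  m2 <- log_threshold(rn$image + 50, 0.11)
  expect_identical(m1, m2)
})

test_that("a rendered nucleus segments to one component with IoU >= 0.9", {
  hs <- fixture_nucleus(3)
  p <- sample_shape_params("AF")
  rn <- render_nucleus(hs, pixel_size_um = 0.11,
                       intensity_mean = p$intensity_mean,
                       intensity_sd = p$texture_sd, rng_seed = 8)
  mask <- log_threshold(rn$image, 0.11)
  objs <- extract_objects(mask, 0.11)
  acc <- Filter(function(o) o$rejected_reason == "none", objs)
  expect_length(acc, 1)
  iou <- sum(mask & rn$mask) / sum(mask | rn$mask)
  expect_gte(iou, 0.9)
})

test_that("object QC assigns border, size and overlap rejection reasons", {
  # two disjoint disks are both accepted
  m <- matrix(FALSE, 80, 160)
  rc <- expand.grid(r = 1:80, c = 1:160)
  d1 <- matrix(sqrt((rc$r - 40)^2 + (rc$c - 40)^2) <= 17, 80, 160)
  d2 <- matrix(sqrt((rc$r - 40)^2 + (rc$c - 120)^2) <= 17, 80, 160)
  objs <- extract_objects(d1 | d2, 0.15)
  expect_length(objs, 2)
  expect_true(all(vapply(objs, `[[`, character(1),
                         "rejected_reason") == "none"))

  # a disk clipped by the image edge is rejected as border
  d3 <- matrix(sqrt((rc$r - 2)^2 + (rc$c - 40)^2) <= 17, 80, 160)
  objs3 <- extract_objects(d3, 0.15)
  expect_equal(objs3[[1]]$rejected_reason, "border")

  # two fused disks (dumbbell) have low solidity -> overlap
  d4 <- matrix(sqrt((rc$r - 40)^2 + (rc$c - 60)^2) <= 17, 80, 160) |
    matrix(sqrt((rc$r - 40)^2 + (rc$c - 94)^2) <= 17, 80, 160)
  objs4 <- extract_objects(d4, 0.15, max_area_um2 = 100)
  expect_equal(objs4[[1]]$rejected_reason, "overlap")
  # brute-force hull check: solidity of two touching disks ~ 2*pi/(pi + 4)
  expect_lt(objs4[[1]]$solidity, 0.92)

  # tiny speck -> too_small
  d5 <- matrix(FALSE, 80, 160); d5[40:42, 40:42] <- TRUE
  expect_equal(extract_objects(d5, 0.15)[[1]]$rejected_reason, "too_small")
})

test_that("perimeter tracing follows boundary pixels with the square and disk geometry", {
  # 10x10 filled square: 36 boundary pixels, chain length 36 px
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  obj <- list(pixels = which(m, arr.ind = TRUE), label = 1L)
  tr <- trace_perimeter(obj, 1, image_nrow = 14)
  expect_equal(length(tr$x) - 1L, 36L)
  expect_equal(perimeter_length(tr), 36)
  # closed convention: first and last vertex identical
  expect_equal(tr$x[1], tr$x[length(tr$x)])
  expect_equal(tr$y[1], tr$y[length(tr$y)])
  # all vertices lie on boundary pixels of the object
  on_obj <- m[cbind(14 - round(tr$y - 0.5), round(tr$x + 0.5))]
  expect_true(all(on_obj))

  # digitized disk radius 30 px: corrected trace length within 3% of 2 pi r
  dm <- disk_mask(30)
  objd <- list(pixels = which(dm, arr.ind = TRUE), label = 1L)
  trd <- trace_perimeter(objd, 1, image_nrow = nrow(dm))
  expect_lt(abs(perimeter_length(trd, corner_correction = TRUE) -
                  2 * pi * 30) / (2 * pi * 30), 0.03)

  # too small an object cannot be traced
  sm <- matrix(FALSE, 6, 6); sm[3, 3] <- TRUE; sm[3, 4] <- TRUE
  objs <- list(pixels = which(sm, arr.ind = TRUE), label = 1L)
  expect_error(trace_perimeter(objs, 1, image_nrow = 6),
               "interrupted_perimeter")
})

test_that("overlay QC paints traces, honours manual rejection and flags bounds", {
  phase <- matrix(100, 60, 60)
  r0 <- overlay_qc(phase, list(), 0.2)
  expect_identical(r0$overlay, phase)
  tr1 <- circle_trace(2, center = c(6, 6)); tr1$label <- 1L
  tr2 <- circle_trace(2, center = c(11.5, 6)); tr2$label <- 3L
  res <- overlay_qc(phase, list(tr1, tr2), 0.2, manual_reject = 3L)
  expect_false(identical(res$overlay, phase))
  expect_equal(res$table$reason[res$table$label == 3], "manual")
  expect_false(3 %in% res$table$label[res$table$accepted])
  troob <- circle_trace(2, center = c(12, 6)); troob$label <- 9L
  res2 <- overlay_qc(phase, list(troob), 0.2)
  expect_equal(res2$table$reason, "out_of_bounds")
})

test_that("segmentation recall and precision reach 0.95 on a clean synthetic field", {
  p <- sample_shape_params("AF")
  fld <- generate_field(25, p, overlap_fraction = 0, pixel_size_um = 0.11,
                        rng_seed = 12)
  seg <- segment_field(fld$fluorescence, 0.11)
  ctrs <- t(vapply(seg$traces, function(tr)
    spermshape:::polygon_centroid(tr$x, tr$y) / 0.11, numeric(2)))
  truth <- as.matrix(fld$truth[, c("centroid_x_px", "centroid_y_px")])
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(sqrt((ctrs[, 1] - truth[i, 1])^2 +
               (ctrs[, 2] - truth[i, 2])^2) < 10)
  }, logical(1))
  matched <- vapply(seq_len(nrow(ctrs)), function(j) {
    any(sqrt((truth[, 1] - ctrs[j, 1])^2 +
               (truth[, 2] - ctrs[j, 2])^2) < 10)
  }, logical(1))
  expect_gte(mean(hit), 0.95)       # recall
  expect_gte(mean(matched), 0.95)   # precision
})

test_that("QC on an overlapping field rejects about the planted overlap count", {
  p <- sample_shape_params("AF")
  fld <- generate_field(20, p, overlap_fraction = 0.1, pixel_size_um = 0.11,
                        rng_seed = 31)
  seg <- segment_field(fld$fluorescence, 0.11)
  n_overlap_truth <- sum(fld$truth$overlap_flag)
  n_rejected <- sum(vapply(seg$objects, `[[`, character(1),
                           "rejected_reason") != "none")
  # fused pairs appear as one rejected object; each planted overlap removes
  # about two truth nuclei but at least one object must be rejected
  expect_gte(n_rejected, max(1, round(n_overlap_truth / 2) - 1))
  expect_lt(length(seg$traces), 20)
})

test_that("downstream amplitudes are stable across rendering rotations", {
  hs <- fixture_nucleus(5)
  p <- sample_shape_params("AF")
  amps <- vapply(seq(0, 2 * pi, length.out = 9)[-9], function(a) {
    rn <- render_nucleus(hs, pose = list(rotation = a),
                         pixel_size_um = 0.11,
                         intensity_mean = p$intensity_mean,
                         intensity_sd = p$texture_sd, rng_seed = 17)
    seg <- segment_field(rn$image, 0.11, median_area_um2 = 28)
    expect_length(seg$traces, 1)
    fit_fourier(to_polar(seg$traces[[1]]), 5)$amplitudes[c(1, 3)]
  }, numeric(2))
  expect_lt(sd(amps[1, ]) / mean(amps[1, ]), 0.02)  # HA0
  expect_lt(sd(amps[2, ]) / mean(amps[2, ]), 0.02)  # HA2
})
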