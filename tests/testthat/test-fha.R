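# Polar transform, trigonometric regression and harmonic summaries.

test_that("polar transform reproduces analytic radii", {
  tr <- circle_trace(1, n = 360)
  pp <- to_polar(tr, M = 64)
  expect_lt(max(abs(pp$r - 1)), 1e-3)
  expect_false(pp$non_star)

  # translation invariance
  tr2 <- translate_trace(circle_trace(1, n = 360), 5.3, -2.1)
  pp2 <- to_polar(tr2, M = 64)
  expect_equal(pp$r, pp2$r, tolerance = 1e-9)

  # ellipse radii on the axes
  te <- ellipse_trace(4.5, 2, n = 1440)
  ppe <- to_polar(te, M = 4)
  expect_lt(abs(ppe$r[1] - 4.5), 1e-3)
  expect_lt(abs(ppe$r[2] - 2), 1e-3)
})

test_that("the fit of a circle is a pure constant", {
  fit <- fit_fourier(to_polar(circle_trace(2.85, n = 720), M = 128), K = 5)
  expect_equal(unname(fit$amplitudes["HA0"]), 2.85, tolerance = 1e-4)
  expect_lt(max(fit$amplitudes[-1]), 1e-3)
})

test_that("a centered ellipse has even harmonics only, matching a numerical oracle", {
  te <- ellipse_trace(4.5, 2, n = 4096)
  fit <- fit_fourier(to_polar(te, M = 256), K = 5)
  expect_lt(max(fit$amplitudes[c("HA1", "HA3", "HA5")]), 1e-6)
  expect_gt(fit$amplitudes["HA2"], fit$amplitudes["HA4"])
  expect_gt(fit$amplitudes["HA4"], 0)
  # independent oracle: Fourier integrals of the analytic polar radius
  ak <- function(k) {
    stats::integrate(function(t) ellipse_polar_r(t) * cos(k * t) / pi,
                     0, 2 * pi, rel.tol = 1e-10)$value
  }
  expect_equal(unname(fit$amplitudes["HA0"]), ak(0) / 2, tolerance = 1e-5)
  expect_equal(unname(fit$amplitudes["HA2"]), abs(ak(2)), tolerance = 1e-5)
  expect_equal(unname(fit$amplitudes["HA4"]), abs(ak(4)), tolerance = 1e-5)
})

test_that("least squares equals the DFT on equal-angle samples", {
  set.seed(8)
  hs <- draw_nucleus(sample_shape_params("AF"), rotation = 0.9)
  M <- 256
  theta <- 2 * pi * (0:(M - 1)) / M
  r <- eval_radius(hs, theta)
  profile <- structure(list(theta = theta, r = r, centroid = c(0, 0),
                            non_star = FALSE), class = "polar_profile")
  fit <- fit_fourier(profile, K = 5)
  ft <- fft(r) / M
  expect_lt(abs(fit$c0 - Re(ft[1])), 1e-9)
  for (k in 1:5) {
    expect_lt(abs(fit$a[k] - 2 * Re(ft[k + 1])), 1e-9)
    expect_lt(abs(fit$b[k] - (-2 * Im(ft[k + 1]))), 1e-9)
  }
})

test_that("fit preconditions are enforced", {
  pp <- to_polar(circle_trace(1), M = 8)
  expect_error(fit_fourier(pp, K = 5), "2K")
  bad <- structure(list(theta = rep(0.3, 20), r = rep(1, 20),
                        centroid = c(0, 0), non_star = FALSE),
                   class = "polar_profile")
  expect_error(fit_fourier(bad, K = 5), "rank")
})

test_that("amplitudes are rotation-invariant and scale linearly", {
  hs <- fixture_nucleus(9)
  poly <- harmonic_polygon(hs, n = 4096)
  tr <- perimeter_trace(poly$x, poly$y)
  fit0 <- fit_fourier(to_polar(tr, 128), 5)
  for (ang in c(0.37, 2.1)) {
    fitr <- fit_fourier(to_polar(rotate_trace(tr, ang), 128), 5)
    expect_lt(max(abs(fitr$amplitudes - fit0$amplitudes)), 1e-6)
  }
  s <- 1.73
  fits <- fit_fourier(to_polar(scale_trace(tr, s), 128), 5)
  expect_equal(unname(fits$amplitudes), unname(s * fit0$amplitudes),
               tolerance = 1e-9)
})

test_that("residual rms is non-increasing in the truncation order", {
  hs <- fixture_nucleus(10)
  poly <- harmonic_polygon(hs, n = 1024)
  pp <- to_polar(perimeter_trace(poly$x, poly$y), 128)
  rms <- vapply(1:5, function(k) fit_fourier(pp, K = k)$residual_rms,
                numeric(1))
  expect_true(all(diff(rms) <= 1e-12))
})

test_that("per-ram summaries compute SAS-convention moments", {
  h <- data.frame(ram_id = "r", HA2 = c(0.8, 0.9, 1.0))
  s <- summarize_ram(h)
  expect_equal(s$mean_HA2, 0.9)
  expect_equal(s$var_HA2, 0.01)

  hd <- data.frame(ram_id = "r", HA2 = rep(0.9, 5))
  sd_ <- summarize_ram(hd)
  expect_equal(sd_$var_HA2, 0)
  expect_equal(sd_$skew_HA2, 0)
  expect_true(sd_$degenerate)

  # direct-summation oracle for the adjusted Fisher-Pearson skewness and
  # bias-corrected excess kurtosis
  set.seed(5)
  v <- rnorm(100)
  sr <- summarize_ram(data.frame(ram_id = "r", HA0 = v))
  n <- length(v); m <- mean(v); s2 <- sum((v - m)^2) / (n - 1)
  g1 <- (sum((v - m)^3) / n) / (sum((v - m)^2) / n)^1.5
  skew_sas <- g1 * sqrt(n * (n - 1)) / (n - 2)
  z4 <- sum(((v - m) / sqrt(s2))^4)
  kurt_sas <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  expect_equal(sr$mean_HA0, m)
  expect_equal(sr$var_HA0, s2)
  expect_equal(sr$skew_HA0, skew_sas, tolerance = 1e-12)
  expect_equal(sr$kurt_HA0, kurt_sas, tolerance = 1e-12)
  expect_error(summarize_ram(data.frame(ram_id = "r", HA0 = 1)), "at least 2")
})

test_that("average shape is idempotent under rotation and tight for identical inputs", {
  hs <- fixture_nucleus(12)
  poly <- harmonic_polygon(hs, n = 720)
  tr <- perimeter_trace(poly$x, poly$y)
  shapes <- list(tr, rotate_trace(tr, 1.1), rotate_trace(tr, -2.4))
  avg <- average_shape(shapes, M = 180)
  expect_lt(max(avg$sd_r), 1e-6)
  # the average equals the aligned shape itself
  avg1 <- average_shape(list(tr, tr), M = 180)
  expect_equal(avg$mean_r, avg1$mean_r, tolerance = 1e-6)

  # identical circles average to a circle with zero spread
  circ <- circle_trace(2.85, n = 360)
  avgc <- suppressWarnings(average_shape(rep(list(circ), 50), M = 90))
  expect_lt(max(avgc$sd_r), 1e-9)
  expect_lt(max(abs(avgc$mean_r - 2.85)), 1e-3)

  # consistency: mean radius of the average of a cohort tracks mean HA0
  coh <- generate_cohort(2, 1, 6, rng_seed = 6)
  avg2 <- average_shape(coh$traces, M = 120)
  expect_lt(abs(mean(avg2$mean_r) - mean(coh$truth$HA0)) /
              mean(coh$truth$HA0), 0.02)
})

test_that("non-star outlines are detected", {
  # a crescent whose centroid falls outside the polygon
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  r <- 1 + 0.95 * cos(th)
  x <- r * cos(th); y <- r * sin(th)
  expect_error(to_polar(perimeter_trace(x + 2, y)), NA)
  # centroid outside: a thin horseshoe
  th2 <- seq(-2.4, 2.4, length.out = 200)
  xs <- c(2 * cos(th2), 2.4 * cos(rev(th2)))
  ys <- c(2 * sin(th2), 2.4 * sin(rev(th2)))
  expect_error(to_polar(perimeter_trace(xs, ys)), "non_star")
})
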