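# Shared fixtures, all generated in code.

# closed circle trace of radius r
circle_trace <- function(r = 1, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  perimeter_trace(center[1] + r * cos(th), center[2] + r * sin(th))
}

# closed axis-aligned ellipse trace with semi-axes a (x) and b (y)
ellipse_trace <- function(a = 4.5, b = 2, n = 720, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  perimeter_trace(center[1] + a * cos(th), center[2] + b * sin(th))
}

# polar radius of a centered axis-aligned ellipse
ellipse_polar_r <- function(theta, a = 4.5, b = 2) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# binary mask of a disk of radius r_px centered in a (2*pad + 2*r)^2 image
disk_mask <- function(r_px = 30, pad = 10) {
  side <- 2 * (r_px + pad)
  ctr <- side / 2 + 0.5
  rc <- expand.grid(row = seq_len(side), col = seq_len(side))
  matrix(sqrt((rc$row - ctr)^2 + (rc$col - ctr)^2) <= r_px, side, side)
}

# a typical adequate-fertility nucleus outline, deterministic
fixture_nucleus <- function(seed = 11, rotation = 0) {
  p <- sample_shape_params("AF")
  withr::with_seed(seed, draw_nucleus(p, rotation = rotation))
}
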