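# Fourier harmonic amplitude (FHA) analysis: transform a closed nuclear
# outline into a polar radius profile about its center of mass, fit a
# truncated Fourier series by trigonometric regression, and summarize the
# amplitudes HA0-HA5 and their dispersion per animal.

#' Transform a perimeter trace into a polar radius profile
#'
#' The pole is the polygon area centroid (the center of mass of the
#' enclosed region). The outline is resampled at `M` equally spaced angles
#' by intersecting rays from the pole with the polygon edges; for a
#' star-shaped outline every ray crosses once. If a ray crosses more than
#' once the farthest intersection is used and a `non_star` flag is set.
#'
#' @param trace A [perimeter_trace()] (simple closed polygon).
#' @param M Number of equally spaced angles (default 128).
#' @return An object of class `polar_profile`: list with `theta` (in
#'   `[0, 2 pi)`), `r` (μm), `centroid`, `non_star`, `ram_id`, `label`.
#' @export
to_polar <- function(trace, M = 128) {
  x <- trace$x; y <- trace$y
  n <- length(x) - 1L                       # closed storage
  ctr <- polygon_centroid(x, y)
  # the parity test can misfire when the test ray passes exactly through
  # vertices (common for symmetric pixel outlines); jitter breaks ties
  eps <- 1e-7 * max(diff(range(x)), diff(range(y)))
  inside <- point_in_polygon(ctr[1], ctr[2], x, y) ||
    point_in_polygon(ctr[1] + eps, ctr[2] + 2 * eps, x, y) ||
    point_in_polygon(ctr[1] - 2 * eps, ctr[2] - eps, x, y)
  if (!inside) {
    stop("non_star_shape: centroid lies outside the outline")
  }
  vx <- x[seq_len(n)] - ctr[1]
  vy <- y[seq_len(n)] - ctr[2]
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  ang <- atan2(vy, vx)
  # unwrap vertex angles along the (counterclockwise) outline
  dang <- c(0, diff(ang))
  dang[dang <= -pi] <- dang[dang <= -pi] + 2 * pi
  dang[dang > pi] <- dang[dang > pi] - 2 * pi
  uw <- ang[1] + cumsum(dang)
  monotone <- all(diff(uw) > 0) &&
    abs((uw[n] - uw[1]) + (uw[1] + 2 * pi - uw[n]) - 2 * pi) < 1e-9
  non_star <- !monotone
  r <- numeric(M)
  if (monotone) {
    # star-shaped fast path, vectorized: each ray hits exactly one edge
    uwc <- c(uw, uw[1] + 2 * pi)
    thq <- uw[1] + ((theta - uw[1]) %% (2 * pi))
    i <- findInterval(thq, uwc, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), n)
    i2 <- ifelse(i == n, 1L, i + 1L)
    ct <- cos(thq); st <- sin(thq)
    den <- (vy[i2] - vy[i]) * ct - (vx[i2] - vx[i]) * st
    r <- (vx[i] * vy[i2] - vx[i2] * vy[i]) / den
    deg <- which(abs(den) < 1e-15)
    for (j in deg) {
      r[j] <- ray_segment_r(thq[j], vx[i[j]], vy[i[j]], vx[i2[j]],
                            vy[i2[j]])
    }
  } else {
    for (j in seq_len(M)) {
      th <- theta[j]
      best <- -Inf
      for (i in seq_len(n)) {
        i2 <- if (i == n) 1L else i + 1L
        ri <- ray_segment_r(th, vx[i], vy[i], vx[i2], vy[i2],
                            strict = TRUE)
        if (!is.na(ri) && ri > best) best <- ri
      }
      if (!is.finite(best)) {
        stop("to_polar: ray at angle ", round(th, 4),
             " does not intersect the outline")
      }
      r[j] <- best
    }
  }
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("to_polar: invalid radius profile")
  }
  structure(list(theta = theta, r = r, centroid = ctr, non_star = non_star,
                 ram_id = trace$ram_id, label = trace$label),
            class = "polar_profile")
}

# Radius at which the ray at angle th from the origin crosses the segment
# (x1,y1)-(x2,y2); NA if it does not (strict mode), otherwise the
# intersection with the supporting line (used on the pre-bracketed edge).
ray_segment_r <- function(th, x1, y1, x2, y2, strict = FALSE) {
  ct <- cos(th); st <- sin(th)
  den <- (y2 - y1) * ct - (x2 - x1) * st
  if (abs(den) < 1e-15) {
    # ray parallel to edge: fall back to the nearer endpoint on the ray
    r1 <- x1 * ct + y1 * st
    if (strict) return(NA_real_)
    return(max(r1, x2 * ct + y2 * st))
  }
  r <- (x1 * y2 - x2 * y1) / den
  if (strict) {
    t <- if (abs(x2 - x1) > abs(y2 - y1)) {
      (r * ct - x1) / (x2 - x1)
    } else {
      (r * st - y1) / (y2 - y1)
    }
    if (r <= 0 || t < -1e-12 || t > 1 + 1e-12) return(NA_real_)
  }
  r
}

#' Fit a truncated Fourier series to a polar profile
#'
#' Ordinary least squares of the radius on the trigonometric basis
#' `{1, cos(k theta), sin(k theta) : k = 1..K}`. For equally spaced angles
#' covering the full circle the solution coincides with the discrete
#' Fourier coefficients.
#'
#' @param profile A [to_polar()] result (requires `M >= 2K + 1`).
#' @param K Highest harmonic (default 5).
#' @return A [harmonic_set()] with `residual_rms` filled in.
#' @export
fit_fourier <- function(profile, K = 5) {
  theta <- profile$theta
  r <- profile$r
  M <- length(theta)
  if (M < 2 * K + 1) stop("fit_fourier: need at least 2K + 1 samples")
  X <- matrix(1, M, 2 * K + 1)
  for (k in seq_len(K)) {
    X[, 2 * k] <- cos(k * theta)
    X[, 2 * k + 1] <- sin(k * theta)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("fit_fourier: rank-deficient design (duplicate angles?)")
  }
  beta <- qr.coef(qx, r)
  res <- r - X %*% beta
  harmonic_set(beta[1], a = beta[2 * seq_len(K)],
               b = beta[2 * seq_len(K) + 1],
               residual_rms = sqrt(mean(res^2)))
}

#' Compute harmonic amplitudes for a list of traces
#'
#' @param traces List of [perimeter_trace()] objects.
#' @param M,K Passed to [to_polar()] and [fit_fourier()].
#' @param on_error `"skip"` (default) drops outlines whose polar transform
#'   fails (e.g. non-star shapes that survived QC), with a warning naming
#'   them; `"stop"` propagates the error.
#' @return Data frame: ram_id, label, c0, a1..a5, b1..b5, HA0..HA5,
#'   residual_rms, non_star.
#' @export
fha_table <- function(traces, M = 128, K = 5,
                      on_error = c("skip", "stop")) {
  on_error <- match.arg(on_error)
  skipped <- character(0)
  rows <- lapply(traces, function(tr) {
    res <- tryCatch({
      pp <- to_polar(tr, M = M)
      hs <- fit_fourier(pp, K = K)
      data.frame(ram_id = tr$ram_id, label = tr$label, c0 = hs$c0,
                 as.list(stats::setNames(hs$a, paste0("a", seq_len(K)))),
                 as.list(stats::setNames(hs$b, paste0("b", seq_len(K)))),
                 as.list(stats::setNames(hs$amplitudes,
                                         paste0("HA", 0:K))),
                 residual_rms = hs$residual_rms, non_star = pp$non_star,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      if (on_error == "stop") stop(e)
      skipped <<- c(skipped, paste0(tr$ram_id, "/", tr$label))
      NULL
    })
    res
  })
  if (length(skipped)) {
    warning("fha_table: skipped ", length(skipped), " outline(s): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-ram harmonic amplitude summary with dispersion moments
#'
#' For each amplitude HA0..HAK: the sample mean, unbiased variance, adjusted
#' Fisher-Pearson skewness and bias-corrected excess kurtosis (the SAS
#' conventions). Zero-variance amplitudes report skewness and kurtosis 0
#' with a degenerate flag. Mean morphometrics are joined when supplied.
#'
#' @param harmonics Data frame from [fha_table()] (or any frame with
#'   `ram_id` and `HA0..HAK` columns), one row per nucleus.
#' @param morpho Optional per-ram morphometric summary from
#'   [summarize_morpho()], joined on `ram_id`.
#' @return Data frame with one row per ram: `ram_id`, `n_sperm`,
#'   `mean_HAk`, `var_HAk`, `skew_HAk`, `kurt_HAk` for each k, a
#'   `degenerate` flag, and the morphometric mean columns when available.
#' @export
summarize_ram <- function(harmonics, morpho = NULL) {
  ha_cols <- grep("^HA[0-9]+$", names(harmonics), value = TRUE)
  stopifnot(length(ha_cols) > 0, !is.null(harmonics$ram_id))
  out <- lapply(split(harmonics, harmonics$ram_id), function(d) {
    if (nrow(d) < 2) {
      stop("summarize_ram: need at least 2 nuclei per ram (ram ",
           d$ram_id[1], ")")
    }
    row <- list(ram_id = d$ram_id[1], n_sperm = nrow(d))
    degen <- FALSE
    for (h in ha_cols) {
      v <- d[[h]]
      ms <- moment_stats(v, type = "sample")
      degen <- degen || ms$degenerate
      row[[paste0("mean_", h)]] <- mean(v)
      row[[paste0("var_", h)]] <- stats::var(v)
      row[[paste0("skew_", h)]] <- ms$skewness
      row[[paste0("kurt_", h)]] <- ms$kurtosis
    }
    row$degenerate <- degen
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(morpho)) {
    keep <- c("ram_id",
              setdiff(names(morpho)[vapply(morpho, is.numeric, logical(1))],
                      c("n_nuclei", grep("^sem_", names(morpho),
                                         value = TRUE))))
    keep <- setdiff(keep, grep("^sem_", keep, value = TRUE))
    res <- merge(res, morpho[keep], by = "ram_id", sort = TRUE)
  }
  res
}

#' Average nuclear shape of a set of outlines
#'
#' Each outline is normalized (centroid at the origin, moment-ellipse major
#' axis horizontal, the anterior end - the half with the greater boundary
#' mass - pointing toward +x, and optionally reflected so the signed
#' skewness of the outline along the minor axis is nonnegative), resampled
#' at `M` common angles about the centroid, and the radii are averaged.
#'
#' @param shapes List of [perimeter_trace()] objects, or of
#'   [harmonic_set()] objects (converted with [harmonic_polygon()]).
#' @param M Number of common angles.
#' @param reflect Apply the reflection normalization (default `TRUE`).
#' @return List of class `average_shape`: `theta`, `mean_r`, `sd_r`, `x`,
#'   `y` (the mean polygon, closed), `n_shapes`.
#' @export
average_shape <- function(shapes, M = 180, reflect = TRUE) {
  stopifnot(length(shapes) >= 2)
  radii <- matrix(NA_real_, length(shapes), M)
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    tr <- if (inherits(s, "harmonic_set")) {
      poly <- harmonic_polygon(s, n = 256)
      perimeter_trace(poly$x, poly$y)
    } else s
    tr <- align_trace(tr, reflect = reflect)
    radii[i, ] <- to_polar(tr, M = M)$r
  }
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  mean_r <- colMeans(radii)
  sd_r <- apply(radii, 2, stats::sd)
  structure(list(theta = theta, mean_r = mean_r, sd_r = sd_r,
                 x = c(mean_r * cos(theta), mean_r[1] * cos(theta[1])),
                 y = c(mean_r * sin(theta), mean_r[1] * sin(theta[1])),
                 n_shapes = length(shapes)),
            class = "average_shape")
}

# Normalize one outline: centroid at origin, major axis horizontal,
# anterior (heavier) end toward +x, optional reflection so the outline's
# signed skew along y is nonnegative.
align_trace <- function(trace, reflect = TRUE) {
  ctr <- polygon_centroid(trace$x, trace$y)
  tr <- translate_trace(trace, -ctr[1], -ctr[2])
  mom <- polygon_moments2(tr$x, tr$y)
  disc <- sqrt(((mom$mxx - mom$myy) / 2)^2 + mom$mxy^2)
  lam1 <- (mom$mxx + mom$myy) / 2 + disc
  lam2 <- (mom$mxx + mom$myy) / 2 - disc
  if (lam1 / max(lam2, 1e-300) < 1.02) {
    warning("average_shape: near-circular outline, orientation arbitrary")
  }
  phi <- 0.5 * atan2(2 * mom$mxy, mom$mxx - mom$myy)
  tr <- rotate_trace(tr, -phi, center = c(0, 0))
  # anterior = half with greater boundary mass (mean radius)
  pp <- to_polar(tr, M = 90)
  right <- mean(pp$r[cos(pp$theta) > 0])
  left <- mean(pp$r[cos(pp$theta) < 0])
  if (left > right) tr <- rotate_trace(tr, pi, center = c(0, 0))
  if (reflect) {
    # signed skew of the region along the minor (y) axis via third moment
    pp <- to_polar(tr, M = 180)
    m3y <- sum((pp$r * sin(pp$theta))^3 * pp$r)
    if (m3y < 0) {
      tr$y <- -tr$y
      tr <- perimeter_trace(tr$x[-length(tr$x)], tr$y[-length(tr$y)],
                            ram_id = tr$ram_id, label = tr$label,
                            pixel_size_um = tr$pixel_size_um)
    }
  }
  tr
}
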