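# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed argument and do
#' not disturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counterclockwise vertex order. Accepts open or closed
#' (first = last) vertex lists.
#' @noRd
polygon_signed_area <- function(x, y) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3) return(0)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a simple polygon
#' @noRd
polygon_centroid <- function(x, y) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  a <- polygon_signed_area(x, y)
  if (abs(a) < .Machine$double.eps * 100) {
    return(c(mean(x), mean(y)))
  }
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Second-order area moments of a simple polygon about its centroid
#'
#' Returns the central covariance-like moments (mxx, mxy, myy), i.e. the
#' per-unit-area second moments of the enclosed region, via Green's theorem.
#' @noRd
polygon_moments2 <- function(x, y) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  a <- polygon_signed_area(x, y)
  ctr <- polygon_centroid(x, y)
  x <- x - ctr[1]; y <- y - ctr[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  ixx <- sum(cr * (y^2 + y * yn + yn^2)) / 12   # integral of y^2 dA
  iyy <- sum(cr * (x^2 + x * xn + xn^2)) / 12   # integral of x^2 dA
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  list(area = a, centroid = ctr,
       mxx = iyy / a, myy = ixx / a, mxy = ixy / a)
}

#' Point-in-polygon test (ray casting), polygon open or closed
#' @noRd
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Rotate 2-D points counterclockwise by alpha radians
#' @noRd
rotate_xy <- function(x, y, alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  list(x = ca * x - sa * y, y = sa * x + ca * y)
}

#' Sample moments with selectable conventions
#'
#' type = "population": g1 = m3/m2^1.5 and excess g2 = m4/m2^2 - 3 (the
#' ImageJ pixel-statistics convention). type = "sample": the adjusted
#' Fisher-Pearson skewness and bias-corrected excess kurtosis (the SAS
#' convention used for harmonic-amplitude dispersion).
#' @noRd
moment_stats <- function(v, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(v)
  m <- mean(v)
  if (type == "population") {
    m2 <- mean((v - m)^2)
    if (m2 <= 0) return(list(skewness = 0, kurtosis = 0, degenerate = TRUE))
    list(skewness = mean((v - m)^3) / m2^1.5,
         kurtosis = mean((v - m)^4) / m2^2 - 3,
         degenerate = FALSE)
  } else {
    s2 <- stats::var(v)
    if (s2 <= 0 || n < 3) {
      return(list(skewness = 0, kurtosis = 0, degenerate = TRUE))
    }
    list(skewness = e1071::skewness(v, type = 2),
         kurtosis = if (n >= 4) e1071::kurtosis(v, type = 2) else 0,
         degenerate = FALSE)
  }
}

#' Standard error of the mean
#' @noRd
sem <- function(v) stats::sd(v) / sqrt(length(v))

`%||%` <- function(a, b) if (is.null(a)) b else a
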