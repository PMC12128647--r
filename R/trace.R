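# PerimeterTrace: the ordered, closed outline of one nucleus in calibrated
# micrometre coordinates (y increasing upward, counterclockwise orientation,
# first vertex repeated as last).

#' Construct a perimeter trace
#'
#' @param x,y Vertex coordinates in μm. The polygon may be given open or
#'   closed; it is stored closed (first vertex repeated at the end) and
#'   reoriented counterclockwise if needed.
#' @param ram_id,label Provenance identifiers (animal and object label).
#' @param pixel_size_um Pixel size of the source image in μm, `NA` for
#'   analytic traces.
#' @param chain Optional integer vector of chain-code step parities (0 =
#'   axial, 1 = diagonal) attached by [trace_perimeter()]; used for
#'   chain-code perimeter estimation.
#' @return An object of class `perimeter_trace`.
#' @export
perimeter_trace <- function(x, y, ram_id = NA_character_,
                            label = NA_integer_, pixel_size_um = NA_real_,
                            chain = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  if (length(x) < 8) {
    stop("perimeter_trace: need at least 8 distinct vertices")
  }
  if (polygon_signed_area(x, y) < 0) {        # enforce counterclockwise
    x <- rev(x); y <- rev(y)
    if (!is.null(chain)) chain <- rev(chain)
  }
  structure(list(x = c(x, x[1]), y = c(y, y[1]),
                 ram_id = ram_id, label = label,
                 pixel_size_um = pixel_size_um, chain = chain),
            class = "perimeter_trace")
}

#' @export
print.perimeter_trace <- function(x, ...) {
  cat(sprintf("Perimeter trace: %d vertices (closed), ram %s, label %s\n",
              length(x$x) - 1L, x$ram_id, x$label))
  invisible(x)
}

#' Perimeter length of a trace
#'
#' For pixel-derived traces the length is the chain-code estimate (1 for
#' axial, sqrt(2) for diagonal steps, in pixel units converted to μm).
#' `corner_correction = TRUE` replaces the raw weights with the
#' Vossepoel-Smeulders weights (0.980 axial, 1.406 diagonal), which remove
#' the systematic overestimate of staircase boundaries on smooth outlines
#' while remaining exact on axis-aligned edges to within 2%. Analytic traces
#' use the Euclidean polyline length.
#'
#' @param trace A [perimeter_trace()].
#' @param corner_correction Apply corner-smoothing chain weights
#'   (default off).
#' @return Length in μm.
#' @export
perimeter_length <- function(trace, corner_correction = FALSE) {
  if (!is.null(trace$chain) && !is.na(trace$pixel_size_um)) {
    n_diag <- sum(trace$chain == 1L)
    n_axial <- sum(trace$chain == 0L)
    w <- if (corner_correction) c(0.980, 1.406) else c(1, sqrt(2))
    return((w[1] * n_axial + w[2] * n_diag) * trace$pixel_size_um)
  }
  dx <- diff(trace$x); dy <- diff(trace$y)
  sum(sqrt(dx^2 + dy^2))
}

#' Translate a trace
#' @param trace A [perimeter_trace()].
#' @param dx,dy Offsets in μm.
#' @export
translate_trace <- function(trace, dx = 0, dy = 0) {
  trace$x <- trace$x + dx
  trace$y <- trace$y + dy
  trace
}

#' Rotate a trace about a point
#' @param trace A [perimeter_trace()].
#' @param alpha Angle in radians (counterclockwise).
#' @param center Rotation center (μm), default the polygon centroid.
#' @export
rotate_trace <- function(trace, alpha, center = NULL) {
  if (is.null(center)) center <- polygon_centroid(trace$x, trace$y)
  p <- rotate_xy(trace$x - center[1], trace$y - center[2], alpha)
  trace$x <- p$x + center[1]
  trace$y <- p$y + center[2]
  trace
}

#' Scale a trace about the origin
#' @param trace A [perimeter_trace()].
#' @param s Scale factor.
#' @export
scale_trace <- function(trace, s) {
  stopifnot(s > 0)
  trace$x <- trace$x * s
  trace$y <- trace$y * s
  if (!is.na(trace$pixel_size_um)) {
    trace$pixel_size_um <- trace$pixel_size_um * s
  }
  trace
}
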