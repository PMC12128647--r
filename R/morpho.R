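# ImageJ-style morphometric and intensity measurements of segmented nuclei:
# area, perimeter, circularity, aspect ratio, roundness, solidity and the
# pixel-intensity moments (mean, SD, median, skewness, excess kurtosis).

#' Measure one nucleus
#'
#' Computes the morphometric and intensity features of an accepted labeled
#' object, following the ImageJ definitions: area is the pixel count scaled
#' by the pixel size; the fitted ellipse comes from the central second-order
#' moments of the member pixels (semi-axes `2 * sqrt(eigenvalue)`); aspect
#' ratio is major/minor, roundness `4 * area / (pi * major^2)`, solidity the
#' outline area over its convex-hull area. Circularity is
#' `4 * pi * area / perimeter^2` evaluated on the staircase-smoothed
#' (equal-angle resampled) outline polygon, clamped to 1. Intensity
#' skewness uses the population moment convention and kurtosis is excess
#' kurtosis (normal = 0), as ImageJ reports them.
#'
#' @param obj One element of an [extract_objects()] result.
#' @param image Intensity image (matrix, same shape as the mask the object
#'   came from).
#' @param pixel_size_um Pixel size (μm/px).
#' @param trace Optional precomputed [trace_perimeter()] result for the
#'   object (computed on demand otherwise).
#' @return A one-row data frame (class `morphometric_record`): `label`,
#'   `area_um2`, `perimeter_um`, `circularity`, `aspect_ratio`, `roundness`,
#'   `solidity`, `intensity_mean`, `intensity_sd`, `intensity_median`,
#'   `intensity_skewness`, `intensity_kurtosis`.
#' @export
measure_nucleus <- function(obj, image, pixel_size_um, trace = NULL) {
  stopifnot(is.matrix(image))
  if (!is.null(obj$rejected_reason) && obj$rejected_reason != "none") {
    stop("measure_nucleus: object was rejected (", obj$rejected_reason, ")")
  }
  pix <- obj$pixels
  npix <- nrow(pix)
  area <- npix * pixel_size_um^2
  if (is.null(trace)) {
    trace <- trace_perimeter(obj, pixel_size_um, image_nrow = nrow(image))
  }
  # Staircase-smoothed outline: equal-angle resampling removes the
  # digitization staircase so perimeter and circularity behave like their
  # continuous definitions (a rasterized disk measures ~1, a square pi/4).
  sm <- tryCatch({
    pp <- to_polar(trace, M = 128)
    # circular moving average suppresses the +/- half-pixel radius jitter
    # of the staircase without rounding genuine corners much
    r <- as.numeric(stats::filter(pp$r, rep(1 / 3, 3), circular = TRUE))
    sx <- c(r * cos(pp$theta), r[1] * cos(pp$theta[1])) + pp$centroid[1]
    sy <- c(r * sin(pp$theta), r[1] * sin(pp$theta[1])) + pp$centroid[2]
    list(perim = sum(sqrt(diff(sx)^2 + diff(sy)^2)),
         area = abs(polygon_signed_area(sx, sy)))
  }, error = function(e) NULL)
  if (is.null(sm)) {
    # non-star outline: fall back to the corner-corrected chain length
    sm <- list(perim = perimeter_length(trace, corner_correction = TRUE),
               area = abs(polygon_signed_area(trace$x, trace$y)))
  }
  perim <- sm$perim
  poly_area <- abs(polygon_signed_area(trace$x, trace$y))
  circ <- min(4 * pi * sm$area / perim^2, 1)

  # moment-fitted ellipse on pixel centers (μm)
  x <- (pix[, 2] - 0.5) * pixel_size_um
  y <- (nrow(image) - pix[, 1] + 0.5) * pixel_size_um
  cxx <- stats::var(x) * (npix - 1) / npix + pixel_size_um^2 / 12
  cyy <- stats::var(y) * (npix - 1) / npix + pixel_size_um^2 / 12
  cxy <- stats::cov(x, y) * (npix - 1) / npix
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  if (ev[2] <= 0) {
    stop("measure_nucleus: degenerate ellipse (zero minor axis)")
  }
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  aspect <- major / minor
  roundness <- min(4 * area / (pi * major^2), 1)

  # solidity from the traced outline vs its convex hull
  h <- grDevices::chull(trace$x, trace$y)
  hull_area <- abs(polygon_signed_area(trace$x[h], trace$y[h]))
  solidity <- if (hull_area > 0) min(poly_area / hull_area, 1) else NA_real_

  v <- image[pix]
  ms <- moment_stats(v, type = "population")
  structure(data.frame(
    label = obj$label,
    area_um2 = area, perimeter_um = perim, circularity = circ,
    aspect_ratio = aspect, roundness = roundness, solidity = solidity,
    intensity_mean = mean(v), intensity_sd = stats::sd(v),
    intensity_median = stats::median(v),
    intensity_skewness = ms$skewness, intensity_kurtosis = ms$kurtosis
  ), class = c("morphometric_record", "data.frame"))
}

#' Measure all accepted nuclei of a field
#'
#' @param objects An [extract_objects()] result.
#' @param image Intensity image.
#' @param pixel_size_um Pixel size (μm/px).
#' @param traces Optional list of precomputed traces matched to the accepted
#'   objects (in order).
#' @return Data frame with one [measure_nucleus()] row per accepted object.
#' @export
measure_objects <- function(objects, image, pixel_size_um, traces = NULL) {
  acc <- Filter(function(o) o$rejected_reason == "none", objects)
  rows <- lapply(seq_along(acc), function(i) {
    measure_nucleus(acc[[i]], image, pixel_size_um,
                    trace = if (!is.null(traces)) traces[[i]] else NULL)
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Per-ram morphometric summary
#'
#' Mean and standard error of every numeric feature, per ram.
#'
#' @param records Data frame of [measure_nucleus()] rows with a `ram_id`
#'   column (added by the caller).
#' @return Data frame with one row per ram: `<feature>` (mean) and
#'   `sem_<feature>` columns plus `n_nuclei`.
#' @export
summarize_morpho <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("summarize_morpho: empty input")
  }
  if (is.null(records$ram_id)) records$ram_id <- "unknown"
  feats <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                   c("label"))
  out <- lapply(split(records, records$ram_id), function(d) {
    if (nrow(d) < 2) {
      stop("summarize_morpho: need at least 2 records per ram (ram ",
           d$ram_id[1], ")")
    }
    means <- vapply(feats, function(f) mean(d[[f]]), numeric(1))
    sems <- vapply(feats, function(f) sem(d[[f]]), numeric(1))
    stats::setNames(
      data.frame(d$ram_id[1], nrow(d), as.list(means), as.list(sems)),
      c("ram_id", "n_nuclei", feats, paste0("sem_", feats)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  stopifnot(!anyNA(res))
  res
}

#' Geometric morphometrics of an analytic outline
#'
#' Computes the shape features that do not require pixels - area, perimeter,
#' circularity, aspect ratio, roundness, solidity - directly from a polygon
#' outline (area and moments via Green's theorem). Used for ground-truth
#' outlines and perimeter-only workflows.
#'
#' @param trace A [perimeter_trace()].
#' @return One-row data frame: `label`, `area_um2`, `perimeter_um`,
#'   `circularity`, `aspect_ratio`, `roundness`, `solidity`.
#' @export
polygon_morpho <- function(trace) {
  a <- abs(polygon_signed_area(trace$x, trace$y))
  p <- perimeter_length(trace)
  mom <- polygon_moments2(trace$x, trace$y)
  disc <- sqrt(((mom$mxx - mom$myy) / 2)^2 + mom$mxy^2)
  lam1 <- (mom$mxx + mom$myy) / 2 + disc
  lam2 <- (mom$mxx + mom$myy) / 2 - disc
  if (lam2 <= 0) stop("polygon_morpho: degenerate outline")
  major <- 4 * sqrt(lam1)
  h <- grDevices::chull(trace$x, trace$y)
  hull_area <- abs(polygon_signed_area(trace$x[h], trace$y[h]))
  data.frame(label = trace$label,
             area_um2 = a, perimeter_um = p,
             circularity = min(4 * pi * a / p^2, 1),
             aspect_ratio = sqrt(lam1 / lam2),
             roundness = min(4 * a / (pi * major^2), 1),
             solidity = if (hull_area > 0) min(a / hull_area, 1) else
               NA_real_)
}
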