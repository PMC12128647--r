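# Nucleus segmentation: Laplacian-of-Gaussian thresholding, connected-object
# extraction with quality-control rejection, and perimeter tracing.

# EBImage morphological ops return Image objects; keep plain logical
# matrices at the module surface.
.as_binary <- function(x) {
  m <- as.matrix(x)
  matrix(m > 0.5, nrow(m), ncol(m))
}

#' Laplacian-of-Gaussian thresholding
#'
#' Computes the negated Laplacian-of-Gaussian response of a single-channel
#' image and thresholds it to a binary nucleus mask. Bright compact blobs
#' produce a strong positive response band just inside their edge; after
#' thresholding, interior holes are filled and the mask is optionally grown
#' out to the response zero-crossing, which marks the blurred edge position,
#' so the mask edge tracks the true boundary rather than the threshold
#' level.
#'
#' @param image Numeric matrix (single channel, gray levels).
#' @param pixel_size_um Pixel size (μm/px).
#' @param sigma_um Gaussian scale of the LoG filter in μm (default 0.3,
#'   about the nuclear edge scale).
#' @param threshold_policy `"otsu"` (default; Otsu's threshold on the
#'   response) or `"zero"` (response > 0).
#' @param fill_holes Fill interior holes of the mask.
#' @param refine_zero_cross Grow the thresholded mask within the positive
#'   response region up to the zero crossing (default `TRUE`).
#' @return Logical matrix; a constant image yields an empty mask.
#' @export
log_threshold <- function(image, pixel_size_um, sigma_um = 0.3,
                          threshold_policy = c("otsu", "zero"),
                          fill_holes = TRUE, refine_zero_cross = TRUE) {
  threshold_policy <- match.arg(threshold_policy)
  stopifnot(is.matrix(image), sigma_um > 0, pixel_size_um > 0)
  if (diff(range(image)) == 0) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  sigma_px <- max(sigma_um / pixel_size_um, 0.5)
  g <- EBImage::gblur(image, sigma = sigma_px)
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- -as.matrix(EBImage::filter2(g, lap_kernel))
  if (diff(range(resp)) == 0) {
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (threshold_policy == "otsu") {
    rn <- (resp - min(resp)) / diff(range(resp))
    thr <- EBImage::otsu(EBImage::Image(rn), range = c(0, 1), levels = 256)
    mask <- rn > thr
  } else {
    mask <- resp > 0
  }
  brush <- EBImage::makeBrush(3, shape = "diamond")
  # close small gaps in the edge-response annulus before hole filling,
  # then remove isolated noise specks
  mask <- .as_binary(EBImage::closing(mask * 1,
                                      EBImage::makeBrush(5, "disc")))
  if (fill_holes) mask <- .as_binary(EBImage::fillHull(mask * 1))
  mask <- .as_binary(EBImage::opening(mask * 1, brush))
  if (refine_zero_cross) {
    pos <- resp > 0
    for (i in 1:20) {
      grown <- (.as_binary(EBImage::dilate(mask * 1, brush)) & pos) | mask
      if (identical(grown, mask)) break
      mask <- grown
    }
    # smooth the noise-rippled zero-crossing boundary
    disc <- EBImage::makeBrush(5, shape = "disc")
    mask <- .as_binary(EBImage::closing(mask * 1, disc))
    mask <- .as_binary(EBImage::opening(mask * 1, disc))
    if (fill_holes) mask <- .as_binary(EBImage::fillHull(mask * 1))
  }
  mask
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass.
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # NW-SE diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # NE-SW diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract labeled objects from a binary mask
#'
#' Labels 8-connected foreground components and applies quality-control
#' gates: objects outside the area window, touching the image border, or
#' with the low solidity / oversize signature of fused (overlapping) nuclei
#' are marked rejected with a reason; accepted objects have
#' `rejected_reason == "none"`.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size (μm/px).
#' @param min_area_um2,max_area_um2 Area gate (defaults 10-80 μm² around the
#'   ~28 μm² nominal nucleus).
#' @param solidity_min Objects with solidity below this are flagged as
#'   overlapping/fused (default 0.92).
#' @param median_area_um2 Optional cohort median nucleus area; objects
#'   larger than 1.6 times it are also flagged as overlap. When `NULL` it is
#'   taken as the median area of the in-gate objects of this mask if at
#'   least 5 are present.
#' @return An object of class `labeled_objects`: a list of objects (fields
#'   `label`, `pixels` (row/col matrix), `bbox`, `area_um2`, `solidity`,
#'   `touches_border`, `rejected_reason`) with the label matrix and pixel
#'   size as attributes.
#' @export
extract_objects <- function(mask, pixel_size_um, min_area_um2 = 10,
                            max_area_um2 = 80, solidity_min = 0.92,
                            median_area_um2 = NULL) {
  stopifnot(is.matrix(mask))
  lab <- label8(mask)
  n <- max(lab)
  px2 <- pixel_size_um^2
  objs <- vector("list", n)
  for (l in seq_len(n)) {
    pix <- which(lab == l, arr.ind = TRUE)
    area <- nrow(pix) * px2
    bbox <- c(row_min = min(pix[, 1]), row_max = max(pix[, 1]),
              col_min = min(pix[, 2]), col_max = max(pix[, 2]))
    border <- bbox["row_min"] == 1 || bbox["col_min"] == 1 ||
      bbox["row_max"] == nrow(mask) || bbox["col_max"] == ncol(mask)
    sol <- object_solidity(pix, px2)
    objs[[l]] <- list(label = l, pixels = pix, bbox = bbox,
                      area_um2 = area, solidity = sol,
                      touches_border = as.logical(border),
                      rejected_reason = "none")
  }
  areas <- vapply(objs, `[[`, numeric(1), "area_um2")
  in_gate <- areas >= min_area_um2 & areas <= max_area_um2
  if (is.null(median_area_um2)) {
    median_area_um2 <- if (sum(in_gate) >= 5) {
      stats::median(areas[in_gate])
    } else NA_real_
  }
  for (l in seq_len(n)) {
    o <- objs[[l]]
    # fused-pair signature: low solidity AND oversize relative to the
    # cohort median; without a usable median, low solidity alone decides
    low_sol <- !is.na(o$solidity) && o$solidity < solidity_min
    oversize <- is.na(median_area_um2) ||
      o$area_um2 > 1.6 * median_area_um2
    reason <- if (o$touches_border) "border"
    else if (o$area_um2 < min_area_um2) "too_small"
    else if (o$area_um2 > max_area_um2) "too_large"
    else if (low_sol && oversize) "overlap"
    else "none"
    objs[[l]]$rejected_reason <- reason
  }
  structure(objs, class = "labeled_objects", labels = lab,
            pixel_size_um = pixel_size_um)
}

# Solidity = pixel area / area of the convex hull of the pixel centers.
object_solidity <- function(pix, px2) {
  if (nrow(pix) < 4) return(NA_real_)
  # Cartesian coordinates of pixel centers; the actual frame is irrelevant
  # for the ratio.
  x <- pix[, 2]; y <- -pix[, 1]
  h <- grDevices::chull(x, y)
  hull_area <- abs(polygon_signed_area(x[h], y[h]))
  # hull of centers underestimates the pixel support; add the half-pixel rim
  hull_area <- hull_area + length(h) * 0.5 +
    0.5 * sum(sqrt(diff(c(x[h], x[h][1]))^2 + diff(c(y[h], y[h][1]))^2))
  if (hull_area <= 0) return(NA_real_)
  min(nrow(pix) / hull_area, 1)
}

#' @export
print.labeled_objects <- function(x, ...) {
  reasons <- vapply(x, `[[`, character(1), "rejected_reason")
  cat(sprintf("%d labeled objects (%d accepted)\n", length(x),
              sum(reasons == "none")))
  if (length(x)) print(table(rejected_reason = reasons))
  invisible(x)
}

#' Trace the outer perimeter of a labeled object
#'
#' Follows the outer boundary pixels of the object with 8-connected
#' Moore-neighbour tracing, then converts the boundary pixel centers to
#' Cartesian μm coordinates (origin at the image bottom-left, y increasing
#' upward) in counterclockwise order, first vertex repeated at the end.
#' Chain-code step parities are retained for perimeter estimation (see
#' [perimeter_length()]).
#'
#' @param obj One element of a [extract_objects()] result (or any list with
#'   a `pixels` row/col matrix and `label`).
#' @param pixel_size_um Pixel size (μm/px).
#' @param image_nrow Number of image rows (needed for the y-up conversion);
#'   defaults to the labels attribute when `obj` carries one.
#' @param ram_id Optional provenance id stored on the trace.
#' @param radial_pad_px Radial outward expansion of the vertex polygon, in
#'   pixels, about the outline centroid. Boundary pixel centers sit about
#'   half a pixel inside the region they delimit, so downstream radius
#'   measurements carry a half-pixel inward bias; a pad of 0.5 (used by
#'   [segment_field()]) removes it. Default 0 (raw pixel centers).
#' @return A [perimeter_trace()].
#' @export
trace_perimeter <- function(obj, pixel_size_um, image_nrow = NULL,
                            ram_id = NA_character_, radial_pad_px = 0) {
  pix <- obj$pixels
  if (is.null(image_nrow)) {
    image_nrow <- attr(obj, "image_nrow") %||% max(pix[, 1])
  }
  # local binary window with 1-px pad on all sides
  r0 <- min(pix[, 1]) - 2L; c0 <- min(pix[, 2]) - 2L
  nr <- max(pix[, 1]) - r0 + 2L; nc <- max(pix[, 2]) - c0 + 2L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pix[, 1] - r0, pix[, 2] - c0)] <- TRUE
  b <- moore_trace(m)
  if (nrow(b$path) < 8) {
    stop("interrupted_perimeter: object boundary has fewer than 8 pixels")
  }
  rows <- b$path[, 1] + r0
  cols <- b$path[, 2] + c0
  x <- (cols - 0.5) * pixel_size_um
  y <- (image_nrow - rows + 0.5) * pixel_size_um
  if (radial_pad_px != 0) {
    ctr <- polygon_centroid(x, y)
    d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
    f <- 1 + radial_pad_px * pixel_size_um / pmax(d, pixel_size_um)
    x <- ctr[1] + (x - ctr[1]) * f
    y <- ctr[2] + (y - ctr[2]) * f
  }
  perimeter_trace(x, y, ram_id = ram_id, label = obj$label,
                  pixel_size_um = pixel_size_um, chain = b$chain)
}

# Moore-neighbour boundary following on a padded binary window. The
# backtrack pixel (last background neighbour examined) restarts each
# clockwise neighbour scan; tracing stops when the start pixel is
# re-entered with the starting backtrack (Jacob's stopping criterion).
# Returns the boundary pixel path (row, col) and chain step parity
# (0 axial, 1 diagonal).
moore_trace <- function(m) {
  # clockwise neighbour order in screen coordinates (row down), from N
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  start_idx <- which(m)[1]
  nr <- nrow(m)
  sp <- c((start_idx - 1L) %% nr + 1L, (start_idx - 1L) %/% nr + 1L)
  if (sum(m) == 1L) return(list(path = rbind(sp), chain = integer(0)))
  # column-major scanning guarantees the W neighbour of the start is empty
  p <- sp
  b <- c(sp[1], sp[2] - 1L)
  max_steps <- 4L * sum(m) + 8L
  path <- matrix(0L, max_steps + 2L, 2)
  path[1, ] <- sp
  np <- 1L
  chain <- integer(max_steps + 2L)
  nc_ <- 0L
  q_first <- NULL
  for (step in seq_len(max_steps)) {
    ib <- which(dr == b[1] - p[1] & dc == b[2] - p[2])
    qd <- 0L
    for (k in 1:8) {
      d <- (ib + k - 1L) %% 8L + 1L
      q <- c(p[1] + dr[d], p[2] + dc[d])
      if (m[q[1], q[2]]) {
        qd <- d
        dprev <- (ib + k - 2L) %% 8L + 1L
        break
      }
    }
    if (qd == 0L) break                     # isolated pixel
    # termination: about to repeat the very first move out of the start
    if (!is.null(q_first) && all(p == sp) && all(q == q_first)) break
    if (is.null(q_first)) q_first <- q
    b <- c(p[1] + dr[dprev], p[2] + dc[dprev])
    nc_ <- nc_ + 1L
    chain[nc_] <- as.integer(abs(dr[qd]) + abs(dc[qd]) == 2L)
    p <- q
    np <- np + 1L
    path[np, ] <- p
  }
  # the path ends back at the start; drop the duplicate closing vertex
  if (np > 1L && all(path[np, ] == sp)) np <- np - 1L
  list(path = path[seq_len(np), , drop = FALSE],
       chain = chain[seq_len(nc_)])
}

#' Overlay traces on a phase-contrast image for quality control
#'
#' Paints each perimeter trace onto the (co-registered) phase image and
#' builds a per-object accept/reject table, honouring a manual rejection
#' list. Traces falling outside the image bounds are flagged.
#'
#' @param phase Numeric matrix (phase-contrast or any co-registered image).
#' @param traces List of [perimeter_trace()] objects.
#' @param pixel_size_um Pixel size (μm/px).
#' @param manual_reject Integer vector of object labels to reject manually.
#' @return List with `overlay` (numeric matrix) and `table` (data frame:
#'   label, ram_id, accepted, reason).
#' @export
overlay_qc <- function(phase, traces, pixel_size_um,
                       manual_reject = integer(0)) {
  stopifnot(is.matrix(phase))
  overlay <- phase
  hi <- max(phase) + 0.25 * max(diff(range(phase)), 1)
  tab <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    cols <- round(tr$x / pixel_size_um + 0.5)
    rows <- round(nrow(phase) - tr$y / pixel_size_um + 0.5)
    inb <- rows >= 1 & rows <= nrow(phase) & cols >= 1 & cols <= ncol(phase)
    out_of_bounds <- any(!inb)
    overlay[cbind(rows[inb], cols[inb])] <- hi
    reason <- if (tr$label %in% manual_reject) "manual"
    else if (out_of_bounds) "out_of_bounds"
    else "none"
    tab[[i]] <- data.frame(label = tr$label, ram_id = tr$ram_id,
                           accepted = reason == "none", reason = reason,
                           stringsAsFactors = FALSE)
  }
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(label = integer(0), ram_id = character(0),
               accepted = logical(0), reason = character(0))
  list(overlay = overlay, table = tab)
}

#' Segment a fluorescence field into accepted perimeter traces
#'
#' Convenience wrapper chaining [log_threshold()], [extract_objects()] and
#' [trace_perimeter()] for all accepted objects.
#'
#' @param image Numeric matrix (fluorescence).
#' @param pixel_size_um Pixel size (μm/px).
#' @param ram_id Provenance id attached to the traces.
#' @param radial_pad_px Half-pixel boundary support correction applied to
#'   the traces (see [trace_perimeter()]); default 0.5.
#' @param ... Passed to [log_threshold()] and [extract_objects()] (matched
#'   by name).
#' @return List with `mask`, `objects` ([extract_objects()] result) and
#'   `traces` (list of [perimeter_trace()] for accepted objects).
#' @export
segment_field <- function(image, pixel_size_um, ram_id = NA_character_,
                          radial_pad_px = 0.5, ...) {
  dots <- list(...)
  lt_args <- dots[names(dots) %in%
                    names(formals(log_threshold))]
  eo_args <- dots[names(dots) %in% names(formals(extract_objects))]
  mask <- do.call(log_threshold,
                  c(list(image = image, pixel_size_um = pixel_size_um),
                    lt_args))
  objs <- do.call(extract_objects,
                  c(list(mask = mask, pixel_size_um = pixel_size_um),
                    eo_args))
  acc <- Filter(function(o) o$rejected_reason == "none", objs)
  traces <- lapply(acc, trace_perimeter, pixel_size_um = pixel_size_um,
                   image_nrow = nrow(image), ram_id = ram_id,
                   radial_pad_px = radial_pad_px)
  list(mask = mask, objects = objs, traces = traces)
}
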