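# Synthetic cohort and image generator. Emulates the study design the
# shape pipeline was built for: two ram fertility groups (adequate, AF, and
# low, LF), ~100 Hoechst-stained sperm nuclei imaged per ram, nuclear
# outlines drawn from a truncated polar Fourier family whose group-level
# harmonic-amplitude means and dispersions follow the published per-group
# summary statistics, rendered as widefield epifluorescence patches with a
# Gaussian PSF, shot noise and read noise.

# Published group-level harmonic amplitude means and SEMs (μm); the shape
# cohort had 47 AF and 9 LF rams with 100 measured sperm per ram.
.HA_TABLE <- list(
  AF = list(mean = c(2.851, 0.085, 0.905, 0.078, 0.153, 0.024),
            sem  = c(0.010, 0.002, 0.006, 0.002, 0.003, 0.001),
            n_rams = 47L),
  LF = list(mean = c(2.838, 0.087, 0.872, 0.082, 0.143, 0.024),
            sem  = c(0.029, 0.005, 0.024, 0.006, 0.011, 0.002),
            n_rams = 9L),
  # overall cohort column (n = 56): anchors the within-ram spread, which is
  # modeled as a common sperm-to-sperm process for both groups
  overall = list(mean = c(2.849, 0.085, 0.900, 0.079, 0.151, 0.024),
                 sem  = c(0.009, 0.002, 0.006, 0.002, 0.003, 0.001),
                 n_rams = 56L)
)

# Published group intensity summaries (8-bit-like gray levels): per-ram mean
# intensity (SEM over rams) and mean within-nucleus intensity SD.
.INTENSITY_TABLE <- list(
  AF = list(mean = 99.168, sem = 3.015, sd_within = 17.754,
            sd_sem = 0.607, n_rams = 47L),
  LF = list(mean = 110.737, sem = 10.719, sd_within = 20.528,
            sd_sem = 2.495, n_rams = 9L)
)

# Conception-rate summaries (percent): group mean, SEM and group size in the
# fertility population (41 AF, 27 LF of 68 rams; population 89.0 +/- 6.6).
.FERTILITY_TABLE <- list(
  AF = list(mean = 95.1, sem = 0.6, n = 41L),
  LF = list(mean = 79.7, sem = 2.5, n = 27L)
)

#' Shape population parameters for a fertility group
#'
#' Returns the generator defaults for one fertility group: harmonic
#' amplitude means equal to the published group means; per-sperm standard
#' deviations `SEM_overall * sqrt(n_sperm)` from the cohort-level SEMs,
#' modelling sperm-to-sperm variability as a common process for both groups
#' (the group-specific printed SEMs differ mostly through group size);
#' between-ram standard deviations `SEM_group * sqrt(n_rams)` so the
#' printed group dispersions are reproduced at the ram level; and intensity
#' defaults from the published morphometric summaries.
#'
#' @param group `"AF"` (adequate fertility) or `"LF"` (low fertility).
#' @param n_sperm Number of sperm measured per ram used in the SEM-to-SD
#'   conversion (default 100, the study's sampling depth).
#' @return An object of class `shape_params` with fields `group_label`,
#'   `ha_means`, `ha_sds` (within-ram, per sperm), `ha_ram_sds` (between
#'   rams), `phase_jitter` (radians), `intensity_mean`, `intensity_sd`
#'   (within-nucleus pixel SD), `intensity_ram_sd`.
#' @examples
#' sample_shape_params("AF")$ha_means[["HA2"]]  # 0.905
#' @export
sample_shape_params <- function(group = c("AF", "LF"), n_sperm = 100) {
  if (length(group) != 1 || !group %in% c("AF", "LF")) {
    stop("unknown group label: ", paste(group, collapse = ", "))
  }
  ha <- .HA_TABLE[[group]]
  it <- .INTENSITY_TABLE[[group]]
  means <- ha$mean
  names(means) <- paste0("HA", 0:5)
  structure(list(
    group_label = group,
    ha_means = means,
    ha_sds = stats::setNames(.HA_TABLE$overall$sem * sqrt(n_sperm),
                             paste0("HA", 0:5)),
    ha_ram_sds = stats::setNames(ha$sem * sqrt(ha$n_rams), paste0("HA", 0:5)),
    phase_jitter = 0.15,
    intensity_mean = it$mean,
    intensity_sd = it$sd_within,
    # injected chromatin texture; calibrated so that the measured
    # within-nucleus pixel SD (texture + PSF-dimmed edge band + shot and
    # read noise) reproduces the published intensity-SD scale
    texture_sd = 0.68 * it$sd_within,
    intensity_ram_sd = it$sem * sqrt(it$n_rams),
    intensity_sd_ram_sd = it$sd_sem * sqrt(it$n_rams)
  ), class = "shape_params")
}

#' Draw one nucleus outline from a shape population
#'
#' Amplitudes HA0 and HA2-HA5 are drawn independently from truncated normal
#' distributions around the population means; harmonic phases receive
#' von-Mises-like jitter around a canonical sperm-head orientation. The
#' outline is then anchored at its center of mass (see
#' [center_harmonics()]), which constrains the first harmonic, and the
#' anchored amplitudes are the ground truth stored for the nucleus.
#'
#' @param params A `shape_params` object (or a list with `ha_means`,
#'   `ha_sds`, `phase_jitter`).
#' @param rotation Outline rotation in radians (default random uniform).
#' @return A [harmonic_set()].
#' @export
draw_nucleus <- function(params, rotation = stats::runif(1, 0, 2 * pi)) {
  mu <- params$ha_means
  sd <- params$ha_sds
  amp <- stats::rnorm(6, mu, sd)
  amp[1] <- max(amp[1], 0.5)          # HA0 stays a valid mean radius
  amp <- pmax(amp, 0)
  jit <- stats::rnorm(4, 0, params$phase_jitter)
  # canonical phases: elongation along x (HA2), tapering harmonics in
  # phase with it, which keeps the head convex (paddle-shaped)
  psi <- c(0, jit[1], jit[2], jit[3], jit[4])
  a <- c(0, amp[3:6] * cos(psi[2:5]))
  b <- c(0, amp[3:6] * sin(psi[2:5]))
  hs <- center_harmonics(harmonic_set(amp[1], a, b))
  if (rotation != 0) hs <- rotate_harmonics(hs, rotation)
  hs
}

#' Render one nucleus as a fluorescence image patch
#'
#' Rasterizes the interior of the outline `r(theta)` on a pixel grid (a
#' pixel belongs to the mask when its center lies inside the outline), fills
#' it with the nuclear intensity plus smooth chromatin-like texture,
#' convolves with a Gaussian point-spread function and adds Poisson shot
#' noise and Gaussian read noise.
#'
#' @param hs A [harmonic_set()] describing the outline (μm).
#' @param pose List with `center_px` (x, y pixel position of the outline
#'   pole, bottom-left origin; default patch center) and `rotation`
#'   (radians).
#' @param pixel_size_um Pixel size (μm/px); the nucleus must span at least
#'   20 px.
#' @param patch_px Patch side length in pixels (default: fits the nucleus
#'   plus PSF margin).
#' @param intensity_mean,intensity_sd Nuclear gray level and within-nucleus
#'   texture SD.
#' @param psf_sigma_um Gaussian PSF sigma (μm), default 0.15 (typical
#'   widefield).
#' @param read_noise_sd Gaussian read noise SD (gray levels).
#' @param shot_noise Add Poisson shot noise.
#' @param bit_depth Image bit depth (default 8).
#' @param rng_seed Optional seed; rendering is bit-identical for a fixed
#'   seed.
#' @return List with `image` (numeric matrix, gray levels), `mask` (logical
#'   matrix), `hs`, `pose`, `pixel_size_um`.
#' @export
render_nucleus <- function(hs, pose = list(center_px = NULL, rotation = 0),
                           pixel_size_um = 0.11, patch_px = NULL,
                           intensity_mean = 100, intensity_sd = 18,
                           psf_sigma_um = 0.15, read_noise_sd = 2,
                           shot_noise = TRUE, bit_depth = 8,
                           rng_seed = NULL) {
  stopifnot(pixel_size_um > 0)
  rot <- pose$rotation %||% 0
  hs_r <- if (rot != 0) rotate_harmonics(hs, rot) else hs
  th <- seq(0, 2 * pi, length.out = 720)
  rr <- eval_radius(hs_r, th)
  if (any(rr <= 0)) {
    stop("render_nucleus: radius function crosses zero (self-intersecting outline)")
  }
  rmax <- max(rr)
  if (2 * min(rr) / pixel_size_um < 20) {
    stop("render_nucleus: pixel size too coarse, nucleus spans < 20 px")
  }
  margin_um <- 4 * psf_sigma_um + 2 * pixel_size_um
  if (is.null(patch_px)) {
    patch_px <- 2L * as.integer(ceiling((rmax + margin_um) / pixel_size_um)) + 1L
  }
  ctr <- pose$center_px %||% c(patch_px / 2, patch_px / 2)
  if (ctr[1] * pixel_size_um - rmax < 0 || ctr[2] * pixel_size_um - rmax < 0 ||
      ctr[1] * pixel_size_um + rmax > patch_px * pixel_size_um ||
      ctr[2] * pixel_size_um + rmax > patch_px * pixel_size_um) {
    stop("render_nucleus: nucleus exceeds patch bounds")
  }
  mask <- rasterize_outline(hs_r, ctr, patch_px, patch_px, pixel_size_um)
  with_seed(rng_seed, {
    img <- synth_illuminate(mask * 1, intensity_mean, intensity_sd,
                            psf_sigma_um / pixel_size_um, read_noise_sd,
                            shot_noise, bit_depth)
    list(image = img, mask = mask, hs = hs, pose = list(center_px = ctr,
         rotation = rot), pixel_size_um = pixel_size_um)
  })
}

# Pixel-center rasterization of a star-shaped outline. Image rows run
# top-to-bottom; Cartesian y runs bottom-up: pixel (row, col) center is at
# ((col - 0.5) * px, (nrow - row + 0.5) * px).
rasterize_outline <- function(hs, center_px, nrow_px, ncol_px,
                              pixel_size_um) {
  cx <- (seq_len(ncol_px) - 0.5) * pixel_size_um - center_px[1] * pixel_size_um
  cy <- (nrow_px - seq_len(nrow_px) + 0.5) * pixel_size_um -
    center_px[2] * pixel_size_um
  dx <- matrix(cx, nrow_px, ncol_px, byrow = TRUE)
  dy <- matrix(cy, nrow_px, ncol_px)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rho <= matrix(eval_radius(hs, as.vector(theta)), nrow_px, ncol_px)
}

# Rasterize one outline into a local window of a larger field (bottom-left
# origin, y up). Returns the window row/col indices and the local mask.
rasterize_local <- function(hs, center_px, field_px, pixel_size_um,
                            r_max_um) {
  half <- as.integer(ceiling(r_max_um / pixel_size_um)) + 2L
  col_c <- center_px[1]
  row_c <- field_px - center_px[2] + 1
  cols <- max(1L, floor(col_c - half)):min(field_px, ceiling(col_c + half))
  rows <- max(1L, floor(row_c - half)):min(field_px, ceiling(row_c + half))
  cx <- (cols - 0.5) * pixel_size_um - center_px[1] * pixel_size_um
  cy <- (field_px - rows + 0.5) * pixel_size_um -
    center_px[2] * pixel_size_um
  dx <- matrix(cx, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(cy, length(rows), length(cols))
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  mask <- rho <= matrix(eval_radius(hs, as.vector(theta)), length(rows),
                        length(cols))
  list(rows = rows, cols = cols, mask = mask)
}

# Shared illumination/noise model: ideal intensity field -> observed image.
synth_illuminate <- function(ideal_mask_scaled, intensity_mean, intensity_sd,
                             psf_sigma_px, read_noise_sd, shot_noise,
                             bit_depth) {
  d <- dim(ideal_mask_scaled)
  ideal <- ideal_mask_scaled * intensity_mean
  if (intensity_sd > 0) {
    tex <- EBImage::gblur(matrix(stats::rnorm(prod(d)), d[1], d[2]),
                          sigma = 2)
    tex <- tex / stats::sd(as.vector(tex)) * intensity_sd
    ideal <- ideal + tex * (ideal_mask_scaled > 0)
  }
  optical <- EBImage::gblur(ideal, sigma = psf_sigma_px)
  optical[optical < 0] <- 0
  img <- if (shot_noise) {
    matrix(stats::rpois(prod(d), as.vector(optical)), d[1], d[2])
  } else optical
  img <- img + stats::rnorm(prod(d), 0, read_noise_sd)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 2^bit_depth - 1] <- 2^bit_depth - 1
  img
}

#' Generate a synthetic microscope field
#'
#' Places `n_nuclei` nuclei drawn from one shape population at random poses
#' in a field, by default without mask overlap; a requested fraction is
#' deliberately placed overlapping a neighbour to exercise downstream
#' quality-control rejection. Produces the fluorescence image, a
#' contrast-inverted phase-like image, a label image and a ground-truth
#' table.
#'
#' @param n_nuclei Number of nuclei (≥ 0).
#' @param params A `shape_params` object from [sample_shape_params()].
#' @param field_px Field side length in pixels (default sized from
#'   `n_nuclei`).
#' @param overlap_fraction Fraction of nuclei placed overlapping a
#'   neighbour, in `[0, 1]`.
#' @param pixel_size_um Pixel size (μm/px).
#' @param psf_sigma_um,read_noise_sd,bit_depth Imaging model parameters as
#'   in [render_nucleus()].
#' @param max_attempts Placement attempts per nucleus before giving up.
#' @param rng_seed Optional seed (field is deterministic given the seed).
#' @return An object of class `synthetic_field`: list with `fluorescence`,
#'   `phase`, `labels` (integer matrix), `truth` (data frame: label,
#'   centroid_x_px, centroid_y_px, rotation_rad, overlap_flag, HA0..HA5,
#'   c0, a1..b5), `harmonics` (list of [harmonic_set()]), `pixel_size_um`.
#' @export
generate_field <- function(n_nuclei, params, field_px = NULL,
                           overlap_fraction = 0, pixel_size_um = 0.11,
                           psf_sigma_um = 0.15, read_noise_sd = 2,
                           bit_depth = 8, max_attempts = 400,
                           rng_seed = NULL) {
  stopifnot(n_nuclei >= 0, overlap_fraction >= 0, overlap_fraction <= 1)
  with_seed(rng_seed, {
    nominal_r <- params$ha_means[1] + sum(params$ha_means[-1])
    if (is.null(field_px)) {
      field_px <- max(64L, as.integer(ceiling(
        sqrt(max(n_nuclei, 1)) * 3.2 * nominal_r / pixel_size_um)))
    }
    labels <- matrix(0L, field_px, field_px)
    ideal_scale <- matrix(0, field_px, field_px)
    truth <- list()
    hs_list <- list()
    pos <- matrix(numeric(0), 0, 2)
    rad <- numeric(0)
    n_overlap <- round(overlap_fraction * n_nuclei)
    overlap_ids <- if (n_overlap > 0) {
      seq(n_nuclei - n_overlap + 1L, n_nuclei)
    } else integer(0)
    for (i in seq_len(n_nuclei)) {
      rot <- stats::runif(1, 0, 2 * pi)
      hs <- draw_nucleus(params, rotation = rot)
      r_i <- max(eval_radius(hs, seq(0, 2 * pi, length.out = 360)))
      margin <- (r_i + 4 * psf_sigma_um) / pixel_size_um + 2
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        if (i %in% overlap_ids && nrow(pos) > 0) {
          j <- sample.int(nrow(pos), 1)
          ang <- stats::runif(1, 0, 2 * pi)
          d_px <- stats::runif(1, 0.5, 0.8) * (rad[j] + r_i) / pixel_size_um
          cand <- pos[j, ] + d_px * c(cos(ang), sin(ang))
          ok_sep <- TRUE
        } else {
          cand <- stats::runif(2, margin, field_px - margin)
          ok_sep <- nrow(pos) == 0 || all(
            sqrt(colSums((t(pos) - cand)^2)) * pixel_size_um >
              (rad + r_i) + 2 * pixel_size_um)
        }
        in_bounds <- all(cand > margin) && all(cand < field_px - margin)
        if (ok_sep && in_bounds) {
          pos <- rbind(pos, cand)
          rad <- c(rad, r_i)
          loc <- rasterize_local(hs, cand, field_px, pixel_size_um, r_i)
          sub <- labels[loc$rows, loc$cols]
          sub[loc$mask] <- i
          labels[loc$rows, loc$cols] <- sub
          sub <- ideal_scale[loc$rows, loc$cols]
          sub[loc$mask] <- 1
          ideal_scale[loc$rows, loc$cols] <- sub
          hs_list[[i]] <- hs
          truth[[i]] <- data.frame(
            label = i, centroid_x_px = cand[1], centroid_y_px = cand[2],
            rotation_rad = rot, overlap_flag = i %in% overlap_ids,
            as.list(stats::setNames(hs$amplitudes, paste0("HA", 0:5))),
            c0 = hs$c0,
            as.list(stats::setNames(c(hs$a, hs$b),
                                    c(paste0("a", 1:5), paste0("b", 1:5)))))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "generate_field: could not place nucleus %d of %d (placed %d)",
          i, n_nuclei, nrow(pos)))
      }
    }
    # mark the partners of deliberately overlapped nuclei
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(label = integer(0), centroid_x_px = numeric(0),
                 centroid_y_px = numeric(0), rotation_rad = numeric(0),
                 overlap_flag = logical(0))
    if (length(overlap_ids) && nrow(truth_df) > 0) {
      for (i in overlap_ids) {
        d <- sqrt((truth_df$centroid_x_px - truth_df$centroid_x_px[i])^2 +
                  (truth_df$centroid_y_px - truth_df$centroid_y_px[i])^2)
        d[i] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) &&
            d[j] * pixel_size_um < rad[i] + rad[j]) {
          truth_df$overlap_flag[j] <- TRUE
        }
      }
    }
    tex_sd <- params$texture_sd %||% (0.68 * params$intensity_sd)
    fluor <- synth_illuminate(ideal_scale, params$intensity_mean, tex_sd,
                              psf_sigma_um / pixel_size_um, read_noise_sd,
                              TRUE, bit_depth)
    phase <- phase_like(ideal_scale, params$intensity_mean,
                        psf_sigma_um / pixel_size_um, bit_depth)
    structure(list(fluorescence = fluor, phase = phase, labels = labels,
                   truth = truth_df, harmonics = hs_list,
                   pixel_size_um = pixel_size_um, params = params),
              class = "synthetic_field")
  })
}

# Contrast-inverted, halo-blurred phase-contrast-like rendering.
phase_like <- function(ideal_scale, intensity_mean, psf_sigma_px,
                       bit_depth) {
  bg <- 0.75 * (2^bit_depth - 1)
  halo <- EBImage::gblur(ideal_scale, sigma = 3 * psf_sigma_px)
  body <- EBImage::gblur(ideal_scale, sigma = psf_sigma_px)
  img <- bg + 0.15 * bg * halo - 0.55 * bg * body +
    stats::rnorm(length(ideal_scale), 0, 2)
  img <- round(img)
  img[img < 0] <- 0
  img[img > 2^bit_depth - 1] <- 2^bit_depth - 1
  matrix(img, nrow(ideal_scale), ncol(ideal_scale))
}

#' Generate a synthetic two-group ram cohort
#'
#' Emulates the study design: `n_af` adequate-fertility and `n_lf`
#' low-fertility rams with `sperm_per_ram` nuclei each. Per-ram harmonic
#' amplitude means are drawn around the group means with between-ram spread
#' `SEM * sqrt(n_rams)`; per-sperm amplitudes around the ram means with
#' within-ram spread `SEM * sqrt(100)`; conception rates are drawn to match
#' the published group means and dispersions. The groups are separable
#' chiefly through HA2 (elongation), with a secondary intensity difference.
#'
#' @param n_af,n_lf Number of rams per group (defaults 47 and 9, the shape
#'   cohort).
#' @param sperm_per_ram Nuclei per ram (default 100).
#' @param output `"perimeters"` returns analytic ground-truth outlines as
#'   [perimeter_trace()] objects; `"images"` additionally renders one
#'   fluorescence field per ram.
#' @param pixel_size_um Pixel size used for rendered fields.
#' @param n_vertices Vertices per analytic outline.
#' @param rng_seed Seed; the cohort is a pure function of it.
#' @param ... Further arguments passed to [generate_field()] when
#'   `output = "images"`.
#' @return An object of class `synthetic_cohort`: list with `fertility`
#'   (data frame: ram_id, conception_rate, group), `truth` (one row per
#'   nucleus: ram_id, group, label, HA0..HA5, intensity_mean), `traces`
#'   (list of [perimeter_trace()], `output = "perimeters"`) or `fields`
#'   (named list of `synthetic_field`), and `ram_params`.
#' @export
generate_cohort <- function(n_af = 47, n_lf = 9, sperm_per_ram = 100,
                            output = c("perimeters", "images"),
                            pixel_size_um = 0.11, n_vertices = 256,
                            rng_seed = 1, ...) {
  stopifnot(n_af >= 1, n_lf >= 1, sperm_per_ram >= 1)
  output <- match.arg(output)
  with_seed(rng_seed, {
    rams <- data.frame(
      ram_id = c(sprintf("AF%02d", seq_len(n_af)),
                 sprintf("LF%02d", seq_len(n_lf))),
      group = rep(c("AF", "LF"), c(n_af, n_lf)),
      stringsAsFactors = FALSE)
    traces <- list()
    fields <- list()
    truth <- vector("list", nrow(rams))
    ram_rows <- vector("list", nrow(rams))
    for (ri in seq_len(nrow(rams))) {
      g <- rams$group[ri]
      pop <- sample_shape_params(g, n_sperm = sperm_per_ram)
      fert <- .FERTILITY_TABLE[[g]]
      rate <- min(100, max(0, stats::rnorm(1, fert$mean,
                                           fert$sem * sqrt(fert$n))))
      ram_mu <- pmax(stats::rnorm(6, pop$ha_means, pop$ha_ram_sds), 0.001)
      ram_int <- max(10, stats::rnorm(1, pop$intensity_mean,
                                      pop$intensity_ram_sd))
      ram_int_sd <- max(2, stats::rnorm(1, pop$intensity_sd,
                                        pop$intensity_sd_ram_sd))
      ram_pop <- pop
      ram_pop$ha_means <- stats::setNames(ram_mu, paste0("HA", 0:5))
      ram_pop$intensity_mean <- ram_int
      ram_pop$intensity_sd <- ram_int_sd
      ram_pop$texture_sd <- 0.68 * ram_int_sd
      ram_rows[[ri]] <- data.frame(
        ram_id = rams$ram_id[ri], group = g, conception_rate = rate,
        intensity_mean = ram_int,
        as.list(stats::setNames(ram_mu, paste0("mu_HA", 0:5))))
      if (output == "perimeters") {
        nuc <- vector("list", sperm_per_ram)
        for (si in seq_len(sperm_per_ram)) {
          hs <- draw_nucleus(ram_pop)
          poly <- harmonic_polygon(hs, n = n_vertices)
          # per-nucleus intensity statistics as they would be observed over
          # ~2000 member pixels of a rendered nucleus
          npx_eff <- 2000
          obs_mean <- stats::rnorm(1, ram_int,
                                   ram_int_sd / sqrt(npx_eff))
          obs_sd <- ram_int_sd *
            sqrt(stats::rchisq(1, npx_eff - 1) / (npx_eff - 1))
          nuc[[si]] <- data.frame(
            ram_id = rams$ram_id[ri], group = g, label = si,
            as.list(stats::setNames(hs$amplitudes, paste0("HA", 0:5))),
            intensity_mean = obs_mean, intensity_sd = obs_sd)
          traces[[length(traces) + 1L]] <- perimeter_trace(
            poly$x, poly$y, ram_id = rams$ram_id[ri], label = si)
        }
        truth[[ri]] <- do.call(rbind, nuc)
      } else {
        fld <- generate_field(sperm_per_ram, ram_pop,
                              pixel_size_um = pixel_size_um, ...)
        fields[[rams$ram_id[ri]]] <- fld
        tr <- fld$truth
        tr <- data.frame(ram_id = rams$ram_id[ri], group = g,
                         label = tr$label,
                         tr[paste0("HA", 0:5)],
                         intensity_mean = ram_int,
                         centroid_x_px = tr$centroid_x_px,
                         centroid_y_px = tr$centroid_y_px,
                         overlap_flag = tr$overlap_flag)
        truth[[ri]] <- tr
      }
    }
    fertility <- do.call(rbind, lapply(ram_rows, function(d)
      d[c("ram_id", "conception_rate", "group")]))
    structure(list(
      fertility = fertility,
      truth = do.call(rbind, truth),
      traces = if (output == "perimeters") traces else NULL,
      fields = if (output == "images") fields else NULL,
      ram_params = do.call(rbind, ram_rows),
      pixel_size_um = if (output == "images") pixel_size_um else NA_real_
    ), class = "synthetic_cohort")
  })
}
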