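# End-to-end orchestration: simulate (or load) -> segment -> measure ->
# harmonic analysis -> per-ram summaries -> fertility classification.

#' Build a validated pipeline configuration
#'
#' All tunable constants of the pipeline in one serializable list. Every
#' source of randomness flows from the single `seed`.
#'
#' @param seed Integer seed.
#' @param simulate Generate a synthetic cohort (`TRUE`) or read inputs from
#'   `traces_csv` / `fertility_csv`.
#' @param n_af,n_lf,sperm_per_ram Cohort design (defaults 47, 9, 100).
#' @param cohort_output `"perimeters"` (analytic outlines) or `"images"`
#'   (rendered fields, segmented back).
#' @param pixel_size_um Pixel size for rendered fields (default 0.11).
#' @param bit_depth Image bit depth (default 8; recorded in outputs).
#' @param sigma_um LoG scale for segmentation.
#' @param min_area_um2,max_area_um2,solidity_min Object QC gates.
#' @param M,K Polar samples and highest harmonic for the Fourier fit.
#' @param entry_p,stay_p Stepwise selection thresholds.
#' @param priors Named classification priors (default equal).
#' @param features Optional fixed feature list; skips stepwise selection.
#' @param traces_csv,fertility_csv Input paths when `simulate = FALSE`.
#' @param outdir Optional output directory for artifacts and the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = TRUE, n_af = 47, n_lf = 9,
                            sperm_per_ram = 100,
                            cohort_output = c("perimeters", "images"),
                            pixel_size_um = 0.11, bit_depth = 8,
                            sigma_um = 0.3, min_area_um2 = 10,
                            max_area_um2 = 80, solidity_min = 0.92,
                            M = 128, K = 5, entry_p = 0.15, stay_p = 0.15,
                            priors = c(AF = 0.5, LF = 0.5),
                            features = NULL, traces_csv = NULL,
                            fertility_csv = NULL, outdir = NULL) {
  cohort_output <- match.arg(cohort_output)
  stopifnot(pixel_size_um > 0, sigma_um > 0, M >= 2 * K + 1, K >= 1,
            entry_p > 0, entry_p < 1, stay_p > 0, stay_p < 1,
            min_area_um2 > 0, max_area_um2 > min_area_um2,
            solidity_min > 0, solidity_min <= 1,
            bit_depth %in% c(8, 12, 16))
  if (!simulate && (is.null(traces_csv) || is.null(fertility_csv))) {
    stop("pipeline_config: traces_csv and fertility_csv are required when ",
         "simulate = FALSE")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full shape-analysis pipeline
#'
#' Chains the stages: synthetic cohort generation (or CSV input), nucleus
#' segmentation (images mode), morphometrics, harmonic amplitude analysis,
#' per-ram summaries, fertility grouping by the one-SD rule, stepwise
#' discriminant selection, model fit and leave-one-out cross-validation.
#' Rerunning with the same configuration reproduces identical results.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `fertility` (with assigned
#'   groups and the cutoff), `harmonics` (per-nucleus), `summary` (per-ram
#'   feature matrix), `selection` (stepwise trace), `model`, `cv`, `report`,
#'   plus `truth` and segmentation diagnostics for synthetic runs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- NULL
  seg_stats <- NULL
  if (config$simulate) {
    cohort <- generate_cohort(config$n_af, config$n_lf,
                              config$sperm_per_ram,
                              output = config$cohort_output,
                              pixel_size_um = config$pixel_size_um,
                              rng_seed = config$seed)
    fertility <- cohort$fertility[c("ram_id", "conception_rate")]
    if (config$cohort_output == "perimeters") {
      traces <- cohort$traces
      harmonics <- fha_table(traces, M = config$M, K = config$K)
      geo <- do.call(rbind, lapply(traces, polygon_morpho))
      geo$ram_id <- vapply(traces, `[[`, character(1), "ram_id")
      intens <- cohort$truth[c("ram_id", "label", "intensity_mean",
                               "intensity_sd")]
      records <- merge(geo, intens, by = c("ram_id", "label"))
      morpho_sum <- summarize_morpho(records)
    } else {
      per_ram <- lapply(names(cohort$fields), function(rid) {
        fld <- cohort$fields[[rid]]
        seg <- segment_field(fld$fluorescence, config$pixel_size_um,
                             ram_id = rid, sigma_um = config$sigma_um,
                             min_area_um2 = config$min_area_um2,
                             max_area_um2 = config$max_area_um2,
                             solidity_min = config$solidity_min)
        rec <- measure_objects(seg$objects, fld$fluorescence,
                               config$pixel_size_um, traces = seg$traces)
        if (!is.null(rec)) rec$ram_id <- rid
        list(traces = seg$traces, records = rec,
             n_objects = length(seg$objects),
             n_accepted = length(seg$traces))
      })
      traces <- do.call(c, lapply(per_ram, `[[`, "traces"))
      records <- do.call(rbind, lapply(per_ram, `[[`, "records"))
      seg_stats <- data.frame(
        ram_id = names(cohort$fields),
        n_objects = vapply(per_ram, `[[`, integer(1), "n_objects"),
        n_accepted = vapply(per_ram, `[[`, integer(1), "n_accepted"))
      harmonics <- fha_table(traces, M = config$M, K = config$K)
      morpho_sum <- summarize_morpho(records)
    }
  } else {
    traces <- read_traces(config$traces_csv)
    fertility <- read_fertility(config$fertility_csv)
    harmonics <- fha_table(traces, M = config$M, K = config$K)
    geo <- do.call(rbind, lapply(traces, polygon_morpho))
    geo$ram_id <- vapply(traces, `[[`, character(1), "ram_id")
    morpho_sum <- summarize_morpho(geo)
  }
  summary_df <- summarize_ram(harmonics, morpho = morpho_sum)
  if (!is.null(config$features)) {
    missing <- setdiff(config$features, names(summary_df))
    if (length(missing)) {
      stop("run_pipeline: unknown feature(s): ",
           paste(missing, collapse = ", "))
    }
  }
  groups <- threshold_groups(fertility)
  merged <- merge(summary_df, groups$records[c("ram_id", "group")],
                  by = "ram_id")
  feat_cols <- setdiff(names(merged)[vapply(merged, is.numeric,
                                            logical(1))],
                       c("n_sperm", "n_nuclei"))
  X <- merged[feat_cols]
  y <- merged$group
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("run_pipeline: fertility thresholding produced fewer than 2 rams ",
         "in a group; cannot fit a discriminant model")
  }
  if (is.null(config$features)) {
    sel <- stepwise_select(X, y, entry_p = config$entry_p,
                           stay_p = config$stay_p)
  } else {
    sel <- list(selected = config$features,
                trace = data.frame(round = integer(0)))
  }
  if (length(sel$selected)) {
    model <- fit_lda(X[sel$selected], y, priors = config$priors)
    cv <- loo_crossvalidate(X[sel$selected], y, priors = config$priors)
  } else {
    model <- NULL
    maj <- names(which.max(table(y)))
    cv <- confusion_metrics(sum(y == "AF") * (maj == "AF"), sum(y == "AF"),
                            sum(y == "LF") * (maj == "LF"), sum(y == "LF"))
  }
  rep <- fertility_report(model, cv,
                          summaries = list(cutoff = groups$cutoff),
                          out_dir = config$outdir)
  result <- structure(list(
    fertility = groups$records, cutoff = groups$cutoff,
    harmonics = harmonics, morpho = morpho_sum, summary = merged,
    selection = sel, model = model, cv = cv, report = rep$json,
    truth = if (!is.null(cohort)) cohort$truth else NULL,
    segmentation = seg_stats, config = config
  ), class = "pipeline_result")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_traces(traces, file.path(config$outdir, "traces.csv"))
    write_features(merged, file.path(config$outdir, "features.csv"))
    write_fertility(groups$records,
                    file.path(config$outdir, "fertility.csv"))
    utils::write.csv(harmonics,
                     file.path(config$outdir, "harmonics.csv"),
                     row.names = FALSE)
    write_manifest(config, config$outdir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Sperm shape pipeline result:", nrow(x$summary), "rams\n")
  cat(sprintf("  fertility cutoff %.1f%% (AF %d / LF %d)\n", x$cutoff,
              sum(x$fertility$group == "AF"),
              sum(x$fertility$group == "LF")))
  if (!is.null(x$model)) {
    cat("  selected:", paste(x$model$features, collapse = ", "), "\n")
  } else {
    cat("  null model (no variable met the entry criterion)\n")
  }
  print(x$cv)
  invisible(x)
}

# Manifest: configuration, package version, seed and file checksums, so a
# run can be audited and reproduced.
write_manifest <- function(config, outdir) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  path <- file.path(outdir, "manifest.json")
  files <- setdiff(list.files(outdir, full.names = TRUE), path)
  jsonlite::write_json(list(
    package = "spermshape",
    version = as.character(utils::packageVersion("spermshape")),
    seed = config$seed,
    config = cfg,
    files = as.list(tools::md5sum(files))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Evaluate ground-truth recovery through the imaging pipeline
#'
#' For a cohort generated with `output = "images"`, segments every field,
#' matches accepted outlines to the ground-truth nuclei by centroid
#' proximity, and returns measured vs true harmonic amplitudes per matched
#' nucleus.
#'
#' @param cohort A `synthetic_cohort` from
#'   [generate_cohort()]`(output = "images")`.
#' @param M,K Polar samples and highest harmonic for the fit.
#' @param match_radius_px Maximum centroid distance for a truth match.
#' @param ... Passed to [segment_field()].
#' @return Data frame with one row per matched nucleus: `ram_id`, `label`,
#'   true `HA0..HAK` (`true_HAk`), measured `HAk`, and centroid distance
#'   `match_px`.
#' @export
evaluate_recovery <- function(cohort, M = 128, K = 5, match_radius_px = 10,
                              ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"), !is.null(cohort$fields))
  px <- cohort$pixel_size_um
  out <- list()
  for (rid in names(cohort$fields)) {
    fld <- cohort$fields[[rid]]
    seg <- segment_field(fld$fluorescence, px, ram_id = rid, ...)
    if (!length(seg$traces)) next
    ht <- fha_table(seg$traces, M = M, K = K)
    if (is.null(ht) || nrow(ht) == 0) next
    ctrs <- t(vapply(seg$traces, function(tr)
      polygon_centroid(tr$x, tr$y) / px, numeric(2)))
    ctrs <- ctrs[match(ht$label, vapply(seg$traces, `[[`, integer(1),
                                        "label")), , drop = FALSE]
    tru <- fld$truth
    for (i in seq_len(nrow(ht))) {
      d <- sqrt((tru$centroid_x_px - ctrs[i, 1])^2 +
                  (tru$centroid_y_px - ctrs[i, 2])^2)
      j <- which.min(d)
      if (d[j] <= match_radius_px) {
        row <- data.frame(ram_id = rid, label = ht$label[i],
                          match_px = d[j])
        for (k in 0:K) {
          row[[paste0("true_HA", k)]] <- tru[[paste0("HA", k)]][j]
          row[[paste0("HA", k)]] <- ht[[paste0("HA", k)]][i]
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
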