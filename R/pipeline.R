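#' Convert mmHg to kPa
#' @param x pressure in mmHg.
#' @return pressure in kPa.
#' @export
mmhg_to_kpa <- function(x) x * 0.133322

#' Morphology + cap mechanics predictors for one slice
#'
#' Runs the full per-slice chain: Four-Quarter Even-Spacing samples and
#' cap thickness on the in-vivo contours, zero-load recovery by
#' circumferential shrink search at the loading pressure, final FE solve,
#' and wall stress/strain extraction at the sample points.
#'
#' @param slice in-vivo [slice_contours()] (with pressure_mmHg).
#' @param materials material map.
#' @param pressure_choice "sys" (default; stress/strain under maximum
#'   pressure) or "dia".
#' @param element_size final-solve mesh size (mm).
#' @param search controls for the shrink search: list(element_size,
#'   n_increments, method, tol).
#' @param n_increments final-solve load increments.
#' @param n_points lumen sample count.
#' @return One-row data frame: slice_id, patient_id, timepoint, LA, PA,
#'   PB, MinCapT, MeanCapT, MaxCapS, MeanCapS, MaxCapSn, MeanCapSn,
#'   circ_shrink, shrink_area_error.
#' @export
slice_features <- function(slice, materials = default_materials(),
                           pressure_choice = c("sys", "dia"),
                           element_size = 0.22,
                           search = list(element_size = 0.35,
                                         n_increments = 3L,
                                         method = "illinois", tol = 0.01),
                           n_increments = 4L, n_points = 100L) {
  pressure_choice <- match.arg(pressure_choice)
  stopifnot(!is.null(slice$pressure_mmHg))
  p_kpa <- mmhg_to_kpa(slice$pressure_mmHg[[pressure_choice]])
  morph <- morphology(slice, n_points)
  cs <- cap_samples(slice, n_points)
  if (length(slice$lipids)) cs <- cap_thickness_profile(slice, cs)
  sr <- find_circ_shrink(slice, materials, pressure = p_kpa,
                         tol = search$tol %||% 0.01,
                         element_size = search$element_size %||% 0.35,
                         n_increments = search$n_increments %||% 3L,
                         method = search$method %||% "illinois")
  mesh <- build_mesh(sr$shrunk, element_size = element_size)
  sol <- solve_slice(mesh, materials, pressure = p_kpa,
                     axial_stretch = 1 / (1 - sr$axial_shrink),
                     n_increments = n_increments)
  cs <- extract_cap_mechanics(sol, cs)
  agg <- cap_aggregates(cs)
  cbind(morph[, c("slice_id", "patient_id", "timepoint", "LA", "PA", "PB")],
        agg[, c("MinCapT", "MeanCapT", "MaxCapS", "MeanCapS",
                "MaxCapSn", "MeanCapSn")],
        data.frame(circ_shrink = sr$circ_shrink,
                   shrink_area_error = sr$achieved_lumen_area_error))
}

#' Predictor tables for a matched cohort
#'
#' Applies [slice_features()] to every baseline slice (and follow-up
#' slices when `timepoints = "both"`).
#'
#' @param pairs list of baseline/follow-up pairs from [generate_cohort()].
#' @param timepoints "both" or "baseline".
#' @param progress print a line every 10 slices.
#' @param ... forwarded to [slice_features()].
#' @return Data frame of per-slice features (one row per slice and
#'   timepoint).
#' @export
cohort_features <- function(pairs, timepoints = c("both", "baseline"),
                            progress = FALSE, ...) {
  timepoints <- match.arg(timepoints)
  rows <- list()
  for (i in seq_along(pairs)) {
    rows[[length(rows) + 1L]] <- slice_features(pairs[[i]]$baseline, ...)
    if (timepoints == "both") {
      rows[[length(rows) + 1L]] <- slice_features(pairs[[i]]$followup, ...)
    }
    if (progress && i %% 10L == 0L) {
      message("processed ", i, "/", length(pairs), " slice pairs")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

PVI_MEASURES <- c(C = "MinCapT", MaxS = "MaxCapS", MeanS = "MeanCapS",
                  MaxSn = "MaxCapSn", MeanSn = "MeanCapSn")

#' Binary PVI-change outcomes for a cohort feature table
#'
#' Scores the chosen index at baseline and follow-up and derives the
#' change and its binary outcome per matched slice.
#'
#' @param features output of [cohort_features()] with both timepoints
#'   (for the C index, follow-up rows may carry morphology only).
#' @param index one of "C", "MaxS", "MeanS", "MaxSn", "MeanSn".
#' @param thresholds a [pvi_thresholds()]; defaults to the published cuts.
#' @return Data frame: slice_id, baseline and follow-up categories,
#'   delta, binary.
#' @export
pvi_outcomes <- function(features, index = "C",
                         thresholds = pvi_thresholds(index)) {
  measure <- PVI_MEASURES[[index]]
  bl <- features[features$timepoint == "baseline", ]
  fu <- features[features$timepoint == "followup", ]
  m <- merge(bl[, c("slice_id", measure)], fu[, c("slice_id", measure)],
             by = "slice_id", suffixes = c("_bl", "_fu"))
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  cb <- score_pvi(m[[paste0(measure, "_bl")]], thresholds)
  cf <- score_pvi(m[[paste0(measure, "_fu")]], thresholds)
  db <- delta_binary(cb, cf)
  data.frame(slice_id = m$slice_id, baseline = cb, followup = cf,
             delta = db$delta, binary = db$binary)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates synthesis -> morphology + mechanics -> PVI scoring ->
#' random-forest prediction for a synthetic cohort.
#'
#' @param spec a [cohort_spec()] (or a pre-generated pairs list).
#' @param indices PVIs to analyse (default "C"; stress/strain indices
#'   require follow-up mechanics and are proportionally slower).
#' @param thresholds_mode "published" (fixed cuts) or "calibrate"
#'   (stress/strain cuts calibrated against baseline C-PVI labels).
#' @param sweep if TRUE, run the full predictor-combination sweep per
#'   index; otherwise evaluate the full nine-predictor set only.
#' @param n_repeats CV repeats for the forests.
#' @param seed integer seed for the prediction stage.
#' @param feature_args list of arguments forwarded to [slice_features()].
#' @param progress verbosity.
#' @return List: `features`, `thresholds`, per-index `outcomes`,
#'   `tables`, `results`.
#' @export
run_pipeline <- function(spec = cohort_spec(), indices = "C",
                         thresholds_mode = c("published", "calibrate"),
                         sweep = FALSE, n_repeats = 20L, seed = 1L,
                         feature_args = list(), progress = FALSE) {
  thresholds_mode <- match.arg(thresholds_mode)
  stopifnot(all(indices %in% names(PVI_MEASURES)))
  pairs <- if (inherits(spec, "cohort_spec")) generate_cohort(spec) else spec
  tp <- if (identical(indices, "C")) "baseline" else "both"
  features <- do.call(cohort_features,
                      c(list(pairs = pairs, timepoints = tp,
                             progress = progress), feature_args))
  if (tp == "baseline") {
    # follow-up morphology (cap thickness) is enough to score C-PVI change
    fu <- do.call(rbind, lapply(pairs, function(p) {
      morphology(p$followup)
    }))
    fu[, c("MaxCapS", "MeanCapS", "MaxCapSn", "MeanCapSn",
           "circ_shrink", "shrink_area_error")] <- NA_real_
    features <- rbind(features, fu[, colnames(features)])
  }
  bl <- features[features$timepoint == "baseline", ]
  thresholds <- list(C = pvi_thresholds("C"))
  c_labels <- score_pvi(bl$MinCapT[is.finite(bl$MinCapT)], thresholds$C)
  for (idx in setdiff(indices, "C")) {
    thresholds[[idx]] <- if (thresholds_mode == "calibrate") {
      vals <- bl[[PVI_MEASURES[[idx]]]]
      ok <- is.finite(vals) & is.finite(bl$MinCapT)
      calibrate_thresholds(vals[ok], score_pvi(bl$MinCapT[ok], thresholds$C),
                           index_name = idx)
    } else {
      pvi_thresholds(idx)
    }
  }
  outcomes <- tables <- results <- list()
  for (idx in indices) {
    outcomes[[idx]] <- pvi_outcomes(features, idx, thresholds[[idx]])
    morph_bl <- bl[, c("slice_id", "patient_id", "timepoint",
                       "LA", "PA", "PB", "MinCapT", "MeanCapT")]
    mech_bl <- bl[, c("slice_id", "MaxCapS", "MeanCapS",
                      "MaxCapSn", "MeanCapSn")]
    ids <- intersect(morph_bl$slice_id, outcomes[[idx]]$slice_id)
    tables[[idx]] <- assemble_features(
      morph_bl[morph_bl$slice_id %in% ids, ],
      mech_bl[mech_bl$slice_id %in% ids, ],
      outcomes[[idx]][outcomes[[idx]]$slice_id %in% ids, ])
    results[[idx]] <- if (sweep) {
      sweep_combinations(tables[[idx]], seed = seed, n_repeats = n_repeats)
    } else {
      pr <- cross_validated_probabilities(tables[[idx]],
                                          n_repeats = n_repeats, seed = seed)
      m <- metrics(pr, tables[[idx]]$target)
      m$predictor_subset <- paste(PREDICTOR_NAMES, collapse = " + ")
      m$n_predictors <- length(PREDICTOR_NAMES)
      m
    }
  }
  list(features = features, thresholds = thresholds, outcomes = outcomes,
       tables = tables, results = results)
}
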