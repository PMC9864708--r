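#' Plaque vulnerability index threshold sets
#'
#' Interval cuts defining the ordinal 1-4 vulnerability categories. For the
#' cap-thickness index (C) *lower* values are more vulnerable: category 4
#' is the thinnest-cap interval (0, 0.20] mm. For stress (MaxS, MeanS) and
#' strain (MaxSn, MeanSn) indices *higher* values are more vulnerable.
#' Defaults are the published interval divisions: C (0.20, 0.26, 0.36) mm;
#' MaxS (80, 101, 110) kPa; MeanS (70, 88, 93) kPa; MaxSn (0.17, 0.18,
#' 0.2); MeanSn (0.18, 0.2, 0.21).
#'
#' @param index_name one of "C", "MaxS", "MeanS", "MaxSn", "MeanSn".
#' @param cuts three strictly ascending cut values (mm, kPa, or unitless).
#' @return A `pvi_thresholds` list with `orientation` derived from the
#'   index ("lower_is_vulnerable" for C, "higher_is_vulnerable" otherwise).
#' @export
pvi_thresholds <- function(index_name = c("C", "MaxS", "MeanS", "MaxSn", "MeanSn"),
                           cuts = NULL) {
  index_name <- match.arg(index_name)
  defaults <- list(C = c(0.20, 0.26, 0.36),
                   MaxS = c(80, 101, 110),
                   MeanS = c(70, 88, 93),
                   MaxSn = c(0.17, 0.18, 0.2),
                   MeanSn = c(0.18, 0.2, 0.21))
  cuts <- cuts %||% defaults[[index_name]]
  if (length(cuts) != 3L || any(diff(cuts) <= 0)) {
    stop("cuts must be 3 strictly ascending values")
  }
  structure(list(index_name = index_name, cuts = as.numeric(cuts),
                 orientation = if (index_name == "C") {
                   "lower_is_vulnerable"
                 } else {
                   "higher_is_vulnerable"
                 }),
            class = "pvi_thresholds")
}

#' Score a measurement into a PVI category 1-4
#'
#' Interval closure follows the printed definitions: right-closed
#' intervals. For C: (0.36, 2) -> 1, (0.26, 0.36] -> 2, (0.20, 0.26] -> 3,
#' (0, 0.20] -> 4; cap thicknesses at or above 2 mm are scored 1 with a
#' warning (sanity bound). For stress/strain: at or below the first cut
#' -> 1, then (c1, c2] -> 2, (c2, c3] -> 3, above the last cut -> 4.
#'
#' @param value measurement(s) in the index's units; vectorised.
#' @param thresholds a [pvi_thresholds()] object.
#' @return Integer vector of categories in 1..4.
#' @export
score_pvi <- function(value, thresholds) {
  stopifnot(inherits(thresholds, "pvi_thresholds"))
  if (any(!is.finite(value))) stop("non-finite measurement")
  cuts <- thresholds$cuts
  if (thresholds$orientation == "lower_is_vulnerable") {
    if (any(value <= 0)) stop("non-positive cap thickness")
    if (any(value >= 2)) {
      warning("cap thickness at or above the 2 mm sanity bound; scored 1")
    }
    # value in (c3, Inf) -> 1 ... (0, c1] -> 4
    idx <- 4L - findInterval(value, cuts, left.open = TRUE)
  } else {
    # value in (-Inf, c1] -> 1 ... (c3, Inf) -> 4
    idx <- 1L + findInterval(value, cuts, left.open = TRUE)
  }
  as.integer(idx)
}

#' Calibrate stress/strain PVI cuts against the cap-thickness index
#'
#' Chooses the three interval cuts whose induced categories best match the
#' given C-PVI labels (maximum exact-agreement fraction), by exhaustive
#' search over ordered triples of candidate cuts (midpoints between
#' consecutive sorted unique values). Ties are broken by (a) larger
#' minimum category occupancy, then (b) lexicographically smallest cut
#' vector.
#'
#' @param values measurements (kPa or unitless strain), one per slice.
#' @param c_pvi_labels C-PVI categories 1-4, same length.
#' @param index_name which stress/strain index the cuts are for.
#' @return A [pvi_thresholds()] with attributes `match_rate` and
#'   `n_candidates`.
#' @export
calibrate_thresholds <- function(values, c_pvi_labels,
                                 index_name = c("MaxS", "MeanS", "MaxSn", "MeanSn")) {
  index_name <- match.arg(index_name)
  stopifnot(length(values) == length(c_pvi_labels),
            all(c_pvi_labels %in% 1:4))
  if (length(values) < 4L || length(unique(c_pvi_labels)) < 2L) {
    stop("need >= 4 slices spanning >= 2 C-PVI categories")
  }
  uv <- sort(unique(values))
  if (length(uv) < 2L) stop("all values identical; cannot calibrate")
  cand <- (uv[-1L] + uv[-length(uv)]) / 2
  o <- order(values)
  lab <- c_pvi_labels[o]
  n <- length(lab)
  # prefix counts of each category along the sorted values
  pref <- sapply(1:4, function(k) cumsum(lab == k))
  pref <- rbind(0, pref)
  # position of each candidate cut in the sorted order: values <= cut
  pos <- findInterval(cand, sort(values))
  np <- length(pos)
  if (np < 3L) stop("too few distinct values to place 3 cuts")
  trip <- combn(np, 3L)
  i <- pos[trip[1L, ]]; j <- pos[trip[2L, ]]; k <- pos[trip[3L, ]]
  # category of a sorted value: 1 below first cut ... 4 above last
  score <- pref[i + 1L, 1L] +
    (pref[j + 1L, 2L] - pref[i + 1L, 2L]) +
    (pref[k + 1L, 3L] - pref[j + 1L, 3L]) +
    (pref[n + 1L, 4L] - pref[k + 1L, 4L])
  occ <- pmin(pmin(i, j - i), pmin(k - j, n - k))
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[occ[best] == max(occ[best])]
  if (length(best) > 1L) {
    cuts_mat <- rbind(cand[trip[1L, best]], cand[trip[2L, best]],
                      cand[trip[3L, best]])
    ordc <- do.call(order, as.data.frame(t(cuts_mat)))
    best <- best[ordc[1L]]
  }
  th <- pvi_thresholds(index_name,
                       cuts = cand[trip[, best]])
  attr(th, "match_rate") <- max(score) / n
  attr(th, "n_candidates") <- ncol(trip)
  th
}

#' PVI change and its binary outcome
#'
#' delta = follow-up category minus baseline category; the binary outcome
#' is +1 when the index increased (progression toward vulnerability) and
#' -1 otherwise.
#'
#' @param baseline,followup categories in 1..4 (vectorised).
#' @return Data frame with `delta` and `binary` (+1/-1).
#' @export
delta_binary <- function(baseline, followup) {
  stopifnot(all(baseline %in% 1:4), all(followup %in% 1:4))
  delta <- as.integer(followup) - as.integer(baseline)
  data.frame(delta = delta, binary = ifelse(delta > 0, 1L, -1L))
}

#' @export
print.pvi_thresholds <- function(x, ...) {
  cat(sprintf("<pvi_thresholds> %s-PVI cuts: %s (%s)\n", x$index_name,
              paste(signif(x$cuts, 4), collapse = ", "), x$orientation))
  mr <- attr(x, "match_rate")
  if (!is.null(mr)) cat(sprintf("  calibrated; match rate %.3f\n", mr))
  invisible(x)
}
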