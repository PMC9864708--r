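PREDICTOR_NAMES <- c("LA", "PA", "PB", "MinCapT", "MeanCapT",
                     "MaxCapS", "MeanCapS", "MaxCapSn", "MeanCapSn")

#' Assemble the baseline feature table for PVI-change prediction
#'
#' Joins per-slice morphology (LA, PA, PB, MinCapT, MeanCapT) and cap
#' mechanics (MaxCapS, MeanCapS, MaxCapSn, MeanCapSn) at baseline with the
#' chosen PVI's binary change outcome. Slices without cap statistics (no
#' lipid core, hence no fibrous cap) are excluded.
#'
#' @param morph data frame of baseline morphology records (one per slice).
#' @param mech data frame with slice_id and the four cap mechanics columns
#'   at baseline.
#' @param outcomes data frame with slice_id and `binary` (+1/-1).
#' @return A `feature_table` data frame: slice_id, the nine predictors,
#'   and `target` (factor "-1"/"+1").
#' @export
assemble_features <- function(morph, mech, outcomes) {
  if (anyDuplicated(morph$slice_id) || anyDuplicated(mech$slice_id) ||
      anyDuplicated(outcomes$slice_id)) {
    stop("duplicated slice ids")
  }
  orphans <- c(setdiff(morph$slice_id, mech$slice_id),
               setdiff(mech$slice_id, morph$slice_id),
               setdiff(morph$slice_id, outcomes$slice_id))
  if (length(orphans)) {
    stop("slice ids not present in all inputs: ",
         paste(unique(orphans), collapse = ", "))
  }
  tab <- merge(merge(morph, mech, by = "slice_id"), outcomes[
    , c("slice_id", "binary")], by = "slice_id")
  keep <- stats::complete.cases(tab[, PREDICTOR_NAMES])
  if (any(!keep)) {
    message(sum(!keep), " slice(s) without cap statistics excluded")
    tab <- tab[keep, , drop = FALSE]
  }
  out <- tab[, c("slice_id", PREDICTOR_NAMES)]
  out$target <- factor(ifelse(tab$binary > 0, "pos", "neg"),
                       levels = c("neg", "pos"))
  if (nlevels(droplevels(out$target)) < 2L ||
      min(table(out$target)) < 2L) {
    stop("need at least 2 slices per outcome class")
  }
  class(out) <- c("feature_table", class(out))
  out
}

#' Repeat-averaged out-of-fold random-forest probabilities
#'
#' Five-fold cross-validation with a 50-tree probability forest, repeated
#' `n_repeats` times with fresh random partitions; each slice's positive-
#' class probability is its out-of-fold prediction averaged over repeats.
#' Deterministic given `seed`.
#'
#' @param table a [assemble_features()] table.
#' @param subset character vector of predictor names (non-empty).
#' @param n_trees trees per forest (default 50).
#' @param n_folds folds (default 5).
#' @param n_repeats repeats of the whole CV (default 100).
#' @param seed integer seed.
#' @return Numeric vector of averaged positive-class probabilities, one
#'   per row of `table`.
#' @export
cross_validated_probabilities <- function(table, subset = PREDICTOR_NAMES,
                                          n_trees = 50L, n_folds = 5L,
                                          n_repeats = 100L, seed = 1L) {
  stopifnot(length(subset) >= 1L, all(subset %in% PREDICTOR_NAMES))
  n <- nrow(table)
  y <- table$target
  if (nlevels(droplevels(y)) < 2L) stop("both outcome classes required")
  x <- table[, subset, drop = FALSE]
  rng <- make_rng(seed)
  probs <- matrix(0, n, n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    folds <- draw_folds(n, n_folds, y, rng)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- ranger::ranger(
        x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
        num.trees = n_trees, probability = TRUE,
        num.threads = 1L, seed = rng(),
        respect.unordered.factors = "ignore")
      pr <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                           num.threads = 1L)$predictions
      probs[!tr, rep_i] <- if ("pos" %in% colnames(pr)) pr[, "pos"] else 0
    }
  }
  rowMeans(probs)
}

# small deterministic integer stream independent of the global RNG state
make_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  function() {
    # LCG modulo 2^31 - 1 (Park-Miller)
    env$state <- as.integer((16807 * as.numeric(env$state)) %% 2147483647)
    env$state
  }
}

# random 5-way partition; re-drawn (up to 20 times) if any training split
# would lack a class, then stratified as a last resort
draw_folds <- function(n, n_folds, y, rng) {
  for (try_i in 1:20) {
    old <- .Random.seed_save()
    set.seed(rng())
    folds <- sample(rep_len(seq_len(n_folds), n))
    .Random.seed_restore(old)
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(y[folds != f])) == 2L
    }, TRUE))
    if (ok) return(folds)
  }
  warning("degenerate folds; falling back to a stratified partition")
  old <- .Random.seed_save()
  set.seed(rng())
  folds <- integer(n)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  .Random.seed_restore(old)
  folds
}

#' Prediction metrics at the ROC-optimal cutoff
#'
#' Builds the ROC curve by sweeping every distinct probability cutoff,
#' integrates AUC by the trapezoid rule, picks the operating cutoff
#' maximising the Youden index (Sen + Spe - 1; ties resolved toward
#' higher sensitivity), and reports accuracy, sensitivity and specificity
#' there: Acc = (TP+TN)/(TP+FP+TN+FN), Sen = TP/(TP+FN), Spe = TN/(TN+FP).
#'
#' @param probabilities positive-class probabilities in [0, 1].
#' @param targets factor with levels neg/pos, or +/-1 vector.
#' @return A one-row `prediction_result` data frame: acc, sen, spe,
#'   sen_plus_spe, auc, cutoff, n_pos, n_neg.
#' @export
metrics <- function(probabilities, targets) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  pos <- if (is.factor(targets)) targets == "pos" else targets > 0
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required in targets")
  cuts <- sort(unique(probabilities))
  # predict positive when probability > cutoff; include -Inf so the
  # all-positive operating point is on the curve
  cuts <- c(-Inf, cuts)
  sen <- vapply(cuts, function(ct) sum(pos & probabilities > ct) / n_pos, 0)
  spe <- vapply(cuts, function(ct) sum(!pos & probabilities <= ct) / n_neg, 0)
  fpr <- 1 - spe
  o <- order(fpr, sen)
  auc <- sum(diff(fpr[o]) * (sen[o][-1L] + sen[o][-length(sen)]) / 2)
  youden <- sen + spe - 1
  best <- which(youden == max(youden))
  if (length(best) > 1L) best <- best[which.max(sen[best])]
  ct <- cuts[best]
  tp <- sum(pos & probabilities > ct)
  tn <- sum(!pos & probabilities <= ct)
  out <- data.frame(acc = (tp + tn) / (n_pos + n_neg),
                    sen = tp / n_pos, spe = tn / n_neg,
                    sen_plus_spe = tp / n_pos + tn / n_neg,
                    auc = auc, cutoff = ct,
                    n_pos = n_pos, n_neg = n_neg)
  class(out) <- c("prediction_result", class(out))
  out
}

#' Sweep all non-empty predictor combinations
#'
#' Evaluates every non-empty subset of the nine baseline risk factors
#' (2^9 - 1 = 511 for the full set) with [cross_validated_probabilities()]
#' + [metrics()], ranked by accuracy (AUC ranking available by sorting).
#'
#' @param table a [assemble_features()] table.
#' @param predictors predictor pool (default all nine).
#' @param seed integer seed; subset evaluations draw independent seeded
#'   streams so the ranked output is reproducible.
#' @param n_trees,n_folds,n_repeats forwarded to the CV routine.
#' @param progress print progress every 64 subsets.
#' @return A data frame, one row per subset: predictor_subset (string,
#'   "+"-separated), n_predictors, acc, sen, spe, sen_plus_spe, auc,
#'   cutoff, ranked by acc (descending).
#' @export
sweep_combinations <- function(table, predictors = PREDICTOR_NAMES,
                               seed = 1L, n_trees = 50L, n_folds = 5L,
                               n_repeats = 100L, progress = FALSE) {
  p <- length(predictors)
  stopifnot(p >= 1L)
  subsets <- unlist(lapply(seq_len(p), function(k) {
    asplit(combn(predictors, k), 2L)
  }), recursive = FALSE)
  res <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sub <- as.character(subsets[[i]])
    pr <- cross_validated_probabilities(table, sub, n_trees = n_trees,
                                        n_folds = n_folds,
                                        n_repeats = n_repeats,
                                        seed = seed + i)
    m <- metrics(pr, table$target)
    m$predictor_subset <- paste(sub, collapse = " + ")
    m$n_predictors <- length(sub)
    res[[i]] <- m
    if (progress && i %% 64L == 0L) {
      message("evaluated ", i, "/", length(subsets), " subsets")
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$acc, -out$auc, out$n_predictors), ]
  rownames(out) <- NULL
  out[, c("predictor_subset", "n_predictors", "acc", "sen", "spe",
          "sen_plus_spe", "auc", "cutoff", "n_pos", "n_neg")]
}

#' Best-combination vs best-single improvement report
#'
#' Summarises, per PVI, the accuracy and AUC of the best combination
#' predictor against the best single predictor, the improvement in
#' percentage points, and the means across PVIs. Values are rounded as
#' printed (accuracy to 3 decimals as a fraction, i.e. 0.1 percentage
#' points; AUC to 3 decimals) before differencing, mirroring how such
#' tables are reported; set `digits = Inf` to difference unrounded values.
#'
#' @param results named list (per PVI) of [sweep_combinations()] outputs,
#'   or data frames with at least n_predictors, acc, auc.
#' @param digits decimals used for the as-printed rounding (default 3).
#' @return List: `per_pvi` data frame (best single/combination acc + auc,
#'   improvements) and `summary` (mean accuracy improvement in points,
#'   mean best-combination AUC).
#' @export
improvement_report <- function(results, digits = 3) {
  per <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    rr <- function(x) if (is.finite(digits)) round(x, digits) else x
    single <- r[r$n_predictors == 1L, , drop = FALSE]
    best_single <- single[which.max(single$acc), , drop = FALSE]
    best_comb <- r[which.max(r$acc), , drop = FALSE]
    data.frame(pvi = nm,
               best_single = best_single$predictor_subset,
               acc_single = rr(best_single$acc),
               best_combination = best_comb$predictor_subset,
               acc_combination = rr(best_comb$acc),
               improvement_pts = round(100 * (rr(best_comb$acc) -
                                                rr(best_single$acc)), 1),
               auc_single = rr(best_single$auc),
               auc_combination = rr(best_comb$auc))
  })
  per <- do.call(rbind, per)
  list(per_pvi = per,
       summary = data.frame(
         mean_improvement_pts = round(mean(per$improvement_pts), 1),
         mean_auc = round(mean(per$auc_combination), 3)))
}
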