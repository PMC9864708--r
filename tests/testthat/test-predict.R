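make_table <- function(n = 114, seed = 1, signal = 0, pos_frac = 0.14) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(X) <- capmech:::PREDICTOR_NAMES
  lin <- signal * (X$MinCapT + X$PB)
  y <- factor(ifelse(lin + rnorm(n) > stats::qnorm(1 - pos_frac),
                     "pos", "neg"), levels = c("neg", "pos"))
  # guarantee both classes
  if (sum(y == "pos") < 3) y[seq_len(3)] <- "pos"
  tab <- cbind(data.frame(slice_id = sprintf("s%03d", seq_len(n))), X)
  tab$target <- y
  class(tab) <- c("feature_table", class(tab))
  tab
}

test_that("metrics reproduce the confusion arithmetic", {
  # TP = 9, FN = 7, TN = 94, FP = 4 at the Youden-optimal cutoff
  pr <- c(rep(0.9, 9), rep(0.02, 7), rep(0.05, 94), rep(0.95, 4))
  tg <- c(rep(1, 16), rep(-1, 98))
  m <- metrics(pr, tg)
  expect_equal(m$acc, 103 / 114, tolerance = 1e-12)
  expect_equal(m$sen, 9 / 16, tolerance = 1e-12)
  expect_equal(m$spe, 94 / 98, tolerance = 1e-12)
  expect_equal(m$n_pos, 16); expect_equal(m$n_neg, 98)
  # decomposition invariant
  expect_equal(m$acc, (m$sen * m$n_pos + m$spe * m$n_neg) /
                 (m$n_pos + m$n_neg), tolerance = 1e-12)
})

test_that("metrics edge cases: perfect and degenerate classifiers", {
  pr <- c(rep(0.9, 5), rep(0.1, 20))
  tg <- c(rep(1, 5), rep(-1, 20))
  m <- metrics(pr, tg)
  expect_equal(c(m$acc, m$sen, m$spe, m$auc), c(1, 1, 1, 1))
  m0 <- metrics(rep(0.4, 25), tg)
  expect_equal(m0$auc, 0.5)
  expect_error(metrics(rep(0.5, 4), rep(1, 4)), "both classes")
})

test_that("AUC is invariant under monotone transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  pr <- runif(60)
  tg <- ifelse(pr + rnorm(60, 0, 0.4) > 0.6, 1, -1)
  if (length(unique(tg)) < 2) tg[1:5] <- 1
  m1 <- metrics(pr, tg)
  m2 <- metrics(pr^3, tg)    # strictly monotone transform
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(tg, pr, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m1$auc, ref, tolerance = 1e-9)
})

test_that("cross-validated probabilities are deterministic and sane", {
  tab <- make_table(60, seed = 4, signal = 3, pos_frac = 0.3)
  p1 <- cross_validated_probabilities(tab, c("MinCapT", "PB"),
                                      n_repeats = 5, seed = 9)
  p2 <- cross_validated_probabilities(tab, c("MinCapT", "PB"),
                                      n_repeats = 5, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # strong signal separates the classes
  m <- metrics(p1, tab$target)
  expect_gt(m$auc, 0.85)
})

test_that("shuffled targets give chance-level AUC", {
  tab <- make_table(114, seed = 6, signal = 0)
  aucs <- vapply(1:5, function(s) {
    tb <- tab
    set.seed(200 + s)
    tb$target <- sample(tb$target)
    metrics(cross_validated_probabilities(tb, n_repeats = 10, seed = s),
            tb$target)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("doubling the number of trees barely changes the metrics", {
  tab <- make_table(80, seed = 8, signal = 2, pos_frac = 0.25)
  m50 <- metrics(cross_validated_probabilities(tab, n_trees = 50,
                                               n_repeats = 20, seed = 5),
                 tab$target)
  m100 <- metrics(cross_validated_probabilities(tab, n_trees = 100,
                                                n_repeats = 20, seed = 5),
                  tab$target)
  expect_lt(abs(m50$acc - m100$acc), 0.02)
  expect_lt(abs(m50$sen - m100$sen), 0.06)
  expect_lt(abs(m50$spe - m100$spe), 0.06)
})

test_that("the combination sweep enumerates every non-empty subset", {
  tab <- make_table(40, seed = 10, signal = 2, pos_frac = 0.3)
  res <- sweep_combinations(tab, predictors = c("MinCapT", "PB", "LA"),
                            n_repeats = 2, seed = 3)
  expect_equal(nrow(res), 2^3 - 1)
  expect_setequal(res$n_predictors, c(1, 1, 1, 2, 2, 2, 3))
  # ranked by accuracy
  expect_true(all(diff(res$acc) <= 0))
  # determinism of the ranked output
  res2 <- sweep_combinations(tab, predictors = c("MinCapT", "PB", "LA"),
                             n_repeats = 2, seed = 3)
  expect_identical(res, res2)
})

test_that("assemble_features joins, excludes capless slices, errors on orphans", {
  ids <- letters[1:6]
  morph <- data.frame(slice_id = ids,
                      LA = 5 + 1:6, PA = 10 + 1:6,
                      PB = seq(0.6, 0.7, length.out = 6),
                      MinCapT = c(0.3, NA, 0.5, 0.2, 0.4, 0.6),
                      MeanCapT = c(0.4, NA, 0.6, 0.3, 0.5, 0.7))
  mech <- data.frame(slice_id = ids,
                     MaxCapS = 80 + 1:6, MeanCapS = 60 + 1:6,
                     MaxCapSn = 0.1 + (1:6) / 100,
                     MeanCapSn = 0.08 + (1:6) / 100)
  outc <- data.frame(slice_id = ids, binary = c(1, -1, -1, 1, 1, -1))
  expect_message(tab <- assemble_features(morph, mech, outc), "excluded")
  expect_equal(nrow(tab), 5)
  expect_equal(levels(tab$target), c("neg", "pos"))
  expect_error(assemble_features(morph[1:2, ], mech, outc), "not present")
  morph2 <- rbind(morph, morph[1, ])
  expect_error(assemble_features(morph2, mech, outc), "duplicated")
})

test_that("improvement report reproduces printed-table arithmetic", {
  # published per-PVI best-combination and best-single operating metrics
  printed <- list(
    C      = list(comb = c(acc = 0.903, auc = 0.877),
                  single = c(acc = 0.837, auc = 0.827)),
    MaxS   = list(comb = c(acc = 0.779, auc = 0.776),
                  single = c(acc = 0.654, auc = 0.675)),
    MeanS  = list(comb = c(acc = 0.856, auc = 0.867),
                  single = c(acc = 0.756, auc = 0.781)),
    MaxSn  = list(comb = c(acc = 0.871, auc = 0.935),
                  single = c(acc = 0.798, auc = 0.909)),
    MeanSn = list(comb = c(acc = 0.833, auc = 0.809),
                  single = c(acc = 0.753, auc = 0.693)))
  results <- lapply(printed, function(p) {
    data.frame(predictor_subset = c("combo", "single"),
               n_predictors = c(3L, 1L),
               acc = c(p$comb[["acc"]], p$single[["acc"]]),
               auc = c(p$comb[["auc"]], p$single[["auc"]]))
  })
  rep <- improvement_report(results)
  expect_equal(rep$per_pvi$improvement_pts,
               c(6.6, 12.5, 10.0, 7.3, 8.0))
  expect_equal(rep$summary$mean_improvement_pts, 8.9)
  expect_equal(rep$summary$mean_auc, 0.853)
})
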