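test_that("repeated holdout separates a strongly shifted synthetic contrast", {
  tab <- synthetic_table(25, shift_cols = oculocog:::ALL_FEATURE_NAMES,
                         delta = 6, seed = 9)
  res <- repeated_holdout(tab, subset = "combined", model_kind = "svm",
                          config = model_config(seed = 1),
                          scheme = split_scheme(base_seed = 2))
  expect_equal(res$mean_accuracy, 1)
  expect_equal(res$sd_accuracy, 0)
  expect_length(res$accuracy, 10)
  expect_equal(unname(res$mean_hit_rate), c(1, 1))
})

test_that("the split scheme uses an 8:2 ratio, 10 repeats, disjoint folds", {
  sch <- split_scheme()
  expect_equal(sch$train_fraction, 0.8)
  expect_equal(sch$n_repeats, 10)
  labels <- factor(rep(c("control", "mci", "young"), c(57, 40, 31)))
  sp <- oculocog:::make_split(labels, sch, repeat_seed = 11)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_equal(length(sp$train) / length(labels), 0.8, tolerance = 0.02)
  # stratification keeps every class in both folds
  expect_setequal(unique(labels[sp$train]), levels(labels))
  expect_setequal(unique(labels[sp$test]), levels(labels))
})

test_that("accuracy equals the confusion trace and the hit-rate identity holds", {
  tab <- synthetic_table(15, shift_cols = "pa_mean_latency", delta = 1,
                         seed = 4)
  res <- repeated_holdout(tab, subset = "combined", model_kind = "rf",
                          config = model_config(seed = 3),
                          scheme = split_scheme(base_seed = 5))
  for (r in seq_along(res$accuracy)) {
    cm <- res$confusion[[r]]
    expect_equal(res$accuracy[r], sum(diag(cm)) / sum(cm))
    n_c <- rowSums(cm)
    expect_equal(res$accuracy[r],
                 sum(res$hit_rate[r, ] * n_c) / sum(n_c))
  }
  res2 <- repeated_holdout(tab, subset = "combined", model_kind = "rf",
                           config = model_config(seed = 3),
                           scheme = split_scheme(base_seed = 5))
  expect_identical(res$accuracy, res2$accuracy)
  expect_identical(res$misclassified, res2$misclassified)
})

test_that("roc_auc equals brute-force pair counting and handles ties", {
  # toy set: positives (0.35, 0.8), negatives (0.1, 0.4); the pair
  # (0.35, 0.4) is a discordance, so 3 of 4 pairs are concordant
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c("control", "control", "mci", "mci")
  brute <- function(s, l) {
    pos <- s[l == "mci"]
    neg <- s[l != "mci"]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(brute(scores, labels), 0.75)
  expect_equal(roc_auc(scores, labels), 0.75)
  # with a genuine tie the pair counts half
  expect_equal(roc_auc(c(0.1, 0.4, 0.4, 0.8),
                       c("control", "control", "mci", "mci")), 0.875)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("control", "mci"), 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c("control", "control", "mci", "mci")),
               1)
  set.seed(6)
  s <- rnorm(40)
  l <- sample(c("control", "mci"), 40, replace = TRUE)
  expect_equal(roc_auc(s, l), brute(s, l))
  expect_error(roc_auc(s, rep("mci", 40)), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(60)
  l <- sample(c("control", "mci"), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, levels = c("control", "mci"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, l), ref, tolerance = 1e-12)
})

test_that("ablation suite covers the seven feature sets with task-specific classes", {
  tab <- synthetic_table(12, groups = c("control", "mci", "young"),
                         shift_cols = "span_bwd_digit", delta = 2, seed = 8)
  ab <- ablation_suite(tab, task = "triple", model_kind = "rf",
                       config = model_config(seed = 1),
                       scheme = split_scheme(n_repeats = 3, base_seed = 2))
  expect_equal(nrow(ab$summary), 7)
  expect_setequal(ab$summary$model,
                  c("combined", "eye_only", "behavior_only", "no_proanti",
                    "no_pursuit", "no_memory", "no_predictive"))
  expect_true(all(c("hit_control_mean", "hit_mci_mean", "hit_young_mean")
                  %in% names(ab$summary)))
  bin <- ablation_suite(tab, task = "binary", model_kind = "rf",
                        config = model_config(seed = 1),
                        scheme = split_scheme(n_repeats = 2, base_seed = 2))
  expect_false("hit_young_mean" %in% names(bin$summary))
  expect_setequal(bin$results$combined$classes, c("control", "mci"))
})

test_that("behavior-only beats eye-only when only behavioral columns carry signal", {
  accs <- vapply(1:8, function(s) {
    tab <- synthetic_table(18, shift_cols = oculocog:::BEHAVIOR_FEATURE_NAMES,
                           delta = 1.5, seed = 300 + s)
    vapply(c("behavior_only", "eye_only"), function(nm)
      repeated_holdout(tab, subset = nm, model_kind = "rf",
                       config = model_config(seed = 1),
                       scheme = split_scheme(n_repeats = 4,
                                             base_seed = s))$mean_accuracy,
      numeric(1))
  }, numeric(2))
  expect_gt(mean(accs["behavior_only", ]), mean(accs["eye_only", ]))
})

test_that("model comparison tabulates all four architectures", {
  tab <- synthetic_table(12, shift_cols = oculocog:::ALL_FEATURE_NAMES,
                         delta = 6, seed = 10)
  mc <- model_comparison(tab, task = "binary",
                         config = small_config(epochs = 25, seed = 1),
                         scheme = split_scheme(n_repeats = 2, base_seed = 3))
  expect_setequal(mc$summary$model, c("cnn", "fcnn", "svm", "rf"))
  # trivially separable contrast: every architecture is essentially perfect
  expect_true(all(mc$summary$accuracy_mean >= 99))
})

test_that("the group screen flags large shifts and calibrates type-I error", {
  tab <- synthetic_table(50, groups = c("young", "control"),
                         shift_cols = "pa_mean_latency", delta = 2,
                         seed = 12)
  tab$group[tab$group == "control"] <- "control"
  scr <- group_difference_screen(tab)
  expect_equal(nrow(scr), 39)
  expect_true(scr$pass_young_elderly[scr$feature == "pa_mean_latency"])
  expect_error(group_difference_screen(tab[tab$group == "young", ]),
               "at least 2")
  # null features: empirical pass rate near alpha (binomial tolerance)
  null_rate <- mean(scr$pass_young_elderly[scr$feature != "pa_mean_latency"])
  expect_lt(null_rate, 0.25)
})

test_that("eye-behavior correlation matrix is 31 x 8 with exact edge cases", {
  tab <- fix_small_table()
  fc <- feature_behavior_correlations(tab)
  expect_equal(dim(fc$r), c(31, 8))
  # engineered exact correlations
  tab2 <- tab
  tab2$pa_mean_latency <- tab2$span_fwd_digit * -1
  fc2 <- feature_behavior_correlations(tab2)
  expect_equal(fc2$r["pa_mean_latency", "span_fwd_digit"], -1)
  tab3 <- tab
  tab3$pa_mean_latency <- 1  # constant -> undefined
  fc3 <- feature_behavior_correlations(tab3)
  expect_true(is.na(fc3$r["pa_mean_latency", "span_fwd_digit"]))
  # independent standard-normal columns rarely exceed |r| = 0.3 at n = 100
  tabn <- synthetic_table(50, groups = c("control", "mci"), seed = 14)
  fcn <- feature_behavior_correlations(tabn)
  expect_gte(mean(abs(fcn$r) < 0.3), 0.95)
})

test_that("chance band covers the permuted-label accuracy", {
  labels <- rep(c("control", "mci"), c(30, 20))
  band <- chance_band(labels, n_perm = 50, seed = 3)
  expect_lt(band["lower"], band["upper"])
  expect_gte(band["upper"], 0.5)
  expect_lte(band["lower"], 0.62)
})
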