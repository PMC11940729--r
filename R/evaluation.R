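# Repeated-holdout evaluation protocol: 8:2 stratified splits repeated 10
# times, per-class hit rates, AUC over pooled test folds, feature-set
# ablations, model comparisons, and the descriptive group screens.

#' Repeated-split evaluation scheme
#'
#' @param train_fraction Fraction of rows in the training fold (default 0.8,
#'   i.e. an 8:2 split).
#' @param n_repeats Number of independent splits (default 10).
#' @param base_seed Base seed; repeat r uses a seed derived from it.
#' @param stratified Stratify splits by class (default TRUE; with a minority
#'   class of 40 in 128, unstratified 20% folds can lose a class).
#' @return A list of class `"oc_split_scheme"`.
#' @export
split_scheme <- function(train_fraction = 0.8, n_repeats = 10,
                         base_seed = 1, stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction, n_repeats = n_repeats,
                 base_seed = base_seed, stratified = stratified),
            class = "oc_split_scheme")
}

make_split <- function(labels, scheme, repeat_seed) {
  n <- length(labels)
  withr_seed(repeat_seed, {
    train_idx <- integer(0)
    if (scheme$stratified) {
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        k <- max(1L, round(length(idx) * scheme$train_fraction))
        # keep at least one row of the class in training; a singleton
        # class then never reaches the test fold (its hit rate is NA)
        if (k >= length(idx)) k <- max(length(idx) - 1L, 1L)
        train_idx <- c(train_idx, sample(idx, k))
      }
    } else {
      k <- round(n * scheme$train_fraction)
      train_idx <- sample.int(n, k)
    }
    list(train = sort(train_idx), test = setdiff(seq_len(n), train_idx))
  })
}

build_model <- function(model_kind, config, n_features) {
  switch(model_kind,
         cnn = build_cnn(config, n_features),
         fcnn = build_fcnn(config, n_features),
         svm = build_baseline("svm", seed = config$seed),
         rf = build_baseline("rf", seed = config$seed),
         stop("unknown model kind: ", model_kind))
}

#' Repeated 8:2 holdout evaluation
#'
#' For each repeat: split the rows (stratified by class by default), fit the
#' normalizer on the training fold only, impute and z-score both folds with
#' it, train the model, and evaluate the held-out fold. Repeats whose
#' training fold lost a class are resampled (logged in the result). Reports
#' the per-repeat accuracies, their mean and SD, per-class hit rates
#' (per-class recall on the test fold), confusion counts, misclassified
#' participant IDs and pooled test-fold probabilities.
#'
#' @param table Canonical feature table (or a subset of it).
#' @param subset Feature subset name (see [select_subset()]); `NULL` uses
#'   the table as given.
#' @param model_kind One of `"cnn"`, `"fcnn"`, `"svm"`, `"rf"`.
#' @param config An `oc_model_config` (neural models; also carries the seed
#'   for baselines).
#' @param scheme An `oc_split_scheme`.
#' @return An object of class `"oc_eval_result"`.
#' @export
repeated_holdout <- function(table, subset = NULL, model_kind = "cnn",
                             config = model_config(), scheme = split_scheme()) {
  if (!is.null(subset)) table <- select_subset(table, subset)
  labels <- as.factor(table$group)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  labels <- droplevels(labels)
  classes <- levels(labels)
  cols <- feature_columns(table)
  config$n_classes <- length(classes)

  acc <- numeric(scheme$n_repeats)
  hit <- matrix(NA_real_, scheme$n_repeats, length(classes),
                dimnames = list(NULL, classes))
  confusion <- vector("list", scheme$n_repeats)
  misclassified <- vector("list", scheme$n_repeats)
  pooled_prob <- pooled_truth <- NULL
  resampled <- 0L
  for (r in seq_len(scheme$n_repeats)) {
    rseed <- derive_seed(scheme$base_seed, r)
    split <- make_split(labels, scheme, rseed)
    tries <- 0
    while (length(unique(labels[split$train])) < length(classes) &&
           tries < 20) {
      tries <- tries + 1
      resampled <- resampled + 1L
      split <- make_split(labels, scheme, derive_seed(rseed, 1000L + tries))
    }
    if (length(split$test) == 0)
      stop("test fold is empty; the table has too few rows per class ",
           "for a ", scheme$train_fraction, " train fraction")
    norm <- fit_normalizer(table[split$train, c(cols), drop = FALSE])
    Xtr <- as.matrix(apply_normalizer(table[split$train, cols, drop = FALSE],
                                      norm))
    Xte <- as.matrix(apply_normalizer(table[split$test, cols, drop = FALSE],
                                      norm))
    cfg_r <- config
    cfg_r$seed <- derive_seed(rseed, 3L)
    model <- build_model(model_kind, cfg_r, ncol(Xtr))
    model <- train_model(model, Xtr, labels[split$train])
    P <- predict_proba(model, Xte)
    pred <- factor(colnames(P)[max.col(P, ties.method = "first")],
                   levels = classes)
    truth <- labels[split$test]
    acc[r] <- mean(pred == truth)
    cm <- table(truth = truth, predicted = pred)
    confusion[[r]] <- cm
    for (cl in classes)
      hit[r, cl] <- if (sum(truth == cl) > 0)
        mean(pred[truth == cl] == cl) else NA_real_
    wrong <- which(pred != truth)
    misclassified[[r]] <- data.frame(
      participant_id = if ("participant_id" %in% names(table))
        table$participant_id[split$test][wrong] else
          as.character(split$test[wrong]),
      true = as.character(truth[wrong]),
      predicted = as.character(pred[wrong]),
      stringsAsFactors = FALSE)
    pooled_prob <- rbind(pooled_prob, P)
    pooled_truth <- c(pooled_truth, as.character(truth))
  }
  structure(list(
    model_kind = model_kind, classes = classes,
    accuracy = acc, mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
    hit_rate = hit, mean_hit_rate = colMeans(hit, na.rm = TRUE),
    sd_hit_rate = apply(hit, 2, stats::sd, na.rm = TRUE),
    confusion = confusion, misclassified = misclassified,
    pooled_prob = pooled_prob, pooled_truth = pooled_truth,
    n_resampled = resampled, scheme = scheme),
    class = "oc_eval_result")
}

#' @export
print.oc_eval_result <- function(x, ...) {
  cat(sprintf("<oc_eval_result> %s: accuracy %.2f%% (%.2f) over %d repeats\n",
              x$model_kind, 100 * x$mean_accuracy, 100 * x$sd_accuracy,
              length(x$accuracy)))
  hr <- sprintf("%s %.2f%% (%.2f)", names(x$mean_hit_rate),
                100 * x$mean_hit_rate, 100 * x$sd_hit_rate)
  cat("  hit rates:", paste(hr, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based AUC of the positive-class score, equal to the normalized
#' Mann-Whitney U statistic (ties counted half).
#'
#' @param scores Numeric scores (probability of the positive class).
#' @param labels Binary truth; `positive` names the positive class.
#' @param positive Positive class label (default `"mci"`).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "mci") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of an evaluation result (binary task)
#'
#' Headline AUC pools the test-fold probabilities over all repeats; the
#' per-repeat average is also available.
#'
#' @param result An `oc_eval_result` from a binary task.
#' @param positive Positive class (default `"mci"`).
#' @return List with `pooled` and `mean_per_repeat` AUC.
#' @export
eval_auc <- function(result, positive = "mci") {
  if (length(result$classes) != 2)
    stop("AUC is defined for the binary task")
  scores <- result$pooled_prob[, positive]
  pooled <- roc_auc(scores, result$pooled_truth, positive)
  # per-repeat: pooled rows are in repeat order
  sizes <- vapply(result$confusion, sum, numeric(1))
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1
  per <- vapply(seq_along(sizes), function(r) {
    sel <- idx_start[r]:idx_end[r]
    tr <- result$pooled_truth[sel]
    if (length(unique(tr)) < 2) return(NA_real_)
    roc_auc(scores[sel], tr, positive)
  }, numeric(1))
  list(pooled = pooled, mean_per_repeat = mean(per, na.rm = TRUE))
}

#' Feature-set ablation suite
#'
#' Runs the repeated-holdout protocol once per canonical feature subset
#' (combined, eye only, behavior only, and combined minus each of the four
#' oculomotor tasks) and tabulates mean (SD) accuracy and per-class hit
#' rates.
#'
#' @param table Canonical 39-feature table.
#' @param task `"triple"` (all three groups) or `"binary"` (control vs MCI;
#'   young rows are dropped).
#' @param model_kind Classifier to use.
#' @param config,scheme As in [repeated_holdout()].
#' @return List with `results` (named list of `oc_eval_result`) and
#'   `summary` (`data.frame`, one row per subset).
#' @export
ablation_suite <- function(table, task = c("triple", "binary"),
                           model_kind = "cnn", config = model_config(),
                           scheme = split_scheme()) {
  task <- match.arg(task)
  if (task == "binary") table <- table[table$group != "young", , drop = FALSE]
  subsets <- names(FEATURE_SUBSETS)
  results <- lapply(subsets, function(nm)
    repeated_holdout(table, subset = nm, model_kind = model_kind,
                     config = config, scheme = scheme))
  names(results) <- subsets
  list(results = results, summary = summarize_results(results))
}

#' Model comparison on combined features
#'
#' Same protocol, four model kinds (cnn, fcnn, svm, rf), combined features.
#'
#' @inheritParams ablation_suite
#' @param kinds Model kinds to compare.
#' @return List with `results` and `summary` as in [ablation_suite()].
#' @export
model_comparison <- function(table, task = c("triple", "binary"),
                             config = model_config(),
                             scheme = split_scheme(),
                             kinds = c("cnn", "fcnn", "svm", "rf")) {
  task <- match.arg(task)
  if (task == "binary") table <- table[table$group != "young", , drop = FALSE]
  results <- lapply(kinds, function(k)
    repeated_holdout(table, subset = "combined", model_kind = k,
                     config = config, scheme = scheme))
  names(results) <- kinds
  list(results = results, summary = summarize_results(results))
}

summarize_results <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    row <- data.frame(model = nm,
                      accuracy_mean = 100 * r$mean_accuracy,
                      accuracy_sd = 100 * r$sd_accuracy)
    for (cl in r$classes) {
      row[[paste0("hit_", cl, "_mean")]] <- 100 * r$mean_hit_rate[[cl]]
      row[[paste0("hit_", cl, "_sd")]] <- 100 * r$sd_hit_rate[[cl]]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Young-vs-elderly and control-vs-MCI feature screens
#'
#' Welch two-sample t-tests per feature: young vs pooled elderly
#' (control + MCI), and control vs MCI. `pass` flags p < alpha (raw
#' p-values by default; Benjamini-Hochberg optionally).
#'
#' @param table Canonical feature table.
#' @param features Columns to screen (default: all 39).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with per-feature t statistics, p-values and pass
#'   flags for both contrasts.
#' @export
group_difference_screen <- function(table, features = ALL_FEATURE_NAMES,
                                    alpha = 0.05,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  young <- table$group == "young"
  elderly <- table$group %in% c("control", "mci")
  ctrl <- table$group == "control"
  mci <- table$group == "mci"
  if (sum(young) < 2 || sum(elderly) < 2)
    stop("need at least 2 young and 2 elderly rows")
  welch <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(c(t = NA_real_, p = NA_real_))
    tt <- stats::t.test(a, b)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  out <- do.call(rbind, lapply(features, function(fn) {
    v <- table[[fn]]
    ye <- welch(v[young], v[elderly])
    cm <- welch(v[ctrl], v[mci])
    data.frame(feature = fn,
               t_young_elderly = ye[["t"]], p_young_elderly = ye[["p"]],
               t_control_mci = cm[["t"]], p_control_mci = cm[["p"]])
  }))
  if (adjust == "BH") {
    out$p_young_elderly <- stats::p.adjust(out$p_young_elderly, "BH")
    out$p_control_mci <- stats::p.adjust(out$p_control_mci, "BH")
  }
  out$pass_young_elderly <- !is.na(out$p_young_elderly) &
    out$p_young_elderly < alpha
  out$pass_control_mci <- !is.na(out$p_control_mci) &
    out$p_control_mci < alpha
  rownames(out) <- NULL
  out
}

#' Eye-feature x behavioral-feature Pearson correlations
#'
#' Pairwise Pearson r with two-sided p-values between the 31 eye features
#' and the 8 behavioral features. Constant columns yield `NA`.
#'
#' @param table Canonical feature table (>= 3 complete rows per pair).
#' @return List with matrices `r` and `p` (31 x 8).
#' @export
feature_behavior_correlations <- function(table) {
  if (nrow(table) < 3) stop("need at least 3 rows")
  r <- p <- matrix(NA_real_, length(EYE_FEATURE_NAMES),
                   length(BEHAVIOR_FEATURE_NAMES),
                   dimnames = list(EYE_FEATURE_NAMES,
                                   BEHAVIOR_FEATURE_NAMES))
  for (ef in EYE_FEATURE_NAMES) for (bf in BEHAVIOR_FEATURE_NAMES) {
    x <- table[[ef]]; y <- table[[bf]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok])
    r[ef, bf] <- unname(ct$estimate)
    p[ef, bf] <- ct$p.value
  }
  list(r = r, p = p)
}

#' Chance-level accuracy band by label permutation
#'
#' Null distribution of the majority-vote accuracy under label permutation,
#' respecting class imbalance: each permutation shuffles the labels and
#' scores the permuted test-fold majority rate.
#'
#' @param labels Class labels.
#' @param n_perm Number of permutations.
#' @param level Band coverage.
#' @param seed RNG seed.
#' @return Named vector `lower`, `upper` of the accuracy band.
#' @export
chance_band <- function(labels, n_perm = 50, level = 0.95, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  withr_seed(seed, {
    accs <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(labels)
      mean(perm == labels)
    }, numeric(1))
  })
  q <- stats::quantile(accs, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}
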