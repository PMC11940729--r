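# Shared fixtures, built once per test run and memoised. Cohorts are kept
# small so the whole suite stays fast; analysis-level properties that need
# more signal use the medium cohort.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 22 participants across the three groups, default profiles.
fix_small_cohort <- function() {
  memo("small_cohort", function() generate_cohort(6, 8, 8, seed = 101))
}

fix_small_table <- function() {
  memo("small_table", function() build_feature_table(fix_small_cohort()))
}

# 48 participants; enough rows for split-based evaluation tests.
fix_medium_cohort <- function() {
  memo("medium_cohort", function() generate_cohort(12, 20, 16, seed = 202))
}

fix_medium_table <- function() {
  memo("medium_table", function() build_feature_table(fix_medium_cohort()))
}

# A degenerate noiseless "ideal participant" session.
fix_ideal_session <- function() {
  memo("ideal_session", function()
    simulate_session("ideal_01", "control", ideal_profile(), seed = 11))
}

fix_ideal_features <- function() {
  memo("ideal_features", function() assemble_eye_features(fix_ideal_session()))
}

# A small neural config for protocol-level tests where the full-width
# network would dominate the runtime; architecture family is unchanged.
small_config <- function(n_classes = 2, epochs = 12, seed = 1, ...) {
  model_config(n_classes = n_classes, epochs = epochs, seed = seed,
               fc_dims = c(32, 16), ...)
}

# Directly constructed feature tables (no simulation): group means shifted
# by `delta` on the chosen columns, standard normal noise elsewhere.
synthetic_table <- function(n_per_group, groups = c("control", "mci"),
                            shift_cols = character(0), delta = 0,
                            seed = 1) {
  set.seed(as.integer(seed))
  nm <- oculocog:::ALL_FEATURE_NAMES
  rows <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    X <- matrix(stats::rnorm(n_per_group * length(nm)), n_per_group,
                dimnames = list(NULL, nm))
    if (gi > 1 && length(shift_cols) > 0)
      X[, shift_cols] <- X[, shift_cols] + delta
    data.frame(participant_id = sprintf("%s_%02d", groups[gi],
                                        seq_len(n_per_group)),
               group = groups[gi], X, stringsAsFactors = FALSE,
               check.names = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

withr_seed <- oculocog:::withr_seed

# Minimal comparable serialization of a session (samples + behavior).
serialize_session <- function(s) {
  list(id = s$participant_id, group = s$group,
       gaze = lapply(s$gaze, function(trs) lapply(trs, `[[`, "samples")),
       behavior = s$behavior)
}
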