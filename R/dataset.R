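# The canonical 39-feature participant table and its subsets, normalization
# and CSV persistence. Ordering is immutable package-wide: positions 1-10
# pro/anti, 11-22 pursuit, 23-27 memory-guided, 28-31 predictive, 32-39
# behavioral.

FEATURE_SUBSETS <- list(
  combined = seq_len(39),
  eye_only = 1:31,
  behavior_only = 32:39,
  no_proanti = setdiff(seq_len(39), 1:10),
  no_pursuit = setdiff(seq_len(39), 11:22),
  no_memory = setdiff(seq_len(39), 23:27),
  no_predictive = setdiff(seq_len(39), 28:31))

#' Build the canonical 39-feature table from sessions
#'
#' Extracts eye and behavioral features for every session and concatenates
#' them in the canonical order. Participants with any unusable task (a task
#' whose feature block is entirely missing) are dropped, mirroring the
#' whole-participant exclusion of incomplete recordings; their IDs are
#' reported in the `"dropped"` attribute.
#'
#' @param sessions An `oc_cohort` or list of `oc_session`.
#' @return `data.frame` with `participant_id`, `group` and the 39 feature
#'   columns; attribute `dropped` lists excluded participant IDs.
#' @export
build_feature_table <- function(sessions) {
  rows <- vector("list", length(sessions))
  dropped <- character(0)
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    vals <- c(assemble_eye_features(s), assemble_behavior_features(s))
    blocks <- list(1:10, 11:22, 23:27, 28:31, 32:39)
    if (any(vapply(blocks, function(b) all(is.na(vals[b])), logical(1)))) {
      dropped <- c(dropped, s$participant_id)
      next
    }
    rows[[i]] <- data.frame(participant_id = s$participant_id,
                            group = s$group, t(vals),
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    empty <- as.data.frame(matrix(numeric(0), 0, 39))
    names(empty) <- ALL_FEATURE_NAMES
    cbind(data.frame(participant_id = character(0), group = character(0)),
          empty)
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Select one of the seven canonical feature subsets
#'
#' Subsets: `combined` (39), `eye_only` (31), `behavior_only` (8),
#' `no_proanti` (29), `no_pursuit` (27), `no_memory` (34),
#' `no_predictive` (35).
#'
#' @param table Canonical feature table from [build_feature_table()].
#' @param name Subset name.
#' @return The table restricted to the subset's feature columns (id and
#'   group columns retained).
#' @export
select_subset <- function(table, name) {
  if (!name %in% names(FEATURE_SUBSETS))
    stop("unknown feature subset: ", name)
  keep <- ALL_FEATURE_NAMES[FEATURE_SUBSETS[[name]]]
  meta <- intersect(c("participant_id", "group"), names(table))
  table[, c(meta, keep), drop = FALSE]
}

feature_columns <- function(table) {
  setdiff(names(table), c("participant_id", "group"))
}

#' Fit a z-score normalizer on training rows
#'
#' Missing entries are imputed with the training-fold median before scaling;
#' centers and scales come from the training rows only. Constant features
#' get their scale floored at `1e-8` (values map to 0).
#'
#' @param train Feature table (training rows only).
#' @return An object of class `"oc_normalizer"` with per-feature `median`,
#'   `center`, `scale`.
#' @export
fit_normalizer <- function(train) {
  cols <- feature_columns(train)
  if (nrow(train) == 0) stop("cannot fit a normalizer on zero rows")
  med <- vapply(cols, function(cn) stats::median(train[[cn]], na.rm = TRUE),
                numeric(1))
  med[is.na(med)] <- 0
  imputed <- train
  for (cn in cols) {
    v <- imputed[[cn]]
    v[is.na(v)] <- med[[cn]]
    imputed[[cn]] <- v
  }
  ctr <- vapply(cols, function(cn) mean(imputed[[cn]]), numeric(1))
  scl <- vapply(cols, function(cn) stats::sd(imputed[[cn]]), numeric(1))
  scl[is.na(scl) | scl < 1e-8] <- 1e-8
  structure(list(features = cols, median = med, center = ctr, scale = scl),
            class = "oc_normalizer")
}

#' Apply (or invert) a fitted normalizer
#'
#' @param table Feature table with the normalizer's feature columns.
#' @param normalizer From [fit_normalizer()].
#' @param invert If `TRUE`, map z-scores back to original units.
#' @return The transformed table.
#' @export
apply_normalizer <- function(table, normalizer, invert = FALSE) {
  for (cn in normalizer$features) {
    if (!cn %in% names(table)) stop("missing feature column: ", cn)
    v <- table[[cn]]
    if (invert) {
      table[[cn]] <- v * normalizer$scale[[cn]] + normalizer$center[[cn]]
    } else {
      v[is.na(v)] <- normalizer$median[[cn]]
      table[[cn]] <- (v - normalizer$center[[cn]]) / normalizer$scale[[cn]]
    }
  }
  table
}

#' Write / read the canonical feature CSV
#'
#' The header is fixed: `participant_id`, `group`, then the 39 canonical
#' feature names. Reading validates the header (unknown or missing columns
#' are an error naming the offender) and reorders shuffled columns to
#' canonical order; the round trip is lossless to full double precision.
#'
#' @param table Canonical feature table.
#' @param path CSV path.
#' @return `write_feature_csv`: `path`, invisibly. `read_feature_csv`: the
#'   table.
#' @export
write_feature_csv <- function(table, path) {
  cols <- c("participant_id", "group", ALL_FEATURE_NAMES)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0)
    stop("table lacks column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(format(table[, cols], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  expected <- c("participant_id", "group", ALL_FEATURE_NAMES)
  unknown <- setdiff(names(df), expected)
  if (length(unknown) > 0)
    stop("unknown column(s) in feature CSV: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0)
    stop("feature CSV lacks column(s): ", paste(missing, collapse = ", "))
  df <- df[, expected]
  for (cn in ALL_FEATURE_NAMES) df[[cn]] <- as.numeric(df[[cn]])
  df
}
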