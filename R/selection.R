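# Fusion of the four feature groups into the 136-column table, train-only
# standardization, and the two-step consensus feature selection: per fold a
# feature is retained when selected simultaneously by a random forest and a
# gradient-boosted-tree model (importance above the method's mean); the
# per-fold intersections are merged over the 8 folds into M (Step 1), then
# each method's importances are accumulated over folds, the top half of M
# per method gives M_r and M_x, and the final subset is N = M_r intersect
# M_x (Step 2).

#' Fuse morphological, radiomics, deep and clinical features
#'
#' Column-wise concatenation with group prefixes `morph_`, `rad_`, `dl_`,
#' `clin_`; sex is encoded female = 0, male = 1. The fused table has exactly
#' 25 + 107 + 2 + 2 = 136 feature columns.
#'
#' @param morph n x 25 matrix of morphological features, rownames = case ids.
#' @param radiomics n x 107 matrix of radiomics features, rownames = case ids.
#' @param deep n x 2 matrix of deep features, rownames = case ids.
#' @param clinical data.frame with columns `case_id`, `sex`, `age` and
#'   optionally `ruptured`.
#' @return A [feature_table()] (labels attached when `ruptured` is present).
#' @export
fuse_features <- function(morph, radiomics, deep, clinical) {
  ids <- rownames(morph)
  if (is.null(ids))
    .anf_stop("anf_alignment_error", "morph matrix needs case-id rownames")
  check_ids <- function(x, what) {
    rn <- if (is.data.frame(x)) x$case_id else rownames(x)
    missing <- setdiff(ids, rn); extra <- setdiff(rn, ids)
    if (length(missing) || length(extra))
      .anf_stop("anf_alignment_error",
                "%s cases do not align: missing [%s], unexpected [%s]",
                what, paste(missing, collapse = ", "),
                paste(extra, collapse = ", "))
  }
  check_ids(radiomics, "radiomics"); check_ids(deep, "deep")
  check_ids(clinical, "clinical")
  radiomics <- radiomics[ids, , drop = FALSE]
  deep <- deep[ids, , drop = FALSE]
  cl <- clinical[match(ids, clinical$case_id), , drop = FALSE]
  sex_num <- ifelse(cl$sex %in% c("male", "1", 1), 1, 0)
  X <- cbind(morph, radiomics, deep,
             clin_sex = sex_num, clin_age = as.numeric(cl$age))
  colnames(X) <- c(paste0("morph_", colnames(morph)),
                   paste0("rad_", colnames(radiomics)),
                   paste0("dl_", colnames(deep)),
                   "clin_sex", "clin_age")
  labels <- if ("ruptured" %in% names(cl) && !anyNA(cl$ruptured))
    as.integer(cl$ruptured) else NULL
  feature_table(ids, X, labels)
}

#' Standardize features with train-split parameters only
#'
#' Per-feature z-scoring `(x - mean_train) / sd_train` with the population
#' standard deviation; constant train columns map to 0 and are flagged. The
#' table in `apply_to` is transformed with the train parameters (no leakage).
#'
#' @param train A [feature_table()] used to estimate the scaler.
#' @param apply_to Optional second table transformed with train parameters.
#' @return List with `train`, `applied` (or NULL), `center`, `scale`
#'   (0 kept as recorded, constant columns divided by 1), `constant`
#'   (logical flags).
#' @export
standardize <- function(train, apply_to = NULL) {
  stopifnot(inherits(train, "feature_table"))
  X <- train$features
  if (nrow(X) == 0L) .anf_stop("anf_validation_error", "empty train table")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  const <- sdv == 0
  div <- ifelse(const, 1, sdv)
  tr <- sweep(sweep(X, 2, mu), 2, div, "/")
  tr[, const] <- 0
  out_applied <- NULL
  if (!is.null(apply_to)) {
    stopifnot(inherits(apply_to, "feature_table"))
    A <- sweep(sweep(apply_to$features[, colnames(X), drop = FALSE], 2, mu),
               2, div, "/")
    A[, const] <- 0
    out_applied <- feature_table(apply_to$ids, A, apply_to$labels)
  }
  list(train = feature_table(train$ids, tr, train$labels),
       applied = out_applied, center = mu, scale = sdv, constant = const)
}

# single-thread gradient-boosted-tree fit via the stable low-level interface
.fit_xgb <- function(X, y, nrounds, max_depth, eta) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y), nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = max_depth, eta = eta,
                                   nthread = 1),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

.predict_xgb <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Importance-based selection on one training fold
#'
#' Fits a random forest (impurity importance) and a gradient-boosted-tree
#' model (total-gain importance) on the standardized training fold; a feature
#' is selected by a method when its importance exceeds that method's mean
#' importance.
#'
#' @param X Standardized numeric matrix (train rows x features).
#' @param labels Binary 0/1 labels, both classes present.
#' @param fold_seed Integer seed for both model fits.
#' @return List with `s_rf`, `s_xgb` (character vectors of selected feature
#'   names) and `imp_rf`, `imp_xgb` (named non-negative importance vectors
#'   over all features).
#' @export
per_fold_select <- function(X, labels, fold_seed = 0L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    .anf_stop("anf_stratification_error", "training fold has a single class")
  feats <- colnames(X)
  set.seed(fold_seed)
  rf <- randomForest::randomForest(x = X, y = factor(labels), ntree = 300)
  imp_rf <- rf$importance[, "MeanDecreaseGini"]
  imp_rf <- imp_rf[feats]; imp_rf[is.na(imp_rf)] <- 0
  names(imp_rf) <- feats
  set.seed(fold_seed)
  bst <- .fit_xgb(X, labels, nrounds = 100, max_depth = 3, eta = 0.1)
  it <- xgboost::xgb.importance(model = bst)
  imp_xgb <- stats::setNames(numeric(length(feats)), feats)
  if (!is.null(it) && nrow(it) > 0)
    imp_xgb[it$Feature] <- it$Gain
  list(s_rf = feats[imp_rf > mean(imp_rf)],
       s_xgb = feats[imp_xgb > mean(imp_xgb)],
       imp_rf = imp_rf, imp_xgb = imp_xgb)
}

#' Step 1: merge per-fold consensus selections into the feature set M
#'
#' Per fold keeps the features selected simultaneously by both methods, then
#' unions over folds.
#'
#' @param fold_results List of [per_fold_select()] results.
#' @return Character vector M (possibly empty, with a warning).
#' @export
step1_union <- function(fold_results) {
  per_fold <- lapply(fold_results, function(fr) intersect(fr$s_rf, fr$s_xgb))
  M <- Reduce(union, per_fold, character(0))
  if (length(M) == 0L)
    warning("Step-1 consensus set M is empty", call. = FALSE)
  M
}

#' Step 2: rank M by accumulated importances and intersect the top halves
#'
#' Importances are summed over folds per method; the top `ceil(|M|/2)`
#' features of M per method give M_r (random forest) and M_x (boosted
#' trees); ties are broken by feature name. `N = intersect(M_r, M_x)`; when
#' N is empty the documented fallback is `union(M_r, M_x)` with a warning.
#'
#' @param M Character vector from [step1_union()].
#' @param fold_results List of [per_fold_select()] results (the ledger).
#' @return A `selection_result`: list with `M`, `M_r`, `M_x`, `N`,
#'   `acc_rf`, `acc_xgb`, `fallback`.
#' @export
step2_intersect <- function(M, fold_results) {
  if (length(M) == 0L)
    .anf_stop("anf_validation_error", "M must be non-empty for Step 2")
  acc_rf <- Reduce(`+`, lapply(fold_results, `[[`, "imp_rf"))
  acc_xgb <- Reduce(`+`, lapply(fold_results, `[[`, "imp_xgb"))
  k <- ceiling(length(M) / 2)
  top_half <- function(acc) {
    sc <- acc[M]
    M[order(-sc, M)][seq_len(k)]
  }
  M_r <- top_half(acc_rf); M_x <- top_half(acc_xgb)
  N <- intersect(M_r, M_x)
  fallback <- FALSE
  if (length(N) == 0L) {
    warning("N = M_r intersect M_x is empty; falling back to the union",
            call. = FALSE)
    N <- union(M_r, M_x)
    fallback <- TRUE
  }
  structure(list(M = M, M_r = M_r, M_x = M_x, N = N,
                 acc_rf = acc_rf, acc_xgb = acc_xgb, fallback = fallback),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> |M| = %d, |M_r| = |M_x| = %d, |N| = %d%s\n",
              length(x$M), length(x$M_r), length(x$N),
              if (x$fallback) " (union fallback)" else ""))
  invisible(x)
}

#' Full two-step consensus feature selection over a fold assignment
#'
#' For each fold, runs [per_fold_select()] on that fold's training split
#' (standardized with train parameters only), then composes [step1_union()]
#' and [step2_intersect()]. Deterministic given `seed`. An empty M falls
#' back to the full feature set with a warning.
#'
#' @param table A labelled [feature_table()].
#' @param fold_assignment Integer fold index per case (1..k).
#' @param seed Integer seed.
#' @return A `selection_result` (see [step2_intersect()]).
#' @export
select_features <- function(table, fold_assignment, seed = 42L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels))
    .anf_stop("anf_validation_error", "feature table has no labels")
  if (length(fold_assignment) != length(table$ids))
    .anf_stop("anf_validation_error", "fold assignment length mismatch")
  folds <- sort(unique(fold_assignment))
  fold_results <- lapply(folds, function(f) {
    tr <- which(fold_assignment != f)
    sub <- feature_table(table$ids[tr],
                         table$features[tr, , drop = FALSE],
                         table$labels[tr])
    std <- standardize(sub)
    per_fold_select(std$train$features, std$train$labels,
                    fold_seed = seed + f)
  })
  M <- step1_union(fold_results)
  if (length(M) == 0L) {
    warning("falling back to the full feature set", call. = FALSE)
    M <- colnames(table$features)
  }
  step2_intersect(M, fold_results)
}
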