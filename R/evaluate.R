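# Nested stratified cross-validation over five classifiers with inner grid
# search scored by mean F2, and the metric suite (F2, accuracy, AUC,
# precision, recall, mean ROC). The outer loop estimates generalization; the
# inner loop tunes hyperparameters on the outer-training split only.

#' Stratified fold assignment
#'
#' Seeded shuffle within each class followed by round-robin assignment, so
#' per-fold class counts differ from exact proportionality by at most one
#' case.
#'
#' @param labels Binary 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in 1..k.
#' @export
stratified_folds <- function(labels, k = 8L, seed = 42L) {
  labels <- as.integer(labels)
  cnt <- table(factor(labels, levels = c(0, 1)))
  if (any(cnt < k))
    .anf_stop("anf_stratification_error",
              "class with %d members cannot be split into %d folds",
              min(cnt), k)
  assign <- integer(length(labels))
  .with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  assign
}

#' F2 score from confusion counts
#'
#' `F2 = 5 P R / (4 P + R)` with precision `P = tp / (tp + fp)` (0 when no
#' positive predictions) and recall `R = tp / (tp + fn)`; 0 when `P = R = 0`.
#'
#' @param tp,fp,fn Confusion counts; `tp + fn` must be positive.
#' @return F2 in \[0, 1\].
#' @export
f2_score <- function(tp, fp, fn) {
  if (tp + fn <= 0)
    .anf_stop("anf_undefined_metric_error",
              "no positive ground truth: F2 undefined")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- tp / (tp + fn)
  if (4 * p + r == 0) return(0)
  5 * p * r / (4 * p + r)
}

#' Rank-based AUC (Mann-Whitney with half-weight ties)
#' @param y_true Binary 0/1 labels (both classes present).
#' @param y_score Numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  npos <- sum(y_true == 1L); nneg <- sum(y_true == 0L)
  if (npos == 0L || nneg == 0L)
    .anf_stop("anf_undefined_metric_error", "AUC undefined for a single class")
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' The five-metric suite on one evaluation split
#'
#' Ruptured (label 1) is the positive class.
#'
#' @param y_true Binary 0/1 ground truth.
#' @param y_pred Binary 0/1 hard predictions.
#' @param y_score Numeric scores for AUC.
#' @return Named numeric vector `f2, acc, auc, precision, recall`.
#' @export
metric_suite <- function(y_true, y_pred, y_score) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(y_score), length(y_true) >= 1L)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(f2 = f2_score(tp, fp, fn), acc = mean(y_true == y_pred),
    auc = auc_score(y_true, y_score), precision = prec, recall = rec)
}

# ---- classifiers ----------------------------------------------------------

#' Hyperparameter grids of the five benchmark classifiers
#'
#' Small standard grids, exhaustively searchable in the inner loop:
#' SVM (RBF) cost x gamma (NA = the 1/p library default), ridge logistic
#' regression inverse-regularization C, random-forest trees x depth
#' (NA = unlimited), gradient boosting trees x depth x learning rate, and
#' KNN neighbours x vote weighting.
#'
#' @return Named list of data.frame grids.
#' @export
default_grids <- function() {
  list(
    svm = expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 0.01, 0.1),
                      stringsAsFactors = FALSE),
    lr = expand.grid(C = c(0.01, 0.1, 1, 10)),
    rf = expand.grid(ntree = c(100, 300), maxdepth = c(NA, 3, 5)),
    xgboost = expand.grid(nrounds = c(100, 300), max_depth = c(2, 3, 4),
                          eta = c(0.05, 0.1, 0.3)),
    knn = expand.grid(k = seq(1, 15, by = 2),
                      weights = c("uniform", "distance"),
                      stringsAsFactors = FALSE))
}

#' Specification of one benchmark classifier
#' @param name One of `"svm"`, `"lr"`, `"rf"`, `"xgboost"`, `"knn"`.
#' @param grid Hyperparameter data.frame (default from [default_grids()]).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name = c("svm", "lr", "rf", "xgboost", "knn"),
                            grid = NULL) {
  name <- match.arg(name)
  if (is.null(grid)) grid <- default_grids()[[name]]
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    .anf_stop("anf_parameter_error", "empty hyperparameter grid")
  structure(list(name = name, grid = grid), class = "classifier_spec")
}

.fit_classifier <- function(name, X, y, params, seed = 0L) {
  y <- as.integer(y)
  set.seed(seed)
  if (name == "svm") {
    gamma <- if (is.na(params$gamma)) 1 / ncol(X) else params$gamma
    model <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                        kernel = "radial", cost = params$cost, gamma = gamma,
                        probability = TRUE)
    return(list(kind = "svm", model = model))
  }
  if (name == "lr") {
    Xp <- if (ncol(X) < 2L) cbind(X, .pad = 0) else X
    lambda <- 1 / (params$C * nrow(Xp))
    model <- glmnet::glmnet(Xp, y, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
    return(list(kind = "lr", model = model, pad = ncol(X) < 2L))
  }
  if (name == "rf") {
    maxnodes <- if (is.na(params$maxdepth)) NULL else 2L^params$maxdepth
    model <- randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                        ntree = params$ntree,
                                        maxnodes = maxnodes)
    return(list(kind = "rf", model = model))
  }
  if (name == "xgboost") {
    model <- .fit_xgb(X, y, nrounds = params$nrounds,
                      max_depth = params$max_depth, eta = params$eta)
    return(list(kind = "xgboost", model = model))
  }
  if (name == "knn") {
    return(list(kind = "knn", X = X, y = y, k = params$k,
                weights = params$weights))
  }
  .anf_stop("anf_parameter_error", "unknown classifier '%s'", name)
}

.predict_score <- function(fit, X) {
  if (fit$kind == "svm") {
    pr <- attr(stats::predict(fit$model, X, probability = TRUE),
               "probabilities")
    return(as.numeric(pr[, "1"]))
  }
  if (fit$kind == "lr") {
    Xp <- if (isTRUE(fit$pad)) cbind(X, .pad = 0) else X
    return(as.numeric(stats::predict(fit$model, Xp, type = "response")))
  }
  if (fit$kind == "rf")
    return(as.numeric(stats::predict(fit$model, X, type = "prob")[, "1"]))
  if (fit$kind == "xgboost")
    return(.predict_xgb(fit$model, X))
  if (fit$kind == "knn") {
    nte <- nrow(X)
    sc <- numeric(nte)
    for (i in seq_len(nte)) {
      d <- sqrt(colSums((t(fit$X) - X[i, ])^2))
      ord <- order(d, seq_along(d))[seq_len(min(fit$k, length(d)))]
      if (fit$weights == "distance") {
        w <- 1 / (d[ord] + 1e-12)
        sc[i] <- sum(w * fit$y[ord]) / sum(w)
      } else sc[i] <- mean(fit$y[ord])
    }
    return(sc)
  }
  .anf_stop("anf_parameter_error", "unknown fit kind")
}

#' Exhaustive inner-loop grid search scored by mean F2
#'
#' Each grid point is evaluated by stratified `k_inner`-fold CV on the
#' outer-training split; ties are broken by grid order; the winner is refit
#' on the full split by the caller.
#'
#' @param spec A [classifier_spec()].
#' @param X Standardized train matrix.
#' @param y Binary labels.
#' @param k_inner Inner fold count (default 7).
#' @param seed Integer seed.
#' @return List with `best` (one-row data.frame), `scores` (mean F2 per grid
#'   row).
#' @export
inner_grid_search <- function(spec, X, y, k_inner = 7L, seed = 42L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  fa <- stratified_folds(y, k = k_inner, seed = seed)
  grid <- spec$grid
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, , drop = FALSE]
    f2s <- vapply(seq_len(k_inner), function(f) {
      tr <- fa != f; te <- fa == f
      fit <- .fit_classifier(spec$name, X[tr, , drop = FALSE], y[tr], params,
                             seed = seed + g)
      sc <- .predict_score(fit, X[te, , drop = FALSE])
      ms <- tryCatch(metric_suite(y[te], as.integer(sc >= 0.5), sc),
                     error = function(e) c(f2 = NA_real_))
      ms[["f2"]]
    }, numeric(1))
    scores[g] <- mean(f2s, na.rm = TRUE)
  }
  best <- which.max(scores)     # first maximum wins ties (grid order)
  list(best = grid[best, , drop = FALSE], scores = scores, best_index = best)
}

#' Pointwise-mean ROC curve over folds
#'
#' Each fold's empirical ROC is linearly interpolated onto a common 101-point
#' false-positive-rate grid; true-positive rates are averaged pointwise and
#' endpoints forced to (0,0) and (1,1). Single-class folds are skipped with
#' a warning.
#'
#' @param fold_scores List of lists with `y_true` and `y_score`.
#' @return List with `fpr` and `tpr` (each length 101).
#' @export
mean_roc <- function(fold_scores) {
  grid <- seq(0, 1, length.out = 101)
  curves <- list()
  for (fs in fold_scores) {
    y <- as.integer(fs$y_true)
    if (length(unique(y)) < 2L) {
      warning("skipping single-class fold in mean ROC", call. = FALSE)
      next
    }
    ord <- order(-fs$y_score)
    tp <- cumsum(y[ord] == 1L) / sum(y == 1L)
    fp <- cumsum(y[ord] == 0L) / sum(y == 0L)
    fp <- c(0, fp); tp <- c(0, tp)
    # collapse duplicate FPR values to their maximal TPR (step ROC)
    tpr_at <- vapply(grid, function(x) max(tp[fp <= x]), numeric(1))
    curves[[length(curves) + 1L]] <- tpr_at
  }
  if (!length(curves))
    .anf_stop("anf_undefined_metric_error", "no fold with both classes")
  tpr <- Reduce(`+`, curves) / length(curves)
  tpr[1] <- 0; tpr[length(tpr)] <- 1
  list(fpr = grid, tpr = tpr)
}

#' Nested stratified cross-validation of one or more classifiers
#'
#' Per outer fold: standardize on the training split, re-run the consensus
#' feature selection on the training split only (or use one global selection
#' when `global_selection = TRUE`), restrict columns, tune by
#' [inner_grid_search()], refit, and evaluate on the held-out fold. Fully
#' seeded and deterministic.
#'
#' @param table A labelled [feature_table()].
#' @param specs A [classifier_spec()] or list of them.
#' @param k_outer,k_inner Outer/inner fold counts (defaults 8 and 7).
#' @param seed Integer seed.
#' @param select Run consensus feature selection (default TRUE).
#' @param global_selection Use a single selection computed from the outer
#'   fold assignment (the single-subset reading) instead of per-fold
#'   re-selection.
#' @return A named list of `cv_report` objects (one per classifier), each
#'   with per-fold metrics, mean metrics, chosen hyperparameters, selected
#'   features and the mean ROC curve.
#' @export
nested_cv <- function(table, specs, k_outer = 8L, k_inner = 7L, seed = 42L,
                      select = TRUE, global_selection = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels))
    .anf_stop("anf_validation_error", "feature table has no labels")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  y <- table$labels
  fa <- stratified_folds(y, k = k_outer, seed = seed)
  sel_global <- if (select && global_selection)
    select_features(table, fa, seed = seed) else NULL
  # per-fold preparation shared by all classifiers
  prep <- lapply(seq_len(k_outer), function(f) {
    tr <- which(fa != f); te <- which(fa == f)
    tr_tab <- feature_table(table$ids[tr], table$features[tr, , drop = FALSE],
                            y[tr])
    te_tab <- feature_table(table$ids[te], table$features[te, , drop = FALSE],
                            y[te])
    std <- standardize(tr_tab, te_tab)
    keep <- colnames(table$features)
    if (select) {
      sel <- if (global_selection) sel_global
      else {
        # the selection's own folds need >= 1 case per class per fold; on
        # small outer-training splits drop below the canonical 8
        k_sel <- min(8L, min(table(factor(y[tr], levels = c(0, 1)))))
        if (k_sel < 8L)
          warning(sprintf(
            "outer fold %d: training split too small for 8 selection folds, using %d",
            f, k_sel), call. = FALSE)
        select_features(tr_tab,
                        stratified_folds(y[tr], k = k_sel,
                                         seed = seed + 1000L + f),
                        seed = seed + 100L * f)
      }
      keep <- sel$N
    }
    list(fold = f,
         Xtr = std$train$features[, keep, drop = FALSE], ytr = y[tr],
         Xte = std$applied$features[, keep, drop = FALSE], yte = y[te],
         selected = keep)
  })
  out <- list()
  for (spec in specs) {
    fold_rows <- list(); fold_scores <- list(); chosen <- list()
    for (p in prep) {
      gs <- inner_grid_search(spec, p$Xtr, p$ytr, k_inner = k_inner,
                              seed = seed + 10L * p$fold)
      fit <- .fit_classifier(spec$name, p$Xtr, p$ytr, gs$best,
                             seed = seed + 10L * p$fold + 1L)
      sc <- .predict_score(fit, p$Xte)
      ms <- metric_suite(p$yte, as.integer(sc >= 0.5), sc)
      fold_rows[[p$fold]] <- c(fold = p$fold, ms)
      fold_scores[[p$fold]] <- list(y_true = p$yte, y_score = sc)
      chosen[[p$fold]] <- as.list(gs$best)
    }
    folds_df <- as.data.frame(do.call(rbind, fold_rows))
    mean_metrics <- colMeans(folds_df[, c("f2", "acc", "auc", "precision",
                                          "recall")])
    roc <- mean_roc(fold_scores)
    out[[spec$name]] <- structure(
      list(classifier = spec$name, folds = folds_df,
           mean = as.list(mean_metrics), hyperparameters = chosen,
           selected_features = lapply(prep, `[[`, "selected"),
           roc = roc, seed = seed, n = length(y)),
      class = "cv_report")
  }
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean F2 %.3f, ACC %.3f, AUC %.3f (n = %d, %d folds)\n",
              x$classifier, x$mean$f2, x$mean$acc, x$mean$auc, x$n,
              nrow(x$folds)))
  invisible(x)
}
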