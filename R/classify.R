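# Faller / non-faller classification under three feature conditions.
#
# Models: random forest (compiled CART ensemble), C-SVM (dual QP via
# quadprog) and k-nearest neighbours, each tuned over the published
# hyperparameter grids by leave-one-out grid search (macro-F1 on pooled
# LOOCV predictions) on a stratified 70% training split, then evaluated
# once on the held-out 30%.

#' Hyperparameter grid for a model
#'
#' Grids enumerate exactly the published combinations: RF 48
#' (trees {100,200,300} x depth {2,3} x min-split {2,5} x min-leaf {3,4} x
#' feature rule {sqrt, log2}), KNN 40 (k 1..10 x {uniform, distance} x
#' {euclidean, manhattan}), SVM 27 (C {0.1,1,10} x gamma {1,0.1,0.01} x
#' kernel {rbf, poly, sigmoid}).
#'
#' @param model One of `"rf"`, `"svm"`, `"knn"`.
#' @return Data frame, one row per hyperparameter combination.
#' @export
build_grid <- function(model) {
  switch(model,
    rf = expand.grid(n_estimators = c(100, 200, 300), max_depth = c(2, 3),
                     min_samples_split = c(2, 5), min_samples_leaf = c(3, 4),
                     max_features = c("sqrt", "log2"),
                     stringsAsFactors = FALSE),
    knn = expand.grid(n_neighbors = 1:10, weights = c("uniform", "distance"),
                      metric = c("euclidean", "manhattan"),
                      stringsAsFactors = FALSE),
    svm = expand.grid(C = c(0.1, 1, 10), gamma = c(1, 0.1, 0.01),
                      kernel = c("rbf", "poly", "sigmoid"),
                      stringsAsFactors = FALSE),
    stop("unknown model: ", model))
}

#' Feature columns for a condition
#' @param name One of `"gps"`, `"accel"`, `"combined"`.
#' @return Character vector of column names.
#' @export
feature_condition <- function(name) {
  switch(name,
    gps = gps_feature_names(),
    accel = gait_feature_names(),
    combined = c(gps_feature_names(), gait_feature_names()),
    stop("unknown condition: ", name))
}

# median imputation + z-score standardisation, fit on training rows only
.prep_fit <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  Xi <- X
  for (j in seq_len(ncol(X))) Xi[is.na(Xi[, j]), j] <- med[j]
  mu <- colMeans(Xi)
  sd <- apply(Xi, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(median = med, mu = mu, sd = sd)
}

.prep_apply <- function(prep, X) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$median[j]
  scale(X, center = prep$mu, scale = prep$sd)[, , drop = FALSE]
}

.kernel_matrix <- function(A, B, kernel, gamma) {
  G <- A %*% t(B)
  if (kernel == "rbf") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
    exp(-gamma * pmax(d2, 0))
  } else if (kernel == "poly") {
    (gamma * G)^3
  } else if (kernel == "sigmoid") {
    tanh(gamma * G)
  } else stop("unknown kernel: ", kernel)
}

# C-SVM dual via quadprog; y in {-1, 1}. Indefinite kernels (sigmoid) get
# an escalating ridge until the QP is solvable.
.svm_fit <- function(X, y, C, gamma, kernel) {
  n <- nrow(X)
  K <- .kernel_matrix(X, X, kernel, gamma)
  D <- (y %o% y) * K
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- tryCatch(
    quadprog::solve.QP(D + diag(1e-8 * max(1, mean(diag(K))), n),
                       rep(1, n), Amat, bvec, meq = 1),
    error = function(e) NULL)
  if (is.null(sol)) {
    # indefinite kernel (sigmoid, some poly settings): shift the spectrum
    # just past PSD and solve the convexified surrogate
    emin <- min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
    sol <- quadprog::solve.QP(D + diag(-emin + 1e-6 * max(1, -emin), n),
                              rep(1, n), Amat, bvec, meq = 1)
  }
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-8
  f_no_b <- as.numeric(K %*% (alpha * y))
  margin <- sv & alpha < C - 1e-8
  use <- if (any(margin)) margin else sv
  b <- mean(y[use] - f_no_b[use])
  list(alpha = alpha, y = y, X = X, b = b, gamma = gamma, kernel = kernel)
}

.svm_decision <- function(fit, Xnew) {
  K <- .kernel_matrix(Xnew, fit$X, fit$kernel, fit$gamma)
  as.numeric(K %*% (fit$alpha * fit$y)) + fit$b
}

.knn_score <- function(Xtr, ytr, Xte, k, weights, metric) {
  nte <- nrow(Xte)
  score <- numeric(nte)
  for (i in seq_len(nte)) {
    d <- if (metric == "euclidean")
      sqrt(rowSums((Xtr - matrix(Xte[i, ], nrow(Xtr), ncol(Xtr),
                                 byrow = TRUE))^2))
    else
      rowSums(abs(Xtr - matrix(Xte[i, ], nrow(Xtr), ncol(Xtr),
                               byrow = TRUE)))
    ord <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
    if (weights == "uniform") {
      score[i] <- mean(ytr[ord])
    } else {
      dn <- d[ord]
      if (any(dn == 0)) {
        score[i] <- mean(ytr[ord][dn == 0])
      } else {
        w <- 1 / dn
        score[i] <- sum(w * ytr[ord]) / sum(w)
      }
    }
  }
  score
}

# Fit one model at one hyperparameter row on preprocessed matrices and
# return class-1 scores for Xte. Scores are probabilities for rf/knn and
# decision values for svm (monotone equivalent for ROC).
.fit_predict <- function(model, par, Xtr, ytr, Xte, seed) {
  p <- ncol(Xtr)
  if (model == "rf") {
    mtry <- if (par$max_features == "sqrt") max(1L, floor(sqrt(p)))
            else max(1L, floor(log2(p)))
    .rf_train_predict(Xtr, as.integer(ytr), Xte,
                      as.integer(par$n_estimators), as.integer(par$max_depth),
                      as.integer(par$min_samples_split),
                      as.integer(par$min_samples_leaf), as.integer(mtry),
                      as.integer(seed))
  } else if (model == "svm") {
    fit <- .svm_fit(Xtr, ifelse(ytr == 1, 1, -1), par$C, par$gamma,
                    as.character(par$kernel))
    .svm_decision(fit, Xte)
  } else {
    .knn_score(Xtr, ytr, Xte, par$n_neighbors, as.character(par$weights),
               as.character(par$metric))
  }
}

.score_to_class <- function(model, score) {
  thr <- if (model == "svm") 0 else 0.5
  as.integer(score > thr)
}

.macro_f1 <- function(truth, pred) {
  f1 <- vapply(c(0, 1), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Rank-based AUC
#'
#' Area under the ROC curve of `score` for detecting `truth == 1`
#' (Mann-Whitney formulation; ties get half credit).
#' @param truth 0/1 labels.
#' @param score Numeric scores.
#' @return AUC in [0, 1] (`NA` if a class is absent).
#' @export
auc <- function(truth, score) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pre-computed LOOCV folds: preprocessing (imputation + scaling) is refit
# inside every fold (no leakage), once, and shared by all grid rows.
.loocv_folds <- function(X) {
  lapply(seq_len(nrow(X)), function(i) {
    prep <- .prep_fit(X[-i, , drop = FALSE])
    list(Xtr = .prep_apply(prep, X[-i, , drop = FALSE]),
         Xte = .prep_apply(prep, X[i, , drop = FALSE]))
  })
}

# Pooled-prediction LOOCV of one model/par on a training set. Returns
# macro-F1 and per-fold accuracy indicators.
.loocv <- function(model, par, folds, y, seed) {
  n <- length(folds)
  pred <- integer(n)
  for (i in seq_len(n)) {
    sc <- .fit_predict(model, par, folds[[i]]$Xtr, y[-i], folds[[i]]$Xte,
                       seed + i)
    pred[i] <- .score_to_class(model, sc)
  }
  list(macro_f1 = .macro_f1(y, pred), fold_acc = as.numeric(pred == y))
}

.stratified_split <- function(y, test_frac, seed) {
  test_idx <- integer(0)
  .with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      n_test <- round(test_frac * length(idx))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  sort(test_idx)
}

#' Fit and evaluate one model under one feature condition
#'
#' Stratified 70/30 split; median imputation and z-scoring fit on training
#' rows only; hyperparameters chosen by leave-one-out grid search on the
#' training split (macro-F1 of pooled LOOCV predictions, ties to the first
#' grid row); the winner is refit on the full training split and reported
#' on the untouched test split. ROC/AUC come from the test-split scores of
#' that single fit, without retraining.
#'
#' @param cohort_table Data frame from [cohort_features()].
#' @param condition `"gps"`, `"accel"` or `"combined"`.
#' @param model `"rf"`, `"svm"` or `"knn"`.
#' @param split_seed Integer seed controlling the split and all model
#'   randomness.
#' @param test_frac Test fraction (0.3).
#' @return A `model_report`: list with `model`, `condition`, `chosen`
#'   (hyperparameters), `precision`, `recall`, `f1` (named per class),
#'   `accuracy`, `loocv_accuracy_sd`, `auc`, `roc` (data frame of
#'   fpr/tpr), `test_n`.
#' @export
fit_evaluate <- function(cohort_table, condition, model, split_seed = 42,
                         test_frac = 0.3) {
  cols <- feature_condition(condition)
  stopifnot(all(cols %in% names(cohort_table)))
  X <- as.matrix(cohort_table[, cols])
  y <- as.integer(cohort_table$group == "faller")
  if (min(table(y)) < 4) stop("need at least 4 subjects per class")
  test_idx <- .stratified_split(y, test_frac, split_seed)
  if (length(unique(y[test_idx])) < 2 ||
      length(unique(y[-test_idx])) < 2)
    stop("a class is absent from one split")
  Xtr_raw <- X[-test_idx, , drop = FALSE]; ytr <- y[-test_idx]
  Xte_raw <- X[test_idx, , drop = FALSE];  yte <- y[test_idx]

  grid <- build_grid(model)
  best <- NULL; best_f1 <- -Inf; best_folds <- NULL
  if (model == "rf") {
    # trees are invariant to monotone feature scaling, so the z-score
    # stage is immaterial; imputation uses the training-split medians.
    # The whole grid x LOOCV runs in compiled code.
    prep0 <- .prep_fit(Xtr_raw)
    Xi <- Xtr_raw
    for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- prep0$median[j]
    p <- ncol(Xi)
    checkpoints <- sort(unique(grid$n_estimators))
    base <- unique(grid[, c("max_depth", "min_samples_split",
                            "min_samples_leaf", "max_features")])
    mtry <- ifelse(base$max_features == "sqrt",
                   pmax(1L, floor(sqrt(p))), pmax(1L, floor(log2(p))))
    probs <- .rf_grid_loocv(Xi, as.integer(ytr),
                            as.integer(checkpoints),
                            as.integer(base$max_depth),
                            as.integer(base$min_samples_split),
                            as.integer(base$min_samples_leaf),
                            as.integer(mtry), as.integer(split_seed))
    for (r in seq_len(nrow(grid))) {
      b <- which(base$max_depth == grid$max_depth[r] &
                 base$min_samples_split == grid$min_samples_split[r] &
                 base$min_samples_leaf == grid$min_samples_leaf[r] &
                 base$max_features == grid$max_features[r])
      ck <- match(grid$n_estimators[r], checkpoints)
      pred <- as.integer(probs[(b - 1) * length(checkpoints) + ck, ] > 0.5)
      f1 <- .macro_f1(ytr, pred)
      if (f1 > best_f1 + 1e-12) {
        best_f1 <- f1; best <- grid[r, , drop = FALSE]
        best_folds <- as.numeric(pred == ytr)
      }
    }
  } else {
    folds <- .loocv_folds(Xtr_raw)
    for (r in seq_len(nrow(grid))) {
      cv <- .loocv(model, grid[r, , drop = FALSE], folds, ytr,
                   seed = split_seed * 1000 + r)
      if (cv$macro_f1 > best_f1 + 1e-12) {
        best_f1 <- cv$macro_f1; best <- grid[r, , drop = FALSE]
        best_folds <- cv$fold_acc
      }
    }
  }

  prep <- .prep_fit(Xtr_raw)
  Xtr <- .prep_apply(prep, Xtr_raw)
  Xte <- .prep_apply(prep, Xte_raw)
  score <- .fit_predict(model, best, Xtr, ytr, Xte, seed = split_seed)
  pred <- .score_to_class(model, score)

  prf <- vapply(c(nonfaller = 0, faller = 1), function(cl) {
    tp <- sum(pred == cl & yte == cl)
    fp <- sum(pred == cl & yte != cl)
    fn <- sum(pred != cl & yte == cl)
    c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
      recall = if (tp + fn == 0) 0 else tp / (tp + fn),
      f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }, numeric(3))

  ths <- c(Inf, sort(unique(score), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(ths, function(th) mean(score[yte == 0] >= th), 0),
    tpr = vapply(ths, function(th) mean(score[yte == 1] >= th), 0))

  structure(list(model = model, condition = condition, chosen = best,
                 cv_macro_f1 = best_f1,
                 precision = prf["precision", ], recall = prf["recall", ],
                 f1 = prf["f1", ],
                 accuracy = mean(pred == yte),
                 loocv_accuracy_sd = stats::sd(best_folds),
                 auc = auc(yte, score), roc = roc,
                 test_n = length(yte)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<%s on %s features> accuracy %.3f, AUC %.3f, LOOCV SD %.3f\n",
              x$model, x$condition, x$accuracy, x$auc, x$loocv_accuracy_sd))
  m <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(m, 3))
  invisible(x)
}

#' Run all models under all feature conditions
#'
#' @param cohort_table Data frame from [cohort_features()].
#' @param seed Split/model seed passed to every [fit_evaluate()] call.
#' @param models,conditions Subsets to run.
#' @return Named list of nine `model_report`s
#'   (`<condition>.<model>`), plus attribute `summary`, a data frame
#'   mirroring the study's report tables.
#' @export
run_conditions <- function(cohort_table, seed = 42,
                           models = c("rf", "svm", "knn"),
                           conditions = c("gps", "accel", "combined")) {
  reports <- list()
  for (cond in conditions)
    for (m in models)
      reports[[paste(cond, m, sep = ".")]] <-
        fit_evaluate(cohort_table, cond, m, split_seed = seed)
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(condition = r$condition, model = r$model,
               precision_nonfaller = r$precision[["nonfaller"]],
               precision_faller = r$precision[["faller"]],
               recall_nonfaller = r$recall[["nonfaller"]],
               recall_faller = r$recall[["faller"]],
               f1_nonfaller = r$f1[["nonfaller"]],
               f1_faller = r$f1[["faller"]],
               accuracy = r$accuracy, sd = r$loocv_accuracy_sd,
               auc = r$auc)))
  rownames(summary) <- NULL
  attr(reports, "summary") <- summary
  reports
}
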