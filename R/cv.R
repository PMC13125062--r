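#' Subject-level K-fold assignment
#'
#' Assigns whole subjects to folds so that all longitudinal visits of a
#' subject share one fold, preventing identity leakage across train/test.
#' Folds are balanced in subject count to within one.
#'
#' @param subject_ids vector of subject identifiers (one entry per subject or
#'   per visit; duplicates are collapsed).
#' @param K number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return Object of class `cv_split`: data.frame `assignment` (subject,
#'   fold), `K`, `seed`.
#' @export
subject_kfold <- function(subject_ids, K = 5, seed = 1) {
  if (K < 2) stop("K must be at least 2")
  subjects <- unique(as.character(subject_ids))
  if (length(subjects) < K) stop("need at least K subjects")
  rng <- local_rng(seed)
  shuffled <- sample(subjects)
  restore_rng(rng)
  fold <- rep_len(seq_len(K), length(shuffled))
  structure(list(
    assignment = data.frame(subject = shuffled, fold = fold,
                            stringsAsFactors = FALSE),
    K = K, seed = seed
  ), class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat(sprintf("Subject-level %d-fold split: %d subjects (seed %s)\n",
              x$K, nrow(x$assignment), format(x$seed)))
  print(table(fold = x$assignment$fold))
  invisible(x)
}

#' Fold of each visit under a subject-level split
#' @param cv a `cv_split`.
#' @param subject_ids per-visit subject identifiers.
#' @return Integer fold per visit.
#' @export
fold_of <- function(cv, subject_ids) {
  f <- cv$assignment$fold[match(as.character(subject_ids), cv$assignment$subject)]
  if (anyNA(f)) stop("subject(s) missing from the cv split")
  f
}

#' Regressor specification for the prediction harness
#'
#' The GP with ARD is the primary model; the remaining regressors form the
#' comparison zoo run through the identical cross-validation and confound
#' harness.
#'
#' @param name one of `"gp_ard"`, `"lasso"`, `"elastic_net"`,
#'   `"random_forest"`, `"svr"`, `"mlp"`.
#' @param ... hyperparameters passed to the underlying fitter.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("gp_ard", "lasso", "elastic_net",
                                "random_forest", "svr", "mlp"), ...) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...)), class = "model_spec")
}

# Fit one regressor on (standardized-inside) training data; returns a list
# with a predict(newX) closure. Seeded deterministically by the caller.
fit_regressor <- function(spec, X, y, seed = 1) {
  X <- as.matrix(X)
  prm <- spec$params
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  switch(spec$name,
    gp_ard = {
      fit <- do.call(gp_ard, c(list(X = X, y = y), prm))
      list(fit = fit, predict = function(newX) predict(fit, newX))
    },
    lasso = ,
    elastic_net = {
      alpha <- if (spec$name == "lasso") 1 else prm$alpha %||% 0.5
      nfolds <- prm$nfolds %||% 5
      fit <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nfolds)
      list(fit = fit, predict = function(newX)
        as.numeric(stats::predict(fit, newx = as.matrix(newX), s = "lambda.min")))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = X, y = y,
        num.trees = prm$num.trees %||% 300,
        mtry = prm$mtry %||% max(1, floor(ncol(X) / 3)),
        seed = seed, num.threads = 1)
      list(fit = fit, predict = function(newX)
        stats::predict(fit, data = as.data.frame(as.matrix(newX)))$predictions)
    },
    svr = {
      fit <- e1071::svm(x = X, y = y, type = "eps-regression",
                        kernel = prm$kernel %||% "radial",
                        cost = prm$cost %||% 1, epsilon = prm$epsilon %||% 0.1)
      list(fit = fit, predict = function(newX)
        as.numeric(stats::predict(fit, as.matrix(newX))))
    },
    mlp = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
      Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      fit <- nnet::nnet(Xs, y, size = prm$size %||% 8, linout = TRUE,
                        decay = prm$decay %||% 0.01,
                        maxit = prm$maxit %||% 300, trace = FALSE,
                        MaxNWts = 100000)
      list(fit = fit, predict = function(newX) {
        newXs <- sweep(sweep(as.matrix(newX), 2, ctr), 2, scl, "/")
        as.numeric(stats::predict(fit, newXs))
      })
    }
  )
}

#' Score predictions against observations
#'
#' @param pred,obs numeric vectors of equal length (>= 3).
#' @return List with `mse`, `r` (Pearson) and `p` (two-sided t
#'   approximation for the correlation). If either vector has zero variance,
#'   `r` and `p` are `NA` and `degenerate = TRUE`.
#' @export
evaluate_prediction <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) < 3) stop("need at least 3 paired values")
  mse <- mean((pred - obs)^2)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    return(list(mse = mse, r = NA_real_, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(pred, obs)
  n <- length(pred)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(mse = mse, r = r, p = p, degenerate = FALSE)
}

# Shared inner loop: residualize features and target with training-fold
# confound models, fit the regressor on training visits, predict test visits.
# Returns test predictions and residualized test observations.
.fit_fold <- function(spec, features, target, confounds, subjects,
                      train_idx, test_idx, seed, fold_id = NA) {
  ftr_tr <- features[train_idx, , drop = FALSE]
  ftr_te <- features[test_idx, , drop = FALSE]
  y_tr <- target[train_idx]
  y_te <- target[test_idx]
  if (!is.null(confounds)) {
    conf_tr <- confounds[train_idx, , drop = FALSE]
    conf_te <- confounds[test_idx, , drop = FALSE]
    sub_tr <- subjects[train_idx]
    all_idx <- c(train_idx, test_idx)
    Xres <- residualize_matrix(ftr_tr, conf_tr, sub_tr,
                               rbind(ftr_tr, ftr_te),
                               rbind(conf_tr, conf_te), fitted_on = fold_id)
    ftr_tr <- Xres[seq_along(train_idx), , drop = FALSE]
    ftr_te <- Xres[length(train_idx) + seq_along(test_idx), , drop = FALSE]
    ymod <- fit_confound_model(y_tr, conf_tr, sub_tr, fitted_on = fold_id)
    y_tr <- residualize(ymod, y_tr, conf_tr)
    y_te <- residualize(ymod, y_te, conf_te)
  }
  reg <- fit_regressor(spec, ftr_tr, y_tr, seed = seed)
  list(pred = reg$predict(ftr_te), obs = y_te, model = reg$fit)
}

#' Cross-validated prediction of a target from FC features
#'
#' For each fold: confound models are fitted on the training visits only and
#' applied to training and test visits (fixed effects); the regressor is
#' fitted on the residualized training data and scored on the residualized
#' held-out visits. Out-of-fold predictions are concatenated and scored by
#' MSE and Pearson r.
#'
#' @param features n_visits x p numeric matrix of vectorized FC features.
#' @param target numeric per-visit response (e.g. whole-brain or regional FA).
#' @param visits data.frame with columns `subject` and `visit` aligned with
#'   the rows of `features`.
#' @param cv a [subject_kfold()] split covering all subjects.
#' @param model a [model_spec()] (default ARD GP).
#' @param confounds optional data.frame of per-visit confound columns; NULL
#'   skips confound removal.
#' @param target_name label stored in the result.
#' @param keep_models keep per-fold fitted models (needed for
#'   [feature_importance()]).
#' @param seed seed for the per-fold regressor fits.
#' @return Object of class `sfc_cv`: data.frame `rows` (subject, visit, fold,
#'   predicted, observed), `summary` (mse, r, p), per-fold `models`, `target`.
#' @export
cross_validated_prediction <- function(features, target, visits, cv,
                                       model = model_spec("gp_ard"),
                                       confounds = NULL, target_name = "target",
                                       keep_models = TRUE, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(target) != n || nrow(visits) != n)
    stop("features, target and visits are not aligned")
  fold <- fold_of(cv, visits$subject)
  # leakage guard: every subject must sit in exactly one fold
  if (any(tapply(fold, visits$subject, function(f) length(unique(f))) != 1))
    stop("subject spans multiple folds (leakage)")
  rows <- vector("list", cv$K)
  models <- vector("list", cv$K)
  for (f in seq_len(cv$K)) {
    te <- which(fold == f); tr <- which(fold != f)
    res <- .fit_fold(model, features, target, confounds, visits$subject,
                     tr, te, seed = child_seed(seed, f), fold_id = f)
    rows[[f]] <- data.frame(subject = visits$subject[te],
                            visit = visits$visit[te],
                            fold = f, predicted = res$pred,
                            observed = res$obs, stringsAsFactors = FALSE)
    models[[f]] <- if (keep_models) res$model else NULL
  }
  rows <- do.call(rbind, rows)
  summ <- evaluate_prediction(rows$predicted, rows$observed)
  # fold-averaged accuracy: the within-fold correlation, averaged over folds.
  # Unlike the pooled r it is immune to the between-fold-mean artifact that
  # biases pooled out-of-fold correlations negative under the null.
  summ$r_fold_mean <- mean(vapply(split(rows, rows$fold), function(d)
    safe_cor(d$predicted, d$observed), 1), na.rm = TRUE)
  structure(list(rows = rows,
                 summary = summ,
                 models = if (keep_models) models else NULL,
                 target = target_name, model_name = model$name, cv = cv),
            class = "sfc_cv")
}

#' @export
print.sfc_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Cross-validated %s prediction of '%s': %d visits, %d folds\n  MSE = %.4g, r = %.3f (p = %.3g)\n",
    x$model_name, x$target, nrow(x$rows), x$cv$K, s$mse, s$r, s$p))
  invisible(x)
}

#' @export
summary.sfc_cv <- function(object, ...) {
  c(list(target = object$target, model = object$model_name,
         n_visits = nrow(object$rows)), object$summary)
}

#' @export
plot.sfc_cv <- function(x, ...) {
  plot(x$rows$observed, x$rows$predicted,
       xlab = "observed (confound-adjusted)", ylab = "predicted",
       main = sprintf("%s: r = %.3f", x$target, x$summary$r),
       col = x$rows$fold, pch = 16, cex = 0.6, ...)
  abline(stats::lm(predicted ~ observed, data = x$rows), lty = 2)
  invisible(x)
}

#' Train-on-one-set, test-on-another evaluation
#'
#' Fits a single model on `train_subset` (confound models fitted within it
#' and applied to both sets) and scores on the disjoint `test_subset`. Used
#' for cross-sex, cross-scanner and cross-cohort generalization checks.
#'
#' @param train_subset,test_subset logical or integer row indices into the
#'   visit table; subject sets must be disjoint.
#' @inheritParams cross_validated_prediction
#' @return An `sfc_cv` object with a single pseudo-fold.
#' @export
transfer_evaluate <- function(train_subset, test_subset, features, target,
                              visits, model = model_spec("gp_ard"),
                              confounds = NULL, target_name = "target",
                              seed = 1) {
  tr <- if (is.logical(train_subset)) which(train_subset) else as.integer(train_subset)
  te <- if (is.logical(test_subset)) which(test_subset) else as.integer(test_subset)
  if (length(intersect(unique(visits$subject[tr]), unique(visits$subject[te]))))
    stop("train and test subject sets overlap")
  res <- .fit_fold(model, as.matrix(features), target, confounds,
                   visits$subject, tr, te, seed = seed, fold_id = "transfer")
  rows <- data.frame(subject = visits$subject[te], visit = visits$visit[te],
                     fold = 1L, predicted = res$pred, observed = res$obs,
                     stringsAsFactors = FALSE)
  structure(list(rows = rows,
                 summary = evaluate_prediction(rows$predicted, rows$observed),
                 models = list(res$model), target = target_name,
                 model_name = model$name,
                 cv = structure(list(K = 1L), class = "cv_split")),
            class = "sfc_cv")
}

#' Stratified scoring of an existing prediction result
#'
#' Re-scores the out-of-fold predictions within strata (e.g. scanner types)
#' without refitting any model.
#'
#' @param result an `sfc_cv`.
#' @param strata per-visit stratum labels aligned with `result$rows`.
#' @return data.frame with one row per stratum: n, mse, r, p.
#' @export
evaluate_strata <- function(result, strata) {
  if (length(strata) != nrow(result$rows))
    stop("strata must align with the prediction rows")
  out <- lapply(split(seq_along(strata), strata), function(idx) {
    e <- evaluate_prediction(result$rows$predicted[idx], result$rows$observed[idx])
    data.frame(n = length(idx), mse = e$mse, r = e$r, p = e$p)
  })
  cbind(stratum = names(out), do.call(rbind, out), row.names = NULL)
}
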