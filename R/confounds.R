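# Mixed-effects confound removal.
#
# Every FC feature and FA target is adjusted for age, sex, scanner, SES and
# race/ethnicity with a linear model carrying a random subject intercept,
# fitted by REML on training visits only and applied to all visits through
# its fixed effects. Because the pipeline fits one model per FC feature per
# fold (hundreds to thousands of fits), the random-intercept REML problem is
# solved here directly by profiling the variance ratio, which reduces each
# fit to a one-dimensional optimization over cheap per-subject sufficient
# statistics. lme4 fits the identical model and is used as the reference
# implementation in the test suite.

# Core REML fit of y = X b + u_subject + e with one variance ratio
# lambda = sigma_u^2 / sigma_e^2. `group` is an integer grouping vector.
lmm_ri <- function(y, X, group) {
  X <- as.matrix(X)
  n <- length(y); q <- ncol(X)
  if (n != nrow(X)) stop("length(y) and nrow(X) differ")
  if (n <= q) stop("more coefficients than observations")
  g <- as.integer(factor(group))
  ni <- tabulate(g)
  S <- rowsum(X, g)                  # per-subject column sums of X
  t_y <- rowsum(y, g)[, 1]           # per-subject sums of y
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y * y)

  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- lam / (1 + lam * ni)
    A <- XtX - crossprod(S, w * S)
    b <- Xty - colSums(w * t_y * S)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(crit = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rVr <- yty - sum(w * t_y^2) - sum(beta * b)
    rVr <- max(rVr, 1e-300)
    sigma2 <- rVr / (n - q)
    crit <- (n - q) * log(sigma2) + sum(log1p(lam * ni)) +
      2 * sum(log(diag(ch)))
    list(crit = crit, beta = beta, sigma2 = sigma2, lam = lam, chol = ch)
  }

  multi_visit <- any(ni > 1)
  if (multi_visit) {
    opt <- stats::optimize(function(l) profile(l)$crit, interval = c(-15, 10))
    best <- profile(opt$minimum)
    # compare against the no-random-intercept boundary
    ols <- profile(-30)
    if (ols$crit <= best$crit) best <- ols
  } else {
    best <- profile(-30)
  }
  lam <- if (best$lam < 1e-10) 0 else best$lam
  sigma_e <- sqrt(best$sigma2)
  vcov <- best$sigma2 * chol2inv(best$chol)
  beta <- best$beta
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(beta = beta, sigma_u = sigma_e * sqrt(lam), sigma_e = sigma_e,
       lambda = lam, vcov = vcov, reml_criterion = best$crit,
       n = n, n_groups = length(ni), multi_visit = multi_visit)
}

# Build the one-hot (treatment-coded) confound design. Character/factor
# columns are expanded against first-level reference; numerics (age, SES)
# kept as-is. `xlevels` freezes factor levels at fit time; unseen levels at
# apply time are mapped to the reference with a warning.
confound_design <- function(confounds, xlevels = NULL) {
  confounds <- as.data.frame(confounds)
  for (nm in names(confounds)) {
    v <- confounds[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      lev <- if (!is.null(xlevels) && nm %in% names(xlevels)) xlevels[[nm]]
             else sort(unique(as.character(v)))
      vv <- factor(as.character(v), levels = lev)
      if (anyNA(vv) & !anyNA(v)) {
        warning("unseen level(s) in '", nm, "' mapped to reference level")
        vv[is.na(vv)] <- lev[1]
      }
      confounds[[nm]] <- vv
    }
  }
  X <- if (ncol(confounds) == 0) {
    matrix(1, nrow(confounds), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = confounds)
  }
  lev <- lapply(confounds[vapply(confounds, is.factor, TRUE)], levels)
  list(X = X, xlevels = lev)
}

#' Fit a confound-removal model
#'
#' Fits `y ~ confounds + (1 | subject)` by REML: fixed effects for every
#' confound column (one-hot for categoricals, first level as reference) plus
#' a random subject intercept. When no subject contributes more than one
#' visit the random intercept is unidentifiable and the fit reduces to
#' ordinary least squares (a warning is logged).
#'
#' @param y numeric per-visit response (an FC feature, an FA value, a gap, or
#'   a behavioral measure).
#' @param confounds data.frame of per-visit confound values.
#' @param subject_ids per-visit subject identifiers.
#' @param fitted_on optional fold label recorded for train/test hygiene.
#' @return Object of class `confound_model` with elements `coefficients`,
#'   `sigma_u`, `sigma_e`, `confound_columns`, `xlevels`, `fitted_on`.
#' @export
fit_confound_model <- function(y, confounds, subject_ids, fitted_on = NULL) {
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  des <- confound_design(confounds)
  qrX <- qr(des$X)
  if (qrX$rank < ncol(des$X)) {
    bad <- colnames(des$X)[qrX$pivot[(qrX$rank + 1):ncol(des$X)]]
    stop("singular confound design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- lmm_ri(y, des$X, subject_ids)
  if (!fit$multi_visit)
    warning("all subjects have a single visit; fitted by ordinary least squares")
  structure(list(
    coefficients = fit$beta,
    sigma_u = fit$sigma_u,
    sigma_e = fit$sigma_e,
    vcov = fit$vcov,
    confound_columns = names(confounds),
    xlevels = des$xlevels,
    fitted_on = fitted_on,
    n = fit$n, n_subjects = fit$n_groups
  ), class = "confound_model")
}

#' @export
print.confound_model <- function(x, ...) {
  cat(sprintf(
    "Random-intercept confound model: %d visits, %d subjects\n  sigma_subject = %.4g, sigma_resid = %.4g%s\n",
    x$n, x$n_subjects, x$sigma_u, x$sigma_e,
    if (is.null(x$fitted_on)) "" else paste0(" (fitted on fold ", x$fitted_on, ")")
  ))
  print(x$coefficients)
  invisible(x)
}

#' Remove fitted confound effects from new data
#'
#' Subtracts the fixed-effect prediction of a [fit_confound_model()] fit.
#' Random subject intercepts are deliberately not subtracted: under
#' subject-level cross-validation test subjects were never seen at training
#' time, so only the fixed effects transfer out of sample.
#'
#' @param model a `confound_model`.
#' @param y per-visit values to adjust.
#' @param confounds data.frame with the columns the model was fitted on.
#' @return Numeric residuals, same length as `y`.
#' @export
residualize <- function(model, y, confounds) {
  if (!identical(sort(model$confound_columns), sort(names(confounds))))
    stop("confound columns do not match the fitted model")
  confounds <- confounds[model$confound_columns]
  X <- confound_design(confounds, xlevels = model$xlevels)$X
  X <- X[, names(model$coefficients), drop = FALSE]
  as.numeric(y - X %*% model$coefficients)
}

#' Column-wise confound removal for a matrix of measures
#'
#' Fits one random-intercept confound model per column of `Y_train` (shared
#' design across columns) and returns the fixed-effect residuals for the
#' apply-time data. This is the batch form used for the per-feature FC and
#' per-target FA adjustment inside cross-validation folds: models are fitted
#' on training visits only and applied to training and test visits alike.
#'
#' @param Y_train numeric visits x measures matrix the models are fitted on.
#' @param confounds_train data.frame of confounds for the training visits.
#' @param subjects_train training-visit subject identifiers.
#' @param Y_apply,confounds_apply the visits to residualize (may include the
#'   training visits).
#' @param fitted_on optional fold label for train/test hygiene bookkeeping.
#' @return Residual matrix with the dimensions of `Y_apply`.
#' @export
residualize_matrix <- function(Y_train, confounds_train, subjects_train,
                               Y_apply, confounds_apply, fitted_on = NULL) {
  des <- confound_design(confounds_train)
  Xa <- confound_design(confounds_apply[names(confounds_train)],
                        xlevels = des$xlevels)$X
  out <- matrix(NA_real_, nrow(Y_apply), ncol(Y_apply),
                dimnames = dimnames(Y_apply))
  for (j in seq_len(ncol(Y_train))) {
    fit <- lmm_ri(Y_train[, j], des$X, subjects_train)
    out[, j] <- Y_apply[, j] - Xa[, names(fit$beta), drop = FALSE] %*% fit$beta
  }
  out
}
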