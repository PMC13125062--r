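# Regularized CCA linking structure-function gaps to behavior.
#
# The ridge regularization follows the shrinkage convention
# C_xx(c) = (1 - c) * cov(X) + c * I on standardized variables, with c
# searched over a logarithmic grid in [1e-4, 1]; weights come from the SVD
# of the whitened cross-covariance. Inference is by subject-level
# permutation of the behavior side.

#' Logarithmic regularization grid
#' @param min,max grid range (default 1e-4 .. 1).
#' @param count number of values (default 50).
#' @param log logarithmic spacing (default TRUE).
#' @return Numeric vector of candidate shrinkage values.
#' @export
reg_grid <- function(min = 1e-4, max = 1, count = 50, log = TRUE) {
  if (log) exp(seq(base::log(min), base::log(max), length.out = count))
  else seq(min, max, length.out = count)
}

# Core regularized CCA on standardized training matrices. Returns weights
# (columns = components) in the standardized space and training correlations.
# `cov` may carry precomputed crossproducts (Sxx, Syy, Sxy over n rows) so a
# regularization grid can be scanned without touching the data again.
rcca_core <- function(Xs, Ys, c1, c2, k, cov = NULL) {
  if (is.null(cov)) {
    n <- nrow(Xs)
    cov <- list(Sxx = crossprod(Xs) / (n - 1),
                Syy = crossprod(Ys) / (n - 1),
                Sxy = crossprod(Xs, Ys) / (n - 1))
  }
  Cxx <- (1 - c1) * cov$Sxx + c1 * diag(nrow(cov$Sxx))
  Cyy <- (1 - c2) * cov$Syy + c2 * diag(nrow(cov$Syy))
  Cxy <- cov$Sxy
  Rx <- chol(Cxx); Ry <- chol(Cyy)
  M <- forwardsolve(t(Rx), Cxy)       # Rx^-T Cxy
  M <- t(forwardsolve(t(Ry), t(M)))   # ... Ry^-1
  sv <- svd(M, nu = k, nv = k)
  Wx <- backsolve(Rx, sv$u[, seq_len(k), drop = FALSE])
  Wy <- backsolve(Ry, sv$v[, seq_len(k), drop = FALSE])
  list(Wx = Wx, Wy = Wy, cors = sv$d[seq_len(k)])
}

# Standardize with training statistics; zero-variance columns get unit scale.
.std_fit <- function(M) {
  ctr <- colMeans(M); scl <- apply(M, 2, stats::sd); scl[scl == 0] <- 1
  list(ctr = ctr, scl = scl)
}
.std_apply <- function(M, s) sweep(sweep(M, 2, s$ctr), 2, s$scl, "/")

# Median-impute missing entries column-wise using training medians.
.impute_fit <- function(M) apply(M, 2, stats::median, na.rm = TRUE)
.impute_apply <- function(M, med) {
  for (j in seq_len(ncol(M))) {
    bad <- is.na(M[, j])
    if (any(bad)) M[bad, j] <- med[j]
  }
  M
}

#' Drop behavior measures with excessive missingness
#'
#' Removes measures missing for more than `max_missing` of participants
#' (default: more than half), evaluated at the subject level (a measure
#' counts as present for a subject if observed at any visit).
#'
#' @param behavior data.frame/matrix of per-visit measures.
#' @param subject_ids per-visit subject identifiers.
#' @param max_missing maximum tolerated missing fraction (default 0.5).
#' @return The filtered behavior matrix.
#' @export
prepare_behavior <- function(behavior, subject_ids, max_missing = 0.5) {
  B <- as.matrix(behavior)
  subjects <- unique(subject_ids)
  frac_missing <- vapply(seq_len(ncol(B)), function(j) {
    seen <- tapply(!is.na(B[, j]), subject_ids, any)
    1 - mean(seen)
  }, 1)
  B[, frac_missing <= max_missing, drop = FALSE]
}

# Inner 80/20 subject split of the training fold selecting (c1, c2) by the
# first-component canonical correlation on the held-in validation part.
.select_reg <- function(X, Y, subjects, grid, k, seed) {
  subj <- unique(subjects)
  rng <- local_rng(seed)
  val_subj <- sample(subj, size = max(1, round(0.2 * length(subj))))
  restore_rng(rng)
  val <- subjects %in% val_subj
  Xs_f <- .std_fit(X[!val, , drop = FALSE])
  Ys_f <- .std_fit(Y[!val, , drop = FALSE])
  Xtr <- .std_apply(X[!val, , drop = FALSE], Xs_f)
  Ytr <- .std_apply(Y[!val, , drop = FALSE], Ys_f)
  Xva <- .std_apply(X[val, , drop = FALSE], Xs_f)
  Yva <- .std_apply(Y[val, , drop = FALSE], Ys_f)
  n_in <- nrow(Xtr)
  cov <- list(Sxx = crossprod(Xtr) / (n_in - 1),
              Syy = crossprod(Ytr) / (n_in - 1),
              Sxy = crossprod(Xtr, Ytr) / (n_in - 1))
  best <- c(NA, NA); best_val <- -Inf
  for (c1 in grid) for (c2 in grid) {
    fit <- tryCatch(rcca_core(NULL, NULL, c1, c2, 1, cov = cov),
                    error = function(e) NULL)
    if (is.null(fit)) next
    v <- safe_cor(Xva %*% fit$Wx[, 1], Yva %*% fit$Wy[, 1])
    if (!is.na(v) && v > best_val) { best_val <- v; best <- c(c1, c2) }
  }
  if (is.na(best[1])) best <- c(grid[length(grid)], grid[length(grid)])
  best
}

#' Cross-validated regularized CCA
#'
#' Relates corrected structure-function gaps to behavioral measures. Within
#' each training fold: behavior confounds (if given) are regressed out with
#' random-intercept models fitted on the training visits; the shrinkage pair
#' (c_x, c_y) is chosen by a nested 80/20 subject split maximizing the
#' first-component validation correlation; canonical weights are fitted on
#' the full training fold. Each component's correlation between the
#' projected X and Y is then computed on the held-out fold and averaged over
#' folds. Components are ordered by training canonical correlation; weight
#' signs are aligned across folds before out-of-fold variates are
#' concatenated.
#'
#' @param X numeric visits x targets matrix of corrected gaps.
#' @param Y numeric visits x measures behavior matrix (NAs allowed; median
#'   imputation with training-fold medians).
#' @param visits data.frame with `subject`, `visit` aligned with rows.
#' @param cv a [subject_kfold()] split.
#' @param grid regularization candidates (see [reg_grid()]).
#' @param n_components number of canonical components (default 10, capped at
#'   min(dim)).
#' @param confounds_y optional data.frame of behavior confounds (age, sex,
#'   race, SES).
#' @param fixed_reg optional `c(c1, c2)` skipping the grid search.
#' @param seed RNG seed (inner splits).
#' @return Object of class `rcca_cv`: `test_cor` (mean over folds, per
#'   component), `per_fold` (fold x component test correlations), `folds`
#'   (per-fold weights and chosen regularization), `variates` (out-of-fold
#'   canonical variates with subject/visit keys), `n_components`.
#' @export
fit_rcca <- function(X, Y, visits, cv, grid = reg_grid(),
                     n_components = 10, confounds_y = NULL,
                     fixed_reg = NULL, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n || nrow(visits) != n) stop("X, Y, visits not aligned")
  k <- min(n_components, ncol(X), ncol(Y))
  if (k < n_components)
    warning("n_components reduced to ", k, " (matrix dimensions)")
  fold <- fold_of(cv, visits$subject)
  per_fold <- matrix(NA_real_, cv$K, k)
  folds <- vector("list", cv$K)
  var_rows <- vector("list", cv$K)
  ref_Wx <- NULL
  for (f in seq_len(cv$K)) {
    te <- which(fold == f); tr <- which(fold != f)
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    Ytr <- Y[tr, , drop = FALSE]; Yte <- Y[te, , drop = FALSE]
    med <- .impute_fit(Ytr)
    Ytr <- .impute_apply(Ytr, med); Yte <- .impute_apply(Yte, med)
    if (!is.null(confounds_y)) {
      Ytr0 <- Ytr
      Ytr <- residualize_matrix(Ytr0, confounds_y[tr, , drop = FALSE],
                                visits$subject[tr], Ytr0,
                                confounds_y[tr, , drop = FALSE])
      Yte <- residualize_matrix(Ytr0, confounds_y[tr, , drop = FALSE],
                                visits$subject[tr], Yte,
                                confounds_y[te, , drop = FALSE])
    }
    reg <- if (!is.null(fixed_reg)) fixed_reg
           else .select_reg(Xtr, Ytr, visits$subject[tr], grid, k,
                            seed = child_seed(seed, f))
    sx <- .std_fit(Xtr); sy <- .std_fit(Ytr)
    fit <- rcca_core(.std_apply(Xtr, sx), .std_apply(Ytr, sy),
                     reg[1], reg[2], k)
    # sign-align components to the first fold for concatenable variates
    if (is.null(ref_Wx)) ref_Wx <- fit$Wx
    flip <- sign(colSums(fit$Wx * ref_Wx))
    flip[flip == 0] <- 1
    fit$Wx <- sweep(fit$Wx, 2, flip, "*")
    fit$Wy <- sweep(fit$Wy, 2, flip, "*")
    Ux <- .std_apply(Xte, sx) %*% fit$Wx
    Uy <- .std_apply(Yte, sy) %*% fit$Wy
    per_fold[f, ] <- vapply(seq_len(k), function(j) safe_cor(Ux[, j], Uy[, j]), 1)
    folds[[f]] <- list(Wx = fit$Wx, Wy = fit$Wy, reg = reg,
                       train_cors = fit$cors, std_x = sx, std_y = sy)
    var_rows[[f]] <- data.frame(subject = visits$subject[te],
                                visit = visits$visit[te], fold = f,
                                x_variate = I(Ux), y_variate = I(Uy))
  }
  variates <- do.call(rbind, var_rows)
  structure(list(test_cor = colMeans(per_fold, na.rm = TRUE),
                 per_fold = per_fold, folds = folds, variates = variates,
                 n_components = k, cv = cv, seed = seed,
                 grid = grid, fixed_reg = fixed_reg),
            class = "rcca_cv")
}

#' @export
print.rcca_cv <- function(x, ...) {
  cat(sprintf("Cross-validated regularized CCA: %d components, %d folds\n",
              x$n_components, x$cv$K))
  cat("  CV-averaged test correlations:\n  ")
  cat(sprintf("%.3f", x$test_cor), sep = "  ")
  cat("\n")
  invisible(x)
}

#' @export
coef.rcca_cv <- function(object, side = c("x", "y"), ...) {
  side <- match.arg(side)
  w <- lapply(object$folds, function(f) if (side == "x") f$Wx else f$Wy)
  Reduce(`+`, w) / length(w)
}

# Subject-level permutation of row blocks: blocks are permuted among
# subjects with the same visit count, so every row keeps a partner row and
# within-subject covariance is preserved exactly.
permute_subject_blocks <- function(subject_ids) {
  idx <- seq_along(subject_ids)
  blocks <- split(idx, subject_ids)
  sizes <- lengths(blocks)
  out <- idx
  for (s in unique(sizes)) {
    cls <- which(sizes == s)
    if (length(cls) < 2) next
    perm <- sample(length(cls))
    from <- unlist(blocks[cls], use.names = FALSE)
    to <- unlist(blocks[cls[perm]], use.names = FALSE)
    out[from] <- to
  }
  out
}

#' Permutation inference for the canonical correlations
#'
#' Builds a null distribution by permuting the behavior rows across subjects
#' (all visits of a subject move together, so longitudinal dependence is
#' respected) and re-running the cross-validated CCA for each permutation.
#' By default the regularization grid search is re-run per permutation
#' (conservative); `refit_grid = FALSE` reuses the regularization selected on
#' the observed data, which is much faster.
#'
#' @inheritParams fit_rcca
#' @param result optional pre-computed [fit_rcca()] result for the observed
#'   data (recomputed if missing).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param refit_grid re-run the regularization search per permutation.
#' @param fixed_reg optional `c(c1, c2)` used for the observed fit and (when
#'   `refit_grid = FALSE`) for every permutation.
#' @return List: `p` (per component), `observed` (test correlations),
#'   `null` (n_perm x components matrix), `result`.
#' @export
permutation_test_cca <- function(X, Y, visits, cv, grid = reg_grid(),
                                 n_components = 10, confounds_y = NULL,
                                 result = NULL, n_perm = 1000,
                                 refit_grid = TRUE, fixed_reg = NULL,
                                 seed = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives low p-value resolution")
  if (is.null(result))
    result <- fit_rcca(X, Y, visits, cv, grid = grid,
                       n_components = n_components,
                       confounds_y = confounds_y, fixed_reg = fixed_reg,
                       seed = seed)
  k <- result$n_components
  fixed <- if (refit_grid) NULL else (fixed_reg %||% result$folds[[1]]$reg)
  rng <- local_rng(child_seed(seed, 7919))
  perm_seeds <- sample.int(2^31 - 1, n_perm)
  nulls <- matrix(NA_real_, n_perm, k)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    idx <- permute_subject_blocks(visits$subject)
    fit_b <- fit_rcca(X, Y[idx, , drop = FALSE], visits, cv, grid = grid,
                      n_components = k,
                      confounds_y = if (is.null(confounds_y)) NULL
                                    else confounds_y[idx, , drop = FALSE],
                      fixed_reg = fixed, seed = child_seed(seed, b))
    nulls[b, ] <- fit_b$test_cor
  }
  restore_rng(rng)
  p <- vapply(seq_len(k), function(j)
    (1 + sum(nulls[, j] >= result$test_cor[j])) / (1 + n_perm), 1)
  list(p = p, observed = result$test_cor, null = nulls, result = result)
}

#' Canonical loadings with permutation significance
#'
#' A variable's loading on a component is its Pearson correlation with the
#' concatenated out-of-fold canonical variate of its own side. Significance
#' of |loading| comes from the same subject-level permutation scheme
#' (behavior permuted, CCA refitted with the selected regularization, null
#' loadings recomputed).
#'
#' @param result an [fit_rcca()] result.
#' @param X,Y the matrices the result was fitted on.
#' @param visits data.frame with `subject`, `visit`.
#' @param component which component to interrogate (default 1).
#' @param n_perm permutations for the loading null (0 skips inference).
#' @param seed RNG seed.
#' @return List with data.frames `x` and `y`: variable, loading, p.
#' @export
canonical_loadings <- function(result, X, Y, visits, component = 1,
                               n_perm = 0, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  med <- .impute_fit(Y)
  Yi <- .impute_apply(Y, med)
  v <- result$variates
  key_fit <- paste(v$subject, v$visit, sep = "\r")
  key_dat <- paste(visits$subject, visits$visit, sep = "\r")
  idx <- match(key_fit, key_dat)
  ux <- v$x_variate[, component]; uy <- v$y_variate[, component]
  load_of <- function(M, u) {
    vapply(seq_len(ncol(M)), function(j) {
      if (stats::sd(M[idx, j]) == 0) {
        warning("zero-variance variable at column ", j)
        return(NA_real_)
      }
      stats::cor(M[idx, j], u)
    }, 1)
  }
  lx <- load_of(X, ux); ly <- load_of(Yi, uy)
  out <- list(
    x = data.frame(variable = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                   loading = lx, p = NA_real_, stringsAsFactors = FALSE),
    y = data.frame(variable = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
                   loading = ly, p = NA_real_, stringsAsFactors = FALSE))
  if (n_perm > 0) {
    fixed <- result$folds[[1]]$reg
    rng <- local_rng(child_seed(seed, 104729))
    perm_seeds <- sample.int(2^31 - 1, n_perm)
    cx <- matrix(0L, length(lx), 1); cy <- matrix(0L, length(ly), 1)
    for (b in seq_len(n_perm)) {
      set.seed(perm_seeds[b])
      pidx <- permute_subject_blocks(visits$subject)
      fit_b <- fit_rcca(X, Yi[pidx, , drop = FALSE], visits, result$cv,
                        grid = result$grid, n_components = component,
                        fixed_reg = fixed, seed = child_seed(seed, b))
      vb <- fit_b$variates
      ib <- match(paste(vb$subject, vb$visit, sep = "\r"), key_dat)
      uxb <- vb$x_variate[, component]; uyb <- vb$y_variate[, component]
      lxb <- vapply(seq_len(ncol(X)), function(j)
        safe_cor(X[ib, j], uxb), 1)
      lyb <- vapply(seq_len(ncol(Yi)), function(j)
        safe_cor(Yi[pidx, , drop = FALSE][ib, j], uyb), 1)
      cx <- cx + (abs(lxb) >= abs(lx))
      cy <- cy + (abs(lyb) >= abs(ly))
    }
    restore_rng(rng)
    out$x$p <- as.numeric((1 + cx) / (1 + n_perm))
    out$y$p <- as.numeric((1 + cy) / (1 + n_perm))
  }
  out
}
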