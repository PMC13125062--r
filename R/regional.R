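#' Cross-validated prediction for the whole-brain and every regional target
#'
#' Runs the identical prediction harness (same subject-level fold split, same
#' confound handling, same regressor) once per FA target: the whole-brain
#' skeleton value plus each white-matter region.
#'
#' @param features n_visits x p FC feature matrix.
#' @param fa_table data.frame of FA targets: one column per target (must
#'   include `whole_brain`), rows aligned with `features`.
#' @param visits data.frame with `subject`, `visit` columns.
#' @param cv a [subject_kfold()] split (shared across all targets).
#' @param model a [model_spec()].
#' @param confounds optional per-visit confound data.frame.
#' @param atlas optional `atlas_spec`; attaches volume and tract metadata to
#'   the accuracy table.
#' @param alpha reliability-filter significance level (default 0.05).
#' @param seed base seed for per-target fits.
#' @return List: `accuracy` (per-target data.frame with mse, r, p,
#'   retained_flag, volume_cm3, mean_observed_fa), `results` (named list of
#'   `sfc_cv`), `importance` (named list of `importance_vector`, GP only),
#'   `retained` (character vector of retained targets).
#' @export
predict_all_regions <- function(features, fa_table, visits, cv,
                                model = model_spec("gp_ard"),
                                confounds = NULL, atlas = NULL,
                                alpha = 0.05, seed = 1) {
  targets <- names(fa_table)
  if (!"whole_brain" %in% targets)
    stop("fa_table must contain a 'whole_brain' column")
  results <- list(); importance <- list()
  for (k in seq_along(targets)) {
    tg <- targets[k]
    if (anyNA(fa_table[[tg]])) stop("missing FA values in target: ", tg)
    res <- cross_validated_prediction(
      features, fa_table[[tg]], visits, cv, model = model,
      confounds = confounds, target_name = tg,
      keep_models = TRUE, seed = child_seed(seed, k))
    results[[tg]] <- res
    if (model$name == "gp_ard")
      importance[[tg]] <- feature_importance(res$models)
  }
  rel <- reliability_filter(results, alpha = alpha)
  acc <- data.frame(
    target = targets,
    mse = vapply(results, function(r) r$summary$mse, 1),
    r = vapply(results, function(r) r$summary$r, 1),
    p = vapply(results, function(r) r$summary$p, 1),
    retained_flag = targets %in% rel$retained,
    mean_observed_fa = vapply(targets, function(tg) mean(fa_table[[tg]]), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(atlas)) {
    m <- match(acc$target, atlas$wm$name)
    acc$volume_cm3 <- atlas$wm$volume_cm3[m]
    acc$tract <- atlas$wm$tract[m]
  }
  list(accuracy = acc, results = results, importance = importance,
       retained = rel$retained, reliability = rel$table)
}

#' Reliability filter for regional prediction models
#'
#' A target is retained only when the observed FA is a significant predictor
#' of the out-of-fold predicted FA under a linear mixed-effects model with
#' random subject intercepts (`predicted ~ observed + (1 | subject)`),
#' i.e. when the slope p-value is below `alpha`.
#'
#' @param pred_results named list of `sfc_cv` objects (or a single one).
#' @param alpha significance level (default 0.05).
#' @return List: `retained` (names of retained targets), `table`
#'   (per-target slope, p, retained).
#' @export
reliability_filter <- function(pred_results, alpha = 0.05) {
  if (inherits(pred_results, "sfc_cv")) pred_results <- list(pred_results)
  nm <- names(pred_results) %||%
    vapply(pred_results, function(r) r$target, "")
  rows <- lapply(seq_along(pred_results), function(i) {
    r <- pred_results[[i]]$rows
    if (stats::sd(r$observed) == 0 || stats::sd(r$predicted) == 0) {
      warning("degenerate variance in target ", nm[i], "; excluded")
      return(data.frame(target = nm[i], slope = NA_real_, p = NA_real_,
                        retained = FALSE))
    }
    fit <- lmm_ri(r$predicted, cbind(`(Intercept)` = 1, observed = r$observed),
                  r$subject)
    z <- fit$beta["observed"] / sqrt(fit$vcov["observed", "observed"])
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(target = nm[i], slope = unname(fit$beta["observed"]),
               p = unname(p), retained = unname(p < alpha))
  })
  tab <- do.call(rbind, rows)
  list(retained = tab$target[tab$retained], table = tab)
}

#' Is regional accuracy explained by region size or FA magnitude?
#'
#' Correlates per-region prediction accuracy with region volume and with the
#' cohort-mean observed FA.
#'
#' @param accuracy per-target accuracy data.frame from
#'   [predict_all_regions()] (needs columns `r`, `volume_cm3`,
#'   `mean_observed_fa`; the whole-brain row is ignored).
#' @return data.frame with one row per covariate: r, p.
#' @export
accuracy_covariate_check <- function(accuracy) {
  acc <- accuracy[accuracy$target != "whole_brain", , drop = FALSE]
  if (nrow(acc) < 3) stop("need at least 3 regional targets")
  out <- lapply(c(volume_cm3 = "volume_cm3", mean_fa = "mean_observed_fa"),
                function(cv) {
    x <- acc[[cv]]
    if (is.null(x) || stats::sd(x) == 0) {
      warning("constant or missing covariate: ", cv)
      return(data.frame(r = NA_real_, p = NA_real_))
    }
    e <- evaluate_prediction(acc$r, x)
    data.frame(r = e$r, p = e$p)
  })
  cbind(covariate = names(out), do.call(rbind, out), row.names = NULL)
}

#' Embed per-region importance vectors in two dimensions
#'
#' Rows (one importance vector per retained white-matter region) are
#' L2-normalized so overall scale differences between targets do not
#' dominate, then projected with [umap_embed()].
#'
#' @param importance_matrix retained-regions x features numeric matrix.
#' @param n_neighbors,min_dist,n_epochs embedding parameters.
#' @param seed RNG seed.
#' @param normalize L2-normalize rows first (default TRUE).
#' @return Object of class `embedding_result`: `coords` (n x 2), parameters.
#' @export
embed_importance <- function(importance_matrix, n_neighbors = 5,
                             min_dist = 0.1, n_epochs = 300, seed = 1,
                             normalize = TRUE) {
  M <- as.matrix(importance_matrix)
  if (nrow(M) < 4) stop("need at least 4 regions to embed")
  if (normalize) {
    nrm <- sqrt(rowSums(M^2))
    nrm[nrm == 0] <- 1
    M <- M / nrm
  }
  coords <- umap_embed(M, n_neighbors = n_neighbors, min_dist = min_dist,
                       n_epochs = n_epochs, seed = seed)
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               n_epochs = n_epochs, seed = seed,
                               normalize = normalize)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("2D embedding of %d regions (n_neighbors = %d, min_dist = %g, seed = %s)\n",
              nrow(x$coords), x$params$n_neighbors, x$params$min_dist,
              format(x$params$seed)))
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, labels = NULL, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(x$coords, col = col, pch = 16, ...)
  if (!is.null(labels))
    text(x$coords, labels = labels, pos = 3, cex = 0.6, col = col)
  invisible(x)
}

# All permutations of 1..n (n small), in a deterministic order.
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# One-way PERMANOVA pseudo-F from a squared-distance accounting.
.pseudo_F <- function(D2, labels) {
  n <- nrow(D2)
  groups <- split(seq_len(n), labels)
  a <- length(groups)
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- sum(vapply(groups, function(idx) {
    if (length(idx) < 2) return(0)
    sub <- D2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 1))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' One-way PERMANOVA on points or a distance matrix
#'
#' Tests whether groups differ in multivariate location using the
#' permutational pseudo-F on (Euclidean, unless a distance matrix is given)
#' distances. The p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` for
#' sampled label permutations, or the exact fraction over all label
#' permutations when `method = "exhaustive"`.
#'
#' @param x numeric point matrix (rows = observations) or a `dist` /
#'   symmetric distance matrix.
#' @param group_labels grouping factor.
#' @param n_perm number of sampled permutations (default 999).
#' @param seed RNG seed for the sampled permutations.
#' @param method `"sampled"` (default) or `"exhaustive"` (all n!
#'   relabellings; only for small n).
#' @return List with `F` (pseudo-F), `p`, `n_perm_used`, `method`.
#' @export
permanova_test <- function(x, group_labels, n_perm = 999, seed = 1,
                           method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  D <- if (inherits(x, "dist")) as.matrix(x)
       else if (is.matrix(x) && isSymmetric(unname(x)) && all(diag(x) == 0) &&
                nrow(x) == length(group_labels) && ncol(x) == nrow(x)) x
       else as.matrix(stats::dist(x))
  n <- nrow(D)
  labels <- factor(group_labels)
  if (length(labels) != n) stop("group_labels length must match observations")
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2))
    message("group(s) with a single member present; power is reduced")
  if (nlevels(droplevels(labels)) >= n)
    stop("PERMANOVA needs fewer groups than observations")
  D2 <- D^2
  F_obs <- .pseudo_F(D2, labels)
  if (!is.finite(F_obs)) {
    warning("degenerate design (zero within-group dispersion); p undefined")
    return(list(F = F_obs, p = NA_real_, n_perm_used = 0L, method = method))
  }
  if (method == "exhaustive") {
    if (n > 9) stop("exhaustive enumeration limited to n <= 9")
    perms <- .all_perms(n)
    Fs <- apply(perms, 1, function(idx) .pseudo_F(D2, labels[idx]))
    p <- mean(Fs >= F_obs - 1e-12)
    return(list(F = F_obs, p = p, n_perm_used = nrow(perms),
                method = "exhaustive"))
  }
  if (n_perm < 100) warning("fewer than 100 permutations: low p resolution")
  rng <- local_rng(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (.pseudo_F(D2, labels[sample.int(n)]) >= F_obs - 1e-12)
      count <- count + 1L
  }
  restore_rng(rng)
  list(F = F_obs, p = (1 + count) / (1 + n_perm), n_perm_used = n_perm,
       method = "sampled")
}
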