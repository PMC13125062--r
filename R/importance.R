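#' Inverse-lengthscale feature importance, averaged over folds
#'
#' For each FC feature the importance is \eqn{1/\ell}, the inverse ARD
#' lengthscale, averaged across the per-fold GP fits. The coefficient of
#' variation (sd/mean) of \eqn{1/\ell} across folds quantifies the stability
#' of each feature's importance.
#'
#' @param models list of per-fold `gp_ard` fits (e.g. `result$models` from
#'   [cross_validated_prediction()]).
#' @return Object of class `importance_vector`: data.frame `table` (feature,
#'   importance, cov), matrix `per_fold` (folds x features), `cov_summary`
#'   (median CoV across features).
#' @export
feature_importance <- function(models) {
  models <- Filter(Negate(is.null), models)
  if (!length(models)) stop("no models supplied")
  if (!all(vapply(models, inherits, TRUE, "gp_ard")))
    stop("feature importance is defined for gp_ard models")
  ells <- do.call(rbind, lapply(models, function(m) m$lengthscales))
  if (any(ells <= 0)) stop("non-positive lengthscale encountered")
  inv <- 1 / ells
  imp <- colMeans(inv)
  cv <- if (nrow(inv) > 1) apply(inv, 2, stats::sd) / imp else rep(NA_real_, ncol(inv))
  cv[imp == 0] <- NA_real_
  tab <- data.frame(feature = colnames(ells) %||% paste0("f", seq_along(imp)),
                    importance = unname(imp), cov = unname(cv),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, per_fold = inv,
                 cov_summary = stats::median(cv, na.rm = TRUE)),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  cat(sprintf("Feature importance (1/lengthscale) over %d folds, %d features\n",
              nrow(x$per_fold), nrow(x$table)))
  cat(sprintf("  median CoV across folds: %.3g\n", x$cov_summary))
  top <- x$table[order(-x$table$importance), ][seq_len(min(5, nrow(x$table))), ]
  print(top, row.names = FALSE)
  invisible(x)
}

#' Aggregate feature importance to gray-matter regions
#'
#' A bilateral region's score aggregates the importance of every FC feature
#' whose pair contains that region; the homotopic self-feature (region
#' paired with itself) is counted once.
#'
#' @param imp an `importance_vector` (or numeric vector named/ordered like
#'   the feature index).
#' @param feature_index data.frame from [fc_feature_index()] matching the
#'   feature order.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Named numeric vector of per-region scores.
#' @export
regional_importance <- function(imp, feature_index, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  v <- if (inherits(imp, "importance_vector")) imp$table$importance else as.numeric(imp)
  if (length(v) != nrow(feature_index))
    stop("importance length does not match the feature index")
  regions <- unique(c(feature_index$region_i, feature_index$region_j))
  out <- vapply(regions, function(g) {
    hit <- feature_index$region_i == g | feature_index$region_j == g
    if (!any(hit)) stop("region absent from feature index: ", g)
    if (aggregate == "mean") mean(v[hit]) else sum(v[hit])
  }, numeric(1))
  stats::setNames(out, regions)
}

#' Friedman rank comparison of regression models across targets
#'
#' Ranks model accuracies within each target (rank 1 = most accurate, ties
#' averaged) and tests whether models differ via the Friedman chi-squared
#' statistic.
#'
#' @param accuracy numeric models x targets matrix of accuracies (higher is
#'   better), with model names as rownames.
#' @return List with `mean_ranks` (per model), `statistic`, `p`, and the
#'   full `ranks` matrix.
#' @export
friedman_rank <- function(accuracy) {
  accuracy <- as.matrix(accuracy)
  if (nrow(accuracy) < 2 || ncol(accuracy) < 2)
    stop("need at least 2 models and 2 targets")
  if (anyNA(accuracy)) stop("missing cells in the accuracy matrix")
  ranks <- apply(accuracy, 2, function(col) rank(-col))
  mean_ranks <- rowMeans(ranks)
  ft <- stats::friedman.test(t(accuracy))
  list(mean_ranks = sort(mean_ranks), statistic = unname(ft$statistic),
       p = ft$p.value, ranks = ranks)
}

#' Tract-averaged importance profiles and their top features
#'
#' Averages per-target importance vectors over the white-matter regions of
#' each anatomical tract family and lists the top-k features per tract (ties
#' broken by feature index).
#'
#' @param importances numeric targets x features matrix (rownames = wm
#'   region names) of fold-averaged importance.
#' @param atlas an `atlas_spec` supplying the region-to-tract grouping.
#' @param top_k how many top features to report per tract (default 10).
#' @return List per tract: `profile` (mean importance vector) and
#'   `top_features` (data.frame feature, importance).
#' @export
tract_importance_profile <- function(importances, atlas, top_k = 10) {
  importances <- as.matrix(importances)
  grp <- atlas$wm$tract[match(rownames(importances), atlas$wm$name)]
  if (anyNA(grp)) stop("importance rows not found in atlas wm table")
  out <- list()
  for (tr in unique(atlas$wm$tract)) {
    members <- which(grp == tr)
    if (!length(members)) {
      warning("tract with no retained member skipped: ", tr)
      next
    }
    prof <- colMeans(importances[members, , drop = FALSE])
    ord <- order(-prof, seq_along(prof))  # ties broken by feature index
    k <- min(top_k, length(prof))
    out[[tr]] <- list(
      profile = prof,
      top_features = data.frame(
        feature = (colnames(importances) %||% paste0("f", seq_along(prof)))[ord[1:k]],
        importance = prof[ord[1:k]], row.names = NULL, stringsAsFactors = FALSE))
  }
  out
}

#' Transfer regional scores between atlases by a weighted mapping
#'
#' Maps per-region scores from atlas A into atlas B through a user-supplied
#' correspondence matrix (rows = A regions, columns = B regions). Weights
#' are normalized per B column; B regions receiving zero total weight are
#' dropped with a warning.
#'
#' @param scores_a named numeric vector of scores in atlas A.
#' @param mapping numeric A x B matrix with dimnames naming the regions.
#' @param native_scores_b optional named scores measured natively in atlas B;
#'   if given, the Pearson correlation between transferred and native scores
#'   is reported.
#' @return List with `scores_b` and (optionally) `correlation`, `p`.
#' @export
cross_atlas_transfer <- function(scores_a, mapping, native_scores_b = NULL) {
  mapping <- as.matrix(mapping)
  if (is.null(rownames(mapping)) || is.null(colnames(mapping)))
    stop("mapping needs region names as dimnames")
  a <- scores_a[rownames(mapping)]
  if (anyNA(a)) stop("scores_a missing for some mapped regions")
  colsum <- colSums(mapping)
  keep <- colsum > 0
  if (any(!keep))
    warning("B region(s) with zero mapping weight dropped: ",
            paste(colnames(mapping)[!keep], collapse = ", "))
  W <- sweep(mapping[, keep, drop = FALSE], 2, colsum[keep], "/")
  scores_b <- as.numeric(crossprod(W, a))
  names(scores_b) <- colnames(W)
  out <- list(scores_b = scores_b)
  if (!is.null(native_scores_b)) {
    common <- intersect(names(scores_b), names(native_scores_b))
    e <- evaluate_prediction(scores_b[common], native_scores_b[common])
    out$correlation <- e$r
    out$p <- e$p
  }
  out
}
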