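#' Structure-function gap: predicted minus observed FA
#'
#' Assembles the per-visit raw gap for each retained target from the
#' out-of-fold predictions. A positive gap means the observed white-matter
#' integrity sits below the level the FC pattern predicts.
#'
#' @param pred_results named list of `sfc_cv` objects (retained regional
#'   targets plus the whole brain).
#' @return data.frame with `subject`, `visit` keys and one gap column per
#'   target.
#' @export
compute_gap <- function(pred_results) {
  if (inherits(pred_results, "sfc_cv")) pred_results <- list(pred_results)
  nm <- names(pred_results) %||% vapply(pred_results, function(r) r$target, "")
  base <- pred_results[[1]]$rows[c("subject", "visit")]
  key <- paste(base$subject, base$visit, sep = "\r")
  out <- base
  for (i in seq_along(pred_results)) {
    r <- pred_results[[i]]$rows
    idx <- match(key, paste(r$subject, r$visit, sep = "\r"))
    if (anyNA(idx)) {
      miss <- key[which(is.na(idx))[1]]
      stop("missing prediction row for visit key: ", gsub("\r", "/", miss),
           " in target ", nm[i])
    }
    out[[nm[i]]] <- r$predicted[idx] - r$observed[idx]
  }
  out
}

#' Correct gaps for head motion and FA magnitude
#'
#' Per target, regresses the raw gap on the per-visit mean relative
#' displacement and the observed FA value with a random subject intercept,
#' and keeps the fixed-effect residual. This removes the two trivial routes
#' to a large residual: noisy scans and large FA values.
#'
#' @param gaps data.frame from [compute_gap()].
#' @param motion numeric per-visit mean relative displacement aligned with
#'   `gaps` rows; visits with missing motion are dropped with a warning.
#' @param observed_fa data.frame of per-visit observed FA with the same
#'   target columns as `gaps`.
#' @return data.frame like `gaps` with corrected gap columns.
#' @export
correct_gap <- function(gaps, motion, observed_fa) {
  targets <- setdiff(names(gaps), c("subject", "visit"))
  if (!all(targets %in% names(observed_fa)))
    stop("observed_fa lacks columns: ",
         paste(setdiff(targets, names(observed_fa)), collapse = ", "))
  if (length(motion) != nrow(gaps)) stop("motion not aligned with gaps")
  keep <- !is.na(motion)
  if (any(!keep)) {
    warning(sum(!keep), " visit(s) dropped for missing motion")
    gaps <- gaps[keep, , drop = FALSE]
    observed_fa <- observed_fa[keep, , drop = FALSE]
    motion <- motion[keep]
  }
  out <- gaps[c("subject", "visit")]
  for (tg in targets) {
    X <- cbind(`(Intercept)` = 1, motion = motion, observed = observed_fa[[tg]])
    fit <- lmm_ri(gaps[[tg]], X, gaps$subject)
    out[[tg]] <- as.numeric(gaps[[tg]] - X %*% fit$beta)
  }
  out
}

#' Spearman SC-FC coupling baseline
#'
#' The traditional per-region coupling statistic: for each region, the
#' Spearman rank correlation between its structural-connectivity profile and
#' its functional-connectivity profile (diagonal excluded).
#'
#' @param sc non-negative region x region structural connectivity matrix.
#' @param fc `fc_matrix` (or symmetric matrix) over the same regions.
#' @return Named numeric vector of per-region coupling values (`NA` with a
#'   warning for all-tied rows).
#' @export
scfc_spearman_coupling <- function(sc, fc) {
  sc <- as.matrix(sc); fc <- as.matrix(fc)
  if (!all(dim(sc) == dim(fc))) stop("SC and FC dimensions differ")
  if (any(sc < 0)) stop("SC must be non-negative")
  labs <- rownames(fc) %||% paste0("V", seq_len(nrow(fc)))
  n <- nrow(fc)
  out <- stats::setNames(rep(NA_real_, n), labs)
  for (g in seq_len(n)) {
    s <- sc[g, -g]; f <- fc[g, -g]
    if (length(unique(s)) < 2 || length(unique(f)) < 2) {
      warning("all-tied profile for region ", labs[g], "; coupling undefined")
      next
    }
    out[g] <- stats::cor(s, f, method = "spearman")
  }
  out
}
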