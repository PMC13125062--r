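#' Functional connectivity matrices and their vectorized feature form
#'
#' An FC matrix is a symmetric region-by-region Pearson correlation matrix.
#' After hemispheric averaging the diagonal no longer holds trivial ones but
#' the homotopic correlation of each region with its contralateral homologue;
#' the `diagonal` attribute records which convention is in force
#' (`"unit"` or `"homotopic"`).
#'
#' @param values symmetric numeric matrix.
#' @param region_labels character vector of region names (defaults to existing
#'   dimnames or `V1..VR`).
#' @param diagonal `"unit"` or `"homotopic"`.
#' @return A matrix of class `fc_matrix` with a `diagonal` attribute.
#' @export
fc_matrix <- function(values, region_labels = NULL,
                      diagonal = c("unit", "homotopic")) {
  diagonal <- match.arg(diagonal)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("FC matrix must be square")
  if (max(abs(values - t(values))) > 1e-8) stop("FC matrix must be symmetric")
  off <- values[row(values) != col(values)]
  if (any(off < -1 - 1e-8 | off > 1 + 1e-8))
    stop("off-diagonal FC entries must lie in [-1, 1]")
  if (diagonal == "unit" && max(abs(diag(values) - 1)) > 1e-8)
    stop("unit-diagonal FC matrix must have ones on the diagonal")
  if (is.null(region_labels)) {
    region_labels <- rownames(values) %||% paste0("V", seq_len(nrow(values)))
  }
  dimnames(values) <- list(region_labels, region_labels)
  structure(values, diagonal = diagonal, class = c("fc_matrix", "matrix", "array"))
}

#' Pearson FC from regional BOLD time series
#'
#' @param series numeric T x R matrix: T timepoints, one column per region.
#' @return An `fc_matrix` with unit diagonal.
#' @export
fc_from_timeseries <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("need at least 3 timepoints")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  fc_matrix(stats::cor(series), region_labels = colnames(series), diagonal = "unit")
}

#' Hemispheric averaging of an FC matrix
#'
#' Collapses a unilateral 2R x 2R unit-diagonal FC matrix into an R x R
#' bilateral matrix. The off-diagonal entry for bilateral regions (i, j) is
#' the mean of the four cross-hemisphere correlations
#' {LiLj, LiRj, RiLj, RiRj}; the diagonal entry for region i is the homotopic
#' correlation cor(Li, Ri).
#'
#' @param fc an `fc_matrix` with unit diagonal over unilateral regions.
#' @param pairing data.frame with columns `left`, `right`, `name` (as from
#'   [atlas_pairing()]).
#' @param fisher average on the Fisher z scale and back-transform (default
#'   FALSE: plain averaging of correlations).
#' @return An `fc_matrix` with `diagonal = "homotopic"`.
#' @export
bilateral_average <- function(fc, pairing, fisher = FALSE) {
  if (attr(fc, "diagonal") != "unit")
    stop("bilateral_average expects a unit-diagonal unilateral FC matrix")
  labs <- rownames(fc)
  missing <- setdiff(c(pairing$left, pairing$right), labs)
  if (length(missing))
    stop("regions in pairing absent from FC matrix: ", paste(missing, collapse = ", "))
  extra <- setdiff(labs, c(pairing$left, pairing$right))
  if (length(extra))
    stop("unpaired region(s) in FC matrix: ", paste(extra, collapse = ", "))
  li <- match(pairing$left, labs)
  ri <- match(pairing$right, labs)
  vals <- unclass(fc)
  if (fisher) vals <- fisher_z(vals)
  out <- (vals[li, li] + vals[li, ri] + vals[ri, li] + vals[ri, ri]) / 4
  out <- (out + t(out)) / 2
  diag(out) <- diag(vals[li, ri])
  if (fisher) out <- tanh(out)
  fc_matrix(out, region_labels = pairing$name, diagonal = "homotopic")
}

#' Feature index of the vectorized FC matrix
#'
#' Row-major upper-triangular order: (1,1), (1,2), ..., (1,R), (2,2), ...
#' This order is fixed package-wide so importance maps, planted supports and
#' regional aggregation always refer to the same features.
#'
#' @param region_labels character vector of R bilateral region names.
#' @param include_diagonal keep the homotopic self-features (default TRUE).
#' @return data.frame with columns `region_i`, `region_j`, `feature`.
#' @export
fc_feature_index <- function(region_labels, include_diagonal = TRUE) {
  R <- length(region_labels)
  idx <- which(upper.tri(matrix(0, R, R), diag = include_diagonal), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    region_i = region_labels[idx[, 1]],
    region_j = region_labels[idx[, 2]],
    feature = paste(region_labels[idx[, 1]], region_labels[idx[, 2]], sep = "|"),
    stringsAsFactors = FALSE
  )
}

#' Vectorize a symmetric FC matrix
#'
#' @param fc an `fc_matrix` (or symmetric matrix).
#' @param include_diagonal include diagonal entries (default TRUE, giving
#'   R(R+1)/2 features; 1431 for R = 53).
#' @return Named numeric vector in [fc_feature_index()] order, with the index
#'   attached as attribute `feature_index`.
#' @export
vectorize_fc <- function(fc, include_diagonal = TRUE) {
  fc <- as.matrix(fc)
  if (max(abs(fc - t(fc))) > 1e-8) stop("matrix is asymmetric beyond tolerance")
  labs <- rownames(fc) %||% paste0("V", seq_len(nrow(fc)))
  idx <- fc_feature_index(labs, include_diagonal)
  v <- fc[cbind(match(idx$region_i, labs), match(idx$region_j, labs))]
  names(v) <- idx$feature
  attr(v, "feature_index") <- idx
  v
}

#' Rebuild the symmetric matrix from a vectorized FC
#'
#' Inverse of [vectorize_fc()]. When the diagonal was excluded it is filled
#' with ones.
#'
#' @param v vector as returned by [vectorize_fc()] (or any vector with a
#'   matching `feature_index` attribute / names in `i|j` form).
#' @param feature_index optional index data.frame overriding the attribute.
#' @return An `fc_matrix`.
#' @export
devectorize_fc <- function(v, feature_index = NULL) {
  idx <- feature_index %||% attr(v, "feature_index")
  if (is.null(idx)) {
    parts <- strsplit(names(v), "|", fixed = TRUE)
    idx <- data.frame(region_i = vapply(parts, `[`, "", 1),
                      region_j = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  }
  labs <- unique(c(idx$region_i, idx$region_j))
  R <- length(labs)
  m <- matrix(NA_real_, R, R, dimnames = list(labs, labs))
  i <- match(idx$region_i, labs); j <- match(idx$region_j, labs)
  m[cbind(i, j)] <- v
  m[cbind(j, i)] <- v
  has_diag <- any(i == j)
  if (!has_diag) diag(m) <- 1
  fc_matrix(m, labs, diagonal = if (has_diag) "homotopic" else "unit")
}

#' Fisher z-transform (optional pre-averaging transform)
#' @param r correlations in (-1, 1); values are clamped to +/- (1 - 1e-12).
#' @return atanh of the clamped input.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
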