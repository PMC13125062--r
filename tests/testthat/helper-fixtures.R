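# Shared fixtures: small cohorts and toy matrices built in code.

small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n_subjects = 40, seed = 7, ...) {
    key <- paste(n_subjects, seed, deparse(list(...)), collapse = "_")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_subjects = n_subjects, n_gray_unilateral = 12,
                        n_wm_targets = 6, visit_range = c(1, 3),
                        n_timepoints = 80, support_size = 4,
                        beta_scale = 0.5, seed = seed, ...)
      cache[[key]] <- simulate_cohort(cfg)
    }
    cache[[key]]
  }
})

# Independent GP oracle: direct kernel algebra on the standardized scale.
closed_form_posterior <- function(X, y, Xt, ell, sf2, sn2) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl); Xts <- scale(Xt, ctr, scl)
  k <- function(a, b) sf2 * exp(-0.5 * sum(((a - b) / ell)^2))
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) k(Xs[i, ], Xs[j, ]))) +
    diag(sn2 + 1e-8 * sf2, n)
  Ks <- outer(seq_len(nrow(Xt)), seq_len(n),
              Vectorize(function(i, j) k(Xts[i, ], Xs[j, ])))
  as.numeric(mean(y) + Ks %*% solve(K, y - mean(y)))
}

# A minimal sfc_cv-shaped object with supplied out-of-fold predictions.
fake_result <- function(pred, obs, subject, visit = NULL, target = "t") {
  if (is.null(visit)) visit <- ave(seq_along(subject), subject, FUN = seq_along)
  structure(list(rows = data.frame(subject = subject, visit = visit,
                                   fold = 1L, predicted = pred, observed = obs),
                 summary = evaluate_prediction(pred, obs),
                 target = target, model_name = "gp_ard",
                 cv = structure(list(K = 1L), class = "cv_split")),
            class = "sfc_cv")
}

toy_visits <- function(n_subjects, visits_per_subject = 2) {
  data.frame(
    subject = rep(sprintf("S%03d", seq_len(n_subjects)), each = visits_per_subject),
    visit = rep(seq_len(visits_per_subject), n_subjects)
  )
}
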