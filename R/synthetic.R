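# Synthetic longitudinal cohort generator with planted ground truth.
#
# The generator emulates the structural features the pipeline relies on:
# longitudinal visits with subject random intercepts, symmetric bounded FC
# with homotopic structure (built from a latent factor model so every FC
# matrix is a genuine correlation matrix), FA depending sparsely on a known
# set of FC features plus confound effects, and behavior linked to the
# FC-unexplained FA component through a low-rank latent trait that is
# independent of FC by construction — so the "gap carries behavior" claim is
# literally true in the simulation and CCA recovery is a valid check.

#' Simulation configuration
#'
#' @param n_subjects number of subjects.
#' @param visit_range integer (min, max) visits per subject, drawn uniformly.
#' @param n_timepoints BOLD series length per visit.
#' @param n_gray_unilateral even count of unilateral gray regions (default
#'   106, i.e. 53 bilateral pairs and 1431 FC features).
#' @param n_wm_targets number of regional FA targets (default 27; the
#'   whole-brain target is always added).
#' @param support_size truly predictive FC features per target.
#' @param beta_scale coupling effect size multiplying the unit-norm planted
#'   coefficient vectors (see [calibrate_beta_scale()]).
#' @param subject_intercept_sd,visit_noise_sd FA noise components (FA units).
#' @param confound_effects named list of fixed-effect sizes on FA:
#'   `age` (per year), `sexM`, `scanner`, `ses` (per year of education).
#' @param fc_age_effect shift of the homotopic coupling weight (logit scale)
#'   per year of age, planting a confound effect inside FC itself.
#' @param homotopic_weight baseline latent-factor weight shared by homologue
#'   pairs (homotopic correlations exceed heterotopic when > 0).
#' @param global_weight weight of the global factor shared by all regions.
#' @param fc_weight_sd between-visit variability of the coupling weights
#'   (this is what makes FC differ across visits beyond sampling noise).
#' @param latent_trait_dim rank of the gap-behavior link.
#' @param gap_loading_scale per-component scale of the latent-trait effect on
#'   FA (length `latent_trait_dim`, FA units).
#' @param behavior_dim number of behavioral measures (default 126).
#' @param behavior_support_size measures loaded per latent component.
#' @param behavior_loading_scale per-component loading scale on behavior.
#' @param behavior_noise_sd behavior residual sd.
#' @param behavior_missing_rate fraction of behavior entries set missing.
#' @param motion_mean,motion_sd mean relative displacement distribution (mm).
#' @param motion_gap_effect direct effect of motion on the raw gap (exercised
#'   by the motion-correction stage; default 0).
#' @param tract_shared_support if TRUE, targets in the same tract family
#'   share their planted support set.
#' @param seed RNG seed; identical config + seed gives identical cohorts.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200, visit_range = c(1, 6),
                       n_timepoints = 160, n_gray_unilateral = 106,
                       n_wm_targets = 27, support_size = 10, beta_scale = 1,
                       subject_intercept_sd = 0.02, visit_noise_sd = 0.02,
                       confound_effects = list(age = 0.003, sexM = 0.005,
                                               scanner = 0.004, ses = 0.0005),
                       fc_age_effect = 0.02, homotopic_weight = 0.55,
                       global_weight = 0.35, fc_weight_sd = 0.4,
                       latent_trait_dim = 2,
                       gap_loading_scale = c(0.015, 0.01),
                       behavior_dim = 126, behavior_support_size = 10,
                       behavior_loading_scale = c(1, 0.8),
                       behavior_noise_sd = 1, behavior_missing_rate = 0.05,
                       motion_mean = 0.12, motion_sd = 0.05,
                       motion_gap_effect = 0, tract_shared_support = TRUE,
                       seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_subjects >= 1, n_timepoints >= 3,
              n_gray_unilateral >= 2, n_gray_unilateral %% 2 == 0,
              n_wm_targets >= 1, support_size >= 1,
              subject_intercept_sd >= 0, visit_noise_sd >= 0,
              behavior_noise_sd >= 0, motion_sd >= 0,
              length(visit_range) == 2, visit_range[1] >= 1,
              visit_range[1] <= visit_range[2],
              latent_trait_dim >= 0)
  })
  R <- n_gray_unilateral / 2
  p <- R * (R + 1) / 2
  if (support_size > p)
    stop("support_size exceeds the number of FC features (", p, ")")
  if (length(cfg$gap_loading_scale) < cfg$latent_trait_dim)
    stop("gap_loading_scale must have latent_trait_dim entries")
  if (length(cfg$behavior_loading_scale) < cfg$latent_trait_dim)
    stop("behavior_loading_scale must have latent_trait_dim entries")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  R <- x$n_gray_unilateral / 2
  cat(sprintf(
    "Synthetic cohort config: %d subjects, %d-%d visits, %d bilateral regions (%d FC features), %d wm targets + whole brain\n  beta_scale %.3g, support %d/target, latent dim %d, seed %s\n",
    x$n_subjects, x$visit_range[1], x$visit_range[2], R, R * (R + 1) / 2,
    x$n_wm_targets, x$beta_scale, x$support_size, x$latent_trait_dim,
    format(x$seed)))
  invisible(x)
}

#' Homotopically structured BOLD time series
#'
#' Each homologue pair shares a latent factor (weight `homotopic_weight` on
#' the correlation scale via the factor loadings) and all regions share a
#' global factor, so homotopic correlations exceed heterotopic ones on
#' average while every implied correlation matrix stays valid.
#'
#' @param n_timepoints series length.
#' @param n_gray_unilateral even region count.
#' @param pairing optional pairing data.frame (columns `left`, `right`);
#'   defaults to pairing region i with region i + R.
#' @param factor_spec list with `homotopic_weight`, `global_weight` (and
#'   optionally per-pair weights `pair_weights`).
#' @param seed RNG seed.
#' @return T x n matrix of BOLD series (columns named by region).
#' @export
sample_homotopic_timeseries <- function(n_timepoints, n_gray_unilateral,
                                        pairing = NULL,
                                        factor_spec = list(homotopic_weight = 0.55,
                                                           global_weight = 0.35),
                                        seed = 1) {
  if (n_gray_unilateral %% 2 != 0 && is.null(pairing))
    stop("odd region count requires an explicit pairing")
  R <- n_gray_unilateral / 2
  rng <- local_rng(seed)
  out <- .sample_ts(n_timepoints, R,
                    pair_w = rep(factor_spec$homotopic_weight %||% 0.55, R),
                    global_w = factor_spec$global_weight %||% 0.35)
  restore_rng(rng)
  if (!is.null(pairing)) {
    colnames(out) <- c(pairing$left, pairing$right)
  } else {
    colnames(out) <- c(sprintf("G%03d_L", 1:R), sprintf("G%03d_R", 1:R))
  }
  out
}

# Factor-model draw: columns 1..R are left regions, R+1..2R right regions.
# x_region = sqrt(1-g^2) * (w * f_pair + sqrt(1-w^2) * e) + g * global
.sample_ts <- function(T_, R, pair_w, global_w) {
  g <- stats::rnorm(T_)
  f <- matrix(stats::rnorm(T_ * R), T_, R)
  eL <- matrix(stats::rnorm(T_ * R), T_, R)
  eR <- matrix(stats::rnorm(T_ * R), T_, R)
  w <- matrix(pair_w, T_, R, byrow = TRUE)
  a <- sqrt(1 - global_w^2)
  left <- a * (w * f + sqrt(1 - w^2) * eL) + global_w * g
  right <- a * (w * f + sqrt(1 - w^2) * eR) + global_w * g
  cbind(left, right)
}

#' Plant behavior on top of latent gap traits
#'
#' @param gap_latents n x d matrix of latent trait values.
#' @param loadings m x d loading matrix.
#' @param noise_sd residual sd added to every measure.
#' @param seed RNG seed.
#' @return n x m behavior matrix.
#' @export
plant_behavior <- function(gap_latents, loadings, noise_sd, seed = 1) {
  gap_latents <- as.matrix(gap_latents)
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != ncol(gap_latents))
    stop("loading columns must match the latent dimension")
  if (qr(loadings)$rank < ncol(loadings))
    warning("rank-deficient loading matrix; proceeding")
  rng <- local_rng(seed)
  B <- tcrossprod(gap_latents, loadings) +
    matrix(stats::rnorm(nrow(gap_latents) * nrow(loadings), sd = noise_sd),
           nrow(gap_latents), nrow(loadings))
  restore_rng(rng)
  colnames(B) <- rownames(loadings) %||% sprintf("B%03d", seq_len(nrow(loadings)))
  B
}

#' Generate a longitudinal synthetic cohort
#'
#' Per visit: confounds are drawn (age uniform 12-22 at baseline plus one
#' year per visit; sex, scanner, race categorical; SES in years of parental
#' education), BOLD series come from the homotopic factor model with
#' visit-varying coupling weights (age-shifted on the logit scale), FC
#' features are the vectorized bilateral correlation matrix, and FA for each
#' target is
#' `base + beta' FC[support] + confound effects + subject intercept +
#' gamma' latent + noise`.
#' Behavior loads on the same latent trait (which is independent of FC by
#' construction) plus confound effects and noise.
#'
#' @param config a [sim_config()].
#' @param keep_timeseries store the per-visit BOLD matrices (memory-heavy;
#'   default FALSE).
#' @return List of class `sim_cohort`: `visits` (subject, visit, age, sex,
#'   scanner, ses, race, motion), `features` (visits x p FC matrix),
#'   `fa` (data.frame, `whole_brain` + one column per wm region),
#'   `behavior` (visits x behavior_dim matrix with NAs),
#'   `ground_truth`, `atlas`, `config`.
#' @export
simulate_cohort <- function(config, keep_timeseries = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  R <- cfg$n_gray_unilateral / 2
  p <- R * (R + 1) / 2
  atlas <- synthetic_atlas(cfg$n_gray_unilateral, cfg$n_wm_targets,
                           seed = child_seed(cfg$seed, 1))
  pairing <- atlas_pairing(atlas)
  fidx <- fc_feature_index(pairing$name, include_diagonal = TRUE)

  rng <- local_rng(child_seed(cfg$seed, 2))
  on.exit(restore_rng(rng))

  ## ---- visit table ----
  nv <- sample(cfg$visit_range[1]:cfg$visit_range[2], cfg$n_subjects,
               replace = TRUE)
  subject <- rep(sprintf("S%04d", seq_len(cfg$n_subjects)), nv)
  visit <- unlist(lapply(nv, seq_len), use.names = FALSE)
  n_vis <- length(subject)
  age_base <- stats::runif(cfg$n_subjects, 12, 22)
  sex_s <- sample(c("F", "M"), cfg$n_subjects, replace = TRUE)
  scan_s <- sample(c("GE", "Siemens"), cfg$n_subjects, replace = TRUE)
  race_s <- sample(c("White", "Black", "Asian", "Other"), cfg$n_subjects,
                   replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.15))
  ses_s <- stats::rnorm(cfg$n_subjects, 16.8, 2.5)
  sidx <- rep(seq_len(cfg$n_subjects), nv)
  visits <- data.frame(
    subject = subject, visit = visit,
    age = age_base[sidx] + (visit - 1),
    sex = sex_s[sidx], scanner = scan_s[sidx], ses = ses_s[sidx],
    race = race_s[sidx],
    motion = abs(stats::rnorm(n_vis, cfg$motion_mean, cfg$motion_sd)),
    stringsAsFactors = FALSE)

  ## ---- FC features ----
  # per-pair trait (stable region differences) + per-visit wobble + age shift
  pair_trait <- stats::rnorm(R, 0, 0.3)
  base_logit <- stats::qlogis(min(max(cfg$homotopic_weight, 0.01), 0.99))
  features <- matrix(NA_real_, n_vis, p,
                     dimnames = list(NULL, fidx$feature))
  ts_store <- if (keep_timeseries) vector("list", n_vis) else NULL
  for (v in seq_len(n_vis)) {
    wv <- stats::plogis(base_logit + pair_trait +
                        cfg$fc_age_effect * (visits$age[v] - 17) +
                        stats::rnorm(R, 0, cfg$fc_weight_sd))
    ts <- .sample_ts(cfg$n_timepoints, R, pair_w = wv,
                     global_w = cfg$global_weight)
    colnames(ts) <- c(pairing$left, pairing$right)
    fc <- fc_from_timeseries(ts)
    bil <- bilateral_average(fc, pairing)
    features[v, ] <- vectorize_fc(bil, include_diagonal = TRUE)
    if (keep_timeseries) ts_store[[v]] <- ts
  }

  ## ---- planted FA model ----
  targets <- c("whole_brain", atlas$wm$name)
  tract_of <- c("whole_brain", atlas$wm$tract)
  n_t <- length(targets)
  support_sets <- vector("list", n_t); names(support_sets) <- targets
  betas <- vector("list", n_t); names(betas) <- targets
  draw_support <- function() sort(sample.int(p, cfg$support_size))
  draw_beta <- function() {
    b <- stats::runif(cfg$support_size, 0.5, 1.5) *
      sample(c(-1, 1), cfg$support_size, replace = TRUE)
    b / sqrt(sum(b^2))
  }
  if (cfg$tract_shared_support) {
    fam_support <- lapply(unique(tract_of), function(f) draw_support())
    names(fam_support) <- unique(tract_of)
    for (t in seq_len(n_t)) support_sets[[t]] <- fam_support[[tract_of[t]]]
  } else {
    for (t in seq_len(n_t)) support_sets[[t]] <- draw_support()
  }
  for (t in seq_len(n_t)) betas[[t]] <- draw_beta()

  d <- cfg$latent_trait_dim
  latent <- if (d > 0) matrix(stats::rnorm(n_vis * d), n_vis, d)
            else matrix(0, n_vis, 0)
  # gap-side loadings: orthonormal directions scaled per component
  gap_load <- if (d > 0) {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_t * d), n_t, d)))
    sweep(Q, 2, cfg$gap_loading_scale[seq_len(d)], "*")
  } else matrix(0, n_t, 0)
  rownames(gap_load) <- targets

  intercepts <- matrix(stats::rnorm(cfg$n_subjects * n_t,
                                    sd = cfg$subject_intercept_sd),
                       cfg$n_subjects, n_t, dimnames = list(NULL, targets))
  fa_base <- c(0.5, stats::runif(n_t - 1, 0.35, 0.6))
  ce <- cfg$confound_effects
  conf_part <- ce$age * (visits$age - 17) + ce$sexM * (visits$sex == "M") +
    ce$scanner * (visits$scanner == "Siemens") + ce$ses * (visits$ses - 16.8)

  fa <- matrix(NA_real_, n_vis, n_t, dimnames = list(NULL, targets))
  for (t in seq_len(n_t)) {
    f_sig <- cfg$beta_scale *
      as.numeric(features[, support_sets[[t]], drop = FALSE] %*% betas[[t]])
    lat <- if (d > 0) as.numeric(latent %*% gap_load[t, ]) else 0
    fa[, t] <- fa_base[t] + f_sig + conf_part + intercepts[cbind(sidx, t)] +
      lat - cfg$motion_gap_effect * visits$motion +
      stats::rnorm(n_vis, 0, cfg$visit_noise_sd)
  }

  ## ---- behavior ----
  m <- cfg$behavior_dim
  beh_load <- matrix(0, m, d,
                     dimnames = list(sprintf("B%03d", seq_len(m)), NULL))
  if (d > 0) {
    for (j in seq_len(d)) {
      rows <- ((j - 1) * cfg$behavior_support_size + 1):
        (j * cfg$behavior_support_size)
      rows <- rows[rows <= m]
      beh_load[rows, j] <- cfg$behavior_loading_scale[j] *
        sample(c(-1, 1), length(rows), replace = TRUE)
    }
  }
  behavior <- tcrossprod(latent, beh_load) +
    0.05 * matrix(conf_part, n_vis, m) +
    matrix(stats::rnorm(n_vis * m, 0, cfg$behavior_noise_sd), n_vis, m)
  colnames(behavior) <- rownames(beh_load)
  if (cfg$behavior_missing_rate > 0) {
    miss <- matrix(stats::runif(n_vis * m) < cfg$behavior_missing_rate, n_vis, m)
    behavior[miss] <- NA
  }

  noise_x <- cfg$subject_intercept_sd^2 + cfg$visit_noise_sd^2
  true_cc <- if (d > 0)
    planted_canonical_correlations(gap_load, beh_load,
                                   noise_x, cfg$behavior_noise_sd^2)
  else numeric(0)

  structure(list(
    visits = visits, features = features,
    fa = as.data.frame(fa), behavior = behavior,
    timeseries = ts_store,
    ground_truth = list(support_sets = support_sets,
                        coupling_coefficients = betas,
                        beta_scale = cfg$beta_scale,
                        gap_loadings = gap_load,
                        behavior_loadings = beh_load,
                        true_canonical_correlations = true_cc,
                        subject_intercepts = intercepts,
                        latent = latent, fa_base = fa_base),
    atlas = atlas, feature_index = fidx, config = cfg
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d visits from %d subjects; %d FC features; %d FA targets; %d behavior measures\n",
    nrow(x$visits), length(unique(x$visits$subject)), ncol(x$features),
    ncol(x$fa), ncol(x$behavior)))
  invisible(x)
}

#' Population canonical correlations of a planted factor link
#'
#' For X = Gx u + ex, Y = Gy u + ey with u ~ N(0, I) and isotropic noise,
#' computes the canonical correlations implied by the model covariance.
#'
#' @param gamma_x,gamma_y loading matrices (targets x d, measures x d).
#' @param noise_x_var,noise_y_var isotropic noise variances.
#' @return Numeric vector of population canonical correlations (length d).
#' @export
planted_canonical_correlations <- function(gamma_x, gamma_y,
                                           noise_x_var, noise_y_var) {
  gamma_x <- as.matrix(gamma_x); gamma_y <- as.matrix(gamma_y)
  d <- ncol(gamma_x)
  Sxx <- tcrossprod(gamma_x) + diag(noise_x_var, nrow(gamma_x))
  Syy <- tcrossprod(gamma_y) + diag(noise_y_var, nrow(gamma_y))
  Sxy <- tcrossprod(gamma_x, gamma_y)
  Rx <- chol(Sxx); Ry <- chol(Syy)
  M <- forwardsolve(t(Rx), Sxy)
  M <- t(forwardsolve(t(Ry), t(M)))
  sv <- svd(M)
  sv$d[seq_len(min(d, length(sv$d)))]
}

#' Oracle prediction accuracy of the planted linear model
#'
#' The accuracy of the best possible FC-based predictor: the planted linear
#' signal evaluated with the true coefficients on the realized FC features,
#' correlated with the confound-adjusted FA. Because the prediction pipeline
#' works on confound-residualized data, both the signal and its accuracy are
#' computed after projecting out the confound design (the part of the planted
#' signal that is collinear with age and the other confounds is not
#' recoverable by any confound-controlled model):
#' `r = sd(signal_resid) / sqrt(var(signal_resid) + noise)`, where the noise
#' collects the subject-intercept, latent-trait and visit-noise variances.
#'
#' @param cohort a `sim_cohort`.
#' @param target target name (default `"whole_brain"`).
#' @return List with `r` (oracle correlation), `signal_var` (residualized),
#'   `noise_var`.
#' @export
oracle_prediction_r <- function(cohort, target = "whole_brain") {
  gt <- cohort$ground_truth
  cfg <- cohort$config
  f <- cfg$beta_scale *
    as.numeric(cohort$features[, gt$support_sets[[target]], drop = FALSE] %*%
               gt$coupling_coefficients[[target]])
  fr <- stats::residuals(stats::lm(
    f ~ age + sex + scanner + ses + race, data = cohort$visits))
  lat_var <- sum(gt$gap_loadings[target, ]^2)
  noise <- cfg$subject_intercept_sd^2 + cfg$visit_noise_sd^2 + lat_var
  vs <- stats::var(fr)
  list(r = sqrt(vs / (vs + noise)), signal_var = vs, noise_var = noise)
}

#' Calibrate the coupling effect size to a target oracle accuracy
#'
#' Runs a pilot simulation at `beta_scale = 1`, measures the realized signal
#' variance for the chosen target, and solves for the `beta_scale` giving the
#' requested population oracle correlation under the configured noise.
#'
#' @param config a [sim_config()].
#' @param target_r desired oracle prediction correlation.
#' @param target target name.
#' @param pilot_subjects subjects used for the pilot (default
#'   `min(n_subjects, 150)`).
#' @return The config with `beta_scale` replaced.
#' @export
calibrate_beta_scale <- function(config, target_r, target = "whole_brain",
                                 pilot_subjects = NULL) {
  pilot <- config
  pilot$n_subjects <- pilot_subjects %||% min(config$n_subjects, 150)
  pilot$beta_scale <- 1
  coh <- simulate_cohort(pilot)
  gt <- coh$ground_truth
  f1 <- as.numeric(coh$features[, gt$support_sets[[target]], drop = FALSE] %*%
                   gt$coupling_coefficients[[target]])
  f1 <- stats::residuals(stats::lm(
    f1 ~ age + sex + scanner + ses + race, data = coh$visits))
  v1 <- stats::var(f1)
  lat_var <- sum(gt$gap_loadings[target, ]^2)
  noise <- config$subject_intercept_sd^2 + config$visit_noise_sd^2 + lat_var
  config$beta_scale <- sqrt(target_r^2 * noise / ((1 - target_r^2) * v1))
  config
}

#' Simulate a matrix pair with exact planted canonical structure
#'
#' Constructs X = U diag(s) Qx' + Ex and Y = U diag(s) Qy' + Ey with
#' orthonormal direction matrices and isotropic unit noise, where the scales
#' s_k are chosen so the population canonical correlations equal `rho`
#' exactly: s_k = sqrt(rho_k / (1 - rho_k)).
#'
#' @param n rows (visits).
#' @param rho vector of target population canonical correlations in (0, 1).
#' @param p,q column counts of X and Y.
#' @param seed RNG seed.
#' @return List `X`, `Y`, `rho` (the planted values), `latent`.
#' @export
simulate_cca_pair <- function(n, rho, p, q, seed = 1) {
  d <- length(rho)
  stopifnot(all(rho > 0 & rho < 1), p >= d, q >= d)
  s <- sqrt(rho / (1 - rho))
  rng <- local_rng(seed)
  Qx <- qr.Q(qr(matrix(stats::rnorm(p * d), p, d)))
  Qy <- qr.Q(qr(matrix(stats::rnorm(q * d), q, d)))
  U <- matrix(stats::rnorm(n * d), n, d)
  X <- tcrossprod(U %*% diag(s, d), Qx) + matrix(stats::rnorm(n * p), n, p)
  Y <- tcrossprod(U %*% diag(s, d), Qy) + matrix(stats::rnorm(n * q), n, q)
  restore_rng(rng)
  colnames(X) <- sprintf("x%02d", seq_len(p))
  colnames(Y) <- sprintf("y%02d", seq_len(q))
  list(X = X, Y = Y, rho = rho, latent = U)
}

#' Write a cohort as delimited tables plus a ground-truth JSON
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_auto(cohort$visits, file.path(dir, "visits.tsv"))
  feat <- cbind(cohort$visits[c("subject", "visit")],
                as.data.frame(cohort$features))
  write_table_auto(feat, file.path(dir, "fc_features.tsv"))
  fa <- cbind(cohort$visits[c("subject", "visit")], cohort$fa)
  write_table_auto(fa, file.path(dir, "fa.tsv"))
  beh <- cbind(cohort$visits[c("subject", "visit")],
               as.data.frame(cohort$behavior))
  write_table_auto(beh, file.path(dir, "behavior.tsv"))
  write_atlas(cohort$atlas, file.path(dir, "atlas_gray.tsv"),
              file.path(dir, "atlas_wm.tsv"))
  gt <- cohort$ground_truth
  gt$subject_intercepts <- NULL
  gt$latent <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
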