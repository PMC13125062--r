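# End-to-end orchestration: simulate (optional) -> features -> cross-validated
# prediction (whole brain + regions) -> importance / clustering -> gap -> CCA,
# with every artifact written as a delimited table plus a manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list; any entry can be overridden through
#' `...` (nested lists are merged shallowly per section). A YAML or JSON file
#' with the same structure can be passed to [run_pipeline()] directly.
#'
#' @param ... named sections overriding the defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(n_subjects = 60, n_gray_unilateral = 20,
                    n_wm_targets = 10, visit_range = c(1, 3),
                    n_timepoints = 100, beta_scale = 0.6, seed = 1),
    inputs = NULL,   # list(visits=, features=, fa=, behavior=, atlas_gray=, atlas_wm=)
    out_dir = tempfile("sfgap_run_"),
    confound_columns = c("age", "sex", "scanner", "ses", "race"),
    cv = list(K = 5, seed = 101),
    model = list(name = "gp_ard"),
    alpha = 0.05,
    embedding = list(n_neighbors = 5, min_dist = 0.1, n_epochs = 300,
                     seed = 303),
    permanova = list(n_perm = 999, seed = 404),
    cca = list(n_components = 10, n_perm = 199,
               grid = list(min = 1e-4, max = 1, count = 8),
               refit_grid = FALSE, seed = 505),
    predict_seed = 202,
    stages = list(cluster = TRUE, cca = TRUE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(over[[nm]]))) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.load_config <- function(config) {
  if (is.character(config)) {
    cfg <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                              simplifyVector = TRUE)
           else yaml::read_yaml(config)
    config <- do.call(pipeline_config, cfg)
  }
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, unclass(config))
  config
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- do.call(sim_config, cfg$simulate)
    cohort <- simulate_cohort(sim)
    list(visits = cohort$visits, features = cohort$features,
         fa = cohort$fa, behavior = cohort$behavior,
         atlas = cohort$atlas, feature_index = cohort$feature_index,
         cohort = cohort)
  } else {
    ip <- cfg$inputs
    need <- c("visits", "features", "fa", "atlas_gray", "atlas_wm")
    for (nm in need)
      if (is.null(ip[[nm]]) || !file.exists(ip[[nm]]))
        stop("configuration error: missing input file for '", nm, "'")
    visits <- read_table_auto(ip$visits)
    feat <- read_table_auto(ip$features)
    fa <- read_table_auto(ip$fa)
    key <- function(d) paste(d$subject, d$visit, sep = "\r")
    if (!identical(key(visits), key(feat)) || !identical(key(visits), key(fa)))
      stop("configuration error: visit keys differ across input tables")
    atlas <- read_atlas(ip$atlas_gray, ip$atlas_wm)
    behavior <- NULL
    if (!is.null(ip$behavior)) {
      beh <- read_table_auto(ip$behavior)
      behavior <- as.matrix(beh[setdiff(names(beh), c("subject", "visit"))])
    }
    fmat <- as.matrix(feat[setdiff(names(feat), c("subject", "visit"))])
    list(visits = visits, features = fmat,
         fa = fa[setdiff(names(fa), c("subject", "visit"))],
         behavior = behavior, atlas = atlas,
         feature_index = fc_feature_index(bilateral_names(atlas)),
         cohort = NULL)
  }
}

#' Run the full structure-function gap pipeline
#'
#' Executes: data loading or simulation, subject-level fold assignment,
#' cross-validated prediction of the whole-brain and every regional FA
#' target, reliability filtering, importance extraction, tract clustering of
#' importance maps (embedding + PERMANOVA), gap computation and correction,
#' and the gap-behavior regularized CCA with permutation inference. All
#' artifacts are written into the run directory with a manifest.
#'
#' @param config a [pipeline_config()], a plain list of overrides, or a path
#'   to a YAML/JSON file.
#' @return Invisibly, a list with the run directory and all in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  res <- withCallingHandlers(
    tryCatch({
      dat <- .load_inputs(cfg)
      if (!is.null(dat$cohort)) write_cohort(dat$cohort, file.path(cfg$out_dir, "data"))

      stage <- "predict"
      cv <- subject_kfold(dat$visits$subject, K = cfg$cv$K, seed = cfg$cv$seed)
      conf_cols <- intersect(cfg$confound_columns, names(dat$visits))
      confounds <- dat$visits[conf_cols]
      spec <- do.call(model_spec, c(list(name = cfg$model$name),
                                    cfg$model[setdiff(names(cfg$model), "name")]))
      reg <- predict_all_regions(dat$features, dat$fa, dat$visits, cv,
                                 model = spec, confounds = confounds,
                                 atlas = dat$atlas, alpha = cfg$alpha,
                                 seed = cfg$predict_seed)
      write_table_auto(reg$accuracy, file.path(cfg$out_dir, "accuracy.tsv"))

      stage <- "importance"
      imp_tab <- NULL; clust <- NULL
      if (length(reg$importance)) {
        imp_mat <- do.call(rbind, lapply(reg$importance,
                                         function(iv) iv$table$importance))
        colnames(imp_mat) <- reg$importance[[1]]$table$feature
        imp_tab <- data.frame(target = rownames(imp_mat), imp_mat,
                              check.names = FALSE)
        write_table_auto(imp_tab, file.path(cfg$out_dir, "importance.tsv"))
        if (isTRUE(cfg$stages$cluster)) {
          stage <- "cluster"
          retained_wm <- setdiff(reg$retained, "whole_brain")
          tr_lab <- dat$atlas$wm$tract[match(retained_wm, dat$atlas$wm$name)]
          if (length(retained_wm) >= 4 &&
              length(unique(tr_lab)) >= 2 &&
              length(unique(tr_lab)) < length(retained_wm)) {
            emb <- embed_importance(imp_mat[retained_wm, , drop = FALSE],
                                    n_neighbors = cfg$embedding$n_neighbors,
                                    min_dist = cfg$embedding$min_dist,
                                    n_epochs = cfg$embedding$n_epochs,
                                    seed = cfg$embedding$seed)
            tracts <- dat$atlas$wm$tract[match(retained_wm, dat$atlas$wm$name)]
            pt <- permanova_test(emb$coords, tracts,
                                 n_perm = cfg$permanova$n_perm,
                                 seed = cfg$permanova$seed)
            pt_raw <- permanova_test(
              imp_mat[retained_wm, , drop = FALSE] /
                sqrt(rowSums(imp_mat[retained_wm, , drop = FALSE]^2)),
              tracts, n_perm = cfg$permanova$n_perm,
              seed = cfg$permanova$seed)
            clust <- list(embedding = emb, tracts = tracts,
                          permanova_embedded = pt, permanova_raw = pt_raw)
            write_table_auto(
              data.frame(target = retained_wm, tract = tracts, emb$coords),
              file.path(cfg$out_dir, "embedding.tsv"))
            write_table_auto(
              data.frame(space = c("embedded", "raw_importance"),
                         F = c(pt$F, pt_raw$F), p = c(pt$p, pt_raw$p)),
              file.path(cfg$out_dir, "permanova.tsv"))
          }
        }
      }

      stage <- "gap"
      keep <- union("whole_brain", reg$retained)
      gaps <- compute_gap(reg$results[keep])
      obs <- as.data.frame(lapply(reg$results[keep], function(r) r$rows$observed))
      names(obs) <- keep
      corrected <- correct_gap(gaps, dat$visits$motion[
        match(paste(gaps$subject, gaps$visit),
              paste(dat$visits$subject, dat$visits$visit))], obs)
      write_table_auto(corrected, file.path(cfg$out_dir, "gaps_corrected.tsv"))

      stage <- "cca"
      cca <- NULL
      if (isTRUE(cfg$stages$cca) && !is.null(dat$behavior)) {
        ord <- match(paste(corrected$subject, corrected$visit),
                     paste(dat$visits$subject, dat$visits$visit))
        B <- prepare_behavior(dat$behavior[ord, , drop = FALSE],
                              corrected$subject)
        Xg <- as.matrix(corrected[setdiff(names(corrected),
                                          c("subject", "visit"))])
        grid <- do.call(reg_grid, cfg$cca$grid)
        fit <- fit_rcca(Xg, B, corrected[c("subject", "visit")], cv,
                        grid = grid, n_components = cfg$cca$n_components,
                        confounds_y = dat$visits[ord, intersect(
                          c("age", "sex", "race", "ses"), conf_cols)],
                        seed = cfg$cca$seed)
        perm <- permutation_test_cca(Xg, B, corrected[c("subject", "visit")],
                                     cv, grid = grid,
                                     n_components = cfg$cca$n_components,
                                     result = fit, n_perm = cfg$cca$n_perm,
                                     refit_grid = isTRUE(cfg$cca$refit_grid),
                                     seed = cfg$cca$seed)
        loads <- canonical_loadings(fit, Xg, B,
                                    corrected[c("subject", "visit")])
        cca <- list(fit = fit, perm = perm, loadings = loads)
        write_table_auto(
          data.frame(component = seq_along(fit$test_cor),
                     test_cor = fit$test_cor, p = perm$p),
          file.path(cfg$out_dir, "cca_components.tsv"))
        write_table_auto(loads$x, file.path(cfg$out_dir, "cca_loadings_gap.tsv"))
        write_table_auto(loads$y, file.path(cfg$out_dir, "cca_loadings_behavior.tsv"))
      }

      stage <- "manifest"
      cfg_file <- file.path(cfg$out_dir, "config.yaml")
      yaml::write_yaml(unclass(cfg), cfg_file)
      arts <- setdiff(list.files(cfg$out_dir, recursive = TRUE),
                      "manifest.json")
      manifest <- list(
        package_version = as.character(utils::packageVersion("sfgap")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seeds = list(cv = cfg$cv$seed, predict = cfg$predict_seed,
                     embed = cfg$embedding$seed,
                     permanova = cfg$permanova$seed, cca = cfg$cca$seed,
                     sim = cfg$simulate$seed),
        artifacts = as.list(tools::md5sum(file.path(cfg$out_dir, arts))))
      names(manifest$artifacts) <- arts
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)

      list(dir = cfg$out_dir, config = cfg, cv = cv, regional = reg,
           clustering = clust, gaps = corrected, cca = cca)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", cfg$out_dir, ")", call. = FALSE)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
  invisible(res)
}

#' Write a human-readable run report
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param file output path (default `report.txt` inside the run directory).
#' @return Invisibly, the report lines.
#' @export
write_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  lines <- c("Structure-function gap pipeline report",
             paste("Run directory:", run_dir), "")
  partial <- FALSE
  acc_f <- file.path(run_dir, "accuracy.tsv")
  if (file.exists(acc_f)) {
    acc <- read_table_auto(acc_f)
    lines <- c(lines, sprintf("Prediction targets: %d (retained: %d)",
                              nrow(acc), sum(acc$retained_flag)), "")
    lines <- c(lines, "Per-target accuracy (r / MSE / retained):")
    lines <- c(lines, sprintf("  %-40s r = %6.3f  MSE = %.3g  %s",
                              acc$target, acc$r, acc$mse,
                              ifelse(acc$retained_flag, "retained", "filtered")))
  } else partial <- TRUE
  pm_f <- file.path(run_dir, "permanova.tsv")
  if (file.exists(pm_f)) {
    pm <- read_table_auto(pm_f)
    lines <- c(lines, "", sprintf(
      "Tract clustering PERMANOVA (%s space): F = %.3f, p = %.4f",
      pm$space, pm$F, pm$p))
  }
  cca_f <- file.path(run_dir, "cca_components.tsv")
  if (file.exists(cca_f)) {
    cc <- read_table_auto(cca_f)
    sig <- cc$component[cc$p < 0.05]
    lines <- c(lines, "", "Gap-behavior CCA components (test r / permutation p):",
               sprintf("  component %d: r = %6.3f, p = %.4f",
                       cc$component, cc$test_cor, cc$p),
               if (length(sig)) paste("Significant components at alpha = 0.05:",
                                      paste(sig, collapse = ", "))
               else "No significant component at alpha = 0.05.")
    ld_f <- file.path(run_dir, "cca_loadings_behavior.tsv")
    if (file.exists(ld_f)) {
      ld <- read_table_auto(ld_f)
      top <- ld[order(-abs(ld$loading)), ][1:min(5, nrow(ld)), ]
      lines <- c(lines, "Top behavior loadings (component 1):",
                 sprintf("  %-12s %6.3f", top$variable, top$loading))
    }
  }
  if (partial) lines <- c(lines, "", "WARNING: incomplete run; partial report.")
  writeLines(lines, file)
  invisible(lines)
}
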