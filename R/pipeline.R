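#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis: the cohort
#' generator settings, movement rules, clustering options (basis size, K
#' range, stability repeats), the segment-cost cutoff, and the regression
#' settings (basis size 10, lambda 0.1 and bootstrap replicates). Defaults
#' follow the method's standard calibration: cutoff 70, ten regression basis
#' functions, lambda = 0.1.
#'
#' @param cohort A [cohort_config()].
#' @param rules A [movement_rules()].
#' @param cluster_n_basis B-spline basis size for curve clustering.
#' @param k_range Candidate cluster counts for silhouette selection.
#' @param stability_repeats Reseeding repeats for the ARI stability check.
#' @param regression_n_basis Basis size of the functional coefficient.
#' @param lambda Curvature-penalty smoothing parameter.
#' @param n_boot Bootstrap replicates for the beta(t) bands.
#' @param seed Master seed (also seeds the cohort unless it sets its own).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(seed = seed),
                            rules = movement_rules(),
                            cluster_n_basis = 12L, k_range = 2:6,
                            stability_repeats = 50L,
                            regression_n_basis = 10L, lambda = 0.1,
                            n_boot = 200L, seed = 1L) {
  structure(list(cohort = cohort, rules = rules,
                 cluster_n_basis = as.integer(cluster_n_basis),
                 k_range = as.integer(k_range),
                 stability_repeats = as.integer(stability_repeats),
                 regression_n_basis = as.integer(regression_n_basis),
                 lambda = lambda, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain top-level keys matching the arguments of
#' [pipeline_config()], a `cohort` mapping with [cohort_config()] arguments,
#' and a `rules` mapping with [movement_rules()] arguments; anything omitted
#' keeps its default.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cohort", "rules"))]
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$rules)) args$rules <- do.call(movement_rules, y$rules)
  do.call(pipeline_config, args)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate -> curves -> cluster -> features -> regress,
#' writing every intermediate artifact as plain CSV/JSON under `out_dir` and
#' returning a run report. All randomness descends from the config seed, so
#' rerunning the same configuration reproduces every output byte for byte.
#'
#' Artifacts: `terrain_<e>.json`, `paths.csv`, `events.csv`,
#' `covariates.csv`, `curves.csv` (long format), `segments.json`,
#' `assignments.csv`, `centroids.csv`, `silhouette.csv`,
#' `composition_*.csv`, `features.csv`, `coefficients_<yk>.csv`,
#' `beta_bands_<yk>.csv`, `report.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run report, invisibly (also saved as `report.json`):
#'   segment/curve counts, exclusions, cluster sizes and shares, silhouette
#'   table, stability ARI, and per-outcome regression summaries.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config

  # -- simulate ------------------------------------------------------------
  cohort <- generate_cohort(cfg$cohort, cfg$rules)
  for (e in seq_along(cohort$terrains))
    write_terrain(cohort$terrains[[e]]$map,
                  file.path(out_dir, sprintf("terrain_%d.json", e)))
  paths <- do.call(rbind, lapply(cohort$sessions, function(s)
    cbind(participant_id = s$path$participant_id,
          session_id = s$path$session_id, s$path$samples)))
  events <- do.call(rbind, lapply(cohort$sessions, function(s)
    cbind(participant_id = s$events$participant_id,
          session_id = s$events$session_id, s$events$events)))
  utils::write.csv(paths, file.path(out_dir, "paths.csv"), row.names = FALSE)
  utils::write.csv(events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)

  # -- curves --------------------------------------------------------------
  cm <- cohort$curve_matrix
  long <- data.frame(
    curve = rep(seq_len(nrow(cm$values)), each = length(cm$grid)),
    participant_id = rep(cm$meta$participant_id, each = length(cm$grid)),
    session_id = rep(cm$meta$session_id, each = length(cm$grid)),
    grid = rep(cm$grid, nrow(cm$values)),
    value = as.vector(t(cm$values)))
  utils::write.csv(long, file.path(out_dir, "curves.csv"), row.names = FALSE)
  write_json_stable(cm$meta, file.path(out_dir, "segments.json"))

  # -- cluster -------------------------------------------------------------
  basis <- bspline_basis(cfg$cluster_n_basis, range = range(cm$grid))
  coefs <- spline_coefficients(cm$values, cm$grid, basis)
  ksel <- select_k_silhouette(coefs, cfg$k_range, seed = cfg$seed)
  clusters <- cluster_curves(coefs, ksel$best_k, seed = cfg$seed)
  stability <- clustering_stability(coefs, ksel$best_k,
                                    n_repeats = cfg$stability_repeats,
                                    base_seed = cfg$seed)
  comp <- composition_tables(clusters, cm$meta)
  utils::write.csv(data.frame(curve = seq_along(clusters$assignments),
                              cluster = clusters$assignments),
                   file.path(out_dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(centroid_curves(clusters, basis, cm$grid)),
                   file.path(out_dir, "centroids.csv"), row.names = FALSE)
  utils::write.csv(ksel$scores, file.path(out_dir, "silhouette.csv"),
                   row.names = FALSE)
  utils::write.csv(comp$by_session,
                   file.path(out_dir, "composition_session.csv"),
                   row.names = FALSE)
  utils::write.csv(comp$by_environment,
                   file.path(out_dir, "composition_environment.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(position = rownames(comp$by_position),
                         as.data.frame(comp$by_position)),
                   file.path(out_dir, "composition_position.csv"),
                   row.names = FALSE)

  # -- features ------------------------------------------------------------
  pf <- participant_features(cm, clusters$assignments,
                             covariates = cohort$participants,
                             cutoff = cfg$cohort$cutoff, k = clusters$k)
  utils::write.csv(pf$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  # -- regress -------------------------------------------------------------
  keep <- pf$features$has_mean_curve
  reg_data <- merge(pf$features[keep, ], cohort$outcomes,
                    by = "participant_id", sort = FALSE)
  reg_data <- droplevels(reg_data)
  # scalar covariates in priority order; the tail is dropped on small
  # cohorts so the unpenalised part of the design stays estimable
  prop_terms <- paste0("cluster_prop_", 2:clusters$k)
  terms_all <- c("removed_curve_count", prop_terms, "average_segment_time",
                 "skill", "age", "sex", "game_experience", "weekly_hours")
  terms_all <- Filter(function(tm) {
    v <- reg_data[[tm]]
    !is.null(v) && (!is.factor(v) || nlevels(v) >= 2) &&
      length(unique(v)) >= 2
  }, terms_all)
  n_cols <- function(tms) ncol(stats::model.matrix(
    stats::as.formula(paste("~", paste(tms, collapse = " + "))), reg_data))
  while (length(terms_all) > 1 &&
         n_cols(terms_all) + 4 > nrow(reg_data))
    terms_all <- terms_all[-length(terms_all)]
  rhs <- paste(terms_all, collapse = " + ")
  Xcurves <- pf$mean_curves[match(reg_data$participant_id,
                                  rownames(pf$mean_curves)), , drop = FALSE]
  fits <- list()
  ridge_used <- c(y1 = 0, y2 = 0, y3 = 0)
  for (yk in c("y1", "y2", "y3")) {
    f <- stats::as.formula(paste(yk, "~", rhs))
    fit <- tryCatch(
      sofr(f, reg_data, Xcurves, pf$grid,
           n_basis = cfg$regression_n_basis, lambda = cfg$lambda),
      error = function(e) NULL)
    if (is.null(fit)) {           # degenerate curve design: stabilise
      ridge_used[yk] <- 1e-6
      fit <- sofr(f, reg_data, Xcurves, pf$grid,
                  n_basis = cfg$regression_n_basis, lambda = cfg$lambda,
                  ridge = 1e-6)
    }
    fit <- sofr_bootstrap(fit, n_boot = cfg$n_boot, seed = cfg$seed)
    fits[[yk]] <- fit
    utils::write.csv(fit$gamma,
                     file.path(out_dir, sprintf("coefficients_%s.csv", yk)),
                     row.names = FALSE)
    utils::write.csv(data.frame(grid = fit$grid, beta = fit$beta,
                                lower = fit$bootstrap$beta_lower,
                                upper = fit$bootstrap$beta_upper),
                     file.path(out_dir, sprintf("beta_bands_%s.csv", yk)),
                     row.names = FALSE)
  }

  report <- list(
    seed = cfg$seed,
    n_participants = cfg$cohort$n_participants,
    n_segments = nrow(cm$meta),
    n_excluded_segments = nrow(cohort$excluded_segments),
    n_low_cost = sum(classify_segment(cm$meta$optimal_start_cost,
                                      cfg$cohort$cutoff) == "low"),
    best_k = ksel$best_k,
    silhouette = ksel$scores,
    cluster_sizes = as.integer(clusters$sizes),
    cluster_shares = round(clusters$sizes / sum(clusters$sizes), 6),
    stability_mean_ari = stability$mean_ari,
    stability_sd_ari = stability$sd_ari,
    participants_excluded_from_regression =
      as.character(pf$excluded),
    regression_formula = rhs,
    regression_ridge = as.list(ridge_used),
    regressions = lapply(fits, function(f)
      list(n = f$n, r_squared = f$r_squared, edf = f$edf,
           gamma = f$gamma)))
  write_json_stable(report, file.path(out_dir, "report.json"))
  invisible(list(report = report, cohort = cohort, clusters = clusters,
                 features = pf, fits = fits))
}
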