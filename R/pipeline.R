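#' Configuration for a full pipeline run
#'
#' @param seed global seed.
#' @param shape_pca_mode PCA matrix for Procrustes coordinates
#'   ("covariance", the default, or "correlation").
#' @param nutrition_pca_mode PCA matrix for nutrient intakes
#'   ("correlation", the default, since nutrient units are heterogeneous).
#' @param retention cumulative-variance cutoff for component retention
#'   (default 0.9).
#' @param alpha_in stepwise entry threshold (default 0.05).
#' @param k_candidates candidate cluster counts (default 2:6).
#' @param accent_weight accentuation weight for per-code mean faces
#'   (default 5).
#' @return a named list of settings.
#' @export
run_config <- function(seed = 1,
                       shape_pca_mode = "covariance",
                       nutrition_pca_mode = "correlation",
                       retention = 0.9,
                       alpha_in = 0.05,
                       k_candidates = 2:6,
                       accent_weight = 5) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (accent_weight < 0) stop("accent_weight must be >= 0")
  list(seed = as.integer(seed), shape_pca_mode = shape_pca_mode,
       nutrition_pca_mode = nutrition_pca_mode, retention = retention,
       alpha_in = alpha_in, k_candidates = k_candidates,
       accent_weight = accent_weight)
}

#' Run the full nutrition-to-face analysis
#'
#' Orchestrates the chain: nutrient estimation and behavior/body scoring;
#' Procrustes alignment, centroid size, shape PCA (sPCs) and nutrition
#' PCA (nPCs) with the Kaiser/90% retention rule; stepwise selection of
#' sPCs for each dietary/body variable; MANCOVA of the selected variables
#' on the selected sPCs; canonical correlation of nPCs vs sPCs with the
#' reconstructed face axis; k-means dietary-pattern clustering (nPC
#' scores + behavior scale sums) with elbow selection; SShD decomposition
#' against the male/female reference, with a per-code ANOVA of
#' non-allometric SShD; the inter-landmark distance panel with per-code
#' ANOVA/Tukey and Benjamini-Hochberg adjustment; and accentuated
#' per-code mean faces.
#'
#' @param cohort a `synthetic_cohort` (or equivalent list of streams read
#'   with [read_cohort()]) carrying configurations, ffq, behavior, body.
#' @param reference male/female reference from
#'   [generate_dimorphism_reference()] (or same-schema user data).
#' @param config settings from [run_config()].
#' @param table food composition table.
#' @return object of class `nutrimorph_report`: a structured list of
#'   stage outputs plus a `manifest` of every setting.
#' @export
run_full_analysis <- function(cohort, reference,
                              config = run_config(),
                              table = synthetic_food_composition()) {
  stopifnot(!is.null(cohort$configurations), !is.null(cohort$ffq),
            !is.null(cohort$behavior), !is.null(cohort$body))
  n <- length(cohort$configurations)
  message("nutrition: ", nrow(cohort$ffq), " FFQ records")
  profiles <- estimate_nutrient_profiles(cohort$ffq, table)
  nut <- as.matrix(profiles[, nutrient_names()])
  rownames(nut) <- profiles$subject_id

  beh_items <- as.matrix(cohort$behavior[, names(behavior_scale_map())])
  beh_scores <- t(apply(beh_items, 1, score_eating_behavior))
  beh_sums <- beh_scores[, levels(behavior_scale_map()), drop = FALSE]
  rownames(beh_sums) <- cohort$behavior$subject_id

  body <- compute_body_indices(cohort$body)
  body_df <- data.frame(subject_id = cohort$body$subject_id,
                        weight = body$weight, muscle_mass = body$muscle_mass,
                        fat_mass = body$fat_mass, bmi = body$bmi,
                        fat_pct = body$fat_pct, ffmi = body$ffmi,
                        fmi = body$fmi)

  message("morpho: aligning ", n, " configurations")
  fit <- gpa(cohort$configurations)
  spc_space <- fit_shape_space(fit$shapes, mode = config$shape_pca_mode,
                               cum_cutoff = config$retention)
  spc <- shape_scores(spc_space, fit$shapes)
  colnames(spc) <- paste0("sPC", seq_len(ncol(spc)))

  # nutrition PCA on intakes with non-degenerate variation
  keep <- apply(nut, 2, stats::sd) > 1e-10
  npc_space <- fit_shape_space(nut[, keep, drop = FALSE],
                               mode = config$nutrition_pca_mode,
                               cum_cutoff = config$retention)
  npc <- shape_scores(npc_space, nut[, keep, drop = FALSE])
  colnames(npc) <- paste0("nPC", seq_len(ncol(npc)))

  message("stats: stepwise selection over ", ncol(spc), " sPCs")
  dependents <- cbind(npc, beh_sums,
                      weight = body_df$weight,
                      muscle_mass = body_df$muscle_mass,
                      fat_mass = body_df$fat_mass, bmi = body_df$bmi)
  steps <- lapply(colnames(dependents), function(v)
    stepwise_select(dependents[, v], spc, alpha_in = config$alpha_in))
  names(steps) <- colnames(dependents)
  selected_vars <- names(steps)[vapply(steps, function(s)
    length(s$selected) > 0, logical(1))]
  selected_spcs <- sort(unique(unlist(lapply(steps, `[[`, "selected"))))

  mancova_res <- NULL
  if (length(selected_vars) >= 2 && length(selected_spcs) >= 1)
    mancova_res <- mancova(dependents[, selected_vars, drop = FALSE],
                           spc[, selected_spcs, drop = FALSE])

  cca <- canonical_analysis(npc, spc)
  v1_shape <- shape_reconstruct(spc_space,
                                as.numeric(cca$right_coef[, 1]))

  message("stats: clustering")
  clus <- kmeans_elbow(cbind(npc, beh_sums),
                       k_candidates = config$k_candidates,
                       seed = config$seed)
  codes <- clus$codes

  message("dimorphism: SShD decomposition")
  male_al <- align_to_mean(reference$male_config, fit$mean_shape)
  female_al <- align_to_mean(reference$female_config, fit$mean_shape)
  axis <- dimorphism_axis(male_al, female_al)
  sshd <- decompose_sshd(fit$shapes, fit$centroid_sizes, axis)
  sshd_anova <- anova_tukey(sshd$sshd_nonallometric, codes)

  message("morpho: inter-landmark panel")
  panel <- t(vapply(cohort$configurations,
                    function(cfg) interlandmark_panel(pose_normalize(cfg)),
                    numeric(16)))
  panel_tests <- lapply(colnames(panel), function(v)
    anova_tukey(panel[, v], codes))
  names(panel_tests) <- colnames(panel)
  panel_table <- data.frame(
    variable = colnames(panel),
    f_stat = vapply(panel_tests, `[[`, numeric(1), "f_stat"),
    p_value = vapply(panel_tests, `[[`, numeric(1), "p_value"),
    eta_sq = vapply(panel_tests, `[[`, numeric(1), "eta_sq"),
    row.names = NULL)
  panel_table$p_adj <- bh_adjust(panel_table$p_value)

  grand <- colMeans(fit$shapes)
  accent <- lapply(sort(unique(codes)), function(cd)
    accentuate_mean(colMeans(fit$shapes[codes == cd, , drop = FALSE]),
                    grand, config$accent_weight))
  names(accent) <- paste0("code", sort(unique(codes)))

  truth <- NULL
  if (!is.null(cohort$true_cluster))
    truth <- list(ari = adjusted_rand_index(codes, cohort$true_cluster))

  manifest <- c(config,
                list(n_subjects = n,
                     n_landmarks = nrow(cohort$configurations[[1]]),
                     spc_retained = spc_space$k, npc_retained = npc_space$k,
                     k_chosen = clus$k,
                     gpa_iterations = fit$iterations,
                     package_version =
                       as.character(utils::packageVersion("nutrimorph"))))

  structure(list(
    profiles = profiles, behavior_scores = beh_sums, body = body_df,
    gpa = fit, spc_space = spc_space, spc_scores = spc,
    npc_space = npc_space, npc_scores = npc,
    stepwise = steps, selected_vars = selected_vars,
    selected_spcs = selected_spcs, mancova = mancova_res,
    cca = cca, cv1_face_axis = v1_shape,
    clusters = clus, codes = codes,
    axis = axis, sshd = sshd, sshd_anova = sshd_anova,
    panel = panel, panel_table = panel_table,
    accentuated = accent, truth = truth,
    manifest = manifest), class = "nutrimorph_report")
}

#' Write a pipeline report as delimited tables plus a manifest
#'
#' Refuses to overwrite a directory containing a completed manifest.
#'
#' @param report a `nutrimorph_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "nutrimorph_report"))
  if (file.exists(file.path(dir, "manifest.json")))
    stop("completed run already present in ", dir,
         "; refusing to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(report$profiles, "nutrient_profiles.csv")
  wcsv(data.frame(subject_id = rownames(report$spc_scores),
                  report$spc_scores, code = report$codes,
                  check.names = FALSE), "spc_scores.csv")
  wcsv(data.frame(subject_id = rownames(report$spc_scores),
                  report$npc_scores, check.names = FALSE), "npc_scores.csv")
  wcsv(report$sshd, "sshd.csv")
  wcsv(report$panel_table, "panel_anova.csv")
  if (!is.null(report$mancova)) {
    wcsv(report$mancova$terms, "mancova_terms.csv")
    cf <- report$mancova$coefficients
    wcsv(data.frame(term = rownames(cf), cf, check.names = FALSE),
         "mancova_coefficients.csv")
  }
  wcsv(report$cca$wilks, "canonical_tests.csv")
  stepsum <- do.call(rbind, lapply(names(report$stepwise), function(v) {
    s <- report$stepwise[[v]]
    data.frame(variable = v,
               selected = paste(s$selected, collapse = "+"),
               r_squared = s$r_squared)
  }))
  wcsv(stepsum, "stepwise_summary.csv")
  accent <- do.call(rbind, lapply(names(report$accentuated), function(cd)
    data.frame(code = cd,
               coord = seq_along(report$accentuated[[cd]]),
               value = report$accentuated[[cd]])))
  wcsv(accent, "accentuated_faces.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
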