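#!/usr/bin/env Rscript
# Stage 4: direct comparisons and dietary-pattern clustering.
#
# Nutrition PCA (correlation matrix, Kaiser/90% retention), forward
# stepwise selection of shape PCs for every dietary / behavior / body
# variable, MANCOVA (Wilks' lambda) of the selected variables on the
# selected shape PCs, canonical correlation of nutrition vs face, and
# k-means clustering of nPC scores + behavior scale sums with elbow
# selection of k.

suppressMessages(library(nutrimorph))

seed <- 20130514
profiles <- read.csv("results/nutrition/nutrient_profiles.csv",
                     check.names = FALSE)
beh <- read.csv("results/nutrition/behavior_scores.csv")
body <- read.csv("results/nutrition/body_indices.csv")
spc_tab <- read.csv("results/morpho/spc_scores.csv")
spc <- as.matrix(spc_tab[, grep("^sPC", names(spc_tab))])
dir.create("results/inference", showWarnings = FALSE, recursive = TRUE)

nut <- as.matrix(profiles[, nutrient_names()])
keep <- apply(nut, 2, sd) > 1e-10
npc_space <- fit_shape_space(nut[, keep], mode = "correlation")
npc <- shape_scores(npc_space, nut[, keep])
colnames(npc) <- paste0("nPC", seq_len(ncol(npc)))
write.csv(data.frame(subject_id = profiles$subject_id, npc),
          "results/inference/npc_scores.csv", row.names = FALSE)
cat("retained", npc_space$k, "nutrition PCs\n")

beh_sums <- as.matrix(beh[, levels(behavior_scale_map())])
dependents <- cbind(npc, beh_sums, weight = body$weight,
                    muscle_mass = body$muscle_mass,
                    fat_mass = body$fat_mass, bmi = body$bmi)
steps <- lapply(colnames(dependents), function(v)
  stepwise_select(dependents[, v], spc))
names(steps) <- colnames(dependents)
sel_vars <- names(steps)[vapply(steps, function(s) length(s$selected) > 0,
                                logical(1))]
sel_spcs <- sort(unique(unlist(lapply(steps, `[[`, "selected"))))
write.csv(data.frame(
  variable = names(steps),
  selected = vapply(steps, function(s) paste(s$selected, collapse = "+"),
                    character(1)),
  r_squared = vapply(steps, `[[`, numeric(1), "r_squared")),
  "results/inference/stepwise.csv", row.names = FALSE)
cat("stepwise: ", length(sel_vars), "variables related to",
    length(sel_spcs), "shape PCs (", paste(sel_spcs, collapse = ", "), ")\n")

if (length(sel_vars) >= 2 && length(sel_spcs) >= 1) {
  mv <- mancova(dependents[, sel_vars], spc[, sel_spcs, drop = FALSE])
  cat(sprintf(
    "MANCOVA: Wilks lambda = %.3f, F(%d, %.1f) = %.2f, p = %.4f, partial eta^2 = %.3f\n",
    mv$wilks_lambda, mv$df1, mv$df2, mv$f_stat, mv$p_value,
    mv$partial_eta_sq))
  write.csv(mv$terms, "results/inference/mancova_terms.csv",
            row.names = FALSE)
  cf <- mv$coefficients
  write.csv(data.frame(term = rownames(cf), cf, check.names = FALSE),
            "results/inference/mancova_coefficients.csv", row.names = FALSE)
}

cca <- canonical_analysis(npc, spc)
cat(sprintf("CV1: r = %.2f, Wilks lambda = %.2f, F(%d, %.1f) = %.2f, p = %.3f\n",
            cca$correlations[1], cca$wilks$wilks_lambda[1],
            cca$wilks$df1[1], cca$wilks$df2[1], cca$wilks$f_stat[1],
            cca$wilks$p_value[1]))
write.csv(cca$wilks, "results/inference/canonical_tests.csv",
          row.names = FALSE)

cl <- kmeans_elbow(cbind(npc, beh_sums), seed = seed)
cat("elbow chose k =", cl$k, "; code sizes:", table(cl$codes), "\n")
write.csv(data.frame(subject_id = profiles$subject_id, code = cl$codes),
          "results/inference/codes.csv", row.names = FALSE)
write.csv(data.frame(k = as.integer(names(cl$wss)), wss = cl$wss),
          "results/inference/wss_curve.csv", row.names = FALSE)

truth <- read.csv("results/cohort/truth.csv")
cat("adjusted Rand index vs planted patterns:",
    round(adjusted_rand_index(cl$codes, truth$true_cluster), 3), "\n")
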