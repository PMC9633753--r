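#!/usr/bin/env Rscript
# Stage 2: dietary condition of each subject.
#
# Estimates the 53 daily nutrient intakes and 7 oil/fatty-acid ratios
# from the FFQ via portion x amount-category x weekly-frequency/7 x
# per-gram density (with the household salt-taste multiplier), scores
# the 55-item eating-behavior questionnaire into its 7 scales, and
# fills the body-composition indices (BMI, fat %, FFMI, FMI).

suppressMessages(library(nutrimorph))

cohort <- read_cohort("results/cohort")
dir.create("results/nutrition", showWarnings = FALSE, recursive = TRUE)

profiles <- estimate_nutrient_profiles(cohort$ffq)
write.csv(profiles, "results/nutrition/nutrient_profiles.csv",
          row.names = FALSE)

beh <- t(apply(as.matrix(cohort$behavior[, -1]), 1, score_eating_behavior))
beh <- data.frame(subject_id = cohort$behavior$subject_id, beh)
write.csv(beh, "results/nutrition/behavior_scores.csv", row.names = FALSE)

body <- compute_body_indices(cohort$body)
body_df <- data.frame(subject_id = cohort$body$subject_id,
                      weight = body$weight, height = body$height,
                      fat_mass = body$fat_mass,
                      fat_free_mass = body$fat_free_mass,
                      muscle_mass = body$muscle_mass, bmi = body$bmi,
                      fat_pct = body$fat_pct, ffmi = body$ffmi,
                      fmi = body$fmi)
write.csv(body_df, "results/nutrition/body_indices.csv", row.names = FALSE)

cat("mean daily energy:", round(mean(profiles$energy_kcal)), "kcal;",
    "mean BMI:", round(mean(body_df$bmi), 1), "kg/m^2\n")
cat("FFMI + FMI - BMI, max abs:",
    max(abs(body_df$ffmi + body_df$fmi - body_df$bmi)), "\n")
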