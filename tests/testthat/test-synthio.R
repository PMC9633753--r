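test_that("identical spec and seed reproduce the cohort bit for bit", {
  spec <- cohort_spec(n_subjects = 25, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$configurations, b$configurations)
  expect_identical(a$ffq, b$ffq)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$body, b$body)
  expect_identical(a$true_cluster, b$true_cluster)
  expect_identical(a$true_sshd, b$true_sshd)

  # sub-streams are independent: generating fewer streams leaves the
  # shared ones untouched
  shapes_only <- generate_cohort(spec, streams = "shape")
  expect_identical(shapes_only$configurations, a$configurations)
})

test_that("zeroed noise and effects reproduce the template exactly", {
  spec <- cohort_spec(n_subjects = 5, seed = 2, shape_noise_sd = 0,
                      individual_sd = 0, cs_sd = 0,
                      dimorphism_effect = c(0, 0, 0),
                      allometric_slope = 0)
  coh <- generate_cohort(spec, streams = "shape")
  tmpl <- face_template(spec$n_landmarks)
  for (cfg in coh$configurations)
    expect_equal(cfg, tmpl, tolerance = 1e-9)
  expect_equal(coh$true_sshd, rep(0, 5))
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(n_subjects = 0), "positive")
  expect_error(cohort_spec(cluster_proportions = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(cohort_spec(shape_noise_sd = -1), ">= 0")
  expect_error(cohort_spec(n_landmarks = 10), "positive")
})

test_that("per-cluster sample nutrient means recover the planted means", {
  spec <- cohort_spec(n_subjects = 300, seed = 61)
  coh <- generate_cohort(spec, streams = "ffq")
  prof <- estimate_nutrient_profiles(coh$ffq)
  direct <- nutrimorph:::direct_nutrient_names()
  planted <- spec$cluster_nutrient_means
  n_checked <- 0; n_ok <- 0
  for (g in 1:3) {
    sel <- coh$true_cluster == g
    for (nm in direct) {
      x <- prof[sel, nm]
      se <- sd(x) / sqrt(sum(sel))
      if (se < 1e-12) next  # nutrient with no sampling variation
      n_checked <- n_checked + 1
      if (abs(mean(x) - planted[g, nm]) <= 3 * se) n_ok <- n_ok + 1
    }
  }
  # with ~129 comparisons at 3 SE a rare boundary case is tolerated
  expect_gte(n_ok / n_checked, 0.97)
  # the headline contrasts are squarely within 3 SE
  for (nm in c("energy_kcal", "protein_g", "lipid_g", "salt_g")) {
    for (g in 1:3) {
      x <- prof[coh$true_cluster == g, nm]
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - planted[g, nm]), 3 * se)
    }
  }
  # high-calorie pattern ranks highest in energy
  em <- tapply(prof$energy_kcal, coh$true_cluster, mean)
  expect_equal(unname(which.max(em)), 2)
})

test_that("body composition couples fat mass to the unhealthy patterns", {
  spec <- cohort_spec(n_subjects = 300, seed = 62)
  coh <- generate_cohort(spec, streams = "body")
  fm <- tapply(coh$body$fat_mass, coh$true_cluster, mean)
  expect_gt(fm[["2"]], fm[["1"]])
  expect_gt(fm[["3"]], fm[["1"]])
  b <- compute_body_indices(coh$body)
  ffmi <- tapply(b$ffmi, coh$true_cluster, mean)
  fmi <- tapply(b$fmi, coh$true_cluster, mean)
  expect_gt(ffmi[["2"]], ffmi[["3"]])   # sarcopenic tendency in pattern 3
  expect_gt(fmi[["3"]], fmi[["1"]])
})

test_that("cohort streams round-trip through delimited files", {
  spec <- cohort_spec(n_subjects = 8, seed = 9)
  coh <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$configurations, coh$configurations, tolerance = 1e-12)
  expect_equal(back$true_cluster, coh$true_cluster)
  expect_equal(back$ffq$salt_taste, coh$ffq$salt_taste)
  expect_equal(back$body$weight, coh$body$weight, tolerance = 1e-12)
  expect_equal(as.matrix(back$behavior[, -1]),
               as.matrix(coh$behavior[, -1]), ignore_attr = TRUE)
})

test_that("landmark noise and allometry act along the planted directions", {
  spec <- cohort_spec(n_subjects = 50, seed = 13, shape_noise_sd = 0,
                      individual_sd = 0)
  coh <- generate_cohort(spec, streams = "shape")
  fit <- gpa(coh$configurations)
  u <- coh$axis_field
  # with no noise, deviations from the mean lie on the axis
  dev <- sweep(fit$shapes, 2, fit$mean_shape)
  off_axis <- dev - outer(as.numeric(dev %*% u), u)
  # superimposition is nonlinear, so off-axis residuals are second order
  # in the planted displacement (~1e-2), not exactly zero
  expect_lt(max(abs(off_axis)), 1e-3)
})
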