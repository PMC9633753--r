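#' Default pattern-level food-group frequency profiles
#'
#' Expected weekly consumption frequencies per food group for the three
#' planted dietary patterns: (1) balanced low-calorie (fish-rich,
#' vegetable-rich), (2) high-calorie (meat, snacks, fats, sweet drinks),
#' (3) imbalanced low-calorie (sweets and vegetable fats, little fish or
#' meat). These are the study conditions of the synthetic cohort.
#'
#' @return 3 x 29 matrix (patterns x food groups).
#' @keywords internal
default_pattern_frequencies <- function() {
  g <- food_group_names()
  f <- matrix(0, 3, length(g), dimnames = list(NULL, g))
  f[1, ] <- c(rice = 10, bread = 3, noodles = 3, potatoes = 2,
    sugar_sweets = 2, beans = 4, green_yellow_vegetables = 7,
    other_vegetables = 10, pickles = 2, fruits = 5, mushrooms = 3,
    seaweed = 3, fish = 6, shellfish = 2, fish_paste = 2, meat = 3,
    processed_meat = 1, eggs = 5, milk = 5, dairy_products = 3,
    butter = 1, vegetable_oil = 4, mayonnaise_dressing = 2, snacks = 2,
    sweet_drinks = 1, alcohol = 0.5, seasoning_sauces = 7, miso = 6,
    jam_honey = 1)[g]
  f[2, ] <- c(rice = 14, bread = 5, noodles = 5, potatoes = 3,
    sugar_sweets = 5, beans = 3, green_yellow_vegetables = 4,
    other_vegetables = 7, pickles = 3, fruits = 4, mushrooms = 2,
    seaweed = 2, fish = 4, shellfish = 1, fish_paste = 2, meat = 8,
    processed_meat = 4, eggs = 7, milk = 7, dairy_products = 5,
    butter = 3, vegetable_oil = 7, mayonnaise_dressing = 4, snacks = 7,
    sweet_drinks = 5, alcohol = 1, seasoning_sauces = 9, miso = 5,
    jam_honey = 2)[g]
  f[3, ] <- c(rice = 7, bread = 4, noodles = 4, potatoes = 2,
    sugar_sweets = 6, beans = 2, green_yellow_vegetables = 4,
    other_vegetables = 6, pickles = 3, fruits = 3, mushrooms = 1,
    seaweed = 1, fish = 1, shellfish = 0.5, fish_paste = 1, meat = 2,
    processed_meat = 2, eggs = 3, milk = 2, dairy_products = 2,
    butter = 1, vegetable_oil = 6, mayonnaise_dressing = 4, snacks = 8,
    sweet_drinks = 6, alcohol = 0.5, seasoning_sauces = 8, miso = 3,
    jam_honey = 2)[g]
  f
}

#' @keywords internal
default_pattern_cooking <- function() {
  ck <- cooking_type_names()
  f <- matrix(0, 3, length(ck), dimnames = list(NULL, ck))
  f[1, ] <- c(boiled = 4, deep_fried = 1, stir_fried = 3, grilled = 3,
    soup = 5, raw = 4, steamed = 2, simmered_sweet = 2, dressing_oil = 2,
    pickled_salt = 1)[ck]
  f[2, ] <- c(boiled = 2, deep_fried = 4, stir_fried = 5, grilled = 3,
    soup = 4, raw = 2, steamed = 1, simmered_sweet = 3, dressing_oil = 3,
    pickled_salt = 2)[ck]
  f[3, ] <- c(boiled = 2, deep_fried = 3, stir_fried = 3, grilled = 2,
    soup = 2, raw = 2, steamed = 1, simmered_sweet = 4, dressing_oil = 3,
    pickled_salt = 2)[ck]
  f
}

#' Expected taste multiplier under the default salt-taste distribution
#' (lighter/equal/saltier with probabilities 0.25/0.50/0.25).
#' @keywords internal
expected_taste_multiplier <- function() {
  sum(c(0.25, 0.5, 0.25) * salt_taste_multipliers())
}

#' Expected direct-nutrient intake means implied by frequency profiles
#'
#' Linear map from weekly food-group frequencies (at expected amount
#' weight 1) and cooking frequencies to the 43 directly estimated daily
#' nutrients, including the expected household salt-taste multiplier on
#' salt and sodium.
#'
#' @param freqs patterns x food-groups frequency matrix.
#' @param cook patterns x cooking-types frequency matrix.
#' @param table composition table.
#' @return patterns x 43 matrix of expected daily intakes.
#' @export
implied_cluster_means <- function(freqs = default_pattern_frequencies(),
                                  cook = default_pattern_cooking(),
                                  table = synthetic_food_composition()) {
  A <- intake_design_matrix(table, cooking = FALSE)
  Ack <- intake_design_matrix(table, cooking = TRUE)
  m <- freqs %*% t(A) + cook %*% t(Ack)
  mult <- expected_taste_multiplier()
  m[, "salt_g"] <- m[, "salt_g"] * mult
  m[, "sodium_mg"] <- m[, "sodium_mg"] * mult
  m
}

#' Linear intake operator: nutrients x food groups (per weekly frequency)
#' @keywords internal
intake_design_matrix <- function(table, cooking = FALSE) {
  rows <- if (cooking) table$is_cooking else !table$is_cooking
  dens <- as.matrix(table[rows, direct_nutrient_names()])
  A <- t(dens * table$portion_g[rows] / 7)
  colnames(A) <- sub("^cook_", "", table$food_group[rows])
  A
}

#' Specification of a synthetic cohort
#'
#' Defines the study conditions: cohort size, landmark density, the three
#' planted dietary patterns (mixture proportions and per-pattern expected
#' nutrient intakes), landmark noise, planted allometry and planted
#' dimorphism shifts, and the global seed.
#'
#' @param n_subjects cohort size (default 115).
#' @param n_landmarks landmarks per configuration (default 60; >= 26).
#' @param n_food_groups number of FFQ food groups (29 with the bundled
#'   composition table).
#' @param cluster_proportions mixture weights of the 3 patterns (sum 1;
#'   default 42/41/32 out of 115).
#' @param cluster_nutrient_means 3 x 43 matrix of planted per-pattern
#'   mean daily intakes of the directly estimated nutrients (default:
#'   the intakes implied by the built-in pattern frequency profiles).
#' @param shape_noise_sd isotropic landmark measurement noise, mm
#'   (default 0.3, a typical template-fitting error).
#' @param individual_sd scale of smooth individual shape variation:
#'   subjects get independent normal coefficients (SD
#'   `individual_sd / sqrt(j)`) on 8 fixed smooth deformation fields,
#'   giving the decaying eigen-spectrum of real facial samples
#'   (default 0.03 unit-shape units; 0 disables).
#' @param allometric_slope planted shape change along the dimorphism
#'   axis per mm of centroid size (unit-shape units; default 8e-4).
#' @param dimorphism_effect length-3 per-pattern shift along the
#'   male-female axis, unit-shape units (default
#'   c(0, -8e-4, 1.2e-3): the high-calorie pattern slightly feminized,
#'   the imbalanced pattern masculinized).
#' @param reference_effect male-female separation used for the reference
#'   axis, unit-shape units (default 0.04).
#' @param cs_sd between-subject SD of centroid size, mm (default 15).
#' @param seed global integer seed (default 1).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 115, n_landmarks = 60,
                        n_food_groups = 29,
                        cluster_proportions = c(42, 41, 32) / 115,
                        cluster_nutrient_means = NULL,
                        shape_noise_sd = 0.3,
                        individual_sd = 0.03,
                        allometric_slope = 8e-4,
                        dimorphism_effect = c(0, -8e-4, 1.2e-3),
                        reference_effect = 0.04,
                        cs_sd = 15, seed = 1) {
  if (n_subjects < 1 || n_landmarks < 26 || n_food_groups < 1)
    stop("counts must be positive (and n_landmarks >= 26)")
  if (length(cluster_proportions) != 3 || any(cluster_proportions < 0) ||
      abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must be 3 non-negative weights summing to 1")
  if (shape_noise_sd < 0 || cs_sd < 0 || individual_sd < 0)
    stop("noise SDs must be >= 0")
  if (length(dimorphism_effect) != 3)
    stop("dimorphism_effect must have one entry per pattern")
  if (is.null(cluster_nutrient_means))
    cluster_nutrient_means <- implied_cluster_means()
  cluster_nutrient_means <- as.matrix(cluster_nutrient_means)
  if (!identical(dim(cluster_nutrient_means), c(3L, 43L)))
    stop("cluster_nutrient_means must be 3 x 43")
  colnames(cluster_nutrient_means) <- direct_nutrient_names()
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_landmarks = as.integer(n_landmarks),
    n_food_groups = as.integer(n_food_groups),
    cluster_proportions = cluster_proportions,
    cluster_nutrient_means = cluster_nutrient_means,
    shape_noise_sd = shape_noise_sd,
    individual_sd = individual_sd,
    allometric_slope = allometric_slope,
    dimorphism_effect = dimorphism_effect,
    reference_effect = reference_effect,
    cs_sd = cs_sd,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Subjects are drawn from the three planted dietary patterns. Faces are
#' built from the landmark template: unit shape = template shape +
#' pattern shift along the masculinity field + allometric_slope x
#' (CS - mean CS) along the same field + isotropic Gaussian landmark
#' noise; the configuration is emitted at its drawn centroid size in
#' template pose. FFQ responses are generated by inverting the intake
#' formula (non-negative least squares from the planted per-pattern
#' nutrient means back to expected food-group frequencies, then Poisson
#' frequencies and amount categories with expected weight 1), so the
#' nutrition estimator is exercised end to end. Eating-behavior items and
#' body composition carry the pattern contrasts (higher fat mass in the
#' high-calorie pattern, high fat / low fat-free mass in the imbalanced
#' pattern). Each stream uses its own sub-stream of the global seed.
#'
#' @param spec a [cohort_spec()].
#' @param streams which data streams to generate (subset of
#'   `c("shape", "ffq", "behavior", "body")`; truth is always included).
#' @return object of class `synthetic_cohort`: list with
#'   `configurations`, `ffq`, `behavior`, `body`, `true_cluster`,
#'   `true_sshd`, `template`, `axis_field`, `spec`.
#' @export
generate_cohort <- function(spec,
                            streams = c("shape", "ffq", "behavior", "body")) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  template <- face_template(spec$n_landmarks)
  u <- dimorphism_field(template)

  cluster <- local_seed(derive_seed(spec$seed, 1),
    sample.int(3, n, replace = TRUE, prob = spec$cluster_proportions))

  out <- list(configurations = NULL, ffq = NULL, behavior = NULL,
              body = NULL, true_cluster = cluster, true_sshd = NULL,
              template = template, axis_field = u, spec = spec)

  if ("shape" %in% streams) {
    cs_t <- centroid_size(template)
    ctr <- colMeans(template)
    t0 <- flatten_config(sweep(template, 2, ctr, "-")) / cs_t
    fields <- individual_variation_fields(template)
    field_sd <- spec$individual_sd / sqrt(seq_len(ncol(fields)))
    sh <- local_seed(derive_seed(spec$seed, 2), {
      cs <- stats::rnorm(n, cs_t, spec$cs_sd)
      delta <- spec$dimorphism_effect[cluster] +
        spec$allometric_slope * (cs - mean(cs))
      coefs <- matrix(stats::rnorm(n * ncol(fields)), nrow = n) %*%
        diag(field_sd)
      noise <- matrix(stats::rnorm(n * length(t0), 0,
                                   spec$shape_noise_sd / cs_t),
                      nrow = n)
      list(cs = cs, delta = delta, coefs = coefs, noise = noise)
    })
    configs <- lapply(seq_len(n), function(i) {
      v <- t0 + sh$delta[i] * u +
        as.numeric(fields %*% sh$coefs[i, ]) + sh$noise[i, ]
      m <- unflatten_config(sh$cs[i] * v, rownames(template))
      sweep(m, 2, ctr, "+")
    })
    names(configs) <- ids
    out$configurations <- configs
    out$true_sshd <- sh$delta / spec$reference_effect
  }

  if ("ffq" %in% streams) {
    table <- synthetic_food_composition()
    A <- intake_design_matrix(table, cooking = FALSE)
    cookA <- intake_design_matrix(table, cooking = TRUE)
    cook_f <- default_pattern_cooking()
    mult <- expected_taste_multiplier()
    fstar <- t(vapply(1:3, function(g) {
      target <- spec$cluster_nutrient_means[g, ]
      target[c("salt_g", "sodium_mg")] <-
        target[c("salt_g", "sodium_mg")] / mult
      resid <- target - as.numeric(cookA %*% cook_f[g, ])
      pracma::lsqnonneg(A, pmax(resid, 0))$x
    }, numeric(ncol(A))))
    colnames(fstar) <- colnames(A)
    ffq <- local_seed(derive_seed(spec$seed, 3), {
      freq <- matrix(stats::rpois(n * ncol(A),
                                  fstar[cluster, , drop = FALSE]),
                     nrow = n,
                     dimnames = list(NULL, paste0("freq_", colnames(A))))
      amt <- matrix(sample(c("A little", "Normal", "Plenty"),
                           n * ncol(A), replace = TRUE,
                           prob = c(0.25, 0.5, 0.25)),
                    nrow = n,
                    dimnames = list(NULL, paste0("amt_", colnames(A))))
      cookn <- matrix(stats::rpois(n * ncol(cookA),
                                   cook_f[cluster, , drop = FALSE]),
                      nrow = n,
                      dimnames = list(NULL, paste0("cook_", colnames(cookA))))
      taste <- sample(names(salt_taste_multipliers()), n, replace = TRUE,
                      prob = c(0.25, 0.5, 0.25))
      data.frame(subject_id = ids, amt, freq, cookn, salt_taste = taste,
                 check.names = FALSE, row.names = NULL)
    })
    out$ffq <- ffq
  }

  if ("behavior" %in% streams) {
    map <- behavior_scale_map()
    # per-pattern item means: (-) 1.7, baseline 2.0, (+) 2.6 per category
    item_mean <- matrix(2.0, 3, 7,
                        dimnames = list(NULL, levels(map)))
    item_mean[1, ] <- 1.7
    item_mean[2, c("weight_recognition", "emotional_eating",
                   "sense_of_hunger", "eating_style")] <- 2.6
    item_mean[3, c("weight_recognition", "external_eating",
                   "emotional_eating", "eating_style", "food_preference",
                   "eating_regularity")] <- 2.6
    beh <- local_seed(derive_seed(spec$seed, 4), {
      mu <- item_mean[cluster, as.character(map), drop = FALSE]
      resp <- matrix(pmin(4, pmax(1, round(stats::rnorm(n * 55, mu, 0.8)))),
                     nrow = n, dimnames = list(NULL, names(map)))
      data.frame(subject_id = ids, resp, row.names = NULL)
    })
    out$behavior <- beh
  }

  if ("body" %in% streams) {
    body <- local_seed(derive_seed(spec$seed, 5), {
      height <- stats::rnorm(n, 1.58, 0.05)
      weight <- stats::rnorm(n, 51, 4.5) + c(0, 3, 1)[cluster]
      fat_frac <- pmin(0.45, pmax(0.12,
        stats::rnorm(n, 0.25, 0.025) + c(0, 0.03, 0.05)[cluster]))
      fat <- fat_frac * weight
      ffm <- weight - fat
      muscle <- pmin(ffm, 0.55 * ffm + stats::rnorm(n, 0, 0.8))
      data.frame(subject_id = ids, weight = weight, height = height,
                 fat_mass = fat, fat_free_mass = ffm, muscle_mass = muscle,
                 row.names = NULL)
    })
    out$body <- body
  }

  structure(out, class = "synthetic_cohort")
}

#' Generate the male/female reference for the dimorphism axis
#'
#' Builds reference mean configurations as the template shifted by plus
#' and minus half the reference effect along the masculinity field, and
#' the corresponding [dimorphism_axis()] in unit-shape space. A stand-in
#' for an external two-sex reference sample.
#'
#' @param spec a [cohort_spec()].
#' @param effect male-female separation in unit-shape units
#'   (default `spec$reference_effect`; must be non-zero).
#' @return list with `male_config`, `female_config` (p x 3, mm),
#'   `axis` (a `dimorphism_axis` on unit shapes), `effect`.
#' @export
generate_dimorphism_reference <- function(spec, effect = spec$reference_effect) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (abs(effect) < 1e-12)
    stop("zero-norm axis requested: effect must be non-zero")
  template <- face_template(spec$n_landmarks)
  u <- dimorphism_field(template)
  cs_t <- centroid_size(template)
  ctr <- colMeans(template)
  t0 <- flatten_config(sweep(template, 2, ctr, "-")) / cs_t
  male <- t0 + (effect / 2) * u
  female <- t0 - (effect / 2) * u
  to_config <- function(v) {
    m <- unflatten_config(cs_t * v, rownames(template))
    sweep(m, 2, ctr, "+")
  }
  list(male_config = to_config(male), female_config = to_config(female),
       axis = dimorphism_axis(male, female), effect = effect)
}

#' Write / read the five cohort streams as delimited text
#'
#' `landmarks.csv` (long format), `ffq.csv`, `behavior.csv`, `body.csv`
#' and `truth.csv` (true cluster and planted SShD displacement).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$configurations))
    write_landmarks(cohort$configurations, file.path(dir, "landmarks.csv"))
  for (nm in c("ffq", "behavior", "body"))
    if (!is.null(cohort[[nm]]))
      utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
  truth <- data.frame(
    subject_id = sprintf("S%03d", seq_along(cohort$true_cluster)),
    true_cluster = cohort$true_cluster,
    true_sshd = if (is.null(cohort$true_sshd)) NA else cohort$true_sshd)
  utils::write.csv(truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  path <- function(f) file.path(dir, f)
  res <- list(
    configurations = if (file.exists(path("landmarks.csv")))
      read_landmarks(path("landmarks.csv")),
    ffq = if (file.exists(path("ffq.csv")))
      utils::read.csv(path("ffq.csv"), check.names = FALSE,
                      stringsAsFactors = FALSE),
    behavior = if (file.exists(path("behavior.csv")))
      utils::read.csv(path("behavior.csv"), stringsAsFactors = FALSE),
    body = if (file.exists(path("body.csv")))
      utils::read.csv(path("body.csv"), stringsAsFactors = FALSE),
    true_cluster = NULL, true_sshd = NULL, template = NULL,
    axis_field = NULL, spec = NULL)
  if (file.exists(path("truth.csv"))) {
    tr <- utils::read.csv(path("truth.csv"))
    res$true_cluster <- tr$true_cluster
    res$true_sshd <- tr$true_sshd
  }
  structure(res, class = "synthetic_cohort")
}
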