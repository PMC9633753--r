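#' Names of the 53 estimated daily nutrient intake items
#'
#' Forty-three items are estimated directly from per-gram densities in the
#' food composition table; ten are derived (percent-of-energy shares,
#' ratios over class totals, equivalents). Units are encoded in the names.
#' @return character vector of length 53.
#' @export
nutrient_names <- function() {
  c(direct_nutrient_names(), derived_nutrient_names())
}

#' @keywords internal
direct_nutrient_names <- function() {
  c("energy_kcal", "water_g", "protein_g", "lipid_g", "fa_total_g",
    "saturated_fa_g", "cholesterol_mg", "mufa_g", "pufa_g", "n3_pufa_g",
    "n6_pufa_g", "carbohydrate_g", "fiber_soluble_g", "fiber_insoluble_g",
    "retinol_ug", "alpha_carotene_ug", "beta_carotene_ug",
    "cryptoxanthin_ug", "vitamin_d_ug", "alpha_tocopherol_mg",
    "beta_tocopherol_mg", "gamma_tocopherol_mg", "delta_tocopherol_mg",
    "vitamin_k_ug", "vitamin_b1_mg", "vitamin_b2_mg", "niacin_mg",
    "vitamin_b6_mg", "vitamin_b12_ug", "folic_acid_ug",
    "pantothenic_acid_mg", "vitamin_c_mg", "mineral_g", "sodium_mg",
    "salt_g", "potassium_mg", "calcium_mg", "magnesium_mg",
    "phosphorus_mg", "iron_mg", "zinc_mg", "copper_mg", "manganese_mg")
}

#' @keywords internal
derived_nutrient_names <- function() {
  c("grain_pctE", "protein_pctE", "lipid_pctE", "carbohydrate_pctE",
    "animal_protein_ratio", "deep_yellow_veg_ratio", "fiber_total_g",
    "beta_carotene_eq_ug", "retinol_eq_ug", "tocopherol_eq_mg")
}

#' Names of the seven oil / fatty-acid ratio fields
#' @return character vector of length 7.
#' @export
ratio_names <- function() {
  c("animal_oil_ratio", "vegetable_oil_ratio", "fish_oil_ratio",
    "saturated_fa_ratio", "mufa_ratio", "pufa_ratio", "n6_n3_ratio")
}

#' Food amount category weights
#' @keywords internal
amount_category_weights <- function() {
  c("No" = 0, "A little" = 0.5, "Normal" = 1, "Plenty" = 1.5)
}

#' Household salt-taste multipliers
#' @keywords internal
salt_taste_multipliers <- function() {
  c(lighter = 1.0, equal = 1.15, saltier = 1.3)
}

#' The 29 food groups and 10 cooking types of the questionnaire
#' @return character vector.
#' @export
food_group_names <- function() {
  c("rice", "bread", "noodles", "potatoes", "sugar_sweets", "beans",
    "green_yellow_vegetables", "other_vegetables", "pickles", "fruits",
    "mushrooms", "seaweed", "fish", "shellfish", "fish_paste", "meat",
    "processed_meat", "eggs", "milk", "dairy_products", "butter",
    "vegetable_oil", "mayonnaise_dressing", "snacks", "sweet_drinks",
    "alcohol", "seasoning_sauces", "miso", "jam_honey")
}

#' @rdname food_group_names
#' @export
cooking_type_names <- function() {
  c("boiled", "deep_fried", "stir_fried", "grilled", "soup", "raw",
    "steamed", "simmered_sweet", "dressing_oil", "pickled_salt")
}

#' Synthetic food composition table
#'
#' A fully synthetic per-gram composition table for the 29 food groups and
#' 10 cooking types, with plausible magnitudes for portion sizes and the
#' 43 directly estimated nutrient densities, class tags (grain, vegetable,
#' deep-yellow, animal) and oil-class gram shares used for ratio fields.
#' It is not a published composition table; users may substitute their own
#' file in the same schema via [read_food_composition()].
#'
#' @return data.frame, one row per food group / cooking type.
#' @export
synthetic_food_composition <- function() {
  g <- food_group_names()
  ck <- cooking_type_names()
  all_rows <- c(g, paste0("cook_", ck))
  n <- length(all_rows)
  idx <- function(keys) match(keys, all_rows)
  vec <- function(default = 0, ...) {
    v <- rep(default, n)
    names(v) <- all_rows
    dots <- list(...)
    bad <- setdiff(names(dots), all_rows)
    if (length(bad)) stop("unknown table row: ", paste(bad, collapse = ", "))
    for (k in names(dots)) v[k] <- dots[[k]]
    unname(v)
  }

  portion <- vec(1,
    rice = 150, bread = 90, noodles = 200, potatoes = 80, sugar_sweets = 20,
    beans = 60, green_yellow_vegetables = 70, other_vegetables = 100,
    pickles = 20, fruits = 100, mushrooms = 30, seaweed = 10, fish = 80,
    shellfish = 40, fish_paste = 40, meat = 80, processed_meat = 30,
    eggs = 50, milk = 200, dairy_products = 80, butter = 10,
    vegetable_oil = 10, mayonnaise_dressing = 12, snacks = 50,
    sweet_drinks = 250, alcohol = 150, seasoning_sauces = 15, miso = 15,
    jam_honey = 15,
    cook_boiled = 5, cook_deep_fried = 10, cook_stir_fried = 6,
    cook_grilled = 2, cook_soup = 150, cook_raw = 1, cook_steamed = 1,
    cook_simmered_sweet = 8, cook_dressing_oil = 8, cook_pickled_salt = 5)

  protein <- vec(0,
    rice = 0.025, bread = 0.09, noodles = 0.05, potatoes = 0.016,
    beans = 0.10, green_yellow_vegetables = 0.02, other_vegetables = 0.012,
    pickles = 0.015, fruits = 0.007, mushrooms = 0.03, seaweed = 0.02,
    fish = 0.20, shellfish = 0.13, fish_paste = 0.12, meat = 0.19,
    processed_meat = 0.13, eggs = 0.12, milk = 0.033, dairy_products = 0.08,
    butter = 0.006, mayonnaise_dressing = 0.015, snacks = 0.06,
    alcohol = 0.004, seasoning_sauces = 0.05, miso = 0.12, jam_honey = 0.002)

  lipid <- vec(0,
    rice = 0.003, bread = 0.04, noodles = 0.01, potatoes = 0.001,
    beans = 0.07, green_yellow_vegetables = 0.002, other_vegetables = 0.001,
    pickles = 0.001, fruits = 0.002, mushrooms = 0.003, seaweed = 0.002,
    fish = 0.08, shellfish = 0.01, fish_paste = 0.02, meat = 0.15,
    processed_meat = 0.25, eggs = 0.10, milk = 0.038, dairy_products = 0.12,
    butter = 0.81, vegetable_oil = 0.97, mayonnaise_dressing = 0.70,
    snacks = 0.25, seasoning_sauces = 0.02, miso = 0.06, jam_honey = 0.001,
    cook_deep_fried = 0.9, cook_stir_fried = 0.9, cook_grilled = 0.5,
    cook_dressing_oil = 0.75)

  carb <- vec(0,
    rice = 0.37, bread = 0.46, noodles = 0.26, potatoes = 0.17,
    sugar_sweets = 0.95, beans = 0.10, green_yellow_vegetables = 0.06,
    other_vegetables = 0.04, pickles = 0.05, fruits = 0.13,
    mushrooms = 0.05, seaweed = 0.05, shellfish = 0.01, fish_paste = 0.08,
    fish = 0.002, meat = 0.002, eggs = 0.004, milk = 0.048,
    dairy_products = 0.06, butter = 0.002, mayonnaise_dressing = 0.03,
    snacks = 0.55, sweet_drinks = 0.10, alcohol = 0.04,
    seasoning_sauces = 0.20, miso = 0.20, jam_honey = 0.60,
    cook_simmered_sweet = 0.9)

  # oil-class split of the lipid fraction: animal / vegetable / fish
  animal_share <- vec(0, bread = 0.3, meat = 1, processed_meat = 1,
    eggs = 1, milk = 1, dairy_products = 1, butter = 1,
    mayonnaise_dressing = 0.1, snacks = 0.3, fish_paste = 0)
  fish_share <- vec(0, fish = 1, shellfish = 1, fish_paste = 0.7)
  veg_share <- pmax(0, 1 - animal_share - fish_share)
  veg_share[lipid == 0] <- 0
  animal_share[lipid == 0] <- 0

  # fatty-acid composition of the lipid, by dominant oil class
  fa_total <- 0.9 * lipid
  sat_frac <- 0.15 + 0.30 * animal_share + 0.10 * fish_share
  mufa_frac <- rep(0.40, n)
  pufa_frac <- pmax(0.05, 1 - sat_frac - mufa_frac)
  n3_frac <- 0.08 + 0.27 * fish_share   # of PUFA

  salt <- vec(0.001, pickles = 0.02, seasoning_sauces = 0.10, miso = 0.12,
    processed_meat = 0.02, bread = 0.012, fish_paste = 0.02, snacks = 0.01,
    sweet_drinks = 0, fruits = 0, milk = 0.002, sugar_sweets = 0,
    jam_honey = 0, vegetable_oil = 0, butter = 0.015,
    cook_boiled = 0, cook_deep_fried = 0.002, cook_stir_fried = 0.005,
    cook_grilled = 0.01, cook_soup = 0.008, cook_raw = 0, cook_steamed = 0,
    cook_simmered_sweet = 0.01, cook_dressing_oil = 0.01,
    cook_pickled_salt = 0.06)

  d <- data.frame(
    food_group = all_rows,
    portion_g = portion,
    is_cooking = startsWith(all_rows, "cook_"),
    is_grain = all_rows %in% c("rice", "bread", "noodles"),
    is_vegetable = all_rows %in% c("green_yellow_vegetables",
                                   "other_vegetables", "pickles"),
    is_deep_yellow = all_rows == "green_yellow_vegetables",
    is_animal = all_rows %in% c("fish", "shellfish", "fish_paste", "meat",
                                "processed_meat", "eggs", "milk",
                                "dairy_products", "butter"),
    animal_oil_g = animal_share * lipid,
    vegetable_oil_g = veg_share * lipid,
    fish_oil_g = fish_share * lipid,
    energy_kcal = 4 * protein + 9 * lipid + 4 * carb,
    water_g = pmax(0, 1 - protein - lipid - carb - 0.01),
    protein_g = protein,
    lipid_g = lipid,
    fa_total_g = fa_total,
    saturated_fa_g = fa_total * sat_frac,
    cholesterol_mg = vec(0, eggs = 4.2, meat = 0.7, processed_meat = 0.6,
      fish = 0.6, shellfish = 1.2, dairy_products = 0.25, milk = 0.12,
      butter = 2.1, mayonnaise_dressing = 0.6, snacks = 0.1),
    mufa_g = fa_total * mufa_frac,
    pufa_g = fa_total * pufa_frac,
    n3_pufa_g = fa_total * pufa_frac * n3_frac,
    n6_pufa_g = fa_total * pufa_frac * (1 - n3_frac),
    carbohydrate_g = carb,
    fiber_soluble_g = vec(0, potatoes = 0.005, beans = 0.006,
      green_yellow_vegetables = 0.007, other_vegetables = 0.005,
      pickles = 0.004, fruits = 0.005, mushrooms = 0.004, seaweed = 0.02,
      rice = 0.001, bread = 0.002, noodles = 0.002, snacks = 0.002),
    fiber_insoluble_g = vec(0, potatoes = 0.009, beans = 0.04,
      green_yellow_vegetables = 0.02, other_vegetables = 0.013,
      pickles = 0.012, fruits = 0.009, mushrooms = 0.03, seaweed = 0.15,
      rice = 0.003, bread = 0.015, noodles = 0.01, snacks = 0.01),
    retinol_ug = vec(0, eggs = 1.5, butter = 5.0, dairy_products = 0.6,
      milk = 0.38, meat = 0.11, processed_meat = 0.05, fish = 0.1),
    alpha_carotene_ug = vec(0, green_yellow_vegetables = 6,
      other_vegetables = 0.5, potatoes = 0.1),
    beta_carotene_ug = vec(0, green_yellow_vegetables = 30,
      other_vegetables = 3, pickles = 1, fruits = 1, seaweed = 15),
    cryptoxanthin_ug = vec(0, fruits = 2, green_yellow_vegetables = 1),
    vitamin_d_ug = vec(0, fish = 0.08, shellfish = 0.01, fish_paste = 0.02,
      eggs = 0.018, milk = 0.003, dairy_products = 0.004, butter = 0.006,
      mushrooms = 0.004),
    alpha_tocopherol_mg = vec(0.0002, vegetable_oil = 0.12,
      mayonnaise_dressing = 0.09, snacks = 0.02, fish = 0.012,
      green_yellow_vegetables = 0.01, beans = 0.008, eggs = 0.01,
      cook_deep_fried = 0.1, cook_stir_fried = 0.1, cook_dressing_oil = 0.08),
    beta_tocopherol_mg = vec(0, vegetable_oil = 0.004, bread = 0.002,
      snacks = 0.001),
    gamma_tocopherol_mg = vec(0, vegetable_oil = 0.4, beans = 0.05,
      mayonnaise_dressing = 0.3, snacks = 0.03, cook_deep_fried = 0.3,
      cook_stir_fried = 0.3, cook_dressing_oil = 0.25),
    delta_tocopherol_mg = vec(0, vegetable_oil = 0.1, beans = 0.02,
      mayonnaise_dressing = 0.07, snacks = 0.01),
    vitamin_k_ug = vec(0.01, beans = 6, green_yellow_vegetables = 1.5,
      other_vegetables = 0.8, pickles = 0.4, seaweed = 3,
      vegetable_oil = 1.2, eggs = 0.12),
    vitamin_b1_mg = vec(0.0001, rice = 0.0008, bread = 0.0007,
      noodles = 0.0005, meat = 0.005, processed_meat = 0.003,
      beans = 0.002, potatoes = 0.0009, eggs = 0.0006, fish = 0.001),
    vitamin_b2_mg = vec(0.0001, milk = 0.0015, dairy_products = 0.002,
      eggs = 0.0037, meat = 0.002, fish = 0.002, mushrooms = 0.002,
      beans = 0.001, green_yellow_vegetables = 0.001),
    niacin_mg = vec(0.001, fish = 0.08, shellfish = 0.02, meat = 0.05,
      processed_meat = 0.03, mushrooms = 0.04, rice = 0.01,
      bread = 0.012, noodles = 0.008, beans = 0.006),
    vitamin_b6_mg = vec(0.0002, fish = 0.004, meat = 0.003,
      potatoes = 0.002, fruits = 0.0015, green_yellow_vegetables = 0.001,
      beans = 0.001),
    vitamin_b12_ug = vec(0, fish = 0.08, shellfish = 0.2,
      fish_paste = 0.02, meat = 0.01, processed_meat = 0.004,
      eggs = 0.009, milk = 0.003, dairy_products = 0.01),
    folic_acid_ug = vec(0.05, beans = 1.2, green_yellow_vegetables = 1.0,
      other_vegetables = 0.6, pickles = 0.3, fruits = 0.3, seaweed = 1.5,
      eggs = 0.4, mushrooms = 0.6),
    pantothenic_acid_mg = vec(0.0005, meat = 0.01, eggs = 0.014,
      dairy_products = 0.005, milk = 0.0055, mushrooms = 0.02,
      fish = 0.007, beans = 0.004, potatoes = 0.005),
    vitamin_c_mg = vec(0.001, fruits = 0.4, green_yellow_vegetables = 0.4,
      other_vegetables = 0.2, pickles = 0.1, potatoes = 0.25),
    mineral_g = vec(0.005, seaweed = 0.2, seasoning_sauces = 0.12,
      miso = 0.14, pickles = 0.03, fish = 0.012, meat = 0.01,
      milk = 0.007, dairy_products = 0.02,
      cook_soup = 0.009, cook_pickled_salt = 0.07),
    salt_g = salt,
    sodium_mg = salt * 1000 / 2.54,
    potassium_mg = vec(0.5, potatoes = 4.0, beans = 5.0, fruits = 2.0,
      green_yellow_vegetables = 3.0, other_vegetables = 2.0,
      pickles = 1.0, fish = 3.0, meat = 3.0, seaweed = 8.0, milk = 1.5,
      mushrooms = 3.0),
    calcium_mg = vec(0.1, milk = 1.1, dairy_products = 4.0, seaweed = 7.0,
      fish = 0.4, shellfish = 0.7, fish_paste = 0.5, beans = 1.0,
      green_yellow_vegetables = 0.5, miso = 1.0),
    magnesium_mg = vec(0.05, seaweed = 10, beans = 1.0, fish = 0.3,
      shellfish = 0.6, rice = 0.3, bread = 0.2, noodles = 0.2,
      green_yellow_vegetables = 0.2, other_vegetables = 0.15),
    phosphorus_mg = vec(0.3, fish = 2.4, shellfish = 1.5, fish_paste = 1.0,
      meat = 1.8, processed_meat = 2.0, eggs = 1.8, milk = 0.93,
      dairy_products = 5.0, beans = 2.0, rice = 0.9, bread = 0.8),
    iron_mg = vec(0.003, meat = 0.01, processed_meat = 0.006,
      beans = 0.02, green_yellow_vegetables = 0.01, seaweed = 0.3,
      eggs = 0.018, fish = 0.009, shellfish = 0.04),
    zinc_mg = vec(0.003, meat = 0.03, shellfish = 0.02, fish = 0.006,
      eggs = 0.013, dairy_products = 0.03, rice = 0.008, bread = 0.008,
      beans = 0.012),
    copper_mg = vec(0.0008, beans = 0.003, seaweed = 0.006,
      shellfish = 0.004, mushrooms = 0.002, rice = 0.002),
    manganese_mg = vec(0.0005, rice = 0.008, bread = 0.005,
      noodles = 0.004, beans = 0.01, seaweed = 0.006,
      green_yellow_vegetables = 0.002),
    row.names = NULL
  )
  d
}

#' Read / write a food composition table
#'
#' Delimited text, one row per food group, with the column dictionary of
#' [synthetic_food_composition()]: `food_group`, `portion_g`, logical
#' class tags, oil-class gram shares, and the 43 per-gram nutrient
#' densities named as in [direct_nutrient_names()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_food_composition <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_food_composition(d)
  d
}

#' @rdname read_food_composition
#' @param table a composition table data.frame.
#' @export
write_food_composition <- function(table, path) {
  validate_food_composition(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
validate_food_composition <- function(table) {
  need <- c("food_group", "portion_g", "is_cooking", "is_grain",
            "is_vegetable", "is_deep_yellow", "is_animal",
            "animal_oil_g", "vegetable_oil_g", "fish_oil_g",
            direct_nutrient_names())
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("composition table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(table$portion_g <= 0)) stop("portion sizes must be > 0")
  dens <- as.matrix(table[, direct_nutrient_names()])
  if (any(dens < 0)) stop("nutrient densities must be >= 0")
  invisible(TRUE)
}

#' Adjust estimated salt intake for household taste
#'
#' Salt (and co-scaled sodium) estimated from the questionnaire is
#' multiplied by 1.0 for households seasoning lighter than restaurant
#' food, 1.15 for equal, and 1.3 for saltier.
#'
#' @param base_salt_g estimated daily salt, g/day (>= 0).
#' @param taste one of "lighter", "equal", "saltier".
#' @return adjusted g/day.
#' @export
adjust_salt <- function(base_salt_g, taste) {
  mult <- salt_taste_multipliers()
  if (!taste %in% names(mult))
    stop("unknown salt-taste category: ", taste)
  if (any(base_salt_g < 0)) stop("base salt must be >= 0")
  base_salt_g * mult[[taste]]
}

#' Estimate a daily nutrient profile from one FFQ record
#'
#' Per nutrient, intake is the sum over food groups of
#' portion size (g) x amount-category weight (No 0, A little 0.5,
#' Normal 1, Plenty 1.5) x weekly frequency / 7 x per-gram density.
#' Cooking-method items contribute through their own table rows at
#' category weight 1. Salt and sodium are then adjusted for household
#' taste, and the derived fields (percent-energy shares via Atwater
#' factors 4/9/4, class ratios, equivalents) and the seven oil /
#' fatty-acid ratios are computed.
#'
#' @param record a list with elements `amount` (named character vector of
#'   amount categories per food group), `frequency` (named numeric,
#'   times/week per food group), `cooking` (named numeric, times/week per
#'   cooking type) and `salt_taste`.
#' @param table food composition table (see [synthetic_food_composition()]).
#' @return named numeric vector of length 60: the 53 nutrient intakes
#'   followed by the 7 ratio fields.
#' @export
estimate_nutrient_intake <- function(record, table = synthetic_food_composition()) {
  validate_food_composition(table)
  freq <- record$frequency
  amt <- record$amount
  cook <- if (is.null(record$cooking)) numeric(0) else record$cooking
  taste <- if (is.null(record$salt_taste)) "lighter" else record$salt_taste

  groups <- table$food_group[!table$is_cooking]
  unknown <- setdiff(names(freq), groups)
  if (length(unknown))
    stop("unknown food group(s): ", paste(unknown, collapse = ", "))
  if (length(cook)) {
    unknown_ck <- setdiff(paste0("cook_", names(cook)), table$food_group)
    if (length(unknown_ck))
      stop("unknown cooking type(s): ", paste(unknown_ck, collapse = ", "))
  }
  if (any(!is.finite(freq)) || any(freq < 0) ||
      (length(cook) && (any(!is.finite(cook)) || any(cook < 0))))
    stop("weekly frequencies must be finite and >= 0")
  w <- amount_category_weights()
  bad <- setdiff(unique(amt), names(w))
  if (length(bad))
    stop("unknown amount category: ", paste(bad, collapse = ", "))
  if (!identical(sort(names(freq)), sort(names(amt))))
    stop("amount and frequency must cover the same food groups")

  # grams/day per table row
  grams <- numeric(nrow(table))
  names(grams) <- table$food_group
  grams[names(freq)] <-
    table$portion_g[match(names(freq), table$food_group)] *
    w[amt[names(freq)]] * freq / 7
  if (length(cook)) {
    ck_rows <- paste0("cook_", names(cook))
    grams[ck_rows] <-
      table$portion_g[match(ck_rows, table$food_group)] * cook / 7
  }

  dens <- as.matrix(table[, direct_nutrient_names()])
  intake <- as.numeric(crossprod(dens, grams))
  names(intake) <- direct_nutrient_names()

  intake["salt_g"] <- adjust_salt(intake["salt_g"], taste)
  intake["sodium_mg"] <- intake["sodium_mg"] * salt_taste_multipliers()[[taste]]

  energy <- intake["energy_kcal"]
  pctE <- function(x) if (energy > 0) 100 * x / energy else 0
  grain_energy <- sum(grams[table$is_grain] *
                        table$energy_kcal[table$is_grain])
  animal_protein <- sum(grams[table$is_animal] *
                          table$protein_g[table$is_animal])
  veg_g <- sum(grams[table$is_vegetable])
  dy_g <- sum(grams[table$is_deep_yellow])
  bce <- intake["beta_carotene_ug"] +
    0.5 * (intake["alpha_carotene_ug"] + intake["cryptoxanthin_ug"])
  derived <- c(
    grain_pctE = unname(pctE(grain_energy)),
    protein_pctE = unname(pctE(4 * intake["protein_g"])),
    lipid_pctE = unname(pctE(9 * intake["lipid_g"])),
    carbohydrate_pctE = unname(pctE(4 * intake["carbohydrate_g"])),
    animal_protein_ratio = unname(
      if (intake["protein_g"] > 0) 100 * animal_protein / intake["protein_g"] else 0),
    deep_yellow_veg_ratio = unname(if (veg_g > 0) dy_g / veg_g else 0),
    fiber_total_g = unname(intake["fiber_soluble_g"] + intake["fiber_insoluble_g"]),
    beta_carotene_eq_ug = unname(bce),
    retinol_eq_ug = unname(intake["retinol_ug"] + bce / 12),
    tocopherol_eq_mg = unname(intake["alpha_tocopherol_mg"] +
      0.4 * intake["beta_tocopherol_mg"] + 0.1 * intake["gamma_tocopherol_mg"] +
      0.01 * intake["delta_tocopherol_mg"]))

  oil <- c(animal = sum(grams * table$animal_oil_g),
           vegetable = sum(grams * table$vegetable_oil_g),
           fish = sum(grams * table$fish_oil_g))
  oil_tot <- sum(oil)
  fa_tot <- intake["fa_total_g"]
  ratios <- c(
    animal_oil_ratio = unname(if (oil_tot > 0) oil[["animal"]] / oil_tot else 0),
    vegetable_oil_ratio = unname(if (oil_tot > 0) oil[["vegetable"]] / oil_tot else 0),
    fish_oil_ratio = unname(if (oil_tot > 0) oil[["fish"]] / oil_tot else 0),
    saturated_fa_ratio = unname(if (fa_tot > 0) intake["saturated_fa_g"] / fa_tot else 0),
    mufa_ratio = unname(if (fa_tot > 0) intake["mufa_g"] / fa_tot else 0),
    pufa_ratio = unname(if (fa_tot > 0) intake["pufa_g"] / fa_tot else 0),
    n6_n3_ratio = unname(
      if (intake["n3_pufa_g"] > 0) intake["n6_pufa_g"] / intake["n3_pufa_g"]
      else if (intake["n6_pufa_g"] == 0) 0 else Inf))

  c(intake, derived, ratios)
}

#' Estimate nutrient profiles for a whole FFQ table
#'
#' @param ffq data.frame in the wide schema written by [write_cohort()]:
#'   `subject_id`, `amt_<group>`, `freq_<group>`, `cook_<type>`,
#'   `salt_taste`.
#' @param table food composition table.
#' @return data.frame: `subject_id` plus the 60 profile columns.
#' @export
estimate_nutrient_profiles <- function(ffq, table = synthetic_food_composition()) {
  groups <- sub("^freq_", "", grep("^freq_", names(ffq), value = TRUE))
  out <- t(vapply(seq_len(nrow(ffq)), function(i) {
    rec <- list(
      amount = stats::setNames(
        as.character(ffq[i, paste0("amt_", groups)]), groups),
      frequency = stats::setNames(
        as.numeric(ffq[i, paste0("freq_", groups)]), groups),
      cooking = stats::setNames(
        as.numeric(ffq[i, paste0("cook_", cooking_type_names())]),
        cooking_type_names()),
      salt_taste = ffq$salt_taste[i])
    estimate_nutrient_intake(rec, table)
  }, numeric(60)))
  data.frame(subject_id = ffq$subject_id, out,
             check.names = FALSE, row.names = NULL)
}

#' Default assignment of the 55 behavior items to the 7 scales
#'
#' The published item-to-scale assignment lives in supplementary material
#' not reproduced here, so the default map splits the 55 items as evenly
#' as possible (8,8,8,8,8,8,7) over the seven categories; any alternative
#' map of the same shape can be supplied to [score_eating_behavior()].
#'
#' @return factor of length 55 with the category of each item.
#' @export
behavior_scale_map <- function() {
  cats <- c("weight_recognition", "external_eating", "emotional_eating",
            "sense_of_hunger", "eating_style", "food_preference",
            "eating_regularity")
  f <- factor(rep(cats, times = c(8, 8, 8, 8, 8, 8, 7)), levels = cats)
  names(f) <- sprintf("q%02d", 1:55)
  f
}

#' Score the eating-behavior questionnaire
#'
#' Each of the 55 items is answered on a four-point scale (1 seldom ...
#' 4 very often); each category score is the sum of its items, plus a
#' grand total. Missing items are an error (no imputation).
#'
#' @param responses named integer vector (`q01` ... `q55`), values 1-4.
#' @param scale_map factor mapping items to categories
#'   (default [behavior_scale_map()]).
#' @return named numeric vector: one sum per category plus `total`.
#' @export
score_eating_behavior <- function(responses, scale_map = behavior_scale_map()) {
  items <- names(scale_map)
  missing <- setdiff(items, names(responses))
  if (length(missing))
    stop("missing behavior item(s): ", paste(missing, collapse = ", "))
  r <- responses[items]
  if (any(is.na(r)))
    stop("missing behavior item(s): ",
         paste(items[is.na(r)], collapse = ", "))
  if (any(!r %in% 1:4)) stop("responses must be integers in 1..4")
  sums <- tapply(as.numeric(r), scale_map, sum)
  c(sums, total = sum(r))
}

#' Fill derived body-composition indices
#'
#' BMI = weight/height^2, body fat percent = 100 fat/weight,
#' FFMI = fat-free mass/height^2, FMI = fat mass/height^2 (so
#' FFMI + FMI = BMI). Weight in kg, height in m.
#'
#' @param raw list or one-row data.frame with `weight`, `height`,
#'   `fat_mass` and optionally `fat_free_mass` (defaults to
#'   weight - fat_mass) and `muscle_mass`.
#' @return list with the raw fields plus `bmi`, `fat_pct`, `ffmi`, `fmi`.
#' @export
compute_body_indices <- function(raw) {
  w <- raw$weight; h <- raw$height; fm <- raw$fat_mass
  if (any(h <= 0) || any(w <= 0)) stop("height and weight must be > 0")
  if (any(fm < 0) || any(fm > w)) stop("fat mass must be in [0, weight]")
  ffm <- if (is.null(raw$fat_free_mass)) w - fm else raw$fat_free_mass
  if (any(abs(fm + ffm - w) > 1e-9))
    stop("fat_mass + fat_free_mass must equal weight")
  list(weight = w, height = h, fat_mass = fm, fat_free_mass = ffm,
       muscle_mass = raw$muscle_mass,
       bmi = w / h^2, fat_pct = 100 * fm / w,
       ffmi = ffm / h^2, fmi = fm / h^2)
}
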