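test_that("intake follows portion x category weight x weekly frequency / 7 x density", {
  tab <- tiny_table(energy_density = 0.5, portion = 100)
  rec <- record_for(tab, frequency = 14, amount = "Plenty")
  prof <- estimate_nutrient_intake(rec, tab)
  expect_equal(prof[["energy_kcal"]], 100 * 1.5 * 2 * 0.5)

  # zero frequency zeroes every intake
  rec0 <- record_for(tab, frequency = 0)
  prof0 <- estimate_nutrient_intake(rec0, tab)
  expect_true(all(prof0[nutrient_names()] == 0))

  # "No" amount category behaves like zero frequency
  recno <- record_for(tab, frequency = 5, amount = "No")
  expect_true(all(estimate_nutrient_intake(recno, tab)[nutrient_names()] == 0))
})

test_that("oil ratios are class totals over the oil sum", {
  tab <- rbind(tiny_table(), tiny_table())
  tab$food_group <- c("fatty_meat", "salad_oil")
  tab$portion_g <- 10
  tab$lipid_g <- c(0.3, 0.1)
  tab$animal_oil_g <- c(0.3, 0)
  tab$vegetable_oil_g <- c(0, 0.1)
  rec <- record_for(tab, frequency = 7, amount = "Normal")
  prof <- estimate_nutrient_intake(rec, tab)
  # 3 g/day animal, 1 g/day vegetable, 0 fish
  expect_equal(prof[["animal_oil_ratio"]], 0.75)
  expect_equal(prof[["vegetable_oil_ratio"]], 0.25)
  expect_equal(prof[["fish_oil_ratio"]], 0)
})

test_that("salt adjustment uses the household-taste multipliers", {
  expect_equal(adjust_salt(5, "saltier"), 6.5)
  expect_equal(adjust_salt(4, "equal"), 4.6)
  expect_equal(adjust_salt(3, "lighter"), 3)
  expect_equal(adjust_salt(0, "saltier"), 0)
  expect_error(adjust_salt(1, "bland"), "unknown")
  expect_error(adjust_salt(-1, "equal"), ">= 0")

  tab <- tiny_table()
  tab$salt_g <- 0.01
  tab$sodium_mg <- 0.01 * 1000 / 2.54
  base <- estimate_nutrient_intake(record_for(tab, 7), tab)
  salty <- estimate_nutrient_intake(
    record_for(tab, 7, salt_taste = "saltier"), tab)
  expect_equal(salty[["salt_g"]], base[["salt_g"]] * 1.3)
  expect_equal(salty[["sodium_mg"]], base[["sodium_mg"]] * 1.3)
})

test_that("unknown groups and invalid frequencies are rejected", {
  tab <- tiny_table()
  rec <- record_for(tab, 3)
  names(rec$frequency)[1] <- names(rec$amount)[1] <- "mystery_food"
  expect_error(estimate_nutrient_intake(rec, tab), "mystery_food")
  rec2 <- record_for(tab, -1)
  expect_error(estimate_nutrient_intake(rec2, tab), ">= 0")
})

test_that("intakes are linear in frequency and monotone in amount category", {
  tab <- synthetic_food_composition()
  rec <- random_record(11)
  prof1 <- estimate_nutrient_intake(rec, tab)
  rec2 <- rec
  rec2$frequency <- rec$frequency * 2
  rec2$cooking <- rec$cooking * 2
  prof2 <- estimate_nutrient_intake(rec2, tab)

  mass_fields <- c(nutrimorph:::direct_nutrient_names(),
                   "fiber_total_g", "beta_carotene_eq_ug",
                   "retinol_eq_ug", "tocopherol_eq_mg")
  share_fields <- setdiff(nutrient_names(), mass_fields)
  expect_equal(prof2[mass_fields], 2 * prof1[mass_fields])
  expect_equal(prof2[share_fields], prof1[share_fields])
  expect_equal(prof2[ratio_names()], prof1[ratio_names()])

  # raising one group's amount never decreases any mass intake
  rec3 <- rec
  rec3$amount[] <- "A little"
  prof_lo <- estimate_nutrient_intake(rec3, tab)
  for (g in c("fish", "snacks", "green_yellow_vegetables")) {
    rec_hi <- rec3
    rec_hi$amount[g] <- "Plenty"
    prof_hi <- estimate_nutrient_intake(rec_hi, tab)
    expect_true(all(prof_hi[mass_fields] >= prof_lo[mass_fields] - 1e-12))
  }
})

test_that("estimator matches an independent per-food-group loop oracle", {
  tab <- synthetic_food_composition()
  w <- c("No" = 0, "A little" = 0.5, "Normal" = 1, "Plenty" = 1.5)
  for (seed in 1:3) {
    rec <- random_record(seed)
    oracle <- setNames(numeric(43), nutrimorph:::direct_nutrient_names())
    for (g in names(rec$frequency)) {
      row <- tab[tab$food_group == g, ]
      grams <- row$portion_g * w[[rec$amount[[g]]]] * rec$frequency[[g]] / 7
      oracle <- oracle + grams *
        unlist(row[nutrimorph:::direct_nutrient_names()])
    }
    for (ck in names(rec$cooking)) {
      row <- tab[tab$food_group == paste0("cook_", ck), ]
      grams <- row$portion_g * rec$cooking[[ck]] / 7
      oracle <- oracle + grams *
        unlist(row[nutrimorph:::direct_nutrient_names()])
    }
    mult <- c(lighter = 1, equal = 1.15, saltier = 1.3)[[rec$salt_taste]]
    oracle["salt_g"] <- oracle["salt_g"] * mult
    oracle["sodium_mg"] <- oracle["sodium_mg"] * mult
    prof <- estimate_nutrient_intake(rec, tab)
    expect_equal(prof[names(oracle)], oracle, tolerance = 1e-10)
  }
})

test_that("behavior scales sum their items and reject missing answers", {
  map <- behavior_scale_map()
  counts <- table(map)
  all1 <- setNames(rep(1L, 55), names(map))
  s1 <- score_eating_behavior(all1)
  expect_equal(unname(s1[names(counts)]), as.numeric(counts))
  all4 <- setNames(rep(4L, 55), names(map))
  s4 <- score_eating_behavior(all4)
  expect_equal(unname(s4[names(counts)]), 4 * as.numeric(counts))
  expect_equal(s4[["total"]], 220)

  # an 8-item scale answered 2,3,2,3,... sums to 20
  resp <- all1
  items8 <- names(map)[map == levels(map)[1]][1:8]
  resp[items8] <- rep(c(2L, 3L), 4)
  expect_equal(score_eating_behavior(resp)[[levels(map)[1]]], 20)

  dropped <- all1[-c(3, 17)]
  expect_error(score_eating_behavior(dropped), "q03")
  expect_error(score_eating_behavior(dropped), "q17")
  bad <- all1; bad["q01"] <- 5L
  expect_error(score_eating_behavior(bad), "1..4")
})

test_that("body indices satisfy their defining identities", {
  b <- compute_body_indices(list(weight = 50, height = 1.6, fat_mass = 10,
                                 muscle_mass = 22))
  expect_equal(b$bmi, 50 / 1.6^2)          # 19.531 kg/m^2
  expect_equal(round(b$bmi, 3), 19.531)
  expect_equal(b$fmi, 10 / 1.6^2)
  expect_equal(b$ffmi, 40 / 1.6^2)
  expect_equal(b$fmi + b$ffmi, b$bmi, tolerance = 1e-12)
  expect_equal(b$fat_pct, 20)

  lean <- compute_body_indices(list(weight = 48, height = 1.55, fat_mass = 0))
  expect_equal(lean$fat_pct, 0)
  expect_equal(lean$fmi, 0)

  expect_error(compute_body_indices(list(weight = 0, height = 1.6,
                                         fat_mass = 0)), "> 0")
  expect_error(compute_body_indices(list(weight = 50, height = 1.6,
                                         fat_mass = 10,
                                         fat_free_mass = 35)),
               "must equal weight")
})
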