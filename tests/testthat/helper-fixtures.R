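# Shared fixtures: small configurations and transform helpers.

# random rotation matrix with det +1
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(config, R = random_rotation(),
                        t = rnorm(3, 0, 20), s = 1) {
  out <- s * as.matrix(config) %*% R
  out <- sweep(out, 2, t, "+")
  rownames(out) <- rownames(config)
  out
}

# four-point, non-coplanar toy configurations sharing one landmark set
toy_quads <- function() {
  lab <- c("a", "b", "c", "d")
  mk <- function(m) {
    rownames(m) <- lab
    colnames(m) <- c("x", "y", "z")
    m
  }
  list(
    q1 = mk(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 1))),
    q2 = mk(rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(-0.1, 0.9, 0.1),
                  c(0.3, 0.2, 1.1))),
    q3 = mk(rbind(c(0, 0, 0), c(0.9, -0.1, 0.1), c(0.1, 1.1, -0.1),
                  c(0.1, 0.4, 0.9))))
}

# minimal one-row composition table: portion 100 g, a single non-zero
# energy density, everything else zero
tiny_table <- function(energy_density = 0.5, portion = 100) {
  d <- data.frame(food_group = "only", portion_g = portion,
                  is_cooking = FALSE, is_grain = FALSE,
                  is_vegetable = FALSE, is_deep_yellow = FALSE,
                  is_animal = FALSE, animal_oil_g = 0,
                  vegetable_oil_g = 0, fish_oil_g = 0)
  for (nm in nutrimorph:::direct_nutrient_names()) d[[nm]] <- 0
  d$energy_kcal <- energy_density
  d
}

record_for <- function(table, frequency, amount = "Normal",
                       cooking = NULL, salt_taste = "lighter") {
  groups <- table$food_group[!table$is_cooking]
  list(amount = setNames(rep(amount, length.out = length(groups)), groups),
       frequency = setNames(rep(frequency, length.out = length(groups)),
                            groups),
       cooking = cooking, salt_taste = salt_taste)
}

# a complete random FFQ record on the bundled synthetic table
random_record <- function(seed = 1) {
  set.seed(seed)
  g <- food_group_names()
  list(amount = setNames(sample(c("No", "A little", "Normal", "Plenty"),
                                length(g), replace = TRUE), g),
       frequency = setNames(rpois(length(g), 4), g),
       cooking = setNames(rpois(length(cooking_type_names()), 2),
                          cooking_type_names()),
       salt_taste = sample(c("lighter", "equal", "saltier"), 1))
}
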