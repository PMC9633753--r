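test_that("centroid size: hand value, translation invariance, homogeneity", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(sweep(sq, 2, c(5, -3, 2), "+")),
               centroid_size(sq))
  expect_equal(centroid_size(2 * sq), 2 * centroid_size(sq))
  expect_error(centroid_size(sq[1, , drop = FALSE]), "at least 2")
})

test_that("pose normalization anchors the nasion and is rigid-invariant", {
  tmpl <- face_template(60)
  posed <- pose_normalize(tmpl)
  expect_equal(unname(posed["N", ]), c(0, 0, 0))

  set.seed(42)
  for (i in 1:5) {
    moved <- apply_rigid(tmpl)
    expect_equal(pose_normalize(moved), posed, tolerance = 1e-8)
  }
  # idempotence
  expect_equal(pose_normalize(posed), posed, tolerance = 1e-8)

  # right-handed frame: subnasale below nasion, right exocanthion at x > 0
  expect_lt(posed["Sn", "z"], 0)
  expect_gt(posed["Ex.R", "x"], 0)

  broken <- tmpl[setdiff(rownames(tmpl), "Po.L"), ]
  expect_error(pose_normalize(broken), "Po.L")
})

test_that("GPA handles single configurations and similarity-equivalent pairs", {
  quads <- toy_quads()
  g1 <- gpa(quads[1])
  c0 <- sweep(quads$q1, 2, colMeans(quads$q1), "-")
  expect_equal(as.numeric(g1$shapes[1, ]),
               nutrimorph:::flatten_config(c0 / sqrt(sum(c0^2))))
  expect_equal(as.numeric(g1$mean_shape), as.numeric(g1$shapes[1, ]))

  set.seed(7)
  moved <- apply_rigid(quads$q1, s = 2.7)
  g2 <- gpa(list(a = quads$q1, b = moved))
  expect_lt(sqrt(sum((g2$shapes[1, ] - g2$shapes[2, ])^2)), 1e-10)
})

test_that("GPA mean matches an independent vegan-based iterative oracle", {
  skip_if_not_installed("vegan")
  quads <- toy_quads()
  fit <- gpa(quads)

  # oracle: center/unit-scale, then alternate vegan rotations and
  # mean updates until the mean stabilizes
  unit <- lapply(quads, function(m) {
    c0 <- sweep(m, 2, colMeans(m), "-")
    c0 / sqrt(sum(c0^2))
  })
  mref <- unit[[1]]
  for (it in 1:200) {
    rot <- lapply(unit, function(m)
      vegan::procrustes(mref, m, scale = FALSE)$Yrot)
    newm <- Reduce(`+`, rot) / length(rot)
    newm <- newm / sqrt(sum(newm^2))
    if (sqrt(mean((newm - mref)^2)) < 1e-14) { mref <- newm; break }
    mref <- newm
  }
  # compare up to a final rotation
  aligned_oracle <- vegan::procrustes(
    nutrimorph:::unflatten_config(fit$mean_shape), mref,
    scale = FALSE)$Yrot
  expect_equal(as.numeric(nutrimorph:::flatten_config(aligned_oracle)),
               as.numeric(fit$mean_shape), tolerance = 1e-8)
})

test_that("GPA output is invariant to per-configuration similarity transforms", {
  spec <- cohort_spec(n_subjects = 20, seed = 5)
  coh <- generate_cohort(spec, streams = "shape")
  base <- gpa(coh$configurations)
  set.seed(99)
  jittered <- lapply(coh$configurations, function(m)
    apply_rigid(m, s = runif(1, 0.5, 2)))
  moved <- gpa(jittered)
  # compare after rotating one consensus onto the other
  R <- nutrimorph:::optimal_rotation(
    nutrimorph:::unflatten_config(moved$mean_shape),
    nutrimorph:::unflatten_config(base$mean_shape))
  rot_shapes <- t(apply(moved$shapes, 1, function(v)
    nutrimorph:::flatten_config(nutrimorph:::unflatten_config(v) %*% R)))
  expect_lt(max(abs(rot_shapes - base$shapes)), 1e-8)
  expect_equal(unname(moved$centroid_sizes / base$centroid_sizes),
               vapply(seq_along(jittered), function(i)
                 centroid_size(jittered[[i]]) /
                   centroid_size(coh$configurations[[i]]), numeric(1)),
               tolerance = 1e-10)
})

test_that("component retention follows the Kaiser/90% rule", {
  # Kaiser keeps 4 (> 1); cumulative share at 4 is 87% < 90% -> k = 4
  ev1 <- c(4, 2, 1.5, 1.2, 0.6, 0.4, 0.3)
  ev1 <- c(ev1, 10 - sum(ev1))  # pad to total 10
  ev1 <- sort(ev1, decreasing = TRUE)
  expect_equal(retained_components(ev1, kaiser_threshold = 1), 4L)

  # Kaiser keeps 3; cumulative reaches 91% at 3 -> k = 3
  ev2 <- c(6, 2, 1.1, 0.5, 0.4)
  expect_equal(retained_components(ev2, kaiser_threshold = 1), 3L)
})

test_that("shape space: rank identity, reconstruction, trace conservation", {
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(5 * 2), 5)))
  x <- matrix(rnorm(40 * 2), 40) %*% t(basis)
  sp <- fit_shape_space(x, mode = "covariance")
  expect_equal(sum(sp$eigenvalues > 1e-10 * sp$eigenvalues[1]), 2)
  sc <- shape_scores(sp, x, k = 2)
  recon <- t(apply(sc, 1, function(s) shape_reconstruct(sp, s)))
  expect_equal(recon, x, tolerance = 1e-8, ignore_attr = TRUE)

  y <- matrix(rnorm(30 * 6), 30)
  spy <- fit_shape_space(y, mode = "covariance")
  expect_equal(sum(spy$eigenvalues), sum(apply(y, 2, var)),
               tolerance = 1e-8)
  expect_true(all(diff(spy$eigenvalues) <= 1e-12))
  ortho <- crossprod(spy$eigenvectors)
  expect_equal(ortho, diag(ncol(y)), tolerance = 1e-8)

  yc <- cbind(y, const = 1)
  expect_error(fit_shape_space(yc, mode = "correlation"), "constant")
})

test_that("inter-landmark panel is scale-invariant with correct raw distances", {
  tmpl <- face_template(60)
  pan <- interlandmark_panel(tmpl)
  expect_length(pan, 16)
  expect_equal(interlandmark_panel(2 * tmpl), pan, tolerance = 1e-10)

  exex <- sqrt(sum((tmpl["Ex.R", ] - tmpl["Ex.L", ])^2))
  zyzy_raw <- pan[["ZyZy"]] * exex
  expect_equal(zyzy_raw, sqrt(sum((tmpl["Zy.R", ] - tmpl["Zy.L", ])^2)))
  # template Zy at (+/-65, -45, -25): width 130 mm
  expect_equal(zyzy_raw, 130)

  # mirror reflection with swapped sides leaves the panel unchanged
  mir <- tmpl
  mir[, 1] <- -mir[, 1]
  swap <- rownames(mir)
  swap <- ifelse(endsWith(swap, ".L"), sub("\\.L$", ".R", swap),
                 ifelse(endsWith(swap, ".R"), sub("\\.R$", ".L", swap), swap))
  rownames(mir) <- swap
  expect_equal(interlandmark_panel(mir)[names(pan)], pan,
               tolerance = 1e-10)

  expect_error(interlandmark_panel(tmpl[-match("Gn", rownames(tmpl)), ]),
               "Gn")
})

test_that("accentuation interpolates and extrapolates from the grand mean", {
  grand <- c(0, 1, 2)
  group <- c(1, 1, 4)
  expect_equal(accentuate_mean(group, grand, 0), grand)
  expect_equal(accentuate_mean(group, grand, 1), group)
  expect_equal(accentuate_mean(group, grand, 5), grand + 5 * (group - grand))
  expect_error(accentuate_mean(group, grand[1:2], 5), "equal length")
})
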