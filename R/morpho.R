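#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks from
#' their centroid; the size measure separated from shape by Procrustes
#' superimposition.
#'
#' @param config p x 3 landmark matrix (mm).
#' @return centroid size (mm).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2) stop("centroid size needs at least 2 landmarks")
  centred <- sweep(config, 2, colMeans(config), "-")
  sqrt(sum(centred^2))
}

#' Normalize a configuration into the anatomical coordinate frame
#'
#' The nasion is translated to the origin. The lateral (x) axis is the
#' mean right-minus-left direction of the exocanthions and endocanthions,
#' so the least-squares symmetry plane of those landmarks maps to x = 0;
#' the vertical (z) axis is the normal of the least-squares plane through
#' the exocanthions, porions and subnasale (orthogonalized against x and
#' signed so the subnasale lies below the nasion); y completes a
#' right-handed frame (anterior positive). The result is invariant to
#' rigid motions of the input.
#'
#' @param config p x 3 landmark matrix with the anchor labels
#'   `N`, `Ex.L/R`, `En.L/R`, `Po.L/R`, `Sn` in its rownames.
#' @return the re-posed p x 3 matrix.
#' @export
pose_normalize <- function(config) {
  config <- as.matrix(config)
  need <- c("N", "Ex.L", "Ex.R", "En.L", "En.R", "Po.L", "Po.R", "Sn")
  missing <- setdiff(need, rownames(config))
  if (length(missing))
    stop("missing anchor landmark(s): ", paste(missing, collapse = ", "))
  P <- sweep(config, 2, config["N", ], "-")

  xdir <- (P["Ex.R", ] - P["Ex.L", ]) + (P["En.R", ] - P["En.L", ])
  nx <- sqrt(sum(xdir^2))
  if (nx < 1e-8) stop("degenerate anchors: zero lateral direction")
  xdir <- xdir / nx

  axial <- P[c("Ex.L", "Ex.R", "Po.L", "Po.R", "Sn"), ]
  ac <- sweep(axial, 2, colMeans(axial), "-")
  ev <- eigen(crossprod(ac), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1))
    stop("degenerate anchors: axial-plane landmarks are collinear")
  zdir <- ev$vectors[, 3]
  zdir <- zdir - sum(zdir * xdir) * xdir
  nz <- sqrt(sum(zdir^2))
  if (nz < 1e-8) stop("degenerate anchors: axial normal parallel to x axis")
  zdir <- zdir / nz
  if (sum((P["Sn", ]) * zdir) > 0) zdir <- -zdir  # subnasale below nasion
  ydir <- c(zdir[2] * xdir[3] - zdir[3] * xdir[2],
            zdir[3] * xdir[1] - zdir[1] * xdir[3],
            zdir[1] * xdir[2] - zdir[2] * xdir[1])
  R <- cbind(xdir, ydir, zdir)
  out <- P %*% R
  rownames(out) <- rownames(config)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Optimal rotation of one configuration onto another (no reflection)
#'
#' Kabsch solution with the determinant forced positive: anatomical
#' configurations are never mirrored. If the unconstrained optimum is a
#' reflection this is reported via a "reflection" attribute.
#'
#' @param from,onto centred p x 3 matrices.
#' @return 3 x 3 rotation matrix (det +1).
#' @keywords internal
optimal_rotation <- function(from, onto) {
  s <- svd(crossprod(from, onto))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  attr(R, "reflection") <- d < 0
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition: each configuration is centred and scaled to
#' unit centroid size, rotated to the current mean shape, and the mean is
#' re-estimated (and itself rescaled to unit size) until its root mean
#' square change falls below `tol`. Rotations never reflect; if any
#' configuration would prefer a reflected fit this is reported, not
#' silently applied.
#'
#' @param configs named list of p x 3 landmark matrices sharing one
#'   landmark set.
#' @param tol convergence tolerance on the mean shape (default 1e-10).
#' @param max_iter iteration cap (default 100).
#' @return list with `shapes` (n x 3p matrix of aligned unit-size shape
#'   vectors), `mean_shape` (3p vector), `centroid_sizes` (mm),
#'   `iterations`, and `labels`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100) {
  if (length(configs) < 1) stop("need at least one configuration")
  labels <- rownames(configs[[1]])
  p <- nrow(configs[[1]])
  same <- vapply(configs, function(m)
    nrow(m) == p && identical(rownames(m), labels), logical(1))
  if (!all(same)) stop("configurations must share one landmark set")

  cs <- vapply(configs, centroid_size, numeric(1))
  unit <- lapply(configs, function(m) {
    c0 <- sweep(as.matrix(m), 2, colMeans(m), "-")
    c0 / sqrt(sum(c0^2))
  })

  mean_m <- unit[[1]]
  reflected <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    aligned <- lapply(unit, function(m) {
      R <- optimal_rotation(m, mean_m)
      if (isTRUE(attr(R, "reflection"))) reflected <<- TRUE
      m %*% R
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_m)^2))
    mean_m <- new_mean
    if (delta < tol || iter >= max_iter) break
  }
  if (reflected)
    warning("a configuration preferred a reflected fit; ",
            "rotation was constrained to det +1")

  shapes <- t(vapply(aligned, flatten_config, numeric(3 * p)))
  rownames(shapes) <- names(configs)
  list(shapes = shapes, mean_shape = flatten_config(mean_m),
       centroid_sizes = cs, iterations = iter, labels = labels)
}

#' Component retention: Kaiser criterion capped by 90% cumulative share
#'
#' Keeps k = min(Kaiser count, smallest k whose cumulative variance share
#' reaches the cutoff): when the Kaiser set already explains more than
#' the cutoff, the cutoff decides. The Kaiser threshold is 1 for
#' correlation-matrix eigenvalues and the mean eigenvalue for
#' covariance-matrix eigenvalues.
#'
#' @param eigenvalues non-increasing, non-negative.
#' @param kaiser_threshold eigenvalue threshold (default mean eigenvalue).
#' @param cum_cutoff cumulative-share cutoff (default 0.9).
#' @return integer k >= 1.
#' @export
retained_components <- function(eigenvalues,
                                kaiser_threshold = mean(eigenvalues),
                                cum_cutoff = 0.9) {
  ev <- eigenvalues[eigenvalues > .Machine$double.eps * max(eigenvalues)]
  kaiser <- sum(eigenvalues > kaiser_threshold)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  k90 <- which(cum >= cum_cutoff)[1]
  max(1L, min(max(kaiser, 1L), k90, length(ev)))
}

#' Fit a principal-component shape (or nutrition) space
#'
#' Eigen-decomposition of the covariance or correlation matrix of the
#' input observations, with the retention rule of
#' [retained_components()]. In correlation mode the Kaiser threshold is
#' the literal eigenvalue > 1; in covariance mode (the default for
#' Procrustes coordinates, whose scale is arbitrary) it is the mean
#' eigenvalue.
#'
#' @param x n x p matrix of observations (rows = subjects).
#' @param mode "covariance" or "correlation".
#' @param cum_cutoff cumulative-share cutoff (default 0.9).
#' @return object of class `shape_space`: list with `mean`, `center`,
#'   `scale`, `eigenvalues`, `eigenvectors` (orthonormal columns),
#'   `k` (retained), `mode`.
#' @export
fit_shape_space <- function(x, mode = c("covariance", "correlation"),
                            cum_cutoff = 0.9) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations")
  ctr <- colMeans(x)
  scl <- rep(1, ncol(x))
  if (mode == "correlation") {
    scl <- apply(x, 2, stats::sd)
    if (any(scl < .Machine$double.eps))
      stop("constant column(s) in correlation mode: ",
           paste(colnames(x)[scl < .Machine$double.eps], collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  cv <- crossprod(xs) / (nrow(x) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  thr <- if (mode == "correlation") 1 else mean(vals)
  k <- retained_components(vals, kaiser_threshold = thr,
                           cum_cutoff = cum_cutoff)
  structure(list(mean = ctr, center = ctr, scale = scl,
                 eigenvalues = vals, eigenvectors = ev$vectors,
                 k = k, mode = mode),
            class = "shape_space")
}

#' Project observations onto the retained components of a shape space
#'
#' @param space a `shape_space`.
#' @param x n x p matrix in the space's original variables.
#' @param k number of components (default the retained k).
#' @return n x k score matrix.
#' @export
shape_scores <- function(space, x, k = space$k) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, space$center, "-"), 2, space$scale, "/")
  sc <- xs %*% space$eigenvectors[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' Reconstruct an observation from component scores
#'
#' @param space a `shape_space`.
#' @param scores numeric vector of length k (or fewer).
#' @return vector in the original variable space.
#' @export
shape_reconstruct <- function(space, scores) {
  k <- length(scores)
  v <- as.numeric(space$eigenvectors[, seq_len(k), drop = FALSE] %*% scores)
  v * space$scale + space$center
}

#' Inter-landmark distance panel (16 unique variables)
#'
#' Twelve linear distances normalized to the exocanthion width |Ex-Ex|
#' (bilateral widths |Ac-Ac|, |Zy-Zy|, |Ch-Ch|, |Go-Go|; nasion distances
#' |N-En|, |N-Sn|, |N-Zy|, |N-Prn|, |N-Ls|; |Sto-Gn|, |Ls-Li|, |Ps-Pi|)
#' and four shape ratios (|Go-Go|/|Zy-Zy|, |Gla-Sn|/|Sn-Gn|,
#' |N-Gn|/|Zy-Zy|, |Gla-Ls|/|Zy-Zy|). Distances to a bilateral landmark
#' use the mean of the left and right distances. The published list of 17
#' contains a typographic duplicate; the 16 unique variables are
#' implemented.
#'
#' @param config p x 3 landmark matrix with the panel labels present.
#' @return named numeric vector of length 16 (scale-free).
#' @export
interlandmark_panel <- function(config) {
  config <- as.matrix(config)
  lab <- rownames(config)
  need <- c("N", "Gla", "Prn", "Sn", "Ls", "Sto", "Li", "Gn",
            paste0(rep(c("Ex", "En", "Ps", "Pi", "Zy", "Ac", "Ch", "Go"),
                       each = 2), c(".L", ".R")))
  missing <- setdiff(need, lab)
  if (length(missing))
    stop("missing panel landmark(s): ", paste(missing, collapse = ", "))
  d <- function(a, b) sqrt(sum((config[a, ] - config[b, ])^2))
  bilat <- function(nm) d(paste0(nm, ".L"), paste0(nm, ".R"))
  to_pair <- function(a, nm)
    (d(a, paste0(nm, ".L")) + d(a, paste0(nm, ".R"))) / 2
  exex <- bilat("Ex")
  if (exex < 1e-12) stop("zero exocanthion distance")
  lin <- c(
    AcAc = bilat("Ac"), ZyZy = bilat("Zy"), ChCh = bilat("Ch"),
    GoGo = bilat("Go"),
    NEn = to_pair("N", "En"), NSn = d("N", "Sn"), NZy = to_pair("N", "Zy"),
    NPrn = d("N", "Prn"), NLs = d("N", "Ls"), StoGn = d("Sto", "Gn"),
    LsLi = d("Ls", "Li"),
    PsPi = (d("Ps.L", "Pi.L") + d("Ps.R", "Pi.R")) / 2)
  ratios <- c(
    GoGo_ZyZy = bilat("Go") / bilat("Zy"),
    GlaSn_SnGn = d("Gla", "Sn") / d("Sn", "Gn"),
    NGn_ZyZy = d("N", "Gn") / bilat("Zy"),
    GlaLs_ZyZy = d("Gla", "Ls") / bilat("Zy"))
  c(lin / exex, ratios)
}

#' Accentuate a group mean away from the grand mean
#'
#' grand + weight x (group - grand): weight 0 returns the grand mean,
#' 1 the group mean, and larger weights exaggerate the group's
#' distinctive features for visualization (the conventional weight is 5).
#'
#' @param group_mean,grand_mean shape vectors of equal length.
#' @param weight non-negative scalar (default 5).
#' @return shape vector.
#' @export
accentuate_mean <- function(group_mean, grand_mean, weight = 5) {
  if (length(group_mean) != length(grand_mean))
    stop("shape vectors must have equal length")
  if (weight < 0) stop("weight must be >= 0")
  grand_mean + weight * (group_mean - grand_mean)
}
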