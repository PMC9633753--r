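#' Anatomical landmark labels required by the pose and panel operations
#'
#' Midline points carry bare labels; bilateral points are suffixed
#' `.L` / `.R`. Units are millimetres throughout.
#' @keywords internal
anatomical_labels <- function() {
  c("N", "Gla", "Prn", "Sn", "Ls", "Sto", "Li", "Gn",
    paste0(rep(c("Ex", "En", "Ps", "Pi", "Po", "Zy", "Ac", "Ch", "Go"),
               each = 2), c(".L", ".R")))
}

#' Synthetic facial landmark template
#'
#' A stylized adult female facial configuration: 26 named anatomical
#' landmarks (nasion at the origin, x lateral towards the subject's right,
#' y anterior, z superior, mm) plus deterministic surface semi-landmarks
#' placed on the frontal half of an ellipsoid by a golden-angle spiral,
#' bringing the configuration to `n_landmarks` points. The semi-landmarks
#' stand in for the dense mesh vertices of template-fitted face scans and
#' are in point-to-point correspondence across all configurations derived
#' from the template.
#'
#' @param n_landmarks total number of landmarks (>= 26; default 60).
#' @return a `n_landmarks` x 3 numeric matrix with rownames giving labels.
#' @export
face_template <- function(n_landmarks = 60) {
  anat <- rbind(
    N   = c(0, 0, 0),
    Gla = c(0, 3, 12),
    Prn = c(0, 22, -42),
    Sn  = c(0, 12, -55),
    Ls  = c(0, 14, -70),
    Sto = c(0, 11, -78),
    Li  = c(0, 13, -86),
    Gn  = c(0, 8, -115))
  bilat <- list(
    Ex = c(45, -20, -4),
    En = c(17, -15, -3),
    Ps = c(31, -14, 1),
    Pi = c(31, -14, -9),
    Po = c(65, -75, -20),
    Zy = c(65, -45, -25),
    Ac = c(17, 8, -48),
    Ch = c(25, 2, -78),
    Go = c(50, -45, -85))
  for (nm in names(bilat)) {
    p <- bilat[[nm]]
    anat <- rbind(anat,
                  matrix(c(-p[1], p[2], p[3]), 1, dimnames = list(paste0(nm, ".L"))),
                  matrix(p, 1, dimnames = list(paste0(nm, ".R"))))
  }
  n_anat <- nrow(anat)
  if (n_landmarks < n_anat)
    stop("n_landmarks must be >= ", n_anat, " (the named anatomical set)")
  m <- n_landmarks - n_anat
  if (m > 0) {
    i <- seq_len(m)
    zt <- 1 - 2 * (i - 0.5) / m
    r <- sqrt(pmax(0, 1 - zt^2))
    ang <- i * 2.39996322972865332   # golden angle
    centre <- c(0, -20, -45)
    semi <- cbind(centre[1] + 70 * r * cos(ang),
                  centre[2] + 55 * abs(r * sin(ang)),  # frontal half only
                  centre[3] + 85 * zt)
    rownames(semi) <- sprintf("sl%03d", i)
    anat <- rbind(anat, semi)
  }
  colnames(anat) <- c("x", "y", "z")
  anat
}

#' Flatten / unflatten landmark configurations
#'
#' Configurations are stored as p x 3 matrices; shape vectors interleave
#' coordinates per landmark (x1, y1, z1, x2, ...).
#' @param m a p x 3 matrix.
#' @return numeric vector of length 3p.
#' @keywords internal
flatten_config <- function(m) as.vector(t(m))

#' @param v numeric vector of length 3p.
#' @param labels optional landmark labels for rownames.
#' @rdname flatten_config
#' @keywords internal
unflatten_config <- function(v, labels = NULL) {
  m <- matrix(v, ncol = 3, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  if (!is.null(labels)) rownames(m) <- labels
  m
}

#' Orthonormal basis of the similarity directions at the template
#'
#' The 7-dimensional subspace spanned by the translation, uniform
#' scaling and infinitesimal rotation directions of the centred
#' template. Planted shape fields are projected out of this subspace
#' (the Procrustes tangent-space construction) so that superimposition
#' neither absorbs nor mixes them.
#'
#' @param template landmark matrix.
#' @return 3p x 7 matrix with orthonormal columns.
#' @keywords internal
similarity_tangent_space <- function(template) {
  p <- nrow(template)
  tc <- sweep(template, 2, colMeans(template), "-")
  trans <- cbind(rep(c(1, 0, 0), p), rep(c(0, 1, 0), p), rep(c(0, 0, 1), p))
  scaling <- flatten_config(tc)
  gens <- list(
    matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3),   # about x
    matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3, 3),   # about y
    matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 0), 3, 3))   # about z
  rots <- vapply(gens, function(G) flatten_config(tc %*% G),
                 numeric(3 * p))
  B <- cbind(trans, scaling, rots)
  qr.Q(qr(B))[, 1:7, drop = FALSE]
}

#' Masculinity displacement field for the template
#'
#' A deterministic unit-norm shape vector encoding the classic male-female
#' facial contrasts on the template geometry: relatively wider lower face
#' and jaw, more prominent brow and nose, longer chin, narrower eye
#' opening. The field is centered and orthogonalized against uniform
#' scaling of the template so it is a pure shape direction; it serves as
#' the planted male-female axis of synthetic cohorts.
#'
#' @param template landmark matrix from [face_template()].
#' @return unit-norm numeric vector of length 3p.
#' @export
dimorphism_field <- function(template) {
  d <- matrix(0, nrow(template), 3)
  x <- template[, 1]; z <- template[, 3]
  lower <- z < -40
  d[lower, 1] <- 0.6 * sign(x[lower])          # wider jaw / lower face
  d[z > 0, 2] <- d[z > 0, 2] + 0.5             # brow prominence
  d[z < -80, 3] <- d[z < -80, 3] - 0.5         # longer lower face
  lab <- rownames(template)
  d[lab == "Gn", 3] <- d[lab == "Gn", 3] - 1.0
  d[lab == "Prn", 2] <- d[lab == "Prn", 2] + 0.4
  d[startsWith(lab, "Ps."), 3] <- d[startsWith(lab, "Ps."), 3] - 0.3
  d[startsWith(lab, "Pi."), 3] <- d[startsWith(lab, "Pi."), 3] + 0.3
  u <- flatten_config(d)
  B <- similarity_tangent_space(template)
  u <- u - as.numeric(B %*% crossprod(B, u))   # pure shape direction
  u / sqrt(sum(u^2))
}

#' Smooth individual-variation deformation fields
#'
#' A fixed orthonormal basis of spatially smooth displacement fields on
#' the template (sinusoidal waves in fixed directions), centered and
#' orthogonalized against uniform scaling, the masculinity field and each
#' other. Subjects of a synthetic cohort carry independent random
#' coefficients on these fields, emulating the smooth, low-rank
#' between-individual variation of real facial samples (as opposed to
#' white landmark noise, which models measurement error).
#'
#' @param template landmark matrix from [face_template()].
#' @param n_fields number of fields (default 8).
#' @return 3p x n_fields matrix of orthonormal shape vectors.
#' @export
individual_variation_fields <- function(template, n_fields = 8) {
  p <- nrow(template)
  pars <- list(
    list(a = c(1, 0, 0),     k = c(0, 0, 1/60),    phi = 0),
    list(a = c(0, 1, 0),     k = c(0, 0, 1/45),    phi = 1),
    list(a = c(0, 0, 1),     k = c(1/50, 0, 0),    phi = 2),
    list(a = c(1, 0, 0),     k = c(0, 1/40, 1/80), phi = 0.5),
    list(a = c(0, 1, 0),     k = c(1/35, 0, 0),    phi = 1.5),
    list(a = c(0, 0, 1),     k = c(0, 1/30, 1/60), phi = 2.5),
    list(a = c(0.7, 0.7, 0), k = c(1/25, 0, 1/50), phi = 3),
    list(a = c(0, 0.7, 0.7), k = c(1/45, 1/30, 0), phi = 0.8))
  if (n_fields > length(pars))
    stop("at most ", length(pars), " fields are defined")
  u <- dimorphism_field(template)
  basis <- cbind(similarity_tangent_space(template), u)
  fields <- matrix(0, 3 * p, n_fields)
  for (j in seq_len(n_fields)) {
    pr <- pars[[j]]
    w <- sin(as.numeric(template %*% pr$k) + pr$phi)
    d <- outer(w, pr$a)
    v <- flatten_config(d)
    v <- v - basis %*% crossprod(basis, v)   # orthogonalize
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stop("degenerate deformation field ", j)
    v <- as.numeric(v) / nv
    fields[, j] <- v
    basis <- cbind(basis, v)
  }
  fields
}

#' Write landmark configurations as long-format delimited text
#'
#' One row per landmark: `subject_id, label, x, y, z`.
#'
#' @param configs named list of p x 3 landmark matrices.
#' @param path output file path.
#' @export
write_landmarks <- function(configs, path) {
  if (is.null(names(configs)) || anyDuplicated(names(configs)))
    stop("configs must be a uniquely named list")
  rows <- lapply(names(configs), function(id) {
    m <- configs[[id]]
    data.frame(subject_id = id, label = rownames(m),
               x = m[, 1], y = m[, 2], z = m[, 3], row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark configurations written by [write_landmarks()]
#'
#' @param path file path.
#' @return named list of p x 3 landmark matrices.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark file must have columns ", paste(need, collapse = ", "))
  lapply(split(d, factor(d$subject_id, levels = unique(d$subject_id))),
         function(s) {
           m <- as.matrix(s[, c("x", "y", "z")])
           rownames(m) <- s$label
           m
         })
}
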