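#' Construct a male-female dimorphism axis
#'
#' The axis is the male mean shape minus the female mean shape; scores
#' are measured relative to the midpoint of the two means, so the male
#' mean projects to +0.5 and the female mean to -0.5.
#'
#' @param male_mean,female_mean shape vectors of equal length.
#' @return object of class `dimorphism_axis`: list with `male_mean`,
#'   `female_mean`, `axis`, `midpoint`, `axis_norm`.
#' @export
dimorphism_axis <- function(male_mean, female_mean) {
  if (length(male_mean) != length(female_mean))
    stop("male and female means must have equal length")
  axis <- male_mean - female_mean
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("zero-norm dimorphism axis")
  structure(list(male_mean = male_mean, female_mean = female_mean,
                 axis = axis, midpoint = (male_mean + female_mean) / 2,
                 axis_norm = nrm),
            class = "dimorphism_axis")
}

#' Sexual shape dimorphism score of a face
#'
#' Projection of the face onto the male-minus-female axis, normalized by
#' the squared axis length: SShD = ((face - midpoint) . axis) / |axis|^2.
#' Under this midpoint convention the male reference mean scores +0.5 and
#' the female mean -0.5; by the conventional reading, scores beyond
#' -1 / +1 are called hyperfeminine / hypermasculine.
#'
#' @param face shape vector (or n x 3p matrix of shape vectors).
#' @param axis a [dimorphism_axis()].
#' @return scalar (or vector of) SShD score(s).
#' @export
compute_sshd <- function(face, axis) {
  if (!inherits(axis, "dimorphism_axis")) stop("axis must be a dimorphism_axis")
  if (is.matrix(face)) {
    if (ncol(face) != length(axis$axis)) stop("dimension mismatch")
    return(as.numeric(sweep(face, 2, axis$midpoint, "-") %*% axis$axis) /
             axis$axis_norm^2)
  }
  if (length(face) != length(axis$axis)) stop("dimension mismatch")
  sum((face - axis$midpoint) * axis$axis) / axis$axis_norm^2
}

#' Decompose SShD scores into allometric and non-allometric parts
#'
#' Shape vectors are regressed on centroid size (multivariate linear
#' regression). The allometric score of a subject is the projection of
#' the size-predicted shape deviation b (CS_i - mean CS) onto the axis;
#' the non-allometric score is the remainder, so the two sum exactly to
#' the total score. With a zero fitted slope all allometric scores are 0.
#'
#' @param shapes n x 3p matrix of aligned shape vectors.
#' @param sizes length-n centroid sizes (must vary).
#' @param axis a [dimorphism_axis()].
#' @return data.frame: `subject_id`, `sshd_total`, `sshd_allometric`,
#'   `sshd_nonallometric`, `centroid_size`.
#' @export
decompose_sshd <- function(shapes, sizes, axis) {
  shapes <- as.matrix(shapes)
  if (nrow(shapes) != length(sizes))
    stop("shapes and sizes must have equal length")
  if (stats::sd(sizes) < 1e-12)
    stop("centroid size is constant across subjects")
  cs_c <- sizes - mean(sizes)
  # multivariate regression slope of shape on CS: b = X'y / y'y per column
  b <- as.numeric(crossprod(shapes, cs_c)) / sum(cs_c^2)
  total <- compute_sshd(shapes, axis)
  slope_proj <- sum(b * axis$axis) / axis$axis_norm^2
  allometric <- slope_proj * cs_c
  data.frame(
    subject_id = if (!is.null(rownames(shapes))) rownames(shapes)
                 else as.character(seq_len(nrow(shapes))),
    sshd_total = total,
    sshd_allometric = allometric,
    sshd_nonallometric = total - allometric,
    centroid_size = sizes,
    row.names = NULL)
}

#' Rigidly fit a configuration into an existing shape space
#'
#' Centres and unit-scales a configuration, then rotates it onto a
#' reference mean shape (no reflection). Used to carry externally
#' supplied male/female reference means into the coordinate frame of a
#' cohort's Procrustes alignment before building the dimorphism axis.
#'
#' @param config p x 3 landmark matrix.
#' @param mean_shape 3p reference shape vector.
#' @return 3p shape vector aligned to the reference.
#' @export
align_to_mean <- function(config, mean_shape) {
  m <- as.matrix(config)
  m <- sweep(m, 2, colMeans(m), "-")
  m <- m / sqrt(sum(m^2))
  ref <- unflatten_config(mean_shape)
  R <- optimal_rotation(m, ref)
  flatten_config(m %*% R)
}
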