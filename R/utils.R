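#' Derive a sub-stream seed from a global seed
#'
#' Each randomised stage of the pipeline draws from its own sub-stream so
#' that adding a stream never perturbs earlier ones. The derived seed is
#' kept inside the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param offset integer stream index (>= 0).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 104729 * offset) %% 2147483587)
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' library functions never disturb user-level reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects;
#' 1 means identical partitions, ~0 means chance-level agreement.
#'
#' @param a,b vectors of cluster labels (equal length).
#' @return a scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maximum <- (sum_i + sum_j) / 2
  if (abs(maximum - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Column-standardize a matrix to z-scores
#'
#' @param x numeric matrix.
#' @return matrix of the same shape, columns centered and scaled; columns
#'   with zero variance are centered only (left at zero) with a warning.
#' @keywords internal
zstandardize <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv < .Machine$double.eps
  if (any(zero)) {
    warning("zero-variance column(s) left centered only: ",
            paste(colnames(x)[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Partial eta squared from Wilks' lambda
#'
#' Multivariate effect size for a MANCOVA effect: eta_p^2 = 1 - lambda^(1/s)
#' where s is the number of non-zero roots of the effect (s = 1 for a
#' single-degree-of-freedom effect, in which case eta_p^2 = 1 - lambda).
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param s number of roots (default 1).
#' @return partial eta squared.
#' @export
partial_eta_sq <- function(lambda, s = 1) {
  if (any(lambda <= 0 | lambda > 1)) stop("lambda must be in (0, 1]")
  if (s < 1) stop("s must be >= 1")
  1 - lambda^(1 / s)
}

#' Eta squared from a one-way ANOVA F statistic
#'
#' eta^2 = F df1 / (F df1 + df2), the between-groups share of total
#' variance implied by the F ratio and its degrees of freedom.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return eta squared.
#' @export
eta_sq_from_f <- function(f, df1, df2) {
  if (f < 0 || df1 <= 0 || df2 <= 0) stop("invalid F or degrees of freedom")
  f * df1 / (f * df1 + df2)
}
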