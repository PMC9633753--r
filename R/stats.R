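#' Forward stepwise selection by partial-F p-values
#'
#' At each step the candidate with the smallest partial-F p-value enters
#' if that p-value is below `alpha_in`; selection stops when no candidate
#' qualifies. Forward-only: the inclusion rule is the only stated
#' criterion, so no removal step is performed. Collinear candidates
#' (those that do not increase the model rank) are skipped with a message.
#'
#' @param response numeric vector.
#' @param candidates n x m matrix of candidate predictors (named columns).
#' @param alpha_in entry threshold on the partial-F p-value (default 0.05).
#' @return object of class `stepwise_fit`: list with `selected` (names in
#'   entry order), `coefficients` (incl. intercept), `p_values` (entry
#'   p-value per selected term), `alpha_in`, `r_squared`, `model` (lm).
#' @export
stepwise_select <- function(response, candidates, alpha_in = 0.05) {
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("x", seq_len(ncol(candidates)))
  if (stats::sd(response) < 1e-12) stop("zero-variance response")
  dat <- data.frame(.y = response, candidates, check.names = FALSE)
  selected <- character(0)
  entry_p <- numeric(0)
  fit <- stats::lm(.y ~ 1, data = dat)
  remaining <- colnames(candidates)
  while (length(remaining) > 0) {
    scope <- stats::as.formula(
      paste("~ . +", paste(sprintf("`%s`", remaining), collapse = " + ")))
    tab <- stats::add1(fit, scope = scope, test = "F")
    cand_rows <- rownames(tab)[-1]
    pv <- tab[["Pr(>F)"]][-1]
    drop_collinear <- is.na(pv)
    if (any(drop_collinear)) {
      message("dropping collinear candidate(s): ",
              paste(gsub("`", "", cand_rows[drop_collinear]), collapse = ", "))
      remaining <- setdiff(remaining,
                           gsub("`", "", cand_rows[drop_collinear]))
      cand_rows <- cand_rows[!drop_collinear]
      pv <- pv[!drop_collinear]
      if (!length(cand_rows)) break
    }
    best <- which.min(pv)
    if (!length(best) || pv[best] >= alpha_in) break
    term <- gsub("`", "", cand_rows[best])
    selected <- c(selected, term)
    entry_p <- c(entry_p, pv[best])
    fit <- stats::update(fit, stats::as.formula(
      paste(". ~ . +", sprintf("`%s`", term))))
    remaining <- setdiff(remaining, term)
  }
  cf <- stats::coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  structure(list(selected = selected,
                 coefficients = cf,
                 p_values = stats::setNames(entry_p, selected),
                 alpha_in = alpha_in,
                 r_squared = summary(fit)$r.squared,
                 model = fit),
            class = "stepwise_fit")
}

#' MANCOVA via Wilks' lambda
#'
#' Multivariate regression of a response matrix on a predictor matrix.
#' The overall test uses Wilks' lambda = det(E) / det(E + H), where E and
#' H are the residual and regression cross-product matrices, with Rao's F
#' approximation; the effect size is partial eta^2 = 1 - lambda^(1/s)
#' with s = min(p, q) roots. Per-predictor (single-root) tests compare
#' the full model against the model dropping that predictor, for which
#' the F transform of lambda is exact and partial eta^2 = 1 - lambda.
#'
#' @param responses n x p numeric matrix.
#' @param predictors n x q numeric matrix (or vector).
#' @return object of class `mancova_result`: list with `wilks_lambda`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `partial_eta_sq`, `terms`
#'   (per-predictor data.frame), `coefficients` (q+1 x p, incl.
#'   intercept), `n`.
#' @export
mancova <- function(responses, predictors) {
  Y <- as.matrix(responses)
  X <- as.matrix(predictors)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(Y); p <- ncol(Y); q <- ncol(X)
  if (nrow(X) != n) stop("responses and predictors must have equal rows")
  if (n <= p + q + 1) stop("too few observations for the design")
  Xd <- cbind(`(Intercept)` = 1, X)
  B <- solve(crossprod(Xd), crossprod(Xd, Y))
  res <- Y - Xd %*% B
  E <- crossprod(res)
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  H <- crossprod(Yc) - E
  if (abs(det(E)) < 1e-300) stop("singular residual cross-product matrix")
  lambda <- det(E) / det(E + H)
  lambda <- min(max(lambda, 1e-300), 1)  # guard against rounding at 0 / 1
  overall <- rao_f(lambda, p, q, n)
  s <- min(p, q)

  terms <- do.call(rbind, lapply(seq_len(q), function(j) {
    Xr <- Xd[, -(j + 1), drop = FALSE]
    Br <- solve(crossprod(Xr), crossprod(Xr, Y))
    Er <- crossprod(Y - Xr %*% Br)
    lam_j <- det(E) / det(Er)
    ve <- n - q - 1
    f_j <- (1 - lam_j) / lam_j * (ve - p + 1) / p
    data.frame(term = colnames(X)[j], wilks_lambda = lam_j,
               f_stat = f_j, df1 = p, df2 = ve - p + 1,
               p_value = stats::pf(f_j, p, ve - p + 1, lower.tail = FALSE),
               partial_eta_sq = 1 - lam_j)
  }))

  structure(list(wilks_lambda = lambda, f_stat = overall$f,
                 df1 = overall$df1, df2 = overall$df2,
                 p_value = overall$p,
                 partial_eta_sq = partial_eta_sq(lambda, s),
                 terms = terms, coefficients = B, n = n),
            class = "mancova_result")
}

#' Rao's F approximation to Wilks' lambda
#' @keywords internal
rao_f <- function(lambda, p, q, n) {
  t <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- n - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * t - (p * q) / 2 + 1
  lam_t <- lambda^(1 / t)
  f <- (1 - lam_t) / lam_t * df2 / df1
  list(f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Canonical correlation analysis with sequential Wilks tests
#'
#' Canonical correlations and weight vectors from the singular value
#' decomposition of the whitened cross-covariance matrix
#' Sxx^(-1/2) Sxy Syy^(-1/2). Each root sequence k..s is tested with
#' Wilks' lambda_k = prod(1 - r_i^2) and Rao's F approximation.
#' Rank-deficient sides are an error (reduce the side first, e.g. to
#' principal component scores).
#'
#' @param left n x p matrix (e.g. nutrition variables).
#' @param right n x q matrix (e.g. shape component scores).
#' @return object of class `canonical_result`: list with `correlations`,
#'   `left_coef` (p x s), `right_coef` (q x s), `wilks` (per-root
#'   data.frame with F, dfs, p), `left_scores`, `right_scores`, `n`.
#' @export
canonical_analysis <- function(left, right) {
  X <- as.matrix(left); Y <- as.matrix(right)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("sides must have equal rows")
  if (n <= max(p, q) + 1) stop("too few observations")
  Xc <- sweep(X, 2, colMeans(X), "-")
  Yc <- sweep(Y, 2, colMeans(Y), "-")
  Sxx <- crossprod(Xc) / (n - 1)
  Syy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  cx <- tryCatch(chol(Sxx), error = function(e)
    stop("left side is rank deficient; reduce it first"))
  cy <- tryCatch(chol(Syy), error = function(e)
    stop("right side is rank deficient; reduce it first"))
  Wx <- backsolve(cx, diag(p))
  Wy <- backsolve(cy, diag(q))
  K <- t(Wx) %*% Sxy %*% Wy
  sv <- svd(K)
  s <- min(p, q)
  r <- pmin(1, pmax(0, sv$d[seq_len(s)]))
  a <- Wx %*% sv$u[, seq_len(s), drop = FALSE]
  b <- Wy %*% sv$v[, seq_len(s), drop = FALSE]
  rownames(a) <- colnames(X); rownames(b) <- colnames(Y)
  colnames(a) <- colnames(b) <- paste0("CV", seq_len(s))

  wilks <- do.call(rbind, lapply(seq_len(s), function(k) {
    lam <- prod(1 - r[k:s]^2)
    pp <- p - k + 1; qq <- q - k + 1
    ap <- rao_f(lam, pp, qq, n - (k - 1))
    data.frame(root = k, r = r[k], wilks_lambda = lam, f_stat = ap$f,
               df1 = ap$df1, df2 = ap$df2, p_value = ap$p)
  }))

  structure(list(correlations = r, left_coef = a, right_coef = b,
                 wilks = wilks,
                 left_scores = Xc %*% a, right_scores = Yc %*% b,
                 n = n),
            class = "canonical_result")
}

#' k-means clustering with elbow selection of k
#'
#' Standardizes the feature matrix, runs seeded k-means (Lloyd
#' iterations, best of `restarts` random starts) for every candidate k,
#' and picks the elbow: the smallest k whose within-cluster sum of
#' squares is essentially zero, otherwise the interior candidate
#' maximizing the second difference of the WSS curve. Candidate k values
#' exceeding the number of distinct rows are dropped with a message.
#'
#' @param features n x d numeric matrix.
#' @param k_candidates integer vector of candidate cluster counts
#'   (default 2:6).
#' @param seed integer seed for the restarts.
#' @param restarts random restarts per k (default 25).
#' @param standardize z-score the columns first (default TRUE).
#' @return object of class `cluster_result`: list with `k`, `codes`,
#'   `centroids`, `wss` (named curve over candidates), `k_candidates`.
#' @export
kmeans_elbow <- function(features, k_candidates = 2:6, seed = 1,
                         restarts = 25, standardize = TRUE) {
  x <- as.matrix(features)
  if (standardize) x <- zstandardize(x)
  n_distinct <- nrow(unique(x))
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates > nrow(x))) stop("k exceeds the number of subjects")
  usable <- k_candidates[k_candidates <= n_distinct]
  if (length(usable) < length(k_candidates))
    message("dropping k > ", n_distinct, " (distinct rows)")
  fits <- local_seed(derive_seed(seed, 7), lapply(usable, function(k) {
    fit <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100,
                    algorithm = "Lloyd"))
    for (retry in 1:5) {
      if (all(fit$size > 0)) break
      message("empty cluster at k = ", k, "; re-seeding")
      fit <- suppressWarnings(
        stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100,
                      algorithm = "Lloyd"))
    }
    fit
  }))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  names(wss) <- usable
  tot <- sum(scale(x, scale = FALSE)^2)
  near_zero <- wss <= 1e-10 * tot
  if (any(near_zero)) {
    pick <- which(near_zero)[1]
  } else if (length(usable) >= 3) {
    second_diff <- utils::head(wss, -2) - 2 * wss[c(-1, -length(wss))] +
      utils::tail(wss, -2)
    pick <- which.max(second_diff) + 1L
  } else {
    pick <- which.min(wss)
  }
  chosen <- fits[[pick]]
  structure(list(k = usable[pick],
                 codes = chosen$cluster,
                 centroids = chosen$centers,
                 wss = wss, k_candidates = usable),
            class = "cluster_result")
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' F test, eta^2 = SS_between / SS_total, and all pairwise Tukey-Kramer
#' honest significant differences (valid for unequal group sizes).
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return list with `f_stat`, `df1`, `df2`, `p_value`, `eta_sq`,
#'   `group_means`, `pairwise` (data.frame: pair, diff, q, p_adj).
#' @export
anova_tukey <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  ssb <- an[["Sum Sq"]][1]; sse <- an[["Sum Sq"]][2]
  tk <- stats::TukeyHSD(fit)$g
  mse <- an[["Mean Sq"]][2]
  ns <- table(g)
  pairs <- rownames(tk)
  qstat <- vapply(seq_along(pairs), function(i) {
    ab <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    se <- sqrt(mse / 2 * (1 / ns[[ab[1]]] + 1 / ns[[ab[2]]]))
    abs(tk[i, "diff"]) / se
  }, numeric(1))
  list(f_stat = an[["F value"]][1],
       df1 = an[["Df"]][1], df2 = an[["Df"]][2],
       p_value = an[["Pr(>F)"]][1],
       eta_sq = ssb / (ssb + sse),
       group_means = tapply(values, g, mean),
       pairwise = data.frame(pair = pairs, diff = tk[, "diff"],
                             q = qstat, p_adj = tk[, "p adj"],
                             row.names = NULL))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, original order
#' preserved.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
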