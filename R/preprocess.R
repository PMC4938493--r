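#' Huber IRLS linear regression residuals
#'
#' Iteratively reweighted least squares with the Huber psi (tuning constant
#' `k = 1.345`, scale re-estimated each iteration by the MAD of residuals),
#' run to a relative coefficient tolerance of 1e-8 or 50 iterations.
#'
#' @param y response vector.
#' @param X design matrix (including intercept column).
#' @param k Huber tuning constant.
#' @param maxit,tol iteration controls.
#' @return list with `coefficients`, `residuals`, `iterations`.
#' @keywords internal
huber_fit <- function(y, X, k = 1.345, maxit = 50L, tol = 1e-8) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s < 1e-12) return(list(coefficients = beta, residuals = r, iterations = it))
    u <- r / s
    w <- ifelse(abs(u) <= k, 1, k / abs(u))
    wX <- X * w
    beta_new <- solve(crossprod(wX, X), crossprod(wX, y))
    if (max(abs(beta_new - beta)) <= tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  r <- y - drop(X %*% beta)
  list(coefficients = drop(beta), residuals = r, iterations = it)
}

#' Adjust expression for covariates by robust regression
#'
#' Fits, per gene, a Huber-weighted IRLS linear model of expression on the
#' named covariates (intercept plus covariates; factors are expanded to
#' dummies) and replaces expression by the residuals.  With an empty
#' covariate list the fit is intercept-only, i.e. a per-gene robust location
#' is removed.
#'
#' @param study an `expression_study` with a covariate table.
#' @param covariate_names character vector of covariate columns (may be
#'   empty).
#' @return a new `expression_study` of residuals, same dimensions.
#' @export
adjust_covariates <- function(study, covariate_names = character(0)) {
  stopifnot(inherits(study, "expression_study"))
  n <- ncol(study$expr)
  if (length(covariate_names) > 0) {
    if (is.null(study$covariates) ||
        !all(covariate_names %in% names(study$covariates)))
      stop("covariates not present: ",
           paste(setdiff(covariate_names, names(study$covariates)), collapse = ", "))
    if (n < length(covariate_names) + 2)
      stop("need at least covariates + 2 samples")
    X <- stats::model.matrix(
      ~ ., data = study$covariates[, covariate_names, drop = FALSE])
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  res <- t(apply(study$expr, 1, function(y) huber_fit(y, X)$residuals))
  dimnames(res) <- dimnames(study$expr)
  expression_study(res, condition = study$condition, covariates = study$covariates)
}

#' Estimate surrogate variables by permutation parallel analysis
#'
#' Removes the supplied model covariates by ordinary regression, then
#' compares the ordered eigenvalues of the residual sample covariance
#' against the null distribution obtained by permuting each gene row
#' independently (`B` permutations; the observed matrix is included in its
#' own reference set).  `k` is the number of leading components whose
#' eigenvalue strictly exceeds the `1 - alpha` null quantile of the
#' same-rank eigenvalue, stopping at the first failure.  The surrogate
#' variables are those `k` right singular vectors.
#'
#' @param study an `expression_study`.
#' @param model_covariates covariate columns to regress out first (ordinary
#'   least squares); empty for none beyond centering.
#' @param alpha per-component significance level.
#' @param B number of row permutations (minimum 10).
#' @param seed integer seed for the permutations.
#' @return list of class `surrogate_variables`: `sv` sample x k matrix,
#'   `k`, `alpha`, `eigenvalues`, `null_quantiles`.
#' @export
estimate_surrogate_variables <- function(study, model_covariates = character(0),
                                         alpha = 0.05, B = 100L, seed = 1L) {
  stopifnot(inherits(study, "expression_study"))
  B <- check_count(B, "B")
  if (B < 10) stop("B must be at least 10")
  check_prob(alpha, "alpha")
  E <- study$expr
  if (length(model_covariates) > 0) {
    X <- stats::model.matrix(
      ~ ., data = study$covariates[, model_covariates, drop = FALSE])
    E <- t(stats::lm.fit(X, t(E))$residuals)
    dimnames(E) <- dimnames(study$expr)
  }
  E <- E - rowMeans(E)
  n <- ncol(E)
  eigvals <- function(M) {
    ev <- eigen(crossprod(M) / nrow(M), symmetric = TRUE, only.values = TRUE)$values
    pmax(ev, 0)
  }
  obs <- eigvals(E)
  with_seed(substream_seed(seed, "parallel-analysis"), {
    null <- matrix(0, B + 1, n)
    null[B + 1, ] <- obs  # observed belongs to its own permutation family
    for (b in seq_len(B)) {
      P <- t(apply(E, 1, sample))
      P <- P - rowMeans(P)
      null[b, ] <- eigvals(P)
    }
    qs <- apply(null, 2, stats::quantile, probs = 1 - alpha, type = 1)
    k <- 0L
    for (i in seq_len(n)) {
      if (obs[i] > qs[i]) k <- k + 1L else break
    }
    sv <- if (k > 0) {
      v <- svd(E, nu = 0, nv = k)$v
      dimnames(v) <- list(colnames(E), paste0("SV", seq_len(k)))
      v
    } else matrix(0, n, 0, dimnames = list(colnames(E), NULL))
    structure(list(sv = sv, k = k, alpha = alpha, eigenvalues = obs,
                   null_quantiles = qs),
              class = "surrogate_variables")
  })
}

#' Remove surrogate variables by ordinary regression
#'
#' Per gene, residuals after least-squares regression on the surrogate
#' variables (plus intercept).  With `k = 0` this is the identity map.
#'
#' @param study an `expression_study`.
#' @param svs a `surrogate_variables` object (or sample x k matrix).
#' @return a new `expression_study` of residuals.
#' @export
remove_svs <- function(study, svs) {
  stopifnot(inherits(study, "expression_study"))
  sv <- if (inherits(svs, "surrogate_variables")) svs$sv else as.matrix(svs)
  if (ncol(sv) == 0) return(study)
  if (nrow(sv) != ncol(study$expr)) stop("surrogate variable rows must match samples")
  if (!is.null(rownames(sv)) &&
      !identical(rownames(sv), colnames(study$expr)))
    stop("sample ids of surrogate variables do not match the study")
  X <- cbind(1, sv)
  res <- t(stats::lm.fit(X, t(study$expr))$residuals)
  dimnames(res) <- dimnames(study$expr)
  expression_study(res, condition = study$condition, covariates = study$covariates)
}

#' Full expression correction: robust covariates then surrogate variables
#'
#' @param study an `expression_study`.
#' @param covariate_names covariates for the robust adjustment.
#' @param alpha,B parallel-analysis controls.
#' @param seed permutation seed.
#' @return list with the corrected `study` and the `svs` object.
#' @export
preprocess_expression <- function(study, covariate_names = c("age", "sex"),
                                  alpha = 0.05, B = 100L, seed = 1L) {
  adj <- adjust_covariates(study, covariate_names)
  svs <- estimate_surrogate_variables(adj, character(0), alpha = alpha,
                                      B = B, seed = seed)
  list(study = remove_svs(adj, svs), svs = svs)
}
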