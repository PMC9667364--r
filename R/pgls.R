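#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits the linear model `formula` by generalized least squares with
#' residual covariance `sigma^2 * lambda_transform(C, lambda)`, where `C` is
#' the Brownian covariance of the tree. `lambda` may be fixed or estimated
#' by maximizing the (restricted) log-likelihood profile over \[0, 1\]:
#' a 101-point grid followed by golden-section refinement, with boundary
#' optima reported as exactly 0 or 1.
#'
#' The overall F statistic compares the full model to the intercept-only
#' model under the full model's fitted covariance, with numerator
#' d.f. `p - 1` and denominator d.f. `n - p`; the adjusted R^2 uses the
#' corresponding generalized residual sums of squares. Categorical
#' predictors enter as treatment contrasts (reference = first level,
#' alphabetical by default).
#'
#' Rows with missing values in the response or predictors are dropped
#' (listwise deletion) and the tree is pruned to the remaining species.
#'
#' @param formula model formula; variables are taken from `data`.
#' @param data data.frame with one row per species; species names in a
#'   `species` column or as rownames.
#' @param tree an [ape::phylo] containing (at least) the modelled species.
#' @param lambda `"ML"` (default: estimate) or a fixed value in \[0, 1\].
#' @param REML logical: use restricted maximum likelihood for the lambda
#'   profile (default `FALSE`, plain ML).
#' @return An object of class `pgls_fit`: coefficient table, `sigma2`,
#'   `lambda` (estimate), `logLik`, `F`, `df`, `p.value`, `r.squared.adj`,
#'   `residuals`, the lambda `profile` (grid and log-likelihoods, with a
#'   `flat` flag when the profile is uninformative), and bookkeeping
#'   (`n`, dropped species).
#' @export
#' @examples
#' tr <- make_tree(32, seed = 7)
#' y <- simulate_bm(tr, rate = 0.1, seed = 2)[, 1]
#' d <- data.frame(species = names(y), y = y,
#'                 x = rnorm(32))
#' fit_pgls(y ~ x, d, tr)
fit_pgls <- function(formula, data, tree, lambda = "ML", REML = FALSE) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  species <- if ("species" %in% names(data)) data$species else rownames(data)
  if (is.null(species)) stop("data needs a 'species' column or rownames")
  species <- normalize_species(species)
  if (anyDuplicated(species)) stop("duplicated species in data")

  mf_all <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf_all)
  dropped <- species[!keep]
  mf <- mf_all[keep, , drop = FALSE]
  species <- species[keep]
  n <- nrow(mf)
  if (n < 3L) stop("need >= 3 complete species")

  cv <- phylo_covariance(tree, species)
  ord <- match(rownames(cv$C), species)
  mf <- mf[ord, , drop = FALSE]
  species <- species[ord]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  C <- cv$C

  prof <- NULL
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, length.out = 101L)
    ll <- vapply(grid, function(l) .pgls_loglik(y, X, C, l, REML), 0)
    if (!any(is.finite(ll))) {
      # perfect fit (zero residual variance): lambda is meaningless
      ll <- rep(0, length(grid))
    }
    flat <- diff(range(ll[is.finite(ll)])) < 1e-6
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    lam_hat <- if (flat) grid[i] else {
      stats::optimize(function(l) .pgls_loglik(y, X, C, l, REML),
                      interval = c(lo, hi), maximum = TRUE,
                      tol = 1e-8)$maximum
    }
    # snap to the boundary when the optimum sits at the edge of the domain
    if (lam_hat < 1e-6) lam_hat <- 0
    if (lam_hat > 1 - 1e-6) lam_hat <- 1
    if (.pgls_loglik(y, X, C, grid[i], REML) >
        .pgls_loglik(y, X, C, lam_hat, REML)) {
      lam_hat <- grid[i]
    }
    prof <- list(lambda = grid, logLik = ll, flat = flat)
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be \"ML\" or a value in [0, 1]")
    }
    lam_hat <- as.numeric(lambda)
  }

  fit <- .pgls_core(y, X, C, lam_hat)
  p <- ncol(X)
  sigma2 <- fit$rss / (n - p)
  se <- sqrt(diag(fit$XtXinv) * sigma2)
  tval <- fit$beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  coef_table <- data.frame(estimate = fit$beta, std.error = se,
                           t.value = tval, p.value = pval,
                           row.names = colnames(X))

  # overall F: full model vs intercept-only, same fitted covariance
  X0 <- matrix(1, n, 1)
  rss0 <- .pgls_core(y, X0, C, lam_hat)$rss
  if (p > 1L) {
    Fstat <- ((rss0 - fit$rss) / (p - 1)) / (fit$rss / (n - p))
    Fp <- stats::pf(Fstat, p - 1, n - p, lower.tail = FALSE)
  } else {
    Fstat <- NA_real_
    Fp <- NA_real_
  }
  r2adj <- 1 - (fit$rss / (n - p)) / (rss0 / (n - 1))

  structure(list(
    coefficients = coef_table,
    vcov = fit$XtXinv * sigma2,
    sigma2 = sigma2,
    lambda = lam_hat,
    lambda_mode = if (identical(lambda, "ML")) "ML" else "fixed",
    REML = REML,
    logLik = .pgls_loglik(y, X, C, lam_hat, REML),
    F = Fstat, df = c(p - 1L, n - p), p.value = Fp,
    r.squared.adj = r2adj,
    residuals = setNames(as.vector(y - X %*% fit$beta), species),
    fitted = setNames(as.vector(X %*% fit$beta), species),
    profile = prof,
    n = n, dropped = dropped,
    model = list(y = y, X = X, C = C, tree = cv$tree,
                 terms = attr(mf, "terms"),
                 frame = mf, species = species, formula = formula)
  ), class = "pgls_fit")
}

# GLS solve for fixed lambda via the Cholesky whitening transform.
.pgls_core <- function(y, X, C, lambda) {
  V <- lambda_transform(C, lambda)
  L <- chol(V)                                     # V = t(L) %*% L
  yt <- backsolve(L, y, transpose = TRUE)
  Xt <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xt)
  beta <- solve(XtX, crossprod(Xt, yt))
  resid_t <- yt - Xt %*% beta
  list(beta = setNames(as.vector(beta), colnames(X)),
       rss = sum(resid_t^2),
       XtXinv = solve(XtX),
       logdetV = 2 * sum(log(diag(L))),
       logdetXtX = determinant(XtX, logarithm = TRUE)$modulus[1])
}

# Profile (restricted) log-likelihood in lambda, sigma^2 profiled out.
.pgls_loglik <- function(y, X, C, lambda, REML = FALSE) {
  f <- .pgls_core(y, X, C, lambda)
  n <- length(y); p <- ncol(X)
  if (REML) {
    s2 <- f$rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + f$logdetV + f$logdetXtX + (n - p))
  } else {
    s2 <- f$rss / n
    -0.5 * (n * log(2 * pi * s2) + f$logdetV + n)
  }
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic generalized least squares\n")
  cat(sprintf("  n = %d species; lambda = %.3f (%s%s)%s\n", x$n, x$lambda,
              x$lambda_mode, if (x$REML) ", REML" else ", ML",
              if (!is.null(x$profile) && x$profile$flat) " [flat profile]" else ""))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  if (!is.na(x$F)) {
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g, adj. R^2 = %.3f\n",
                x$df[1], x$df[2], x$F, x$p.value, x$r.squared.adj))
  }
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
vcov.pgls_fit <- function(object, ...) object$vcov

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logLik, df = ncol(object$model$X) + 2, class = "logLik")
}

#' F test for dropping one term from a PGLS fit
#'
#' Compares the fitted model to the model without `term`, holding the
#' fitted covariance (the full model's lambda) constant: the conventional
#' covariate-adjusted factor test.
#'
#' @param fit a [fit_pgls()] result.
#' @param term character name of a term in the model formula.
#' @return A list: `F`, `df` (numerator, denominator), `p.value`.
#' @export
pgls_term_test <- function(fit, term) {
  stopifnot(inherits(fit, "pgls_fit"))
  trm <- fit$model$terms
  labels <- attr(trm, "term.labels")
  if (!term %in% labels) {
    stop("term '", term, "' not in model (has: ",
         paste(labels, collapse = ", "), ")")
  }
  asgn <- attr(fit$model$X, "assign")
  drop_cols <- asgn == match(term, labels)
  X_red <- fit$model$X[, !drop_cols, drop = FALSE]
  full <- .pgls_core(fit$model$y, fit$model$X, fit$model$C, fit$lambda)
  red <- .pgls_core(fit$model$y, X_red, fit$model$C, fit$lambda)
  q <- sum(drop_cols)
  df2 <- fit$n - ncol(fit$model$X)
  Fstat <- ((red$rss - full$rss) / q) / (full$rss / df2)
  list(F = Fstat, df = c(q, df2),
       p.value = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Refit a PGLS with a releveled factor
#'
#' Refits the model with `ref` as the reference level of `factor_name`, so
#' the intercept-adjacent coefficients report per-level slopes/effects
#' relative to the new reference. Used to report per-group effects (e.g.
#' the metamorphosis-stage deltas per post-metamorphic environment).
#'
#' @param fit a [fit_pgls()] result.
#' @param factor_name name of a factor variable in the model frame.
#' @param ref the level to use as reference.
#' @param lambda lambda for the refit; default reuses the original fit's
#'   estimate (fixed), keeping the covariance identical across relevels.
#' @return A new `pgls_fit`.
#' @export
pgls_relevel <- function(fit, factor_name, ref, lambda = fit$lambda) {
  frame <- fit$model$frame
  if (!factor_name %in% names(frame)) stop("no such variable: ", factor_name)
  frame[[factor_name]] <- stats::relevel(factor(frame[[factor_name]]), ref = ref)
  frame$species <- fit$model$species
  fit_pgls(fit$model$formula, frame, fit$model$tree,
           lambda = lambda, REML = fit$REML)
}
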