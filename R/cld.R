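#' Pairwise post-hoc comparisons among factor levels of a PGLS fit
#'
#' Tests every pair of levels of a single factor in a fitted PGLS model
#' using the coefficient covariance of the fit (Wald t-tests on level-mean
#' differences under the fitted phylogenetic covariance), adjusts the
#' p-values for multiplicity, and summarizes the result as a compact
#' letter display: levels sharing a letter are not significantly different.
#'
#' @param fit a [fit_pgls()] result whose model contains `factor_name`.
#' @param factor_name name of the factor term.
#' @param method p-value adjustment: `"holm"` (default), `"bonferroni"`, or
#'   any method of [stats::p.adjust()].
#' @param alpha significance level for the letter grouping (default 0.05).
#' @return A list of class `pgls_posthoc`: `pairs` (data.frame of pairwise
#'   estimates, t, raw and adjusted p), `letters` (named character vector),
#'   `method`, `alpha`.
#' @export
pgls_pairwise <- function(fit, factor_name, method = "holm", alpha = 0.05) {
  stopifnot(inherits(fit, "pgls_fit"))
  frame <- fit$model$frame
  if (!factor_name %in% names(frame)) {
    stop("no variable '", factor_name, "' in the model frame")
  }
  f <- droplevels(factor(frame[[factor_name]]))
  levs <- levels(f)
  if (length(levs) < 2L) stop("factor has fewer than 2 levels")
  X <- fit$model$X
  cols <- colnames(X)
  # column index of the treatment-contrast dummy for each level (NA = reference)
  dummy_of <- vapply(levs, function(l) {
    hit <- which(cols == paste0(factor_name, l))
    if (length(hit)) hit else NA_integer_
  }, 0L)
  V <- fit$vcov
  est <- coef(fit)
  df2 <- fit$df[2]
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    cvec <- numeric(length(est))
    if (!is.na(dummy_of[pr[1]])) cvec[dummy_of[pr[1]]] <- 1
    if (!is.na(dummy_of[pr[2]])) cvec[dummy_of[pr[2]]] <- -1
    d <- sum(cvec * est)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- d / se
    data.frame(level_a = pr[1], level_b = pr[2], estimate = d,
               std.error = se, t.value = tval,
               p.value = 2 * pt(-abs(tval), df2))
  })
  tab <- do.call(rbind, rows)
  tab$p.adjusted <- stats::p.adjust(tab$p.value, method = method)
  sig <- tab[tab$p.adjusted < alpha, c("level_a", "level_b"), drop = FALSE]
  structure(list(pairs = tab,
                 letters = compact_letters(levs, sig),
                 method = method, alpha = alpha),
            class = "pgls_posthoc")
}

#' @export
print.pgls_posthoc <- function(x, ...) {
  cat(sprintf("Pairwise PGLS contrasts (%s-adjusted, alpha = %.2f)\n",
              x$method, x$alpha))
  print(x$pairs, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Compact letter display from significant pairs
#'
#' Insert-and-absorb algorithm: starting from a single letter covering all
#' levels, each significantly different pair splits every letter column
#' containing both members; columns that become subsets of others are
#' absorbed. Levels sharing any letter are not significantly different.
#'
#' @param levels character vector of level names.
#' @param sig_pairs data.frame (or 2-column matrix) of significantly
#'   different pairs.
#' @return Named character vector of letter strings, one per level.
#' @export
compact_letters <- function(levels, sig_pairs) {
  cols <- list(levels)
  if (!is.null(sig_pairs) && nrow(sig_pairs) > 0) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- as.character(sig_pairs[r, 1]); b <- as.character(sig_pairs[r, 2])
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another column
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
      cols <- cols[vapply(cols, length, 0L) > 0]
    }
  }
  lab <- letters[seq_along(cols)]
  out <- vapply(levels, function(l) {
    paste(lab[vapply(cols, function(col) l %in% col, TRUE)], collapse = "")
  }, "")
  out
}
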