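#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), the form implied by
#' non-integer d.f. in reported results.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return A list: `t`, `df`, `p.value`, `estimate` (mean difference x - y).
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    stop("zero variance in both groups: t is undefined")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, estimate = mean(x) - mean(y))
}

#' Principal component analysis of species trait means
#'
#' Eigendecomposition of the covariance (`scale = FALSE`) or correlation
#' (`scale = TRUE`) matrix of column-centered data. Loadings are unit-norm
#' eigenvectors with a deterministic sign convention: when a variable named
#' in `sign_reference` loads on PC1, its PC1 loading is made negative (for
#' display comparability across runs); every other component is flipped so
#' its largest-magnitude loading is positive.
#'
#' @param data numeric species x traits matrix or data.frame.
#' @param scale logical: analyse the correlation matrix (default `TRUE`,
#'   appropriate when traits differ strongly in variance).
#' @param sign_reference variable anchoring the PC1 sign (default
#'   `"anisotropy"`; ignored when absent).
#' @return A list of class `lens_pca`: `loadings` (variables x components),
#'   `proportion` (variance proportions, summing to 1), `sdev`, `scores`
#'   (species x components), `center`, `scale`.
#' @export
pca <- function(data, scale = TRUE, sign_reference = "anisotropy") {
  X <- as.matrix(data)
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need >= 2 species and >= 2 traits")
  if (anyNA(X)) stop("data contains missing values")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (scale) {
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) {
      stop("constant column(s) with scale = TRUE: ",
           paste(colnames(X)[scl == 0], collapse = ", "))
    }
    Xc <- sweep(Xc, 2, scl, `/`)
  }
  S <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(S, symmetric = TRUE)
  load <- eg$vectors
  rownames(load) <- colnames(X)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  for (j in seq_len(ncol(load))) {
    flip <- if (j == 1L && sign_reference %in% rownames(load)) {
      load[sign_reference, 1] > 0
    } else {
      load[which.max(abs(load[, j])), j] < 0
    }
    if (isTRUE(flip)) load[, j] <- -load[, j]
  }
  ev <- pmax(eg$values, 0)
  structure(list(loadings = load,
                 proportion = ev / sum(ev),
                 sdev = sqrt(ev),
                 scores = Xc %*% load,
                 center = ctr, scale = if (scale) scl else NULL),
            class = "lens_pca")
}

#' @export
print.lens_pca <- function(x, ...) {
  cat("Principal component analysis\n")
  cat("  variance proportions:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * x$proportion),
            collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Collinearity screen over shape metrics
#'
#' Computes pairwise Pearson correlations among metric columns and, for
#' each pair exceeding the absolute-correlation threshold, drops the
#' lower-priority member. Mirrors the practice of excluding flatness from
#' downstream analyses because it is almost perfectly (inversely)
#' determined by anisotropy.
#'
#' @param data numeric species x metrics matrix or data.frame.
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.9).
#' @param priority character vector, most-preferred first; metrics absent
#'   from this list rank last. Default keeps anisotropy over sphericity
#'   over elongation over flatness.
#' @return A list of class `collinearity_screen`: `retained`, `dropped`,
#'   `correlations` (full matrix), `decisions` (one row per flagged pair).
#' @export
collinearity_screen <- function(data, threshold = 0.9,
                                priority = c("anisotropy", "sphericity",
                                             "elongation", "flatness")) {
  X <- as.matrix(data)
  if (nrow(X) < 3L) stop("need >= 3 species")
  R <- cor(X)
  vars <- colnames(X)
  rank_of <- match(vars, priority)
  rank_of[is.na(rank_of)] <- length(priority) + seq_len(sum(is.na(rank_of)))
  names(rank_of) <- vars
  dropped <- character()
  decisions <- list()
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  ord <- order(-abs(R[pairs]))  # strongest correlations decided first
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (abs(R[i, j]) <= threshold) next
    vi <- vars[i]; vj <- vars[j]
    if (vi %in% dropped || vj %in% dropped) next
    loser <- if (rank_of[vi] <= rank_of[vj]) vj else vi
    dropped <- c(dropped, loser)
    decisions[[length(decisions) + 1L]] <- data.frame(
      metric_a = vi, metric_b = vj, r = R[i, j], dropped = loser)
  }
  structure(list(retained = setdiff(vars, dropped),
                 dropped = dropped,
                 correlations = R,
                 decisions = if (length(decisions)) {
                   do.call(rbind, decisions)
                 } else {
                   data.frame(metric_a = character(), metric_b = character(),
                              r = numeric(), dropped = character())
                 },
                 threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| > %.2f): retained %s\n",
              x$threshold, paste(x$retained, collapse = ", ")))
  if (length(x$dropped)) {
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
    print(x$decisions)
  }
  invisible(x)
}
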