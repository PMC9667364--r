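#' Normalize species names for tip matching
#'
#' Species names are matched to tree tips after trimming whitespace and
#' collapsing runs of spaces/underscores to a single underscore, so
#' `"Xenopus laevis"` and `"Xenopus_laevis"` are the same species.
#'
#' @param x character vector of names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  gsub("[ _]+", "_", trimws(as.character(x)))
}

#' Phylogenetic covariance matrix from a tree
#'
#' Builds the Brownian-motion covariance matrix `C` of a rooted tree with
#' branch lengths: `C[i, j]` is the shared root-to-MRCA path length of tips
#' i and j (the expected trait covariance under unit-rate Brownian motion).
#' Computed from first principles via the edge-incidence construction
#' `C = A' diag(len) A`, where `A[e, i]` marks edge `e` on the root-to-tip
#' path of tip `i`.
#'
#' Zero-length terminal branches are replaced by `1e-8` times tree height
#' (with a warning) so that `C` stays invertible.
#'
#' @param tree an [ape::phylo] object (rooted, with branch lengths).
#' @param tips optional character vector of tips to keep (tree is pruned
#'   first); names are matched after [normalize_species()].
#' @return A list of class `phylo_vcv`: `C` (named matrix), `tree` (the
#'   pruned tree).
#' @export
#' @examples
#' tr <- make_tree(5, seed = 1)
#' phylo_covariance(tr)$C
phylo_covariance <- function(tree, tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree$tip.label <- normalize_species(tree$tip.label)
  if (!is.null(tips)) {
    tips <- normalize_species(tips)
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) {
      stop("tips absent from tree: ", paste(missing, collapse = ", "))
    }
    tree <- ape::keep.tip(tree, tips)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  height <- max(ape::node.depth.edgelength(tree))
  term <- tree$edge[, 2] <= length(tree$tip.label)
  zero_term <- term & tree$edge.length <= 0
  if (any(zero_term)) {
    warning(sum(zero_term), " zero-length terminal branch(es) replaced by ",
            "1e-8 x tree height to keep C invertible")
    tree$edge.length[zero_term] <- 1e-8 * height
  }
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))  # edge whose child is this node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n + 1L
  A <- matrix(0, nrow(tree$edge), n)
  for (i in seq_len(n)) {
    node <- i
    while (node != root) {
      A[edge_of[node], i] <- 1
      node <- parent[node]
    }
  }
  C <- t(A) %*% (tree$edge.length * A)
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  structure(list(C = C, tree = tree), class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(sprintf("<phylo_vcv> %d tips, tree height %.4g\n",
              nrow(x$C), max(diag(x$C))))
  invisible(x)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal unchanged: `lambda = 1` is the Brownian expectation, `lambda = 0`
#' removes all phylogenetic covariance (a star phylogeny with the original
#' tip variances).
#'
#' @param C a `phylo_vcv` or a plain covariance matrix.
#' @param lambda value in \[0, 1\].
#' @return Transformed matrix (same type as the input).
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  if (inherits(C, "phylo_vcv")) {
    C$C <- lambda_transform(C$C, lambda)
    return(C)
  }
  d <- diag(C)
  out <- C * lambda
  diag(out) <- d
  out
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' Generates a bifurcating pure-birth (Yule) tree, rescales it to unit
#' height, and names tips `sp0001`, `sp0002`, ... The generator is a pure
#' function of `n_tips` and `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return An ultrametric [ape::phylo] of height 1.
#' @export
make_tree <- function(n_tips, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2")
  tree <- .with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  height <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / height
  tree$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tree
}

#' Simulate multivariate traits under lambda-scaled Brownian motion
#'
#' Draws `n_traits` independent trait columns from a multivariate normal
#' with covariance `lambda_transform(C, lambda) * rate` across species,
#' where `C` is the Brownian covariance of the tree. Reproducible under
#' `seed`.
#'
#' @param tree an [ape::phylo].
#' @param n_traits number of trait columns.
#' @param rate Brownian rate sigma^2 per trait (scalar or length `n_traits`).
#' @param lambda Pagel's lambda in \[0, 1\] (default 1, pure Brownian motion).
#' @param seed integer RNG seed.
#' @param mean trait mean at the root (scalar or length `n_traits`).
#' @return A species x traits numeric matrix with tip labels as rownames.
#' @export
simulate_bm <- function(tree, n_traits = 1L, rate = 1, lambda = 1,
                        seed = 1L, mean = 0) {
  if (any(rate <= 0)) stop("rate must be > 0")
  V <- lambda_transform(phylo_covariance(tree)$C, lambda)
  n <- nrow(V)
  L <- chol(V)  # V = t(L) %*% L
  rate <- rep(rate, length.out = n_traits)
  mean <- rep(mean, length.out = n_traits)
  Z <- .with_seed(seed, matrix(rnorm(n * n_traits), n, n_traits))
  X <- crossprod(L, Z) %*% diag(sqrt(rate), n_traits)
  X <- sweep(X, 2, mean, `+`)
  rownames(X) <- rownames(V)
  colnames(X) <- paste0("trait", seq_len(n_traits))
  X
}
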