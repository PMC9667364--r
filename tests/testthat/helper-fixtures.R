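# Shared fixtures and independent oracles.

# Brute-force two-pass covariance of voxel-center coordinates: the
# independent oracle for covariance_eigenvalues().
brute_force_eigen <- function(volume, label = 1L) {
  idx <- which(volume$grid == label, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2, volume$spacing, `*`)
  n <- nrow(pts)
  ctr <- colSums(pts) / n
  S <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- pts[i, ] - ctr
    S <- S + tcrossprod(d)
  }
  S <- S / (n - 1)
  sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Small sphere phantom reused across tests (radius 16 on a 40^3 grid).
small_sphere <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_phantom(phantom_spec(shape = "sphere", semi_axes = 16,
                                          grid = 40, spacing = 0.01))
    }
    cache
  }
})

# Brute-force phylogenetic covariance: shared path length of each tip pair
# via node depths and ape's MRCA table.
brute_force_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  m <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) depth[i] else depth[m[i, j]]
    }
  }
  C
}

# Deterministic tiny trait table with both life stages.
toy_trait_table <- function(n = 12, seed = 1, shift = 0) {
  tr <- make_tree(n, seed = seed)
  sp <- tr$tip.label
  set.seed(seed + 100)
  tad <- data.frame(
    species = sp, life_stage = "tadpole",
    adult_environment = rep(c("aquatic", "terrestrial"), length.out = n),
    anisotropy = runif(n, 0.05, 0.15), sphericity = runif(n, 0.9, 0.98),
    elongation = runif(n, 0.9, 0.96))
  ad <- tad
  ad$life_stage <- "adult"
  ad$anisotropy <- pmin(ad$anisotropy + shift, 1)
  ad$habit <- rep(c("aquatic", "scansorial", "ground-dwelling"),
                  length.out = n)
  ad$activity <- rep(c("nocturnal", "non-nocturnal"), length.out = n)
  ad$lens_diameter_mm <- runif(n, 1, 3)
  ad$eye_diameter_mm <- ad$lens_diameter_mm / 0.5
  tad$habit <- NA; tad$activity <- NA
  tad$lens_diameter_mm <- NA_real_; tad$eye_diameter_mm <- NA_real_
  list(table = rbind(ad, tad), tree = tr)
}
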