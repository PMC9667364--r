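test_that("welch_t matches a hand computation of the Welch formulas", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  w <- welch_t(x, y)
  # independent oracle: the Welch statistic and Satterthwaite d.f. by hand
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p.value, p_hand, tolerance = 1e-12)
})

test_that("welch_t degenerate and symmetric cases behave as expected", {
  x <- c(1, 2, 3, 4)
  w <- welch_t(x, x)
  expect_equal(w$t, 0)
  expect_equal(w$p.value, 1)
  # equal variances and equal n: Welch t coincides with pooled Student t
  set.seed(1)
  a <- rnorm(10); b <- rnorm(10)
  pooled <- t.test(a, b, var.equal = TRUE)
  expect_equal(welch_t(a, b)$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("pca proportions equal the variance shares of uncorrelated data", {
  # four points giving exactly orthogonal columns with variances 3 > 2 > 1
  v1 <- c(-1, -1, 1, 1); v2 <- c(-1, 1, -1, 1); v3 <- c(-1, 1, 1, -1)
  X <- cbind(a = v1 * sqrt(3 / var(v1)), b = v2 * sqrt(2 / var(v2)),
             c = v3 * sqrt(1 / var(v3)))
  p <- pca(X, scale = FALSE)
  expect_equal(unname(p$proportion), c(3, 2, 1) / 6, tolerance = 1e-12)
})

test_that("pca scores invert back to the data and match prcomp", {
  set.seed(2)
  X <- matrix(rnorm(60), 15, 4,
              dimnames = list(NULL, c("anisotropy", "sphericity",
                                      "elongation", "flatness")))
  for (sc in c(TRUE, FALSE)) {
    p <- pca(X, scale = sc)
    expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
    expect_equal(crossprod(p$loadings), diag(4), ignore_attr = TRUE,
                 tolerance = 1e-10)
    rec <- p$scores %*% t(p$loadings)
    if (sc) rec <- sweep(rec, 2, p$scale, `*`)
    rec <- sweep(rec, 2, p$center, `+`)
    expect_equal(unname(rec), unname(X), tolerance = 1e-10)
    pr <- prcomp(X, scale. = sc)
    expect_equal(abs(unname(p$loadings)), abs(unname(pr$rotation)),
                 tolerance = 1e-8)
  }
})

test_that("pca sign convention pins anisotropy negative on PC1", {
  set.seed(3)
  X <- matrix(rnorm(80), 20, 4,
              dimnames = list(NULL, c("anisotropy", "sphericity",
                                      "elongation", "flatness")))
  p <- pca(X, scale = TRUE)
  expect_lte(p$loadings["anisotropy", 1], 0)
  expect_error(pca(cbind(X, k = rep(1, 20)), scale = TRUE), "constant")
  expect_error(pca(X[1, , drop = FALSE]), ">= 2")
})

test_that("collinearity screen drops the lower-priority member of tight pairs", {
  set.seed(4)
  ani <- runif(30, 0, 0.5)
  X <- cbind(anisotropy = ani, flatness = 1 - ani,
             sphericity = runif(30), elongation = runif(30))
  sc <- collinearity_screen(X, threshold = 0.9)
  expect_setequal(sc$retained, c("anisotropy", "sphericity", "elongation"))
  expect_identical(sc$dropped, "flatness")
  expect_equal(sc$decisions$r[1], -1, tolerance = 1e-12)

  indep <- matrix(rnorm(120), 30, 4,
                  dimnames = list(NULL, c("anisotropy", "flatness",
                                          "sphericity", "elongation")))
  expect_length(collinearity_screen(indep, threshold = 0.9)$dropped, 0)
  expect_length(collinearity_screen(X, threshold = 2)$dropped, 0)
})

test_that("compact letters connect exactly the non-different level pairs", {
  levs <- c("A", "B", "C", "D")
  sig <- data.frame(a = c("A", "A"), b = c("C", "D"))
  lt <- compact_letters(levs, sig)
  # A differs from C and D; B bridges both groups
  expect_false(any(strsplit(lt[["A"]], "")[[1]] %in%
                     strsplit(lt[["C"]], "")[[1]]))
  expect_false(any(strsplit(lt[["A"]], "")[[1]] %in%
                     strsplit(lt[["D"]], "")[[1]]))
  expect_true(any(strsplit(lt[["B"]], "")[[1]] %in%
                    strsplit(lt[["A"]], "")[[1]]))
  expect_true(any(strsplit(lt[["B"]], "")[[1]] %in%
                    strsplit(lt[["C"]], "")[[1]]))
  # no significant pairs: everyone shares one letter
  expect_true(all(compact_letters(levs, NULL) == "a"))
})
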