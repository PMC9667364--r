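make_pgls_fixture <- function(n = 32, seed = 5) {
  tr <- make_tree(n, seed = seed)
  y <- simulate_bm(tr, rate = 0.3, lambda = 0.8, seed = seed + 1)[, 1]
  set.seed(seed + 2)
  d <- data.frame(species = names(y), y = y, x = rnorm(n),
                  g = factor(sample(c("A", "B", "C"), n, TRUE)))
  list(tree = tr, data = d)
}

test_that("PGLS with lambda = 0 reproduces OLS exactly", {
  fx <- make_pgls_fixture()
  fit <- fit_pgls(y ~ x + g, fx$data, fx$tree, lambda = 0)
  ols <- lm(y ~ x + g, fx$data)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  s <- summary(ols)
  expect_equal(fit$coefficients$std.error, unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$F, unname(s$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$r.squared.adj, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(
    fit$p.value,
    unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE)),
    tolerance = 1e-10)
})

test_that("fixed-lambda PGLS matches an independent GLS implementation", {
  fx <- make_pgls_fixture()
  for (lam in c(0.4, 1)) {
    fit <- fit_pgls(y ~ x + g, fx$data, fx$tree, lambda = lam)
    ref <- nlme::gls(y ~ x + g, data = fx$data,
                     correlation = ape::corPagel(lam, phy = fx$tree,
                                                  form = ~species,
                                                  fixed = TRUE))
    expect_equal(coef(fit), coef(ref), tolerance = 1e-8)
    expect_equal(fit$coefficients$std.error,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)
  }
})

test_that("ML and REML lambda estimates match the independent optimizer", {
  fx <- make_pgls_fixture(n = 32, seed = 5)
  for (reml in c(FALSE, TRUE)) {
    fit <- fit_pgls(y ~ x, fx$data, fx$tree, lambda = "ML", REML = reml)
    ref <- nlme::gls(y ~ x, data = fx$data,
                     correlation = ape::corPagel(0.5, phy = fx$tree,
                                                  form = ~species),
                     method = if (reml) "REML" else "ML")
    lam_ref <- as.numeric(coef(ref$modelStruct$corStruct,
                               unconstrained = FALSE))
    expect_equal(fit$lambda, lam_ref, tolerance = 1e-4)
    expect_equal(coef(fit), coef(ref), tolerance = 1e-6)
  }
})

test_that("the grid-plus-refinement search never undershoots the independent optimizer", {
  # this fixture has a near-zero terminal branch that puts the global ML
  # optimum on the lambda = 1 boundary; a pure local search can miss it
  fx <- make_pgls_fixture(n = 40, seed = 7)
  fit <- fit_pgls(y ~ x, fx$data, fx$tree, lambda = "ML")
  ref <- nlme::gls(y ~ x, data = fx$data,
                   correlation = ape::corPagel(0.5, phy = fx$tree,
                                               form = ~species),
                   method = "ML")
  expect_gte(fit$logLik, as.numeric(logLik(ref)) - 1e-6)
})

test_that("on a star tree lambda is unidentifiable and the fit equals OLS", {
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("s%02d:1", 1:20), collapse = ","), ");"))
  set.seed(3)
  d <- data.frame(species = star$tip.label, y = rnorm(20), x = rnorm(20))
  fit <- fit_pgls(y ~ x, d, star, lambda = "ML")
  expect_true(fit$profile$flat)
  expect_equal(coef(fit), coef(lm(y ~ x, d)), tolerance = 1e-8)
})

test_that("PGLS estimates are invariant to row order of the data", {
  fx <- make_pgls_fixture()
  fit1 <- fit_pgls(y ~ x + g, fx$data, fx$tree, lambda = "ML")
  shuffled <- fx$data[sample(nrow(fx$data)), ]
  fit2 <- fit_pgls(y ~ x + g, shuffled, fx$tree, lambda = "ML")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-10)
  expect_equal(fit1$F, fit2$F, tolerance = 1e-10)
  expect_equal(fit1$lambda, fit2$lambda, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly naming the aliased columns", {
  fx <- make_pgls_fixture()
  fx$data$x2 <- 2 * fx$data$x
  expect_error(fit_pgls(y ~ x + x2, fx$data, fx$tree, lambda = 0),
               "aliased.*x2")
})

test_that("species absent from the tree are reported by name", {
  fx <- make_pgls_fixture(n = 10)
  fx$data$species[3] <- "not_a_frog"
  expect_error(fit_pgls(y ~ x, fx$data, fx$tree), "not_a_frog")
})

test_that("missing data are dropped listwise and recorded", {
  fx <- make_pgls_fixture(n = 20)
  fx$data$x[c(4, 9)] <- NA
  fit <- fit_pgls(y ~ x, fx$data, fx$tree, lambda = 0)
  expect_equal(fit$n, 18)
  expect_setequal(fit$dropped, fx$data$species[c(4, 9)])
  expect_equal(fit$df[2], 16)  # n - p
})

test_that("term test of a lone factor equals the overall F", {
  fx <- make_pgls_fixture(n = 30, seed = 11)
  fit <- fit_pgls(y ~ g, fx$data, fx$tree, lambda = 0.3)
  tt <- pgls_term_test(fit, "g")
  expect_equal(tt$F, fit$F, tolerance = 1e-10)
  expect_equal(tt$df, fit$df)
})

test_that("releveling changes the reference but not the fitted model", {
  fx <- make_pgls_fixture(n = 30, seed = 13)
  fit <- fit_pgls(y ~ g, fx$data, fx$tree, lambda = "ML")
  re <- pgls_relevel(fit, "g", "B")
  expect_equal(re$F, fit$F, tolerance = 1e-8)
  # new intercept = old intercept + old coefficient of level B
  expect_equal(unname(coef(re)["(Intercept)"]),
               unname(coef(fit)["(Intercept)"] + coef(fit)["gB"]),
               tolerance = 1e-8)
})

test_that("recovered regression effects track a known simulated habit shift", {
  # smaller-scale mirror of the full recovery experiment: effect +0.15
  tr <- make_tree(96, seed = 21)
  est <- vapply(1:25, function(i) {
    y <- simulate_bm(tr, rate = 0.003, lambda = 0.5, seed = 300 + i)[, 1]
    set.seed(600 + i)
    env <- factor(sample(c("aquatic", "terrestrial"), 96, TRUE, c(0.3, 0.7)))
    y <- y + ifelse(env == "terrestrial", 0.15, 0)
    d <- data.frame(species = names(y), y = y, env = env)
    unname(coef(fit_pgls(y ~ env, d, tr, lambda = "ML"))["envterrestrial"])
  }, 0)
  expect_lt(abs(mean(est) - 0.15),
            max(3 * sd(est) / sqrt(length(est)), 0.01))
})
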