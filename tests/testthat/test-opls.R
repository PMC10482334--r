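test_that("pure class-aligned signal gives a saturated, ortho-free model", {
  set.seed(3)
  y <- rep(c(1, -1), each = 6)
  v <- rnorm(20)
  X <- y %*% t(v)  # X = y v': one direction, perfectly class-aligned
  fit <- fit_opls_da(X, ifelse(y > 0, "test", "control"), n_ortho = 3,
                     folds = 3)
  expect_equal(fit$model$n_ortho, 0)  # nothing orthogonal to extract
  expect_equal(fit$diagnostics$r2x_pred, 1, tolerance = 1e-10)
  expect_equal(fit$diagnostics$r2y, 1, tolerance = 1e-10)
  expect_equal(fit$diagnostics$r2x_residual, 0, tolerance = 1e-10)
})

test_that("n_ortho = 0 reduces exactly to 1-component PLS1-DA", {
  inst <- make_planted_instance(14, 25, seed = 21)
  fit <- fit_opls_da(inst$X, inst$labels, n_ortho = 0, folds = 7)
  pls <- oracle_pls1(inst$X, inst$y)
  expect_equal(unname(fit$model$t_pred), pls$t, tolerance = 1e-12)
  expect_equal(unname(fit$model$p_pred), pls$p, tolerance = 1e-12)
  expect_equal(fit$model$b, pls$b, tolerance = 1e-12)
  pred <- predict(fit$model, inst$X)
  expect_equal(unname(pred$y_hat), pls$y_hat, tolerance = 1e-12)
})

test_that("predictive component matches the OSC+PLS oracle on planted data", {
  for (seed in 1:10) {
    n <- sample(12:30, 1); p <- sample(8:100, 1)
    inst <- make_planted_instance(n, p, seed = seed)
    fit <- fit_opls_da(inst$X, inst$labels, n_ortho = 1, folds = 4)
    orc <- oracle_osc_pls(inst$X, inst$y, k = 1)
    sgn <- sign(sum(fit$model$t_pred * orc$t))
    expect_equal(unname(fit$model$t_pred), sgn * orc$t, tolerance = 1e-6)
    expect_equal(unname(fit$model$p_pred), sgn * orc$p, tolerance = 1e-6)
  }
})

test_that("model geometry invariants hold after fitting", {
  inst <- make_planted_instance(20, 40, seed = 5)
  fit <- fit_opls_da(inst$X, inst$labels, n_ortho = 2, folds = 5)
  m <- fit$model
  expect_lte(fit$diagnostics$q2, fit$diagnostics$r2y + 1e-8)
  expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
  for (j in seq_len(m$n_ortho)) {
    expect_equal(sum(m$W_ortho[, j]^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(m$W_ortho[, j] * m$w)), 1e-8)
    expect_lt(abs(sum(m$T_ortho[, j] * m$t_pred)), 1e-8)
  }
})

test_that("R2X fractions conserve variance on random matrices", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(8:25, 1); p <- sample(5:60, 1)
    X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    labels <- rep(c("test", "control"), length.out = n)
    fit <- fit_opls_da(X, labels, n_ortho = sample(0:3, 1), folds = 3)
    d <- fit$diagnostics
    expect_equal(d$r2x_pred + sum(d$r2x_ortho) + d$r2x_residual, 1,
                 tolerance = 1e-8)
  }
})

test_that("flipping the class encoding flips signs but not the model", {
  inst <- make_planted_instance(16, 30, seed = 8)
  f1 <- fit_opls_da(inst$X, inst$labels, n_ortho = 1, folds = 4,
                    positive_class = "test")
  f2 <- fit_opls_da(inst$X, inst$labels, n_ortho = 1, folds = 4,
                    positive_class = "control")
  expect_equal(f2$model$t_pred, -f1$model$t_pred, tolerance = 1e-10)
  expect_equal(f2$model$p_pred, -f1$model$p_pred, tolerance = 1e-10)
  expect_equal(f2$diagnostics$r2y, f1$diagnostics$r2y, tolerance = 1e-10)
  expect_equal(f2$diagnostics$q2, f1$diagnostics$q2, tolerance = 1e-10)
  expect_identical(significant_loadings(f2$model),
                   significant_loadings(f1$model))
})

test_that("cross-validated Q2 behaves at both signal extremes", {
  # strong signal: near-perfect prediction
  inst <- make_planted_instance(28, 40, seed = 13)
  expect_gt(cross_validate_q2(inst$X, inst$labels, n_ortho = 1), 0.9)

  # noise-only: Q2 at or below zero in expectation
  set.seed(77)
  q2 <- replicate(100, {
    X <- matrix(rnorm(12 * 10), 12, 10)
    cross_validate_q2(scale(X, scale = FALSE),
                      rep(c("test", "control"), 6), n_ortho = 0, folds = 4)
  })
  expect_lt(mean(q2), 0.05)
})

test_that("cross_validate_q2 validates folds and stratification", {
  inst <- make_planted_instance(12, 10, seed = 2)
  expect_error(cross_validate_q2(inst$X, inst$labels, folds = 1), "folds")
  expect_error(cross_validate_q2(inst$X, inst$labels, folds = 13), "folds")
  labels <- c("test", rep("control", 11))
  expect_error(cross_validate_q2(inst$X, labels, folds = 4), "2 observations")
})

test_that("auto n_ortho picks up a dominant orthogonal direction", {
  d <- study_design(n_features = 300, n_discriminative = 20, n_exclusive = 0,
                    seed = 4)
  sim <- generate_dataset(d)
  tab <- impute_missing(sim$table)
  X <- pareto_scale(t(tab$abundance))
  fit <- fit_opls_da(X, tab$sample_meta$condition, n_ortho = "auto")
  expect_gte(fit$model$n_ortho, 1)
  expect_lte(fit$model$n_ortho, 5)
  expect_gt(fit$diagnostics$r2x_ortho[1], 0.3)
})

test_that("permutation test separates signal from null and is seeded", {
  inst <- make_planted_instance(16, 20, seed = 31)
  perm <- permutation_test(inst$X, inst$labels, n_ortho = 1, n_perm = 50,
                           folds = 4, seed = 123)
  expect_equal(perm$p_value, 1 / 51)
  expect_true(all(perm$permuted_q2 < perm$observed_q2))
  perm2 <- permutation_test(inst$X, inst$labels, n_ortho = 1, n_perm = 50,
                            folds = 4, seed = 123)
  expect_identical(perm$permuted_q2, perm2$permuted_q2)

  set.seed(9)
  Xn <- scale(matrix(rnorm(12 * 8), 12, 8), scale = FALSE)
  pn <- permutation_test(Xn, rep(c("test", "control"), 6), n_ortho = 0,
                         n_perm = 99, folds = 4, seed = 7)
  expect_gt(pn$p_value, 0.05)  # no signal: should not look valid
})

test_that("significant_loadings implements the |loading| > sd rule", {
  skeleton <- function(p_pred) {
    structure(list(p_pred = p_pred), class = "opls_model")
  }
  # hand case: one entry 3.0 among 99 entries 0.1 -> sd approx 0.289
  v <- c(one = 3.0, setNames(rep(0.1, 99), paste0("f", 1:99)))
  expect_equal(unname(sd(v)), 0.290, tolerance = 1e-2)
  expect_identical(significant_loadings(skeleton(v)), "one")
  # all equal and nonzero: sd 0, everything flagged (documented degenerate)
  v2 <- setNames(rep(0.5, 4), paste0("f", 1:4))
  expect_identical(significant_loadings(skeleton(v2)), names(v2))
  # all zero: nothing flagged
  v3 <- setNames(rep(0, 4), paste0("f", 1:4))
  expect_identical(significant_loadings(skeleton(v3)), character(0))
})

test_that("degenerate inputs are rejected", {
  X0 <- matrix(0, 8, 5)
  expect_error(fit_opls_da(X0, rep(c("test", "control"), 4), n_ortho = 0,
                           folds = 2), "variance")
  inst <- make_planted_instance(10, 6, seed = 1)
  expect_error(fit_opls_da(inst$X, rep("test", 10), n_ortho = 0), "two classes")
})
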