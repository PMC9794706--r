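test_that("NB-GLM matches its maximum-likelihood identities and oracles", {
  set.seed(71)
  # intercept-only: fitted mean equals the sample mean
  y <- rnbinom(300, size = 2, mu = 6)
  f0 <- fit_nb_glm(y)
  expect_equal(unname(coef(f0)[1]), log(mean(y)), tolerance = 1e-6)

  # Poisson-limit oracle: on Poisson data the NB fit matches a Poisson GLM
  x <- rnorm(400)
  yp <- rpois(400, exp(1 + 0.4 * x))
  fnb <- fit_nb_glm(yp, data.frame(x = x))
  fpo <- glm(yp ~ x, family = poisson())
  expect_equal(unname(coef(fnb)[1:2]), unname(coef(fpo)), tolerance = 1e-3)

  # AIC counts intercept and theta: -2 logLik + 2 (p + 2)
  ynb <- rnbinom(400, size = 3, mu = exp(1 + 0.5 * x))
  f <- fit_nb_glm(ynb, data.frame(x = x))
  expect_equal(f$aic, -2 * as.numeric(logLik(f$glm)) + 2 * 3)
  expect_equal(f$aic, AIC(f$glm))
  expect_lte(f$resid_deviance, f$null_deviance + 1e-8)

  # degenerate response flagged, not fitted
  expect_warning(fd <- fit_nb_glm(rep(4L, 50)), "no variance")
  expect_true(fd$degenerate)
  expect_equal(unname(fd$coefficients[1]), log(4))

  expect_error(fit_nb_glm(c(-1, 2, 3)), "non-negative")
  expect_error(fit_nb_glm(c(1.5, 2, 3)), "non-negative")
})

test_that("NB-GLM recovers generative coefficients on a synthetic scene", {
  scene <- suppressWarnings(simulate_scene(scene_config(seed = 5)))
  tc <- scene$truth_cells
  expect_equal(nrow(tc), 400)
  zcols <- paste0("z_", names(scene$truth$beta))
  f <- fit_nb_glm(tc$count, setNames(tc[zcols], names(scene$truth$beta)))
  est <- coef(f)[-1]
  se <- f$se[-1]
  expect_true(all(abs(est - scene$truth$beta) <= 3 * se))
  expect_true(abs(coef(f)[1] - scene$truth$beta0) <= 3 * f$se[1])
  # strong true effects: full model beats the null by more than the
  # parameter penalty
  f_null <- fit_nb_glm(tc$count)
  expect_lt(f$aic, f_null$aic)
})

test_that("adjusted explained deviance follows its closed form", {
  # boundary identities
  expect_equal(adjusted_explained_deviance(100, 100, 223, 3), 0 * 100 -
                 ((223 - 1) / (223 - 3 - 1) - 1) * 100)
  expect_equal(adjusted_explained_deviance(100, 0, 50, 3), 100)
  # direct formula evaluation: D2 = 0.5, n = 223, p = 3 -> 49.32%
  got <- adjusted_explained_deviance(100, 50, 223, 3)
  expect_equal(round(got, 2), 49.32)
  expect_equal(got, (1 - (222 / 219) * 0.5) * 100)
  expect_error(adjusted_explained_deviance(100, 50, 4, 3), "n > p")
  # adjusted never exceeds the unadjusted percentage for p >= 1
  for (d2 in c(0.1, 0.5, 0.9)) {
    expect_lte(adjusted_explained_deviance(100, 100 * (1 - d2), 60, 4),
               d2 * 100)
  }
})

test_that("VIFs equal the closed-form OLS oracle and flag collinearity", {
  set.seed(42)
  n <- 200
  # columns orthogonal to each other and to the constant -> VIF exactly 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif_screen(X)), rep(1, 3), tolerance = 1e-10)

  # correlated Gaussians with known structure vs. direct 1/(1 - R2)
  S <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3, 3)
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  colnames(Z) <- c("a", "b", "c")
  got <- vif_screen(Z)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(got), oracle, tolerance = 1e-10)
  # cross-check against the field-standard implementation
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(n)
    expect_equal(unname(got),
                 unname(car::vif(lm(y ~ Z[, "a"] + Z[, "b"] + Z[, "c"]))),
                 tolerance = 1e-8)
  }

  # duplicated column -> infinite VIF flagged
  D <- cbind(Z, d = Z[, 1])
  vd <- vif_screen(D)
  expect_true(any(is.infinite(vd)))
  expect_true(attr(vd, "collinear"))

  expect_error(vif_screen(Z[, 1, drop = FALSE]), "two")
  expect_error(vif_screen(cbind(Z, k = rep(1, n))), "constant")
})

test_that("all-subsets enumeration fits 2^p - 1 models ranked by AIC", {
  set.seed(9)
  n <- 150
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  colnames(X) <- c("MAT", "MAP", "PET", "HHET", "DIST")
  y <- rnbinom(n, size = 3, mu = exp(1 + 0.5 * X$PET + 0.3 * X$MAP))

  sel <- all_subsets(y, X)
  expect_equal(sel$n_models, 31)
  expect_equal(nrow(sel$ranking), 31)
  # ranking equals an independent re-sort of the AIC column
  expect_false(is.unsorted(sel$ranking$aic))
  aics <- vapply(sel$fits, `[[`, numeric(1), "aic")
  expect_equal(sel$ranking$aic, aics)
  expect_equal(sel$ranking$aic, sort(aics))
  # best model passes the VIF screen and has the smallest admissible AIC
  expect_true(all(is.null(sel$best$vif) | sel$best$vif < 5))
  admissible <- sel$ranking$aic[sel$ranking$vif_ok]
  expect_equal(sel$best$aic, min(admissible))

  # p = 2 -> 3 models
  sel2 <- all_subsets(y, X[, c("PET", "MAP")])
  expect_equal(sel2$n_models, 3)
  for (p in c(1, 3)) {
    expect_equal(all_subsets(y, X[, seq_len(p), drop = FALSE])$n_models,
                 2^p - 1)
  }

  # stepwise mode is bounded below by the exhaustive optimum and here,
  # with clean signal, finds it
  sel_sw <- all_subsets(y, X, method = "stepwise")
  expect_gte(sel_sw$stepwise$aic, sel_sw$ranking$aic[1] - 1e-6)
  expect_equal(sel_sw$stepwise$aic, sel_sw$ranking$aic[1], tolerance = 1e-6)
  expect_true(all(sel_sw$stepwise$variables %in% colnames(X)))
})

test_that("path coefficients reduce to standardized regression identities", {
  set.seed(13)
  n <- 500
  # single predictor: coefficient = correlation, R2 = r^2
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n, 0, 0.8)
  pf <- path_model(y, data.frame(x = x))
  r <- cor(x, y)
  expect_equal(unname(coef(pf)["x"]), r, tolerance = 1e-10)
  expect_equal(pf$r_squared_total, r^2, tolerance = 1e-10)

  # orthogonal (centered) predictors: coefficients equal marginal
  # correlations and R2 sums their squares
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  X2 <- data.frame(a = Q[, 1], b = Q[, 2])
  y2 <- 1.5 * X2$a - 1 * X2$b + rnorm(n, 0, 0.5)
  pf2 <- path_model(y2, X2)
  expect_equal(unname(coef(pf2)), c(cor(X2$a, y2), cor(X2$b, y2)),
               tolerance = 1e-10)
  expect_equal(pf2$r_squared_total, sum(coef(pf2)^2), tolerance = 1e-10)

  # independent normal-equations oracle on correlated predictors
  S <- matrix(c(1, .5, .5, 1), 2, 2)
  Z <- matrix(rnorm(n * 2), n, 2) %*% chol(S)
  y3 <- Z %*% c(0.5, -0.3) + rnorm(n)
  pf3 <- path_model(as.numeric(y3), data.frame(p = Z[, 1], q = Z[, 2]))
  Zs <- scale(Z)
  ys <- as.numeric(scale(y3))
  beta_oracle <- solve(crossprod(Zs), crossprod(Zs, ys))
  expect_equal(unname(coef(pf3)), as.numeric(beta_oracle), tolerance = 1e-10)
  pred <- Zs %*% beta_oracle
  r2_oracle <- 1 - sum((ys - pred)^2) / sum(ys^2)
  expect_equal(pf3$r_squared_total, r2_oracle, tolerance = 1e-8)

  expect_error(path_model(y2, data.frame(a = Q[, 1], b = Q[, 1])), "singular")
})

test_that("path model recovers known standardized effects on scene predictors", {
  scene <- suppressWarnings(simulate_scene(scene_config(seed = 2)))
  tc <- scene$truth_cells
  Z <- as.matrix(tc[, c("z_PET", "z_MAP", "z_HHET", "z_DIST")])
  truth <- c(PET = 0.5, MAP = 0.3, HHET = 0.1, DIST = -0.25)
  set.seed(207)
  y <- as.numeric(Z %*% truth) + rnorm(nrow(Z), 0, 0.6)
  pf <- path_model(y, setNames(as.data.frame(Z), names(truth)))
  # standardized truth: rescale the generative coefficients by sd(y)
  truth_std <- truth * apply(Z, 2, sd) / sd(y)
  expect_true(all(abs(coef(pf) - truth_std) <= 3 * pf$se))
  expect_gt(pf$r_squared_total, 0.2)
})
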