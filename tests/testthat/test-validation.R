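test_that("fit statistics satisfy their defining algebra", {
  set.seed(40)
  X <- matrix(rnorm(90), 30, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(30, 0, 0.5)
  fit <- qsar_mlr(X, y = y)
  fs <- fit_statistics(y, fitted(fit), 30, 3)
  rss <- sum((y - fitted(fit))^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fs$R2, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(fs$R2_adj, 1 - (1 - fs$R2) * 29 / 26, tolerance = 1e-12)
  expect_equal(fs$RMSE_tr, sqrt(rss / 30))
  expect_equal(fs$s, sqrt(rss / 26))
  expect_equal(fs$F, (fs$R2 / 3) / ((1 - fs$R2) / 26))
  # perfect fit limits
  perf <- fit_statistics(y, y, 30, 3)
  expect_equal(perf$R2, 1)
  expect_equal(perf$RMSE_tr, 0)
  expect_equal(perf$CCC_tr, 1)
  expect_error(fit_statistics(rep(1, 10), rep(1, 10), 10, 2), "variance")
})

test_that("Lin's CCC equals Pearson r when moments match", {
  set.seed(41)
  x <- rnorm(50)
  # construct y with identical mean and variance but imperfect correlation
  z <- rnorm(50)
  y <- x * 0.6 + z * 0.8
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(x)
  n <- length(x)
  # population-variance CCC vs Pearson (equal means/vars => CCC = r)
  expect_equal(ccc(x, y), cor(x, y), tolerance = 1e-10)
  expect_lte(abs(ccc(x, rev(x))), 1)
})

test_that("LOO shortcut equals explicit refits (hat-matrix identity)", {
  set.seed(42)
  X <- matrix(rnorm(80), 20, 4)
  y <- drop(X %*% c(1, 0.5, -1, 2)) + rnorm(20, 0, 0.4)
  short <- loo_cv(X, y)
  refit <- loo_cv(X, y, refit = TRUE)
  expect_equal(short$predictions, refit$predictions, tolerance = 1e-8)
  expect_equal(short$Q2_LOO, refit$Q2_LOO, tolerance = 1e-10)
  # defining algebra
  expect_equal(short$RMSE_cv, sqrt(short$PRESS_cv / 20), tolerance = 1e-12)
  # exact linear data: Q2 = 1
  y0 <- drop(X %*% c(1, 1, 1, 1))
  expect_equal(loo_cv(X, y0)$Q2_LOO, 1, tolerance = 1e-10)
  # Q2_LOO <= R2 for OLS on the same data
  fit <- qsar_mlr(X, y = y)
  expect_lte(short$Q2_LOO, summary(fit)$fit$R2)
})

test_that("leave-many-out behaves and is reproducible", {
  set.seed(43)
  X <- matrix(rnorm(150), 30, 5)
  y <- drop(X %*% c(1, -1, 0.5, 2, -0.5)) + rnorm(30, 0, 0.3)
  a <- lmo_cv(X, y, iters = 200, seed = 7)
  b <- lmo_cv(X, y, iters = 200, seed = 7)
  expect_identical(a$Q2_LMO, b$Q2_LMO)
  # noiseless data: Q2_LMO = 1
  y0 <- drop(X %*% c(1, 1, 1, 1, 1))
  expect_equal(lmo_cv(X, y0, iters = 50, seed = 1)$Q2_LMO, 1,
               tolerance = 1e-10)
  # small held-out fraction approaches the LOO result in expectation
  loo <- loo_cv(X, y)$Q2_LOO
  lmo_small <- lmo_cv(X, y, fraction = 1 / 30, iters = 2000, seed = 11)
  expect_equal(lmo_small$Q2_LMO, loo, tolerance = 0.05)
  expect_error(lmo_cv(X, y, iters = 10), "seed")
})

test_that("y-scrambling destroys genuine signal but not noise fits", {
  set.seed(44)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4)
  y_signal <- drop(X %*% c(2, -1.5, 1, 0.5)) + rnorm(n, 0, 0.3)
  fit <- qsar_mlr(X, y = y_signal)
  r2_real <- summary(fit)$fit$R2
  ys <- y_scramble(X, y_signal, iters = 200, seed = 5)
  expect_lt(ys$R2_Yscr, r2_real)
  expect_lt(ys$Q2_Yscr, 0)
  # pure-noise response: scrambling changes nothing in expectation
  y_noise <- rnorm(n)
  fitn <- qsar_mlr(X, y = y_noise)
  ysn <- y_scramble(X, y_noise, iters = 400, seed = 6)
  expect_equal(ysn$R2_Yscr, summary(fitn)$fit$R2, tolerance = 0.12)
  # determinism
  expect_identical(y_scramble(X, y_signal, iters = 50, seed = 9)$R2_Yscr,
                   y_scramble(X, y_signal, iters = 50, seed = 9)$R2_Yscr)
})

test_that("external validation matches an independent formula oracle", {
  set.seed(45)
  X <- matrix(rnorm(100), 25, 4)
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(25, 0, 0.4)
  fit <- qsar_mlr(X[1:18, ], y = y[1:18])
  Xe <- X[19:25, ]; ye <- y[19:25]
  ev <- external_validation(fit, Xe, ye)
  # hand-coded formula oracle
  pred <- drop(cbind(1, Xe) %*% coef(fit))
  press <- sum((ye - pred)^2)
  expect_equal(ev$PRESS_ext, press, tolerance = 1e-10)
  expect_equal(ev$RMSE_ext, sqrt(press / 7), tolerance = 1e-12)
  expect_equal(ev$Q2_F1, 1 - press / sum((ye - mean(y[1:18]))^2))
  expect_equal(ev$Q2_F2, 1 - press / sum((ye - mean(ye))^2))
  expect_equal(ev$Q2_F3,
               1 - (press / 7) / (sum((y[1:18] - mean(y[1:18]))^2) / 18))
  # constant prediction gives Q2_F2 = 0
  fit0 <- fit
  fit0$coefficients[] <- 0
  fit0$coefficients[1] <- mean(ye)
  expect_equal(external_validation(fit0, Xe, ye)$Q2_F2, 0, tolerance = 1e-10)
  expect_error(external_validation(fit, Xe[1:2, ], ye[1:2]), "n_ext")
})

test_that("Q2_F2 <= Q2_F1 on random instances", {
  set.seed(46)
  for (rep in 1:100) {
    n_tr <- 15; n_ext <- 6
    X <- matrix(rnorm((n_tr + n_ext) * 2), n_tr + n_ext, 2)
    y <- drop(X %*% rnorm(2)) + rnorm(n_tr + n_ext, 0, runif(1, 0.1, 2))
    fit <- qsar_mlr(X[1:n_tr, ], y = y[1:n_tr])
    ev <- external_validation(fit, X[-(1:n_tr), ], y[-(1:n_tr)])
    expect_lte(ev$Q2_F2, ev$Q2_F1 + 1e-12)
  }
})

test_that("validation_report bundles all blocks and respects PRESS algebra", {
  set.seed(47)
  X <- matrix(rnorm(120), 30, 4)
  colnames(X) <- paste0("d", 1:4)
  y <- drop(X %*% c(1, -1, 2, 0.5)) + rnorm(30, 0, 0.4)
  fit <- qsar_mlr(X[1:22, ], y = y[1:22])
  rep_ <- validation_report(fit, X_ext = X[23:30, ], y_ext = y[23:30],
                            lmo_iters = 100, yscr_iters = 100, seed = 3)
  expect_s3_class(rep_, "validation_report")
  expect_equal(rep_$internal$RMSE_cv,
               sqrt(rep_$internal$PRESS_cv / 22), tolerance = 1e-12)
  expect_equal(rep_$external$RMSE_ext,
               sqrt(rep_$external$PRESS_ext / 8), tolerance = 1e-12)
  expect_true(all(abs(c(rep_$fit$CCC_tr, rep_$internal$CCC_cv,
                        rep_$external$CCC_ext)) <= 1))
  expect_output(print(rep_), "External validation")
})
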