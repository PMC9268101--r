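#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements, penalizing both dispersion
#' and location shifts; equals the Pearson correlation when the means and
#' variances of the two vectors match exactly.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx <- sum((x - mx)^2) / n; sy <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx + sy + (mx - my)^2)
}

#' Fit statistics of a regression
#'
#' Computes the usual QSAR fit block from observed and fitted responses:
#' `R2 = 1 - RSS/TSS`, adjusted R2, `RMSE = sqrt(RSS/n)`, MAE, the standard
#' error of estimate `s = sqrt(RSS/(n-k-1))`, the F statistic
#' `(R2/k) / ((1-R2)/(n-k-1))`, Friedman's lack-of-fit
#' `LOF = (RSS/n) / (1 - (k + 1 + d k)/n)^2` and Lin's concordance
#' correlation.
#'
#' @param y observed response.
#' @param yhat fitted response.
#' @param n,k observations and descriptor count.
#' @param lof_d smoothing factor d in Friedman's LOF (default 0.5).
#' @return list with `R2`, `R2_adj`, `RMSE_tr`, `MAE_tr`, `s`, `F`, `LOF`,
#'   `CCC_tr`.
#' @export
fit_statistics <- function(y, yhat, n = length(y), k, lof_d = 0.5) {
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) stop("zero-variance response")
  rss <- sum((y - yhat)^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  lof_denom <- (1 - (k + 1 + lof_d * k) / n)^2
  list(R2 = r2,
       R2_adj = r2_adj,
       RMSE_tr = sqrt(rss / n),
       MAE_tr = mean(abs(y - yhat)),
       s = sqrt(rss / (n - k - 1)),
       F = (r2 / k) / ((1 - r2) / (n - k - 1)),
       LOF = (rss / n) / lof_denom,
       CCC_tr = ccc(y, yhat))
}

#' Leave-one-out cross-validation of an OLS fit
#'
#' Each compound is predicted by a model fitted without it. For OLS this is
#' computed exactly through the hat-matrix shortcut
#' `e_i / (1 - h_ii)`; set `refit = TRUE` to use explicit refits instead
#' (identical up to numerical noise, and the path used by the algebraic
#' identity test).
#'
#' @param X descriptor matrix / data.frame.
#' @param y response.
#' @param refit use explicit per-fold refits instead of the shortcut.
#' @return list with `Q2_LOO`, `PRESS_cv`, `RMSE_cv`, `MAE_cv`, `CCC_cv` and
#'   the vector of out-of-fold `predictions`.
#' @export
loo_cv <- function(X, y, refit = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= ncol(X) + 2L) stop("need n > k + 2 for LOO")
  if (refit) {
    preds <- vapply(seq_len(n), function(i) {
      fit <- tryCatch(qsar_mlr(X[-i, , drop = FALSE], y = y[-i]),
                      error = function(e)
                        stop("LOO refit failed leaving out row ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      predict(fit, as.data.frame(X)[i, , drop = FALSE])
    }, 0)
  } else {
    fit <- qsar_mlr(X, y = y)
    h <- leverages(X)
    preds <- y - fit$residuals / (1 - h)
  }
  press <- sum((y - preds)^2)
  tss <- sum((y - mean(y))^2)
  list(Q2_LOO = 1 - press / tss,
       PRESS_cv = press,
       RMSE_cv = sqrt(press / n),
       MAE_cv = mean(abs(y - preds)),
       CCC_cv = ccc(y, preds),
       predictions = preds)
}

#' Leave-many-out cross-validation
#'
#' Repeatedly holds out a random fraction of the training compounds, refits,
#' and scores `Q2 = 1 - PRESS/TSS` on the held-out block (TSS about the full
#' training mean, the convention matching leave-one-out). Degenerate
#' subsamples (rank-deficient refits) are skipped and counted.
#'
#' @param X descriptor matrix / data.frame.
#' @param y response.
#' @param fraction held-out fraction per iteration (default 0.3).
#' @param iters iterations (default 2000).
#' @param seed integer seed.
#' @return list with `Q2_LMO` (mean), `q2` (per-iteration values), `skipped`.
#' @export
lmo_cv <- function(X, y, fraction = 0.3, iters = 2000L, seed) {
  if (missing(seed)) stop("lmo_cv requires an explicit integer seed")
  X <- as.matrix(X)
  n <- nrow(X)
  m <- max(1L, round(fraction * n))
  if (n - m <= ncol(X) + 1L) stop("held-in set too small for the refit")
  set.seed(seed)
  q2 <- rep(NA_real_, iters)
  press_all <- 0; tss_all <- 0
  tss_mean <- mean(y)
  for (it in seq_len(iters)) {
    out <- sample.int(n, m)
    fit <- tryCatch(qsar_mlr(X[-out, , drop = FALSE], y = y[-out]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    preds <- predict(fit, as.data.frame(X)[out, , drop = FALSE])
    press <- sum((y[out] - preds)^2)
    tss <- sum((y[out] - tss_mean)^2)
    if (tss < 1e-12) next
    q2[it] <- 1 - press / tss
    press_all <- press_all + press
    tss_all <- tss_all + tss
  }
  ok <- !is.na(q2)
  # pooled aggregation (1 - sum PRESS / sum TSS): unlike the mean of the
  # per-iteration ratios it converges to the leave-one-out Q2 as the
  # held-out fraction shrinks to 1/n
  list(Q2_LMO = 1 - press_all / tss_all, q2 = q2[ok], skipped = sum(!ok))
}

#' Y-scrambling (response randomization) test
#'
#' Refits the model on randomly permuted responses and reports the mean R2
#' and mean leave-one-out Q2 of the scrambled models, plus the mean RMSE of
#' the scrambled fits. A real structure-activity relationship shows scrambled
#' R2 far below the true fit and scrambled Q2 below zero.
#'
#' @param X descriptor matrix / data.frame.
#' @param y response.
#' @param iters scrambling iterations (default 2000).
#' @param seed integer seed.
#' @return list with `R2_Yscr`, `Q2_Yscr`, `RMSE_AV_Yscr` (means) and the
#'   per-iteration vectors `r2`, `q2`.
#' @export
y_scramble <- function(X, y, iters = 2000L, seed) {
  if (missing(seed)) stop("y_scramble requires an explicit integer seed")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  r2 <- numeric(iters); q2 <- numeric(iters); rmse <- numeric(iters)
  h <- leverages(X)
  Xa <- cbind(1, X)
  qr_x <- qr(Xa)
  for (it in seq_len(iters)) {
    ys <- sample(y)
    res <- qr.resid(qr_x, ys)
    tss <- sum((ys - mean(ys))^2)
    r2[it] <- 1 - sum(res^2) / tss
    press <- sum((res / (1 - h))^2)
    q2[it] <- 1 - press / tss
    rmse[it] <- sqrt(mean(res^2))
  }
  list(R2_Yscr = mean(r2), Q2_Yscr = mean(q2), RMSE_AV_Yscr = mean(rmse),
       r2 = r2, q2 = q2)
}

# origin-forced r2m agreement metric for one direction
r2m_one <- function(obs, pred) {
  if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12) return(NA_real_)
  r2 <- stats::cor(obs, pred)^2
  k_slope <- sum(obs * pred) / sum(pred^2)
  r0_num <- sum((obs - k_slope * pred)^2)
  r0 <- 1 - r0_num / sum((obs - mean(obs))^2)
  r2 * (1 - sqrt(abs(r2 - r0)))
}

#' External validation statistics
#'
#' Predictive metrics on an external (test) set: `PRESS_ext`, `RMSE_ext`,
#' `MAE_ext`, squared Pearson correlation `R2_ext`, the three predictive
#' determination coefficients
#' `Q2_F1 = 1 - PRESS / sum((y_ext - ybar_train)^2)`,
#' `Q2_F2 = 1 - PRESS / sum((y_ext - ybar_ext)^2)`,
#' `Q2_F3 = 1 - (PRESS/n_ext) / (TSS_train/n_train)`,
#' Lin's concordance `CCC_ext`, and the origin-forced agreement metrics
#' `r2m_aver` / `r2m_delta` (mean and absolute difference of the two
#' regression directions).
#'
#' @param model a fitted `qsar_mlr` (must carry training mean and TSS,
#'   i.e. come from [qsar_mlr()] rather than [published_tlr7_model()]).
#' @param X_ext external descriptor table.
#' @param y_ext external responses (n >= 3).
#' @return list of the metrics above plus `predictions`.
#' @export
external_validation <- function(model, X_ext, y_ext) {
  if (length(y_ext) < 3L) stop("external validation needs n_ext >= 3")
  if (!is.finite(model$y_mean) || !is.finite(model$tss))
    stop("model carries no training response summary")
  preds <- predict(model, as.data.frame(X_ext))
  n_ext <- length(y_ext)
  press <- sum((y_ext - preds)^2)
  q2f1 <- 1 - press / sum((y_ext - model$y_mean)^2)
  q2f2 <- 1 - press / sum((y_ext - mean(y_ext))^2)
  q2f3 <- 1 - (press / n_ext) / (model$tss / model$n)
  r2_ext <- if (stats::sd(preds) < 1e-12) NA_real_
            else stats::cor(y_ext, preds)^2
  list(RMSE_ext = sqrt(press / n_ext),
       MAE_ext = mean(abs(y_ext - preds)),
       PRESS_ext = press,
       R2_ext = r2_ext,
       Q2_F1 = q2f1, Q2_F2 = q2f2, Q2_F3 = q2f3,
       CCC_ext = ccc(y_ext, preds),
       r2m_aver = (r2m_one(y_ext, preds) + r2m_one(preds, y_ext)) / 2,
       r2m_delta = abs(r2m_one(y_ext, preds) - r2m_one(preds, y_ext)),
       predictions = preds)
}

#' Full validation report for a fitted model
#'
#' Bundles the fit, internal-validation and external-validation blocks into
#' one object. Internal validation runs leave-one-out, leave-many-out (30%
#' out) and y-scrambling; external validation needs a held-out set.
#'
#' @param model a fitted `qsar_mlr`.
#' @param X_ext,y_ext optional external set.
#' @param lmo_iters,yscr_iters iteration counts (defaults 2000).
#' @param seed integer seed for the randomized blocks.
#' @return object of class `validation_report` (a list with elements `fit`,
#'   `internal`, `external`).
#' @export
validation_report <- function(model, X_ext = NULL, y_ext = NULL,
                              lmo_iters = 2000L, yscr_iters = 2000L, seed) {
  if (missing(seed)) stop("validation_report requires an explicit seed")
  if (is.null(model$X)) stop("model carries no training data")
  fit <- fit_statistics(model$y, model$fitted, model$n, model$k)
  loo <- loo_cv(model$X, model$y)
  lmo <- lmo_cv(model$X, model$y, iters = lmo_iters, seed = seed)
  ys <- y_scramble(model$X, model$y, iters = yscr_iters, seed = seed + 1L)
  internal <- c(loo[c("Q2_LOO", "RMSE_cv", "MAE_cv", "PRESS_cv", "CCC_cv")],
                list(Q2_LMO = lmo$Q2_LMO, R2_Yscr = ys$R2_Yscr,
                     Q2_Yscr = ys$Q2_Yscr, RMSE_AV_Yscr = ys$RMSE_AV_Yscr))
  external <- if (!is.null(X_ext)) {
    ev <- external_validation(model, X_ext, y_ext)
    ev[setdiff(names(ev), "predictions")]
  }
  structure(list(fit = fit, internal = internal, external = external),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  block <- function(name, lst) {
    if (is.null(lst)) return()
    cat(name, ":\n", sep = "")
    vals <- vapply(lst, function(v) format(round(v, digits)), "")
    cat(paste0("  ", format(names(lst), width = 14), vals, collapse = "\n"),
        "\n")
  }
  cat("QSAR validation report\n")
  block("Fit", x$fit)
  block("Internal validation", x$internal)
  block("External validation", x$external)
  invisible(x)
}
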