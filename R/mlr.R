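#' Fit a multiple-linear-regression QSAR model
#'
#' Ordinary-least-squares fit of an activity (pIC50, log units) on a
#' descriptor table. This is the package's central fitting function; the
#' returned object carries everything the validation and applicability
#' domain machinery needs (training design, response, mean and total sum of
#' squares), and supports the usual `print`, `summary`, `coef`, `predict`,
#' `residuals`, `fitted`, `plot` and `simulate` methods.
#'
#' @param x either a formula (with `data` supplying the variables) or a
#'   numeric data.frame / matrix of descriptors (one row per compound).
#' @param y response vector (pIC50), required when `x` is not a formula.
#' @param data data.frame holding the formula variables.
#' @param ids optional compound ids (default: rownames or row numbers).
#' @param ... unused.
#' @return object of class `qsar_mlr` with components `coefficients`
#'   (intercept first), `descriptors` (names), `X` (training descriptor
#'   matrix), `y`, `fitted`, `residuals`, `ids`, `y_mean`, `tss`, `n`, `k`.
#' @examples
#' X <- data.frame(a = rnorm(20), b = rnorm(20))
#' fit <- qsar_mlr(X, y = 1 + 2 * X$a - X$b + rnorm(20, sd = 0.1))
#' coef(fit)
#' @export
qsar_mlr <- function(x, y = NULL, data = NULL, ids = NULL, ...) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    y <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (is.null(y)) stop("response vector y is required")
  storage.mode(X) <- "double"
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n <= k + 1L)
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")")
  Xa <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xa)
  if (qr_x$rank < ncol(Xa)) {
    drop_cols <- colnames(Xa)[qr_x$pivot[(qr_x$rank + 1L):ncol(Xa)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(Xa %*% beta)
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(n))
  }
  structure(list(coefficients = beta,
                 descriptors = colnames(X),
                 X = X, y = y, fitted = fitted,
                 residuals = y - fitted,
                 ids = as.character(ids),
                 y_mean = mean(y), tss = sum((y - mean(y))^2),
                 n = n, k = k),
            class = "qsar_mlr")
}

#' The published five-descriptor TLR7 antagonist potency model
#'
#' The frozen coefficients of the reported 2D-QSAR equation relating pIC50
#' (micromolar scale) to the five descriptors computed by
#' [descriptor_vector()]:
#' `pIC50 = -6.2155 + 0.1409 VE3sign_D_Dt + 4.1832 SpMin2_Bh_s +
#'  0.0366 P_VSA_logP_5 - 0.9329 Eig02_EA_dm - 0.1016 CATS2D_09_AA`.
#' The object predicts but carries no training data (the underlying
#' 54-compound set is not machine-readable), so leverage-based methods need
#' an explicit training design.
#'
#' @return a `qsar_mlr` object with `X`, `y` set to `NULL`.
#' @examples
#' m <- published_tlr7_model()
#' predict(m, data.frame(VE3sign_D_Dt = 0, SpMin2_Bh_s = 0, P_VSA_logP_5 = 0,
#'                       Eig02_EA_dm = 0, CATS2D_09_AA = 0))  # the intercept
#' @export
published_tlr7_model <- function() {
  beta <- c(`(Intercept)` = -6.2155,
            VE3sign_D_Dt = 0.1409, SpMin2_Bh_s = 4.1832,
            P_VSA_logP_5 = 0.0366, Eig02_EA_dm = -0.9329,
            CATS2D_09_AA = -0.1016)
  structure(list(coefficients = beta, descriptors = names(beta)[-1],
                 X = NULL, y = NULL, fitted = NULL, residuals = NULL,
                 ids = NULL, y_mean = NA_real_, tss = NA_real_,
                 n = NA_integer_, k = 5L),
            class = "qsar_mlr")
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' Predict activities from a fitted QSAR model
#'
#' @param object a `qsar_mlr`.
#' @param newdata data.frame or matrix containing the model's descriptor
#'   columns (extra columns ignored); omitted for training fitted values.
#' @param ... unused.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted))
      stop("model has no training data; supply newdata")
    return(object$fitted)
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$descriptors, names(newdata))
  if (length(missing_cols) == length(object$descriptors) &&
      ncol(newdata) == length(object$descriptors)) {
    # no descriptor name present at all: treat columns as positional
    names(newdata) <- object$descriptors
    missing_cols <- character()
  }
  if (length(missing_cols) > 0L)
    stop("newdata lacks descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(newdata[, object$descriptors, drop = FALSE])
  storage.mode(X) <- "double"
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("QSAR multiple linear regression model\n")
  b <- x$coefficients
  terms <- sprintf("%s %s x %s", ifelse(b[-1] < 0, "-", "+"),
                   format(abs(b[-1]), digits = digits), names(b[-1]))
  cat(sprintf("  pIC50 = %s %s\n", format(b[1], digits = digits),
              paste(terms, collapse = " ")))
  if (!is.null(x$X))
    cat(sprintf("  trained on n = %d compounds, k = %d descriptors\n",
                x$n, x$k))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  if (is.null(object$X))
    stop("summary needs a model with training data")
  fit <- fit_statistics(object$y, object$fitted, object$n, object$k)
  se <- coef_standard_errors(object)
  tval <- object$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = object$n - object$k - 1L,
                        lower.tail = FALSE)
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `t value` = tval, `Pr(>|t|)` = pval)
  structure(list(model = object, fit = fit, coefficients = coefs),
            class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  f <- x$fit
  cat(sprintf(paste0("\nR2 %.4f  R2adj %.4f  RMSE_tr %.4f  MAE_tr %.4f\n",
                     "s %.4f  F %.2f  LOF %.4f  CCC_tr %.4f\n"),
              f$R2, f$R2_adj, f$RMSE_tr, f$MAE_tr, f$s, f$F, f$LOF, f$CCC_tr))
  invisible(x)
}

coef_standard_errors <- function(object) {
  Xa <- cbind(1, object$X)
  s2 <- sum(object$residuals^2) / (object$n - object$k - 1L)
  sqrt(diag(s2 * solve(crossprod(Xa))))
}

#' Simulate responses from a fitted model
#'
#' Draws `nsim` response vectors `X beta + N(0, sigma^2)` at the training
#' design, with `sigma` the training RMSE (or as supplied).
#'
#' @param object a fitted `qsar_mlr`.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param sigma residual standard deviation (default: training RMSE).
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, sigma = NULL,
                              ...) {
  if (is.null(object$X)) stop("simulate needs a model with training data")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- sqrt(mean(object$residuals^2))
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(object$n, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Williams-plot display of a fitted model
#'
#' Plots standardized residuals against leverages for the training set (and
#' an optional external set), with the leverage threshold `h* = 3(k+1)/n`
#' and the +/- `sigma_limit` residual band.
#'
#' @param x a fitted `qsar_mlr`.
#' @param external optional list with components `X` and `y` for a test set.
#' @param sigma_limit residual band half-width in standard-deviation units.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qsar_mlr <- function(x, external = NULL, sigma_limit = 2.5, ...) {
  wd <- williams_data(x, external = external, sigma_limit = sigma_limit)
  hstar <- attr(wd, "h_star")
  graphics::plot(wd$leverage, wd$std_residual,
                 pch = ifelse(wd$set == "training", 19, 1),
                 xlab = "leverage h", ylab = "standardized residual",
                 main = "Williams plot", ...)
  graphics::abline(h = c(-sigma_limit, sigma_limit), lty = 2)
  graphics::abline(v = hstar, lty = 3)
  invisible(wd)
}
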