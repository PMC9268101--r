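#' Leverage (hat) values of query compounds
#'
#' `h_q = x_q' (X'X)^-1 x_q` with the design augmented by an intercept
#' column. For training rows this equals the hat-matrix diagonal; the sum of
#' training leverages equals `k + 1`.
#'
#' @param X_train training descriptor matrix / data.frame.
#' @param X_query query rows (default: the training rows themselves).
#' @return numeric vector of leverages.
#' @export
leverages <- function(X_train, X_query = X_train) {
  Xt <- cbind(1, as.matrix(X_train))
  Xq <- cbind(1, as.matrix(X_query))
  xtx <- crossprod(Xt)
  inv <- tryCatch(solve(xtx), error = function(e)
    stop("X'X is singular; training design is rank deficient", call. = FALSE))
  unname(rowSums((Xq %*% inv) * Xq))
}

#' Leverage threshold h* of the applicability domain
#'
#' `h* = 3 (k + 1) / n` with `k` the descriptor count and `n` the training
#' set size.
#'
#' @param k number of descriptors.
#' @param n number of training compounds.
#' @return numeric scalar.
#' @examples
#' leverage_threshold(5, 38)  # 0.474
#' @export
leverage_threshold <- function(k, n) {
  if (n <= 0) stop("n must be positive")
  3 * (k + 1) / n
}

#' Williams plot data
#'
#' Per-compound leverage and standardized residual for the training set and
#' an optional external set, with outlier flags: `high_leverage` when
#' `h > h*` and `residual_outlier` when the standardized residual exceeds
#' `sigma_limit` in absolute value. Residuals are standardized by their own
#' set's RMSE (training RMSE for training rows, external RMSE for external
#' rows).
#'
#' @param model a fitted `qsar_mlr`.
#' @param external optional list with components `X`, `y` and optionally
#'   `ids`.
#' @param sigma_limit residual band half-width (default 2.5).
#' @return data.frame (id, set, leverage, std_residual, high_leverage,
#'   residual_outlier) with `h_star` as an attribute.
#' @export
williams_data <- function(model, external = NULL, sigma_limit = 2.5) {
  if (is.null(model$X)) stop("model carries no training data")
  h_star <- leverage_threshold(model$k, model$n)
  h_tr <- leverages(model$X)
  rmse_tr <- sqrt(mean(model$residuals^2))
  out <- data.frame(id = model$ids, set = "training", leverage = h_tr,
                    std_residual = model$residuals / rmse_tr)
  if (!is.null(external)) {
    preds <- predict(model, as.data.frame(external$X))
    res <- external$y - preds
    rmse_ext <- sqrt(mean(res^2))
    ids <- external$ids %||% paste0("ext_", seq_along(res))
    out <- rbind(out, data.frame(id = ids, set = "external",
                                 leverage = leverages(model$X, external$X),
                                 std_residual = res / rmse_ext))
  }
  out$high_leverage <- out$leverage > h_star
  out$residual_outlier <- abs(out$std_residual) > sigma_limit
  rownames(out) <- NULL
  structure(out, h_star = h_star)
}

#' Insubria plot data for compounds without experimental activity
#'
#' For new (designed) compounds with no measured activity the Williams plot
#' ordinate is replaced by the predicted value; a compound is in-domain when
#' its leverage does not exceed `h*`.
#'
#' @param model a fitted `qsar_mlr` (needs the training design for
#'   leverages).
#' @param X_new descriptor table of the new compounds.
#' @param ids optional compound ids.
#' @return data.frame (id, leverage, predicted, in_domain) with `h_star`
#'   attribute.
#' @export
insubria_data <- function(model, X_new, ids = NULL) {
  if (is.null(model$X)) stop("model carries no training data")
  h_star <- leverage_threshold(model$k, model$n)
  h <- leverages(model$X, X_new)
  preds <- predict(model, as.data.frame(X_new))
  if (is.null(ids)) ids <- rownames(as.data.frame(X_new)) %||%
      paste0("new_", seq_along(h))
  out <- data.frame(id = ids, leverage = h, predicted = preds,
                    in_domain = h <= h_star)
  rownames(out) <- NULL
  structure(out, h_star = h_star)
}
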