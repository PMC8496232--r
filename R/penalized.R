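PEN_METHODS <- c("RR", "LASSO", "EN", "MTV_RR", "MTV_LASSO", "MTV_EN")

is_multivariate <- function(method) startsWith(method, "MTV_")

default_alpha_grid <- function(method, n_alpha = 20) {
  switch(sub("^MTV_", "", method),
    RR = 0,
    LASSO = 1,
    EN = seq(0, 1, length.out = n_alpha)
  )
}

default_nlambda <- function(method) {
  if (sub("^MTV_", "", method) == "EN") 500L else 100L
}

#' Seeded k-fold partitions
#'
#' Balanced random fold assignment, used for both the outer and inner folds
#' of nested cross-validation.  The same partition object is reused across
#' methods and traits within a run so that all methods see identical
#' training/test splits.
#'
#' @param n Number of observations.
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids in `1:k`, length `n`.
#' @export
make_folds <- function(n, k, seed = NULL) {
  if (k < 2 || k > n) stop("`k` must be in [2, n]", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  sample(rep_len(seq_len(k), n))
}

# normalise Y to an n x k matrix
as_response <- function(Y) {
  if (is.data.frame(Y)) Y <- as.matrix(Y[vapply(Y, is.numeric, TRUE)])
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  storage.mode(Y) <- "double"
  Y
}

glmnet_family <- function(method) {
  if (is_multivariate(method)) "mgaussian" else "gaussian"
}

new_qtlgp_fit <- function(method, alpha, lambda, beta, intercept, col_info,
                          tuning_trace = NULL, glmnet_fit = NULL) {
  sel <- which(rowSums(abs(beta)) > 0)
  structure(list(
    method = method, alpha = alpha, lambda = lambda,
    beta = beta, intercept = intercept,
    selected = sel,
    selected_markers = if (!is.null(col_info)) unique(col_info$marker[sel]),
    col_info = col_info,
    tuning_trace = tuning_trace,
    glmnet_fit = glmnet_fit
  ), class = "qtlgp_fit")
}

# beta (p x k) and intercepts (k) at lambda s from a glmnet object
extract_coefs <- function(fit, s, p) {
  cf <- coef(fit, s = s)
  if (!is.list(cf)) cf <- list(cf)
  beta <- vapply(cf, function(co) as.numeric(co)[-1L], numeric(p))
  beta <- matrix(beta, nrow = p)
  intercept <- vapply(cf, function(co) as.numeric(co)[1L], numeric(1))
  list(beta = beta, intercept = intercept)
}

#' Fit a penalized regression at fixed tuning parameters
#'
#' Fits ridge (`RR`), LASSO, elastic net (`EN`) or their multi-response
#' counterparts (`MTV_RR`, `MTV_LASSO`, `MTV_EN`) at a given mixing
#' parameter `alpha` and penalty `lambda`.  The multivariate methods use the
#' multi-response Gaussian family, whose row-wise group penalty (L2 norm of
#' each predictor's effect vector across traits) forces a predictor to be
#' zero or nonzero jointly across all traits.  Predictors are internally
#' standardized (population SD) and the intercept is unpenalized;
#' coefficients are returned on the original predictor scale.
#'
#' @param X Predictor matrix (a `qtlgp_design` or plain numeric matrix).
#' @param Y Response: numeric vector, matrix, or data frame of numeric
#'   columns (multi-column required for `MTV_*` methods).
#' @param method One of `"RR"`, `"LASSO"`, `"EN"`, `"MTV_RR"`,
#'   `"MTV_LASSO"`, `"MTV_EN"`.
#' @param alpha Elastic-net mixing parameter; defaults to 0 for ridge, 1 for
#'   LASSO (must be supplied for EN).
#' @param lambda Penalty value (scalar) or decreasing vector; if `NULL` the
#'   solver's own path is used and the smallest lambda is returned.
#' @param ... Passed to [glmnet::glmnet()].
#' @return A `qtlgp_fit`: coefficients `beta` (`p x k`), `intercept`,
#'   `selected` predictor indices, `selected_markers` (when `X` carries
#'   design metadata), and the underlying path object.
#' @export
fit_penalized <- function(X, Y, method = PEN_METHODS, alpha = NULL,
                          lambda = NULL, ...) {
  method <- match.arg(method)
  Y <- as_response(Y)
  if (is_multivariate(method) && ncol(Y) < 2L) {
    stop("multivariate methods need a multi-column response", call. = FALSE)
  }
  if (any(apply(Y, 2L, sd) == 0)) stop("zero-variance response", call. = FALSE)
  if (is.null(alpha)) {
    alpha <- default_alpha_grid(method)
    if (length(alpha) != 1L) stop("supply `alpha` for EN methods", call. = FALSE)
  }
  col_info <- attr(X, "col_info")
  Xm <- unclass(X)
  fit <- glmnet::glmnet(
    Xm, if (ncol(Y) == 1L) drop(Y) else Y,
    family = glmnet_family(method), alpha = alpha,
    lambda = if (!is.null(lambda)) sort(unique(c(lambda)), decreasing = TRUE),
    ...
  )
  s <- if (is.null(lambda)) min(fit$lambda) else min(lambda)
  cf <- extract_coefs(fit, s, ncol(Xm))
  new_qtlgp_fit(method, alpha, s, cf$beta, cf$intercept, col_info,
                glmnet_fit = fit)
}

#' Tune a penalized regression by cross-validation
#'
#' Grid search matching the study protocol: an outer grid of `alpha` values
#' (20 equispaced values in `[0, 1]` for EN; the singleton 0 for ridge and 1
#' for LASSO) and, for each `alpha`, a path of `nlambda` values (500 for EN,
#' 100 otherwise) evaluated by k-fold cross-validation with mean squared
#' error as the cost.  The fold assignment is shared across all `alpha`
#' values; the returned fit is at the `(alpha, lambda)` pair minimizing the
#' mean CV MSE (ties broken toward the largest, i.e. sparsest, lambda).
#'
#' @inheritParams fit_penalized
#' @param alpha_grid Vector of mixing parameters (defaults per method).
#' @param nlambda Length of each lambda path (defaults per method).
#' @param k_folds Number of CV folds (default 5).
#' @param foldid Optional explicit fold assignment (overrides `k_folds`).
#' @param seed Optional seed for the fold assignment.
#' @return A `qtlgp_fit` with a `tuning_trace` tibble (`alpha`, `lambda`,
#'   `cvm`) recording the mean CV MSE at every grid point.
#' @export
tune_penalized <- function(X, Y, method = PEN_METHODS, alpha_grid = NULL,
                           nlambda = NULL, k_folds = 5, foldid = NULL,
                           seed = NULL, ...) {
  method <- match.arg(method)
  Y <- as_response(Y)
  if (is.null(alpha_grid)) alpha_grid <- default_alpha_grid(method)
  if (is.null(nlambda)) nlambda <- default_nlambda(method)
  if (is.null(foldid)) foldid <- make_folds(nrow(X), k_folds, seed)
  col_info <- attr(X, "col_info")
  Xm <- unclass(X)
  y_in <- if (ncol(Y) == 1L) drop(Y) else Y

  cvs <- lapply(alpha_grid, function(a) {
    glmnet::cv.glmnet(Xm, y_in, family = glmnet_family(method), alpha = a,
                      nlambda = nlambda, foldid = foldid,
                      type.measure = "mse", ...)
  })
  best_cvm <- vapply(cvs, function(cv) min(cv$cvm), numeric(1))
  i <- which.min(best_cvm)
  cv <- cvs[[i]]
  # lambda path is decreasing, so which.min on cvm already prefers the
  # largest lambda among exact ties
  s <- cv$lambda[which.min(cv$cvm)]
  cf <- extract_coefs(cv$glmnet.fit, s, ncol(Xm))
  trace <- purrr::map2_dfr(cvs, alpha_grid, function(cv, a) {
    tibble(alpha = a, lambda = cv$lambda, cvm = cv$cvm)
  })
  new_qtlgp_fit(method, alpha_grid[i], s, cf$beta, cf$intercept, col_info,
                tuning_trace = trace, glmnet_fit = cv$glmnet.fit)
}

#' Predict from a penalized fit
#'
#' @param object A `qtlgp_fit`.
#' @param newx Predictor matrix with the same columns as the training design.
#' @param ... Unused.
#' @return Numeric matrix `n_new x k` of predictions.
#' @export
predict.qtlgp_fit <- function(object, newx, ...) {
  newx <- unclass(newx)
  if (ncol(newx) != nrow(object$beta)) {
    stop("`newx` has ", ncol(newx), " columns; fit expects ",
         nrow(object$beta), call. = FALSE)
  }
  sel <- object$selected
  base <- matrix(object$intercept, nrow(newx), length(object$intercept),
                 byrow = TRUE)
  if (length(sel)) {
    base <- base + newx[, sel, drop = FALSE] %*% object$beta[sel, , drop = FALSE]
  }
  base
}

#' @export
print.qtlgp_fit <- function(x, ...) {
  cat(sprintf(
    "<qtlgp_fit> %s: alpha = %.3g, lambda = %.4g, %d/%d predictors selected\n",
    x$method, x$alpha, x$lambda, length(x$selected), nrow(x$beta)))
  invisible(x)
}

#' Tidy a penalized fit
#'
#' @param x A `qtlgp_fit`.
#' @param ... Unused.
#' @return Tibble of nonzero coefficients: `column`, `marker`/`kind`/`label`
#'   when design metadata is available, `trait`, `estimate`.
#' @method tidy qtlgp_fit
#' @export
tidy.qtlgp_fit <- function(x, ...) {
  k <- ncol(x$beta)
  sel <- x$selected
  out <- tidyr::expand_grid(column = sel, trait = paste0("y", seq_len(k))) |>
    dplyr::mutate(estimate = as.numeric(t(x$beta[sel, , drop = FALSE])))
  if (!is.null(x$col_info)) {
    out <- dplyr::bind_cols(
      out["column"],
      x$col_info[out$column, ],
      out[c("trait", "estimate")]
    )
  }
  out[out$estimate != 0, , drop = FALSE]
}

#' @rdname tidy.qtlgp_fit
#' @method glance qtlgp_fit
#' @export
glance.qtlgp_fit <- function(x, ...) {
  tibble(
    method = x$method, alpha = x$alpha, lambda = x$lambda,
    n_selected = length(x$selected),
    n_markers = length(x$selected_markers %||% integer())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
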