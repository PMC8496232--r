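new_selection <- function(method_label, markers, statistic = NULL,
                          control = NULL, predictor_table = NULL) {
  structure(list(
    method_label = method_label,
    selected_markers = markers,
    statistic = statistic,
    control = control,
    predictor_table = predictor_table
  ), class = "qtlgp_selection")
}

#' @export
print.qtlgp_selection <- function(x, ...) {
  cat(sprintf("<qtlgp_selection> %s: %d markers selected\n",
              x$method_label, length(x$selected_markers)))
  invisible(x)
}

#' Stability selection on a LASSO path
#'
#' Computes the empirical selection probability of each predictor by fitting
#' the LASSO (or its multi-response group-penalized counterpart) to repeated
#' random half-samples of the observations over a fixed lambda grid.  A
#' predictor's probability is the fraction of half-samples in which it is
#' nonzero for at least one lambda of the grid; predictors at or above
#' `pi_threshold` are selected (0.6 is the study default for `LASSO.SS`,
#' 0.7 for `MTV_LASSO.SS`).  Selections are collapsed to markers when the
#' design carries metadata (a marker is selected if any of its 8 columns
#' is).
#'
#' @inheritParams fit_penalized
#' @param method `"LASSO"` or `"MTV_LASSO"`.
#' @param lambda Lambda grid; defaults to the full-data path (truncated to
#'   `nlambda` values).
#' @param nlambda Path length when `lambda` is not supplied (default 50).
#' @param n_subsamples Number of half-samples (default 100, minimum 20).
#' @param pi_threshold Selection-probability threshold in `[0.5, 1]`.
#' @param seed Optional integer seed.
#' @return A `qtlgp_selection` with a per-predictor `predictor_table`
#'   (`column`, `prob`) and the selected marker set.
#' @export
stability_selection <- function(X, Y, method = c("LASSO", "MTV_LASSO"),
                                lambda = NULL, nlambda = 50,
                                n_subsamples = 100, pi_threshold = 0.6,
                                seed = NULL) {
  method <- match.arg(method)
  if (n_subsamples < 20) stop("`n_subsamples` must be at least 20", call. = FALSE)
  if (pi_threshold < 0.5 || pi_threshold > 1) {
    stop("`pi_threshold` must be in [0.5, 1]", call. = FALSE)
  }
  Y <- as_response(Y)
  col_info <- attr(X, "col_info")
  Xm <- unclass(X)
  n <- nrow(Xm); p <- ncol(Xm)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(lambda)) {
    base <- glmnet::glmnet(Xm, if (ncol(Y) == 1L) drop(Y) else Y,
                           family = glmnet_family(method), alpha = 1,
                           nlambda = nlambda)
    lambda <- base$lambda
  }
  lambda <- sort(unique(lambda), decreasing = TRUE)
  if (!length(lambda)) stop("empty lambda grid", call. = FALSE)

  half <- floor(n / 2)
  counts <- numeric(p)
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, half)
    fit <- glmnet::glmnet(Xm[idx, , drop = FALSE],
                          if (ncol(Y) == 1L) Y[idx, 1L] else Y[idx, , drop = FALSE],
                          family = glmnet_family(method), alpha = 1,
                          lambda = lambda)
    bet <- fit$beta
    if (!is.list(bet)) bet <- list(bet)
    nz <- Reduce(`|`, lapply(bet, function(bm) {
      Matrix_rowany(bm)
    }))
    counts <- counts + as.numeric(nz)
  }
  prob <- counts / n_subsamples
  sel_cols <- which(prob >= pi_threshold)
  markers <- if (!is.null(col_info)) unique(col_info$marker[sel_cols]) else
    as.character(sel_cols)
  label <- paste0(method, ".SS")
  new_selection(label, markers, statistic = prob, control = pi_threshold,
                predictor_table = tibble(column = seq_len(p), prob = prob))
}

# any nonzero entry per row of a (possibly sparse) coefficient matrix
Matrix_rowany <- function(bm) {
  as.logical(tabulate(bm@i + 1L, nbins = bm@Dim[1L]))
}

#' Marginal false discovery rate along a penalized path
#'
#' Estimates, for every lambda of a LASSO or elastic-net path, the expected
#' number of marginally null predictors entering the model, and the marginal
#' FDR (expected false discoveries / selection count).  For the linear model
#' with standardized predictors, a null predictor enters when its inner
#' product with the current residual exceeds the effective L1 threshold
#' `alpha * lambda`, so the expected count is
#' `p * 2 * pnorm(-sqrt(n) * alpha * lambda / sigma_hat)`, with the residual
#' SD `sigma_hat` estimated at each lambda from `RSS / (n - df)`.  The mFDR
#' is clamped to `[0, 1]` and set to 0 when nothing is selected.
#'
#' @inheritParams fit_penalized
#' @param y Numeric response vector (mFDR is univariate).
#' @param method `"LASSO"` or `"EN"`.
#' @param alpha Mixing parameter (1 for LASSO; 0.7 is the study's EN ROC
#'   setting).
#' @param lambda Optional decreasing lambda grid; defaults to the fitted
#'   path.
#' @param nlambda Path length (default 100).
#' @return A `qtlgp_mfdr` tibble (`lambda`, `n_selected`, `ef`, `mfdr`)
#'   with the underlying path fit stored as an attribute.
#' @export
mfdr_path <- function(X, y, method = c("LASSO", "EN"), alpha = NULL,
                      lambda = NULL, nlambda = 100) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- if (method == "LASSO") 1 else 0.7
  if (alpha <= 0) stop("mFDR needs an L1 component (alpha > 0)", call. = FALSE)
  y <- drop(as_response(y))
  col_info <- attr(X, "col_info")
  Xm <- unclass(X)
  n <- nrow(Xm); p <- ncol(Xm)
  if (!is.null(lambda)) {
    if (is.unsorted(rev(lambda), strictly = FALSE)) {
      stop("`lambda` grid must be decreasing", call. = FALSE)
    }
  }
  fit <- glmnet::glmnet(Xm, y, family = "gaussian", alpha = alpha,
                        lambda = lambda, nlambda = nlambda)
  pred <- predict(fit, Xm)
  rss <- unname(colSums((y - pred)^2))
  df <- fit$df + 1L
  sigma <- sqrt(rss / pmax(n - df, 1))
  ef <- 2 * p * pnorm(-sqrt(n) * alpha * fit$lambda / sigma)
  nsel <- fit$df
  mfdr <- ifelse(nsel == 0, 0, pmin(1, ef / nsel))
  out <- tibble(lambda = fit$lambda, n_selected = as.integer(nsel),
                ef = ef, mfdr = mfdr)
  attr(out, "fit") <- fit
  attr(out, "col_info") <- col_info
  attr(out, "method") <- method
  class(out) <- c("qtlgp_mfdr", class(out))
  out
}

#' Select markers at a controlled marginal FDR
#'
#' Returns the selection set at the smallest lambda of the path whose
#' estimated mFDR stays at or below `level` — the largest model still
#' controlled.  The study sets the level to 10% for `LASSO.mFDR` and
#' `EN.mFDR`.
#'
#' @param path A `qtlgp_mfdr` tibble from [mfdr_path()].
#' @param level mFDR level (default 0.10).
#' @return A `qtlgp_selection` (possibly empty).
#' @export
select_at_mfdr <- function(path, level = 0.10) {
  stopifnot(inherits(path, "qtlgp_mfdr"))
  fit <- attr(path, "fit")
  col_info <- attr(path, "col_info")
  label <- paste0(attr(path, "method"), ".mFDR")
  ok <- which(path$mfdr <= level)
  if (!length(ok)) {
    return(new_selection(label, character(), control = level))
  }
  i <- max(ok)  # smallest lambda still controlled (path is decreasing)
  beta <- coef(fit, s = path$lambda[i])
  sel_cols <- which(as.numeric(beta)[-1L] != 0)
  markers <- if (!is.null(col_info)) unique(col_info$marker[sel_cols]) else
    as.character(sel_cols)
  new_selection(label, markers,
                statistic = setNames(path$mfdr[i], "mfdr_at_selection"),
                control = level,
                predictor_table = tibble(column = sel_cols))
}
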