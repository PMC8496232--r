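#' Tuning-parameter ranges for ROC sweeps
#'
#' The conventional sweep ranges for comparing selection methods by ROC
#' curves: LOD threshold 0 to 14 for SIM/MIM, lambda 10e-5 to 0.25 for
#' LASSO and MTV_LASSO, selection-probability threshold 0.5 to 0.9 for
#' stability selection, lambda 10e-4 to 8 for EN (alpha fixed at 0.7), and
#' mFDR level 0.3 down to 0.
#'
#' @return Tibble `method`, `parameter`, `lowest`, `highest`.
#' @export
roc_parameter_ranges <- function() {
  tibble(
    method = c("SIM/MIM", "LASSO/MTV_LASSO", "SS", "EN", "mFDR"),
    parameter = c("LOD", "lambda", "probability threshold", "lambda", "mFDR"),
    lowest = c(0, 10e-5, 0.5, 10e-4, 0.3),
    highest = c(14, 0.25, 0.9, 8, 0)
  )
}

# nearest mapped marker to a grid position
nearest_marker <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  sub$marker[which.min(abs(sub$pos_cM - pos))]
}

#' Selection sweeps for ROC curves
#'
#' Each helper varies exactly one tuning parameter over its range and
#' returns the list of selected-marker sets expected by [roc_curve()].
#'
#' `roc_sweep_scan()` thresholds a LOD scan: at each threshold the retained
#' chromosome peaks are mapped to their nearest marker.
#' `roc_sweep_path()` fits a LASSO/EN path (or the multi-response group
#' variant) and reads the nonzero predictors at each lambda of the grid.
#' `roc_sweep_ss()` thresholds stability-selection probabilities.
#' `roc_sweep_mfdr()` applies [select_at_mfdr()] at each level.
#'
#' @param scan A `qtlgp_scan` from [scan_sim()].
#' @param map Genetic map tibble.
#' @param lod Numeric vector of LOD thresholds (default 15 values, 14 to 0).
#' @return A list with elements `selections` (list of marker-name vectors)
#'   and `parameter` (the swept values), ready for [roc_curve()].
#' @name roc_sweeps
NULL

#' @rdname roc_sweeps
#' @export
roc_sweep_scan <- function(scan, map, lod = seq(14, 0, length.out = 15)) {
  sels <- lapply(lod, function(thr) {
    pk <- find_peaks(scan, thr)
    if (!nrow(pk)) return(character())
    vapply(seq_len(nrow(pk)), function(i) {
      if (!is.na(pk$marker[i])) pk$marker[i] else
        nearest_marker(map, pk$chrom[i], pk$pos[i])
    }, character(1))
  })
  list(selections = sels, parameter = lod)
}

#' @rdname roc_sweeps
#' @inheritParams fit_penalized
#' @param lambda Decreasing lambda grid (defaults to the conventional
#'   range for the method).
#' @param n_lambda Grid length when `lambda` is not supplied.
#' @export
roc_sweep_path <- function(X, Y, method = c("LASSO", "EN", "MTV_LASSO"),
                           alpha = NULL, lambda = NULL, n_lambda = 30) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- if (method == "EN") 0.7 else 1
  if (is.null(lambda)) {
    rng <- if (method == "EN") c(10e-4, 8) else c(10e-5, 0.25)
    lambda <- exp(seq(log(rng[2L]), log(rng[1L]), length.out = n_lambda))
  }
  lambda <- sort(unique(lambda), decreasing = TRUE)
  Y <- as_response(Y)
  col_info <- attr(X, "col_info")
  fit <- glmnet::glmnet(unclass(X), if (ncol(Y) == 1L) drop(Y) else Y,
                        family = glmnet_family(if (startsWith(method, "MTV"))
                          "MTV_LASSO" else "LASSO"),
                        alpha = alpha, lambda = lambda)
  sels <- lapply(seq_along(fit$lambda), function(i) {
    cf <- coef(fit, s = fit$lambda[i])
    if (!is.list(cf)) cf <- list(cf)
    nz <- Reduce(union, lapply(cf, function(co) which(as.numeric(co)[-1L] != 0)))
    if (!is.null(col_info)) unique(col_info$marker[nz]) else as.character(nz)
  })
  list(selections = sels, parameter = fit$lambda)
}

#' @rdname roc_sweeps
#' @param ss A `qtlgp_selection` from [stability_selection()].
#' @param thresholds Probability thresholds (default 0.9 down to 0.5).
#' @export
roc_sweep_ss <- function(ss, X, thresholds = seq(0.9, 0.5, by = -0.05)) {
  col_info <- attr(X, "col_info")
  prob <- ss$statistic
  sels <- lapply(thresholds, function(pi) {
    nz <- which(prob >= pi)
    if (!is.null(col_info)) unique(col_info$marker[nz]) else as.character(nz)
  })
  list(selections = sels, parameter = thresholds)
}

#' @rdname roc_sweeps
#' @param path A `qtlgp_mfdr` from [mfdr_path()].
#' @param levels mFDR levels (default 0 up to 0.3).
#' @export
roc_sweep_mfdr <- function(path, levels = seq(0, 0.3, by = 0.05)) {
  sels <- lapply(levels, function(lv) select_at_mfdr(path, lv)$selected_markers)
  list(selections = sels, parameter = levels)
}
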