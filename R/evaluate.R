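#' Prediction performance metrics
#'
#' The metric set used to compare prediction methods: Pearson correlation
#' (`corP`, the prediction accuracy / predictive ability), Spearman
#' correlation (`corS`), root mean square predicted error (`rmspe`),
#' Nash-Sutcliffe-type model efficiency
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, and t-test p-values
#' for bias (intercept = 0) and slope (= 1) from the linear regression of
#' observations on predictions.  Constant predictions make the correlations
#' undefined; they are reported as 0 with `degenerate = TRUE` so that
#' aggregation never drops cells silently.
#'
#' @param obs,pred Numeric vectors of equal length (>= 3).
#' @return A one-row tibble: `corP`, `corS`, `rmspe`, `model_efficiency`,
#'   `bias_pvalue`, `slope_pvalue`, `degenerate`.
#' @examples
#' prediction_metrics(c(1, 2, 3, 4), c(1, 2, 3, 8))
#' @export
prediction_metrics <- function(obs, pred) {
  if (length(obs) != length(pred) || length(obs) < 3) {
    stop("`obs` and `pred` must have equal length >= 3", call. = FALSE)
  }
  degenerate <- sd(pred) == 0 || sd(obs) == 0
  corP <- if (degenerate) 0 else cor(obs, pred)
  corS <- if (degenerate) 0 else cor(obs, pred, method = "spearman")
  rmspe <- sqrt(mean((obs - pred)^2))
  me <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  if (!degenerate) {
    fit <- lm(obs ~ pred)
    # a perfect fit is a legitimate input here (oracle predictors)
    sm <- suppressWarnings(summary(fit))$coefficients
    bias_p <- sm[1L, 4L]
    slope_t <- (sm[2L, 1L] - 1) / sm[2L, 2L]
    slope_p <- 2 * pt(-abs(slope_t), df = length(obs) - 2L)
  } else {
    bias_p <- NA_real_
    slope_p <- NA_real_
  }
  tibble(corP = corP, corS = corS, rmspe = rmspe, model_efficiency = me,
         bias_pvalue = bias_p, slope_pvalue = slope_p, degenerate = degenerate)
}

IM_METHODS <- c("SIM", "MIM")

# tuning + prediction for one outer fold of one method
fit_and_predict <- function(method, X, Y, train, test, inner_foldid,
                            probs, control, fold_seed) {
  k <- ncol(Y)
  if (method %in% PEN_METHODS) {
    alpha_grid <- if (sub("^MTV_", "", method) == "EN") {
      seq(0, 1, length.out = control$n_alpha)
    } else NULL
    if (is_multivariate(method)) {
      fit <- tune_penalized(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                            method, alpha_grid = alpha_grid,
                            nlambda = control$nlambda, foldid = inner_foldid)
      predict(fit, X[test, , drop = FALSE])
    } else {
      preds <- lapply(seq_len(k), function(j) {
        fit <- tune_penalized(X[train, , drop = FALSE], Y[train, j], method,
                              alpha_grid = alpha_grid,
                              nlambda = control$nlambda, foldid = inner_foldid)
        predict(fit, X[test, , drop = FALSE])[, 1L]
      })
      do.call(cbind, preds)
    }
  } else if (method %in% IM_METHODS) {
    ptr <- subset_genoprob(probs, which(train))
    pte <- subset_genoprob(probs, which(test))
    preds <- lapply(seq_len(k), function(j) {
      ytr <- Y[train, j]
      thr <- permutation_threshold(ptr, ytr, n_perm = control$n_perm,
                                   seed = fold_seed + j)
      pos <- if (method == "SIM") {
        find_peaks(scan_sim(ptr, ytr), thr)[, c("chrom", "pos")]
      } else {
        mim_stepwise(ptr, ytr, max_qtl = control$max_qtl,
                     penalty = max(thr, 1e-6),
                     n_restarts = control$n_restarts,
                     seed = fold_seed + 100L + j)$positions
      }
      im_predict(pos, ptr, ytr, pte)
    })
    do.call(cbind, preds)
  } else {
    stop("unknown method ", method, call. = FALSE)
  }
}

#' Nested cross-validation of genomic prediction methods
#'
#' Outer `k1`-fold cross-validation estimates the performance metrics; on
#' the training set of each outer fold, an inner `k2`-fold CV (penalized
#' methods) or a permutation threshold (interval-mapping methods, 10
#' permutations by default) finds the tuning parameters, so the held-out
#' observations never enter tuning.  The outer partitions are seeded and
#' reused across all methods and traits; the whole procedure can be
#' repeated `r` times (10 for experimental data, once per simulation
#' replicate for simulated data).
#'
#' @param X A `qtlgp_design` matrix.
#' @param Y Response matrix or data frame (`n x k`).
#' @param methods Character vector among `RR`, `LASSO`, `EN`, `MTV_RR`,
#'   `MTV_LASSO`, `MTV_EN`, `SIM`, `MIM`.
#' @param genotypes,map Needed when `methods` includes `SIM` or `MIM`
#'   (genotype-class probabilities are computed on the marker grid).
#' @param k1,k2 Outer and inner fold counts (default 5 and 5).
#' @param r Number of CV repetitions (default 1).
#' @param seed Integer seed controlling all partitions and permutations.
#' @param truth Optional `n x k` matrix of true genetic values; when given,
#'   metrics compare predictions to it (prediction accuracy) instead of to
#'   `Y` (predictive ability).
#' @param control List of tuning-protocol sizes: `n_alpha` (EN mixing grid,
#'   default 20), `nlambda` (path length, default per method: 500 for EN,
#'   100 otherwise), `n_perm` (permutations for the IM threshold inside CV,
#'   default 10), `max_qtl` (default 4), `n_restarts` (MIM restarts,
#'   default 10), `step_cM` (probability-grid step for IM, default `NULL` =
#'   markers only).
#' @return A long tibble of per-fold metrics: `rep`, `fold`, `method`,
#'   `trait`, plus the [prediction_metrics()] columns.
#' @export
nested_cv <- function(X, Y, methods, genotypes = NULL, map = NULL,
                      k1 = 5, k2 = 5, r = 1, seed = 1, truth = NULL,
                      control = list()) {
  methods <- match.arg(methods, c(PEN_METHODS, IM_METHODS),
                       several.ok = TRUE)
  control <- utils::modifyList(
    list(n_alpha = 20, nlambda = NULL, n_perm = 10, max_qtl = 4,
         n_restarts = 10, step_cM = NULL), control)
  Y <- as_response(Y)
  n <- nrow(Y)
  k <- ncol(Y)
  truth <- if (is.null(truth)) Y else as_response(truth)
  stopifnot(nrow(truth) == n, ncol(truth) == k)
  probs <- NULL
  if (any(methods %in% IM_METHODS)) {
    if (is.null(genotypes) || is.null(map)) {
      stop("SIM/MIM need `genotypes` and `map`", call. = FALSE)
    }
    probs <- calc_genoprob(genotypes, map, step_cM = control$step_cM)
  }

  out <- list()
  for (ri in seq_len(r)) {
    outer_id <- make_folds(n, k1, seed = seed + 1000L * ri)
    for (f in seq_len(k1)) {
      test <- outer_id == f
      train <- !test
      if (any(train & test)) stop("fold leakage detected", call. = FALSE)
      inner_foldid <- make_folds(sum(train), k2,
                                 seed = seed + 1000L * ri + f)
      fold_seed <- seed + 10000L * ri + 100L * f
      for (method in methods) {
        pred <- fit_and_predict(method, X, Y, train, test, inner_foldid,
                                probs, control, fold_seed)
        for (j in seq_len(k)) {
          out[[length(out) + 1L]] <- dplyr::bind_cols(
            tibble(rep = ri, fold = f, method = method,
                   trait = colnames(Y)[j] %||% paste0("y", j)),
            prediction_metrics(truth[test, j], pred[, j])
          )
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate nested-CV metrics
#'
#' Averages per-fold metrics according to the study's rules: for
#' equal-heritability simulations over traits, replicates and folds; pass
#' `by = c("method", "trait")` to keep traits apart (different-heritability
#' simulations and experimental data).
#'
#' @param results Tibble from [nested_cv()] (optionally row-bound over
#'   simulation replicates with a `replicate` column).
#' @param by Grouping columns (default `"method"`).
#' @return Summary tibble of metric means.
#' @export
summarise_cv <- function(results, by = "method") {
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dplyr::across(
      c("corP", "corS", "rmspe", "model_efficiency"),
      ~ mean(.x, na.rm = TRUE)), n_cells = dplyr::n(), .groups = "drop")
}

#' ROC curve for marker selection
#'
#' Scores a sweep of selection sets (obtained by relaxing one tuning
#' parameter) against the simulated truth.  A simulated QTL counts as found
#' (true positive) when at least one selected marker lies within
#' `tol_cM` (2 cM by default) of it on the same chromosome;
#' `TPR = found QTLs / s`.  Selected markers farther than `tol_cM` from
#' every QTL are false positives; `FPR = FP / (number of markers outside
#' all QTL windows)`.
#'
#' @param selections List of character vectors of selected marker names,
#'   ordered from the most to the least constrained parameter value.
#' @param truth_qtls Character vector of true QTL marker names.
#' @param map Genetic map tibble.
#' @param tol_cM True-positive window half-width (default 2).
#' @param parameter Optional numeric vector of the swept parameter values.
#' @return A `qtlgp_roc` tibble: `parameter`, `n_selected`, `tpr`, `fpr`.
#' @export
roc_curve <- function(selections, truth_qtls, map, tol_cM = 2,
                      parameter = NULL) {
  if (!length(truth_qtls)) stop("empty truth set", call. = FALSE)
  validate_genetic_map(map)
  qtl <- map[match(truth_qtls, map$marker), , drop = FALSE]
  if (anyNA(qtl$marker)) stop("truth markers not on map", call. = FALSE)
  # markers inside any +-tol window
  inside <- purrr::map_lgl(seq_len(nrow(map)), function(i) {
    any(qtl$chrom == map$chrom[i] & abs(qtl$pos_cM - map$pos_cM[i]) <= tol_cM)
  })
  n_outside <- sum(!inside)
  score_one <- function(sel) {
    sel_idx <- match(sel, map$marker)
    if (anyNA(sel_idx)) stop("selected markers not on map", call. = FALSE)
    found <- purrr::map_lgl(seq_len(nrow(qtl)), function(q) {
      any(map$chrom[sel_idx] == qtl$chrom[q] &
            abs(map$pos_cM[sel_idx] - qtl$pos_cM[q]) <= tol_cM)
    })
    fp <- sum(!inside[sel_idx])
    tibble(n_selected = length(sel), tpr = mean(found),
           fpr = if (n_outside > 0) fp / n_outside else 0)
  }
  pts <- purrr::map_dfr(selections, score_one)
  pts <- dplyr::bind_cols(
    tibble(parameter = parameter %||% seq_along(selections)), pts)
  class(pts) <- c("qtlgp_roc", class(pts))
  pts
}

#' Partial area under a ROC curve
#'
#' Trapezoidal integral of TPR over `FPR` in `[0, fpr_max]` (0.1 by
#' default, the low-FPR region relevant for QTL detection), so the maximum
#' attainable value is `fpr_max`.  Duplicate FPR values keep their maximum
#' TPR; if the smallest observed FPR is positive the curve is anchored at
#' (0, 0), and if the largest is below `fpr_max` the last TPR is extended
#' horizontally.
#'
#' @param curve A `qtlgp_roc` tibble (or any tibble with `fpr`, `tpr`).
#' @param fpr_max Upper integration bound (default 0.1).
#' @return Scalar pAUC in `[0, fpr_max]`.
#' @export
pauc <- function(curve, fpr_max = 0.1) {
  stopifnot(nrow(curve) > 0)
  pts <- tibble(fpr = curve$fpr, tpr = curve$tpr) |>
    dplyr::group_by(.data$fpr) |>
    dplyr::summarise(tpr = max(.data$tpr), .groups = "drop") |>
    dplyr::arrange(.data$fpr)
  if (min(pts$fpr) > 0) pts <- dplyr::bind_rows(tibble(fpr = 0, tpr = 0), pts)
  if (max(pts$fpr) < fpr_max) {
    pts <- dplyr::bind_rows(pts, tibble(fpr = fpr_max,
                                        tpr = pts$tpr[nrow(pts)]))
  }
  pts <- pts[pts$fpr <= fpr_max + 1e-12, , drop = FALSE]
  if (max(pts$fpr) < fpr_max) {
    ontop <- approx(curve$fpr, curve$tpr, xout = fpr_max, ties = max,
                    rule = 2)$y
    pts <- dplyr::bind_rows(pts, tibble(fpr = fpr_max, tpr = ontop))
  }
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

#' Average ROC curves over traits or replicates
#'
#' Pointwise mean of TPR and FPR across curves computed on the same
#' parameter sweep (multivariate selections are scored per trait and then
#' averaged this way).
#'
#' @param curves List of `qtlgp_roc` tibbles sharing the parameter grid.
#' @return A `qtlgp_roc` tibble.
#' @export
average_roc <- function(curves) {
  stopifnot(length(curves) > 0)
  out <- curves[[1L]]
  out$tpr <- rowMeans(vapply(curves, function(cv) cv$tpr,
                             numeric(nrow(out))))
  out$fpr <- rowMeans(vapply(curves, function(cv) cv$fpr,
                             numeric(nrow(out))))
  out
}

#' @rdname roc_curve
#' @param x A `qtlgp_roc` object.
#' @param ... Unused.
#' @method autoplot qtlgp_roc
#' @export
autoplot.qtlgp_roc <- function(x, ...) {
  ggplot2::ggplot(dplyr::arrange(x, .data$fpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

#' Broad-sense heritability on a genotype-mean basis
#'
#' `H2 = var_G / (var_G + var_GY / n_year + var_e / (n_year * n_rep))`,
#' assuming a balanced design: `var_G` is the genotypic variance, `var_GY`
#' the genotype-by-year interaction variance, `var_e` the residual
#' variance, `n_year` the mean number of trials (years) and `n_rep` the
#' mean number of replicates per trial.
#'
#' @param var_G,var_GY,var_e Nonnegative variance components.
#' @param n_year,n_rep Positive mean counts (may be fractional).
#' @return Scalar heritability in `[0, 1]`.
#' @examples
#' broad_sense_h2(2, 1, 3, n_year = 2, n_rep = 2.5)
#' @export
broad_sense_h2 <- function(var_G, var_GY, var_e, n_year, n_rep) {
  if (any(c(var_G, var_GY, var_e) < 0)) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  if (n_year <= 0 || n_rep <= 0) stop("counts must be positive", call. = FALSE)
  denom <- var_G + var_GY / n_year + var_e / (n_year * n_rep)
  if (denom == 0) stop("zero denominator", call. = FALSE)
  var_G / denom
}

#' Cluster traits for grouped multivariate analysis
#'
#' Hierarchical (Ward) clustering of traits on their standardized genotypic
#' values, cut into `n_groups` groups — used to split large trait panels
#' before multivariate fits.
#'
#' @param traits Numeric matrix or data frame, columns = traits (an
#'   `offspring` id column is ignored).
#' @param n_groups Number of groups (default 3).
#' @return Tibble `trait`, `group`.
#' @export
cluster_traits <- function(traits, n_groups = 3) {
  if (is.data.frame(traits)) {
    traits <- as.matrix(traits[setdiff(names(traits), "offspring")])
  }
  if (ncol(traits) < n_groups) {
    stop("need at least `n_groups` traits", call. = FALSE)
  }
  sds <- apply(traits, 2L, sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ",
         paste(colnames(traits)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(traits)
  hc <- hclust(dist(t(z)), method = "ward.D2")
  grp <- cutree(hc, k = n_groups)
  tibble(trait = colnames(traits), group = unname(grp))
}
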