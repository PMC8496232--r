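#' Genotype-class probabilities on a cM grid
#'
#' Infers the probability of each genotype class (`ac`, `ad`, `bc`, `bd`) at
#' every marker and every `step_cM` between markers.  Because the data are
#' complete and fully informative, the hidden-Markov computation reduces to
#' the two-point Markov bridge with Haldane recombination fractions: for a
#' position flanked by markers L and R at distances giving fractions
#' `r_L`, `r_R`, `r_LR`, the probability that the maternal allele matches
#' both (identical) flanking alleles is `(1 - r_L)(1 - r_R) / (1 - r_LR)`,
#' and `(1 - r_L) r_R / r_LR` that it matches a discordant left flank.  The
#' paternal chromosome is treated identically and independently; a class
#' probability is the product of its two parental probabilities.  At marker
#' positions the vector is the unit indicator of the observed class.
#'
#' Internally only the two parental probabilities `P(a)` and `P(c)` are
#' stored; the four class probabilities are their products.
#'
#' @param genotypes Genotype tibble or matrix of `ac/ad/bc/bd` classes.
#' @param map Genetic map tibble.
#' @param step_cM Grid step between markers in cM (default 0.1); `NULL`
#'   restricts the grid to marker positions (used in cross-validation).
#' @return A `qtlgp_genoprob` object.
#' @export
calc_genoprob <- function(genotypes, map, step_cM = 0.1) {
  if (!is.null(step_cM) && step_cM <= 0) stop("`step_cM` must be positive",
                                              call. = FALSE)
  g <- geno_matrix(genotypes, map)
  cls <- matrix(match(g, GENO_CLASSES), nrow(g), ncol(g),
                dimnames = dimnames(g))
  n <- nrow(g)

  chroms <- unique(map$chrom)
  blocks <- lapply(chroms, function(ch) {
    sel <- map$chrom == ch
    d <- map$pos_cM[sel]
    mk <- map$marker[sel]
    S_mat <- matrix(as.integer(cls[, mk, drop = FALSE] > 2L), n)      # 1 = b
    S_pat <- matrix(as.integer(cls[, mk, drop = FALSE] %% 2L == 0L), n) # 1 = d
    grid <- if (is.null(step_cM) || length(d) == 1L) unique(d) else
      sort(unique(c(d, seq(min(d), max(d), by = step_cM))))
    at <- match(round(grid, 9), round(d, 9))
    pA <- matrix(NA_real_, n, length(grid))
    pC <- matrix(NA_real_, n, length(grid))
    for (j in seq_along(grid)) {
      if (!is.na(at[j])) {
        pA[, j] <- 1 - S_mat[, at[j]]
        pC[, j] <- 1 - S_pat[, at[j]]
      } else {
        L <- findInterval(grid[j], d)
        pA[, j] <- bridge_prob(S_mat[, L], S_mat[, L + 1L],
                               grid[j] - d[L], d[L + 1L] - grid[j])
        pC[, j] <- bridge_prob(S_pat[, L], S_pat[, L + 1L],
                               grid[j] - d[L], d[L + 1L] - grid[j])
      }
    }
    list(pos = grid, marker = mk[at], pA = pA, pC = pC)
  })
  names(blocks) <- chroms
  structure(list(chroms = blocks, offspring = rownames(g), n = n,
                 step_cM = step_cM),
            class = "qtlgp_genoprob")
}

# P(state = 0 at an interior point | flanking states sL, sR), Haldane bridge
bridge_prob <- function(sL, sR, dL, dR) {
  rL <- haldane_r(dL); rR <- haldane_r(dR); rLR <- haldane_r(dL + dR)
  if (rLR == 0) return(1 - sL)  # zero-distance bracket: indicator
  (1 - sL) * (1 - sR) * (1 - rL) * (1 - rR) / (1 - rLR) +
    (1 - sL) * sR * (1 - rL) * rR / rLR +
    sL * (1 - sR) * rL * (1 - rR) / rLR +
    sL * sR * rL * rR / (1 - rLR)
}

#' Four-class probabilities at a grid position
#'
#' @param probs A `qtlgp_genoprob` object.
#' @param chrom Chromosome label.
#' @param pos Position in cM (must be on the grid).
#' @return `n x 4` matrix of class probabilities (`ac`, `ad`, `bc`, `bd`),
#'   each row summing to 1.
#' @export
class_probs <- function(probs, chrom, pos) {
  b <- probs$chroms[[chrom]]
  if (is.null(b)) stop("unknown chromosome ", chrom, call. = FALSE)
  j <- which(abs(b$pos - pos) < 1e-9)[1L]
  if (is.na(j)) stop("position not on the probability grid", call. = FALSE)
  pA <- b$pA[, j]; pC <- b$pC[, j]
  out <- cbind(ac = pA * pC, ad = pA * (1 - pC),
               bc = (1 - pA) * pC, bd = (1 - pA) * (1 - pC))
  rownames(out) <- probs$offspring
  out
}

#' @export
print.qtlgp_genoprob <- function(x, ...) {
  npos <- sum(vapply(x$chroms, function(b) length(b$pos), integer(1)))
  cat(sprintf("<qtlgp_genoprob> %d offspring, %d chromosomes, %d grid positions\n",
              x$n, length(x$chroms), npos))
  invisible(x)
}

# subset offspring (rows); used by cross-validation
subset_genoprob <- function(probs, idx) {
  probs$chroms <- lapply(probs$chroms, function(b) {
    b$pA <- b$pA[idx, , drop = FALSE]
    b$pC <- b$pC[idx, , drop = FALSE]
    b
  })
  probs$offspring <- probs$offspring[idx]
  probs$n <- length(idx)
  probs
}

# tibble of all grid positions
genoprob_positions <- function(probs) {
  purrr::imap_dfr(probs$chroms, function(b, ch) {
    tibble(chrom = ch, pos = b$pos, marker = b$marker)
  })
}

LOD_CAP <- 300

# Haley-Knott predictors at one grid column: [pA, pC, pA*pC] spans, with the
# intercept, the same space as three of the four class probabilities
hk_cols <- function(b, j) cbind(b$pA[, j], b$pC[, j], b$pA[, j] * b$pC[, j])

# LOD matrix (positions x response columns) for a response matrix Ymat
scan_lod_matrix <- function(probs, Ymat) {
  Ymat <- as.matrix(Ymat)
  n <- nrow(Ymat)
  rss0 <- colSums(sweep(Ymat, 2L, colMeans(Ymat))^2)
  lod <- lapply(probs$chroms, function(b) {
    out <- matrix(NA_real_, length(b$pos), ncol(Ymat))
    for (j in seq_along(b$pos)) {
      qx <- qr(cbind(1, hk_cols(b, j)))
      rss1 <- colSums(qr.resid(qx, Ymat)^2)
      out[j, ] <- ifelse(rss0 <= 0, 0,
                         ifelse(rss1 < 1e-12 * pmax(rss0, 1e-300), LOD_CAP,
                                pmin(n / 2 * log10(rss0 / rss1), LOD_CAP)))
    }
    out
  })
  do.call(rbind, lod)
}

#' Simple interval mapping LOD scan
#'
#' Haley-Knott regression of a trait on the genotype-class probabilities at
#' every grid position: `LOD = (n/2) log10(RSS0 / RSS1)` where `RSS0` is the
#' intercept-only residual sum of squares and `RSS1` that of the regression
#' on the class probabilities (3 informative degrees of freedom, the four
#' probabilities summing to 1).  Perfect fits are capped at LOD 300 with a
#' warning.
#'
#' @param probs A `qtlgp_genoprob` object.
#' @param y Numeric trait vector (length `n`, complete).
#' @return A `qtlgp_scan` tibble: `chrom`, `pos`, `marker`, `lod`.
#' @export
scan_sim <- function(probs, y) {
  y <- as.numeric(y)
  if (length(y) != probs$n) stop("`y` length does not match genotypes",
                                 call. = FALSE)
  if (anyNA(y)) stop("`y` must be complete", call. = FALSE)
  lod <- drop(scan_lod_matrix(probs, matrix(y)))
  if (any(lod >= LOD_CAP)) {
    warning("perfect fit: LOD capped at ", LOD_CAP, call. = FALSE)
  }
  out <- genoprob_positions(probs)
  out$lod <- lod
  class(out) <- c("qtlgp_scan", class(out))
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the trait against the (fixed) genotype rows, records the
#' genome-wide maximum LOD of each permuted scan, and returns the
#' `1 - fwer` empirical quantile — the LOD threshold controlling the
#' family-wise error rate at level `fwer`.  The study protocol uses 1,000
#' permutations at FWER 5% for QTL detection, and 10 permutations inside
#' cross-validation.
#'
#' This same quantity serves as the per-QTL penalty of the stepwise
#' multiple-QTL search ([mim_stepwise()]): with interactions excluded, the
#' main-effect penalty is the genome-wide single-scan threshold.
#'
#' @inheritParams scan_sim
#' @param n_perm Number of permutations (>= 10).
#' @param fwer Target family-wise error rate (default 0.05).
#' @param seed Optional integer seed.
#' @return Scalar LOD threshold.
#' @export
permutation_threshold <- function(probs, y, n_perm = 1000, fwer = 0.05,
                                  seed = NULL) {
  if (n_perm < 10) stop("`n_perm` must be at least 10", call. = FALSE)
  y <- as.numeric(y)
  if (!is.null(seed)) withr::local_seed(seed)
  Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
               numeric(length(y)))
  lod <- scan_lod_matrix(probs, Yp)
  maxima <- apply(lod, 2L, max)
  quantile(maxima, 1 - fwer, names = FALSE)
}

#' @rdname permutation_threshold
#' @export
mim_penalty <- permutation_threshold

#' Peaks of a LOD scan
#'
#' One peak per chromosome (simple interval mapping assumes at most one QTL
#' per chromosome): the position of the chromosome-wise maximum LOD, kept if
#' it reaches the threshold.
#'
#' @param scan A `qtlgp_scan` tibble.
#' @param threshold LOD threshold (e.g. from [permutation_threshold()]).
#' @return Tibble `chrom`, `pos`, `marker`, `lod` of retained peaks.
#' @export
find_peaks <- function(scan, threshold) {
  scan |>
    dplyr::group_by(.data$chrom) |>
    dplyr::slice_max(.data$lod, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$lod >= threshold)
}

#' LOD support interval around a peak
#'
#' The widest contiguous interval around the peak over which the LOD stays
#' within `drop` of the peak LOD (LOD-1 interval by default), truncated at
#' the chromosome ends.
#'
#' @param scan A `qtlgp_scan` tibble.
#' @param chrom Chromosome of the peak.
#' @param peak_pos Peak position (must be a scan position).
#' @param drop LOD drop defining the interval (default 1).
#' @return Tibble `chrom`, `start`, `end`, `peak_pos`, `peak_lod`.
#' @export
lod_support_interval <- function(scan, chrom, peak_pos, drop = 1) {
  s <- scan[scan$chrom == chrom, , drop = FALSE]
  i <- which(abs(s$pos - peak_pos) < 1e-9)[1L]
  if (is.na(i)) stop("`peak_pos` is not a scan position", call. = FALSE)
  ok <- s$lod >= s$lod[i] - drop
  left <- i; right <- i
  while (left > 1L && ok[left - 1L]) left <- left - 1L
  while (right < nrow(s) && ok[right + 1L]) right <- right + 1L
  tibble(chrom = chrom, start = s$pos[left], end = s$pos[right],
         peak_pos = s$pos[i], peak_lod = s$lod[i])
}

# stacked HK predictors (3 columns per position) for a set of positions
hk_design <- function(probs, positions) {
  if (nrow(positions) == 0L) return(matrix(numeric(), probs$n, 0L))
  cols <- purrr::map(seq_len(nrow(positions)), function(i) {
    b <- probs$chroms[[positions$chrom[i]]]
    j <- which(abs(b$pos - positions$pos[i]) < 1e-9)[1L]
    if (is.na(j)) stop("model position not on the probability grid",
                       call. = FALSE)
    hk_cols(b, j)
  })
  do.call(cbind, cols)
}

model_rss <- function(probs, positions, y) {
  X <- cbind(1, hk_design(probs, positions))
  sum(qr.resid(qr(X), y)^2)
}

model_plod <- function(probs, positions, y, penalty, rss0) {
  rss <- model_rss(probs, positions, y)
  lod <- if (rss0 <= 0) 0 else if (rss < 1e-12 * rss0) LOD_CAP else
    min(probs$n / 2 * log10(rss0 / rss), LOD_CAP)
  lod - penalty * nrow(positions)
}

# profile pLOD over all candidate positions added to a fixed model, via
# Frisch-Waugh: residualize y and the candidate predictors on the current
# model, then score each candidate by its 3-column regression on the
# residualized response
forward_profile <- function(probs, positions, y, penalty, rss0) {
  base <- qr(cbind(1, hk_design(probs, positions)))
  ry <- qr.resid(base, y)
  ryy <- sum(ry^2)
  n <- probs$n
  q1 <- nrow(positions) + 1L
  purrr::imap_dfr(probs$chroms, function(b, ch) {
    PA <- qr.resid(base, b$pA)
    PC <- qr.resid(base, b$pC)
    PAC <- qr.resid(base, b$pA * b$pC)
    rss <- vapply(seq_along(b$pos), function(j) {
      Z <- cbind(PA[, j], PC[, j], PAC[, j])
      fit <- tryCatch(lm.fit(Z, ry), error = function(e) NULL)
      if (is.null(fit)) ryy else sum(fit$residuals^2)
    }, numeric(1))
    lod <- ifelse(rss < 1e-12 * max(rss0, 1e-300), LOD_CAP,
                  pmin(n / 2 * log10(rss0 / rss), LOD_CAP))
    tibble(chrom = ch, pos = b$pos, plod = lod - penalty * q1)
  })
}

#' Stepwise multiple interval mapping
#'
#' Forward/backward selection of a multiple-QTL Haley-Knott regression
#' model, main effects only (no QTL x QTL interactions).  Each forward step
#' adds the grid position maximizing the penalized LOD
#' `pLOD = LOD_model - penalty * #QTL`; after every addition, backward
#' sweeps drop any QTL whose removal increases the pLOD.  The search stops
#' when no move improves, or at `max_qtl` QTLs (4 by default, 10 for ROC
#' sweeps).  QTL positions are then refined by coordinate-wise re-scan
#' holding the other QTLs fixed.  Because plain stepwise search is
#' deterministic, the "restarts" used to overcome instability are
#' implemented as seeded random tie-breaking among near-equal candidates;
#' the highest-pLOD model across restarts is returned.
#'
#' @inheritParams scan_sim
#' @param max_qtl Maximum number of QTLs in the model.
#' @param penalty Per-QTL pLOD penalty, typically the genome-wide
#'   permutation threshold ([mim_penalty()]).
#' @param n_restarts Number of randomized restarts (default 10).
#' @param seed Optional integer seed.
#' @return A `qtlgp_mim` object: `positions` tibble, `plod`, `penalty`.
#' @export
mim_stepwise <- function(probs, y, max_qtl = 4, penalty, n_restarts = 10,
                         seed = NULL) {
  if (penalty <= 0) stop("`penalty` must be positive", call. = FALSE)
  y <- as.numeric(y)
  if (!is.null(seed)) withr::local_seed(seed)
  rss0 <- sum((y - mean(y))^2)
  empty <- tibble(chrom = character(), pos = numeric())

  run_once <- function() {
    model <- empty
    cur <- 0  # pLOD of the empty model
    repeat {
      improved <- FALSE
      if (nrow(model) < max_qtl && max_qtl > 0L) {
        prof <- forward_profile(probs, model, y, penalty, rss0)
        best <- max(prof$plod)
        if (best > cur + 1e-10) {
          cand <- which(prof$plod > best - 1e-8)
          pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
          model <- dplyr::bind_rows(model,
                                    prof[pick, c("chrom", "pos")])
          cur <- best
          improved <- TRUE
        }
      }
      repeat {  # backward sweeps
        if (nrow(model) == 0L) break
        drops <- vapply(seq_len(nrow(model)), function(i) {
          model_plod(probs, model[-i, , drop = FALSE], y, penalty, rss0)
        }, numeric(1))
        if (max(drops) > cur + 1e-10) {
          model <- model[-which.max(drops), , drop = FALSE]
          cur <- max(drops)
          improved <- TRUE
        } else break
      }
      if (!improved) break
    }
    # coordinate-wise position refinement
    if (nrow(model) > 1L) {
      for (it in seq_len(10L)) {
        moved <- FALSE
        for (i in seq_len(nrow(model))) {
          prof <- forward_profile(probs, model[-i, , drop = FALSE], y,
                                  penalty, rss0)
          j <- which.max(prof$plod)
          if (prof$plod[j] > cur + 1e-10) {
            model[i, ] <- prof[j, c("chrom", "pos")]
            cur <- prof$plod[j]
            moved <- TRUE
          }
        }
        if (!moved) break
      }
    }
    list(model = model, plod = cur)
  }

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    res <- run_once()
    if (is.null(best) || res$plod > best$plod + 1e-12) best <- res
  }
  pos_tbl <- genoprob_positions(probs)
  model <- dplyr::left_join(best$model, pos_tbl, by = c("chrom", "pos")) |>
    dplyr::arrange(.data$chrom, .data$pos)
  structure(list(positions = model, plod = best$plod, penalty = penalty,
                 max_qtl = max_qtl),
            class = "qtlgp_mim")
}

#' @export
print.qtlgp_mim <- function(x, ...) {
  cat(sprintf("<qtlgp_mim> %d QTLs, pLOD = %.3f (penalty %.3f)\n",
              nrow(x$positions), x$plod, x$penalty))
  if (nrow(x$positions)) print(x$positions)
  invisible(x)
}

#' Predict genotypic values from fitted QTL positions
#'
#' Ordinary least squares of the training trait on the stacked
#' genotype-class probability predictors at all QTL positions; the estimated
#' class effects are then applied to the test-set probabilities.  An empty
#' model predicts the training mean.  Rank deficiency is resolved through
#' the pivoting least-squares solve (aliased predictors get zero weight).
#'
#' @param positions Tibble of QTL positions (`chrom`, `pos`), e.g. from
#'   [find_peaks()] or a [mim_stepwise()] model.
#' @param probs_train,probs_test `qtlgp_genoprob` objects sharing the grid.
#' @param y_train Training trait values.
#' @return Numeric vector of predictions for the test offspring.
#' @export
im_predict <- function(positions, probs_train, y_train, probs_test) {
  y_train <- as.numeric(y_train)
  if (is.null(positions) || nrow(positions) == 0L) {
    return(rep(mean(y_train), probs_test$n))
  }
  Xtr <- cbind(1, hk_design(probs_train, positions))
  fit <- lm.fit(Xtr, y_train)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  Xte <- cbind(1, hk_design(probs_test, positions))
  drop(Xte %*% beta)
}

#' @rdname scan_sim
#' @param x A `qtlgp_scan` object.
#' @param ... Unused.
#' @method autoplot qtlgp_scan
#' @export
autoplot.qtlgp_scan <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(.data$pos, .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD")
}
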