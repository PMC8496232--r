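#' Within-chromosome linkage disequilibrium matrix
#'
#' Squared Pearson correlation (r2) between markers of the same chromosome,
#' computed on the 0/1/2 dose coding of [dose_matrix()].  The expansion
#' threshold is the 95% quantile of all within-chromosome pairwise r2 values
#' across the genome (0.84 on the study's experimental data).
#'
#' @inheritParams encode_design
#' @param map Genetic map tibble.
#' @param quantile_level Quantile defining the LD threshold (default 0.95).
#' @return A `qtlgp_ld` object: per-chromosome r2 matrices and the
#'   `threshold`.
#' @export
ld_matrix <- function(genotypes, map, quantile_level = 0.95) {
  validate_genetic_map(map)
  d <- dose_matrix(genotypes, map)
  chroms <- unique(map$chrom)
  mats <- lapply(chroms, function(ch) {
    mk <- map$marker[map$chrom == ch]
    sub <- d[, mk, drop = FALSE]
    r2 <- suppressWarnings(cor(sub))^2
    r2[!is.finite(r2)] <- 0   # monomorphic markers carry no LD information
    diag(r2) <- 1
    r2
  })
  names(mats) <- chroms
  offdiag <- unlist(lapply(mats, function(m) m[upper.tri(m)]))
  threshold <- if (length(offdiag)) quantile(offdiag, quantile_level,
                                             names = FALSE) else 1
  structure(list(matrices = mats, threshold = threshold,
                 quantile_level = quantile_level),
            class = "qtlgp_ld")
}

#' @export
print.qtlgp_ld <- function(x, ...) {
  cat(sprintf("<qtlgp_ld> %d chromosomes, threshold (q=%.2f) = %.3f\n",
              length(x$matrices), x$quantile_level, x$threshold))
  invisible(x)
}

#' Expand a marker selection through linkage disequilibrium
#'
#' All same-chromosome markers in LD at or above the threshold with any
#' selected marker are considered selected too.  The expansion is a single
#' pass (not a transitive closure), which avoids chromosome-wide
#' percolation in dense maps.
#'
#' @param selected Character vector of marker names.
#' @param ld A `qtlgp_ld` object.
#' @return Character vector: the union of the input and its LD proxies.
#' @export
ld_expand <- function(selected, ld) {
  stopifnot(inherits(ld, "qtlgp_ld"))
  extra <- unlist(lapply(ld$matrices, function(m) {
    hit <- intersect(selected, colnames(m))
    if (!length(hit)) return(character())
    rows <- m[, hit, drop = FALSE]
    rownames(m)[apply(rows >= ld$threshold, 1L, any)]
  }))
  union(selected, extra)
}

#' Tally highly reliable markers across methods
#'
#' A marker is called highly reliable for a trait if it was selected
#' (after LD expansion) by at least `min_methods` distinct methods —
#' whatever the methods — or by both `EN.mFDR` and `MIM`.
#'
#' @param selections Long tibble with columns `trait`, `method`, `marker`:
#'   one row per (trait, method, selected marker).
#' @param min_methods Method-count rule (default 5).
#' @param pair Character pair whose joint selection is sufficient on its
#'   own (default `c("EN.mFDR", "MIM")`).
#' @return Tibble `trait`, `marker`, `n_methods`, `methods`, `reliable`,
#'   filtered to reliable markers.
#' @export
tally_reliable <- function(selections, min_methods = 5,
                           pair = c("EN.mFDR", "MIM")) {
  stopifnot(all(c("trait", "method", "marker") %in% names(selections)))
  selections |>
    dplyr::distinct(.data$trait, .data$method, .data$marker) |>
    dplyr::group_by(.data$trait, .data$marker) |>
    dplyr::summarise(
      n_methods = dplyr::n(),
      methods = paste(sort(.data$method), collapse = ","),
      reliable = dplyr::n() >= min_methods ||
        all(pair %in% .data$method),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$reliable)
}

#' Monotone cM-to-bp conversion
#'
#' Fits, per chromosome, a local polynomial regression (loess) of physical
#' on genetic position (and the reverse), post-processed with an isotonic
#' correction so the conversion is nondecreasing.  Chromosomes with fewer
#' than 5 markers fall back to linear interpolation (with a warning).
#'
#' @param map Genetic map tibble.
#' @param span loess span (default 0.3).
#' @return Function `(chrom, cM)` returning interpolated bp positions,
#'   with an attribute `inverse` mapping `(chrom, bp)` to cM.
#' @export
fit_cm_bp_smoother <- function(map, span = 0.3) {
  validate_genetic_map(map)
  build <- function(xx, yy) {
    ord <- order(xx)
    xx <- xx[ord]; yy <- yy[ord]
    if (length(xx) < 5L) {
      return(function(q) approx(xx, yy, xout = q, rule = 2, ties = mean)$y)
    }
    lo <- tryCatch(
      suppressWarnings(loess(yy ~ xx, span = span,
                             degree = 2, family = "gaussian")),
      error = function(e) NULL)
    grid <- seq(min(xx), max(xx), length.out = 512L)
    fitted_g <- if (is.null(lo)) approx(xx, yy, xout = grid, ties = mean)$y
      else predict(lo, newdata = data.frame(xx = grid))
    fitted_g[is.na(fitted_g)] <- approx(xx, yy, xout = grid[is.na(fitted_g)],
                                        rule = 2, ties = mean)$y
    iso <- cummax(fitted_g)  # isotonic correction
    function(q) approx(grid, iso, xout = pmin(pmax(q, min(xx)), max(xx)),
                       rule = 2)$y
  }
  by_chr <- split(map, map$chrom)
  thin <- names(by_chr)[vapply(by_chr, nrow, integer(1)) < 5L]
  if (length(thin)) {
    warning("fewer than 5 markers on ", paste(thin, collapse = ", "),
            ": linear interpolation fallback", call. = FALSE)
  }
  fwd <- lapply(by_chr, function(s) build(s$pos_cM, s$pos_bp))
  inv <- lapply(by_chr, function(s) build(s$pos_bp, s$pos_cM))
  f <- function(chrom, cM) {
    g <- fwd[[chrom]]
    if (is.null(g)) stop("unknown chromosome ", chrom, call. = FALSE)
    g(cM)
  }
  attr(f, "inverse") <- function(chrom, bp) {
    g <- inv[[chrom]]
    if (is.null(g)) stop("unknown chromosome ", chrom, call. = FALSE)
    g(bp)
  }
  f
}

#' Build highly reliable QTL intervals
#'
#' Places a window of `half_width_cM` (3 by default) on either side of each
#' highly reliable anchor marker, merges overlapping windows per trait and
#' chromosome (several anchors inside one 6 cM window extend the interval
#' accordingly), clips at the chromosome ends, and converts the cM bounds
#' to physical coordinates with the fitted monotone smoother.
#'
#' @param reliable Tibble from [tally_reliable()] (`trait`, `marker`, ...).
#' @param map Genetic map tibble.
#' @param half_width_cM Window half-width (default 3).
#' @param smoother Optional conversion from [fit_cm_bp_smoother()]
#'   (fitted from `map` if missing).
#' @return Tibble `trait`, `chrom`, `cM_start`, `cM_end`, `bp_start`,
#'   `bp_end`, `anchors`, `n_anchors`.
#' @export
build_intervals <- function(reliable, map, half_width_cM = 3,
                            smoother = NULL) {
  validate_genetic_map(map)
  if (!nrow(reliable)) {
    return(tibble(trait = character(), chrom = character(),
                  cM_start = numeric(), cM_end = numeric(),
                  bp_start = numeric(), bp_end = numeric(),
                  anchors = character(), n_anchors = integer()))
  }
  idx <- match(reliable$marker, map$marker)
  if (anyNA(idx)) stop("anchor markers not on map", call. = FALSE)
  if (is.null(smoother)) smoother <- fit_cm_bp_smoother(map)
  anchors <- dplyr::bind_cols(reliable[, "trait"],
                              map[idx, c("marker", "chrom", "pos_cM")])
  lims <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$pos_cM), hi = max(.data$pos_cM),
                     .groups = "drop")
  anchors |>
    dplyr::left_join(lims, by = "chrom") |>
    dplyr::mutate(start = pmax(.data$pos_cM - half_width_cM, .data$lo),
                  end = pmin(.data$pos_cM + half_width_cM, .data$hi)) |>
    dplyr::group_by(.data$trait, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(.data$start >
                                     dplyr::lag(cummax(.data$end),
                                                default = -Inf))) |>
    dplyr::group_by(.data$trait, .data$chrom, .data$cluster) |>
    dplyr::summarise(
      cM_start = min(.data$start), cM_end = max(.data$end),
      anchors = paste(.data$marker, collapse = ","),
      n_anchors = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      bp_start = purrr::map2_dbl(.data$chrom, .data$cM_start, smoother),
      bp_end = purrr::map2_dbl(.data$chrom, .data$cM_end, smoother)) |>
    dplyr::select("trait", "chrom", "cM_start", "cM_end",
                  "bp_start", "bp_end", "anchors", "n_anchors")
}

#' Merge QTL intervals across traits
#'
#' Overlapping physical intervals on the same chromosome are merged by
#' union and their trait lists concatenated.
#'
#' @param intervals Tibble from [build_intervals()].
#' @return Tibble `chrom`, `bp_start`, `bp_end`, `traits`, `n_traits`.
#' @export
merge_across_traits <- function(intervals) {
  if (!nrow(intervals)) {
    return(tibble(chrom = character(), bp_start = numeric(),
                  bp_end = numeric(), traits = character(),
                  n_traits = integer()))
  }
  intervals |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$bp_start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(.data$bp_start >
                                     dplyr::lag(cummax(.data$bp_end),
                                                default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      bp_start = min(.data$bp_start), bp_end = max(.data$bp_end),
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      n_traits = dplyr::n_distinct(.data$trait), .groups = "drop") |>
    dplyr::select(-"cluster")
}

#' Variance explained by anchor markers
#'
#' Adjusted R-squared of the least-squares regression of a trait's
#' genotypic values on the additive codings of all anchor markers.
#' Aliased (rank-deficient) columns are dropped by the pivoting solve.
#'
#' @param X A `qtlgp_design` matrix.
#' @param anchors Character vector of anchor marker names.
#' @param y Numeric trait vector.
#' @return Scalar adjusted R-squared (can be negative).
#' @export
pve_adjusted_r2 <- function(X, anchors, y) {
  if (!length(anchors)) stop("need at least one anchor marker", call. = FALSE)
  A <- additive_submatrix(X, anchors)
  df <- data.frame(y = as.numeric(y), A)
  fit <- lm(y ~ ., data = df)
  suppressWarnings(summary(fit))$adj.r.squared
}
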