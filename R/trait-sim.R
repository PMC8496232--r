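#' Place QTLs on the map
#'
#' Samples the marker positions of the simulated QTLs.  Under the `"same"`
#' distribution one set of `s` markers is drawn uniformly without replacement
#' and shared by all traits (QTLs at the same positions, hence genetic
#' correlation between traits).  Under `"diff"` each trait receives its own
#' set and the sets are disjoint (no QTL in common, hence no genetic
#' correlation).
#'
#' @param map Genetic map tibble.
#' @param s Number of QTLs per trait.
#' @param distribution `"same"` or `"diff"`.
#' @param k Number of traits (default 2).
#' @param seed Optional integer seed.
#' @return A list of `k` character vectors of marker names.
#' @export
place_qtls <- function(map, s, distribution = c("same", "diff"), k = 2,
                       seed = NULL) {
  distribution <- match.arg(distribution)
  validate_genetic_map(map)
  m <- nrow(map)
  if (s < 1 || s > m) stop("`s` must be between 1 and the marker count",
                           call. = FALSE)
  if (distribution == "diff" && k * s > m) {
    stop("`diff` needs k*s <= marker count for disjoint QTL sets",
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  if (distribution == "same") {
    set <- sample(map$marker, s)
    rep(list(set), k)
  } else {
    picks <- sample(map$marker, k * s)
    split(picks, rep(seq_len(k), each = s))
  }
}

# symmetric matrix square root; tolerates positive semi-definite inputs
# (zero variances, |rho| = 1) where a Cholesky factor does not exist
mat_sqrt <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(V)) %*% t(e$vectors)
}

genetic_covariance <- function(sigma2_B, rho_B, k = 2) {
  s2 <- rep_len(sigma2_B, k)
  V <- rho_B * sqrt(outer(s2, s2))
  diag(V) <- s2
  V
}

#' Draw QTL allelic effects
#'
#' Builds the `p x k` effects matrix `B` of the bivariate trait model
#' `Y = X B + E`.  Only the four additive rows of each QTL marker are
#' nonzero; all dominance rows are zero.  Under the `"same"` distribution the
#' `4 s` shared rows are drawn i.i.d. from a `k`-variate normal with genetic
#' covariance `V_B` (diagonal `sigma2_B`, off-diagonal
#' `rho_B * sigma_B1 * sigma_B2`), the row-independent form of the
#' matrix-variate normal `B ~ MN(0, I, V_B)`.  Under `"diff"` each trait's
#' `4 s` entries are drawn independently `N(0, sigma2_B)` at that trait's own
#' markers.
#'
#' @param X A `qtlgp_design` matrix (defines row indexing).
#' @param qtl_sets List of per-trait marker sets from [place_qtls()].
#' @param sigma2_B Per-trait genetic variance of individual allelic effects
#'   (scalar or length-`k`; default 0.1).
#' @param rho_B Genetic correlation between traits (default 0.8).
#' @param seed Optional integer seed.
#' @return A list of class `qtlgp_effects`: `B` (`p x k` matrix),
#'   `qtl_markers`, `V_B`.
#' @export
draw_effects <- function(X, qtl_sets, sigma2_B = 0.1, rho_B = 0.8,
                         seed = NULL) {
  info <- design_col_info(X)
  k <- length(qtl_sets)
  p <- ncol(X)
  if (!is.null(seed)) withr::local_seed(seed)
  B <- matrix(0, p, k)
  shared <- k > 1L && all(vapply(qtl_sets[-1L], identical, TRUE, y = qtl_sets[[1L]]))
  if (shared) {
    rows <- which(info$kind == "additive" & info$marker %in% qtl_sets[[1L]])
    V_B <- genetic_covariance(sigma2_B, rho_B, k)
    Z <- matrix(rnorm(length(rows) * k), length(rows), k)
    B[rows, ] <- Z %*% mat_sqrt(V_B)
  } else {
    s2 <- rep_len(sigma2_B, k)
    for (j in seq_len(k)) {
      rows <- which(info$kind == "additive" & info$marker %in% qtl_sets[[j]])
      B[rows, j] <- rnorm(length(rows), 0, sqrt(s2[j]))
    }
    V_B <- genetic_covariance(sigma2_B, if (k > 1) 0 else rho_B, k)
  }
  structure(list(B = B, qtl_markers = qtl_sets, V_B = V_B),
            class = "qtlgp_effects")
}

#' Deduce the error variance from a heritability target
#'
#' The simulation fixes the genetic architecture and *deduces* the error
#' variance so that the trait reaches a target narrow-sense heritability:
#' `sigma2_E = var(G) (1 - h2) / h2`, with `var(G)` the sample variance of
#' the realized genetic values.  Deducing from the realized (not expected)
#' genetic variance means every replicate hits its target heritability in
#' expectation regardless of the effects actually drawn.
#'
#' @param G Numeric vector of realized genetic values for one trait.
#' @param h2 Target narrow-sense heritability, strictly inside (0, 1).
#' @return Scalar error variance.
#' @examples
#' deduce_error_variance(c(-1, 0, 1) * sqrt(1), 0.8)
#' @export
deduce_error_variance <- function(G, h2) {
  if (h2 <= 0 || h2 >= 1) stop("`h2` must be strictly inside (0, 1)",
                               call. = FALSE)
  vG <- var(G)
  if (!is.finite(vG) || vG <= 0) {
    stop("realized genetic values have zero variance; redraw effects",
         call. = FALSE)
  }
  vG * (1 - h2) / h2
}

#' Simulate correlated quantitative traits
#'
#' Completes the model `Y = X B + E`: forms the true genetic values
#' `G = X B`, deduces the per-trait error variance from the target
#' heritabilities ([deduce_error_variance()]), and draws error rows i.i.d.
#' `k`-variate normal with covariance built from `rho_E` and the deduced
#' variances.  `Y = G + E` exactly.
#'
#' @param X A `qtlgp_design` matrix.
#' @param effects A `qtlgp_effects` object from [draw_effects()].
#' @param h2 Target narrow-sense heritability, scalar or length-`k`
#'   (e.g. `c(0.1, 0.5)` for the different-heritability set).
#' @param rho_E Residual correlation between traits (default 0).
#' @param seed Optional integer seed.
#' @return A list of class `qtlgp_traits`: `Y`, `G`, `E` (`n x k` matrices,
#'   trait columns named `y1 ... yk`), `sigma2_E`, `realized_h2`,
#'   `realized_genetic_cor` (for `k = 2`), `qtl_markers`, `effects`.
#' @export
sim_traits <- function(X, effects, h2 = 0.8, rho_E = 0, seed = NULL) {
  stopifnot(inherits(effects, "qtlgp_effects"))
  B <- effects$B
  if (nrow(B) != ncol(X)) stop("effects and design dimensions differ",
                               call. = FALSE)
  k <- ncol(B)
  n <- nrow(X)
  h2 <- rep_len(h2, k)
  if (!is.null(seed)) withr::local_seed(seed)

  nz <- which(rowSums(B != 0) > 0)
  G <- if (length(nz)) unclass(X)[, nz, drop = FALSE] %*% B[nz, , drop = FALSE]
       else matrix(0, n, k)
  sigma2_E <- vapply(seq_len(k), function(j) deduce_error_variance(G[, j], h2[j]),
                     numeric(1))
  V_E <- rho_E * sqrt(outer(sigma2_E, sigma2_E))
  diag(V_E) <- sigma2_E
  E <- matrix(rnorm(n * k), n, k) %*% mat_sqrt(V_E)
  Y <- G + E
  colnames(Y) <- colnames(G) <- colnames(E) <- paste0("y", seq_len(k))
  rownames(Y) <- rownames(G) <- rownames(E) <- rownames(X)
  realized_h2 <- vapply(seq_len(k), function(j) {
    var(G[, j]) / (var(G[, j]) + var(E[, j]))
  }, numeric(1))
  names(realized_h2) <- names(sigma2_E) <- colnames(Y)
  structure(list(
    Y = Y, G = G, E = E,
    sigma2_E = sigma2_E,
    realized_h2 = realized_h2,
    realized_genetic_cor = if (k == 2L) cor(G[, 1L], G[, 2L]) else NA_real_,
    qtl_markers = effects$qtl_markers,
    effects = effects
  ), class = "qtlgp_traits")
}

#' One-call simulation of a cross and a trait pair
#'
#' Convenience wrapper chaining [place_qtls()], [draw_effects()] and
#' [sim_traits()] on an existing design matrix, using one base seed for all
#' three draws.  Replicate `i` of a study should use `seed = base_seed + i`.
#'
#' @inheritParams sim_traits
#' @inheritParams place_qtls
#' @inheritParams draw_effects
#' @param map Genetic map matching `X`.
#' @return A `qtlgp_traits` object.
#' @export
sim_trait_study <- function(X, map, s = 50, distribution = "same",
                            h2 = 0.8, sigma2_B = 0.1, rho_B = 0.8,
                            rho_E = 0, k = 2, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  qtls <- place_qtls(map, s, distribution, k = k)
  eff <- draw_effects(X, qtls, sigma2_B = sigma2_B, rho_B = rho_B)
  sim_traits(X, eff, h2 = h2, rho_E = rho_E)
}

#' @export
print.qtlgp_traits <- function(x, ...) {
  cat(sprintf(
    "<qtlgp_traits> %d offspring x %d traits; %s QTLs/trait; realized h2: %s\n",
    nrow(x$Y), ncol(x$Y),
    paste(lengths(x$qtl_markers), collapse = "/"),
    paste(sprintf("%.3f", x$realized_h2), collapse = ", ")))
  invisible(x)
}

#' @rdname sim_traits
#' @param x A `qtlgp_traits` object.
#' @param ... Unused.
#' @method glance qtlgp_traits
#' @export
glance.qtlgp_traits <- function(x, ...) {
  tibble(
    n = nrow(x$Y), k = ncol(x$Y),
    s = length(x$qtl_markers[[1L]]),
    realized_h2 = list(x$realized_h2),
    realized_genetic_cor = x$realized_genetic_cor,
    sigma2_E = list(x$sigma2_E)
  )
}

#' @rdname sim_traits
#' @method tidy qtlgp_traits
#' @export
tidy.qtlgp_traits <- function(x, ...) {
  as_tibble(as.data.frame(x$Y)) |>
    dplyr::mutate(offspring = rownames(x$Y), .before = 1L) |>
    tidyr::pivot_longer(-"offspring", names_to = "trait", values_to = "value")
}
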