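#' Encode four-way genotype classes into a design matrix
#'
#' Each fully informative marker is expanded into eight predictor columns:
#' four additive columns counting the parental alleles `a`, `b`, `c`, `d`
#' carried by the offspring (each 0/1; `A_a + A_b = A_c + A_d = 1`, so the
#' four sum to 2) and four dominance columns, the 0/1 indicators of the
#' genotype classes `ac`, `ad`, `bc`, `bd` (summing to 1).  With `m` markers
#' the design has `p = 8 m` columns, grouped by marker in map order — 3,961
#' markers give 31,688 predictors.  Within a marker the eight columns have
#' rank at most 4; this known collinearity is left to the penalized fits to
#' absorb, so every parental allelic effect stays explicitly representable.
#'
#' @param genotypes Genotype tibble (from [sim_cross_genotypes()] or
#'   [read_genotypes()]) or a character matrix of classes.
#' @param map Optional map tibble; if given, columns are ordered to match and
#'   marker names are validated.
#' @return A numeric matrix of class `qtlgp_design` with attributes
#'   `col_info` (tibble: `marker`, `kind`, `label`) and `additive_cols`
#'   (indices of the `4 m` additive columns, in map order).
#' @examples
#' map <- sim_genetic_map(1, 2, seed = 1)
#' geno <- sim_cross_genotypes(map, 3, seed = 2)
#' X <- encode_design(geno, map)
#' dim(X)  # 3 x 16
#' @export
encode_design <- function(genotypes, map = NULL) {
  g <- geno_matrix(genotypes, map)
  n <- nrow(g)
  m <- ncol(g)
  markers <- colnames(g)
  cls <- matrix(match(g, GENO_CLASSES), n, m)  # 1=ac 2=ad 3=bc 4=bd

  X <- matrix(0, n, 8L * m)
  # defining class sets: additive a={ac,ad}, b={bc,bd}, c={ac,bc}, d={ad,bd};
  # dominance columns are the class indicators themselves
  sets <- list(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(2L, 4L),
               1L, 2L, 3L, 4L)
  for (k in seq_along(sets)) {
    w <- which(matrix(cls %in% sets[[k]], n, m), arr.ind = TRUE)
    X[(8L * (w[, 2L] - 1L) + k - 1L) * n + w[, 1L]] <- 1
  }
  labels <- c("a", "b", "c", "d", GENO_CLASSES)
  kinds <- rep(c("additive", "dominance"), each = 4L)
  col_info <- tibble(
    marker = rep(markers, each = 8L),
    kind = rep(kinds, m),
    label = rep(labels, m)
  )
  colnames(X) <- paste(col_info$marker, col_info$label, sep = "_")
  rownames(X) <- rownames(g)
  structure(
    X,
    col_info = col_info,
    additive_cols = which(col_info$kind == "additive"),
    class = c("qtlgp_design", "matrix", "array")
  )
}

#' Restrict a design matrix to the additive columns of chosen markers
#'
#' Simulated QTL effects live only on additive columns (all dominance effects
#' are zero), so the trait simulator and several oracles need the `4 s`
#' additive columns of a set of `s` markers, preserving map order.
#'
#' @param X A `qtlgp_design` matrix.
#' @param markers Character vector of marker names (may be empty).
#' @return Numeric matrix with `4 * length(markers)` columns.
#' @export
additive_submatrix <- function(X, markers) {
  info <- design_col_info(X)
  unknown <- setdiff(markers, info$marker)
  if (length(unknown)) {
    stop("unknown markers: ", paste(head(unknown, 3L), collapse = ", "),
         call. = FALSE)
  }
  keep <- which(info$kind == "additive" & info$marker %in% markers)
  X[, keep, drop = FALSE]
}

#' Column metadata of a design matrix
#' @param X A `qtlgp_design` matrix.
#' @return Tibble with columns `marker`, `kind`, `label`.
#' @export
design_col_info <- function(X) {
  info <- attr(X, "col_info")
  if (is.null(info)) stop("`X` is not a qtlgp_design matrix", call. = FALSE)
  info
}

# markers, in design order
design_markers <- function(X) unique(design_col_info(X)$marker)

# collapse predictor column indices to the markers they belong to
columns_to_markers <- function(X, cols) {
  unique(design_col_info(X)$marker[cols])
}

#' Biallelic dose coding of four-way genotypes
#'
#' Convenience 0/1/2 recoding for interoperability and for the LD
#' computations of the consensus module: the dose at a marker is the number
#' of "first" parental alleles carried, i.e. `#a + #c` (`ac` = 2, `ad` =
#' `bc` = 1, `bd` = 0).  No model-fitting operation depends on this coding.
#'
#' @inheritParams encode_design
#' @return Integer matrix (offspring x markers).
#' @export
dose_matrix <- function(genotypes, map = NULL) {
  g <- geno_matrix(genotypes, map)
  d <- matrix(c(2L, 1L, 1L, 0L)[match(g, GENO_CLASSES)], nrow(g), ncol(g))
  dimnames(d) <- dimnames(g)
  d
}

#' @export
print.qtlgp_design <- function(x, ...) {
  info <- design_col_info(x)
  cat(sprintf(
    "<qtlgp_design> %d offspring x %d predictors (%d markers x 8 columns)\n",
    nrow(x), ncol(x), length(unique(info$marker))))
  invisible(x)
}
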