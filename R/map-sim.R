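#' Haldane map function
#'
#' Converts a genetic distance in centiMorgans to a recombination fraction
#' under Haldane's no-interference model, `r = (1 - exp(-2 d / 100)) / 2`.
#' This is the map function used throughout the package, both for progeny
#' simulation and for genotype-probability interpolation between markers: it
#' makes the two-point formulas exact for a Markov model of meiosis.
#'
#' @param d_cM Numeric vector of nonnegative genetic distances (cM).
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 10, 1e6))
#' @export
haldane_r <- function(d_cM) {
  if (!is.numeric(d_cM)) stop("`d_cM` must be numeric", call. = FALSE)
  if (any(d_cM < 0)) stop("genetic distances must be nonnegative", call. = FALSE)
  0.5 * (1 - exp(-2 * d_cM / 100))
}

default_markers_per_chromosome <- function(n_chromosomes) {
  # split as evenly as possible while summing to ~3961 for 19 chromosomes
  if (n_chromosomes == 19L) c(rep(209L, 9L), rep(208L, 10L)) else
    rep(209L, n_chromosomes)
}

#' Simulate a genetic map for a four-way cross
#'
#' Generates an ordered marker map: `n_chromosomes` linkage groups, each
#' carrying `markers_per_chromosome` markers on `[0, chrom_length_cM]`
#' centiMorgans.  Physical positions are cumulative sums of positive random
#' increments scaled to `chrom_length_bp`, so they are strictly increasing
#' within each chromosome and define a noisy but monotone cM-to-bp relation
#' (as needed by [fit_cm_bp_smoother()]).
#'
#' The defaults emulate the shape of a dense consensus map for a grapevine-type
#' bi-parental progeny: 19 chromosomes and 3,961 fully informative markers in
#' total.
#'
#' @param n_chromosomes Number of chromosomes (default 19).
#' @param markers_per_chromosome Integer scalar or vector (recycled) of marker
#'   counts per chromosome.  The default places 3,961 markers on 19
#'   chromosomes.
#' @param chrom_length_cM Chromosome length in cM (scalar or vector).
#' @param chrom_length_bp Chromosome length in base pairs (scalar or vector).
#' @param spacing `"equidistant"` (default) or `"uniform"` marker placement.
#' @param seed Optional integer seed; the seed fully determines the map.
#' @return A tibble with columns `marker`, `chrom`, `pos_cM`, `pos_bp`.
#' @examples
#' map <- sim_genetic_map(n_chromosomes = 2, markers_per_chromosome = 5,
#'                        seed = 1)
#' map
#' @export
sim_genetic_map <- function(n_chromosomes = 19,
                            markers_per_chromosome = NULL,
                            chrom_length_cM = 75,
                            chrom_length_bp = 2.2e7,
                            spacing = c("equidistant", "uniform"),
                            seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_chromosomes < 1) stop("`n_chromosomes` must be positive", call. = FALSE)
  if (is.null(markers_per_chromosome)) {
    markers_per_chromosome <- default_markers_per_chromosome(as.integer(n_chromosomes))
  }
  m_chr <- as.integer(rep_len(markers_per_chromosome, n_chromosomes))
  len_cM <- rep_len(chrom_length_cM, n_chromosomes)
  len_bp <- rep_len(chrom_length_bp, n_chromosomes)
  if (any(m_chr < 1)) stop("marker counts must be positive", call. = FALSE)
  if (any(len_cM <= 0) || any(len_bp <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  one_chrom <- function(i) {
    m <- m_chr[i]
    pos_cM <- if (m == 1L) 0 else switch(spacing,
      equidistant = seq(0, len_cM[i], length.out = m),
      uniform = sort(runif(m, 0, len_cM[i]))
    )
    # strictly increasing bp: gamma increments rescaled to the chromosome span,
    # rounded, then offset by the marker index to break any rounding ties
    inc <- stats::rgamma(m, shape = 2, rate = 1)
    bp <- round(cumsum(inc) / sum(inc) * max(len_bp[i] - m, m)) + seq_len(m)
    tibble(
      marker = sprintf("chr%02d_m%04d", i, seq_len(m)),
      chrom = sprintf("chr%02d", i),
      pos_cM = pos_cM,
      pos_bp = as.integer(bp)
    )
  }
  map <- purrr::map_dfr(seq_len(n_chromosomes), one_chrom)
  validate_genetic_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the invariants assumed by every downstream operation: unique marker
#' names, nondecreasing cM and strictly increasing bp positions within each
#' chromosome.
#'
#' @param map A map tibble (`marker`, `chrom`, `pos_cM`, `pos_bp`).
#' @return The map, invisibly, or an error.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker", "chrom", "pos_cM", "pos_bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("duplicated marker names in map", call. = FALSE)
  if (any(map$pos_cM < 0)) stop("negative cM positions in map", call. = FALSE)
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      cM_ok = !is.unsorted(.data$pos_cM),
      bp_ok = all(diff(.data$pos_bp) > 0) || dplyr::n() == 1L,
      .groups = "drop"
    )
  if (any(!bad$cM_ok)) {
    stop("cM positions not nondecreasing on ",
         paste(bad$chrom[!bad$cM_ok], collapse = ", "), call. = FALSE)
  }
  if (any(!bad$bp_ok)) {
    stop("bp positions not strictly increasing on ",
         paste(bad$chrom[!bad$bp_ok], collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

GENO_CLASSES <- c("ac", "ad", "bc", "bd")

# simulate one parental allele sequence (0/1 states) along a chromosome as a
# two-state Markov chain with switch probabilities r between adjacent markers
sim_parent_states <- function(n, r_vec) {
  m <- length(r_vec) + 1L
  first <- sample(0:1, n, replace = TRUE)
  if (m == 1L) return(matrix(first, n, 1L))
  sw <- matrix(rbinom(n * (m - 1L), 1L, rep(r_vec, each = n)), n, m - 1L)
  states <- cbind(first, sw)
  # cumulative xor = cumulative sum mod 2
  t(apply(states, 1L, cumsum)) %% 2L
}

#' Simulate fully informative four-way-cross progeny genotypes
#'
#' Each offspring inherits, per chromosome, a maternal allele sequence over
#' `{a, b}` and an independent paternal sequence over `{c, d}`, each a
#' two-state Markov chain whose switch probability between adjacent markers is
#' [haldane_r()] of their cM distance (started uniformly).  Chromosomes are
#' independent.  The observed genotype class is the pair: one of `ac`, `ad`,
#' `bc`, `bd`, with no missing data (abxcd segregation).
#'
#' @param map A genetic map tibble from [sim_genetic_map()] or
#'   [read_genetic_map()].
#' @param n_offspring Number of offspring (default 188).
#' @param seed Optional integer seed.
#' @return A tibble with column `offspring` followed by one character column
#'   per marker, in map order.
#' @examples
#' map <- sim_genetic_map(2, 5, seed = 1)
#' geno <- sim_cross_genotypes(map, n_offspring = 4, seed = 2)
#' geno
#' @export
sim_cross_genotypes <- function(map, n_offspring = 188, seed = NULL) {
  validate_genetic_map(map)
  if (n_offspring < 1) stop("`n_offspring` must be positive", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_offspring)

  chroms <- unique(map$chrom)
  blocks <- lapply(chroms, function(ch) {
    d <- map$pos_cM[map$chrom == ch]
    r <- haldane_r(diff(d))
    mat <- sim_parent_states(n, r)   # 0 = a, 1 = b
    pat <- sim_parent_states(n, r)   # 0 = c, 1 = d
    cls <- matrix(GENO_CLASSES[2L * mat + pat + 1L], n, length(d))
    colnames(cls) <- map$marker[map$chrom == ch]
    cls
  })
  geno <- do.call(cbind, blocks)
  out <- as_tibble(as.data.frame(geno, stringsAsFactors = FALSE))
  out <- dplyr::bind_cols(
    tibble(offspring = sprintf("off_%04d", seq_len(n))), out
  )
  out
}

# internal: genotype tibble -> character matrix (offspring x markers)
geno_matrix <- function(genotypes, map = NULL) {
  if (is.matrix(genotypes)) {
    g <- genotypes
  } else {
    stopifnot(is.data.frame(genotypes))
    ids <- if ("offspring" %in% names(genotypes)) genotypes$offspring else
      sprintf("off_%04d", seq_len(nrow(genotypes)))
    g <- as.matrix(genotypes[setdiff(names(genotypes), "offspring")])
    rownames(g) <- ids
  }
  bad <- which(!(g %in% GENO_CLASSES))
  if (length(bad)) {
    pos <- arrayInd(bad[1L], dim(g))
    stop(sprintf(
      "unknown genotype class \"%s\" at marker %s, offspring row %d",
      g[bad[1L]], colnames(g)[pos[2L]], pos[1L]), call. = FALSE)
  }
  if (!is.null(map)) {
    validate_genetic_map(map)
    if (!setequal(colnames(g), map$marker)) {
      stop("genotype markers do not match the map", call. = FALSE)
    }
    g <- g[, map$marker, drop = FALSE]
  }
  g
}

#' Read and write the delimited input files
#'
#' The package exchanges three tab-separated formats: a genetic map
#' (`marker`, `chrom`, `pos_cM`, `pos_bp`), a genotype table (rows =
#' offspring, first column `offspring`, remaining columns markers with cells
#' in `{ac, ad, bc, bd}`) and a phenotype table (first column `offspring`,
#' remaining columns numeric trait values, typically genotypic BLUPs).
#' Readers validate on load: the pipeline assumes complete, fully informative
#' data, so unknown genotype classes, missing values or map inconsistencies
#' are errors, not warnings.
#'
#' @param path File path.
#' @param map Optional map tibble to validate genotype columns against.
#' @param x Object to write.
#' @return Readers return tibbles; writers return `x` invisibly.
#' @name qtlgp_io
NULL

#' @rdname qtlgp_io
#' @export
read_genetic_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE)
  validate_genetic_map(map)
  map
}

#' @rdname qtlgp_io
#' @export
write_genetic_map <- function(x, path) {
  validate_genetic_map(x)
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname qtlgp_io
#' @export
read_genotypes <- function(path, map = NULL) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (names(g)[1L] != "offspring") {
    stop("genotype file must start with an `offspring` column", call. = FALSE)
  }
  if (anyNA(g)) stop("missing values in genotype file; complete data required",
                     call. = FALSE)
  geno_matrix(g, map)  # validates classes and marker set
  g
}

#' @rdname qtlgp_io
#' @export
write_genotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname qtlgp_io
#' @export
read_phenotypes <- function(path) {
  y <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(y)[1L] != "offspring") {
    stop("phenotype file must start with an `offspring` column", call. = FALSE)
  }
  if (anyNA(y)) stop("missing values in phenotype file", call. = FALSE)
  y
}

#' @rdname qtlgp_io
#' @export
write_phenotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}
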