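hand_ld <- function(mat, threshold) {
  structure(list(matrices = list(chr01 = mat), threshold = threshold,
                 quantile_level = 0.95), class = "qtlgp_ld")
}

test_that("LD expansion adds exactly the above-threshold proxies", {
  m <- diag(4)
  rownames(m) <- colnames(m) <- paste0("m", 1:4)
  m["m1", "m2"] <- m["m2", "m1"] <- 0.9
  m["m2", "m3"] <- m["m3", "m2"] <- 0.9
  m["m1", "m4"] <- m["m4", "m1"] <- 0.3

  ld <- hand_ld(m, 0.8)
  # single pass: m3 is pulled in by m2 only if m2 was an input, not a proxy
  expect_setequal(ld_expand("m1", ld), c("m1", "m2"))
  expect_setequal(ld_expand(c("m1", "m2"), ld), c("m1", "m2", "m3"))

  # threshold 1: only perfect proxies join
  ld1 <- hand_ld(m, 1)
  expect_setequal(ld_expand("m1", ld1), "m1")
  m["m1", "m4"] <- m["m4", "m1"] <- 1
  expect_setequal(ld_expand("m1", hand_ld(m, 1)), c("m1", "m4"))
})

test_that("the LD threshold on simulated data is interior and reproducible", {
  cr <- small_cross()
  ld <- ld_matrix(cr$geno, cr$map)
  expect_gt(ld$threshold, 0)
  expect_lt(ld$threshold, 1)
  ld2 <- ld_matrix(cr$geno, cr$map)
  expect_identical(ld$threshold, ld2$threshold)

  # a duplicated marker column has LD = 1 and is always co-selected
  geno <- cr$geno
  dupmap <- dplyr::bind_rows(
    cr$map,
    tibble::tibble(marker = "dup", chrom = cr$map$chrom[1],
                   pos_cM = max(cr$map$pos_cM[cr$map$chrom == cr$map$chrom[1]]),
                   pos_bp = max(cr$map$pos_bp[cr$map$chrom == cr$map$chrom[1]]) + 1L)
  )
  geno$dup <- geno[[cr$map$marker[1]]]
  ldd <- ld_matrix(geno, dupmap)
  expect_true("dup" %in% ld_expand(cr$map$marker[1], ldd))
})

test_that("reliability rules fire on the method count and the MIM/EN.mFDR pair", {
  base <- tibble::tibble(trait = "y1", marker = "m1")
  five <- dplyr::bind_rows(lapply(c("SIM", "LASSO", "EN", "MTV_EN", "LASSO.SS"),
                                  function(m) dplyr::mutate(base, method = m)))
  expect_equal(tally_reliable(five)$marker, "m1")

  pair <- dplyr::bind_rows(dplyr::mutate(base, method = "EN.mFDR"),
                           dplyr::mutate(base, method = "MIM"))
  expect_equal(tally_reliable(pair)$marker, "m1")

  four <- dplyr::bind_rows(lapply(c("SIM", "LASSO", "EN", "MTV_EN"),
                                  function(m) dplyr::mutate(base, method = m)))
  expect_equal(nrow(tally_reliable(four)), 0L)

  # rule-(ii) subset property: the pair stays reliable whatever else selects
  mixed <- dplyr::bind_rows(pair, dplyr::mutate(base, method = "RR"))
  expect_equal(tally_reliable(mixed)$marker, "m1")

  # duplicated rows for one method count once
  dup <- dplyr::bind_rows(four, four)
  expect_equal(nrow(tally_reliable(dup)), 0L)
})

test_that("intervals are +-3 cM windows, merged and clipped", {
  map <- toy_map(101, by = 1)  # 0..100 cM, bp = 1e5 * cM + 1
  rel <- tibble::tibble(trait = "y1", marker = "m011")  # 10 cM
  iv <- build_intervals(rel, map)
  expect_equal(c(iv$cM_start, iv$cM_end), c(7, 13))

  rel2 <- tibble::tibble(trait = "y1", marker = c("m011", "m015"))  # 10, 14
  iv2 <- build_intervals(rel2, map)
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$cM_start, iv2$cM_end), c(7, 17))
  expect_equal(iv2$n_anchors, 2L)

  rel3 <- tibble::tibble(trait = "y1", marker = "m002")  # 1 cM, clips at 0
  iv3 <- build_intervals(rel3, map)
  expect_equal(c(iv3$cM_start, iv3$cM_end), c(0, 4))

  # disjoint anchors stay separate
  rel4 <- tibble::tibble(trait = "y1", marker = c("m011", "m051"))
  expect_equal(nrow(build_intervals(rel4, map)), 2L)
})

test_that("the cM-bp smoother is monotone and near-exact on a linear map", {
  map <- toy_map(60, by = 1)  # exactly 1 cM = 1e5 bp
  sm <- fit_cm_bp_smoother(map)
  q <- seq(0, 59, by = 0.5)
  bp <- sm("chr01", q)
  expect_true(all(diff(bp) >= 0))
  lin <- q * 1e5 + 1
  expect_lt(max(abs(bp - lin) / pmax(lin, 1e5)), 0.01)
  # residuals at input markers are within the smoothing tolerance
  at <- sm("chr01", map$pos_cM)
  expect_lt(max(abs(at - map$pos_bp)) / 1e5, 0.5)
  # inverse maps back
  inv <- attr(sm, "inverse")
  expect_equal(inv("chr01", sm("chr01", 30)), 30, tolerance = 0.5)
  expect_error(sm("nope", 1), "unknown chromosome")
  expect_warning(fit_cm_bp_smoother(toy_map(3)), "fewer than 5")
})

test_that("physical intervals merge across traits by union", {
  iv <- tibble::tibble(
    trait = c("y1", "y2", "y3"), chrom = "chr01",
    cM_start = c(10, 15, 40), cM_end = c(20, 30, 50),
    bp_start = c(1e6, 1.5e6, 4e6), bp_end = c(2e6, 3e6, 5e6),
    anchors = "x", n_anchors = 1L
  )
  mg <- merge_across_traits(iv)
  expect_equal(nrow(mg), 2L)
  expect_equal(mg$bp_start, c(1e6, 4e6))
  expect_equal(mg$bp_end, c(3e6, 5e6))
  expect_equal(mg$traits[1], "y1,y2")

  iv$bp_start <- c(1e6, 1e6, 1e6); iv$bp_end <- c(2e6, 2e6, 2e6)
  mg2 <- merge_across_traits(iv)
  expect_equal(nrow(mg2), 1L)
  expect_equal(mg2$n_traits, 3L)
  expect_equal(nrow(merge_across_traits(iv[0, ])), 0L)
})

test_that("variance explained matches the least-squares oracle", {
  cr <- small_cross()
  mk <- unique(design_col_info(cr$X)$marker)

  # noiseless linear function of one anchor's additive coding
  A <- additive_submatrix(cr$X, mk[3])
  y <- drop(A %*% c(2, -1, 0.5, 0))
  expect_equal(pve_adjusted_r2(cr$X, mk[3], y), 1, tolerance = 1e-9)

  # trait independent of the anchors
  withr::local_seed(103)
  expect_lt(abs(pve_adjusted_r2(cr$X, mk[3], rnorm(120))), 0.15)

  # planted-variance toy vs an explicit projection oracle
  tp <- sim_trait_study(cr$X, cr$map, s = 3, h2 = 0.6, seed = 104)
  anchors <- tp$qtl_markers[[1]]
  yv <- tp$Y[, 1]
  Aa <- additive_submatrix(cr$X, anchors)
  fit <- lm.fit(cbind(1, Aa), yv)
  rank <- fit$rank
  r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  adj <- 1 - (1 - r2) * (120 - 1) / (120 - rank)
  expect_equal(pve_adjusted_r2(cr$X, anchors, yv), adj, tolerance = 1e-8)
})

test_that("consensus intervals are enriched for true QTLs end-to-end", {
  map <- sim_genetic_map(6, 12, chrom_length_cM = 60, seed = 111)
  containing <- 0L; total <- 0L
  for (rep in 1:5) {
    geno <- sim_cross_genotypes(map, 150, seed = 120 + rep)
    X <- encode_design(geno, map)
    tp <- sim_trait_study(X, map, s = 20, h2 = 0.8, seed = 130 + rep)
    y <- tp$Y[, 1]
    pr <- calc_genoprob(geno, map, step_cM = NULL)
    ld <- ld_matrix(geno, map)

    thr <- permutation_threshold(pr, y, n_perm = 20, seed = 140 + rep)
    sels <- list(
      SIM = {
        pk <- find_peaks(scan_sim(pr, y), thr)
        vapply(seq_len(nrow(pk)), function(i) pk$marker[i], character(1))
      },
      MIM = mim_stepwise(pr, y, 4, max(thr, 1), n_restarts = 2,
                         seed = 150 + rep)$positions$marker,
      LASSO = tune_penalized(X, y, "LASSO", nlambda = 40,
                             seed = 160 + rep)$selected_markers,
      MTV_LASSO = tune_penalized(X, tp$Y, "MTV_LASSO", nlambda = 40,
                                 seed = 170 + rep)$selected_markers,
      LASSO.SS = stability_selection(X, y, "LASSO", n_subsamples = 25,
                                     pi_threshold = 0.6,
                                     seed = 180 + rep)$selected_markers,
      EN.mFDR = select_at_mfdr(mfdr_path(X, y, "EN"), 0.1)$selected_markers
    )
    long <- purrr::imap_dfr(sels, function(mk, nm) {
      mk <- ld_expand(mk[!is.na(mk)], ld)
      if (!length(mk)) return(tibble::tibble())
      tibble::tibble(trait = "y1", method = nm, marker = mk)
    })
    rel <- tally_reliable(long)
    if (!nrow(rel)) next
    iv <- build_intervals(rel, map)
    truth <- map[match(tp$qtl_markers[[1]], map$marker), ]
    hit <- vapply(seq_len(nrow(iv)), function(i) {
      any(truth$chrom == iv$chrom[i] &
            truth$pos_cM >= iv$cM_start[i] - 1e-9 &
            truth$pos_cM <= iv$cM_end[i] + 1e-9)
    }, logical(1))
    containing <- containing + sum(hit)
    total <- total + length(hit)
  }
  expect_gt(total, 0L)
  expect_gte(containing / total, 0.6)
})
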