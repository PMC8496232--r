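test_that("class probabilities are indicators at markers and normalized everywhere", {
  cr <- small_cross()
  sub <- cr$map[cr$map$chrom == "chr01", ]
  pr <- calc_genoprob(cr$geno, cr$map, step_cM = 2)
  g <- as.matrix(cr$geno[-1])

  for (mk in sample(sub$marker, 5)) {
    cp <- class_probs(pr, "chr01", sub$pos_cM[sub$marker == mk])
    expect_true(all(abs(rowSums(cp) - 1) < 1e-10))
    obs <- g[, mk]
    expect_equal(cp[cbind(seq_len(nrow(cp)), match(obs, colnames(cp)))],
                 rep(1, nrow(cp)), ignore_attr = TRUE)
  }
  # a pseudomarker position: still normalized, strictly interior probabilities
  b <- pr$chroms[["chr01"]]
  j <- which(is.na(b$marker))[1]
  cp <- class_probs(pr, "chr01", b$pos[j])
  expect_true(all(abs(rowSums(cp) - 1) < 1e-10))
  expect_true(all(cp >= 0 & cp <= 1))
})

test_that("the bridge probability at a midpoint matches the closed form", {
  map <- toy_map(2, by = 20)
  geno <- tibble::tibble(offspring = c("o1", "o2"),
                         m001 = c("ac", "ac"), m002 = c("ac", "bc"))
  pr <- calc_genoprob(geno, map, step_cM = 10)
  cp <- class_probs(pr, "chr01", 10)
  r <- haldane_r(10)
  p_same <- (1 - r)^2 / ((1 - r)^2 + r^2)  # same maternal allele both flanks
  # o1: flanks a/a and c/c
  expect_equal(unname(cp["o1", "ac"]), p_same^2, tolerance = 1e-12)
  # o2: maternal a -> b discordant, paternal c concordant
  p_disc <- (1 - r) * r / haldane_r(20)
  expect_equal(unname(cp["o2", "ac"]), p_disc * p_same, tolerance = 1e-12)

  # zero-distance bracket keeps the marker indicator
  map0 <- tibble::tibble(marker = c("m1", "m2"), chrom = "chr01",
                         pos_cM = c(0, 0), pos_bp = c(1L, 2L))
  geno0 <- tibble::tibble(offspring = "o1", m1 = "ad", m2 = "ad")
  pr0 <- calc_genoprob(geno0, map0, step_cM = 0.1)
  expect_equal(unname(class_probs(pr0, "chr01", 0)["o1", "ad"]), 1)
})

test_that("the bridge matches a meiosis simulation at an interior point", {
  # markers 20 cM apart; condition on both flanks carrying maternal 'a'
  withr::local_seed(31)
  n <- 200000
  r10 <- haldane_r(10)
  left <- rbinom(n, 1, 0.5)
  mid <- ifelse(rbinom(n, 1, r10), 1 - left, left)
  right <- ifelse(rbinom(n, 1, r10), 1 - mid, mid)
  sim <- mean(mid[left == 0 & right == 0] == 0)
  closed <- (1 - r10)^2 / ((1 - r10)^2 + r10^2)
  expect_equal(sim, closed, tolerance = 0.01)
})

test_that("LOD scans match a direct least-squares oracle", {
  map <- toy_map(2, by = 5)
  withr::local_seed(33)
  geno <- sim_cross_genotypes(map, 8, seed = 34)
  y <- rnorm(8)
  pr <- calc_genoprob(geno, map, step_cM = NULL)
  sc <- scan_sim(pr, y)
  for (i in 1:2) {
    cp <- class_probs(pr, "chr01", sc$pos[i])
    rss1 <- sum(lm(y ~ cp[, 1:3])$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    expect_equal(sc$lod[i], 8 / 2 * log10(rss0 / rss1), tolerance = 1e-8)
  }

  # constant trait: zero LOD everywhere
  expect_true(all(scan_sim(pr, rep(2, 8))$lod == 0))

  # perfect class-mean response: capped LOD at the marker
  y2 <- match(geno$m001, c("ac", "ad", "bc", "bd"))
  expect_warning(sc2 <- scan_sim(pr, y2), "capped")
  expect_equal(max(sc2$lod), 300)
  expect_equal(sc2$pos[which.max(sc2$lod)], 0)
})

test_that("permutation thresholds behave like empirical quantiles", {
  cr <- small_cross()
  pr <- calc_genoprob(cr$geno, cr$map, step_cM = NULL)
  withr::local_seed(35)
  y <- rnorm(120)
  t5 <- permutation_threshold(pr, y, n_perm = 50, fwer = 0.05, seed = 36)
  t1 <- permutation_threshold(pr, y, n_perm = 50, fwer = 0.01, seed = 36)
  tall <- permutation_threshold(pr, y, n_perm = 50, fwer = 1, seed = 36)
  expect_gte(t1, t5)           # stricter FWER, higher threshold
  expect_gt(tall, 0)
  expect_lte(tall, t5)         # fwer = 1 is the minimum of the maxima
  t5b <- permutation_threshold(pr, y, n_perm = 50, fwer = 0.05, seed = 37)
  expect_false(identical(t5, t5b))
  expect_gt(t5b, 0)
  expect_error(permutation_threshold(pr, y, n_perm = 5), "at least 10")
})

test_that("genome-wide FWER is controlled near its nominal level on null data", {
  map <- sim_genetic_map(3, 10, chrom_length_cM = 60, seed = 41)
  geno <- sim_cross_genotypes(map, 60, seed = 42)
  pr <- calc_genoprob(geno, map, step_cM = NULL)
  withr::local_seed(43)
  thr <- permutation_threshold(pr, rnorm(60), n_perm = 200, seed = 44)
  exceed <- vapply(1:150, function(i) {
    max(scan_sim(pr, rnorm(60))$lod) > thr
  }, logical(1))
  # nominal 5%; binomial sd ~ 1.8% over 150 trials
  expect_lt(mean(exceed), 0.12)
  expect_gt(mean(exceed), 0.005)
})

test_that("LOD support intervals enumerate the drop region exactly", {
  sc <- tibble::tibble(
    chrom = "chr01", pos = 0:8, marker = NA_character_,
    lod = c(0.1, 1.5, 2.5, 3.4, 4.0, 3.2, 2.9, 1.0, 0.2)
  )
  class(sc) <- c("qtlgp_scan", class(sc))
  iv <- lod_support_interval(sc, "chr01", 4, drop = 1)
  expect_equal(c(iv$start, iv$end), c(3, 5))  # lod >= 3.0 contiguous
  # flat curve: the whole chromosome
  sc$lod <- rep(2, 9)
  iv2 <- lod_support_interval(sc, "chr01", 4, drop = 1)
  expect_equal(c(iv2$start, iv2$end), c(0, 8))
  # drop = 0 keeps the peak (plus exact ties)
  sc$lod <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  iv3 <- lod_support_interval(sc, "chr01", 4, drop = 0)
  expect_equal(c(iv3$start, iv3$end), c(4, 4))
})

test_that("stepwise MIM finds planted QTLs and respects its penalty", {
  map <- sim_genetic_map(3, 12, chrom_length_cM = 60, seed = 51)
  geno <- sim_cross_genotypes(map, 120, seed = 52)
  X <- encode_design(geno, map)
  pr <- calc_genoprob(geno, map, step_cM = NULL)

  # null data with a prohibitive penalty: empty model
  withr::local_seed(53)
  ynull <- rnorm(120)
  m0 <- mim_stepwise(pr, ynull, max_qtl = 4, penalty = 50, n_restarts = 2,
                     seed = 54)
  expect_equal(nrow(m0$positions), 0L)
  expect_equal(m0$plod, 0)

  # max_qtl = 0 always yields the empty model
  tp <- sim_trait_study(X, map, s = 1, h2 = 0.8, seed = 55)
  mq0 <- mim_stepwise(pr, tp$Y[, 1], max_qtl = 0, penalty = 3, seed = 56)
  expect_equal(nrow(mq0$positions), 0L)

  # single strong QTL: found within 2 cM in >= 9/10 seeds
  hits <- 0L
  for (i in 1:10) {
    tpi <- sim_trait_study(X, map, s = 1, h2 = 0.8, seed = 600 + i)
    mi <- mim_stepwise(pr, tpi$Y[, 1], max_qtl = 4, penalty = 3,
                       n_restarts = 2, seed = 700 + i)
    truth <- map[match(tpi$qtl_markers[[1]], map$marker), ]
    ok <- nrow(mi$positions) >= 1L &&
      any(mi$positions$chrom == truth$chrom &
            abs(mi$positions$pos - truth$pos_cM) <= 2)
    hits <- hits + ok
  }
  expect_gte(hits, 9L)

  # the first forward step is the SIM peak
  sc <- scan_sim(pr, tp$Y[, 1])
  best <- sc[which.max(sc$lod), ]
  m1 <- mim_stepwise(pr, tp$Y[, 1], max_qtl = 1, penalty = 3, n_restarts = 1,
                     seed = 57)
  expect_equal(m1$positions$pos, best$pos)
  expect_equal(m1$positions$chrom, best$chrom)
})

test_that("QTL-based prediction matches the normal-equations oracle", {
  map <- sim_genetic_map(2, 10, chrom_length_cM = 50, seed = 61)
  geno <- sim_cross_genotypes(map, 80, seed = 62)
  X <- encode_design(geno, map)
  pr <- calc_genoprob(geno, map, step_cM = NULL)
  tp <- sim_trait_study(X, map, s = 2, h2 = 0.8, seed = 63)
  truth <- map[match(tp$qtl_markers[[1]], map$marker), ]
  pos <- tibble::tibble(chrom = truth$chrom, pos = truth$pos_cM)

  tr <- 1:60; te <- 61:80
  ptr <- qtlgp:::subset_genoprob(pr, tr)
  pte <- qtlgp:::subset_genoprob(pr, te)
  pred <- im_predict(pos, ptr, tp$Y[tr, 1], pte)

  D <- cbind(1, qtlgp:::hk_design(pr, pos))
  beta <- qr.solve(crossprod(D[tr, ]), crossprod(D[tr, ], tp$Y[tr, 1]))
  expect_equal(pred, drop(D[te, ] %*% beta), tolerance = 1e-6)

  # empty model: training mean
  empty <- tibble::tibble(chrom = character(), pos = numeric())
  expect_equal(im_predict(empty, ptr, tp$Y[tr, 1], pte),
               rep(mean(tp$Y[tr, 1]), 20))

  # noiseless class-mean response at one marker: perfect test prediction
  yperf <- match(geno$chr01_m0003, c("ac", "ad", "bc", "bd"))
  pos1 <- tibble::tibble(chrom = "chr01",
                         pos = map$pos_cM[map$marker == "chr01_m0003"])
  predp <- im_predict(pos1, ptr, yperf[tr], pte)
  expect_equal(predp, yperf[te], tolerance = 1e-8)
})
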