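test_that("null fit recovers h2 and degrades to OLS without kinship", {
  # h2 = 0: iid noise, estimate should be small
  cfg <- quick_sim(seed = 31, n = 500, markers = 31)
  gp <- simulate_genome(cfg)
  ids <- individual_ids(gp)
  K <- compute_kinship(gp, "overall")[["overall"]]
  set.seed(311)
  y0 <- named_trait(rnorm(500), ids)
  f0 <- fit_null(y0, intercept_cov(ids), K)
  expect_lt(f0$h2, 0.15)

  # h2 = 0.5: simulate from the model with known K and recover within 0.15
  ed <- decompose_kinship(K)
  cfg4 <- quick_sim(seed = 32, n = 400, markers = 31)
  gp4 <- simulate_genome(cfg4)
  ids4 <- individual_ids(gp4)
  K4 <- compute_kinship(gp4, "overall")[["overall"]]
  ed4 <- decompose_kinship(K4)
  set.seed(321)
  # simulate exactly from V = h2 K + (1-h2) I with h2 = 0.5
  g <- as.numeric(ed4$vectors %*% (sqrt(ed4$values) * rnorm(400)))
  y5 <- named_trait(sqrt(0.5) * g + sqrt(0.5) * rnorm(400), ids4)
  f5 <- fit_null(y5, intercept_cov(ids4), K4)
  expect_lt(abs(f5$h2 - 0.5), 0.15)

  # K = identity: LODs downstream identical to kinship = none
  gp_s <- simulate_genome(quick_sim(seed = 33, n = 60, markers = 11))
  ids_s <- individual_ids(gp_s)
  set.seed(331)
  ys <- named_trait(rnorm(60), ids_s)
  I_K <- diag(60); dimnames(I_K) <- list(ids_s, ids_s)
  sc_I <- scan_additive(gp_s, ys, intercept_cov(ids_s), I_K)
  sc_0 <- scan_additive(gp_s, ys, intercept_cov(ids_s), NULL)
  expect_equal(sc_I$lod, sc_0$lod, tolerance = 1e-6)

  # rank-deficient covariates error names the collinear column
  X <- cbind(intercept = 1, a = rnorm(60), b = 0)
  X[, "b"] <- X[, "a"] * 2
  rownames(X) <- ids_s
  expect_error(fit_null(ys, covariate_matrix(X), NULL), "\\bb\\b")
})

test_that("ols-oracle equivalence on random small instances (kinship = none)", {
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    m <- sample(3:12, 1)
    cfg <- quick_sim(seed = 3400 + rep, n = n, markers = m,
                     chromosomes = one_chr)
    gp <- simulate_genome(cfg)
    ids <- individual_ids(gp)
    y <- named_trait(rnorm(n), ids)
    X <- cbind(intercept = 1, cov1 = rnorm(n))
    rownames(X) <- ids
    cov <- covariate_matrix(X)
    sc <- scan_additive(gp, y, cov, NULL)
    a <- gp[["1"]]
    for (j in seq_len(m)) {
      expect_equal(sc$lod[j], oracle_lod(X, a[, , j], as.numeric(y)),
                   tolerance = 1e-8)
    }
  }
})

test_that("degenerate markers and invariances behave as specified", {
  cfg <- quick_sim(seed = 35, n = 80, markers = 7, chromosomes = one_chr,
                   blur = FALSE)
  gp <- simulate_genome(cfg)
  ids <- individual_ids(gp)
  set.seed(351)
  y <- named_trait(rnorm(80), ids)
  cov <- intercept_cov(ids)

  # genoprob slice identical across individuals -> LOD 0
  a <- gp[["1"]]
  a[, , 4] <- matrix(rep(c(.5, .5, 0, 0, 0, 0, 0, 0), each = 80), 80, 8)
  gp_c <- geno_probs(list(`1` = a), attr(gp, "map"))
  sc <- scan_additive(gp_c, y, cov, NULL)
  expect_equal(sc$lod[4], 0, tolerance = 1e-10)

  # affine invariance: y -> a*y + b leaves LODs unchanged
  sc0 <- scan_additive(gp, y, cov, NULL)
  sc1 <- scan_additive(gp, named_trait(-2.5 * as.numeric(y) + 7, ids), cov, NULL)
  expect_equal(sc0$lod, sc1$lod, tolerance = 1e-6)

  # founder-column-drop invariance: dropping any founder column leaves the
  # fitted subspace (with intercept) unchanged
  for (f in c(1, 5, 8)) {
    gp_d <- gp
    a_d <- gp_d[["1"]]
    lods <- vapply(seq_len(dim(a_d)[3]), function(j)
      oracle_lod(matrix(1, 80, 1), a_d[, -f, j], as.numeric(y)), numeric(1))
    expect_equal(sc0$lod, lods, tolerance = 1e-8)
  }
})

test_that("planted additive QTL is localized by the scan", {
  hits <- 0L
  for (rep in 1:5) {
    cfg <- sim_config(n_individuals = 200, chromosomes = one_chr,
                      markers_per_chr = 101, seed = 3600 + rep,
                      traits = list(sim_trait("q", loci = list(
                        list(chr = "1", marker = 50, frac = 0.4, sdp = 34)))))
    gp <- simulate_genome(cfg)
    sim <- simulate_traits(gp, cfg)
    y <- named_trait(unclass(sim$traits)[, "q"], individual_ids(gp))
    sc <- scan_additive(gp, y, sim$covariates, NULL)
    if (abs(which.max(sc$lod) - 50) <= 5) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("interactive scans: nesting, null interaction, planted interaction", {
  cfg <- quick_sim(seed = 37, n = 300, markers = 41, chromosomes = one_chr,
                   traits = list(sim_trait("add", loci = list(
                     list(chr = "1", marker = 20, frac = 0.3, sdp = 12)))))
  gp <- simulate_genome(cfg)
  tt <- simulate_traits(gp, cfg)
  ids <- individual_ids(gp)
  y <- named_trait(unclass(tt$traits)[, "add"], ids)
  res <- scan_interactive(gp, y, tt$covariates, "sexM", NULL)

  # monotone nesting: full >= additive >= 0 everywhere
  expect_true(all(res$full$lod - res$additive$lod >= -1e-6))
  expect_true(all(res$additive$lod >= -1e-8))
  expect_true(all(res$delta$lod >= -1e-6))
  # pure additive QTL: interaction carries no signal
  expect_lt(max(res$delta$lod), max(res$additive$lod))

  # planted opposite-sign sex-by-QTL interaction
  sex <- unclass(tt$covariates)[, "sexM"]
  a <- gp[["1"]]
  dose <- as.numeric(a[, , 20] %*% ifelse(sdp_to_bits(34), 0.5, -0.5))
  set.seed(371)
  yint <- named_trait(scale(dose)[, 1] * ifelse(sex == 1, 1, -1) + rnorm(300) * 0.6,
                      ids)
  res2 <- scan_interactive(gp, yint, tt$covariates, "sexM", NULL)
  expect_gt(max(res2$delta$lod), 3)
  expect_lte(abs(which.max(res2$delta$lod) - 20), 5)

  # degenerate factor errors
  Xc <- unclass(tt$covariates)
  Xc[, "sexM"] <- 0
  cov_c <- covariate_matrix(Xc, attr(tt$covariates, "info"))
  expect_error(scan_interactive(gp, y, cov_c, "sexM", NULL), "constant")
  expect_error(scan_interactive(gp, y, tt$covariates, "nosuch", NULL), "not found")
})

test_that("null calibration: per-marker LOD under no QTL matches its chi-square law", {
  # At a fixed marker with no planted QTL, 2 ln(10) LOD is asymptotically
  # chi-square with 7 df for the 8-founder dosage block (median LOD
  # ~ 6.35 / (2 ln 10) ~ 1.38) and 1 df for a single SNP dosage (median
  # ~ 0.455 / (2 ln 10) ~ 0.10). The loose sanity bands below bracket those
  # medians; note a 7-df scan can never have median LOD below 0.5.
  lod8 <- numeric(30); lod1 <- numeric(30)
  for (rep in seq_along(lod8)) {
    cfg <- sim_config(n_individuals = 100, chromosomes = one_chr,
                      markers_per_chr = 21, seed = 3800 + rep,
                      traits = list(sim_trait("y0", h2 = 0.3)))
    gp <- simulate_genome(cfg)
    tt <- simulate_traits(gp, cfg)
    ids <- individual_ids(gp)
    y <- named_trait(unclass(tt$traits)[, "y0"], ids)
    K <- compute_kinship(gp, "overall")[["overall"]]
    sc <- scan_additive(gp, y, tt$covariates, K)
    lod8[rep] <- sc$lod[11]  # fixed marker
    d <- sdp_dosage(gp, "1", attr(gp, "map")$pos_Mbp[11], 34)
    lod1[rep] <- oracle_lod(unclass(tt$covariates), d, as.numeric(y))
  }
  expect_gt(median(lod8), 0.5)   # 7-df law, well above the 1-df scale
  expect_lt(median(lod8), 2.5)
  expect_lt(median(lod1), 0.5)   # 1-df law: the small-median band applies here
})

test_that("scan LOD is invariant to jointly rescaling the kinship matrix", {
  cfg <- quick_sim(seed = 39, n = 80, markers = 9,
                   traits = list(sim_trait("y", h2 = 0.4, loci = list(
                     list(chr = "1", marker = 5, frac = 0.2, sdp = 160)))))
  gp <- simulate_genome(cfg)
  tt <- simulate_traits(gp, cfg)
  ids <- individual_ids(gp)
  y <- named_trait(unclass(tt$traits)[, "y"], ids)
  K <- compute_kinship(gp, "overall")[["overall"]]
  sc1 <- scan_additive(gp, y, tt$covariates, K)
  sc2 <- scan_additive(gp, y, tt$covariates, K * 3.7)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-4)
})
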