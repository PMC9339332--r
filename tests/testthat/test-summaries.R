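mk_scan <- function(lod, trait_id = "t", chr = "1") {
  m <- length(lod)
  map <- data.frame(marker_id = sprintf("%s_%03d", chr, 1:m),
                    chromosome = chr, pos_cM = 1:m, pos_Mbp = as.numeric(1:m),
                    stringsAsFactors = FALSE)
  structure(list(map = map, lod = lod, kind = "additive",
                 trait_id = trait_id), class = "lod_scan")
}

test_that("peak calling: threshold, peakdrop, support intervals", {
  expect_equal(nrow(find_peaks(mk_scan(rep(0, 20)), threshold = 3)), 0L)

  # single triangular peak of height 8 at marker 50
  tri <- pmax(0, 8 - abs(1:101 - 50) * 0.4)
  pk <- find_peaks(mk_scan(tri), threshold = 7)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$pos_Mbp, 50)
  expect_equal(pk$lod, 8)
  # support interval: contiguous region within 1.5 LOD of the peak
  expect_true(pk$ci_lo_Mbp <= 50 - 3 + 1 && pk$ci_hi_Mbp >= 50 + 3 - 1)
  expect_true(pk$ci_lo_Mbp <= pk$pos_Mbp && pk$ci_hi_Mbp >= pk$pos_Mbp)

  # two peaks (8 and 7.5) separated by a valley at 4
  lod2 <- c(pmax(0, 8 - abs(1:30 - 15) * 0.5),
            rep(4, 5),
            pmax(0, 7.5 - abs(1:30 - 15) * 0.5))
  pk_drop <- find_peaks(mk_scan(lod2), threshold = 7, peakdrop = 1.8)
  expect_equal(nrow(pk_drop), 2L)
  expect_equal(sort(pk_drop$lod), c(7.5, 8))
  pk_one <- find_peaks(mk_scan(lod2), threshold = 7)
  expect_equal(nrow(pk_one), 1L)
  expect_equal(pk_one$lod, 8)
})

test_that("peak calling is threshold-monotone (property)", {
  set.seed(71)
  for (rep in 1:10) {
    lod <- abs(cumsum(rnorm(60, sd = 0.8)))
    sc <- mk_scan(lod)
    prev <- Inf
    for (thr in c(1, 2, 3, 5)) {
      k <- nrow(find_peaks(sc, threshold = thr, peakdrop = 1.5))
      expect_lte(k, prev)
      prev <- k
    }
  }
})

test_that("transcriptome map labels local vs distal", {
  peaks <- structure(data.frame(
    trait_id = c("g13", "g_near", "g_far", "g_unk"),
    chromosome = c("13", "11", "11", "2"),
    marker_id = paste0("m", 1:4),
    pos_Mbp = c(65, 22, 62, 10), lod = c(12, 9, 8, 7.2),
    ci_lo_Mbp = NA_real_, ci_hi_Mbp = NA_real_,
    stringsAsFactors = FALSE), class = c("peak_table", "data.frame"))
  ann <- data.frame(trait_id = c("g13", "g_near", "g_far"),
                    symbol = c("S", "N", "F"),
                    chromosome = c("11", "11", "11"),
                    midpoint_Mbp = c(70, 20, 22), stringsAsFactors = FALSE)
  tm <- transcriptome_map(peaks, ann, window_Mbp = 10)
  expect_equal(attr(tm, "n_skipped"), 1L)
  # QTL on chr 13 for a gene on chr 11 -> distal
  expect_equal(tm$type[tm$trait_id == "g13"], "distal")
  # 2 Mbp away on the same chromosome -> local
  expect_equal(tm$type[tm$trait_id == "g_near"], "local")
  # 40 Mbp away on the same chromosome -> distal
  expect_equal(tm$type[tm$trait_id == "g_far"], "distal")

  # shrinking the window never converts distal -> local
  tm5 <- transcriptome_map(peaks, ann, window_Mbp = 5)
  for (id in tm$trait_id[tm$type == "distal"])
    expect_equal(tm5$type[tm5$trait_id == id], "distal")
})

test_that("hotspot counts bin distal peaks deterministically", {
  tmap <- data.frame(chromosome = rep("3", 10), pos_Mbp = rep(9.7, 10),
                     type = "distal", stringsAsFactors = FALSE)
  hc <- hotspot_counts(tmap, window_Mbp = 4)
  expect_equal(sum(hc$count), 10L)
  expect_equal(hc$count[hc$bin_lo_Mbp == 8], 10L)

  # empty table -> all-zero counts over declared chromosome lengths
  hc0 <- hotspot_counts(tmap[0, ], window_Mbp = 4, chr_lengths = c(`1` = 12))
  expect_equal(nrow(hc0), 3L)
  expect_true(all(hc0$count == 0L))

  # uniform peaks: occupancy consistent with a Poisson spread (loose band)
  set.seed(72)
  tu <- data.frame(chromosome = "1", pos_Mbp = runif(40, 0, 100),
                   type = "distal", stringsAsFactors = FALSE)
  hcu <- hotspot_counts(tu, window_Mbp = 4, chr_lengths = c(`1` = 100))
  expect_equal(sum(hcu$count), 40L)
  expect_lt(max(hcu$count), stats::qpois(0.9999, 40 / 25) + 3)
})

test_that("correlation: identities, residualization, planted negative pair", {
  ids <- sprintf("i%02d", 1:40)
  set.seed(73)
  y <- named_trait(rnorm(40), ids)
  ds <- trait_matrix(cbind(self = as.numeric(y), neg = -as.numeric(y),
                           other = rnorm(40)) |>
                       `rownames<-`(ids))
  res <- correlate(y, ds)
  expect_equal(res$r[res$trait_id == "self"], 1)
  expect_equal(res$r[res$trait_id == "neg"], -1)
  expect_identical(res$trait_id[1:2], c("self", "neg"))  # sorted by |r|

  # intercept-only adjustment equals plain Pearson
  x <- named_trait(rnorm(40), ids)
  r_adj <- correlate(x, ds)$r
  r_plain <- apply(unclass(ds), 2, function(v) cor(as.numeric(x), v))
  expect_equal(r_adj, unname(r_plain[order(-abs(r_plain))]), tolerance = 1e-10)

  # planted negative regulator: M inhibits T
  cfg <- sim_config(n_individuals = 200, chromosomes = one_chr,
                    markers_per_chr = 21, seed = 730,
                    traits = list(
                      sim_trait("M", loci = list(list(chr = "1", marker = 11,
                                                      frac = 0.4, sdp = 34))),
                      sim_trait("T", mediator = "M", mediator_frac = 0.45)))
  gp <- simulate_genome(cfg)
  tt <- simulate_traits(gp, cfg)
  tvals <- unclass(tt$traits)
  yT <- named_trait(-tvals[, "T"], rownames(tvals))  # inhibition: flip sign
  rMT <- correlate(yT, tt$traits, covariates = tt$covariates)
  expect_lt(rMT$r[rMT$trait_id == "M"], 0)
})

test_that("profile groups and summarizes by factor level", {
  ids <- sprintf("i%d", 1:6)
  y <- named_trait(c(1, 2, 3, 4, 5, 6), ids)
  f <- setNames(c("a", "a", "a", "b", "b", "b"), ids)
  pr <- profile_by_factor(y, f)
  expect_equal(pr$summary$median, c(2, 5))
  expect_equal(pr$summary$n, c(3L, 3L))

  # single-level factor: one group covering the whole sample
  pr1 <- profile_by_factor(y, setNames(rep("all", 6), ids))
  expect_equal(pr1$summary$n, 6L)

  # missing values excluded from group n
  y2 <- y; y2[2] <- NA
  pr2 <- profile_by_factor(y2, f)
  expect_equal(pr2$summary$n, c(2L, 3L))
})
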