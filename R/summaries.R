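# Result summaries: peak calling with support intervals, transcriptome-map
# local/distal labeling, hotspot bin counts, covariate-adjusted trait
# correlation, and grouped profile summaries.

#' Call LOD peaks from genome scans
#'
#' Per trait and chromosome, reports the maximum-LOD marker when it reaches
#' the threshold. With `peakdrop` set, additional local maxima are reported
#' when separated from every already-accepted peak by a valley at least
#' `peakdrop` below the lower of the two peaks. The support interval is the
#' contiguous region around each peak within a 1.5-LOD drop.
#'
#' @param scans A `lod_scan` or a (optionally named) list of them.
#' @param threshold Minimum LOD to call a peak (> 0).
#' @param peakdrop Optional LOD valley depth separating multiple peaks per
#'   chromosome; NULL reports one peak per chromosome.
#' @param drop Support-interval LOD drop (default 1.5).
#' @return A `peak_table` data frame: trait_id, chromosome, marker_id,
#'   pos_Mbp, lod, ci_lo_Mbp, ci_hi_Mbp.
#' @export
find_peaks <- function(scans, threshold = 7, peakdrop = NULL, drop = 1.5) {
  stopifnot(threshold > 0)
  if (inherits(scans, "lod_scan")) scans <- list(scans)
  rows <- list()
  for (sc in scans) {
    map <- sc$map
    for (chr in unique(map$chromosome)) {
      sel <- which(map$chromosome == chr)
      lod <- sc$lod[sel]
      pos <- map$pos_Mbp[sel]
      pk <- chr_peaks(lod, threshold, peakdrop)
      for (i in pk) {
        ci <- support_interval(lod, pos, i, drop)
        rows[[length(rows) + 1L]] <- data.frame(
          trait_id = sc$trait_id, chromosome = chr,
          marker_id = map$marker_id[sel[i]], pos_Mbp = pos[i], lod = lod[i],
          ci_lo_Mbp = ci[1], ci_hi_Mbp = ci[2], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(trait_id = character(0), chromosome = character(0),
                         marker_id = character(0), pos_Mbp = numeric(0),
                         lod = numeric(0), ci_lo_Mbp = numeric(0),
                         ci_hi_Mbp = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("peak_table", "data.frame"))
}

# indices of accepted peaks within one chromosome's LOD vector
chr_peaks <- function(lod, threshold, peakdrop) {
  if (!length(lod) || max(lod) < threshold) return(integer(0))
  if (is.null(peakdrop)) return(which.max(lod))
  # local maxima (plateau-safe) at or above threshold
  cand <- which(vapply(seq_along(lod), function(i) {
    l <- if (i > 1) lod[i - 1] else -Inf
    r <- if (i < length(lod)) lod[i + 1] else -Inf
    lod[i] >= l && lod[i] >= r && lod[i] >= threshold
  }, logical(1)))
  cand <- cand[order(lod[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in cand) {
    ok <- TRUE
    for (j in accepted) {
      rng <- if (i < j) i:j else j:i
      valley <- min(lod[rng])
      if (valley > min(lod[i], lod[j]) - peakdrop) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  sort(accepted)
}

# contiguous region around peak index within `drop` LOD of the peak
support_interval <- function(lod, pos, i, drop) {
  lo <- i; hi <- i
  while (lo > 1 && lod[lo - 1] > lod[i] - drop) lo <- lo - 1
  while (hi < length(lod) && lod[hi + 1] > lod[i] - drop) hi <- hi + 1
  c(pos[lo], pos[hi])
}

#' Transcriptome map: QTL position vs gene position
#'
#' Joins an -omic peak table with trait annotations and labels each peak
#' `local` when it lies on the gene's chromosome within `window_Mbp` of the
#' gene midpoint, else `distal`. Unannotated traits are skipped and counted.
#'
#' @param peaks A `peak_table`.
#' @param annotations Data frame with `trait_id`, `chromosome`,
#'   `midpoint_Mbp` (as carried by a `trait_matrix`).
#' @param window_Mbp Local window (default 10).
#' @return Data frame of annotated peaks with `gene_chromosome`,
#'   `gene_midpoint_Mbp` and `type` ("local"/"distal"); attribute
#'   `n_skipped` counts peaks of unannotated traits.
#' @export
transcriptome_map <- function(peaks, annotations, window_Mbp = 10) {
  i <- match(peaks$trait_id, annotations$trait_id)
  skip <- is.na(i) | is.na(annotations$chromosome[i]) |
    is.na(annotations$midpoint_Mbp[i])
  out <- peaks[!skip, , drop = FALSE]
  ii <- i[!skip]
  out$gene_chromosome <- as.character(annotations$chromosome[ii])
  out$gene_midpoint_Mbp <- annotations$midpoint_Mbp[ii]
  same <- out$chromosome == out$gene_chromosome
  near <- same & abs(out$pos_Mbp - out$gene_midpoint_Mbp) <= window_Mbp
  out$type <- ifelse(near, "local", "distal")
  rownames(out) <- NULL
  structure(as.data.frame(out), n_skipped = sum(skip))
}

#' Count distal peaks in genomic bins (hotspot screen)
#'
#' Bins distal peaks into deterministic half-open windows `[lo, hi)` from
#' each chromosome start; regions where many distal -omic QTL co-map are
#' candidate hotspots.
#'
#' @param tmap Output of [transcriptome_map()] (or any peak table with a
#'   `type` column).
#' @param window_Mbp Bin width (> 0).
#' @param chr_lengths Optional named vector of chromosome lengths (Mbp) so
#'   empty trailing bins are reported; defaults to the span of the peaks.
#' @return Data frame: chromosome, bin_lo_Mbp, bin_hi_Mbp, count.
#' @export
hotspot_counts <- function(tmap, window_Mbp = 4, chr_lengths = NULL) {
  stopifnot(window_Mbp > 0)
  distal <- tmap[tmap$type == "distal", , drop = FALSE]
  chrs <- if (!is.null(chr_lengths)) names(chr_lengths)
          else unique(distal$chromosome)
  rows <- list()
  for (chr in chrs) {
    len <- if (!is.null(chr_lengths)) chr_lengths[[chr]]
           else if (any(distal$chromosome == chr)) max(distal$pos_Mbp[distal$chromosome == chr])
           else 0
    n_bins <- max(1L, ceiling(len / window_Mbp))
    lo <- (seq_len(n_bins) - 1) * window_Mbp
    cnt <- integer(n_bins)
    p <- distal$pos_Mbp[distal$chromosome == chr]
    if (length(p)) {
      idx <- pmin(floor(p / window_Mbp) + 1L, n_bins)
      tb <- table(idx)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    rows[[chr]] <- data.frame(chromosome = chr, bin_lo_Mbp = lo,
                              bin_hi_Mbp = lo + window_Mbp, count = cnt,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chromosome = character(0), bin_lo_Mbp = numeric(0),
                         bin_hi_Mbp = numeric(0), count = integer(0))
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted correlation of one trait against a dataset
#'
#' Residualizes both the focus trait and every candidate trait on the
#' adjustment design (always including an intercept), then reports the
#' Pearson correlation of the residuals, sorted by |r| descending. With an
#' intercept-only adjustment this equals the plain Pearson correlation.
#'
#' @param y Named focus-trait vector.
#' @param dataset A `trait_matrix`.
#' @param covariates Optional `covariate_matrix` used as the adjustment set;
#'   NULL adjusts for the intercept only.
#' @param min_n Minimum shared complete cases per pair (default 3).
#' @return Data frame: trait_id, r, n.
#' @export
correlate <- function(y, dataset, covariates = NULL, min_n = 3) {
  vals <- unclass(dataset)
  ids <- intersect(names(y), rownames(vals))
  X <- if (is.null(covariates)) matrix(1, length(ids), 1,
                                       dimnames = list(ids, "intercept"))
       else unclass(covariates)[ids, , drop = FALSE]
  yv <- as.numeric(y[ids])
  out <- data.frame(trait_id = colnames(vals), r = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) {
    vj <- vals[ids, j]
    ok <- !is.na(yv) & !is.na(vj) & stats::complete.cases(X)
    n <- sum(ok)
    out$n[j] <- n
    if (n < max(min_n, ncol(X) + 2)) next
    ry <- .lm.fit(X[ok, , drop = FALSE], yv[ok])$residuals
    rv <- .lm.fit(X[ok, , drop = FALSE], vj[ok])$residuals
    if (stats::sd(ry) == 0 || stats::sd(rv) == 0) next
    out$r[j] <- stats::cor(ry, rv)
  }
  out <- out[order(-abs(out$r), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile a trait by a factor covariate
#'
#' Splits trait values by the levels of a factor (e.g. sex) and returns the
#' per-level values plus summary statistics, the tabular backing of a
#' boxplot profile. Missing trait values are excluded from their group.
#'
#' @param y Named trait vector.
#' @param factor_values Named vector (character/factor) of group labels.
#' @return List with `groups` (named list of value vectors) and `summary`
#'   (data frame: level, n, median, q1, q3).
#' @export
profile_by_factor <- function(y, factor_values) {
  ids <- intersect(names(y), names(factor_values))
  f <- factor(factor_values[ids])
  if (nlevels(f) < 1) stop("profile_by_factor: factor has no levels")
  groups <- split(as.numeric(y[ids]), f)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  sm <- do.call(rbind, lapply(names(groups), function(lev) {
    v <- groups[[lev]]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(level = lev, n = length(v), median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(sm) <- NULL
  list(groups = groups, summary = sm)
}
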