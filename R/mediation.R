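# LOD-drop mediation: retest a target QTL while conditioning one-by-one on
# candidate -omic mediators. The kinship term is excluded from BOTH the null
# and the alternative of every conditional fit (the standard efficiency
# shortcut), so conditional LODs are comparable within a scan; each
# mediator's fit uses the complete cases of (target, mediator, covariates)
# with the null recomputed on that subset, and the marginal (unconditioned)
# LOD on the same subset is reported alongside.

#' Mediation scan for a target QTL
#'
#' For each candidate mediator, the conditional LOD is the LOD of the
#' 8-founder dosage block at the locus with the mediator appended to the
#' covariates (no kinship). A strong causal mediator drives the conditional
#' LOD toward 0 while the marginal LOD stays high. A mediator numerically
#' identical to the target (or that makes the null fit degenerate) is
#' reported with conditional LOD 0 and `degenerate = TRUE`.
#'
#' @param y Named target trait vector.
#' @param genoprobs A `geno_probs` object.
#' @param chr,marker_id Locus of the QTL being retested.
#' @param covariates A `covariate_matrix`.
#' @param mediators A `trait_matrix` of candidate mediators (typically with
#'   gene-position annotations).
#' @return A `mediation_result` data frame: mediator_id, chromosome,
#'   midpoint_Mbp, lod_conditional, lod_marginal, n_used, degenerate;
#'   sorted ascending by conditional LOD.
#' @export
mediation_scan <- function(y, genoprobs, chr, marker_id, covariates,
                           mediators) {
  stopifnot(inherits(mediators, "trait_matrix"))
  if (!chr %in% names(genoprobs)) stop("mediation_scan: unknown chromosome ", chr)
  a <- genoprobs[[chr]]
  mk <- dimnames(a)[[3]]
  if (!marker_id %in% mk) stop("mediation_scan: unknown marker ", marker_id)
  P <- a[, , match(marker_id, mk)]
  Xall <- unclass(covariates)
  med_m <- unclass(mediators)
  ann <- attr(mediators, "annotations")
  ids0 <- intersect(rownames(P), intersect(names(y), rownames(Xall)))
  ids0 <- intersect(ids0, rownames(med_m))

  n_med <- ncol(med_m)
  out <- data.frame(mediator_id = colnames(med_m),
                    chromosome = NA_character_, midpoint_Mbp = NA_real_,
                    lod_conditional = NA_real_, lod_marginal = NA_real_,
                    n_used = NA_integer_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(ann)) {
    i <- match(out$mediator_id, ann$trait_id)
    out$chromosome <- as.character(ann$chromosome[i])
    out$midpoint_Mbp <- ann$midpoint_Mbp[i]
  }

  for (j in seq_len(n_med)) {
    mj <- med_m[ids0, j]
    yj <- y[ids0]
    ok <- !is.na(mj) & !is.na(yj) & stats::complete.cases(Xall[ids0, , drop = FALSE])
    idj <- ids0[ok]
    n <- length(idj)
    out$n_used[j] <- n
    X0 <- Xall[idj, , drop = FALSE]
    if (n < ncol(X0) + 10) next
    Pj <- P[idj, , drop = FALSE]
    yv <- as.numeric(yj[ok]); mv <- as.numeric(mj[ok])

    # marginal LOD on the same subset, for comparability
    rss0_marg <- rss_fit(X0, yv)
    rss1_marg <- rss_fit(cbind(X0, Pj), yv)
    out$lod_marginal[j] <- max(0, (n / 2) * log10(rss0_marg / rss1_marg))

    Xm <- cbind(X0, mediator = mv)
    rss0 <- rss_fit(Xm, yv)
    if (rss0 < 1e-12 * max(1, sum(yv^2))) {
      # mediator explains the target exactly (e.g. the target itself)
      out$lod_conditional[j] <- 0
      out$degenerate[j] <- TRUE
      next
    }
    rss1 <- rss_fit(cbind(Xm, Pj), yv)
    out$lod_conditional[j] <- max(0, (n / 2) * log10(rss0 / rss1))
  }
  out <- out[order(out$lod_conditional), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, target = attr(y, "trait_id") %||% "trait",
            locus = paste0(chr, ":", marker_id),
            class = c("mediation_result", "data.frame"))
}
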