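# Strain-distribution-pattern variant association.
#
# A biallelic variant segregating among the 8 founders is described by its
# SDP; its allele dosage for a DO individual is imputed by summing the
# founder-haplotype probabilities of the alt-carrying founders at the
# marker nearest the variant (tie -> lower position). Variants sharing
# (nearest marker, SDP) are statistically identical, so each such group is
# fit once and the LOD broadcast to all members.

#' Impute a biallelic allele dosage from an SDP
#'
#' @param genoprobs A `geno_probs` object.
#' @param chr Chromosome of the SNP.
#' @param pos_Mbp SNP position.
#' @param sdp Strain distribution pattern, integer 1..254.
#' @return Named dosage vector over individuals, each in \[0, 1\]:
#'   \eqn{d_i = \sum_{f: bit_f(sdp)=1} p_{if}} at the nearest marker.
#' @export
sdp_dosage <- function(genoprobs, chr, pos_Mbp, sdp) {
  if (!chr %in% names(genoprobs))
    stop("sdp_dosage: chromosome ", chr, " not in genoprobs")
  bits <- sdp_to_bits(sdp)
  map <- attr(genoprobs, "map")
  idx <- nearest_marker_index(map, chr, pos_Mbp)
  p <- genoprobs[[chr]][, , idx, drop = TRUE]
  d <- rowSums(p[, bits, drop = FALSE])
  pmin(pmax(d, 0), 1)
}

# nearest marker (index within chromosome); ties broken to the lower position
nearest_marker_index <- function(map, chr, pos_Mbp) {
  pos <- map$pos_Mbp[map$chromosome == chr]
  if (!length(pos)) stop("no markers on chromosome ", chr)
  d <- abs(pos - pos_Mbp)
  which(d == min(d))[1]
}

#' SNP association scan over a genomic region
#'
#' Substitutes each variant's imputed allele dosage for the 8-founder dosage
#' block in the additive (or interactive) model and reports the LOD per
#' variant. Association with kinship uses the region chromosome's LOCO
#' matrix and the null h2 from the haplotype scan engine. Variants sharing
#' (nearest marker, SDP) are deduplicated: computed once, broadcast to all
#' members; the number of distinct fits is recorded in attribute `n_fits`.
#'
#' @param genoprobs A `geno_probs` object.
#' @param snps A `founder_snp_table`.
#' @param y Named trait vector.
#' @param covariates A `covariate_matrix`.
#' @param kinship Kinship family/matrix or NULL.
#' @param region String `"chr:lo-hi"` in Mbp, e.g. `"13:64-68"`.
#' @param intcovar Optional interactive covariate column name; adds the
#'   dosage-by-factor product and reports the full-model LOD.
#' @return A `snp_assoc_table` data frame: snp_id, chromosome, pos_Mbp, sdp,
#'   csq, lod; attribute `n_fits` counts distinct (marker, sdp) fits.
#' @export
scan_snps <- function(genoprobs, snps, y, covariates, kinship = NULL,
                      region, intcovar = NULL) {
  reg <- parse_region(region)
  if (!reg$chr %in% names(genoprobs))
    stop("scan_snps: region chromosome ", reg$chr, " not in genoprobs")
  sub <- snps[snps$chromosome == reg$chr &
                snps$pos_Mbp >= reg$lo & snps$pos_Mbp <= reg$hi, , drop = FALSE]
  empty <- structure(data.frame(snp_id = character(0), chromosome = character(0),
                                pos_Mbp = numeric(0), sdp = integer(0),
                                csq = character(0), lod = numeric(0),
                                stringsAsFactors = FALSE),
                     n_fits = 0L, class = c("snp_assoc_table", "data.frame"))
  if (!nrow(sub)) return(empty)
  validate_founder_snp_table(sub)

  K <- kinship_for_chr(kinship, reg$chr)
  fit <- fit_null(y, covariates, K)
  ids <- fit$ids
  map <- attr(genoprobs, "map")
  a <- genoprobs[[reg$chr]][ids, , , drop = FALSE]
  n <- fit$n

  int_col <- NULL
  if (!is.null(intcovar)) {
    X <- unclass(covariates)
    if (!intcovar %in% colnames(X)) stop("unknown interactive covariate ", intcovar)
    int_col <- X[ids, intcovar]
  }

  mk_idx <- vapply(sub$pos_Mbp, function(p) nearest_marker_index(map, reg$chr, p),
                   integer(1))
  key <- paste(mk_idx, sub$sdp)
  groups <- split(seq_len(nrow(sub)), key)
  lod <- numeric(nrow(sub))
  n_fits <- 0L
  for (g in groups) {
    j <- mk_idx[g[1]]
    bits <- sdp_to_bits(sub$sdp[g[1]])
    d <- rowSums(a[, bits, j, drop = FALSE])
    cols <- if (is.null(int_col)) cbind(dose = d)
            else cbind(dose = d, dxf = d * int_col)
    Xj <- cbind(fit$X_rot, rotate_block(fit, cols))
    rss <- rss_fit(Xj, fit$y_rot)
    lod[g] <- max(0, (n / 2) * log10(fit$rss0 / rss))
    n_fits <- n_fits + 1L
  }
  out <- data.frame(snp_id = sub$snp_id, chromosome = sub$chromosome,
                    pos_Mbp = sub$pos_Mbp, sdp = sub$sdp, csq = sub$csq,
                    lod = lod, stringsAsFactors = FALSE)
  structure(out, n_fits = n_fits, class = c("snp_assoc_table", "data.frame"))
}

# "13:64-68" -> list(chr, lo, hi)
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9.]+)-([0-9.]+)$", region))[[1]]
  if (length(m) != 4) stop("invalid region '", region, "'; expected chr:lo-hi")
  lo <- as.numeric(m[3]); hi <- as.numeric(m[4])
  if (hi < lo) stop("invalid region: hi < lo")
  list(chr = m[2], lo = lo, hi = hi)
}
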