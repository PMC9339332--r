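# Genetic relationship matrices from founder-haplotype dosage probabilities.
# K_ij = (1/M) sum over markers m, founders f of p_imf * p_jmf: the average
# probability-weighted founder sharing. With certain homozygous calls the
# diagonal is exactly 1. The LOCO family leaves out each chromosome in turn
# so a scanned locus never contributes to its own polygenic control.

#' Compute kinship matrices from genotype probabilities
#'
#' Estimates the genetic relationship matrix K as the marker-averaged
#' cross-product of founder dosage probabilities,
#' \eqn{K_{ij} = \frac{1}{M}\sum_m \sum_f p_{imf}\,p_{jmf}}. In `"loco"`
#' mode one matrix per chromosome is returned, each computed from all
#' markers *except* that chromosome's (leave one chromosome out), the form
#' used by mixed-model genome scans to avoid absorbing the tested locus into
#' the polygenic term.
#'
#' @param genoprobs A `geno_probs` object.
#' @param mode `"overall"` (one matrix from all markers) or `"loco"`.
#' @return A `kinship_loco` object: named list of n x n symmetric matrices
#'   (one entry named `"overall"`, or one per chromosome).
#' @export
compute_kinship <- function(genoprobs, mode = c("loco", "overall")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genoprobs, "geno_probs"))
  chrs <- names(genoprobs)
  ids <- individual_ids(genoprobs)
  n <- length(ids)
  if (n < 2) stop("compute_kinship: need >= 2 individuals")
  if (mode == "loco" && length(chrs) < 2)
    stop("compute_kinship: loco mode needs >= 2 chromosomes (no markers would remain)")

  # per-chromosome raw cross-product sums and marker counts
  xps <- list(); nmk <- numeric(0)
  for (chr in chrs) {
    a <- genoprobs[[chr]]
    m <- dim(a)[3]
    flat <- matrix(a, nrow = n)  # n x (8*m), founders/markers flattened
    xps[[chr]] <- tcrossprod(flat)
    nmk[chr] <- m
  }
  out <- list()
  if (mode == "overall") {
    K <- Reduce(`+`, xps) / sum(nmk)
    dimnames(K) <- list(ids, ids)
    out[["overall"]] <- K
  } else {
    # summed directly over the retained chromosomes (not total-minus-one):
    # perturbing chromosome c then leaves K_c unchanged bit-for-bit
    for (chr in chrs) {
      keep <- setdiff(chrs, chr)
      K <- Reduce(`+`, xps[keep]) / sum(nmk[keep])
      dimnames(K) <- list(ids, ids)
      out[[chr]] <- K
    }
  }
  structure(out, mode = mode, class = "kinship_loco")
}

#' @rdname compute_kinship
#' @param x Object to validate.
#' @param tol_sym Symmetry tolerance.
#' @param tol_psd Lower bound for the minimum eigenvalue.
#' @export
validate_kinship <- function(x, tol_sym = 1e-10, tol_psd = -1e-8) {
  stopifnot(inherits(x, "kinship_loco") || is.matrix(x))
  mats <- if (is.matrix(x)) list(x) else x
  for (K in mats) {
    if (max(abs(K - t(K))) > tol_sym) stop("kinship: matrix not symmetric")
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < tol_psd) stop("kinship: matrix not positive semidefinite")
    if (any(diag(K) <= 0) || any(diag(K) > 1 + 1e-8))
      stop("kinship: diagonal entries outside (0, 1]")
  }
  invisible(x)
}

#' Eigendecompose a kinship matrix
#'
#' Standard mixed-model machinery: K = V diag(lambda) V'. Eigenvalues below
#' the clipping threshold are set to 0 so downstream variance-component
#' weights are never negative.
#'
#' @param K Symmetric kinship matrix.
#' @param clip Eigenvalues below this are clipped to 0 (numerical PSD repair).
#' @return List with `values` (decreasing) and `vectors`.
#' @export
decompose_kinship <- function(K, clip = 1e-10) {
  stopifnot(is.matrix(K))
  if (max(abs(K - t(K))) > 1e-8) stop("decompose_kinship: K is not symmetric")
  ed <- eigen(K, symmetric = TRUE)
  ed$values[ed$values < clip] <- 0
  list(values = ed$values, vectors = ed$vectors)
}

#' Write kinship matrices as labeled dense CSV
#'
#' @param kinship A `kinship_loco` object or single matrix.
#' @param dir Output directory; files are `kinship_<name>.csv`.
#' @return Written paths, invisibly.
#' @export
write_kinship_csv <- function(kinship, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- if (is.matrix(kinship)) list(overall = kinship) else kinship
  paths <- character(0)
  for (nm in names(mats)) {
    df <- data.frame(individual_id = rownames(mats[[nm]]),
                     as.data.frame(mats[[nm]]), check.names = FALSE,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0("kinship_", nm, ".csv"))
    write_csv_stable(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
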