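# Founder allele effects along one chromosome.
#
# Fixed mode: at each marker the trait (eigen-rotated and variance-weighted
# under the chromosome's null h2) is regressed on the 8 founder-dosage
# columns plus covariates; the intercept is absorbed into the dosage block
# (the 8 columns sum to 1 row-wise), and effects are centered to sum 0 for
# display, with the raw basis retained. BLUP mode treats the 8 founder
# effects as a random effect with a common variance whose ratio to the
# residual is estimated per marker by REML; the reported effects are the
# posterior means, which shrink extreme effects of rarely observed alleles.

new_allele_effects <- function(map, raw, centered, lod, mode, chromosome,
                               trait_id) {
  structure(list(map = as.data.frame(map), effects_raw = raw,
                 effects_centered = centered, lod = lod, mode = mode,
                 chromosome = chromosome, trait_id = trait_id),
            class = "allele_effects")
}

#' @export
print.allele_effects <- function(x, ...) {
  cat("allele_effects (", x$mode, ") for trait ", x$trait_id,
      " on chromosome ", x$chromosome, ": ", nrow(x$map), " markers\n", sep = "")
  invisible(x)
}

#' Founder allele effects as fixed regression coefficients
#'
#' @param genoprobs A `geno_probs` object.
#' @param chr Chromosome to estimate along.
#' @param y Named trait vector.
#' @param covariates A `covariate_matrix`.
#' @param K Kinship matrix for this chromosome (typically the LOCO matrix),
#'   or NULL.
#' @return An `allele_effects` object with raw and centered (sum-zero)
#'   coefficient matrices (markers x 8) and the marker LODs.
#' @export
estimate_effects_fixed <- function(genoprobs, chr, y, covariates, K = NULL) {
  stopifnot(chr %in% names(genoprobs))
  fit <- fit_null(y, covariates, K)
  ids <- fit$ids
  a <- genoprobs[[chr]][ids, , , drop = FALSE]
  m <- dim(a)[3]; n <- fit$n
  founders <- dimnames(a)[[2]]
  Xcov <- fit$X_rot
  # drop the intercept from the covariate block: it is absorbed by the
  # dosage columns, which sum to 1 for every individual
  noint <- Xcov[, colnames(Xcov) != "intercept", drop = FALSE]
  flat <- rotate_block(fit, matrix(a, nrow = n))

  raw <- matrix(NA_real_, m, 8, dimnames = list(dimnames(a)[[3]], founders))
  lod <- numeric(m)
  p_full <- 8 + ncol(noint)
  for (j in seq_len(m)) {
    Pj <- flat[, ((j - 1) * 8 + 1):(j * 8), drop = FALSE]
    colnames(Pj) <- founders
    if (n <= p_full) { lod[j] <- NA_real_; next }
    f <- stats::lm.fit(cbind(Pj, noint), fit$y_rot)
    raw[j, ] <- f$coefficients[founders]
    rss <- sum(f$residuals^2)
    lod[j] <- max(0, (n / 2) * log10(fit$rss0 / rss))
  }
  centered <- raw - rowMeans(raw, na.rm = TRUE)
  map_chr <- attr(genoprobs, "map")
  map_chr <- map_chr[map_chr$chromosome == chr, , drop = FALSE]
  new_allele_effects(map_chr, raw, centered, lod, "fixed", chr,
                     attr(y, "trait_id") %||% "trait")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# REML machinery for a random 8-founder effect with ratio r = tau2/sigma2,
# in the (already kinship-rotated, weighted) working space. Woodbury keeps
# every solve at 8 x 8.
blup_reml_pieces <- function(r, X, Z, y) {
  n <- nrow(X); p <- ncol(X)
  if (r <= 0) {
    f <- .lm.fit(X, y)
    q <- sum(f$residuals^2)
    ll <- -0.5 * ((n - p) * log(q / (n - p)) + (n - p) +
                    as.numeric(determinant(crossprod(X), TRUE)$modulus))
    return(list(ll = ll, b = rep(0, ncol(Z)), q = q))
  }
  A <- crossprod(Z)                       # 8 x 8
  M <- diag(ncol(Z)) / r + A
  Mi <- solve(M)
  Vi <- function(v) v - Z %*% (Mi %*% crossprod(Z, v))
  ViX <- Vi(X); Viy <- as.numeric(Vi(y))
  W <- crossprod(X, ViX)
  Xty <- crossprod(X, Viy)
  beta <- solve(W, Xty)
  q <- sum(y * Viy) - sum(Xty * beta)
  q <- max(q, 1e-300)
  ld_V <- as.numeric(determinant(diag(ncol(Z)) + r * A, TRUE)$modulus)
  ll <- -0.5 * ((n - p) * log(q / (n - p)) + (n - p) + ld_V +
                  as.numeric(determinant(W, TRUE)$modulus))
  resid <- y - X %*% beta
  b <- r * as.numeric(crossprod(Z, Vi(resid)))
  list(ll = ll, b = b, q = q)
}

#' Founder allele effects as best linear unbiased predictors (BLUPs)
#'
#' Re-estimates the 8 founder effects at each marker as a random effect with
#' common variance; the variance ratio is estimated by a grid-refined Brent
#' REML search per marker (tolerance 1e-6) and the returned effects are the
#' posterior means. BLUPs shrink extreme effects driven by rare alleles; in
#' the flat-prior limit they coincide with the centered fixed effects.
#'
#' @inheritParams estimate_effects_fixed
#' @param ratio Optional fixed variance ratio tau2/sigma2 (skips the REML
#'   search); 0 gives complete shrinkage, a very large value the flat-prior
#'   limit.
#' @return An `allele_effects` object, mode "blup".
#' @export
estimate_effects_blup <- function(genoprobs, chr, y, covariates, K = NULL,
                                  ratio = NULL) {
  stopifnot(chr %in% names(genoprobs))
  fit <- fit_null(y, covariates, K)
  ids <- fit$ids
  a <- genoprobs[[chr]][ids, , , drop = FALSE]
  m <- dim(a)[3]; n <- fit$n
  founders <- dimnames(a)[[2]]
  X <- fit$X_rot                           # includes intercept (fixed)
  flat <- rotate_block(fit, matrix(a, nrow = n))
  fixed <- estimate_effects_fixed(genoprobs, chr, y, covariates, K)

  raw <- matrix(NA_real_, m, 8, dimnames = list(dimnames(a)[[3]], founders))
  for (j in seq_len(m)) {
    Z <- flat[, ((j - 1) * 8 + 1):(j * 8), drop = FALSE]
    if (n <= ncol(X) + 1) next
    if (!is.null(ratio)) {
      raw[j, ] <- blup_reml_pieces(ratio, X, Z, fit$y_rot)$b
    } else {
      obj <- function(t) blup_reml_pieces(t / (1 - t), X, Z, fit$y_rot)$ll
      grid <- c(0, 0.05, 0.15, 0.3, 0.5, 0.7, 0.85, 0.95, 0.99)
      vals <- vapply(grid, obj, numeric(1))
      k <- which.max(vals)
      lo <- grid[max(1, k - 1)]; hi <- min(grid[min(length(grid), k + 1)], 0.999999)
      opt <- stats::optimize(obj, interval = c(lo, hi), maximum = TRUE,
                             tol = 1e-6)
      t_best <- if (opt$objective >= vals[k]) opt$maximum else grid[k]
      raw[j, ] <- blup_reml_pieces(t_best / (1 - t_best), X, Z, fit$y_rot)$b
    }
  }
  centered <- raw - rowMeans(raw, na.rm = TRUE)
  map_chr <- attr(genoprobs, "map")
  map_chr <- map_chr[map_chr$chromosome == chr, , drop = FALSE]
  new_allele_effects(map_chr, raw, centered, fixed$lod, "blup", chr,
                     attr(y, "trait_id") %||% "trait")
}
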