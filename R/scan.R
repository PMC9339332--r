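# Mixed-model genome scan engine.
#
# Model: trait_i = QTL_im + covariates_i + kinship_i + error_i, where the
# QTL term at marker m is the 8-column founder-dosage block and the kinship
# term is a random effect with covariance h2 * K (LOCO K per scanned
# chromosome). h2 is estimated once per (trait, chromosome) under the null
# by REML and held fixed across markers, so each marker costs one GLS solve
# in the eigen-rotated space: LOD_m = (n/2) log10(RSS0 / RSS_m). With
# kinship = NULL the scan reduces to Haley-Knott style OLS.

# complete-case index: non-missing trait and fully observed covariates
complete_obs <- function(y, X) {
  ok <- !is.na(y) & stats::complete.cases(X)
  which(ok)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(q)
}

rss_fit <- function(X, y) {
  f <- .lm.fit(X, y)  # pivoted QR, rank-revealing
  sum(f$residuals^2)
}

# restricted log-likelihood (natural log, additive constants dropped) of the
# variance ratio h2 given eigenvalues lambda and rotated y / X
reml_loglik <- function(h2, lambda, yr, Xr) {
  n <- length(yr); p <- ncol(Xr)
  w <- h2 * lambda + (1 - h2)
  sw <- sqrt(w)
  Xw <- Xr / sw; yw <- yr / sw
  rss <- rss_fit(Xw, yw)
  xtx <- crossprod(Xw)
  ld_xtx <- determinant(xtx, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(rss / (n - p)) + (n - p) + sum(log(w)) + as.numeric(ld_xtx))
}

#' Fit the null mixed model for one trait
#'
#' Estimates the variance ratio h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) of
#' the kinship random term by restricted maximum likelihood (Brent search on
#' \[0, 1 - 1e-6\]), and returns the eigen-rotated, variance-weighted working
#' data in which every downstream marker fit is an ordinary least-squares
#' solve. `K = NULL` forces h2 = 0 (pure linear model).
#'
#' @param y Named numeric trait vector (names = individual ids).
#' @param covariates A `covariate_matrix` (or plain design matrix with an
#'   intercept column) over the same individuals.
#' @param K Kinship matrix for these individuals, or NULL.
#' @param tol Convergence tolerance for the h2 search.
#' @return A `null_fit`: h2, log10 restricted likelihood, residual variance,
#'   rotated/weighted responses and design, eigen system and complete-case ids.
#' @export
fit_null <- function(y, covariates, K = NULL, tol = 1e-8) {
  stopifnot(!is.null(names(y)))
  X <- unclass(covariates)[names(y), , drop = FALSE]
  obs <- complete_obs(y, X)
  if (length(obs) < ncol(X) + 2)
    stop("fit_null: need at least p + 2 complete cases (have ", length(obs), ")")
  ids <- names(y)[obs]
  yo <- as.numeric(y[obs]); Xo <- X[obs, , drop = FALSE]
  check_full_rank(Xo)
  n <- length(yo); p <- ncol(Xo)

  if (is.null(K)) {
    rss <- rss_fit(Xo, yo)
    ll <- -0.5 * ((n - p) * log(rss / (n - p)) + (n - p) +
                    as.numeric(determinant(crossprod(Xo), TRUE)$modulus))
    fit <- list(h2 = 0, log10_lik = ll / log(10), sigma2 = rss / (n - p),
                ids = ids, U = NULL, lambda = rep(1, n), weights = rep(1, n),
                y_rot = yo, X_rot = Xo, rss0 = rss, n = n, p = p)
    class(fit) <- "null_fit"
    return(fit)
  }

  Ko <- K[ids, ids]
  ed <- decompose_kinship(Ko)
  U <- ed$vectors; lambda <- ed$values
  yr <- as.numeric(crossprod(U, yo))
  Xr <- crossprod(U, Xo)

  f <- function(h2) reml_loglik(h2, lambda, yr, Xr)
  opt <- stats::optimize(f, interval = c(0, 1 - 1e-6), maximum = TRUE, tol = tol)
  cand_h2 <- c(opt$maximum, 0)
  cand_ll <- c(opt$objective, f(0))
  best <- which.max(cand_ll)
  h2 <- cand_h2[best]; ll <- cand_ll[best]

  w <- h2 * lambda + (1 - h2)
  sw <- sqrt(w)
  yt <- yr / sw; Xt <- Xr / sw
  rss <- rss_fit(Xt, yt)
  if (!is.finite(ll)) stop("fit_null: non-finite restricted likelihood")
  fit <- list(h2 = h2, log10_lik = ll / log(10), sigma2 = rss / (n - p),
              ids = ids, U = U, lambda = lambda, weights = w,
              y_rot = yt, X_rot = Xt, rss0 = rss, n = n, p = p)
  class(fit) <- "null_fit"
  fit
}

# rotate and weight an n x q block into the null fit's working space
rotate_block <- function(fit, M) {
  if (is.null(fit$U)) return(M)
  crossprod(fit$U, M) / sqrt(fit$weights)
}

# resolve the kinship matrix to use when scanning chromosome chr
kinship_for_chr <- function(kinship, chr) {
  if (is.null(kinship)) return(NULL)
  if (is.matrix(kinship)) return(kinship)
  if (!is.null(kinship[[chr]])) return(kinship[[chr]])
  if (!is.null(kinship[["overall"]])) return(kinship[["overall"]])
  stop("no kinship matrix available for chromosome ", chr)
}

new_lod_scan <- function(map, lod, kind, trait_id, h2 = NULL, n = NULL) {
  structure(list(map = as.data.frame(map), lod = as.numeric(lod), kind = kind,
                 trait_id = trait_id, h2 = h2, n = n),
            class = "lod_scan")
}

#' @export
print.lod_scan <- function(x, ...) {
  cat("lod_scan (", x$kind, ") for trait ", x$trait_id, ": ",
      length(x$lod), " markers, max LOD ", round(max(x$lod), 3),
      " at ", x$map$marker_id[which.max(x$lod)], "\n", sep = "")
  invisible(x)
}

# shared scan driver: per chromosome, fit the null once, then compute LODs
# for each marker design produced by `design_fun(fit, chr, obs_idx)` which
# must return a list of extra-column matrices (one per marker, original space)
scan_driver <- function(genoprobs, y, covariates, kinship, trait_id, kind,
                        extra_cols_fun) {
  map <- attr(genoprobs, "map")
  X_all <- unclass(covariates)
  lods <- numeric(0); h2s <- c(); keep_rows <- NULL; ns <- c()
  for (chr in names(genoprobs)) {
    K <- kinship_for_chr(kinship, chr)
    fit <- fit_null(y, covariates, K)
    ids <- fit$ids
    a <- genoprobs[[chr]][ids, , , drop = FALSE]
    n <- fit$n
    m <- dim(a)[3]
    extra <- extra_cols_fun(a, ids)  # n x (q*m) matrix in original space
    q <- ncol(extra) / m
    ext_rot <- rotate_block(fit, extra)
    lod_chr <- numeric(m)
    for (j in seq_len(m)) {
      cols <- ((j - 1) * q + 1):(j * q)
      Xj <- cbind(fit$X_rot, ext_rot[, cols, drop = FALSE])
      rss <- rss_fit(Xj, fit$y_rot)
      lod_chr[j] <- (n / 2) * log10(fit$rss0 / rss)
    }
    lod_chr[lod_chr < 0 & lod_chr > -1e-8] <- 0
    lods <- c(lods, lod_chr)
    h2s[chr] <- fit$h2
    ns[chr] <- n
  }
  new_lod_scan(map, lods, kind, trait_id, h2 = h2s, n = ns)
}

#' Additive genome scan
#'
#' For each marker, tests the 8-founder dosage block against the null model
#' of covariates plus kinship; the LOD is the log10 likelihood ratio,
#' computed as (n/2) log10(RSS0 / RSS_m) in the eigen-rotated space at the
#' chromosome's null h2. Markers with no dosage variance yield LOD 0.
#'
#' @param genoprobs A `geno_probs` object.
#' @param y Named trait vector.
#' @param covariates A `covariate_matrix`.
#' @param kinship A `kinship_loco` family (LOCO or overall), a single matrix,
#'   or NULL for ordinary least-squares (Haley-Knott style) scanning.
#' @param trait_id Label stored in the result.
#' @return A `lod_scan` of kind "additive".
#' @export
scan_additive <- function(genoprobs, y, covariates, kinship = NULL,
                          trait_id = "trait") {
  scan_driver(genoprobs, y, covariates, kinship, trait_id, "additive",
              function(a, ids) matrix(a, nrow = dim(a)[1]))
}

#' Locus-by-factor interactive genome scan
#'
#' Fits the full interactive model (founder dosages, factor, dosage-by-factor
#' products, covariates, kinship) and reports both the full-model LOD against
#' the null and the interaction-delta LOD (full minus additive), the
#' improvement attributable to the locus-by-factor interaction alone.
#'
#' @inheritParams scan_additive
#' @param factor_col Name(s) of covariate design column(s) flagged
#'   interactive; must be present in `covariates`.
#' @return List with `full` (kind "full-interactive") and `delta`
#'   (kind "interaction-delta") `lod_scan` objects.
#' @export
scan_interactive <- function(genoprobs, y, covariates, factor_col,
                             kinship = NULL, trait_id = "trait") {
  X <- unclass(covariates)
  if (!all(factor_col %in% colnames(X)))
    stop("interactive factor not found in covariates: ",
         paste(setdiff(factor_col, colnames(X)), collapse = ", "))
  info <- attr(covariates, "info")
  if (!is.null(info) && !all(info$interactive[match(factor_col, info$name)]))
    stop("covariate column(s) not flagged interactive: ",
         paste(factor_col, collapse = ", "))
  # factor must vary on the complete cases
  obs <- complete_obs(y[rownames(X)], X)
  for (fc in factor_col)
    if (stats::var(X[obs, fc]) == 0)
      stop("interactive factor '", fc, "' is constant on the analyzed individuals")

  additive <- scan_additive(genoprobs, y, covariates, kinship, trait_id)
  full <- scan_driver(genoprobs, y, covariates, kinship, trait_id,
                      "full-interactive",
                      function(a, ids) {
                        n <- dim(a)[1]; m <- dim(a)[3]
                        fmat <- X[ids, factor_col, drop = FALSE]
                        blocks <- vector("list", m)
                        for (j in seq_len(m)) {
                          pj <- a[, , j]
                          ints <- do.call(cbind, lapply(seq_len(ncol(fmat)),
                                                        function(k) pj * fmat[, k]))
                          blocks[[j]] <- cbind(pj, ints)
                        }
                        do.call(cbind, blocks)
                      })
  delta <- full$lod - additive$lod
  delta[delta < 0 & delta > -1e-6] <- 0
  list(full = full,
       delta = new_lod_scan(full$map, delta, "interaction-delta", trait_id,
                            h2 = full$h2, n = full$n),
       additive = additive)
}

#' Extract one trait as a named vector
#'
#' @param study A `study` object.
#' @param dataset Name of the trait dataset.
#' @param trait_id Trait (column) id.
#' @return Named numeric vector over the study individuals.
#' @export
get_trait <- function(study, dataset, trait_id) {
  if (!dataset %in% names(study$traits))
    stop("unknown dataset '", dataset, "'")
  tm <- study$traits[[dataset]]
  if (!trait_id %in% colnames(tm))
    stop("trait '", trait_id, "' not found in dataset '", dataset, "'")
  stats::setNames(unclass(tm)[, trait_id], rownames(tm))
}
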