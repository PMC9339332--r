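# Shared fixtures and independent oracles.

# Independent least-squares oracle: residual sum of squares through the SVD
# projector (explicit normal-equations machinery, no shared code with the
# scan engine's pivoted-QR path).
oracle_rss <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  U <- s$u[, keep, drop = FALSE]
  r <- y - U %*% crossprod(U, y)
  sum(r^2)
}

# brute-force LOD of adding `extra` columns to covariates X0
oracle_lod <- function(X0, extra, y) {
  n <- length(y)
  (n / 2) * log10(oracle_rss(X0, y) / oracle_rss(cbind(X0, extra), y))
}

# hand-buildable genotype probabilities: `slices` is a list (per marker) of
# n x 8 matrices; single chromosome "1" with unit-spaced markers
probs_from_slices <- function(slices, chr = "1", ids = NULL) {
  n <- nrow(slices[[1]])
  m <- length(slices)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  mk <- sprintf("%s_m%02d", chr, seq_len(m))
  a <- array(0, dim = c(n, 8, m), dimnames = list(ids, LETTERS[1:8], mk))
  for (j in seq_len(m)) a[, , j] <- slices[[j]]
  map <- marker_map(mk, rep(chr, m), seq_len(m), seq_len(m))
  gp <- list(); gp[[chr]] <- a
  geno_probs(gp, map)
}

# certain homozygous call: row with all mass on one founder
certain_row <- function(f) { v <- rep(0, 8); v[f] <- 1; v }

# a small simulated study used across tests
quick_sim <- function(seed, n = 150, traits = list(), markers = 51,
                      chromosomes = NULL, blur = TRUE, generations = 20) {
  args <- list(n_individuals = n, markers_per_chr = markers, blur = blur,
               generations = generations, traits = traits, seed = seed)
  if (!is.null(chromosomes)) args$chromosomes <- chromosomes
  do.call(sim_config, args)
}

one_chr <- data.frame(name = "1", length_cM = 90, length_Mbp = 120,
                      stringsAsFactors = FALSE)

# intercept-only covariates for a set of ids
intercept_cov <- function(ids) {
  covariate_matrix(matrix(1, length(ids), 1, dimnames = list(ids, "intercept")))
}

named_trait <- function(values, ids) stats::setNames(values, ids)
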