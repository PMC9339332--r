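#' @keywords internal
#' @importFrom stats .lm.fit lm.fit
"_PACKAGE"

# Founder strain conventions for 8-founder mouse MPPs (CC / DO).
# Letter codes A-H map onto the canonical founder order; SDP bit f is set
# when founder f (0-based, A = bit 0) carries the alternate allele.

#' Founder strain letter codes and names
#'
#' The eight founder strains of the Collaborative Cross / Diversity Outbred
#' populations in their conventional order. Letter codes A-H index the
#' founder axis of genotype-probability arrays and the bits of a strain
#' distribution pattern (A = bit 0 ... H = bit 7).
#'
#' @return Named character vector: names are letters A-H, values strain names.
#' @export
#' @examples
#' founder_strains()
founder_strains <- function() {
  c(A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
    E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ")
}

#' Construct a marker map
#'
#' A marker map indexes the loci at which founder haplotype probabilities are
#' available: one row per marker with chromosome label and genetic (cM) and
#' physical (Mbp) positions. Markers must be sorted by chromosome and
#' physical position; chromosome labels are strings so "X" is supported.
#'
#' @param marker_id Character vector of unique marker names.
#' @param chromosome Character vector of chromosome labels ("1".."19", "X").
#' @param pos_cM Numeric genetic positions in centimorgans.
#' @param pos_Mbp Numeric physical positions in megabase pairs (1-based).
#' @return A `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chromosome, pos_cM, pos_Mbp) {
  mm <- data.frame(marker_id = as.character(marker_id),
                   chromosome = as.character(chromosome),
                   pos_cM = as.numeric(pos_cM),
                   pos_Mbp = as.numeric(pos_Mbp),
                   stringsAsFactors = FALSE)
  class(mm) <- c("marker_map", "data.frame")
  validate_marker_map(mm)
  mm
}

#' @rdname marker_map
#' @param x Object to validate.
#' @export
validate_marker_map <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("marker_id", "chromosome", "pos_cM", "pos_Mbp") %in% names(x)))
  if (anyDuplicated(x$marker_id))
    stop("marker_map: duplicated marker_ids: ",
         paste(unique(x$marker_id[duplicated(x$marker_id)]), collapse = ", "))
  for (chr in unique(x$chromosome)) {
    sub <- x[x$chromosome == chr, ]
    if (is.unsorted(sub$pos_Mbp, strictly = TRUE))
      stop("marker_map: markers not strictly sorted by pos_Mbp on chromosome ", chr)
    if (is.unsorted(sub$pos_cM))
      stop("marker_map: pos_cM not non-decreasing on chromosome ", chr)
  }
  # chromosome blocks must be contiguous
  r <- rle(x$chromosome)
  if (anyDuplicated(r$values))
    stop("marker_map: chromosome blocks are not contiguous")
  invisible(x)
}

#' Construct founder genotype probabilities
#'
#' Per-chromosome 3-D arrays of founder-haplotype dosage probabilities,
#' dimensioned individual x founder(8) x marker. Each (individual, marker)
#' slice is a probability vector over the 8 founders (sums to 1); these are
#' the regressors for haplotype-based QTL mapping.
#'
#' @param probs Named list (by chromosome) of arrays `[n, 8, n_markers]` with
#'   dimnames individual ids, founder letters, marker ids.
#' @param map A `marker_map` covering exactly the markers of `probs`, in order.
#' @return A `geno_probs` object (list of arrays with attributes).
#' @export
geno_probs <- function(probs, map) {
  stopifnot(is.list(probs), length(probs) >= 1)
  gp <- probs
  attr(gp, "map") <- map
  class(gp) <- "geno_probs"
  validate_geno_probs(gp)
  gp
}

#' @rdname geno_probs
#' @param x Object to validate.
#' @param tol Tolerance for probability-slice normalization.
#' @export
validate_geno_probs <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "geno_probs"))
  map <- attr(x, "map")
  validate_marker_map(map)
  ids <- NULL
  for (chr in names(x)) {
    a <- x[[chr]]
    if (length(dim(a)) != 3L || dim(a)[2] != 8L)
      stop("geno_probs: chromosome ", chr, " array must be individuals x 8 founders x markers")
    if (any(a < -tol) || any(a > 1 + tol))
      stop("geno_probs: entries outside [0,1] on chromosome ", chr)
    sums <- apply(a, c(1, 3), sum)
    if (any(abs(sums - 1) > tol))
      stop("geno_probs: probability slices do not sum to 1 (max dev ",
           signif(max(abs(sums - 1)), 3), ") on chromosome ", chr)
    mk <- map$marker_id[map$chromosome == chr]
    if (dim(a)[3] != length(mk) || !identical(dimnames(a)[[3]], mk))
      stop("geno_probs: marker axis of chromosome ", chr, " does not match map order")
    if (is.null(ids)) ids <- dimnames(a)[[1]]
    else if (!identical(ids, dimnames(a)[[1]]))
      stop("geno_probs: individual ids differ between chromosomes")
  }
  invisible(x)
}

#' Individual ids of a study component
#' @param x A `geno_probs`, `trait_matrix` or `covariate_matrix`.
#' @return Character vector of individual ids in storage order.
#' @export
individual_ids <- function(x) {
  if (inherits(x, "geno_probs")) dimnames(x[[1]])[[1]]
  else rownames(x)
}

#' Construct a trait matrix
#'
#' Quantitative measurements (physiological or -omic) for the mapped
#' individuals: a numeric matrix individuals x traits, with optional per-trait
#' genomic annotation (gene symbol, chromosome, midpoint) used for
#' transcriptome maps and mediation, and a transform tag recording whether
#' values are raw counts, normalized, or rank-based inverse normal (rz).
#'
#' @param values Numeric matrix, rownames individual ids, colnames trait ids.
#'   Missing values allowed.
#' @param annotations Optional data frame with columns `trait_id`, `symbol`,
#'   `chromosome`, `midpoint_Mbp`.
#' @param transform One of "raw", "norm", "rz".
#' @return A `trait_matrix`.
#' @export
trait_matrix <- function(values, annotations = NULL, transform = c("norm", "raw", "rz")) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("trait_matrix: trait ids (colnames) are required")
  storage.mode(values) <- "double"
  if (!is.null(annotations)) {
    stopifnot(all(c("trait_id", "chromosome", "midpoint_Mbp") %in% names(annotations)))
    annotations <- annotations[match(colnames(values), annotations$trait_id), , drop = FALSE]
  }
  structure(values, annotations = annotations, transform = transform,
            class = c("trait_matrix", "matrix", "array"))
}

#' @rdname trait_matrix
#' @param x Object to validate.
#' @export
validate_trait_matrix <- function(x) {
  stopifnot(inherits(x, "trait_matrix"))
  n_ok <- colSums(!is.na(unclass(x)))
  if (any(n_ok < 3))
    warning("trait_matrix: traits with < 3 non-missing values are not scannable: ",
            paste(colnames(x)[n_ok < 3], collapse = ", "))
  invisible(x)
}

#' Construct a covariate design matrix
#'
#' The fixed-effect covariate design used by every model fit. The design
#' carries an explicit intercept column; factor covariates are stored
#' treatment-coded (reference level omitted). Columns flagged interactive are
#' eligible as the factor of a locus-by-factor interaction scan.
#'
#' @param design Numeric matrix individuals x p, rownames individual ids,
#'   colnames covariate names; must include an `intercept` column of ones.
#' @param info Optional data frame with columns `name`, `kind`
#'   ("numeric"/"factor"), `interactive` (logical). Defaults to numeric,
#'   non-interactive for every non-intercept column.
#' @return A `covariate_matrix`.
#' @export
covariate_matrix <- function(design, info = NULL) {
  stopifnot(is.matrix(design), !is.null(rownames(design)), !is.null(colnames(design)))
  storage.mode(design) <- "double"
  if (!"intercept" %in% colnames(design))
    stop("covariate_matrix: an explicit 'intercept' column is required")
  if (is.null(info)) {
    info <- data.frame(name = colnames(design),
                       kind = "numeric",
                       interactive = FALSE,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "kind", "interactive") %in% names(info)),
            setequal(info$name, colnames(design)))
  info <- info[match(colnames(design), info$name), , drop = FALSE]
  dup <- duplicated(t(design))
  if (any(dup))
    stop("covariate_matrix: duplicated design columns: ",
         paste(colnames(design)[dup], collapse = ", "))
  structure(design, info = info, class = c("covariate_matrix", "matrix", "array"))
}

#' Build a covariate matrix from a data frame
#'
#' Convenience constructor: numeric columns pass through, character/factor
#' columns are treatment-coded against their first level.
#'
#' @param df Data frame with rownames = individual ids.
#' @param interactive Character vector of source column names whose derived
#'   design columns are flagged interactive.
#' @return A `covariate_matrix`.
#' @export
covariates_from_df <- function(df, interactive = character(0)) {
  n <- nrow(df)
  cols <- list(intercept = rep(1, n))
  kinds <- c(intercept = "numeric")
  inter <- c(intercept = FALSE)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
      kinds[nm] <- "numeric"
      inter[nm] <- nm %in% interactive
    } else {
      f <- factor(v)
      for (lev in levels(f)[-1]) {
        cn <- paste0(nm, lev)
        cols[[cn]] <- as.numeric(f == lev)
        kinds[cn] <- "factor"
        inter[cn] <- nm %in% interactive
      }
    }
  }
  design <- do.call(cbind, cols)
  rownames(design) <- rownames(df)
  covariate_matrix(design,
                   info = data.frame(name = colnames(design),
                                     kind = unname(kinds),
                                     interactive = unname(inter),
                                     stringsAsFactors = FALSE))
}

#' Construct a founder SNP table
#'
#' Biallelic variants segregating among the 8 founder strains, each carrying
#' a strain distribution pattern (SDP): an 8-bit integer whose bit f is set
#' when founder f carries the alternate allele (A/J = bit 0 ... WSB/EiJ =
#' bit 7, little-endian, stored as a decimal 1..254). SDPs 0 and 255 are
#' monomorphic, hence non-segregating, and rejected.
#'
#' @param snp_id,chromosome,pos_Mbp,ref,alt,sdp,csq Column vectors; `csq`
#'   (consequence) optional.
#' @return A `founder_snp_table` data frame.
#' @export
founder_snp_table <- function(snp_id, chromosome, pos_Mbp, ref, alt, sdp,
                              csq = NA_character_) {
  if (length(csq) <= 1) csq <- rep(if (length(csq)) csq else NA_character_,
                                   length(snp_id))
  tb <- data.frame(snp_id = as.character(snp_id),
                   chromosome = as.character(chromosome),
                   pos_Mbp = as.numeric(pos_Mbp),
                   ref = as.character(ref), alt = as.character(alt),
                   sdp = as.integer(sdp),
                   csq = as.character(csq),
                   stringsAsFactors = FALSE)
  class(tb) <- c("founder_snp_table", "data.frame")
  validate_founder_snp_table(tb)
  tb
}

#' @rdname founder_snp_table
#' @param x Object to validate.
#' @export
validate_founder_snp_table <- function(x) {
  stopifnot(is.data.frame(x))
  bad <- !is.na(x$sdp) & (x$sdp < 1L | x$sdp > 254L)
  if (any(bad))
    stop("founder_snp_table: non-segregating sdp (0 or 255, or out of range) for: ",
         paste(x$snp_id[bad], collapse = ", "))
  invisible(x)
}

#' Expand an SDP integer into founder carrier flags
#'
#' @param sdp Integer 1..254.
#' @return Logical vector of length 8, TRUE where the founder carries the
#'   alternate allele (A = bit 0).
#' @export
#' @examples
#' sdp_to_bits(34)  # bits 1 and 5: C57BL/6J and CAST/EiJ
sdp_to_bits <- function(sdp) {
  stopifnot(length(sdp) == 1, !is.na(sdp))
  if (sdp < 1 || sdp > 254) stop("sdp must be in 1..254 (0 and 255 are non-segregating)")
  as.logical(bitwAnd(as.integer(sdp), bitwShiftL(1L, 0:7)))
}

#' @rdname sdp_to_bits
#' @param bits Logical vector of length 8.
#' @export
bits_to_sdp <- function(bits) {
  stopifnot(length(bits) == 8)
  sum(bitwShiftL(1L, 0:7)[as.logical(bits)])
}

#' A complete aligned study
#'
#' Bundles genotype probabilities, marker map, one or more trait datasets,
#' covariates and an optional founder SNP table, with all components aligned
#' to a common individual order (the genoprob order).
#'
#' @param genoprobs `geno_probs`.
#' @param traits Named list of `trait_matrix` datasets.
#' @param covariates `covariate_matrix`.
#' @param founder_snps Optional `founder_snp_table`.
#' @return A `study` object.
#' @export
study <- function(genoprobs, traits, covariates, founder_snps = NULL) {
  obj <- structure(list(genoprobs = genoprobs,
                        map = attr(genoprobs, "map"),
                        traits = traits,
                        covariates = covariates,
                        founder_snps = founder_snps),
                   class = "study")
  align_study(obj)
}

# Intersect individual ids across components, stable-sorted by genoprob
# order; warn on partial overlap >= 50%, fail below.
align_study <- function(obj) {
  gp_ids <- individual_ids(obj$genoprobs)
  comps <- c(list(covariates = rownames(obj$covariates)),
             lapply(obj$traits, rownames))
  common <- gp_ids
  for (ids in comps) common <- intersect(common, ids)
  common <- gp_ids[gp_ids %in% common]  # stable genoprob order
  frac <- length(common) / length(gp_ids)
  if (frac < 0.5)
    stop("study: individual overlap across components is ",
         round(100 * frac), "% (< 50%); misaligned ids, e.g. missing: ",
         paste(utils::head(setdiff(gp_ids, common), 5), collapse = ", "))
  if (length(common) < length(gp_ids))
    warning("study: using intersection of ", length(common), " of ",
            length(gp_ids), " genotyped individuals")
  obj$genoprobs[] <- lapply(unclass(obj$genoprobs)[names(obj$genoprobs)],
                            function(a) a[common, , , drop = FALSE])
  obj$covariates <- covariate_matrix(
    unclass(obj$covariates)[common, , drop = FALSE], attr(obj$covariates, "info"))
  obj$traits <- lapply(obj$traits, function(tm)
    trait_matrix(unclass(tm)[common, , drop = FALSE],
                 annotations = attr(tm, "annotations"),
                 transform = attr(tm, "transform")))
  obj
}

#' @export
print.study <- function(x, ...) {
  cat("mppscan study:", length(individual_ids(x$genoprobs)), "individuals,",
      nrow(x$map), "markers on", length(x$genoprobs), "chromosomes\n")
  for (nm in names(x$traits))
    cat("  dataset '", nm, "': ", ncol(x$traits[[nm]]), " traits (",
        attr(x$traits[[nm]], "transform"), ")\n", sep = "")
  if (!is.null(x$founder_snps))
    cat("  founder SNPs:", nrow(x$founder_snps), "\n")
  invisible(x)
}
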