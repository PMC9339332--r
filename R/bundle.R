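# Study bundle: a directory with a control JSON naming the component files.
# All metadata is diffable UTF-8 text; genotype probabilities are one wide
# CSV per chromosome (rows = individual x marker, 8 founder columns), the
# only large object. Numbers are written with 17 significant digits so the
# write/read round trip is identity up to float representation and the
# output is byte-stable for fixed inputs.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  for (j in which(!num)) out[[j]] <- ifelse(is.na(df[[j]]), "", as.character(df[[j]]))
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

read_csv_plain <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "."), check.names = FALSE,
                    colClasses = NA, comment.char = "")
}

#' Write a study bundle to a directory
#'
#' Serializes all study components to a language-neutral directory layout:
#' `bundle.json` (control file), `map.csv`, `covariates.csv` +
#' `covariate_info.csv`, one `genoprobs_<chr>.csv` per chromosome,
#' one `traits_<name>.csv` (plus optional `annot_<name>.csv`) per trait
#' dataset, and `founder_snps.tsv`. Output is byte-stable: writing the same
#' study twice yields identical content hashes.
#'
#' @param study A `study` object (see [study()]).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(study, path) {
  stopifnot(inherits(study, "study"))
  for (nm in names(study$traits))
    if (ncol(study$traits[[nm]]) == 0L)
      stop("write_bundle: trait dataset '", nm, "' is empty")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("write_bundle: cannot create directory ", path)

  map <- study$map
  write_csv_stable(as.data.frame(map), file.path(path, "map.csv"))

  control <- list(format = "mppscan-bundle", version = 1L,
                  map = "map.csv",
                  covariates = "covariates.csv",
                  covariate_info = "covariate_info.csv",
                  geno_probs = list(), traits = list())

  gp <- study$genoprobs
  ids <- individual_ids(gp)
  for (chr in names(gp)) {
    a <- gp[[chr]]
    mk <- dimnames(a)[[3]]
    # rows ordered individual-major to keep files diffable
    long <- data.frame(
      individual_id = rep(ids, times = length(mk)),
      marker_id = rep(mk, each = length(ids)),
      stringsAsFactors = FALSE)
    pm <- matrix(aperm(a, c(1, 3, 2)), nrow = length(ids) * length(mk), ncol = 8)
    colnames(pm) <- dimnames(a)[[2]]
    fn <- paste0("genoprobs_", chr, ".csv")
    write_csv_stable(cbind(long, as.data.frame(pm)), file.path(path, fn))
    control$geno_probs[[chr]] <- fn
  }

  cov <- study$covariates
  cov_df <- data.frame(individual_id = rownames(cov), stringsAsFactors = FALSE)
  cov_df <- cbind(cov_df, as.data.frame(unclass(cov)))
  write_csv_stable(cov_df, file.path(path, "covariates.csv"))
  write_csv_stable(attr(cov, "info"), file.path(path, "covariate_info.csv"))

  for (nm in names(study$traits)) {
    tm <- study$traits[[nm]]
    fn <- paste0("traits_", nm, ".csv")
    df <- data.frame(individual_id = rownames(tm), stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(unclass(tm)))
    write_csv_stable(df, file.path(path, fn))
    entry <- list(id = nm, file = fn, transform = attr(tm, "transform"))
    ann <- attr(tm, "annotations")
    if (!is.null(ann)) {
      afn <- paste0("annot_", nm, ".csv")
      write_csv_stable(ann, file.path(path, afn))
      entry$annotations <- afn
    }
    control$traits[[length(control$traits) + 1L]] <- entry
  }

  if (!is.null(study$founder_snps)) {
    snp <- as.data.frame(study$founder_snps)
    names(snp)[names(snp) == "chromosome"] <- "chr"
    con <- file.path(path, "founder_snps.tsv")
    df <- snp[, c("snp_id", "chr", "pos_Mbp", "ref", "alt", "sdp", "csq")]
    out <- df
    out$pos_Mbp <- fmt_num(df$pos_Mbp)
    out$csq <- ifelse(is.na(df$csq), "", df$csq)
    fh <- file(con, open = "wb")
    writeLines(paste(names(df), collapse = "\t"), fh)
    if (nrow(out)) writeLines(do.call(paste, c(unname(out), sep = "\t")), fh)
    close(fh)
    control$founder_snps <- "founder_snps.tsv"
  }

  json <- jsonlite::toJSON(control, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, file.path(path, "bundle.json"), useBytes = TRUE)
  invisible(path)
}

#' Read a study bundle from a directory
#'
#' Loads and cross-validates all components written by [write_bundle()].
#' Individuals present in only some components are dropped to the
#' intersection (stable genoprob order) with a warning when partial; overlap
#' below 50% is an error. Probability normalization, map sorting and SDP
#' validity are all enforced on load.
#'
#' @param path Bundle directory containing `bundle.json`.
#' @return A `study` object.
#' @export
read_bundle <- function(path) {
  ctl_path <- file.path(path, "bundle.json")
  if (!file.exists(ctl_path)) stop("read_bundle: missing control file ", ctl_path)
  ctl <- jsonlite::fromJSON(ctl_path, simplifyVector = FALSE)
  need <- function(fn) {
    fp <- file.path(path, fn)
    if (!file.exists(fp)) stop("read_bundle: missing component file ", fn)
    fp
  }

  map_df <- read_csv_plain(need(ctl$map))
  map <- marker_map(map_df$marker_id, map_df$chromosome, map_df$pos_cM, map_df$pos_Mbp)

  probs <- list()
  for (chr in names(ctl$geno_probs)) {
    df <- read_csv_plain(need(ctl$geno_probs[[chr]]))
    ids <- unique(df$individual_id)
    mk <- map$marker_id[map$chromosome == chr]
    founders <- names(df)[-(1:2)]
    a <- array(NA_real_, dim = c(length(ids), 8, length(mk)),
               dimnames = list(ids, founders, mk))
    ridx <- match(df$individual_id, ids)
    midx <- match(df$marker_id, mk)
    for (f in seq_len(8))
      a[cbind(rep(ridx, 1), f, midx)] <- df[[founders[f]]]
    probs[[chr]] <- a
  }
  gp <- geno_probs(probs, map)

  cov_df <- read_csv_plain(need(ctl$covariates))
  cov_m <- as.matrix(cov_df[, -1, drop = FALSE])
  rownames(cov_m) <- cov_df$individual_id
  info <- read_csv_plain(need(ctl$covariate_info))
  info$interactive <- as.logical(info$interactive)
  covariates <- covariate_matrix(cov_m, info)

  traits <- list()
  for (entry in ctl$traits) {
    df <- read_csv_plain(need(entry$file))
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$individual_id
    ann <- NULL
    if (!is.null(entry$annotations)) {
      ann <- read_csv_plain(need(entry$annotations))
      ann$chromosome <- as.character(ann$chromosome)
    }
    traits[[entry$id]] <- trait_matrix(vals, annotations = ann,
                                       transform = entry$transform)
  }

  snps <- NULL
  if (!is.null(ctl$founder_snps)) {
    df <- read_csv_plain(need(ctl$founder_snps), sep = "\t")
    snps <- founder_snp_table(df$snp_id, df$chr, df$pos_Mbp, df$ref, df$alt,
                              df$sdp, df$csq)
  }

  study(gp, traits, covariates, founder_snps = snps)
}

#' Export a result object as schema-versioned JSON
#'
#' Serializes scan, effect, mediation, peak and SNP-association results to
#' JSON with a `schema` tag, stable key order and full double precision.
#'
#' @param x A `lod_scan`, `allele_effects`, `mediation_result` data frame,
#'   peak table, or SNP association table.
#' @param path Optional file; when NULL the JSON text is returned.
#' @return JSON text (class `json`), invisibly when written to `path`.
#' @export
export_results_json <- function(x, path = NULL) {
  payload <- result_payload(x)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

result_payload <- function(x) {
  if (inherits(x, "lod_scan")) {
    list(schema = "mppscan/lod_scan/v1",
         kind = x$kind, trait_id = x$trait_id,
         records = data.frame(marker_id = x$map$marker_id,
                              chromosome = x$map$chromosome,
                              pos_Mbp = x$map$pos_Mbp,
                              lod = as.numeric(x$lod),
                              stringsAsFactors = FALSE))
  } else if (inherits(x, "allele_effects")) {
    eff <- as.data.frame(x$effects_centered)
    list(schema = "mppscan/allele_effects/v1",
         trait_id = x$trait_id, chromosome = x$chromosome, mode = x$mode,
         founders = colnames(x$effects_centered),
         records = cbind(data.frame(marker_id = x$map$marker_id,
                                    pos_Mbp = x$map$pos_Mbp,
                                    lod = as.numeric(x$lod),
                                    stringsAsFactors = FALSE), eff))
  } else if (inherits(x, "mediation_result")) {
    list(schema = "mppscan/mediation/v1",
         target = attr(x, "target"), records = as.data.frame(x))
  } else if (inherits(x, "peak_table")) {
    list(schema = "mppscan/peaks/v1", records = as.data.frame(x))
  } else if (inherits(x, "snp_assoc_table")) {
    list(schema = "mppscan/snp_assoc/v1", records = as.data.frame(x))
  } else if (is.data.frame(x)) {
    list(schema = "mppscan/table/v1", records = x)
  } else stop("export_results_json: unsupported result type: ", class(x)[1])
}

#' Write a result object as CSV
#'
#' CSV twin of [export_results_json()]: the flat record table only.
#' @inheritParams export_results_json
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_results_csv <- function(x, path) {
  payload <- result_payload(x)
  write_csv_stable(payload$records, path)
}
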