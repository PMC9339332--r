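# DO-style synthetic studies.
#
# Each simulated individual carries two founder-mosaic haplotypes per
# chromosome, generated by a first-order Markov chain along the marker map:
# across an interval of d cM a recombination event occurs with probability
# 1 - exp(-g d / 100) (g = outbreeding-generation scaling), after which the
# founder is redrawn uniformly from the 8 — uniform founder frequencies are
# the stationary law, adequate for testing though not a population-genetic
# model of real DO generations. Dosage probabilities are the haplotype-pair
# indicators averaged, optionally blurred by Dirichlet noise to emulate
# genotyping uncertainty. Traits are sums of standardized components
# (planted locus effects, polygenic term, covariate effects, mediator
# transmission) weighted by sqrt of their variance fractions plus iid noise.

#' Simulation configuration
#'
#' The stated world for the synthetic generator. Defaults describe a modest
#' DO cohort: 200 individuals, ~20 outbreeding generations, two chromosomes,
#' near-certain genotype calls (Dirichlet concentration 200).
#'
#' @param n_individuals Cohort size.
#' @param chromosomes Data frame with `name`, `length_cM`, `length_Mbp`.
#' @param markers_per_chr Marker count per chromosome (recycled).
#' @param generations Outbreeding-generation scaling g of the recombination
#'   process.
#' @param dirichlet_conc Concentration of the probability blurring; larger is
#'   closer to certain calls.
#' @param blur Whether to blur the haplotype-indicator probabilities.
#' @param traits List of trait architectures; see [sim_trait()].
#' @param sex_ratio Proportion of males for the generated sex covariate.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 200,
                       chromosomes = data.frame(
                         name = c("1", "2"),
                         length_cM = c(90, 80),
                         length_Mbp = c(120, 100),
                         stringsAsFactors = FALSE),
                       markers_per_chr = 101,
                       generations = 20,
                       dirichlet_conc = 200,
                       blur = TRUE,
                       traits = list(),
                       sex_ratio = 0.5,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  for (tr in traits) {
    fr <- sum(vapply(tr$loci, function(l) l$frac, numeric(1)), tr$h2,
              tr$mediator_frac %||% 0)
    if (fr >= 1) stop("sim_config: variance fractions for trait '", tr$name,
                      "' sum to ", fr, " (must be < 1)")
  }
  structure(list(n_individuals = n_individuals, chromosomes = chromosomes,
                 markers_per_chr = rep_len(markers_per_chr, nrow(chromosomes)),
                 generations = generations, dirichlet_conc = dirichlet_conc,
                 blur = blur, traits = traits, sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trait architecture for the simulator
#'
#' @param name Trait id.
#' @param loci List of planted QTL, each
#'   `list(chr =, marker =, frac =, effects = 8-vector | sdp = int)`:
#'   `marker` is the marker index on `chr`, `frac` the fraction of trait
#'   variance explained; effects may be given per founder or as a biallelic
#'   SDP split (alt carriers +1/2, others -1/2).
#' @param h2 Polygenic variance fraction (kinship-structured).
#' @param sex_effect Additive male-vs-female shift in residual-SD units.
#' @param mediator,mediator_frac Optional name of a previously defined trait
#'   whose standardized values are transmitted to this trait with variance
#'   fraction `mediator_frac` (a QTL -> mediator -> target causal link).
#' @return A trait-architecture list.
#' @export
sim_trait <- function(name, loci = list(), h2 = 0, sex_effect = 0,
                      mediator = NULL, mediator_frac = 0) {
  list(name = name, loci = loci, h2 = h2, sex_effect = sex_effect,
       mediator = mediator, mediator_frac = mediator_frac)
}

# evenly spaced marker map from the chromosome table
default_sim_map <- function(config) {
  rows <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    chr <- config$chromosomes$name[i]
    m <- config$markers_per_chr[i]
    pos_Mbp <- seq(0.5, config$chromosomes$length_Mbp[i], length.out = m)
    pos_cM <- pos_Mbp / config$chromosomes$length_Mbp[i] *
      config$chromosomes$length_cM[i]
    rows[[i]] <- data.frame(
      marker_id = sprintf("%s_%03d", chr, seq_len(m)),
      chromosome = chr, pos_cM = pos_cM, pos_Mbp = pos_Mbp,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  marker_map(df$marker_id, df$chromosome, df$pos_cM, df$pos_Mbp)
}

#' Simulate DO-style founder genotype probabilities
#'
#' @param config A `sim_config`.
#' @return A `geno_probs` object over the configured marker map.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$markers_per_chr < 1)) stop("simulate_genome: zero markers")
  set.seed(config$seed)
  map <- default_sim_map(config)
  n <- config$n_individuals
  ids <- sprintf("DO%04d", seq_len(n))
  founders <- LETTERS[1:8]
  g <- config$generations
  probs <- list()
  for (chr in config$chromosomes$name) {
    pos_cM <- map$pos_cM[map$chromosome == chr]
    m <- length(pos_cM)
    hap <- array(0L, dim = c(n, 2, m))
    for (h in 1:2) {
      cur <- sample.int(8, n, replace = TRUE)
      hap[, h, 1] <- cur
      if (m > 1) for (j in 2:m) {
        d <- pos_cM[j] - pos_cM[j - 1]
        pr <- 1 - exp(-g * d / 100)
        sw <- stats::runif(n) < pr
        if (any(sw)) cur[sw] <- sample.int(8, sum(sw), replace = TRUE)
        hap[, h, j] <- cur
      }
    }
    a <- array(0, dim = c(n, 8, m), dimnames = list(ids, founders,
                                                    map$marker_id[map$chromosome == chr]))
    for (j in seq_len(m)) {
      p <- matrix(0, n, 8)
      p[cbind(seq_len(n), hap[, 1, j])] <- p[cbind(seq_len(n), hap[, 1, j])] + 0.5
      p[cbind(seq_len(n), hap[, 2, j])] <- p[cbind(seq_len(n), hap[, 2, j])] + 0.5
      if (config$blur) {
        eps <- 0.01
        alpha <- config$dirichlet_conc * (p * (1 - eps) + eps / 8)
        gam <- matrix(stats::rgamma(n * 8, shape = alpha), n, 8)
        p <- gam / rowSums(gam)
      }
      a[, , j] <- p
    }
    probs[[chr]] <- a
  }
  geno_probs(probs, map)
}

#' Simulate a founder SNP table
#'
#' SNP positions are uniform along each chromosome with Poisson counts at
#' the requested density; SDPs are uniform on 1..254 (never monomorphic).
#'
#' @param config A `sim_config` (chromosome lengths are taken from it).
#' @param density_per_Mbp Expected SNPs per Mbp.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return A `founder_snp_table`.
#' @export
simulate_founder_snps <- function(config, density_per_Mbp = 5,
                                  seed = config$seed + 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (i in seq_len(nrow(config$chromosomes))) {
    chr <- config$chromosomes$name[i]
    len <- config$chromosomes$length_Mbp[i]
    k <- stats::rpois(1, density_per_Mbp * len)
    if (k == 0) next
    pos <- sort(stats::runif(k, 0, len))
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    rows[[chr]] <- data.frame(
      snp_id = sprintf("%s_snp%05d", chr, seq_len(k)),
      chr = chr, pos_Mbp = pos, ref = ref, alt = alt,
      sdp = sample(1:254, k, replace = TRUE),
      csq = sample(c("intergenic_variant", "intron_variant",
                     "missense_variant", "synonymous_variant"),
                   k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(founder_snp_table(character(0), character(0), numeric(0),
                             character(0), character(0), integer(0)))
  df <- do.call(rbind, rows)
  founder_snp_table(df$snp_id, df$chr, df$pos_Mbp, df$ref, df$alt, df$sdp, df$csq)
}

locus_effect_vector <- function(locus) {
  if (!is.null(locus$effects)) {
    stopifnot(length(locus$effects) == 8)
    as.numeric(locus$effects)
  } else if (!is.null(locus$sdp)) {
    ifelse(sdp_to_bits(locus$sdp), 0.5, -0.5)
  } else stop("locus needs 'effects' or 'sdp'")
}

standardize <- function(v) {
  s <- stats::sd(v)
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Simulate traits with planted architectures
#'
#' Each trait is built as a sum of standardized components weighted by the
#' square root of their configured variance fractions — planted locus
#' effects (founder dosages times an effect vector), a kinship-structured
#' polygenic term, transmitted mediator values for causal links — plus a
#' sex shift and iid Gaussian noise carrying the remaining variance. Because
#' components are standardized empirically, realized variance fractions
#' match the configuration closely at large n.
#'
#' @param genoprobs A `geno_probs` from [simulate_genome()].
#' @param config The same `sim_config`.
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return List with `traits` (a `trait_matrix`), `covariates` (a
#'   `covariate_matrix` with intercept and sex), and `truth` (per-trait
#'   planted positions, effects, mediators and variance fractions).
#' @export
simulate_traits <- function(genoprobs, config, seed = config$seed + 2L) {
  set.seed(seed)
  ids <- individual_ids(genoprobs)
  n <- length(ids)
  map <- attr(genoprobs, "map")
  sex <- sample(c("F", "M"), n, replace = TRUE,
                prob = c(1 - config$sex_ratio, config$sex_ratio))
  names(sex) <- ids
  cov_df <- data.frame(sex = sex, row.names = ids, stringsAsFactors = FALSE)
  covariates <- covariates_from_df(cov_df, interactive = "sex")

  K1 <- NULL
  vals <- matrix(NA_real_, n, length(config$traits),
                 dimnames = list(ids, vapply(config$traits, `[[`, "", "name")))
  truth <- list()
  built <- list()
  for (tr in config$traits) {
    total <- 0
    comp <- rep(0, n)
    loci_truth <- list()
    for (locus in tr$loci) {
      if (!locus$chr %in% names(genoprobs))
        stop("simulate_traits: architecture references absent chromosome ", locus$chr)
      a <- genoprobs[[locus$chr]]
      if (locus$marker > dim(a)[3])
        stop("simulate_traits: architecture references absent marker ",
             locus$marker, " on chromosome ", locus$chr)
      beta <- locus_effect_vector(locus)
      gcomp <- as.numeric(a[, , locus$marker] %*% beta)
      comp <- comp + sqrt(locus$frac) * standardize(gcomp)
      total <- total + locus$frac
      loci_truth[[length(loci_truth) + 1L]] <- list(
        chr = locus$chr,
        marker_id = dimnames(a)[[3]][locus$marker],
        marker = locus$marker, frac = locus$frac, effects = beta)
    }
    if (tr$h2 > 0) {
      if (is.null(K1)) {
        K1 <- compute_kinship(genoprobs, "overall")[["overall"]]
        ed1 <- decompose_kinship(K1)
      }
      u <- as.numeric(ed1$vectors %*% (sqrt(ed1$values) * stats::rnorm(n)))
      comp <- comp + sqrt(tr$h2) * standardize(u)
      total <- total + tr$h2
    }
    med_id <- NULL
    if (!is.null(tr$mediator)) {
      if (is.null(built[[tr$mediator]]))
        stop("simulate_traits: mediator '", tr$mediator,
             "' must be defined before its target")
      comp <- comp + sqrt(tr$mediator_frac) * standardize(built[[tr$mediator]])
      total <- total + tr$mediator_frac
      med_id <- tr$mediator
    }
    stopifnot(total < 1)
    yv <- comp + sqrt(1 - total) * stats::rnorm(n)
    if (tr$sex_effect != 0) yv <- yv + tr$sex_effect * (sex == "M")
    vals[, tr$name] <- yv
    built[[tr$name]] <- yv
    truth[[tr$name]] <- list(loci = loci_truth, h2 = tr$h2,
                             mediator = med_id,
                             mediator_frac = tr$mediator_frac,
                             sex_effect = tr$sex_effect)
  }
  list(traits = trait_matrix(vals, transform = "norm"),
       covariates = covariates, truth = truth)
}

#' Simulate a complete study bundle
#'
#' Genome, covariates, traits and founder SNPs from one configuration; the
#' result passes [read_bundle()] validation after [write_bundle()].
#'
#' @param config A `sim_config`.
#' @param snp_density_per_Mbp Founder SNP density (0 for none).
#' @return List with `study` and `truth`.
#' @export
simulate_study <- function(config, snp_density_per_Mbp = 0) {
  gp <- simulate_genome(config)
  tt <- simulate_traits(gp, config)
  snps <- if (snp_density_per_Mbp > 0)
    simulate_founder_snps(config, snp_density_per_Mbp) else NULL
  st <- study(gp, list(main = tt$traits), tt$covariates, founder_snps = snps)
  list(study = st, truth = tt$truth)
}
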