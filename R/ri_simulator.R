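# Synthetic recombinant-inbred (RI) panels: an evenly spaced genetic map,
# two-class genotypes with Markov-chain linkage along each chromosome, and
# traits that are linear in one marker's standardized dosage plus Gaussian
# noise at a chosen heritability, with the planted truth recorded.

#' Simulation configuration for a recombinant-inbred panel
#'
#' @param n_strains Number of inbred strains (>= 4). Default 80, the scale of
#'   a well-powered BXD-style expression study.
#' @param n_chromosomes Number of chromosomes. Default 20 (mouse autosomes
#'   plus X).
#' @param chr_length_cM Chromosome length in centimorgans. Default 100.
#' @param marker_spacing_cM Distance between adjacent markers in cM.
#'   Default 2.
#' @param n_traits Number of simulated traits. Default 1000.
#' @param prop_with_qtl Proportion of traits carrying one planted eQTL.
#'   Default 0.3.
#' @param h2 Heritability of each planted eQTL: the population squared
#'   correlation between trait and causal marker dosage, in `[0, 1)`.
#'   Default 0.4.
#' @param map_function `"haldane"` (default) converts the marker spacing `d`
#'   cM to a per-meiosis recombination fraction `r = (1 - exp(-2d/100))/2`;
#'   `"haldane_ri_expanded"` additionally applies the RI-by-sib-mating map
#'   expansion `R = 4r / (1 + 6r)`.
#' @param seed Integer seed; fixed seed gives bit-identical panels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_strains = 80L, n_chromosomes = 20L,
                       chr_length_cM = 100, marker_spacing_cM = 2,
                       n_traits = 1000L, prop_with_qtl = 0.3, h2 = 0.4,
                       map_function = c("haldane", "haldane_ri_expanded"),
                       seed = 1L) {
  map_function <- match.arg(map_function)
  n_strains <- as.integer(n_strains)
  stopifnot(n_strains >= 4L, n_chromosomes >= 1L,
            chr_length_cM > 0, marker_spacing_cM > 0,
            n_traits >= 1L, prop_with_qtl >= 0, prop_with_qtl <= 1,
            h2 >= 0)
  if (h2 >= 1) stop("h2 must be < 1 (noise-free traits are degenerate)")
  structure(list(n_strains = n_strains,
                 n_chromosomes = as.integer(n_chromosomes),
                 chr_length_cM = chr_length_cM,
                 marker_spacing_cM = marker_spacing_cM,
                 n_traits = as.integer(n_traits),
                 prop_with_qtl = prop_with_qtl, h2 = h2,
                 map_function = map_function, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build an evenly spaced genetic map
#'
#' Markers sit at 0, s, 2s, ... up to the chromosome length on each
#' chromosome, with deterministic ids `c{chr}m{idx}`.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `marker`, `chr`, `cM`.
#' @export
make_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$marker_spacing_cM > config$chr_length_cM)
    stop("marker spacing exceeds chromosome length")
  pos <- seq(0, config$chr_length_cM, by = config$marker_spacing_cM)
  maps <- lapply(seq_len(config$n_chromosomes), function(chr) {
    data.frame(marker = sprintf("c%dm%d", chr, seq_along(pos)),
               chr = as.character(chr), cM = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Recombination fraction between adjacent markers
#'
#' Haldane map function `r = (1 - exp(-2d/100)) / 2` for a spacing of `d`
#' cM; with the RI expansion, `R = 4r / (1 + 6r)` (sib-mated RI lines see
#' more historical recombination than a single meiosis).
#'
#' @param d_cM Spacing in centimorgans.
#' @param map_function `"haldane"` or `"haldane_ri_expanded"`.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
recomb_fraction <- function(d_cM, map_function = "haldane") {
  r <- (1 - exp(-2 * d_cM / 100)) / 2
  if (map_function == "haldane_ri_expanded") r <- 4 * r / (1 + 6 * r)
  r
}

#' Simulate two-class RI genotypes with linkage
#'
#' Each strain is an independent two-state {0, 1} Markov chain along each
#' chromosome: the first marker is Bernoulli(0.5) and adjacent markers flip
#' with the recombination fraction implied by the map function and spacing.
#' Chromosomes are independent.
#'
#' @param map Genetic map from [make_map()].
#' @param config A [sim_config()] (supplies spacing, map function, strains,
#'   seed).
#' @return A `genotype_matrix` with hard 0/1 dosages.
#' @export
simulate_genotypes <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_strains
  r <- recomb_fraction(config$marker_spacing_cM, config$map_function)
  chrs <- unique(map$chr)
  blocks <- lapply(chrs, function(ch) {
    p_chr <- sum(map$chr == ch)
    g <- matrix(0L, n, p_chr)
    g[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (p_chr > 1L) {
      flips <- matrix(stats::rbinom(n * (p_chr - 1L), 1L, r), n, p_chr - 1L)
      for (j in 2L:p_chr) g[, j] <- bitwXor(g[, j - 1L], flips[, j - 1L])
    }
    g
  })
  dosage <- do.call(cbind, blocks)
  storage.mode(dosage) <- "double"
  rownames(dosage) <- sprintf("S%03d", seq_len(n))
  new_genotype_matrix(dosage, map)
}

#' Simulate traits with planted eQTL
#'
#' A fraction `prop_with_qtl` of traits get one causal marker drawn
#' uniformly over the map; such a trait is
#' `y = beta * z(g) + e`, where `z(g)` is the marker's standardized dosage,
#' `e ~ N(0, 1)`, and `beta = sqrt(h2 / (1 - h2))` so that the population
#' squared correlation between trait and marker equals `h2`. Null traits are
#' pure `N(0, 1)`.
#'
#' @param geno A complete `genotype_matrix` from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return List with `traits` (a `trait_matrix`) and `truth` (data.frame
#'   `trait`, `has_qtl`, `marker_index`, `marker_id`, `chr`, `cM`, `beta`,
#'   `noise_sd`).
#' @export
simulate_traits <- function(geno, config) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  # offset keeps the trait stream distinct from the genotype stream while
  # remaining a deterministic function of the one user-facing seed
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  n <- nrow(geno$dosage)
  p <- ncol(geno$dosage)
  m <- config$n_traits
  has_qtl <- seq_len(m) <= round(config$prop_with_qtl * m)
  beta <- sqrt(config$h2 / (1 - config$h2))
  qtl_idx <- ifelse(has_qtl, sample.int(p, m, replace = TRUE), NA_integer_)
  Y <- matrix(stats::rnorm(n * m), n, m)
  for (i in which(has_qtl)) {
    g <- geno$dosage[, qtl_idx[i]]
    sdg <- sqrt(mean((g - mean(g))^2))
    z <- if (sdg > 0) (g - mean(g)) / sdg else rep(0, n)
    Y[, i] <- beta * z + Y[, i]
  }
  trait_ids <- sprintf("T%05d", seq_len(m))
  dimnames(Y) <- list(rownames(geno$dosage), trait_ids)
  truth <- data.frame(trait = trait_ids, has_qtl = has_qtl,
                      marker_index = qtl_idx,
                      marker_id = ifelse(has_qtl, geno$map$marker[qtl_idx], NA),
                      chr = ifelse(has_qtl, geno$map$chr[qtl_idx], NA),
                      cM = ifelse(has_qtl, geno$map$cM[qtl_idx], NA),
                      beta = ifelse(has_qtl, beta, 0), noise_sd = 1,
                      stringsAsFactors = FALSE)
  list(traits = new_trait_matrix(Y), truth = truth)
}

#' Simulate a full panel (map, genotypes, traits, truth)
#'
#' Convenience wrapper chaining [make_map()], [simulate_genotypes()] and
#' [simulate_traits()].
#'
#' @param config A [sim_config()].
#' @return List with `geno`, `traits`, `truth`.
#' @export
simulate_panel <- function(config = sim_config()) {
  map <- make_map(config)
  geno <- simulate_genotypes(map, config)
  st <- simulate_traits(geno, config)
  list(geno = geno, traits = st$traits, truth = st$truth)
}
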