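# Shared fixture builders: everything is generated in code at test time.

# small deterministic RI panel
tiny_panel <- function(n_strains = 40, n_chromosomes = 3, n_traits = 20,
                       h2 = 0.4, prop_with_qtl = 0.5, seed = 11,
                       marker_spacing_cM = 5, ...) {
  simulate_panel(sim_config(n_strains = n_strains,
                            n_chromosomes = n_chromosomes,
                            marker_spacing_cM = marker_spacing_cM,
                            n_traits = n_traits, h2 = h2,
                            prop_with_qtl = prop_with_qtl, seed = seed, ...))
}

# plain random matrices (not linked markers) for algebra-level checks
random_matrix <- function(n, k, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k,
         dimnames = list(sprintf("s%d", 1:n), sprintf("v%d", 1:k)))
}

# genotype_matrix from a raw dosage matrix on a single-chromosome map
geno_from_matrix <- function(dosage, chr = "1", spacing = 1) {
  p <- ncol(dosage)
  map <- data.frame(marker = sprintf("m%d", seq_len(p)), chr = chr,
                    cM = (seq_len(p) - 1) * spacing, stringsAsFactors = FALSE)
  colnames(dosage) <- map$marker
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("s%d", seq_len(nrow(dosage)))
  new_genotype_matrix(dosage, map)
}

# write a toy .geno file and return its path
write_toy_geno <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.geno")
  writeLines(lines, path)
  path
}

# peak distance to the planted marker: Inf when on another chromosome
peak_distance_cM <- function(peaks, truth) {
  truth <- truth[truth$has_qtl, ]
  idx <- match(truth$trait, peaks$trait_id)
  ifelse(peaks$chromosome[idx] == truth$chr,
         abs(peaks$position_cM[idx] - truth$cM), Inf)
}
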