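# Small models and genotype fixtures shared across test files.

single_deme_model <- function(N = 1000, n_dip = 1, mu = 1e-8) {
  demographic_model(
    populations = list(population_spec("A", N, sample_size = n_dip)),
    metapopulations = list(),
    mutation_rate = mu)
}

two_deme_model <- function(N = 1000, tdiv = 500, n_dip = 2, mu = 1e-7,
                           N_root = NULL, mig = 0) {
  demographic_model(
    populations = list(
      population_spec("A", N, sample_size = n_dip, divergence_time = tdiv,
                      migration_rate = mig),
      population_spec("B", N, sample_size = n_dip, divergence_time = tdiv,
                      migration_rate = mig)),
    metapopulations = list(population_spec("ROOT", N_root %||% N)),
    mutation_rate = mu)
}

# four exchangeable islands off one metapopulation
symmetric_four_pop_model <- function(N = 2000, tdiv = 800, n_dip = 3,
                                     mu = 1e-8, N_meta = 10000, mig = 1e-4) {
  demographic_model(
    populations = lapply(c("P1", "P2", "P3", "P4"), function(nm)
      population_spec(nm, N, sample_size = n_dip, divergence_time = tdiv,
                      migration_rate = mig)),
    metapopulations = list(population_spec("META", N_meta)),
    mutation_rate = mu)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# genotype matrix on one scaffold from a plain sites x samples matrix
toy_gm <- function(geno, pops, pos = NULL, scaffold_len = NULL,
                   dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  pos <- pos %||% (seq_len(nrow(geno)) * 100L - 100L)
  genotype_matrix(
    geno,
    sites = data.frame(scaffold = rep("s1", nrow(geno)), pos = pos),
    scaffolds = data.frame(name = "s1",
                           length = scaffold_len %||% (max(pos) + 1000L)),
    sample_ids = paste0("ind", seq_len(ncol(geno))),
    populations = pops, dp = dp, gq = gq)
}

# single-site genotype matrix realizing given allele counts in two pops of
# 5 diploids each (n = 10 alleles per pop)
one_site_two_pops <- function(ac1, ac2) {
  g1 <- c(rep(2L, ac1 %/% 2), rep(1L, ac1 %% 2))
  g1 <- c(g1, rep(0L, 5 - length(g1)))
  g2 <- c(rep(2L, ac2 %/% 2), rep(1L, ac2 %% 2))
  g2 <- c(g2, rep(0L, 5 - length(g2)))
  toy_gm(matrix(c(g1, g2), nrow = 1), pops = rep(c("p1", "p2"), each = 5))
}
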