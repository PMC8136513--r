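# SFS construction, expected SFS, composite likelihood and unit conversions.

test_that("folded marginal SFS matches the toy enumeration", {
  # 2 diploids, minor-allele counts (1, 1, 2) -> cells {1: 2, 2: 1}
  g <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  gm <- toy_gm(g, pops = c("p", "p"))
  sfs <- sfs_from_genotypes(gm, "p")
  expect_equal(sfs$cells, c(`1` = 2L, `2` = 1L))
  expect_equal(sfs$n_sites_total, 3L)
})

test_that("monomorphic input gives an empty polymorphic SFS", {
  gm <- toy_gm(matrix(c(0L, 2L, 0L, 2L), 2), pops = c("p", "p"))
  sfs <- sfs_from_genotypes(gm, "p")
  expect_length(sfs$cells, 0L)
  expect_equal(sfs$n_sites_total, 2L)
})

test_that("folded SFS is invariant under allele relabeling", {
  set.seed(12)
  g <- matrix(sample(0:2, 60, TRUE), 10)
  gm <- toy_gm(g, pops = rep(c("a", "b"), each = 3))
  flipped <- gm
  flipped$geno <- 2L - gm$geno
  s1 <- sfs_from_genotypes(gm)
  s2 <- sfs_from_genotypes(flipped)
  expect_equal(s1$cells[order(names(s1$cells))], s2$cells[order(names(s2$cells))])
})

test_that("population with zero samples or missing data is an error", {
  gm <- toy_gm(matrix(c(0L, 1L), 1), pops = c("a", "b"))
  expect_error(sfs_from_genotypes(gm, c("a", "z")), "zero samples")
  gm$geno[1, 1] <- NA
  expect_error(sfs_from_genotypes(gm, c("a", "b")), "missing genotypes")
})

test_that("composite log-likelihood matches hand arithmetic and MLE property", {
  obs <- structure(list(populations = "p", sample_sizes = 4L,
                        cells = c(`1` = 3L, `2` = 1L), n_sites_total = 4L,
                        folded = TRUE), class = "folded_sfs")
  cl <- composite_log_likelihood(obs, c(`1` = 0.75, `2` = 0.25))
  expect_equal(cl, 3 * log(0.75) + log(0.25), tolerance = 1e-12)
  expect_equal(cl, -2.24934, tolerance = 1e-5)
  # probabilities proportional to counts maximize CL over the simplex
  cl_mle <- composite_log_likelihood(obs, c(`1` = 0.75, `2` = 0.25))
  for (p1 in c(0.5, 0.6, 0.9))
    expect_lt(composite_log_likelihood(obs, setNames(c(p1, 1 - p1), c("1", "2"))),
              cl_mle)
  # additive over independent blocks
  obs2 <- obs; obs2$cells <- c(`1` = 1L, `2` = 2L)
  both <- obs; both$cells <- c(`1` = 4L, `2` = 3L)
  p <- c(`1` = 0.7, `2` = 0.3)
  expect_equal(composite_log_likelihood(both, p),
               composite_log_likelihood(obs, p) +
                 composite_log_likelihood(obs2, p), tolerance = 1e-12)
  # observed cell missing from the expectation is an error
  expect_error(composite_log_likelihood(obs, c(`1` = 1)), "absent")
})

test_that("expected unfolded single-deme SFS follows the 1/i neutral shape", {
  m <- single_deme_model(N = 800, n_dip = 2, mu = 2e-7)   # n = 4 lineages
  probs <- expected_sfs(m, n_replicates = 1500, seed = 21, window_length = 20000,
                        folded = FALSE)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  an <- sum(1 / (1:3))
  expected <- c(`1` = 1, `2` = 1 / 2, `3` = 1 / 3) / an
  got <- as.numeric(probs[c("1", "2", "3")])
  expect_equal(got, unname(expected), tolerance = 0.08)
})

test_that("symmetric two-deme marginals agree within Monte-Carlo error", {
  m <- two_deme_model(N = 1000, tdiv = 400, n_dip = 2, mu = 1e-7)
  probs <- expected_sfs(m, n_replicates = 800, seed = 31, window_length = 20000)
  cells <- do.call(rbind, strsplit(names(probs), ","))
  marg <- function(col) tapply(as.numeric(probs), cells[, col], sum)
  mA <- marg(1); mB <- marg(2)
  expect_equal(as.numeric(mA), as.numeric(mB[names(mA)]), tolerance = 0.12)
})

test_that("empty cells are floored and the vector stays a distribution", {
  m <- two_deme_model(N = 500, tdiv = 3000, n_dip = 2, mu = 5e-8)
  probs <- expected_sfs(m, n_replicates = 50, seed = 3, window_length = 5000)
  expect_true(all(probs > 0))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_true(any(probs == min(probs)))  # floored mass present at desk scale
})

test_that("zero free parameters returns the template evaluation", {
  m <- two_deme_model(N = 800, tdiv = 300, n_dip = 2, mu = 1e-7)
  gm <- simulate_window(m, 50000, 77)$genotypes
  obs <- sfs_from_genotypes(gm)
  fit <- fit_parameters(obs, m, character(0), list(), seed = 5,
                        n_replicates = 200, window_length = 10000)
  expect_length(fit$parameter_estimates, 0L)
  expect_equal(fit$n_evaluations, 1L)
  expect_true(is.finite(fit$log_composite_likelihood))
})

test_that("fits are deterministic given the master seed", {
  m <- two_deme_model(N = 800, tdiv = 300, n_dip = 1, mu = 1e-7)
  gm <- simulate_window(m, 30000, 15)$genotypes
  obs <- sfs_from_genotypes(gm)
  fit1 <- fit_parameters(obs, m, "populations.A.divergence_time",
                         list("populations.A.divergence_time" = c(50, 1000)),
                         seed = 9, n_replicates = 120, window_length = 10000)
  fit2 <- fit_parameters(obs, m, "populations.A.divergence_time",
                         list("populations.A.divergence_time" = c(50, 1000)),
                         seed = 9, n_replicates = 120, window_length = 10000)
  expect_identical(fit1$parameter_estimates, fit2$parameter_estimates)
  expect_identical(fit1$log_composite_likelihood, fit2$log_composite_likelihood)
})

test_that("generating parameters beat a +/-50% perturbation in most replicates", {
  # Monte-Carlo precision matters here: at ~1,300 observed SNPs the
  # generating vs +50% contrast is ~15 CL units, so the expected SFS needs
  # enough replicates that its own noise (~2 units at 2,000) stays smaller.
  m <- two_deme_model(N = 600, tdiv = 500, n_dip = 2, mu = 1e-7)
  setp <- function(mm, t) {
    mm <- set_model_param(mm, "populations.A.divergence_time", t)
    set_model_param(mm, "populations.B.divergence_time", t)
  }
  m_hi <- setp(m, 750); m_lo <- setp(m, 250)
  wins <- 0L
  seeds <- derive_seeds(2026, 10)
  for (k in seq_along(seeds)) {
    sims <- simulate_null_windows(m, 80, 20000, seed = seeds[k])
    geno <- do.call(rbind, lapply(sims, function(s) s$genotypes$geno))
    gm0 <- sims[[1]]$genotypes
    gm <- genotype_matrix(geno, data.frame(scaffold = "s1",
                                           pos = seq_len(nrow(geno)) * 10L),
                          data.frame(name = "s1", length = nrow(geno) * 10L + 10L),
                          gm0$sample_ids, gm0$populations)
    obs <- sfs_from_genotypes(gm)
    cl <- function(mod) composite_log_likelihood(
      obs, expected_sfs(mod, 2000, seed = seeds[k] + 1L, window_length = 20000))
    if (cl(m) >= max(cl(m_hi), cl(m_lo))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("SFS TSV serialization writes header metadata and one row per cell", {
  g <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L))
  sfs <- sfs_from_genotypes(toy_gm(g, pops = c("p", "p")), "p")
  path <- tempfile(fileext = ".tsv")
  write_sfs_tsv(sfs, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "#")), 4L)
  body <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), length(sfs$cells))
  expect_equal(sum(body$count), sum(sfs$cells))
})

test_that("singleton masking drops exactly the total-count-1 cells", {
  set.seed(15)
  g <- matrix(sample(0:2, 80, TRUE), 10)
  gm <- toy_gm(g, pops = rep(c("a", "b"), each = 4))
  sfs <- sfs_from_genotypes(gm)
  masked <- drop_singleton_cells(sfs)
  tot <- function(x) vapply(strsplit(names(x$cells), ","),
                            function(v) sum(as.integer(v)), 0L)
  expect_true(all(tot(masked) > 1L))
  expect_equal(sum(sfs$cells) - sum(masked$cells), sum(sfs$cells[tot(sfs) == 1L]))
  expect_equal(masked$n_sites_total, sfs$n_sites_total)
  # masked fit still evaluates
  m <- two_deme_model(N = 800, tdiv = 300, n_dip = 2, mu = 1e-7)
  gm2 <- simulate_window(m, 30000, 3)$genotypes
  obs <- sfs_from_genotypes(gm2)
  fit <- fit_parameters(obs, m, character(0), list(), seed = 4,
                        n_replicates = 150, window_length = 10000,
                        mask_singletons = TRUE)
  expect_true(is.finite(fit$log_composite_likelihood))
})

test_that("unit conversions reproduce the printed generation figures exactly", {
  expect_identical(years_to_generations(7500, 5), 1500)
  expect_identical(years_to_generations(9200, 5), 1840)
  expect_identical(years_to_generations(0, 5), 0)
  expect_equal(generations_to_years(years_to_generations(8400, 5), 5), 8400)
  expect_error(years_to_generations(-1, 5), "non-negative")
  expect_error(years_to_generations(10, 0), "> 0")
})
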