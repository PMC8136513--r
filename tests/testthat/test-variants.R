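# VCF ingestion, filters, window tiling and PCA.

test_that("VCF round-trip preserves genotypes, positions and metadata", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L, 2L, 2L, 0L, 1L, NA, 2L), nrow = 4)
  gm <- toy_gm(g, pops = c("p1", "p1", "p2"),
               pos = c(0L, 100L, 250L, 999L), scaffold_len = 2000L,
               dp = matrix(15, 4, 3), gq = matrix(60, 4, 3))
  path <- tempfile(fileext = ".vcf.gz")
  write_vcf(gm, path)
  back <- read_vcf(path, setNames(gm$populations, gm$sample_ids))
  expect_identical(back$geno, gm$geno)
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$scaffolds, gm$scaffolds)
  expect_equal(back$populations, gm$populations)
  expect_equal(unname(back$dp), unname(gm$dp))
})

test_that("indel and multiallelic records are skipped; positions become 0-based", {
  dir <- tempfile(); dir.create(dir)
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t101\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\t.\tAC\tA\t.\tPASS\t.\tGT\t0/0\t0/1",     # indel
    "chr1\t300\t.\tG\tC\t.\tPASS\t.\tGT\t0/1\t0/1",
    "chr1\t400\t.\tG\tA,T\t.\tPASS\t.\tGT\t1/2\t0/0",    # triallelic
    "chr1\t500\t.\tT\tG\t.\tPASS\t.\tGT\t./.\t1/1"), vcf)
  gm <- suppressMessages(read_vcf(vcf, c(s1 = "x", s2 = "y")))
  expect_equal(nrow(gm$geno), 3L)
  expect_equal(gm$sites$pos, c(100L, 299L, 499L))
  expect_equal(gm$geno[1, ], c(0L, 2L))
  expect_true(is.na(gm$geno[3, 1]))
})

test_that("a sample missing from the population map is an error", {
  gm <- toy_gm(matrix(c(0L, 2L), 1), pops = c("a", "b"))
  path <- tempfile(fileext = ".vcf.gz")
  write_vcf(gm, path)
  expect_error(read_vcf(path, c(ind1 = "a")), "absent from population map")
})

test_that("filters drop the constructed failures and nothing else", {
  # 40 samples; thresholds: MAF >= 0.025, missing <= 5%, DP >= 10
  n <- 40
  mk_site <- function(ac, n_missing = 0) {
    g <- integer(n)
    g[seq_len(ac %/% 2)] <- 2L
    if (ac %% 2) g[ac %/% 2 + 1L] <- 1L
    if (n_missing) g[(n - n_missing + 1L):n] <- NA_integer_
    g
  }
  geno <- rbind(
    mk_site(10),            # passes everything
    mk_site(1),             # MAF 1/80 = 0.0125 < 0.025 -> dropped
    mk_site(40),            # passes (MAF 0.5)
    mk_site(1),             # second MAF failure -> dropped
    mk_site(8, n_missing = 3),  # 3/40 = 7.5% missing -> dropped
    mk_site(6))             # passes; one genotype DP-masked below
  dp <- matrix(30, 6, n)
  dp[6, 1] <- 5             # DP < 10: masked, site still has 1/40 missing
  gm <- toy_gm(geno, pops = rep(c("p1", "p2"), each = n / 2), dp = dp,
               scaffold_len = 2e6)   # above the 1-Mb scaffold filter
  out <- apply_filters(gm, filter_config())
  expect_equal(nrow(out$geno), 3L)
  expect_equal(out$sites$pos, gm$sites$pos[c(1, 3, 6)])
  expect_true(is.na(out$geno[3, 1]))   # the DP-masked call
})

test_that("an all-defaults-off filter config is the identity", {
  gm <- toy_gm(matrix(c(0L, 1L, NA, 2L, 0L, 1L), nrow = 3),
               pops = c("a", "b"))
  cfg <- filter_config(min_DP = 0, min_GQ = 0, min_maf = 0,
                       max_missing_fraction = 1, min_scaffold_length = 0,
                       require_complete = FALSE)
  expect_identical(apply_filters(gm, cfg)$geno, gm$geno)
})

test_that("require_complete removes exactly the sites with missing calls", {
  g <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3)
  gm <- toy_gm(g, pops = c("a", "b"))
  cfg <- filter_config(min_DP = 0, min_GQ = 0, min_maf = 0,
                       max_missing_fraction = 1, min_scaffold_length = 0,
                       require_complete = TRUE)
  out <- apply_filters(gm, cfg)
  expect_equal(nrow(out$geno), 2L)
  expect_false(anyNA(out$geno))
})

test_that("filtering is idempotent", {
  set.seed(8)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 200, TRUE, prob = c(.4, .2, .3, .1)),
              nrow = 20)
  gm <- toy_gm(g, pops = rep(c("a", "b"), each = 5),
               dp = matrix(sample(5:30, 200, TRUE), 20),
               gq = matrix(sample(10:60, 200, TRUE), 20))
  cfg <- filter_config(min_scaffold_length = 0, max_missing_fraction = 0.3)
  once <- apply_filters(gm, cfg)
  twice <- apply_filters(once, cfg)
  expect_identical(twice, once)
})

test_that("short scaffolds are dropped and empty results warn", {
  g <- matrix(c(2L, 0L), 1)
  gm <- toy_gm(g, pops = c("a", "b"), scaffold_len = 5000L)
  expect_warning(out <- apply_filters(gm, filter_config(min_maf = 0)),
                 "all sites removed")
  expect_equal(nrow(out$geno), 0L)
  expect_equal(nrow(out$scaffolds), 0L)
})

test_that("window tiling matches the arithmetic examples", {
  w <- tile_windows(c(s = 100000))
  full <- w[!w$partial, ]
  expect_equal(nrow(full), 6L)
  expect_equal(full$start, seq(0, 50000, by = 10000))
  expect_equal(nrow(tile_windows(c(s = 50000))), 1L)
  w1m <- tile_windows(c(s = 1000000))
  expect_equal(sum(!w1m$partial), 96L)   # floor((1e6 - 5e4)/1e4) + 1
})

test_that("terminal partials cover uncovered tails and short scaffolds get one window", {
  w <- tile_windows(c(s = 104000))       # 4-kb uncovered tail: partial emitted
  expect_true(any(w$partial))
  expect_equal(max(w$end), 104000)
  w2 <- tile_windows(c(s = 7000))        # shorter than one window
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0, 7000))
})

test_that("tiling covers every base when step <= window size", {
  for (len in c(50000, 63000, 104000, 1000000, 1037777)) {
    w <- tile_windows(c(s = len))
    covered <- rep(FALSE, 100)
    probe <- seq(0, len - 1, length.out = 100)
    for (i in seq_len(nrow(w)))
      covered <- covered | (probe >= w$start[i] & probe < w$end[i])
    expect_true(all(covered), label = paste("coverage at length", len))
  }
})

test_that("PCA separates two fixed groups on PC1 and is order-invariant up to sign", {
  g <- cbind(matrix(0L, 20, 4), matrix(2L, 20, 4))
  gm <- toy_gm(g, pops = rep(c("a", "b"), each = 4))
  p <- genotype_pca(gm, 2)
  expect_gt(p$varfrac[1], 0.999)
  expect_true(all(p$scores[1:4, 1] * p$scores[5:8, 1] < 0))
  # permute samples: same coordinates up to sign, matched by id
  perm <- c(3, 7, 1, 5, 2, 8, 4, 6)
  gm2 <- gm; gm2$geno <- gm$geno[, perm]
  gm2$sample_ids <- gm$sample_ids[perm]; gm2$populations <- gm$populations[perm]
  p2 <- genotype_pca(gm2, 2)
  s1 <- p$scores[gm$sample_ids, 1]; s2 <- p2$scores[gm$sample_ids, 1]
  expect_equal(abs(cor(s1, s2)), 1, tolerance = 1e-10)
})

test_that("PCA on simulated four-population data assigns samples to their population", {
  m <- symmetric_four_pop_model(N = 500, tdiv = 1500, n_dip = 4, mu = 2e-8)
  sims <- simulate_null_windows(m, 40, 50000, seed = 88)
  geno <- do.call(rbind, lapply(sims, function(s) s$genotypes$geno))
  gm0 <- sims[[1]]$genotypes
  gm <- genotype_matrix(geno,
                        sites = data.frame(scaffold = "s1",
                                           pos = seq_len(nrow(geno)) * 10L),
                        scaffolds = data.frame(name = "s1",
                                               length = nrow(geno) * 10L + 10L),
                        sample_ids = gm0$sample_ids,
                        populations = gm0$populations)
  p <- genotype_pca(gm, 2)
  cent <- apply(p$scores, 2, tapply, gm$populations, mean)
  assign <- apply(p$scores, 1, function(x)
    rownames(cent)[which.min(colSums((t(cent) - x)^2))])
  expect_gte(mean(assign == gm$populations), 0.95)
})

test_that("monomorphic-only input is a PCA error", {
  gm <- toy_gm(matrix(0L, 5, 4), pops = rep(c("a", "b"), each = 2))
  expect_error(genotype_pca(gm), "polymorphic")
})
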