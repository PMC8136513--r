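# Hudson FST, the T transform, mPBS and outlier extraction.

test_that("Hudson FST reproduces the hand-computed single-site values", {
  # p1 = 0.9, p2 = 0.1, n1 = n2 = 10 alleles:
  # N = 0.64 - 2 * 0.09/9 = 0.62 ; D = 0.82 ; FST = 0.75610
  gm <- one_site_two_pops(9, 1)
  expect_equal(hudson_fst(gm, c("p1", "p2"), min_sites = 1)$fst,
               0.62 / 0.82, tolerance = 1e-10)
  # p1 = p2 = 0.5: N = -2 * 0.25/9 = -0.25/4.5 ; D = 0.5 ; FST ~ -0.1111
  gm2 <- one_site_two_pops(5, 5)
  expect_equal(hudson_fst(gm2, c("p1", "p2"), min_sites = 1)$fst,
               (-0.25 / 4.5) / 0.5, tolerance = 1e-10)
})

test_that("sites monomorphic across both populations yield a missing estimate", {
  gm <- toy_gm(matrix(2L, 3, 10), pops = rep(c("p1", "p2"), each = 5))
  r <- hudson_fst(gm, c("p1", "p2"), min_sites = 1)
  expect_true(is.na(r$fst))
  expect_equal(r$n_sites, 0L)
})

test_that("window FST is a ratio of sums, not a mean of per-site ratios", {
  # two sites with very different per-site ratios
  g <- rbind(c(rep(2L, 5), rep(0L, 5)),        # p1 = 1, p2 = 0: ratio 1
             c(2L, rep(0L, 4), rep(0L, 5)))    # p1 = 0.2, p2 = 0
  gm <- toy_gm(g, pops = rep(c("p1", "p2"), each = 5))  # sites at pos 0, 100
  win1 <- list(scaffold = "s1", start = 0, end = 50)
  win2 <- list(scaffold = "s1", start = 50, end = 150)
  h1 <- hudson_fst(gm, c("p1", "p2"), win1, min_sites = 1)$fst
  h2 <- hudson_fst(gm, c("p1", "p2"), win2, min_sites = 1)$fst
  both <- hudson_fst(gm, c("p1", "p2"), min_sites = 1)$fst
  expect_false(isTRUE(all.equal(both, mean(c(h1, h2)))))
  # explicit ratio of sums
  n1 <- 1 + (0.2 - 0)^2 - 0.2 * 0.8 / 9
  d1 <- 1 + 0.2
  expect_equal(both, n1 / d1, tolerance = 1e-10)
})

test_that("fst_to_time matches the printed worked example and clamps", {
  expect_equal(fst_to_time(0), 0)
  expect_equal(fst_to_time(0.164), -log(0.836), tolerance = 1e-10)
  expect_equal(fst_to_time(0.164), 0.17913, tolerance = 1e-4)
  expect_equal(fst_to_time(-0.05), 0)
  expect_true(is.na(fst_to_time(1)))
  expect_error(fst_to_time(1.2), "<= 1")
  # strictly increasing on [0, 1)
  x <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(fst_to_time(x)) > 0))
})

test_that("mPBS on equal and star-additive T matrices recovers branch lengths", {
  pops <- c("a", "b", "c", "d")
  t_eq <- matrix(0.4, 4, 4, dimnames = list(pops, pops)); diag(t_eq) <- 0
  for (p in pops) expect_equal(mpbs(t_eq, p), 0.2)
  b <- c(a = 0.3, b = 0.1, c = 0.1, d = 0.1)
  t_star <- outer(b, b, "+"); diag(t_star) <- 0
  expect_equal(mpbs(t_star, "a"), 0.3, tolerance = 1e-12)
  expect_equal(mpbs(t_star, "b"), 0.1, tolerance = 1e-12)
})

test_that("mPBS equals the mean of the three brute-force PBS triplets", {
  pbs3 <- function(tm, a, b, c_) (tm[a, b] + tm[a, c_] - tm[b, c_]) / 2
  brute <- function(tm, focal) {
    oth <- setdiff(rownames(tm), focal)
    mean(c(pbs3(tm, focal, oth[1], oth[2]),
           pbs3(tm, focal, oth[1], oth[3]),
           pbs3(tm, focal, oth[2], oth[3])))
  }
  pops <- c("w", "x", "y", "z")
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    tm <- matrix(0, 4, 4, dimnames = list(pops, pops))
    tm[upper.tri(tm)] <- runif(6, 0, 3)
    tm <- tm + t(tm)
    for (p in pops)
      worst <- max(worst, abs(mpbs(tm, p) - brute(tm, p)))
  }
  expect_lt(worst, 1e-12)
})

test_that("mPBS is invariant under permutation of the non-focal labels", {
  pops <- c("a", "b", "c", "d")
  set.seed(7)
  for (i in 1:50) {
    tm <- matrix(0, 4, 4, dimnames = list(pops, pops))
    tm[upper.tri(tm)] <- runif(6)
    tm <- tm + t(tm)
    perm <- c("a", sample(c("b", "c", "d")))
    tm_p <- tm[perm, perm]
    expect_equal(mpbs(tm_p, "a"), mpbs(tm, "a"), tolerance = 1e-14)
  }
})

test_that("the literal asymmetric variant differs and weights the first pair", {
  pops <- c("a", "b", "c", "d")
  tm <- matrix(0, 4, 4, dimnames = list(pops, pops))
  tm[upper.tri(tm)] <- c(1, 0.2, 0.3, 0.1, 0.2, 0.4)
  tm <- tm + t(tm)
  lit <- mpbs(tm, "a", literal = TRUE)
  expect_equal(lit, (2 * tm["a", "b"] + tm["a", "c"] + tm["a", "d"] -
                       tm["b", "c"] - tm["b", "d"] - tm["c", "d"]) / 6)
  expect_false(isTRUE(all.equal(lit, mpbs(tm, "a"))))
})

test_that("mpbs_track needs exactly four populations and flags sparse windows", {
  gm3 <- toy_gm(matrix(c(0L, 1L, 2L), 1), pops = c("a", "b", "c"))
  expect_error(mpbs_track(gm3, windows = data.frame(scaffold = "s1",
                                                    start = 0, end = 100)),
               "four populations")
  set.seed(2)
  g <- matrix(sample(0:2, 8 * 5, TRUE), 5)
  gm <- toy_gm(g, pops = rep(c("a", "b", "c", "d"), each = 2))
  tr <- mpbs_track(gm, windows = data.frame(scaffold = "s1", start = 0,
                                            end = 1000), min_sites = 10)
  expect_true(all(is.na(tr[1, grep("^mpbs_", names(tr))])))
})

test_that("exchangeable demes give statistically equal per-population mPBS", {
  m <- symmetric_four_pop_model(n_dip = 2, mu = 5e-8)
  null <- null_mpbs_distribution(m, n_windows = 400, window_length = 20000,
                                 seed = 19, min_sites = 5)
  v <- null$values
  mu_ <- colMeans(v, na.rm = TRUE)
  se_ <- apply(v, 2, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(mu_[i] - mu_[j]), 2 * sqrt(se_[i]^2 + se_[j]^2) + 1e-9)
})

test_that("null distributions are reproducible and respond to deme size", {
  m <- symmetric_four_pop_model(n_dip = 2, mu = 5e-8)
  n1 <- null_mpbs_distribution(m, 60, 20000, seed = 4, min_sites = 5)
  n2 <- null_mpbs_distribution(m, 60, 20000, seed = 4, min_sites = 5)
  expect_identical(n1$values, n2$values)
  shrunk <- set_model_param(m, "populations.P2.diploid_size", 200)
  n3 <- null_mpbs_distribution(shrunk, 150, 20000, seed = 4, min_sites = 5)
  n1b <- null_mpbs_distribution(m, 150, 20000, seed = 4, min_sites = 5)
  expect_gt(mean(n3$values[, "P2"], na.rm = TRUE),
            mean(n1b$values[, "P2"], na.rm = TRUE))
})

test_that("permutation KS matches classical KS on clean data and handles ties", {
  set.seed(6)
  x <- rnorm(120); y <- rnorm(150)
  pk <- ks_permutation_test(x, y, n_perm = 600, seed = 2)
  cl <- ks.test(x, y)
  expect_equal(pk$statistic, unname(cl$statistic), tolerance = 1e-12)
  expect_lt(abs(pk$p_value - cl$p.value), 0.12)
  # genuine shift is detected
  expect_lt(ks_permutation_test(x, x + 1, n_perm = 600, seed = 2)$p_value, 0.01)
  # heavy ties (atoms at zero) do not break it
  xt <- c(rep(0, 60), rexp(60)); yt <- c(rep(0, 80), rexp(80))
  pt <- ks_permutation_test(xt, yt, n_perm = 300, seed = 3)
  expect_gt(pt$p_value, 0.05)
  expect_identical(pt, ks_permutation_test(xt, yt, n_perm = 300, seed = 3))
})

test_that("outlier extraction obeys the count and tie rules", {
  mk_track <- function(v) data.frame(scaffold = rep("s", length(v)),
                                     start = seq_along(v),
                                     end = seq_along(v) + 1, mpbs_X = v)
  set.seed(3)
  v <- runif(10000)
  out <- outlier_windows(mk_track(v), 0.001, "X")
  expect_equal(nrow(out), 10L)
  # all-equal values: everything is tied at the threshold
  out_tie <- outlier_windows(mk_track(rep(1, 50)), 0.1, "X")
  expect_equal(nrow(out_tie), 50L)
  # missing values drop out of numerator and denominator
  v2 <- c(rep(NA, 5000), v)
  out2 <- outlier_windows(mk_track(v2), 0.001, "X")
  expect_equal(nrow(out2), 10L)
  expect_equal(sort(out2$mpbs_X), sort(out$mpbs_X))
  expect_equal(nrow(outlier_windows(mk_track(numeric(0)), 0.001, "X")), 0L)
})
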