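#' Per-population allele counts (internal)
#'
#' @return list with `ac` (alt allele count) and `an` (called allele
#'   count), each sites x populations.
#' @noRd
pop_allele_counts <- function(gm, populations = NULL) {
  pops <- populations %||% sort(unique(gm$populations))
  ac <- do.call(cbind, lapply(pops, function(p) {
    g <- gm$geno[, gm$populations == p, drop = FALSE]
    rowSums(g, na.rm = TRUE)
  }))
  an <- do.call(cbind, lapply(pops, function(p) {
    g <- gm$geno[, gm$populations == p, drop = FALSE]
    2L * rowSums(!is.na(g))
  }))
  colnames(ac) <- colnames(an) <- pops
  list(ac = ac, an = an)
}

#' Per-site Hudson FST components (internal)
#'
#' Numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)` per site. Sites with fewer than two
#' called alleles in either population, or monomorphic across both
#' populations (0/0), are flagged unusable.
#' @noRd
hudson_components <- function(ac1, an1, ac2, an2) {
  ok <- an1 >= 2L & an2 >= 2L
  p1 <- ifelse(ok, ac1 / an1, NA_real_)
  p2 <- ifelse(ok, ac2 / an2, NA_real_)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  usable <- ok & !(den == 0 & num == 0)
  num[!usable] <- 0; den[!usable] <- 0
  list(num = num, den = den, usable = usable)
}

#' Windowed Hudson FST for one population pair
#'
#' The window estimate is a ratio of sums: per-site numerators and
#' denominators of Hudson's estimator are summed over usable sites in the
#' window and divided once (not a mean of per-site ratios). Negative
#' estimates are legal. The estimate is `NA` when fewer than `min_sites`
#' usable sites fall in the window or the summed denominator is zero.
#'
#' @param gm a [genotype_matrix()].
#' @param pair character vector of two population labels.
#' @param window single-row data.frame or list with `scaffold`, `start`,
#'   `end` (0-based half-open); `NULL` uses all sites.
#' @param min_sites minimum usable sites; default 10.
#' @return data.frame with `scaffold`, `start`, `end`, `pop1`, `pop2`,
#'   `fst`, `n_sites`.
#' @export
hudson_fst <- function(gm, pair, window = NULL, min_sites = 10) {
  stopifnot(length(pair) == 2L, all(pair %in% gm$populations))
  if (is.null(window))
    window <- list(scaffold = NA_character_, start = 0,
                   end = max(gm$scaffolds$length))
  keep <- if (is.na(window$scaffold)) rep(TRUE, n_sites(gm))
          else gm$sites$scaffold == window$scaffold &
               gm$sites$pos >= window$start & gm$sites$pos < window$end
  sub <- subset_sites(gm, keep)
  cc <- pop_allele_counts(sub, pair)
  h <- hudson_components(cc$ac[, 1L], cc$an[, 1L], cc$ac[, 2L], cc$an[, 2L])
  ns <- sum(h$usable)
  den <- sum(h$den)
  fst <- if (ns < min_sites || den == 0) NA_real_ else sum(h$num) / den
  data.frame(scaffold = window$scaffold, start = window$start,
             end = window$end, pop1 = pair[1L], pop2 = pair[2L],
             fst = fst, n_sites = ns, stringsAsFactors = FALSE)
}

#' Transform FST to branch time
#'
#' `T = -log(1 - FST)`, the divergence time in drift units between two
#' populations. Negative FST estimates are clamped to 0 before the
#' transform so that T >= 0; FST of exactly 1 yields `NA` (non-finite,
#' propagated as missing downstream).
#'
#' @param fst numeric vector of FST values (<= 1).
#' @return numeric vector of branch times.
#' @export
fst_to_time <- function(fst) {
  if (any(fst > 1, na.rm = TRUE)) stop("FST must be <= 1", call. = FALSE)
  t <- -log(1 - pmax(fst, 0))
  t[is.infinite(t)] <- NA_real_
  t
}

#' Metapopulation branch statistic for one focal population
#'
#' For four populations that each diverged independently from a shared
#' metapopulation, the focal population's terminal branch length is
#' estimated as the mean of the three classic three-population PBS values
#' over the three choices of non-focal pair:
#' `mPBS_a = [2(T_ab + T_ac + T_ad) - (T_bc + T_bd + T_cd)] / 6`.
#' This form is symmetric in the non-focal labels and recovers terminal
#' branch lengths exactly on additive T matrices. `literal = TRUE` computes
#' the asymmetric variant `(2 T_ab + T_ac + T_ad - T_bc - T_bd - T_cd) / 6`
#' (non-focal labels in their matrix order) for comparison.
#'
#' @param t_matrix symmetric 4x4 numeric matrix of pairwise branch times
#'   with population names as dimnames.
#' @param focal focal population label.
#' @param literal use the asymmetric literal variant.
#' @return the mPBS value (`NA` if any needed T is missing).
#' @export
mpbs <- function(t_matrix, focal, literal = FALSE) {
  stopifnot(is.matrix(t_matrix), nrow(t_matrix) == 4L, ncol(t_matrix) == 4L,
            !is.null(rownames(t_matrix)))
  pops <- rownames(t_matrix)
  stopifnot(focal %in% pops)
  others <- setdiff(pops, focal)
  t_focal <- t_matrix[focal, others]
  t_cross <- c(t_matrix[others[1L], others[2L]],
               t_matrix[others[1L], others[3L]],
               t_matrix[others[2L], others[3L]])
  if (anyNA(c(t_focal, t_cross))) return(NA_real_)
  if (literal)
    unname(2 * t_focal[1L] + t_focal[2L] + t_focal[3L] - sum(t_cross)) / 6
  else
    (2 * sum(t_focal) - sum(t_cross)) / 6
}

pair_labels <- function(pops) {
  cmb <- utils::combn(pops, 2L)
  sprintf("%s_%s", cmb[1L, ], cmb[2L, ])
}

#' Windowed mPBS track over four populations
#'
#' Per window: six pairwise windowed Hudson FST estimates (ratio of sums),
#' transformed to branch times `T = -log(1 - FST)`, then the four
#' per-population mPBS values. Any missing component (too few sites, zero
#' denominator, FST = 1) propagates to a missing record.
#'
#' @param gm a [genotype_matrix()].
#' @param populations exactly four population labels.
#' @param windows data.frame from [tile_windows()] (columns `scaffold`,
#'   `start`, `end`).
#' @param min_sites minimum usable sites per window per pair; default 10.
#' @return data.frame with the window columns, per-pair `fst_*`, `t_*` and
#'   `nsites_*` columns, and per-population `mpbs_*` columns.
#' @export
mpbs_track <- function(gm, populations = sort(unique(gm$populations)),
                       windows, min_sites = 10) {
  if (length(populations) != 4L)
    stop("mPBS is defined for exactly four populations (got ",
         length(populations), ")", call. = FALSE)
  stopifnot(all(populations %in% gm$populations))
  cc <- pop_allele_counts(gm, populations)
  cmb <- utils::combn(populations, 2L)
  n_pair <- ncol(cmb)

  out <- windows[, c("scaffold", "start", "end")]
  fst_m <- matrix(NA_real_, nrow(windows), n_pair)
  ns_m <- matrix(0L, nrow(windows), n_pair)

  for (k in seq_len(n_pair)) {
    h <- hudson_components(cc$ac[, cmb[1L, k]], cc$an[, cmb[1L, k]],
                           cc$ac[, cmb[2L, k]], cc$an[, cmb[2L, k]])
    for (sc in unique(windows$scaffold)) {
      wi <- which(windows$scaffold == sc)
      si <- which(gm$sites$scaffold == sc)
      pos <- gm$sites$pos[si]
      cn <- c(0, cumsum(h$num[si]))
      cd <- c(0, cumsum(h$den[si]))
      cu <- c(0, cumsum(as.integer(h$usable[si])))
      lo <- findInterval(windows$start[wi] - 0.5, pos) + 1L
      hi <- findInterval(windows$end[wi] - 0.5, pos) + 1L
      ns <- cu[hi] - cu[lo]
      den <- cd[hi] - cd[lo]
      num <- cn[hi] - cn[lo]
      fst <- ifelse(ns < min_sites | den == 0, NA_real_, num / den)
      fst_m[wi, k] <- fst
      ns_m[wi, k] <- ns
    }
  }
  t_m <- matrix(fst_to_time(fst_m), nrow(windows), n_pair)

  labs <- pair_labels(populations)
  colnames(fst_m) <- paste0("fst_", labs)
  colnames(t_m) <- paste0("t_", labs)
  colnames(ns_m) <- paste0("nsites_", labs)

  mpbs_m <- matrix(NA_real_, nrow(windows), 4L,
                   dimnames = list(NULL, paste0("mpbs_", populations)))
  for (a in seq_len(4L)) {
    focal <- populations[a]
    is_focal <- cmb[1L, ] == focal | cmb[2L, ] == focal
    mpbs_m[, a] <- (2 * rowSums(t_m[, is_focal, drop = FALSE]) -
                      rowSums(t_m[, !is_focal, drop = FALSE])) / 6
  }
  cbind(out, as.data.frame(fst_m), as.data.frame(t_m), as.data.frame(ns_m),
        as.data.frame(mpbs_m))
}

#' Neutral mPBS null distribution from coalescent simulation
#'
#' Simulates `n_windows` independent windows under the model
#' ([simulate_null_windows()]) and computes the four per-population mPBS
#' values of each window exactly as for observed data (whole-window Hudson
#' FST, ratio of sums). Full-scale nulls (1e6 windows) are supported; the
#' desk-scale default is 1e4.
#'
#' @inheritParams simulate_null_windows
#' @param min_sites minimum usable sites per pair per window.
#' @param n_recomb_blocks independent genealogy blocks per window (match
#'   the treatment of the observed data; default 1 = fully linked).
#' @param probs quantiles to summarise; default includes the 0.999 tail.
#' @return an `mpbs_null`: list with `values` (windows x populations matrix,
#'   `NA` for missing records), `quantiles`, `populations`, `n_windows`,
#'   `seed`.
#' @export
null_mpbs_distribution <- function(model, n_windows = 1e4, window_length,
                                   seed, min_sites = 10, n_recomb_blocks = 1L,
                                   probs = c(0.5, 0.9, 0.99, 0.999)) {
  stopifnot(n_windows >= 1)
  pops <- sort(vapply(Filter(function(p) p$sample_size > 0, all_demes(model)),
                      `[[`, "", "name"))
  if (length(pops) != 4L)
    stop("mPBS null requires a model sampling exactly four populations",
         call. = FALSE)
  seeds <- derive_seeds(seed, n_windows)
  vals <- matrix(NA_real_, n_windows, 4L, dimnames = list(NULL, pops))
  win <- NULL
  for (i in seq_len(n_windows)) {
    sw <- simulate_window(model, window_length, seeds[i], n_recomb_blocks)
    gm <- sw$genotypes
    if (is.null(win))
      win <- data.frame(scaffold = "sim", start = 0, end = window_length)
    tr <- mpbs_track(gm, pops, win, min_sites = min_sites)
    vals[i, ] <- as.numeric(tr[1L, paste0("mpbs_", pops)])
  }
  qs <- apply(vals, 2L, quantile, probs = probs, na.rm = TRUE)
  structure(list(values = vals, quantiles = qs, populations = pops,
                 n_windows = n_windows, window_length = window_length,
                 seed = as.integer(seed)),
            class = "mpbs_null")
}

#' @export
print.mpbs_null <- function(x, ...) {
  cat(sprintf("mpbs_null: %d window(s) of %g bp, populations %s\n",
              x$n_windows, x$window_length,
              paste(x$populations, collapse = ", ")))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' Permutation Kolmogorov-Smirnov comparison
#'
#' Two-sample KS test with the reference distribution of the D statistic
#' obtained by permuting the pooled sample, which keeps the p-value valid
#' in the presence of ties (windowed mPBS can carry ties: the FST-to-time
#' clamp maps every all-negative-FST window to exactly zero, a regime where
#' the classical KS p-value is not guaranteed). Deterministic given `seed`.
#'
#' @param x,y numeric samples (`NA` dropped).
#' @param n_perm number of permutations; default 500.
#' @param seed integer seed for the permutations.
#' @return list with `statistic` (D) and `p_value`
#'   (`(1 + #\{D* >= D\}) / (n_perm + 1)`).
#' @export
ks_permutation_test <- function(x, y, n_perm = 500, seed = 1L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  ks_d <- function(a, b) {
    w <- c(a, b)
    ord <- order(w)
    z <- cumsum(ifelse(ord <= length(a), 1 / length(a), -1 / length(b)))
    sw <- w[ord]
    # evaluate only where the pooled value changes (tie-safe)
    at <- c(sw[-1] != sw[-length(sw)], TRUE)
    max(abs(z[at]))
  }
  d_obs <- ks_d(x, y)
  pooled <- c(x, y)
  n_x <- length(x)
  exceed <- with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n_x)
      ks_d(pooled[idx], pooled[-idx]) >= d_obs - 1e-12
    }, NA))
  })
  list(statistic = d_obs, p_value = (1 + exceed) / (n_perm + 1))
}

#' Extract top-fraction outlier windows
#'
#' Returns the `ceiling(top_fraction * n_nonmissing)` windows with the
#' highest mPBS for the focal population; windows tied with the threshold
#' value are all included. Missing windows are excluded from both the
#' numerator and the denominator.
#'
#' @param track data.frame from [mpbs_track()].
#' @param top_fraction upper tail fraction; default 0.001 (top 0.1%).
#' @param population focal population label.
#' @return the outlier rows of `track`, ordered by decreasing mPBS.
#' @export
outlier_windows <- function(track, top_fraction = 0.001, population) {
  col <- paste0("mpbs_", population)
  if (!col %in% names(track))
    stop("no mPBS column for population '", population, "'", call. = FALSE)
  v <- track[[col]]
  ok <- !is.na(v)
  n <- sum(ok)
  if (n == 0L) return(track[integer(0), , drop = FALSE])
  k <- ceiling(top_fraction * n)
  thr <- sort(v[ok], decreasing = TRUE)[k]
  out <- track[ok & v >= thr, , drop = FALSE]
  out[order(out[[col]], decreasing = TRUE), , drop = FALSE]
}
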