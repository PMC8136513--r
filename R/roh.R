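#' Detect runs of homozygosity for one individual
#'
#' Transparent sliding-window rule over the individual's called sites on
#' each scaffold: an interval of consecutive sites qualifies when every
#' `window_sites`-site sub-window inside it contains at most
#' `max_het_per_window` heterozygous calls (intervals shorter than
#' `window_sites` qualify when their total heterozygote count is within the
#' limit). Maximal qualifying intervals are merged where they overlap (so
#' segments are disjoint) and become segments spanning
#' `[first site, last site + 1)`; segments shorter than `min_length` bp or
#' supported by fewer than `min_sites_per_run` homozygous sites are
#' dropped. Deterministic; missing calls are ignored. Absolute ROH calls
#' are method-dependent — see the methods vignette.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_id sample to scan.
#' @param max_het_per_window maximum heterozygous calls per site window;
#'   default 1.
#' @param window_sites sites per window; default 50.
#' @param min_length minimum segment span in bp; default 10 kb.
#' @param min_sites_per_run minimum supporting homozygous sites; default 25.
#' @return data.frame with columns `sample_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `n_sites`.
#' @export
detect_roh <- function(gm, sample_id, max_het_per_window = 1,
                       window_sites = 50, min_length = 10000,
                       min_sites_per_run = 25) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(sample_id, gm$sample_ids)
  if (is.na(j)) stop("no sample '", sample_id, "'", call. = FALSE)
  out <- list()
  for (sc in gm$scaffolds$name) {
    si <- which(gm$sites$scaffold == sc & !is.na(gm$geno[, j]))
    if (length(si) < 2L) next
    pos <- gm$sites$pos[si]
    het <- gm$geno[si, j] == 1L
    runs <- maximal_qualifying_runs(het, window_sites, max_het_per_window)
    if (!nrow(runs)) next
    seg <- data.frame(sample_id = sample_id, scaffold = sc,
                      start = pos[runs$from], end = pos[runs$to] + 1L,
                      n_sites = runs$n_hom, stringsAsFactors = FALSE)
    seg <- seg[seg$end - seg$start >= min_length &
                 seg$n_sites >= min_sites_per_run, , drop = FALSE]
    out[[sc]] <- seg
  }
  if (!length(out))
    return(data.frame(sample_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Two-pointer enumeration of maximal qualifying site intervals.
# Qualifying is hereditary (every sub-interval of a qualifying interval
# qualifies), so the right frontier j is monotone in the left end i and an
# interval [i, f(i)] is maximal exactly when its frontier advances past all
# previously recorded ones. Extension from [i, j] to [i, j+1] only needs
# the newest constraint: the total-het rule while the interval is shorter
# than window_sites, the window ending at j+1 afterwards (earlier windows
# were checked when the frontier first reached their right edge).
maximal_qualifying_runs <- function(het, window_sites, max_het) {
  n <- length(het)
  chet <- c(0L, cumsum(het))
  win_het <- function(i, j) chet[j + 1L] - chet[i]   # hets in sites i..j
  from <- integer(0); to <- integer(0)
  j <- 0L; last_to <- 0L
  for (i in seq_len(n)) {
    if (j < i - 1L) j <- i - 1L
    repeat {
      if (j >= n) break
      len <- j + 2L - i
      ok <- if (len <= window_sites) win_het(i, j + 1L) <= max_het
            else win_het(j + 2L - window_sites, j + 1L) <= max_het
      if (!ok) break
      j <- j + 1L
    }
    if (j >= i && j > last_to) {
      from <- c(from, i); to <- c(to, j)
      last_to <- j
    }
  }
  # merge overlapping maximal runs: segments must be disjoint, and merging
  # keeps detection monotone in max_het (the union of qualifying intervals
  # only grows as the limit is relaxed)
  if (length(from) > 1L) {
    keep_from <- from[1L]; keep_to <- to[1L]
    for (k in 2L:length(from)) {
      if (from[k] <= keep_to[length(keep_to)]) {
        keep_to[length(keep_to)] <- max(keep_to[length(keep_to)], to[k])
      } else {
        keep_from <- c(keep_from, from[k]); keep_to <- c(keep_to, to[k])
      }
    }
    from <- keep_from; to <- keep_to
  }
  data.frame(from = from, to = to,
             n_hom = (to - from + 1L) - (chet[to + 1L] - chet[from]))
}

#' Classify ROH segments into length classes
#'
#' Length classes follow the standard reporting convention: detection
#' classes `[10-100 kb)`, `[100 kb-1 Mb)`, `>= 1 Mb`, plus the reporting
#' split `[1-2 Mb)` / `>= 2 Mb` and the total `>= 100 kb`. Proportions use
#' the subtraction-denominator convention: the `>= 1 Mb` proportion divides
#' by the full autosome length, the `[100 kb-1 Mb)` proportion divides by
#' the autosome length minus the `>= 1 Mb` total, and the `[10-100 kb)`
#' proportion divides by the autosome length minus the `>= 100 kb` total.
#'
#' @param segments data.frame from [detect_roh()] for one individual;
#'   segments must not overlap within a scaffold.
#' @param autosome_length total autosomal length in bp (> 0).
#' @return a `roh_summary`: list with `sample_id`, `class_lengths`,
#'   `class_proportions`, `reporting_lengths` and `autosome_length`.
#' @export
classify_roh <- function(segments, autosome_length) {
  stopifnot(autosome_length > 0)
  if (nrow(segments)) {
    if (length(unique(segments$sample_id)) > 1L)
      stop("classify_roh() summarises one individual at a time", call. = FALSE)
    for (sc in unique(segments$scaffold)) {
      s <- segments[segments$scaffold == sc, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
        stop("overlapping ROH segments on scaffold ", sc,
             " (upstream detection bug)", call. = FALSE)
    }
  }
  len <- if (nrow(segments)) segments$end - segments$start else numeric(0)
  L <- function(lo, hi = Inf) sum(len[len >= lo & len < hi])
  class_lengths <- c(
    kb10_100 = L(1e4, 1e5),
    kb100_1Mb = L(1e5, 1e6),
    Mb1_plus = L(1e6)
  )
  class_proportions <- c(
    Mb1_plus = class_lengths[["Mb1_plus"]] / autosome_length,
    kb100_1Mb = class_lengths[["kb100_1Mb"]] /
      (autosome_length - class_lengths[["Mb1_plus"]]),
    kb10_100 = class_lengths[["kb10_100"]] /
      (autosome_length - class_lengths[["Mb1_plus"]] -
         class_lengths[["kb100_1Mb"]])
  )
  reporting_lengths <- c(
    Mb2_plus = L(2e6),
    Mb1_2 = L(1e6, 2e6),
    kb100_1Mb = L(1e5, 1e6),
    total_100kb_plus = L(1e5)
  )
  structure(list(sample_id = if (nrow(segments)) segments$sample_id[1L] else NA_character_,
                 class_lengths = class_lengths,
                 class_proportions = class_proportions,
                 reporting_lengths = reporting_lengths,
                 autosome_length = autosome_length),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("roh_summary for", x$sample_id, "\n")
  cat(sprintf("  [10-100 kb): %g bp (prop %.3g)\n",
              x$class_lengths[["kb10_100"]], x$class_proportions[["kb10_100"]]))
  cat(sprintf("  [100 kb-1 Mb): %g bp (prop %.3g)\n",
              x$class_lengths[["kb100_1Mb"]], x$class_proportions[["kb100_1Mb"]]))
  cat(sprintf("  >= 1 Mb: %g bp (prop %.3g)\n",
              x$class_lengths[["Mb1_plus"]], x$class_proportions[["Mb1_plus"]]))
  cat(sprintf("  reporting: >=2 Mb %g | 1-2 Mb %g | total >=100 kb %g\n",
              x$reporting_lengths[["Mb2_plus"]], x$reporting_lengths[["Mb1_2"]],
              x$reporting_lengths[["total_100kb_plus"]]))
  invisible(x)
}

#' Write per-individual ROH summaries as TSV
#'
#' One row per individual: length-class totals (bp) and the
#' subtraction-denominator proportions.
#'
#' @param summaries a `roh_summary` or list of them.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_roh_summary_tsv <- function(summaries, path) {
  if (inherits(summaries, "roh_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, function(s) data.frame(
    sample_id = s$sample_id,
    len_10_100kb = s$class_lengths[["kb10_100"]],
    len_100kb_1mb = s$class_lengths[["kb100_1Mb"]],
    len_over_1mb = s$class_lengths[["Mb1_plus"]],
    prop_10_100kb = s$class_proportions[["kb10_100"]],
    prop_100kb_1mb = s$class_proportions[["kb100_1Mb"]],
    prop_over_1mb = s$class_proportions[["Mb1_plus"]],
    len_over_2mb = s$reporting_lengths[["Mb2_plus"]],
    len_1_2mb = s$reporting_lengths[["Mb1_2"]],
    len_total_over_100kb = s$reporting_lengths[["total_100kb_plus"]],
    autosome_length = s$autosome_length,
    stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROH segments as BED
#' @param segments data.frame from [detect_roh()].
#' @param path output BED file.
#' @export
write_roh_bed <- function(segments, path) {
  df <- data.frame(segments$scaffold, as.integer(segments$start),
                   as.integer(segments$end), segments$sample_id,
                   segments$n_sites)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
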