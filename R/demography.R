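#' Joint (folded) site frequency spectrum from genotypes
#'
#' Counts polymorphic sites by their per-population allele-count cell. With
#' `folded = TRUE` (the default; no outgroup polarization assumed) the cell
#' `(d_1, ..., d_k)` is identified with its complement
#' `(n_1 - d_1, ..., n_k - d_k)` and the representative with the smaller
#' total count (ties broken lexicographically) is kept, so the spectrum is
#' invariant under allele relabeling. Monomorphic sites are excluded from
#' the cells but retained in `n_sites_total`.
#'
#' @param gm a [genotype_matrix()] with no missing genotypes at counted
#'   sites (apply `require_complete` filtering upstream).
#' @param populations population labels to include (each must have >= 1
#'   sample).
#' @param folded fold to minor-allele counts (default TRUE).
#' @return a `folded_sfs`: list with `populations`, `sample_sizes` (alleles
#'   per population), `cells` (named integer vector, names are
#'   comma-separated allele counts), `n_sites_total`, `folded`.
#' @export
sfs_from_genotypes <- function(gm, populations = sort(unique(gm$populations)),
                               folded = TRUE) {
  for (p in populations)
    if (!any(gm$populations == p))
      stop("population with zero samples: ", p, call. = FALSE)
  sub_cols <- gm$populations %in% populations
  if (anyNA(gm$geno[, sub_cols]))
    stop("missing genotypes; filter with require_complete first", call. = FALSE)
  cc <- pop_allele_counts(gm, populations)
  n_al <- vapply(populations, function(p) 2L * sum(gm$populations == p), 0L)
  d <- cc$ac
  mono <- rowSums(d) == 0L | rowSums(sweep(d, 2L, n_al)) == 0L
  cells <- sfs_cell_names(d[!mono, , drop = FALSE], n_al, folded)
  tab <- table(cells)
  structure(list(populations = populations, sample_sizes = n_al,
                 cells = setNames(as.integer(tab), names(tab)),
                 n_sites_total = n_sites(gm), folded = folded),
            class = "folded_sfs")
}

# canonical cell name per site; d = sites x pops allele counts
sfs_cell_names <- function(d, n_al, folded) {
  if (nrow(d) == 0L) return(character(0))
  if (folded) {
    comp <- sweep(-d, 2L, n_al, "+")
    tot_d <- rowSums(d); tot_c <- rowSums(comp)
    use_comp <- tot_c < tot_d
    tie <- tot_c == tot_d
    if (any(tie)) {
      for (j in seq_len(ncol(d))) {
        undec <- tie & d[, j] != comp[, j]
        use_comp[undec] <- comp[undec, j] < d[undec, j]
        tie <- tie & !undec
      }
    }
    d[use_comp, ] <- comp[use_comp, ]
  }
  apply(d, 1L, paste, collapse = ",")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("%s_sfs over %s (%s alleles): %d polymorphic cell(s), %d site(s) total\n",
              if (x$folded) "folded" else "unfolded",
              paste(x$populations, collapse = ","),
              paste(x$sample_sizes, collapse = ","),
              length(x$cells), x$n_sites_total))
  invisible(x)
}

#' Write / read an SFS as TSV
#' @param sfs a `folded_sfs`.
#' @param path output file.
#' @export
write_sfs_tsv <- function(sfs, path) {
  cellmat <- do.call(rbind, strsplit(names(sfs$cells), ","))
  df <- as.data.frame(cellmat, stringsAsFactors = FALSE)
  names(df) <- sfs$populations
  df$count <- as.integer(sfs$cells)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# populations: %s", paste(sfs$populations, collapse = ",")),
               sprintf("# sample_sizes: %s", paste(sfs$sample_sizes, collapse = ",")),
               sprintf("# n_sites_total: %d", sfs$n_sites_total),
               sprintf("# folded: %s", sfs$folded)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate the polymorphic cell universe for given sample sizes (internal)
#' @noRd
sfs_cell_universe <- function(n_al, folded) {
  grid <- as.matrix(expand.grid(lapply(n_al, function(n) 0:n)))
  mono <- rowSums(grid) == 0L | rowSums(sweep(grid, 2L, n_al)) == 0L
  grid <- grid[!mono, , drop = FALSE]
  unique(sfs_cell_names(grid, n_al, folded))
}

#' Monte-Carlo expected SFS cell probabilities under a model
#'
#' Simulates windows under the model, accumulates the joint SFS of all
#' segregating sites, and normalizes to cell probabilities over the
#' polymorphic-cell universe. Cells with zero simulated mass are floored at
#' `epsilon` (default `1 / (10 * n_replicates)`) and the vector is
#' renormalized, the standard stabilization for simulation-based composite
#' likelihoods.
#'
#' @param model a [demographic_model()].
#' @param n_replicates simulated windows (>= 1,000 recommended for fitting).
#' @param seed master seed (common random numbers: a fitting routine passes
#'   the same seed for every parameter evaluation).
#' @param window_length bp per simulated window; default 50 kb.
#' @param folded fold the spectrum (default TRUE).
#' @param epsilon floor for empty cells; `NULL` for the default.
#' @return an `sfs_probs`: named probability vector over polymorphic cells
#'   with attributes `populations`, `sample_sizes`, `n_replicates`,
#'   `n_polymorphic_sites`.
#' @export
expected_sfs <- function(model, n_replicates, seed, window_length = 50000,
                         folded = TRUE, epsilon = NULL) {
  stopifnot(n_replicates >= 1)
  cd <- compile_demes(model)
  sampled <- cd$demes$sample_size > 0
  pops <- sort(cd$demes$name[sampled])
  n_al <- 2L * cd$demes$sample_size[sampled][order(cd$demes$name[sampled])]
  universe <- sfs_cell_universe(n_al, folded)
  counts <- setNames(numeric(length(universe)), universe)

  seeds <- derive_seeds(seed, n_replicates)
  for (i in seq_len(n_replicates)) {
    gm <- simulate_window(model, window_length, seeds[i])$genotypes
    if (n_sites(gm) == 0L) next
    cc <- pop_allele_counts(gm, pops)
    nm <- sfs_cell_names(cc$ac, n_al, folded)
    tab <- table(nm)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  total <- sum(counts)
  if (total == 0) stop("no polymorphic sites simulated; increase n_replicates or mutation rate",
                       call. = FALSE)
  probs <- counts / total
  eps <- epsilon %||% (1 / (10 * n_replicates))
  zero <- probs == 0
  if (any(zero)) {
    probs[zero] <- eps
    probs <- probs / sum(probs)
  }
  attr(probs, "populations") <- pops
  attr(probs, "sample_sizes") <- n_al
  attr(probs, "n_replicates") <- n_replicates
  attr(probs, "n_polymorphic_sites") <- total
  class(probs) <- "sfs_probs"
  probs
}

#' Composite log-likelihood of an observed SFS
#'
#' `CL = sum_i m_i log(p_i)` with observed cell counts `m_i` and expected
#' cell probabilities `p_i` renormalized over the polymorphic cells, the
#' multinomial composite likelihood treating sites as independent.
#'
#' @param obs a `folded_sfs` (from [sfs_from_genotypes()]).
#' @param probs an `sfs_probs` (from [expected_sfs()]) or any named
#'   probability vector covering the observed cells.
#' @return the composite log-likelihood (natural log).
#' @export
composite_log_likelihood <- function(obs, probs) {
  p <- unclass(probs)
  p <- p / sum(p)
  missing_cells <- setdiff(names(obs$cells), names(p))
  if (length(missing_cells))
    stop("observed SFS cells absent from the expected probabilities ",
         "(after flooring): ", paste(head(missing_cells, 5), collapse = "; "),
         call. = FALSE)
  pe <- p[names(obs$cells)]
  if (any(pe <= 0))
    stop("zero expected probability on an observed cell", call. = FALSE)
  sum(obs$cells * log(pe))
}

#' Fit demographic parameters by composite likelihood
#'
#' Maximizes [composite_log_likelihood()] over a small set of free
#' parameters using derivative-free search with common random numbers (the
#' same simulation seed at every evaluation, so the objective surface is
#' deterministic). One free parameter uses golden-section search within its
#' bounds; several use Nelder-Mead with `n_restarts` seeded starting
#' points and out-of-bounds penalties. Supports a two-stage protocol: fit a
#' stage-1 model, freeze its estimates into the template, then fit the
#' stage-2 parameters of a nested-subpopulation model.
#'
#' @param obs observed `folded_sfs`.
#' @param model_template a [demographic_model()]; fixed parameters are
#'   taken from it.
#' @param free_parameters character vector of parameter addresses (see
#'   [set_model_param()]); length 0 evaluates the template only.
#' @param bounds named list of `c(lower, upper)` per free parameter.
#' @param seed master seed (also the common-random-numbers seed).
#' @param n_replicates simulated windows per evaluation (default 1,000).
#' @param window_length bp per simulated window.
#' @param n_restarts Nelder-Mead restarts when more than one parameter is
#'   free.
#' @param mask_singletons drop singleton cells (total minor-allele count 1)
#'   from both the observed spectrum and the expected probabilities before
#'   computing the likelihood, a standard robustness check against
#'   low-frequency genotyping error.
#' @return a `composite_fit_result`: list with `parameter_estimates`,
#'   `log_composite_likelihood`, `n_evaluations`, `at_bound`, `model`.
#' @export
fit_parameters <- function(obs, model_template, free_parameters, bounds,
                           seed, n_replicates = 1000, window_length = 50000,
                           n_restarts = 5, mask_singletons = FALSE) {
  stopifnot(inherits(obs, "folded_sfs"))
  validate_model(model_template)
  free_parameters <- as.character(free_parameters)
  n_free <- length(free_parameters)
  if (n_free > 0) {
    stopifnot(all(free_parameters %in% names(bounds)))
    for (b in bounds[free_parameters])
      if (length(b) != 2L || !all(is.finite(b)) || b[1L] >= b[2L])
        stop("each bound must be a finite c(lower, upper)", call. = FALSE)
  }
  if (mask_singletons) obs <- drop_singleton_cells(obs)
  n_eval <- 0L
  eval_cl <- function(theta) {
    m <- model_template
    for (j in seq_len(n_free))
      m <- set_model_param(m, free_parameters[j], theta[j])
    probs <- expected_sfs(m, n_replicates, seed = seed,
                          window_length = window_length, folded = obs$folded)
    if (mask_singletons) {
      keep <- !cell_is_singleton(names(probs))
      att <- attributes(probs)
      probs <- unclass(probs)[keep]
      probs <- probs / sum(probs)
      attr(probs, "populations") <- att$populations
    }
    n_eval <<- n_eval + 1L
    cl <- composite_log_likelihood(obs, probs)
    if (!is.finite(cl)) stop("non-finite composite likelihood", call. = FALSE)
    cl
  }

  if (n_free == 0L) {
    cl <- eval_cl(numeric(0))
    return(structure(list(parameter_estimates = numeric(0),
                          log_composite_likelihood = cl,
                          n_evaluations = n_eval, at_bound = logical(0),
                          model = model_template),
                     class = "composite_fit_result"))
  }

  lo <- vapply(bounds[free_parameters], `[[`, 0, 1L)
  hi <- vapply(bounds[free_parameters], `[[`, 0, 2L)
  if (n_free == 1L) {
    opt <- optimize(function(x) eval_cl(x), lower = lo, upper = hi,
                    maximum = TRUE, tol = (hi - lo) * 1e-3)
    est <- opt$maximum; cl <- opt$objective
  } else {
    pen_obj <- function(theta) {
      if (any(theta < lo) || any(theta > hi))
        return(1e12 + sum(pmax(lo - theta, 0) + pmax(theta - hi, 0)))
      -eval_cl(theta)
    }
    starts <- with_seed(as.integer(seed) + 1L, {
      lapply(seq_len(n_restarts), function(i)
        lo + runif(n_free) * (hi - lo))
    })
    best <- NULL
    for (s in starts) {
      o <- optim(s, pen_obj, method = "Nelder-Mead",
                 control = list(maxit = 200))
      if (is.null(best) || o$value < best$value) best <- o
    }
    est <- best$par; cl <- -best$value
  }
  names(est) <- free_parameters
  at_bound <- est <= lo + (hi - lo) * 1e-3 | est >= hi - (hi - lo) * 1e-3
  names(at_bound) <- free_parameters
  final <- model_template
  for (j in seq_len(n_free))
    final <- set_model_param(final, free_parameters[j], est[[j]])
  structure(list(parameter_estimates = est,
                 log_composite_likelihood = cl,
                 n_evaluations = n_eval,
                 at_bound = at_bound,
                 model = final),
            class = "composite_fit_result")
}

#' @export
print.composite_fit_result <- function(x, ...) {
  cat("composite_fit_result\n")
  if (length(x$parameter_estimates)) {
    for (i in seq_along(x$parameter_estimates))
      cat(sprintf("  %-40s %.6g%s\n", names(x$parameter_estimates)[i],
                  x$parameter_estimates[i],
                  if (x$at_bound[i]) "  [at bound]" else ""))
  } else cat("  (no free parameters; template evaluation)\n")
  cat(sprintf("  log composite likelihood: %.4f  (%d evaluations)\n",
              x$log_composite_likelihood, x$n_evaluations))
  invisible(x)
}

cell_is_singleton <- function(cell_names) {
  vapply(strsplit(cell_names, ","), function(x) sum(as.integer(x)) == 1L, NA)
}

#' Drop singleton cells from a folded SFS
#'
#' Removes cells whose total (minor-)allele count is one. Offered as a
#' robustness check: singletons are the class most affected by genotyping
#' error and low coverage.
#'
#' @param sfs a `folded_sfs`.
#' @return the SFS without singleton cells (`n_sites_total` unchanged).
#' @export
drop_singleton_cells <- function(sfs) {
  stopifnot(inherits(sfs, "folded_sfs"))
  sfs$cells <- sfs$cells[!cell_is_singleton(names(sfs$cells))]
  sfs
}

#' Plain-text fit report
#' @param fit a `composite_fit_result`.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  writeLines(utils::capture.output(print(fit)), path)
  invisible(path)
}
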