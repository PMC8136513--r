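#' Simulate one genomic window under a continent-island demography
#'
#' Draws a genealogy of the configured samples under the structured
#' coalescent implied by the model (per-deme coalescence at rate
#' `k(k-1)/2 / (2N)` per generation, backward migration of island lineages
#' into their parent metapopulation, wholesale merger at the divergence
#' time, bottleneck epochs of constant reduced size), then drops
#' infinite-sites mutations on branches as a Poisson process with rate
#' `mutation_rate * branch length * window_length`, on an integer
#' coordinate grid with collisions redrawn. Deterministic given `seed`.
#'
#' Intra-window recombination is off by default; `n_recomb_blocks > 1`
#' approximates it by concatenating that many independently simulated
#' equal-length blocks.
#'
#' @param model a [demographic_model()].
#' @param window_length window length in bp (>= 1).
#' @param seed integer seed.
#' @param n_recomb_blocks number of independent genealogy blocks (default 1
#'   = no recombination).
#' @return a `simulated_window`: list with `genotypes` (a
#'   [genotype_matrix()] on one scaffold named `sim`), `window_length`,
#'   `seed`, `tmrca`, `total_branch_length` and the per-lineage genealogy
#'   (`node_time`, `parent`) of the first block.
#' @export
simulate_window <- function(model, window_length, seed, n_recomb_blocks = 1L) {
  validate_model(model)
  assert_scalar_num(window_length, "window_length", lo = 1)
  stopifnot(n_recomb_blocks >= 1L)
  cd <- compile_demes(model)
  if (length(cd$lineage_deme) == 0L)
    stop("model samples zero lineages", call. = FALSE)

  block_len <- window_length / n_recomb_blocks
  sims <- with_seed(as.integer(seed), {
    lapply(seq_len(n_recomb_blocks), function(b)
      sim_window_cpp(cd$lineage_deme,
                     cd$demes$diploid_size,
                     cd$demes$migration_rate,
                     cd$demes$parent_idx,
                     cd$demes$divergence_time,
                     cd$epochs$deme, cd$epochs$start, cd$epochs$end,
                     cd$epochs$size,
                     model$mutation_rate, block_len,
                     max_time = 1e9))
  })

  pos <- integer(0); alle <- NULL
  for (b in seq_along(sims)) {
    pb <- sims[[b]]$positions + round((b - 1) * block_len)
    pos <- c(pos, pb)
    alle <- rbind(alle, sims[[b]]$alleles)
  }
  n_dip <- length(cd$lineage_deme) %/% 2L
  geno <- if (length(pos))
    alle[, 2 * seq_len(n_dip) - 1L, drop = FALSE] +
      alle[, 2 * seq_len(n_dip), drop = FALSE]
  else matrix(integer(0), 0L, n_dip)

  ids <- make_sample_ids(cd$sample_pop)
  gm <- genotype_matrix(
    geno = geno,
    sites = data.frame(scaffold = rep("sim", length(pos)), pos = pos),
    scaffolds = data.frame(name = "sim", length = window_length),
    sample_ids = ids, populations = cd$sample_pop)
  structure(list(genotypes = gm, window_length = window_length,
                 seed = as.integer(seed),
                 tmrca = sims[[1L]]$tmrca,
                 total_branch_length = sims[[1L]]$total_branch_length,
                 node_time = sims[[1L]]$node_time,
                 parent = sims[[1L]]$parent),
            class = "simulated_window")
}

make_sample_ids <- function(sample_pop) {
  ave_idx <- stats::ave(seq_along(sample_pop), sample_pop, FUN = seq_along)
  paste0(sample_pop, "_", ave_idx)
}

#' @export
print.simulated_window <- function(x, ...) {
  cat(sprintf("simulated_window: %d segregating site(s), L = %g bp, TMRCA = %.1f gen\n",
              nrow(x$genotypes$geno), x$window_length, x$tmrca))
  invisible(x)
}

#' Simulate independent neutral windows
#'
#' Replicates [simulate_window()] with per-window seeds derived from the
#' master seed by a counter scheme ([derive_seeds()]), so window `i` is the
#' same regardless of `n_windows`. Model parameters are held fixed across
#' replicates.
#'
#' @inheritParams simulate_window
#' @param n_windows number of replicates (>= 1).
#' @return list of `simulated_window`.
#' @export
simulate_null_windows <- function(model, n_windows, window_length, seed,
                                  n_recomb_blocks = 1L) {
  stopifnot(n_windows >= 1)
  seeds <- derive_seeds(seed, n_windows)
  lapply(seq_len(n_windows), function(i)
    simulate_window(model, window_length, seeds[i], n_recomb_blocks))
}

#' Forward Wright-Fisher simulation (validation oracle)
#'
#' A genuinely forward, discrete-generation Wright-Fisher simulation of the
#' same demography: the root deme is burned in to mutation-drift
#' equilibrium, child demes are founded from their parent at their
#' divergence time, each generation every child chooses a parent uniformly
#' (from the parent deme with probability `migration_rate`), and mutations
#' arise forward in time at rate `2N * mu * L` per deme per generation
#' under infinite sites. Intended as an independent distributional check on
#' [simulate_window()]; it refuses models too large for forward simulation.
#'
#' @inheritParams simulate_window
#' @param burn_in burn-in generations before the oldest demographic event;
#'   default `10 * 2N` of the root deme.
#' @param max_N,max_generations refusal thresholds.
#' @return a `simulated_window` (genotypes only; no genealogy fields).
#' @export
forward_wf_oracle <- function(model, window_length, seed,
                              burn_in = NULL,
                              max_N = 500, max_generations = 5000) {
  validate_model(model)
  cd <- compile_demes(model)
  d <- cd$demes
  if (any(d$diploid_size > max_N) ||
      (nrow(cd$epochs) && any(cd$epochs$size > max_N)))
    stop("model too large for the forward Wright-Fisher oracle (N > ", max_N,
         ")", call. = FALSE)
  L <- as.integer(window_length)
  mu <- model$mutation_rate
  root <- which(d$parent_idx == -1L)
  if (is.null(burn_in)) burn_in <- 10 * 2 * d$diploid_size[root]
  oldest <- max(c(0, d$divergence_time[is.finite(d$divergence_time)],
                  if (nrow(cd$epochs)) cd$epochs$end))
  T_total <- ceiling(oldest + burn_in)
  if (T_total > max_generations + burn_in || oldest > max_generations)
    stop("model too deep for the forward Wright-Fisher oracle (> ",
         max_generations, " generations)", call. = FALSE)

  res <- with_seed(as.integer(seed), {
    D <- nrow(d)
    size_at <- function(i, tb) {
      if (nrow(cd$epochs)) {
        e <- cd$epochs
        hit <- which(e$deme == i - 1L & tb >= e$start & tb < e$end)
        if (length(hit)) return(e$size[hit[1L]])
      }
      d$diploid_size[i]
    }
    # haplotype ancestry tables (grown as needed)
    cap <- 4096L
    hap_parent <- integer(cap); hap_pos <- integer(cap)
    n_hap <- 1L   # hap 1 = ancestral, no mutations
    used_pos <- logical(L)
    new_hap <- function(parent_hap, pos) {
      n_hap <<- n_hap + 1L
      if (n_hap > length(hap_parent)) {
        hap_parent <<- c(hap_parent, integer(length(hap_parent)))
        hap_pos <<- c(hap_pos, integer(length(hap_pos)))
      }
      hap_parent[n_hap] <<- parent_hap
      hap_pos[n_hap] <<- pos
      n_hap
    }
    pools <- vector("list", D)   # haplotype id vector per living deme
    pools[[root]] <- rep.int(1L, 2L * size_at(root, T_total))

    for (g in seq_len(T_total)) {
      tb <- T_total - g   # backward time after this generation's birth
      # found demes whose divergence time is reached
      for (i in seq_len(D)) {
        if (is.null(pools[[i]]) && is.finite(d$divergence_time[i]) &&
            d$divergence_time[i] >= tb && d$divergence_time[i] < tb + 1) {
          src <- pools[[d$parent_idx[i] + 1L]]
          pools[[i]] <- src[sample.int(length(src), 2L * size_at(i, tb),
                                       replace = TRUE)]
        }
      }
      for (i in seq_len(D)) {
        if (is.null(pools[[i]])) next
        n_child <- 2L * size_at(i, tb)
        pi <- d$parent_idx[i] + 1L
        m <- d$migration_rate[i]
        if (pi > 0L && m > 0 && !is.null(pools[[pi]])) {
          from_parent <- runif(n_child) < m
          kids <- integer(n_child)
          n_mig <- sum(from_parent)
          if (n_mig)
            kids[from_parent] <- pools[[pi]][sample.int(length(pools[[pi]]),
                                                        n_mig, replace = TRUE)]
          kids[!from_parent] <- pools[[i]][sample.int(length(pools[[i]]),
                                                      n_child - n_mig,
                                                      replace = TRUE)]
        } else {
          kids <- pools[[i]][sample.int(length(pools[[i]]), n_child,
                                        replace = TRUE)]
        }
        n_mut <- rpois(1L, n_child * mu * L)
        if (n_mut > 0) for (k in seq_len(n_mut)) {
          repeat {
            pos <- sample.int(L, 1L) - 1L
            if (!used_pos[pos + 1L]) break
          }
          used_pos[pos + 1L] <- TRUE
          who <- sample.int(n_child, 1L)
          kids[who] <- new_hap(kids[who], pos)
        }
        pools[[i]] <- kids
      }
    }

    # sample lineages at present
    samp <- integer(0)
    for (i in seq_len(D)) {
      ss <- d$sample_size[i]
      if (ss > 0) {
        if (is.null(pools[[i]]))
          stop("sampled deme '", d$name[i], "' does not exist at present",
               call. = FALSE)
        samp <- c(samp, pools[[i]][sample.int(length(pools[[i]]), 2L * ss)])
      }
    }
    muts_of <- function(h) {
      out <- integer(0)
      while (h > 1L) { out <- c(out, hap_pos[h]); h <- hap_parent[h] }
      out
    }
    mut_sets <- lapply(samp, muts_of)
    all_pos <- sort(unique(unlist(mut_sets)))
    allele <- matrix(0L, length(all_pos), length(samp))
    for (j in seq_along(mut_sets))
      allele[match(mut_sets[[j]], all_pos), j] <- 1L
    seg <- rowSums(allele) > 0 & rowSums(allele) < ncol(allele)
    list(pos = all_pos[seg], allele = allele[seg, , drop = FALSE])
  })

  n_dip <- length(cd$lineage_deme) %/% 2L
  geno <- if (length(res$pos))
    res$allele[, 2 * seq_len(n_dip) - 1L, drop = FALSE] +
      res$allele[, 2 * seq_len(n_dip), drop = FALSE]
  else matrix(integer(0), 0L, n_dip)
  gm <- genotype_matrix(
    geno = geno,
    sites = data.frame(scaffold = rep("sim", length(res$pos)), pos = res$pos),
    scaffolds = data.frame(name = "sim", length = window_length),
    sample_ids = make_sample_ids(cd$sample_pop),
    populations = cd$sample_pop)
  structure(list(genotypes = gm, window_length = window_length,
                 seed = as.integer(seed), tmrca = NA_real_,
                 total_branch_length = NA_real_),
            class = "simulated_window")
}
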