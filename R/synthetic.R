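#' Specification for a synthetic dataset
#'
#' Describes a complete seeded desk-scale dataset: windows simulated under
#' a continent-island model and concatenated into scaffolds, with an
#' optional selection-like signal injected by locally shrinking the focal
#' population's effective size (elevated local drift, the demographic
#' signature of a sweep) in a set of designated windows, plus a uniform
#' gene annotation and a GO-style term map in which one designated term
#' tags the genes overlapping injected windows.
#'
#' @param model a [demographic_model()]; default [default_tiger_model()].
#' @param n_scaffolds number of scaffolds; default 4.
#' @param scaffold_length bp per scaffold; default 50 Mb (about 20,000
#'   sliding 50-kb/10-kb windows in total with the default layout, so the
#'   top-0.1% outlier set has room for the injected loci and the sliding
#'   windows overlapping them).
#' @param n_injected_windows windows receiving the injected signal;
#'   default 5.
#' @param injection_factor multiplier in (0, 1] applied to the focal
#'   population's diploid size inside injected windows; default 0.02, a
#'   post-divergence drift intensity t/2N of about 12 in the focal deme,
#'   i.e. essentially certain local fixation -- the footprint of a
#'   completed hard sweep, whose hallmark is zero within-population
#'   diversity at the swept locus.
#' @param focal_population label of the population carrying the signal.
#' @param annotation_density genes per Mb; default 5.
#' @param window_length simulated locus length in bp; default 50 kb.
#' @param n_recomb_blocks independent genealogy blocks per locus (default
#'   40, i.e. 1.25-kb linkage blocks), emulating intra-window recombination;
#'   real 50-kb windows in a large population are far from single
#'   genealogies, and fully linked windows make windowed statistics
#'   unrealistically noisy.
#' @param seed master seed (mandatory).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(model = default_tiger_model(),
                         n_scaffolds = 4, scaffold_length = 5e7,
                         n_injected_windows = 5, injection_factor = 0.02,
                         focal_population = "AMU",
                         annotation_density = 5,
                         window_length = 50000,
                         n_recomb_blocks = 40,
                         seed) {
  validate_model(model)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (injection_factor <= 0 || injection_factor > 1)
    stop("'injection_factor' must be in (0, 1]", call. = FALSE)
  if (n_injected_windows < 0)
    stop("'n_injected_windows' must be >= 0", call. = FALSE)
  if (scaffold_length < window_length)
    stop("'scaffold_length' must be at least the window length", call. = FALSE)
  pops <- vapply(all_demes(model), `[[`, "", "name")
  if (n_injected_windows > 0 && !focal_population %in% pops)
    stop("focal population '", focal_population, "' not in the model",
         call. = FALSE)
  n_slots <- n_scaffolds * (scaffold_length %/% window_length)
  if (n_injected_windows > n_slots)
    stop("more injected windows than window slots", call. = FALSE)
  structure(list(model = model, n_scaffolds = n_scaffolds,
                 scaffold_length = scaffold_length,
                 n_injected_windows = n_injected_windows,
                 injection_factor = injection_factor,
                 focal_population = focal_population,
                 annotation_density = annotation_density,
                 window_length = window_length,
                 n_recomb_blocks = n_recomb_blocks,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Illustrative four-subspecies continent-island model
#'
#' The bundled stage-1 topology: four tiger subspecies (SUM, BEN, MAL,
#' AMU) diverging within the last ~1,900 generations from a large Asian
#' metapopulation with weak continued immigration, founder events for SUM
#' and BEN, strong recent bottlenecks for SUM and AMU, and an ancient
#' bottleneck of the metapopulation itself. Divergence times follow the
#' published point estimates; sizes and rates are illustrative desk-scale
#' values chosen once (see the methods vignette).
#'
#' @return a [demographic_model()].
#' @export
default_tiger_model <- function() {
  read_model_yaml(system.file("extdata", "tiger_stage1.yaml",
                              package = "mpbscan", mustWork = TRUE))
}

#' Generate a complete synthetic dataset bundle
#'
#' Simulates consecutive non-overlapping loci per scaffold under the
#' model ([simulate_window()] with counter-derived per-locus seeds),
#' switching to the perturbed model (focal diploid size multiplied by
#' `injection_factor`) in the injected windows, and writes:
#' `sim.vcf.gz`, `scaffolds.tsv`, `popmap.tsv`, `genes.bed`,
#' `go_map.tsv` and `manifest.yaml` (ground truth: injected window
#' coordinates, designated term, seed, model file `model.yaml`).
#' The annotation places genes uniformly at `annotation_density` per Mb
#' and guarantees one gene inside every injected window; the designated
#' term `GO:SIM0001` is assigned to the genes overlapping injected windows
#' plus about 1% of the background. Regeneration with the same spec is
#' deterministic.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with the file paths and the ground-truth manifest,
#'   invisibly.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- spec$window_length
  n_per_scaf <- spec$scaffold_length %/% wl
  n_slots <- spec$n_scaffolds * n_per_scaf
  scaf_names <- sprintf("scaf%02d", seq_len(spec$n_scaffolds))

  injected_slots <- if (spec$n_injected_windows > 0)
    sort(with_seed(spec$seed, sample.int(n_slots, spec$n_injected_windows)))
  else integer(0)

  perturbed <- spec$model
  if (length(injected_slots)) {
    block <- if (spec$focal_population %in%
                 vapply(spec$model$populations, `[[`, "", "name"))
      "populations" else "metapopulations"
    addr <- paste(block, spec$focal_population, "diploid_size", sep = ".")
    cur <- NULL
    for (p in spec$model[[block]])
      if (p$name == spec$focal_population) cur <- p$diploid_size
    perturbed <- set_model_param(spec$model, addr,
                                 max(1, cur * spec$injection_factor))
  }

  seeds <- derive_seeds(spec$seed + 1L, n_slots)
  cd <- compile_demes(spec$model)
  geno_list <- vector("list", n_slots)
  site_list <- vector("list", n_slots)
  for (s in seq_len(n_slots)) {
    scaf_i <- (s - 1L) %/% n_per_scaf + 1L
    off <- ((s - 1L) %% n_per_scaf) * wl
    m <- if (s %in% injected_slots) perturbed else spec$model
    sw <- simulate_window(m, wl, seeds[s],
                          n_recomb_blocks = spec$n_recomb_blocks)
    geno_list[[s]] <- sw$genotypes$geno
    site_list[[s]] <- data.frame(scaffold = rep(scaf_names[scaf_i],
                                                nrow(sw$genotypes$geno)),
                                 pos = sw$genotypes$sites$pos + off)
  }
  geno <- do.call(rbind, geno_list)
  sites <- do.call(rbind, site_list)
  scaffolds <- data.frame(name = scaf_names,
                          length = rep(spec$scaffold_length, spec$n_scaffolds))
  gm <- genotype_matrix(geno, sites, scaffolds,
                        sample_ids = make_sample_ids(cd$sample_pop),
                        populations = cd$sample_pop)

  inj <- if (length(injected_slots)) data.frame(
    scaffold = scaf_names[(injected_slots - 1L) %/% n_per_scaf + 1L],
    start = ((injected_slots - 1L) %% n_per_scaf) * wl,
    end = ((injected_slots - 1L) %% n_per_scaf) * wl + wl,
    stringsAsFactors = FALSE)
  else data.frame(scaffold = character(), start = numeric(), end = numeric())

  genes <- synth_annotation(spec, scaf_names, inj)
  go <- synth_term_map(spec, genes, inj)

  paths <- list(
    vcf = file.path(dir, "sim.vcf.gz"),
    scaffolds = file.path(dir, "scaffolds.tsv"),
    popmap = file.path(dir, "popmap.tsv"),
    genes = file.path(dir, "genes.bed"),
    go_map = file.path(dir, "go_map.tsv"),
    model = file.path(dir, "model.yaml"),
    manifest = file.path(dir, "manifest.yaml"))
  write_vcf(gm, paths$vcf)
  write.table(scaffolds, paths$scaffolds, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(gm$sample_ids, gm$populations), paths$popmap,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(genes$scaffold, as.integer(genes$start),
                         as.integer(genes$end), genes$gene_id, 0L,
                         genes$strand),
              paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(go, paths$go_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_model_yaml(spec$model, paths$model)
  manifest <- list(seed = spec$seed,
                   focal_population = spec$focal_population,
                   injection_factor = spec$injection_factor,
                   n_recomb_blocks = spec$n_recomb_blocks,
                   window_length = spec$window_length,
                   n_scaffolds = spec$n_scaffolds,
                   scaffold_length = spec$scaffold_length,
                   designated_term = "GO:SIM0001",
                   injected_windows = if (nrow(inj))
                     lapply(seq_len(nrow(inj)), function(i) as.list(inj[i, ]))
                   else list())
  yaml::write_yaml(manifest, paths$manifest)
  invisible(list(paths = paths, manifest = manifest, injected_windows = inj))
}

# uniform gene placement + one guaranteed gene centred in each injected
# window, so enrichment ground truth is always scoreable
synth_annotation <- function(spec, scaf_names, inj) {
  n_per <- max(1L, round(spec$annotation_density * spec$scaffold_length / 1e6))
  with_seed(spec$seed + 2L, {
    rows <- list()
    g <- 0L
    for (sc in scaf_names) {
      starts <- sort(sample.int(spec$scaffold_length - 30000L, n_per))
      lens <- sample(2000:30000, n_per, replace = TRUE)
      for (k in seq_len(n_per)) {
        g <- g + 1L
        rows[[g]] <- data.frame(
          gene_id = sprintf("gene%05d", g), scaffold = sc,
          start = starts[k],
          end = min(starts[k] + lens[k], spec$scaffold_length),
          strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(inj))) {
      g <- g + 1L
      mid <- (inj$start[i] + inj$end[i]) / 2
      rows[[g]] <- data.frame(
        gene_id = sprintf("gene%05d", g), scaffold = inj$scaffold[i],
        start = mid - 5000, end = mid + 5000,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$scaffold, out$start), , drop = FALSE]
  })
}

#' Score outlier recovery against fixture ground truth
#'
#' An injected window counts as recovered when at least one outlier window
#' overlaps it (half-open interval intersection); precision is the
#' fraction of outlier windows overlapping any injected window.
#'
#' @param outliers data.frame of outlier windows (`scaffold`, `start`,
#'   `end`), e.g. from [outlier_windows()].
#' @param injected data.frame of injected windows from the fixture
#'   manifest.
#' @return list with `n_injected`, `n_recovered`, `recall`, `precision`.
#' @export
score_recovery <- function(outliers, injected) {
  overlaps <- function(a, b)
    a$scaffold == b$scaffold & a$start < b$end & b$start < a$end
  rec <- vapply(seq_len(nrow(injected)), function(i)
    any(overlaps(outliers, injected[i, ])), NA)
  prec <- if (nrow(outliers)) vapply(seq_len(nrow(outliers)), function(i)
    any(overlaps(injected, outliers[i, ])), NA) else logical(0)
  list(n_injected = nrow(injected), n_recovered = sum(rec),
       recall = if (nrow(injected)) mean(rec) else NA_real_,
       precision = if (length(prec)) mean(prec) else NA_real_)
}

synth_term_map <- function(spec, genes, inj, n_background_terms = 40L) {
  with_seed(spec$seed + 3L, {
    hits <- map_windows_to_genes(inj, genes, flank = 0)
    n_extra <- max(2L, round(0.01 * nrow(genes)))
    extra <- sample(setdiff(genes$gene_id, hits), n_extra)
    rows <- data.frame(gene_id = c(hits, extra),
                       term_id = "GO:SIM0001", stringsAsFactors = FALSE)
    for (t in seq_len(n_background_terms)) {
      size <- sample(5:60, 1L)
      members <- sample(genes$gene_id, min(size, nrow(genes)))
      rows <- rbind(rows, data.frame(gene_id = members,
                                     term_id = sprintf("GO:%07d", t),
                                     stringsAsFactors = FALSE))
    }
    rows[order(rows$term_id, rows$gene_id), , drop = FALSE]
  })
}
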