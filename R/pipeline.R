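#' Run configuration for the end-to-end selection scan
#'
#' Collects paths and parameters for [run_scan()]. Any omitted filter or
#' window setting takes the documented default and is echoed in the run
#' report, so every run is self-describing.
#'
#' @param vcf multi-sample VCF path.
#' @param popmap population map (2-column TSV path, data.frame or named
#'   vector).
#' @param out_dir output directory.
#' @param scaffolds optional scaffold-length TSV (else the VCF contig
#'   header).
#' @param genes optional gene annotation (BED/GFF3) for candidate mapping.
#' @param go_map optional gene-to-term TSV for enrichment.
#' @param model optional model YAML for the simulated null.
#' @param filters a [filter_config()].
#' @param window_size,step window tiling in bp.
#' @param min_sites minimum usable sites per window per pair.
#' @param top_fraction outlier tail fraction.
#' @param flank gene flanking distance in bp.
#' @param n_null simulated null windows (0 disables the null stage).
#' @param n_recomb_blocks independent genealogy blocks per simulated null
#'   window (match the linkage structure of the observed data).
#' @param focal_populations populations to extract outliers for; default
#'   all four.
#' @param seed seed for any stochastic stage (mandatory when `n_null` > 0).
#' @return a `run_config`.
#' @export
run_config <- function(vcf, popmap, out_dir,
                       scaffolds = NULL, genes = NULL, go_map = NULL,
                       model = NULL, filters = filter_config(),
                       window_size = 50000, step = 10000, min_sites = 10,
                       top_fraction = 0.001, flank = 50000,
                       n_null = 0, n_recomb_blocks = 1L,
                       focal_populations = NULL, seed = NULL) {
  miss <- c(vcf = missing(vcf), popmap = missing(popmap),
            out_dir = missing(out_dir))
  if (any(miss))
    stop("run_config: missing mandatory field(s): ",
         paste(names(miss)[miss], collapse = ", "), call. = FALSE)
  if (n_null > 0 && is.null(seed))
    stop("run_config: 'seed' is mandatory when a simulated null is requested",
         call. = FALSE)
  structure(list(vcf = vcf, popmap = popmap, out_dir = out_dir,
                 scaffolds = scaffolds, genes = genes, go_map = go_map,
                 model = model, filters = filters,
                 window_size = window_size, step = step,
                 min_sites = min_sites, top_fraction = top_fraction,
                 flank = flank, n_null = n_null,
                 n_recomb_blocks = n_recomb_blocks,
                 focal_populations = focal_populations, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `filters` block
#' mirrors [filter_config()].
#' @param path YAML file.
#' @param out_dir overrides the configured output directory if given.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  fc <- do.call(filter_config, y$filters %||% list())
  for (f in c("vcf", "popmap"))
    if (is.null(y[[f]])) stop("run config: missing mandatory field '", f, "'",
                              call. = FALSE)
  run_config(vcf = y$vcf, popmap = y$popmap,
             out_dir = out_dir %||% y$out_dir %||%
               stop("run config: missing mandatory field 'out_dir'",
                    call. = FALSE),
             scaffolds = y$scaffolds, genes = y$genes, go_map = y$go_map,
             model = y$model, filters = fc,
             window_size = y$window_size %||% 50000,
             step = y$step %||% 10000,
             min_sites = y$min_sites %||% 10,
             top_fraction = y$top_fraction %||% 0.001,
             flank = y$flank %||% 50000,
             n_null = y$n_null %||% 0,
             n_recomb_blocks = y$n_recomb_blocks %||% 1L,
             focal_populations = y$focal_populations,
             seed = y$seed)
}

#' Run the end-to-end selection scan
#'
#' Fixed stage order: read and filter genotypes, tile windows, windowed
#' Hudson FST and mPBS track, optional coalescent null, per-population
#' outlier extraction, candidate gene mapping, Fisher enrichment. Every
#' intermediate artifact is written under `out_dir` and a run report logs
#' versions, seed, settings and the record counts dropped at each filter
#' stage. Re-running on identical inputs reproduces all outputs.
#'
#' @param cfg a [run_config()] or the path of a YAML run configuration.
#' @return list with the main results (`track`, `outliers`, `candidates`,
#'   `enrichment`, `null`), invisibly.
#' @export
run_scan <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("vcf", "popmap")) {
    p <- cfg[[f]]
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("run_scan: config field '", f, "': file not found: ", p,
           call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(cfg$out_dir, "run_report.txt")
  lines <- c(sprintf("mpbscan %s scan report", packageVersion("mpbscan")),
             sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("seed: %s", cfg$seed %||% "none (no stochastic stage)"),
             sprintf("settings: window=%d step=%d min_sites=%d top_fraction=%g flank=%d n_null=%d",
                     cfg$window_size, cfg$step, cfg$min_sites,
                     cfg$top_fraction, cfg$flank, cfg$n_null),
             sprintf("filters: %s",
                     paste(names(unclass(cfg$filters)),
                           unlist(cfg$filters), sep = "=", collapse = " ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  gm <- stage("read_vcf", read_vcf(cfg$vcf, cfg$popmap, cfg$scaffolds))
  lines <- c(lines, sprintf("input: %d sites x %d samples on %d scaffolds",
                            n_sites(gm), n_samples(gm), nrow(gm$scaffolds)))
  n0 <- n_sites(gm)
  gm <- stage("filter", apply_filters(gm, cfg$filters))
  lines <- c(lines, sprintf("filter: %d of %d sites retained (%d dropped)",
                            n_sites(gm), n0, n0 - n_sites(gm)))

  pops <- sort(unique(gm$populations))
  windows <- stage("windows",
                   tile_windows(gm$scaffolds, cfg$window_size, cfg$step))
  lines <- c(lines, sprintf("windows: %d (%d partial)", nrow(windows),
                            sum(windows$partial)))
  track <- stage("mpbs_track",
                 mpbs_track(gm, pops, windows, min_sites = cfg$min_sites))
  track_path <- file.path(cfg$out_dir, "mpbs_track.tsv")
  write.table(track, track_path, sep = "\t", quote = FALSE, row.names = FALSE)

  null <- NULL
  if (cfg$n_null > 0) {
    model <- stage("null", {
      if (is.null(cfg$model)) stop("simulated null requested but no model file given")
      read_model_yaml(cfg$model)
    })
    null <- stage("null", null_mpbs_distribution(
      model, n_windows = cfg$n_null, window_length = cfg$window_size,
      seed = cfg$seed, min_sites = cfg$min_sites,
      n_recomb_blocks = cfg$n_recomb_blocks))
    write.table(null$values, file.path(cfg$out_dir, "null_mpbs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    lines <- c(lines, sprintf("null: %d simulated windows", cfg$n_null))
  }

  focal <- cfg$focal_populations %||% pops
  genes <- if (!is.null(cfg$genes))
    stage("genes", dedup_annotation(read_gene_annotation(cfg$genes)))
  term_map <- if (!is.null(cfg$go_map)) stage("enrich", read_term_map(cfg$go_map))
  outliers <- list(); candidates <- list(); enrichment <- list()
  for (p in focal) {
    out_p <- stage("outliers", outlier_windows(track, cfg$top_fraction, p))
    outliers[[p]] <- out_p
    bed <- file.path(cfg$out_dir, sprintf("outliers_%s.bed", p))
    write.table(data.frame(out_p$scaffold, as.integer(out_p$start),
                           as.integer(out_p$end),
                           sprintf("mpbs=%.4f", out_p[[paste0("mpbs_", p)]])),
                bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    lines <- c(lines, sprintf("outliers %s: %d window(s)", p, nrow(out_p)))
    if (!is.null(genes)) {
      cand <- stage("genes", map_windows_to_genes(out_p, genes, cfg$flank,
                                                  gm$scaffolds))
      candidates[[p]] <- cand
      writeLines(cand, file.path(cfg$out_dir, sprintf("candidates_%s.txt", p)))
      lines <- c(lines, sprintf("candidates %s: %d gene(s)", p, length(cand)))
      if (!is.null(term_map)) {
        enr <- stage("enrich", fisher_enrichment(cand, genes$gene_id, term_map))
        enrichment[[p]] <- enr
        write.table(enr, file.path(cfg$out_dir,
                                   sprintf("enrichment_%s.tsv", p)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        lines <- c(lines, sprintf("enrichment %s: %d term(s) tested", p,
                                  nrow(enr)))
      }
    }
  }
  writeLines(lines, report)
  message(paste(lines, collapse = "\n"))
  invisible(list(track = track, outliers = outliers, candidates = candidates,
                 enrichment = enrichment, null = null,
                 genotypes = gm, report = report))
}
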