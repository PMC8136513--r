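#' Population specification for a continent-island demographic model
#'
#' One deme of the model: either a sampled population (an "island") or a
#' metapopulation level (the "continent" it diverged from). Going backward
#' in time, lineages in the deme migrate into the parent deme at
#' `migration_rate` per lineage per generation and are merged wholesale
#' into the parent at `divergence_time` generations before present.
#'
#' @param name label for the deme.
#' @param diploid_size effective diploid size (individuals), at present.
#' @param sample_size number of diploid individuals sampled at present.
#' @param divergence_time generations before present at which the deme's
#'   lineages join the parent deme; `Inf` for the root deme.
#' @param migration_rate backward-in-time probability per generation that a
#'   lineage in this deme derives from the parent deme, in `[0, 1]`.
#' @param parent name of the parent deme, or `NA` for the root (or to
#'   default to the single metapopulation of the model).
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, diploid_size, sample_size = 0L,
                            divergence_time = Inf, migration_rate = 0,
                            parent = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_scalar_num(diploid_size, "diploid_size", lo = 1)
  assert_scalar_num(sample_size, "sample_size", lo = 0)
  if (!identical(divergence_time, Inf))
    assert_scalar_num(divergence_time, "divergence_time", lo = 0)
  assert_scalar_num(migration_rate, "migration_rate", lo = 0, hi = 1)
  structure(list(name = name, diploid_size = diploid_size,
                 sample_size = as.integer(sample_size),
                 divergence_time = divergence_time,
                 migration_rate = migration_rate,
                 parent = as.character(parent)),
            class = "population_spec")
}

#' Bottleneck event
#'
#' An epoch of constant reduced effective size in one deme, spanning
#' `[start_time, start_time + duration)` generations before present. The
#' derived intensity is the classic `t / 2N` drift measure of the epoch.
#'
#' @param population name of the deme the bottleneck applies to.
#' @param start_time generations before present at which the epoch starts
#'   (its most recent edge).
#' @param duration epoch length in generations (> 0).
#' @param bottleneck_size effective diploid size during the epoch (>= 1).
#' @return a `bottleneck_event` list with an `intensity` field.
#' @export
bottleneck_event <- function(population, start_time, duration, bottleneck_size) {
  assert_scalar_num(start_time, "start_time", lo = 0)
  assert_scalar_num(duration, "duration")
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  assert_scalar_num(bottleneck_size, "bottleneck_size", lo = 1)
  structure(list(population = population, start_time = start_time,
                 duration = duration, bottleneck_size = bottleneck_size,
                 intensity = duration / (2 * bottleneck_size)),
            class = "bottleneck_event")
}

#' Hierarchical continent-island demographic model
#'
#' A set of sampled populations nested under one or more metapopulation
#' levels, with bottleneck epochs, a mutation rate and a generation time.
#' Populations with no explicit `parent` attach to the single metapopulation
#' when only one is given. Exactly one deme must be the root (infinite
#' divergence time).
#'
#' @param populations list of [population_spec()] for the sampled demes.
#' @param metapopulations list of [population_spec()] for the
#'   metapopulation levels (usually unsampled; a nested level, e.g. a
#'   regional metapopulation inside the continental one, names its parent).
#' @param bottlenecks list of [bottleneck_event()].
#' @param mutation_rate per site per generation; default 0.35e-8.
#' @param generation_time years per generation; default 5.
#' @return a validated `demographic_model`.
#' @export
demographic_model <- function(populations, metapopulations,
                              bottlenecks = list(),
                              mutation_rate = 0.35e-8,
                              generation_time = 5) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  if (inherits(metapopulations, "population_spec")) metapopulations <- list(metapopulations)
  if (inherits(bottlenecks, "bottleneck_event")) bottlenecks <- list(bottlenecks)
  assert_scalar_num(mutation_rate, "mutation_rate")
  if (mutation_rate <= 0) stop("'mutation_rate' must be > 0", call. = FALSE)
  assert_scalar_num(generation_time, "generation_time")
  if (generation_time <= 0) stop("'generation_time' must be > 0", call. = FALSE)
  m <- structure(list(populations = populations,
                      metapopulations = metapopulations,
                      bottlenecks = bottlenecks,
                      mutation_rate = mutation_rate,
                      generation_time = generation_time),
                 class = "demographic_model")
  validate_model(m)
  m
}

#' @export
print.demographic_model <- function(x, ...) {
  d <- compile_demes(x)
  cat("demographic_model:", nrow(d$demes), "demes,",
      length(x$bottlenecks), "bottleneck epochs\n")
  cat(sprintf("  mutation_rate = %g /site/gen, generation_time = %g y\n",
              x$mutation_rate, x$generation_time))
  print(d$demes, row.names = FALSE)
  invisible(x)
}

all_demes <- function(model) c(model$metapopulations, model$populations)

#' Validate a demographic model
#'
#' Checks spec invariants: a single root deme, finite divergence chains to
#' the root for every other deme, child divergence times not exceeding the
#' parent level's, non-overlapping bottleneck epochs per deme, and a
#' coalescing configuration.
#'
#' @param model a `demographic_model`.
#' @return the model, invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  demes <- all_demes(model)
  nm <- vapply(demes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate deme names in model", call. = FALSE)
  single_meta <- length(model$metapopulations) == 1L

  root <- character()
  for (d in demes) {
    tdiv <- d$divergence_time
    is_root <- !is.finite(tdiv)
    has_parent <- !is.na(d$parent) && nzchar(d$parent)
    if (is_root && !has_parent) { root <- c(root, d$name); next }
    parent <- if (has_parent) d$parent
              else if (single_meta) model$metapopulations[[1L]]$name
              else stop(sprintf("deme '%s' has no parent and the model has %d metapopulations",
                                d$name, length(model$metapopulations)), call. = FALSE)
    if (!parent %in% nm)
      stop(sprintf("parent '%s' of deme '%s' is not a deme in the model",
                   parent, d$name), call. = FALSE)
    if (!is.finite(tdiv))
      stop(sprintf("non-root deme '%s' needs a finite divergence_time", d$name),
           call. = FALSE)
    ptdiv <- demes[[match(parent, nm)]]$divergence_time
    if (is.finite(ptdiv) && tdiv > ptdiv)
      stop(sprintf("deme '%s' diverges at %g, after its parent '%s' (%g)",
                   d$name, tdiv, parent, ptdiv), call. = FALSE)
  }
  if (length(root) != 1L)
    stop(sprintf("model must have exactly one root deme (found %d); no common ancestor is reachable",
                 length(root)), call. = FALSE)

  for (b in model$bottlenecks) {
    if (!b$population %in% nm)
      stop(sprintf("bottleneck refers to unknown deme '%s'", b$population),
           call. = FALSE)
  }
  for (d in nm) {
    eps <- Filter(function(b) b$population == d, model$bottlenecks)
    if (length(eps) > 1L) {
      iv <- t(vapply(eps, function(b) c(b$start_time, b$start_time + b$duration),
                     numeric(2)))
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
        stop(sprintf("overlapping bottleneck epochs for deme '%s'", d),
             call. = FALSE)
    }
  }
  if (total_sampled_lineages(model) < 2L)
    stop("model must sample at least two lineages in total", call. = FALSE)
  invisible(model)
}

total_sampled_lineages <- function(model) {
  2L * sum(vapply(all_demes(model), `[[`, 0L, "sample_size"))
}

#' Compile a model into flat deme/epoch tables (internal)
#'
#' @return list with `demes` (data.frame), `epochs` (data.frame) and
#'   `lineage_deme` (0-based deme index per sampled haploid lineage).
#' @noRd
compile_demes <- function(model) {
  demes <- all_demes(model)
  nm <- vapply(demes, `[[`, "", "name")
  single_meta <- length(model$metapopulations) == 1L
  parent <- vapply(demes, function(d) {
    if (!is.na(d$parent) && nzchar(d$parent)) d$parent
    else if (!is.finite(d$divergence_time)) NA_character_
    else if (single_meta) model$metapopulations[[1L]]$name
    else NA_character_
  }, "")
  df <- data.frame(
    name = nm,
    diploid_size = vapply(demes, `[[`, 0, "diploid_size"),
    sample_size = vapply(demes, `[[`, 0L, "sample_size"),
    divergence_time = vapply(demes, `[[`, 0, "divergence_time"),
    migration_rate = vapply(demes, `[[`, 0, "migration_rate"),
    parent = parent,
    stringsAsFactors = FALSE
  )
  df$parent_idx <- match(df$parent, df$name) - 1L   # 0-based, NA for root
  df$parent_idx[is.na(df$parent_idx)] <- -1L

  epochs <- if (length(model$bottlenecks)) {
    data.frame(
      deme = match(vapply(model$bottlenecks, `[[`, "", "population"), nm) - 1L,
      start = vapply(model$bottlenecks, `[[`, 0, "start_time"),
      end = vapply(model$bottlenecks, function(b) b$start_time + b$duration, 0),
      size = vapply(model$bottlenecks, `[[`, 0, "bottleneck_size")
    )
  } else data.frame(deme = integer(), start = numeric(), end = numeric(),
                    size = numeric())

  lineage_deme <- integer(0)
  sample_pop <- character(0)
  for (i in seq_along(demes)) {
    ss <- df$sample_size[i]
    if (ss > 0) {
      lineage_deme <- c(lineage_deme, rep.int(i - 1L, 2L * ss))
      sample_pop <- c(sample_pop, rep(df$name[i], ss))
    }
  }
  list(demes = df, epochs = epochs, lineage_deme = lineage_deme,
       sample_pop = sample_pop)
}

#' Read a demographic model from a YAML file
#'
#' The schema mirrors the constructor arguments: top-level `mutation_rate`
#' and `generation_time`, plus `metapopulations`, `populations` and
#' `bottlenecks` blocks, each a list of records with the fields of
#' [population_spec()] / [bottleneck_event()]. A bundled example encoding a
#' four-subspecies continent-island topology ships as
#' `system.file("extdata", "tiger_stage1.yaml", package = "mpbscan")`.
#'
#' @param path YAML file path.
#' @return a validated [demographic_model()].
#' @export
read_model_yaml <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  as_spec <- function(p) population_spec(
    name = p$name, diploid_size = p$diploid_size,
    sample_size = p$sample_size %||% 0L,
    divergence_time = if (is.null(p$divergence_time)) Inf else
      if (identical(p$divergence_time, "Inf")) Inf else p$divergence_time,
    migration_rate = p$migration_rate %||% 0,
    parent = p$parent %||% NA_character_)
  demographic_model(
    populations = lapply(y$populations, as_spec),
    metapopulations = lapply(y$metapopulations, as_spec),
    bottlenecks = lapply(y$bottlenecks %||% list(), function(b)
      bottleneck_event(b$population, b$start_time, b$duration, b$bottleneck_size)),
    mutation_rate = y$mutation_rate %||% 0.35e-8,
    generation_time = y$generation_time %||% 5)
}

#' Write a demographic model to YAML
#' @param model a `demographic_model`.
#' @param path output file.
#' @export
write_model_yaml <- function(model, path) {
  strip <- function(p) {
    p <- unclass(p)
    if (!is.finite(p$divergence_time)) p$divergence_time <- "Inf"
    if (is.na(p$parent)) p$parent <- NULL
    p
  }
  y <- list(mutation_rate = model$mutation_rate,
            generation_time = model$generation_time,
            metapopulations = lapply(model$metapopulations, strip),
            populations = lapply(model$populations, strip),
            bottlenecks = lapply(model$bottlenecks, function(b)
              unclass(b)[c("population", "start_time", "duration", "bottleneck_size")]))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Modify one scalar parameter of a demographic model
#'
#' Addresses follow `"populations.<name>.<field>"`,
#' `"metapopulations.<name>.<field>"` or `"bottlenecks.<i>.<field>"`, the
#' convention used by [fit_parameters()] for its free-parameter vector.
#'
#' @param model a `demographic_model`.
#' @param address parameter address string.
#' @param value new value.
#' @return the modified (re-validated) model.
#' @export
set_model_param <- function(model, address, value) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop("parameter address must have three '.'-separated parts: ", address,
         call. = FALSE)
  block <- parts[1L]; key <- parts[2L]; field <- parts[3L]
  if (block %in% c("populations", "metapopulations")) {
    nm <- vapply(model[[block]], `[[`, "", "name")
    i <- match(key, nm)
    if (is.na(i)) stop("no deme named '", key, "' in ", block, call. = FALSE)
    model[[block]][[i]][[field]] <- value
  } else if (block == "bottlenecks") {
    i <- as.integer(key)
    if (is.na(i) || i < 1L || i > length(model$bottlenecks))
      stop("bottleneck index out of range: ", key, call. = FALSE)
    model$bottlenecks[[i]][[field]] <- value
    b <- model$bottlenecks[[i]]
    model$bottlenecks[[i]]$intensity <- b$duration / (2 * b$bottleneck_size)
  } else stop("unknown parameter block: ", block, call. = FALSE)
  validate_model(model)
  model
}

#' Convert years to generations
#'
#' @param years elapsed time in years (>= 0).
#' @param generation_time years per generation (> 0).
#' @return time in generations.
#' @export
years_to_generations <- function(years, generation_time) {
  if (any(years < 0)) stop("'years' must be non-negative", call. = FALSE)
  if (generation_time <= 0) stop("'generation_time' must be > 0", call. = FALSE)
  years / generation_time
}

#' Convert generations to years
#' @param generations elapsed time in generations (>= 0).
#' @inheritParams years_to_generations
#' @return time in years.
#' @export
generations_to_years <- function(generations, generation_time) {
  if (any(generations < 0)) stop("'generations' must be non-negative", call. = FALSE)
  if (generation_time <= 0) stop("'generation_time' must be > 0", call. = FALSE)
  generations * generation_time
}
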