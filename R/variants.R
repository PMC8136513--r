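#' Genotype matrix container
#'
#' Diploid genotypes at biallelic sites on a set of scaffolds, with one
#' population label per sample. Genotypes are alternate-allele counts in
#' `{0, 1, 2}` or `NA` for missing. Positions are 0-based and strictly
#' increasing within each scaffold; VCF input/output converts at the
#' boundary.
#'
#' @param geno integer matrix, sites x samples, values 0/1/2/NA.
#' @param sites data.frame with columns `scaffold`, `pos` (0-based bp).
#' @param scaffolds data.frame with columns `name`, `length` (bp).
#' @param sample_ids character vector, one per column of `geno`.
#' @param populations character vector of population labels, one per sample.
#' @param dp,gq optional numeric matrices of per-genotype depth and
#'   genotype quality, same shape as `geno`.
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, scaffolds, sample_ids, populations,
                            dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(nrow(geno) == nrow(sites),
            ncol(geno) == length(sample_ids),
            length(populations) == length(sample_ids),
            all(c("scaffold", "pos") %in% names(sites)),
            all(c("name", "length") %in% names(scaffolds)))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  if (!all(sites$scaffold %in% scaffolds$name))
    stop("sites reference scaffolds missing from the scaffold table", call. = FALSE)
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == sc]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within scaffold ", sc,
           call. = FALSE)
    len <- scaffolds$length[match(sc, scaffolds$name)]
    if (any(p < 0) || any(p >= len))
      stop("site positions outside [0, length) on scaffold ", sc, call. = FALSE)
  }
  if (!is.null(dp)) stopifnot(identical(dim(dp), dim(geno)))
  if (!is.null(gq)) stopifnot(identical(dim(gq), dim(geno)))
  rownames(sites) <- NULL
  structure(list(geno = geno,
                 sites = sites[, c("scaffold", "pos")],
                 scaffolds = scaffolds[, c("name", "length")],
                 sample_ids = as.character(sample_ids),
                 populations = as.character(populations),
                 dp = dp, gq = gq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d scaffold(s)\n",
              nrow(x$geno), ncol(x$geno), nrow(x$scaffolds)))
  tab <- table(x$populations)
  cat("  populations:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

n_sites <- function(gm) nrow(gm$geno)
n_samples <- function(gm) ncol(gm$geno)

#' Subset a genotype matrix by site index (internal)
#' @noRd
subset_sites <- function(gm, keep) {
  gm$geno <- gm$geno[keep, , drop = FALSE]
  gm$sites <- gm$sites[keep, , drop = FALSE]
  rownames(gm$sites) <- NULL
  if (!is.null(gm$dp)) gm$dp <- gm$dp[keep, , drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[keep, , drop = FALSE]
  gm
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only; indels and multiallelic sites are
#' skipped and counted in a message. VCF 1-based positions become 0-based.
#' Scaffold lengths come from `##contig` header lines unless a table is
#' supplied.
#'
#' @param path VCF file (plain or gzipped).
#' @param population_map named character vector (`sample -> population`), a
#'   data.frame with columns `sample`/`population`, or the path of a
#'   2-column TSV.
#' @param scaffold_lengths optional data.frame (`name`, `length`) or path of
#'   a 2-column TSV, overriding the VCF contig header.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, population_map, scaffold_lengths = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  pm <- read_population_map(population_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  missing_pm <- setdiff(samples, pm$sample)
  if (length(missing_pm))
    stop("samples absent from population map: ",
         paste(missing_pm, collapse = ", "), call. = FALSE)

  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L

  grab_num <- function(el) {
    if (!grepl(paste0("(^|:)", el, "(:|$)"), v@gt[1, "FORMAT"])) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m[snp, , drop = FALSE]
  }
  dp <- grab_num("DP")
  gq <- grab_num("GQ")

  geno <- geno[snp, , drop = FALSE]
  sites <- data.frame(scaffold = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]) - 1L,
                      stringsAsFactors = FALSE)

  scafs <- if (is.null(scaffold_lengths)) contig_lengths(v) else
    read_scaffold_table(scaffold_lengths)
  if (is.null(scafs))
    stop("no ##contig header in VCF; supply 'scaffold_lengths'", call. = FALSE)

  genotype_matrix(geno, sites, scafs,
                  sample_ids = samples,
                  populations = pm$population[match(samples, pm$sample)],
                  dp = dp, gq = gq)
}

read_population_map <- function(population_map) {
  if (is.character(population_map) && length(population_map) == 1L &&
      file.exists(population_map)) {
    population_map <- read.table(population_map, header = FALSE, sep = "\t",
                                 col.names = c("sample", "population"),
                                 stringsAsFactors = FALSE)
  }
  if (is.character(population_map) && !is.null(names(population_map)))
    population_map <- data.frame(sample = names(population_map),
                                 population = unname(population_map),
                                 stringsAsFactors = FALSE)
  if (!is.data.frame(population_map) ||
      !all(c("sample", "population") %in% names(population_map)))
    stop("'population_map' must map sample to population", call. = FALSE)
  population_map
}

read_scaffold_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.table(x, header = FALSE, sep = "\t",
                    col.names = c("name", "length"), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "length") %in% names(x)))
  x
}

contig_lengths <- function(v) {
  meta <- v@meta[grepl("^##contig=", v@meta)]
  if (!length(meta)) return(NULL)
  id <- sub('.*ID=([^,>]+).*', "\\1", meta)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", meta)))
  if (anyNA(len)) return(NULL)
  data.frame(name = id, length = len, stringsAsFactors = FALSE)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Alleles are written as REF `A` / ALT `T` placeholders (the container
#' does not keep nucleotide identities); DP/GQ matrices are emitted when
#' present. Output is gzip-compressed (name the file `.vcf.gz`).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path, conventionally ending in `.vcf.gz`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- n_sites(gm)
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", gm$scaffolds$name,
                    as.integer(gm$scaffolds$length)),
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  fmt <- "GT"
  if (!is.null(gm$dp)) {
    meta <- c(meta, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
    fmt <- paste0(fmt, ":DP")
  }
  if (!is.null(gm$gq)) {
    meta <- c(meta, '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
    fmt <- paste0(fmt, ":GQ")
  }
  fix <- cbind(CHROM = gm$sites$scaffold,
               POS = as.character(gm$sites$pos + 1L),
               ID = rep(".", n), REF = rep("A", n), ALT = rep("T", n),
               QUAL = rep(".", n), FILTER = rep("PASS", n), INFO = rep(".", n))
  gt_str <- matrix(".(missing)", n, n_samples(gm))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_str[] <- ifelse(is.na(gm$geno), "./.", code[as.character(gm$geno)])
  if (!is.null(gm$dp))
    gt_str <- matrix(paste0(gt_str, ":", ifelse(is.na(gm$dp), ".", gm$dp)),
                     n, n_samples(gm))
  if (!is.null(gm$gq))
    gt_str <- matrix(paste0(gt_str, ":", ifelse(is.na(gm$gq), ".", gm$gq)),
                     n, n_samples(gm))
  gt <- cbind(FORMAT = rep(fmt, n), gt_str)
  colnames(gt) <- c("FORMAT", gm$sample_ids)
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls, meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Variant and genotype filter configuration
#'
#' Defaults follow a standard resequencing filter set: genotypes with
#' depth < 10 or genotype quality < 30 are set missing, sites with minor
#' allele frequency below 0.025 or more than 5% missing genotypes are
#' dropped, and scaffolds shorter than 1 Mb are excluded.
#' `min_base_quality` is recorded for provenance but operates at the
#' variant-calling stage and cannot be re-applied to a VCF.
#'
#' @param min_DP minimum per-genotype depth; below it the call is set
#'   missing (requires a DP matrix; ignored otherwise).
#' @param min_GQ minimum per-genotype quality (requires a GQ matrix).
#' @param min_maf minimum minor allele frequency, computed on non-missing
#'   alleles; sites strictly below are dropped.
#' @param max_missing_fraction maximum fraction of missing genotypes per
#'   site, in `[0, 1]`.
#' @param min_scaffold_length scaffolds shorter than this are dropped.
#' @param require_complete drop any site with at least one missing call.
#' @param min_base_quality recorded only (see above).
#' @return a `filter_config`.
#' @export
filter_config <- function(min_DP = 10, min_GQ = 30, min_maf = 0.025,
                          max_missing_fraction = 0.05,
                          min_scaffold_length = 1e6,
                          require_complete = FALSE,
                          min_base_quality = 30) {
  for (v in c(min_DP = min_DP, min_GQ = min_GQ, min_maf = min_maf,
              min_scaffold_length = min_scaffold_length,
              min_base_quality = min_base_quality))
    if (v < 0) stop("filter thresholds must be >= 0", call. = FALSE)
  assert_scalar_num(max_missing_fraction, "max_missing_fraction", 0, 1)
  structure(list(min_DP = min_DP, min_GQ = min_GQ, min_maf = min_maf,
                 max_missing_fraction = max_missing_fraction,
                 min_scaffold_length = min_scaffold_length,
                 require_complete = isTRUE(require_complete),
                 min_base_quality = min_base_quality),
            class = "filter_config")
}

#' Apply site and genotype filters
#'
#' Filter order is fixed and documented: (1) genotype-level, DP then GQ
#' masking to missing; (2) site-level, minor allele frequency on non-missing
#' alleles, then missingness fraction, then `require_complete`; (3)
#' scaffold-level minimum length. The operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @param verbose log per-stage drop counts via `message()`.
#' @return the filtered [genotype_matrix()]; a warning (not an error) is
#'   raised if no sites survive.
#' @export
apply_filters <- function(gm, cfg = filter_config(), verbose = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "filter_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(gm$dp) && cfg$min_DP > 0) {
    mask <- !is.na(gm$dp) & gm$dp < cfg$min_DP & !is.na(gm$geno)
    gm$geno[mask] <- NA_integer_
    log_("genotype filter DP<%g: %d call(s) set missing", cfg$min_DP, sum(mask))
  }
  if (!is.null(gm$gq) && cfg$min_GQ > 0) {
    mask <- !is.na(gm$gq) & gm$gq < cfg$min_GQ & !is.na(gm$geno)
    gm$geno[mask] <- NA_integer_
    log_("genotype filter GQ<%g: %d call(s) set missing", cfg$min_GQ, sum(mask))
  }

  an <- 2L * rowSums(!is.na(gm$geno))
  ac <- rowSums(gm$geno, na.rm = TRUE)
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= cfg$min_maf
  log_("site filter MAF>=%g: %d site(s) dropped", cfg$min_maf, sum(!keep))
  miss <- rowMeans(is.na(gm$geno))
  keep2 <- miss <= cfg$max_missing_fraction
  log_("site filter missingness<=%g: %d additional site(s) dropped",
       cfg$max_missing_fraction, sum(keep & !keep2))
  keep <- keep & keep2
  if (cfg$require_complete) {
    keep3 <- miss == 0
    log_("site filter complete-cases: %d additional site(s) dropped",
         sum(keep & !keep3))
    keep <- keep & keep3
  }
  gm <- subset_sites(gm, keep)

  ok_scaf <- gm$scaffolds$length >= cfg$min_scaffold_length
  if (!all(ok_scaf)) {
    drop_names <- gm$scaffolds$name[!ok_scaf]
    ns <- sum(gm$sites$scaffold %in% drop_names)
    log_("scaffold filter length>=%g: %d scaffold(s), %d site(s) dropped",
         cfg$min_scaffold_length, length(drop_names), ns)
    gm <- subset_sites(gm, !(gm$sites$scaffold %in% drop_names))
    gm$scaffolds <- gm$scaffolds[ok_scaf, , drop = FALSE]
    rownames(gm$scaffolds) <- NULL
  }
  if (n_sites(gm) == 0L)
    warning("all sites removed by filtering", call. = FALSE)
  gm
}

#' Tile scaffolds into sliding windows
#'
#' Windows are 0-based half-open `[start, start + window_size)` starting at
#' multiples of `step`. A terminal partial window is emitted (flagged
#' `partial = TRUE`) only when it covers bases no full window reaches; with
#' the default 50-kb/10-kb layout such a partial is always at least half a
#' window long. Tiling therefore covers every base whenever
#' `step <= window_size`. A scaffold shorter than the window yields a
#' single (partial) window covering it.
#'
#' @param scaffold_lengths data.frame (`name`, `length`), named numeric
#'   vector, or TSV path.
#' @param window_size window width in bp; default 50 kb.
#' @param step distance between window starts in bp; default 10 kb.
#' @return data.frame with columns `scaffold`, `start`, `end`, `partial`.
#' @export
tile_windows <- function(scaffold_lengths, window_size = 50000, step = 10000) {
  if (is.numeric(scaffold_lengths) && !is.null(names(scaffold_lengths)))
    scaffold_lengths <- data.frame(name = names(scaffold_lengths),
                                   length = unname(scaffold_lengths))
  scaffold_lengths <- read_scaffold_table(scaffold_lengths)
  stopifnot(window_size >= step, step >= 1)
  out <- lapply(seq_len(nrow(scaffold_lengths)), function(i) {
    nm <- scaffold_lengths$name[i]
    len <- scaffold_lengths$length[i]
    if (len <= 0) stop("scaffold length must be positive: ", nm, call. = FALSE)
    if (len < window_size) {
      return(data.frame(scaffold = nm, start = 0, end = len, partial = TRUE))
    }
    starts <- seq(0, len - window_size, by = step)
    df <- data.frame(scaffold = nm, start = starts, end = starts + window_size,
                     partial = FALSE)
    covered_to <- starts[length(starts)] + window_size
    if (covered_to < len) {
      tail_start <- starts[length(starts)] + step
      df <- rbind(df, data.frame(scaffold = nm, start = tail_start,
                                 end = len, partial = TRUE))
    }
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Variance-standardized genotype PCA
#'
#' Each site is centered by twice its allele frequency and scaled by
#' `sqrt(2p(1-p))` (the plink "variance-standardized relationship"
#' convention), then samples are projected on the leading principal
#' components.
#'
#' @param gm a [genotype_matrix()] with no missing data, unless
#'   `impute = TRUE` (mean imputation, flagged in the result).
#' @param n_components number of PCs to return.
#' @param impute mean-impute missing genotypes.
#' @return list with `scores` (samples x PCs), `varfrac` (fraction of total
#'   variance per returned PC; sums to <= 1), `sample_ids`, `populations`,
#'   `imputed`.
#' @export
genotype_pca <- function(gm, n_components = 2, impute = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2L) stop("PCA needs at least two samples", call. = FALSE)
  G <- t(gm$geno)   # samples x sites
  imputed <- FALSE
  if (anyNA(G)) {
    if (!impute)
      stop("missing genotypes; rerun with impute = TRUE for mean imputation",
           call. = FALSE)
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2L]]
    imputed <- TRUE
  }
  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L)
    stop("need at least two polymorphic sites for PCA", call. = FALSE)
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(G, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  k <- min(n_components, nrow(X) - 1L, ncol(X))
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- gm$sample_ids
  structure(list(scores = scores,
                 varfrac = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)],
                 sample_ids = gm$sample_ids,
                 populations = gm$populations,
                 imputed = imputed),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, %d components (%s of variance)%s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$varfrac), collapse = " + "),
              if (x$imputed) ", mean-imputed" else ""))
  invisible(x)
}
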