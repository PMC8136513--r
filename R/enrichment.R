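#' Deduplicate homolog annotations
#'
#' Within each scaffold and strand, overlapping homolog records are grouped
#' transitively into clusters and only the first record of each cluster in
#' coordinate order is retained; records overlapping on opposite strands
#' are both kept. Intervals are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `scaffold`, `start`,
#'   `end`, `strand` (and optionally `homolog_group`).
#' @return the deduplicated data.frame, sorted by scaffold then start.
#' @export
dedup_annotation <- function(genes) {
  req <- c("gene_id", "scaffold", "start", "end", "strand")
  stopifnot(all(req %in% names(genes)))
  if (any(genes$end <= genes$start))
    stop("malformed gene interval(s): end must exceed start", call. = FALSE)
  genes <- genes[order(genes$scaffold, genes$start, genes$end), , drop = FALSE]
  keep <- logical(nrow(genes))
  for (key in unique(paste(genes$scaffold, genes$strand))) {
    idx <- which(paste(genes$scaffold, genes$strand) == key)
    cluster_end <- -Inf
    for (i in idx) {
      if (genes$start[i] >= cluster_end) {
        keep[i] <- TRUE                   # starts a new cluster
        cluster_end <- genes$end[i]
      } else {
        cluster_end <- max(cluster_end, genes$end[i])
      }
    }
  }
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map outlier windows to candidate genes
#'
#' A gene is a candidate when its flanked interval
#' `[start - flank, end + flank)` (clipped at scaffold bounds when lengths
#' are supplied) intersects any outlier window, half-open on both sides.
#'
#' @param windows data.frame with `scaffold`, `start`, `end` (outlier
#'   windows).
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`.
#' @param flank flanking distance in bp; default 50 kb.
#' @param scaffold_lengths optional data.frame (`name`, `length`) used to
#'   clip flanks.
#' @return character vector of candidate gene ids (unique, in annotation
#'   order).
#' @export
map_windows_to_genes <- function(windows, genes, flank = 50000,
                                 scaffold_lengths = NULL) {
  if (!nrow(windows) || !nrow(genes)) return(character(0))
  gstart <- pmax(genes$start - flank, 0)
  gend <- genes$end + flank
  if (!is.null(scaffold_lengths)) {
    scaffold_lengths <- read_scaffold_table(scaffold_lengths)
    len <- scaffold_lengths$length[match(genes$scaffold, scaffold_lengths$name)]
    gend <- pmin(gend, len, na.rm = TRUE)
  }
  hit <- logical(nrow(genes))
  for (w in seq_len(nrow(windows))) {
    hit <- hit | (genes$scaffold == windows$scaffold[w] &
                    gstart < windows$end[w] & windows$start[w] < gend)
  }
  unique(genes$gene_id[hit])
}

#' Fisher's exact GO-term enrichment of candidate genes
#'
#' One-sided (over-representation) Fisher's exact test per term on the
#' 2x2 table (candidates with term, candidates without, background-only
#' with term, background-only without), with Benjamini-Hochberg adjustment
#' across the tested terms. Genes without any term still count in the
#' table margins. Terms with fewer than `min_term_size` background hits
#' are skipped.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of `background`).
#' @param background character vector of all genes after filtering (the
#'   reference list).
#' @param term_map data.frame with columns `gene_id`, `term_id` (one row
#'   per assignment).
#' @param min_term_size minimum background hits per tested term; default 1.
#' @return data.frame sorted by p-value with columns `term_id`,
#'   `candidate_hits`, `candidate_size`, `background_hits`,
#'   `background_size`, `p_value`, `adjusted_p`.
#' @export
fisher_enrichment <- function(candidates, background, term_map,
                              min_term_size = 1) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  background <- unique(background)
  candidates <- unique(candidates)
  stray <- setdiff(candidates, background)
  if (length(stray))
    stop("candidate gene(s) absent from background: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  empty <- data.frame(term_id = character(), candidate_hits = integer(),
                      candidate_size = integer(), background_hits = integer(),
                      background_size = integer(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE)
  if (!length(candidates)) return(empty)

  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id")])
  n_bg <- length(background)
  n_cand <- length(candidates)
  terms <- split(tm$gene_id, tm$term_id)
  terms <- terms[lengths(terms) >= min_term_size]
  if (!length(terms)) return(empty)

  rows <- lapply(names(terms), function(tid) {
    g <- terms[[tid]]
    a <- sum(candidates %in% g)
    b <- n_cand - a
    c_ <- length(g) - a
    d <- (n_bg - n_cand) - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(term_id = tid, candidate_hits = a, candidate_size = n_cand,
               background_hits = length(g), background_size = n_bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read gene annotation from BED or GFF3
#'
#' BED (>= 4 columns, 0-based half-open) or GFF3 (`gene` features, 1-based
#' closed, converted to the internal 0-based half-open convention; the
#' `ID=` attribute becomes `gene_id`).
#'
#' @param path annotation file; format inferred from the extension.
#' @return data.frame with `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) {
    g <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("scaffold", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
    g <- g[g$type == "gene", , drop = FALSE]
    id <- sub(".*ID=([^;]+).*", "\\1", g$attributes)
    data.frame(gene_id = id, scaffold = g$scaffold, start = g$start - 1L,
               end = g$end, strand = g$strand, stringsAsFactors = FALSE)
  } else {
    g <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
    if (ncol(g) < 4L) stop("BED needs at least 4 columns", call. = FALSE)
    data.frame(gene_id = g[[4L]], scaffold = g[[1L]], start = g[[2L]],
               end = g[[3L]],
               strand = if (ncol(g) >= 6L) g[[6L]] else "+",
               stringsAsFactors = FALSE)
  }
}

#' Read a gene-to-term mapping TSV
#' @param path 2-column TSV (gene_id, term_id), no header.
#' @return data.frame with `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  read.table(path, sep = "\t", header = FALSE,
             col.names = c("gene_id", "term_id"), stringsAsFactors = FALSE)
}
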