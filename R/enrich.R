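#' Pathway database
#'
#' Holds named pathway gene sets over a gene universe (typically all genes
#' mappable from the genotyping panel). Genes of a set outside the universe
#' are dropped with a warning so that the subset invariant always holds.
#'
#' @param sets named list of character vectors (pathway id -> gene symbols).
#' @param universe character vector of all mappable genes.
#' @return list of class `pathway_db` with elements `sets` and `universe`.
#' @export
pathway_db <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty gene universe")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("pathway sets must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  out <- sum(!unlist(sets) %in% universe)
  if (out > 0) {
    warnf("%d pathway gene(s) outside the universe dropped", out)
    sets <- lapply(sets, intersect, universe)
  }
  structure(list(sets = sets, universe = universe), class = "pathway_db")
}

#' Read a GMT pathway file
#'
#' GMT lines are tab-separated: pathway id, description, then gene symbols.
#'
#' @param path GMT file path.
#' @param universe gene universe for [pathway_db()]; defaults to the union
#'   of all genes in the file.
#' @return a [pathway_db()] with a `descriptions` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                      paste(utils::head(which(bad), 5), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- ids
  db <- pathway_db(sets, universe %||% unique(unlist(sets)))
  attr(db, "descriptions") <- stats::setNames(desc, ids)
  db
}

#' Read a SNP-to-gene map
#'
#' Tab-separated with header; columns `snp_id` and `genes` (comma-separated
#' symbols), optional `location`.
#'
#' @param path TSV path.
#' @return data frame `snp_id`, `genes`, `location`.
#' @export
read_snp_gene_map <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("snp_id", "genes") %in% names(df)))
    stopf("gene map needs columns `snp_id` and `genes`")
  if (!"location" %in% names(df)) df$location <- NA_character_
  df
}

#' Map SNPs to their annotated genes
#'
#' Union of gene symbols over the given SNPs, de-duplicated; SNPs with
#' multi-gene annotations contribute every gene. Unmapped SNPs are counted
#' in a message.
#'
#' @param snps character vector of SNP ids.
#' @param gmap data frame as from [read_snp_gene_map()].
#' @return character vector of unique gene symbols.
#' @export
map_snps_to_genes <- function(snps, gmap) {
  at <- match(snps, gmap$snp_id)
  unmapped <- sum(is.na(at))
  if (unmapped > 0)
    message(sprintf("%d of %d SNP(s) have no gene annotation", unmapped, length(snps)))
  raw <- gmap$genes[at[!is.na(at)]]
  genes <- unlist(strsplit(raw, "[,;] *"))
  genes <- trimws(genes)
  unique(genes[nzchar(genes)])
}

check_enrich_counts <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stopf("inconsistent counts: k=%d K=%d n=%d N=%d (need 0 <= k <= min(K, n), K,n <= N)",
          k, K, n, N)
}

#' One-sided Fisher over-representation p-value
#'
#' Hypergeometric upper tail `P(X >= k)` for observing `k` of `n` selected
#' genes inside a pathway of size `K` drawn from a universe of `N`.
#'
#' @param k selected genes inside the pathway.
#' @param K pathway size.
#' @param n number of selected genes.
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact_enrichment <- function(k, K, n, N) {
  check_enrich_counts(k, K, n, N)
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' EASE-adjusted over-representation score
#'
#' The Fisher one-sided tail recomputed with the overlap reduced by one
#' (a jackknife penalty that discounts single-gene overlaps): `ease(k) =
#' fisher(k - 1)`, and 1 for `k <= 1`.
#'
#' @inheritParams fisher_exact_enrichment
#' @return p-value in `(0, 1]`, always `>=` the Fisher p for `k >= 1`.
#' @export
ease_score <- function(k, K, n, N) {
  check_enrich_counts(k, K, n, N)
  if (k < 1) return(1)
  fisher_exact_enrichment(k - 1, K, n, N)
}

#' Pathway over-representation of a gene selection
#'
#' Tests every pathway with at least one selected gene; selected genes
#' outside the universe are dropped with a warning. No multiple-testing
#' correction is applied: significance is called at a raw EASE p-value
#' threshold.
#'
#' @param genes character vector of selected gene symbols.
#' @param db a [pathway_db()].
#' @param threshold EASE p-value below which a pathway is flagged
#'   significant (default 0.1).
#' @return data frame of class `enrichment_result`, sorted by ascending
#'   `ease_p`: `pathway`, `k`, `K`, `n`, `N`, `fisher_p`, `ease_p`,
#'   `significant`.
#' @export
enrich_pathways <- function(genes, db, threshold = 0.1) {
  if (!inherits(db, "pathway_db")) stopf("`db` must be a pathway_db")
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, db$universe)
  if (length(outside)) {
    warnf("%d selected gene(s) outside the universe dropped", length(outside))
    genes <- intersect(genes, db$universe)
  }
  N <- length(db$universe)
  n <- length(genes)
  rows <- lapply(names(db$sets), function(pw) {
    set <- db$sets[[pw]]
    k <- length(intersect(genes, set))
    if (k < 1L) return(NULL)
    K <- length(set)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N,
               fisher_p = fisher_exact_enrichment(k, K, n, N),
               ease_p = ease_score(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fisher_p = numeric(),
                      ease_p = numeric(), stringsAsFactors = FALSE)
  out$significant <- out$ease_p < threshold
  out <- out[order(out$ease_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
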