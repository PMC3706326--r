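#' Construct a pathway membership map
#'
#' @param pathways named list mapping pathway id to a character vector of
#'   gene ids (each pathway non-empty).
#' @param universe character vector of all genes under consideration (must
#'   contain every pathway gene); defaults to the union of pathway genes.
#' @param names optional named character vector of human-readable pathway
#'   names.
#' @return object of class `pathway_map`.
#' @export
pathway_map <- function(pathways, universe = NULL, names = NULL) {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0L)) stop("pathways must be non-empty")
  all_genes <- unique(unlist(pathways, use.names = FALSE))
  if (is.null(universe)) universe <- all_genes
  universe <- unique(as.character(universe))
  outside <- setdiff(all_genes, universe)
  if (length(outside))
    stop("pathway gene(s) outside the universe: ", outside[1])
  if (is.null(names))
    names <- stats::setNames(base::names(pathways), base::names(pathways))
  structure(list(pathways = pathways, universe = universe,
                 pathway_names = names),
            class = "pathway_map")
}

#' Read a pathway membership table
#'
#' TSV with columns `pathway_id`, `pathway_name` (optional) and `gene_ids`
#' (`;`-separated).
#'
#' @param path path to the TSV file.
#' @param universe optional gene universe; defaults to the union of pathway
#'   genes.
#' @return a [pathway_map()].
#' @export
read_pathway_table <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  missing <- setdiff(c("pathway_id", "gene_ids"), names(tab))
  if (length(missing))
    stop("pathway table is missing column(s): ",
         paste(missing, collapse = ", "))
  pw <- lapply(strsplit(tab$gene_ids, ";", fixed = TRUE), trimws)
  names(pw) <- tab$pathway_id
  nm <- if ("pathway_name" %in% names(tab))
    stats::setNames(tab$pathway_name, tab$pathway_id) else NULL
  pathway_map(pw, universe = universe, names = nm)
}

#' One-tailed Fisher's exact p-value for a 2x2 over-representation table
#'
#' Closed form for the upper-tail (over-representation) Fisher's exact test:
#' the hypergeometric survival probability `P(X >= overlap)` of drawing at
#' least `overlap` pathway genes when `n_de` genes are drawn from a universe
#' of `universe_size` genes of which `size` lie in the pathway.
#'
#' @param overlap observed number of DE genes in the pathway.
#' @param size pathway size.
#' @param n_de number of DE genes.
#' @param universe_size number of genes in the universe.
#' @return p-value(s) in (0, 1]; arguments recycle like [stats::phyper()].
#' @export
fisher_pvalue <- function(overlap, size, n_de, universe_size) {
  stats::phyper(overlap - 1L, size, universe_size - size, n_de,
                lower.tail = FALSE)
}

#' One-tailed Fisher's exact pathway over-representation test
#'
#' For each pathway, tests over-representation of the differentially
#' expressed gene set with the one-tailed Fisher's exact test on the 2x2
#' table (in-pathway & DE, in-pathway & not DE, DE & outside, rest), i.e. the
#' hypergeometric upper tail `P(X >= overlap)`.
#'
#' @param de_genes character vector of differentially expressed gene ids;
#'   genes outside the universe are dropped with a warning.
#' @param pathways a [pathway_map()].
#' @param direction optional label (`"up"`/`"down"`) carried into the result.
#' @return data.frame of class `enrichment_result` with columns `pathway`,
#'   `name`, `size`, `overlap`, `p` (and `q` after [storey_qvalue()] /
#'   [bh_adjust()] via [significant_pathways()]).
#' @export
fisher_enrich <- function(de_genes, pathways, direction = NA_character_) {
  stopifnot(inherits(pathways, "pathway_map"))
  de_genes <- unique(as.character(de_genes))
  if (length(pathways$universe) == 0L) stop("empty gene universe")
  outside <- setdiff(de_genes, pathways$universe)
  if (length(outside)) {
    warning(length(outside), " DE gene(s) outside the universe were dropped")
    de_genes <- intersect(de_genes, pathways$universe)
  }
  if (length(de_genes) == 0L) stop("empty DE gene set")
  N <- length(pathways$universe)
  n_de <- length(de_genes)
  ids <- names(pathways$pathways)
  size <- lengths(pathways$pathways)
  overlap <- vapply(pathways$pathways, function(g)
    length(intersect(g, de_genes)), integer(1))
  # hypergeometric upper tail P(X >= overlap) == one-tailed Fisher p
  p <- fisher_pvalue(overlap, size, n_de, N)
  res <- data.frame(pathway = ids,
                    name = unname(pathways$pathway_names[ids]),
                    size = as.integer(size),
                    overlap = as.integer(overlap),
                    p = as.numeric(p),
                    stringsAsFactors = FALSE)
  attr(res, "direction") <- direction
  attr(res, "n_de") <- n_de
  attr(res, "universe_size") <- N
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Storey q-values with a single-lambda pi0 estimate
#'
#' Estimates the null proportion at a fixed lambda,
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))`, and returns
#' `q = pi0 * BH(p)` (monotone by construction of the step-up adjustment).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @return q-values in \[0, 1\], same order as the input.
#' @export
storey_qvalue <- function(pvalues, lambda = 0.5) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  pi0 <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
  pmin(1, pi0 * stats::p.adjust(pvalues, method = "BH"))
}

#' Significantly enriched pathways
#'
#' Adds q-values to an enrichment result, filters at the FDR threshold and
#' sorts by ascending p.
#'
#' @param result a [fisher_enrich()] data.frame.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @param method `"storey"` (default) or `"bh"`.
#' @return data.frame with columns `pathway`, `name`, `size`, `overlap`, `p`,
#'   `q`, rows with `q < fdr` only, sorted by `p`.
#' @export
significant_pathways <- function(result, fdr = 0.05,
                                 method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(inherits(result, "enrichment_result") || is.data.frame(result))
  q <- if (method == "storey") storey_qvalue(result$p) else
    bh_adjust(result$p)
  result$q <- q
  keep <- result[result$q < fdr, , drop = FALSE]
  keep[order(keep$p, keep$pathway), , drop = FALSE]
}
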