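#' Read a per-gene differential-expression score table
#'
#' TSV with columns `gene`, `log2fc` and optionally `pvalue`; an adjusted
#' p-value column `qvalue` is computed by Benjamini--Hochberg when a `pvalue`
#' column is present and `qvalue` is not.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `log2fc` and, when available,
#'   `pvalue` and `qvalue`.
#' @export
read_gene_scores <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(c("gene", "log2fc"), names(tab))
  if (length(missing))
    stop("gene score table is missing column(s): ",
         paste(missing, collapse = ", "))
  gene_score_table(tab)
}

#' Validate a gene score table
#'
#' @param tab data.frame with columns `gene` (unique ids), `log2fc` (finite
#'   signed log2 fold-changes) and optionally `pvalue` in \[0, 1\].
#' @return the validated data.frame, with a `qvalue` column added by
#'   [bh_adjust()] when `pvalue` is present.
#' @export
gene_score_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  missing <- setdiff(c("gene", "log2fc"), names(tab))
  if (length(missing))
    stop("gene score table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab$gene <- as.character(tab$gene)
  if (anyDuplicated(tab$gene)) stop("duplicate gene ids in score table")
  if (!all(is.finite(tab$log2fc))) stop("log2fc must be finite")
  if ("pvalue" %in% names(tab)) {
    if (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE))
      stop("pvalue outside [0, 1]")
    if (!("qvalue" %in% names(tab)))
      tab$qvalue <- bh_adjust(tab$pvalue)
  }
  tab
}

#' Benjamini--Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; output is in the order of the input.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values in \[0, 1\].
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Score a metabolic network from gene expression changes
#'
#' Each reaction receives the arithmetic mean log2 fold-change of its
#' measured associated genes; reactions with no measured gene receive the
#' median of the data-derived reaction scores (and are recorded in
#' `imputed`). Each metabolite receives a negative weight proportional to its
#' connectivity, `w_m = -c * d_m`. With `direction = "down"` all reaction
#' scores are negated after imputation, so that a single maximisation routine
#' finds both up- and down-regulated modules.
#'
#' @param net a [metabolic_network()].
#' @param genes a [gene_score_table()] data.frame.
#' @param direction `"up"` or `"down"`.
#' @param c positive weight constant; the default (`NULL`) calibrates `c` so
#'   that a metabolite of median connectivity costs 10% of one standard
#'   deviation of the reaction scores.
#' @return An object of class `scored_network`: list with `network`,
#'   `reaction_score` (named numeric), `metabolite_weight` (named numeric,
#'   all `<= 0`), `weight_constant`, `imputed` (reaction ids) and
#'   `direction`.
#' @export
score_network <- function(net, genes, direction = c("up", "down"), c = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  direction <- match.arg(direction)
  genes <- gene_score_table(genes)
  if (length(net$reactions) == 0L)
    stop("network has no reactions")
  lfc <- stats::setNames(genes$log2fc, genes$gene)
  s <- vapply(net$reactions, function(r) {
    g <- intersect(net$genes[[r]], names(lfc))
    if (length(g) == 0L) return(NA_real_)
    mean(lfc[g])
  }, numeric(1))
  measured <- !is.na(s)
  if (!any(measured))
    stop("no expression information: every reaction is unmeasured")
  med <- stats::median(s[measured])
  imputed <- names(s)[!measured]
  s[!measured] <- med
  if (direction == "down") s <- -s
  w <- metabolite_weights(net, c = if (is.null(c)) {
    sdev <- stats::sd(s)
    dmed <- stats::median(as.numeric(metabolite_degree(net)))
    if (!is.finite(sdev) || sdev == 0 || dmed == 0) 0.1
    else 0.1 * sdev / dmed
  } else c)
  structure(list(network = net,
                 reaction_score = s,
                 metabolite_weight = w,
                 weight_constant = attr(w, "weight_constant"),
                 imputed = imputed,
                 direction = direction),
            class = "scored_network")
}

#' Connectivity-proportional metabolite weights
#'
#' `w_m = -c * d_m`, where `d_m` is the number of reactions adjacent to
#' metabolite `m`. The negative weights discourage modules from bridging
#' through highly connected currency metabolites unless the expression signal
#' justifies it.
#'
#' @param net a [metabolic_network()].
#' @param c positive constant.
#' @return named numeric vector of weights (`<= 0`), with the constant stored
#'   in attribute `weight_constant`.
#' @export
metabolite_weights <- function(net, c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("weight constant c must be a single positive number")
  d <- metabolite_degree(net)
  w <- -c * as.numeric(d)
  names(w) <- names(d)
  attr(w, "weight_constant") <- c
  w
}

#' Score of a node set
#'
#' The module score is the plain sum of member reaction scores and member
#' metabolite weights; it is additive over disjoint node sets.
#'
#' @param scored a [score_network()] result.
#' @param nodes character vector of node ids (reactions and metabolites).
#' @return numeric score.
#' @export
module_score <- function(scored, nodes) {
  stopifnot(inherits(scored, "scored_network"))
  nodes <- unique(as.character(nodes))
  r <- intersect(nodes, names(scored$reaction_score))
  m <- intersect(nodes, names(scored$metabolite_weight))
  unknown <- setdiff(nodes, c(r, m))
  if (length(unknown)) stop("unknown node id: ", unknown[1])
  sum(scored$reaction_score[r]) + sum(scored$metabolite_weight[m])
}

#' Differentially expressed gene sets
#'
#' Applies the conventional microarray criterion: a gene is called up if its
#' fold-change exceeds `fold_threshold` (log2fc > log2(fold_threshold)) and
#' its FDR-adjusted p-value is below `fdr_threshold`; down analogously.
#' Inequalities are strict on both sides.
#'
#' @param genes a [gene_score_table()] data.frame; a `qvalue` column is
#'   required (computed from `pvalue` by [bh_adjust()] if absent).
#' @param fold_threshold fold-change threshold (> 0), default 2.
#' @param fdr_threshold FDR threshold, default 0.01.
#' @return list with character vectors `up` and `down`.
#' @export
filter_de_genes <- function(genes, fold_threshold = 2, fdr_threshold = 0.01) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 0)
    stop("fold_threshold must be positive")
  genes <- gene_score_table(genes)
  if (!("qvalue" %in% names(genes))) {
    if (!("pvalue" %in% names(genes)))
      stop("gene table has neither qvalue nor pvalue column")
    genes$qvalue <- bh_adjust(genes$pvalue)
  }
  thr <- log2(fold_threshold)
  up <- genes$gene[genes$log2fc > thr & genes$qvalue < fdr_threshold]
  down <- genes$gene[genes$log2fc < -thr & genes$qvalue < fdr_threshold]
  list(up = up, down = down)
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("Scored metabolic network (direction: %s)\n", x$direction))
  cat(sprintf("  reactions: %d (%d median-imputed)\n",
              length(x$reaction_score), length(x$imputed)))
  cat(sprintf("  metabolites: %d, weight constant c = %.4g\n",
              length(x$metabolite_weight), x$weight_constant))
  cat(sprintf("  reaction score range: [%.3g, %.3g]\n",
              min(x$reaction_score), max(x$reaction_score)))
  invisible(x)
}
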