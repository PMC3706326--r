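#' Configuration for an end-to-end analysis run
#'
#' Collects every tunable of the pipeline: input paths (or in-memory
#' objects), the metabolite weight constant, the annealing schedule, the
#' empirical-null size, q-value method and the reporting thresholds. A seed
#' is mandatory; nothing is ever seeded from the wall clock.
#'
#' @param network a [metabolic_network()] or path to a reaction table TSV
#'   (SBML paths ending in `.xml`/`.sbml` are read with [read_sbml()]).
#' @param gene_scores a [gene_score_table()] data.frame or TSV path.
#' @param pathways optional [pathway_map()] or pathway table TSV path; when
#'   absent the enrichment comparison is skipped.
#' @param out_dir optional output directory for the report files.
#' @param c metabolite weight constant (`NULL` = auto-calibrated, see
#'   [score_network()]).
#' @param anneal an [anneal_control()]; defaults to the standard schedule
#'   seeded from `seed`.
#' @param B null samples per module composition (default 1000).
#' @param qvalue_method `"bh"` or `"storey"` for module q-values.
#' @param top_n candidate modules per direction (default 20).
#' @param fold_threshold,gene_fdr DE filter for the enrichment comparison
#'   (defaults 2-fold, 0.01).
#' @param module_fdr,pathway_fdr significance thresholds (defaults 0.05).
#' @param seed integer master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(network, gene_scores, pathways = NULL, out_dir = NULL,
                       c = NULL, anneal = NULL, B = 1000,
                       qvalue_method = c("bh", "storey"), top_n = 20,
                       fold_threshold = 2, gene_fdr = 0.01,
                       module_fdr = 0.05, pathway_fdr = 0.05, seed) {
  if (missing(seed)) stop("an integer seed is required")
  qvalue_method <- match.arg(qvalue_method)
  stopifnot(fold_threshold > 0, gene_fdr > 0, gene_fdr < 1,
            module_fdr > 0, module_fdr < 1, pathway_fdr > 0, pathway_fdr < 1,
            top_n >= 1, B >= 100)
  if (is.null(anneal)) anneal <- anneal_control(seed = seed)
  structure(list(network = network, gene_scores = gene_scores,
                 pathways = pathways, out_dir = out_dir, c = c,
                 anneal = anneal, B = B, qvalue_method = qvalue_method,
                 top_n = top_n, fold_threshold = fold_threshold,
                 gene_fdr = gene_fdr, module_fdr = module_fdr,
                 pathway_fdr = pathway_fdr, seed = as.integer(seed)),
            class = "run_config")
}

resolve_network <- function(x) {
  if (inherits(x, "metabolic_network")) return(x)
  if (is.character(x)) {
    if (grepl("\\.(xml|sbml)$", x, ignore.case = TRUE)) return(read_sbml(x))
    return(read_reaction_table(x))
  }
  stop("network must be a metabolic_network or a file path")
}

#' Run the full active-module analysis
#'
#' Stages, in order: load the network; score it in the up direction; anneal;
#' extract the top candidate modules; set aside modules without expression
#' evidence; attach empirical significance; repeat for the down direction;
#' correct both families together; run the pathway-enrichment comparison on
#' the strict DE gene sets (skipped with a log entry when a direction has no
#' DE genes or no pathway map is given); write the report files. The same
#' configuration always produces byte-identical tabular outputs.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_result` with `up`/`down`
#'   (`active_modules`), `module_table` (combined data.frame),
#'   `enrichment_up`/`enrichment_down` (full tables, or `NULL`),
#'   `significant_pathways`, `de_genes`, `log` (character vector) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character()
  files <- character()
  note <- function(...) log <<- c(log, paste0(...))
  on_error <- function(stage) function(e) {
    if (length(files)) unlink(files)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  net <- tryCatch(resolve_network(cfg$network), error = on_error("load_network"))
  note("network: ", length(net$reactions), " reactions, ",
       length(net$metabolites), " metabolites, ", nrow(net$edges), " edges")
  genes <- tryCatch({
    if (is.character(cfg$gene_scores)) read_gene_scores(cfg$gene_scores)
    else gene_score_table(cfg$gene_scores)
  }, error = on_error("load_gene_scores"))
  note("gene scores: ", nrow(genes), " genes; master seed ", cfg$seed)

  fams <- list()
  cache_note <- NULL
  for (dir in c("up", "down")) {
    fams[[dir]] <- tryCatch({
      scored <- score_network(net, genes, direction = dir, c = cfg$c)
      note(sprintf("%s: c = %.6g, %d imputed reactions", dir,
                   scored$weight_constant, length(scored$imputed)))
      ctl <- cfg$anneal
      ctl$seed <- ctl$seed + if (dir == "up") 0L else 500000L
      am <- find_active_modules(scored, ctl, top_n = cfg$top_n)
      note(sprintf("%s: t0 = %.6g, alpha = %.3g, %d temps x %d steps x %d restarts, anneal seed %d, objective %.6g",
                   dir, am$control$t0, am$control$alpha, am$control$n_temps,
                   am$control$steps_per_temp, am$control$restarts,
                   ctl$seed, am$objective))
      note(sprintf("%s: %d candidate modules, %d excluded (no expression evidence)",
                   dir, length(am$modules) + length(am$excluded),
                   length(am$excluded)))
      am <- assess_significance(am, B = cfg$B,
                                seed = cfg$seed + if (dir == "up") 1000L
                                       else 2000L)
      note(sprintf("%s: empirical null B = %d", dir, cfg$B))
      am
    }, error = on_error(paste0("modules_", dir)))
  }
  qq <- tryCatch(
    module_qvalues(fams$up, fams$down, method = cfg$qvalue_method,
                   fdr = cfg$module_fdr),
    error = on_error("module_qvalues"))
  fams$up <- qq[[1]]; fams$down <- qq[[2]]
  note("module q-values: method ", cfg$qvalue_method,
       ", families corrected together (m = ",
       length(fams$up$modules) + length(fams$down$modules), ")")

  de <- tryCatch(
    filter_de_genes(genes, cfg$fold_threshold, cfg$gene_fdr),
    error = on_error("de_filter"))
  note("DE filter: >", cfg$fold_threshold, "-fold, q < ", cfg$gene_fdr,
       " -> ", length(de$up), " up, ", length(de$down), " down")

  enr <- list(up = NULL, down = NULL)
  sig_pw <- list(up = NULL, down = NULL)
  if (!is.null(cfg$pathways)) {
    pmap <- tryCatch({
      if (is.character(cfg$pathways)) read_pathway_table(cfg$pathways)
      else cfg$pathways
    }, error = on_error("load_pathways"))
    for (dir in c("up", "down")) {
      if (length(de[[dir]]) == 0L) {
        note("enrichment (", dir, "): skipped, no DE genes")
        next
      }
      enr[[dir]] <- tryCatch(
        fisher_enrich(de[[dir]], pmap, direction = dir),
        error = on_error(paste0("enrichment_", dir)))
      sig_pw[[dir]] <- significant_pathways(
        enr[[dir]], fdr = cfg$pathway_fdr,
        method = if (cfg$qvalue_method == "bh") "bh" else "storey")
      note("enrichment (", dir, "): ", nrow(sig_pw[[dir]]),
           " pathway(s) at q < ", cfg$pathway_fdr)
    }
  } else note("enrichment: skipped, no pathway map")

  mt <- rbind(module_table(fams$up, B = cfg$B),
              module_table(fams$down, B = cfg$B))
  res <- structure(list(up = fams$up, down = fams$down, module_table = mt,
                        enrichment_up = enr$up, enrichment_down = enr$down,
                        significant_pathways = sig_pw, de_genes = de,
                        log = log, files = files, config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    res <- tryCatch({
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      f_mod <- file.path(cfg$out_dir, "modules.tsv")
      utils::write.table(mt, f_mod, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- f_mod
      for (dir in c("up", "down")) {
        if (!is.null(sig_pw[[dir]])) {
          f <- file.path(cfg$out_dir, paste0("enrichment_", dir, ".tsv"))
          out <- sig_pw[[dir]]
          out$p <- sprintf("%.6g", out$p)
          out$q <- sprintf("%.6g", out$q)
          utils::write.table(out, f, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          files <- c(files, f)
        }
      }
      f_log <- file.path(cfg$out_dir, "run_log.txt")
      writeLines(log, f_log)
      files <- c(files, f_log)
      res$files <- files
      res
    }, error = on_error("write_reports"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Active-module analysis\n")
  cat(sprintf("  up:   %d modules (%d significant at q < %g)\n",
              length(x$up$modules),
              sum(vapply(x$up$modules, `[[`, numeric(1), "q") <
                    x$config$module_fdr),
              x$config$module_fdr))
  cat(sprintf("  down: %d modules (%d significant at q < %g)\n",
              length(x$down$modules),
              sum(vapply(x$down$modules, `[[`, numeric(1), "q") <
                    x$config$module_fdr),
              x$config$module_fdr))
  cat(sprintf("  DE genes: %d up, %d down\n",
              length(x$de_genes$up), length(x$de_genes$down)))
  invisible(x)
}

# q-value display: fixed floor notation when the empirical p sits at its
# Monte-Carlo minimum 1/(B+1) the q is only an upper bound, printed "<x".
format_qvalue <- function(q, p, B) {
  at_floor <- !is.na(p) & abs(p - 1 / (B + 1)) < 1e-12
  txt <- signif(q, 2)
  out <- as.character(txt)
  out[at_floor] <- paste0("<", format(signif(1 / (B + 1), 2),
                                      scientific = FALSE, trim = TRUE))
  out[is.na(q)] <- NA_character_
  out
}

#' Format a ranked module report table
#'
#' One row per module, ids `u1..uN` / `d1..dN` by rank; q-values to two
#' significant figures, with `<` notation when the empirical p-value sits at
#' the Monte-Carlo floor `1/(B+1)` (the q is then only an upper bound); the
#' free-text label column is left to the analyst.
#'
#' @param am an `active_modules` object (p and q filled).
#' @param B the null size used, for the floor notation; defaults to `am$B`.
#' @return data.frame with columns `module`, `q_value`, `score`,
#'   `n_reactions`, `n_metabolites`, `n_reactions_with_genes`, `label`.
#' @export
module_table <- function(am, B = am$B) {
  stopifnot(inherits(am, "active_modules"))
  mods <- am$modules
  prefix <- if (am$direction == "up") "u" else "d"
  p <- vapply(mods, `[[`, numeric(1), "p_empirical")
  q <- vapply(mods, `[[`, numeric(1), "q")
  data.frame(
    module = if (length(mods)) paste0(prefix, seq_along(mods)) else character(),
    q_value = format_qvalue(q, p, B),
    score = round(vapply(mods, `[[`, numeric(1), "score"), 4),
    n_reactions = vapply(mods, `[[`, integer(1), "n_reactions"),
    n_metabolites = vapply(mods, `[[`, integer(1), "n_metabolites"),
    n_reactions_with_genes = vapply(mods, `[[`, integer(1),
                                    "n_reactions_with_genes"),
    label = vapply(mods, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
}

#' Export a module (or any node set) as GraphML and SIF
#'
#' Node attributes: `node_type` (reaction/metabolite), `score` (reaction
#' score or metabolite weight) and `imputed`; the edge list is undirected.
#' With `extended = TRUE` the module is first closed over all metabolites
#' adjacent to its reactions ([extend_module()]).
#'
#' @param scored a [score_network()] result.
#' @param module a module record.
#' @param basename output path without extension; writes `basename.graphml`
#'   and `basename.sif`.
#' @param extended apply [extend_module()] first (default `FALSE`).
#' @return character vector of the two paths written, invisibly.
#' @export
export_module_graph <- function(scored, module, basename, extended = FALSE) {
  stopifnot(inherits(scored, "scored_network"))
  net <- scored$network
  nodes <- if (extended) {
    e <- extend_module(net, module)
    c(e$reaction_ids, e$metabolite_ids)
  } else c(module$reaction_ids, module$metabolite_ids)
  g <- igraph::induced_subgraph(as_igraph(net), nodes)
  vn <- igraph::V(g)$name
  sc <- ifelse(vn %in% names(scored$reaction_score),
               scored$reaction_score[vn], scored$metabolite_weight[vn])
  igraph::V(g)$score <- as.numeric(sc)
  igraph::V(g)$imputed <- vn %in% scored$imputed
  f_gml <- paste0(basename, ".graphml")
  f_sif <- paste0(basename, ".sif")
  igraph::write_graph(g, f_gml, format = "graphml")
  el <- igraph::as_edgelist(g)
  writeLines(if (nrow(el)) paste(el[, 1], "rm", el[, 2]) else character(),
             f_sif)
  invisible(c(f_gml, f_sif))
}

#' Export a whole network as GraphML and SIF
#'
#' @param net a [metabolic_network()].
#' @param basename output path without extension.
#' @return character vector of the two paths written, invisibly.
#' @export
export_network_graph <- function(net, basename) {
  stopifnot(inherits(net, "metabolic_network"))
  g <- as_igraph(net)
  f_gml <- paste0(basename, ".graphml")
  f_sif <- paste0(basename, ".sif")
  igraph::write_graph(g, f_gml, format = "graphml")
  el <- igraph::as_edgelist(g)
  writeLines(if (nrow(el)) paste(el[, 1], "rm", el[, 2]) else character(),
             f_sif)
  invisible(c(f_gml, f_sif))
}
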