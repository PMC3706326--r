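#' Annealing schedule and budget
#'
#' The search runs `restarts` independent annealing chains; restart `r` is
#' seeded with `seed + r` so the whole run is reproducible. Within a chain
#' the temperature follows `T_k = t0 * alpha^k` over `n_temps` levels with
#' `steps_per_temp` single-node toggle proposals at each level.
#'
#' @param t0 initial temperature (> 0); `NULL` defaults to the standard
#'   deviation of the reaction scores at run time.
#' @param alpha geometric cooling factor in (0, 1).
#' @param n_temps number of temperature levels.
#' @param steps_per_temp proposals per level; `NULL` defaults to 10 times the
#'   number of network nodes.
#' @param restarts number of independent chains.
#' @param seed integer seed (mandatory; no wall-clock seeding).
#' @return list of class `anneal_control`.
#' @export
anneal_control <- function(t0 = NULL, alpha = 0.95, n_temps = 100,
                           steps_per_temp = NULL, restarts = 3, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required")
  if (!is.null(t0) && (!is.numeric(t0) || t0 <= 0))
    stop("t0 must be positive")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (n_temps < 1 || restarts < 1)
    stop("n_temps and restarts must be positive counts")
  if (!is.null(steps_per_temp) && steps_per_temp < 1)
    stop("steps_per_temp must be a positive count")
  structure(list(t0 = t0, alpha = alpha, n_temps = as.integer(n_temps),
                 steps_per_temp = if (is.null(steps_per_temp)) NULL
                                  else as.integer(steps_per_temp),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "anneal_control")
}

# CSR adjacency over nodes ordered c(reactions, metabolites); 0-based.
build_csr <- function(net) {
  nodes <- c(net$reactions, net$metabolites)
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  from <- c(idx[net$edges$reaction], idx[net$edges$metabolite])
  to <- c(idx[net$edges$metabolite], idx[net$edges$reaction])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  ptr <- c(0L, cumsum(tabulate(from + 1L, nbins = length(nodes))))
  list(nodes = nodes, adj = as.integer(to), ptr = as.integer(ptr),
       idx = idx)
}

#' Simulated-annealing search for high-scoring connected subnetworks
#'
#' Searches binary on/off states over all network nodes. The objective is the
#' total score of the `top_k` highest-scoring connected components of the
#' on-subgraph, each clamped at zero: components whose total is negative
#' contribute nothing, and the searcher is free to drop them. Whenever the
#' state holds at most `top_k` positive components this equals the plain sum
#' of positive component scores; the cap is what makes bundling positive
#' reactions into connected modules (paying the metabolite weights) pay off,
#' and it matches what the analysis reports — the `top_k` best modules. The
#' best state ever visited across all restarts is returned; the same seed
#' always yields the same result.
#'
#' @param scored a [score_network()] result.
#' @param control an [anneal_control()].
#' @param top_k number of components counted by the objective (default 20,
#'   the number of modules reported per direction).
#' @return list with `nodes` (character ids of the on-state), `objective`
#'   (best objective attained) and the resolved `control`.
#' @export
anneal <- function(scored, control, top_k = 20) {
  stopifnot(inherits(scored, "scored_network"),
            inherits(control, "anneal_control"))
  net <- scored$network
  if (length(net$reactions) + length(net$metabolites) == 0L)
    stop("network is empty")
  csr <- build_csr(net)
  sc <- c(scored$reaction_score[net$reactions],
          scored$metabolite_weight[net$metabolites])
  n <- length(csr$nodes)
  t0 <- control$t0
  if (is.null(t0)) {
    t0 <- stats::sd(scored$reaction_score)
    if (!is.finite(t0) || t0 <= 0) t0 <- 1
  }
  spt <- control$steps_per_temp
  if (is.null(spt)) spt <- 10L * n
  best <- NULL
  for (r in seq_len(control$restarts)) {
    set.seed(control$seed + r)
    res <- anneal_run(csr$adj, csr$ptr, as.numeric(sc),
                      t0, control$alpha, control$n_temps, spt,
                      as.integer(top_k))
    if (is.null(best) || res$objective > best$objective + 1e-12) best <- res
  }
  list(nodes = csr$nodes[best$state],
       objective = best$objective,
       control = utils::modifyList(unclass(control),
                                   list(t0 = t0, steps_per_temp = spt)))
}

# construct one module record from a node id vector
make_module <- function(scored, ids, direction) {
  net <- scored$network
  r <- sort(intersect(ids, net$reactions))
  m <- sort(intersect(ids, net$metabolites))
  list(reaction_ids = r,
       metabolite_ids = m,
       score = module_score(scored, c(r, m)),
       direction = direction,
       n_reactions = length(r),
       n_metabolites = length(m),
       n_reactions_with_genes = length(setdiff(r, scored$imputed)),
       p_empirical = NA_real_,
       q = NA_real_,
       label = "")
}

#' Extract ranked modules from an annealing on-state
#'
#' The connected components of the on-state are scored, ranked (score
#' descending, then number of reactions descending, then smallest reaction id)
#' and truncated to the `top_n` best.
#'
#' @param scored a [score_network()] result.
#' @param on_state character vector of node ids (from [anneal()]).
#' @param top_n maximum number of modules to keep (default 20 per direction).
#' @return list of module records.
#' @export
extract_modules <- function(scored, on_state, top_n = 20) {
  stopifnot(inherits(scored, "scored_network"))
  comps <- network_components(scored$network, on_state)
  mods <- lapply(comps, function(cp)
    make_module(scored, c(cp$reaction_ids, cp$metabolite_ids),
                scored$direction))
  if (length(mods) == 0L) return(list())
  sc <- vapply(mods, `[[`, numeric(1), "score")
  nr <- vapply(mods, `[[`, numeric(1), "n_reactions")
  first_r <- vapply(mods, function(m)
    if (length(m$reaction_ids)) m$reaction_ids[1] else "\uffff", character(1))
  mods <- mods[order(-sc, -nr, first_r)]
  mods[seq_len(min(top_n, length(mods)))]
}

#' Exclude modules with no expression evidence
#'
#' Modules in which every reaction was median-imputed carry no experimental
#' information about the response and are set aside.
#'
#' @param modules list of module records.
#' @return list with `kept` and `excluded`, input order preserved.
#' @export
exclude_unsupported <- function(modules) {
  if (length(modules) == 0L) return(list(kept = list(), excluded = list()))
  supported <- vapply(modules, function(m) m$n_reactions_with_genes > 0,
                      logical(1))
  list(kept = modules[supported], excluded = modules[!supported])
}

#' Merge modules through a shared bridging metabolite
#'
#' Combines modules that a highly connected metabolite (e.g. hydrogen
#' peroxide) links together: the union of their nodes plus the bridge is
#' rescored, paying the bridge's connectivity penalty exactly once.
#'
#' @param scored a [score_network()] result.
#' @param modules list of module records to merge.
#' @param bridge metabolite id adjacent to at least one reaction in each
#'   module.
#' @return a single merged module record.
#' @export
merge_modules <- function(scored, modules, bridge) {
  stopifnot(inherits(scored, "scored_network"), length(modules) >= 1L)
  net <- scored$network
  if (!(bridge %in% net$metabolites)) stop("unknown metabolite id: ", bridge)
  adj_r <- net$edges$reaction[net$edges$metabolite == bridge]
  for (i in seq_along(modules)) {
    if (!length(intersect(modules[[i]]$reaction_ids, adj_r)))
      stop("bridge metabolite '", bridge,
           "' is not adjacent to any reaction of module ", i)
  }
  ids <- unique(c(unlist(lapply(modules, function(m)
    c(m$reaction_ids, m$metabolite_ids))), bridge))
  comps <- network_components(net, ids)
  if (length(comps) != 1L)
    stop("merged node set is not connected")
  make_module(scored, ids, modules[[1]]$direction)
}

#' Extend a module to all adjacent metabolites
#'
#' Adds every metabolite adjacent to any member reaction; reactions are
#' unchanged. Used to draw modules in their metabolic context (shared
#' substrates/products across modules); extended sets are never rescored for
#' significance.
#'
#' @param net a [metabolic_network()].
#' @param module a module record.
#' @return list with `reaction_ids` and `metabolite_ids`.
#' @export
extend_module <- function(net, module) {
  stopifnot(inherits(net, "metabolic_network"))
  adj <- net$edges$metabolite[net$edges$reaction %in% module$reaction_ids]
  list(reaction_ids = module$reaction_ids,
       metabolite_ids = sort(unique(c(module$metabolite_ids, adj))))
}

#' Find active modules in a scored metabolic network
#'
#' The central fitting function: runs the simulated-annealing search on a
#' scored network, extracts the top-ranked connected components as candidate
#' modules and sets aside modules with no expression evidence. Empirical
#' significance can then be added with [assess_significance()].
#'
#' @param scored a [score_network()] result.
#' @param control an [anneal_control()]; `seed` is mandatory.
#' @param top_n maximum number of candidate modules (default 20, one
#'   module list per direction).
#' @return An object of class `active_modules`: list with `modules` (kept
#'   module records), `excluded`, `direction`, `objective`, `control` and
#'   `scored`.
#' @export
find_active_modules <- function(scored, control, top_n = 20) {
  res <- anneal(scored, control, top_k = top_n)
  mods <- extract_modules(scored, res$nodes, top_n = top_n)
  ex <- exclude_unsupported(mods)
  structure(list(modules = ex$kept,
                 excluded = ex$excluded,
                 direction = scored$direction,
                 objective = res$objective,
                 control = res$control,
                 scored = scored),
            class = "active_modules")
}

#' @export
print.active_modules <- function(x, ...) {
  cat(sprintf("Active modules (%s-regulated): %d kept, %d excluded (no expression evidence)\n",
              x$direction, length(x$modules), length(x$excluded)))
  cat(sprintf("  annealing objective: %.4g\n", x$objective))
  df <- as.data.frame(x)
  if (nrow(df)) print(utils::head(df, 10), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.active_modules <- function(x, ...) {
  mods <- x$modules
  prefix <- if (x$direction == "up") "u" else "d"
  data.frame(
    module = if (length(mods)) paste0(prefix, seq_along(mods)) else character(),
    score = vapply(mods, `[[`, numeric(1), "score"),
    p_empirical = vapply(mods, `[[`, numeric(1), "p_empirical"),
    q_value = vapply(mods, `[[`, numeric(1), "q"),
    n_reactions = vapply(mods, `[[`, numeric(1), "n_reactions"),
    n_metabolites = vapply(mods, `[[`, numeric(1), "n_metabolites"),
    n_reactions_with_genes = vapply(mods, `[[`, numeric(1),
                                    "n_reactions_with_genes"),
    label = vapply(mods, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
}

#' @export
summary.active_modules <- function(object, ...) {
  df <- as.data.frame(object)
  res <- list(direction = object$direction,
              n_modules = nrow(df),
              n_excluded = length(object$excluded),
              n_significant = sum(df$q_value < 0.05, na.rm = TRUE),
              table = df)
  class(res) <- "summary.active_modules"
  res
}

#' @export
print.summary.active_modules <- function(x, ...) {
  cat(sprintf("%d %s-regulated module(s), %d excluded, %d significant at q < 0.05\n",
              x$n_modules, x$direction, x$n_excluded, x$n_significant))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.active_modules <- function(x, which = 1, extended = FALSE, ...) {
  if (length(x$modules) < which) stop("no module at rank ", which)
  m <- x$modules[[which]]
  ids <- if (extended) {
    e <- extend_module(x$scored$network, m)
    c(e$reaction_ids, e$metabolite_ids)
  } else c(m$reaction_ids, m$metabolite_ids)
  plot(x$scored$network, nodes = ids, ...)
  invisible(x)
}
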