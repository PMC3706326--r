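#' Sample a null score distribution for a module composition
#'
#' Draws `B` connected node sets with exactly the requested numbers of
#' reactions and metabolites by seeded random growth: start at a uniformly
#' random node of a type still needed, then repeatedly add a uniformly random
#' frontier neighbour of a type still needed; dead ends trigger a restart.
#' Each sampled set is scored with [module_score()]. Observed modules are
#' connected, so the matched null is drawn over connected sets too; an
#' unconnected variant (independent uniform draws of reactions and
#' metabolites) is available for comparison.
#'
#' @param scored a [score_network()] result.
#' @param composition integer vector `c(n_reactions, n_metabolites)`.
#' @param B number of null samples (>= 100).
#' @param seed integer seed.
#' @param connected sample connected sets (default `TRUE`).
#' @param max_tries growth attempts before declaring the composition
#'   infeasible.
#' @return object of class `null_distribution`: list with `composition`,
#'   `samples` (numeric of length `B`), `B` and `seed`.
#' @export
sample_null <- function(scored, composition, B = 1000, seed,
                        connected = TRUE, max_tries = 1000 * B) {
  stopifnot(inherits(scored, "scored_network"))
  if (missing(seed)) stop("an integer seed is required")
  if (B < 100) stop("B must be at least 100")
  nr <- as.integer(composition[1]); nm <- as.integer(composition[2])
  if (nr < 0 || nm < 0 || nr + nm == 0) stop("invalid composition")
  net <- scored$network
  if (nr > length(net$reactions) || nm > length(net$metabolites))
    stop("composition infeasible: not enough nodes of the required type")
  set.seed(seed)
  if (!connected) {
    samples <- vapply(seq_len(B), function(i) {
      ids <- c(sample(net$reactions, nr), sample(net$metabolites, nm))
      module_score(scored, ids)
    }, numeric(1))
    return(structure(list(composition = c(nr, nm), samples = samples,
                          B = B, seed = seed, connected = FALSE),
                     class = "null_distribution"))
  }
  # adjacency lists over integer node indices; reactions first
  csr <- build_csr(net)
  n_r <- length(net$reactions)
  n_all <- length(csr$nodes)
  is_reaction <- seq_len(n_all) <= n_r
  neighbours <- lapply(seq_len(n_all), function(i)
    csr$adj[(csr$ptr[i] + 1L):csr$ptr[i + 1L]] + 1L)
  neighbours[csr$ptr[-1] == csr$ptr[-length(csr$ptr)]] <- list(integer())
  score_vec <- c(scored$reaction_score[net$reactions],
                 scored$metabolite_weight[net$metabolites])
  samples <- numeric(B)
  got <- 0L
  tries <- 0L
  while (got < B) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("composition (", nr, ", ", nm,
           ") appears infeasible: no connected set found after ",
           max_tries, " attempts")
    need_r <- nr; need_m <- nm
    pool <- c(if (need_r > 0) which(is_reaction),
              if (need_m > 0) which(!is_reaction))
    v <- pool[sample.int(length(pool), 1L)]
    members <- v
    if (is_reaction[v]) need_r <- need_r - 1L else need_m <- need_m - 1L
    frontier <- setdiff(neighbours[[v]], members)
    ok <- TRUE
    while (need_r + need_m > 0L) {
      cand <- frontier[(is_reaction[frontier] & need_r > 0L) |
                       (!is_reaction[frontier] & need_m > 0L)]
      if (length(cand) == 0L) { ok <- FALSE; break }
      u <- cand[sample.int(length(cand), 1L)]
      members <- c(members, u)
      if (is_reaction[u]) need_r <- need_r - 1L else need_m <- need_m - 1L
      frontier <- setdiff(union(frontier, neighbours[[u]]), members)
    }
    if (!ok) next
    got <- got + 1L
    samples[got] <- sum(score_vec[members])
  }
  structure(list(composition = c(nr, nm), samples = samples, B = B,
                 seed = seed, connected = TRUE),
            class = "null_distribution")
}

#' Empirical one-sided p-value of a module score
#'
#' Monte-Carlo p-value with add-one correction:
#' `p = (#\{null >= observed\} + 1) / (B + 1)`; large scores are significant
#' and p can never be exactly zero (its floor is `1/(B+1)`).
#'
#' @param observed observed module score.
#' @param null a [sample_null()] result.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$samples) == 0L) stop("empty null distribution")
  (sum(null$samples >= observed) + 1) / (null$B + 1)
}

#' Attach empirical p-values to active modules
#'
#' Samples (and caches, keyed by composition) a null distribution for each
#' module's (reactions, metabolites) composition and computes the one-sided
#' empirical p-value of its score. Distinct compositions use seeds
#' `seed + rank of the composition`, so a run is reproducible end to end.
#'
#' @param am an [find_active_modules()] result (or a plain list of module
#'   records together with `scored`).
#' @param B null samples per composition (default 1000).
#' @param seed integer seed.
#' @param scored the generating [score_network()] result; defaults to
#'   `am$scored`.
#' @param cache optional environment carrying previously sampled null
#'   distributions across calls (e.g. across the up and down families).
#' @return `am` with `p_empirical` filled on every module, plus the attribute
#'   `B`.
#' @export
assess_significance <- function(am, B = 1000, seed, scored = am$scored,
                                cache = new.env(parent = emptyenv())) {
  if (missing(seed)) stop("an integer seed is required")
  mods <- if (inherits(am, "active_modules")) am$modules else am
  if (length(mods)) {
    keys <- vapply(mods, function(m)
      paste(m$n_reactions, m$n_metabolites, sep = "_"), character(1))
    for (k in sort(unique(keys))) {
      if (!exists(k, envir = cache, inherits = FALSE)) {
        comp <- as.integer(strsplit(k, "_")[[1]])
        off <- match(k, sort(unique(keys)))
        assign(k, sample_null(scored, comp, B = B, seed = seed + off),
               envir = cache)
      }
    }
    for (i in seq_along(mods)) {
      nd <- get(keys[i], envir = cache, inherits = FALSE)
      mods[[i]]$p_empirical <- empirical_pvalue(mods[[i]]$score, nd)
    }
  }
  if (inherits(am, "active_modules")) {
    am$modules <- mods
    am$B <- B
    am
  } else structure(mods, B = B)
}

#' Multiple-testing correction across module families
#'
#' Corrects the empirical p-values of one or more module families together
#' (up- and down-regulated modules from the same run share one correction)
#' and flags significance at `q < fdr`.
#'
#' @param ... one or more `active_modules` objects (or lists of module
#'   records) with `p_empirical` filled.
#' @param method `"bh"` (Benjamini--Hochberg, default) or `"storey"`.
#' @param fdr significance threshold on q (default 0.05).
#' @return the input objects, q filled, returned as a list in input order
#'   (a single input is returned unwrapped).
#' @export
module_qvalues <- function(..., method = c("bh", "storey"), fdr = 0.05) {
  method <- match.arg(method)
  objs <- list(...)
  modlists <- lapply(objs, function(o)
    if (inherits(o, "active_modules")) o$modules else o)
  p <- unlist(lapply(modlists, function(ms)
    vapply(ms, `[[`, numeric(1), "p_empirical")))
  if (length(p) && anyNA(p))
    stop("p_empirical missing on some modules; run assess_significance first")
  q <- if (length(p) == 0L) numeric() else
    if (method == "bh") bh_adjust(p) else storey_qvalue(p)
  k <- 0L
  for (j in seq_along(modlists)) {
    for (i in seq_along(modlists[[j]])) {
      k <- k + 1L
      modlists[[j]][[i]]$q <- q[k]
      modlists[[j]][[i]]$significant <- q[k] < fdr
    }
    if (inherits(objs[[j]], "active_modules")) objs[[j]]$modules <- modlists[[j]]
    else objs[[j]] <- modlists[[j]]
  }
  if (length(objs) == 1L) objs[[1]] else objs
}
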