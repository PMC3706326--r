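# Internal: adjacency index over nodes ordered c(reactions, metabolites).
adjacency_index <- function(net) {
  csr <- build_csr(net)
  n_all <- length(csr$nodes)
  neigh <- lapply(seq_len(n_all), function(i) {
    if (csr$ptr[i] == csr$ptr[i + 1L]) integer() else
      csr$adj[(csr$ptr[i] + 1L):csr$ptr[i + 1L]] + 1L
  })
  list(nodes = csr$nodes, neighbours = neigh,
       is_reaction = seq_len(n_all) <= length(net$reactions))
}

# Internal: grow one connected node set of composition (nr reactions,
# nm metabolites) by uniform frontier expansion; NULL on dead end.
# Uses the current RNG stream.
random_connected_set <- function(ai, nr, nm) {
  need_r <- nr; need_m <- nm
  pool <- c(if (need_r > 0L) which(ai$is_reaction),
            if (need_m > 0L) which(!ai$is_reaction))
  v <- pool[sample.int(length(pool), 1L)]
  members <- v
  if (ai$is_reaction[v]) need_r <- need_r - 1L else need_m <- need_m - 1L
  frontier <- setdiff(ai$neighbours[[v]], members)
  while (need_r + need_m > 0L) {
    cand <- frontier[(ai$is_reaction[frontier] & need_r > 0L) |
                     (!ai$is_reaction[frontier] & need_m > 0L)]
    if (length(cand) == 0L) return(NULL)
    u <- cand[sample.int(length(cand), 1L)]
    members <- c(members, u)
    if (ai$is_reaction[u]) need_r <- need_r - 1L else need_m <- need_m - 1L
    frontier <- setdiff(union(frontier, ai$neighbours[[u]]), members)
  }
  members
}

#' Generate a draft-quality synthetic bipartite metabolic network
#'
#' Emulates the shape of an automatically reconstructed genome-scale model:
#' each reaction is linked to 2--4 ordinary metabolites by degree-biased
#' attachment (a right-skewed metabolite degree distribution), a small set of
#' currency metabolites (water/ATP-like hubs) is attached until each reaches
#' exactly `currency_degree` reactions, and a bridging pass guarantees a
#' single connected component without touching the currency hubs. By default
#' each reaction carries one gene, with 10% of reactions left gene-less to
#' exercise median imputation downstream.
#'
#' @param n_reactions number of reactions.
#' @param n_metabolites number of ordinary (non-currency) metabolites.
#' @param mean_degree target mean number of ordinary metabolites per reaction,
#'   in \[2, 4\] (default 3).
#' @param n_currency number of currency metabolites (default 3).
#' @param currency_degree exact reaction-degree of each currency metabolite
#'   (default 12; must be `>= mean_degree` and `<= n_reactions`).
#' @param geneless_fraction fraction of reactions without gene associations
#'   (default 0.1).
#' @param seed integer seed; the same seed reproduces the same edge set.
#' @return a [metabolic_network()].
#' @export
generate_network <- function(n_reactions, n_metabolites, mean_degree = 3,
                             n_currency = 3, currency_degree = 12,
                             geneless_fraction = 0.1, seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (n_reactions < 1 || n_metabolites < 2 || n_currency < 0)
    stop("node counts must be positive")
  if (mean_degree < 2 || mean_degree > 4)
    stop("mean_degree must lie in [2, 4]")
  if (n_currency > 0 && currency_degree < mean_degree)
    stop("currency_degree must be at least mean_degree")
  if (n_currency > 0 && currency_degree > n_reactions)
    stop("currency_degree exceeds the number of reactions")
  set.seed(seed)
  rxn <- sprintf("R%04d", seq_len(n_reactions))
  met <- sprintf("M%04d", seq_len(n_metabolites))
  cur <- if (n_currency > 0) sprintf("CUR%02d", seq_len(n_currency))
         else character()
  # per-reaction ordinary-metabolite count: mixture over {2,3,4} hitting the
  # target mean (degenerate at the boundaries)
  p2 <- if (mean_degree <= 7 / 3) NA else min(max((11 / 3 - mean_degree) / 2, 0), 2 / 3)
  ks <- if (mean_degree <= 7 / 3 || mean_degree >= 11 / 3) {
    pmin(pmax(round(stats::runif(n_reactions, mean_degree - 0.5,
                                 mean_degree + 0.5)), 2L), 4L)
  } else {
    sample(2:4, n_reactions, replace = TRUE, prob = c(p2, 1 / 3, 2 / 3 - p2))
  }
  deg <- rep(0L, n_metabolites)
  e_r <- vector("list", n_reactions)
  for (i in seq_len(n_reactions)) {
    k <- min(ks[i], n_metabolites)
    picked <- sample.int(n_metabolites, k, prob = deg + 1)
    deg[picked] <- deg[picked] + 1L
    e_r[[i]] <- picked
  }
  edges <- data.frame(reaction = rep(rxn, lengths(e_r)),
                      metabolite = met[unlist(e_r)],
                      stringsAsFactors = FALSE)
  for (j in seq_along(cur)) {
    attach_to <- sample.int(n_reactions, currency_degree)
    edges <- rbind(edges, data.frame(reaction = rxn[attach_to],
                                     metabolite = cur[j],
                                     stringsAsFactors = FALSE))
  }
  # bridging pass: connect minor components to the giant one via ordinary
  # metabolites only, keeping currency degrees exact
  repeat {
    net_tmp <- metabolic_network(rxn, c(met, cur), edges)
    comps <- network_components(net_tmp, c(rxn, met, cur))
    if (length(comps) <= 1L) break
    giant <- comps[[1]]
    giant_mets <- setdiff(giant$metabolite_ids, cur)
    giant_rxns <- giant$reaction_ids
    for (cp in comps[-1]) {
      if (length(cp$reaction_ids)) {
        r <- cp$reaction_ids[sample.int(length(cp$reaction_ids), 1L)]
        m <- giant_mets[sample.int(length(giant_mets), 1L)]
      } else {
        ords <- setdiff(cp$metabolite_ids, cur)
        if (!length(ords)) next  # currency-only component cannot arise
        m <- ords[sample.int(length(ords), 1L)]
        r <- giant_rxns[sample.int(length(giant_rxns), 1L)]
      }
      edges <- rbind(edges, data.frame(reaction = r, metabolite = m,
                                       stringsAsFactors = FALSE))
    }
  }
  genes <- stats::setNames(lapply(rxn, function(r) paste0("g_", r)), rxn)
  n_off <- floor(geneless_fraction * n_reactions)
  if (n_off > 0) {
    off <- sample.int(n_reactions, n_off)
    genes[off] <- list(character())
  }
  metabolic_network(rxn, c(met, cur), edges, genes)
}

#' Plant ground-truth modules in a network
#'
#' Chooses disjoint connected node sets of the requested compositions (every
#' member reaction must carry at least one gene) and records the effect and
#' noise levels their genes will receive in [plant_and_simulate()].
#'
#' A planted module of composition `(R, M)` is the closed neighbourhood of a
#' connected set of `M` metabolites whose reactions number exactly `R`: the
#' member metabolites touch no reaction outside the module. This makes the
#' ground truth well-posed. If a planted metabolite kept reactions outside
#' the truth set, every outside neighbour whose noisy score happens to be
#' positive would raise any score-sum module containing that metabolite, so
#' no method maximising summed scores could exclude it, and the planted label
#' would be unrecoverable by construction rather than hard. The module's
#' reactions still touch non-member metabolites, so the boundary remains
#' contested in the realistic direction.
#'
#' @param net a [metabolic_network()].
#' @param compositions list of integer vectors `c(n_reactions,
#'   n_metabolites)`, one per planted module (default one module of 8
#'   reactions and 2 metabolites).
#' @param directions character vector (`"up"`/`"down"`), one per module.
#' @param effect_size mean absolute log2 fold-change given to planted genes
#'   (>= 0, default 2; 0 yields a planted labelling with no expression
#'   effect, useful as a distributional control).
#' @param noise_sd standard deviation of every gene's observed log2
#'   fold-change (default 0.5).
#' @param background_fraction fraction of non-planted genes made responsive
#'   (random sign, same effect size); default 0 for a clean truth.
#' @param seed integer seed.
#' @return object of class `synthetic_truth`.
#' @export
plant_modules <- function(net, compositions = list(c(8, 2)),
                          directions = rep("up", length(compositions)),
                          effect_size = 2, noise_sd = 0.5,
                          background_fraction = 0, seed) {
  stopifnot(inherits(net, "metabolic_network"),
            length(directions) == length(compositions))
  if (missing(seed)) stop("an integer seed is required")
  if (effect_size < 0)
    stop("effect_size must be non-negative")
  set.seed(seed)
  rxn_neigh <- lapply(split(net$edges$reaction, net$edges$metabolite), unique)
  met_neigh <- lapply(split(net$edges$metabolite, net$edges$reaction), unique)
  planted <- list()
  used <- character()
  for (i in seq_along(compositions)) {
    comp <- c(as.integer(compositions[[i]][1]), as.integer(compositions[[i]][2]))
    if (comp[1] < 1L || comp[2] < 1L)
      stop("compositions must have at least one reaction and one metabolite")
    ok <- FALSE
    for (try in seq_len(10000)) {
      # grow a connected metabolite set whose reaction neighbourhood closes
      # at exactly comp[1] reactions
      m0 <- net$metabolites[sample.int(length(net$metabolites), 1L)]
      mets <- m0
      rxns <- rxn_neigh[[m0]]
      dead <- FALSE
      while (length(mets) < comp[2] && !dead) {
        cand <- setdiff(unique(unlist(met_neigh[rxns], use.names = FALSE)), mets)
        cand <- cand[vapply(cand, function(m)
          length(union(rxns, rxn_neigh[[m]])) <= comp[1], logical(1))]
        if (!length(cand)) { dead <- TRUE; break }
        m <- cand[sample.int(length(cand), 1L)]
        mets <- c(mets, m)
        rxns <- union(rxns, rxn_neigh[[m]])
      }
      if (dead || length(rxns) != comp[1]) next
      ids <- c(rxns, mets)
      if (any(lengths(net$genes[rxns]) == 0L)) next
      if (length(intersect(ids, used))) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not plant a disjoint closed module of composition (",
                  comp[1], ", ", comp[2], ")")
    used <- c(used, ids)
    planted[[i]] <- list(reaction_ids = sort(rxns),
                         metabolite_ids = sort(mets),
                         direction = directions[i])
  }
  structure(list(planted = planted, effect_size = effect_size,
                 noise_sd = noise_sd,
                 background_fraction = background_fraction, seed = seed),
            class = "synthetic_truth")
}

#' Simulate replicate expression and summarise per-gene scores
#'
#' Every gene receives a true log2 fold-change (plus or minus `effect_size`
#' for genes of planted reactions, 0 for background unless
#' `background_fraction > 0`). Replicate-level expression is then simulated
#' for two conditions with three biological replicates each, and each gene is
#' summarised by its observed log2 fold-change (difference of replicate
#' means, distributed `N(true, noise_sd)`) and the p-value of a plain
#' pooled-variance two-sample t-test, adjusted by Benjamini--Hochberg. An
#' empty truth yields a pure null dataset.
#'
#' @param net a [metabolic_network()].
#' @param truth a [plant_modules()] result.
#' @param n_replicates biological replicates per condition (default 3).
#' @param seed integer seed; defaults to `truth$seed + 1`.
#' @return a [gene_score_table()] data.frame with columns `gene`, `log2fc`,
#'   `pvalue`, `qvalue`.
#' @export
plant_and_simulate <- function(net, truth, n_replicates = 3,
                               seed = truth$seed + 1) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(truth, "synthetic_truth"))
  genes <- sort(unique(unlist(net$genes, use.names = FALSE)))
  if (length(genes) == 0L) stop("network carries no gene associations")
  true_lfc <- stats::setNames(rep(0, length(genes)), genes)
  for (pm in truth$planted) {
    g <- unique(unlist(net$genes[pm$reaction_ids], use.names = FALSE))
    if (length(g) == 0L) stop("planted module reactions carry no genes")
    true_lfc[g] <- if (pm$direction == "up") truth$effect_size
                   else -truth$effect_size
  }
  set.seed(seed)
  if (truth$background_fraction > 0) {
    bg <- names(true_lfc)[true_lfc == 0]
    n_resp <- floor(truth$background_fraction * length(bg))
    if (n_resp > 0) {
      resp <- sample(bg, n_resp)
      true_lfc[resp] <- sample(c(-1, 1), n_resp, replace = TRUE) *
        truth$effect_size
    }
  }
  m <- length(genes)
  k <- n_replicates
  # replicate sd chosen so the observed log2fc has sd exactly noise_sd
  sd_rep <- truth$noise_sd * sqrt(k / 2)
  y_c <- matrix(stats::rnorm(m * k, 0, sd_rep), m, k)
  y_t <- matrix(stats::rnorm(m * k, true_lfc, sd_rep), m, k)
  m_c <- rowMeans(y_c); m_t <- rowMeans(y_t)
  v_c <- apply(y_c, 1, stats::var); v_t <- apply(y_t, 1, stats::var)
  sp2 <- ((k - 1) * v_c + (k - 1) * v_t) / (2 * k - 2)
  tstat <- (m_t - m_c) / sqrt(sp2 * 2 / k)
  pval <- 2 * stats::pt(-abs(tstat), df = 2 * k - 2)
  gene_score_table(data.frame(gene = genes,
                              log2fc = m_t - m_c,
                              pvalue = pval,
                              stringsAsFactors = FALSE))
}

#' Generate a synthetic pathway membership map
#'
#' Random gene sets over the network's gene universe, optionally with one
#' pathway enriched for the genes of a planted module at a given overlap
#' fraction (ground truth for the enrichment comparison).
#'
#' @param net a [metabolic_network()].
#' @param n_pathways number of pathways (default 20).
#' @param size_range inclusive pathway size bounds (default `c(3, 94)`).
#' @param planted_overlap_fraction fraction of the first pathway drawn from
#'   `planted_genes` (default 0).
#' @param planted_genes gene ids of the planted module (required when
#'   `planted_overlap_fraction > 0`).
#' @param seed integer seed.
#' @return a [pathway_map()] with universe equal to all genes of `net`.
#' @export
generate_pathways <- function(net, n_pathways = 20, size_range = c(3, 94),
                              planted_overlap_fraction = 0,
                              planted_genes = NULL, seed) {
  stopifnot(inherits(net, "metabolic_network"))
  if (missing(seed)) stop("an integer seed is required")
  universe <- sort(unique(unlist(net$genes, use.names = FALSE)))
  if (length(universe) < size_range[1]) stop("gene universe too small")
  hi <- min(size_range[2], length(universe))
  set.seed(seed)
  sizes <- sample(size_range[1]:hi, n_pathways, replace = TRUE)
  ids <- sprintf("P%03d", seq_len(n_pathways))
  pw <- vector("list", n_pathways)
  names(pw) <- ids
  for (i in seq_len(n_pathways)) pw[[i]] <- sample(universe, sizes[i])
  if (planted_overlap_fraction > 0) {
    if (is.null(planted_genes)) stop("planted_genes required")
    planted_genes <- intersect(planted_genes, universe)
    need <- ceiling(planted_overlap_fraction * sizes[1])
    need <- min(need, length(planted_genes))
    sizes[1] <- max(sizes[1], need)
    fill <- sample(setdiff(universe, planted_genes), sizes[1] - need)
    pw[[1]] <- c(sample(planted_genes, need), fill)
  }
  pathway_map(pw, universe = universe)
}
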