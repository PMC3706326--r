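# Shared in-code fixtures; no data files needed.

# The documented toy: three reactions scoring +2, +1, -5 chained by two
# degree-2 metabolites, weight constant 0.1. Exhaustive enumeration over all
# 2^5 node subsets gives the best component {RA, mAB, RB} with
# S = 2 + 1 - 0.2 = 2.8 (frozen oracle value).
toy_chain <- function(c = 0.1) {
  net <- metabolic_network(
    reactions = c("RA", "RB", "RC"),
    metabolites = c("mAB", "mBC"),
    edges = data.frame(reaction = c("RA", "RB", "RB", "RC"),
                       metabolite = c("mAB", "mAB", "mBC", "mBC")),
    genes = list(RA = "gA", RB = "gB", RC = "gC"))
  gs <- gene_score_table(data.frame(gene = c("gA", "gB", "gC"),
                                    log2fc = c(2, 1, -5)))
  score_network(net, gs, direction = "up", c = c)
}

# Hand-sized network for scoring algebra: four reactions, three metabolites.
# Scores (c = 0.2): R1 = 1.5, R2 = -1, R3 = 0.5 (imputed median), R4 = 0.5;
# weights: A = -0.4 (degree 2), B = -0.6 (degree 3), C = -0.2 (degree 1).
algebra_net <- function() {
  metabolic_network(
    reactions = paste0("R", 1:4),
    metabolites = c("A", "B", "C"),
    edges = data.frame(
      reaction = c("R1", "R2", "R2", "R3", "R4", "R4"),
      metabolite = c("A", "A", "B", "B", "B", "C")),
    genes = list(R1 = c("g1", "g2"), R2 = "g3", R4 = c("g4", "g5")))
}

algebra_genes <- function() {
  gene_score_table(data.frame(gene = c("g1", "g2", "g3", "g4"),
                              log2fc = c(1, 2, -1, 0.5)))
}

algebra_scored <- function(direction = "up", c = 0.2) {
  score_network(algebra_net(), algebra_genes(), direction = direction, c = c)
}

# Random scored bipartite network with at most 14 nodes, one measured gene
# per reaction, for comparing the annealer against exhaustive enumeration.
small_scored <- function(seed) {
  set.seed(seed)
  nr <- sample(3:8, 1)
  nm <- sample(2:min(6, 14 - nr), 1)
  rxn <- paste0("R", seq_len(nr))
  met <- paste0("M", seq_len(nm))
  repeat {
    ne <- sample(max(nr, nm):(2 * (nr + nm)), 1)
    ed <- unique(data.frame(reaction = sample(rxn, ne, TRUE),
                            metabolite = sample(met, ne, TRUE)))
    if (all(table(factor(ed$reaction, rxn)) > 0) &&
        all(table(factor(ed$metabolite, met)) > 0)) break
  }
  net <- metabolic_network(rxn, met, ed,
                           genes = stats::setNames(as.list(paste0("g", rxn)),
                                                   rxn))
  gs <- gene_score_table(data.frame(gene = paste0("g", rxn),
                                    log2fc = round(stats::rnorm(nr, 0, 2), 2),
                                    pvalue = stats::runif(nr)))
  score_network(net, gs, direction = "up", c = stats::runif(1, 0.05, 0.5))
}

# Moderate-scale synthetic study: network, planted truth, gene scores and the
# study-calibrated weight constant (one score-sd per unit of connectivity).
planted_study <- function(seed, n_reactions = 150, n_metabolites = 100,
                          compositions = list(c(8, 2)),
                          directions = rep("up", length(compositions)),
                          noise_sd = 0.5) {
  net <- generate_network(n_reactions, n_metabolites, mean_degree = 3,
                          seed = seed)
  truth <- plant_modules(net, compositions, directions,
                         noise_sd = noise_sd, seed = seed + 1)
  genes <- plant_and_simulate(net, truth, seed = seed + 2)
  sc0 <- score_network(net, genes, direction = "up")
  list(net = net, truth = truth, genes = genes,
       c_study = stats::sd(sc0$reaction_score))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
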