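#' Construct a bipartite reaction--metabolite network
#'
#' A metabolic network is represented as an undirected bipartite graph with
#' two node classes: reactions and metabolites. Edges join a reaction to a
#' metabolite it consumes or produces; reversibility is deliberately ignored
#' (module membership must not depend on flux direction). Each reaction may
#' carry a set of associated gene identifiers.
#'
#' @param reactions character vector of reaction ids (unique).
#' @param metabolites character vector of metabolite ids (unique, disjoint
#'   from `reactions`).
#' @param edges data.frame with character columns `reaction` and `metabolite`;
#'   duplicate pairs are collapsed.
#' @param genes named list mapping reaction id to a character vector of gene
#'   ids (may be empty). Reactions absent from the list get an empty gene set.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `reactions`, `metabolites`, `edges` (deduplicated data.frame) and
#'   `genes` (complete named list over all reactions).
#' @export
metabolic_network <- function(reactions, metabolites, edges, genes = list()) {
  reactions <- as.character(reactions)
  metabolites <- as.character(metabolites)
  if (anyDuplicated(reactions)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolites)) stop("duplicate metabolite ids")
  if (length(intersect(reactions, metabolites)) > 0L)
    stop("reaction and metabolite id sets must be disjoint")
  if (nrow(edges) > 0L) {
    edges <- data.frame(reaction = as.character(edges$reaction),
                        metabolite = as.character(edges$metabolite),
                        stringsAsFactors = FALSE)
    edges <- unique(edges)
    bad_r <- setdiff(edges$reaction, reactions)
    bad_m <- setdiff(edges$metabolite, metabolites)
    if (length(bad_r)) stop("edge references unknown reaction: ", bad_r[1])
    if (length(bad_m)) stop("edge references unknown metabolite: ", bad_m[1])
  } else {
    edges <- data.frame(reaction = character(), metabolite = character(),
                        stringsAsFactors = FALSE)
  }
  gene_map <- stats::setNames(rep(list(character()), length(reactions)),
                              reactions)
  if (length(genes)) {
    unknown <- setdiff(names(genes), reactions)
    if (length(unknown)) stop("gene map references unknown reaction: ",
                              unknown[1])
    for (r in names(genes)) {
      g <- unique(as.character(genes[[r]]))
      gene_map[[r]] <- g[!is.na(g) & nzchar(g)]
    }
  }
  structure(list(reactions = reactions, metabolites = metabolites,
                 edges = edges, genes = gene_map),
            class = "metabolic_network")
}

#' Read a reaction table into a metabolic network
#'
#' The reaction table is a UTF-8 TSV with header columns `reaction_id`,
#' `metabolite_ids` and `gene_ids`; multi-valued fields are `;`-separated and
#' an empty or `NA` gene field means the reaction has no associated genes.
#'
#' @param path path to the TSV file.
#' @return A [metabolic_network()].
#' @export
read_reaction_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  required <- c("reaction_id", "metabolite_ids", "gene_ids")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("reaction table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L)
    return(metabolic_network(character(), character(),
                             data.frame(reaction = character(),
                                        metabolite = character())))
  split_field <- function(x) {
    if (is.na(x) || x == "" || x == "NA") return(character())
    v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    unique(v[nzchar(v)])
  }
  # duplicate reaction rows are allowed only if byte-identical
  if (anyDuplicated(tab$reaction_id)) {
    key <- paste(tab$reaction_id, tab$metabolite_ids, tab$gene_ids, sep = "\r")
    tab <- tab[!duplicated(key), , drop = FALSE]
    dup <- tab$reaction_id[duplicated(tab$reaction_id)]
    if (length(dup))
      stop("conflicting rows for reaction_id: ", dup[1])
  }
  mets_by_r <- lapply(tab$metabolite_ids, split_field)
  genes_by_r <- lapply(tab$gene_ids, split_field)
  names(genes_by_r) <- tab$reaction_id
  edges <- data.frame(
    reaction = rep(tab$reaction_id, lengths(mets_by_r)),
    metabolite = unlist(mets_by_r, use.names = FALSE),
    stringsAsFactors = FALSE)
  metabolic_network(tab$reaction_id,
                    unique(edges$metabolite),
                    edges,
                    genes_by_r)
}

#' Write a metabolic network as a reaction table
#'
#' Inverse of [read_reaction_table()]: round-tripping reproduces the network
#' exactly (node sets, edges and gene map). Metabolites with no incident
#' reaction cannot be represented and raise an error.
#'
#' @param net a [metabolic_network()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  orphan <- setdiff(net$metabolites, net$edges$metabolite)
  if (length(orphan))
    stop("metabolite(s) without incident reactions cannot be written: ",
         orphan[1])
  mets <- vapply(net$reactions, function(r) {
    paste(sort(net$edges$metabolite[net$edges$reaction == r]), collapse = ";")
  }, character(1))
  gens <- vapply(net$reactions, function(r) {
    paste(sort(net$genes[[r]]), collapse = ";")
  }, character(1))
  out <- data.frame(reaction_id = net$reactions, metabolite_ids = mets,
                    gene_ids = gens, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a metabolic network from an SBML file
#'
#' Minimal read-only SBML Level 2/3 reader: `species` become metabolite
#' nodes, `reaction` elements become reaction nodes and every reactant or
#' product reference becomes one undirected edge. Reversibility flags are
#' ignored. Gene associations are read, when present, from
#' `GENE_ASSOCIATION:` lines in reaction `<notes>` or from fbc
#' `geneProductRef` annotations; boolean AND/OR structure is flattened to the
#' set of gene identifiers.
#'
#' @param path path to an SBML file.
#' @return A [metabolic_network()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file: ",
                                           conditionMessage(e)))
  nsall <- xml2::xml_ns(doc)
  sburi <- unname(nsall[grepl("sbml", nsall, fixed = TRUE)])[1]
  if (is.na(sburi)) sburi <- unname(nsall[[1]])
  ns <- c(s = sburi)
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_ids <- xml2::xml_attr(species, "id")
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxns, "id")
  edge_r <- character(); edge_m <- character()
  genes <- list()
  for (i in seq_along(rxns)) {
    rx <- rxns[[i]]
    refs <- xml2::xml_find_all(
      rx, "./s:listOfReactants/s:speciesReference | ./s:listOfProducts/s:speciesReference",
      ns)
    sp <- unique(xml2::xml_attr(refs, "species"))
    edge_r <- c(edge_r, rep(rxn_ids[i], length(sp)))
    edge_m <- c(edge_m, sp)
    g <- character()
    notes <- xml2::xml_find_first(rx, "./s:notes", ns)
    if (!inherits(notes, "xml_missing")) {
      txt <- xml2::xml_text(notes)
      m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n]*", txt))
      if (length(m)) {
        body <- sub("^GENE_ASSOCIATION:\\s*", "", m)
        toks <- unlist(strsplit(body, "[()[:space:]]+"))
        g <- toks[!tolower(toks) %in% c("and", "or", "")]
      }
    }
    gpr <- xml2::xml_find_all(rx, ".//*[local-name()='geneProductRef']")
    if (length(gpr)) {
      ref <- xml2::xml_attr(gpr, "geneProduct")
      ref2 <- xml2::xml_attr(gpr, "fbc:geneProduct")
      g <- c(g, ref[!is.na(ref)], ref2[!is.na(ref2)])
    }
    g <- unique(g[!is.na(g) & nzchar(g)])
    if (length(g)) genes[[rxn_ids[i]]] <- g
  }
  keep <- edge_m %in% met_ids
  metabolic_network(rxn_ids, met_ids,
                    data.frame(reaction = edge_r[keep],
                               metabolite = edge_m[keep],
                               stringsAsFactors = FALSE),
                    genes)
}

# igraph view of the network; vertex attribute node_type in {reaction,
# metabolite}. Isolated nodes are kept.
as_igraph <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  nodes <- c(net$reactions, net$metabolites)
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(
      name = nodes,
      node_type = rep(c("reaction", "metabolite"),
                      c(length(net$reactions), length(net$metabolites))),
      stringsAsFactors = FALSE))
  g
}

#' Number of reactions adjacent to a metabolite
#'
#' Metabolite connectivity drives the penalty weights: highly connected
#' currency metabolites (water, ATP, hydrogen peroxide, ...) would otherwise
#' create spurious bridges between unrelated reactions.
#'
#' @param net a [metabolic_network()].
#' @param m metabolite id(s).
#' @return integer vector of degrees, named by metabolite id.
#' @export
metabolite_degree <- function(net, m = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(m)) m <- net$metabolites
  unknown <- setdiff(m, net$metabolites)
  if (length(unknown)) stop("unknown metabolite id: ", unknown[1])
  tab <- table(net$edges$metabolite)
  deg <- stats::setNames(integer(length(m)), m)
  hit <- m %in% names(tab)
  deg[hit] <- as.integer(tab[m[hit]])
  deg
}

#' Connected components of an induced subgraph
#'
#' @param net a [metabolic_network()].
#' @param nodes character vector of node ids (reactions and/or metabolites).
#' @return A list of components, each a list with `reaction_ids` and
#'   `metabolite_ids`, ordered by decreasing size then by the
#'   lexicographically smallest node id.
#' @export
network_components <- function(net, nodes) {
  stopifnot(inherits(net, "metabolic_network"))
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, c(net$reactions, net$metabolites))
  if (length(unknown)) stop("unknown node id: ", unknown[1])
  if (length(nodes) == 0L) return(list())
  g <- igraph::induced_subgraph(as_igraph(net), nodes)
  cmp <- igraph::components(g)
  comps <- split(names(cmp$membership), cmp$membership)
  out <- lapply(comps, function(ids) {
    list(reaction_ids = sort(intersect(ids, net$reactions)),
         metabolite_ids = sort(intersect(ids, net$metabolites)))
  })
  sizes <- vapply(comps, length, integer(1))
  firsts <- vapply(comps, function(x) min(x), character(1))
  out[order(-sizes, firsts)]
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("Bipartite metabolic network\n")
  cat(sprintf("  reactions:   %d\n", length(x$reactions)))
  cat(sprintf("  metabolites: %d\n", length(x$metabolites)))
  cat(sprintf("  edges:       %d\n", nrow(x$edges)))
  with_genes <- sum(lengths(x$genes) > 0)
  cat(sprintf("  reactions with gene associations: %d\n", with_genes))
  invisible(x)
}

#' @export
summary.metabolic_network <- function(object, ...) {
  deg <- metabolite_degree(object)
  res <- list(
    n_reactions = length(object$reactions),
    n_metabolites = length(object$metabolites),
    n_edges = nrow(object$edges),
    n_components = length(network_components(
      object, c(object$reactions, object$metabolites))),
    metabolite_degree = summary(as.numeric(deg)),
    max_degree_metabolite = if (length(deg)) names(deg)[which.max(deg)] else NA)
  class(res) <- "summary.metabolic_network"
  res
}

#' @export
print.summary.metabolic_network <- function(x, ...) {
  cat(sprintf("Bipartite metabolic network: %d reactions, %d metabolites, %d edges, %d component(s)\n",
              x$n_reactions, x$n_metabolites, x$n_edges, x$n_components))
  cat("Metabolite connectivity:\n")
  print(x$metabolite_degree)
  cat(sprintf("Most connected metabolite: %s\n", x$max_degree_metabolite))
  invisible(x)
}

#' @export
plot.metabolic_network <- function(x, nodes = NULL, ...) {
  g <- as_igraph(x)
  if (!is.null(nodes)) g <- igraph::induced_subgraph(g, nodes)
  shape <- ifelse(igraph::V(g)$node_type == "reaction", "square", "circle")
  igraph::plot.igraph(g, vertex.shape = shape, vertex.size = 8,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}
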