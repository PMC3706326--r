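test_that("constructor validates node sets and edges", {
  expect_error(metabolic_network(c("R1", "R1"), "A",
                                 data.frame(reaction = "R1", metabolite = "A")),
               "duplicate reaction")
  expect_error(metabolic_network("R1", c("A", "A"),
                                 data.frame(reaction = "R1", metabolite = "A")),
               "duplicate metabolite")
  expect_error(metabolic_network("X", "X",
                                 data.frame(reaction = "X", metabolite = "X")),
               "disjoint")
  expect_error(metabolic_network("R1", "A",
                                 data.frame(reaction = "R2", metabolite = "A")),
               "unknown reaction")
  expect_error(metabolic_network("R1", "A",
                                 data.frame(reaction = "R1", metabolite = "B")),
               "unknown metabolite")
  expect_error(metabolic_network("R1", "A",
                                 data.frame(reaction = "R1", metabolite = "A"),
                                 genes = list(R9 = "g")),
               "unknown reaction")
})

test_that("duplicate edges are collapsed and gene map completed", {
  net <- metabolic_network("R1", "A",
                           data.frame(reaction = c("R1", "R1"),
                                      metabolite = c("A", "A")))
  expect_equal(nrow(net$edges), 1L)
  expect_named(net$genes, "R1")
  expect_identical(net$genes$R1, character())
})

test_that("reaction table round-trips exactly", {
  net <- algebra_net()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(net, path)
  back <- read_reaction_table(path)
  expect_setequal(back$reactions, net$reactions)
  expect_setequal(back$metabolites, net$metabolites)
  key <- function(e) sort(paste(e$reaction, e$metabolite))
  expect_identical(key(back$edges), key(net$edges))
  expect_identical(lapply(back$genes[sort(names(back$genes))], sort),
                   lapply(net$genes[sort(names(net$genes))], sort))
})

test_that("reaction table input is validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tmetabolite_ids", "R1\tA"), path)
  expect_error(read_reaction_table(path), "missing column")

  writeLines(c("reaction_id\tmetabolite_ids\tgene_ids",
               "R1\tA;B\tg1", "R1\tA\tg1"), path)
  expect_error(read_reaction_table(path), "conflicting rows")

  # byte-identical duplicate rows are tolerated
  writeLines(c("reaction_id\tmetabolite_ids\tgene_ids",
               "R1\tA;B\tg1", "R1\tA;B\tg1"), path)
  net <- read_reaction_table(path)
  expect_identical(net$reactions, "R1")
  expect_setequal(net$metabolites, c("A", "B"))
})

test_that("orphan metabolites cannot be written", {
  net <- metabolic_network("R1", c("A", "B"),
                           data.frame(reaction = "R1", metabolite = "A"))
  expect_error(write_reaction_table(net, tempfile()), "without incident")
})

test_that("minimal SBML import reads species, reactions and genes", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy">
    <listOfSpecies>
      <species id="M_a" name="A"/>
      <species id="M_b" name="B"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_1" reversible="true">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (gene1 and gene2) or gene3</p>
        </body></notes>
        <listOfReactants>
          <speciesReference species="M_a" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_b" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_2">
        <listOfReactants>
          <speciesReference species="M_b"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- read_sbml(path)
  expect_setequal(net$reactions, c("R_1", "R_2"))
  expect_setequal(net$metabolites, c("M_a", "M_b"))
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$genes$R_1, c("gene1", "gene2", "gene3"))
  expect_identical(net$genes$R_2, character())
  expect_error(read_sbml(withr::local_tempfile(fileext = ".xml")),
               "cannot parse")
})

test_that("metabolite degree counts distinct adjacent reactions", {
  # a 12-reaction hub mirrors the currency construction target
  rxn <- paste0("R", 1:12)
  net <- metabolic_network(rxn, c("hub", "iso", "chainA"),
    data.frame(reaction = c(rxn, "R1", "R2"),
               metabolite = c(rep("hub", 12), "chainA", "chainA")))
  expect_equal(unname(metabolite_degree(net, "hub")), 12L)
  expect_equal(unname(metabolite_degree(net, "iso")), 0L)
  expect_equal(unname(metabolite_degree(net, "chainA")), 2L)
  expect_error(metabolite_degree(net, "nope"), "unknown metabolite")
})

test_that("components are ordered by size then smallest id", {
  net <- algebra_net()
  # {R1, A, R2} vs {R4, C}: sizes 3 and 2
  comps <- network_components(net, c("R1", "A", "R2", "R4", "C"))
  expect_length(comps, 2L)
  expect_setequal(comps[[1]]$reaction_ids, c("R1", "R2"))
  expect_identical(comps[[2]]$reaction_ids, "R4")
  # equal sizes: smallest node id first
  comps2 <- network_components(net, c("R4", "C", "R1", "A"))
  expect_identical(comps2[[1]]$metabolite_ids, "A")
  expect_error(network_components(net, "zzz"), "unknown node")
  expect_identical(network_components(net, character()), list())
})

test_that("graph exports write GraphML and SIF", {
  sc <- algebra_scored()
  base <- file.path(withr::local_tempdir(), "mod")
  mod <- list(reaction_ids = c("R1", "R2"), metabolite_ids = "A")
  paths <- export_module_graph(sc, mod, base)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[1], format = "graphml")
  expect_setequal(igraph::V(g)$name, c("R1", "R2", "A"))
  expect_setequal(igraph::V(g)$node_type, c("reaction", "metabolite"))
  sif <- readLines(paths[2])
  expect_length(sif, 2L)
  expect_true(all(grepl(" rm ", sif)))

  # extended export closes over adjacent metabolites (R2 also touches B)
  paths2 <- export_module_graph(sc, mod, paste0(base, "_ext"),
                                extended = TRUE)
  g2 <- igraph::read_graph(paths2[1], format = "graphml")
  expect_true("B" %in% igraph::V(g2)$name)

  pn <- export_network_graph(algebra_net(), paste0(base, "_net"))
  expect_true(all(file.exists(pn)))
})

test_that("print and summary methods run", {
  net <- algebra_net()
  expect_output(print(net), "Bipartite metabolic network")
  s <- summary(net)
  expect_equal(s$n_reactions, 4L)
  expect_output(print(s), "Most connected metabolite: B")
})
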