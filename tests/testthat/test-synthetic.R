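test_that("network generation is deterministic and connected", {
  a <- generate_network(80, 50, mean_degree = 3, seed = 10)
  b <- generate_network(80, 50, mean_degree = 3, seed = 10)
  expect_identical(a$edges, b$edges)
  expect_identical(a$genes, b$genes)
  comps <- network_components(a, c(a$reactions, a$metabolites))
  expect_length(comps, 1L)
  # ~10% of reactions are gene-less to exercise imputation
  expect_equal(sum(lengths(a$genes) == 0), 8L)
})

test_that("currency hubs have exactly the requested degree", {
  net <- generate_network(80, 50, mean_degree = 3, n_currency = 2,
                          currency_degree = 12, seed = 11)
  deg <- metabolite_degree(net)
  expect_equal(unname(deg[c("CUR01", "CUR02")]), c(12L, 12L))
  # right-skewed ordinary degrees: mean above median
  ord <- deg[!grepl("^CUR", names(deg))]
  expect_gt(mean(ord), stats::median(as.numeric(ord)))
})

test_that("genome-scale generation is fast and connected", {
  t0 <- Sys.time()
  net <- generate_network(963, 600, mean_degree = 3, seed = 12)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_length(network_components(net, c(net$reactions, net$metabolites)),
                1L)
  expect_length(net$reactions, 963L)
})

test_that("generation parameters are validated", {
  expect_error(generate_network(10, 10, seed = 1, mean_degree = 5),
               "mean_degree")
  expect_error(generate_network(10, 10, seed = 1, currency_degree = 2),
               "at least mean_degree")
  expect_error(generate_network(5, 10, seed = 1, currency_degree = 12),
               "exceeds")
  expect_error(generate_network(10, 10), "seed")
})

test_that("planted modules are closed, connected, disjoint and gene-backed", {
  st <- planted_study(401, compositions = list(c(8, 2), c(6, 2)),
                      directions = c("up", "down"))
  expect_s3_class(st$truth, "synthetic_truth")
  expect_length(st$truth$planted, 2L)
  all_ids <- character()
  for (pm in st$truth$planted) {
    expect_length(pm$reaction_ids, if (pm$direction == "up") 8L else 6L)
    expect_length(pm$metabolite_ids, 2L)
    # closure: planted metabolites touch no reaction outside the module
    for (m in pm$metabolite_ids) {
      adj <- st$net$edges$reaction[st$net$edges$metabolite == m]
      expect_true(all(adj %in% pm$reaction_ids))
    }
    # connected
    comps <- network_components(st$net,
                                c(pm$reaction_ids, pm$metabolite_ids))
    expect_length(comps, 1L)
    # every member reaction carries a gene
    expect_true(all(lengths(st$net$genes[pm$reaction_ids]) > 0))
    all_ids <- c(all_ids, pm$reaction_ids, pm$metabolite_ids)
  }
  expect_false(anyDuplicated(all_ids) > 0)
})

test_that("planting is deterministic and validates arguments", {
  net <- generate_network(150, 100, mean_degree = 3, seed = 402)
  a <- plant_modules(net, list(c(8, 2)), "up", seed = 403)
  b <- plant_modules(net, list(c(8, 2)), "up", seed = 403)
  expect_identical(a$planted, b$planted)
  expect_error(plant_modules(net, list(c(8, 2)), "up",
                             effect_size = -1, seed = 1), "non-negative")
  expect_error(plant_modules(net, list(c(8, 2)), c("up", "down"), seed = 1))
})

test_that("simulated scores hit the planted effect", {
  st <- planted_study(404)
  sc <- score_network(st$net, st$genes, direction = "up", c = 0.3)
  planted_mean <- mean(sc$reaction_score[st$truth$planted[[1]]$reaction_ids])
  # CLT bound at module size 8, effect 2, per-gene sd 0.5
  expect_gt(planted_mean, 1.5)
  expect_lt(planted_mean, 2.5)
  # background stays centred
  bg <- setdiff(names(sc$reaction_score),
                c(st$truth$planted[[1]]$reaction_ids, sc$imputed))
  expect_lt(abs(mean(sc$reaction_score[bg])), 0.25)
})

test_that("p-values come from replicate-level t-tests", {
  st <- planted_study(405)
  g <- st$genes
  expect_true(all(c("gene", "log2fc", "pvalue", "qvalue") %in% names(g)))
  expect_true(all(g$pvalue >= 0 & g$pvalue <= 1))
  # deterministic under seed
  g2 <- plant_and_simulate(st$net, st$truth, seed = st$truth$seed + 1)
  expect_identical(g, g2)
})

test_that("effect_size = 0 is distributionally indistinguishable from null", {
  net <- generate_network(963, 600, mean_degree = 3, seed = 406)
  t_eff0 <- plant_modules(net, list(c(8, 2)), "up", effect_size = 0,
                          seed = 407)
  t_null <- plant_modules(net, list(), character(0), seed = 407)
  g_eff0 <- plant_and_simulate(net, t_eff0, seed = 500)
  g_null <- plant_and_simulate(net, t_null, seed = 501)
  ks <- suppressWarnings(stats::ks.test(g_eff0$log2fc, g_null$log2fc))
  expect_gt(ks$p.value, 0.01)
})

test_that("an empty truth yields a valid pure-null dataset", {
  st <- planted_study(408, compositions = list())
  expect_length(st$truth$planted, 0L)
  expect_lt(abs(mean(st$genes$log2fc)), 0.1)
})

test_that("background_fraction makes extra genes responsive", {
  net <- generate_network(150, 100, mean_degree = 3, seed = 409)
  tr <- plant_modules(net, list(), character(0),
                      background_fraction = 0.16, seed = 410)
  g <- plant_and_simulate(net, tr, seed = 411)
  # ~16% of genes responsive at |effect| = 2: spread far beyond noise
  expect_gt(mean(abs(g$log2fc) > 1), 0.10)
})

test_that("generated pathways respect the size bounds", {
  st <- planted_study(412, compositions = list())
  pmap <- generate_pathways(st$net, n_pathways = 20, size_range = c(3, 94),
                            seed = 413)
  sizes <- lengths(pmap$pathways)
  expect_true(all(sizes >= 3 & sizes <= 94))
  expect_length(pmap$pathways, 20L)
  expect_setequal(pmap$universe,
                  unique(unlist(st$net$genes, use.names = FALSE)))
  p2 <- generate_pathways(st$net, n_pathways = 20, size_range = c(3, 94),
                          seed = 413)
  expect_identical(pmap$pathways, p2$pathways)
  expect_error(generate_pathways(st$net, planted_overlap_fraction = 0.5,
                                 seed = 1), "planted_genes required")
})
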