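test_that("null samples respect composition and are seed-deterministic", {
  sc <- algebra_scored()
  nd <- sample_null(sc, c(1, 1), B = 200, seed = 5)
  expect_s3_class(nd, "null_distribution")
  expect_length(nd$samples, 200L)
  # composition (1,1): every sample is s_r + w_m for an adjacent pair
  pair_scores <- apply(algebra_net()$edges, 1, function(e)
    unname(sc$reaction_score[e["reaction"]] + sc$metabolite_weight[e["metabolite"]]))
  expect_true(all(vapply(nd$samples, function(s)
    any(abs(s - pair_scores) < 1e-12), logical(1))))
  nd2 <- sample_null(sc, c(1, 1), B = 200, seed = 5)
  expect_identical(nd$samples, nd2$samples)
})

test_that("null scores are <= 0 when all reaction scores are zero", {
  net <- algebra_net()
  gs <- gene_score_table(data.frame(gene = paste0("g", 1:4),
                                    log2fc = rep(0, 4)))
  sc <- score_network(net, gs, c = 0.3)
  nd <- sample_null(sc, c(2, 1), B = 100, seed = 9)
  expect_true(all(nd$samples <= 0))
})

test_that("the (1,0) null mean matches the exact reaction-score mean", {
  st <- planted_study(301, n_reactions = 60, n_metabolites = 40,
                      compositions = list())
  sc <- score_network(st$net, st$genes, c = 0.3)
  nd <- sample_null(sc, c(1, 0), B = 10000, seed = 11)
  se <- stats::sd(sc$reaction_score) / sqrt(10000)
  expect_lt(abs(mean(nd$samples) - mean(sc$reaction_score)), 4 * se)
})

test_that("two seeds give null distributions with compatible means", {
  st <- planted_study(302, n_reactions = 60, n_metabolites = 40,
                      compositions = list())
  sc <- score_network(st$net, st$genes, c = 0.3)
  a <- sample_null(sc, c(3, 1), B = 1000, seed = 1)
  b <- sample_null(sc, c(3, 1), B = 1000, seed = 2)
  se <- sqrt(stats::var(a$samples) / 1000 + stats::var(b$samples) / 1000)
  expect_lt(abs(mean(a$samples) - mean(b$samples)), 3 * se)
})

test_that("infeasible compositions raise errors", {
  sc <- algebra_scored()
  expect_error(sample_null(sc, c(100, 1), B = 100, seed = 1), "infeasible")
  expect_error(sample_null(sc, c(0, 0), B = 100, seed = 1), "invalid")
  expect_error(sample_null(sc, c(1, 0), B = 50, seed = 1), "at least 100")
  expect_error(sample_null(sc, c(1, 0), B = 100), "seed")
})

test_that("the unconnected null variant is available for comparison", {
  sc <- algebra_scored()
  nd <- sample_null(sc, c(2, 1), B = 150, seed = 3, connected = FALSE)
  expect_false(nd$connected)
  expect_length(nd$samples, 150L)
})

test_that("empirical p follows the add-one formula", {
  nd <- structure(list(samples = as.numeric(1:999), B = 999L),
                  class = "null_distribution")
  expect_equal(empirical_pvalue(1000, nd), 1 / 1000)
  expect_equal(empirical_pvalue(0, nd), 1)
  # observed equal to the null median, B odd: (ceiling(B/2) + 1)/(B + 1)
  expect_equal(empirical_pvalue(500, nd), (500 + 1) / 1000)
  # monotone: larger observed never has larger p
  expect_lte(empirical_pvalue(700, nd), empirical_pvalue(300, nd))
})

test_that("empirical p of unselected random modules is calibrated", {
  # the p-value machinery applied to modules NOT chosen by the search:
  # random same-composition sets must give roughly uniform p
  st <- planted_study(303, n_reactions = 100, n_metabolites = 70,
                      compositions = list())
  sc <- score_network(st$net, st$genes, c = 0.3)
  nd <- sample_null(sc, c(3, 1), B = 1000, seed = 21)
  obs <- sample_null(sc, c(3, 1), B = 200, seed = 22)
  p <- vapply(obs$samples, empirical_pvalue, numeric(1), null = nd)
  expect_lte(mean(p < 0.05), 0.10)
  expect_gt(mean(p), 0.4)
})

test_that("assess_significance fills p per composition with caching", {
  sc <- toy_chain()
  am <- find_active_modules(sc, anneal_control(seed = 2))
  am <- assess_significance(am, B = 100, seed = 50)
  p <- vapply(am$modules, `[[`, numeric(1), "p_empirical")
  expect_true(all(p >= 1 / 101 & p <= 1))
  expect_equal(am$B, 100)
  # shared cache reuses identical compositions across families
  cache <- new.env(parent = emptyenv())
  am1 <- assess_significance(am, B = 100, seed = 50, cache = cache)
  am2 <- assess_significance(am, B = 100, seed = 50, cache = cache)
  expect_identical(vapply(am1$modules, `[[`, numeric(1), "p_empirical"),
                   vapply(am2$modules, `[[`, numeric(1), "p_empirical"))
})

test_that("module q-values correct families jointly", {
  mk <- function(ps) lapply(ps, function(p)
    list(p_empirical = p, q = NA_real_))
  # single module: q equals p
  one <- module_qvalues(mk(0.004))
  expect_equal(one[[1]]$q, 0.004)
  # forty identical tiny p-values: all q = 0.001
  forty <- module_qvalues(mk(rep(0.001, 40)))
  expect_true(all(vapply(forty, `[[`, numeric(1), "q") == 0.001))
  # joint correction across two families equals BH on the pooled vector
  up <- mk(c(0.001, 0.02))
  dn <- mk(c(0.03, 0.8))
  both <- module_qvalues(up, dn)
  got <- c(vapply(both[[1]], `[[`, numeric(1), "q"),
           vapply(both[[2]], `[[`, numeric(1), "q"))
  expect_equal(got, bh_adjust(c(0.001, 0.02, 0.03, 0.8)))
  # missing p is an error
  expect_error(module_qvalues(mk(NA_real_)), "p_empirical missing")
  # storey variant
  st <- module_qvalues(mk(c(0.01, 0.04, 0.9)), method = "storey")
  expect_equal(vapply(st, `[[`, numeric(1), "q"),
               storey_qvalue(c(0.01, 0.04, 0.9)))
})
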