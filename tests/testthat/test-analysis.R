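toy <- build_toy_model()

test_that("FVA under MiMBl and FBA locks brackets the toy reroute", {
  ko <- knockout(toy$model, deletion_spec(reactions = "R5"))
  fm <- fva(ko, lock = "mimbl", ref = toy$ref, reactions = c("R6", "R7"))
  expect_equal(fm$min[fm$reaction == "R6"], 1, tolerance = 1e-8)
  expect_equal(fm$max[fm$reaction == "R6"], 1, tolerance = 1e-8)
  expect_true(all(fm$unique))
  ff <- fva(ko, lock = "fba", reactions = c("R6", "R7"))
  expect_equal(ff$min[ff$reaction == "R6"], 0, tolerance = 1e-8)
  expect_equal(ff$max[ff$reaction == "R6"], 1, tolerance = 1e-8)
  expect_false(ff$unique[ff$reaction == "R6"])
  # empty request gives an empty frame
  expect_equal(nrow(fva(ko, lock = "fba", reactions = character(0))), 0)
  expect_error(fva(ko, lock = "mimbl"), "reference")
})

test_that("FVA ranges bracket an optimal solution's fluxes", {
  gen <- generate_random_model(55, n_met = 6, n_rxn = 11)
  internal <- setdiff(reaction_ids(gen$model), c("UPT", "SINK"))
  ko <- knockout(gen$model, deletion_spec(reactions = internal[1]))
  m <- mimbl(ko, gen$ref)
  fr <- fva(ko, lock = "mimbl", ref = gen$ref)
  for (i in seq_len(nrow(fr))) {
    v <- m$flux$values[[fr$reaction[i]]]
    expect_gte(v, fr$min[i] - 1e-6)
    expect_lte(v, fr$max[i] + 1e-6)
  }
})

test_that("alternative-optima enumeration finds the toy's route patterns", {
  sols <- enumerate_alternative_optima(toy$model, n = 6, seed = 11)
  expect_gte(length(sols), 2)
  opt <- attr(sols, "optimum")
  expect_equal(opt, 1)
  route_r6 <- any(vapply(sols, function(s) s$values[["R6"]] > 0.5, logical(1)))
  route_long <- any(vapply(sols, function(s) s$values[["R2"]] > 0.5,
                           logical(1)))
  expect_true(route_r6)
  expect_true(route_long)
  pats <- vapply(sols, function(s) paste(as.integer(abs(s$values) > 1e-6),
                                         collapse = ""), character(1))
  expect_equal(anyDuplicated(pats), 0L)
  for (s in sols) {  # every solution re-verifies at the shared optimum
    expect_equal(s$values[["R7"]], opt, tolerance = 1e-6)
    expect_lt(s$residual, 1e-8)
  }
  # a linear chain has a unique optimum
  chain <- metabolic_model(
    data.frame(id = c("A", "B", "A[e]", "B[e]"),
               boundary = c(FALSE, FALSE, TRUE, TRUE)),
    list(reaction("E1", c("A[e]" = -1, A = 1), 0, 1),
         reaction("C1", c(A = -1, B = 1)),
         reaction("E2", c(B = -1, "B[e]" = 1))), objective = "E2")
  expect_length(enumerate_alternative_optima(chain, n = 5, seed = 2), 1)
  expect_length(enumerate_alternative_optima(chain, n = 0, seed = 2), 0)
})

test_that("epistasis scores and calls follow the multiplicative null", {
  r <- epistasis(0.8, 0.9, 0.72, 1)
  expect_equal(r$epsilon, 0)
  expect_equal(r$call, "none")
  r2 <- epistasis(1, 1, 0, 1)  # synthetic lethal
  expect_equal(r2$epsilon, -1)
  expect_equal(r2$call, "negative")
  r3 <- epistasis(1, 0.5, 0.6, 1)
  expect_equal(r3$epsilon, 0.1, tolerance = 1e-12)
  expect_equal(r3$call, "positive")
  # growths are normalized by the wild type and clipped at zero
  r4 <- epistasis(-0.2, 1, 1, 2)
  expect_equal(r4$f_a, 0)
  expect_error(epistasis(1, 1, 1, 0), "positive")
})

test_that("the interaction screen runs the toy gene pairs", {
  toyg <- build_toy_model(with_genes = TRUE)
  recs <- interaction_screen(toyg$model, data.frame(a = "gR5", b = "gR6"),
                             simulator = "fba")
  expect_equal(recs$f_a, 1)
  expect_equal(recs$f_b, 1)
  expect_equal(recs$f_ab, 1)  # the long path sustains full growth
  expect_equal(recs$epsilon, 0)
  # remove the long path: the double becomes lethal, a negative interaction
  no_long <- knockout(toyg$model, deletion_spec(reactions = "R2"))
  recs2 <- interaction_screen(no_long, data.frame(a = "gR5", b = "gR6"),
                              simulator = "fba")
  expect_equal(recs2$f_ab, 0)
  expect_equal(recs2$epsilon, -1)
  expect_equal(recs2$call, "negative")
  # adjustment-based screens need a reference
  expect_error(interaction_screen(toyg$model,
                                  data.frame(a = "gR5", b = "gR6"),
                                  simulator = "mimbl"), "reference")
  empty <- interaction_screen(toyg$model, data.frame(a = character(0),
                                                     b = character(0)),
                              simulator = "fba")
  expect_equal(nrow(empty), 0)
})

test_that("the screen's records are invariant to pair ordering", {
  gen <- generate_random_model(66, n_met = 6, n_rxn = 12)
  genes <- model_genes(gen$model)[1:2]
  a <- interaction_screen(gen$model, data.frame(genes[1], genes[2]),
                          simulator = "fba")
  b <- interaction_screen(gen$model, data.frame(genes[2], genes[1]),
                          simulator = "fba")
  expect_equal(a$epsilon, b$epsilon, tolerance = 1e-12)
  expect_equal(a$f_ab, b$f_ab, tolerance = 1e-12)
})

test_that("sensitivity/precision counting matches hand-built cases", {
  truth <- data.frame(gene_a = c("a", "b", "c", "d", "e", "f"),
                      gene_b = c("x", "x", "x", "x", "x", "x"),
                      sign = c("positive", "positive", "positive",
                               "negative", "negative", "none"))
  # predictor identical to the truth: perfect at any cutoff below |eps|
  pred_perfect <- data.frame(
    gene_a = truth$gene_a, gene_b = truth$gene_b,
    epsilon = c(0.5, 0.5, 0.5, -0.5, -0.5, 0))
  cp <- sensitivity_precision_curve(pred_perfect, truth, cutoffs = 0.1)
  expect_equal(cp$sensitivity[cp$sign == "positive"], 1)
  expect_equal(cp$precision[cp$sign == "positive"], 1)
  expect_equal(cp$sensitivity[cp$sign == "negative"], 1)
  # nothing predicted at a high cutoff: sensitivity 0, precision undefined
  cp2 <- sensitivity_precision_curve(pred_perfect, truth, cutoffs = 0.9)
  expect_equal(cp2$sensitivity, c(0, 0))
  expect_true(all(is.na(cp2$precision)))
  expect_equal(cp2$n_predicted, c(0L, 0L))
  # constructed counts: 4 positive calls, 2 true among them, 3 true positives
  pred <- data.frame(gene_a = c("a", "b", "d", "e"),
                     gene_b = rep("x", 4),
                     epsilon = c(0.5, 0.5, 0.5, 0.5))
  cp3 <- sensitivity_precision_curve(pred, truth, cutoffs = 0.1)
  pos <- cp3[cp3$sign == "positive", ]
  expect_equal(pos$precision, 0.5)
  expect_equal(pos$sensitivity, 2 / 3)
  # conflicting truth labels are rejected
  bad <- rbind(truth, data.frame(gene_a = "x", gene_b = "a",
                                 sign = "negative"))
  expect_error(sensitivity_precision_curve(pred, bad, 0.1), "conflicting")
})

test_that("network distance walks the reaction-adjacency graph", {
  toyg <- build_toy_model(with_genes = TRUE)$model
  expect_equal(network_distance(toyg, "gR2", "gR2"), 0)
  expect_equal(network_distance(toyg, "gR2", "gR4",
                                currency_degree_cutoff = 10), 2)
  expect_equal(network_distance(toyg, "gR5", "gR6",
                                currency_degree_cutoff = 10), 1)
  expect_error(network_distance(toyg, "gZZ", "gR2"), "absent")
  # two disconnected islands
  m <- metabolic_model(
    data.frame(id = c("A", "B", "A[e]", "B[e]"),
               boundary = c(FALSE, FALSE, TRUE, TRUE)),
    list(reaction("E1", c("A[e]" = -1, A = 1), gene_rule = "g1"),
         reaction("E1b", c(A = -1), gene_rule = "g1b"),
         reaction("E2", c("B[e]" = -1, B = 1), gene_rule = "g2"),
         reaction("E2b", c(B = -1), gene_rule = "g2b")))
  expect_equal(network_distance(m, "g1", "g2", currency_degree_cutoff = 10),
               Inf)
  # high-degree (currency) metabolites do not create shortcuts
  expect_equal(network_distance(toyg, "gR2", "gR4",
                                currency_degree_cutoff = 1), Inf)
})

test_that("theta scans flag invariance and locate breakpoints", {
  ko <- knockout(toy$model, deletion_spec(reactions = "R5"))
  sm <- theta_scan(ko, "mimbl", "R6", thetas = c(0.1, 0.25, 1, 4, 10),
                   ref = toy$ref)
  expect_true(sm$invariant)
  expect_equal(nrow(sm$breakpoints), 0)
  expect_equal(max(sm$points$objective) - min(sm$points$objective), 0,
               tolerance = 1e-9)
  sl <- theta_scan(ko, "lmoma", "R6",
                   thetas = c(0.1, 0.2, 0.33, 0.34, 0.5, 1, 10),
                   ref = toy$ref)
  expect_false(sl$invariant)
  expect_equal(nrow(sl$breakpoints), 1)
  expect_equal(sl$breakpoints$theta_lo, 0.33)
  expect_equal(sl$breakpoints$theta_hi, 0.34)
  s1 <- theta_scan(ko, "lmoma", "R6", thetas = 1, ref = toy$ref)
  expect_true(s1$invariant)
  expect_error(theta_scan(ko, "lmoma", "R6", thetas = c(1, -1),
                          ref = toy$ref), "positive")
})
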