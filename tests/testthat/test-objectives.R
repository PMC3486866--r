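toy <- build_toy_model()

test_that("FBA on the toy is capacity-limited and scaling-robust", {
  r <- fba(toy$model)
  expect_equal(r$status, "optimal")
  expect_equal(unname(r$objective), 1)
  expect_equal(unname(fba(scale_reactions(toy$model, c(R6 = 0.1)))$objective),
               1)
  # all exchanges shut: optimum 0
  r0 <- fba(toy$model, fixed = c(R1 = 0, R7 = 0))
  expect_equal(unname(r0$objective), 0)
  # unbounded objective is reported as such
  m <- metabolic_model(
    data.frame(id = c("A", "A[e]", "B[e]"), boundary = c(FALSE, TRUE, TRUE)),
    list(reaction("IN", c("A[e]" = -1, A = 1)),
         reaction("OUT", c(A = -1, "B[e]" = 1))), objective = "OUT")
  expect_equal(fba(m)$status, "unbounded")
  expect_error(fba(toy$model, objective = "NOPE"), "unknown")
})

test_that("total-flux minimization reroutes under rescaling", {
  r <- minimize_total_flux(toy$model, fixed = c(R7 = 1))
  expect_equal(unname(r$objective), 3)  # one-step route: R1 + (R5 or R6) + R7
  # rescaling both direct routes by 1/4 makes the long route cheaper:
  # direct 1 + 4 + 1 = 6 vs long 5
  sc <- scale_reactions(toy$model, c(R5 = 0.25, R6 = 0.25))
  r2 <- minimize_total_flux(sc, fixed = c(R7 = 1))
  expect_equal(unname(r2$objective), 5)
  expect_equal(r2$flux$values[["R2"]], 1)
  # everything shut
  r3 <- minimize_total_flux(toy$model, fixed = c(R1 = 0, R7 = 0))
  expect_equal(unname(r3$objective), 0)
  expect_true(all(abs(r3$flux$values) < 1e-9))
})

test_that("total-turnover minimization is scaling-invariant", {
  r <- minimize_total_turnover(toy$model, fixed = c(R7 = 1))
  expect_equal(unname(r$objective), 2)  # t_A + t_D
  for (th in c(0.1, 0.25, 4)) {
    sc <- scale_reactions(toy$model, c(R5 = th, R6 = th))
    expect_equal(unname(minimize_total_turnover(sc,
                                                fixed = c(R7 = 1))$objective),
                 2, info = th)
  }
  expect_equal(unname(minimize_total_turnover(toy$model,
    fixed = c(R1 = 0, R7 = 0))$objective), 0)
  # long-path-only variant: every metabolite turns over once
  ko <- knockout(toy$model, deletion_spec(reactions = c("R5", "R6")))
  expect_equal(unname(minimize_total_turnover(ko, fixed = c(R7 = 1))$objective),
               4)
})

test_that("lMoMA reproduces the rerouting switch of the worked example", {
  ko <- knockout(toy$model, deletion_spec(reactions = "R5"))
  r <- lmoma(ko, toy$ref)
  expect_equal(unname(r$objective), 2)
  expect_equal(r$flux$values[["R6"]], 1)
  # theta = 1/4: the R6 route costs 1 + 1/theta = 5, the long route 4
  sc <- knockout(scale_reactions(toy$model, c(R6 = 0.25)),
                 deletion_spec(reactions = "R5"))
  r2 <- lmoma(sc, toy$ref)
  expect_equal(unname(r2$objective), 4)
  expect_equal(r2$flux$values[["R2"]], 1)
  expect_equal(r2$flux$values[["R6"]], 0)
  # reference feasible in the perturbed model: distance 0, reference returned
  r3 <- lmoma(toy$model, toy$ref)
  expect_equal(unname(r3$objective), 0)
  expect_equal(r3$flux$values, toy$ref$flux$values)
})

test_that("lMoMA optimum matches the route oracle across theta", {
  for (th in c(0.1, 0.2, 1 / 3, 0.4, 1, 4, 10)) {
    ko <- knockout(scale_reactions(toy$model, c(R6 = th)),
                   deletion_spec(reactions = "R5"))
    got <- unname(lmoma(ko, toy$ref)$objective)
    oracle <- toy_pattern_oracle(
      function(v) sum(abs(v - toy$ref$flux$values)),
      delete = "R5", theta = c(R6 = th))
    expect_equal(got, oracle$value, tolerance = 1e-8, info = th)
    expect_equal(got, min(1 + 1 / th, 4), tolerance = 1e-8, info = th)
  }
})

test_that("qMoMA matches its closed-form optimum on the R5-deleted toy", {
  ko <- knockout(toy$model, deletion_spec(reactions = "R5"))
  r <- qmoma(ko, toy$ref)
  expect_equal(unname(r$objective), qmoma_toy_value(1), tolerance = 1e-8)
  expect_equal(r$flux$values[["R2"]], qmoma_toy_lambda(1), tolerance = 1e-8)
  for (th in c(0.25, 1 / sqrt(3), 2)) {
    sc <- knockout(scale_reactions(toy$model, c(R6 = th)),
                   deletion_spec(reactions = "R5"))
    r2 <- qmoma(sc, toy$ref)
    expect_equal(unname(r2$objective), qmoma_toy_value(th), tolerance = 1e-8,
                 info = th)
    expect_equal(r2$flux$values[["R2"]], qmoma_toy_lambda(th),
                 tolerance = 1e-8, info = th)
  }
  # the route usage crosses over at theta = 1/sqrt(3)
  lam <- function(th) qmoma(knockout(scale_reactions(toy$model, c(R6 = th)),
                                     deletion_spec(reactions = "R5")),
                            toy$ref)$flux$values[["R2"]]
  expect_gt(lam(1 / sqrt(3) - 0.05), 0.5)
  expect_lt(lam(1 / sqrt(3) + 0.05), 0.5)
  # identity reference
  expect_equal(unname(qmoma(toy$model, toy$ref)$objective), 0,
               tolerance = 1e-10)
})

test_that("normalized lMoMA floors zero-reference fluxes and is covariant", {
  expect_equal(unname(norm_lmoma(toy$model, toy$ref)$objective), 0)
  ko <- knockout(toy$model, deletion_spec(reactions = "R5"))
  r <- norm_lmoma(ko, toy$ref, floor = 1)
  expect_equal(unname(r$objective), 2)  # R5 term 1/1 + R6 term 1/1
  expect_equal(r$flux$values[["R6"]], 1)
  # rescaling a flux-carrying reaction leaves its objective term invariant
  sc <- knockout(scale_reactions(toy$model, c(R2 = 3, R5 = 0.5, R6 = 2)),
                 deletion_spec(reactions = "R5"))
  r2 <- norm_lmoma(sc, reference_distribution(
    scale_reactions(toy$model, c(R2 = 3, R5 = 0.5, R6 = 2)),
    map_flux_scaling(toy$ref$flux, c(R2 = 3, R5 = 0.5, R6 = 2))), floor = 1)
  expect_equal(unname(r2$objective), unname(r$objective), tolerance = 1e-9)
  expect_error(norm_lmoma(ko, toy$ref, floor = 0), "positive")
})

test_that("MiMBl step 1 is zero whenever a turnover-neutral reroute exists", {
  for (th in c(0.1, 0.25, 1, 4, 10)) {
    ko <- knockout(scale_reactions(toy$model, c(R6 = th)),
                   deletion_spec(reactions = "R5"))
    m <- mimbl(ko, toy$ref)
    expect_equal(m$status, "optimal")
    expect_equal(unname(m$objective["turnover_distance"]), 0,
                 tolerance = 1e-9, info = th)
    # net A->D conversion of one unit through R6 at flux 1/theta
    expect_equal(m$flux$values[["R6"]], 1 / th, tolerance = 1e-8, info = th)
    expect_equal(m$turnover$values, c(A = 1, B = 0, C = 0, D = 1),
                 tolerance = 1e-8)
  }
})

test_that("MiMBl reroutes through the long path when both directs are gone", {
  ko <- knockout(toy$model, deletion_spec(reactions = c("R5", "R6")))
  m <- mimbl(ko, toy$ref)
  expect_equal(unname(m$objective["turnover_distance"]), 2, tolerance = 1e-9)
  expect_equal(m$flux$values[["R2"]], 1, tolerance = 1e-8)
})

test_that("MiMBl identity: a feasible reference is returned unchanged", {
  m <- mimbl(toy$model, toy$ref)
  expect_equal(unname(m$objective["turnover_distance"]), 0)
  expect_equal(unname(m$objective["normalized_flux_distance"]), 0,
               tolerance = 1e-9)
  expect_equal(m$flux$values, toy$ref$flux$values, tolerance = 1e-9)
  gen <- generate_random_model(77)
  m2 <- mimbl(gen$model, gen$ref)
  expect_equal(unname(m2$objective["turnover_distance"]), 0,
               tolerance = 1e-9)
  expect_equal(m2$flux$values, gen$ref$flux$values, tolerance = 1e-8)
})

test_that("MiMBl step 2 respects the step-1 turnover budget", {
  rtol <- 1e-6; atol <- 1e-9
  for (seed in 1:8) {
    gen <- generate_random_model(900 + seed, n_met = 7, n_rxn = 13,
                                 reversible_frac = 0.3)
    internal <- setdiff(reaction_ids(gen$model), c("UPT", "SINK"))
    set.seed(seed)
    del <- internal[sample.int(length(internal), 1)]
    ko <- knockout(gen$model, deletion_spec(reactions = del))
    m <- mimbl(ko, gen$ref, rtol = rtol, atol = atol)
    expect_equal(m$status, "optimal", info = seed)
    dstar <- unname(m$objective["turnover_distance"])
    recomputed <- turnover_distance(m$turnover, gen$ref$turnover)
    expect_lte(recomputed, dstar * (1 + rtol) + atol + 1e-9)
  }
})

test_that("an infeasible perturbation is reported, not fudged", {
  ko <- knockout(toy$model, deletion_spec(reactions = c("R2", "R5", "R6")))
  m <- mimbl(ko, toy$ref)  # uptake is pinned to 1 but no route remains
  expect_equal(m$status, "infeasible")
  expect_null(m$flux)
  expect_equal(lmoma(ko, toy$ref)$status, "infeasible")
  expect_equal(fba(ko)$status, "infeasible")
  expect_equal(qmoma(ko, toy$ref)$status, "infeasible")
})

test_that("metabolite-turnover optimization matches FBA for biomass", {
  r <- optimize_metabolite_turnover(toy$model, "D", "max")
  expect_equal(unname(r$objective), 1)
  r0 <- optimize_metabolite_turnover(toy$model, "B", "max",
                                     fixed = c(R1 = 0, R7 = 0))
  expect_equal(unname(r0$objective), 0)
  expect_error(optimize_metabolite_turnover(toy$model, "A[e]", "max"),
               "intracellular")
  bm <- build_biomass_model()
  growth <- unname(fba(bm$model)$objective)
  expect_equal(unname(optimize_metabolite_turnover(bm$model, "BIO",
                                                   "max")$objective),
               growth, tolerance = 1e-9)
})

test_that("distance objectives are nonnegative and zero iff ref feasible", {
  set.seed(31)
  for (seed in 1:6) {
    gen <- generate_random_model(1200 + seed, n_met = 6, n_rxn = 11)
    internal <- setdiff(reaction_ids(gen$model), c("UPT", "SINK"))
    del <- internal[sample.int(length(internal), 1)]
    ko <- knockout(gen$model, deletion_spec(reactions = del))
    ref_active <- abs(gen$ref$flux$values[del]) > 1e-9
    for (res in list(lmoma(ko, gen$ref), mimbl(ko, gen$ref))) {
      if (res$status != "optimal") next
      expect_gte(unname(res$objective[1]), -1e-12)
      if (!ref_active) expect_lt(unname(res$objective[1]), 1e-9)
    }
  }
})
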