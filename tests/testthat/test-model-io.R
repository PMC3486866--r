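test_that("model construction validates ids, bounds and stoichiometry", {
  expect_error(reaction("R", c(A = 0)), "cancelling")
  expect_error(reaction("R", c(A = 1), lb = 2, ub = 1), "bounds")
  expect_error(reaction("R", setNames(1, "")), "named")
  # both-sides entries collapse to net coefficients
  r <- reaction("R", c(A = -2, A = 1, B = 1))
  expect_equal(unname(r$stoich[["A"]]), -1)
  mets <- data.frame(id = c("A", "B"), boundary = c(FALSE, FALSE))
  expect_error(metabolic_model(mets, list()), "empty reaction list")
  expect_error(
    metabolic_model(mets, list(reaction("R1", c(A = 1)),
                               reaction("R1", c(B = 1)))),
    "duplicate reaction")
  expect_error(metabolic_model(mets, list(reaction("R1", c(C = 1)))),
               "unknown")
  expect_error(
    metabolic_model(data.frame(id = c("A", "A")),
                    list(reaction("R1", c(A = 1)))),
    "duplicate metabolite")
})

test_that("exchange reactions are auto-detected", {
  toy <- build_toy_model()$model
  ex <- vapply(toy$reactions, `[[`, logical(1), "is_exchange")
  expect_setequal(names(ex[ex]), c("R1", "R7"))
  # a reaction touching exactly one intracellular metabolite is an exchange
  # even without an explicit boundary species
  m <- metabolic_model(data.frame(id = c("A", "B")),
                       list(reaction("EX", c(A = 1)),
                            reaction("C1", c(A = -1, B = 1)),
                            reaction("EX2", c(B = -1))))
  ex2 <- vapply(m$reactions, `[[`, logical(1), "is_exchange")
  expect_equal(unname(ex2), c(TRUE, FALSE, TRUE))
})

test_that("toy TSV has the documented shape and round-trips exactly", {
  toy <- build_toy_model(with_genes = TRUE)$model
  path <- tempfile(fileext = ".tsv")
  write_model_tsv(toy, path)
  back <- load_model(path)
  expect_length(back$reactions, 7)
  expect_length(metabolite_ids(back), 4)
  expect_identical(back$objective, "R7")
  for (rid in reaction_ids(toy)) {
    expect_identical(back$reactions[[rid]]$stoich, toy$reactions[[rid]]$stoich)
    expect_identical(back$reactions[[rid]]$lb, toy$reactions[[rid]]$lb)
    expect_identical(back$reactions[[rid]]$ub, toy$reactions[[rid]]$ub)
    expect_identical(back$reactions[[rid]]$gene_rule,
                     toy$reactions[[rid]]$gene_rule)
  }
  # irrational coefficients and infinite bounds survive bit-faithfully
  m <- metabolic_model(
    data.frame(id = c("A", "B")),
    list(reaction("R1", c(A = pi, B = -exp(1)), lb = -Inf, ub = 1 / 3,
                  gene_rule = "g1 and (g2 or g3)"),
         reaction("R2", c(A = -1))))
  p2 <- tempfile(fileext = ".tsv")
  write_model_tsv(m, p2)
  b2 <- read_model_tsv(p2)
  expect_identical(b2$reactions[["R1"]]$stoich, m$reactions[["R1"]]$stoich)
  expect_identical(b2$reactions[["R1"]]$ub, 1 / 3)
  expect_identical(b2$reactions[["R1"]]$lb, -Inf)
})

test_that("SBML round-trip preserves the model", {
  gen <- generate_random_model(11, n_met = 6, n_rxn = 10)
  path <- tempfile(fileext = ".xml")
  write_model_sbml(gen$model, path)
  back <- load_model(path)  # format auto-detected from extension
  expect_identical(reaction_ids(back), reaction_ids(gen$model))
  expect_identical(back$objective, gen$model$objective)
  expect_identical(metabolite_ids(back, intracellular = FALSE) |> sort(),
                   metabolite_ids(gen$model, intracellular = FALSE) |> sort())
  for (rid in reaction_ids(gen$model)) {
    expect_identical(back$reactions[[rid]]$stoich,
                     gen$model$reactions[[rid]]$stoich)
    expect_identical(back$reactions[[rid]]$lb, gen$model$reactions[[rid]]$lb)
    expect_identical(back$reactions[[rid]]$ub, gen$model$reactions[[rid]]$ub)
    expect_identical(back$reactions[[rid]]$gene_rule,
                     gen$model$reactions[[rid]]$gene_rule)
  }
  expect_error(read_model_sbml(tempfile()), "")
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model></model></sbml>", bad)
  expect_error(read_model_sbml(bad), "parse failure")
})

test_that("flux and turnover TSV round-trips preserve values", {
  toy <- build_toy_model()
  p <- tempfile(fileext = ".tsv")
  write_flux_tsv(toy$ref$flux, p)
  expect_identical(read_flux_tsv(p), toy$ref$flux$values)
  p2 <- tempfile(fileext = ".tsv")
  write_turnover_tsv(toy$ref$turnover, p2)
  expect_equal(read_flux_tsv(p2), toy$ref$turnover$values)
})

test_that("flux_state computes the steady-state residual", {
  toy <- build_toy_model()$model
  fs <- flux_state(toy, c(R1 = 1, R2 = 0, R3 = 0, R4 = 0, R5 = 1, R6 = 0,
                          R7 = 1))
  expect_identical(fs$residual, 0)
  fs2 <- flux_state(toy, c(R1 = 1, R2 = 0, R3 = 0, R4 = 0, R5 = 0, R6 = 0,
                           R7 = 1))
  expect_equal(fs2$residual, 1)
  expect_error(flux_state(toy, c(R1 = 1)), "missing")
})
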