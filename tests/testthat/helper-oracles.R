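# Independent oracles for the worked examples and equivalence checks.

# The toy network has one degree of freedom once the uptake is pinned: the
# unit of A->D conversion splits over the three routes (long chain, R5, R6).
# Every objective used on the toy is linear (or piecewise linear with kinks
# at the route vertices) in that split, so exhaustive enumeration of the
# route vertices is an exact oracle. `theta` rescales stoichiometries, so a
# route reaction's flux is its conversion divided by its theta.
toy_route_fluxes <- function(delete = character(), theta = c()) {
  th <- function(r) if (r %in% names(theta)) theta[[r]] else 1
  routes <- list(long = c("R2", "R3", "R4"), r5 = "R5", r6 = "R6")
  routes <- Filter(function(rr) !any(rr %in% delete), routes)
  lapply(routes, function(rr) {
    v <- c(R1 = 1 / th("R1"), R2 = 0, R3 = 0, R4 = 0, R5 = 0, R6 = 0,
           R7 = 1 / th("R7"))
    for (r in rr) v[r] <- 1 / th(r)
    v
  })
}

# Minimal objective value over the feasible route vertices.
toy_pattern_oracle <- function(objective_fn, delete = character(),
                               theta = c()) {
  pats <- toy_route_fluxes(delete, theta)
  if (length(pats) == 0L) return(NULL)
  vals <- vapply(pats, objective_fn, numeric(1))
  list(value = min(vals), flux = pats[[which.min(vals)]])
}

# Turnovers of a toy flux vector under theta-scaled coefficients.
toy_turnover <- function(v, theta = c()) {
  th <- function(r) if (r %in% names(theta)) theta[[r]] else 1
  prod_of <- function(pairs) {
    s <- 0
    for (p in pairs) s <- s + max(p, 0)
    s
  }
  c(A = prod_of(th("R1") * v[["R1"]]) ,
    B = prod_of(th("R2") * v[["R2"]]),
    C = prod_of(th("R3") * v[["R3"]]),
    D = prod_of(c(th("R4") * v[["R4"]], th("R5") * v[["R5"]],
                  th("R6") * v[["R6"]])))
}

# Closed-form qMoMA optimum on the R5-deleted toy: with lambda the share of
# the long route, the squared distance is 1 + 3*lambda^2 + ((1-lambda)/th)^2,
# minimized at lambda* = 1 / (1 + 3 th^2).
qmoma_toy_lambda <- function(th) 1 / (1 + 3 * th^2)
qmoma_toy_value <- function(th) {
  l <- qmoma_toy_lambda(th)
  1 + 3 * l^2 + ((1 - l) / th)^2
}
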