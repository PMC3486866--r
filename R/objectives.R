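# Simulation objectives: FBA, flux/turnover minimization, lMoMA, qMoMA,
# normalized lMoMA, metabolite-turnover optimization, and two-step MiMBl.

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of a single reaction subject to
#' steady-state mass balance and flux bounds. Because a single flux is the
#' objective, the optimum is invariant under rescaling of any reaction's
#' stoichiometric coefficients (the objective reaction's optimum maps by
#' 1/theta like every flux).
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id; defaults to the model's objective reaction.
#' @param sense `"max"` or `"min"`.
#' @param fixed optional named numeric of fluxes pinned to exact values
#'   (overriding bounds).
#' @return a `simulation_result`.
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min"),
                fixed = NULL) {
  sense <- match.arg(sense)
  j <- match(objective, reaction_ids(model))
  if (is.na(j)) stop("fba: unknown objective reaction '", objective, "'",
                     call. = FALSE)
  se <- .sim_env(model, fixed)
  raw <- .simulate_lp(model, fixed = fixed, w_obj = .net_row(se, j),
                      maximize = sense == "max", se = se)
  .mk_result(model, raw, c(objective = raw$value), method = "fba")
}

#' Minimize the total absolute flux
#'
#' Minimizes `sum(|v_i|)` over the selected reactions (default: all, so that
#' exchange fluxes pinned by `fixed` contribute their magnitude) subject to
#' steady state, bounds, and pinned fluxes; implemented over split
#' non-negative fluxes. This parsimony objective is sensitive to the
#' stoichiometry representation: rescaling a flux-carrying reaction rescales
#' its contribution.
#'
#' @param model a `metabolic_model`.
#' @param fixed named numeric of pinned fluxes (typically the exchanges).
#' @param reactions optional reaction ids to restrict the sum to.
#' @return a `simulation_result`.
#' @export
minimize_total_flux <- function(model, fixed = NULL, reactions = NULL) {
  se <- .sim_env(model, fixed)
  sel <- if (is.null(reactions)) rep(TRUE, se$K)
         else se$comp_rxn %in% match(reactions, se$rids)
  raw <- .simulate_lp(model, fixed = fixed, w_obj = as.numeric(sel), se = se)
  .mk_result(model, raw, c(total_flux = raw$value), method = "minflux")
}

#' Minimize the total metabolite turnover
#'
#' Minimizes `sum(t_m)` over intracellular metabolites subject to steady
#' state, bounds, and pinned fluxes. Equivalent to a turnover-space
#' adjustment minimization against a null reference, and invariant under
#' stoichiometry rescaling.
#'
#' @inheritParams minimize_total_flux
#' @return a `simulation_result`.
#' @export
minimize_total_turnover <- function(model, fixed = NULL) {
  se <- .sim_env(model, fixed)
  raw <- .simulate_lp(model, fixed = fixed, w_obj = colSums(se$Aprod), se = se)
  .mk_result(model, raw, c(total_turnover = raw$value), method = "minturnover")
}

#' Linear minimization of metabolic adjustment (lMoMA)
#'
#' Finds the flux distribution minimizing the Manhattan distance
#' `sum(|v_i - v_i_ref|)` to a reference, subject to steady state and bounds.
#' The optimum is representation-dependent: rescaling a reaction rescales its
#' contribution to the distance.
#'
#' @param model a `metabolic_model` (typically a knockout of the reference's
#'   model).
#' @param ref a [reference_distribution()] (or a `flux_state`/named numeric
#'   covering all reactions).
#' @return a `simulation_result`.
#' @export
lmoma <- function(model, ref) {
  vref <- .ref_flux(model, ref)
  raw <- .simulate_lp(model, flux_dev = list(ref = vref))
  .mk_result(model, raw, c(flux_distance = raw$value), method = "lmoma")
}

.ref_flux <- function(model, ref) {
  v <- if (inherits(ref, "reference_distribution")) ref$flux$values
       else as_flux_values(ref)
  missing <- setdiff(reaction_ids(model), names(v))
  if (length(missing) > 0L) {
    stop("reference does not cover reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v[reaction_ids(model)]
}

# Normalization weights for the reference-relative flux distance. h_i is the
# largest |stoichiometric coefficient| of reaction i, so floor / h_i is the
# flux magnitude at which the reaction converts `floor` turnover units: using
# it as the normalization floor keeps every term of the objective invariant
# under coefficient rescaling (see norm_lmoma).
.norm_weights <- function(model, vref, floor) {
  h <- vapply(model$reactions, function(r) max(abs(r$stoich)), numeric(1))
  1 / pmax(abs(vref), floor / h[names(vref)])
}

.ref_turnover <- function(model, ref) {
  if (inherits(ref, "reference_distribution")) {
    tv <- ref$turnover$values
    if (setequal(names(tv), metabolite_ids(model))) return(tv)
  }
  suppressWarnings(turnover_of_flux(model, .ref_flux(model, ref)))$values
}

#' Quadratic minimization of metabolic adjustment (qMoMA)
#'
#' Minimizes the squared Euclidean distance `sum((v_i - v_i_ref)^2)` to the
#' reference subject to steady state and bounds, solved as a strictly convex
#' quadratic program. Like lMoMA, representation-dependent.
#'
#' @inheritParams lmoma
#' @return a `simulation_result` whose objective is the squared distance.
#' @export
qmoma <- function(model, ref) {
  vref <- .ref_flux(model, ref)
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  bounds <- reaction_bounds(model)
  # solve.QP: min 1/2 x'Dx - d'x with A'x >= b, first meq rows equalities
  Dmat <- diag(2, n)
  dvec <- 2 * vref
  Amat <- t(S); bvec <- rep(0, nrow(S)); meq <- nrow(S)
  for (j in seq_len(n)) {
    if (is.finite(bounds[j, "lb"])) {
      r <- numeric(n); r[j] <- 1
      Amat <- cbind(Amat, r); bvec <- c(bvec, bounds[j, "lb"])
    }
    if (is.finite(bounds[j, "ub"])) {
      r <- numeric(n); r[j] <- -1
      Amat <- cbind(Amat, r); bvec <- c(bvec, -bounds[j, "ub"])
    }
  }
  sol <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq),
                  error = function(e) e)
  if (inherits(sol, "error")) {
    return(.mk_result(model, list(status = "infeasible", v = NULL),
                      c(squared_distance = NA_real_), method = "qmoma"))
  }
  v <- stats::setNames(sol$solution, reaction_ids(model))
  .mk_result(model, list(status = "optimal", v = v),
             c(squared_distance = sum((v - vref)^2)), method = "qmoma")
}

#' Normalized lMoMA
#'
#' Minimizes the reference-normalized Manhattan flux distance
#' `sum(|v_i - v_i_ref| / max(|v_i_ref|, floor / h_i))` subject to steady
#' state and bounds, where `h_i` is the largest stoichiometric coefficient of
#' reaction i. Normalizing each deviation by the reference flux makes the
#' terms of flux-carrying reactions invariant under stoichiometry rescaling;
#' reactions with zero (or tiny) reference flux are kept in the objective
#' with bounded weight through the floor. The floor is expressed in turnover
#' units (`floor / h_i` in flux units): a coefficient-rescaled reaction has
#' its flux and its floored weight rescaled oppositely, so the whole
#' objective — not just its flux-carrying terms — is independent of the
#' stoichiometry representation. For unit coefficients this reduces to the
#' flat flux floor `max(|v_i_ref|, floor)`.
#'
#' @inheritParams lmoma
#' @param floor positive flux magnitude below which reference fluxes are
#'   floored for normalization (default 1, in the model's flux units).
#' @param extra optional list of additional constraints: `turn_ref` plus
#'   `turn_budget` impose `sum(|t_m - turn_ref_m|) <= turn_budget` (used by
#'   the second MiMBl step).
#' @return a `simulation_result`.
#' @export
norm_lmoma <- function(model, ref, floor = 1, extra = NULL) {
  if (!is.numeric(floor) || floor <= 0) {
    stop("norm_lmoma: floor must be positive", call. = FALSE)
  }
  vref <- .ref_flux(model, ref)
  wts <- .norm_weights(model, vref, floor)
  turn_dev <- NULL
  if (!is.null(extra) && !is.null(extra$turn_budget)) {
    turn_dev <- list(ref = extra$turn_ref, weight = 0,
                     budget = extra$turn_budget)
  }
  raw <- .simulate_lp(model, flux_dev = list(ref = vref, weights = wts),
                      turn_dev = turn_dev)
  .mk_result(model, raw, c(normalized_flux_distance = raw$value),
             method = "normlmoma")
}

#' Minimization of metabolites balance (MiMBl)
#'
#' Two sequential linear programs. Step 1 finds the minimal Manhattan
#' distance `D* = min sum_m |t_m - t_m_ref|` between mutant and reference
#' intracellular metabolite turnovers. Step 2 reinforces proximity to the
#' reference flux distribution: it minimizes the reference-normalized flux
#' distance (as in [norm_lmoma()]) subject to the turnover distance staying
#' within `D* * (1 + rtol) + atol`. Because turnovers carry the
#' stoichiometric coefficients, the step-1 optimum, the predicted growth and
#' the turnover state are invariant under rescaling of reaction
#' stoichiometries.
#'
#' @inheritParams norm_lmoma
#' @param rtol,atol relative/absolute slack coupling step 2 to the step-1
#'   optimum (defaults 1e-6 / 1e-9; float LP duality slack).
#' @param direction_cap the absolute-value linearization of turnovers over
#'   split fluxes is exact only when no reaction carries simultaneous forward
#'   and backward flux; up to `direction_cap` reversible reactions, both
#'   steps are therefore solved once per forward/backward direction pattern
#'   (an implicit-enumeration equivalent of the complementarity constraint),
#'   and the reported distance is attained by the reported net flux. Above
#'   the cap the plain LP relaxation is used and logged, and the relaxed
#'   distance may undercut the best attainable net-turnover distance on
#'   networks where futile two-way flux can mimic production.
#' @param tertiary if `TRUE`, an additional LP minimizes the total conversion
#'   (coefficient-weighted split flux) at the fixed step-1/step-2 optima.
#' @return a `simulation_result` carrying both objective values
#'   (`turnover_distance`, `normalized_flux_distance`); the flux is the final
#'   optimum and the turnover state is computed from it.
#' @export
mimbl <- function(model, ref, floor = 1, rtol = 1e-6, atol = 1e-9,
                  direction_cap = 8, tertiary = FALSE) {
  vref <- .ref_flux(model, ref)
  tref <- .ref_turnover(model, ref)
  wts <- .norm_weights(model, vref, floor)
  se <- .sim_env(model)
  patterns <- .direction_patterns(se, direction_cap)
  relaxed <- is.null(patterns)
  if (relaxed) patterns <- list(NULL)

  # step 1 per direction pattern; keep the first pattern attaining the best
  # exactly-attained turnover distance (enumeration order is model order, so
  # the choice is deterministic and representation-independent)
  best <- NULL
  step1_status <- "infeasible"
  for (zc in patterns) {
    s1 <- .simulate_lp(model, turn_dev = list(ref = tref, weight = 1),
                       se = se, zero_comps = zc, units = "conversion")
    if (s1$status == "unbounded") step1_status <- "unbounded"
    if (s1$status != "optimal") next
    step1_status <- "optimal"
    if (is.null(best) || s1$value < best$value * (1 - 1e-12) - atol) {
      best <- list(value = s1$value, zc = zc)
    }
  }
  log1 <- list(list(step = "turnover_distance", status = step1_status,
                    objective = if (is.null(best)) NA_real_ else best$value,
                    n_direction_patterns = length(patterns),
                    relaxation = relaxed))
  if (is.null(best)) {
    return(.mk_result(model, list(status = step1_status, v = NULL),
                      c(turnover_distance = NA_real_,
                        normalized_flux_distance = NA_real_),
                      step_log = log1, method = "mimbl"))
  }
  dstar <- best$value
  run_step2 <- function(rt) {
    .simulate_lp(model, flux_dev = list(ref = vref, weights = wts),
                 turn_dev = list(ref = tref, weight = 0,
                                 budget = dstar * (1 + rt) + atol),
                 se = se, zero_comps = best$zc, units = "conversion")
  }
  rt <- rtol
  step2 <- run_step2(rt)
  retried <- FALSE
  if (step2$status != "optimal") {  # numerical slack too tight: relax once
    rt <- rtol * 1e4
    step2 <- run_step2(rt)
    retried <- TRUE
  }
  log2 <- list(list(step = "normalized_flux_distance", status = step2$status,
                    objective = step2$value, rtol = rt, retried = retried))
  if (step2$status != "optimal") {
    return(.mk_result(model, step2, c(turnover_distance = dstar,
                                      normalized_flux_distance = NA_real_),
                      step_log = c(log1, log2), method = "mimbl"))
  }
  final <- step2
  logs <- c(log1, log2)
  if (isTRUE(tertiary)) {
    h <- vapply(model$reactions, function(r) max(abs(r$stoich)), numeric(1))
    step3 <- .simulate_lp(model, w_obj = h[se$comp_rxn],
                          flux_dev = list(ref = vref, weights = wts,
                                          budget = step2$value * (1 + rtol) +
                                            atol,
                                          budget_only = TRUE),
                          turn_dev = list(ref = tref, weight = 0,
                                          budget = dstar * (1 + rt) + atol),
                          se = se, zero_comps = best$zc,
                          units = "conversion")
    logs <- c(logs, list(list(step = "total_conversion",
                              status = step3$status,
                              objective = step3$value)))
    if (step3$status == "optimal") final <- step3
  }
  .mk_result(model, final,
             c(turnover_distance = dstar,
               normalized_flux_distance = step2$value),
             step_log = logs, method = "mimbl")
}

# Forward/backward direction patterns over the genuinely two-sided reversible
# reactions: a list of component-index vectors to pin at zero, or NULL when
# there are more such reactions than the cap (use the LP relaxation then).
.direction_patterns <- function(se, direction_cap) {
  rev_rxns <- which(se$lb < 0 & se$ub > 0)
  if (length(rev_rxns) == 0L) return(list(NULL))
  if (length(rev_rxns) > direction_cap) return(NULL)
  fwd_comp <- vapply(rev_rxns, function(j) {
    which(se$comp_rxn == j & se$comp_sign > 0)[1]
  }, integer(1))
  bwd_comp <- vapply(rev_rxns, function(j) {
    which(se$comp_rxn == j & se$comp_sign < 0)[1]
  }, integer(1))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(rev_rxns)))
  lapply(seq_len(nrow(grid)), function(i) {
    backward <- as.logical(grid[i, ])
    c(fwd_comp[backward], bwd_comp[!backward])
  })
}

#' Optimize the turnover of a single metabolite
#'
#' Maximizes or minimizes `t_m` subject to steady state, bounds, and pinned
#' fluxes. With a single-reaction biomass pseudo-metabolite this reproduces
#' the FBA growth optimum, which is why growth maximization is
#' representation-invariant in both formulations.
#'
#' @param model a `metabolic_model`.
#' @param metabolite id of an intracellular metabolite.
#' @param sense `"max"` or `"min"`.
#' @param fixed named numeric of pinned fluxes.
#' @return a `simulation_result`.
#' @export
optimize_metabolite_turnover <- function(model, metabolite,
                                         sense = c("max", "min"),
                                         fixed = NULL) {
  sense <- match.arg(sense)
  if (!(metabolite %in% metabolite_ids(model, intracellular = TRUE))) {
    stop("optimize_metabolite_turnover: '", metabolite,
         "' is not an intracellular metabolite", call. = FALSE)
  }
  se <- .sim_env(model, fixed)
  m <- match(metabolite, se$mets)
  raw <- .simulate_lp(model, fixed = fixed, w_obj = se$Aprod[m, ],
                      maximize = sense == "max", se = se)
  .mk_result(model, raw, stats::setNames(raw$value,
                                         paste0("turnover_", metabolite)),
             method = "metturnover")
}
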