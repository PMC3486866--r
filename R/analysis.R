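# Flux variability analysis under objective locks, alternative-optima
# enumeration, epistasis scoring and screening, network distance, and
# scaling-sensitivity scans.

# Build the rows that lock a named objective at (near) its optimum, plus the
# deviation blocks those rows need. Returns arguments for .simulate_lp.
.lock_args <- function(model, lock, ref, objective, rtol, atol) {
  lock <- match.arg(lock, c("fba", "mimbl", "lmoma"))
  if (lock == "fba") {
    base <- fba(model, objective = objective)
    if (base$status != "optimal") {
      stop("fva: lock infeasible (FBA status ", base$status, ")", call. = FALSE)
    }
    opt <- unname(base$objective["objective"])
    se <- .sim_env(model)
    j <- match(objective, reaction_ids(model))
    list(extra_rows = list(list(row = .net_row(se, j), dir = ">=",
                                rhs = opt - (abs(opt) * rtol + atol))),
         flux_dev = NULL, turn_dev = NULL, lock_value = opt)
  } else if (lock == "mimbl") {
    if (is.null(ref)) stop("fva: mimbl lock needs a reference", call. = FALSE)
    tref <- .ref_turnover(model, ref)
    step1 <- .simulate_lp(model, turn_dev = list(ref = tref, weight = 1))
    if (step1$status != "optimal") {
      stop("fva: lock infeasible (turnover-distance step status ",
           step1$status, ")", call. = FALSE)
    }
    dstar <- step1$value
    list(extra_rows = NULL, flux_dev = NULL,
         turn_dev = list(ref = tref, weight = 0,
                         budget = dstar * (1 + rtol) + atol),
         lock_value = dstar)
  } else {
    if (is.null(ref)) stop("fva: lmoma lock needs a reference", call. = FALSE)
    base <- lmoma(model, ref)
    if (base$status != "optimal") {
      stop("fva: lock infeasible (lMoMA status ", base$status, ")",
           call. = FALSE)
    }
    lstar <- unname(base$objective["flux_distance"])
    list(extra_rows = NULL,
         flux_dev = list(ref = .ref_flux(model, ref),
                         budget = lstar * (1 + rtol) + atol,
                         budget_only = TRUE),
         turn_dev = NULL, lock_value = lstar)
  }
}

#' Flux variability analysis under an objective lock
#'
#' Per reaction, minimal and maximal flux subject to steady state, bounds,
#' and the chosen objective held at its optimum: the FBA optimum of the
#' objective reaction (`lock = "fba"`), the minimal turnover distance to the
#' reference (`lock = "mimbl"`), or the minimal Manhattan flux distance
#' (`lock = "lmoma"`).
#'
#' The `ratio` column is `min(|v_min|, |v_max|) / max(|v_min|, |v_max|)` when
#' the range does not span zero (`NA` otherwise, with `defined = FALSE`), and
#' a flux is flagged unique if its ratio exceeds 0.99; an exactly zero range
#' (0/0) counts as unique.
#'
#' @param model a `metabolic_model` (typically a knockout).
#' @param lock `"fba"`, `"mimbl"` or `"lmoma"`.
#' @param ref reference distribution (required for the adjustment locks).
#' @param reactions reaction ids to analyse (default: all).
#' @param objective objective reaction id for the FBA lock.
#' @param rtol,atol slack on the locked optimum.
#' @return data.frame: `reaction`, `min`, `max`, `ratio`, `defined`, `unique`,
#'   with the lock value in attribute `"lock_value"`.
#' @export
fva <- function(model, lock = c("fba", "mimbl", "lmoma"), ref = NULL,
                reactions = NULL, objective = model$objective,
                rtol = 1e-6, atol = 1e-9) {
  lock <- match.arg(lock)
  la <- .lock_args(model, lock, ref, objective, rtol, atol)
  rids <- reaction_ids(model)
  if (is.null(reactions)) reactions <- rids
  se <- .sim_env(model)
  out <- data.frame(reaction = character(0), min = numeric(0),
                    max = numeric(0), ratio = numeric(0),
                    defined = logical(0), unique = logical(0),
                    stringsAsFactors = FALSE)
  for (rid in reactions) {
    j <- match(rid, rids)
    if (is.na(j)) stop("fva: unknown reaction '", rid, "'", call. = FALSE)
    vals <- vapply(c(FALSE, TRUE), function(mx) {
      raw <- .simulate_lp(model, w_obj = .net_row(se, j), maximize = mx,
                          flux_dev = la$flux_dev, turn_dev = la$turn_dev,
                          extra_rows = la$extra_rows, se = se)
      if (raw$status != "optimal") {
        stop("fva: subproblem for '", rid, "' returned status ", raw$status,
             call. = FALSE)
      }
      raw$v[[rid]]
    }, numeric(1))
    vmin <- vals[1]; vmax <- vals[2]
    zero_tol <- atol * 1e3 + 1e-9
    both_zero <- abs(vmin) < zero_tol && abs(vmax) < zero_tol
    spans <- (vmin < -zero_tol && vmax > zero_tol)
    ratio <- if (both_zero || spans) NA_real_
             else min(abs(vmin), abs(vmax)) / max(abs(vmin), abs(vmax))
    uniq <- both_zero || (!is.na(ratio) && ratio > 0.99)
    out <- rbind(out, data.frame(reaction = rid, min = vmin, max = vmax,
                                 ratio = ratio, defined = !is.na(ratio),
                                 unique = uniq, stringsAsFactors = FALSE))
  }
  attr(out, "lock_value") <- la$lock_value
  out
}

#' Enumerate alternative FBA optima
#'
#' Collects up to `n` flux distributions that all attain the FBA optimum
#' (within tolerance) but differ in their active-reaction pattern
#' (`|v| > activity_tol`). The optimum is locked as a constraint and the
#' polytope of optima is probed with seeded random secondary objectives;
#' solutions are deduplicated by activity pattern.
#'
#' @param model a `metabolic_model`.
#' @param objective objective reaction id.
#' @param n maximum number of distinct optima to return (`0` gives an empty
#'   list).
#' @param seed integer seed for the randomized secondary objectives.
#' @param max_iter iteration cap.
#' @param activity_tol threshold defining an active reaction.
#' @param rtol,atol slack on the locked optimum.
#' @return list of `flux_state`s, each attaining the optimum; attribute
#'   `"optimum"` carries the shared objective value.
#' @export
enumerate_alternative_optima <- function(model, objective = model$objective,
                                         n = 10, seed = 1, max_iter = 1000,
                                         activity_tol = 1e-6,
                                         rtol = 1e-9, atol = 1e-9) {
  if (n <= 0) return(list())
  base <- fba(model, objective = objective)
  if (base$status != "optimal") {
    stop("enumerate_alternative_optima: base FBA status ", base$status,
         call. = FALSE)
  }
  opt <- unname(base$objective["objective"])
  rids <- reaction_ids(model)
  se <- .sim_env(model)
  j <- match(objective, rids)
  lock <- list(list(row = .net_row(se, j), dir = ">=",
                    rhs = opt - (abs(opt) * rtol + atol)))
  pattern_of <- function(v) paste(as.integer(abs(v) > activity_tol),
                                  collapse = "")
  found <- list(flux_state(model, base$flux$values))
  patterns <- pattern_of(base$flux$values)
  set.seed(seed)
  it <- 0L
  while (length(found) < n && it < max_iter) {
    it <- it + 1L
    c_net <- stats::runif(length(rids), -1, 1)
    w_obj <- c_net[se$comp_rxn] * se$comp_sign
    raw <- .simulate_lp(model, w_obj = w_obj, extra_rows = lock, se = se)
    if (raw$status != "optimal") next
    pat <- pattern_of(raw$v)
    if (!(pat %in% patterns)) {
      patterns <- c(patterns, pat)
      found[[length(found) + 1L]] <- flux_state(model, raw$v)
    }
  }
  attr(found, "optimum") <- opt
  found
}

#' Epistasis score of a gene pair
#'
#' Fitnesses are growths normalized by the wild-type growth and clipped to be
#' non-negative; the score is the deviation of the double mutant from the
#' multiplicative null, `epsilon = f_ab - f_a * f_b`. The pair is called
#' positively interacting when `epsilon > cutoff`, negatively when
#' `epsilon < -cutoff`, and non-interacting otherwise.
#'
#' @param growth_a,growth_b single-mutant growths.
#' @param growth_ab double-mutant growth.
#' @param growth_wt wild-type growth (> 0).
#' @param cutoff interaction cutoff on `|epsilon|` (default 0.013).
#' @param gene_a,gene_b optional gene ids recorded in the result.
#' @return one-row data.frame: `gene_a`, `gene_b`, `f_a`, `f_b`, `f_ab`,
#'   `epsilon`, `call`.
#' @export
epistasis <- function(growth_a, growth_b, growth_ab, growth_wt,
                      cutoff = 0.013, gene_a = NA_character_,
                      gene_b = NA_character_) {
  if (!is.finite(growth_wt) || growth_wt <= 0) {
    stop("epistasis: wild-type growth must be positive", call. = FALSE)
  }
  f_a <- max(growth_a / growth_wt, 0)
  f_b <- max(growth_b / growth_wt, 0)
  f_ab <- max(growth_ab / growth_wt, 0)
  eps <- f_ab - f_a * f_b
  call <- if (eps > cutoff) "positive" else if (eps < -cutoff) "negative"
          else "none"
  data.frame(gene_a = gene_a, gene_b = gene_b, f_a = f_a, f_b = f_b,
             f_ab = f_ab, epsilon = eps, call = call,
             stringsAsFactors = FALSE)
}

# Growth of one mutant under the chosen simulator; infeasible mutants grow 0.
.mutant_growth <- function(model, genes, simulator, ref, objective, mode) {
  ko <- knockout(model, deletion_spec(genes = genes, mode = mode),
                 missing_genes = "ignore")
  res <- switch(simulator,
    fba = fba(ko, objective = objective),
    mimbl = mimbl(ko, ref),
    lmoma = lmoma(ko, ref),
    qmoma = qmoma(ko, ref))
  if (res$status != "optimal") return(0)
  max(res$flux$values[[objective]], 0)
}

#' Screen gene pairs for genetic interactions
#'
#' Runs single- and double-deletion simulations under the chosen objective
#' and scores each pair with [epistasis()]. Single-deletion growths are
#' computed once per gene and cached; infeasible mutants get growth 0. The
#' wild-type growth is the FBA optimum for the FBA simulator and the
#' reference's own objective flux for the adjustment-based simulators.
#'
#' @param model a `metabolic_model` with gene rules and an objective reaction.
#' @param pairs two-column data.frame (or list of length-2 vectors) of gene
#'   pairs.
#' @param simulator `"fba"`, `"mimbl"`, `"lmoma"` or `"qmoma"`.
#' @param ref reference distribution (required for non-FBA simulators).
#' @param cutoff epistasis cutoff (default 0.013).
#' @param mode deletion mode, see [deletion_spec()].
#' @return data.frame of epistasis records, one row per pair.
#' @export
interaction_screen <- function(model, pairs,
                               simulator = c("fba", "mimbl", "lmoma", "qmoma"),
                               ref = NULL, cutoff = 0.013,
                               mode = c("gene_centered",
                                        "reaction_centered_isoenzyme")) {
  simulator <- match.arg(simulator)
  mode <- match.arg(mode)
  objective <- model$objective
  if (is.null(objective)) {
    stop("interaction_screen: model has no objective reaction", call. = FALSE)
  }
  if (simulator != "fba" && is.null(ref)) {
    stop("interaction_screen: simulator '", simulator,
         "' requires a reference distribution", call. = FALSE)
  }
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) as.character(unlist(pairs[i, 1:2])))
  }
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      f_a = numeric(0), f_b = numeric(0), f_ab = numeric(0),
                      epsilon = numeric(0), call = character(0),
                      stringsAsFactors = FALSE))
  }
  growth_wt <- if (simulator == "fba") {
    res <- fba(model, objective = objective)
    if (res$status != "optimal") {
      stop("interaction_screen: wild-type FBA not optimal", call. = FALSE)
    }
    unname(res$objective["objective"])
  } else {
    .ref_flux(model, ref)[[objective]]
  }
  cache <- new.env(parent = emptyenv())
  single <- function(g) {
    if (is.null(cache[[g]])) {
      cache[[g]] <- .mutant_growth(model, g, simulator, ref, objective, mode)
    }
    cache[[g]]
  }
  out <- NULL
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    rec <- epistasis(single(a), single(b),
                     .mutant_growth(model, c(a, b), simulator, ref, objective,
                                    mode),
                     growth_wt, cutoff = cutoff, gene_a = a, gene_b = b)
    out <- rbind(out, rec)
  }
  rownames(out) <- NULL
  out
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Sensitivity/precision curves for interaction predictions
#'
#' For each cutoff and each interaction sign, predictions are the pairs whose
#' score exceeds the cutoff (in the signed direction); the observed table
#' defines the truth universe. Sensitivity is the fraction of observed
#' interactions of that sign that are predicted; precision is the fraction of
#' predictions (restricted to the universe) that are observed with that sign,
#' reported `NA` when nothing is predicted.
#'
#' @param predicted data.frame with `gene_a`, `gene_b`, `epsilon` (e.g. from
#'   [interaction_screen()]).
#' @param observed data.frame with `gene_a`, `gene_b`, `sign`
#'   (`"positive"`/`"negative"`); pairs are unordered.
#' @param cutoffs numeric vector of cutoffs to evaluate.
#' @return data.frame of curve points: `cutoff`, `sign`, `sensitivity`,
#'   `precision`, `n_predicted`.
#' @export
sensitivity_precision_curve <- function(predicted, observed, cutoffs) {
  okey <- .pair_key(as.character(observed$gene_a),
                    as.character(observed$gene_b))
  osign <- as.character(observed$sign)
  if (anyDuplicated(okey)) {
    agg <- tapply(osign, okey, function(s) length(unique(s)))
    if (any(agg > 1L)) {
      stop("sensitivity_precision_curve: conflicting truth labels for pair(s)",
           call. = FALSE)
    }
    keep <- !duplicated(okey)
    okey <- okey[keep]; osign <- osign[keep]
  }
  pkey <- .pair_key(as.character(predicted$gene_a),
                    as.character(predicted$gene_b))
  eps <- as.numeric(predicted$epsilon)
  in_universe <- pkey %in% okey
  out <- NULL
  for (cf in cutoffs) {
    for (sgn in c("positive", "negative")) {
      pred <- if (sgn == "positive") eps > cf else eps < -cf
      pred_keys <- unique(pkey[pred & in_universe])
      truth_keys <- okey[osign == sgn]
      tp <- length(intersect(pred_keys, truth_keys))
      sens <- if (length(truth_keys) == 0L) NA_real_
              else tp / length(truth_keys)
      prec <- if (length(pred_keys) == 0L) NA_real_
              else tp / length(pred_keys)
      out <- rbind(out, data.frame(cutoff = cf, sign = sgn,
                                   sensitivity = sens, precision = prec,
                                   n_predicted = length(pred_keys),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Graph-theoretic distance between two genes in the reaction network
#'
#' Reactions are nodes; two reactions are adjacent iff they share an
#' intracellular metabolite whose reaction-degree does not exceed
#' `currency_degree_cutoff` (excluding currency metabolites such as cofactors
#' from creating shortcuts). The distance between two genes is the shortest
#' path between their reaction sets; genes sharing a reaction have
#' distance 0, and `Inf` marks unreachable pairs.
#'
#' @param model a `metabolic_model`.
#' @param gene_a,gene_b gene ids (must appear in some gene rule).
#' @param currency_degree_cutoff metabolite reaction-degree above which a
#'   metabolite no longer connects reactions; default: the 95th percentile of
#'   the metabolite degree distribution.
#' @return non-negative integer distance, or `Inf` if unreachable.
#' @export
network_distance <- function(model, gene_a, gene_b,
                             currency_degree_cutoff = NULL) {
  rids <- reaction_ids(model)
  genes_of <- lapply(model$reactions, function(r) rule_genes(r$rule))
  rxns_a <- rids[vapply(genes_of, function(g) gene_a %in% g, logical(1))]
  rxns_b <- rids[vapply(genes_of, function(g) gene_b %in% g, logical(1))]
  if (length(rxns_a) == 0L) stop("network_distance: gene '", gene_a,
                                 "' absent from all gene rules", call. = FALSE)
  if (length(rxns_b) == 0L) stop("network_distance: gene '", gene_b,
                                 "' absent from all gene rules", call. = FALSE)
  if (length(intersect(rxns_a, rxns_b)) > 0L) return(0)
  S <- stoichiometric_matrix(model)
  degree <- rowSums(S != 0)
  if (is.null(currency_degree_cutoff)) {
    currency_degree_cutoff <- stats::quantile(degree, 0.95, names = FALSE)
  }
  keep <- degree <= currency_degree_cutoff
  edges <- character(0)
  for (m in rownames(S)[keep]) {
    touching <- rids[S[m, ] != 0]
    if (length(touching) >= 2L) {
      cmb <- utils::combn(touching, 2L)
      edges <- c(edges, as.character(cmb))
    }
  }
  g <- igraph::make_empty_graph(n = length(rids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rids)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  d <- igraph::distances(g, v = rxns_a, to = rxns_b)
  min(d)
}

#' Scan a simulator across stoichiometry rescalings of one reaction
#'
#' For each theta the model is rescaled ([scale_reactions()]), the simulator
#' is run, and the objective value plus the scanned reaction's flux (raw and
#' mapped back by multiplying with theta) are recorded. The scan is flagged
#' invariant when all objective values agree within `tol`; consecutive thetas
#' whose objective jumps off the locally linear trend mark representation
#' sensitivity, and solution-switch breakpoints are reported as the theta
#' intervals where the active-reaction pattern changes.
#'
#' @param model a `metabolic_model`.
#' @param method `"fba"`, `"lmoma"`, `"qmoma"`, `"normlmoma"`, `"mimbl"`,
#'   `"minflux"` or `"minturnover"`.
#' @param reaction reaction id to rescale.
#' @param thetas positive scaling factors to scan.
#' @param ref reference distribution (adjustment-based methods).
#' @param objective objective reaction (FBA).
#' @param fixed pinned fluxes (minimization methods).
#' @param tol objective-invariance tolerance.
#' @param activity_tol threshold defining the active-reaction pattern.
#' @return list with `points` (data.frame theta/status/objective/flux),
#'   `invariant` flag and `breakpoints` (data.frame of theta intervals).
#' @export
theta_scan <- function(model, method, reaction, thetas, ref = NULL,
                       objective = model$objective, fixed = NULL,
                       tol = 1e-6, activity_tol = 1e-6) {
  if (any(thetas <= 0)) stop("theta_scan: thetas must be positive",
                             call. = FALSE)
  run_one <- function(mdl) {
    switch(method,
      fba = fba(mdl, objective = objective),
      lmoma = lmoma(mdl, ref),
      qmoma = qmoma(mdl, ref),
      normlmoma = norm_lmoma(mdl, ref),
      mimbl = mimbl(mdl, ref),
      minflux = minimize_total_flux(mdl, fixed = fixed),
      minturnover = minimize_total_turnover(mdl, fixed = fixed),
      stop("theta_scan: unknown method '", method, "'", call. = FALSE))
  }
  pts <- NULL
  patterns <- character(0)
  for (th in thetas) {
    scaled <- scale_reactions(model, stats::setNames(th, reaction))
    res <- tryCatch(run_one(scaled), error = function(e) e)
    if (inherits(res, "error") || res$status != "optimal") {
      status <- if (inherits(res, "error")) conditionMessage(res) else res$status
      pts <- rbind(pts, data.frame(theta = th, status = status,
                                   objective = NA_real_, flux = NA_real_,
                                   flux_mapped = NA_real_,
                                   stringsAsFactors = FALSE))
      patterns <- c(patterns, NA_character_)
      next
    }
    v <- res$flux$values
    pts <- rbind(pts, data.frame(theta = th, status = "optimal",
                                 objective = unname(res$objective[1]),
                                 flux = v[[reaction]],
                                 flux_mapped = v[[reaction]] * th,
                                 stringsAsFactors = FALSE))
    patterns <- c(patterns, paste(as.integer(abs(v) > activity_tol),
                                  collapse = ""))
  }
  obj <- pts$objective[pts$status == "optimal"]
  invariant <- length(obj) > 0L &&
    (max(obj) - min(obj)) <= tol * max(1, max(abs(obj)))
  bp <- NULL
  ord <- order(pts$theta)
  for (k in seq_len(length(ord) - 1L)) {
    i <- ord[k]; j <- ord[k + 1L]
    if (!is.na(patterns[i]) && !is.na(patterns[j]) &&
        patterns[i] != patterns[j]) {
      bp <- rbind(bp, data.frame(theta_lo = pts$theta[i],
                                 theta_hi = pts$theta[j]))
    }
  }
  list(points = pts, invariant = invariant,
       breakpoints = bp %||% data.frame(theta_lo = numeric(0),
                                        theta_hi = numeric(0)))
}
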