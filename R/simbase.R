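# Internal assembly of simulation LPs.
#
# Every simulation optimizes over non-negative split flux components
# (reversible reactions contribute a forward and a backward column with
# negated stoichiometry), optionally augmented with absolute-deviation
# variable pairs for fluxes (d+ / d-) and for metabolite turnovers (e+ / e-);
# |x| is linearized as x+ + x- with x = x+ - x- throughout. Turnover inside an
# LP is the production-side sum over split components,
#   t_m = sum_j max(s_mj, 0) * w_j,
# which coincides with the net-flux turnover whenever no reaction carries
# simultaneous forward and backward split flux.

# Split-model scaffolding: components, their boxes, and coefficient matrices.
.sim_env <- function(model, fixed = NULL) {
  rids <- reaction_ids(model)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), rids)
    if (length(unknown) > 0L) {
      stop("fixed flux for unknown reaction(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  lb <- bounds[, "lb"]; ub <- bounds[, "ub"]
  if (!is.null(fixed)) {  # fixed values override bounds (equality pin)
    lb[names(fixed)] <- as.numeric(fixed)
    ub[names(fixed)] <- as.numeric(fixed)
  }
  comp_rxn <- integer(0); comp_sign <- numeric(0); comp_ub <- numeric(0)
  for (j in seq_along(rids)) {
    if (lb[j] < 0) {
      comp_rxn <- c(comp_rxn, j, j)
      comp_sign <- c(comp_sign, 1, -1)
      comp_ub <- c(comp_ub, max(ub[j], 0), -lb[j])
    } else {
      comp_rxn <- c(comp_rxn, j)
      comp_sign <- c(comp_sign, 1)
      comp_ub <- c(comp_ub, ub[j])
    }
  }
  Ssplit <- S[, comp_rxn, drop = FALSE] *
    matrix(comp_sign, nrow(S), length(comp_sign), byrow = TRUE)
  list(model = model, rids = rids, mets = rownames(S), S = S,
       lb = lb, ub = ub,
       comp_rxn = comp_rxn, comp_sign = comp_sign, comp_ub = comp_ub,
       K = length(comp_rxn),
       Ssplit = Ssplit, Aprod = pmax(Ssplit, 0))
}

# Row over the component block giving the net flux of reaction j.
.net_row <- function(se, j) {
  r <- numeric(se$K)
  sel <- se$comp_rxn == j
  r[sel] <- se$comp_sign[sel]
  r
}

# Assemble and solve one simulation LP. Returns status, objective value, net
# fluxes v, split fluxes w, and the deviation blocks when present.
.simulate_lp <- function(model, fixed = NULL, w_obj = NULL,
                         flux_dev = NULL, turn_dev = NULL, maximize = FALSE,
                         extra_rows = NULL, se = NULL, zero_comps = NULL,
                         units = c("flux", "conversion")) {
  units <- match.arg(units)
  if (is.null(se)) se <- .sim_env(model, fixed)
  K <- se$K
  nr <- length(se$rids)
  nm <- length(se$mets)
  use_fd <- !is.null(flux_dev)
  use_td <- !is.null(turn_dev)
  ncol_fd <- if (use_fd) 2L * nr else 0L
  ncol_td <- if (use_td) 2L * nm else 0L
  ntot <- K + ncol_fd + ncol_td
  fd_pos <- function(j) K + 2L * (j - 1L) + 1L          # d+ column of rxn j
  td_pos <- function(m) K + ncol_fd + 2L * (m - 1L) + 1L # e+ column of met m

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  row_rxn <- integer(0)  # reaction whose flux units the row's rhs carries
  add <- function(idx, val, dir, b, unit_rxn = NA_integer_) {
    r <- numeric(ntot); r[idx] <- val
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
    row_rxn <<- c(row_rxn, unit_rxn)
  }
  comp_ub <- se$comp_ub
  if (!is.null(zero_comps)) comp_ub[zero_comps] <- 0  # direction fixing
  ub <- c(comp_ub, rep(Inf, ncol_fd + ncol_td))
  # steady state over intracellular metabolites
  for (m in seq_len(nm)) {
    add(seq_len(K), se$Ssplit[m, ], "=", 0)
  }
  # residual net-bound rows (component boxes are variable bounds)
  for (j in seq_len(nr)) {
    if (se$lb[j] > 0) add(which(se$comp_rxn == j),
                          se$comp_sign[se$comp_rxn == j], ">=", se$lb[j], j)
    if (se$ub[j] < 0) add(which(se$comp_rxn == j),
                          se$comp_sign[se$comp_rxn == j], "<=", se$ub[j], j)
  }
  obj <- numeric(ntot)
  if (!is.null(w_obj)) obj[seq_len(K)] <- w_obj
  if (use_fd) {
    ref <- flux_dev$ref[se$rids]
    wts <- if (is.null(flux_dev$weights)) stats::setNames(rep(1, nr), se$rids)
           else flux_dev$weights[se$rids]
    for (j in seq_len(nr)) {
      sel <- se$comp_rxn == j
      add(c(which(sel), fd_pos(j), fd_pos(j) + 1L),
          c(se$comp_sign[sel], -1, 1), "=", ref[j], j)
      obj[fd_pos(j)] <- obj[fd_pos(j)] + wts[j]
      obj[fd_pos(j) + 1L] <- obj[fd_pos(j) + 1L] + wts[j]
    }
    if (!is.null(flux_dev$budget)) {
      r <- numeric(ntot)
      for (j in seq_len(nr)) r[c(fd_pos(j), fd_pos(j) + 1L)] <- wts[j]
      rows[[length(rows) + 1L]] <- r; dirs <- c(dirs, "<=")
      rhs <- c(rhs, flux_dev$budget)
      if (isTRUE(flux_dev$budget_only)) {  # budget constraint, no objective term
        obj[(K + 1L):(K + ncol_fd)] <- 0
      }
    }
  }
  if (use_td) {
    tref <- turn_dev$ref[se$mets]
    twt <- turn_dev$weight %||% 0
    for (m in seq_len(nm)) {
      add(c(seq_len(K), td_pos(m), td_pos(m) + 1L),
          c(se$Aprod[m, ], -1, 1), "=", tref[m])
      obj[td_pos(m)] <- obj[td_pos(m)] + twt
      obj[td_pos(m) + 1L] <- obj[td_pos(m) + 1L] + twt
    }
    if (!is.null(turn_dev$budget)) {
      r <- numeric(ntot)
      r[(K + ncol_fd + 1L):ntot] <- 1
      rows[[length(rows) + 1L]] <- r; dirs <- c(dirs, "<=")
      rhs <- c(rhs, turn_dev$budget)
    }
  }
  if (!is.null(extra_rows)) {
    for (er in extra_rows) {
      r <- numeric(ntot)
      r[seq_along(er$row)] <- er$row  # rows over the component block
      rows[[length(rows) + 1L]] <- r; dirs <- c(dirs, er$dir)
      rhs <- c(rhs, er$rhs)
    }
  }
  mat <- do.call(rbind, rows)
  cscale <- rep(1, ntot)
  if (units == "conversion") {
    # solve in conversion units u = h * w (h = largest |coefficient| of the
    # reaction): the program's matrices are then invariant under coefficient
    # rescaling, so equivalent representations follow identical pivot paths
    # and return the same optimum even through degenerate ties
    h <- vapply(se$model$reactions, function(r) max(abs(r$stoich)),
                numeric(1))
    cscale[seq_len(K)] <- 1 / h[se$comp_rxn]
    if (use_fd) {
      for (j in seq_len(nr)) {
        cscale[c(fd_pos(j), fd_pos(j) + 1L)] <- 1 / h[j]
      }
    }
    mat <- mat * matrix(cscale, nrow(mat), ntot, byrow = TRUE)
    obj <- obj * cscale
    ub <- ub / cscale
    # rows whose rhs is a flux of reaction r are rescaled into its
    # conversion units as well, making every row of the program invariant
    for (i in which(!is.na(row_rxn))) {
      mat[i, ] <- mat[i, ] * h[row_rxn[i]]
      rhs[i] <- rhs[i] * h[row_rxn[i]]
    }
  }
  sol <- solve_lp(obj, mat, dirs, rhs, ub = ub, maximize = maximize)
  if (sol$status != "optimal") {
    return(list(status = sol$status, value = sol$value, v = NULL, w = NULL,
                se = se))
  }
  sol$x <- sol$x * cscale
  w <- sol$x[seq_len(K)]
  v <- stats::setNames(numeric(nr), se$rids)
  for (j in seq_len(nr)) {
    sel <- se$comp_rxn == j
    v[j] <- sum(se$comp_sign[sel] * w[sel])
  }
  list(status = "optimal", value = sol$value, v = v, w = w, se = se)
}

# Package a raw LP result as a user-facing simulation_result.
.mk_result <- function(model, raw, objective, step_log = list(),
                       method = "lp") {
  if (is.null(raw$v)) {
    return(structure(list(status = raw$status, objective = objective,
                          flux = NULL, turnover = NULL, step_log = step_log,
                          method = method),
                     class = "simulation_result"))
  }
  fs <- flux_state(model, raw$v)
  structure(list(status = "optimal", objective = objective, flux = fs,
                 turnover = suppressWarnings(turnover_of_flux(model, fs)),
                 step_log = step_log, method = method),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result [", x$method, "] status:", x$status, "\n")
  if (length(x$objective) > 0L) {
    for (nm in names(x$objective)) {
      cat("  ", nm, "=", format(x$objective[[nm]], digits = 8), "\n")
    }
  }
  invisible(x)
}
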