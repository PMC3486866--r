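# Metabolite turnover: the quantity in which representation-independent
# objectives are expressed.
#
# The turnover t_m of an intracellular metabolite m under a flux distribution
# v is the sum of all fluxes producing it, each multiplied by its (positive)
# stoichiometric coefficient: t_m = sum over { i : s_mi * v_i > 0 } of
# s_mi * v_i. At exact steady state this equals the analogous consumption-side
# sum. Because coefficients enter the definition, t_m is invariant under
# rescaling a reaction's stoichiometry (coefficients x theta, flux / theta).

#' Compute metabolite turnovers from a flux distribution
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_state` or named numeric vector covering all reactions.
#' @param ss_tol steady-state residual above which a diagnostic warning is
#'   emitted (production- and consumption-side turnovers then disagree by up
#'   to that residual).
#' @return a `turnover_state`: list with `values` (named non-negative numeric
#'   over intracellular metabolites) and `residual`.
#' @export
turnover_of_flux <- function(model, flux, ss_tol = 1e-6) {
  v <- as_flux_values(flux)
  missing <- setdiff(reaction_ids(model), names(v))
  if (length(missing) > 0L) {
    stop("turnover_of_flux: flux missing reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- v[reaction_ids(model)]
  S <- stoichiometric_matrix(model)
  contrib <- sweep(S, 2L, v, `*`)      # s_mi * v_i
  tv <- rowSums(pmax(contrib, 0))      # production side
  res <- if (nrow(S) > 0L) max(abs(S %*% v)) else 0
  if (res > ss_tol) {
    warning("turnover_of_flux: flux is not at steady state (residual ",
            format(res, digits = 3), "); production- and consumption-side ",
            "turnovers differ", call. = FALSE)
  }
  structure(list(values = tv, residual = res), class = "turnover_state")
}

#' @export
print.turnover_state <- function(x, ...) {
  cat("turnover_state over", length(x$values), "metabolites; total",
      format(sum(x$values), digits = 6), "\n")
  invisible(x)
}

as_turnover_values <- function(x) {
  if (inherits(x, "turnover_state")) x$values
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("expected a turnover_state or a named numeric vector", call. = FALSE)
}

#' Manhattan distance between two turnover states
#'
#' @param a,b `turnover_state`s (or named numeric vectors) over the same set
#'   of intracellular metabolites.
#' @return `sum(|a_m - b_m|)`, non-negative.
#' @export
turnover_distance <- function(a, b) {
  av <- as_turnover_values(a); bv <- as_turnover_values(b)
  if (!setequal(names(av), names(bv))) {
    stop("turnover_distance: metabolite domains differ", call. = FALSE)
  }
  sum(abs(av - bv[names(av)]))
}

#' Bundle a reference (wild-type) flux with its derived turnovers
#'
#' @param model a `metabolic_model`.
#' @param flux reference flux distribution (`flux_state` or named numeric).
#' @return a `reference_distribution` with elements `flux` and `turnover`.
#' @export
reference_distribution <- function(model, flux) {
  fs <- if (inherits(flux, "flux_state")) flux else flux_state(model, flux)
  structure(list(flux = fs, turnover = turnover_of_flux(model, fs)),
            class = "reference_distribution")
}
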