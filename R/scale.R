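# Stoichiometry rescaling and reversible-reaction splitting.
#
# Multiplying all coefficients of a reaction by a positive scalar theta is a
# biochemically equivalent re-representation of the same network: any flux v_r
# maps to v_r / theta with identical net conversions. Whether a simulation
# objective is invariant under this transformation is the central property
# this package exposes for study.

#' Construct a scaling transform
#'
#' @param factors named numeric vector, reaction id -> theta (> 0).
#' @param rescale_bounds if `TRUE` (default) finite flux bounds of scaled
#'   reactions are divided by theta so that the representation is exactly
#'   equivalent also for bounded reactions; `FALSE` reproduces
#'   coefficients-only scaling.
#' @return a `scaling_transform`.
#' @export
scaling_transform <- function(factors, rescale_bounds = TRUE) {
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("scaling factors must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("scaling factors must be positive and finite", call. = FALSE)
  }
  structure(list(factors = factors, rescale_bounds = isTRUE(rescale_bounds)),
            class = "scaling_transform")
}

#' Rescale the stoichiometry of selected reactions
#'
#' Every coefficient of reaction r is multiplied by `theta_r`; with
#' `rescale_bounds` on, finite bounds are divided by `theta_r`. The feasible
#' net-conversion space is unchanged, with the flux of r mapping as
#' `v_r -> v_r / theta_r`.
#'
#' @param model a `metabolic_model`.
#' @param transform a [scaling_transform()], or a bare named numeric vector of
#'   thetas (bounds then rescaled by default).
#' @return the rescaled model.
#' @export
scale_reactions <- function(model, transform) {
  if (!inherits(transform, "scaling_transform")) {
    transform <- scaling_transform(transform)
  }
  unknown <- setdiff(names(transform$factors), reaction_ids(model))
  if (length(unknown) > 0L) {
    stop("scale_reactions: unknown reaction id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (rid in names(transform$factors)) {
    th <- transform$factors[[rid]]
    r <- model$reactions[[rid]]
    r$stoich <- r$stoich * th
    if (transform$rescale_bounds) {
      if (is.finite(r$lb)) r$lb <- r$lb / th
      if (is.finite(r$ub)) r$ub <- r$ub / th
    }
    model$reactions[[rid]] <- r
  }
  validate_model(model)
}

#' Map a flux distribution between scaled representations
#'
#' Given fluxes on the original model, returns the equivalent fluxes on the
#' theta-scaled model (`v_r / theta_r`), or the inverse with `inverse = TRUE`.
#'
#' @param flux named numeric vector or `flux_state`.
#' @param transform a [scaling_transform()] or named theta vector.
#' @param inverse map scaled-model fluxes back to the original representation.
#' @return named numeric vector.
#' @export
map_flux_scaling <- function(flux, transform, inverse = FALSE) {
  if (!inherits(transform, "scaling_transform")) {
    transform <- scaling_transform(transform)
  }
  v <- as_flux_values(flux)
  ids <- intersect(names(transform$factors), names(v))
  th <- transform$factors[ids]
  v[ids] <- if (inverse) v[ids] * th else v[ids] / th
  v
}

#' Split reversible reactions into forward/backward components
#'
#' Every reaction with `lb < 0` is replaced by a forward component (bounds
#' `[0, ub]`) and a backward component (bounds `[0, -lb]`, negated
#' stoichiometry). The returned mapping recombines split fluxes into net
#' fluxes `v = w_fwd - w_bwd`.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` (the split model) and `mapping`, a data.frame
#'   with columns `reaction`, `forward`, `backward` (`NA` when not split).
#' @export
split_reversible <- function(model) {
  rxns <- list()
  map <- data.frame(reaction = character(0), forward = character(0),
                    backward = character(0), stringsAsFactors = FALSE)
  for (r in model$reactions) {
    if (r$lb < 0) {
      fwd <- r; fwd$id <- paste0(r$id, "__fwd"); fwd$lb <- 0
      fwd$ub <- max(r$ub, 0)
      bwd <- r; bwd$id <- paste0(r$id, "__bwd"); bwd$stoich <- -r$stoich
      bwd$lb <- 0; bwd$ub <- -r$lb
      rxns <- c(rxns, list(fwd, bwd))
      map <- rbind(map, data.frame(reaction = r$id, forward = fwd$id,
                                   backward = bwd$id, stringsAsFactors = FALSE))
    } else {
      rxns <- c(rxns, list(r))
      map <- rbind(map, data.frame(reaction = r$id, forward = r$id,
                                   backward = NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  obj <- model$objective
  if (!is.null(obj) && map$forward[match(obj, map$reaction)] != obj) {
    obj <- NULL  # objective reaction was split; net flux no longer one column
  }
  list(model = metabolic_model(model$metabolites, rxns, objective = obj,
                               provenance = model$provenance),
       mapping = map)
}

#' Recombine split-component fluxes into net fluxes
#'
#' @param split_flux named numeric vector over the split model's reactions.
#' @param mapping the mapping returned by [split_reversible()].
#' @return named numeric vector over the original reactions.
#' @export
recombine_fluxes <- function(split_flux, mapping) {
  out <- numeric(nrow(mapping))
  names(out) <- mapping$reaction
  for (i in seq_len(nrow(mapping))) {
    v <- split_flux[[mapping$forward[i]]]
    if (!is.na(mapping$backward[i])) v <- v - split_flux[[mapping$backward[i]]]
    out[i] <- v
  }
  out
}
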