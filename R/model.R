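# Core model data structures: metabolites, reactions with signed stoichiometry,
# flux bounds, gene rules, and the stoichiometric matrix over intracellular
# metabolites.

#' Construct a reaction
#'
#' Stoichiometric coefficients are signed: negative for substrates, positive
#' for products. A metabolite appearing on both sides is collapsed to its net
#' coefficient at construction time, so that every reaction either produces or
#' consumes each of its participants; entries that net to zero are dropped.
#'
#' @param id reaction identifier (unique within a model).
#' @param stoich named numeric vector, metabolite id -> signed coefficient.
#' @param lb,ub lower/upper flux bounds (mmol/gDW/h by convention); `-Inf`/`Inf`
#'   allowed.
#' @param gene_rule boolean gene association string (see [parse_gene_rule()]),
#'   empty for non-gene-associated reactions.
#' @return a `reaction` object (list).
#' @export
reaction <- function(id, stoich, lb = 0, ub = Inf, gene_rule = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "': stoichiometry must be a named numeric vector",
         call. = FALSE)
  }
  # net-collapse duplicated metabolites, drop zero coefficients
  agg <- tapply(as.numeric(stoich), names(stoich), sum)
  stoich <- stats::setNames(as.numeric(agg), names(agg))
  stoich <- stoich[abs(stoich) > 0]
  if (length(stoich) == 0L) {
    stop("reaction '", id, "': empty (or fully cancelling) stoichiometry",
         call. = FALSE)
  }
  if (!is.numeric(lb) || !is.numeric(ub) || length(lb) != 1L || length(ub) != 1L ||
      is.na(lb) || is.na(ub) || lb > ub) {
    stop("reaction '", id, "': invalid bounds (need lb <= ub)", call. = FALSE)
  }
  structure(list(
    id = id,
    stoich = stoich[order(names(stoich))],
    lb = as.numeric(lb), ub = as.numeric(ub),
    gene_rule = as.character(gene_rule %||% ""),
    rule = parse_gene_rule(gene_rule)
  ), class = "reaction")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`,
#'   `compartment`, `boundary` (logical; boundary species are excluded from
#'   mass balance and from the turnover set).
#' @param reactions list of [reaction()] objects.
#' @param objective optional id of the objective (biomass/growth) reaction.
#' @param provenance free-text provenance note.
#' @return a validated `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            provenance = "") {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  metabolites <- metabolites[, c("id", "name", "compartment", "boundary")]
  rownames(metabolites) <- NULL
  model <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    objective = objective,
    provenance = provenance
  ), class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, that every metabolite referenced by a
#' reaction exists, that the model is non-empty, and (re)derives the exchange
#' flag for each reaction: a reaction is an exchange if it touches a boundary
#' metabolite or exactly one intracellular metabolite.
#'
#' @param model a `metabolic_model`.
#' @return the model, with exchange flags attached.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(model$reactions) == 0L) {
    stop("model validation: empty reaction list", call. = FALSE)
  }
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("model validation: duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "),
         call. = FALSE)
  }
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("model validation: duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  }
  names(model$reactions) <- rids
  boundary <- mets$id[mets$boundary]
  intra <- mets$id[!mets$boundary]
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), mets$id)
    if (length(unknown) > 0L) {
      stop("model validation: reaction '", r$id, "' references unknown ",
           "metabolite(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  model$reactions <- lapply(model$reactions, function(r) {
    n_intra <- sum(names(r$stoich) %in% intra)
    r$is_exchange <- any(names(r$stoich) %in% boundary) || n_intra == 1L
    r
  })
  if (!is.null(model$objective) && !(model$objective %in% rids)) {
    stop("model validation: objective reaction '", model$objective,
         "' not in model", call. = FALSE)
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", length(x$reactions), "reactions,",
      sum(!x$metabolites$boundary), "intracellular metabolites",
      sprintf("(+%d boundary)", sum(x$metabolites$boundary)), "\n")
  if (!is.null(x$objective)) cat("  objective:", x$objective, "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector in model order.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

#' Metabolite ids of a model
#' @param model a `metabolic_model`.
#' @param intracellular if `TRUE` (default) only non-boundary species.
#' @return character vector.
#' @export
metabolite_ids <- function(model, intracellular = TRUE) {
  m <- model$metabolites
  if (intracellular) m$id[!m$boundary] else m$id
}

#' Flux bounds of a model
#' @param model a `metabolic_model`.
#' @return two-column matrix (`lb`, `ub`) with reaction ids as rownames.
#' @export
reaction_bounds <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
        ub = vapply(model$reactions, `[[`, numeric(1), "ub"))
}

#' Stoichiometric matrix over intracellular metabolites
#'
#' Rows are intracellular metabolites, columns reactions (model order);
#' boundary species never enter mass balance.
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix |M| x |N| with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- metabolite_ids(model, intracellular = TRUE)
  rids <- reaction_ids(model)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    keep <- names(st) %in% mets
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  S
}

#' All genes appearing in a model's gene rules
#' @param model a `metabolic_model`.
#' @return character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$reactions, function(r) rule_genes(r$rule))))
}

# ---- flux / turnover state containers ---------------------------------------

#' Construct a flux state
#'
#' A reaction -> flux mapping plus its steady-state residual
#' `max |S v|` over intracellular metabolites.
#'
#' @param model a `metabolic_model`.
#' @param values named numeric vector covering all reactions of `model`.
#' @return a `flux_state` with elements `values` and `residual`.
#' @export
flux_state <- function(model, values) {
  rids <- reaction_ids(model)
  missing <- setdiff(rids, names(values))
  if (length(missing) > 0L) {
    stop("flux state missing reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- as.numeric(values[rids])
  names(v) <- rids
  S <- stoichiometric_matrix(model)
  res <- if (nrow(S) > 0L) max(abs(S %*% v)) else 0
  structure(list(values = v, residual = res), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state over", length(x$values), "reactions; steady-state residual",
      format(x$residual, digits = 3), "\n")
  invisible(x)
}

# Accept either a flux_state or a bare named numeric vector.
as_flux_values <- function(flux) {
  if (inherits(flux, "flux_state")) flux$values
  else if (is.numeric(flux) && !is.null(names(flux))) flux
  else stop("expected a flux_state or a named numeric vector", call. = FALSE)
}
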