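# Deterministic fixtures: the four-metabolite toy network used for the
# worked examples, a biomass-bearing mini model, and random feasible
# synthetic models for the invariance property suites.

#' Build the toy network
#'
#' Four intracellular metabolites A-D. R1 imports A, R7 exports D; A can be
#' converted to D directly via R5 or R6, or via the longer route
#' R2 (A->B), R3 (B->C), R4 (C->D). All coefficients are 1 and the uptake R1
#' is pinned to 1 (the reference rate), so every feasible flux distribution
#' routes exactly one unit from A to D. The wild-type reference carries that
#' unit through R5 only, giving turnovers A=1, B=0, C=0, D=1.
#'
#' @param with_genes attach single-gene rules `gR2`..`gR6` to the internal
#'   reactions (for interaction-screen examples).
#' @return list with `model`, `ref` (a [reference_distribution()]), and
#'   `deletions` (named list of reaction-deletion vectors: `R5`, `R5_R6`).
#' @export
build_toy_model <- function(with_genes = FALSE) {
  g <- function(x) if (with_genes) x else ""
  rxns <- list(
    reaction("R1", c("A[e]" = -1, "A" = 1), lb = 1, ub = 1),
    reaction("R2", c("A" = -1, "B" = 1), gene_rule = g("gR2")),
    reaction("R3", c("B" = -1, "C" = 1), gene_rule = g("gR3")),
    reaction("R4", c("C" = -1, "D" = 1), gene_rule = g("gR4")),
    reaction("R5", c("A" = -1, "D" = 1), gene_rule = g("gR5")),
    reaction("R6", c("A" = -1, "D" = 1), gene_rule = g("gR6")),
    reaction("R7", c("D" = -1, "D[e]" = 1))
  )
  mets <- data.frame(id = c("A", "B", "C", "D", "A[e]", "D[e]"),
                     boundary = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                     stringsAsFactors = FALSE)
  model <- metabolic_model(mets, rxns, objective = "R7", provenance = "toy")
  wt <- c(R1 = 1, R2 = 0, R3 = 0, R4 = 0, R5 = 1, R6 = 0, R7 = 1)
  list(model = model,
       ref = reference_distribution(model, wt),
       deletions = list(R5 = "R5", R5_R6 = c("R5", "R6")))
}

#' Build a mini model with a biomass reaction
#'
#' A linear chain with a biomass pseudo-reaction consuming two precursors and
#' producing a biomass pseudo-metabolite drained by an exchange. Used to
#' illustrate that maximizing the turnover of the single-reaction biomass
#' metabolite equals the FBA biomass optimum.
#'
#' @return list with `model` and `ref`.
#' @export
build_biomass_model <- function() {
  rxns <- list(
    reaction("UPT", c("S[e]" = -1, "S" = 1), lb = 0, ub = 10),
    reaction("V1", c("S" = -1, "P1" = 1)),
    reaction("V2", c("S" = -1, "P2" = 1)),
    reaction("BIOMASS", c("P1" = -1, "P2" = -1, "BIO" = 1)),
    reaction("EXBIO", c("BIO" = -1, "BIO[e]" = 1))
  )
  mets <- data.frame(
    id = c("S", "P1", "P2", "BIO", "S[e]", "BIO[e]"),
    boundary = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  model <- metabolic_model(mets, rxns, objective = "EXBIO",
                          provenance = "biomass-mini")
  wt <- c(UPT = 10, V1 = 5, V2 = 5, BIOMASS = 5, EXBIO = 5)
  list(model = model, ref = reference_distribution(model, wt))
}

#' Generate a random feasible model with a known reference flux
#'
#' Builds a connected conversion network over `n_met` intracellular
#' metabolites with one uptake and one sink exchange. `parallel_paths` random
#' routes from the source to the sink metabolite are superposed with
#' continuous random weights and recorded as the steady-state reference flux
#' (continuous weights keep rerouting costs generic, avoiding accidental
#' objective ties). Conversion reactions carry equal substrate/product
#' coefficients drawn from {1, 2}, exercising non-unit stoichiometry while
#' excluding flux-amplifying cycles, so FBA stays bounded; extra reactions
#' beyond the routes (a fraction reversible) carry zero reference flux. Each
#' internal reaction gets a gene `g_<id>`; with probability 0.2 an isoenzyme
#' partner gene is added through an `or` rule. The sink is the objective
#' reaction and the uptake is capped at the reference uptake.
#'
#' @param seed integer seed (the generator is deterministic given it).
#' @param n_met number of intracellular metabolites (>= 2).
#' @param n_rxn total number of reactions, exchanges included (>= n_met).
#' @param reversible_frac fraction of the extra (off-route) reactions made
#'   reversible.
#' @param parallel_paths number of superposed source-to-sink routes.
#' @return list with `model` and `ref` (a [reference_distribution()] with
#'   zero steady-state residual by construction).
#' @export
generate_random_model <- function(seed, n_met = 8, n_rxn = 14,
                                  reversible_frac = 0.2, parallel_paths = 3) {
  if (n_met < 2) stop("generate_random_model: n_met must be >= 2",
                      call. = FALSE)
  if (n_rxn < n_met) stop("generate_random_model: n_rxn must be >= n_met",
                          call. = FALSE)
  set.seed(seed)
  pick <- function(x, k = 1L) x[sample.int(length(x), k)]  # safe for length-1 x
  mets <- paste0("M", seq_len(n_met))
  hops <- list()        # key "i_j" -> coefficient
  hop_flux <- list()    # key -> accumulated reference flux
  uptake_total <- 0
  for (p in seq_len(parallel_paths)) {
    k <- pick(0:(n_met - 2L))
    via <- if (k > 0) sort(pick(seq(2L, n_met - 1L), k)) else integer(0)
    nodes <- c(1L, via, n_met)
    wt <- stats::runif(1, 0.5, 2)
    uptake_total <- uptake_total + wt
    for (h in seq_len(length(nodes) - 1L)) {
      key <- paste(nodes[h], nodes[h + 1L], sep = "_")
      if (is.null(hops[[key]])) {
        hops[[key]] <- pick(1:2)
        hop_flux[[key]] <- 0
      }
      # coefficient c on both sides: flux c*v converts c*q units, so a route
      # carrying q units of metabolite needs flux q / c
      hop_flux[[key]] <- hop_flux[[key]] + wt / hops[[key]]
    }
  }
  rxns <- list()
  ref <- numeric(0)
  add_rxn <- function(r, flux) {
    rxns[[length(rxns) + 1L]] <<- r
    ref[r$id] <<- flux
  }
  add_rxn(reaction("UPT", stats::setNames(c(-1, 1), c("SRC[e]", mets[1])),
                   lb = 0, ub = uptake_total),
          uptake_total)
  for (key in names(hops)) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    cc <- hops[[key]]
    st <- stats::setNames(c(-cc, cc), mets[ij])
    id <- paste0("R", key)
    add_rxn(reaction(id, st, lb = 0, ub = Inf,
                     gene_rule = paste0("g", id)), hop_flux[[key]])
  }
  # pad with extra (zero-reference) conversions up to n_rxn - 1 internal
  n_extra <- n_rxn - 2L - length(hops)
  tries <- 0L
  while (n_extra > 0 && tries < 50L * n_rxn) {
    tries <- tries + 1L
    i <- pick(seq_len(n_met - 1L))
    j <- pick(seq(i + 1L, n_met))
    key <- paste(i, j, sep = "_")
    id <- paste0("X", key)
    if (!is.null(hops[[key]]) || id %in% names(ref)) next
    cc <- pick(1:2)
    rev <- stats::runif(1) < reversible_frac
    add_rxn(reaction(id, stats::setNames(c(-cc, cc), mets[c(i, j)]),
                     lb = if (rev) -Inf else 0, ub = Inf,
                     gene_rule = paste0("g", id)), 0)
    n_extra <- n_extra - 1L
  }
  add_rxn(reaction("SINK", stats::setNames(c(-1, 1),
                                           c(mets[n_met], "SNK[e]")),
                   lb = 0, ub = Inf), uptake_total)
  # sprinkle isoenzyme partners (OR rules) on some internal reactions
  internal <- setdiff(seq_along(rxns),
                      c(1L, length(rxns)))
  for (i in internal) {
    if (stats::runif(1) < 0.2) {
      rid <- rxns[[i]]$id
      rxns[[i]]$gene_rule <- paste0("g", rid, " or g", rid, "b")
      rxns[[i]]$rule <- parse_gene_rule(rxns[[i]]$gene_rule)
    }
  }
  met_df <- data.frame(id = c(mets, "SRC[e]", "SNK[e]"),
                       boundary = c(rep(FALSE, n_met), TRUE, TRUE),
                       stringsAsFactors = FALSE)
  model <- metabolic_model(met_df, rxns, objective = "SINK",
                           provenance = paste0("synthetic:seed", seed))
  list(model = model, ref = reference_distribution(model, ref))
}
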