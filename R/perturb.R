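# Genetic and reaction perturbations.

#' Construct a deletion specification
#'
#' @param genes character vector of deleted gene ids (may be empty when
#'   explicit `reactions` are given).
#' @param mode `"gene_centered"`: a reaction is switched off iff its gene rule
#'   evaluates false with the deleted genes absent (standard GPR evaluation,
#'   so an isoenzyme reaction survives single deletions).
#'   `"reaction_centered_isoenzyme"`: a reaction is switched off as soon as
#'   any deleted gene appears in its rule, probing interactions of genes whose
#'   isoenzymes would otherwise silently compensate.
#' @param reactions optional explicit reaction ids to switch off regardless of
#'   gene rules.
#' @return a `deletion_spec`.
#' @export
deletion_spec <- function(genes = character(),
                          mode = c("gene_centered",
                                   "reaction_centered_isoenzyme"),
                          reactions = NULL) {
  mode <- match.arg(mode)
  genes <- unique(as.character(genes))
  if (length(genes) == 0L && length(reactions) == 0L) {
    stop("deletion_spec: need at least one gene or explicit reaction",
         call. = FALSE)
  }
  structure(list(genes = genes, mode = mode, reactions = reactions),
            class = "deletion_spec")
}

#' Apply a gene/reaction deletion to a model
#'
#' Switched-off reactions get bounds `[0, 0]`. Deleting a superset of genes
#' never re-enables a reaction, and the operation is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param spec a [deletion_spec()], or a character vector of gene ids
#'   (gene-centered deletion).
#' @param missing_genes what to do when a deleted gene appears in no gene
#'   rule: `"warn"` (default; experimental gene lists contain non-metabolic
#'   genes), `"error"`, or `"ignore"`.
#' @return the constrained model.
#' @export
knockout <- function(model, spec, missing_genes = c("warn", "error", "ignore")) {
  missing_genes <- match.arg(missing_genes)
  if (is.character(spec)) spec <- deletion_spec(genes = spec)
  stopifnot(inherits(spec, "deletion_spec"))
  if (length(spec$genes) > 0L && missing_genes != "ignore") {
    absent <- setdiff(spec$genes, model_genes(model))
    if (length(absent) > 0L) {
      msg <- paste0("gene(s) absent from every gene rule: ",
                    paste(absent, collapse = ", "))
      if (missing_genes == "error") stop(msg, call. = FALSE) else
        warning(msg, call. = FALSE)
    }
  }
  if (!is.null(spec$reactions)) {
    unknown <- setdiff(spec$reactions, reaction_ids(model))
    if (length(unknown) > 0L) {
      stop("knockout: unknown reaction id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    off <- r$id %in% (spec$reactions %||% character())
    if (!off && length(spec$genes) > 0L && !is.null(r$rule)) {
      off <- switch(spec$mode,
        gene_centered = !eval_gene_rule(r$rule, deleted = spec$genes),
        reaction_centered_isoenzyme =
          length(intersect(rule_genes(r$rule), spec$genes)) > 0L)
    }
    if (off) {
      model$reactions[[i]]$lb <- 0
      model$reactions[[i]]$ub <- 0
    }
  }
  model
}

#' Read a deletion list from TSV
#'
#' One mutant per line; multiple genes of one mutant separated by `;`.
#'
#' @param path file path (no header).
#' @return list of character vectors of gene ids.
#' @export
read_deletions_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) trimws(strsplit(ln, ";", fixed = TRUE)[[1]]))
}
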