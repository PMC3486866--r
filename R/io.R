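# Model and flux-distribution input/output.
#
# Two model formats are supported: a human-writable tabular (TSV) dialect and
# the COBRA-style SBML Level 2 dialect (species boundaryCondition, kineticLaw
# LOWER_BOUND/UPPER_BOUND parameters, GENE_ASSOCIATION note).
#
# TSV dialect: header line, then one reaction per line,
#   id <TAB> equation <TAB> lb <TAB> ub <TAB> gene_rule
# with equations like "1 A + 2 B -> 1 C"; a metabolite id suffixed "[e]" is a
# boundary (external) species. One side of the arrow may be empty.

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (is.infinite(v)) { if (v > 0) "Inf" else "-Inf" }
    else sprintf("%.17g", v)
  }, character(1))
}

#' Load a metabolic model from disk
#'
#' @param path file path.
#' @param format `"tsv"` or `"sbml"`; `"auto"` (default) decides from the file
#'   extension (`.xml`/`.sbml` are SBML, anything else TSV).
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "tsv"
  }
  switch(format, tsv = read_model_tsv(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param format `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  switch(format, tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
}

# ---- TSV dialect ------------------------------------------------------------

.parse_equation <- function(eq, rxn_id) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L) {
    stop("format error in reaction '", rxn_id, "': more than one '->'",
         call. = FALSE)
  }
  if (length(sides) == 1L) {
    sides <- c(sides, "")
    if (!grepl("->", eq, fixed = TRUE)) {
      stop("format error in reaction '", rxn_id, "': no '->' in equation",
           call. = FALSE)
    }
  }
  if (grepl("->$", trimws(eq))) sides <- c(sides[1], "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (term in terms) {
      toks <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1])); met <- toks[2]
        if (is.na(coef)) {
          stop("format error in reaction '", rxn_id, "': bad coefficient '",
               toks[1], "'", call. = FALSE)
        }
      } else {
        stop("format error in reaction '", rxn_id, "': bad term '", term, "'",
             call. = FALSE)
      }
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], +1))
}

.deparse_equation <- function(stoich) {
  side <- function(sel) {
    if (!any(sel)) return("")
    paste(sprintf("%s %s", .fmt_num(abs(stoich[sel])), names(stoich)[sel]),
          collapse = " + ")
  }
  paste(side(stoich < 0), "->", side(stoich > 0))
}

#' Read a model in the tabular dialect
#' @param path file path.
#' @return a validated [metabolic_model()].
#' @export
read_model_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) < 2L) stop("model file '", path, "': no reactions",
                               call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rxns <- list()
  all_mets <- character(0)
  objective <- NULL
  for (ln in lines[-1]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) stop("format error: short line in '", path, "': ", ln,
                             call. = FALSE)
    gene_rule <- if (length(f) >= 5L) f[5] else ""
    id <- trimws(f[1])
    if (grepl("\\*$", id)) {  # trailing '*' marks the objective reaction
      id <- sub("\\*$", "", id)
      objective <- id
    }
    st <- .parse_equation(f[2], id)
    lb <- suppressWarnings(as.numeric(f[3])); ub <- suppressWarnings(as.numeric(f[4]))
    if (is.na(lb) || is.na(ub)) {
      stop("format error in reaction '", id, "': bad bounds", call. = FALSE)
    }
    rxns[[length(rxns) + 1L]] <- reaction(id, st, lb, ub, gene_rule)
    all_mets <- union(all_mets, names(st))
  }
  mets <- data.frame(id = all_mets,
                     boundary = grepl("\\[e\\]$", all_mets),
                     stringsAsFactors = FALSE)
  metabolic_model(mets, rxns, objective = objective,
                  provenance = paste0("tsv:", basename(path)))
}

#' Write a model in the tabular dialect
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  lines <- c("id\tequation\tlb\tub\tgene_rule")
  for (r in model$reactions) {
    id <- r$id
    if (!is.null(model$objective) && identical(id, model$objective)) {
      id <- paste0(id, "*")
    }
    lines <- c(lines, paste(id, .deparse_equation(r$stoich), .fmt_num(r$lb),
                            .fmt_num(r$ub), r$gene_rule, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- SBML (COBRA Level-2 dialect) -------------------------------------------

#' Write a model as SBML
#'
#' Writes SBML Level 2 in the classic constraint-based dialect: species carry
#' `boundaryCondition`, each reaction a `kineticLaw` with `LOWER_BOUND` and
#' `UPPER_BOUND` parameters (infinities as +/-`INF`), and the gene rule in a
#' `GENE_ASSOCIATION` note.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2", level = "2", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             name = model$provenance %||% "model")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = cmp, size = "1")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = .sbml_escape_id(m$id), name = m$name,
      compartment = m$compartment,
      boundaryCondition = if (m$boundary) "true" else "false")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lr, "reaction", id = .sbml_escape_id(r$id),
      name = r$id, reversible = if (r$lb < 0) "true" else "false")
    if (nzchar(r$gene_rule)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", r$gene_rule))
    }
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(subs) > 0L) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(subs)) {
        xml2::xml_add_child(lre, "speciesReference", species = .sbml_escape_id(m),
                            stoichiometry = .fmt_num(abs(subs[m])))
      }
    }
    if (length(prods) > 0L) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prods)) {
        xml2::xml_add_child(lpr, "speciesReference", species = .sbml_escape_id(m),
                            stoichiometry = .fmt_num(prods[m]))
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    lp <- xml2::xml_add_child(kl, "listOfParameters")
    xml2::xml_add_child(lp, "parameter", id = "LOWER_BOUND",
                        value = .sbml_fmt_bound(r$lb))
    xml2::xml_add_child(lp, "parameter", id = "UPPER_BOUND",
                        value = .sbml_fmt_bound(r$ub))
    xml2::xml_add_child(lp, "parameter", id = "OBJECTIVE_COEFFICIENT",
      value = if (!is.null(model$objective) && identical(r$id, model$objective))
                "1" else "0")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_fmt_bound <- function(x) {
  if (is.infinite(x)) { if (x > 0) "INF" else "-INF" } else sprintf("%.17g", x)
}

.sbml_parse_bound <- function(s) {
  if (s %in% c("INF", "inf", "Inf")) return(Inf)
  if (s %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  as.numeric(s)
}

# SBML ids must match SId; bracketed compartment tags are encoded.
.sbml_escape_id <- function(id) {
  id <- gsub("\\[", "_LSQBKT_", id)
  gsub("\\]", "_RSQBKT_", id)
}

.sbml_unescape_id <- function(id) {
  id <- gsub("_LSQBKT_", "[", id, fixed = TRUE)
  gsub("_RSQBKT_", "]", id, fixed = TRUE)
}

#' Read a model from SBML
#'
#' Accepts the dialect written by [write_model_sbml()]: Level 2 with
#' `boundaryCondition` on species, flux bounds as `LOWER_BOUND`/`UPPER_BOUND`
#' kineticLaw parameters (defaulting to `[-Inf, Inf]` for reversible and
#' `[0, Inf]` for irreversible reactions when absent), and gene rules in
#' `GENE_ASSOCIATION` notes.
#'
#' @param path file path.
#' @return a validated [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  ns <- tryCatch(xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s"),
                 error = function(e) stop("SBML parse failure in '", path,
                                          "': no SBML namespace",
                                          call. = FALSE))
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("SBML parse failure: no species in '", path, "'",
                             call. = FALSE)
  mets <- data.frame(
    id = .sbml_unescape_id(xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    boundary = xml2::xml_attr(sp, "boundaryCondition") %in% "true",
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$compartment[is.na(mets$compartment)] <- "c"
  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) stop("SBML parse failure: no reactions in '",
                                   path, "'", call. = FALSE)
  objective <- NULL
  rxns <- lapply(rx_nodes, function(nd) {
    id <- .sbml_unescape_id(xml2::xml_attr(nd, "id"))
    reversible <- !(xml2::xml_attr(nd, "reversible") %in% "false")
    st <- numeric(0)
    for (ref in xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- .sbml_unescape_id(xml2::xml_attr(ref, "species"))
      co <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      if (is.na(co)) co <- 1
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) - co
    }
    for (ref in xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- .sbml_unescape_id(xml2::xml_attr(ref, "species"))
      co <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
      if (is.na(co)) co <- 1
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) + co
    }
    lb <- if (reversible) -Inf else 0
    ub <- Inf
    for (par in xml2::xml_find_all(nd, ".//s:parameter", ns)) {
      pid <- xml2::xml_attr(par, "id")
      val <- xml2::xml_attr(par, "value")
      if (identical(pid, "LOWER_BOUND")) lb <- .sbml_parse_bound(val)
      if (identical(pid, "UPPER_BOUND")) ub <- .sbml_parse_bound(val)
      if (identical(pid, "OBJECTIVE_COEFFICIENT") &&
          isTRUE(as.numeric(val) != 0)) objective <<- id
    }
    gene_rule <- ""
    for (p in xml2::xml_find_all(nd, "./s:notes//*", ns)) {
      txt <- xml2::xml_text(p)
      if (grepl("GENE_ASSOCIATION:", txt)) {
        gene_rule <- trimws(sub(".*GENE_ASSOCIATION:", "", txt))
      }
    }
    reaction(id, st, lb, ub, gene_rule)
  })
  metabolic_model(mets, rxns, objective = objective,
                  provenance = paste0("sbml:", basename(path)))
}

# ---- flux / turnover TSV ----------------------------------------------------

#' Read a flux distribution from a two-column TSV
#' @param path file with header and rows `reaction_id<TAB>flux`.
#' @return named numeric vector.
#' @export
read_flux_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write a flux distribution as a two-column TSV
#' @param flux a `flux_state` or named numeric vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(flux, path) {
  v <- as_flux_values(flux)
  writeLines(c("reaction_id\tflux",
               paste(names(v), .fmt_num(v), sep = "\t")), path)
  invisible(path)
}

#' Write a turnover state as a two-column TSV
#' @param turnover a `turnover_state` or named numeric vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_turnover_tsv <- function(turnover, path) {
  v <- if (inherits(turnover, "turnover_state")) turnover$values else turnover
  writeLines(c("metabolite_id\tturnover",
               paste(names(v), .fmt_num(v), sep = "\t")), path)
  invisible(path)
}
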