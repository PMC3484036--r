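# Model I/O. The JSON dialect mirrors the community constraint-based schema
# (objects `metabolites`, `reactions`, `genes`; reactions carry `metabolites`
# maps, `lower_bound`/`upper_bound`, `gene_reaction_rule`) so deposited
# genome-scale models load unchanged. SBML is read from Level 3 core with
# the fbc extension (flux bounds as parameters, geneProductAssociation).

#' Load a metabolic model from disk
#'
#' @param path Path to a model file.
#' @param format `"json"` (community constraint-based schema) or `"sbml"`
#'   (Level 3 with the fbc package). Guessed from the file extension by
#'   default.
#' @param biomass_reaction_id Optional explicit biomass reaction id;
#'   otherwise the reaction with objective coefficient 1 is used.
#' @return An [metabolic_model()] object.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass_reaction_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format,
         json = read_model_json(path, biomass_reaction_id),
         sbml = read_model_sbml(path, biomass_reaction_id))
}

read_model_json <- function(path, biomass_reaction_id = NULL) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse JSON model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  mets <- purrr::map_dfr(raw$metabolites, function(m) {
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      formula = m$formula %||% "",
      compartment = m$compartment %||% "c",
      mw = as.numeric(m$mw %||% NA_real_)
    )
  })
  rxns <- purrr::map_dfr(raw$reactions, function(r) {
    tibble::tibble(
      id = r$id,
      name = r$name %||% r$id,
      lower_bound = as.numeric(r$lower_bound %||% 0),
      upper_bound = as.numeric(r$upper_bound %||% 1000),
      gene_rule = r$gene_reaction_rule %||% "",
      subsystem = r$subsystem %||% "",
      objective_coefficient = as.numeric(r$objective_coefficient %||% 0)
    )
  })
  rxns$stoich <- purrr::map(raw$reactions, function(r) {
    st <- unlist(r$metabolites)
    stats::setNames(as.numeric(st), names(st))
  })
  genes <- vapply(raw$genes, function(g) if (is.list(g)) g$id else g, character(1))
  if (is.null(biomass_reaction_id)) {
    obj <- rxns$id[rxns$objective_coefficient != 0]
    biomass_reaction_id <- if (length(obj)) obj[[1]] else NA_character_
  }
  if (is.na(biomass_reaction_id) || !biomass_reaction_id %in% rxns$id) {
    stop("model '", raw$id %||% path, "' has no biomass reaction", call. = FALSE)
  }
  rxns$objective_coefficient <- NULL
  metabolic_model(mets, rxns, genes, biomass_reaction_id,
                  id = raw$id %||% basename(path))
}

#' Write a model to the JSON dialect
#'
#' Writing then re-loading preserves stoichiometry, bounds and gene rules
#' exactly (round-trip identity).
#'
#' @param model An `fs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- purrr::pmap(model$metabolites, function(id, name, formula, compartment,
                                                  mw, carbon, ...) {
    out <- list(id = id, name = name, formula = formula, compartment = compartment)
    if (!is.na(mw)) out$mw <- mw
    out
  })
  rxns <- purrr::pmap(model$reactions,
                      function(id, name, lower_bound, upper_bound, gene_rule,
                               subsystem, stoich, ...) {
    list(id = id, name = name, metabolites = as.list(stoich),
         lower_bound = lower_bound, upper_bound = upper_bound,
         gene_reaction_rule = gene_rule, subsystem = subsystem,
         objective_coefficient = if (id == model$biomass_reaction_id) 1 else 0)
  })
  out <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = purrr::map(model$genes, ~ list(id = .x)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_model_sbml <- function(path, biomass_reaction_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]] %||% "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  param_vals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                                xml2::xml_attr(params, "id"))
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"),
                           xml2::xml_attr(species, "id")),
    formula = dplyr::coalesce(xml2::xml_attr(species, "chemicalFormula",
                                             ns = character()), ""),
    compartment = dplyr::coalesce(xml2::xml_attr(species, "compartment"), "c"),
    mw = NA_real_
  )
  # fbc:chemicalFormula is namespaced; retry explicitly where empty
  ff <- vapply(species, function(sp) {
    f <- xml2::xml_attr(sp, "chemicalFormula")
    if (is.na(f)) f <- xml2::xml_attr(sp, "fbc:chemicalFormula")
    f %||% ""
  }, character(1))
  mets$formula <- ifelse(is.na(ff), "", ff)
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  parse_refs <- function(node, xpath, sign) {
    refs <- xml2::xml_find_all(node, xpath, ns)
    if (length(refs) == 0L) return(numeric(0))
    stats::setNames(sign * as.numeric(dplyr::coalesce(
      xml2::xml_attr(refs, "stoichiometry"), "1")),
      xml2::xml_attr(refs, "species"))
  }
  bound_of <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr)
    if (!is.na(ref) && ref %in% names(param_vals)) return(param_vals[[ref]])
    num <- suppressWarnings(as.numeric(ref))
    if (!is.na(num)) num else default
  }
  gpr_of <- function(node) {
    gpa <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    if (inherits(gpa, "xml_missing")) return("")
    render <- function(x) {
      nm <- xml2::xml_name(x)
      if (nm == "geneProductRef") return(xml2::xml_attr(x, "geneProduct"))
      kids <- xml2::xml_children(x)
      parts <- vapply(kids, render, character(1))
      op <- if (nm == "and") " and " else " or "
      paste0("(", paste(parts, collapse = op), ")")
    }
    kids <- xml2::xml_children(gpa)
    if (length(kids) == 0L) return("")
    render(kids[[1]])
  }
  rev_default <- function(node) {
    rv <- xml2::xml_attr(node, "reversible")
    isTRUE(rv == "true")
  }
  rxns <- purrr::map_dfr(rxn_nodes, function(node) {
    tibble::tibble(
      id = xml2::xml_attr(node, "id"),
      name = dplyr::coalesce(xml2::xml_attr(node, "name"),
                             xml2::xml_attr(node, "id")),
      lower_bound = bound_of(node, "lowerFluxBound",
                             if (rev_default(node)) -1000 else 0),
      upper_bound = bound_of(node, "upperFluxBound", 1000),
      gene_rule = gpr_of(node),
      subsystem = ""
    )
  })
  rxns$stoich <- purrr::map(rxn_nodes, function(node) {
    st <- c(parse_refs(node, ".//s:listOfReactants/s:speciesReference", -1),
            parse_refs(node, ".//s:listOfProducts/s:speciesReference", 1))
    tapply(st, names(st), sum)[unique(names(st))]
  })
  gene_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gene_nodes, "id")
  if (is.null(biomass_reaction_id)) {
    obj_ref <- xml2::xml_find_first(
      doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
    biomass_reaction_id <- if (!inherits(obj_ref, "xml_missing")) {
      xml2::xml_attr(obj_ref, "reaction")
    } else NA_character_
  }
  if (is.na(biomass_reaction_id) || !biomass_reaction_id %in% rxns$id) {
    stop("model '", xml2::xml_attr(model_node, "id") %||% path,
         "' has no biomass reaction", call. = FALSE)
  }
  metabolic_model(mets, rxns, genes, biomass_reaction_id,
                  id = xml2::xml_attr(model_node, "id") %||% basename(path))
}
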