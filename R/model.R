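#' Construct a constraint-based metabolic model
#'
#' A metabolic model bundles the stoichiometric matrix `A` (m metabolites by
#' n reactions, implied by per-reaction stoichiometries), flux bounds, GPR
#' rules, the biomass reaction and the exchange reactions. Steady state is
#' `A x = 0` with `lb_i <= x_i <= ub_i`; exchange reactions carry one
#' metabolite each and encode the medium through their lower bounds (uptake
#' is a negative exchange flux).
#'
#' @param metabolites A data frame with columns `id`, `name`, `formula`,
#'   `compartment` and optionally `mw` (g/mol). A `carbon` column is derived
#'   from `formula`.
#' @param reactions A data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`, and a list-column `stoich` of
#'   named numeric vectors (metabolite id to signed coefficient).
#' @param genes Character vector of gene ids.
#' @param biomass_reaction_id Id of the biomass reaction (objective of
#'   growth screens).
#' @param id Organism/model tag.
#' @return An object of class `fs_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes,
                            biomass_reaction_id, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"mw" %in% names(metabolites)) metabolites$mw <- NA_real_
  metabolites$carbon <- vapply(metabolites$formula, carbon_count, integer(1))
  exchange_ids <- reactions$id[grepl("^EX_", reactions$id)]
  model <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      genes = genes,
      biomass_reaction_id = biomass_reaction_id,
      exchange_reaction_ids = exchange_ids
    ),
    class = "fs_model"
  )
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: every stoichiometry key is a known
#' metabolite, bounds are ordered, stoichiometries are non-empty, the
#' biomass reaction exists, exchange reactions touch exactly one metabolite,
#' and GPR rules reference only known genes.
#'
#' @param model An `fs_model`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids", call. = FALSE)
  if (any(vapply(rxns$stoich, length, integer(1)) == 0L)) {
    stop("reactions with empty stoichiometry: ",
         paste(rxns$id[vapply(rxns$stoich, length, integer(1)) == 0L], collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(unlist(lapply(rxns$stoich, names)))
  unknown <- setdiff(keys, mets$id)
  if (length(unknown)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_bounds <- rxns$lower_bound > rxns$upper_bound
  if (any(bad_bounds)) {
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[bad_bounds], collapse = ", "), call. = FALSE)
  }
  if (is.null(model$biomass_reaction_id) || is.na(model$biomass_reaction_id) ||
      !model$biomass_reaction_id %in% rxns$id) {
    stop("model '", model$id, "' has no biomass reaction", call. = FALSE)
  }
  for (ex in model$exchange_reaction_ids) {
    st <- rxns$stoich[[match(ex, rxns$id)]]
    if (length(st) != 1L) {
      stop("exchange reaction ", ex, " must touch exactly one metabolite",
           call. = FALSE)
    }
  }
  rule_genes <- unique(unlist(lapply(rxns$gene_rule,
                                     function(r) gpr_genes(parse_gene_rule(r)))))
  missing_genes <- setdiff(rule_genes, model$genes)
  if (length(missing_genes)) {
    stop("gene rules reference unknown genes: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(mets$mw) & mets$mw < 0)) stop("negative molecular weight", call. = FALSE)
  invisible(model)
}

#' @export
print.fs_model <- function(x, ...) {
  cat("<fs_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", nrow(x$reactions),
      " (", length(x$exchange_reaction_ids), " exchanges)\n",
      "  genes:       ", length(x$genes), "\n",
      "  biomass:     ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Dense stoichiometric matrix of a model
#'
#' @param model An `fs_model`.
#' @return An m x n numeric matrix with metabolite ids as row names and
#'   reaction ids as column names.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  A <- matrix(0, m, n, dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(n)) {
    st <- model$reactions$stoich[[j]]
    A[names(st), j] <- unname(st)
  }
  A
}

#' Resolve gene labels against model gene ids
#'
#' Published deletion labels do not always match model ids exactly; labels
#' are resolved by exact match first, then by unique case-insensitive prefix
#' match with a warning.
#'
#' @param labels Character vector of gene labels.
#' @param model An `fs_model`.
#' @return Character vector of resolved model gene ids; unresolvable labels
#'   raise an error.
#' @export
resolve_genes <- function(labels, model) {
  vapply(labels, function(lab) {
    if (lab %in% model$genes) return(lab)
    hits <- model$genes[startsWith(tolower(model$genes), tolower(lab)) |
                          startsWith(tolower(lab), tolower(model$genes))]
    if (length(hits) == 1L) {
      warning("gene label '", lab, "' resolved to model id '", hits, "'",
              call. = FALSE)
      return(hits)
    }
    stop("cannot resolve gene label '", lab, "' (",
         length(hits), " candidate ids)", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Metabolite carbon counts as a named vector
#' @param model An `fs_model`.
#' @return Named integer vector of carbon atoms per metabolite.
#' @keywords internal
metabolite_carbon <- function(model) {
  stats::setNames(model$metabolites$carbon, model$metabolites$id)
}

# metabolite carried by an exchange reaction
exchange_metabolite <- function(model, exchange_id) {
  st <- model$reactions$stoich[[match(exchange_id, model$reactions$id)]]
  names(st)[1]
}
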