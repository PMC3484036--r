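# Flux balance analysis: max f'x subject to A x = 0 (steady state) and
# alpha_i <= x_i <= beta_i. The medium is imposed through exchange lower
# bounds (uptake is negative flux; closed nutrients have lower bound 0), a
# knockout sets both bounds of every disabled reaction to zero.

FS_BIG <- 1e6 # stand-in for infinite bounds; a solution at this cap is unbounded

#' Flux bounds for a design (medium plus deletions)
#'
#' The medium-controlled exchange uptakes (the catalog's exchange ids,
#' carried on the medium's `"controlled"` attribute; all exchanges when the
#' attribute is absent) are closed, then each medium nutrient opens its
#' exchange to `-max_uptake`. Non-controlled exchanges (secreted products,
#' freely exchanged CO2) keep their model bounds. Reactions whose GPR rule
#' evaluates inactive under the deletions are fixed to zero flux.
#'
#' @param model An `fs_model`.
#' @param medium Named list (category to catalog row) as produced by the
#'   design machinery, or `NULL` for the model's native bounds.
#' @param deletions Character vector of deleted gene ids (resolved via
#'   [resolve_genes()]).
#' @return A list with numeric vectors `lb` and `ub` over reactions.
#' @export
design_bounds <- function(model, medium = NULL, deletions = character(0)) {
  rxns <- model$reactions
  lb <- rxns$lower_bound
  ub <- rxns$upper_bound
  names(lb) <- names(ub) <- rxns$id
  if (!is.null(medium)) {
    if (length(medium)) {
      cats <- names(medium)
      if (anyDuplicated(cats)) stop("at most one nutrient per category", call. = FALSE)
    }
    ex <- intersect(attr(medium, "controlled") %||% model$exchange_reaction_ids,
                    model$exchange_reaction_ids)
    lb[ex] <- pmax(lb[ex], 0) # close controlled uptakes; secretion stays open
    for (nut in medium) {
      if (!nut$exchange_id %in% ex) {
        stop("medium nutrient is not an exchange reaction: ", nut$exchange_id,
             call. = FALSE)
      }
      lb[[nut$exchange_id]] <- -nut$max_uptake
    }
  }
  if (length(deletions)) {
    deletions <- resolve_genes(deletions, model)
    inactive <- !vapply(rxns$gene_rule, evaluate_gene_rule, logical(1),
                        deleted = deletions)
    lb[inactive] <- 0
    ub[inactive] <- 0
  }
  list(lb = unname(lb), ub = unname(ub))
}

#' Solve the FBA linear program for a design
#'
#' Maximizes (or minimizes) a linear flux objective subject to steady state
#' and the design's bounds. With `pfba = TRUE` (the default alternate-optima
#' policy) a second LP fixes the objective at its optimum and minimizes the
#' total absolute flux, yielding a reproducible flux vector; with
#' `pfba = FALSE` the raw simplex vertex is returned.
#'
#' @inheritParams design_bounds
#' @param objective A reaction id or a named numeric vector of flux
#'   coefficients (a linear combination).
#' @param sense `"max"` or `"min"`.
#' @param pfba Apply the total-flux-minimizing secondary LP.
#' @return An `fs_flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `fluxes` (named,
#'   all zero when not optimal).
#' @export
solve_fba <- function(model, medium = NULL, deletions = character(0),
                      objective = model$biomass_reaction_id,
                      sense = c("max", "min"), pfba = TRUE) {
  sense <- match.arg(sense)
  A <- stoichiometric_matrix(model)
  bounds <- design_bounds(model, medium, deletions)
  obj <- objective_vector(model, objective)
  solve_fba_matrix(A, bounds$lb, bounds$ub, obj, sense, pfba,
                   reaction_ids = model$reactions$id)
}

objective_vector <- function(model, objective) {
  n <- nrow(model$reactions)
  obj <- stats::setNames(rep(0, n), model$reactions$id)
  if (is.character(objective)) {
    missing <- setdiff(objective, model$reactions$id)
    if (length(missing)) stop("unknown objective reaction: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    obj[objective] <- 1
  } else {
    missing <- setdiff(names(objective), model$reactions$id)
    if (length(missing)) stop("unknown objective reaction: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    obj[names(objective)] <- objective
  }
  unname(obj)
}

solve_fba_matrix <- function(A, lb, ub, obj, sense = "max", pfba = TRUE,
                             reaction_ids = colnames(A)) {
  infinite <- !is.finite(lb) | !is.finite(ub)
  lb <- pmax(lb, -FS_BIG)
  ub <- pmin(ub, FS_BIG)
  m <- nrow(A)
  res <- lp_solve(obj, A, rep(0, m), lb, ub, maximize = (sense == "max"))
  zero_fluxes <- stats::setNames(rep(0, length(obj)), reaction_ids)
  if (res$status != "optimal") {
    return(new_flux_solution(res$status, 0, zero_fluxes))
  }
  if (any(infinite) && any(abs(res$x[infinite]) > FS_BIG - 1)) {
    return(new_flux_solution("unbounded", NA_real_, zero_fluxes))
  }
  x <- res$x
  if (pfba) {
    x <- pfba_minimize(A, lb, ub, obj, res$objective, x)
  }
  new_flux_solution("optimal", res$objective,
                    stats::setNames(x, reaction_ids))
}

# secondary LP: fix obj'x = opt, minimize sum |x_i| via x = xp - xn split
pfba_minimize <- function(A, lb, ub, obj, opt, fallback) {
  n <- ncol(A)
  Aeq <- cbind(A, -A)
  Aeq <- rbind(Aeq, c(obj, -obj))
  beq <- c(rep(0, nrow(A)), opt)
  # positive/negative parts keep the original box: x in [lb, ub] exactly
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- tryCatch(
    lp_solve(rep(1, 2 * n), Aeq, beq, lb2, ub2, maximize = FALSE),
    error = function(e) NULL)
  if (is.null(res) || res$status != "optimal") return(fallback)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

new_flux_solution <- function(status, objective_value, fluxes) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes),
            class = "fs_flux_solution")
}

#' @export
print.fs_flux_solution <- function(x, ...) {
  cat("<fs_flux_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 6), "\n")
  invisible(x)
}

#' Is a growth solution viable?
#'
#' A design is viable when its biomass-maximizing solve is optimal with a
#' growth rate above `epsilon` (default 1e-6 /hr).
#'
#' @param solution An `fs_flux_solution` from a biomass-maximizing solve.
#' @param epsilon Viability threshold in 1/hr.
#' @return Logical.
#' @export
is_viable <- function(solution, epsilon = 1e-6) {
  identical(solution$status, "optimal") && solution$objective_value > epsilon
}

#' Theoretical extremum of a linear engineering metric
#'
#' Optimizes a metric objective (a linear flux combination) over the same
#' constraint set as growth FBA, without requiring growth unless
#' `growth_fraction > 0`, in which case biomass is constrained to at least
#' that fraction of its maximum.
#'
#' @inheritParams solve_fba
#' @param growth_fraction Required fraction of maximal growth in `[0, 1]`.
#' @return An `fs_flux_solution`.
#' @export
theoretical_extreme <- function(model, medium = NULL, deletions = character(0),
                                objective, sense = c("max", "min"),
                                growth_fraction = 0) {
  sense <- match.arg(sense)
  if (growth_fraction > 0) {
    growth <- solve_fba(model, medium, deletions, pfba = FALSE)
    if (growth$status != "optimal") return(growth)
    A <- stoichiometric_matrix(model)
    bounds <- design_bounds(model, medium, deletions)
    i <- match(model$biomass_reaction_id, model$reactions$id)
    bounds$lb[i] <- max(bounds$lb[i], growth_fraction * growth$objective_value)
    return(solve_fba_matrix(A, bounds$lb, bounds$ub,
                            objective_vector(model, objective), sense,
                            pfba = FALSE, reaction_ids = model$reactions$id))
  }
  solve_fba(model, medium, deletions, objective = objective, sense = sense,
            pfba = FALSE)
}

#' Mass-balance residual of a flux solution
#'
#' Largest absolute steady-state violation `max |A x|` over internal
#' metabolites; at most ~1e-6 for any optimal solution.
#'
#' @param model An `fs_model`.
#' @param solution An `fs_flux_solution`.
#' @return A nonnegative number.
#' @export
mass_balance_residual <- function(model, solution) {
  A <- stoichiometric_matrix(model)
  max(abs(A %*% solution$fluxes[colnames(A)]))
}

#' Exchange fluxes of a solution split into uptake and secretion
#'
#' @param model An `fs_model`.
#' @param solution An `fs_flux_solution`.
#' @param tol Fluxes within `tol` of zero are treated as zero.
#' @return A tibble with `exchange_id`, `metabolite`, `flux`, `uptake`
#'   (positive consumption rate) and `secretion` (positive production rate).
#' @export
exchange_fluxes <- function(model, solution, tol = 1e-7) {
  ex <- model$exchange_reaction_ids
  flux <- solution$fluxes[ex]
  flux[abs(flux) < tol] <- 0
  tibble::tibble(
    exchange_id = ex,
    metabolite = vapply(ex, exchange_metabolite, character(1), model = model),
    flux = unname(flux),
    uptake = pmax(-unname(flux), 0),
    secretion = pmax(unname(flux), 0)
  )
}
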