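# Expression-to-flux consistency (GIMME-style). Reactions whose mapped
# expression falls below the cutoff are penalized in proportion to the
# shortfall; the penalized LP finds the minimal-inconsistency flux state
# that still delivers a required fraction of maximal growth. The raw
# inconsistency sum I is normalized to a bounded consistency score
# s = 1 - I / I_ref, where I_ref penalizes every reaction at the full
# cutoff weight (the worst-informed state delivering the same growth).

#' GIMME expression-consistency score of a design
#'
#' Maps the expression profile onto reactions through their GPR rules
#' (AND = min over complex members, OR = max over isozymes), builds
#' penalties `c_i = max(0, cutoff - expression_i)` for below-cutoff
#' reactions, and solves: minimize `sum c_i |x_i|` subject to steady state,
#' the design's bounds, and biomass at least `functionality_fraction` of
#' its maximum. The score is `1 - I / I_ref`, clipped to `[0, 1]`.
#'
#' @inheritParams solve_fba
#' @param profile An `fs_expression_profile` (named expression vector plus
#'   cutoff).
#' @param functionality_fraction Required fraction of maximal growth in
#'   `(0, 1]`.
#' @return A score in `[0, 1]`; `NA` when the functionality requirement is
#'   infeasible; 1 (with a message) for an empty profile.
#' @export
gimme_score <- function(model, medium = NULL, deletions = character(0),
                        profile, functionality_fraction = 0.9) {
  stopifnot(functionality_fraction > 0, functionality_fraction <= 1)
  if (length(profile$expression) == 0L) {
    message("empty expression profile: consistency is trivially 1")
    return(1)
  }
  unknown <- setdiff(names(profile$expression), model$genes)
  if (length(unknown)) {
    warning("expression for genes absent from the model ignored: ",
            paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  growth <- solve_fba(model, medium, deletions, pfba = FALSE)
  if (!is_viable(growth)) return(NA_real_)
  A <- stoichiometric_matrix(model)
  bounds <- design_bounds(model, medium, deletions)
  i_bio <- match(model$biomass_reaction_id, model$reactions$id)
  bounds$lb[i_bio] <- max(bounds$lb[i_bio],
                          functionality_fraction * growth$objective_value)
  expr <- vapply(model$reactions$gene_rule, reaction_expression, numeric(1),
                 expression = profile$expression)
  penalties <- pmax(0, profile$cutoff - expr)
  penalties[is.na(penalties)] <- 0 # non-genetic or unmeasured reactions
  inconsistency <- penalized_flux_min(A, bounds$lb, bounds$ub, penalties)
  if (is.na(inconsistency)) return(NA_real_)
  ref_penalties <- rep(profile$cutoff, ncol(A))
  i_ref <- penalized_flux_min(A, bounds$lb, bounds$ub, ref_penalties)
  if (is.na(i_ref) || i_ref <= 1e-12) return(1)
  min(1, max(0, 1 - inconsistency / i_ref))
}

# minimize sum w_i |x_i| over {A x = 0, lb <= x <= ub} via x = xp - xn
penalized_flux_min <- function(A, lb, ub, weights) {
  n <- ncol(A)
  lb <- pmax(lb, -FS_BIG)
  ub <- pmin(ub, FS_BIG)
  Aeq <- cbind(A, -A)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  res <- tryCatch(
    lp_solve(c(weights, weights), Aeq, rep(0, nrow(A)), lb2, ub2,
             maximize = FALSE),
    error = function(e) NULL)
  if (is.null(res) || res$status != "optimal") return(NA_real_)
  res$objective
}
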