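# Design-space enumeration and screening. A design is one nutrient per
# category (electron acceptor optional for anaerobic growth) plus 0-2 gene
# deletions; the space is the Cartesian product of category catalogs with
# all genotypes up to double deletions.

#' Closed-form design count
#'
#' `prod(per-category source counts) * (1 + n + choose(n, 2))` for up to two
#' deletions; the wild type counts as one genotype and "no electron
#' acceptor" as one more EA option when enabled.
#'
#' @param catalog_sizes Named counts per category (`carbon`,
#'   `electron_acceptor`, `nitrogen`, `phosphorus`, `sulfur`); absent
#'   categories count 1 (no choice).
#' @param ea_includes_none Count the anaerobic (no acceptor) option.
#' @param n_genes Number of deletable genes.
#' @param max_deletions 0, 1 or 2.
#' @return An integer-valued count (as double to avoid overflow at genome
#'   scale).
#' @examples
#' count_designs(c(carbon = 3, electron_acceptor = 2, nitrogen = 2,
#'                 phosphorus = 1, sulfur = 1),
#'               ea_includes_none = FALSE, n_genes = 4, max_deletions = 2)
#' @export
count_designs <- function(catalog_sizes, ea_includes_none = FALSE,
                          n_genes = 0, max_deletions = 2) {
  stopifnot(all(catalog_sizes >= 0), max_deletions %in% 0:2)
  sizes <- catalog_sizes
  if (ea_includes_none) {
    sizes[["electron_acceptor"]] <- (sizes[["electron_acceptor"]] %||% 0) + 1
  }
  media <- prod(sizes[sizes > 0])
  genotypes <- 1 +
    (if (max_deletions >= 1) n_genes else 0) +
    (if (max_deletions >= 2) choose(n_genes, 2) else 0)
  media * genotypes
}

#' Enumerate the full design space
#'
#' Deterministic, ordered enumeration: media vary category-lexicographically
#' (carbon, electron acceptor, nitrogen, phosphorus, sulfur, in catalog row
#' order), then genotypes (wild type, single deletions by gene index,
#' unordered pairs `i < j`). Each deletion pair appears exactly once.
#'
#' @param catalog A nutrient catalog (see [validate_catalog()]).
#' @param genes Character vector of deletable genes.
#' @param max_deletions 0, 1 or 2.
#' @param ea_includes_none Include the anaerobic option (no electron
#'   acceptor, `NA` in the `electron_acceptor` column).
#' @return A tibble with one row per design: `design_id`, one column per
#'   category, `gene1`, `gene2` (`NA` when unused).
#' @export
enumerate_designs <- function(catalog, genes = character(0), max_deletions = 2,
                              ea_includes_none = FALSE) {
  catalog <- validate_catalog(catalog)
  opts <- lapply(stats::setNames(NUTRIENT_CATEGORIES, NUTRIENT_CATEGORIES),
                 function(cat) catalog$exchange_id[catalog$category == cat])
  if (ea_includes_none) {
    opts$electron_acceptor <- c(opts$electron_acceptor, NA_character_)
  }
  opts <- opts[vapply(opts, length, integer(1)) > 0]
  genotypes <- genotype_table(genes, max_deletions)
  media <- rev(expand.grid(rev(opts), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE))
  designs <- tidyr::crossing(media_idx = seq_len(nrow(media)),
                             geno_idx = seq_len(nrow(genotypes)))
  out <- dplyr::bind_cols(
    media[designs$media_idx, , drop = FALSE],
    genotypes[designs$geno_idx, , drop = FALSE]
  )
  out <- tibble::as_tibble(out)
  for (cat in setdiff(NUTRIENT_CATEGORIES, names(out))) out[[cat]] <- NA_character_
  out <- out[, c(NUTRIENT_CATEGORIES, "gene1", "gene2")]
  out$design_id <- design_key(out)
  dplyr::relocate(out, "design_id")
}

genotype_table <- function(genes, max_deletions) {
  rows <- list(tibble::tibble(gene1 = NA_character_, gene2 = NA_character_))
  if (max_deletions >= 1 && length(genes)) {
    rows <- c(rows, list(tibble::tibble(gene1 = genes, gene2 = NA_character_)))
  }
  if (max_deletions >= 2 && length(genes) >= 2) {
    pairs <- utils::combn(genes, 2)
    rows <- c(rows, list(tibble::tibble(gene1 = pairs[1, ], gene2 = pairs[2, ])))
  }
  dplyr::bind_rows(rows)
}

design_key <- function(designs) {
  cols <- c(NUTRIENT_CATEGORIES, "gene1", "gene2")
  apply(designs[, cols], 1, function(r) {
    paste(ifelse(is.na(r), ".", r), collapse = "|")
  })
}

design_deletions <- function(row) {
  dels <- c(row$gene1, row$gene2)
  dels[!is.na(dels)]
}

#' Screen designs: FBA-solve each, keep viable ones with their trait vectors
#'
#' For every design the growth-maximizing FBA problem is solved under the
#' design's medium and deletions; nonviable designs (growth below `epsilon`)
#' are pruned, and each viable design receives its full engineering trait
#' vector. LP failures on individual designs are logged and counted, never
#' abort the stream.
#'
#' @param designs A design tibble from [enumerate_designs()].
#' @param model An `fs_model`.
#' @param catalog Nutrient catalog.
#' @param prices Product price table (`compound_id`, `unit_price`, `mw`).
#' @param epsilon Viability threshold (1/hr).
#' @param pfba Use the total-flux-minimizing alternate-optima policy.
#' @param expression_profile Optional `fs_expression_profile` for the
#'   microarray-consistency trait.
#' @param registry Metric registry (see [metric_registry()]).
#' @param keep_fluxes Retain each solution's flux vector as a list-column.
#' @return A tibble with one row per viable design: the design key columns,
#'   the trait columns, and `economics_available`. Screening totals are
#'   attached as the `"screen_summary"` attribute (total, viable,
#'   viable_fraction, lp_failures).
#' @export
screen_designs <- function(designs, model, catalog, prices = NULL,
                           epsilon = 1e-6, pfba = TRUE,
                           expression_profile = NULL,
                           registry = metric_registry(model),
                           keep_fluxes = FALSE) {
  catalog <- validate_catalog(catalog)
  A <- stoichiometric_matrix(model)
  n_total <- nrow(designs)
  lp_failures <- 0L
  rows <- vector("list", n_total)
  fluxes <- if (keep_fluxes) vector("list", n_total) else NULL
  for (i in seq_len(n_total)) {
    row <- designs[i, ]
    sol <- tryCatch({
      medium <- medium_from_design(row, catalog)
      bounds <- design_bounds(model, medium, design_deletions(row))
      solve_fba_matrix(A, bounds$lb, bounds$ub,
                       objective_vector(model, model$biomass_reaction_id),
                       sense = "max", pfba = pfba,
                       reaction_ids = model$reactions$id)
    }, error = function(e) {
      lp_failures <<- lp_failures + 1L
      message("design ", row$design_id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(sol) || !is_viable(sol, epsilon)) next
    metrics <- compute_metrics(row, sol, model, catalog, prices,
                               registry = registry,
                               expression_profile = expression_profile)
    rows[[i]] <- dplyr::bind_cols(row, metrics)
    if (keep_fluxes) fluxes[[i]] <- sol$fluxes
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- dplyr::bind_rows(rows[keep])
  if (keep_fluxes && nrow(out)) out$fluxes <- fluxes[keep]
  attr(out, "screen_summary") <- list(
    total = n_total,
    viable = sum(keep),
    viable_fraction = if (n_total) sum(keep) / n_total else NA_real_,
    lp_failures = lp_failures
  )
  out
}
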