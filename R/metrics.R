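# Engineering trait vector: 36 metrics per viable design. Six target
# products (acetate, D-lactate, hydrogen, ethanol, formate, succinate) each
# contribute a production rate (mmol/gDW/hr), a purity (titer ratio), a
# carbon yield and a revenue rate ($/hr/gDW); twelve global traits cover
# growth, carbon bookkeeping, economics and expression consistency.

TARGET_PRODUCTS <- c("acetate", "d_lactate", "hydrogen", "ethanol",
                     "formate", "succinate")

#' The metric registry
#'
#' Declares the trait names and the product-to-metabolite mapping used by
#' [compute_metrics()]. The default registry yields the full 36-trait
#' vector: 6 products x 4 per-product traits + 12 global traits.
#'
#' @param model An `fs_model`; products are matched to model metabolites by
#'   conventional ids (`ac`, `lac_D`/`lac`, `h2`, `etoh`, `for`/`form`,
#'   `succ`) unless `products` overrides the mapping.
#' @param products Optional tibble (`product`, `metabolite`) overriding the
#'   mapping; products without a model metabolite report `NA` traits.
#' @return A list with `products` (mapping tibble) and `names` (the trait
#'   vector names, in registry order).
#' @export
metric_registry <- function(model, products = NULL) {
  if (is.null(products)) {
    aliases <- list(acetate = c("ac", "ac_e", "acetate"),
                    d_lactate = c("lac", "lac_D", "lac_D_e", "d_lactate"),
                    hydrogen = c("h2", "h2_e", "hydrogen"),
                    ethanol = c("etoh", "etoh_e", "ethanol"),
                    formate = c("form", "for", "for_e", "formate"),
                    succinate = c("succ", "succ_e", "succinate"))
    products <- tibble::tibble(
      product = TARGET_PRODUCTS,
      metabolite = vapply(TARGET_PRODUCTS, function(p) {
        hit <- intersect(aliases[[p]], model$metabolites$id)
        if (length(hit)) hit[[1]] else NA_character_
      }, character(1))
    )
  }
  per_product <- c("production_rate", "purity", "carbon_yield", "revenue_rate")
  nm <- c(
    as.vector(t(outer(products$product, per_product, paste, sep = "_"))),
    "biomass_production_rate", "biomass_carbon_yield",
    "total_carbon_yield", "total_carbon_change",
    "total_economic_cost_rate", "total_intake_price",
    "price_change_all", "price_change_targets",
    "profit_rate", "microarray_consistency",
    "total_secretion_rate", "n_secreted_products"
  )
  list(products = products, names = nm)
}

#' Titer-ratio purity of a target product
#'
#' The ratio of the target's secretion to total secretion over the
#' byproduct set (water, protons, biomass and by default CO2 are not
#' byproducts). Zero total secretion yields purity 0 with the
#' `"zero_secretion"` attribute set.
#'
#' @param target Exchange reaction id of the target product.
#' @param solution An `fs_flux_solution`.
#' @param model An `fs_model`.
#' @param byproduct_set Exchange ids forming the purity denominator; must
#'   contain `target`.
#' @return Purity in `[0, 1]`.
#' @export
purity <- function(target, solution, model,
                   byproduct_set = default_byproduct_set(model)) {
  if (!target %in% byproduct_set) {
    stop("target ", target, " is not in the byproduct set", call. = FALSE)
  }
  secretion <- pmax(solution$fluxes[byproduct_set], 0)
  total <- sum(secretion)
  if (total <= 1e-9) {
    return(structure(0, zero_secretion = TRUE))
  }
  unname(secretion[[target]] / total)
}

#' Default byproduct set of a model
#'
#' All exchange reactions except water, protons, biomass, the medium
#' nutrient exchanges are irrelevant (they never secrete), and CO2 is
#' excluded by default (the named fermentation products and other organics
#' are the byproducts of interest).
#'
#' @param model An `fs_model`.
#' @param exclude_co2 Drop CO2 from the set.
#' @return Character vector of exchange ids.
#' @export
default_byproduct_set <- function(model, exclude_co2 = TRUE) {
  drop_mets <- c("h2o", "h2o_e", "h", "h_e", "biomass", "biomass_e")
  if (exclude_co2) drop_mets <- c(drop_mets, "co2", "co2_e")
  ex <- model$exchange_reaction_ids
  mets <- vapply(ex, exchange_metabolite, character(1), model = model)
  ex[!mets %in% drop_mets]
}

#' Carbon yield of a target product
#'
#' Fraction of consumed carbon atoms channeled into the target:
#' `secretion * C(target) / sum(uptake_i * C(nutrient_i))`.
#'
#' @inheritParams purity
#' @return Yield in `[0, 1]`, or `NA` when no carbon is consumed.
#' @export
carbon_yield <- function(target, solution, model) {
  exf <- exchange_fluxes(model, solution)
  carbon <- metabolite_carbon(model)[exf$metabolite]
  c_in <- sum(exf$uptake * carbon)
  if (c_in <= 1e-9) return(NA_real_)
  i <- match(target, exf$exchange_id)
  unname(exf$secretion[i] * carbon[i] / c_in)
}

#' Nutrient cost rate
#'
#' The economic cost of one consumed nutrient:
#' `unit_price ($/g) x mw (g/mol) x uptake (mmol/gDW/hr) / 1000 (mmol/mol)`,
#' in $/hr/gDW.
#'
#' @param unit_price Price in $/g (`NA` when unknown).
#' @param mw Molecular weight in g/mol.
#' @param uptake Uptake flux in mmol/gDW/hr (nonnegative).
#' @return Cost rate in $/hr/gDW; `NA` when the price is missing and uptake
#'   is positive (a missing price is unavailable, not zero).
#' @examples
#' nutrient_cost_rate(0.05, 180, 10) # 0.09
#' @export
nutrient_cost_rate <- function(unit_price, mw, uptake) {
  stopifnot(all(uptake >= 0), all(is.na(mw) | mw >= 0))
  out <- unit_price * mw * uptake / 1000
  out[uptake == 0] <- 0
  out
}

#' Compute the full engineering trait vector for a viable design
#'
#' Fills every registry metric from the flux solution, the catalog and the
#' price tables. Economic traits are flagged unavailable
#' (`economics_available = FALSE`, values `NA`) whenever any consumed
#' nutrient lacks a unit price; revenue and profit use the product price
#' table.
#'
#' @param design One design row (or a list with the category columns).
#' @param solution An optimal `fs_flux_solution` from a growth-maximizing
#'   solve.
#' @param model An `fs_model`.
#' @param catalog Nutrient catalog (prices for consumed nutrients).
#' @param prices Product price table (`compound_id`, `unit_price`, `mw`).
#' @param registry From [metric_registry()].
#' @param expression_profile Optional `fs_expression_profile`; when present
#'   the microarray-consistency trait is the GIMME score of the design.
#' @return A one-row tibble with the registry's trait columns plus
#'   `economics_available`.
#' @export
compute_metrics <- function(design, solution, model, catalog, prices = NULL,
                            registry = metric_registry(model),
                            expression_profile = NULL) {
  exf <- exchange_fluxes(model, solution)
  carbon <- metabolite_carbon(model)[exf$metabolite]
  byset <- default_byproduct_set(model)
  in_byset <- exf$exchange_id %in% byset
  c_in <- sum(exf$uptake * carbon)
  c_out <- sum(exf$secretion * carbon)

  # price lookup over both catalog (nutrients, by exchange id) and product
  # table (by metabolite id)
  price_of <- function(met, exch) {
    i <- match(exch, catalog$exchange_id)
    if (!is.na(i)) {
      return(list(price = catalog$unit_price[i], mw = catalog$mw[i]))
    }
    if (!is.null(prices)) {
      j <- match(met, prices$compound_id)
      if (!is.na(j)) return(list(price = prices$unit_price[j], mw = prices$mw[j]))
    }
    list(price = NA_real_, mw = NA_real_)
  }
  pinfo <- purrr::map2(exf$metabolite, exf$exchange_id, price_of)
  p_price <- vapply(pinfo, `[[`, numeric(1), "price")
  p_mw <- vapply(pinfo, `[[`, numeric(1), "mw")

  consumed <- exf$uptake > 0
  secreted <- exf$secretion > 0
  # the missing-price rule applies to medium nutrients (catalog entries);
  # non-catalog exchanges (e.g. freely exchanged CO2) consumed without a
  # price are environmental, not purchased
  in_catalog <- exf$exchange_id %in% catalog$exchange_id
  economics_available <- !any(consumed & in_catalog & is.na(p_price))
  cost_terms <- nutrient_cost_rate(ifelse(consumed & !is.na(p_price), p_price, 0),
                                   ifelse(is.na(p_mw), 0, p_mw), exf$uptake)
  total_cost <- if (economics_available) sum(cost_terms) else NA_real_
  value_out_all <- sum(p_price * p_mw * exf$secretion / 1000, na.rm = TRUE)

  biomass_flux <- solution$fluxes[[model$biomass_reaction_id]]
  # carbon drawn into biomass synthesis per unit growth
  bio_st <- model$reactions$stoich[[match(model$biomass_reaction_id,
                                          model$reactions$id)]]
  bio_c <- -sum(pmin(bio_st, 0) *
                  metabolite_carbon(model)[names(bio_st)])
  biomass_carbon_yield <- if (c_in > 1e-9) biomass_flux * bio_c / c_in else NA_real_

  vals <- list()
  revenue_total <- 0
  for (p in seq_len(nrow(registry$products))) {
    prod <- registry$products$product[p]
    met <- registry$products$metabolite[p]
    ex_id <- if (!is.na(met)) {
      hit <- exf$exchange_id[exf$metabolite == met]
      if (length(hit)) hit[[1]] else NA_character_
    } else NA_character_
    if (is.na(ex_id)) {
      vals[paste0(prod, c("_production_rate", "_purity", "_carbon_yield",
                          "_revenue_rate"))] <- NA_real_
      next
    }
    i <- match(ex_id, exf$exchange_id)
    rate <- exf$secretion[i]
    vals[[paste0(prod, "_production_rate")]] <- rate
    vals[[paste0(prod, "_purity")]] <- as.numeric(purity(ex_id, solution, model, byset))
    vals[[paste0(prod, "_carbon_yield")]] <- carbon_yield(ex_id, solution, model)
    rev <- if (!is.na(p_price[i])) p_price[i] * p_mw[i] * rate / 1000 else NA_real_
    vals[[paste0(prod, "_revenue_rate")]] <- rev
    if (!is.na(rev)) revenue_total <- revenue_total + rev
  }

  value_targets_out <- revenue_total
  vals$biomass_production_rate <- biomass_flux
  vals$biomass_carbon_yield <- biomass_carbon_yield
  vals$total_carbon_yield <- if (c_in > 1e-9) {
    sum(exf$secretion[in_byset] * carbon[in_byset]) / c_in
  } else NA_real_
  vals$total_carbon_change <- c_out - c_in
  vals$total_economic_cost_rate <- total_cost
  vals$total_intake_price <- if (economics_available) {
    sum(p_price[consumed] * p_mw[consumed] / 1000, na.rm = TRUE)
  } else NA_real_
  vals$price_change_all <- if (economics_available) {
    value_out_all - total_cost
  } else NA_real_
  vals$price_change_targets <- if (economics_available) {
    value_targets_out - total_cost
  } else NA_real_
  vals$profit_rate <- if (economics_available) {
    revenue_total - total_cost
  } else NA_real_
  vals$microarray_consistency <- if (!is.null(expression_profile)) {
    gimme_score(model,
                medium = medium_from_design(design, catalog),
                deletions = design_deletions(design),
                profile = expression_profile)
  } else NA_real_
  vals$total_secretion_rate <- sum(exf$secretion[in_byset])
  vals$n_secreted_products <- sum(secreted & in_byset)

  out <- tibble::as_tibble(lapply(vals[registry$names], unname))
  out$economics_available <- economics_available
  out
}
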