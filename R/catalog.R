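# Nutrient catalogs and price tables. A catalog row is one candidate
# nutrient: the exchange reaction that imports it, its category (carbon,
# electron acceptor, nitrogen, phosphorus or sulfur source), the maximal
# uptake rate imposed when it is in the medium, and pricing data.

NUTRIENT_CATEGORIES <- c("carbon", "electron_acceptor", "nitrogen",
                         "phosphorus", "sulfur")

#' Read a nutrient catalog
#'
#' @param path TSV file with header columns `exchange_id`, `category`,
#'   `max_uptake` (mmol/gDW/hr), `unit_price` ($/g, may be empty) and `mw`
#'   (g/mol).
#' @return A tibble, validated by [validate_catalog()].
#' @export
read_nutrient_catalog <- function(path) {
  cat_tbl <- readr::read_tsv(path, col_types = readr::cols(
    exchange_id = readr::col_character(),
    category = readr::col_character(),
    max_uptake = readr::col_double(),
    unit_price = readr::col_double(),
    mw = readr::col_double()
  ))
  validate_catalog(cat_tbl)
}

#' Validate a nutrient catalog
#'
#' @param catalog A data frame of nutrient specifications.
#' @return The catalog as a tibble; errors on duplicate exchange ids,
#'   unknown categories or non-positive uptake rates.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  needed <- c("exchange_id", "category", "max_uptake")
  missing <- setdiff(needed, names(catalog))
  if (length(missing)) {
    stop("catalog lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(catalog$exchange_id)) {
    stop("duplicate exchange ids in catalog: ",
         paste(unique(catalog$exchange_id[duplicated(catalog$exchange_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !catalog$category %in% NUTRIENT_CATEGORIES
  if (any(bad)) {
    stop("unknown nutrient categories: ",
         paste(unique(catalog$category[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(catalog$max_uptake <= 0)) {
    stop("max_uptake must be positive", call. = FALSE)
  }
  if (!"unit_price" %in% names(catalog)) catalog$unit_price <- NA_real_
  if (!"mw" %in% names(catalog)) catalog$mw <- NA_real_
  if (any(!is.na(catalog$unit_price) & catalog$unit_price < 0)) {
    stop("unit prices must be nonnegative", call. = FALSE)
  }
  catalog
}

#' Write a nutrient catalog as TSV
#' @param catalog A catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nutrient_catalog <- function(catalog, path) {
  readr::write_tsv(validate_catalog(catalog), path)
  invisible(path)
}

#' Default nutrient categorization by elemental content
#'
#' Assigns categories progressively and exclusively in the order carbon,
#' electron acceptor, nitrogen, phosphorus, sulfur: a compound containing
#' carbon is a carbon source regardless of other elements, a carbon-free
#' compound in `acceptors` is an electron acceptor, then nitrogen,
#' phosphorus and sulfur are assigned by element. This is only a default:
#' the catalog file is authoritative and may override it (e.g. a
#' carbon-containing amine used as the nitrogen source).
#'
#' @param model An `fs_model`.
#' @param exchange_ids Exchange reactions to categorize.
#' @param acceptors Metabolite ids treated as electron acceptors.
#' @return A character vector of categories (`NA` when no rule applies).
#' @export
categorize_nutrients <- function(model, exchange_ids,
                                 acceptors = c("o2", "o2_e", "no3", "no3_e",
                                               "fum", "fum_e")) {
  carbon <- metabolite_carbon(model)
  vapply(exchange_ids, function(ex) {
    met <- exchange_metabolite(model, ex)
    counts <- parse_formula(model$metabolites$formula[[match(met, model$metabolites$id)]])
    if (carbon[[met]] > 0) return("carbon")
    if (met %in% acceptors) return("electron_acceptor")
    if ("N" %in% names(counts)) return("nitrogen")
    if ("P" %in% names(counts)) return("phosphorus")
    if ("S" %in% names(counts)) return("sulfur")
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Read a price table
#'
#' @param path TSV with columns `compound_id`, `unit_price` ($/g), `mw`
#'   (g/mol).
#' @return A tibble with nonnegative prices.
#' @export
read_price_table <- function(path) {
  prices <- readr::read_tsv(path, col_types = readr::cols(
    compound_id = readr::col_character(),
    unit_price = readr::col_double(),
    mw = readr::col_double()
  ))
  if (any(!is.na(prices$unit_price) & prices$unit_price < 0)) {
    stop("unit prices must be nonnegative", call. = FALSE)
  }
  prices
}

#' Write a price table as TSV
#' @param prices A price tibble (`compound_id`, `unit_price`, `mw`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_price_table <- function(prices, path) {
  readr::write_tsv(prices, path)
  invisible(path)
}

#' Build a medium from a design row and a catalog
#'
#' Maps the design's per-category nutrient choices onto catalog rows,
#' producing the named list consumed by [solve_fba()]. Absent categories
#' (e.g. the anaerobic `NA` electron acceptor) are skipped. The catalog's
#' full exchange set is recorded on the `"controlled"` attribute so that
#' unchosen nutrients are closed while non-catalog exchanges keep their
#' model bounds.
#'
#' @param design A list or one-row data frame with elements named after the
#'   nutrient categories (`carbon`, `electron_acceptor`, ...).
#' @param catalog A validated nutrient catalog.
#' @return A named list of catalog rows, one per present category.
#' @export
medium_from_design <- function(design, catalog) {
  medium <- list()
  cols <- c(carbon = "carbon", electron_acceptor = "electron_acceptor",
            nitrogen = "nitrogen", phosphorus = "phosphorus", sulfur = "sulfur")
  for (cat in names(cols)) {
    ex <- design[[cols[[cat]]]]
    if (is.null(ex) || is.na(ex)) next
    row <- catalog[catalog$exchange_id == ex, ]
    if (nrow(row) != 1L) stop("design references unknown nutrient: ", ex, call. = FALSE)
    medium[[cat]] <- as.list(row)
  }
  # medium control extends to every catalog nutrient: unchosen ones are
  # closed, non-catalog exchanges (CO2, products) keep their model bounds
  attr(medium, "controlled") <- catalog$exchange_id
  medium
}
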