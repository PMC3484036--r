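# Synthetic fixtures: a small carbon-balanced toy model with redox (NADH)
# and energy (ATP) bookkeeping, so byproduct secretion is growth-coupled
# the way it is in real fermentations. Glycolysis yields pyruvate, NADH and
# ATP; anaerobic growth must re-oxidize NADH through the ethanol or
# succinate branches and cover ATP demand through formate-lyase overflow,
# so wild-type anaerobic designs secrete ethanol plus acetate/formate,
# ADH-deficient genotypes become succinate producers, and the
# melibiose-like disaccharide (hydrolyzed through a branch that co-releases
# acetate) buys high uptake rates at a purity cost. Maximum theoretical
# yields are closed-form by construction (per mole glucose: acetate 2,
# formate 2, hydrogen 2, D-lactate 2, ethanol 1, succinate 1 -- the last
# two are NADH-limited).

TOY_PRODUCTS <- c("acetate", "ethanol", "formate", "succinate",
                  "d_lactate", "hydrogen")

TOY_YIELDS <- c(acetate = 2, d_lactate = 2, formate = 2, hydrogen = 2,
                ethanol = 1, succinate = 1)

#' Generate a toy metabolic model, nutrient catalog and price table
#'
#' The network (about 30 reactions) has a glycolysis-like core, the six
#' fermentative branches, respiration, urease, a biomass reaction drawing
#' pyruvate, ATP, NADH, ammonium, phosphate and sulfate, and exchanges for
#' all five nutrient categories. CO2 exchange is open in both directions
#' (the succinate branch carboxylates pyruvate). Gene rules include
#' isozymes (`gGLY1 or gGLY2`) and complexes (`gADH and gPDC`,
#' `gOXA and gOXB`). Everything is deterministic for a fixed seed.
#'
#' @param rng_seed Stored alongside the fixture; the network itself is
#'   fully deterministic.
#' @param n_carbon_sources 1-3 carbon sources: glucose, then the
#'   melibiose-like disaccharide, then glycerol (deliberately unpriced, to
#'   exercise missing-price handling; fermentable only aerobically, its
#'   catabolism is too reduced for anaerobic redox balance).
#' @param include_anaerobic Whether designs may omit the electron acceptor.
#' @param byproducts Products to include as branches. Acetate and formate
#'   are always present (both come from the ATP-yielding overflow reaction);
#'   ethanol, succinate, D-lactate and hydrogen branches are droppable.
#' @param designed_max_yields Named mol/mol-glucose yields to verify
#'   against the construction (`TOY_YIELDS`); any other value violates the
#'   carbon/redox balance of the generated stoichiometry and errors.
#' @return A list with elements `model` (`fs_model`), `catalog`, `prices`,
#'   `include_anaerobic` and `rng_seed`.
#' @export
make_toy_model <- function(rng_seed = 1L, n_carbon_sources = 3,
                           include_anaerobic = TRUE,
                           byproducts = TOY_PRODUCTS,
                           designed_max_yields = NULL) {
  stopifnot(n_carbon_sources >= 1, n_carbon_sources <= 3)
  byproducts <- union(c("acetate", "formate"),
                      match.arg(byproducts, TOY_PRODUCTS, several.ok = TRUE))
  if (!is.null(designed_max_yields)) {
    bad <- names(designed_max_yields)[
      designed_max_yields != TOY_YIELDS[names(designed_max_yields)]]
    if (length(bad)) {
      stop("designed yields violate carbon balance of the toy network: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  mets <- tibble::tribble(
    ~id,       ~name,             ~formula,    ~compartment, ~mw,
    "glc",     "D-glucose",       "C6H12O6",   "e",          180.16,
    "mel",     "disaccharide",    "C12H22O11", "e",          342.30,
    "glyc",    "glycerol",        "C3H8O3",    "e",          92.09,
    "o2",      "oxygen",          "O2",        "e",          32.00,
    "nh4",     "ammonium",        "H4N",       "e",          18.04,
    "urea",    "urea",            "CH4N2O",    "e",          60.06,
    "pi",      "phosphate",       "HO4P",      "e",          94.97,
    "so4",     "sulfate",         "O4S",       "e",          96.06,
    "co2",     "carbon dioxide",  "CO2",       "e",          44.01,
    "ac",      "acetate",         "C2H3O2",    "e",          59.04,
    "etoh",    "ethanol",         "C2H6O",     "e",          46.07,
    "form",    "formate",         "CH1O2",     "e",          45.02,
    "succ",    "succinate",       "C4H4O4",    "e",          116.07,
    "lac",     "D-lactate",       "C3H5O3",    "e",          89.07,
    "h2",      "hydrogen",        "H2",        "e",          2.02,
    "gal",     "hexose moiety",   "C6H12O6",   "c",          180.16,
    "pyr",     "pyruvate",        "C3H3O3",    "c",          87.05,
    "oaa4",    "C4 intermediate", "C4H4O5",    "c",          132.07,
    "nadh",    "redox carrier",   "",          "c",          NA,
    "atp",     "energy carrier",  "",          "c",          NA,
    "biomass", "biomass",         "C3H7NO2",   "c",          100
  )

  rxn <- function(id, name, stoich, rule = "", subsystem = "",
                  lb = 0, ub = 1000) {
    stoich <- stoich[stoich != 0]
    tibble::tibble(id = id, name = name, lower_bound = lb, upper_bound = ub,
                   gene_rule = rule, subsystem = subsystem,
                   stoich = list(stoich))
  }
  internal <- list(
    rxn("GLY", "glycolysis", c(glc = -1, pyr = 2, nadh = 2, atp = 2),
        "(gPTS and (gGLY1 or gGLY2))", "glycolysis"),
    rxn("MELH", "disaccharide hydrolysis", c(mel = -1, glc = 1, gal = 1),
        "gMEL", "glycolysis"),
    rxn("GALD", "hexose moiety catabolism",
        c(gal = -1, pyr = 1, ac = 1, co2 = 1, nadh = 1, atp = 1),
        "gGAL", "glycolysis"),
    rxn("GLPD", "glycerol assimilation",
        c(glyc = -1, pyr = 1, nadh = 2, atp = 1),
        "gGLP", "glycolysis"),
    rxn("LDH", "lactate dehydrogenase", c(pyr = -1, nadh = -1, lac = 1),
        "gLDH", "pyruvate metabolism"),
    rxn("PFL", "formate lyase overflow",
        c(pyr = -1, ac = 1, form = 1, atp = 1),
        "gPFL", "pyruvate metabolism"),
    rxn("ETOH", "ethanol branch",
        c(pyr = -1, nadh = -2, etoh = 1, co2 = 1),
        "(gADH and gPDC)", "pyruvate metabolism"),
    rxn("PPC", "pyruvate carboxylation", c(pyr = -1, co2 = -1, oaa4 = 1),
        "gPPC", "citric acid cycle"),
    rxn("FRD", "reductive succinate branch",
        c(oaa4 = -1, nadh = -2, succ = 1),
        "gFRD", "citric acid cycle"),
    rxn("FHL", "formate hydrogen lyase", c(form = -1, co2 = 1, h2 = 1),
        "gFHL", "pyruvate metabolism"),
    rxn("OX", "respiration", c(nadh = -1, o2 = -0.5, atp = 2.5),
        "(gOXA and gOXB)", "oxidative phosphorylation"),
    rxn("URE", "urease", c(urea = -1, nh4 = 2, co2 = 1),
        "gURE", "nitrogen metabolism"),
    rxn("ATPM", "energy dissipation", c(atp = -1),
        "", "energy"),
    rxn("GROWTH", "biomass synthesis",
        c(pyr = -1, atp = -2, nadh = -0.5, nh4 = -0.5, pi = -0.1,
          so4 = -0.05, biomass = 1),
        "", "biomass")
  )
  # acetate and formate are core overflow products (the ATP-yielding lyase
  # reaction makes both); only the decoupled branches can be dropped
  branch_of <- c(ethanol = "ETOH", succinate = "PPC",
                 d_lactate = "LDH", hydrogen = "FHL")
  met_of <- c(ethanol = "etoh", succinate = "succ",
              d_lactate = "lac", hydrogen = "h2")
  drop_products <- setdiff(names(branch_of), byproducts)
  drop_rxns <- unname(branch_of[drop_products])
  if ("succinate" %in% drop_products) drop_rxns <- c(drop_rxns, "FRD")
  drop_mets <- unname(met_of[drop_products])

  carbon_sources <- c("glc", "mel", "glyc")[seq_len(n_carbon_sources)]
  exchangeable <- setdiff(
    c(carbon_sources, "o2", "nh4", "urea", "pi", "so4", "co2",
      "ac", "etoh", "form", "succ", "lac", "h2", "biomass"),
    drop_mets)
  default_lb <- c(glc = -10, o2 = -20, nh4 = -100, pi = -100, so4 = -100,
                  co2 = -1000) # co2 freely exchanged (carboxylation substrate)
  exchanges <- lapply(exchangeable, function(met) {
    lb <- if (met %in% names(default_lb)) default_lb[[met]] else 0
    rxn(paste0("EX_", met), paste0(met, " exchange"),
        stats::setNames(-1, met), lb = lb)
  })
  rxns <- dplyr::bind_rows(c(internal, exchanges))
  rxns <- rxns[!rxns$id %in% drop_rxns, ]
  if (n_carbon_sources < 2) rxns <- rxns[!rxns$id %in% c("MELH", "GALD"), ]
  if (n_carbon_sources < 3) rxns <- rxns[rxns$id != "GLPD", ]
  used_mets <- unique(unlist(lapply(rxns$stoich, names)))
  mets <- mets[mets$id %in% used_mets, ]
  genes <- sort(unique(unlist(lapply(rxns$gene_rule,
                                     function(r) gpr_genes(parse_gene_rule(r))))))
  model <- metabolic_model(mets, rxns, genes, "GROWTH", id = "toy")

  catalog <- tibble::tribble(
    ~exchange_id, ~category,           ~max_uptake, ~unit_price, ~mw,
    "EX_glc",     "carbon",            10,          0.05,        180.16,
    "EX_mel",     "carbon",            8,           0.08,        342.30,
    "EX_glyc",    "carbon",            10,          NA,          92.09,
    "EX_o2",      "electron_acceptor", 20,          0.01,        32.00,
    "EX_nh4",     "nitrogen",          100,         0.01,        18.04,
    "EX_urea",    "nitrogen",          50,          0.02,        60.06,
    "EX_pi",      "phosphorus",        100,         0.03,        94.97,
    "EX_so4",     "sulfur",            100,         0.02,        96.06
  )
  catalog <- catalog[catalog$exchange_id %in% model$reactions$id, ]
  prices <- tibble::tribble(
    ~compound_id, ~unit_price, ~mw,
    "ac",         0.10,        59.04,
    "etoh",       0.50,        46.07,
    "form",       0.20,        45.02,
    "succ",       1.00,        116.07,
    "lac",        0.30,        89.07,
    "h2",         2.00,        2.02
  )
  prices <- prices[prices$compound_id %in% model$metabolites$id, ]
  list(model = model, catalog = validate_catalog(catalog), prices = prices,
       include_anaerobic = include_anaerobic, rng_seed = rng_seed)
}

#' Generate a synthetic gene-expression profile
#'
#' Active genes draw expression above the cutoff, inactive genes below, so
#' consistency scores have a known direction by construction.
#'
#' @param model An `fs_model`.
#' @param active_genes Genes considered expressed (subset of model genes).
#' @param rng_seed Seed for the draws.
#' @param cutoff Expression cutoff separating active from inactive.
#' @param condition Condition label.
#' @return An `fs_expression_profile`: list with named `expression` in
#'   `[0, 1]`, `cutoff` and `condition`.
#' @export
make_expression_profile <- function(model, active_genes = model$genes,
                                    rng_seed = 1L, cutoff = 0.5,
                                    condition = "synthetic") {
  stopifnot(all(active_genes %in% model$genes))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(rng_seed)
  n <- length(model$genes)
  expr <- stats::runif(n, 0.05, 0.45)
  names(expr) <- model$genes
  expr[active_genes] <- stats::runif(length(active_genes), 0.55, 0.95)
  structure(list(expression = expr, cutoff = cutoff, condition = condition),
            class = "fs_expression_profile")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Read and write expression profiles as TSV
#'
#' @param path TSV with columns `gene_id`, `expression`; the cutoff is
#'   stored as a `# cutoff:` header comment.
#' @return An `fs_expression_profile`.
#' @export
read_expression_profile <- function(path) {
  first <- readLines(path, n = 1L)
  cutoff <- if (grepl("^# cutoff:", first)) {
    as.numeric(sub("^# cutoff:\\s*", "", first))
  } else 0.5
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene_id = readr::col_character(), expression = readr::col_double()))
  structure(list(expression = stats::setNames(tbl$expression, tbl$gene_id),
                 cutoff = cutoff, condition = basename(path)),
            class = "fs_expression_profile")
}

#' @rdname read_expression_profile
#' @param profile An `fs_expression_profile`.
#' @export
write_expression_profile <- function(profile, path) {
  writeLines(paste0("# cutoff: ", profile$cutoff), path)
  readr::write_tsv(tibble::tibble(gene_id = names(profile$expression),
                                  expression = unname(profile$expression)),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}
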