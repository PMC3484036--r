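test_that("elemental formulas parse and carbon atoms are counted", {
  expect_equal(carbon_count("C6H12O6"), 6L)    # glucose: 6 carbons per mole
  expect_equal(carbon_count("H2O"), 0L)
  expect_equal(carbon_count("C36H62O31"), 36L) # maltohexaose-class sugar
  expect_equal(carbon_count("CH4N2O"), 1L)     # urea
  expect_equal(parse_formula("CH3COOH"), c(C = 2L, H = 4L, O = 2L))
  expect_equal(carbon_count(""), 0L)
  expect_error(carbon_count("C6?"), "malformed")
  expect_error(carbon_count("c6h12"), "malformed")
})

test_that("carbon counting is additive over concatenated element runs", {
  set.seed(7)
  elements <- c("C", "H", "O", "N", "P", "S")
  for (i in 1:20) {
    k <- sample(2:4, 1)
    parts <- replicate(k, paste0(
      paste0(sample(elements, sample(1:3, 1)), sample(1:9, sample(1:3, 1)[1],
                                                      replace = TRUE),
             collapse = ""), collapse = ""))
    whole <- paste(parts, collapse = "")
    expect_equal(carbon_count(whole), sum(vapply(parts, carbon_count,
                                                 integer(1))))
  }
})

test_that("gene rules follow complex/isozyme knockout semantics", {
  expect_false(evaluate_gene_rule("(g1 and g2)", deleted = "g1"))
  expect_true(evaluate_gene_rule("(g1 or g2)", deleted = "g1"))
  expect_true(evaluate_gene_rule("", deleted = "g1"))
  expect_false(evaluate_gene_rule("(g1 or g2) and g3", deleted = c("g1", "g2")))
  expect_true(evaluate_gene_rule("(g1 and g2) or g3", deleted = c("g1")))
  expect_warning(
    out <- evaluate_gene_rule("g1", deleted = "nope", genes = c("g1")),
    "unknown")
  expect_true(out)
  expect_error(parse_gene_rule("(g1 and"), "gene rule")
  expect_error(parse_gene_rule("g1 and or g2"), "gene rule")
})

test_that("gene rule evaluation matches a truth-table oracle", {
  genes <- c("g1", "g2", "g3", "g4")
  rules <- c("g1", "g1 and g2", "g1 or g2", "(g1 and g2) or (g3 and g4)",
             "((g1 or g2) and g3) or g4", "g1 and (g2 or (g3 and g4))")
  for (rule in rules) {
    for (mask in 0:15) {
      deleted <- genes[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
      expect_equal(evaluate_gene_rule(rule, deleted),
                   gpr_r_oracle(rule, deleted, genes),
                   info = paste(rule, "|", paste(deleted, collapse = ",")))
    }
  }
})

test_that("expression maps onto reactions with AND = min, OR = max", {
  expr <- c(g1 = 0.2, g2 = 0.8, g3 = 0.5)
  expect_equal(reaction_expression("g1 and g2", expr), 0.2)
  expect_equal(reaction_expression("g1 or g2", expr), 0.8)
  expect_equal(reaction_expression("(g1 and g2) or g3", expr), 0.5)
  expect_equal(reaction_expression("g1 and (g2 or g3)", expr), 0.2)
  expect_true(is.na(reaction_expression("", expr)))
  expect_true(is.na(reaction_expression("g9", expr)))
})

test_that("JSON model round-trip preserves every field exactly", {
  toy <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(toy$model, path)
  back <- load_model(path, format = "json")
  expect_identical(back$reactions$id, toy$model$reactions$id)
  expect_identical(back$reactions$stoich, toy$model$reactions$stoich)
  expect_identical(back$reactions$lower_bound, toy$model$reactions$lower_bound)
  expect_identical(back$reactions$upper_bound, toy$model$reactions$upper_bound)
  expect_identical(back$reactions$gene_rule, toy$model$reactions$gene_rule)
  expect_identical(back$genes, toy$model$genes)
  expect_identical(back$biomass_reaction_id, toy$model$biomass_reaction_id)
  expect_identical(back$metabolites$formula, toy$model$metabolites$formula)
})

test_that("a model without a biomass reaction is rejected by name", {
  toy <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  raw <- jsonlite::fromJSON(write_model_json(toy$model, path),
                            simplifyVector = FALSE)
  raw$reactions <- lapply(raw$reactions, function(r) {
    r$objective_coefficient <- 0
    r
  })
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad, auto_unbox = TRUE)
  expect_error(load_model(bad, format = "json"), "no biomass reaction")
  expect_error(load_model("/nonexistent/model.json"), "not found")
})

test_that("structural invariants are enforced at construction", {
  toy <- toy_fixture()
  mets <- toy$model$metabolites
  rxns <- toy$model$reactions
  # unknown metabolite in stoichiometry
  bad <- rxns
  bad$stoich[[1]] <- c(ghost = 1)
  expect_error(metabolic_model(mets, bad, toy$model$genes, "GROWTH"),
               "unknown metabolites")
  # inverted bounds
  bad <- rxns
  bad$lower_bound[2] <- bad$upper_bound[2] + 1
  expect_error(metabolic_model(mets, bad, toy$model$genes, "GROWTH"),
               "lower bound exceeds")
  # exchange touching two metabolites
  bad <- rxns
  bad$stoich[[match("EX_glc", bad$id)]] <- c(glc = -1, pyr = 1)
  expect_error(metabolic_model(mets, bad, toy$model$genes, "GROWTH"),
               "exactly one metabolite")
})

test_that("SBML models load with fbc bounds and gene associations", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="s" compartment="c" fbc:chemicalFormula="C2H4"/>
      <species id="biomass" compartment="c" fbc:chemicalFormula="C2H4"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_s" reversible="true" fbc:lowerFluxBound="lb_ex"
                fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="s" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="GROWTH" reversible="false" fbc:lowerFluxBound="zero"
                fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="s" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="biomass" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="g1"/>
            <fbc:or>
              <fbc:geneProductRef fbc:geneProduct="g2"/>
              <fbc:geneProductRef fbc:geneProduct="g3"/>
            </fbc:or>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_biomass" reversible="false" fbc:lowerFluxBound="zero"
                fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="biomass" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g1"/>
      <fbc:geneProduct fbc:id="g2"/>
      <fbc:geneProduct fbc:id="g3"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  m <- load_model(path)
  expect_s3_class(m, "fs_model")
  expect_equal(m$biomass_reaction_id, "GROWTH")
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_s"], -10)
  expect_equal(sort(m$genes), c("g1", "g2", "g3"))
  gr <- m$reactions$gene_rule[m$reactions$id == "GROWTH"]
  expect_false(evaluate_gene_rule(gr, "g1"))
  expect_true(evaluate_gene_rule(gr, "g2"))
  expect_false(evaluate_gene_rule(gr, c("g2", "g3")))
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 10)
})

test_that("gene labels resolve exactly, then by unique prefix with warning", {
  toy <- toy_fixture()
  expect_identical(resolve_genes("gADH", toy$model), "gADH")
  expect_warning(out <- resolve_genes("gadh", toy$model), "resolved")
  expect_identical(out, "gADH")
  expect_warning(out2 <- resolve_genes("gFRDx", toy$model), "resolved")
  expect_identical(out2, "gFRD")
  expect_error(suppressWarnings(resolve_genes("gG", toy$model)), "resolve")
})

test_that("default nutrient categorization is progressive and exclusive", {
  toy <- toy_fixture()
  cats <- categorize_nutrients(toy$model,
                               c("EX_glc", "EX_o2", "EX_nh4", "EX_pi",
                                 "EX_so4", "EX_urea"))
  expect_equal(cats, c("carbon", "electron_acceptor", "nitrogen",
                       "phosphorus", "sulfur", "carbon"))
  # urea contains carbon, so the element rule calls it carbon; the toy
  # catalog overrides it to nitrogen (catalog is authoritative)
  expect_equal(toy$catalog$category[toy$catalog$exchange_id == "EX_urea"],
               "nitrogen")
})

test_that("nutrient catalogs validate and round-trip as TSV", {
  toy <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nutrient_catalog(toy$catalog, path)
  back <- read_nutrient_catalog(path)
  expect_equal(back, toy$catalog)
  dup <- rbind(toy$catalog, toy$catalog[1, ])
  expect_error(validate_catalog(dup), "duplicate")
  bad <- toy$catalog
  bad$category[1] <- "vitamins"
  expect_error(validate_catalog(bad), "unknown nutrient categories")
  bad <- toy$catalog
  bad$max_uptake[1] <- 0
  expect_error(validate_catalog(bad), "positive")
})
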