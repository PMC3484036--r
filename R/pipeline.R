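# Pipeline orchestration: a two-phase architecture. Phase 1 (enumerate +
# screen) writes the phenotype matrix once; every phase-2 analysis
# (clustering, Pareto, transition network) consumes that table without
# re-solving any LP.

CENTRAL_SUBSYSTEMS <- c("citric acid cycle", "glycolysis", "gluconeogenesis",
                        "oxidative phosphorylation", "pentose phosphate",
                        "pyruvate metabolism")

#' Deletable genes from the central-metabolism subsystems
#'
#' Default deletion candidates: every gene appearing in a GPR rule of a
#' reaction annotated to the citric acid cycle, glycolysis,
#' gluconeogenesis, oxidative phosphorylation, pentose phosphate or
#' pyruvate metabolism subsystems.
#'
#' @param model An `fs_model`.
#' @param subsystems Subsystem names (matched case-insensitively).
#' @return Character vector of gene ids.
#' @export
central_genes <- function(model, subsystems = CENTRAL_SUBSYSTEMS) {
  hit <- tolower(model$reactions$subsystem) %in% tolower(subsystems)
  sort(unique(unlist(lapply(model$reactions$gene_rule[hit],
                            function(r) gpr_genes(parse_gene_rule(r))))))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; stage seeds derive from it.
#' @param ... Overrides of the default fields.
#' @return A named list (`fs_config`).
#' @export
pipeline_config <- function(out_dir = tempfile("fluxscape_run_"), seed = 1L, ...) {
  cfg <- list(
    model = "toy",             # "toy" or a model file path
    catalog = NULL,            # TSV path; NULL = toy catalog
    prices = NULL,             # TSV path; NULL = toy price table
    expression = NULL,         # TSV profile path or NULL
    genes = NULL,              # NULL = central-metabolism genes
    max_deletions = 2,
    ea_includes_none = TRUE,
    epsilon = 1e-6,
    pfba = TRUE,
    economic_subset = TRUE,
    k = NULL,                  # NULL = gap statistic
    k_max = 8,
    gap_B = 50,
    goals = list(list(metric = "succinate_production_rate",
                      sense = "maximize", weight = 0.5),
                 list(metric = "succinate_purity",
                      sense = "maximize", weight = 0.5)),
    min_relative_frequency = 0.01,
    out_dir = out_dir,
    seed = seed
  )
  utils::modifyList(cfg, list(...))
}

read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full multi-goal design pipeline
#'
#' Enumerates the design space, screens every design by FBA, computes the
#' trait matrix, clusters it into meta-phenotypes, extracts the Pareto
#' frontier and tradeoff slopes for the configured goals, builds the
#' perturbation-typed transition network, and writes all artifacts (TSV,
#' GraphML, JSON summary) into `config$out_dir`.
#'
#' @param config A list from [pipeline_config()] or a YAML file path.
#' @return Invisibly, a list with `phenotypes`, `meta`, `front`, `slopes`,
#'   `network`, `influence`, `summary` and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (identical(config$model, "toy")) {
    toy <- make_toy_model(rng_seed = config$seed)
    model <- toy$model
    catalog <- toy$catalog
    prices <- toy$prices
  } else {
    model <- load_model(config$model)
    catalog <- read_nutrient_catalog(config$catalog)
    prices <- if (!is.null(config$prices)) read_price_table(config$prices)
  }
  profile <- if (!is.null(config$expression)) {
    read_expression_profile(config$expression)
  }
  genes <- config$genes %||% central_genes(model)

  designs <- enumerate_designs(catalog, genes,
                               max_deletions = config$max_deletions,
                               ea_includes_none = config$ea_includes_none)
  phenotypes <- screen_designs(designs, model, catalog, prices,
                               epsilon = config$epsilon, pfba = config$pfba,
                               expression_profile = profile)
  summ <- attr(phenotypes, "screen_summary")
  paths$phenotypes <- file.path(config$out_dir, "phenotype_matrix.tsv")
  readr::write_tsv(phenotypes, paths$phenotypes)

  meta <- cluster_phenotypes(phenotypes, k = config$k,
                             economic_subset = config$economic_subset,
                             k_max = config$k_max, B = config$gap_B,
                             rng_seed = config$seed)
  paths$assignments <- file.path(config$out_dir, "meta_phenotype_assignments.tsv")
  readr::write_tsv(tidy(meta), paths$assignments)
  paths$centroids <- file.path(config$out_dir, "meta_phenotype_centroids.tsv")
  readr::write_tsv(centroid_table(meta), paths$centroids)

  goals <- do.call(goal_spec, purrr::transpose(config$goals) |>
                     purrr::map(unlist))
  eco <- phenotypes[phenotypes$economics_available, ]
  front <- pareto_front(eco, goals)
  paths$frontier <- file.path(config$out_dir, "pareto_frontier.tsv")
  readr::write_tsv(front$frontier, paths$frontier)
  slopes <- if (nrow(front$frontier) >= 2 && nrow(goals) >= 2) {
    tradeoff_slopes(front$frontier, x = goals$metric[2], y = goals$metric[1])
  }
  if (!is.null(slopes)) {
    paths$slopes <- file.path(config$out_dir, "tradeoff_slopes.tsv")
    readr::write_tsv(slopes, paths$slopes)
  }

  assign_all <- dplyr::left_join(
    designs, tidy(meta)[, c("design_id", "cluster")], by = "design_id")
  assign_all$cluster[is.na(assign_all$cluster)] <- 0L
  network <- build_transition_network(assign_all, catalog)
  influence <- perturbation_influence(network)
  filtered <- filter_edges(network, config$min_relative_frequency)
  paths$network <- file.path(config$out_dir, "transition_network.graphml")
  write_transition_graphml(filtered, paths$network)
  paths$edges <- file.path(config$out_dir, "transition_edges.tsv")
  write_transition_edges(network, paths$edges)
  paths$influence <- file.path(config$out_dir, "perturbation_influence.tsv")
  readr::write_tsv(influence, paths$influence)

  cluster_shares <- sort(meta$cluster_sizes, decreasing = TRUE) /
    sum(meta$cluster_sizes)
  summary <- list(
    n_designs = summ$total,
    n_viable = summ$viable,
    viable_fraction = summ$viable_fraction,
    lp_failures = summ$lp_failures,
    n_meta_phenotypes = meta$k,
    largest_cluster_share = cluster_shares[[1]],
    seed = config$seed
  )
  paths$summary <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  paths$config <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], paths$config)

  invisible(list(phenotypes = phenotypes, meta = meta, front = front,
                 slopes = slopes, network = network, influence = influence,
                 summary = summary, paths = paths))
}

centroid_table <- function(meta) {
  ct <- tibble::as_tibble(meta$centroids)
  ct$cluster <- seq_len(meta$k)
  ct$size <- meta$cluster_sizes
  ct$sse <- meta$cluster_sse
  ct$heterogeneity <- meta$heterogeneity
  dplyr::relocate(ct, "cluster", "size", "sse", "heterogeneity")
}
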