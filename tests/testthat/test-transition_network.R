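# small hand-checkable design tables reuse the toy catalog columns
mini_catalog <- function() {
  tibble::tribble(
    ~exchange_id, ~category,           ~max_uptake, ~unit_price, ~mw,
    "C1", "carbon", 10, 0.1, 100,
    "C2", "carbon", 10, 0.1, 100,
    "C3", "carbon", 10, 0.1, 100,
    "EA1", "electron_acceptor", 10, 0.1, 100,
    "N1", "nitrogen", 10, 0.1, 100,
    "P1", "phosphorus", 10, 0.1, 100,
    "S1", "sulfur", 10, 0.1, 100
  )
}

design_row <- function(carbon = "C1", ea = "EA1", gene1 = NA_character_,
                       gene2 = NA_character_, cluster = 1L) {
  tibble::tibble(carbon = carbon, electron_acceptor = ea, nitrogen = "N1",
                 phosphorus = "P1", sulfur = "S1",
                 gene1 = gene1, gene2 = gene2, cluster = cluster)
}

test_that("single-component substitutions increment the typed edge once", {
  asg <- dplyr::bind_rows(design_row("C1", cluster = 1L),
                          design_row("C2", cluster = 2L))
  net <- build_transition_network(asg, mini_catalog())
  e <- net$edges
  expect_equal(nrow(e[e$type == "C", ]), 1)
  expect_equal(e$count[e$type == "C"], 1L)
  expect_equal(e$from[e$type == "C"], 1L)
  expect_equal(e$to[e$type == "C"], 2L)
  expect_equal(sum(e$type != "C"), 0)
  # both in the same cluster: the pair becomes a self-loop
  asg2 <- dplyr::bind_rows(design_row("C1", cluster = 1L),
                           design_row("C2", cluster = 1L))
  net2 <- build_transition_network(asg2, mini_catalog())
  e2 <- net2$edges
  expect_equal(e2$from[e2$type == "C"], 1L)
  expect_equal(e2$to[e2$type == "C"], 1L)
})

test_that("per-type pair totals match exhaustive enumeration", {
  # 3 carbon sources x 2 genotypes (WT, single deletion), one medium rest
  asg <- dplyr::bind_rows(
    design_row("C1", cluster = 1L), design_row("C2", cluster = 2L),
    design_row("C3", cluster = 1L),
    design_row("C1", gene1 = "g1", cluster = 0L),
    design_row("C2", gene1 = "g1", cluster = 2L),
    design_row("C3", gene1 = "g1", cluster = 3L))
  net <- build_transition_network(asg, mini_catalog())
  # C pairs: per genotype, choose(3, 2) = 3 pairs; 2 genotypes -> 6
  expect_equal(unname(net$type_totals["C"]), 6L)
  # SGD pairs: per carbon source, WT vs single deletion -> 3
  expect_equal(unname(net$type_totals["SGD"]), 3L)
  expect_true(is.na(net$type_totals["EA"]) || net$type_totals["EA"] == 0)
  # count conservation: edge counts sum to the per-type totals
  sums <- tapply(net$edges$count, net$edges$type, sum)
  expect_equal(unname(sums["C"]), 6L)
  expect_equal(unname(sums["SGD"]), 3L)
  # symmetry is structural: unordered keys with from <= to
  expect_true(all(net$edges$from <= net$edges$to))
  # nonviable designs participate as node 0
  expect_true(0 %in% net$nodes$cluster)
  expect_true(any(net$edges$from == 0))
})

test_that("genetic edges distinguish single- from double-deletion edits", {
  asg <- dplyr::bind_rows(
    design_row(cluster = 1L),                                  # WT
    design_row(gene1 = "g1", cluster = 2L),                    # single
    design_row(gene1 = "g2", cluster = 2L),                    # single
    design_row(gene1 = "g1", gene2 = "g2", cluster = 3L),      # double
    design_row(gene1 = "g1", gene2 = "g3", cluster = 3L))      # double
  net <- build_transition_network(asg, mini_catalog())
  # SGD: WT<->g1, WT<->g2, g1<->g2 (substitution) = 3 pairs
  expect_equal(unname(net$type_totals["SGD"]), 3L)
  # DGD: g1+g2 <-> g1+g3 (substitution), g1 <-> g1+g2 and g2 <-> g1+g2
  # (addition), g1 <-> g1+g3 (addition) = 4 pairs
  expect_equal(unname(net$type_totals["DGD"]), 4L)
})

test_that("edge filtering respects the relative-frequency threshold", {
  asg <- dplyr::bind_rows(
    lapply(1:9, function(i) design_row("C1", gene1 = paste0("g", i),
                                       cluster = 1L)),
    design_row("C1", gene1 = "g99", cluster = 2L))
  net <- build_transition_network(asg, mini_catalog())
  full <- filter_edges(net, 0)
  expect_equal(full$edges, net$edges)
  # SGD pairs: choose(10, 2) = 45, of which 9 touch cluster 2
  expect_equal(unname(net$type_totals["SGD"]), 45L)
  kept <- filter_edges(net, 0.5)
  expect_true(all(kept$edges$rel_freq >= 0.5))
  expect_lt(nrow(kept$edges), nrow(net$edges))
  only_total <- filter_edges(net, 1.0)
  expect_true(all(only_total$edges$rel_freq == 1))
  # manual recomputation of surviving edges at the 1% default
  manual <- net$edges[net$edges$count / net$type_totals[net$edges$type] >=
                        0.01, ]
  expect_equal(filter_edges(net, 0.01)$edges, manual)
})

test_that("perturbation influence normalizes change fractions across types", {
  asg <- dplyr::bind_rows(
    design_row("C1", cluster = 1L), design_row("C2", cluster = 2L),
    design_row("C1", "EA1", cluster = 1L)[0, ], # no EA variation
    design_row("C1", gene1 = "g1", cluster = 1L),
    design_row("C2", gene1 = "g1", cluster = 2L))
  net <- build_transition_network(asg, mini_catalog())
  infl <- perturbation_influence(net)
  # carbon substitutions always change the cluster; SGD never does
  expect_equal(infl$change_fraction[infl$type == "C"], 1)
  expect_equal(infl$change_fraction[infl$type == "SGD"], 0)
  expect_equal(infl$influence[infl$type == "C"], 1)
  expect_equal(infl$influence[infl$type == "SGD"], 0)
  expect_true(all(is.na(infl$influence[infl$type %in% c("EA", "N", "P", "S")])))
  expect_equal(sum(infl$influence, na.rm = TRUE), 1)
})

test_that("random assignments spread influence roughly evenly", {
  set.seed(77)
  grid <- tidyr::crossing(carbon = c("C1", "C2", "C3"),
                          electron_acceptor = "EA1",
                          nitrogen = "N1", phosphorus = "P1", sulfur = "S1",
                          gene1 = c(NA_character_, "g1", "g2", "g3"))
  grid$gene2 <- NA_character_
  grid$cluster <- sample(1:2, nrow(grid), replace = TRUE)
  net <- build_transition_network(grid, mini_catalog())
  infl <- perturbation_influence(net)
  ok <- infl[infl$type %in% c("C", "SGD"), ]
  expect_true(all(abs(ok$change_fraction - 0.5) < 0.35)) # sampling slack
})

test_that("coarsening clusters merges edge mass without creating it", {
  set.seed(5)
  grid <- tidyr::crossing(carbon = c("C1", "C2", "C3"),
                          electron_acceptor = "EA1", nitrogen = "N1",
                          phosphorus = "P1", sulfur = "S1",
                          gene1 = c(NA_character_, "g1"))
  grid$gene2 <- NA_character_
  grid$cluster <- sample(1:3, nrow(grid), replace = TRUE)
  fine <- build_transition_network(grid, mini_catalog())
  merged <- grid
  merged$cluster[merged$cluster == 3] <- 2L
  coarse <- build_transition_network(merged, mini_catalog())
  expect_equal(sum(coarse$edges$count), sum(fine$edges$count))
  expect_lte(nrow(coarse$edges), nrow(fine$edges))
  expect_equal(coarse$type_totals, fine$type_totals)
})

test_that("GraphML export drops the nonviable node by convention", {
  asg <- dplyr::bind_rows(
    design_row("C1", cluster = 1L), design_row("C2", cluster = 2L),
    design_row("C3", cluster = 0L))
  net <- build_transition_network(asg, mini_catalog())
  path <- withr::local_tempfile(fileext = ".graphml")
  write_transition_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_false("0" %in% igraph::V(g)$name)
  expect_true(all(c("1", "2") %in% igraph::V(g)$name))
  edges_path <- withr::local_tempfile(fileext = ".tsv")
  write_transition_edges(net, edges_path)
  back <- readr::read_tsv(edges_path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  # unknown catalog entries are rejected
  bad <- design_row("C9")
  expect_error(build_transition_network(bad, mini_catalog()), "unknown catalog")
})
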