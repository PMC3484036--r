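# Shared fixtures and independent oracles. Everything is generated in code;
# expensive artifacts (the full toy screen) are computed lazily once per
# session and reused across test files.

.fs_cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fs_cache$toy)) .fs_cache$toy <- make_toy_model()
  .fs_cache$toy
}

toy_medium <- function(carbon = "EX_glc", ea = NA, nitrogen = "EX_nh4",
                       phosphorus = "EX_pi", sulfur = "EX_so4") {
  medium_from_design(list(carbon = carbon, electron_acceptor = ea,
                          nitrogen = nitrogen, phosphorus = phosphorus,
                          sulfur = sulfur), toy_fixture()$catalog)
}

# full screen of the toy design space, shared across test files
toy_screen <- function() {
  if (is.null(.fs_cache$screen)) {
    toy <- toy_fixture()
    designs <- enumerate_designs(toy$catalog, central_genes(toy$model),
                                 max_deletions = 2, ea_includes_none = TRUE)
    .fs_cache$designs <- designs
    .fs_cache$screen <- screen_designs(designs, toy$model, toy$catalog,
                                       toy$prices)
  }
  .fs_cache$screen
}

toy_designs <- function() {
  toy_screen()
  .fs_cache$designs
}

# minimal linear-chain model: substrate -> biomass, one gene
chain_model <- function(uptake = 10) {
  mets <- tibble::tibble(
    id = c("s", "biomass"), name = c("substrate", "biomass"),
    formula = c("C1", "C1"), compartment = "c", mw = NA_real_)
  rxns <- tibble::tibble(
    id = c("EX_s", "GROWTH", "EX_biomass"),
    name = id,
    lower_bound = c(-uptake, 0, 0),
    upper_bound = 1000,
    gene_rule = c("", "g1", ""),
    subsystem = "",
    stoich = list(c(s = -1), c(s = -1, biomass = 1), c(biomass = -1)))
  metabolic_model(mets, rxns, genes = "g1", biomass_reaction_id = "GROWTH",
                  id = "chain")
}

# branched model (8 reactions) with an inefficient alternative route
branched_model <- function() {
  mets <- tibble::tibble(
    id = c("a", "b", "biomass"),
    name = id, formula = c("C2", "C2", "C2"),
    compartment = "c", mw = NA_real_)
  rxns <- tibble::tibble(
    id = c("EX_a", "R1", "R2", "GROWTH", "EX_biomass"),
    name = id,
    lower_bound = c(-10, 0, 0, 0, 0),
    upper_bound = c(1000, 6, 1000, 1000, 1000),
    gene_rule = c("", "g1", "g2", "", ""),
    subsystem = "",
    stoich = list(c(a = -1), c(a = -1, b = 1), c(a = -1, b = 0.5),
                  c(b = -1, biomass = 1), c(biomass = -1)))
  metabolic_model(mets, rxns, genes = c("g1", "g2"),
                  biomass_reaction_id = "GROWTH", id = "branched")
}

# brute-force LP oracle: enumerate basic solutions of {Ax = b, lb<=x<=ub}
# by fixing (n - m) variables at bounds and solving the square system
vertex_oracle <- function(obj, A, lb, ub, b = rep(0, nrow(A)),
                          maximize = TRUE) {
  n <- ncol(A)
  m <- nrow(A)
  best <- NA_real_
  feasible <- FALSE
  for (nb in utils::combn(n, n - m, simplify = FALSE)) {
    bset <- setdiff(seq_len(n), nb)
    B <- A[, bset, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    combos <- expand.grid(rep(list(1:2), length(nb)))
    for (ci in seq_len(max(1, nrow(combos)))) {
      xn <- if (length(nb)) {
        ifelse(unlist(combos[ci, ]) == 1, lb[nb], ub[nb])
      } else numeric(0)
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% xn else 0
      xb <- solve(B, rhs)
      if (any(xb < lb[bset] - 1e-8) || any(xb > ub[bset] + 1e-8)) next
      x <- numeric(n)
      x[nb] <- xn
      x[bset] <- xb
      v <- sum(obj * x)
      feasible <- TRUE
      if (is.na(best) || (maximize && v > best) || (!maximize && v < best)) {
        best <- v
      }
    }
  }
  list(feasible = feasible, best = best)
}

# O(n^2) pairwise dominance oracle (maximize orientation)
dominance_oracle <- function(g) {
  n <- nrow(g)
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(g[j, ] >= g[i, ]) && any(g[j, ] > g[i, ])) {
        nd[i] <- FALSE
        break
      }
    }
  }
  nd
}

# evaluate a GPR string with R's own parser as an independent oracle
gpr_r_oracle <- function(rule, deleted, genes) {
  expr <- rule
  for (g in genes) {
    expr <- gsub(paste0("\\b", g, "\\b"), as.character(!(g %in% deleted)),
                 expr)
  }
  expr <- gsub("\\band\\b", "&&", expr, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "||", expr, ignore.case = TRUE)
  eval(parse(text = expr))
}

expect_deterministic_tsv <- function(path_a, path_b) {
  expect_identical(readLines(path_a), readLines(path_b))
}
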