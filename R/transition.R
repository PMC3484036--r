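# Meta-phenotype transition networks. For each perturbation type (carbon,
# electron acceptor, nitrogen, phosphorus, sulfur source, single and double
# gene deletions) every unordered pair of designs differing in exactly one
# component of that type is evaluated; the pair increments the typed edge
# between the two designs' clusters (node 0 = nonviable). Edges are
# bidirectional by construction (unordered keys).

PERTURBATION_TYPES <- c("C", "EA", "N", "P", "S", "SGD", "DGD")

#' Build a perturbation-typed meta-phenotype transition network
#'
#' @param assignments A design tibble (the category columns plus
#'   `gene1`/`gene2`) with a `cluster` column; nonviable designs carry
#'   cluster 0.
#' @param catalog The nutrient catalog the designs were enumerated from
#'   (designs referencing nutrients outside it are an error).
#' @return An `fs_transition_network`: `edges` (tibble `type`, `from`,
#'   `to`, `count`, `rel_freq` with `from <= to`), `nodes` (cluster sizes),
#'   `type_totals` (pairs evaluated per type).
#' @export
build_transition_network <- function(assignments, catalog) {
  catalog <- validate_catalog(catalog)
  df <- tibble::as_tibble(assignments)
  needed <- c(NUTRIENT_CATEGORIES, "gene1", "gene2", "cluster")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("assignments lack columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  used <- unique(stats::na.omit(unlist(df[NUTRIENT_CATEGORIES])))
  unknown <- setdiff(used, catalog$exchange_id)
  if (length(unknown)) stop("designs reference unknown catalog entries: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  df$genotype <- paste(ifelse(is.na(df$gene1), ".", df$gene1),
                       ifelse(is.na(df$gene2), ".", df$gene2), sep = "+")
  df$n_del <- (!is.na(df$gene1)) + (!is.na(df$gene2))

  env_types <- c(C = "carbon", EA = "electron_acceptor", N = "nitrogen",
                 P = "phosphorus", S = "sulfur")
  edge_rows <- list()
  for (ty in names(env_types)) {
    col <- env_types[[ty]]
    others <- c(setdiff(NUTRIENT_CATEGORIES, col), "genotype")
    edge_rows[[ty]] <- pair_edges(df, vary = col, fixed = others, type = ty)
  }
  edge_rows[["SGD"]] <- genetic_edges(df, double = FALSE)
  edge_rows[["DGD"]] <- genetic_edges(df, double = TRUE)
  edges <- dplyr::bind_rows(edge_rows)
  totals <- edges |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  edges <- edges |>
    dplyr::group_by(.data$type, .data$from, .data$to) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(totals, by = "type") |>
    dplyr::mutate(rel_freq = .data$count / .data$total) |>
    dplyr::select(-"total")
  nodes <- df |>
    dplyr::count(.data$cluster, name = "size") |>
    dplyr::arrange(.data$cluster)
  structure(list(edges = edges, nodes = nodes,
                 type_totals = stats::setNames(totals$total, totals$type)),
            class = "fs_transition_network")
}

# unordered pairs of designs identical on `fixed` and differing on `vary`
pair_edges <- function(df, vary, fixed, type) {
  key <- do.call(paste, c(lapply(df[fixed], function(x) ifelse(is.na(x), ".", x)),
                          sep = "|"))
  v <- ifelse(is.na(df[[vary]]), ".", df[[vary]])
  rows <- list()
  for (grp in split(seq_len(nrow(df)), key)) {
    if (length(grp) < 2) next
    vals <- v[grp]
    pairs <- utils::combn(seq_along(grp), 2)
    differ <- vals[pairs[1, ]] != vals[pairs[2, ]]
    if (!any(differ)) next
    a <- df$cluster[grp[pairs[1, differ]]]
    b <- df$cluster[grp[pairs[2, differ]]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = type, from = pmin(a, b), to = pmax(a, b), count = 1L)
  }
  dplyr::bind_rows(rows)
}

# SGD: single-gene edits among genotypes with <= 1 deletion (wild type <->
# single, single <-> single). DGD: single-gene edits touching a
# double-deletion genotype (double <-> double substitution, single <->
# double addition).
genetic_edges <- function(df, double) {
  key <- do.call(paste, c(lapply(df[NUTRIENT_CATEGORIES],
                                 function(x) ifelse(is.na(x), ".", x)),
                          sep = "|"))
  rows <- list()
  for (grp in split(seq_len(nrow(df)), key)) {
    if (length(grp) < 2) next
    dels <- lapply(grp, function(i) {
      d <- c(df$gene1[i], df$gene2[i])
      d[!is.na(d)]
    })
    sizes <- lengths(dels)
    pairs <- utils::combn(seq_along(grp), 2)
    for (pp in seq_len(ncol(pairs))) {
      i <- pairs[1, pp]; j <- pairs[2, pp]
      sym <- length(union(dels[[i]], dels[[j]])) -
        length(intersect(dels[[i]], dels[[j]]))
      one_gene_edit <- (sym == 1 && abs(sizes[i] - sizes[j]) == 1) ||
        (sym == 2 && sizes[i] == sizes[j])
      if (!one_gene_edit) next
      involves_double <- max(sizes[i], sizes[j]) == 2
      if (double != involves_double) next
      a <- df$cluster[grp[i]]; b <- df$cluster[grp[j]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = if (double) "DGD" else "SGD",
        from = min(a, b), to = max(a, b), count = 1L)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.fs_transition_network <- function(x, ...) {
  cat("<fs_transition_network>", nrow(x$nodes), "nodes,",
      nrow(x$edges), "typed edges\n  pairs per type:",
      paste(names(x$type_totals), x$type_totals, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Filter low-frequency edges
#'
#' Drops edges whose within-type relative frequency falls below the
#' threshold (1% in the published networks). The node set is unchanged;
#' the nonviable node 0 stays in the counts but is conventionally dropped
#' at export.
#'
#' @param network An `fs_transition_network`.
#' @param min_relative_frequency Threshold on `rel_freq`.
#' @return The filtered network.
#' @export
filter_edges <- function(network, min_relative_frequency = 0.01) {
  network$edges <- network$edges[network$edges$rel_freq >=
                                   min_relative_frequency |
                                   min_relative_frequency == 0, ]
  network
}

#' Relative perturbation influence on phenotype change
#'
#' For each perturbation type, the fraction of its evaluated pairs that
#' change cluster, normalized across types so influences sum to 1.
#'
#' @param network An `fs_transition_network`.
#' @return A tibble: `type`, `pairs`, `changed`, `change_fraction`,
#'   `influence`. Types with zero evaluated pairs report `NA`.
#' @export
perturbation_influence <- function(network) {
  e <- network$edges
  per_type <- purrr::map_dfr(PERTURBATION_TYPES, function(ty) {
    sub <- e[e$type == ty, ]
    total <- unname(network$type_totals[ty])
    if (is.na(total) || is.null(total) || total == 0) {
      return(tibble::tibble(type = ty, pairs = 0L, changed = 0L,
                            change_fraction = NA_real_))
    }
    changed <- sum(sub$count[sub$from != sub$to])
    tibble::tibble(type = ty, pairs = as.integer(total),
                   changed = as.integer(changed),
                   change_fraction = changed / total)
  })
  denom <- sum(per_type$change_fraction, na.rm = TRUE)
  per_type$influence <- if (denom > 0) {
    per_type$change_fraction / denom
  } else ifelse(is.na(per_type$change_fraction), NA_real_, 0)
  per_type
}

#' Export a transition network as GraphML
#'
#' Writes typed edges (attributes `type`, `count`, `rel_freq`) and node
#' sizes; by default the nonviable node 0 is dropped, matching the
#' published rendering convention.
#'
#' @param network An `fs_transition_network`.
#' @param path Output `.graphml` path.
#' @param drop_nonviable Exclude node 0 and its edges.
#' @return `path`, invisibly.
#' @export
write_transition_graphml <- function(network, path, drop_nonviable = TRUE) {
  edges <- network$edges
  nodes <- network$nodes
  if (drop_nonviable) {
    edges <- edges[edges$from != 0 & edges$to != 0, ]
    nodes <- nodes[nodes$cluster != 0, ]
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from),
                   to = as.character(edges$to),
                   type = edges$type, count = edges$count,
                   rel_freq = edges$rel_freq),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$cluster),
                          size = nodes$size))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export edges as a typed edge-list TSV
#' @inheritParams write_transition_graphml
#' @export
write_transition_edges <- function(network, path, drop_nonviable = FALSE) {
  edges <- network$edges
  if (drop_nonviable) edges <- edges[edges$from != 0 & edges$to != 0, ]
  readr::write_tsv(edges, path)
  invisible(path)
}
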