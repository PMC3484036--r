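# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy meta-phenotype assignments
#' @param x An `fs_meta_phenotypes`.
#' @param ... Unused.
#' @return A tibble: `design_id` (when available), `cluster`.
#' @method tidy fs_meta_phenotypes
#' @export
tidy.fs_meta_phenotypes <- function(x, ...) {
  tibble::tibble(
    design_id = x$design_id %||% seq_along(x$assignments),
    cluster = unname(x$assignments)
  )
}

#' One-row clustering summary
#' @param x An `fs_meta_phenotypes`.
#' @param ... Unused.
#' @return A tibble: `k`, `n`, `E`, `largest_cluster_share`.
#' @method glance fs_meta_phenotypes
#' @export
glance.fs_meta_phenotypes <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = length(x$assignments),
    E = x$E,
    largest_cluster_share = max(x$cluster_sizes) / sum(x$cluster_sizes)
  )
}

#' Phenotypic map of meta-phenotype centroids
#'
#' Heatmap of centroid z-scores (traits by meta-phenotype), the condensed
#' global view of dominant phenotypic characteristics.
#'
#' @param object An `fs_meta_phenotypes`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_meta_phenotypes
#' @export
autoplot.fs_meta_phenotypes <- function(object, ...) {
  ct <- tibble::as_tibble(object$centroids)
  ct$cluster <- factor(seq_len(object$k))
  long <- tidyr::pivot_longer(ct, -"cluster",
                              names_to = "trait", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cluster, y = .data$trait,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "meta-phenotype", y = NULL, fill = "z-score") +
    ggplot2::theme_minimal()
}

#' Tidy a Pareto front
#' @param x An `fs_pareto_front`.
#' @param ... Unused.
#' @return All evaluated points with their `nondominated` flag.
#' @method tidy fs_pareto_front
#' @export
tidy.fs_pareto_front <- function(x, ...) x$points

#' One-row Pareto summary
#' @param x An `fs_pareto_front`.
#' @param ... Unused.
#' @method glance fs_pareto_front
#' @export
glance.fs_pareto_front <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points),
    n_nondominated = nrow(x$frontier),
    goals = paste(x$goals$metric, collapse = " / ")
  )
}

#' Candidate cloud and Pareto frontier for the first two goals
#' @param object An `fs_pareto_front`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_pareto_front
#' @export
autoplot.fs_pareto_front <- function(object, ...) {
  gx <- object$goals$metric[min(2, nrow(object$goals))]
  gy <- object$goals$metric[1]
  frontier <- object$frontier[order(object$frontier[[gx]]), ]
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data[[gx]], y = .data[[gy]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$nondominated),
                        alpha = 0.6) +
    ggplot2::geom_line(data = frontier, colour = "#b2182b") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "#b2182b")) +
    ggplot2::labs(colour = "Pareto optimal") +
    ggplot2::theme_minimal()
}

#' Tidy transition-network edges
#' @param x An `fs_transition_network`.
#' @param ... Unused.
#' @method tidy fs_transition_network
#' @export
tidy.fs_transition_network <- function(x, ...) x$edges

#' One-row transition-network summary
#' @param x An `fs_transition_network`.
#' @param ... Unused.
#' @method glance fs_transition_network
#' @export
glance.fs_transition_network <- function(x, ...) {
  infl <- perturbation_influence(x)
  top <- infl$type[which.max(infl$influence)]
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    pairs_evaluated = sum(x$type_totals),
    top_influence_type = top
  )
}

#' Per-type perturbation influence bars
#' @param object An `fs_transition_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_transition_network
#' @export
autoplot.fs_transition_network <- function(object, ...) {
  infl <- perturbation_influence(object)
  infl$type <- factor(infl$type, levels = PERTURBATION_TYPES)
  ggplot2::ggplot(infl, ggplot2::aes(x = .data$type, y = .data$influence)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "perturbation type", y = "relative influence") +
    ggplot2::theme_minimal()
}

#' Tidy a correlation map into long format
#' @param x An `fs_correlation_map`.
#' @param ... Unused.
#' @return A tibble: `trait1`, `trait2`, `r` (leaf order preserved).
#' @method tidy fs_correlation_map
#' @export
tidy.fs_correlation_map <- function(x, ...) {
  r <- x$correlation
  long <- tibble::as_tibble(as.table(r), .name_repair = "minimal")
  names(long) <- c("trait1", "trait2", "r")
  long$trait1 <- factor(long$trait1, levels = x$order)
  long$trait2 <- factor(long$trait2, levels = x$order)
  long
}

#' Hierarchically ordered trait correlation heatmap
#' @param object An `fs_correlation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fs_correlation_map
#' @export
autoplot.fs_correlation_map <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait1, y = .data$trait2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' @importFrom rlang .data
NULL
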