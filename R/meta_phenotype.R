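# Meta-phenotypes: k-means clustering of z-scored engineering trait
# vectors, gap-statistic selection of k, cluster heterogeneities, and
# correlation maps between traits or meta-phenotypes.

#' Row-wise z-score transform
#'
#' Standardizes each row (trait) to mean 0 and standard deviation 1
#' (population or sample sd). Constant rows map to all zeros and are
#' recorded in the `"constant_rows"` attribute; the `"center"`/`"scale"`
#' attributes allow the inverse transform.
#'
#' @param mat A numeric matrix (traits in rows, observations in columns).
#' @param population Use the population standard deviation (divide by n).
#' @return The transformed matrix with attributes `center`, `scale`,
#'   `constant_rows`.
#' @export
zscore_rows <- function(mat, population = TRUE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  ctr <- rowMeans(mat)
  dev <- mat - ctr
  sd_row <- sqrt(rowSums(dev^2) / (ncol(mat) - if (population) 0 else 1))
  constant <- sd_row <= 1e-12
  scl <- ifelse(constant, 1, sd_row)
  out <- dev / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "constant_rows") <- rownames(mat)[constant] %||% which(constant)
  out
}

#' Invert a row-wise z-score transform
#' @param zmat A matrix from [zscore_rows()].
#' @return The original-scale matrix.
#' @export
unzscore_rows <- function(zmat) {
  zmat * attr(zmat, "scale") + attr(zmat, "center")
}

#' K-means meta-phenotype clustering
#'
#' Lloyd-type k-means with `n_seeds` random restarts and up to `max_iter`
#' iterations, keeping the restart with the lowest within-cluster
#' square-error `E = sum_i sum_{x in C_i} ||x - m_i||^2 / n`. Empty
#' clusters are handled by re-seeding (a fresh restart).
#'
#' @param x Observations-by-features numeric matrix (typically z-scored
#'   traits; use `t()` when starting from a traits-by-designs matrix).
#' @param k Number of clusters.
#' @param n_seeds Random restarts (10, matching the screening protocol).
#' @param max_iter Iteration cap per restart (100).
#' @param rng_seed Seed making the clustering reproducible.
#' @return An `fs_meta_phenotypes` object: `k`, `centroids`, `assignments`,
#'   `cluster_sizes`, `cluster_sse`, `heterogeneity` (SSE normalized by the
#'   maximum cluster SSE), and `E`.
#' @export
kmeans_cluster <- function(x, k, n_seeds = 10, max_iter = 100, rng_seed = 1L) {
  stopifnot(k >= 1, k <= nrow(x))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(rng_seed)
  if (k == nrow(x)) {
    # degenerate case: every observation is its own centroid, E = 0
    return(structure(list(
      k = k, centroids = x, assignments = seq_len(k),
      cluster_sizes = rep(1L, k), cluster_sse = rep(0, k),
      heterogeneity = rep(0, k), E = 0
    ), class = "fs_meta_phenotypes"))
  }
  fit <- NULL
  for (attempt in 1:20) {
    fit <- tryCatch(
      stats::kmeans(x, centers = k, nstart = n_seeds, iter.max = max_iter),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("k-means failed to converge for k = ", k, call. = FALSE)
  sse <- fit$withinss
  structure(list(
    k = k,
    centroids = fit$centers,
    assignments = fit$cluster,
    cluster_sizes = as.integer(fit$size),
    cluster_sse = sse,
    heterogeneity = if (max(sse) > 0) sse / max(sse) else rep(0, k),
    E = fit$tot.withinss / nrow(x)
  ), class = "fs_meta_phenotypes")
}

#' @export
print.fs_meta_phenotypes <- function(x, ...) {
  cat("<fs_meta_phenotypes> k =", x$k,
      " n =", length(x$assignments),
      " E =", format(x$E, digits = 5), "\n",
      " cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of meta-phenotypes with the gap statistic
#'
#' Compares the observed within-cluster dispersion to that of `B` uniform
#' reference samples over the per-feature data range. Two selection rules
#' are available: the one-standard-error rule (smallest k with
#' `gap(k) >= gap(k+1) - s(k+1)`) and the global gap maximum.
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest k considered.
#' @param B Reference samples (>= 10).
#' @param rule `"firstSEmax"` (one-standard-error) or `"globalmax"`.
#' @return The chosen `k`, with the full gap table as attribute
#'   `"gap_table"` (tibble: k, logW, E_logW, gap, SE_sim) and the gap at
#'   `k - 1` / `k + 1` as attribute `"robustness"`.
#' @export
select_k_gap <- function(x, k_max = 8, B = 50, rng_seed = 1L,
                         rule = c("firstSEmax", "globalmax"),
                         n_seeds = 10, max_iter = 100) {
  rule <- match.arg(rule)
  stopifnot(k_max >= 1, B >= 10)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(rng_seed)
  k_max <- min(k_max, nrow(x) - 1L)
  gap <- cluster::clusGap(
    x,
    FUNcluster = function(xx, k) {
      list(cluster = kmeans_cluster(xx, k, n_seeds = n_seeds,
                                    max_iter = max_iter,
                                    rng_seed = sample.int(1e6, 1))$assignments)
    },
    K.max = k_max, B = B, verbose = FALSE)
  tab <- gap$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                      method = if (rule == "firstSEmax") "Tibs2001SEmax"
                               else "globalmax")
  out <- k
  attr(out, "gap_table") <- tibble::tibble(
    k = seq_len(nrow(tab)), logW = tab[, "logW"], E_logW = tab[, "E.logW"],
    gap = tab[, "gap"], SE_sim = tab[, "SE.sim"])
  attr(out, "robustness") <- c(
    gap_km1 = if (k > 1) tab[k - 1, "gap"] else NA_real_,
    gap_k = tab[k, "gap"],
    gap_kp1 = if (k < nrow(tab)) tab[k + 1, "gap"] else NA_real_)
  out
}

#' Cluster a phenotype table into meta-phenotypes
#'
#' The tidy entry point: takes the screened phenotype tibble, z-scores the
#' trait columns, optionally restricts to the economic subset
#' (`economics_available`), selects k by the gap statistic when not given,
#' and runs best-of-seeds k-means.
#'
#' @param phenotypes Tibble from [screen_designs()].
#' @param traits Trait columns to use; defaults to every numeric metric
#'   column present.
#' @param k Number of clusters, or `NULL` to select via [select_k_gap()].
#' @param economic_subset Keep only rows with `economics_available = TRUE`
#'   and drop all-`NA` trait columns.
#' @param k_max,B,rng_seed,n_seeds,max_iter Passed through to the
#'   clustering and gap machinery.
#' @return An `fs_meta_phenotypes` with extra elements `design_id`,
#'   `traits`, `zscore_center`, `zscore_scale` and (when selected) the gap
#'   table.
#' @export
cluster_phenotypes <- function(phenotypes, traits = NULL, k = NULL,
                               economic_subset = TRUE, k_max = 8, B = 50,
                               rng_seed = 1L, n_seeds = 10, max_iter = 100) {
  df <- phenotypes
  if (economic_subset && "economics_available" %in% names(df)) {
    df <- df[df$economics_available, ]
  }
  if (is.null(traits)) {
    candidates <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          c("design_id"))
    traits <- candidates[colSums(!is.na(df[candidates])) == nrow(df)]
  }
  if (nrow(df) < 2) stop("need at least two phenotypes to cluster", call. = FALSE)
  mat <- t(as.matrix(df[, traits])) # traits x designs
  z <- zscore_rows(mat)
  x <- t(z) # designs x traits for k-means
  gap_table <- NULL
  if (is.null(k)) {
    k <- select_k_gap(x, k_max = k_max, B = B, rng_seed = rng_seed,
                      n_seeds = n_seeds, max_iter = max_iter)
    gap_table <- attr(k, "gap_table")
    k <- as.integer(k)
  }
  fit <- kmeans_cluster(x, k, n_seeds = n_seeds, max_iter = max_iter,
                        rng_seed = rng_seed)
  fit$design_id <- df$design_id
  fit$traits <- traits
  fit$zscore_center <- attr(z, "center")
  fit$zscore_scale <- attr(z, "scale")
  fit$gap_table <- gap_table
  fit
}

#' Pearson correlation map with hierarchical ordering
#'
#' Correlations between all trait pairs (columns of `x`), with rows and
#' columns ordered by average-linkage hierarchical clustering on the
#' `1 - |r|` distance. Zero-variance traits are reported in the
#' `"dropped"` attribute and omitted.
#'
#' @param x Observations-by-traits matrix or data frame.
#' @return An `fs_correlation_map`: list with `correlation` (symmetric,
#'   unit diagonal, leaf-ordered), `order`, `hclust` and `dropped`.
#' @export
correlation_map <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least three observations", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[is.na(sds) | sds <= 1e-12]
  keep <- setdiff(colnames(x), dropped)
  r <- stats::cor(x[, keep, drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = "average")
  ord <- hc$order
  structure(list(correlation = r[ord, ord, drop = FALSE],
                 order = colnames(r)[ord], hclust = hc, dropped = dropped),
            class = "fs_correlation_map")
}

#' @export
print.fs_correlation_map <- function(x, ...) {
  cat("<fs_correlation_map>", ncol(x$correlation), "traits")
  if (length(x$dropped)) cat(" (", length(x$dropped), "dropped: zero variance)")
  cat("\n")
  invisible(x)
}

#' Count strongly correlated trait pairs
#' @param map An `fs_correlation_map`.
#' @param threshold Absolute correlation threshold.
#' @return Number of off-diagonal pairs with `|r| > threshold`.
#' @export
strong_pairs <- function(map, threshold = 0.8) {
  r <- map$correlation
  sum(abs(r[upper.tri(r)]) > threshold)
}
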