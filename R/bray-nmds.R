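# Community ordination: fourth-root Bray-Curtis, nMDS, environment vectors.

#' Bray-Curtis dissimilarity on fourth-root transformed counts
#'
#' The fourth-root transform down-weights the most abundant species before
#' computing \eqn{BC(a,b) = \sum|x_a - x_b| / \sum(x_a + x_b)}. Transects
#' with no individuals are excluded with a warning (their dissimilarity is
#' undefined).
#'
#' @param counts transects x species count matrix (or `community_matrix`).
#' @return a `dist` object over the retained transects, values in `[0, 1]`.
#' @export
fourth_root_bray_curtis <- function(counts) {
  if (inherits(counts, "community_matrix")) counts <- community_counts(counts)
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning(sum(empty), " all-zero transect(s) excluded from the dissimilarity")
    m <- m[!empty, , drop = FALSE]
  }
  vegan::vegdist(m^0.25, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 minimisation (monotone regression of configuration
#' distances on dissimilarities) via `vegan::metaMDS` with random restarts;
#' the best configuration and its final stress are returned.
#'
#' @param d `dist` of dissimilarities.
#' @param k ordination dimensionality.
#' @param restarts number of random starts.
#' @param max_iter maximum iterations per start.
#' @param seed integer seed.
#' @param outlier_sd if non-`NULL`, points farther than this many robust
#'   standard deviations from the ordination centroid are flagged (and
#'   reported), mirroring the practice of removing extreme transects from
#'   ordination plots. No points are dropped; flags are returned.
#' @return list: `points` (n x k), `stress`, `converged`, `outlier` flags.
#' @export
nmds_ordination <- function(d, k = 2, restarts = 20, max_iter = 200, seed = 1L,
                            outlier_sd = NULL) {
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = restarts, trymax = restarts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  pts <- fit$points
  out <- rep(FALSE, nrow(pts))
  if (!is.null(outlier_sd)) {
    ctr <- apply(pts, 2, stats::median)
    dev <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    out <- dev > outlier_sd * stats::mad(dev)
    if (any(out)) message(sum(out), " ordination outlier(s) flagged")
  }
  list(points = pts, stress = fit$stress, converged = fit$converged > 0,
       outlier = out)
}

#' Fit environmental vectors onto an ordination
#'
#' Least-squares projection of each environmental variable onto the
#' ordination axes (`vegan::envfit`), with permutation p-values.
#'
#' @param ordination result of [nmds_ordination()] (or any matrix of
#'   ordination scores).
#' @param env data.frame of numeric environment variables, rows aligned
#'   with the ordination points.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame: `variable`, axis direction columns, `r2`, `p_value`.
#' @export
fit_environment_vectors <- function(ordination, env, n_perm = 999, seed = 1L) {
  pts <- if (is.list(ordination) && !is.null(ordination$points)) {
    ordination$points
  } else {
    as.matrix(ordination)
  }
  stopifnot(nrow(pts) == nrow(env))
  set.seed(seed)
  ef <- vegan::envfit(pts, env, permutations = n_perm)
  arr <- ef$vectors$arrows
  data.frame(variable = rownames(arr), arr,
             r2 = ef$vectors$r, p_value = ef$vectors$pvals,
             row.names = NULL, check.names = FALSE)
}
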