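# Negative-binomial GLMs and the multivariate deviance test with PIT-trap
# resampling.

#' Fit a negative-binomial GLM (log link)
#'
#' NB2 regression (Var = mu + mu^2/theta) by iteratively reweighted least
#' squares, with the dispersion theta estimated by maximum-likelihood
#' profiling between IRLS passes. The same core drives the multivariate
#' deviance test, so single fits are directly comparable to its per-species
#' components.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix (or a one-sided formula plus `data`).
#' @param data data.frame used when `X` is a formula.
#' @return list: `coefficients` (named), `theta`, `loglik`, `fitted`, `ok`
#'   (`FALSE` flags a degenerate all-zero response, which callers exclude).
#' @export
fit_nb_glm <- function(y, X = ~1, data = NULL) {
  if (inherits(X, "formula")) {
    X <- stats::model.matrix(X, data = data %||% parent.frame())
  }
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient design: aliased columns dropped")
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  }
  f <- .nb_fit_cpp(as.numeric(y), X)
  names(f$coefficients) <- colnames(X)
  f
}

#' Multivariate NB deviance test with PIT-trap resampling
#'
#' Sequential (Type-I) analysis of deviance for a community matrix: species
#' are modelled by separate negative-binomial GLMs over a common design, and
#' each term's statistic is the sum across species of the likelihood-ratio
#' statistics between the nested fits with and without the term.
#' P-values come from the PIT-trap bootstrap: probability-integral-transform
#' residuals are computed under the smaller model, whole transect rows are
#' resampled with replacement (preserving cross-species correlation),
#' pseudo-counts are reconstructed through the null inverse CDFs, and the
#' statistic is recomputed `n_boot` times;
#' `p = (1 + #\{boot >= observed\}) / (n_boot + 1)`.
#'
#' @param counts transects x species count matrix (or `community_matrix`).
#' @param design data.frame of factors aligned with the rows of `counts`.
#' @param formula model formula over `design` columns; terms are tested in
#'   the order returned by [stats::terms()] (main effects first, then
#'   interactions of increasing order).
#' @param n_boot bootstrap resamples per term.
#' @param seed integer seed (required; the bootstrap is stochastic).
#' @return data.frame: `term`, `res_df` (residual df after adding the
#'   term), `deviance` (sum-of-LR statistic), `p_value`; `n_boot` and
#'   `seed` in attributes.
#' @export
multivariate_deviance_test <- function(counts, design,
                                       formula = ~ zone * year * season * site,
                                       n_boot = 999, seed) {
  if (missing(seed)) stop("seed is required")
  if (inherits(counts, "community_matrix")) counts <- community_counts(counts)
  Y <- as.matrix(counts)
  stopifnot(nrow(Y) == nrow(design))

  # drop single-level factors (and any term touching them) with a warning
  vars <- all.vars(formula)
  for (v in vars) {
    if (length(unique(design[[v]])) < 2) {
      warning("factor '", v, "' has a single level and is dropped")
      formula <- stats::update(formula, paste("~ . -", v, "- .:", v))
    }
  }
  trm <- stats::terms(formula, data = design)
  labels <- attr(trm, "term.labels")
  mm <- stats::model.matrix(formula, data = design)
  asg <- attr(mm, "assign")
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    keep <- qr_$pivot[seq_len(qr_$rank)]
    warning("rank-deficient design: ", ncol(mm) - qr_$rank, " aliased column(s) dropped")
    mm <- mm[, sort(keep), drop = FALSE]
    asg <- asg[sort(keep)]
  }

  set.seed(seed)
  res <- lapply(seq_along(labels), function(k) {
    X0 <- mm[, asg < k, drop = FALSE]
    X1 <- mm[, asg <= k, drop = FALSE]
    if (ncol(X1) == ncol(X0)) {
      return(data.frame(term = labels[k], res_df = nrow(Y) - ncol(X1),
                        deviance = 0, p_value = NA_real_))
    }
    pt <- .pit_trap_cpp(Y, X0, X1, n_boot)
    data.frame(term = labels[k],
               res_df = nrow(Y) - ncol(X1),
               deviance = pt$observed,
               p_value = (1 + sum(pt$boot >= pt$observed)) / (n_boot + 1))
  })
  out <- do.call(rbind, res)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
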