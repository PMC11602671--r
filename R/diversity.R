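# Hill numbers (taxonomic and attribute/functional), taxonomic distinctness
# and its permutation funnel.

#' Taxonomic Hill number of order q
#'
#' Effective number of species: `q = 0` is species richness, `q = 1` the
#' exponential of Shannon entropy, general `q` is
#' \eqn{(\sum_i p_i^q)^{1/(1-q)}} over positive relative abundances.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @param q diversity order (scalar, >= 0).
#' @return effective number of species.
#' @export
hill_taxonomic <- function(x, q = 0) {
  if (any(x < 0) || !any(x > 0)) stop("abundances must be >= 0 with at least one > 0")
  p <- x[x > 0] / sum(x)
  if (q == 0) return(as.numeric(length(p)))
  if (abs(q - 1) < 1e-12) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Functional (attribute-diversity) Hill number of order q
#'
#' Hill number over functional entities with pairwise distances truncated at
#' a threshold `tau`: entities closer than `tau` partially pool their
#' abundances. With \eqn{a_i = \sum_j (1 - \min(d_{ij}, \tau)/\tau)\, p_j}
#' and \eqn{v_i = p_i / a_i}, the order-q attribute diversity is
#' \eqn{\sum_i v_i} for `q = 0`, \eqn{\exp(-\sum_i v_i a_i \log a_i)} for
#' `q = 1`, and \eqn{(\sum_i v_i a_i^q)^{1/(1-q)}} otherwise. When every
#' pair is at least `tau` apart this reduces to the taxonomic Hill number;
#' when all distances are zero it is 1 (one effective entity).
#'
#' @param x non-negative abundance vector over entities (named or aligned
#'   with `dmat` rows).
#' @param dmat symmetric pairwise distance matrix between entities.
#' @param q diversity order.
#' @param tau truncation threshold (> 0); `"mean"` (default) uses the mean
#'   nonzero pairwise distance in `dmat`, `"max"` the maximum.
#' @return effective number of functional entities.
#' @export
hill_functional <- function(x, dmat, q = 0, tau = "mean") {
  dmat <- as.matrix(dmat)
  if (is.character(tau)) {
    off <- dmat[upper.tri(dmat)]
    tau <- switch(match.arg(tau, c("mean", "max")),
                  mean = mean(off[off > 0]),
                  max = max(off))
    if (!is.finite(tau) || tau <= 0) tau <- 1 # all-zero distances: any tau works
  }
  if (tau <= 0) stop("tau must be > 0")
  if (any(x < 0) || !any(x > 0)) stop("abundances must be >= 0 with at least one > 0")
  keep <- x > 0
  if (!is.null(names(x)) && !is.null(rownames(dmat))) {
    dmat <- dmat[names(x), names(x), drop = FALSE]
  }
  p <- x[keep] / sum(x)
  dd <- pmin(dmat[keep, keep, drop = FALSE], tau)
  a <- as.vector((1 - dd / tau) %*% p)
  v <- p / a
  if (q == 0) return(sum(v[a > 0]))
  if (abs(q - 1) < 1e-12) return(exp(-sum(v * a * log(a))))
  sum(v * a^q)^(1 / (1 - q))
}

# Pairwise Linnaean path lengths: omega = level index (genus = 1 ...
# superclass = 6) of the lowest shared rank, 6 when none is shared.
.omega_matrix <- function(taxonomy) {
  lv <- .taxonomy_levels
  n <- nrow(taxonomy)
  omega <- matrix(length(lv), n, n,
                  dimnames = list(taxonomy$species, taxonomy$species))
  for (k in rev(seq_along(lv))) {
    same <- outer(taxonomy[[lv[k]]], taxonomy[[lv[k]]], `==`)
    omega[same] <- k
  }
  diag(omega) <- 0
  omega
}

#' Abundance-weighted taxonomic distinctness (Delta*)
#'
#' Mean Linnaean path length between individuals of *different* species:
#' \deqn{\Delta^* = \frac{\sum_{i<j} \omega_{ij} x_i x_j}
#'                       {\sum_{i<j} x_i x_j}}
#' where \eqn{\omega_{ij}} counts the steps to the lowest taxonomic rank
#' shared by species i and j (1 = same genus, ..., 6 = sharing at most the
#' superclass), rescaled so the maximum possible path equals 100.
#'
#' @param x named non-negative abundance vector (names = species); at least
#'   two species must be present.
#' @param taxonomy data.frame with `species` and the six rank columns
#'   (`genus`, `family`, `order`, `subclass`, `class`, `superclass`).
#' @return Delta* in `[0, 100]`; flagged `NA` for single-species
#'   assemblages.
#' @export
taxonomic_distinctness <- function(x, taxonomy) {
  x <- x[x > 0]
  if (length(x) < 2) return(structure(NA_real_, singleton = TRUE))
  miss <- setdiff(names(x), taxonomy$species)
  if (length(miss)) stop("species missing from taxonomy: ", paste(miss, collapse = ", "))
  tax <- taxonomy[match(names(x), taxonomy$species), ]
  omega <- .omega_matrix(tax) * (100 / length(.taxonomy_levels))
  xx <- outer(x, x)
  ut <- upper.tri(xx)
  sum(omega[ut] * xx[ut]) / sum(xx[ut])
}

#' Expected Delta* funnel by subsample size
#'
#' For each subsample size `m`, draws `n_draws` random subsets (without
#' replacement) from the master species list, computes Delta* with equal
#' abundances, and returns the mean and the 2.5/97.5 percentiles — the 95%
#' simulation envelope against which observed per-transect values are
#' judged. The null carries no abundance structure; observed values below
#' the lower envelope indicate assemblages more closely related than
#' expected by chance.
#'
#' @param taxonomy master taxonomy table (all species in the pool).
#' @param sizes integer vector of subsample sizes (each in `[2, pool]`).
#' @param n_draws random subsets per size.
#' @param seed integer seed.
#' @return data.frame: `m`, `mean`, `lower`, `upper`.
#' @export
distinctness_funnel <- function(taxonomy, sizes, n_draws = 999, seed = 1L) {
  pool <- taxonomy$species
  if (any(sizes < 2) || any(sizes > length(pool))) {
    stop("sizes must lie in [2, pool size]")
  }
  omega_full <- .omega_matrix(taxonomy) * (100 / length(.taxonomy_levels))
  with_seed(derive_seed(seed, "funnel"), {
    res <- lapply(sizes, function(m) {
      vals <- vapply(seq_len(n_draws), function(b) {
        ix <- sample.int(length(pool), m)
        om <- omega_full[ix, ix]
        mean(om[upper.tri(om)])
      }, numeric(1))
      data.frame(m = m, mean = mean(vals),
                 lower = stats::quantile(vals, 0.025, names = FALSE),
                 upper = stats::quantile(vals, 0.975, names = FALSE))
    })
    do.call(rbind, res)
  })
}

#' Per-transect diversity profiles
#'
#' Assembles the full per-transect profile: S, N, taxonomic Hill numbers
#' (q = 0, 1), functional Hill numbers over FEs (q = 0, 1; tau-truncated
#' Gower distances), the convex-hull indices from
#' [transect_functional_indices()], and Delta*.
#'
#' @param cm a `community_matrix`.
#' @param traits species x trait table.
#' @param taxonomy species taxonomy table.
#' @param axes functional-space dimensionality for FRic/FOri/FDiv.
#' @param tau truncation threshold for functional Hill numbers (`"mean"`,
#'   `"max"` or a positive number).
#' @param min_richness S threshold below which convex-hull indices are not
#'   attempted (the trait count, 6).
#' @param scheme trait scheme.
#' @return data.frame with one row per transect and the transect metadata;
#'   `tau` used is stored in `attr(, "tau")`.
#' @export
diversity_profiles <- function(cm, traits, taxonomy, axes = 4, tau = "mean",
                               min_richness = 6, scheme = trait_scheme()) {
  counts <- community_counts(cm)
  ent <- encode_functional_entities(traits, abundances = counts, scheme = scheme)
  feD <- gower_distance(ent$fe_traits, scheme = scheme)
  if (is.character(tau)) {
    off <- feD[upper.tri(feD)]
    tau <- if (tau == "max") max(off) else mean(off[off > 0])
  }
  feA <- ent$fe_abundance

  prof <- data.frame(
    transect_id = cm$transect_id, site = cm$site, stratum = cm$stratum,
    season = cm$season, year = cm$year, S = cm$S, N = cm$N,
    stringsAsFactors = FALSE
  )
  prof$tax_hill_q0 <- apply(counts, 1, function(x) if (any(x > 0)) hill_taxonomic(x, 0) else NA)
  prof$tax_hill_q1 <- apply(counts, 1, function(x) if (any(x > 0)) hill_taxonomic(x, 1) else NA)
  prof$func_hill_q0 <- apply(feA, 1, function(x) {
    if (any(x > 0)) hill_functional(x, feD, 0, tau) else NA
  })
  prof$func_hill_q1 <- apply(feA, 1, function(x) {
    if (any(x > 0)) hill_functional(x, feD, 1, tau) else NA
  })
  prof$delta_star <- apply(counts, 1, function(x) {
    as.numeric(taxonomic_distinctness(x, taxonomy))
  })

  rich <- cm[cm$S >= min_richness, , drop = FALSE]
  attr(rich, "species") <- attr(cm, "species")
  class(rich) <- class(cm)
  fi <- transect_functional_indices(rich, traits, axes = axes, scheme = scheme)
  prof$n_fe <- prof$fric <- prof$fori <- prof$fdiv <- NA_real_
  ix <- match(fi$transect_id, prof$transect_id)
  prof$n_fe[ix] <- fi$n_fe
  prof$fric[ix] <- fi$fric
  prof$fori[ix] <- fi$fori
  prof$fdiv[ix] <- fi$fdiv
  attr(prof, "tau") <- tau
  attr(prof, "space") <- attr(fi, "space")
  prof
}
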