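# Functional entities, Gower distance, PCoA functional space and the
# convex-hull indices FRic, FOri, FDiv.

.check_traits <- function(traits, scheme) {
  stopifnot(is.data.frame(traits), "species" %in% names(traits))
  for (tr in names(scheme)) {
    if (is.null(traits[[tr]])) stop("trait table lacks trait: ", tr)
    bad <- is.na(traits[[tr]]) | !traits[[tr]] %in% scheme[[tr]]$levels
    if (any(bad)) {
      stop("invalid/missing '", tr, "' for species: ",
           paste(utils::head(traits$species[bad], 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Collapse species into functional entities
#'
#' Species sharing the same category on all six traits form one functional
#' entity (FE), identified by an alphanumeric code concatenating the
#' category indices of the traits. When an abundance matrix is supplied, FE
#' weights (summed relative abundance per assemblage row) are returned.
#'
#' @param traits species x trait data.frame (columns of [trait_scheme()]
#'   plus `species`).
#' @param abundances optional transects x species matrix (column names =
#'   species) used to build FE weights.
#' @param scheme trait scheme; defaults to [trait_scheme()].
#' @return list with `fe` (data.frame: `fe`, `species`), `fe_traits` (one
#'   trait row per FE), and, when abundances are given, `fe_abundance`
#'   (transects x FE counts) and `fe_weights` (rows summing to 1; all-zero
#'   rows left at 0).
#' @export
encode_functional_entities <- function(traits, abundances = NULL,
                                       scheme = trait_scheme()) {
  .check_traits(traits, scheme)
  tags <- c("L", "M", "A", "G", "P", "D")[seq_along(scheme)]
  codes <- rep("", nrow(traits))
  for (i in seq_along(scheme)) {
    tr <- names(scheme)[i]
    codes <- paste0(codes, tags[i], match(traits[[tr]], scheme[[tr]]$levels))
  }
  fe <- data.frame(fe = codes, species = traits$species, stringsAsFactors = FALSE)
  fe_traits <- traits[!duplicated(codes), c("species", names(scheme))]
  fe_traits$species <- NULL
  fe_traits <- cbind(fe = codes[!duplicated(codes)], fe_traits)
  out <- list(fe = fe, fe_traits = fe_traits)
  if (!is.null(abundances)) {
    ab <- as.matrix(abundances)
    common <- intersect(colnames(ab), fe$species)
    if (!length(common)) stop("no abundance columns match trait species")
    map <- fe$fe[match(common, fe$species)]
    agg <- t(rowsum(t(ab[, common, drop = FALSE]), group = map))
    tot <- rowSums(agg)
    w <- agg
    pos <- tot > 0
    w[pos, ] <- agg[pos, , drop = FALSE] / tot[pos]
    out$fe_abundance <- agg
    out$fe_weights <- w
  }
  out
}

#' Gower distance between species (or FEs) from categorical traits
#'
#' Classic Gower coefficient with all traits equally weighted: for each
#' trait, nominal categories contribute 0/1 mismatch and ordinal categories
#' contribute the absolute rank difference divided by the trait's range
#' (levels - 1); the distance is the mean contribution over the six traits.
#' A trait with a single level in the scheme contributes 0 with a warning.
#'
#' @param traits data.frame with an id column (first column or `species`)
#'   and the trait columns.
#' @param scheme trait scheme; defaults to [trait_scheme()].
#' @return symmetric `dist`-convertible matrix with values in `[0, 1]` and
#'   zero diagonal, dimnames = the id column.
#' @export
gower_distance <- function(traits, scheme = trait_scheme()) {
  id_col <- if ("species" %in% names(traits)) "species" else
    if ("fe" %in% names(traits)) "fe" else names(traits)[1]
  ids <- traits[[id_col]]
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (tr in names(scheme)) {
    lv <- scheme[[tr]]$levels
    if (length(lv) < 2) {
      warning("trait '", tr, "' has a single level and contributes 0")
      next
    }
    r <- match(traits[[tr]], lv)
    if (anyNA(r)) stop("invalid category in trait '", tr, "'")
    if (scheme[[tr]]$ordered) {
      D <- D + abs(outer(r, r, `-`)) / (length(lv) - 1)
    } else {
      D <- D + (outer(r, r, `!=`)) * 1
    }
  }
  D / length(scheme)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: eigendecomposition of the double-centred
#' \eqn{-D^2/2} matrix. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues (possible for
#' non-Euclidean distances such as Gower on categories) are reported but
#' excluded from the coordinates and from explained-variance fractions.
#'
#' @param d symmetric distance matrix (zero diagonal) or `dist`.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are treated as zero.
#' @return a `functional_space` list: `coordinates` (n x k, positive axes
#'   ordered by decreasing eigenvalue), `eigenvalues` (all, sorted
#'   decreasing), `explained_variance` (cumulative fraction per axis count,
#'   over positive eigenvalues).
#' @export
pcoa_space <- function(d, tol = 1e-8) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- ev > tol * max(abs(ev))
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords,
         eigenvalues = ev,
         explained_variance = cumsum(ev[pos]) / sum(ev[pos])),
    class = "functional_space"
  )
}

#' Choose the number of functional-space axes
#'
#' Returns the configured number of axes (4 by default, following the
#' convention of keeping a low-dimensional space whose explained variance is
#' close to that of the next dimension), reduced with a warning when fewer
#' positive eigenvalues exist. The explained variance at `m` and `m + 1`
#' axes is reported via `message()`.
#'
#' @param space a `functional_space` from [pcoa_space()].
#' @param target_axes requested number of axes.
#' @return integer axis count.
#' @export
select_dimensionality <- function(space, target_axes = 4) {
  k <- ncol(space$coordinates)
  m <- min(target_axes, k)
  if (m < target_axes) {
    warning("only ", k, " positive axes available; using ", m)
  }
  ev <- space$explained_variance
  message(sprintf("explained variance: %.1f%% at %d axes%s", 100 * ev[m], m,
                  if (m < k) sprintf(", %.1f%% at %d axes", 100 * ev[m + 1], m + 1) else ""))
  m
}

#' Functional richness (FRic)
#'
#' Fraction of the pool's convex-hull volume occupied by the assemblage's
#' FEs in the reduced functional space. Assemblages whose FEs do not span
#' the space (fewer than axes + 1 affinely independent FEs) yield `NA` with
#' an attribute flag; callers exclude them downstream.
#'
#' @param present character vector (or logical/indices) of FEs present.
#' @param coords pool FE coordinates (FE x axes, rownames = FE codes).
#' @param pool_volume hull volume of the full pool in `coords` (computed
#'   when omitted).
#' @return numeric in `[0, 1]`, or flagged `NA` for degenerate assemblages.
#' @export
fric <- function(present, coords, pool_volume = NULL) {
  if (is.null(pool_volume)) pool_volume <- convex_hull_volume(coords)$volume
  sub <- coords[present, , drop = FALSE]
  if (!is_full_dimensional(sub)) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  convex_hull_volume(sub)$volume / pool_volume
}

#' Functional originality (FOri)
#'
#' Abundance-weighted mean isolation of the assemblage's FEs: each FE's
#' distance to its nearest neighbour in the *global pool*, weighted by the
#' FE's relative abundance and scaled by the maximum nearest-neighbour
#' distance in the pool, so the index lies in `[0, 1]`. Low values indicate
#' high redundancy (every abundant FE has a close functional substitute).
#'
#' @param weights named relative-abundance vector over the assemblage's FEs
#'   (sums to 1).
#' @param coords pool FE coordinates (rownames = FE codes).
#' @return numeric in `[0, 1]`; `NA` (flagged) for a single-FE pool or a
#'   pool of fully duplicated FEs.
#' @export
fori <- function(weights, coords) {
  if (nrow(coords) < 2) return(structure(NA_real_, degenerate = TRUE))
  dd <- as.matrix(stats::dist(coords))
  diag(dd) <- Inf
  dnn <- apply(dd, 1, min)
  mx <- max(dnn)
  if (mx == 0) return(0)
  w <- weights / sum(weights)
  sum(w * dnn[names(w)]) / mx
}

#' Functional divergence (FDiv)
#'
#' Measures whether abundant FEs lie far from the centre of the functional
#' space. Let G be the centroid of the assemblage's hull vertices, dG the
#' distances of the assemblage's FEs to G and \eqn{\bar d} their unweighted
#' mean; with abundance-weighted deviations
#' \eqn{\Delta d = \sum_i w_i (dG_i - \bar d)} and
#' \eqn{\Delta|d| = \sum_i w_i |dG_i - \bar d|},
#' \deqn{FDiv = (\Delta d + \bar d) / (\Delta|d| + \bar d).}
#'
#' @param weights named relative-abundance vector over assemblage FEs.
#' @param coords pool FE coordinates (rownames = FE codes).
#' @return numeric in `(0, 1]`; flagged `NA` when the assemblage hull is
#'   degenerate or all FEs coincide with G.
#' @export
fdiv <- function(weights, coords) {
  fes <- names(weights)
  sub <- coords[fes, , drop = FALSE]
  if (!is_full_dimensional(sub)) return(structure(NA_real_, degenerate = TRUE))
  hull <- convex_hull_volume(sub)
  G <- colMeans(sub[hull$vertices, , drop = FALSE])
  dG <- sqrt(rowSums(sweep(sub, 2, G)^2))
  dbar <- mean(dG)
  if (dbar == 0) return(structure(NA_real_, degenerate = TRUE))
  w <- weights / sum(weights)
  dd <- sum(w * (dG - dbar))
  dabs <- sum(w * abs(dG - dbar))
  (dd + dbar) / (dabs + dbar)
}

#' Build the pool functional space from a trait table
#'
#' Convenience wrapper chaining [encode_functional_entities()],
#' [gower_distance()] on FEs, [pcoa_space()] and [select_dimensionality()],
#' and computing the pool convex hull in the reduced space.
#'
#' @param traits species x trait table.
#' @param axes requested number of axes (default 4).
#' @param scheme trait scheme.
#' @return list: `entities` (FE encoding), `space` (full PCoA), `axes`,
#'   `coords` (FE x axes), `pool_hull` (volume + vertices).
#' @export
build_functional_space <- function(traits, axes = 4, scheme = trait_scheme()) {
  ent <- encode_functional_entities(traits, scheme = scheme)
  D <- gower_distance(ent$fe_traits, scheme = scheme)
  space <- pcoa_space(D)
  m <- select_dimensionality(space, axes)
  coords <- space$coordinates[, seq_len(m), drop = FALSE]
  list(entities = ent, space = space, axes = m, coords = coords,
       pool_hull = convex_hull_volume(coords))
}

#' Per-transect functional indices
#'
#' Computes FRic, FOri and FDiv for every row of a community matrix, using a
#' shared pool functional space built from the trait table. Transects whose
#' FEs are degenerate in the reduced space receive flagged `NA`s.
#'
#' @param cm a `community_matrix` (ideally pre-filtered with
#'   [functional_filter()]).
#' @param traits species x trait table covering the matrix's species.
#' @param axes functional-space dimensionality.
#' @param scheme trait scheme.
#' @return data.frame: `transect_id`, `n_fe`, `fric`, `fori`, `fdiv`,
#'   `degenerate` (logical); pool objects in attributes `space` and
#'   `entities`.
#' @export
transect_functional_indices <- function(cm, traits, axes = 4,
                                        scheme = trait_scheme()) {
  fsp <- build_functional_space(traits, axes = axes, scheme = scheme)
  counts <- community_counts(cm)
  ent <- encode_functional_entities(traits, abundances = counts, scheme = scheme)
  W <- ent$fe_weights
  coords <- fsp$coords
  res <- lapply(seq_len(nrow(W)), function(i) {
    w <- W[i, W[i, ] > 0]
    if (!length(w)) {
      return(data.frame(n_fe = 0L, fric = NA, fori = NA, fdiv = NA,
                        degenerate = TRUE))
    }
    fr <- fric(names(w), coords, fsp$pool_hull$volume)
    fo <- fori(w, coords)
    fd <- fdiv(w, coords)
    data.frame(n_fe = length(w), fric = as.numeric(fr), fori = as.numeric(fo),
               fdiv = as.numeric(fd),
               degenerate = isTRUE(attr(fr, "degenerate")) ||
                 isTRUE(attr(fd, "degenerate")))
  })
  out <- cbind(transect_id = rownames(W), do.call(rbind, res))
  rownames(out) <- NULL
  attr(out, "space") <- fsp
  attr(out, "entities") <- ent
  out
}
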