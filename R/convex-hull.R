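# Exact convex-hull volume in low dimension (beneath-beyond incremental
# algorithm). Used for the functional-richness index; written for small point
# clouds (tens of functional entities) in up to ~6 dimensions.

# Hyperplane through the d rows of P (d x d), oriented away from `inside`:
# returns list(n = unit normal, b = offset) with n . x <= b for interior x,
# or NULL when the points are affinely dependent (degenerate facet).
.facet_plane <- function(P, inside, tol) {
  d <- ncol(P)
  A <- t(P[-1, , drop = FALSE]) - P[1, ]   # d x (d-1)
  qr_ <- qr(A)
  if (qr_$rank < d - 1) return(NULL)
  n <- qr.Q(qr_, complete = TRUE)[, d]
  b <- sum(n * P[1, ])
  if (sum(n * inside) > b) { n <- -n; b <- -b }
  list(n = n, b = b)
}

# Greedy affinely-independent seed: d+1 point indices spanning d dimensions.
.initial_simplex <- function(pts, tol) {
  n <- nrow(pts); d <- ncol(pts)
  i0 <- which.max(pts[, 1])
  idx <- i0
  Q <- matrix(0, d, 0)
  for (k in seq_len(d)) {
    rel <- sweep(pts, 2, pts[i0, ])
    if (ncol(Q)) rel <- rel - rel %*% Q %*% t(Q)
    dist <- sqrt(rowSums(rel^2))
    j <- which.max(dist)
    if (dist[j] < tol) return(NULL)
    idx <- c(idx, j)
    v <- rel[j, ] / dist[j]
    Q <- cbind(Q, v)
  }
  idx
}

#' Convex-hull volume and vertices of a point cloud
#'
#' Computes the exact volume of the convex hull of `points` in its ambient
#' dimension, together with the identities of the hull vertices, using an
#' incremental (beneath-beyond) construction: facets visible from each new
#' point are replaced by the cone over their horizon ridges, and the volume
#' is accumulated as a fan of simplices around an interior point.
#'
#' @param points numeric matrix, one row per point, `m` columns (`m >= 1`).
#'   At least `m + 1` affinely independent rows are required.
#' @param tol numeric tolerance for visibility / degeneracy tests.
#' @return list with `volume` (non-negative number), `vertices` (row indices
#'   of hull vertices, sorted) and `nfacets`.
#' @examples
#' simplex <- rbind(0, diag(4)) # unit 4-simplex: volume 1/4! = 1/24
#' convex_hull_volume(simplex)$volume
#' @export
convex_hull_volume <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts); d <- ncol(pts)
  if (d < 1) stop("points must have at least one coordinate")
  if (n < d + 1) stop("degenerate point set: need at least ", d + 1, " points in ", d, "-D")
  if (d == 1) {
    r <- range(pts[, 1])
    return(list(volume = diff(r),
                vertices = sort(unique(c(which.min(pts[, 1]), which.max(pts[, 1])))),
                nfacets = 2L))
  }
  scale_ <- max(apply(pts, 2, function(x) diff(range(x))))
  if (scale_ <= 0) stop("degenerate point set: all points coincide")
  tol <- tol * max(1, scale_)

  seed <- .initial_simplex(pts, tol)
  if (is.null(seed)) stop("degenerate point set: points are affinely dependent")
  inside <- colMeans(pts[seed, , drop = FALSE])

  facets <- list()
  for (i in seq_along(seed)) {
    v <- seed[-i]
    pl <- .facet_plane(pts[v, , drop = FALSE], inside, tol)
    facets[[length(facets) + 1]] <- list(v = v, n = pl$n, b = pl$b)
  }

  for (p in setdiff(seq_len(n), seed)) {
    x <- pts[p, ]
    vis <- vapply(facets, function(f) sum(f$n * x) > f$b + tol, logical(1))
    if (!any(vis)) next
    # horizon ridges: (d-1)-faces belonging to exactly one visible facet
    ridges <- list()
    for (f in facets[vis]) {
      for (i in seq_len(d)) {
        r <- sort(f$v[-i])
        key <- paste(r, collapse = ",")
        ridges[[key]] <- if (is.null(ridges[[key]])) r else NA
      }
    }
    horizon <- Filter(function(r) !anyNA(r), ridges)
    facets <- facets[!vis]
    for (r in horizon) {
      v <- c(r, p)
      pl <- .facet_plane(pts[v, , drop = FALSE], inside, tol)
      if (is.null(pl)) next # numerically degenerate sliver
      facets[[length(facets) + 1]] <- list(v = v, n = pl$n, b = pl$b)
    }
  }

  vol <- 0
  fact <- factorial(d)
  for (f in facets) {
    M <- sweep(pts[f$v, , drop = FALSE], 2, inside)
    vol <- vol + abs(det(M)) / fact
  }
  verts <- sort(unique(unlist(lapply(facets, `[[`, "v"))))
  list(volume = vol, vertices = verts, nfacets = length(facets))
}

#' Test whether a point set spans its ambient dimension
#' @param points numeric matrix (rows = points).
#' @param tol rank tolerance.
#' @return logical; `TRUE` when a hull with positive volume exists.
#' @export
is_full_dimensional <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  if (nrow(pts) < ncol(pts) + 1) return(FALSE)
  rel <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  qr(rel, tol = tol)$rank == ncol(pts)
}
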