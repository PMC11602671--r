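# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Convex-hull volume by exhaustive facet enumeration (every d-subset whose
# hyperplane supports the cloud) + Monte-Carlo rejection sampling in the
# bounding box.
oracle_hull_volume_mc <- function(pts, n_samples = 4e5, seed = 1) {
  d <- ncol(pts)
  n <- nrow(pts)
  combs <- utils::combn(n, d)
  planes <- list()
  for (j in seq_len(ncol(combs))) {
    P <- pts[combs[, j], , drop = FALSE]
    A <- t(P[-1, , drop = FALSE]) - P[1, ]
    qr_ <- qr(A)
    if (qr_$rank < d - 1) next
    nv <- qr.Q(qr_, complete = TRUE)[, d]
    b <- sum(nv * P[1, ])
    s <- drop(pts %*% nv) - b
    if (all(s <= 1e-9)) {
      planes[[length(planes) + 1]] <- c(nv, b)
    } else if (all(s >= -1e-9)) {
      planes[[length(planes) + 1]] <- c(-nv, -b)
    }
  }
  M <- do.call(rbind, planes)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  set.seed(seed)
  chunk <- 5e4
  inside <- 0L
  done <- 0
  while (done < n_samples) {
    k <- min(chunk, n_samples - done)
    X <- sapply(seq_len(d), function(jj) stats::runif(k, lo[jj], hi[jj]))
    S <- X %*% t(M[, seq_len(d), drop = FALSE])
    ok <- rowSums(sweep(S, 2, M[, d + 1], `-`) > 1e-9) == 0
    inside <- inside + sum(ok)
    done <- done + k
  }
  prod(hi - lo) * inside / n_samples
}

# Gower distance by explicit per-trait arithmetic for a pair of species.
oracle_gower_pair <- function(row_i, row_j, scheme) {
  contrib <- vapply(names(scheme), function(tr) {
    lv <- scheme[[tr]]$levels
    ri <- match(row_i[[tr]], lv)
    rj <- match(row_j[[tr]], lv)
    if (scheme[[tr]]$ordered) abs(ri - rj) / (length(lv) - 1) else as.numeric(ri != rj)
  }, numeric(1))
  mean(contrib)
}

# Delta* by explicit double loop over species pairs; omega found by walking
# the six ranks bottom-up.
oracle_delta_star <- function(x, taxonomy) {
  lv <- c("genus", "family", "order", "subclass", "class", "superclass")
  sp <- names(x)[x > 0]
  x <- x[sp]
  tax <- taxonomy[match(sp, taxonomy$species), ]
  num <- 0
  den <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      omega <- 6
      for (k in seq_along(lv)) {
        if (tax[[lv[k]]][i] == tax[[lv[k]]][j]) { omega <- k; break }
      }
      num <- num + (omega * 100 / 6) * x[i] * x[j]
      den <- den + x[i] * x[j]
    }
  }
  unname(num / den)
}

# Attribute-diversity Hill number by literal transcription of the
# truncated-distance definition.
oracle_hill_functional <- function(x, dmat, q, tau) {
  p <- x[x > 0] / sum(x)
  dd <- pmin(dmat[x > 0, x > 0, drop = FALSE], tau)
  a <- numeric(length(p))
  for (i in seq_along(p)) {
    a[i] <- sum((1 - dd[i, ] / tau) * p)
  }
  v <- p / a
  if (q == 0) return(sum(v[a > 0]))
  if (q == 1) return(exp(-sum(v * a * log(a))))
  sum(v * a^q)^(1 / (1 - q))
}

# FOri / FDiv by literal per-definition loops.
oracle_fori <- function(w, coords) {
  dd <- as.matrix(stats::dist(coords))
  dnn <- vapply(seq_len(nrow(dd)), function(i) min(dd[i, -i]), numeric(1))
  names(dnn) <- rownames(coords)
  sum((w / sum(w)) * dnn[names(w)]) / max(dnn)
}

oracle_fdiv <- function(w, coords, hull_vertex_names) {
  sub <- coords[names(w), , drop = FALSE]
  G <- colMeans(coords[hull_vertex_names, , drop = FALSE])
  dG <- apply(sub, 1, function(r) sqrt(sum((r - G)^2)))
  dbar <- mean(dG)
  ww <- w / sum(w)
  (sum(ww * (dG - dbar)) + dbar) / (sum(ww * abs(dG - dbar)) + dbar)
}
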