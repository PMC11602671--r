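test_that("functional entities pool identical trait combinations", {
  tr <- toy_traits() # spA and spC identical, spB distinct
  ent <- encode_functional_entities(tr)
  expect_equal(nrow(ent$fe_traits), 2)
  expect_equal(sort(table(ent$fe$fe), decreasing = TRUE)[[1]], 2)
  # all-distinct traits: one FE per species
  pool <- generate_species_pool(pool_config(seed = 31))
  ent2 <- encode_functional_entities(pool$traits)
  expect_equal(nrow(ent2$fe_traits), length(unique(ent2$fe$fe)))
  # missing trait errors with species named
  bad <- tr
  bad$diet[2] <- NA
  expect_error(encode_functional_entities(bad), "spB")
})

test_that("FE weights conserve abundance per assemblage", {
  tr <- toy_traits()
  ab <- matrix(c(3, 1, 2, 0, 5, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("t1", "t2"), c("spA", "spB", "spC")))
  ent <- encode_functional_entities(tr, abundances = ab)
  expect_equal(unname(rowSums(ent$fe_abundance)), unname(rowSums(ab)))
  expect_equal(unname(rowSums(ent$fe_weights)), c(1, 1))
  # spA + spC pooled into one FE
  expect_equal(max(ent$fe_abundance["t1", ]), 5)
})

test_that("Gower distance matches per-trait arithmetic and is a metric here", {
  tr <- toy_traits()
  D <- gower_distance(tr)
  expect_equal(D["spA", "spC"], 0)       # identical species
  expect_equal(D["spA", "spB"], 1)       # maximal difference on every trait
  scheme <- trait_scheme()
  # random tables vs the pairwise oracle + metric properties
  set.seed(17)
  for (r in 1:5) {
    n <- 8
    tab <- data.frame(species = sprintf("s%d", 1:n))
    for (t in names(scheme)) tab[[t]] <- sample(scheme[[t]]$levels, n, TRUE)
    D2 <- gower_distance(tab)
    expect_true(isSymmetric(unname(D2)))
    expect_true(all(diag(D2) == 0))
    expect_true(all(D2 >= 0 & D2 <= 1))
    for (i in 1:4) {
      for (j in (i + 1):5) {
        expect_equal(D2[i, j], oracle_gower_pair(tab[i, ], tab[j, ], scheme))
      }
    }
    # triangle inequality, exhaustively
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(D2[i, j], D2[i, k] + D2[k, j] + 1e-12)
    }
  }
})

test_that("Gower distance agrees with cluster::daisy on ordinal+nominal data", {
  scheme <- trait_scheme()
  set.seed(23)
  tab <- data.frame(species = sprintf("s%d", 1:12))
  for (t in names(scheme)) {
    lv <- scheme[[t]]$levels
    # pin both extremes so daisy's observed-range standardisation equals
    # the scheme-range convention
    tab[[t]] <- c(lv[1], lv[length(lv)], sample(lv, 10, TRUE))
  }
  df <- tab[-1]
  for (t in names(scheme)) {
    df[[t]] <- factor(df[[t]], levels = scheme[[t]]$levels,
                      ordered = scheme[[t]]$ordered)
  }
  D_pkg <- gower_distance(tab)
  D_ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(D_pkg), unname(D_ref), tolerance = 1e-10)
})

test_that("PCoA reproduces Euclidean configurations and orders eigenvalues", {
  set.seed(5)
  X <- matrix(rnorm(40), ncol = 4)
  sp <- pcoa_space(as.matrix(dist(X)))
  expect_equal(as.matrix(dist(sp$coordinates)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(sp$eigenvalues) <= 1e-8))
  expect_true(all(diff(sp$explained_variance) >= -1e-12))
  # 2-point case: one positive axis, coordinates +-0.5
  two <- pcoa_space(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sum(two$eigenvalues > 1e-8), 1)
  expect_equal(sort(two$coordinates[, 1]), c(-0.5, 0.5))
  expect_error(pcoa_space(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with ape::pcoa on a Gower matrix", {
  pool <- generate_species_pool(pool_config(n_species = 15, seed = 6,
                                            taxonomy_shape = c(genus = 10, family = 6,
                                                               order = 4, subclass = 2,
                                                               class = 2, superclass = 1)))
  D <- gower_distance(pool$traits)
  mine <- pcoa_space(D)
  ref <- ape::pcoa(as.dist(D))
  npos <- min(ncol(mine$coordinates), ncol(ref$vectors))
  for (k in seq_len(npos)) {
    expect_equal(abs(mine$coordinates[, k]), abs(ref$vectors[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("dimensionality selection reduces gracefully", {
  set.seed(8)
  sp <- pcoa_space(as.matrix(dist(matrix(rnorm(60), ncol = 6))))
  suppressMessages({
    expect_equal(select_dimensionality(sp, 4), 4)
    flat <- pcoa_space(as.matrix(dist(matrix(rnorm(30), ncol = 2))))
    expect_warning(m <- select_dimensionality(flat, 4), "positive axes")
    expect_lt(m, 4)
  })
})

test_that("FRic is a fraction of the pool volume with hull monotonicity", {
  set.seed(9)
  coords <- matrix(rnorm(30 * 4), ncol = 4,
                   dimnames = list(sprintf("fe%02d", 1:30), NULL))
  pool_vol <- convex_hull_volume(coords)$volume
  expect_equal(fric(rownames(coords), coords, pool_vol), 1)
  # hull vertices alone give the same hull
  verts <- rownames(coords)[convex_hull_volume(coords)$vertices]
  expect_equal(fric(verts, coords, pool_vol), 1)
  # nested assemblages: FRic monotone
  a <- rownames(coords)[1:8]
  b <- rownames(coords)[1:16]
  fa <- fric(a, coords, pool_vol)
  fb <- fric(b, coords, pool_vol)
  if (!is.na(fa) && !is.na(fb)) expect_lte(fa, fb + 1e-12)
  # degenerate assemblage flagged
  expect_true(is.na(fric(rownames(coords)[1:3], coords, pool_vol)))
})

test_that("FOri matches its nearest-neighbour definition", {
  coords <- rbind(fe1 = c(0, 0), fe2 = c(1, 0), fe3 = c(0, 1),
                  fe4 = c(5, 5), fe5 = c(0.1, 0))
  # all weight on the most isolated FE -> 1
  expect_equal(fori(c(fe4 = 1), coords), 1)
  # duplicated pool: all nearest-neighbour distances zero -> 0
  dup <- rbind(coords, coords)
  rownames(dup) <- paste0("g", 1:10)
  expect_equal(fori(setNames(rep(0.1, 10), rownames(dup)), dup), 0)
  # 5-FE hand example vs brute-force oracle
  w <- c(fe1 = 0.4, fe2 = 0.3, fe3 = 0.2, fe5 = 0.1)
  expect_equal(fori(w, coords), oracle_fori(w, coords))
  # scale invariance
  expect_equal(fori(w, coords * 7.3), fori(w, coords))
})

test_that("FDiv matches its centroid-deviation definition", {
  # all FEs equidistant from the hull-vertex centroid -> 1
  sq <- rbind(a = c(1, 0), b = c(0, 1), c = c(-1, 0), d = c(0, -1))
  w <- setNames(c(0.4, 0.3, 0.2, 0.1), rownames(sq))
  expect_equal(fdiv(w, sq), 1)
  # 6-FE example vs step-by-step oracle
  set.seed(10)
  coords <- matrix(rnorm(12), ncol = 2, dimnames = list(letters[1:6], NULL))
  w2 <- setNames(c(.3, .25, .2, .1, .1, .05), letters[1:6])
  verts <- rownames(coords)[convex_hull_volume(coords)$vertices]
  expect_equal(fdiv(w2, coords), oracle_fdiv(w2, coords, verts))
  expect_gt(fdiv(w2, coords), 0)
  expect_lte(fdiv(w2, coords), 1)
  # rigid motion invariance
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(coords %*% R, 2, c(3, -2), `+`)
  rownames(moved) <- rownames(coords)
  expect_equal(fdiv(w2, moved), fdiv(w2, coords), tolerance = 1e-10)
  # weight concentrated on the farthest FE pushes FDiv towards 1
  G <- colMeans(coords[verts, , drop = FALSE])
  far <- names(which.max(sqrt(rowSums(sweep(coords, 2, G)^2))))
  wfar <- setNames(rep(1e-6, 6), letters[1:6])
  wfar[far] <- 1
  expect_gt(fdiv(wfar / sum(wfar), coords), 0.95)
})

test_that("per-transect indices run end-to-end on synthetic data", {
  pool <- generate_species_pool(pool_config(seed = 13))
  des <- survey_design(baseline_log_mean = log(2), seed = 13)
  cm <- suppressMessages(build_community_matrix(
    read_survey_records(filter_records(generate_survey(des, pool)))))
  cm6 <- suppressMessages(functional_filter(cm))
  fi <- suppressMessages(transect_functional_indices(cm6, pool$traits))
  ok <- !fi$degenerate
  expect_gt(sum(ok), 0)
  expect_true(all(fi$fric[ok] >= 0 & fi$fric[ok] <= 1, na.rm = TRUE))
  expect_true(all(fi$fori[ok] >= 0 & fi$fori[ok] <= 1, na.rm = TRUE))
  expect_true(all(fi$fdiv[ok] > 0 & fi$fdiv[ok] <= 1, na.rm = TRUE))
})
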