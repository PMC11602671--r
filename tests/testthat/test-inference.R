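test_that("fourth-root Bray-Curtis matches direct arithmetic", {
  m <- rbind(t1 = c(16, 0, 1), t2 = c(0, 81, 1))
  d <- as.matrix(fourth_root_bray_curtis(m))
  x <- m[1, ]^0.25
  y <- m[2, ]^0.25
  expect_equal(d["t1", "t2"], sum(abs(x - y)) / sum(x + y))
  # identical transects -> 0; disjoint -> 1
  m2 <- rbind(a = c(3, 4, 0), b = c(3, 4, 0), c = c(0, 0, 9))
  d2 <- as.matrix(fourth_root_bray_curtis(m2))
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  # all-zero transects excluded with a warning
  expect_warning(d3 <- fourth_root_bray_curtis(rbind(c(1, 2), c(0, 0), c(2, 1))),
                 "all-zero")
  expect_equal(attr(d3, "Size"), 2)
})

test_that("nMDS recovers representable configurations", {
  set.seed(22)
  X <- matrix(rnorm(40), ncol = 2)
  d <- dist(X)
  # vegan warns that near-zero stress usually signals degenerate input; here
  # it is the expected outcome of a perfectly representable configuration
  fit <- suppressWarnings(nmds_ordination(d, k = 2, restarts = 5, seed = 2))
  expect_lt(fit$stress, 1e-3) # exactly representable in 2-D
  # duplicate points land together
  X2 <- rbind(X, X[1, ])
  fit2 <- suppressWarnings(nmds_ordination(dist(X2), k = 2, restarts = 5, seed = 2))
  expect_lt(sqrt(sum((fit2$points[21, ] - fit2$points[1, ])^2)), 1e-4)
})

test_that("environment vectors recover axis-aligned gradients", {
  set.seed(23)
  pts <- matrix(rnorm(60), ncol = 2)
  env <- data.frame(grad = pts[, 1], noise = rnorm(30), flat = rep(1, 30))
  suppressWarnings({
    ef <- fit_environment_vectors(pts, env, n_perm = 199, seed = 3)
  })
  expect_equal(ef$r2[ef$variable == "grad"], 1, tolerance = 1e-6)
  expect_equal(abs(ef[ef$variable == "grad", 2]), 1, tolerance = 1e-3)
  expect_lt(ef$p_value[ef$variable == "grad"], 0.01)
  expect_equal(ef$r2[ef$variable == "flat"], 0, tolerance = 1e-9)
  expect_gt(ef$p_value[ef$variable == "noise"], 0.05)
})

test_that("the NB fitter agrees with MASS::glm.nb", {
  set.seed(24)
  x <- rep(0:1, each = 100)
  y <- rnbinom(200, size = 1.5, mu = exp(0.5 + 0.8 * x))
  f <- fit_nb_glm(y, cbind(`(Intercept)` = 1, x = x))
  g <- MASS::glm.nb(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
  expect_equal(f$theta, g$theta, tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  # intercept-only exact mean
  f2 <- fit_nb_glm(c(2, 2, 2, 2), matrix(1, 4, 1))
  expect_equal(exp(unname(f2$coefficients)), 2)
  # Poisson-generated data: dispersion pushed towards the Poisson limit
  # (extra variance mu^2/theta small next to mu), matching MASS exactly
  yp <- rpois(500, 4)
  fp <- fit_nb_glm(yp, matrix(1, 500, 1))
  gp <- suppressWarnings(MASS::glm.nb(yp ~ 1))
  expect_gt(fp$theta, 20)
  expect_equal(fp$theta, gp$theta, tolerance = 1e-6)
  # all-zero response flagged as degenerate
  expect_false(fit_nb_glm(rep(0L, 20), matrix(1, 20, 1))$ok)
})

test_that("NB coefficient recovery on simulated data", {
  set.seed(25)
  n <- 500
  x1 <- rnorm(n)
  x2 <- rep(0:1, length.out = n)
  beta <- c(0.3, 0.5, -0.7)
  y <- rnbinom(n, size = 2, mu = exp(cbind(1, x1, x2) %*% beta))
  f <- fit_nb_glm(y, cbind(1, x1, x2))
  g <- MASS::glm.nb(y ~ x1 + x2)
  se <- summary(g)$coefficients[, 2]
  expect_true(all(abs(f$coefficients - beta) < 3 * se))
})

test_that("multivariate deviance test detects a strong zone effect", {
  set.seed(26)
  n <- 60
  zone <- rep(c("shallow", "mesophotic"), each = n / 2)
  mu <- exp(outer(ifelse(zone == "shallow", 1.5, 0), rnorm(15, 0, 0.5), `+`))
  Y <- matrix(rnbinom(n * 15, size = 1, mu = mu), n, 15)
  mv <- multivariate_deviance_test(Y, data.frame(zone = zone), ~ zone,
                                   n_boot = 199, seed = 5)
  expect_equal(mv$term, "zone")
  expect_lte(mv$p_value, 0.01)
  expect_gt(mv$deviance, 0)
  expect_equal(mv$res_df, n - 2)
})

test_that("sequential deviances accumulate over ordered terms", {
  pool <- generate_species_pool(pool_config(n_species = 15, seed = 27,
                                            taxonomy_shape = c(genus = 10, family = 6,
                                                               order = 4, subclass = 2,
                                                               class = 2, superclass = 1)))
  des <- survey_design(year_totals = c("2021" = 40, "2022" = 40), seed = 27)
  cm <- suppressMessages(build_community_matrix(read_survey_records(
    filter_records(generate_survey(des, pool)))))
  dsg <- data.frame(zone = cm$stratum, year = cm$year, season = cm$season,
                    site = cm$site)
  Y <- community_counts(cm)
  mv <- multivariate_deviance_test(Y[, colSums(Y) > 0], dsg,
                                   ~ zone + year + season + site,
                                   n_boot = 49, seed = 6)
  expect_equal(mv$term, c("zone", "year", "season", "site"))
  expect_true(all(mv$deviance >= 0))
  expect_true(all(diff(mv$res_df) <= 0))
  expect_true(all(mv$p_value > 0 & mv$p_value <= 1))
  # single-species matrix: statistic equals that species' LR
  one <- multivariate_deviance_test(Y[, which.max(colSums(Y)), drop = FALSE],
                                    dsg, ~ zone, n_boot = 19, seed = 7)
  f0 <- fit_nb_glm(Y[, which.max(colSums(Y))], matrix(1, nrow(Y), 1))
  f1 <- fit_nb_glm(Y[, which.max(colSums(Y))],
                   stats::model.matrix(~ zone, dsg))
  expect_equal(one$deviance, 2 * (f1$loglik - f0$loglik), tolerance = 1e-6)
  # single-level factor dropped with warning
  expect_warning(multivariate_deviance_test(Y[, 1:3], transform(dsg, flat = "x"),
                                            ~ zone + flat, n_boot = 19, seed = 8),
                 "single level")
})

test_that("PIT-trap p-values carry the +1 correction", {
  set.seed(28)
  Y <- matrix(rnbinom(40 * 5, size = 1, mu = 2), 40, 5)
  mv <- multivariate_deviance_test(Y, data.frame(zone = rep(c("a", "b"), 20)),
                                   ~ zone, n_boot = 19, seed = 9)
  expect_gte(mv$p_value, 1 / 20)
})

test_that("GLMM collapses to a GLM when random variances vanish", {
  set.seed(31) # a draw whose variance estimates all land on the boundary
  n <- 400
  zone <- rep(c("shallow", "mesophotic"), each = n / 2)
  year <- sample(c("2021", "2022"), n, TRUE)
  season <- sample(c("cold", "warm"), n, TRUE)
  site <- sample(c("A", "B", "C"), n, TRUE)
  y <- rpois(n, lambda = exp(1 + 0.5 * (zone == "shallow"))) # no group structure
  suppressWarnings({
    mm <- fit_glmm(y, zone, year, season, site, family = "poisson-log")
  })
  gg <- glm(y ~ factor(zone, levels = c("mesophotic", "shallow")),
            family = poisson())
  expect_equal(sort(mm$fixed$estimate), sort(unname(coef(gg))), tolerance = 1e-4)
  expect_true(mm$boundary) # variances at or near zero reported as such
})

test_that("GLMM recovers a simulated zone effect within 3 SE", {
  set.seed(30)
  n <- 200
  zone <- rep(c("mesophotic", "shallow"), each = n / 2)
  year <- sample(c("2021", "2022"), n, TRUE)
  season <- sample(c("cold", "warm"), n, TRUE)
  site <- sample(c("A", "B", "C"), n, TRUE)
  re <- rnorm(2, 0, 0.1)[factor(year)] + rnorm(2, 0, 0.1)[factor(season)] +
    rnorm(3, 0, 0.1)[factor(site)]
  y <- rpois(n, exp(1 + 0.5 * (zone == "shallow") + re))
  res <- suppressWarnings(fit_glmm(y, zone, year, season, site,
                                   family = "poisson-log"))
  zi <- grep("^zone", res$fixed$term)
  expect_lt(abs(res$fixed$estimate[zi] - 0.5), 3 * res$fixed$std_error[zi])
  # single-level random factor dropped with warning
  expect_warning(fit_glmm(y, zone, year = rep("2021", n), season = season,
                          site = site, family = "poisson-log"),
                 "dropped")
})
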