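test_that("species-pool partition follows largest-remainder rounding", {
  pool <- generate_species_pool(pool_config(seed = 1))
  expect_equal(unname(pool$partition), c(52L, 29L, 15L))
  expect_equal(sum(pool$partition), 96L)
  # degenerate: everything shared
  p2 <- generate_species_pool(pool_config(n_species = 10, prop_shared = 1,
                                          prop_shallow_only = 0, prop_deep_only = 0,
                                          taxonomy_shape = c(genus = 5, family = 4,
                                                             order = 3, subclass = 2,
                                                             class = 2, superclass = 1)))
  expect_equal(unname(p2$partition), c(10L, 0L, 0L))
  expect_error(pool_config(prop_shared = 0.8, prop_shallow_only = 0.3,
                           prop_deep_only = 0.1), "sum to 1")
})

test_that("pool generation is seed-reproducible and structurally valid", {
  a <- generate_species_pool(pool_config(seed = 7))
  b <- generate_species_pool(pool_config(seed = 7))
  expect_identical(a, b)
  scheme <- trait_scheme()
  for (tr in names(scheme)) {
    expect_true(all(a$traits[[tr]] %in% scheme[[tr]]$levels))
  }
  # consistent nesting: each genus maps to exactly one family, etc.
  tx <- a$taxonomy
  lv <- c("genus", "family", "order", "subclass", "class", "superclass")
  for (k in seq_len(length(lv) - 1)) {
    parents <- tapply(tx[[lv[k + 1]]], tx[[lv[k]]], function(v) length(unique(v)))
    expect_true(all(parents == 1))
  }
  expect_equal(length(unique(tx$genus)), 65)
  expect_equal(length(unique(tx$family)), 35)
})

test_that("survey counts respect structural zeros and the factorial layout", {
  pool <- generate_species_pool(pool_config(seed = 2))
  des <- survey_design(seed = 2)
  rec <- generate_survey(des, pool)
  # 189 transects x 96 species rows
  expect_equal(nrow(rec), 189 * 96)
  expect_equal(length(unique(rec$transect_id)), 189)
  aff <- setNames(pool$affinity$affinity, pool$affinity$species)
  deep_counts <- rec$count[rec$stratum == "mesophotic" &
                             aff[rec$species] == "shallow_only"]
  shal_counts <- rec$count[rec$stratum == "shallow" &
                             aff[rec$species] == "deep_only"]
  expect_true(all(deep_counts == 0))
  expect_true(all(shal_counts == 0))
})

test_that("survey NB draws match their closed-form moments", {
  # single shared species, zone effect +1: mean ratio shallow/meso ~ e
  pool <- list(affinity = data.frame(species = "spX", affinity = "shared"))
  des <- survey_design(sites = "A", transects_per_cell = 1500,
                       effect_sizes = list(zone_shallow = 1, site = 0,
                                           season_cold = 0, year2 = 0),
                       baseline_log_mean = log(2), species_sd = 0,
                       nb_dispersion = 1.5, flag_rates = c(dragged = 0, parallel_swim = 0),
                       seed = 3)
  rec <- generate_survey(des, pool)
  m_sh <- mean(rec$count[rec$stratum == "shallow"])
  m_dp <- mean(rec$count[rec$stratum == "mesophotic"])
  expect_equal(m_sh / m_dp, exp(1), tolerance = 0.05)
  # NB variance ~ mu + mu^2/theta
  x <- rec$count[rec$stratum == "mesophotic"]
  expect_equal(var(x), 2 + 4 / 1.5, tolerance = 0.1)
  # vanishing mean: all counts zero
  des0 <- survey_design(baseline_log_mean = -20, species_sd = 0,
                        effect_sizes = list(zone_shallow = 0, site = 0,
                                            season_cold = 0, year2 = 0), seed = 4)
  rec0 <- generate_survey(des0, generate_species_pool(pool_config(seed = 4)))
  expect_true(all(rec0$count == 0))
})

test_that("Kd490 series respects seasonal ranges, ordering and seeding", {
  cfg <- turbidity_config(seed = 9)
  kd <- generate_kd490_series(cfg)
  expect_true(all(kd$kd490 > 0))
  expect_gt(mean(kd$kd490[kd$season == "cold"]), mean(kd$kd490[kd$season == "warm"]))
  expect_identical(kd, generate_kd490_series(turbidity_config(seed = 9)))
  # degenerate noise-free range: exact values
  c0 <- turbidity_config(cold_kd490_range = c(0.09, 0.09),
                         warm_kd490_range = c(0.05, 0.05), noise_sd = 0, seed = 1)
  kd0 <- generate_kd490_series(c0)
  expect_true(all(kd0$kd490[kd0$season == "cold"] == 0.09))
  expect_error(turbidity_config(cold_kd490_range = c(-0.1, 0.2)), "positive")
  expect_error(turbidity_config(cold_kd490_range = c(0.01, 0.05),
                                warm_kd490_range = c(0.04, 0.08)), "cold")
})

test_that("Kd490 series round-trips through CSV and CDL text formats", {
  kd <- generate_kd490_series(turbidity_config(months = 6, seed = 11))
  csv <- tempfile(fileext = ".csv")
  cdl <- tempfile(fileext = ".cdl")
  write_kd490_csv(kd, csv)
  back <- read_kd490_csv(csv)
  expect_equal(back$kd490, kd$kd490, tolerance = 1e-12)
  write_kd490_cdl(kd, cdl)
  back2 <- read_kd490_cdl(cdl)
  m <- merge(kd, back2, by = c("site", "month"))
  expect_equal(m$kd490.x, m$kd490.y, tolerance = 1e-6)
  expect_identical(m$season.x, m$season.y)
  unlink(c(csv, cdl))
})

test_that("PIT generator yields 30 points per transect with the right mix", {
  des <- survey_design(seed = 5)
  pit <- generate_benthic_pit(des, substrate_mix = c(sand = 1, gravel = 0,
                                                     block = 0, rock = 0))
  expect_true(all(table(pit$transect_id) == 30))
  expect_true(all(pit$substrate == "sand"))
  # law of large numbers on a balanced mix
  des2 <- survey_design(transects_per_cell = 100, seed = 6)
  pit2 <- generate_benthic_pit(des2, substrate_mix = c(sand = .25, gravel = .25,
                                                       block = .25, rock = .25))
  freq <- table(pit2$substrate) / nrow(pit2)
  expect_true(all(abs(freq - 0.25) < 0.01))
  expect_error(generate_benthic_pit(des, substrate_mix = c(sand = .5, gravel = .2,
                                                           block = .2, rock = .2)),
               "summing|sum")
})
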