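# Synthetic video-transect surveys and benthic point-intercept records.

#' Factorial survey design for synthetic transects
#'
#' The defaults reproduce the structure of the source monitoring programme:
#' three sites, two depth strata, two seasons and two years, with per-year
#' transect totals of 94 and 95 (allocated to the 12 site x stratum x season
#' cells of each year by largest remainder), i.e. 189 transects in all.
#' Expected counts are log-linear in the design factors and drawn from a
#' negative binomial with dispersion `nb_dispersion` (Var = mu + mu^2/theta).
#'
#' @param sites character vector of site labels.
#' @param seasons,years factor labels (two each by default).
#' @param transects_per_cell single count per design cell, or `NULL` to use
#'   `year_totals`.
#' @param year_totals named per-year transect totals used when
#'   `transects_per_cell` is `NULL`.
#' @param nb_dispersion negative-binomial dispersion theta (> 0).
#' @param effect_sizes named list of log-scale effects: `zone_shallow`
#'   (added to shallow-stratum means), `site`, `season_cold`, `year2`,
#'   `zone_season` (interaction). `site` may be a vector matched to `sites`.
#' @param baseline_log_mean log expected count per species per transect for a
#'   shared species in the mesophotic stratum at the reference levels.
#' @param species_sd standard deviation of per-species lognormal deviations
#'   around the baseline (rank-abundance heterogeneity).
#' @param flag_rates named probabilities for the `dragged` and
#'   `parallel_swim` quality flags (the remainder are `ok`).
#' @param depth_ranges list with `shallow` and `mesophotic` (min, max) depths
#'   in metres used to place transects within their stratum.
#' @param seed integer seed.
#' @return a `survey_design` list.
#' @export
survey_design <- function(sites = c("PuntaLobos", "LosIslotes", "ElBajo"),
                          seasons = c("cold", "warm"),
                          years = c("2021", "2022"),
                          transects_per_cell = NULL,
                          year_totals = c("2021" = 94, "2022" = 95),
                          nb_dispersion = 1,
                          effect_sizes = list(zone_shallow = 0.7,
                                              site = c(0, 0.15, 0.3),
                                              season_cold = 0.2,
                                              year2 = 0.05,
                                              zone_season = 0),
                          baseline_log_mean = log(0.8),
                          species_sd = 1,
                          flag_rates = c(dragged = 0.02, parallel_swim = 0.02),
                          depth_ranges = list(shallow = c(4, 21),
                                              mesophotic = c(22, 60)),
                          seed = 1L) {
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be > 0")
  if (!is.null(transects_per_cell) && transects_per_cell < 1) {
    stop_config("transects_per_cell must be >= 1")
  }
  if (is.null(transects_per_cell)) {
    if (length(year_totals) != length(years)) {
      stop_config("year_totals must give one total per year")
    }
  }
  if (sum(flag_rates) >= 1) stop_config("flag rates must sum to < 1")
  structure(
    list(sites = sites, strata = c("shallow", "mesophotic"),
         seasons = seasons, years = as.character(years),
         transects_per_cell = transects_per_cell,
         year_totals = year_totals, nb_dispersion = nb_dispersion,
         effect_sizes = effect_sizes, baseline_log_mean = baseline_log_mean,
         species_sd = species_sd, flag_rates = flag_rates,
         depth_ranges = depth_ranges, seed = as.integer(seed)),
    class = "survey_design"
  )
}

# Transect layout: one row per transect with its design-cell factors + depth.
.design_grid <- function(design) {
  cells <- expand.grid(site = design$sites, stratum = design$strata,
                       season = design$seasons, year = design$years,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(design$transects_per_cell)) {
    cells$n <- design$transects_per_cell
  } else {
    cells$n <- 0L
    for (yr in design$years) {
      ix <- which(cells$year == yr)
      cells$n[ix] <- largest_remainder(design$year_totals[[yr]],
                                       rep(1 / length(ix), length(ix)))
    }
  }
  out <- cells[rep(seq_len(nrow(cells)), cells$n), c("site", "stratum", "season", "year")]
  rownames(out) <- NULL
  out$transect_id <- sprintf("t%04d", seq_len(nrow(out)))
  out
}

#' Generate synthetic survey records
#'
#' Draws per-transect, per-species counts from a negative binomial whose log
#' mean is the sum of the design effects. Zone affinity enters as structural
#' zeros: a shallow-exclusive species has expected abundance 0 in every
#' mesophotic transect and vice versa, so the Venn partition of the pool is
#' recoverable exactly from a sufficiently sampled survey. Each record
#' carries the transect metadata, a depth drawn within its stratum's range
#' and a quality flag.
#'
#' @param design a [survey_design()].
#' @param pool a pool from [generate_species_pool()].
#' @return data.frame of records (one row per transect x species with the
#'   full metadata; zero counts retained).
#' @export
generate_survey <- function(design = survey_design(), pool = generate_species_pool()) {
  stopifnot(inherits(design, "survey_design"))
  with_seed(derive_seed(design$seed, "survey"), {
    grid <- .design_grid(design)
    nt <- nrow(grid)
    sp <- pool$affinity$species
    ns <- length(sp)

    rng <- design$depth_ranges
    grid$depth <- ifelse(
      grid$stratum == "shallow",
      stats::runif(nt, rng$shallow[1], rng$shallow[2]),
      stats::runif(nt, rng$mesophotic[1], rng$mesophotic[2])
    )
    fl <- design$flag_rates
    grid$quality_flag <- sample(c("ok", names(fl)), nt, replace = TRUE,
                                prob = c(1 - sum(fl), fl))

    ef <- design$effect_sizes
    site_ef <- ef$site
    if (length(site_ef) == 1) site_ef <- rep(site_ef, length(design$sites))
    names(site_ef) <- design$sites

    # per-transect linear predictor shared by all species
    eta_t <- design$baseline_log_mean +
      ifelse(grid$stratum == "shallow", ef$zone_shallow %||% 0, 0) +
      site_ef[grid$site] +
      ifelse(grid$season == design$seasons[1], ef$season_cold %||% 0, 0) +
      ifelse(grid$year == design$years[2], ef$year2 %||% 0, 0) +
      ifelse(grid$stratum == "shallow" & grid$season == design$seasons[1],
             ef$zone_season %||% 0, 0)

    sp_ef <- stats::rnorm(ns, 0, design$species_sd)

    # structural zeros outside a species' zone affinity
    aff <- pool$affinity$affinity
    allowed <- outer(grid$stratum, aff, function(st, a) {
      !(a == "shallow_only" & st == "mesophotic") &
        !(a == "deep_only" & st == "shallow")
    })
    mu <- exp(outer(eta_t, sp_ef, `+`)) * allowed
    counts <- matrix(
      stats::rnbinom(nt * ns, size = design$nb_dispersion, mu = as.vector(mu)),
      nrow = nt
    )

    out <- data.frame(
      transect_id = rep(grid$transect_id, ns),
      site = rep(grid$site, ns),
      stratum = rep(grid$stratum, ns),
      season = rep(grid$season, ns),
      year = rep(grid$year, ns),
      depth = rep(grid$depth, ns),
      quality_flag = rep(grid$quality_flag, ns),
      species = rep(sp, each = nt),
      count = as.vector(counts),
      stringsAsFactors = FALSE
    )
    out[order(out$transect_id, out$species), ]
  })
}

#' Generate benthic point-intercept (PIT) records
#'
#' Every transect receives exactly 30 categorical substrate draws (one per
#' 10-second interval) from `substrate_mix`, plus soft-coral and black-coral
#' colony counts (Poisson) and a hard-coral percent cover (scaled beta).
#'
#' @param design a [survey_design()] (supplies the transect layout and seed).
#' @param substrate_mix named probability vector over
#'   `c("sand", "gravel", "block", "rock")`; must sum to 1.
#' @param coral_rates list with Poisson means `soft`, `black` and a mean
#'   hard-coral percent cover `hard_mean` in (0, 100).
#' @param points_per_transect number of PIT points (30 in the field protocol).
#' @return data.frame with one row per PIT point (`transect_id`, `point`,
#'   `substrate`) and per-transect coral columns repeated on each row.
#' @export
generate_benthic_pit <- function(design = survey_design(),
                                 substrate_mix = c(sand = 0.3, gravel = 0.15,
                                                   block = 0.25, rock = 0.3),
                                 coral_rates = list(soft = 1.5, black = 0.8,
                                                    hard_mean = 6),
                                 points_per_transect = 30L) {
  cats <- c("sand", "gravel", "block", "rock")
  if (!setequal(names(substrate_mix), cats)) {
    stop_config("substrate_mix must name exactly: ", paste(cats, collapse = ", "))
  }
  substrate_mix <- substrate_mix[cats]
  if (any(substrate_mix < 0) || abs(sum(substrate_mix) - 1) > 1e-9) {
    stop_config("substrate_mix must be a probability vector summing to 1")
  }
  with_seed(derive_seed(design$seed, "pit"), {
    grid <- .design_grid(design)
    nt <- nrow(grid)
    k <- as.integer(points_per_transect)
    sub <- sample(cats, nt * k, replace = TRUE, prob = substrate_mix)
    soft <- stats::rpois(nt, coral_rates$soft)
    black <- stats::rpois(nt, coral_rates$black)
    m <- coral_rates$hard_mean / 100
    hard <- 100 * stats::rbeta(nt, shape1 = m * 5, shape2 = (1 - m) * 5)
    data.frame(
      transect_id = rep(grid$transect_id, each = k),
      point = rep(seq_len(k), nt),
      substrate = sub,
      soft_coral = rep(soft, each = k),
      black_coral = rep(black, each = k),
      hard_coral_pct = rep(hard, each = k),
      stringsAsFactors = FALSE
    )
  })
}
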