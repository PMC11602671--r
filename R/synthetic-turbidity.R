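# Synthetic monthly Kd490 series and their on-disk formats.

#' Configuration for a synthetic seasonal turbidity series
#'
#' Monthly Kd490 values are drawn uniformly within a season-specific range
#' and perturbed by truncated Gaussian noise, with the cold season more
#' turbid than the warm season (wind-driven mixing and upwelling raise
#' nutrient loads and phytoplankton in winter). Defaults bracket the study
#' region's reported seasonal values (cold Kd490 around 0.09-0.1 m^-1, warm
#' around 0.04-0.05 m^-1).
#'
#' @param months number of consecutive months to generate (start = January).
#' @param cold_kd490_range,warm_kd490_range (min, max) Kd490 in m^-1; both
#'   positive, and the cold minimum must be >= the warm minimum.
#' @param noise_sd Gaussian noise SD in m^-1 (values floored at `floor_kd`).
#' @param season_of_month integer vector of length 12 mapping calendar month
#'   to `"cold"`/`"warm"`.
#' @param sites site labels; each gets an independent series.
#' @param floor_kd small positive lower bound applied after noise.
#' @param seed integer seed.
#' @return a `turbidity_config` list.
#' @export
turbidity_config <- function(months = 24,
                             cold_kd490_range = c(0.08, 0.12),
                             warm_kd490_range = c(0.035, 0.055),
                             noise_sd = 0.004,
                             season_of_month = c(rep("cold", 6), rep("warm", 5), "cold"),
                             sites = c("PuntaLobos", "LosIslotes", "ElBajo"),
                             floor_kd = 1e-3,
                             seed = 1L) {
  if (any(c(cold_kd490_range, warm_kd490_range) <= 0)) {
    stop_config("Kd490 ranges must be positive")
  }
  if (diff(cold_kd490_range) < 0 || diff(warm_kd490_range) < 0) {
    stop_config("ranges must be (min, max)")
  }
  if (cold_kd490_range[1] < warm_kd490_range[1]) {
    stop_config("cold-season minimum Kd490 must be >= warm-season minimum")
  }
  if (length(season_of_month) != 12 ||
      !all(season_of_month %in% c("cold", "warm"))) {
    stop_config("season_of_month must map the 12 calendar months to cold/warm")
  }
  structure(
    list(months = as.integer(months), cold = cold_kd490_range,
         warm = warm_kd490_range, noise_sd = noise_sd,
         season_of_month = season_of_month, sites = sites,
         floor_kd = floor_kd, seed = as.integer(seed)),
    class = "turbidity_config"
  )
}

#' Generate a monthly Kd490 series per site
#'
#' @param cfg a [turbidity_config()].
#' @return data.frame with columns `site`, `month` (1-based index),
#'   `calendar_month`, `season`, `kd490` (m^-1).
#' @export
generate_kd490_series <- function(cfg = turbidity_config()) {
  stopifnot(inherits(cfg, "turbidity_config"))
  with_seed(derive_seed(cfg$seed, "kd490"), {
    res <- lapply(cfg$sites, function(site) {
      cal <- ((seq_len(cfg$months) - 1) %% 12) + 1
      season <- cfg$season_of_month[cal]
      lo <- ifelse(season == "cold", cfg$cold[1], cfg$warm[1])
      hi <- ifelse(season == "cold", cfg$cold[2], cfg$warm[2])
      kd <- stats::runif(cfg$months, lo, hi) +
        stats::rnorm(cfg$months, 0, cfg$noise_sd)
      kd <- pmax(kd, cfg$floor_kd)
      data.frame(site = site, month = seq_len(cfg$months),
                 calendar_month = cal, season = season, kd490 = kd,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Write / read a Kd490 series as CSV
#' @param series data.frame from [generate_kd490_series()].
#' @param path file path.
#' @return `read_kd490_csv` returns the series data.frame.
#' @export
write_kd490_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kd490_csv
#' @export
read_kd490_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "month", "season", "kd490")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("Kd490 CSV lacks column(s): ", paste(miss, collapse = ", "))
  out
}

#' Write / read a Kd490 series as a CDL-style gridded text file
#'
#' Serialises the series in the layout of a gridded satellite product
#' (dimensions `time`, `lat`, `lon`; variable `KD490` in m^-1) using the
#' plain-text CDL notation (`ncdump` style). Each site occupies one grid
#' cell; time indexes months. The reader parses the file back to the long
#' data.frame produced by [generate_kd490_series()].
#'
#' @param series data.frame from [generate_kd490_series()].
#' @param path file path (conventionally `.cdl`).
#' @param site_coords optional data.frame `site`, `lat`, `lon`; synthesised
#'   on a line of grid cells when absent.
#' @return `read_kd490_cdl` returns the series data.frame.
#' @export
write_kd490_cdl <- function(series, path, site_coords = NULL) {
  sites <- unique(series$site)
  if (is.null(site_coords)) {
    site_coords <- data.frame(site = sites, lat = 24.5,
                              lon = -110.3 + 0.04 * (seq_along(sites) - 1))
  }
  months <- sort(unique(series$month))
  season_map <- series$season[match(months, series$month)]
  grid <- matrix(NA_real_, nrow = length(months), ncol = length(sites),
                 dimnames = list(NULL, sites))
  for (i in seq_len(nrow(series))) {
    grid[match(series$month[i], months), series$site[i]] <- series$kd490[i]
  }
  lines <- c(
    "netcdf kd490_synthetic {",
    "dimensions:",
    sprintf("\ttime = %d ;", length(months)),
    "\tlat = 1 ;",
    sprintf("\tlon = %d ;", length(sites)),
    "variables:",
    "\tdouble KD490(time, lat, lon) ;",
    "\t\tKD490:units = \"m-1\" ;",
    "\t\tKD490:long_name = \"diffuse attenuation coefficient at 490 nm\" ;",
    sprintf("\t\t// site_names = %s", paste(sites, collapse = ",")),
    sprintf("\t\t// season_of_time = %s", paste(season_map, collapse = ",")),
    "data:",
    " KD490 =",
    paste0("  ", apply(grid, 1, function(r) paste(sprintf("%.8f", r), collapse = ", ")),
           c(rep(",", length(months) - 1), " ;")),
    sprintf(" lat = %s ;", paste(unique(site_coords$lat), collapse = ", ")),
    sprintf(" lon = %s ;", paste(site_coords$lon, collapse = ", ")),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_kd490_cdl
#' @export
read_kd490_cdl <- function(path) {
  lines <- readLines(path)
  get_meta <- function(tag) {
    ln <- grep(tag, lines, value = TRUE, fixed = TRUE)
    strsplit(sub(paste0(".*", tag, " = "), "", ln), ",")[[1]]
  }
  sites <- get_meta("site_names")
  seasons <- get_meta("season_of_time")
  i0 <- grep("^ KD490 =$", lines)
  rows <- lines[(i0 + 1):(i0 + length(seasons))]
  vals <- lapply(strsplit(gsub("[;,]", "", rows), "\\s+"), function(x) {
    as.numeric(x[nzchar(x)])
  })
  out <- do.call(rbind, lapply(seq_along(vals), function(m) {
    data.frame(site = sites, month = m,
               calendar_month = ((m - 1) %% 12) + 1,
               season = seasons[m], kd490 = vals[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
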