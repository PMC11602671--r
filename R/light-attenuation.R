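#' Convert Kd490 to KdPAR (Morel Case-I waters)
#'
#' Transforms the diffuse attenuation coefficient of downwelling light at
#' 490 nm into the attenuation coefficient over the photosynthetically active
#' band, using the Morel et al. Case-I relation
#' \deqn{K_{dPAR} = 0.0864 + 0.884\,K_{d490} - 0.00137 / K_{d490}}
#' valid for clear, phytoplankton-dominated waters (Kd490 < 0.2 m\eqn{^{-1}};
#' a warning is emitted outside that range). The relation is strictly
#' increasing on its domain.
#'
#' @param kd490 numeric vector of Kd490 values in m^-1; must be > 0.
#' @param printed_eq1 logical; if `TRUE`, use the coefficient 0.0884 on the
#'   linear term instead of 0.884. That variant circulates in some secondary
#'   sources but is inconsistent with standard Case-I conversions (e.g. it
#'   maps 0.09 to 0.08 m^-1 rather than 0.15 m^-1); it is provided for audit
#'   only.
#' @return numeric vector of KdPAR values in m^-1.
#' @examples
#' round(kd490_to_kdpar(c(0.09, 0.07, 0.04)), 2) # 0.15 0.13 0.09
#' @export
kd490_to_kdpar <- function(kd490, printed_eq1 = FALSE) {
  if (!is.numeric(kd490) || any(!is.finite(kd490)) || any(kd490 <= 0)) {
    stop("kd490 must be finite and > 0 (m^-1)")
  }
  if (any(kd490 >= 0.2)) {
    warning("Kd490 >= 0.2 m^-1 lies outside the Case-I validity range")
  }
  slope <- if (printed_eq1) 0.0884 else 0.884
  0.0864 + slope * kd490 - 0.00137 / kd490
}

#' Optical depths bounding the mesophotic zone
#'
#' Computes the depths at which downwelling light falls to 10%, 1% and 0.1%
#' of its surface value, given the minimum (`kd1`) and maximum (`kd2`) mean
#' monthly KdPAR. The constants are -ln(0.10) = 2.3, -ln(0.01) = 4.6 and
#' -ln(0.001) = 6.9:
#' \deqn{z_{10\%} = 2.3/K_{d2},\quad z_{1\%} = 4.6/\bar K_d,\quad
#'       z_{0.1\%} = 6.9/K_{d1}}
#' with \eqn{\bar K_d = (K_{d1}+K_{d2})/2}. z10 is the upper limit, z1 the
#' midpoint and z01 the lower limit of the mesophotic band.
#'
#' @param kd1,kd2 minimum and maximum mean monthly KdPAR (m^-1); must satisfy
#'   `0 < kd1 <= kd2`.
#' @param season optional label stored on the result.
#' @return a `zone_limits` data.frame with columns `season`, `kd1`, `kd2`,
#'   `z10`, `z1`, `z01` (depths in metres).
#' @examples
#' optical_depths(0.23, 0.23) # 10, 20, 30 m
#' @export
optical_depths <- function(kd1, kd2, season = NA_character_) {
  if (!is.numeric(kd1) || !is.numeric(kd2) || any(!is.finite(c(kd1, kd2)))) {
    stop("kd1 and kd2 must be finite numerics")
  }
  if (any(kd1 <= 0) || any(kd2 <= 0)) stop("KdPAR values must be > 0")
  if (any(kd1 > kd2)) stop("kd1 must not exceed kd2")
  out <- data.frame(
    season = season,
    kd1 = kd1,
    kd2 = kd2,
    z10 = 2.3 / kd2,
    z1  = 4.6 / ((kd1 + kd2) / 2),
    z01 = 6.9 / kd1,
    stringsAsFactors = FALSE
  )
  class(out) <- c("zone_limits", "data.frame")
  out
}

#' Seasonal mesophotic zone limits from a monthly KdPAR series
#'
#' For each season, takes the minimum and maximum of the monthly mean KdPAR
#' (months pooled across sites by default) and converts them to the optical
#' depths delimiting the mesophotic band via [optical_depths()].
#'
#' @param series data.frame with columns `month`, `kd490` (or `kdpar`) and
#'   `season`; a `site` column is used when `by_site = TRUE`.
#' @param by_site logical; if `TRUE`, monthly means are computed per site and
#'   the min/max are taken over site-months rather than pooled monthly means.
#' @param printed_eq1 passed to [kd490_to_kdpar()] when `kdpar` is absent.
#' @return a `zone_limits` data.frame, one row per season.
#' @export
seasonal_zone_limits <- function(series, by_site = FALSE, printed_eq1 = FALSE) {
  stopifnot(is.data.frame(series))
  need <- c("month", "season")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("series lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(series)) stop("empty Kd series")
  if (is.null(series$kdpar)) {
    if (is.null(series$kd490)) stop("series needs a kd490 or kdpar column")
    series$kdpar <- kd490_to_kdpar(series$kd490, printed_eq1 = printed_eq1)
  }
  key <- if (by_site && !is.null(series$site)) {
    interaction(series$site, series$month, drop = TRUE)
  } else {
    factor(series$month)
  }
  monthly <- tapply(series$kdpar, list(key, factor(series$season)), mean)
  res <- lapply(colnames(monthly), function(s) {
    v <- monthly[, s]
    v <- v[!is.na(v)]
    if (!length(v)) stop("season '", s, "' has no months")
    optical_depths(min(v), max(v), season = s)
  })
  out <- do.call(rbind, res)
  class(out) <- c("zone_limits", "data.frame")
  out
}

#' Assign a transect depth to the shallow or mesophotic stratum
#'
#' The boundary is closed on the shallow side: a transect exactly at the
#' upper limit of the mesophotic band is shallow, anything strictly deeper is
#' mesophotic. The default operational limit is the minimum seasonal z10 over
#' the study (the upper limit of the mesophotic zone under the most
#' transparent conditions; 21 m in the source study).
#'
#' @param depth numeric vector of transect depths (m), >= 0.
#' @param upper_limit single positive depth (m) separating the strata.
#' @return character vector, `"shallow"` or `"mesophotic"`.
#' @examples
#' assign_stratum(c(5, 21, 21.01), 21)
#' @export
assign_stratum <- function(depth, upper_limit = 21) {
  if (!is.numeric(depth) || any(!is.finite(depth)) || any(depth < 0)) {
    stop("depth must be finite and >= 0")
  }
  if (length(upper_limit) != 1 || !is.finite(upper_limit) || upper_limit <= 0) {
    stop("upper_limit must be a single positive depth")
  }
  ifelse(depth <= upper_limit, "shallow", "mesophotic")
}
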