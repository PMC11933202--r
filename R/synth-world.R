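#' World configuration for the synthetic GPS feed
#'
#' Defines the geography and observation calendar of a fully synthetic world:
#' one or more countries, each with metropolitan areas laid out as square grids
#' of administrative units (an urban core surrounded by a rural ring), observed
#' over a calendar year spanning a pandemic declaration date.
#'
#' @param n_countries Number of countries.
#' @param n_metros_per_country Metropolitan areas per country.
#' @param grid_size Cells per metro side (square grid); must be >= 3 so that
#'   every metro has both urban and rural cells.
#' @param cell_km Edge length of one administrative unit, in km.
#' @param n_users Number of device users to simulate.
#' @param observation_start,observation_end Observation window (dates).
#' @param pandemic_date Pandemic declaration date; behavioural effects are
#'   planted strictly after this date. Must lie strictly inside the window.
#' @param baseline_start Start of the baseline comparison window (its end is
#'   `pandemic_date`).
#' @param regression_start First day of the policy-regression window.
#' @param seed Integer seed controlling all world-level randomness.
#' @return A list of class `mobgap_world_config`.
#' @export
world_config <- function(n_countries = 1L, n_metros_per_country = 2L,
                         grid_size = 5L, cell_km = 2, n_users = 2000L,
                         observation_start = "2020-01-01",
                         observation_end = "2020-12-31",
                         pandemic_date = "2020-03-15",
                         baseline_start = "2020-02-01",
                         regression_start = "2020-04-11",
                         seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries),
              n_metros_per_country = as.integer(n_metros_per_country),
              grid_size = as.integer(grid_size), cell_km = as.numeric(cell_km),
              n_users = as.integer(n_users),
              observation_start = as_date(observation_start),
              observation_end = as_date(observation_end),
              pandemic_date = as_date(pandemic_date),
              baseline_start = as_date(baseline_start),
              regression_start = as_date(regression_start),
              seed = as.integer(seed))
  if (cfg$grid_size < 3L) stop("grid_size must be >= 3")
  if (any(c(cfg$n_countries, cfg$n_metros_per_country, cfg$n_users) < 1L))
    stop("all counts must be positive")
  if (!(cfg$pandemic_date > cfg$observation_start &&
        cfg$pandemic_date < cfg$observation_end))
    stop("pandemic_date must lie strictly inside the observation window")
  if (cfg$baseline_start < cfg$observation_start ||
      cfg$baseline_start >= cfg$pandemic_date)
    stop("baseline window must lie inside the pre-pandemic period")
  class(cfg) <- "mobgap_world_config"
  cfg
}

#' Generate the synthetic geography bundle
#'
#' Builds every metro as a `grid_size` x `grid_size` grid of administrative
#' units. Central cells form the urban core: population density decreases from
#' the centre and is at least 1500 inhabitants/km^2 in every urban cell, with a
#' contiguous urban population of at least 50,000 by construction. Ring cells
#' are rural. Each unit receives a latent wealth score that declines with
#' distance from the metro centre, and six census indicator columns generated
#' as loadings on that latent score plus Gaussian noise (a one-factor
#' structure, so a first principal component recovers the latent ranking).
#'
#' @param config A [world_config()].
#' @return A list of class `mobgap_world` with elements `units` (one row per
#'   administrative unit: geometry bounds, population, latent wealth, census
#'   indicators, true urban flag and metro membership), `extents` (one
#'   urban-extent rectangle per metro), `countries` (timezone offsets) and the
#'   `config` used.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "mobgap_world_config"))
  set.seed(config$seed)
  G <- config$grid_size
  ck <- config$cell_km
  tz_pool <- c(-5L, 1L, 7L, -6L, 8L, 2L)
  countries <- data.table(
    country = seq_len(config$n_countries),
    country_id = sprintf("C%d", seq_len(config$n_countries)),
    tz_offset_hours = rep_len(tz_pool, config$n_countries))

  centre <- (G + 1) / 2
  r_urb <- (G - 1) / 2 - 1  # Chebyshev radius of the urban core
  cell <- CJ(row = seq_len(G), col = seq_len(G))
  units_list <- vector("list", config$n_countries * config$n_metros_per_country)
  ext_list <- vector("list", length(units_list))
  k <- 0L
  for (ci in seq_len(config$n_countries)) {
    for (mi in seq_len(config$n_metros_per_country)) {
      k <- k + 1L
      u <- copy(cell)
      u[, `:=`(country = ci,
               metro_id = sprintf("C%dM%d", ci, mi),
               unit_id = sprintf("C%dM%dU%02d", ci, mi, seq_len(.N)))]
      r_cheb <- pmax(abs(u$row - centre), abs(u$col - centre))
      d_norm <- sqrt((u$row - centre)^2 + (u$col - centre)^2) /
        (sqrt(2) * (G - 1) / 2)
      u[, urban := r_cheb <= r_urb]
      dens <- fifelse(u$urban, 1500 * (1.5 + 3.5 * (1 - d_norm)),
                      250 * (1 + 0.2 * (1 - d_norm)))
      # guarantee the contiguous-core population floor
      core_pop <- sum(dens[u$urban]) * ck^2
      if (core_pop < 50000) dens[u$urban] <- dens[u$urban] * 50000 / core_pop
      u[, population := round(dens * ck^2)]
      u[, density := population / ck^2]
      u[, latent_wealth := 1.8 * (1 - d_norm) - 0.9 + rnorm(.N, 0, 0.05)]
      # geometry: countries 15 degrees apart in lon, metros 1.5 apart
      lat_base <- 10
      lon_base <- 10 + 15 * (ci - 1) + 1.5 * (mi - 1)
      dlat <- ck * 1000 / m_per_deg_lat()
      dlon <- ck * 1000 / m_per_deg_lon(lat_base)
      u[, `:=`(lat0 = lat_base + (row - 1) * dlat, lat1 = lat_base + row * dlat,
               lon0 = lon_base + (col - 1) * dlon, lon1 = lon_base + col * dlon)]
      u[, `:=`(centroid_lat = (lat0 + lat1) / 2, centroid_lon = (lon0 + lon1) / 2)]
      if (!any(u$urban) || all(u$urban))
        stop("degenerate grid: metro must contain both urban and rural cells")
      units_list[[k]] <- u
      ub <- u[urban == TRUE]
      ext_list[[k]] <- data.table(
        extent_id = sprintf("E%d", k), metro_id = ub$metro_id[1],
        lat0 = min(ub$lat0), lat1 = max(ub$lat1),
        lon0 = min(ub$lon0), lon1 = max(ub$lon1))
    }
  }
  units <- rbindlist(units_list)
  # six census indicators: loadings on latent wealth + noise
  loadings <- c(assets = 0.90, education = 0.85, health_access = 0.80,
                water = 0.90, electricity = 0.75, rooms = 0.80)
  for (nm in names(loadings)) {
    units[[paste0("ind_", nm)]] <-
      loadings[[nm]] * units$latent_wealth + rnorm(nrow(units), 0, 0.12)
  }
  out <- list(units = units, extents = rbindlist(ext_list),
              countries = countries, config = config)
  class(out) <- "mobgap_world"
  out
}

#' @export
print.mobgap_world <- function(x, ...) {
  cat(sprintf("<mobgap_world> %d countries, %d units (%d urban), pop %s\n",
              nrow(x$countries), nrow(x$units), sum(x$units$urban),
              format(sum(x$units$population), big.mark = ",")))
  invisible(x)
}

#' Extract the census table of a synthetic world
#'
#' Returns the per-unit census view consumed by [compute_wealth_index()]:
#' identifiers, population and the indicator columns (the latent wealth score
#' is deliberately excluded — it is ground truth, not census data).
#'
#' @param world A `mobgap_world`.
#' @return A data.table with `unit_id`, `metro_id`, `population` and `ind_*`
#'   indicator columns.
#' @export
census_table <- function(world) {
  stopifnot(inherits(world, "mobgap_world"))
  keep <- c("unit_id", "metro_id", "population",
            grep("^ind_", names(world$units), value = TRUE))
  world$units[, ..keep]
}

# polygon (closed ring, lon/lat matrix) for a rectangle row
rect_polygon <- function(lat0, lat1, lon0, lon1) {
  cbind(lon = c(lon0, lon1, lon1, lon0, lon0),
        lat = c(lat0, lat0, lat1, lat1, lat0))
}
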