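#' Daily per-user mobility flags
#'
#' For every active user-day: `self_isolating` is TRUE iff the user has at
#' least one stop event that day and every stop is at the current home
#' location (the home of the most recent completed labeling window);
#' `commuted` is TRUE iff at least one stop falls at the user's primary work
#' location (NA for non-commuters); `minutes_home`/`minutes_work` sum stop
#' durations at those locations clipped to the local calendar day.
#'
#' @param event_days Output of [stop_event_days()].
#' @param labelings Output of [label_windows()].
#' @param profiles Profiles from [build_home_history()].
#' @param presence Output of [daily_presence()].
#' @param n_days Days in the observation period.
#' @return data.table, one row per active user-day.
#' @export
daily_flags <- function(event_days, labelings, profiles, presence, n_days) {
  lab <- as.data.table(labelings)
  # the labeling of the most recent completed window applies from the next
  # day onward; days before the first completed window inherit the first one
  hl <- lab[, .(user_id, jday = window_end + 1L, home_location)]
  first <- lab[, .(home_location = home_location[which.min(window_end)]),
               by = user_id]
  setkey(hl, user_id, jday)
  dd <- as.data.table(presence)[day <= n_days]
  dd[, home_loc := hl[dd, on = c("user_id", jday = "day"), roll = TRUE,
                      x.home_location]]
  dd[first, on = "user_id",
     home_loc := fifelse(is.na(home_loc), i.home_location, home_loc)]
  pr <- as.data.table(profiles)
  dd[pr, work_loc := i.work_location, on = "user_id"]

  v <- as.data.table(event_days)[day <= n_days & minutes > 0,
                                 .(user_id, day, location_id, minutes)]
  v[dd, `:=`(home_loc = i.home_loc, work_loc = i.work_loc),
    on = c("user_id", "day")]
  ag <- v[, .(n_stops = .N,
              all_home = all(location_id == home_loc),
              any_work = any(!is.na(work_loc) & location_id == work_loc),
              minutes_home = sum(minutes[location_id == home_loc]),
              minutes_work = sum(minutes[!is.na(work_loc) &
                                           location_id == work_loc])),
          by = .(user_id, day)]
  out <- ag[dd, on = c("user_id", "day")]
  out[is.na(n_stops), `:=`(n_stops = 0L, all_home = FALSE, any_work = FALSE,
                           minutes_home = 0, minutes_work = 0)]
  out[, `:=`(active = TRUE,
             self_isolating = n_stops > 0 & all_home,
             commuted = any_work)]
  out[pr, commuter := i.commuter, on = "user_id"]
  out[commuter != TRUE, commuted := NA]
  out[, .(user_id, day, active, self_isolating, commuted,
          minutes_home, minutes_work)]
}

#' Daily per-group indicator series with baseline-relative change
#'
#' Computes, per administrative unit and day, the indicator share (or mean
#' minutes) among active users whose primary home is in the unit; the group
#' level is the population-weighted mean over the group's units; `sem` is the
#' standard error of the mean across unit-level values pooled within
#' country-group; and `rel_change` is the percent change of the level versus
#' its mean over the baseline window. Group-days with no active user are
#' missing, not zero. Users enter under the wealth group of their primary
#' (pre-pandemic) home unit; only urban-resident labelled users contribute.
#'
#' @param daily Output of [daily_flags()].
#' @param profiles Profiles from [build_home_history()].
#' @param units Units table with `population` (and `wealth_group`).
#' @param origin Observation start date.
#' @param baseline_days Integer day indices of the baseline window.
#' @param indicator One of "self_isolation", "non_commuting", "minutes_home",
#'   "minutes_work".
#' @param split_low_by_work If TRUE (non-commuting only), low-wealth-home
#'   commuters are split into `low_work_high`/`low_work_low` strata by
#'   workplace wealth.
#' @param include_all Also emit an `all` pseudo-group pooling every labelled
#'   user (used by conservation checks and the null model).
#' @param roll Optional centred rolling-mean width (days) applied to a
#'   presentation column `rel_roll`; never feeds downstream statistics.
#' @return data.table of class `mobgap_group_series`.
#' @export
group_series <- function(daily, profiles, units, origin, baseline_days,
                         indicator = c("self_isolation", "non_commuting",
                                       "minutes_home", "minutes_work"),
                         split_low_by_work = FALSE, include_all = FALSE,
                         roll = NULL) {
  indicator <- match.arg(indicator)
  pr <- as.data.table(profiles)
  pr <- pr[!is.na(wealth_group) & urban_primary == TRUE]
  if (indicator == "non_commuting") pr <- pr[commuter == TRUE]
  pr[, group := as.character(wealth_group)]
  if (split_low_by_work) {
    if (indicator != "non_commuting")
      stop("split_low_by_work applies to the non-commuting indicator")
    pr <- pr[!(group == "low" & is.na(work_wealth))]
    pr[group == "low", group := paste0("low_work_", work_wealth)]
    pr <- pr[group %in% c("low_work_high", "low_work_low", "high", "medium")]
  }
  d <- as.data.table(daily)[active == TRUE]
  d <- d[pr[, .(user_id, group, country, unit_id = home_unit_primary)],
         on = "user_id", nomatch = NULL]
  d[, value := switch(indicator,
                      self_isolation = as.numeric(self_isolating),
                      non_commuting = 1 - as.numeric(commuted),
                      minutes_home = minutes_home,
                      minutes_work = minutes_work)]
  d <- d[!is.na(value)]
  if (include_all) d <- rbind(d, copy(d)[, group := "all"])
  ud <- d[, .(value = mean(value), n_users = .N),
          by = .(country, group, unit_id, day)]
  pop <- as.data.table(units)[, .(unit_id, population)]
  ud[pop, population := i.population, on = "unit_id"]
  gs <- ud[, .(level = sum(value * population) / sum(population),
               sem = if (.N > 1) sd(value) / sqrt(.N) else 0,
               n_users = sum(n_users), n_units = .N),
           by = .(country, group, day)]
  base <- gs[day %in% baseline_days,
             .(base_level = mean(level)), by = .(country, group)]
  gs[base, base_level := i.base_level, on = c("country", "group")]
  gs[, rel_change := 100 * (level - base_level) / base_level]
  gs[, date := as_date(origin) + day - 1L]
  setorder(gs, country, group, day)
  if (!is.null(roll)) {
    gs[, rel_roll := data.table::frollmean(rel_change, roll, align = "center"),
       by = .(country, group)]
  }
  setattr(gs, "indicator", indicator)
  setattr(gs, "class", c("mobgap_group_series", class(gs)))
  gs[]
}

#' Net urban-to-rural relocation series per wealth group
#'
#' Per labeling window and group: (urban-to-rural movers minus rural-to-urban
#' movers) divided by the group's urban user count at the observation start.
#' Urban-to-rural events carry the mover's primary-home wealth group;
#' rural-to-urban events the destination unit's group. `cum_excess` cumulates
#' the windowed net flow after subtracting the mean pre-pandemic windowed net
#' flow (removing baseline relocation churn), and `rel_change` expresses each
#' window's net flow relative to that baseline rate.
#'
#' @param relocations,profiles From [build_home_history()].
#' @param units Units with `wealth_group`.
#' @param pandemic_day Day index of the pandemic declaration.
#' @param step_days,window_days As in [label_windows()].
#' @param n_days Days in the observation period.
#' @param baseline "group" normalises each group by its own pre-pandemic net
#'   rate; "pooled" uses the all-user pre-pandemic rate (per urban user) for
#'   every group — groups share baseline churn under the generator, and the
#'   pooled rate is estimated with far less Monte-Carlo noise.
#' @return data.table: per (country, group incl. "all", window) net rates,
#'   cumulative excess share, baseline rate and relative change.
#' @export
net_relocation_series <- function(relocations, profiles, units, pandemic_day,
                                  n_days, step_days = 7L, window_days = 49L,
                                  baseline = c("group", "pooled")) {
  baseline <- match.arg(baseline)
  pr <- as.data.table(profiles)
  rel <- as.data.table(relocations)
  un <- as.data.table(units)
  k <- window_days %/% step_days
  w_max <- n_days %/% step_days
  n0 <- pr[urban_primary == TRUE & !is.na(wealth_group),
           .(n0 = .N), by = .(country, group = as.character(wealth_group))]
  n0 <- rbind(n0, pr[urban_primary == TRUE & !is.na(wealth_group),
                     .(group = "all", n0 = .N), by = country])
  if (nrow(n0) == 0) stop("no urban users with wealth labels")

  if (nrow(rel)) {
    rel[pr, `:=`(country = i.country, grp_origin = as.character(i.wealth_group)),
        on = "user_id"]
    rel[un, grp_dest := as.character(i.wealth_group), on = c(to_unit = "unit_id")]
    ur <- rel[from_urban == TRUE & to_urban == FALSE & !is.na(grp_origin),
              .(n_ur = .N), by = .(country, group = grp_origin, window)]
    ru <- rel[from_urban == FALSE & to_urban == TRUE & !is.na(grp_dest),
              .(n_ru = .N), by = .(country, group = grp_dest, window)]
    ur_all <- rel[from_urban == TRUE & to_urban == FALSE,
                  .(n_ur = .N, group = "all"), by = .(country, window)]
    ru_all <- rel[from_urban == FALSE & to_urban == TRUE,
                  .(n_ru = .N, group = "all"), by = .(country, window)]
    ur <- rbind(ur, ur_all[, .(country, group, window, n_ur)])
    ru <- rbind(ru, ru_all[, .(country, group, window, n_ru)])
  } else {
    ur <- data.table(country = integer(), group = character(),
                     window = integer(), n_ur = integer())
    ru <- data.table(country = integer(), group = character(),
                     window = integer(), n_ru = integer())
  }
  grid <- n0[, CJ(window = seq(k + 1L, w_max)), by = .(country, group)]
  grid[ur, n_ur := i.n_ur, on = c("country", "group", "window")]
  grid[ru, n_ru := i.n_ru, on = c("country", "group", "window")]
  grid[is.na(n_ur), n_ur := 0L]
  grid[is.na(n_ru), n_ru := 0L]
  grid[n0, n0 := i.n0, on = c("country", "group")]
  grid[, net_rate := (n_ur - n_ru) / n0]
  grid[, window_end := window * as.integer(step_days)]
  pre <- grid[window_end <= pandemic_day,
              .(base_rate = sum(n_ur - n_ru) / mean(n0) / .N),
              by = .(country, group)]
  if (baseline == "pooled") {
    pooled <- pre[group == "all", .(country, pooled_rate = base_rate)]
    pre[pooled, base_rate := i.pooled_rate, on = "country"]
  }
  grid[pre, base_rate := i.base_rate, on = c("country", "group")]
  setorder(grid, country, group, window)
  grid[, cum_excess := cumsum(net_rate - base_rate), by = .(country, group)]
  grid[, rel_change := 100 * (net_rate - base_rate) / base_rate]
  grid[]
}

#' Standardised commute-distance distributions
#'
#' Haversine distance between each commuter's primary home and work location
#' centroids; the log distance is standardised within wealth group (mean 0,
#' sd 1), and within (home wealth x workplace wealth) pairing. Zero distances
#' (identical centroids) are excluded with a message.
#'
#' @param profiles Profiles from [build_home_history()].
#' @return data.table with raw `dist_m`, `log_dist` and standardised scores
#'   `z_group` (within home-wealth group) and `z_pair` (within pairing).
#' @export
commute_distance_distribution <- function(profiles) {
  pr <- as.data.table(profiles)
  cm <- pr[commuter == TRUE & !is.na(wealth_group) & !is.na(home_lat) &
             !is.na(work_lat)]
  if (nrow(cm) == 0) stop("no commuters with resolved home and work locations")
  cm[, dist_m := haversine_m(home_lat, home_lon, work_lat, work_lon)]
  n0 <- cm[dist_m == 0, .N]
  if (n0 > 0) {
    message(sprintf("excluding %d commuters with zero home-work distance", n0))
    cm <- cm[dist_m > 0]
  }
  cm[, log_dist := log(dist_m)]
  sds <- cm[, sd(log_dist), by = wealth_group]
  if (any(is.na(sds$V1) | sds$V1 == 0))
    stop("degenerate commute-distance distribution (zero variance in a group)")
  cm[, z_group := (log_dist - mean(log_dist)) / sd(log_dist),
     by = wealth_group]
  cm[, pair := paste0(wealth_group, "_", work_wealth)]
  cm[, z_pair := {
    s <- sd(log_dist)
    if (is.na(s) || s == 0) rep(NA_real_, .N)
    else (log_dist - mean(log_dist)) / s
  }, by = pair]
  cm[, .(user_id, country, group = as.character(wealth_group),
         work_wealth, dist_m, log_dist, z_group, z_pair)]
}

#' Wealth-label reshuffling null model
#'
#' Randomly reassigns users' wealth labels within country (preserving group
#' sizes) and recomputes the group series for each permutation. Under the
#' null, systematic wealth-related differences vanish and every permuted
#' group curve collapses onto the population-average trend; the returned
#' ensemble summary carries the per-day mean and 2.5%/97.5% band.
#'
#' @inheritParams group_series
#' @param n_perm Number of permutations (>= 2).
#' @param seed Integer seed.
#' @return list(`summary` = per (country, group, day) ensemble mean and
#'   quantile band of level and rel_change, `ensemble` = stacked permuted
#'   series with a `perm` column).
#' @export
null_model_reshuffle <- function(daily, profiles, units, origin, baseline_days,
                                 indicator = "self_isolation", n_perm = 20L,
                                 seed = 1L) {
  if (n_perm < 2) stop("n_perm must be >= 2")
  set.seed(seed)
  pr <- as.data.table(profiles)
  out <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    prp <- copy(pr)
    prp[!is.na(wealth_group) & urban_primary == TRUE,
        wealth_group := sample(wealth_group), by = country]
    gs <- group_series(daily, prp, units, origin, baseline_days,
                       indicator = indicator, include_all = FALSE)
    out[[p]] <- gs[, perm := p]
  }
  ens <- rbindlist(out)
  summ <- ens[, .(mean_level = mean(level),
                  mean_rel = mean(rel_change),
                  lo_rel = quantile(rel_change, 0.025, na.rm = TRUE),
                  hi_rel = quantile(rel_change, 0.975, na.rm = TRUE)),
              by = .(country, group, day, date)]
  list(summary = summ[], ensemble = ens[])
}
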