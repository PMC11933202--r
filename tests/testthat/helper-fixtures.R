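# Shared fixture builders and the canonical constants file.

paper_defaults <- yaml::read_yaml(system.file("config", "paper_defaults.yml",
                                              package = "mobgap"))
stage_const <- paper_defaults$stages

# pings for one user at fixed coordinates (numeric seconds)
make_pings <- function(times, lat, lon, acc = 10, user = 1L) {
  n <- length(times)
  data.table::data.table(
    user_id = rep(user, n), t = as.numeric(times),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    accuracy_m = rep_len(acc, n))
}

# displace a WGS84 coordinate by meters (small-offset approximation)
offset_m <- function(lat, lon, north_m, east_m) {
  c(lat = lat + north_m / 110574,
    lon = lon + east_m / (111320 * cos(lat * pi / 180)))
}

# a small world + behaviour for fast simulations
tiny_world <- function(n_users = 200, seed = 1, ...) {
  world_config(n_users = n_users, n_metros_per_country = 2, seed = seed, ...)
}

# run the measurement chain (stops -> locations -> wealth -> labels ->
# profiles -> daily flags) on simulated trajectories; returns the pieces
run_chain <- function(users, world, tr, st = stage_const) {
  wc <- world$config
  origin <- wc$observation_start
  n_days <- as.integer(wc$observation_end - origin) + 1L
  pd <- as.integer(wc$pandemic_date - origin) + 1L
  ev <- suppressMessages(filter_by_accuracy(
    detect_stop_events(tr$pings, st$d_max_m, st$t_min_s),
    st$max_mean_accuracy_m))
  pres <- daily_presence(tr$pings, users, world$countries, origin)
  keep <- filter_active_users(pres, seq_len(n_days), seq_len(pd),
                              st$activity_threshold)
  cl <- cluster_stop_locations(ev[user_id %in% keep], st$eps_m, st$min_samples)
  ed <- stop_event_days(cl$events, users, world$countries, origin)
  lab <- label_windows(ed, pres[user_id %in% keep], n_days, st$window_days,
                       st$step_days, st$min_visit_share, st$work_min_dwell_min)
  wi <- compute_wealth_index(census_table(world))
  u <- data.table::copy(world$units)[wi, wealth_index := i.wealth_index,
                                     on = "unit_id"]
  u <- assign_wealth_groups(classify_urban(u, world$extents),
                            st$high_pop_share, st$low_pop_share)
  h <- suppressMessages(build_home_history(lab, cl$locations, u, users, pd))
  d <- daily_flags(ed, lab, h$profiles, pres[user_id %in% keep], n_days)
  base_days <- seq(as.integer(wc$baseline_start - origin) + 1L, pd)
  list(events = ev, presence = pres, keep = keep, clusters = cl,
       event_days = ed, labels = lab, units = u, history = h, daily = d,
       base_days = base_days, origin = origin, n_days = n_days,
       pandemic_day = pd)
}

mean_rel <- function(gs, grp, from_day) {
  x <- as.data.table(gs)[group == grp & day > from_day, rel_change]
  mean(x, na.rm = TRUE)
}
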