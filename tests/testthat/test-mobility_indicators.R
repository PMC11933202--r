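# compact constructed fixtures for the indicator layer
mk_daily <- function(n_users, n_days, p_si, commuted = NA) {
  d <- data.table::CJ(user_id = seq_len(n_users), day = seq_len(n_days))
  d[, `:=`(active = TRUE,
           self_isolating = runif(.N) < p_si,
           commuted = if (is.na(commuted)) NA else runif(.N) < commuted,
           minutes_home = 900 + rnorm(.N, 0, 30),
           minutes_work = 0)]
  d
}
mk_profiles <- function(n_users, groups, units) {
  data.table::data.table(
    user_id = seq_len(n_users), country = 1L,
    wealth_group = rep_len(groups, n_users),
    home_unit_primary = rep_len(units, n_users),
    urban_primary = TRUE, commuter = FALSE,
    work_wealth = NA_character_, home_lat = 10, home_lon = 20,
    work_lat = NA_real_, work_lon = NA_real_)
}
mk_units <- function(ids, pop) data.table::data.table(
  unit_id = ids, population = pop)

test_that("constant behaviour gives zero relative change and share invariance", {
  set.seed(1)
  d <- mk_daily(200, 120, p_si = 0.3)
  pr <- mk_profiles(200, c("high", "low"), c("u1", "u2", "u3", "u4"))
  un <- mk_units(c("u1", "u2", "u3", "u4"), c(10, 20, 30, 40))
  gs <- group_series(d, pr, un, "2020-01-01", 1:40, "self_isolation",
                     include_all = TRUE)
  expect_true(all(abs(gs[, mean(rel_change), by = group]$V1) < 8))
  # doubling every user leaves group levels unchanged
  d2 <- rbind(d, data.table::copy(d)[, user_id := user_id + 200L])
  pr2 <- rbind(pr, data.table::copy(pr)[, user_id := user_id + 200L])
  gs2 <- group_series(d2, pr2, un, "2020-01-01", 1:40, "self_isolation")
  m <- merge(gs[group != "all"], gs2, by = c("country", "group", "day"))
  expect_equal(mean(abs(m$level.x - m$level.y)), 0, tolerance = 0.05)
})

test_that("group levels conserve the population-weighted all-user level", {
  set.seed(2)
  d <- mk_daily(300, 60, p_si = 0.4)
  pr <- mk_profiles(300, c("high", "medium", "low"),
                    c("u1", "u2", "u3", "u4", "u5", "u6"))
  un <- mk_units(sprintf("u%d", 1:6), c(5, 10, 15, 20, 25, 30))
  gs <- group_series(d, pr, un, "2020-01-01", 1:20, "self_isolation",
                     include_all = TRUE)
  # units are nested in groups, so the all-user level equals the
  # population-weighted mean of group levels, day by day
  wts <- data.table::data.table(
    group = c("high", "medium", "low"),
    w = c(5 + 20, 10 + 25, 15 + 30))  # unit pops per group (u1,u4 | u2,u5 | u3,u6)
  g3 <- gs[group != "all"][wts, on = "group"]
  agg <- g3[, .(lvl = sum(level * w) / sum(w)), by = day]
  allg <- gs[group == "all", .(day, level)]
  m <- merge(agg, allg, by = "day")
  expect_equal(m$lvl, m$level, tolerance = 1e-12)
})

test_that("self-isolation and commuting are mutually exclusive flags", {
  wc <- tiny_world(n_users = 150, seed = 19)
  w <- generate_world(wc)
  bc <- behavior_config(); ec <- emission_config()
  users <- generate_population(w, bc, seed = 19)
  tr <- simulate_trajectories(users, w, bc, ec, seed = 19)
  ch <- run_chain(users, w, tr)
  expect_equal(ch$daily[self_isolating == TRUE & commuted == TRUE, .N], 0L)
  # group-day with no active users is missing, not zero
  gs <- group_series(ch$daily, ch$history$profiles, ch$units, ch$origin,
                     ch$base_days, "self_isolation")
  expect_true(all(gs$n_users > 0))
})

test_that("relative-change series are invariant to a uniform date shift", {
  set.seed(3)
  d <- mk_daily(100, 80, p_si = 0.25)
  d[day > 40, self_isolating := runif(.N) < 0.5]
  pr <- mk_profiles(100, "high", "u1")
  un <- mk_units("u1", 10)
  gs1 <- group_series(d, pr, un, "2020-01-01", 1:40, "self_isolation")
  d2 <- data.table::copy(d)[, day := day + 30L]
  gs2 <- group_series(d2, pr, un, "2020-01-01", 31:70, "self_isolation")
  gap1 <- gs1[day > 40, mean(rel_change)]
  gap2 <- gs2[day > 70, mean(rel_change)]
  expect_equal(gap1, gap2, tolerance = 1e-9)
})

test_that("net relocation cancels under symmetric churn and is zero without churn", {
  mkrel <- function(n_ur, n_ru, windows) {
    rbind(
      data.table::data.table(user_id = seq_len(n_ur), window = windows[1],
                             window_end = windows[1] * 7L,
                             from_unit = "uu", to_unit = "ru",
                             from_urban = TRUE, to_urban = FALSE),
      data.table::data.table(user_id = 400L + seq_len(n_ru),
                             window = windows[2], window_end = windows[2] * 7L,
                             from_unit = "ru", to_unit = "uu",
                             from_urban = FALSE, to_urban = TRUE))
  }
  pr <- mk_profiles(500, c("high", "low"), "uu")
  un <- data.table::data.table(unit_id = c("uu", "ru"),
                               population = c(100, 10),
                               wealth_group = factor(c("high", NA),
                                                     c("high", "medium", "low")),
                               urban = c(TRUE, FALSE))
  rel <- mkrel(12, 12, c(20, 21))
  nr <- net_relocation_series(rel, pr, un, 75, 366)
  expect_equal(nr[group == "all", sum(n_ur - n_ru)], 0L)
  expect_equal(nr[group == "all", max(abs(cum_excess))], 12 / 500,
               tolerance = 1e-12)  # transient, then cancels
  expect_equal(nr[group == "all"][window == max(window), cum_excess], 0,
               tolerance = 1e-12)
  # no relocation at all: flat zero series
  nr0 <- net_relocation_series(rel[0], pr, un, 75, 366)
  expect_true(all(nr0$net_rate == 0))
  expect_true(all(nr0$cum_excess == 0))
})

test_that("commute distances standardise to mean 0, sd 1 per group", {
  set.seed(5)
  n <- 120
  pr <- mk_profiles(n, c("high", "low"), "u1")
  pr[, `:=`(commuter = TRUE, work_wealth = rep_len(c("high", "low"), n),
            work_lat = 10 + runif(n, 0.01, 0.2), work_lon = 20)]
  cd <- suppressMessages(commute_distance_distribution(pr))
  st <- cd[, .(m = mean(z_group), s = sd(z_group)), by = group]
  expect_equal(st$m, c(0, 0), tolerance = 1e-9)
  expect_equal(st$s, c(1, 1), tolerance = 1e-9)
  # all identical distances: degenerate
  pr2 <- data.table::copy(pr)[, `:=`(work_lat = 10.1, work_lon = 20)]
  expect_error(suppressMessages(commute_distance_distribution(pr2)),
               "degenerate")
})

test_that("low-home/high-work commutes are longer than low-home/low-work", {
  wc <- tiny_world(n_users = 1200, seed = 23)
  w <- generate_world(wc)
  bc <- behavior_config()
  users <- generate_population(w, bc, seed = 23)
  # geometry of the synthetic metro: high-wealth units are central, low-wealth
  # peripheral, so low-home commuters to high-wealth units travel farther
  cm <- users[commuter == TRUE & group_true == "low" &
                !is.na(work_wealth_true)]
  d <- haversine_m(cm$home_lat, cm$home_lon, cm$work_lat, cm$work_lon)
  expect_gt(median(d[cm$work_wealth_true == "high"]),
            median(d[cm$work_wealth_true == "low"]))
})

test_that("label reshuffling collapses group curves onto the population mean", {
  wc <- tiny_world(n_users = 500, seed = 29)
  w <- generate_world(wc)
  bc <- behavior_config(); ec <- emission_config()
  users <- generate_population(w, bc, seed = 29)
  tr <- simulate_trajectories(users, w, bc, ec, seed = 29)
  ch <- run_chain(users, w, tr)
  gs <- group_series(ch$daily, ch$history$profiles, ch$units, ch$origin,
                     ch$base_days, "self_isolation", include_all = TRUE)
  nm <- null_model_reshuffle(ch$daily, ch$history$profiles, ch$units,
                             ch$origin, ch$base_days, n_perm = 8, seed = 1)
  post <- merge(nm$summary[day > ch$pandemic_day],
                gs[group == "all", .(day, all_rel = rel_change)], by = "day")
  # permuted group means track the population-average trend far more closely
  # than the real (planted) groups separate from it
  dev_null <- post[, mean(abs(mean_rel - all_rel))]
  real_gap <- abs(mean_rel(gs, "high", ch$pandemic_day) -
                    mean_rel(gs, "low", ch$pandemic_day))
  expect_lt(dev_null, real_gap / 4)
  # ensemble is reproducible under the same seed
  nm2 <- null_model_reshuffle(ch$daily, ch$history$profiles, ch$units,
                              ch$origin, ch$base_days, n_perm = 8, seed = 1)
  expect_identical(nm$summary, nm2$summary)
  expect_error(null_model_reshuffle(ch$daily, ch$history$profiles, ch$units,
                                    ch$origin, ch$base_days, n_perm = 1),
               "n_perm")
})

test_that("raising the planted stay-home effect raises the measured change", {
  rels <- c(60, 150, 252)
  got <- vapply(seq_along(rels), function(i) {
    wc <- tiny_world(n_users = 350, seed = 40 + i)
    w <- generate_world(wc)
    bc <- behavior_config(rel_selfisolate = c(high = rels[i], medium = 50,
                                              low = 40))
    ec <- emission_config()
    users <- generate_population(w, bc, seed = 40 + i)
    tr <- simulate_trajectories(users, w, bc, ec, seed = 40 + i)
    ch <- run_chain(users, w, tr)
    gs <- group_series(ch$daily, ch$history$profiles, ch$units, ch$origin,
                       ch$base_days, "self_isolation")
    mean_rel(gs, "high", ch$pandemic_day)
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})
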