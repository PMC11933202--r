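#' Planted behavioural effects per wealth group
#'
#' The generator is parameterised directly in terms of the *period-averaged
#' relative changes* of each mobility indicator over the post-declaration
#' window, so planted values are the literal ground truth the pipeline should
#' recover. Post-pandemic effects follow an exponential relaxation toward
#' pre-pandemic levels (halflife `recovery_halflife_days`) whose shape is
#' mean-normalised over the post window: the planted period average is
#' preserved exactly while the trajectory peaks early and decays, and the
#' between-group gap persists throughout.
#'
#' @param p_selfisolate_pre Daily probability of an all-day stay-at-home
#'   (identical across groups pre-pandemic).
#' @param rel_selfisolate Named vector (high/medium/low): planted
#'   period-averaged % change of the self-isolating share.
#' @param rel_noncommute Named vector (high/medium): planted period-averaged %
#'   change of the non-commuting share among commuters.
#' @param rel_noncommute_low_by_work Named vector (high/low): the same, for
#'   low-wealth-home commuters split by workplace wealth.
#' @param frac_low_home_high_work Share of low-wealth-home commuters whose
#'   workplace is in a high-wealth unit (the rest work in low-wealth units).
#' @param commuter_fraction Fraction of urban users with a workplace.
#' @param rel_minutes_home Named vector (high/medium/low): planted
#'   period-averaged % change of daily minutes spent at home.
#' @param other_duration_pre_min Pre-pandemic duration of the daily
#'   out-of-home "other" visit, minutes.
#' @param commute_leave_min,commute_return_min Local minutes at which
#'   commuters leave/return home on commuting days.
#' @param transit_min One-way transit duration, minutes (transit pings never
#'   form stops and are not emitted).
#' @param recovery_halflife_days Relaxation halflife of all planted effects.
#' @param relocation_baseline_weekly Named vector: baseline weekly probability
#'   of moving home `urban_rural` (urban residents) and `rural_urban` (rural
#'   residents).
#' @param rel_relocation Named vector (high/medium/low): planted % change,
#'   relative to the baseline net urban-to-rural flow rate, of each group's
#'   net flow averaged over the first `relocation_window_weeks` pandemic
#'   weeks.
#' @param relocation_halflife_days Front-loading halflife of pandemic-era
#'   moves (relocations concentrate in the first pandemic weeks).
#' @param relocation_window_weeks Length of the planted relocation window.
#' @param penetration_weight Named sampling weights (high/medium/low/rural)
#'   reproducing wealth-biased device ownership.
#' @param policy_effects Optional data.frame (`group`, `work_wealth`, `index_name`,
#'   `beta`) adding `beta * policy_index(t)` to the daily stop-commuting
#'   probability of that (group, workplace-wealth) stratum, coupling policy
#'   series into simulated behaviour for regression-recovery experiments.
#' @return A list of class `mobgap_behavior_config`.
#' @export
behavior_config <- function(
    p_selfisolate_pre = 0.15,
    rel_selfisolate = c(high = 252, medium = 195, low = 141),
    rel_noncommute = c(high = 93.5, medium = 78),
    rel_noncommute_low_by_work = c(high = 82, low = 45),
    frac_low_home_high_work = 0.5,
    commuter_fraction = 0.26,
    rel_minutes_home = c(high = 19, medium = 16, low = 13),
    other_duration_pre_min = 360,
    commute_leave_min = 480, commute_return_min = 1080, transit_min = 30,
    recovery_halflife_days = 300,
    relocation_baseline_weekly = c(urban_rural = 2e-4, rural_urban = 1e-4),
    rel_relocation = c(high = 70, medium = 45, low = 21),
    relocation_halflife_days = 10,
    relocation_window_weeks = 13,
    penetration_weight = c(high = 5, medium = 1.3, low = 0.7, rural = 0.5),
    policy_effects = NULL) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_selfisolate_pre, cfg$commuter_fraction,
             cfg$frac_low_home_high_work, cfg$relocation_baseline_weekly)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$penetration_weight <= 0)) stop("penetration weights must be > 0")
  class(cfg) <- "mobgap_behavior_config"
  cfg
}

#' Ping-emission configuration
#'
#' Controls how occupancy is turned into GPS pings. Every occupancy interval
#' emits anchor pings at its start and end (location-update-on-transition
#' behaviour typical of SDK feeds) plus a Poisson stream at `pings_per_hour`
#' inside the interval. Positions are jittered isotropically; accuracy values
#' are lognormal. A fraction `frac_low_accuracy` of intervals is emitted with
#' accuracy inflated past the 100 m quality cutoff to exercise the accuracy
#' filter (0 by default).
#'
#' @param pings_per_hour Poisson rate of in-interval pings.
#' @param accuracy_log_mean,accuracy_log_sd Lognormal accuracy parameters
#'   (meters).
#' @param jitter_sd_m Isotropic positional noise, meters.
#' @param p_active_day Probability a device reports at all on a given day.
#' @param frac_low_accuracy Fraction of occupancy intervals emitted with
#'   accuracy inflated above the quality cutoff.
#' @return A list of class `mobgap_emission_config`.
#' @export
emission_config <- function(pings_per_hour = 0.5,
                            accuracy_log_mean = log(20), accuracy_log_sd = 0.5,
                            jitter_sd_m = 5, p_active_day = 0.9,
                            frac_low_accuracy = 0) {
  cfg <- as.list(environment())
  if (cfg$pings_per_hour <= 0) stop("pings_per_hour must be > 0")
  if (cfg$p_active_day < 0 || cfg$p_active_day > 1 ||
      cfg$frac_low_accuracy < 0 || cfg$frac_low_accuracy > 1)
    stop("fractions must lie in [0, 1]")
  class(cfg) <- "mobgap_emission_config"
  cfg
}

# ground-truth wealth grouping of units from the latent score (the same
# cumulative-population rule the pipeline applies to the PCA index)
true_unit_groups <- function(world) {
  u <- copy(world$units)
  u[, wealth_index := latent_wealth]
  assign_wealth_groups(u)[, .(unit_id, group_true = as.character(wealth_group))]
}

#' Generate the synthetic user population
#'
#' Samples each user's true home unit proportionally to unit population times
#' the wealth-specific device-penetration weight (reproducing the
#' over-representation of wealthy neighbourhoods in commercial GPS feeds),
#' assigns a workplace to a `commuter_fraction` of urban users, and records
#' the planted ground truth (wealth group of the home unit, workplace wealth).
#' Low-wealth-home commuters work in a high-wealth unit with probability
#' `frac_low_home_high_work`, in a low-wealth unit otherwise; other commuters
#' draw a workplace from all urban units proportionally to population.
#'
#' @param world A `mobgap_world`.
#' @param behavior A [behavior_config()].
#' @param seed Integer seed.
#' @param n_users Number of users; defaults to the world config value.
#' @return data.table, one row per user, with home/work units and coordinates
#'   and planted truth columns (`group_true`, `work_wealth_true`, `commuter`).
#' @export
generate_population <- function(world, behavior, seed = 1L, n_users = NULL) {
  stopifnot(inherits(world, "mobgap_world"),
            inherits(behavior, "mobgap_behavior_config"))
  set.seed(seed)
  n_users <- as.integer(n_users %||% world$config$n_users)
  units <- copy(world$units)
  tg <- true_unit_groups(world)
  units[tg, group_true := i.group_true, on = "unit_id"]
  units[is.na(group_true), group_true := "rural"]
  w <- units$population * behavior$penetration_weight[units$group_true]
  idx <- sample.int(nrow(units), n_users, replace = TRUE, prob = w)
  hu <- units[idx]
  users <- data.table(
    user_id = seq_len(n_users),
    country = hu$country,
    home_unit = hu$unit_id,
    home_lat = runif(n_users, hu$lat0, hu$lat1),
    home_lon = runif(n_users, hu$lon0, hu$lon1),
    group_true = hu$group_true,
    urban_true = hu$urban)
  users[, commuter := urban_true & runif(.N) < behavior$commuter_fraction]
  users[, `:=`(work_unit = NA_character_, work_wealth_true = NA_character_,
               work_lat = NA_real_, work_lon = NA_real_)]
  urb <- units[urban == TRUE]
  for (ci in world$countries$country) {
    uc <- urb[country == ci]
    ids <- users[commuter == TRUE & country == ci, user_id]
    if (!length(ids)) next
    grp <- users[user_id %in% ids, group_true]
    pick <- integer(length(ids))
    is_low <- grp == "low"
    if (any(is_low)) {
      to_high <- runif(sum(is_low)) < behavior$frac_low_home_high_work
      pool_h <- which(uc$group_true == "high")
      pool_l <- which(uc$group_true == "low")
      low_pick <- integer(sum(is_low))
      if (any(to_high))
        low_pick[to_high] <- resample(pool_h, sum(to_high),
                                      prob = uc$population[pool_h])
      if (any(!to_high))
        low_pick[!to_high] <- resample(pool_l, sum(!to_high),
                                       prob = uc$population[pool_l])
      pick[is_low] <- low_pick
    }
    if (any(!is_low))
      pick[!is_low] <- resample(seq_len(nrow(uc)), sum(!is_low),
                                prob = uc$population)
    wu <- uc[pick]
    users[user_id %in% ids,
          `:=`(work_unit = wu$unit_id,
               work_wealth_true = wu$group_true,
               work_lat = runif(.N, wu$lat0, wu$lat1),
               work_lon = runif(.N, wu$lon0, wu$lon1))]
  }
  users[]
}

# sample() with safe single-element pools
resample <- function(pool, n, prob = NULL) {
  if (length(pool) == 0) stop("empty sampling pool")
  if (length(pool) == 1) return(rep(pool, n))
  pool[sample.int(length(pool), n, replace = TRUE, prob = prob)]
}
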