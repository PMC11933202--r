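#' Generate synthetic policy stringency and case-incidence series
#'
#' Per country and day: five containment-policy stringency indices in [0, 1]
#' (school closure, workplace closure, public-transport closure, internal
#' movement restrictions, stay-at-home orders) as step functions, and smooth
#' local/global epidemic curves. Enactments cluster in a short window after
#' the pandemic declaration (policies were near-synchronous at first), while
#' relaxations and second-wave re-tightenings are drawn with wide
#' country-specific jitter, so the post-first-month period carries the
#' cross-country variation the panel regression exploits.
#'
#' @param world A `mobgap_world`.
#' @param seed Integer seed.
#' @param policy_names Names of the five policy indices.
#' @return A list with `policy` (long table `country`, `date`, `index_name`,
#'   `value`) and `incidence` (`country`, `date`, `incidence_local`,
#'   `incidence_global`).
#' @export
generate_policy_incidence <- function(world, seed = 1L,
                                      policy_names = c("school_closure",
                                                       "workplace_closure",
                                                       "transport_closure",
                                                       "internal_movement",
                                                       "stay_at_home")) {
  stopifnot(inherits(world, "mobgap_world"))
  set.seed(seed)
  cfg <- world$config
  origin <- cfg$observation_start
  n_days <- as.integer(cfg$observation_end - origin) + 1L
  pd <- day_index(cfg$pandemic_date, origin)
  days <- seq_len(n_days)
  pol_list <- vector("list", 0L)
  inc_list <- vector("list", 0L)
  for (ci in world$countries$country) {
    for (pn in policy_names) {
      enact <- pd + sample(-7:10, 1)
      lvl <- runif(1, 0.6, 1)
      relax <- enact + sample(60:150, 1)
      lvl2 <- lvl * runif(1, 0.25, 0.7)
      wave2 <- relax + sample(40:120, 1)
      lvl3 <- pmin(1, lvl2 + runif(1, 0.1, 0.5))
      v <- numeric(n_days)
      v[days >= enact & days < relax] <- lvl
      v[days >= relax & days < wave2] <- lvl2
      v[days >= wave2] <- lvl3
      pol_list[[length(pol_list) + 1L]] <-
        data.table(country = ci, day = days, index_name = pn, value = v)
    }
    p1 <- pd + sample(20:60, 1)
    p2 <- p1 + sample(120:200, 1)
    a1 <- runif(1, 50, 200); a2 <- a1 * runif(1, 0.8, 2.5)
    local <- a1 * exp(-(days - p1)^2 / (2 * 25^2)) +
      a2 * exp(-(days - p2)^2 / (2 * 40^2))
    inc_list[[length(inc_list) + 1L]] <-
      data.table(country = ci, day = days, incidence_local = local)
  }
  policy <- rbindlist(pol_list)
  incidence <- rbindlist(inc_list)
  glob <- incidence[, .(incidence_global = mean(incidence_local)), by = day]
  incidence[glob, incidence_global := i.incidence_global, on = "day"]
  policy[, date := as_date(origin) + day - 1L]
  incidence[, date := as_date(origin) + day - 1L]
  list(policy = policy[, .(country, date, index_name, value)],
       incidence = incidence[, .(country, date, incidence_local,
                                 incidence_global)])
}
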