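# shared 6-country policy/incidence world for panel tests
panel_world <- function(seed = 1) {
  w <- generate_world(world_config(n_countries = 6, n_metros_per_country = 1,
                                   n_users = 10, seed = seed))
  generate_policy_incidence(w, seed = seed)
}

test_that("panel assembly standardizes within country and honours the window", {
  pi_ <- panel_world(2)
  coefs <- c(incidence_g = 0.3, incidence_c = 0.1, school_closure = 0.15,
             workplace_closure = 0.2, transport_closure = 0.1,
             internal_movement = 0.12, stay_at_home = 0)
  s <- simulate_panel_outcome(pi_, coefs, seed = 2)
  p <- build_panel(s, pi_)
  expect_s3_class(p, "mobgap_panel")
  expect_equal(min(p$date), as.Date("2020-04-11"))
  expect_equal(max(p$date), as.Date("2020-12-31"))
  st <- p[, .(m = mean(mb), s = sd(mb)), by = country]
  expect_equal(st$m, rep(0, 6), tolerance = 1e-9)
  expect_equal(st$s, rep(1, 6), tolerance = 1e-9)
  for (cl in c("incidence_g", "transport_closure"))
    expect_equal(p[, mean(.SD[[1]]), .SDcols = cl, by = country]$V1,
                 rep(0, 6), tolerance = 1e-9)
  # a covariate that is constant over the window is excluded with a warning
  pi2 <- pi_
  pi2$policy <- data.table::copy(pi_$policy)[index_name == "stay_at_home",
                                             value := 0.5]
  expect_warning(p2 <- build_panel(s, pi2), "stay_at_home")
  expect_false("stay_at_home" %in% names(p2))
})

test_that("VIF matches its closed form and fails at the inclusive boundary", {
  set.seed(7)
  n <- 400
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(lm(z ~ x))                   # exactly orthogonal
  x <- (x - mean(x)) / sd(x); z <- (z - mean(z)) / sd(z)
  v0 <- vif_screen(cbind(a = x, b = z))
  expect_equal(unname(v0$vif), c(1, 1), tolerance = 1e-9)
  expect_true(v0$pass)
  # empirical correlation exactly 0.9 -> VIF = 1/(1-0.81) = 5.263...
  y <- 0.9 * x + sqrt(1 - 0.81) * z
  v1 <- vif_screen(cbind(a = x, b = y))
  expect_equal(unname(v1$vif), rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_false(v1$pass)
  # boundary: R^2 = 0.75 gives VIF exactly 4, which fails (VIF >= 4)
  y2 <- sqrt(0.75) * x + sqrt(0.25) * z
  v2 <- vif_screen(cbind(a = x, b = y2))
  expect_equal(unname(v2$vif), c(4, 4), tolerance = 1e-6)
  expect_false(v2$pass)
  expect_equal(unname(vif_screen(cbind(a = x))$vif), 1)
})

test_that("the group fit equals the normal-equations oracle", {
  pi_ <- panel_world(3)
  coefs <- c(incidence_g = 0.25, incidence_c = 0.1, transport_closure = 0.2,
             school_closure = 0.1, workplace_closure = 0.15,
             internal_movement = 0.05, stay_at_home = -0.05)
  s <- simulate_panel_outcome(pi_, coefs, seed = 3)
  p <- build_panel(s, pi_)
  f <- fit_group_model(p)
  covs <- setdiff(names(p), c("country", "group", "date", "mb"))
  want <- oracle_panel_fit(p, covs)
  expect_equal(f$coefficients$estimate, unname(want[f$coefficients$term]),
               tolerance = 1e-8)
  # rank-deficient design raises and names the collinear column
  p2 <- data.table::copy(p)[, dup := transport_closure]
  expect_error(fit_group_model(p2), "collinear")
})

test_that("planted coefficients are recovered with near-nominal CI coverage", {
  pi_ <- panel_world(5)
  truth <- c(incidence_g = 0.3, incidence_c = 0.1, school_closure = 0.15,
             workplace_closure = 0.2, transport_closure = 0.1,
             internal_movement = 0.12, stay_at_home = 0)
  nrep <- 40
  cover <- matrix(FALSE, nrep, length(truth),
                  dimnames = list(NULL, names(truth)))
  est_tr <- numeric(nrep)
  for (r in seq_len(nrep)) {
    s <- simulate_panel_outcome(pi_, truth, seed = 100 + r)
    f <- fit_group_model(build_panel(s, pi_))
    ct <- f$coefficients
    cover[r, ct$term] <- truth[ct$term] >= ct$ci_lo & truth[ct$term] <= ct$ci_hi
    est_tr[r] <- ct[term == "transport_closure", estimate]
  }
  expect_gte(mean(cover[, "transport_closure"]), 0.85)
  expect_gte(mean(cover), 0.85)
  expect_lt(abs(mean(est_tr) - 0.10), 0.02)
  # pure-noise outcome: the CIs cover zero at roughly the nominal rate
  cover0 <- vapply(1:30, function(r) {
    s <- simulate_panel_outcome(pi_, truth * 0, seed = 500 + r)
    f <- fit_group_model(build_panel(s, pi_))
    mean(f$coefficients$ci_lo <= 0 & f$coefficients$ci_hi >= 0)
  }, numeric(1))
  expect_gte(mean(cover0), 0.85)
})

test_that("coefficients are invariant to affine rescaling of raw covariates", {
  pi_ <- panel_world(6)
  coefs <- c(incidence_g = 0.2, transport_closure = 0.15)
  s <- simulate_panel_outcome(pi_, coefs, seed = 6)
  f1 <- fit_group_model(build_panel(s, pi_))
  pi2 <- list(policy = data.table::copy(pi_$policy)[, value := 100 * value + 3],
              incidence = data.table::copy(pi_$incidence)[,
                incidence_local := incidence_local / 7 + 2])
  f2 <- fit_group_model(build_panel(s, pi2))
  m <- merge(f1$coefficients, f2$coefficients, by = "term")
  expect_equal(m$estimate.x, m$estimate.y, tolerance = 1e-9)
})

test_that("BIC selection finds the planted model and penalises irrelevance", {
  pi_ <- panel_world(8)
  truth <- c(incidence_g = 0.35, transport_closure = 0.25,
             internal_movement = 0.2)
  hits <- 0; nrep <- 10
  for (r in seq_len(nrep)) {
    s <- simulate_panel_outcome(pi_, truth, seed = 300 + r)
    p <- build_panel(s, pi_)
    sel <- select_model_bic(p)
    terms <- sel$best$coefficients$term
    if (all(c("incidence_g", "transport_closure", "internal_movement")
            %in% terms) && !"incidence_c" %in% terms)
      hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.7)
  # adding an irrelevant covariate increases BIC in expectation
  dbic <- vapply(1:10, function(r) {
    s <- simulate_panel_outcome(pi_, truth, seed = 400 + r)
    p <- build_panel(s, pi_)
    f_true <- fit_group_model(p, covariates = names(truth))
    f_plus <- fit_group_model(p, covariates = c(names(truth), "incidence_c"))
    f_plus$bic - f_true$bic
  }, numeric(1))
  expect_gt(mean(dbic), 0)
  # a duplicated covariate fails the VIF screen and is excluded from selection
  s <- simulate_panel_outcome(pi_, truth, seed = 999)
  p <- build_panel(s, pi_)
  p2 <- data.table::copy(p)[, dup := transport_closure]
  data.table::setattr(p2, "class", class(p))
  sel2 <- select_model_bic(p2, candidates = list(
    c("transport_closure", "dup"), c("incidence_g", "transport_closure")))
  expect_false("dup" %in% sel2$best$coefficients$term)
  expect_true(any(!sel2$table$pass))
})

test_that("leave-one-country-out refits keep coefficient signs", {
  pi_ <- panel_world(9)
  truth <- c(incidence_g = 0.3, transport_closure = 0.25)
  s <- simulate_panel_outcome(pi_, truth, seed = 9)
  p <- build_panel(s, pi_)
  full <- fit_group_model(p)
  sgn <- sign(full$coefficients[term %in% names(truth), estimate])
  for (cc in unique(p$country)) {
    f <- fit_group_model(p[country != cc])
    expect_equal(sign(f$coefficients[term %in% names(truth), estimate]), sgn)
  }
})

test_that("a policy effect planted in behaviour shifts commuting on enactment days", {
  wc <- tiny_world(n_users = 250, seed = 31)
  w <- generate_world(wc)
  pi_ <- generate_policy_incidence(w, seed = 31)
  pe <- data.frame(group = "low", work_wealth = "high",
                   index_name = "transport_closure", beta = 0.5)
  bc <- behavior_config(policy_effects = pe)
  ec <- emission_config()
  users <- generate_population(w, bc, seed = 31)
  tr <- simulate_trajectories(users, w, bc, ec, seed = 31,
                              policy = pi_$policy)
  tr0 <- simulate_trajectories(users, w, behavior_config(), ec, seed = 31)
  rt <- merge(tr$routines, tr0$routines, by = c("user_id", "day"))
  aff <- users[commuter == TRUE & group_true == "low" &
                 work_wealth_true == "high", user_id]
  pol <- data.table::as.data.table(pi_$policy)[index_name == "transport_closure"]
  pol[, day := as.integer(date - as.Date("2020-01-01")) + 1L]
  on_days <- pol[value > 0.5 & country == 1, day]
  r_aff <- rt[user_id %in% aff & day %in% on_days]
  # with the planted coupling, affected commuters commute strictly less
  expect_lt(mean(r_aff$routine.x == "commute"),
            mean(r_aff$routine.y == "commute"))
  unaff <- users[commuter == TRUE & group_true == "low" &
                   work_wealth_true == "low", user_id]
  r_un <- rt[user_id %in% unaff & day %in% on_days]
  expect_equal(mean(r_un$routine.x == "commute"),
               mean(r_un$routine.y == "commute"), tolerance = 0.08)
})
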