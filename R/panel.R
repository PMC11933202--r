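#' Assemble the standardized policy-regression panel
#'
#' Joins a daily group mobility series with policy stringency indices and
#' local/global case incidence over the estimation window, and standardizes
#' outcome and covariates to mean 0, sd 1 within (group, country) over that
#' window. Days with a missing outcome are dropped listwise; covariates with
#' zero variance in the window are excluded with a warning.
#'
#' @param series A `mobgap_group_series` (daily `rel_change`/`level` per
#'   country and group) or any table with `country`, `group`, `date` and an
#'   outcome column.
#' @param policy_incidence Output of [generate_policy_incidence()] or a list
#'   with compatible `policy` and `incidence` tables.
#' @param window Date vector `c(start, end)` of the estimation window
#'   (default April 11 to December 31, 2020).
#' @param outcome Name of the outcome column in `series` (default
#'   "rel_change").
#' @param lag Days by which policy/incidence covariates lead the outcome
#'   (default 0: contemporaneous indices).
#' @return data.table of class `mobgap_panel`: one row per (group, country,
#'   date) with standardized `mb`, `incidence_g`, `incidence_c` and one
#'   standardized column per policy index.
#' @export
build_panel <- function(series, policy_incidence,
                        window = c("2020-04-11", "2020-12-31"),
                        outcome = "rel_change", lag = 0L) {
  s <- as.data.table(series)
  if (!all(c("country", "group", "date") %in% names(s)))
    stop("series needs country, group, date columns")
  w0 <- as_date(window[1]); w1 <- as_date(window[2])
  if (w0 > w1) stop("empty estimation window")
  pol <- data.table::dcast(as.data.table(policy_incidence$policy),
                           country + date ~ index_name, value.var = "value")
  inc <- as.data.table(policy_incidence$incidence)
  cov <- inc[pol, on = c("country", "date")]
  if (lag != 0) cov[, date := date + as.integer(lag)]
  p <- s[, c("country", "group", "date", outcome), with = FALSE]
  setnames(p, outcome, "mb")
  p <- p[cov, on = c("country", "date"), nomatch = NULL]
  p <- p[date >= w0 & date <= w1 & !is.na(mb)]
  if (nrow(p) == 0) stop("empty estimation window")
  setnames(p, c("incidence_global", "incidence_local"),
           c("incidence_g", "incidence_c"))
  covs <- setdiff(names(p), c("country", "group", "date", "mb"))
  zv <- character()
  for (cl in c("mb", covs)) {
    p[, (cl) := {
      s_ <- sd(.SD[[1]]); m_ <- mean(.SD[[1]])
      if (is.na(s_) || s_ == 0) rep(NA_real_, .N) else (.SD[[1]] - m_) / s_
    }, by = .(group, country), .SDcols = cl]
    if (cl != "mb" && all(is.na(p[[cl]]))) zv <- c(zv, cl)
  }
  # a covariate constant in one country but not others: drop the whole column
  part <- covs[vapply(covs, function(cl) anyNA(p[[cl]]), TRUE)]
  zv <- union(zv, part)
  if (length(zv)) {
    warning("excluding zero-variance covariate(s): ",
            paste(zv, collapse = ", "))
    p[, (zv) := NULL]
  }
  p <- p[!is.na(mb)]
  setattr(p, "covariates", setdiff(covs, zv))
  setattr(p, "class", c("mobgap_panel", class(p)))
  p[]
}

#' Variance inflation factors of a design matrix
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on the remaining
#' covariates. The screen fails if any VIF is >= `threshold` (boundary
#' inclusive).
#'
#' @param design Numeric matrix or data.frame of covariates.
#' @param threshold Failure threshold (default 4).
#' @return list(`vif` = named vector, `pass` = logical).
#' @export
vif_screen <- function(design, threshold = 4) {
  X <- as.matrix(design)
  k <- ncol(X)
  if (k == 1) return(list(vif = setNames(1, colnames(X)), pass = TRUE))
  vif <- vapply(seq_len(k), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  list(vif = vif, pass = all(vif < threshold))
}

#' Fit the group-specific pooled panel regression
#'
#' Least-squares fit of
#' `mb(t) = a * incidence_g(t) + b * incidence_c(t) + sum_n c_n * C_n(t)`
#' pooling countries, with country fixed effects absorbed by within-country
#' demeaning and standard errors clustered by country. All variables enter
#' standardized (see [build_panel()]), so coefficients are comparable across
#' groups and invariant to affine rescaling of the raw covariates.
#'
#' @param panel A `mobgap_panel`, already filtered to one group (or pass
#'   `group`).
#' @param group Optional group label to filter on.
#' @param covariates Covariate columns to include (default: all in the panel).
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return list of class `mobgap_fit`: `coefficients` table (estimate,
#'   clustered se, CI bounds), `bic`, `vif`, `n`, `fit` (the lm object on
#'   demeaned data) and the estimation window.
#' @export
fit_group_model <- function(panel, group = NULL, covariates = NULL,
                            conf_level = 0.95) {
  p <- as.data.table(panel)
  if (!is.null(group)) p <- p[p$group == group]
  if (length(unique(p$group)) != 1)
    stop("panel must contain exactly one group (use the 'group' argument)")
  covariates <- covariates %||%
    setdiff(names(p), c("country", "group", "date", "mb"))
  if (length(unique(p$country)) < 2)
    warning("fewer than 2 countries pooled; fixed effects are fragile")
  if (nrow(p) < 30) warning("fewer than 30 time points")
  X <- as.matrix(p[, covariates, with = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- covariates[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  # absorb country fixed effects
  dem <- copy(p)
  for (cl in c("mb", covariates))
    dem[, (cl) := .SD[[1]] - mean(.SD[[1]]), by = country, .SDcols = cl]
  fml <- stats::as.formula(paste("mb ~ 0 +", paste(covariates, collapse = "+")))
  fit <- lm(fml, data = dem)
  vc <- sandwich::vcovCL(fit, cluster = dem$country, type = "HC2")
  se <- sqrt(diag(vc))
  df <- length(unique(p$country)) - 1L
  tq <- qt(1 - (1 - conf_level) / 2, max(df, 1))
  est <- coef(fit)
  ct <- data.table(term = names(est), estimate = unname(est),
                   se = unname(se),
                   ci_lo = unname(est - tq * se),
                   ci_hi = unname(est + tq * se))
  ct[, t_value := estimate / se]
  ct[, p_value := 2 * stats::pt(-abs(t_value), max(df, 1))]
  vf <- vif_screen(X)
  out <- list(coefficients = ct[], bic = BIC(fit), vif = vf$vif,
              vif_pass = vf$pass, n = nrow(p),
              countries = length(unique(p$country)),
              window = range(p$date), fit = fit,
              group = p$group[1])
  class(out) <- "mobgap_fit"
  out
}

#' @export
print.mobgap_fit <- function(x, ...) {
  cat(sprintf("<mobgap_fit> group=%s n=%d countries=%d BIC=%.1f VIF %s\n",
              x$group, x$n, x$countries, x$bic,
              if (x$vif_pass) "pass" else "FAIL"))
  print(x$coefficients)
  invisible(x)
}

#' BIC model selection over candidate covariate sets
#'
#' Fits every candidate covariate set and returns the minimum-BIC model among
#' those passing the VIF screen (any VIF >= `vif_threshold` excludes the
#' candidate). By default candidates are all non-empty combinations of the
#' incidence terms with policy blocks mirroring a hierarchical grouping of
#' containment policies, capped at 64 models.
#'
#' @param panel A one-group `mobgap_panel`.
#' @param candidates Optional list of character vectors of covariate names.
#' @param vif_threshold VIF exclusion threshold (default 4).
#' @param group Optional group filter passed to [fit_group_model()].
#' @return list: `best` (a `mobgap_fit`), `table` (candidate BIC/VIF summary).
#' @export
select_model_bic <- function(panel, candidates = NULL, vif_threshold = 4,
                             group = NULL) {
  p <- as.data.table(panel)
  if (!is.null(group)) p <- p[p$group == group]
  covs <- setdiff(names(p), c("country", "group", "date", "mb"))
  if (is.null(candidates)) {
    inc <- intersect(c("incidence_g", "incidence_c"), covs)
    pols <- setdiff(covs, inc)
    blocks <- list()
    if (length(pols)) {
      closure <- intersect(c("school_closure", "workplace_closure"), pols)
      movement <- intersect(c("transport_closure", "internal_movement"), pols)
      stay <- intersect("stay_at_home", pols)
      blocks <- Filter(length, list(closure, movement, stay))
      if (!length(blocks)) blocks <- list(pols)
    }
    atoms <- c(as.list(inc), blocks)
    idx <- expand.grid(rep(list(c(FALSE, TRUE)), length(atoms)))
    candidates <- apply(idx, 1, function(sel) unlist(atoms[sel]))
    candidates <- Filter(length, candidates)
    if (length(candidates) > 64) candidates <- candidates[seq_len(64)]
  }
  rows <- vector("list", length(candidates))
  best <- NULL
  for (i in seq_along(candidates)) {
    cv <- candidates[[i]]
    f <- try(fit_group_model(p, covariates = cv), silent = TRUE)
    if (inherits(f, "try-error")) {
      rows[[i]] <- data.table(model = paste(cv, collapse = "+"),
                              bic = NA_real_, max_vif = Inf, pass = FALSE)
      next
    }
    mv <- max(f$vif)
    pass <- mv < vif_threshold
    rows[[i]] <- data.table(model = paste(cv, collapse = "+"), bic = f$bic,
                            max_vif = mv, pass = pass)
    if (pass && (is.null(best) || f$bic < best$bic)) best <- f
  }
  tab <- rbindlist(rows)
  if (is.null(best))
    stop("all candidate models fail the VIF screen; decorrelate covariates")
  setorder(tab, -pass, bic)
  list(best = best, table = tab[])
}

#' Simulate a planted-coefficient panel outcome
#'
#' Builds a daily group outcome over the estimation window as a linear
#' combination of the within-country standardized covariates plus Gaussian
#' noise, with the noise variance chosen so the outcome itself has unit
#' variance per country (hence the planted values are standardized
#' coefficients, directly comparable to the regression estimates).
#'
#' @param policy_incidence Output of [generate_policy_incidence()].
#' @param coefs Named vector of planted standardized coefficients (names among
#'   `incidence_g`, `incidence_c` and the policy index names).
#' @param group Group label for the generated series.
#' @param window Estimation window dates.
#' @param seed Integer seed.
#' @return A series table (`country`, `group`, `date`, `rel_change`) suitable
#'   for [build_panel()].
#' @export
simulate_panel_outcome <- function(policy_incidence, coefs, group = "low_work_high",
                                   window = c("2020-04-11", "2020-12-31"),
                                   seed = 1L) {
  set.seed(seed)
  pol <- data.table::dcast(as.data.table(policy_incidence$policy),
                           country + date ~ index_name, value.var = "value")
  inc <- as.data.table(policy_incidence$incidence)
  d <- inc[pol, on = c("country", "date")]
  setnames(d, c("incidence_global", "incidence_local"),
           c("incidence_g", "incidence_c"))
  d <- d[date >= as_date(window[1]) & date <= as_date(window[2])]
  covs <- names(coefs)
  for (cl in covs)
    d[, (cl) := (.SD[[1]] - mean(.SD[[1]])) /
        ifelse(sd(.SD[[1]]) == 0, 1, sd(.SD[[1]])),
      by = country, .SDcols = cl]
  d[, signal := as.matrix(.SD) %*% coefs, .SDcols = covs]
  d[, noise_sd := sqrt(pmax(1 - var(signal), 0.05)), by = country]
  d[, rel_change := signal + rnorm(.N, 0, noise_sd)]
  d[, group := group]
  d[, .(country, group, date, rel_change)]
}
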