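# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each rule with plain loops and, where
# possible, third-party primitives (geosphere, igraph), so they share no code
# with the package internals they verify.

suppressPackageStartupMessages({
  library(data.table)
})

hav_oracle <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# exhaustive sequential segmentation: recompute the candidate centroid from
# scratch at every step
oracle_stops <- function(t, lat, lon, d_max = 25, t_min = 300) {
  n <- length(t)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n) {
      cen_lat <- mean(lat[i:j])
      cen_lon <- mean(lon[i:j])
      if (hav_oracle(lat[j + 1L], lon[j + 1L], cen_lat, cen_lon) <= d_max)
        j <- j + 1L
      else break
    }
    if (t[j] - t[i] >= t_min)
      out[[length(out) + 1L]] <- data.frame(
        t_start = t[i], t_end = t[j], lat = mean(lat[i:j]),
        lon = mean(lon[i:j]), n_pings = j - i + 1L)
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(t_start = numeric(), t_end = numeric(), lat = numeric(),
                  lon = numeric(), n_pings = integer())
}

# transitive closure of the eps-neighbourhood graph via igraph components
oracle_eps_components <- function(lat, lon, eps = 25) {
  n <- length(lat)
  if (n == 1) return(1L)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    hav_oracle(lat[i], lon[i], lat[j], lon[j]) <= eps)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# cumulative-population wealth partition, re-derived with an explicit loop
oracle_wealth_groups <- function(pop, index, high = 0.2, low = 0.4) {
  o <- order(-index)
  total <- sum(pop)
  b1 <- high * total
  b2 <- (1 - low) * total
  cum <- 0
  lab <- character(length(pop))
  for (k in o) {
    lo_ <- cum; hi_ <- cum + pop[k]
    seg <- c(high = max(0, min(hi_, b1) - lo_),
             medium = max(0, min(hi_, b2) - max(lo_, b1)),
             low = max(0, hi_ - max(lo_, b2)))
    lab[k] <- names(seg)[which.max(seg)]
    cum <- hi_
  }
  lab
}

# normal-equations least squares on within-country demeaned data
oracle_panel_fit <- function(panel, covariates) {
  p <- as.data.frame(panel)
  for (cl in c("mb", covariates)) {
    p[[cl]] <- p[[cl]] - ave(p[[cl]], p$country)
  }
  X <- as.matrix(p[, covariates, drop = FALSE])
  drop(solve(crossprod(X), crossprod(X, p$mb)))
}
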