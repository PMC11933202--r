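#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EARTH_R = 6371000.0; // meters
static const double DEG = M_PI / 180.0;

inline double hav_m(double lat1, double lon1, double lat2, double lon2) {
  double dlat = (lat2 - lat1) * DEG / 2.0;
  double dlon = (lon2 - lon1) * DEG / 2.0;
  double a = std::sin(dlat) * std::sin(dlat) +
             std::cos(lat1 * DEG) * std::cos(lat2 * DEG) *
             std::sin(dlon) * std::sin(dlon);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// [[Rcpp::export]]
NumericVector haversine_m_cpp(NumericVector lat1, NumericVector lon1,
                              NumericVector lat2, NumericVector lon2) {
  R_xlen_t n = lat1.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hav_m(lat1[i], lon1[i], lat2[i], lon2[i]);
  return out;
}

// Greedy sequential stop segmentation (Hariharan-Toyama style).
// Input: pings sorted by (user, t). A candidate cluster grows while each new
// ping lies within d_max_m of the running centroid; a breaking ping closes the
// candidate, which is emitted iff its time span >= t_min_s. The breaking ping
// seeds the next candidate. Pings never forming a valid stop are discarded.
// Returns a list of equal-length vectors describing stop events, plus the
// 1-based stop index of each ping (0 = transit/discarded).
// [[Rcpp::export]]
List detect_stops_cpp(IntegerVector user, NumericVector t, NumericVector lat,
                      NumericVector lon, NumericVector acc,
                      double d_max_m, double t_min_s, bool diameter) {
  R_xlen_t n = user.size();
  std::vector<int> ev_user;
  std::vector<double> ev_t0, ev_t1, ev_lat, ev_lon, ev_acc;
  std::vector<int> ev_n;
  IntegerVector ping_ev(n);

  R_xlen_t cs = 0;         // start index of candidate
  double slat = 0, slon = 0, sacc = 0; // running sums
  R_xlen_t cn = 0;         // candidate size

  auto close_candidate = [&](R_xlen_t end_excl) {
    if (cn > 0 && (t[end_excl - 1] - t[cs]) >= t_min_s) {
      ev_user.push_back(user[cs]);
      ev_t0.push_back(t[cs]);
      ev_t1.push_back(t[end_excl - 1]);
      ev_lat.push_back(slat / cn);
      ev_lon.push_back(slon / cn);
      ev_acc.push_back(sacc / cn);
      ev_n.push_back((int)cn);
      int id = (int)ev_user.size();
      for (R_xlen_t k = cs; k < end_excl; ++k) ping_ev[k] = id;
    }
  };

  for (R_xlen_t i = 0; i < n; ++i) {
    if (i > 0 && user[i] == user[i - 1] && t[i] < t[i - 1])
      stop("pings must be time-sorted within each user");
    bool same_user = (cn > 0) && (user[i] == user[cs]);
    if (same_user) {
      bool ok;
      if (diameter) {
        // pairwise-diameter predicate: within d_max of every member ping
        ok = true;
        for (R_xlen_t k = cs; k < cs + (R_xlen_t)cn; ++k)
          if (hav_m(lat[i], lon[i], lat[k], lon[k]) > d_max_m) { ok = false; break; }
      } else {
        ok = hav_m(lat[i], lon[i], slat / cn, slon / cn) <= d_max_m;
      }
      if (ok) {
        slat += lat[i]; slon += lon[i]; sacc += acc[i]; ++cn;
        continue;
      }
    }
    close_candidate(i);
    cs = i; slat = lat[i]; slon = lon[i]; sacc = acc[i]; cn = 1;
  }
  close_candidate(n);

  return List::create(
    _["user"] = wrap(ev_user), _["t_start"] = wrap(ev_t0),
    _["t_end"] = wrap(ev_t1), _["lat"] = wrap(ev_lat),
    _["lon"] = wrap(ev_lon), _["mean_accuracy_m"] = wrap(ev_acc),
    _["n_pings"] = wrap(ev_n), _["ping_event"] = ping_ev);
}

// DBSCAN over points with haversine metric. With min_samples = 1 every point
// is core and clusters are the connected components of the eps-graph.
// Points are assumed grouped by user (cluster ids never cross a group
// boundary). Returns 1-based cluster ids per point; 0 = noise
// (only possible when min_samples > 1).
// [[Rcpp::export]]
IntegerVector dbscan_eps_cpp(IntegerVector grp, NumericVector lat,
                             NumericVector lon, double eps_m,
                             int min_samples) {
  R_xlen_t n = grp.size();
  IntegerVector cl(n, 0);
  int next_id = 0;
  R_xlen_t g0 = 0;
  std::vector<int> stack;
  std::vector<char> core;
  std::vector<int> nb;

  for (R_xlen_t g1 = 0; g1 <= n; ++g1) {
    if (g1 < n && grp[g1] == grp[g0]) continue;
    R_xlen_t m = g1 - g0;
    core.assign(m, 0);
    if (min_samples <= 1) {
      core.assign(m, 1);
    } else {
      for (R_xlen_t i = 0; i < m; ++i) {
        int cnt = 0;
        for (R_xlen_t j = 0; j < m; ++j)
          if (hav_m(lat[g0 + i], lon[g0 + i], lat[g0 + j], lon[g0 + j]) <= eps_m)
            ++cnt; // includes self
        core[i] = cnt >= min_samples;
      }
    }
    for (R_xlen_t i = 0; i < m; ++i) {
      if (cl[g0 + i] != 0 || !core[i]) continue;
      ++next_id;
      cl[g0 + i] = next_id;
      stack.clear();
      stack.push_back((int)i);
      while (!stack.empty()) {
        int c = stack.back(); stack.pop_back();
        if (!core[c]) continue;
        for (R_xlen_t j = 0; j < m; ++j) {
          if (cl[g0 + j] != 0) continue;
          if (hav_m(lat[g0 + c], lon[g0 + c], lat[g0 + j], lon[g0 + j]) <= eps_m) {
            cl[g0 + j] = next_id;
            stack.push_back((int)j);
          }
        }
      }
    }
    g0 = g1;
  }
  return cl;
}
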