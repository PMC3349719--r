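// Half-sarcomere Monte Carlo engine.
//
// Per time step: (1) instantaneous force balance over all filament nodes
// given the current attachment set, (2) thin-filament and cross-bridge
// rate evaluation from the start-of-step snapshot, (3) synchronous Monte
// Carlo updates (thin phase committed before the XB phase so nodes made
// available in a step can be bound within it), (4) trace record.
//
// The stiffness matrix is T + k_xb * W W^T where T (filament chains +
// boundary anchors) is fixed for a run and block-tridiagonal per filament.
// The solve uses the Woodbury identity against the precomputed per-filament
// inverses of T, which is exact direct linear algebra: cost is O(m) chain
// responses plus one small dense SPD solve in the number of attached
// bridges, instead of a full sparse refactorisation per step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct XBParams {
  double k_xb, kT, phi, w2, w3, x_ps, f1, h23, d31, d31s, rate_cap;
};

inline double r12_of(double x, const XBParams& p) {
  return p.f1 * std::exp(-p.phi * x * x);
}
inline double r21_of(double x, const XBParams& p) {
  // exact detailed-balance form r12 * exp(G2): the x^2 terms cancel,
  // avoiding 0 * Inf at extreme strains
  return p.f1 * std::exp(-p.w2);
}
inline double dg32_of(double x, const XBParams& p) {
  double g2 = -p.w2 + p.phi * x * x;
  double g3 = -p.w3 + p.phi * (x - p.x_ps) * (x - p.x_ps);
  return g3 - g2;
}
inline double r23_of(double x, const XBParams& p) {
  return p.h23 / (1.0 + std::exp(dg32_of(x, p)));
}
inline double r32_of(double x, const XBParams& p) {
  return p.h23 / (1.0 + std::exp(-dg32_of(x, p)));
}
inline double r31_of(double x, const XBParams& p) {
  double rel = (x - p.x_ps) / p.x_ps;
  return p.d31 * (1.0 + p.d31s * rel * rel);
}

} // namespace

// Strain-dependent rate probe sharing the engine's inline rate functions,
// used to cross-validate against the R-level formulas.
// [[Rcpp::export]]
Rcpp::DataFrame cpp_xb_rates_probe(Rcpp::NumericVector x, Rcpp::List par) {
  XBParams p;
  p.k_xb = par["k_xb"]; p.kT = par["kT"]; p.phi = par["phi"];
  p.w2 = par["w2"]; p.w3 = par["w3"]; p.x_ps = par["x_ps"];
  p.f1 = par["f1"]; p.h23 = par["h23"]; p.d31 = par["d31"];
  p.d31s = par["d31_strain"]; p.rate_cap = par["rate_cap"];
  int n = x.size();
  NumericVector r12(n), r21(n), r23(n), r32(n), r31(n);
  for (int i = 0; i < n; ++i) {
    r12[i] = r12_of(x[i], p);
    r21[i] = r21_of(x[i], p);
    r23[i] = r23_of(x[i], p);
    r32[i] = r32_of(x[i], p);
    r31[i] = r31_of(x[i], p);
  }
  return DataFrame::create(_["x"] = x, _["r12"] = r12, _["r21"] = r21,
                           _["r23"] = r23, _["r32"] = r32, _["r31"] = r31);
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(Rcpp::List geom, Rcpp::List kin, Rcpp::List ctrl) {
  // ---- geometry ----
  const IntegerVector fil_of = geom["fil_of"];        // 0-based filament id per node
  const NumericVector p0 = geom["p0"];                // rest positions (nm)
  const IntegerVector el_a = geom["el_a"];            // 0-based, -1 = wall
  const IntegerVector el_b = geom["el_b"];
  const NumericVector el_k = geom["el_k"];            // scaled stiffness
  const IntegerVector zanch_node = geom["zanch_node"];
  const NumericVector zanch_k = geom["zanch_k"];
  const IntegerVector manch_node = geom["manch_node"];
  const NumericVector manch_k = geom["manch_k"];
  const IntegerVector myo_node = geom["myo_node"];    // 0-based node per myosin
  const IntegerVector cand_ptr = geom["cand_ptr"];    // 0-based CSR over myosins
  const IntegerVector cand_node = geom["cand_node"];
  const IntegerVector trop_func = geom["trop_func"];
  const IntegerVector trop_prev = geom["trop_prev"];  // 0-based, -1 = none
  const IntegerVector trop_next = geom["trop_next"];
  const IntegerVector infl_ptr = geom["infl_ptr"];    // CSR troponin -> nodes
  const IntegerVector infl_node = geom["infl_node"];
  const int n_thin_nodes = as<int>(geom["n_thin_nodes"]);

  const int n_nodes = fil_of.size();
  const int n_myo = myo_node.size();
  const int n_trop = trop_func.size();
  int n_fil = 0;
  for (int i = 0; i < n_nodes; ++i) n_fil = std::max(n_fil, fil_of[i] + 1);

  // ---- kinetics ----
  const double Ca = as<double>(kin["Ca"]);
  const double dt = as<double>(kin["dt"]);
  const double rt12 = as<double>(kin["r_t12"]), rt21 = as<double>(kin["r_t21"]);
  const double rt23 = as<double>(kin["r_t23"]), rt32 = as<double>(kin["r_t32"]);
  const double rt31 = as<double>(kin["r_t31"]), rt13 = as<double>(kin["r_t13"]);
  const double crt12 = as<double>(kin["coop_r_t12"]);
  const double crt23 = as<double>(kin["coop_r_t23"]);
  const bool coop_on = as<bool>(kin["coop_enabled"]);
  const bool src_tf3 = as<bool>(kin["src_tf3"]);
  const bool src_xb2 = as<bool>(kin["src_xb2"]);
  const bool src_xb3 = as<bool>(kin["src_xb3"]);
  const bool tgt12 = as<bool>(kin["tgt_rt12"]);
  const bool tgt23 = as<bool>(kin["tgt_rt23"]);
  // 0 = free (availability gates attachment only), 1 = block deactivation
  // while a bridge is bound in the unit's region, 2 = release such bridges
  const int deact_mode = as<int>(kin["deact_mode"]);
  const bool block_deact = deact_mode == 1;
  const bool xb_binding = as<bool>(kin["xb_binding"]);

  XBParams xp;
  xp.k_xb = as<double>(kin["k_xb"]); xp.kT = as<double>(kin["kT"]);
  xp.phi = as<double>(kin["phi"]); xp.w2 = as<double>(kin["w2"]);
  xp.w3 = as<double>(kin["w3"]); xp.x_ps = as<double>(kin["x_ps"]);
  xp.f1 = as<double>(kin["f1"]); xp.h23 = as<double>(kin["h23"]);
  xp.d31 = as<double>(kin["d31"]); xp.d31s = as<double>(kin["d31_strain"]);
  xp.rate_cap = as<double>(kin["rate_cap"]);

  const int n_steps = as<int>(ctrl["n_steps"]);
  const int n_substeps = as<int>(ctrl["n_substeps"]);

  // ---- per-filament tridiagonal inverses ----
  std::vector<int> fil_size(n_fil, 0), fil_off(n_fil, 0), loc(n_nodes);
  for (int i = 0; i < n_nodes; ++i) fil_size[fil_of[i]]++;
  for (int f = 1; f < n_fil; ++f) fil_off[f] = fil_off[f - 1] + fil_size[f - 1];
  {
    std::vector<int> cnt(n_fil, 0);
    for (int i = 0; i < n_nodes; ++i) {
      if (fil_of[i] != fil_of[fil_off[fil_of[i]]])
        stop("nodes must be contiguous per filament");
      loc[i] = cnt[fil_of[i]]++;
    }
  }
  std::vector<arma::mat> Ginv(n_fil);
  {
    std::vector<arma::mat> T(n_fil);
    for (int f = 0; f < n_fil; ++f) T[f] = arma::zeros(fil_size[f], fil_size[f]);
    for (int e = 0; e < el_a.size(); ++e) {
      int b = el_b[e], f = fil_of[b];
      if (el_a[e] < 0) {
        T[f](loc[b], loc[b]) += el_k[e];
      } else {
        int a = el_a[e];
        if (fil_of[a] != f) stop("element spans filaments");
        T[f](loc[a], loc[a]) += el_k[e];
        T[f](loc[b], loc[b]) += el_k[e];
        T[f](loc[a], loc[b]) -= el_k[e];
        T[f](loc[b], loc[a]) -= el_k[e];
      }
    }
    for (int f = 0; f < n_fil; ++f) {
      arma::mat G;
      if (!arma::inv_sympd(G, T[f]))
        stop("filament stiffness block is not positive definite (missing anchor?)");
      Ginv[f] = G;
    }
  }

  // ---- state ----
  std::vector<int> ru(n_trop, 1);          // TF1
  std::vector<int> xb(n_myo, 1);           // XB1
  std::vector<int> partner(n_myo, -1);     // 0-based actin node
  std::vector<int> occupied(n_nodes, -1);  // myosin index
  std::vector<char> avail(n_nodes, 0);
  arma::vec u(n_nodes, arma::fill::zeros);
  long atp_total = 0, forced_thin = 0, substep_events = 0;
  double force_z = 0.0, force_m = 0.0;

  std::vector<int> ru_new(n_trop);

  // mechanics solve for the current attachment set
  auto solve_mech = [&]() {
    std::vector<int> att;
    for (int i = 0; i < n_myo; ++i) if (xb[i] >= 2) att.push_back(i);
    const int m = (int) att.size();
    u.zeros();
    if (m > 0) {
      arma::vec z0(n_nodes, arma::fill::zeros);
      std::vector<double> cvec(m);
      for (int j = 0; j < m; ++j) {
        int i = att[j];
        int mn = myo_node[i], an = partner[i];
        double d = (xb[i] == 3) ? xp.x_ps : 0.0;
        double c = (p0[mn] - p0[an]) - d;
        cvec[j] = c;
        int fm = fil_of[mn], fa = fil_of[an];
        z0.subvec(fil_off[fm], fil_off[fm] + fil_size[fm] - 1) +=
          (-xp.k_xb * c) * Ginv[fm].col(loc[mn]);
        z0.subvec(fil_off[fa], fil_off[fa] + fil_size[fa] - 1) -=
          (-xp.k_xb * c) * Ginv[fa].col(loc[an]);
      }
      arma::mat S(m, m, arma::fill::eye);
      for (int j = 0; j < m; ++j) {
        int mj = myo_node[att[j]], aj = partner[att[j]];
        for (int i2 = j; i2 < m; ++i2) {
          int mi = myo_node[att[i2]], ai = partner[att[i2]];
          double g = 0.0;
          if (fil_of[mi] == fil_of[mj]) g += Ginv[fil_of[mj]](loc[mi], loc[mj]);
          if (fil_of[ai] == fil_of[aj]) g += Ginv[fil_of[aj]](loc[ai], loc[aj]);
          S(i2, j) += xp.k_xb * g;
          if (i2 != j) S(j, i2) = S(i2, j);
        }
      }
      arma::vec q(m);
      for (int j = 0; j < m; ++j)
        q[j] = z0[myo_node[att[j]]] - z0[partner[att[j]]];
      arma::vec beta = arma::solve(S, q, arma::solve_opts::likely_sympd);
      u = z0;
      for (int j = 0; j < m; ++j) {
        int i = att[j];
        int mn = myo_node[i], an = partner[i];
        int fm = fil_of[mn], fa = fil_of[an];
        u.subvec(fil_off[fm], fil_off[fm] + fil_size[fm] - 1) -=
          (xp.k_xb * beta[j]) * Ginv[fm].col(loc[mn]);
        u.subvec(fil_off[fa], fil_off[fa] + fil_size[fa] - 1) +=
          (xp.k_xb * beta[j]) * Ginv[fa].col(loc[an]);
      }
    }
    force_z = 0.0; force_m = 0.0;
    for (int j = 0; j < zanch_node.size(); ++j)
      force_z += zanch_k[j] * (-u[zanch_node[j]]);
    for (int j = 0; j < manch_node.size(); ++j)
      force_m += manch_k[j] * u[manch_node[j]];
  };

  auto refresh_avail = [&]() {
    std::fill(avail.begin(), avail.end(), 0);
    for (int t = 0; t < n_trop; ++t) {
      if (trop_func[t] && ru[t] == 3) {
        for (int k = infl_ptr[t]; k < infl_ptr[t + 1]; ++k)
          avail[infl_node[k]] = 1;
      }
    }
  };

  auto count_avail = [&]() {
    long c = 0;
    for (int i = 0; i < n_nodes; ++i) c += avail[i];
    return (double) c / (double) n_thin_nodes;
  };

  // trace: t, force, force_m, frac_avail, tf1..3, xb1..3, n_bound, atp,
  // forced_thin, substeps
  const int NC = 14;
  NumericMatrix trace(n_steps + 1, NC);
  int n_func = 0;
  for (int t = 0; t < n_trop; ++t) n_func += trop_func[t];
  auto record = [&](int row, double tnow) {
    int c1 = 0, c2 = 0, c3 = 0, x1 = 0, x2 = 0, x3 = 0;
    for (int t = 0; t < n_trop; ++t) {
      if (!trop_func[t]) continue;
      if (ru[t] == 1) c1++; else if (ru[t] == 2) c2++; else c3++;
    }
    for (int i = 0; i < n_myo; ++i) {
      if (xb[i] == 1) x1++; else if (xb[i] == 2) x2++; else x3++;
    }
    trace(row, 0) = tnow;
    trace(row, 1) = force_z;
    trace(row, 2) = force_m;
    trace(row, 3) = count_avail();
    double nf = std::max(n_func, 1);
    trace(row, 4) = c1 / nf; trace(row, 5) = c2 / nf; trace(row, 6) = c3 / nf;
    trace(row, 7) = (double) x1 / n_myo;
    trace(row, 8) = (double) x2 / n_myo;
    trace(row, 9) = (double) x3 / n_myo;
    trace(row, 10) = x2 + x3;
    trace(row, 11) = (double) atp_total;
    trace(row, 12) = (double) forced_thin;
    trace(row, 13) = (double) substep_events;
  };

  refresh_avail();
  record(0, 0.0);

  for (int step = 1; step <= n_steps; ++step) {
    // ---------- thin-filament phase (synchronous, start-of-step state) ----
    for (int t = 0; t < n_trop; ++t) {
      ru_new[t] = ru[t];
      if (!trop_func[t]) continue;
      bool hot = false;
      if (coop_on) {
        const int nb[2] = {trop_prev[t], trop_next[t]};
        for (int k = 0; k < 2 && !hot; ++k) {
          int b = nb[k];
          if (b < 0) continue;
          if (src_tf3 && trop_func[b] && ru[b] == 3) { hot = true; break; }
          if (src_xb2 || src_xb3) {
            for (int q = infl_ptr[b]; q < infl_ptr[b + 1]; ++q) {
              int mi = occupied[infl_node[q]];
              if (mi >= 0) {
                if ((src_xb2 && xb[mi] == 2) || (src_xb3 && xb[mi] == 3)) {
                  hot = true; break;
                }
              }
            }
          }
        }
      }
      double pa = 0.0, pb = 0.0;
      int ta = 0, tb = 0;
      if (ru[t] == 1) {
        double r12 = (hot && tgt12) ? crt12 : rt12;
        pa = r12 * Ca * dt; ta = 2;
        pb = rt13 * Ca * dt; tb = 3;
      } else if (ru[t] == 2) {
        double r23 = (hot && tgt23) ? crt23 : rt23;
        pa = r23 * dt; ta = 3;
        pb = rt21 * dt; tb = 1;
      } else {
        bool blocked = false;
        if (block_deact) {
          for (int q = infl_ptr[t]; q < infl_ptr[t + 1] && !blocked; ++q)
            if (occupied[infl_node[q]] >= 0) blocked = true;
        }
        if (blocked) continue;  // tropomyosin held by a bound bridge
        pa = rt32 * dt; ta = 2;
        pb = rt31 * dt; tb = 1;
      }
      double tot = pa + pb;
      if (tot <= 0.0) continue;
      if (tot >= 1.0) { pa /= tot; pb /= tot; forced_thin++; }
      double nd = unif_rand();
      if (nd < pa) ru_new[t] = ta;
      else if (nd < pa + pb) ru_new[t] = tb;
    }
    ru = ru_new;
    refresh_avail();
    if (deact_mode == 2) {
      // releasing deactivation: a bridge whose node lost availability is
      // forcibly released (interrupted cycle, no ATP counted)
      for (int i = 0; i < n_myo; ++i) {
        if (xb[i] >= 2 && !avail[partner[i]]) {
          occupied[partner[i]] = -1;
          partner[i] = -1;
          xb[i] = 1;
        }
      }
    }

    // ---------- cross-bridge phase (x from start-of-step solve) ----------
    if (xb_binding) {
      for (int i = 0; i < n_myo; ++i) {
        int mn = myo_node[i];
        double pm = p0[mn] + u[mn];
        if (xb[i] == 1) {
          // nearest available, unoccupied candidate by current offset;
          // ties broken toward the Z-line (larger axial coordinate)
          int best = -1; double besty = 0.0, bestabs = 1e300, bestpos = -1e300;
          for (int k = cand_ptr[i]; k < cand_ptr[i + 1]; ++k) {
            int an = cand_node[k];
            if (!avail[an] || occupied[an] >= 0) continue;
            double pa_ = p0[an] + u[an];
            double y = pm - pa_;
            double ay = std::fabs(y);
            if (ay < bestabs - 1e-12 ||
                (std::fabs(ay - bestabs) <= 1e-12 && pa_ > bestpos)) {
              best = an; besty = y; bestabs = ay; bestpos = pa_;
            }
          }
          if (best < 0) continue;
          double p = r12_of(besty, xp) * dt;
          if (p <= 0.0) continue;
          if (p > 1.0) p = 1.0;
          if (unif_rand() < p) {
            if (occupied[best] >= 0) stop("invalid state: actin node double-claimed");
            xb[i] = 2; partner[i] = best; occupied[best] = i;
          }
        } else {
          int an = partner[i];
          double y = pm - (p0[an] + u[an]);
          double ra, rb; int ta, tb;
          auto rates_for = [&](int st, double& ra_, double& rb_, int& ta_, int& tb_) {
            if (st == 2) { ra_ = r23_of(y, xp); ta_ = 3; rb_ = r21_of(y, xp); tb_ = 1; }
            else { ra_ = r32_of(y, xp); ta_ = 2; rb_ = r31_of(y, xp); tb_ = 1; }
          };
          rates_for(xb[i], ra, rb, ta, tb);
          int nsub = 1;
          double rmax = std::max(ra, rb);
          if (rmax > xp.rate_cap || rmax * dt >= 1.0) {
            nsub = n_substeps; substep_events++;
          }
          double sdt = dt / nsub;
          for (int s = 0; s < nsub; ++s) {
            rates_for(xb[i], ra, rb, ta, tb);
            double pa_ = ra * sdt, pb_ = rb * sdt;
            double tot = pa_ + pb_;
            if (tot >= 1.0) { pa_ /= tot; pb_ /= tot; }
            double nd = unif_rand();
            int from = xb[i];
            if (nd < pa_) xb[i] = ta;
            else if (nd < pa_ + pb_) xb[i] = tb;
            if (xb[i] == 1 && from > 1) {
              if (from == 3) atp_total++;
              occupied[partner[i]] = -1;
              partner[i] = -1;
              break;  // detached bridges do not reattach within the step
            }
          }
        }
      }
    }

    // ---------- mechanics with the updated attachment set ----------------
    solve_mech();
    record(step, step * dt);
  }

  // final attachment table (1-based ids for R)
  IntegerVector f_state(n_myo), f_partner(n_myo);
  for (int i = 0; i < n_myo; ++i) {
    f_state[i] = xb[i];
    f_partner[i] = partner[i] < 0 ? NA_INTEGER : partner[i] + 1;
  }
  IntegerVector f_ru(n_trop);
  for (int t = 0; t < n_trop; ++t) f_ru[t] = ru[t];

  return List::create(
    _["trace"] = trace,
    _["ru_states"] = f_ru,
    _["xb_states"] = f_state,
    _["xb_partner"] = f_partner,
    _["u"] = NumericVector(u.begin(), u.end()),
    _["atp_total"] = (double) atp_total,
    _["forced_thin"] = (double) forced_thin,
    _["substep_events"] = (double) substep_events,
    _["force_z"] = force_z,
    _["force_m"] = force_m
  );
}
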