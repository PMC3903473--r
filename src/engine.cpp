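#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell type codes used throughout: 1 = MIC, 2 = PC, 3 = MM, 4 = TMM.
// Sites are linear indices into an nx * ny * nz array (column-major, as in R).

static inline double pow_n(double x, double n) {
  if (n == 1.0) return x;
  if (n == 2.0) return x * x;
  if (n == 3.0) return x * x * x;
  return std::pow(x, n);
}

static inline double hill_scalar(double x, double K, double n, double lo,
                                 double hi) {
  if (x <= 0.0) return lo;
  double xn = pow_n(x, n);
  double Kn = pow_n(K, n);
  return lo + (hi - lo) * xn / (Kn + xn);
}

// [[Rcpp::export]]
NumericVector cpp_hill(NumericVector x, double K, double n, double lo,
                       double hi) {
  R_xlen_t m = x.size();
  NumericVector out(m);
  const double Kn = pow_n(K, n);
  const double span = hi - lo;
  for (R_xlen_t i = 0; i < m; ++i) {
    double v = x[i];
    if (v <= 0.0) { out[i] = lo; continue; }
    double xn = pow_n(v, n);
    out[i] = lo + span * xn / (Kn + xn);
  }
  return out;
}

// Explicit forward-time central-space step for the SDF-1 reaction-diffusion
// field: dS/dt = D Lap(S) + secretion - lambda S, sub-stepped so that
// dt_sub * (6 D / h^2 + lambda) <= 1 (which also keeps
// D dt_sub / h^2 <= 1/6). All three processes advance together within each
// sub-step, so the fixed point of the update is exactly the steady discrete
// reaction-diffusion equation on the lattice. Boundary handling is
// Dirichlet at S_boundary (or reflecting, for the mass-conservation
// self-check mode).
// [[Rcpp::export]]
NumericVector cpp_step_sdf1(NumericVector field, IntegerVector dims,
                            LogicalVector mask, IntegerVector mic_sites,
                            double D, double lambda, double sigma,
                            double S_boundary, double dt, double spacing,
                            bool reflecting) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  std::vector<double> S(field.begin(), field.end());
  std::vector<double> src(N, 0.0);
  for (R_xlen_t k = 0; k < mic_sites.size(); ++k)
    src[mic_sites[k] - 1] += sigma;

  if (!reflecting)
    for (int i = 0; i < N; ++i)
      if (!mask[i]) S[i] = S_boundary;

  double rate = 6.0 * D / (spacing * spacing) + lambda;
  int n_sub = rate > 0.0 ? (int)std::ceil(rate * dt) : 1;
  if (n_sub < 1) n_sub = 1;
  if (n_sub > 1000000) stop("diffusion sub-stepping unsatisfiable");
  const double dt_sub = dt / n_sub;
  const double alpha = D * dt_sub / (spacing * spacing);

  // precompute the in-domain site list with 6-neighbour indices
  // (-1 codes an out-of-grid / out-of-mask neighbour, which takes the
  // boundary value under Dirichlet or mirrors the centre when reflecting)
  std::vector<int> sites;
  sites.reserve(N);
  std::vector<int> nbidx;
  const int off[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        sites.push_back(i);
        for (int q = 0; q < 6; ++q) {
          int xx = x + off[q][0], yy = y + off[q][1], zz = z + off[q][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
              zz >= nz) {
            nbidx.push_back(-1);
          } else {
            int j = xx + nx * (yy + ny * zz);
            nbidx.push_back(mask[j] ? j : -1);
          }
        }
      }
    }
  }
  const int m = (int)sites.size();
  std::vector<double> S0(N);
  for (int s = 0; s < n_sub; ++s) {
    S0 = S;
    const double *S0p = S0.data();
    const int *nb = nbidx.data();
    for (int r = 0; r < m; ++r) {
      int i = sites[r];
      double c = S0p[i];
      double bnd = reflecting ? c : S_boundary;
      double acc = -6.0 * c;
      const int *nbr = nb + 6 * r;
      for (int q = 0; q < 6; ++q) {
        int j = nbr[q];
        acc += j >= 0 ? S0p[j] : bnd;
      }
      S[i] = c + alpha * acc + dt_sub * (src[i] - lambda * c);
    }
  }

  if (!reflecting)
    for (int i = 0; i < N; ++i)
      if (!mask[i]) S[i] = S_boundary;
  for (int i = 0; i < N; ++i)
    if (S[i] < 0.0) S[i] = 0.0;

  return NumericVector(S.begin(), S.end());
}

// Mean of `field` over the in-domain Chebyshev neighbourhood of each
// in-domain site (radius 0 = the site itself); 0 outside the domain.
// Separable implementation: three axis passes of running box sums over the
// masked field and over the mask indicator, then a final divide.
static void box_sum_axis(std::vector<double> &dst,
                         const std::vector<double> &src, int nx, int ny,
                         int nz, int radius, int axis) {
  int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  int n_outer = (nx * ny * nz) / len;
  for (int o = 0; o < n_outer; ++o) {
    // compute the base index of this 1-D line
    int base;
    if (axis == 0) {
      base = o * nx;
    } else if (axis == 1) {
      int x = o % nx, z = o / nx;
      base = x + nx * ny * z;
    } else {
      base = o;
    }
    for (int k = 0; k < len; ++k) {
      double acc = 0.0;
      int lo = k - radius < 0 ? 0 : k - radius;
      int hi = k + radius >= len ? len - 1 : k + radius;
      for (int q = lo; q <= hi; ++q) acc += src[base + q * stride];
      dst[base + k * stride] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector field, IntegerVector dims,
                           LogicalVector mask, int radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  if (radius == 0) {
    NumericVector out(N);
    for (int i = 0; i < N; ++i) out[i] = mask[i] ? field[i] : 0.0;
    return out;
  }
  std::vector<double> fm(N), cm(N), tmp(N);
  for (int i = 0; i < N; ++i) {
    fm[i] = mask[i] ? field[i] : 0.0;
    cm[i] = mask[i] ? 1.0 : 0.0;
  }
  for (int axis = 0; axis < 3; ++axis) {
    box_sum_axis(tmp, fm, nx, ny, nz, radius, axis);
    fm.swap(tmp);
    box_sum_axis(tmp, cm, nx, ny, nz, radius, axis);
    cm.swap(tmp);
  }
  NumericVector out(N);
  for (int i = 0; i < N; ++i)
    out[i] = (mask[i] && cm[i] > 0.0) ? fm[i] / cm[i] : 0.0;
  return out;
}

// Weighted draw of one free in-domain site within Chebyshev distance `radius`
// of site0 (0-based), weight exp(beta * E(site)); candidates enumerated in a
// fixed lexicographic order so the single uniform draw is the only stochastic
// element. `wE` is the precomputed exp(beta * E) table (NULL when beta = 0,
// i.e. uniform weights). Returns -1 when no free site exists.
static int choose_site_core(int site0, int radius, const int *occ,
                            const double *wE, int nx, int ny, int nz,
                            const int *mask) {
  int x0 = site0 % nx;
  int y0 = (site0 / nx) % ny;
  int z0 = site0 / (nx * ny);
  static std::vector<int> cand;
  static std::vector<double> w;
  cand.clear();
  w.clear();
  double total = 0.0;
  for (int dz = -radius; dz <= radius; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    for (int dy = -radius; dy <= radius; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -radius; dx <= radius; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        int j = xx + nx * (yy + ny * zz);
        if (!mask[j] || occ[j] != 0) continue;
        double wt = wE ? wE[j] : 1.0;
        cand.push_back(j);
        w.push_back(wt);
        total += wt;
      }
    }
  }
  if (cand.empty()) return -1;
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t k = 0; k < cand.size(); ++k) {
    acc += w[k];
    if (u <= acc) return cand[k];
  }
  return cand.back();
}

// [[Rcpp::export]]
int cpp_choose_target(int site, int radius, IntegerVector occ,
                      NumericVector stiffness, double beta, IntegerVector dims,
                      LogicalVector mask) {
  std::vector<int> msk(mask.begin(), mask.end());
  const int N = dims[0] * dims[1] * dims[2];
  std::vector<double> wE;
  const double *wp = NULL;
  if (beta != 0.0) {
    wE.resize(N);
    for (int i = 0; i < N; ++i) wE[i] = std::exp(beta * stiffness[i]);
    wp = wE.data();
  }
  int r = choose_site_core(site - 1, radius, INTEGER(occ), wp, dims[0],
                           dims[1], dims[2], msk.data());
  return r < 0 ? NA_INTEGER : r + 1;
}

// One macro time step of the per-cell stochastic update. Phase order per cell:
// dying progression -> apoptosis decision -> division attempt -> migration.
// Cells are visited in a freshly shuffled order; daughters born this step are
// not updated until the next step.
//
// Event codes: 1 birth, 2 division, 3 conversion, 4 apoptosis entry,
// 5 removal (death), 6 migration.
// [[Rcpp::export]]
List cpp_cells_step(IntegerVector id, IntegerVector type, IntegerVector site,
                    IntegerVector passage, NumericVector cycle,
                    NumericVector dying, NumericVector stiffness,
                    IntegerVector dims, LogicalVector mask, List par,
                    double bzm, double dt, int next_id, double time,
                    bool record_events) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int N = nx * ny * nz;
  const int n0 = id.size();

  NumericVector cycle_len = par["cycle_len"];   // hours, per type
  NumericVector p_mig = par["p_mig"];           // per-step, per type
  NumericVector beta = par["beta"];             // stiffness preference
  NumericVector base_apop = par["base_apop"];   // per hour, per type
  NumericVector div_K = par["div_K"], div_n = par["div_n"],
                div_lo = par["div_lo"], div_hi = par["div_hi"];
  NumericVector self_par = par["self_par"];     // K, n, lo, hi
  double asym_share = as<double>(par["asym_share"]);
  NumericVector apop_prot = par["apop_prot"];   // K, n, lo, hi (MIC only)
  NumericVector bzm_K = par["bzm_K"], bzm_n = par["bzm_n"],
                bzm_hi = par["bzm_hi"];
  double mic_resist = as<double>(par["mic_resist"]);
  NumericVector prot = par["prot"];             // K, n, lo, hi (MIC only)
  int lgn_pc = as<int>(par["lgn_pc"]);
  int lgn_mm = as<int>(par["lgn_mm"]);
  double apop_dur = as<double>(par["apop_dur"]);
  int mig_dist = as<int>(par["mig_dist"]);
  int div_dist = as<int>(par["div_dist"]);

  std::vector<int> c_id(id.begin(), id.end());
  std::vector<int> c_type(type.begin(), type.end());
  std::vector<int> c_site(site.begin(), site.end());  // 1-based
  std::vector<int> c_pass(passage.begin(), passage.end());
  std::vector<double> c_cycle(cycle.begin(), cycle.end());
  std::vector<double> c_dying(dying.begin(), dying.end());
  std::vector<char> alive(n0, 1);

  std::vector<int> msk(mask.begin(), mask.end());
  std::vector<int> occ(N, 0);
  for (int i = 0; i < n0; ++i) occ[c_site[i] - 1] = i + 1;

  std::vector<double> ev;  // rows of (time, id, code, from, to, site)
  ev.reserve(record_events ? 6 * (n0 / 4 + 16) : 0);
  auto push_event = [&](int cid, int code, int from, int to, int s1) {
    if (!record_events) return;
    ev.push_back(time);
    ev.push_back((double)cid);
    ev.push_back((double)code);
    ev.push_back((double)from);
    ev.push_back((double)to);
    ev.push_back((double)s1);
  };

  // shuffled visitation order (Fisher-Yates with R's RNG)
  std::vector<int> ord(n0);
  for (int i = 0; i < n0; ++i) ord[i] = i;
  for (int i = n0 - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }

  const double *E = REAL(stiffness);

  // precomputed exp(beta * E) tables, shared across types with equal beta
  std::vector<std::vector<double> > wtabs;
  const double *wE_type[4] = {NULL, NULL, NULL, NULL};
  {
    std::vector<double> betas_done;
    for (int t = 0; t < 4; ++t) {
      double b = beta[t];
      if (b == 0.0) continue;
      int found = -1;
      for (size_t k = 0; k < betas_done.size(); ++k)
        if (betas_done[k] == b) { found = (int)k; break; }
      if (found < 0) {
        std::vector<double> tab(N);
        for (int i = 0; i < N; ++i) tab[i] = std::exp(b * E[i]);
        wtabs.push_back(tab);
        betas_done.push_back(b);
        found = (int)wtabs.size() - 1;
      }
      wE_type[t] = NULL;  // filled after wtabs stops reallocating
    }
    // map types to tables now that wtabs is stable
    for (int t = 0; t < 4; ++t) {
      double b = beta[t];
      if (b == 0.0) continue;
      for (size_t k = 0; k < betas_done.size(); ++k)
        if (betas_done[k] == b) wE_type[t] = wtabs[k].data();
    }
  }

  for (int q = 0; q < n0; ++q) {
    int i = ord[q];
    if (!alive[i]) continue;
    int t = c_type[i];

    // (1) dying progression: no other actions, removal at clock zero
    if (c_dying[i] >= 0.0) {
      c_dying[i] -= dt;
      if (c_dying[i] <= 1e-9) {
        alive[i] = 0;
        occ[c_site[i] - 1] = 0;
        push_event(c_id[i], 5, t, 0, c_site[i]);
      }
      continue;
    }

    double Eloc = E[c_site[i] - 1];

    // (2) apoptosis decision: baseline hazard (stiffness-shielded for MICs)
    // plus the drug-induced per-step increment
    double p_base = base_apop[t - 1] * dt;
    if (t == 1)
      p_base *= 1.0 - hill_scalar(Eloc, apop_prot[0], apop_prot[1],
                                  apop_prot[2], apop_prot[3]);
    double p_drug = hill_scalar(bzm, bzm_K[t - 1], bzm_n[t - 1], 0.0,
                                bzm_hi[t - 1]);
    if (t == 1)
      p_drug *= mic_resist *
                (1.0 - hill_scalar(Eloc, prot[0], prot[1], prot[2], prot[3]));
    double p_apop = p_base + p_drug;
    if (p_apop > 1.0) p_apop = 1.0;
    if (p_apop < 0.0) p_apop = 0.0;
    if (unif_rand() < p_apop) {
      c_dying[i] = apop_dur;
      push_event(c_id[i], 4, t, t, c_site[i]);
      continue;
    }

    // (3) division
    c_cycle[i] -= dt;
    bool divided = false, blocked = false;
    if (c_cycle[i] <= 0.0 && t != 4) {
      double pdiv = hill_scalar(Eloc, div_K[t - 1], div_n[t - 1],
                                div_lo[t - 1], div_hi[t - 1]);
      if (unif_rand() < pdiv) {
        int tgt = choose_site_core(c_site[i] - 1, div_dist, occ.data(),
                                   wE_type[t - 1], nx, ny, nz, msk.data());
        if (tgt < 0) {
          blocked = true;  // remain in M-phase, retry next step
        } else {
          divided = true;
          int parent_type = t, daughter_type = t;
          int parent_pass = c_pass[i], daughter_pass = c_pass[i];
          if (t == 1) {
            // MIC fate: self-renewal / asymmetric / differentiation
            double p_self = hill_scalar(Eloc, self_par[0], self_par[1],
                                        self_par[2], self_par[3]);
            double rest = 1.0 - p_self;
            double p_asym = rest * asym_share;
            double u = unif_rand();
            if (u < p_self) {
              parent_type = 1; daughter_type = 1;
            } else if (u < p_self + p_asym) {
              parent_type = 1; daughter_type = 2;
            } else {
              parent_type = 2; daughter_type = 2;
            }
            parent_pass = 0;
            daughter_pass = 0;
          } else if (t == 2) {
            int np = c_pass[i] + 1;
            if (np >= lgn_pc) {
              parent_type = daughter_type = 3;
              parent_pass = daughter_pass = 0;
            } else {
              parent_pass = daughter_pass = np;
            }
          } else if (t == 3) {
            int np = c_pass[i] + 1;
            if (np >= lgn_mm) {
              parent_type = daughter_type = 4;
              parent_pass = daughter_pass = 0;
            } else {
              parent_pass = daughter_pass = np;
            }
          }
          push_event(c_id[i], 2, t, parent_type, c_site[i]);
          if (parent_type != t)
            push_event(c_id[i], 3, t, parent_type, c_site[i]);
          c_type[i] = parent_type;
          c_pass[i] = parent_pass;
          c_cycle[i] = cycle_len[parent_type - 1];
          // daughter
          c_id.push_back(next_id);
          c_type.push_back(daughter_type);
          c_site.push_back(tgt + 1);
          c_pass.push_back(daughter_pass);
          c_cycle.push_back(cycle_len[daughter_type - 1]);
          c_dying.push_back(-1.0);
          alive.push_back(1);
          occ[tgt] = (int)c_id.size();
          push_event(next_id, 1, t, daughter_type, tgt + 1);
          ++next_id;
        }
      }
    }
    if (divided || blocked) continue;

    // (4) migration (non-M-phase cells only)
    if (c_cycle[i] > 0.0 && p_mig[t - 1] > 0.0 &&
        unif_rand() < p_mig[t - 1]) {
      int tgt = choose_site_core(c_site[i] - 1, mig_dist, occ.data(),
                                 wE_type[t - 1], nx, ny, nz, msk.data());
      if (tgt >= 0) {
        occ[c_site[i] - 1] = 0;
        occ[tgt] = i + 1;
        c_site[i] = tgt + 1;
        push_event(c_id[i], 6, t, t, tgt + 1);
      }
    }
  }

  // compact survivors + newborns
  int n1 = (int)c_id.size();
  int kept = 0;
  for (int i = 0; i < n1; ++i)
    if (alive[i]) ++kept;
  IntegerVector o_id(kept), o_type(kept), o_site(kept), o_pass(kept);
  NumericVector o_cycle(kept), o_dying(kept);
  int k = 0;
  for (int i = 0; i < n1; ++i) {
    if (!alive[i]) continue;
    o_id[k] = c_id[i];
    o_type[k] = c_type[i];
    o_site[k] = c_site[i];
    o_pass[k] = c_pass[i];
    o_cycle[k] = c_cycle[i];
    o_dying[k] = c_dying[i];
    ++k;
  }

  NumericMatrix events(0, 6);
  if (record_events && !ev.empty()) {
    int nr = (int)(ev.size() / 6);
    events = NumericMatrix(nr, 6);
    for (int r = 0; r < nr; ++r)
      for (int c2 = 0; c2 < 6; ++c2) events(r, c2) = ev[6 * r + c2];
  }
  colnames(events) = CharacterVector::create("time", "id", "event", "from",
                                             "to", "site");

  return List::create(
      _["id"] = o_id, _["type"] = o_type, _["site"] = o_site,
      _["passage"] = o_pass, _["cycle"] = o_cycle, _["dying"] = o_dying,
      _["next_id"] = next_id, _["events"] = events);
}
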