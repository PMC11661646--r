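// Exact stochastic simulation of the four-gene alternating-cushions lattice model.
//
// Direct-method Gillespie over all reaction channels of all nuclei, with diffusive
// hopping between neighbouring reaction volumes folded into the propensity sum
// (equivalent to the next-subvolume method: hopping is an exact first-order event).
// Per-nucleus total propensities are cached; an event only touches the propensity
// of its own nucleus (and the hop target), so one event costs O(N_cells) for the
// linear scan plus O(channels per nucleus) for the local update.
//
// Gene indices 0..3 = A, B, C, D.  Strong (next-nearest-neighbour) pairs are
// (A,C) and (B,D): g ^ h == 2.  All other ordered pairs are weak (nearest
// neighbour).  All randomness is drawn from R's RNG (unif_rand), so set.seed()
// on the R side makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double beta, muM, muD, konD, koffD, konR, koffs, koffw;
  bool nn_sites;        // false when kappa = Inf (weak repressor sites absent)
  double VN, kdiff;     // kdiff = 4 D_P / l^2, total per-particle hop propensity
  int Nz, Nphi, Ncell;
  bool pinned;
};

inline bool strong_pair(int g, int h) { return (g ^ h) == 2; }

struct Sys {
  Pars p;
  std::vector<int> n1, n2;        // [g*Ncell + c]
  std::vector<int> bnd;           // [ (tgt*4 + rep)*Ncell + c ], 0/1
  std::vector<double> acell;      // per-cell total propensity
  double Atot;
  double tot1[4], tot2[4], totb[4]; // system totals: monomers, free dimers, bound dimers
  double t;

  inline int idx(int g, int c) const { return g * p.Ncell + c; }
  inline int bidx(int tgt, int rep, int c) const { return (tgt * 4 + rep) * p.Ncell + c; }
  inline int zof(int c) const { return c % p.Nz; }
  inline bool boundary_ring(int c) const { int z = zof(c); return z == 0 || z == p.Nz - 1; }

  bool site_exists(int c, int tgt, int rep) const {
    if (tgt == rep) return false;
    if (p.pinned && tgt == 0 && boundary_ring(c)) return false;
    if (!strong_pair(tgt, rep) && !p.nn_sites) return false;
    return true;
  }
  double off_rate(int tgt, int rep) const {
    return strong_pair(tgt, rep) ? p.koffs : p.koffw;
  }
  bool production_active(int c, int g) const {
    if (p.pinned && g == 0 && boundary_ring(c)) return true;
    for (int r = 0; r < 4; ++r)
      if (site_exists(c, g, r) && bnd[bidx(g, r, c)]) return false;
    return true;
  }
  int n_neighbours(int c) const {
    int z = zof(c);
    int nn = (p.Nphi > 1) ? 2 : 0;          // circumferential (periodic)
    if (p.Nphi == 1) nn = 0;
    if (z > 0) ++nn;
    if (z < p.Nz - 1) ++nn;
    return nn;
  }
  // neighbour k (0..n_neighbours-1) of cell c, order: z-1, z+1, phi-1, phi+1
  int neighbour(int c, int k) const {
    int z = zof(c), ph = c / p.Nz;
    int m = 0;
    if (z > 0)        { if (m == k) return c - 1; ++m; }
    if (z < p.Nz - 1) { if (m == k) return c + 1; ++m; }
    if (p.Nphi > 1) {
      int dn = (ph + p.Nphi - 1) % p.Nphi, up = (ph + 1) % p.Nphi;
      if (m == k) return dn * p.Nz + z; ++m;
      if (m == k) return up * p.Nz + z;
    }
    return c; // not reached
  }

  double cell_propensity(int c) const {
    double a = 0.0;
    double hop = p.kdiff * n_neighbours(c) / 4.0;
    for (int g = 0; g < 4; ++g) {
      int m = n1[idx(g, c)], d = n2[idx(g, c)];
      if (production_active(c, g)) a += p.beta;
      a += p.muM * m + p.muD * d;
      a += p.konD * m * (m - 1) / (2.0 * p.VN);
      a += p.koffD * d;
      a += hop * (m + d);
    }
    for (int tgt = 0; tgt < 4; ++tgt)
      for (int rep = 0; rep < 4; ++rep) {
        if (!site_exists(c, tgt, rep)) continue;
        if (bnd[bidx(tgt, rep, c)]) a += off_rate(tgt, rep);
        else a += p.konR * n2[idx(rep, c)] / p.VN;
      }
    return a;
  }

  void refresh_cell(int c) {
    double old = acell[c];
    acell[c] = cell_propensity(c);
    Atot += acell[c] - old;
  }
  void full_refresh() {
    Atot = 0.0;
    for (int c = 0; c < p.Ncell; ++c) { acell[c] = cell_propensity(c); Atot += acell[c]; }
  }

  // Execute one channel inside cell c chosen by residual propensity u in [0, acell[c]).
  // Channel order must mirror cell_propensity exactly.
  void fire(int c, double u) {
    double hop = p.kdiff * n_neighbours(c) / 4.0;
    for (int g = 0; g < 4; ++g) {
      int m = n1[idx(g, c)], d = n2[idx(g, c)];
      if (production_active(c, g)) {
        if (u < p.beta) { n1[idx(g, c)]++; tot1[g]++; refresh_cell(c); return; }
        u -= p.beta;
      }
      double a;
      a = p.muM * m;
      if (u < a) { n1[idx(g, c)]--; tot1[g]--; refresh_cell(c); return; }
      u -= a;
      a = p.muD * d;
      if (u < a) { n2[idx(g, c)]--; tot2[g]--; refresh_cell(c); return; }
      u -= a;
      a = p.konD * m * (m - 1) / (2.0 * p.VN);
      if (u < a) {
        n1[idx(g, c)] -= 2; n2[idx(g, c)]++;
        tot1[g] -= 2; tot2[g]++; refresh_cell(c); return;
      }
      u -= a;
      a = p.koffD * d;
      if (u < a) {
        n2[idx(g, c)]--; n1[idx(g, c)] += 2;
        tot2[g]--; tot1[g] += 2; refresh_cell(c); return;
      }
      u -= a;
      a = hop * m;
      if (u < a) {
        int k = (int)(unif_rand() * n_neighbours(c));
        if (k >= n_neighbours(c)) k = n_neighbours(c) - 1;
        int c2 = neighbour(c, k);
        n1[idx(g, c)]--; n1[idx(g, c2)]++;
        refresh_cell(c); refresh_cell(c2); return;
      }
      u -= a;
      a = hop * d;
      if (u < a) {
        int k = (int)(unif_rand() * n_neighbours(c));
        if (k >= n_neighbours(c)) k = n_neighbours(c) - 1;
        int c2 = neighbour(c, k);
        n2[idx(g, c)]--; n2[idx(g, c2)]++;
        refresh_cell(c); refresh_cell(c2); return;
      }
      u -= a;
    }
    for (int tgt = 0; tgt < 4; ++tgt)
      for (int rep = 0; rep < 4; ++rep) {
        if (!site_exists(c, tgt, rep)) continue;
        if (bnd[bidx(tgt, rep, c)]) {
          double a = off_rate(tgt, rep);
          if (u < a) {
            bnd[bidx(tgt, rep, c)] = 0; n2[idx(rep, c)]++;
            totb[rep]--; tot2[rep]++; refresh_cell(c); return;
          }
          u -= a;
        } else {
          double a = p.konR * n2[idx(rep, c)] / p.VN;
          if (u < a) {
            bnd[bidx(tgt, rep, c)] = 1; n2[idx(rep, c)]--;
            totb[rep]++; tot2[rep]--; refresh_cell(c); return;
          }
          u -= a;
        }
      }
    // Rounding can leave a sliver of u; re-fire on the last nonzero channel by
    // refreshing and retrying once with a fresh uniform draw.
    refresh_cell(c);
  }
};

Pars parse_pars(const List& pl) {
  Pars p;
  p.beta  = as<double>(pl["beta"]);
  p.muM   = as<double>(pl["mu_M"]);
  p.muD   = as<double>(pl["mu_D"]);
  p.konD  = as<double>(pl["kon_D"]);
  p.koffD = as<double>(pl["koff_D"]);
  p.konR  = as<double>(pl["kon_R"]);
  p.koffs = as<double>(pl["koff_s"]);
  double kappa = as<double>(pl["kappa"]);
  p.nn_sites = R_finite(kappa);
  p.koffw = p.nn_sites ? kappa * p.koffs : 0.0;
  p.VN   = as<double>(pl["V_N"]);
  double DP = as<double>(pl["D_P"]), l = as<double>(pl["l"]);
  p.kdiff = 4.0 * DP / (l * l);
  p.Nz   = as<int>(pl["N_z"]);
  p.Nphi = as<int>(pl["N_phi"]);
  p.Ncell = p.Nz * p.Nphi;
  p.pinned = as<bool>(pl["pinned"]);
  return p;
}

Sys make_sys(const List& state, const List& pl) {
  Sys s;
  s.p = parse_pars(pl);
  IntegerMatrix n1 = state["n1"], n2 = state["n2"];
  IntegerVector bnd = state["bnd"];
  if (n1.ncol() != s.p.Ncell || n2.ncol() != s.p.Ncell)
    stop("state dimensions do not match lattice geometry");
  s.n1.assign(s.p.Ncell * 4, 0);
  s.n2.assign(s.p.Ncell * 4, 0);
  s.bnd.assign(s.p.Ncell * 16, 0);
  for (int g = 0; g < 4; ++g) s.tot1[g] = s.tot2[g] = s.totb[g] = 0;
  for (int c = 0; c < s.p.Ncell; ++c)
    for (int g = 0; g < 4; ++g) {
      s.n1[s.idx(g, c)] = n1(g, c);
      s.n2[s.idx(g, c)] = n2(g, c);
      s.tot1[g] += n1(g, c);
      s.tot2[g] += n2(g, c);
    }
  // bnd comes in as array dim c(4,4,Ncell) = [tgt, rep, cell], column-major
  for (int c = 0; c < s.p.Ncell; ++c)
    for (int rep = 0; rep < 4; ++rep)
      for (int tgt = 0; tgt < 4; ++tgt) {
        int v = bnd[tgt + 4 * rep + 16 * c];
        s.bnd[s.bidx(tgt, rep, c)] = v;
        if (v) s.totb[rep] += 1;
      }
  s.t = as<double>(state["time"]);
  s.acell.assign(s.p.Ncell, 0.0);
  s.full_refresh();
  return s;
}

List export_state(const Sys& s) {
  IntegerMatrix n1(4, s.p.Ncell), n2(4, s.p.Ncell);
  IntegerVector bnd(16 * s.p.Ncell);
  for (int c = 0; c < s.p.Ncell; ++c)
    for (int g = 0; g < 4; ++g) {
      n1(g, c) = s.n1[s.idx(g, c)];
      n2(g, c) = s.n2[s.idx(g, c)];
    }
  for (int c = 0; c < s.p.Ncell; ++c)
    for (int rep = 0; rep < 4; ++rep)
      for (int tgt = 0; tgt < 4; ++tgt)
        bnd[tgt + 4 * rep + 16 * c] = s.bnd[s.bidx(tgt, rep, c)];
  bnd.attr("dim") = IntegerVector::create(4, 4, s.p.Ncell);
  return List::create(_["time"] = s.t, _["n1"] = n1, _["n2"] = n2, _["bnd"] = bnd,
                      _["N_z"] = s.p.Nz, _["N_phi"] = s.p.Nphi);
}

} // namespace

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(List state, List params, double t_end, double acq_dt,
                 int record_level, double max_events) {
  // record_level: 0 none, 1 totals, 2 totals+profile, 3 totals+profile+snapshots
  RNGScope scope;
  Sys s = make_sys(state, params);
  const int NC = s.p.Ncell, NZ = s.p.Nz;

  std::vector<double> rec_t;
  std::vector<double> rec_tot;           // 4 per record (total copies incl. bound)
  List profiles, snapshots;
  std::vector<NumericMatrix> profs;
  std::vector<List> snaps;

  double next_rec = s.t;                  // record initial state too
  bool absorbed = false;
  double nev = 0.0;
  long refresh_ctr = 0;

  auto do_record = [&](double at) {
    if (record_level < 1) return;
    rec_t.push_back(at);
    for (int g = 0; g < 4; ++g)
      rec_tot.push_back(s.tot1[g] + 2.0 * (s.tot2[g] + s.totb[g]));
    if (record_level >= 2) {
      NumericMatrix pr(NZ, 4);
      for (int c = 0; c < NC; ++c) {
        int z = c % NZ;
        for (int g = 0; g < 4; ++g)
          pr(z, g) += s.n1[s.idx(g, c)] + 2.0 * s.n2[s.idx(g, c)];
      }
      // bound dimers attributed to their repressor gene at their nucleus
      for (int c = 0; c < NC; ++c) {
        int z = c % NZ;
        for (int rep = 0; rep < 4; ++rep)
          for (int tgt = 0; tgt < 4; ++tgt)
            if (s.bnd[s.bidx(tgt, rep, c)]) pr(z, rep) += 2.0;
      }
      profs.push_back(pr);
    }
    if (record_level >= 3) snaps.push_back(export_state(s));
  };

  while (s.t < t_end && nev < max_events) {
    if (s.Atot <= 1e-14) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / s.Atot;
    double tnew = s.t + dt;
    while (acq_dt > 0 && next_rec <= std::min(tnew, t_end) + 1e-9) {
      do_record(next_rec);
      next_rec += acq_dt;
    }
    if (tnew >= t_end) { s.t = t_end; break; }
    s.t = tnew;
    // pick cell by linear scan of cached per-cell propensities
    double u = unif_rand() * s.Atot;
    double cum = 0.0;
    int c = NC - 1;
    for (int i = 0; i < NC; ++i) {
      cum += s.acell[i];
      if (u < cum) { c = i; break; }
    }
    double resid = u - (cum - s.acell[c]);
    if (resid < 0) resid = 0;
    if (resid >= s.acell[c]) resid = s.acell[c] * (1.0 - 1e-12);
    s.fire(c, resid);
    nev += 1.0;
    if (++refresh_ctr >= 1000000) { s.full_refresh(); refresh_ctr = 0; }
  }
  // An absorbed state is frozen forever, so the remaining acquisition grid can
  // be filled with it; an event-budget stop cannot (state would still evolve).
  if (acq_dt > 0 && (absorbed || s.t >= t_end - 1e-9))
    while (next_rec <= t_end + 1e-9) { do_record(next_rec); next_rec += acq_dt; }

  int nr = (int)rec_t.size();
  NumericMatrix totals(4, nr);
  NumericVector times(nr);
  for (int i = 0; i < nr; ++i) {
    times[i] = rec_t[i];
    for (int g = 0; g < 4; ++g) totals(g, i) = rec_tot[4 * i + g];
  }
  List out = List::create(
    _["state"] = export_state(s),
    _["times"] = times,
    _["totals"] = totals,
    _["n_events"] = nev,
    _["absorbed"] = absorbed);
  if (record_level >= 2) {
    List pl(profs.size());
    for (size_t i = 0; i < profs.size(); ++i) pl[i] = profs[i];
    out["profiles"] = pl;
  }
  if (record_level >= 3) {
    List sl(snaps.size());
    for (size_t i = 0; i < snaps.size(); ++i) sl[i] = snaps[i];
    out["snapshots"] = sl;
  }
  return out;
}

// [[Rcpp::export(name = ".ssa_totals_cpp")]]
NumericVector ssa_totals_cpp(List state, List params) {
  Sys s = make_sys(state, params);
  NumericVector tot(4);
  for (int g = 0; g < 4; ++g) tot[g] = s.tot1[g] + 2.0 * (s.tot2[g] + s.totb[g]);
  tot.attr("names") = CharacterVector::create("A", "B", "C", "D");
  return tot;
}

// Per-channel propensities of one nucleus, for cross-checking against the
// R-level reaction list (build_reactions). Returns named vector in the fixed
// channel order used by the simulator.
// [[Rcpp::export(name = ".cell_propensities_cpp")]]
NumericVector cell_propensities_cpp(List state, List params, int cell) {
  Sys s = make_sys(state, params);
  int c = cell - 1;
  if (c < 0 || c >= s.p.Ncell) stop("cell out of range");
  std::vector<double> a;
  std::vector<std::string> nm;
  const char* G = "ABCD";
  double hop = s.p.kdiff * s.n_neighbours(c) / 4.0;
  for (int g = 0; g < 4; ++g) {
    int m = s.n1[s.idx(g, c)], d = s.n2[s.idx(g, c)];
    a.push_back(s.production_active(c, g) ? s.p.beta : 0.0);
    nm.push_back(std::string("prod_") + G[g]);
    a.push_back(s.p.muM * m);           nm.push_back(std::string("mdecay_") + G[g]);
    a.push_back(s.p.muD * d);           nm.push_back(std::string("ddecay_") + G[g]);
    a.push_back(s.p.konD * m * (m - 1) / (2.0 * s.p.VN));
    nm.push_back(std::string("dim_") + G[g]);
    a.push_back(s.p.koffD * d);         nm.push_back(std::string("dedim_") + G[g]);
    a.push_back(hop * m);               nm.push_back(std::string("hopm_") + G[g]);
    a.push_back(hop * d);               nm.push_back(std::string("hopd_") + G[g]);
  }
  for (int tgt = 0; tgt < 4; ++tgt)
    for (int rep = 0; rep < 4; ++rep) {
      if (!s.site_exists(c, tgt, rep)) continue;
      std::string suff = std::string("_") + G[rep] + "_on_" + G[tgt];
      if (s.bnd[s.bidx(tgt, rep, c)]) {
        a.push_back(s.off_rate(tgt, rep)); nm.push_back("unbind" + suff);
      } else {
        a.push_back(s.p.konR * s.n2[s.idx(rep, c)] / s.p.VN);
        nm.push_back("bind" + suff);
      }
    }
  NumericVector out(a.begin(), a.end());
  CharacterVector nms(nm.size());
  for (size_t i = 0; i < nm.size(); ++i) nms[i] = nm[i];
  out.attr("names") = nms;
  return out;
}
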