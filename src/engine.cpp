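#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// 26-site Moore neighborhood, fixed order (dz slowest, dx fastest),
// matching neighbor_offsets() on the R side.
static const int NOFF = 26;
static int OFF[NOFF][3];
static bool off_ready = false;

static void init_offsets() {
  if (off_ready) return;
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF[k][0] = dx; OFF[k][1] = dy; OFF[k][2] = dz; ++k;
      }
  off_ready = true;
}

// "forward" offsets select each unordered in-bounds pair exactly once
static bool forward_off(int i) {
  int dx = OFF[i][0], dy = OFF[i][1], dz = OFF[i][2];
  return dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx > 0)));
}

struct Grid {
  const int *lat;
  int Lx, Ly, Lz;
  int loff[NOFF];  // linear neighbor offsets, valid away from the boundary
  void init() {
    init_offsets();
    for (int k = 0; k < NOFF; ++k)
      loff[k] = OFF[k][0] + Lx * (OFF[k][1] + Ly * OFF[k][2]);
  }
  int n() const { return Lx * Ly * Lz; }
  void coords(int idx, int &x, int &y, int &z) const {
    x = idx % Lx; y = (idx / Lx) % Ly; z = idx / (Lx * Ly);
  }
  bool interior(int x, int y, int z) const {
    return x > 0 && x < Lx - 1 && y > 0 && y < Ly - 1 && z > 0 && z < Lz - 1;
  }
  // neighbor index for offset k, or -1 if out of bounds (virtual medium)
  int nbr(int x, int y, int z, int k) const {
    int nx = x + OFF[k][0], ny = y + OFF[k][1], nz = z + OFF[k][2];
    if (nx < 0 || nx >= Lx || ny < 0 || ny >= Ly || nz < 0 || nz >= Lz)
      return -1;
    return nx + Lx * (ny + Ly * nz);
  }
  // all 26 neighbor indices of site idx into out[] (-1 = virtual medium)
  void nbrs(int idx, int *out) const {
    int x, y, z;
    coords(idx, x, y, z);
    if (interior(x, y, z)) {
      for (int k = 0; k < NOFF; ++k) out[k] = idx + loff[k];
    } else {
      for (int k = 0; k < NOFF; ++k) out[k] = nbr(x, y, z, k);
    }
  }
};

// [[Rcpp::export]]
List cpp_count_bonds(IntegerVector lat, IntegerVector dims) {
  init_offsets();
  Grid g{INTEGER(lat), dims[0], dims[1], dims[2]};
  g.init();
  NumericMatrix pairs(5, 5);
  NumericVector types(5), boundary(5);
  for (int idx = 0; idx < g.n(); ++idx) {
    int t = g.lat[idx];
    types[t] += 1;
    int x, y, z; g.coords(idx, x, y, z);
    for (int k = 0; k < NOFF; ++k) {
      int nb = g.nbr(x, y, z, k);
      if (nb < 0) { boundary[t] += 1; continue; }
      if (!forward_off(k)) continue;
      int u = g.lat[nb];
      int a = std::min(t, u), b = std::max(t, u);
      pairs(a, b) += 1;
    }
  }
  for (int a = 0; a < 5; ++a)
    for (int b = a + 1; b < 5; ++b) pairs(b, a) = pairs(a, b);
  return List::create(_["pairs"] = pairs, _["types"] = types,
                      _["boundary"] = boundary);
}

// Local bond-sum energy change of swapping the (different-type) particles
// at sites a and b; virtual out-of-bounds neighbors count as medium.
static double delta_swap(const Grid &g, int ia, int ib, int ta, int tb,
                         const double *eps /* 4x4 col-major */) {
  double dE = 0.0;
  int nb[NOFF];
  g.nbrs(ia, nb);
  for (int k = 0; k < NOFF; ++k) {
    if (nb[k] == ib) continue;  // the shared bond is invariant under the swap
    int t = nb[k] < 0 ? 0 : g.lat[nb[k]];
    dE += eps[ta + 4 * t] - eps[tb + 4 * t];
  }
  g.nbrs(ib, nb);
  for (int k = 0; k < NOFF; ++k) {
    if (nb[k] == ia) continue;
    int t = nb[k] < 0 ? 0 : g.lat[nb[k]];
    dE += eps[tb + 4 * t] - eps[ta + 4 * t];
  }
  return dE;
}

// [[Rcpp::export]]
double cpp_delta_energy_swap(IntegerVector lat, IntegerVector dims,
                             IntegerVector a, IntegerVector b,
                             NumericMatrix eps) {
  init_offsets();
  Grid g{INTEGER(lat), dims[0], dims[1], dims[2]};
  g.init();
  int ia = a[0] + g.Lx * (a[1] + g.Ly * a[2]);
  int ib = b[0] + g.Lx * (b[1] + g.Ly * b[2]);
  return delta_swap(g, ia, ib, g.lat[ia], g.lat[ib], REAL(eps));
}

// Sizes of 26-connected components of the cell sites (types 2 and 3, or a
// caller-chosen subset).
// [[Rcpp::export]]
IntegerVector cpp_cluster_sizes(IntegerVector lat, IntegerVector dims,
                                IntegerVector cell_types) {
  init_offsets();
  Grid g{INTEGER(lat), dims[0], dims[1], dims[2]};
  g.init();
  std::unordered_set<int> want(cell_types.begin(), cell_types.end());
  std::unordered_set<int> cells;
  for (int idx = 0; idx < g.n(); ++idx)
    if (want.count(g.lat[idx])) cells.insert(idx);
  std::vector<int> sizes;
  std::unordered_set<int> seen;
  std::vector<int> stack;
  for (int start : cells) {
    if (seen.count(start)) continue;
    int sz = 0;
    stack.push_back(start);
    seen.insert(start);
    while (!stack.empty()) {
      int s = stack.back(); stack.pop_back();
      ++sz;
      int x, y, z; g.coords(s, x, y, z);
      for (int k = 0; k < NOFF; ++k) {
        int nb = g.nbr(x, y, z, k);
        if (nb >= 0 && cells.count(nb) && !seen.count(nb)) {
          seen.insert(nb);
          stack.push_back(nb);
        }
      }
    }
    sizes.push_back(sz);
  }
  std::sort(sizes.begin(), sizes.end(), std::greater<int>());
  return wrap(sizes);
}

static int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Metropolis Monte Carlo engine: one call runs n_mcs sweeps, threading R's
// RNG (bit-reproducible under set.seed, resumable across calls).
// [[Rcpp::export]]
List cpp_run(IntegerVector lat_in, IntegerVector dims, IntegerVector region,
             NumericMatrix eps, NumericMatrix gamma, double ET,
             double p2, double p3, int n_mcs, int metrics_interval,
             int mcs0, bool validate) {
  init_offsets();
  std::vector<int> lat(lat_in.begin(), lat_in.end());
  Grid g{lat.data(), dims[0], dims[1], dims[2]};
  g.init();
  const double *E = REAL(eps);
  const int *reg = INTEGER(region);

  // running bond-count bookkeeping (exact, updated on every event)
  double npairs[4][4] = {{0}};
  double ntypes[4] = {0};
  double nbound[4] = {0};
  std::vector<int> cellSites;
  for (int idx = 0; idx < g.n(); ++idx) {
    int t = lat[idx];
    if (t < 0 || t > 3)
      stop("the engine simulates particle types 0..3 only (found type %d).", t);
    ntypes[t] += 1;
    if (t >= 2) cellSites.push_back(idx);
    int x, y, z; g.coords(idx, x, y, z);
    for (int k = 0; k < NOFF; ++k) {
      int nb = g.nbr(x, y, z, k);
      if (nb < 0) { nbound[t] += 1; continue; }
      if (!forward_off(k)) continue;
      int u = lat[nb];
      npairs[std::min(t, u)][std::max(t, u)] += 1;
    }
  }

  auto change_type = [&](int idx, int to) {
    int from = lat[idx];
    int nb[NOFF];
    g.nbrs(idx, nb);
    for (int k = 0; k < NOFF; ++k) {
      if (nb[k] < 0) { nbound[from] -= 1; nbound[to] += 1; continue; }
      int u = lat[nb[k]];
      npairs[std::min(from, u)][std::max(from, u)] -= 1;
      npairs[std::min(to, u)][std::max(to, u)] += 1;
    }
    ntypes[from] -= 1; ntypes[to] += 1;
    lat[idx] = to;
  };

  auto interfacial = [&](int idx, int t) {
    int nb[NOFF];
    g.nbrs(idx, nb);
    for (int k = 0; k < NOFF; ++k) {
      if (nb[k] < 0 || lat[nb[k]] != t) return true;  // virtual medium differs
    }
    return false;
  };

  // trajectory storage
  std::vector<double> r_mcs, r_Etot, r_Eint, r_Ecoh;
  std::vector<double> r_N[4];
  std::vector<double> r_pairs[10];
  std::vector<double> r_prolif, r_acc, r_rej, r_skip;
  std::vector<double> r_infil, r_wrap, r_esc, r_nclust, r_meanclust, r_maxclust;
  int pair_i[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
  int pair_j[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};
  double tal_prolif = 0, tal_acc = 0, tal_rej = 0, tal_skip = 0;

  auto record = [&](int mcs) {
    if (validate) {  // full recomputation cross-check of the running counts
      double chk[4][4] = {{0}};
      int fwd[13], nf = 0;
      for (int k = 0; k < NOFF; ++k) if (forward_off(k)) fwd[nf++] = k;
      for (int idx = 0; idx < g.n(); ++idx) {
        int x, y, z; g.coords(idx, x, y, z);
        int t = lat[idx];
        if (g.interior(x, y, z)) {
          for (int q = 0; q < nf; ++q) {
            int u = lat[idx + g.loff[fwd[q]]];
            chk[std::min(t, u)][std::max(t, u)] += 1;
          }
        } else {
          for (int q = 0; q < nf; ++q) {
            int nb = g.nbr(x, y, z, fwd[q]);
            if (nb < 0) continue;
            int u = lat[nb];
            chk[std::min(t, u)][std::max(t, u)] += 1;
          }
        }
      }
      for (int a = 0; a < 4; ++a)
        for (int b = a; b < 4; ++b)
          if (chk[a][b] != npairs[a][b])
            stop("internal bond-count drift detected at MCS %d.", mcs);
    }
    double e_int = 0, e_coh = 0;
    for (int a = 0; a < 4; ++a) {
      e_coh -= 13.0 * eps(a, a) * ntypes[a];
      for (int b = a + 1; b < 4; ++b) e_int += gamma(a, b) * npairs[a][b];
    }
    r_mcs.push_back(mcs);
    r_Etot.push_back(e_int + e_coh);
    r_Eint.push_back(e_int);
    r_Ecoh.push_back(e_coh);
    for (int a = 0; a < 4; ++a) r_N[a].push_back(ntypes[a]);
    for (int q = 0; q < 10; ++q)
      r_pairs[q].push_back(npairs[pair_i[q]][pair_j[q]]);
    r_prolif.push_back(tal_prolif); r_acc.push_back(tal_acc);
    r_rej.push_back(tal_rej); r_skip.push_back(tal_skip);
    tal_prolif = tal_acc = tal_rej = tal_skip = 0;
    // morphometrics against the frozen initial-geometry labels
    double in_tumor2 = 0, in_medium3 = 0;
    for (int s : cellSites) {
      if (lat[s] == 2 && reg[s] == 1) in_tumor2 += 1;
      if (lat[s] == 3 && reg[s] == 0) in_medium3 += 1;
    }
    r_infil.push_back(ntypes[2] > 0 ? in_tumor2 / ntypes[2] : 0.0);
    r_esc.push_back(ntypes[3] > 0 ? in_medium3 / ntypes[3] : 0.0);
    double het3 = npairs[0][3] + npairs[1][3] + npairs[2][3];
    r_wrap.push_back(het3 > 0 ? npairs[2][3] / het3 : 0.0);
    // 26-connected cell clusters
    std::unordered_set<int> cells(cellSites.begin(), cellSites.end());
    std::unordered_set<int> seen;
    std::vector<int> stack;
    int nclust = 0, maxsz = 0;
    for (int start : cells) {
      if (seen.count(start)) continue;
      ++nclust;
      int sz = 0;
      stack.push_back(start); seen.insert(start);
      while (!stack.empty()) {
        int s = stack.back(); stack.pop_back();
        ++sz;
        int x, y, z; g.coords(s, x, y, z);
        for (int k = 0; k < NOFF; ++k) {
          int nb = g.nbr(x, y, z, k);
          if (nb >= 0 && cells.count(nb) && !seen.count(nb)) {
            seen.insert(nb); stack.push_back(nb);
          }
        }
      }
      if (sz > maxsz) maxsz = sz;
    }
    r_nclust.push_back(nclust);
    r_meanclust.push_back(nclust > 0 ? (double)cells.size() / nclust : 0.0);
    r_maxclust.push_back(maxsz);
  };

  auto shuffle_vec = [&](std::vector<int> &v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
      int j = rand_int(i + 1);
      std::swap(v[i], v[j]);
    }
  };

  std::vector<int> cand(NOFF), list3, list2;

  // One cell event: one Bernoulli(p) draw decides proliferation vs move,
  // then a uniformly chosen eligible partner, then (moves with dE > 0 only)
  // the Metropolis acceptance draw — this draw order is the reproducibility
  // contract.
  auto process = [&](const std::vector<int> &positions, int t, double p) {
    for (int pos : positions) {
      int s = cellSites[pos];
      if (lat[s] != t) { tal_skip += 1; continue; }  // displaced since listing
      int nbs[NOFF];
      g.nbrs(s, nbs);
      double u = unif_rand();
      if (u < p) {
        // proliferation: daughter replaces a random hydrogel/medium neighbor
        int m = 0;
        for (int k = 0; k < NOFF; ++k) {
          if (nbs[k] >= 0 && lat[nbs[k]] <= 1) cand[m++] = nbs[k];
        }
        if (m == 0) { tal_skip += 1; continue; }  // buried: only superficial cells divide
        int d = cand[rand_int(m)];
        change_type(d, t);
        cellSites.push_back(d);  // daughter acts from the next MCS
        tal_prolif += 1;
      } else {
        // trial move: cancer cells may swap with any different type;
        // peritumoral cells only with medium or hydrogel
        int m = 0;
        for (int k = 0; k < NOFF; ++k) {
          if (nbs[k] < 0) continue;
          int nt = lat[nbs[k]];
          bool ok = (t == 3) ? (nt != 3) : (nt <= 1);
          if (ok) cand[m++] = nbs[k];
        }
        if (m == 0) { tal_skip += 1; continue; }
        int b = cand[rand_int(m)];
        int tb = lat[b];
        double dE = delta_swap(g, s, b, t, tb, E);
        bool acc = dE <= 0.0 || unif_rand() < std::exp(-dE / ET);
        if (acc) {
          change_type(s, tb);
          change_type(b, t);
          if (tb <= 1) cellSites[pos] = b;  // cell moved into material
          tal_acc += 1;
        } else {
          tal_rej += 1;
        }
      }
    }
  };

  record(mcs0);  // initial state
  for (int step = 1; step <= n_mcs; ++step) {
    // canonical sweep state: the cell-site list is sorted before listing, so
    // a run resumed from a snapshot replays exactly like an uninterrupted one
    std::sort(cellSites.begin(), cellSites.end());
    list3.clear(); list2.clear();
    for (int pos = 0; pos < (int)cellSites.size(); ++pos) {
      int s = cellSites[pos];
      int t = lat[s];
      if (t == 3 && interfacial(s, 3)) list3.push_back(pos);
      else if (t == 2 && interfacial(s, 2)) list2.push_back(pos);
    }
    shuffle_vec(list3);
    process(list3, 3, p3);
    shuffle_vec(list2);
    process(list2, 2, p2);
    int mcs = mcs0 + step;
    if (step == n_mcs || (metrics_interval > 0 && mcs % metrics_interval == 0))
      record(mcs);
    if (step % 1000 == 0) checkUserInterrupt();
  }

  List traj(22);
  CharacterVector tn(22);
  int ti = 0;
  auto put = [&](const char *nm, const std::vector<double> &v) {
    tn[ti] = nm; traj[ti] = wrap(v); ++ti;
  };
  put("mcs", r_mcs); put("E_total", r_Etot);
  put("E_interfacial", r_Eint); put("E_cohesion", r_Ecoh);
  put("N0", r_N[0]); put("N1", r_N[1]); put("N2", r_N[2]); put("N3", r_N[3]);
  const char *pair_nm[10] = {"N00", "N01", "N02", "N03", "N11",
                             "N12", "N13", "N22", "N23", "N33"};
  for (int q = 0; q < 10; ++q) put(pair_nm[q], r_pairs[q]);
  put("ev_proliferation", r_prolif); put("ev_move_accepted", r_acc);
  put("ev_move_rejected", r_rej); put("ev_skipped", r_skip);
  traj.attr("names") = tn;
  List morph = List::create(
      _["infiltration_index"] = r_infil, _["wrapping_index"] = r_wrap,
      _["escape_fraction"] = r_esc, _["n_clusters"] = r_nclust,
      _["mean_cluster_size"] = r_meanclust, _["max_cluster_size"] = r_maxclust);
  return List::create(_["lat"] = wrap(lat), _["trajectory"] = traj,
                      _["morphometrics"] = morph,
                      _["final_mcs"] = mcs0 + n_mcs);
}
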