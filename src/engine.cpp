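// Event-driven (Gillespie) core of the FGBA lattice automaton.
//
// States are coded 0=F (forest), 1=G (grass), 2=B (burning), 3=A (ash).
// The lattice is a torus with 4 directional neighbour slots per cell; on
// width- or height-2 domains the two distinct neighbours are each counted
// twice, keeping the lattice 4-regular.
//
// All channels except spontaneous ignition live in a Fenwick tree of
// per-cell propensities; ignition is a single scalar channel phi_eff * nG
// with a maintained list of grass cells, so that feedback control of phi
// costs O(1) per event.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

namespace {

struct Kahan {
  double s, c;
  Kahan() : s(0.0), c(0.0) {}
  void add(double x) {
    double y = x - c;
    double t = s + y;
    c = (t - s) - y;
    s = t;
  }
  double val() const { return s; }
};

struct Fenwick {
  int n;
  std::vector<double> tr;
  void init(int n_) {
    n = n_;
    tr.assign(n + 1, 0.0);
  }
  void add(int i, double d) {
    for (++i; i <= n; i += i & -i) tr[i] += d;
  }
  double total() const {
    double s = 0;
    for (int i = n; i > 0; i -= i & -i) s += tr[i];
    return s;
  }
  // first 0-based index whose prefix sum exceeds u
  int sample(double u) const {
    int pos = 0, pw = 1;
    while ((pw << 1) <= n) pw <<= 1;
    for (; pw; pw >>= 1) {
      int nxt = pos + pw;
      if (nxt <= n && tr[nxt] <= u) {
        pos = nxt;
        u -= tr[nxt];
      }
    }
    return pos < n ? pos : n - 1;
  }
};

void build_neighbours(int W, int H, std::vector<int>& nbr) {
  // column-major indexing: cell i at row r = i % H, col c = i / H
  int N = W * H;
  nbr.resize(4 * N);
  for (int i = 0; i < N; ++i) {
    int r = i % H, c = i / H;
    int up = (r + H - 1) % H, dn = (r + 1) % H;
    int lf = (c + W - 1) % W, rt = (c + 1) % W;
    nbr[4 * i + 0] = c * H + up;
    nbr[4 * i + 1] = c * H + dn;
    nbr[4 * i + 2] = lf * H + r;
    nbr[4 * i + 3] = rt * H + r;
  }
}

// grass-cluster flood fill; sizes/fg in raw cell / pair counts,
// clusters numbered 1.. in row-major-equivalent (index) discovery order
void label_grass(const std::vector<int>& st, const std::vector<int>& nbr,
                 int N, std::vector<int>& lab, std::vector<double>& sizes,
                 std::vector<double>& fgs) {
  lab.assign(N, 0);
  sizes.clear();
  fgs.clear();
  std::vector<int> stack;
  int nc = 0;
  for (int i = 0; i < N; ++i) {
    if (st[i] != 1 || lab[i]) continue;
    ++nc;
    lab[i] = nc;
    stack.push_back(i);
    double sz = 0, fg = 0;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      sz += 1;
      for (int k = 0; k < 4; ++k) {
        int j = nbr[4 * c + k];
        if (st[j] == 1) {
          if (!lab[j]) {
            lab[j] = nc;
            stack.push_back(j);
          }
        } else if (st[j] == 0) {
          fg += 1;
        }
      }
    }
    sizes.push_back(sz);
    fgs.push_back(fg);
  }
}

inline double pair_fg(const std::vector<int>& st, const std::vector<int>& nbr,
                      int N) {
  double p = 0;
  for (int i = 0; i < N; ++i) {
    if (st[i] != 1) continue;
    for (int k = 0; k < 4; ++k)
      if (st[nbr[4 * i + k]] == 0) p += 1;
  }
  return p;
}

}  // namespace

// [[Rcpp::export]]
List cpp_grass_clusters(IntegerVector grid, int W, int H) {
  int N = W * H;
  std::vector<int> st(grid.begin(), grid.end());
  std::vector<int> nbr;
  build_neighbours(W, H, nbr);
  std::vector<int> lab;
  std::vector<double> sizes, fgs;
  label_grass(st, nbr, N, lab, sizes, fgs);
  return List::create(_["labels"] = IntegerVector(lab.begin(), lab.end()),
                      _["sizes"] = NumericVector(sizes.begin(), sizes.end()),
                      _["fg"] = NumericVector(fgs.begin(), fgs.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(IntegerVector grid, int W, int H) {
  int N = W * H;
  std::vector<int> st(grid.begin(), grid.end());
  std::vector<int> nbr;
  build_neighbours(W, H, nbr);
  NumericMatrix P(4, 4);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 4; ++k) P(st[i], st[nbr[4 * i + k]]) += 1;
  return P;  // ordered directional adjacency counts
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector grid, int W, int H, double alpha, double beta,
                  double gam, double phi, double lam, double mu, double rho_g,
                  double rho_f, double t_end, double record_dt,
                  NumericVector snapshot_times, bool record_pairs,
                  bool control_on, double ctrl_g, double ctrl_Fref,
                  bool stop_when_no_B, bool track_burn, bool track_occupancy,
                  bool track_ignitions, double max_events) {
  const int N = W * H;
  std::vector<int> st(grid.begin(), grid.end());
  std::vector<int> nbr;
  build_neighbours(W, H, nbr);

  std::vector<int> nF(N, 0), nB(N, 0);
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < N; ++i) {
    cnt[st[i]]++;
    for (int k = 0; k < 4; ++k) {
      int s = st[nbr[4 * i + k]];
      if (s == 0) nF[i]++;
      if (s == 2) nB[i]++;
    }
  }

  // grass-cell list for the scalar ignition channel
  std::vector<int> glist, gpos(N, -1);
  for (int i = 0; i < N; ++i)
    if (st[i] == 1) {
      gpos[i] = (int)glist.size();
      glist.push_back(i);
    }

  std::vector<double> rate(N, 0.0);
  Fenwick fen;
  fen.init(N);
  auto cell_rate = [&](int i) -> double {
    switch (st[i]) {
      case 0:
        return gam + rho_f * nB[i];
      case 1:
        return beta + alpha * nF[i] + rho_g * nB[i];
      case 2:
        return mu;
      default:
        return beta + lam + alpha * nF[i];
    }
  };
  for (int i = 0; i < N; ++i) {
    rate[i] = cell_rate(i);
    fen.add(i, rate[i]);
  }
  auto upd_rate = [&](int i) {
    double nr = cell_rate(i);
    if (nr != rate[i]) {
      fen.add(i, nr - rate[i]);
      rate[i] = nr;
    }
  };

  std::vector<char> everB(track_burn ? N : 0, 0);
  if (track_burn)
    for (int i = 0; i < N; ++i)
      if (st[i] == 2) everB[i] = 1;

  // occupancy tracking for tiny lattices
  std::unordered_map<long, double> occ;
  long code = 0;
  std::vector<long> pow4;
  if (track_occupancy) {
    if (N > 12) stop("occupancy tracking only supported for N <= 12 cells");
    pow4.resize(N);
    long p = 1;
    for (int i = 0; i < N; ++i) {
      pow4[i] = p;
      p *= 4;
    }
    for (int i = 0; i < N; ++i) code += st[i] * pow4[i];
  }

  auto apply_change = [&](int c, int snew) {
    int sold = st[c];
    if (track_occupancy) code += (long)(snew - sold) * pow4[c];
    st[c] = snew;
    cnt[sold]--;
    cnt[snew]++;
    if (sold == 1) {
      int p = gpos[c], last = (int)glist.size() - 1;
      glist[p] = glist[last];
      gpos[glist[p]] = p;
      glist.pop_back();
      gpos[c] = -1;
    }
    if (snew == 1) {
      gpos[c] = (int)glist.size();
      glist.push_back(c);
    }
    if (snew == 2 && track_burn) everB[c] = 1;
    for (int k = 0; k < 4; ++k) {
      int j = nbr[4 * c + k];
      if (sold == 0) nF[j]--;
      else if (sold == 2) nB[j]--;
      if (snew == 0) nF[j]++;
      else if (snew == 2) nB[j]++;
      upd_rate(j);
    }
    upd_rate(c);
  };

  // channel counters
  double ev_beta_GF = 0, ev_beta_AF = 0, ev_alpha_GF = 0, ev_alpha_AF = 0,
         ev_gamma_FG = 0, ev_phi_GB = 0, ev_rhog_GB = 0, ev_rhof_FB = 0,
         ev_mu_BA = 0, ev_lambda_AG = 0;
  std::vector<double> ignition_times;

  // record buffers
  std::vector<double> r_t, r_F, r_G, r_B, r_A, r_phi, r_iF, r_iG, r_FG, r_FGcg;
  std::vector<int> lab_buf;
  std::vector<double> sz_buf, fg_buf;

  Kahan tK, intF, intG, clampK;
  double t = 0.0;
  double next_rec = 0.0;
  double phi_eff = phi;
  bool truncated = false;
  double n_events = 0;
  double rebuild_at = 1048576;

  NumericVector snap_t = clone(snapshot_times);
  std::sort(snap_t.begin(), snap_t.end());
  int si = 0, ns = snap_t.size();
  List snaps;
  std::vector<double> snap_done_t;

  auto do_record = [&](double rt) {
    r_t.push_back(rt);
    double fF = cnt[0] / (double)N, fG = cnt[1] / (double)N;
    r_F.push_back(fF);
    r_G.push_back(fG);
    r_B.push_back(cnt[2] / (double)N);
    r_A.push_back(cnt[3] / (double)N);
    r_phi.push_back(phi_eff);
    r_iF.push_back(intF.val() + fF * (rt - t));
    r_iG.push_back(intG.val() + fG * (rt - t));
    if (record_pairs) {
      r_FG.push_back(pair_fg(st, nbr, N) / N);
      label_grass(st, nbr, N, lab_buf, sz_buf, fg_buf);
      double totG = cnt[1];
      double w = 0;
      if (totG > 0)
        for (size_t j = 0; j < sz_buf.size(); ++j)
          w += (sz_buf[j] / totG) * (fg_buf[j] / N);
      r_FGcg.push_back(w);
    }
  };
  auto do_snapshot = [&](double stime) {
    snaps.push_back(IntegerVector(st.begin(), st.end()));
    snap_done_t.push_back(stime);
  };

  while (t < t_end) {
    if (control_on) {
      phi_eff = phi + ctrl_g * (cnt[0] / (double)N - ctrl_Fref);
      if (phi_eff < 0) phi_eff = 0;
    }
    double ign = phi_eff * (double)glist.size();
    double tot = fen.total() + ign;
    if (tot <= 0) {
      // frozen chain: jump to t_end
      while (next_rec <= t_end + 1e-12) {
        do_record(next_rec);
        next_rec += record_dt;
      }
      while (si < ns && snap_t[si] <= t_end + 1e-12) do_snapshot(snap_t[si++]);
      intF.add(cnt[0] / (double)N * (t_end - t));
      intG.add(cnt[1] / (double)N * (t_end - t));
      if (track_occupancy) occ[code] += t_end - t;
      t = t_end;
      tK = Kahan();
      tK.add(t);
      break;
    }
    double dt = R::exp_rand() / tot;
    double t_new = t + dt;

    while (next_rec <= t_end + 1e-12 && next_rec < t_new) {
      do_record(next_rec);
      next_rec += record_dt;
    }
    while (si < ns && snap_t[si] < t_new && snap_t[si] <= t_end + 1e-12)
      do_snapshot(snap_t[si++]);

    if (t_new >= t_end) {
      double rem = t_end - t;
      intF.add(cnt[0] / (double)N * rem);
      intG.add(cnt[1] / (double)N * rem);
      if (track_occupancy) occ[code] += rem;
      if (control_on && phi_eff <= 0) clampK.add(rem);
      t = t_end;
      break;
    }

    intF.add(cnt[0] / (double)N * dt);
    intG.add(cnt[1] / (double)N * dt);
    if (track_occupancy) occ[code] += dt;
    if (control_on && phi_eff <= 0) clampK.add(dt);
    tK.add(dt);
    t = tK.val();

    double u = R::unif_rand() * tot;
    if (u < ign) {
      // spontaneous ignition on a uniformly chosen grass cell
      int idx = (int)(R::unif_rand() * glist.size());
      if (idx >= (int)glist.size()) idx = (int)glist.size() - 1;
      int c = glist[idx];
      apply_change(c, 2);
      ev_phi_GB += 1;
      if (track_ignitions) ignition_times.push_back(t);
    } else {
      int c = fen.sample(u - ign);
      double rc = rate[c];
      if (rc <= 0) {  // numerical fringe: resample by scan
        for (int i = 0; i < N; ++i)
          if (rate[i] > rc) {
            c = i;
            rc = rate[i];
          }
        if (rc <= 0) continue;
      }
      double v = R::unif_rand() * rc;
      switch (st[c]) {
        case 0:  // F: gamma -> G, rho_f*nB -> B
          if (v < gam) {
            apply_change(c, 1);
            ev_gamma_FG += 1;
          } else {
            apply_change(c, 2);
            ev_rhof_FB += 1;
          }
          break;
        case 1:  // G: beta -> F, alpha*nF -> F, rho_g*nB -> B
          if (v < beta) {
            apply_change(c, 0);
            ev_beta_GF += 1;
          } else if (v < beta + alpha * nF[c]) {
            apply_change(c, 0);
            ev_alpha_GF += 1;
          } else {
            apply_change(c, 2);
            ev_rhog_GB += 1;
          }
          break;
        case 2:  // B: mu -> A
          apply_change(c, 3);
          ev_mu_BA += 1;
          break;
        default:  // A: beta -> F, lambda -> G, alpha*nF -> F
          if (v < beta) {
            apply_change(c, 0);
            ev_beta_AF += 1;
          } else if (v < beta + lam) {
            apply_change(c, 1);
            ev_lambda_AG += 1;
          } else {
            apply_change(c, 0);
            ev_alpha_AF += 1;
          }
          break;
      }
    }
    n_events += 1;
    if (n_events >= rebuild_at) {
      rebuild_at += 1048576;
      fen.init(N);
      for (int i = 0; i < N; ++i) fen.add(i, rate[i]);
    }
    if (stop_when_no_B && cnt[2] == 0) break;
    if (n_events >= max_events) {
      truncated = true;
      break;
    }
  }

  // flush any remaining record/snapshot times not beyond current t
  while (next_rec <= t + 1e-12) {
    do_record(next_rec);
    next_rec += record_dt;
  }
  while (si < ns && snap_t[si] <= t + 1e-12) do_snapshot(snap_t[si++]);

  NumericVector counts = NumericVector::create(
      _["beta_GF"] = ev_beta_GF, _["beta_AF"] = ev_beta_AF,
      _["alpha_GF"] = ev_alpha_GF, _["alpha_AF"] = ev_alpha_AF,
      _["gamma_FG"] = ev_gamma_FG, _["phi_GB"] = ev_phi_GB,
      _["rhog_GB"] = ev_rhog_GB, _["rhof_FB"] = ev_rhof_FB,
      _["mu_BA"] = ev_mu_BA, _["lambda_AG"] = ev_lambda_AG);

  List out = List::create(
      _["t"] = NumericVector(r_t.begin(), r_t.end()),
      _["F"] = NumericVector(r_F.begin(), r_F.end()),
      _["G"] = NumericVector(r_G.begin(), r_G.end()),
      _["B"] = NumericVector(r_B.begin(), r_B.end()),
      _["A"] = NumericVector(r_A.begin(), r_A.end()),
      _["phi"] = NumericVector(r_phi.begin(), r_phi.end()),
      _["intF"] = NumericVector(r_iF.begin(), r_iF.end()),
      _["intG"] = NumericVector(r_iG.begin(), r_iG.end()),
      _["FG"] = NumericVector(r_FG.begin(), r_FG.end()),
      _["FGcg"] = NumericVector(r_FGcg.begin(), r_FGcg.end()),
      _["counts"] = counts,
      _["ignition_times"] =
          NumericVector(ignition_times.begin(), ignition_times.end()),
      _["final"] = IntegerVector(st.begin(), st.end()),
      _["t_final"] = t, _["n_events"] = n_events, _["truncated"] = truncated,
      _["clamped_time"] = clampK.val(),
      _["snapshots"] = snaps,
      _["snapshot_times"] =
          NumericVector(snap_done_t.begin(), snap_done_t.end()));
  if (track_burn) out["ever_burned"] = LogicalVector(everB.begin(), everB.end());
  if (track_occupancy) {
    std::vector<double> codes, times;
    codes.reserve(occ.size());
    for (auto& kv : occ) {
      codes.push_back((double)kv.first);
      times.push_back(kv.second);
    }
    out["occupancy_codes"] = NumericVector(codes.begin(), codes.end());
    out["occupancy_times"] = NumericVector(times.begin(), times.end());
  }
  return out;
}
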