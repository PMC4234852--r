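// Event-driven exact SSA for the nucleosome-array spreading model.
//
// State: per-position modification (0=U, 1=A, 2=M) and occupancy
// (0=empty, 1=Mt, 2=At). Channels are statically indexed:
//   0: initiate Mt, 1: initiate At,
//   2 + 10*i + {0..9}: unbind, catalyze_site, catalyze_neighbor left/right,
//                      slide left/right, recruit Mt, recruit At,
//                      background_acetylate, demodify   (position i),
//   2 + 10*n + p: connectivity pair p (lexicographic site pairs).
// Methods: next-reaction (indexed priority queue, Gibson-Bruck time reuse,
// ties broken by smallest channel index) and direct (full recompute +
// linear scan), both statistically exact. Randomness comes from R's RNG.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// kinds
enum { K_INITIATE = 0, K_UNBIND, K_CAT_SITE, K_CAT_NBR, K_SLIDE, K_RECRUIT,
       K_BG_ACET, K_DEMOD, K_CONNECT };

struct Engine {
  int n, mech, dual;           // mech: 0 diffusion, 1 recruitment, 2 combined
  int mtSite, atSite;          // 0-based; -1 disabled
  std::vector<int> conn;       // 0-based connectivity sites
  std::vector<std::pair<int,int>> pairs;
  double kOn, kOff, kCat, kNbr, kSlide, kRecr, kDemod, kBg, kInt;

  std::vector<int> mods, occ;
  int C;                       // number of channels
  std::vector<double> a;       // propensities

  // dependency: channels reading state at position p
  std::vector<std::vector<int>> dep;

  bool diffOn() const { return mech == 0 || mech == 2; }
  bool recrOn() const { return mech == 1 || mech == 2; }
  int base(int i) const { return 2 + 10 * i; }

  double prop(int c) const {
    if (c == 0) return (mtSite >= 0 && occ[mtSite] == 0) ? kOn : 0.0;
    if (c == 1) return (dual && atSite >= 0 && occ[atSite] == 0) ? kOn : 0.0;
    int cc = c - 2;
    if (cc < 10 * n) {
      int i = cc / 10, op = cc % 10;
      switch (op) {
      case 0: return occ[i] != 0 ? kOff : 0.0;
      case 1: return (occ[i] != 0 && mods[i] == 0) ? kCat : 0.0;
      case 2: return (recrOn() && occ[i] != 0 && i > 0 && mods[i-1] == 0)
                     ? kNbr : 0.0;
      case 3: return (recrOn() && occ[i] != 0 && i < n-1 && mods[i+1] == 0)
                     ? kNbr : 0.0;
      case 4: return (diffOn() && occ[i] != 0 && i > 0 && occ[i-1] == 0)
                     ? kSlide : 0.0;
      case 5: return (diffOn() && occ[i] != 0 && i < n-1 && occ[i+1] == 0)
                     ? kSlide : 0.0;
      case 6: return (recrOn() && occ[i] == 0 && mods[i] == 2) ? kRecr : 0.0;
      case 7: return (dual && recrOn() && occ[i] == 0 && mods[i] == 1)
                     ? kRecr : 0.0;
      case 8: return (!dual && mods[i] == 0) ? kBg : 0.0;
      case 9: return mods[i] != 0 ? kDemod : 0.0;
      }
    }
    const std::pair<int,int> &pq = pairs[cc - 10 * n];
    return (occ[pq.first] != 0 || occ[pq.second] != 0) ? kInt : 0.0;
  }

  void buildDeps() {
    dep.assign(n, std::vector<int>());
    for (int p = 0; p < n; ++p) {
      if (p == mtSite) dep[p].push_back(0);
      if (p == atSite) dep[p].push_back(1);
      for (int op = 0; op < 10; ++op) dep[p].push_back(base(p) + op);
      if (p > 0) {     // channels at p-1 reading position p
        dep[p].push_back(base(p-1) + 3); // catalyze_neighbor right
        dep[p].push_back(base(p-1) + 5); // slide right
      }
      if (p < n-1) {
        dep[p].push_back(base(p+1) + 2);
        dep[p].push_back(base(p+1) + 4);
      }
    }
    for (size_t k = 0; k < pairs.size(); ++k) {
      dep[pairs[k].first].push_back(2 + 10 * n + (int)k);
      dep[pairs[k].second].push_back(2 + 10 * n + (int)k);
    }
  }
};

// indexed binary min-heap over (tau, channel index)
struct Heap {
  std::vector<int> h, pos;
  const std::vector<double> *tau;
  bool lt(int x, int y) const {
    double tx = (*tau)[x], ty = (*tau)[y];
    return tx < ty || (tx == ty && x < y);
  }
  void init(int C, const std::vector<double> *t) {
    tau = t; h.resize(C); pos.resize(C);
    for (int i = 0; i < C; ++i) { h[i] = i; pos[i] = i; }
    for (int i = C / 2 - 1; i >= 0; --i) down(i);
  }
  void swp(int i, int j) {
    std::swap(h[i], h[j]); pos[h[i]] = i; pos[h[j]] = j;
  }
  void up(int i)   { while (i > 0 && lt(h[i], h[(i-1)/2])) { swp(i,(i-1)/2); i=(i-1)/2; } }
  void down(int i) {
    int nC = (int)h.size();
    for (;;) {
      int l = 2*i+1, r = l+1, m = i;
      if (l < nC && lt(h[l], h[m])) m = l;
      if (r < nC && lt(h[r], h[m])) m = r;
      if (m == i) break;
      swp(i, m); i = m;
    }
  }
  void update(int c) { int i = pos[c]; up(i); down(pos[c]); }
  int top() const { return h[0]; }
};

// [[Rcpp::export]]
List cpp_simulate(int n, int mech, bool dual,
                  int mt_site, int at_site, IntegerVector conn_sites,
                  double k_on, double k_off, double k_cat, double k_nbr,
                  double k_slide, double k_recr, double k_demod, double k_bg,
                  double k_int,
                  IntegerVector init_mods, IntegerVector init_occ,
                  double t_end, int method, bool validate,
                  bool record_events, double bin_dt, double window_start,
                  bool state_dist, double max_events) {
  Engine E;
  E.n = n; E.mech = mech; E.dual = dual;
  E.mtSite = mt_site - 1; E.atSite = at_site - 1;
  E.kOn = k_on; E.kOff = k_off; E.kCat = k_cat; E.kNbr = k_nbr;
  E.kSlide = k_slide; E.kRecr = k_recr; E.kDemod = k_demod; E.kBg = k_bg;
  E.kInt = k_int;
  for (int i = 0; i < conn_sites.size(); ++i)
    E.conn.push_back(conn_sites[i] - 1);
  for (size_t i = 0; i + 1 < E.conn.size(); ++i)
    for (size_t j = i + 1; j < E.conn.size(); ++j)
      E.pairs.push_back(std::make_pair(E.conn[i], E.conn[j]));
  E.mods.assign(init_mods.begin(), init_mods.end());
  E.occ.assign(init_occ.begin(), init_occ.end());
  E.C = 2 + 10 * n + (int)E.pairs.size();
  E.buildDeps();

  // species counters: counts of U/A/M marks and of bound Mt/At
  int cntMod[3] = {0,0,0}, cntOcc[3] = {0,0,0};
  for (int i = 0; i < n; ++i) { cntMod[E.mods[i]]++; cntOcc[E.occ[i]]++; }

  // recorders -------------------------------------------------------------
  std::vector<double> ev_t; std::vector<int> ev_k, ev_e, ev_p1, ev_p2;

  int nbins = bin_dt > 0 ? (int)std::ceil(t_end / bin_dt - 1e-9) : 0;
  if (bin_dt > 0 && nbins < 1) nbins = 1;
  NumericMatrix bins(std::max(nbins, 1), 5); // U A M Mt At (time-integrated)
  std::vector<double> binDur(std::max(nbins, 1), 0.0);

  double w0 = window_start < 0 ? 0.0 : window_start;
  double wlen = t_end - w0;
  NumericMatrix profile(n, 5);               // per-position U A M Mt At
  std::vector<double> lastModT(n, 0.0), lastOccT(n, 0.0);
  NumericMatrix cdist(n + 1, 5);             // total-count distribution

  std::unordered_map<long long, double> sdist;
  std::vector<long long> pow9(n);
  long long code = 0;
  if (state_dist) {
    if (n > 12) stop("state-distribution recording requires n <= 12");
    pow9[0] = 1;
    for (int i = 1; i < n; ++i) pow9[i] = pow9[i-1] * 9;
    for (int i = 0; i < n; ++i)
      code += (long long)(E.mods[i] + 3 * E.occ[i]) * pow9[i];
  }

  // interval accumulation [t0, t1) with the current (pre-event) state
  auto accumulate = [&](double t0, double t1) {
    if (t1 <= t0) return;
    if (bin_dt > 0) {
      int b0 = (int)(t0 / bin_dt);
      if (b0 >= nbins) b0 = nbins - 1;
      double s = t0;
      while (s < t1) {
        double bend = (b0 == nbins - 1) ? t_end : (b0 + 1) * bin_dt;
        double e = std::min(t1, bend);
        double d = e - s;
        bins(b0, 0) += cntMod[0] * d; bins(b0, 1) += cntMod[1] * d;
        bins(b0, 2) += cntMod[2] * d; bins(b0, 3) += cntOcc[1] * d;
        bins(b0, 4) += cntOcc[2] * d;
        binDur[b0] += d;
        s = e;
        if (s >= t1) break;
        ++b0;
      }
    }
    double wd = std::min(t1, t_end) - std::max(t0, w0); // window overlap
    if (wd > 0) {
      cdist(cntMod[0], 0) += wd; cdist(cntMod[1], 1) += wd;
      cdist(cntMod[2], 2) += wd; cdist(cntOcc[1], 3) += wd;
      cdist(cntOcc[2], 4) += wd;
      if (state_dist) sdist[code] += wd;
    }
  };

  // lazy per-position profile accumulation, clipped to [w0, t_end]
  auto flushMod = [&](int i, double t) {
    double d = std::min(t, t_end) - std::max(lastModT[i], w0);
    if (d > 0) profile(i, E.mods[i]) += d;
    lastModT[i] = t;
  };
  auto flushOcc = [&](int i, double t) {
    double d = std::min(t, t_end) - std::max(lastOccT[i], w0);
    if (d > 0) {
      if (E.occ[i] == 1) profile(i, 3) += d;
      else if (E.occ[i] == 2) profile(i, 4) += d;
    }
    lastOccT[i] = t;
  };
  auto setMod = [&](int i, int v, double t) {
    if (E.mods[i] == v) return;
    flushMod(i, t);
    cntMod[E.mods[i]]--; cntMod[v]++;
    if (state_dist) code += (long long)(v - E.mods[i]) * pow9[i];
    E.mods[i] = v;
  };
  auto setOcc = [&](int i, int v, double t) {
    if (E.occ[i] == v) return;
    flushOcc(i, t);
    cntOcc[E.occ[i]]--; cntOcc[v]++;
    if (state_dist) code += (long long)(3 * (v - E.occ[i])) * pow9[i];
    E.occ[i] = v;
  };

  // decode channel -> event description + state update ---------------------
  int chg[2];
  auto fire = [&](int c, double t, int &kind, int &enz, int &p1, int &p2,
                  int &nchg) {
    p2 = -1; nchg = 1;
    if (c == 0) { kind = K_INITIATE; enz = 1; p1 = E.mtSite;
                  setOcc(E.mtSite, 1, t); chg[0] = E.mtSite; return; }
    if (c == 1) { kind = K_INITIATE; enz = 2; p1 = E.atSite;
                  setOcc(E.atSite, 2, t); chg[0] = E.atSite; return; }
    int cc = c - 2;
    if (cc < 10 * n) {
      int i = cc / 10, op = cc % 10;
      p1 = i; chg[0] = i;
      switch (op) {
      case 0: kind = K_UNBIND; enz = E.occ[i]; setOcc(i, 0, t); return;
      case 1: kind = K_CAT_SITE; enz = E.occ[i];
              setMod(i, enz == 1 ? 2 : 1, t); return;
      case 2: case 3: {
        int j = op == 2 ? i - 1 : i + 1;
        kind = K_CAT_NBR; enz = E.occ[i]; p2 = j;
        setMod(j, enz == 1 ? 2 : 1, t);
        chg[0] = j; return; }         // only the neighbour's state changed
      case 4: case 5: {
        int j = op == 4 ? i - 1 : i + 1;
        kind = K_SLIDE; enz = E.occ[i]; p2 = j;
        setOcc(j, E.occ[i], t); setOcc(i, 0, t);
        chg[0] = i; chg[1] = j; nchg = 2; return; }
      case 6: kind = K_RECRUIT; enz = 1; setOcc(i, 1, t); return;
      case 7: kind = K_RECRUIT; enz = 2; setOcc(i, 2, t); return;
      case 8: kind = K_BG_ACET; enz = 0; setMod(i, 1, t); return;
      case 9: kind = K_DEMOD; enz = 0; setMod(i, 0, t); return;
      }
    }
    const std::pair<int,int> &pq = E.pairs[cc - 10 * n];
    kind = K_CONNECT; enz = 0; p1 = pq.first; p2 = pq.second;
    int o1 = E.occ[pq.first], o2 = E.occ[pq.second];
    setOcc(pq.first, o2, t); setOcc(pq.second, o1, t);
    chg[0] = pq.first; chg[1] = pq.second; nchg = 2;
  };

  // main loops -------------------------------------------------------------
  RNGScope rng;
  double t = 0.0, nev = 0.0;
  E.a.resize(E.C);
  for (int c = 0; c < E.C; ++c) E.a[c] = E.prop(c);

  std::vector<int> stamp(E.C, -1);

  if (method == 0) { // next-reaction
    std::vector<double> tau(E.C);
    for (int c = 0; c < E.C; ++c)
      tau[c] = E.a[c] > 0 ? R::exp_rand() / E.a[c] : INF;
    Heap H; H.init(E.C, &tau);
    for (;;) {
      int c = H.top();
      double tn = tau[c];
      if (!(tn <= t_end)) break;     // absorbing or horizon reached
      if (max_events > 0 && nev >= max_events)
        stop("event budget exceeded");
      accumulate(t, tn);
      int kind, enz, p1, p2, nchg;
      fire(c, tn, kind, enz, p1, p2, nchg);
      t = tn;
      nev += 1;
      if (record_events) {
        ev_t.push_back(t); ev_k.push_back(kind); ev_e.push_back(enz);
        ev_p1.push_back(p1 + 1); ev_p2.push_back(p2 >= 0 ? p2 + 1 : 0);
      }
      // update dependent channels (Gibson-Bruck reuse), fired one afresh
      int iev = (int)nev;
      for (int k = 0; k < nchg; ++k) {
        const std::vector<int> &dd = E.dep[chg[k]];
        for (size_t q = 0; q < dd.size(); ++q) {
          int c2 = dd[q];
          if (stamp[c2] == iev || c2 == c) continue;
          stamp[c2] = iev;
          double an = E.prop(c2), ao = E.a[c2];
          if (an == ao) continue;
          if (an <= 0) tau[c2] = INF;
          else if (ao > 0 && tau[c2] < INF)
            tau[c2] = t + (ao / an) * (tau[c2] - t);
          else tau[c2] = t + R::exp_rand() / an;
          E.a[c2] = an;
          H.update(c2);
        }
      }
      double an = E.prop(c);
      E.a[c] = an;
      tau[c] = an > 0 ? t + R::exp_rand() / an : INF;
      H.update(c);
      if (validate) {
        for (int c2 = 0; c2 < E.C; ++c2) {
          double af = E.prop(c2);
          if (std::fabs(af - E.a[c2]) > 1e-9 * std::max(1.0, af))
            stop("propensity bookkeeping mismatch at channel %d", c2);
        }
      }
    }
  } else {          // direct method, full recompute per step
    for (;;) {
      double total = 0.0;
      for (int c = 0; c < E.C; ++c) { E.a[c] = E.prop(c); total += E.a[c]; }
      if (total <= 0) break;
      double dt = R::exp_rand() / total;
      if (t + dt > t_end) break;
      if (max_events > 0 && nev >= max_events)
        stop("event budget exceeded");
      double r = unif_rand() * total, cum = 0.0;
      int c = -1;
      for (int c2 = 0; c2 < E.C; ++c2) {
        if (E.a[c2] <= 0) continue;
        c = c2;
        cum += E.a[c2];
        if (r <= cum) break;  // fp overshoot falls back to last active channel
      }
      if (c < 0) break;
      double tn = t + dt;
      accumulate(t, tn);
      int kind, enz, p1, p2, nchg;
      fire(c, tn, kind, enz, p1, p2, nchg);
      t = tn;
      nev += 1;
      if (record_events) {
        ev_t.push_back(t); ev_k.push_back(kind); ev_e.push_back(enz);
        ev_p1.push_back(p1 + 1); ev_p2.push_back(p2 >= 0 ? p2 + 1 : 0);
      }
    }
  }

  // close out the final quiescent stretch and flush lazy accumulators
  accumulate(t, t_end);
  for (int i = 0; i < n; ++i) { flushMod(i, t_end); flushOcc(i, t_end); }

  // normalize
  if (bin_dt > 0)
    for (int b = 0; b < nbins; ++b)
      if (binDur[b] > 0)
        for (int s = 0; s < 5; ++s) bins(b, s) /= binDur[b];
  if (wlen > 0) {
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < 5; ++s) profile(i, s) /= wlen;
    for (int k = 0; k <= n; ++k)
      for (int s = 0; s < 5; ++s) cdist(k, s) /= wlen;
  }

  List out = List::create(
    _["t_final"] = t, _["n_events"] = nev,
    _["final_mods"] = IntegerVector(E.mods.begin(), E.mods.end()),
    _["final_occ"] = IntegerVector(E.occ.begin(), E.occ.end()),
    _["profile"] = profile, _["count_dist"] = cdist);
  if (record_events)
    out["events"] = List::create(
      _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["kind"] = IntegerVector(ev_k.begin(), ev_k.end()),
      _["enzyme"] = IntegerVector(ev_e.begin(), ev_e.end()),
      _["pos1"] = IntegerVector(ev_p1.begin(), ev_p1.end()),
      _["pos2"] = IntegerVector(ev_p2.begin(), ev_p2.end()));
  if (bin_dt > 0) out["bins"] = bins;
  if (state_dist) {
    int m = (int)sdist.size();
    NumericVector codes(m), times(m);
    int k = 0;
    for (std::unordered_map<long long,double>::iterator it = sdist.begin();
         it != sdist.end(); ++it, ++k) {
      codes[k] = (double)it->first; times[k] = it->second;
    }
    out["state_codes"] = codes; out["state_times"] = times;
  }
  return out;
}
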