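// Simplified minimum-free-energy RNA folder.
//
// Zuker-style dynamic program over Watson-Crick + G.U pairs with
// nearest-neighbor stack energies and affine hairpin / bulge / interior /
// multibranch loop penalties.  Energies are handled in integer hundredths
// of kcal/mol.  The DP is banded: only spans up to the window length are
// computed, so all tiling windows of one gene are folded in a single pass.
//
// Deliberate simplifications (this is the deterministic test backend, not a
// ViennaRNA replacement): no dangling ends, no coaxial stacking, no
// terminal-AU penalty inside folds, flat stack constant for stacks that
// involve a wobble pair, interior/bulge sides capped at `max_loop` nt.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const int INF = std::numeric_limits<int>::max() / 4;

struct Params {
  int stack[6][6];   // pair types AU,UA,GC,CG,GU,UG
  int ha, hb;        // hairpin: ha + hb*(loop-3)
  int ba, bb;        // bulge:   ba + bb*(len-1)
  int ia, ib;        // interior: ia + ib*(total_unpaired-2)
  int mla, mlb, mlc; // multiloop closing, per-branch, per-unpaired
  int max_loop;      // per-side cap on bulge/interior unpaired
};

static inline int enc(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'U': return 3; }
  return -1;
}

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 2 && b == 1) return 2; // GC
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

class Folder {
public:
  std::vector<int> s;
  int n, band;
  Params par;
  // row-major n x n matrices, only spans <= band are valid
  std::vector<int> V, WM, W;
  // partners[k]: l > k with finite V(k, l), ascending (filled span-wise)
  std::vector<std::vector<int>> partners;

  int &v(int i, int j)  { return V[(size_t)i * n + j]; }
  int &wm(int i, int j) { return WM[(size_t)i * n + j]; }
  int &w(int i, int j)  { return W[(size_t)i * n + j]; }

  Folder(const std::string &seq, int L, const Params &p) : par(p) {
    n = (int)seq.size();
    band = std::min(L, n);
    s.resize(n);
    for (int i = 0; i < n; ++i) {
      s[i] = enc(seq[i]);
      if (s[i] < 0) stop("fold: invalid character '%c'", seq[i]);
    }
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    W.assign((size_t)n * n, 0);
    partners.assign(n, std::vector<int>());
    fill();
  }

  int loop_energy(int d1, int d2, int pt_out, int pt_in) const {
    if (d1 == 0 && d2 == 0) return par.stack[pt_out][pt_in];
    if (d1 > par.max_loop || d2 > par.max_loop) return INF;
    if (d1 == 0 || d2 == 0) {
      int d = d1 + d2;
      return par.ba + par.bb * (d - 1);
    }
    return par.ia + par.ib * (d1 + d2 - 2);
  }

  void fill() {
    for (int len = 2; len <= band; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // --- V ---
        int pt = pair_type(s[i], s[j]);
        int best = INF;
        if (pt >= 0) {
          int loop = j - i - 1;
          if (loop >= 3) best = par.ha + par.hb * (loop - 3);
          int d1max = std::min(par.max_loop, j - i - 2);
          for (int d1 = 0; d1 <= d1max; ++d1) {
            int k = i + 1 + d1;
            int lmin = std::max(k + 1, j - 1 - par.max_loop);
            const std::vector<int> &pl = partners[k];
            auto it = std::lower_bound(pl.begin(), pl.end(), lmin);
            for (; it != pl.end() && *it <= j - 1; ++it) {
              int l = *it;
              int d2 = j - 1 - l;
              int vin = v(k, l);
              int pin = pair_type(s[k], s[l]);
              int le = loop_energy(d1, d2, pt, pin);
              if (le >= INF) continue;
              if (vin + le < best) best = vin + le;
            }
          }
          // multiloop: >= 2 branches inside
          for (int m = i + 2; m <= j - 3; ++m) {
            int a = wm(i + 1, m), b = wm(m + 1, j - 1);
            if (a >= INF || b >= INF) continue;
            int e = par.mla + par.mlb + a + b;
            if (e < best) best = e;
          }
        }
        v(i, j) = best;
        if (best < INF) partners[i].push_back(j);
        // --- WM (>= 1 branch, multiloop context) ---
        int bwm = INF;
        if (len >= 2) {
          if (wm(i + 1, j) < INF) bwm = std::min(bwm, wm(i + 1, j) + par.mlc);
          if (wm(i, j - 1) < INF) bwm = std::min(bwm, wm(i, j - 1) + par.mlc);
          if (best < INF) bwm = std::min(bwm, best + par.mlb);
          for (int m = i + 1; m <= j - 1; ++m) {
            int a = wm(i, m), b = wm(m + 1, j);
            if (a < INF && b < INF) bwm = std::min(bwm, a + b);
          }
        }
        wm(i, j) = bwm;
        // --- W (exterior) ---
        int bw = w(i, j - 1); // j unpaired
        for (int k = i; k <= j - 4; ++k) {
          int vv = v(k, j);
          if (vv >= INF) continue;
          int left = (k == i) ? 0 : w(i, k - 1);
          if (left + vv < bw) bw = left + vv;
        }
        w(i, j) = bw;
      }
    }
  }

  // ---- traceback ----
  void trace_V(int i, int j, std::string &db) {
    db[i] = '('; db[j] = ')';
    int pt = pair_type(s[i], s[j]);
    int target = v(i, j);
    int d1max = std::min(par.max_loop, j - i - 2);
    for (int d1 = 0; d1 <= d1max; ++d1) {
      int k = i + 1 + d1;
      int d2max = std::min(par.max_loop, j - k - 1);
      for (int d2 = 0; d2 <= d2max; ++d2) {
        int l = j - 1 - d2;
        if (l <= k) break;
        int vin = v(k, l);
        if (vin >= INF) continue;
        int le = loop_energy(d1, d2, pt, pair_type(s[k], s[l]));
        if (le < INF && vin + le == target) { trace_V(k, l, db); return; }
      }
    }
    int loop = j - i - 1;
    if (loop >= 3 && target == par.ha + par.hb * (loop - 3)) return; // hairpin
    for (int m = i + 2; m <= j - 3; ++m) {
      int a = wm(i + 1, m), b = wm(m + 1, j - 1);
      if (a < INF && b < INF && par.mla + par.mlb + a + b == target) {
        trace_WM(i + 1, m, db); trace_WM(m + 1, j - 1, db); return;
      }
    }
    stop("fold traceback failed in V");
  }

  void trace_WM(int i, int j, std::string &db) {
    int target = wm(i, j);
    if (v(i, j) < INF && v(i, j) + par.mlb == target) { trace_V(i, j, db); return; }
    if (i + 1 <= j && wm(i + 1, j) < INF && wm(i + 1, j) + par.mlc == target) {
      trace_WM(i + 1, j, db); return;
    }
    if (i <= j - 1 && wm(i, j - 1) < INF && wm(i, j - 1) + par.mlc == target) {
      trace_WM(i, j - 1, db); return;
    }
    for (int m = i + 1; m <= j - 1; ++m) {
      int a = wm(i, m), b = wm(m + 1, j);
      if (a < INF && b < INF && a + b == target) {
        trace_WM(i, m, db); trace_WM(m + 1, j, db); return;
      }
    }
    stop("fold traceback failed in WM");
  }

  void trace_W(int i, int j, std::string &db) {
    while (j >= i) {
      if (j == i) return;                   // single nt: unpaired
      int target = w(i, j);
      if (target == w(i, j - 1)) { --j; continue; } // prefer unpaired on ties
      bool done = false;
      for (int k = i; k <= j - 4; ++k) {
        int vv = v(k, j);
        if (vv >= INF) continue;
        int left = (k == i) ? 0 : w(i, k - 1);
        if (left + vv == target) {
          trace_V(k, j, db);
          if (k == i) return;
          j = k - 1; done = true; break;
        }
      }
      if (!done) stop("fold traceback failed in W");
    }
  }

  // MFE and dot-bracket of subsequence [i, j]
  void window(int i, int j, double &dg, std::string &db) {
    int e = w(i, j);
    db.assign(j - i + 1, '.');
    if (e < 0) {
      std::string full(n, '.');
      trace_W(i, j, full);
      db = full.substr(i, j - i + 1);
      dg = e / 100.0;
    } else {
      dg = 0.0;
    }
  }
};

static Params make_params(List p) {
  Params par;
  NumericMatrix st = p["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      par.stack[a][b] = (int)std::lround(100.0 * st(a, b));
  par.ha  = (int)std::lround(100.0 * as<double>(p["hairpin_a"]));
  par.hb  = (int)std::lround(100.0 * as<double>(p["hairpin_b"]));
  par.ba  = (int)std::lround(100.0 * as<double>(p["bulge_a"]));
  par.bb  = (int)std::lround(100.0 * as<double>(p["bulge_b"]));
  par.ia  = (int)std::lround(100.0 * as<double>(p["interior_a"]));
  par.ib  = (int)std::lround(100.0 * as<double>(p["interior_b"]));
  par.mla = (int)std::lround(100.0 * as<double>(p["ml_close"]));
  par.mlb = (int)std::lround(100.0 * as<double>(p["ml_branch"]));
  par.mlc = (int)std::lround(100.0 * as<double>(p["ml_unpaired"]));
  par.max_loop = as<int>(p["max_loop"]);
  return par;
}

// [[Rcpp::export(name = ".fold_one_cpp")]]
List fold_one_cpp(std::string seq, List params) {
  int n = (int)seq.size();
  if (n == 0) return List::create(_["delta_g"] = 0.0, _["structure"] = "");
  Folder f(seq, n, make_params(params));
  double dg; std::string db;
  if (n >= 2) f.window(0, n - 1, dg, db); else { dg = 0.0; db = "."; }
  return List::create(_["delta_g"] = dg, _["structure"] = db);
}

// Fold every length-L window whose start index (0-based) is in
// [0, n_starts).  Windows running past the end of `seq` get NA.
// [[Rcpp::export(name = ".fold_windows_cpp")]]
List fold_windows_cpp(std::string seq, int L, int n_starts, List params,
                      bool structures = true) {
  int n = (int)seq.size();
  if (L < 1) stop("window length must be >= 1");
  Folder f(seq, L, make_params(params));
  NumericVector dg(n_starts, NA_REAL);
  CharacterVector db(n_starts, NA_STRING);
  for (int s = 0; s < n_starts; ++s) {
    int e = s + L - 1;
    if (e >= n) continue;
    double g; std::string str;
    if (L == 1) { g = 0.0; str = "."; } else f.window(s, e, g, str);
    dg[s] = g;
    if (structures) db[s] = str;
  }
  return List::create(_["delta_g"] = dg, _["structure"] = db);
}
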