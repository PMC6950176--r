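// Banded Zuker-style MFE folding over a simplified nearest-neighbour model.
//
// The DP is computed once, banded to the maximal window width, over the whole
// target sequence; V(i,j) and WM(i,j) depend only on the subsequence [i..j],
// so every sliding window re-uses the same matrices and only the exterior
// (W) recursion is window-specific.  Energies are kcal/mol at 37 C.
//
// Model constraints (enforced identically by the R enumeration oracle):
//   - allowed pairs AU, UA, GC, CG, GU, UG; N never pairs
//   - hairpin loops >= min_hairpin unpaired bases
//   - interior/bulge loops capped at max_loop total unpaired bases
//   - multiloop energy affine: ml_a + ml_b * branches + ml_c * unpaired
//   - exterior unpaired bases are free

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const double NEG_OK = 1e8;   // anything above this is "impossible"
static const double INF9 = 1e9;
static const double EPS = 1e-4;

// base codes: 1=A 2=C 3=G 4=U 5=N (0 unused)
static inline int ptype(int a, int b) {
  if (a == 1 && b == 4) return 1;  // AU
  if (a == 4 && b == 1) return 2;  // UA
  if (a == 3 && b == 2) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // CG
  if (a == 3 && b == 4) return 5;  // GU
  if (a == 4 && b == 3) return 6;  // UG
  return 0;
}

struct Model {
  double stack[7][7];
  std::vector<double> hairpin;   // index size-1
  std::vector<double> bulge;     // index size-1
  std::vector<double> interior;  // index size-1
  double ml_a, ml_b, ml_c;
  int max_loop, min_hairpin;

  double hairpin_e(int size) const {
    if (size < min_hairpin) return INF9;
    if (size <= (int)hairpin.size()) return hairpin[size - 1];
    return INF9;
  }
  double loop_e(int pt_out, int pt_in, int d1, int d2) const {
    if (d1 == 0 && d2 == 0) return stack[pt_out][pt_in];
    int sz = d1 + d2;
    if (sz > max_loop) return INF9;
    if (d1 == 0 || d2 == 0) return bulge[sz - 1];
    return interior[sz - 1];
  }
};

struct Fold {
  const std::vector<int>& s;
  int n, band;                 // V,WM stored for 0 <= j-i <= band-1
  const Model& m;
  std::vector<double> V, WM;

  Fold(const std::vector<int>& seq, int band_, const Model& model)
    : s(seq), n((int)seq.size()), band(band_), m(model),
      V((size_t)n * band_, INF9), WM((size_t)n * band_, INF9) {
    fill();
  }
  inline double v(int i, int j) const {
    int d = j - i;
    if (i < 0 || j >= n || d < 0 || d >= band) return INF9;
    return V[(size_t)i * band + d];
  }
  inline double wm(int i, int j) const {
    int d = j - i;
    if (i < 0 || j >= n || d < 0 || d >= band) return INF9;
    return WM[(size_t)i * band + d];
  }

  void fill() {
    for (int d = 0; d < band; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        double vv = INF9;
        int pt = ptype(s[i], s[j]);
        if (pt > 0 && d - 1 >= m.min_hairpin) {
          vv = m.hairpin_e(d - 1);
          // interior / bulge / stack
          int d1max = std::min(m.max_loop, j - i - 2 - m.min_hairpin);
          for (int d1 = 0; d1 <= d1max; ++d1) {
            int k = i + 1 + d1;
            int d2max = std::min(m.max_loop - d1, j - k - 2 - m.min_hairpin);
            for (int d2 = 0; d2 <= d2max; ++d2) {
              int l = j - 1 - d2;
              double vin = v(k, l);
              if (vin > NEG_OK) continue;
              int pt2 = ptype(s[k], s[l]);
              double le = m.loop_e(pt, pt2, d1, d2);
              if (le > NEG_OK) continue;
              double cand = le + vin;
              if (cand < vv) vv = cand;
            }
          }
          // multiloop: >= 2 branches inside
          for (int k = i + 2; k <= j - 2; ++k) {
            double a = wm(i + 1, k - 1), b = wm(k, j - 1);
            if (a > NEG_OK || b > NEG_OK) continue;
            double cand = m.ml_a + a + b;
            if (cand < vv) vv = cand;
          }
        }
        V[(size_t)i * band + d] = vv;

        // WM: [i..j] as multiloop interior with >= 1 branch
        double ww = INF9;
        if (vv < NEG_OK) ww = vv + m.ml_b;
        if (d >= 1) {
          double a = wm(i + 1, j);
          if (a < NEG_OK && a + m.ml_c < ww) ww = a + m.ml_c;
          a = wm(i, j - 1);
          if (a < NEG_OK && a + m.ml_c < ww) ww = a + m.ml_c;
          for (int k = i + 1; k <= j; ++k) {
            double l = wm(i, k - 1), r = v(k, j);
            if (l > NEG_OK || r > NEG_OK) continue;
            double cand = l + r + m.ml_b;
            if (cand < ww) ww = cand;
          }
        }
        WM[(size_t)i * band + d] = ww;
      }
    }
  }

  // ---- traceback (deterministic fixed preference order) ----
  void trace_v(int i, int j, std::string& db) const {
    db[i] = '('; db[j] = ')';
    double target = v(i, j);
    int pt = ptype(s[i], s[j]);
    // interior/stack first (prefers pairing the 5'-most inner base)
    int d1max = std::min(m.max_loop, j - i - 2 - m.min_hairpin);
    for (int d1 = 0; d1 <= d1max; ++d1) {
      int k = i + 1 + d1;
      int d2max = std::min(m.max_loop - d1, j - k - 2 - m.min_hairpin);
      for (int d2 = 0; d2 <= d2max; ++d2) {
        int l = j - 1 - d2;
        double vin = v(k, l);
        if (vin > NEG_OK) continue;
        double le = m.loop_e(pt, ptype(s[k], s[l]), d1, d2);
        if (le > NEG_OK) continue;
        if (std::abs(le + vin - target) < EPS) {
          trace_v(k, l, db);
          return;
        }
      }
    }
    if (std::abs(m.hairpin_e(j - i - 1) - target) < EPS) return;  // all dots
    for (int k = i + 2; k <= j - 2; ++k) {
      double a = wm(i + 1, k - 1), b = wm(k, j - 1);
      if (a > NEG_OK || b > NEG_OK) continue;
      if (std::abs(m.ml_a + a + b - target) < EPS) {
        trace_wm(i + 1, k - 1, db);
        trace_wm(k, j - 1, db);
        return;
      }
    }
    Rcpp::stop("traceback failure in V(%d,%d)", i, j);
  }

  void trace_wm(int i, int j, std::string& db) const {
    double target = wm(i, j);
    double vv = v(i, j);
    if (vv < NEG_OK && std::abs(vv + m.ml_b - target) < EPS) {
      trace_v(i, j, db);
      return;
    }
    for (int k = i + 1; k <= j; ++k) {
      double l = wm(i, k - 1), r = v(k, j);
      if (l > NEG_OK || r > NEG_OK) continue;
      if (std::abs(l + r + m.ml_b - target) < EPS) {
        trace_wm(i, k - 1, db);
        trace_v(k, j, db);
        return;
      }
    }
    if (j - i >= 1) {
      double a = wm(i + 1, j);
      if (a < NEG_OK && std::abs(a + m.ml_c - target) < EPS) {
        trace_wm(i + 1, j, db);
        return;
      }
      a = wm(i, j - 1);
      if (a < NEG_OK && std::abs(a + m.ml_c - target) < EPS) {
        trace_wm(i, j - 1, db);
        return;
      }
    }
    Rcpp::stop("traceback failure in WM(%d,%d)", i, j);
  }

  // exterior DP + traceback for window [a..b] (0-based inclusive); returns MFE
  double window_fold(int a, int b, std::string& db) const {
    int w = b - a + 1;
    std::vector<double> W(w + 1, 0.0);
    for (int x = a; x <= b; ++x) {
      double best = W[x - a];  // x unpaired
      for (int k = a; k <= x - m.min_hairpin - 1; ++k) {
        double vv = v(k, x);
        if (vv > NEG_OK) continue;
        double cand = W[k - a] + vv;
        if (cand < best) best = cand;
      }
      W[x - a + 1] = best;
    }
    db.assign(w, '.');
    // traceback left to right: prefer pairing with the smallest partner start
    int x = b;
    std::string full(n, '.');
    while (x >= a) {
      bool paired = false;
      for (int k = a; k <= x - m.min_hairpin - 1 && !paired; ++k) {
        double vv = v(k, x);
        if (vv > NEG_OK) continue;
        if (std::abs(W[k - a] + vv - W[x - a + 1]) < EPS) {
          trace_v(k, x, full);
          x = k - 1;
          paired = true;
        }
      }
      if (!paired) {
        if (std::abs(W[x - a] - W[x - a + 1]) > EPS)
          Rcpp::stop("traceback failure in exterior at %d", x);
        --x;
      }
    }
    for (int t = 0; t < w; ++t) db[t] = full[a + t];
    return W[w];
  }
};

static Model unpack_model(List model) {
  Model m;
  NumericMatrix st = model["stack"];
  for (int i = 1; i <= 6; ++i)
    for (int j = 1; j <= 6; ++j)
      m.stack[i][j] = st(i - 1, j - 1);
  m.hairpin = as<std::vector<double> >(model["hairpin"]);
  m.bulge = as<std::vector<double> >(model["bulge"]);
  m.interior = as<std::vector<double> >(model["internal"]);
  m.ml_a = as<double>(model["ml_a"]);
  m.ml_b = as<double>(model["ml_b"]);
  m.ml_c = as<double>(model["ml_c"]);
  m.max_loop = as<int>(model["max_loop"]);
  m.min_hairpin = as<int>(model["min_hairpin"]);
  return m;
}

//' @name cpp_fold_windows
//' @title Fold a set of windows over one sequence (internal)
//' @param seq integer vector of base codes (1=A,2=C,3=G,4=U,5=N)
//' @param windows integer matrix, columns start/end, 0-based half-open
//' @param model energy model list (see \code{default_energy_model})
//' @return list with numeric \code{mfe} and character \code{db} per window
//' @keywords internal
// [[Rcpp::export]]
List cpp_fold_windows(IntegerVector seq, IntegerMatrix windows, List model) {
  std::vector<int> s = as<std::vector<int> >(seq);
  int n = (int)s.size();
  Model m = unpack_model(model);
  int nw = windows.nrow();
  int band = 1;
  for (int r = 0; r < nw; ++r) {
    int wlen = windows(r, 1) - windows(r, 0);
    if (wlen > band) band = wlen;
    if (windows(r, 0) < 0 || windows(r, 1) > n || wlen < 1)
      stop("window %d out of bounds", r + 1);
  }
  if (band > n) band = n;
  if ((int)m.hairpin.size() < band)
    stop("hairpin penalty table shorter than the widest window");

  Fold f(s, band, m);
  NumericVector mfe(nw);
  CharacterVector db(nw);
  for (int r = 0; r < nw; ++r) {
    std::string d;
    mfe[r] = f.window_fold(windows(r, 0), windows(r, 1) - 1, d);
    db[r] = d;
  }
  return List::create(_["mfe"] = mfe, _["db"] = db);
}
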