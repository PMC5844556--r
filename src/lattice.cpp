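#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Equilibrium statistics of hard-core ligands with footprints on a 1-D
// basepair lattice (grand-canonical, no ligand-ligand cooperativity).
// Each legal placement of species s starting at basepair j carries a
// statistical weight w_s[j] = K_s(j) * c_free_s; the partition function is
// the sum over all non-overlapping placement configurations of the product
// of placement weights, computed by the standard sequential
// (transfer-matrix) recursion. Per-start occupation probabilities follow
// from forward/backward partial partition functions.
//
// Partial partition functions grow geometrically, so values are kept as
// (mantissa, k) pairs meaning mantissa * 2^(256 k): the mantissa is
// renormalized into [1, 2^256] as the recursion sweeps, which keeps the
// hot loop free of exp/log calls.

static const double SCALE_HI = 0x1p256;
static const double SCALE_LO = 0x1p-256;
static const double LOG_SCALE = 256.0 * M_LN2;

struct PathFB {
  std::vector<double> m;   // mantissas, in [1, 2^256]
  std::vector<int> sc;     // scale counts (powers of 2^256)
};

// Forward over the path of sites a..b (1-based absolute, no wrap):
// entry k describes Z(sites a .. a+k-1), k = 0..n.
static void path_forward(const std::vector<const double*> &w,
                         const IntegerVector &foot,
                         int a, int b, PathFB &out) {
  int n = b - a + 1;
  int S = foot.size();
  out.m.assign(n + 1, 1.0);
  out.sc.assign(n + 1, 0);
  for (int k = 1; k <= n; ++k) {
    int scref = out.sc[k - 1];
    double acc = out.m[k - 1];
    for (int s = 0; s < S; ++s) {
      int f = foot[s];
      if (k - f >= 0) {
        double ws = w[s][(a + k - f) - 1];
        if (ws > 0.0) {
          double z = out.m[k - f];
          int d = scref - out.sc[k - f];
          if (d) z = std::ldexp(z, -256 * d);
          acc += ws * z;
        }
      }
    }
    if (acc > SCALE_HI) { acc *= SCALE_LO; ++scref; }
    out.m[k] = acc;
    out.sc[k] = scref;
  }
}

// Backward: entry k describes Z(sites a+k .. b), k = 0..n.
static void path_backward(const std::vector<const double*> &w,
                          const IntegerVector &foot,
                          int a, int b, PathFB &out) {
  int n = b - a + 1;
  int S = foot.size();
  out.m.assign(n + 1, 1.0);
  out.sc.assign(n + 1, 0);
  for (int k = n - 1; k >= 0; --k) {
    int scref = out.sc[k + 1];
    double acc = out.m[k + 1];
    for (int s = 0; s < S; ++s) {
      int f = foot[s];
      if (k + f <= n) {
        double ws = w[s][(a + k) - 1];
        if (ws > 0.0) {
          double z = out.m[k + f];
          int d = scref - out.sc[k + f];
          if (d) z = std::ldexp(z, -256 * d);
          acc += ws * z;
        }
      }
    }
    if (acc > SCALE_HI) { acc *= SCALE_LO; ++scref; }
    out.m[k] = acc;
    out.sc[k] = scref;
  }
}

static double path_logZ(const PathFB &fw) {
  return std::log(fw.m.back()) + fw.sc.back() * LOG_SCALE;
}

// Add, scaled by `frac`, the per-start occupation probabilities of the
// linear problem on path a..b into `acc` (per species, absolute indexing).
static void path_accumulate(const std::vector<const double*> &w,
                            const IntegerVector &foot,
                            int a, int b, double frac,
                            std::vector<std::vector<double> > &acc) {
  if (b < a || frac <= 0.0) return;
  int n = b - a + 1;
  int S = foot.size();
  PathFB fw, bw;
  path_forward(w, foot, a, b, fw);
  path_backward(w, foot, a, b, bw);
  for (int s = 0; s < S; ++s) {
    int f = foot[s];
    for (int j = a; j + f - 1 <= b; ++j) {
      double ws = w[s][j - 1];
      if (ws > 0.0) {
        int kf = j - a;          // Z(left of the ligand)
        int kb = j + f - a;      // Z(right of the ligand)
        double mm = fw.m[kf] / fw.m[n] * ws * bw.m[kb];
        int e = fw.sc[kf] + bw.sc[kb] - fw.sc[n];
        acc[s][j - 1] += frac * std::ldexp(mm, 256 * e);
      }
    }
  }
}

// [[Rcpp::export]]
List lattice_occupancy_cpp(int L, IntegerVector footprints, List weights,
                           bool circular) {
  int S = footprints.size();
  if ((int) weights.size() != S)
    stop("one weight vector per species required");
  std::vector<NumericVector> wkeep(S);
  std::vector<const double*> w(S);
  for (int s = 0; s < S; ++s) {
    wkeep[s] = as<NumericVector>(weights[s]);
    if ((int) wkeep[s].size() != L)
      stop("weight vectors must have length L");
    w[s] = wkeep[s].begin();
  }
  std::vector<std::vector<double> > acc(S, std::vector<double>(L, 0.0));
  double logZ;

  if (!circular) {
    PathFB fw;
    path_forward(w, footprints, 1, L, fw);
    logZ = path_logZ(fw);
    path_accumulate(w, footprints, 1, L, 1.0, acc);
  } else {
    // Condition on the content of the cut between site L and site 1:
    // case 0 = no ligand crosses the cut (plain linear problem on 1..L);
    // one case per ligand placement wrapping the cut, each leaving a
    // linear path of L - f sites.
    std::vector<double> caseLog;
    std::vector<int> caseSpecies, caseStart;
    {
      PathFB fw;
      path_forward(w, footprints, 1, L, fw);
      caseLog.push_back(path_logZ(fw));
      caseSpecies.push_back(-1);
      caseStart.push_back(-1);
    }
    for (int s = 0; s < S; ++s) {
      int f = footprints[s];
      if (f > L) continue;                  // cannot fit even when wrapped
      for (int i = std::max(2, L - f + 2); i <= L; ++i) {
        double ws = w[s][i - 1];
        if (ws <= 0.0) continue;
        int a = i + f - L, b = i - 1;       // remaining path, length L - f
        double lz = 0.0;
        if (b >= a) {
          PathFB fw;
          path_forward(w, footprints, a, b, fw);
          lz = path_logZ(fw);
        }
        caseLog.push_back(std::log(ws) + lz);
        caseSpecies.push_back(s);
        caseStart.push_back(i);
      }
    }
    double m = caseLog[0];
    for (size_t k = 1; k < caseLog.size(); ++k) m = std::max(m, caseLog[k]);
    double sum = 0.0;
    for (size_t k = 0; k < caseLog.size(); ++k)
      sum += std::exp(caseLog[k] - m);
    logZ = m + std::log(sum);

    for (size_t k = 0; k < caseLog.size(); ++k) {
      double frac = std::exp(caseLog[k] - logZ);
      if (caseSpecies[k] < 0) {
        path_accumulate(w, footprints, 1, L, frac, acc);
      } else {
        int s = caseSpecies[k], i = caseStart[k], f = footprints[s];
        acc[s][i - 1] += frac;              // the wrapped ligand itself
        path_accumulate(w, footprints, i + f - L, i - 1, frac, acc);
      }
    }
  }

  List pstart(S);
  for (int s = 0; s < S; ++s)
    pstart[s] = NumericVector(acc[s].begin(), acc[s].end());
  return List::create(_["logZ"] = logZ, _["pstart"] = pstart);
}
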