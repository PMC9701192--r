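// Hot paths of the mass-response statistic: the 1-D Wasserstein distance
// between sorted samples, with-replacement resampling, and the embedded
// bootstrap-t kernels. Resampling kernels are seeded explicitly with
// substream seeds derived at the R level from the master seed, so outer
// replicates are independent of execution order and every result is
// bit-reproducible for a given seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: a small, fast, well-tested PRNG
// for the resampling indices (the statistic needs many millions of draws).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform index in [0, n)
  int index(int n) {
    return static_cast<int>((next() >> 11) * 0x1.0p-53 * n);
  }
};

// with-replacement resample of a sorted vector, returned sorted:
// draw multiplicities per position instead of sorting the draws.
static void resample_sorted(const std::vector<double>& v,
                            std::vector<double>& out,
                            std::vector<int>& cnt, Xoshiro& rng) {
  const int n = static_cast<int>(v.size());
  std::fill(cnt.begin(), cnt.begin() + n, 0);
  for (int i = 0; i < n; ++i) ++cnt[rng.index(n)];
  out.clear();
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < cnt[i]; ++c) out.push_back(v[i]);
}

// Wasserstein-1 between the empirical distributions of two sorted samples
// (merged-CDF integral), scaled by |z| so equal sizes reduce to the
// order-statistic sum pairing of the statistic's definition.
static double w1_scaled(const std::vector<double>& x,
                        const std::vector<double>& z) {
  const int n = static_cast<int>(x.size());
  const int m = static_cast<int>(z.size());
  int i = 0, j = 0;
  double w1 = 0.0;
  double prev = (x[0] < z[0]) ? x[0] : z[0];
  while (i < n || j < m) {
    double v;
    if (i < n && (j >= m || x[i] <= z[j])) v = x[i];
    else v = z[j];
    const double diff = static_cast<double>(i) / n -
                        static_cast<double>(j) / m;
    w1 += std::fabs(diff) * (v - prev);
    while (i < n && x[i] == v) ++i;
    while (j < m && z[j] == v) ++j;
    prev = v;
  }
  return m * w1;
}

static double sum_of(const std::vector<double>& v) {
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += v[i];
  return s;
}

// theta = (EMD(x, z) - EMD(y, z)) / sum z; order-statistic fast path when
// all three sizes agree, merged-CDF path otherwise.
static double theta_any(const std::vector<double>& x,
                        const std::vector<double>& y,
                        const std::vector<double>& z) {
  const size_t n = z.size();
  if (x.size() == n && y.size() == n) {
    double sx = 0.0, sy = 0.0, sz = 0.0;
    for (size_t i = 0; i < n; ++i) {
      sx += std::fabs(x[i] - z[i]);
      sy += std::fabs(y[i] - z[i]);
      sz += z[i];
    }
    return (sx - sy) / sz;
  }
  return (w1_scaled(x, z) - w1_scaled(y, z)) / sum_of(z);
}

static double sd_of(const std::vector<double>& v) {
  const size_t r = v.size();
  double m = 0.0;
  for (size_t i = 0; i < r; ++i) m += v[i];
  m /= r;
  double ss = 0.0;
  for (size_t i = 0; i < r; ++i) ss += (v[i] - m) * (v[i] - m);
  return std::sqrt(ss / (r - 1));
}

// Scaled EMD (|z| * W1) between two sorted samples of arbitrary sizes.
// [[Rcpp::export(name = ".cpp_emd_sorted")]]
double cpp_emd_sorted(NumericVector xs, NumericVector zs) {
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> z(zs.begin(), zs.end());
  return w1_scaled(x, z);
}

// Bootstrap distribution of the mass response: R independent
// with-replacement resamples of (X, Z), sizes preserved.
// [[Rcpp::export(name = ".cpp_mr_boot")]]
NumericVector cpp_mr_boot(NumericVector xs, NumericVector zs, int R,
                          double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> z(zs.begin(), zs.end());
  const size_t n = x.size(), m = z.size();
  const size_t nm = (n > m) ? n : m;
  std::vector<double> xb, zb;
  std::vector<int> cnt(nm);
  xb.reserve(n); zb.reserve(m);
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    resample_sorted(x, xb, cnt, rng);
    resample_sorted(z, zb, cnt, rng);
    if (n == m) {
      double s = 0.0, sz = 0.0;
      for (size_t i = 0; i < n; ++i) {
        s += std::fabs(xb[i] - zb[i]);
        sz += zb[i];
      }
      out[r] = s / sz;
    } else {
      out[r] = w1_scaled(xb, zb) / sum_of(zb);
    }
  }
  return out;
}

// Standard error of theta over r joint resamples of (X, Y, Z).
// [[Rcpp::export(name = ".cpp_inner_se")]]
double cpp_inner_se(NumericVector xs, NumericVector ys, NumericVector zs,
                    int r, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> y(ys.begin(), ys.end());
  std::vector<double> z(zs.begin(), zs.end());
  size_t nm = x.size();
  if (y.size() > nm) nm = y.size();
  if (z.size() > nm) nm = z.size();
  std::vector<double> xb, yb, zb, th(r);
  std::vector<int> cnt(nm);
  xb.reserve(x.size()); yb.reserve(y.size()); zb.reserve(z.size());
  for (int i = 0; i < r; ++i) {
    resample_sorted(x, xb, cnt, rng);
    resample_sorted(y, yb, cnt, rng);
    resample_sorted(z, zb, cnt, rng);
    th[i] = theta_any(xb, yb, zb);
  }
  return sd_of(th);
}

// One outer replicate of the embedded bootstrap: resample (X*, Y*, Z*),
// compute theta*, estimate its own inner-bootstrap standard error S* from
// r_inner joint resamples of the starred triple, and return
// T* = (theta* - theta_hat) / S*. A degenerate S* = 0 maps to +/-Inf by
// the sign of the numerator (0 if the numerator is 0).
// [[Rcpp::export(name = ".cpp_tstar")]]
double cpp_tstar(NumericVector xs, NumericVector ys, NumericVector zs,
                 double theta_hat, int r_inner, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  std::vector<double> x(xs.begin(), xs.end());
  std::vector<double> y(ys.begin(), ys.end());
  std::vector<double> z(zs.begin(), zs.end());
  size_t nm = x.size();
  if (y.size() > nm) nm = y.size();
  if (z.size() > nm) nm = z.size();
  std::vector<double> xb, yb, zb, xi, yi, zi, th(r_inner);
  std::vector<int> cnt(nm);
  xb.reserve(x.size()); yb.reserve(y.size()); zb.reserve(z.size());
  xi.reserve(x.size()); yi.reserve(y.size()); zi.reserve(z.size());

  resample_sorted(x, xb, cnt, rng);
  resample_sorted(y, yb, cnt, rng);
  resample_sorted(z, zb, cnt, rng);
  const double th_b = theta_any(xb, yb, zb);

  for (int i = 0; i < r_inner; ++i) {
    resample_sorted(xb, xi, cnt, rng);
    resample_sorted(yb, yi, cnt, rng);
    resample_sorted(zb, zi, cnt, rng);
    th[i] = theta_any(xi, yi, zi);
  }
  const double s_b = sd_of(th);
  const double num = th_b - theta_hat;
  if (!(s_b > 0.0)) {
    if (num > 0.0) return R_PosInf;
    if (num < 0.0) return R_NegInf;
    return 0.0;
  }
  return num / s_b;
}
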