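// Brownian-dynamics simulation of fluorescent molecules in a periodic
// cuboid, observed through a 3D Gaussian confocal volume, with Poisson
// photon counting per bin. All randomness comes from one xoshiro256++
// stream seeded (via splitmix64) by the caller, so a seed fully
// determines the output. A fast generator matters here: every molecule
// takes three Gaussian steps per time bin.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xoshiro256++ (Blackman & Vigna), seeded via splitmix64
struct Xoshiro256pp {
  std::uint64_t s[4];

  explicit Xoshiro256pp(std::uint64_t seed) {
    std::uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      std::uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]
  inline double uniform01() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }

  // uniform in [-1, 1)
  inline double uniformSym() {
    return static_cast<double>(static_cast<std::int64_t>(next())) * 0x1.0p-63;
  }
};

// standard normal via the Marsaglia polar method with one cached spare
struct NormalGen {
  Xoshiro256pp& rng;
  bool hasSpare = false;
  double spare = 0.0;

  explicit NormalGen(Xoshiro256pp& r) : rng(r) {}

  inline double operator()() {
    if (hasSpare) {
      hasSpare = false;
      return spare;
    }
    double u, v, s;
    do {
      u = rng.uniformSym();
      v = rng.uniformSym();
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    hasSpare = true;
    return u * f;
  }
};

// Poisson draw: inversion by sequential search for small means, otherwise
// the PTRS transformed-rejection sampler (Hoermann, 1993).
double poissonDraw(Xoshiro256pp& rng, NormalGen& norm, double lambda) {
  if (lambda <= 0.0) return 0.0;
  if (lambda < 30.0) {
    double l = std::exp(-lambda);
    double p = 1.0;
    double k = 0.0;
    do {
      ++k;
      p *= rng.uniform01();
    } while (p > l);
    return k - 1.0;
  }
  // PTRS
  const double b = 0.931 + 2.53 * std::sqrt(lambda);
  const double a = -0.059 + 0.02483 * b;
  const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
  const double v_r = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    double u = rng.uniform01() - 0.5;
    double v = rng.uniform01();
    double us = 0.5 - std::fabs(u);
    double k = std::floor((2.0 * a / us + b) * u + lambda + 0.43);
    if (us >= 0.07 && v <= v_r) return k;
    if (k < 0.0 || (us < 0.013 && v > us)) continue;
    if (std::log(v * inv_alpha / (a / (us * us) + b)) <=
        k * std::log(lambda) - lambda - std::lgamma(k + 1.0))
      return k;
  }
  (void)norm;
}

}  // namespace

// [[Rcpp::export]]
List simulate_photon_traces_cpp(IntegerVector nMol,
                                NumericVector dCoef,
                                NumericVector brightG,
                                NumericVector brightR,
                                double wXY, double wZ,
                                double bx, double by, double bz,
                                double binWidth, int nBins,
                                int nSubsteps, double seed) {
  const int nSpec = nMol.size();
  if (dCoef.size() != nSpec || brightG.size() != nSpec ||
      brightR.size() != nSpec)
    stop("species arrays must have equal length");

  long total = 0;
  for (int s = 0; s < nSpec; ++s) {
    if (nMol[s] < 0) stop("negative molecule count");
    total += nMol[s];
  }

  const double dt = binWidth / nSubsteps;
  Xoshiro256pp rng(static_cast<std::uint64_t>(seed));
  NormalGen norm(rng);

  std::vector<double> px(total), py(total), pz(total);
  std::vector<double> stepSd(total), bg(total), br(total);
  {
    long k = 0;
    for (int s = 0; s < nSpec; ++s) {
      const double sd = std::sqrt(2.0 * dCoef[s] * dt);
      for (int i = 0; i < nMol[s]; ++i, ++k) {
        px[k] = rng.uniformSym() * bx;
        py[k] = rng.uniformSym() * by;
        pz[k] = rng.uniformSym() * bz;
        stepSd[k] = sd;
        bg[k] = brightG[s];
        br[k] = brightR[s];
      }
    }
  }

  const double ax = 2.0 / (wXY * wXY);
  const double az = 2.0 / (wZ * wZ);
  const double argCut = 23.0;  // exp(-23) ~ 1e-10 of the peak rate

  IntegerVector outG(nBins), outR(nBins);
  const double twoBx = 2.0 * bx, twoBy = 2.0 * by, twoBz = 2.0 * bz;

  for (int b = 0; b < nBins; ++b) {
    double expG = 0.0, expR = 0.0;
    for (int sub = 0; sub < nSubsteps; ++sub) {
      for (long k = 0; k < total; ++k) {
        double x = px[k] + stepSd[k] * norm();
        double y = py[k] + stepSd[k] * norm();
        double z = pz[k] + stepSd[k] * norm();
        // periodic wrap (steps are small relative to the box)
        if (x > bx) x -= twoBx; else if (x < -bx) x += twoBx;
        if (y > by) y -= twoBy; else if (y < -by) y += twoBy;
        if (z > bz) z -= twoBz; else if (z < -bz) z += twoBz;
        px[k] = x; py[k] = y; pz[k] = z;
        const double arg = ax * (x * x + y * y) + az * z * z;
        if (arg < argCut) {
          const double w = std::exp(-arg);
          expG += bg[k] * w;
          expR += br[k] * w;
        }
      }
    }
    outG[b] = static_cast<int>(poissonDraw(rng, norm, expG * dt));
    outR[b] = static_cast<int>(poissonDraw(rng, norm, expR * dt));
  }

  return List::create(Named("green") = outG, Named("red") = outR);
}
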