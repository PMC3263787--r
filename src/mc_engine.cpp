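// Weighted-packet Monte Carlo photon transport in a layered semi-infinite
// slab (MCML-style hop/drop/spin with Russian roulette).  Pencil beam enters
// normally at the origin; diffuse reflectance is scored in annular bins
// centred on the requested source-detector distances, together with the
// per-layer pathlengths of each detected packet.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro256+ with splitmix64 seeding: fast, high-quality, and fully
// deterministic across platforms for a given (seed, stream) pair.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97f4A7C15ULL + stream;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    // avoid the all-zero state
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]; never returns 0 so -log(u) is finite
  double unif_pos() {
    double u = (next() >> 11) * 0x1.0p-53;
    return u > 0.0 ? u : 0x1.0p-53;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// unpolarized Fresnel reflectance for cos(theta_i) = ci, indices n1 -> n2
double fresnel(double n1, double n2, double ci, double &ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  if (ci > 0.999999) {            // normal incidence
    ct = 1.0;
    double r = (n1 - n2) / (n1 + n2);
    return r * r;
  }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { ct = 0.0; return 1.0; }  // total internal reflection
  ct = std::sqrt(std::max(0.0, 1.0 - st * st));
  double cap = ci * ct - si * st;  // cos(i + t)
  double cam = ci * ct + si * st;  // cos(i - t)
  double sap = si * ct + ci * st;  // sin(i + t)
  double sam = si * ct - ci * st;  // sin(i - t)
  double rs = sam / sap;
  double rp = cap / cam;
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export]]
List mc_transport_cpp(NumericVector thickness, NumericVector mua,
                      NumericVector mus, NumericVector g,
                      NumericVector n_refr, double n_ambient,
                      NumericVector distances, double half_width,
                      double n_photons, int seed, int stream,
                      double w_threshold, double p_survival,
                      double max_path, bool store_paths) {
  const int L = thickness.size();
  const int K = distances.size();
  const long N = static_cast<long>(n_photons);

  // cumulative layer boundaries; z_bound[0] = 0 (surface)
  std::vector<double> z_bound(L + 1);
  z_bound[0] = 0.0;
  for (int i = 0; i < L; ++i)
    z_bound[i + 1] = R_FINITE(thickness[i]) ? z_bound[i] + thickness[i]
                                            : R_PosInf;

  Xoshiro rng(static_cast<uint64_t>(seed), static_cast<uint64_t>(stream));

  std::vector<double> sumw(K, 0.0), sumw2(K, 0.0);
  std::vector<long> ndet(K, 0);
  std::vector<double> sumwL(static_cast<size_t>(K) * L, 0.0);
  std::vector<double> path_store;  // (bin, w, L_1..L_L) per detected packet

  double specular = 0.0, diffuse = 0.0, absorbed = 0.0;
  double roulette_net = 0.0, cap_killed = 0.0;

  std::vector<double> pl(L);

  for (long ip = 0; ip < N; ++ip) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    // launch: pencil beam, normal incidence; specular loss at the surface
    double ci_dummy;
    double rsp = fresnel(n_ambient, n_refr[0], 1.0, ci_dummy);
    specular += rsp;
    double w = 1.0 - rsp;
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double path = 0.0;
    std::fill(pl.begin(), pl.end(), 0.0);
    double sleft = 0.0;  // dimensionless remaining optical step
    bool alive = true;

    while (alive) {
      double mt = mua[layer] + mus[layer];
      if (sleft <= 0.0) sleft = -std::log(rng.unif_pos());
      double s = sleft / mt;

      // distance to the layer boundary along the flight direction
      double db = R_PosInf;
      if (uz > 0.0) {
        if (R_FINITE(z_bound[layer + 1])) db = (z_bound[layer + 1] - z) / uz;
      } else if (uz < 0.0) {
        db = (z_bound[layer] - z) / uz;
      }

      if (db <= s) {
        // hop to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        path += db; pl[layer] += db;
        sleft -= db * mt;

        bool up = uz < 0.0;
        double n1 = n_refr[layer];
        double n2 = up ? (layer == 0 ? n_ambient : n_refr[layer - 1])
                       : n_refr[layer + 1];
        double ct;
        double R = fresnel(n1, n2, std::fabs(uz), ct);
        if (rng.unif() < R) {
          uz = -uz;  // internal reflection
        } else if (up && layer == 0) {
          // escapes through the surface: score as diffuse reflectance
          diffuse += w;
          double r = std::sqrt(x * x + y * y);
          for (int k = 0; k < K; ++k) {
            if (std::fabs(r - distances[k]) <= half_width) {
              sumw[k] += w;
              sumw2[k] += w * w;
              ndet[k] += 1;
              for (int l = 0; l < L; ++l)
                sumwL[static_cast<size_t>(k) * L + l] += w * pl[l];
              if (store_paths) {
                path_store.push_back(static_cast<double>(k + 1));
                path_store.push_back(w);
                for (int l = 0; l < L; ++l) path_store.push_back(pl[l]);
              }
            }
          }
          alive = false;
        } else {
          // refract across the internal interface
          double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = up ? -ct : ct;
          double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= norm; uy /= norm; uz /= norm;
          layer += up ? -1 : 1;
        }
      } else {
        // hop, drop, spin
        x += ux * s; y += uy * s; z += uz * s;
        path += s; pl[layer] += s;
        sleft = 0.0;

        absorbed += w * mua[layer] / mt;
        w *= mus[layer] / mt;

        double cost;
        double gl = g[layer];
        if (std::fabs(gl) < 1e-6) {
          cost = 2.0 * rng.unif() - 1.0;
        } else {
          double t = (1.0 - gl * gl) / (1.0 - gl + 2.0 * gl * rng.unif());
          cost = (1.0 + gl * gl - t * t) / (2.0 * gl);
          if (cost > 1.0) cost = 1.0;
          if (cost < -1.0) cost = -1.0;
        }
        double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
        double phi = 2.0 * M_PI * rng.unif();
        double cosp = std::cos(phi), sinp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sint * cosp;
          uy = sint * sinp;
          uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double ux2 = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
          double uy2 = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
          double uz2 = -sint * cosp * den + uz * cost;
          ux = ux2; uy = uy2; uz = uz2;
        }

        if (w < w_threshold && w > 0.0) {
          if (rng.unif() < p_survival) {
            double w_new = w / p_survival;
            roulette_net -= (w_new - w);  // weight created by the boost
            w = w_new;
          } else {
            roulette_net += w;  // weight destroyed by the kill
            alive = false;
          }
        }
      }

      if (alive && path > max_path) {
        cap_killed += w;
        alive = false;
      }
    }
  }

  NumericMatrix mppw(K, L);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l)
      mppw(k, l) = sumwL[static_cast<size_t>(k) * L + l];

  List out = List::create(
      _["sumw"] = NumericVector(sumw.begin(), sumw.end()),
      _["sumw2"] = NumericVector(sumw2.begin(), sumw2.end()),
      _["n_detected"] = NumericVector(ndet.begin(), ndet.end()),
      _["sumwL"] = mppw,
      _["specular"] = specular / N,
      _["diffuse"] = diffuse / N,
      _["absorbed"] = absorbed / N,
      _["roulette_net"] = roulette_net / N,
      _["cap_killed"] = cap_killed / N,
      _["n_photons"] = static_cast<double>(N));

  if (store_paths) {
    int ncol = 2 + L;
    int nrow = static_cast<int>(path_store.size() / ncol);
    NumericMatrix pm(nrow, ncol);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < ncol; ++j)
        pm(i, j) = path_store[static_cast<size_t>(i) * ncol + j];
    out["paths"] = pm;
  }
  return out;
}
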