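// Multilayer Monte Carlo photon transport (MCML-style random walk).
// Planar layers perpendicular to z, pencil beam at the origin, normal
// incidence.  Henyey-Greenstein scattering, Fresnel reflection/refraction at
// every refractive-index mismatch, implicit-capture absorption weighting and
// Russian-roulette termination.  Diffuse reflectance escaping the top
// surface is accumulated into annular radial bins.
#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr double W_THRESHOLD = 1e-4; // roulette trigger
constexpr double ROULETTE_P  = 0.1;  // survival probability
// hard cap on random-walk events per photon: without absorption the weight
// never decays and a photon in a semi-infinite non-absorbing medium can walk
// arbitrarily long; capped photons are tallied as lost weight
constexpr long   MAX_EVENTS  = 2000000;

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(uint64_t seed) : eng(seed) {}
  // (0, 1]: never 0 so log() is safe
  double next() {
    double u = unif(eng);
    return u > 0.0 ? u : std::numeric_limits<double>::min();
  }
};

// Unpolarized Fresnel reflectance for incidence cosine ci (>0), n1 -> n2.
// Returns reflectance and, via ct, the transmission cosine.
double fresnel(double n1, double n2, double ci, double& ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { ct = 0.0; return 1.0; } // total internal reflection
  ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine
double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  return (1.0 + g * g - f * f) / (2.0 * g);
}

} // namespace

// [[Rcpp::export(name = ".mc_layered_cpp")]]
List mc_layered_cpp(NumericVector thickness, NumericVector mua,
                    NumericVector mus, NumericVector g, NumericVector n,
                    double n_ambient, int n_photons, double dr, int nr,
                    double seed) {
  const int nl = thickness.size();
  if (nl < 1) stop("at least one layer is required");
  // cumulative layer boundaries z[0]=0 .. z[nl]
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i)
    zb[i + 1] = zb[i] + (std::isfinite(thickness[i]) ? thickness[i] : 1e12);

  Rng rng(static_cast<uint64_t>(seed));

  std::vector<double> refl(nr + 1, 0.0); // last bin = overflow
  double total_diffuse = 0.0, total_trans = 0.0, total_abs = 0.0,
         total_lost = 0.0;

  // specular reflection at normal incidence on the top interface
  double rsp = (n_ambient - n[0]) / (n_ambient + n[0]);
  rsp *= rsp;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int layer = 0;
    double sleft = 0.0; // dimensionless step left over from a boundary hit
    long events = 0;

    for (;;) {
      if (++events > MAX_EVENTS) { total_lost += w; break; }
      double mut = mua[layer] + mus[layer];
      double step;
      if (mut <= 0.0) {
        step = 1e12;
      } else {
        if (sleft <= 0.0) sleft = -std::log(rng.next());
        step = sleft / mut;
      }

      // distance to the boundary along uz
      double dbound = 1e12;
      int tolayer = layer;
      if (uz > 0.0) { dbound = (zb[layer + 1] - z) / uz; tolayer = layer + 1; }
      else if (uz < 0.0) { dbound = (zb[layer] - z) / uz; tolayer = layer - 1; }

      if (step >= dbound) {
        // hit the boundary: move there, keep unspent step
        x += ux * dbound; y += uy * dbound; z += uz * dbound;
        if (mut > 0.0) sleft -= dbound * mut; else sleft = 0.0;
        double ci = std::fabs(uz);
        double n1 = n[layer];
        double n2 = (tolayer < 0) ? n_ambient
                  : (tolayer >= nl) ? n[nl - 1] : n[tolayer];
        double ct;
        double R = fresnel(n1, n2, ci, ct);
        if (rng.next() <= R) {
          uz = -uz; // internal reflection
        } else {
          if (tolayer < 0) {
            // escaped the top: diffuse reflectance
            double r = std::sqrt(x * x + y * y);
            int ib = static_cast<int>(r / dr);
            if (ib >= nr) ib = nr;
            refl[ib] += w;
            total_diffuse += w;
            break;
          } else if (tolayer >= nl) {
            total_trans += w; // only reachable with finite last layer
            break;
          } else {
            // refract into the next layer
            double s = n1 / n2;
            ux *= s; uy *= s;
            uz = (uz > 0.0) ? ct : -ct;
            layer = tolayer;
          }
        }
        continue;
      }

      // interact inside the layer
      x += ux * step; y += uy * step; z += uz * step;
      sleft = 0.0;
      double dw = w * mua[layer] / mut;
      total_abs += dw;
      w -= dw;

      // scatter (Henyey-Greenstein)
      double ct = hg_cos(g[layer], rng.next());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * rng.next();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }

      if (w < W_THRESHOLD) {
        if (rng.next() <= ROULETTE_P) w /= ROULETTE_P;
        else { total_abs += w; break; }
      }
    }
  }

  return List::create(
    _["bin_weights"]   = NumericVector(refl.begin(), refl.end() - 1),
    _["overflow"]      = refl[nr],
    _["specular"]      = rsp,
    _["total_diffuse"] = total_diffuse / n_photons,
    _["total_trans"]   = total_trans / n_photons,
    _["total_abs"]     = total_abs / n_photons,
    _["total_lost"]    = total_lost / n_photons);
}
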