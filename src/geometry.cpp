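#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley SASA with a deterministic golden-section spiral point lattice.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii, double probe,
                       int n_points) {
  const int n = coords.nrow();
  if (n == 0) stop("empty coordinate set");
  // unit sphere lattice
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    sx[k] = r * std::cos(phi);
    sy[k] = r * std::sin(phi);
    sz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + rj;
      if (d2 < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = coords(i, 0) + ri * sx[k];
      double py = coords(i, 1) + ri * sy[k];
      double pz = coords(i, 2) + ri * sz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = px - coords(j, 0);
        double dy = py - coords(j, 1);
        double dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return area;
}

// Per-residue-pair minimum heavy-atom distance (dense nres x nres matrix) and
// per-residue inter-residue atom-contact counts at `contact_cutoff`.
// `res` holds 1-based residue indices per atom.
// [[Rcpp::export]]
List residue_dist_stats_cpp(NumericMatrix coords, IntegerVector res, int nres,
                            double contact_cutoff) {
  const int n = coords.nrow();
  NumericMatrix mind(nres, nres);
  std::fill(mind.begin(), mind.end(), R_PosInf);
  IntegerVector contacts(nres);
  const double cc2 = contact_cutoff * contact_cutoff;
  for (int i = 0; i < n; ++i) {
    int ri = res[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      int rj = res[j] - 1;
      if (ri == rj) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind(ri, rj)) { mind(ri, rj) = d2; mind(rj, ri) = d2; }
      if (d2 <= cc2) { contacts[ri]++; contacts[rj]++; }
    }
  }
  for (int a = 0; a < nres; ++a)
    for (int b = 0; b < nres; ++b)
      if (R_finite(mind(a, b))) mind(a, b) = std::sqrt(mind(a, b));
  return List::create(_["min_dist"] = mind, _["atom_contacts"] = contacts);
}

// Mutual information (bits) of two discretized vectors with levels 0..k-1.
// [[Rcpp::export]]
double mi_disc_cpp(IntegerVector x, IntegerVector y, int kx, int ky) {
  const int n = x.size();
  if (n != y.size()) stop("length mismatch");
  std::vector<double> joint(kx * ky, 0.0), px(kx, 0.0), py(ky, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[x[i] * ky + y[i]] += 1.0;
    px[x[i]] += 1.0;
    py[y[i]] += 1.0;
  }
  double mi = 0.0;
  for (int a = 0; a < kx; ++a)
    for (int b = 0; b < ky; ++b) {
      double pj = joint[a * ky + b] / n;
      if (pj > 0.0)
        mi += pj * std::log2(pj * n * n / (px[a] * py[b]));
    }
  return std::max(mi, 0.0);
}
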