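#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

// 3-D Delaunay tessellation via incremental Bowyer-Watson insertion with a
// large enclosing super-tetrahedron. Near-cospherical or coplanar
// configurations raise a degeneracy flag; the R wrapper retries on jittered
// coordinates (seeded, deterministic).

namespace {

struct Tet {
  int v[4];
  double cc[3];   // circumcenter
  double r2;      // squared circumradius
  bool alive;
};

// circumsphere of 4 points; returns false when (near-)coplanar
bool circumsphere(const std::vector<std::array<double, 3> >& P, const int v[4],
                  double cc[3], double& r2) {
  const std::array<double, 3>&a = P[v[0]];
  double A[3][3], b[3];
  for (int i = 0; i < 3; ++i) {
    const std::array<double, 3>& q = P[v[i + 1]];
    b[i] = 0.0;
    for (int d = 0; d < 3; ++d) {
      A[i][d] = 2.0 * (q[d] - a[d]);
      b[i] += q[d] * q[d] - a[d] * a[d];
    }
  }
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int d = 0; d < 3; ++d) scale = std::max(scale, std::fabs(A[i][d]));
  if (std::fabs(det) < 1e-10 * scale * scale * scale + 1e-30) return false;
  // Cramer's rule
  for (int d = 0; d < 3; ++d) {
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int e = 0; e < 3; ++e) M[i][e] = (e == d) ? b[i] : A[i][e];
    double dd = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    cc[d] = dd / det;
  }
  r2 = 0.0;
  for (int d = 0; d < 3; ++d) r2 += (cc[d] - a[d]) * (cc[d] - a[d]);
  return true;
}

}  // namespace

// [[Rcpp::export]]
List delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  bool degenerate = false;

  std::vector<std::array<double, 3> > P(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf},
         hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      P[i + 4][d] = pts(i, d);
      lo[d] = std::min(lo[d], pts(i, d));
      hi[d] = std::max(hi[d], pts(i, d));
    }
  double c[3], L = 1.0;
  for (int d = 0; d < 3; ++d) {
    c[d] = 0.5 * (lo[d] + hi[d]);
    L = std::max(L, hi[d] - lo[d]);
  }
  double M = 50.0 * L + 50.0;
  P[0] = {c[0], c[1], c[2] + 3.0 * M};
  P[1] = {c[0] - 2.0 * M, c[1] - M, c[2] - M};
  P[2] = {c[0] + 2.0 * M, c[1] - M, c[2] - M};
  P[3] = {c[0], c[1] + 2.0 * M, c[2] - M};

  std::vector<Tet> tets;
  {
    Tet t0;
    t0.v[0] = 0; t0.v[1] = 1; t0.v[2] = 2; t0.v[3] = 3;
    t0.alive = circumsphere(P, t0.v, t0.cc, t0.r2);
    if (!t0.alive) stop("internal error: degenerate super-tetrahedron");
    tets.push_back(t0);
  }

  typedef std::array<int, 3> Face;
  for (int ip = 4; ip < n + 4; ++ip) {
    const std::array<double, 3>& p = P[ip];
    std::vector<int> bad;
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d)
        d2 += (p[d] - tets[t].cc[d]) * (p[d] - tets[t].cc[d]);
      double margin = d2 - tets[t].r2;
      if (std::fabs(margin) < 1e-12 * (d2 + tets[t].r2) + 1e-12)
        degenerate = true;
      if (margin < 0.0) bad.push_back((int)t);
    }
    if (bad.empty()) { degenerate = true; continue; }

    std::map<Face, int> fcount;
    for (size_t b = 0; b < bad.size(); ++b) {
      const int* v = tets[bad[b]].v;
      static const int fidx[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
      for (int f = 0; f < 4; ++f) {
        Face fc = {v[fidx[f][0]], v[fidx[f][1]], v[fidx[f][2]]};
        std::sort(fc.begin(), fc.end());
        fcount[fc]++;
      }
      tets[bad[b]].alive = false;
    }
    for (std::map<Face, int>::iterator it = fcount.begin(); it != fcount.end(); ++it) {
      if (it->second != 1) continue;  // internal face of the cavity
      Tet nt;
      nt.v[0] = it->first[0]; nt.v[1] = it->first[1];
      nt.v[2] = it->first[2]; nt.v[3] = ip;
      nt.alive = circumsphere(P, nt.v, nt.cc, nt.r2);
      if (!nt.alive) { degenerate = true; continue; }
      tets.push_back(nt);
    }
  }

  std::vector<std::array<int, 4> > keep;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k)
      if (tets[t].v[k] < 4) { super = true; break; }
    if (!super) {
      std::array<int, 4> tv;
      for (int k = 0; k < 4; ++k) tv[k] = tets[t].v[k] - 4 + 1;  // 1-based
      keep.push_back(tv);
    }
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (size_t t = 0; t < keep.size(); ++t)
    for (int k = 0; k < 4; ++k) out(t, k) = keep[t][k];
  return List::create(_["tets"] = out, _["degenerate"] = degenerate);
}
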