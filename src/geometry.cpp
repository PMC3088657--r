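#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid overlap volume between the union of ligand vdW spheres and the union
// of protein vdW spheres. The grid covers the ligand bounding box padded by
// the largest vdW radius present; each grid point is counted once, so
// multi-atom overlap is never double counted.
// [[Rcpp::export(name = ".clash_volume_grid")]]
double clash_volume_grid(NumericMatrix lig, NumericVector lig_r,
                         NumericMatrix prot, NumericVector prot_r,
                         double spacing) {
  int nl = lig.nrow(), np = prot.nrow();
  if (nl == 0 || np == 0) return 0.0;
  double pad = 0.0;
  for (int i = 0; i < nl; ++i) pad = std::max(pad, lig_r[i]);
  for (int j = 0; j < np; ++j) pad = std::max(pad, prot_r[j]);
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < nl; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], lig(i, k));
      hi[k] = std::max(hi[k], lig(i, k));
    }
  for (int k = 0; k < 3; ++k) { lo[k] -= pad; hi[k] += pad; }

  // pre-filter protein atoms that cannot reach the padded box
  std::vector<int> keep;
  for (int j = 0; j < np; ++j) {
    bool in = true;
    for (int k = 0; k < 3; ++k)
      if (prot(j, k) < lo[k] - prot_r[j] || prot(j, k) > hi[k] + prot_r[j])
        { in = false; break; }
    if (in) keep.push_back(j);
  }
  if (keep.empty()) return 0.0;

  long count = 0;
  int nx = (int)std::floor((hi[0] - lo[0]) / spacing) + 1;
  int ny = (int)std::floor((hi[1] - lo[1]) / spacing) + 1;
  int nz = (int)std::floor((hi[2] - lo[2]) / spacing) + 1;
  for (int ix = 0; ix < nx; ++ix) {
    double px = lo[0] + ix * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      double py = lo[1] + iy * spacing;
      for (int iz = 0; iz < nz; ++iz) {
        double pz = lo[2] + iz * spacing;
        bool in_lig = false;
        for (int i = 0; i < nl; ++i) {
          double dx = px - lig(i, 0), dy = py - lig(i, 1), dz = pz - lig(i, 2);
          if (dx * dx + dy * dy + dz * dz <= lig_r[i] * lig_r[i]) {
            in_lig = true; break;
          }
        }
        if (!in_lig) continue;
        for (size_t jj = 0; jj < keep.size(); ++jj) {
          int j = keep[jj];
          double dx = px - prot(j, 0), dy = py - prot(j, 1), dz = pz - prot(j, 2);
          if (dx * dx + dy * dy + dz * dz <= prot_r[j] * prot_r[j]) {
            ++count; break;
          }
        }
      }
    }
  }
  return count * spacing * spacing * spacing;
}

// Shrake-Rupley solvent-accessible surface area for the query atoms, with
// all atoms (query + occluders) as the occluding set. Sphere points come
// from the golden-section spiral.
// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix xyz, NumericVector radii,
                                 IntegerVector query, double probe,
                                 int n_points) {
  int n = xyz.nrow(), nq = query.size();
  NumericVector out(nq);
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = zk;
  }
  for (int q = 0; q < nq; ++q) {
    int i = query[q] - 1;  // 1-based from R
    double ri = radii[i] + probe;
    // neighbours that can occlude atom i's expanded sphere
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < (ri + rj) * (ri + rj)) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = xyz(i, 0) + ri * px[k];
      double sy = xyz(i, 1) + ri * py[k];
      double sz = xyz(i, 2) + ri * pz[k];
      bool buried = false;
      for (size_t jj = 0; jj < nb.size(); ++jj) {
        int j = nb[jj];
        double rj = radii[j] + probe;
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[q] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return out;
}
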