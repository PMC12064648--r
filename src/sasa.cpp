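#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic golden-section spiral on the unit sphere.  No RNG: point k of
// n sits at z = 1 - 2(k+1/2)/n, longitude k * golden angle.  The set is
// close to uniform for n >= 92 and identical across calls and platforms.
static void golden_spiral(int n, std::vector<double> &px,
                          std::vector<double> &py, std::vector<double> &pz) {
  const double golden_angle = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden_angle * k;
    px[k] = rho * std::cos(phi);
    py[k] = rho * std::sin(phi);
    pz[k] = z;
  }
}

// [[Rcpp::export(name = ".sphere_points_cpp")]]
NumericMatrix sphere_points_cpp(int n_points) {
  std::vector<double> px, py, pz;
  golden_spiral(n_points, px, py, pz);
  NumericMatrix out(n_points, 3);
  for (int k = 0; k < n_points; ++k) {
    out(k, 0) = px[k]; out(k, 1) = py[k]; out(k, 2) = pz[k];
  }
  return out;
}

// Occlusion test shared by both neighbour strategies: a surface test point is
// buried iff it lies strictly inside some other atom's probe-expanded sphere.
static double atom_area(int i, const NumericMatrix &xyz,
                        const NumericVector &radii, double probe,
                        const std::vector<double> &px,
                        const std::vector<double> &py,
                        const std::vector<double> &pz,
                        const std::vector<int> &nbr) {
  const int n_points = (int)px.size();
  const double Ri = radii[i] + probe;
  const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
  const int m = (int)nbr.size();
  int accessible = 0;
  for (int k = 0; k < n_points; ++k) {
    const double qx = xi + Ri * px[k];
    const double qy = yi + Ri * py[k];
    const double qz = zi + Ri * pz[k];
    bool buried = false;
    for (int t = 0; t < m; ++t) {
      const int j = nbr[t];
      const double Rj = radii[j] + probe;
      const double dx = qx - xyz(j, 0);
      const double dy = qy - xyz(j, 1);
      const double dz = qz - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
    }
    if (!buried) ++accessible;
  }
  return 4.0 * M_PI * Ri * Ri * (double)accessible / (double)n_points;
}

// Shrake-Rupley SASA, all-pairs neighbour search (the reference path).
// [[Rcpp::export(name = ".sasa_all_pairs_cpp")]]
NumericVector sasa_all_pairs_cpp(NumericMatrix xyz, NumericVector radii,
                                 double probe, int n_points) {
  const int n = xyz.nrow();
  std::vector<double> px, py, pz;
  golden_spiral(n_points, px, py, pz);
  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    const double Ri = radii[i] + probe;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double cut = Ri + radii[j] + probe;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    area[i] = atom_area(i, xyz, radii, probe, px, py, pz, nbr);
  }
  return area;
}

// Shrake-Rupley SASA with a cell (linked-list) neighbour search.  Cells have
// edge 2*(r_max + probe) so every occluding pair lies in adjacent cells; the
// candidate set after the exact distance filter equals the all-pairs set, so
// the two paths return identical areas.
// [[Rcpp::export(name = ".sasa_cell_list_cpp")]]
NumericVector sasa_cell_list_cpp(NumericMatrix xyz, NumericVector radii,
                                 double probe, int n_points) {
  const int n = xyz.nrow();
  std::vector<double> px, py, pz;
  golden_spiral(n_points, px, py, pz);

  double r_max = 0.0;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i) {
    if (radii[i] > r_max) r_max = radii[i];
    for (int d = 0; d < 3; ++d) {
      if (xyz(i, d) < lo[d]) lo[d] = xyz(i, d);
      if (xyz(i, d) > hi[d]) hi[d] = xyz(i, d);
    }
  }
  const double cell = 2.0 * (r_max + probe);
  int dim[3];
  for (int d = 0; d < 3; ++d) {
    dim[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  }
  std::vector<int> head((size_t)dim[0] * dim[1] * dim[2], -1);
  std::vector<int> nxt(n, -1);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    int a = std::min(dim[0] - 1, (int)std::floor((xyz(i, 0) - lo[0]) / cell));
    int b = std::min(dim[1] - 1, (int)std::floor((xyz(i, 1) - lo[1]) / cell));
    int c = std::min(dim[2] - 1, (int)std::floor((xyz(i, 2) - lo[2]) / cell));
    ci[i] = a; cj[i] = b; ck[i] = c;
    size_t idx = ((size_t)a * dim[1] + b) * dim[2] + c;
    nxt[i] = head[idx];
    head[idx] = i;
  }

  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    const double Ri = radii[i] + probe;
    for (int da = -1; da <= 1; ++da) {
      int a = ci[i] + da;
      if (a < 0 || a >= dim[0]) continue;
      for (int db = -1; db <= 1; ++db) {
        int b = cj[i] + db;
        if (b < 0 || b >= dim[1]) continue;
        for (int dc = -1; dc <= 1; ++dc) {
          int c = ck[i] + dc;
          if (c < 0 || c >= dim[2]) continue;
          int j = head[((size_t)a * dim[1] + b) * dim[2] + c];
          while (j != -1) {
            if (j != i) {
              const double cut = Ri + radii[j] + probe;
              const double dx = xyz(i, 0) - xyz(j, 0);
              const double dy = xyz(i, 1) - xyz(j, 1);
              const double dz = xyz(i, 2) - xyz(j, 2);
              if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
            }
            j = nxt[j];
          }
        }
      }
    }
    // sort so the burial scan visits neighbours in the same order as the
    // all-pairs path (identical results even under FP-order paranoia)
    std::sort(nbr.begin(), nbr.end());
    area[i] = atom_area(i, xyz, radii, probe, px, py, pz, nbr);
  }
  return area;
}

// Per-residue minimum distance to a ligand atom set, one frame.
// group_start/group_end are 0-based half-open offsets into prot_idx.
// [[Rcpp::export(name = ".residue_min_dist_cpp")]]
NumericVector residue_min_dist_cpp(NumericMatrix xyz, IntegerVector prot_idx,
                                   IntegerVector group_start,
                                   IntegerVector group_end,
                                   IntegerVector lig_idx) {
  const int n_res = group_start.size();
  const int n_lig = lig_idx.size();
  NumericVector out(n_res);
  for (int r = 0; r < n_res; ++r) {
    double best = R_PosInf;
    for (int a = group_start[r]; a < group_end[r]; ++a) {
      const int i = prot_idx[a];
      for (int b = 0; b < n_lig; ++b) {
        const int j = lig_idx[b];
        const double dx = xyz(i, 0) - xyz(j, 0);
        const double dy = xyz(i, 1) - xyz(j, 1);
        const double dz = xyz(i, 2) - xyz(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[r] = std::sqrt(best);
  }
  return out;
}
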