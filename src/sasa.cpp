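#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Test points are placed on a deterministic golden-spiral lattice (no RNG),
// scaled to each atom's expanded sphere of radius r_i + probe. A point is
// accessible when it lies outside every other atom's expanded sphere
// (r_j + probe). Per-atom SASA = 4*pi*(r_i+probe)^2 * accessible / n_points.

// [[Rcpp::export(name = ".sasa_atoms_cpp")]]
NumericVector sasa_atoms_cpp(NumericMatrix xyz, NumericVector radii,
                             double probe, int n_points) {
  const int n = xyz.nrow();
  if (radii.size() != n) stop("radii length must match atom count");
  if (n_points < 1) stop("n_points must be positive");

  // golden-spiral unit sphere lattice
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double phi = golden * k;
    px[k] = std::cos(phi) * rho;
    py[k] = std::sin(phi) * rho;
    pz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double lim = Ri + Rj;
      if (d2 < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double x = xyz(i, 0) + Ri * px[k];
      const double y = xyz(i, 1) + Ri * py[k];
      const double z = xyz(i, 2) + Ri * pz[k];
      bool free_point = true;
      for (size_t t = 0; t < nbr.size(); ++t) {
        const int j = nbr[t];
        const double Rj = radii[j] + probe;
        const double dx = x - xyz(j, 0);
        const double dy = y - xyz(j, 1);
        const double dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * acc / n_points;
  }
  return area;
}
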