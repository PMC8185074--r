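#include <Rcpp.h>
#include <cmath>
#include <unordered_set>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double *a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

// Place atom X given bonded reference A, then B, C defining the frame:
// |X-A| = bond, angle X-A-B = ang (deg), dihedral X-A-B-C = tor (deg).
static inline void nerf_place(const double *A, const double *B, const double *C,
                              double bond, double ang, double tor, double *X) {
  double ab[3], bc[3], n[3], m[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = A[k] - B[k];   // B -> A
    bc[k] = B[k] - C[k];   // C -> B
  }
  double nab = norm3(ab);
  for (int k = 0; k < 3; ++k) ab[k] /= nab;
  cross3(bc, ab, n);       // normal of C-B-A plane
  double nn = norm3(n);
  for (int k = 0; k < 3; ++k) n[k] /= nn;
  cross3(n, ab, m);        // completes right-handed frame (ab, m, n)
  double th = ang * DEG, ph = tor * DEG;
  double d1 = -bond * std::cos(th);
  double d2 = bond * std::sin(th) * std::cos(ph);
  double d3 = bond * std::sin(th) * std::sin(ph);
  for (int k = 0; k < 3; ++k)
    X[k] = A[k] + d1 * ab[k] + d2 * m[k] + d3 * n[k];
}

// Build cartesian coordinates from an internal-coordinate table.
// refs: n x 3 (1-based atom indices, 0 => atom is fixed, use coords_init)
// geom: n x 3 (bond A, angle deg, base torsion deg)
// tor_idx: n (0 => torsion fixed at base; k>0 => base + tvals[k-1])
// [[Rcpp::export]]
NumericMatrix ic_build_cpp(IntegerMatrix refs, NumericMatrix geom,
                           IntegerVector tor_idx, NumericVector tvals,
                           NumericMatrix coords_init) {
  int n = refs.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i) {
    if (refs(i, 0) == 0) {
      for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords_init(i, k);
    } else {
      int a = refs(i, 0) - 1, b = refs(i, 1) - 1, c = refs(i, 2) - 1;
      if (a >= i || b >= i || c >= i)
        stop("internal-coordinate reference atoms must precede the atom");
      double tor = geom(i, 2);
      if (tor_idx[i] > 0) tor += tvals[tor_idx[i] - 1];
      nerf_place(&xyz[3 * a], &xyz[3 * b], &xyz[3 * c],
                 geom(i, 0), geom(i, 1), tor, &xyz[3 * i]);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = xyz[3 * i + k];
  return out;
}

// Signed dihedral p1-p2-p3-p4, IUPAC convention, degrees in (-180, 180].
// [[Rcpp::export]]
double dihedral_cpp(NumericVector p1, NumericVector p2, NumericVector p3,
                    NumericVector p4) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], c[3];
  for (int k = 0; k < 3; ++k) {
    b1[k] = p2[k] - p1[k];
    b2[k] = p3[k] - p2[k];
    b3[k] = p4[k] - p3[k];
  }
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  cross3(n1, n2, c);
  double nb2 = norm3(b2);
  double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
  double y = (c[0] * b2[0] + c[1] * b2[1] + c[2] * b2[2]) / nb2;
  double ang = std::atan2(y, x) / DEG;
  if (ang <= -180.0) ang += 360.0;
  return ang;
}

// Pairwise nonbonded energy terms over one coordinate set.
// role: 0 none, 1 donor(heavy), 2 acceptor, 3 both
// excl: 2 x m matrix of 1-based atom index pairs to skip (bonded/1-3/1-4)
// active: pairs with both atoms inactive are skipped (for interface-only)
// Returns c(lj_rep, lj_atr, hb, elec) unweighted.
// [[Rcpp::export]]
NumericVector pair_energy_cpp(NumericMatrix coords, NumericVector radius,
                              NumericVector charge, IntegerVector role,
                              IntegerMatrix excl, LogicalVector active,
                              double cutoff = 10.0, double eps_lj = 0.15,
                              double hb_ideal = 2.9, double hb_sd = 0.3,
                              double hb_max = 3.5, double hb_depth = 1.0,
                              double elec_eps = 10.0, double elec_kappa = 10.0) {
  int n = coords.nrow();
  std::unordered_set<long long> skip;
  for (int j = 0; j < excl.ncol(); ++j) {
    long long a = excl(0, j) - 1, b = excl(1, j) - 1;
    if (a > b) std::swap(a, b);
    skip.insert(a * (long long)n + b);
  }
  double rep = 0, atr = 0, hb = 0, elec = 0;
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (!active[i] && !active[j]) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      if (skip.count((long long)i * n + j)) continue;
      double d = std::sqrt(d2);
      double s = radius[i] + radius[j];
      // 12-6 split at the minimum (d = s): rep >= 0 for d < s, atr <= 0
      double deff = d < 0.6 * s ? 0.6 * s : d;  // flatten deep overlap
      double r6 = std::pow(s / deff, 6.0);
      double e = eps_lj * (r6 * r6 - 2.0 * r6);
      if (d < s) {
        rep += e + eps_lj;
        atr += -eps_lj;
      } else {
        atr += e;
      }
      // distance-only hydrogen bond: donor-heavy vs acceptor
      bool don_i = role[i] == 1 || role[i] == 3;
      bool acc_i = role[i] == 2 || role[i] == 3;
      bool don_j = role[j] == 1 || role[j] == 3;
      bool acc_j = role[j] == 2 || role[j] == 3;
      if (d < hb_max && ((don_i && acc_j) || (don_j && acc_i))) {
        double z = (d - hb_ideal) / hb_sd;
        hb += -hb_depth * std::exp(-0.5 * z * z);
      }
      if (charge[i] != 0 && charge[j] != 0)
        elec += 332.0 * charge[i] * charge[j] / (elec_eps * d) *
                std::exp(-d / elec_kappa);
    }
  }
  return NumericVector::create(_["lj_rep"] = rep, _["lj_atr"] = atr,
                               _["hb"] = hb, _["elec"] = elec);
}

// Count pairs between two coordinate sets closer than cutoff.
// [[Rcpp::export]]
int count_close_pairs_cpp(NumericMatrix a, NumericMatrix b, double cutoff) {
  int n = a.nrow(), m = b.nrow(), count = 0;
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      if (dx * dx + dy * dy + dz * dz < cut2) ++count;
    }
  return count;
}
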