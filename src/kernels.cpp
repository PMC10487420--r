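#include <Rcpp.h>
using namespace Rcpp;

// Geometry and pair-energy kernels. Coordinates are n x 3 matrices in
// Angstrom; all angle arguments are radians. Indices arriving from R are
// 1-based and converted here.

static inline void unitv(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

static inline void crossv(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Natural-extension reference frame chain build. Atom k is placed bonded to
// ref1 with the stated bond length, bond angle (to ref2) and dihedral (to
// ref3): dihedral(ref3, ref2, ref1, atom) = dbase + theta[toridx] when a
// torsion drives the placement. Refs < 1 mark the seed atoms of chain 1.
// [[Rcpp::export]]
NumericMatrix cpp_rebuild(IntegerVector ref1, IntegerVector ref2,
                          IntegerVector ref3, NumericVector bond,
                          NumericVector angle, NumericVector dbase,
                          IntegerVector toridx, NumericVector theta) {
  int n = ref1.size();
  NumericMatrix xyz(n, 3);
  for (int k = 0; k < n; ++k) {
    double dihe = dbase[k];
    if (toridx[k] > 0) dihe += theta[toridx[k] - 1];
    if (ref1[k] < 1) {  // first atom at origin
      xyz(k, 0) = xyz(k, 1) = xyz(k, 2) = 0.0;
      continue;
    }
    int a = ref1[k] - 1;
    if (ref2[k] < 1) {  // second atom along +x
      xyz(k, 0) = xyz(a, 0) + bond[k];
      xyz(k, 1) = xyz(a, 1);
      xyz(k, 2) = xyz(a, 2);
      continue;
    }
    int b = ref2[k] - 1;
    if (ref3[k] < 1) {  // third atom in the xy plane
      double u[3] = {xyz(a, 0) - xyz(b, 0), xyz(a, 1) - xyz(b, 1),
                     xyz(a, 2) - xyz(b, 2)};
      unitv(u);
      double z[3] = {0.0, 0.0, 1.0};
      double e[3];
      crossv(z, u, e);
      unitv(e);
      for (int d = 0; d < 3; ++d)
        xyz(k, d) = xyz(a, d) +
          bond[k] * (-std::cos(angle[k]) * u[d] + std::sin(angle[k]) * e[d]);
      continue;
    }
    int c = ref3[k] - 1;
    // NeRF: place D given chain C(ref3) - B(ref2) - A(ref1)
    double bcv[3] = {xyz(a, 0) - xyz(b, 0), xyz(a, 1) - xyz(b, 1),
                     xyz(a, 2) - xyz(b, 2)};
    unitv(bcv);
    double abv[3] = {xyz(b, 0) - xyz(c, 0), xyz(b, 1) - xyz(c, 1),
                     xyz(b, 2) - xyz(c, 2)};
    double nv[3];
    crossv(abv, bcv, nv);
    unitv(nv);
    double mv[3];
    crossv(nv, bcv, mv);
    double d2[3] = {-bond[k] * std::cos(angle[k]),
                    bond[k] * std::sin(angle[k]) * std::cos(dihe),
                    bond[k] * std::sin(angle[k]) * std::sin(dihe)};
    for (int d = 0; d < 3; ++d)
      xyz(k, d) = xyz(a, d) + bcv[d] * d2[0] + mv[d] * d2[1] + nv[d] * d2[2];
  }
  return xyz;
}

// Dihedral angles (radians, IUPAC sign) for quadruples of atom indices.
// [[Rcpp::export]]
NumericVector cpp_dihedrals(NumericMatrix xyz, IntegerVector q1,
                            IntegerVector q2, IntegerVector q3,
                            IntegerVector q4) {
  int n = q1.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    int a = q1[k] - 1, b = q2[k] - 1, c = q3[k] - 1, d = q4[k] - 1;
    double b1[3], b2[3], b3[3];
    for (int i = 0; i < 3; ++i) {
      b1[i] = xyz(b, i) - xyz(a, i);
      b2[i] = xyz(c, i) - xyz(b, i);
      b3[i] = xyz(d, i) - xyz(c, i);
    }
    double n1[3], n2[3];
    crossv(b1, b2, n1);
    crossv(b2, b3, n2);
    double b2u[3] = {b2[0], b2[1], b2[2]};
    unitv(b2u);
    double m[3];
    crossv(n1, n2, m);
    double x = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double y = m[0] * b2u[0] + m[1] * b2u[1] + m[2] * b2u[2];
    out[k] = std::atan2(y, x);
  }
  return out;
}

// Soft-core nonbonded repulsion: sum over listed pairs of
// eps * ((rmin - r) / rmin)^2 for r < rmin.
// [[Rcpp::export]]
double cpp_softcore(NumericMatrix xyz, IntegerVector pi, IntegerVector pj,
                    NumericVector rmin, double eps) {
  int n = pi.size();
  double e = 0.0;
  for (int k = 0; k < n; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < rmin[k] * rmin[k]) {
      double f = (rmin[k] - std::sqrt(r2)) / rmin[k];
      e += eps * f * f;
    }
  }
  return e;
}

// Count, per listed pair, whether the two atoms are within cutoff, and
// accumulate a per-atom neighbour (burial) count.
// [[Rcpp::export]]
IntegerVector cpp_burial(NumericMatrix xyz, IntegerVector pi, IntegerVector pj,
                         double cutoff) {
  int n = pi.size();
  IntegerVector counts(xyz.nrow());
  double c2 = cutoff * cutoff;
  for (int k = 0; k < n; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    if (dx * dx + dy * dy + dz * dz <= c2) {
      counts[i] += 1;
      counts[j] += 1;
    }
  }
  return counts;
}

// Count listed pairs with r < rmin - overlap (clash pairs).
// [[Rcpp::export]]
int cpp_clash_count(NumericMatrix xyz, IntegerVector pi, IntegerVector pj,
                    NumericVector rmin, double overlap) {
  int n = pi.size(), cnt = 0;
  for (int k = 0; k < n; ++k) {
    int i = pi[k] - 1, j = pj[k] - 1;
    double dx = xyz(i, 0) - xyz(j, 0);
    double dy = xyz(i, 1) - xyz(j, 1);
    double dz = xyz(i, 2) - xyz(j, 2);
    double lim = rmin[k] - overlap;
    if (lim > 0 && dx * dx + dy * dy + dz * dz < lim * lim) ++cnt;
  }
  return cnt;
}

// r^-6 summed effective distance per restraint. Pairs for restraint k
// occupy positions starts[k] .. starts[k+1]-1 (1-based, half-open) of
// ai/bi.
// [[Rcpp::export]]
NumericVector cpp_reff(NumericMatrix xyz, IntegerVector ai, IntegerVector bi,
                       IntegerVector starts) {
  int nr = starts.size() - 1;
  NumericVector out(nr);
  for (int k = 0; k < nr; ++k) {
    double s = 0.0;
    for (int p = starts[k] - 1; p < starts[k + 1] - 1; ++p) {
      int i = ai[p] - 1, j = bi[p] - 1;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      s += 1.0 / (r2 * r2 * r2);
    }
    out[k] = std::pow(s, -1.0 / 6.0);
  }
  return out;
}
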