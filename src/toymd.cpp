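// Toy Lennard-Jones / Monte Carlo engine.
//
// Energy model (kcal/mol, Angstrom):
//  * pair LJ: U = eps * [ (rmin^2/r^2)^6 - 2 (rmin^2/r^2)^3 ], with
//    Lorentz-Berthelot mixing (arithmetic rmin, geometric eps), a 10 A
//    cutoff and a CHARMM-style polynomial switching function from 6 A;
//  * alchemical pairs (one particle carrying coupling strength lc in [0,1]):
//    U = lc * eps * [ (rmin^2/(r^2 + shift*(1-lc)))^6
//                     - 2 (rmin^2/(r^2 + shift*(1-lc)))^3 ] * S(r),
//    the soft-core squared-distance-shift form; cross pairs between the
//    decoupling and coupling sets are excluded, pairs within one set stay
//    fully coupled;
//  * bonds and restraints: (k/2) (r - r0)^2.
//
// The decoupling progress variable lam in [0,1] maps to per-particle
// coupling strengths: decoupling set lc = 1 - lam, coupling set lc = lam.
// Restraint force constants are supplied per lambda value by the caller, so
// any restraint schedule can be used. Periodic systems use the minimum
// image convention in an orthorhombic box.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double RCUT = 10.0, RON = 6.0;

struct Restraint {
  int kind;                 // 0 atom-atom, 1 centroid-centroid
  std::vector<int> i, j;    // 0-based member indices
  double r0;
};

static inline double switchFn(double r2) {
  const double ron2 = RON * RON, rcut2 = RCUT * RCUT;
  if (r2 <= ron2) return 1.0;
  if (r2 >= rcut2) return 0.0;
  double a = rcut2 - r2;
  double denom = (rcut2 - ron2);
  return a * a * (rcut2 + 2.0 * r2 - 3.0 * ron2) / (denom * denom * denom);
}

static inline double ljKernel(double r2eff, double eps, double rmin) {
  double s = rmin * rmin / r2eff;
  double s3 = s * s * s;
  return eps * (s3 * s3 - 2.0 * s3);
}

static inline double minImage(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

static inline double dist2(const NumericMatrix& pos, int i, int j,
                           const NumericVector& box) {
  double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
         dz = pos(i, 2) - pos(j, 2);
  if (box.size() == 3) {
    dx = minImage(dx, box[0]); dy = minImage(dy, box[1]);
    dz = minImage(dz, box[2]);
  }
  return dx * dx + dy * dy + dz * dz;
}

// coupling strength of the pair (i, j); returns -1 for excluded pairs
static inline double pairLambda(int ri, int rj, double lam) {
  if (ri == 0 && rj == 0) return 1.0;
  if (ri == rj) return 1.0;                 // intra-set stays coupled
  if (ri != 0 && rj != 0) return -1.0;      // decouple x couple: excluded
  int r = ri != 0 ? ri : rj;
  return r == 1 ? 1.0 - lam : lam;
}

static inline double pairEnergy(const NumericMatrix& pos, int i, int j,
                                const NumericVector& eps,
                                const NumericVector& rmin,
                                const IntegerVector& role,
                                const NumericVector& box,
                                double lam, double shift) {
  double lc = pairLambda(role[i], role[j], lam);
  if (lc < 0.0 || lc == 0.0) return 0.0;
  double e = std::sqrt(eps[i] * eps[j]);
  if (e == 0.0) return 0.0;
  double rm = 0.5 * (rmin[i] + rmin[j]);
  double r2 = dist2(pos, i, j, box);
  if (r2 >= RCUT * RCUT) return 0.0;
  double sw = switchFn(r2);
  if (lc >= 1.0) return ljKernel(r2, e, rm) * sw;
  return lc * ljKernel(r2 + shift * (1.0 - lc), e, rm) * sw;
}

static std::vector<Restraint> parseRestraints(const List& rl) {
  std::vector<Restraint> out;
  for (int k = 0; k < rl.size(); ++k) {
    List r = rl[k];
    Restraint rr;
    rr.kind = as<int>(r["kind"]);
    IntegerVector ii = r["i"], jj = r["j"];
    for (int q = 0; q < ii.size(); ++q) rr.i.push_back(ii[q] - 1);
    for (int q = 0; q < jj.size(); ++q) rr.j.push_back(jj[q] - 1);
    rr.r0 = as<double>(r["r0"]);
    out.push_back(rr);
  }
  return out;
}

// distance of a restraint (centroid distances are non-periodic: restrained
// groups are expected to stay together)
static inline double restraintDist(const NumericMatrix& pos,
                                   const Restraint& r,
                                   const NumericVector& box) {
  double ci[3] = {0, 0, 0}, cj[3] = {0, 0, 0};
  for (size_t q = 0; q < r.i.size(); ++q)
    for (int d = 0; d < 3; ++d) ci[d] += pos(r.i[q], d);
  for (size_t q = 0; q < r.j.size(); ++q)
    for (int d = 0; d < 3; ++d) cj[d] += pos(r.j[q], d);
  double dx[3];
  for (int d = 0; d < 3; ++d)
    dx[d] = ci[d] / r.i.size() - cj[d] / r.j.size();
  if (r.i.size() == 1 && r.j.size() == 1 && box.size() == 3)
    for (int d = 0; d < 3; ++d) dx[d] = minImage(dx[d], box[d]);
  return std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
}

static double totalEnergy(const NumericMatrix& pos, const NumericVector& eps,
                          const NumericVector& rmin, const IntegerVector& role,
                          const IntegerVector& bi, const IntegerVector& bj,
                          const NumericVector& bk, const NumericVector& br0,
                          const std::vector<Restraint>& rest,
                          const NumericVector& kres,
                          const NumericVector& box, double lam, double shift,
                          double* comp) {
  int n = pos.nrow();
  double vdw = 0.0, bonded = 0.0, restr = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      vdw += pairEnergy(pos, i, j, eps, rmin, role, box, lam, shift);
  for (int b = 0; b < bi.size(); ++b) {
    double r = std::sqrt(dist2(pos, bi[b] - 1, bj[b] - 1, box));
    double d = r - br0[b];
    bonded += 0.5 * bk[b] * d * d;
  }
  for (size_t q = 0; q < rest.size(); ++q) {
    if (kres[q] == 0.0) continue;
    double d = restraintDist(pos, rest[q], box) - rest[q].r0;
    restr += 0.5 * kres[q] * d * d;
  }
  if (comp) { comp[0] = vdw; comp[1] = bonded; comp[2] = restr; }
  return vdw + bonded + restr;
}

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix pos, NumericVector eps,
                         NumericVector rmin, IntegerVector role,
                         IntegerVector bi, IntegerVector bj,
                         NumericVector bk, NumericVector br0,
                         List restraints, NumericVector kres,
                         NumericVector box, double lam, double shift) {
  std::vector<Restraint> rest = parseRestraints(restraints);
  double comp[3];
  double tot = totalEnergy(pos, eps, rmin, role, bi, bj, bk, br0, rest,
                           kres, box, lam, shift, comp);
  return NumericVector::create(_["vdw"] = comp[0], _["bonded"] = comp[1],
                               _["restraint"] = comp[2], _["total"] = tot);
}

// energy terms involving particle p only (for Metropolis moves)
static double localEnergy(const NumericMatrix& pos, int p,
                          const NumericVector& eps, const NumericVector& rmin,
                          const IntegerVector& role,
                          const IntegerVector& bi, const IntegerVector& bj,
                          const NumericVector& bk, const NumericVector& br0,
                          const std::vector<Restraint>& rest,
                          const NumericVector& kres,
                          const NumericVector& box, double lam, double shift) {
  int n = pos.nrow();
  double e = 0.0;
  for (int j = 0; j < n; ++j)
    if (j != p) e += pairEnergy(pos, p, j, eps, rmin, role, box, lam, shift);
  for (int b = 0; b < bi.size(); ++b)
    if (bi[b] - 1 == p || bj[b] - 1 == p) {
      double r = std::sqrt(dist2(pos, bi[b] - 1, bj[b] - 1, box));
      double d = r - br0[b];
      e += 0.5 * bk[b] * d * d;
    }
  for (size_t q = 0; q < rest.size(); ++q) {
    if (kres[q] == 0.0) continue;
    bool inv = false;
    for (size_t t = 0; t < rest[q].i.size() && !inv; ++t)
      if (rest[q].i[t] == p) inv = true;
    for (size_t t = 0; t < rest[q].j.size() && !inv; ++t)
      if (rest[q].j[t] == p) inv = true;
    if (!inv) continue;
    double d = restraintDist(pos, rest[q], box) - rest[q].r0;
    e += 0.5 * kres[q] * d * d;
  }
  return e;
}

// [[Rcpp::export]]
List cpp_mc(NumericMatrix posIn, NumericVector eps, NumericVector rmin,
            IntegerVector role, LogicalVector fixed,
            IntegerVector bi, IntegerVector bj,
            NumericVector bk, NumericVector br0,
            List restraints, NumericVector kcur, NumericVector kprev,
            NumericVector knext, NumericVector box,
            double lam, double lamPrev, double lamNext,
            int nsweeps, int sampleEvery, double stepSize, double beta,
            double shift, int trackI, int trackJ, int track2I, int track2J) {
  NumericMatrix pos = clone(posIn);
  std::vector<Restraint> rest = parseRestraints(restraints);
  int n = pos.nrow();
  std::vector<int> movable;
  for (int i = 0; i < n; ++i) if (!fixed[i]) movable.push_back(i);
  if (movable.empty()) stop("no movable particles");

  int nsamp = nsweeps / sampleEvery;
  NumericMatrix samples(nsamp, 9);
  colnames(samples) = CharacterVector::create("sweep", "total", "vdw",
      "bonded", "restraint", "dU_prev", "dU_next", "dist", "dist2");
  long accepted = 0, attempted = 0;
  int srow = 0;
  bool hasPrev = R_finite(lamPrev), hasNext = R_finite(lamNext);

  for (int sw = 1; sw <= nsweeps; ++sw) {
    for (size_t m = 0; m < movable.size(); ++m) {
      int p = movable[m];
      double old0 = pos(p, 0), old1 = pos(p, 1), old2 = pos(p, 2);
      double e0 = localEnergy(pos, p, eps, rmin, role, bi, bj, bk, br0,
                              rest, kcur, box, lam, shift);
      pos(p, 0) = old0 + stepSize * (2.0 * unif_rand() - 1.0);
      pos(p, 1) = old1 + stepSize * (2.0 * unif_rand() - 1.0);
      pos(p, 2) = old2 + stepSize * (2.0 * unif_rand() - 1.0);
      if (box.size() == 3)
        for (int d = 0; d < 3; ++d)
          pos(p, d) -= box[d] * std::floor(pos(p, d) / box[d]);
      double e1 = localEnergy(pos, p, eps, rmin, role, bi, bj, bk, br0,
                              rest, kcur, box, lam, shift);
      ++attempted;
      if (e1 <= e0 || unif_rand() < std::exp(-beta * (e1 - e0))) {
        ++accepted;
      } else {
        pos(p, 0) = old0; pos(p, 1) = old1; pos(p, 2) = old2;
      }
    }
    if (sw % sampleEvery == 0 && srow < nsamp) {
      double comp[3];
      double u = totalEnergy(pos, eps, rmin, role, bi, bj, bk, br0, rest,
                             kcur, box, lam, shift, comp);
      samples(srow, 0) = sw;
      samples(srow, 1) = u;
      samples(srow, 2) = comp[0];
      samples(srow, 3) = comp[1];
      samples(srow, 4) = comp[2];
      samples(srow, 5) = hasPrev
        ? totalEnergy(pos, eps, rmin, role, bi, bj, bk, br0, rest, kprev,
                      box, lamPrev, shift, nullptr) - u
        : NA_REAL;
      samples(srow, 6) = hasNext
        ? totalEnergy(pos, eps, rmin, role, bi, bj, bk, br0, rest, knext,
                      box, lamNext, shift, nullptr) - u
        : NA_REAL;
      samples(srow, 7) = (trackI > 0 && trackJ > 0)
        ? std::sqrt(dist2(pos, trackI - 1, trackJ - 1, box)) : NA_REAL;
      samples(srow, 8) = (track2I > 0 && track2J > 0)
        ? std::sqrt(dist2(pos, track2I - 1, track2J - 1, box)) : NA_REAL;
      ++srow;
    }
  }
  return List::create(_["samples"] = samples,
                      _["acceptance"] = double(accepted) / double(attempted),
                      _["positions"] = pos);
}
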