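// Deterministic tensor streamline tracking and tensor-field sampling.
// Tensor volumes are (nx, ny, nz, 6) arrays in lower-triangular order
// (dxx, dxy, dyy, dxz, dyz, dzz), components expressed in world axes.
// Interpolation is component-wise cubic (Catmull-Rom) on the 6 unique
// elements; eigen-decomposition happens after interpolation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Vol {
  const double *d;
  int nx, ny, nz;
  inline double at(int i, int j, int k, int c) const {
    return d[i + (size_t)nx * (j + (size_t)ny * (k + (size_t)nz * c))];
  }
};

inline void crWeights(double t, double *w) {
  // Catmull-Rom cubic convolution weights for offsets -1, 0, 1, 2
  double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t3 + 2 * t2 - t);
  w[1] = 0.5 * (3 * t3 - 5 * t2 + 2);
  w[2] = 0.5 * (-3 * t3 + 4 * t2 + t);
  w[3] = 0.5 * (t3 - t2);
}

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// cubic interpolation of the 6 tensor components at voxel coordinates p
// (0-based, continuous); returns false if p is outside the grid
bool interpTensor(const Vol &v, const double *p, double *out) {
  for (int a = 0; a < 3; ++a) {
    double n = (a == 0 ? v.nx : (a == 1 ? v.ny : v.nz));
    if (p[a] < 0 || p[a] > n - 1) return false;
  }
  int bx = (int)std::floor(p[0]), by = (int)std::floor(p[1]),
      bz = (int)std::floor(p[2]);
  double wx[4], wy[4], wz[4];
  crWeights(p[0] - bx, wx);
  crWeights(p[1] - by, wy);
  crWeights(p[2] - bz, wz);
  int ix[4], iy[4], iz[4];
  for (int s = 0; s < 4; ++s) {
    ix[s] = clampi(bx - 1 + s, 0, v.nx - 1);
    iy[s] = clampi(by - 1 + s, 0, v.ny - 1);
    iz[s] = clampi(bz - 1 + s, 0, v.nz - 1);
  }
  for (int c = 0; c < 6; ++c) out[c] = 0.0;
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 4; ++j) {
      double wjk = wy[j] * wz[k];
      if (wjk == 0.0) continue;
      for (int i = 0; i < 4; ++i) {
        double w = wx[i] * wjk;
        if (w == 0.0) continue;
        for (int c = 0; c < 6; ++c) out[c] += w * v.at(ix[i], iy[j], iz[k], c);
      }
    }
  return true;
}

inline void eigSym(const double *t6, arma::vec &eval, arma::mat &evec) {
  arma::mat33 D;
  D(0, 0) = t6[0]; D(0, 1) = t6[1]; D(1, 1) = t6[2];
  D(0, 2) = t6[3]; D(1, 2) = t6[4]; D(2, 2) = t6[5];
  D(1, 0) = D(0, 1); D(2, 0) = D(0, 2); D(2, 1) = D(1, 2);
  arma::eig_sym(eval, evec, D);  // ascending eigenvalues
}

inline double faFromEvals(const arma::vec &ev) {
  double md = (ev(0) + ev(1) + ev(2)) / 3.0;
  double num = (ev(0) - md) * (ev(0) - md) + (ev(1) - md) * (ev(1) - md) +
               (ev(2) - md) * (ev(2) - md);
  double den = ev(0) * ev(0) + ev(1) * ev(1) + ev(2) * ev(2);
  if (den <= 0) return NA_REAL;
  return std::sqrt(1.5 * num / den);
}

struct Affine {
  arma::mat44 A, Ainv;
};

Affine makeAffine(const NumericMatrix &aff) {
  Affine a;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) a.A(i, j) = aff(i, j);
  a.Ainv = arma::inv(a.A);
  return a;
}

inline void worldToVox(const Affine &a, const double *w, double *p) {
  for (int i = 0; i < 3; ++i)
    p[i] = a.Ainv(i, 0) * w[0] + a.Ainv(i, 1) * w[1] + a.Ainv(i, 2) * w[2] +
           a.Ainv(i, 3);
}

// one propagation branch from seed along initial direction dir0
std::vector<arma::vec3> trackBranch(const Vol &v, const Affine &aff,
                                    const arma::vec3 &seed,
                                    const arma::vec3 &dir0, double faThresh,
                                    double cosMax, double step, int maxSteps) {
  std::vector<arma::vec3> pts;
  arma::vec3 cur = seed, dir = dir0;
  double t6[6], p[3];
  arma::vec eval;
  arma::mat evec;
  for (int s = 0; s < maxSteps; ++s) {
    arma::vec3 cand = cur + step * dir;
    double w[3] = {cand(0), cand(1), cand(2)};
    worldToVox(aff, w, p);
    if (!interpTensor(v, p, t6)) break;           // left the volume
    eigSym(t6, eval, evec);
    double fa = faFromEvals(eval);
    if (!(fa >= faThresh)) break;                 // FA stop (or undefined)
    arma::vec3 e1 = evec.col(2);                  // principal eigenvector
    if (arma::dot(e1, dir) < 0) e1 = -e1;         // sign continuity
    if (arma::dot(e1, dir) < cosMax) break;       // angle stop
    cur = cand;
    dir = e1;
    pts.push_back(cur);
  }
  return pts;
}

}  // namespace

// [[Rcpp::export(name = ".faVolume")]]
NumericVector faVolume(NumericVector data) {
  IntegerVector dm = data.attr("dim");
  if (dm.size() != 4 || dm[3] != 6) stop("expected (nx, ny, nz, 6) array");
  Vol v{REAL(data), dm[0], dm[1], dm[2]};
  size_t n = (size_t)dm[0] * dm[1] * dm[2];
  NumericVector out(n);
  arma::vec eval;
  arma::mat evec;
  double t6[6];
  size_t plane = n;
  for (size_t idx = 0; idx < n; ++idx) {
    for (int c = 0; c < 6; ++c) t6[c] = data[idx + plane * c];
    eigSym(t6, eval, evec);
    double den = eval(0) * eval(0) + eval(1) * eval(1) + eval(2) * eval(2);
    out[idx] = den <= 0 ? NA_REAL : faFromEvals(eval);
  }
  out.attr("dim") = IntegerVector::create(dm[0], dm[1], dm[2]);
  return out;
}

// [[Rcpp::export(name = ".trackStreamlines")]]
List trackStreamlines(NumericVector data, NumericMatrix affineMat,
                      NumericMatrix seedsVox, double faThresh,
                      double angleMaxDeg, double stepMm, double minLenMm,
                      int maxSteps) {
  IntegerVector dm = data.attr("dim");
  Vol v{REAL(data), dm[0], dm[1], dm[2]};
  Affine aff = makeAffine(affineMat);
  double cosMax = std::cos(angleMaxDeg * M_PI / 180.0);
  List out;
  arma::vec eval;
  arma::mat evec;
  double t6[6], p[3];
  for (int s = 0; s < seedsVox.nrow(); ++s) {
    // seed at the voxel centre, in world mm
    arma::vec4 vx = {seedsVox(s, 0), seedsVox(s, 1), seedsVox(s, 2), 1.0};
    arma::vec4 wd = aff.A * vx;
    arma::vec3 seed = {wd(0), wd(1), wd(2)};
    double w[3] = {seed(0), seed(1), seed(2)};
    worldToVox(aff, w, p);
    if (!interpTensor(v, p, t6)) continue;
    eigSym(t6, eval, evec);
    if (!(faFromEvals(eval) >= faThresh)) continue;
    arma::vec3 e1 = evec.col(2);
    std::vector<arma::vec3> fwd =
        trackBranch(v, aff, seed, e1, faThresh, cosMax, stepMm, maxSteps);
    std::vector<arma::vec3> bwd =
        trackBranch(v, aff, seed, -e1, faThresh, cosMax, stepMm, maxSteps);
    int np = (int)(fwd.size() + bwd.size()) + 1;
    double len = stepMm * (np - 1);
    if (len < minLenMm) continue;
    NumericMatrix m(np, 3);
    int r = 0;
    for (int i = (int)bwd.size() - 1; i >= 0; --i, ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = bwd[i](c);
    for (int c = 0; c < 3; ++c) m(r, c) = seed(c);
    ++r;
    for (size_t i = 0; i < fwd.size(); ++i, ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = fwd[i](c);
    out.push_back(m);
  }
  return out;
}

// [[Rcpp::export(name = ".sampleTensorMetrics")]]
NumericMatrix sampleTensorMetrics(NumericMatrix pointsWorld, NumericVector data,
                                  NumericMatrix affineMat) {
  IntegerVector dm = data.attr("dim");
  Vol v{REAL(data), dm[0], dm[1], dm[2]};
  Affine aff = makeAffine(affineMat);
  int n = pointsWorld.nrow();
  NumericMatrix out(n, 4);  // fa, md, ad, rd
  arma::vec eval;
  arma::mat evec;
  double t6[6], p[3];
  for (int i = 0; i < n; ++i) {
    double w[3] = {pointsWorld(i, 0), pointsWorld(i, 1), pointsWorld(i, 2)};
    worldToVox(aff, w, p);
    if (!interpTensor(v, p, t6)) {
      out(i, 0) = out(i, 1) = out(i, 2) = out(i, 3) = NA_REAL;
      continue;
    }
    eigSym(t6, eval, evec);
    double md = (eval(0) + eval(1) + eval(2)) / 3.0;
    out(i, 0) = faFromEvals(eval);
    out(i, 1) = md;
    out(i, 2) = eval(2);                  // axial = largest eigenvalue
    out(i, 3) = (eval(0) + eval(1)) / 2;  // radial = mean of the two smallest
  }
  colnames(out) = CharacterVector::create("fa", "md", "ad", "rd");
  return out;
}
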