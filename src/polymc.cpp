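// Geometry kernels: GJK convex distance, cuboid bounds/collision checks,
// neighbour queries and initial box packing.  All randomness is drawn from
// R's RNG stream (unif_rand/norm_rand) so set.seed() governs everything.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(V3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double nrm2(V3 a) { return dot(a, a); }

// quaternion (w,x,y,z) to rotation matrix, row-major R[3][3]
static void quat_to_mat(const double q[4], double R[3][3]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

static inline V3 matvec(const double R[3][3], V3 v) {
  return v3(R[0][0] * v.x + R[0][1] * v.y + R[0][2] * v.z,
            R[1][0] * v.x + R[1][1] * v.y + R[1][2] * v.z,
            R[2][0] * v.x + R[2][1] * v.y + R[2][2] * v.z);
}

// Hamilton product
static inline void qmul(const double a[4], const double b[4], double out[4]) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

// ---------------------------------------------------------------------------
// GJK distance between convex hulls of two point sets
// ---------------------------------------------------------------------------

static inline V3 supportSet(const std::vector<V3>& P, V3 d) {
  int best = 0; double bd = dot(P[0], d);
  for (size_t k = 1; k < P.size(); ++k) {
    double dk = dot(P[k], d);
    if (dk > bd) { bd = dk; best = (int)k; }
  }
  return P[best];
}

// support of Minkowski difference A - B in direction d
static inline V3 supportMink(const std::vector<V3>& A, const std::vector<V3>& B, V3 d) {
  return supportSet(A, d) - supportSet(B, v3(-d.x, -d.y, -d.z));
}

// closest point to origin on segment ab; keep mask bit1=a bit2=b
static V3 closestSegment(V3 a, V3 b, int& keep) {
  V3 ab = b - a;
  double denom = dot(ab, ab);
  if (denom < 1e-300) { keep = 1; return a; }
  double t = -dot(a, ab) / denom;
  if (t <= 0) { keep = 1; return a; }
  if (t >= 1) { keep = 2; return b; }
  keep = 3; return a + ab * t;
}

// closest point to origin on triangle abc; keep mask bit1=a bit2=b bit4=c
static V3 closestTriangle(V3 a, V3 b, V3 c, int& keep) {
  V3 ab = b - a, ac = c - a, ap = v3(0, 0, 0) - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { keep = 1; return a; }
  V3 bp = v3(0, 0, 0) - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { keep = 2; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = (d1 - d3) != 0 ? d1 / (d1 - d3) : 0.0;
    keep = 3; return a + ab * t;
  }
  V3 cp = v3(0, 0, 0) - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { keep = 4; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = (d2 - d6) != 0 ? d2 / (d2 - d6) : 0.0;
    keep = 5; return a + ac * t;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double s = (d4 - d3) + (d5 - d6);
    double t = s != 0 ? (d4 - d3) / s : 0.0;
    keep = 6; return b + (c - b) * t;
  }
  double s = va + vb + vc;
  if (fabs(s) < 1e-300) { // degenerate (collinear): best of the three edges
    int k1, k2, k3;
    V3 p1 = closestSegment(a, b, k1), p2 = closestSegment(a, c, k2), p3 = closestSegment(b, c, k3);
    double n1 = nrm2(p1), n2 = nrm2(p2), n3 = nrm2(p3);
    if (n1 <= n2 && n1 <= n3) { keep = (k1 == 1 ? 1 : (k1 == 2 ? 2 : 3)); return p1; }
    if (n2 <= n3) { keep = (k2 == 1 ? 1 : (k2 == 2 ? 4 : 5)); return p2; }
    keep = (k3 == 1 ? 2 : (k3 == 2 ? 4 : 6)); return p3;
  }
  double denom = 1.0 / s;
  double v = vb * denom, w = vc * denom;
  keep = 7; return a + ab * v + ac * w;
}

static V3 closestTetra(V3* W, int& n, bool& inside) {
  V3 a = W[0], b = W[1], c = W[2], d = W[3];
  // origin outside face (p,q,r) if it lies on the opposite side from opp
  bool degen = false;
  int o[4];
  {
    V3 P[4][4] = { {a, b, c, d}, {a, b, d, c}, {a, c, d, b}, {b, c, d, a} };
    for (int f = 0; f < 4; ++f) {
      V3 nrm = cross(P[f][1] - P[f][0], P[f][2] - P[f][0]);
      double sP = dot(nrm, v3(0, 0, 0) - P[f][0]);
      double sO = dot(nrm, P[f][3] - P[f][0]);
      if (fabs(sO) < 1e-300) { degen = true; o[f] = 1; }
      else o[f] = (sP * sO < 0) ? 1 : 0;
    }
  }
  if (!degen && !o[0] && !o[1] && !o[2] && !o[3]) {
    inside = true; n = 4; return v3(0, 0, 0);
  }
  double bestD = R_PosInf; V3 bestP = a; V3 keepPts[3]; int keepN = 1; keepPts[0] = a;
  int faceIdx[4][3] = { {0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3} };
  for (int f = 0; f < 4; ++f) {
    if (!degen && !o[f]) continue;
    V3 p = W[faceIdx[f][0]], q = W[faceIdx[f][1]], r = W[faceIdx[f][2]];
    int k; V3 cp = closestTriangle(p, q, r, k);
    double dd = nrm2(cp);
    if (dd < bestD) {
      bestD = dd; bestP = cp; keepN = 0;
      if (k & 1) keepPts[keepN++] = p;
      if (k & 2) keepPts[keepN++] = q;
      if (k & 4) keepPts[keepN++] = r;
    }
  }
  for (int k = 0; k < keepN; ++k) W[k] = keepPts[k];
  n = keepN;
  return bestP;
}

static V3 closestOnSimplex(V3* W, int& n, bool& inside) {
  inside = false;
  if (n == 1) return W[0];
  if (n == 2) {
    int k; V3 a = W[0], b = W[1];
    V3 p = closestSegment(a, b, k);
    n = 0; if (k & 1) W[n++] = a; if (k & 2) W[n++] = b;
    return p;
  }
  if (n == 3) {
    int k; V3 a = W[0], b = W[1], c = W[2];
    V3 p = closestTriangle(a, b, c, k);
    n = 0; if (k & 1) W[n++] = a; if (k & 2) W[n++] = b; if (k & 4) W[n++] = c;
    return p;
  }
  return closestTetra(W, n, inside);
}

static double gjk_core(const std::vector<V3>& A, const std::vector<V3>& B,
                       double tol, int maxit) {
  V3 W[4]; int n = 0;
  V3 v = A[0] - B[0];
  double tol2 = tol * tol;
  for (int it = 0; it < maxit; ++it) {
    double vn2 = nrm2(v);
    if (vn2 < tol2) return 0.0;
    V3 w = supportMink(A, B, v3(-v.x, -v.y, -v.z));
    double vw = dot(v, w);
    if (vn2 - vw <= 1e-12 * vn2) return sqrt(vn2);
    bool dup = false;
    for (int k = 0; k < n; ++k) if (nrm2(w - W[k]) < 1e-24) { dup = true; break; }
    if (dup) return sqrt(vn2);
    W[n++] = w;
    bool inside = false;
    v = closestOnSimplex(W, n, inside);
    if (inside) return 0.0;
  }
  return sqrt(nrm2(v));
}

// [[Rcpp::export]]
double cpp_gjk_vertices(NumericMatrix A, NumericMatrix B,
                        double tol = 1e-10, int maxit = 64) {
  std::vector<V3> pa(A.nrow()), pb(B.nrow());
  for (int i = 0; i < A.nrow(); ++i) pa[i] = v3(A(i, 0), A(i, 1), A(i, 2));
  for (int i = 0; i < B.nrow(); ++i) pb[i] = v3(B(i, 0), B(i, 1), B(i, 2));
  return gjk_core(pa, pb, tol, maxit);
}

// ---------------------------------------------------------------------------
// bead helpers (pos n x 3, quat n x 4 (w,x,y,z), half n x 3; column-major)
// ---------------------------------------------------------------------------

static void beadVerts(const NumericMatrix& pos, const NumericMatrix& quat,
                      const NumericMatrix& half, int i, std::vector<V3>& out) {
  double q[4] = { quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3) };
  double R[3][3]; quat_to_mat(q, R);
  V3 c = v3(pos(i, 0), pos(i, 1), pos(i, 2));
  double h[3] = { half(i, 0), half(i, 1), half(i, 2) };
  out.resize(8);
  int k = 0;
  for (int sx = -1; sx <= 1; sx += 2)
    for (int sy = -1; sy <= 1; sy += 2)
      for (int sz = -1; sz <= 1; sz += 2)
        out[k++] = c + matvec(R, v3(sx * h[0], sy * h[1], sz * h[2]));
}

// axis-aligned extent of oriented cuboid i along axis k: sum_j |R[k][j]| h_j
static void beadExtents(const NumericMatrix& pos, const NumericMatrix& quat,
                        const NumericMatrix& half, int i,
                        double lo[3], double hi[3]) {
  double q[4] = { quat(i, 0), quat(i, 1), quat(i, 2), quat(i, 3) };
  double R[3][3]; quat_to_mat(q, R);
  for (int k = 0; k < 3; ++k) {
    double e = fabs(R[k][0]) * half(i, 0) + fabs(R[k][1]) * half(i, 1) +
               fabs(R[k][2]) * half(i, 2);
    lo[k] = pos(i, k) - e;
    hi[k] = pos(i, k) + e;
  }
}

// [[Rcpp::export]]
double cpp_gjk_beads(NumericMatrix pos, NumericMatrix quat, NumericMatrix half,
                     int i, int j, double tol = 1e-10) {
  std::vector<V3> a, b;
  beadVerts(pos, quat, half, i - 1, a);
  beadVerts(pos, quat, half, j - 1, b);
  return gjk_core(a, b, tol, 64);
}

// beads among idx (1-based) with any vertex outside [0, edge]
// [[Rcpp::export]]
IntegerVector cpp_bounds_violations(NumericMatrix pos, NumericMatrix quat,
                                    NumericMatrix half, NumericVector edge,
                                    IntegerVector idx) {
  std::vector<int> bad;
  double lo[3], hi[3];
  for (int t = 0; t < idx.size(); ++t) {
    int i = idx[t] - 1;
    beadExtents(pos, quat, half, i, lo, hi);
    for (int k = 0; k < 3; ++k) {
      if (lo[k] < -1e-9 || hi[k] > edge[k] + 1e-9) { bad.push_back(idx[t]); break; }
    }
  }
  return wrap(bad);
}

// nearest bead (1-based) to point within radius; 0 if none.
// exclude_pid > 0 restricts to beads of other polymers.
// [[Rcpp::export]]
int cpp_nearest_bead(NumericMatrix pos, NumericVector point, double radius,
                     IntegerVector polymer_id, int exclude_pid = -1) {
  int n = pos.nrow(), best = -1;
  double bd = radius * radius;
  for (int i = 0; i < n; ++i) {
    if (exclude_pid > 0 && polymer_id[i] == exclude_pid) continue;
    double dx = pos(i, 0) - point[0], dy = pos(i, 1) - point[1], dz = pos(i, 2) - point[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 <= bd) { bd = d2; best = i; }
  }
  return best < 0 ? 0 : best + 1;
}

static inline long long pairKey(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (long long)lo * (long long)n + hi;
}

// feasibility of beads idx (1-based) against the whole box: bounds + collisions
// against all non-bonded beads (intra-idx pairs counted once).
// Returns list(oob = bead ids, pairs = k x 2 colliding bead ids).
// [[Rcpp::export]]
List cpp_check_moved(NumericMatrix pos, NumericMatrix quat, NumericMatrix half,
                     IntegerVector idx, IntegerMatrix bonds, NumericVector edge,
                     double contact_tol = 1e-9, bool first_only = true) {
  int n = pos.nrow();
  IntegerVector oob = cpp_bounds_violations(pos, quat, half, edge, idx);
  std::vector<std::pair<int, int> > hits;
  if (!(first_only && oob.size() > 0)) {
    std::unordered_set<long long> bonded;
    for (int r = 0; r < bonds.nrow(); ++r)
      bonded.insert(pairKey(bonds(r, 0) - 1, bonds(r, 1) - 1, n));
    std::vector<char> inIdx(n, 0);
    for (int t = 0; t < idx.size(); ++t) inIdx[idx[t] - 1] = 1;
    std::vector<double> rad(n);
    for (int i = 0; i < n; ++i)
      rad[i] = sqrt(half(i, 0) * half(i, 0) + half(i, 1) * half(i, 1) +
                    half(i, 2) * half(i, 2));
    std::vector<V3> va, vb;
    bool done = false;
    for (int t = 0; t < idx.size() && !done; ++t) {
      int i = idx[t] - 1;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        if (inIdx[j] && j < i) continue; // intra pair handled once
        double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
               dz = pos(i, 2) - pos(j, 2);
        double cut = rad[i] + rad[j] + contact_tol;
        if (dx * dx + dy * dy + dz * dz >= cut * cut) continue;
        if (bonded.count(pairKey(i, j, n))) continue;
        beadVerts(pos, quat, half, i, va);
        beadVerts(pos, quat, half, j, vb);
        if (gjk_core(va, vb, 1e-10, 64) < contact_tol) {
          hits.push_back(std::make_pair(i + 1, j + 1));
          if (first_only) { done = true; break; }
        }
      }
    }
  }
  IntegerMatrix pairs(hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    pairs(k, 0) = hits[k].first; pairs(k, 1) = hits[k].second;
  }
  return List::create(_["oob"] = oob, _["pairs"] = pairs);
}

// lean per-step feasibility: 0 ok, 1 out of bounds, 2 collision.
// bonds are scanned linearly only for pairs passing the broad phase.
// [[Rcpp::export]]
int cpp_feasible(NumericMatrix pos, NumericMatrix quat, NumericMatrix half,
                 IntegerVector idx, IntegerMatrix bonds, NumericVector edge,
                 double contact_tol = 1e-9) {
  int n = pos.nrow(), m = bonds.nrow(), nidx = idx.size();
  double lo[3], hi[3];
  for (int t = 0; t < nidx; ++t) {
    int i = idx[t] - 1;
    beadExtents(pos, quat, half, i, lo, hi);
    for (int k = 0; k < 3; ++k)
      if (lo[k] < -1e-9 || hi[k] > edge[k] + 1e-9) return 1;
  }
  std::vector<char> inIdx(n, 0);
  for (int t = 0; t < nidx; ++t) inIdx[idx[t] - 1] = 1;
  std::vector<double> rad(n);
  for (int j = 0; j < n; ++j)
    rad[j] = sqrt(half(j, 0) * half(j, 0) + half(j, 1) * half(j, 1) +
                  half(j, 2) * half(j, 2));
  std::vector<V3> va, vb;
  for (int t = 0; t < nidx; ++t) {
    int i = idx[t] - 1;
    double ri = rad[i];
    double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (inIdx[j] && j < i) continue;
      double dx = xi - pos(j, 0), dy = yi - pos(j, 1), dz = zi - pos(j, 2);
      double cut = ri + rad[j] + contact_tol;
      if (dx * dx + dy * dy + dz * dz >= cut * cut) continue;
      bool isBonded = false;
      int i1 = i + 1, j1 = j + 1;
      for (int r = 0; r < m; ++r) {
        if ((bonds(r, 0) == i1 && bonds(r, 1) == j1) ||
            (bonds(r, 0) == j1 && bonds(r, 1) == i1)) { isBonded = true; break; }
      }
      if (isBonded) continue;
      beadVerts(pos, quat, half, i, va);
      beadVerts(pos, quat, half, j, vb);
      if (gjk_core(va, vb, 1e-10, 64) < contact_tol) return 2;
    }
  }
  return 0;
}

// ---------------------------------------------------------------------------
// uniform cell grid for all-pairs collision scan and packing
// ---------------------------------------------------------------------------

struct CellGrid {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;
  long long key(double x, double y, double z) const {
    long long ix = (long long)floor(x / cell) + 2048;
    long long iy = (long long)floor(y / cell) + 2048;
    long long iz = (long long)floor(z / cell) + 2048;
    return ix + 4096LL * (iy + 4096LL * iz);
  }
  void insert(int i, double x, double y, double z) { cells[key(x, y, z)].push_back(i); }
  template <class F>
  void forNeighbours(double x, double y, double z, F f) const {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          long long k = key(x + dx * cell, y + dy * cell, z + dz * cell);
          std::unordered_map<long long, std::vector<int> >::const_iterator it = cells.find(k);
          if (it == cells.end()) continue;
          for (size_t t = 0; t < it->second.size(); ++t) f(it->second[t]);
        }
  }
};

// all-pairs validation: bounds violations plus colliding non-bonded pairs
// [[Rcpp::export]]
List cpp_validate_collisions(NumericMatrix pos, NumericMatrix quat,
                             NumericMatrix half, IntegerMatrix bonds,
                             NumericVector edge, double contact_tol = 1e-9) {
  int n = pos.nrow();
  IntegerVector all(n);
  for (int i = 0; i < n; ++i) all[i] = i + 1;
  IntegerVector oob = cpp_bounds_violations(pos, quat, half, edge, all);
  std::unordered_set<long long> bonded;
  for (int r = 0; r < bonds.nrow(); ++r)
    bonded.insert(pairKey(bonds(r, 0) - 1, bonds(r, 1) - 1, n));
  std::vector<double> rad(n);
  double maxrad = 0;
  for (int i = 0; i < n; ++i) {
    rad[i] = sqrt(half(i, 0) * half(i, 0) + half(i, 1) * half(i, 1) +
                  half(i, 2) * half(i, 2));
    if (rad[i] > maxrad) maxrad = rad[i];
  }
  CellGrid grid;
  grid.cell = std::max(2.0 * maxrad + contact_tol, 0.5);
  for (int i = 0; i < n; ++i) grid.insert(i, pos(i, 0), pos(i, 1), pos(i, 2));
  std::vector<std::pair<int, int> > hits;
  std::vector<V3> va, vb;
  for (int i = 0; i < n; ++i) {
    std::vector<int> cand;
    grid.forNeighbours(pos(i, 0), pos(i, 1), pos(i, 2),
                       [&](int j) { if (j > i) cand.push_back(j); });
    for (size_t t = 0; t < cand.size(); ++t) {
      int j = cand[t];
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      double cut = rad[i] + rad[j] + contact_tol;
      if (dx * dx + dy * dy + dz * dz >= cut * cut) continue;
      if (bonded.count(pairKey(i, j, n))) continue;
      beadVerts(pos, quat, half, i, va);
      beadVerts(pos, quat, half, j, vb);
      if (gjk_core(va, vb, 1e-10, 64) < contact_tol)
        hits.push_back(std::make_pair(i + 1, j + 1));
    }
  }
  IntegerMatrix pairs(hits.size(), 2);
  for (size_t k = 0; k < hits.size(); ++k) {
    pairs(k, 0) = hits[k].first; pairs(k, 1) = hits[k].second;
  }
  return List::create(_["oob"] = oob, _["pairs"] = pairs);
}

// ---------------------------------------------------------------------------
// initial packing: monomers/dimers/trimers by rejection sampling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pack_box(int n_mono, int n_di, int n_tri, NumericVector edge,
                  NumericVector half, double bond_length,
                  double bond_angle_deg, double contact_tol = 1e-9,
                  int max_attempts = 1000) {
  int n_mol = n_mono + n_di + n_tri;
  int n_beads = n_mono + 2 * n_di + 3 * n_tri;
  NumericMatrix pos(n_beads, 3), quat(n_beads, 4), halfm(n_beads, 3);
  IntegerVector polymer_id(n_beads);
  std::vector<std::pair<int, int> > bondv;

  double theta = bond_angle_deg * M_PI / 180.0;
  double aoff = M_PI - theta;
  // local templates: bead 0 at origin, chain along +x, third bead kinked in xy
  V3 off[3]; double lq[3][4];
  off[0] = v3(0, 0, 0);
  off[1] = v3(bond_length, 0, 0);
  off[2] = off[1] + v3(bond_length * cos(aoff), bond_length * sin(aoff), 0);
  lq[0][0] = 1; lq[0][1] = lq[0][2] = lq[0][3] = 0;
  lq[1][0] = 1; lq[1][1] = lq[1][2] = lq[1][3] = 0;
  lq[2][0] = cos(aoff / 2); lq[2][1] = 0; lq[2][2] = 0; lq[2][3] = sin(aoff / 2);

  double rad = sqrt(half[0] * half[0] + half[1] * half[1] + half[2] * half[2]);
  CellGrid grid;
  grid.cell = std::max(2.0 * rad + contact_tol, 0.5);

  int placed_beads = 0, placed_mols = 0;
  // place larger species first (trimers, dimers, monomers)
  for (int species = 3; species >= 1; --species) {
    int count = species == 1 ? n_mono : (species == 2 ? n_di : n_tri);
    for (int m = 0; m < count; ++m) {
      bool ok = false;
      V3 c[3]; double bq[3][4];
      for (int attempt = 0; attempt < max_attempts && !ok; ++attempt) {
        // uniform random rotation from normalised 4-normal quaternion
        double q[4], qn = 0;
        do {
          qn = 0;
          for (int k = 0; k < 4; ++k) { q[k] = norm_rand(); qn += q[k] * q[k]; }
        } while (qn < 1e-12);
        qn = sqrt(qn);
        for (int k = 0; k < 4; ++k) q[k] /= qn;
        double R[3][3]; quat_to_mat(q, R);
        V3 p0 = v3(unif_rand() * edge[0], unif_rand() * edge[1], unif_rand() * edge[2]);
        ok = true;
        for (int b = 0; b < species; ++b) {
          c[b] = p0 + matvec(R, off[b]);
          qmul(q, lq[b], bq[b]);
          // bounds via oriented extents
          double Rb[3][3]; quat_to_mat(bq[b], Rb);
          for (int k = 0; k < 3 && ok; ++k) {
            double e = fabs(Rb[k][0]) * half[0] + fabs(Rb[k][1]) * half[1] +
                       fabs(Rb[k][2]) * half[2];
            double ck = k == 0 ? c[b].x : (k == 1 ? c[b].y : c[b].z);
            if (ck - e < 0 || ck + e > edge[k]) ok = false;
          }
          if (!ok) break;
        }
        if (!ok) continue;
        // collision against already placed beads
        for (int b = 0; b < species && ok; ++b) {
          std::vector<int> cand;
          grid.forNeighbours(c[b].x, c[b].y, c[b].z,
                             [&](int j) { cand.push_back(j); });
          std::vector<V3> va(8), vb;
          double Rb[3][3]; quat_to_mat(bq[b], Rb);
          int vk = 0;
          for (int sx = -1; sx <= 1; sx += 2)
            for (int sy = -1; sy <= 1; sy += 2)
              for (int sz = -1; sz <= 1; sz += 2)
                va[vk++] = c[b] + matvec(Rb, v3(sx * half[0], sy * half[1], sz * half[2]));
          for (size_t t = 0; t < cand.size() && ok; ++t) {
            int j = cand[t];
            double dx = c[b].x - pos(j, 0), dy = c[b].y - pos(j, 1),
                   dz = c[b].z - pos(j, 2);
            double cut = 2 * rad + contact_tol;
            if (dx * dx + dy * dy + dz * dz >= cut * cut) continue;
            beadVerts(pos, quat, halfm, j, vb);
            if (gjk_core(va, vb, 1e-10, 64) < contact_tol) ok = false;
          }
        }
      }
      if (!ok) {
        double vol = edge[0] * edge[1] * edge[2];
        stop("box packing failed: placed %d of %d molecules (%d beads, %.4f beads/nm^3); "
             "reduce n_molecules or enlarge the box",
             placed_mols, n_mol, placed_beads, placed_beads / vol);
      }
      int base = placed_beads;
      ++placed_mols;
      for (int b = 0; b < species; ++b) {
        int i = placed_beads++;
        pos(i, 0) = c[b].x; pos(i, 1) = c[b].y; pos(i, 2) = c[b].z;
        for (int k = 0; k < 4; ++k) quat(i, k) = bq[b][k];
        for (int k = 0; k < 3; ++k) halfm(i, k) = half[k];
        polymer_id[i] = placed_mols;
        grid.insert(i, c[b].x, c[b].y, c[b].z);
        if (b > 0) bondv.push_back(std::make_pair(base + b, base + b + 1)); // 1-based
      }
    }
  }
  IntegerMatrix bonds(bondv.size(), 2);
  for (size_t k = 0; k < bondv.size(); ++k) {
    bonds(k, 0) = bondv[k].first; bonds(k, 1) = bondv[k].second;
  }
  return List::create(_["pos"] = pos, _["quat"] = quat, _["half"] = halfm,
                      _["polymer_id"] = polymer_id, _["bonds"] = bonds);
}
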