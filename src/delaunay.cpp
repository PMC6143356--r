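// Incremental (Bowyer-Watson) Delaunay tessellation in 3D.
//
// The tessellator works on a pre-conditioned point cloud (caller centres,
// scales and symbolically perturbs the coordinates) and returns every
// simplex not touching the enclosing super-tetrahedron.  Conflict location
// scans all live simplices, which is O(n^2) overall but cache-friendly and
// entirely adequate for the cloud sizes produced by liquid-state frames
// (a few thousand points including periodic ghosts).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  double cx, cy, cz, r2;
  bool alive;
};

// Circumcentre of the tetrahedron spanned by v via Cramer's rule on
// 2(b-a).x = |b-a|^2 etc.  Returns false when the four points are
// (numerically) coplanar.
bool circumsphere(const std::vector<double>& X, const std::vector<double>& Y,
                  const std::vector<double>& Z, const int v[4], Tet& t) {
  const double ax = X[v[0]], ay = Y[v[0]], az = Z[v[0]];
  double m[3][3], rhs[3];
  for (int i = 0; i < 3; ++i) {
    const double dx = X[v[i + 1]] - ax;
    const double dy = Y[v[i + 1]] - ay;
    const double dz = Z[v[i + 1]] - az;
    m[i][0] = 2.0 * dx;
    m[i][1] = 2.0 * dy;
    m[i][2] = 2.0 * dz;
    rhs[i] = dx * dx + dy * dy + dz * dz;
  }
  const double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                     m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                     m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-30) return false;
  const double d0 = rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                    m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                    m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2]);
  const double d1 = m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                    rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                    m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]);
  const double d2 = m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                    m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                    rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  const double px = d0 / det, py = d1 / det, pz = d2 / det;
  t.cx = ax + px;
  t.cy = ay + py;
  t.cz = az + pz;
  t.r2 = px * px + py * py + pz * pz;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".bw_delaunay")]]
IntegerMatrix bw_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("Delaunay tessellation needs at least 4 points");
  std::vector<double> X(n + 4), Y(n + 4), Z(n + 4);
  double cx = 0.0, cy = 0.0, cz = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0);
    Y[i] = pts(i, 1);
    Z[i] = pts(i, 2);
    cx += X[i];
    cy += Y[i];
    cz += Z[i];
  }
  cx /= n;
  cy /= n;
  cz /= n;
  double R = 1.0;
  for (int i = 0; i < n; ++i) {
    const double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
    R = std::max(R, std::sqrt(dx * dx + dy * dy + dz * dz));
  }
  // Super-tetrahedron: regular tetrahedron whose insphere radius is 100 R,
  // comfortably outside every circumsphere of the (perturbed) input.
  const double S = 3.0 * 100.0 * R / std::sqrt(3.0);
  const int s0 = n, s1 = n + 1, s2 = n + 2, s3 = n + 3;
  X[s0] = cx + S; Y[s0] = cy + S; Z[s0] = cz + S;
  X[s1] = cx + S; Y[s1] = cy - S; Z[s1] = cz - S;
  X[s2] = cx - S; Y[s2] = cy + S; Z[s2] = cz - S;
  X[s3] = cx - S; Y[s3] = cy - S; Z[s3] = cz + S;

  std::vector<Tet> tets;
  tets.reserve(16 * static_cast<size_t>(n));
  {
    Tet t0;
    t0.v[0] = s0; t0.v[1] = s1; t0.v[2] = s2; t0.v[3] = s3;
    if (!circumsphere(X, Y, Z, t0.v, t0))
      stop("internal error: degenerate super-tetrahedron");
    t0.alive = true;
    tets.push_back(t0);
  }

  // Deterministic shuffled insertion order (xorshift64), independent of
  // R's RNG so identical input always yields the identical simplex set.
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uint64_t st = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    st ^= st << 13; st ^= st >> 7; st ^= st << 17;
    const int j = static_cast<int>(st % static_cast<std::uint64_t>(i + 1));
    std::swap(order[i], order[j]);
  }

  const std::uint64_t K = static_cast<std::uint64_t>(n + 4);
  std::vector<int> conflicts;
  conflicts.reserve(256);
  std::unordered_map<std::uint64_t, int> facecnt;
  facecnt.reserve(512);
  size_t ndead = 0;

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const double px = X[p], py = Y[p], pz = Z[p];
    conflicts.clear();
    const int nt = static_cast<int>(tets.size());
    for (int ti = 0; ti < nt; ++ti) {
      const Tet& t = tets[ti];
      if (!t.alive) continue;
      const double dx = px - t.cx, dy = py - t.cy, dz = pz - t.cz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      // Tolerance scaled by r2 so the huge super-tet spheres get a
      // proportionally larger guard band against round-off.
      if (d2 < t.r2 - 1e-12 * (1.0 + t.r2)) conflicts.push_back(ti);
    }
    if (conflicts.empty())
      stop("tessellation failure: inserted point conflicts with no simplex "
           "(coincident or degenerate input points?)");
    facecnt.clear();
    for (const int ci : conflicts) {
      Tet& t = tets[ci];
      for (int f = 0; f < 4; ++f) {
        int a = t.v[(f + 1) & 3], b = t.v[(f + 2) & 3], c = t.v[(f + 3) & 3];
        if (a > b) std::swap(a, b);
        if (b > c) std::swap(b, c);
        if (a > b) std::swap(a, b);
        const std::uint64_t key =
            (static_cast<std::uint64_t>(a) * K + b) * K + c;
        ++facecnt[key];
      }
      t.alive = false;
      ++ndead;
    }
    for (const auto& kv : facecnt) {
      if (kv.second != 1) continue;  // interior cavity face
      const std::uint64_t key = kv.first;
      const int c = static_cast<int>(key % K);
      const int b = static_cast<int>((key / K) % K);
      const int a = static_cast<int>(key / (K * K));
      Tet ntet;
      ntet.v[0] = a; ntet.v[1] = b; ntet.v[2] = c; ntet.v[3] = p;
      if (!circumsphere(X, Y, Z, ntet.v, ntet)) {
        // Numerically coplanar cavity face + point: give the sliver an
        // infinite conflict sphere so the next nearby insertion removes it;
        // survivors are filtered by volume downstream.
        ntet.cx = (X[a] + X[b] + X[c] + px) / 4.0;
        ntet.cy = (Y[a] + Y[b] + Y[c] + py) / 4.0;
        ntet.cz = (Z[a] + Z[b] + Z[c] + pz) / 4.0;
        ntet.r2 = std::numeric_limits<double>::infinity();
      }
      ntet.alive = true;
      tets.push_back(ntet);
    }
    if (ndead > 4096 && ndead * 2 > tets.size()) {
      size_t w = 0;
      for (size_t r = 0; r < tets.size(); ++r)
        if (tets[r].alive) tets[w++] = tets[r];
      tets.resize(w);
      ndead = 0;
    }
  }

  int m = 0;
  for (const Tet& t : tets)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Tet& t : tets) {
    if (!(t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n))
      continue;
    for (int j = 0; j < 4; ++j) out(r, j) = t.v[j] + 1;  // 1-based for R
    ++r;
  }
  return out;
}

// Edge lengths (pair order 12,13,14,23,24,34), volume, circumcentre and
// circumradius of each simplex, evaluated on the *unperturbed* coordinates.
// [[Rcpp::export(name = ".simplex_geometry")]]
List simplex_geometry(NumericMatrix pts, IntegerMatrix simp) {
  const int m = simp.nrow();
  NumericMatrix edges(m, 6), cc(m, 3);
  NumericVector vol(m), crad(m);
  std::vector<double> X(pts.nrow()), Y(pts.nrow()), Z(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
  }
  for (int i = 0; i < m; ++i) {
    int v[4];
    for (int j = 0; j < 4; ++j) v[j] = simp(i, j) - 1;
    int e = 0;
    for (int a = 0; a < 3; ++a) {
      for (int b = a + 1; b < 4; ++b) {
        const double dx = X[v[a]] - X[v[b]];
        const double dy = Y[v[a]] - Y[v[b]];
        const double dz = Z[v[a]] - Z[v[b]];
        edges(i, e++) = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
    const double bx = X[v[1]] - X[v[0]], by = Y[v[1]] - Y[v[0]],
                 bz = Z[v[1]] - Z[v[0]];
    const double cx2 = X[v[2]] - X[v[0]], cy2 = Y[v[2]] - Y[v[0]],
                 cz2 = Z[v[2]] - Z[v[0]];
    const double dx2 = X[v[3]] - X[v[0]], dy2 = Y[v[3]] - Y[v[0]],
                 dz2 = Z[v[3]] - Z[v[0]];
    const double det = bx * (cy2 * dz2 - cz2 * dy2) -
                       by * (cx2 * dz2 - cz2 * dx2) +
                       bz * (cx2 * dy2 - cy2 * dx2);
    vol[i] = std::fabs(det) / 6.0;
    Tet t;
    if (circumsphere(X, Y, Z, v, t)) {
      cc(i, 0) = t.cx; cc(i, 1) = t.cy; cc(i, 2) = t.cz;
      crad[i] = std::sqrt(t.r2);
    } else {
      cc(i, 0) = (X[v[0]] + X[v[1]] + X[v[2]] + X[v[3]]) / 4.0;
      cc(i, 1) = (Y[v[0]] + Y[v[1]] + Y[v[2]] + Y[v[3]]) / 4.0;
      cc(i, 2) = (Z[v[0]] + Z[v[1]] + Z[v[2]] + Z[v[3]]) / 4.0;
      crad[i] = NA_REAL;
    }
  }
  return List::create(Named("edges") = edges, Named("volume") = vol,
                      Named("centre") = cc, Named("radius") = crad);
}

// Sequential random insertion with a periodic hard-core exclusion.
// Draws from R's RNG so set.seed() fully determines the configuration.
// [[Rcpp::export(name = ".place_hardcore")]]
NumericMatrix place_hardcore_cpp(int n, NumericVector box, double min_sep,
                                 int max_tries) {
  NumericMatrix out(n, 3);
  const double ms2 = min_sep * min_sep;
  const double bx = box[0], by = box[1], bz = box[2];
  const double hx = bx / 2, hy = by / 2, hz = bz / 2;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int t = 0; t < max_tries && !placed; ++t) {
      const double px = unif_rand() * bx;
      const double py = unif_rand() * by;
      const double pz = unif_rand() * bz;
      bool ok = true;
      for (int j = 0; j < i; ++j) {
        double dx = std::fabs(out(j, 0) - px); if (dx > hx) dx = bx - dx;
        double dy = std::fabs(out(j, 1) - py); if (dy > hy) dy = by - dy;
        double dz = std::fabs(out(j, 2) - pz); if (dz > hz) dz = bz - dz;
        if (dx * dx + dy * dy + dz * dz < ms2) { ok = false; break; }
      }
      if (ok) {
        out(i, 0) = px; out(i, 1) = py; out(i, 2) = pz;
        placed = true;
      }
    }
    if (!placed)
      stop("hard-core placement failed after %d tries; "
           "reduce min_separation or density", max_tries);
  }
  return out;
}
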