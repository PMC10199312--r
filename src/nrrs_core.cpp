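#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Voxel grids are passed as flat numeric vectors in R array order:
// linear index = x + nx * (y + ny * z), coordinates 0-based.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of intensity at a continuous voxel coordinate.
// Coordinates are clamped to the grid so border queries are well defined.
static double trilin(const double* img, int nx, int ny, int nz,
                     double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
  if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
  if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  #define AT(i, j, k) img[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double c00 = AT(x0, y0, z0) * (1 - fx) + AT(x1, y0, z0) * fx;
  double c10 = AT(x0, y1, z0) * (1 - fx) + AT(x1, y1, z0) * fx;
  double c01 = AT(x0, y0, z1) * (1 - fx) + AT(x1, y0, z1) * fx;
  double c11 = AT(x0, y1, z1) * (1 - fx) + AT(x1, y1, z1) * fx;
  #undef AT
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
double cpp_trilinear(NumericVector img, IntegerVector dims,
                     double x, double y, double z) {
  return trilin(REAL(img), dims[0], dims[1], dims[2], x, y, z);
}

// Dijkstra shortest path on the 26-connected voxel graph.
// Edge weight (v0,v1) = ||v0-v1|| * (gI(v0) + gI(v1)) / 2 with
// gI(v) = exp(lambdaI * (1 - I(v)/Imax)^2); physical edge lengths use the
// per-axis voxel size. Ties are broken deterministically by preferring the
// lexicographically smaller predecessor index.
// [[Rcpp::export]]
IntegerMatrix cpp_dijkstra(NumericVector img, IntegerVector dims,
                           IntegerVector start, IntegerVector end,
                           double lambdaI, NumericVector voxel_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const double* I = REAL(img);

  double Imax = 0.0;
  for (size_t i = 0; i < N; ++i) if (I[i] > Imax) Imax = I[i];
  if (Imax <= 0.0) stop("degenerate image block: maximum intensity is 0");

  std::vector<double> g(N);
  for (size_t i = 0; i < N; ++i) {
    double t = 1.0 - I[i] / Imax;
    g[i] = std::exp(lambdaI * t * t);
  }

  // 26-neighbourhood offsets with physical lengths
  int dx[26], dy[26], dz[26];
  double elen[26];
  int m = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        dx[m] = a; dy[m] = b; dz[m] = c;
        double lx = a * voxel_size[0], ly = b * voxel_size[1], lz = c * voxel_size[2];
        elen[m] = std::sqrt(lx * lx + ly * ly + lz * lz);
        ++m;
      }

  auto idx_of = [&](int x, int y, int z) -> size_t {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
  };
  const size_t s = idx_of(start[0], start[1], start[2]);
  const size_t e = idx_of(end[0], end[1], end[2]);

  std::vector<double> dist(N, R_PosInf);
  std::vector<int64_t> pred(N, -1);
  std::vector<char> done(N, 0);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s] = 0.0;
  pq.push(QE(0.0, s));

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    size_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == e) break;
    int ux = (int)(u % nx);
    int uy = (int)((u / nx) % ny);
    int uz = (int)(u / ((size_t)nx * ny));
    double gu = g[u];
    for (int k = 0; k < 26; ++k) {
      int vx = ux + dx[k], vy = uy + dy[k], vz = uz + dz[k];
      if (vx < 0 || vy < 0 || vz < 0 || vx >= nx || vy >= ny || vz >= nz) continue;
      size_t v = idx_of(vx, vy, vz);
      if (done[v]) continue;
      double nd = dist[u] + elen[k] * 0.5 * (gu + g[v]);
      if (nd < dist[v] ||
          (nd == dist[v] && pred[v] >= 0 && (int64_t)u < pred[v])) {
        dist[v] = nd;
        pred[v] = (int64_t)u;
        pq.push(QE(nd, v));
      }
    }
  }

  if (!done[e] && e != s) stop("end voxel unreachable (internal error)");

  std::vector<size_t> path;
  size_t cur = e;
  while (true) {
    path.push_back(cur);
    if (cur == s) break;
    int64_t p = pred[cur];
    if (p < 0) stop("path reconstruction failed (internal error)");
    cur = (size_t)p;
  }
  const int K = (int)path.size();
  IntegerMatrix out(K, 3);
  for (int i = 0; i < K; ++i) {
    size_t v = path[K - 1 - i];
    out(i, 0) = (int)(v % nx);
    out(i, 1) = (int)((v / nx) % ny);
    out(i, 2) = (int)(v / ((size_t)nx * ny));
  }
  out.attr("total_weight") = dist[e];
  return out;
}

// Neighbourhood statistics of Theta(C, r): voxels whose centre lies within
// Euclidean distance r (voxel units) of the continuous point C, clipped to
// the block. Returns max intensity, intensity sum, intensity-weighted sum of
// squared distances and the intensity-weighted centroid.
static void theta_stats(const double* img, int nx, int ny, int nz,
                        double cx, double cy, double cz, double r,
                        double& maxI, double& sumI, double& sumd2I,
                        double cen[3]) {
  maxI = 0.0; sumI = 0.0; sumd2I = 0.0;
  cen[0] = cx; cen[1] = cy; cen[2] = cz;
  double wx = 0, wy = 0, wz = 0;
  const double r2 = r * r;
  int x0 = std::max(0, (int)std::ceil(cx - r));
  int x1 = std::min(nx - 1, (int)std::floor(cx + r));
  int y0 = std::max(0, (int)std::ceil(cy - r));
  int y1 = std::min(ny - 1, (int)std::floor(cy + r));
  int z0 = std::max(0, (int)std::ceil(cz - r));
  int z1 = std::min(nz - 1, (int)std::floor(cz + r));
  for (int z = z0; z <= z1; ++z)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double ddx = x - cx, ddy = y - cy, ddz = z - cz;
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 > r2) continue;
        double v = img[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
        if (v > maxI) maxI = v;
        sumI += v;
        sumd2I += d2 * v;
        wx += x * v; wy += y * v; wz += z * v;
      }
  if (sumI > 0) {
    cen[0] = wx / sumI; cen[1] = wy / sumI; cen[2] = wz / sumI;
  }
}

// Per-control-point image energy terms (EI, EC). A control point whose
// neighbourhood is entirely zero contributes lambdaI to EI (logged upstream)
// and 0 to EC.
// [[Rcpp::export]]
List cpp_energy_image(NumericMatrix curve, NumericVector img, IntegerVector dims,
                      double lambdaI, double lambdaC, double r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* I = REAL(img);
  const int K = curve.nrow();
  NumericVector ei(K), ec(K);
  LogicalVector dark(K);
  for (int k = 0; k < K; ++k) {
    double maxI, sumI, sumd2I, cen[3];
    theta_stats(I, nx, ny, nz, curve(k, 0), curve(k, 1), curve(k, 2), r,
                maxI, sumI, sumd2I, cen);
    if (maxI <= 0.0) {
      ei[k] = lambdaI;
      ec[k] = 0.0;
      dark[k] = true;
    } else {
      double Ic = trilin(I, nx, ny, nz, curve(k, 0), curve(k, 1), curve(k, 2));
      double t = 1.0 - Ic / maxI;
      ei[k] = lambdaI * t * t;
      ec[k] = lambdaC * sumd2I / sumI;
      dark[k] = false;
    }
  }
  return List::create(_["ei"] = ei, _["ec"] = ec, _["dark"] = dark);
}

// Intensity-weighted centroid of the voxels within r of a continuous point;
// NA when the window carries no intensity.
// [[Rcpp::export]]
NumericVector cpp_ms_centroid(NumericVector img, IntegerVector dims,
                              double x, double y, double z, double r) {
  double maxI, sumI, sumd2I, cen[3];
  theta_stats(REAL(img), dims[0], dims[1], dims[2], x, y, z, r,
              maxI, sumI, sumd2I, cen);
  if (sumI <= 0.0)
    return NumericVector::create(NA_REAL, NA_REAL, NA_REAL);
  return NumericVector::create(cen[0], cen[1], cen[2]);
}

static double total_energy_cpp(const NumericMatrix& cur, const double* I,
                               int nx, int ny, int nz,
                               double alpha, double beta, double gamma,
                               double lambdaI, double lambdaC, double r) {
  const int K = cur.nrow();
  double eimg = 0.0;
  for (int k = 0; k < K; ++k) {
    double maxI, sumI, sumd2I, cen[3];
    theta_stats(I, nx, ny, nz, cur(k, 0), cur(k, 1), cur(k, 2), r,
                maxI, sumI, sumd2I, cen);
    if (maxI <= 0.0) {
      eimg += lambdaI;
    } else {
      double Ic = trilin(I, nx, ny, nz, cur(k, 0), cur(k, 1), cur(k, 2));
      double t = 1.0 - Ic / maxI;
      eimg += lambdaI * t * t + lambdaC * sumd2I / sumI;
    }
  }
  double elen = 0.0;
  for (int k = 1; k < K; ++k) {
    double a = cur(k, 0) - cur(k - 1, 0);
    double b = cur(k, 1) - cur(k - 1, 1);
    double c = cur(k, 2) - cur(k - 1, 2);
    elen += a * a + b * b + c * c;
  }
  double esm = 0.0;
  for (int k = 1; k < K - 1; ++k) {
    double a = cur(k, 0) - 0.5 * (cur(k - 1, 0) + cur(k + 1, 0));
    double b = cur(k, 1) - 0.5 * (cur(k - 1, 1) + cur(k + 1, 1));
    double c = cur(k, 2) - 0.5 * (cur(k - 1, 2) + cur(k + 1, 2));
    esm += a * a + b * b + c * c;
  }
  return alpha * eimg + beta * elen + gamma * esm;
}

// Energy-minimising deformation of a curve with fixed endpoints.
// Cyclic (Gauss-Seidel) sweeps: each interior point takes a damped step
// towards the minimiser of its local quadratic terms (intensity-weighted
// centroid for the centring term, neighbour midpoint for the length and
// smoothness terms). A sweep is only accepted if the total energy does not
// increase; otherwise the step is halved (up to 4 times) and finally the
// sweep is rejected, so the energy trace is monotone non-increasing.
// [[Rcpp::export]]
List cpp_deform(NumericMatrix curve, NumericVector img, IntegerVector dims,
                double alpha, double beta, double gamma,
                double lambdaI, double lambdaC, double r,
                double step, double tol, int max_iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* I = REAL(img);
  const int K = curve.nrow();
  NumericMatrix cur = clone(curve);
  std::vector<double> trace;
  double E = total_energy_cpp(cur, I, nx, ny, nz, alpha, beta, gamma,
                              lambdaI, lambdaC, r);
  trace.push_back(E);
  bool converged = false;
  int iters = 0;
  if (K <= 2) {
    converged = true;
  }
  for (int it = 0; it < max_iters && K > 2; ++it) {
    bool accepted = false;
    double s = step;
    for (int attempt = 0; attempt < 5; ++attempt) {
      NumericMatrix cand = clone(cur);
      for (int k = 1; k < K - 1; ++k) {
        double maxI, sumI, sumd2I, cen[3];
        theta_stats(I, nx, ny, nz, cand(k, 0), cand(k, 1), cand(k, 2), r,
                    maxI, sumI, sumd2I, cen);
        double wimg = (sumI > 0.0) ? alpha * lambdaC : 0.0;
        double wnb = 2.0 * beta + gamma;
        double denom = wimg + wnb;
        if (denom <= 0.0) continue;
        for (int d = 0; d < 3; ++d) {
          double mid = 0.5 * (cand(k - 1, d) + cand(k + 1, d));
          double target = (wimg * cen[d] + wnb * mid) / denom;
          double nv = cand(k, d) + s * (target - cand(k, d));
          double hi = (d == 0 ? nx : (d == 1 ? ny : nz)) - 1.0;
          cand(k, d) = clampd(nv, 0.0, hi);
        }
      }
      double E1 = total_energy_cpp(cand, I, nx, ny, nz, alpha, beta, gamma,
                                   lambdaI, lambdaC, r);
      if (E1 <= E) {
        double dE = E - E1;
        cur = cand;
        E = E1;
        trace.push_back(E);
        accepted = true;
        ++iters;
        if (dE < tol) converged = true;
        break;
      }
      s *= 0.5;
    }
    if (!accepted) { converged = true; break; }
    if (converged) break;
  }
  return List::create(_["curve"] = cur,
                      _["energy"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iters,
                      _["converged"] = converged);
}
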