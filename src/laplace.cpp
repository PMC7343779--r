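#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Tissue codes shared with the R side: 0 other, 1 white, 2 grey matter, 3 pial.
static const int T_OTHER = 0, T_WHITE = 1, T_GM = 2, T_PIAL = 3;

inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// BFS over 6-connected GM voxels starting from all GM voxels adjacent to a
// boundary tissue; marks which GM voxels can reach that boundary.
static void flood_from_boundary(const IntegerVector& tissue,
                                int nx, int ny, int nz,
                                int boundary, std::vector<char>& reached) {
  std::queue<int> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (tissue[v] != T_GM) continue;
        for (int d = 0; d < 6; ++d) {
          int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          if (tissue[idx3(ii, jj, kk, nx, ny)] == boundary) {
            if (!reached[v]) { reached[v] = 1; q.push(v); }
            break;
          }
        }
      }
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int k = v / (nx * ny), r = v % (nx * ny), j = r / nx, i = r % nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int w = idx3(ii, jj, kk, nx, ny);
      if (tissue[w] == T_GM && !reached[w]) { reached[w] = 1; q.push(w); }
    }
  }
}

// Solve Laplace's equation on the GM shell with Dirichlet boundaries
// (0 on white, 1 on pial) by Gauss-Seidel with successive over-relaxation.
// Neighbours outside the domain ("other") are ignored (Neumann).
// [[Rcpp::export(name = ".laplace_solve_cpp")]]
List laplace_solve_cpp(IntegerVector tissue, IntegerVector dims,
                       double tol, int max_iter, double omega) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;

  std::vector<char> from_white(n, 0), from_pial(n, 0);
  flood_from_boundary(tissue, nx, ny, nz, T_WHITE, from_white);
  flood_from_boundary(tissue, nx, ny, nz, T_PIAL, from_pial);

  LogicalVector unreachable(n, false);
  std::vector<char> solve_here(n, 0);
  int n_gm = 0;
  for (int v = 0; v < n; ++v) {
    if (tissue[v] != T_GM) continue;
    ++n_gm;
    if (from_white[v] && from_pial[v]) solve_here[v] = 1;
    else unreachable[v] = true;
  }

  // phi holds boundary values outside GM so the stencil can read them.
  NumericVector phi(n, NA_REAL);
  for (int v = 0; v < n; ++v) {
    if (tissue[v] == T_WHITE) phi[v] = 0.0;
    else if (tissue[v] == T_PIAL) phi[v] = 1.0;
    else if (solve_here[v]) phi[v] = 0.5;
  }

  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  double max_update = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter && max_update > tol; ++iter) {
    max_update = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int v = idx3(i, j, k, nx, ny);
          if (!solve_here[v]) continue;
          double s = 0.0; int m = 0;
          for (int d = 0; d < 6; ++d) {
            int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            double pv = phi[idx3(ii, jj, kk, nx, ny)];
            if (!ISNAN(pv)) { s += pv; ++m; }
          }
          if (m == 0) continue;
          double upd = s / m;
          double nv = phi[v] + omega * (upd - phi[v]);
          if (nv < 0.0) nv = 0.0;
          if (nv > 1.0) nv = 1.0;
          double delta = std::fabs(nv - phi[v]);
          if (delta > max_update) max_update = delta;
          phi[v] = nv;
        }
  }

  // Expose only GM values (plus boundary values kept for gradient stencils).
  NumericVector out(n, NA_REAL);
  for (int v = 0; v < n; ++v) {
    if (solve_here[v] || tissue[v] == T_WHITE || tissue[v] == T_PIAL) out[v] = phi[v];
  }
  out.attr("dim") = dims;
  unreachable.attr("dim") = dims;
  return List::create(_["potential"] = out,
                      _["unreachable"] = unreachable,
                      _["iterations"] = iter,
                      _["converged"] = max_update <= tol,
                      _["n_gm"] = n_gm);
}

// Central/one-sided finite-difference gradient of the potential at voxel v,
// in voxel units (per-axis spacing handled by the caller via voxel sizes).
static bool voxel_gradient(const NumericVector& phi, int i, int j, int k,
                           int nx, int ny, int nz, double g[3]) {
  int off[3][2][3] = {{{1,0,0},{-1,0,0}}, {{0,1,0},{0,-1,0}}, {{0,0,1},{0,0,-1}}};
  for (int a = 0; a < 3; ++a) {
    double vp = NA_REAL, vm = NA_REAL;
    int ip = i + off[a][0][0], jp = j + off[a][0][1], kp = k + off[a][0][2];
    int im = i + off[a][1][0], jm = j + off[a][1][1], km = k + off[a][1][2];
    if (ip >= 0 && jp >= 0 && kp >= 0 && ip < nx && jp < ny && kp < nz)
      vp = phi[idx3(ip, jp, kp, nx, ny)];
    if (im >= 0 && jm >= 0 && km >= 0 && im < nx && jm < ny && km < nz)
      vm = phi[idx3(im, jm, km, nx, ny)];
    double v0 = phi[idx3(i, j, k, nx, ny)];
    if (!ISNAN(vp) && !ISNAN(vm)) g[a] = 0.5 * (vp - vm);
    else if (!ISNAN(vp)) g[a] = vp - v0;
    else if (!ISNAN(vm)) g[a] = v0 - vm;
    else g[a] = 0.0;
  }
  return !(g[0] == 0.0 && g[1] == 0.0 && g[2] == 0.0);
}

// Trilinear interpolation of the precomputed per-voxel gradient field; corners
// with no defined potential fall back to zero weight.
static bool interp_gradient(const std::vector<double>& gx,
                            const std::vector<double>& gy,
                            const std::vector<double>& gz,
                            const std::vector<char>& has_g,
                            double x, double y, double z,
                            int nx, int ny, int nz, double g[3]) {
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double wsum = 0.0; g[0] = g[1] = g[2] = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        int v = idx3(i, j, k, nx, ny);
        if (!has_g[v]) continue;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        g[0] += w * gx[v]; g[1] += w * gy[v]; g[2] += w * gz[v];
        wsum += w;
      }
  if (wsum <= 0.0) return false;
  g[0] /= wsum; g[1] /= wsum; g[2] /= wsum;
  return true;
}

// Trace streamlines of the normalised potential gradient from seed voxels to
// the pial boundary. Positions are continuous 0-based voxel coordinates;
// steps have physical length step_h (mm) using the per-axis voxel sizes.
// Flags: 0 ok, 1 zero gradient, 2 left domain, 3 max steps reached.
// [[Rcpp::export(name = ".trace_streamlines_cpp")]]
List trace_streamlines_cpp(NumericVector phi, IntegerVector tissue,
                           IntegerVector dims, NumericMatrix seeds,
                           NumericVector voxel_size, double step_h,
                           int max_steps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;

  std::vector<double> gx(n, 0), gy(n, 0), gz(n, 0);
  std::vector<char> has_g(n, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = idx3(i, j, k, nx, ny);
        if (ISNAN(phi[v])) continue;
        double g[3];
        voxel_gradient(phi, i, j, k, nx, ny, nz, g);
        gx[v] = g[0]; gy[v] = g[1]; gz[v] = g[2];
        has_g[v] = 1;
      }

  int n_seeds = seeds.nrow();
  List paths(n_seeds);
  IntegerVector flags(n_seeds);

  for (int s = 0; s < n_seeds; ++s) {
    double x = seeds(s, 0), y = seeds(s, 1), z = seeds(s, 2);
    std::vector<double> px, py, pz;
    int flag = 3;
    for (int step = 0; step < max_steps; ++step) {
      px.push_back(x); py.push_back(y); pz.push_back(z);
      int iv = (int)std::lround(x), jv = (int)std::lround(y), kv = (int)std::lround(z);
      if (iv < 0 || jv < 0 || kv < 0 || iv >= nx || jv >= ny || kv >= nz) { flag = 2; break; }
      int tv = tissue[idx3(iv, jv, kv, nx, ny)];
      if (tv == T_PIAL) { flag = 0; break; }
      if (tv == T_OTHER || tv == T_WHITE) {
        // A seed sits on the white/GM interface; only abort once off the seed.
        if (step > 0) { flag = 2; break; }
      }
      double g[3];
      if (!interp_gradient(gx, gy, gz, has_g, x, y, z, nx, ny, nz, g)) { flag = 1; break; }
      // Convert voxel-space gradient to a world-space direction.
      double gw[3] = {g[0] / voxel_size[0], g[1] / voxel_size[1], g[2] / voxel_size[2]};
      double norm = std::sqrt(gw[0] * gw[0] + gw[1] * gw[1] + gw[2] * gw[2]);
      if (norm < 1e-12) { flag = 1; break; }
      x += step_h * (gw[0] / norm) / voxel_size[0];
      y += step_h * (gw[1] / norm) / voxel_size[1];
      z += step_h * (gw[2] / norm) / voxel_size[2];
    }
    NumericMatrix path(px.size(), 3);
    for (size_t t = 0; t < px.size(); ++t) {
      path(t, 0) = px[t]; path(t, 1) = py[t]; path(t, 2) = pz[t];
    }
    paths[s] = path;
    flags[s] = flag;
  }
  return List::create(_["paths"] = paths, _["flags"] = flags);
}
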