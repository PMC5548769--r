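#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Parallel-beam forward projector, pixel-driven splatting.
// Each voxel's value is deposited onto the detector with linear weights, so
// the total sinogram mass per angle equals the volume sum exactly.
// vol: [nx, ny, nz]; returns [nu, nz, n_ang] line integrals in voxel-length units.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, NumericVector angles, int nu) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int na = angles.size();
  NumericVector out(Dimension(nu, nz, na));
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cs = (nu - 1) / 2.0;
  std::vector<double> sx(nx), sy(ny);
  for (int a = 0; a < na; ++a) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int i = 0; i < nx; ++i) sx[i] = (i - cx) * c;
    for (int j = 0; j < ny; ++j) sy[j] = (j - cy) * s;
    double *pa = &out[(R_xlen_t)a * nu * nz];
    for (int k = 0; k < nz; ++k) {
      double *pk = pa + (R_xlen_t)k * nu;
      const double *vk = &vol[(R_xlen_t)k * nx * ny];
      for (int j = 0; j < ny; ++j) {
        const double *vj = vk + (R_xlen_t)j * nx;
        for (int i = 0; i < nx; ++i) {
          double v = vj[i];
          if (v == 0.0) continue;
          double u = sx[i] + sy[j] + cs;
          int u0 = (int)std::floor(u);
          double w = u - u0;
          if (u0 >= 0 && u0 < nu) pk[u0] += v * (1.0 - w);
          if (u0 + 1 >= 0 && u0 + 1 < nu) pk[u0 + 1] += v * w;
        }
      }
    }
  }
  return out;
}

// Backprojection with linear detector interpolation.
// filt: [nu, nz, n_ang] ramp-filtered sinogram stack; returns [n, n, nz].
// Caller applies the pi / n_ang angular quadrature weight.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filt, NumericVector angles, int n) {
  IntegerVector d = filt.attr("dim");
  int nu = d[0], nz = d[1];
  int na = angles.size();
  NumericVector out(Dimension(n, n, nz));
  double cx = (n - 1) / 2.0, cs = (nu - 1) / 2.0;
  std::vector<double> sx(n), sy(n);
  for (int a = 0; a < na; ++a) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int i = 0; i < n; ++i) sx[i] = (i - cx) * c;
    for (int j = 0; j < n; ++j) sy[j] = (j - cx) * s;
    const double *pa = &filt[(R_xlen_t)a * nu * nz];
    for (int k = 0; k < nz; ++k) {
      const double *pk = pa + (R_xlen_t)k * nu;
      double *ok = &out[(R_xlen_t)k * n * n];
      for (int j = 0; j < n; ++j) {
        double *oj = ok + (R_xlen_t)j * n;
        for (int i = 0; i < n; ++i) {
          double u = sx[i] + sy[j] + cs;
          int u0 = (int)std::floor(u);
          if (u0 < 0 || u0 + 1 >= nu) continue;
          double w = u - u0;
          oj[i] += pk[u0] * (1.0 - w) + pk[u0 + 1] * w;
        }
      }
    }
  }
  return out;
}

// 3D median filter over the (2r+1)^3 cube, edge-replicated borders.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int r) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(Dimension(nx, ny, nz));
  if (r <= 0) { std::copy(vol.begin(), vol.end(), out.begin()); return out; }
  int side = 2 * r + 1;
  std::vector<double> buf((size_t)side * side * side);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t m = 0;
        for (int dk = -r; dk <= r; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -r; dj <= r; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -r; di <= r; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              buf[m++] = vol[idx3(ii, jj, kk, nx, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[idx3(i, j, k, nx, ny)] = buf[m / 2];
      }
  return out;
}

// 3^3 box mean, clamped borders; used to anti-alias binary masks before
// surface triangulation.
// [[Rcpp::export]]
NumericVector cpp_boxmean3(NumericVector vol) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out(Dimension(nx, ny, nz));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -1; di <= 1; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              s += vol[idx3(ii, jj, kk, nx, ny)];
            }
          }
        }
        out[idx3(i, j, k, nx, ny)] = s / 27.0;
      }
  return out;
}

// 6-connected component labeling, labels assigned in decreasing size order;
// components smaller than min_voxels are dropped.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, int min_voxels) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<int> lab(nvox, 0);
  std::vector<R_xlen_t> stack;
  std::vector<R_xlen_t> sizes; // size per provisional label (1-based)
  int next = 0;
  for (R_xlen_t p = 0; p < nvox; ++p) {
    if (!mask[p] || lab[p]) continue;
    ++next;
    R_xlen_t sz = 0;
    stack.push_back(p); lab[p] = next;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back(); ++sz;
      int i = q % nx, j = (q / nx) % ny, k = q / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t qq = idx3(ii, jj, kk, nx, ny);
        if (mask[qq] && !lab[qq]) { lab[qq] = next; stack.push_back(qq); }
      }
    }
    sizes.push_back(sz);
  }
  // order labels by decreasing size, drop small ones
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  int out_next = 0;
  for (int r = 0; r < next; ++r)
    if (sizes[order[r]] >= (R_xlen_t)min_voxels) remap[order[r] + 1] = ++out_next;
  IntegerVector out(Dimension(nx, ny, nz));
  for (R_xlen_t p = 0; p < nvox; ++p) out[p] = remap[lab[p]];
  return out;
}

// Fill enclosed cavities: background is flooded with 26-connectivity from the
// volume border; background voxels never reached are interior holes and
// become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(nvox, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1)
          continue;
        R_xlen_t p = idx3(i, j, k, nx, ny);
        if (!mask[p] && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  while (!stack.empty()) {
    R_xlen_t q = stack.back(); stack.pop_back();
    int i = q % nx, j = (q / nx) % ny, k = q / ((R_xlen_t)nx * ny);
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
          R_xlen_t qq = idx3(ii, jj, kk, nx, ny);
          if (!mask[qq] && !outside[qq]) { outside[qq] = 1; stack.push_back(qq); }
        }
  }
  LogicalVector out(Dimension(nx, ny, nz));
  for (R_xlen_t p = 0; p < nvox; ++p) out[p] = mask[p] || !outside[p];
  return out;
}

// Iso-surface area by marching tetrahedra: each cell is split into 6
// tetrahedra sharing the main diagonal; intra-tet crossings are triangulated
// exactly. Area is returned in voxel-edge units squared.
// [[Rcpp::export]]
double cpp_surface_area_mt(NumericVector vol, double iso) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  double v[8];
  double P[8][3];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double vmin = R_PosInf, vmax = R_NegInf;
        for (int c = 0; c < 8; ++c) {
          v[c] = vol[idx3(i + corner[c][0], j + corner[c][1], k + corner[c][2], nx, ny)];
          if (v[c] < vmin) vmin = v[c];
          if (v[c] > vmax) vmax = v[c];
          P[c][0] = i + corner[c][0]; P[c][1] = j + corner[c][1]; P[c][2] = k + corner[c][2];
        }
        if (vmax < iso || vmin >= iso) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], out[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) {
            if (v[id[q]] >= iso) in[ni++] = id[q]; else out[no++] = id[q];
          }
          if (ni == 0 || ni == 4) continue;
          double p[4][3];
          auto interp = [&](int a, int b, double *dst) {
            double ta = (iso - v[a]) / (v[b] - v[a]);
            for (int x = 0; x < 3; ++x) dst[x] = P[a][x] + ta * (P[b][x] - P[a][x]);
          };
          auto tri_area = [](const double *a, const double *b, const double *c) {
            double u[3], w[3], x[3];
            for (int m = 0; m < 3; ++m) { u[m] = b[m] - a[m]; w[m] = c[m] - a[m]; }
            x[0] = u[1] * w[2] - u[2] * w[1];
            x[1] = u[2] * w[0] - u[0] * w[2];
            x[2] = u[0] * w[1] - u[1] * w[0];
            return 0.5 * std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
          };
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? in[0] : out[0];
            int *oth = (ni == 1) ? out : in;
            for (int q = 0; q < 3; ++q) interp(apex, oth[q], p[q]);
            area += tri_area(p[0], p[1], p[2]);
          } else { // quad: two triangles
            interp(in[0], out[0], p[0]);
            interp(in[0], out[1], p[1]);
            interp(in[1], out[1], p[2]);
            interp(in[1], out[0], p[3]);
            area += tri_area(p[0], p[1], p[2]);
            area += tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}

static inline bool in_grid(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
}

static bool is_exposed(const int *lab, int id, int i, int j, int k,
                       int nx, int ny, int nz) {
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int m = 0; m < 6; ++m) {
    int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
    if (!in_grid(ii, jj, kk, nx, ny, nz)) return true;
    if (lab[idx3(ii, jj, kk, nx, ny)] == 0) return true;
  }
  return false;
}

// Topological number T6 on the 18-neighborhood: number of 6-connected
// components of bone within N18 that touch a face neighbor. Removal of the
// center keeps the label 6-connected iff T6 == 1 (simple-point criterion
// for the (6,26) adjacency pair).
static int t6_number(const int *lab, int id, int i, int j, int k,
                     int nx, int ny, int nz) {
  // enumerate N18 offsets
  int offs[18][3], n18 = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int l1 = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (l1 == 1 || l1 == 2) { offs[n18][0] = di; offs[n18][1] = dj; offs[n18][2] = dk; ++n18; }
      }
  bool bone[18];
  for (int m = 0; m < n18; ++m) {
    int ii = i + offs[m][0], jj = j + offs[m][1], kk = k + offs[m][2];
    bone[m] = in_grid(ii, jj, kk, nx, ny, nz) &&
              lab[idx3(ii, jj, kk, nx, ny)] == id;
  }
  int comp[18];
  for (int m = 0; m < n18; ++m) comp[m] = -1;
  int ncomp = 0, t6 = 0;
  for (int m = 0; m < n18; ++m) {
    if (!bone[m] || comp[m] >= 0) continue;
    // BFS within N18 under 6-adjacency
    int stack[18], top = 0;
    stack[top++] = m; comp[m] = ncomp;
    bool has_face = false;
    while (top) {
      int q = stack[--top];
      int l1q = std::abs(offs[q][0]) + std::abs(offs[q][1]) + std::abs(offs[q][2]);
      if (l1q == 1) has_face = true;
      for (int r = 0; r < n18; ++r) {
        if (!bone[r] || comp[r] >= 0) continue;
        int dd = std::abs(offs[q][0] - offs[r][0]) + std::abs(offs[q][1] - offs[r][1]) +
                 std::abs(offs[q][2] - offs[r][2]);
        if (dd == 1) { comp[r] = ncomp; stack[top++] = r; }
      }
    }
    if (has_face) ++t6;
    ++ncomp;
  }
  return t6;
}

static bool try_remove(int *L, int *O, int id, R_xlen_t p,
                       int nx, int ny, int nz, int wall) {
  if (L[p] != id) return false;
  int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
  if (!is_exposed(L, id, i, j, k, nx, ny, nz)) return false;
  // Wall protection: within a ball of radius `wall` around the candidate,
  // exterior and cavity background must not both occur. At wall = 1 this
  // reduces to the topological no-breach rule (removal would 26-connect a
  // cavity to the outside); larger radii keep cavity walls at least `wall`
  // voxels thick so they stay resolvable through the imaging chain.
  bool has_out = false, has_cav = false;
  for (int dk = -wall; dk <= wall; ++dk)
    for (int dj = -wall; dj <= wall; ++dj)
      for (int di = -wall; di <= wall; ++di) {
        if (!di && !dj && !dk) continue;
        if (di * di + dj * dj + dk * dk > wall * wall + 1) continue;
        int ii = i + di, jj = j + dj, kk = k + dk;
        if (!in_grid(ii, jj, kk, nx, ny, nz)) { has_out = true; continue; }
        R_xlen_t q = idx3(ii, jj, kk, nx, ny);
        if (L[q] == 0) { if (O[q]) has_out = true; else has_cav = true; }
      }
  if (has_out && has_cav) return false;
  // simple-point test keeps the label a single 6-connected body
  if (t6_number(L, id, i, j, k, nx, ny, nz) != 1) return false;
  L[p] = 0;
  O[p] = has_out; // new background inherits its side of the wall
  return true;
}

// Focal erosion: each candidate linear index (0-based) nucleates a
// hemispherical "bite" of the given radius on the surface it sits on.
// Within a bite, voxels are removed nearest-first so every removal acts on
// a currently exposed voxel. Removals that would disconnect the label
// (simple-point test for the (6,26) pair) or breach a cavity wall
// (outside_bg classifies exterior vs enclosed background) are skipped.
// Stops after max_remove removals. bite_radius = 0 removes single voxels.
// [[Rcpp::export]]
List cpp_erode_batch(IntegerVector labels, int id, IntegerVector cand,
                     int max_remove, LogicalVector outside_bg,
                     double bite_radius, int wall_protect) {
  IntegerVector d = labels.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  IntegerVector lab = clone(labels);
  lab.attr("dim") = d;
  LogicalVector obg = clone(outside_bg);
  int *L = INTEGER(lab);
  int *O = LOGICAL(obg);
  // bite offsets sorted by distance from the nucleus
  int rb = (int)std::floor(bite_radius);
  std::vector<std::pair<double, std::array<int, 3> > > offs;
  for (int dk = -rb; dk <= rb; ++dk)
    for (int dj = -rb; dj <= rb; ++dj)
      for (int di = -rb; di <= rb; ++di) {
        double r2 = (double)di * di + (double)dj * dj + (double)dk * dk;
        if (r2 <= bite_radius * bite_radius)
          offs.push_back({r2, {di, dj, dk}});
      }
  std::sort(offs.begin(), offs.end(),
            [](const std::pair<double, std::array<int, 3> > &a,
               const std::pair<double, std::array<int, 3> > &b) {
              return a.first < b.first;
            });
  int removed = 0, removed_outside = 0;
  for (R_xlen_t c = 0; c < cand.size() && removed < max_remove; ++c) {
    R_xlen_t p = cand[c];
    if (L[p] != id) continue;
    int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
    for (size_t m = 0; m < offs.size() && removed < max_remove; ++m) {
      int ii = i + offs[m].second[0], jj = j + offs[m].second[1],
          kk = k + offs[m].second[2];
      if (!in_grid(ii, jj, kk, nx, ny, nz)) continue;
      R_xlen_t q = idx3(ii, jj, kk, nx, ny);
      if (try_remove(L, O, id, q, nx, ny, nz, wall_protect)) {
        ++removed;
        if (O[q]) ++removed_outside;
      }
    }
  }
  return List::create(_["labels"] = lab, _["outside_bg"] = obg,
                      _["removed"] = removed,
                      _["removed_outside"] = removed_outside);
}

// 0-based linear indices of exposed (surface) voxels of a label.
// [[Rcpp::export]]
IntegerVector cpp_surface_voxels(IntegerVector labels, int id) {
  IntegerVector d = labels.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const int *L = INTEGER(labels);
  std::vector<int> out;
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t p = 0; p < nvox; ++p) {
    if (L[p] != id) continue;
    int i = p % nx, j = (p / nx) % ny, k = p / ((R_xlen_t)nx * ny);
    if (is_exposed(L, id, i, j, k, nx, ny, nz)) out.push_back((int)p);
  }
  return wrap(out);
}
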