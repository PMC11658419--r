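// 3D binary morphology and labeling with a 6-connected (connectivity-1)
// structuring element. Arrays are R arrays in (z, y, x) logical order but
// stored column-major, so dim = c(nz, ny, nx) and index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// one 6-connected dilation pass
static void dilate_once(const std::vector<char>& in, std::vector<char>& out,
                        int nz, int ny, int nx) {
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        char v = in[i];
        if (!v) {
          if (z > 0      && in[idx3(z - 1, y, x, nz, ny)]) v = 1;
          else if (z < nz - 1 && in[idx3(z + 1, y, x, nz, ny)]) v = 1;
          else if (y > 0      && in[idx3(z, y - 1, x, nz, ny)]) v = 1;
          else if (y < ny - 1 && in[idx3(z, y + 1, x, nz, ny)]) v = 1;
          else if (x > 0      && in[idx3(z, y, x - 1, nz, ny)]) v = 1;
          else if (x < nx - 1 && in[idx3(z, y, x + 1, nz, ny)]) v = 1;
        }
        out[i] = v;
      }
}

// one 6-connected erosion pass; voxels on the array boundary erode against
// an implicit background outside the array
static void erode_once(const std::vector<char>& in, std::vector<char>& out,
                       int nz, int ny, int nx) {
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        char v = in[i];
        if (v) {
          if (z == 0 || !in[idx3(z - 1, y, x, nz, ny)]) v = 0;
          else if (z == nz - 1 || !in[idx3(z + 1, y, x, nz, ny)]) v = 0;
          else if (y == 0 || !in[idx3(z, y - 1, x, nz, ny)]) v = 0;
          else if (y == ny - 1 || !in[idx3(z, y + 1, x, nz, ny)]) v = 0;
          else if (x == 0 || !in[idx3(z, y, x - 1, nz, ny)]) v = 0;
          else if (x == nx - 1 || !in[idx3(z, y, x + 1, nz, ny)]) v = 0;
        }
        out[i] = v;
      }
}

static std::vector<char> as_mask(const LogicalVector& mask) {
  std::vector<char> m(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) m[i] = (mask[i] == TRUE) ? 1 : 0;
  return m;
}

static LogicalVector to_logical(const std::vector<char>& m, const LogicalVector& tmpl) {
  LogicalVector out(m.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)m.size(); ++i) out[i] = m[i] != 0;
  out.attr("dim") = tmpl.attr("dim");
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dim, int iter) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> a = as_mask(mask), b(a.size());
  for (int k = 0; k < iter; ++k) { dilate_once(a, b, nz, ny, nx); std::swap(a, b); }
  return to_logical(a, mask);
}

// [[Rcpp::export]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dim, int iter) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> a = as_mask(mask), b(a.size());
  for (int k = 0; k < iter; ++k) { erode_once(a, b, nz, ny, nx); std::swap(a, b); }
  return to_logical(a, mask);
}

// erode until voxel count first reaches <= target; returns the eroded mask
// and the number of iterations taken (as attribute "iterations")
// [[Rcpp::export]]
LogicalVector cpp_erode_to_count(LogicalVector mask, IntegerVector dim, double target) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> a = as_mask(mask), b(a.size());
  R_xlen_t count = 0;
  for (size_t i = 0; i < a.size(); ++i) count += a[i];
  int it = 0;
  while ((double)count > target && count > 0) {
    erode_once(a, b, nz, ny, nx);
    std::swap(a, b);
    count = 0;
    for (size_t i = 0; i < a.size(); ++i) count += a[i];
    ++it;
  }
  LogicalVector out = to_logical(a, mask);
  out.attr("iterations") = it;
  return out;
}

// 6-connected component labeling (BFS), labels 1..k in first-voxel order
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> m = as_mask(mask);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!m[i] || lab[i]) continue;
        lab[i] = ++next;
        q.push(i);
        while (!q.empty()) {
          R_xlen_t cur = q.front(); q.pop();
          int cz = (int)(cur % nz);
          R_xlen_t r = cur / nz;
          int cy = (int)(r % ny);
          int cx = (int)(r / ny);
          const int dz[6] = {-1, 1, 0, 0, 0, 0};
          const int dy[6] = {0, 0, -1, 1, 0, 0};
          const int dx[6] = {0, 0, 0, 0, -1, 1};
          for (int k = 0; k < 6; ++k) {
            int tz = cz + dz[k], ty = cy + dy[k], tx = cx + dx[k];
            if (tz < 0 || tz >= nz || ty < 0 || ty >= ny || tx < 0 || tx >= nx) continue;
            R_xlen_t j = idx3(tz, ty, tx, nz, ny);
            if (m[j] && !lab[j]) { lab[j] = next; q.push(j); }
          }
        }
      }
  lab.attr("dim") = mask.attr("dim");
  return lab;
}

// fill interior holes: background connected (6-conn) to the array border
// stays background, everything else becomes foreground
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<char> m = as_mask(mask);
  std::vector<char> outside(m.size(), 0);
  std::queue<R_xlen_t> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1)
          continue;
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!m[i] && !outside[i]) { outside[i] = 1; q.push(i); }
      }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int cz = (int)(cur % nz);
    R_xlen_t r = cur / nz;
    int cy = (int)(r % ny);
    int cx = (int)(r / ny);
    const int dz[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dx[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < 6; ++k) {
      int tz = cz + dz[k], ty = cy + dy[k], tx = cx + dx[k];
      if (tz < 0 || tz >= nz || ty < 0 || ty >= ny || tx < 0 || tx >= nx) continue;
      R_xlen_t j = idx3(tz, ty, tx, nz, ny);
      if (!m[j] && !outside[j]) { outside[j] = 1; q.push(j); }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)m.size(); ++i) out[i] = m[i] || !outside[i];
  out.attr("dim") = mask.attr("dim");
  return out;
}
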