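#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim (Z, Y, X): linear index z + Z*(y + Y*x).

static inline int reflect_idx(int i, int n) {
  // symmetric boundary: ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector vol, IntegerVector dims,
                        NumericVector kernel, int axis) {
  // axis: 0 = z, 1 = y, 2 = x; kernel has odd length, centre in the middle
  int Z = dims[0], Y = dims[1], X = dims[2];
  int K = kernel.size(), r = K / 2;
  NumericVector out(vol.size());
  int n_axis = (axis == 0) ? Z : (axis == 1 ? Y : X);
  long stride = (axis == 0) ? 1L : (axis == 1 ? (long)Z : (long)Z * Y);

  for (int x = 0; x < X; ++x) {
    for (int y = 0; y < Y; ++y) {
      for (int z = 0; z < Z; ++z) {
        long base = z + (long)Z * (y + (long)Y * x);
        int pos = (axis == 0) ? z : (axis == 1 ? y : x);
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int p = reflect_idx(pos + k, n_axis);
          acc += kernel[k + r] * vol[base + stride * (p - pos)];
        }
        out[base] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Closed-form eigenvalues of the symmetric 3x3 Hessian per voxel, sorted
// by absolute value |l1| <= |l2| <= |l3|.
// [[Rcpp::export(name = ".hessian_eigs")]]
List hessian_eigs(NumericVector hzz, NumericVector hyy, NumericVector hxx,
                  NumericVector hzy, NumericVector hzx, NumericVector hyx) {
  long n = hzz.size();
  NumericVector l1(n), l2(n), l3(n);
  for (long i = 0; i < n; ++i) {
    double a11 = hzz[i], a22 = hyy[i], a33 = hxx[i];
    double a12 = hzy[i], a13 = hzx[i], a23 = hyx[i];
    double e[3];
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    if (p1 == 0.0) {
      e[0] = a11; e[1] = a22; e[2] = a33;
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                  (a33 - q) * (a33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      r = std::max(-1.0, std::min(1.0, r));
      double phi = std::acos(r) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e[1] = 3.0 * q - e[0] - e[2];
    }
    // sort by |.| ascending
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2 - a; ++b)
        if (std::fabs(e[b]) > std::fabs(e[b + 1])) std::swap(e[b], e[b + 1]);
    l1[i] = e[0]; l2[i] = e[1]; l3[i] = e[2];
  }
  return List::create(_["lam1"] = l1, _["lam2"] = l2, _["lam3"] = l3);
}

static void neighbor_offsets(int conn, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
}

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  long n = (long)Z * Y * X;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);
  int cur = 0;
  std::vector<long> stack;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int z = (int)(v % Z), y = (int)((v / Z) % Y), x = (int)(v / ((long)Z * Y));
      for (auto& o : off) {
        int nz = z + o[0], ny = y + o[1], nx = x + o[2];
        if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X) continue;
        long w = nz + (long)Z * (ny + (long)Y * nx);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// [[Rcpp::export(name = ".morph3d")]]
LogicalVector morph3d(LogicalVector mask, IntegerVector dims,
                      IntegerMatrix offsets, bool dilate) {
  // offsets: rows of (dz, dy, dx) defining the structuring element
  int Z = dims[0], Y = dims[1], X = dims[2];
  long n = (long)Z * Y * X;
  LogicalVector out(n);
  int m = offsets.nrow();
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        long i = z + (long)Z * (y + (long)Y * x);
        bool acc = dilate ? false : true;
        for (int k = 0; k < m; ++k) {
          int nz = z + offsets(k, 0), ny = y + offsets(k, 1), nx = x + offsets(k, 2);
          bool v;
          if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
            v = false; // outside the volume is background
          else
            v = mask[nz + (long)Z * (ny + (long)Y * nx)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[i] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// ---- 3D topology-preserving thinning -------------------------------------
// A border voxel may be deleted when it is a simple point for the (26, 6)
// adjacency pair: exactly one 26-connected foreground component among its 26
// neighbours, and exactly one 6-connected background component in the
// 18-neighbourhood that touches a face neighbour. Endpoints (exactly one
// foreground 26-neighbour) are never deleted, so curve ends survive.

static inline int nb_index(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1)); // 0..26, centre = 13
}

static bool is_simple(const std::vector<unsigned char>& nb) {
  // nb: 27 flags of the 3x3x3 neighbourhood (centre at 13 ignored)
  // --- foreground 26-connectivity check ---
  int seen[27] = {0};
  int fg_comp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++fg_comp;
    if (fg_comp > 1) return false;
    std::vector<int> st; st.push_back(i); seen[i] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vz = v % 3, vy = (v / 3) % 3, vx = v / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nz = vz + dz, ny = vy + dy, nx = vx + dx;
            if (nz < 0 || nz > 2 || ny < 0 || ny > 2 || nx < 0 || nx > 2) continue;
            int w = nz + 3 * (ny + 3 * nx);
            if (w == 13 || !nb[w] || seen[w]) continue;
            seen[w] = 1; st.push_back(w);
          }
    }
  }
  if (fg_comp != 1) return false;

  // --- background 6-connectivity check within the 18-neighbourhood ---
  // N18: offsets with |dz|+|dy|+|dx| <= 2 (excluding centre)
  int seenb[27] = {0};
  int bg_comp = 0;
  static const int face[6] = { nb_index(-1,0,0), nb_index(1,0,0),
                               nb_index(0,-1,0), nb_index(0,1,0),
                               nb_index(0,0,-1), nb_index(0,0,1) };
  for (int f = 0; f < 6; ++f) {
    int s = face[f];
    if (nb[s] || seenb[s]) continue;
    ++bg_comp;
    if (bg_comp > 1) return false;
    std::vector<int> st; st.push_back(s); seenb[s] = 1;
    while (!st.empty()) {
      int v = st.back(); st.pop_back();
      int vz = v % 3 - 1, vy = (v / 3) % 3 - 1, vx = v / 9 - 1;
      static const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int nz = vz + d6[k][0], ny = vy + d6[k][1], nx = vx + d6[k][2];
        if (nz < -1 || nz > 1 || ny < -1 || ny > 1 || nx < -1 || nx > 1) continue;
        if (std::abs(nz) + std::abs(ny) + std::abs(nx) > 2) continue; // stay in N18
        int w = nb_index(nz, ny, nx);
        if (w == 13 || nb[w] || seenb[w]) continue;
        seenb[w] = 1; st.push_back(w);
      }
    }
  }
  return bg_comp == 1;
}

// [[Rcpp::export(name = ".skeletonize3d")]]
LogicalVector skeletonize3d(LogicalVector mask, IntegerVector dims) {
  int Z = dims[0], Y = dims[1], X = dims[2];
  long n = (long)Z * Y * X;
  std::vector<unsigned char> img(n);
  for (long i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> unsigned char {
    if (z < 0 || z >= Z || y < 0 || y >= Y || x < 0 || x >= X) return 0;
    return img[z + (long)Z * (y + (long)Y * x)];
  };
  auto gather = [&](int z, int y, int x, std::vector<unsigned char>& nb) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          nb[nb_index(dz, dy, dx)] = at(z + dz, y + dy, x + dx);
  };
  auto fg_neighbors = [&](const std::vector<unsigned char>& nb) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  };

  static const int dirs[6][3] = { // (dz, dy, dx) border directions U D N S E W
    {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}
  };
  std::vector<unsigned char> nb(27);
  std::vector<long> cand;
  std::vector<long> fglist;
  for (long i = 0; i < n; ++i) if (img[i]) fglist.push_back(i);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (long i : fglist) {
        if (!img[i]) continue;
        int z = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ((long)Z * Y));
        if (at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2])) continue;
        gather(z, y, x, nb);
        int fn = fg_neighbors(nb);
        if (fn <= 1) continue;       // endpoint or isolated: keep
        if (is_simple(nb)) cand.push_back(i);
      }
      // sequential re-check so earlier deletions cannot break topology
      for (long i : cand) {
        int z = (int)(i % Z), y = (int)((i / Z) % Y), x = (int)(i / ((long)Z * Y));
        gather(z, y, x, nb);
        int fn = fg_neighbors(nb);
        if (fn <= 1) continue;
        if (is_simple(nb)) { img[i] = 0; changed = true; }
      }
    }
    if (changed) {
      std::vector<long> keep;
      keep.reserve(fglist.size());
      for (long i : fglist) if (img[i]) keep.push_back(i);
      fglist.swap(keep);
    }
  }

  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// For each row of A (points, columns z,y,x) the minimum weighted Euclidean
// distance to any row of B. w scales each axis before distances are taken.
// [[Rcpp::export(name = ".rows_min_dist")]]
NumericVector rows_min_dist(NumericMatrix A, NumericMatrix B, NumericVector w) {
  int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double az = A(i,0) * w[0], ay = A(i,1) * w[1], ax = A(i,2) * w[2];
    for (int j = 0; j < nb; ++j) {
      double dz = az - B(j,0) * w[0];
      double dy = ay - B(j,1) * w[1];
      double dx = ax - B(j,2) * w[2];
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
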