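#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: logical/integer matrix (rows x cols),
// nonzero = foreground. Output: logical matrix of the 1-px skeleton.
// The two sub-iterations are repeated until no pixel changes.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix a(clone(img));
  for (int i = 0; i < nr * nc; ++i) a[i] = a[i] ? 1 : 0;
  // neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row = y, col = x)
  const int dr[8] = {-1, -1,  0,  1, 1,  1,  0, -1};
  const int dc[8] = { 0,  1,  1,  1, 0, -1, -1, -1};
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c < nc - 1; ++c) {
        for (int r = 1; r < nr - 1; ++r) {
          if (!a(r, c)) continue;
          int p[8], B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            p[k] = a(r + dr[k], c + dc[k]);
            B += p[k];
          }
          if (B < 2 || B > 6) continue;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue; // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue; // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue; // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue; // P2*P6*P8
          }
          kill.push_back(r + nr * c);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) a[kill[i]] = 0;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = a[i] != 0;
  return out;
}

// 8-connected component labelling by BFS. 0 = background.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push(r + nr * c);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int rr = idx % nr, cc = idx / nr;
        for (int dr2 = -1; dr2 <= 1; ++dr2) {
          for (int dc2 = -1; dc2 <= 1; ++dc2) {
            int r2 = rr + dr2, c2 = cc + dc2;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (img(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              q.push(r2 + nr * c2);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Longest geodesic path (graph diameter, unit weights) through an
// 8-connected skeleton: BFS from an arbitrary foreground pixel to find the
// farthest pixel u, BFS again from u to the farthest pixel v, and return
// the ordered pixel path u..v (1-based row/col). For a two-arm particle
// this path runs tip -> vertex -> tip and ignores short spurs.
static int bfs_far(const IntegerMatrix &img, int start,
                   std::vector<int> &parent) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dist(nr * nc, -1);
  parent.assign(nr * nc, -1);
  std::queue<int> q;
  dist[start] = 0;
  q.push(start);
  int far = start, fard = 0;
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int r = idx % nr, c = idx / nr;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int r2 = r + dr, c2 = c + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int j = r2 + nr * c2;
        if (img(r2, c2) && dist[j] < 0) {
          dist[j] = dist[idx] + 1;
          parent[j] = idx;
          if (dist[j] > fard) { fard = dist[j]; far = j; }
          q.push(j);
        }
      }
    }
  }
  return far;
}

// [[Rcpp::export(name = ".diameter_path_cpp")]]
IntegerMatrix diameter_path_cpp(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  int start = -1;
  for (int i = 0; i < nr * nc; ++i) if (img[i]) { start = i; break; }
  if (start < 0) return IntegerMatrix(0, 2);
  std::vector<int> parent;
  int u = bfs_far(img, start, parent);
  int v = bfs_far(img, u, parent);
  std::vector<int> path;
  for (int p = v; p != -1; p = parent[p]) path.push_back(p);
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    out(i, 0) = path[i] % nr + 1;  // row
    out(i, 1) = path[i] / nr + 1;  // col
  }
  return out;
}
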