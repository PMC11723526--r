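// Low-level raster operations used by the post-processing stage:
// connected-component labelling, exact Euclidean distance transform,
// Zhang-Suen thinning, and marker-controlled watershed flooding.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* DR = (connectivity == 8) ? DR8 : DR4;
  const int* DC = (connectivity == 8) ? DC8 : DC4;
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  // row-major scan so label ids follow reading order
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + DR[k], cc = p.second + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance from each foreground pixel to nearest background
// pixel. Background pixels map to 0. Pixels outside the image border are NOT
// treated as background.
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix d2(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      d2(r, c) = (mask(r, c) != 0) ? INF : 0.0;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int c = 0; c < W; ++c) {            // columns
    for (int r = 0; r < H; ++r) f[r] = d2(r, c);
    dt1d(f, d, H);
    for (int r = 0; r < H; ++r) d2(r, c) = d[r];
  }
  for (int r = 0; r < H; ++r) {            // rows
    for (int c = 0; c < W; ++c) f[c] = d2(r, c);
    dt1d(f, d, W);
    for (int c = 0; c < W; ++c) d2(r, c) = std::sqrt(d[c]);
  }
  return d2;
}

// Zhang-Suen thinning: iterative two-subcycle boundary peeling until
// stable, followed by a sequential unit-width pruning pass that removes
// remaining 8-simple non-endpoint pixels (Zhang-Suen can leave two-pixel
// staircases on shallow diagonals, which would read as spurious
// junctions during branch decomposition).
// [[Rcpp::export(name = ".thin_zs")]]
IntegerMatrix thin_zs(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img = clone(mask);
  for (int i = 0; i < H * W; ++i) img[i] = img[i] != 0 ? 1 : 0;
  std::vector<std::pair<int,int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (img(r, c) == 0) continue;
          // neighbours P2..P9 clockwise from north; outside counts as 0
          int p[8];
          p[0] = (r > 0) ? img(r - 1, c) : 0;                       // N
          p[1] = (r > 0 && c < W - 1) ? img(r - 1, c + 1) : 0;      // NE
          p[2] = (c < W - 1) ? img(r, c + 1) : 0;                   // E
          p[3] = (r < H - 1 && c < W - 1) ? img(r + 1, c + 1) : 0;  // SE
          p[4] = (r < H - 1) ? img(r + 1, c) : 0;                   // S
          p[5] = (r < H - 1 && c > 0) ? img(r + 1, c - 1) : 0;      // SW
          p[6] = (c > 0) ? img(r, c - 1) : 0;                       // W
          p[7] = (r > 0 && c > 0) ? img(r - 1, c - 1) : 0;          // NW
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k) A += (p[k] == 0 && p[(k + 1) % 8] == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t i = 0; i < del.size(); ++i) img(del[i].first, del[i].second) = 0;
      }
    }
  }
  // sequential unit-width pruning: a pixel with >= 2 neighbours whose
  // neighbour ring forms a single connected run (crossing number 1) is
  // redundant for both connectivity and extent; removing it one at a
  // time (raster order, immediate effect) until stable leaves a strictly
  // one-pixel-wide, topology-equivalent skeleton.
  bool pruning = true;
  while (pruning) {
    pruning = false;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        if (img(r, c) == 0) continue;
        int p[8];
        p[0] = (r > 0) ? img(r - 1, c) : 0;
        p[1] = (r > 0 && c < W - 1) ? img(r - 1, c + 1) : 0;
        p[2] = (c < W - 1) ? img(r, c + 1) : 0;
        p[3] = (r < H - 1 && c < W - 1) ? img(r + 1, c + 1) : 0;
        p[4] = (r < H - 1) ? img(r + 1, c) : 0;
        p[5] = (r < H - 1 && c > 0) ? img(r + 1, c - 1) : 0;
        p[6] = (c > 0) ? img(r, c - 1) : 0;
        p[7] = (r > 0 && c > 0) ? img(r - 1, c - 1) : 0;
        int B = 0, A = 0;
        for (int k = 0; k < 8; ++k) B += p[k];
        for (int k = 0; k < 8; ++k) A += (p[k] == 0 && p[(k + 1) % 8] == 1);
        if (B >= 2 && A == 1) {
          img(r, c) = 0;
          pruning = true;
        }
      }
    }
  }
  return img;
}

// Constant-width stroke along a continuous polyline: pixels whose distance
// to the densely-sampled path is at most `half`. Rendering from the
// continuous path (not its pixelation) keeps angled strokes at their
// nominal width. Points are 1-based (row, col); sampling must be dense
// (<= ~0.5 px spacing) for the distance to be effectively exact.
// [[Rcpp::export(name = ".stroke_mask")]]
IntegerMatrix stroke_mask(const NumericMatrix& pts, double half,
                          int H, int W) {
  NumericMatrix d2(H, W);
  const double BIG = 1e18;
  std::fill(d2.begin(), d2.end(), BIG);
  const double reach = half + 1.0;
  for (int k = 0; k < pts.nrow(); ++k) {
    const double r0 = pts(k, 0), c0 = pts(k, 1);
    const int rlo = std::max(1, (int)std::floor(r0 - reach));
    const int rhi = std::min(H, (int)std::ceil(r0 + reach));
    const int clo = std::max(1, (int)std::floor(c0 - reach));
    const int chi = std::min(W, (int)std::ceil(c0 + reach));
    for (int r = rlo; r <= rhi; ++r) {
      for (int c = clo; c <= chi; ++c) {
        const double dd = (r - r0) * (r - r0) + (c - c0) * (c - c0);
        if (dd < d2(r - 1, c - 1)) d2(r - 1, c - 1) = dd;
      }
    }
  }
  IntegerMatrix mask(H, W);
  const double h2 = half * half;
  for (int i = 0; i < H * W; ++i) mask[i] = d2[i] <= h2 ? 1 : 0;
  return mask;
}

struct WsNode {
  double relief;
  long seq;
  int r, c;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.relief != b.relief) return a.relief > b.relief;  // min-heap
    return a.seq > b.seq;                                  // FIFO within level
  }
};

// Marker-controlled watershed. markers: 0 = unknown, >=1 = marker labels
// (1 background, 2..K+1 nuclei). relief: flooding height map. Floods the
// unknown region in non-decreasing relief order with deterministic FIFO
// tie-breaking. A pixel whose already-labelled 4-neighbours carry two or
// more distinct NUCLEUS labels (>= 2) becomes watershed line (-1): lines
// separate object floods from each other, never an object from the
// background flood (a single marked disk yields no line).
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(const IntegerMatrix& markers,
                              const NumericMatrix& relief) {
  const int H = markers.nrow(), W = markers.ncol();
  IntegerMatrix lab = clone(markers);  // working label field; -1 = WL
  IntegerMatrix queued(H, W);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long seq = 0;
  // seed: unknown pixels 4-adjacent to any marker, row-major order
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (lab(r, c) != 0) continue;
      bool adj = false;
      for (int k = 0; k < 4 && !adj; ++k) {
        int rr = r + DR4[k], cc = c + DC4[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (lab(rr, cc) > 0) adj = true;
      }
      if (adj) {
        WsNode n;
        n.relief = relief(r, c);
        n.seq = seq++;
        n.r = r;
        n.c = c;
        pq.push(n);
        queued(r, c) = 1;
      }
    }
  }
  while (!pq.empty()) {
    WsNode n = pq.top();
    pq.pop();
    const int r = n.r, c = n.c;
    if (lab(r, c) != 0) continue;
    int first_nuc = 0;               // first nucleus label seen (>= 2)
    bool conflict = false, sawWL = false, sawBg = false;
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR4[k], cc = c + DC4[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int l = lab(rr, cc);
      if (l >= 2) {
        if (first_nuc == 0) first_nuc = l;
        else if (l != first_nuc) conflict = true;
      } else if (l == 1) {
        sawBg = true;
      } else if (l == -1) {
        sawWL = true;
      }
    }
    if (conflict) lab(r, c) = -1;
    else if (first_nuc > 0) lab(r, c) = first_nuc;
    else if (sawBg) lab(r, c) = 1;
    else if (sawWL) lab(r, c) = -1;  // walled in by watershed line
    else continue;                   // stale entry; unreachable in practice
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR4[k], cc = c + DC4[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (lab(rr, cc) == 0 && queued(rr, cc) == 0) {
        WsNode m;
        m.relief = relief(rr, cc);
        m.seq = seq++;
        m.r = rr;
        m.c = cc;
        pq.push(m);
        queued(rr, cc) = 1;
      }
    }
  }
  // anything still unknown is separated from all markers; mark as WL
  for (int i = 0; i < H * W; ++i)
    if (lab[i] == 0 && markers[i] == 0) lab[i] = -1;
  // pixels that were never adjacent to the flood (markers==0 disconnected)
  // have been handled above; marker pixels keep their labels
  return lab;
}
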