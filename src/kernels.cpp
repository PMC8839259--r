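// Hot numerical kernels: non-flat ellipsoidal grayscale morphology,
// nearest-neighbour hole filling, deformation-grid interpolation,
// per-column vertical warping, masked pairwise column correlation, and the
// greedy move queue of the band-straightening optimizer. Matrices follow
// R's column-major layout; row index = y (migration axis), col index = x.
#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <deque>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Sparse table for O(1) range-min / range-max queries on each image
// column; used to prune the rolling-ellipsoid footprint search.
struct RangeTable {
  int H, W, L;
  bool use_max;
  std::vector<double> t;  // level-major: t[l][x][y]
  void build(const double *I, int H_, int W_, bool use_max_) {
    H = H_; W = W_; use_max = use_max_;
    L = 1; while ((1 << L) <= H) ++L;
    t.assign((size_t)L * W * H, 0.0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) t[(size_t)x * H + y] = I[(size_t)x * H + y];
    for (int l = 1; l < L; ++l) {
      int half = 1 << (l - 1);
      for (int x = 0; x < W; ++x) {
        const double *prev = t.data() + (size_t)(l - 1) * W * H + (size_t)x * H;
        double *cur = t.data() + (size_t)l * W * H + (size_t)x * H;
        for (int y = 0; y + (1 << l) <= H; ++y) {
          double a = prev[y], b = prev[y + half];
          cur[y] = use_max ? (a > b ? a : b) : (a < b ? a : b);
        }
      }
    }
  }
  inline double query(int x, int lo, int hi) const {
    int len = hi - lo + 1;
    int k = 31 - __builtin_clz(len);
    const double *lev = t.data() + (size_t)k * W * H + (size_t)x * H;
    double a = lev[lo], b = lev[hi - (1 << k) + 1];
    return use_max ? (a > b ? a : b) : (a < b ? a : b);
  }
};

// ---------------------------------------------------------------------------
// Nearest-neighbour inpainting: every missing pixel takes the value of the
// nearest (4-connected BFS, i.e. Manhattan-nearest) non-missing pixel.
// [[Rcpp::export]]
NumericMatrix cpp_fill_nearest(NumericMatrix I, LogicalMatrix miss) {
  int H = I.nrow(), W = I.ncol();
  NumericMatrix out(H, W);
  std::vector<char> seen((size_t)H * W, 0);
  std::deque<int> q;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int id = x * H + y;
      if (!miss(y, x)) {
        out[id] = I[id];
        seen[id] = 1;
        q.push_back(id);
      }
    }
  if (q.empty()) stop("lane has no non-missing pixel");
  while (!q.empty()) {
    int id = q.front(); q.pop_front();
    int y = id % H, x = id / H;
    const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int ny = y + dy[k], nx = x + dx[k];
      if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
      int nid = nx * H + ny;
      if (!seen[nid]) {
        seen[nid] = 1;
        out[nid] = out[id];
        q.push_back(nid);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rolling-ellipsoid background: grayscale opening with the non-flat
// structuring function b(dx,dy) = rz * sqrt(1 - (dx/rx)^2 - (dy/ry)^2),
// i.e. the upper envelope reachable by an ellipsoid with radii (rx,ry,rz)
// rolling beneath the intensity surface. Supports are truncated at the
// image border (min/max over available pixels), which preserves bg <= I.
// [[Rcpp::export]]
NumericMatrix cpp_roll_ellipsoid(NumericMatrix I, double rx, double ry,
                                 double rz) {
  if (rx <= 0 || ry <= 0 || rz <= 0) stop("ellipsoid radii must be positive");
  int H = I.nrow(), W = I.ncol();
  int Rx = (int)std::floor(rx);
  // Per-dx vertical half-extent and structuring-function column.
  std::vector<int> dyMax(2 * Rx + 1);
  std::vector< std::vector<double> > btab(2 * Rx + 1);
  for (int dx = -Rx; dx <= Rx; ++dx) {
    double u = 1.0 - (double)dx * dx / (rx * rx);
    int dym = (u <= 0) ? -1 : (int)std::floor(ry * std::sqrt(u));
    dyMax[dx + Rx] = dym;
    if (dym >= 0) {
      std::vector<double> col(2 * dym + 1);
      for (int dy = -dym; dy <= dym; ++dy) {
        double v = u - (double)dy * dy / (ry * ry);
        col[dy + dym] = rz * std::sqrt(v > 0 ? v : 0.0);
      }
      btab[dx + Rx] = col;
    }
  }
  NumericMatrix ero(H, W), bg(H, W);

  // One morphological pass (erosion: sign = -1 / dilation: sign = +1) with
  // footprint pruning: per-column sparse tables give O(1) bounds on what a
  // column offset or dy block could contribute, so exact scans happen only
  // where the result can still improve. dx are visited center-outward, dy
  // in blocks of ascending |dy| (b decreases with |dx| and |dy|).
  const int B = 32;
  auto pass = [&](const double *src, double *dst, int sign) {
    RangeTable rt;
    rt.build(src, H, W, sign > 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double m = sign > 0 ? -INF : INF;
        for (int adx = 0; adx <= Rx; ++adx)
          for (int pm = 0; pm < (adx == 0 ? 1 : 2); ++pm) {
            int dx = pm == 0 ? adx : -adx;
            int c = x + dx;
            if (c < 0 || c >= W) continue;
            int dym = dyMax[dx + Rx];
            if (dym < 0) continue;
            int lo = std::max(0, y - dym), hi = std::min(H - 1, y + dym);
            const double *b = btab[dx + Rx].data() + dym;
            double bmax = b[0];
            double bound = rt.query(c, lo, hi);
            if (sign > 0 ? bound + bmax <= m : bound - bmax >= m) continue;
            const double *col = src + (size_t)c * H;
            for (int d0 = 0; d0 <= dym; d0 += B) {
              int d1 = std::min(d0 + B - 1, dym);
              double bb = b[d0];
              // downward block: dy in [d0, d1]
              int blo = y + d0, bhi = std::min(y + d1, H - 1);
              if (blo <= bhi) {
                double q = rt.query(c, blo, bhi);
                if (sign > 0 ? q + bb > m : q - bb < m) {
                  for (int yy = blo; yy <= bhi; ++yy) {
                    double v = sign > 0 ? col[yy] + b[yy - y]
                                        : col[yy] - b[yy - y];
                    if (sign > 0 ? v > m : v < m) m = v;
                  }
                }
              }
              // upward block: dy in [-d1, -max(d0, 1)] (dy = 0 was already
              // covered by the first downward block)
              blo = std::max(y - d1, 0); bhi = y - std::max(d0, 1);
              if (blo <= bhi) {
                double q = rt.query(c, blo, bhi);
                if (sign > 0 ? q + bb > m : q - bb < m) {
                  for (int yy = blo; yy <= bhi; ++yy) {
                    double v = sign > 0 ? col[yy] + b[y - yy]
                                        : col[yy] - b[y - yy];
                    if (sign > 0 ? v > m : v < m) m = v;
                  }
                }
              }
            }
          }
        dst[(size_t)x * H + y] = m;
      }
  };

  pass(REAL(I), REAL(ero), -1);   // erosion
  pass(REAL(ero), REAL(bg), +1);  // dilation of the eroded image
  return bg;
}

// ---------------------------------------------------------------------------
// Bilinear interpolation of a deformation grid onto an H x W pixel field.
// node_y / node_x are node coordinates in pixels (0-based, strictly
// increasing, spanning [0, H-1] / [0, W-1]); shifts is rg x cg.
// center_rows subtracts each pixel row's mean (the zero-mean-shift-per-row
// constraint projection used by the optimizer).
static void grid_field_into(std::vector<double> &field, int H, int W,
                            const NumericVector &node_y,
                            const NumericVector &node_x,
                            const double *shifts, int rg, int cg,
                            bool center_rows) {
  // Precompute per-row and per-column segment index + weight.
  std::vector<int> si(H), sj(W);
  std::vector<double> wi(H), wj(W);
  for (int y = 0; y < H; ++y) {
    int i = 0;
    while (i < rg - 2 && node_y[i + 1] < y) ++i;
    double h = node_y[i + 1] - node_y[i];
    double t = h > 0 ? ((double)y - node_y[i]) / h : 0.0;
    si[y] = i; wi[y] = std::min(1.0, std::max(0.0, t));
  }
  for (int x = 0; x < W; ++x) {
    int j = 0;
    while (j < cg - 2 && node_x[j + 1] < x) ++j;
    double h = node_x[j + 1] - node_x[j];
    double t = h > 0 ? ((double)x - node_x[j]) / h : 0.0;
    sj[x] = j; wj[x] = std::min(1.0, std::max(0.0, t));
  }
  for (int x = 0; x < W; ++x) {
    int j = sj[x]; double tx = wj[x];
    for (int y = 0; y < H; ++y) {
      int i = si[y]; double ty = wi[y];
      double v00 = shifts[j * rg + i], v10 = shifts[j * rg + i + 1];
      double v01 = shifts[(j + 1) * rg + i], v11 = shifts[(j + 1) * rg + i + 1];
      field[(size_t)x * H + y] =
        (1 - ty) * ((1 - tx) * v00 + tx * v01) +
        ty * ((1 - tx) * v10 + tx * v11);
    }
  }
  if (center_rows) {
    for (int y = 0; y < H; ++y) {
      double m = 0;
      for (int x = 0; x < W; ++x) m += field[(size_t)x * H + y];
      m /= W;
      for (int x = 0; x < W; ++x) field[(size_t)x * H + y] -= m;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_grid_field(int H, int W, NumericVector node_y,
                             NumericVector node_x, NumericMatrix shifts,
                             bool center_rows) {
  int rg = shifts.nrow(), cg = shifts.ncol();
  if ((int)node_y.size() != rg || (int)node_x.size() != cg)
    stop("node coordinate / shift dimension mismatch");
  if (rg < 2 || cg < 2) stop("deformation grid must be at least 2 x 2");
  std::vector<double> field((size_t)H * W);
  grid_field_into(field, H, W, node_y, node_x, REAL(shifts), rg, cg,
                  center_rows);
  NumericMatrix out(H, W);
  std::copy(field.begin(), field.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Per-column vertical warp. Forward map t(y) = y + dY(x,y); the warped
// image is built by linear interpolation of the inverse map (first crossing
// from the top when the forward map folds). Targets outside [t(0), t(H-1)]
// or whose source interval touches a missing pixel are missing.
static void warp_columns_into(std::vector<double> &WI, std::vector<char> &WM,
                              const double *I, const int *miss, int H, int W,
                              const std::vector<double> &field) {
  std::vector<double> t(H);
  for (int x = 0; x < W; ++x) {
    const double *col = I + (size_t)x * H;
    const int *mcol = miss + (size_t)x * H;
    const double *f = field.data() + (size_t)x * H;
    for (int y = 0; y < H; ++y) t[y] = y + f[y];
    int k = 0;
    for (int yt = 0; yt < H; ++yt) {
      size_t id = (size_t)x * H + yt;
      if (yt < t[0] || yt > t[H - 1]) { WM[id] = 1; WI[id] = NA_REAL; continue; }
      while (k < H - 2 && t[k + 1] < yt) ++k;
      // rewind if previous target was further down the column than this one
      while (k > 0 && t[k] > yt) --k;
      double denom = t[k + 1] - t[k];
      double a = denom > 1e-12 ? (yt - t[k]) / denom : 0.0;
      if (a < 0) a = 0; if (a > 1) a = 1;
      // an endpoint with zero weight does not contribute, so its missing
      // status is irrelevant (keeps the zero field an exact identity)
      if (a <= 1e-9 && !mcol[k]) { WM[id] = 0; WI[id] = col[k]; }
      else if (a >= 1 - 1e-9 && !mcol[k + 1]) { WM[id] = 0; WI[id] = col[k + 1]; }
      else if (mcol[k] || mcol[k + 1]) { WM[id] = 1; WI[id] = NA_REAL; }
      else { WM[id] = 0; WI[id] = (1 - a) * col[k] + a * col[k + 1]; }
    }
  }
}

// [[Rcpp::export]]
List cpp_warp_columns(NumericMatrix I, LogicalMatrix miss,
                      NumericMatrix field) {
  int H = I.nrow(), W = I.ncol();
  if (field.nrow() != H || field.ncol() != W || miss.nrow() != H ||
      miss.ncol() != W)
    stop("lane / field dimension mismatch");
  std::vector<double> f(REAL(field), REAL(field) + (size_t)H * W);
  std::vector<double> WI((size_t)H * W);
  std::vector<char> WM((size_t)H * W);
  warp_columns_into(WI, WM, REAL(I), LOGICAL(miss), H, W, f);
  NumericMatrix outI(H, W);
  LogicalMatrix outM(H, W);
  for (size_t i = 0; i < WI.size(); ++i) { outI[i] = WI[i]; outM[i] = WM[i]; }
  return List::create(_["intensity"] = outI, _["missing"] = outM);
}

// ---------------------------------------------------------------------------
// Mean clamped pairwise Pearson correlation of lane columns over shared
// non-missing rows. Pairs with overlap < min_overlap or zero variance are
// excluded; negative correlations are clamped to 0 before averaging.
// Returns -1 when no valid pair exists. The per-pair masked sums come from
// four BLAS crossproducts of the zero-filled intensity matrix Z, its
// elementwise square and the 0/1 observation matrix M:
//   n = M'M, sum_x = Z'M, sum_x2 = Z2'M, sum_xy = Z'Z
// (all restricted to rows where both columns are observed, because Z is
// zero wherever M is zero).
struct CorrWork {
  std::vector<double> Z, Z2, M, Pn, Psx, Psxx, Psxy;
};

static double colcorr_mean(const std::vector<double> &I,
                           const std::vector<char> &miss, int H, int W,
                           int min_overlap, CorrWork &wk) {
  size_t n = (size_t)H * W;
  wk.Z.resize(n); wk.Z2.resize(n); wk.M.resize(n);
  for (size_t k = 0; k < n; ++k) {
    if (miss[k]) { wk.Z[k] = 0; wk.Z2[k] = 0; wk.M[k] = 0; }
    else { wk.Z[k] = I[k]; wk.Z2[k] = I[k] * I[k]; wk.M[k] = 1; }
  }
  size_t w2 = (size_t)W * W;
  wk.Pn.resize(w2); wk.Psx.resize(w2); wk.Psxx.resize(w2); wk.Psxy.resize(w2);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &W, &W, &H, &one, wk.M.data(), &H, wk.M.data(),
                  &H, &zero, wk.Pn.data(), &W FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &W, &W, &H, &one, wk.Z.data(), &H, wk.M.data(),
                  &H, &zero, wk.Psx.data(), &W FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &W, &W, &H, &one, wk.Z2.data(), &H, wk.M.data(),
                  &H, &zero, wk.Psxx.data(), &W FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &W, &W, &H, &one, wk.Z.data(), &H, wk.Z.data(),
                  &H, &zero, wk.Psxy.data(), &W FCONE FCONE);
  double acc = 0; long nvalid = 0;
  for (int i = 0; i < W - 1; ++i)
    for (int j = i + 1; j < W; ++j) {
      double np = wk.Pn[(size_t)j * W + i];
      if (np < min_overlap || np < 2) continue;
      double sx = wk.Psx[(size_t)j * W + i];   // sum x_i over shared rows
      double sy = wk.Psx[(size_t)i * W + j];   // sum x_j over shared rows
      double sxx = wk.Psxx[(size_t)j * W + i];
      double syy = wk.Psxx[(size_t)i * W + j];
      double sxy = wk.Psxy[(size_t)j * W + i];
      double vx = np * sxx - sx * sx, vy = np * syy - sy * sy;
      if (vx <= 1e-12 * np * np || vy <= 1e-12 * np * np) continue;
      double r = (np * sxy - sx * sy) / std::sqrt(vx * vy);
      if (r < 0) r = 0; if (r > 1) r = 1;
      acc += r; ++nvalid;
    }
  if (nvalid == 0) return -1.0;
  return acc / nvalid;
}

// [[Rcpp::export]]
double cpp_colcorr_mean(NumericMatrix I, LogicalMatrix miss, int min_overlap) {
  int H = I.nrow(), W = I.ncol();
  std::vector<double> vi(REAL(I), REAL(I) + (size_t)H * W);
  std::vector<char> vm((size_t)H * W);
  for (size_t k = 0; k < vm.size(); ++k) vm[k] = (char)LOGICAL(miss)[k];
  CorrWork wk;
  return colcorr_mean(vi, vm, H, W, min_overlap, wk);
}

// ---------------------------------------------------------------------------
// Full energy evaluation used by the optimizer. Keeps its own buffers so a
// pass makes no R allocations.
class Energy {
public:
  Energy(const NumericMatrix &I_, const LogicalMatrix &miss_,
         const NumericVector &ny, const NumericVector &nx, int rg_, int cg_,
         double wx_, double wy_, double p_, int min_overlap_)
    : I(REAL(I_), REAL(I_) + (size_t)I_.nrow() * I_.ncol()),
      H(I_.nrow()), W(I_.ncol()), node_y(ny), node_x(nx), rg(rg_), cg(cg_),
      wx(wx_), wy(wy_), p(p_), min_overlap(min_overlap_),
      field((size_t)H * W), WI((size_t)H * W), WM((size_t)H * W),
      miss((size_t)H * W), imiss((size_t)H * W) {
    for (size_t k = 0; k < miss.size(); ++k) {
      miss[k] = (char)LOGICAL(miss_)[k];
      imiss[k] = LOGICAL(miss_)[k];
    }
  }

  double operator()(const double *shifts) {
    grid_field_into(field, H, W, node_y, node_x, shifts, rg, cg, true);
    warp_columns_into(WI, WM, I.data(), imiss.data(), H, W, field);
    double cbar = colcorr_mean(WI, WM, H, W, min_overlap, corr);
    double ext = (cbar < 0) ? 1.0 : std::pow(1.0 - cbar, p);
    double sx = 0, sy = 0;
    for (int x = 0; x < W - 1; ++x)
      for (int y = 0; y < H; ++y)
        sx += std::fabs(field[(size_t)(x + 1) * H + y] -
                        field[(size_t)x * H + y]);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H - 1; ++y)
        sy += std::fabs(field[(size_t)x * H + y + 1] -
                        field[(size_t)x * H + y]);
    return ext + wx * sx + wy * sy;
  }

private:
  std::vector<double> I;
public:
  int H, W;
private:
  NumericVector node_y, node_x;
  int rg, cg;
  double wx, wy, p;
  int min_overlap;
  std::vector<double> field, WI;
  std::vector<char> WM, miss;
  std::vector<int> imiss;
  CorrWork corr;
};

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix I, LogicalMatrix miss,
                        NumericVector node_y, NumericVector node_x,
                        NumericMatrix shifts, double wx, double wy, double p,
                        int min_overlap) {
  Energy E(I, miss, node_y, node_x, shifts.nrow(), shifts.ncol(), wx, wy, p,
           min_overlap);
  return E(REAL(shifts));
}

// ---------------------------------------------------------------------------
// One pass of the greedy move queue for a single move type (grid size).
// perm: 0-based linear node indices (column-major) giving the random
// permutation that seeds the queue. Accepted moves append the node's
// in-bounds 4-neighbours (no dedup) and trigger the 0.5x / 1.5x shift
// refinement; the lowest-energy candidate wins, ties resolved toward the
// smaller shift. Returns the updated shifts, final energy, the sequence of
// accepted-move energies, and the acceptance count.
// [[Rcpp::export]]
List cpp_run_pass(NumericMatrix I, LogicalMatrix miss, NumericVector node_y,
                  NumericVector node_x, NumericMatrix shifts, double delta,
                  double wx, double wy, double p, int min_overlap,
                  IntegerVector perm, double cur_energy) {
  int rg = shifts.nrow(), cg = shifts.ncol();
  if (cg < 2) stop("degenerate deformation grid: fewer than 2 columns");
  Energy E(I, miss, node_y, node_x, rg, cg, wx, wy, p, min_overlap);
  std::vector<double> S(REAL(shifts), REAL(shifts) + (size_t)rg * cg);
  std::vector<double> cand((size_t)rg * cg), best((size_t)rg * cg);
  std::deque<int> q(perm.begin(), perm.end());
  std::vector<double> accepted;
  double Ecur = cur_energy;
  int n_accept = 0;

  auto propose = [&](std::vector<double> &dst, int gr, int gc, double d) {
    dst = S;
    double off = -d / (cg - 1);
    for (int j = 0; j < cg; ++j) dst[(size_t)j * rg + gr] += off;
    // node k itself gets +d, not the counter-shift
    dst[(size_t)gc * rg + gr] = S[(size_t)gc * rg + gr] + d;
  };

  while (!q.empty()) {
    int k = q.front(); q.pop_front();
    int gr = k % rg, gc = k / rg;
    for (int si = 0; si < 2; ++si) {
      double s = (si == 0) ? -1.0 : 1.0;
      propose(cand, gr, gc, s * delta);
      double Ec = E(cand.data());
      if (Ec < Ecur) {
        double bestE = Ec; best = cand; double bestMag = 1.0;
        // refinement: smaller (0.5x) and larger (1.5x) shifts from the
        // pre-move state; ties go to the smaller shift
        propose(cand, gr, gc, 0.5 * s * delta);
        double Eh = E(cand.data());
        if (Eh <= bestE) { bestE = Eh; best = cand; bestMag = 0.5; }
        propose(cand, gr, gc, 1.5 * s * delta);
        double El = E(cand.data());
        if (El < bestE) { bestE = El; best = cand; bestMag = 1.5; }
        (void)bestMag;
        S = best; Ecur = bestE; ++n_accept;
        accepted.push_back(Ecur);
        // enqueue in-bounds 4-neighbours of k
        if (gr > 0) q.push_back(k - 1);
        if (gr < rg - 1) q.push_back(k + 1);
        if (gc > 0) q.push_back(k - rg);
        if (gc < cg - 1) q.push_back(k + rg);
      }
    }
  }
  NumericMatrix outS(rg, cg);
  std::copy(S.begin(), S.end(), outS.begin());
  return List::create(_["shifts"] = outS, _["energy"] = Ecur,
                      _["accepted"] = NumericVector(accepted.begin(),
                                                    accepted.end()),
                      _["n_accept"] = n_accept);
}

// ---------------------------------------------------------------------------
// Block-mean downsampling ignoring missing pixels; an all-missing block
// stays missing.
// [[Rcpp::export]]
List cpp_block_mean(NumericMatrix I, LogicalMatrix miss, int fr, int fc) {
  int H = I.nrow(), W = I.ncol();
  if (fr < 1 || fc < 1) stop("downsampling factors must be >= 1");
  if (fr > H || fc > W) stop("downsampling factor exceeds lane dimensions");
  int Ho = (H + fr - 1) / fr, Wo = (W + fc - 1) / fc;
  NumericMatrix out(Ho, Wo);
  LogicalMatrix outm(Ho, Wo);
  for (int bx = 0; bx < Wo; ++bx)
    for (int by = 0; by < Ho; ++by) {
      double s = 0; int n = 0;
      int y1 = std::min(H, (by + 1) * fr), x1 = std::min(W, (bx + 1) * fc);
      for (int x = bx * fc; x < x1; ++x)
        for (int y = by * fr; y < y1; ++y)
          if (!miss(y, x)) { s += I(y, x); ++n; }
      if (n == 0) { out(by, bx) = NA_REAL; outm(by, bx) = 1; }
      else { out(by, bx) = s / n; outm(by, bx) = 0; }
    }
  return List::create(_["intensity"] = out, _["missing"] = outm);
}
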