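#include <Rcpp.h>
#include <deque>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shared helpers for voxel graph traversal on 2D/3D grids stored in
// column-major order (R array layout). All indices arriving from R are
// 1-based; they are converted to 0-based linear offsets here.

namespace {

struct Grid {
  int nd;          // 2 or 3
  int dim[3];      // nx, ny, nz (nz = 1 in 2D)
  long n;          // total voxels

  Grid(const IntegerVector &d) {
    nd = d.size();
    if (nd != 2 && nd != 3) stop("grid must be 2D or 3D");
    dim[0] = d[0]; dim[1] = d[1]; dim[2] = (nd == 3) ? d[2] : 1;
    n = (long)dim[0] * dim[1] * dim[2];
  }
  inline long lin(int x, int y, int z) const {
    return (long)x + (long)dim[0] * ((long)y + (long)dim[1] * z);
  }
  inline void coords(long i, int &x, int &y, int &z) const {
    x = (int)(i % dim[0]); i /= dim[0];
    y = (int)(i % dim[1]); z = (int)(i / dim[1]);
  }
};

// Neighbour offsets for the requested connectivity.
// 2D: 4 or 8; 3D: 6 or 26.
std::vector<std::array<int,3> > neighbour_offsets(int nd, int connectivity) {
  std::vector<std::array<int,3> > off;
  if (nd == 2) {
    if (connectivity != 4 && connectivity != 8)
      stop("2D connectivity must be 4 or 8");
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0) continue;
        if (connectivity == 4 && std::abs(dx) + std::abs(dy) != 1) continue;
        off.push_back({{dx, dy, 0}});
      }
  } else {
    if (connectivity != 6 && connectivity != 26)
      stop("3D connectivity must be 6 or 26");
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
            continue;
          off.push_back({{dx, dy, dz}});
        }
  }
  return off;
}

struct Box {
  int lo[3], hi[3];  // 0-based inclusive bounds
  Box(const IntegerVector &lo1, const IntegerVector &hi1, const Grid &g) {
    for (int k = 0; k < 3; ++k) { lo[k] = 0; hi[k] = g.dim[k] - 1; }
    for (int k = 0; k < lo1.size() && k < 3; ++k) {
      lo[k] = lo1[k] - 1;
      hi[k] = hi1[k] - 1;
      if (lo[k] < 0 || hi[k] >= g.dim[k] || lo[k] > hi[k])
        stop("bounding box outside grid");
    }
  }
  inline bool contains(int x, int y, int z) const {
    return x >= lo[0] && x <= hi[0] && y >= lo[1] && y <= hi[1] &&
           z >= lo[2] && z <= hi[2];
  }
};

// Seed matrix (n x nd, 1-based coords) -> linear indices, checked in-box.
std::vector<long> seed_indices(const IntegerMatrix &seeds, const Grid &g,
                               const Box &b) {
  if (seeds.nrow() == 0) stop("seeds must be nonempty");
  if (seeds.ncol() != g.nd) stop("seed coordinates do not match grid dimension");
  std::vector<long> idx;
  idx.reserve(seeds.nrow());
  for (int i = 0; i < seeds.nrow(); ++i) {
    int x = seeds(i, 0) - 1;
    int y = seeds(i, 1) - 1;
    int z = (g.nd == 3) ? seeds(i, 2) - 1 : 0;
    if (x < 0 || x >= g.dim[0] || y < 0 || y >= g.dim[1] ||
        z < 0 || z >= g.dim[2])
      stop("seed outside grid");
    if (!b.contains(x, y, z)) stop("seed outside bounding box");
    idx.push_back(g.lin(x, y, z));
  }
  return idx;
}

} // namespace

// Seeded region growing (queue-based). A candidate x joins the region A iff
// it is connectivity-adjacent to A, lies inside the bounding box,
// I(x) >= threshold, and |I(x) - mean(A)| < delta.
// mean_mode: 0 = frozen at the seed mean (order independent),
//            1 = running mean, FIFO over lexicographically ordered seeds.
// [[Rcpp::export]]
LogicalVector cpp_grow(NumericVector img, IntegerVector dim,
                       IntegerMatrix seeds, double threshold, double delta,
                       int connectivity, int mean_mode,
                       IntegerVector bbox_lo, IntegerVector bbox_hi) {
  Grid g(dim);
  if ((long)img.size() != g.n) stop("image length does not match dim");
  Box box(bbox_lo, bbox_hi, g);
  std::vector<long> sidx = seed_indices(seeds, g, box);
  std::sort(sidx.begin(), sidx.end());
  sidx.erase(std::unique(sidx.begin(), sidx.end()), sidx.end());
  for (long i : sidx) {
    if (!(img[i] >= threshold))
      stop("seed intensity below threshold");
    if (!R_finite(img[i])) stop("non-finite intensity at seed");
  }
  std::vector<char> inA(g.n, 0), seen(g.n, 0);
  std::deque<long> q;
  double sum = 0.0;
  long cnt = 0;
  for (long i : sidx) {
    inA[i] = 1; seen[i] = 1;
    sum += img[i]; ++cnt;
    q.push_back(i);
  }
  const double frozen_mean = sum / cnt;
  auto offs = neighbour_offsets(g.nd, connectivity);

  while (!q.empty()) {
    long cur = q.front(); q.pop_front();
    int x, y, z; g.coords(cur, x, y, z);
    for (const auto &o : offs) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!box.contains(nx, ny, nz)) continue;
      long ni = g.lin(nx, ny, nz);
      if (inA[ni]) continue;
      if (mean_mode == 0 && seen[ni]) continue;  // frozen: verdict is final
      double v = img[ni];
      if (!R_finite(v)) { seen[ni] = 1; continue; }
      double mean = (mean_mode == 0) ? frozen_mean : (sum / cnt);
      bool ok = (v >= threshold) && (std::abs(v - mean) < delta);
      seen[ni] = 1;
      if (ok) {
        inA[ni] = 1;
        sum += v; ++cnt;
        q.push_back(ni);
      }
      // running mode: a rejected voxel may be revisited later when an
      // adjacent voxel joins A; it will then be re-examined from that voxel
      else if (mean_mode == 1) {
        seen[ni] = 0;
      }
    }
  }
  LogicalVector out(img.size());
  for (long i = 0; i < g.n; ++i) out[i] = (bool)inA[i];
  out.attr("dim") = dim;
  return out;
}

// Connected component(s) of {img >= threshold} containing the seeds,
// restricted to the bounding box. Pure threshold + connectivity (no delta):
// this is the A(T) used by the per-slice threshold search. Seeds whose
// intensity falls below the threshold simply do not contribute.
// [[Rcpp::export]]
LogicalVector cpp_threshold_component(NumericVector img, IntegerVector dim,
                                      IntegerMatrix seeds, double threshold,
                                      int connectivity,
                                      IntegerVector bbox_lo,
                                      IntegerVector bbox_hi) {
  Grid g(dim);
  if ((long)img.size() != g.n) stop("image length does not match dim");
  Box box(bbox_lo, bbox_hi, g);
  std::vector<long> sidx = seed_indices(seeds, g, box);
  std::vector<char> inA(g.n, 0);
  std::deque<long> q;
  for (long i : sidx) {
    if (R_finite(img[i]) && img[i] >= threshold && !inA[i]) {
      inA[i] = 1;
      q.push_back(i);
    }
  }
  auto offs = neighbour_offsets(g.nd, connectivity);
  while (!q.empty()) {
    long cur = q.front(); q.pop_front();
    int x, y, z; g.coords(cur, x, y, z);
    for (const auto &o : offs) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!box.contains(nx, ny, nz)) continue;
      long ni = g.lin(nx, ny, nz);
      if (inA[ni]) continue;
      double v = img[ni];
      if (R_finite(v) && v >= threshold) {
        inA[ni] = 1;
        q.push_back(ni);
      }
    }
  }
  LogicalVector out(img.size());
  for (long i = 0; i < g.n; ++i) out[i] = (bool)inA[i];
  out.attr("dim") = dim;
  return out;
}

// Area (voxel count) of the seed-connected thresholded component; cheap
// version used inside the bisection search.
// [[Rcpp::export]]
int cpp_threshold_component_area(NumericVector img, IntegerVector dim,
                                 IntegerMatrix seeds, double threshold,
                                 int connectivity, IntegerVector bbox_lo,
                                 IntegerVector bbox_hi) {
  LogicalVector m = cpp_threshold_component(img, dim, seeds, threshold,
                                            connectivity, bbox_lo, bbox_hi);
  int a = 0;
  for (R_xlen_t i = 0; i < m.size(); ++i) if (m[i]) ++a;
  return a;
}

// Connected component of a binary mask containing the seeds (union over
// seeds). Seeds outside the mask contribute nothing.
// [[Rcpp::export]]
LogicalVector cpp_mask_component(LogicalVector mask, IntegerVector dim,
                                 IntegerMatrix seeds, int connectivity) {
  Grid g(dim);
  if ((long)mask.size() != g.n) stop("mask length does not match dim");
  IntegerVector lo(g.nd, 1), hi(g.nd);
  for (int k = 0; k < g.nd; ++k) hi[k] = g.dim[k];
  Box box(lo, hi, g);
  std::vector<long> sidx = seed_indices(seeds, g, box);
  std::vector<char> inA(g.n, 0);
  std::deque<long> q;
  for (long i : sidx) {
    if (mask[i] && !inA[i]) { inA[i] = 1; q.push_back(i); }
  }
  auto offs = neighbour_offsets(g.nd, connectivity);
  while (!q.empty()) {
    long cur = q.front(); q.pop_front();
    int x, y, z; g.coords(cur, x, y, z);
    for (const auto &o : offs) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (nx < 0 || nx >= g.dim[0] || ny < 0 || ny >= g.dim[1] ||
          nz < 0 || nz >= g.dim[2]) continue;
      long ni = g.lin(nx, ny, nz);
      if (!inA[ni] && mask[ni]) { inA[ni] = 1; q.push_back(ni); }
    }
  }
  LogicalVector out(mask.size());
  for (long i = 0; i < g.n; ++i) out[i] = (bool)inA[i];
  out.attr("dim") = dim;
  return out;
}

// Inverse region growing: grow the background from every bounding-box
// boundary voxel that is not in the mask (pure connectivity, no intensity
// test); the complement of that background inside the box fills every
// enclosed cavity. Voxels outside the box are returned unchanged from the
// input mask.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim,
                             int connectivity, IntegerVector bbox_lo,
                             IntegerVector bbox_hi) {
  Grid g(dim);
  if ((long)mask.size() != g.n) stop("mask length does not match dim");
  Box box(bbox_lo, bbox_hi, g);
  std::vector<char> bg(g.n, 0);
  std::deque<long> q;
  // enqueue box-boundary voxels not in the mask
  for (int z = box.lo[2]; z <= box.hi[2]; ++z)
    for (int y = box.lo[1]; y <= box.hi[1]; ++y)
      for (int x = box.lo[0]; x <= box.hi[0]; ++x) {
        bool boundary = (x == box.lo[0] || x == box.hi[0] ||
                         y == box.lo[1] || y == box.hi[1]);
        if (g.nd == 3)
          boundary = boundary || z == box.lo[2] || z == box.hi[2];
        if (!boundary) continue;
        long i = g.lin(x, y, z);
        if (!mask[i] && !bg[i]) { bg[i] = 1; q.push_back(i); }
      }
  auto offs = neighbour_offsets(g.nd, connectivity);
  while (!q.empty()) {
    long cur = q.front(); q.pop_front();
    int x, y, z; g.coords(cur, x, y, z);
    for (const auto &o : offs) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (!box.contains(nx, ny, nz)) continue;
      long ni = g.lin(nx, ny, nz);
      if (!bg[ni] && !mask[ni]) { bg[ni] = 1; q.push_back(ni); }
    }
  }
  LogicalVector out(mask.size());
  for (long i = 0; i < g.n; ++i) out[i] = (bool)mask[i];
  for (int z = box.lo[2]; z <= box.hi[2]; ++z)
    for (int y = box.lo[1]; y <= box.hi[1]; ++y)
      for (int x = box.lo[0]; x <= box.hi[0]; ++x) {
        long i = g.lin(x, y, z);
        if (!bg[i]) out[i] = true;
      }
  out.attr("dim") = dim;
  return out;
}

// 2D median filter with odd square kernel and reflected edges.
// Brute-force per-pixel sort; kernels in this pipeline are tiny (3-7 px).
// [[Rcpp::export]]
NumericMatrix cpp_median2d(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel width must be odd and >= 1");
  int nx = img.nrow(), ny = img.ncol(), r = k / 2;
  NumericMatrix out(nx, ny);
  if (k == 1) { out = clone(img); return out; }
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      buf.clear();
      for (int dy = -r; dy <= r; ++dy) {
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx, yy = y + dy;
          // reflect (without repeating the edge sample)
          if (nx == 1) xx = 0;
          else while (xx < 0 || xx >= nx) {
            if (xx < 0) xx = -xx;
            if (xx >= nx) xx = 2 * nx - 2 - xx;
          }
          if (ny == 1) yy = 0;
          else while (yy < 0 || yy >= ny) {
            if (yy < 0) yy = -yy;
            if (yy >= ny) yy = 2 * ny - 2 - yy;
          }
          buf.push_back(img(xx, yy));
        }
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(x, y) = buf[mid];
    }
  }
  return out;
}
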