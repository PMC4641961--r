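#include <Rcpp.h>
#include <set>
#include <vector>
#include <utility>
#include <cmath>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Best-first seeded region growing on a grayscale raster.
//
// The region starts at a single seed pixel. A frontier of 4-connected
// neighbours is maintained; at every step the frontier pixel whose
// intensity is closest to the *running* region mean is admitted, the mean
// is updated, and its unvisited 4-neighbours join the frontier. Growth
// stops when the best frontier pixel differs from the mean by more than
// `tol`. Ties in |intensity - mean| are broken by row-major scan order
// (smallest (row, col) first) so the result is fully deterministic.
//
// The frontier is kept in an ordered set of (intensity, scan_key) pairs so
// the closest-to-mean lookup is O(log n) even though the mean drifts.
// [[Rcpp::export]]
LogicalMatrix rg_grow_cpp(NumericMatrix img, int seed_row, int seed_col,
                          double tol) {
  const int H = img.nrow(), W = img.ncol();
  if (seed_row < 0 || seed_row >= H || seed_col < 0 || seed_col >= W)
    stop("seed outside image");
  LogicalMatrix in_region(H, W);
  std::vector<uint8_t> in_frontier((size_t)H * W, 0);

  typedef std::pair<double, long long> Entry;  // (intensity, row-major key)
  std::set<Entry> frontier;

  double sum = img(seed_row, seed_col);
  long long n = 1;
  in_region(seed_row, seed_col) = true;

  // push a pixel onto the frontier if new
  #define PUSH(r, c)                                                  \
    do {                                                              \
      int rr = (r), cc = (c);                                         \
      if (rr >= 0 && rr < H && cc >= 0 && cc < W) {                   \
        size_t li = (size_t)rr + (size_t)cc * H;                      \
        if (!in_region(rr, cc) && !in_frontier[li]) {                 \
          in_frontier[li] = 1;                                        \
          frontier.insert(Entry(img(rr, cc),                          \
                                (long long)rr * W + cc));             \
        }                                                             \
      }                                                               \
    } while (0)

  PUSH(seed_row - 1, seed_col);
  PUSH(seed_row + 1, seed_col);
  PUSH(seed_row, seed_col - 1);
  PUSH(seed_row, seed_col + 1);

  while (!frontier.empty()) {
    const double mu = sum / (double)n;
    // nearest intensity >= mu (its smallest scan key comes first because
    // the set is ordered by (intensity, key))
    std::set<Entry>::iterator above =
        frontier.lower_bound(Entry(mu, LLONG_MIN));
    std::set<Entry>::iterator pick = frontier.end();
    double d_above = R_PosInf, d_below = R_PosInf;
    if (above != frontier.end()) d_above = std::fabs(above->first - mu);
    std::set<Entry>::iterator below = frontier.end();
    if (above != frontier.begin()) {
      std::set<Entry>::iterator prev = above;
      --prev;
      // first entry holding the same intensity -> smallest scan key
      below = frontier.lower_bound(Entry(prev->first, LLONG_MIN));
      d_below = std::fabs(below->first - mu);
    }
    if (d_above < d_below) {
      pick = above;
    } else if (d_below < d_above) {
      pick = below;
    } else {  // equal distance: smaller scan key wins
      if (above == frontier.end())
        pick = below;
      else if (below == frontier.end())
        pick = above;
      else
        pick = (below->second < above->second) ? below : above;
    }
    if (pick == frontier.end()) break;
    const double delta = std::fabs(pick->first - mu);
    if (delta > tol) break;

    const long long key = pick->second;
    const int r = (int)(key / W), c = (int)(key % W);
    frontier.erase(pick);
    in_frontier[(size_t)r + (size_t)c * H] = 0;
    in_region(r, c) = true;
    sum += img(r, c);
    n += 1;
    PUSH(r - 1, c);
    PUSH(r + 1, c);
    PUSH(r, c - 1);
    PUSH(r, c + 1);
  }
  #undef PUSH
  return in_region;
}

// Connected component labelling of a logical raster (stack-based fill),
// 4- or 8-connectivity. Labels are assigned in row-major order of first
// encounter, from 1.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int r0 = 0; r0 < H; ++r0) {
    for (int c0 = 0; c0 < W; ++c0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.push_back(r0 + c0 * H);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % H, c = idx / H;
        const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
        const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
        const int nn = (connectivity == 8) ? 8 : 4;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}
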