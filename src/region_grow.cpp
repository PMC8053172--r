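#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Region-growing candidate selection for off-resonance phasor resolution.
//
// ang1/ang2: candidate phasor angles (radians) per voxel; mag: magnitude
// used for visit ordering; mask: voxels to resolve. Growth starts at the
// seed voxel with the given candidate choice; each visited voxel adopts
// the candidate whose phasor is closest in angle to the mean phasor of its
// already-resolved 8-neighbors. The frontier is processed in descending
// magnitude order (ties broken by linear index for determinism).
// [[Rcpp::export]]
IntegerMatrix rg_resolve(NumericMatrix ang1, NumericMatrix ang2,
                         NumericMatrix mag, LogicalMatrix mask,
                         int seed_r, int seed_c, int seed_choice) {
  const int nr = ang1.nrow(), nc = ang1.ncol();
  IntegerMatrix sel(nr, nc);
  std::vector<bool> queued((size_t)nr * nc, false);

  typedef std::pair<double, int> Node; // (magnitude, linear index)
  std::priority_queue<Node> pq;

  auto push_neighbors = [&](int r, int c) {
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        size_t li = (size_t)rr + (size_t)cc * nr;
        if (!mask(rr, cc) || sel(rr, cc) != 0 || queued[li]) continue;
        queued[li] = true;
        pq.push(Node(mag(rr, cc), -(int)li)); // -li: low index wins ties
      }
    }
  };

  if (seed_r < 0 || seed_r >= nr || seed_c < 0 || seed_c >= nc ||
      !mask(seed_r, seed_c))
    stop("seed voxel outside mask");
  sel(seed_r, seed_c) = seed_choice;
  push_neighbors(seed_r, seed_c);

  while (!pq.empty()) {
    int li = -pq.top().second;
    pq.pop();
    int r = li % nr, c = li / nr;
    if (sel(r, c) != 0) continue;
    // mean phasor of resolved neighbors
    double sx = 0.0, sy = 0.0;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int ch = sel(rr, cc);
        if (ch == 0) continue;
        double a = (ch == 1) ? ang1(rr, cc) : ang2(rr, cc);
        sx += std::cos(a);
        sy += std::sin(a);
      }
    }
    double ref = std::atan2(sy, sx);
    double d1 = std::fabs(std::remainder(ang1(r, c) - ref, 2.0 * M_PI));
    double d2 = std::fabs(std::remainder(ang2(r, c) - ref, 2.0 * M_PI));
    sel(r, c) = (d1 <= d2) ? 1 : 2;
    push_neighbors(r, c);
  }
  return sel;
}
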