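#include <Rcpp.h>
using namespace Rcpp;

// On-lattice diffusion-limited aggregation with a sticking probability.
//
// Walkers are launched from a circle just outside the cluster, take
// unit steps on the square lattice (4-neighbourhood), are re-launched
// when they stray beyond the kill radius, never step onto occupied
// sites, and stick to their current site with probability `stickiness`
// whenever a 4-neighbour is occupied. Uses R's RNG so results are
// reproducible under set.seed().
//
// Returns an n x 2 integer matrix of site coordinates in deposition
// order; the first row is the central seed site.
// [[Rcpp::export]]
IntegerMatrix dla_grow_cpp(int n_particles, double stickiness) {
  if (n_particles < 1) stop("n_particles must be >= 1");
  if (stickiness <= 0.0 || stickiness > 1.0)
    stop("stickiness must be in (0, 1]");

  // generous grid: cluster radius grows ~ n^(1/1.71)
  int gh = (int)std::ceil(2.6 * std::pow((double)n_particles, 0.6)) + 10;
  int W = 2 * gh + 1;
  std::vector<char> grid((size_t)W * W, 0);
  IntegerMatrix out(n_particles, 2);

  int cc = gh;  // center offset
  auto at = [&](int x, int y) -> char& {
    return grid[(size_t)(y + cc) * W + (x + cc)];
  };
  auto neighbor_occupied = [&](int x, int y) -> bool {
    return at(x + 1, y) || at(x - 1, y) || at(x, y + 1) || at(x, y - 1);
  };

  at(0, 0) = 1;
  out(0, 0) = 0; out(0, 1) = 0;
  double rmax = 0.0;

  for (int p = 1; p < n_particles; ++p) {
    double launch = rmax + 5.0;
    double kill = std::min(3.0 * launch, (double)(gh - 2));
    int x = 0, y = 0;
    bool placed = false;
    while (!placed) {
      double th = 2.0 * M_PI * unif_rand();
      x = (int)std::lround(launch * std::cos(th));
      y = (int)std::lround(launch * std::sin(th));
      if (at(x, y)) continue;  // extremely unlikely
      for (;;) {
        // stick before moving if already adjacent
        if (neighbor_occupied(x, y) && unif_rand() < stickiness) {
          at(x, y) = 1;
          out(p, 0) = x; out(p, 1) = y;
          double r = std::sqrt((double)x * x + (double)y * y);
          if (r > rmax) rmax = r;
          placed = true;
          break;
        }
        double u = unif_rand();
        int nx = x, ny = y;
        if (u < 0.25) ++nx;
        else if (u < 0.5) --nx;
        else if (u < 0.75) ++ny;
        else --ny;
        double r2 = (double)nx * nx + (double)ny * ny;
        if (r2 > kill * kill) break;  // lost: relaunch
        if (!at(nx, ny)) { x = nx; y = ny; }
      }
    }
  }
  return out;
}
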