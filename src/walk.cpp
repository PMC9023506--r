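#include <Rcpp.h>
using namespace Rcpp;

// Fold a radius back inside [0, r] by successive reflections at the wall.
static inline double fold_radius(double rad, double r) {
  while (rad > r) rad = 2.0 * r - rad;
  // over-folding past the center reflects through it; keep magnitude
  return rad < 0.0 ? -rad : rad;
}

// Reflected random walk inside a circular well.
//
// moved:  0/1 per frame (movement already drawn in R).
// bias:   per-frame vertical bias in [-1, 1]; P(step up) = (1 + bias) / 2.
// u_dir:  U(0,1) draws deciding the vertical step sign.
// sx:     +/-1 horizontal step signs (symmetric, drawn in R).
// mag_x, mag_y: step magnitudes in mm (drawn in R).
// r:      containment radius in mm.
// x0, y0: initial position (inside the circle).
//
// Returns an n x 2 matrix of positions after each frame; frames without
// movement repeat the previous position exactly.
// [[Rcpp::export]]
NumericMatrix walk_core(IntegerVector moved, NumericVector bias,
                        NumericVector u_dir, NumericVector sx,
                        NumericVector mag_x, NumericVector mag_y,
                        double r, double x0, double y0) {
  const int n = moved.size();
  NumericMatrix pos(n, 2);
  double x = x0, y = y0;
  for (int i = 0; i < n; ++i) {
    if (moved[i]) {
      double sy = (u_dir[i] < (1.0 + bias[i]) / 2.0) ? 1.0 : -1.0;
      double nx = x + sx[i] * mag_x[i];
      double ny = y + sy * mag_y[i];
      double rad = std::sqrt(nx * nx + ny * ny);
      if (rad > r) {
        // radial fold: keep the heading, reflect the radius at the wall
        double scale = fold_radius(rad, r) / rad;
        nx *= scale;
        ny *= scale;
      }
      x = nx;
      y = ny;
    }
    pos(i, 0) = x;
    pos(i, 1) = y;
  }
  return pos;
}
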