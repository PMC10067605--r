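#ifndef FLEXREACH_CORE_H
#define FLEXREACH_CORE_H

#include <RcppArmadillo.h>
#include <cstdint>
#include <cmath>

// ---------------------------------------------------------------------------
// Geometry of the planar 3-DoF limb (torso, upper arm, lower arm) plus the
// fixed virtual camera (identity mapping: workspace coordinates are pixels).
// ---------------------------------------------------------------------------
struct Geom {
  double L[3];       // segment lengths, px
  double lo[3];      // joint lower limits, rad
  double hi[3];      // joint upper limits, rad
  double base[2];    // anchored neck position, px
  double w[3];       // segment half-widths, px
  int W, H;          // image size (width x height)
};

inline Geom geom_from_list(const Rcpp::List& g) {
  Geom gm;
  Rcpp::NumericVector L = g["lengths"], lo = g["lower"], hi = g["upper"],
    base = g["base"], w = g["widths"];
  for (int i = 0; i < 3; ++i) {
    gm.L[i] = L[i]; gm.lo[i] = lo[i]; gm.hi[i] = hi[i]; gm.w[i] = w[i];
  }
  gm.base[0] = base[0]; gm.base[1] = base[1];
  gm.W = Rcpp::as<int>(g["img_width"]);
  gm.H = Rcpp::as<int>(g["img_height"]);
  return gm;
}

// chain of 4 points: neck, shoulder, elbow, hand
inline void fk_chain(const Geom& g, const double* th, double P[4][2]) {
  P[0][0] = g.base[0]; P[0][1] = g.base[1];
  double phi = 0.0;
  for (int i = 0; i < 3; ++i) {
    phi += th[i];
    P[i + 1][0] = P[i][0] + g.L[i] * std::cos(phi);
    P[i + 1][1] = P[i][1] + g.L[i] * std::sin(phi);
  }
}

// d P_i / d theta_j = perp(P_i - P_{j-1}) for j <= i (1-indexed chain pts)
inline void chain_jacobian_hand(const double P[4][2], double J[2][3]) {
  for (int j = 0; j < 3; ++j) {
    double vx = P[3][0] - P[j][0], vy = P[3][1] - P[j][1];
    J[0][j] = -vy; J[1][j] = vx;
  }
}

inline double clampd(double x, double a, double b) {
  return x < a ? a : (x > b ? b : x);
}

// ---------------------------------------------------------------------------
// PCG32 RNG + Box-Muller normals: deterministic across platforms.
// ---------------------------------------------------------------------------
struct Pcg32 {
  uint64_t state, inc;
  bool has_spare; double spare;
  Pcg32(uint64_t seed = 42u, uint64_t seq = 54u) { init(seed, seq); }
  void init(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
    has_spare = false; spare = 0.0;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { // (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
  // ziggurat normal (Marsaglia-Tsang, 128 layers): ~4x faster than
  // Box-Muller; used in the bulk visual-noise path
  double normal_fast();
};

// fused per-step visual computation for the analytic model: renders the
// hard observation, the soft prediction and the pixel noise on the fly,
// accumulating the belief-space pullback of the (noisy) image error and the
// squared error norm without materializing any image. Draw order per pixel:
// planes 0,1,2 (only when sigma_v > 0).
void fused_visual_pass(const Geom& g, const double* theta_true, double tcx,
                       double tcy, double radius, bool visible,
                       const double* mu6, double blur_limb, double blur_tgt,
                       double halo_amp, double halo_width, bool occlude,
                       double sigma_v, Pcg32& rng, double* pb6,
                       double* err_norm2);

// ---------------------------------------------------------------------------
// Rasterizer core. Internal image layout: channel-major matrix (3 x W*H),
// spatial index = iy*W + ix, pixel centers at (ix + .5, iy + .5).
// Channel 0 = target (red), channel 1 = unused, channel 2 = limb (blue).
// ---------------------------------------------------------------------------
// target drawn as a disc centered at (tgt_cx, tgt_cy) in pixel coordinates
void render_core(const Geom& g, const double* th_arm, double tgt_cx,
                 double tgt_cy, double radius, bool target_visible, bool hard,
                 double blur_limb, double blur_tgt, double halo_amp,
                 double halo_width, bool occlude, arma::mat& out);

void soft_pullback_core(const Geom& g, const double* mu6, const arma::mat& err,
                        double radius, double blur_limb, double blur_tgt,
                        double halo_amp, double halo_width, bool occlude,
                        double* grad6);

// Convert internal (3 x W*H) layout to R layout vector dim c(3, W, H):
// element (p, x, y) at p + 3*(x + W*y). Internal col = y*W + x, row = p.
inline Rcpp::NumericVector to_r_image(const arma::mat& img, int W, int H) {
  Rcpp::NumericVector out(3 * W * H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      for (int p = 0; p < 3; ++p)
        out[p + 3 * (x + W * y)] = img(p, y * W + x);
  out.attr("dim") = Rcpp::IntegerVector::create(3, W, H);
  return out;
}

inline arma::mat from_r_image(const Rcpp::NumericVector& v, int W, int H) {
  arma::mat img(3, W * H);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x)
      for (int p = 0; p < 3; ++p)
        img(p, y * W + x) = v[p + 3 * (x + W * y)];
  return img;
}

// Gradient (wrt the 6-d latent; only target rows nonzero) of the summed
// squared prediction outside the camera frame: the model predicts on an
// unbounded plane, and out-of-view pixels carry structural zero
// observations. Suppressing them removes the boundary-clip bias of the
// in-frame gradient for targets near the frame edge.
void frame_suppression_core(const Geom& g, const double* mu6, double radius,
                            double blur_tgt, double halo_amp,
                            double halo_width, int pad, double* grad6);

// Damped-least-squares inverse kinematics for the hand position.
// Returns final error; th is updated in place (clamped to limits).
double ik_solve(const Geom& g, const double* target_xy, double* th,
                int max_iter, double damp, double tol);

// ---------------------------------------------------------------------------
// VAE: architecture bundled with weights on the R side; C++ receives the
// weight list (16 arrays); channel dims are inferred from shapes. See vae.cpp.
// Opaque-handle interface for the trial runner:
// ---------------------------------------------------------------------------
void* vae_open(const Rcpp::List& weights);
void vae_close(void* h);
void vae_decode_internal(void* h, const Geom& g, const double* mu6,
                         arma::mat& out);
void vae_pullback_internal(void* h, const Geom& g, const double* mu6,
                           const arma::mat& err, double* grad6);

#endif

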