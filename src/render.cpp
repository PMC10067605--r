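// Scene rasterizer: the generative process's visual channel (hard edges) and
// the analytic visual model's decoder (soft edges, exact adjoint).
//
// The limb is three capsules (rectangles with circular joints/tips), drawn on
// the blue plane; the target is a disc on the red plane, occluded by the limb
// (limb drawn last). Soft intensities are logistic in the signed distance to
// the primitive boundary; the adjoint backpropagates through capsule/disc
// distances and the kinematic chain.

#include "core.h"
using namespace Rcpp;

static inline double sig(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// distance from p to segment a-b; sets t (clamped projection parameter)
// and unit vector u = (p - q)/d where q is the closest point
static inline double seg_dist(double px, double py, double ax, double ay,
                              double bx, double by, double& t,
                              double& ux, double& uy) {
  double dx = bx - ax, dy = by - ay;
  double l2 = dx * dx + dy * dy;
  t = l2 > 0 ? clampd(((px - ax) * dx + (py - ay) * dy) / l2, 0.0, 1.0) : 0.0;
  double qx = ax + t * dx, qy = ay + t * dy;
  double ex = px - qx, ey = py - qy;
  double d = std::sqrt(ex * ex + ey * ey);
  if (d > 1e-12) { ux = ex / d; uy = ey / d; } else { ux = 0.0; uy = 0.0; }
  return d;
}

// soft target blob: logistic-edged disc (core) soft-OR'd with a faint wide
// Gaussian halo that extends the gradient's capture range
static inline double tgt_soft(double d, double radius, double tau,
                              double halo_amp, double halo_w, double& dIdd) {
  double A = 0.0, dA = 0.0, B = 0.0, dB = 0.0;
  if (d - radius < 7.5 * tau) {   // support cutoff, identical everywhere
    A = sig((radius - d) / tau);
    dA = -A * (1.0 - A) / tau;
  }
  if (halo_amp > 0.0) {
    double q = d / halo_w;
    if (q < 3.5) {
      B = halo_amp * std::exp(-0.5 * q * q);
      dB = -B * d / (halo_w * halo_w);
    }
  }
  dIdd = (1.0 - B) * dA + (1.0 - A) * dB;
  return 1.0 - (1.0 - A) * (1.0 - B);
}

// matching support radius for bounding boxes
static inline double tgt_support(double radius, double tau, double halo_amp,
                                 double halo_w) {
  double s = radius + 7.5 * tau;
  if (halo_amp > 0) s = std::max(s, 3.5 * halo_w);
  return s;
}

void render_core(const Geom& g, const double* th_arm, double tgt_cx,
                 double tgt_cy, double radius, bool target_visible, bool hard,
                 double blur_limb, double blur_tgt, double halo_amp,
                 double halo_width, bool occlude, arma::mat& out) {
  double P[4][2];
  fk_chain(g, th_arm, P);
  const double cx = tgt_cx, cy = tgt_cy;
  out.set_size(3, g.W * g.H);
  out.zeros();

  // bounding boxes (inflated by half-width + soft tail support)
  double pad_l = hard ? 0.0 : 7.5 * blur_limb;
  double pad_t = hard ? 0.0
    : tgt_support(0, blur_tgt, halo_amp, halo_width);
  double bb[4][4]; // 3 segments + target: xmin, xmax, ymin, ymax
  for (int k = 0; k < 3; ++k) {
    double m = g.w[k] + pad_l + 1.0;
    bb[k][0] = std::min(P[k][0], P[k + 1][0]) - m;
    bb[k][1] = std::max(P[k][0], P[k + 1][0]) + m;
    bb[k][2] = std::min(P[k][1], P[k + 1][1]) - m;
    bb[k][3] = std::max(P[k][1], P[k + 1][1]) + m;
  }
  double mt = radius + pad_t + 1.0;
  bb[3][0] = cx - mt; bb[3][1] = cx + mt; bb[3][2] = cy - mt; bb[3][3] = cy + mt;

  double t, ux, uy;
  for (int iy = 0; iy < g.H; ++iy) {
    double py = iy + 0.5;
    for (int ix = 0; ix < g.W; ++ix) {
      double px = ix + 0.5;
      int idx = iy * g.W + ix;
      double limb = 0.0, inv = 1.0;
      bool any = false;
      for (int k = 0; k < 3; ++k) {
        if (px < bb[k][0] || px > bb[k][1] || py < bb[k][2] || py > bb[k][3])
          continue;
        double d = seg_dist(px, py, P[k][0], P[k][1], P[k + 1][0], P[k + 1][1],
                            t, ux, uy);
        double I;
        if (hard) I = d <= g.w[k] ? 1.0 : 0.0;
        else I = d - g.w[k] < 7.5 * blur_limb
          ? sig((g.w[k] - d) / blur_limb) : 0.0;
        if (I > 0.0) { inv *= (1.0 - I); any = true; }
      }
      if (any) { limb = 1.0 - inv; out(2, idx) = limb; }
      if (target_visible &&
          px >= bb[3][0] && px <= bb[3][1] && py >= bb[3][2] && py <= bb[3][3]) {
        double ex = px - cx, ey = py - cy;
        double d = std::sqrt(ex * ex + ey * ey);
        double dum;
        double I = hard ? (d <= radius ? 1.0 : 0.0)
                        : tgt_soft(d, radius, blur_tgt, halo_amp, halo_width,
                                   dum);
        if (I > 0.0) out(0, idx) = occlude ? I * (1.0 - limb) : I;
      }
    }
  }
}

void soft_pullback_core(const Geom& g, const double* mu6, const arma::mat& err,
                        double radius, double blur_limb, double blur_tgt,
                        double halo_amp, double halo_width, bool occlude,
                        double* grad6) {
  double P[4][2], Q[4][2];
  fk_chain(g, mu6, P);
  fk_chain(g, mu6 + 3, Q);
  const double cx = Q[3][0], cy = Q[3][1];
  for (int j = 0; j < 6; ++j) grad6[j] = 0.0;

  // dP_i/dtheta_j = perp(P_i - P_{j-1}) for j <= i (points 0..3, joints 0..2)
  // target hand gradient dC/dtheta_j = perp(C - Q_j)
  double dC[3][2];
  for (int j = 0; j < 3; ++j) {
    dC[j][0] = -(cy - Q[j][1]);
    dC[j][1] = (cx - Q[j][0]);
  }

  double pad_l = 7.5 * blur_limb;
  double pad_t = tgt_support(0, blur_tgt, halo_amp, halo_width);
  double bb[4][4];
  for (int k = 0; k < 3; ++k) {
    double m = g.w[k] + pad_l + 1.0;
    bb[k][0] = std::min(P[k][0], P[k + 1][0]) - m;
    bb[k][1] = std::max(P[k][0], P[k + 1][0]) + m;
    bb[k][2] = std::min(P[k][1], P[k + 1][1]) - m;
    bb[k][3] = std::max(P[k][1], P[k + 1][1]) + m;
  }
  double mtp = radius + pad_t + 1.0;
  bb[3][0] = cx - mtp; bb[3][1] = cx + mtp; bb[3][2] = cy - mtp; bb[3][3] = cy + mtp;

  for (int iy = 0; iy < g.H; ++iy) {
    double py = iy + 0.5;
    for (int ix = 0; ix < g.W; ++ix) {
      double px = ix + 0.5;
      int idx = iy * g.W + ix;
      double eb = err(2, idx), er = err(0, idx);

      // limb intensities and their angle gradients at this pixel
      double I[3] = {0, 0, 0};
      double dIth[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}}; // [segment][joint]
      bool inlimb = false;
      for (int k = 0; k < 3; ++k) {
        if (px < bb[k][0] || px > bb[k][1] || py < bb[k][2] || py > bb[k][3])
          continue;
        double t, ux, uy;
        double d = seg_dist(px, py, P[k][0], P[k][1], P[k + 1][0], P[k + 1][1],
                            t, ux, uy);
        if (d - g.w[k] >= 7.5 * blur_limb) continue;
        double s = sig((g.w[k] - d) / blur_limb);
        if (s < 1e-12) continue;
        I[k] = s; inlimb = true;
        double dsdd = -s * (1.0 - s) / blur_limb;
        if (dsdd != 0.0) {
          // dd/dtheta_j = -u . ((1-t) dA/dth_j + t dB/dth_j); A = P_k, B = P_{k+1}
          for (int j = 0; j <= k; ++j) {
            double dAx = -(P[k][1] - P[j][1]), dAy = (P[k][0] - P[j][0]);
            double dBx = -(P[k + 1][1] - P[j][1]), dBy = (P[k + 1][0] - P[j][0]);
            double ddx = (1.0 - t) * dAx + t * dBx;
            double ddy = (1.0 - t) * dAy + t * dBy;
            double dd = -(ux * ddx + uy * ddy);
            dIth[k][j] = dsdd * dd;
          }
        }
      }
      double limb = 0.0, dlimb[3] = {0, 0, 0};
      if (inlimb) {
        double inv01 = (1.0 - I[0]) * (1.0 - I[1]);
        limb = 1.0 - inv01 * (1.0 - I[2]);
        // dlimb/dI_k = prod_{m != k} (1 - I_m)
        double f0 = (1.0 - I[1]) * (1.0 - I[2]);
        double f1 = (1.0 - I[0]) * (1.0 - I[2]);
        double f2 = inv01;
        for (int j = 0; j < 3; ++j)
          dlimb[j] = f0 * dIth[0][j] + f1 * dIth[1][j] + f2 * dIth[2][j];
      }

      // blue plane
      if (eb != 0.0 && inlimb)
        for (int j = 0; j < 3; ++j) grad6[j] += eb * dlimb[j];

      // red plane: IT * (1 - limb)
      if (px >= bb[3][0] && px <= bb[3][1] && py >= bb[3][2] && py <= bb[3][3]) {
        double ex = px - cx, ey = py - cy;
        double d = std::sqrt(ex * ex + ey * ey);
        double dITdd;
        double IT = tgt_soft(d, radius, blur_tgt, halo_amp, halo_width,
                             dITdd);
        if (IT > 1e-12 && er != 0.0) {
          // arm part: -IT * dlimb (only when the decoder models occlusion)
          if (occlude && inlimb)
            for (int j = 0; j < 3; ++j) grad6[j] -= er * IT * dlimb[j];
          // target part: (1 - limb) * dIT/dC . dC/dtheta_t
          if (d > 1e-9 && dITdd != 0.0) {
            double ux = ex / d, uy = ey / d;
            // dd/dC = -u
            double gx = dITdd * (-ux), gy = dITdd * (-uy);
            double w = er * (occlude ? (1.0 - limb) : 1.0);
            for (int j = 0; j < 3; ++j)
              grad6[3 + j] += w * (gx * dC[j][0] + gy * dC[j][1]);
          }
        }
      }
    }
  }
}

void frame_suppression_core(const Geom& g, const double* mu6, double radius,
                            double blur_tgt, double halo_amp,
                            double halo_width, int pad, double* grad6) {
  double Q[4][2];
  fk_chain(g, mu6 + 3, Q);
  const double cx = Q[3][0], cy = Q[3][1];
  for (int j = 0; j < 6; ++j) grad6[j] = 0.0;
  double dC[3][2];
  for (int j = 0; j < 3; ++j) {
    dC[j][0] = -(cy - Q[j][1]);
    dC[j][1] = (cx - Q[j][0]);
  }
  // band [-pad, W+pad) x [-pad, H+pad) minus the frame, on a 2 x 2
  // subsampled grid (weight 4): the suppression force is a smooth
  // functional of the blob position and tolerates coarse quadrature
  double sup = tgt_support(radius, blur_tgt, halo_amp, halo_width);
  for (int iy = -pad; iy < g.H + pad; iy += 2) {
    double py = iy + 0.5;
    bool yin = iy >= 0 && iy < g.H;
    for (int ix = -pad; ix < g.W + pad; ix += 2) {
      if (yin && ix >= 0 && ix < g.W) {
        // resume the band right of the frame, preserving stride phase
        ix = ((g.W % 2 == pad % 2) ? g.W : g.W + 1) - 2;
        continue;
      }
      double px = ix + 0.5;
      double ex = px - cx, ey = py - cy;
      if (std::fabs(ex) > sup || std::fabs(ey) > sup) continue;
      double d = std::sqrt(ex * ex + ey * ey);
      if (d > sup || d < 1e-9) continue;
      double dITdd;
      double IT = tgt_soft(d, radius, blur_tgt, halo_amp, halo_width, dITdd);
      if (IT < 1e-12 || dITdd == 0.0) continue;
      // err = 0 - IT; gradient of 1/2 err^2 wrt C pulled into angles
      double ux = ex / d, uy = ey / d;
      double gx = dITdd * (-ux), gy = dITdd * (-uy);
      double w = -4.0 * IT; // subsample weight
      for (int j = 0; j < 3; ++j)
        grad6[3 + j] += w * (gx * dC[j][0] + gy * dC[j][1]);
    }
  }
}

// ---------------------------------------------------------------------------
// ziggurat normal sampler (Marsaglia & Tsang, 128 layers)
// ---------------------------------------------------------------------------
namespace {
struct ZigTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
const ZigTables& zig() { static ZigTables t; return t; }
}

double Pcg32::normal_fast() {
  const ZigTables& t = zig();
  const double r = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)next();
    uint32_t iz = (uint32_t)hz & 127u;
    uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < t.kn[iz]) return hz * t.wn[iz];
    if (iz == 0) { // tail
      double x, y;
      do {
        x = -std::log(unif()) / r;
        y = -std::log(unif());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -(r + x);
    }
    double x = hz * t.wn[iz];
    if (t.fn[iz] + unif() * (t.fn[iz - 1] - t.fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

// ---------------------------------------------------------------------------
// fused per-step visual pass (see core.h)
// ---------------------------------------------------------------------------
void fused_visual_pass(const Geom& g, const double* theta_true, double tcx,
                       double tcy, double radius, bool visible,
                       const double* mu6, double blur_limb, double blur_tgt,
                       double halo_amp, double halo_width, bool occlude,
                       double sigma_v, Pcg32& rng, double* pb6,
                       double* err_norm2) {
  double PT[4][2], P[4][2], Q[4][2];
  fk_chain(g, theta_true, PT);
  fk_chain(g, mu6, P);
  fk_chain(g, mu6 + 3, Q);
  const double mcx = Q[3][0], mcy = Q[3][1];
  for (int j = 0; j < 6; ++j) pb6[j] = 0.0;
  double dC[3][2];
  for (int j = 0; j < 3; ++j) {
    dC[j][0] = -(mcy - Q[j][1]);
    dC[j][1] = (mcx - Q[j][0]);
  }

  // bounding boxes: hard (true) limb, soft (believed) limb, hard disc,
  // soft blob
  double bbh[3][4], bbs[3][4];
  for (int k = 0; k < 3; ++k) {
    double mh = g.w[k] + 1.0;
    bbh[k][0] = std::min(PT[k][0], PT[k + 1][0]) - mh;
    bbh[k][1] = std::max(PT[k][0], PT[k + 1][0]) + mh;
    bbh[k][2] = std::min(PT[k][1], PT[k + 1][1]) - mh;
    bbh[k][3] = std::max(PT[k][1], PT[k + 1][1]) + mh;
    double ms = g.w[k] + 7.5 * blur_limb + 1.0;
    bbs[k][0] = std::min(P[k][0], P[k + 1][0]) - ms;
    bbs[k][1] = std::max(P[k][0], P[k + 1][0]) + ms;
    bbs[k][2] = std::min(P[k][1], P[k + 1][1]) - ms;
    bbs[k][3] = std::max(P[k][1], P[k + 1][1]) + ms;
  }
  double rh = radius + 1.0;
  double rs = tgt_support(radius, blur_tgt, halo_amp, halo_width) + 1.0;

  const bool noisy = sigma_v > 0;
  double n0 = 0, n1 = 0, n2 = 0, norm2 = 0;
  double t, ux, uy;
  for (int iy = 0; iy < g.H; ++iy) {
    double py = iy + 0.5;
    for (int ix = 0; ix < g.W; ++ix) {
      double px = ix + 0.5;
      if (noisy) {
        n0 = sigma_v * rng.normal_fast();
        n1 = sigma_v * rng.normal_fast();
        n2 = sigma_v * rng.normal_fast();
      }
      // ---- observation (hard render)
      double obs_b = 0.0;
      for (int k = 0; k < 3 && obs_b == 0.0; ++k) {
        if (px < bbh[k][0] || px > bbh[k][1] || py < bbh[k][2] ||
            py > bbh[k][3])
          continue;
        double d = seg_dist(px, py, PT[k][0], PT[k][1], PT[k + 1][0],
                            PT[k + 1][1], t, ux, uy);
        if (d <= g.w[k]) obs_b = 1.0;
      }
      double obs_r = 0.0;
      if (visible && obs_b == 0.0 && std::fabs(px - tcx) <= rh &&
          std::fabs(py - tcy) <= rh) {
        double dx = px - tcx, dy = py - tcy;
        if (dx * dx + dy * dy <= radius * radius) obs_r = 1.0;
      }
      if (noisy) {
        obs_r = clampd(obs_r + n0, 0.0, 1.0);
        obs_b = clampd(obs_b + n2, 0.0, 1.0);
      }

      // ---- prediction (soft) + gradients
      double I[3] = {0, 0, 0};
      double dIth[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      bool inlimb = false;
      for (int k = 0; k < 3; ++k) {
        if (px < bbs[k][0] || px > bbs[k][1] || py < bbs[k][2] ||
            py > bbs[k][3])
          continue;
        double d = seg_dist(px, py, P[k][0], P[k][1], P[k + 1][0],
                            P[k + 1][1], t, ux, uy);
        if (d - g.w[k] >= 7.5 * blur_limb) continue;
        double sv = sig((g.w[k] - d) / blur_limb);
        if (sv < 1e-12) continue;
        I[k] = sv;
        inlimb = true;
        double dsdd = -sv * (1.0 - sv) / blur_limb;
        for (int j = 0; j <= k; ++j) {
          double dAx = -(P[k][1] - P[j][1]), dAy = (P[k][0] - P[j][0]);
          double dBx = -(P[k + 1][1] - P[j][1]), dBy = (P[k + 1][0] - P[j][0]);
          double ddx = (1.0 - t) * dAx + t * dBx;
          double ddy = (1.0 - t) * dAy + t * dBy;
          dIth[k][j] = dsdd * -(ux * ddx + uy * ddy);
        }
      }
      double limb = 0.0, dlimb[3] = {0, 0, 0};
      if (inlimb) {
        double inv01 = (1.0 - I[0]) * (1.0 - I[1]);
        limb = 1.0 - inv01 * (1.0 - I[2]);
        double f0 = (1.0 - I[1]) * (1.0 - I[2]);
        double f1 = (1.0 - I[0]) * (1.0 - I[2]);
        double f2 = inv01;
        for (int j = 0; j < 3; ++j)
          dlimb[j] = f0 * dIth[0][j] + f1 * dIth[1][j] + f2 * dIth[2][j];
      }
      double IT = 0.0, dITdd = 0.0, tux = 0.0, tuy = 0.0;
      if (std::fabs(px - mcx) <= rs && std::fabs(py - mcy) <= rs) {
        double dx = px - mcx, dy = py - mcy;
        double d = std::sqrt(dx * dx + dy * dy);
        if (d <= rs - 1.0) {
          IT = tgt_soft(d, radius, blur_tgt, halo_amp, halo_width, dITdd);
          if (d > 1e-9) { tux = dx / d; tuy = dy / d; }
          else dITdd = 0.0;
        }
      }
      double pred_r = occlude ? IT * (1.0 - limb) : IT;

      // ---- errors (plane order 0, 1, 2 as in the R image layout)
      double e0 = obs_r - pred_r;
      double e1 = noisy ? clampd(n1, 0.0, 1.0) : 0.0;
      double e2 = obs_b - limb;
      norm2 += e0 * e0 + e1 * e1 + e2 * e2;

      // ---- pullback
      if (inlimb && e2 != 0.0)
        for (int j = 0; j < 3; ++j) pb6[j] += e2 * dlimb[j];
      if (IT > 1e-12 && e0 != 0.0) {
        if (occlude && inlimb)
          for (int j = 0; j < 3; ++j) pb6[j] -= e0 * IT * dlimb[j];
        if (dITdd != 0.0) {
          double gx = dITdd * (-tux), gy = dITdd * (-tuy);
          double w = e0 * (occlude ? (1.0 - limb) : 1.0);
          for (int j = 0; j < 3; ++j)
            pb6[3 + j] += w * (gx * dC[j][0] + gy * dC[j][1]);
        }
      }
    }
  }
  *err_norm2 = norm2;
}

double ik_solve(const Geom& g, const double* target_xy, double* th,
                int max_iter, double damp, double tol) {
  double P[4][2];
  double err = 1e30;
  for (int it = 0; it < max_iter; ++it) {
    fk_chain(g, th, P);
    double rx = target_xy[0] - P[3][0], ry = target_xy[1] - P[3][1];
    err = std::sqrt(rx * rx + ry * ry);
    if (err < tol) break;
    double J[2][3];
    chain_jacobian_hand(P, J);
    // solve (J J' + damp^2 I) y = r  (2x2), step = J' y
    double a = damp * damp, b = 0.0, c = damp * damp;
    for (int j = 0; j < 3; ++j) {
      a += J[0][j] * J[0][j];
      b += J[0][j] * J[1][j];
      c += J[1][j] * J[1][j];
    }
    double det = a * c - b * b;
    if (det < 1e-12) break;
    double y0 = (c * rx - b * ry) / det, y1 = (a * ry - b * rx) / det;
    for (int j = 0; j < 3; ++j) {
      th[j] += J[0][j] * y0 + J[1][j] * y1;
      th[j] = clampd(th[j], g.lo[j], g.hi[j]);
    }
  }
  fk_chain(g, th, P);
  double rx = target_xy[0] - P[3][0], ry = target_xy[1] - P[3][1];
  return std::sqrt(rx * rx + ry * ry);
}

// ------------------------------- exports -----------------------------------

// [[Rcpp::export]]
NumericVector cpp_render(List geom, NumericVector theta_arm,
                         NumericVector theta_target, double radius,
                         bool target_visible, bool hard,
                         double blur_limb, double blur_target,
                         double halo_amp = 0, double halo_width = 20,
                         bool occlude = true) {
  Geom g = geom_from_list(geom);
  double Q[4][2];
  fk_chain(g, theta_target.begin(), Q);
  arma::mat img;
  render_core(g, theta_arm.begin(), Q[3][0], Q[3][1], radius,
              target_visible, hard, blur_limb, blur_target, halo_amp,
              halo_width, occlude, img);
  return to_r_image(img, g.W, g.H);
}

// [[Rcpp::export]]
NumericVector cpp_soft_pullback(List geom, NumericVector mu6,
                                NumericVector err, double radius,
                                double blur_limb, double blur_target,
                                double halo_amp = 0, double halo_width = 20,
                                bool occlude = true) {
  Geom g = geom_from_list(geom);
  arma::mat E = from_r_image(err, g.W, g.H);
  NumericVector out(6);
  soft_pullback_core(g, mu6.begin(), E, radius, blur_limb, blur_target,
                     halo_amp, halo_width, occlude, out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_frame_suppression(List geom, NumericVector mu6,
                                    double radius, double blur_target,
                                    double halo_amp = 0,
                                    double halo_width = 20, int pad = 60) {
  Geom g = geom_from_list(geom);
  NumericVector out(6);
  frame_suppression_core(g, mu6.begin(), radius, blur_target, halo_amp,
                         halo_width, pad, out.begin());
  return out;
}

// draws from the package RNG (testing hook: validates the ziggurat and
// Box-Muller samplers feeding the simulation noise)
// [[Rcpp::export]]
NumericVector cpp_rng_normal(int n, int seed, bool fast) {
  Pcg32 rng((uint64_t)(unsigned int)seed, 2468u);
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = fast ? rng.normal_fast() : rng.normal();
  return out;
}

// [[Rcpp::export]]
List cpp_ik(List geom, NumericVector target_xy, NumericVector theta_init,
            int max_iter, double damp, double tol) {
  Geom g = geom_from_list(geom);
  NumericVector th = clone(theta_init);
  double err = ik_solve(g, target_xy.begin(), th.begin(), max_iter, damp, tol);
  return List::create(_["theta"] = th, _["error"] = err,
                      _["converged"] = err < tol);
}
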