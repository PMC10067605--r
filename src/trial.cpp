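// Fast inner loop for one trial of the active inference agent.
//
// Implements the same per-step cycle as the R-level agent_step() (predict,
// error, precision-weight, belief update at orders 0/1, action update, world
// step), specialized for speed: analytic soft-rasterizer or VAE decode,
// PCG32 noise, optional moving target with elastic reflection. The R path and
// this runner are equivalence-tested on noiseless trials.

#include "core.h"
using namespace Rcpp;

static const int NCOL = 43;

// [[Rcpp::export]]
NumericMatrix cpp_simulate_trial(List geom, List pars) {
  Geom g = geom_from_list(geom);

  arma::vec theta = as<arma::vec>(pars["theta0"]);
  arma::vec mu = as<arma::vec>(pars["mu0"]);
  arma::vec mup = as<arma::vec>(pars["mu_prime0"]);
  arma::vec act(3, arma::fill::zeros);

  bool moving = as<bool>(pars["moving"]);
  arma::vec th_tgt(3, arma::fill::zeros);
  double tpos[2] = {0, 0}, tvel[2] = {0, 0}, tb[4] = {0, 0, 0, 0};
  if (moving) {
    arma::vec p0 = as<arma::vec>(pars["target_pos"]);
    arma::vec v0 = as<arma::vec>(pars["target_vel"]);
    arma::vec bb = as<arma::vec>(pars["target_bounds"]);
    tpos[0] = p0[0]; tpos[1] = p0[1];
    tvel[0] = v0[0]; tvel[1] = v0[1];
    for (int i = 0; i < 4; ++i) tb[i] = bb[i];
    th_tgt = as<arma::vec>(pars["theta_target"]); // warm start for tracking IK
  } else {
    th_tgt = as<arma::vec>(pars["theta_target"]);
  }

  const double radius = as<double>(pars["radius"]);
  const bool visible = as<bool>(pars["target_visible"]);
  const double alpha = as<double>(pars["alpha"]);
  const double beta = as<double>(pars["beta"]);
  const double lambda = as<double>(pars["lambda"]);
  const double pi_vt = as<double>(pars["pi_vt"]);
  const double vgain = as<double>(pars["visual_gain"]);
  const double lr = as<double>(pars["belief_lr"]);
  const double dta = as<double>(pars["dt_action"]);
  const double dt = as<double>(pars["dt"]);
  const double sig_p = as<double>(pars["sigma_p"]);
  const double sig_v = as<double>(pars["sigma_v"]);
  const double sig_a = as<double>(pars["sigma_a"]);
  const std::string model = as<std::string>(pars["model_type"]);
  const double bl = as<double>(pars["blur_limb"]);
  const double bt = as<double>(pars["blur_target"]);
  const double halo_amp = as<double>(pars["halo_amp"]);
  const int frame_pad = as<int>(pars["frame_pad"]);
  const double halo_width = as<double>(pars["halo_width"]);
  const bool occl = as<bool>(pars["occlusion"]);
  const std::string control = as<std::string>(pars["control"]);
  const std::string onset = as<std::string>(pars["onset"]);
  const int delay = as<int>(pars["delay"]);
  const double on_thr = as<double>(pars["onset_threshold"]);
  const int on_persist = as<int>(pars["onset_persist"]);
  const int n_steps = as<int>(pars["n_steps"]);
  const int seed = as<int>(pars["seed"]);
  const double guard = as<double>(pars["divergence_guard"]);
  const double range_prior = as<double>(pars["range_prior"]);

  void* vae = nullptr;
  if (model == "vae") vae = vae_open(as<List>(pars["weights"]));

  Pcg32 rng((uint64_t)(unsigned int)seed, 2468u);

  const int NP = g.W * g.H;
  arma::mat obs(3, NP), pred(3, NP), errv(3, NP);

  // true target center (static: hand of the target posture)
  double tcx, tcy;
  if (moving) { tcx = tpos[0]; tcy = tpos[1]; }
  else {
    double Q[4][2];
    fk_chain(g, th_tgt.memptr(), Q);
    tcx = Q[3][0]; tcy = Q[3][1];
  }

  double range_mag = 0.0;
  for (int j = 0; j < 3; ++j)
    range_mag = std::max(range_mag, g.hi[j] - g.lo[j]);

  NumericMatrix log(n_steps, NCOL);
  std::fill(log.begin(), log.end(), NA_REAL);
  bool active = (onset == "immediate");
  int below_count = 0;
  bool diverged = false;
  int diverged_step = -1;

  for (int s = 0; s < n_steps; ++s) {
    // ---- observe (proprioception)
    double sp[3];
    for (int j = 0; j < 3; ++j)
      sp[j] = theta[j] + (sig_p > 0 ? sig_p * rng.normal() : 0.0);
    double eps_sp[3];
    for (int j = 0; j < 3; ++j) eps_sp[j] = sp[j] - mu[j];

    // ---- visual channel: observe, predict, error, pullback
    double pb[6];
    double nsv2 = 0.0;
    if (model == "vae") {
      render_core(g, theta.memptr(), tcx, tcy, radius, visible, true, 0, 0,
                  0, 20, true, obs);
      if (sig_v > 0)
        for (int i = 0; i < 3 * NP; ++i)
          obs(i) = clampd(obs(i) + sig_v * rng.normal(), 0.0, 1.0);
      vae_decode_internal(vae, g, mu.memptr(), pred);
      errv = obs - pred;
      vae_pullback_internal(vae, g, mu.memptr(), errv, pb);
      nsv2 = arma::accu(errv % errv);
    } else {
      fused_visual_pass(g, theta.memptr(), tcx, tcy, radius, visible,
                        mu.memptr(), bl, bt, halo_amp, halo_width, occl,
                        sig_v, rng, pb, &nsv2);
      if (frame_pad > 0) {
        double fs[6];
        frame_suppression_core(g, mu.memptr(), radius, bt, halo_amp,
                               halo_width, frame_pad, fs);
        for (int j = 3; j < 6; ++j) pb[j] += fs[j];
      }
    }
    for (int j = 0; j < 6; ++j) pb[j] *= vgain;

    // ---- weighted sensory contribution (belief space)
    arma::vec eps_s(9, arma::fill::zeros);
    for (int j = 0; j < 3; ++j) {
      eps_s[j] = (1.0 - alpha) * eps_sp[j] + alpha * pb[j];
      eps_s[3 + j] = pi_vt * pb[3 + j];
    }
    // joint-range prior: the belief knows the joint limits
    if (range_prior > 0)
      for (int j = 0; j < 9; ++j) {
        double cl = clampd(mu[j], g.lo[j % 3], g.hi[j % 3]);
        eps_s[j] += range_prior * (cl - mu[j]);
      }

    // ---- intentions
    double lam = active ? lambda : 0.0;
    arma::vec e_it(9, arma::fill::zeros), e_ih(9, arma::fill::zeros);
    for (int j = 0; j < 3; ++j) {
      e_it[j] = mu[3 + j] - mu[j];
      e_ih[j] = mu[6 + j] - mu[j];
    }
    arma::vec eps_i = -mup + lam * ((1.0 - beta) * e_it + beta * e_ih);

    // ---- free energy and gradient norms (before the update)
    double nsp = 0, nsv = nsv2;
    for (int j = 0; j < 3; ++j) nsp += eps_sp[j] * eps_sp[j];
    arma::vec em_t = mup - lam * e_it, em_h = mup - lam * e_ih;
    double F = 0.5 * (1.0 - alpha) * nsp + 0.5 * alpha * vgain * nsv +
      0.5 * (1.0 - beta) * arma::dot(em_t, em_t) +
      0.5 * beta * arma::dot(em_h, em_h);
    arma::vec mu_dot = mup + eps_s;

    // ---- log (state before the update, consistent with observation)
    {
      int r = s;
      log(r, 0) = s + 1;
      log(r, 1) = active ? 1.0 : 0.0;
      for (int j = 0; j < 3; ++j) log(r, 2 + j) = theta[j];
      for (int j = 0; j < 9; ++j) log(r, 5 + j) = mu[j];
      for (int j = 0; j < 9; ++j) log(r, 14 + j) = mup[j];
      for (int j = 0; j < 3; ++j) log(r, 23 + j) = act[j];
      double P[4][2], Ph[4][2], Pt[4][2];
      fk_chain(g, theta.memptr(), P);
      fk_chain(g, mu.memptr(), Ph);
      fk_chain(g, mu.memptr() + 3, Pt);
      log(r, 26) = P[3][0]; log(r, 27) = P[3][1];
      log(r, 28) = tcx; log(r, 29) = tcy;
      log(r, 30) = Ph[3][0]; log(r, 31) = Ph[3][1];
      log(r, 32) = Pt[3][0]; log(r, 33) = Pt[3][1];
      log(r, 34) = std::hypot(P[3][0] - tcx, P[3][1] - tcy);
      log(r, 35) = std::hypot(Pt[3][0] - tcx, Pt[3][1] - tcy);
      log(r, 36) = std::sqrt(nsp);
      log(r, 37) = std::sqrt(nsv);
      log(r, 38) = F;
      log(r, 39) = std::sqrt(mu_dot[0] * mu_dot[0] + mu_dot[1] * mu_dot[1] +
                             mu_dot[2] * mu_dot[2]);
      log(r, 40) = std::sqrt(mu_dot[3] * mu_dot[3] + mu_dot[4] * mu_dot[4] +
                             mu_dot[5] * mu_dot[5]);
      log(r, 41) = std::sqrt(eps_i[0] * eps_i[0] + eps_i[1] * eps_i[1] +
                             eps_i[2] * eps_i[2]);
      log(r, 42) = std::sqrt(eps_i[3] * eps_i[3] + eps_i[4] * eps_i[4] +
                             eps_i[5] * eps_i[5]);
    }

    // ---- movement onset policy
    if (!active) {
      if (onset == "fixed") {
        if (s + 1 >= delay) active = true;
      } else if (onset == "dynamic") {
        if (log(s, 40) < on_thr) below_count++; else below_count = 0;
        if (below_count >= on_persist) active = true;
      }
    }

    // ---- belief update (orders 0 and 1)
    mu += lr * mu_dot;
    mup += lr * eps_i;

    // ---- action and world update
    if (active) {
      if (control == "full")
        for (int j = 0; j < 3; ++j) act[j] += -dta * eps_s[j];
      else
        for (int j = 0; j < 3; ++j) act[j] += -dta * (1.0 - alpha) * eps_sp[j];
      for (int j = 0; j < 3; ++j) {
        double thdot = act[j] + (sig_a > 0 ? sig_a * rng.normal() : 0.0);
        double raw = theta[j] + thdot * dt;
        theta[j] = clampd(raw, g.lo[j], g.hi[j]);
        if (raw != theta[j]) act[j] = 0.0; // anti-windup at a joint stop
      }
    }

    // ---- moving target
    if (moving) {
      for (int d = 0; d < 2; ++d) {
        tpos[d] += tvel[d];
        if (tpos[d] < tb[2 * d]) { tpos[d] = 2 * tb[2 * d] - tpos[d]; tvel[d] = -tvel[d]; }
        if (tpos[d] > tb[2 * d + 1]) { tpos[d] = 2 * tb[2 * d + 1] - tpos[d]; tvel[d] = -tvel[d]; }
      }
      tcx = tpos[0]; tcy = tpos[1];
      ik_solve(g, tpos, th_tgt.memptr(), 5, 1.0, 1e-3);
    }

    // ---- divergence guard
    for (int j = 0; j < 9; ++j)
      if (!std::isfinite(mu[j]) || std::fabs(mu[j]) > guard * range_mag) {
        diverged = true; diverged_step = s + 1; break;
      }
    if (diverged) break;
  }

  if (vae) vae_close(vae);
  log.attr("diverged") = diverged;
  log.attr("diverged_step") = diverged_step;
  return log;
}
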