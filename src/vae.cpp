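// Convolutional visual generative model: a supervised VAE whose decoder maps
// the 6-d (arm, target) joint-angle latent to the 3 x 128 x 96 scene and whose
// reverse-mode gradient pulls image errors back into the belief space.
//
// Decoder: 1 fully connected layer -> 2 transposed convolutions (k8 s4 p2)
// -> 2 convolutions (k3 s1 p1), tanh hidden units, sigmoid output.
// Encoder: 2 convolutions (k8 s4 p2) -> fully connected, regressing the
// normalized latent. The recognition-density s.d. is fixed (not learned) and
// enters training as jitter on the decoder's latent input.
//
// Convolutions are im2col gathers + GEMM; transposed convolutions are the
// adjoint (scatter) of the matching convolution, so one index map serves
// forward, backward-data and backward-weight passes.

#include "core.h"
using namespace Rcpp;

// spatial levels: l0 8x6, l1 32x24, l2 128x96
static const int W0s = 8, H0s = 6, N0 = 48;
static const int W1s = 32, H1s = 24, N1 = 768;
static const int W2s = 128, H2s = 96, N2 = 12288;

static std::vector<int> make_map(int Wb, int Hb, int Ws, int Hs, int k, int s,
                                 int p) {
  std::vector<int> map((size_t)Ws * Hs * k * k);
  for (int ys = 0; ys < Hs; ++ys)
    for (int xs = 0; xs < Ws; ++xs) {
      int n = ys * Ws + xs;
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          int yb = ys * s - p + ky, xb = xs * s - p + kx;
          map[(size_t)n * k * k + ky * k + kx] =
            (yb >= 0 && yb < Hb && xb >= 0 && xb < Wb) ? yb * Wb + xb : -1;
        }
    }
  return map;
}

static const std::vector<int>& mapA() { // 32x24 -> 8x6, k8 s4 p2
  static std::vector<int> m = make_map(W1s, H1s, W0s, H0s, 8, 4, 2);
  return m;
}
static const std::vector<int>& mapB() { // 128x96 -> 32x24, k8 s4 p2
  static std::vector<int> m = make_map(W2s, H2s, W1s, H1s, 8, 4, 2);
  return m;
}
static const std::vector<int>& mapC() { // 128x96 -> 128x96, k3 s1 p1
  static std::vector<int> m = make_map(W2s, H2s, W2s, H2s, 3, 1, 1);
  return m;
}

static void gather(const arma::mat& X, const std::vector<int>& map, int k2,
                   int Ns, arma::mat& col) {
  int C = X.n_rows;
  col.set_size(C * k2, Ns);
  for (int n = 0; n < Ns; ++n) {
    const int* mp = map.data() + (size_t)n * k2;
    for (int t = 0; t < k2; ++t) {
      int src = mp[t];
      if (src < 0)
        for (int c = 0; c < C; ++c) col(c * k2 + t, n) = 0.0;
      else
        for (int c = 0; c < C; ++c) col(c * k2 + t, n) = X(c, src);
    }
  }
}

static void scatter(const arma::mat& col, const std::vector<int>& map, int k2,
                    int Ns, int C, int Nb, arma::mat& X) {
  X.zeros(C, Nb);
  for (int n = 0; n < Ns; ++n) {
    const int* mp = map.data() + (size_t)n * k2;
    for (int t = 0; t < k2; ++t) {
      int dst = mp[t];
      if (dst < 0) continue;
      for (int c = 0; c < C; ++c) X(c, dst) += col(c * k2 + t, n);
    }
  }
}

struct VaeNet {
  arma::mat Wfc, W1, W2, W3, W4, V1, V2, Vfc;
  arma::vec bfc, b1, b2, b3, b4, a1, a2, afc;
  int c0, c1, c2, c3, e1, e2;

  void from_list(const List& w) {
    Wfc = as<arma::mat>(w["dec_fc_W"]); bfc = as<arma::vec>(w["dec_fc_b"]);
    W1 = as<arma::mat>(w["dec_t1_W"]); b1 = as<arma::vec>(w["dec_t1_b"]);
    W2 = as<arma::mat>(w["dec_t2_W"]); b2 = as<arma::vec>(w["dec_t2_b"]);
    W3 = as<arma::mat>(w["dec_c3_W"]); b3 = as<arma::vec>(w["dec_c3_b"]);
    W4 = as<arma::mat>(w["dec_c4_W"]); b4 = as<arma::vec>(w["dec_c4_b"]);
    V1 = as<arma::mat>(w["enc_c1_W"]); a1 = as<arma::vec>(w["enc_c1_b"]);
    V2 = as<arma::mat>(w["enc_c2_W"]); a2 = as<arma::vec>(w["enc_c2_b"]);
    Vfc = as<arma::mat>(w["enc_fc_W"]); afc = as<arma::vec>(w["enc_fc_b"]);
    c0 = Wfc.n_rows / N0; c1 = W1.n_cols / 64; c2 = W2.n_cols / 64;
    c3 = W3.n_rows; e1 = V1.n_rows; e2 = V2.n_rows;
  }

  // forward pass with cached activations (for backward)
  struct Cache {
    arma::vec z, h0;
    arma::mat X0, X1, X2, X3, Y;
  };

  void decode(const arma::vec& z, Cache& cc) const {
    cc.z = z;
    cc.h0 = arma::tanh(Wfc * z + bfc);
    cc.X0 = arma::reshape(cc.h0, c0, N0);
    arma::mat colbuf, t;
    t = W1.t() * cc.X0;                       // (c1*64) x 48
    scatter(t, mapA(), 64, N0, c1, N1, cc.X1);
    cc.X1.each_col() += b1;
    cc.X1 = arma::tanh(cc.X1);
    t = W2.t() * cc.X1;                       // (c2*64) x 768
    scatter(t, mapB(), 64, N1, c2, N2, cc.X2);
    cc.X2.each_col() += b2;
    cc.X2 = arma::tanh(cc.X2);
    gather(cc.X2, mapC(), 9, N2, colbuf);
    cc.X3 = W3 * colbuf;
    cc.X3.each_col() += b3;
    cc.X3 = arma::tanh(cc.X3);
    gather(cc.X3, mapC(), 9, N2, colbuf);
    cc.Y = W4 * colbuf;
    cc.Y.each_col() += b4;
    cc.Y = 1.0 / (1.0 + arma::exp(-cc.Y));
  }

  // reverse-mode product J_decode^T * dY; if grads != nullptr also
  // accumulates weight gradients
  arma::vec decode_backward(const Cache& cc, const arma::mat& dY,
                            std::vector<arma::mat>* gW = nullptr,
                            std::vector<arma::vec>* gb = nullptr) const {
    arma::mat colbuf, t;
    arma::mat dp4 = dY % (cc.Y % (1.0 - cc.Y));
    if (gW) {
      gather(cc.X3, mapC(), 9, N2, colbuf);
      (*gW)[4] += dp4 * colbuf.t();
      (*gb)[4] += arma::sum(dp4, 1);
    }
    t = W4.t() * dp4;
    arma::mat dX3;
    scatter(t, mapC(), 9, N2, c3, N2, dX3);
    arma::mat dp3 = dX3 % (1.0 - cc.X3 % cc.X3);
    if (gW) {
      gather(cc.X2, mapC(), 9, N2, colbuf);
      (*gW)[3] += dp3 * colbuf.t();
      (*gb)[3] += arma::sum(dp3, 1);
    }
    t = W3.t() * dp3;
    arma::mat dX2;
    scatter(t, mapC(), 9, N2, c2, N2, dX2);
    arma::mat dp2 = dX2 % (1.0 - cc.X2 % cc.X2);
    gather(dp2, mapB(), 64, N1, colbuf);  // tconv2 backward-data
    arma::mat dX1 = W2 * colbuf;
    if (gW) {
      (*gW)[2] += cc.X1 * colbuf.t();
      (*gb)[2] += arma::sum(dp2, 1);
    }
    arma::mat dp1 = dX1 % (1.0 - cc.X1 % cc.X1);
    gather(dp1, mapA(), 64, N0, colbuf);
    arma::mat dX0 = W1 * colbuf;
    if (gW) {
      (*gW)[1] += cc.X0 * colbuf.t();
      (*gb)[1] += arma::sum(dp1, 1);
    }
    arma::vec dh0 = arma::vectorise(dX0) % (1.0 - cc.h0 % cc.h0);
    if (gW) {
      (*gW)[0] += dh0 * cc.z.t();
      (*gb)[0] += dh0;
    }
    return Wfc.t() * dh0;
  }

  struct ECache {
    arma::mat X, E1, E2;
    arma::vec zhat;
  };

  void encode(const arma::mat& img, ECache& ec) const {
    arma::mat colbuf;
    ec.X = img;
    gather(img, mapB(), 64, N1, colbuf);
    ec.E1 = V1 * colbuf;
    ec.E1.each_col() += a1;
    ec.E1 = arma::tanh(ec.E1);
    gather(ec.E1, mapA(), 64, N0, colbuf);
    ec.E2 = V2 * colbuf;
    ec.E2.each_col() += a2;
    ec.E2 = arma::tanh(ec.E2);
    ec.zhat = Vfc * arma::vectorise(ec.E2) + afc;
  }

  void encode_backward(const ECache& ec, const arma::vec& dz,
                       std::vector<arma::mat>& gW,
                       std::vector<arma::vec>& gb) const {
    arma::mat colbuf;
    gW[7] += dz * arma::vectorise(ec.E2).t();
    gb[7] += dz;
    arma::vec dE2v = Vfc.t() * dz;
    arma::mat dE2 = arma::reshape(dE2v, e2, N0);
    arma::mat dp2 = dE2 % (1.0 - ec.E2 % ec.E2);
    gather(ec.E1, mapA(), 64, N0, colbuf);
    gW[6] += dp2 * colbuf.t();
    gb[6] += arma::sum(dp2, 1);
    arma::mat t = V2.t() * dp2;
    arma::mat dE1;
    scatter(t, mapA(), 64, N0, e1, N1, dE1);
    arma::mat dp1 = dE1 % (1.0 - ec.E1 % ec.E1);
    gather(ec.X, mapB(), 64, N1, colbuf);
    gW[5] += dp1 * colbuf.t();
    gb[5] += arma::sum(dp1, 1);
  }
};

// latent normalization: radians -> [-1, 1] per joint (same limits for the
// arm and target blocks)
static void norm_z(const Geom& g, const double* mu6, arma::vec& z) {
  z.set_size(6);
  for (int j = 0; j < 6; ++j) {
    int jj = j % 3;
    z[j] = 2.0 * (mu6[j] - g.lo[jj]) / (g.hi[jj] - g.lo[jj]) - 1.0;
  }
}

// [[Rcpp::export]]
List cpp_vae_init(int c0, int c1, int c2, int c3, int e1, int e2, int seed) {
  Pcg32 rng((uint64_t)seed, 1234u);
  auto init = [&](int r, int c) {
    arma::mat M(r, c);
    double sd = 1.0 / std::sqrt((double)c);
    for (arma::uword i = 0; i < M.n_elem; ++i) M(i) = sd * rng.normal();
    return M;
  };
  return List::create(
    _["dec_fc_W"] = init(c0 * N0, 6), _["dec_fc_b"] = arma::vec(c0 * N0, arma::fill::zeros),
    _["dec_t1_W"] = init(c0, c1 * 64), _["dec_t1_b"] = arma::vec(c1, arma::fill::zeros),
    _["dec_t2_W"] = init(c1, c2 * 64), _["dec_t2_b"] = arma::vec(c2, arma::fill::zeros),
    _["dec_c3_W"] = init(c3, c2 * 9), _["dec_c3_b"] = arma::vec(c3, arma::fill::zeros),
    _["dec_c4_W"] = init(3, c3 * 9), _["dec_c4_b"] = arma::vec(3, arma::fill::zeros),
    _["enc_c1_W"] = init(e1, 3 * 64), _["enc_c1_b"] = arma::vec(e1, arma::fill::zeros),
    _["enc_c2_W"] = init(e2, e1 * 64), _["enc_c2_b"] = arma::vec(e2, arma::fill::zeros),
    _["enc_fc_W"] = init(6, e2 * N0), _["enc_fc_b"] = arma::vec(6, arma::fill::zeros));
}

// [[Rcpp::export]]
List cpp_vae_train(List weights, List geom, arma::mat ang_arm,
                   arma::mat ang_tgt, arma::vec radii, int epochs, int batch,
                   double lr, double enc_sd, double w_lat, int seed) {
  Geom g = geom_from_list(geom);
  if (g.W != W2s || g.H != H2s)
    stop("the visual model requires a 128 x 96 image frame");
  VaeNet net;
  net.from_list(weights);
  int n = ang_arm.n_rows;

  std::vector<arma::mat*> Ws = {&net.Wfc, &net.W1, &net.W2, &net.W3, &net.W4,
                                &net.V1, &net.V2, &net.Vfc};
  std::vector<arma::vec*> bs = {&net.bfc, &net.b1, &net.b2, &net.b3, &net.b4,
                                &net.a1, &net.a2, &net.afc};
  std::vector<arma::mat> gW(8), mW(8), vW(8);
  std::vector<arma::vec> gb(8), mb(8), vb(8);
  for (int i = 0; i < 8; ++i) {
    mW[i].zeros(Ws[i]->n_rows, Ws[i]->n_cols);
    vW[i].zeros(Ws[i]->n_rows, Ws[i]->n_cols);
    mb[i].zeros(bs[i]->n_elem);
    vb[i].zeros(bs[i]->n_elem);
  }

  Pcg32 rng((uint64_t)seed, 77u);
  const double b1m = 0.9, b2m = 0.999, eps = 1e-8;
  int step = 0;
  arma::vec loss_epoch(epochs), recon_epoch(epochs), lat_epoch(epochs);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  VaeNet::Cache cc;
  VaeNet::ECache ec;
  arma::mat img;
  arma::vec ztrue, zin;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with package RNG for reproducibility
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng.unif() * (i + 1));
      std::swap(ord[i], ord[j]);
    }
    double tot = 0.0, totr = 0.0, totl = 0.0;
    for (int bstart = 0; bstart < n; bstart += batch) {
      int bend = std::min(bstart + batch, n);
      int bsize = bend - bstart;
      for (int i = 0; i < 8; ++i) {
        gW[i].zeros(Ws[i]->n_rows, Ws[i]->n_cols);
        gb[i].zeros(bs[i]->n_elem);
      }
      for (int bi = bstart; bi < bend; ++bi) {
        int idx = ord[bi];
        double tha[3], tht[3], mu6[6];
        for (int j = 0; j < 3; ++j) {
          tha[j] = ang_arm(idx, j);
          tht[j] = ang_tgt(idx, j);
          mu6[j] = tha[j]; mu6[3 + j] = tht[j];
        }
        double Q[4][2];
        fk_chain(g, tht, Q);
        render_core(g, tha, Q[3][0], Q[3][1], radii[idx], true, true, 0.0, 0.0,
                    0.0, 20.0, true, img);
        norm_z(g, mu6, ztrue);
        zin = ztrue;
        for (int j = 0; j < 6; ++j) zin[j] += enc_sd * rng.normal();
        net.decode(zin, cc);
        arma::mat dY = cc.Y - img;
        totr += 0.5 * arma::accu(dY % dY);
        net.decode_backward(cc, dY, &gW, &gb);
        net.encode(img, ec);
        arma::vec dz = w_lat * (ec.zhat - ztrue);
        totl += 0.5 * w_lat * arma::accu(arma::square(ec.zhat - ztrue));
        net.encode_backward(ec, dz, gW, gb);
      }
      // Adam
      step++;
      double corr1 = 1.0 - std::pow(b1m, step), corr2 = 1.0 - std::pow(b2m, step);
      for (int i = 0; i < 8; ++i) {
        gW[i] /= bsize; gb[i] /= bsize;
        mW[i] = b1m * mW[i] + (1 - b1m) * gW[i];
        vW[i] = b2m * vW[i] + (1 - b2m) * (gW[i] % gW[i]);
        *Ws[i] -= lr * (mW[i] / corr1) / (arma::sqrt(vW[i] / corr2) + eps);
        mb[i] = b1m * mb[i] + (1 - b1m) * gb[i];
        vb[i] = b2m * vb[i] + (1 - b2m) * (gb[i] % gb[i]);
        *bs[i] -= lr * (mb[i] / corr1) / (arma::sqrt(vb[i] / corr2) + eps);
      }
    }
    loss_epoch[ep] = (totr + totl) / n;
    recon_epoch[ep] = totr / n;
    lat_epoch[ep] = totl / n;
    if (!std::isfinite(loss_epoch[ep]))
      stop("visual-model training diverged (non-finite loss)");
    Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["dec_fc_W"] = net.Wfc, _["dec_fc_b"] = net.bfc,
    _["dec_t1_W"] = net.W1, _["dec_t1_b"] = net.b1,
    _["dec_t2_W"] = net.W2, _["dec_t2_b"] = net.b2,
    _["dec_c3_W"] = net.W3, _["dec_c3_b"] = net.b3,
    _["dec_c4_W"] = net.W4, _["dec_c4_b"] = net.b4,
    _["enc_c1_W"] = net.V1, _["enc_c1_b"] = net.a1,
    _["enc_c2_W"] = net.V2, _["enc_c2_b"] = net.a2,
    _["enc_fc_W"] = net.Vfc, _["enc_fc_b"] = net.afc);
  return List::create(_["weights"] = out, _["loss"] = loss_epoch,
                      _["recon_loss"] = recon_epoch, _["latent_loss"] = lat_epoch);
}

// [[Rcpp::export]]
NumericVector cpp_vae_decode(List weights, List geom, NumericVector mu6) {
  Geom g = geom_from_list(geom);
  VaeNet net;
  net.from_list(weights);
  arma::vec z;
  norm_z(g, mu6.begin(), z);
  VaeNet::Cache cc;
  net.decode(z, cc);
  return to_r_image(cc.Y, g.W, g.H);
}

// [[Rcpp::export]]
NumericVector cpp_vae_pullback(List weights, List geom, NumericVector mu6,
                               NumericVector err) {
  Geom g = geom_from_list(geom);
  VaeNet net;
  net.from_list(weights);
  arma::vec z;
  norm_z(g, mu6.begin(), z);
  VaeNet::Cache cc;
  net.decode(z, cc);
  arma::mat E = from_r_image(err, g.W, g.H);
  arma::vec dz = net.decode_backward(cc, E);
  NumericVector out(6);
  for (int j = 0; j < 6; ++j) {
    int jj = j % 3;
    out[j] = dz[j] * 2.0 / (g.hi[jj] - g.lo[jj]); // chain rule to radians
  }
  return out;
}

// opaque handle used by the trial runner (parse the weight list once)
void* vae_open(const Rcpp::List& weights) {
  VaeNet* net = new VaeNet();
  net->from_list(weights);
  return (void*)net;
}
void vae_close(void* h) { delete (VaeNet*)h; }
void vae_decode_internal(void* h, const Geom& g, const double* mu6,
                         arma::mat& out) {
  VaeNet* net = (VaeNet*)h;
  arma::vec z;
  norm_z(g, mu6, z);
  VaeNet::Cache cc;
  net->decode(z, cc);
  out = cc.Y;
}
void vae_pullback_internal(void* h, const Geom& g, const double* mu6,
                           const arma::mat& err, double* grad6) {
  VaeNet* net = (VaeNet*)h;
  arma::vec z;
  norm_z(g, mu6, z);
  VaeNet::Cache cc;
  net->decode(z, cc);
  arma::vec dz = net->decode_backward(cc, err);
  for (int j = 0; j < 6; ++j) {
    int jj = j % 3;
    grad6[j] = dz[j] * 2.0 / (g.hi[jj] - g.lo[jj]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_vae_encode(List weights, List geom, NumericVector img) {
  Geom g = geom_from_list(geom);
  VaeNet net;
  net.from_list(weights);
  VaeNet::ECache ec;
  arma::mat X = from_r_image(img, g.W, g.H);
  net.encode(X, ec);
  NumericVector out(6);
  for (int j = 0; j < 6; ++j) {
    int jj = j % 3;
    out[j] = (ec.zhat[j] + 1.0) * 0.5 * (g.hi[jj] - g.lo[jj]) + g.lo[jj];
  }
  return out;
}
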