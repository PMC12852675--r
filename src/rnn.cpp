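// Training loop for the continuous-time recurrent network.
// Euler dynamics: x <- x + (dt/tau) * (-x + W_rec * tanh(x) + b_rec + W_in * u)
// output z = W_out * tanh(x) + b_out; squared-error loss on the final
// (post-stimulus) window only. Gradients by backpropagation through time;
// Adam updates. Trial structure and all randomness use R's RNG so runs are
// reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Adam {
  mat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double b1, double b2,
            double eps, double bc1, double bc2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    w -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
};

// [[Rcpp::export]]
Rcpp::List rnn_train_cpp(arma::mat W_in, arma::mat W_rec, arma::mat W_out,
                         arma::vec b_rec, arma::vec b_out,
                         int epochs, int batch, double lr,
                         double tau_s, double dt_s,
                         int n_pre, int n_stim, int n_post,
                         double noise_sd, double vel_range,
                         double depth_near, double depth_far) {
  const int n = W_rec.n_rows, n_in = W_in.n_cols, n_out = W_out.n_rows;
  const int T = n_pre + n_stim + n_post;
  const double a = dt_s / tau_s;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  Adam aWin(n, n_in), aWrec(n, n), aWout(n_out, n),
       aBrec(n, 1), aBout(n_out, 1);
  vec loss_hist(epochs);

  cube U(n_in, batch, T), R(n, batch, T), DX(n, batch, T);
  mat Y(n_out, batch), Z(n_out, batch);

  for (int ep = 0; ep < epochs; ++ep) {
    // ---- generate a batch of trials
    for (int bIdx = 0; bIdx < batch; ++bIdx) {
      // R trials: moving object, depth ambiguous (target 0), world motion
      // is the coordinate transformation ret + eye. RT trials: stationary
      // object whose retinal motion is pure parallax d' * eye, so the
      // world-motion target is 0 and the depth target is d'.
      bool rt = R::unif_rand() < 0.5;
      double om_eye = R::runif(-vel_range, vel_range);
      double ret, near_f, far_f, motion, depth;
      if (rt) {
        double dp = R::runif(-1.0, 1.0);
        ret = dp * om_eye;
        near_f = depth_near * om_eye;
        far_f = depth_far * om_eye;
        motion = 0.0;
        depth = dp;
      } else {
        ret = R::runif(-vel_range, vel_range);
        near_f = -om_eye;
        far_f = -om_eye;
        motion = ret + om_eye;
        depth = 0.0;
      }
      Y(0, bIdx) = motion;
      Y(1, bIdx) = depth;
      for (int t = 0; t < T; ++t) {
        bool stim = (t >= n_pre) && (t < n_pre + n_stim);
        U(0, bIdx, t) = noise_sd * R::norm_rand() + (stim ? ret : 0.0);
        U(1, bIdx, t) = noise_sd * R::norm_rand() + (stim ? near_f : 0.0);
        U(2, bIdx, t) = noise_sd * R::norm_rand() + (stim ? far_f : 0.0);
      }
    }

    // ---- forward
    mat X(n, batch, fill::zeros), Rt(n, batch, fill::zeros);
    double loss = 0.0;
    const double Nnorm = double(n_post) * batch * n_out;
    mat gWout(n_out, n, fill::zeros), gBout(n_out, 1, fill::zeros);
    for (int t = 0; t < T; ++t) {
      X = (1 - a) * X + a * (W_rec * Rt + b_rec * rowvec(batch, fill::ones)
                              + W_in * U.slice(t));
      Rt = tanh(X);
      R.slice(t) = Rt;
      if (t >= n_pre + n_stim) {
        Z = W_out * Rt;
        Z.each_col() += b_out;
        mat E = Z - Y;
        loss += accu(E % E) / Nnorm;
      }
    }
    if (!std::isfinite(loss)) {
      Rcpp::stop("training diverged at epoch %d (non-finite loss)", ep + 1);
    }
    loss_hist(ep) = loss;

    // ---- backward through time
    mat dx_next(n, batch, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      Rt = R.slice(t);
      mat dr(n, batch, fill::zeros);
      if (t >= n_pre + n_stim) {
        Z = W_out * Rt;
        Z.each_col() += b_out;
        mat dz = 2.0 * (Z - Y) / Nnorm;
        gWout += dz * Rt.t();
        gBout += sum(dz, 1);
        dr = W_out.t() * dz;
      }
      dr += a * (W_rec.t() * dx_next);
      mat dx = dr % (1 - Rt % Rt) + (1 - a) * dx_next;
      DX.slice(t) = dx;
      dx_next = dx;
    }

    // grads of the recurrent update, accumulated as one big GEMM:
    // update at step t used r_{t-1} (zero at t = 0) and u_t
    mat DXf(n, batch * T);
    mat Rprev(n, batch * T, fill::zeros);
    mat Uf(n_in, batch * T);
    for (int t = 0; t < T; ++t) {
      DXf.cols(t * batch, (t + 1) * batch - 1) = DX.slice(t);
      Uf.cols(t * batch, (t + 1) * batch - 1) = U.slice(t);
      if (t > 0)
        Rprev.cols(t * batch, (t + 1) * batch - 1) = R.slice(t - 1);
    }
    mat gWrec = a * (DXf * Rprev.t());
    mat gWin = a * (DXf * Uf.t());
    mat gBrec = a * sum(DXf, 1);

    double bc1 = 1 - std::pow(b1, ep + 1), bc2 = 1 - std::pow(b2, ep + 1);
    aWin.step(W_in, gWin, lr, b1, b2, eps, bc1, bc2);
    aWrec.step(W_rec, gWrec, lr, b1, b2, eps, bc1, bc2);
    aWout.step(W_out, gWout, lr, b1, b2, eps, bc1, bc2);
    mat brm(b_rec), bom(b_out);
    aBrec.step(brm, gBrec, lr, b1, b2, eps, bc1, bc2);
    aBout.step(bom, gBout, lr, b1, b2, eps, bc1, bc2);
    b_rec = brm.col(0);
    b_out = bom.col(0);

    if (ep % 500 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("W_in") = W_in, Rcpp::Named("W_rec") = W_rec,
    Rcpp::Named("W_out") = W_out, Rcpp::Named("b_rec") = b_rec,
    Rcpp::Named("b_out") = b_out,
    Rcpp::Named("loss_history") = loss_hist);
}

// [[Rcpp::export]]
arma::cube rnn_forward_cpp(const arma::mat& W_in, const arma::mat& W_rec,
                           const arma::mat& W_out, const arma::vec& b_rec,
                           const arma::vec& b_out, const arma::cube& U,
                           double tau_s, double dt_s) {
  const int n = W_rec.n_rows, batch = U.n_cols, T = U.n_slices;
  const int n_out = W_out.n_rows;
  const double a = dt_s / tau_s;
  mat X(n, batch, fill::zeros), Rt(n, batch, fill::zeros);
  cube Z(n_out, batch, T);
  for (int t = 0; t < T; ++t) {
    X = (1 - a) * X + a * (W_rec * Rt + b_rec * rowvec(batch, fill::ones)
                            + W_in * U.slice(t));
    Rt = tanh(X);
    mat z = W_out * Rt;
    z.each_col() += b_out;
    Z.slice(t) = z;
  }
  return Z;
}

// [[Rcpp::export]]
arma::mat rnn_final_activation_cpp(const arma::mat& W_in, const arma::mat& W_rec,
                                   const arma::vec& b_rec, const arma::cube& U,
                                   double tau_s, double dt_s) {
  const int n = W_rec.n_rows, batch = U.n_cols, T = U.n_slices;
  const double a = dt_s / tau_s;
  mat X(n, batch, fill::zeros), Rt(n, batch, fill::zeros);
  for (int t = 0; t < T; ++t) {
    X = (1 - a) * X + a * (W_rec * Rt + b_rec * rowvec(batch, fill::ones)
                            + W_in * U.slice(t));
    Rt = tanh(X);
  }
  return Rt;
}
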