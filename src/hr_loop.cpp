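// Closed-loop runner: world update, input encoding, forward pass,
// population-vector decoding and (optionally) RTRL learning, per time step.
// Mirrors the pure-R reference implementation exactly, including the order
// of draws from R's global RNG, so short runs can be compared 1:1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double logi(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
List hr_run_cpp(arma::mat W_in, arma::mat W_rec, arma::mat W_out,
                arma::vec b_hid, arma::vec b_out, arma::mat mask_in,
                arma::vec h_prev,
                arma::mat P, arma::vec g_wh, arma::mat g_out, arma::vec g_bout,
                int sens_steps,
                IntegerVector hands, IntegerMatrix others,
                IntegerVector prev_cmd,
                int t0, int n_steps,
                int area_w, int area_h, int block, int fov_rows,
                double hand_value, double other_value, bool cd_enabled,
                bool test_phase,
                bool learn, double lr, int update_period,
                int reposition_period, int other_move_period,
                double threshold,
                bool log_traj, bool log_hidden, bool log_J) {
  const int n_in = W_in.n_rows, n_hid = W_in.n_cols, n_out = W_out.n_cols;
  const int nv = area_w * fov_rows;
  const int ppo = nv, cdo = nv + 18;
  const int n_agency = n_hid / 2;
  const size_t off_rec = (size_t)n_in * n_hid;
  const size_t off_b = off_rec + (size_t)n_hid * n_hid;

  int lx = hands[0], ly = hands[1], rx = hands[2], ry = hands[3];
  const int n_oth = others.nrow();
  std::vector<int> ox(n_oth), oy(n_oth);
  for (int i = 0; i < n_oth; ++i) { ox[i] = others(i, 0); oy[i] = others(i, 1); }
  int cmd[4] = {prev_cmd[0], prev_cmd[1], prev_cmd[2], prev_cmd[3]};
  const int oth_h = test_phase ? fov_rows : area_h;  // others' allowed rows

  IntegerVector cen(n_steps);
  IntegerMatrix traj(log_traj ? n_steps : 0, 4);
  NumericMatrix hid_log(log_hidden ? n_steps : 0, n_hid);
  NumericVector J_log(log_J ? n_steps : 0);

  arma::vec x(n_in), net_h(n_hid), h(n_hid), y(n_out), dh(n_hid);
  arma::vec delta(n_out), q(n_hid);
  const int dxs[4] = {1, 0, -1, 0}, dys[4] = {0, -1, 0, 1};

  for (int s = 0; s < n_steps; ++s) {
    const int t = t0 + s;
    // (1) reposition every reposition_period steps (not at t = 0)
    if (reposition_period > 0 && t > 0 && t % reposition_period == 0) {
      lx = (int)(unif_rand() * area_w); ly = (int)(unif_rand() * area_h);
      rx = (int)(unif_rand() * area_w); ry = (int)(unif_rand() * area_h);
      for (int i = 0; i < n_oth; ++i) {
        ox[i] = (int)(unif_rand() * area_w);
        oy[i] = (int)(unif_rand() * oth_h);
      }
    }
    // (2) distractor random step every other_move_period steps
    if (other_move_period > 0 && t > 0 && t % other_move_period == 0) {
      for (int i = 0; i < n_oth; ++i) {
        int dir = (int)(unif_rand() * 4);
        int nx2 = ox[i] + dxs[dir], ny2 = oy[i] + dys[dir];
        if (nx2 >= 0 && nx2 < area_w && ny2 >= 0 && ny2 < oth_h) {
          ox[i] = nx2; oy[i] = ny2;
        }
      }
    }
    // (3) build input: visual (others then hands), proprio, corollary disch.
    x.zeros();
    if (other_value != 0.0)
      for (int i = 0; i < n_oth; ++i)
        if (oy[i] < fov_rows) x[oy[i] * area_w + ox[i]] = other_value;
    if (hand_value != 0.0) {
      if (ly < fov_rows) x[ly * area_w + lx] = hand_value;
      if (ry < fov_rows) x[ry * area_w + rx] = hand_value;
    }
    const int bxl = lx / block, byl = ly / block;
    const int bxr = rx / block, byr = ry / block;
    x[ppo + byl * 3 + bxl] = 1.0;
    x[ppo + 9 + byr * 3 + bxr] = 1.0;
    if (cd_enabled) {
      for (int hnd = 0; hnd < 2; ++hnd) {
        const int dx = cmd[2 * hnd], dy = cmd[2 * hnd + 1];
        const int o = cdo + 5 * hnd;
        if (dx == 1) x[o] = 1.0;
        if (dy == -1) x[o + 1] = 1.0;
        if (dx == -1) x[o + 2] = 1.0;
        if (dy == 1) x[o + 3] = 1.0;
        if (dx == 0 && dy == 0) x[o + 4] = 1.0;
      }
    }
    // (4) forward pass (h_prev untouched until sensitivities are done)
    net_h = W_in.t() * x + W_rec.t() * h_prev + b_hid;
    for (int j = 0; j < n_hid; ++j) h[j] = logi(net_h[j]);
    y = W_out.t() * h + b_out;
    for (int k = 0; k < n_out; ++k) y[k] = logi(y[k]);
    // (5) decode movement command
    int ncmd[4] = {0, 0, 0, 0};
    for (int hnd = 0; hnd < 2; ++hnd) {
      const int o = 4 * hnd;
      double dx_diff = y[o] - y[o + 2], dy_diff = y[o + 1] - y[o + 3];
      if (dx_diff >= threshold) ncmd[2 * hnd] = 1;
      else if (dx_diff <= -threshold) ncmd[2 * hnd] = -1;
      if (dy_diff >= threshold) ncmd[2 * hnd + 1] = -1;       // up
      else if (dy_diff <= -threshold) ncmd[2 * hnd + 1] = 1;  // down
    }
    // (6) learning: sensitivities, feedback errors, accumulate, update
    if (learn) {
      P = W_rec.t() * P;
      for (int i = 0; i < n_in; ++i) {
        if (x[i] == 0.0) continue;
        const int jmax = (i >= cdo) ? n_agency : n_hid;
        for (int j = 0; j < jmax; ++j)
          P(j, (size_t)j * n_in + i) += x[i];
      }
      for (int j = 0; j < n_hid; ++j) {
        const size_t base = off_rec + (size_t)j * n_hid;
        for (int m = 0; m < n_hid; ++m) P(j, base + m) += h_prev[m];
        P(j, off_b + j) += 1.0;
      }
      for (int j = 0; j < n_hid; ++j) dh[j] = h[j] * (1.0 - h[j]);
      P.each_col() %= dh;
      const double e[8] = {
        (double)(1 - bxl), (double)(byl - 1),
        (double)(bxl - 1), (double)(1 - byl),
        (double)(1 - bxr), (double)(byr - 1),
        (double)(bxr - 1), (double)(1 - byr)};
      for (int k = 0; k < n_out; ++k) delta[k] = e[k] * y[k] * (1.0 - y[k]);
      q = W_out * delta;
      g_wh += (q.t() * P).t();
      g_out += h * delta.t();
      g_bout += delta;
      if (log_J) {
        double J = 0; for (int k = 0; k < 8; ++k) J += e[k] * e[k];
        J_log[s] = 0.5 * J;
      }
      if (++sens_steps % update_period == 0) {
        W_in = (W_in + lr * arma::reshape(g_wh.subvec(0, off_rec - 1),
                                          n_in, n_hid)) % mask_in;
        W_rec += lr * arma::reshape(g_wh.subvec(off_rec, off_b - 1),
                                    n_hid, n_hid);
        b_hid += lr * g_wh.subvec(off_b, off_b + n_hid - 1);
        W_out += lr * g_out;
        b_out += lr * g_bout;
        if (!W_rec.is_finite() || !b_out.is_finite())
          stop("non-finite weights after update; training aborted");
        g_wh.zeros(); g_out.zeros(); g_bout.zeros();
      }
    }
    h_prev = h;
    // (7) apply moves, clamped to the movable area
    lx = clampi(lx + ncmd[0], 0, area_w - 1);
    ly = clampi(ly + ncmd[1], 0, area_h - 1);
    rx = clampi(rx + ncmd[2], 0, area_w - 1);
    ry = clampi(ry + ncmd[3], 0, area_h - 1);
    cmd[0] = ncmd[0]; cmd[1] = ncmd[1]; cmd[2] = ncmd[2]; cmd[3] = ncmd[3];
    // (8) record post-move success
    cen[s] = ((lx / block == 1 && ly / block == 1) ||
              (rx / block == 1 && ry / block == 1)) ? 1 : 0;
    if (log_traj) {
      traj(s, 0) = lx; traj(s, 1) = ly; traj(s, 2) = rx; traj(s, 3) = ry;
    }
    if (log_hidden)
      for (int j = 0; j < n_hid; ++j) hid_log(s, j) = h[j];
  }

  IntegerMatrix others_out(n_oth, 2);
  for (int i = 0; i < n_oth; ++i) { others_out(i, 0) = ox[i]; others_out(i, 1) = oy[i]; }
  return List::create(
    _["W_in"] = W_in, _["W_rec"] = W_rec, _["W_out"] = W_out,
    _["b_hid"] = b_hid, _["b_out"] = b_out, _["h_prev"] = h_prev,
    _["P"] = P, _["g_wh"] = g_wh, _["g_out"] = g_out, _["g_bout"] = g_bout,
    _["sens_steps"] = sens_steps,
    _["hands"] = IntegerVector::create(lx, ly, rx, ry),
    _["others"] = others_out,
    _["prev_cmd"] = IntegerVector::create(cmd[0], cmd[1], cmd[2], cmd[3]),
    _["t"] = t0 + n_steps,
    _["in_center"] = cen,
    _["traj"] = traj, _["hidden_log"] = hid_log, _["J"] = J_log,
    _["output"] = NumericVector(y.begin(), y.end()));
}
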