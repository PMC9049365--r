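// Simulation core: forward pass and fused forward+backward (BPTT) pass of
// the two-compartment PC / interneuron circuit. Mirrors the R reference
// implementation (ci_forward / ci_backward) exactly; parity and
// finite-difference tests guard the correspondence. Work matrices are
// hoisted out of the time loops so their memory is reused across steps.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Consts {
  double dt, theta, refrac, beta;
  double a_s, a_w, a_d, a_dw, a_i, a_syn, a_u, a_r;
  double ku, kr, kd, gs, gd, cd, bs, Fs;
  double Ed, Dd;
};

static Consts read_consts(const Rcpp::List& k) {
  Consts c;
  c.dt = k["dt"]; c.theta = k["theta"]; c.refrac = k["refrac"];
  c.beta = k["beta"];
  c.a_s = k["a_s"]; c.a_w = k["a_w"]; c.a_d = k["a_d"]; c.a_dw = k["a_dw"];
  c.a_i = k["a_i"]; c.a_syn = k["a_syn"]; c.a_u = k["a_u"]; c.a_r = k["a_r"];
  c.ku = k["ku"]; c.kr = k["kr"]; c.kd = k["kd"];
  c.gs = k["gs"]; c.gd = k["gd"]; c.cd = k["cd"]; c.bs = k["bs"];
  c.Fs = k["Fs"]; c.Ed = k["Ed"]; c.Dd = k["Dd"];
  return c;
}

struct Net {
  int N_E, N_I;
  bool shared;
  mat W_ei_abs, W_ii_abs, U;
  mat ws_abs_m, wd_abs_m;   // heterogeneous mode (N_I, N_E)
  vec ws_abs_v, wd_abs_v;   // shared mode (N_I)
};

static Net read_net(const Rcpp::List& net) {
  Net n;
  n.N_E = Rcpp::as<int>(net["N_E"]); n.N_I = Rcpp::as<int>(net["N_I"]);
  n.shared = Rcpp::as<bool>(net["shared"]);
  n.W_ei_abs = Rcpp::as<mat>(net["W_ei_abs"]);
  n.W_ii_abs = Rcpp::as<mat>(net["W_ii_abs"]);
  n.U = Rcpp::as<mat>(net["U"]);
  if (n.shared) {
    n.ws_abs_v = Rcpp::as<vec>(net["ws_abs"]);
    n.wd_abs_v = Rcpp::as<vec>(net["wd_abs"]);
  } else {
    n.ws_abs_m = Rcpp::as<mat>(net["ws_abs"]);
    n.wd_abs_m = Rcpp::as<mat>(net["wd_abs"]);
  }
  return n;
}

static uvec block_cols(int N_I, int B) {
  uvec idx(N_I * B);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < N_I; ++j) idx[b * N_I + j] = b;
  return idx;
}

// Shared pieces of the forward sweep, used by both entry points.
struct Fwd {
  // parameters of the sweep
  Consts c; Net n; int T, B, N_E, N_I;
  uvec repb;
  mat W_rep, U_rep;
  mat stim_s_m, stim_d_m;
  cube bg_s_c, bg_d_c, bg_i_c;
  const mat *stim_s, *stim_d;
  const cube *bg_s, *bg_d, *bg_i;
  bool relaxed;
  // state
  mat vs, ws, refs, vd, wd, vi, refi, sE, sI, u, R, SE1, SE2;
  // per-step work
  mat fd, inh_s, inh_d, Es, Ed_, vs_pre, actS, SE, bap, vd_new, mu, driveE,
      driveI, vi_pre, actI, SI, u1, R1, sE_big, SE_big, tmpE, tmpS;
  rowvec inh_s_b, inh_d_b, dE_flat;

  void init(const Rcpp::List& net_l, const Rcpp::List& consts,
            const Rcpp::List& inputs, bool relaxed_) {
    c = read_consts(consts); n = read_net(net_l); relaxed = relaxed_;
    stim_s_m = Rcpp::as<mat>(inputs["stim_s"]);
    stim_d_m = Rcpp::as<mat>(inputs["stim_d"]);
    bg_s_c = Rcpp::as<cube>(inputs["bg_s"]);
    bg_d_c = Rcpp::as<cube>(inputs["bg_d"]);
    bg_i_c = Rcpp::as<cube>(inputs["bg_i"]);
    stim_s = &stim_s_m; stim_d = &stim_d_m;
    bg_s = &bg_s_c; bg_d = &bg_d_c; bg_i = &bg_i_c;
    T = stim_s_m.n_rows; B = stim_s_m.n_cols;
    N_E = n.N_E; N_I = n.N_I;
    repb = block_cols(N_I, B);
    W_rep = repmat(n.W_ei_abs, 1, B);
    U_rep = repmat(n.U, 1, B);
    vs.zeros(N_E, B); ws.zeros(N_E, B); refs.zeros(N_E, B);
    vd.zeros(N_E, B); wd.zeros(N_E, B);
    vi.zeros(N_I, B); refi.zeros(N_I, B);
    sE.zeros(N_E, B); sI.zeros(N_I, B);
    u = U_rep; R.ones(N_E, N_I * B);
    SE1.zeros(N_E, B); SE2.zeros(N_E, B);
  }

  void step(int t) {
    fd = 1.0 / (1.0 + exp(-(vd - c.Ed) / c.Dd));
    if (n.shared) {
      inh_s_b = n.ws_abs_v.t() * sI;
      inh_d_b = n.wd_abs_v.t() * sI;
    } else {
      inh_s = n.ws_abs_m.t() * sI;
      inh_d = n.wd_abs_m.t() * sI;
    }
    Es = bg_s->slice(t); Es.each_row() += stim_s->row(t);
    Ed_ = bg_d->slice(t); Ed_.each_row() += stim_d->row(t);

    vs_pre = vs * c.a_s + c.dt * (c.gs * fd + ws + Es);
    if (n.shared) vs_pre.each_row() -= c.dt * inh_s_b;
    else vs_pre -= c.dt * inh_s;

    if (relaxed) {
      actS.ones(N_E, B);
      SE = 0.5 + (vs_pre - c.theta) / (1.0 + c.beta * abs(vs_pre - c.theta));
    } else {
      actS = conv_to<mat>::from(refs <= 0.0);
      SE = actS % conv_to<mat>::from(vs_pre >= c.theta);
    }
    vs = actS % (1.0 - SE) % vs_pre;
    if (!relaxed) {
      refs = clamp(refs - c.dt, 0.0, datum::inf);
      refs.elem(find(SE > 0)).fill(c.refrac);
    }
    ws = ws * c.a_w + c.bs * SE;

    bap = c.cd * (SE1 + SE2);
    vd_new = vd * c.a_d + c.dt * (c.gd * fd + bap + wd + Ed_);
    if (n.shared) vd_new.each_row() -= c.dt * inh_d_b;
    else vd_new -= c.dt * inh_d;
    wd = wd * c.a_dw + c.kd * vd;
    vd = vd_new;

    mu = u % R;
    sE_big = sE.cols(repb);
    dE_flat = sum(W_rep % mu % sE_big, 0);
    driveE = reshape(dE_flat.t(), N_I, B);
    driveI = n.W_ii_abs * sI;
    vi_pre = vi * c.a_i + c.dt * (driveE - driveI + bg_i->slice(t));

    if (relaxed) {
      actI.ones(N_I, B);
      SI = 0.5 + (vi_pre - c.theta) / (1.0 + c.beta * abs(vi_pre - c.theta));
    } else {
      actI = conv_to<mat>::from(refi <= 0.0);
      SI = actI % conv_to<mat>::from(vi_pre >= c.theta);
    }
    vi = actI % (1.0 - SI) % vi_pre;
    if (!relaxed) {
      refi = clamp(refi - c.dt, 0.0, datum::inf);
      refi.elem(find(SI > 0)).fill(c.refrac);
    }

    sE = sE * c.a_syn + SE;
    sI = sI * c.a_syn + SI;

    SE_big = SE.cols(repb);
    u1 = u * c.a_u + c.ku * U_rep;
    u = u1 + (1.0 - u1) * c.Fs % SE_big;
    R1 = R * c.a_r + c.kr;
    R = R1 % (1.0 - u % SE_big);

    SE2 = SE1; SE1 = SE;

    if (t % 100 == 99 && (!vs.is_finite() || !vd.is_finite() || !vi.is_finite())) {
      Rcpp::stop("non-finite network state at step %d", t + 1);
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_forward(Rcpp::List net_l, Rcpp::List consts, Rcpp::List inputs,
                       bool relaxed) {
  Fwd f;
  f.init(net_l, consts, inputs, relaxed);
  cube spikes_E(f.N_E, f.B, f.T), spikes_I(f.N_I, f.B, f.T);
  mat I_s_sh, I_d_sh; cube I_s_het, I_d_het;
  if (f.n.shared) { I_s_sh.set_size(f.B, f.T); I_d_sh.set_size(f.B, f.T); }
  else { I_s_het.set_size(f.N_E, f.B, f.T); I_d_het.set_size(f.N_E, f.B, f.T); }

  for (int t = 0; t < f.T; ++t) {
    f.step(t);
    spikes_E.slice(t) = f.SE; spikes_I.slice(t) = f.SI;
    if (f.n.shared) {
      I_s_sh.col(t) = -f.inh_s_b.t(); I_d_sh.col(t) = -f.inh_d_b.t();
    } else {
      I_s_het.slice(t) = -f.inh_s; I_d_het.slice(t) = -f.inh_d;
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("spikes_E") = spikes_E,
    Rcpp::Named("spikes_I") = spikes_I);
  if (f.n.shared) { out["I_s"] = I_s_sh; out["I_d"] = I_d_sh; }
  else { out["I_s"] = I_s_het; out["I_d"] = I_d_het; }
  return out;
}

// Fused forward + backward pass: simulates with in-memory history, computes
// the compartment-specific E/I matching loss and its gradients for all
// optimizable parameter groups (|W| sign chains and masks applied on the R
// side). Spike reset and refractory gates are detached; in relaxed mode the
// forward pass is smooth and reset gradients are attached.
// [[Rcpp::export]]
Rcpp::List cpp_train_step(Rcpp::List net_l, Rcpp::List consts,
                          Rcpp::List inputs, double alpha_mu_s,
                          double alpha_mu_d, bool relaxed) {
  Fwd f;
  f.init(net_l, consts, inputs, relaxed);
  const int T = f.T, B = f.B, N_E = f.N_E, N_I = f.N_I;
  const Consts c = f.c;
  const bool shared = f.n.shared;

  cube H_SE(N_E, B, T), H_SI(N_I, B, T), H_vspre(N_E, B, T),
       H_vipre(N_I, B, T), H_actS(N_E, B, T), H_actI(N_I, B, T),
       H_vd(N_E, B, T + 1), H_sE(N_E, B, T + 1), H_sI(N_I, B, T + 1);
  cube H_u(N_E, N_I * B, T + 1), H_R(N_E, N_I * B, T + 1);
  mat inh_s_rec, inh_d_rec; cube inh_s_cube, inh_d_cube;
  if (shared) { inh_s_rec.set_size(B, T); inh_d_rec.set_size(B, T); }
  else { inh_s_cube.set_size(N_E, B, T); inh_d_cube.set_size(N_E, B, T); }

  H_vd.slice(0) = f.vd; H_sE.slice(0) = f.sE; H_sI.slice(0) = f.sI;
  H_u.slice(0) = f.u; H_R.slice(0) = f.R;

  double loss_soma = 0.0, loss_dend = 0.0;
  mat r_s, r_d;

  for (int t = 0; t < T; ++t) {
    f.step(t);
    r_s = f.Es - alpha_mu_s; r_d = f.Ed_ - alpha_mu_d;
    if (shared) {
      r_s.each_row() -= f.inh_s_b; r_d.each_row() -= f.inh_d_b;
      inh_s_rec.col(t) = f.inh_s_b.t(); inh_d_rec.col(t) = f.inh_d_b.t();
    } else {
      r_s -= f.inh_s; r_d -= f.inh_d;
      inh_s_cube.slice(t) = f.inh_s; inh_d_cube.slice(t) = f.inh_d;
    }
    loss_soma += accu(square(r_s));
    loss_dend += accu(square(r_d));

    H_SE.slice(t) = f.SE; H_SI.slice(t) = f.SI;
    H_vspre.slice(t) = f.vs_pre; H_vipre.slice(t) = f.vi_pre;
    H_actS.slice(t) = f.actS; H_actI.slice(t) = f.actI;
    H_vd.slice(t + 1) = f.vd;
    H_sE.slice(t + 1) = f.sE; H_sI.slice(t + 1) = f.sI;
    H_u.slice(t + 1) = f.u; H_R.slice(t + 1) = f.R;
  }
  loss_soma /= B; loss_dend /= B;

  // ---------------- backward ----------------
  mat lam_vs(N_E, B, fill::zeros), lam_ws(N_E, B, fill::zeros),
      lam_vd(N_E, B, fill::zeros), lam_wd(N_E, B, fill::zeros),
      lam_vi(N_I, B, fill::zeros), lam_sE(N_E, B, fill::zeros),
      lam_sI(N_I, B, fill::zeros);
  mat lam_u(N_E, N_I * B, fill::zeros), lam_R(N_E, N_I * B, fill::zeros);
  mat pendA(N_E, B, fill::zeros), pendB(N_E, B, fill::zeros);

  mat gU_acc(N_E, N_I * B, fill::zeros), gA_acc(N_E, N_I * B, fill::zeros);
  mat gB(N_I, N_I, fill::zeros);
  vec g_ws_v(N_I, fill::zeros), g_wd_v(N_I, fill::zeros);
  mat g_ws_m, g_wd_m;
  if (!shared) { g_ws_m.zeros(N_I, N_E); g_wd_m.zeros(N_I, N_E); }

  // hoisted work matrices
  mat SE, SI, vs_pre, vi_pre, actS, actI, vd_prev, sE_prev, sI_prev,
      u_prev, R_prev, u_post, Es, Ed_, SEb, u1, R1,
      lam_R1, lam_u_tot, lam_u1, gSE_flat, gSE, lam_u_new, lam_R_new,
      gSI, lam_sI_new, lam_sE_new, sur_i, lam_vi_pre, lam_dE, lam_dI,
      mu, sE_big, P, lam_mu, Pmu, lam_wd_new, lam_vd_prev, fd, lam_fd,
      bap_contrib, sur_s, lam_vs_pre, newA, lam_inh_s_het, lam_inh_d_het;
  rowvec ldE_row, lam_inh_s_sh, lam_inh_d_sh;

  for (int t = T - 1; t >= 0; --t) {
    SE = H_SE.slice(t); SI = H_SI.slice(t);
    vs_pre = H_vspre.slice(t); vi_pre = H_vipre.slice(t);
    actS = H_actS.slice(t); actI = H_actI.slice(t);
    vd_prev = H_vd.slice(t);
    sE_prev = H_sE.slice(t); sI_prev = H_sI.slice(t);
    u_prev = H_u.slice(t); R_prev = H_R.slice(t); u_post = H_u.slice(t + 1);

    Es = f.bg_s->slice(t); Es.each_row() += f.stim_s->row(t);
    Ed_ = f.bg_d->slice(t); Ed_.each_row() += f.stim_d->row(t);
    r_s = Es - alpha_mu_s; r_d = Ed_ - alpha_mu_d;
    if (shared) {
      r_s.each_row() -= inh_s_rec.col(t).t();
      r_d.each_row() -= inh_d_rec.col(t).t();
    } else {
      r_s -= inh_s_cube.slice(t); r_d -= inh_d_cube.slice(t);
    }

    SEb = SE.cols(f.repb);
    u1 = u_prev * c.a_u + c.ku * f.U_rep;
    R1 = R_prev * c.a_r + c.kr;

    // short-term plasticity
    lam_R1 = lam_R % (1.0 - u_post % SEb);
    lam_u_tot = lam_u - lam_R % R1 % SEb;
    lam_u1 = lam_u_tot % (1.0 - c.Fs * SEb);
    gU_acc += lam_u1 * c.ku;
    gSE_flat = lam_u_tot % (1.0 - u1) * c.Fs - lam_R % u_post % R1;
    gSE.set_size(N_E, B);
    for (int b = 0; b < B; ++b) {
      gSE.col(b) = sum(gSE_flat.cols(b * N_I, (b + 1) * N_I - 1), 1);
    }
    lam_u_new = lam_u1 * c.a_u;
    lam_R_new = lam_R1 * c.a_r;

    // synaptic traces
    gSI = lam_sI;
    lam_sI_new = lam_sI * c.a_syn;
    gSE += lam_sE;
    lam_sE_new = lam_sE * c.a_syn;

    // interneurons
    sur_i = 1.0 / square(1.0 + c.beta * abs(vi_pre - c.theta));
    lam_vi_pre = lam_vi % actI % (1.0 - SI) + gSI % actI % sur_i;
    if (relaxed) lam_vi_pre -= lam_vi % vi_pre % sur_i;
    lam_vi = lam_vi_pre * c.a_i;
    lam_dE = c.dt * lam_vi_pre;
    lam_dI = -c.dt * lam_vi_pre;

    mu = u_prev % R_prev;
    sE_big = sE_prev.cols(f.repb);
    ldE_row = vectorise(lam_dE).t();
    P = f.W_rep.each_row() % ldE_row;
    Pmu = mu % sE_big;                 // reused below for sE adjoints
    gA_acc += Pmu.each_row() % ldE_row;
    lam_mu = P % sE_big;
    lam_u_new += lam_mu % R_prev;
    lam_R_new += lam_mu % u_prev;
    Pmu = P % mu;                      // now P * mu for the trace adjoints
    for (int b = 0; b < B; ++b) {
      lam_sE_new.col(b) += sum(Pmu.cols(b * N_I, (b + 1) * N_I - 1), 1);
    }
    gB += lam_dI * sI_prev.t();
    lam_sI_new += f.n.W_ii_abs.t() * lam_dI;

    // dendrite
    lam_wd_new = lam_wd * c.a_dw + lam_vd * c.dt;
    lam_vd_prev = lam_vd * c.a_d + lam_wd * c.kd;
    fd = 1.0 / (1.0 + exp(-(vd_prev - c.Ed) / c.Dd));
    lam_fd = lam_vd * c.dt * c.gd;
    bap_contrib = c.cd * c.dt * lam_vd;
    if (shared) lam_inh_d_sh = -c.dt * sum(lam_vd, 0) - (2.0 / B) * sum(r_d, 0);
    else lam_inh_d_het = -c.dt * lam_vd - (2.0 / B) * r_d;

    // soma (all spike-path adjoints collected first)
    gSE += lam_ws * c.bs + pendA;
    sur_s = 1.0 / square(1.0 + c.beta * abs(vs_pre - c.theta));
    lam_vs_pre = lam_vs % actS % (1.0 - SE) + gSE % actS % sur_s;
    if (relaxed) lam_vs_pre -= lam_vs % vs_pre % sur_s;
    lam_ws = lam_ws * c.a_w + lam_vs_pre * c.dt;
    lam_vs = lam_vs_pre * c.a_s;
    lam_fd += lam_vs_pre * c.dt * c.gs;
    lam_vd_prev += lam_fd % fd % (1.0 - fd) / c.Dd;
    if (shared) lam_inh_s_sh = -c.dt * sum(lam_vs_pre, 0) - (2.0 / B) * sum(r_s, 0);
    else lam_inh_s_het = -c.dt * lam_vs_pre - (2.0 / B) * r_s;

    // output-weight paths (use sI at t-1)
    if (shared) {
      g_ws_v += sI_prev * lam_inh_s_sh.t();
      g_wd_v += sI_prev * lam_inh_d_sh.t();
      lam_sI_new += f.n.ws_abs_v * lam_inh_s_sh + f.n.wd_abs_v * lam_inh_d_sh;
    } else {
      g_ws_m += sI_prev * lam_inh_s_het.t();
      g_wd_m += sI_prev * lam_inh_d_het.t();
      lam_sI_new += f.n.ws_abs_m * lam_inh_s_het + f.n.wd_abs_m * lam_inh_d_het;
    }

    // rotate
    lam_vd = lam_vd_prev;
    lam_wd = lam_wd_new;
    lam_sE = lam_sE_new;
    lam_sI = lam_sI_new;
    lam_u = lam_u_new;
    lam_R = lam_R_new;
    newA = pendB + bap_contrib;
    pendB = bap_contrib;
    pendA = newA;
  }

  gU_acc += lam_u;   // u(0) = U initial condition

  mat gU(N_E, N_I, fill::zeros), gA(N_E, N_I, fill::zeros);
  for (int b = 0; b < B; ++b) {
    gU += gU_acc.cols(b * N_I, (b + 1) * N_I - 1);
    gA += gA_acc.cols(b * N_I, (b + 1) * N_I - 1);
  }

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("W_ei_abs") = gA, Rcpp::Named("U") = gU,
    Rcpp::Named("W_ii_abs") = gB,
    Rcpp::Named("ws_abs") = shared ? Rcpp::wrap(g_ws_v) : Rcpp::wrap(g_ws_m),
    Rcpp::Named("wd_abs") = shared ? Rcpp::wrap(g_wd_v) : Rcpp::wrap(g_wd_m));

  // spike rasters for correlation/diagnostics
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss_soma") = loss_soma,
    Rcpp::Named("loss_dend") = loss_dend,
    Rcpp::Named("grads") = grads,
    Rcpp::Named("spikes_E") = H_SE,
    Rcpp::Named("spikes_I") = H_SI);
  if (shared) { out["I_s"] = -inh_s_rec; out["I_d"] = -inh_d_rec; }
  else { out["I_s"] = -inh_s_cube; out["I_d"] = -inh_d_cube; }
  return out;
}
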