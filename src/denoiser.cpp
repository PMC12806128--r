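// Fast path for the transformer denoiser: forward pass, reverse-mode
// gradients and batched evaluation. This mirrors the reference R
// implementation in R/denoiser.R and R/backprop.R operation for operation
// (layer normalization epsilon, softmax stabilisation, SiLU, head layout),
// and the test suite asserts agreement between the two backends to
// floating-point tolerance.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LN_EPS = 1e-5;

struct Pars {
  std::unordered_map<std::string, arma::mat> M;
  std::unordered_map<std::string, arma::vec> V;
  const arma::mat& m(const std::string& k) const {
    auto it = M.find(k);
    if (it == M.end()) stop("missing matrix parameter: " + k);
    return it->second;
  }
  const arma::vec& v(const std::string& k) const {
    auto it = V.find(k);
    if (it == V.end()) stop("missing vector parameter: " + k);
    return it->second;
  }
};

static Pars load_pars(List par) {
  Pars P;
  CharacterVector nms = par.names();
  for (int i = 0; i < par.size(); ++i) {
    std::string n = as<std::string>(nms[i]);
    RObject o = par[i];
    if (o.hasAttribute("dim")) P.M[n] = as<arma::mat>(o);
    else P.V[n] = as<arma::vec>(o);
  }
  return P;
}

struct Grads {
  std::unordered_map<std::string, arma::mat> M;
  std::unordered_map<std::string, arma::vec> V;
  void init_like(const Pars& P) {
    for (auto& kv : P.M) M[kv.first] = arma::zeros<arma::mat>(kv.second.n_rows, kv.second.n_cols);
    for (auto& kv : P.V) V[kv.first] = arma::zeros<arma::vec>(kv.second.n_elem);
  }
};

struct Cfg {
  int variant; // 1 crossdit, 2 catcrossdit, 3 catonlycrossdit, 4 adadit
  int ng, d, nl, nh, dff;
};

static Cfg load_cfg(List cfg) {
  Cfg c;
  std::string v = as<std::string>(cfg["variant"]);
  if (v == "crossdit") c.variant = 1;
  else if (v == "catcrossdit") c.variant = 2;
  else if (v == "catonlycrossdit") c.variant = 3;
  else if (v == "adadit") c.variant = 4;
  else stop("unknown variant: " + v);
  c.ng = as<int>(cfg["n_gene"]);
  c.d = as<int>(cfg["d_model"]);
  c.nl = as<int>(cfg["n_layers"]);
  c.nh = as<int>(cfg["n_heads"]);
  c.dff = as<int>(cfg["d_ff"]);
  return c;
}

static inline arma::mat silu(const arma::mat& x) {
  return x % (1.0 / (1.0 + arma::exp(-x)));
}
static inline arma::mat silu_grad(const arma::mat& x) {
  arma::mat s = 1.0 / (1.0 + arma::exp(-x));
  return s % (1.0 + x % (1.0 - s));
}

struct LnCache { arma::mat y; arma::vec inv; };

static arma::mat ln_fwd(const arma::mat& X, LnCache& c) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X;
  xc.each_col() -= mu;
  arma::vec v = arma::mean(xc % xc, 1);
  c.inv = 1.0 / arma::sqrt(v + LN_EPS);
  xc.each_col() %= c.inv;
  c.y = xc;
  return c.y;
}

static arma::mat ln_bwd(const LnCache& c, const arma::mat& dy) {
  arma::vec m1 = arma::mean(dy, 1);
  arma::vec m2 = arma::mean(dy % c.y, 1);
  arma::mat t = c.y;
  t.each_col() %= m2;
  arma::mat dx = dy;
  dx.each_col() -= m1;
  dx -= t;
  dx.each_col() %= c.inv;
  return dx;
}

static arma::mat softmax_rows(arma::mat S) {
  S.each_col() -= arma::max(S, 1);
  arma::mat E = arma::exp(S);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

struct MhaCache {
  arma::mat Qin, Cin, Q, K, V, O;
  std::vector<arma::mat> P;
  arma::mat out;
};

static arma::mat mha_fwd(const Pars& Pp, const std::string& pre,
                         const arma::mat& Qin, const arma::mat& Cin,
                         int nh, MhaCache& c) {
  int d = Qin.n_cols, dh = d / nh;
  c.Qin = Qin; c.Cin = Cin;
  c.Q = Qin * Pp.m(pre + ".Wq"); c.Q.each_row() += Pp.v(pre + ".bq").t();
  c.K = Cin * Pp.m(pre + ".Wk"); c.K.each_row() += Pp.v(pre + ".bk").t();
  c.V = Cin * Pp.m(pre + ".Wv"); c.V.each_row() += Pp.v(pre + ".bv").t();
  c.O.zeros(Qin.n_rows, d);
  c.P.assign(nh, arma::mat());
  double sc = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < nh; ++h) {
    arma::span cs(h * dh, (h + 1) * dh - 1);
    arma::mat S = c.Q.cols(cs) * c.K.cols(cs).t() * sc;
    c.P[h] = softmax_rows(S);
    c.O.cols(cs) = c.P[h] * c.V.cols(cs);
  }
  c.out = c.O * Pp.m(pre + ".Wo");
  c.out.each_row() += Pp.v(pre + ".bo").t();
  return c.out;
}

// returns dQin; accumulates dCin into dCin_acc (callers pass the right
// accumulator: the perturbation-token grad, the control-stream grad, or,
// for self-attention, the same matrix as dQin).
static void mha_bwd(const Pars& Pp, const std::string& pre, const MhaCache& c,
                    const arma::mat& dout, int nh, Grads& G,
                    arma::mat& dQin, arma::mat& dCin) {
  int d = c.O.n_cols, dh = d / nh;
  G.V[pre + ".bo"] += arma::sum(dout, 0).t();
  G.M[pre + ".Wo"] += c.O.t() * dout;
  arma::mat dO = dout * Pp.m(pre + ".Wo").t();
  arma::mat dQ(c.Q.n_rows, d, arma::fill::zeros);
  arma::mat dK(c.K.n_rows, d, arma::fill::zeros);
  arma::mat dV(c.V.n_rows, d, arma::fill::zeros);
  double sc = 1.0 / std::sqrt((double)dh);
  for (int h = 0; h < nh; ++h) {
    arma::span cs(h * dh, (h + 1) * dh - 1);
    const arma::mat& P = c.P[h];
    arma::mat dOh = dO.cols(cs);
    arma::mat dP = dOh * c.V.cols(cs).t();
    dV.cols(cs) = P.t() * dOh;
    arma::mat dS = dP;                        // P % (dP - rowsum(dP % P))
    dS.each_col() -= arma::sum(P % dP, 1);
    dS %= P;
    dS *= sc;
    dQ.cols(cs) = dS * c.K.cols(cs);
    dK.cols(cs) = dS.t() * c.Q.cols(cs);
  }
  G.M[pre + ".Wq"] += c.Qin.t() * dQ; G.V[pre + ".bq"] += arma::sum(dQ, 0).t();
  G.M[pre + ".Wk"] += c.Cin.t() * dK; G.V[pre + ".bk"] += arma::sum(dK, 0).t();
  G.M[pre + ".Wv"] += c.Cin.t() * dV; G.V[pre + ".bv"] += arma::sum(dV, 0).t();
  dQin += dQ * Pp.m(pre + ".Wq").t();
  dCin += dK * Pp.m(pre + ".Wk").t() + dV * Pp.m(pre + ".Wv").t();
}

struct FfnCache { arma::mat X, A1, H, out; };

static arma::mat ffn_fwd(const Pars& Pp, const std::string& pre,
                         const arma::mat& X, FfnCache& c) {
  c.X = X;
  c.A1 = X * Pp.m(pre + ".W1"); c.A1.each_row() += Pp.v(pre + ".b1").t();
  c.H = silu(c.A1);
  c.out = c.H * Pp.m(pre + ".W2"); c.out.each_row() += Pp.v(pre + ".b2").t();
  return c.out;
}

static arma::mat ffn_bwd(const Pars& Pp, const std::string& pre,
                         const FfnCache& c, const arma::mat& dout, Grads& G) {
  G.M[pre + ".W2"] += c.H.t() * dout;
  G.V[pre + ".b2"] += arma::sum(dout, 0).t();
  arma::mat dA1 = (dout * Pp.m(pre + ".W2").t()) % silu_grad(c.A1);
  G.M[pre + ".W1"] += c.X.t() * dA1;
  G.V[pre + ".b1"] += arma::sum(dA1, 0).t();
  return dA1 * Pp.m(pre + ".W1").t();
}

static arma::rowvec sinusoid(double t, int d) {
  int half = d / 2;
  arma::rowvec out(d);
  for (int i = 0; i < half; ++i) {
    double f = std::exp(-std::log(10000.0) * i / half);
    out(i) = std::sin(t * f);
    out(half + i) = std::cos(t * f);
  }
  return out;
}

struct AdaSet { arma::rowvec g1, b1, a1, g2, b2, a2; };

struct LayerCache {
  LnCache ln1, ln2, ln3, lnA1, lnA2;
  MhaCache at1, at2;
  FfnCache ff;
  arma::rowvec raw;
  AdaSet md;
  arma::mat M1, M2;
};

struct FwCache {
  double tstep;
  arma::rowvec sinus, t_a1, t_h, temb;
  arma::mat H0, Hc0, P0, XC, ptok;
  arma::rowvec cond, pv, p_a1, p_h;
  std::vector<LayerCache> L;
  LnCache lnf;
  arma::vec x_t, c_pre, eps_hat;
};

// pert: token matrix (n_valid x d_text) for variants 1-3, or a 1 x d_text
// row vector for adadit.
static arma::vec forward_record(const Pars& Pp, const Cfg& cfg,
                                const arma::vec& x_t, const arma::vec& c_pre,
                                const arma::mat& pert, FwCache& C) {
  int d = cfg.d;
  C.x_t = x_t; C.c_pre = c_pre;
  // T-adapter -------------------------------------------------------------
  C.sinus = sinusoid(C.tstep, d); // tstep set by caller before this call
  C.t_a1 = C.sinus * Pp.m("t.W1") + Pp.v("t.b1").t();
  C.t_h = silu(C.t_a1);
  C.temb = C.t_h * Pp.m("t.W2") + Pp.v("t.b2").t();
  // adapters --------------------------------------------------------------
  arma::mat H;
  if (cfg.variant == 1) {
    C.H0 = x_t * Pp.m("ax.W"); // (ng x 1) * (1 x d)
    C.H0.each_row() += Pp.v("ax.b").t() + C.temb;
    C.H0 += Pp.m("pos");
    C.Hc0 = c_pre * Pp.m("ac.W");
    C.Hc0.each_row() += Pp.v("ac.b").t() + C.temb;
    C.Hc0 += Pp.m("pos");
  } else {
    C.XC = arma::join_rows(x_t, c_pre);
    C.H0 = C.XC * Pp.m("ax.W");
    C.H0.each_row() += Pp.v("ax.b").t() + C.temb;
    C.H0 += Pp.m("pos");
  }
  H = C.H0;
  if (cfg.variant == 4) {
    C.pv = arma::rowvec(pert.row(0));
    C.p_a1 = C.pv * Pp.m("ap.W1") + Pp.v("ap.b1").t();
    C.p_h = silu(C.p_a1);
    C.cond = C.temb + C.p_h * Pp.m("ap.W2") + Pp.v("ap.b2").t();
  } else {
    C.ptok = pert;
    C.P0 = pert * Pp.m("ap.W");
    C.P0.each_row() += Pp.v("ap.b").t() + C.temb;
  }
  // layers ----------------------------------------------------------------
  C.L.assign(cfg.nl, LayerCache());
  for (int l = 0; l < cfg.nl; ++l) {
    std::string Lp = "L" + std::to_string(l + 1);
    LayerCache& lc = C.L[l];
    if (cfg.variant == 1 || cfg.variant == 2) {
      ln_fwd(H, lc.ln1);
      if (cfg.variant == 1) H += mha_fwd(Pp, Lp + ".ca1", lc.ln1.y, C.Hc0, cfg.nh, lc.at1);
      else H += mha_fwd(Pp, Lp + ".sa", lc.ln1.y, lc.ln1.y, cfg.nh, lc.at1);
      ln_fwd(H, lc.ln2);
      H += mha_fwd(Pp, Lp + (cfg.variant == 1 ? ".ca2" : ".ca"), lc.ln2.y, C.P0, cfg.nh, lc.at2);
      ln_fwd(H, lc.ln3);
      H += ffn_fwd(Pp, Lp + ".ffn", lc.ln3.y, lc.ff);
    } else if (cfg.variant == 3) {
      ln_fwd(H, lc.ln2);
      H += mha_fwd(Pp, Lp + ".ca", lc.ln2.y, C.P0, cfg.nh, lc.at2);
      ln_fwd(H, lc.ln3);
      H += ffn_fwd(Pp, Lp + ".ffn", lc.ln3.y, lc.ff);
    } else { // adadit
      lc.raw = C.cond * Pp.m(Lp + ".ada.W") + Pp.v(Lp + ".ada.b").t();
      lc.md.g1 = 1.0 + lc.raw.cols(0, d - 1);
      lc.md.b1 = lc.raw.cols(d, 2 * d - 1);
      lc.md.a1 = lc.raw.cols(2 * d, 3 * d - 1);
      lc.md.g2 = 1.0 + lc.raw.cols(3 * d, 4 * d - 1);
      lc.md.b2 = lc.raw.cols(4 * d, 5 * d - 1);
      lc.md.a2 = lc.raw.cols(5 * d, 6 * d - 1);
      ln_fwd(H, lc.ln1);
      lc.M1 = lc.ln1.y;
      lc.M1.each_row() %= lc.md.g1;
      lc.M1.each_row() += lc.md.b1;
      arma::mat A = mha_fwd(Pp, Lp + ".sa", lc.M1, lc.M1, cfg.nh, lc.at1);
      A.each_row() %= lc.md.a1;
      H += A;
      ln_fwd(H, lc.ln2);
      lc.M2 = lc.ln2.y;
      lc.M2.each_row() %= lc.md.g2;
      lc.M2.each_row() += lc.md.b2;
      arma::mat F = ffn_fwd(Pp, Lp + ".ffn", lc.M2, lc.ff);
      F.each_row() %= lc.md.a2;
      H += F;
    }
  }
  ln_fwd(H, C.lnf);
  C.eps_hat = C.lnf.y * Pp.v("head.w") + Pp.v("head.b")(0);
  return C.eps_hat;
}

static void backward_record(const Pars& Pp, const Cfg& cfg, const FwCache& C,
                            const arma::vec& d_eps, Grads& G) {
  int d = cfg.d;
  G.V["head.w"] += C.lnf.y.t() * d_eps;
  G.V["head.b"](0) += arma::accu(d_eps);
  arma::mat dH = ln_bwd(C.lnf, d_eps * Pp.v("head.w").t());
  arma::mat dHc0, dP0;
  arma::rowvec dcond;
  if (cfg.variant == 1) dHc0.zeros(C.Hc0.n_rows, d);
  if (cfg.variant != 4) dP0.zeros(C.P0.n_rows, d);
  else dcond.zeros(d);
  for (int l = cfg.nl - 1; l >= 0; --l) {
    std::string Lp = "L" + std::to_string(l + 1);
    const LayerCache& lc = C.L[l];
    if (cfg.variant != 4) {
      arma::mat dX = ffn_bwd(Pp, Lp + ".ffn", lc.ff, dH, G);
      dH += ln_bwd(lc.ln3, dX);
      std::string ca = Lp + (cfg.variant == 1 ? ".ca2" : ".ca");
      arma::mat dQin(dH.n_rows, d, arma::fill::zeros);
      mha_bwd(Pp, ca, lc.at2, dH, cfg.nh, G, dQin, dP0);
      dH += ln_bwd(lc.ln2, dQin);
      if (cfg.variant == 1) {
        arma::mat dQ1(dH.n_rows, d, arma::fill::zeros);
        mha_bwd(Pp, Lp + ".ca1", lc.at1, dH, cfg.nh, G, dQ1, dHc0);
        dH += ln_bwd(lc.ln1, dQ1);
      } else if (cfg.variant == 2) {
        arma::mat dln(dH.n_rows, d, arma::fill::zeros);
        mha_bwd(Pp, Lp + ".sa", lc.at1, dH, cfg.nh, G, dln, dln);
        dH += ln_bwd(lc.ln1, dln);
      }
    } else {
      const AdaSet& md = lc.md;
      arma::rowvec d_a2 = arma::sum(dH % lc.ff.out, 0);
      arma::mat dF = dH; dF.each_row() %= md.a2;
      arma::mat dM2 = ffn_bwd(Pp, Lp + ".ffn", lc.ff, dF, G);
      arma::rowvec d_g2 = arma::sum(dM2 % lc.ln2.y, 0);
      arma::rowvec d_b2 = arma::sum(dM2, 0);
      arma::mat dln2 = dM2; dln2.each_row() %= md.g2;
      dH += ln_bwd(lc.ln2, dln2);
      arma::rowvec d_a1 = arma::sum(dH % lc.at1.out, 0);
      arma::mat dA = dH; dA.each_row() %= md.a1;
      arma::mat dM1(dH.n_rows, d, arma::fill::zeros);
      mha_bwd(Pp, Lp + ".sa", lc.at1, dA, cfg.nh, G, dM1, dM1);
      arma::rowvec d_g1 = arma::sum(dM1 % lc.ln1.y, 0);
      arma::rowvec d_b1 = arma::sum(dM1, 0);
      arma::mat dln1 = dM1; dln1.each_row() %= md.g1;
      dH += ln_bwd(lc.ln1, dln1);
      arma::rowvec draw = arma::join_rows(
        arma::join_rows(arma::join_rows(d_g1, d_b1), d_a1),
        arma::join_rows(arma::join_rows(d_g2, d_b2), d_a2));
      G.M[Lp + ".ada.W"] += C.cond.t() * draw;
      G.V[Lp + ".ada.b"] += draw.t();
      dcond += draw * Pp.m(Lp + ".ada.W").t();
    }
  }
  arma::rowvec d_temb(d, arma::fill::zeros);
  if (cfg.variant == 1) {
    G.M["ax.W"] += C.x_t.t() * dH;
    G.V["ax.b"] += arma::sum(dH, 0).t();
    G.M["ac.W"] += C.c_pre.t() * dHc0;
    G.V["ac.b"] += arma::sum(dHc0, 0).t();
    G.M["pos"] += dH + dHc0;
    d_temb += arma::sum(dH, 0) + arma::sum(dHc0, 0);
  } else {
    G.M["ax.W"] += C.XC.t() * dH;
    G.V["ax.b"] += arma::sum(dH, 0).t();
    G.M["pos"] += dH;
    d_temb += arma::sum(dH, 0);
  }
  if (cfg.variant == 4) {
    d_temb += dcond;
    G.M["ap.W2"] += C.p_h.t() * dcond;
    G.V["ap.b2"] += dcond.t();
    arma::rowvec dh_ = dcond * Pp.m("ap.W2").t();
    arma::rowvec da1 = dh_ % silu_grad(C.p_a1);
    G.M["ap.W1"] += C.pv.t() * da1;
    G.V["ap.b1"] += da1.t();
  } else {
    G.M["ap.W"] += C.ptok.t() * dP0;
    G.V["ap.b"] += arma::sum(dP0, 0).t();
    d_temb += arma::sum(dP0, 0);
  }
  G.V["t.b2"] += d_temb.t();
  G.M["t.W2"] += C.t_h.t() * d_temb;
  arma::rowvec dth = d_temb * Pp.m("t.W2").t();
  arma::rowvec dta1 = dth % silu_grad(C.t_a1);
  G.M["t.W1"] += C.sinus.t() * dta1;
  G.V["t.b1"] += dta1.t();
}

static List grads_to_list(const Grads& G, List par) {
  CharacterVector nms = par.names();
  List out(par.size());
  for (int i = 0; i < par.size(); ++i) {
    std::string n = as<std::string>(nms[i]);
    RObject o = par[i];
    if (o.hasAttribute("dim")) out[i] = wrap(G.M.at(n));
    else {
      const arma::vec& v = G.V.at(n);
      out[i] = NumericVector(v.begin(), v.end());
    }
  }
  out.names() = nms;
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad_batch(List par, List cfg_list, const arma::mat& XT,
                         const arma::mat& CPRE, List perts,
                         const IntegerVector& tvec, const arma::mat& EPS) {
  Pars Pp = load_pars(par);
  Cfg cfg = load_cfg(cfg_list);
  Grads G;
  G.init_like(Pp);
  double loss = 0.0;
  int B = XT.n_cols;
  FwCache C;
  for (int j = 0; j < B; ++j) {
    C.tstep = tvec[j];
    arma::mat pert = as<arma::mat>(perts[j]);
    arma::vec eps_hat = forward_record(Pp, cfg, XT.col(j), CPRE.col(j), pert, C);
    arma::vec diff = eps_hat - EPS.col(j);
    loss += arma::dot(diff, diff);
    backward_record(Pp, cfg, C, 2.0 * diff, G);
  }
  return List::create(_["loss"] = loss,
                      _["grads"] = grads_to_list(G, par));
}

// [[Rcpp::export]]
arma::mat cpp_forward_batch(List par, List cfg_list, const arma::mat& XT,
                            const arma::mat& CPRE, List perts,
                            const IntegerVector& tvec) {
  Pars Pp = load_pars(par);
  Cfg cfg = load_cfg(cfg_list);
  int B = XT.n_cols;
  arma::mat out(cfg.ng, B);
  FwCache C;
  for (int j = 0; j < B; ++j) {
    C.tstep = tvec[j];
    arma::mat pert = as<arma::mat>(perts[j]);
    out.col(j) = forward_record(Pp, cfg, XT.col(j), CPRE.col(j), pert, C);
  }
  return out;
}
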