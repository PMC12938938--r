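// GPTNeXt network: forward, backprop and SGD-with-momentum, implemented on
// dense Armadillo matrices. Activations are stored as (N*H*W) x C matrices,
// sample n occupying rows [n*H*W, (n+1)*H*W), spatial index s = h + H*w.
// Caches for backprop are only kept when store == true; inference runs with
// constant memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double NORM_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// ---------------------------------------------------------------- conv ----

struct ConvSpec {
  int k, stride, pad, in_c, out_c, groups;
  int in_pg() const { return in_c / groups; }
  int out_pg() const { return out_c / groups; }
  int wrows() const { return k * k * in_pg(); }
};

struct PConv {
  ConvSpec cs;
  mat W;  // (k*k*in_pg) x out_c, column j belongs to group j / out_pg
  vec b;
  mat gW; vec gb;
  mat vW; vec vb;
  void alloc() {
    W.zeros(cs.wrows(), cs.out_c); b.zeros(cs.out_c);
    gW.zeros(size(W)); gb.zeros(size(b));
    vW.zeros(size(W)); vb.zeros(size(b));
  }
};

struct ConvCache { mat Ain; int H, W, N, Ho, Wo; };

// gather the im2col matrix for one sample / one group
static mat im2col(const mat& A, int n, int H, int Wd, const ConvSpec& cs,
                  int g, int Ho, int Wo) {
  const int ipg = cs.in_pg();
  mat cols(Ho * Wo, cs.wrows(), fill::zeros);
  const int base = n * H * Wd;
  for (int cl = 0; cl < ipg; ++cl) {
    const int c = g * ipg + cl;
    for (int kw = 0; kw < cs.k; ++kw) {
      for (int kh = 0; kh < cs.k; ++kh) {
        const int col = cl * cs.k * cs.k + kw * cs.k + kh;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * cs.stride - cs.pad + kw;
          if (wi < 0 || wi >= Wd) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * cs.stride - cs.pad + kh;
            if (hi < 0 || hi >= H) continue;
            cols(ho + Ho * wo, col) = A(base + hi + H * wi, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(mat& dA, const mat& dcols, int n, int H, int Wd,
                       const ConvSpec& cs, int g, int Ho, int Wo) {
  const int ipg = cs.in_pg();
  const int base = n * H * Wd;
  for (int cl = 0; cl < ipg; ++cl) {
    const int c = g * ipg + cl;
    for (int kw = 0; kw < cs.k; ++kw) {
      for (int kh = 0; kh < cs.k; ++kh) {
        const int col = cl * cs.k * cs.k + kw * cs.k + kh;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * cs.stride - cs.pad + kw;
          if (wi < 0 || wi >= Wd) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * cs.stride - cs.pad + kh;
            if (hi < 0 || hi >= H) continue;
            dA(base + hi + H * wi, c) += dcols(ho + Ho * wo, col);
          }
        }
      }
    }
  }
}

static mat conv_forward(PConv& L, const mat& A, int N, int H, int Wd,
                        int& Ho_out, int& Wo_out, ConvCache* cache) {
  const ConvSpec& cs = L.cs;
  const int Ho = (H + 2 * cs.pad - cs.k) / cs.stride + 1;
  const int Wo = (Wd + 2 * cs.pad - cs.k) / cs.stride + 1;
  const int opg = cs.out_pg();
  mat Y(N * Ho * Wo, cs.out_c);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < cs.groups; ++g) {
      mat cols = im2col(A, n, H, Wd, cs, g, Ho, Wo);
      Y.submat(n * Ho * Wo, g * opg, (n + 1) * Ho * Wo - 1, (g + 1) * opg - 1) =
          cols * L.W.cols(g * opg, (g + 1) * opg - 1);
    }
  }
  Y.each_row() += L.b.t();
  if (cache) {
    cache->Ain = A; cache->H = H; cache->W = Wd; cache->N = N;
    cache->Ho = Ho; cache->Wo = Wo;
  }
  Ho_out = Ho; Wo_out = Wo;
  return Y;
}

static mat conv_backward(PConv& L, const ConvCache& cache, const mat& dY) {
  const ConvSpec& cs = L.cs;
  const int opg = cs.out_pg();
  const int N = cache.N, H = cache.H, Wd = cache.W, Ho = cache.Ho, Wo = cache.Wo;
  mat dA(size(cache.Ain), fill::zeros);
  L.gb += sum(dY, 0).t();
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < cs.groups; ++g) {
      mat cols = im2col(cache.Ain, n, H, Wd, cs, g, Ho, Wo);
      mat dYblk = dY.submat(n * Ho * Wo, g * opg,
                            (n + 1) * Ho * Wo - 1, (g + 1) * opg - 1);
      L.gW.cols(g * opg, (g + 1) * opg - 1) += cols.t() * dYblk;
      mat dcols = dYblk * L.W.cols(g * opg, (g + 1) * opg - 1).t();
      col2im_add(dA, dcols, n, H, Wd, cs, g, Ho, Wo);
    }
  }
  return dA;
}

// ---------------------------------------------------------------- norm ----

// batch == true: batch norm (stats per channel over all rows, running stats
// for inference); batch == false: layer norm (stats per row over channels).
struct PNorm {
  int C; bool batch;
  vec g, be, gg, gbe, vg, vbe;
  vec rmean, rvar;
  void alloc() {
    g.ones(C); be.zeros(C);
    gg.zeros(C); gbe.zeros(C); vg.zeros(C); vbe.zeros(C);
    rmean.zeros(C); rvar.ones(C);
  }
};

struct NormCache { mat Xhat; vec invstd; };  // invstd: per row (LN) / per col (BN)

static mat norm_forward(PNorm& L, const mat& A, bool training, NormCache* cache,
                        double bn_mom = BN_MOMENTUM) {
  mat Xhat; vec invstd;
  if (L.batch) {
    vec mu, va;
    if (training) {
      mu = mean(A, 0).t();
      va = mean(square(A.each_row() - mu.t()), 0).t();
      L.rmean = (1.0 - bn_mom) * L.rmean + bn_mom * mu;
      L.rvar  = (1.0 - bn_mom) * L.rvar  + bn_mom * va;
    } else {
      mu = L.rmean; va = L.rvar;
    }
    invstd = 1.0 / sqrt(va + NORM_EPS);
    Xhat = (A.each_row() - mu.t());
    Xhat.each_row() %= invstd.t();
  } else {
    vec mu = mean(A, 1);
    vec va = mean(square(A.each_col() - mu), 1);
    invstd = 1.0 / sqrt(va + NORM_EPS);
    Xhat = (A.each_col() - mu);
    Xhat.each_col() %= invstd;
  }
  mat Y = Xhat;
  Y.each_row() %= L.g.t();
  Y.each_row() += L.be.t();
  if (cache) { cache->Xhat = std::move(Xhat); cache->invstd = std::move(invstd); }
  return Y;
}

static mat norm_backward(PNorm& L, const NormCache& cache, const mat& dY,
                         bool training) {
  L.gg  += sum(dY % cache.Xhat, 0).t();
  L.gbe += sum(dY, 0).t();
  mat dXhat = dY;
  dXhat.each_row() %= L.g.t();
  if (L.batch) {
    if (!training) {  // inference-mode stats are constants
      dXhat.each_row() %= cache.invstd.t();
      return dXhat;
    }
    const double M = (double)dXhat.n_rows;
    rowvec s1 = sum(dXhat, 0) / M;
    rowvec s2 = sum(dXhat % cache.Xhat, 0) / M;
    mat dA = dXhat;
    dA.each_row() -= s1;
    dA -= cache.Xhat.each_row() % s2;
    dA.each_row() %= cache.invstd.t();
    return dA;
  } else {
    const double M = (double)dXhat.n_cols;
    vec s1 = sum(dXhat, 1) / M;
    vec s2 = sum(dXhat % cache.Xhat, 1) / M;
    mat dA = dXhat;
    dA.each_col() -= s1;
    dA -= cache.Xhat.each_col() % s2;
    dA.each_col() %= cache.invstd;
    return dA;
  }
}

// ---------------------------------------------------------------- gelu ----

struct GeluCache { mat X; };

static mat gelu_forward(const mat& A, GeluCache* cache) {
  if (cache) cache->X = A;
  return A % normcdf(A);
}

static mat gelu_backward(const GeluCache& cache, const mat& dY) {
  const mat& X = cache.X;
  mat phi = exp(-0.5 * square(X)) / std::sqrt(2.0 * datum::pi);
  return dY % (normcdf(X) + X % phi);
}

// ----------------------------------------------------------------- net ----

struct PDense {
  mat W; vec b; mat gW; vec gb; mat vW; vec vb;
  void alloc(int in, int out) {
    W.zeros(in, out); b.zeros(out);
    gW.zeros(size(W)); gb.zeros(size(b));
    vW.zeros(size(W)); vb.zeros(size(b));
  }
};

struct SubUnit { PNorm ln; PConv dw; PConv pw; PNorm bn; };
struct Block { SubUnit u[2]; };
struct Down { PConv conv; PNorm ln; };

struct SubCache { NormCache ln; ConvCache dw; GeluCache ge; ConvCache pw; NormCache bn; };
struct BlockCache { SubCache u[2]; };
struct DownCache { ConvCache conv; NormCache ln; GeluCache ge; };
struct OutCache {
  ConvCache conv; NormCache ln; GeluCache ge; NormCache bn;
  int HW; int N;
  mat pregap; mat gap; mat probs;
};

struct ParamRef { double* w; double* g; double* v; size_t n; std::string kind; };

struct Net {
  int input_side, in_ch, ncls, expf;
  std::vector<int> filters, reps;

  PConv stem; PNorm stem_bn;
  std::vector<std::vector<Block> > stages;  // 4 stages
  std::vector<Down> downs;                  // 3 downsamples
  PConv outconv; PNorm out_ln; PNorm out_bn; PDense fc;

  std::vector<ParamRef> prefs;
  double bn_mom = BN_MOMENTUM;

  // forward caches (kept on the object between loss_grad calls)
  ConvCache c_stem; NormCache c_stem_bn; GeluCache c_stem_ge;
  std::vector<std::vector<BlockCache> > c_stages;
  std::vector<DownCache> c_downs;
  OutCache c_out;

  void add_conv(PConv& L, const std::string& kind) {
    prefs.push_back({L.W.memptr(), L.gW.memptr(), L.vW.memptr(), L.W.n_elem, kind});
    prefs.push_back({L.b.memptr(), L.gb.memptr(), L.vb.memptr(), L.b.n_elem, "bias"});
  }
  void add_norm(PNorm& L) {
    prefs.push_back({L.g.memptr(),  L.gg.memptr(),  L.vg.memptr(),  L.g.n_elem,  "scale"});
    prefs.push_back({L.be.memptr(), L.gbe.memptr(), L.vbe.memptr(), L.be.n_elem, "shift"});
  }

  void build() {
    const int f0 = filters[0], f4 = filters[4];
    stem.cs = ConvSpec{4, 4, 0, in_ch, f0, 1}; stem.alloc();
    stem_bn.C = f0; stem_bn.batch = true; stem_bn.alloc();
    stages.resize(4); c_stages.resize(4);
    for (int i = 0; i < 4; ++i) {
      const int C = filters[i];
      stages[i].resize(reps[i]);
      for (int r = 0; r < reps[i]; ++r) {
        Block& B = stages[i][r];
        for (int s = 0; s < 2; ++s) {
          SubUnit& U = B.u[s];
          U.ln.C = C; U.ln.batch = false; U.ln.alloc();
          U.dw.cs = ConvSpec{3, 1, 1, C, C * expf, C}; U.dw.alloc();
          U.pw.cs = ConvSpec{1, 1, 0, C * expf, C, 1}; U.pw.alloc();
          U.bn.C = C; U.bn.batch = true; U.bn.alloc();
        }
      }
      c_stages[i].resize(reps[i]);
    }
    downs.resize(3); c_downs.resize(3);
    for (int i = 0; i < 3; ++i) {
      const int C = filters[i], Cn = filters[i + 1];
      downs[i].conv.cs = ConvSpec{2, 2, 0, C, Cn, C}; downs[i].conv.alloc();
      downs[i].ln.C = Cn; downs[i].ln.batch = false; downs[i].ln.alloc();
    }
    outconv.cs = ConvSpec{1, 1, 0, filters[3], f4, 1}; outconv.alloc();
    out_ln.C = f4; out_ln.batch = false; out_ln.alloc();
    out_bn.C = f4; out_bn.batch = true;  out_bn.alloc();
    fc.alloc(f4, ncls);

    prefs.clear();
    add_conv(stem, "conv"); add_norm(stem_bn);
    for (int i = 0; i < 4; ++i) {
      for (int r = 0; r < reps[i]; ++r) {
        for (int s = 0; s < 2; ++s) {
          SubUnit& U = stages[i][r].u[s];
          add_norm(U.ln); add_conv(U.dw, "conv"); add_conv(U.pw, "conv");
          add_norm(U.bn);
        }
      }
      if (i < 3) { add_conv(downs[i].conv, "conv"); add_norm(downs[i].ln); }
    }
    add_conv(outconv, "conv"); add_norm(out_ln); add_norm(out_bn);
    prefs.push_back({fc.W.memptr(), fc.gW.memptr(), fc.vW.memptr(), fc.W.n_elem, "fc"});
    prefs.push_back({fc.b.memptr(), fc.gb.memptr(), fc.vb.memptr(), fc.b.n_elem, "bias"});
  }

  size_t n_params() const {
    size_t n = 0;
    for (size_t i = 0; i < prefs.size(); ++i) n += prefs[i].n;
    return n;
  }

  // forward through the trunk at spatial side H0 x W0 (the trunk is
  // size-agnostic; native-mode patch features use sides below input_side)
  void forward(const mat& X0, int N, int H0, int W0, bool training, bool store) {
    int H = H0, Wd = W0, Ho, Wo;
    mat A = conv_forward(stem, X0, N, H, Wd, Ho, Wo, store ? &c_stem : 0);
    H = Ho; Wd = Wo;
    A = norm_forward(stem_bn, A, training, store ? &c_stem_bn : 0, bn_mom);
    A = gelu_forward(A, store ? &c_stem_ge : 0);
    for (int i = 0; i < 4; ++i) {
      for (int r = 0; r < reps[i]; ++r) {
        Block& B = stages[i][r];
        BlockCache* BC = store ? &c_stages[i][r] : 0;
        for (int s = 0; s < 2; ++s) {
          SubUnit& U = B.u[s];
          SubCache* SC = BC ? &BC->u[s] : 0;
          mat t = norm_forward(U.ln, A, training, SC ? &SC->ln : 0, bn_mom);
          t = conv_forward(U.dw, t, N, H, Wd, Ho, Wo, SC ? &SC->dw : 0);
          t = gelu_forward(t, SC ? &SC->ge : 0);
          t = conv_forward(U.pw, t, N, H, Wd, Ho, Wo, SC ? &SC->pw : 0);
          t = norm_forward(U.bn, t, training, SC ? &SC->bn : 0, bn_mom);
          A += t;  // shortcut
        }
      }
      if (i < 3) {
        Down& D = downs[i];
        DownCache* DC = store ? &c_downs[i] : 0;
        A = conv_forward(D.conv, A, N, H, Wd, Ho, Wo, DC ? &DC->conv : 0);
        H = Ho; Wd = Wo;
        A = norm_forward(D.ln, A, training, DC ? &DC->ln : 0, bn_mom);
        A = gelu_forward(A, DC ? &DC->ge : 0);
      }
    }
    A = conv_forward(outconv, A, N, H, Wd, Ho, Wo, store ? &c_out.conv : 0);
    A = norm_forward(out_ln, A, training, store ? &c_out.ln : 0, bn_mom);
    A = gelu_forward(A, store ? &c_out.ge : 0);
    A = norm_forward(out_bn, A, training, store ? &c_out.bn : 0, bn_mom);
    const int HW = H * Wd;
    c_out.HW = HW; c_out.N = N;
    c_out.pregap = A;  // final activation map (HW x C per sample), small
    mat G(N, filters[4]);
    for (int n = 0; n < N; ++n)
      G.row(n) = mean(A.rows(n * HW, (n + 1) * HW - 1), 0);
    c_out.gap = G;
    mat logits = G * fc.W;
    logits.each_row() += fc.b.t();
    mat P = logits.each_col() - max(logits, 1);
    P = exp(P);
    P.each_col() /= sum(P, 1);
    c_out.probs = P;
  }

  double loss_from_probs(const uvec& y) const {
    double L = 0.0;
    for (uword n = 0; n < y.n_elem; ++n)
      L -= std::log(std::max(c_out.probs(n, y(n)), 1e-300));
    return L / (double)y.n_elem;
  }

  void zero_grads() {
    for (size_t i = 0; i < prefs.size(); ++i)
      std::memset(prefs[i].g, 0, prefs[i].n * sizeof(double));
  }

  // backward from cross-entropy; forward(..., store = true) must have run
  void backward(const uvec& y, bool training) {
    const int N = c_out.N, HW = c_out.HW;
    mat dlogits = c_out.probs;
    for (int n = 0; n < N; ++n) dlogits(n, y(n)) -= 1.0;
    dlogits /= (double)N;
    fc.gW += c_out.gap.t() * dlogits;
    fc.gb += sum(dlogits, 0).t();
    mat dG = dlogits * fc.W.t();
    mat dA(N * HW, filters[4]);
    for (int n = 0; n < N; ++n)
      dA.rows(n * HW, (n + 1) * HW - 1) =
          repmat(dG.row(n) / (double)HW, HW, 1);
    dA = norm_backward(out_bn, c_out.bn, dA, training);
    dA = gelu_backward(c_out.ge, dA);
    dA = norm_backward(out_ln, c_out.ln, dA, training);
    dA = conv_backward(outconv, c_out.conv, dA);
    for (int i = 3; i >= 0; --i) {
      if (i < 3) {
        Down& D = downs[i]; DownCache& DC = c_downs[i];
        dA = gelu_backward(DC.ge, dA);
        dA = norm_backward(D.ln, DC.ln, dA, training);
        dA = conv_backward(D.conv, DC.conv, dA);
      }
      for (int r = reps[i] - 1; r >= 0; --r) {
        Block& B = stages[i][r]; BlockCache& BC = c_stages[i][r];
        for (int s = 1; s >= 0; --s) {
          SubUnit& U = B.u[s]; SubCache& SC = BC.u[s];
          mat dt = norm_backward(U.bn, SC.bn, dA, training);
          dt = conv_backward(U.pw, SC.pw, dt);
          dt = gelu_backward(SC.ge, dt);
          dt = conv_backward(U.dw, SC.dw, dt);
          dt = norm_backward(U.ln, SC.ln, dt, training);
          dA += dt;  // shortcut: gradient flows through identity + sub-unit
        }
      }
    }
    dA = gelu_backward(c_stem_ge, dA);
    dA = norm_backward(stem_bn, c_stem_bn, dA, training);
    conv_backward(stem, c_stem, dA);
  }

  void sgd_step(double lr, double momentum) {
    for (size_t i = 0; i < prefs.size(); ++i) {
      ParamRef& p = prefs[i];
      for (size_t j = 0; j < p.n; ++j) {
        p.v[j] = momentum * p.v[j] - lr * p.g[j];
        p.w[j] += p.v[j];
      }
    }
  }

  void drop_caches() {
    c_stem = ConvCache(); c_stem_bn = NormCache(); c_stem_ge = GeluCache();
    for (size_t i = 0; i < c_stages.size(); ++i)
      for (size_t r = 0; r < c_stages[i].size(); ++r)
        c_stages[i][r] = BlockCache();
    for (size_t i = 0; i < c_downs.size(); ++i) c_downs[i] = DownCache();
    c_out.conv = ConvCache(); c_out.ln = NormCache();
    c_out.ge = GeluCache(); c_out.bn = NormCache();
  }
};

// ------------------------------------------------------------ R bridge ----

static Net* get_net(SEXP ptr) {
  Rcpp::XPtr<Net> x(ptr);
  return x.get();
}

// convert (H,W,C,N) array into the internal (N*H*W) x C matrix
static mat array_to_batch(const Rcpp::NumericVector& x, int H, int Wd, int C, int N) {
  mat A(N * H * Wd, C);
  const double* p = x.begin();
  const size_t HW = (size_t)H * Wd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      std::memcpy(A.colptr(c) + (size_t)n * HW,
                  p + HW * ((size_t)c + (size_t)C * n), HW * sizeof(double));
  return A;
}

static void check_side(int H) {
  if (H % 4 != 0 || H / 4 < 8)
    Rcpp::stop("input side %d unsupported: must be a multiple of 4 with side/4 >= 8", H);
}

// [[Rcpp::export]]
SEXP cpp_net_create(Rcpp::List spec) {
  Net* net = new Net();
  net->input_side = Rcpp::as<int>(spec["input_side"]);
  net->in_ch      = Rcpp::as<int>(spec["input_channels"]);
  net->ncls       = Rcpp::as<int>(spec["num_classes"]);
  net->expf       = Rcpp::as<int>(spec["expansion_factor"]);
  net->filters    = Rcpp::as<std::vector<int> >(spec["filters"]);
  net->reps       = Rcpp::as<std::vector<int> >(spec["repetitions"]);
  net->build();
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
Rcpp::List cpp_net_layout(SEXP ptr) {
  Net* net = get_net(ptr);
  Rcpp::IntegerVector sizes(net->prefs.size());
  Rcpp::CharacterVector kinds(net->prefs.size());
  for (size_t i = 0; i < net->prefs.size(); ++i) {
    sizes[i] = (int)net->prefs[i].n;
    kinds[i] = net->prefs[i].kind;
  }
  return Rcpp::List::create(Rcpp::Named("sizes") = sizes,
                            Rcpp::Named("kinds") = kinds);
}

// [[Rcpp::export]]
double cpp_net_nparams(SEXP ptr) {
  return (double)get_net(ptr)->n_params();
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_net_get_params(SEXP ptr) {
  Net* net = get_net(ptr);
  Rcpp::NumericVector out(net->n_params());
  double* q = out.begin();
  for (size_t i = 0; i < net->prefs.size(); ++i) {
    std::memcpy(q, net->prefs[i].w, net->prefs[i].n * sizeof(double));
    q += net->prefs[i].n;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_params(SEXP ptr, Rcpp::NumericVector flat) {
  Net* net = get_net(ptr);
  if ((size_t)flat.size() != net->n_params())
    Rcpp::stop("parameter vector length %d does not match model (%d)",
               (int)flat.size(), (int)net->n_params());
  const double* q = flat.begin();
  for (size_t i = 0; i < net->prefs.size(); ++i) {
    std::memcpy(net->prefs[i].w, q, net->prefs[i].n * sizeof(double));
    q += net->prefs[i].n;
  }
}

static std::vector<PNorm*> bn_layers(Net* net) {
  std::vector<PNorm*> bns;
  bns.push_back(&net->stem_bn);
  for (int i = 0; i < 4; ++i)
    for (int r = 0; r < net->reps[i]; ++r)
      for (int s = 0; s < 2; ++s) bns.push_back(&net->stages[i][r].u[s].bn);
  bns.push_back(&net->out_bn);
  return bns;
}

// running batch-norm statistics, concatenated (mean then var per BN layer)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_net_get_state(SEXP ptr) {
  Net* net = get_net(ptr);
  std::vector<PNorm*> bns = bn_layers(net);
  size_t total = 0;
  for (size_t i = 0; i < bns.size(); ++i) total += 2 * bns[i]->C;
  Rcpp::NumericVector out(total);
  double* q = out.begin();
  for (size_t i = 0; i < bns.size(); ++i) {
    std::memcpy(q, bns[i]->rmean.memptr(), bns[i]->C * sizeof(double)); q += bns[i]->C;
    std::memcpy(q, bns[i]->rvar.memptr(),  bns[i]->C * sizeof(double)); q += bns[i]->C;
  }
  return out;
}

// [[Rcpp::export]]
void cpp_net_set_state(SEXP ptr, Rcpp::NumericVector flat) {
  Net* net = get_net(ptr);
  std::vector<PNorm*> bns = bn_layers(net);
  size_t total = 0;
  for (size_t i = 0; i < bns.size(); ++i) total += 2 * bns[i]->C;
  if ((size_t)flat.size() != total) Rcpp::stop("state vector length mismatch");
  const double* q = flat.begin();
  for (size_t i = 0; i < bns.size(); ++i) {
    std::memcpy(bns[i]->rmean.memptr(), q, bns[i]->C * sizeof(double)); q += bns[i]->C;
    std::memcpy(bns[i]->rvar.memptr(),  q, bns[i]->C * sizeof(double)); q += bns[i]->C;
  }
}

// inference/feature forward; input (H,W,C,N), H == W a multiple of 4
// [[Rcpp::export]]
Rcpp::List cpp_net_forward(SEXP ptr, Rcpp::NumericVector x, bool training) {
  Net* net = get_net(ptr);
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[2] != net->in_ch)
    Rcpp::stop("input must be an H x W x %d x N array", net->in_ch);
  check_side(dims[0]); check_side(dims[1]);
  const int N = dims[3];
  mat X0 = array_to_batch(x, dims[0], dims[1], dims[2], N);
  net->forward(X0, N, dims[0], dims[1], training, false);
  return Rcpp::List::create(
      Rcpp::Named("probs")  = Rcpp::wrap(net->c_out.probs),
      Rcpp::Named("gap")    = Rcpp::wrap(net->c_out.gap),
      Rcpp::Named("pregap") = Rcpp::wrap(net->c_out.pregap),
      Rcpp::Named("hw")     = net->c_out.HW);
}

// one SGD-with-momentum step on a batch; returns loss and batch accuracy
// [[Rcpp::export]]
Rcpp::List cpp_net_train_batch(SEXP ptr, Rcpp::NumericVector x,
                               Rcpp::IntegerVector y0, double lr,
                               double momentum) {
  Net* net = get_net(ptr);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int N = dims[3];
  mat X0 = array_to_batch(x, dims[0], dims[1], dims[2], N);
  uvec y(N);
  for (int n = 0; n < N; ++n) y(n) = (uword)y0[n];
  net->forward(X0, N, dims[0], dims[1], true, true);
  const double loss = net->loss_from_probs(y);
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
  uword correct = 0;
  for (int n = 0; n < N; ++n)
    if (net->c_out.probs.row(n).index_max() == y(n)) ++correct;
  net->zero_grads();
  net->backward(y, true);
  net->sgd_step(lr, momentum);
  net->drop_caches();
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("acc")  = (double)correct / N);
}

// loss and flattened gradient without updating (used by the gradient checks)
// [[Rcpp::export]]
Rcpp::List cpp_net_loss_grad(SEXP ptr, Rcpp::NumericVector x,
                             Rcpp::IntegerVector y0, bool training) {
  Net* net = get_net(ptr);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int N = dims[3];
  mat X0 = array_to_batch(x, dims[0], dims[1], dims[2], N);
  uvec y(N);
  for (int n = 0; n < N; ++n) y(n) = (uword)y0[n];
  // preserve running stats so repeated evaluations are pure
  Rcpp::NumericVector state = cpp_net_get_state(ptr);
  net->forward(X0, N, dims[0], dims[1], training, true);
  const double loss = net->loss_from_probs(y);
  net->zero_grads();
  net->backward(y, training);
  cpp_net_set_state(ptr, state);
  Rcpp::NumericVector grad(net->n_params());
  double* q = grad.begin();
  for (size_t i = 0; i < net->prefs.size(); ++i) {
    std::memcpy(q, net->prefs[i].g, net->prefs[i].n * sizeof(double));
    q += net->prefs[i].n;
  }
  net->drop_caches();
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// Batch-norm calibration ("precise BN"): one training-mode forward with
// update momentum 1 pins every BN layer's running statistics to the exact
// statistics of this batch under the current weights. Called with the whole
// training split (or a large stratified subset) after training, so inference
// normalization matches the final weights instead of an exponential average
// accumulated across stale ones.
// [[Rcpp::export]]
void cpp_net_calibrate_bn(SEXP ptr, Rcpp::NumericVector x) {
  Net* net = get_net(ptr);
  Rcpp::IntegerVector dims = x.attr("dim");
  const int N = dims[3];
  mat X0 = array_to_batch(x, dims[0], dims[1], dims[2], N);
  net->bn_mom = 1.0;
  net->forward(X0, N, dims[0], dims[1], true, false);
  net->bn_mom = BN_MOMENTUM;
}

// [[Rcpp::export]]
void cpp_net_reset_velocity(SEXP ptr) {
  Net* net = get_net(ptr);
  for (size_t i = 0; i < net->prefs.size(); ++i)
    std::memset(net->prefs[i].v, 0, net->prefs[i].n * sizeof(double));
}
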