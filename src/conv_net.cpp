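// 1D convolutional encoder-decoder denoiser: forward, backprop and Adam
// training, written against Armadillo so all heavy lifting is BLAS gemm.
//
// Geometry. Encoder layer i maps (T_{i-1} x C_{i-1}) -> (T_i x C_i) with a
// "same"-padded convolution of kernel k and stride s (T_i = T_{i-1}/s).
// Decoder layers are transposed convolutions parameterized as the exact
// adjoint of the corresponding strided convolution, which guarantees the
// mirrored lengths without output trimming. Additive skip junctions sit
// after decoder layers 2, 4, 6 and 8 (before their activation), sourcing the
// post-activation encoder outputs of matching size; the final junction adds
// the raw network input and the output activation is linear.
//
// Weight layout. Conv: W is (k*Cin x Cout), column index of the input patch
// is c*k + kk (channel-major); bias b is length Cout. Transposed conv from
// (S x Cin) to (s*S x Cout): W is (k*Cout x Cin), i.e. the weight of the
// adjoint convolution, bias length Cout.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Layer {
  fmat W;
  fvec b;
  int k = 15, stride = 1, Cin = 0, Cout = 0, Tin = 0, Tout = 0;
  bool transposed = false;
};

struct Model {
  std::vector<Layer> layers; // 8 encoder then 8 decoder
  float slope = 0.2f;
  int seg_len = 1920, in_ch = 4, kernel = 15;
  // Adam state
  std::vector<fmat> mW, vW;
  std::vector<fvec> mb, vb;
  long adam_step = 0;
};

static inline int same_pad(int Tin, int Tout, int k, int stride) {
  int p = (Tout - 1) * stride + k - Tin;
  return p > 0 ? p / 2 : 0; // left pad; remainder implicitly pads right
}

// im2col for one segment: X (T x C) -> A rows [row0 .. row0+Tout) of out,
// out has k*C columns, column index c*k + kk.
static void im2col(const fmat& X, fmat& out, int row0, int k, int stride,
                   int pad, int Tout) {
  const int T = X.n_rows, C = X.n_cols;
  for (int c = 0; c < C; ++c) {
    const float* xc = X.colptr(c);
    for (int kk = 0; kk < k; ++kk) {
      float* oc = out.colptr(c * k + kk) + row0;
      for (int t = 0; t < Tout; ++t) {
        int src = t * stride + kk - pad;
        oc[t] = (src >= 0 && src < T) ? xc[src] : 0.0f;
      }
    }
  }
}

// Adjoint of im2col: scatter-add rows [row0 .. row0+Tout) of dA into dX.
static void col2im(const fmat& dA, int row0, fmat& dX, int k, int stride,
                   int pad, int Tout) {
  const int T = dX.n_rows, C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    float* xc = dX.colptr(c);
    for (int kk = 0; kk < k; ++kk) {
      const float* ac = dA.colptr(c * k + kk) + row0;
      for (int t = 0; t < Tout; ++t) {
        int dst = t * stride + kk - pad;
        if (dst >= 0 && dst < T) xc[dst] += ac[t];
      }
    }
  }
}

static inline void leaky_inplace(fmat& Z, float slope) {
  Z.for_each([slope](float& v) { if (v < 0) v *= slope; });
}

// Derivative mask from post-activation values (valid for slope > 0).
static inline fmat leaky_grad(const fmat& Y, float slope) {
  fmat g(Y.n_rows, Y.n_cols);
  for (arma::uword i = 0; i < Y.n_elem; ++i)
    g(i) = Y(i) >= 0 ? 1.0f : slope;
  return g;
}

static Model* get_model(SEXP ptr) {
  XPtr<Model> p(ptr);
  return p.get();
}

// [[Rcpp::export(name = ".nn_create")]]
SEXP nn_create(IntegerVector enc_channels, IntegerVector enc_strides,
               int kernel, int in_ch, int seg_len, double slope,
               int seed) {
  if (enc_channels.size() != enc_strides.size())
    stop("channel and stride schedules differ in length");
  Model* m = new Model();
  m->slope = (float)slope;
  m->seg_len = seg_len;
  m->in_ch = in_ch;
  m->kernel = kernel;
  const int L = enc_channels.size();
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> gauss(0.0f, 1.0f);

  int T = seg_len, C = in_ch;
  std::vector<int> encT, encC;
  for (int i = 0; i < L; ++i) {
    Layer ly;
    ly.k = kernel;
    ly.stride = enc_strides[i];
    ly.Cin = C;
    ly.Cout = enc_channels[i];
    ly.Tin = T;
    if (T % ly.stride != 0) stop("segment length not divisible by strides");
    ly.Tout = T / ly.stride;
    ly.W.set_size(kernel * ly.Cin, ly.Cout);
    float sd = std::sqrt(2.0f / (kernel * ly.Cin));
    for (arma::uword j = 0; j < ly.W.n_elem; ++j) ly.W(j) = sd * gauss(rng);
    ly.b.zeros(ly.Cout);
    m->layers.push_back(std::move(ly));
    T = m->layers.back().Tout;
    C = enc_channels[i];
    encT.push_back(T);
    encC.push_back(C);
  }
  // decoder: mirror. Output channels (C_{L-1}, C_{L-2}, ..., C_1, in_ch),
  // strides reversed (so last decoder layer has stride 1).
  for (int j = 0; j < L; ++j) {
    Layer ly;
    ly.k = kernel;
    ly.transposed = true;
    ly.stride = enc_strides[L - 1 - j];
    ly.Cin = C;
    ly.Cout = (j == L - 1) ? in_ch : encC[L - 2 - j];
    ly.Tin = T;
    ly.Tout = T * ly.stride;
    ly.W.set_size(kernel * ly.Cout, ly.Cin);
    float sd = std::sqrt(2.0f / (kernel * ly.Cin));
    for (arma::uword jj = 0; jj < ly.W.n_elem; ++jj) ly.W(jj) = sd * gauss(rng);
    ly.b.zeros(ly.Cout);
    m->layers.push_back(std::move(ly));
    T = ly.Tout;
    C = ly.Cout;
  }
  if (T != seg_len || C != in_ch) stop("decoder does not mirror the encoder");
  XPtr<Model> ptr(m, true);
  return ptr;
}

// [[Rcpp::export(name = ".nn_shapes")]]
IntegerMatrix nn_shapes(SEXP ptr) {
  Model* m = get_model(ptr);
  IntegerMatrix out(m->layers.size(), 4);
  for (size_t i = 0; i < m->layers.size(); ++i) {
    out(i, 0) = m->layers[i].Tout;
    out(i, 1) = m->layers[i].Cout;
    out(i, 2) = m->layers[i].stride;
    out(i, 3) = m->layers[i].transposed ? 1 : 0;
  }
  colnames(out) = CharacterVector::create("length", "channels", "stride",
                                          "transposed");
  return out;
}

// [[Rcpp::export(name = ".nn_num_params")]]
double nn_num_params(SEXP ptr) {
  Model* m = get_model(ptr);
  double n = 0;
  for (auto& ly : m->layers) n += ly.W.n_elem + ly.b.n_elem;
  return n;
}

// [[Rcpp::export(name = ".nn_zero_weights")]]
void nn_zero_weights(SEXP ptr) {
  Model* m = get_model(ptr);
  for (auto& ly : m->layers) { ly.W.zeros(); ly.b.zeros(); }
}

// [[Rcpp::export(name = ".nn_get_weights")]]
List nn_get_weights(SEXP ptr) {
  Model* m = get_model(ptr);
  List out(m->layers.size());
  for (size_t i = 0; i < m->layers.size(); ++i) {
    const Layer& ly = m->layers[i];
    out[i] = List::create(
      Named("W") = wrap(arma::conv_to<arma::mat>::from(ly.W)),
      Named("b") = wrap(arma::conv_to<arma::vec>::from(ly.b)),
      Named("stride") = ly.stride,
      Named("transposed") = ly.transposed);
  }
  return out;
}

// [[Rcpp::export(name = ".nn_set_weights")]]
void nn_set_weights(SEXP ptr, List weights) {
  Model* m = get_model(ptr);
  if ((size_t)weights.size() != m->layers.size())
    stop("weight list length does not match the model");
  for (size_t i = 0; i < m->layers.size(); ++i) {
    List wi = weights[i];
    arma::mat W = wi["W"];
    arma::vec b = wi["b"];
    if (W.n_rows != m->layers[i].W.n_rows || W.n_cols != m->layers[i].W.n_cols)
      stop("weight matrix %d has wrong shape", (int)i + 1);
    m->layers[i].W = arma::conv_to<fmat>::from(W);
    m->layers[i].b = arma::conv_to<fvec>::from(b);
  }
}

// Extract segment i of an (N, T, C) R array into a (T x C) fmat.
static fmat get_segment(const NumericVector& arr, int N, int T, int C, int i) {
  fmat X(T, C);
  const double* p = arr.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < T; ++t)
      X(t, c) = (float)p[i + (size_t)N * (t + (size_t)T * c)];
  return X;
}

struct ForwardState {
  // per layer, post-activation batched activations ((N*T_l) x C_l)
  std::vector<fmat> act;
  fmat input; // (N*T0) x C0
};

// Skip source for decoder layer j (0-based within decoder, j = 1, 3, 5, 7):
// encoder activation index; -1 means the raw input.
static int skip_source(int L, int j) {
  // decoder layer (L-1) takes the input; decoder layer j takes encoder
  // output L-2-j (0-based), counting only the junction layers.
  if (j == L - 1) return -1;
  return L - 2 - j;
}

static void forward_batch(Model* m, const std::vector<fmat>& segs,
                          ForwardState& st) {
  const int L = (int)m->layers.size() / 2;
  const int N = (int)segs.size();
  st.act.assign(m->layers.size(), fmat());
  st.input.set_size(N * m->seg_len, m->in_ch);
  for (int i = 0; i < N; ++i)
    st.input.rows(i * m->seg_len, (i + 1) * m->seg_len - 1) = segs[i];

  fmat cur = st.input;
  int curT = m->seg_len;
  // encoder
  for (int li = 0; li < L; ++li) {
    Layer& ly = m->layers[li];
    int pad = same_pad(ly.Tin, ly.Tout, ly.k, ly.stride);
    fmat A(N * ly.Tout, ly.k * ly.Cin);
    for (int i = 0; i < N; ++i)
      im2col(cur.rows(i * curT, (i + 1) * curT - 1), A, i * ly.Tout, ly.k,
             ly.stride, pad, ly.Tout);
    fmat Z = A * ly.W;
    Z.each_row() += ly.b.t();
    leaky_inplace(Z, m->slope);
    st.act[li] = std::move(Z);
    cur = st.act[li];
    curT = ly.Tout;
  }
  // decoder
  for (int j = 0; j < L; ++j) {
    Layer& ly = m->layers[L + j];
    int pad = same_pad(ly.Tout, ly.Tin, ly.k, ly.stride); // adjoint geometry
    fmat M = cur * ly.W.t(); // (N*S) x (k*Cout)
    fmat Z(N * ly.Tout, ly.Cout, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      fmat dXi(ly.Tout, ly.Cout, arma::fill::zeros);
      col2im(M, i * ly.Tin, dXi, ly.k, ly.stride, pad, ly.Tin);
      Z.rows(i * ly.Tout, (i + 1) * ly.Tout - 1) = dXi;
    }
    Z.each_row() += ly.b.t();
    if (j % 2 == 1) { // junction layer
      int src = skip_source(L, j);
      Z += (src < 0) ? st.input : st.act[src];
    }
    if (j < L - 1) leaky_inplace(Z, m->slope); // final activation linear
    st.act[L + j] = std::move(Z);
    cur = st.act[L + j];
    curT = ly.Tout;
  }
}

// [[Rcpp::export(name = ".nn_forward")]]
NumericVector nn_forward(SEXP ptr, NumericVector x, IntegerVector dims) {
  Model* m = get_model(ptr);
  int N = dims[0], T = dims[1], C = dims[2];
  if (T != m->seg_len || C != m->in_ch)
    stop("input shape (%d x %d) does not match the model (%d x %d)", T, C,
         m->seg_len, m->in_ch);
  std::vector<fmat> segs;
  for (int i = 0; i < N; ++i) segs.push_back(get_segment(x, N, T, C, i));
  ForwardState st;
  forward_batch(m, segs, st);
  const fmat& Y = st.act.back();
  NumericVector out(x.size());
  out.attr("dim") = dims;
  double* p = out.begin();
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < N; ++i)
        p[i + (size_t)N * (t + (size_t)T * c)] = Y(i * T + t, c);
  return out;
}

// NMSE loss over a batch given clean and prediction, both (N*T x C) stacked;
// msq(i, c) = mean_t clean^2. Returns loss; if dpred != nullptr, writes the
// gradient dL/dpred into it.
static double nmse_batch(const fmat& pred, const fmat& clean, int N, int T,
                         fmat* dpred) {
  const int C = clean.n_cols;
  double loss = 0;
  if (dpred) dpred->zeros(pred.n_rows, pred.n_cols);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < C; ++c) {
      double msq = 0, se = 0;
      for (int t = 0; t < T; ++t) {
        double cv = clean(i * T + t, c);
        double dv = pred(i * T + t, c) - cv;
        msq += cv * cv;
        se += dv * dv;
      }
      msq /= T;
      if (msq <= 0) stop("zero-power clean channel in batch (segment %d, channel %d)", i + 1, c + 1);
      loss += se / T / msq;
      if (dpred) {
        float g = (float)(2.0 / ((double)N * C * T * msq));
        for (int t = 0; t < T; ++t)
          (*dpred)(i * T + t, c) =
            g * (pred(i * T + t, c) - clean(i * T + t, c));
      }
    }
  }
  return loss / (N * (double)C);
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
};

static void backward_batch(Model* m, const ForwardState& st, const fmat& dY,
                           int N, Grads& g, fmat* dinput = nullptr) {
  const int L = (int)m->layers.size() / 2;
  g.dW.assign(m->layers.size(), fmat());
  g.db.assign(m->layers.size(), fvec());
  // gradients accumulated at each encoder activation (from skips)
  std::vector<fmat> enc_skip_grad(L);
  fmat input_grad; // from final junction

  fmat cur = dY; // gradient w.r.t. post-activation of current layer
  // decoder, reversed
  for (int j = L - 1; j >= 0; --j) {
    Layer& ly = m->layers[L + j];
    // activation
    if (j < L - 1) cur %= leaky_grad(st.act[L + j], m->slope);
    // junction: gradient flows unchanged into the skip source
    if (j % 2 == 1) {
      int src = skip_source(L, j);
      if (src < 0) input_grad = cur;
      else enc_skip_grad[src] = cur;
    }
    // transposed conv backward: forward was Z = col2im(X * W^T) + b
    int pad = same_pad(ly.Tout, ly.Tin, ly.k, ly.stride);
    fmat A(N * ly.Tin, ly.k * ly.Cout);
    for (int i = 0; i < N; ++i)
      im2col(cur.rows(i * ly.Tout, (i + 1) * ly.Tout - 1), A, i * ly.Tin,
             ly.k, ly.stride, pad, ly.Tin);
    const fmat& X = (j == 0) ? st.act[L - 1] : st.act[L + j - 1];
    g.dW[L + j] = A.t() * X;
    g.db[L + j] = arma::conv_to<fvec>::from(arma::sum(cur, 0).t());
    cur = A * ly.W; // gradient w.r.t. layer input (N*Tin x Cin)
  }
  // encoder, reversed; cur currently holds dL/d(enc activation L-1)
  for (int li = L - 1; li >= 0; --li) {
    Layer& ly = m->layers[li];
    if (enc_skip_grad[li].n_elem) cur += enc_skip_grad[li];
    cur %= leaky_grad(st.act[li], m->slope);
    int pad = same_pad(ly.Tin, ly.Tout, ly.k, ly.stride);
    const fmat& Xin = (li == 0) ? st.input : st.act[li - 1];
    fmat A(N * ly.Tout, ly.k * ly.Cin);
    for (int i = 0; i < N; ++i)
      im2col(Xin.rows(i * ly.Tin, (i + 1) * ly.Tin - 1), A, i * ly.Tout,
             ly.k, ly.stride, pad, ly.Tout);
    g.dW[li] = A.t() * cur;
    g.db[li] = arma::conv_to<fvec>::from(arma::sum(cur, 0).t());
    fmat dA = cur * ly.W.t();
    fmat dX(N * ly.Tin, ly.Cin, arma::fill::zeros);
    for (int i = 0; i < N; ++i) {
      fmat dXi(ly.Tin, ly.Cin, arma::fill::zeros);
      col2im(dA, i * ly.Tout, dXi, ly.k, ly.stride, pad, ly.Tout);
      dX.rows(i * ly.Tin, (i + 1) * ly.Tin - 1) = dXi;
    }
    cur = std::move(dX);
  }
  if (input_grad.n_elem) cur += input_grad;
  if (dinput) *dinput = cur;
}

// Evaluate mean NMSE loss over a dataset without updating weights.
static double eval_loss(Model* m, const NumericVector& noisy,
                        const NumericVector& clean, int N, int T, int C,
                        int batch) {
  double total = 0;
  int nb = 0;
  for (int start = 0; start < N; start += batch) {
    int bs = std::min(batch, N - start);
    std::vector<fmat> segs;
    fmat cl(bs * T, C);
    for (int i = 0; i < bs; ++i) {
      segs.push_back(get_segment(noisy, N, T, C, start + i));
      cl.rows(i * T, (i + 1) * T - 1) = get_segment(clean, N, T, C, start + i);
    }
    ForwardState st;
    forward_batch(m, segs, st);
    total += nmse_batch(st.act.back(), cl, bs, T, nullptr) * bs;
    nb += bs;
  }
  return total / nb;
}

// [[Rcpp::export(name = ".nn_loss")]]
double nn_loss(SEXP ptr, NumericVector noisy, NumericVector clean,
               IntegerVector dims, int batch = 16) {
  return eval_loss(get_model(ptr), noisy, clean, dims[0], dims[1], dims[2],
                   batch);
}

// [[Rcpp::export(name = ".nn_grad_norms")]]
NumericVector nn_grad_norms(SEXP ptr, NumericVector noisy, NumericVector clean,
                            IntegerVector dims) {
  Model* m = get_model(ptr);
  int N = dims[0], T = dims[1], C = dims[2];
  std::vector<fmat> segs;
  fmat cl(N * T, C);
  for (int i = 0; i < N; ++i) {
    segs.push_back(get_segment(noisy, N, T, C, i));
    cl.rows(i * T, (i + 1) * T - 1) = get_segment(clean, N, T, C, i);
  }
  ForwardState st;
  forward_batch(m, segs, st);
  fmat dY;
  nmse_batch(st.act.back(), cl, N, T, &dY);
  Grads g;
  backward_batch(m, st, dY, N, g);
  NumericVector out(m->layers.size());
  for (size_t i = 0; i < m->layers.size(); ++i)
    out[i] = std::sqrt((double)arma::accu(arma::square(g.dW[i])));
  return out;
}

// Per-layer activation dimensions observed during an actual forward pass
// of one batch: (temporal length, channels) per layer.
// [[Rcpp::export(name = ".nn_forward_dims")]]
IntegerMatrix nn_forward_dims(SEXP ptr, NumericVector x, IntegerVector dims) {
  Model* m = get_model(ptr);
  int N = dims[0], T = dims[1], C = dims[2];
  std::vector<fmat> segs;
  for (int i = 0; i < N; ++i) segs.push_back(get_segment(x, N, T, C, i));
  ForwardState st;
  forward_batch(m, segs, st);
  IntegerMatrix out(m->layers.size(), 2);
  for (size_t i = 0; i < m->layers.size(); ++i) {
    out(i, 0) = (int)(st.act[i].n_rows / N);
    out(i, 1) = (int)st.act[i].n_cols;
  }
  colnames(out) = CharacterVector::create("length", "channels");
  return out;
}

// [[Rcpp::export(name = ".nn_grads")]]
List nn_grads(SEXP ptr, NumericVector noisy, NumericVector clean,
              IntegerVector dims) {
  Model* m = get_model(ptr);
  int N = dims[0], T = dims[1], C = dims[2];
  std::vector<fmat> segs;
  fmat cl(N * T, C);
  for (int i = 0; i < N; ++i) {
    segs.push_back(get_segment(noisy, N, T, C, i));
    cl.rows(i * T, (i + 1) * T - 1) = get_segment(clean, N, T, C, i);
  }
  ForwardState st;
  forward_batch(m, segs, st);
  fmat dY;
  nmse_batch(st.act.back(), cl, N, T, &dY);
  Grads g;
  backward_batch(m, st, dY, N, g);
  List out(m->layers.size());
  for (size_t i = 0; i < m->layers.size(); ++i)
    out[i] = List::create(
      Named("dW") = wrap(arma::conv_to<arma::mat>::from(g.dW[i])),
      Named("db") = wrap(arma::conv_to<arma::vec>::from(g.db[i])));
  return out;
}

// [[Rcpp::export(name = ".nn_train")]]
NumericMatrix nn_train(SEXP ptr, NumericVector noisy, NumericVector clean,
                       IntegerVector dims, NumericVector val_noisy,
                       NumericVector val_clean, IntegerVector val_dims,
                       int batch_size, double lr, int epochs, int seed,
                       double clip_norm = 5.0, double beta1 = 0.9,
                       double beta2 = 0.999, double eps = 1e-8) {
  Model* m = get_model(ptr);
  int N = dims[0], T = dims[1], C = dims[2];
  int Nv = val_dims[0];
  if (T != m->seg_len || C != m->in_ch) stop("training data shape mismatch");

  if (m->mW.empty()) {
    for (auto& ly : m->layers) {
      m->mW.push_back(fmat(ly.W.n_rows, ly.W.n_cols, arma::fill::zeros));
      m->vW.push_back(fmat(ly.W.n_rows, ly.W.n_cols, arma::fill::zeros));
      m->mb.push_back(fvec(ly.b.n_elem, arma::fill::zeros));
      m->vb.push_back(fvec(ly.b.n_elem, arma::fill::zeros));
    }
  }
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  NumericMatrix history(epochs, 2);
  double best_val = R_PosInf;
  std::vector<fmat> best_W;
  std::vector<fvec> best_b;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0;
    int seen = 0;
    for (int start = 0; start < N; start += batch_size) {
      int bs = std::min(batch_size, N - start);
      std::vector<fmat> segs;
      fmat cl(bs * T, C);
      for (int i = 0; i < bs; ++i) {
        int idx = order[start + i];
        segs.push_back(get_segment(noisy, N, T, C, idx));
        cl.rows(i * T, (i + 1) * T - 1) = get_segment(clean, N, T, C, idx);
      }
      ForwardState st;
      forward_batch(m, segs, st);
      fmat dY;
      double loss = nmse_batch(st.act.back(), cl, bs, T, &dY);
      ep_loss += loss * bs;
      seen += bs;
      Grads g;
      backward_batch(m, st, dY, bs, g);
      // global gradient-norm clipping stabilizes the occasional huge
      // gradient from very low-SNR batches
      if (clip_norm > 0) {
        double gn2 = 0;
        for (size_t li = 0; li < m->layers.size(); ++li)
          gn2 += arma::accu(arma::square(g.dW[li])) +
                 arma::accu(arma::square(g.db[li]));
        double gn = std::sqrt(gn2);
        if (gn > clip_norm) {
          float sc = (float)(clip_norm / gn);
          for (size_t li = 0; li < m->layers.size(); ++li) {
            g.dW[li] *= sc;
            g.db[li] *= sc;
          }
        }
      }
      // Adam update
      m->adam_step += 1;
      double bc1 = 1.0 - std::pow(beta1, (double)m->adam_step);
      double bc2 = 1.0 - std::pow(beta2, (double)m->adam_step);
      for (size_t li = 0; li < m->layers.size(); ++li) {
        Layer& ly = m->layers[li];
        m->mW[li] = (float)beta1 * m->mW[li] + (float)(1 - beta1) * g.dW[li];
        m->vW[li] = (float)beta2 * m->vW[li] +
                    (float)(1 - beta2) * arma::square(g.dW[li]);
        ly.W -= (float)(lr / bc1) * m->mW[li] /
                (arma::sqrt(m->vW[li] / (float)bc2) + (float)eps);
        m->mb[li] = (float)beta1 * m->mb[li] + (float)(1 - beta1) * g.db[li];
        m->vb[li] = (float)beta2 * m->vb[li] +
                    (float)(1 - beta2) * arma::square(g.db[li]);
        ly.b -= (float)(lr / bc1) * m->mb[li] /
                (arma::sqrt(m->vb[li] / (float)bc2) + (float)eps);
      }
      Rcpp::checkUserInterrupt();
    }
    history(ep, 0) = ep_loss / seen;
    if (Nv > 0) {
      double vl = eval_loss(m, val_noisy, val_clean, Nv, T, C, batch_size);
      history(ep, 1) = vl;
      if (vl < best_val) {
        best_val = vl;
        best_W.clear();
        best_b.clear();
        for (auto& ly : m->layers) { best_W.push_back(ly.W); best_b.push_back(ly.b); }
      }
    } else {
      history(ep, 1) = NA_REAL;
    }
  }
  if (!best_W.empty()) {
    for (size_t li = 0; li < m->layers.size(); ++li) {
      m->layers[li].W = best_W[li];
      m->layers[li].b = best_b[li];
    }
  }
  colnames(history) = CharacterVector::create("train_loss", "val_loss");
  return history;
}
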