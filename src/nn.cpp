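// Fully convolutional backbone: 3x3 conv stacks around one 2x2 max-pool,
// 1x1 linear head. Forward/backward are hand-rolled (im2col + BLAS gemm) in
// single precision; weights live on the R side as double matrices shaped
// (kernel_area * C_in) x C_out.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// im2col for 3x3 kernels with zero "same" padding: (H*W) x (9*Cin).
// Column order: channel-major, then (dr, dc) row-major over the 3x3 window,
// matching the weight layout produced on the R side.
static fmat im2col3(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat out(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const fmat& xc = x.slice(c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        uword col = c * 9 + (uword)(dr + 1) * 3 + (uword)(dc + 1);
        int r0 = std::max(0, -dr), r1 = std::min((int)H, (int)H - dr);
        int c0 = std::max(0, -dc), c1 = std::min((int)W, (int)W - dc);
        for (int j = c0; j < c1; ++j) {
          float* dst = out.colptr(col) + (uword)j * H;
          const float* src = xc.colptr(j + dc);
          for (int i = r0; i < r1; ++i) dst[i] = src[i + dr];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add (H*W) x (9*Cin) gradients back to H x W x Cin.
static fcube col2im3(const fmat& g, uword H, uword W, uword C) {
  fcube out(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    fmat& oc = out.slice(c);
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        uword col = c * 9 + (uword)(dr + 1) * 3 + (uword)(dc + 1);
        int r0 = std::max(0, -dr), r1 = std::min((int)H, (int)H - dr);
        int c0 = std::max(0, -dc), c1 = std::min((int)W, (int)W - dc);
        for (int j = c0; j < c1; ++j) {
          const float* src = g.colptr(col) + (uword)j * H;
          float* dst = oc.colptr(j + dc);
          for (int i = r0; i < r1; ++i) dst[i + dr] += src[i];
        }
      }
    }
  }
  return out;
}

static fcube mat_to_cube(const fmat& y, uword H, uword W) {
  fcube out(H, W, y.n_cols);
  std::memcpy(out.memptr(), y.memptr(), y.n_elem * sizeof(float));
  return out;
}

static fmat cube_to_mat(const fcube& x) {
  fmat out(x.n_rows * x.n_cols, x.n_slices);
  std::memcpy(out.memptr(), x.memptr(), x.n_elem * sizeof(float));
  return out;
}

struct NetCache {
  int n_pre = 0, n_post = 0;
  uword H = 0, W = 0;
  std::vector<fmat> cols;    // im2col input of each conv layer (incl. head)
  std::vector<fcube> act;    // post-ReLU output of each ReLU conv layer
  Cube<uword> argmax;        // winning offset (0..3) per pooled cell/channel
};

static fcube rarray_to_fcube(const Rcpp::NumericVector& a) {
  Rcpp::IntegerVector d = a.attr("dim");
  uword H = d[0], W = d[1], C = (d.size() > 2) ? (uword)d[2] : 1;
  cube tmp(const_cast<double*>(a.begin()), H, W, C, false, true);
  return conv_to<fcube>::from(tmp);
}

static Rcpp::NumericVector fcube_to_rarray(const fcube& x) {
  cube tmp = conv_to<cube>::from(x);
  Rcpp::NumericVector out(tmp.begin(), tmp.end());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

static std::vector<fmat> weights_to_f(const Rcpp::List& Ws) {
  std::vector<fmat> out;
  for (R_xlen_t i = 0; i < Ws.size(); ++i)
    out.push_back(conv_to<fmat>::from(Rcpp::as<arma::mat>(Ws[i])));
  return out;
}

static std::vector<fvec> biases_to_f(const Rcpp::List& bs) {
  std::vector<fvec> out;
  for (R_xlen_t i = 0; i < bs.size(); ++i)
    out.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(bs[i])));
  return out;
}

// Forward pass. image: H x W x Cin double array; Ws/bs: per-layer weights,
// layers ordered pre-pool convs, post-pool convs, head. Returns the head
// output (H/2 x W/2 x Cout) and, optionally, an external-pointer cache for
// the matching backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_net_forward(Rcpp::NumericVector image, Rcpp::List Ws, Rcpp::List bs,
                           int n_pre, int n_post, bool with_cache) {
  fcube x = rarray_to_fcube(image);
  const uword H = x.n_rows, W = x.n_cols;
  if (H % 2 != 0 || W % 2 != 0)
    Rcpp::stop("input dimensions must be divisible by the pooling factor 2");
  std::vector<fmat> Wf = weights_to_f(Ws);
  std::vector<fvec> bf = biases_to_f(bs);
  NetCache* cache = with_cache ? new NetCache() : nullptr;
  if (cache) { cache->n_pre = n_pre; cache->n_post = n_post; cache->H = H; cache->W = W; }

  fcube h = x;
  int li = 0;
  for (int l = 0; l < n_pre; ++l, ++li) {
    fmat cols = im2col3(h);
    fmat y = cols * Wf[li];
    y.each_row() += bf[li].t();
    y = clamp(y, 0.0f, fdatum::inf);
    h = mat_to_cube(y, H, W);
    if (cache) { cache->cols.push_back(std::move(cols)); cache->act.push_back(h); }
  }
  // 2x2 max-pool, stride 2
  const uword H2 = H / 2, W2 = W / 2, C = h.n_slices;
  fcube p(H2, W2, C);
  Cube<uword> amax(H2, W2, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W2; ++j) {
      for (uword i = 0; i < H2; ++i) {
        float v00 = h(2 * i, 2 * j, c), v10 = h(2 * i + 1, 2 * j, c);
        float v01 = h(2 * i, 2 * j + 1, c), v11 = h(2 * i + 1, 2 * j + 1, c);
        float m = v00; uword a = 0;
        if (v10 > m) { m = v10; a = 1; }
        if (v01 > m) { m = v01; a = 2; }
        if (v11 > m) { m = v11; a = 3; }
        p(i, j, c) = m; amax(i, j, c) = a;
      }
    }
  }
  if (cache) cache->argmax = std::move(amax);
  h = p;
  for (int l = 0; l < n_post; ++l, ++li) {
    fmat cols = im2col3(h);
    fmat y = cols * Wf[li];
    y.each_row() += bf[li].t();
    y = clamp(y, 0.0f, fdatum::inf);
    h = mat_to_cube(y, H2, W2);
    if (cache) { cache->cols.push_back(std::move(cols)); cache->act.push_back(h); }
  }
  // 1x1 linear head
  fmat cols = cube_to_mat(h);
  fmat y = cols * Wf[li];
  y.each_row() += bf[li].t();
  fcube out = mat_to_cube(y, H2, W2);
  if (cache) cache->cols.push_back(std::move(cols));

  Rcpp::List res = Rcpp::List::create(Rcpp::Named("out") = fcube_to_rarray(out));
  if (cache) {
    Rcpp::XPtr<NetCache> ptr(cache, true);
    res["cache"] = ptr;
  }
  return res;
}

// Backward pass: gradient of a scalar loss w.r.t. all weights and biases,
// given the gradient w.r.t. the head output. Consumes a cache produced by
// cpp_net_forward(with_cache = TRUE).
// [[Rcpp::export]]
Rcpp::List cpp_net_backward(SEXP cache_ptr, Rcpp::NumericVector dout, Rcpp::List Ws) {
  Rcpp::XPtr<NetCache> cache(cache_ptr);
  std::vector<fmat> Wf = weights_to_f(Ws);
  const int n_pre = cache->n_pre, n_post = cache->n_post;
  const int L = n_pre + n_post + 1;
  const uword H = cache->H, W = cache->W, H2 = H / 2, W2 = W / 2;

  std::vector<fmat> dW(L);
  std::vector<fvec> db(L);

  fcube dc = rarray_to_fcube(dout);
  fmat dY = cube_to_mat(dc);           // (H2*W2) x Cout
  // head
  int li = L - 1;
  dW[li] = cache->cols[li].t() * dY;
  db[li] = sum(dY, 0).t();
  fmat dX = dY * Wf[li].t();           // (H2*W2) x C
  // post-pool convs (reverse)
  for (int l = n_post - 1; l >= 0; --l) {
    li = n_pre + l;
    fmat mask = cube_to_mat(cache->act[li]);
    dX.elem(find(mask <= 0)).zeros();  // ReLU
    dW[li] = cache->cols[li].t() * dX;
    db[li] = sum(dX, 0).t();
    fmat g = dX * Wf[li].t();
    fcube dxi = col2im3(g, H2, W2, Wf[li].n_rows / 9);
    dX = cube_to_mat(dxi);
  }
  // unpool
  const uword C = dX.n_cols;
  fcube dfull(H, W, C, fill::zeros);
  {
    fcube dhalf = mat_to_cube(dX, H2, W2);
    for (uword c = 0; c < C; ++c)
      for (uword j = 0; j < W2; ++j)
        for (uword i = 0; i < H2; ++i) {
          uword a = cache->argmax(i, j, c);
          dfull(2 * i + (a & 1u), 2 * j + (a >> 1u), c) += dhalf(i, j, c);
        }
  }
  dX = cube_to_mat(dfull);
  // pre-pool convs (reverse)
  for (int l = n_pre - 1; l >= 0; --l) {
    fmat mask = cube_to_mat(cache->act[l]);
    dX.elem(find(mask <= 0)).zeros();
    dW[l] = cache->cols[l].t() * dX;
    db[l] = sum(dX, 0).t();
    if (l > 0) {
      fmat g = dX * Wf[l].t();
      fcube dxi = col2im3(g, H, W, Wf[l].n_rows / 9);
      dX = cube_to_mat(dxi);
    }
  }

  // release the bulk of the cache now; the XPtr finalizer only runs at GC
  std::vector<fmat>().swap(cache->cols);
  std::vector<fcube>().swap(cache->act);

  Rcpp::List rdW(L), rdb(L);
  for (int l = 0; l < L; ++l) {
    rdW[l] = Rcpp::wrap(conv_to<arma::mat>::from(dW[l]));
    rdb[l] = Rcpp::wrap(conv_to<arma::vec>::from(db[l]));
  }
  return Rcpp::List::create(Rcpp::Named("dW") = rdW, Rcpp::Named("db") = rdb);
}
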