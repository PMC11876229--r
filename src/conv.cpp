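// Minimal conv2d kernels for the compact CNN engine.
// Layout conventions (must match the R side):
//   - activations: arma::cube H x W x C
//   - weights: matrix (k*k*Cin) x Cout, row index = ki + kj*k + c*k*k,
//     i.e. the column-major flattening of an R array dim (k, k, Cin, Cout)
//   - im2col rows indexed ho + wo*Ho (column-major over output pixels)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube &x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  mat cols(Ho * Wo, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            cols(ho + wo * Ho, col) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube &x, const arma::mat &w,
                       const arma::vec &b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, stride, pad);
  mat out = cols * w;
  out.each_row() += b.t();
  cube z(Ho, Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    z.slice(o) = reshape(out.col(o), Ho, Wo);
  return z;
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube &x, const arma::mat &w,
                       const arma::cube &gout, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  mat gout_mat(Ho * Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    gout_mat.col(o) = vectorise(gout.slice(o));
  mat cols = im2col(x, k, stride, pad);
  mat gw = cols.t() * gout_mat;
  vec gb = sum(gout_mat, 0).t();
  // col2im scatter-add
  mat gcols = gout_mat * w.t();
  cube gx(H, W, x.n_slices, fill::zeros);
  const int C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + kj * k + c * k * k;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            gx(hi, wi, c) += gcols(ho + wo * Ho, col);
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}


static cube conv_grad_mask(const cube &z) {
  cube m(z.n_rows, z.n_cols, z.n_slices);
  for (unsigned i = 0; i < z.n_elem; ++i) m(i) = z(i) > 0 ? 1.0 : 0.0;
  return m;
}

// Whole-encoder forward/backward (stack of k x k stride-s conv + ReLU
// blocks with global average pooling) in one call, to keep the per-layer
// marshalling cost out of the training loop.

static cube conv_fwd_core(const cube &x, const mat &w, const vec &b,
                          int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  mat cols = im2col(x, k, stride, pad);
  mat out = cols * w;
  out.each_row() += b.t();
  cube z(Ho, Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    z.slice(o) = reshape(out.col(o), Ho, Wo);
  return z;
}

// [[Rcpp::export]]
Rcpp::List enc_fwd(const arma::cube &x, Rcpp::List Ws, Rcpp::List bs,
                   int k, int stride, int pad, bool keep) {
  const int L = Ws.size();
  Rcpp::List preacts(L);
  cube a = x;
  for (int i = 0; i < L; ++i) {
    mat w = Rcpp::as<mat>(Ws[i]);
    vec b = Rcpp::as<vec>(bs[i]);
    cube z = conv_fwd_core(a, w, b, k, stride, pad);
    if (keep) preacts[i] = z;
    a = clamp(z, 0.0, datum::inf);
  }
  vec features(a.n_slices);
  for (unsigned o = 0; o < a.n_slices; ++o)
    features(o) = accu(a.slice(o)) / (a.n_rows * a.n_cols);
  return Rcpp::List::create(Rcpp::Named("features") = features,
                            Rcpp::Named("preacts") = preacts,
                            Rcpp::Named("last") = a);
}

// [[Rcpp::export]]
Rcpp::List enc_bwd(const arma::cube &x0, Rcpp::List preacts, Rcpp::List Ws,
                   const arma::vec &gfeat, int k, int stride, int pad,
                   bool keep_act_grads) {
  const int L = Ws.size();
  cube lastz = Rcpp::as<cube>(preacts[L - 1]);
  const double hw = lastz.n_rows * lastz.n_cols;
  cube g(lastz.n_rows, lastz.n_cols, lastz.n_slices);
  for (unsigned o = 0; o < g.n_slices; ++o)
    g.slice(o).fill(gfeat(o) / hw);
  Rcpp::List gWs(L), gbs(L), act_grads(L);
  for (int i = L - 1; i >= 0; --i) {
    if (keep_act_grads) act_grads[i] = g;
    cube z = Rcpp::as<cube>(preacts[i]);
    g %= conv_grad_mask(z);
    cube input = (i == 0) ? x0 : clamp(Rcpp::as<cube>(preacts[i - 1]),
                                       0.0, datum::inf);
    mat gout_mat(g.n_rows * g.n_cols, g.n_slices);
    for (unsigned o = 0; o < g.n_slices; ++o)
      gout_mat.col(o) = vectorise(g.slice(o));
    mat cols = im2col(input, k, stride, pad);
    gWs[i] = cols.t() * gout_mat;
    gbs[i] = vec(sum(gout_mat, 0).t());
    if (i > 0) {  // gradient below the first block is never consumed
      mat w = Rcpp::as<mat>(Ws[i]);
      mat gcols = gout_mat * w.t();
      const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
      const int Ho = g.n_rows, Wo = g.n_cols;
      cube gx(H, W, C, fill::zeros);
      for (int c = 0; c < C; ++c)
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            const int col = ki + kj * k + c * k * k;
            for (int wo = 0; wo < Wo; ++wo) {
              const int wi = wo * stride - pad + kj;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + ki;
                if (hi < 0 || hi >= H) continue;
                gx(hi, wi, c) += gcols(ho + wo * Ho, col);
              }
            }
          }
      g = gx;
    }
  }
  return Rcpp::List::create(Rcpp::Named("gWs") = gWs,
                            Rcpp::Named("gbs") = gbs,
                            Rcpp::Named("act_grads") = act_grads);
}
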