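// Compact U-Net backbone: forward, loss and analytic gradients.
//
// The network is a symmetric encoder/decoder with one 3x3 convolution + ReLU
// per stage, 2x2 max-pooling between encoder stages, nearest-neighbour
// upsampling with skip concatenation in the decoder, and a final 1x1
// convolution to per-class scores.  All parameters live in one flat vector so
// that federated aggregation and serialization are trivial; the layout is
// fixed by the descriptor (see layout comments below and unet_n_params()).
//
// Descriptor: integer vector (H, W, base_channels, depth, n_classes).
// Input images are single-channel H x W in [0,1]; H and W must be divisible
// by 2^(depth-1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Desc {
  int H, W, base, depth, K;
};

Desc read_desc(const Rcpp::IntegerVector& d) {
  if (d.size() != 5) Rcpp::stop("descriptor must have 5 entries");
  Desc ds{d[0], d[1], d[2], d[3], d[4]};
  if (ds.depth < 1 || ds.base < 1 || ds.K < 2)
    Rcpp::stop("invalid descriptor");
  int f = 1 << (ds.depth - 1);
  if (ds.H % f != 0 || ds.W % f != 0)
    Rcpp::stop("image size must be divisible by 2^(depth-1)");
  return ds;
}

int chan(const Desc& d, int level) {  // level 1..depth
  return d.base << (level - 1);
}

// Parameter layout, in order:
//   encoder l = 1..depth:      W (Cout x 9*Cin), b (Cout)
//   decoder l = depth-1..1:    W (Cout x 9*Cin), b (Cout), Cin = ch[l+1]+ch[l]
//   output 1x1:                U (K x ch[1]), u (K)
struct Layer { int w_off, b_off, cin, cout; };

std::vector<Layer> layout(const Desc& d, int& total) {
  std::vector<Layer> L;
  int off = 0;
  auto push = [&](int cin, int cout, int k2) {
    Layer l{off, off + cout * k2 * cin, cin, cout};
    off = l.b_off + cout;
    L.push_back(l);
  };
  for (int l = 1; l <= d.depth; ++l)
    push(l == 1 ? 1 : chan(d, l - 1), chan(d, l), 9);
  for (int l = d.depth - 1; l >= 1; --l)
    push(chan(d, l + 1) + chan(d, l), chan(d, l), 9);
  push(chan(d, 1), d.K, 1);
  total = off;
  return L;
}

// im2col for a 3x3 kernel with zero padding: (9*C) x (H*W).
mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat out(9 * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        mat Z(H, W, fill::zeros);
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        Z.submat(r0, c0, r1 - 1, c1 - 1) =
            S.submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
        out.row(c * 9 + k) = vectorise(Z).t();
        ++k;
      }
    }
  }
  return out;
}

// adjoint of im2col3
cube col2im3(const mat& cols, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        // reshape row into H x W and scatter-add with the offset
        mat R = reshape(cols.row(c * 9 + k), H, W);
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        out.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx) +=
            R.submat(r0, c0, r1 - 1, c1 - 1);
        ++k;
      }
    }
  }
  return out;
}

cube mat_to_cube(const mat& Y, int H, int W) {  // rows = channels
  cube out(H, W, Y.n_rows);
  for (uword c = 0; c < Y.n_rows; ++c)
    out.slice(c) = reshape(Y.row(c), H, W);
  return out;
}

mat cube_to_mat(const cube& X) {  // channels -> rows
  mat out(X.n_slices, X.n_rows * X.n_cols);
  for (uword c = 0; c < X.n_slices; ++c)
    out.row(c) = vectorise(X.slice(c)).t();
  return out;
}

cube maxpool2(const cube& X, ucube& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = X(2 * i, 2 * j, c);
        uword bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = X(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bi = 2 * i + di; bj = 2 * j + dj; }
          }
        out(i, j, c) = best;
        idx(i, j, c) = bi + bj * X.n_rows;
      }
  return out;
}

cube maxpool2_back(const cube& dY, const ucube& idx, int H, int W) {
  cube out(H, W, dY.n_slices, fill::zeros);
  for (uword c = 0; c < dY.n_slices; ++c)
    for (uword j = 0; j < dY.n_cols; ++j)
      for (uword i = 0; i < dY.n_rows; ++i) {
        uword lin = idx(i, j, c);
        out(lin % H, lin / H, c) += dY(i, j, c);
      }
  return out;
}

cube upsample2(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

cube upsample2_back(const cube& dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        out(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                       dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return out;
}

struct Caches {
  std::vector<mat> cols;       // im2col input of every conv, in layer order
  std::vector<cube> relu_out;  // post-ReLU output of every 3x3 conv
  std::vector<ucube> pool_idx;
  std::vector<std::pair<int,int>> pool_hw;  // input H,W of each pool
  cube dec_in_last;            // input to the 1x1 conv (H,W,ch1)
  cube probs;                  // softmax probabilities (H,W,K)
};

// Full forward pass; fills caches when train = true.
cube forward(const vec& par, const Desc& d, const std::vector<Layer>& L,
             const mat& x, Caches* cache) {
  cube cur(d.H, d.W, 1);
  cur.slice(0) = x;
  std::vector<cube> enc(d.depth);
  int li = 0;
  // encoder
  for (int l = 1; l <= d.depth; ++l, ++li) {
    const Layer& ly = L[li];
    mat Wm(const_cast<double*>(par.memptr()) + ly.w_off, ly.cout, 9 * ly.cin, false);
    vec b(const_cast<double*>(par.memptr()) + ly.b_off, ly.cout, false);
    mat cols = im2col3(cur);
    mat Y = Wm * cols;
    Y.each_col() += b;
    cube a = mat_to_cube(Y, cur.n_rows, cur.n_cols);
    a.transform([](double v) { return v > 0 ? v : 0.1 * v; });  // leaky ReLU
    enc[l - 1] = a;
    if (cache) { cache->cols.push_back(std::move(cols)); cache->relu_out.push_back(a); }
    if (l < d.depth) {
      ucube idx;
      if (cache) cache->pool_hw.push_back({(int)a.n_rows, (int)a.n_cols});
      cur = maxpool2(a, idx);
      if (cache) cache->pool_idx.push_back(std::move(idx));
    } else {
      cur = a;
    }
  }
  // decoder
  for (int l = d.depth - 1; l >= 1; --l, ++li) {
    const Layer& ly = L[li];
    mat Wm(const_cast<double*>(par.memptr()) + ly.w_off, ly.cout, 9 * ly.cin, false);
    vec b(const_cast<double*>(par.memptr()) + ly.b_off, ly.cout, false);
    cube up = upsample2(cur);
    cube cat = join_slices(up, enc[l - 1]);
    mat cols = im2col3(cat);
    mat Y = Wm * cols;
    Y.each_col() += b;
    cube a = mat_to_cube(Y, cat.n_rows, cat.n_cols);
    a.transform([](double v) { return v > 0 ? v : 0.1 * v; });  // leaky ReLU
    if (cache) { cache->cols.push_back(std::move(cols)); cache->relu_out.push_back(a); }
    cur = a;
  }
  // output 1x1
  const Layer& lo = L[li];
  mat Wm(const_cast<double*>(par.memptr()) + lo.w_off, lo.cout, lo.cin, false);
  vec b(const_cast<double*>(par.memptr()) + lo.b_off, lo.cout, false);
  if (cache) cache->dec_in_last = cur;
  mat Y = Wm * cube_to_mat(cur);
  Y.each_col() += b;
  return mat_to_cube(Y, d.H, d.W);
}

cube softmax_probs(const cube& logits) {
  const int H = logits.n_rows, W = logits.n_cols, K = logits.n_slices;
  cube p = logits;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double mx = p(i, j, 0);
      for (int k = 1; k < K; ++k) mx = std::max(mx, p(i, j, k));
      double s = 0;
      for (int k = 0; k < K; ++k) { double e = std::exp(p(i, j, k) - mx); p(i, j, k) = e; s += e; }
      for (int k = 0; k < K; ++k) p(i, j, k) /= s;
    }
  return p;
}

// macro soft IoU over foreground classes with positive soft union;
// optionally fills dS/dp.
double soft_iou_probs(const cube& p, const imat& y, cube* dS) {
  const int H = p.n_rows, W = p.n_cols, K = p.n_slices;
  if (dS) dS->zeros(H, W, K);
  double acc = 0;
  int m = 0;
  std::vector<std::pair<double,double>> iu(K);
  for (int k = 1; k < K; ++k) {
    double I = 0, U = 0;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double pk = p(i, j, k);
        double yk = (y(i, j) == k) ? 1.0 : 0.0;
        I += pk * yk;
        U += pk + yk - pk * yk;
      }
    iu[k] = {I, U};
    if (U > 0) { acc += I / U; ++m; }
  }
  if (m == 0) return 1.0;  // no foreground anywhere
  if (dS) {
    for (int k = 1; k < K; ++k) {
      double I = iu[k].first, U = iu[k].second;
      if (U <= 0) continue;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double yk = (y(i, j) == k) ? 1.0 : 0.0;
          (*dS)(i, j, k) = (yk * U - I * (1.0 - yk)) / (U * U) / m;
        }
    }
  }
  return acc / m;
}

void backward(const vec& par, const Desc& d, const std::vector<Layer>& L,
              const Caches& cache, const cube& dlogits, vec& grad) {
  int li = (int)L.size() - 1;
  // output 1x1 conv
  {
    const Layer& lo = L[li];
    mat Wm(const_cast<double*>(par.memptr()) + lo.w_off, lo.cout, lo.cin, false);
    mat dY = cube_to_mat(dlogits);
    mat Xm = cube_to_mat(cache.dec_in_last);
    mat dW = dY * Xm.t();
    vec db = sum(dY, 1);
    grad.subvec(lo.w_off, lo.b_off - 1) = vectorise(dW);
    grad.subvec(lo.b_off, lo.b_off + lo.cout - 1) = db;
    mat dXm = Wm.t() * dY;
    // carry into decoder as cube
    cube dcur = mat_to_cube(dXm, dlogits.n_rows, dlogits.n_cols);
    --li;
    // decoder stages l = 1 .. depth-1 in reverse of forward (forward went
    // depth-1 down to 1; caches are in forward order: conv index depth..2*depth-2)
    std::vector<cube> denc(d.depth);  // gradient wrt enc relu outputs
    for (int l = 1; l <= d.depth - 1; ++l, --li) {
      const Layer& ly = L[li];
      const cube& a = cache.relu_out[li];
      // relu gate
      for (uword s = 0; s < dcur.n_slices; ++s)
        dcur.slice(s) %= conv_to<mat>::from(a.slice(s) > 0) * 0.9 + 0.1;
      mat dY2 = cube_to_mat(dcur);
      mat dW2 = dY2 * cache.cols[li].t();
      vec db2 = sum(dY2, 1);
      grad.subvec(ly.w_off, ly.b_off - 1) = vectorise(dW2);
      grad.subvec(ly.b_off, ly.b_off + ly.cout - 1) = db2;
      mat dcols = mat(const_cast<double*>(par.memptr()) + ly.w_off, ly.cout,
                      9 * ly.cin, false).t() * dY2;
      cube dcat = col2im3(dcols, dcur.n_rows, dcur.n_cols, ly.cin);
      int c_up = ly.cin - chan(d, l);  // channels that came from below
      cube dup = dcat.slices(0, c_up - 1);
      denc[l - 1] = dcat.slices(c_up, ly.cin - 1);
      dcur = upsample2_back(dup);
    }
    // encoder stages depth..1 in reverse
    for (int l = d.depth; l >= 1; --l, --li) {
      const Layer& ly = L[li];
      const cube& a = cache.relu_out[li];
      cube dth;
      if (l == d.depth) {
        dth = dcur;
      } else {
        // gradient through the pooling path plus the skip connection
        dth = maxpool2_back(dcur, cache.pool_idx[l - 1],
                            cache.pool_hw[l - 1].first, cache.pool_hw[l - 1].second);
        dth += denc[l - 1];
      }
      for (uword s = 0; s < dth.n_slices; ++s)
        dth.slice(s) %= conv_to<mat>::from(a.slice(s) > 0) * 0.9 + 0.1;
      mat dY2 = cube_to_mat(dth);
      mat dW2 = dY2 * cache.cols[li].t();
      vec db2 = sum(dY2, 1);
      grad.subvec(ly.w_off, ly.b_off - 1) = vectorise(dW2);
      grad.subvec(ly.b_off, ly.b_off + ly.cout - 1) = db2;
      if (l > 1) {
        mat dcols = mat(const_cast<double*>(par.memptr()) + ly.w_off, ly.cout,
                        9 * ly.cin, false).t() * dY2;
        dcur = col2im3(dcols, dth.n_rows, dth.n_cols, ly.cin);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
int cpp_unet_n_params(Rcpp::IntegerVector descriptor) {
  Desc d = read_desc(descriptor);
  int total = 0;
  layout(d, total);
  return total;
}

// [[Rcpp::export]]
arma::cube cpp_unet_forward(const arma::vec& par, Rcpp::IntegerVector descriptor,
                            const arma::mat& x) {
  Desc d = read_desc(descriptor);
  int total = 0;
  std::vector<Layer> L = layout(d, total);
  if ((int)par.n_elem != total) Rcpp::stop("parameter vector has wrong length");
  if ((int)x.n_rows != d.H || (int)x.n_cols != d.W) Rcpp::stop("image shape mismatch");
  return forward(par, d, L, x, nullptr);
}

// Loss + gradient for one sample.
//   coef:     multiplier on the cross-entropy term (loss reweighting)
//   variant:  0 = none, 1 = selective, 2 = tiered (additive soft-IoU penalty)
//   w:        progressive weight; ref_mean: detached epoch-mean IoU reference
// Returns ce, soft_iou (always computed), and d(coef*CE + penalty)/d par.
// [[Rcpp::export]]
Rcpp::List cpp_unet_loss_grad(const arma::vec& par, Rcpp::IntegerVector descriptor,
                              const arma::mat& x, const arma::imat& y,
                              double coef, int variant, double w, double ref_mean) {
  Desc d = read_desc(descriptor);
  int total = 0;
  std::vector<Layer> L = layout(d, total);
  if ((int)par.n_elem != total) Rcpp::stop("parameter vector has wrong length");
  if ((int)y.n_rows != d.H || (int)y.n_cols != d.W) Rcpp::stop("mask shape mismatch");
  Caches cache;
  cube logits = forward(par, d, L, x, &cache);
  cube p = softmax_probs(logits);

  const int H = d.H, W = d.W, K = d.K;
  const double npx = (double)H * W;
  double ce = 0;
  cube dlogits(H, W, K);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int t = y(i, j);
      if (t < 0 || t >= K) Rcpp::stop("mask label out of range");
      ce -= std::log(std::max(p(i, j, t), 1e-12));
      for (int k = 0; k < K; ++k)
        dlogits(i, j, k) = coef * (p(i, j, k) - (k == t ? 1.0 : 0.0)) / npx;
    }
  ce /= npx;

  cube dS;
  double s = soft_iou_probs(p, y, variant != 0 ? &dS : nullptr);
  if (variant != 0) {
    double delta = s - ref_mean;
    double pen_c = 0;  // d(penalty)/d(soft IoU)
    if (variant == 1 && delta > 0) pen_c = w;               // w * max(dP, 0)
    if (variant == 2 && w * delta > 0) pen_c = w;           // max(w * dP, 0)
    if (pen_c != 0) {
      // chain dS/dp through softmax onto logits
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double dot = 0;
          for (int k = 0; k < K; ++k) dot += dS(i, j, k) * p(i, j, k);
          for (int k = 0; k < K; ++k)
            dlogits(i, j, k) += pen_c * p(i, j, k) * (dS(i, j, k) - dot);
        }
    }
  }

  vec grad(total, fill::zeros);
  backward(par, d, L, cache, dlogits, grad);
  return Rcpp::List::create(Rcpp::Named("ce") = ce,
                            Rcpp::Named("soft_iou") = s,
                            Rcpp::Named("grad") = grad);
}

// Hard multi-class IoU of argmax(forward(x)) against y, without gradients.
// [[Rcpp::export]]
Rcpp::List cpp_unet_predict(const arma::vec& par, Rcpp::IntegerVector descriptor,
                            const arma::mat& x) {
  Desc d = read_desc(descriptor);
  int total = 0;
  std::vector<Layer> L = layout(d, total);
  if ((int)par.n_elem != total) Rcpp::stop("parameter vector has wrong length");
  cube logits = forward(par, d, L, x, nullptr);
  imat lab(d.H, d.W);
  for (int j = 0; j < d.W; ++j)
    for (int i = 0; i < d.H; ++i) {
      int best = 0;
      double bv = logits(i, j, 0);
      for (int k = 1; k < d.K; ++k)
        if (logits(i, j, k) > bv) { bv = logits(i, j, k); best = k; }
      lab(i, j) = best;
    }
  return Rcpp::List::create(Rcpp::Named("labels") = lab);
}
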