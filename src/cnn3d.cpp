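// Compact 3D convolutional network engine.
//
// Feature maps are stored as (n_voxels x n_channels) matrices, voxel index
// v = x + X*(y + Y*z) (column-major volume). Convolutions are 3x3x3,
// same-padded, realised as vol2col followed by a dense matrix product so the
// heavy lifting stays inside BLAS. Max-pooling is 2x2x2 with edge-clipped
// windows. The dense head flattens the last block channel-major
// (arma::vectorise). Training is Adam on mean binary cross-entropy plus an
// L2 penalty on all weight matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvLayer {
  int cin, cout;
  mat W;     // (27*cin) x cout
  rowvec b;  // 1 x cout
  mat mW, vW; rowvec mb, vb;  // Adam state (lazy)
};

struct DenseLayer {
  int nin, nout;
  mat W;   // nin x nout
  vec b;   // nout
  mat mW, vW; vec mb, vb;
};

struct Net {
  int X, Y, Z;
  std::vector<std::vector<ConvLayer> > blocks;
  int n_pool;  // pooling after the first n_pool blocks
  std::vector<DenseLayer> dense;
  double l2;
  long adam_t;
  bool adam_ready;
};

struct Dims { int X, Y, Z; };

inline int pool_out(int n) { return (n + 1) / 2; }

// im2col for a 3x3x3 neighbourhood, zero padding. out: nvox x (27*cin),
// column o*cin + c holds channel c shifted by offset o.
void vol2col(const mat& in, int X, int Y, int Z, mat& out) {
  const int cin = in.n_cols;
  out.zeros(in.n_rows, 27 * cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        // valid x-run: x in [x0, x1] with x+dx in [0, X-1]
        const int x0 = std::max(0, -dx), x1 = std::min(X - 1, X - 1 - dx);
        const int len = x1 - x0 + 1;
        if (len <= 0) continue;
        for (int c = 0; c < cin; ++c) {
          const double* src = in.colptr(c);
          double* dst = out.colptr(o * cin + c);
          for (int z = 0; z < Z; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= Y) continue;
              const int di = x0 + X * (y + Y * z);
              const int si = x0 + dx + X * (ys + Y * zs);
              std::memcpy(dst + di, src + si, len * sizeof(double));
            }
          }
        }
      }
    }
  }
}

// Transpose of vol2col: scatter-add column gradients back onto the volume.
void col2vol(const mat& dcol, int X, int Y, int Z, int cin, mat& din) {
  din.zeros(dcol.n_rows, cin);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        const int x0 = std::max(0, -dx), x1 = std::min(X - 1, X - 1 - dx);
        if (x1 < x0) continue;
        for (int c = 0; c < cin; ++c) {
          const double* src = dcol.colptr(o * cin + c);
          double* dst = din.colptr(c);
          for (int z = 0; z < Z; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= Y) continue;
              for (int x = x0; x <= x1; ++x) {
                dst[x + dx + X * (ys + Y * zs)] += src[x + X * (y + Y * z)];
              }
            }
          }
        }
      }
    }
  }
}

void maxpool(const mat& in, Dims d, mat& out, umat& amax) {
  const int C = in.n_cols;
  const int Xo = pool_out(d.X), Yo = pool_out(d.Y), Zo = pool_out(d.Z);
  out.set_size((uword)Xo * Yo * Zo, C);
  amax.set_size(out.n_rows, C);
  for (int c = 0; c < C; ++c) {
    const double* src = in.colptr(c);
    for (int z = 0; z < Zo; ++z) {
      for (int y = 0; y < Yo; ++y) {
        for (int x = 0; x < Xo; ++x) {
          double best = -datum::inf; uword bi = 0;
          for (int kz = 2 * z; kz < std::min(2 * z + 2, d.Z); ++kz)
            for (int ky = 2 * y; ky < std::min(2 * y + 2, d.Y); ++ky)
              for (int kx = 2 * x; kx < std::min(2 * x + 2, d.X); ++kx) {
                const uword i = kx + d.X * (ky + (uword)d.Y * kz);
                if (src[i] > best) { best = src[i]; bi = i; }
              }
          const uword oi = x + Xo * (y + (uword)Yo * z);
          out(oi, c) = best;
          amax(oi, c) = bi;
        }
      }
    }
  }
}

struct Cache {
  // per conv layer (flattened over blocks): col matrix and post-relu output
  std::vector<mat> cols, acts;
  // per pool layer: argmax and input dims
  std::vector<umat> amax;
  std::vector<Dims> pre_pool;
  // dense activations: a[0] = flatten input, a[i] = post-activation of layer i
  std::vector<vec> da;
};

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Forward pass for one image. Fills cache when train = true.
// Returns final sigmoid score; penult receives the post-relu activation of
// the second-to-last dense layer.
double forward_one(Net& net, const vec& img, bool train, Cache* cache,
                   vec* penult) {
  mat cur(img);  // nvox x 1
  Dims d = {net.X, net.Y, net.Z};
  for (size_t b = 0; b < net.blocks.size(); ++b) {
    for (size_t l = 0; l < net.blocks[b].size(); ++l) {
      ConvLayer& cl = net.blocks[b][l];
      mat col;
      vol2col(cur, d.X, d.Y, d.Z, col);
      mat z = col * cl.W;
      z.each_row() += cl.b;
      z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      if (train) { cache->cols.push_back(std::move(col)); cache->acts.push_back(z); }
      cur = std::move(z);
    }
    if ((int)b < net.n_pool) {
      mat pooled; umat am;
      maxpool(cur, d, pooled, am);
      if (train) { cache->amax.push_back(std::move(am)); cache->pre_pool.push_back(d); }
      d.X = pool_out(d.X); d.Y = pool_out(d.Y); d.Z = pool_out(d.Z);
      cur = std::move(pooled);
    }
  }
  vec a = vectorise(cur);
  if (train) cache->da.push_back(a);
  const size_t nd = net.dense.size();
  for (size_t i = 0; i < nd; ++i) {
    DenseLayer& dl = net.dense[i];
    vec z = dl.W.t() * a + dl.b;
    if (i + 1 < nd) {
      z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      if (i + 2 == nd && penult) *penult = z;
    }
    a = z;
    if (train) cache->da.push_back(a);
  }
  return sigmoid(a(0));
}

struct Grads {
  std::vector<mat> cW; std::vector<rowvec> cb;
  std::vector<mat> dW; std::vector<vec> db;
};

void init_grads(Net& net, Grads& g) {
  for (auto& blk : net.blocks)
    for (auto& cl : blk) {
      g.cW.push_back(zeros<mat>(cl.W.n_rows, cl.W.n_cols));
      g.cb.push_back(zeros<rowvec>(cl.b.n_elem));
    }
  for (auto& dl : net.dense) {
    g.dW.push_back(zeros<mat>(dl.W.n_rows, dl.W.n_cols));
    g.db.push_back(zeros<vec>(dl.b.n_elem));
  }
}

// Backprop one image; dscore = dL/dz at the output logit (= p - y for BCE).
void backward_one(Net& net, Cache& cache, double dscore, Grads& g) {
  const size_t nd = net.dense.size();
  vec dz(1); dz(0) = dscore;
  for (int i = (int)nd - 1; i >= 0; --i) {
    DenseLayer& dl = net.dense[i];
    const vec& a_prev = cache.da[i];
    g.dW[i] += a_prev * dz.t();
    g.db[i] += dz;
    if (i > 0) {
      vec da = dl.W * dz;
      const vec& a = cache.da[i];  // post-activation of layer i-1 (relu)
      dz = da % conv_to<vec>::from(a > 0);
    } else {
      vec da = dl.W * dz;
      dz = da;  // gradient wrt flatten
    }
  }
  // un-flatten
  int nconv = (int)cache.acts.size();
  const mat& last = cache.acts[nconv - 1];
  mat dcur = reshape(dz, last.n_rows, last.n_cols);

  // dims at the output of each block after pooling; rebuild the dim trace
  std::vector<Dims> dim_at_conv(nconv);  // input dims of each conv layer
  {
    Dims d = {net.X, net.Y, net.Z};
    int li = 0;
    for (size_t b = 0; b < net.blocks.size(); ++b) {
      for (size_t l = 0; l < net.blocks[b].size(); ++l) dim_at_conv[li++] = d;
      if ((int)b < net.n_pool) { d.X = pool_out(d.X); d.Y = pool_out(d.Y); d.Z = pool_out(d.Z); }
    }
  }

  int li = nconv - 1;
  int pi = (int)cache.amax.size() - 1;
  for (int b = (int)net.blocks.size() - 1; b >= 0; --b) {
    if (b < net.n_pool) {
      // route gradient through pool pi
      const umat& am = cache.amax[pi];
      Dims pd = cache.pre_pool[pi];
      mat dun(zeros<mat>((uword)pd.X * pd.Y * pd.Z, dcur.n_cols));
      for (uword c = 0; c < dcur.n_cols; ++c)
        for (uword i = 0; i < dcur.n_rows; ++i)
          dun(am(i, c), c) += dcur(i, c);
      dcur = std::move(dun);
      --pi;
    }
    for (int l = (int)net.blocks[b].size() - 1; l >= 0; --l, --li) {
      ConvLayer& cl = net.blocks[b][l];
      const mat& act = cache.acts[li];
      mat dzc = dcur % conv_to<mat>::from(act > 0);
      g.cW[li] += cache.cols[li].t() * dzc;
      g.cb[li] += sum(dzc, 0);
      if (li > 0) {
        mat dcol = dzc * cl.W.t();
        Dims d = dim_at_conv[li];
        mat din;
        col2vol(dcol, d.X, d.Y, d.Z, cl.cin, din);
        dcur = std::move(din);
      }
    }
  }
}

void adam_update(mat& W, mat& m, mat& v, const mat& g, double lr,
                 double b1, double b2, double eps, long t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * square(g);
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  W -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

void ensure_adam(Net& net) {
  if (net.adam_ready) return;
  for (auto& blk : net.blocks)
    for (auto& cl : blk) {
      cl.mW = zeros<mat>(cl.W.n_rows, cl.W.n_cols); cl.vW = cl.mW;
      cl.mb = zeros<rowvec>(cl.b.n_elem); cl.vb = cl.mb;
    }
  for (auto& dl : net.dense) {
    dl.mW = zeros<mat>(dl.W.n_rows, dl.W.n_cols); dl.vW = dl.mW;
    dl.mb = zeros<vec>(dl.b.n_elem); dl.vb = dl.mb;
  }
  net.adam_ready = true;
}

Net* get_net(SEXP xp) {
  Rcpp::XPtr<Net> p(xp);
  if (!p) Rcpp::stop("invalid network handle");
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP cnn_create(Rcpp::IntegerVector input_shape, Rcpp::List conv_blocks,
                Rcpp::IntegerVector dense_widths, double l2) {
  if (input_shape.size() != 3) Rcpp::stop("input_shape must have 3 elements");
  Net* net = new Net();
  net->X = input_shape[0]; net->Y = input_shape[1]; net->Z = input_shape[2];
  if (net->X < 1 || net->Y < 1 || net->Z < 1) Rcpp::stop("input_shape must be positive");
  net->l2 = l2;
  net->adam_t = 0;
  net->adam_ready = false;
  net->n_pool = (int)conv_blocks.size() - 1;
  int cin = 1;
  Dims d = {net->X, net->Y, net->Z};
  for (int b = 0; b < conv_blocks.size(); ++b) {
    Rcpp::IntegerVector widths(conv_blocks[b]);
    std::vector<ConvLayer> blk;
    for (int l = 0; l < widths.size(); ++l) {
      ConvLayer cl;
      cl.cin = cin; cl.cout = widths[l];
      if (cl.cout < 1) Rcpp::stop("conv width must be positive");
      cl.W = zeros<mat>(27 * cl.cin, cl.cout);
      cl.b = zeros<rowvec>(cl.cout);
      blk.push_back(std::move(cl));
      cin = widths[l];
    }
    net->blocks.push_back(std::move(blk));
    if (b < net->n_pool) { d.X = pool_out(d.X); d.Y = pool_out(d.Y); d.Z = pool_out(d.Z); }
  }
  int nin = d.X * d.Y * d.Z * cin;
  for (int i = 0; i < dense_widths.size(); ++i) {
    DenseLayer dl;
    dl.nin = nin; dl.nout = dense_widths[i];
    dl.W = zeros<mat>(dl.nin, dl.nout);
    dl.b = zeros<vec>(dl.nout);
    net->dense.push_back(std::move(dl));
    nin = dense_widths[i];
  }
  if (nin != 1) Rcpp::stop("final dense layer must have width 1");
  Rcpp::XPtr<Net> xp(net, true);
  return xp;
}

// [[Rcpp::export]]
Rcpp::List cnn_get_weights(SEXP xp) {
  Net* net = get_net(xp);
  Rcpp::List out;
  int k = 0;
  for (auto& blk : net->blocks)
    for (auto& cl : blk) {
      out.push_back(Rcpp::wrap(cl.W));
      out.push_back(Rcpp::wrap(vec(cl.b.t())));
      k += 2;
    }
  for (auto& dl : net->dense) {
    out.push_back(Rcpp::wrap(dl.W));
    out.push_back(Rcpp::wrap(dl.b));
    k += 2;
  }
  return out;
}

// [[Rcpp::export]]
void cnn_set_weights(SEXP xp, Rcpp::List weights) {
  Net* net = get_net(xp);
  int k = 0;
  for (auto& blk : net->blocks)
    for (auto& cl : blk) {
      mat W = Rcpp::as<mat>(weights[k++]);
      vec b = Rcpp::as<vec>(weights[k++]);
      if (W.n_rows != cl.W.n_rows || W.n_cols != cl.W.n_cols)
        Rcpp::stop("conv weight shape mismatch");
      cl.W = W; cl.b = b.t();
    }
  for (auto& dl : net->dense) {
    mat W = Rcpp::as<mat>(weights[k++]);
    vec b = Rcpp::as<vec>(weights[k++]);
    if (W.n_rows != dl.W.n_rows || W.n_cols != dl.W.n_cols)
      Rcpp::stop("dense weight shape mismatch");
    dl.W = W; dl.b = b;
  }
}

// [[Rcpp::export]]
double cnn_param_count(SEXP xp) {
  Net* net = get_net(xp);
  double n = 0;
  for (auto& blk : net->blocks)
    for (auto& cl : blk) n += cl.W.n_elem + cl.b.n_elem;
  for (auto& dl : net->dense) n += dl.W.n_elem + dl.b.n_elem;
  return n;
}

// [[Rcpp::export]]
Rcpp::IntegerVector cnn_shape_trace(SEXP xp) {
  // spatial dims + channels after each block (post-pool where applicable)
  Net* net = get_net(xp);
  Dims d = {net->X, net->Y, net->Z};
  std::vector<int> tr;
  for (size_t b = 0; b < net->blocks.size(); ++b) {
    int ch = net->blocks[b].back().cout;
    if ((int)b < net->n_pool) { d.X = pool_out(d.X); d.Y = pool_out(d.Y); d.Z = pool_out(d.Z); }
    tr.push_back(d.X); tr.push_back(d.Y); tr.push_back(d.Z); tr.push_back(ch);
  }
  return Rcpp::wrap(tr);
}

// boxes: numeric vector of length X*Y*Z*N (column-major 4D array)
// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_forward(SEXP xp, Rcpp::NumericVector boxes,
                                Rcpp::IntegerVector dim, bool features) {
  Net* net = get_net(xp);
  if (dim.size() != 4 || dim[0] != net->X || dim[1] != net->Y || dim[2] != net->Z)
    Rcpp::stop("box dimensions do not match the network input shape");
  const int N = dim[3];
  const uword nvox = (uword)net->X * net->Y * net->Z;
  if ((uword)boxes.size() != nvox * N) Rcpp::stop("box array length mismatch");
  const int pw = net->dense.size() >= 2 ? net->dense[net->dense.size() - 2].nout : 1;
  Rcpp::NumericMatrix out(N, features ? pw : 1);
  for (int i = 0; i < N; ++i) {
    vec img(&boxes[0] + (uword)i * nvox, nvox);
    vec pen;
    double s = forward_one(*net, img, false, nullptr, features ? &pen : nullptr);
    if (features) {
      for (int j = 0; j < pw; ++j) out(i, j) = pen(j);
    } else {
      out(i, 0) = s;
    }
  }
  return out;
}

// Mean-batch gradients (including the L2 term), in cnn_get_weights order.
// [[Rcpp::export]]
Rcpp::List cnn_gradients(SEXP xp, Rcpp::NumericVector boxes, Rcpp::IntegerVector dim,
                         Rcpp::NumericVector labels) {
  Net* net = get_net(xp);
  const int N = dim[3];
  const uword nvox = (uword)net->X * net->Y * net->Z;
  Grads g;
  init_grads(*net, g);
  for (int i = 0; i < N; ++i) {
    vec img(&boxes[0] + (uword)i * nvox, nvox);
    Cache cache;
    double p = forward_one(*net, img, true, &cache, nullptr);
    backward_one(*net, cache, p - labels[i], g);
  }
  Rcpp::List out;
  int li = 0;
  for (auto& blk : net->blocks)
    for (auto& cl : blk) {
      out.push_back(Rcpp::wrap(mat(g.cW[li] / N + 2.0 * net->l2 * cl.W)));
      out.push_back(Rcpp::wrap(vec(g.cb[li].t() / N)));
      ++li;
    }
  li = 0;
  for (auto& dl : net->dense) {
    out.push_back(Rcpp::wrap(mat(g.dW[li] / N + 2.0 * net->l2 * dl.W)));
    out.push_back(Rcpp::wrap(vec(g.db[li] / N)));
    ++li;
  }
  return out;
}

// [[Rcpp::export]]
double cnn_train_batch(SEXP xp, Rcpp::NumericVector boxes, Rcpp::IntegerVector dim,
                       Rcpp::NumericVector labels, double lr,
                       double beta1, double beta2, double eps) {
  Net* net = get_net(xp);
  if (dim.size() != 4 || dim[0] != net->X || dim[1] != net->Y || dim[2] != net->Z)
    Rcpp::stop("box dimensions do not match the network input shape");
  const int N = dim[3];
  if (labels.size() != N) Rcpp::stop("labels length mismatch");
  const uword nvox = (uword)net->X * net->Y * net->Z;
  Grads g;
  init_grads(*net, g);
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    vec img(&boxes[0] + (uword)i * nvox, nvox);
    Cache cache;
    double p = forward_one(*net, img, true, &cache, nullptr);
    const double y = labels[i];
    const double pe = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    loss += -(y * std::log(pe) + (1.0 - y) * std::log(1.0 - pe));
    backward_one(*net, cache, p - y, g);
  }
  loss /= N;
  // L2 penalty on weight matrices (not biases)
  double pen = 0.0;
  for (auto& blk : net->blocks) for (auto& cl : blk) pen += accu(square(cl.W));
  for (auto& dl : net->dense) pen += accu(square(dl.W));
  loss += net->l2 * pen;

  ensure_adam(*net);
  net->adam_t += 1;
  if (lr > 0.0) {
    int li = 0;
    for (auto& blk : net->blocks)
      for (auto& cl : blk) {
        mat gW = g.cW[li] / N + 2.0 * net->l2 * cl.W;
        mat gb(g.cb[li] / N);
        mat bW(cl.b); mat mb(cl.mb), vb(cl.vb);
        adam_update(cl.W, cl.mW, cl.vW, gW, lr, beta1, beta2, eps, net->adam_t);
        adam_update(bW, mb, vb, gb, lr, beta1, beta2, eps, net->adam_t);
        cl.b = bW.row(0); cl.mb = mb.row(0); cl.vb = vb.row(0);
        ++li;
      }
    li = 0;
    for (auto& dl : net->dense) {
      mat gW = g.dW[li] / N + 2.0 * net->l2 * dl.W;
      mat gb(g.db[li] / N);
      mat bW(dl.b); mat mb(dl.mb), vb(dl.vb);
      adam_update(dl.W, dl.mW, dl.vW, gW, lr, beta1, beta2, eps, net->adam_t);
      adam_update(bW, mb, vb, gb, lr, beta1, beta2, eps, net->adam_t);
      dl.b = bW.col(0); dl.mb = mb.col(0); dl.vb = vb.col(0);
      ++li;
    }
  }
  return loss;
}
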