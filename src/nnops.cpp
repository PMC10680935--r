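// Compiled core: 3D convolutional network primitives (im2col + BLAS GEMM),
// separable Gaussian filtering with reflective boundaries and its exact
// adjoint, grid resampling, and 3D morphology used for brain masking.
//
// Network feature maps are stored as (n_voxels x channels) single-precision
// matrices (the conventional deep-learning precision), voxel index fastest
// along x (column-major array order), v = ix + nx*(iy + ny*iz).  Losses and
// everything exported to R are double.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;
typedef arma::fmat fm;
typedef arma::fvec fv;

namespace {

struct Dims {
  int nx, ny, nz;
  int n() const { return nx * ny * nz; }
};

// ---------------------------------------------------------------------------
// im2col for 3x3x3 same-padding convolution, blocked over z-slabs so the
// column matrix stays small while every copy runs along contiguous x-lines.
// Column index k = c*27 + o with o = (dx+1) + 3*(dy+1) + 9*(dz+1).
// ---------------------------------------------------------------------------
int conv_slab(const Dims& d, int K) {
  const double target = 8.0e6;  // elements per column block
  const int zs = std::max(1, static_cast<int>(target / (static_cast<double>(d.nx) * d.ny * K)));
  return std::min(zs, d.nz);
}

void im2col_slab(const fm& X, const Dims& d, int z0, int nslab, fm& C) {
  const int cin = X.n_cols;
  const int nxy = d.nx * d.ny;
  for (int c = 0; c < cin; ++c) {
    const float* xc = X.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(d.nx, d.nx - dx);
      float* col = C.colptr(c * 27 + o);
      for (int s = 0; s < nslab; ++s) {
        const int jz = z0 + s + dz;
        float* dslab = col + static_cast<size_t>(s) * nxy;
        if (jz < 0 || jz >= d.nz) {
          std::fill(dslab, dslab + nxy, 0.0f);
          continue;
        }
        for (int iy = 0; iy < d.ny; ++iy) {
          const int jy = iy + dy;
          float* drow = dslab + static_cast<size_t>(iy) * d.nx;
          if (jy < 0 || jy >= d.ny) {
            std::fill(drow, drow + d.nx, 0.0f);
            continue;
          }
          const float* src = xc + static_cast<size_t>(jz) * nxy +
                             static_cast<size_t>(jy) * d.nx;
          for (int ix = 0; ix < x0; ++ix) drow[ix] = 0.0f;
          std::copy(src + x0 + dx, src + x1 + dx, drow + x0);
          for (int ix = x1; ix < d.nx; ++ix) drow[ix] = 0.0f;
        }
      }
    }
  }
}

// Y = conv3(X, W) + b, same padding.  W is (27*cin x cout).
fm conv3_forward(const fm& X, const Dims& d, const fm& W, const fv& b) {
  const int n = d.n(), nxy = d.nx * d.ny;
  const int zstep = conv_slab(d, W.n_rows);
  fm Y(n, W.n_cols);
  fm C;
  for (int z0 = 0; z0 < d.nz; z0 += zstep) {
    const int ns = std::min(zstep, d.nz - z0);
    C.set_size(static_cast<size_t>(nxy) * ns, W.n_rows);
    im2col_slab(X, d, z0, ns, C);
    Y.rows(static_cast<size_t>(z0) * nxy, static_cast<size_t>(z0 + ns) * nxy - 1) = C * W;
  }
  Y.each_row() += b.t();
  return Y;
}

// Adjoint of im2col: accumulate a slab's column gradient back onto dX.
void col2im_slab(const fm& G, const Dims& d, int z0, int nslab, fm& dX) {
  const int cin = dX.n_cols;
  const int nxy = d.nx * d.ny;
  for (int c = 0; c < cin; ++c) {
    float* xc = dX.colptr(c);
    for (int o = 0; o < 27; ++o) {
      const int dx = o % 3 - 1, dy = (o / 3) % 3 - 1, dz = o / 9 - 1;
      const int x0 = std::max(0, -dx), x1 = std::min(d.nx, d.nx - dx);
      const float* col = G.colptr(c * 27 + o);
      for (int s = 0; s < nslab; ++s) {
        const int jz = z0 + s + dz;
        if (jz < 0 || jz >= d.nz) continue;
        const float* dslab = col + static_cast<size_t>(s) * nxy;
        for (int iy = 0; iy < d.ny; ++iy) {
          const int jy = iy + dy;
          if (jy < 0 || jy >= d.ny) continue;
          const float* srow = dslab + static_cast<size_t>(iy) * d.nx;
          float* dst = xc + static_cast<size_t>(jz) * nxy +
                       static_cast<size_t>(jy) * d.nx + x0 + dx;
          const int len = x1 - x0;
          const float* sp = srow + x0;
          for (int ix = 0; ix < len; ++ix) dst[ix] += sp[ix];
        }
      }
    }
  }
}

// Backward pass of conv3: fills dW, db, and (if wanted) dX.
void conv3_backward(const fm& X, const Dims& d, const fm& W, const fm& dY,
                    fm& dW, fv& db, fm* dX) {
  const int nxy = d.nx * d.ny;
  dW.zeros(W.n_rows, W.n_cols);
  db = arma::sum(dY, 0).t();
  if (dX) dX->zeros(d.n(), X.n_cols);
  const int zstep = conv_slab(d, W.n_rows);
  fm C;
  for (int z0 = 0; z0 < d.nz; z0 += zstep) {
    const int ns = std::min(zstep, d.nz - z0);
    C.set_size(static_cast<size_t>(nxy) * ns, W.n_rows);
    im2col_slab(X, d, z0, ns, C);
    const fm dYb = dY.rows(static_cast<size_t>(z0) * nxy,
                           static_cast<size_t>(z0 + ns) * nxy - 1);
    dW += C.t() * dYb;
    if (dX) {
      fm Gb = dYb * W.t();
      col2im_slab(Gb, d, z0, ns, *dX);
    }
  }
}

// ---------------------------------------------------------------------------
// Instance normalization (per channel over all voxels), leaky ReLU, pooling,
// transpose convolution (2x2x2, stride 2).
// ---------------------------------------------------------------------------
const float IN_EPS = 1e-5f;

struct INCache { fm xhat; fv invstd; };

fm inorm_forward(const fm& X, const fv& g, const fv& b, INCache& cache) {
  const int n = X.n_rows, c = X.n_cols;
  cache.xhat.set_size(n, c);
  cache.invstd.set_size(c);
  fm Y(n, c);
  for (int j = 0; j < c; ++j) {
    // accumulate moments in double for stability
    double s1 = 0.0, s2 = 0.0;
    const float* x = X.colptr(j);
    for (int i = 0; i < n; ++i) { s1 += x[i]; s2 += static_cast<double>(x[i]) * x[i]; }
    const double mu = s1 / n;
    const double var = std::max(0.0, s2 / n - mu * mu);
    const float is = static_cast<float>(1.0 / std::sqrt(var + IN_EPS));
    cache.invstd(j) = is;
    cache.xhat.col(j) = (X.col(j) - static_cast<float>(mu)) * is;
    Y.col(j) = g(j) * cache.xhat.col(j) + b(j);
  }
  return Y;
}

fm inorm_backward(const fm& dY, const fv& g, const INCache& cache,
                  fv& dg, fv& db) {
  const int n = dY.n_rows, c = dY.n_cols;
  dg.set_size(c); db.set_size(c);
  fm dX(n, c);
  for (int j = 0; j < c; ++j) {
    dg(j) = arma::dot(dY.col(j), cache.xhat.col(j));
    db(j) = arma::accu(dY.col(j));
    const fv dxh = dY.col(j) * g(j);
    const float m1 = arma::mean(dxh);
    const float m2 = arma::mean(dxh % cache.xhat.col(j));
    dX.col(j) = cache.invstd(j) * (dxh - m1 - cache.xhat.col(j) * m2);
  }
  return dX;
}

inline fm lrelu_forward(const fm& X, float slope) {
  fm Y = X;
  Y.transform([slope](float x) { return x > 0.0f ? x : slope * x; });
  return Y;
}

// Uses the forward output: for slope > 0, sign(y) == sign(x).
inline fm lrelu_backward(const fm& dY, const fm& Y, float slope) {
  fm dX(dY.n_rows, dY.n_cols);
  const float* y = Y.memptr();
  const float* g = dY.memptr();
  float* o = dX.memptr();
  const size_t n = dY.n_elem;
  for (size_t i = 0; i < n; ++i) o[i] = y[i] > 0.0f ? g[i] : slope * g[i];
  return dX;
}

fm maxpool_forward(const fm& X, const Dims& d, Dims& dout, arma::umat& argmax) {
  dout = {d.nx / 2, d.ny / 2, d.nz / 2};
  const int c = X.n_cols;
  fm Y(dout.n(), c);
  argmax.set_size(dout.n(), c);
  const int nxy = d.nx * d.ny, sxy = dout.nx * dout.ny;
  for (int iz = 0; iz < dout.nz; ++iz)
    for (int iy = 0; iy < dout.ny; ++iy)
      for (int ix = 0; ix < dout.nx; ++ix) {
        const int vs = ix + dout.nx * iy + sxy * iz;
        int idx[8]; int t = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx)
              idx[t++] = (2 * ix + dx) + d.nx * (2 * iy + dy) + nxy * (2 * iz + dz);
        for (int j = 0; j < c; ++j) {
          float best = X(idx[0], j); int bi = idx[0];
          for (int k = 1; k < 8; ++k)
            if (X(idx[k], j) > best) { best = X(idx[k], j); bi = idx[k]; }
          Y(vs, j) = best;
          argmax(vs, j) = bi;
        }
      }
  return Y;
}

fm maxpool_backward(const fm& dY, const arma::umat& argmax, int n_big) {
  fm dX(n_big, dY.n_cols, arma::fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (uword v = 0; v < dY.n_rows; ++v)
      dX(argmax(v, j), j) += dY(v, j);
  return dX;
}

fm avgpool_forward(const fm& X, const Dims& d, Dims& dout) {
  dout = {d.nx / 2, d.ny / 2, d.nz / 2};
  const int c = X.n_cols;
  fm Y(dout.n(), c, arma::fill::zeros);
  const int nxy = d.nx * d.ny, sxy = dout.nx * dout.ny;
  for (int iz = 0; iz < dout.nz; ++iz)
    for (int iy = 0; iy < dout.ny; ++iy)
      for (int ix = 0; ix < dout.nx; ++ix) {
        const int vs = ix + dout.nx * iy + sxy * iz;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int vb = (2 * ix + dx) + d.nx * (2 * iy + dy) + nxy * (2 * iz + dz);
              for (int j = 0; j < c; ++j) Y(vs, j) += 0.125f * X(vb, j);
            }
      }
  return Y;
}

fm avgpool_backward(const fm& dY, const Dims& dbig) {
  const int c = dY.n_cols;
  Dims ds = {dbig.nx / 2, dbig.ny / 2, dbig.nz / 2};
  fm dX(dbig.n(), c);
  const int nxy = dbig.nx * dbig.ny, sxy = ds.nx * ds.ny;
  for (int iz = 0; iz < ds.nz; ++iz)
    for (int iy = 0; iy < ds.ny; ++iy)
      for (int ix = 0; ix < ds.nx; ++ix) {
        const int vs = ix + ds.nx * iy + sxy * iz;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int vb = (2 * ix + dx) + dbig.nx * (2 * iy + dy) + nxy * (2 * iz + dz);
              for (int j = 0; j < c; ++j) dX(vb, j) = 0.125f * dY(vs, j);
            }
      }
  return dX;
}

// Transpose convolution, kernel 2x2x2, stride 2.  W is (cin x 8*cout) with
// column index o*cout + oc, o = dx + 2*dy + 4*dz.
fm tconv_forward(const fm& X, const Dims& ds, const fm& W, const fv& b,
                 Dims& dbig) {
  dbig = {ds.nx * 2, ds.ny * 2, ds.nz * 2};
  const int cout_ = b.n_elem;
  const fm M = X * W;  // (n_small x 8*cout)
  fm Y(dbig.n(), cout_);
  Y.each_row() = b.t();
  const int bxy = dbig.nx * dbig.ny, sxy = ds.nx * ds.ny;
  for (int iz = 0; iz < ds.nz; ++iz)
    for (int iy = 0; iy < ds.ny; ++iy)
      for (int ix = 0; ix < ds.nx; ++ix) {
        const int vs = ix + ds.nx * iy + sxy * iz;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int o = dx + 2 * dy + 4 * dz;
              const int vb = (2 * ix + dx) + dbig.nx * (2 * iy + dy) + bxy * (2 * iz + dz);
              for (int oc = 0; oc < cout_; ++oc)
                Y(vb, oc) += M(vs, o * cout_ + oc);
            }
      }
  return Y;
}

fm tconv_backward(const fm& X, const Dims& ds, const fm& W, const fm& dY,
                  const Dims& dbig, fm& dW, fv& db) {
  const int cout_ = dY.n_cols;
  fm dM(ds.n(), 8 * cout_);
  const int bxy = dbig.nx * dbig.ny, sxy = ds.nx * ds.ny;
  for (int iz = 0; iz < ds.nz; ++iz)
    for (int iy = 0; iy < ds.ny; ++iy)
      for (int ix = 0; ix < ds.nx; ++ix) {
        const int vs = ix + ds.nx * iy + sxy * iz;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const int o = dx + 2 * dy + 4 * dz;
              const int vb = (2 * ix + dx) + dbig.nx * (2 * iy + dy) + bxy * (2 * iz + dz);
              for (int oc = 0; oc < cout_; ++oc)
                dM(vs, o * cout_ + oc) = dY(vb, oc);
            }
      }
  dW = X.t() * dM;
  db = arma::sum(dY, 0).t();
  return dM * W.t();
}

// ---------------------------------------------------------------------------
// Network assembly.  Parameters come in as a named R list (double arrays);
// order/shape fixed by the R-side initializer.  Converted to float per call.
// ---------------------------------------------------------------------------
struct NetCfg { int levels; float slope; int pool; };  // pool: 0 = max, 1 = average

fm getW(const List& p, const std::string& nm) {
  const NumericMatrix m = as<NumericMatrix>(p[nm]);
  fm out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
fv getv(const List& p, const std::string& nm) {
  const NumericVector v = as<NumericVector>(p[nm]);
  fv out(v.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

std::string enc(int l, const char* what) {
  return "enc" + std::to_string(l) + "_" + what;
}
std::string dec(int l, const char* what) {
  return "dec" + std::to_string(l) + "_" + what;
}

struct BlockCache {
  fm in1;             // input to conv1
  INCache n1, n2;
  fm a1, a2;          // leaky ReLU outputs (a1 also input to conv2)
};

struct Tape {
  NetCfg cfg;
  Dims d0;
  std::vector<Dims> dims;             // grid at each level
  std::vector<BlockCache> encB, decB;
  std::vector<arma::umat> poolArg;
  std::vector<fm> upIn;               // inputs to transpose convs
  std::vector<fm> encOut;             // skip tensors
  fm outIn;                           // input to final 1x1x1 conv
  fm pred;
};

fm run_block(const List& p, const std::string& pre, const fm& X, const Dims& d,
             float slope, BlockCache& cb) {
  cb.in1 = X;
  fm y = conv3_forward(X, d, getW(p, pre + "conv1_W"), getv(p, pre + "conv1_b"));
  y = inorm_forward(y, getv(p, pre + "in1_g"), getv(p, pre + "in1_b"), cb.n1);
  cb.a1 = lrelu_forward(y, slope);
  y = conv3_forward(cb.a1, d, getW(p, pre + "conv2_W"), getv(p, pre + "conv2_b"));
  y = inorm_forward(y, getv(p, pre + "in2_g"), getv(p, pre + "in2_b"), cb.n2);
  cb.a2 = lrelu_forward(y, slope);
  return cb.a2;
}

void put_grad(List& grads, const std::string& nm, const fm& g) {
  NumericMatrix out(g.n_rows, g.n_cols);
  std::copy(g.begin(), g.end(), out.begin());
  grads[nm] = out;
}
void put_grad(List& grads, const std::string& nm, const fv& g) {
  NumericVector out(g.n_elem);
  std::copy(g.begin(), g.end(), out.begin());
  grads[nm] = out;
}

fm back_block(const List& p, const std::string& pre, const Dims& d, float slope,
              const BlockCache& cb, const fm& dOut, List& grads, bool need_dx) {
  fm g = lrelu_backward(dOut, cb.a2, slope);
  fv dg2, db2;
  g = inorm_backward(g, getv(p, pre + "in2_g"), cb.n2, dg2, db2);
  put_grad(grads, pre + "in2_g", dg2); put_grad(grads, pre + "in2_b", db2);
  fm dW2; fv dbv2; fm dA1;
  conv3_backward(cb.a1, d, getW(p, pre + "conv2_W"), g, dW2, dbv2, &dA1);
  put_grad(grads, pre + "conv2_W", dW2); put_grad(grads, pre + "conv2_b", dbv2);
  g = lrelu_backward(dA1, cb.a1, slope);
  fv dg1, db1;
  g = inorm_backward(g, getv(p, pre + "in1_g"), cb.n1, dg1, db1);
  put_grad(grads, pre + "in1_g", dg1); put_grad(grads, pre + "in1_b", db1);
  fm dW1; fv dbv1; fm dX;
  conv3_backward(cb.in1, d, getW(p, pre + "conv1_W"), g, dW1, dbv1,
                 need_dx ? &dX : nullptr);
  put_grad(grads, pre + "conv1_W", dW1); put_grad(grads, pre + "conv1_b", dbv1);
  return dX;
}

void unet_forward_impl(const List& params, const fm& input, const Dims& d0,
                       const NetCfg& cfg, Tape& tp) {
  tp.cfg = cfg; tp.d0 = d0;
  const int L = cfg.levels;
  tp.dims.resize(L);
  tp.encB.resize(L);
  tp.decB.resize(L);
  tp.poolArg.resize(L);
  tp.upIn.resize(L);
  tp.encOut.resize(L);
  fm x = input;
  Dims d = d0;
  for (int l = 1; l <= L; ++l) {
    if (l > 1) {
      Dims ds;
      if (cfg.pool == 0) x = maxpool_forward(x, d, ds, tp.poolArg[l - 1]);
      else x = avgpool_forward(x, d, ds);
      d = ds;
    }
    tp.dims[l - 1] = d;
    x = run_block(params, enc(l, ""), x, d, cfg.slope, tp.encB[l - 1]);
    tp.encOut[l - 1] = x;
  }
  for (int l = L - 1; l >= 1; --l) {
    tp.upIn[l - 1] = x;
    Dims dbig;
    x = tconv_forward(x, d, getW(params, dec(l, "up_W")), getv(params, dec(l, "up_b")), dbig);
    d = dbig;
    x = arma::join_rows(x, tp.encOut[l - 1]);   // [upsampled | skip]
    x = run_block(params, dec(l, ""), x, d, cfg.slope, tp.decB[l - 1]);
  }
  tp.outIn = x;
  tp.pred = x * getW(params, "out_W");
  tp.pred.each_row() += getv(params, "out_b").t();
}

List unet_backward_impl(const List& params, const Tape& tp, const fm& dPred) {
  const int L = tp.cfg.levels;
  List grads;
  put_grad(grads, "out_W", fm(tp.outIn.t() * dPred));
  put_grad(grads, "out_b", fv(arma::sum(dPred, 0).t()));
  fm g = dPred * getW(params, "out_W").t();
  std::vector<fm> skipGrad(L);
  Dims d = tp.d0;
  for (int l = 1; l <= L - 1; ++l) {
    g = back_block(params, dec(l, ""), d, tp.cfg.slope, tp.decB[l - 1], g, grads, true);
    // split concat: first cols were the upsampled path, rest the skip
    const int c_skip = tp.encOut[l - 1].n_cols;
    const int c_up = g.n_cols - c_skip;
    skipGrad[l - 1] = g.cols(c_up, g.n_cols - 1);
    fm gup = g.cols(0, c_up - 1);
    Dims ds = tp.dims[l];
    fm dWu; fv dbu;
    g = tconv_backward(tp.upIn[l - 1], ds, getW(params, dec(l, "up_W")), gup, d, dWu, dbu);
    put_grad(grads, dec(l, "up_W"), dWu); put_grad(grads, dec(l, "up_b"), dbu);
    d = ds;
  }
  for (int l = L; l >= 1; --l) {
    if (l < L) g += skipGrad[l - 1];
    g = back_block(params, enc(l, ""), tp.dims[l - 1], tp.cfg.slope,
                   tp.encB[l - 1], g, grads, l > 1);
    if (l > 1) {
      if (tp.cfg.pool == 0)
        g = maxpool_backward(g, tp.poolArg[l - 1], tp.dims[l - 2].n());
      else
        g = avgpool_backward(g, tp.dims[l - 2]);
    }
  }
  return grads;
}

}  // namespace

// double-precision separable filter (declared early; defined below)
mat sep_filter_axis(const mat& Xcol, const Dims& d, const vec& k, int axis, bool adjoint);

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List params, NumericVector input, IntegerVector dims,
                               int levels, double slope, int pool) {
  Dims d0 = {dims[0], dims[1], dims[2]};
  fm x(d0.n(), 1);
  std::copy(input.begin(), input.end(), x.begin());
  Tape tp;
  unet_forward_impl(params, x, d0, {levels, static_cast<float>(slope), pool}, tp);
  NumericVector out(tp.pred.n_elem);
  std::copy(tp.pred.begin(), tp.pred.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Forward + backward in one call: returns loss components, the predicted
// log-field, and parameter gradients.
// loss_space: 0 = linear-space field L2 (la) + corrected-image L2 (lb);
//             1 = log-space L2 on the field alone.
// If gk (a 1D Gaussian kernel) is non-empty, the exponentiated field is
// smoothed (separable, reflect boundary) before entering the loss, and the
// exact adjoint of that filtering is used in the backward pass.
// [[Rcpp::export]]
List cpp_unet_train_step(List params, NumericVector input, IntegerVector dims,
                         int levels, double slope, int pool,
                         NumericVector a_img, NumericVector b_true,
                         NumericVector u_true, LogicalVector mask,
                         double eps, int loss_space, NumericVector gk) {
  Dims d0 = {dims[0], dims[1], dims[2]};
  const int n = d0.n();
  fm x(n, 1);
  std::copy(input.begin(), input.end(), x.begin());
  Tape tp;
  unet_forward_impl(params, x, d0, {levels, static_cast<float>(slope), pool}, tp);

  // ---- loss on prediction (double precision) ------------------------------
  vec lp(n);
  for (int i = 0; i < n; ++i) lp(i) = tp.pred(i, 0);
  vec ef = arma::exp(lp);
  vec field = ef;
  const bool smooth = gk.size() > 0;
  vec kk(gk.begin(), gk.size());
  if (smooth) {
    mat s(field.memptr(), n, 1);
    for (int ax = 0; ax < 3; ++ax) s = sep_filter_axis(s, d0, kk, ax, false);
    field = s.col(0);
  }
  const vec av(a_img.begin(), n), bv(b_true.begin(), n), uv(u_true.begin(), n);
  double N = 0.0;
  for (int i = 0; i < n; ++i) if (mask[i]) N += 1.0;
  if (N < 1.0) stop("empty mask");
  double la = 0.0, lb = 0.0;
  vec dfield(n, arma::fill::zeros);
  vec dlp_log(n, arma::fill::zeros);
  if (loss_space == 0) {
    for (int i = 0; i < n; ++i) {
      if (!mask[i]) continue;
      const double f = std::max(field(i), eps);
      const double ra = f - bv(i);
      la += ra * ra;
      const double rb = av(i) / f - uv(i);
      lb += rb * rb;
      dfield(i) = (2.0 / N) * ra + (2.0 / N) * rb * (-av(i) / (f * f));
    }
    la /= N; lb /= N;
  } else {
    for (int i = 0; i < n; ++i) {
      if (!mask[i]) continue;
      const double r = lp(i) - std::log(std::max(bv(i), eps));
      la += r * r;
      dlp_log(i) = (2.0 / N) * r;
    }
    la /= N;
  }
  vec dlp;
  if (loss_space == 0) {
    if (smooth) {
      mat s(dfield.memptr(), n, 1);
      for (int ax = 2; ax >= 0; --ax) s = sep_filter_axis(s, d0, kk, ax, true);
      dlp = s.col(0) % ef;
    } else {
      dlp = dfield % ef;
    }
  } else {
    dlp = dlp_log;
  }
  fm dPred(n, 1);
  for (int i = 0; i < n; ++i) dPred(i, 0) = static_cast<float>(dlp(i));
  List grads = unet_backward_impl(params, tp, dPred);

  NumericVector pred(n);
  std::copy(tp.pred.begin(), tp.pred.end(), pred.begin());
  pred.attr("dim") = dims;
  return List::create(_["la"] = la, _["lb"] = lb, _["loss"] = la + lb,
                      _["pred"] = pred, _["grads"] = grads);
}

// ---------------------------------------------------------------------------
// Separable filtering along one axis with reflective (mirror-without-repeat)
// boundaries, plus its exact adjoint.
// ---------------------------------------------------------------------------
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return i < n ? i : period - i;
}

mat sep_filter_axis(const mat& Xcol, const Dims& d, const vec& k, int axis, bool adjoint) {
  const int r = (static_cast<int>(k.n_elem) - 1) / 2;
  const int nax = axis == 0 ? d.nx : (axis == 1 ? d.ny : d.nz);
  mat Y(Xcol.n_rows, Xcol.n_cols);
  const int nxy = d.nx * d.ny;
  const double* kp = k.memptr();
  const int kw = 2 * r + 1;
  std::vector<double> buf(nax + 2 * r), out(nax), acc(nax + 2 * r);
  for (uword ch = 0; ch < Xcol.n_cols; ++ch) {
    const double* xc = Xcol.colptr(ch);
    double* yc = Y.colptr(ch);
    for (int iz = 0; iz < (axis == 2 ? 1 : d.nz); ++iz)
      for (int iy = 0; iy < (axis == 1 ? 1 : d.ny); ++iy)
        for (int ix = 0; ix < (axis == 0 ? 1 : d.nx); ++ix) {
          size_t stride, base;
          if (axis == 0) { stride = 1; base = static_cast<size_t>(d.nx) * iy + static_cast<size_t>(nxy) * iz; }
          else if (axis == 1) { stride = d.nx; base = ix + static_cast<size_t>(nxy) * iz; }
          else { stride = nxy; base = ix + static_cast<size_t>(d.nx) * iy; }
          if (!adjoint) {
            // pad line with mirrored (no-repeat) boundaries, then correlate
            for (int i = 0; i < nax; ++i) buf[r + i] = xc[base + stride * i];
            for (int t = 1; t <= r; ++t) {
              buf[r - t] = xc[base + stride * reflect_idx(-t, nax)];
              buf[r + nax - 1 + t] = xc[base + stride * reflect_idx(nax - 1 + t, nax)];
            }
            for (int i = 0; i < nax; ++i) {
              double s = 0.0;
              const double* bp = buf.data() + i;
              for (int t = 0; t < kw; ++t) s += kp[t] * bp[t];
              yc[base + stride * i] = s;
            }
          } else {
            // adjoint: full correlation into a padded accumulator, then fold
            // the mirrored margins back inside
            std::fill(acc.begin(), acc.end(), 0.0);
            for (int i = 0; i < nax; ++i) {
              const double g = xc[base + stride * i];
              double* ap = acc.data() + i;
              for (int t = 0; t < kw; ++t) ap[t] += kp[t] * g;
            }
            for (int i = 0; i < nax; ++i) out[i] = acc[r + i];
            for (int t = 1; t <= r; ++t) {
              out[reflect_idx(-t, nax)] += acc[r - t];
              out[reflect_idx(nax - 1 + t, nax)] += acc[r + nax - 1 + t];
            }
            for (int i = 0; i < nax; ++i) yc[base + stride * i] = out[i];
          }
        }
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector cpp_separable_filter(NumericVector x, IntegerVector dims,
                                   NumericVector kernel, bool adjoint) {
  Dims d = {dims[0], dims[1], dims[2]};
  mat X(x.begin(), d.n(), 1);
  vec k(kernel.begin(), kernel.size());
  mat Y = X;
  if (!adjoint) {
    for (int ax = 0; ax < 3; ++ax) Y = sep_filter_axis(Y, d, k, ax, false);
  } else {
    for (int ax = 2; ax >= 0; --ax) Y = sep_filter_axis(Y, d, k, ax, true);
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Grid resampling (trilinear / nearest) between voxel-center-aligned grids
// sharing one physical origin at the corner of voxel (0,0,0).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector x, IntegerVector sdims, NumericVector sspac,
                           IntegerVector odims, NumericVector ospac, bool nearest) {
  const int snx = sdims[0], sny = sdims[1], snz = sdims[2];
  const int onx = odims[0], ony = odims[1], onz = odims[2];
  NumericVector out(static_cast<R_xlen_t>(onx) * ony * onz);
  const double* src = x.begin();
  auto sample1 = [&](double cx, double cy, double cz) -> double {
    if (nearest) {
      int ix = std::min(std::max(static_cast<int>(std::floor(cx + 0.5)), 0), snx - 1);
      int iy = std::min(std::max(static_cast<int>(std::floor(cy + 0.5)), 0), sny - 1);
      int iz = std::min(std::max(static_cast<int>(std::floor(cz + 0.5)), 0), snz - 1);
      return src[ix + snx * (iy + static_cast<R_xlen_t>(sny) * iz)];
    }
    const double fx = std::min(std::max(cx, 0.0), snx - 1.0);
    const double fy = std::min(std::max(cy, 0.0), sny - 1.0);
    const double fz = std::min(std::max(cz, 0.0), snz - 1.0);
    const int x0 = std::max(0, std::min(static_cast<int>(std::floor(fx)), snx - 2));
    const int y0 = std::max(0, std::min(static_cast<int>(std::floor(fy)), sny - 2));
    const int z0 = std::max(0, std::min(static_cast<int>(std::floor(fz)), snz - 2));
    const double tx = snx > 1 ? fx - x0 : 0.0;
    const double ty = sny > 1 ? fy - y0 : 0.0;
    const double tz = snz > 1 ? fz - z0 : 0.0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz)
      for (int dy = 0; dy <= 1; ++dy)
        for (int dx = 0; dx <= 1; ++dx) {
          const int jx = std::min(x0 + dx, snx - 1);
          const int jy = std::min(y0 + dy, sny - 1);
          const int jz = std::min(z0 + dz, snz - 1);
          const double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) * (dz ? tz : 1 - tz);
          acc += w * src[jx + snx * (jy + static_cast<R_xlen_t>(sny) * jz)];
        }
    return acc;
  };
  R_xlen_t v = 0;
  for (int iz = 0; iz < onz; ++iz) {
    const double cz = ((iz + 0.5) * ospac[2]) / sspac[2] - 0.5;
    for (int iy = 0; iy < ony; ++iy) {
      const double cy = ((iy + 0.5) * ospac[1]) / sspac[1] - 0.5;
      for (int ix = 0; ix < onx; ++ix, ++v) {
        const double cx = ((ix + 0.5) * ospac[0]) / sspac[0] - 0.5;
        out[v] = sample1(cx, cy, cz);
      }
    }
  }
  out.attr("dim") = odims;
  return out;
}

// ---------------------------------------------------------------------------
// 3D morphology: 6-connected components and hole filling for brain masking.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector m, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      const int iz = v / sz; const R_xlen_t r2 = v - iz * sz;
      const int iy = r2 / nx; const int ix = r2 - static_cast<R_xlen_t>(iy) * nx;
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {ix > 0, ix < nx - 1, iy > 0, iy < ny - 1, iz > 0, iz < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (ok[k] && m[nb[k]] && lab[nb[k]] == 0) {
          lab[nb[k]] = next;
          stack.push_back(nb[k]);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Fill holes: background voxels not 6-connected to the array border become
// foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector m, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
  auto push_if = [&](R_xlen_t v) {
    if (!m[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
  };
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        if (ix == 0 || iy == 0 || iz == 0 || ix == nx - 1 || iy == ny - 1 || iz == nz - 1)
          push_if(ix + sy * iy + sz * iz);
  while (!stack.empty()) {
    const R_xlen_t v = stack.back(); stack.pop_back();
    const int iz = v / sz; const R_xlen_t r2 = v - iz * sz;
    const int iy = r2 / nx; const int ix = r2 - static_cast<R_xlen_t>(iy) * nx;
    if (ix > 0) push_if(v - sx);
    if (ix < nx - 1) push_if(v + sx);
    if (iy > 0) push_if(v - sy);
    if (iy < ny - 1) push_if(v + sy);
    if (iz > 0) push_if(v - sz);
    if (iz < nz - 1) push_if(v + sz);
  }
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = m[v] || !outside[v];
  out.attr("dim") = dims;
  return out;
}
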