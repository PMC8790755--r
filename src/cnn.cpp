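// Compact 3D convolutional scorer: forward pass, backpropagation (parameter
// and input gradients) and an Adam training loop.
//
// Architecture: a stack of 3x3x3 convolutions with stride 2 and padding 1
// (each halves the spatial side), ReLU after each, then a dense head on the
// flattened conv features: one ReLU hidden layer and a linear scalar output
// (the logit for classifiers, the prediction for regression). Per-position
// dense weights keep gradients — and hence attributions — spatially
// resolved.
//
// Volumes are arma::mat of shape (channels x voxels); voxel column index is
// x + n*(y + n*z). The R-side grid layout is channels-last (array dim
// c(n, n, n, C)), converted at the boundary.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvDims {
  int cin, cout, nin, nout, K, Min, Mout;
};

struct NetDims {
  std::vector<ConvDims> conv;
  int cLast;    // channels of the last conv output
  int mLast;    // voxels of the last conv output
  int feat;     // flattened feature width = cLast * mLast
  int hidden;   // dense hidden width
  int nParams;
  std::vector<int> convW, convB; // param offsets
  int d1W, d1B, d2W, d2B;
};

NetDims make_dims(int n, const Rcpp::IntegerVector& convCh, int hidden) {
  NetDims d;
  int side = n;
  for (int l = 0; l + 1 < convCh.size(); ++l) {
    ConvDims c;
    c.cin = convCh[l];
    c.cout = convCh[l + 1];
    c.nin = side;
    if (side % 2 != 0 && side != 3)
      Rcpp::stop("spatial side must halve cleanly through the conv stack");
    c.nout = side / 2;
    if (c.nout < 1) Rcpp::stop("too many conv layers for grid size");
    c.K = c.cin * 27;
    c.Min = c.nin * c.nin * c.nin;
    c.Mout = c.nout * c.nout * c.nout;
    d.conv.push_back(c);
    side = c.nout;
  }
  d.cLast = convCh[convCh.size() - 1];
  d.mLast = d.conv.back().Mout;
  d.feat = d.cLast * d.mLast;
  d.hidden = hidden;
  int off = 0;
  for (auto& c : d.conv) {
    d.convW.push_back(off); off += c.K * c.cout;
    d.convB.push_back(off); off += c.cout;
  }
  d.d1W = off; off += d.feat * hidden;
  d.d1B = off; off += hidden;
  d.d2W = off; off += hidden;
  d.d2B = off; off += 1;
  d.nParams = off;
  return d;
}

// Gather the 27-point stride-2 patches of A (cin x Min) into Cols (K x Mout).
void im2col(const mat& A, const ConvDims& c, mat& Cols) {
  Cols.zeros(c.K, c.Mout);
  const int n = c.nin, no = c.nout, cin = c.cin;
  for (int z = 0; z < no; ++z)
    for (int y = 0; y < no; ++y)
      for (int x = 0; x < no; ++x) {
        const int m = x + no * (y + no * z);
        double* colm = Cols.colptr(m);
        for (int dz = 0; dz < 3; ++dz) {
          const int iz = 2 * z + dz - 1;
          if (iz < 0 || iz >= n) continue;
          for (int dy = 0; dy < 3; ++dy) {
            const int iy = 2 * y + dy - 1;
            if (iy < 0 || iy >= n) continue;
            for (int dx = 0; dx < 3; ++dx) {
              const int ix = 2 * x + dx - 1;
              if (ix < 0 || ix >= n) continue;
              const int src = ix + n * (iy + n * iz);
              const int r = cin * (dx + 3 * (dy + 3 * dz));
              std::memcpy(colm + r, A.colptr(src), cin * sizeof(double));
            }
          }
        }
      }
}

// Scatter-add dCols (K x Mout) back onto the input layout (cin x Min).
void col2im(const mat& dCols, const ConvDims& c, mat& dA) {
  dA.zeros(c.cin, c.Min);
  const int n = c.nin, no = c.nout, cin = c.cin;
  for (int z = 0; z < no; ++z)
    for (int y = 0; y < no; ++y)
      for (int x = 0; x < no; ++x) {
        const int m = x + no * (y + no * z);
        const double* colm = dCols.colptr(m);
        for (int dz = 0; dz < 3; ++dz) {
          const int iz = 2 * z + dz - 1;
          if (iz < 0 || iz >= n) continue;
          for (int dy = 0; dy < 3; ++dy) {
            const int iy = 2 * y + dy - 1;
            if (iy < 0 || iy >= n) continue;
            for (int dx = 0; dx < 3; ++dx) {
              const int ix = 2 * x + dx - 1;
              if (ix < 0 || ix >= n) continue;
              const int dst = ix + n * (iy + n * iz);
              const int r = cin * (dx + 3 * (dy + 3 * dz));
              double* acc = dA.colptr(dst);
              for (int cc = 0; cc < cin; ++cc) acc[cc] += colm[r + cc];
            }
          }
        }
      }
}

struct Cache {
  std::vector<mat> act;   // act[0] = input, act[l+1] = post-ReLU conv output
  std::vector<mat> cols;  // im2col of act[l]
  vec g, hpre, h;
  double out;
};

double forward(const double* x, const double* p, const NetDims& d,
               Cache* cache) {
  const ConvDims& c0 = d.conv[0];
  // R layout channels-last -> (cin x M)
  mat A(c0.cin, c0.Min);
  for (int cc = 0; cc < c0.cin; ++cc)
    for (int m = 0; m < c0.Min; ++m)
      A(cc, m) = x[m + (size_t)c0.Min * cc];
  if (cache) { cache->act.clear(); cache->cols.clear(); cache->act.push_back(A); }

  mat Cols;
  for (size_t l = 0; l < d.conv.size(); ++l) {
    const ConvDims& c = d.conv[l];
    im2col(A, c, Cols);
    const mat W(const_cast<double*>(p + d.convW[l]), c.K, c.cout, false, true);
    const vec b(const_cast<double*>(p + d.convB[l]), c.cout, false, true);
    mat Out = W.t() * Cols;
    Out.each_col() += b;
    Out.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (cache) { cache->cols.push_back(Cols); cache->act.push_back(Out); }
    A = std::move(Out);
  }

  vec g = vectorise(A); // column-major: channel fastest, then position
  const mat W1(const_cast<double*>(p + d.d1W), d.feat, d.hidden, false, true);
  const vec b1(const_cast<double*>(p + d.d1B), d.hidden, false, true);
  const vec w2(const_cast<double*>(p + d.d2W), d.hidden, false, true);
  vec hpre = W1.t() * g + b1;
  vec h = hpre;
  h.transform([](double v) { return v > 0.0 ? v : 0.0; });
  double out = dot(w2, h) + p[d.d2B];
  if (cache) { cache->g = g; cache->hpre = hpre; cache->h = h; cache->out = out; }
  return out;
}

// Backpropagate d(out)/d(...) scaled by dout. Accumulates parameter
// gradients into pg (if non-null) and writes the input gradient into
// dInput (if non-null, R channels-last layout).
void backward(const Cache& cache, const double* p, const NetDims& d,
              double dout, double* pg, double* dInput) {
  const int L = (int)d.conv.size();
  const ConvDims& cl = d.conv[L - 1];

  vec dh = vec(const_cast<double*>(p + d.d2W), d.hidden, false, true) * dout;
  vec dhpre = dh;
  for (int i = 0; i < d.hidden; ++i)
    if (cache.hpre(i) <= 0.0) dhpre(i) = 0.0;
  if (pg) {
    for (int i = 0; i < d.hidden; ++i) pg[d.d2W + i] += cache.h(i) * dout;
    pg[d.d2B] += dout;
    for (int j = 0; j < d.hidden; ++j) {
      pg[d.d1B + j] += dhpre(j);
      const double dj = dhpre(j);
      if (dj != 0.0) {
        double* pw = pg + d.d1W + (size_t)d.feat * j;
        const double* gp = cache.g.memptr();
        for (int i = 0; i < d.feat; ++i) pw[i] += gp[i] * dj;
      }
    }
  }
  const mat W1(const_cast<double*>(p + d.d1W), d.feat, d.hidden, false, true);
  vec dg = W1 * dhpre;
  mat dA(dg.memptr(), d.cLast, cl.Mout); // copies into conv layout

  for (int l = L - 1; l >= 0; --l) {
    const ConvDims& c = d.conv[l];
    // ReLU mask of this conv's output
    mat dOut = dA % (cache.act[l + 1] > 0);
    if (pg) {
      mat dW = cache.cols[l] * dOut.t();        // K x cout
      vec db = sum(dOut, 1);
      double* pw = pg + d.convW[l];
      const double* dwp = dW.memptr();
      for (size_t i = 0; i < (size_t)c.K * c.cout; ++i) pw[i] += dwp[i];
      for (int o = 0; o < c.cout; ++o) pg[d.convB[l] + o] += db(o);
    }
    const bool needInput = (l > 0) || (dInput != nullptr);
    if (!needInput) break;
    const mat W(const_cast<double*>(p + d.convW[l]), c.K, c.cout, false, true);
    mat dCols = W * dOut;
    mat dAl;
    col2im(dCols, c, dAl);
    if (l == 0) {
      for (int cc = 0; cc < c.cin; ++cc)
        for (int m = 0; m < c.Min; ++m)
          dInput[m + (size_t)c.Min * cc] = dAl(cc, m);
    } else {
      dA = std::move(dAl);
    }
  }
}

double softplus(double z) {
  if (z > 30.0) return z;
  if (z < -30.0) return 0.0;
  return std::log1p(std::exp(z));
}

double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

} // namespace

// [[Rcpp::export]]
double cnn_forward_cpp(Rcpp::NumericVector x, Rcpp::NumericVector params,
                       int n, Rcpp::IntegerVector convCh, int hidden) {
  NetDims d = make_dims(n, convCh, hidden);
  if ((int)params.size() != d.nParams) Rcpp::stop("parameter vector length mismatch");
  return forward(x.begin(), params.begin(), d, nullptr);
}

// [[Rcpp::export]]
int cnn_n_params_cpp(int n, Rcpp::IntegerVector convCh, int hidden) {
  return make_dims(n, convCh, hidden).nParams;
}

// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::NumericVector x, Rcpp::NumericVector params,
                        int n, Rcpp::IntegerVector convCh, int hidden,
                        bool inputGrad, bool paramGrad) {
  NetDims d = make_dims(n, convCh, hidden);
  if ((int)params.size() != d.nParams) Rcpp::stop("parameter vector length mismatch");
  Cache cache;
  double out = forward(x.begin(), params.begin(), d, &cache);
  Rcpp::NumericVector gin, gpar;
  double* gi = nullptr; double* gp = nullptr;
  if (inputGrad) { gin = Rcpp::NumericVector(x.size()); gi = gin.begin(); }
  if (paramGrad) { gpar = Rcpp::NumericVector(d.nParams); gp = gpar.begin(); }
  backward(cache, params.begin(), d, 1.0, gp, gi);
  return Rcpp::List::create(Rcpp::Named("output") = out,
                            Rcpp::Named("inputGrad") = gin,
                            Rcpp::Named("paramGrad") = gpar);
}

// Mean-over-steps input gradient along a straight path from baseline to x,
// evaluated at midpoint nodes; the quadrature core of Integrated Gradients.
// [[Rcpp::export]]
Rcpp::List cnn_path_grad_cpp(Rcpp::NumericVector x, Rcpp::NumericVector baseline,
                             Rcpp::NumericVector params, int n,
                             Rcpp::IntegerVector convCh, int hidden, int steps) {
  NetDims d = make_dims(n, convCh, hidden);
  if ((int)params.size() != d.nParams) Rcpp::stop("parameter vector length mismatch");
  const size_t D = x.size();
  std::vector<double> xi(D), gi(D);
  std::vector<double> gsum(D, 0.0);
  Rcpp::NumericVector outs(steps);
  for (int s = 0; s < steps; ++s) {
    const double a = (s + 0.5) / steps;
    for (size_t i = 0; i < D; ++i)
      xi[i] = baseline[i] + a * (x[i] - baseline[i]);
    Cache cache;
    outs[s] = forward(xi.data(), params.begin(), d, &cache);
    std::fill(gi.begin(), gi.end(), 0.0);
    backward(cache, params.begin(), d, 1.0, nullptr, gi.data());
    for (size_t i = 0; i < D; ++i) gsum[i] += gi[i];
  }
  Rcpp::NumericVector gmean(D);
  for (size_t i = 0; i < D; ++i) gmean[i] = gsum[i] / steps;
  return Rcpp::List::create(Rcpp::Named("meanGrad") = gmean,
                            Rcpp::Named("outputs") = outs);
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_forward_batch_cpp(Rcpp::NumericMatrix X,
                                          Rcpp::NumericVector params, int n,
                                          Rcpp::IntegerVector convCh, int hidden) {
  NetDims d = make_dims(n, convCh, hidden);
  const int m = X.ncol();
  Rcpp::NumericVector out(m);
  for (int j = 0; j < m; ++j)
    out[j] = forward(&X(0, j), params.begin(), d, nullptr);
  return out;
}

// Adam training with early stopping on validation loss (5% relative
// min-delta, patience epochs, a warmup of minEpochs during which stopping
// cannot trigger); the best-validation parameters are returned. X/Xval
// columns are samples (channels-last flattened grids). task: "class"
// (logistic loss on the logit) or "reg" (0.5 squared error).
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericMatrix X, Rcpp::NumericVector y,
                         Rcpp::NumericMatrix Xval, Rcpp::NumericVector yval,
                         Rcpp::NumericVector params0, int n,
                         Rcpp::IntegerVector convCh, int hidden,
                         std::string task, int epochs, int batch, double lr,
                         int patience, int minEpochs, int seed) {
  NetDims d = make_dims(n, convCh, hidden);
  if ((int)params0.size() != d.nParams) Rcpp::stop("parameter vector length mismatch");
  const int ntr = X.ncol(), nval = Xval.ncol();
  const bool classif = (task == "class");

  std::vector<double> p(params0.begin(), params0.end());
  std::vector<double> g(d.nParams), mAdam(d.nParams, 0.0), vAdam(d.nParams, 0.0);
  std::vector<double> best(p);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tAdam = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(ntr);
  for (int i = 0; i < ntr; ++i) idx[i] = i;

  Rcpp::NumericVector trainLoss, valLoss;
  double bestVal = std::numeric_limits<double>::infinity();
  int bestEpoch = 0, sinceBest = 0, epochsRun = 0;
  bool diverged = false;

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double lsum = 0.0;
    for (int start = 0; start < ntr; start += batch) {
      const int bend = std::min(start + batch, ntr);
      const int bs = bend - start;
      std::fill(g.begin(), g.end(), 0.0);
      for (int b = start; b < bend; ++b) {
        const int j = idx[b];
        Cache cache;
        const double z = forward(&X(0, j), p.data(), d, &cache);
        double loss, dz;
        if (classif) {
          loss = softplus(z) - y[j] * z;
          dz = sigmoid(z) - y[j];
        } else {
          const double r = z - y[j];
          loss = 0.5 * r * r;
          dz = r;
        }
        lsum += loss;
        backward(cache, p.data(), d, dz / bs, g.data(), nullptr);
      }
      ++tAdam;
      const double corr = std::sqrt(1.0 - std::pow(b2, (double)tAdam)) /
                          (1.0 - std::pow(b1, (double)tAdam));
      for (int i = 0; i < d.nParams; ++i) {
        mAdam[i] = b1 * mAdam[i] + (1 - b1) * g[i];
        vAdam[i] = b2 * vAdam[i] + (1 - b2) * g[i] * g[i];
        p[i] -= lr * corr * mAdam[i] / (std::sqrt(vAdam[i]) + eps);
      }
    }
    const double trl = lsum / ntr;
    if (!std::isfinite(trl)) { diverged = true; }
    trainLoss.push_back(trl);

    double vsum = 0.0;
    for (int j = 0; j < nval; ++j) {
      const double z = forward(&Xval(0, j), p.data(), d, nullptr);
      if (classif) vsum += softplus(z) - yval[j] * z;
      else { const double r = z - yval[j]; vsum += 0.5 * r * r; }
    }
    const double vl = nval > 0 ? vsum / nval : trl;
    if (!std::isfinite(vl)) diverged = true;
    valLoss.push_back(vl);
    epochsRun = ep + 1;

    const bool improved = !diverged &&
      (!std::isfinite(bestVal) ||
       vl < bestVal - std::max(1e-6, 0.05 * bestVal));
    if (improved) {
      bestVal = vl; bestEpoch = ep + 1; best = p; sinceBest = 0;
    } else {
      if (!diverged && vl < bestVal) { bestVal = vl; bestEpoch = ep + 1; best = p; }
      ++sinceBest;
      if (ep + 1 >= minEpochs && sinceBest >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::NumericVector(best.begin(), best.end()),
      Rcpp::Named("trainLoss") = trainLoss,
      Rcpp::Named("valLoss") = valLoss,
      Rcpp::Named("bestEpoch") = bestEpoch,
      Rcpp::Named("epochsRun") = epochsRun,
      Rcpp::Named("bestValLoss") = bestVal,
      Rcpp::Named("diverged") = diverged);
}
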