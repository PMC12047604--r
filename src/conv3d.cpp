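// 3D convolutional network primitives for lesion-map regression.
//
// Volumes are passed as column vectors of length d1*d2*d3 (R array
// column-major order, x fastest). Convolutions are 3x3x3, zero padded
// ("same"), realised as an im2col gather followed by a BLAS matrix
// product; the backward pass mirrors this with a scatter-add.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// neighbour table: for every voxel the 27 linear indices of its 3x3x3
// neighbourhood, -1 outside the grid
static Mat<long long> neighbor_table(int d1, int d2, int d3) {
  const long long n = (long long)d1 * d2 * d3;
  Mat<long long> N(n, 27);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        long long v = x + (long long)y * d1 + (long long)z * d1 * d2;
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              N(v, k++) =
                (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 ||
                 zz >= d3)
                  ? -1
                  : xx + (long long)yy * d1 + (long long)zz * d1 * d2;
            }
      }
  return N;
}

// gather H (nvox x C) into the im2col matrix A (nvox x C*27)
static mat im2col(const mat& H, const Mat<long long>& N) {
  const uword n = H.n_rows, C = H.n_cols;
  mat A(n, C * 27, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const double* h = H.colptr(c);
    for (int k = 0; k < 27; ++k) {
      double* a = A.colptr(c * 27 + k);
      const long long* nb = N.colptr(k);
      for (uword v = 0; v < n; ++v)
        if (nb[v] >= 0) a[v] = h[nb[v]];
    }
  }
  return A;
}

// scatter-add dA (nvox x C*27) back onto dH (nvox x C)
static void col2im_add(const mat& dA, const Mat<long long>& N, mat& dH) {
  const uword n = dH.n_rows, C = dH.n_cols;
  for (uword c = 0; c < C; ++c) {
    double* h = dH.colptr(c);
    for (int k = 0; k < 27; ++k) {
      const double* a = dA.colptr(c * 27 + k);
      const long long* nb = N.colptr(k);
      for (uword v = 0; v < n; ++v)
        if (nb[v] >= 0) h[nb[v]] += a[v];
    }
  }
}

// 2x2x2 max pooling (ceil dims); records argmax source indices
static mat maxpool(const mat& H, int d1, int d2, int d3,
                   Mat<long long>& arg, int& p1, int& p2, int& p3) {
  p1 = (d1 + 1) / 2; p2 = (d2 + 1) / 2; p3 = (d3 + 1) / 2;
  const long long np = (long long)p1 * p2 * p3;
  const uword C = H.n_cols;
  mat P(np, C);
  arg.set_size(np, C);
  for (uword c = 0; c < C; ++c) {
    const double* h = H.colptr(c);
    for (int z = 0; z < p3; ++z)
      for (int y = 0; y < p2; ++y)
        for (int x = 0; x < p1; ++x) {
          long long o = x + (long long)y * p1 + (long long)z * p1 * p2;
          double best = -datum::inf; long long bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int xx = 2 * x + dx, yy = 2 * y + dy, zz = 2 * z + dz;
                if (xx >= d1 || yy >= d2 || zz >= d3) continue;
                long long i =
                  xx + (long long)yy * d1 + (long long)zz * d1 * d2;
                if (h[i] > best) { best = h[i]; bi = i; }
              }
          P(o, c) = best;
          arg(o, c) = bi;
        }
  }
  return P;
}

struct NetParams {
  mat W1, W2;      // (Cin*27 x C1), (C1*27 x C2)
  rowvec b1, b2;   // conv biases
  mat Wl1;         // flatten -> (1 or hidden)
  vec bl1;
  mat Wl2;         // hidden -> 1 (regularized only)
  double bl2;
  bool regularized;
};

static NetParams unpack(const Rcpp::List& params, bool regularized) {
  NetParams P;
  P.W1 = Rcpp::as<mat>(params["W1"]);
  P.b1 = Rcpp::as<rowvec>(params["b1"]);
  P.W2 = Rcpp::as<mat>(params["W2"]);
  P.b2 = Rcpp::as<rowvec>(params["b2"]);
  P.Wl1 = Rcpp::as<mat>(params["Wl1"]);
  P.bl1 = Rcpp::as<vec>(params["bl1"]);
  P.regularized = regularized;
  if (regularized) {
    P.Wl2 = Rcpp::as<mat>(params["Wl2"]);
    P.bl2 = Rcpp::as<double>(params["bl2"]);
  } else {
    P.bl2 = 0;
  }
  return P;
}

// forward one sample; optionally keep intermediates for backprop.
struct Cache {
  mat A1, H1, A2, H2;       // im2col inputs and post-ReLU activations
  mat P1;                   // post-pool1 activations (regularized)
  Mat<long long> arg1, arg2;
  vec flat, z1, r1;
  umat m1, m2;              // ReLU masks
};

static double forward_one(const vec& x, const NetParams& P,
                          const Mat<long long>& N0,
                          const Mat<long long>& N1, int d1, int d2, int d3,
                          const vec* drop1, const vec* drop2, Cache* C) {
  mat H0(x);                              // nvox x 1
  mat A1 = im2col(H0, N0);
  mat Z1 = A1 * P.W1;
  Z1.each_row() += P.b1;
  umat m1 = Z1 > 0;
  mat H1 = Z1 % conv_to<mat>::from(m1);   // ReLU
  if (drop1) H1.each_col() %= *drop1;

  int p1 = d1, p2 = d2, p3 = d3;
  Mat<long long> arg1;
  mat Hp1 = H1;
  if (P.regularized) Hp1 = maxpool(H1, d1, d2, d3, arg1, p1, p2, p3);

  mat A2 = im2col(Hp1, N1);  // N1 is the pooled-grid table when pooling
  mat Z2 = A2 * P.W2;
  Z2.each_row() += P.b2;
  umat m2 = Z2 > 0;
  mat H2 = Z2 % conv_to<mat>::from(m2);
  if (drop2) H2.each_col() %= *drop2;

  int q1 = p1, q2 = p2, q3 = p3;
  Mat<long long> arg2;
  mat Hp2 = H2;
  if (P.regularized) Hp2 = maxpool(H2, p1, p2, p3, arg2, q1, q2, q3);

  vec flat = vectorise(Hp2);
  double out;
  vec z1, r1;
  if (P.regularized) {
    z1 = P.Wl1.t() * flat + P.bl1;
    r1 = clamp(z1, 0.0, datum::inf);
    out = dot(r1, P.Wl2.col(0)) + P.bl2;
  } else {
    out = dot(flat, P.Wl1.col(0)) + P.bl1(0);
  }
  if (C) {
    C->A1 = std::move(A1); C->H1 = std::move(H1);
    C->A2 = std::move(A2); C->H2 = std::move(H2);
    C->P1 = std::move(Hp1);
    C->arg1 = std::move(arg1); C->arg2 = std::move(arg2);
    C->flat = std::move(flat); C->z1 = std::move(z1);
    C->r1 = std::move(r1); C->m1 = std::move(m1); C->m2 = std::move(m2);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_forward")]]
arma::vec cnn_forward_cpp(const arma::mat& X, Rcpp::IntegerVector dims,
                          Rcpp::List params, bool regularized) {
  NetParams P = unpack(params, regularized);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  Mat<long long> N0 = neighbor_table(d1, d2, d3);
  Mat<long long> N1 = regularized
    ? neighbor_table((d1 + 1) / 2, (d2 + 1) / 2, (d3 + 1) / 2)
    : N0;
  vec out(X.n_cols);
  for (uword j = 0; j < X.n_cols; ++j)
    out(j) = forward_one(X.col(j), P, N0, N1, d1, d2, d3, nullptr, nullptr,
                         nullptr);
  return out;
}

// forward + backward over a batch; returns predictions, loss and
// parameter gradients (averaged over the batch).
// lossType: 0 = MSE, 1 = 2*MSE + L1 (both on prediction error)
// [[Rcpp::export(name = ".cnn_train_batch")]]
Rcpp::List cnn_train_batch_cpp(const arma::mat& X, const arma::vec& y,
                               Rcpp::IntegerVector dims, Rcpp::List params,
                               bool regularized, int lossType,
                               Rcpp::Nullable<Rcpp::NumericMatrix> dropMask1,
                               Rcpp::Nullable<Rcpp::NumericMatrix> dropMask2) {
  NetParams P = unpack(params, regularized);
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  Mat<long long> N0 = neighbor_table(d1, d2, d3);
  int p1 = (d1 + 1) / 2, p2 = (d2 + 1) / 2, p3 = (d3 + 1) / 2;
  Mat<long long> N1 =
    regularized ? neighbor_table(p1, p2, p3) : N0;

  mat dm1, dm2;
  bool useDrop = dropMask1.isNotNull();
  if (useDrop) {
    dm1 = Rcpp::as<mat>(dropMask1);
    dm2 = Rcpp::as<mat>(dropMask2);
  }

  const uword B = X.n_cols;
  mat gW1(size(P.W1), fill::zeros), gW2(size(P.W2), fill::zeros);
  rowvec gb1(P.b1.n_elem, fill::zeros), gb2(P.b2.n_elem, fill::zeros);
  mat gWl1(size(P.Wl1), fill::zeros), gWl2;
  vec gbl1(P.bl1.n_elem, fill::zeros);
  double gbl2 = 0;
  if (regularized) gWl2.zeros(size(P.Wl2));

  vec pred(B);
  double loss = 0;
  for (uword j = 0; j < B; ++j) {
    Cache C;
    vec dcol1, dcol2;
    const vec* dp1 = nullptr; const vec* dp2 = nullptr;
    if (useDrop) {
      dcol1 = dm1.col(j); dcol2 = dm2.col(j);
      dp1 = &dcol1; dp2 = &dcol2;
    }
    double out = forward_one(X.col(j), P, N0, N1, d1, d2, d3, dp1, dp2, &C);
    pred(j) = out;
    double e = out - y(j);
    double dout;
    if (lossType == 1) {
      loss += (2.0 * e * e + std::abs(e)) / B;
      dout = (4.0 * e + (e > 0 ? 1.0 : (e < 0 ? -1.0 : 0.0))) / B;
    } else {
      loss += e * e / B;
      dout = 2.0 * e / B;
    }

    // ---- backward ----
    vec dflat;
    if (regularized) {
      vec dr1 = P.Wl2.col(0) * dout;
      gWl2.col(0) += C.r1 * dout;
      gbl2 += dout;
      vec dz1 = dr1 % conv_to<vec>::from(C.z1 > 0);
      gWl1 += C.flat * dz1.t();
      gbl1 += dz1;
      dflat = P.Wl1 * dz1;
    } else {
      gWl1.col(0) += C.flat * dout;
      gbl1(0) += dout;
      dflat = P.Wl1.col(0) * dout;
    }

    // un-flatten to post-(pool2|conv2) activations
    uword C2 = P.b2.n_elem;
    mat dHp2(dflat.memptr(), dflat.n_elem / C2, C2);

    mat dH2;
    if (regularized) {
      dH2.zeros(C.H2.n_rows, C2);
      for (uword c = 0; c < C2; ++c)
        for (uword o = 0; o < dHp2.n_rows; ++o)
          dH2(C.arg2(o, c), c) += dHp2(o, c);
    } else {
      dH2 = dHp2;
    }
    if (useDrop) dH2.each_col() %= dcol2;
    mat dZ2 = dH2 % conv_to<mat>::from(C.m2);
    gW2 += C.A2.t() * dZ2;
    gb2 += sum(dZ2, 0);
    mat dA2 = dZ2 * P.W2.t();
    mat dHp1(C.P1.n_rows, C.P1.n_cols, fill::zeros);
    col2im_add(dA2, regularized ? N1 : N0, dHp1);

    mat dH1;
    if (regularized) {
      dH1.zeros(C.H1.n_rows, C.H1.n_cols);
      for (uword c = 0; c < dHp1.n_cols; ++c)
        for (uword o = 0; o < dHp1.n_rows; ++o)
          dH1(C.arg1(o, c), c) += dHp1(o, c);
    } else {
      dH1 = dHp1;
    }
    if (useDrop) dH1.each_col() %= dcol1;
    mat dZ1 = dH1 % conv_to<mat>::from(C.m1);
    gW1 += C.A1.t() * dZ1;
    gb1 += sum(dZ1, 0);
    // gradient w.r.t. the input volume is not needed
  }

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("W1") = gW1, Rcpp::Named("b1") = gb1,
    Rcpp::Named("W2") = gW2, Rcpp::Named("b2") = gb2,
    Rcpp::Named("Wl1") = gWl1, Rcpp::Named("bl1") = gbl1);
  if (regularized) {
    grads["Wl2"] = gWl2;
    grads["bl2"] = gbl2;
  }
  return Rcpp::List::create(Rcpp::Named("pred") = pred,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
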