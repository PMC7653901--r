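// Stacked gated-recurrent-unit sequence regressor: forward pass and
// backpropagation through time. Layer widths are arbitrary; the package
// uses input 9 (one feature per conformal beam) -> hidden 18 -> 9 -> 1,
// with the final size-1 hidden-state sequence as the predicted curve.
//
// Gate equations (Cho formulation):
//   z_t = sigmoid(Wz x_t + Uz h_{t-1} + bz)
//   r_t = sigmoid(Wr x_t + Ur h_{t-1} + br)
//   n_t = tanh(Wn x_t + Un (r_t . h_{t-1}) + bn)
//   h_t = (1 - z_t) . n_t + z_t . h_{t-1},  h_0 = 0
//
// Parameters are passed as one flat vector; per-layer packing order is
// Wz, Wr, Wn (H x I, column-major), Uz, Ur, Un (H x H), bz, br, bn (H).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Layer {
  mat Wz, Wr, Wn, Uz, Ur, Un;
  vec bz, br, bn;
};

struct Cache {
  mat X;                 // layer input, T x I
  mat Z, R, N, Hs, HR;   // gate activations and states, T x H
};

static uword layer_param_count(uword I, uword H) {
  return 3 * H * I + 3 * H * H + 3 * H;
}

static std::vector<Layer> unpack(const vec& p, const ivec& sizes) {
  std::vector<Layer> layers;
  uword off = 0;
  for (uword l = 1; l < sizes.n_elem; ++l) {
    uword I = (uword)sizes(l - 1), H = (uword)sizes(l);
    Layer ly;
    ly.Wz = reshape(p.subvec(off, off + H * I - 1), H, I); off += H * I;
    ly.Wr = reshape(p.subvec(off, off + H * I - 1), H, I); off += H * I;
    ly.Wn = reshape(p.subvec(off, off + H * I - 1), H, I); off += H * I;
    ly.Uz = reshape(p.subvec(off, off + H * H - 1), H, H); off += H * H;
    ly.Ur = reshape(p.subvec(off, off + H * H - 1), H, H); off += H * H;
    ly.Un = reshape(p.subvec(off, off + H * H - 1), H, H); off += H * H;
    ly.bz = p.subvec(off, off + H - 1); off += H;
    ly.br = p.subvec(off, off + H - 1); off += H;
    ly.bn = p.subvec(off, off + H - 1); off += H;
    layers.push_back(std::move(ly));
  }
  if (off != p.n_elem) Rcpp::stop("parameter vector length does not match layer sizes");
  return layers;
}

static vec pack_grads(const std::vector<Layer>& g) {
  uword total = 0;
  for (const Layer& ly : g)
    total += layer_param_count(ly.Wz.n_cols, ly.bz.n_elem);
  vec out(total);
  uword off = 0;
  auto put_m = [&](const mat& M) { out.subvec(off, off + M.n_elem - 1) = vectorise(M); off += M.n_elem; };
  auto put_v = [&](const vec& v) { out.subvec(off, off + v.n_elem - 1) = v; off += v.n_elem; };
  for (const Layer& ly : g) {
    put_m(ly.Wz); put_m(ly.Wr); put_m(ly.Wn);
    put_m(ly.Uz); put_m(ly.Ur); put_m(ly.Un);
    put_v(ly.bz); put_v(ly.br); put_v(ly.bn);
  }
  return out;
}

static mat layer_forward(const Layer& ly, const mat& X, Cache* cache) {
  uword T = X.n_rows, H = ly.bz.n_elem;
  mat Hs(T, H), Z(T, H), R(T, H), N(T, H), HR(T, H);
  vec h(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec x = X.row(t).t();
    vec z = 1.0 / (1.0 + exp(-(ly.Wz * x + ly.Uz * h + ly.bz)));
    vec r = 1.0 / (1.0 + exp(-(ly.Wr * x + ly.Ur * h + ly.br)));
    vec hr = r % h;
    vec n = tanh(ly.Wn * x + ly.Un * hr + ly.bn);
    h = (1.0 - z) % n + z % h;
    Z.row(t) = z.t(); R.row(t) = r.t(); N.row(t) = n.t();
    HR.row(t) = hr.t(); Hs.row(t) = h.t();
  }
  if (cache) { cache->X = X; cache->Z = Z; cache->R = R; cache->N = N; cache->Hs = Hs; cache->HR = HR; }
  return Hs;
}

// returns gradient w.r.t. the layer input; accumulates parameter grads in g
static mat layer_backward(const Layer& ly, const Cache& c, const mat& dH, Layer& g) {
  uword T = c.X.n_rows, H = ly.bz.n_elem;
  mat dX(T, c.X.n_cols, fill::zeros);
  vec carry(H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    vec dh = dH.row(t).t() + carry;
    vec z = c.Z.row(t).t(), r = c.R.row(t).t(), n = c.N.row(t).t(), hr = c.HR.row(t).t();
    vec hprev = (t > 0) ? vec(c.Hs.row(t - 1).t()) : vec(H, fill::zeros);
    vec x = c.X.row(t).t();

    vec dz = dh % (hprev - n);
    vec dn = dh % (1.0 - z);
    carry = dh % z;

    vec dpn = dn % (1.0 - n % n);
    g.Wn += dpn * x.t();
    g.Un += dpn * hr.t();
    g.bn += dpn;
    dX.row(t) += (ly.Wn.t() * dpn).t();
    vec dhr = ly.Un.t() * dpn;
    vec dr = dhr % hprev;
    carry += dhr % r;

    vec dpz = dz % z % (1.0 - z);
    vec dpr = dr % r % (1.0 - r);
    g.Wz += dpz * x.t(); g.Uz += dpz * hprev.t(); g.bz += dpz;
    dX.row(t) += (ly.Wz.t() * dpz).t(); carry += ly.Uz.t() * dpz;
    g.Wr += dpr * x.t(); g.Ur += dpr * hprev.t(); g.br += dpr;
    dX.row(t) += (ly.Wr.t() * dpr).t(); carry += ly.Ur.t() * dpr;
  }
  return dX;
}

// [[Rcpp::export]]
arma::mat cpp_gru_forward(const arma::vec& params, const arma::ivec& sizes,
                          const arma::mat& X) {
  std::vector<Layer> layers = unpack(params, sizes);
  mat cur = X;
  for (const Layer& ly : layers) cur = layer_forward(ly, cur, nullptr);
  return cur;
}

// [[Rcpp::export]]
double cpp_gru_loss(const arma::vec& params, const arma::ivec& sizes,
                    const Rcpp::List& X_list, const Rcpp::List& Y_list) {
  std::vector<Layer> layers = unpack(params, sizes);
  double sse = 0.0;
  uword count = 0;
  for (int s = 0; s < X_list.size(); ++s) {
    mat X = Rcpp::as<mat>(X_list[s]);
    vec y = Rcpp::as<vec>(Y_list[s]);
    mat cur = X;
    for (const Layer& ly : layers) cur = layer_forward(ly, cur, nullptr);
    vec diff = cur.col(0) - y;
    sse += dot(diff, diff);
    count += y.n_elem;
  }
  return sse / (double)count;
}

// Mean squared error over all curve points in the batch, and its gradient
// with respect to the flat parameter vector.
// [[Rcpp::export]]
Rcpp::List cpp_gru_grad(const arma::vec& params, const arma::ivec& sizes,
                        const Rcpp::List& X_list, const Rcpp::List& Y_list) {
  std::vector<Layer> layers = unpack(params, sizes);
  uword L = layers.size();
  std::vector<Layer> grads(L);
  for (uword l = 0; l < L; ++l) {
    const Layer& ly = layers[l];
    Layer g;
    g.Wz = zeros<mat>(size(ly.Wz)); g.Wr = zeros<mat>(size(ly.Wr)); g.Wn = zeros<mat>(size(ly.Wn));
    g.Uz = zeros<mat>(size(ly.Uz)); g.Ur = zeros<mat>(size(ly.Ur)); g.Un = zeros<mat>(size(ly.Un));
    g.bz = zeros<vec>(ly.bz.n_elem); g.br = zeros<vec>(ly.br.n_elem); g.bn = zeros<vec>(ly.bn.n_elem);
    grads[l] = std::move(g);
  }

  uword count = 0;
  for (int s = 0; s < X_list.size(); ++s)
    count += Rcpp::as<vec>(Y_list[s]).n_elem;

  double sse = 0.0;
  for (int s = 0; s < X_list.size(); ++s) {
    mat X = Rcpp::as<mat>(X_list[s]);
    vec y = Rcpp::as<vec>(Y_list[s]);
    std::vector<Cache> caches(L);
    mat cur = X;
    for (uword l = 0; l < L; ++l) cur = layer_forward(layers[l], cur, &caches[l]);
    vec diff = cur.col(0) - y;
    sse += dot(diff, diff);
    mat dH(cur.n_rows, cur.n_cols, fill::zeros);
    dH.col(0) = 2.0 * diff / (double)count;
    for (uword l = L; l-- > 0;)
      dH = layer_backward(layers[l], caches[l], dH, grads[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = sse / (double)count,
    Rcpp::Named("grad") = pack_grads(grads)
  );
}

// [[Rcpp::export]]
int cpp_gru_n_params(const arma::ivec& sizes) {
  uword total = 0;
  for (uword l = 1; l < sizes.n_elem; ++l)
    total += layer_param_count((uword)sizes(l - 1), (uword)sizes(l));
  return (int)total;
}
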