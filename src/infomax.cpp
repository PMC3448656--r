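#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Natural-gradient logistic Infomax (Bell-Sejnowski) on sphered data.
//
// Block updates W <- W + lr * (I + (1 - 2y) u') W with y = logistic(u),
// EEGLAB-style annealing: when the angle between successive weight
// changes exceeds annealdeg the learning rate is multiplied by
// annealstep.  Sample order is re-permuted each pass with a local
// xorshift generator so results are bit-reproducible for a given seed
// regardless of R's RNG state.

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s;
}

static void permute_order(arma::uvec &ord, uint64_t &state) {
  const arma::uword n = ord.n_elem;
  for (arma::uword i = n - 1; i > 0; --i) {
    arma::uword j = static_cast<arma::uword>(xorshift64(state) % (i + 1));
    std::swap(ord[i], ord[j]);
  }
}

// [[Rcpp::export(name = ".infomax_core")]]
Rcpp::List infomax_core(const arma::mat &X, int seed,
                        int block = 0, double lrate = 0.0,
                        double annealdeg = 60.0, double annealstep = 0.9,
                        double tol = 1e-6, int max_iter = 512) {
  const arma::uword k = X.n_rows, n = X.n_cols;
  if (block <= 0)
    block = std::min<arma::uword>(n, (arma::uword)std::ceil(
        std::min(256.0, 5.0 * std::sqrt((double)n))));
  if (lrate <= 0.0) lrate = 0.00065 / std::log((double)k) * 10.0;

  arma::mat W = arma::eye(k, k);
  arma::mat oldW = W, prev_dW(k, k, arma::fill::zeros);
  arma::mat I = arma::eye(k, k);
  uint64_t state = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(seed + 1);
  arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);

  const double wchange_floor = tol;
  bool converged = false;
  int iter = 0;
  double change = arma::datum::inf;

  for (iter = 1; iter <= max_iter; ++iter) {
    permute_order(ord, state);
    bool blowup = false;
    for (arma::uword start = 0; start + block <= n; start += block) {
      arma::mat xb = X.cols(ord.subvec(start, start + block - 1));
      arma::mat u = W * xb;
      arma::mat y = 1.0 / (1.0 + arma::exp(-u));
      arma::mat dW = lrate * ((double)block * I + (1.0 - 2.0 * y) * u.t()) * W;
      W += dW;
      if (!W.is_finite() || arma::abs(W).max() > 1e8) { blowup = true; break; }
    }
    if (blowup) {
      W = arma::eye(k, k); oldW = W; prev_dW.zeros();
      lrate *= 0.5; change = arma::datum::inf;
      if (lrate < 1e-12) break;
      continue;
    }
    arma::mat dW = W - oldW;
    change = arma::accu(dW % dW);
    if (iter > 1) {
      double denom = std::sqrt(arma::accu(dW % dW) * arma::accu(prev_dW % prev_dW));
      if (denom > 0) {
        double cosang = arma::accu(dW % prev_dW) / denom;
        cosang = std::max(-1.0, std::min(1.0, cosang));
        double ang = std::acos(cosang) * 180.0 / arma::datum::pi;
        if (ang > annealdeg) lrate *= annealstep;
      }
    }
    prev_dW = dW;
    oldW = W;
    if (change < wchange_floor) { converged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("final_change") = change,
                            Rcpp::Named("lrate") = lrate);
}
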