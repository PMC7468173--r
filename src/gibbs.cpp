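// Gibbs sampler core for the random regression test-day model.
//
// Blocked single-pass Gibbs: each sweep draws every effect block (scalar
// fixed-effect levels, per-animal additive-genetic coefficient vectors,
// per-cow permanent-environmental vectors) from its Gaussian full
// conditional by iteration on data, then the (co)variance components from
// their inverted-Wishart / scaled inverse-chi-square conditionals. Residuals
// e = y - W theta are maintained incrementally. The observation structure is
// gathered into dense per-block row sets once up front (the sparsity pattern
// never changes over the chain); only the variance components re-weight it.
// All randomness comes from R's RNG so chains are reproducible from
// set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

// Inverted-Wishart draw via Bartlett decomposition: G ~ IW(S, df).
static arma::mat riw(const arma::mat& S, double df) {
  const int K = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(K, K, arma::fill::zeros);
  for (int i = 0; i < K; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat X = L * A;             // chol factor of Wishart(df, Sinv) draw
  arma::mat W = X * X.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export]]
arma::mat rinvwishart_cpp(double df, const arma::mat& S) {
  if (df <= S.n_rows - 1.0)
    stop("inverted-Wishart df must exceed dimension - 1");
  return riw(S, df);
}

// [[Rcpp::export]]
List gibbs_chain_cpp(const S4 W, const arma::vec& y,
                     const arma::ivec& stratum, int n_strata,
                     const S4 Ainv, const IntegerVector block_start,
                     const IntegerVector block_size,
                     const IntegerVector block_type,
                     const IntegerVector block_index,
                     const IntegerVector block_start2,
                     const IntegerVector block_index2,
                     arma::mat G0, arma::mat P0, arma::vec Rv,
                     int n_animals, int n_cows,
                     int chain, int burn_in, int thin,
                     double g0_df0, const arma::mat& g0_scale,
                     double p0_df0, const arma::mat& p0_scale,
                     double r_df0, const arma::vec& r_scale,
                     bool update_g0, bool update_p0, bool update_r,
                     bool store_theta) {
  // CSC slots of the observation matrix (n_obs x n_eq)
  const IntegerVector Wp = W.slot("p"), Wi = W.slot("i");
  const NumericVector Wx = W.slot("x");
  const IntegerVector Wdim = W.slot("Dim");
  const int n_obs = Wdim[0], n_eq = Wdim[1];
  // CSC slots of A-inverse (general matrix, both triangles)
  const IntegerVector Ap = Ainv.slot("p"), Ai = Ainv.slot("i");
  const NumericVector Ax = Ainv.slot("x");

  const int K = G0.n_rows;
  const int n_blocks = block_start.size();
  // equation offsets of the AG and PE regions from the block table
  int ag_off = n_eq, pe_off = n_eq;
  for (int b = 0; b < n_blocks; ++b) {
    if ((block_type[b] == 1 || block_type[b] == 3) &&
        block_start[b] - K * (block_index[b]) < ag_off)
      ag_off = block_start[b] - K * block_index[b];
    if (block_type[b] == 2 && block_start[b] - K * block_index[b] < pe_off)
      pe_off = block_start[b] - K * block_index[b];
    if (block_type[b] == 3 && block_start2[b] - K * block_index2[b] < pe_off)
      pe_off = block_start2[b] - K * block_index2[b];
  }

  // ---- one-off gather: per block, its observation rows and dense
  //      incidence sub-matrix
  std::vector<arma::uvec> brows(n_blocks);
  std::vector<arma::mat> bW(n_blocks);
  {
    std::vector<int> rowpos(n_obs, -1);
    std::vector<std::vector<int>> rws(n_blocks);
    std::vector<std::vector<double>> wvals(n_blocks);
    for (int b = 0; b < n_blocks; ++b) {
      const int c0 = block_start[b];
      const int bs = (block_type[b] == 3) ? 2 * block_size[b]
                                          : block_size[b];
      std::vector<int>& rv = rws[b];
      std::vector<double>& wv = wvals[b];
      for (int j = 0; j < bs; ++j) {
        const int col = (j < block_size[b])
          ? c0 + j : block_start2[b] + (j - block_size[b]);
        for (int q = Wp[col]; q < Wp[col + 1]; ++q) {
          const int r = Wi[q];
          if (Wx[q] == 0.0) continue;
          int slot = rowpos[r];
          if (slot < 0) {
            slot = rv.size();
            rv.push_back(r);
            rowpos[r] = slot;
            wv.resize(wv.size() + bs, 0.0);
          }
          wv[slot * bs + j] += Wx[q];
        }
      }
      for (size_t s = 0; s < rv.size(); ++s) rowpos[rv[s]] = -1;
      brows[b] = arma::uvec(rv.size());
      bW[b] = arma::mat(rv.size(), bs);
      for (size_t s = 0; s < rv.size(); ++s) {
        brows[b](s) = rv[s];
        for (int j = 0; j < bs; ++j) bW[b](s, j) = wv[s * bs + j];
      }
    }
  }

  // scatter/gather for blocks that span the AG and PE regions
  auto block_cols = [&](int b) {
    const int half = block_size[b];
    const int tot = (block_type[b] == 3) ? 2 * half : half;
    arma::uvec cols(tot);
    for (int j = 0; j < tot; ++j)
      cols(j) = (j < half) ? block_start[b] + j
                           : block_start2[b] + (j - half);
    return cols;
  };

  arma::vec theta(n_eq, arma::fill::zeros);
  arma::vec e = y;                  // residuals at theta = 0
  arma::mat G0inv = arma::inv_sympd(G0);
  arma::mat P0inv = arma::inv_sympd(P0);

  arma::vec n_strat(n_strata, arma::fill::zeros);
  for (int r = 0; r < n_obs; ++r) n_strat(stratum(r)) += 1.0;

  const int n_store = (chain > burn_in) ? (chain - burn_in) / thin : 0;
  arma::cube G0_draws(K, K, std::max(n_store, 1));
  arma::cube P0_draws(K, K, std::max(n_store, 1));
  arma::mat R_draws(std::max(n_store, 1), n_strata);
  arma::mat theta_draws(store_theta ? n_eq : 1,
                        store_theta ? std::max(n_store, 1) : 1,
                        arma::fill::zeros);
  arma::vec theta_sum(n_eq, arma::fill::zeros);

  int stored = 0;
  for (int it = 1; it <= chain; ++it) {
    // ---- location sweep
    for (int b = 0; b < n_blocks; ++b) {
      const int half = block_size[b];
      const int bs = (block_type[b] == 3) ? 2 * half : half;
      const arma::uvec& rows = brows[b];
      const arma::mat& Wb = bW[b];
      const int nr = rows.n_elem;
      if (nr == 0 && block_type[b] == 0) continue;  // no data, no prior

      const arma::uvec cols = block_cols(b);
      arma::vec th_old = theta.elem(cols);
      arma::mat Cb(bs, bs, arma::fill::zeros);
      arma::vec rb(bs, arma::fill::zeros);
      if (nr > 0) {
        arma::vec wgt(nr), eadj(nr);
        for (int s = 0; s < nr; ++s) {
          const arma::uword r = rows(s);
          wgt(s) = 1.0 / Rv(stratum(r));
          eadj(s) = e(r);
        }
        arma::mat Wt = Wb.each_col() % wgt;   // weighted rows
        Cb = Wt.t() * Wb;
        rb = Wt.t() * eadj + Cb * th_old;
      }

      if (block_type[b] == 1 || block_type[b] == 3) {
        // AG part: pedigree prior over the first `half` coordinates
        const int ia = block_index[b];
        for (int q = Ap[ia]; q < Ap[ia + 1]; ++q) {
          const int j = Ai[q];
          const double v = Ax[q];
          if (j == ia) {
            Cb.submat(0, 0, half - 1, half - 1) += v * G0inv;
          } else {
            rb.subvec(0, half - 1) -=
              v * (G0inv *
                   theta.subvec(ag_off + j * K, ag_off + (j + 1) * K - 1));
          }
        }
      }
      if (block_type[b] == 2) {            // pure PE block
        Cb += P0inv;
      } else if (block_type[b] == 3) {     // PE part of a joint cow block
        Cb.submat(half, half, bs - 1, bs - 1) += P0inv;
      }

      arma::mat U;
      if (!arma::chol(U, Cb)) {
        Cb.diag() += 1e-8 * (arma::trace(Cb) / bs + 1.0);
        if (!arma::chol(U, Cb))
          stop("non-SPD full conditional in location sweep (block %d)", b + 1);
      }
      arma::vec mu = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), rb));
      arma::vec z(bs);
      for (int j = 0; j < bs; ++j) z(j) = R::norm_rand();
      arma::vec th_new = mu + arma::solve(arma::trimatu(U), z);

      if (nr > 0) {
        arma::vec shift = Wb * (th_new - th_old);
        for (int s = 0; s < nr; ++s) e(rows(s)) -= shift(s);
      }
      theta.elem(cols) = th_new;
    }

    // ---- G0 | a : IW(M' Ainv M + S0, n_animals + df0)
    if (update_g0) {
      arma::mat S = g0_scale;
      for (int jc = 0; jc < n_animals; ++jc) {
        arma::vec aj = theta.subvec(ag_off + jc * K, ag_off + (jc + 1) * K - 1);
        for (int q = Ap[jc]; q < Ap[jc + 1]; ++q) {
          const int ir = Ai[q];
          arma::vec ai = theta.subvec(ag_off + ir * K,
                                      ag_off + (ir + 1) * K - 1);
          S += Ax[q] * (ai * aj.t());
        }
      }
      G0 = riw(arma::symmatu(0.5 * (S + S.t())), n_animals + g0_df0);
      G0inv = arma::inv_sympd(G0);
    }

    // ---- P0 | p : IW(P'P + S0, n_cows + df0)
    if (update_p0) {
      arma::mat S = p0_scale;
      for (int c = 0; c < n_cows; ++c) {
        arma::vec pc = theta.subvec(pe_off + c * K, pe_off + (c + 1) * K - 1);
        S += pc * pc.t();
      }
      P0 = riw(arma::symmatu(0.5 * (S + S.t())), n_cows + p0_df0);
      P0inv = arma::inv_sympd(P0);
    }

    // ---- R | e : per-stratum scaled inverse-chi-square
    if (update_r) {
      arma::vec sse(n_strata, arma::fill::zeros);
      for (int r = 0; r < n_obs; ++r) sse(stratum(r)) += e(r) * e(r);
      for (int s = 0; s < n_strata; ++s) {
        if (n_strat(s) == 0) continue;     // keep previous draw
        Rv(s) = (sse(s) + r_scale(s)) / R::rchisq(n_strat(s) + r_df0);
      }
    }

    // ---- store thinned post-burn-in draws
    if (it > burn_in && (it - burn_in) % thin == 0 && stored < n_store) {
      G0_draws.slice(stored) = G0;
      P0_draws.slice(stored) = P0;
      R_draws.row(stored) = Rv.t();
      if (store_theta) theta_draws.col(stored) = theta;
      theta_sum += theta;
      ++stored;
    }
  }

  return List::create(
    _["G0_draws"] = G0_draws,
    _["P0_draws"] = P0_draws,
    _["R_draws"] = R_draws,
    _["theta_draws"] = theta_draws,
    _["theta_mean"] = (stored > 0) ? arma::vec(theta_sum / stored) : theta_sum,
    _["theta_last"] = theta,
    _["e_last"] = e,
    _["retained"] = stored
  );
}
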