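#' Retained-draw bookkeeping
#'
#' Number of stored posterior draws for a chain: `floor((chain - burn_in) /
#' thin)`. The published protocol (chain 200,000, burn-in 50,000, thinning
#' 20) retains 7,500 samples.
#'
#' @param chain Total chain length.
#' @param burn_in Discarded initial samples (>= 0, < chain for a non-empty
#'   retention).
#' @param thin Thinning interval (>= 1).
#' @return Integer count of retained draws; warns when zero.
#' @export
retained_draws <- function(chain, burn_in, thin) {
  if (thin < 1 || burn_in < 0 || chain < 1) {
    abort("need chain >= 1, burn_in >= 0, thin >= 1.")
  }
  n <- max(0L, as.integer(floor((chain - burn_in) / thin)))
  if (n == 0L) warn("no draws retained: chain does not outlast burn-in.")
  n
}

#' Priors for the variance components
#'
#' The near-flat default makes every conditional proper at any data size: an
#' inverted-Wishart with scale `1e-6 * I` and degrees of freedom `dim + 1`
#' for G0 and P0, and zero prior df/scale for the residual variances (the
#' uniform-on-log convention). `type = "flat"` sets all prior df and scales
#' to zero; [run_gibbs()] then errors when a conditional would be improper
#' (fewer animals/cows than coefficients).
#'
#' @param spec A [model_spec()].
#' @param type `"near_flat"` (default) or `"flat"`.
#' @return List of prior df and scale matrices.
#' @export
gibbs_priors <- function(spec, type = c("near_flat", "flat")) {
  type <- match.arg(type)
  K <- spec$n_coef
  if (type == "near_flat") {
    list(g0_df0 = K + 1, g0_scale = diag(1e-6, K),
         p0_df0 = K + 1, p0_scale = diag(1e-6, K),
         r_df0 = 0, r_scale = rep(0, spec$n_strata), type = type)
  } else {
    list(g0_df0 = 0, g0_scale = matrix(0, K, K),
         p0_df0 = 0, p0_scale = matrix(0, K, K),
         r_df0 = 0, r_scale = rep(0, spec$n_strata), type = type)
  }
}

#' Gibbs sampling of the (co)variance components
#'
#' Runs a single-chain blocked Gibbs sampler over the full model hierarchy:
#' every fixed-effect level, each animal's additive-genetic coefficient
#' vector (jointly) and each cow's permanent-environmental vector are drawn
#' from their Gaussian full conditionals; G0 and P0 from inverted-Wishart
#' conditionals with scales `M' A^-1 M` and `P'P`; the residual variances
#' from per-stratum scaled inverse-chi-squares. Posterior means of the
#' thinned post-burn-in draws are the point estimates.
#'
#' @param records Edited test-day tibble.
#' @param ped Pedigree accepted by [as_pedigree()].
#' @param spec A [model_spec()].
#' @param init Starting [covariance_set()]; a generic diagonal start is used
#'   when omitted.
#' @param chain,burn_in,thin Chain protocol (desk-scale default
#'   20,000/5,000/10; the published protocol is 200,000/50,000/20).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param priors From [gibbs_priors()].
#' @param store_theta Keep thinned draws of all location effects (memory!).
#' @param basis Optional [legendre_basis()].
#' @return Object of class `gibbs_fit`: draw arrays `G0_draws`
#'   (K x K x retained), `P0_draws`, `R_draws` (retained x strata),
#'   the posterior-mean `covset`, location posterior means, and the chain
#'   settings. Methods: [tidy.gibbs_fit()], [glance.gibbs_fit()],
#'   [autoplot.gibbs_fit()].
#' @export
run_gibbs <- function(records, ped, spec, init = NULL,
                      chain = 20000L, burn_in = 5000L, thin = 10L,
                      seed = NULL, priors = gibbs_priors(spec),
                      store_theta = FALSE, basis = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_ret <- retained_draws(chain, burn_in, thin)
  K <- spec$n_coef
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  if (is.null(init)) {
    # generic start: split the raw phenotypic variance of the first trait
    # evenly over AG / PE / R, flat across the basis
    vbar <- mean(diag(crossprod(basis$Phi)) / length(basis$dims))
    v0 <- stats::var(records[[spec$traits[1]]], na.rm = TRUE)
    if (!is.finite(v0) || v0 <= 0) v0 <- 1
    init <- covariance_set(diag(v0 / (3 * vbar * spec$order), K),
                           diag(v0 / (3 * vbar * spec$order), K),
                           rep(v0 / 3, spec$n_strata), spec)
  }
  sys <- assemble_mme(records, ped, init, spec, basis)
  if (identical(priors$type, "flat")) {
    if (sys$n_animals <= K - 1 || sys$n_cows <= K - 1) {
      abort(paste("flat prior gives an improper inverted-Wishart",
                  "conditional: need more animals/cows than coefficients,",
                  "or an informative prior."))
    }
  }
  if (any(tabulate(sys$stratum, spec$n_strata) == 0L)) {
    warn("empty trait-lactation stratum: its residual variance keeps its start value.")
  }
  Ainv_g <- methods::as(sys$Ainv, "generalMatrix")
  res <- gibbs_chain_cpp(
    sys$W, sys$y, as.integer(sys$stratum - 1L), spec$n_strata,
    Ainv_g,
    as.integer(sys$blocks$start - 1L), as.integer(sys$blocks$size),
    as.integer(sys$blocks$type), as.integer(sys$blocks$index - 1L),
    as.integer(sys$blocks$start2 - 1L), as.integer(sys$blocks$index2 - 1L),
    init$G0, init$P0, init$R, sys$n_animals, sys$n_cows,
    as.integer(chain), as.integer(burn_in), as.integer(thin),
    priors$g0_df0, priors$g0_scale, priors$p0_df0, priors$p0_scale,
    priors$r_df0, priors$r_scale,
    TRUE, TRUE, TRUE, store_theta
  )
  finish_gibbs_fit(res, sys, spec, chain, burn_in, thin, store_theta)
}

finish_gibbs_fit <- function(res, sys, spec, chain, burn_in, thin,
                             store_theta) {
  G0m <- apply(res$G0_draws, c(1, 2), mean)
  P0m <- apply(res$P0_draws, c(1, 2), mean)
  Rm <- colMeans(res$R_draws)
  posterior <- covariance_set(G0m, P0m, Rm, spec)
  structure(
    list(G0_draws = res$G0_draws, P0_draws = res$P0_draws,
         R_draws = res$R_draws,
         theta_draws = if (store_theta) res$theta_draws else NULL,
         theta_mean = as.numeric(res$theta_mean),
         covset = posterior, spec = spec, system = sys,
         chain = chain, burn_in = burn_in, thin = thin,
         retained = res$retained),
    class = "gibbs_fit"
  )
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf(
    "<gibbs_fit> chain %d, burn-in %d, thin %d: %d retained draws; %d coefficients, %d strata\n",
    x$chain, x$burn_in, x$thin, x$retained, x$spec$n_coef, x$spec$n_strata))
  invisible(x)
}

#' One inverted-Wishart draw for the genetic covariance matrix
#'
#' Conditional of G0 given the current additive-genetic coefficient matrix:
#' `IW(M' A^-1 M + prior_scale, n_animals + prior_df)`.
#'
#' @param M Animals x coefficients matrix of current AG coefficients (in
#'   pedigree order).
#' @param Ainv Sparse A-inverse from [build_A_inverse()].
#' @param prior_df,prior_scale Prior degrees of freedom and scale matrix
#'   (defaults 0: the flat-prior conditional).
#' @return One SPD draw.
#' @export
sample_g0 <- function(M, Ainv, prior_df = 0, prior_scale = NULL) {
  M <- as.matrix(M)
  K <- ncol(M)
  prior_scale <- prior_scale %||% matrix(0, K, K)
  S <- as.matrix(Matrix::t(M) %*% (Ainv %*% M)) + prior_scale
  df <- nrow(M) + prior_df
  if (df <= K - 1) {
    abort("improper conditional: need more animals than coefficients or an informative prior.")
  }
  rinvwishart_cpp(df, (S + t(S)) / 2)
}

#' One inverted-Wishart draw for the permanent-environment covariance
#'
#' As [sample_g0()] with identity weighting: `IW(P'P + prior_scale,
#' n_cows + prior_df)`.
#'
#' @param P Cows x coefficients matrix of current PE coefficients.
#' @inheritParams sample_g0
#' @return One SPD draw.
#' @export
sample_p0 <- function(P, prior_df = 0, prior_scale = NULL) {
  P <- as.matrix(P)
  sample_g0(P, Matrix::Diagonal(nrow(P)), prior_df, prior_scale)
}

#' Residual variance draws by stratum
#'
#' Each trait-lactation stratum's residual variance is drawn from a scaled
#' inverse-chi-square with scale `sum(e^2) + prior_scale` and df
#' `n + prior_df`. An empty stratum keeps its previous value, with a
#' warning.
#'
#' @param e Residual vector.
#' @param stratum Integer stratum per residual (1-based).
#' @param n_strata Number of strata.
#' @param prior_df,prior_scale Prior df and scale (scalars or per stratum).
#' @param prev Previous draws (required when a stratum may be empty).
#' @return Numeric vector of variance draws.
#' @export
sample_r <- function(e, stratum, n_strata, prior_df = 0, prior_scale = 0,
                     prev = NULL) {
  prior_df <- rep_len(prior_df, n_strata)
  prior_scale <- rep_len(prior_scale, n_strata)
  out <- numeric(n_strata)
  for (s in seq_len(n_strata)) {
    idx <- stratum == s
    n <- sum(idx)
    if (n == 0L) {
      if (is.null(prev)) abort(sprintf("stratum %d empty and no previous draw.", s))
      warn(sprintf("stratum %d empty: keeping previous residual variance.", s))
      out[s] <- prev[s]
      next
    }
    out[s] <- (sum(e[idx]^2) + prior_scale[s]) / rchisq(1, n + prior_df[s])
  }
  out
}

#' Geweke convergence z-scores
#'
#' Compares the mean of the first `frac1` and last `frac2` of a chain of
#' draws with a simple batch-variance estimate; |z| around 2 or more flags
#' non-convergence.
#'
#' @param x Numeric vector of sequential draws.
#' @param frac1,frac2 Window fractions (defaults 0.1 and 0.5).
#' @return The z-score.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2, floor(frac2 * n)) + 1L, n)]
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
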