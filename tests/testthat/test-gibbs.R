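test_that("retained-draw bookkeeping is exact", {
  expect_equal(retained_draws(200000, 50000, 20), 7500L)
  expect_equal(retained_draws(20000, 5000, 10), 1500L)
  expect_equal(retained_draws(101, 1, 7), 14L)
  expect_warning(n <- retained_draws(100, 100, 1), "retained")
  expect_equal(n, 0L)
  expect_error(retained_draws(100, -1, 1), "burn_in")
})

test_that("residual draws follow the scaled inverse-chi-square", {
  set.seed(61)
  e <- rnorm(2000, 0, 2)
  n <- length(e)
  draws <- vapply(1:4000, function(i) sample_r(e, rep(1L, n), 1L),
                  numeric(1))
  target <- sum(e^2) / (n - 2)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - target), 3 * se)
  # residuals all zero with a proper prior -> draw from the prior
  z <- rep(0, 50)
  prior_draws <- vapply(1:4000, function(i) {
    sample_r(z, rep(1L, 50), 1L, prior_df = 10, prior_scale = 20)
  }, numeric(1))
  expect_lt(abs(mean(prior_draws) - 20 / (50 + 10 - 2)), 0.02)
  # empty stratum keeps the previous value
  expect_warning(
    out <- sample_r(e, rep(1L, n), 2L, prev = c(99, 5)), "empty")
  expect_equal(out[2], 5)
})

test_that("genetic covariance draws have the inverted-Wishart moments", {
  set.seed(62)
  n <- 400
  a <- rnorm(n, 0, 1.5)
  I_n <- Matrix::Diagonal(n)
  draws <- vapply(1:3000, function(i) {
    as.numeric(sample_g0(matrix(a, ncol = 1), I_n))
  }, numeric(1))
  target <- sum(a^2) / (n - 2)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - target), 3 * se)
  # zero coefficients with a proper prior -> the prior itself
  z <- matrix(0, 60, 1)
  pd <- vapply(1:3000, function(i) {
    as.numeric(sample_g0(z, Matrix::Diagonal(60), prior_df = 8,
                         prior_scale = matrix(12, 1, 1)))
  }, numeric(1))
  expect_lt(abs(mean(pd) - 12 / (60 + 8 - 2)), 0.02)
  # matrix draws are always SPD
  M <- matrix(rnorm(50 * 3), 50, 3)
  for (i in 1:20) {
    d <- sample_g0(M, Matrix::Diagonal(50))
    expect_silent(chol(d))
  }
  # improper conditional is refused
  expect_error(sample_g0(matrix(rnorm(2 * 3), 2, 3), Matrix::Diagonal(2)),
               "improper")
})

test_that("permanent-environment draws mirror the genetic machinery", {
  set.seed(63)
  P <- matrix(rnorm(200 * 2), 200, 2)
  d <- sample_p0(P)
  expect_silent(chol(d))
  expect_equal(dim(d), c(2L, 2L))
  draws <- vapply(1:2000, function(i) sample_p0(P)[1, 1], numeric(1))
  # marginal of a diagonal element concentrates near the scale/(n-K-1)
  Sc <- crossprod(P)
  expect_lt(abs(mean(draws) - Sc[1, 1] / (200 - 2 - 1)), 0.05)
})

test_that("chains are reproducible and store the configured draws", {
  sim <- tiny_sim(seed = 64, n_cows = 12L, n_tests = 5L)
  f1 <- run_gibbs(sim$rec, sim$ped, sim$spec, chain = 300, burn_in = 100,
                  thin = 5, seed = 2024)
  f2 <- run_gibbs(sim$rec, sim$ped, sim$spec, chain = 300, burn_in = 100,
                  thin = 5, seed = 2024)
  expect_identical(f1$G0_draws, f2$G0_draws)
  expect_identical(f1$R_draws, f2$R_draws)
  expect_equal(f1$retained, 40L)
  expect_equal(dim(f1$G0_draws)[3], 40L)
  # different seed changes the draws
  f3 <- run_gibbs(sim$rec, sim$ped, sim$spec, chain = 300, burn_in = 100,
                  thin = 5, seed = 9)
  expect_false(identical(f1$G0_draws, f3$G0_draws))
  # every stored draw is SPD with positive residuals
  for (i in seq_len(f1$retained)) {
    expect_silent(chol(f1$G0_draws[, , i]))
    expect_silent(chol(f1$P0_draws[, , i]))
  }
  expect_true(all(f1$R_draws > 0))
})

test_that("a no-data founder draws from its pedigree prior", {
  # one extra unrelated founder with no records: conditional is N(0, G0)
  sim <- tiny_sim(seed = 65, n_cows = 10L, n_tests = 5L)
  ped <- dplyr::bind_rows(
    sim$ped,
    tibble::tibble(animal = 9999L, sire = 0L, dam = 0L,
                   birth_year = 2001L, role = "sire"))
  sys <- assemble_mme(sim$rec, ped, sim$covset)
  Ainv_g <- methods::as(sys$Ainv, "generalMatrix")
  set.seed(66)
  res <- rrtdm:::gibbs_chain_cpp(
    sys$W, sys$y, as.integer(sys$stratum - 1L), 1L, Ainv_g,
    as.integer(sys$blocks$start - 1L), as.integer(sys$blocks$size),
    as.integer(sys$blocks$type), as.integer(sys$blocks$index - 1L),
    as.integer(sys$blocks$start2 - 1L), as.integer(sys$blocks$index2 - 1L),
    sim$covset$G0, sim$covset$P0, sim$covset$R, sys$n_animals, sys$n_cows,
    4000L, 0L, 1L, 0, matrix(0, 2, 2), 0, matrix(0, 2, 2), 0, 0,
    FALSE, FALSE, FALSE, TRUE)
  ia <- match(9999L, sys$animal_ids)
  cols <- sys$n_fixed + (ia - 1L) * 2L + 1:2
  th <- t(res$theta_draws[cols, ])
  expect_lt(abs(mean(th[, 1])), 3 * sqrt(sim$covset$G0[1, 1] / 4000) * 3)
  expect_lt(abs(var(th[, 1]) - sim$covset$G0[1, 1]),
            4 * sim$covset$G0[1, 1] / sqrt(4000) * 3)
})

test_that("posterior mean of location draws matches the BLUP solution", {
  sim <- tiny_sim(seed = 67, n_cows = 15L, n_tests = 5L)
  # collapse the contemporary classifications: near-collinear fixed levels
  # mix as slow random walks and would need impractically long chains for
  # their Monte-Carlo means to settle
  rec <- dplyr::mutate(sim$rec, test_year = 2000L, test_month = 1L,
                       hf_fraction = 0.9, calving_month = 1L,
                       age_calving = 30)
  sys <- assemble_mme(rec, sim$ped, sim$covset)
  sol <- solve_mme(sys, tol = 1e-12)$solution
  Ainv_g <- methods::as(sys$Ainv, "generalMatrix")
  set.seed(68)
  res <- rrtdm:::gibbs_chain_cpp(
    sys$W, sys$y, as.integer(sys$stratum - 1L), 1L, Ainv_g,
    as.integer(sys$blocks$start - 1L), as.integer(sys$blocks$size),
    as.integer(sys$blocks$type), as.integer(sys$blocks$index - 1L),
    as.integer(sys$blocks$start2 - 1L), as.integer(sys$blocks$index2 - 1L),
    sim$covset$G0, sim$covset$P0, sim$covset$R, sys$n_animals, sys$n_cows,
    30000L, 2000L, 1L, 0, matrix(0, 2, 2), 0, matrix(0, 2, 2), 0, 0,
    FALSE, FALSE, FALSE, FALSE)
  # compare on the estimable EBV scale
  e_gibbs <- extract_ebv(res$theta_mean, sys)$ebv
  e_blup <- extract_ebv(sol, sys)$ebv
  expect_gt(stats::cor(e_gibbs, e_blup), 0.995)
  expect_lt(max(abs(e_gibbs - e_blup)), 0.2 * stats::sd(e_blup) + 0.5)
})

test_that("flat priors are refused when the conditional is improper", {
  sim <- tiny_sim(seed = 69, n_cows = 4L, n_tests = 5L, order = 5L,
                  ag = 4, pe = 4, r = 2)
  expect_error(
    run_gibbs(sim$rec, sim$ped, sim$spec, chain = 50, burn_in = 10,
              thin = 1, seed = 1,
              priors = gibbs_priors(sim$spec, "flat")),
    "improper")
})

test_that("geweke z-scores are finite and near zero for white noise", {
  set.seed(70)
  z <- geweke_z(rnorm(5000))
  expect_true(is.finite(z))
  expect_lt(abs(z), 4)
})
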