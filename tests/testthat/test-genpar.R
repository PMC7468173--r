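random_covset <- function(spec, scale = 1) {
  k <- spec$n_coef
  G <- crossprod(matrix(rnorm(k * k), k)) + diag(k)
  P <- crossprod(matrix(rnorm(k * k), k)) + diag(k)
  covariance_set(scale * G, scale * P, rep(runif(spec$n_strata, 0.5, 3)),
                 spec)
}

test_that("constant-basis closed forms hold to machine precision", {
  spec <- model_spec("milk", 1L, order = 1L)
  covset <- covariance_set(matrix(2), matrix(2), 1, spec)
  h2 <- daily_h2(covset)
  # phi0^2 = 1/2 so daily AG = PE = 1 and h2 = 1/3 on every day
  expect_equal(unique(h2$v_ag), 1, tolerance = 1e-12)
  expect_equal(h2$h2, rep(1 / 3, 301), tolerance = 1e-12)
  avg <- average_daily_h2(covset)
  expect_equal(avg$h2_mean_of_ratios, 1 / 3, tolerance = 1e-12)
  expect_equal(avg$h2_ratio_of_means, 1 / 3, tolerance = 1e-12)
  # 305-d: AG_305 = 301^2 * daily variance; h2_305 = 301/603 > 1/3
  agg <- aggregate_305d(covset)
  expect_equal(agg$summary$ag_305, 301^2 * 1, tolerance = 1e-12)
  expect_equal(agg$summary$h2_305, 301 / 603, tolerance = 1e-12)
  expect_gt(agg$summary$h2_305, 1 / 3)
  # omitting the residual term changes the denominator
  agg0 <- aggregate_305d(covset, residual = "omit")
  expect_equal(agg0$summary$h2_305, 0.5, tolerance = 1e-12)
})

test_that("daily variance curves match a brute-force loop", {
  set.seed(81)
  spec <- model_spec(c("milk", "fat"), 1:2, order = 3L)
  covset <- random_covset(spec)
  basis <- legendre_basis(3L)
  dv <- daily_variance(covset, basis)
  # loop oracle on one stratum, every tenth day
  s <- 3L
  cols <- (s - 1L) * 3L + 1:3
  G <- covset$G0[cols, cols]
  for (t in seq(5L, 305L, by = 10L)) {
    phi <- drop(leg_covariables(basis, t))
    expect_equal(
      dv$variance[dv$component == "ag" &
                    dv$trait == spec$strata$trait[s] &
                    dv$lactation == spec$strata$lactation[s] &
                    dv$dim == t],
      drop(phi %*% G %*% phi), tolerance = 1e-12)
  }
  expect_true(all(dv$variance > 0))
  # average of the daily curve equals the trace-weighted form
  Phibar <- crossprod(basis$Phi) / 301
  avg_loop <- mean(dv$variance[dv$component == "ag" & dv$trait == "milk" &
                                 dv$lactation == 1])
  expect_equal(avg_loop, sum(covset$G0[1:3, 1:3] * Phibar),
               tolerance = 1e-12)
})

test_that("305-d aggregates equal the brute-force double sum", {
  set.seed(82)
  spec <- model_spec(c("milk", "fat"), 1L, order = 2L)
  covset <- random_covset(spec)
  basis <- legendre_basis(2L)
  agg <- aggregate_305d(covset, basis)
  Phi <- basis$Phi
  # double-loop oracle for the (milk, fat) cross block
  G12 <- covset$G0[1:2, 3:4]
  brute <- sum(Phi %*% G12 %*% t(Phi))
  expect_equal(agg$ag_cov[1, 2], brute, tolerance = 1e-9)
  expect_equal(unname(diag(agg$ag_cor)), c(1, 1), tolerance = 1e-12)
})

test_that("correlation surfaces stay in [-1, 1] with unit diagonal", {
  set.seed(83)
  spec <- model_spec(c("milk", "fat"), 1L, order = 3L)
  for (rep in 1:50) {
    covset <- random_covset(spec)
    surf <- correlation_surface(covset, trait_i = "milk", trait_j = "milk")
    same <- surf$correlation[surf$dim_i == surf$dim_j]
    expect_equal(same, rep(1, 6), tolerance = 1e-12)
    cross <- correlation_surface(covset, trait_i = "milk",
                                 trait_j = "fat")
    expect_true(all(abs(cross$correlation) <= 1 + 1e-12))
  }
  # rank-one basis: every correlation is exactly one
  spec1 <- model_spec("milk", 1L, order = 1L)
  cs1 <- covariance_set(matrix(3), matrix(2), 1, spec1)
  surf1 <- correlation_surface(cs1)
  expect_equal(surf1$correlation, rep(1, 36), tolerance = 1e-12)
})

test_that("trend regression recovers exact lines and flags degenerate input", {
  ebv <- tibble::tibble(
    animal = 1:40, trait = "milk", lactation = 1L,
    ebv = 10 * rep(1:10, each = 4) + rep(c(-1, 1, -2, 2), 10))
  years <- tibble::tibble(animal = 1:40,
                          birth_year = 2000L + rep(1:10, each = 4))
  fit <- genetic_trend(ebv, years)
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant EBVs -> zero slope
  flat <- dplyr::mutate(ebv, ebv = 7)
  expect_equal(genetic_trend(flat, years)$slope, 0, tolerance = 1e-10)
  # single year is an error
  one_year <- tibble::tibble(animal = 1:40, birth_year = 2001L)
  expect_error(genetic_trend(ebv, one_year), "two distinct birth years")
})

test_that("the two average-heritability conventions agree closely at
           realistic magnitudes", {
  spec <- model_spec()
  covset <- default_true_params(spec)
  avg <- average_daily_h2(covset)
  expect_true(all(abs(avg$h2_mean_of_ratios - avg$h2_ratio_of_means) < 0.02))
})
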