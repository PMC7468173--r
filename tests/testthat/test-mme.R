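test_that("assembled equations match an independent dense constructor", {
  sim <- tiny_sim(seed = 21, n_cows = 50L, n_sires = 8L, n_tests = 6L)
  sys <- assemble_mme(sim$rec, sim$ped, sim$covset)
  oracle <- dense_mme_oracle(sim$rec, sim$ped, sim$covset, sim$spec)
  expect_equal(dim(oracle$C), dim(sys$C))
  expect_lt(max(abs(as.matrix(sys$C) - oracle$C)), 1e-8)
  expect_equal(sys$rhs, oracle$rhs, tolerance = 1e-10)
})

test_that("assembly validates its inputs", {
  sim <- tiny_sim(seed = 22, n_cows = 8L)
  # a record cow missing from the pedigree is named
  bad <- dplyr::mutate(sim$rec, cow = ifelse(dplyr::row_number() <= 2,
                                             99999L, cow))
  expect_error(assemble_mme(bad, sim$ped, sim$covset), "99999")
  # non-SPD covariance set is rejected at construction
  G <- sim$covset$G0
  G[1, 2] <- G[2, 1] <- 10 * sqrt(G[1, 1] * G[2, 2])
  expect_error(covariance_set(G, sim$covset$P0, sim$covset$R, sim$spec),
               "positive definite")
})

test_that("zero observations give the prior-only system with zero solution", {
  sim <- tiny_sim(seed = 23, n_cows = 6L)
  sys <- assemble_mme(sim$rec[0, ], sim$ped, sim$covset)
  expect_equal(length(sys$y), 0L)
  expect_equal(max(abs(sys$rhs)), 0)
  fit <- solve_mme(sys)
  expect_equal(max(abs(fit$solution)), 0)
})

test_that("PCG matches dense solves", {
  # identity system
  n <- 25
  C <- Matrix::Diagonal(n)
  b <- rnorm(n)
  res <- rrtdm:::pcg_solve(C, b)
  expect_equal(res$solution, b, tolerance = 1e-12)
  # random SPD system
  set.seed(31)
  M <- matrix(rnorm(300 * 300), 300)
  C <- methods::as(crossprod(M) + 300 * diag(300), "CsparseMatrix")
  b <- rnorm(300)
  res <- rrtdm:::pcg_solve(C, b, tol = 1e-12, max_iter = 2000)
  expect_lt(max(abs(res$solution - solve(as.matrix(C), b))), 1e-8)
})

test_that("solver reports non-convergence instead of failing", {
  set.seed(32)
  M <- matrix(rnorm(60 * 60), 60)
  C <- methods::as(crossprod(M) + diag(60), "CsparseMatrix")
  b <- rnorm(60)
  expect_warning(res <- rrtdm:::pcg_solve(C, b, tol = 1e-14, max_iter = 2L),
                 "max_iter")
  expect_false(res$converged)
  expect_gt(res$rel_residual, 0)
})

test_that("305-d EBVs are the summed covariables of the coefficients", {
  sim <- tiny_sim(seed = 24, n_cows = 10L)
  sys <- assemble_mme(sim$rec, sim$ped, sim$covset)
  basis <- sys$basis
  # zero solutions -> zero EBVs
  ebv0 <- extract_ebv(rep(0, sys$n_eq), sys)
  expect_equal(ebv0$ebv, rep(0, nrow(ebv0)))
  # a unit constant coefficient for the first animal -> EBV = S[1]
  sol <- rep(0, sys$n_eq)
  sol[sys$n_fixed + 1L] <- 1
  ebv1 <- extract_ebv(sol, sys)
  expect_equal(ebv1$ebv[1], summing_vector(basis)[1], ignore_attr = TRUE)
  expect_equal(ebv1$ebv[-1], rep(0, nrow(ebv1) - 1))
})

test_that("EBVs are invariant to a phenotype-level shift (estimability)", {
  sim <- tiny_sim(seed = 25, n_cows = 25L, n_sires = 5L)
  ebv_a <- blup_ebv(sim$rec, sim$ped, sim$covset, tol = 1e-12)
  shifted <- dplyr::mutate(sim$rec, milk = milk + 10)
  ebv_b <- blup_ebv(shifted, sim$ped, sim$covset, tol = 1e-12)
  expect_equal(ebv_a$ebv, ebv_b$ebv, tolerance = 1e-6)
})

test_that("stronger shrinkage never inflates the EBV spread", {
  sim <- tiny_sim(seed = 26, n_cows = 25L, n_sires = 5L)
  scale_fit <- function(c) {
    cv <- covariance_set(c * sim$covset$G0, sim$covset$P0, sim$covset$R,
                         sim$spec)
    mean(abs(blup_ebv(sim$rec, sim$ped, cv, tol = 1e-12)$ebv))
  }
  spread <- vapply(c(0.1, 0.5, 1), scale_fit, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("EBVs approach the true aggregates in the noise-free limit", {
  # exact records y = phi' a on one shared test grid: free contemporary
  # classifications then absorb only a common curve, so centred EBVs must
  # reproduce the true aggregates. (With cow-specific grids or several
  # herds the free group effects legitimately absorb part of each animal's
  # level even at zero residual - expected animal-model behaviour.)
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 1e-8, r = 1e-8)
  des <- sim_design(spec = spec, covset = covset, n_sires = 4L,
                    n_cows = 30L, n_herds = 1L)
  set.seed(27)
  ped <- simulate_pedigree(des)
  a_true <- rrtdm:::simulate_true_bv(ped, des)
  basis <- legendre_basis(2L)
  dims <- seq(10L, 220L, by = 30L)
  phi <- leg_covariables(basis, dims)
  cows <- ped$animal[ped$role == "cow"]
  rec <- purrr::map_dfr(cows, function(cw) {
    tibble::tibble(
      cow = cw, lactation = 1L, dim = dims, test_year = 2000L,
      test_month = 1L, herd = 1L,
      milk = as.numeric(phi %*% a_true[as.character(cw), ]),
      fat = NA_real_, protein = NA_real_, age_calving = 30,
      hf_fraction = 0.9, calving_month = 1L, sire_known = TRUE)
  })
  ebv <- blup_ebv(rec, ped, covset, tol = 1e-12, max_iter = 20000L)
  S <- summing_vector(basis)
  true_305 <- drop(a_true[as.character(ebv$animal), ] %*% S)
  idx <- ebv$animal %in% cows
  est <- ebv$ebv[idx] - mean(ebv$ebv[idx])
  tru <- true_305[idx] - mean(true_305[idx])
  expect_gt(stats::cor(est, tru), 0.999)
  expect_lt(max(abs(est - tru)) / stats::sd(tru), 0.05)
})
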