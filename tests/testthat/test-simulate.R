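test_that("default true parameters hit the anchor variances", {
  spec <- model_spec()
  covset <- default_true_params(spec)
  anchors <- variance_anchors()
  basis <- legendre_basis(5L)
  Phibar <- crossprod(basis$Phi) / 301
  for (s in seq_len(spec$n_strata)) {
    cols <- (s - 1L) * 5L + 1:5
    implied <- sum(covset$G0[cols, cols] * Phibar)
    target <- anchors$ag[match(paste(spec$strata$trait[s],
                                     spec$strata$lactation[s]),
                               paste(anchors$trait, anchors$lactation))]
    expect_lt(abs(implied - target) / target, 0.10)
    expect_equal(implied, target, tolerance = 1e-8)
  }
  # residuals equal the anchors exactly (milk lactation 2 = 2.11)
  expect_equal(covset$R[stratum_of(spec, "milk", 2L)], 2.11)
  expect_silent(chol(covset$G0))
  expect_silent(chol(covset$P0))
})

test_that("pedigree simulation produces the designed counts", {
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 4, r = 2)
  des <- sim_design(spec = spec, covset = covset, n_sires = 10L,
                    n_cows = 100L, n_dams = 10L, n_herds = 2L)
  set.seed(91)
  ped <- simulate_pedigree(des)
  expect_equal(nrow(ped), 120L)                  # 10 + 10 + 100
  cows <- ped[ped$role == "cow", ]
  expect_equal(nrow(cows), 100L)
  expect_true(all(cows$sire > 0 & cows$dam > 0))
  # multi-generation option: second cohort dams are first cohort cows
  des2 <- sim_design(spec = spec, covset = covset, n_years = 2L,
                     n_sires = 5L, n_cows = 30L, dam_from_cows = TRUE)
  ped2 <- simulate_pedigree(des2, seed = 92)
  c2 <- ped2[ped2$role == "cow" & ped2$birth_year == 2002L, ]
  c1 <- ped2$animal[ped2$role == "cow" & ped2$birth_year == 2001L]
  expect_true(all(c2$dam %in% c1))
})

test_that("simulated phenotype variance decomposes as designed", {
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 4, r = 2)
  des <- sim_design(spec = spec, covset = covset, n_sires = 60L,
                    n_cows = 2500L, n_herds = 1L, n_tests = 1L,
                    missing_rate = 0, sd_htm = 0, sd_bsm = 0,
                    beta_age = c(0, 0))
  set.seed(93)
  ped <- simulate_pedigree(des)
  rec <- simulate_records(ped, des)
  basis <- legendre_basis(2L)
  # variance at each observed DIM pooled over cows
  rec$phi_var <- {
    phi <- leg_covariables(basis, rec$dim)
    rowSums((phi %*% (covset$G0 + covset$P0)) * phi) + covset$R
  }
  # compare the standardized residual variance of y to 1
  z <- (rec$milk - mean(rec$milk)) / sqrt(rec$phi_var)
  expect_lt(abs(var(z) - 1), 0.06)
})

test_that("Mendelian sampling variance is half the genetic covariance", {
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 4, r = 2)
  des <- sim_design(spec = spec, covset = covset, n_sires = 40L,
                    n_cows = 3000L, n_herds = 1L, n_tests = 1L,
                    missing_rate = 0)
  set.seed(94)
  ped <- simulate_pedigree(des)
  rec <- simulate_records(ped, des)
  truth <- attr(rec, "truth")
  cows <- which(ped$role == "cow")
  bv <- truth$bv[as.character(ped$animal), , drop = FALSE]
  ms <- bv[cows, ] - 0.5 * (bv[match(ped$sire[cows], ped$animal), ] +
                              bv[match(ped$dam[cows], ped$animal), ])
  emp <- stats::cov(ms)
  expect_lt(max(abs(emp - 0.5 * covset$G0)) / max(abs(covset$G0)), 0.05)
})

test_that("an imposed trend shifts true cohort means linearly", {
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 4, r = 2)
  S <- summing_vector(legendre_basis(2L))
  fit_true_trend <- function(trend, seed) {
    des <- sim_design(spec = spec, covset = covset, n_years = 6L,
                      n_sires = 10L, n_cows = 150L, trend = trend)
    set.seed(seed)
    ped <- simulate_pedigree(des)
    rec <- simulate_records(ped, des)
    bv305 <- drop(attr(rec, "truth")$bv %*% S)
    df <- data.frame(y = tapply(bv305, ped$birth_year, mean),
                     year = sort(unique(ped$birth_year)))
    unname(coef(lm(y ~ year, df))[2])
  }
  slopes0 <- vapply(1:3, function(s) fit_true_trend(0, s), numeric(1))
  expect_lt(abs(mean(slopes0)), 3 * stats::sd(slopes0) / sqrt(3) + 1)
  slopes10 <- vapply(4:6, function(s) fit_true_trend(10, s), numeric(1))
  expect_lt(abs(mean(slopes10) - 10),
            3 * stats::sd(slopes10) / sqrt(3) + 1)
})

test_that("records respect missingness, drop-out and the noise-free limit", {
  spec <- model_spec()
  des <- sim_design(spec = spec, n_years = 1L, n_sires = 4L, n_cows = 40L,
                    n_tests = 11L, missing_rate = 0.3)
  set.seed(95)
  ped <- simulate_pedigree(des)
  rec <- simulate_records(ped, des)
  # fat and protein missing together at roughly the design rate
  expect_identical(is.na(rec$fat), is.na(rec$protein))
  expect_gt(mean(is.na(rec$fat)), 0.15)
  expect_lt(mean(is.na(rec$fat)), 0.45)
  # lactation continuation thins later lactations
  n_by_lact <- table(dplyr::distinct(rec, cow, lactation)$lactation)
  expect_true(n_by_lact[1] > n_by_lact[2] && n_by_lact[2] >= n_by_lact[3])
  # noise-free limit: y equals the genetic curve exactly
  spec1 <- model_spec("milk", 1L, order = 2L)
  cs0 <- make_true_params(spec1, ag_mean = 4, pe_mean = 1e-9, r = 1e-9)
  des0 <- sim_design(spec = spec1, covset = cs0, n_sires = 3L,
                     n_cows = 10L, n_tests = 5L, missing_rate = 0,
                     sd_htm = 0, sd_bsm = 0, beta_age = c(0, 0))
  set.seed(96)
  ped0 <- simulate_pedigree(des0)
  rec0 <- simulate_records(ped0, des0)
  truth0 <- attr(rec0, "truth")
  phi <- leg_covariables(legendre_basis(2L), rec0$dim)
  g <- unname(rowSums(phi * truth0$bv[as.character(rec0$cow), ]))
  expect_equal(rec0$milk - des0$mu[["milk"]], g, tolerance = 1e-3)
})

test_that("fixtures are deterministic and match the design arithmetic", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- make_fixture("tiny", seed = 5L, dir = dir1)
  p2 <- make_fixture("tiny", seed = 5L, dir = dir2)
  expect_identical(readLines(p1$testday), readLines(p2$testday))
  expect_identical(readLines(p1$pedigree), readLines(p2$pedigree))
  ped <- read_pedigree(p1$pedigree)
  expect_equal(nrow(ped), 2L * (3L + 10L + 10L)) # two cohorts
  rec <- read_testday(p1$testday)
  expect_lte(nrow(rec), 20L * 8L)
  expect_gte(nrow(rec), 20L * 5L)
  # truth files re-read to the written values
  g0 <- as.matrix(readr::read_csv(p1$truth_g0, show_col_types = FALSE))
  expect_equal(unname(g0),
               unname(make_true_params(model_spec("milk", 1L, order = 2L),
                                       ag_mean = 4, pe_mean = 4,
                                       r = 2)$G0),
               tolerance = 1e-12)
})

test_that("the tiny fixture drives the full pipeline end to end", {
  dir <- withr::local_tempdir()
  paths <- make_fixture("tiny", seed = 11L, dir = dir)
  ped <- read_pedigree(paths$pedigree)
  rec <- read_testday(paths$testday)
  spec <- model_spec("milk", 1L, order = 2L)
  edited <- apply_edits(rec, edit_rules(first_td_window = c(5, 35)))
  expect_gt(nrow(edited), 0)
  fit <- run_gibbs(edited, ped, spec, chain = 400, burn_in = 100,
                   thin = 5, seed = 3)
  expect_equal(fit$retained, 60L)
  covset <- fit$covset
  params <- genetic_parameters(covset)
  expect_true(all(params$h2_305$h2_305 > 0 & params$h2_305$h2_305 < 1))
  ebv <- blup_ebv(edited, ped, covset)
  expect_equal(nrow(ebv), nrow(ped))
  trend <- genetic_trend(ebv, ped)
  expect_s3_class(trend, "trend_fit")
  out <- write_results(params, ebv, dir, components = tidy(fit),
                       trend = trend)
  expect_true(all(file.exists(out)))
})
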