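#' Literature-calibrated average daily variance anchors
#'
#' Average daily additive-genetic, permanent-environmental and residual
#' variances (kg^2) for milk, fat and protein in lactations 1-3 of a
#' tropical Holstein-Friesian upgrade population, used to scale the default
#' simulation parameters. Fat and protein values are on the natural kg^2
#' scale (published tables often print them multiplied by 1,000).
#'
#' @return Tibble with `trait`, `lactation`, `ag`, `pe`, `r`.
#' @export
variance_anchors <- function() {
  tibble::tibble(
    trait = rep(c("milk", "fat", "protein"), each = 3),
    lactation = rep(1:3, times = 3),
    ag = c(4.55, 7.58, 8.02,
           10.58e-3, 16.67e-3, 18.75e-3,
           6.33e-3, 10.50e-3, 12.33e-3),
    pe = c(6.03, 5.97, 6.49,
           11.62e-3, 11.83e-3, 11.38e-3,
           7.26e-3, 7.76e-3, 8.83e-3),
    r = c(1.75, 2.11, 2.37,
          9.13e-3, 10.68e-3, 11.77e-3,
          3.29e-3, 3.76e-3, 4.20e-3)
  )
}

# 305-d stratum correlation anchors (trait-lactation by trait-lactation),
# used to give the default G0/P0 realistic cross-stratum structure
anchor_correlations <- function(component = c("ag", "pe")) {
  component <- match.arg(component)
  lab <- paste(rep(c("milk", "fat", "protein"), each = 3), rep(1:3, 3))
  m <- diag(9)
  dimnames(m) <- list(lab, lab)
  fill <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  if (component == "ag") {
    up <- list(
      c("milk 1", "milk 2", .81), c("milk 1", "milk 3", .72),
      c("milk 1", "fat 1", .59), c("milk 1", "fat 2", .56),
      c("milk 1", "fat 3", .48), c("milk 1", "protein 1", .69),
      c("milk 1", "protein 2", .61), c("milk 1", "protein 3", .50),
      c("milk 2", "milk 3", .63), c("milk 2", "fat 1", .59),
      c("milk 2", "fat 2", .60), c("milk 2", "fat 3", .43),
      c("milk 2", "protein 1", .68), c("milk 2", "protein 2", .64),
      c("milk 2", "protein 3", .45),
      c("milk 3", "fat 1", .49), c("milk 3", "fat 2", .46),
      c("milk 3", "fat 3", .56), c("milk 3", "protein 1", .57),
      c("milk 3", "protein 2", .52), c("milk 3", "protein 3", .58),
      c("fat 1", "fat 2", .48), c("fat 1", "fat 3", .41),
      c("fat 1", "protein 1", .52), c("fat 1", "protein 2", .46),
      c("fat 1", "protein 3", .38),
      c("fat 2", "fat 3", .39), c("fat 2", "protein 1", .49),
      c("fat 2", "protein 2", .51), c("fat 2", "protein 3", .36),
      c("fat 3", "protein 1", .39), c("fat 3", "protein 2", .36),
      c("fat 3", "protein 3", .44),
      c("protein 1", "protein 2", .54), c("protein 1", "protein 3", .45),
      c("protein 2", "protein 3", .40)
    )
  } else {
    up <- list(
      c("milk 1", "milk 2", .10), c("milk 1", "milk 3", .08),
      c("milk 2", "milk 3", .25),
      c("milk 1", "fat 1", .62), c("milk 2", "fat 1", .03),
      c("milk 3", "fat 1", .04),
      c("milk 1", "fat 2", .07), c("milk 2", "fat 2", .59),
      c("milk 3", "fat 2", .13), c("fat 1", "fat 2", .12),
      c("milk 1", "fat 3", .03), c("milk 2", "fat 3", .17),
      c("milk 3", "fat 3", .59), c("fat 1", "fat 3", .04),
      c("fat 2", "fat 3", .17),
      c("milk 1", "protein 1", .68), c("milk 2", "protein 1", .06),
      c("milk 3", "protein 1", .07), c("fat 1", "protein 1", .57),
      c("fat 2", "protein 1", .05), c("fat 3", "protein 1", .02),
      c("milk 1", "protein 2", .07), c("milk 2", "protein 2", .62),
      c("milk 3", "protein 2", .18), c("fat 1", "protein 2", .05),
      c("fat 2", "protein 2", .51), c("fat 3", "protein 2", .14),
      c("protein 1", "protein 2", .07),
      c("milk 1", "protein 3", .05), c("milk 2", "protein 3", .19),
      c("milk 3", "protein 3", .62), c("fat 1", "protein 3", .03),
      c("fat 2", "protein 3", .14), c("fat 3", "protein 3", .51),
      c("protein 1", "protein 3", .04), c("protein 2", "protein 3", .17)
    )
  }
  for (e in up) m <- fill(m, e[1], e[2], as.numeric(e[3]))
  # shrink toward identity until positive definite (safety net)
  while (inherits(try(chol(m), silent = TRUE), "try-error")) {
    m <- 0.95 * m + 0.05 * diag(9)
    dimnames(m) <- list(lab, lab)
  }
  m
}

#' Construct a true covariance set with given average daily variances
#'
#' Builds SPD G0 and P0 from a Kronecker construction
#' `K_strata (x) Lambda`: a stratum-level covariance matrix (scales =
#' average daily variances, correlations as given) crossed with a decaying
#' diagonal coefficient profile normalized so that the average daily
#' variance over the DIM grid equals each stratum's target exactly.
#'
#' @param spec A [model_spec()].
#' @param basis Optional [legendre_basis()].
#' @param ag_mean,pe_mean Average daily AG / PE variance per stratum
#'   (recycled).
#' @param r Residual variance per stratum (recycled).
#' @param ag_cor,pe_cor Stratum correlation matrices (default identity).
#' @param decay,decay_pe Relative weights of the polynomial coefficients
#'   (first = constant term dominates, as fitted lactation curves show).
#' @return A [covariance_set()].
#' @export
make_true_params <- function(spec, basis = NULL, ag_mean, pe_mean, r,
                             ag_cor = NULL, pe_cor = NULL,
                             decay = c(1, 0.35, 0.15, 0.07, 0.03),
                             decay_pe = c(1, 0.5, 0.25, 0.12, 0.06)) {
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  ns <- spec$n_strata
  k <- spec$order
  ag_mean <- rep_len(ag_mean, ns)
  pe_mean <- rep_len(pe_mean, ns)
  r <- rep_len(r, ns)
  ag_cor <- ag_cor %||% diag(ns)
  pe_cor <- pe_cor %||% diag(ns)
  Phibar <- crossprod(basis$Phi) / length(basis$dims)
  lam <- function(dec) {
    d <- diag(rep_len(dec, k), k)
    d / sum(diag(d %*% Phibar))      # tr(Lambda Phibar) = 1
  }
  Kmat <- function(mean_v, corm) {
    d <- sqrt(mean_v)
    corm * outer(d, d)
  }
  G0 <- kronecker(Kmat(ag_mean, ag_cor), lam(decay))
  P0 <- kronecker(Kmat(pe_mean, pe_cor), lam(decay_pe))
  covariance_set(G0, P0, r, spec)
}

#' Default true parameters for simulation
#'
#' A covariance set whose implied average daily variances equal the
#' [variance_anchors()] for every trait-lactation stratum in the spec, with
#' cross-stratum correlations from the 305-d anchor tables.
#'
#' @inheritParams make_true_params
#' @return A [covariance_set()].
#' @export
default_true_params <- function(spec = model_spec(), basis = NULL) {
  anchors <- variance_anchors()
  key <- paste(spec$strata$trait, spec$strata$lactation)
  idx <- match(key, paste(anchors$trait, anchors$lactation))
  if (anyNA(idx)) {
    abort("spec contains trait/lactation without a variance anchor.")
  }
  sub <- function(m) {
    s <- m[key, key, drop = FALSE]
    while (inherits(try(chol(s), silent = TRUE), "try-error")) {
      s <- 0.95 * s + 0.05 * diag(nrow(s))
    }
    s
  }
  make_true_params(spec, basis,
                   ag_mean = anchors$ag[idx], pe_mean = anchors$pe[idx],
                   r = anchors$r[idx],
                   ag_cor = sub(anchor_correlations("ag")),
                   pe_cor = sub(anchor_correlations("pe")))
}

#' Simulation design
#'
#' Describes a synthetic population: yearly cohorts of founder sires and
#' dams with one recorded daughter per dam, monthly test-day records with
#' configurable missingness of fat/protein, lactation continuation, and an
#' optional true genetic trend imposed by shifting founder coefficient means
#' per birth year (all milk strata; kg of 305-d yield per year).
#'
#' @param spec A [model_spec()].
#' @param covset True [covariance_set()] (default [default_true_params()]).
#' @param n_years Number of birth-year cohorts.
#' @param n_sires,n_cows Founder sires and recorded cows per cohort.
#' @param n_dams Dams per cohort (default one per cow); fewer dams than cows
#'   gives full-sib families, with daughters spread evenly over dams.
#' @param n_herds Herds, shared across cohorts.
#' @param first_year First birth year.
#' @param n_tests Maximum tests per lactation.
#' @param test_interval Days between tests (plus small jitter).
#' @param continuation Probability of continuing to lactation 2 and to 3.
#' @param missing_rate Probability that fat and protein are missing on a
#'   test.
#' @param trend True genetic trend, kg of 305-d milk per birth year.
#' @param dam_from_cows If `TRUE`, cohorts after the first draw their dams
#'   from the previous cohort's recorded cows instead of new founder dams,
#'   giving recorded dam-daughter pairs (the structure that separates
#'   additive-genetic from permanent-environmental variance). If `FALSE`
#'   (default) every cohort gets its own founder dams, so a founder-mean
#'   trend maps exactly onto cohort means.
#' @param sire_from_cows If `TRUE` (with `dam_from_cows`), later cohorts
#'   draw both parents from the previous cohort's recorded cows, paired into
#'   matings: every offspring then has two recorded parents plus full sibs,
#'   the most informative structure per recorded animal for the AG/PE
#'   split.
#' @param mu Phenotypic mean per trait (kg/day), named.
#' @param sd_htm,sd_bsm Fixed-effect standard deviations, as multiples of
#'   each stratum's residual SD.
#' @param beta_age Linear and quadratic age-at-calving coefficients, as
#'   multiples of the residual SD per month (and month^2).
#' @param seed Seed stored with the design (used by [make_fixture()]).
#' @return List of class `sim_design`.
#' @export
sim_design <- function(spec = model_spec(), covset = NULL,
                       n_years = 1L, n_sires = 10L, n_cows = 100L,
                       n_dams = n_cows, n_herds = 8L, first_year = 2001L,
                       n_tests = 10L, test_interval = 30L,
                       continuation = c(0.55, 0.5),
                       missing_rate = 0.15, trend = 0,
                       dam_from_cows = FALSE, sire_from_cows = FALSE,
                       mu = c(milk = 13.1, fat = 0.47, protein = 0.41),
                       sd_htm = 0.6, sd_bsm = 0.3,
                       beta_age = c(0.02, -0.001),
                       seed = 1L) {
  covset <- covset %||% default_true_params(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(covset, "covariance_set"))
  if (any(continuation < 0 | continuation > 1) ||
      missing_rate < 0 || missing_rate > 1) {
    abort("probabilities must lie in [0, 1].")
  }
  if (n_herds < 1 || n_sires < 1 || n_cows < 1) {
    abort("population sizes must be >= 1.")
  }
  if (!all(spec$traits %in% names(mu))) {
    abort("`mu` must name every trait in the spec.")
  }
  structure(
    list(spec = spec, covset = covset, n_years = as.integer(n_years),
         n_sires = as.integer(n_sires), n_cows = as.integer(n_cows),
         n_dams = as.integer(n_dams),
         n_herds = as.integer(n_herds), first_year = as.integer(first_year),
         n_tests = as.integer(n_tests),
         test_interval = as.integer(test_interval),
         continuation = continuation, missing_rate = missing_rate,
         trend = trend, dam_from_cows = dam_from_cows,
         sire_from_cows = sire_from_cows, mu = mu, sd_htm = sd_htm, sd_bsm = sd_bsm,
         beta_age = beta_age, seed = as.integer(seed)),
    class = "sim_design"
  )
}

# joint pedigree + true-BV generation with truncation selection of parents
# on true 305-d breeding value (needed because parents must be chosen on
# BVs that exist before their offspring do)
simulate_selected_population <- function(design) {
  spec <- design$spec
  basis <- legendre_basis(spec$order, spec$dim_range)
  S <- summing_vector(basis)
  K <- spec$n_coef
  Lg <- t(chol(design$covset$G0))
  tr_strata <- which(spec$strata$trait == "milk")
  if (!length(tr_strata)) tr_strata <- 1L
  s_cols <- (tr_strata[1] - 1L) * spec$order + seq_len(spec$order)

  Lp <- t(chol(design$covset$P0))
  r_bar <- mean(design$covset$R)
  animal <- sire <- dam <- integer(0)
  year <- integer(0)
  role <- character(0)
  bv <- matrix(0, 0, K)
  pe <- matrix(0, 0, K)
  crit <- numeric(0)                 # own-record information per animal
  add_animal <- function(s, d, y, r, a) {
    animal[length(animal) + 1L] <<- length(animal) + 1L
    sire[length(sire) + 1L] <<- s
    dam[length(dam) + 1L] <<- d
    year[length(year) + 1L] <<- y
    role[length(role) + 1L] <<- r
    bv <<- rbind(bv, a)
    p <- if (r == "cow") as.numeric(Lp %*% rnorm(K)) else rep(0, K)
    pe <<- rbind(pe, p)
    # what the cow's own records reveal: average daily genetic + permanent
    # value plus the measurement error of an 8-test mean
    crit[length(crit) + 1L] <<- sum(S * (a + p)) / length(basis$dims) +
      rnorm(1, 0, sqrt(r_bar / max(design$n_tests, 1L)))
  }
  draw_founder <- function() as.numeric(Lg %*% rnorm(K))
  prev_cows <- integer(0)
  for (yi in seq_len(design$n_years)) {
    yr <- design$first_year + yi - 1L
    if (yi == 1L) {
      sires <- dams <- integer(0)
      for (i in seq_len(design$n_sires)) {
        add_animal(0L, 0L, yr, "sire", draw_founder())
        sires <- c(sires, length(animal))
      }
      for (i in seq_len(min(design$n_dams, design$n_cows))) {
        add_animal(0L, 0L, yr, "dam", draw_founder())
        dams <- c(dams, length(animal))
      }
      sire_vec <- sample(sires, design$n_cows, replace = TRUE)
      dam_vec <- rep(dams, length.out = design$n_cows)
    } else {
      # truncation selection on the cows' own-record information (the
      # criterion an animal model accounts for); the truncation point is
      # the largest group whose true 305-d BV mean advances the cohort
      # mean by the design trend
      bv305 <- as.numeric(bv[prev_cows, s_cols, drop = FALSE] %*% S)
      ord <- order(crit[prev_cows], decreasing = TRUE)
      cm <- cumsum(bv305[ord]) / seq_along(ord)
      target <- mean(bv305) + design$trend
      ok <- which(cm >= target)
      k <- if (length(ok)) max(4L, max(ok)) else max(4L, length(ord) %/% 3L)
      k <- min(k, length(ord))
      pool <- sample(prev_cows[ord[seq_len(k)]])
      n_pairs <- max(2L, length(pool) %/% 2L)
      sire_pool <- pool[seq_len(n_pairs)]
      dam_pool <- pool[n_pairs + seq_len(min(n_pairs,
                                             length(pool) - n_pairs))]
      pair <- rep(seq_along(dam_pool), length.out = design$n_cows)
      sire_vec <- sire_pool[pair]
      dam_vec <- dam_pool[pair]
    }
    # offspring: midparent + Mendelian residual with inbreeding adjustment
    F <- meuwissen_luo_f(sire, dam, length(animal))
    for (i in seq_len(design$n_cows)) {
      s <- sire_vec[i]; d <- dam_vec[i]
      w <- 0.5 - 0.25 * (F[s] + F[d])
      a <- 0.5 * (bv[s, ] + bv[d, ]) + sqrt(w) * draw_founder()
      add_animal(s, d, yr, "cow", a)
    }
    prev_cows <- which(role == "cow" & year == yr)
  }
  ped <- tibble::tibble(animal = animal, sire = sire, dam = dam,
                        birth_year = year, role = role)
  rownames(bv) <- rownames(pe) <- ped$animal
  attr(ped, "true_bv") <- bv
  attr(ped, "true_pe") <- pe
  ped
}

#' Simulate a pedigree of yearly cohorts
#'
#' Each birth-year cohort has `n_sires` founder sires, `n_cows` founder dams
#' and `n_cows` recorded daughters (random sire, one daughter per dam).
#' Cohort parents share the daughters' birth year so a founder-mean trend
#' propagates exactly.
#'
#' @param design A [sim_design()].
#' @param seed Optional seed.
#' @return Ordered pedigree tibble with a `role` column
#'   (`"sire"`/`"dam"`/`"cow"`).
#' @export
simulate_pedigree <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (design$trend != 0 && isTRUE(design$dam_from_cows) &&
      isTRUE(design$sire_from_cows)) {
    return(simulate_selected_population(design))
  }
  rows <- list()
  next_id <- 1L
  prev_cows <- integer(0)
  for (yi in seq_len(design$n_years)) {
    year <- design$first_year + yi - 1L
    sires <- next_id + seq_len(design$n_sires) - 1L
    next_id <- next_id + design$n_sires
    n_dams <- min(design$n_dams, design$n_cows)
    recycle <- isTRUE(design$dam_from_cows) && length(prev_cows) > 0L
    both_rec <- recycle && isTRUE(design$sire_from_cows) &&
      length(prev_cows) >= 4L
    if (both_rec) {
      # recorded mating pairs: both parents are previous-cohort cows
      pool <- sample(prev_cows)
      n_pairs <- length(pool) %/% 2L
      sire_pool <- pool[seq_len(n_pairs)]
      dam_pool <- pool[n_pairs + seq_len(n_pairs)]
      pair <- rep(seq_len(n_pairs), length.out = design$n_cows)
      sire_vec <- sire_pool[pair]
      dams <- dam_pool[pair]
      sires <- integer(0)
      next_id <- next_id - design$n_sires      # no founder sires this cohort
      founder_dams <- integer(0)
    } else if (recycle) {
      pool <- sample(prev_cows, min(n_dams, length(prev_cows)))
      dams <- rep(pool, length.out = design$n_cows)
      founder_dams <- integer(0)
      sire_vec <- sample(sires, design$n_cows, replace = TRUE)
    } else {
      founder_dams <- next_id + seq_len(n_dams) - 1L
      next_id <- next_id + n_dams
      dams <- rep(founder_dams, length.out = design$n_cows)
      sire_vec <- sample(sires, design$n_cows, replace = TRUE)
    }
    cows <- next_id + seq_len(design$n_cows) - 1L
    next_id <- next_id + design$n_cows
    rows[[yi]] <- tibble::tibble(
      animal = c(sires, founder_dams, cows),
      sire = c(rep(0L, length(sires) + length(founder_dams)), sire_vec),
      dam = c(rep(0L, length(sires) + length(founder_dams)), dams),
      birth_year = year,
      role = c(rep("sire", length(sires)),
               rep("dam", length(founder_dams)),
               rep("cow", design$n_cows))
    )
    prev_cows <- cows
  }
  ped <- dplyr::bind_rows(rows)
  out <- as_pedigree(ped)
  out$role <- ped$role[match(out$animal, ped$animal)]
  out
}

# recursive draw of true breeding-value coefficient vectors:
# founders N(mu_year, G0); offspring = midparent + Mendelian residual with
# covariance (0.5 - 0.25 (F_s + F_d)) G0
simulate_true_bv <- function(ped, design) {
  spec <- design$spec
  basis <- legendre_basis(spec$order, spec$dim_range)
  K <- spec$n_coef
  G0 <- design$covset$G0
  Lg <- t(chol(G0))
  n <- nrow(ped)
  pi <- ped_index(ped)
  F <- meuwissen_luo_f(pi$si, pi$di, n)
  # trend shift on the constant coefficient of every milk stratum
  shift <- matrix(0, n, K)
  if (design$trend != 0) {
    tr_strata <- which(spec$strata$trait == "milk")
    if (!length(tr_strata)) tr_strata <- 1L
    S1 <- summing_vector(basis)[1]
    dy <- ped$birth_year - min(ped$birth_year)
    for (s in tr_strata) {
      shift[, (s - 1L) * spec$order + 1L] <- design$trend * dy / S1
    }
  }
  a <- matrix(0, n, K)
  z <- matrix(rnorm(n * K), n, K)
  for (i in seq_len(n)) {
    s <- pi$si[i]; d <- pi$di[i]
    if (s == 0L && d == 0L) {
      a[i, ] <- shift[i, ] + as.numeric(Lg %*% z[i, ])
    } else {
      mp <- (if (s > 0L) a[s, ] else shift[i, ]) * 0.5 +
            (if (d > 0L) a[d, ] else shift[i, ]) * 0.5
      w <- if (s > 0L && d > 0L) {
        0.5 - 0.25 * (F[s] + F[d])
      } else if (s > 0L) {
        0.75 - 0.25 * F[s]
      } else if (d > 0L) {
        0.75 - 0.25 * F[d]
      } else 1
      a[i, ] <- mp + sqrt(w) * as.numeric(Lg %*% z[i, ])
    }
  }
  rownames(a) <- ped$animal
  a
}

#' Simulate test-day records from the generative model
#'
#' Draws true additive-genetic coefficient vectors down the pedigree
#' (Mendelian sampling), permanent-environmental vectors per cow, and builds
#' records `y = fixed effects + phi(t)' a + phi(t)' p + e` on a monthly DIM
#' grid with jitter, masking fat/protein at the design's missingness rate
#' and applying lactation drop-out.
#'
#' @param ped Pedigree from [simulate_pedigree()] (needs the `role` column).
#' @param design A [sim_design()].
#' @param seed Optional seed.
#' @return Test-day tibble with attribute `"truth"`: list with the true
#'   coefficient matrices `bv` and `pe`, the true `covset`, the fixed-effect
#'   tables and the design.
#' @export
simulate_records <- function(ped, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- design$spec
  basis <- legendre_basis(spec$order, spec$dim_range)
  pre_bv <- attr(ped, "true_bv")
  pre_pe <- attr(ped, "true_pe")
  ped <- as_pedigree(ped)
  if (!"role" %in% names(ped)) {
    abort("`ped` must carry the `role` column from simulate_pedigree().")
  }
  a_true <- if (!is.null(pre_bv)) {
    pre_bv[as.character(ped$animal), , drop = FALSE]
  } else {
    simulate_true_bv(ped, design)
  }
  cows <- ped$animal[ped$role == "cow"]
  n_cows <- length(cows)
  if (!is.null(pre_pe)) {
    p_true <- pre_pe[as.character(cows), , drop = FALSE]
  } else {
    Lp <- t(chol(design$covset$P0))
    p_true <- t(Lp %*% matrix(rnorm(n_cows * spec$n_coef), spec$n_coef))
    rownames(p_true) <- cows
  }

  cow_tbl <- tibble::tibble(
    cow = cows,
    birth_year = ped$birth_year[match(cows, ped$animal)],
    herd = sample.int(design$n_herds, n_cows, replace = TRUE),
    hf = sample(c(0.75, 0.875, 0.9375, 1), n_cows, replace = TRUE,
                prob = c(0.2, 0.35, 0.3, 0.15)),
    age1 = round(runif(n_cows, 24, 46))
  )

  recs <- list()
  for (li in seq_along(spec$lactations)) {
    lact <- spec$lactations[li]
    keep <- if (li == 1L) rep(TRUE, n_cows) else {
      recs[[li - 1L]]$continued
    }
    cont <- keep & (if (li == 1L) TRUE else
      runif(n_cows) < design$continuation[min(li - 1L,
                                              length(design$continuation))])
    age <- cow_tbl$age1 + (lact - 1L) * 13L + sample(-1:1, n_cows, TRUE)
    calv_year <- cow_tbl$birth_year + (age %/% 12L)
    calv_month <- sample.int(12L, n_cows, replace = TRUE)
    n_td <- design$n_tests
    first <- sample(5:30, n_cows, replace = TRUE)
    per_cow <- purrr::map(which(cont), function(ci) {
      dims <- cumsum(c(first[ci],
                       design$test_interval +
                         sample(-3:3, n_td - 1L, replace = TRUE)))
      dims <- dims[dims <= spec$dim_range[2]]
      mo <- calv_month[ci] - 1L + round(dims / 30.4)
      tibble::tibble(
        cow = cows[ci], lactation = lact, dim = as.integer(dims),
        test_year = as.integer(calv_year[ci] + mo %/% 12L),
        test_month = as.integer(mo %% 12L + 1L),
        herd = cow_tbl$herd[ci], age_calving = age[ci],
        hf_fraction = cow_tbl$hf[ci], calving_month = calv_month[ci]
      )
    })
    recs[[li]] <- list(rows = dplyr::bind_rows(per_cow), continued = cont)
  }
  rec <- dplyr::bind_rows(purrr::map(recs, "rows"))
  if (!nrow(rec)) abort("design produced no records.")
  rec$sire_known <- TRUE

  # fixed effects drawn once per level, scaled by each stratum's residual SD
  rec$stage <- stage_month(rec$dim)
  htm_key <- paste(rec$herd, rec$test_year, rec$test_month)
  bsm_key <- paste(rec$lactation, assign_breed_group(rec$hf_fraction),
                   as.integer(assign_season(rec$calving_month)), rec$stage)
  htm_lv <- sort(unique(htm_key))
  bsm_lv <- sort(unique(bsm_key))
  ns <- spec$n_strata
  htm_eff <- matrix(rnorm(length(htm_lv) * length(spec$traits)),
                    length(htm_lv), length(spec$traits),
                    dimnames = list(htm_lv, spec$traits))
  bsm_eff <- matrix(rnorm(length(bsm_lv) * length(spec$traits)),
                    length(bsm_lv), length(spec$traits),
                    dimnames = list(bsm_lv, spec$traits))
  age_c <- stats::ave(rec$age_calving, rec$lactation,
                      FUN = function(x) x - mean(x))
  age_c2 <- stats::ave(age_c^2, rec$lactation,
                       FUN = function(x) x - mean(x))

  phi <- leg_covariables(basis, rec$dim)
  ia <- match(rec$cow, rownames(a_true))
  ic <- match(rec$cow, rownames(p_true))
  n_rec <- nrow(rec)
  k <- spec$order
  for (tr in spec$traits) {
    strat <- stratum_of(spec, rep(tr, n_rec), rec$lactation)
    sdr <- sqrt(design$covset$R[strat])
    cols <- outer((strat - 1L) * k, seq_len(k), `+`)   # n_rec x k
    gsum <- rowSums(phi * matrix(a_true[cbind(rep(ia, k), as.integer(cols))],
                                 n_rec, k))
    psum <- rowSums(phi * matrix(p_true[cbind(rep(ic, k), as.integer(cols))],
                                 n_rec, k))
    y <- design$mu[[tr]] +
      design$sd_htm * sdr * unname(htm_eff[htm_key, tr]) +
      design$sd_bsm * sdr * unname(bsm_eff[bsm_key, tr]) +
      design$beta_age[1] * sdr * age_c +
      design$beta_age[2] * sdr * age_c2 +
      gsum + psum + rnorm(n_rec, 0, sdr)
    rec[[tr]] <- as.numeric(y)
  }
  for (tr in setdiff(c("milk", "fat", "protein"), spec$traits)) {
    rec[[tr]] <- NA_real_
  }
  if (design$missing_rate > 0 &&
      any(c("fat", "protein") %in% spec$traits)) {
    mask <- runif(nrow(rec)) < design$missing_rate
    rec$fat[mask] <- NA_real_
    rec$protein[mask] <- NA_real_
  }
  rec <- rec[, testday_cols]
  attr(rec, "truth") <- list(
    bv = a_true, pe = p_true, covset = design$covset,
    htm_eff = htm_eff, bsm_eff = bsm_eff,
    beta_age = design$beta_age, design = design
  )
  rec
}

#' Write a synthetic fixture to disk
#'
#' Builds a deterministic pedigree + test-day fixture at one of three
#' scales: `"tiny"` (under 50 animals, single trait, order 2 — unit tests),
#' `"small"` (500 recorded cows, single trait — recovery tests),
#' `"paper_shaped"` (all 9 strata, order 5, reduced cow count — smoke
#' tests). Truth files (true coefficient vectors and covariance components)
#' are written alongside.
#'
#' @param scale `"tiny"`, `"small"` or `"paper_shaped"`.
#' @param seed Integer seed; the same seed gives byte-identical files.
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper_shaped"),
                         seed = 1L, dir = tempdir()) {
  scale <- match.arg(scale)
  set.seed(seed)
  design <- switch(scale,
    tiny = sim_design(
      spec = model_spec("milk", 1L, order = 2L),
      covset = make_true_params(model_spec("milk", 1L, order = 2L),
                                ag_mean = 4, pe_mean = 4, r = 2),
      n_years = 2L, n_sires = 3L, n_cows = 10L, n_herds = 2L,
      n_tests = 8L, missing_rate = 0, seed = seed),
    small = sim_design(
      spec = model_spec("milk", 1L, order = 2L),
      covset = make_true_params(model_spec("milk", 1L, order = 2L),
                                ag_mean = 4, pe_mean = 4, r = 2),
      n_years = 1L, n_sires = 25L, n_cows = 500L, n_herds = 8L,
      n_tests = 8L, missing_rate = 0, seed = seed),
    paper_shaped = sim_design(
      spec = model_spec(), n_years = 2L, n_sires = 5L, n_cows = 40L,
      n_herds = 4L, n_tests = 11L, missing_rate = 0.15, seed = seed)
  )
  ped <- simulate_pedigree(design)
  rec <- simulate_records(ped, design)
  truth <- attr(rec, "truth")
  colnames(truth$bv) <- paste0("coef", seq_len(ncol(truth$bv)))
  g0 <- truth$covset$G0
  p0 <- truth$covset$P0
  dimnames(g0) <- dimnames(p0) <-
    list(NULL, paste0("c", seq_len(ncol(g0))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    pedigree = file.path(dir, sprintf("%s_pedigree.csv", scale)),
    testday = file.path(dir, sprintf("%s_testday.csv", scale)),
    truth_bv = file.path(dir, sprintf("%s_truth_bv.csv", scale)),
    truth_g0 = file.path(dir, sprintf("%s_truth_g0.csv", scale)),
    truth_p0 = file.path(dir, sprintf("%s_truth_p0.csv", scale)),
    truth_r = file.path(dir, sprintf("%s_truth_r.csv", scale))
  )
  write_pedigree(ped, paths$pedigree)
  write_testday(rec, paths$testday)
  readr::write_csv(tibble::as_tibble(truth$bv, rownames = "animal"),
                   paths$truth_bv)
  readr::write_csv(tibble::as_tibble(g0), paths$truth_g0)
  readr::write_csv(tibble::as_tibble(p0), paths$truth_p0)
  readr::write_csv(tibble::tibble(stratum = seq_along(truth$covset$R),
                                  r = truth$covset$R), paths$truth_r)
  invisible(paths)
}

#' Predefined validation study designs
#'
#' Two fixed synthetic designs used by the package's validation suite.
#'
#' `recovery_design()` is the variance-component recovery study: a single
#' trait, single lactation, order-2 model with true average daily variances
#' AG = 4, PE = 4, R = 2 (true average daily heritability 0.40), 500
#' recorded cows in two cohorts of 250 with 8 tests each. The second
#' cohort's sires and dams are both recorded first-cohort cows (mating
#' pairs), the pedigree structure that carries the most information per
#' recorded animal about the AG/PE split.
#'
#' `trend_design()` is the selection-response study: milk in lactations 1-3
#' (order 2), eleven yearly cohorts of 150 recorded cows whose parents are
#' selected recorded cows of the previous cohort, with the truncation point
#' calibrated so the true 305-d breeding value advances `trend` kg per
#' year. The genetic scale is set to a 305-d genetic SD of 40 kg so the
#' imposed trend is an intense-selection regime (about a quarter of a
#' genetic SD per year); records over three lactations spread each cow's
#' tests across calendar years, which ties birth cohorts together inside
#' herd-year-month classes and makes the trend estimable.
#'
#' @param trend True genetic trend for the trend study (kg/yr).
#' @return A [sim_design()].
#' @export
recovery_design <- function() {
  spec <- model_spec("milk", 1L, order = 2L)
  covset <- make_true_params(spec, ag_mean = 4, pe_mean = 4, r = 2)
  sim_design(spec = spec, covset = covset, n_years = 2L, n_sires = 25L,
             n_cows = 250L, n_herds = 8L, n_tests = 8L, missing_rate = 0,
             dam_from_cows = TRUE, sire_from_cows = TRUE)
}

#' @rdname recovery_design
#' @export
trend_design <- function(trend = 10) {
  spec <- model_spec("milk", 1:3, order = 2L)
  basis <- legendre_basis(2L)
  S <- summing_vector(basis)
  lam1 <- make_true_params(model_spec("milk", 1L, order = 2L),
                           ag_mean = 1, pe_mean = 1, r = 1)$G0
  ag <- 40^2 / drop(S %*% lam1 %*% S)      # 305-d genetic SD of 40 kg
  cors <- matrix(0.9, 3, 3); diag(cors) <- 1
  pcors <- matrix(0.2, 3, 3); diag(pcors) <- 1
  covset <- make_true_params(spec, ag_mean = ag, pe_mean = 0.3 * ag,
                             r = 0.02, ag_cor = cors, pe_cor = pcors)
  sim_design(spec = spec, covset = covset, n_years = 11L, n_sires = 50L,
             n_cows = 150L, n_herds = 3L, n_tests = 8L, missing_rate = 0,
             continuation = c(0.9, 0.9), trend = trend,
             dam_from_cows = TRUE, sire_from_cows = TRUE)
}
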