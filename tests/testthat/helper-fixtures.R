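# shared fixture builders (everything generated in code)

# random valid pedigree with inbred loops: parents always earlier animals
random_pedigree <- function(n, n_founders = max(4L, n %/% 8L)) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    pair <- sample.int(i - 1L, 2L)
    sire[i] <- pair[1]
    dam[i] <- pair[2]
  }
  as_pedigree(tibble::tibble(animal = seq_len(n), sire = sire, dam = dam,
                             birth_year = 2000L + (seq_len(n) %% 7L)))
}

# a single clean cow-lactation record set
clean_cowlact <- function(cow, lactation = 1L, dims = c(10L, 40L, 70L, 100L,
                                                        130L, 160L),
                          age = 30, milk = 15, sire_known = TRUE) {
  tibble::tibble(
    cow = cow, lactation = lactation, dim = dims,
    test_year = 2005L, test_month = pmin(12L, 1L + dims %/% 30L),
    herd = 1L, milk = milk, fat = 0.5, protein = 0.45,
    age_calving = age, hf_fraction = 0.9, calving_month = 1L,
    sire_known = sire_known
  )
}

# eight cow-lactations violating exactly one edit rule each, plus one clean
edit_fixture <- function() {
  dplyr::bind_rows(
    clean_cowlact(1L),
    # milk out of bounds on one of five raw tests -> 4 valid tests
    dplyr::mutate(clean_cowlact(2L, dims = c(10L, 40L, 70L, 100L, 160L)),
                  milk = c(15, 41, 15, 15, 15)),
    # DIM beyond 305 on one of five raw tests
    dplyr::mutate(clean_cowlact(3L, dims = c(10L, 40L, 70L, 160L, 310L))),
    # first test too late
    clean_cowlact(4L, dims = c(40L, 70L, 100L, 130L, 160L)),
    # only four tests
    clean_cowlact(5L, dims = c(10L, 60L, 110L, 160L)),
    # last test before 150 DIM
    clean_cowlact(6L, dims = c(10L, 40L, 70L, 100L, 130L)),
    # age outside the first-lactation window
    clean_cowlact(7L, age = 50),
    # lactation 2 without a first lactation
    clean_cowlact(8L, lactation = 2L, age = 44),
    # unidentified sire
    clean_cowlact(9L, sire_known = FALSE)
  )
}

# small single-trait simulation bundle used across tests
tiny_sim <- function(seed = 1L, n_cows = 20L, n_sires = 4L, n_tests = 6L,
                     order = 2L, ag = 4, pe = 4, r = 2, ...) {
  spec <- model_spec("milk", 1L, order = order)
  covset <- make_true_params(spec, ag_mean = ag, pe_mean = pe, r = r)
  des <- sim_design(spec = spec, covset = covset, n_sires = n_sires,
                    n_cows = n_cows, n_herds = 2L, n_tests = n_tests,
                    missing_rate = 0, ...)
  set.seed(seed)
  ped <- simulate_pedigree(des)
  rec <- simulate_records(ped, des)
  list(spec = spec, covset = covset, design = des, ped = ped, rec = rec)
}

# independent dense construction of the mixed-model equations, from first
# principles: explicit incidence matrices and base-R kronecker/solve
dense_mme_oracle <- function(records, ped, covset, spec) {
  basis <- legendre_basis(spec$order, spec$dim_range)
  rec <- build_effect_coding(records)
  obs <- tidyr::pivot_longer(
    rec, dplyr::any_of(spec$traits), names_to = "trait", values_to = "y")
  obs <- obs[!is.na(obs$y), ]
  n <- nrow(obs)
  fx_key <- c(paste0("htm:", obs$trait, ":", obs$htm),
              paste0("bsm:", obs$trait, ":", obs$bsm),
              paste0("age1:", obs$trait, ":", obs$lactation),
              paste0("age2:", obs$trait, ":", obs$lactation))
  fx_val <- c(rep(1, n), rep(1, n), obs$age_c, obs$age_c2)
  lev <- sort(unique(fx_key))
  X <- matrix(0, n, length(lev))
  X[cbind(rep(seq_len(n), 4L), match(fx_key, lev))] <- fx_val
  K <- spec$n_coef
  ped <- as_pedigree(ped)
  cows <- sort(unique(records$cow))
  Za <- matrix(0, n, K * nrow(ped))
  Zp <- matrix(0, n, K * length(cows))
  phi <- leg_covariables(basis, obs$dim)
  st <- rrtdm:::stratum_of(spec, obs$trait, obs$lactation)
  for (i in seq_len(n)) {
    cols <- (st[i] - 1L) * spec$order + seq_len(spec$order)
    ia <- match(obs$cow[i], ped$animal)
    ic <- match(obs$cow[i], cows)
    Za[i, (ia - 1L) * K + cols] <- phi[i, ]
    Zp[i, (ic - 1L) * K + cols] <- phi[i, ]
  }
  M <- cbind(X, Za, Zp)
  w <- 1 / covset$R[st]
  A <- build_A(ped)
  prior <- matrix(0, ncol(M), ncol(M))
  gi <- ncol(X) + seq_len(K * nrow(ped))
  pi <- ncol(X) + K * nrow(ped) + seq_len(K * length(cows))
  prior[gi, gi] <- kronecker(solve(A), solve(covset$G0))
  prior[pi, pi] <- kronecker(diag(length(cows)), solve(covset$P0))
  list(C = t(M) %*% (w * M) + prior, rhs = as.numeric(t(M) %*% (w * obs$y)))
}
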