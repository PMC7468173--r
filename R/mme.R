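#' Assemble the mixed-model equations
#'
#' Builds Henderson's mixed-model equations for the random regression
#' test-day model `y = Xb + Q(Za + Wp) + e`: fixed effects (herd-year-month
#' of test per trait, breed-season-stage per trait, linear and quadratic age
#' at calving per trait and lactation), additive-genetic regression
#' coefficients per pedigree animal with precision `A^-1 (x) G0^-1`, and
#' permanent-environmental coefficients per cow with records with precision
#' `I (x) P0^-1`. The Legendre covariables are folded into the incidence
#' rows at assembly. A record contributes one observation row per
#' non-missing trait; traits on one test day are residual-independent
#' (diagonal R), so rows are weighted by their stratum residual variance.
#'
#' @param records Edited test-day tibble; coding columns are added with
#'   [build_effect_coding()] when absent.
#' @param ped Pedigree accepted by [as_pedigree()]. Every record cow must
#'   appear in it.
#' @param covset A [covariance_set()].
#' @param spec A [model_spec()]; defaults to the spec inside `covset`.
#' @param basis A [legendre_basis()]; defaults to the spec's order and range.
#' @return An object of class `mme_system`: sparse symmetric `C`, `rhs`,
#'   observation matrix `W` with `y`, `stratum` and weights, the equation
#'   map, the Gibbs block table, and the pedigree/cow orderings.
#' @export
assemble_mme <- function(records, ped, covset, spec = covset$spec,
                         basis = NULL) {
  stopifnot(inherits(covset, "covariance_set"), inherits(spec, "model_spec"))
  ped <- as_pedigree(ped)
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  if (basis$order != spec$order) abort("basis order differs from model spec.")
  rec <- tibble::as_tibble(records)
  if (!all(c("htm", "bsm", "age_c", "age_c2") %in% names(rec))) {
    rec <- build_effect_coding(rec)
  }
  miss <- setdiff(unique(rec$cow), ped$animal)
  if (length(miss)) {
    abort(sprintf("record cow(s) absent from pedigree: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  if (any(rec$dim < spec$dim_range[1] | rec$dim > spec$dim_range[2])) {
    abort("records contain DIM outside the model range; apply edits first.")
  }
  if (!all(rec$lactation %in% spec$lactations)) {
    abort("records contain lactations outside the model spec.")
  }

  # one observation row per present trait
  obs <- rec |>
    dplyr::select(dplyr::all_of(c("cow", "lactation", "dim", "htm", "bsm",
                                  "age_c", "age_c2")),
                  dplyr::any_of(spec$traits)) |>
    tidyr::pivot_longer(dplyr::any_of(spec$traits), names_to = "trait",
                        values_to = "y") |>
    dplyr::filter(!is.na(.data$y))
  n_obs <- nrow(obs)
  if (!n_obs && nrow(rec)) {
    abort("no observations after removing missing traits.")
  }
  obs$stratum <- stratum_of(spec, obs$trait, obs$lactation)

  # ---- fixed-effect columns (built from the data, per trait);
  #      paste0 recycles zero-length inputs, so guard the empty case
  if (n_obs > 0L) {
    fx_key <- c(paste0("htm:", obs$trait, ":", obs$htm),
                paste0("bsm:", obs$trait, ":", obs$bsm),
                paste0("age1:", obs$trait, ":", obs$lactation),
                paste0("age2:", obs$trait, ":", obs$lactation))
    fx_val <- c(rep(1, n_obs), rep(1, n_obs), obs$age_c, obs$age_c2)
  } else {
    fx_key <- character(0)
    fx_val <- numeric(0)
  }
  fixed_levels <- sort(unique(fx_key))
  n_fixed <- length(fixed_levels)
  fx_col <- match(fx_key, fixed_levels)

  k <- spec$order
  K <- spec$n_coef
  n_anim <- nrow(ped)
  cow_ids <- sort(unique(rec$cow))
  n_cows <- length(cow_ids)
  off_ag <- n_fixed
  off_pe <- n_fixed + K * n_anim
  n_eq <- n_fixed + K * (n_anim + n_cows)

  phi <- leg_covariables(basis, obs$dim)            # n_obs x k
  ia <- match(obs$cow, ped$animal)
  ic <- match(obs$cow, cow_ids)
  scol <- (obs$stratum - 1L) * k                     # stratum offset

  if (n_obs > 0L) {
    rows <- c(rep(seq_len(n_obs), 4L),
              rep(seq_len(n_obs), each = k),
              rep(seq_len(n_obs), each = k))
    cols <- c(fx_col,
              off_ag + rep((ia - 1L) * K + scol, each = k) + seq_len(k),
              off_pe + rep((ic - 1L) * K + scol, each = k) + seq_len(k))
    vals <- c(fx_val, as.numeric(t(phi)), as.numeric(t(phi)))
    W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c(n_obs, n_eq))
  } else {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(0L, n_eq))
  }

  w <- 1 / covset$R[obs$stratum]
  C_data <- Matrix::t(W) %*% (w * W)
  G0inv <- chol2inv(chol(covset$G0))
  P0inv <- chol2inv(chol(covset$P0))
  Ainv <- build_A_inverse(ped)
  prior <- Matrix::bdiag(
    Matrix::Matrix(0, n_fixed, n_fixed, sparse = TRUE),
    Matrix::kronecker(Ainv, G0inv),
    Matrix::kronecker(Matrix::Diagonal(n_cows), P0inv)
  )
  C <- Matrix::forceSymmetric(C_data + prior)
  rhs <- as.numeric(Matrix::t(W) %*% (w * obs$y))

  eq_map <- tibble::tibble(
    col = seq_len(n_eq),
    effect = c(fixed_levels,
               paste0("ag:", rep(ped$animal, each = K)),
               if (n_cows > 0L) paste0("pe:", rep(cow_ids, each = K))
               else character(0))
  )
  # Gibbs blocks: scalar fixed effects; animals without records get a pure
  # AG block; a recorded cow's AG and PE vectors are drawn as one joint
  # block (their sum is data-pinned, so separate updates mix poorly)
  cow_of_animal <- match(ped$animal, cow_ids)
  has_rec <- !is.na(cow_of_animal)
  blocks <- dplyr::bind_rows(
    tibble::tibble(start = seq_len(n_fixed), size = 1L, type = 0L,
                   index = seq_len(n_fixed), start2 = 0L, index2 = 0L),
    tibble::tibble(start = off_ag + (which(!has_rec) - 1L) * K + 1L,
                   size = K, type = 1L, index = which(!has_rec),
                   start2 = 0L, index2 = 0L),
    tibble::tibble(start = off_ag + (which(has_rec) - 1L) * K + 1L,
                   size = K, type = 3L, index = which(has_rec),
                   start2 = off_pe +
                     (cow_of_animal[has_rec] - 1L) * K + 1L,
                   index2 = cow_of_animal[has_rec])
  )

  structure(
    list(C = C, rhs = rhs, W = W, y = obs$y, stratum = obs$stratum,
         weights = w, eq_map = eq_map, blocks = blocks,
         n_eq = n_eq, n_fixed = n_fixed, n_animals = n_anim,
         n_cows = n_cows, animal_ids = ped$animal, cow_ids = cow_ids,
         ped = ped, Ainv = Ainv, covset = covset, spec = spec,
         basis = basis),
    class = "mme_system"
  )
}

#' @export
print.mme_system <- function(x, ...) {
  cat(sprintf(
    "<mme_system> %d equations (%d fixed, %d animals x %d, %d cows x %d), %d observations\n",
    x$n_eq, x$n_fixed, x$n_animals, x$spec$n_coef, x$n_cows, x$spec$n_coef,
    length(x$y)))
  invisible(x)
}

#' Preconditioned conjugate gradient solver
#'
#' Solves the assembled mixed-model equations with Jacobi (diagonal)
#' preconditioning from a zero start. Rank-deficient fixed-effect blocks are
#' tolerated: on the singular but consistent system, CG converges to a
#' particular solution in which estimable functions (EBVs, contrasts) are
#' unique.
#'
#' @param system An `mme_system` from [assemble_mme()].
#' @param tol Relative residual tolerance `||C x - rhs|| / ||rhs||`.
#' @param max_iter Iteration cap; if reached, the achieved residual is
#'   reported with a warning.
#' @return An object of class `mme_fit`: `solution`, `iterations`,
#'   `rel_residual`, `converged`, and the originating system.
#' @export
solve_mme <- function(system, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(system, "mme_system"))
  res <- pcg_solve(system$C, system$rhs, tol = tol, max_iter = max_iter)
  structure(c(res, list(system = system)), class = "mme_fit")
}

pcg_solve <- function(C, b, tol = 1e-10, max_iter = 10000L, x0 = NULL) {
  M <- Matrix::diag(C)
  M[M <= 0] <- 1
  x <- x0 %||% numeric(length(b))
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(solution = x, iterations = 0L, rel_residual = 0,
                converged = TRUE))
  }
  r <- b - as.numeric(C %*% x)
  z <- r / M
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Cp <- as.numeric(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel <= tol) {
      return(list(solution = x, iterations = it, rel_residual = rel,
                  converged = TRUE))
    }
    z <- r / M
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warn(sprintf("PCG stopped at max_iter = %d with relative residual %.3e",
               max_iter, rel))
  list(solution = x, iterations = max_iter, rel_residual = rel,
       converged = FALSE)
}

#' @export
print.mme_fit <- function(x, ...) {
  cat(sprintf("<mme_fit> %d equations, %d PCG iterations, residual %.2e\n",
              length(x$solution), x$iterations, x$rel_residual))
  invisible(x)
}

#' 305-day estimated breeding values
#'
#' Turns solved additive-genetic regression coefficients into 305-day EBVs:
#' for each animal and trait-lactation stratum, `EBV = S' a_block` with `S`
#' the summed Legendre covariables over the DIM grid.
#'
#' @param fit An `mme_fit` from [solve_mme()], or a bare solution vector
#'   together with `system`.
#' @param system The `mme_system` (taken from the fit when omitted).
#' @return Tibble with `animal`, `trait`, `lactation`, `ebv` and the raw
#'   coefficient vector in list-column `coef`.
#' @export
extract_ebv <- function(fit, system = NULL) {
  if (inherits(fit, "mme_fit")) {
    system <- system %||% fit$system
    sol <- fit$solution
  } else {
    if (is.null(system)) abort("supply the mme_system with a bare solution.")
    sol <- as.numeric(fit)
  }
  spec <- system$spec
  K <- spec$n_coef
  S <- summing_vector(system$basis)
  off <- system$n_fixed
  A <- matrix(sol[off + seq_len(K * system$n_animals)],
              nrow = system$n_animals, ncol = K, byrow = TRUE)
  out <- tidyr::expand_grid(animal = system$animal_ids,
                            spec$strata)
  # per stratum: S' a
  ebv <- matrix(0, system$n_animals, spec$n_strata)
  for (s in seq_len(spec$n_strata)) {
    ebv[, s] <- A[, stratum_cols(spec, s), drop = FALSE] %*% S
  }
  # row order of `out` is animal-major, strata within animal
  out$ebv <- as.numeric(t(ebv))
  coefs <- vector("list", nrow(out))
  for (i in seq_len(system$n_animals)) {
    for (s in seq_len(spec$n_strata)) {
      coefs[[(i - 1L) * spec$n_strata + s]] <-
        A[i, stratum_cols(spec, s)]
    }
  }
  out$coef <- coefs
  dplyr::select(out, "animal", "trait", "lactation", "ebv", "coef")
}

#' One-call BLUP pipeline
#'
#' Assembles and solves the mixed-model equations and extracts 305-day EBVs.
#'
#' @inheritParams assemble_mme
#' @inheritParams solve_mme
#' @return The EBV tibble from [extract_ebv()], with the `mme_fit` attached
#'   as attribute `"fit"`.
#' @export
blup_ebv <- function(records, ped, covset, spec = covset$spec,
                     basis = NULL, tol = 1e-10, max_iter = 10000L) {
  sys <- assemble_mme(records, ped, covset, spec, basis)
  fit <- solve_mme(sys, tol = tol, max_iter = max_iter)
  ebv <- extract_ebv(fit)
  attr(ebv, "fit") <- fit
  ebv
}
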