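#' Specify the random regression test-day model
#'
#' Defines the traits, lactations, polynomial order and DIM range of the
#' model. The default is the full 3-trait (milk, fat, protein), 3-lactation
#' model with order-5 Legendre regressions, i.e. 45 additive-genetic and 45
#' permanent-environmental regression coefficients per animal/cow and 9
#' trait-lactation strata with their own residual variances.
#'
#' Coefficients are laid out stratum-major within an animal: strata are
#' ordered by lactation, traits within lactation (lactation 1: milk, fat,
#' protein; then lactation 2; ...), and each stratum holds `order`
#' consecutive coefficients (constant first).
#'
#' @param traits Character vector of trait names.
#' @param lactations Integer vector of lactation numbers (subset of 1:3).
#' @param order Legendre polynomial order (default 5).
#' @param dim_range Inclusive DIM range (default `c(5L, 305L)`).
#' @return An object of class `model_spec` with a `strata` tibble
#'   (`stratum`, `lactation`, `trait`) and `n_coef = order * n_strata`.
#' @examples
#' model_spec()                                   # full 45-coefficient model
#' model_spec("milk", 1L, order = 2L)             # scaled-down single stratum
#' @export
model_spec <- function(traits = c("milk", "fat", "protein"),
                       lactations = 1:3,
                       order = 5L,
                       dim_range = c(5L, 305L)) {
  if (!is.character(traits) || !length(traits) || anyDuplicated(traits)) {
    abort("`traits` must be distinct trait names.")
  }
  if (!is_whole(lactations) || !all(lactations %in% 1:3) ||
      anyDuplicated(lactations)) {
    abort("`lactations` must be distinct values in 1:3.")
  }
  if (!is_whole(order) || order < 1L) abort("`order` must be an integer >= 1.")
  lactations <- sort(as.integer(lactations))
  strata <- tidyr::expand_grid(lactation = lactations, trait = traits) |>
    dplyr::mutate(stratum = dplyr::row_number(), .before = 1)
  structure(
    list(traits = traits, lactations = lactations, order = as.integer(order),
         dim_range = as.integer(dim_range), strata = strata,
         n_strata = nrow(strata), n_coef = as.integer(order) * nrow(strata)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %d trait(s) x %d lactation(s), order %d: %d coefficients/animal, %d strata\n",
    length(x$traits), length(x$lactations), x$order, x$n_coef, x$n_strata))
  invisible(x)
}

# column index range of stratum s within one animal's coefficient block
stratum_cols <- function(spec, s) {
  (s - 1L) * spec$order + seq_len(spec$order)
}

# stratum id for trait/lactation pairs
stratum_of <- function(spec, trait, lactation) {
  key <- paste(lactation, trait)
  out <- match(key, paste(spec$strata$lactation, spec$strata$trait))
  if (anyNA(out)) abort("trait/lactation not in model spec.")
  out
}

#' Covariance components of the random regression model
#'
#' Bundles the additive-genetic (G0) and permanent-environmental (P0)
#' regression-coefficient covariance matrices and the per-stratum residual
#' variances R. G0 and P0 are `n_coef` x `n_coef` symmetric positive
#' definite; R has one positive value per trait-lactation stratum and is
#' constant along DIM.
#'
#' @param G0,P0 SPD matrices of dimension `spec$n_coef`.
#' @param R Positive numeric vector of length `spec$n_strata`.
#' @param spec A [model_spec()].
#' @return An object of class `covariance_set`.
#' @export
covariance_set <- function(G0, P0, R, spec) {
  stopifnot(inherits(spec, "model_spec"))
  G0 <- check_spd(as.matrix(G0), "G0")
  P0 <- check_spd(as.matrix(P0), "P0")
  if (nrow(G0) != spec$n_coef || nrow(P0) != spec$n_coef) {
    abort(sprintf("G0 and P0 must be %d x %d for this model spec.",
                  spec$n_coef, spec$n_coef))
  }
  R <- as.numeric(R)
  if (length(R) != spec$n_strata || any(!is.finite(R)) || any(R <= 0)) {
    abort(sprintf("R must be %d positive residual variances.", spec$n_strata))
  }
  structure(list(G0 = G0, P0 = P0, R = R, spec = spec),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat(sprintf("<covariance_set> G0, P0: %d x %d; R: %d strata\n",
              nrow(x$G0), ncol(x$G0), length(x$R)))
  invisible(x)
}

# G0/P0 block for strata (s, t): order x order submatrix
cov_block <- function(M, spec, s, t = s) {
  M[stratum_cols(spec, s), stratum_cols(spec, t), drop = FALSE]
}
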