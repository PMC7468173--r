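#' Orthonormal Legendre covariables for days in milk
#'
#' Random regression test-day models carry all the days-in-milk (DIM)
#' dependence of the additive-genetic and permanent-environmental effects in
#' a small set of covariables: Legendre polynomials evaluated on DIM
#' standardized to \eqn{[-1, 1]}, scaled to be orthonormal,
#' \deqn{\phi_j(t) = \sqrt{(2j+1)/2}\, P_j(x(t)), \quad j = 0, \dots, k-1,}
#' with \eqn{P_j} the classical Legendre polynomial and \eqn{x(t)} the
#' standardized DIM. The default order 5 gives the constant, linear,
#' quadratic, cubic and quartic terms used in national dairy evaluations.
#'
#' The basis also carries the summing vector \eqn{S_j = \sum_t \phi_j(t)}
#' over the integer DIM grid, which turns regression-coefficient solutions
#' and (co)variances into 305-day aggregates.
#'
#' @param order Number of polynomial terms \eqn{k} (order 5 = constant
#'   through quartic). Must be at least 1.
#' @param dim_range Integer vector of length 2, the inclusive DIM range
#'   covered by the model (default `c(5L, 305L)`, the usual 301-day grid).
#'
#' @return An object of class `legendre_basis`: a list with elements
#'   `order`, `dim_range`, `dims` (the integer DIM grid), `Phi` (grid x
#'   order covariable matrix) and `S` (column sums of `Phi`).
#'
#' @examples
#' b <- legendre_basis(order = 5)
#' b$S[1]                     # 301 / sqrt(2)
#' leg_covariables(b, 155)    # covariables at mid lactation
#' @export
legendre_basis <- function(order = 5L, dim_range = c(5L, 305L)) {
  if (!is_whole(order) || length(order) != 1L || order < 1L) {
    abort("`order` must be a single integer >= 1.")
  }
  if (!is_whole(dim_range) || length(dim_range) != 2L ||
      dim_range[1] >= dim_range[2]) {
    abort("`dim_range` must be two integers with min < max.")
  }
  order <- as.integer(order)
  dim_range <- as.integer(dim_range)
  dims <- seq.int(dim_range[1], dim_range[2])
  Phi <- legendre_phi(standardize_dim(dims, dim_range), order)
  rownames(Phi) <- dims
  colnames(Phi) <- paste0("phi", seq_len(order) - 1L)
  structure(
    list(order = order, dim_range = dim_range, dims = dims,
         Phi = Phi, S = colSums(Phi)),
    class = "legendre_basis"
  )
}

#' Standardize days in milk to the polynomial domain
#'
#' Maps integer DIM linearly onto \eqn{[-1, 1]}:
#' \eqn{x = -1 + 2 (t - t_{min}) / (t_{max} - t_{min})}.
#'
#' @param t Vector of DIM values.
#' @param dim_range Inclusive DIM range, as in [legendre_basis()].
#' @return Numeric vector in \eqn{[-1, 1]}.
#' @export
standardize_dim <- function(t, dim_range = c(5L, 305L)) {
  if (any(t < dim_range[1] | t > dim_range[2])) {
    abort(sprintf("DIM out of range [%d, %d].", dim_range[1], dim_range[2]))
  }
  -1 + 2 * (t - dim_range[1]) / (dim_range[2] - dim_range[1])
}

# orthonormal Legendre values by the three-term recurrence
# (j+1) P_{j+1} = (2j+1) x P_j - j P_{j-1}
legendre_phi <- function(x, order) {
  n <- length(x)
  P <- matrix(0, n, order)
  P[, 1] <- 1
  if (order >= 2L) P[, 2] <- x
  if (order >= 3L) {
    for (j in 1L:(order - 2L)) {
      P[, j + 2L] <- ((2 * j + 1) * x * P[, j + 1L] - j * P[, j]) / (j + 1)
    }
  }
  sweep(P, 2L, sqrt((2 * seq_len(order) - 1) / 2), `*`)
}

#' Evaluate basis covariables at given DIM
#'
#' @param basis A [legendre_basis()].
#' @param t Vector of integer DIM values inside the basis range.
#' @return Matrix `length(t)` x `order` of covariables \eqn{\phi_j(t)}.
#' @export
leg_covariables <- function(basis, t) {
  stopifnot(inherits(basis, "legendre_basis"))
  if (!is_whole(t)) abort("`t` must be integer DIM values.")
  if (any(t < basis$dim_range[1] | t > basis$dim_range[2])) {
    abort(sprintf("DIM out of range [%d, %d].",
                  basis$dim_range[1], basis$dim_range[2]))
  }
  basis$Phi[as.character(t), , drop = FALSE]
}

#' Summing vector for 305-day aggregation
#'
#' Column sums of the covariable matrix over the integer DIM grid; the same
#' vector applies to milk, fat and protein. A regression-coefficient vector
#' `a` for one trait-lactation has 305-day total \eqn{S^\top a}.
#'
#' @param basis A [legendre_basis()].
#' @return Numeric vector of length `order`.
#' @export
summing_vector <- function(basis) {
  stopifnot(inherits(basis, "legendre_basis"))
  basis$S
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("<legendre_basis> order %d on DIM [%d, %d] (%d days)\n",
              x$order, x$dim_range[1], x$dim_range[2], length(x$dims)))
  invisible(x)
}

#' Plot the basis functions over days in milk
#'
#' @param object A [legendre_basis()].
#' @param ... Unused.
#' @return A ggplot object, one line per polynomial term.
#' @method autoplot legendre_basis
#' @export
autoplot.legendre_basis <- function(object, ...) {
  df <- tibble::as_tibble(object$Phi) |>
    dplyr::mutate(dim = object$dims) |>
    tidyr::pivot_longer(-"dim", names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$dim, .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Days in milk", y = expression(phi[j](t)),
                  colour = NULL)
}
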