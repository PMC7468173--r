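#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries of a Gibbs fit
#'
#' One row per (co)variance component with posterior mean and SD: the
#' average daily AG and PE variances per stratum (the published-table scale)
#' and the residual variances.
#'
#' @param x A `gibbs_fit` from [run_gibbs()].
#' @param ... Unused.
#' @return Tibble with `component`, `trait`, `lactation`, `estimate`,
#'   `std_error`.
#' @method tidy gibbs_fit
#' @export
tidy.gibbs_fit <- function(x, ...) {
  spec <- x$spec
  basis <- legendre_basis(spec$order, spec$dim_range)
  Phibar <- crossprod(basis$Phi) / length(basis$dims)
  nd <- x$retained
  avg_daily <- function(draws, s) {
    cols <- stratum_cols(spec, s)
    vapply(seq_len(nd), function(i) {
      sum(draws[cols, cols, i] * Phibar)
    }, numeric(1))
  }
  rows <- purrr::map_dfr(seq_len(spec$n_strata), function(s) {
    ag <- avg_daily(x$G0_draws, s)
    pe <- avg_daily(x$P0_draws, s)
    r <- x$R_draws[, s]
    tibble::tibble(
      component = c("ag", "pe", "r"),
      trait = spec$strata$trait[s],
      lactation = spec$strata$lactation[s],
      estimate = c(mean(ag), mean(pe), mean(r)),
      std_error = c(stats::sd(ag), stats::sd(pe), stats::sd(r))
    )
  })
  rows
}

#' @param x A `gibbs_fit`.
#' @param ... Unused.
#' @rdname tidy.gibbs_fit
#' @return [glance.gibbs_fit()]: one-row tibble with chain settings and
#'   retained-draw count.
#' @method glance gibbs_fit
#' @export
glance.gibbs_fit <- function(x, ...) {
  tibble::tibble(
    chain = x$chain, burn_in = x$burn_in, thin = x$thin,
    retained = x$retained, n_coef = x$spec$n_coef,
    n_strata = x$spec$n_strata,
    n_animals = x$system$n_animals, n_cows = x$system$n_cows,
    n_obs = length(x$system$y)
  )
}

#' Trace plot of average daily variance draws
#'
#' @param object A `gibbs_fit`.
#' @param ... Unused.
#' @return A ggplot: retained draws of the average daily AG, PE and residual
#'   variances per stratum.
#' @method autoplot gibbs_fit
#' @export
autoplot.gibbs_fit <- function(object, ...) {
  spec <- object$spec
  basis <- legendre_basis(spec$order, spec$dim_range)
  Phibar <- crossprod(basis$Phi) / length(basis$dims)
  df <- purrr::map_dfr(seq_len(spec$n_strata), function(s) {
    cols <- stratum_cols(spec, s)
    nd <- object$retained
    tibble::tibble(
      draw = rep(seq_len(nd), 3L),
      component = rep(c("ag", "pe", "r"), each = nd),
      stratum = paste0(spec$strata$trait[s], " L",
                       spec$strata$lactation[s]),
      value = c(
        vapply(seq_len(nd),
               function(i) sum(object$G0_draws[cols, cols, i] * Phibar),
               numeric(1)),
        vapply(seq_len(nd),
               function(i) sum(object$P0_draws[cols, cols, i] * Phibar),
               numeric(1)),
        object$R_draws[, s])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$draw, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "Retained draw", y = "Average daily variance",
                  colour = NULL)
}

#' Tidy a trend fit
#'
#' @param x A `trend_fit` from [genetic_trend()].
#' @param ... Unused.
#' @return Long tibble with one row per trait-lactation-term.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("intercept", "slope"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::mutate(std_error = ifelse(.data$term == "intercept",
                                     .data$se_intercept, .data$se_slope)) |>
    dplyr::select("trait", "lactation", "term", "estimate", "std_error",
                  "r_squared", "n_years")
}

#' @param x A `trend_fit`.
#' @param ... Unused.
#' @rdname tidy.trend_fit
#' @return [glance.trend_fit()]: one row per trait-lactation with slope and
#'   fit quality.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("trait", "lactation", "slope", "se_slope",
                           "r_squared", "n_years")]
}

#' Plot daily heritability curves
#'
#' @param covset A [covariance_set()].
#' @param basis Optional [legendre_basis()].
#' @return A ggplot of h2 against DIM, one line per lactation, facetted by
#'   trait.
#' @export
plot_daily_h2 <- function(covset, basis = NULL) {
  df <- daily_h2(covset, basis)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim, .data$h2,
                                   colour = factor(.data$lactation))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "Days in milk", y = expression(h^2),
                  colour = "Lactation")
}

#' Plot genetic trends
#'
#' @param ebv EBV tibble from [extract_ebv()].
#' @param birth_years Pedigree tibble or vector, see [genetic_trend()].
#' @return A ggplot of yearly mean EBV against birth year with the fitted
#'   regression line, facetted by trait and lactation.
#' @export
plot_trend <- function(ebv, birth_years) {
  if (is.data.frame(birth_years)) {
    by <- birth_years$birth_year[match(ebv$animal, birth_years$animal)]
  } else {
    by <- rep_len(as.numeric(birth_years), nrow(ebv))
  }
  df <- ebv |>
    dplyr::mutate(birth_year = by) |>
    dplyr::filter(!is.na(.data$birth_year)) |>
    dplyr::group_by(.data$trait, .data$lactation, .data$birth_year) |>
    dplyr::summarise(mean_ebv = mean(.data$ebv), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$birth_year, .data$mean_ebv)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_grid(trait ~ lactation, scales = "free_y") +
    ggplot2::labs(x = "Birth year", y = "Mean 305-d EBV")
}
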